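## Internal helpers shared across modules.

# Display rounding: one decimal, full precision kept upstream.
round1 <- function(x) round(x, 1)

fmt1 <- function(x) {
  ifelse(is.na(x), "N/A", sprintf("%.1f", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lmt <- function(..., class = "lmt_error") {
  stop(structure(
    class = c(class, "lmt_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

slugify <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == trunc(x)

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
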