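#' Configuration for the synthetic assessment generator
#'
#' No real assessment data from the published pilot is available (it is
#' confidential), so every downstream module is exercised against seeded
#' synthetic assessments. Each subcategory is drawn independently: blank
#' with probability `blank_rate`, Not applicable with probability
#' `na_rate`, otherwise answered with a level drawn from
#' `level_distribution`.
#'
#' @param seed Integer master seed (< 2^31).
#' @param level_distribution Probabilities over levels 1..4 (summing to 1),
#'   either a numeric vector of length 4 (global) or a list of such
#'   vectors with a `default` entry plus per-area-id overrides, which is
#'   the mechanism tests use to build cohorts with known between-area
#'   structure.
#' @param blank_rate,na_rate Per-item probabilities; `blank_rate + na_rate`
#'   must be <= 1.
#' @param n_labs Number of laboratories for [generate_cohort()].
#' @param label_prefix Label prefix for generated assessments.
#' @return An object of class `lmt_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             level_distribution = rep(0.25, 4),
                             blank_rate = 0, na_rate = 0,
                             n_labs = 1L, label_prefix = "lab") {
  check_dist <- function(p, what) {
    if (!is.numeric(p) || length(p) != 4L || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9)
      stop_lmt(what, " must be 4 non-negative probabilities summing to 1")
  }
  if (is.list(level_distribution)) {
    if (is.null(level_distribution$default))
      stop_lmt("per-area level_distribution needs a 'default' entry")
    for (nm in names(level_distribution))
      check_dist(level_distribution[[nm]],
                 paste0("level_distribution$", nm))
  } else {
    check_dist(level_distribution, "level_distribution")
  }
  if (blank_rate < 0 || na_rate < 0 || blank_rate + na_rate > 1)
    stop_lmt("need blank_rate >= 0, na_rate >= 0, blank_rate + na_rate <= 1")
  if (!is_count(n_labs) || n_labs < 1) stop_lmt("n_labs must be >= 1")
  if (!is_count(abs(seed)) || abs(seed) >= 2^31)
    stop_lmt("seed must be an integer below 2^31")
  structure(
    list(seed = as.integer(seed), level_distribution = level_distribution,
         blank_rate = blank_rate, na_rate = na_rate,
         n_labs = as.integer(n_labs), label_prefix = label_prefix),
    class = "lmt_generator_config"
  )
}

# Documented seed-derivation rule: lab k (1-based) uses
# (seed + k * 7919) mod (2^31 - 1), so any single laboratory of a cohort
# can be regenerated on its own.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + as.double(k) * 7919) %% (2^31 - 1))
}

#' Generate one synthetic assessment
#'
#' Deterministic under a fixed config: the same config always yields the
#' same assessment. The caller's RNG stream is left untouched.
#'
#' @param cfg An `lmt_generator_config`.
#' @param t An `lmt_taxonomy`.
#' @param label Assessment label (default `"<label_prefix>-1"`).
#' @param seed Override seed (used internally for cohort members).
#' @return An `lmt_assessment`.
#' @export
generate_assessment <- function(cfg, t, label = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "lmt_generator_config"),
            inherits(t, "lmt_taxonomy"))
  idx <- taxonomy_index(t)
  dist_for_area <- function(area_id) {
    if (is.list(cfg$level_distribution))
      cfg$level_distribution[[area_id]] %||% cfg$level_distribution$default
    else cfg$level_distribution
  }
  vals <- with_seed(seed, {
    vapply(seq_len(nrow(idx)), function(i) {
      p_lv <- dist_for_area(idx$area_id[i])
      p_ans <- 1 - cfg$blank_rate - cfg$na_rate
      sample(c("", "NA", "1", "2", "3", "4"), 1L,
             prob = c(cfg$blank_rate, cfg$na_rate, p_ans * p_lv))
    }, "")
  })
  names(vals) <- idx$subcategory_id
  vals <- vals[vals != ""]   # absent entry is the canonical blank
  new_assessment(vals,
                 label = label %||% paste0(cfg$label_prefix, "-1"),
                 lab_info = list(name = label %||%
                                   paste0(cfg$label_prefix, "-1")))
}

#' Generate a cohort of synthetic laboratories
#'
#' Laboratories are independent; each lab's seed is derived reproducibly
#' from the master seed (see the seed-derivation rule in
#' [generate_assessment()]), so two runs with the same config produce
#' byte-identical cohorts.
#'
#' @param cfg An `lmt_generator_config` (uses `n_labs`, `label_prefix`).
#' @param t An `lmt_taxonomy`.
#' @return List of `lmt_assessment` of length `cfg$n_labs`.
#' @export
generate_cohort <- function(cfg, t) {
  stopifnot(inherits(cfg, "lmt_generator_config"))
  lapply(seq_len(cfg$n_labs), function(k) {
    generate_assessment(cfg, t,
                        label = paste0(cfg$label_prefix, "-", k),
                        seed = derive_seed(cfg$seed, k))
  })
}

#' Construct an assessment hitting a target overall score
#'
#' Deterministically solves, by brute-force search over (number answered,
#' level sum), for the response vector whose exclude-policy overall
#' percent is closest to `target` (at full precision), then realizes it:
#' the first `n` subcategories in instrument order are answered with
#' levels as equal as possible summing to `S`, the rest are left blank.
#' Used to build synthetic exemplars that reproduce published score
#' progressions (e.g. a 43.8 baseline and a 55.6 follow-up).
#'
#' @param target Target overall percent in \[25, 100\].
#' @param t An `lmt_taxonomy`.
#' @param label Assessment label.
#' @return An `lmt_assessment` whose `score_assessment(..., "exclude")`
#'   overall percent rounds (1 decimal) to the closest achievable value
#'   to `target`.
#' @export
assessment_with_overall <- function(target, t, label = "synthetic") {
  if (target < 25 || target > 100)
    stop_lmt("target must be in [25, 100] (the exclude-policy range)")
  idx <- taxonomy_index(t)
  n_tot <- nrow(idx)
  best <- NULL
  for (n in seq_len(n_tot)) {
    S <- round(target * n / 25)        # overall = 25 * S / n
    for (Sc in unique(pmin(4L * n, pmax(n, S + (-1:1))))) {
      err <- abs(25 * Sc / n - target)
      if (is.null(best) || err < best$err - 1e-12)
        best <- list(n = n, S = Sc, err = err)
    }
  }
  n <- best$n; S <- best$S
  base <- S %/% n; rem <- S %% n
  levels <- c(rep(base + 1L, rem), rep(base, n - rem))
  vals <- setNames(as.character(levels), idx$subcategory_id[seq_len(n)])
  new_assessment(vals, label = label)
}
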