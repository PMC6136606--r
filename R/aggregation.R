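#' Summarize a cohort of laboratories
#'
#' Aggregates many laboratories' score reports into per-scope cohort
#' statistics — mean, sample standard deviation (n-1 denominator), min,
#' max and the number of laboratories with a defined score — in the shape
#' of a regional summary table, plus a discrepancy ranking of scopes by
#' inter-laboratory SD. Laboratories whose score at a scope is Undefined
#' are excluded from that scope's statistics. Output is anonymous by
#' default: it carries the laboratory count, never labels, unless
#' `named = TRUE`.
#'
#' @param reports List of `lmt_score_report`, all scored against the same
#'   taxonomy and policy.
#' @param named Include assessment labels in the summary (default FALSE).
#' @return An object of class `lmt_cohort_summary`: list with `n_labs`,
#'   `policy`, `taxonomy`, `per_scope` (data.frame: `scope_level`,
#'   `scope_id`, `scope_name`, `mean`, `sd`, `min`, `max`, `n_defined`;
#'   `sd` is `NA` when `n_defined < 2`), `discrepancy_metric` (`"sd"`)
#'   and, when `named`, `labels`.
#' @export
aggregate_reports <- function(reports, named = FALSE) {
  if (length(reports) == 0L) stop_lmt("empty cohort")
  stopifnot(all(vapply(reports, inherits, TRUE, "lmt_score_report")))
  pol <- unique(vapply(reports, `[[`, "", "policy"))
  tax <- unique(vapply(reports, function(r)
    paste(r$taxonomy$name, r$taxonomy$version, sep = "@"), ""))
  if (length(pol) != 1L)
    stop_lmt("mixed blank policies in cohort: ", paste(pol, collapse = ", "))
  if (length(tax) != 1L)
    stop_lmt("mixed taxonomies in cohort: ", paste(tax, collapse = ", "))

  base <- report_scopes(reports[[1L]])
  mat <- vapply(reports, function(r) report_scopes(r)$percent,
                numeric(nrow(base)))
  mat <- matrix(mat, nrow = nrow(base))
  per_scope <- base[, c("scope_level", "scope_id", "scope_name")]
  per_scope$n_defined <- rowSums(!is.na(mat))
  per_scope$mean <- ifelse(per_scope$n_defined >= 1L,
                           rowMeans(mat, na.rm = TRUE), NA_real_)
  per_scope$sd <- apply(mat, 1L, function(x)
    if (sum(!is.na(x)) >= 2L) stats::sd(x, na.rm = TRUE) else NA_real_)
  per_scope$min <- suppressWarnings(apply(mat, 1L, min, na.rm = TRUE))
  per_scope$max <- suppressWarnings(apply(mat, 1L, max, na.rm = TRUE))
  per_scope$min[!is.finite(per_scope$min)] <- NA_real_
  per_scope$max[!is.finite(per_scope$max)] <- NA_real_
  per_scope <- per_scope[, c("scope_level", "scope_id", "scope_name",
                             "mean", "sd", "min", "max", "n_defined")]
  out <- list(n_labs = length(reports), policy = pol,
              taxonomy = reports[[1L]]$taxonomy,
              per_scope = per_scope, discrepancy_metric = "sd")
  if (isTRUE(named))
    out$labels <- vapply(reports, `[[`, "", "label")
  structure(out, class = "lmt_cohort_summary")
}

#' Rank scopes by inter-laboratory discrepancy
#'
#' Orders areas or categories by descending inter-laboratory sample SD of
#' their percentage scores — the scopes on which laboratories differ the
#' most. Ties (including the all-identical cohort, where every SD is 0)
#' are broken by instrument order.
#'
#' @param reports List of at least 2 `lmt_score_report`s (same taxonomy
#'   and policy).
#' @param level `"area"` or `"category"`.
#' @return Data.frame of scopes sorted by descending `sd` with columns as
#'   in [aggregate_reports()]'s `per_scope`.
#' @export
discrepancy_ranking <- function(reports, level = c("category", "area")) {
  level <- match.arg(level)
  if (length(reports) < 2L)
    stop_lmt("discrepancy ranking needs at least 2 reports")
  ps <- aggregate_reports(reports)$per_scope
  ps <- ps[ps$scope_level == level, , drop = FALSE]
  ps$.ord <- seq_len(nrow(ps))
  sd_key <- ifelse(is.na(ps$sd), -Inf, ps$sd)
  ps <- ps[order(-sd_key, ps$.ord), , drop = FALSE]
  ps$.ord <- NULL
  rownames(ps) <- NULL
  ps
}

# "41.3 (±14.2); range 13–64%" — the published summary-cell grammar.
# Mean/SD one decimal; range endpoints as printed integers.
format_cohort_cell <- function(mean, sd, min, max) {
  if (is.na(mean)) return("N/A")
  rng <- sprintf("range %d–%d%%", as.integer(round(min)),
                 as.integer(round(max)))
  if (is.na(sd)) sprintf("%.1f; %s", mean, rng)
  else sprintf("%.1f (±%.1f); %s", mean, sd, rng)
}

#' @export
format.lmt_cohort_summary <- function(x, level = c("area", "category", "all"),
                                      ...) {
  level <- match.arg(level)
  ps <- x$per_scope
  keep <- if (level == "all") rep(TRUE, nrow(ps)) else
    ps$scope_level %in% c("overall", level)
  ps <- ps[keep, , drop = FALSE]
  cells <- mapply(format_cohort_cell, ps$mean, ps$sd, ps$min, ps$max)
  header <- sprintf("Cohort summary (n = %d laboratories, policy: %s)",
                    x$n_labs, x$policy)
  paste(c(header,
          sprintf("  %-55s %s", ps$scope_name, cells)),
        collapse = "\n")
}

#' @export
print.lmt_cohort_summary <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}
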