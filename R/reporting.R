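#' Radar-chart geometry for score reports
#'
#' Pure computation behind [render_radar()], exposed so the geometry is
#' testable and deterministic: axis angles (first axis at 12 o'clock,
#' proceeding clockwise in instrument order), the five 20-point band
#' radii, and one polygon per report with `NA` vertices at Undefined
#' scopes (the polygon breaks there rather than interpolating).
#'
#' @param reports One `lmt_score_report` or a list of 1..3.
#' @param level `"area"` or `"category"`.
#' @return List with `axes` (data.frame: `scope_id`, `scope_name`,
#'   `angle`), `bands` (data.frame: `band`, `r_inner`, `r_outer`,
#'   `color`), and `series` (list per report: `label`, `color`, `percent`,
#'   `x`, `y` on a 0--100 radial scale).
#' @export
radar_coords <- function(reports, level = c("area", "category")) {
  level <- match.arg(level)
  if (inherits(reports, "lmt_score_report")) reports <- list(reports)
  if (length(reports) == 0L) stop_lmt("no reports to render")
  if (length(reports) > 3L)
    stop_lmt("radar overlays at most 3 reports (got ", length(reports), ")")
  stopifnot(all(vapply(reports, inherits, TRUE, "lmt_score_report")))
  tax <- unique(vapply(reports, function(r)
    paste(r$taxonomy$name, r$taxonomy$version, sep = "@"), ""))
  if (length(tax) != 1L) stop_lmt("reports use different taxonomies")

  sc <- if (level == "area") reports[[1L]]$per_area else
    reports[[1L]]$per_category
  k <- nrow(sc)
  angle <- pi / 2 - 2 * pi * (seq_len(k) - 1L) / k   # clockwise from top
  axes <- data.frame(scope_id = sc$scope_id, scope_name = sc$scope_name,
                     angle = angle, stringsAsFactors = FALSE)

  # five concentric bands, red (bottom band) to green (top band)
  band_cols <- grDevices::colorRampPalette(
    c("#d73027", "#fc8d59", "#fee08b", "#a6d96a", "#1a9850"))(5)
  bands <- data.frame(band = 0:4, r_inner = seq(0, 80, 20),
                      r_outer = seq(20, 100, 20), color = band_cols,
                      stringsAsFactors = FALSE)

  series_cols <- c("#1f77b4", "#d62728", "#7f7f7f")  # blue, red, grey
  series <- lapply(seq_along(reports), function(j) {
    r <- if (level == "area") reports[[j]]$per_area else
      reports[[j]]$per_category
    p <- r$percent
    list(label = reports[[j]]$label, color = series_cols[j], percent = p,
         x = p * cos(angle), y = p * sin(angle))
  })
  list(axes = axes, bands = bands, series = series)
}

#' Render a color-coded radar chart
#'
#' One axis per area or category in instrument order, five concentric
#' shaded rings at 20-percent intervals (green at the top band, red at
#' the bottom), and one polygon per report — the first series blue, the
#' second red, a third grey. The radial scale is fixed at 0--100
#' regardless of the data so charts are comparable across laboratories
#' and over time. Undefined scopes leave a gap in the polygon.
#'
#' @param reports One `lmt_score_report` or a list of 1..3 (e.g. baseline
#'   and follow-up).
#' @param out Output image path; the device is chosen by extension
#'   (`.png` or `.pdf`).
#' @param level `"area"` or `"category"`.
#' @param width,height Device size in inches.
#' @return `out`, invisibly.
#' @export
render_radar <- function(reports, out, level = c("area", "category"),
                         width = 7, height = 7) {
  level <- match.arg(level)
  g <- radar_coords(reports, level)
  ext <- tolower(tools::file_ext(out))
  switch(ext,
         png = grDevices::png(out, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(out, width = width, height = height),
         stop_lmt("unsupported image extension '.", ext,
                  "' (use .png or .pdf)"))
  on.exit(grDevices::dev.off())

  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot(NA, xlim = c(-130, 130), ylim = c(-130, 130), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  th <- seq(0, 2 * pi, length.out = 181)
  for (i in rev(seq_len(nrow(g$bands)))) {
    graphics::polygon(g$bands$r_outer[i] * cos(th),
                      g$bands$r_outer[i] * sin(th),
                      col = grDevices::adjustcolor(g$bands$color[i], 0.35),
                      border = "grey70")
  }
  for (i in seq_len(nrow(g$axes))) {
    a <- g$axes$angle[i]
    graphics::segments(0, 0, 100 * cos(a), 100 * sin(a), col = "grey60")
    graphics::text(115 * cos(a), 115 * sin(a), g$axes$scope_name[i],
                   cex = 0.6)
  }
  for (s in g$series) {
    ok <- !is.na(s$percent)
    # close the polygon only through defined vertices; NAs break the line
    xs <- s$x; ys <- s$y
    if (all(ok)) { xs <- c(xs, xs[1L]); ys <- c(ys, ys[1L]) }
    graphics::lines(xs, ys, col = s$color, lwd = 2)
    graphics::points(s$x[ok], s$y[ok], col = s$color, pch = 19, cex = 0.7)
  }
  graphics::legend("topleft",
                   legend = vapply(g$series, `[[`, "", "label"),
                   col = vapply(g$series, `[[`, "", "color"),
                   lwd = 2, bty = "n", cex = 0.8)
  graphics::title(main = sprintf("Safety and biosecurity scores by %s",
                                 level))
  invisible(out)
}

#' Tabulate one or more score reports
#'
#' Rows are the overall score, the areas and the categories in instrument
#' order; one column per assessment. Percentages are shown to one
#' decimal; Undefined scopes render as `"N/A"`. A completion/confidence
#' line per assessment is appended.
#'
#' @param reports One `lmt_score_report` or a list.
#' @return An object of class `lmt_summary_table` (a data.frame of
#'   formatted cells with a `confidence` attribute); its
#'   [format()]/[print()] methods produce the human-readable table.
#' @export
render_summary_tables <- function(reports) {
  if (inherits(reports, "lmt_score_report")) reports <- list(reports)
  if (length(reports) == 0L) stop_lmt("no reports to tabulate")
  stopifnot(all(vapply(reports, inherits, TRUE, "lmt_score_report")))
  base <- report_scopes(reports[[1L]])
  out <- base[, c("scope_level", "scope_id", "scope_name")]
  for (r in reports) {
    sc <- report_scopes(r)
    if (!identical(sc$scope_id, out$scope_id))
      stop_lmt("reports use different taxonomies")
    out[[r$label]] <- fmt1(sc$percent)
  }
  conf <- vapply(reports, function(r)
    sprintf("completion %s%%, confidence %s", fmt1(r$completion_percent),
            r$confidence_band), "")
  names(conf) <- vapply(reports, `[[`, "", "label")
  structure(out, class = c("lmt_summary_table", "data.frame"),
            confidence = conf)
}

#' @export
format.lmt_summary_table <- function(x, ...) {
  labels <- setdiff(names(x), c("scope_level", "scope_id", "scope_name"))
  widths <- pmax(nchar(labels), 6L)
  w <- max(nchar(x$scope_name)) + 2L
  header <- sprintf("%-*s %s", w, "scope",
                    paste(sprintf("%*s", widths, labels), collapse = "  "))
  rows <- vapply(seq_len(nrow(x)), function(i) {
    ind <- if (x$scope_level[i] == "category") "  " else ""
    cells <- vapply(seq_along(labels), function(j)
      sprintf("%*s", widths[j], x[[labels[j]]][i]), "")
    sprintf("%-*s %s", w, paste0(ind, x$scope_name[i]),
            paste(cells, collapse = "  "))
  }, "")
  conf <- attr(x, "confidence")
  c(header, rows,
    sprintf("%s: %s", names(conf), unname(conf)))
}

#' @export
print.lmt_summary_table <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
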