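# Fixed-ROI germ-layer intensity quantification and per-line two-tailed
# t tests with up/down/unchanged calls.

#' Measure mean reporter intensity in circular germ-layer ROIs
#'
#' Places a circular ROI of constant pixel radius at each region's
#' normalized (AP, DV) coordinates and reports the mean reporter intensity
#' inside it. All ROI pixels must fall inside the embryo mask.
#'
#' @param image an `embryo_image` or reporter matrix.
#' @param frame an `embryo_frame` or `embryo_geometry`.
#' @param mask optional `embryo_mask`/logical matrix; defaults to the
#'   frame's ellipse.
#' @param roi_radius ROI radius in pixels.
#' @param region_defs named list of `c(ap, dv)` centers (defaults to
#'   lateral/ventral/posterior = ectoderm/mesoderm/endoderm).
#' @param embryo_id optional id carried through.
#' @return Object of class `region_triplet`: list with `values` (named
#'   numeric), `roi_radius`, `region_defs`, `embryo_id`.
#' @export
measure_regions <- function(image, frame, mask = NULL, roi_radius = 15,
                            region_defs = default_region_defs(),
                            embryo_id = NA) {
  rep_ch <- if (inherits(image, "embryo_image")) image$reporter else image
  if (!is.matrix(rep_ch)) ee_input_error("`image` must be an embryo_image or matrix")
  if (roi_radius <= 0) ee_input_error("`roi_radius` must be positive")
  nr <- nrow(rep_ch); nc <- ncol(rep_ch)
  m <- if (is.null(mask)) {
    geom <- embryo_geometry(frame$a, frame$b, frame$center, frame$angle,
                            anterior = if (identical(frame$anterior, "right"))
                              "right" else "left")
    ellipse_mask(geom, c(nr, nc))
  } else if (inherits(mask, "embryo_mask")) mask$mask else mask
  vals <- vapply(names(region_defs), function(rn) {
    rd <- region_defs[[rn]]
    ctr <- norm_to_pixel(frame, rd[1], rd[2])
    rr <- max(1L, floor(ctr$row - roi_radius)):min(nr, ceiling(ctr$row + roi_radius))
    cc <- max(1L, floor(ctr$col - roi_radius)):min(nc, ceiling(ctr$col + roi_radius))
    disk <- outer(rr, cc, function(R, C)
      (R - ctr$row)^2 + (C - ctr$col)^2 <= roi_radius^2)
    if (ctr$row - roi_radius < 1 || ctr$row + roi_radius > nr ||
        ctr$col - roi_radius < 1 || ctr$col + roi_radius > nc ||
        !all(m[rr, cc][disk])) {
      ee_placement_error(sprintf(
        "ROI for region '%s' leaves the embryo mask", rn))
    }
    mean(rep_ch[rr, cc][disk])
  }, numeric(1))
  structure(list(values = vals, roi_radius = roi_radius,
                 region_defs = region_defs, embryo_id = embryo_id),
            class = "region_triplet")
}

#' @export
print.region_triplet <- function(x, ...) {
  cat("region_triplet:",
      paste(sprintf("%s=%.2f", names(x$values), x$values), collapse = ", "),
      "\n")
  invisible(x)
}

#' Two-sample two-tailed t test (pooled variance)
#'
#' Student's two-sample statistic with pooled variance,
#' `t = (mean(a) - mean(b)) / sqrt(sp2 * (1/n1 + 1/n2))` with
#' `sp2 = ((n1-1) var(a) + (n2-1) var(b)) / (n1+n2-2)`, and the two-sided
#' p from the t distribution with `n1+n2-2` degrees of freedom. When the
#' pooled variance is zero, p is 1 for equal means (by convention) and 0
#' otherwise. Set `welch = TRUE` for the unequal-variance form.
#'
#' @param a,b numeric samples, each with >= 2 observations.
#' @param welch use the Welch-Satterthwaite statistic instead of the
#'   pooled-variance default.
#' @return List with `t`, `p`, `df`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
two_tailed_t <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) ee_input_error("both samples need >= 2 observations")
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      return(list(t = 0, p = if (m1 == m2) 1 else 0, df = NA_real_,
                  mean_a = m1, mean_b = m2, n_a = n1, n_b = n2))
    }
    t_stat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    if (sp2 == 0) {
      return(list(t = if (m1 == m2) 0 else Inf * sign(m1 - m2),
                  p = if (m1 == m2) 1 else 0, df = df,
                  mean_a = m1, mean_b = m2, n_a = n1, n_b = n2))
    }
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, p = p, df = df, mean_a = m1, mean_b = m2,
       n_a = n1, n_b = n2)
}

#' Classify a line against control by expression level
#'
#' Runs [two_tailed_t()] and calls the line `"up"` or `"down"` by the sign
#' of the mean difference when p < alpha, `"unchanged"` otherwise. No
#' multiple-testing correction is applied per call; apply
#' [stats::p.adjust()] across lines if a corrected table is needed.
#'
#' @param line_values,control_values numeric samples (>= 2 each).
#' @param alpha significance level.
#' @param line_id optional id carried through.
#' @param welch passed to [two_tailed_t()].
#' @return Object of class `line_comparison`: list with `line_id`, `n_line`,
#'   `n_control`, `mean_line`, `mean_control`, `t`, `p`, `alpha`, `call`.
#' @export
classify_line <- function(line_values, control_values, alpha = 0.05,
                          line_id = NA, welch = FALSE) {
  tt <- two_tailed_t(line_values, control_values, welch = welch)
  call <- if (tt$p >= alpha) "unchanged"
          else if (tt$mean_a > tt$mean_b) "up" else "down"
  structure(list(line_id = line_id, n_line = tt$n_a, n_control = tt$n_b,
                 mean_line = tt$mean_a, mean_control = tt$mean_b,
                 t = tt$t, p = tt$p, alpha = alpha, call = call),
            class = "line_comparison")
}

#' @export
print.line_comparison <- function(x, ...) {
  cat(sprintf(
    "line_comparison [%s]: mean %.3f vs control %.3f, t = %.3f, p = %.4g -> %s\n",
    x$line_id, x$mean_line, x$mean_control, x$t, x$p, x$call))
  invisible(x)
}
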