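# Normalized anterior-posterior expression profiles: central-band column
# averaging, Gaussian conditioning, posterior-tail quantile normalization,
# and embryo-level bootstrap confidence bands.

#' Extract a raw AP intensity profile from the reporter channel
#'
#' Averages reporter intensity over a central band covering
#' `band_fraction` of the embryo height, per pixel position along the AP
#' axis. The band is taken in the fitted frame (no image resampling):
#' every pixel inside mask and band contributes to the column given by its
#' AP-axis coordinate.
#'
#' @param image an `embryo_image` or reporter matrix.
#' @param frame a resolved `embryo_frame` (or `embryo_geometry` with known
#'   anterior end).
#' @param mask optional `embryo_mask`/logical matrix restricting the band.
#' @param band_fraction fraction of embryo height in the band (0, 1].
#' @return Numeric vector over AP pixel columns (anterior first); columns
#'   with no band pixels are NA. Attribute `L` carries the egg length.
#' @export
extract_ap_profile <- function(image, frame, mask = NULL,
                               band_fraction = 0.30) {
  rep_ch <- if (inherits(image, "embryo_image")) image$reporter else image
  if (!is.matrix(rep_ch)) ee_input_error("`image` must be an embryo_image or matrix")
  if (!band_fraction > 0 || band_fraction > 1) {
    ee_input_error("`band_fraction` must be in (0, 1]")
  }
  if (is.null(frame$anterior) || frame$anterior == "unresolved") {
    ee_orientation_error("frame anterior end is unresolved")
  }
  nr <- nrow(rep_ch); nc <- ncol(rep_ch)
  m <- if (is.null(mask)) matrix(TRUE, nr, nc)
       else if (inherits(mask, "embryo_mask")) mask$mask else mask
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  nn <- pixel_to_norm(frame, as.vector(rows), as.vector(cols))
  L <- 2 * frame$a
  H <- 2 * frame$b
  # distance from the AP midline in px; band = central band_fraction of H
  d_px <- (0.5 - nn$dv) * H
  in_band <- abs(d_px) <= band_fraction * H / 2 & as.vector(m) &
    nn$ap >= 0 & nn$ap <= 1
  ncol_out <- max(2L, ceiling(L))
  colidx <- pmin(pmax(floor(nn$ap * ncol_out) + 1L, 1L), ncol_out)
  sel <- which(in_band)
  sums <- rowsum(as.vector(rep_ch)[sel], colidx[sel])
  cnts <- rowsum(rep(1, length(sel)), colidx[sel])
  prof <- rep(NA_real_, ncol_out)
  prof[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
  structure(prof, L = L)
}

#' Smooth and resample a raw profile onto a fixed AP grid
#'
#' Gaussian-smooths the raw pixel-column profile (edge-renormalized kernel,
#' so constant profiles are invariant) and linearly interpolates it onto a
#' fixed grid of `n_samples` points spanning AP \[0, 1\]. Missing columns
#' are linearly interpolated before smoothing.
#'
#' @param raw numeric vector from [extract_ap_profile()].
#' @param sigma smoothing sd as an AP (egg-length) fraction; 0 disables.
#' @param n_samples number of grid points (>= 2).
#' @return Object of class `ap_profile`: list with `samples`, `grid`, and
#'   `provenance` (parameters used).
#' @export
condition_profile <- function(raw, sigma = 0.01, n_samples = 1000L) {
  raw <- as.numeric(raw)
  if (length(raw) < 2L) ee_input_error("raw profile must have >= 2 points")
  if (sigma < 0) ee_input_error("`sigma` must be >= 0")
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) ee_input_error("`n_samples` must be >= 2")
  n <- length(raw)
  if (anyNA(raw)) {
    ok <- which(!is.na(raw))
    if (length(ok) < 2L) ee_input_error("profile has fewer than 2 finite points")
    raw <- stats::approx(ok, raw[ok], xout = seq_len(n), rule = 2)$y
  }
  if (sigma > 0) {
    s_px <- sigma * n
    half <- max(1L, ceiling(4 * s_px))
    k <- stats::dnorm(seq(-half, half), sd = s_px)
    padded <- c(rep(NA, half), raw, rep(NA, half))
    sm <- vapply(seq_len(n), function(i) {
      w <- padded[i:(i + 2 * half)]
      valid <- !is.na(w)
      sum(w[valid] * k[valid]) / sum(k[valid])
    }, numeric(1))
  } else sm <- raw
  grid_in <- (seq_len(n) - 0.5) / n
  grid_out <- seq(0, 1, length.out = n_samples)
  out <- stats::approx(grid_in, sm, xout = grid_out, rule = 2)$y
  structure(list(samples = out, grid = grid_out,
                 provenance = list(sigma = sigma, n_samples = n_samples,
                                   n_raw = n)),
            class = "ap_profile")
}

#' Normalize a profile to its posterior tail
#'
#' Background removal and normalization against the posterior
#' `tail_fraction` of the egg length: with `Q_bg` and `Q_norm` the
#' `q_bg`- and `q_norm`-quantiles (linear interpolation between order
#' statistics) of the tail samples, the profile maps to
#' `(I - Q_bg) / (Q_norm - Q_bg)`. The transform is affine-invariant; the
#' tail's `q_bg` quantile maps to 0 and its `q_norm` quantile to 1.
#'
#' @param profile an `ap_profile`.
#' @param tail_fraction posterior fraction of the AP axis used (default
#'   last 20% of egg length).
#' @param q_bg,q_norm background / normalization quantiles.
#' @param tol minimum `Q_norm - Q_bg`; a flatter tail raises a
#'   degenerate-normalization error.
#' @return The normalized `ap_profile`, provenance extended with
#'   `tail_fraction`, `q_bg`, `q_norm`, `Q_bg`, `Q_norm`.
#' @export
normalize_profile <- function(profile, tail_fraction = 0.20,
                              q_bg = 0.10, q_norm = 0.50, tol = 1e-9) {
  stopifnot(inherits(profile, "ap_profile"))
  if (!(tail_fraction > 0 && tail_fraction < 1)) {
    ee_input_error("`tail_fraction` must be in (0, 1)")
  }
  tail_idx <- profile$grid >= 1 - tail_fraction
  if (sum(tail_idx) < 2L) ee_input_error("posterior tail region is degenerate")
  tail_vals <- profile$samples[tail_idx]
  Q <- stats::quantile(tail_vals, c(q_bg, q_norm), names = FALSE, type = 7)
  if (Q[2] - Q[1] < tol) {
    ee_degenerate_error("flat posterior tail: normalization quantiles coincide")
  }
  profile$samples <- (profile$samples - Q[1]) / (Q[2] - Q[1])
  profile$provenance <- c(profile$provenance,
                          list(tail_fraction = tail_fraction, q_bg = q_bg,
                               q_norm = q_norm, Q_bg = Q[1], Q_norm = Q[2]))
  profile
}

#' @export
print.ap_profile <- function(x, ...) {
  cat(sprintf("ap_profile: %d samples on [0,1], range [%.3g, %.3g]\n",
              length(x$samples), min(x$samples), max(x$samples)))
  invisible(x)
}

#' Bootstrap confidence band over embryo profiles
#'
#' Resamples embryos (profiles, not pixels) with replacement `n_boot`
#' times; the band envelopes are the pointwise `(1 - ci)/2` and
#' `(1 + ci)/2` quantiles of the resampled mean profiles.
#'
#' @param profiles list of `ap_profile` objects on identical grids (>= 2).
#' @param n_boot number of bootstrap replicates.
#' @param ci confidence level (e.g. 0.95).
#' @param seed integer RNG seed.
#' @return Object of class `bootstrap_band`: list with `grid`, `mean`,
#'   `lower`, `upper`, `n_boot`, `ci`, `n_profiles`, `seed`.
#' @export
bootstrap_band <- function(profiles, n_boot = 1000L, ci = 0.95, seed = 1L) {
  if (length(profiles) < 2L) ee_input_error("need >= 2 profiles")
  grids <- lapply(profiles, `[[`, "grid")
  if (!all(vapply(grids[-1], function(g)
    isTRUE(all.equal(g, grids[[1]])), logical(1)))) {
    ee_input_error("profiles are on mismatched grids")
  }
  P <- do.call(rbind, lapply(profiles, `[[`, "samples"))
  n <- nrow(P); m <- ncol(P)
  probs <- c((1 - ci) / 2, (1 + ci) / 2)
  with_seed_ee(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    means <- matrix(0, n_boot, m)
    for (b in seq_len(n_boot)) means[b, ] <- colMeans(P[idx[, b], , drop = FALSE])
    env <- apply(means, 2, stats::quantile, probs = probs, names = FALSE,
                 type = 7)
    structure(list(grid = grids[[1]], mean = colMeans(P),
                   lower = env[1, ], upper = env[2, ],
                   n_boot = as.integer(n_boot), ci = ci,
                   n_profiles = n, seed = as.integer(seed)),
              class = "bootstrap_band")
  })
}

#' @export
print.bootstrap_band <- function(x, ...) {
  cat(sprintf("bootstrap_band: %d profiles, %d replicates, %.0f%% CI\n",
              x$n_profiles, x$n_boot, 100 * x$ci))
  invisible(x)
}

#' Plot a bootstrap band
#'
#' @param x a `bootstrap_band`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bootstrap_band <- function(x, ...) {
  graphics::plot(x$grid, x$mean, type = "n",
                 xlab = "AP position (fraction of egg length)",
                 ylab = "normalized intensity", ...)
  graphics::polygon(c(x$grid, rev(x$grid)), c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$grid, x$mean, col = "steelblue4", lwd = 2)
  invisible(x)
}

#' Write a profile band as CSV
#'
#' Columns: `ap`, `mean`, `lower`, `upper`.
#'
#' @param band a `bootstrap_band`.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_band_csv <- function(band, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(ap = band$grid, mean = band$mean,
                              lower = band$lower, upper = band$upper),
                   path, row.names = FALSE)
  invisible(path)
}
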