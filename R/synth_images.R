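# Synthetic two-channel embryo max-projections with analytic ground truth.
#
# Coordinate convention shared by all modules: AP fraction 0 = anterior,
# 1 = posterior; DV fraction 0 = dorsal, 1 = ventral; rasters are row-major
# matrices with row 1 at the top of the image.

#' Embryo ellipse geometry
#'
#' @param a,b semi-major / semi-minor axes in pixels (`a > b > 0`).
#' @param center numeric `(row, col)` center in pixels; may be `NULL` when
#'   the renderer chooses the image size.
#' @param angle rotation of the AP axis, degrees counter-clockwise from the
#'   image x-axis (as displayed, y up); must lie in (-90, 90].
#' @param anterior which image side holds the anterior pole after
#'   derotation: `"left"` or `"right"`.
#' @return An object of class `embryo_geometry`.
#' @export
embryo_geometry <- function(a, b, center = NULL, angle = 0,
                            anterior = c("left", "right")) {
  anterior <- match.arg(anterior)
  if (!(a > b && b > 0)) ee_input_error("need a > b > 0")
  if (!(angle > -90 && angle <= 90)) ee_input_error("angle must be in (-90, 90]")
  structure(list(a = a, b = b, center = center, angle = angle,
                 anterior = anterior),
            class = "embryo_geometry")
}

# Shared pixel <-> normalized transform. `frame` is any list carrying
# a, b, center = c(row, col), angle (degrees CCW, y-up convention) and
# anterior in {"left","right"}.

#' Pixel to normalized embryo coordinates
#'
#' Projects pixel positions onto the embryo's AP/DV axes. AP in \[0,1\]
#' runs anterior -> posterior along the major axis; DV runs dorsal (0,
#' image top for an unrotated embryo) -> ventral (1).
#'
#' @param frame an `embryo_geometry` or `embryo_frame`.
#' @param row,col pixel coordinates (vectorized).
#' @return data.frame with columns `ap`, `dv` (values outside \[0,1\] mean
#'   the pixel lies outside the embryo box).
#' @export
pixel_to_norm <- function(frame, row, col) {
  th <- frame$angle * pi / 180
  dx <- col - frame$center[2]
  dy <- -(row - frame$center[1])        # y up
  p <- dx * cos(th) + dy * sin(th)      # along AP axis
  d <- -dx * sin(th) + dy * cos(th)     # toward dorsal (+)
  ap <- (p + frame$a) / (2 * frame$a)
  if (identical(frame$anterior, "right")) ap <- 1 - ap
  dv <- (frame$b - d) / (2 * frame$b)
  data.frame(ap = ap, dv = dv)
}

#' Normalized embryo coordinates to pixels
#'
#' Inverse of [pixel_to_norm()].
#'
#' @inheritParams pixel_to_norm
#' @param ap,dv normalized coordinates (vectorized).
#' @return data.frame with columns `row`, `col` (fractional pixels).
#' @export
norm_to_pixel <- function(frame, ap, dv) {
  th <- frame$angle * pi / 180
  if (identical(frame$anterior, "right")) ap <- 1 - ap
  p <- (2 * ap - 1) * frame$a
  d <- frame$b * (1 - 2 * dv)
  dx <- p * cos(th) - d * sin(th)
  dy <- p * sin(th) + d * cos(th)
  data.frame(row = frame$center[1] - dy, col = frame$center[2] + dx)
}

#' Rasterize an embryo ellipse mask
#'
#' @param geometry an `embryo_geometry` (center must be set).
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return Logical matrix, TRUE inside the ellipse.
#' @export
ellipse_mask <- function(geometry, dim) {
  nr <- dim[1]; nc <- dim[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  th <- geometry$angle * pi / 180
  dx <- cols - geometry$center[2]
  dy <- -(rows - geometry$center[1])
  p <- dx * cos(th) + dy * sin(th)
  d <- -dx * sin(th) + dy * cos(th)
  matrix((p / geometry$a)^2 + (d / geometry$b)^2 <= 1, nr, nc)
}

# ---- expression pattern primitives ----------------------------------------

pattern_primitive <- function(type, ...) {
  structure(list(type = type, ...), class = "pattern_primitive")
}

#' Expression-pattern primitives
#'
#' Building blocks for synthetic reporter patterns, all additive:
#' `ap_stripe()` is a Gaussian stripe across the AP axis (an eve-stripe
#' stand-in), `dv_band()` a Gaussian band along DV, `lateral_domain()` two
#' DV-symmetric bands (neurogenic-ectoderm style), `ventral_domain()` a
#' ventral band (mesoderm style), `posterior_domain()` a smooth posterior
#' cap (endoderm style), and `uniform_level()` a constant. Amplitudes are
#' arbitrary fluorescence units; centers and widths are axis fractions.
#'
#' @param center,sigma Gaussian center / sd as an AP or DV fraction in (0,1).
#' @param amplitude peak intensity added by the primitive (>= 0).
#' @param edge,scale logistic edge position / softness of the posterior cap.
#' @return A `pattern_primitive` for use in [pattern_spec()].
#' @name pattern_primitives
NULL

#' @rdname pattern_primitives
#' @export
ap_stripe <- function(center, sigma, amplitude) {
  stopifnot(center > 0, center < 1, sigma > 0, sigma < 1, amplitude >= 0)
  pattern_primitive("ap_stripe", center = center, sigma = sigma,
                    amplitude = amplitude)
}

#' @rdname pattern_primitives
#' @export
dv_band <- function(center, sigma, amplitude) {
  stopifnot(center > 0, center < 1, sigma > 0, sigma < 1, amplitude >= 0)
  pattern_primitive("dv_band", center = center, sigma = sigma,
                    amplitude = amplitude)
}

#' @rdname pattern_primitives
#' @export
lateral_domain <- function(amplitude, center = 0.3, sigma = 0.08) {
  stopifnot(amplitude >= 0)
  pattern_primitive("lateral_domain", center = center, sigma = sigma,
                    amplitude = amplitude)
}

#' @rdname pattern_primitives
#' @export
ventral_domain <- function(amplitude, center = 0.85, sigma = 0.08) {
  stopifnot(amplitude >= 0)
  pattern_primitive("ventral_domain", center = center, sigma = sigma,
                    amplitude = amplitude)
}

#' @rdname pattern_primitives
#' @export
posterior_domain <- function(amplitude, edge = 0.8, scale = 0.02) {
  stopifnot(amplitude >= 0)
  pattern_primitive("posterior_domain", edge = edge, scale = scale,
                    amplitude = amplitude)
}

#' @rdname pattern_primitives
#' @export
uniform_level <- function(amplitude) {
  stopifnot(amplitude >= 0)
  pattern_primitive("uniform", amplitude = amplitude)
}

#' Assemble an expression-pattern specification
#'
#' @param ... `pattern_primitive` objects.
#' @param baseline constant added everywhere (>= 0).
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(..., baseline = 0) {
  prims <- list(...)
  if (length(prims) == 1L && is.list(prims[[1]]) &&
      !inherits(prims[[1]], "pattern_primitive")) prims <- prims[[1]]
  ok <- vapply(prims, inherits, logical(1), "pattern_primitive")
  if (!all(ok)) ee_input_error("all pattern components must be primitives")
  stopifnot(baseline >= 0)
  structure(list(primitives = prims, baseline = baseline),
            class = "pattern_spec")
}

#' Evaluate a pattern at normalized embryo coordinates
#'
#' Deterministic, additive over primitives plus the baseline.
#'
#' @param spec a `pattern_spec`.
#' @param ap,dv normalized coordinates in \[0,1\] (vectorized, recycled).
#' @return Numeric vector of intensities (arbitrary units).
#' @export
pattern_value <- function(spec, ap, dv) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (any(ap < 0 | ap > 1 | dv < 0 | dv > 1, na.rm = TRUE)) {
    ee_input_error("ap and dv must lie in [0, 1]")
  }
  n <- max(length(ap), length(dv))
  ap <- rep_len(ap, n); dv <- rep_len(dv, n)
  val <- rep_len(spec$baseline, n)
  for (pr in spec$primitives) {
    val <- val + switch(pr$type,
      ap_stripe = pr$amplitude * exp(-(ap - pr$center)^2 / (2 * pr$sigma^2)),
      dv_band = pr$amplitude * exp(-(dv - pr$center)^2 / (2 * pr$sigma^2)),
      lateral_domain = pr$amplitude * (
        exp(-(dv - pr$center)^2 / (2 * pr$sigma^2)) +
        exp(-(dv - (1 - pr$center))^2 / (2 * pr$sigma^2))),
      ventral_domain = pr$amplitude *
        exp(-(dv - pr$center)^2 / (2 * pr$sigma^2)),
      posterior_domain = pr$amplitude *
        stats::plogis((ap - pr$edge) / pr$scale),
      uniform = pr$amplitude,
      ee_input_error(sprintf("unknown primitive '%s'", pr$type)))
  }
  val
}

# Stripe-level ground truth carried by a pattern: center and full width at
# half maximum (FWHM = 2*sqrt(2*log 2)*sigma) per Gaussian stripe/band.
pattern_stripe_truth <- function(spec) {
  fw <- 2 * sqrt(2 * log(2))
  out <- lapply(spec$primitives, function(pr) {
    if (pr$type == "ap_stripe") {
      data.frame(axis = "ap", center = pr$center, width = fw * pr$sigma)
    } else if (pr$type %in% c("dv_band", "ventral_domain")) {
      data.frame(axis = "dv", center = pr$center, width = fw * pr$sigma)
    } else NULL
  })
  do.call(rbind, out)
}

# ---- renderer --------------------------------------------------------------

#' Render a synthetic two-channel embryo max-projection
#'
#' Channel 1 ("nuclear") contains a diffuse embryo body plus bright nuclear
#' disks; channel 2 ("reporter") samples [pattern_value()] at each pixel's
#' normalized coordinates, restricted to nuclear occupancy. Gaussian pixel
#' noise and an optional linear shading gradient are added to both
#' channels; intensities are clipped to the 16-bit range \[0, 65535\].
#' Ground truth (per-nucleus position and true mean reporter intensity,
#' per-region pattern values, stripe centers/FWHM widths) is returned
#' alongside so every downstream stage can be validated.
#'
#' @param geometry an [embryo_geometry()]; `center = NULL` centers the
#'   embryo in an automatically sized image.
#' @param spec a [pattern_spec()].
#' @param nuclei list with `n` (count), `radius` (px), `min_sep`
#'   (center-to-center separation, px).
#' @param noise list with `sd` (Gaussian sd, a.u.) and optional `gradient`
#'   (additive a.u. ramp from left to right image edge).
#' @param seed integer seed; the full raster is reproducible.
#' @param dim optional `c(nrow, ncol)` image size.
#' @param nuclear_amp,body_level channel-1 intensities of nuclear disks and
#'   embryo body.
#' @param region_defs named list of `c(ap, dv)` region centers used for the
#'   ground-truth region means.
#' @param max_tries placement attempts per nucleus before a generation
#'   error is raised.
#' @return A list of class `embryo_sim` with elements `image` (class
#'   `embryo_image`: matrices `nuclear`, `reporter`), `geometry`, and
#'   `truth` (list: `nuclei` data.frame with `id`, `row`, `col`, `ap`,
#'   `dv`, `true_mean`; `regions`; `stripes`).
#' @export
render_embryo <- function(geometry, spec,
                          nuclei = list(n = 250, radius = 5, min_sep = 14),
                          noise = list(sd = 0, gradient = NULL),
                          seed = 1L, dim = NULL,
                          nuclear_amp = 1000, body_level = 80,
                          region_defs = default_region_defs(),
                          max_tries = 400L) {
  stopifnot(inherits(geometry, "embryo_geometry"), inherits(spec, "pattern_spec"))
  th <- geometry$angle * pi / 180
  half_x <- sqrt((geometry$a * cos(th))^2 + (geometry$b * sin(th))^2)
  half_y <- sqrt((geometry$a * sin(th))^2 + (geometry$b * cos(th))^2)
  margin <- 15
  if (is.null(dim)) {
    dim <- c(2 * ceiling(half_y + margin) + 1, 2 * ceiling(half_x + margin) + 1)
  }
  if (is.null(geometry$center)) {
    geometry$center <- c((dim[1] + 1) / 2, (dim[2] + 1) / 2)
  }
  nr <- dim[1]; nc <- dim[2]
  r <- nuclei$radius
  min_sep <- nuclei$min_sep %||% (3 * r)
  n_nuc <- nuclei$n

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  norm <- pixel_to_norm(geometry, as.vector(rows), as.vector(cols))
  apm <- matrix(norm$ap, nr, nc)
  dvm <- matrix(norm$dv, nr, nc)
  # inside-ellipse test in axis units
  pax <- (2 * apm - 1)             # [-1,1] along AP
  dax <- (1 - 2 * dvm)             # [-1,1] along DV (dorsal +)
  inside <- pax^2 + dax^2 <= 1

  with_seed_ee(seed, {
    # -- nucleus placement by rejection sampling inside the eroded ellipse
    keep_margin <- r + 2
    ea <- geometry$a - keep_margin
    eb <- geometry$b - keep_margin
    if (ea <= 0 || eb <= 0) ee_generation_error("nuclei do not fit inside the ellipse")
    centers <- matrix(numeric(0), 0, 2)  # row, col
    tries <- 0L
    while (nrow(centers) < n_nuc) {
      tries <- tries + 1L
      if (tries > max_tries * n_nuc) {
        ee_generation_error("nucleus packing infeasible at the requested separation")
      }
      p0 <- stats::runif(1, -ea, ea)
      d0 <- stats::runif(1, -eb, eb)
      if ((p0 / ea)^2 + (d0 / eb)^2 > 1) next
      dx <- p0 * cos(th) - d0 * sin(th)
      dy <- p0 * sin(th) + d0 * cos(th)
      cand <- c(geometry$center[1] - dy, geometry$center[2] + dx)
      if (nrow(centers) > 0) {
        dd <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
        if (any(dd < min_sep)) next
      }
      centers <- rbind(centers, cand)
    }

    occupancy <- matrix(FALSE, nr, nc)
    true_mean <- numeric(n_nuc)
    for (i in seq_len(n_nuc)) {
      r0 <- centers[i, 1]; c0 <- centers[i, 2]
      rr <- max(1L, floor(r0 - r)):min(nr, ceiling(r0 + r))
      cc <- max(1L, floor(c0 - r)):min(nc, ceiling(c0 + r))
      sub <- outer(rr, cc, function(R, C) (R - r0)^2 + (C - c0)^2 <= r^2)
      occupancy[rr, cc] <- occupancy[rr, cc] | sub
      idx <- which(sub, arr.ind = TRUE)
      prs <- rr[idx[, 1]]; pcs <- cc[idx[, 2]]
      nn <- pixel_to_norm(geometry, prs, pcs)
      true_mean[i] <- mean(pattern_value(spec, pmin(pmax(nn$ap, 0), 1),
                                         pmin(pmax(nn$dv, 0), 1)))
    }

    ch1 <- matrix(0, nr, nc)
    ch1[inside] <- body_level
    ch1[occupancy] <- body_level + nuclear_amp

    patm <- matrix(0, nr, nc)
    sel <- which(occupancy)
    patm[sel] <- pattern_value(spec, pmin(pmax(apm[sel], 0), 1),
                               pmin(pmax(dvm[sel], 0), 1))
    ch2 <- patm

    sd <- noise$sd %||% 0
    if (sd > 0) {
      ch1 <- ch1 + matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
      ch2 <- ch2 + matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
    }
    if (!is.null(noise$gradient)) {
      ramp <- matrix(noise$gradient * (seq_len(nc) - 1) / (nc - 1),
                     nr, nc, byrow = TRUE)
      ch1 <- ch1 + ramp
      ch2 <- ch2 + ramp
    }
    ch1 <- pmin(pmax(ch1, 0), 65535)
    ch2 <- pmin(pmax(ch2, 0), 65535)

    cn <- pixel_to_norm(geometry, centers[, 1], centers[, 2])
    truth <- list(
      nuclei = data.frame(id = seq_len(n_nuc),
                          row = centers[, 1], col = centers[, 2],
                          ap = cn$ap, dv = cn$dv, true_mean = true_mean),
      regions = vapply(region_defs, function(rd)
        pattern_value(spec, rd[1], rd[2]), numeric(1)),
      stripes = pattern_stripe_truth(spec))

    structure(list(
      image = structure(list(nuclear = ch1, reporter = ch2),
                        class = "embryo_image"),
      geometry = geometry, truth = truth, seed = as.integer(seed)),
      class = "embryo_sim")
  })
}

#' Simulate a normalized nucleus table directly from a pattern
#'
#' Samples nucleus positions quasi-uniformly over the normalized (AP, DV)
#' unit square (jittered grid, guaranteeing a minimum spacing) and assigns
#' each nucleus the pattern intensity at its center plus i.i.d. Gaussian
#' noise. This is the fixture generator for stripe detection and width
#' measurement, where only nucleus centroids and mean intensities matter;
#' it bypasses rendering and segmentation.
#'
#' @param spec a [pattern_spec()].
#' @param spacing approximate nucleus spacing in normalized units (grid
#'   pitch; one nucleus "diameter").
#' @param noise_sd Gaussian intensity noise sd (a.u.).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `ap`, `dv`, `mean_reporter`
#'   (compatible with the segmentation output), with attribute `spacing`.
#' @export
simulate_nucleus_table <- function(spec, spacing = 0.02, noise_sd = 0,
                                   seed = 1L) {
  stopifnot(inherits(spec, "pattern_spec"), spacing > 0, spacing < 0.5)
  with_seed_ee(seed, {
    g <- seq(spacing / 2, 1 - spacing / 2, by = spacing)
    ap <- rep(g, times = length(g))
    dv <- rep(g, each = length(g))
    # near-maximal jitter: real blastoderm nuclei are irregularly packed,
    # and a regular lattice would alias into extreme-distance statistics
    jit <- spacing * 0.45
    ap <- pmin(pmax(ap + stats::runif(length(ap), -jit, jit), 0), 1)
    dv <- pmin(pmax(dv + stats::runif(length(dv), -jit, jit), 0), 1)
    val <- pattern_value(spec, ap, dv)
    if (noise_sd > 0) val <- val + stats::rnorm(length(val), 0, noise_sd)
    structure(data.frame(id = seq_along(ap), ap = ap, dv = dv,
                         mean_reporter = val),
              spacing = spacing)
  })
}

#' Write a rendered embryo to TIFF files
#'
#' Writes the two channels as 16-bit grayscale TIFFs (`<stem>_nuclear.tif`,
#' `<stem>_reporter.tif`) plus the ground-truth nuclei as CSV and the full
#' truth as JSON.
#'
#' @param sim an `embryo_sim` from [render_embryo()].
#' @param stem output path stem.
#' @return Invisibly, the files written.
#' @export
write_embryo_sim <- function(sim, stem) {
  stopifnot(inherits(sim, "embryo_sim"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  f1 <- paste0(stem, "_nuclear.tif")
  f2 <- paste0(stem, "_reporter.tif")
  EBImage::writeImage(EBImage::Image(sim$image$nuclear / 65535), f1,
                      type = "tiff", bits.per.sample = 16L)
  EBImage::writeImage(EBImage::Image(sim$image$reporter / 65535), f2,
                      type = "tiff", bits.per.sample = 16L)
  fc <- paste0(stem, "_truth_nuclei.csv")
  utils::write.csv(sim$truth$nuclei, fc, row.names = FALSE)
  fj <- paste0(stem, "_truth.json")
  jsonlite::write_json(list(
    geometry = unclass(sim$geometry),
    regions = as.list(sim$truth$regions),
    stripes = sim$truth$stripes,
    seed = sim$seed), fj, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(f1, f2, fc, fj))
}

#' Read a two-channel embryo image from TIFF/PNG files
#'
#' @param nuclear,reporter file paths; 16-bit TIFFs written by
#'   [write_embryo_sim()] round-trip to the original a.u. scale.
#' @param scale multiplier applied to the \[0,1\] pixel data read from
#'   disk (default restores 16-bit counts).
#' @return An `embryo_image` (list of matrices `nuclear`, `reporter`).
#' @export
read_embryo_image <- function(nuclear, reporter, scale = 65535) {
  rd <- function(f) {
    img <- EBImage::imageData(EBImage::readImage(f))
    if (length(base::dim(img)) > 2) img <- img[, , 1]
    img * scale
  }
  structure(list(nuclear = rd(nuclear), reporter = rd(reporter)),
            class = "embryo_image")
}

# Default germ-layer region coordinates (AP, DV fractions): ectoderm =
# lateral, mesoderm = ventral, endoderm = posterior.

#' Default germ-layer region coordinates
#'
#' Lateral (ectoderm), ventral (mesoderm) and posterior (endoderm)
#' sampling points in normalized (AP, DV) coordinates.
#'
#' @return Named list of `c(ap, dv)` pairs.
#' @export
default_region_defs <- function() {
  list(ectoderm = c(0.50, 0.30),
       mesoderm = c(0.50, 0.85),
       endoderm = c(0.92, 0.50))
}
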