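# Embryo masking, axis-frame fitting (ellipse moments + maximum Feret
# diameter), and watershed nucleus segmentation.

#' Mask the embryo in a two-channel image
#'
#' Heavily blurs the nuclear channel (merging nuclei and embryo body into
#' one smooth region), thresholds with Otsu's method, fills holes, and
#' keeps the largest connected foreground component so that debris and
#' bright specks outside the embryo are discarded.
#'
#' @param image an `embryo_image` or a numeric matrix (nuclear channel).
#' @param blur_sigma Gaussian blur sd in pixels.
#' @return Object of class `embryo_mask`: list with `mask` (logical
#'   matrix) and `area` (px^2).
#' @export
mask_embryo <- function(image, blur_sigma = 6) {
  x <- if (inherits(image, "embryo_image")) image$nuclear else image
  if (!is.matrix(x)) ee_input_error("`image` must be an embryo_image or matrix")
  mx <- max(x)
  if (!is.finite(mx) || mx <= 0) ee_no_embryo_error("empty image: no foreground")
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(x / mx),
                                          sigma = blur_sigma)) * mx
  # threshold on a log scale: the embryo body vs exterior gap dominates
  # the (body vs bright-nuclei) gap there, so Otsu finds the outline
  lg <- log1p(pmax(sm, 0))
  thr <- otsu_threshold(as.vector(lg))
  bin <- lg > thr
  if (!any(bin)) ee_no_embryo_error("no foreground after thresholding")
  bin <- EBImage::fillHull(EBImage::Image(bin * 1))
  lab <- EBImage::bwlabel(bin)
  tab <- tabulate(as.vector(EBImage::imageData(lab)))
  keep <- which.max(tab)
  mask <- matrix(EBImage::imageData(lab) == keep, nrow(x), ncol(x))
  structure(list(mask = mask, area = sum(mask)), class = "embryo_mask")
}

#' @export
print.embryo_mask <- function(x, ...) {
  cat(sprintf("embryo_mask: %d x %d, area %d px^2\n",
              nrow(x$mask), ncol(x$mask), x$area))
  invisible(x)
}

# Maximum Feret diameter of the mask point cloud: coarse caliper search
# over an angle grid, then sub-degree refinement by the chord between the
# centroids of the two tip point clusters (the caliper extent is nearly
# flat around its maximum for elongated shapes, so the raw argmax is
# pixelation-noisy; tip-cluster averaging removes that noise). Returns the
# angle (deg, CCW, y-up) and the diameter.
feret_axis <- function(px, py, step_deg = 0.25, tip_depth = 3) {
  hull <- grDevices::chull(px, py)
  hx <- px[hull]; hy <- py[hull]
  ang <- seq(-90, 90 - step_deg, by = step_deg) * pi / 180
  proj <- outer(hx, cos(ang)) + outer(hy, sin(ang))
  ext <- apply(proj, 2, max) - apply(proj, 2, min)
  theta <- ang[which.max(ext)]
  # refine on the full point cloud: filled tip caps average away the
  # pixelation of individual hull vertices
  for (it in 1:3) {
    pr <- px * cos(theta) + py * sin(theta)
    hi <- pr >= max(pr) - tip_depth
    lo <- pr <= min(pr) + tip_depth
    dxc <- mean(px[hi]) - mean(px[lo])
    dyc <- mean(py[hi]) - mean(py[lo])
    theta <- atan2(dyc, dxc)
    if (theta > pi / 2) theta <- theta - pi
    if (theta <= -pi / 2) theta <- theta + pi
  }
  deg <- theta * 180 / pi
  pr <- hx * cos(theta) + hy * sin(theta)
  list(angle = deg, length = diff(range(pr)) + 1)
}

#' Fit the embryo coordinate frame from a mask
#'
#' Fits an ellipse by second-order moments of the mask and determines the
#' AP-axis direction from the maximum Feret diameter (longest caliper
#' distance) of the mask's convex hull. The frame's rotation is the angle
#' that, when applied to the image, brings the AP axis horizontal. Egg
#' length L is the maximum Feret diameter; egg height H the caliper extent
#' perpendicular to it. The 180-degree anterior/posterior ambiguity of the
#' axis cannot be resolved from the mask alone: `anterior` defaults to
#' `"unresolved"` and must be supplied by the caller (or ground truth) via
#' [resolve_anterior()] before profile extraction.
#'
#' @param mask an `embryo_mask` or logical matrix.
#' @param anterior `"left"`, `"right"`, or `"unresolved"`.
#' @param min_axis_ratio masks with fitted axis ratio below this are
#'   rejected as orientation-ambiguous.
#' @return Object of class `embryo_frame`: list with `center` (row, col),
#'   `a`, `b` (semi-axes, from L and H), `angle` (= Feret angle, degrees
#'   CCW y-up), `orientation` (moment-ellipse angle), `rotation`
#'   (= -angle, the derotation to apply), `L`, `H`, `axes` (moment
#'   semi-axes), and `anterior`.
#' @export
fit_embryo_frame <- function(mask, anterior = "unresolved",
                             min_axis_ratio = 1.1) {
  m <- if (inherits(mask, "embryo_mask")) mask$mask else mask
  if (!any(m)) ee_input_error("empty mask")
  idx <- which(m, arr.ind = TRUE)
  px <- idx[, 2]          # x = col
  py <- -idx[, 1]         # y up
  cx <- mean(px); cy <- mean(py)
  cv <- stats::cov(cbind(px, py))
  eg <- eigen(cv, symmetric = TRUE)
  ax <- 2 * sqrt(pmax(eg$values, 0))   # uniform-ellipse semi-axes
  if (ax[2] <= 0 || ax[1] / ax[2] < min_axis_ratio) {
    ee_orientation_error("mask is near-circular: axis orientation is ambiguous")
  }
  orientation <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi
  if (orientation <= -90) orientation <- orientation + 180
  if (orientation > 90) orientation <- orientation - 180
  fr <- feret_axis(px, py)
  # egg height: caliper extent perpendicular to the Feret axis
  tp <- (fr$angle + 90) * pi / 180
  hp <- px * cos(tp) + py * sin(tp)
  H <- diff(range(hp)) + 1
  structure(list(center = c(-cy, cx), a = fr$length / 2, b = H / 2,
                 angle = fr$angle, orientation = orientation,
                 rotation = -fr$angle, L = fr$length, H = H,
                 axes = ax, anterior = anterior),
            class = "embryo_frame")
}

#' @export
print.embryo_frame <- function(x, ...) {
  cat(sprintf(
    "embryo_frame: center (%.1f, %.1f), L %.1f px, H %.1f px, angle %.2f deg, anterior %s\n",
    x$center[1], x$center[2], x$L, x$H, x$angle, x$anterior))
  invisible(x)
}

#' Set the anterior end of a fitted frame
#'
#' @param frame an `embryo_frame`.
#' @param anterior `"left"` or `"right"` (after derotation).
#' @return The frame with the ambiguity resolved.
#' @export
resolve_anterior <- function(frame, anterior = c("left", "right")) {
  anterior <- match.arg(anterior)
  frame$anterior <- anterior
  frame
}

#' Segment nuclei in the nuclear channel
#'
#' Otsu-thresholds the nuclear channel within the embryo mask, removes
#' objects below `min_area`, and splits fused objects by a watershed on
#' the distance transform (tolerance controls how deep a saddle must be
#' to separate two nuclei). Centroid, area, and mean nuclear intensity are
#' measured per label; normalized (AP, DV) centroid coordinates are added
#' when a resolved or unresolved frame is supplied.
#'
#' @param nuclear numeric matrix (nuclear channel).
#' @param mask an `embryo_mask` or logical matrix congruent with `nuclear`.
#' @param min_area minimum object area in px^2 (> 0).
#' @param frame optional `embryo_frame` for normalized coordinates.
#' @param tolerance watershed height tolerance (px, in distance-map units).
#' @return data.frame of class `nucleus_records` with columns `id`, `row`,
#'   `col`, `ap`, `dv`, `area`, `mean_nuclear`, `mean_reporter` (NA until
#'   [measure_nuclei()]); the label matrix is attached as attribute
#'   `labels`.
#' @export
segment_nuclei <- function(nuclear, mask, min_area = 4, frame = NULL,
                           tolerance = 1) {
  m <- if (inherits(mask, "embryo_mask")) mask$mask else mask
  if (!identical(base::dim(nuclear), base::dim(m))) {
    ee_input_error("mask and nuclear channel have different dimensions")
  }
  if (min_area <= 0) ee_input_error("`min_area` must be positive")
  vals <- nuclear[m]
  empty <- function() {
    rec <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      ap = numeric(0), dv = numeric(0), area = integer(0),
                      mean_nuclear = numeric(0), mean_reporter = numeric(0))
    structure(rec, labels = matrix(0L, nrow(nuclear), ncol(nuclear)),
              class = c("nucleus_records", "data.frame"))
  }
  if (length(vals) == 0L || diff(range(vals)) == 0) return(empty())
  thr <- otsu_threshold(vals)
  bin <- (nuclear > thr) & m
  if (!any(bin)) return(empty())
  # drop sub-minimum specks before the watershed
  lab0 <- EBImage::bwlabel(EBImage::Image(bin * 1))
  sizes <- tabulate(as.vector(EBImage::imageData(lab0)))
  small <- which(sizes < min_area)
  if (length(small)) bin[matrix(EBImage::imageData(lab0) %in% small,
                                nrow(bin), ncol(bin))] <- FALSE
  if (!any(bin)) return(empty())
  dm <- EBImage::distmap(EBImage::Image(bin * 1))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  labels <- matrix(as.integer(EBImage::imageData(ws)), nrow(bin), ncol(bin))
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0L) return(empty())
  relut <- integer(length(sizes))
  relut[keep] <- seq_along(keep)
  labels[labels > 0] <- relut[labels[labels > 0]]
  nlab <- length(keep)
  idx <- which(labels > 0)
  lab_v <- labels[idx]
  rows_v <- ((idx - 1L) %% nrow(labels)) + 1L
  cols_v <- ((idx - 1L) %/% nrow(labels)) + 1L
  area <- tabulate(lab_v, nbins = nlab)
  crow <- rowsum(as.numeric(rows_v), lab_v)[, 1] / area
  ccol <- rowsum(as.numeric(cols_v), lab_v)[, 1] / area
  mean_nuc <- rowsum(as.numeric(nuclear[idx]), lab_v)[, 1] / area
  if (!is.null(frame)) {
    nn <- pixel_to_norm(frame, crow, ccol)
    ap <- pmin(pmax(nn$ap, 0), 1)
    dv <- pmin(pmax(nn$dv, 0), 1)
  } else {
    ap <- rep(NA_real_, nlab); dv <- rep(NA_real_, nlab)
  }
  rec <- data.frame(id = seq_len(nlab), row = crow, col = ccol,
                    ap = ap, dv = dv, area = area,
                    mean_nuclear = mean_nuc, mean_reporter = NA_real_)
  structure(rec, labels = labels, class = c("nucleus_records", "data.frame"))
}

#' Measure mean reporter intensity per segmented nucleus
#'
#' @param records `nucleus_records` from [segment_nuclei()] (carrying the
#'   label raster).
#' @param reporter numeric matrix, congruent with the label raster.
#' @return The records with `mean_reporter` filled in (arithmetic mean of
#'   reporter pixels under each label).
#' @export
measure_nuclei <- function(records, reporter) {
  labels <- attr(records, "labels")
  if (is.null(labels)) ee_input_error("records carry no label raster")
  if (!identical(base::dim(labels), base::dim(reporter))) {
    ee_input_error("label raster and reporter channel have different dimensions")
  }
  if (nrow(records) == 0L) return(records)
  idx <- which(labels > 0)
  lab_v <- labels[idx]
  area <- tabulate(lab_v, nbins = nrow(records))
  msum <- rowsum(as.numeric(reporter[idx]), lab_v)[, 1]
  records$mean_reporter <- msum / area
  records
}

#' Write / read nucleus tables as CSV
#'
#' @param records a `nucleus_records` data.frame (or any data.frame with
#'   the same columns).
#' @param path CSV path.
#' @return `write_nuclei_csv` invisibly returns `path`; `read_nuclei_csv`
#'   returns a `nucleus_records` data.frame (without a label raster).
#' @export
write_nuclei_csv <- function(records, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nuclei_csv
#' @export
read_nuclei_csv <- function(path) {
  if (!file.exists(path)) ee_io_error(sprintf("no such file: %s", path))
  rec <- utils::read.csv(path)
  structure(rec, class = c("nucleus_records", "data.frame"))
}
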