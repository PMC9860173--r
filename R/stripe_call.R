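# Nucleus-based stripe calling: AP binning, per-bin smoothed DV
# fluorescence profiles, peak detection and cross-bin alignment, half-max
# membership, and perpendicular width measurement along a piecewise-linear
# midline.

#' Bin nuclei by AP coordinate
#'
#' Partitions \[0, 1\] into half-open bins `[lo, hi)` of width `bin_width`
#' (the last bin is closed at 1) and assigns every nucleus to exactly one
#' bin. Empty bins are retained.
#'
#' @param nuclei data.frame with normalized `ap`, `dv` columns (e.g. from
#'   [segment_nuclei()] or [simulate_nucleus_table()]).
#' @param bin_width AP bin width in (0, 1].
#' @return Object of class `ap_bins`: list with `bins` (data.frame
#'   `index`, `lo`, `hi`), `assignment` (bin index per nucleus row), and
#'   `bin_width`.
#' @export
bin_nuclei <- function(nuclei, bin_width = 0.05) {
  if (!(bin_width > 0 && bin_width <= 1)) {
    ee_input_error("`bin_width` must be in (0, 1]")
  }
  if (is.null(nuclei$ap) || is.null(nuclei$dv) || anyNA(nuclei$ap)) {
    ee_input_error("nuclei lack normalized AP/DV coordinates")
  }
  n_bins <- max(1L, ceiling(round(1 / bin_width, 10) - 1e-9))
  breaks <- c((seq_len(n_bins) - 1L) * bin_width, 1)
  breaks[n_bins + 1L] <- max(breaks[n_bins + 1L], 1)
  assignment <- findInterval(nuclei$ap, breaks, rightmost.closed = TRUE)
  assignment <- pmin(pmax(assignment, 1L), n_bins)
  structure(list(
    bins = data.frame(index = seq_len(n_bins),
                      lo = breaks[seq_len(n_bins)],
                      hi = breaks[seq_len(n_bins) + 1L]),
    assignment = assignment, bin_width = bin_width),
    class = "ap_bins")
}

#' Smoothed DV fluorescence profile of one AP bin
#'
#' Kernel-weighted (Gaussian, Nadaraya-Watson) mean of member-nucleus
#' intensities over a regular DV grid.
#'
#' @param bins an `ap_bins` object.
#' @param bin_index which bin to profile.
#' @param nuclei the nucleus table used to build `bins`.
#' @param grid_step DV grid spacing.
#' @param sigma kernel sd (DV fraction).
#' @param intensity_col column holding the per-nucleus mean fluorescence.
#' @return Object of class `dv_profile`: list with `grid`, `value`,
#'   `bin_index`, `n_members`, `empty` (flag; empty bins give an empty
#'   profile, not an error).
#' @export
bin_dv_profile <- function(bins, bin_index, nuclei, grid_step = 0.01,
                           sigma = 0.02, intensity_col = "mean_reporter") {
  stopifnot(inherits(bins, "ap_bins"))
  member <- which(bins$assignment == bin_index)
  grid <- seq(0, 1, by = grid_step)
  if (length(member) == 0L) {
    return(structure(list(grid = grid, value = rep(NA_real_, length(grid)),
                          bin_index = bin_index, n_members = 0L,
                          empty = TRUE),
                     class = "dv_profile"))
  }
  dv <- nuclei$dv[member]
  iv <- nuclei[[intensity_col]][member]
  w <- outer(grid, dv, function(g, d) stats::dnorm((g - d) / sigma))
  val <- as.vector(w %*% iv) / pmax(rowSums(w), .Machine$double.xmin)
  structure(list(grid = grid, value = val, bin_index = bin_index,
                 n_members = length(member), empty = FALSE),
            class = "dv_profile")
}

# local maxima of y with prominence >= prom_frac * range(y), measured
# against the profile's minimum (local baseline); returns peak index,
# height, and half-max interval bounds on `grid`.
find_profile_peaks <- function(grid, y, prom_frac = 0.25) {
  ok <- is.finite(y)
  if (!any(ok)) return(NULL)
  rng <- diff(range(y[ok]))
  # flat profiles (incl. float-level ripple on uniform input) have no peaks
  if (rng <= 1e-9 * max(abs(y[ok]), 1e-300)) return(NULL)
  baseline <- min(y[ok])
  thr <- prom_frac * rng
  n <- length(y)
  peaks <- which(vapply(seq_len(n), function(i) {
    if (!ok[i]) return(FALSE)
    lo <- if (i > 1) y[i - 1] else -Inf
    hi <- if (i < n) y[i + 1] else -Inf
    y[i] >= lo && y[i] > hi && (y[i] - baseline) >= thr
  }, logical(1)))
  if (length(peaks) == 0L) return(NULL)
  out <- lapply(peaks, function(p) {
    half <- baseline + (y[p] - baseline) / 2
    l <- p
    while (l > 1 && is.finite(y[l - 1]) && y[l - 1] >= half) l <- l - 1
    r <- p
    while (r < n && is.finite(y[r + 1]) && y[r + 1] >= half) r <- r + 1
    data.frame(dv = grid[p], height = y[p], half_lo = grid[l],
               half_hi = grid[r])
  })
  do.call(rbind, out)
}

#' Detect expression stripes across AP bins
#'
#' Per bin, peaks of the smoothed DV profile above a prominence threshold
#' (relative to the bin's local baseline) are found with their half-max DV
#' intervals; peaks in adjacent bins are linked by nearest-DV matching
#' under a maximum-jump constraint, and traces spanning fewer than
#' `min_span` of the occupied bins are discarded.
#'
#' @param bins an `ap_bins` object.
#' @param nuclei the nucleus table used to build `bins`.
#' @param grid_step,sigma,intensity_col passed to [bin_dv_profile()].
#' @param prominence peak prominence threshold as a fraction of the bin
#'   profile's range.
#' @param max_jump maximum DV distance between linked peaks in adjacent
#'   bins.
#' @param min_span minimum trace length as a fraction of non-empty bins.
#' @param refine recompute per-bin peaks and half-max intervals on DV
#'   residuals about the aligned midline (second pass; removes the
#'   widening a slanted stripe suffers from the bin's AP extent).
#' @return List of `stripe_trace` objects; each is a data.frame with one
#'   row per bin (`bin`, `ap_lo`, `ap_hi`, `ap_mid`, `dv`, `height`,
#'   `half_lo`, `half_hi`). An empty list is a valid result.
#' @export
detect_stripes <- function(bins, nuclei, grid_step = 0.01, sigma = 0.02,
                           intensity_col = "mean_reporter",
                           prominence = 0.25, max_jump = 0.05,
                           min_span = 0.6, refine = TRUE) {
  stopifnot(inherits(bins, "ap_bins"))
  nb <- nrow(bins$bins)
  if (nb < 3L) ee_input_error("need >= 3 AP bins")
  peak_tab <- vector("list", nb)
  occupied <- 0L
  for (i in seq_len(nb)) {
    pr <- bin_dv_profile(bins, i, nuclei, grid_step = grid_step,
                         sigma = sigma, intensity_col = intensity_col)
    if (pr$empty) next
    occupied <- occupied + 1L
    pk <- find_profile_peaks(pr$grid, pr$value, prom_frac = prominence)
    if (!is.null(pk)) {
      pk$bin <- i
      peak_tab[[i]] <- pk
    }
  }
  # link greedily bin-to-bin by nearest DV
  open <- list()   # each: list(rows = data.frame, last_bin, last_dv)
  done <- list()
  for (i in seq_len(nb)) {
    pk <- peak_tab[[i]]
    matched_open <- rep(FALSE, length(open))
    if (!is.null(pk)) {
      taken <- rep(FALSE, nrow(pk))
      if (length(open)) {
        ord <- order(vapply(open, function(tr) -tr$rows$height[nrow(tr$rows)],
                            numeric(1)))
        for (oi in ord) {
          tr <- open[[oi]]
          if (i - tr$last_bin > 1L) next   # only adjacent bins link
          d <- abs(pk$dv - tr$last_dv)
          d[taken] <- Inf
          j <- which.min(d)
          if (length(j) && is.finite(d[j]) && d[j] <= max_jump) {
            row <- pk[j, , drop = FALSE]
            open[[oi]]$rows <- rbind(tr$rows, row)
            open[[oi]]$last_bin <- i
            open[[oi]]$last_dv <- row$dv
            taken[j] <- TRUE
            matched_open[oi] <- TRUE
          }
        }
      }
      for (j in which(!taken)) {
        open[[length(open) + 1L]] <- list(rows = pk[j, , drop = FALSE],
                                          last_bin = i, last_dv = pk$dv[j])
        matched_open[length(open)] <- TRUE
      }
    }
    # close traces that could no longer be extended
    still <- vapply(open, function(tr) i - tr$last_bin < 1L, logical(1))
    done <- c(done, open[!still])
    open <- open[still]
  }
  done <- c(done, open)
  min_bins <- max(2L, ceiling(min_span * max(occupied, 1L)))
  traces <- Filter(function(tr) nrow(tr$rows) >= min_bins, done)
  traces <- lapply(traces, function(tr) {
    rows <- tr$rows
    b <- bins$bins[rows$bin, ]
    out <- data.frame(bin = rows$bin, ap_lo = b$lo, ap_hi = b$hi,
                      ap_mid = (b$lo + b$hi) / 2, dv = rows$dv,
                      height = rows$height, half_lo = rows$half_lo,
                      half_hi = rows$half_hi)
    structure(out, class = c("stripe_trace", "data.frame"))
  })
  if (refine) {
    traces <- lapply(traces, refine_trace, bins = bins, nuclei = nuclei,
                     grid_step = grid_step, sigma = sigma,
                     intensity_col = intensity_col, max_jump = max_jump)
  }
  # drop degenerate bins (clipped stripe corners, near-empty bins) whose
  # half-max interval is far wider than the trace's typical interval
  traces <- lapply(traces, function(tr) {
    wd <- tr$half_hi - tr$half_lo
    keep <- wd <= 2 * stats::median(wd)
    if (sum(keep) >= 2L) tr <- tr[keep, , drop = FALSE]
    structure(tr, class = c("stripe_trace", "data.frame"))
  })
  Filter(function(tr) nrow(tr) >= min_bins, traces)
}

# Second pass over an aligned trace: per bin, the DV profile is recomputed
# on residuals about the interpolated midline, so a slanted stripe is not
# widened by the bin's AP extent; the peak nearest the midline and its
# half-max interval (vs the residual profile's minimum) replace the
# first-pass values.
refine_trace <- function(trace, bins, nuclei, grid_step, sigma,
                         intensity_col, max_jump) {
  for (k in seq_len(nrow(trace))) {
    in_bin <- which(bins$assignment == trace$bin[k])
    if (length(in_bin) == 0L) next
    ctr <- stats::approx(trace$ap_mid, trace$dv, xout = nuclei$ap[in_bin],
                         rule = 2)$y
    r <- nuclei$dv[in_bin] - ctr
    iv <- nuclei[[intensity_col]][in_bin]
    span <- max(abs(r)) + 2 * sigma
    grid <- seq(-span, span, by = grid_step)
    w <- outer(grid, r, function(g, d) stats::dnorm((g - d) / sigma))
    val <- as.vector(w %*% iv) / pmax(rowSums(w), .Machine$double.xmin)
    pk <- find_profile_peaks(grid, val, prom_frac = 0)
    if (is.null(pk)) next
    pk <- pk[abs(pk$dv) <= max_jump, , drop = FALSE]
    if (nrow(pk) == 0L) next
    j <- which.min(abs(pk$dv))
    mid <- stats::approx(trace$ap_mid, trace$dv, xout = trace$ap_mid[k],
                         rule = 2)$y
    trace$dv[k] <- mid + pk$dv[j]
    trace$half_lo[k] <- mid + pk$half_lo[j]
    trace$half_hi[k] <- mid + pk$half_hi[j]
    trace$height[k] <- pk$height[j]
  }
  trace
}

# Half-max membership interval for arbitrary AP positions along a trace:
# the peak DV and the half-max offsets are linearly interpolated between
# bin centers, so the interval follows the aligned peaks continuously
# rather than stepwise (a slanted stripe is not smeared by bin width).
trace_interval <- function(trace, ap) {
  if (nrow(trace) == 1L) {
    return(data.frame(lo = rep(trace$half_lo, length(ap)),
                      hi = rep(trace$half_hi, length(ap))))
  }
  ctr <- stats::approx(trace$ap_mid, trace$dv, xout = ap, rule = 2)$y
  off_lo <- stats::approx(trace$ap_mid, trace$half_lo - trace$dv,
                          xout = ap, rule = 2)$y
  off_hi <- stats::approx(trace$ap_mid, trace$half_hi - trace$dv,
                          xout = ap, rule = 2)$y
  data.frame(lo = ctr + off_lo, hi = ctr + off_hi)
}

#' Assign nuclei to a stripe by the half-maximum rule
#'
#' Within the AP bins spanned by the trace, nuclei whose DV position lies
#' inside the peak's half-maximum interval are stripe members; the
#' interval is evaluated at each nucleus's own AP position by linear
#' interpolation of the aligned per-bin peaks. A manual curation override
#' (explicit include/exclude id lists) is honored verbatim.
#'
#' @param trace a `stripe_trace` from [detect_stripes()].
#' @param bins the `ap_bins` used for detection.
#' @param nuclei the nucleus table.
#' @param override optional list with integer vectors `include` and/or
#'   `exclude` of nucleus ids.
#' @return Integer vector of member nucleus ids (sorted).
#' @export
assign_membership <- function(trace, bins, nuclei, override = NULL) {
  stopifnot(inherits(trace, "stripe_trace"), inherits(bins, "ap_bins"))
  if (any(trace$bin > nrow(bins$bins))) {
    ee_input_error("trace references bins outside the binning")
  }
  in_bins <- which(bins$assignment %in% trace$bin)
  iv <- trace_interval(trace, nuclei$ap[in_bins])
  dv <- nuclei$dv[in_bins]
  ids <- unique(nuclei$id[in_bins[dv >= iv$lo & dv <= iv$hi]])
  if (!is.null(override)) {
    ids <- union(ids, override$include %||% integer(0))
    ids <- setdiff(ids, override$exclude %||% integer(0))
  }
  sort(ids)
}

#' Measure stripe width along a piecewise-linear midline
#'
#' The stripe is fitted lengthwise (along AP) with a piecewise-linear
#' midline: the AP range of the members is cut into segments of length
#' `segment_length`, each segment's line is the least-squares fit of DV on
#' AP over its member nuclei, and each member belongs to exactly one
#' segment (half-open AP intervals). Per-segment width is the largest
#' perpendicular distance between member nucleus centers (extent of the
#' perpendicular projections); overall width is the arithmetic mean of the
#' per-segment widths.
#'
#' @param members integer vector of member nucleus ids.
#' @param nuclei the nucleus table.
#' @param segment_length segment length as an AP fraction.
#' @param min_members segments with fewer members are skipped.
#' @return Object of class `stripe_measurement`: list with `members`,
#'   `segments` (data.frame `ap1`, `dv1`, `ap2`, `dv2`, `n`, `width`),
#'   and `overall_width`.
#' @export
measure_stripe <- function(members, nuclei, segment_length = 0.1,
                           min_members = 2L) {
  rows <- nuclei[nuclei$id %in% members, ]
  if (nrow(rows) < 2L) ee_input_error("need >= 2 member nuclei")
  ap <- rows$ap; dv <- rows$dv
  if (diff(range(ap)) <= .Machine$double.eps) {
    ee_degenerate_error("all members at a single AP position")
  }
  lo <- floor(min(ap) / segment_length) * segment_length
  breaks <- seq(lo, max(ap) + segment_length, by = segment_length)
  seg_of <- findInterval(ap, breaks, rightmost.closed = FALSE)
  # under-populated segments (stripe ends clipped by the field of view)
  # cannot support an extreme-distance width: skip segments holding fewer
  # than half the median member count
  occ <- table(seg_of)
  min_n <- max(min_members, 0.5 * stats::median(occ))
  segs <- list()
  for (s in sort(unique(seg_of))) {
    in_seg <- seg_of == s
    if (sum(in_seg) < min_n) next
    x <- ap[in_seg]; y <- dv[in_seg]
    if (diff(range(x)) > .Machine$double.eps) {
      fit <- stats::lm.fit(cbind(1, x), y)
      beta <- fit$coefficients
    } else {
      beta <- c(mean(y), 0)
    }
    slope <- beta[2]
    nv <- c(-slope, 1) / sqrt(1 + slope^2)   # unit normal to the segment
    proj <- x * nv[1] + y * nv[2]
    width <- diff(range(proj))
    x1 <- breaks[s]; x2 <- breaks[s + 1L]
    segs[[length(segs) + 1L]] <- data.frame(
      ap1 = x1, dv1 = beta[1] + slope * x1,
      ap2 = x2, dv2 = beta[1] + slope * x2,
      n = sum(in_seg), width = width)
  }
  if (length(segs) == 0L) {
    ee_degenerate_error("no segment has enough members to fit a midline")
  }
  segments <- do.call(rbind, segs)
  structure(list(members = sort(members), segments = segments,
                 overall_width = mean(segments$width)),
            class = "stripe_measurement")
}

#' @export
print.stripe_measurement <- function(x, ...) {
  cat(sprintf("stripe_measurement: %d members, %d segments, overall width %.4f\n",
              length(x$members), nrow(x$segments), x$overall_width))
  invisible(x)
}

#' Run the full stripe pipeline on a nucleus table
#'
#' Convenience wrapper: bin, detect, assign membership, and measure every
#' detected stripe.
#'
#' @param nuclei nucleus table with `ap`, `dv` and an intensity column.
#' @param bin_width AP bin width.
#' @param segment_length midline segment length (AP fraction).
#' @param override optional curation override (see [assign_membership()]).
#' @param ... passed to [detect_stripes()].
#' @return List of lists, one per stripe: `trace`, `members`,
#'   `measurement`.
#' @export
call_stripes <- function(nuclei, bin_width = 0.05, segment_length = 0.1,
                         override = NULL, ...) {
  bins <- bin_nuclei(nuclei, bin_width)
  traces <- detect_stripes(bins, nuclei, ...)
  lapply(traces, function(tr) {
    members <- assign_membership(tr, bins, nuclei, override = override)
    meas <- tryCatch(measure_stripe(members, nuclei, segment_length),
                     embryoexpress_error = function(e) NULL)
    list(trace = tr, members = members, measurement = meas)
  })
}

#' Write called stripes as JSON
#'
#' @param stripes result of [call_stripes()].
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_stripes_json <- function(stripes, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- lapply(stripes, function(s) list(
    trace = as.data.frame(s$trace),
    members = s$members,
    segments = if (!is.null(s$measurement)) s$measurement$segments else NULL,
    overall_width = if (!is.null(s$measurement)) s$measurement$overall_width
                    else NA))
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
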