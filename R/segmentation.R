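#' Global auto-threshold of a single frame
#'
#' Computes a global intensity threshold from the frame's 256-bin histogram.
#' Frames whose values are already integers in `[0, 255]` are binned
#' identically (bin = intensity); any other bit depth or float data is
#' linearly rescaled so its `[min, max]` range spans the 256 bins, matching
#' the behaviour of the reference histogram implementations. The returned
#' value `t` lies in `[min, max)` of the frame and foreground is `frame > t`
#' for a bright cell on a dark background.
#'
#' Methods: `otsu` maximizes between-class variance; `mean` is the arithmetic
#' mean of all intensities; `isodata` is the Ridler-Calvard iterative
#' intermeans rule; `li` iterates the minimum-cross-entropy update;
#' `triangle` maximizes the distance between the histogram and the line from
#' its peak to the far tail; `yen` maximizes Yen's maximum-correlation
#' criterion; `minimum` smooths the histogram until it is bimodal and takes
#' the minimum between the two modes.
#'
#' @param frame Numeric matrix of intensities with >= 2 distinct values.
#' @param method One of `"otsu"`, `"mean"`, `"li"`, `"triangle"`, `"yen"`,
#'   `"isodata"`, `"minimum"`.
#' @param frame_index Optional 0-based index used in error messages.
#' @return A single threshold intensity.
#' @export
auto_threshold <- function(frame,
                           method = c("otsu", "mean", "li", "triangle",
                                      "yen", "isodata", "minimum"),
                           frame_index = NA_integer_) {
  method <- match.arg(method)
  v <- as.vector(frame)
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    abort(sprintf("frame %s is constant (single intensity %g); cannot threshold",
                  ifelse(is.na(frame_index), "?", as.character(frame_index)), lo))
  }
  if (method == "mean") return(mean(v))

  h <- hist256(v)
  tbin <- switch(method,
    otsu = otsu_bin(h$counts),
    isodata = isodata_bin(h$counts),
    li = li_bin(h$counts),
    triangle = triangle_bin(h$counts),
    yen = yen_bin(h$counts),
    minimum = minimum_bin(h$counts)
  )
  h$levels[tbin + 1L]
}

# 256-bin histogram; identity binning for 8-bit-like integer data
hist256 <- function(v) {
  lo <- min(v); hi <- max(v)
  if (all(v == round(v)) && lo >= 0 && hi <= 255) {
    counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
    levels <- 0:255
  } else {
    bins <- as.integer(round((v - lo) / (hi - lo) * 255))
    counts <- tabulate(bins + 1L, nbins = 256L)
    levels <- lo + (0:255) * (hi - lo) / 255
  }
  list(counts = counts, levels = as.numeric(levels))
}

# Otsu: argmax over cuts k (foreground = bins > k) of between-class variance.
otsu_bin <- function(counts) {
  p <- counts / sum(counts)
  i <- 0:255
  w0 <- cumsum(p)
  mu0 <- cumsum(p * i)
  muT <- mu0[256]
  k <- 0:254
  w0k <- w0[k + 1L]
  num <- (muT * w0k - mu0[k + 1L])^2
  den <- w0k * (1 - w0k)
  sb <- ifelse(den > 0, num / den, -Inf)
  k[which.max(sb)]
}

isodata_bin <- function(counts) {
  i <- 0:255
  t <- floor(sum(counts * i) / sum(counts))
  repeat {
    lower <- counts[i <= t]; upper <- counts[i > t]
    if (sum(upper) == 0) { t <- t - 1L; next }
    if (sum(lower) == 0) { t <- t + 1L; next }
    m0 <- sum(i[i <= t] * lower) / sum(lower)
    m1 <- sum(i[i > t] * upper) / sum(upper)
    t_new <- floor((m0 + m1) / 2)
    if (t_new == t) return(t)
    t <- t_new
  }
}

# Li & Lee minimum cross entropy, iterative update on the bin scale.
li_bin <- function(counts) {
  i <- 0:255
  eps <- 1e-10
  t <- sum(counts * i) / sum(counts)
  repeat {
    lower <- i <= t
    s0 <- sum(counts[lower]); s1 <- sum(counts[!lower])
    m0 <- if (s0 > 0) sum(counts[lower] * i[lower]) / s0 else eps
    m1 <- if (s1 > 0) sum(counts[!lower] * i[!lower]) / s1 else eps
    m0 <- max(m0, eps); m1 <- max(m1, eps)
    if (abs(m0 - m1) < eps) return(as.integer(floor(t)))
    t_new <- (m0 - m1) / (log(m0) - log(m1))
    if (abs(t_new - t) < 0.5) return(as.integer(floor(t_new)))
    t <- t_new
  }
}

triangle_bin <- function(counts) {
  nz <- which(counts > 0)
  b_min <- nz[1] - 1L; b_max <- nz[length(nz)] - 1L
  b_peak <- which.max(counts) - 1L
  # work on the longer tail side of the peak; flip so the tail is to the right
  flipped <- (b_peak - b_min) > (b_max - b_peak)
  h <- if (flipped) rev(counts) else counts
  peak <- if (flipped) 255L - b_peak else b_peak
  endb <- if (flipped) 255L - b_min else b_max
  if (endb <= peak) return(if (flipped) 255L - peak else peak)
  ks <- seq.int(peak, endb)
  # largest drop of the histogram below the line from (peak, h_peak) to
  # (endb, 0): the valley between the peak and the tail end
  line_y <- h[peak + 1L] + (ks - peak) * (0 - h[peak + 1L]) / (endb - peak)
  d <- line_y - h[ks + 1L]
  k <- ks[which.max(d)]
  if (flipped) 255L - k else k
}

yen_bin <- function(counts) {
  p <- counts / sum(counts)
  p2 <- cumsum(p^2)
  P1 <- cumsum(p)
  tot2 <- p2[256]
  k <- 0:254
  g0 <- p2[k + 1L]
  g1 <- tot2 - g0
  w0 <- P1[k + 1L]
  w1 <- 1 - w0
  crit <- ifelse(
    g0 > 0 & g1 > 0 & w0 > 0 & w1 > 0,
    -log(g0 * g1) + 2 * log(w0 * w1),
    -Inf
  )
  k[which.max(crit)]
}

# Prewitt & Mendelsohn mode method: smooth until bimodal, take the valley.
minimum_bin <- function(counts) {
  h <- as.numeric(counts)
  n_modes <- function(x) {
    sum(x[2:255] > x[1:254] & x[2:255] >= x[3:256])
  }
  iter <- 0L
  while (n_modes(h) > 2L && iter < 10000L) {
    h <- (c(h[1], h[-256]) + h + c(h[-1], h[256])) / 3
    iter <- iter + 1L
  }
  if (n_modes(h) != 2L) {
    abort("histogram could not be reduced to two modes for method 'minimum'")
  }
  modes <- which(h[2:255] > h[1:254] & h[2:255] >= h[3:256]) + 1L
  valley <- seq.int(modes[1], modes[2])
  valley[which.min(h[valley])] - 1L
}

#' Binarize a stack with a selectable auto-threshold method
#'
#' In `first_frame` mode the threshold computed on frame 0 is applied to the
#' whole series (the interactive workflow previews all methods on the first
#' frame); in `per_frame` mode (default) it is recomputed on each frame,
#' which is robust to intensity drift over hours of imaging. A per-frame
#' threshold report is attached as the `"threshold_report"` attribute and can
#' be retrieved with [threshold_report()].
#'
#' @param stack An [image_stack()].
#' @param method Threshold method, see [auto_threshold()].
#' @param mode `"per_frame"` or `"first_frame"`.
#' @param polarity `"bright_cell"` (fluorescence, default) or `"dark_cell"`;
#'   dark cells are inverted before thresholding.
#' @return A [mask_stack()] with compartment `"tracer"` (the raw binarized
#'   series, before clean-up).
#' @export
binarize_stack <- function(stack, method = "otsu",
                           mode = c("per_frame", "first_frame"),
                           polarity = c("bright_cell", "dark_cell")) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  stopifnot(inherits(stack, "image_stack"))
  work <- if (polarity == "dark_cell") lapply(stack$frames, function(f) -f)
          else stack$frames

  if (mode == "first_frame") {
    t0 <- auto_threshold(work[[1]], method, frame_index = 0L)
    thr <- rep(t0, length(work))
  } else {
    thr <- vapply(seq_along(work), function(i) {
      auto_threshold(work[[i]], method, frame_index = i - 1L)
    }, numeric(1))
  }
  frames <- map2(work, thr, function(f, t) f > t)
  out <- mask_stack(frames, "tracer",
                    pixel_size_um = stack$pixel_size_um,
                    frame_interval_min = stack$frame_interval_min)
  attr(out, "threshold_report") <- tibble(
    frame = seq_along(work) - 1L,
    method = method,
    mode = mode,
    polarity = polarity,
    threshold = thr
  )
  out
}

#' Retrieve the threshold report attached to a binarized mask stack
#'
#' @param mask A [mask_stack()] produced by [binarize_stack()] or
#'   [segment_whole_cell()].
#' @return A tibble with columns `frame`, `method`, `mode`, `polarity`,
#'   `threshold`.
#' @export
threshold_report <- function(mask) {
  attr(mask, "threshold_report")
}

#' Fill interior holes in a binary frame or mask stack
#'
#' Every background region not 4-connected to the frame border becomes
#' foreground (4-connected holes complement the 8-connected foreground).
#' Idempotent.
#'
#' @param x A logical matrix or a [mask_stack()].
#' @return Same type as `x`.
#' @export
fill_holes <- function(x) {
  if (inherits(x, "mask_stack")) {
    x$frames <- lapply(x$frames, fill_holes_frame)
    return(x)
  }
  fill_holes_frame(x)
}

fill_holes_frame <- function(m) {
  mode(m) <- "logical"
  if (!any(m) || all(m)) return(m)
  bg <- matrix(0, nrow(m), ncol(m))
  bg[!m] <- 1
  lab <- EBImage::bwlabel(bg) # 4-connected background components
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  hole <- lab > 0 & !(lab %in% border_labels)
  m | hole
}

#' Remove background components by size
#'
#' `keep_largest` retains only the largest 8-connected component (ties broken
#' by lowest label id in scan order); `min_area` removes every component
#' smaller than `min_area_um2`. Idempotent under both policies.
#'
#' @param x A logical matrix or a [mask_stack()].
#' @param policy `"keep_largest"` or `"min_area"`.
#' @param min_area_um2 Minimum component area in square microns
#'   (`min_area` policy).
#' @param pixel_size_um Pixel size used to convert the area cut-off
#'   (taken from the stack when `x` is a [mask_stack()]).
#' @return Same type as `x`.
#' @export
size_exclude <- function(x, policy = c("keep_largest", "min_area"),
                         min_area_um2 = 0, pixel_size_um = 1) {
  policy <- match.arg(policy)
  if (inherits(x, "mask_stack")) {
    x$frames <- lapply(x$frames, size_exclude_frame, policy = policy,
                       min_area_um2 = min_area_um2,
                       pixel_size_um = x$pixel_size_um)
    return(x)
  }
  size_exclude_frame(x, policy, min_area_um2, pixel_size_um)
}

size_exclude_frame <- function(m, policy, min_area_um2, pixel_size_um) {
  mode(m) <- "logical"
  lab <- label_components(m)
  if (length(lab$areas_px) == 0L) {
    if (policy == "keep_largest") warn("size_exclude: empty frame, nothing to keep")
    return(m)
  }
  if (policy == "keep_largest") {
    keep <- which.max(lab$areas_px) # ties -> lowest id (scan order)
  } else {
    keep <- which(lab$areas_px * pixel_size_um^2 >= min_area_um2)
  }
  lab$labels %in% keep & m
}

#' Remove thin noise objects attached to the cell outline
#'
#' Morphological opening with a Euclidean disk of radius `radius_px`
#' (pixels at distance <= r from the centre; r = 1 is the 3 x 3 cross).
#' `radius_px = 0` is the identity. Anti-extensive and idempotent; the
#' headless replacement for manually cutting attached debris.
#'
#' @param x A logical matrix or a [mask_stack()].
#' @param radius_px Disk radius in pixels (>= 0).
#' @return Same type as `x`.
#' @export
remove_attached_noise <- function(x, radius_px = 0) {
  stopifnot(radius_px >= 0)
  if (inherits(x, "mask_stack")) {
    x$frames <- lapply(x$frames, open_frame, r = radius_px)
    return(x)
  }
  open_frame(x, radius_px)
}

# offsets of a Euclidean disk structuring element of radius r
disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# binary erosion/dilation by offset shifts; outside the frame is background
shift_mask <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) > 0L && length(cs) > 0L) {
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}

erode_mask <- function(m, offs) {
  out <- m
  for (i in seq_len(nrow(offs))) {
    out <- out & shift_mask(m, -offs$dr[i], -offs$dc[i], FALSE)
  }
  out
}

dilate_mask <- function(m, offs) {
  out <- m
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_mask(m, offs$dr[i], offs$dc[i], FALSE)
  }
  out
}

open_frame <- function(m, r) {
  mode(m) <- "logical"
  if (r == 0 || !any(m)) return(m)
  offs <- disk_offsets(r)
  dilate_mask(erode_mask(m, offs), offs)
}

#' Segment the whole cell from an intensity stack
#'
#' The standard clean-up chain: binarize with a global auto-threshold
#' ([binarize_stack()]), fill interior holes, remove attached noise by
#' opening, and apply size exclusion so the final whole-cell mask has at most
#' one connected component per frame (under the default `keep_largest`
#' policy). Optional exclusion ROIs are erased from the intensity data first
#' ([apply_exclusions()]).
#'
#' @inheritParams binarize_stack
#' @param fill Fill interior holes (default `TRUE`).
#' @param size_policy,min_area_um2 Passed to [size_exclude()].
#' @param open_radius_px Passed to [remove_attached_noise()] (0 disables).
#' @param exclusions Optional [roi_set()] of background regions to erase
#'   before thresholding.
#' @return A [mask_stack()] with compartment `"whole_cell"` and the
#'   threshold report attached (see [threshold_report()]).
#' @export
segment_whole_cell <- function(stack, method = "otsu",
                               mode = c("per_frame", "first_frame"),
                               polarity = c("bright_cell", "dark_cell"),
                               fill = TRUE,
                               size_policy = c("keep_largest", "min_area"),
                               min_area_um2 = 0,
                               open_radius_px = 0,
                               exclusions = NULL) {
  size_policy <- match.arg(size_policy)
  stack <- apply_exclusions(stack, exclusions)
  bin <- binarize_stack(stack, method = method, mode = mode, polarity = polarity)
  rep <- threshold_report(bin)
  out <- bin
  if (fill) out <- fill_holes(out)
  if (open_radius_px > 0) out <- remove_attached_noise(out, open_radius_px)
  out <- size_exclude(out, policy = size_policy, min_area_um2 = min_area_um2)
  out$compartment <- "whole_cell"
  attr(out, "threshold_report") <- rep
  out
}

#' Frame-0 masks for every threshold method
#'
#' The headless analogue of the interactive method-preview loop: binarizes
#' the first frame with each supported method so the masks can be inspected
#' offline before committing to one.
#'
#' @param stack An [image_stack()].
#' @param polarity See [binarize_stack()].
#' @return Named list of logical matrices, one per method, with the
#'   thresholds in the `"thresholds"` attribute.
#' @export
preview_all_methods <- function(stack, polarity = c("bright_cell", "dark_cell")) {
  polarity <- match.arg(polarity)
  f <- stack$frames[[1]]
  if (polarity == "dark_cell") f <- -f
  methods <- c("otsu", "mean", "li", "triangle", "yen", "isodata", "minimum")
  thr <- vapply(methods, function(m) {
    tryCatch(auto_threshold(f, m, frame_index = 0L),
             error = function(e) NA_real_)
  }, numeric(1))
  out <- lapply(thr, function(t) if (is.na(t)) NULL else f > t)
  attr(out, "thresholds") <- thr
  out
}
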