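#' 8-connected component labeling of a binary frame
#'
#' Foreground components use 8-connectivity (two pixels touching at a corner
#' belong to the same object); label ids are consecutive from 1 in scan order
#' (row-major order of each component's first pixel). Built on a 4-connected
#' base labeling whose diagonally adjacent labels are merged by union-find.
#'
#' @param m Logical matrix.
#' @return A list of class `labeled_frame` with `labels` (integer matrix,
#'   0 = background) and `areas_px` (pixel count per id).
#' @export
label_components <- function(m) {
  mode(m) <- "logical"
  num <- matrix(0, nrow(m), ncol(m)); num[m] <- 1
  lab4 <- EBImage::bwlabel(num)
  K <- max(lab4)
  if (K == 0) {
    return(structure(list(labels = matrix(0L, nrow(m), ncol(m)),
                          areas_px = numeric(0)),
                     class = "labeled_frame"))
  }
  nr <- nrow(m); nc <- ncol(m)
  parent <- seq_len(K)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  # collect diagonal label adjacencies
  pairs <- NULL
  if (nr > 1L && nc > 1L) {
    a <- lab4[-nr, -nc]; b <- lab4[-1, -1]     # down-right diagonals
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
    a <- lab4[-1, -nc]; b <- lab4[-nr, -1]     # up-right diagonals
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (!is.null(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ri <- find(pairs[r, 1]); rj <- find(pairs[r, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(K), find, integer(1))

  labels <- matrix(0L, nr, nc)
  fg <- lab4 > 0
  merged <- root[lab4[fg]]
  # relabel roots consecutively by row-major first-pixel scan order
  rows <- row(lab4)[fg]; cols <- col(lab4)[fg]
  scan_pos <- (rows - 1L) * nc + cols
  first_pos <- tapply(scan_pos, merged, min)
  ord <- order(first_pos)
  newid <- integer(max(merged))
  newid[as.integer(names(first_pos))[ord]] <- seq_along(ord)
  labels[fg] <- newid[merged]
  areas <- tabulate(labels[fg])
  structure(list(labels = labels, areas_px = as.numeric(areas)),
            class = "labeled_frame")
}

#' Subtract the cell body to isolate the blebs
#'
#' `all_blebs = whole AND NOT body`, frame by frame. The body may be given as
#' a [roi_set()] (rasterized with nearest-earlier inheritance) or directly as
#' a [mask_stack()]. A body that covers the whole-cell mask on every frame is
#' a bleb-free cell and raises a warning, not an error.
#'
#' @param whole Whole-cell [mask_stack()].
#' @param body A [roi_set()] or a [mask_stack()] defining the cell body.
#' @return A [mask_stack()] with compartment `"all_blebs"`.
#' @export
remove_body <- function(whole, body) {
  stopifnot(inherits(whole, "mask_stack"))
  if (inherits(body, "roi_set")) {
    body <- rois_to_mask(body, frame_dim(whole), n_frames(whole),
                         compartment = "cell_body",
                         pixel_size_um = whole$pixel_size_um,
                         frame_interval_min = whole$frame_interval_min)
  }
  stopifnot(inherits(body, "mask_stack"))
  if (n_frames(body) != n_frames(whole)) {
    abort("body mask must have the same frame count as the whole-cell mask")
  }
  frames <- map2(whole$frames, body$frames, function(w, b) w & !b)
  if (!any(vapply(frames, any, logical(1)))) {
    warn("remove_body: no bleb pixels on any frame (bleb-free cell)")
  }
  out <- mask_stack(frames, "all_blebs",
                    pixel_size_um = whole$pixel_size_um,
                    frame_interval_min = whole$frame_interval_min)
  out
}

#' Derive the cell body as whole cell minus blebs
#'
#' `cell_body = whole AND NOT all_blebs`; together the two compartments
#' partition the whole-cell mask exactly (disjoint, union = whole).
#'
#' @param whole Whole-cell [mask_stack()].
#' @param all_blebs Bleb [mask_stack()], a subset of `whole` on every frame.
#' @return A [mask_stack()] with compartment `"cell_body"`.
#' @export
derive_cell_body <- function(whole, all_blebs) {
  stopifnot(inherits(whole, "mask_stack"), inherits(all_blebs, "mask_stack"))
  if (n_frames(whole) != n_frames(all_blebs)) {
    abort("frame counts differ between whole-cell and bleb masks")
  }
  for (t in seq_len(n_frames(whole))) {
    if (any(all_blebs$frames[[t]] & !whole$frames[[t]])) {
      abort(sprintf("all_blebs is not contained in whole_cell on frame %d", t - 1L))
    }
  }
  frames <- map2(whole$frames, all_blebs$frames, function(w, b) w & !b)
  mask_stack(frames, "cell_body",
             pixel_size_um = whole$pixel_size_um,
             frame_interval_min = whole$frame_interval_min)
}

#' Label individual blebs on a frame
#'
#' 8-connected labeling of the bleb mask with an optional minimum-area filter
#' (thresholding speckle can masquerade as blebs; the default of 0 keeps
#' everything).
#'
#' @param x Logical matrix (one bleb frame) or an all-blebs [mask_stack()].
#' @param min_bleb_area_um2 Components below this area are dropped before
#'   labeling.
#' @param pixel_size_um Pixel size (taken from the stack when `x` is a
#'   [mask_stack()]).
#' @return A `labeled_frame` (see [label_components()]) with an extra
#'   `areas_um2` element, or a list of them for a stack.
#' @export
label_blebs <- function(x, min_bleb_area_um2 = 0, pixel_size_um = 1) {
  if (inherits(x, "mask_stack")) {
    return(lapply(x$frames, label_blebs,
                  min_bleb_area_um2 = min_bleb_area_um2,
                  pixel_size_um = x$pixel_size_um))
  }
  if (min_bleb_area_um2 > 0) {
    x <- size_exclude(x, "min_area", min_area_um2 = min_bleb_area_um2,
                      pixel_size_um = pixel_size_um)
  }
  lab <- label_components(x)
  lab$areas_um2 <- lab$areas_px * pixel_size_um^2
  lab
}

#' Isolate the largest bleb by area on each frame
#'
#' Per frame, only the maximum-area 8-connected component of the bleb mask is
#' retained. Area ties are broken by the lowest label id (deterministic scan
#' order) and logged; bleb-free frames stay empty and are recorded in the
#' `"bleb_free_frames"` attribute (0-based indices).
#'
#' @param all_blebs An all-blebs [mask_stack()].
#' @param min_bleb_area_um2 Passed to [label_blebs()].
#' @return A [mask_stack()] with compartment `"largest_bleb"`.
#' @export
largest_bleb <- function(all_blebs, min_bleb_area_um2 = 0) {
  stopifnot(inherits(all_blebs, "mask_stack"))
  empty <- integer(0)
  frames <- vector("list", n_frames(all_blebs))
  for (t in seq_len(n_frames(all_blebs))) {
    lab <- label_blebs(all_blebs$frames[[t]],
                       min_bleb_area_um2 = min_bleb_area_um2,
                       pixel_size_um = all_blebs$pixel_size_um)
    if (length(lab$areas_px) == 0L) {
      frames[[t]] <- matrix(FALSE, nrow(all_blebs$frames[[t]]),
                            ncol(all_blebs$frames[[t]]))
      empty <- c(empty, t - 1L)
      next
    }
    if (sum(lab$areas_px == max(lab$areas_px)) > 1L) {
      inform(sprintf(
        "largest_bleb: area tie on frame %d, keeping lowest label id", t - 1L))
    }
    frames[[t]] <- lab$labels == which.max(lab$areas_px)
  }
  out <- mask_stack(frames, "largest_bleb",
                    pixel_size_um = all_blebs$pixel_size_um,
                    frame_interval_min = all_blebs$frame_interval_min)
  attr(out, "bleb_free_frames") <- empty
  out
}
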