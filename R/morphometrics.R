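#' Shape descriptors of a binary region
#'
#' Computes the standard descriptor battery for one region: area (pixel count
#' scaled to square microns), perimeter, circularity `4*pi*A/P^2` (clamped at
#' 1, since digitization can push it above), fitted-ellipse major/minor axes,
#' aspect ratio `major/minor`, roundness `4*A/(pi*major^2)`, solidity
#' `A / convex hull area`, and the centroid in microns.
#'
#' The perimeter is a corner-corrected chain-code estimator on the traced
#' 8-connected boundary (`0.980` per straight step, `1.406` per diagonal
#' step, `-0.091` per corner), which is accurate to well under 1% on smooth
#' shapes such as disks; regions of three pixels or fewer fall back to the
#' exposed-edge (crack) length. Ellipse axes come from the second-order
#' central moments of the pixel centres (plus the 1/12 within-pixel variance
#' term), rescaled so the fitted ellipse has the same area as the region;
#' with that normalization `roundness = 1/aspect_ratio` exactly. The convex
#' hull is taken over the pixel corner points, so a filled square has
#' solidity exactly 1.
#'
#' If the mask holds several components, area and perimeter are summed,
#' moments and hull are taken over the union.
#'
#' @param m Logical matrix containing the region (non-empty).
#' @param pixel_size_um Microns per pixel.
#' @return A one-row tibble with columns `area_um2`, `perimeter_um`,
#'   `circularity`, `roundness`, `aspect_ratio`, `solidity`,
#'   `major_axis_um`, `minor_axis_um`, `centroid_x_um`, `centroid_y_um`.
#' @export
measure_region <- function(m, pixel_size_um = 1) {
  mode(m) <- "logical"
  if (!any(m)) abort("measure_region: empty region")
  px <- pixel_size_um
  rows <- row(m)[m]; cols <- col(m)[m]
  npx <- length(rows)

  # centroid and second-order central moments of pixel centres
  x <- cols - 0.5; y <- rows - 0.5
  xb <- mean(x); yb <- mean(y)
  mu20 <- mean((x - xb)^2) + 1 / 12
  mu02 <- mean((y - yb)^2) + 1 / 12
  mu11 <- mean((x - xb) * (y - yb))
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  l2 <- max(l2, 1e-12)
  major_px <- 4 * sqrt(l1)
  minor_px <- 4 * sqrt(l2)
  # rescale so the ellipse area matches the region area
  s <- sqrt(npx / (pi * (major_px / 2) * (minor_px / 2)))
  major_px <- major_px * s
  minor_px <- minor_px * s
  aspect <- major_px / minor_px
  roundness <- min(1, 4 * npx / (pi * major_px^2))

  lab <- label_components(m)
  per_px <- sum(vapply(seq_along(lab$areas_px), function(id) {
    component_perimeter_px(lab$labels == id)
  }, numeric(1)))

  area <- npx * px^2
  perim <- per_px * px
  circ <- min(1, 4 * pi * area / perim^2)

  hull_px2 <- convex_hull_area_px(rows, cols)
  solidity <- npx / hull_px2

  tibble(
    area_um2 = area,
    perimeter_um = perim,
    circularity = circ,
    roundness = roundness,
    aspect_ratio = aspect,
    solidity = solidity,
    major_axis_um = major_px * px,
    minor_axis_um = minor_px * px,
    centroid_x_um = xb * px,
    centroid_y_um = yb * px
  )
}

# Convex hull area (in px^2) over the corner points of the listed pixels.
convex_hull_area_px <- function(rows, cols) {
  xs <- c(cols - 1, cols, cols - 1, cols)
  ys <- c(rows - 1, rows - 1, rows, rows)
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) < 3L) return(length(rows)) # degenerate: solidity 1
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# Chain-code perimeter of a single 8-connected component (pixel units).
component_perimeter_px <- function(m) {
  npx <- sum(m)
  if (npx <= 3L) return(crack_length_px(m))
  chain <- trace_boundary_chain(m)
  if (length(chain) == 0L) return(crack_length_px(m))
  diag_step <- chain %% 2L == 1L
  nd <- sum(diag_step); ns <- length(chain) - nd
  corners <- sum(chain != c(chain[-1], chain[1]))
  max(0.980 * ns + 1.406 * nd - 0.091 * corners, 1)
}

# exposed pixel edges (crack boundary), exact for tiny regions
crack_length_px <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- p[2:(nr + 1L), 2:(nc + 1L)]
  sum(core & !p[1:nr, 2:(nc + 1L)]) + sum(core & !p[3:(nr + 2L), 2:(nc + 1L)]) +
    sum(core & !p[2:(nr + 1L), 1:nc]) + sum(core & !p[2:(nr + 1L), 3:(nc + 2L)])
}

# Moore boundary tracing with an explicit backtrack pixel and Jacob's
# stopping criterion; returns the Freeman chain code (0 = E, clockwise
# through 7 = NE) of the closed 8-connected boundary of the component in m.
trace_boundary_chain <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  # clockwise neighbour offsets starting at E (dr, dc) in matrix coords
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  # start: topmost then leftmost foreground pixel (its W neighbour is bg)
  idx <- which(p, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  sr <- idx[ord[1], 1]; sc <- idx[ord[1], 2]
  pr0 <- sr; pc0 <- sc - 1L # initial backtrack: the background W neighbour

  chain <- integer(0)
  cr <- sr; cc <- sc; pr <- pr0; pc <- pc0
  for (safety in seq_len(8L * (nr + 2L) * (nc + 2L))) {
    if (safety > 1L && cr == sr && cc == sc && pr == pr0 && pc == pc0) break
    # direction from current to the backtrack pixel
    db <- which(dr == pr - cr & dc == pc - cc) - 1L
    found <- -1L
    for (k in 1:8) {
      d <- (db + k) %% 8L
      if (p[cr + dr[d + 1L], cc + dc[d + 1L]]) { found <- d; break }
      pr <- cr + dr[d + 1L]; pc <- cc + dc[d + 1L] # last background examined
    }
    if (found < 0L) return(integer(0)) # isolated pixel
    chain <- c(chain, found)
    cr <- cr + dr[found + 1L]; cc <- cc + dc[found + 1L]
  }
  chain
}

#' Measure every labeled object on a frame
#'
#' @param m Logical matrix.
#' @param pixel_size_um Microns per pixel.
#' @param min_area_um2 Objects below this area are skipped.
#' @return A tibble with one row per 8-connected component (column `object`
#'   gives the label id); zero rows for an empty frame.
#' @export
measure_frame <- function(m, pixel_size_um = 1, min_area_um2 = 0) {
  lab <- label_components(m)
  ids <- which(lab$areas_px * pixel_size_um^2 >= pmax(min_area_um2, 0) &
                 lab$areas_px > 0)
  if (length(lab$areas_px) == 0L || length(ids) == 0L) {
    return(empty_measure_tbl())
  }
  bind_rows(lapply(ids, function(id) {
    mutate(measure_region(lab$labels == id, pixel_size_um), object = id,
           .before = 1)
  }))
}

empty_measure_tbl <- function() {
  tibble(
    object = integer(0), area_um2 = numeric(0), perimeter_um = numeric(0),
    circularity = numeric(0), roundness = numeric(0),
    aspect_ratio = numeric(0), solidity = numeric(0),
    major_axis_um = numeric(0), minor_axis_um = numeric(0),
    centroid_x_um = numeric(0), centroid_y_um = numeric(0)
  )
}

#' Measure every object on every frame of a mask stack
#'
#' @param mask A [mask_stack()].
#' @param min_area_um2 Passed to [measure_frame()].
#' @return A tibble with columns `frame` (0-based), `compartment`, then the
#'   [measure_frame()] columns.
#' @export
measure_stack <- function(mask, min_area_um2 = 0) {
  stopifnot(inherits(mask, "mask_stack"))
  bind_rows(lapply(seq_along(mask$frames), function(t) {
    tb <- measure_frame(mask$frames[[t]], mask$pixel_size_um, min_area_um2)
    if (nrow(tb) == 0L) return(tb)
    mutate(tb, frame = t - 1L, compartment = mask$compartment, .before = 1)
  }))
}

#' Percent-of-cell-area measures
#'
#' @param whole_area_um2 Whole-cell area of the frame (> 0).
#' @param total_bleb_area_um2 Summed area of all blebs on the frame.
#' @param largest_bleb_area_um2 Area of the largest bleb (0 if bleb-free).
#' @return A one-row tibble with `pct_total_blebs` and `pct_leader_bleb`
#'   (percent, 0-100; `pct_leader_bleb <= pct_total_blebs`).
#' @export
percent_areas <- function(whole_area_um2, total_bleb_area_um2,
                          largest_bleb_area_um2) {
  if (!is.finite(whole_area_um2) || whole_area_um2 <= 0) {
    abort("whole-cell area must be positive")
  }
  tibble(
    pct_total_blebs = 100 * total_bleb_area_um2 / whole_area_um2,
    pct_leader_bleb = 100 * largest_bleb_area_um2 / whole_area_um2
  )
}

#' Per-frame, per-compartment morphometrics table
#'
#' Builds the frame-by-frame record the per-image CSVs are written from: one
#' row per frame for `whole_cell`, `cell_body` and `largest_bleb` (measuring
#' the compartment mask), plus one `all_blebs` row per frame carrying the
#' bleb count, the total bleb area and the frame's percent-of-cell-area
#' measures. Frames with an empty whole-cell mask are skipped with a warning;
#' bleb-free frames keep their `all_blebs` row (`bleb_count = 0`) and have no
#' `largest_bleb` row.
#'
#' @param whole,body,blebs,largest The four compartment [mask_stack()]s.
#' @param min_bleb_area_um2 Minimum bleb area counted as a bleb.
#' @return A tibble; `pct_total_blebs` and `pct_leader_bleb` are repeated on
#'   every row of a frame.
#' @export
compartment_table <- function(whole, body, blebs, largest,
                              min_bleb_area_um2 = 0) {
  px <- whole$pixel_size_um
  out <- vector("list", n_frames(whole))
  for (t in seq_len(n_frames(whole))) {
    wf <- whole$frames[[t]]
    if (!any(wf)) {
      warn(sprintf("compartment_table: empty whole-cell mask on frame %d", t - 1L))
      next
    }
    w <- mutate(measure_region(wf, px), compartment = "whole_cell")
    b <- if (any(body$frames[[t]])) {
      mutate(measure_region(body$frames[[t]], px), compartment = "cell_body")
    }
    bleb_tb <- measure_frame(blebs$frames[[t]], px, min_bleb_area_um2)
    lg <- if (any(largest$frames[[t]])) {
      mutate(measure_region(largest$frames[[t]], px), compartment = "largest_bleb")
    }
    all_row <- tibble(
      compartment = "all_blebs",
      area_um2 = sum(bleb_tb$area_um2),
      bleb_count = nrow(bleb_tb),
      mean_bleb_area_um2 = if (nrow(bleb_tb)) mean(bleb_tb$area_um2) else NA_real_
    )
    pct <- percent_areas(w$area_um2, sum(bleb_tb$area_um2),
                         if (is.null(lg)) 0 else lg$area_um2)
    rows <- bind_rows(w, b, all_row, lg)
    rows$frame <- t - 1L
    rows$pct_total_blebs <- pct$pct_total_blebs
    rows$pct_leader_bleb <- pct$pct_leader_bleb
    out[[t]] <- rows
  }
  tb <- bind_rows(out)
  if (nrow(tb) == 0L) return(tb)
  select(tb, "frame", "compartment", dplyr::everything())
}

#' Per-cell averages over frames
#'
#' Collapses a [compartment_table()] into one row per cell: the unweighted
#' mean of each descriptor over the frames that possess it. Bleb-count
#' averages include bleb-free frames (count 0); bleb size and largest-bleb
#' shape averages by default use only frames with at least one bleb (the
#' shape of nothing cannot be averaged) — set `include_blebfree_frames =
#' TRUE` to count bleb-free frames as zero-area instead. Both denominators
#' are reported (`n_frames`, `n_frames_with_blebs`).
#'
#' @param frame_tbl A [compartment_table()].
#' @param cell_id Identifier copied into the output.
#' @param include_blebfree_frames Include bleb-free frames (as zero area) in
#'   the bleb-size averages.
#' @return A one-row tibble of per-cell means.
#' @export
summarize_cell <- function(frame_tbl, cell_id = "cell",
                           include_blebfree_frames = FALSE) {
  if (nrow(frame_tbl) == 0L) {
    warn("summarize_cell: no usable frames")
    return(tibble(cell_id = cell_id, n_frames = 0L))
  }
  shape_cols <- c("area_um2", "roundness", "circularity", "solidity",
                  "aspect_ratio")
  comp_means <- function(comp, prefix) {
    tb <- filter(frame_tbl, .data$compartment == comp)
    if (nrow(tb) == 0L) {
      return(setNames(as.list(rep(NA_real_, length(shape_cols))),
                      paste0(prefix, shape_cols)))
    }
    setNames(as.list(colMeans(tb[shape_cols])), paste0(prefix, shape_cols))
  }
  ab <- filter(frame_tbl, .data$compartment == "all_blebs")
  bleb_sizes <- ab$mean_bleb_area_um2
  if (include_blebfree_frames) {
    bleb_sizes[is.na(bleb_sizes)] <- 0
  } else {
    bleb_sizes <- bleb_sizes[!is.na(bleb_sizes)]
  }
  frames <- sort(unique(frame_tbl$frame))
  out <- c(
    list(
      cell_id = cell_id,
      avg_bleb_count = if (nrow(ab)) mean(ab$bleb_count) else NA_real_,
      avg_bleb_area_um2 = if (length(bleb_sizes)) mean(bleb_sizes) else NA_real_,
      avg_pct_total_blebs = if (nrow(ab)) mean(ab$pct_total_blebs) else NA_real_,
      avg_pct_leader_bleb = if (nrow(ab)) mean(ab$pct_leader_bleb) else NA_real_
    ),
    comp_means("largest_bleb", "avg_largest_bleb_"),
    comp_means("cell_body", "avg_cell_body_"),
    comp_means("whole_cell", "avg_whole_cell_"),
    list(
      n_frames = length(frames),
      n_frames_with_blebs = sum(ab$bleb_count > 0)
    )
  )
  as_tibble(out)
}
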