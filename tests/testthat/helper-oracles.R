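# Independent brute-force oracles, deliberately naive implementations that
# share no code with the package internals.

# Otsu by exhaustive search: try every cut point t (foreground = value > t),
# maximize between-class variance of the raw 8-bit values.
oracle_otsu_8bit <- function(v) {
  v <- as.integer(v)
  best_t <- NA_integer_; best_var <- -Inf
  for (t in 0:254) {
    bg <- v[v <= t]; fg <- v[v > t]
    if (length(bg) == 0L || length(fg) == 0L) next
    w0 <- length(bg) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (bc > best_var) { best_var <- bc; best_t <- t }
  }
  best_t
}

# Connected components by BFS flood fill (8-connectivity).
oracle_flood_fill <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!m[r, c] || lab[r, c] > 0L) next
    k <- k + 1L
    queue <- list(c(r, c)); lab[r, c] <- k
    while (length(queue) > 0L) {
      q <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- q[1] + dr; cc <- q[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (m[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- k
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Convex hull area over pixel corner points: Andrew's monotone chain plus
# the shoelace formula (no grDevices::chull).
oracle_hull_area <- function(m) {
  rows <- row(m)[m]; cols <- col(m)[m]
  pts <- unique(rbind(
    cbind(cols - 1, rows - 1), cbind(cols, rows - 1),
    cbind(cols - 1, rows), cbind(cols, rows)
  ))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- list()
    for (i in idx) {
      p <- pts[i, ]
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], p) <= 0) {
        h[[length(h)]] <- NULL
      }
      h[[length(h) + 1]] <- p
    }
    h
  }
  lower <- build(seq_len(nrow(pts)))
  upper <- build(rev(seq_len(nrow(pts))))
  hull <- do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
  x <- hull[, 1]; y <- hull[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Morphological opening by explicit neighborhood min (erosion) then max
# (dilation) over the offsets of a Euclidean disk.
oracle_opening <- function(m, r) {
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  nr <- nrow(m); nc <- ncol(m)
  shift_all <- function(x, all_of) {
    out <- matrix(all_of, nr, nc)
    for (i in seq_len(nrow(offs))) {
      sh <- matrix(FALSE, nr, nc) # out-of-bounds counts as background
      rs <- (1:nr) + offs$dr[i]; cs <- (1:nc) + offs$dc[i]
      ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
      sh[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
      out <- if (all_of) out & sh else out | sh
    }
    out
  }
  er <- shift_all(m, TRUE)
  shift_all(er, FALSE)
}

# Exhaustive one-to-one assignment between consecutive-frame components,
# maximizing total overlap subject to the minimum-overlap-fraction gate.
oracle_best_assignment <- function(lab_a, areas_a, lab_b, areas_b, min_frac) {
  na <- length(areas_a); nb <- length(areas_b)
  ov <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    ov[i, j] <- sum(lab_a == i & lab_b == j)
  }
  allowed <- ov / outer(areas_a, areas_b, pmin) >= min_frac & ov > 0
  best <- NULL; best_tot <- -1
  perms <- function(v) if (length(v) <= 1) list(v) else {
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  # try every injective mapping of b-components to a-components (small n)
  cand_a <- c(seq_len(na), rep(NA_integer_, max(0, nb - na)))
  for (p in perms(cand_a)) {
    sel <- p[seq_len(nb)]
    tot <- 0; ok <- TRUE
    for (j in seq_len(nb)) {
      i <- sel[j]
      if (is.na(i)) next
      if (!allowed[i, j]) { sel[j] <- NA_integer_; next }
      tot <- tot + ov[i, j]
    }
    if (tot > best_tot) { best_tot <- tot; best <- sel }
  }
  best
}

# small utilities for building mask fixtures
mk_mask <- function(h, w, pred) {
  m <- matrix(FALSE, h, w)
  m[pred(row(m), col(m))] <- TRUE
  m
}

mk_disk <- function(h, w, cr, cc, r) {
  mk_mask(h, w, function(rr, cc2) (rr - cr)^2 + (cc2 - cc) ^ 2 <= r^2)
}

as_stack <- function(frames, px = 1, dt = 8) {
  image_stack(frames, pixel_size_um = px, frame_interval_min = dt)
}
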