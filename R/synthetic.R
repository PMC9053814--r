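#' Parameters of a synthetic blebbing-cell scene
#'
#' Describes one cell as an elliptical body with circular blebs attached to
#' its rim, moving (or not) over a fixed field of view, rendered at a given
#' calibration with additive Gaussian noise. The defaults emulate a confined
#' melanoma-like cell imaged every 8 minutes at 0.5 um/pixel: a body of
#' 10 x 7 um semi-axes on a ~100 intensity-unit contrast, with noise at 5%
#' of that contrast. A single integer seed fully determines the rendered
#' movie (noise) — the geometry itself is deterministic given the bleb list.
#'
#' @param dim_px Frame size `c(height, width)` in pixels.
#' @param pixel_size_um Microns per pixel.
#' @param frame_interval_min Minutes per frame.
#' @param n_frames Number of frames.
#' @param body List with `center_um = c(x, y)` (first-frame centre) and
#'   `semi_axes_um = c(a, b)` (x and y semi-axes of the ellipse).
#' @param motion List: `type` one of `"none"`, `"linear"`, `"random_walk"`;
#'   `velocity_um_min = c(vx, vy)` for linear; `step_um` for random walk.
#' @param blebs Tibble/data.frame with one row per bleb: `angle_deg`
#'   (attachment angle on the body rim, 0 = +x, counter-clockwise),
#'   `radius_um`, `birth_frame` (0-based), `lifetime_frames`.
#' @param intensities `c(background, cell)` intensity levels (8-bit scale).
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed Integer seed driving the noise.
#' @param name Scene name.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(dim_px = c(96L, 192L),
                         pixel_size_um = 0.5,
                         frame_interval_min = 8,
                         n_frames = 10L,
                         body = list(center_um = c(25, 24),
                                     semi_axes_um = c(10, 7)),
                         motion = list(type = "none"),
                         blebs = NULL,
                         intensities = c(background = 20, cell = 120),
                         noise_sd = 5,
                         seed = 1L,
                         name = "synthetic") {
  if (is.null(blebs)) {
    blebs <- tibble(angle_deg = numeric(0), radius_um = numeric(0),
                    birth_frame = integer(0), lifetime_frames = integer(0))
  }
  blebs <- as_tibble(blebs)
  stopifnot(
    length(dim_px) == 2L, all(dim_px > 0),
    pixel_size_um > 0, frame_interval_min > 0, n_frames >= 1L,
    all(body$semi_axes_um > 0),
    all(c("angle_deg", "radius_um", "birth_frame", "lifetime_frames") %in%
          names(blebs)),
    length(intensities) == 2L, noise_sd >= 0
  )
  structure(
    list(dim_px = as.integer(dim_px), pixel_size_um = pixel_size_um,
         frame_interval_min = frame_interval_min, n_frames = as.integer(n_frames),
         body = body, motion = motion, blebs = blebs,
         intensities = intensities, noise_sd = noise_sd,
         seed = as.integer(seed), name = name),
    class = "scene_params"
  )
}

body_center_at <- function(params, t) {
  c0 <- params$body$center_um
  mo <- params$motion
  if (identical(mo$type, "linear")) {
    c0 + mo$velocity_um_min * t * params$frame_interval_min
  } else if (identical(mo$type, "random_walk")) {
    if (t == 0) return(c0)
    # deterministic walk from the scene seed, independent of the noise stream
    steps <- with_seed(params$seed + 104729L, {
      ang <- stats::runif(t, 0, 2 * pi)
      cbind(cos(ang), sin(ang)) * mo$step_um
    })
    c0 + colSums(steps[seq_len(t), , drop = FALSE])
  } else {
    c0
  }
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# centre of bleb k at frame t: on the body rim at its attachment angle,
# pushed half a radius outward so most of the disc lies outside the body
bleb_center_at <- function(params, k, t) {
  ctr <- body_center_at(params, t)
  a <- params$body$semi_axes_um[1]; b <- params$body$semi_axes_um[2]
  phi <- params$blebs$angle_deg[k] * pi / 180
  rim_r <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  reach <- rim_r + 0.5 * params$blebs$radius_um[k]
  ctr + reach * c(cos(phi), sin(phi))
}

bleb_alive <- function(params, k, t) {
  b0 <- params$blebs$birth_frame[k]
  t >= b0 & t < b0 + params$blebs$lifetime_frames[k]
}

ellipse_mask <- function(dim_px, px, center_um, semi_um) {
  xs <- (seq_len(dim_px[2]) - 0.5) * px
  ys <- (seq_len(dim_px[1]) - 0.5) * px
  u <- outer(rep(1, dim_px[1]), (xs - center_um[1]) / semi_um[1])
  v <- outer((ys - center_um[2]) / semi_um[2], rep(1, dim_px[2]))
  u^2 + v^2 <= 1
}

disc_mask <- function(dim_px, px, center_um, radius_um) {
  ellipse_mask(dim_px, px, center_um, c(radius_um, radius_um))
}

#' Render a synthetic movie with ground truth
#'
#' Rasterizes the body ellipse and every live bleb at the cell intensity on
#' the background level, adds Gaussian noise and quantizes to 8 bits. The
#' ground truth is the noise-free geometry: the truth cell body is the body
#' ellipse, truth all-blebs are the bleb discs minus the body (the same
#' subtraction convention as the analysis pipeline), the truth whole cell is
#' their union. Truth bleb tracks and the truth phenotype come from the
#' scene parameters themselves, not from any image processing.
#'
#' @param params A [scene_params()].
#' @return A list of class `bleb_scene` with elements `stack`
#'   ([image_stack()]), `truth` (list of `whole`, `body`, `blebs`, `largest`
#'   [mask_stack()]s, `tracks` tibble, `lifetimes` tibble, `phenotype`
#'   one-row tibble, `body_rois` [roi_set()]) and `params`.
#' @export
render_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  d <- params$dim_px; px <- params$pixel_size_um
  nb <- nrow(params$blebs)

  body_frames <- vector("list", params$n_frames)
  bleb_frames <- vector("list", params$n_frames)
  whole_frames <- vector("list", params$n_frames)
  per_bleb_px <- vector("list", params$n_frames)
  for (t in seq_len(params$n_frames) - 1L) {
    ctr <- body_center_at(params, t)
    body <- ellipse_mask(d, px, ctr, params$body$semi_axes_um)
    blebs <- matrix(FALSE, d[1], d[2])
    areas <- rep(NA_real_, nb)
    for (k in seq_len(nb)) {
      if (!bleb_alive(params, k, t)) next
      disc <- disc_mask(d, px, bleb_center_at(params, k, t),
                        params$blebs$radius_um[k])
      only <- disc & !body
      areas[k] <- sum(only)
      blebs <- blebs | only
    }
    whole <- body | blebs
    if (any(whole[1, ]) || any(whole[d[1], ]) ||
        any(whole[, 1]) || any(whole[, d[2]])) {
      abort(sprintf("scene geometry touches the frame border on frame %d", t))
    }
    body_frames[[t + 1L]] <- body
    bleb_frames[[t + 1L]] <- blebs
    whole_frames[[t + 1L]] <- whole
    per_bleb_px[[t + 1L]] <- areas
  }

  bg <- params$intensities[[1]]; fg <- params$intensities[[2]]
  noise <- with_seed(params$seed, {
    lapply(seq_len(params$n_frames), function(i) {
      matrix(stats::rnorm(prod(d), 0, params$noise_sd), d[1], d[2])
    })
  })
  frames <- map2(whole_frames, noise, function(m, e) {
    f <- matrix(bg, d[1], d[2])
    f[m] <- fg
    pmin(pmax(round(f + if (params$noise_sd > 0) e else 0), 0), 255)
  })

  mk <- function(fr, comp) {
    mask_stack(fr, comp, pixel_size_um = px,
               frame_interval_min = params$frame_interval_min)
  }
  truth_blebs <- mk(bleb_frames, "all_blebs")
  truth <- list(
    whole = mk(whole_frames, "whole_cell"),
    body = mk(body_frames, "cell_body"),
    blebs = truth_blebs,
    largest = largest_bleb(truth_blebs),
    tracks = truth_tracks(params, per_bleb_px),
    phenotype = truth_phenotype(params, per_bleb_px, whole_frames),
    body_rois = body_rois(params)
  )
  truth$lifetimes <- bleb_lifetimes(truth$tracks,
                                    frame_interval_min = params$frame_interval_min)
  structure(
    list(
      stack = image_stack(frames, pixel_size_um = px,
                          frame_interval_min = params$frame_interval_min,
                          name = params$name),
      truth = truth,
      params = params
    ),
    class = "bleb_scene"
  )
}

truth_tracks <- function(params, per_bleb_px) {
  px2 <- params$pixel_size_um^2
  rows <- list()
  for (k in seq_len(nrow(params$blebs))) {
    for (t in seq_len(params$n_frames) - 1L) {
      a <- per_bleb_px[[t + 1L]][k]
      if (!is.na(a) && a > 0) {
        rows[[length(rows) + 1L]] <- tibble(
          track_id = k, frame = t, component_id = NA_integer_,
          area_um2 = a * px2
        )
      }
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(track_id = integer(0), frame = integer(0),
                  component_id = integer(0), area_um2 = numeric(0))
  }
  attr(out, "frame_interval_min") <- params$frame_interval_min
  class(out) <- c("bleb_tracks", class(out))
  out
}

# truth phenotype from the scene's own bookkeeping (never via the pipeline)
truth_phenotype <- function(params, per_bleb_px, whole_frames,
                            persistence_frames = 5, leader_area_frac = 0.10,
                            speed_min = 0.25) {
  px2 <- params$pixel_size_um^2
  whole_areas <- vapply(whole_frames, sum, numeric(1)) * px2
  has_leader <- FALSE
  for (k in seq_len(nrow(params$blebs))) {
    alive <- which(!is.na(vapply(per_bleb_px, `[`, numeric(1), k)) &
                     vapply(per_bleb_px, `[`, numeric(1), k) > 0)
    if (length(alive) < persistence_frames) next
    mean_area <- mean(vapply(per_bleb_px[alive], `[`, numeric(1), k)) * px2
    if (mean_area >= leader_area_frac * mean(whole_areas[alive])) {
      has_leader <- TRUE
    }
  }
  mo <- params$motion
  is_mobile <- identical(mo$type, "linear") &&
    sqrt(sum(mo$velocity_um_min^2)) >= speed_min &&
    params$n_frames >= persistence_frames
  label <- if (has_leader && is_mobile) "LM" else if (has_leader) "LNM" else "NL"
  tibble(cell_id = params$name, label = label,
         has_leader_bleb = has_leader, is_mobile = is_mobile)
}

# truth body ROIs: the body ellipse as a polygon per frame (0-based (r, c))
body_rois <- function(params, n_vertices = 72L) {
  px <- params$pixel_size_um
  polys <- list()
  for (t in seq_len(params$n_frames) - 1L) {
    ctr <- body_center_at(params, t)
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    x <- ctr[1] + params$body$semi_axes_um[1] * cos(th)
    y <- ctr[2] + params$body$semi_axes_um[2] * sin(th)
    polys[[as.character(t)]] <- cbind(row = y / px - 0.5, col = x / px - 0.5)
  }
  roi_set(polys, cell_id = params$name)
}

#' Preset synthetic scenes for the three confinement phenotypes and the
#' apoptotic / low-confinement contrast
#'
#' * `LM` — moves linearly at 0.5 um/min (30 um/h, the speed scale typical
#'   of leader-bleb-based migration) with a persistent leader bleb of about
#'   a quarter of the cell area.
#' * `LNM` — the same leader bleb, stationary cell.
#' * `NL` — stationary, six small circumferential blebs living at most
#'   2 frames each (about 4% of cell area).
#' * `apoptotic_like` — many (eight) 1-2-frame blebs, the highly dynamic
#'   blebbing of apoptotic cells.
#' * `low_confinement_like` — two long-lived blebs spanning the whole movie,
#'   the stable blebbing of weakly confined cells.
#'
#' Bleb attachment angles and birth frames of the short-lived presets are
#' drawn deterministically from `seed`.
#'
#' @param name Preset name.
#' @param seed Integer seed (drives both geometry draws and rendering noise).
#' @param n_frames Movie length in frames (default 10).
#' @param noise_sd Noise level (default 5, i.e. 5% of the 100-unit contrast).
#' @return A [scene_params()].
#' @export
preset_scene <- function(name = c("LM", "LNM", "NL", "apoptotic_like",
                                  "low_confinement_like"),
                         seed = 1L, n_frames = 10L, noise_sd = 5) {
  name <- match.arg(name)
  leader <- tibble(angle_deg = 0, radius_um = 6.5,
                   birth_frame = 0L, lifetime_frames = n_frames)
  small_blebs <- function(n, radius_um, max_life, base_angle_seed) {
    with_seed(seed + base_angle_seed, {
      # angles on a grid (leader sector excluded) with jitter: no overlaps
      slots <- seq(40, 320, length.out = n)
      tibble(
        angle_deg = slots + stats::runif(n, -10, 10),
        radius_um = radius_um,
        birth_frame = sample.int(n_frames - max_life + 1L, n, replace = TRUE) - 1L,
        lifetime_frames = sample.int(max_life, n, replace = TRUE)
      )
    })
  }
  cfg <- switch(name,
    LM = list(motion = list(type = "linear", velocity_um_min = c(0.5, 0)),
              blebs = leader),
    LNM = list(motion = list(type = "none"), blebs = leader),
    NL = list(motion = list(type = "none"),
              blebs = small_blebs(6L, 2.0, 2L, 7L)),
    apoptotic_like = list(motion = list(type = "none"),
                          blebs = small_blebs(8L, 2.5, 2L, 13L)),
    low_confinement_like = list(
      motion = list(type = "none"),
      blebs = tibble(angle_deg = c(90, 270), radius_um = c(5, 4),
                     birth_frame = 0L, lifetime_frames = n_frames))
  )
  scene_params(
    n_frames = n_frames,
    motion = cfg$motion,
    blebs = cfg$blebs,
    noise_sd = noise_sd,
    seed = seed,
    name = name
  )
}
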