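#' Whole-cell centroid trajectory
#'
#' One centroid per frame of the whole-cell mask, in microns, with elapsed
#' time in minutes. Frames with an empty mask are dropped (with a warning),
#' so downstream speeds use only analyzed frames.
#'
#' @param whole Whole-cell [mask_stack()].
#' @param cell_id Identifier copied into the output.
#' @return A tibble of class `bleb_trajectory` with columns `cell_id`,
#'   `frame` (0-based), `t_min`, `x_um`, `y_um`; the frame interval is kept
#'   in the `"frame_interval_min"` attribute.
#' @export
cell_trajectory <- function(whole, cell_id = "cell") {
  stopifnot(inherits(whole, "mask_stack"))
  px <- whole$pixel_size_um
  dt <- whole$frame_interval_min
  rows <- map(seq_along(whole$frames), function(t) {
    m <- whole$frames[[t]]
    if (!any(m)) return(NULL)
    tibble(
      cell_id = cell_id,
      frame = t - 1L,
      t_min = (t - 1L) * dt,
      x_um = (mean(col(m)[m]) - 0.5) * px,
      y_um = (mean(row(m)[m]) - 0.5) * px
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warn(sprintf("cell_trajectory: %d empty frame(s) dropped", dropped))
  }
  out <- bind_rows(rows)
  attr(out, "frame_interval_min") <- dt
  class(out) <- c("bleb_trajectory", class(out))
  out
}

#' Build a trajectory from raw centroid coordinates
#'
#' @param x_um,y_um Centroid coordinates in microns, one per frame.
#' @param frame_interval_min Minutes per frame.
#' @param cell_id Identifier.
#' @return A `bleb_trajectory` tibble (see [cell_trajectory()]).
#' @export
trajectory <- function(x_um, y_um, frame_interval_min = 8, cell_id = "cell") {
  stopifnot(length(x_um) == length(y_um), length(x_um) >= 1)
  out <- tibble(
    cell_id = cell_id,
    frame = seq_along(x_um) - 1L,
    t_min = (seq_along(x_um) - 1L) * frame_interval_min,
    x_um = as.numeric(x_um),
    y_um = as.numeric(y_um)
  )
  attr(out, "frame_interval_min") <- frame_interval_min
  class(out) <- c("bleb_trajectory", class(out))
  out
}

#' Instantaneous speeds along a trajectory
#'
#' `speed_i = |p_{i+1} - p_i| / frame_interval`, in microns per minute; the
#' maximum is the cell's top instantaneous speed (`"top_speed_um_min"`
#' attribute). Speeds are invariant under translation and rotation of the
#' trajectory.
#'
#' @param traj A `bleb_trajectory` (see [cell_trajectory()]).
#' @return A tibble with one row per interval: `frame` (interval start,
#'   0-based), `t_min`, `step_um`, `speed_um_min`.
#' @export
instantaneous_speeds <- function(traj) {
  dt <- attr(traj, "frame_interval_min") %||% 8
  if (nrow(traj) < 2L) {
    warn("instantaneous_speeds: fewer than 2 points")
    out <- tibble(frame = integer(0), t_min = numeric(0),
                  step_um = numeric(0), speed_um_min = numeric(0))
    attr(out, "top_speed_um_min") <- NA_real_
    return(out)
  }
  step <- sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2)
  out <- tibble(
    frame = head(traj$frame, -1L),
    t_min = head(traj$t_min, -1L),
    step_um = step,
    speed_um_min = step / dt
  )
  attr(out, "top_speed_um_min") <- max(out$speed_um_min)
  out
}

#' Translate a trajectory so it starts at the origin
#'
#' The plot-of-origin convention: every cell's first point moves to (0, 0);
#' all pairwise displacements (and therefore speeds) are preserved.
#'
#' @param traj A `bleb_trajectory`.
#' @return The translated trajectory.
#' @export
zero_origin <- function(traj) {
  traj$x_um <- traj$x_um - traj$x_um[1]
  traj$y_um <- traj$y_um - traj$y_um[1]
  traj
}

#' Track blebs across frames by mask overlap
#'
#' Greedy frame-to-frame linking: candidate pairs between the labeled blebs
#' of consecutive frames are taken in order of decreasing pixel overlap, and
#' a pair is linked when `overlap / min(area_i, area_j) >= link_min_overlap`.
#' Unmatched components start new tracks; a track ends as soon as its bleb is
#' unmatched — there is no gap closing, because at multi-minute sampling a
#' bleb genuinely retracts and a later bleb at the same spot is a new object.
#' Overlap linking is used instead of curvature-based tracking, which needs
#' far higher temporal resolution than migration-scale movies provide.
#'
#' @param all_blebs An all-blebs [mask_stack()] (or a list of labeled frames
#'   from [label_blebs()] plus explicit calibration).
#' @param link_min_overlap Minimum overlap fraction of the smaller bleb
#'   (default 0.5).
#' @param min_bleb_area_um2 Passed to [label_blebs()].
#' @return A tibble of class `bleb_tracks` with columns `track_id`, `frame`
#'   (0-based), `component_id`, `area_um2`; the frame interval is kept as an
#'   attribute for [bleb_lifetimes()].
#' @export
track_blebs <- function(all_blebs, link_min_overlap = 0.5,
                        min_bleb_area_um2 = 0) {
  stopifnot(inherits(all_blebs, "mask_stack"))
  labs <- label_blebs(all_blebs, min_bleb_area_um2 = min_bleb_area_um2)
  dt <- all_blebs$frame_interval_min
  px2 <- all_blebs$pixel_size_um^2

  rows <- list()
  next_track <- 1L
  active <- integer(0) # track id per component of the previous frame
  for (t in seq_along(labs)) {
    lab <- labs[[t]]
    k <- length(lab$areas_px)
    assigned <- rep(NA_integer_, k)
    if (t > 1L && k > 0L && length(active) > 0L) {
      prev <- labs[[t - 1L]]
      both <- prev$labels > 0 & lab$labels > 0
      if (any(both)) {
        ov <- table(prev$labels[both], lab$labels[both])
        cand <- as.data.frame(ov, stringsAsFactors = FALSE)
        cand <- cand[cand$Freq > 0, , drop = FALSE]
        i <- as.integer(cand$Var1); j <- as.integer(cand$Var2)
        frac <- cand$Freq / pmin(prev$areas_px[i], lab$areas_px[j])
        ord <- order(-cand$Freq, i, j)
        used_prev <- rep(FALSE, length(prev$areas_px))
        for (q in ord) {
          if (frac[q] < link_min_overlap) next
          if (used_prev[i[q]] || !is.na(assigned[j[q]])) next
          used_prev[i[q]] <- TRUE
          assigned[j[q]] <- active[i[q]]
        }
      }
    }
    if (k > 0L) {
      new <- which(is.na(assigned))
      if (length(new) > 0L) {
        assigned[new] <- seq.int(next_track, next_track + length(new) - 1L)
        next_track <- next_track + length(new)
      }
      rows[[t]] <- tibble(
        track_id = assigned,
        frame = t - 1L,
        component_id = seq_len(k),
        area_um2 = lab$areas_px * px2
      )
    }
    active <- assigned
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(track_id = integer(0), frame = integer(0),
                  component_id = integer(0), area_um2 = numeric(0))
  }
  out <- arrange(out, .data$track_id, .data$frame)
  attr(out, "frame_interval_min") <- dt
  class(out) <- c("bleb_tracks", class(out))
  out
}

#' Lifetime and mean area of each bleb track
#'
#' A track alive for `k` consecutive frames has a lifetime of `k` frames,
#' i.e. `k * frame_interval` minutes (at the 8 min reference interval, the
#' 5-frame persistence window is 40 min).
#'
#' @param tracks A `bleb_tracks` tibble from [track_blebs()].
#' @param frame_interval_min Override for the frame interval (defaults to
#'   the attribute carried by `tracks`).
#' @return A tibble with `track_id`, `start_frame`, `end_frame`,
#'   `lifetime_frames`, `lifetime_min`, `mean_area_um2`.
#' @export
bleb_lifetimes <- function(tracks, frame_interval_min = NULL) {
  dt <- frame_interval_min %||% attr(tracks, "frame_interval_min") %||% 8
  if (nrow(tracks) == 0L) {
    return(tibble(track_id = integer(0), start_frame = integer(0),
                  end_frame = integer(0), lifetime_frames = integer(0),
                  lifetime_min = numeric(0), mean_area_um2 = numeric(0)))
  }
  tracks |>
    group_by(.data$track_id) |>
    summarise(
      start_frame = min(.data$frame),
      end_frame = max(.data$frame),
      lifetime_frames = n(),
      lifetime_min = n() * dt,
      mean_area_um2 = mean(.data$area_um2),
      .groups = "drop"
    )
}

#' Classify a cell as leader-mobile, leader-non-mobile or no-leader
#'
#' The two predicates mirror the field's working definitions. A cell *has a
#' leader bleb* when some bleb track persists for at least
#' `persistence_frames` frames (40 min at the 8-min reference interval) with
#' a mean area of at least `leader_area_frac` of the mean whole-cell area
#' over those frames. A cell *is mobile* when some window of
#' `persistence_frames` consecutive intervals has mean instantaneous speed
#' of at least `speed_min` and a directionality ratio (net displacement over
#' path length) of at least `dir_min` — directionally persistent migration,
#' with the speed floor set to half the ~30 um/h (0.5 um/min) speed typical
#' of leader-bleb-based migration. Labels: LM = leader bleb and mobile,
#' LNM = leader bleb and not mobile, NL = no leader bleb; fewer than
#' `persistence_frames` analyzed frames yields `"undetermined"`.
#'
#' @param traj A `bleb_trajectory`.
#' @param tracks A `bleb_tracks` tibble.
#' @param whole_areas Tibble with `frame` and `area_um2` for the whole cell
#'   (e.g. the `whole_cell` rows of a [compartment_table()]).
#' @param persistence_frames Persistence window in frames (default 5).
#' @param leader_area_frac Leader bleb area threshold as a fraction of mean
#'   whole-cell area (default 0.10).
#' @param speed_min Speed floor in um/min (default 0.25).
#' @param dir_min Directionality-ratio floor (default 0.5).
#' @param cell_id Identifier.
#' @return A one-row tibble with `cell_id`, `label`, `has_leader_bleb`,
#'   `is_mobile`, the parameters used, and the supporting quantities
#'   (`best_window_speed_um_min`, `best_leader_area_frac`,
#'   `top_speed_um_min`).
#' @export
classify_phenotype <- function(traj, tracks, whole_areas,
                               persistence_frames = 5,
                               leader_area_frac = 0.10,
                               speed_min = 0.25,
                               dir_min = 0.5,
                               cell_id = "cell") {
  dt <- attr(traj, "frame_interval_min") %||% 8
  n <- nrow(traj)

  if (n < persistence_frames) {
    return(phenotype_row(cell_id, "undetermined", NA, NA, persistence_frames,
                         leader_area_frac, speed_min, dir_min,
                         NA_real_, NA_real_, NA_real_))
  }

  # mobility: best persistence window of consecutive intervals
  steps <- sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2)
  w <- persistence_frames
  best_speed <- 0; is_mobile <- FALSE
  if (length(steps) >= w) {
    for (i in seq_len(length(steps) - w + 1L)) {
      seg <- i:(i + w - 1L)
      path <- sum(steps[seg])
      mean_speed <- path / (w * dt)
      net <- sqrt((traj$x_um[i + w] - traj$x_um[i])^2 +
                    (traj$y_um[i + w] - traj$y_um[i])^2)
      dir_ratio <- if (path > 0) net / path else 0
      if (mean_speed >= speed_min && dir_ratio >= dir_min) is_mobile <- TRUE
      if (mean_speed > best_speed) best_speed <- mean_speed
    }
  }

  # leader bleb: a long-lived track large relative to the cell
  lt <- bleb_lifetimes(tracks, frame_interval_min = dt)
  has_leader <- FALSE; best_frac <- 0
  if (nrow(lt) > 0L) {
    for (r in seq_len(nrow(lt))) {
      if (lt$lifetime_frames[r] < persistence_frames) next
      fr <- lt$start_frame[r]:lt$end_frame[r]
      cell_area <- mean(whole_areas$area_um2[whole_areas$frame %in% fr])
      if (!is.finite(cell_area) || cell_area <= 0) next
      frac <- lt$mean_area_um2[r] / cell_area
      best_frac <- max(best_frac, frac)
      if (frac >= leader_area_frac) has_leader <- TRUE
    }
  }

  label <- if (has_leader && is_mobile) "LM"
           else if (has_leader) "LNM"
           else "NL"
  top <- if (length(steps)) max(steps) / dt else NA_real_
  phenotype_row(cell_id, label, has_leader, is_mobile, persistence_frames,
                leader_area_frac, speed_min, dir_min, best_speed, best_frac,
                top)
}

phenotype_row <- function(cell_id, label, has_leader, is_mobile,
                          persistence_frames, leader_area_frac, speed_min,
                          dir_min, best_speed, best_frac, top_speed) {
  tibble(
    cell_id = cell_id,
    label = label,
    has_leader_bleb = has_leader,
    is_mobile = is_mobile,
    persistence_frames = persistence_frames,
    leader_area_frac = leader_area_frac,
    speed_min_um_min = speed_min,
    dir_min = dir_min,
    best_window_speed_um_min = best_speed,
    best_leader_area_frac = best_frac,
    top_speed_um_min = top_speed
  )
}
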