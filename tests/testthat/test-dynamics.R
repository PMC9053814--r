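test_that("instantaneous speeds follow the displacement arithmetic", {
  # straight line, 2 um steps at 8 min/frame -> 0.25 um/min = 15 um/h
  tr <- trajectory(x_um = seq(0, 10, by = 2), y_um = rep(0, 6),
                   frame_interval_min = 8)
  sp <- instantaneous_speeds(tr)
  expect_equal(sp$speed_um_min, rep(0.25, 5))
  expect_equal(sp$speed_um_min * 60, rep(15, 5))
  expect_equal(attr(sp, "top_speed_um_min"), 0.25)

  still <- trajectory(rep(3, 4), rep(7, 4))
  expect_equal(instantaneous_speeds(still)$speed_um_min, rep(0, 3))

  # 3-4-5 step over 8 min
  tr2 <- trajectory(c(0, 3), c(0, 4), frame_interval_min = 8)
  expect_equal(instantaneous_speeds(tr2)$speed_um_min, 5 / 8)

  expect_warning(one <- instantaneous_speeds(trajectory(1, 1)), "fewer than 2")
  expect_equal(nrow(one), 0L)
})

test_that("speeds are invariant under translation and rotation", {
  set.seed(8)
  x <- cumsum(rnorm(10)); y <- cumsum(rnorm(10))
  base <- instantaneous_speeds(trajectory(x, y))$speed_um_min
  shifted <- instantaneous_speeds(trajectory(x + 100, y - 42))$speed_um_min
  th <- 0.7
  rot <- instantaneous_speeds(trajectory(x * cos(th) - y * sin(th),
                                         x * sin(th) + y * cos(th)))$speed_um_min
  expect_equal(shifted, base)
  expect_equal(rot, base)
})

test_that("zero_origin translates to the origin and preserves displacements", {
  tr <- trajectory(c(5, 7, 10), c(3, 3, -1))
  z <- zero_origin(tr)
  expect_equal(c(z$x_um[1], z$y_um[1]), c(0, 0))
  expect_equal(diff(z$x_um), diff(tr$x_um))
  expect_equal(instantaneous_speeds(z)$speed_um_min,
               instantaneous_speeds(tr)$speed_um_min)
  single <- zero_origin(trajectory(4, 9))
  expect_equal(c(single$x_um, single$y_um), c(0, 0))
})

test_that("a static bleb over 5 frames is one track of 40 minutes", {
  disk <- mk_disk(30, 30, 15, 15, 5)
  ab <- mask_stack(rep(list(disk), 5), "all_blebs", pixel_size_um = 1,
                   frame_interval_min = 8)
  tracks <- track_blebs(ab)
  lt <- bleb_lifetimes(tracks)
  expect_equal(nrow(lt), 1L)
  expect_equal(lt$lifetime_frames, 5L)
  expect_equal(lt$lifetime_min, 40)
})

test_that("a one-frame gap ends the track: no gap closing", {
  disk <- mk_disk(30, 30, 15, 15, 5)
  none <- matrix(FALSE, 30, 30)
  ab <- mask_stack(list(disk, disk, none, disk), "all_blebs")
  lt <- bleb_lifetimes(track_blebs(ab))
  expect_equal(nrow(lt), 2L)
  expect_equal(sort(lt$lifetime_frames), c(1L, 2L))
})

test_that("well-separated blebs keep their identities and match the assignment oracle", {
  f <- function(c1, c2) mk_disk(40, 60, 15, c1, 5) | mk_disk(40, 60, 30, c2, 4)
  frames <- list(f(15, 45), f(16, 44), f(17, 43), f(18, 42))
  ab <- mask_stack(frames, "all_blebs")
  tracks <- track_blebs(ab)
  lt <- bleb_lifetimes(tracks)
  expect_equal(nrow(lt), 2L)
  expect_equal(lt$lifetime_frames, c(4L, 4L))
  # per-frame areas per track stay constant: no identity swaps
  for (id in lt$track_id) {
    ar <- tracks$area_um2[tracks$track_id == id]
    expect_equal(length(unique(round(ar, 6))) <= 2, TRUE)
  }
  # frame-to-frame links equal the exhaustive-assignment oracle
  labs <- label_blebs(ab)
  for (t in 1:3) {
    a <- labs[[t]]; b <- labs[[t + 1]]
    oracle <- oracle_best_assignment(a$labels, a$areas_px,
                                     b$labels, b$areas_px, 0.5)
    prev_tracks <- tracks[tracks$frame == t - 1, ]
    cur_tracks <- tracks[tracks$frame == t, ]
    for (j in seq_along(b$areas_px)) {
      i <- oracle[j]
      tid_cur <- cur_tracks$track_id[cur_tracks$component_id == j]
      if (is.na(i)) {
        expect_false(tid_cur %in% prev_tracks$track_id)
      } else {
        expect_equal(tid_cur,
                     prev_tracks$track_id[prev_tracks$component_id == i])
      }
    }
  }
})

test_that("tracking partitions each frame's bleb area and survives time reversal", {
  sc <- render_scene(preset_scene("NL", seed = 4, n_frames = 8))
  ab <- sc$truth$blebs
  tracks <- track_blebs(ab)
  per_frame <- dplyr::summarise(dplyr::group_by(tracks, frame),
                                total = sum(area_um2), .groups = "drop")
  for (t in seq_len(8) - 1L) {
    mask_area <- sum(ab$frames[[t + 1]]) * ab$pixel_size_um^2
    tracked <- per_frame$total[per_frame$frame == t]
    expect_equal(if (length(tracked)) tracked else 0, mask_area)
  }
  rev_ab <- mask_stack(rev(ab$frames), "all_blebs",
                       pixel_size_um = ab$pixel_size_um,
                       frame_interval_min = ab$frame_interval_min)
  lt <- bleb_lifetimes(track_blebs(ab))
  lt_rev <- bleb_lifetimes(track_blebs(rev_ab))
  expect_equal(sort(lt$lifetime_frames), sort(lt_rev$lifetime_frames))
})

test_that("phenotype labels follow the leader-bleb and mobility predicates", {
  whole_areas <- tibble::tibble(frame = 0:9, area_um2 = 100)
  big_track <- structure(
    tibble::tibble(track_id = 1L, frame = 0:9, component_id = 1L,
                   area_um2 = 30),
    frame_interval_min = 8, class = c("bleb_tracks", "tbl_df", "tbl", "data.frame"))
  small_tracks <- structure(
    tibble::tibble(track_id = c(1L, 1L, 2L, 2L), frame = c(0L, 1L, 4L, 5L),
                   component_id = 1L, area_um2 = 5),
    frame_interval_min = 8, class = c("bleb_tracks", "tbl_df", "tbl", "data.frame"))

  still <- trajectory(rep(0, 10), rep(0, 10), frame_interval_min = 8)
  mover <- trajectory(seq(0, 36, by = 4), rep(0, 10), frame_interval_min = 8)
  set.seed(2)
  jitter <- trajectory(rnorm(10, sd = 0.2), rnorm(10, sd = 0.2),
                       frame_interval_min = 8)

  expect_equal(classify_phenotype(still, big_track, whole_areas)$label, "LNM")
  expect_equal(classify_phenotype(mover, big_track, whole_areas)$label, "LM")
  expect_equal(classify_phenotype(jitter, small_tracks, whole_areas)$label, "NL")
  # mover at 0.5 um/min: straight line -> directionality ratio 1
  lm <- classify_phenotype(mover, big_track, whole_areas)
  expect_true(lm$is_mobile && lm$has_leader_bleb)
  expect_equal(lm$best_window_speed_um_min, 0.5)

  short <- trajectory(0:2, rep(0, 3), frame_interval_min = 8)
  expect_equal(classify_phenotype(short, big_track, whole_areas)$label,
               "undetermined")
})
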