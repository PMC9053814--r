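test_that("descriptors hit their closed forms on ideal shapes", {
  disk <- mk_disk(110, 110, 55, 55, 50)
  d <- measure_region(disk)
  expect_lt(abs(d$circularity - 1), 0.02)
  expect_lt(abs(d$roundness - 1), 0.02)
  expect_lt(abs(d$aspect_ratio - 1), 0.02)
  expect_lt(abs(d$solidity - 1), 0.02)
  expect_lt(abs(d$perimeter_um - 2 * pi * 50) / (2 * pi * 50), 0.01)

  # 2:1 ellipse, major 100 minor 50 (diameters)
  ell <- mk_mask(120, 220, function(r, c) {
    ((c - 110) / 50)^2 + ((r - 60) / 25)^2 <= 1
  })
  e <- measure_region(ell)
  expect_lt(abs(e$aspect_ratio - 2), 0.05)
  expect_lt(abs(e$roundness - 0.5), 0.05)

  # plus-sign polyomino: 5 unit squares, hull area 7
  plus <- matrix(FALSE, 5, 5)
  plus[2:4, 3] <- TRUE; plus[3, 2:4] <- TRUE
  p <- measure_region(plus)
  expect_lt(abs(p$solidity - 5 / 7) / (5 / 7), 0.01)
  expect_equal(oracle_hull_area(plus), 7)

  sq <- mk_mask(30, 30, function(r, c) r >= 6 & r <= 25 & c >= 6 & c <= 25)
  s <- measure_region(sq)
  expect_equal(s$solidity, 1)
  expect_equal(s$area_um2, 400)
})

test_that("calibration scales area by pixel size squared", {
  m <- matrix(FALSE, 6, 6); m[3:4, 3:4] <- TRUE
  expect_equal(measure_region(m, pixel_size_um = 0.5)$area_um2, 1.0)
  expect_equal(measure_region(m, pixel_size_um = 1)$area_um2, 4)
  d1 <- measure_region(mk_disk(60, 60, 30, 30, 20), pixel_size_um = 1)
  d2 <- measure_region(mk_disk(60, 60, 30, 30, 20), pixel_size_um = 0.25)
  expect_equal(d2$area_um2, d1$area_um2 * 0.25^2)
  expect_equal(d2$perimeter_um, d1$perimeter_um * 0.25)
  expect_equal(d2$circularity, d1$circularity)
})

test_that("dimensionless descriptors are invariant under 2x upsampling", {
  # the same continuous shape digitized at 1x and 2x resolution
  digitize <- function(s) {
    list(
      disk = mk_disk(110 * s, 110 * s, 55 * s, 55 * s, 50 * s),
      ell = mk_mask(200 * s, 400 * s, function(r, c) {
        ((c - 200 * s) / (90 * s))^2 + ((r - 100 * s) / (45 * s))^2 <= 1
      }),
      rect = mk_mask(80 * s, 80 * s, function(r, c) {
        r > 10 * s & r <= 70 * s & c > 15 * s & c <= 55 * s
      })
    )
  }
  lo <- digitize(1); hi <- digitize(2)
  for (nm in names(lo)) {
    a <- measure_region(lo[[nm]]); b <- measure_region(hi[[nm]])
    expect_lt(abs(b$area_um2 - 4 * a$area_um2) / (4 * a$area_um2), 0.01)
    descs <- c("circularity", "roundness", "aspect_ratio", "solidity")
    # chain-code perimeters converge slowly at sharp corners, so the
    # rectangle's circularity is only compared loosely
    for (d in descs) {
      tol <- if (d == "circularity" && nm == "rect") 0.05 else 0.01
      expect_lt(abs(b[[d]] - a[[d]]) / a[[d]], tol)
    }
  }
})

test_that("solidity matches the hull oracle and roundness the ellipse identity", {
  set.seed(33)
  for (i in 1:12) {
    blob <- mk_disk(50, 50, 25, 25, sample(8:14, 1)) |
      mk_disk(50, 50, sample(15:35, 1), sample(15:35, 1), sample(4:9, 1))
    m <- measure_region(blob)
    expect_lt(abs(m$solidity - sum(blob) / oracle_hull_area(blob)) /
                m$solidity, 0.01)
    expect_gte(m$aspect_ratio, 1)
    expect_lte(m$solidity, 1 + 1e-9)
  }
  # roundness = 1 / aspect ratio for moment-fitted digital ellipses
  for (ar_true in c(1.5, 2, 3)) {
    ell <- mk_mask(90, 160, function(r, c) {
      ((c - 80) / (20 * ar_true))^2 + ((r - 45) / 20)^2 <= 1
    })
    m <- measure_region(ell)
    expect_lt(abs(m$roundness * m$aspect_ratio - 1), 0.05)
    expect_lt(abs(m$aspect_ratio - ar_true) / ar_true, 0.05)
  }
})

test_that("percent-of-cell-area measures follow the area arithmetic", {
  p <- percent_areas(140, 40, 25)
  expect_equal(p$pct_total_blebs, 100 * 40 / 140)
  expect_equal(p$pct_leader_bleb, 100 * 25 / 140)
  expect_lte(p$pct_leader_bleb, p$pct_total_blebs)
  none <- percent_areas(140, 0, 0)
  expect_equal(none$pct_total_blebs, 0)
  expect_equal(none$pct_leader_bleb, 0)
  one <- percent_areas(140, 25, 25)
  expect_equal(one$pct_leader_bleb, one$pct_total_blebs)
  expect_error(percent_areas(0, 1, 1), "positive")
})

test_that("the per-frame table partitions areas and flags bleb-free frames", {
  whole_f <- mk_mask(16, 16, function(r, c) r >= 3 & r <= 12 & c >= 3 & c <= 12)
  body_roi <- roi_set(list("0" = cbind(c(2, 2, 11, 11), c(2, 7, 7, 2))))
  whole <- mask_stack(list(whole_f, whole_f), "whole_cell")
  blebs <- remove_body(whole, body_roi)
  blebs$frames[[2]][] <- FALSE # frame 1 bleb-free
  body <- derive_cell_body(whole, blebs)
  lg <- largest_bleb(blebs)
  tb <- compartment_table(whole, body, blebs, lg)
  w0 <- tb[tb$frame == 0 & tb$compartment == "whole_cell", ]
  b0 <- tb[tb$frame == 0 & tb$compartment == "cell_body", ]
  a0 <- tb[tb$frame == 0 & tb$compartment == "all_blebs", ]
  expect_equal(b0$area_um2 + a0$area_um2, w0$area_um2)
  expect_equal(a0$bleb_count, 1)
  expect_equal(a0$pct_total_blebs, 100 * 40 / 100)
  a1 <- tb[tb$frame == 1 & tb$compartment == "all_blebs", ]
  expect_equal(a1$bleb_count, 0)
  expect_equal(a1$pct_total_blebs, 0)
  expect_equal(nrow(tb[tb$frame == 1 & tb$compartment == "largest_bleb", ]), 0L)
})

test_that("per-cell averages use the documented denominators", {
  # four frames, blebs on two of them with mean per-frame areas 10 and 30
  frame_tbl <- dplyr::bind_rows(
    tibble::tibble(frame = 0:3, compartment = "whole_cell", area_um2 = 100,
                   roundness = 0.9, circularity = 0.8, solidity = 1,
                   aspect_ratio = 1.1, pct_total_blebs = c(10, 30, 0, 0),
                   pct_leader_bleb = c(10, 30, 0, 0)),
    tibble::tibble(frame = 0:3, compartment = "all_blebs",
                   area_um2 = c(10, 30, 0, 0), bleb_count = c(1, 1, 0, 0),
                   mean_bleb_area_um2 = c(10, 30, NA, NA),
                   pct_total_blebs = c(10, 30, 0, 0),
                   pct_leader_bleb = c(10, 30, 0, 0)),
    tibble::tibble(frame = 0:1, compartment = "largest_bleb",
                   area_um2 = c(10, 30), roundness = c(0.6, 0.8),
                   circularity = c(0.5, 0.7), solidity = c(0.9, 1),
                   aspect_ratio = c(2, 1),
                   pct_total_blebs = c(10, 30), pct_leader_bleb = c(10, 30))
  )
  s <- summarize_cell(frame_tbl, cell_id = "c1")
  expect_equal(s$avg_bleb_count, 0.5)        # zero frames included
  expect_equal(s$avg_bleb_area_um2, 20)      # bleb frames only
  expect_equal(s$avg_largest_bleb_area_um2, 20)
  expect_equal(s$avg_largest_bleb_roundness, 0.7)
  expect_equal(s$n_frames, 4L)
  expect_equal(s$n_frames_with_blebs, 2L)
  # toggled rule: bleb-free frames count as zero area
  s0 <- summarize_cell(frame_tbl, include_blebfree_frames = TRUE)
  expect_equal(s0$avg_bleb_area_um2, 10)
  # constant descriptor -> mean equals it; means lie within frame range
  expect_equal(s$avg_whole_cell_area_um2, 100)
  expect_true(s$avg_largest_bleb_solidity >= 0.9 &&
                s$avg_largest_bleb_solidity <= 1)
  expect_warning(s_empty <- summarize_cell(frame_tbl[0, ]), "no usable frames")
  expect_equal(s_empty$n_frames, 0L)
})

test_that("summary means can be reproduced from the exported per-frame CSV", {
  sc <- render_scene(preset_scene("LNM", seed = 5, n_frames = 6))
  res <- suppressWarnings(suppressMessages(
    analyze_cell(sc$stack, body = sc$truth$body_rois, cell_id = "c")))
  tf <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(res$frames), tf, row.names = FALSE)
  back <- tibble::as_tibble(utils::read.csv(tf))
  s2 <- summarize_cell(back, cell_id = "c")
  expect_equal(as.data.frame(s2), as.data.frame(res$summary), tolerance = 1e-12)
})
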