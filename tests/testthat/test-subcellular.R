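test_that("foreground labeling is 8-connected and matches a flood-fill oracle", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE # diagonal touch = one component
  lab <- label_components(m)
  expect_equal(length(lab$areas_px), 1L)
  expect_equal(lab$areas_px, 2)

  m2 <- matrix(FALSE, 20, 30)
  m2[2:6, 2:7] <- TRUE    # 30 px
  m2[10:14, 10:19] <- TRUE # 50 px
  m2[16:19, 25:29] <- TRUE # 20 px
  lab2 <- label_components(m2)
  expect_equal(sort(lab2$areas_px), c(20, 30, 50))
  # scan-order ids: first pixel encountered row-major gets id 1
  expect_equal(lab2$labels[2, 2], 1L)
  expect_equal(lab2$labels[10, 10], 2L)
  expect_equal(lab2$labels[16, 25], 3L)

  set.seed(21)
  for (i in 1:20) {
    m3 <- matrix(runif(32 * 32) > 0.62, 32, 32)
    ours <- label_components(m3)
    oracle <- oracle_flood_fill(m3)
    expect_equal(length(ours$areas_px), max(oracle))
    # identical partitions (label names may differ)
    if (max(oracle) > 0) {
      expect_equal(length(unique(paste(ours$labels, oracle))),
                   max(oracle) + 1L)
    }
  }
})

test_that("label counts and areas are invariant under translation", {
  set.seed(3)
  m <- matrix(runif(400) > 0.6, 20, 20)
  big <- matrix(FALSE, 40, 40)
  big[3:22, 5:24] <- m
  shifted <- matrix(FALSE, 40, 40)
  shifted[11:30, 14:33] <- m
  a <- label_components(big); b <- label_components(shifted)
  expect_equal(sort(a$areas_px), sort(b$areas_px))
})

test_that("remove_body subtracts the body and derive_cell_body partitions exactly", {
  whole_f <- mk_mask(14, 14, function(r, c) r >= 3 & r <= 12 & c >= 3 & c <= 12)
  whole <- mask_stack(list(whole_f), "whole_cell")
  # body ROI covering the left 10 x 6 of the square (0-based corners)
  body_roi <- roi_set(list("0" = cbind(row = c(2, 2, 11, 11),
                                       col = c(2, 7, 7, 2))))
  blebs <- remove_body(whole, body_roi)
  expect_equal(sum(blebs$frames[[1]]), 40) # right 10 x 4 region
  body_mask <- derive_cell_body(whole, blebs)
  expect_equal(sum(body_mask$frames[[1]]), 60)
  # exact pixel partition
  expect_equal(body_mask$frames[[1]] | blebs$frames[[1]], whole_f)
  expect_false(any(body_mask$frames[[1]] & blebs$frames[[1]]))

  # whole == body -> bleb-free warning
  full_roi <- roi_set(list("0" = cbind(row = c(2, 2, 12, 12),
                                       col = c(2, 12, 12, 2))))
  expect_warning(nb <- remove_body(whole, full_roi), "bleb-free")
  expect_equal(sum(nb$frames[[1]]), 0)

  # body polygon partly outside the whole mask: intersection semantics
  over_roi <- roi_set(list("0" = cbind(row = c(0, 0, 13, 13),
                                       col = c(0, 7, 7, 0))))
  blebs2 <- suppressWarnings(remove_body(whole, over_roi))
  expect_equal(sum(blebs2$frames[[1]]), 40)

  # blebs empty -> cell body is the whole cell
  empty <- mask_stack(list(matrix(FALSE, 14, 14)), "all_blebs")
  cb <- derive_cell_body(whole, empty)
  expect_equal(cb$frames[[1]], whole_f)

  # containment violation detected
  bad <- mask_stack(list(mk_mask(14, 14, function(r, c) r == 1)), "all_blebs")
  expect_error(derive_cell_body(whole, bad), "frame 0")
})

test_that("area conservation holds on random synthetic frames", {
  set.seed(17)
  for (i in 1:25) {
    whole_f <- mk_disk(48, 48, 24, 24, sample(8:16, 1)) |
      mk_disk(48, 48, sample(10:38, 1), sample(10:38, 1), sample(3:6, 1))
    body_f <- mk_disk(48, 48, 24, 24, sample(6:12, 1))
    whole <- mask_stack(list(whole_f), "whole_cell")
    body <- mask_stack(list(body_f), "cell_body")
    blebs <- suppressWarnings(remove_body(whole, body))
    cb <- derive_cell_body(whole, blebs)
    expect_equal(sum(cb$frames[[1]]) + sum(blebs$frames[[1]]), sum(whole_f))
  }
})

test_that("largest_bleb keeps the max-area component with scan-order tie-break", {
  f <- matrix(FALSE, 30, 40)
  f[2:6, 2:7] <- TRUE     # 30 px, id 1
  f[10:14, 10:19] <- TRUE # 50 px, id 2
  f[20:23, 30:34] <- TRUE # 20 px, id 3
  ab <- mask_stack(list(f), "all_blebs")
  lg <- largest_bleb(ab)
  expect_equal(sum(lg$frames[[1]]), 50)
  expect_true(all(lg$frames[[1]][10:14, 10:19]))

  # tie: two 20-px components -> lowest label id kept, tie logged
  tie <- matrix(FALSE, 20, 20)
  tie[2:5, 2:6] <- TRUE   # id 1, 20 px
  tie[10:13, 10:14] <- TRUE # id 2, 20 px
  expect_message(
    lt <- largest_bleb(mask_stack(list(tie), "all_blebs")), "tie")
  expect_true(all(lt$frames[[1]][2:5, 2:6]))
  expect_false(any(lt$frames[[1]][10:13, 10:14]))

  # single bleb unchanged; empty frame stays empty and is recorded
  single <- mk_disk(20, 20, 10, 10, 4)
  ls <- largest_bleb(mask_stack(list(single, matrix(FALSE, 20, 20)),
                                "all_blebs"))
  expect_equal(ls$frames[[1]], single)
  expect_equal(sum(ls$frames[[2]]), 0)
  expect_equal(attr(ls, "bleb_free_frames"), 1L)
})

test_that("largest_bleb agrees with a sort-all-components oracle on random masks", {
  set.seed(29)
  for (i in 1:15) {
    f <- matrix(runif(40 * 40) > 0.8, 40, 40)
    lg <- largest_bleb(mask_stack(list(f), "all_blebs"))
    oracle <- oracle_flood_fill(f)
    if (max(oracle) == 0) {
      expect_equal(sum(lg$frames[[1]]), 0)
    } else {
      sizes <- tabulate(oracle[oracle > 0])
      expect_equal(sum(lg$frames[[1]]), max(sizes))
      expect_true(all(!lg$frames[[1]] | f)) # subset of the input
    }
  }
})

test_that("label_blebs applies the minimum-area filter before counting", {
  f <- matrix(FALSE, 20, 20)
  f[2:4, 2:4] <- TRUE   # 9 px
  f[10, 10] <- TRUE     # 1 px speckle
  lab <- label_blebs(f, min_bleb_area_um2 = 0, pixel_size_um = 1)
  expect_equal(length(lab$areas_px), 2L)
  lab2 <- label_blebs(f, min_bleb_area_um2 = 4, pixel_size_um = 1)
  expect_equal(length(lab2$areas_px), 1L)
  expect_equal(lab2$areas_um2, 9)
})
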