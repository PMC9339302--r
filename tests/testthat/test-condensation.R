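test_that("segmentation separates disjoint masses and flags near-contact", {
  img <- make_disk(200, 200, 60, 60, 40) + make_disk(200, 200, 140, 140, 40)
  seg <- segment_masses(img * 0.8, "fixed", 0.4, min_area_px = 50)
  expect_equal(nrow(seg$masses), 2)
  expect_true(all(seg$masses$status == "pending"))

  # centres 46 px apart: gap of 6 px closes under a 5 px dilation radius
  close_img <- make_disk(200, 200, 80, 60, 40) + make_disk(200, 200, 80, 106, 40)
  close_img <- pmin(close_img, 1) * 0.8
  seg2 <- segment_masses(close_img, "fixed", 0.4, min_area_px = 50,
                         overlap_dilate_px = 5)
  expect_equal(nrow(seg2$masses), 2)
  expect_true(all(seg2$masses$status == "omitted_overlap"))

  blank <- segment_masses(matrix(0, 50, 50), "fixed", 0.4)
  expect_equal(nrow(blank$masses), 0)
  otsu_blank <- segment_masses(matrix(0.2, 50, 50), "otsu")
  expect_equal(nrow(otsu_blank$masses), 0)
})

test_that("opening strips thin protrusions but keeps the mass core", {
  disk <- make_disk(120, 120, 60, 50, 40)
  tail <- matrix(0L, 120, 120)
  tail[59:61, 70:110] <- 1L            # 3-px-wide, 41-px-long tail
  mass <- pmin(disk + tail, 1L)
  core <- prune_protrusions(mass, max_width_px = 7)
  expect_false(is.null(core))
  expect_true(attr(core, "pruned"))
  expect_lte(abs(sum(core) - sum(disk)) / sum(disk), 0.05)
  # tail region is gone
  expect_equal(sum(core[59:61, 95:110]), 0)

  bare <- prune_protrusions(disk, max_width_px = 7)
  expect_false(attr(bare, "pruned"))
  # opening may shave a sub-percent raster rim but nothing more
  expect_lte(abs(sum(bare) - sum(disk)) / sum(disk), 0.01)

  line <- matrix(0L, 60, 60)
  line[30:31, 10:50] <- 1L             # 2-px-wide line only
  expect_null(prune_protrusions(line, max_width_px = 7))
})

test_that("mask classification uses fill OR edge-contact criteria", {
  mask <- mask_spec(diameter_px = 62)
  full <- make_disk(160, 160, 80, 80, 62)
  expect_equal(as.character(classify_mass(full, mask)), "matched")

  small <- make_disk(160, 160, 80, 80, 40)
  call <- classify_mass(small, mask)
  expect_equal(as.character(call), "failed")
  expect_lte(abs(attr(call, "fill") - (40 / 62)^2), 0.03)
  expect_equal(attr(call, "edge_coincidence"), 0)

  # hollow annulus spanning the mask boundary: fails fill, passes edges
  outer <- make_disk(160, 160, 80, 80, 66)
  inner <- make_disk(160, 160, 80, 80, 54)
  annulus <- outer - inner
  call2 <- classify_mass(annulus, mask)
  expect_equal(as.character(call2), "matched")
  expect_lt(attr(call2, "fill"), mask$fill_fraction)
  expect_gte(attr(call2, "edge_coincidence"), mask$edge_fraction)
})

test_that("classifier equals the analytic fill/edge rule across compaction", {
  mask <- mask_spec()
  for (theta in seq(0.5, 1.0, by = 0.05)) {
    f <- render_field(field_spec(width = 200, height = 200, n_nuclei = 1,
                                 compaction = theta, noise_sd = 0,
                                 loop_probability = 0, seed = 50))
    res <- score_fields(list(f), mask, threshold_method = "fixed",
                        threshold = 0.4)
    analytic <- (theta^2 >= mask$fill_fraction) ||
      (31 * (1 - theta) <= mask$edge_tolerance_px)
    expect_equal(res$per_mass$status == "matched", analytic,
                 info = sprintf("theta = %.2f", theta))
  }
})

test_that("field scoring pools replicate counts and excludes empty fields", {
  # field 1: 3 wildtype-sized + 3 hypercondensed masses; field 2: 2 + 2
  f1 <- matrix(0, 300, 300)
  for (c0 in c(60, 150, 240)) f1 <- f1 + make_disk(300, 300, 60, c0, 62)
  for (c0 in c(60, 150, 240)) f1 <- f1 + make_disk(300, 300, 200, c0, 30)
  f2 <- matrix(0, 300, 300)
  for (c0 in c(80, 220)) f2 <- f2 + make_disk(300, 300, 80, c0, 62)
  for (c0 in c(80, 220)) f2 <- f2 + make_disk(300, 300, 220, c0, 30)
  res <- score_fields(list(a = f1 * 0.8, b = f2 * 0.8), mask_spec(),
                      threshold_method = "fixed", threshold = 0.4,
                      min_area_px = 50)
  expect_equal(res$per_field$n_scored, c(6, 4))
  expect_equal(res$per_field$n_matched, c(3, 2))
  expect_equal(res$pooled$n_scored, 10)
  expect_equal(res$pooled$percent_matched, 50)

  expect_warning(
    res2 <- score_fields(list(good = f1 * 0.8, empty = matrix(0, 80, 80)),
                         mask_spec(), threshold_method = "fixed"),
    "no scorable")
  expect_equal(nrow(res2$per_field), 1)
})

test_that("omitted and unscorable masses are conserved out of percentages", {
  img <- matrix(0, 260, 260)
  img <- img + make_disk(260, 260, 60, 60, 62)       # scorable
  img <- img + make_disk(260, 260, 60, 170, 40)      # scorable, fails
  img <- img + make_disk(260, 260, 180, 60, 40)      # overlap pair
  img <- img + make_disk(260, 260, 180, 106, 40)     # overlap pair
  img[240:242, 40:220] <- 1                          # thin line: unscorable
  img <- pmin(img, 1) * 0.8
  res <- score_fields(list(img), mask_spec(), threshold_method = "fixed",
                      threshold = 0.4, min_area_px = 50)
  counts <- table(res$per_mass$status)
  expect_equal(unname(counts["omitted_overlap"]), 2L, ignore_attr = TRUE)
  expect_equal(unname(counts["unscorable"]), 1L, ignore_attr = TRUE)
  n_segmented <- nrow(res$per_mass)
  expect_equal(res$per_field$n_scored +
                 sum(res$per_mass$status == "omitted_overlap") +
                 sum(res$per_mass$status == "unscorable"),
               n_segmented)
  expect_equal(res$per_field$n_scored, 2)
  expect_equal(res$per_field$n_matched, 1)
})

test_that("loop protrusions are pruned before classification", {
  f <- render_field(field_spec(width = 250, height = 250, n_nuclei = 2,
                               compaction = 1, noise_sd = 0,
                               loop_probability = 1, loop_width_px = 3,
                               min_separation_px = 110, seed = 51))
  res <- score_fields(list(f), mask_spec(), threshold_method = "fixed",
                      threshold = 0.4)
  expect_true(all(res$per_mass$loop_pruned))
  expect_true(all(res$per_mass$status == "matched"))
})
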