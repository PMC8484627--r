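test_that("contours classify into the expected bins", {
  th <- bin_thresholds()
  # long straight horizontal line
  lab <- classify_contour(contour(cbind(c(0, 300), c(5, 5))), th)
  expect_equal(format(lab), "long_low_horizontal")
  # short straight vertical line
  lab2 <- classify_contour(contour(cbind(c(5, 5), c(0, 40))), th)
  expect_equal(format(lab2), "short_low_vertical")
  # equal-length 0 and 90 degree segments with extreme_fraction = 0.5
  both <- contour(cbind(c(0, 60, 60), c(0, 0, 60)))
  expect_equal(classify_contour(both,
                                bin_thresholds(extreme_fraction = 0.4))$orientation_class,
               "both")
  # zig-zag of short 45-degree-mean segments with large turns
  zz <- synth_contour(contour_recipe("short_high_diagonal"), 800, 600)
  expect_equal(format(classify_contour(zz, th)), "short_high_diagonal")
})

test_that("classification respects threshold monotonicity", {
  set.seed(33)
  cts <- lapply(1:40, function(i) synth_random_contour())
  for (split in c(30, 87.10, 200)) {
    th_lo <- bin_thresholds(length_split = split)
    th_hi <- bin_thresholds(length_split = split * 1.5)
    for (ct in cts) {
      a <- classify_contour(ct, th_lo)$length_class
      b <- classify_contour(ct, th_hi)$length_class
      # raising the split can only move long -> short, never the reverse
      expect_false(a == "short" && b == "long")
    }
  }
})

test_that("the pool partitions contours and reports empty bins", {
  set.seed(41)
  pool_src <- synth_pool(n_per_bin = 5, seed = 41)
  cpool <- build_contour_pool(pool_src$drawings)
  n_in_pool <- sum(vapply(cpool, length, integer(1)))
  n_contours <- sum(vapply(pool_src$drawings,
                           function(d) length(d$contours), integer(1)))
  expect_equal(n_in_pool, n_contours)   # every contour in exactly one bin
  expect_length(attr(cpool, "empty_bins"), 0)
  expect_error(build_contour_pool(list()), "no drawings")

  # a pool from one straight line has 23 empty bins
  d <- line_drawing(contour(cbind(c(0, 300), c(5, 5))), 800, 600)
  p1 <- build_contour_pool(list(d))
  expect_length(attr(p1, "empty_bins"), 23)
})

test_that("placement scales, shifts and shortens per the stated rules", {
  # scaling example: [400, 300] -> [100, 75]
  pc <- place_contour(contour(cbind(c(400, 500), c(300, 200))))
  expect_equal(unname(pc$points[1, ]), c(100, 75))
  expect_equal(attr(pc, "adjustment"), "as-is")

  # contour sticking out to the right gets shifted back inside
  pc2 <- place_contour(contour(cbind(c(700, 900), c(100, 100))))
  expect_equal(attr(pc2, "adjustment"), "shifted")
  expect_lte(max(pc2$points[, 1]), 200)
  expect_equal(diff(pc2$points[, 1]), 50)  # shape preserved

  # 900-px-wide original (225 px scaled) must be shortened
  wide <- contour(cbind(seq(0, 900, by = 100), rep(50, 10)))
  pc3 <- place_contour(wide)
  expect_equal(attr(pc3, "adjustment"), "shortened")
  expect_lte(diff(range(pc3$points[, 1])), 200)
  expect_gte(nrow(pc3$points), 2)

  # unplaceable: a single 1000-px segment cannot be truncated
  seg <- contour(cbind(c(0, 1000), c(0, 0)))
  expect_null(place_contour(seg))
})

test_that("per-bin image generation respects the length budget", {
  set.seed(17)
  pool_src <- synth_pool(n_per_bin = 150, seed = 17)
  cpool <- build_contour_pool(pool_src$drawings)
  imgs <- generate_images_for_bin(cpool, "long_low_horizontal",
                                  n_images = 3)
  expect_length(imgs, 3)
  for (im in imgs) {
    expect_gt(im$total_length, 1000)
    expect_equal(im$total_length,
                 sum(vapply(im$drawing$contours, contour_length,
                            numeric(1))),
                 tolerance = 1e-9)
    # the last contour pushed the total over the budget
    expect_lte(im$total_length -
                 contour_length(im$drawing$contours[[length(im$drawing$contours)]]),
               1000)
  }
  # zero budget: exactly one contour per image
  img0 <- generate_images_for_bin(cpool, "short_high_both", n_images = 2,
                                  length_budget = 0)
  expect_true(all(vapply(img0, function(im)
    length(im$drawing$contours), integer(1)) == 1L))
  # an impossible budget errors with the bin named
  expect_error(generate_images_for_bin(cpool, "short_low_both",
                                       n_images = 1,
                                       length_budget = 1e6),
               "short_low_both")
  expect_error(generate_images_for_bin(cpool, "nonexistent_bin_name",
                                       n_images = 1),
               "no contours")
})

test_that("the full stimulus set has 480 contained, budgeted images", {
  pool_src <- synth_pool(n_per_bin = 150, seed = 29)
  cpool <- build_contour_pool(pool_src$drawings)
  ss <- generate_stimulus_set(cpool, seed = 30)
  expect_equal(nrow(ss$manifest), 480)
  expect_equal(anyDuplicated(ss$manifest$image_id), 0L)
  cells <- unique(paste(ss$manifest$length_class, ss$manifest$angularity_class,
                        ss$manifest$orientation_class, sep = "_"))
  expect_length(cells, 24)
  expect_true(all(table(paste(ss$manifest$length_class,
                              ss$manifest$angularity_class,
                              ss$manifest$orientation_class)) == 20))
  expect_gt(min(ss$manifest$total_length), 1000)
  # canvas containment for every point of every image
  for (im in ss$images[seq(1, 480, by = 24)]) {
    for (ct in im$drawing$contours) {
      expect_true(all(ct$points[, 1] >= 0 & ct$points[, 1] <= 200))
      expect_true(all(ct$points[, 2] >= 0 & ct$points[, 2] <= 150))
    }
  }
  # provenance: contours originate from the image's own bin
  im1 <- ss$images[[1]]
  key <- format(im1$bin)
  src_ids <- vapply(cpool[[key]], function(ct) ct$id, character(1))
  expect_true(all(im1$provenance$source_id %in% src_ids))
})

test_that("stimulus generation is seed-deterministic", {
  pool_src <- synth_pool(n_per_bin = 150, seed = 55)
  cpool <- build_contour_pool(pool_src$drawings)
  s1 <- generate_stimulus_set(cpool, n_per_bin = 2, seed = 99)
  s2 <- generate_stimulus_set(cpool, n_per_bin = 2, seed = 99)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(lapply(s1$images, function(im) im$drawing$contours),
                   lapply(s2$images, function(im) im$drawing$contours))
  s3 <- generate_stimulus_set(cpool, n_per_bin = 2, seed = 100)
  expect_false(identical(s1$manifest$total_length,
                         s3$manifest$total_length))
})

test_that("an incomplete pool is rejected with the missing bins listed", {
  d <- line_drawing(contour(cbind(c(0, 300), c(5, 5))), 800, 600)
  p1 <- build_contour_pool(list(d))
  expect_error(generate_stimulus_set(p1), "empty bins")
})
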