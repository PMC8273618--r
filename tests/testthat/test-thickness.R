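test_that("squared EDT is exact, with outside-the-grid treated as background", {
  m <- matrix(1, 5, 5)
  d <- sqedt(m)
  expect_equal(d[3, 3], 9)  # nearest outside background centre is 3 away
  expect_equal(d[1, 1], 1)
  m2 <- matrix(0, 5, 7); m2[3, 4] <- 1
  expect_equal(sqedt(m2)[3, 4], 1)
  expect_true(all(sqedt(m2)[m2 == 0] == 0))
})

test_that("slab law: an axis-aligned slab has thickness equal to its height", {
  for (h in c(4, 10, 24)) {
    H <- h + 8; W <- 4 * h + 20
    sl <- matrix(0, H, W)
    sl[5:(4 + h), ] <- 1
    tm <- local_thickness(sl)
    interior_cols <- (h + 1):(W - h)
    expect_true(all(tm$values[5:(4 + h), interior_cols] == h))
    expect_true(all(tm$values[sl == 0] == 0))
  }
})

test_that("an isolated pixel has thickness 2 and covers itself", {
  sp <- matrix(0, 9, 9); sp[5, 5] <- 1
  tm <- local_thickness(sp)
  expect_equal(tm$values[5, 5], 2)
  expect_equal(sum(tm$values > 0), 1)
})

test_that("thickness is at least twice the EDT at every foreground element", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_mask_2d(40, 40, p = 0.5)
    if (sum(m) == 0) next
    tm <- local_thickness(m)$values
    lower <- 2 * sqrt(sqedt(m))
    expect_true(all(tm[m == 1] >= lower[m == 1] - 1e-12))
  }
})

test_that("fast implementation equals the brute-force oracle bitwise (2D)", {
  set.seed(7)
  for (i in 1:40) {
    h <- sample(5:48, 1); w <- sample(5:48, 1)
    m <- random_mask_2d(h, w, p = stats::runif(1, 0.2, 0.8),
                        smooth = sample(0:2, 1))
    if (sum(m) == 0) next
    expect_identical(local_thickness(m)$values, brute_force_thickness(m)$values)
  }
})

test_that("fast implementation equals the brute-force oracle bitwise (3D)", {
  set.seed(8)
  for (i in 1:6) {
    d <- sample(4:16, 3, replace = TRUE)
    m <- random_mask_3d(d, p = stats::runif(1, 0.2, 0.6))
    if (sum(m) == 0) next
    expect_identical(local_thickness(m)$values, brute_force_thickness(m)$values)
  }
})

test_that("dilation never decreases local thickness at retained elements", {
  set.seed(9)
  for (i in 1:5) {
    m <- random_mask_2d(32, 32, p = 0.3, smooth = 1)
    if (sum(m) == 0) next
    dil <- pmax(m, rbind(m[-1, ], 0), rbind(0, m[-nrow(m), ]),
                cbind(m[, -1], 0), cbind(0, m[, -ncol(m)]))
    t1 <- local_thickness(m)$values
    t2 <- local_thickness(dil)$values
    expect_true(all(t2[m == 1] >= t1[m == 1]))
  }
})

test_that("brute-force guard and empty-mask errors trigger", {
  expect_error(local_thickness(matrix(0, 4, 4)), "no foreground")
  expect_error(brute_force_thickness(matrix(1, 120, 120), max_fg = 100), "guard")
})

test_that("summaries convert to micrometres with population SD", {
  m <- matrix(0, 16, 30); m[4:13, ] <- 1  # slab of height 10
  tm <- local_thickness(binary_mask(m, grid_metadata(3.2, "microct")))
  s <- summarize_thickness(tm)
  # away from lateral ends tau = 10; ends are limited by the boundary
  expect_equal(max(tm$values), 10)
  vals <- c(2, 4)
  fake <- structure(list(values = matrix(c(vals, 0, 0), 2, 2),
                         meta = grid_metadata(1, "histology")),
                    class = "cc_thickness_map")
  fs <- summarize_thickness(fake)
  expect_equal(fs$mean_um, 3)
  expect_equal(fs$median_um, 3)
  expect_equal(fs$max_um, 4)
  expect_equal(fs$sd_um, 1)  # population SD
  expect_equal(fs$n_foreground, 2)
})

test_that("micrometre outputs scale linearly with the pixel size", {
  m <- matrix(0, 12, 20); m[4:9, ] <- 1
  s1 <- summarize_thickness(local_thickness(binary_mask(m, grid_metadata(1))))
  s2 <- summarize_thickness(local_thickness(binary_mask(m, grid_metadata(2.5))))
  expect_equal(s2$mean_um, 2.5 * s1$mean_um)
  expect_equal(s2$max_um, 2.5 * s1$max_um)
  expect_equal(s2$sd_um, 2.5 * s1$sd_um)
})

test_that("per-sample thickness averages slices unweighted, order-invariant", {
  mk <- function(mean_um) structure(list(mean_um = mean_um),
                                    class = "cc_thickness_summary")
  expect_equal(sample_mean_thickness(list(mk(30))), 30)
  expect_equal(sample_mean_thickness(list(mk(30), mk(50))), 40)
  expect_equal(sample_mean_thickness(list(mk(50), mk(30))), 40)
  expect_error(sample_mean_thickness(list()), "empty")
})
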