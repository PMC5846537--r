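test_that("the source threshold is the median above 1% of expected", {
  x <- c(0, 0.05, 2, 3, 7)
  expect_equal(source_threshold(x, 10), 3)      # candidates {2, 3, 7}
  expect_equal(source_threshold(rep(10, 6), 10), 10)
  expect_error(source_threshold(numeric(5), 10), "1%")
  expect_error(source_threshold(x, 0), "> 0")
  # ROI membership is strictly above the threshold
  expect_equal(roi_nodes(x, 3), 5L)             # only the node at 7
  expect_equal(roi_nodes(x, max(x)), integer(0))
  expect_equal(roi_nodes(x, -1), 1:5)
})

test_that("VR and DICE are volume-weighted with the documented edge cases", {
  v <- rep(1, 6)
  expect_equal(volume_ratio(1:3, 1:3, v), 1)
  expect_equal(volume_ratio(integer(0), 1:3, v), 0)
  # equal sizes give VR = 1 regardless of overlap (the known caveat)
  expect_equal(volume_ratio(4:6, 1:3, v), 1)
  expect_error(volume_ratio(1:3, integer(0), v), "empty")

  expect_equal(dice_coefficient(1:3, 1:3, v), 1)
  expect_equal(dice_coefficient(1:2, 5:6, v), 0)
  expect_equal(dice_coefficient(1:3, 2:4, v), 2 * 2 / 6)  # 0.6667
  expect_error(dice_coefficient(integer(0), integer(0), v), "empty")
  # volume weighting: a big node dominates the overlap
  v2 <- c(10, 1, 1, 1)
  expect_equal(dice_coefficient(c(1, 2), c(1, 3), v2), 2 * 10 / (11 + 11))
})

test_that("MSE averages squared error over all mesh nodes", {
  expect_equal(mean_square_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mean_square_error(c(1, 0), c(0, 0)), 0.5)
  x <- stats::runif(10); y <- stats::runif(10)
  expect_equal(mean_square_error(x + 2, y + 2), mean_square_error(x, y))
  expect_error(mean_square_error(1:3, 1:4), "mismatch")
})

test_that("metrics are invariant under node relabelling with volumes carried", {
  set.seed(31)
  n <- 40
  x_hat <- stats::runif(n) * c(rep(0, 30), rep(10, 10))
  x_true <- c(rep(0, 32), rep(10, 8))
  vols <- stats::runif(n, 0.5, 2)
  m1 <- recon_metrics(x_hat, x_true, vols, expected_value = 10)
  p <- sample(n)
  m2 <- recon_metrics(x_hat[p], x_true[p], vols[p], expected_value = 10)
  expect_equal(m1, m2)
})

test_that("FWHM of a sampled Gaussian and a rectangle match closed forms", {
  pf <- usblt:::profile_fwhm
  u <- seq(-12, 12, by = 0.05)
  g <- pf(u, exp(-u^2 / (2 * 2^2)))
  expect_true(g$defined)
  expect_equal(g$fwhm, 2 * sqrt(2 * log(2)) * 2, tolerance = 1e-3)  # 4.7096 mm
  # rectangle of width 6 sampled finely: FWHM converges to the width
  r <- pf(u, as.numeric(abs(u) <= 3))
  expect_equal(r$fwhm, 6, tolerance = 0.06)
  # scale invariance
  g2 <- pf(u, 37 * exp(-u^2 / (2 * 2^2)))
  expect_equal(g2$fwhm, g$fwhm)
  # no crossing on one side: undefined and flagged
  h <- pf(u, exp(u / 5))
  expect_false(h$defined)
  expect_true(is.na(h$fwhm))
})

test_that("lattice profiles through a mesh measure a painted Gaussian", {
  mesh <- build_slab_mesh(c(30, 4, 4), 0.5)
  sig <- 2
  x_hat <- exp(-mesh$nodes[, 1]^2 / (2 * sig^2)) *
    as.numeric(abs(mesh$nodes[, 2]) < 1e-9 & abs(mesh$nodes[, 3] - 2) < 1e-9)
  prof <- fwhm_profile(x_hat, mesh, axis = "x", through = c(0, 0, 2))
  expect_equal(prof$fwhm, 2 * sqrt(2 * log(2)) * sig, tolerance = 0.01)
  expect_equal(prof$peak_position, 0)
  expect_s3_class(prof, "blt_profile")
})

test_that("two-source contrast follows the Michelson form on the smaller peak", {
  mkprof <- function(v) list(position = seq_along(v), value = v)
  expect_equal(two_source_contrast(mkprof(c(0, 10, 2, 8, 0))), (8 - 2) / (8 + 2))
  expect_equal(two_source_contrast(mkprof(c(0, 10, 0, 8, 0))), 1)  # valley at zero
  merged <- two_source_contrast(mkprof(c(0, 5, 9, 5, 0)))
  expect_true(is.na(merged))
  expect_true(attr(merged, "merged"))
  # near-flat valley: contrast approaches zero
  expect_lt(two_source_contrast(mkprof(c(0, 5, 4.999, 5, 0))), 1e-3)
})

test_that("metric summaries match a direct two-pass computation", {
  set.seed(32)
  trials <- data.frame(method = rep(c("a", "b"), each = 7),
                       vr = stats::runif(14), dice = stats::runif(14),
                       mse = stats::runif(14))
  s <- summarize_metrics(trials)
  a <- trials[trials$method == "a", ]
  expect_equal(s$mse_mean[s$method == "a"], sum(a$mse) / 7, tolerance = 1e-12)
  expect_equal(s$mse_sd[s$method == "a"],
               sqrt(sum((a$mse - mean(a$mse))^2) / 6), tolerance = 1e-12)
  one <- summarize_metrics(trials[1, ])
  expect_equal(one$vr_sd, 0)
  expect_equal(one$vr_mean, trials$vr[1])
})
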