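test_that("source painting uses node-centre inclusion", {
  mesh <- build_slab_mesh(c(20, 20, 10), 2)
  # a 1.5 mm sphere centred on a lattice node covers exactly that node
  x <- paint_source(mesh, blt_source("sphere", c(0, 0, 4), 1.5, intensity = 10))
  expect_equal(sum(x > 0), 1)
  expect_equal(max(x), 10)
  expect_equal(min(x), 0)
  expect_equal(which(x > 0), nearest_node(mesh, c(0, 0, 4)))
  # the standard cylinder (r = 1.5, h = 5) covers the axis nodes within h/2
  xc <- paint_source(mesh, blt_source("cylinder", c(0, 0, 5), 1.5, 5, intensity = 10))
  got <- which(xc > 0)
  want <- which(sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2) <= 1.5 &
                abs(mesh$nodes[, 3] - 5) <= 2.5)
  expect_setequal(got, want)
  # disjoint sources are additive
  s1 <- blt_source("sphere", c(-4, 0, 4), 1.5, intensity = 10)
  s2 <- blt_source("sphere", c(4, 0, 4), 1.5, intensity = 10)
  expect_equal(paint_source(mesh, list(s1, s2)),
               paint_source(mesh, s1) + paint_source(mesh, s2))
  # a source smaller than the lattice can represent is an error
  expect_error(paint_source(mesh, blt_source("sphere", c(1, 1, 3), 0.4)),
               "no mesh node")
})

test_that("noise respects the SNR convention, the seed and the provenance", {
  y <- rep(1, 1e5)
  clean <- add_noise(y, Inf, seed = 1)
  expect_equal(clean$y, y)
  n1 <- add_noise(y, 20, seed = 42)
  n2 <- add_noise(y, 20, seed = 42)
  expect_identical(n1$y, n2$y)
  n3 <- add_noise(y, 20, seed = 43)
  expect_false(identical(n1$y, n3$y))
  # realized SNR of per-measurement proportional noise: 20 +- 0.1 dB
  eps <- n1$y - y
  expect_equal(20 * log10(1 / stats::sd(eps)), 20, tolerance = 0.1)
  expect_equal(n1$provenance$snr_db, 20)
  expect_equal(n1$provenance$seed, 42L)
  # global-RMS convention: one sigma for all measurements
  yv <- c(rep(10, 5e4), rep(0.1, 5e4))
  ng <- add_noise(yv, 20, seed = 7, convention = "global_rms")
  sig <- sqrt(mean(yv^2)) / 10
  expect_equal(stats::sd(ng$y - yv), sig, tolerance = 0.01 * sig)
  # the caller's RNG stream is left untouched
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(add_noise(y[1:10], 20, seed = 3)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("trials are deterministic and methods share the noisy data per seed", {
  tb <- tiny_testbed()
  t1 <- run_trial(tb, "us_guided", seed = 5, d = 3)
  t2 <- run_trial(tb, "us_guided", seed = 5, d = 3)
  expect_identical(t1$metrics, t2$metrics)
  expect_identical(t1$recon$x_hat, t2$recon$x_hat)
  tw <- run_trial(tb, "whole", seed = 5)
  expect_identical(tw$recon$y, t1$recon$y)  # paired-noise design
  # a noiseless trial beats a noisy one on the same setup
  t0 <- run_trial(tb, "us_guided", seed = 5, d = 3, snr_db = Inf)
  expect_lt(t0$metrics$mse, t1$metrics$mse)
})

test_that("noiseless well-conditioned recovery returns the painted intensity", {
  tb <- tiny_testbed()
  fit <- blt_reconstruct(tb$jacobian, tb$y0, method = "us_guided",
                         mesh = tb$mesh, us_position = c(0, 0, 4), d = 3)
  src <- which(tb$x_true > 0)
  expect_true(all(abs(fit$x_hat[src] - 10) < 0.1))  # within 1% of 10
  expect_true(all(fit$x_hat[-src] < 0.1))
  # the sub-Jacobian is genuinely well posed here
  tr <- truncate_jacobian(tb$jacobian, fit$region)
  expect_gte(nrow(tr$J), ncol(tr$J))
  expect_equal(qr(tr$J)$rank, ncol(tr$J))
})

test_that("repeated runs summarise per-method means and stay reproducible", {
  tb <- tiny_testbed()
  r1 <- run_repeated(tb, methods = c("whole", "us_guided"), realizations = 3,
                     base_seed = 11, d = 3)
  r2 <- run_repeated(tb, methods = c("whole", "us_guided"), realizations = 3,
                     base_seed = 11, d = 3)
  expect_identical(r1$trials, r2$trials)
  expect_equal(nrow(r1$trials), 6)
  expect_equal(sort(unique(r1$trials$seed)), 11:13)
  single <- run_repeated(tb, methods = "us_guided", realizations = 1,
                         base_seed = 11)
  expect_equal(single$summary$mse_sd, 0)
  expect_equal(single$summary$mse_mean, single$trials$mse[1])
})

test_that("the dynamic-range sweep pairs seeds across d values", {
  tb <- tiny_testbed()
  sw <- dynamic_range_sweep(tb, d_values = c(2, 4), realizations = 2, base_seed = 3)
  expect_equal(nrow(sw$table), 2)
  expect_equal(sw$table$d, c(2, 4))
  expect_equal(unique(sw$trials$seed), c(3, 4))
  expect_true(all(c("vr_mean", "dice_mean", "mse_mean") %in% names(sw$table)))
})

test_that("the two-source driver reports contrasts per separation and method", {
  res <- two_source_experiment(
    separations = 6, depth = 3, realizations = 2, base_seed = 2,
    methods = c("whole", "us_guided"),
    testbed_args = list(dims = c(20, 20, 8), spacing = 2,
                        det_extent = c(12, 12), det_pitch = 3))
  expect_equal(nrow(res$table), 2)
  expect_true(all(res$table$contrast_mean >= 0 & res$table$contrast_mean <= 1))
  expect_true(all(c("sep6_whole", "sep6_us_guided") %in% names(res$profiles)))
})
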