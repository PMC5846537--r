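test_that("total sensitivity is the column sum over all stacked measurements", {
  J <- matrix(c(1, 3, 2, 4), nrow = 2)  # [[1,2],[3,4]]
  s <- total_sensitivity(J)
  expect_equal(s$s, c(4, 6))
  expect_equal(s$positive_floor, 4)
  J1 <- matrix(c(0.5, 2, 8), nrow = 1)
  expect_equal(total_sensitivity(J1)$s, c(0.5, 2, 8))
  # permuting rows leaves the profile unchanged
  set.seed(1)
  Jr <- matrix(stats::runif(35), 5, 7)
  expect_equal(total_sensitivity(Jr[sample(5), ])$s, total_sensitivity(Jr)$s)
})

test_that("dynamic range is max over min positive sensitivity", {
  expect_equal(dynamic_range_of(c(0.5, 2, 8)), 16)
  expect_equal(dynamic_range_of(c(3, 3, 3)), 1)
  expect_equal(dynamic_range_of(c(0, 1, 10)), 10)  # zeros excluded
  expect_error(dynamic_range_of(c(0, 0)), "zero")
})

test_that("NOI selection matches a brute-force filter and is monotone in d", {
  s <- c(1, 2, 4, 8, 16)
  expect_equal(select_noi(s, 3, 2), c(2L, 3L, 4L))     # values 2, 4, 8
  expect_equal(select_noi(s, 3, 1), 3L)                # degenerate interval
  expect_equal(select_noi(s, 3, 16), 1:5)              # covers the whole range
  expect_error(select_noi(c(0, 1), 1, 2), "zero sensitivity")
  expect_error(select_noi(s, 3, 0.5), ">= 1")

  set.seed(11)
  for (k in 1:1000) {
    n <- sample(3:40, 1)
    sv <- stats::runif(n)^3 * 10
    sv[sample(n, sample(0:2, 1))] <- 0
    pos <- which(sv > 0)
    ref <- pos[sample.int(length(pos), 1)]
    d <- 1 + stats::rexp(1)
    got <- select_noi(sv, ref, d)
    want <- sort(Filter(function(i) sv[i] >= sv[ref] / d && sv[i] <= sv[ref] * d,
                        seq_len(n)))
    expect_identical(got, as.integer(want))
  }
  # monotonicity: widening d never drops a node
  set.seed(12)
  for (k in 1:50) {
    sv <- stats::runif(30)^2
    ref <- sample(30, 1)
    d1 <- 1 + stats::rexp(1); d2 <- d1 * (1 + stats::rexp(1))
    expect_true(all(select_noi(sv, ref, d1) %in% select_noi(sv, ref, d2)))
  }
})

test_that("guided regions contain the reference node and bound their dynamic range", {
  tb <- tiny_testbed()
  s <- total_sensitivity(tb$jacobian)
  reg <- us_guided_region(tb$mesh, s, c(0, 0, 4), 3)
  expect_identical(reg$method_tag, "us_guided")
  expect_true(reg$reference_node %in% reg$noi)
  # all true source nodes fall inside the region at d = 3
  expect_true(all(which(tb$x_true > 0) %in% reg$noi))
  # the truncated profile's dynamic range is at most d^2
  expect_lte(dynamic_range_of(s$s[reg$noi]), 3^2 + 1e-9)
  # a huge d degenerates towards every positive-sensitivity node
  reg_inf <- us_guided_region(tb$mesh, s, c(0, 0, 4), 1e12)
  expect_setequal(reg_inf$noi, which(s$s > 0))
  expect_error(us_guided_region(tb$mesh, s, c(100, 0, 4), 3), "bounding box")
})

test_that("large permissible regions are laterally bounded and depth-free", {
  mesh <- build_slab_mesh(c(20, 20, 10), 2)
  all_reg <- large_pr_region(mesh, c(0, 0), 10)
  expect_equal(all_reg$noi, seq_len(nrow(mesh$nodes)))
  reg <- large_pr_region(mesh, c(0, 0), 5)
  want <- which(abs(mesh$nodes[, 1]) <= 5 + 1e-9 & abs(mesh$nodes[, 2]) <= 5 + 1e-9)
  expect_equal(reg$noi, sort(want))
  # every selected lateral column carries every z level
  zs <- sort(unique(mesh$nodes[, 3]))
  cols <- unique(mesh$nodes[reg$noi, 1:2, drop = FALSE])
  expect_equal(length(reg$noi), nrow(cols) * length(zs))
})

test_that("Jacobian truncation restricts columns and keeps the map back", {
  J <- matrix(1:12, 3, 4)
  whole <- usblt:::new_region("whole", 1:4)
  tr <- truncate_jacobian(J, whole)
  expect_equal(tr$J, J)
  one <- usblt:::new_region("us_guided", 2L, reference_node = 2L, d = 1)
  tr1 <- truncate_jacobian(J, one)
  expect_equal(tr1$J, J[, 2, drop = FALSE])
  expect_equal(tr1$columns, 2L)
})

test_that("solving the truncated system equals a zero-constrained full solve", {
  # well-conditioned overdetermined instance with a nonnegative solution
  set.seed(21)
  J <- matrix(stats::runif(15 * 6, 0.1, 1), 15, 6)
  noi <- c(2L, 4L, 5L)
  x_true <- numeric(6); x_true[noi] <- c(2, 1, 3)
  y <- as.numeric(J %*% x_true)
  reg <- usblt:::new_region("us_guided", noi, reference_node = 4L, d = 2)
  tr <- truncate_jacobian(J, reg)
  fit <- cscg_solve(tr$J, y)
  x_embed <- numeric(6); x_embed[tr$columns] <- fit$x
  # dense oracle: least squares on the free columns, zeros elsewhere
  x_oracle <- numeric(6)
  x_oracle[noi] <- qr.solve(J[, noi], y)
  expect_equal(x_embed, x_oracle, tolerance = 1e-8)
  expect_equal(x_embed, x_true, tolerance = 1e-8)
})

test_that("ultrasound depth converts to a permissible-region depth", {
  expect_equal(us_depth_to_pr_depth(15.5, 20), 4.5)
  expect_equal(us_depth_to_pr_depth(15.5, 20, detectors_on = "same"), 15.5)
  expect_error(us_depth_to_pr_depth(25, 20), "thickness")
})
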