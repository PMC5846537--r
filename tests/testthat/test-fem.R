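test_that("with zero diffusion and no boundary term the system is the mass matrix", {
  mesh <- build_slab_mesh(c(6, 6, 4), 2)
  K <- assemble_fem(mesh, mua = 1, kappa = 0, robin = FALSE)
  # row sums of the absorption mass matrix are the nodal volumes
  expect_equal(as.numeric(Matrix::rowSums(K)), node_volumes(mesh), tolerance = 1e-12)
  expect_true(Matrix::isSymmetric(K))
})

test_that("assembly matches an independent dense oracle on small meshes", {
  for (cfg in list(list(d = c(1, 1, 1), h = 1), list(d = c(4, 2, 2), h = 2))) {
    mesh <- build_slab_mesh(cfg$d, cfg$h)
    n <- nrow(mesh$nodes)
    set.seed(7)
    mua <- stats::runif(n, 0.01, 0.05)
    kappa <- stats::runif(n, 0.2, 0.4)
    K <- assemble_fem(mesh, mua, kappa, refractive_index = 1.33, robin = TRUE)
    Ko <- dense_fem_oracle(mesh, mua, kappa, 1.33, robin = TRUE)
    expect_equal(as.matrix(K), Ko, tolerance = 1e-12, ignore_attr = TRUE)
    # and without the boundary term
    K2 <- assemble_fem(mesh, mua, kappa, robin = FALSE)
    Ko2 <- dense_fem_oracle(mesh, mua, kappa, 1.33, robin = FALSE)
    expect_equal(as.matrix(K2), Ko2, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("boundary reflection parameter behaves like the Fresnel mismatch factor", {
  expect_equal(boundary_reflection_parameter(1), 1)
  expect_gt(boundary_reflection_parameter(1.33), 2)   # tissue-air is strongly reflecting
  expect_lt(boundary_reflection_parameter(1.33), 3)
  expect_true(boundary_reflection_parameter(1.5) > boundary_reflection_parameter(1.33))
  expect_error(boundary_reflection_parameter(0.8), ">= 1")
})

test_that("point-source fields are nonnegative and decay monotonically at first", {
  mesh <- build_slab_mesh(c(20, 20, 12), 2)
  K <- assemble_fem(mesh, 0.02, diffusion_coefficient(0.02, 1))
  q <- nearest_node(mesh, c(0, 0, 6))
  phi <- solve_green(K, q)
  expect_true(all(phi >= 0))
  expect_gt(phi[q], 0)
  # zero source: zero field
  expect_equal(solve_green(K, numeric(nrow(mesh$nodes))), numeric(nrow(mesh$nodes)))
  # field decreases along +x from the source until near the boundary
  line <- which(abs(mesh$nodes[, 2]) < 1e-9 & abs(mesh$nodes[, 3] - 6) < 1e-9 &
                mesh$nodes[, 1] >= 0 & mesh$nodes[, 1] <= 8)
  line <- line[order(mesh$nodes[line, 1])]
  expect_true(all(diff(phi[line]) < 0))
})

test_that("the FEM field tracks the infinite-medium Green's function within 15%", {
  mesh <- build_slab_mesh(c(24, 24, 24), 1)
  mua <- 0.05; musp <- 1.0
  kappa <- diffusion_coefficient(mua, musp)
  K <- assemble_fem(mesh, mua, kappa, refractive_index = 1.33)
  q <- nearest_node(mesh, c(0, 0, 12))
  phi <- solve_green(K, q)
  r <- sqrt(rowSums(sweep(mesh$nodes, 2, mesh$nodes[q, ])^2))
  mueff <- sqrt(mua / kappa)
  analytic <- exp(-mueff * r) / (4 * pi * kappa * r)
  sel <- r >= 3 & r <= 8
  expect_gt(sum(sel), 1000)
  ratio <- phi[sel] / analytic[sel]
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("forward data respect the symmetry of a centred source layout", {
  tb <- fixture("sym_testbed", function() {
    slab_testbed(dims = c(20, 20, 12), spacing = 2, det_extent = c(12, 12),
                 det_pitch = 4,
                 sources = blt_source("sphere", c(0, 0, 6), 2.2, intensity = 10))
  })
  pos <- tb$detectors$positions
  mirror <- vapply(seq_len(nrow(pos)), function(j)
    which(abs(pos[, 1] + pos[j, 1]) < 1e-9 & abs(pos[, 2] - pos[j, 2]) < 1e-9)[1],
    integer(1))
  ndet <- nrow(pos)
  for (w in seq_along(tb$jacobian$wavelengths)) {
    yy <- tb$y0$y[(w - 1) * ndet + seq_len(ndet)]
    # structured triangulation has a preferred diagonal, so symmetry holds
    # to discretisation accuracy, not machine accuracy
    expect_lt(max(abs(yy - yy[mirror])) / max(yy), 0.10)
  }
})

test_that("raising absorption everywhere lowers every measurement", {
  setup <- mini_jacobian_setup()
  x <- paint_source(setup$mesh, blt_source("sphere", c(0, 0, 3), 2.1, intensity = 10))
  darker <- blt_spectral_model(chromophores = list(water = 0.5, hbo = 0.02, hb = 0.01))
  jac2 <- suppressWarnings(build_jacobian(setup$mesh, setup$detectors, darker,
                                          setup$wavelengths))
  y1 <- forward_measurements(setup$jac, x)$y
  y2 <- forward_measurements(jac2, x)$y
  expect_true(all(y2 < y1))
})
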