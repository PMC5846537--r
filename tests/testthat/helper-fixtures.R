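# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# ~245-node slab with a well-conditioned guided subproblem: 25 detectors,
# 5 wavelengths, a 7-node spherical source fully inside the d = 3 region.
tiny_testbed <- function() {
  fixture("tiny_testbed", function() {
    slab_testbed(dims = c(12, 12, 8), spacing = 2,
                 det_extent = c(8, 8), det_pitch = 2,
                 sources = blt_source("sphere", c(0, 0, 4), 2.2, intensity = 10))
  })
}

# 100-node mesh + 4 detectors x 2 wavelengths for reciprocity checks.
mini_jacobian_setup <- function() {
  fixture("mini_jac", function() {
    mesh <- build_slab_mesh(c(8, 8, 6), 2)
    detectors <- place_detector_grid(mesh, c(4, 4), 4, face = "z+")
    model <- blt_spectral_model()
    wavelengths <- c(600, 620)
    jac <- suppressWarnings(build_jacobian(mesh, detectors, model, wavelengths))
    list(mesh = mesh, detectors = detectors, model = model,
         wavelengths = wavelengths, jac = jac)
  })
}

# Independent dense FEM assembly oracle: per-element matrices from explicit
# linear-basis integration, accumulated into a dense matrix. Shares only
# the node/element lists with the implementation under test.
dense_fem_oracle <- function(mesh, mua, kappa, n_ref, robin = TRUE) {
  nd <- mesh$nodes
  n <- nrow(nd)
  K <- matrix(0, n, n)
  for (e in seq_len(nrow(mesh$elements))) {
    v <- mesh$elements[e, ]
    p <- nd[v, , drop = FALSE]
    V <- abs(det(cbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))) / 6
    # gradients of the four barycentric basis functions
    G <- matrix(0, 4, 3)
    Ainv <- solve(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))
    G[2:4, ] <- t(Ainv)
    G[1, ] <- -colSums(G[2:4, , drop = FALSE])
    kap_e <- mean(kappa[v]); mua_e <- mean(mua[v])
    Ke <- kap_e * V * (G %*% t(G)) +
      mua_e * V / 20 * (matrix(1, 4, 4) + diag(4))
    K[v, v] <- K[v, v] + Ke
  }
  if (robin) {
    alpha <- 1 / (2 * boundary_reflection_parameter(n_ref))
    # boundary faces: element faces occurring once
    faces <- rbind(mesh$elements[, c(1, 2, 3)], mesh$elements[, c(1, 2, 4)],
                   mesh$elements[, c(1, 3, 4)], mesh$elements[, c(2, 3, 4)])
    key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
    single <- names(which(table(key) == 1))
    tri <- faces[match(single, key), , drop = FALSE]
    for (t_i in seq_len(nrow(tri))) {
      v <- tri[t_i, ]
      p <- nd[v, , drop = FALSE]
      cr <- c(
        (p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) - (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
        (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) - (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
        (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) - (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
      area <- sqrt(sum(cr^2)) / 2
      K[v, v] <- K[v, v] + alpha * area / 12 * (matrix(1, 3, 3) + diag(3))
    }
  }
  K
}
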