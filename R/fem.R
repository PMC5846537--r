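# Linear (P1) tetrahedral finite elements for the continuous-wave photon
# diffusion equation  (-div kappa grad + mua) Phi = q  with the Robin
# (refractive-index-mismatch) boundary condition
#   kappa dPhi/dn + Phi / (2A(n)) = 0.

# Per-mesh geometric quantities reused across wavelengths: basis-function
# gradients, element volumes, boundary triangles and their areas.
fem_geometry <- function(mesh) {
  el <- mesh$elements; nd <- mesh$nodes
  a <- nd[el[, 1], , drop = FALSE]
  e1 <- nd[el[, 2], , drop = FALSE] - a
  e2 <- nd[el[, 3], , drop = FALSE] - a
  e3 <- nd[el[, 4], , drop = FALSE] - a
  cross3 <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  c23 <- cross3(e2, e3); c31 <- cross3(e3, e1); c12 <- cross3(e1, e2)
  det6 <- rowSums(e1 * c23)          # 6 * signed volume
  vol <- abs(det6) / 6
  if (any(vol <= 1e-14)) stop("degenerate (zero-volume) tetrahedra in mesh")
  # gradients of barycentric coordinates 2..4 are rows of inv([e1;e2;e3]^T)
  g2 <- c23 / det6; g3 <- c31 / det6; g4 <- c12 / det6
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)

  # boundary triangles: element faces that occur exactly once
  faces <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
                 el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  fs <- cbind(pmin(faces[, 1], faces[, 2], faces[, 3]),
              pmax(faces[, 1], faces[, 2], faces[, 3]))
  fs <- cbind(fs[, 1], faces[, 1] + faces[, 2] + faces[, 3] - fs[, 1] - fs[, 2], fs[, 2])
  o <- order(fs[, 1], fs[, 2], fs[, 3])
  fo <- fs[o, , drop = FALSE]
  same_next <- c(rowSums(fo[-nrow(fo), , drop = FALSE] == fo[-1, , drop = FALSE]) == 3, FALSE)
  same_prev <- c(FALSE, same_next[-length(same_next)])
  tri <- fo[!(same_next | same_prev), , drop = FALSE]
  p <- nd[tri[, 1], , drop = FALSE]
  q <- nd[tri[, 2], , drop = FALSE] - p
  r <- nd[tri[, 3], , drop = FALSE] - p
  tri_area <- sqrt(rowSums(cross3(q, r)^2)) / 2

  list(grads = grads, vol = vol, tri = tri, tri_area = tri_area)
}

#' Boundary reflection parameter A(n)
#'
#' Internal-reflection factor of the Robin boundary condition for a tissue
#' to air refractive-index mismatch, via the critical-angle / Fresnel
#' approximation commonly used in CW diffuse optics. \code{A(1) = 1}
#' (matched boundary).
#'
#' @param n tissue refractive index relative to the outside medium (>= 1).
#' @return dimensionless A >= 1.
#' @export
boundary_reflection_parameter <- function(n) {
  if (any(n < 1)) stop("refractive index must be >= 1")
  r0 <- ((n - 1) / (n + 1))^2
  cos_c <- sqrt(pmax(0, 1 - (1 / n)^2))
  out <- (2 / (1 - r0) - 1 + cos_c^3) / (1 - cos_c^2)
  out[n == 1] <- 1
  out
}

#' Assemble the diffusion FEM system matrix
#'
#' Stiffness (diffusion), mass (absorption) and Robin boundary contributions
#' on linear tetrahedral elements:
#' \code{K = stiffness(kappa) + mass(mua) + boundary(1/(2A(n)))}.
#' Element coefficients are vertex averages. The result is sparse, symmetric
#' and positive definite for a valid mesh with positive \code{kappa}.
#'
#' @param mesh a \code{blt_mesh}.
#' @param mua per-node absorption (mm^-1).
#' @param kappa per-node diffusion coefficient (mm).
#' @param refractive_index scalar tissue refractive index for the boundary
#'   term.
#' @param robin include the Robin boundary term (set \code{FALSE} for a pure
#'   Neumann problem, e.g. when inspecting the mass matrix).
#' @param geometry optional precomputed \code{fem_geometry(mesh)} (reused
#'   across wavelengths by the Jacobian builder).
#' @return sparse symmetric matrix (\code{Matrix} package) of size N x N.
#' @export
assemble_fem <- function(mesh, mua, kappa, refractive_index = 1.33,
                         robin = TRUE, geometry = NULL) {
  n <- nrow(mesh$nodes)
  if (length(mua) == 1) mua <- rep(mua, n)
  if (length(kappa) == 1) kappa <- rep(kappa, n)
  if (length(mua) != n || length(kappa) != n)
    stop("`mua` and `kappa` must have one value per node")
  if (any(kappa < 0) || any(mua < 0)) stop("optical properties must be nonnegative")
  g <- if (is.null(geometry)) fem_geometry(mesh) else geometry
  el <- mesh$elements
  vol <- g$vol
  kap_e <- (kappa[el[, 1]] + kappa[el[, 2]] + kappa[el[, 3]] + kappa[el[, 4]]) / 4
  mua_e <- (mua[el[, 1]] + mua[el[, 2]] + mua[el[, 3]] + mua[el[, 4]]) / 4

  ne <- nrow(el)
  ii <- jj <- integer(16L * ne); xx <- numeric(16L * ne)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    stiff <- kap_e * vol * rowSums(g$grads[[a]] * g$grads[[b]])
    mass <- mua_e * vol / 20 * (if (a == b) 2 else 1)
    rng <- pos + seq_len(ne)
    ii[rng] <- el[, a]; jj[rng] <- el[, b]; xx[rng] <- stiff + mass
    pos <- pos + ne
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))

  if (robin) {
    alpha <- 1 / (2 * boundary_reflection_parameter(refractive_index))
    tri <- g$tri; area <- g$tri_area
    nt <- nrow(tri)
    bi <- bj <- integer(9L * nt); bx <- numeric(9L * nt)
    pos <- 0L
    for (a in 1:3) for (b in 1:3) {
      rng <- pos + seq_len(nt)
      bi[rng] <- tri[, a]; bj[rng] <- tri[, b]
      bx[rng] <- alpha * area / 12 * (if (a == b) 2 else 1)
      pos <- pos + nt
    }
    K <- K + Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(n, n))
  }
  Matrix::forceSymmetric(K)
}

# Cached CHOLMOD factorisation with a positive-definiteness check.
fem_factorize <- function(K) {
  ch <- tryCatch(Matrix::Cholesky(K, LDL = FALSE, perm = TRUE),
                 error = function(e)
                   stop("FEM system is not positive definite (degenerate mesh or zero diffusion): ",
                        conditionMessage(e)))
  ch
}

# Linear elements undershoot near point sources by O(h^2); small negative
# fluence values are clipped to zero, with a warning only when the
# undershoot is large enough (1% of the field maximum) to question the
# discretisation.
clip_negative_field <- function(phi, context = "field") {
  mn <- min(phi)
  if (mn < 0) {
    mx <- max(phi)
    if (mx > 0 && -mn > 1e-2 * mx)
      warning(sprintf("clipping negative %s values (largest clip %.3g of field max)",
                      context, -mn / mx))
    phi[phi < 0] <- 0
  }
  phi
}

#' Solve the diffusion system for a point source
#'
#' Computes the nodal photon fluence for a unit point source at node
#' \code{q} (right-hand side \code{e_q}); small negative values from the
#' discretisation are clipped to zero.
#'
#' @param K assembled FEM matrix (from \code{assemble_fem}) or a
#'   factorisation returned by the internal factoriser.
#' @param q source node index, or a full right-hand-side vector.
#' @return numeric nodal field, >= 0.
#' @export
solve_green <- function(K, q) {
  n <- nrow(K)
  rhs <- if (length(q) == 1) {
    if (q < 1 || q > n) stop("source node out of range")
    b <- numeric(n); b[q] <- 1; b
  } else {
    if (length(q) != n) stop("right-hand side length must match the system")
    q
  }
  if (all(rhs == 0)) return(numeric(n))
  ch <- if (inherits(K, "CHMfactor")) K else fem_factorize(K)
  phi <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  res <- if (inherits(K, "CHMfactor")) 0 else sqrt(sum((as.numeric(K %*% phi) - rhs)^2))
  if (res > 1e-6 * sqrt(sum(rhs^2)))
    stop(sprintf("diffusion solve did not converge (residual norm %.3g)", res))
  clip_negative_field(phi, "fluence")
}
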