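#' Assemble the stacked multi-wavelength BLT Jacobian
#'
#' Builds the sensitivity matrix \code{J} (rows = detector x wavelength
#' measurements, columns = mesh nodes) relating nodal source intensity
#' \code{x} to boundary data \code{y = J x}. Each row is obtained by
#' reciprocity from one adjoint diffusion solve: a unit source at the
#' boundary node nearest the detector, scaled by the per-wavelength emission
#' weight and by the lumped nodal volumes (the source term is an intensity
#' per node volume). Rows are ordered wavelength-major: all detectors at the
#' first wavelength, then the second, and so on.
#'
#' @param mesh a \code{blt_mesh}.
#' @param detectors a \code{blt_detectors} grid on a mesh face.
#' @param model a \code{blt_spectral_model} (or named per-region list).
#' @param wavelengths wavelengths in nm.
#' @param emission_weights per-wavelength source-spectrum weights
#'   \eqn{\gamma_\lambda}; must sum to 1. Default: uniform.
#' @return object of class \code{blt_jacobian}: list with dense matrix
#'   \code{J} (M_total x N), \code{wavelengths}, \code{gamma},
#'   \code{n_detectors}, \code{detector_nodes}, \code{node_volumes} and
#'   \code{row_map} (data.frame row / detector / wavelength).
#' @export
build_jacobian <- function(mesh, detectors, model, wavelengths,
                           emission_weights = NULL) {
  stopifnot(inherits(mesh, "blt_mesh"), inherits(detectors, "blt_detectors"))
  nw <- length(wavelengths)
  if (nw < 1) stop("at least one wavelength required")
  if (is.null(emission_weights)) emission_weights <- rep(1 / nw, nw)
  if (length(emission_weights) != nw)
    stop("`emission_weights` must have one weight per wavelength")
  if (abs(sum(emission_weights) - 1) > 1e-8)
    stop("`emission_weights` must sum to 1")

  # detectors must lie on the mesh boundary (slab bounding box surface)
  lim <- apply(mesh$nodes, 2, range)
  pos <- detectors$positions
  on_face <- (abs(pos[, 1] - lim[1, 1]) < 1e-9) | (abs(pos[, 1] - lim[2, 1]) < 1e-9) |
             (abs(pos[, 2] - lim[1, 2]) < 1e-9) | (abs(pos[, 2] - lim[2, 2]) < 1e-9) |
             (abs(pos[, 3] - lim[1, 3]) < 1e-9) | (abs(pos[, 3] - lim[2, 3]) < 1e-9)
  if (!all(on_face))
    stop(sprintf("%d detector position(s) are not on the mesh boundary", sum(!on_face)))

  ndet <- nrow(pos)
  n <- nrow(mesh$nodes)
  det_nodes <- vapply(seq_len(ndet), function(j) nearest_node(mesh, pos[j, ]), integer(1))
  vol <- node_volumes(mesh)
  geom <- fem_geometry(mesh)

  J <- matrix(0, nrow = ndet * nw, ncol = n)
  B <- Matrix::sparseMatrix(i = det_nodes, j = seq_len(ndet), x = 1, dims = c(n, ndet))
  for (w in seq_len(nw)) {
    props <- optical_properties(mesh, model, wavelengths[w])
    K <- assemble_fem(mesh, props$mua, props$kappa, props$refractive_index,
                      robin = TRUE, geometry = geom)
    ch <- fem_factorize(K)
    Phi <- as.matrix(Matrix::solve(ch, B, system = "A"))
    Phi <- clip_negative_field(Phi, "adjoint fluence")
    rows <- (w - 1L) * ndet + seq_len(ndet)
    J[rows, ] <- emission_weights[w] * t(Phi * vol)
  }

  row_map <- data.frame(row = seq_len(ndet * nw),
                        detector = rep(seq_len(ndet), times = nw),
                        wavelength = rep(wavelengths, each = ndet))
  structure(list(J = J, wavelengths = wavelengths, gamma = emission_weights,
                 n_detectors = ndet, detector_nodes = det_nodes,
                 node_volumes = vol, row_map = row_map),
            class = "blt_jacobian")
}

#' @export
print.blt_jacobian <- function(x, ...) {
  cat(sprintf("blt_jacobian: %d measurements (%d detectors x %d wavelengths) x %d nodes\n",
              nrow(x$J), x$n_detectors, length(x$wavelengths), ncol(x$J)))
  invisible(x)
}

jacobian_matrix <- function(J) {
  if (inherits(J, "blt_jacobian")) J$J
  else if (is.matrix(J)) J
  else stop("expected a blt_jacobian or a numeric matrix")
}

#' Noiseless forward measurements y = J x
#'
#' @param jacobian a \code{blt_jacobian} (or plain matrix).
#' @param x nodal source intensity vector, length N, >= 0.
#' @return object of class \code{blt_measurements}: list with vector
#'   \code{y}, \code{wavelengths} and a \code{provenance} list.
#' @export
forward_measurements <- function(jacobian, x) {
  J <- jacobian_matrix(jacobian)
  if (length(x) != ncol(J))
    stop(sprintf("source vector length %d does not match Jacobian columns %d",
                 length(x), ncol(J)))
  y <- as.numeric(J %*% x)
  structure(list(y = y,
                 wavelengths = if (inherits(jacobian, "blt_jacobian")) jacobian$wavelengths else NULL,
                 provenance = list(noise = "noiseless")),
            class = "blt_measurements")
}

#' @export
print.blt_measurements <- function(x, ...) {
  cat(sprintf("blt_measurements: %d values, noise: %s\n", length(x$y),
              if (identical(x$provenance$noise, "noiseless")) "none"
              else sprintf("SNR %g dB (seed %s)", x$provenance$snr_db, x$provenance$seed)))
  invisible(x)
}

measurement_vector <- function(y) {
  if (inherits(y, "blt_measurements")) y$y else as.numeric(y)
}
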