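#' Options for the sparsity-promoting conjugate-gradient solver
#'
#' @param inner_iterations CG (CGLS) iterations per projection round.
#' @param outer_rounds projection rounds: each round restricts CG to the
#'   free variables (currently positive, or pushed positive by the
#'   gradient) and projects the result onto the nonnegative cone.
#' @param keep_fraction support threshold tau: after the constrained solve,
#'   entries below \code{tau * max(x)} are discarded and the solve is
#'   repeated on the surviving support. In (0, 1].
#' @param tol relative residual tolerance for early CG termination.
#' @param normalize_columns scale Jacobian columns to unit Euclidean norm
#'   before solving (compensates the depth-dependent sensitivity scale).
#' @return list of class \code{cscg_options}.
#' @export
cscg_options <- function(inner_iterations = 50, outer_rounds = 5,
                         keep_fraction = 0.1, tol = 1e-8,
                         normalize_columns = TRUE) {
  stopifnot(inner_iterations >= 1, outer_rounds >= 1,
            keep_fraction > 0, keep_fraction <= 1, tol > 0)
  structure(list(inner_iterations = as.integer(inner_iterations),
                 outer_rounds = as.integer(outer_rounds),
                 keep_fraction = keep_fraction, tol = tol,
                 normalize_columns = isTRUE(normalize_columns)),
            class = "cscg_options")
}

# CGLS: conjugate gradients on the normal equations A'A x = A'y without
# forming A'A. Warm-startable. The data residual is non-increasing in exact
# arithmetic; a finite-precision loss of conjugacy can make it grow, so the
# best iterate seen is tracked and returned if divergence is detected.
cgls <- function(A, y, x0 = NULL, maxit = 50, tol = 1e-8) {
  x <- if (is.null(x0)) numeric(ncol(A)) else x0
  r <- y - as.numeric(A %*% x)
  s <- as.numeric(crossprod(A, r))
  p <- s
  gam <- sum(s^2)
  gam0 <- gam
  it <- 0L
  best_x <- x
  best_rn <- sqrt(sum(r^2))
  while (it < maxit && is.finite(gam) && gam > (tol^2) * gam0 && gam > 0) {
    q <- as.numeric(A %*% p)
    qq <- sum(q^2)
    if (!is.finite(qq) || qq == 0) break
    alpha <- gam / qq
    x <- x + alpha * p
    r <- r - alpha * q
    s <- as.numeric(crossprod(A, r))
    gam_new <- sum(s^2)
    p <- s + (gam_new / gam) * p
    gam <- gam_new
    it <- it + 1L
    rn <- sqrt(sum(r^2))
    if (is.finite(rn) && rn < best_rn) {
      best_rn <- rn; best_x <- x
    } else if (!is.finite(rn) || rn > 2 * best_rn) {
      break
    }
  }
  list(x = best_x, iterations = it, residual = best_rn)
}

# Projected CGLS rounds on the nonnegative cone: each round identifies the
# free set (positive entries plus zero entries whose gradient is negative,
# i.e. would become positive), runs CGLS restricted to it, and projects.
# This is the gradient-projection CG scheme for bound-constrained least
# squares; it converges towards the nonnegative LS solution, which for an
# all-positive sensitivity matrix is naturally sparse and has bounded
# coefficients (no sign-cancellation blow-up).
nn_cgls_rounds <- function(A, y, support, inner, rounds, tol) {
  z <- numeric(ncol(A))
  total_it <- 0L
  residual <- sqrt(sum(y^2))
  for (r in seq_len(rounds)) {
    g <- as.numeric(crossprod(A, as.numeric(A %*% z) - y))
    free <- support[z[support] > 0 | g[support] < 0]
    if (!length(free)) break
    fit <- cgls(A[, free, drop = FALSE], y, x0 = z[free],
                maxit = inner, tol = tol)
    z[] <- 0
    z[free] <- pmax(fit$x, 0)
    total_it <- total_it + fit$iterations
    residual <- sqrt(sum((y - as.numeric(A %*% z))^2))
  }
  list(z = z, iterations = total_it, residual = residual)
}

#' Sparsity-promoting conjugate-gradient inversion
#'
#' Solves the underdetermined linear BLT system \code{A x = y} for a sparse
#' nonnegative source vector. Columns are first scaled to unit norm
#' (compensating the strong depth dependence of the sensitivity scale);
#' the normalised system is then solved by nonnegativity-constrained CGLS
#' (gradient-projection rounds: CG on the free variables, projection onto
#' \code{x >= 0}), which for an all-positive matrix yields a naturally
#' sparse, bounded solution. Finally, entries below
#' \code{keep_fraction * max(x)} are discarded and the constrained solve is
#' repeated on the surviving support, concentrating the reconstruction on
#' the dominant source nodes; the result is un-normalised back to
#' intensities.
#'
#' @param A measurement matrix (M x N), e.g. a (truncated) Jacobian.
#' @param y measurement vector (length M) or \code{blt_measurements}.
#' @param options a \code{cscg_options} list.
#' @return list with \code{x} (length N, >= 0), \code{iterations} (total CG
#'   iterations), \code{residual} (final residual norm on the normalised
#'   system), \code{support_size}, \code{rounds} and \code{dropped_columns}
#'   (indices of all-zero columns, excluded with a warning).
#' @export
cscg_solve <- function(A, y, options = cscg_options()) {
  y <- measurement_vector(y)
  A <- jacobian_matrix(A)
  if (nrow(A) != length(y))
    stop(sprintf("measurement length %d does not match matrix rows %d", length(y), nrow(A)))
  n <- ncol(A)
  cn <- sqrt(.colSums(A^2, nrow(A), n))
  dropped <- which(cn == 0)
  if (length(dropped)) {
    warning(sprintf("dropping %d zero column(s) from the system", length(dropped)))
  }
  active0 <- which(cn > 0)
  An <- if (isTRUE(options$normalize_columns)) {
    sweep(A[, active0, drop = FALSE], 2, cn[active0], "/")
  } else {
    A[, active0, drop = FALSE]
  }

  if (all(y == 0) || !length(active0)) {
    return(list(x = numeric(n), iterations = 0L, residual = sqrt(sum(y^2)),
                support_size = 0L, rounds = 0L, dropped_columns = dropped))
  }

  fit <- nn_cgls_rounds(An, y, seq_along(active0),
                        options$inner_iterations, options$outer_rounds,
                        options$tol)
  z <- fit$z
  total_it <- fit$iterations
  residual <- fit$residual
  rounds <- options$outer_rounds
  mx <- max(z)
  if (mx > 0) {
    keep <- which(z > options$keep_fraction * mx)
    if (length(keep) && length(keep) < sum(z > 0)) {
      refit <- nn_cgls_rounds(An, y, keep,
                              options$inner_iterations, options$outer_rounds,
                              options$tol)
      z <- refit$z
      total_it <- total_it + refit$iterations
      residual <- refit$residual
      rounds <- rounds + options$outer_rounds
    } else {
      z[setdiff(which(z > 0), keep)] <- 0
    }
  }
  x <- numeric(n)
  x[active0] <- z / (if (isTRUE(options$normalize_columns)) cn[active0] else 1)
  list(x = x, iterations = total_it, residual = residual,
       support_size = sum(x > 0), rounds = rounds, dropped_columns = dropped)
}

#' Fit a bioluminescence source reconstruction
#'
#' The central fitting function: reconstructs the nodal source intensity
#' vector from boundary measurements under one of three support strategies:
#' \describe{
#'   \item{\code{"whole"}}{all mesh nodes are free (no permissible region);}
#'   \item{\code{"large_pr"}}{a conventional permissible region limited only
#'     laterally (no depth limit) around \code{center_xy};}
#'   \item{\code{"us_guided"}}{the ultrasound-guided, model-driven region:
#'     the node nearest \code{us_position} is the reference node and only
#'     nodes with total sensitivity within a factor \code{d} of its own are
#'     free.}
#' }
#' The same sparsity-promoting conjugate-gradient solver is used in every
#' case, so differences between methods isolate the effect of the region.
#'
#' @param jacobian a \code{blt_jacobian}.
#' @param measurements a \code{blt_measurements} or numeric vector.
#' @param method reconstruction strategy (see above).
#' @param mesh the \code{blt_mesh} (required for \code{"large_pr"} and
#'   \code{"us_guided"}).
#' @param us_position guide coordinate (mm), required for
#'   \code{"us_guided"}.
#' @param d dynamic range of the guided region (default 3).
#' @param center_xy lateral centre (mm), required for \code{"large_pr"}.
#' @param half_width lateral half width of the large region (mm, default
#'   7.5).
#' @param options solver options from \code{cscg_options()}.
#' @return object of class \code{blt_recon}: the fitted reconstruction, with
#'   components \code{x_hat} (full-length nodal intensities, zero outside
#'   the region), \code{region}, \code{solver_stats}, \code{fitted.values}
#'   (\code{J x_hat}), \code{residuals} and \code{method}.
#' @seealso \code{\link{cscg_solve}}, \code{\link{us_guided_region}},
#'   \code{\link{recon_metrics}}
#' @examples
#' \dontrun{
#' tb <- slab_testbed(spacing = 4, det_pitch = 5)
#' fit <- blt_reconstruct(tb$jacobian, tb$y0, method = "us_guided",
#'                        mesh = tb$mesh, us_position = c(0, 0, 5), d = 3)
#' summary(fit)
#' }
#' @export
blt_reconstruct <- function(jacobian, measurements,
                            method = c("us_guided", "whole", "large_pr"),
                            mesh = NULL, us_position = NULL, d = 3,
                            center_xy = NULL, half_width = 7.5,
                            options = cscg_options()) {
  method <- match.arg(method)
  y <- measurement_vector(measurements)
  region <- switch(method,
    whole = {
      if (!is.null(mesh)) whole_mesh_region(mesh)
      else new_region("whole", seq_len(ncol(jacobian_matrix(jacobian))))
    },
    large_pr = {
      if (is.null(mesh) || is.null(center_xy))
        stop("method \"large_pr\" requires `mesh` and `center_xy`")
      large_pr_region(mesh, center_xy, half_width)
    },
    us_guided = {
      if (is.null(mesh) || is.null(us_position))
        stop("method \"us_guided\" requires `mesh` and `us_position`")
      us_guided_region(mesh, total_sensitivity(jacobian), us_position, d)
    })
  tr <- truncate_jacobian(jacobian, region)
  fit <- cscg_solve(tr$J, y, options)
  x_hat <- numeric(ncol(jacobian_matrix(jacobian)))
  x_hat[tr$columns] <- fit$x
  fitted <- as.numeric(jacobian_matrix(jacobian) %*% x_hat)
  structure(list(x_hat = x_hat, region = region,
                 solver_stats = fit[c("iterations", "residual", "support_size",
                                      "rounds", "dropped_columns")],
                 method = method, d = if (method == "us_guided") d else NA_real_,
                 y = y, fitted.values = fitted, residuals = y - fitted,
                 n_nodes = length(x_hat), call = match.call()),
            class = "blt_recon")
}

#' @export
print.blt_recon <- function(x, ...) {
  cat(sprintf("blt_recon (%s): %d of %d nodes in region, %d with nonzero intensity\n",
              x$method, length(x$region$noi), x$n_nodes, sum(x$x_hat > 0)))
  cat(sprintf("  max intensity %.4g a.u., residual norm %.4g (%d CG iterations)\n",
              max(x$x_hat), x$solver_stats$residual, x$solver_stats$iterations))
  invisible(x)
}

#' @export
summary.blt_recon <- function(object, ...) {
  s <- list(method = object$method,
            d = object$d,
            region_size = length(object$region$noi),
            n_nodes = object$n_nodes,
            support_size = sum(object$x_hat > 0),
            max_intensity = max(object$x_hat),
            total_intensity = sum(object$x_hat),
            residual = object$solver_stats$residual,
            iterations = object$solver_stats$iterations,
            relative_misfit = sqrt(sum(object$residuals^2) / sum(object$y^2)))
  class(s) <- "summary.blt_recon"
  s
}

#' @export
print.summary.blt_recon <- function(x, ...) {
  cat(sprintf("Reconstruction method: %s%s\n", x$method,
              if (!is.na(x$d)) sprintf(" (dynamic range %g)", x$d) else ""))
  cat(sprintf("  permissible region: %d / %d nodes\n", x$region_size, x$n_nodes))
  cat(sprintf("  nonzero nodes: %d, max intensity %.4g, total %.4g a.u.\n",
              x$support_size, x$max_intensity, x$total_intensity))
  cat(sprintf("  data misfit: %.3g (relative), %d CG iterations\n",
              x$relative_misfit, x$iterations))
  invisible(x)
}

#' @export
coef.blt_recon <- function(object, ...) object$x_hat

#' @export
fitted.blt_recon <- function(object, ...) object$fitted.values

#' @export
residuals.blt_recon <- function(object, ...) object$residuals

#' Depth profile of a fitted reconstruction
#'
#' Plots the maximum reconstructed intensity in each constant-z node plane
#' against depth, a quick check of depth localisation.
#'
#' @param x a \code{blt_recon}.
#' @param mesh the mesh the reconstruction lives on.
#' @param ... passed to \code{plot}.
#' @export
plot.blt_recon <- function(x, mesh, ...) {
  if (missing(mesh)) stop("plot.blt_recon needs the `mesh` the fit lives on")
  z <- mesh$nodes[, 3]
  zs <- sort(unique(z))
  prof <- vapply(zs, function(zz) max(x$x_hat[abs(z - zz) < 1e-9]), numeric(1))
  graphics::plot(zs, prof, type = "b", xlab = "z (mm)",
                 ylab = "max intensity (a.u.)",
                 main = sprintf("Depth profile (%s)", x$method), ...)
  invisible(x)
}
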