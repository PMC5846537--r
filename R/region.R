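# Permissible-region construction: total sensitivity, dynamic-range node
# selection around an ultrasound-derived reference node, and Jacobian
# truncation. This is the model-driven part of the guided reconstruction:
# nodes whose total sensitivity is within a factor d of the reference
# node's form the nodes of interest (NOI); everything else is fixed at zero.

#' Total nodal sensitivity
#'
#' \eqn{s_n = \sum_j J_{j,n}} over all stacked measurements (all detectors
#' and wavelengths).
#'
#' @param jacobian a \code{blt_jacobian} or plain matrix.
#' @return object of class \code{blt_sensitivity}: list with per-node vector
#'   \code{s} and \code{positive_floor}, the smallest positive entry.
#' @export
total_sensitivity <- function(jacobian) {
  J <- jacobian_matrix(jacobian)
  s <- colSums(J)
  pos <- s[s > 0]
  structure(list(s = s,
                 positive_floor = if (length(pos)) min(pos) else NA_real_),
            class = "blt_sensitivity")
}

sensitivity_vector <- function(s) {
  if (inherits(s, "blt_sensitivity")) s$s else as.numeric(s)
}

#' Dynamic range of a sensitivity profile
#'
#' Ratio of the largest to the smallest strictly positive total sensitivity;
#' zero-sensitivity nodes are excluded (their log-range is unbounded).
#'
#' @param s a \code{blt_sensitivity} or numeric vector.
#' @return scalar >= 1.
#' @export
dynamic_range_of <- function(s) {
  sv <- sensitivity_vector(s)
  pos <- sv[sv > 0]
  if (!length(pos)) stop("all sensitivities are zero; dynamic range undefined")
  max(pos) / min(pos)
}

#' Select the nodes of interest for a dynamic range
#'
#' Nodes whose sensitivity lies in the inclusive interval
#' \eqn{[s_0/d, s_0 d]} around the reference node's sensitivity \eqn{s_0}.
#'
#' @param s a \code{blt_sensitivity} or numeric vector.
#' @param reference_node index of the reference node.
#' @param d dynamic range, >= 1.
#' @return sorted integer vector of node indices (always contains
#'   \code{reference_node}).
#' @export
select_noi <- function(s, reference_node, d) {
  sv <- sensitivity_vector(s)
  if (reference_node < 1 || reference_node > length(sv))
    stop("reference node out of range")
  if (!is.finite(d) || d < 1) stop("dynamic range `d` must be >= 1")
  s0 <- sv[reference_node]
  if (s0 <= 0)
    stop("reference node has zero sensitivity; the guide point lies outside the model's sensitive volume")
  which(sv >= s0 / d & sv <= s0 * d)
}

new_region <- function(method_tag, noi, reference_node = NA_integer_,
                       d = NA_real_, us_position = NULL, extra = list()) {
  if (!length(noi)) stop("permissible region is empty")
  structure(c(list(method_tag = method_tag, noi = sort(as.integer(noi)),
                   reference_node = reference_node, d = d,
                   us_position = us_position), extra),
            class = "blt_region")
}

#' @export
print.blt_region <- function(x, ...) {
  cat(sprintf("blt_region [%s]: %d nodes", x$method_tag, length(x$noi)))
  if (!is.na(x$d)) cat(sprintf(", dynamic range %g", x$d))
  if (!is.na(x$reference_node)) cat(sprintf(", reference node %d", x$reference_node))
  cat("\n")
  invisible(x)
}

#' Ultrasound-guided, model-driven permissible region
#'
#' The mesh node closest to the supplied guide coordinate (e.g. a source
#' position read from an ultrasound image) becomes the reference node; the
#' region is the set of nodes whose total sensitivity is within a factor
#' \code{d} of the reference node's.
#'
#' @param mesh a \code{blt_mesh}.
#' @param s a \code{blt_sensitivity} (from \code{total_sensitivity}).
#' @param us_position guide coordinate \code{c(x0, y0, z0)} in mm; must lie
#'   inside the mesh bounding box.
#' @param d dynamic range, >= 1.
#' @return a \code{blt_region} with \code{method_tag = "us_guided"}.
#' @export
us_guided_region <- function(mesh, s, us_position, d) {
  lim <- apply(mesh$nodes, 2, range)
  if (any(us_position < lim[1, ] - 1e-9) || any(us_position > lim[2, ] + 1e-9))
    stop("`us_position` lies outside the mesh bounding box")
  ref <- nearest_node(mesh, us_position)
  noi <- select_noi(s, ref, d)
  new_region("us_guided", noi, reference_node = ref, d = d,
             us_position = as.numeric(us_position))
}

#' Large permissible region (laterally limited, no depth limit)
#'
#' Conventional comparator region: a box constraint on the two in-plane
#' coordinates only, leaving the depth axis unconstrained.
#'
#' @param mesh a \code{blt_mesh}.
#' @param center_xy in-plane centre \code{c(x0, y0)} in mm.
#' @param half_width lateral half width in mm.
#' @return a \code{blt_region} with \code{method_tag = "large_pr"}.
#' @export
large_pr_region <- function(mesh, center_xy, half_width) {
  noi <- which(abs(mesh$nodes[, 1] - center_xy[1]) <= half_width + 1e-9 &
               abs(mesh$nodes[, 2] - center_xy[2]) <= half_width + 1e-9)
  if (!length(noi)) stop("large permissible region selects no nodes")
  new_region("large_pr", noi,
             extra = list(center_xy = as.numeric(center_xy), half_width = half_width))
}

#' Whole-mesh (unconstrained) region
#'
#' @param mesh a \code{blt_mesh}.
#' @return a \code{blt_region} containing every node.
#' @export
whole_mesh_region <- function(mesh) {
  new_region("whole", seq_len(nrow(mesh$nodes)))
}

#' Truncate a Jacobian to a permissible region
#'
#' Restricts the Jacobian columns to the region's nodes of interest,
#' keeping the map back to global node indices. Solving on the truncated
#' matrix is equivalent to constraining the emitted intensity of every
#' outside node to zero.
#'
#' @param jacobian a \code{blt_jacobian} or plain matrix.
#' @param region a \code{blt_region}.
#' @return list with matrix \code{J} (M x |NOI|) and integer \code{columns}
#'   (global node index of each retained column).
#' @export
truncate_jacobian <- function(jacobian, region) {
  J <- jacobian_matrix(jacobian)
  noi <- region$noi
  if (any(noi < 1 | noi > ncol(J))) stop("region refers to nodes outside the Jacobian")
  list(J = J[, noi, drop = FALSE], columns = noi)
}

#' Convert an ultrasound-reported source depth to a permissible-region depth
#'
#' An ultrasound scan reports the source position as a distance from the
#' imaged face. When the optical detectors sit on the opposite face of a
#' slab of thickness \code{Lz}, the depth below the detector face is
#' \code{Lz - z_us}; when they share the imaged face it is \code{z_us}
#' itself (e.g. a 20 mm slab imaged at 15.5 mm gives a region depth of
#' 4.5 mm from the far face).
#'
#' @param z_us reported source distance from the imaged face (mm).
#' @param thickness slab thickness \code{Lz} (mm).
#' @param detectors_on \code{"opposite"} (default) or \code{"same"}: which
#'   face the optical detectors occupy relative to the ultrasound probe.
#' @return depth of the permissible-region centre below the detector face (mm).
#' @export
us_depth_to_pr_depth <- function(z_us, thickness, detectors_on = c("opposite", "same")) {
  detectors_on <- match.arg(detectors_on)
  if (z_us < 0 || z_us > thickness) stop("`z_us` must lie within the slab thickness")
  if (detectors_on == "opposite") thickness - z_us else z_us
}
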