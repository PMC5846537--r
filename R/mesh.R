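#' Build a structured tetrahedral slab mesh
#'
#' Discretises a rectangular slab on a regular node grid and splits every
#' grid cube into six tetrahedra (Kuhn triangulation with a common main
#' diagonal, so faces of neighbouring cubes match). The slab occupies
#' \code{x} in \code{[-Lx/2, Lx/2]}, \code{y} in \code{[-Ly/2, Ly/2]} and
#' \code{z} in \code{[0, Lz]}; detectors conventionally sit on the top face
#' \code{z = Lz}, so a source "depth" is \code{Lz - z}.
#'
#' @param dimensions numeric length-3, slab extents \code{c(Lx, Ly, Lz)} in mm.
#' @param spacing nominal inter-node distance in mm; every dimension must be
#'   an integral multiple of it.
#' @return An object of class \code{blt_mesh}: a list with \code{nodes}
#'   (N x 3 matrix, mm), \code{elements} (E x 4 integer matrix, 1-based),
#'   \code{region} (integer per-node region label, all 1 for a homogeneous
#'   slab), \code{spacing} and \code{dimensions}.
#' @examples
#' m <- build_slab_mesh(c(10, 10, 10), 5)
#' nrow(m$nodes)  # 27
#' @export
build_slab_mesh <- function(dimensions, spacing) {
  if (length(dimensions) != 3 || !all(is.finite(dimensions)) || any(dimensions <= 0))
    stop("`dimensions` must be three positive extents (mm)")
  if (!is.finite(spacing) || spacing <= 0)
    stop("`spacing` must be a positive distance (mm)")
  ncell <- dimensions / spacing
  for (ax in 1:3) {
    if (abs(ncell[ax] - round(ncell[ax])) > 1e-9)
      stop(sprintf("dimension along the %s axis (%g mm) is not an integral multiple of spacing %g mm",
                   c("x", "y", "z")[ax], dimensions[ax], spacing))
  }
  ncell <- as.integer(round(ncell))
  nx <- ncell[1] + 1L; ny <- ncell[2] + 1L; nz <- ncell[3] + 1L
  xs <- seq(-dimensions[1] / 2, dimensions[1] / 2, length.out = nx)
  ys <- seq(-dimensions[2] / 2, dimensions[2] / 2, length.out = ny)
  zs <- seq(0, dimensions[3], length.out = nz)
  nodes <- cbind(
    x = rep(xs, times = ny * nz),
    y = rep(rep(ys, each = nx), times = nz),
    z = rep(zs, each = nx * ny)
  )

  # cell corner ids; node id = i + (j-1)*nx + (k-1)*nx*ny
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  id <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  n000 <- id(ci,      cj,      ck)
  n100 <- id(ci + 1L, cj,      ck)
  n010 <- id(ci,      cj + 1L, ck)
  n110 <- id(ci + 1L, cj + 1L, ck)
  n001 <- id(ci,      cj,      ck + 1L)
  n101 <- id(ci + 1L, cj,      ck + 1L)
  n011 <- id(ci,      cj + 1L, ck + 1L)
  n111 <- id(ci + 1L, cj + 1L, ck + 1L)

  # six Kuhn tetrahedra per cube, all sharing the 000-111 diagonal
  elements <- rbind(
    cbind(n000, n100, n110, n111),
    cbind(n000, n100, n101, n111),
    cbind(n000, n010, n110, n111),
    cbind(n000, n010, n011, n111),
    cbind(n000, n001, n101, n111),
    cbind(n000, n001, n011, n111)
  )
  storage.mode(elements) <- "integer"
  dimnames(elements) <- NULL

  structure(
    list(nodes = nodes, elements = elements,
         region = rep(1L, nrow(nodes)),
         spacing = spacing, dimensions = as.numeric(dimensions)),
    class = "blt_mesh"
  )
}

#' @export
print.blt_mesh <- function(x, ...) {
  cat(sprintf("blt_mesh: %d nodes, %d tetrahedra\n", nrow(x$nodes), nrow(x$elements)))
  cat(sprintf("  slab %g x %g x %g mm, spacing %g mm, %d region(s)\n",
              x$dimensions[1], x$dimensions[2], x$dimensions[3],
              x$spacing, length(unique(x$region))))
  invisible(x)
}

#' Signed-free volumes of all tetrahedral elements
#'
#' @param mesh a \code{blt_mesh}.
#' @return numeric vector of element volumes (mm^3), all positive for a
#'   non-degenerate mesh.
#' @export
element_volumes <- function(mesh) {
  el <- mesh$elements; nd <- mesh$nodes
  a <- nd[el[, 1], , drop = FALSE]
  v1 <- nd[el[, 2], , drop = FALSE] - a
  v2 <- nd[el[, 3], , drop = FALSE] - a
  v3 <- nd[el[, 4], , drop = FALSE] - a
  det3 <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
          v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
          v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  abs(det3) / 6
}

#' Lumped nodal volumes
#'
#' Each tetrahedron contributes a quarter of its volume to each of its four
#' vertices (the row sum of the lumped finite-element mass matrix). The
#' resulting per-node volumes are what the volume-weighted reconstruction
#' metrics use for the size of a node set.
#'
#' @param mesh a \code{blt_mesh}.
#' @return numeric vector of length \code{nrow(mesh$nodes)}, mm^3; sums to
#'   the total mesh volume.
#' @export
node_volumes <- function(mesh) {
  vol <- element_volumes(mesh)
  idx <- as.vector(mesh$elements)
  w <- rep(vol / 4, times = 4)
  out <- numeric(nrow(mesh$nodes))
  acc <- rowsum(w, group = idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Index of the mesh node nearest to a point
#'
#' Euclidean nearest neighbour with a deterministic tie-break: the lowest
#' node index wins.
#'
#' @param mesh a \code{blt_mesh}.
#' @param point numeric length-3 coordinate (mm).
#' @return integer node index.
#' @export
nearest_node <- function(mesh, point) {
  if (length(point) != 3 || !all(is.finite(point)))
    stop("`point` must be a finite 3D coordinate")
  if (is.null(mesh$nodes) || nrow(mesh$nodes) == 0)
    stop("mesh has no nodes")
  d2 <- (mesh$nodes[, 1] - point[1])^2 +
        (mesh$nodes[, 2] - point[2])^2 +
        (mesh$nodes[, 3] - point[3])^2
  which.min(d2)  # which.min returns the first (lowest) index on ties
}

face_axis <- function(face) {
  switch(face,
         "z+" = , "z-" = 3L,
         "y+" = , "y-" = 2L,
         "x+" = , "x-" = 1L,
         stop("`face` must be one of x+, x-, y+, y-, z+, z-"))
}

face_coordinate <- function(mesh, face) {
  ax <- face_axis(face)
  lim <- range(mesh$nodes[, ax])
  if (substr(face, 2, 2) == "+") lim[2] else lim[1]
}

#' Place a rectangular detector grid on a slab face
#'
#' @param mesh a \code{blt_mesh}.
#' @param extent numeric length-2 grid extent \code{c(w, h)} in mm; an extent
#'   of \code{c(0, 0)} places a single detector at \code{center}.
#' @param pitch grid spacing in mm.
#' @param face boundary plane, one of \code{"z+"} (default; \code{z = Lz}),
#'   \code{"z-"}, \code{"x+"}, \code{"x-"}, \code{"y+"}, \code{"y-"}.
#' @param center in-plane centre of the grid (mm), default the face centre.
#' @return An object of class \code{blt_detectors}: list with
#'   \code{positions} (n x 3 matrix, mm), \code{face}, \code{pitch},
#'   \code{extent}.
#' @examples
#' m <- build_slab_mesh(c(40, 40, 20), 2)
#' d <- place_detector_grid(m, c(30, 30), 0.75)
#' nrow(d$positions)  # 1681
#' @export
place_detector_grid <- function(mesh, extent, pitch, face = "z+", center = NULL) {
  if (length(extent) != 2 || any(extent < 0)) stop("`extent` must be two nonnegative lengths (mm)")
  if (!is.finite(pitch) || pitch <= 0) stop("`pitch` must be positive (mm)")
  ax <- face_axis(face)
  inplane <- setdiff(1:3, ax)
  if (is.null(center)) {
    center <- c(mean(range(mesh$nodes[, inplane[1]])),
                mean(range(mesh$nodes[, inplane[2]])))
  }
  grid_1d <- function(c0, w) {
    n <- floor(w / pitch + 1 + 1e-9)
    c0 + ((seq_len(n) - 1) * pitch) - (n - 1) * pitch / 2
  }
  u <- grid_1d(center[1], extent[1])
  v <- grid_1d(center[2], extent[2])
  for (k in 1:2) {
    lim <- range(mesh$nodes[, inplane[k]])
    uv <- if (k == 1) u else v
    if (min(uv) < lim[1] - 1e-9 || max(uv) > lim[2] + 1e-9)
      stop(sprintf("detector grid exceeds the %s bounds of face %s",
                   c("x", "y", "z")[inplane[k]], face))
  }
  pos <- matrix(0, nrow = length(u) * length(v), ncol = 3)
  pos[, inplane[1]] <- rep(u, times = length(v))
  pos[, inplane[2]] <- rep(v, each = length(u))
  pos[, ax] <- face_coordinate(mesh, face)
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos, face = face, pitch = pitch,
                 extent = as.numeric(extent)),
            class = "blt_detectors")
}

#' @export
print.blt_detectors <- function(x, ...) {
  cat(sprintf("blt_detectors: %d detectors on face %s (%g x %g mm grid, pitch %g mm)\n",
              nrow(x$positions), x$face, x$extent[1], x$extent[2], x$pitch))
  invisible(x)
}
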