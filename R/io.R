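# Plain-text persistence: NIRFAST-style node/element mesh files, detector
# and measurement CSVs, region and reconstruction dumps, a minimal legacy
# VTK exporter and run manifests.

#' Write a mesh to node and element text files
#'
#' Node file: a header line with the node count, then one
#' \code{x y z region} line per node. Element file: a header line with the
#' element count, then one \code{i j k l} line (1-based node indices) per
#' tetrahedron. Coordinates are printed with full double precision so a
#' write/read roundtrip is exact.
#'
#' @param mesh a \code{blt_mesh}.
#' @param node_file,element_file output paths.
#' @export
write_mesh <- function(mesh, node_file, element_file) {
  nd <- mesh$nodes
  lines <- c(sprintf("%d", nrow(nd)),
             sprintf("%.17g %.17g %.17g %d", nd[, 1], nd[, 2], nd[, 3], mesh$region))
  writeLines(lines, node_file)
  el <- mesh$elements
  lines <- c(sprintf("%d", nrow(el)),
             sprintf("%d %d %d %d", el[, 1], el[, 2], el[, 3], el[, 4]))
  writeLines(lines, element_file)
  invisible(c(node_file, element_file))
}

parse_numeric_line <- function(line, n_expected, file, lineno, what = "numeric") {
  parts <- strsplit(trimws(line), "\\s+")[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) != n_expected || any(is.na(vals)))
    stop(sprintf("malformed %s line %d in %s: \"%s\"", what, lineno, file, line))
  vals
}

#' Read a mesh from node and element text files
#'
#' @param node_file,element_file paths written by \code{write_mesh} (or in
#'   the same format).
#' @param spacing optional nominal node spacing to record; inferred from
#'   the smallest inter-node coordinate step if missing.
#' @return a \code{blt_mesh}.
#' @export
read_mesh <- function(node_file, element_file, spacing = NULL) {
  nl <- readLines(node_file)
  if (!length(nl)) stop("empty node file")
  n <- suppressWarnings(as.integer(nl[1]))
  if (is.na(n) || n < 1 || length(nl) < n + 1)
    stop(sprintf("bad node file header or truncated file: %s", node_file))
  nodes <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  region <- integer(n)
  for (i in seq_len(n)) {
    v <- parse_numeric_line(nl[i + 1], 4, node_file, i + 1, "node")
    nodes[i, ] <- v[1:3]; region[i] <- as.integer(v[4])
  }
  el <- readLines(element_file)
  if (!length(el)) stop("empty element file")
  ne <- suppressWarnings(as.integer(el[1]))
  if (is.na(ne) || ne < 1 || length(el) < ne + 1)
    stop(sprintf("element file has no elements or a bad header: %s", element_file))
  elements <- matrix(0L, ne, 4)
  for (i in seq_len(ne)) {
    v <- parse_numeric_line(el[i + 1], 4, element_file, i + 1, "element")
    if (any(v != round(v)) || any(v < 1) || any(v > n))
      stop(sprintf("element line %d in %s references node index outside 1..%d",
                   i + 1, element_file, n))
    elements[i, ] <- as.integer(v)
  }
  if (is.null(spacing)) {
    ux <- sort(unique(nodes[, 1]))
    spacing <- if (length(ux) > 1) min(diff(ux)) else 1
  }
  dims <- apply(nodes, 2, function(v) diff(range(v)))
  structure(list(nodes = nodes, elements = elements, region = region,
                 spacing = spacing, dimensions = as.numeric(dims)),
            class = "blt_mesh")
}

#' Write detector positions to CSV
#' @param detectors a \code{blt_detectors}.
#' @param file output path.
#' @export
write_detectors <- function(detectors, file) {
  utils::write.csv(as.data.frame(detectors$positions), file, row.names = FALSE)
  invisible(file)
}

#' Write measurements to CSV with a JSON provenance sidecar
#'
#' CSV columns: \code{detector_id}, \code{wavelength_nm}, \code{value}.
#' The sidecar (\code{<file>.json}) records the noise provenance.
#'
#' @param measurements a \code{blt_measurements}.
#' @param jacobian the \code{blt_jacobian} that produced them (for the
#'   detector/wavelength row map).
#' @param file output CSV path.
#' @export
write_measurements <- function(measurements, jacobian, file) {
  df <- jacobian$row_map
  df$value <- measurement_vector(measurements)
  names(df)[names(df) == "detector"] <- "detector_id"
  names(df)[names(df) == "wavelength"] <- "wavelength_nm"
  utils::write.csv(df[, c("detector_id", "wavelength_nm", "value")], file,
                   row.names = FALSE)
  jsonlite::write_json(measurements$provenance, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read measurements written by \code{write_measurements}
#' @param file CSV path.
#' @return a \code{blt_measurements}.
#' @export
read_measurements <- function(file) {
  df <- utils::read.csv(file)
  prov_file <- paste0(file, ".json")
  prov <- if (file.exists(prov_file)) jsonlite::read_json(prov_file, simplifyVector = TRUE)
          else list(noise = "unknown")
  structure(list(y = df$value, wavelengths = unique(df$wavelength_nm),
                 provenance = prov),
            class = "blt_measurements")
}

#' Persist a permissible region as JSON
#' @param region a \code{blt_region}.
#' @param file output path.
#' @export
write_region <- function(region, file) {
  jsonlite::write_json(list(method_tag = region$method_tag,
                            us_position = region$us_position,
                            d = region$d,
                            reference_node = region$reference_node,
                            noi = region$noi),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a permissible region written by \code{write_region}
#' @param file JSON path.
#' @return a \code{blt_region}.
#' @export
read_region <- function(file) {
  r <- jsonlite::read_json(file, simplifyVector = TRUE)
  new_region(r$method_tag, r$noi,
             reference_node = if (is.null(r$reference_node)) NA_integer_ else r$reference_node,
             d = if (is.null(r$d)) NA_real_ else r$d,
             us_position = r$us_position)
}

#' Write a reconstruction to CSV plus a solver-stats JSON sidecar
#' @param recon a \code{blt_recon}.
#' @param file output CSV path (\code{node_id}, \code{x_hat}).
#' @export
write_recon <- function(recon, file) {
  utils::write.csv(data.frame(node_id = seq_along(recon$x_hat), x_hat = recon$x_hat),
                   file, row.names = FALSE)
  jsonlite::write_json(c(list(method = recon$method, d = recon$d),
                         recon$solver_stats),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' Export a mesh (with optional nodal data) as legacy ASCII VTK
#'
#' Minimal unstructured-grid writer for visual inspection in ParaView and
#' similar tools.
#'
#' @param mesh a \code{blt_mesh}.
#' @param file output path.
#' @param point_data optional named list of per-node numeric vectors.
#' @export
write_vtk <- function(mesh, file, point_data = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  nd <- mesh$nodes; el <- mesh$elements
  writeLines(c("# vtk DataFile Version 3.0", "usblt mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nd))), con)
  writeLines(sprintf("%g %g %g", nd[, 1], nd[, 2], nd[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(el), nrow(el) * 5), con)
  writeLines(sprintf("4 %d %d %d %d", el[, 1] - 1L, el[, 2] - 1L,
                     el[, 3] - 1L, el[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(rep("10", nrow(el)), con)
  if (!is.null(point_data) && length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(nd)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%g", point_data[[nm]]), con)
    }
  }
  invisible(file)
}

#' Write a run manifest
#'
#' Records tool version, the exact arguments, seeds and MD5 digests of any
#' declared input files, so every output is attributable to its inputs.
#'
#' @param file output JSON path.
#' @param args named list of run arguments.
#' @param inputs character vector of input file paths to digest.
#' @param seed integer seed (or NULL).
#' @export
write_manifest <- function(file, args = list(), inputs = character(0), seed = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  jsonlite::write_json(list(tool = "usblt",
                            version = as.character(utils::packageVersion("usblt")),
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                            seed = seed, args = args, input_digests = digests),
                       file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
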