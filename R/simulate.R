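# Synthetic-data generation and experiment drivers: paint geometric sources
# onto the mesh, add SNR-specified Gaussian noise, run paired-noise trials
# of the three reconstruction strategies, sweep the permissible-region
# dynamic range, and the two-source separation study.

#' Describe a geometric bioluminescent source
#'
#' @param shape \code{"cylinder"} or \code{"sphere"}.
#' @param center centre (mm).
#' @param radius radius (mm), > 0.
#' @param height cylinder length (mm); ignored for spheres.
#' @param axis cylinder axis, \code{"x"}, \code{"y"} or \code{"z"}.
#' @param intensity emitted intensity per source node (a.u.), > 0.
#' @return list of class \code{blt_source}.
#' @export
blt_source <- function(shape = c("cylinder", "sphere"), center, radius,
                       height = NULL, axis = "z", intensity = 10) {
  shape <- match.arg(shape)
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be > 0")
  if (!is.finite(intensity) || intensity <= 0) stop("`intensity` must be > 0")
  if (shape == "cylinder" && (is.null(height) || height <= 0))
    stop("a cylinder source needs a positive `height`")
  structure(list(shape = shape, center = as.numeric(center), radius = radius,
                 height = height, axis = axis, intensity = intensity),
            class = "blt_source")
}

source_membership <- function(mesh, spec) {
  nd <- mesh$nodes
  if (spec$shape == "sphere") {
    d2 <- (nd[, 1] - spec$center[1])^2 + (nd[, 2] - spec$center[2])^2 +
          (nd[, 3] - spec$center[3])^2
    d2 <= spec$radius^2 + 1e-12
  } else {
    ax <- match(spec$axis, c("x", "y", "z"))
    if (is.na(ax)) stop("cylinder `axis` must be x, y or z")
    off <- setdiff(1:3, ax)
    r2 <- (nd[, off[1]] - spec$center[off[1]])^2 + (nd[, off[2]] - spec$center[off[2]])^2
    r2 <= spec$radius^2 + 1e-12 &
      abs(nd[, ax] - spec$center[ax]) <= spec$height / 2 + 1e-9
  }
}

#' Paint sources onto the mesh
#'
#' Nodes whose coordinates fall inside a source shape (node-centre
#' inclusion) are tagged with that source's intensity; overlapping sources
#' add. It is an error for a source to contain no node (the source is
#' smaller than the mesh resolution can represent).
#'
#' @param mesh a \code{blt_mesh}.
#' @param sources a \code{blt_source} or list of them.
#' @return nodal intensity vector \code{x_true} (length N).
#' @export
paint_source <- function(mesh, sources) {
  if (inherits(sources, "blt_source")) sources <- list(sources)
  x <- numeric(nrow(mesh$nodes))
  for (k in seq_along(sources)) {
    inside <- source_membership(mesh, sources[[k]])
    if (!any(inside))
      stop(sprintf("source %d contains no mesh node (smaller than the mesh resolution)", k))
    x[inside] <- x[inside] + sources[[k]]$intensity
  }
  x
}

#' Add SNR-specified Gaussian noise to measurements
#'
#' Default convention: per-measurement amplitude-proportional noise,
#' \eqn{y_i' = y_i + \epsilon_i} with
#' \eqn{\epsilon_i \sim N(0, (|y_i|\,10^{-SNR/20})^2)}. The alternative
#' \code{"global_rms"} convention uses a single noise level
#' \eqn{\sigma = rms(y)\,10^{-SNR/20}} for all measurements. Fully
#' deterministic given the seed; an infinite SNR returns the data
#' unchanged.
#'
#' @param measurements a \code{blt_measurements} or numeric vector.
#' @param snr_db signal-to-noise ratio in dB (may be \code{Inf}).
#' @param seed integer seed recorded in the provenance.
#' @param convention \code{"per_measurement"} (default) or
#'   \code{"global_rms"}.
#' @return a \code{blt_measurements} with noise provenance.
#' @export
add_noise <- function(measurements, snr_db, seed,
                      convention = c("per_measurement", "global_rms")) {
  convention <- match.arg(convention)
  y <- measurement_vector(measurements)
  wl <- if (inherits(measurements, "blt_measurements")) measurements$wavelengths else NULL
  if (is.infinite(snr_db)) {
    return(structure(list(y = y, wavelengths = wl,
                          provenance = list(noise = "noiseless")),
                     class = "blt_measurements"))
  }
  amp <- 10^(-snr_db / 20)
  sigma <- switch(convention,
                  per_measurement = abs(y) * amp,
                  global_rms = rep(sqrt(mean(y^2)) * amp, length(y)))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  eps <- stats::rnorm(length(y), mean = 0, sd = sigma)
  structure(list(y = y + eps, wavelengths = wl,
                 provenance = list(noise = "gaussian", snr_db = snr_db,
                                   seed = as.integer(seed), convention = convention)),
            class = "blt_measurements")
}

#' Build the slab simulation testbed
#'
#' Prepares everything the experiment drivers need: the slab mesh, the
#' detector grid on the top face, the stacked multi-wavelength Jacobian,
#' the painted true source vector and its noiseless forward data. Defaults
#' regenerate the desk-scale study conditions: a 40 x 40 x 20 mm slab at
#' 2 mm node spacing (4851 nodes), an 11 x 11 detector grid (30 x 30 mm at
#' 3 mm pitch) on z = 20 mm, five wavelengths 600-640 nm with uniform
#' emission weights, and a cylindrical source (r = 1.5 mm, h = 5 mm,
#' intensity 10 a.u.) at 15 mm depth below the detector face.
#'
#' @param dims slab dimensions (mm).
#' @param spacing node spacing (mm).
#' @param det_extent detector grid extent (mm).
#' @param det_pitch detector pitch (mm).
#' @param wavelengths wavelengths (nm).
#' @param model spectral tissue model.
#' @param sources a \code{blt_source} or list of them; \code{NULL} gives the
#'   default 15-mm-deep cylinder.
#' @param emission_weights per-wavelength source weights (default uniform).
#' @return object of class \code{blt_testbed}: list with \code{mesh},
#'   \code{detectors}, \code{jacobian}, \code{sources}, \code{x_true},
#'   \code{y0} (noiseless data), \code{volumes}, \code{us_position} (true
#'   source centroid, the simulated ultrasound guide).
#' @export
slab_testbed <- function(dims = c(40, 40, 20), spacing = 2,
                         det_extent = c(30, 30), det_pitch = 3,
                         wavelengths = seq(600, 640, by = 10),
                         model = blt_spectral_model(),
                         sources = NULL, emission_weights = NULL) {
  mesh <- build_slab_mesh(dims, spacing)
  detectors <- place_detector_grid(mesh, det_extent, det_pitch, face = "z+")
  if (is.null(sources))
    sources <- blt_source("cylinder", center = c(0, 0, dims[3] - 15),
                          radius = 1.5, height = 5, intensity = 10)
  if (inherits(sources, "blt_source")) sources <- list(sources)
  jac <- build_jacobian(mesh, detectors, model, wavelengths, emission_weights)
  x_true <- paint_source(mesh, sources)
  y0 <- forward_measurements(jac, x_true)
  centers <- t(vapply(sources, `[[`, numeric(3), "center"))
  structure(list(mesh = mesh, detectors = detectors, jacobian = jac,
                 sources = sources, x_true = x_true, y0 = y0,
                 volumes = jac$node_volumes,
                 us_position = colMeans(centers)),
            class = "blt_testbed")
}

#' @export
print.blt_testbed <- function(x, ...) {
  cat(sprintf("blt_testbed: %d nodes, %d detectors, %d wavelengths, %d source(s)\n",
              nrow(x$mesh$nodes), nrow(x$detectors$positions),
              length(x$jacobian$wavelengths), length(x$sources)))
  invisible(x)
}

#' Run one noise realization of one reconstruction method
#'
#' Adds Gaussian noise with the given seed, reconstructs with the requested
#' method (the ultrasound guide is the true source centroid, optionally
#' jittered), and evaluates VR / DICE / MSE against the painted truth.
#' Deterministic given \code{(testbed, method, seed)}.
#'
#' @param testbed a \code{blt_testbed}.
#' @param method \code{"whole"}, \code{"large_pr"} or \code{"us_guided"}.
#' @param seed noise seed.
#' @param d dynamic range for the guided region.
#' @param snr_db noise level (dB); \code{Inf} for a noiseless trial.
#' @param half_width lateral half width for the large region (mm).
#' @param us_jitter_sd standard deviation (mm) of Gaussian jitter applied to
#'   the guide coordinate (default 0: exact knowledge of the position).
#' @param options solver options.
#' @return list with \code{recon} (a \code{blt_recon}) and \code{metrics}
#'   (one-row data.frame vr / dice / mse).
#' @export
run_trial <- function(testbed, method, seed, d = 3, snr_db = 20,
                      half_width = 7.5, us_jitter_sd = 0,
                      options = cscg_options()) {
  yn <- add_noise(testbed$y0, snr_db, seed)
  guide <- testbed$us_position
  if (us_jitter_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed) + 500000L)
    guide <- guide + stats::rnorm(3, 0, us_jitter_sd)
  }
  recon <- blt_reconstruct(testbed$jacobian, yn, method = method,
                           mesh = testbed$mesh, us_position = guide, d = d,
                           center_xy = guide[1:2], half_width = half_width,
                           options = options)
  metrics <- recon_metrics(recon, testbed$x_true, testbed$volumes,
                           expected_value = max(testbed$x_true))
  list(recon = recon, metrics = metrics)
}

#' Repeated paired-noise comparison of reconstruction methods
#'
#' Runs \code{realizations} noise seeds (\code{base_seed}, \code{base_seed
#' + 1}, ...); every method sees the identical noisy data at each seed, so
#' method differences are attributable to the region strategy alone. Failed
#' trials are recorded and excluded with a warning.
#'
#' @param testbed a \code{blt_testbed}.
#' @param methods character vector of methods to compare.
#' @param realizations number of noise realizations, >= 1.
#' @param base_seed seed of the first realization; realization k uses
#'   \code{base_seed + k - 1}.
#' @inheritParams run_trial
#' @return object of class \code{blt_metrics}: list with \code{trials}
#'   (per-trial data.frame), \code{summary} (per-method mean and sd of VR,
#'   DICE, MSE), \code{failed} (count).
#' @export
run_repeated <- function(testbed, methods = c("whole", "large_pr", "us_guided"),
                         realizations = 20, base_seed = 1, d = 3, snr_db = 20,
                         half_width = 7.5, options = cscg_options()) {
  stopifnot(realizations >= 1)
  rows <- list(); failed <- 0L
  for (k in seq_len(realizations)) {
    seed <- base_seed + k - 1L
    for (m in methods) {
      res <- tryCatch(run_trial(testbed, m, seed, d = d, snr_db = snr_db,
                                half_width = half_width, options = options),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("trial failed (method %s, seed %d): %s", m, seed,
                        conditionMessage(res)))
        failed <- failed + 1L
      } else {
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(trial = k, seed = seed, method = m), res$metrics)
      }
    }
  }
  trials <- do.call(rbind, rows)
  structure(list(trials = trials, summary = summarize_metrics(trials),
                 realizations = realizations, failed = failed),
            class = "blt_metrics")
}

#' @export
print.blt_metrics <- function(x, ...) {
  cat(sprintf("blt_metrics: %d realizations (%d failed trials)\n",
              x$realizations, x$failed))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Sweep the permissible-region dynamic range
#'
#' Runs the guided reconstruction across a set of dynamic-range values with
#' identical noise seeds per value (paired comparison) and tabulates the
#' mean and standard deviation of each metric versus \code{d}.
#'
#' @param testbed a \code{blt_testbed}.
#' @param d_values dynamic ranges to test, all >= 1.
#' @inheritParams run_repeated
#' @return object of class \code{blt_sweep}: data.frame in \code{$table}
#'   with one row per \code{d}, plus the raw trials.
#' @export
dynamic_range_sweep <- function(testbed, d_values = c(1.2, 1.5, 2, 2.5, 3, 4, 6, 10),
                                realizations = 20, base_seed = 1, snr_db = 20,
                                options = cscg_options()) {
  stopifnot(all(d_values >= 1))
  rows <- list(); trials <- list()
  for (d in d_values) {
    rep_d <- run_repeated(testbed, methods = "us_guided",
                          realizations = realizations, base_seed = base_seed,
                          d = d, snr_db = snr_db, options = options)
    s <- rep_d$summary
    rows[[length(rows) + 1L]] <- cbind(data.frame(d = d), s[, setdiff(names(s), "method")])
    trials[[length(trials) + 1L]] <- cbind(data.frame(d = d), rep_d$trials)
  }
  structure(list(table = do.call(rbind, rows), trials = do.call(rbind, trials)),
            class = "blt_sweep")
}

#' @export
print.blt_sweep <- function(x, ...) {
  cat("blt_sweep: reconstruction quality vs permissible-region dynamic range\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
plot.blt_sweep <- function(x, metric = "mse_mean", ...) {
  graphics::plot(x$table$d, x$table[[metric]], type = "b", log = "x",
                 xlab = "dynamic range d", ylab = metric, ...)
  invisible(x)
}

#' Two-source separation experiment
#'
#' Places two equal sources at a given depth, separated along x, runs each
#' reconstruction method over paired noise seeds, and measures the
#' two-source contrast of the 1D x-profile through the source plane. A
#' merged profile (single peak) has contrast \code{NA}; the summary column
#' \code{contrast_mean} treats merged as 0 (no separation).
#'
#' @param separations centre-to-centre distances (mm).
#' @param depth source depth below the detector face (mm).
#' @param methods reconstruction methods to compare.
#' @param realizations noise realizations per separation and method.
#' @param base_seed first noise seed.
#' @param d dynamic range for the guided method.
#' @param snr_db noise level (dB).
#' @param testbed_args list of arguments passed on to \code{slab_testbed}
#'   (geometry, detectors, spectra); sources are set per separation.
#' @param source_radius,source_height cylinder source dimensions (mm).
#' @param intensity source intensity (a.u.).
#' @param options solver options.
#' @return object of class \code{blt_two_source}: \code{$table} with one
#'   row per (separation, method) and the per-trial contrasts; profiles of
#'   the first realization in \code{$profiles}.
#' @export
two_source_experiment <- function(separations = c(4, 6, 8), depth = 6,
                                  methods = c("whole", "large_pr", "us_guided"),
                                  realizations = 5, base_seed = 1, d = 3,
                                  snr_db = 20, testbed_args = list(),
                                  source_radius = 1.5, source_height = 5,
                                  intensity = 10, options = cscg_options()) {
  stopifnot(all(separations > 0))
  pair_at <- function(sep, zc) list(
    blt_source("cylinder", c(-sep / 2, 0, zc), source_radius, source_height,
               intensity = intensity),
    blt_source("cylinder", c(sep / 2, 0, zc), source_radius, source_height,
               intensity = intensity))
  dims <- if (!is.null(testbed_args$dims)) testbed_args$dims else c(40, 40, 20)
  zc <- dims[3] - depth
  base <- do.call(slab_testbed,
                  c(testbed_args, list(sources = pair_at(separations[1], zc))))
  rows <- list(); profiles <- list()
  for (sep in separations) {
    sources <- pair_at(sep, zc)
    tb <- base
    tb$sources <- sources
    tb$x_true <- paint_source(tb$mesh, sources)
    tb$y0 <- forward_measurements(tb$jacobian, tb$x_true)
    tb$us_position <- c(0, 0, zc)   # midpoint of the two centres as guide
    for (m in methods) {
      contrasts <- numeric(0); merged <- 0L
      for (k in seq_len(realizations)) {
        res <- run_trial(tb, m, base_seed + k - 1L, d = d, snr_db = snr_db,
                         options = options)
        prof <- source_plane_profile(res$recon$x_hat, tb$mesh, axis = "x",
                                     through = c(0, 0, zc))
        ct <- two_source_contrast(prof)
        if (is.na(ct)) { merged <- merged + 1L; ct <- 0 } # merged: no separation
        contrasts <- c(contrasts, ct)
        if (k == 1L)
          profiles[[sprintf("sep%g_%s", sep, m)]] <- prof
      }
      rows[[length(rows) + 1L]] <- data.frame(
        separation = sep, method = m, n = realizations,
        contrast_mean = mean(contrasts),
        contrast_sd = if (realizations > 1) stats::sd(contrasts) else 0,
        merged = merged)
    }
  }
  structure(list(table = do.call(rbind, rows), profiles = profiles),
            class = "blt_two_source")
}

#' @export
print.blt_two_source <- function(x, ...) {
  cat("blt_two_source: profile contrast by separation and method\n")
  print(x$table, digits = 4)
  invisible(x)
}
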