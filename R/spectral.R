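#' Bundled chromophore extinction table
#'
#' Approximate extinction coefficients for oxy- and deoxy-haemoglobin and
#' absorption of pure water over 600-700 nm, at 10 nm steps. Haemoglobin
#' columns are in mm^-1 per mM (natural-log convention), the water column is
#' the absorption coefficient of pure water in mm^-1 (so a water
#' "concentration" is a volume fraction). These are replaceable defaults for
#' simulation work: pass your own table to \code{blt_spectral_model} for
#' quantitative use.
#'
#' @return data.frame with columns \code{wavelength_nm}, \code{hbo},
#'   \code{hb}, \code{water}.
#' @export
blt_chromophores <- function() {
  # hb/hbo derived from standard molar extinction compilations,
  # converted to mm^-1 mM^-1 (x ln10 x 1e-4); water from published
  # pure-water absorption spectra.
  data.frame(
    wavelength_nm = seq(600, 700, by = 10),
    hbo   = c(0.737, 0.347, 0.217, 0.141, 0.102, 0.085, 0.074, 0.068, 0.064, 0.064, 0.067),
    hb    = c(3.380, 2.497, 1.740, 1.186, 1.001, 0.864, 0.743, 0.644, 0.554, 0.472, 0.413),
    water = c(2.24e-4, 2.56e-4, 2.76e-4, 2.92e-4, 3.28e-4, 3.40e-4,
              3.84e-4, 4.25e-4, 4.58e-4, 4.91e-4, 6.00e-4)
  )
}

#' Spectral tissue model
#'
#' Chromophore concentrations plus a reduced-scattering power law
#' \eqn{\mu_s'(\lambda) = a (\lambda/1000\,nm)^{-b}} (wavelength expressed in
#' micrometres) and a refractive index. Absorption follows Beer's law:
#' \eqn{\mu_a(\lambda) = \sum_c C_c\, \epsilon_c(\lambda)}.
#'
#' @param chromophores named list/vector of concentrations; names must match
#'   columns of \code{extinction}. Defaults: water fraction 0.5, HbO 0.01 mM,
#'   Hb 0.005 mM (muscle-like in the red).
#' @param scatter_amplitude scatter amplitude \code{a} (dimensionless), > 0.
#' @param scatter_power scatter power \code{b} (dimensionless).
#' @param refractive_index tissue refractive index, >= 1.
#' @param extinction extinction table (data.frame with a
#'   \code{wavelength_nm} column and one column per chromophore).
#' @return object of class \code{blt_spectral_model}.
#' @export
blt_spectral_model <- function(chromophores = list(water = 0.5, hbo = 0.01, hb = 0.005),
                               scatter_amplitude = 0.14,
                               scatter_power = 2.8,
                               refractive_index = 1.33,
                               extinction = blt_chromophores()) {
  conc <- unlist(chromophores)
  if (is.null(names(conc)) || any(!nzchar(names(conc))))
    stop("`chromophores` must be a named list of concentrations")
  if (any(conc < 0)) stop("chromophore concentrations must be >= 0")
  if (!is.finite(scatter_amplitude) || scatter_amplitude <= 0)
    stop("`scatter_amplitude` must be > 0")
  if (!is.finite(refractive_index) || refractive_index < 1)
    stop("`refractive_index` must be >= 1")
  missing_cols <- setdiff(names(conc), names(extinction))
  if (length(missing_cols))
    stop("extinction table lacks column(s): ", paste(missing_cols, collapse = ", "))
  structure(list(chromophores = conc,
                 scatter_amplitude = scatter_amplitude,
                 scatter_power = scatter_power,
                 refractive_index = refractive_index,
                 extinction = extinction),
            class = "blt_spectral_model")
}

#' @export
print.blt_spectral_model <- function(x, ...) {
  cat("blt_spectral_model\n")
  cat("  chromophores:",
      paste(sprintf("%s = %g", names(x$chromophores), x$chromophores), collapse = ", "), "\n")
  cat(sprintf("  mus' = %g * (lambda/1um)^-%g mm^-1, n = %g\n",
              x$scatter_amplitude, x$scatter_power, x$refractive_index))
  invisible(x)
}

#' Absorption coefficient at a wavelength
#'
#' Beer's-law sum of concentration times extinction, linearly interpolated
#' within the extinction table. No extrapolation: wavelengths outside the
#' table range are an error.
#'
#' @param model a \code{blt_spectral_model}.
#' @param wavelength wavelength in nm.
#' @return \eqn{\mu_a} in mm^-1.
#' @export
absorption_at <- function(model, wavelength) {
  tab <- model$extinction
  rng <- range(tab$wavelength_nm)
  if (any(wavelength < rng[1] - 1e-9) || any(wavelength > rng[2] + 1e-9))
    stop(sprintf("wavelength outside extinction table range [%g, %g] nm", rng[1], rng[2]))
  vapply(wavelength, function(w) {
    eps <- vapply(names(model$chromophores), function(ch)
      stats::approx(tab$wavelength_nm, tab[[ch]], xout = w)$y, numeric(1))
    sum(model$chromophores * eps)
  }, numeric(1))
}

#' Reduced scattering coefficient at a wavelength
#'
#' Power law \eqn{a (\lambda_{\mu m})^{-b}} with the wavelength in
#' micrometres (so \code{a} is the value at 1000 nm).
#'
#' @inheritParams absorption_at
#' @return \eqn{\mu_s'} in mm^-1.
#' @export
scattering_at <- function(model, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  model$scatter_amplitude * (wavelength / 1000)^(-model$scatter_power)
}

#' Diffusion coefficient
#'
#' \eqn{\kappa = 1 / (3 (\mu_a + \mu_s'))} in mm.
#'
#' @param mua absorption coefficient (mm^-1), >= 0.
#' @param musp reduced scattering coefficient (mm^-1), > 0.
#' @export
diffusion_coefficient <- function(mua, musp) {
  if (any(mua < 0)) stop("`mua` must be >= 0")
  if (any(mua + musp <= 0)) stop("`mua + musp` must be > 0")
  1 / (3 * (mua + musp))
}

#' Per-node optical properties at a wavelength
#'
#' For a homogeneous model every node gets the same coefficients; passing a
#' named list of models keyed by region label ("1", "2", ...) gives
#' heterogeneous slabs.
#'
#' @param mesh a \code{blt_mesh}.
#' @param model a \code{blt_spectral_model}, or a named list of them keyed by
#'   region label.
#' @param wavelength wavelength in nm.
#' @return list with numeric per-node vectors \code{mua}, \code{musp},
#'   \code{kappa} and scalar \code{refractive_index} (region-averaged if
#'   heterogeneous).
#' @export
optical_properties <- function(mesh, model, wavelength) {
  n <- nrow(mesh$nodes)
  if (inherits(model, "blt_spectral_model")) {
    mua <- rep(absorption_at(model, wavelength), n)
    musp <- rep(scattering_at(model, wavelength), n)
    nref <- model$refractive_index
  } else if (is.list(model)) {
    mua <- musp <- numeric(n)
    nref_by_region <- numeric(0)
    for (reg in unique(mesh$region)) {
      key <- as.character(reg)
      if (is.null(model[[key]]))
        stop("no spectral model supplied for region ", key)
      sel <- mesh$region == reg
      mua[sel] <- absorption_at(model[[key]], wavelength)
      musp[sel] <- scattering_at(model[[key]], wavelength)
      nref_by_region[key] <- model[[key]]$refractive_index
    }
    nref <- mean(nref_by_region)
  } else stop("`model` must be a blt_spectral_model or a named list of them")
  list(mua = mua, musp = musp, kappa = diffusion_coefficient(mua, musp),
       refractive_index = nref)
}

#' Gaussian emission spectrum weights
#'
#' Normalised per-wavelength weights of a Gaussian emission spectrum, for
#' phantom-like sources with a stated peak and FWHM (e.g. a chemiluminescent
#' source peaking at 640 nm with FWHM 60 nm).
#'
#' @param wavelengths wavelengths (nm) at which the source is measured.
#' @param peak peak emission wavelength (nm).
#' @param fwhm full width at half maximum of the spectrum (nm).
#' @return numeric weights summing to 1.
#' @export
emission_weights_gaussian <- function(wavelengths, peak = 640, fwhm = 60) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-((wavelengths - peak)^2) / (2 * sigma^2))
  w / sum(w)
}
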