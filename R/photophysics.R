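#' Power sweep container
#'
#' Paired excitation powers and detected fluorescence intensities from a dye
#' characterisation at fixed wavelength.
#'
#' @param powers Excitation powers (mW), strictly positive, length >= 3.
#' @param intensities Detected intensities (arbitrary detector units),
#'   strictly positive, same length.
#' @param wavelength Excitation wavelength (nm).
#' @return Object of class `power_sweep`.
#' @export
power_sweep <- function(powers, intensities, wavelength = NA_real_) {
  if (length(powers) != length(intensities))
    stop("powers and intensities must have equal length")
  if (length(powers) < 3) stop("a power sweep needs at least 3 points")
  if (any(powers <= 0) || any(intensities <= 0))
    stop("powers and intensities must be strictly positive")
  structure(list(powers = as.numeric(powers),
                 intensities = as.numeric(intensities),
                 wavelength = wavelength),
            class = "power_sweep")
}

#' Fit the multiphoton excitation order
#'
#' Ordinary least squares of log(intensity) on log(power). For an n-photon
#' absorption process the fluorescence scales as P^n, so the log-log slope
#' estimates the excitation order; a slope near 2 indicates two-photon
#' excitation.
#'
#' @param sweep A [power_sweep()].
#' @return List with `slope`, `slope_se`, `intercept`, `r_squared`, `n`, and
#'   the underlying `lm` fit.
#' @export
fit_power_slope <- function(sweep) {
  stopifnot(inherits(sweep, "power_sweep"))
  lp <- log(sweep$powers)
  li <- log(sweep$intensities)
  fit <- stats::lm(li ~ lp)
  res <- stats::residuals(fit)
  n <- length(lp)
  sxx <- sum((lp - mean(lp))^2)
  ss_res <- sum(res^2)
  ss_tot <- sum((li - mean(li))^2)
  list(slope = unname(stats::coef(fit)[2]),
       slope_se = sqrt(ss_res / (n - 2) / sxx),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n = n,
       fit = fit)
}

#' Two-photon cross section by the reference-ratio method
#'
#' Estimates a sample's two-photon cross section from the ratio of its
#' fluorescence signal to that of a reference fluorophore of known cross
#' section, measured under identical excitation wavelength, power and
#' collection geometry:
#' \deqn{\sigma_s = \sigma_r \frac{F_s \, \phi_r \, C_r}{F_r \, \phi_s \, C_s}}
#' Quantum yields default to 1 so that action cross sections (sigma*phi) can
#' be supplied and returned directly.
#'
#' @param sample_signal,reference_signal Detected fluorescence signals (> 0).
#' @param sample_conc,reference_conc Concentrations (> 0, same units).
#' @param sample_qy,reference_qy Fluorescence quantum yields (> 0), default 1.
#' @param reference_sigma Reference cross section, m^4 s / photon.
#' @param wavelength Excitation wavelength (nm), recorded in the result.
#' @param reference_name Label of the reference fluorophore.
#' @return List of class `cross_section_estimate` with `sigma`
#'   (m^4 s / photon), `wavelength`, `reference_name`, `reference_sigma`.
#' @export
cross_section_from_reference <- function(sample_signal, reference_signal,
                                         sample_conc = 1, reference_conc = 1,
                                         sample_qy = 1, reference_qy = 1,
                                         reference_sigma,
                                         wavelength = NA_real_,
                                         reference_name = "reference") {
  if (reference_signal == 0) stop("reference signal must be non-zero")
  vals <- c(sample_signal, reference_signal, sample_conc, reference_conc,
            sample_qy, reference_qy, reference_sigma)
  if (any(vals <= 0)) stop("all inputs must be strictly positive")
  sigma <- reference_sigma * (sample_signal * reference_qy * reference_conc) /
    (reference_signal * sample_qy * sample_conc)
  structure(list(sigma = sigma, wavelength = wavelength,
                 reference_name = reference_name,
                 reference_sigma = reference_sigma),
            class = "cross_section_estimate")
}

#' Focal fluence of a pulsed laser at the focus
#'
#' Order-of-magnitude estimate of the per-pulse fluence delivered at the
#' focal plane: pulse energy = average power / repetition rate, spread over a
#' diffraction-limited spot of Rayleigh-criterion radius 0.61 lambda / NA.
#' Used to compare the excitation regime against the ~1 J/cm^2 ablation
#' threshold of biological tissue; values well below it rule out cavitation
#' damage as the occlusion mechanism. The repetition rate defaults to 80 MHz
#' (typical Ti:Sapphire oscillator) and all assumptions are recorded in the
#' result, as the estimate is sensitive to them.
#'
#' @param avg_power_mW Average power at the focal plane (mW, > 0).
#' @param rep_rate_MHz Laser repetition rate (MHz, > 0). Default 80.
#' @param wavelength_nm Excitation wavelength (nm, > 0).
#' @param numerical_aperture Objective NA, in (0, 1.5].
#' @return List of class `fluence_estimate`: `fluence_J_cm2`,
#'   `pulse_energy_J`, `spot_radius_m`, and an `assumptions` list.
#' @export
focal_fluence <- function(avg_power_mW, rep_rate_MHz = 80, wavelength_nm,
                          numerical_aperture) {
  stopifnot(avg_power_mW > 0, rep_rate_MHz > 0, wavelength_nm > 0)
  if (numerical_aperture <= 0 || numerical_aperture > 1.5)
    stop("numerical_aperture must lie in (0, 1.5]")
  pulse_energy <- (avg_power_mW * 1e-3) / (rep_rate_MHz * 1e6)      # J
  spot_radius <- 0.61 * wavelength_nm * 1e-9 / numerical_aperture   # m
  area_m2 <- pi * spot_radius^2
  fluence <- pulse_energy / area_m2 / 1e4                           # J/cm^2
  structure(list(fluence_J_cm2 = fluence,
                 pulse_energy_J = pulse_energy,
                 spot_radius_m = spot_radius,
                 assumptions = list(
                   spot_model = "Rayleigh radius 0.61*lambda/NA, uniform disc",
                   rep_rate_MHz = rep_rate_MHz,
                   note = paste("order-of-magnitude estimate; repetition rate,",
                                "pulse width and NA are assumptions, not",
                                "measured quantities"))),
            class = "fluence_estimate")
}
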