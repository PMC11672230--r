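# Ellipsometry: Cauchy dispersion of the film index, De Feijter conversion
# of (thickness, index) to surface density, and kinetic-series summaries.

#' Cauchy refractive index of a film
#'
#' n(lambda) = A + B / lambda^2 with lambda in micrometres (the standard
#' ellipsometry convention for the B coefficient; `wavelength` is given in
#' nm and converted internally).
#'
#' @param a Cauchy coefficient A (dimensionless, >= 1)
#' @param b Cauchy coefficient B, micrometre^2
#' @param wavelength nm (> 0)
#' @return refractive index
#' @export
cauchy_index <- function(a, b, wavelength) {
  stopifnot(a >= 1)
  if (any(wavelength <= 0)) stop("wavelength must be > 0")
  a + b / (wavelength / 1000)^2
}

#' Surface density from ellipsometric layer parameters (De Feijter)
#'
#' Gamma = tau * (n_film - n_ambient) / (dn/dc), converted to mg/m^2 with
#' tau in Angstrom and dn/dc in mL/g. The default refractive-index
#' increment for proteins is 0.18 mL/g at 630 nm; the default ambient index
#' is aqueous buffer at 630 nm.
#'
#' @param tau layer thickness, Angstrom
#' @param n_film film refractive index (>= n_ambient)
#' @param n_ambient ambient (buffer) refractive index
#' @param dndc refractive-index increment, mL/g (> 0)
#' @return surface density Gamma, mg/m^2
#' @export
defeijter_gamma <- function(tau, n_film, n_ambient = 1.335, dndc = 0.18) {
  if (dndc <= 0) stop("dn/dc must be > 0")
  if (any(n_film < n_ambient)) stop("unphysical film: n_film < n_ambient")
  # tau [A] * dn / (dn/dc [cm^3/g]) = 1e-8 cm * g/cm^3 -> g/cm^2; x1e7 -> mg/m^2
  0.1 * tau * (n_film - n_ambient) / dndc
}

#' Build a kinetic adsorption point
#'
#' @param time s
#' @param thickness tau, Angstrom
#' @param n_film film refractive index at 630 nm
#' @param n_ambient,dndc passed to [defeijter_gamma()]
#' @return data.frame row with time, thickness, n_film, gamma
#' @export
kinetic_point <- function(time, thickness, n_film, n_ambient = 1.335, dndc = 0.18) {
  data.frame(time = time, thickness = thickness, n_film = n_film,
             gamma = defeijter_gamma(thickness, n_film, n_ambient, dndc))
}

#' Plateau statistics of a kinetic adsorption series
#'
#' The plateau surface density is the mean Gamma over the final `window`
#' seconds of the series (default: the final 20% of the time span), with
#' its standard deviation. Time-to-plateau is the first time from which
#' Gamma stays within 5% of the plateau for the remainder of the series
#' (NA if never).
#'
#' @param time s, increasing
#' @param gamma surface density, mg/m^2
#' @param window averaging window, s; default 20% of the span
#' @param tol relative band defining "at plateau" (default 0.05)
#' @return list with `plateau`, `sd`, `n_window`, `time_to_plateau`
#' @export
saturation_stats <- function(time, gamma, window = NULL, tol = 0.05) {
  stopifnot(length(time) == length(gamma), length(time) >= 3,
            !is.unsorted(time))
  span <- max(time) - min(time)
  if (is.null(window)) window <- 0.2 * span
  if (window <= 0 && span > 0) stop("empty averaging window")
  in_win <- time >= max(time) - window
  plateau <- mean(gamma[in_win])
  s <- sd(gamma[in_win])
  ok <- abs(gamma - plateau) <= tol * abs(plateau)
  # first index from which every later point stays inside the band
  stays <- rev(cumprod(rev(ok))) > 0
  t_pl <- if (any(stays)) time[which(stays)[1]] else NA_real_
  list(plateau = plateau, sd = s, n_window = sum(in_win),
       time_to_plateau = t_pl)
}

#' Read a kinetic ellipsometry series from CSV
#'
#' Expects columns `time`, `thickness`, `n_film`; computes `gamma` via
#' [defeijter_gamma()] if absent.
#'
#' @param path CSV file
#' @param n_ambient,dndc passed to [defeijter_gamma()]
#' @return data.frame with time, thickness, n_film, gamma
#' @export
read_kinetic_series <- function(path, n_ambient = 1.335, dndc = 0.18) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("time", "thickness", "n_film")
  if (!all(need %in% names(df)))
    stop("kinetic series needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$gamma))
    df$gamma <- defeijter_gamma(df$thickness, df$n_film, n_ambient, dndc)
  df
}

#' Write a kinetic series (with Gamma) as CSV
#'
#' @param df data.frame as returned by [read_kinetic_series()]
#' @param path output CSV path
#' @export
write_kinetic_series <- function(df, path) {
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
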