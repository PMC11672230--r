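# Specular reflectivity forward model: Abeles matrix kernel over a layer
# stack, Gaussian resolution smearing, and instrument scale/background.

#' Momentum transfer from angle and wavelength
#'
#' Q = 4 pi sin(theta) / lambda.
#'
#' @param theta incident angle, degrees, in (0, 90\]
#' @param wavelength neutron wavelength, Angstrom (> 0)
#' @return Q, 1/Angstrom
#' @export
q_from_angle <- function(theta, wavelength) {
  if (any(theta <= 0) || any(theta > 90)) stop("theta must lie in (0, 90] degrees")
  if (any(wavelength <= 0)) stop("wavelength must be > 0")
  4 * pi * sin(theta * pi / 180) / wavelength
}

#' Critical momentum transfer of a single interface
#'
#' Q_c = 4 sqrt(pi * delta_rho) for backing SLD above fronting SLD; below
#' Q_c the interface is totally reflecting. Returns 0 when there is no
#' total-reflection edge (delta_rho <= 0).
#'
#' @param delta_rho backing SLD minus fronting SLD, 1/Angstrom^2
#' @return Q_c, 1/Angstrom
#' @export
critical_q <- function(delta_rho) {
  ifelse(delta_rho > 0, 4 * sqrt(pi * pmax(delta_rho, 0)), 0)
}

#' Construct a reflectivity curve
#'
#' @param q strictly increasing momentum-transfer grid, 1/Angstrom, q > 0
#' @param r reflectivity
#' @param dr optional 1-sigma uncertainties
#' @param dq optional resolution widths (FWHM), 1/Angstrom
#' @return object of class `nr_curve`
#' @export
reflectivity_curve <- function(q, r, dr = NULL, dq = NULL) {
  stopifnot(is.numeric(q), is.numeric(r), length(q) == length(r), length(q) > 0)
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and > 0")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (!is.null(dr)) stopifnot(length(dr) == length(q), all(dr >= 0))
  if (!is.null(dq)) stopifnot(length(dq) == length(q), all(dq >= 0))
  structure(list(q = q, r = r, dr = dr, dq = dq), class = "nr_curve")
}

#' @export
print.nr_curve <- function(x, ...) {
  cat(sprintf("<nr_curve> %d points, Q in [%.4g, %.4g] 1/A%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$dr)) "" else ", with uncertainties"))
  invisible(x)
}

# Resolve an nr_stack + solvent into the per-layer (sld, thick, rough)
# vectors the Abeles kernel expects: Si | SiO2 | slabs... | solvent.
stack_to_layers <- function(stack, solvent) {
  stopifnot(inherits(stack, "nr_stack"), inherits(solvent, "contrast_solvent"))
  sub <- stack$substrate
  p_sld <- protein_sld_for_solvent(stack$protein, solvent$sld)
  phi <- vapply(stack$slabs, `[[`, 0, "phi")
  tau <- vapply(stack$slabs, `[[`, 0, "thickness")
  sig <- vapply(stack$slabs, `[[`, 0, "roughness")
  oxide_sld <- mix_sld(1 - sub$oxide_hydration, sub$oxide_sld, solvent$sld)
  # rough[j]: interface between layer j and j+1; each slab carries the width
  # of its substrate-side interface; the outermost interface is taken sharp.
  if (sub$oxide_thickness > 0) {
    sld <- c(sub$fronting_sld, oxide_sld, mix_sld(phi, p_sld, solvent$sld),
             solvent$sld)
    thick <- c(0, sub$oxide_thickness, tau, 0)
    rough <- c(sub$oxide_roughness, sig, 0)
  } else {
    # no oxide: a zero-thickness layer must not contribute an extra
    # interface, so the oxide roughness moves to the first real interface
    sld <- c(sub$fronting_sld, mix_sld(phi, p_sld, solvent$sld), solvent$sld)
    thick <- c(0, tau, 0)
    rough <- if (length(sig)) c(max(sub$oxide_roughness, sig[1]), sig[-1], 0)
             else sub$oxide_roughness
  }
  list(sld = sld, thick = thick, rough = rough)
}

#' Specular reflectivity of a layer stack (Abeles matrix method)
#'
#' Computes unpolarized specular reflectivity with complex perpendicular
#' wavevectors k_i = sqrt((Q/2)^2 - 4 pi (rho_i - rho_fronting)) and Fresnel
#' coefficients damped by Nevot-Croce factors exp(-2 k_i k_{i+1} sigma^2).
#' Per-slab SLDs are resolved for the given contrast via the two-component
#' mixing rule with the H/D-exchange-adjusted protein SLD.
#'
#' @param stack an `nr_stack`
#' @param solvent a [contrast_solvent()]
#' @param q momentum-transfer grid, 1/Angstrom
#' @return an `nr_curve` with the model reflectivity (in \[0, 1\])
#' @export
abeles_reflectivity <- function(stack, solvent, q) {
  if (length(q) == 0) stop("empty q grid")
  lay <- stack_to_layers(stack, solvent)
  reflectivity_curve(q, abeles_kernel(q, lay$sld, lay$thick, lay$rough))
}

# 13-point Gaussian quadrature rule (nodes in units of sigma, weights
# normalized) used for resolution smearing; truncated at +-3.5 sigma.
smear_rule <- function(n_points = 13, width = 3.5) {
  gl <- pracma::gaussLegendre(n_points, -width, width)
  w <- gl$w * dnorm(gl$x)
  list(x = gl$x, w = w / sum(w))
}

#' Resolution-smeared model reflectivity
#'
#' Exact fixed-quadrature smearing of the forward model: for each Q the
#' kernel is evaluated at quadrature nodes of the Gaussian resolution
#' function with sigma_Q = (dq_over_q / 2.355) * Q and combined with
#' Gaussian-weighted Gauss-Legendre weights.
#'
#' @inheritParams abeles_reflectivity
#' @param dq_over_q fractional FWHM resolution, in \[0, 0.2\]
#' @param n_points quadrature points (default 13)
#' @return an `nr_curve`
#' @export
abeles_smeared <- function(stack, solvent, q, dq_over_q = 0.04, n_points = 13) {
  if (dq_over_q < 0 || dq_over_q > 0.2) stop("dq_over_q must lie in [0, 0.2]")
  if (dq_over_q == 0) return(abeles_reflectivity(stack, solvent, q))
  lay <- stack_to_layers(stack, solvent)
  rule <- smear_rule(n_points)
  qq <- outer(q, 1 + (dq_over_q / 2.355) * rule$x)  # nq x n_points
  qq[qq < 1e-6] <- 1e-6
  rr <- matrix(abeles_kernel(as.numeric(qq), lay$sld, lay$thick, lay$rough),
               nrow = length(q))
  reflectivity_curve(q, as.numeric(rr %*% rule$w))
}

#' Gaussian-smear a tabulated reflectivity curve
#'
#' Convolution in Q with sigma_Q = (dq_over_q / 2.355) * Q, by quadrature
#' over the tabulated curve. Interpolation is linear in log R where R > 0
#' (linear otherwise) and flat beyond the tabulated range. `dq_over_q = 0`
#' returns the curve unchanged.
#'
#' @param curve an `nr_curve`
#' @param dq_over_q fractional FWHM resolution
#' @param n_points quadrature points
#' @return an `nr_curve`
#' @export
smear <- function(curve, dq_over_q, n_points = 13) {
  stopifnot(inherits(curve, "nr_curve"), dq_over_q >= 0)
  if (dq_over_q == 0) return(curve)
  rule <- smear_rule(n_points)
  qq <- outer(curve$q, 1 + (dq_over_q / 2.355) * rule$x)
  qq[qq < min(curve$q)] <- min(curve$q)
  qq[qq > max(curve$q)] <- max(curve$q)
  rr <- matrix(interp_reflectivity(curve$q, curve$r, as.numeric(qq)),
               nrow = length(curve$q))
  reflectivity_curve(curve$q, as.numeric(rr %*% rule$w), dr = curve$dr, dq = curve$dq)
}

# Interpolate a reflectivity curve onto new q points, linear in log R where
# all bracketing values are positive, linear otherwise; flat extrapolation.
interp_reflectivity <- function(q, r, q_new) {
  if (all(r > 0)) {
    exp(approx(q, log(r), xout = q_new, rule = 2)$y)
  } else {
    approx(q, r, xout = q_new, rule = 2)$y
  }
}

#' Define an instrument model
#'
#' Multiplicative scale, additive background, and fractional Gaussian Q
#' resolution (FWHM / Q).
#'
#' @param scale multiplicative factor (> 0)
#' @param background additive constant reflectivity (>= 0)
#' @param dq_over_q fractional resolution in \[0, 0.2\]
#' @return object of class `nr_instrument`
#' @export
instrument_model <- function(scale = 1, background = 0, dq_over_q = 0.04) {
  stopifnot(scale > 0, background >= 0, dq_over_q >= 0, dq_over_q <= 0.2)
  structure(list(scale = scale, background = background, dq_over_q = dq_over_q),
            class = "nr_instrument")
}

#' Apply instrument scale and background to a curve
#'
#' R' = scale * R + background. Uncertainties, if present, are scaled.
#'
#' @param curve an `nr_curve`
#' @param instrument an [instrument_model()]
#' @return an `nr_curve`
#' @export
apply_instrument <- function(curve, instrument) {
  stopifnot(inherits(curve, "nr_curve"), inherits(instrument, "nr_instrument"))
  reflectivity_curve(curve$q, instrument$scale * curve$r + instrument$background,
                     dr = if (!is.null(curve$dr)) instrument$scale * curve$dr,
                     dq = curve$dq)
}

#' Full instrument-convolved model curve
#'
#' Convenience wrapper: smeared Abeles reflectivity with scale and
#' background applied — the quantity compared against measured data.
#'
#' @inheritParams abeles_reflectivity
#' @param instrument an [instrument_model()]
#' @return an `nr_curve`
#' @export
model_reflectivity <- function(stack, solvent, q, instrument = instrument_model()) {
  apply_instrument(abeles_smeared(stack, solvent, q, instrument$dq_over_q),
                   instrument)
}

#' Read a reflectivity curve from delimited ASCII
#'
#' Accepts whitespace- or comma-delimited text with 2-4 numeric columns
#' (Q, R\[, dR\[, dQ\]\]); lines starting with `#` are treated as header
#' comments and returned in attribute `header`.
#'
#' @param path input file
#' @return an `nr_curve`
#' @export
read_reflectivity <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path)
  sep_comma <- grepl(",", body[1])
  tab <- read.table(text = body, sep = if (sep_comma) "," else "",
                    header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2 || ncol(tab) > 4)
    stop("expected 2-4 numeric columns (Q, R[, dR[, dQ]]), got ", ncol(tab))
  cur <- reflectivity_curve(tab[[1]], tab[[2]],
                            dr = if (ncol(tab) >= 3) tab[[3]],
                            dq = if (ncol(tab) >= 4) tab[[4]])
  attr(cur, "header") <- hdr
  cur
}

#' Write a reflectivity curve as delimited ASCII
#'
#' Writes `# key: value` header lines followed by whitespace-delimited
#' columns Q, R\[, dR\[, dQ\]\] — the same layout [read_reflectivity()]
#' accepts.
#'
#' @param curve an `nr_curve`
#' @param path output file
#' @param header optional character vector of header lines (without `#`)
#' @export
write_reflectivity <- function(curve, path, header = character()) {
  stopifnot(inherits(curve, "nr_curve"))
  cols <- list(q = curve$q, r = curve$r)
  if (!is.null(curve$dr)) cols$dr <- curve$dr
  if (!is.null(curve$dq)) cols$dq <- curve$dq
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#", c(paste("columns:", paste(names(cols), collapse = " ")),
                            header))), con)
  write.table(as.data.frame(cols), con, sep = " ", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
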