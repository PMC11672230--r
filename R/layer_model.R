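# Core slab-layer data model: solvent contrasts, protein constants, slabs,
# stacks, and all SLD <-> volume-fraction <-> adsorbed-amount arithmetic.

#' Avogadro constant (exact SI value), mol^-1
#' @export
N_AVOGADRO <- 6.02214076e23

#' Scattering length density of pure H2O, 1/Angstrom^2
#' @export
SLD_H2O <- -0.56e-6

#' Scattering length density of pure D2O, 1/Angstrom^2
#' @export
SLD_D2O <- 6.35e-6

#' Define a solvent contrast
#'
#' A water contrast used in a reflectivity measurement. Mixtures of H2O
#' (SLD -0.56e-6 1/A^2) and D2O (SLD 6.35e-6 1/A^2) span the physically
#' accessible SLD range; values outside it are rejected.
#'
#' @param name label, e.g. "D2O", "CM4", "H2O"
#' @param sld solvent scattering length density, 1/Angstrom^2
#' @return an object of class `contrast_solvent`
#' @export
contrast_solvent <- function(name, sld) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(sld), length(sld) == 1L, is.finite(sld))
  if (sld < SLD_H2O - 1e-12 || sld > SLD_D2O + 1e-12)
    stop("solvent SLD ", format(sld), " outside the H2O/D2O mixing range [",
         format(SLD_H2O), ", ", format(SLD_D2O), "]")
  structure(list(name = name, sld = sld), class = "contrast_solvent")
}

#' @export
print.contrast_solvent <- function(x, ...) {
  cat(sprintf("<contrast_solvent> %s: SLD %.3g 1/A^2\n", x$name, x$sld))
  invisible(x)
}

#' Define a protein species
#'
#' Holds the molecular constants that drive the adsorbed-amount formula and
#' the labile-hydrogen (H/D) exchange of the protein SLD. The SLD anchors are
#' the values in pure H2O and pure D2O; intermediate contrasts are obtained
#' by linear interpolation in solvent SLD (see
#' [protein_sld_for_solvent()]).
#'
#' @param name label
#' @param mw molecular weight, g/mol
#' @param volume molecular volume, Angstrom^3
#' @param sld_h2o protein SLD in pure H2O, 1/Angstrom^2
#' @param sld_d2o protein SLD in pure D2O, 1/Angstrom^2
#' @return an object of class `protein_species`
#' @export
protein_species <- function(name, mw, volume, sld_h2o, sld_d2o) {
  stopifnot(is.numeric(mw), mw > 0, is.numeric(volume), volume > 0,
            is.finite(sld_h2o), is.finite(sld_d2o))
  if (sld_d2o <= sld_h2o)
    stop("protein SLD must increase with solvent SLD (labile-H exchange)")
  structure(list(name = name, mw = mw, volume = volume,
                 sld_h2o = sld_h2o, sld_d2o = sld_d2o),
            class = "protein_species")
}

#' @export
print.protein_species <- function(x, ...) {
  cat(sprintf("<protein_species> %s: MW %.0f g/mol, V %.0f A^3, SLD %.3g (H2O) .. %.3g (D2O)\n",
              x$name, x$mw, x$volume, x$sld_h2o, x$sld_d2o))
  invisible(x)
}

#' Read the shipped protein-constants table
#'
#' Molecular weight, volume and per-contrast SLDs of the whole IgG1 antibody
#' (COE-3) and its Fab and Fc fragments, as used throughout the layer-model
#' arithmetic.
#'
#' @param path CSV file; defaults to the table shipped with the package
#' @return data.frame with one row per species
#' @export
protein_constants <- function(path = system.file("extdata", "protein_constants.csv",
                                                 package = "nrslab")) {
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Look up a protein species from the shipped constants table
#'
#' @param name one of the names in [protein_constants()] ("COE-3", "Fab", "Fc")
#' @return a [protein_species()] object (CM4 entry kept as attribute
#'   `sld_cm4` for consistency checks)
#' @export
get_protein <- function(name) {
  tab <- protein_constants()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown protein '", name, "'; known: ",
                     paste(tab$name, collapse = ", "))
  p <- protein_species(tab$name[i], tab$mw_g_mol[i], tab$volume_A3[i],
                       tab$sld_h2o_A2[i], tab$sld_d2o_A2[i])
  attr(p, "sld_cm4") <- tab$sld_cm4_A2[i]
  p
}

#' Define a protein slab
#'
#' One homogeneous sublayer of the adsorbed protein film: thickness tau,
#' protein volume fraction phi (the water fraction is 1 - phi), and a
#' Gaussian interfacial width sigma for the interface on its substrate side.
#'
#' @param thickness tau, Angstrom (> 0)
#' @param phi protein volume fraction in \[0, 1\]
#' @param roughness sigma, Angstrom (>= 0)
#' @return an object of class `nr_slab`
#' @export
slab <- function(thickness, phi, roughness = 0) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L,
            is.numeric(phi), length(phi) == 1L,
            is.numeric(roughness), length(roughness) == 1L)
  if (!is.finite(thickness) || thickness <= 0) stop("slab thickness must be > 0")
  if (!is.finite(phi) || phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  if (!is.finite(roughness) || roughness < 0) stop("roughness must be >= 0")
  structure(list(thickness = thickness, phi = phi, roughness = roughness),
            class = "nr_slab")
}

#' Define the solid substrate
#'
#' Silicon fronting with an ultrathin native oxide. Default SLDs are the
#' standard literature values for Si and amorphous SiO2; all fields are
#' configurable. `oxide_hydration` is the solvent volume fraction inside the
#' oxide (default 0, i.e. no solvent penetration).
#'
#' @param fronting_sld Si SLD, 1/Angstrom^2
#' @param oxide_thickness Angstrom
#' @param oxide_sld SiO2 SLD, 1/Angstrom^2
#' @param oxide_roughness Gaussian width of the Si/SiO2 interface, Angstrom
#' @param oxide_hydration solvent volume fraction in the oxide, \[0, 1\]
#' @return an object of class `nr_substrate`
#' @export
substrate <- function(fronting_sld = 2.07e-6, oxide_thickness = 15,
                      oxide_sld = 3.41e-6, oxide_roughness = 3,
                      oxide_hydration = 0) {
  stopifnot(oxide_thickness >= 0, oxide_roughness >= 0,
            oxide_hydration >= 0, oxide_hydration <= 1)
  structure(list(fronting_sld = fronting_sld,
                 oxide_thickness = oxide_thickness,
                 oxide_sld = oxide_sld,
                 oxide_roughness = oxide_roughness,
                 oxide_hydration = oxide_hydration),
            class = "nr_substrate")
}

#' Assemble a layer stack
#'
#' The structural model refined against all contrasts: Si fronting, native
#' oxide, an ordered list of protein slabs (SiO2 surface outward), and the
#' solvent backing.
#'
#' @param slabs list of [slab()] objects, ordered surface -> solvent
#' @param protein a [protein_species()]
#' @param substrate a [substrate()]
#' @return an object of class `nr_stack`
#' @export
layer_stack <- function(slabs, protein, substrate = nrslab::substrate()) {
  if (inherits(slabs, "nr_slab")) slabs <- list(slabs)
  stopifnot(is.list(slabs), all(vapply(slabs, inherits, TRUE, "nr_slab")),
            inherits(protein, "protein_species"),
            inherits(substrate, "nr_substrate"))
  structure(list(substrate = substrate, slabs = slabs, protein = protein),
            class = "nr_stack")
}

#' @export
print.nr_stack <- function(x, ...) {
  cat(sprintf("<nr_stack> %s on Si/SiO2 (%g A oxide), %d slab(s):\n",
              x$protein$name, x$substrate$oxide_thickness, length(x$slabs)))
  for (i in seq_along(x$slabs)) {
    s <- x$slabs[[i]]
    cat(sprintf("  slab %d: tau = %.1f A, phi = %.3f, sigma = %.1f A\n",
                i, s$thickness, s$phi, s$roughness))
  }
  invisible(x)
}

total_thickness <- function(stack) {
  sum(vapply(stack$slabs, `[[`, 0, "thickness"))
}

#' Mix protein and water SLDs for one slab
#'
#' The slab SLD is the volume-fraction weighted sum of the protein and water
#' contributions; protein and water fractions sum to unity.
#'
#' @param phi_protein protein volume fraction in \[0, 1\]
#' @param sld_protein protein SLD at the working contrast, 1/Angstrom^2
#' @param sld_water solvent SLD, 1/Angstrom^2
#' @return slab SLD, 1/Angstrom^2
#' @export
mix_sld <- function(phi_protein, sld_protein, sld_water) {
  if (any(!is.finite(phi_protein)) || any(phi_protein < 0) || any(phi_protein > 1))
    stop("phi_protein must lie in [0, 1]")
  phi_protein * sld_protein + (1 - phi_protein) * sld_water
}

#' Invert a slab SLD to a protein volume fraction
#'
#' Rearranges the two-component mixing rule to recover phi from a fitted slab
#' SLD. Degenerate contrast (protein SLD equal to water SLD) carries no
#' compositional information and is an error. Slab SLDs outside the
#' protein/water interval imply phi outside \[0, 1\]; by default this is an
#' error, with `out_of_range = "clamp"` available for noisy fits (clamps with
#' a warning).
#'
#' @param sld_slab fitted slab SLD, 1/Angstrom^2
#' @param sld_protein,sld_water endpoint SLDs, 1/Angstrom^2
#' @param out_of_range "error" (default) or "clamp"
#' @return protein volume fraction
#' @export
invert_sld <- function(sld_slab, sld_protein, sld_water,
                       out_of_range = c("error", "clamp")) {
  out_of_range <- match.arg(out_of_range)
  if (abs(sld_protein - sld_water) < 1e-15)
    stop("no contrast: protein and water SLDs are equal")
  phi <- (sld_slab - sld_water) / (sld_protein - sld_water)
  bad <- phi < 0 | phi > 1
  if (any(bad)) {
    if (out_of_range == "error")
      stop("slab SLD outside the protein/water interval implies phi outside [0, 1]")
    warning("clamping ", sum(bad), " volume fraction(s) to [0, 1]")
    phi <- pmin(pmax(phi, 0), 1)
  }
  phi
}

#' Protein SLD at an arbitrary solvent contrast
#'
#' Labile hydrogens on amide linkages and polar/charged side chains exchange
#' with solvent deuterium, so the protein SLD rises with the solvent SLD.
#' The dependence is modelled as linear between the pure-H2O and pure-D2O
#' anchor values (the shipped CM4 entries confirm linearity to two decimals).
#'
#' @param protein a [protein_species()]
#' @param solvent_sld solvent SLD, 1/Angstrom^2, within the H2O..D2O range
#' @return protein SLD, 1/Angstrom^2
#' @export
protein_sld_for_solvent <- function(protein, solvent_sld) {
  stopifnot(inherits(protein, "protein_species"))
  if (any(solvent_sld < SLD_H2O - 1e-12) || any(solvent_sld > SLD_D2O + 1e-12))
    stop("solvent SLD outside the H2O/D2O range")
  f <- (solvent_sld - SLD_H2O) / (SLD_D2O - SLD_H2O)
  protein$sld_h2o + f * (protein$sld_d2o - protein$sld_h2o)
}

#' Adsorbed amount per slab and in total
#'
#' Converts slab thickness and protein volume fraction to surface mass
#' density: Gamma_i = tau_i * phi_i * MW / (V * N_A), reported in mg/m^2.
#' Total adsorbed amount is the sum over slabs.
#'
#' @param x an `nr_stack`, or a list of [slab()] objects
#' @param protein a [protein_species()]; taken from the stack if `x` is one
#' @return list with `per_slab` (mg/m^2 vector) and `total`
#' @export
adsorbed_amount <- function(x, protein = NULL) {
  if (inherits(x, "nr_stack")) {
    slabs <- x$slabs
    protein <- x$protein
  } else {
    slabs <- if (inherits(x, "nr_slab")) list(x) else x
    stopifnot(inherits(protein, "protein_species"))
  }
  tau <- vapply(slabs, `[[`, 0, "thickness")
  phi <- vapply(slabs, `[[`, 0, "phi")
  # tau*phi [A] * MW [g/mol] / (V [A^3] * N_A [1/mol]) = g/A^2; 1 g/A^2 = 1e23 mg/m^2
  gamma <- tau * phi * protein$mw / (protein$volume * N_AVOGADRO) * 1e23
  list(per_slab = gamma, total = sum(gamma))
}

#' Volume-fraction profile of a stack
#'
#' phi(z) with z = 0 at the oxide/solvent boundary and z increasing into the
#' solvent. The unbroadened profile is the step function of the slab volume
#' fractions; with `broadened = TRUE` adjacent steps are joined by
#' error-function transitions whose widths are the slab roughnesses (the
#' outermost boundary uses `outer_roughness`). Broadening conserves the
#' integral of phi.
#'
#' @param stack an `nr_stack`
#' @param z grid of distances from the surface, Angstrom; default covers
#'   \[-margin, total thickness + margin\] at `dz` spacing
#' @param broadened logical
#' @param dz,margin grid construction when `z` is NULL
#' @param outer_roughness Gaussian width of the outermost boundary, Angstrom
#' @return object of class `nr_profile` with fields `z` and `phi`
#' @export
volume_fraction_profile <- function(stack, z = NULL, broadened = FALSE,
                                    dz = 0.1, margin = 25, outer_roughness = 0) {
  stopifnot(inherits(stack, "nr_stack"))
  tau <- vapply(stack$slabs, `[[`, 0, "thickness")
  phi <- vapply(stack$slabs, `[[`, 0, "phi")
  sig <- vapply(stack$slabs, `[[`, 0, "roughness")
  edges <- c(0, cumsum(tau))
  if (is.null(z)) z <- seq(-margin, sum(tau) + margin, by = dz)
  stopifnot(length(z) > 1)
  p <- numeric(length(z))
  if (!broadened) {
    for (i in seq_along(tau))
      p <- p + phi[i] * (z >= edges[i] & z < edges[i + 1])
  } else {
    sig_b <- c(sig, outer_roughness)  # boundary widths, inner -> outer
    cdf <- function(z0, s) if (s > 0) pnorm(z, mean = z0, sd = s) else as.numeric(z >= z0)
    for (i in seq_along(tau))
      p <- p + phi[i] * (cdf(edges[i], sig_b[i]) - cdf(edges[i + 1], sig_b[i + 1]))
  }
  structure(list(z = z, phi = p), class = "nr_profile")
}

#' @export
print.nr_profile <- function(x, ...) {
  cat(sprintf("<nr_profile> %d points, z in [%.1f, %.1f] A, integral %.2f A\n",
              length(x$z), min(x$z), max(x$z), trapz_(x$z, x$phi)))
  invisible(x)
}

# trapezoidal integral
trapz_ <- function(x, y) sum(diff(x) * (head_(y, -1) + tail_(y, -1)) / 2)
head_ <- function(x, n) utils::head(x, n)
tail_ <- function(x, n) utils::tail(x, n)

#' Mass-center-to-surface distance
#'
#' First moment of the interfacial profile measured from the SiO2 surface:
#' integral(z * phi) / integral(phi). For an `nr_stack` the step-profile
#' moment is evaluated analytically; for an `nr_profile` numerically by the
#' trapezoidal rule.
#'
#' @param x an `nr_stack` or `nr_profile`
#' @return distance, Angstrom
#' @export
mass_center_distance <- function(x) UseMethod("mass_center_distance")

#' @export
mass_center_distance.nr_stack <- function(x) {
  tau <- vapply(x$slabs, `[[`, 0, "thickness")
  phi <- vapply(x$slabs, `[[`, 0, "phi")
  edges <- c(0, cumsum(tau))
  w <- tau * phi
  if (sum(w) <= 0) stop("empty profile: integral of phi is zero")
  centers <- (head_(edges, -1) + tail_(edges, -1)) / 2
  sum(w * centers) / sum(w)
}

#' @export
mass_center_distance.nr_profile <- function(x) {
  denom <- trapz_(x$z, x$phi)
  if (denom <= 0) stop("empty profile: integral of phi is zero")
  trapz_(x$z, x$z * x$phi) / denom
}

#' Summarize a layer stack in the standard report layout
#'
#' Per-slab and total thickness, volume fraction (%), adsorbed amount
#' (mg/m^2), per-slab mass fractions, and the mass-center distance. The
#' "average" volume fraction is the thickness-weighted mean over slabs.
#'
#' @param stack an `nr_stack`
#' @return object of class `layer_summary`
#' @export
layer_summary <- function(stack) {
  stopifnot(inherits(stack, "nr_stack"))
  tau <- vapply(stack$slabs, `[[`, 0, "thickness")
  phi <- vapply(stack$slabs, `[[`, 0, "phi")
  gam <- adsorbed_amount(stack)
  mass_frac <- if (gam$total > 0) gam$per_slab / gam$total else rep(NA_real_, length(tau))
  structure(list(
    protein = stack$protein$name,
    n_slabs = length(tau),
    thickness = tau,
    total_thickness = sum(tau),
    volume_fraction_pct = 100 * phi,
    mean_volume_fraction_pct = 100 * sum(tau * phi) / sum(tau),
    adsorbed_amount = gam$per_slab,
    total_adsorbed_amount = gam$total,
    mass_fraction = mass_frac,
    mass_center = mass_center_distance(stack)
  ), class = "layer_summary")
}

#' @export
print.layer_summary <- function(x, ...) {
  cat(sprintf("<layer_summary> %s, %d slab(s)\n", x$protein, x$n_slabs))
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("mass center: %.1f A from the SiO2 surface\n", x$mass_center))
  invisible(x)
}

#' @export
as.data.frame.layer_summary <- function(x, ...) {
  data.frame(
    slab = c(as.character(seq_len(x$n_slabs)), "total/average"),
    thickness_A = c(x$thickness, x$total_thickness),
    volume_fraction_pct = c(x$volume_fraction_pct, x$mean_volume_fraction_pct),
    adsorbed_amount_mg_m2 = c(x$adsorbed_amount, x$total_adsorbed_amount),
    mass_fraction = c(x$mass_fraction, 1),
    stringsAsFactors = FALSE
  )
}

#' Write a layer summary as CSV
#'
#' Columns mirror the standard per-slab report: thickness, volume fraction
#' (%), adsorbed amount (mg/m^2), mass fraction, with a total/average row.
#'
#' @param x a `layer_summary`
#' @param path output CSV path
#' @export
write_layer_summary <- function(x, path) {
  stopifnot(inherits(x, "layer_summary"))
  write.table(as.data.frame(x), path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
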