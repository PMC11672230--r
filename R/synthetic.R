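# Synthetic data generation at desk scale: multi-contrast reflectivity
# datasets with counting-statistics-like noise from known stacks, and
# pseudo-protein atom sets near a planar silica surface. Every generated
# dataset carries its ground truth so recovery can be checked.

#' The three standard water contrasts
#'
#' D2O (6.35e-6), contrast-matched CM4 water (4.0e-6) and H2O (-0.56e-6),
#' all in 1/Angstrom^2.
#'
#' @return list of [contrast_solvent()]
#' @export
default_contrasts <- function() {
  list(contrast_solvent("D2O", SLD_D2O),
       contrast_solvent("CM4", 4.0e-6),
       contrast_solvent("H2O", SLD_H2O))
}

#' Reference two-slab antibody stacks
#'
#' The fitted saturated COE-3 layer structures at the two buffer pH values:
#' at pH 5.5 slabs (42.5 A, phi 0.441) and (20.0 A, phi 0.183); at pH 9
#' slabs (35.0 A, phi 0.405) and (43.0 A, phi 0.187). COE-3 molecular
#' constants come from the shipped table.
#'
#' @param ph_label "5.5" or "9"
#' @param substrate a [substrate()]
#' @return an `nr_stack`
#' @export
make_table1_stack <- function(ph_label = c("5.5", "9"),
                              substrate = nrslab::substrate()) {
  ph_label <- match.arg(ph_label)
  pars <- switch(ph_label,
                 "5.5" = list(tau = c(42.5, 20.0), phi = c(0.441, 0.183)),
                 "9"   = list(tau = c(35.0, 43.0), phi = c(0.405, 0.187)))
  slabs <- list(slab(pars$tau[1], pars$phi[1], roughness = 3),
                slab(pars$tau[2], pars$phi[2], roughness = 0))
  layer_stack(slabs, get_protein("COE-3"), substrate)
}

#' Define a measurement noise model
#'
#' Gaussian noise with per-point sigma = max(relative_error_floor * R,
#' background_level), emulating the counting statistics of a reflectometer.
#' Identical seeds give identical datasets.
#'
#' @param relative_error_floor fractional error floor on R
#' @param background_level reflectivity scale below which the absolute
#'   error floor takes over
#' @param seed integer seed
#' @return object of class `noise_model`
#' @export
noise_model <- function(relative_error_floor = 0.02, background_level = 5e-7,
                        seed = 1) {
  stopifnot(relative_error_floor >= 0, background_level >= 0)
  structure(list(relative_error_floor = relative_error_floor,
                 background_level = background_level, seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a multi-contrast reflectivity experiment
#'
#' Forward-models each contrast from the stack (resolution-smeared, with
#' instrument scale and background), then adds seeded Gaussian noise with
#' sigma = max(floor * R, background_level). The generating parameters are
#' attached as ground truth.
#'
#' @param stack an `nr_stack` (the ground truth)
#' @param contrasts list of [contrast_solvent()]
#' @param q_range c(min, max), 1/Angstrom
#' @param n_points number of log-spaced Q points (>= 20)
#' @param noise a [noise_model()]
#' @param instrument an [instrument_model()] applied to every contrast
#' @return list with `datasets` (list of [contrast_dataset()]) and
#'   `truth` (stack parameters, noise and instrument settings)
#' @export
simulate_contrast_set <- function(stack, contrasts = default_contrasts(),
                                  q_range = c(0.008, 0.25), n_points = 80,
                                  noise = noise_model(),
                                  instrument = instrument_model()) {
  stopifnot(inherits(stack, "nr_stack"), n_points >= 20,
            inherits(noise, "noise_model"))
  q <- exp(seq(log(q_range[1]), log(q_range[2]), length.out = n_points))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(noise$seed)
  datasets <- lapply(contrasts, function(cs) {
    m <- model_reflectivity(stack, cs, q, instrument)
    dr <- pmax(noise$relative_error_floor * m$r, noise$background_level)
    r_obs <- if (noise$relative_error_floor > 0 || noise$background_level > 0)
      m$r + rnorm(length(q)) * dr else m$r
    contrast_dataset(reflectivity_curve(q, r_obs, dr = dr,
                                        dq = instrument$dq_over_q * q),
                     cs, instrument)
  })
  truth <- list(
    protein = stack$protein$name,
    thickness = vapply(stack$slabs, `[[`, 0, "thickness"),
    phi = vapply(stack$slabs, `[[`, 0, "phi"),
    roughness = vapply(stack$slabs, `[[`, 0, "roughness"),
    substrate = unclass(stack$substrate),
    summary = unclass(layer_summary(stack)),
    contrasts = vapply(contrasts, function(x) x$sld, 0),
    q_range = q_range, n_points = n_points,
    noise = unclass(noise), instrument = unclass(instrument))
  list(datasets = datasets, truth = truth)
}

#' Write a simulated contrast set to disk
#'
#' One ASCII reflectivity file per contrast (readable by
#' [read_reflectivity()]) plus a JSON ground-truth sidecar.
#'
#' @param sim result of [simulate_contrast_set()]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisible character vector of written paths
#' @export
write_contrast_set <- function(sim, dir, prefix = "nr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (d in sim$datasets) {
    p <- file.path(dir, sprintf("%s_%s.dat", prefix, d$solvent$name))
    write_reflectivity(d$curve, p,
                       header = c(paste("solvent:", d$solvent$name),
                                  paste("solvent_sld:", format(d$solvent$sld))))
    paths <- c(paths, p)
  }
  tp <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(sim$truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tp))
}

#' Read a contrast set written by [write_contrast_set()]
#'
#' @param dir directory
#' @param prefix file-name prefix
#' @param contrasts list of [contrast_solvent()] to look for
#' @param instrument an [instrument_model()] to attach
#' @return list with `datasets` and `truth` (NULL if no sidecar)
#' @export
read_contrast_set <- function(dir, prefix = "nr", contrasts = default_contrasts(),
                              instrument = instrument_model()) {
  datasets <- lapply(contrasts, function(cs) {
    p <- file.path(dir, sprintf("%s_%s.dat", prefix, cs$name))
    if (!file.exists(p)) stop("missing reflectivity file: ", p)
    contrast_dataset(read_reflectivity(p), cs, instrument)
  })
  tp <- file.path(dir, paste0(prefix, "_truth.json"))
  truth <- if (file.exists(tp)) jsonlite::read_json(tp, simplifyVector = TRUE)
  list(datasets = datasets, truth = truth)
}

# Sample n points uniformly inside an axis-aligned ellipsoid with the given
# semi-axes, centered at `center`.
sample_ellipsoid <- function(n, semi_axes, center) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m <- m / sqrt(rowSums(m^2)) * runif(n)^(1 / 3)
  sweep(m %*% diag(semi_axes), 2, center, "+")
}

#' Generate a pseudo-antibody atom set near a surface
#'
#' Three ellipsoidal point clouds mimic the two Fab fragments (47.3 kDa
#' each) and the Fc fragment (50.2 kDa; total 144.8 kDa). In the "flat_on"
#' layout all three fragments lie at the surface with their short axes
#' along the surface normal (the compact, pH 5.5-like state); in "tilted"
#' the Fc is displaced along z above the Fabs (the extended, pH 9-like
#' state), giving a visibly larger 95%-mass extent. The mass center is
#' placed exactly at `center_z` above the surface plane z = 0.
#'
#' @param layout "flat_on" or "tilted"
#' @param center_z mass-center height above the surface, Angstrom (> 0)
#' @param seed integer seed
#' @param n_per_fragment sampled points per fragment
#' @return an `atom_set` with group "protein"
#' @export
make_pseudo_protein <- function(layout = c("flat_on", "tilted"),
                                center_z = 27.5, seed = 1,
                                n_per_fragment = 1200) {
  layout <- match.arg(layout)
  stopifnot(center_z > 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  mass_fab <- 47300; mass_fc <- 144800 - 2 * 47300
  if (layout == "flat_on") {
    # all fragments rest on the surface: Fab minor axes (~45 A) along the
    # surface normal, Fc long axis (~70 A) near-normal beside them
    frags <- list(
      sample_ellipsoid(n_per_fragment, c(35, 25, 22.5), c(-45, 0, 22.5)),
      sample_ellipsoid(n_per_fragment, c(35, 25, 22.5), c(45, 0, 22.5)),
      sample_ellipsoid(n_per_fragment, c(22.5, 25, 35), c(0, 40, 35)))
  } else {
    # Fabs anchored at the surface; the Fc lifted along the normal into
    # the diffuse outer region (natural mass center ~31, matching the
    # extended layer)
    frags <- list(
      sample_ellipsoid(n_per_fragment, c(35, 25, 17.5), c(-30, 0, 17.5)),
      sample_ellipsoid(n_per_fragment, c(35, 25, 17.5), c(30, 0, 17.5)),
      sample_ellipsoid(n_per_fragment, c(25, 25, 21.5), c(0, 0, 56.5)))
  }
  xyz <- do.call(rbind, frags)
  mass <- rep(c(mass_fab, mass_fab, mass_fc) / n_per_fragment,
              each = n_per_fragment)
  zc <- sum(mass * xyz[, 3]) / sum(mass)
  xyz[, 3] <- xyz[, 3] - zc + center_z
  atom_set(xyz, mass,
           label = rep(c("Fab1", "Fab2", "Fc"), each = n_per_fragment),
           group = rep("protein", nrow(xyz)))
}

#' Generate a planar silica surface atom set
#'
#' A simple cubic grid of pseudo-silica atoms (mean mass of SiO2 per atom)
#' spanning `lx` by `ly` laterally with `n_layers` layers at and below
#' z = 0, tagged "surface". Used as the partner group for contact counts.
#'
#' @param lx,ly lateral extent, Angstrom
#' @param spacing grid spacing, Angstrom
#' @param n_layers atom layers stacked downward from z = 0
#' @return an `atom_set` with group "surface"
#' @export
make_silica_surface <- function(lx = 120, ly = 120, spacing = 3, n_layers = 2) {
  xs <- seq(-lx / 2, lx / 2, by = spacing)
  ys <- seq(-ly / 2, ly / 2, by = spacing)
  zs <- -spacing * (seq_len(n_layers) - 1)
  g <- expand.grid(x = xs, y = ys, z = zs)
  atom_set(as.matrix(g), rep(20.03, nrow(g)),  # SiO2 mass per atom (60.08/3)
           group = rep("surface", nrow(g)))
}
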