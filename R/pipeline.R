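# Run-level orchestration: a single YAML run configuration drives
# simulation, fitting, bootstrap and simulation-vs-reflectivity comparison.
# The numbered scripts under analysis/ are thin drivers over these
# functions; a run is reproducible from the config and its seeds alone.

#' Read and validate a run configuration
#'
#' A single YAML document with sections `output_dir`, `seed`, `protein`,
#' `stack`, `noise`, `instrument`, `simulate`, `fit`, `bootstrap`, `md`.
#' Missing required fields raise an error naming the field; optional
#' sections fall back to package defaults.
#'
#' @param path YAML file
#' @return object of class `run_config` (a validated named list)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (field in c("output_dir", "seed", "protein"))
    if (is.null(cfg[[field]])) stop("config missing required field '", field, "'")
  defaults <- list(
    stack = list(ph_label = "5.5"),
    noise = list(relative_error_floor = 0.02, background_level = 5e-7),
    instrument = list(scale = 1, background = 5e-7, dq_over_q = 0.04),
    simulate = list(q_min = 0.008, q_max = 0.25, n_points = 80, prefix = "nr"),
    fit = list(n_slabs = 2, max_slabs = 3, threshold = 0.10, n_starts = 16),
    bootstrap = list(n_resamples = 200, method = "points"),
    md = list(layout = "flat_on", center_z = 27.5, contact_cutoff = 5,
              n_per_fragment = 1200, bin_width = 2))
  for (s in names(defaults))
    cfg[[s]] <- modifyList(defaults[[s]], if (is.null(cfg[[s]])) list() else cfg[[s]])
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

config_stack <- function(config) {
  st <- config$stack
  if (!is.null(st$ph_label)) return(make_table1_stack(as.character(st$ph_label)))
  if (is.null(st$thickness) || is.null(st$phi))
    stop("config 'stack' needs either ph_label or thickness + phi")
  rough <- if (is.null(st$roughness)) c(3, rep(0, length(st$thickness) - 1)) else st$roughness
  slabs <- lapply(seq_along(st$thickness), function(i)
    slab(st$thickness[[i]], st$phi[[i]], rough[[i]]))
  layer_stack(slabs, get_protein(config$protein))
}

run_log <- function(config, lines) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$output_dir, "run.log")
  cat(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), lines, "\n"),
      file = path, append = TRUE, sep = "")
  invisible(path)
}

#' Simulate the datasets described by a run configuration
#'
#' Wraps [simulate_contrast_set()] and [write_contrast_set()]: generates
#' the three-contrast experiment for the configured stack and writes the
#' reflectivity files plus the JSON ground truth under
#' `output_dir/simulated/`.
#'
#' @param config a [read_run_config()] object
#' @return invisible list with `datasets`, `truth`, `paths`
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stack <- config_stack(config)
  sim <- simulate_contrast_set(
    stack,
    q_range = c(config$simulate$q_min, config$simulate$q_max),
    n_points = config$simulate$n_points,
    noise = noise_model(config$noise$relative_error_floor,
                        config$noise$background_level, seed = config$seed),
    instrument = instrument_model(config$instrument$scale,
                                  config$instrument$background,
                                  config$instrument$dq_over_q))
  paths <- write_contrast_set(sim, file.path(config$output_dir, "simulated"),
                              prefix = config$simulate$prefix)
  run_log(config, sprintf("simulated %d contrasts (prefix %s, seed %d)",
                          length(sim$datasets), config$simulate$prefix, config$seed))
  invisible(list(datasets = sim$datasets, truth = sim$truth, paths = paths))
}

#' Fit the datasets described by a run configuration
#'
#' Reads the simulated (or measured) contrast set, optionally selects the
#' slab count by the elbow rule (`fit$n_slabs: auto`), refines the model
#' simultaneously against all contrasts, bootstraps uncertainties, and
#' writes the fit JSON, a per-slab summary CSV in the standard report
#' layout, and a chi-squared log.
#'
#' @param config a [read_run_config()] object
#' @param datasets optional list of [contrast_dataset()] (read from
#'   `output_dir/simulated/` when NULL)
#' @return invisible list with `fit`, `bootstrap`, `selection`
#' @export
run_fit <- function(config, datasets = NULL) {
  stopifnot(inherits(config, "run_config"))
  protein <- get_protein(config$protein)
  if (is.null(datasets)) {
    rs <- read_contrast_set(file.path(config$output_dir, "simulated"),
                            prefix = config$simulate$prefix,
                            instrument = instrument_model(
                              config$instrument$scale, config$instrument$background,
                              config$instrument$dq_over_q))
    datasets <- rs$datasets
  }
  selection <- NULL
  n_slabs <- config$fit$n_slabs
  if (identical(n_slabs, "auto")) {
    selection <- select_slab_count(datasets, protein,
                                   max_slabs = config$fit$max_slabs,
                                   threshold = config$fit$threshold,
                                   seed = config$seed,
                                   n_starts = config$fit$n_starts)
    n_slabs <- selection$chosen
    run_log(config, sprintf("elbow selection: chose %d slab(s); chi2 = %s",
                            n_slabs,
                            paste(signif(selection$table$chi2_global, 4),
                                  collapse = ", ")))
  }
  fit <- fit_simultaneous(datasets, fit_spec(n_slabs = n_slabs), protein,
                          seed = config$seed, n_starts = config$fit$n_starts)
  run_log(config, c(fit$trace,
                    sprintf("final global chi2 %.6g (%s)", fit$chi2_global,
                            if (fit$converged) "converged" else "NOT converged")))
  boot <- NULL
  if (!is.null(config$bootstrap$n_resamples) && config$bootstrap$n_resamples > 0) {
    boot <- bootstrap_fit(fit, n_resamples = config$bootstrap$n_resamples,
                          seed = config$seed, method = config$bootstrap$method)
    run_log(config, sprintf("bootstrap: %d resamples, %d failed",
                            boot$n_resamples, boot$n_fail))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_layer_summary(fit$summary,
                      file.path(config$output_dir,
                                paste0(config$simulate$prefix, "_summary.csv")))
  out <- list(par = as.list(fit$par), chi2_global = fit$chi2_global,
              chi2_per_contrast = as.list(fit$chi2_per_contrast),
              converged = fit$converged,
              summary = unclass(fit$summary))
  if (!is.null(boot)) out$bootstrap_intervals <- boot$intervals
  jsonlite::write_json(out, file.path(config$output_dir,
                                      paste0(config$simulate$prefix, "_fit.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(fit = fit, bootstrap = boot, selection = selection))
}

#' Compare a conformation with a reflectivity profile per the run config
#'
#' Builds (or reads) the adsorbed conformation, computes its density
#' profile, mass-center distance and surface contact count, compares the
#' profile with the configured stack's volume-fraction profile, and writes
#' a JSON report. When no surface atoms are available the contact count is
#' omitted with a warning.
#'
#' @param config a [read_run_config()] object
#' @param stack optional `nr_stack` (defaults to the configured stack)
#' @return invisible list with the report fields
#' @export
run_mdcompare <- function(config, stack = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(stack)) stack <- config_stack(config)
  md <- config$md
  atoms <- if (!is.null(md$coordinates)) {
    if (grepl("\\.pdb$", md$coordinates, ignore.case = TRUE))
      read_pdb_atoms(md$coordinates) else read_xyz_mass(md$coordinates)
  } else {
    make_pseudo_protein(md$layout, center_z = md$center_z, seed = config$seed,
                        n_per_fragment = md$n_per_fragment)
  }
  prof_md <- density_profile(atoms, bin_width = md$bin_width)
  prof_nr <- volume_fraction_profile(stack)
  cmp <- compare_profiles(prof_md, prof_nr)
  report <- list(
    mass_center_md = md_mass_center_distance(atoms),
    mass_center_nr = mass_center_distance(stack),
    center_diff = cmp$center_diff,
    extent95_md = cmp$extent_md, extent95_nr = cmp$extent_nr,
    overlap = cmp$overlap)
  if (isTRUE(md$use_surface) || is.null(md$coordinates)) {
    surf <- make_silica_surface()
    report$contact_count <- contact_count(atoms, surf, cutoff = md$contact_cutoff)
  } else {
    warning("no surface atoms configured: contact count omitted")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report,
                       file.path(config$output_dir, "md_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  run_log(config, sprintf("md comparison: centers %.1f (MD) vs %.1f (NR) A, overlap %.3f",
                          report$mass_center_md, report$mass_center_nr,
                          report$overlap))
  invisible(report)
}
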