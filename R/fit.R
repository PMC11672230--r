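# Simultaneous least-squares refinement of one structural model against
# multiple isotopic-contrast reflectivity datasets, with slab-count
# selection (elbow rule) and bootstrap uncertainties.

#' Bind a reflectivity curve to a solvent contrast
#'
#' @param curve an `nr_curve`; uncertainties (`dr`) should be present for
#'   weighted fitting
#' @param solvent a [contrast_solvent()]
#' @param instrument an [instrument_model()] describing how the curve was
#'   (or should be) measured
#' @return object of class `contrast_dataset`
#' @export
contrast_dataset <- function(curve, solvent, instrument = instrument_model()) {
  stopifnot(inherits(curve, "nr_curve"), inherits(solvent, "contrast_solvent"),
            inherits(instrument, "nr_instrument"))
  structure(list(curve = curve, solvent = solvent, instrument = instrument),
            class = "contrast_dataset")
}

#' @export
print.contrast_dataset <- function(x, ...) {
  cat(sprintf("<contrast_dataset> %s, %d points\n", x$solvent$name, length(x$curve$q)))
  invisible(x)
}

#' Specify the free parameters of a simultaneous fit
#'
#' Structural parameters (per-slab thickness and protein volume fraction,
#' plus fixed interfacial roughnesses) are shared across all contrasts;
#' only instrument terms (background, optionally scale) are per-contrast.
#'
#' @param n_slabs number of protein slabs
#' @param bounds named list of length-2 ranges for `tau` (Angstrom), `phi`,
#'   `background`, `scale`
#' @param fit_background fit one additive background per contrast
#' @param fit_scale fit one multiplicative scale per contrast (otherwise
#'   fixed at the dataset instrument value)
#' @param roughness per-slab substrate-side interfacial widths, Angstrom
#'   (fixed, not fitted); default 3 at the oxide/protein interface and 0
#'   between protein slabs
#' @return object of class `fit_spec`
#' @export
fit_spec <- function(n_slabs = 2,
                     bounds = list(tau = c(5, 120), phi = c(0, 0.7),
                                   background = c(0, 1e-5), scale = c(0.9, 1.1)),
                     fit_background = TRUE, fit_scale = FALSE,
                     roughness = NULL) {
  stopifnot(n_slabs >= 1)
  def <- list(tau = c(5, 120), phi = c(0, 0.7),
              background = c(0, 1e-5), scale = c(0.9, 1.1))
  bounds <- modifyList(def, bounds)
  if (is.null(roughness)) roughness <- c(3, rep(0, n_slabs - 1))
  stopifnot(length(roughness) == n_slabs, all(roughness >= 0))
  structure(list(n_slabs = n_slabs, bounds = bounds,
                 fit_background = fit_background, fit_scale = fit_scale,
                 roughness = roughness),
            class = "fit_spec")
}

# ---- internal fitting machinery ------------------------------------------

# Parameter vector layout: tau_1..n, phi_1..n, then per-contrast background
# and per-contrast scale if fitted.
par_names <- function(spec, n_contrasts) {
  nm <- c(paste0("tau", seq_len(spec$n_slabs)),
          paste0("phi", seq_len(spec$n_slabs)))
  if (spec$fit_background) nm <- c(nm, paste0("background", seq_len(n_contrasts)))
  if (spec$fit_scale) nm <- c(nm, paste0("scale", seq_len(n_contrasts)))
  nm
}

par_bounds <- function(spec, n_contrasts) {
  lo <- c(rep(spec$bounds$tau[1], spec$n_slabs), rep(spec$bounds$phi[1], spec$n_slabs))
  hi <- c(rep(spec$bounds$tau[2], spec$n_slabs), rep(spec$bounds$phi[2], spec$n_slabs))
  if (spec$fit_background) {
    lo <- c(lo, rep(spec$bounds$background[1], n_contrasts))
    hi <- c(hi, rep(spec$bounds$background[2], n_contrasts))
  }
  if (spec$fit_scale) {
    lo <- c(lo, rep(spec$bounds$scale[1], n_contrasts))
    hi <- c(hi, rep(spec$bounds$scale[2], n_contrasts))
  }
  nm <- par_names(spec, n_contrasts)
  list(lower = setNames(lo, nm), upper = setNames(hi, nm))
}

# Precompute everything that does not change between objective evaluations.
fit_context <- function(datasets, spec, protein, substrate, n_smear = 13) {
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, TRUE, "contrast_dataset")),
            inherits(protein, "protein_species"),
            inherits(substrate, "nr_substrate"))
  rule <- smear_rule(n_smear)
  ctx <- list(spec = spec, protein = protein, substrate = substrate,
              n_contrasts = length(datasets), rule_w = rule$w)
  ctx$per <- lapply(datasets, function(d) {
    q <- d$curve$q
    dqq <- d$instrument$dq_over_q
    if (dqq > 0) {
      qq <- outer(q, 1 + (dqq / 2.355) * rule$x)
      qq[qq < 1e-6] <- 1e-6
      qq <- as.numeric(qq)
    } else qq <- q
    dr <- d$curve$dr
    if (is.null(dr) || any(dr <= 0)) {
      warning("missing or zero uncertainties in contrast '", d$solvent$name,
              "': falling back to unweighted residuals")
      dr <- rep(1, length(q))
    }
    list(q = q, qq = qq, smeared = dqq > 0, r = d$curve$r, dr = dr,
         n = length(q),
         solvent_sld = d$solvent$sld,
         protein_sld = protein_sld_for_solvent(protein, d$solvent$sld),
         oxide_sld = mix_sld(1 - substrate$oxide_hydration,
                             substrate$oxide_sld, d$solvent$sld),
         scale0 = d$instrument$scale, bg0 = d$instrument$background)
  })
  ctx$n_total <- sum(vapply(ctx$per, `[[`, 0L, "n"))
  ctx
}

# Model reflectivity for contrast ic at parameter vector p.
ctx_model <- function(ctx, p, ic) {
  ns <- ctx$spec$n_slabs
  tau <- p[seq_len(ns)]
  phi <- p[ns + seq_len(ns)]
  ofs <- 2 * ns
  bg <- if (ctx$spec$fit_background) p[ofs + ic] else ctx$per[[ic]]$bg0
  if (ctx$spec$fit_background) ofs <- ofs + ctx$n_contrasts
  sc <- if (ctx$spec$fit_scale) p[ofs + ic] else ctx$per[[ic]]$scale0
  pc <- ctx$per[[ic]]
  sld <- c(ctx$substrate$fronting_sld, pc$oxide_sld,
           phi * pc$protein_sld + (1 - phi) * pc$solvent_sld, pc$solvent_sld)
  thick <- c(0, ctx$substrate$oxide_thickness, tau, 0)
  rough <- c(ctx$substrate$oxide_roughness, ctx$spec$roughness, 0)
  rm <- abeles_kernel(pc$qq, sld, thick, rough)
  if (pc$smeared) rm <- as.numeric(matrix(rm, nrow = pc$n) %*% ctx$rule_w)
  sc * rm + bg
}

# Weighted residual vector across all contrasts; w is a list of per-contrast
# per-point multiplicities (bootstrap weights), or NULL.
ctx_residuals <- function(ctx, p, w = NULL) {
  unlist(lapply(seq_len(ctx$n_contrasts), function(ic) {
    pc <- ctx$per[[ic]]
    res <- (ctx_model(ctx, p, ic) - pc$r) / pc$dr
    if (!is.null(w)) res * sqrt(w[[ic]]) else res
  }), use.names = FALSE)
}

ctx_chi2 <- function(ctx, p) {
  per <- vapply(seq_len(ctx$n_contrasts), function(ic) {
    pc <- ctx$per[[ic]]
    sum(((ctx_model(ctx, p, ic) - pc$r) / pc$dr)^2)
  }, 0)
  list(per_contrast = per / vapply(ctx$per, `[[`, 0L, "n"),
       global = sum(per) / ctx$n_total)
}

lm_refine <- function(ctx, start, lower, upper, maxiter = 100, w = NULL) {
  # the iteration cap is deliberate (multistart / bootstrap refits); the
  # convergence state is propagated through $info, so the cap warning from
  # nls.lm is muffled rather than repeated hundreds of times
  withCallingHandlers(
    minpack.lm::nls.lm(par = start,
                       lower = lower, upper = upper,
                       fn = function(p) ctx_residuals(ctx, p, w),
                       control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                                            ftol = 1e-12,
                                                            ptol = 1e-10)),
    warning = function(w) {
      if (grepl("maxiter", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# ---- public fitting API ---------------------------------------------------

#' Normalized chi-squared of model curves against datasets
#'
#' chi^2 = sum(((R_model - R_data) / dR)^2) / N per contrast; the global
#' value is the sum of squared residuals over all contrasts divided by the
#' total number of points. If a model curve is tabulated on a different Q
#' grid it is interpolated onto the data grid (linear in log R where
#' positive). Missing or zero uncertainties trigger an unweighted fallback
#' with a warning.
#'
#' @param model_curves an `nr_curve` or list of them, one per dataset
#' @param datasets a `contrast_dataset` or list of them
#' @return list with `per_contrast` and `global`
#' @export
chi_squared <- function(model_curves, datasets) {
  if (inherits(model_curves, "nr_curve")) model_curves <- list(model_curves)
  if (inherits(datasets, "contrast_dataset")) datasets <- list(datasets)
  stopifnot(length(model_curves) == length(datasets))
  ss <- ns <- numeric(length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]; m <- model_curves[[i]]
    rm <- if (length(m$q) == length(d$curve$q) && all(m$q == d$curve$q)) m$r
          else interp_reflectivity(m$q, m$r, d$curve$q)
    dr <- d$curve$dr
    if (is.null(dr) || any(dr <= 0)) {
      warning("missing or zero uncertainties in contrast '", d$solvent$name,
              "': unweighted chi-squared")
      dr <- rep(1, length(d$curve$q))
    }
    ss[i] <- sum(((rm - d$curve$r) / dr)^2)
    ns[i] <- length(d$curve$q)
  }
  list(per_contrast = ss / ns, global = sum(ss) / sum(ns))
}

#' Simultaneously refine one slab model against several contrasts
#'
#' Minimizes the global normalized chi-squared over shared structural
#' parameters (per-slab thickness and volume fraction) and per-contrast
#' instrument terms. Per-contrast slab SLDs are recomputed at every
#' evaluation from the two-component mixing rule with the H/D-adjusted
#' protein SLD. The search is a seeded Latin-hypercube multistart over the
#' parameter bounds, each start polished by bounded Levenberg-Marquardt;
#' results are deterministic for a given seed.
#'
#' @param datasets list of [contrast_dataset()]
#' @param spec a [fit_spec()]
#' @param protein a [protein_species()]
#' @param substrate a [substrate()] (oxide parameters held fixed)
#' @param seed integer seed for the multistart
#' @param n_starts number of Latin-hypercube starting points
#' @param start optional named numeric vector used as an additional start
#'   (e.g. a previous fit); with `n_starts = 0` it is the only start
#' @param maxiter Levenberg-Marquardt iteration cap per start
#' @return object of class `nr_fit`: best-fit parameters, per-contrast and
#'   global normalized chi-squared, fitted `nr_stack` and [layer_summary()]
#' @export
fit_simultaneous <- function(datasets, spec = fit_spec(), protein,
                             substrate = nrslab::substrate(),
                             seed = 1, n_starts = 16, start = NULL,
                             maxiter = 100) {
  ctx <- fit_context(datasets, spec, protein, substrate)
  b <- par_bounds(spec, ctx$n_contrasts)
  npar <- length(b$lower)
  starts <- list()
  if (n_starts > 0) {
    set.seed(seed)
    u <- lhs::randomLHS(n_starts, npar)
    for (i in seq_len(n_starts))
      starts[[i]] <- setNames(b$lower + u[i, ] * (b$upper - b$lower), names(b$lower))
    # midpoint start as a deterministic anchor
    starts[[n_starts + 1]] <- (b$lower + b$upper) / 2
  }
  if (!is.null(start)) {
    full <- (b$lower + b$upper) / 2
    full[intersect(names(start), names(full))] <-
      start[intersect(names(start), names(full))]
    starts[[length(starts) + 1]] <- pmin(pmax(full, b$lower), b$upper)
  }
  if (!length(starts)) stop("no starting points: give n_starts > 0 or start")
  best <- NULL
  trace <- character()
  for (i in seq_along(starts)) {
    f <- tryCatch(lm_refine(ctx, starts[[i]], b$lower, b$upper, maxiter),
                  error = function(e) NULL)
    if (is.null(f)) next
    chi2 <- sum(f$fvec^2) / ctx$n_total
    if (is.null(best) || chi2 < best$chi2) {
      best <- list(par = setNames(f$par, names(b$lower)), chi2 = chi2,
                   info = f$info, message = f$message)
      trace <- c(trace, sprintf("start %d: global chi2 improved to %.6g", i, chi2))
    }
  }
  if (is.null(best))
    stop("no start converged: all Levenberg-Marquardt attempts failed")
  converged <- best$info %in% 1:4
  if (!converged)
    warning("fit did not formally converge (info = ", best$info,
            "); reporting best-found state")
  chi <- ctx_chi2(ctx, best$par)
  stack <- stack_from_par(best$par, spec, protein, substrate)
  structure(list(par = best$par, chi2_global = chi$global,
                 chi2_per_contrast = setNames(chi$per_contrast,
                   vapply(datasets, function(d) d$solvent$name, "")),
                 stack = stack, summary = layer_summary(stack),
                 converged = converged, trace = trace,
                 spec = spec, protein = protein, substrate = substrate,
                 datasets = datasets, seed = seed),
            class = "nr_fit")
}

# Rebuild an nr_stack from a fitted parameter vector.
stack_from_par <- function(p, spec, protein, substrate) {
  ns <- spec$n_slabs
  slabs <- lapply(seq_len(ns), function(i)
    slab(p[[i]], p[[ns + i]], roughness = spec$roughness[i]))
  layer_stack(slabs, protein, substrate)
}

#' @export
print.nr_fit <- function(x, ...) {
  cat(sprintf("<nr_fit> %d slab(s), %d contrast(s), global chi2 = %.4g%s\n",
              x$spec$n_slabs, length(x$datasets), x$chi2_global,
              if (x$converged) "" else " (NOT converged)"))
  print(x$summary)
  invisible(x)
}

#' Fitted model curves of an nr_fit
#'
#' @param fit an `nr_fit`
#' @return list of `nr_curve`, one per dataset, on the data Q grids
#' @export
fitted_curves <- function(fit) {
  stopifnot(inherits(fit, "nr_fit"))
  ctx <- fit_context(fit$datasets, fit$spec, fit$protein, fit$substrate)
  lapply(seq_along(fit$datasets), function(ic)
    reflectivity_curve(ctx$per[[ic]]$q, ctx_model(ctx, fit$par, ic)))
}

#' Choose the slab count by the elbow rule
#'
#' Fits n = 1..max_slabs slabs and returns the smallest n whose relative
#' global chi-squared improvement from n to n+1 falls below `threshold`
#' (default 10%), together with the elbow table. The principle is the
#' minimum number of slabs that still achieves a satisfactory fit.
#'
#' @inheritParams fit_simultaneous
#' @param max_slabs largest slab count tried (>= 1)
#' @param threshold relative improvement cutoff
#' @param ... passed to [fit_simultaneous()] (e.g. `n_starts`)
#' @return list with `chosen`, `table` (n, chi2_global), and `fits`
#' @export
select_slab_count <- function(datasets, protein, max_slabs = 4,
                              threshold = 0.10, substrate = nrslab::substrate(),
                              seed = 1, ...) {
  stopifnot(max_slabs >= 1)
  fits <- lapply(seq_len(max_slabs), function(n)
    fit_simultaneous(datasets, fit_spec(n_slabs = n), protein,
                     substrate = substrate, seed = seed + n, ...))
  chi2 <- vapply(fits, `[[`, 0, "chi2_global")
  chosen <- max_slabs
  if (max_slabs > 1) {
    for (n in seq_len(max_slabs - 1)) {
      impr <- if (chi2[n] > 0) (chi2[n] - chi2[n + 1]) / chi2[n] else 0
      if (impr < threshold) { chosen <- n; break }
    }
  } else chosen <- 1
  list(chosen = chosen, table = data.frame(n_slabs = seq_len(max_slabs),
                                           chi2_global = chi2),
       fits = fits)
}

#' Bootstrap uncertainties of a simultaneous fit
#'
#' Resamples data points with replacement within each contrast (or resamples
#' residuals with `method = "residuals"`), refits from the best-fit state,
#' and reports 68% and 95% percentile intervals for every parameter and for
#' the derived quantities (per-slab and total adsorbed amount, total
#' thickness, thickness-weighted mean volume fraction, mass-center
#' distance). Reproducible for a given seed; failed refits are skipped and
#' counted.
#'
#' @param fit an `nr_fit`
#' @param n_resamples number of bootstrap resamples
#' @param seed integer seed
#' @param method "points" (default) or "residuals"
#' @param maxiter Levenberg-Marquardt iteration cap per refit
#' @return object of class `nr_bootstrap` with `draws`, `intervals`,
#'   `n_fail`
#' @export
bootstrap_fit <- function(fit, n_resamples = 1000, seed = 1,
                          method = c("points", "residuals"), maxiter = 25) {
  stopifnot(inherits(fit, "nr_fit"), n_resamples >= 1)
  method <- match.arg(method)
  ctx <- fit_context(fit$datasets, fit$spec, fit$protein, fit$substrate)
  b <- par_bounds(fit$spec, ctx$n_contrasts)
  base_model <- lapply(seq_len(ctx$n_contrasts), function(ic)
    ctx_model(ctx, fit$par, ic))
  set.seed(seed)
  rows <- vector("list", n_resamples)
  n_fail <- 0L
  for (bi in seq_len(n_resamples)) {
    f <- tryCatch({
      if (method == "points") {
        w <- lapply(ctx$per, function(pc)
          tabulate(sample.int(pc$n, pc$n, replace = TRUE), nbins = pc$n))
        lm_refine(ctx, fit$par, b$lower, b$upper, maxiter, w = w)
      } else {
        ctx_b <- ctx
        for (ic in seq_len(ctx$n_contrasts)) {
          pc <- ctx$per[[ic]]
          res <- (pc$r - base_model[[ic]]) / pc$dr
          ctx_b$per[[ic]]$r <- base_model[[ic]] +
            sample(res, pc$n, replace = TRUE) * pc$dr
        }
        lm_refine(ctx_b, fit$par, b$lower, b$upper, maxiter)
      }
    }, error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f$par))) { n_fail <- n_fail + 1L; next }
    rows[[bi]] <- derived_row(setNames(f$par, names(b$lower)), fit)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("all bootstrap refits failed")
  draws <- do.call(rbind, rows)
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.16, 0.5, 0.84, 0.975),
              names = FALSE)
  intervals <- data.frame(quantity = colnames(draws),
                          estimate = derived_row(fit$par, fit),
                          lo95 = qs[1, ], lo68 = qs[2, ], median = qs[3, ],
                          hi68 = qs[4, ], hi95 = qs[5, ],
                          row.names = NULL)
  if (n_fail > 0)
    warning(n_fail, " of ", n_resamples, " bootstrap refits failed and were skipped")
  structure(list(draws = draws, intervals = intervals, n_fail = n_fail,
                 n_resamples = n_resamples, method = method, seed = seed),
            class = "nr_bootstrap")
}

# Named vector of parameters + derived quantities for one parameter vector.
derived_row <- function(p, fit) {
  stack <- stack_from_par(p, fit$spec, fit$protein, fit$substrate)
  s <- layer_summary(stack)
  out <- c(p,
           setNames(s$adsorbed_amount, paste0("gamma", seq_len(s$n_slabs))),
           gamma_total = s$total_adsorbed_amount,
           total_thickness = s$total_thickness,
           mean_phi = s$mean_volume_fraction_pct / 100,
           mass_center = s$mass_center)
  out
}

#' @export
print.nr_bootstrap <- function(x, ...) {
  cat(sprintf("<nr_bootstrap> %d resamples (%s), %d failed\n",
              x$n_resamples, x$method, x$n_fail))
  print(x$intervals, digits = 4, row.names = FALSE)
  invisible(x)
}
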