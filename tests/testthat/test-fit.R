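# Simultaneous multi-contrast refinement: chi-squared bookkeeping,
# parameter recovery, slab-count selection, determinism, and bootstrap
# interval behavior.

true_par <- c(tau1 = 42.5, tau2 = 20, phi1 = 0.441, phi2 = 0.183,
              background1 = 0, background2 = 0, background3 = 0)

noiseless_set <- function(stack = make_table1_stack("5.5")) {
  sim <- simulate_contrast_set(stack, noise = noise_model(0, 0, seed = 1))
  # attach uniform uncertainties so weighted fitting is defined
  lapply(sim$datasets, function(d) {
    contrast_dataset(reflectivity_curve(d$curve$q, d$curve$r,
                                        dr = pmax(0.02 * d$curve$r, 5e-7)),
                     d$solvent, d$instrument)
  })
}

test_that("normalized chi-squared follows its definition", {
  q <- exp(seq(log(0.01), log(0.2), length.out = 30))
  r <- exp(-30 * q)
  dr <- 0.1 * r
  ds <- contrast_dataset(reflectivity_curve(q, r, dr = dr), d2o)
  model <- reflectivity_curve(q, r)
  expect_equal(chi_squared(model, ds)$global, 0)
  # residuals all exactly 1 sigma -> chi2 = 1
  m1 <- reflectivity_curve(q, r + dr)
  expect_equal(chi_squared(m1, ds)$global, 1)
  # two contrasts with equal N: global is the mean of the per-contrast values
  ds2 <- contrast_dataset(reflectivity_curve(q, r, dr = 2 * dr), h2o)
  both <- chi_squared(list(m1, m1), list(ds, ds2))
  expect_equal(both$global, mean(both$per_contrast))
  expect_equal(both$per_contrast[2], 0.25)
  # missing uncertainties fall back to unweighted with a warning
  ds0 <- contrast_dataset(reflectivity_curve(q, r), d2o)
  expect_warning(chi_squared(m1, ds0), "unweighted")
})

test_that("chi-squared interpolates model curves onto the data grid", {
  q <- exp(seq(log(0.01), log(0.2), length.out = 40))
  r <- exp(-30 * q)
  ds <- contrast_dataset(reflectivity_curve(q, r, dr = 0.02 * r), d2o)
  qf <- exp(seq(log(0.008), log(0.25), length.out = 500))
  mod <- reflectivity_curve(qf, exp(-30 * qf))
  expect_lt(chi_squared(mod, ds)$global, 1e-4)
})

test_that("the true parameters are a fixed point of the noiseless fit", {
  ds <- noiseless_set()
  fit <- fit_simultaneous(ds, fit_spec(2), coe3, n_starts = 0, start = true_par)
  expect_lt(fit$chi2_global, 1e-10)
  expect_equal(fit$par[c("tau1", "tau2")], true_par[c("tau1", "tau2")],
               tolerance = 1e-4)
  expect_equal(fit$par[c("phi1", "phi2")], true_par[c("phi1", "phi2")],
               tolerance = 1e-4)
})

test_that("noiseless recovery from a perturbed start is accurate", {
  ds <- noiseless_set()
  start <- true_par * c(1.25, 0.8, 0.85, 1.25, 1, 1, 1) + c(0, 0, 0, 0, 1e-6, 1e-6, 1e-6)
  fit <- fit_simultaneous(ds, fit_spec(2), coe3, n_starts = 0, start = start,
                          maxiter = 200)
  expect_equal(fit$par[["tau1"]], 42.5, tolerance = 0.02)
  expect_equal(fit$par[["tau2"]], 20.0, tolerance = 0.02)
  expect_equal(fit$par[["phi1"]], 0.441, tolerance = 0.02 / 0.441)
  expect_equal(fit$par[["phi2"]], 0.183, tolerance = 0.02 / 0.183)
  # recovered summary matches the generator's within 2% on every field
  s <- fit$summary; s0 <- layer_summary(make_table1_stack("5.5"))
  expect_equal(s$total_thickness, s0$total_thickness, tolerance = 0.02)
  expect_equal(s$total_adsorbed_amount, s0$total_adsorbed_amount, tolerance = 0.02)
  expect_equal(s$mean_volume_fraction_pct, s0$mean_volume_fraction_pct,
               tolerance = 0.02)
  expect_equal(s$mass_center, s0$mass_center, tolerance = 0.02)
})

test_that("fits are deterministic and invariant to contrast order", {
  ds <- noiseless_set()
  f1 <- fit_simultaneous(ds, fit_spec(2), coe3, seed = 5, n_starts = 4, maxiter = 40)
  f2 <- fit_simultaneous(ds, fit_spec(2), coe3, seed = 5, n_starts = 4, maxiter = 40)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$chi2_global, f2$chi2_global)
  # relabeling the contrasts permutes per-contrast backgrounds only
  perm <- ds[c(3, 1, 2)]
  f3 <- fit_simultaneous(perm, fit_spec(2), coe3, seed = 5, n_starts = 4, maxiter = 40)
  expect_equal(f3$chi2_global, f1$chi2_global, tolerance = 1e-8)
  expect_equal(f3$par[c("tau1", "tau2", "phi1", "phi2")],
               f1$par[c("tau1", "tau2", "phi1", "phi2")], tolerance = 1e-6)
})

test_that("adding a slab never worsens the best fit", {
  st <- make_table1_stack("5.5")
  sim <- simulate_contrast_set(st, noise = noise_model(seed = 21))
  f1 <- fit_simultaneous(sim$datasets, fit_spec(1), coe3, seed = 2, n_starts = 8)
  f2 <- fit_simultaneous(sim$datasets, fit_spec(2), coe3, seed = 2, n_starts = 8,
                         start = c(f1$par[c("tau1")], tau2 = 20,
                                   f1$par[c("phi1")], phi2 = 0.1))
  expect_lte(f2$chi2_global, f1$chi2_global + 1e-6)
})

test_that("elbow selection recovers the generating slab count", {
  one <- layer_stack(list(slab(45, 0.4, roughness = 3)), coe3)
  sim1 <- simulate_contrast_set(one, noise = noise_model(seed = 8))
  sel1 <- select_slab_count(sim1$datasets, coe3, max_slabs = 2, seed = 3,
                            n_starts = 8)
  expect_equal(sel1$chosen, 1)

  sim2 <- simulate_contrast_set(make_table1_stack("5.5"),
                                noise = noise_model(seed = 9))
  sel2 <- select_slab_count(sim2$datasets, coe3, max_slabs = 3, seed = 3,
                            n_starts = 10)
  expect_equal(sel2$chosen, 2)
  expect_equal(nrow(sel2$table), 3)
  expect_true(all(diff(sel2$table$chi2_global) <= 1e-6))

  # a threshold of 1 always accepts the single-slab model
  sel3 <- select_slab_count(sim2$datasets, coe3, max_slabs = 2, threshold = 1,
                            seed = 3, n_starts = 4)
  expect_equal(sel3$chosen, 1)
})

test_that("bootstrap intervals shrink with added contrasts and vanish at one resample", {
  st <- make_table1_stack("5.5")
  sim <- simulate_contrast_set(st, noise = noise_model(seed = 31))
  fit3 <- fit_simultaneous(sim$datasets, fit_spec(2), coe3, n_starts = 0,
                           start = true_par)
  b3 <- suppressWarnings(bootstrap_fit(fit3, n_resamples = 60, seed = 1, maxiter = 8))
  # single-contrast fit of the same data: less information, wider intervals
  fit1 <- fit_simultaneous(sim$datasets[1], fit_spec(2), coe3, n_starts = 0,
                           start = true_par[1:5])
  b1 <- suppressWarnings(bootstrap_fit(fit1, n_resamples = 60, seed = 1, maxiter = 8))
  w3 <- subset(b3$intervals, quantity == "gamma_total")
  w1 <- subset(b1$intervals, quantity == "gamma_total")
  expect_gt(w1$hi68 - w1$lo68, w3$hi68 - w3$lo68)
  # one resample gives a degenerate interval equal to the single refit
  b_one <- suppressWarnings(bootstrap_fit(fit3, n_resamples = 1, seed = 2, maxiter = 8))
  iv <- subset(b_one$intervals, quantity == "gamma_total")
  expect_equal(iv$lo95, iv$hi95)
  # determinism given the seed
  b3b <- suppressWarnings(bootstrap_fit(fit3, n_resamples = 60, seed = 1, maxiter = 8))
  expect_identical(b3$draws, b3b$draws)
})

test_that("bootstrap intervals collapse as the noise vanishes", {
  st <- make_table1_stack("5.5")
  widths <- vapply(c(0.02, 0.002), function(nl) {
    sim <- simulate_contrast_set(st, noise = noise_model(nl, nl * 2.5e-5, seed = 17))
    fit <- fit_simultaneous(sim$datasets, fit_spec(2), coe3, n_starts = 0,
                            start = true_par)
    b <- suppressWarnings(bootstrap_fit(fit, n_resamples = 40, seed = 4, maxiter = 8))
    iv <- subset(b$intervals, quantity == "gamma_total")
    iv$hi68 - iv$lo68
  }, 0)
  expect_lt(widths[2], widths[1] / 2)
})
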