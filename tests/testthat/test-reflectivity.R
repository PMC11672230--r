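# Forward model: kinematics, Fresnel oracle, matrix invariances, smearing,
# instrument terms, and ASCII round-tripping.

test_that("momentum transfer follows Q = 4 pi sin(theta) / lambda", {
  expect_equal(q_from_angle(90, 4 * pi), 1.0)
  expect_equal(q_from_angle(1, 6), 4 * pi * sin(pi / 180) / 6)
  expect_equal(q_from_angle(1, 6), 0.03655, tolerance = 1e-3)
  expect_lt(q_from_angle(1e-6, 6), 1e-6)
  expect_error(q_from_angle(0, 6))
  expect_error(q_from_angle(10, -1))
})

test_that("critical edge follows Q_c = 4 sqrt(pi delta_rho)", {
  expect_equal(critical_q(0), 0)
  expect_equal(critical_q(-1e-6), 0)
  expect_equal(critical_q(6.35e-6 - 2.07e-6), 0.01467, tolerance = 1e-3)
  expect_equal(critical_q(2 * 4.28e-6) / critical_q(4.28e-6), sqrt(2))
})

test_that("matrix reflectivity matches the closed-form Fresnel oracle", {
  q <- exp(seq(log(0.004), log(0.4), length.out = 400))
  bare <- bare_interface_stack()
  for (sv in list(d2o, cm4, h2o)) {
    r <- abeles_reflectivity(bare, sv, q)$r
    oracle <- fresnel_r(q, 2.07e-6, sv$sld)
    expect_equal(r, oracle, tolerance = 1e-10)
  }
  # rough interface against the Nevot-Croce-damped closed form
  r3 <- abeles_reflectivity(bare_interface_stack(roughness = 4), d2o, q)$r
  expect_equal(r3, fresnel_r(q, 2.07e-6, SLD_D2O, sigma = 4), tolerance = 1e-10)
})

test_that("total reflection plateau and zero-contrast limits hold", {
  q <- seq(0.002, 0.014, by = 0.0005)
  r <- abeles_reflectivity(bare_interface_stack(), d2o, q)$r
  qc <- critical_q(SLD_D2O - 2.07e-6)
  expect_true(all(abs(r[q < qc] - 1) < 1e-12))
  # fronting == backing: no interface, no reflection
  si_match <- contrast_solvent("Si-matched", 2.07e-6)
  r0 <- abeles_reflectivity(bare_interface_stack(), si_match,
                            seq(0.01, 0.2, by = 0.01))$r
  expect_true(all(r0 < 1e-20))
})

test_that("invisible layers and slab splitting leave R unchanged", {
  q <- exp(seq(log(0.008), log(0.3), length.out = 200))
  sub0 <- substrate(oxide_roughness = 0)
  base <- layer_stack(list(), coe3, sub0)
  r_base <- abeles_reflectivity(base, d2o, q)$r
  # a slab with solvent SLD (phi chosen so slab SLD == backing) is invisible
  inv <- layer_stack(list(slab(57, 0, roughness = 0)), coe3, sub0)
  expect_equal(abeles_reflectivity(inv, d2o, q)$r, r_base, tolerance = 1e-10)
  # splitting one slab into two identical halves changes nothing
  one <- layer_stack(list(slab(60, 0.4, roughness = 0)), coe3, sub0)
  two <- layer_stack(list(slab(30, 0.4, roughness = 0), slab(30, 0.4, roughness = 0)),
                     coe3, sub0)
  expect_equal(abeles_reflectivity(two, d2o, q)$r,
               abeles_reflectivity(one, d2o, q)$r, tolerance = 1e-10)
})

test_that("unscaled model reflectivity stays within [0, 1] for random stacks", {
  set.seed(4)
  q <- exp(seq(log(0.005), log(0.4), length.out = 150))
  for (i in 1:25) {
    n <- sample(1:4, 1)
    sl <- lapply(seq_len(n), function(j)
      slab(runif(1, 5, 100), runif(1, 0, 1), roughness = runif(1, 0, 6)))
    st <- layer_stack(sl, coe3, substrate(oxide_roughness = runif(1, 0, 5)))
    sv <- contrast_solvent("mix", runif(1, SLD_H2O, SLD_D2O))
    r <- abeles_reflectivity(st, sv, q)$r
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("thickness fringes appear at spacing 2 pi / tau", {
  # the fringe period of a single slab encodes its thickness
  for (tau in c(60, 70, 80)) {
    st <- layer_stack(list(slab(tau, 0.6, roughness = 0)), coe3,
                      substrate(oxide_thickness = 0, oxide_roughness = 0))
    q <- seq(0.05, 0.3, length.out = 6000)
    r <- abeles_reflectivity(st, h2o, q)$r
    lr <- log(r)
    ismin <- which(diff(sign(diff(lr))) > 0) + 1
    spacing <- mean(diff(q[ismin]))
    expect_equal(spacing, 2 * pi / tau, tolerance = 0.02)
  }
})

test_that("resolution smearing has an identity limit and preserves constants", {
  q <- exp(seq(log(0.01), log(0.2), length.out = 100))
  cur <- reflectivity_curve(q, exp(-q * 20))
  expect_identical(smear(cur, 0), cur)
  flat <- reflectivity_curve(q, rep(0.5, length(q)))
  expect_equal(smear(flat, 0.05)$r, rep(0.5, length(q)), tolerance = 1e-12)
})

test_that("smearing agrees with brute-force quadrature and keeps edges monotone", {
  bare <- bare_interface_stack()
  q <- seq(0.005, 0.05, length.out = 3000)
  fine <- reflectivity_curve(q, abeles_reflectivity(bare, d2o, q)$r)
  sm <- smear(fine, 0.05)
  # independent dense-quadrature convolution at a few probe points
  sm_dense <- smear(fine, 0.05, n_points = 201)
  for (qc0 in c(0.012, 0.016, 0.02)) {
    i0 <- which.min(abs(q - qc0))
    q0 <- q[i0]
    sig <- 0.05 / 2.355 * q0
    xs <- seq(-3.5, 3.5, length.out = 4001)
    w <- dnorm(xs); w <- w / sum(w)
    rq <- approx(fine$q, fine$r, xout = q0 + sig * xs, rule = 2)$y
    expect_equal(sm_dense$r[i0], sum(w * rq), tolerance = 1e-3)
    # the 13-point production rule stays within 2% of the dense result
    expect_equal(sm$r[i0], sm_dense$r[i0], tolerance = 0.02)
  }
  # unsmeared edge is monotone decreasing past Qc; smearing keeps it monotone
  qc <- critical_q(SLD_D2O - 2.07e-6)
  seg <- sm$r[q > qc * 1.1]
  expect_true(all(diff(seg) < 0))
})

test_that("exact model smearing matches smearing a finely tabulated curve", {
  st <- make_table1_stack("5.5")
  q <- exp(seq(log(0.01), log(0.2), length.out = 60))
  exact <- abeles_smeared(st, d2o, q, dq_over_q = 0.04)
  qf <- exp(seq(log(0.006), log(0.3), length.out = 4000))
  tab <- smear(reflectivity_curve(qf, abeles_reflectivity(st, d2o, qf)$r), 0.04)
  interp <- approx(tab$q, log(tab$r), xout = q)$y
  expect_equal(log(exact$r), interp, tolerance = 1e-3)
})

test_that("instrument terms act as scale and additive background", {
  q <- exp(seq(log(0.01), log(0.2), length.out = 50))
  cur <- reflectivity_curve(q, exp(-30 * q))
  expect_equal(apply_instrument(cur, instrument_model())$r, cur$r)
  bg <- apply_instrument(cur, instrument_model(background = 1e-6))
  expect_true(all(bg$r >= 1e-6))
  sc <- apply_instrument(cur, instrument_model(scale = 2))
  expect_equal(sc$r, 2 * cur$r)
})

test_that("reflectivity ASCII I/O round-trips data and headers", {
  q <- exp(seq(log(0.01), log(0.25), length.out = 40))
  cur <- reflectivity_curve(q, exp(-25 * q), dr = 0.02 * exp(-25 * q),
                            dq = 0.04 * q)
  path <- tempfile(fileext = ".dat")
  write_reflectivity(cur, path, header = c("solvent: D2O"))
  back <- read_reflectivity(path)
  expect_equal(back$q, cur$q, tolerance = 1e-12)
  expect_equal(back$r, cur$r, tolerance = 1e-12)
  expect_equal(back$dr, cur$dr, tolerance = 1e-12)
  expect_equal(back$dq, cur$dq, tolerance = 1e-12)
  expect_true(any(grepl("solvent: D2O", attr(back, "header"))))
  # comma-separated two-column files are accepted too
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("# q, r", paste(q, exp(-25 * q), sep = ",")), p2)
  c2 <- read_reflectivity(p2)
  expect_equal(c2$r, cur$r, tolerance = 1e-12)
  expect_error(reflectivity_curve(c(0.2, 0.1), c(1, 1)), "increasing")
  expect_error(abeles_reflectivity(make_table1_stack("5.5"), d2o, numeric(0)),
               "empty q grid")
})
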