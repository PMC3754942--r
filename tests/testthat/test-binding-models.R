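test_that("one-site equilibrium matches an independent root-finding solver", {
  set.seed(23)
  for (i in 1:5) {
    m <- 10^runif(1, -6, -4)
    x <- 10^runif(1, -6, -4)
    kd <- 10^runif(1, -9, -5)
    mx <- alphareplib:::.one_site_complex(m, x, kd)
    # independent: solve the mass balance for free receptor numerically
    free_m <- uniroot(function(fm) fm + fm * x / (fm + kd) - m,
                      c(0, m), tol = 1e-18)$root
    mx_oracle <- free_m * x / (free_m + kd)
    expect_equal(mx, mx_oracle, tolerance = 1e-9)
  }
})

test_that("simulated isotherms have the expected shape and saturation", {
  p <- one_site_params(kd = 141e-9, n = 0.9, dh = -12)
  e <- itc_experiment(cell_conc = 30e-6, syringe_conc = 350e-6,
                      injection_volumes = rep(2e-6, 40))
  h <- itc_heats(p, e)
  # Wiseman c = n [cell] / Kd ~ 191: sigmoid with inflection near ratio n
  expect_gt(p$n * e$cell_conc / p$kd, 150)
  drop <- abs(diff(h$heat_per_mol))
  expect_equal(h$molar_ratio[which.max(drop)], p$n, tolerance = 0.15)
  # heats vanish past saturation
  expect_lt(abs(h$heat_per_mol[40]), abs(h$heat_per_mol[1]) / 50)
  # cumulative heat at saturation ~ n * [cell] * V0 * dH (dilution-corrected)
  expect_equal(sum(h$heat_kcal),
               p$n * e$cell_conc * e$cell_volume * p$dh, tolerance = 0.05)
})

test_that("fits recover generating parameters exactly at zero noise", {
  p <- one_site_params(kd = 141e-9, n = 0.9, dh = -12)
  e <- itc_experiment(cell_conc = 30e-6, syringe_conc = 350e-6)
  f <- fit_one_site(itc_heats(p, e), e)
  est <- setNames(tidy(f)$estimate, tidy(f)$term)
  expect_equal(unname(est["kd"]), p$kd, tolerance = 1e-6)
  expect_equal(unname(est["n"]), p$n, tolerance = 1e-6)
  expect_equal(unname(est["dh"]), p$dh, tolerance = 1e-6)

  strong <- one_site_params(kd = 3.7e-9, dh = -14)
  weak <- one_site_params(kd = 141e-9, dh = -12)
  ec <- itc_experiment(cell_conc = 25e-6, syringe_conc = 350e-6)
  hc <- simulate_competition(strong, weak, ec, weak_conc = 43e-6)
  fc <- fit_competition(hc, ec, weak, weak_conc = 43e-6)
  expect_equal(tidy(fc)$estimate[1], 3.7e-9, tolerance = 1e-6)
  expect_equal(tidy(fc)$estimate[2], -14, tolerance = 1e-6)

  th <- simulate_dsc(357.75, 80.2)
  fd <- fit_dsc(th)
  est_d <- setNames(tidy(fd)$estimate, tidy(fd)$term)
  expect_equal(unname(est_d["tm"]), 357.75, tolerance = 1e-8)
  expect_equal(unname(est_d["dh_cal"]), 80.2, tolerance = 1e-6)
  expect_equal(unname(est_d["dh_vh"]), 80.2, tolerance = 1e-6)

  k <- spr_kinetics(3e4, 1.7e-4)
  fs <- fit_spr(simulate_spr(k, c(71.3, 142.6, 713, 1426) * 1e-9))
  est_s <- setNames(tidy(fs)$estimate, tidy(fs)$term)
  expect_equal(unname(est_s["k_on"]), 3e4, tolerance = 1e-5)
  expect_equal(unname(est_s["k_off"]), 1.7e-4, tolerance = 1e-5)
})

test_that("the ternary competition solver matches the cubic-polynomial oracle", {
  set.seed(37)
  for (i in 1:10) {
    m <- 10^runif(1, -6, -4)
    a <- 10^runif(1, -6, -4)
    b <- 10^runif(1, -7, -4)
    ka_a <- 10^runif(1, 5, 8)
    ka_b <- 10^runif(1, 6, 9)
    got <- alphareplib:::.ternary_free_receptor(m, a, b, ka_a, ka_b)
    oracle <- oracle_ternary_free(m, a, b, ka_a, ka_b)
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("competition reduces to the one-site model when one ligand vanishes", {
  strong <- one_site_params(kd = 3.7e-9, dh = -14)
  weak <- one_site_params(kd = 141e-9, dh = -12)
  e <- itc_experiment(cell_conc = 25e-6, syringe_conc = 350e-6)
  # no weak ligand in the cell: the displacement titration is a direct one
  hc <- simulate_competition(strong, weak, e, weak_conc = 0)
  h1 <- itc_heats(one_site_params(kd = 3.7e-9, n = 1, dh = -14), e)
  expect_equal(hc$heat_per_mol, h1$heat_per_mol, tolerance = 1e-9)
})

test_that("apparent affinity follows the displacement formula", {
  ka_s <- 1 / 3.7e-9
  ka_w <- 1 / 141e-9
  expect_equal(apparent_ka(ka_s, ka_w, 0), ka_s)
  kapp <- apparent_ka(ka_s, ka_w, 43e-6)
  expect_equal(kapp, ka_s / (1 + ka_w * 43e-6), tolerance = 1e-12)
  expect_equal(kapp, 8.8e5, tolerance = 0.01)       # apparent Kd ~ 1.1 uM
  expect_equal(1 / kapp, 1.13e-6, tolerance = 0.01)
  expect_equal(apparent_ka(ka_s, 1e-30, 43e-6), ka_s, tolerance = 1e-9)
  # monotone decreasing in the competitor concentration
  ks <- vapply(c(0, 1e-6, 1e-5, 1e-4), function(cw) apparent_ka(ka_s, ka_w, cw),
               numeric(1))
  expect_true(all(diff(ks) < 0))
})

test_that("the two-state heat-capacity curve has the exact peak and area", {
  tm <- 84.60 + 273.15
  peak <- dsc_excess_cp(tm, tm, 80.2)
  expect_equal(peak, 80.2^2 / (4 * 1.9872e-3 * tm^2), tolerance = 1e-12)
  expect_equal(peak, 6.3, tolerance = 0.01)
  # K(Tm) = 1 makes the occupancy factor exactly 1/4
  expect_equal(dsc_excess_cp(tm, tm, 1, 1), 1 / (4 * 1.9872e-3 * tm^2))
  # quadrature over +/- 30 K conserves the calorimetric enthalpy
  area <- integrate(dsc_excess_cp, tm - 30, tm + 30, tm = tm, dh_cal = 80.2,
                    rel.tol = 1e-10)$value
  expect_equal(area, 80.2, tolerance = 1e-3)
})

test_that("DSC fits recover the transition from noisy thermograms", {
  tm <- 84.60 + 273.15
  tms <- vapply(1:5, function(s) {
    fd <- fit_dsc(simulate_dsc(tm, 80.2, noise = 0.005, seed = s))
    tidy(fd)$estimate[1]
  }, numeric(1))
  expect_lt(abs(mean(tms) - tm), 0.1)
  # van't Hoff / calorimetric ratio recovered on non-two-state-like data
  fd2 <- fit_dsc(simulate_dsc(357.75, dh_cal = 80.2, dh_vh = 120,
                              noise = 0.005, seed = 3))
  est <- setNames(tidy(fd2)$estimate, tidy(fd2)$term)
  expect_equal(unname(est["dh_vh"] / est["dh_cal"]), 120 / 80.2,
               tolerance = 0.1)
})

test_that("SPR rates, derived constants and noisy recovery behave as expected", {
  k <- spr_kinetics(3e4, 1.7e-4)
  expect_equal(spr_kd(k), 1.7e-4 / 3e4)
  expect_equal(signif(spr_kd(k), 1), 6e-9)
  expect_equal(spr_kd(spr_kinetics(1e12, 1.7e-4)), 1.7e-16)  # k_on -> Inf limit
  conc <- c(71.3, 118, 142.6, 237.6, 713, 1426) * 1e-9
  fs <- fit_spr(simulate_spr(k, conc, noise = 0.01, seed = 6))
  est <- setNames(tidy(fs)$estimate, tidy(fs)$term)
  expect_lt(abs(est["k_off"] - 1.7e-4) / 1.7e-4, 0.10)
  expect_error(spr_kinetics(-1, 1e-4), "rates")
})

test_that("binding thermodynamics satisfy the Gibbs relations", {
  expect_equal(gibbs(1)$dg, 0)
  g <- gibbs(1 / 3.7e-9, 298.15)
  expect_equal(g$dg, -11.5, tolerance = 0.01)
  g2 <- gibbs(1e6, 300, dh = gibbs(1e6, 300)$dg)
  expect_equal(g2$ds, 0, tolerance = 1e-12)
  g3 <- gibbs(2.5e7, 298.15, dh = -14)
  expect_equal(g3$dg, g3$dh - g3$temperature * g3$ds, tolerance = 1e-9)
})

test_that("tidy, glance and autoplot provide the standard accessors", {
  p <- one_site_params(kd = 1e-6, n = 1, dh = -10)
  e <- itc_experiment(cell_conc = 20e-6, syringe_conc = 200e-6)
  f <- fit_one_site(itc_heats(p, e, noise = 0.01, seed = 2), e)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  gl <- glance(f)
  expect_true(all(c("sigma", "rss", "nobs") %in% names(gl)))
  expect_s3_class(autoplot(f), "ggplot")
  fd <- fit_dsc(simulate_dsc(350, 90, noise = 0.01, seed = 1))
  expect_s3_class(autoplot(fd), "ggplot")
})
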