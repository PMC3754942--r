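test_that("assembly config resolves distributions and validates inputs", {
  cfg <- assembly_config(n_mean = 2)
  expect_equal(sum(cfg$p_n), 1, tolerance = 1e-12)
  expect_equal(sum((0:cfg$n_max) * cfg$p_n), 2, tolerance = 1e-9)
  expect_error(assembly_config(eps_mod = 1.2), "\\[0, 1\\]")
  expect_error(assembly_config(n_dist = c(0.5, 0.4)), "summing to 1")
  fixed2 <- assembly_config(n_dist = c(0, 0, 1))
  expect_equal(fixed2$p_n, c(0, 0, 1))
})

test_that("analytic in-frame fraction matches its closed form", {
  expect_equal(analytic_inframe(assembly_config(eps_mod = 0, eps_cap = 0.1)),
               0.81)
  expect_equal(analytic_inframe(assembly_config(n_dist = c(0, 0, 1),
                                                eps_mod = 0.2, eps_cap = 0)),
               0.64)
  # monotone decreasing in both error rates
  f <- function(em, ec) analytic_inframe(assembly_config(eps_mod = em,
                                                         eps_cap = ec))
  expect_true(all(diff(sapply(c(0, 0.1, 0.3, 0.6), f, ec = 0)) < 0))
  expect_true(all(diff(sapply(c(0, 0.1, 0.3), f, em = 0.2)) < 0))
})

test_that("simulated in-frame fractions agree with the closed form within 3 sigma", {
  n <- 1e5
  cfg <- assembly_config(n_dist = c(0, 0, 1), eps_mod = 0.2, eps_cap = 0)
  pop <- simulate_assembly(cfg, n, seed = 5)
  p <- analytic_inframe(cfg)
  expect_lt(abs(mean(pop$in_frame) - p), 3 * sqrt(p * (1 - p) / n))

  cfg2 <- assembly_config(n_mean = 2, eps_mod = 0.2, eps_cap = 0.05)
  pop2 <- simulate_assembly(cfg2, n, seed = 6)
  p2 <- analytic_inframe(cfg2)
  expect_lt(abs(mean(pop2$in_frame) - p2), 3 * sqrt(p2 * (1 - p2) / n))

  # error-free assembly is fully in frame; fixed seed reproduces exactly
  clean <- simulate_assembly(assembly_config(eps_mod = 0, eps_cap = 0), 1000)
  expect_true(all(clean$in_frame))
  expect_identical(simulate_assembly(cfg, 500, seed = 9),
                   simulate_assembly(cfg, 500, seed = 9))
})

test_that("filtration retains exactly the in-frame clones and is idempotent", {
  cfg <- assembly_config(eps_mod = 0.3, eps_cap = 0.1)
  pop <- simulate_assembly(cfg, 2e4, seed = 2)
  filt <- filter_inframe(pop)
  expect_equal(nrow(filt),
               sum(pop$n_defective == 0 & pop$ncap_ok & pop$ccap_ok))
  expect_true(all(filt$in_frame))
  expect_identical(filter_inframe(filt), filt)
  # post-filter correct-motif fraction is 1 before any shuffling
  expect_equal(library_stats(filt)$frac_correct_motifs, 1)
})

test_that("shuffling introduces only ligation errors at the configured rate", {
  cfg <- assembly_config(eps_mod = 0.2, eps_lig = 0.03)
  pop <- simulate_assembly(cfg, 1e5, seed = 3)
  shuf <- shuffle_modules(filter_inframe(pop), cfg, n_clones = 1e5, seed = 4)
  st <- library_stats(shuf)
  p <- 1 - 0.03
  n_mot <- st$n_motifs_seen
  expect_lt(abs(st$frac_correct_motifs - p), 3 * sqrt(p * (1 - p) / n_mot))
  perfect <- shuffle_modules(filter_inframe(pop),
                             assembly_config(eps_mod = 0.2, eps_lig = 0),
                             n_clones = 1000, seed = 1)
  expect_equal(library_stats(perfect)$frac_correct_motifs, 1)
  empty <- pop[pop$in_frame & pop$n_modules == -1, ]
  expect_error(shuffle_modules(empty, cfg), "empty")
})

test_that("filtration plus shuffling reproduces the library-optimization trend", {
  # a primary library with 20% defective motifs, then filtration + shuffling
  cfg <- assembly_config(n_mean = 2, eps_mod = 0.2, eps_lig = 0.03)
  lib20 <- simulate_assembly(cfg, 1e5, seed = 11)
  lib21 <- shuffle_modules(filter_inframe(lib20), cfg, n_clones = 1e5,
                           seed = 12)
  s20 <- library_stats(lib20)
  s21 <- library_stats(lib21)
  expect_gt(s21$frac_inframe, s20$frac_inframe)
  expect_gt(s21$mean_motifs_inframe, s20$mean_motifs_inframe)
  expect_gt(s21$frac_correct_motifs, s20$frac_correct_motifs)
})

test_that("library stats mirror hand computation and sampling conventions", {
  pop <- tibble::tibble(clone = 1:5,
                        n_modules = c(0L, 2L, 3L, 1L, 4L),
                        n_defective = c(0L, 0L, 1L, 0L, 0L),
                        ncap_ok = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                        ccap_ok = TRUE)
  st <- library_stats(pop)
  # in frame: clones 1, 2, 5; with n >= 1: clones 2, 5
  expect_equal(st$frac_inframe, 3 / 5)
  expect_equal(st$frac_inframe_n1, 2 / 5)
  expect_equal(st$mean_motifs_inframe, mean(c(0, 2, 4)))
  expect_equal(st$mean_motifs_inframe_n1, mean(c(2, 4)))
  expect_equal(st$frac_correct_motifs, 1 - 1 / 10)
  expect_gte(st$mean_motifs_inframe_n1, st$mean_motifs_inframe)
  expect_error(library_stats(pop, sample_size = 9), "exceeds")
  # all-in-frame fixed-n population
  fixed <- tibble::tibble(clone = 1:10, n_modules = 3L, n_defective = 0L,
                          ncap_ok = TRUE, ccap_ok = TRUE)
  stf <- library_stats(fixed)
  expect_equal(stf$frac_inframe, 1)
  expect_equal(stf$mean_motifs_inframe, 3)
})

test_that("independent-module error model links motif rate to in-frame rate", {
  expect_equal(inframe_from_motif_rate(1, 5), 1)
  expect_equal(inframe_from_motif_rate(0.8, 2), 0.64)
  expect_error(inframe_from_motif_rate(1.2, 1), "\\[0, 1\\]")
})
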