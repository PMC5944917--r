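test_that("generators are bitwise reproducible and substreams are stable", {
  cfg <- cline_sim_config(n_pops = 3, n_per_pop = 5, n_sites = 50,
                          altitudes = c(1000, 1500, 2000), seed = 11)
  G1 <- simulate_genotypes(cfg)
  G2 <- simulate_genotypes(cfg)
  expect_identical(G1$calls, G2$calls)
  lab <- attr(G1, "labels")
  p1 <- simulate_genome_size(G1, lab$altitude, seed = 11)
  # interleaving another generator must not perturb the substream
  invisible(simulate_growth_data(growth_sim_config(n_maternal = 3,
                                                   n_per_family = 2, seed = 11)))
  p2 <- simulate_genome_size(G1, lab$altitude, seed = 11)
  expect_identical(p1$gs_gb, p2$gs_gb)
})

test_that("Balding-Nichols limits behave: no differentiation as F -> 0 and no missing at rate 0", {
  cfg <- cline_sim_config(n_pops = 4, n_per_pop = 25, n_sites = 400,
                          fst = 1e-6, altitudes = c(0, 500, 1000, 1500),
                          missing_rate = 0, seed = 2)
  G <- simulate_genotypes(cfg)
  expect_false(anyNA(G$calls))
  pop <- attr(G, "labels")$population
  freq_by_pop <- apply(G$calls, 2, function(g) tapply(g, pop, mean) / 2)
  between_var <- mean(apply(freq_by_pop, 2, var))
  # with F = 1e-6 the residual between-population variance is sampling noise
  # of order p(1-p)/(2n) ~ 0.004, far below any real differentiation
  expect_lt(between_var, 0.01)
})

test_that("realized Weir-Cockerham FST matches the target over replicates", {
  fst_hat <- vapply(1:200, function(r) {
    cfg <- cline_sim_config(n_pops = 4, n_per_pop = 25, n_sites = 5000,
                            fst = 0.1, altitudes = c(0, 500, 1000, 1500),
                            missing_rate = 0, seed = 1000 + r)
    G <- simulate_genotypes(cfg)
    wc_fst(G$calls, attr(G, "labels")$population)
  }, numeric(1))
  expect_lt(abs(mean(fst_hat) - 0.1), 0.02)
})

test_that("genome-size generator honors its deterministic limits", {
  cfg <- cline_sim_config(n_pops = 2, n_per_pop = 5, n_sites = 60,
                          altitudes = c(1000, 2000), missing_rate = 0,
                          seed = 3)
  G <- simulate_genotypes(cfg)
  alt <- attr(G, "labels")$altitude
  p0 <- simulate_genome_size(G, alt, beta_alt = 0, va = 0, ve = 0, mu = 5,
                             seed = 3)
  expect_equal(p0$gs_gb, rep(5, 10))
  expect_equal(p0$mb_te, rep(0.85 * 5 * 1000, 10))
  # class Mb never exceeds genome size
  p1 <- simulate_genome_size(G, alt, seed = 4)
  mb_cols <- grep("^mb_", names(p1), value = TRUE)
  expect_true(all(rowSums(p1[, mb_cols]) <= p1$gs_gb * 1000 + 1e-9))
})

test_that("clinal slope is recovered on average by OLS across replicates", {
  cfg <- cline_sim_config(n_pops = 4, n_per_pop = 10, n_sites = 300,
                          altitudes = c(0, 333, 667, 1000), missing_rate = 0,
                          seed = 5)
  G <- simulate_genotypes(cfg)
  alt <- attr(G, "labels")$altitude
  slopes <- vapply(1:500, function(r) {
    p <- simulate_genome_size(G, alt, beta_alt = -1.08e-4, va = 0.02,
                              ve = 0.01, mu = 5, seed = 5000 + r)
    unname(coef(lm(p$gs_gb ~ alt))[2])
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) + 1.08e-4), 4 * mc_se)
})

test_that("read assignments are a closed multinomial consistent with the profile", {
  cfg <- cline_sim_config(n_pops = 2, n_per_pop = 4, n_sites = 50,
                          altitudes = c(0, 100), missing_rate = 0, seed = 7)
  G <- simulate_genotypes(cfg)
  alt <- attr(G, "labels")$altitude
  prof <- simulate_genome_size(G, alt, beta_alt = 0, va = 0, ve = 0, mu = 5,
                               repeat_fractions = c(te = 0.85), seed = 7)
  counts <- simulate_read_assignments(prof, total_reads = 1e5, seed = 7)
  expect_true(all(counts$te + counts$other == 1e5))
  # observed TE fraction within 3 binomial SD of 0.85
  sd_bin <- sqrt(0.85 * 0.15 / 1e5)
  expect_true(all(abs(counts$te / 1e5 - 0.85) < 3 * sd_bin))
  # a single class occupying the whole genome takes every read
  prof2 <- simulate_genome_size(G, alt, beta_alt = 0, va = 0, ve = 0, mu = 5,
                                repeat_fractions = c(te = 1), seed = 7)
  counts2 <- simulate_read_assignments(prof2, total_reads = 1000, seed = 7)
  expect_true(all(counts2$te == 1000))
})

test_that("growth generator satisfies its noiseless identities", {
  cfg0 <- growth_sim_config(n_maternal = 4, n_per_family = 2, gamma_gs = 0,
                            beta0 = log(4) - log(0.003), beta_gs = 0,
                            tau_a2 = 0, tau_b2 = 0, sigma_cs2 = 0,
                            sigma_cp2 = 0, sigma_cell_obs2 = 0,
                            sigma_ler_obs2 = 0, seed = 9)
  gd0 <- simulate_growth_data(cfg0)
  inc <- diff(gd0$lengths$length_cm[gd0$lengths$seedling ==
                                      gd0$seedlings$seedling[1]])
  expect_equal(inc, rep(exp(cfg0$gamma0 + cfg0$beta0), cfg0$n_days - 1))
  # doubling CP doubles the noiseless elongation rate
  cfg2 <- cfg0; cfg2$beta0 <- cfg0$beta0 + log(2)
  gd2 <- simulate_growth_data(cfg2)
  inc2 <- diff(gd2$lengths$length_cm[gd2$lengths$seedling ==
                                       gd2$seedlings$seedling[1]])
  expect_equal(inc2, 2 * inc)
  # truth record satisfies LER = CS * CP identically
  gd <- simulate_growth_data(growth_sim_config(n_maternal = 5,
                                               n_per_family = 3, seed = 10))
  expect_identical(gd$truth$log_ler, gd$truth$log_cs + gd$truth$log_cp)
})

test_that("SAM generator recovers its planted slope in the degenerate limits", {
  sam <- simulate_sam_data(slope = -0.1, effect_bak1 = 0, effect_sda1 = 0,
                           va = 0, noise = 0, sigma_block = 0,
                           sigma_count = 0, seed = 12)
  b <- fit_blues(sam, "G1")
  fm <- flowering_model(setNames(sam$lines$flowering, sam$lines$line),
                        list(G1 = b), sam$lines$bak1, sam$lines$sda1,
                        diag(nrow(sam$lines)))
  expect_equal(fm$slope, -0.1, tolerance = 1e-8)
  # slope 0 with no structure fits ~0
  sam0 <- simulate_sam_data(slope = 0, effect_bak1 = 0, effect_sda1 = 0,
                            va = 0, noise = 0.5, seed = 13)
  b0 <- fit_blues(sam0, "G1")
  fm0 <- flowering_model(setNames(sam0$lines$flowering, sam0$lines$line),
                         list(G1 = b0), sam0$lines$bak1, sam0$lines$sda1,
                         diag(nrow(sam0$lines)))
  expect_lt(abs(fm0$slope), 3 * fm0$se)
})

test_that("SAM slope is unbiased across replicates", {
  est <- vapply(1:200, function(r) {
    sam <- simulate_sam_data(n_lines = 20, slope = -0.1, va = 1, noise = 1,
                             seed = 20000 + r)
    b <- lapply(list(G1 = "G1"), function(p) fit_blues(sam, p))
    fm <- flowering_model(setNames(sam$lines$flowering, sam$lines$line),
                          b, sam$lines$bak1, sam$lines$sda1,
                          diag(nrow(sam$lines)))
    fm$slope
  }, numeric(1))
  expect_lt(abs(mean(est) + 0.1), 4 * sd(est) / sqrt(length(est)))
})

test_that("config validation rejects out-of-range values", {
  expect_error(cline_sim_config(fst = 0), "fst")
  expect_error(cline_sim_config(fst = 1.2), "fst")
  expect_error(cline_sim_config(repeat_fractions = c(te = 0.9, knob = 0.2)),
               "repeat_fractions")
  expect_error(cline_sim_config(n_pops = 3, n_per_pop = 5,
                                altitudes = c(1, 2)), "altitudes")
  expect_error(growth_sim_config(tau_a2 = -1), "variance")
  expect_error(growth_sim_config(n_days = 1), "n_days")
})
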