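rand_geno <- function(n, m, miss = 0.2, seed = 1, depths = TRUE) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  calls[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
  genotype_matrix(calls,
                  depths = if (depths) matrix(rpois(n * m, 20), n, m))
}

test_that("missingness filter matches a brute-force recount", {
  G <- rand_geno(10, 10, miss = 0.35, seed = 1)
  out <- filter_missingness(G, max_site_missing = 0.3, max_ind_missing = 0.4)
  # independent recount: site pass first, then individuals on surviving sites
  keep_s <- which(colMeans(is.na(G$calls)) <= 0.3)
  keep_i <- which(rowMeans(is.na(G$calls[, keep_s])) <= 0.4)
  expect_identical(out$calls, G$calls[keep_i, keep_s])
  rep <- attr(out, "report")
  expect_equal(rep$sites_removed, 10 - length(keep_s))
  expect_equal(rep$individuals_removed, 10 - length(keep_i))
})

test_that("missingness filter edge cases", {
  G <- rand_geno(5, 5, miss = 0, seed = 2)
  expect_identical(filter_missingness(G)$calls, G$calls)
  # one site exactly 50% missing is removed at the 0.40 default
  calls <- matrix(1L, 4, 3)
  calls[1:2, 2] <- NA_integer_
  G2 <- genotype_matrix(calls)
  out <- filter_missingness(G2)
  expect_equal(ncol(out$calls), 2)
  expect_false("s2" %in% out$site_ids)
  # every site carries a missing call: a zero-tolerance filter empties it
  calls_all <- matrix(1L, 3, 3)
  diag(calls_all) <- NA_integer_
  expect_error(filter_missingness(genotype_matrix(calls_all),
                                  max_site_missing = 0, max_ind_missing = 0),
               "sites")
})

test_that("random imputation draws from the observed site distribution", {
  calls <- matrix(2L, 6, 2)
  calls[1:3, 1] <- NA_integer_
  G <- genotype_matrix(calls)
  expect_true(all(impute_random(G, 1)$calls == 2L))
  G2 <- rand_geno(5, 5, miss = 0, seed = 3, depths = FALSE)
  expect_identical(impute_random(G2, 1)$calls, G2$calls)
  expect_identical(impute_random(rand_geno(8, 8, 0.3, 4), 9)$calls,
                   impute_random(rand_geno(8, 8, 0.3, 4), 9)$calls)
  # 50/50 site: imputed values split evenly within 3 binomial SD
  calls3 <- matrix(c(rep(c(0L, 2L), 50), rep(NA_integer_, 10000)), ncol = 1)
  G3 <- genotype_matrix(calls3)
  imp <- impute_random(G3, 5)$calls[101:10100, 1]
  expect_lt(abs(mean(imp == 2) - 0.5), 3 * sqrt(0.25 / 10000))
  # all-missing site errors
  G4 <- genotype_matrix(matrix(NA_integer_, 3, 1))
  expect_error(impute_random(G4, 1), "observed")
})

test_that("alternative imputation schemes fill every gap deterministically", {
  G <- rand_geno(10, 12, miss = 0.25, seed = 14)
  Gm <- impute_mean(G)
  expect_false(anyNA(Gm$calls))
  j <- which(colSums(is.na(G$calls)) > 0)[1]
  i <- which(is.na(G$calls[, j]))[1]
  expect_equal(Gm$calls[i, j], mean(G$calls[, j], na.rm = TRUE))
  Gk <- impute_knn(G, k = 3)
  expect_false(anyNA(Gk$calls))
  expect_identical(Gk$calls, impute_knn(G, k = 3)$calls)
  obs <- !is.na(G$calls)
  expect_identical(Gk$calls[obs], G$calls[obs]) # observed calls untouched
  # duplicate of an observed individual inherits its genotypes
  base <- G$calls[1, ]; base[is.na(base)] <- 1L
  dup <- base; dup[3] <- NA_integer_
  G2 <- genotype_matrix(rbind(base, base, dup, t(matrix(rep(2 - base, 2), ncol = 2))))
  expect_equal(impute_knn(G2, k = 2)$calls[3, 3], base[[3]])
})

test_that("centered-IBS kinship equals the naive double-loop oracle", {
  for (seed in 1:5) {
    G <- rand_geno(6, 20, miss = 0, seed = seed, depths = FALSE)
    K <- kinship_centered_ibs(G)
    expect_lt(max(abs(K$values - naive_centered_ibs(G$calls))), 1e-12)
    ev <- eigen(K$values, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10) # Gram form: PSD
  }
})

test_that("kinship is invariant to site order and equivariant to individual permutation", {
  G <- rand_geno(7, 30, miss = 0, seed = 6, depths = FALSE)
  K <- kinship_centered_ibs(G)$values
  perm_s <- sample(30)
  Gs <- genotype_matrix(G$calls[, perm_s])
  expect_equal(kinship_centered_ibs(Gs)$values, K, tolerance = 1e-12,
               ignore_attr = TRUE)
  perm_i <- sample(7)
  Gi <- genotype_matrix(G$calls[perm_i, ])
  expect_equal(kinship_centered_ibs(Gi)$values, K[perm_i, perm_i],
               tolerance = 1e-12, ignore_attr = TRUE)
  # duplicate outbred homozygous individuals: K_ii equals K_ij
  calls <- rbind(c(0L, 2L, 0L, 2L, 0L, 2L), c(0L, 2L, 0L, 2L, 0L, 2L),
                 c(2L, 0L, 2L, 0L, 2L, 0L), c(1L, 1L, 1L, 1L, 1L, 1L))
  Kd <- kinship_centered_ibs(genotype_matrix(calls))$values
  expect_equal(Kd[1, 1], Kd[1, 2], tolerance = 1e-12)
  expect_error(kinship_centered_ibs(genotype_matrix(matrix(2L, 4, 5))),
               "monomorphic")
})

test_that("inbreeding from the kinship diagonal is calibrated", {
  set.seed(7)
  # outbred HWE population: mean F ~ 0
  p <- runif(400, 0.1, 0.9)
  calls <- vapply(p, function(pp) rbinom(60, 2, pp), integer(60))
  F_out <- inbreeding_from_kinship(kinship_centered_ibs(genotype_matrix(calls)))
  expect_lt(abs(mean(F_out)), 0.1)
  # fully inbred lines (all homozygous): mean F ~ 1
  calls_in <- vapply(p, function(pp) 2L * rbinom(60, 1, pp), integer(60))
  F_in <- inbreeding_from_kinship(kinship_centered_ibs(genotype_matrix(calls_in)))
  expect_lt(abs(mean(F_in) - 1), 0.15)
})

test_that("IBS duplicate removal drops the lower-depth member and leaves no close pair", {
  set.seed(8)
  base <- sample(0:2, 60, replace = TRUE)
  mutate <- function(g, k) { i <- sample(60, k); g[i] <- (g[i] + 1L) %% 3L; g }
  calls <- rbind(A = base, B = mutate(base, 1), C = mutate(base, 2),
                 D = sample(0:2, 60, replace = TRUE))
  G <- genotype_matrix(calls)
  depths <- c(A = 10, B = 5, C = 20, D = 8)
  out <- remove_ibs_duplicates(G, depths, threshold = 0.07)
  expect_true(all(attr(out, "dropped") %in% c("A", "B", "C")))
  D2 <- ibs_distance_matrix(out)
  expect_true(all(D2[upper.tri(D2)] >= 0.07, na.rm = TRUE))
  # exact duplicate pair: exactly the lower-depth one goes
  G2 <- genotype_matrix(rbind(X = base, Y = base))
  out2 <- remove_ibs_duplicates(G2, c(X = 3, Y = 9))
  expect_identical(attr(out2, "dropped"), "X")
  # distant individuals: identity
  G3 <- genotype_matrix(rbind(A = base, D = calls["D", ]))
  out3 <- remove_ibs_duplicates(G3, c(A = 1, D = 2))
  expect_length(attr(out3, "dropped"), 0)
  expect_equal(nrow(out3$calls), 2)
})

test_that("HWE filter follows the 1-df chi-squared rule", {
  calls <- cbind(rep(c(0L, 1L, 2L), times = c(25, 50, 25)), # exact HWE
                 rep(1L, 100)) # all heterozygotes: chi2 = n = 100
  G <- genotype_matrix(calls, depths = matrix(50, 100, 2))
  keep <- hwe_filter(G)
  expect_true(keep[1])
  expect_false(keep[2])
  p <- attr(keep, "p")
  expect_equal(p[1], 1, tolerance = 1e-12)
  expect_equal(p[2], pchisq(100, 1, lower.tail = FALSE), tolerance = 1e-12)
  # permuting individuals leaves the mask unchanged
  perm <- sample(100)
  Gp <- genotype_matrix(calls[perm, ], depths = matrix(50, 100, 2))
  expect_identical(as.logical(hwe_filter(Gp)), as.logical(keep))
  # depth window: out-of-range depths make a site untestable (kept)
  Gd <- genotype_matrix(calls, depths = matrix(5, 100, 2))
  expect_true(all(hwe_filter(Gd)))
})

test_that("LD thinning removes the lower-coverage member of violating pairs", {
  set.seed(9)
  g <- sample(0:2, 40, replace = TRUE)
  calls <- cbind(g, g, sample(0:2, 40, replace = TRUE))
  G <- genotype_matrix(calls, positions = c(100L, 5000L, 10000L),
                       depths = matrix(rep(c(30, 10, 20), each = 40), 40, 3))
  keep <- ld_thin(G)
  expect_identical(as.logical(keep), c(TRUE, FALSE, TRUE)) # r2 = 1 pair
  # adjacent pair: lower coverage goes regardless of correlation
  G2 <- genotype_matrix(calls, positions = c(100L, 600L, 10000L),
                        depths = matrix(rep(c(10, 30, 20), each = 40), 40, 3))
  keep2 <- ld_thin(G2)
  expect_identical(as.logical(keep2), c(FALSE, TRUE, TRUE))
  # far apart, uncorrelated: identity
  set.seed(10)
  calls3 <- matrix(sample(0:2, 40 * 3, replace = TRUE), 40, 3)
  G3 <- genotype_matrix(calls3, positions = c(1L, 2000L, 4000L),
                        depths = matrix(20, 40, 3))
  expect_true(all(ld_thin(G3)))
})

test_that("LD thinning survivors pass an exhaustive pair recheck", {
  set.seed(11)
  n <- 30; m <- 50
  base <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  # plant LD blocks: copy neighbours with small perturbation
  for (j in seq(2, m, by = 5)) {
    base[, j] <- base[, j - 1]
    flip <- sample(n, 2)
    base[flip, j] <- (base[flip, j] + 1L) %% 3L
  }
  pos <- cumsum(sample(c(200L, 700L, 1500L), m, replace = TRUE))
  G <- genotype_matrix(base, positions = pos,
                       depths = matrix(rpois(n * m, 20), n, m))
  keep <- ld_thin(G)
  surv <- which(keep)
  for (a in seq_along(surv)) for (b in seq_len(a - 1)) {
    i <- surv[b]; j <- surv[a]
    expect_gte(pos[j] - pos[i], 1000)
    nh <- colSums(G$depths >= 9 & G$depths <= 300)
    if (nh[i] >= 12 && nh[j] >= 12) {
      r <- cor(base[, i], base[, j])
      if (is.finite(r) && r^2 > 0.8) {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        expect_gte(2 * pt(-abs(tt), n - 2), 0.05)
      }
    }
  }
})

test_that("within-population kinship exceeds between-population kinship under structure", {
  ok <- vapply(1:20, function(r) {
    cfg <- cline_sim_config(n_pops = 3, n_per_pop = 8, n_sites = 300,
                            fst = 0.2, altitudes = c(0, 500, 1000),
                            missing_rate = 0, seed = 300 + r)
    G <- simulate_genotypes(cfg)
    pop <- attr(G, "labels")$population
    K <- kinship_centered_ibs(G)$values
    same <- outer(pop, pop, "==") & upper.tri(K)
    diff <- outer(pop, pop, "!=") & upper.tri(K)
    mean(K[same]) > mean(K[diff])
  }, logical(1))
  expect_true(all(ok))
})
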