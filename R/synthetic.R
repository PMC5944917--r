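#' Configuration for the clinal population simulator
#'
#' Defaults describe the study conditions the downstream selection tests are
#' designed for: eight highland-teosinte-like populations (70 individuals in
#' all) spanning roughly 1,100 m of altitude, moderate differentiation
#' (FST = 0.1), a clinal decline of 270 kb of (2C) genome size per metre, and
#' a genome that is mostly transposable elements (85%) with heterochromatic
#' knobs as the other large repeat class.
#'
#' @param n_pops Number of populations.
#' @param n_per_pop Individuals per population; scalar or vector of length
#'   `n_pops`.
#' @param n_sites Number of biallelic SNP sites.
#' @param fst Wright's FST among populations, in (0,1).
#' @param altitudes Altitude (m) per population.
#' @param beta_alt Clinal slope of genome size on altitude, Gb per m.
#' @param mu Grand-mean 2C genome size, Gb.
#' @param va Additive genetic variance of genome size, Gb^2.
#' @param ve Residual (measurement) variance, Gb^2.
#' @param repeat_fractions Named fractions of the genome per repeat class;
#'   must be non-negative and sum to at most 1 (remainder is "other").
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param mean_depth Mean per-genotype read depth for simulated depths.
#' @param seed Master integer seed.
#' @return A validated list of class `cline_sim_config`.
#' @export
cline_sim_config <- function(n_pops = 8,
                             n_per_pop = c(9, 9, 9, 9, 9, 9, 8, 8),
                             n_sites = 5000,
                             fst = 0.1,
                             altitudes = seq(1600, 2700, length.out = n_pops),
                             beta_alt = -2.7e-4,
                             mu = 5.5,
                             va = 0.04,
                             ve = 0.01,
                             repeat_fractions = c(te = 0.85, knob180 = 0.06,
                                                  tr1 = 0.008, rdna = 0.003,
                                                  centc = 0.005),
                             missing_rate = 0.1,
                             mean_depth = 30,
                             seed = 1) {
  check_count(n_pops, "n_pops")
  if (length(n_per_pop) == 1L) n_per_pop <- rep(n_per_pop, n_pops)
  check_count(n_per_pop, "n_per_pop")
  if (length(n_per_pop) != n_pops) stop("n_per_pop must match n_pops")
  check_count(n_sites, "n_sites")
  check_fraction(fst, "fst", open = TRUE)
  if (length(altitudes) != n_pops) stop("altitudes must have one value per population")
  stopifnot(all(is.finite(altitudes)), is.finite(beta_alt), is.finite(mu),
            is.finite(va), va >= 0, is.finite(ve), ve >= 0)
  if (any(repeat_fractions < 0) || sum(repeat_fractions) > 1)
    stop("repeat_fractions must be non-negative and sum to at most 1")
  if (is.null(names(repeat_fractions)) || any(!nzchar(names(repeat_fractions))))
    stop("repeat_fractions must be named by repeat class")
  check_fraction(missing_rate, "missing_rate")
  structure(list(n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
                 n_sites = as.integer(n_sites), fst = fst,
                 altitudes = altitudes, beta_alt = beta_alt, mu = mu,
                 va = va, ve = ve, repeat_fractions = repeat_fractions,
                 missing_rate = missing_rate, mean_depth = mean_depth,
                 seed = as.integer(seed)),
            class = "cline_sim_config")
}

#' Simulate population-structured genotypes (Balding-Nichols model)
#'
#' Per site, an ancestral allele frequency `p ~ U(0.05, 0.95)` is drawn; each
#' population's frequency is Beta-distributed with mean `p` and variance
#' `F p (1 - p)` (shape parameters `p(1-F)/F` and `(1-p)(1-F)/F`, `F = fst`);
#' genotypes are Binomial(2, p_pop). Missing calls are injected uniformly at
#' `missing_rate`, and Poisson read depths (mean `mean_depth`) are attached.
#'
#' @param cfg A [cline_sim_config()].
#' @return A `genotype_matrix`; attribute `labels` is a data frame with
#'   `individual_id`, `population` and `altitude`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "cline_sim_config"))
  set.seed(derive_seed(cfg$seed, "simulate_genotypes"))
  n <- sum(cfg$n_per_pop)
  m <- cfg$n_sites
  F <- cfg$fst
  p_anc <- runif(m, 0.05, 0.95)
  pop <- rep(seq_len(cfg$n_pops), cfg$n_per_pop)
  calls <- matrix(NA_integer_, n, m)
  for (k in seq_len(cfg$n_pops)) {
    pk <- rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    rows <- which(pop == k)
    calls[rows, ] <- matrix(rbinom(length(rows) * m, 2L,
                                   rep(pk, each = length(rows))),
                            length(rows), m)
  }
  depths <- matrix(stats::rpois(n * m, cfg$mean_depth), n, m)
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(n * m) < cfg$missing_rate, n, m)
    calls[miss] <- NA_integer_
  }
  ids <- sprintf("pop%02d_ind%02d", pop, unlist(lapply(cfg$n_per_pop, seq_len)))
  G <- genotype_matrix(calls, individual_ids = ids,
                       site_ids = paste0("s", seq_len(m)),
                       chrom = rep("1", m),
                       positions = seq_len(m) * 100L, depths = depths)
  attr(G, "labels") <- data.frame(individual_id = ids, population = pop,
                                  altitude = cfg$altitudes[pop])
  G
}

#' Simulate genome size and its repeat-class decomposition along a cline
#'
#' Genome size for individual i is
#' \deqn{GS_i = \mu + \beta_{alt} A_i + g_i + \epsilon_i,\quad
#'   g \sim MVN(0, V_A K)}
#' with `K` the centered-IBS kinship computed from the supplied genotypes
#' (after random imputation). Positivity is enforced by resampling
#' \eqn{\epsilon} only, which leaves the covariance of `g` intact; the number
#' of resampled draws is recorded. Each genome is then partitioned into
#' repeat-class megabases according to `repeat_fractions`, with the remainder
#' labelled "other".
#'
#' @param G A `genotype_matrix` (typically from [simulate_genotypes()]).
#' @param altitudes Altitude (m) per individual.
#' @param beta_alt,va,ve,mu,repeat_fractions See [cline_sim_config()].
#' @param seed Master integer seed.
#' @return A `repeat_profile` data frame: `individual_id`, `altitude`,
#'   `gs_gb`, one `mb_<class>` column per repeat class and `mb_other`.
#'   Attributes: `truth` (generator parameters and the latent `g`),
#'   `n_resampled`, and `K` (the kinship used).
#' @export
simulate_genome_size <- function(G, altitudes, beta_alt = -2.7e-4, va = 0.04,
                                 ve = 0.01, mu = 5.5,
                                 repeat_fractions = c(te = 0.85, knob180 = 0.06,
                                                      tr1 = 0.008, rdna = 0.003,
                                                      centc = 0.005),
                                 seed = 1) {
  n <- nrow(G$calls)
  if (length(altitudes) != n) stop("altitudes must have one value per individual")
  if (any(repeat_fractions < 0) || sum(repeat_fractions) > 1)
    stop("repeat_fractions must be non-negative and sum to at most 1")
  Gi <- if (anyNA(G$calls)) impute_random(G, derive_seed(seed, "gs_impute")) else G
  K <- kinship_centered_ibs(Gi)
  Kv <- as_kinship_values(K)
  set.seed(derive_seed(seed, "simulate_genome_size"))
  if (va > 0) {
    ev <- eigen((Kv + t(Kv)) / 2, symmetric = TRUE)
    if (min(ev$values) < -1e-8)
      stop("kinship matrix is not PSD; cannot draw genetic values")
    L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    g <- sqrt(va) * drop(L %*% rnorm(n))
  } else {
    g <- rep(0, n)
  }
  eps <- if (ve > 0) rnorm(n, 0, sqrt(ve)) else rep(0, n)
  gs <- mu + beta_alt * altitudes + g + eps
  n_resampled <- 0L
  while (any(gs <= 0)) {
    bad <- which(gs <= 0)
    if (ve <= 0)
      stop("non-positive genome size with ve = 0; check mu/beta_alt")
    eps[bad] <- rnorm(length(bad), 0, sqrt(ve))
    gs <- mu + beta_alt * altitudes + g + eps
    n_resampled <- n_resampled + length(bad)
  }
  out <- data.frame(individual_id = G$individual_ids, altitude = altitudes,
                    gs_gb = gs)
  for (cl in names(repeat_fractions))
    out[[paste0("mb_", cl)]] <- repeat_fractions[[cl]] * gs * 1000
  out$mb_other <- (1 - sum(repeat_fractions)) * gs * 1000
  class(out) <- c("repeat_profile", "data.frame")
  attr(out, "truth") <- list(mu = mu, beta_alt = beta_alt, va = va, ve = ve,
                             repeat_fractions = repeat_fractions, g = g)
  attr(out, "n_resampled") <- n_resampled
  attr(out, "K") <- K
  out
}

#' Simulate low-coverage shotgun read-class assignments
#'
#' Reads are assigned to repeat classes by a multinomial draw with
#' probabilities proportional to each class's share of the genome
#' (class Mb / genome size in Mb); the remaining probability mass goes to
#' "other". Emulates class-level counts from low-coverage whole-genome
#' sequencing mapped against a repeat library.
#'
#' @param profile A `repeat_profile` from [simulate_genome_size()].
#' @param total_reads Reads per individual.
#' @param seed Master integer seed.
#' @return Data frame with `individual_id`, one count column per class,
#'   `other`, and `total_reads`; counts sum to `total_reads` per row.
#' @export
simulate_read_assignments <- function(profile, total_reads = 1e5, seed = 1) {
  check_count(total_reads, "total_reads")
  classes <- sub("^mb_", "", grep("^mb_", names(profile), value = TRUE))
  classes <- setdiff(classes, "other")
  set.seed(derive_seed(seed, "simulate_read_assignments"))
  n <- nrow(profile)
  counts <- matrix(0L, n, length(classes) + 1L,
                   dimnames = list(NULL, c(classes, "other")))
  for (i in seq_len(n)) {
    gs_mb <- profile$gs_gb[i] * 1000
    mb <- vapply(classes, function(cl) profile[[paste0("mb_", cl)]][i],
                 numeric(1))
    if (any(mb > gs_mb + 1e-9))
      stop("class Mb exceeds genome size for individual ",
           profile$individual_id[i])
    pr <- c(mb / gs_mb, max(0, 1 - sum(mb) / gs_mb))
    counts[i, ] <- drop(rmultinom(1, total_reads, pr))
  }
  out <- data.frame(individual_id = profile$individual_id, counts,
                    total_reads = as.integer(total_reads))
  out
}

#' Simulate technical flow-cytometry replicates
#'
#' Two technical measurements per line are drawn around a line-specific true
#' genome size. Defaults represent the repeatability typical of plant flow
#' cytometry with a co-prepared internal standard: a between-line standard
#' deviation of about 0.104 pg/1C and a measurement standard deviation of
#' about 0.031 pg/1C, which together imply a replicate-replicate correlation
#' near 0.92 and a mean absolute replicate difference near 0.035 pg/1C.
#'
#' @param n_lines Number of inbred lines measured in duplicate.
#' @param mean_1c_pg Mean 1C genome size, pg.
#' @param sd_line Between-line SD of true 1C genome size, pg.
#' @param sd_meas Measurement SD per technical replicate, pg.
#' @param seed Master integer seed.
#' @return Data frame with `line`, `rep1_pg`, `rep2_pg`.
#' @export
simulate_cytometry_replicates <- function(n_lines = 35, mean_1c_pg = 2.3,
                                          sd_line = 0.1039848,
                                          sd_meas = 0.03066345, seed = 1) {
  check_count(n_lines, "n_lines", min = 2L)
  set.seed(derive_seed(seed, "simulate_cytometry_replicates"))
  truth <- rnorm(n_lines, mean_1c_pg, sd_line)
  data.frame(line = paste0("line", seq_len(n_lines)),
             rep1_pg = truth + rnorm(n_lines, 0, sd_meas),
             rep2_pg = truth + rnorm(n_lines, 0, sd_meas))
}
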