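#' Configuration for the growth-chamber simulator
#'
#' Defaults mirror the growth-chamber conditions the mediation model targets:
#' 200 seedlings in 50 maternal families, 2C genome sizes spanning about
#' 1.13 Gb, stomatal cell size near 0.003 cm, observed mean daily leaf growth
#' near 4.56 cm/day, a weak positive genome-size effect on cell size
#' (+0.05 per Gb on the log scale) and a stronger negative effect on
#' cell-production rate (-0.3 per Gb). When `beta0` is `NULL` it is set so
#' that the expected observed elongation rate equals `ler_mean` given the
#' lognormal variance terms.
#'
#' @param n_maternal Number of maternal families.
#' @param n_per_family Seedlings per family.
#' @param gamma0 Log mean cell size (log cm).
#' @param gamma_gs Genome-size effect on log cell size, per Gb.
#' @param beta0 Log mean cell-production rate (log cells/day); `NULL` derives
#'   it from `ler_mean`.
#' @param beta_gs Genome-size effect on log cell-production rate, per Gb.
#' @param ler_mean Target expected observed leaf elongation rate, cm/day.
#' @param tau_a2,tau_b2 Maternal variances on log cell size / log production.
#' @param sigma_cs2,sigma_cp2 Seedling variances on the two mediators.
#' @param sigma_cell_obs2,sigma_ler_obs2 Observation (log-scale) variances of
#'   cell-length and daily-increment measurements.
#' @param n_cells_per_seedling Stomatal cell lengths measured per seedling.
#' @param n_days Number of daily length measurements (>= 2; increments are
#'   `n_days - 1` per seedling).
#' @param gs_range Range (Gb, 2C) of the uniform genome-size distribution.
#' @param seed Master integer seed.
#' @return A validated list of class `growth_sim_config`.
#' @export
growth_sim_config <- function(n_maternal = 50, n_per_family = 4,
                              gamma0 = log(0.003), gamma_gs = 0.05,
                              beta0 = NULL, beta_gs = -0.3, ler_mean = 4.56,
                              tau_a2 = 0.01, tau_b2 = 0.01,
                              sigma_cs2 = 0.01, sigma_cp2 = 0.01,
                              sigma_cell_obs2 = 0.04, sigma_ler_obs2 = 0.04,
                              n_cells_per_seedling = 10, n_days = 3,
                              gs_range = c(4.9, 6.03), seed = 1) {
  check_count(n_maternal, "n_maternal")
  check_count(n_per_family, "n_per_family")
  check_count(n_cells_per_seedling, "n_cells_per_seedling")
  check_count(n_days, "n_days", min = 2L)
  vars <- c(tau_a2 = tau_a2, tau_b2 = tau_b2, sigma_cs2 = sigma_cs2,
            sigma_cp2 = sigma_cp2, sigma_cell_obs2 = sigma_cell_obs2,
            sigma_ler_obs2 = sigma_ler_obs2)
  if (any(!is.finite(vars)) || any(vars < 0))
    stop("all variances must be finite and non-negative")
  if (length(gs_range) != 2 || gs_range[1] > gs_range[2] || any(gs_range <= 0))
    stop("gs_range must be an increasing positive pair (Gb)")
  if (is.null(beta0)) {
    vtot <- tau_a2 + tau_b2 + sigma_cs2 + sigma_cp2 + sigma_ler_obs2
    beta0 <- log(ler_mean) - gamma0 - vtot / 2
  }
  stopifnot(is.finite(gamma0), is.finite(gamma_gs), is.finite(beta0),
            is.finite(beta_gs))
  structure(list(n_maternal = as.integer(n_maternal),
                 n_per_family = as.integer(n_per_family),
                 gamma0 = gamma0, gamma_gs = gamma_gs, beta0 = beta0,
                 beta_gs = beta_gs, tau_a2 = tau_a2, tau_b2 = tau_b2,
                 sigma_cs2 = sigma_cs2, sigma_cp2 = sigma_cp2,
                 sigma_cell_obs2 = sigma_cell_obs2,
                 sigma_ler_obs2 = sigma_ler_obs2,
                 n_cells_per_seedling = as.integer(n_cells_per_seedling),
                 n_days = as.integer(n_days), gs_range = gs_range,
                 seed = as.integer(seed)),
            class = "growth_sim_config")
}

#' Simulate growth-chamber data under the multiplicative mediation model
#'
#' Leaf elongation rate is the product of cell size (CS) and cell-production
#' rate (CP); on the log scale, for seedling i in maternal family m(i):
#' \deqn{\log CS_i = \gamma_0 + \gamma_{GS}\tilde{GS}_i + a_{m(i)} + e_i}
#' \deqn{\log CP_i = \beta_0 + \beta_{GS}\tilde{GS}_i + b_{m(i)} + f_i}
#' with centered genome size \eqn{\tilde{GS}}, maternal effects
#' `a, b ~ N(0, tau^2)` and seedling deviations `e, f`. Observed stomatal
#' cell lengths are lognormal around CS; observed daily increments are
#' lognormal around CS x CP. Daily leaf lengths are emitted as a baseline
#' length plus cumulative increments. The truth record satisfies
#' `LER = CS x CP` identically before observation noise.
#'
#' @param cfg A [growth_sim_config()].
#' @return A list of class `growth_data` with elements `seedlings`
#'   (seedling, maternal, gs_gb), `lengths` (seedling, day, length_cm),
#'   `cells` (seedling, cell_cm) and `truth` (config plus the latent
#'   seedling-level log CS, log CP, log LER).
#' @export
simulate_growth_data <- function(cfg) {
  stopifnot(inherits(cfg, "growth_sim_config"))
  set.seed(derive_seed(cfg$seed, "simulate_growth_data"))
  n <- cfg$n_maternal * cfg$n_per_family
  maternal <- rep(seq_len(cfg$n_maternal), each = cfg$n_per_family)
  seedling <- sprintf("m%02d_s%d", maternal,
                      rep(seq_len(cfg$n_per_family), cfg$n_maternal))
  gs <- runif(n, cfg$gs_range[1], cfg$gs_range[2])
  gs_c <- gs - mean(cfg$gs_range)
  a <- rnorm(cfg$n_maternal, 0, sqrt(cfg$tau_a2))
  b <- rnorm(cfg$n_maternal, 0, sqrt(cfg$tau_b2))
  e <- rnorm(n, 0, sqrt(cfg$sigma_cs2))
  f <- rnorm(n, 0, sqrt(cfg$sigma_cp2))
  log_cs <- cfg$gamma0 + cfg$gamma_gs * gs_c + a[maternal] + e
  log_cp <- cfg$beta0 + cfg$beta_gs * gs_c + b[maternal] + f
  log_ler <- log_cs + log_cp

  n_cells <- cfg$n_cells_per_seedling
  cells <- data.frame(seedling = rep(seedling, each = n_cells),
                      cell_cm = rlnorm(n * n_cells, rep(log_cs, each = n_cells),
                                       sqrt(cfg$sigma_cell_obs2)))
  n_inc <- cfg$n_days - 1L
  inc <- matrix(rlnorm(n * n_inc, rep(log_ler, each = n_inc),
                       sqrt(cfg$sigma_ler_obs2)), n_inc, n)
  base_len <- 10 # cm at first measurement
  lengths <- data.frame(seedling = rep(seedling, each = cfg$n_days),
                        day = rep(seq_len(cfg$n_days), n),
                        length_cm = as.vector(rbind(base_len,
                                                    base_len + apply(inc, 2, cumsum))))
  structure(list(seedlings = data.frame(seedling = seedling,
                                        maternal = maternal, gs_gb = gs),
                 lengths = lengths, cells = cells,
                 truth = list(config = cfg, log_cs = log_cs, log_cp = log_cp,
                              log_ler = log_ler, gs_centered = gs_c)),
            class = "growth_data")
}

#' Simulate a SAM cell-count and flowering-time panel
#'
#' Generates an inbred-line panel in which flowering time depends linearly on
#' a latent line-level cell count, two candidate-locus genotypes, a polygenic
#' term with covariance `V_A K`, and independent noise; replicated cell counts
#' with shared block effects are emitted per growth phase for BLUE estimation.
#'
#' @param n_lines Number of inbred lines.
#' @param slope Flowering-time change per cell (days/cell).
#' @param effect_bak1,effect_sda1 Additive fixed effects of the two candidate
#'   loci (days per allele).
#' @param K Kinship among lines (`kinship_matrix`, plain matrix, or `NULL`
#'   for independence).
#' @param va Polygenic variance (days^2).
#' @param noise Residual SD of flowering time (days).
#' @param n_blocks Replicate blocks per phase.
#' @param sigma_block SD of block effects (cells).
#' @param sigma_count SD of within-block count noise (cells).
#' @param phases Growth-phase labels.
#' @param seed Master integer seed.
#' @return List of class `sam_data`: `lines` (line, flowering, bak1, sda1,
#'   true cell count per phase), `counts` (line, block, phase, cells) and
#'   `truth`.
#' @export
simulate_sam_data <- function(n_lines = 14, slope = -0.1, effect_bak1 = 2,
                              effect_sda1 = -1.5, K = NULL, va = 4, noise = 1,
                              n_blocks = 3, sigma_block = 15, sigma_count = 10,
                              phases = c("G1", "G2", "G3"), seed = 1) {
  check_count(n_lines, "n_lines", min = 2L)
  set.seed(derive_seed(seed, "simulate_sam_data"))
  Kv <- if (is.null(K)) diag(n_lines) else as_kinship_values(K)
  if (nrow(Kv) != n_lines) stop("K must be n_lines x n_lines")
  ev <- eigen((Kv + t(Kv)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("K must be PSD")
  line <- paste0("line", seq_len(n_lines))
  bak1 <- rbinom(n_lines, 2, 0.3)
  sda1 <- rbinom(n_lines, 2, 0.3)
  phase_mean <- setNames(seq(350, 550, length.out = length(phases)), phases)
  cells_base <- rnorm(n_lines, 0, 50)
  g <- if (va > 0) {
    L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    sqrt(va) * drop(L %*% rnorm(n_lines))
  } else rep(0, n_lines)
  flowering <- 70 + slope * cells_base + effect_bak1 * bak1 +
    effect_sda1 * sda1 + g + (if (noise > 0) rnorm(n_lines, 0, noise) else 0)
  counts <- do.call(rbind, lapply(phases, function(ph) {
    do.call(rbind, lapply(seq_len(n_blocks), function(bl) {
      be <- rnorm(1, 0, sigma_block)
      data.frame(line = line, block = paste0("b", bl), phase = ph,
                 cells = phase_mean[[ph]] + cells_base + be +
                   rnorm(n_lines, 0, sigma_count))
    }))
  }))
  lines <- data.frame(line = line, flowering = flowering, bak1 = bak1,
                      sda1 = sda1)
  for (ph in phases) lines[[paste0("cells_", ph)]] <- phase_mean[[ph]] + cells_base
  structure(list(lines = lines, counts = counts,
                 truth = list(slope = slope, effect_bak1 = effect_bak1,
                              effect_sda1 = effect_sda1, va = va,
                              noise = noise, cells_base = cells_base, g = g)),
            class = "sam_data")
}
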