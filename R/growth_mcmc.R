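#' Specification of the hierarchical growth model and its sampler
#'
#' Priors are informative on the measurement scales of the two mediators:
#' the cell-size intercept is centred on `log(prior_cs_mean)` (default
#' 0.003 cm, a typical stomatal cell length) and the cell-production
#' intercept on `log(prior_ler_mean) - log(prior_cs_mean)` (default LER
#' 4.0 cm/day), so the two intercepts jointly encode a prior elongation
#' rate. Genome-size slopes are centred at zero; variances get half-normal
#' priors. Default chain settings match a long production run (200,000
#' burn-in, 500,000 iterations thinned by 500, two chains); recovery tests
#' use the scaled-down settings documented in the vignette.
#'
#' @param prior_cs_mean Prior mean stomatal cell size, cm.
#' @param prior_ler_mean Prior mean leaf elongation rate, cm/day.
#' @param prior_sd_intercepts Prior SD of the two intercepts (log scale).
#' @param prior_sd_slopes Prior SD of the genome-size slopes (per Gb).
#' @param var_prior_scale Scale of the half-normal priors on variances.
#' @param chains Number of MCMC chains.
#' @param burn_in Burn-in iterations (adaptation happens only here).
#' @param iterations Post-burn-in iterations.
#' @param thin Thinning interval; `floor(iterations / thin)` samples are
#'   kept per chain.
#' @param seed Master integer seed.
#' @return A validated list of class `growth_model_spec`.
#' @export
growth_model_spec <- function(prior_cs_mean = 0.003, prior_ler_mean = 4.0,
                              prior_sd_intercepts = 0.5,
                              prior_sd_slopes = 0.5, var_prior_scale = 0.5,
                              chains = 2, burn_in = 200000,
                              iterations = 500000, thin = 500, seed = 1) {
  stopifnot(prior_cs_mean > 0, prior_ler_mean > 0, prior_sd_intercepts > 0,
            prior_sd_slopes > 0, var_prior_scale > 0)
  check_count(chains, "chains")
  check_count(burn_in, "burn_in")
  check_count(iterations, "iterations")
  check_count(thin, "thin")
  structure(list(prior_cs_mean = prior_cs_mean,
                 prior_ler_mean = prior_ler_mean,
                 prior_sd_intercepts = prior_sd_intercepts,
                 prior_sd_slopes = prior_sd_slopes,
                 var_prior_scale = var_prior_scale,
                 chains = as.integer(chains), burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "growth_model_spec")
}

# Parameters monitored in the posterior sample matrices.
growth_par_names <- c("gamma0", "gamma_gs", "beta0", "beta_gs",
                      "tau_a2", "tau_b2", "sigma_cs2", "sigma_cp2",
                      "sigma_cell_obs2", "sigma_ler_obs2",
                      "mean_log_cs", "mean_log_cp", "mean_log_ler")

#' Fit the hierarchical Bayesian growth mediation model
#'
#' Samples the posterior of the log-scale mediation model in which leaf
#' elongation rate is the product of cell size and an unobserved
#' cell-production rate:
#' observation level, `log(cell length) ~ N(log CS_i, sigma2_cell_obs)` and
#' `log(daily increment) ~ N(log CS_i + log CP_i, sigma2_ler_obs)`;
#' seedling level, `log CS_i = gamma0 + gamma_gs GS~_i + a_m + e_i` and
#' `log CP_i = beta0 + beta_gs GS~_i + b_m + f_i` with centered genome size;
#' maternal level, `a_m ~ N(0, tau2_a)`, `b_m ~ N(0, tau2_b)`. The sampler
#' is Metropolis-within-Gibbs: all location parameters have conjugate normal
#' full conditionals; the six variances use random-walk Metropolis on the log
#' scale with half-normal priors, adapted during burn-in only.
#'
#' @param data Long observation table from [derive_observations()].
#' @param spec A [growth_model_spec()].
#' @return Object of class `growth_posterior`: `samples` (list of one matrix
#'   per chain, `floor(iterations/thin)` rows), `summary` (posterior mean,
#'   sd, 95% interval, split R-hat, ESS per parameter), `spec`,
#'   `accept_rates`, `n_seedlings`, `n_families`, `flags`.
#' @export
fit_growth_model <- function(data, spec = growth_model_spec()) {
  stopifnot(inherits(spec, "growth_model_spec"))
  if (any(data$value <= 0)) stop("non-positive observations reached the sampler")
  seedlings <- unique(data$seedling)
  n <- length(seedlings)
  sidx <- match(data$seedling, seedlings)
  first <- match(seedlings, data$seedling)
  fam_lab <- data$maternal[first]
  fams <- unique(fam_lab)
  M <- length(fams)
  fam <- match(fam_lab, fams)
  if (M < 2) warning("only one maternal family: tau2 parameters are unidentified")
  gs <- data$gs_gb[first]
  gsc <- gs - mean(gs)

  is_cell <- data$obs_type == "cell"
  is_inc <- data$obs_type == "increment"
  if (!any(is_cell) || !any(is_inc))
    stop("both cell and increment observations are required")
  ylc <- log(data$value[is_cell]); sc <- sidx[is_cell]
  yli <- log(data$value[is_inc]); si <- sidx[is_inc]
  n_cell <- tabulate(sc, n)
  S_cell <- numeric(n); S_cell[sort(unique(sc))] <- as.vector(rowsum(ylc, sc))
  Q_cell <- numeric(n); Q_cell[sort(unique(sc))] <- as.vector(rowsum(ylc^2, sc))
  n_inc <- tabulate(si, n)
  S_inc <- numeric(n); S_inc[sort(unique(si))] <- as.vector(rowsum(yli, si))
  Q_inc <- numeric(n); Q_inc[sort(unique(si))] <- as.vector(rowsum(yli^2, si))
  n_fam <- tabulate(fam, M)
  Xf <- cbind(1, gsc)
  XtX <- crossprod(Xf)

  pm_g0 <- log(spec$prior_cs_mean)
  pm_b0 <- log(spec$prior_ler_mean) - log(spec$prior_cs_mean)
  pv_int <- spec$prior_sd_intercepts^2
  pv_slp <- spec$prior_sd_slopes^2
  hn_scale <- spec$var_prior_scale

  n_keep <- spec$iterations %/% spec$thin
  total <- spec$burn_in + n_keep * spec$thin
  var_names <- c("tau_a2", "tau_b2", "sigma_cs2", "sigma_cp2",
                 "sigma_cell_obs2", "sigma_ler_obs2")

  run_chain <- function(chain_id) {
    set.seed(derive_seed(spec$seed, paste0("growth_chain_", chain_id)))
    # data-driven initial values, jittered per chain
    u <- ifelse(n_cell > 0, S_cell / pmax(n_cell, 1), pm_g0) +
      rnorm(n, 0, 0.05)
    v <- ifelse(n_inc > 0, S_inc / pmax(n_inc, 1), pm_g0 + pm_b0) - u +
      rnorm(n, 0, 0.05)
    a <- rep(0, M); b <- rep(0, M)
    cf_u <- drop(solve(XtX + diag(1e-8, 2), crossprod(Xf, u)))
    cf_v <- drop(solve(XtX + diag(1e-8, 2), crossprod(Xf, v)))
    gamma0 <- cf_u[1]; gamma_gs <- cf_u[2]
    beta0 <- cf_v[1]; beta_gs <- cf_v[2]
    vars <- c(tau_a2 = 0.02, tau_b2 = 0.02, sigma_cs2 = 0.02,
              sigma_cp2 = 0.02, sigma_cell_obs2 = 0.05,
              sigma_ler_obs2 = 0.05)
    step <- setNames(rep(0.5, 6), var_names)
    acc <- n_prop <- setNames(rep(0, 6), var_names)
    acc_window <- n_window <- setNames(rep(0, 6), var_names)
    out <- matrix(NA_real_, n_keep, length(growth_par_names),
                  dimnames = list(NULL, growth_par_names))
    k <- 0L

    log_var_post <- function(s2, ss, nn) {
      # normal likelihood with nn residuals summing squares ss, half-normal
      # prior on the variance, log-scale Jacobian
      -0.5 * nn * log(s2) - 0.5 * ss / s2 - 0.5 * (s2 / hn_scale)^2 + log(s2)
    }
    mh_update <- function(name, ss, nn) {
      s2 <- vars[[name]]
      prop <- s2 * exp(rnorm(1, 0, step[[name]]))
      lr <- log_var_post(prop, ss, nn) - log_var_post(s2, ss, nn)
      n_prop[[name]] <<- n_prop[[name]] + 1
      n_window[[name]] <<- n_window[[name]] + 1
      if (is.finite(lr) && log(runif(1)) < lr) {
        vars[[name]] <<- prop
        acc[[name]] <<- acc[[name]] + 1
        acc_window[[name]] <<- acc_window[[name]] + 1
      }
    }

    for (it in seq_len(total)) {
      mu_u <- gamma0 + gamma_gs * gsc + a[fam]
      mu_v <- beta0 + beta_gs * gsc + b[fam]
      # seedling-level latent log CS
      P <- 1 / vars[["sigma_cs2"]] + n_cell / vars[["sigma_cell_obs2"]] +
        n_inc / vars[["sigma_ler_obs2"]]
      mn <- (mu_u / vars[["sigma_cs2"]] + S_cell / vars[["sigma_cell_obs2"]] +
               (S_inc - n_inc * v) / vars[["sigma_ler_obs2"]]) / P
      u <- rnorm(n, mn, sqrt(1 / P))
      # seedling-level latent log CP
      P <- 1 / vars[["sigma_cp2"]] + n_inc / vars[["sigma_ler_obs2"]]
      mn <- (mu_v / vars[["sigma_cp2"]] +
               (S_inc - n_inc * u) / vars[["sigma_ler_obs2"]]) / P
      v <- rnorm(n, mn, sqrt(1 / P))
      # maternal effects
      ru <- u - gamma0 - gamma_gs * gsc
      Ra <- numeric(M); Ra[sort(unique(fam))] <- as.vector(rowsum(ru, fam))
      P <- n_fam / vars[["sigma_cs2"]] + 1 / vars[["tau_a2"]]
      a <- rnorm(M, (Ra / vars[["sigma_cs2"]]) / P, sqrt(1 / P))
      rv <- v - beta0 - beta_gs * gsc
      Rb <- numeric(M); Rb[sort(unique(fam))] <- as.vector(rowsum(rv, fam))
      P <- n_fam / vars[["sigma_cp2"]] + 1 / vars[["tau_b2"]]
      b <- rnorm(M, (Rb / vars[["sigma_cp2"]]) / P, sqrt(1 / P))
      # fixed effects, bivariate conjugate updates
      z <- u - a[fam]
      Lam <- XtX / vars[["sigma_cs2"]] + diag(c(1 / pv_int, 1 / pv_slp))
      rhs <- crossprod(Xf, z) / vars[["sigma_cs2"]] + c(pm_g0 / pv_int, 0)
      ch <- chol(Lam)
      mu_post <- backsolve(ch, forwardsolve(t(ch), rhs))
      draw <- mu_post + backsolve(ch, rnorm(2))
      gamma0 <- draw[1]; gamma_gs <- draw[2]
      z <- v - b[fam]
      Lam <- XtX / vars[["sigma_cp2"]] + diag(c(1 / pv_int, 1 / pv_slp))
      rhs <- crossprod(Xf, z) / vars[["sigma_cp2"]] + c(pm_b0 / pv_int, 0)
      ch <- chol(Lam)
      mu_post <- backsolve(ch, forwardsolve(t(ch), rhs))
      draw <- mu_post + backsolve(ch, rnorm(2))
      beta0 <- draw[1]; beta_gs <- draw[2]
      # variances by random-walk Metropolis on the log scale
      e <- u - gamma0 - gamma_gs * gsc - a[fam]
      f <- v - beta0 - beta_gs * gsc - b[fam]
      mh_update("sigma_cs2", sum(e^2), n)
      mh_update("sigma_cp2", sum(f^2), n)
      mh_update("tau_a2", sum(a^2), M)
      mh_update("tau_b2", sum(b^2), M)
      ss_cell <- sum(Q_cell - 2 * u * S_cell + n_cell * u^2)
      mh_update("sigma_cell_obs2", ss_cell, sum(n_cell))
      w <- u + v
      ss_ler <- sum(Q_inc - 2 * w * S_inc + n_inc * w^2)
      mh_update("sigma_ler_obs2", ss_ler, sum(n_inc))
      # step-size adaptation during burn-in only (targets ~0.44 acceptance)
      if (it <= spec$burn_in && it %% 50 == 0) {
        rate <- ifelse(n_window > 0, acc_window / pmax(n_window, 1), 0.44)
        step[] <- pmin(pmax(step * exp(0.6 * (rate - 0.44)), 1e-3), 5)
        acc_window[] <- 0; n_window[] <- 0
      }
      if (it > spec$burn_in && (it - spec$burn_in) %% spec$thin == 0) {
        k <- k + 1L
        out[k, ] <- c(gamma0, gamma_gs, beta0, beta_gs,
                      vars[["tau_a2"]], vars[["tau_b2"]],
                      vars[["sigma_cs2"]], vars[["sigma_cp2"]],
                      vars[["sigma_cell_obs2"]], vars[["sigma_ler_obs2"]],
                      mean(u), mean(v), mean(u + v))
      }
    }
    list(samples = out, accept = ifelse(n_prop > 0, acc / n_prop, NA_real_))
  }

  chains <- lapply(seq_len(spec$chains), run_chain)
  samples <- lapply(chains, `[[`, "samples")
  accept <- do.call(rbind, lapply(chains, `[[`, "accept"))
  flags <- character(0)
  if (any(accept < 0.05, na.rm = TRUE))
    flags <- c(flags, "divergent adaptation: variance acceptance < 0.05")
  if (M < 2) flags <- c(flags, "tau2 unidentified (single maternal family)")

  all_s <- do.call(rbind, samples)
  summ <- data.frame(
    parameter = growth_par_names,
    mean = colMeans(all_s),
    sd = apply(all_s, 2, sd),
    q2.5 = apply(all_s, 2, quantile, 0.025),
    q97.5 = apply(all_s, 2, quantile, 0.975),
    rhat = vapply(growth_par_names, function(p)
      split_rhat(lapply(samples, function(s) s[, p])), numeric(1)),
    ess = vapply(growth_par_names, function(p)
      ess_chains(lapply(samples, function(s) s[, p])), numeric(1)),
    row.names = NULL)

  structure(list(samples = samples, summary = summ, spec = spec,
                 accept_rates = accept, n_seedlings = n, n_families = M,
                 flags = flags),
            class = "growth_posterior")
}

#' @export
print.growth_posterior <- function(x, ...) {
  cat(sprintf("growth_posterior: %d chains x %d samples, %d seedlings / %d families\n",
              length(x$samples), nrow(x$samples[[1]]), x$n_seedlings,
              x$n_families))
  print(x$summary[1:4, ], digits = 3, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Split R-hat (each chain halved) for a list of numeric chains.
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); nn <- length(halves[[1]])
  if (nn < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- nn * var(means)
  if (W < 1e-12) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Effective sample size by Geyer initial positive sequence, summed over chains.
ess_chains <- function(chain_list) {
  sum(vapply(chain_list, function(x) {
    nn <- length(x)
    if (sd(x) < 1e-12) return(nn)
    rho <- acf(x, lag.max = min(nn - 1, 200), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq(1, length(rho) - 1, by = 2)) {
      pair <- rho[k] + rho[k + 1]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    nn / (1 + 2 * s)
  }, numeric(1)))
}

#' Prior-sensitivity scan over elongation-rate and cell-size prior means
#'
#' Refits the growth model over a grid of prior means (one independent seeded
#' fit per cell, typically with reduced MCMC settings) and collects the
#' posterior mean and the posterior probability of a negative sign for both
#' genome-size slopes, plus an R-hat convergence flag. Per-cell failures are
#' recorded and the scan continues.
#'
#' @param data Long observation table from [derive_observations()].
#' @param ler_prior_grid Prior means for leaf elongation rate, cm/day.
#' @param cs_prior_grid Prior means for cell size, cm.
#' @param spec Base [growth_model_spec()] (its prior means are overridden
#'   per cell; use reduced `burn_in`/`iterations` for scans).
#' @return Data frame with one row per grid cell: prior means, posterior
#'   means, `p_neg_*` sign probabilities, `max_rhat`, `error`.
#' @export
prior_sensitivity_scan <- function(data, ler_prior_grid, cs_prior_grid,
                                   spec = growth_model_spec(chains = 1,
                                                            burn_in = 1000,
                                                            iterations = 4000,
                                                            thin = 4)) {
  stopifnot(length(ler_prior_grid) > 0, length(cs_prior_grid) > 0)
  grid <- expand.grid(prior_ler_mean = ler_prior_grid,
                      prior_cs_mean = cs_prior_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- spec
    sp$prior_ler_mean <- grid$prior_ler_mean[i]
    sp$prior_cs_mean <- grid$prior_cs_mean[i]
    sp$seed <- derive_seed(spec$seed, paste0("scan_cell_", i))
    res <- tryCatch(fit_growth_model(data, sp), error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(grid[i, ], gamma_gs_mean = NA, beta_gs_mean = NA,
                        p_neg_gamma_gs = NA, p_neg_beta_gs = NA,
                        max_rhat = NA, error = conditionMessage(res)))
    s <- do.call(rbind, res$samples)
    data.frame(grid[i, ],
               gamma_gs_mean = mean(s[, "gamma_gs"]),
               beta_gs_mean = mean(s[, "beta_gs"]),
               p_neg_gamma_gs = mean(s[, "gamma_gs"] < 0),
               p_neg_beta_gs = mean(s[, "beta_gs"] < 0),
               max_rhat = max(res$summary$rhat, na.rm = TRUE),
               error = NA_character_)
  })
  do.call(rbind, rows)
}
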