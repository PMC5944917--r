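#' Derive model-ready observations from raw growth-chamber records
#'
#' Daily leaf lengths are differenced into daily increments; zero or negative
#' increments (measurement slips) are excluded and counted. Cell-length
#' observations pass through. All observations are emitted in long format
#' with an observation-type tag, ready for [fit_growth_model()].
#'
#' @param raw A `growth_data` list (from [simulate_growth_data()] or
#'   [read_growth_data()]): `seedlings` (seedling, maternal, gs_gb),
#'   `lengths` (seedling, day, length_cm), `cells` (seedling, cell_cm).
#' @return Data frame with columns `seedling`, `maternal`, `gs_gb`,
#'   `obs_type` (`"cell"` or `"increment"`), `day` (NA for cells), `value`.
#'   Attributes: `n_dropped_increments`, `dropped_seedlings` (no positive
#'   increment).
#' @export
derive_observations <- function(raw) {
  stopifnot(is.list(raw), !is.null(raw$seedlings), !is.null(raw$lengths),
            !is.null(raw$cells))
  sinfo <- raw$seedlings
  inc_rows <- list()
  n_dropped <- 0L
  for (s in unique(raw$lengths$seedling)) {
    li <- raw$lengths[raw$lengths$seedling == s, , drop = FALSE]
    li <- li[order(li$day), , drop = FALSE]
    if (nrow(li) < 2) next
    inc <- diff(li$length_cm)
    keep <- inc > 0
    n_dropped <- n_dropped + sum(!keep)
    if (any(keep))
      inc_rows[[s]] <- data.frame(seedling = s, day = li$day[-1][keep],
                                  value = inc[keep])
  }
  inc_tab <- do.call(rbind, inc_rows)
  no_inc <- setdiff(sinfo$seedling, inc_tab$seedling)
  if (length(no_inc))
    warning("seedlings with no positive increment excluded: ",
            paste(no_inc, collapse = ", "))
  keep_seed <- setdiff(sinfo$seedling, no_inc)
  sinfo <- sinfo[sinfo$seedling %in% keep_seed, , drop = FALSE]
  cells <- raw$cells[raw$cells$seedling %in% keep_seed, , drop = FALSE]
  if (any(cells$cell_cm <= 0)) stop("cell lengths must be positive")
  look <- function(s, col) sinfo[[col]][match(s, sinfo$seedling)]
  out <- rbind(
    data.frame(seedling = cells$seedling,
               maternal = look(cells$seedling, "maternal"),
               gs_gb = look(cells$seedling, "gs_gb"),
               obs_type = "cell", day = NA_integer_, value = cells$cell_cm),
    data.frame(seedling = inc_tab$seedling,
               maternal = look(inc_tab$seedling, "maternal"),
               gs_gb = look(inc_tab$seedling, "gs_gb"),
               obs_type = "increment", day = inc_tab$day,
               value = inc_tab$value))
  attr(out, "n_dropped_increments") <- n_dropped
  attr(out, "dropped_seedlings") <- no_inc
  out
}

#' Marginal genome-size effect on log leaf elongation rate
#'
#' Regresses seedling-mean log daily increments on centered genome size by
#' ordinary least squares with maternal-family-clustered standard errors.
#' Under the mediation model the marginal slope equals the sum of the two
#' path slopes (effect on log cell size plus effect on log cell-production
#' rate), so this is the model-free consistency check for
#' \eqn{\gamma_{GS} + \beta_{GS}}.
#'
#' @param data Long observation table from [derive_observations()].
#' @return List with `slope`, `se` (cluster-robust), `p`, `n_seedlings`.
#' @export
marginal_gs_effect <- function(data) {
  inc <- data[data$obs_type == "increment", , drop = FALSE]
  agg <- aggregate(list(mean_log_ler = log(inc$value)),
                   by = list(seedling = inc$seedling,
                             maternal = inc$maternal, gs_gb = inc$gs_gb),
                   FUN = mean)
  if (nrow(agg) < 3) stop("at least 3 seedlings are required")
  if (sd(agg$gs_gb) == 0) stop("zero genome-size variance; slope undefined")
  agg$gs_c <- agg$gs_gb - mean(agg$gs_gb)
  fit <- lm(mean_log_ler ~ gs_c, data = agg)
  # suppressWarnings: summary.lm complains on noiseless (zero-residual) input
  vc <- suppressWarnings(sandwich::vcovCL(fit, cluster = agg$maternal))
  slope <- unname(coef(fit)["gs_c"])
  se <- sqrt(vc["gs_c", "gs_c"])
  list(slope = slope, se = se,
       p = 2 * pnorm(-abs(slope / se)), n_seedlings = nrow(agg))
}

#' Uncorrected seedling-level correlations with genome size
#'
#' Pearson correlations (with two-sided tests) of genome size against
#' seedling-mean leaf elongation rate and seedling-mean cell size, with no
#' relatedness correction. Labelled "uncorrected": family structure is
#' ignored, so these are descriptive companions to the hierarchical model.
#'
#' @param data Long observation table from [derive_observations()].
#' @return Data frame with rows `ler` and `cell_size`: `r`, `p`, `n`.
#' @export
raw_correlations <- function(data) {
  res <- lapply(c(ler = "increment", cell_size = "cell"), function(tp) {
    d <- data[data$obs_type == tp, , drop = FALSE]
    agg <- aggregate(list(value = d$value),
                     by = list(seedling = d$seedling, gs_gb = d$gs_gb),
                     FUN = mean)
    if (nrow(agg) < 3) stop("at least 3 seedlings are required")
    if (sd(agg$value) == 0 || sd(agg$gs_gb) == 0)
      stop("zero variance; correlation undefined")
    ct <- cor.test(agg$gs_gb, agg$value)
    data.frame(r = unname(ct$estimate), p = ct$p.value, n = nrow(agg))
  })
  out <- do.call(rbind, res)
  rownames(out) <- c("ler", "cell_size")
  out
}
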