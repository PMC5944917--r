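#' Clinal selection tests on genome size and repeat abundance
#'
#' Fits the kinship-null mixed model of [fit_lmm()] in one of three modes:
#' \describe{
#'   \item{`genome_size`}{trait = total genome size, fixed effects intercept
#'     and altitude — tests whether the cline in genome size exceeds the
#'     relatedness null.}
#'   \item{`repeat_conditional`}{trait = Mb of one repeat class, with genome
#'     size as an additional covariate — tests for selection on the repeat
#'     beyond its contribution to total genome size.}
#'   \item{`knob_excluded`}{trait = genome size minus the Mb attributable to
#'     both knob repeat classes (180bp and TR1) — re-tests the genome-size
#'     cline with knobs removed.}
#' }
#' Altitude (and genome size, when present) are mean-centered before fitting;
#' centering leaves the slope estimates unchanged. The raw (uncorrected)
#' Pearson correlation of the trait with altitude is reported alongside.
#'
#' @param profiles A `repeat_profile` data frame with columns `gs_gb` and
#'   `mb_<class>` (from [simulate_genome_size()], [abundance_from_assignments()]
#'   rows, or a read-in phenotype table).
#' @param altitudes Altitude (m) per individual; defaults to
#'   `profiles$altitude`.
#' @param K Kinship matrix over the same individuals.
#' @param mode One of `"genome_size"`, `"repeat_conditional"`,
#'   `"knob_excluded"`.
#' @param repeat_class Class analysed in `repeat_conditional` mode.
#' @param knob_classes Classes subtracted in `knob_excluded` mode.
#' @return A list of class `selection_fit`: the `lmm_fit`, the trait used,
#'   slope conversions (`beta_alt_gb_per_m`, `beta_alt_mb_per_m`,
#'   `beta_alt_kb_per_m`), and `raw_r`/`raw_p` from the uncorrected Pearson
#'   correlation with altitude.
#' @export
selection_scan <- function(profiles, altitudes = profiles$altitude, K,
                           mode = c("genome_size", "repeat_conditional",
                                    "knob_excluded"),
                           repeat_class = NULL,
                           knob_classes = c("knob180", "tr1")) {
  mode <- match.arg(mode)
  if (is.null(altitudes)) stop("altitudes are required")
  n <- nrow(profiles)
  if (length(altitudes) != n) stop("altitudes must match profiles rows")
  alt_c <- altitudes - mean(altitudes)
  if (mode == "genome_size") {
    y <- profiles$gs_gb
    X <- cbind(intercept = 1, altitude = alt_c)
  } else if (mode == "repeat_conditional") {
    if (is.null(repeat_class)) stop("repeat_class is required in repeat_conditional mode")
    col <- paste0("mb_", repeat_class)
    if (!col %in% names(profiles))
      stop("profiles has no column '", col, "'")
    y <- profiles[[col]]
    gs_c <- profiles$gs_gb - mean(profiles$gs_gb)
    X <- cbind(intercept = 1, altitude = alt_c, gs = gs_c)
  } else {
    cols <- paste0("mb_", knob_classes)
    miss <- setdiff(cols, names(profiles))
    if (length(miss)) stop("profiles missing knob columns: ",
                           paste(miss, collapse = ", "))
    knob_gb <- rowSums(profiles[, cols, drop = FALSE]) / 1000
    y <- profiles$gs_gb - knob_gb
    X <- cbind(intercept = 1, altitude = alt_c)
  }
  fit <- fit_lmm(y, X, K, lrt_term = 2L)
  r <- if (sd(y) > 0) cor.test(y, altitudes) else NULL
  structure(list(mode = mode, repeat_class = repeat_class, fit = fit,
                 trait = y,
                 beta_alt = unname(fit$beta["altitude"]),
                 beta_alt_gb_per_m = if (mode == "repeat_conditional")
                   NA_real_ else unname(fit$beta["altitude"]),
                 beta_alt_mb_per_m = if (mode == "repeat_conditional")
                   unname(fit$beta["altitude"]) else
                     unname(fit$beta["altitude"]) * 1000,
                 beta_alt_kb_per_m = if (mode == "repeat_conditional")
                   unname(fit$beta["altitude"]) * 1000 else
                     unname(fit$beta["altitude"]) * 1e6,
                 raw_r = if (is.null(r)) NA_real_ else unname(r$estimate),
                 raw_p = if (is.null(r)) NA_real_ else r$p.value),
            class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf("Clinal selection test (%s%s)\n", x$mode,
              if (!is.null(x$repeat_class)) paste0(": ", x$repeat_class) else ""))
  cat(sprintf("  beta_alt = %.4g  (Wald p = %.3g, LRT p = %.3g)\n",
              x$beta_alt, x$fit$wald_p[2], x$fit$lrt_p))
  cat(sprintf("  raw Pearson r with altitude = %.3f (p = %.3g)\n",
              x$raw_r, x$raw_p))
  invisible(x)
}

#' Per-family transposable-element scan with binomial excess test
#'
#' Fits the conditional repeat model (altitude effect on family abundance
#' given genome size and kinship) separately for each TE family, counts
#' families whose altitude LRT p-value falls below `alpha`, and asks by an
#' exact two-sided binomial test whether that count exceeds the `alpha * m`
#' expected by chance. Families with zero abundance variance are skipped and
#' reported.
#'
#' @param family_mb Numeric matrix or data frame, individuals x families, of
#'   per-family Mb.
#' @param altitudes Altitude (m) per individual.
#' @param gs Genome size (Gb) per individual.
#' @param K Kinship matrix.
#' @param alpha Per-family significance level.
#' @return List of class `family_scan`: per-family table (`family`,
#'   `beta_alt`, `p`), `n_significant`, `n_families` (tested), `binomial_p`,
#'   and `skipped` family names.
#' @export
te_family_scan <- function(family_mb, altitudes, gs, K, alpha = 0.05) {
  family_mb <- as.matrix(family_mb)
  if (!ncol(family_mb)) stop("at least one family is required")
  fam_names <- colnames(family_mb) %||% paste0("fam", seq_len(ncol(family_mb)))
  alt_c <- altitudes - mean(altitudes)
  gs_c <- gs - mean(gs)
  X <- cbind(intercept = 1, altitude = alt_c, gs = gs_c)
  rows <- list()
  skipped <- character(0)
  for (j in seq_len(ncol(family_mb))) {
    y <- family_mb[, j]
    if (sd(y) == 0) {
      skipped <- c(skipped, fam_names[j])
      next
    }
    fit <- fit_lmm(y, X, K, lrt_term = 2L)
    rows[[length(rows) + 1L]] <-
      data.frame(family = fam_names[j],
                 beta_alt = unname(fit$beta["altitude"]), p = fit$lrt_p)
  }
  tab <- do.call(rbind, rows)
  m <- nrow(tab)
  n_sig <- sum(tab$p < alpha, na.rm = TRUE)
  structure(list(families = tab, n_significant = n_sig, n_families = m,
                 binomial_p = binom.test(n_sig, m, alpha)$p.value,
                 alpha = alpha, skipped = skipped),
            class = "family_scan")
}

#' @export
print.family_scan <- function(x, ...) {
  cat(sprintf("TE family scan: %d/%d families significant at alpha = %.2f",
              x$n_significant, x$n_families, x$alpha))
  cat(sprintf(" (binomial p = %.3g)\n", x$binomial_p))
  if (length(x$skipped))
    cat("  skipped (zero variance):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
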