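#' Per-line BLUEs of SAM cell counts
#'
#' Fits, for one growth phase, the mixed model with genotype (line) as a
#' fixed effect and replicate block as a random effect, by REML through the
#' same spectral machinery as [fit_lmm()] (the block design contributes a
#' `Z Z'` covariance in place of a kinship matrix). Returns the best linear
#' unbiased estimate of each line's cell count with its standard error. With
#' a single block the random effect is degenerate and the function falls
#' back to fixed-effects line means with a warning.
#'
#' @param sam A `sam_data` list (or a data frame like its `counts` element,
#'   with columns `line`, `block`, `phase`, `cells`).
#' @param phase Growth phase to analyse.
#' @return Data frame `line`, `blue`, `se`; attribute `fit` holds the
#'   underlying `lmm_fit` (when a mixed model was fitted).
#' @export
fit_blues <- function(sam, phase) {
  counts <- if (is.data.frame(sam)) sam else sam$counts
  d <- counts[counts$phase == phase, , drop = FALSE]
  if (!nrow(d)) stop("no rows for phase ", phase)
  lines <- unique(d$line) # keep first-appearance order
  if (length(lines) < 2) stop("at least two lines are required")
  blocks <- unique(d$block)
  X <- model.matrix(~ 0 + factor(line, levels = lines), data = d)
  colnames(X) <- lines
  if (length(blocks) < 2) {
    warning("single replicate block: returning fixed-effects line means")
    mu <- tapply(d$cells, d$line, mean)[lines]
    nre <- tapply(d$cells, d$line, length)[lines]
    s2 <- mean(tapply(d$cells, d$line, var), na.rm = TRUE)
    return(data.frame(line = lines, blue = as.numeric(mu),
                      se = sqrt(s2 / as.numeric(nre))))
  }
  Z <- model.matrix(~ 0 + factor(block), data = d)
  K <- tcrossprod(Z) # block-design covariance: V = va ZZ' + ve I
  fit <- fit_lmm(d$cells, X, K, lrt_term = NULL)
  out <- data.frame(line = lines, blue = unname(fit$beta),
                    se = unname(fit$se))
  attr(out, "fit") <- fit
  out
}

#' Standardized genomic relatedness matrix
#'
#' Filters sites by minor allele frequency and missingness, standardizes each
#' genotype column as `(x - 2p) / sqrt(2p(1-p))` with missing entries set to
#' zero after centering, and returns `K = W W' / m` over the `m` surviving
#' sites.
#'
#' @param G A `genotype_matrix` (missing calls allowed).
#' @param maf_min Minimum minor allele frequency.
#' @param max_missing Maximum per-site missing fraction.
#' @return A `kinship_matrix` with attribute `n_snps`.
#' @export
grm_standardized <- function(G, maf_min = 0.01, max_missing = 0.6) {
  M <- G$calls
  miss <- colMeans(is.na(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(miss <= max_missing & !is.na(maf) & maf >= maf_min)
  if (!length(keep)) stop("no sites survive the MAF/missingness filters")
  W <- matrix(0, nrow(M), length(keep))
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    w <- (M[, j] - 2 * p[j]) / sqrt(2 * p[j] * (1 - p[j]))
    w[is.na(w)] <- 0
    W[, jj] <- w
  }
  K <- tcrossprod(W) / length(keep)
  K <- (K + t(K)) / 2
  out <- kinship_matrix(K, individual_ids = G$individual_ids, check = FALSE)
  attr(out, "n_snps") <- length(keep)
  out
}

#' Kinship-corrected regression of flowering time on SAM cell counts
#'
#' Per growth phase, fits
#' `flowering = mu + alpha * cells + beta_BAK1 + beta_SDA1 + g + e` with
#' `g ~ MVN(0, V_A K)` through [fit_lmm()], where `cells` are the per-line
#' BLUEs for that phase and the two candidate loci enter as additive fixed
#' effects. Reports the cell-count slope with Wald and LRT p-values.
#'
#' @param flowering Named numeric vector of flowering times (days to
#'   anthesis) per line.
#' @param blues_per_phase Named list of BLUE tables (from [fit_blues()]) or
#'   numeric vectors, one per phase, aligned to `flowering`.
#' @param bak1,sda1 Additive genotype codes (0/1/2) per line.
#' @param K A `kinship_matrix`/GRM over the same lines.
#' @return Data frame with one row per phase: `slope`, `se`, `wald_p`,
#'   `lrt_p`, `va`, `ve`; attribute `fits` holds the `lmm_fit` objects.
#' @export
flowering_model <- function(flowering, blues_per_phase, bak1, sda1, K) {
  n <- length(flowering)
  stopifnot(length(bak1) == n, length(sda1) == n)
  fits <- list()
  rows <- lapply(names(blues_per_phase), function(ph) {
    b <- blues_per_phase[[ph]]
    cells <- if (is.data.frame(b)) {
      if (!is.null(names(flowering))) {
        if (!all(names(flowering) %in% b$line))
          stop("phase ", ph, " BLUEs missing lines present in flowering")
        b$blue[match(names(flowering), b$line)]
      } else b$blue
    } else as.numeric(b)
    if (length(cells) != n || anyNA(cells))
      stop("phase ", ph, " BLUEs do not match lines")
    X <- cbind(intercept = 1, cells = cells, bak1 = bak1, sda1 = sda1)
    drop_cols <- apply(X[, -1, drop = FALSE], 2, sd) == 0
    if (any(drop_cols))
      X <- X[, c(TRUE, !drop_cols), drop = FALSE]
    if (qr(X)$rank < ncol(X)) {
      cn <- colnames(X)
      stop("collinear covariates in phase ", ph, ": ",
           paste(cn[-1], collapse = ", "))
    }
    fit <- fit_lmm(flowering, X, K, lrt_term = which(colnames(X) == "cells"))
    fits[[ph]] <<- fit
    data.frame(phase = ph, slope = unname(fit$beta["cells"]),
               se = unname(fit$se[which(colnames(X) == "cells")]),
               wald_p = unname(fit$wald_p[which(colnames(X) == "cells")]),
               lrt_p = fit$lrt_p, va = fit$va, ve = fit$ve)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}
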