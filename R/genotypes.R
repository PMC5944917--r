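#' Filter sites and individuals by missingness
#'
#' Sites whose missing fraction exceeds `max_site_missing` are removed first;
#' individuals whose missing fraction (over the retained sites) exceeds
#' `max_ind_missing` are removed second.
#'
#' @param G A `genotype_matrix`.
#' @param max_site_missing,max_ind_missing Missing-fraction thresholds.
#' @return The filtered `genotype_matrix`, with an attribute `report` listing
#'   the numbers of sites and individuals removed.
#' @export
filter_missingness <- function(G, max_site_missing = 0.40,
                               max_ind_missing = 0.90) {
  check_fraction(max_site_missing, "max_site_missing")
  check_fraction(max_ind_missing, "max_ind_missing")
  miss_site <- colMeans(is.na(G$calls))
  keep_s <- which(miss_site <= max_site_missing)
  if (!length(keep_s))
    stop(sprintf("all %d sites exceed %.0f%% missingness", ncol(G$calls),
                 100 * max_site_missing))
  miss_ind <- rowMeans(is.na(G$calls[, keep_s, drop = FALSE]))
  keep_i <- which(miss_ind <= max_ind_missing)
  if (!length(keep_i))
    stop(sprintf("all %d individuals exceed %.0f%% missingness",
                 nrow(G$calls), 100 * max_ind_missing))
  out <- subset_genotypes(G, keep_i, keep_s)
  attr(out, "report") <- list(sites_removed = ncol(G$calls) - length(keep_s),
                              individuals_removed = nrow(G$calls) - length(keep_i))
  out
}

#' Random imputation of missing genotypes
#'
#' Each missing call is replaced by a draw from the empirical distribution of
#' the observed calls at that site. Random imputation (rather than mean
#' imputation) keeps the diagonal of the downstream kinship matrix an unbiased
#' basis for inbreeding estimates.
#'
#' @param G A `genotype_matrix`.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A `genotype_matrix` without missing calls.
#' @export
impute_random <- function(G, seed) {
  calls <- G$calls
  na_by_site <- colSums(is.na(calls))
  if (any(na_by_site == nrow(calls)))
    stop("sites with no observed calls cannot be imputed; filter them first")
  set.seed(derive_seed(seed, "impute_random"))
  for (j in which(na_by_site > 0L)) {
    obs <- calls[!is.na(calls[, j]), j]
    miss <- which(is.na(calls[, j]))
    calls[miss, j] <- sample(obs, length(miss), replace = TRUE)
  }
  out <- G
  out$calls <- calls
  out
}

#' Mean imputation of missing genotypes
#'
#' Alternative imputation under the same contract as [impute_random()]: each
#' missing call is replaced by the site mean of observed calls (a non-integer
#' dosage). Provided for robustness comparisons; note mean imputation shrinks
#' kinship diagonals and thus biases inbreeding estimates.
#'
#' @param G A `genotype_matrix`.
#' @return A list with the dosage matrix (`calls`), since dosages are no
#'   longer integer codes, plus the ids carried over.
#' @export
impute_mean <- function(G) {
  calls <- G$calls
  if (any(colSums(!is.na(calls)) == 0L))
    stop("sites with no observed calls cannot be imputed; filter them first")
  mu <- colMeans(calls, na.rm = TRUE)
  idx <- which(is.na(calls), arr.ind = TRUE)
  out <- matrix(as.numeric(calls), nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  if (nrow(idx)) out[idx] <- mu[idx[, 2]]
  list(calls = out, individual_ids = G$individual_ids, site_ids = G$site_ids)
}

#' Nearest-neighbour imputation of missing genotypes
#'
#' Third imputation scheme under the same contract: each missing call is
#' replaced by the majority genotype among the `k` nearest individuals (by
#' IBS distance over co-observed sites) that are observed at that site,
#' falling back to the site majority when no neighbour is observed. Ties
#' break toward the smaller genotype code; fully deterministic.
#'
#' @param G A `genotype_matrix`.
#' @param k Number of neighbours.
#' @return A `genotype_matrix` without missing calls.
#' @export
impute_knn <- function(G, k = 5) {
  calls <- G$calls
  if (any(colSums(!is.na(calls)) == 0L))
    stop("sites with no observed calls cannot be imputed; filter them first")
  D <- ibs_distance_matrix(G)
  diag(D) <- Inf
  D[is.na(D)] <- Inf
  majority <- function(g) which.max(tabulate(g + 1L, 3L)) - 1L
  for (j in seq_len(ncol(calls))) {
    miss <- which(is.na(calls[, j]))
    if (!length(miss)) next
    obs_i <- which(!is.na(G$calls[, j]))
    site_major <- majority(G$calls[obs_i, j])
    for (i in miss) {
      nb <- obs_i[order(D[i, obs_i])]
      nb <- nb[is.finite(D[i, nb])]
      nb <- head(nb, k)
      calls[i, j] <- if (length(nb)) majority(G$calls[nb, j]) else site_major
    }
  }
  out <- G
  out$calls <- calls
  out
}

#' Centered identity-by-state kinship
#'
#' Computes the centered-IBS relatedness estimator
#' \deqn{K = W W^\top / \left(2 \sum_j p_j (1 - p_j)\right)}
#' where \eqn{W = M - 2P}, `M` is the 0/1/2 dosage matrix and `P` broadcasts
#' the per-site allele frequency. Monomorphic sites carry no information and
#' are dropped before centering.
#'
#' @param G A `genotype_matrix` with no missing calls (impute first), or a
#'   list with a complete numeric `calls` matrix (e.g. from [impute_mean()]).
#' @return A `kinship_matrix`.
#' @export
kinship_centered_ibs <- function(G) {
  M <- if (inherits(G, "genotype_matrix")) G$calls else G$calls
  if (anyNA(M)) stop("kinship requires complete genotypes; impute first")
  M <- matrix(as.numeric(M), nrow(M), ncol(M), dimnames = dimnames(M))
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all sites are monomorphic; kinship undefined")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(M, 2, 2 * p, "-")
  cst <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / cst
  K <- (K + t(K)) / 2
  ids <- if (inherits(G, "genotype_matrix")) G$individual_ids else
    G$individual_ids %||% rownames(M)
  kinship_matrix(K, individual_ids = ids, check = FALSE)
}

#' Inbreeding coefficients from a centered-IBS kinship diagonal
#'
#' Under the centered-IBS normalization the expected diagonal for an outbred
#' individual is 1; the per-individual inbreeding coefficient is therefore
#' `diag(K) - 1`.
#'
#' @param K A `kinship_matrix` from [kinship_centered_ibs()].
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding_from_kinship <- function(K) {
  v <- as_kinship_values(K)
  setNames(diag(v) - 1, rownames(v))
}

#' Pairwise IBS distance matrix
#'
#' IBS distance between two individuals is defined as
#' `1 - shared_alleles / 2` averaged over sites where both are observed
#' (0 for identical genotypes, 1 for opposite homozygotes).
#'
#' @param G A `genotype_matrix` (missing calls allowed).
#' @return Symmetric numeric matrix of distances; `NA` where no site is
#'   co-observed.
#' @export
ibs_distance_matrix <- function(G) {
  M <- G$calls
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(G$individual_ids, G$individual_ids))
  obs <- !is.na(M)
  Mz <- M
  Mz[!obs] <- 0L
  # per-site distance |gi - gj| / 2; accumulate via loop over pairs (n modest)
  for (i in seq_len(n - 1L)) {
    co <- obs[rep(i, n - i), , drop = FALSE] & obs[(i + 1L):n, , drop = FALSE]
    dif <- abs(sweep(Mz[(i + 1L):n, , drop = FALSE], 2, Mz[i, ], "-")) / 2
    dif[!co] <- 0
    nco <- rowSums(co)
    dd <- ifelse(nco > 0, rowSums(dif) / nco, NA_real_)
    D[i, (i + 1L):n] <- dd
    D[(i + 1L):n, i] <- dd
  }
  D
}

#' Remove near-duplicate individuals by IBS distance
#'
#' Pairs closer than `threshold` are resolved in ascending order of distance;
#' in each unresolved pair the member with the lower mean sequencing depth is
#' dropped.
#'
#' @param G A `genotype_matrix`.
#' @param depths Named numeric vector of per-individual mean sequencing depth
#'   (defaults to row means of `G$depths`).
#' @param threshold IBS distance below which a pair is a duplicate.
#' @return Filtered `genotype_matrix` with attribute `dropped` (ids).
#' @export
remove_ibs_duplicates <- function(G, depths = NULL, threshold = 0.07) {
  if (is.null(depths)) {
    if (is.null(G$depths)) stop("per-individual depths are required")
    depths <- rowMeans(G$depths, na.rm = TRUE)
    names(depths) <- G$individual_ids
  }
  D <- ibs_distance_matrix(G)
  pairs <- which(upper.tri(D) & D < threshold, arr.ind = TRUE)
  dropped <- character(0)
  if (nrow(pairs)) {
    ord <- order(D[pairs])
    pairs <- pairs[ord, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      a <- G$individual_ids[pairs[k, 1]]
      b <- G$individual_ids[pairs[k, 2]]
      if (a %in% dropped || b %in% dropped) next
      da <- depths[a]; db <- depths[b]
      if (is.na(da) || is.na(db))
        stop("missing depth for individual implicated in a duplicate pair")
      dropped <- c(dropped, if (da <= db) a else b)
    }
  }
  keep <- which(!(G$individual_ids %in% dropped))
  out <- subset_genotypes(G, individuals = keep)
  attr(out, "dropped") <- dropped
  out
}

#' Hardy-Weinberg equilibrium site filter
#'
#' Per site, genotype counts are taken over usable individuals (read depth in
#' `[depth_min, depth_max]`, optionally restricted to outbred individuals) and
#' compared with Hardy-Weinberg expectations by a 1-df chi-squared
#' goodness-of-fit test. Sites with p below `alpha` are flagged for removal;
#' sites with fewer than two usable genotypes are untestable and kept.
#'
#' @param G A `genotype_matrix` with `depths`.
#' @param depth_min,depth_max Usable read-depth range per genotype call.
#' @param alpha Significance level for removal.
#' @param outbred Optional logical vector marking outbred individuals.
#' @return Logical keep-mask over sites, with attribute `p` of HWE p-values
#'   (`NA` where untestable).
#' @export
hwe_filter <- function(G, depth_min = 9, depth_max = 300, alpha = 0.05,
                       outbred = NULL) {
  if (is.null(G$depths)) stop("hwe_filter requires per-genotype depths")
  usable <- !is.na(G$calls) & G$depths >= depth_min & G$depths <= depth_max
  if (!is.null(outbred)) usable <- usable & outbred
  m <- ncol(G$calls)
  pval <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    g <- G$calls[usable[, j], j]
    nn <- length(g)
    if (nn < 2L) next
    counts <- tabulate(g + 1L, nbins = 3L)
    p <- (2 * counts[3] + counts[2]) / (2 * nn)
    if (p <= 0 || p >= 1) next # monomorphic among usable calls: untestable
    expd <- nn * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((counts - expd)^2 / expd)
    pval[j] <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  keep <- is.na(pval) | pval >= alpha
  attr(keep, "p") <- pval
  keep
}

#' Linkage-disequilibrium thinning of sites
#'
#' Two rules are applied per chromosome in a deterministic left-to-right
#' sweep: (i) of any two retained sites closer than `window_bp`, the
#' lower-coverage site is removed; (ii) of any tested pair with genotype
#' correlation `r^2 > r2_max` and correlation-test p below `alpha`, the
#' lower-coverage site is removed. A pair is tested only when both sites have
#' at least `min_high_depth` high-depth genotypes (depth within
#' `[depth_min, depth_max]`).
#'
#' @param G A `genotype_matrix` (with `depths` when depth-based rules apply).
#' @param window_bp Physical distance defining rule (i).
#' @param r2_max Squared-correlation threshold for rule (ii).
#' @param alpha Correlation-test significance level for rule (ii).
#' @param min_high_depth Minimum high-depth genotypes for a site to be tested.
#' @param depth_min,depth_max High-depth range.
#' @param r2_window_bp Maximum physical distance at which pairs are tested for
#'   rule (ii); `Inf` tests all pairs within a chromosome.
#' @return Logical keep-mask over sites.
#' @export
ld_thin <- function(G, window_bp = 1000, r2_max = 0.8, alpha = 0.05,
                    min_high_depth = 12, depth_min = 9, depth_max = 300,
                    r2_window_bp = Inf) {
  m <- ncol(G$calls)
  for (ch in unique(G$chrom)) {
    pp <- G$positions[G$chrom == ch]
    if (any(diff(pp) <= 0)) stop("positions must be sorted within chromosome")
  }
  cov_site <- if (!is.null(G$depths)) colMeans(G$depths, na.rm = TRUE)
  else colMeans(!is.na(G$calls))
  n_high <- if (!is.null(G$depths))
    colSums(!is.na(G$calls) & G$depths >= depth_min & G$depths <= depth_max)
  else colSums(!is.na(G$calls))
  keep <- rep(TRUE, m)
  for (ch in unique(G$chrom)) {
    idx <- which(G$chrom == ch)
    kept <- integer(0)
    for (j in idx) {
      drop_j <- FALSE
      for (i in kept) {
        if (!keep[i]) next
        gap <- G$positions[j] - G$positions[i]
        close_pair <- gap < window_bp
        ld_pair <- FALSE
        if (!close_pair && gap <= r2_window_bp &&
            n_high[i] >= min_high_depth && n_high[j] >= min_high_depth) {
          gi <- G$calls[, i]; gj <- G$calls[, j]
          co <- !is.na(gi) & !is.na(gj)
          nco <- sum(co)
          if (nco >= 3 && sd(gi[co]) > 0 && sd(gj[co]) > 0) {
            r <- cor(gi[co], gj[co])
            tt <- r * sqrt((nco - 2) / max(1 - r^2, 1e-12))
            pv <- 2 * pt(-abs(tt), df = nco - 2)
            ld_pair <- r^2 > r2_max && pv < alpha
          }
        }
        if (close_pair || ld_pair) {
          if (cov_site[j] <= cov_site[i]) {
            drop_j <- TRUE
            break
          } else {
            keep[i] <- FALSE
          }
        }
      }
      if (drop_j) keep[j] <- FALSE else kept <- c(kept, j)
    }
  }
  keep
}
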