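#' Genotype matrix container
#'
#' Biallelic genotypes coded 0/1/2 (count of the alternate allele) with `NA`
#' for missing calls. Individuals are rows, sites are columns. Site positions
#' are 1-based and must be strictly increasing within each chromosome.
#'
#' @param calls Integer matrix, individuals x sites, values in `{0,1,2,NA}`.
#' @param individual_ids Character vector, one per row.
#' @param site_ids Character vector, one per column.
#' @param chrom Character vector of chromosome labels per site.
#' @param positions Integer vector of 1-based site positions.
#' @param depths Optional numeric matrix of per-genotype read depths with the
#'   same dimensions as `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individual_ids = rownames(calls),
                            site_ids = colnames(calls),
                            chrom = rep("1", ncol(calls)),
                            positions = seq_len(ncol(calls)),
                            depths = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(site_ids)) site_ids <- paste0("s", seq_len(ncol(calls)))
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (length(individual_ids) != nrow(calls) || length(site_ids) != ncol(calls))
    stop("id lengths inconsistent with call matrix dimensions")
  if (length(chrom) != ncol(calls) || length(positions) != ncol(calls))
    stop("chrom/positions must have one entry per site")
  if (any(positions < 1) || any(positions != round(positions)))
    stop("positions must be positive 1-based integers")
  for (ch in unique(chrom)) {
    p <- positions[chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    if (!all(dim(depths) == dim(calls)))
      stop("depths must match the dimensions of calls")
  }
  dimnames(calls) <- list(individual_ids, site_ids)
  structure(list(calls = calls, individual_ids = individual_ids,
                 site_ids = site_ids, chrom = as.character(chrom),
                 positions = as.integer(positions), depths = depths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat(sprintf("genotype_matrix: %d individuals x %d sites (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

subset_genotypes <- function(G, individuals = NULL, sites = NULL) {
  ii <- individuals %||% seq_len(nrow(G$calls))
  jj <- sites %||% seq_len(ncol(G$calls))
  genotype_matrix(G$calls[ii, jj, drop = FALSE],
                  individual_ids = G$individual_ids[ii],
                  site_ids = G$site_ids[jj],
                  chrom = G$chrom[jj], positions = G$positions[jj],
                  depths = if (!is.null(G$depths)) G$depths[ii, jj, drop = FALSE])
}

#' Kinship matrix container
#'
#' Symmetric positive semi-definite relatedness matrix with individual labels.
#' Symmetry is required to 1e-10; eigenvalues may be no smaller than -1e-8
#' after a diagonal jitter of 1e-8.
#'
#' @param values Numeric n x n matrix.
#' @param individual_ids Character vector of labels.
#' @param check When `FALSE`, skip the (O(n^3)) eigenvalue check.
#' @return An object of class `kinship_matrix`.
#' @export
kinship_matrix <- function(values, individual_ids = rownames(values),
                           check = TRUE) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("kinship matrix must be square")
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  if (max(abs(values - t(values))) > 1e-10)
    stop("kinship matrix is not symmetric (tolerance 1e-10)")
  if (check) {
    ev <- eigen((values + t(values)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-8 - 1e-8) # allowance after nominal 1e-8 jitter
      stop(sprintf("kinship matrix is not PSD (min eigenvalue %.3e)", min(ev)))
  }
  dimnames(values) <- list(individual_ids, individual_ids)
  structure(list(values = values, individual_ids = individual_ids),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d individuals, mean diagonal %.3f\n",
              nrow(x$values), mean(diag(x$values))))
  invisible(x)
}

as_kinship_values <- function(K) {
  if (inherits(K, "kinship_matrix")) K$values else as.matrix(K)
}
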