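#' Read and write genotype tables
#'
#' Genotypes are stored as a TSV with individuals in rows and sites in
#' columns (codes 0/1/2, `NA` for missing). The first column `individual_id`
#' holds labels; site columns are named `<chrom>:<pos>` with 1-based
#' positions.
#'
#' @param G A `genotype_matrix`.
#' @param path File path.
#' @return `read_genotypes` returns a `genotype_matrix`; `write_genotypes`
#'   returns `path` invisibly.
#' @export
write_genotypes <- function(G, path) {
  df <- data.frame(individual_id = G$individual_ids,
                   G$calls, check.names = FALSE)
  colnames(df)[-1] <- paste0(G$chrom, ":", G$positions)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "individual_id")
    stop("genotype table must start with an 'individual_id' column")
  ids <- df$individual_id
  calls <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(calls) <- "integer")
  site_spec <- strsplit(colnames(calls), ":", fixed = TRUE)
  if (any(lengths(site_spec) != 2))
    stop("site columns must be named <chrom>:<pos>")
  genotype_matrix(calls, individual_ids = ids,
                  site_ids = colnames(calls),
                  chrom = vapply(site_spec, `[`, "", 1),
                  positions = as.integer(vapply(site_spec, `[`, "", 2)))
}

#' Read and write kinship matrices as CSV
#'
#' Square CSV with a header row of individual ids and an `individual_id`
#' first column.
#'
#' @param K A `kinship_matrix`.
#' @param path File path.
#' @export
write_kinship <- function(K, path) {
  v <- as_kinship_values(K)
  df <- data.frame(individual_id = rownames(v), v, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  ids <- df$individual_id
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- ids
  v <- (v + t(v)) / 2 # CSV round-trips can break symmetry in the last digit
  kinship_matrix(v, individual_ids = ids, check = FALSE)
}

#' Read a phenotype table with declared genome-size units
#'
#' Reads a CSV, checks required columns, and normalizes genome size to
#' gigabases internally (1 pg = 0.978 Gb by default).
#'
#' @param path CSV path with a header.
#' @param units Unit of the `gs` column: `"gb"` or `"pg"`.
#' @param gs_col Name of the genome-size column.
#' @param required Additional required column names.
#' @param gb_per_pg Conversion constant.
#' @return Data frame with `gs_gb` normalized to Gb; attribute `report`
#'   lists row counts and per-column missing values.
#' @export
read_phenotypes <- function(path, units = c("gb", "pg"), gs_col = "gs",
                            required = character(0), gb_per_pg = 0.978) {
  units <- match.arg(units)
  df <- read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("phenotype file is empty: ", path)
  for (col in unique(c(gs_col, required)))
    if (!col %in% names(df)) stop("missing required column '", col, "'")
  gs <- as.numeric(df[[gs_col]])
  df$gs_gb <- if (units == "pg") pg_to_gb(gs, gb_per_pg) else gs
  attr(df, "report") <- list(n_rows = nrow(df),
                             n_missing = vapply(df, function(x) sum(is.na(x)),
                                                integer(1)))
  df
}

#' @rdname read_phenotypes
#' @param df Phenotype data frame.
#' @export
write_phenotypes <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read BED-style mask intervals
#'
#' Three-column BED (sequence id, start, end), 0-based half-open, as produced
#' by external homology searches.
#'
#' @param path BED path (no header).
#' @return Data frame `seq_id`, `start`, `end` for [mask_library()].
#' @export
read_bed_intervals <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("seq_id", "start",
                                                       "end"),
                   colClasses = c("character", "integer", "integer"))
  if (any(df$end <= df$start)) stop("BED intervals must satisfy end > start")
  df
}

#' Read and write a repeat library as FASTA
#'
#' Thin wrappers over Biostrings FASTA IO, kept so pipeline stages share one
#' entry point.
#'
#' @param path FASTA path.
#' @param lib A `DNAStringSet`.
#' @export
read_repeat_library <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_repeat_library
#' @export
write_repeat_library <- function(lib, path) {
  Biostrings::writeXStringSet(lib, path)
  invisible(path)
}

#' Read and write growth-chamber data (long CSV)
#'
#' Long format: one row per observation with columns `seedling`, `maternal`,
#' `gs_gb`, `obs_type` (`length`, `cell`), `day` (NA for cells) and `value`
#' (cm). `read_growth_data` reassembles the `growth_data` structure consumed
#' by [derive_observations()].
#'
#' @param gd A `growth_data` list.
#' @param path CSV path.
#' @export
write_growth_data <- function(gd, path) {
  long <- rbind(
    data.frame(seedling = gd$lengths$seedling, obs_type = "length",
               day = gd$lengths$day, value = gd$lengths$length_cm),
    data.frame(seedling = gd$cells$seedling, obs_type = "cell",
               day = NA_integer_, value = gd$cells$cell_cm))
  long <- merge(gd$seedlings, long, by = "seedling", sort = FALSE)
  write.csv(long[order(long$seedling, long$obs_type, long$day), ],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_data
#' @export
read_growth_data <- function(path) {
  df <- read.csv(path)
  need <- c("seedling", "maternal", "gs_gb", "obs_type", "day", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("growth CSV missing columns: ",
                         paste(miss, collapse = ", "))
  first <- !duplicated(df$seedling)
  structure(list(
    seedlings = data.frame(seedling = df$seedling[first],
                           maternal = df$maternal[first],
                           gs_gb = df$gs_gb[first]),
    lengths = with(df[df$obs_type == "length", ],
                   data.frame(seedling = seedling, day = day,
                              length_cm = value)),
    cells = with(df[df$obs_type == "cell", ],
                 data.frame(seedling = seedling, cell_cm = value))),
    class = "growth_data")
}
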