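#' Mask homology hits out of a repeat library
#'
#' Homology-hit intervals (externally computed, e.g. BLAST alignments longer
#' than 30 bp at >= 80% identity) are unioned per sequence and subtracted;
#' unmasked segments strictly longer than `min_unmasked_len` are emitted as
#' new reference sequences named `<id>:<start>-<end>` (0-based half-open
#' coordinates). Sequences wholly masked, or whose surviving segments are all
#' too short, are dropped.
#'
#' @param lib A [Biostrings::DNAStringSet] (or named character vector) of
#'   repeat reference sequences with unique names.
#' @param hit_intervals Data frame with columns `seq_id`, `start`, `end`
#'   (0-based half-open) of regions to mask.
#' @param min_unmasked_len Minimum surviving segment length (strictly
#'   greater-than).
#' @return A `DNAStringSet` of unmasked segments.
#' @export
mask_library <- function(lib, hit_intervals, min_unmasked_len = 70) {
  if (!methods::is(lib, "DNAStringSet")) lib <- Biostrings::DNAStringSet(lib)
  if (is.null(names(lib)) || anyDuplicated(names(lib)))
    stop("library sequences must have unique names")
  req <- c("seq_id", "start", "end")
  if (!all(req %in% names(hit_intervals)))
    stop("hit_intervals needs columns seq_id, start, end")
  if (nrow(hit_intervals)) {
    if (any(!hit_intervals$seq_id %in% names(lib)))
      stop("hit interval references unknown sequence id")
    w <- Biostrings::width(lib)[match(hit_intervals$seq_id, names(lib))]
    if (any(hit_intervals$start < 0) || any(hit_intervals$end > w) ||
        any(hit_intervals$end <= hit_intervals$start))
      stop("hit interval out of sequence bounds")
  }
  out_seq <- character(0)
  out_nm <- character(0)
  for (id in names(lib)) {
    len <- Biostrings::width(lib[id])
    h <- hit_intervals[hit_intervals$seq_id == id, , drop = FALSE]
    if (nrow(h)) {
      # convert 0-based half-open -> 1-based inclusive IRanges
      masked <- IRanges::reduce(IRanges::IRanges(start = h$start + 1L,
                                                 end = h$end))
      segs <- IRanges::setdiff(IRanges::IRanges(1L, len), masked)
    } else {
      segs <- IRanges::IRanges(1L, len)
    }
    segs <- segs[IRanges::width(segs) > min_unmasked_len]
    if (!length(segs)) next
    pieces <- Biostrings::extractAt(lib[[id]], segs)
    out_seq <- c(out_seq, as.character(pieces))
    out_nm <- c(out_nm, sprintf("%s:%d-%d", id, IRanges::start(segs) - 1L,
                                IRanges::end(segs)))
  }
  res <- Biostrings::DNAStringSet(out_seq)
  names(res) <- out_nm
  res
}

#' Per-individual repeat abundance from read-class assignments
#'
#' Converts read counts (or per-read candidate class sets) into megabases per
#' repeat class: reads assigned to organellar classes are removed from the
#' total first, a read tied between several classes contributes equal
#' fractional weight to each, the abundance fraction of class c is its weight
#' over the filtered total, and `Mb_c = f_c x genome size (Gb) x 1000`.
#' Unassigned reads contribute to "other".
#'
#' @param assignments Either a named numeric vector of per-class read counts,
#'   or a data frame with columns `read_id` and `classes` (comma-separated
#'   candidate classes; empty for unassigned reads).
#' @param genome_size Genome size in Gb.
#' @param total_reads Total reads sequenced (must be at least the summed
#'   class counts).
#' @param remove_classes Classes treated as contamination and removed from
#'   the total before fractions (plastid by default; add "mito" to filter
#'   mitochondrial reads as well).
#' @return A one-row `repeat_profile` data frame (`gs_gb`, `mb_<class>`,
#'   `mb_other`, `total_reads`), with attribute `fractions`.
#' @export
abundance_from_assignments <- function(assignments, genome_size, total_reads,
                                       remove_classes = c("plastid",
                                                          "chloroplast")) {
  if (!is.numeric(genome_size) || genome_size <= 0)
    stop("genome_size must be positive (Gb)")
  check_count(total_reads, "total_reads")
  if (is.data.frame(assignments)) {
    if (!all(c("read_id", "classes") %in% names(assignments)))
      stop("per-read assignments need columns read_id, classes")
    weights <- list()
    for (cl_str in assignments$classes) {
      cls <- strsplit(cl_str, ",", fixed = TRUE)[[1]]
      cls <- trimws(cls[nzchar(trimws(cls))])
      if (!length(cls)) next
      w <- 1 / length(cls) # tie-splitting: equal weight across tied classes
      for (cl in cls) weights[[cl]] <- (weights[[cl]] %||% 0) + w
    }
    counts <- unlist(weights) %||% numeric(0)
    if (nrow(assignments) > total_reads)
      stop("more assigned reads than total_reads")
  } else {
    counts <- assignments
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("per-class counts must be named")
    if (any(counts < 0)) stop("negative read counts")
    if (sum(counts) > total_reads + 1e-9)
      stop("class counts exceed total_reads")
  }
  rm_mask <- names(counts) %in% remove_classes
  total_eff <- total_reads - sum(counts[rm_mask])
  if (total_eff <= 0) stop("no reads remain after contamination filtering")
  counts <- counts[!rm_mask]
  frac <- counts / total_eff
  out <- data.frame(gs_gb = genome_size,
                    total_reads = as.integer(total_reads))
  for (cl in names(counts))
    out[[paste0("mb_", cl)]] <- frac[[cl]] * genome_size * 1000
  out$mb_other <- max(0, 1 - sum(frac)) * genome_size * 1000
  class(out) <- c("repeat_profile", "data.frame")
  attr(out, "fractions") <- c(frac, other = max(0, 1 - sum(frac)))
  out
}

#' Concordance between cytological knob counts and sequence abundance
#'
#' Per repeat class, Pearson correlation (with its two-sided test) between
#' per-individual cytological counts (e.g. FISH knob counts) and
#' sequence-estimated megabases; individuals missing either value are dropped
#' listwise.
#'
#' @param cyto_counts Data frame: `individual_id` plus one count column per
#'   class.
#' @param seq_mb Data frame: `individual_id` plus matching Mb columns (same
#'   class names, with or without an `mb_` prefix).
#' @return Data frame with `class`, `n`, `r`, `p`.
#' @export
fish_concordance <- function(cyto_counts, seq_mb) {
  stopifnot("individual_id" %in% names(cyto_counts),
            "individual_id" %in% names(seq_mb))
  classes <- setdiff(names(cyto_counts), "individual_id")
  merged <- merge(cyto_counts, seq_mb, by = "individual_id",
                  suffixes = c(".cyto", ".seq"))
  res <- lapply(classes, function(cl) {
    x <- merged[[cl]] %||% merged[[paste0(cl, ".cyto")]]
    ynm <- if (paste0("mb_", cl) %in% names(merged)) paste0("mb_", cl)
    else if (paste0(cl, ".seq") %in% names(merged)) paste0(cl, ".seq")
    else cl
    y <- merged[[ynm]]
    if (is.null(x) || is.null(y)) stop("no matching column for class ", cl)
    ok <- complete.cases(x, y)
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for class ", cl)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
      stop("zero variance for class ", cl, "; correlation undefined")
    ct <- cor.test(x[ok], y[ok])
    data.frame(class = cl, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value)
  })
  do.call(rbind, res)
}
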