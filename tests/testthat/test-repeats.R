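test_that("library masking performs exact interval arithmetic", {
  lib <- Biostrings::DNAStringSet(c(
    A = paste(rep("ACGT", 25), collapse = ""),   # 100 bp
    B = paste(rep("ACGT", 50), collapse = "")))  # 200 bp
  # no intervals: full-length segment retained under its coordinate name
  out <- mask_library(lib, data.frame(seq_id = character(0),
                                      start = integer(0), end = integer(0)))
  expect_identical(names(out), c("A:0-100", "B:0-200"))
  # full-length hit drops the sequence entirely
  out2 <- mask_library(lib, data.frame(seq_id = "A", start = 0L, end = 100L))
  expect_identical(names(out2), "B:0-200")
  # 200 bp masked [50,120): 50 bp segment dropped (not > 70), 80 bp kept
  out3 <- mask_library(lib["B"], data.frame(seq_id = "B", start = 50L,
                                            end = 120L))
  expect_identical(names(out3), "B:120-200")
  expect_equal(Biostrings::width(out3), 80)
  expect_identical(as.character(out3[[1]]),
                   substr(as.character(lib[["B"]]), 121, 200))
  expect_error(mask_library(lib, data.frame(seq_id = "A", start = 0L,
                                            end = 101L)), "bounds")
})

test_that("masked segments tile the complement of the hit union exactly", {
  set.seed(41)
  seq_len_bp <- 500
  lib <- Biostrings::DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), seq_len_bp, TRUE), collapse = ""), "R"))
  hits <- data.frame(seq_id = "R",
                     start = c(10L, 50L, 200L, 190L, 400L),
                     end = c(60L, 90L, 260L, 210L, 470L))
  out <- mask_library(lib, hits, min_unmasked_len = 0)
  covered <- rep(FALSE, seq_len_bp)
  for (i in seq_len(nrow(hits)))
    covered[(hits$start[i] + 1):hits$end[i]] <- TRUE
  seg_covered <- rep(FALSE, seq_len_bp)
  for (nm in names(out)) {
    coords <- strsplit(sub("^R:", "", nm), "-")[[1]]
    s <- as.integer(coords[1]); e <- as.integer(coords[2])
    expect_false(any(covered[(s + 1):e])) # never overlaps a hit
    seg_covered[(s + 1):e] <- TRUE
  }
  expect_identical(seg_covered, !covered) # tiles the complement exactly
})

test_that("abundance estimation converts read fractions to megabases", {
  p <- abundance_from_assignments(c(te = 1000), genome_size = 2.3,
                                  total_reads = 10000)
  expect_equal(p$mb_te, 0.1 * 2.3 * 1000) # 230 Mb
  expect_equal(p$mb_other, 0.9 * 2.3 * 1000)
  # linearity in genome size at fixed counts
  p2 <- abundance_from_assignments(c(te = 1000), genome_size = 4.6,
                                   total_reads = 10000)
  expect_equal(p2$mb_te, 2 * p$mb_te)
  # fractions (with other) sum to one
  fr <- attr(abundance_from_assignments(c(te = 700, knob = 150), 5, 1000),
             "fractions")
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_error(abundance_from_assignments(c(te = -1), 5, 100), "negative")
  expect_error(abundance_from_assignments(c(te = 200), 5, 100), "exceed")
})

test_that("tied multi-class reads split weight equally and plastid reads are excluded", {
  asg <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                    classes = c("knob180,tr1", "knob180", "", "plastid"))
  p <- abundance_from_assignments(asg, genome_size = 1, total_reads = 4)
  # plastid read removed from the denominator: 3 effective reads
  expect_equal(p$mb_knob180, (1.5 / 3) * 1000)
  expect_equal(p$mb_tr1, (0.5 / 3) * 1000)
  expect_equal(p$mb_other, (1 / 3) * 1000)
  # mitochondrial filtering is optional
  asg2 <- data.frame(read_id = c("r1", "r2"), classes = c("mito", "te"))
  p_keep <- abundance_from_assignments(asg2, 1, 2)
  expect_equal(p_keep$mb_mito, 500)
  p_drop <- abundance_from_assignments(asg2, 1, 2,
                                       remove_classes = c("plastid", "mito"))
  expect_false("mb_mito" %in% names(p_drop))
  expect_equal(p_drop$mb_te, 1000)
})

test_that("multinomial counts round-trip to the generating profile", {
  cfg <- cline_sim_config(n_pops = 2, n_per_pop = 2, n_sites = 50,
                          altitudes = c(0, 100), missing_rate = 0, seed = 42)
  G <- simulate_genotypes(cfg)
  prof <- simulate_genome_size(G, attr(G, "labels")$altitude, beta_alt = 0,
                               va = 0, ve = 0, mu = 5, seed = 42)
  total <- 5e4
  classes <- c("te", "knob180", "tr1", "rdna", "centc")
  err <- matrix(0, 50, length(classes), dimnames = list(NULL, classes))
  for (r in 1:50) {
    cnt <- simulate_read_assignments(prof, total, seed = 4200 + r)
    est <- abundance_from_assignments(
      unlist(cnt[1, classes]), prof$gs_gb[1], total)
    err[r, ] <- vapply(classes, function(cl)
      est[[paste0("mb_", cl)]] - prof[[paste0("mb_", cl)]][1], numeric(1))
  }
  for (cl in classes) {
    f <- prof[[paste0("mb_", cl)]][1] / (prof$gs_gb[1] * 1000)
    sd_mb <- sqrt(f * (1 - f) / total) * prof$gs_gb[1] * 1000
    expect_lt(abs(mean(err[, cl])), 3 * sd_mb / sqrt(50))
  }
})

test_that("FISH concordance reproduces the textbook correlation", {
  ids <- paste0("i", 1:10)
  set.seed(43)
  mb <- runif(10, 50, 400)
  cyto <- data.frame(individual_id = ids, knob180 = mb / 20)
  seqs <- data.frame(individual_id = ids, mb_knob180 = mb)
  res <- fish_concordance(cyto, seqs)
  expect_equal(res$r, 1, tolerance = 1e-12)
  # anti-proportional
  cyto2 <- data.frame(individual_id = ids, knob180 = -mb / 20 + 30)
  expect_equal(fish_concordance(cyto2, seqs)$r, -1, tolerance = 1e-12)
  # noisy fixture against the explicit product-moment formula
  counts <- mb / 20 + rnorm(10, 0, 3)
  cyto3 <- data.frame(individual_id = ids, knob180 = counts)
  r_hand <- sum((counts - mean(counts)) * (mb - mean(mb))) /
    sqrt(sum((counts - mean(counts))^2) * sum((mb - mean(mb))^2))
  expect_equal(fish_concordance(cyto3, seqs)$r, r_hand, tolerance = 1e-12)
  # degenerate input errors
  cyto4 <- data.frame(individual_id = ids, knob180 = 5)
  expect_error(fish_concordance(cyto4, seqs), "zero variance")
  expect_error(fish_concordance(cyto3[1:2, ], seqs), "3 complete pairs")
})
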