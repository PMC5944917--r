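#' Configuration for the synthetic end-to-end pipeline
#'
#' Bundles the stage configurations, a global master seed, and the output
#' directory. Stages are run in dependency order: simulate -> genotypes
#' (kinship) -> repeats (abundance) -> selection; the growth stage is
#' independent of the genotype stages.
#'
#' @param seed Global master seed (stage seeds are derived from it).
#' @param out_dir Output directory for stage artifacts and manifests.
#' @param cline A [cline_sim_config()] (its `seed` is overridden).
#' @param growth A [growth_sim_config()] or `NULL` to skip the growth stage.
#' @param growth_spec A [growth_model_spec()] used when fitting the growth
#'   model; `NULL` skips the fit and only writes the simulated data.
#' @param total_reads Reads per individual for the read-assignment stage.
#' @param stages Character vector of stages to run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("gsclines_run_"),
                            cline = cline_sim_config(),
                            growth = growth_sim_config(),
                            growth_spec = NULL,
                            total_reads = 1e5,
                            stages = c("simulate", "genotypes", "repeats",
                                       "selection", "growth")) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(seed = as.integer(seed), out_dir = out_dir, cline = cline,
                 growth = growth, growth_spec = growth_spec,
                 total_reads = total_reads, stages = stages),
            class = "pipeline_config")
}

write_manifest <- function(out_dir, stage, inputs, seed) {
  manifest <- list(stage = stage, seed = seed,
                   package_version = as.character(packageVersion("gsclines")),
                   inputs = lapply(inputs, function(f)
                     list(path = basename(f), md5 = unname(md5sum(f)))))
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run the synthetic pipeline end to end
#'
#' Executes the requested stages in dependency order, writing each stage's
#' artifacts plus a JSON manifest (input file hashes, stage seed, package
#' version) under `config$out_dir`. Re-running with an unchanged
#' configuration reproduces byte-identical outputs. A stage failure stops
#' dependent stages but the manifests written so far are kept.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of stage results (`genotypes`, `profiles`,
#'   `counts`, `kinship`, `selection`, `growth`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(out_dir = config$out_dir)
  st <- config$stages

  if (any(c("simulate", "genotypes", "repeats", "selection") %in% st)) {
    cline <- config$cline
    cline$seed <- derive_seed(config$seed, "stage_simulate")
    G <- simulate_genotypes(cline)
    labels <- attr(G, "labels")
    profiles <- simulate_genome_size(G, labels$altitude,
                                     beta_alt = cline$beta_alt,
                                     va = cline$va, ve = cline$ve,
                                     mu = cline$mu,
                                     repeat_fractions = cline$repeat_fractions,
                                     seed = cline$seed)
    counts <- simulate_read_assignments(profiles, config$total_reads,
                                        seed = cline$seed)
    gpath <- file.path(config$out_dir, "genotypes.tsv")
    ppath <- file.path(config$out_dir, "phenotypes.csv")
    cpath <- file.path(config$out_dir, "read_counts.csv")
    tpath <- file.path(config$out_dir, "truth.json")
    write_genotypes(G, gpath)
    write_phenotypes(profiles, ppath)
    write.csv(counts, cpath, row.names = FALSE, quote = FALSE)
    truth <- attr(profiles, "truth")
    jsonlite::write_json(truth[c("mu", "beta_alt", "va", "ve",
                                 "repeat_fractions")],
                         tpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(config$out_dir, "simulate", c(gpath, ppath, cpath, tpath),
                   cline$seed)
    res$genotypes <- G
    res$profiles <- profiles
    res$counts <- counts
  }

  if (any(c("genotypes", "selection") %in% st)) {
    Gf <- filter_missingness(res$genotypes)
    Gi <- impute_random(Gf, derive_seed(config$seed, "stage_genotypes"))
    K <- kinship_centered_ibs(Gi)
    kpath <- file.path(config$out_dir, "kinship.csv")
    write_kinship(K, kpath)
    write_manifest(config$out_dir, "genotypes", kpath,
                   derive_seed(config$seed, "stage_genotypes"))
    res$kinship <- K
  }

  if ("repeats" %in% st) {
    prof_rows <- lapply(seq_len(nrow(res$counts)), function(i) {
      cls <- setdiff(names(res$counts), c("individual_id", "total_reads"))
      cnt <- unlist(res$counts[i, cls])
      abundance_from_assignments(cnt[setdiff(cls, "other")],
                                 res$profiles$gs_gb[i],
                                 res$counts$total_reads[i])
    })
    est <- do.call(rbind, prof_rows)
    est <- data.frame(individual_id = res$counts$individual_id, est)
    epath <- file.path(config$out_dir, "repeat_abundance.csv")
    write.csv(est, epath, row.names = FALSE, quote = FALSE)
    write_manifest(config$out_dir, "repeats", epath, config$seed)
    res$abundance <- est
  }

  if ("selection" %in% st) {
    sel <- selection_scan(res$profiles, res$profiles$altitude, res$kinship,
                          mode = "genome_size")
    spath <- file.path(config$out_dir, "selection_genome_size.json")
    jsonlite::write_json(list(beta_alt_gb_per_m = sel$beta_alt,
                              beta_alt_kb_per_m = sel$beta_alt_kb_per_m,
                              wald_p = sel$fit$wald_p[[2]],
                              lrt_p = sel$fit$lrt_p,
                              va = sel$fit$va, ve = sel$fit$ve,
                              raw_r = sel$raw_r),
                         spath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(config$out_dir, "selection", spath, config$seed)
    res$selection <- sel
  }

  if ("growth" %in% st && !is.null(config$growth)) {
    gcfg <- config$growth
    gcfg$seed <- derive_seed(config$seed, "stage_growth")
    gd <- simulate_growth_data(gcfg)
    gdpath <- file.path(config$out_dir, "growth_data.csv")
    write_growth_data(gd, gdpath)
    files <- gdpath
    if (!is.null(config$growth_spec)) {
      obs <- derive_observations(gd)
      post <- fit_growth_model(obs, config$growth_spec)
      for (ch in seq_along(post$samples)) {
        cpath <- file.path(config$out_dir,
                           sprintf("growth_posterior_chain%d.csv", ch))
        write.csv(as.data.frame(post$samples[[ch]]), cpath, row.names = FALSE)
        files <- c(files, cpath)
      }
      res$growth <- post
    }
    write_manifest(config$out_dir, "growth", files, gcfg$seed)
    res$growth_data <- gd
  }

  invisible(res)
}
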