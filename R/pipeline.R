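#' Pipeline run configuration
#'
#' Collects stage parameters for [run_pipeline()].  Inputs may come from a
#' seeded simulation (default) or from files (`sites`, gene `fasta` +
#' `meta`); every stage parameter of the individual analysis functions has
#' an equivalent here.
#'
#' @param out_dir output directory (created if missing).
#' @param stages subset of `simulate`, `survey`, `shet`, `mtr`, `maps`,
#'   `doubletons`.
#' @param seed integer seed for the simulation stage.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param sites,fasta,meta optional input files replacing the simulation
#'   stage.
#' @param aaf_cutoff,prior s_het stage parameters.
#' @param window,fdr_alpha,percentile_cutoff,min_length,max_gap MTR stage
#'   parameters.
#' @param score,grid_step,min_variants MAPS calibration parameters.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "survey", "shet", "mtr",
                                  "maps", "doubletons"),
                       seed = 1L,
                       sim = sim_config(seed = seed),
                       sites = NULL, fasta = NULL, meta = NULL,
                       aaf_cutoff = 0.001, prior = "fit",
                       window = 31L, fdr_alpha = 0.1,
                       percentile_cutoff = 15, min_length = 5L, max_gap = 0L,
                       score = "spliceai", grid_step = 0.01,
                       min_variants = 500L) {
  known <- c("simulate", "survey", "shet", "mtr", "maps", "doubletons")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (!"simulate" %in% stages && (is.null(sites) || is.null(fasta) || is.null(meta)))
    stopf("without the simulate stage, sites, fasta and meta inputs are required")
  sim$seed <- as.integer(seed)
  structure(as.list(environment())[c("out_dir", "stages", "seed", "sim",
                                     "sites", "fasta", "meta", "aaf_cutoff",
                                     "prior", "window", "fdr_alpha",
                                     "percentile_cutoff", "min_length",
                                     "max_gap", "score", "grid_step",
                                     "min_variants")],
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (gene models and
#' mutation rates first, then the per-gene and per-variant analyses),
#' writes one TSV per result into the output directory and a JSON manifest
#' recording package version, parameters and input/output checksums.
#' Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return invisible list of in-memory results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  written <- character()
  emit <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
    p
  }

  if ("simulate" %in% config$stages) {
    exome <- simulate_exome(config$sim)
    genes <- exome$genes
    sites <- exome$sites
    emit(sites, "sites")
    write_gene_models(genes, file.path(config$out_dir, "genes.fa"),
                      file.path(config$out_dir, "genes.tsv"))
    written <- c(written, file.path(config$out_dir, c("genes.fa", "genes.tsv")))
    emit(exome$truth$s, "truth_shet")
    emit(exome$truth$depleted, "truth_depleted")
    table <- exome$rate_table
    results$exome <- exome
  } else {
    sites <- read_sites(config$sites)
    genes <- read_gene_models(config$fasta, config$meta)
    table <- build_rate_table()
  }
  possible <- lapply(genes, enumerate_possible_variants)

  if ("survey" %in% config$stages) {
    coding <- sites[sites$consequence %in% SURVEY_CLASSES, ]
    results$survey <- saturation_survey(coding, genes,
                                        possible = do.call(rbind, possible))
    emit(results$survey, "saturation")
  }
  if ("shet" %in% config$stages) {
    rates <- vapply(genes, gene_mutation_rate, 0, table = table)
    results$shet <- shet_table(sites, rates, prior = config$prior,
                               aaf_cutoff = config$aaf_cutoff)
    emit(results$shet, "shet")
  }
  if ("mtr" %in% config$stages) {
    results$mtr <- mtr_analysis(genes, sites, w = config$window,
                                alpha = config$fdr_alpha,
                                percentile_cutoff = config$percentile_cutoff,
                                min_length = config$min_length,
                                max_gap = config$max_gap,
                                possible = possible)
    emit(results$mtr$tracks, "mtr_tracks")
    emit(results$mtr$regions, "mtr_regions")
    emit(results$mtr$gene_tests, "mtr_gene_tests")
  }
  if ("maps" %in% config$stages) {
    syn <- sites[sites$consequence == "synonymous", ]
    model <- fit_singleton_model(syn, allow_constant = TRUE)
    results$maps_profile <- suppressWarnings(class_maps_profile(sites, model))
    emit(results$maps_profile, "maps_profile")
    ref <- sites[sites$consequence == "missense" &
                   !is.na(sites$pred_del_count) & sites$pred_del_count == 5L, ]
    if (nrow(ref) > 0L) {
      results$calibration <- calibrate_threshold(sites, config$score, model,
                                                 ref,
                                                 grid_step = config$grid_step,
                                                 min_variants = config$min_variants)
      emit(results$calibration$curve, "maps_calibration")
    }
  }
  if ("doubletons" %in% config$stages) {
    N <- max(sites$AN) / 2
    results$doubletons <- doubleton_summary(sites, N)
    refcls <- results$doubletons[results$doubletons$class %in%
                                   c("missense", "synonymous"), ]
    Fhat <- if (sum(refcls$D) > 0) estimate_inbreeding(refcls) else NA_real_
    results$inbreeding <- Fhat
    emit(results$doubletons, "doubletons")
  }

  manifest <- list(package = "excon",
                   version = as.character(utils::packageVersion("excon")),
                   seed = config$seed,
                   stages = config$stages,
                   parameters = config[setdiff(names(config),
                                               c("out_dir", "stages", "sim"))],
                   sim = unclass(config$sim),
                   outputs = as.list(tools::md5sum(sort(unique(written)))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
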