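#' Pipeline configuration
#'
#' Bundles the stage toggles and parameters of [run_pipeline()]. Stage
#' dependencies are validated before execution: `normalize` needs
#' `simulate`, `rollup` needs `normalize`, `differential` needs `rollup`,
#' and `enrich`, `pharmacology` and `reversal` need `differential`.
#'
#' @param out_dir output directory for stage artifacts and the manifest
#' @param sim a [sim_config()] describing the synthetic study
#' @param stages character vector of stages to run, in pipeline order
#' @param present_call present-call threshold for [normalize_psd()]
#' @param outlier_k MAD multiplier for outlier detection
#' @param pecora_alpha adjusted-p threshold for uncorrelated-peptide flags
#' @param covariates covariate names for the AD+P vs AD-P contrast
#' @param de_alpha raw-p threshold defining the top-DE subset
#' @param nominate_alpha screening threshold for [nominate_drugs()]
#' @param min_shared minimum shared entities for knockdown correlations
#' @param reversal_fraction fraction of signature proteins reversed in the
#'   simulated treatment experiment
#' @param seed master seed; stage-level seeds are derived from it
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            stages = c("simulate", "normalize", "rollup",
                                       "differential", "enrich",
                                       "pharmacology", "reversal"),
                            present_call = 1, outlier_k = 3,
                            pecora_alpha = 0.01,
                            covariates = c("age", "pmi", "sex", "apoe4",
                                           "lewy", "log2_ptau"),
                            de_alpha = 0.05, nominate_alpha = 0.01,
                            min_shared = 10, reversal_fraction = 0.6,
                            seed = sim$rng_seed) {
  known <- c("simulate", "normalize", "rollup", "differential", "enrich",
             "pharmacology", "reversal")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  deps <- list(normalize = "simulate", rollup = "normalize",
               differential = "rollup", enrich = "differential",
               pharmacology = "differential", reversal = "differential")
  for (s in stages) {
    need <- deps[[s]]
    if (!is.null(need) && !(need %in% stages))
      stop("stage '", s, "' requires stage '", need, "'")
  }
  structure(list(out_dir = out_dir, sim = sim, stages = stages,
                 present_call = present_call, outlier_k = outlier_k,
                 pecora_alpha = pecora_alpha, covariates = covariates,
                 de_alpha = de_alpha, nominate_alpha = nominate_alpha,
                 min_shared = min_shared,
                 reversal_fraction = reversal_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic-study pipeline
#'
#' Executes the toggled stages (simulate, normalize, roll-up, differential,
#' network enrichment, pharmacology screening, reversal evaluation), writes
#' every stage artifact as TSV/JSON under `config$out_dir`, and finishes
#' with a `manifest.json` recording parameters, the seed, and the md5 hash
#' of every written file so a rerun with the same configuration can be
#' verified to be identical.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list of in-memory stage results plus `manifest`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(config$out_dir, paste0(...))
  res <- list()
  st <- config$stages

  if ("simulate" %in% st) {
    cohort <- generate_cohort(config$sim, seed = config$seed)
    gen <- generate_peptide_data(config$sim, cohort,
                                 seed = config$seed + 1L)
    res$cohort <- cohort
    res$raw <- gen$matrix
    res$truth <- gen$truth
    write_tsv_file(cohort, path("cohort.tsv"))
    write_peptide_matrix(gen$matrix, path("peptides_raw"))
    jsonlite::write_json(gen$truth, path("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if ("normalize" %in% st) {
    norm <- normalize_psd(res$raw, present_call = config$present_call,
                          outlier_k = config$outlier_k)
    res$normalized <- norm$matrix
    res$norm_report <- norm$report
    write_peptide_matrix(norm$matrix, path("peptides_normalized"))
    jsonlite::write_json(unclass(norm$report), path("normalization_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  if ("rollup" %in% st) {
    meta <- res$cohort
    ya <- yield_adjust(res$normalized, meta)
    flags <- pecora_flag(ya, meta, alpha = config$pecora_alpha)
    pm <- rollup_protein(ya, flags)
    res$flags <- flags
    res$proteins <- pm
    write_tsv_file(flags, path("pecora_flags.tsv"))
    write_tsv_file(data.frame(protein = rownames(pm$values), pm$values,
                              check.names = FALSE),
                   path("protein_matrix.tsv"))
  }
  if ("differential" %in% st) {
    spec <- contrast_spec("ADP_vs_ADNP", "AD+P", "AD-P",
                          covariates = config$covariates)
    dr <- fit_contrast(res$proteins, res$cohort, spec)
    res$differential <- dr
    res$global_shift <- global_shift_test(dr)
    res$sig_full <- build_signature(dr, "full")
    res$sig_top <- build_signature(dr, "top", alpha = config$de_alpha)
    write_tsv_file(as.data.frame(dr), path("differential_ADP_vs_ADNP.tsv"))
    write_tsv_file(as.data.frame(res$sig_full), path("signature_full.tsv"))
    write_tsv_file(as.data.frame(res$sig_top), path("signature_top.tsv"))
    jsonlite::write_json(res$global_shift, path("global_shift.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if ("enrich" %in% st) {
    de <- de_set(res$differential, alpha = config$de_alpha)
    bg <- res$differential$protein
    seed_set <- sprintf("KIN%02d", 1:23)
    graph <- generate_interaction_graph(bg, seed_set, de,
                                        seed = config$seed + 2L)
    enr <- tryCatch(
      interaction_enrichment(graph, seed_set, de, bg),
      error = function(e) list(error = conditionMessage(e)))
    res$enrichment <- enr
    write_tsv_file(graph, path("interaction_graph.tsv"))
    jsonlite::write_json(list(chi2 = enr$chi2, df = enr$df, p = enr$p,
                              table = enr$table, error = enr$error),
                         path("enrichment.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  if ("pharmacology" %in% st) {
    fx <- generate_pharmacology_fixtures(res$sig_full,
                                         top_entities = res$sig_top$entity,
                                         seed = config$seed + 3L)
    screen <- screen_drugs(fx$atlas, fx$drugs, fx$lincs, res$sig_full,
                           res$sig_top, alpha = config$nominate_alpha,
                           min_shared = config$min_shared)
    res$pharmacology <- list(fixtures = fx, screen = screen)
    write_tsv_file(fx$atlas, path("knockdown_atlas.tsv"))
    write_tsv_file(fx$drugs, path("drug_targets.tsv"))
    write_tsv_file(fx$lincs, path("lincs_profiles.tsv"))
    write_tsv_file(screen, path("drug_screen.tsv"))
  }
  if ("reversal" %in% st) {
    exp <- generate_treatment_experiment(
      res$sig_full, reversal_fraction = config$reversal_fraction,
      seed = config$seed + 4L)
    norm <- normalize_psd(exp$matrix, present_call = 1,
                          outlier_k = config$outlier_k)
    pm <- rollup_protein(norm$matrix)
    fc <- treatment_log2fc(pm, exp$labels)
    tr <- reversal_test(fc, res$sig_full, res$sig_top)
    res$reversal <- tr
    write_tsv_file(data.frame(protein = names(fc), log2fc = fc,
                              in_full = names(fc) %in% tr$overlap_full,
                              in_top = names(fc) %in% tr$overlap_top),
                   path("treatment_log2fc.tsv"))
    jsonlite::write_json(
      list(n_overlap_full = length(tr$overlap_full),
           n_overlap_top = length(tr$overlap_top),
           t_full = tr$t_full, t_top = tr$t_top, signed_jaccard = tr$j),
      path("reversal_summary.json"), auto_unbox = TRUE, digits = NA)
  }

  files <- sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                        file.path(config$out_dir, "manifest.json")))
  manifest <- list(
    seed = config$seed,
    stages = st,
    parameters = unclass(config)[setdiff(names(config),
                                         c("out_dir", "sim"))],
    sim = unclass(config$sim),
    files = as.list(setNames(unname(tools::md5sum(files)),
                             basename(files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}
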