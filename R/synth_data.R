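#' Simulation configuration for the synthetic multiplex proteomics study
#'
#' Defaults encode the study conditions the pipeline is designed for: 59
#' subjects with Alzheimer disease and psychosis (AD+P), 47 without (AD-P)
#' and 19 cognitively normal comparison subjects, processed in multiplexes
#' (plexes) of 10-11 subjects balanced for diagnosis and sex plus 2
#' pooled-control channels; a fraction `pi_altered` of proteins carries a
#' linear-scale mean group ratio of `mean_ratio_altered` (AD+P lower),
#' residual SD 1.0 on the log2 scale, and a reduced mean PSD yield in AD+P.
#'
#' @param n_adp,n_adnp,n_cn subject counts per group (AD+P, AD-P,
#'   cognitively normal)
#' @param n_proteins number of simulated proteins
#' @param peptides_per_protein integer range (length-2) of peptides per
#'   protein, sampled uniformly
#' @param plex_size length-2 range of subjects per plex
#' @param n_pooled_channels pooled-control channels per plex
#' @param pi_altered fraction of proteins with a disease effect
#' @param mean_ratio_altered linear-scale AD-P/AD+P mean ratio for altered
#'   proteins (1.17: altered proteins are reduced in AD+P by log2(1.17))
#' @param log2_sd residual SD on the log2 scale
#' @param missing_rate probability an abundance is recorded as zero/missing
#' @param batch_sd SD (log2) of the per-plex, per-peptide multiplicative
#'   batch effect that internal reference scaling is designed to remove
#' @param yield_means named per-group mean PSD yield (ug PSD per ug gray
#'   matter), AD+P below AD-P
#' @param yield_sd SD of the PSD yield within group
#' @param frac_uncorrelated_peptides fraction of peptides (among
#'   multi-peptide proteins) given a discordant condition effect
#' @param uncorrelated_effect log2 effect (in AD+P) given to discordant
#'   peptides
#' @param covariate_effect_sizes named slopes on log2 abundance for
#'   standardized covariates (`age`, `pmi`, `sex`, `apoe4`, `lewy`,
#'   `log2_ptau`); default all zero
#' @param baseline_log2_mean,baseline_log2_sd protein baseline abundance
#'   distribution (log2)
#' @param peptide_offset_sd SD of per-peptide ionization offsets (log2)
#' @param rng_seed integer seed making every generator deterministic
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_adp = 59, n_adnp = 47, n_cn = 19,
                       n_proteins = 300,
                       peptides_per_protein = c(1, 5),
                       plex_size = c(10, 11),
                       n_pooled_channels = 2,
                       pi_altered = 0.15,
                       mean_ratio_altered = 1.17,
                       log2_sd = 1.0,
                       missing_rate = 0.05,
                       batch_sd = 0.5,
                       yield_means = c("AD+P" = 0.8, "AD-P" = 1.0,
                                       "CN" = 1.05),
                       yield_sd = 0.15,
                       frac_uncorrelated_peptides = 0,
                       uncorrelated_effect = 1.0,
                       covariate_effect_sizes = NULL,
                       baseline_log2_mean = 14,
                       baseline_log2_sd = 1,
                       peptide_offset_sd = 0.7,
                       rng_seed = 1L) {
  cfg <- list(n_adp = n_adp, n_adnp = n_adnp, n_cn = n_cn,
              n_proteins = n_proteins,
              peptides_per_protein = peptides_per_protein,
              plex_size = plex_size, n_pooled_channels = n_pooled_channels,
              pi_altered = pi_altered,
              mean_ratio_altered = mean_ratio_altered,
              log2_sd = log2_sd, missing_rate = missing_rate,
              batch_sd = batch_sd, yield_means = yield_means,
              yield_sd = yield_sd,
              frac_uncorrelated_peptides = frac_uncorrelated_peptides,
              uncorrelated_effect = uncorrelated_effect,
              covariate_effect_sizes = covariate_effect_sizes %||%
                c(age = 0, pmi = 0, sex = 0, apoe4 = 0, lewy = 0,
                  log2_ptau = 0),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              peptide_offset_sd = peptide_offset_sd,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c("pi_altered", "missing_rate", "frac_uncorrelated_peptides")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$mean_ratio_altered <= 0) stop("mean_ratio_altered must be > 0")
  if (cfg$n_proteins < 1) stop("n_proteins must be positive")
  if (cfg$n_adp + cfg$n_adnp + cfg$n_cn < 4) stop("too few subjects")
  if (any(cfg$plex_size < 1) || cfg$plex_size[2] < cfg$plex_size[1])
    stop("invalid plex_size range")
  if (cfg$log2_sd < 0 || cfg$batch_sd < 0) stop("SDs must be non-negative")
  invisible(cfg)
}

# Number of plexes that accommodates N subjects at plex sizes in [lo, hi];
# errors when no partition exists.
n_plexes_for <- function(n, lo, hi) {
  k_min <- ceiling(n / hi)
  k_max <- floor(n / lo)
  if (k_min > k_max)
    stop("cannot partition ", n, " subjects into plexes of ", lo, "-", hi)
  k_min
}

#' Generate the synthetic cohort metadata
#'
#' Draws per-subject covariates and PSD yields from group-specific
#' distributions and assigns subjects to plexes of `plex_size` subjects,
#' balanced for diagnosis and sex (stratified round-robin), with
#' `n_pooled_channels` pooled-control channels appended to each plex.
#'
#' @param config a `sim_config`
#' @param seed overrides `config$rng_seed`
#' @return data.frame (`SampleMeta`) with one row per subject: `sample`,
#'   `group`, `age`, `pmi`, `sex`, `apoe4`, `lewy`, `ptau_area`,
#'   `log2_ptau`, `psd_yield`, `plex`, `channel`
#' @export
generate_cohort <- function(config, seed = config$rng_seed) {
  validate_sim_config(config)
  n <- config$n_adp + config$n_adnp + config$n_cn
  k <- n_plexes_for(n, config$plex_size[1], config$plex_size[2])
  with_seed(seed, {
    group <- c(rep("AD+P", config$n_adp), rep("AD-P", config$n_adnp),
               rep("CN", config$n_cn))
    is_ad <- group != "CN"
    meta <- data.frame(
      sample = sprintf("S%03d", seq_len(n)),
      group = group,
      age = rnorm(n, 84, 7),
      pmi = pmax(1, rnorm(n, 7, 4)),
      sex = rbinom(n, 1, 0.5),
      apoe4 = rbinom(n, 1, ifelse(is_ad, 0.55, 0.16)),
      lewy = rbinom(n, 1, ifelse(is_ad, 0.30, 0.05)),
      stringsAsFactors = FALSE)
    meta$ptau_area <- exp(rnorm(n, log(ifelse(is_ad, 0.02, 0.002)), 0.5))
    meta$log2_ptau <- log2(meta$ptau_area)
    ym <- config$yield_means[meta$group]
    meta$psd_yield <- pmax(0.05, rnorm(n, ym, config$yield_sd))

    # stratified round-robin: near-equal diagnosis and sex per plex
    ord <- order(meta$group, meta$sex, runif(n))
    plex <- integer(n)
    plex[ord] <- rep_len(seq_len(k), n)
    meta$plex <- plex
    meta <- meta[order(meta$plex, meta$sample), , drop = FALSE]
    meta$channel <- unlist(lapply(split(meta$plex, meta$plex), function(p)
      sprintf("p%02d.c%02d", p[1], seq_along(p))), use.names = FALSE)
    rownames(meta) <- NULL
    meta
  })
}

# Channel metadata (subjects + pooled channels) for a cohort.
cohort_channels <- function(meta, n_pooled) {
  plexes <- sort(unique(meta$plex))
  pooled <- do.call(rbind, lapply(plexes, function(p) {
    n_subj <- sum(meta$plex == p)
    data.frame(channel = sprintf("p%02d.c%02d", p, n_subj + seq_len(n_pooled)),
               plex = p, sample = NA_character_, pooled = TRUE,
               stringsAsFactors = FALSE)
  }))
  subj <- data.frame(channel = meta$channel, plex = meta$plex,
                     sample = meta$sample, pooled = FALSE,
                     stringsAsFactors = FALSE)
  ch <- rbind(subj, pooled)
  ch[order(ch$plex, ch$channel), , drop = FALSE]
}

#' Generate multiplexed peptide-level abundances with known ground truth
#'
#' Log2 abundances are the sum of a protein baseline, a per-peptide offset,
#' the disease effect (`-log2(mean_ratio_altered)` in AD+P for altered
#' proteins), covariate terms, a per-plex per-peptide batch effect and
#' residual noise; discordant ("uncorrelated") peptides receive an
#' independent condition effect. Values are exponentiated to the linear
#' scale; a `missing_rate` fraction is recorded as zero (the raw-data
#' missingness convention). Pooled-control channels carry the all-subject
#' average profile plus batch effect and noise.
#'
#' @param config a `sim_config`
#' @param cohort output of [generate_cohort()]
#' @param seed overrides `config$rng_seed` (offset internally from the
#'   cohort seed so cohort and peptide draws are independent)
#' @return list with `matrix` (a `PeptideMatrix`, zeros = missing) and
#'   `truth` (`GroundTruth`: `true_effect` per protein, `altered_set`,
#'   `uncorrelated_peptides`, per-peptide effect map)
#' @export
generate_peptide_data <- function(config, cohort,
                                  seed = config$rng_seed + 1L) {
  validate_sim_config(config)
  with_seed(seed, {
    P <- config$n_proteins
    proteins <- sprintf("PROT%04d", seq_len(P))
    rng <- config$peptides_per_protein
    n_pep_per <- if (rng[1] == rng[2]) rep(rng[1], P) else
      sample(rng[1]:rng[2], P, replace = TRUE)
    prot_of_pep <- rep(proteins, n_pep_per)
    peptides <- unlist(lapply(seq_len(P), function(i)
      sprintf("%s_pep%02d", proteins[i], seq_len(n_pep_per[i]))),
      use.names = FALSE)
    n_pep <- length(peptides)

    n_alt <- round(config$pi_altered * P)
    altered <- sample(proteins, n_alt)
    true_effect <- setNames(rep(0, P), proteins)
    true_effect[altered] <- -log2(config$mean_ratio_altered)
    pep_effect <- true_effect[prot_of_pep]

    eligible <- peptides[prot_of_pep %in% proteins[n_pep_per > 1]]
    n_unc <- min(length(eligible),
                 round(config$frac_uncorrelated_peptides * n_pep))
    uncorrelated <- if (n_unc > 0) sample(eligible, n_unc) else character(0)
    pep_effect[match(uncorrelated, peptides)] <- config$uncorrelated_effect

    baseline <- rnorm(P, config$baseline_log2_mean, config$baseline_log2_sd)
    pep_base <- baseline[match(prot_of_pep, proteins)] +
      rnorm(n_pep, 0, config$peptide_offset_sd)

    # standardized covariate contribution, shared across peptides
    slopes <- config$covariate_effect_sizes
    cov_term <- rep(0, nrow(cohort))
    for (cv in names(slopes)) {
      if (slopes[[cv]] == 0) next
      v <- cohort[[cv]]
      s <- sd(v)
      cov_term <- cov_term + slopes[[cv]] * if (s > 0) (v - mean(v)) / s else 0
    }

    is_adp <- as.numeric(cohort$group == "AD+P")
    true_subj <- outer(pep_base, rep(1, nrow(cohort))) +
      outer(pep_effect, is_adp) +
      outer(rep(1, n_pep), cov_term)
    colnames(true_subj) <- cohort$channel
    rownames(true_subj) <- peptides

    channels <- cohort_channels(cohort, config$n_pooled_channels)
    pooled_true <- rowMeans(true_subj)
    log2_mat <- matrix(NA_real_, n_pep, nrow(channels),
                       dimnames = list(peptides, channels$channel))
    plexes <- sort(unique(channels$plex))
    batch <- matrix(rnorm(n_pep * length(plexes), 0, config$batch_sd),
                    n_pep, length(plexes),
                    dimnames = list(peptides, as.character(plexes)))
    for (j in seq_len(nrow(channels))) {
      base_j <- if (channels$pooled[j]) pooled_true
                else true_subj[, channels$channel[j]]
      log2_mat[, j] <- base_j + batch[, as.character(channels$plex[j])] +
        rnorm(n_pep, 0, config$log2_sd)
    }
    lin <- 2^log2_mat
    if (config$missing_rate > 0) {
      miss <- matrix(runif(length(lin)) < config$missing_rate, nrow(lin))
      lin[miss] <- 0
    }
    pep2prot <- data.frame(peptide = peptides, protein = prot_of_pep,
                           stringsAsFactors = FALSE)
    truth <- list(true_effect = true_effect,
                  altered_set = sort(altered),
                  uncorrelated_peptides = sort(uncorrelated),
                  peptide_effect = setNames(pep_effect, peptides))
    list(matrix = peptide_matrix(lin, channels, pep2prot), truth = truth)
  })
}

#' Generate a protein-protein interaction edge list
#'
#' Each background protein interacts with a random seed-set member with a
#' probability that may differ between differentially expressed and other
#' proteins, providing a graph with controllable enrichment.
#'
#' @param background character vector of analyzed proteins (seed excluded
#'   internally)
#' @param seed_proteins the seed set (e.g. kinases)
#' @param de differentially expressed proteins
#' @param p_de,p_nonde interaction probabilities for DE / non-DE proteins
#' @param seed RNG seed
#' @return data.frame edge list (`protein_a`, `protein_b`, `score`)
#' @export
generate_interaction_graph <- function(background, seed_proteins, de,
                                       p_de = 0.35, p_nonde = 0.25,
                                       seed = 1L) {
  with_seed(seed, {
    background <- setdiff(background, seed_proteins)
    p <- ifelse(background %in% de, p_de, p_nonde)
    hit <- runif(length(background)) < p
    partners <- background[hit]
    if (!length(partners))
      return(data.frame(protein_a = character(0), protein_b = character(0),
                        score = numeric(0)))
    data.frame(protein_a = sample(seed_proteins, length(partners),
                                  replace = TRUE),
               protein_b = partners,
               score = round(runif(length(partners), 0.4, 1), 3),
               stringsAsFactors = FALSE)
  })
}

#' Generate knockdown-atlas, drug-target, and LINCS-style fixtures
#'
#' Constructs a knockdown atlas containing a reversing gene (sign-flipped
#' disease signature plus noise), a recapitulating gene (same sign), an
#' optional subset-inconsistent gene (concordant off the top subset but
#' discordant on it, the MTOR-like pattern), and null genes; a drug-target
#' table wiring drugs of known action to these genes (including a reversing
#' antagonist, a potentiator of the recapitulating gene, a potentiator of
#' the inconsistent gene, an action-mismatched drug, and a decoy on a null
#' gene); and LINCS-style Z profiles in which the reversing drug opposes the
#' disease signature in CNS cell lines at qualifying doses, the
#' recapitulating-gene potentiator is only tested in non-CNS lines, and the
#' decoy is absent.
#'
#' @param disease_sig disease `SignedSignature` (magnitudes used if present)
#' @param top_entities entities of the top-DE subset (enables the
#'   subset-inconsistent gene)
#' @param n_null number of null knockdown genes (default 3)
#' @param noise_sd noise SD relative to the signature magnitude SD
#' @param seed RNG seed
#' @return list with `atlas`, `drugs`, `lincs`, `truth`
#' @export
generate_pharmacology_fixtures <- function(disease_sig, top_entities = NULL,
                                           n_null = 3, noise_sd = 0.3,
                                           seed = 1L) {
  if (!nrow(disease_sig)) stop("disease signature is empty")
  with_seed(seed, {
    ent <- disease_sig$entity
    m <- if ("magnitude" %in% names(disease_sig)) disease_sig$magnitude
         else disease_sig$sign
    n <- length(ent)
    eps <- function() rnorm(n, 0, noise_sd * max(sd(m), 1e-8))
    rows <- list(
      data.frame(gene = "GENE_REV", entity = ent, value = -m + eps()),
      data.frame(gene = "GENE_RECAP", entity = ent, value = m + eps()))
    if (!is.null(top_entities)) {
      v <- ifelse(ent %in% top_entities, -m, m)
      rows <- c(rows, list(
        data.frame(gene = "GENE_INCON", entity = ent, value = v + eps())))
    }
    for (i in seq_len(n_null))
      rows <- c(rows, list(data.frame(gene = sprintf("GENE_NULL%d", i),
                                      entity = ent, value = rnorm(n))))
    atlas <- do.call(rbind, rows)

    drugs <- data.frame(
      drug = c("drug_reverser", "drug_recap", "drug_wrong_action",
               if (!is.null(top_entities)) "drug_inconsistent",
               "drug_decoy"),
      gene = c("GENE_REV", "GENE_RECAP", "GENE_REV",
               if (!is.null(top_entities)) "GENE_INCON",
               "GENE_NULL1"),
      action = c("antagonist", "potentiator", "potentiator",
                 if (!is.null(top_entities)) "potentiator",
                 "antagonist"),
      stringsAsFactors = FALSE)

    cns_lines <- c("neuron_like", "npc_like")
    lincs_rows <- list()
    for (cl in cns_lines)
      lincs_rows <- c(lincs_rows, list(data.frame(
        drug = "drug_reverser", gene = ent,
        z = -2 * sign(m) + rnorm(n, 0, 0.5),
        cell_line = cl, is_cns = TRUE, dose_um = 10)))
    # sub-threshold dose and non-CNS chaff for the reversing drug
    lincs_rows <- c(lincs_rows, list(
      data.frame(drug = "drug_reverser", gene = ent, z = rnorm(n),
                 cell_line = "hepatocyte_like", is_cns = FALSE,
                 dose_um = 10),
      data.frame(drug = "drug_reverser", gene = ent, z = rnorm(n),
                 cell_line = cns_lines[1], is_cns = TRUE, dose_um = 0.1),
      data.frame(drug = "drug_recap", gene = ent, z = rnorm(n),
                 cell_line = "hepatocyte_like", is_cns = FALSE,
                 dose_um = 10)))
    if (!is.null(top_entities))
      lincs_rows <- c(lincs_rows, list(
        data.frame(drug = "drug_inconsistent", gene = ent, z = rnorm(n),
                   cell_line = cns_lines[1], is_cns = TRUE, dose_um = 10)))
    lincs <- do.call(rbind, lincs_rows)

    list(atlas = atlas, drugs = drugs, lincs = lincs,
         truth = list(reversing_genes = "GENE_REV",
                      reversing_drugs = "drug_reverser",
                      recapitulating_genes = "GENE_RECAP",
                      inconsistent_genes = if (!is.null(top_entities))
                        "GENE_INCON" else character(0),
                      null_genes = sprintf("GENE_NULL%d", seq_len(n_null))))
  })
}

#' Generate a two-arm drug-treatment peptide experiment
#'
#' Treated animals receive a log2 shift opposing the disease sign on a
#' random `reversal_fraction` of signature proteins, with magnitude
#' proportional to the protein's disease magnitude (scaled by
#' `reversal_scale`), so the most disease-altered proteins are reversed
#' most. All animals are measured in one plex with two pooled-control
#' channels. Optionally one treated sample is generated as a low-loading
#' outlier (its linear abundances scaled by `outlier_scale`).
#'
#' @param disease_sig disease `SignedSignature` with magnitudes
#' @param n_treated,n_vehicle animals per arm
#' @param reversal_fraction fraction of signature proteins reversed
#' @param reversal_scale multiplier on the disease magnitude
#' @param noise_sd residual SD (log2)
#' @param peptides_per_protein length-2 integer range
#' @param missing_rate zero/missing probability
#' @param include_outlier generate one low-yield treated sample
#' @param outlier_scale linear scaling of the outlier sample (default
#'   0.35/1.31, a low-yield sample against the remaining animals)
#' @param seed RNG seed
#' @return list with `matrix` (`PeptideMatrix`), `labels` (named vector,
#'   `"treated"`/`"vehicle"` per sample), `meta` (sample metadata with unit
#'   PSD yields) and `truth` (`reversed_set`, per-protein `delta`)
#' @export
generate_treatment_experiment <- function(disease_sig, n_treated = 6,
                                          n_vehicle = 6,
                                          reversal_fraction = 0.6,
                                          reversal_scale = 1,
                                          noise_sd = 0.3,
                                          peptides_per_protein = c(1, 3),
                                          missing_rate = 0,
                                          include_outlier = FALSE,
                                          outlier_scale = 0.35 / 1.31,
                                          seed = 1L) {
  if (!nrow(disease_sig)) stop("disease signature is empty")
  with_seed(seed, {
    proteins <- disease_sig$entity
    m <- if ("magnitude" %in% names(disease_sig)) disease_sig$magnitude
         else disease_sig$sign
    P <- length(proteins)
    reversed <- sample(proteins, round(reversal_fraction * P))
    delta <- setNames(rep(0, P), proteins)
    idx <- match(reversed, proteins)
    delta[idx] <- -sign(m[idx]) * reversal_scale * abs(m[idx])

    rng <- peptides_per_protein
    n_pep_per <- if (rng[1] == rng[2]) rep(rng[1], P) else
      sample(rng[1]:rng[2], P, replace = TRUE)
    prot_of_pep <- rep(proteins, n_pep_per)
    peptides <- unlist(lapply(seq_len(P), function(i)
      sprintf("%s_mpep%02d", proteins[i], seq_len(n_pep_per[i]))),
      use.names = FALSE)
    n_pep <- length(peptides)
    pep_base <- rnorm(P, 14, 1)[match(prot_of_pep, proteins)] +
      rnorm(n_pep, 0, 0.7)
    pep_delta <- delta[prot_of_pep]

    samples <- c(sprintf("TRT%02d", seq_len(n_treated)),
                 sprintf("VEH%02d", seq_len(n_vehicle)))
    labels <- setNames(rep(c("treated", "vehicle"),
                           c(n_treated, n_vehicle)), samples)
    n_samp <- length(samples)
    true_subj <- outer(pep_base, rep(1, n_samp)) +
      outer(pep_delta, as.numeric(labels == "treated"))
    pooled_true <- rowMeans(true_subj)
    channels <- data.frame(
      channel = sprintf("p01.c%02d", seq_len(n_samp + 2)),
      plex = 1L,
      sample = c(samples, NA, NA),
      pooled = c(rep(FALSE, n_samp), TRUE, TRUE),
      stringsAsFactors = FALSE)
    log2_mat <- cbind(true_subj, pooled_true, pooled_true) +
      matrix(rnorm(n_pep * (n_samp + 2), 0, noise_sd), n_pep)
    dimnames(log2_mat) <- list(peptides, channels$channel)
    lin <- 2^log2_mat
    if (include_outlier)
      lin[, 1] <- lin[, 1] * outlier_scale
    if (missing_rate > 0) {
      miss <- matrix(runif(length(lin)) < missing_rate, nrow(lin))
      lin[miss] <- 0
    }
    meta <- data.frame(sample = samples, group = unname(labels),
                       psd_yield = 1, stringsAsFactors = FALSE)
    pep2prot <- data.frame(peptide = peptides, protein = prot_of_pep,
                           stringsAsFactors = FALSE)
    list(matrix = peptide_matrix(lin, channels, pep2prot),
         labels = labels, meta = meta,
         truth = list(reversed_set = sort(reversed), delta = delta))
  })
}
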