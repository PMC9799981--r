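#' Configuration for synthetic label-free AP-MS intensities
#'
#' Emulates the statistical structure of a label-free AP-MS experiment:
#' per-protein log-normal intensities, biological and technical replicate
#' noise in log2 space, multiplicative run-level scale offsets (the
#' motivation for median normalization), intensity-dependent
#' left-censoring of missing values (a logistic model in log2 intensity,
#' the situation that low-quantile imputation presupposes), spiked-in
#' enriched proteins with known log2 fold changes, and per-protein PSM
#' counts.
#'
#' @param n_proteins Number of proteins.
#' @param groups Tibble/data.frame with columns `condition`,
#'   `compartment`; defaults to the four (normoxia/hypoxia x
#'   nucleus/cytoplasm) groups.
#' @param n_bio_replicates Biological replicates per group (3-4 typical).
#' @param n_tech_replicates Technical (injection) replicates per
#'   biological sample (2-3 typical).
#' @param log_intensity_mean,log_intensity_sd Protein baseline
#'   distribution, log2 units.
#' @param bio_sd,tech_sd Replicate noise standard deviations, log2 units.
#' @param run_scale_sd Per-run systematic offset sd, log2 units
#'   (multiplicative on the raw scale).
#' @param missing_mid,missing_slope Logistic missingness model:
#'   P(missing) = plogis((missing_mid - log2 intensity) / missing_slope);
#'   set `missing_slope = 0` to disable missingness entirely.
#' @param spiked Tibble with columns `protein` (row index or name),
#'   `condition`, `compartment`, `log2_fc`: the named group's true log2
#'   abundance is shifted by `log2_fc`. At most one spike per
#'   protein/group.
#' @param psm_lambda Mean of the per-protein Poisson PSM model (per run,
#'   in addition to a guaranteed single PSM).
#' @param seed Integer seed.
#' @return A `sim_lfq_config` list.
#' @export
sim_lfq_config <- function(n_proteins = 1000,
                           groups = NULL,
                           n_bio_replicates = 4,
                           n_tech_replicates = 3,
                           log_intensity_mean = 20,
                           log_intensity_sd = 2,
                           bio_sd = 0.3,
                           tech_sd = 0.1,
                           run_scale_sd = 0.3,
                           missing_mid = 15,
                           missing_slope = 1,
                           spiked = NULL,
                           psm_lambda = 5,
                           seed = 1) {
  if (is.null(groups)) {
    groups <- expand.grid(condition = c("normoxia", "hypoxia"),
                          compartment = c("nucleus", "cytoplasm"),
                          stringsAsFactors = FALSE)
  }
  groups <- tibble::as_tibble(groups)
  if (!all(c("condition", "compartment") %in% names(groups))) {
    abort_input("groups must have columns condition, compartment")
  }
  if (!is.null(spiked)) {
    spiked <- tibble::as_tibble(spiked)
    need <- c("protein", "condition", "compartment", "log2_fc")
    if (!all(need %in% names(spiked))) {
      abort_input("spiked must have columns: %s", paste(need, collapse = ", "))
    }
    if (any(!is.finite(spiked$log2_fc))) {
      abort_input("spiked log2_fc must be finite")
    }
    if (anyDuplicated(spiked[c("protein", "condition", "compartment")])) {
      abort_input("overlapping spike definitions for one protein/group")
    }
  }
  if (n_bio_replicates < 2) abort_input("n_bio_replicates must be >= 2")
  if (n_tech_replicates < 1) abort_input("n_tech_replicates must be >= 1")
  structure(list(n_proteins = as.integer(n_proteins), groups = groups,
                 n_bio_replicates = as.integer(n_bio_replicates),
                 n_tech_replicates = as.integer(n_tech_replicates),
                 log_intensity_mean = log_intensity_mean,
                 log_intensity_sd = log_intensity_sd,
                 bio_sd = bio_sd, tech_sd = tech_sd,
                 run_scale_sd = run_scale_sd,
                 missing_mid = missing_mid, missing_slope = missing_slope,
                 spiked = spiked, psm_lambda = psm_lambda,
                 seed = as.integer(seed)),
            class = "sim_lfq_config")
}

#' Simulate a label-free AP-MS intensity matrix
#'
#' @param config A [sim_lfq_config()].
#' @return List with `lfq` (a raw-stage [lfq_matrix()] with `NA` for
#'   missing values and a PSM matrix) and `truth` (tibble `protein`,
#'   `condition`, `compartment`, `log2_fc` of the spiked effects; zero
#'   rows when nothing is spiked).
#' @examples
#' sim <- simulate_lfq(sim_lfq_config(n_proteins = 50, seed = 3))
#' sim$lfq
#' @export
simulate_lfq <- function(config) {
  stopifnot(inherits(config, "sim_lfq_config"))
  set.seed(config$seed)
  groups <- config$groups
  runs <- tidyr::expand_grid(
    group = seq_len(nrow(groups)),
    bio_rep = seq_len(config$n_bio_replicates),
    tech_rep = seq_len(config$n_tech_replicates)
  )
  runs$condition <- groups$condition[runs$group]
  runs$compartment <- groups$compartment[runs$group]
  runs$run <- sprintf("%s_%s_b%d_t%d", runs$condition, runs$compartment,
                      runs$bio_rep, runs$tech_rep)

  prots <- sprintf("P%04d", seq_len(config$n_proteins))
  base <- rnorm(config$n_proteins, config$log_intensity_mean,
                config$log_intensity_sd)

  # true log2 mean per protein x group (baseline + spikes)
  mu <- matrix(base, config$n_proteins, nrow(groups))
  truth <- tibble::tibble(protein = character(), condition = character(),
                          compartment = character(), log2_fc = numeric())
  if (!is.null(config$spiked) && nrow(config$spiked) > 0) {
    sp <- config$spiked
    p_idx <- if (is.numeric(sp$protein)) as.integer(sp$protein) else
      match(sp$protein, prots)
    g_idx <- match(paste(sp$condition, sp$compartment),
                   paste(groups$condition, groups$compartment))
    if (anyNA(p_idx) || anyNA(g_idx)) {
      abort_input("spiked proteins/groups not found in the design")
    }
    mu[cbind(p_idx, g_idx)] <- mu[cbind(p_idx, g_idx)] + sp$log2_fc
    truth <- dplyr::filter(
      tibble::tibble(protein = prots[p_idx],
                     condition = sp$condition,
                     compartment = sp$compartment,
                     log2_fc = sp$log2_fc),
      .data$log2_fc != 0)
  }

  # biological sample effects, shared by that sample's technical replicates
  bio_keys <- unique(runs[c("group", "bio_rep")])
  bio_eff <- matrix(rnorm(config$n_proteins * nrow(bio_keys), 0,
                          config$bio_sd),
                    config$n_proteins, nrow(bio_keys))
  run_offset <- rnorm(nrow(runs), 0, config$run_scale_sd)

  log2_int <- matrix(NA_real_, config$n_proteins, nrow(runs),
                     dimnames = list(prots, runs$run))
  for (j in seq_len(nrow(runs))) {
    b <- which(bio_keys$group == runs$group[j] &
               bio_keys$bio_rep == runs$bio_rep[j])
    log2_int[, j] <- mu[, runs$group[j]] + bio_eff[, b] + run_offset[j] +
      rnorm(config$n_proteins, 0, config$tech_sd)
  }
  intens <- 2^log2_int

  if (config$missing_slope > 0) {
    p_miss <- stats::plogis((config$missing_mid - log2_int) /
                              config$missing_slope)
    miss <- matrix(runif(length(p_miss)) < p_miss,
                   nrow(p_miss), ncol(p_miss))
    intens[miss] <- NA_real_
  }
  # keep every run quantifiable: ensure at least one observed value per run
  for (j in which(colSums(!is.na(intens)) == 0)) {
    intens[which.max(log2_int[, j]), j] <- 2^max(log2_int[, j])
  }

  psm <- matrix(1 + rpois(length(intens),
                          config$psm_lambda *
                            2^((base - config$log_intensity_mean) / 4)),
                config$n_proteins, nrow(runs),
                dimnames = dimnames(intens))
  psm[is.na(intens)] <- 0

  ann <- tibble::tibble(run = runs$run, condition = runs$condition,
                        compartment = runs$compartment,
                        bio_rep = runs$bio_rep, tech_rep = runs$tech_rep)
  list(lfq = lfq_matrix(intens, ann, psm = psm), truth = truth)
}

#' Configuration for synthetic qPCR Ct tables
#'
#' Emulates a polysome-recruitment PCR array: per-gene baseline Ct values,
#' a reference gene, plate-level additive Ct shifts per sample (which the
#' delta-delta-Ct normalization must cancel), and per-gene true
#' recruitment effects expressed as log2 fold changes of the polysomal
#' fraction under each non-calibrator treatment.
#'
#' @param genes Tibble with columns `gene`, `class` (`IRES`, `ITAF`,
#'   `other`); the reference gene is appended automatically if absent.
#' @param reference_gene Reference (housekeeping) gene, default `"Gapdh"`;
#'   its true effect is always 0.
#' @param treatments Character vector; the first is the calibrator.
#' @param fractions Character vector of RNA fractions.
#' @param true_recruitment_log2fc Tibble `gene`, `treatment`, `log2_fc`
#'   giving each gene's true polysomal-fraction effect; genes/treatments
#'   not listed have effect 0.
#' @param ct_noise_sd Measurement noise in cycles.
#' @param sample_shift_sd Additive per-sample plate shift sd in cycles.
#' @param n_bio_replicates,n_tech_replicates Replicate counts (the array
#'   design uses 2 biological x 3 technical).
#' @param seed Integer seed.
#' @return A `sim_ct_config` list.
#' @export
sim_ct_config <- function(genes = NULL,
                          reference_gene = "Gapdh",
                          treatments = c("control", "gapmer_Neat1",
                                         "gapmer_Neat1_2"),
                          fractions = c("total", "polysomal"),
                          true_recruitment_log2fc = NULL,
                          ct_noise_sd = 0.2,
                          sample_shift_sd = 0.5,
                          n_bio_replicates = 2,
                          n_tech_replicates = 3,
                          seed = 1) {
  if (is.null(genes)) {
    genes <- tibble::tibble(
      gene = c(sprintf("Ires%02d", 1:8), sprintf("Itaf%02d", 1:4),
               sprintf("Gene%02d", 1:4)),
      class = rep(c("IRES", "ITAF", "other"), c(8, 4, 4)))
  }
  genes <- tibble::as_tibble(genes)
  if (!all(c("gene", "class") %in% names(genes))) {
    abort_input("genes must have columns gene, class")
  }
  if (!reference_gene %in% genes$gene) {
    genes <- dplyr::bind_rows(genes, tibble::tibble(gene = reference_gene,
                                                    class = "other"))
  }
  if (!is.null(true_recruitment_log2fc)) {
    true_recruitment_log2fc <- tibble::as_tibble(true_recruitment_log2fc)
    need <- c("gene", "treatment", "log2_fc")
    if (!all(need %in% names(true_recruitment_log2fc))) {
      abort_input("true_recruitment_log2fc must have columns: %s",
                  paste(need, collapse = ", "))
    }
    if (any(true_recruitment_log2fc$gene == reference_gene &
            true_recruitment_log2fc$log2_fc != 0)) {
      abort_input("the reference gene must have true effect 0")
    }
    bad <- setdiff(true_recruitment_log2fc$gene, genes$gene)
    if (length(bad)) abort_input("unknown gene(s) in effects: %s",
                                 paste(bad, collapse = ", "))
  }
  structure(list(genes = genes, reference_gene = reference_gene,
                 treatments = treatments, fractions = fractions,
                 true_recruitment_log2fc = true_recruitment_log2fc,
                 ct_noise_sd = ct_noise_sd,
                 sample_shift_sd = sample_shift_sd,
                 n_bio_replicates = as.integer(n_bio_replicates),
                 n_tech_replicates = as.integer(n_tech_replicates),
                 seed = as.integer(seed)),
            class = "sim_ct_config")
}

#' Simulate a qPCR Ct table with known recruitment effects
#'
#' Ct values follow `Ct = base(gene) + sample shift - effect + noise`,
#' where the effect applies only to the polysomal fraction of
#' non-calibrator treatments (a transcript recruited 2-fold amplifies one
#' cycle earlier). With `ct_noise_sd = 0` the downstream delta-delta-Ct
#' analysis recovers the configured effects exactly.
#'
#' @param config A [sim_ct_config()].
#' @return List with `ct` (long tibble `gene`, `gene_class`, `fraction`,
#'   `treatment`, `bio_rep`, `tech_rep`, `ct`) and `truth` (tibble `gene`,
#'   `treatment`, `log2_fc` including zero-effect genes).
#' @export
simulate_ct <- function(config) {
  stopifnot(inherits(config, "sim_ct_config"))
  set.seed(config$seed)
  genes <- config$genes
  base_ct <- setNames(runif(nrow(genes), 18, 30), genes$gene)
  base_ct[config$reference_gene] <- 17

  eff <- matrix(0, nrow(genes), length(config$treatments),
                dimnames = list(genes$gene, config$treatments))
  if (!is.null(config$true_recruitment_log2fc)) {
    tr <- config$true_recruitment_log2fc
    eff[cbind(match(tr$gene, genes$gene),
              match(tr$treatment, config$treatments))] <- tr$log2_fc
  }
  eff[, config$treatments[1]] <- 0  # calibrator defines the baseline

  samples <- tidyr::expand_grid(fraction = config$fractions,
                                treatment = config$treatments,
                                bio_rep = seq_len(config$n_bio_replicates))
  samples$shift <- rnorm(nrow(samples), 0, config$sample_shift_sd)

  rows <- tidyr::expand_grid(samples,
                             tech_rep = seq_len(config$n_tech_replicates),
                             gene = genes$gene)
  effect <- ifelse(rows$fraction == "polysomal",
                   eff[cbind(rows$gene, rows$treatment)], 0)
  ct <- base_ct[rows$gene] + rows$shift - effect +
    rnorm(nrow(rows), 0, config$ct_noise_sd)
  ct <- pmin(pmax(ct, 5), 40)
  out <- tibble::tibble(
    gene = rows$gene,
    gene_class = genes$class[match(rows$gene, genes$gene)],
    fraction = rows$fraction, treatment = rows$treatment,
    bio_rep = rows$bio_rep, tech_rep = rows$tech_rep,
    ct = unname(ct))
  truth <- tidyr::expand_grid(gene = genes$gene,
                              treatment = config$treatments[-1])
  truth$log2_fc <- eff[cbind(truth$gene, truth$treatment)]
  list(ct = out, truth = truth)
}

#' Configuration for synthetic dual-luciferase plates
#'
#' Emulates bicistronic reporter readings: per-well Renilla (LucR,
#' cap-dependent cistron) signal, Firefly (LucF, IRES-driven cistron)
#' signal equal to the construct's true activity ratio times the LucR
#' signal, independent multiplicative gain noise per channel, additive
#' plate background, and dedicated non-transduced background wells.
#'
#' @param constructs Character vector of construct names; include a
#'   hairpin control with a much smaller true ratio.
#' @param conditions Character vector of condition labels.
#' @param true_ires_activity Tibble `construct`, `condition`, `ratio`
#'   (> 0) of true LucF/LucR ratios; missing combinations default to the
#'   first listed value per construct or 0.2.
#' @param lucR_scale Mean LucR signal in RLU (must be positive).
#' @param gain_cv Coefficient of variation of the per-channel
#'   multiplicative gain (log-normal).
#' @param background_mean,background_sd Additive background RLU.
#' @param n_bio,n_tech Biological and technical replicates (9 x 3 in the
#'   targeted assay design).
#' @param n_background_wells Non-transduced wells per plate.
#' @param seed Integer seed.
#' @return A `sim_plate_config` list.
#' @export
sim_plate_config <- function(constructs = c("FGF1", "hairpin"),
                             conditions = c("normoxia", "hypoxia"),
                             true_ires_activity = NULL,
                             lucR_scale = 10000,
                             gain_cv = 0.1,
                             background_mean = 500,
                             background_sd = 0,
                             n_bio = 9,
                             n_tech = 3,
                             n_background_wells = 3,
                             seed = 1) {
  if (lucR_scale <= 0) abort_input("lucR_scale must be positive")
  if (gain_cv < 0) abort_input("gain_cv must be >= 0")
  if (is.null(true_ires_activity)) {
    true_ires_activity <- tidyr::expand_grid(construct = constructs,
                                             condition = conditions)
    true_ires_activity$ratio <-
      ifelse(true_ires_activity$construct == "hairpin", 0.01,
             ifelse(true_ires_activity$condition == "hypoxia", 0.4, 0.2))
  }
  true_ires_activity <- tibble::as_tibble(true_ires_activity)
  if (!all(c("construct", "condition", "ratio") %in%
             names(true_ires_activity))) {
    abort_input("true_ires_activity must have columns construct, condition, ratio")
  }
  if (any(true_ires_activity$ratio <= 0)) {
    abort_input("true activity ratios must be > 0")
  }
  structure(list(constructs = constructs, conditions = conditions,
                 true_ires_activity = true_ires_activity,
                 lucR_scale = lucR_scale, gain_cv = gain_cv,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 n_background_wells = as.integer(n_background_wells),
                 seed = as.integer(seed)),
            class = "sim_plate_config")
}

#' Simulate dual-luciferase plate readings
#'
#' @param config A [sim_plate_config()].
#' @return List with `readings` (tibble `well`, `construct`, `condition`,
#'   `bio_rep`, `tech_rep`, `lucR`, `lucF`, `is_background`) and `truth`
#'   (the configured activity table).
#' @export
simulate_plate <- function(config) {
  stopifnot(inherits(config, "sim_plate_config"))
  set.seed(config$seed)
  design <- tidyr::expand_grid(construct = config$constructs,
                               condition = config$conditions,
                               bio_rep = seq_len(config$n_bio),
                               tech_rep = seq_len(config$n_tech))
  truth <- config$true_ires_activity
  ratio <- truth$ratio[match(paste(design$construct, design$condition),
                             paste(truth$construct, truth$condition))]
  if (anyNA(ratio)) {
    abort_input("true_ires_activity must cover every construct x condition")
  }
  gain_sd <- sqrt(log(1 + config$gain_cv^2))
  gain <- function(n) exp(rnorm(n, -gain_sd^2 / 2, gain_sd))
  n <- nrow(design)
  bg <- function(n) config$background_mean +
    rnorm(n, 0, config$background_sd)
  lucR <- config$lucR_scale * gain(n) + bg(n)
  lucF <- ratio * config$lucR_scale * gain(n) + bg(n)
  readings <- tibble::tibble(
    well = sprintf("W%03d", seq_len(n)),
    construct = design$construct, condition = design$condition,
    bio_rep = design$bio_rep, tech_rep = design$tech_rep,
    lucR = pmax(lucR, 0), lucF = pmax(lucF, 0),
    is_background = FALSE)
  nb <- config$n_background_wells
  background <- tibble::tibble(
    well = sprintf("B%03d", seq_len(nb)),
    construct = NA_character_, condition = NA_character_,
    bio_rep = NA_integer_, tech_rep = NA_integer_,
    lucR = pmax(bg(nb), 0), lucF = pmax(bg(nb), 0),
    is_background = TRUE)
  list(readings = dplyr::bind_rows(readings, background), truth = truth)
}
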