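#' Relative quantification by the 2^-ddCt method
#'
#' Technical replicates are averaged in Ct space; within each sample,
#' dCt = Ct(gene) - Ct(reference gene); ddCt compares each treatment's
#' dCt to the calibrator treatment's mean dCt; biological replicates are
#' combined by averaging ddCt in log space before exponentiating, so the
#' calibrator's RQ is exactly 1 and RQ is invariant to per-sample
#' additive Ct shifts.
#'
#' @param ct Long Ct tibble with columns `gene`, `fraction` (optional),
#'   `treatment`, `bio_rep`, `tech_rep`, `ct`; `NA` Ct values
#'   (undetermined wells) are ignored, and genes with no usable Ct in a
#'   treatment are dropped with a message.
#' @param reference_gene Reference gene name, default `"Gapdh"`.
#' @param calibrator_treatment Calibrator treatment, default `"control"`.
#' @return Tibble `gene`, (`fraction`,) `treatment`, `rq`, `log2_rq`.
#' @examples
#' ct <- tibble::tibble(
#'   gene = rep(c("A", "Gapdh"), 2),
#'   treatment = rep(c("treated", "control"), each = 2),
#'   bio_rep = 1, tech_rep = 1,
#'   ct = c(25, 20, 26, 20))
#' delta_delta_ct(ct, calibrator_treatment = "control")
#' @export
delta_delta_ct <- function(ct, reference_gene = "Gapdh",
                           calibrator_treatment = "control") {
  ct <- tibble::as_tibble(ct)
  need <- c("gene", "treatment", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(ct))) {
    abort_input("Ct table must have columns: %s", paste(need, collapse = ", "))
  }
  if (!reference_gene %in% ct$gene) {
    abort_input("reference gene '%s' absent from the Ct table", reference_gene)
  }
  if (!calibrator_treatment %in% ct$treatment) {
    abort_input("calibrator treatment '%s' absent", calibrator_treatment)
  }
  has_fraction <- "fraction" %in% names(ct)
  if (!has_fraction) ct$fraction <- "all"

  # technical replicates averaged in Ct space; undetermined wells dropped
  tech <- ct |>
    dplyr::filter(!is.na(.data$ct)) |>
    dplyr::group_by(.data$gene, .data$fraction, .data$treatment,
                    .data$bio_rep) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  ref <- tech |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("fraction", "treatment", "bio_rep", ref_ct = "ct")
  if (nrow(ref) == 0) abort_input("reference gene has no usable Ct values")

  dct <- tech |>
    dplyr::inner_join(ref, by = c("fraction", "treatment", "bio_rep")) |>
    dplyr::mutate(dct = .data$ct - .data$ref_ct)

  calib <- dct |>
    dplyr::filter(.data$treatment == calibrator_treatment) |>
    dplyr::group_by(.data$gene, .data$fraction) |>
    dplyr::summarise(calib_dct = mean(.data$dct), .groups = "drop")

  all_cells <- tidyr::expand_grid(
    gene = unique(ct$gene),
    fraction = unique(ct$fraction),
    treatment = unique(ct$treatment))
  res <- dct |>
    dplyr::inner_join(calib, by = c("gene", "fraction")) |>
    dplyr::mutate(ddct = .data$dct - .data$calib_dct) |>
    dplyr::group_by(.data$gene, .data$fraction, .data$treatment) |>
    dplyr::summarise(rq = 2^(-mean(.data$ddct)), .groups = "drop")
  dropped <- dplyr::anti_join(all_cells, res,
                              by = c("gene", "fraction", "treatment"))
  if (nrow(dropped) > 0) {
    message(sprintf(
      "%d gene/treatment cell(s) not quantified (undetermined Ct); excluded",
      nrow(dropped)))
  }
  res$log2_rq <- log2(res$rq)
  if (!has_fraction) res$fraction <- NULL
  res
}

#' Signed fold change of a relative quantity
#'
#' Maps RQ >= 1 to RQ and RQ < 1 to -1/RQ, the reporting convention under
#' which a halving (RQ 0.5) reads as a fold change of -2. Satisfies
#' `f(RQ) = -f(1/RQ)`.
#'
#' @param rq Positive numeric vector of relative quantifications.
#' @return Numeric vector of signed fold changes, all with magnitude >= 1.
#' @export
signed_fold_change <- function(rq) {
  if (any(!is.finite(rq) | rq <= 0)) {
    abort_input("RQ values must be finite and > 0")
  }
  ifelse(rq >= 1, rq, -1 / rq)
}

#' Polysome recruitment from a fractionated Ct table
#'
#' Runs [delta_delta_ct()] within each RNA fraction and reports, per gene
#' and non-calibrator treatment, the recruitment RQ: either the polysomal
#' fraction's RQ divided by the total fraction's RQ
#' (`"polysomal_over_total"`, the translational-efficiency proxy) or the
#' polysomal fraction's RQ alone (`"polysomal_only"`).
#'
#' @param ct Long Ct tibble with a `fraction` column containing at least
#'   the fractions the chosen metric needs, plus `gene_class` (optional).
#' @param metric Recruitment metric.
#' @param reference_gene,calibrator_treatment See [delta_delta_ct()].
#' @return Tibble `gene`, `gene_class` (if supplied), `treatment`, `rq`,
#'   `log2_rq`, `fold_change` (signed), `metric`.
#' @export
recruitment <- function(ct,
                        metric = c("polysomal_over_total", "polysomal_only"),
                        reference_gene = "Gapdh",
                        calibrator_treatment = "control") {
  metric <- match.arg(metric)
  ct <- tibble::as_tibble(ct)
  if (!"fraction" %in% names(ct)) {
    abort_input("Ct table must have a 'fraction' column")
  }
  need_fr <- if (metric == "polysomal_over_total")
    c("polysomal", "total") else "polysomal"
  missing_fr <- setdiff(need_fr, unique(ct$fraction))
  if (length(missing_fr)) {
    abort_input("fraction(s) required by metric '%s' missing: %s",
                metric, paste(missing_fr, collapse = ", "))
  }
  rq <- delta_delta_ct(ct, reference_gene, calibrator_treatment) |>
    dplyr::filter(.data$treatment != calibrator_treatment)
  if (metric == "polysomal_over_total") {
    wide <- rq |>
      dplyr::select("gene", "fraction", "treatment", "rq") |>
      tidyr::pivot_wider(names_from = "fraction", values_from = "rq")
    out <- wide |>
      dplyr::filter(!is.na(.data$polysomal) & !is.na(.data$total)) |>
      dplyr::mutate(rq = .data$polysomal / .data$total) |>
      dplyr::select("gene", "treatment", "rq")
  } else {
    out <- rq |>
      dplyr::filter(.data$fraction == "polysomal") |>
      dplyr::select("gene", "treatment", "rq")
  }
  out <- out |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::mutate(log2_rq = log2(.data$rq),
                  fold_change = signed_fold_change(.data$rq),
                  metric = metric)
  if ("gene_class" %in% names(ct)) {
    classes <- dplyr::distinct(ct, .data$gene, .data$gene_class)
    if (anyDuplicated(classes$gene)) {
      abort_input("inconsistent gene_class labels for one gene")
    }
    out <- dplyr::left_join(out, classes, by = "gene") |>
      dplyr::relocate("gene_class", .after = "gene")
  }
  out
}

#' Class-level recruitment summary
#'
#' Per gene class and treatment: the number of quantified genes and the
#' percentage with decreased (RQ < 1), increased (RQ > 1) and unchanged
#' (RQ = 1) recruitment. An `"all"` row aggregates every class. Exact
#' fractions are retained alongside integer-rounded display percentages.
#'
#' @param results Recruitment tibble from [recruitment()] (columns `gene`,
#'   `gene_class`, `treatment`, `rq`).
#' @param classes Allowed gene classes; anything else raises an error.
#' @return Tibble `gene_class`, `treatment`, `n_genes`, `frac_decreased`,
#'   `frac_increased`, `frac_unchanged`, `pct_decreased`,
#'   `pct_increased`, `pct_unchanged`.
#' @export
summarize_classes <- function(results,
                              classes = c("IRES", "ITAF", "other")) {
  results <- tibble::as_tibble(results)
  need <- c("gene", "gene_class", "treatment", "rq")
  if (!all(need %in% names(results))) {
    abort_input("results must have columns: %s", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(results$gene_class), classes)
  if (length(bad)) {
    abort_input("unknown gene class label(s): %s", paste(bad, collapse = ", "))
  }
  all_rows <- dplyr::mutate(results, gene_class = "all")
  dplyr::bind_rows(results, all_rows) |>
    dplyr::group_by(.data$gene_class, .data$treatment) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      frac_decreased = mean(.data$rq < 1),
      frac_increased = mean(.data$rq > 1),
      frac_unchanged = mean(.data$rq == 1),
      .groups = "drop") |>
    dplyr::mutate(pct_decreased = round(100 * .data$frac_decreased),
                  pct_increased = round(100 * .data$frac_increased),
                  pct_unchanged = 100 - .data$pct_decreased -
                    .data$pct_increased)
}

#' Signed-display matrix for recruitment heatmaps
#'
#' Genes x treatments matrix of signed fold changes (repression negative,
#' induction positive), ordered by gene class.
#'
#' @param results Recruitment tibble from [recruitment()].
#' @return Numeric matrix with gene rownames and treatment colnames.
#' @export
recruitment_matrix <- function(results) {
  wide <- results |>
    dplyr::arrange(.data$gene_class, .data$gene) |>
    dplyr::select("gene", "treatment", "fold_change") |>
    tidyr::pivot_wider(names_from = "treatment",
                       values_from = "fold_change")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  m
}
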