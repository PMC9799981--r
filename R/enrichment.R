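#' Define a pairwise group comparison
#'
#' A comparison names two groups of runs, each a (condition, compartment)
#' pair; the reported log2 fold change is mean(group1) - mean(group2).
#'
#' @param name Comparison label.
#' @param group1,group2 Length-2 character vectors
#'   `c(condition, compartment)`.
#' @return A `comparison_spec` list.
#' @export
comparison_spec <- function(name, group1, group2) {
  if (length(group1) != 2 || length(group2) != 2) {
    abort_input("groups must be c(condition, compartment) pairs")
  }
  if (identical(group1, group2)) abort_input("group1 and group2 must differ")
  structure(list(name = name, group1 = group1, group2 = group2),
            class = "comparison_spec")
}

#' The four canonical AP-MS comparisons
#'
#' Hypoxia versus normoxia within each compartment, and nucleus versus
#' cytoplasm within each condition.
#'
#' @return Named list of four [comparison_spec()] objects.
#' @export
canonical_comparisons <- function() {
  list(
    nucleus_hypoxia_vs_normoxia = comparison_spec(
      "nucleus_hypoxia_vs_normoxia",
      c("hypoxia", "nucleus"), c("normoxia", "nucleus")),
    cytoplasm_hypoxia_vs_normoxia = comparison_spec(
      "cytoplasm_hypoxia_vs_normoxia",
      c("hypoxia", "cytoplasm"), c("normoxia", "cytoplasm")),
    normoxia_nucleus_vs_cytoplasm = comparison_spec(
      "normoxia_nucleus_vs_cytoplasm",
      c("normoxia", "nucleus"), c("normoxia", "cytoplasm")),
    hypoxia_nucleus_vs_cytoplasm = comparison_spec(
      "hypoxia_nucleus_vs_cytoplasm",
      c("hypoxia", "nucleus"), c("hypoxia", "cytoplasm"))
  )
}

group_columns <- function(mat, group) {
  which(mat$annotation$condition == group[1] &
        mat$annotation$compartment == group[2])
}

#' Pooled-variance t-test of per-protein enrichment
#'
#' For every protein, computes the log2 fold change (mean of group1 minus
#' mean of group2 across biological replicates, in log2 space) and a
#' two-sided unpaired Student t-test with pooled (equal) variance. A
#' protein is flagged `enriched` when |log2FC| > `fc_threshold` and
#' p < `p_threshold` (defaults: linear FC > 2 or < 0.5, p < 0.05).
#' Proteins with fewer than two biological replicates in either group are
#' flagged untestable (`p = NA`).
#'
#' @param mat An `lfq_matrix` at stage `"averaged"` (log2,
#'   technical-averaged, imputed).
#' @param spec A [comparison_spec()].
#' @param fc_threshold,p_threshold Enrichment thresholds on |log2FC| and p.
#' @return An `enrichment_table` tibble: `protein`, `comparison`,
#'   `log2_fc`, `fc` (linear), `t`, `df`, `p_value`, `p_adjust`
#'   (Benjamini-Hochberg, informational only), `n_detected_g1`,
#'   `n_detected_g2` (biological replicates observed before imputation),
#'   `psm_total` (summed averaged PSM over both groups, `NA` when PSM
#'   counts are unavailable), `enriched`.
#' @export
test_enrichment <- function(mat, spec, fc_threshold = 1, p_threshold = 0.05) {
  stopifnot(inherits(mat, "lfq_matrix"), inherits(spec, "comparison_spec"))
  require_stage(mat, "averaged", "test_enrichment")
  i1 <- group_columns(mat, spec$group1)
  i2 <- group_columns(mat, spec$group2)
  if (length(i1) == 0 || length(i2) == 0) {
    abort_input("comparison '%s': group absent from annotation", spec$name)
  }
  x1 <- mat$intensities[, i1, drop = FALSE]
  x2 <- mat$intensities[, i2, drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  log2_fc <- m1 - m2
  testable <- n1 >= 2 && n2 >= 2
  if (testable) {
    v1 <- apply(x1, 1, stats::var)
    v2 <- apply(x2, 1, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tval <- ifelse(se > 0, log2_fc / se, ifelse(abs(log2_fc) < .EPS, 0, Inf))
    df <- n1 + n2 - 2
    p <- ifelse(is.finite(tval), 2 * pt(-abs(tval), df),
                ifelse(tval == 0, 1, 0))
    p <- pmax(pmin(p, 1), 0)
    # zero fold change with zero variance is a perfectly null protein
    p[se == 0 & abs(log2_fc) < .EPS] <- 1
  } else {
    tval <- rep(NA_real_, nrow(mat$intensities))
    df <- NA_real_
    p <- rep(NA_real_, nrow(mat$intensities))
  }
  det <- mat$detected
  if (is.null(det)) det <- matrix(TRUE, nrow(mat$intensities),
                                  ncol(mat$intensities))
  nd1 <- rowSums(det[, i1, drop = FALSE])
  nd2 <- rowSums(det[, i2, drop = FALSE])
  psm_total <- if (!is.null(mat$psm)) {
    rowSums(mat$psm[, c(i1, i2), drop = FALSE])
  } else {
    rep(NA_real_, nrow(mat$intensities))
  }
  out <- tibble::tibble(
    protein = rownames(mat$intensities),
    comparison = spec$name,
    log2_fc = unname(log2_fc),
    fc = 2^unname(log2_fc),
    t = unname(tval),
    df = df,
    p_value = unname(p),
    p_adjust = stats::p.adjust(unname(p), method = "BH"),
    n_detected_g1 = unname(nd1),
    n_detected_g2 = unname(nd2),
    psm_total = unname(psm_total),
    enriched = !is.na(p) & abs(log2_fc) > fc_threshold & p < p_threshold
  )
  class(out) <- c("enrichment_table", class(out))
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Identification-confidence filters
#'
#' Removes likely false positives arising from quantitation of low-intensity
#' signals: a protein keeps its significance only when its total averaged
#' PSM count exceeds `psm_min` (strictly) and it was quantified before
#' imputation in at least `min_bio_detected` biological replicates of at
#' least one compared group. Adds the `significant_after_filters` flag;
#' `enriched` is left untouched.
#'
#' @param table An `enrichment_table` from [test_enrichment()].
#' @param psm_min PSM total that must be exceeded (default 4; proteins at
#'   exactly 4 are excluded).
#' @param min_bio_detected Minimum pre-imputation biological replicates in
#'   at least one group (default 2).
#' @return The table with `significant_after_filters` added.
#' @export
apply_confidence_filters <- function(table, psm_min = 4,
                                     min_bio_detected = 2) {
  stopifnot(inherits(table, "enrichment_table"))
  psm_ok <- !is.na(table$psm_total) & table$psm_total > psm_min
  if (all(is.na(table$psm_total))) psm_ok <- TRUE  # no PSM layer available
  rep_ok <- pmax(table$n_detected_g1, table$n_detected_g2) >=
    min_bio_detected
  table$significant_after_filters <- table$enriched & psm_ok & rep_ok
  table
}

#' Volcano-plot coordinates
#'
#' @param table An `enrichment_table`, ideally after
#'   [apply_confidence_filters()].
#' @param p_cap p-values of exactly 0 are replaced by this cap with a
#'   warning so -log10 stays finite.
#' @return Tibble `protein`, `comparison`, `log2_fc`, `neglog10_p`,
#'   `enriched`, `significant_after_filters`, with attributes
#'   `fc_line` (|log2FC| threshold) and `p_line` (-log10 of the p cutoff,
#'   1.30 for p = 0.05).
#' @export
volcano_data <- function(table, p_cap = 1e-300) {
  stopifnot(inherits(table, "enrichment_table"))
  p <- table$p_value
  if (any(p == 0, na.rm = TRUE)) {
    warning(sprintf("p-values of 0 capped at %g for -log10 display", p_cap))
    p[which(p == 0)] <- p_cap
  }
  out <- tibble::tibble(
    protein = table$protein,
    comparison = table$comparison,
    log2_fc = table$log2_fc,
    neglog10_p = -log10(p),
    enriched = table$enriched,
    significant_after_filters =
      if ("significant_after_filters" %in% names(table))
        table$significant_after_filters else rep(NA, nrow(table))
  )
  attr(out, "fc_line") <- attr(table, "fc_threshold")
  attr(out, "p_line") <- -log10(attr(table, "p_threshold"))
  out
}

#' Volcano plot of a comparison
#'
#' @param table An `enrichment_table` after [apply_confidence_filters()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(table) {
  vd <- volcano_data(table)
  status <- dplyr::case_when(
    vd$significant_after_filters ~ "significant",
    vd$enriched ~ "enriched",
    TRUE ~ "background"
  )
  ggplot2::ggplot(vd, ggplot2::aes(x = .data$log2_fc, y = .data$neglog10_p,
                                   colour = status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(vd, "fc_line"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(vd, "p_line"),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(background = "grey60",
                                            enriched = "black",
                                            significant = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = unique(vd$comparison)) +
    ggplot2::theme_minimal()
}

#' Run the full enrichment pipeline
#'
#' Applies the fixed processing order -- median normalization, 5% quantile
#' imputation, log2 transform, technical-replicate averaging, pooled
#' t-tests per comparison, confidence filters -- to a raw `lfq_matrix`.
#'
#' @param mat An `lfq_matrix` at stage `"raw"`.
#' @param comparisons List of [comparison_spec()]; default the four
#'   [canonical_comparisons()] restricted to those present in the
#'   annotation.
#' @param impute_q Imputation quantile.
#' @param fc_threshold,p_threshold,psm_min,min_bio_detected Thresholds, see
#'   [test_enrichment()] and [apply_confidence_filters()].
#' @return Tibble binding the per-comparison enrichment tables.
#' @export
run_enrichment <- function(mat, comparisons = NULL, impute_q = 0.05,
                           fc_threshold = 1, p_threshold = 0.05,
                           psm_min = 4, min_bio_detected = 2) {
  stopifnot(inherits(mat, "lfq_matrix"))
  require_stage(mat, "raw", "run_enrichment")
  processed <- mat |>
    normalize_median() |>
    impute_quantile(q = impute_q) |>
    log2_transform() |>
    average_technical()
  if (is.null(comparisons)) {
    groups <- unique(paste(mat$annotation$condition,
                           mat$annotation$compartment))
    comparisons <- Filter(function(sp) {
      all(c(paste(sp$group1, collapse = " "),
            paste(sp$group2, collapse = " ")) %in% groups)
    }, canonical_comparisons())
  }
  res <- lapply(comparisons, function(sp) {
    test_enrichment(processed, sp, fc_threshold = fc_threshold,
                    p_threshold = p_threshold) |>
      apply_confidence_filters(psm_min = psm_min,
                               min_bio_detected = min_bio_detected)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("enrichment_table", class(out))
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Published paraspeckle component annotation
#'
#' Loads the packaged annotation of 40 reported paraspeckle components:
#' name, alternative name, protein class (`IA`, `IB`, `II`, `IIIA`, `IIIB`,
#' `n/d`, or blank when unreported), known ITAF function, and presence in
#' the bait interactome reported by the originating MS study.
#'
#' @param path Optional path to an alternative annotation CSV with the same
#'   columns.
#' @return Tibble `name`, `alternative_name`, `class`, `itaf`,
#'   `presence_in_ms`.
#' @export
paraspeckle_components <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "paraspeckle_components.csv",
                        package = "speckletools", mustWork = TRUE)
  }
  tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                    na.strings = character()))
  if (anyDuplicated(toupper(tab$name))) {
    abort_input("duplicate component names in annotation")
  }
  tab
}

#' Overlap of an interactome with the paraspeckle component list
#'
#' Counts how many annotated paraspeckle components are present in an
#' interactome. In `"fixture"` mode the packaged `presence_in_ms` column is
#' used directly; in `"analysis"` mode presence is determined by
#' case-insensitive matching of a character vector of identified proteins
#' against component names and alternative names.
#'
#' @param annotation Component annotation from [paraspeckle_components()].
#' @param identified Character vector of identified/enriched protein names
#'   (required for `mode = "analysis"`).
#' @param mode `"fixture"` or `"analysis"`.
#' @return Tibble `n_present`, `n_total`, `n_itaf_present`, `mode`.
#' @export
annotate_paraspeckle <- function(annotation = paraspeckle_components(),
                                 identified = NULL,
                                 mode = c("fixture", "analysis")) {
  mode <- match.arg(mode)
  annotation <- tibble::as_tibble(annotation)
  if (anyDuplicated(toupper(annotation$name))) {
    abort_input("duplicate component names in annotation")
  }
  if (nrow(annotation) == 0) {
    return(tibble::tibble(n_present = 0L, n_total = 0L,
                          n_itaf_present = 0L, mode = mode))
  }
  if (mode == "fixture") {
    present <- tolower(annotation$presence_in_ms) == "yes"
  } else {
    if (is.null(identified)) {
      abort_input("mode = 'analysis' requires 'identified' protein names")
    }
    ids <- toupper(identified)
    present <- toupper(annotation$name) %in% ids |
      (nzchar(annotation$alternative_name) &
         toupper(annotation$alternative_name) %in% ids)
  }
  itaf <- tolower(annotation$itaf) == "yes"
  tibble::tibble(
    n_present = sum(present),
    n_total = nrow(annotation),
    n_itaf_present = sum(present & itaf),
    mode = mode
  )
}
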