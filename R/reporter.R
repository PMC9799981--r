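#' Subtract plate background from luminometer readings
#'
#' Each channel (LucR, LucF) is reduced by the mean of the plate's
#' non-transduced background wells for that channel. Sample wells whose
#' reading does not exceed the background are flagged invalid and excluded
#' from downstream ratio computation.
#'
#' @param readings Plate tibble with columns `well`, `construct`,
#'   `condition`, `bio_rep`, `tech_rep`, `lucR`, `lucF`, `is_background`
#'   (see [simulate_plate()] for the layout).
#' @param no_background Skip subtraction entirely (identity), for plates
#'   measured without background wells.
#' @return The sample wells (background rows removed) with `lucR`/`lucF`
#'   background-subtracted and a logical `valid` column.
#' @export
subtract_background <- function(readings, no_background = FALSE) {
  readings <- tibble::as_tibble(readings)
  need <- c("construct", "condition", "bio_rep", "tech_rep",
            "lucR", "lucF", "is_background")
  if (!all(need %in% names(readings))) {
    abort_input("plate table must have columns: %s",
                paste(need, collapse = ", "))
  }
  samples <- dplyr::filter(readings, !.data$is_background)
  if (no_background) {
    samples$valid <- samples$lucR > 0 & samples$lucF > 0
    return(samples)
  }
  bg <- dplyr::filter(readings, .data$is_background)
  if (nrow(bg) == 0) {
    abort_input(paste("no background wells; pass no_background = TRUE to",
                      "analyze uncorrected readings"))
  }
  samples$lucR <- samples$lucR - mean(bg$lucR)
  samples$lucF <- samples$lucF - mean(bg$lucF)
  samples$valid <- samples$lucR > 0 & samples$lucF > 0
  samples
}

#' IRES activity as the LucF/LucR ratio
#'
#' Computes the per-well LucF/LucR ratio (the IRES activity readout of a
#' bicistronic reporter: LucF is IRES-driven, LucR cap-driven, so a shared
#' gain cancels) and averages each biological replicate's technical
#' ratios.
#'
#' @param readings Background-subtracted readings from
#'   [subtract_background()]; invalid wells are dropped with a message.
#' @return Tibble `construct`, `condition`, `bio_rep`, `n_tech`, `ratio`.
#' @export
ires_activity <- function(readings) {
  readings <- tibble::as_tibble(readings)
  if (!"valid" %in% names(readings)) {
    abort_input("run subtract_background() first (missing 'valid' column)")
  }
  n_bad <- sum(!readings$valid)
  if (n_bad > 0) {
    message(sprintf("dropping %d invalid well(s) (reading <= background)",
                    n_bad))
    readings <- dplyr::filter(readings, .data$valid)
  }
  if (any(readings$lucR <= 0)) abort_input("LucR must be positive")
  readings |>
    dplyr::mutate(well_ratio = .data$lucF / .data$lucR) |>
    dplyr::group_by(.data$construct, .data$condition, .data$bio_rep) |>
    dplyr::summarise(n_tech = dplyr::n(),
                     ratio = mean(.data$well_ratio), .groups = "drop")
}

#' Normalize activities to a reference group
#'
#' Divides every biological-replicate ratio by the mean ratio of the
#' reference group, so the reference group's normalized mean is exactly 1.
#'
#' @param activities Tibble from [ires_activity()].
#' @param reference Named list/vector selecting the reference rows by any
#'   subset of `construct` and `condition`
#'   (e.g. `list(condition = "normoxia")`).
#' @return `activities` with a `normalized_ratio` column.
#' @export
normalize_to_reference <- function(activities, reference) {
  activities <- tibble::as_tibble(activities)
  sel <- rep(TRUE, nrow(activities))
  for (key in names(reference)) {
    if (!key %in% names(activities)) {
      abort_input("unknown reference key '%s'", key)
    }
    sel <- sel & activities[[key]] == reference[[key]]
  }
  if (!any(sel)) abort_input("reference group is empty")
  ref_mean <- mean(activities$ratio[sel])
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    abort_input("reference group mean must be positive")
  }
  dplyr::mutate(activities, normalized_ratio = .data$ratio / ref_mean)
}

#' Mann-Whitney (Wilcoxon rank-sum) group comparison
#'
#' Two-sided test of two independent groups. Without ties and with
#' n1 + n2 <= 20 the p-value is exact (equivalent to full enumeration of
#' the rank permutations); otherwise the normal approximation with tie
#' correction and continuity correction is used. The method actually
#' applied is recorded.
#'
#' @param group_a,group_b Numeric vectors (>= 1 observation each; the
#'   assay design typically has n = 9 biological replicates per group).
#' @return Tibble `n_a`, `n_b`, `U` (statistic for `group_a`), `p_value`,
#'   `method`, `mean_a`, `mean_b`, `sd_a`, `sd_b`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort_input("both groups must be non-empty")
  }
  if (length(unique(c(group_a, group_b))) == 1) {
    # complete ties: the rank distribution is degenerate, no evidence at all
    return(tibble::tibble(
      n_a = length(group_a), n_b = length(group_b),
      U = length(group_a) * length(group_b) / 2,
      p_value = 1, method = "normal approximation, tie-corrected",
      mean_a = mean(group_a), mean_b = mean(group_b),
      sd_a = sd(group_a), sd_b = sd(group_b)))
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && (length(group_a) + length(group_b)) <= 20
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE,
                alternative = "two.sided"))
  tibble::tibble(
    n_a = length(group_a), n_b = length(group_b),
    U = unname(wt$statistic),
    p_value = min(wt$p.value, 1),
    method = if (exact) "exact" else "normal approximation, tie-corrected",
    mean_a = mean(group_a), mean_b = mean(group_b),
    sd_a = sd(group_a), sd_b = sd(group_b))
}

#' Compare IRES activities between two groups
#'
#' Convenience wrapper running [mann_whitney()] on the biological-replicate
#' activities of two (construct, condition) groups.
#'
#' @param activities Tibble from [ires_activity()] or
#'   [normalize_to_reference()].
#' @param group_a,group_b Named lists selecting rows as in
#'   [normalize_to_reference()].
#' @param value Column to compare, `"ratio"` or `"normalized_ratio"`.
#' @return One-row tibble from [mann_whitney()] with group labels added.
#' @export
compare_groups <- function(activities, group_a, group_b, value = "ratio") {
  pick <- function(sel) {
    keep <- rep(TRUE, nrow(activities))
    for (key in names(sel)) keep <- keep & activities[[key]] == sel[[key]]
    activities[[value]][keep]
  }
  res <- mann_whitney(pick(group_a), pick(group_b))
  res$group_a <- paste(unlist(group_a), collapse = "/")
  res$group_b <- paste(unlist(group_b), collapse = "/")
  dplyr::relocate(res, "group_a", "group_b")
}
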