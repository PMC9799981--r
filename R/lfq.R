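#' Label-free quantification matrix
#'
#' Container for an AP-MS label-free experiment: a protein x run intensity
#' matrix with missing values encoded as `NA` (never 0), optional matching
#' PSM (peptide-spectrum-match) counts, and a run annotation giving each
#' run's condition (`normoxia`/`hypoxia`), subcellular compartment
#' (`nucleus`/`cytoplasm`), biological replicate and technical (injection)
#' replicate. The object tracks which pipeline stage it has passed
#' (`raw`, `normalized`, `imputed`, `log2`, `averaged`) so the fixed
#' processing order -- aggregate, median-normalize, impute, log2, average
#' technical replicates, test -- cannot be applied out of order.
#'
#' @param intensities Numeric matrix, proteins in rows (rownames required),
#'   runs in columns (colnames required); `NA` marks missing, observed
#'   values must be positive on the raw scale.
#' @param annotation Tibble/data.frame with columns `run`, `condition`,
#'   `compartment`, `bio_rep`, `tech_rep` covering every column of
#'   `intensities`.
#' @param psm Optional matrix of PSM counts, same dimensions as
#'   `intensities`.
#' @param stage Pipeline stage label; user code normally leaves the
#'   default.
#' @return An `lfq_matrix` object.
#' @export
lfq_matrix <- function(intensities, annotation, psm = NULL, stage = "raw") {
  if (!is.matrix(intensities) || is.null(rownames(intensities)) ||
      is.null(colnames(intensities))) {
    abort_input("'intensities' must be a matrix with protein rownames and run colnames")
  }
  annotation <- tibble::as_tibble(annotation)
  need <- c("run", "condition", "compartment", "bio_rep", "tech_rep")
  if (!all(need %in% names(annotation))) {
    abort_input("annotation must have columns: %s", paste(need, collapse = ", "))
  }
  if (!setequal(annotation$run, colnames(intensities)) ||
      anyDuplicated(annotation$run)) {
    abort_input("annotation runs must match intensity columns one-to-one")
  }
  annotation <- annotation[match(colnames(intensities), annotation$run), ]
  if (stage %in% c("raw", "normalized", "imputed") &&
      any(intensities <= 0, na.rm = TRUE)) {
    abort_input("raw-scale intensities must be positive where observed")
  }
  if (!is.null(psm) &&
      !(is.matrix(psm) && all(dim(psm) == dim(intensities)))) {
    abort_input("'psm' must be a matrix with the same dimensions as 'intensities'")
  }
  structure(list(intensities = intensities, annotation = annotation,
                 psm = psm, stage = stage),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf(
    "<lfq_matrix> %d proteins x %d runs (stage: %s, %.1f%% missing)\n",
    nrow(x$intensities), ncol(x$intensities), x$stage,
    100 * mean(is.na(x$intensities))))
  invisible(x)
}

require_stage <- function(mat, allowed, op) {
  if (!mat$stage %in% allowed) {
    abort_input("%s expects an lfq_matrix at stage %s (got '%s')",
                op, paste(sQuote(allowed), collapse = " or "), mat$stage)
  }
}

#' Sum unique-peptide intensities into protein intensities
#'
#' Protein intensity per run is the sum of its unique peptide intensities;
#' peptides mapped to more than one protein are dropped entirely (they
#' contribute to none) and their number is reported via a message.
#'
#' @param peptides Long tibble with columns `peptide`, `protein`, `run`,
#'   `intensity` and optionally `psm`; absent peptide/run combinations are
#'   treated as missing.
#' @param annotation Run annotation passed through to [lfq_matrix()].
#' @return An `lfq_matrix` at stage `"raw"`.
#' @export
aggregate_peptides <- function(peptides, annotation) {
  peptides <- tibble::as_tibble(peptides)
  need <- c("peptide", "protein", "run", "intensity")
  if (!all(need %in% names(peptides))) {
    abort_input("peptide table must have columns: %s",
                paste(need, collapse = ", "))
  }
  shared <- peptides |>
    dplyr::distinct(.data$peptide, .data$protein) |>
    dplyr::count(.data$peptide) |>
    dplyr::filter(.data$n > 1)
  if (nrow(shared) > 0) {
    message(sprintf("dropping %d peptide(s) shared between proteins",
                    nrow(shared)))
    peptides <- dplyr::filter(peptides, !.data$peptide %in% shared$peptide)
  }
  agg <- peptides |>
    dplyr::filter(!is.na(.data$intensity)) |>
    dplyr::group_by(.data$protein, .data$run) |>
    dplyr::summarise(intensity = sum(.data$intensity),
                     psm = if ("psm" %in% names(peptides))
                       sum(.data$psm) else NA_real_,
                     .groups = "drop")
  runs <- tibble::as_tibble(annotation)$run
  prots <- sort(unique(agg$protein))
  intens <- matrix(NA_real_, length(prots), length(runs),
                   dimnames = list(prots, runs))
  intens[cbind(match(agg$protein, prots), match(agg$run, runs))] <-
    agg$intensity
  psm <- NULL
  if ("psm" %in% names(peptides)) {
    psm <- matrix(0, length(prots), length(runs),
                  dimnames = list(prots, runs))
    psm[cbind(match(agg$protein, prots), match(agg$run, runs))] <- agg$psm
  }
  lfq_matrix(intens, annotation, psm = psm)
}

#' Median-normalize runs
#'
#' Rescales each run multiplicatively so that every run's median observed
#' intensity equals the median of the original per-run medians. Missing
#' entries are untouched; within-run intensity ranks are preserved.
#'
#' @param mat An `lfq_matrix` at stage `"raw"`.
#' @return An `lfq_matrix` at stage `"normalized"`.
#' @export
normalize_median <- function(mat) {
  stopifnot(inherits(mat, "lfq_matrix"))
  require_stage(mat, "raw", "normalize_median")
  meds <- apply(mat$intensities, 2, median, na.rm = TRUE)
  if (any(!is.finite(meds))) {
    abort_input("run(s) with no observed intensities: %s",
                paste(colnames(mat$intensities)[!is.finite(meds)],
                      collapse = ", "))
  }
  target <- median(meds)
  mat$intensities <- sweep(mat$intensities, 2, target / meds, `*`)
  mat$stage <- "normalized"
  mat
}

#' Replace missing values by a low run-level quantile
#'
#' Each run's missing entries are replaced by the `q` quantile (linear
#' interpolation between order statistics, R's default type 7) of that
#' run's observed intensities -- the classical left-censoring surrogate for
#' values lost below the detection limit. The pre-imputation missingness
#' pattern is kept in the `detected` element for downstream
#' replicate-count filters.
#'
#' @param mat An `lfq_matrix` at stage `"normalized"`.
#' @param q Quantile in (0, 1); default 0.05.
#' @return An `lfq_matrix` at stage `"imputed"` with no missing entries.
#' @export
impute_quantile <- function(mat, q = 0.05) {
  stopifnot(inherits(mat, "lfq_matrix"))
  require_stage(mat, c("normalized", "imputed"), "impute_quantile")
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort_input("q must lie strictly in (0, 1)")
  }
  if (is.null(mat$detected)) mat$detected <- !is.na(mat$intensities)
  for (j in seq_len(ncol(mat$intensities))) {
    col <- mat$intensities[, j]
    miss <- is.na(col)
    if (any(miss)) {
      mat$intensities[miss, j] <- quantile(col[!miss], probs = q,
                                           names = FALSE)
    }
  }
  mat$stage <- "imputed"
  mat
}

#' log2-transform intensities
#'
#' @param mat An `lfq_matrix` at stage `"imputed"` (or `"normalized"` when
#'   imputation is deliberately skipped on complete data).
#' @return An `lfq_matrix` at stage `"log2"`.
#' @export
log2_transform <- function(mat) {
  stopifnot(inherits(mat, "lfq_matrix"))
  require_stage(mat, c("imputed", "normalized"), "log2_transform")
  if (anyNA(mat$intensities)) {
    abort_input("log2_transform requires complete data; impute first")
  }
  if (is.null(mat$detected)) mat$detected <- !is.na(mat$intensities)
  mat$intensities <- log2(mat$intensities)
  mat$stage <- "log2"
  mat
}

#' Average technical replicates
#'
#' Arithmetic mean, in log2 space, of the technical (injection) replicates
#' of each biological sample. PSM counts are averaged the same way; the
#' pre-imputation detection matrix is collapsed to "observed in any
#' technical replicate".
#'
#' @param mat An `lfq_matrix` at stage `"log2"`.
#' @return An `lfq_matrix` at stage `"averaged"` with one column per
#'   biological sample (`condition`, `compartment`, `bio_rep`).
#' @export
average_technical <- function(mat) {
  stopifnot(inherits(mat, "lfq_matrix"))
  require_stage(mat, "log2", "average_technical")
  ann <- mat$annotation
  key <- paste(ann$condition, ann$compartment, ann$bio_rep, sep = ".")
  groups <- split(seq_along(key), key)
  avg <- vapply(groups, function(idx)
    rowMeans(mat$intensities[, idx, drop = FALSE]),
    numeric(nrow(mat$intensities)))
  rownames(avg) <- rownames(mat$intensities)
  new_ann <- ann |>
    dplyr::distinct(.data$condition, .data$compartment, .data$bio_rep) |>
    dplyr::mutate(run = paste(.data$condition, .data$compartment,
                              .data$bio_rep, sep = "."),
                  tech_rep = NA_integer_)
  new_ann <- new_ann[match(colnames(avg), new_ann$run), ]
  out <- lfq_matrix(avg, new_ann, stage = "averaged")
  if (!is.null(mat$psm)) {
    out$psm <- vapply(groups, function(idx)
      rowMeans(mat$psm[, idx, drop = FALSE]),
      numeric(nrow(mat$psm)))
    rownames(out$psm) <- rownames(mat$intensities)
  }
  det <- mat$detected
  if (is.null(det)) det <- !is.na(mat$intensities)
  out$detected <- vapply(groups, function(idx)
    rowSums(det[, idx, drop = FALSE]) > 0,
    logical(nrow(det)))
  rownames(out$detected) <- rownames(mat$intensities)
  out
}
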