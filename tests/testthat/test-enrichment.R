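averaged_matrix <- function(values1, values2, protein_rows = 1) {
  # build an averaged-stage lfq_matrix with the given per-group log2 values
  n1 <- length(values1[[1]]); n2 <- length(values2[[1]])
  ann <- tibble::tibble(
    run = c(sprintf("hyp.nuc.%d", 1:n1), sprintf("nor.nuc.%d", 1:n2)),
    condition = rep(c("hypoxia", "normoxia"), c(n1, n2)),
    compartment = "nucleus",
    bio_rep = c(1:n1, 1:n2), tech_rep = NA_integer_)
  intens <- cbind(do.call(rbind, values1), do.call(rbind, values2))
  rownames(intens) <- sprintf("P%d", seq_len(nrow(intens)))
  colnames(intens) <- ann$run
  lfq_matrix(intens, ann, stage = "averaged")
}

nuc_spec <- comparison_spec("hyp_vs_nor", c("hypoxia", "nucleus"),
                            c("normoxia", "nucleus"))

test_that("pooled t-test matches the closed form and its symmetries", {
  mat <- averaged_matrix(list(c(1, 2, 3)), list(c(2, 3, 4)))
  res <- test_enrichment(mat, nuc_spec)
  oracle <- pooled_t_oracle(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, oracle$t, tolerance = 1e-6)
  expect_equal(res$t, -1.224745, tolerance = 1e-5)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-6)
  expect_equal(res$p_value, 0.2879, tolerance = 1e-3)
  expect_equal(res$log2_fc, -1)

  # identical groups: FC 0, p 1, not enriched
  same <- test_enrichment(averaged_matrix(list(c(5, 6, 7)),
                                          list(c(5, 6, 7))), nuc_spec)
  expect_equal(same$log2_fc, 0)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$enriched)

  # swapping groups flips the fold change, not the p-value
  flipped_spec <- comparison_spec("nor_vs_hyp", c("normoxia", "nucleus"),
                                  c("hypoxia", "nucleus"))
  flipped <- test_enrichment(mat, flipped_spec)
  expect_equal(flipped$log2_fc, -res$log2_fc)
  expect_equal(flipped$p_value, res$p_value)
})

test_that("pooled t agrees with the closed form on random data", {
  set.seed(19)
  for (i in 1:5) {
    x <- rnorm(4, 10, 1); y <- rnorm(3, 11, 1)
    mat <- averaged_matrix(list(x), list(y))
    res <- test_enrichment(mat, nuc_spec)
    oracle <- pooled_t_oracle(x, y)
    expect_equal(res$t, oracle$t, tolerance = 1e-8)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-8)
  }
})

test_that("enrichment flag needs both |log2FC| > 1 and p < 0.05", {
  big_shift <- averaged_matrix(list(c(10, 10.1, 9.9, 10)),
                               list(c(12, 12.1, 11.9, 12)))
  res <- test_enrichment(big_shift, nuc_spec)
  expect_true(res$enriched)
  small_shift <- averaged_matrix(list(c(10, 10.1, 9.9, 10)),
                                 list(c(10.5, 10.6, 10.4, 10.5)))
  expect_false(test_enrichment(small_shift, nuc_spec)$enriched)
})

test_that("confidence filters apply strict PSM and replicate rules", {
  mat <- averaged_matrix(list(c(10, 10.2, 9.8)), list(c(13, 13.2, 12.8)))
  res <- test_enrichment(mat, nuc_spec)
  expect_true(res$enriched)

  with_meta <- function(psm_total, nd1, nd2) {
    r <- res
    r$psm_total <- psm_total
    r$n_detected_g1 <- nd1
    r$n_detected_g2 <- nd2
    apply_confidence_filters(r)
  }
  expect_false(with_meta(4, 3, 3)$significant_after_filters)   # PSM > 4 strict
  expect_true(with_meta(5, 3, 3)$significant_after_filters)
  expect_false(with_meta(10, 1, 1)$significant_after_filters)  # < 2 bio reps
  expect_true(with_meta(10, 2, 0)$significant_after_filters)   # one group enough
})

test_that("volcano coordinates use -log10 p with thresholds recorded", {
  mat <- averaged_matrix(list(c(10, 10.2, 9.8)), list(c(13, 13.2, 12.8)))
  res <- apply_confidence_filters(test_enrichment(mat, nuc_spec))
  vd <- volcano_data(res)
  expect_equal(vd$neglog10_p, -log10(res$p_value))
  expect_equal(attr(vd, "p_line"), -log10(0.05))
  expect_equal(attr(vd, "p_line"), 1.30103, tolerance = 1e-5)
  expect_equal(attr(vd, "fc_line"), 1)
  expect_equal(vd$significant_after_filters, res$significant_after_filters)
})

test_that("full pipeline recovers spiked proteins and only them as a set", {
  spiked <- tibble::tibble(protein = 1:6, condition = "hypoxia",
                           compartment = "nucleus", log2_fc = 2)
  sim <- simulate_lfq(sim_lfq_config(n_proteins = 150, seed = 29,
                                     spiked = spiked))
  enr <- run_enrichment(sim$lfq)
  nuc <- dplyr::filter(enr, comparison == "nucleus_hypoxia_vs_normoxia")
  hits <- nuc$protein[nuc$significant_after_filters]
  expect_true(all(sim$truth$protein %in% hits))
  expect_lt(length(setdiff(hits, sim$truth$protein)), 5)
  # spiked effect should not bleed into the cytoplasm comparison
  cyt <- dplyr::filter(enr, comparison == "cytoplasm_hypoxia_vs_normoxia",
                       protein %in% sim$truth$protein)
  expect_true(all(abs(cyt$log2_fc) < 1))
})

test_that("paraspeckle overlap counts come from the packaged annotation", {
  tab <- paraspeckle_components()
  expect_equal(nrow(tab), 40)
  overlap <- annotate_paraspeckle(tab, mode = "fixture")
  expect_equal(overlap$n_present, 22)
  expect_equal(overlap$n_total, 40)
  expect_equal(overlap$n_itaf_present, 6)

  empty <- annotate_paraspeckle(tab[0, ], mode = "fixture")
  expect_equal(unlist(empty[1, 1:3], use.names = FALSE), c(0, 0, 0))

  all_yes <- dplyr::mutate(tab, presence_in_ms = "Yes")
  expect_equal(annotate_paraspeckle(all_yes, mode = "fixture")$n_present, 40)
})

test_that("analysis-mode overlap honours alternative names case-insensitively", {
  tab <- paraspeckle_components()
  res <- annotate_paraspeckle(tab, identified = c("NONO", "sfpq", "FUS"),
                              mode = "analysis")
  expect_equal(res$n_present, 3)   # NONO matches p54nrb via alternative name
  expect_equal(res$n_itaf_present, 3)
  dup <- dplyr::bind_rows(tab, tab[1, ])
  expect_error(annotate_paraspeckle(dup, mode = "fixture"), "duplicate")
})
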