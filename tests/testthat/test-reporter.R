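plate_fixture <- function(lucR, lucF, bg_lucR = 500, bg_lucF = 400,
                          n_bg = 2) {
  n <- length(lucR)
  dplyr::bind_rows(
    tibble::tibble(well = sprintf("W%02d", seq_len(n)), construct = "FGF1",
                   condition = "normoxia", bio_rep = 1L,
                   tech_rep = seq_len(n), lucR = lucR, lucF = lucF,
                   is_background = FALSE),
    tibble::tibble(well = sprintf("B%02d", seq_len(n_bg)),
                   construct = NA, condition = NA,
                   bio_rep = NA, tech_rep = NA,
                   lucR = bg_lucR, lucF = bg_lucF, is_background = TRUE))
}

test_that("background subtraction removes the plate mean per channel", {
  out <- subtract_background(plate_fixture(10000, 1900))
  expect_equal(out$lucR, 9500)
  expect_equal(out$lucF, 1500)
  expect_true(out$valid)
  # reading at the background level is invalidated, not clamped
  flat <- subtract_background(plate_fixture(500, 400))
  expect_false(flat$valid)
  # no background wells: error unless explicitly skipped
  naked <- dplyr::filter(plate_fixture(10000, 1900), !is_background)
  expect_error(subtract_background(naked), "no background")
  skipped <- subtract_background(naked, no_background = TRUE)
  expect_equal(skipped$lucR, 10000)
})

test_that("IRES activity is the mean technical LucF/LucR ratio", {
  out <- subtract_background(
    plate_fixture(c(9500, 9500, 9500) + 500, c(950, 1900, 2850) + 400))
  act <- ires_activity(out)
  expect_equal(act$ratio, mean(c(0.1, 0.2, 0.3)))
  expect_equal(act$n_tech, 3)
  # a common per-well gain cancels in the ratio
  gained <- subtract_background(
    plate_fixture(3 * 9500 + 500, 3 * 1900 + 400))
  expect_equal(ires_activity(gained)$ratio, 0.2)
  # invalid wells are excluded with a message
  mixed <- subtract_background(plate_fixture(c(10000, 500), c(1900, 400)))
  expect_message(act2 <- ires_activity(mixed), "invalid")
  expect_equal(act2$n_tech, 1)
})

test_that("normalization sets the reference-group mean exactly to 1", {
  act <- tibble::tibble(construct = "FGF1",
                        condition = rep(c("normoxia", "hypoxia"), c(3, 1)),
                        bio_rep = c(1:3, 1), n_tech = 3,
                        ratio = c(2, 2, 2, 4))
  norm <- normalize_to_reference(act, list(condition = "normoxia"))
  expect_equal(norm$normalized_ratio[norm$condition == "hypoxia"], 2)
  expect_equal(mean(norm$normalized_ratio[norm$condition == "normoxia"]), 1)
  expect_error(normalize_to_reference(act, list(condition = "anoxia")),
               "empty")
})

test_that("noise-free simulated plates recover configured activities exactly", {
  truth <- tidyr::expand_grid(construct = c("FGF1", "hairpin"),
                              condition = c("normoxia", "hypoxia"))
  truth$ratio <- c(0.2, 0.5, 0.01, 0.01)
  sim <- simulate_plate(sim_plate_config(true_ires_activity = truth,
                                         gain_cv = 0, background_sd = 0,
                                         n_bio = 3, seed = 14))
  act <- ires_activity(subtract_background(sim$readings))
  merged <- dplyr::inner_join(act, truth, by = c("construct", "condition"))
  expect_equal(merged$ratio.x, merged$ratio.y, tolerance = 1e-12)
  # doubling the LucR scale leaves recovered ratios unchanged
  sim2 <- simulate_plate(sim_plate_config(true_ires_activity = truth,
                                          lucR_scale = 20000, gain_cv = 0,
                                          background_sd = 0, n_bio = 3,
                                          seed = 14))
  act2 <- ires_activity(subtract_background(sim2$readings))
  expect_equal(act2$ratio, act$ratio, tolerance = 1e-12)
  # normalization to normoxia recovers the true activation factor
  norm <- normalize_to_reference(
    dplyr::filter(act, construct == "FGF1"), list(condition = "normoxia"))
  expect_equal(norm$normalized_ratio[norm$condition == "hypoxia"],
               rep(2.5, 3), tolerance = 1e-12)
})

test_that("noisy plates recover the truth within Monte-Carlo error", {
  truth <- tidyr::expand_grid(construct = "FGF1",
                              condition = c("normoxia", "hypoxia"))
  truth$ratio <- c(0.2, 0.4)
  sim <- simulate_plate(sim_plate_config(constructs = "FGF1",
                                         true_ires_activity = truth,
                                         gain_cv = 0.1, n_bio = 9,
                                         seed = 25))
  act <- ires_activity(subtract_background(sim$readings))
  per_cond <- act |>
    dplyr::group_by(condition) |>
    dplyr::summarise(m = mean(ratio), sem = sd(ratio) / sqrt(dplyr::n()))
  merged <- dplyr::inner_join(per_cond, truth, by = "condition")
  expect_true(all(abs(merged$m - merged$ratio) <= 3 * merged$sem))
})

test_that("Mann-Whitney is exact without ties and matches enumeration", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, enumerate_mw_p(c(1, 2, 3), c(4, 5, 6)))
  # symmetry in the argument order
  swap <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$p_value, res$p_value)
  expect_equal(swap$U, 9)  # U_A + U_B = n1 * n2
  # complete ties give p = 1 under the tie-corrected approximation
  expect_equal(mann_whitney(rep(1, 5), rep(1, 5))$p_value, 1)
  expect_match(mann_whitney(rep(1, 5), rep(1, 5))$method, "tie")
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p equals full enumeration for n1, n2 <= 5", {
  set.seed(55)
  for (n1 in 3:5) for (n2 in 3:5) {
    for (rep in 1:3) {
      a <- sample(seq(1, 100), n1)
      b <- sample(seq(1, 100) + 0.5, n2)  # offset grid: no ties
      expect_equal(mann_whitney(a, b)$p_value, enumerate_mw_p(a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("group comparison wrapper selects the right replicate values", {
  act <- tibble::tibble(construct = "FGF1",
                        condition = rep(c("normoxia", "hypoxia"), each = 4),
                        bio_rep = rep(1:4, 2), n_tech = 3,
                        ratio = c(1.1, 1.3, 1.2, 1.4, 2.1, 2.3, 2.2, 2.4))
  res <- compare_groups(act, list(condition = "hypoxia"),
                        list(condition = "normoxia"))
  expect_equal(res$n_a, 4)
  expect_equal(res$U, 16)   # complete separation
  expect_equal(res$p_value,
               enumerate_mw_p(act$ratio[5:8], act$ratio[1:4]))
})
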