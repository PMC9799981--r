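test_that("blank images produce no nuclei and no spots", {
  blank <- image_stack(list(DAPI = matrix(0, 32, 32),
                            Cy3 = matrix(0, 32, 32)))
  expect_warning(mask <- segment_nuclei(blank), "flat")
  expect_equal(nrow(mask$areas), 0)
  spots <- detect_spots(blank, "Cy3", threshold = 5)
  expect_equal(nrow(spots), 0)
  expect_error(count_foci(spots, mask), "no nuclei")
})

test_that("disjoint synthetic nuclei are segmented one label each", {
  img <- matrix(0, 150, 150)
  centers <- expand.grid(x = c(25, 75, 125), y = c(30, 100))
  for (k in seq_len(nrow(centers))) {
    for (i in 1:150) {
      d2 <- (i - centers$x[k])^2 + ((1:150) - centers$y[k])^2
      img[i, ] <- img[i, ] + 100 * (d2 <= 12^2)
    }
  }
  mask <- segment_nuclei(image_stack(list(DAPI = img)), min_area = 50)
  expect_equal(nrow(mask$areas), nrow(centers))
  expect_equal(sort(unique(as.vector(mask$labels))),
               0:nrow(centers))
})

test_that("touching nuclei are declumped by the watershed step", {
  img <- matrix(0, 80, 80)
  for (ctr in list(c(40, 28), c(40, 52))) {  # two disks, 24 px apart
    for (i in 1:80) {
      d2 <- (i - ctr[1])^2 + ((1:80) - ctr[2])^2
      img[i, ] <- pmax(img[i, ], 100 * (d2 <= 13^2))
    }
  }
  merged <- segment_nuclei(image_stack(list(DAPI = img)), declump = FALSE)
  expect_equal(nrow(merged$areas), 1)  # they touch: one component
  split <- segment_nuclei(image_stack(list(DAPI = img)), declump = TRUE)
  expect_equal(nrow(split$areas), 2)
})

test_that("LoG detection localizes single and paired spots", {
  one <- make_spot_field(matrix(c(20, 20), ncol = 2))
  spots <- detect_spots(one, "FISH", sigma = 1.5, threshold = 50)
  expect_equal(nrow(spots), 1)
  expect_lt(sqrt((spots$x - 20)^2 + (spots$y - 20)^2), 1)
  # agreement with a direct-convolution oracle
  oracle <- direct_log_argmax(get_channel(one, "FISH"), 1.5)
  expect_lt(sqrt((spots$x - oracle[1])^2 + (spots$y - oracle[2])^2), 1)

  two <- make_spot_field(matrix(c(20, 20, 20, 30), ncol = 2, byrow = TRUE))
  spots2 <- detect_spots(two, "FISH", sigma = 1.5, threshold = 50)
  expect_equal(nrow(spots2), 2)
})

test_that("detection is equivariant under integer translation", {
  base <- matrix(c(15, 15, 30, 40), ncol = 2, byrow = TRUE)
  shift <- c(7, 5)
  a <- detect_spots(make_spot_field(base), "FISH", threshold = 50)
  b <- detect_spots(make_spot_field(sweep(base, 2, shift, `+`)),
                    "FISH", threshold = 50)
  a <- a[order(a$x), ]; b <- b[order(b$x), ]
  expect_equal(b$x, a$x + shift[1], tolerance = 1e-8)
  expect_equal(b$y, a$y + shift[2], tolerance = 1e-8)
})

test_that("lowering the threshold never loses spots", {
  img <- make_spot_field(matrix(c(20, 20, 40, 45), ncol = 2, byrow = TRUE),
                         noise_sd = 10, seed = 31)
  n_prev <- -1
  for (thr in c(80, 50, 25, 10)) {
    n <- nrow(detect_spots(img, "FISH", threshold = thr))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("non-positive sigma and missing channels are rejected", {
  img <- make_spot_field(matrix(c(10, 10), ncol = 2))
  expect_error(detect_spots(img, "FISH", sigma = 0, threshold = 5), "sigma")
  expect_error(detect_spots(img, "Cy5", threshold = 5), "not present")
})

test_that("foci statistics average over all cells including empty ones", {
  labels <- matrix(0L, 20, 60)
  for (k in 1:10) labels[9:12, (k * 6 - 4):(k * 6 - 2)] <- k
  mask <- speckletools:::new_nucleus_mask(labels)
  # 2 of 10 nuclei hold one spot each; one extra spot outside any nucleus
  spots <- tibble::tibble(x = c(10, 10, 1), y = c(8, 14, 1),
                          cell = c(1L, 2L, 0L))
  fs <- count_foci(spots, mask)
  expect_equal(fs$mean_foci, 0.2)
  expect_equal(fs$fraction_positive, 0.2)
  one <- speckletools:::new_nucleus_mask(matrix(1L, 5, 5))
  fs1 <- count_foci(tibble::tibble(x = c(2, 3, 4), y = c(2, 3, 4),
                                   cell = c(1L, 1L, 1L)), one)
  expect_equal(fs1$mean_foci, 3)
  expect_equal(fs1$fraction_positive, 1)
})

test_that("greedy colocalization pairs identical sets completely", {
  a <- tibble::tibble(x = c(3, 9, 20), y = c(4, 9, 6))
  res <- colocalize(a, a, max_dist = 0.1)
  expect_equal(res$n_pairs, 3)
  expect_true(all(res$pairs$distance == 0))
  far <- dplyr::mutate(a, x = x + 50)
  expect_equal(colocalize(a, far, max_dist = 1)$n_pairs, 0)
})

test_that("colocalization count is symmetric and each spot pairs at most once", {
  set.seed(41)
  a <- tibble::tibble(x = runif(12, 0, 30), y = runif(12, 0, 30))
  b <- tibble::tibble(x = runif(9, 0, 30), y = runif(9, 0, 30))
  ab <- colocalize(a, b, max_dist = 4)
  ba <- colocalize(b, a, max_dist = 4)
  expect_equal(ab$n_pairs, ba$n_pairs)
  expect_false(any(duplicated(ab$pairs$idA)))
  expect_false(any(duplicated(ab$pairs$idB)))
  expect_true(all(ab$pairs$distance <= 4))
  expect_lte(ab$n_pairs, min(nrow(a), nrow(b)))
})

test_that("greedy matching equals exhaustive minimum matching on separated instances", {
  # an ambiguous-neighbour instance: B1 between A1 and A2
  a <- tibble::tibble(x = c(0, 3, 10), y = c(0, 0, 0))
  b <- tibble::tibble(x = c(1.4, 10.2), y = c(0, 0))
  res <- colocalize(a, b, max_dist = 2)
  oracle <- brute_force_matching(a$x, a$y, b$x, b$y, max_dist = 2)
  expect_equal(res$n_pairs, oracle$count)
  expect_equal(sum(res$pairs$distance), oracle$total, tolerance = 1e-9)
})

test_that("max-dist conversion uses the physical pixel size", {
  a <- tibble::tibble(x = c(0), y = c(0))
  b <- tibble::tibble(x = c(2), y = c(0))      # 2 px apart
  expect_equal(colocalize(a, b, max_dist = 0.3,
                          pixel_size = 0.1)$n_pairs, 1)
  expect_equal(colocalize(a, b, max_dist = 0.3,
                          pixel_size = 0.2)$n_pairs, 0)
})
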