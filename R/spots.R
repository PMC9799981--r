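#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing, Otsu thresholding, hole filling and
#' distance-transform watershed declumping, followed by removal of
#' components below `min_area`. This is the standard recipe for separating
#' touching interphase nuclei in widefield/confocal fields.
#'
#' @param img An [image_stack()] (3D stacks are maximum-intensity
#'   projected).
#' @param channel Nuclear stain channel, default `"DAPI"`.
#' @param min_area Minimum retained nucleus area in pixels.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels.
#' @param declump Split touching nuclei by watershed on the distance
#'   transform.
#' @return A `nucleus_mask`: list with `labels` (integer matrix, 0 =
#'   background, k = nucleus k with contiguous labels) and `areas`
#'   (tibble `cell`, `area`).
#' @examples
#' sim <- simulate_images(sim_image_config(seed = 2))
#' mask <- segment_nuclei(sim$fields[[1]])
#' mask$areas
#' @export
segment_nuclei <- function(img, channel = "DAPI", min_area = 50,
                           smooth_sigma = 2, declump = TRUE) {
  m <- get_channel(img, channel)
  if (max(m) - min(m) < .EPS) {
    warning("nuclear channel is flat; returning an empty mask")
    return(new_nucleus_mask(matrix(0L, nrow(m), ncol(m))))
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = smooth_sigma))
  norm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  binary <- norm > thr
  binary <- as.matrix(EBImage::fillHull(EBImage::Image(binary))) > 0
  if (!any(binary)) {
    warning("no foreground after thresholding; returning an empty mask")
    return(new_nucleus_mask(matrix(0L, nrow(m), ncol(m))))
  }
  if (declump) {
    dm <- EBImage::distmap(EBImage::Image(binary))
    labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(binary)))
  }
  labels <- matrix(as.integer(labels), nrow(m), ncol(m))
  # drop small components, relabel 1..K
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= min_area)
  remap <- integer(length(tab))
  remap[keep] <- seq_along(keep)
  labels[labels > 0] <- remap[labels[labels > 0]]
  new_nucleus_mask(labels)
}

new_nucleus_mask <- function(labels) {
  n <- max(labels)
  areas <- if (n > 0) {
    tibble::tibble(cell = seq_len(n), area = tabulate(labels[labels > 0], n))
  } else {
    tibble::tibble(cell = integer(), area = integer())
  }
  structure(list(labels = labels, areas = areas), class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> %d x %d px, %d nuclei\n",
              nrow(x$labels), ncol(x$labels), nrow(x$areas)))
  invisible(x)
}

# zero-sum negated LoG kernel, amplitude-calibrated: the response to an
# isotropic Gaussian spot of matching sigma equals the spot's peak amplitude
log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  ax <- -r:r
  d2 <- outer(ax^2, ax^2, `+`)
  k <- (d2 - 2 * sigma^2) / sigma^4 * exp(-d2 / (2 * sigma^2))
  k <- k - mean(k)        # flat background maps to exactly 0
  k <- -k                 # bright blobs give positive responses
  k / sum(k * exp(-d2 / (2 * sigma^2)))
}

#' Laplacian-of-Gaussian blob response
#'
#' Convolves a channel with a zero-sum negated LoG kernel so bright
#' diffraction-limited spots appear as positive peaks. The kernel is
#' calibrated so that a Gaussian spot whose width matches `sigma` responds
#' with its own peak amplitude; detection thresholds are therefore on the
#' intensity scale of the image.
#'
#' @param m Numeric matrix.
#' @param sigma Kernel scale in pixels.
#' @return Response matrix of the same size.
#' @export
log_response <- function(m, sigma) {
  if (sigma <= 0) abort_input("sigma must be > 0")
  as.matrix(EBImage::filter2(EBImage::Image(m), log_kernel(sigma),
                             boundary = "replicate"))
}

# 8-connected neighborhood maximum via shifted copies
neighborhood_max <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(-Inf, nr, nc)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    out <- pmax(out, pad[(2 + dx):(nr + 1 + dx), (2 + dy):(nc + 1 + dy)])
  }
  out
}

#' Detect diffraction-limited spots
#'
#' Spots are local maxima (8-connectivity) of the Laplacian-of-Gaussian
#' response above `threshold`. Plateaus of equal response are collapsed to
#' their centroid. Each spot is assigned the label of the nucleus containing
#' it (0 when outside every nucleus or when no mask is given); cytoplasmic
#' spots are therefore retained but distinguishable.
#'
#' @param img An [image_stack()] (3D stacks are maximum-intensity
#'   projected before detection).
#' @param channel FISH channel to analyze.
#' @param sigma LoG scale in pixels (default 1.5, about one PSF width).
#' @param threshold Minimum LoG response retained.
#' @param mask Optional [segment_nuclei()] result used for cell assignment.
#' @return Tibble with columns `x`, `y` (1-based pixel coordinates, may be
#'   fractional for plateaus), `response`, `channel`, `cell`.
#' @examples
#' sim <- simulate_images(sim_image_config(seed = 3, noise_sd = 0))
#' spots <- detect_spots(sim$fields[[1]], "Cy3", threshold = 20)
#' nrow(spots)
#' @export
detect_spots <- function(img, channel, sigma = 1.5, threshold, mask = NULL) {
  if (sigma <= 0) abort_input("sigma must be > 0")
  if (missing(threshold) || !is.numeric(threshold)) {
    abort_input("'threshold' (minimum LoG response) is required")
  }
  m <- get_channel(img, channel)
  resp <- log_response(m, sigma)
  cand <- (resp >= neighborhood_max(resp)) & (resp > threshold)
  if (!any(cand)) {
    return(tibble::tibble(x = numeric(), y = numeric(),
                          response = numeric(),
                          channel = character(), cell = integer()))
  }
  # plateau handling: connected candidate pixels collapse to one centroid
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand)))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  xs <- tapply(idx[, 1], comp, mean)
  ys <- tapply(idx[, 2], comp, mean)
  rs <- tapply(resp[lab > 0], comp, max)
  spots <- tibble::tibble(x = as.numeric(xs), y = as.numeric(ys),
                          response = as.numeric(rs),
                          channel = channel)
  spots$cell <- assign_to_nuclei(spots, mask, dim(m))
  spots
}

assign_to_nuclei <- function(spots, mask, dims) {
  if (is.null(mask)) return(rep(0L, nrow(spots)))
  stopifnot(inherits(mask, "nucleus_mask"))
  i <- pmin(pmax(round(spots$x), 1), dims[1])
  j <- pmin(pmax(round(spots$y), 1), dims[2])
  as.integer(mask$labels[cbind(i, j)])
}

#' Per-cell focus counts
#'
#' Counts detected spots per segmented nucleus, including nuclei with zero
#' foci, and summarizes the mean foci per cell and the fraction of cells
#' harboring at least one focus. Spots outside every nucleus (cell 0) are
#' excluded from the statistics.
#'
#' @param spots Spot tibble from [detect_spots()] with a `cell` column
#'   assigned against `mask`.
#' @param mask The [segment_nuclei()] result the spots were assigned to.
#' @return A `foci_summary`: list with `per_cell` (tibble `cell`,
#'   `n_foci`), `mean_foci`, `fraction_positive`, `n_cells`.
#' @export
count_foci <- function(spots, mask) {
  stopifnot(inherits(mask, "nucleus_mask"))
  n_cells <- nrow(mask$areas)
  if (n_cells == 0) abort_input("mask contains no nuclei to normalize by")
  assigned <- spots$cell[spots$cell > 0]
  counts <- tabulate(assigned, nbins = n_cells)
  structure(list(
    per_cell = tibble::tibble(cell = seq_len(n_cells), n_foci = counts),
    mean_foci = sum(counts) / n_cells,
    fraction_positive = mean(counts >= 1),
    n_cells = n_cells
  ), class = "foci_summary")
}

#' @export
print.foci_summary <- function(x, ...) {
  cat(sprintf(
    "<foci_summary> %d cells, %.3g foci/cell, %.1f%% cells with >= 1 focus\n",
    x$n_cells, x$mean_foci, 100 * x$fraction_positive))
  invisible(x)
}

#' Two-channel spot colocalization
#'
#' Greedy one-to-one nearest-neighbour matching: candidate pairs within
#' `max_dist` are accepted in increasing distance order, each spot being
#' used at most once. The matched count is symmetric in the argument order.
#'
#' @param spotsA,spotsB Spot tibbles (columns `x`, `y`, optionally `cell`)
#'   from the same field.
#' @param max_dist Maximum pairing distance in micrometers (default 0.3,
#'   about one PSF width).
#' @param pixel_size Micrometers per pixel used to convert pixel distances;
#'   take it from the field's `image_stack` (default 1 leaves distances in
#'   pixel units).
#' @return A `coloc_result`: list with `pairs` (tibble `idA`, `idB`,
#'   `distance` in the same units as `max_dist`), `per_cell` counts (from
#'   the A-spot cell assignment when present), `n_pairs` and `max_dist`.
#' @export
colocalize <- function(spotsA, spotsB, max_dist = 0.3, pixel_size = 1) {
  if (!is.numeric(max_dist) || max_dist < 0) {
    abort_input("max_dist must be a non-negative distance")
  }
  nA <- nrow(spotsA); nB <- nrow(spotsB)
  pairs <- tibble::tibble(idA = integer(), idB = integer(),
                          distance = numeric())
  if (nA > 0 && nB > 0) {
    d <- sqrt(outer(spotsA$x, spotsB$x, `-`)^2 +
              outer(spotsA$y, spotsB$y, `-`)^2) * pixel_size
    cand <- which(d <= max_dist, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      usedA <- logical(nA); usedB <- logical(nB)
      keep <- matrix(integer(0), ncol = 2)
      for (r in seq_len(nrow(cand))) {
        a <- cand[r, 1]; b <- cand[r, 2]
        if (!usedA[a] && !usedB[b]) {
          usedA[a] <- TRUE; usedB[b] <- TRUE
          keep <- rbind(keep, c(a, b))
        }
      }
      pairs <- tibble::tibble(idA = keep[, 1], idB = keep[, 2],
                              distance = d[keep])
    }
  }
  per_cell <- NULL
  if ("cell" %in% names(spotsA) && nrow(pairs) > 0) {
    per_cell <- pairs |>
      dplyr::mutate(cell = spotsA$cell[.data$idA]) |>
      dplyr::count(.data$cell, name = "n_colocalized")
  }
  structure(list(pairs = pairs, per_cell = per_cell,
                 n_pairs = nrow(pairs), max_dist = max_dist),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d pairs within %g\n", x$n_pairs, x$max_dist))
  invisible(x)
}

#' Score detected spots against a ground-truth table
#'
#' Matches detections to true spots with [colocalize()] (one-to-one,
#' within `match_dist` pixels) and reports recall, precision and F1.
#'
#' @param detected,truth Spot tibbles with `x`, `y` columns.
#' @param match_dist Maximum match distance in pixels.
#' @return Tibble with `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`, `f1`.
#' @export
score_detection <- function(detected, truth, match_dist = 2) {
  matched <- colocalize(detected, truth, max_dist = match_dist,
                        pixel_size = 1)$n_pairs
  recall <- if (nrow(truth) > 0) matched / nrow(truth) else NA_real_
  precision <- if (nrow(detected) > 0) matched / nrow(detected) else NA_real_
  f1 <- if (isTRUE(recall + precision > 0)) {
    2 * recall * precision / (recall + precision)
  } else {
    0
  }
  tibble::tibble(n_true = nrow(truth), n_detected = nrow(detected),
                 n_matched = matched, recall = recall,
                 precision = precision, f1 = f1)
}
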