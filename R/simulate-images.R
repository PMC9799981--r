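#' Configuration for synthetic FISH/smiFISH fields
#'
#' Describes simulated microscopy fields: disk-shaped nuclei rendered into a
#' DAPI channel, and diffraction-limited RNA spots (isotropic Gaussian PSF)
#' placed inside nuclei at per-cell Poisson rates in one or two FISH
#' channels. An optional colocalization mechanism places a configurable
#' fraction of second-channel spots within a small offset of first-channel
#' spots, emulating two-color smiFISH of an mRNA and the lncRNA scaffold it
#' is recruited to.
#'
#' @param n_fields Number of fields to simulate.
#' @param image_shape Integer vector `c(rows, cols)` in pixels.
#' @param n_nuclei_per_field Nuclei per field.
#' @param nucleus_radius Nucleus radius in pixels; must be smaller than half
#'   the smallest image dimension.
#' @param spots_per_cell_rate Named numeric vector of per-cell Poisson means,
#'   one entry per FISH channel (e.g. `c(Cy3 = 2)`).
#' @param spot_sigma PSF standard deviation in pixels.
#' @param spot_amplitude Peak spot intensity above background.
#' @param background_level,noise_sd Additive background mean and Gaussian
#'   noise standard deviation (intensity units).
#' @param coloc_fraction Probability that a spot of the second listed channel
#'   is placed within `coloc_offset` of a randomly chosen spot of the first
#'   channel in the same nucleus.
#' @param coloc_offset Maximum placement offset for colocalized spots (px).
#' @param min_spot_separation Minimum center-to-center distance enforced
#'   between same-channel spots in one nucleus (px); 0 disables.
#' @param nucleus_amplitude DAPI intensity of nucleus interiors.
#' @param pixel_size Micrometers per pixel.
#' @param seed Integer seed; all randomness in [simulate_images()] flows
#'   from it.
#' @return A `sim_image_config` list.
#' @export
sim_image_config <- function(n_fields = 1,
                             image_shape = c(128, 128),
                             n_nuclei_per_field = 8,
                             nucleus_radius = 12,
                             spots_per_cell_rate = c(Cy3 = 2),
                             spot_sigma = 1.5,
                             spot_amplitude = 100,
                             background_level = 20,
                             noise_sd = 5,
                             coloc_fraction = 0,
                             coloc_offset = 0.5,
                             min_spot_separation = 0,
                             nucleus_amplitude = 120,
                             pixel_size = 0.107,
                             seed = 1) {
  cfg <- list(n_fields = as.integer(n_fields),
              image_shape = as.integer(image_shape),
              n_nuclei_per_field = as.integer(n_nuclei_per_field),
              nucleus_radius = nucleus_radius,
              spots_per_cell_rate = spots_per_cell_rate,
              spot_sigma = spot_sigma,
              spot_amplitude = spot_amplitude,
              background_level = background_level,
              noise_sd = noise_sd,
              coloc_fraction = coloc_fraction,
              coloc_offset = coloc_offset,
              min_spot_separation = min_spot_separation,
              nucleus_amplitude = nucleus_amplitude,
              pixel_size = pixel_size,
              seed = as.integer(seed))
  validate_sim_image_config(cfg)
  structure(cfg, class = "sim_image_config")
}

validate_sim_image_config <- function(cfg) {
  if (cfg$n_fields < 1) abort_input("n_fields must be >= 1")
  if (length(cfg$image_shape) != 2 || any(cfg$image_shape < 8)) {
    abort_input("image_shape must be c(rows, cols) with both >= 8")
  }
  if (is.null(names(cfg$spots_per_cell_rate)) ||
      any(!nzchar(names(cfg$spots_per_cell_rate)))) {
    abort_input("spots_per_cell_rate must be a named vector (channel names)")
  }
  if (any(cfg$spots_per_cell_rate < 0)) {
    abort_input("spot rates must be >= 0")
  }
  if (cfg$coloc_fraction < 0 || cfg$coloc_fraction > 1) {
    abort_input("coloc_fraction must lie in [0, 1]")
  }
  if (cfg$nucleus_radius >= min(cfg$image_shape) / 2) {
    abort_input("nucleus_radius must be < min(image_shape)/2")
  }
  if (cfg$spot_sigma <= 0) abort_input("spot_sigma must be > 0")
  if (cfg$noise_sd < 0 || cfg$background_level < 0) {
    abort_input("background_level and noise_sd must be >= 0")
  }
  invisible(cfg)
}

# rejection-sample non-overlapping nucleus centers
place_nuclei <- function(shape, n, radius) {
  margin <- radius + 2
  if (2 * margin >= min(shape)) {
    abort_input("image_shape %s too small to contain one nucleus of radius %g",
                paste(shape, collapse = "x"), radius)
  }
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < n && tries < 5000 * n) {
    tries <- tries + 1
    cand <- c(runif(1, margin, shape[1] - margin),
              runif(1, margin, shape[2] - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > 2 * radius + 2)) {
      centers <- rbind(centers, cand)
    }
  }
  if (nrow(centers) < n) {
    abort_input("could not place %d non-overlapping nuclei in a %s field",
                n, paste(shape, collapse = "x"))
  }
  centers
}

# additive rendering of a soft-edged disk (logistic edge profile)
render_disk <- function(img, cx, cy, radius, amplitude, edge = 1.2) {
  r <- ceiling(radius + 5 * edge)
  xs <- max(1, floor(cx - r)):min(nrow(img), ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(ncol(img), ceiling(cy + r))
  dist <- sqrt(outer((xs - cx)^2, (ys - cy)^2, `+`))
  img[xs, ys] <- img[xs, ys] + amplitude / (1 + exp((dist - radius) / edge))
  img
}

# additive rendering of an isotropic Gaussian spot
render_spot <- function(img, cx, cy, sigma, amplitude) {
  r <- ceiling(4 * sigma)
  xs <- max(1, floor(cx - r)):min(nrow(img), ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(ncol(img), ceiling(cy + r))
  d2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
  img[xs, ys] <- img[xs, ys] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

# uniform point in a disk, optionally respecting a minimum separation
sample_in_nucleus <- function(cx, cy, radius, existing = NULL, min_sep = 0) {
  for (i in seq_len(200)) {
    a <- runif(1, 0, 2 * pi)
    r <- (radius - 1) * sqrt(runif(1))
    p <- c(cx + r * cos(a), cy + r * sin(a))
    if (min_sep <= 0 || is.null(existing) || nrow(existing) == 0 ||
        all(sqrt(rowSums(sweep(existing, 2, p)^2)) >= min_sep)) {
      return(p)
    }
  }
  p  # dense nucleus: accept the last draw rather than fail
}

#' Simulate FISH/smiFISH fields with known ground truth
#'
#' Generates `n_fields` multi-channel fields according to a
#' [sim_image_config()]: a DAPI channel holding soft-edged disk nuclei, and
#' one FISH channel per entry of `spots_per_cell_rate` holding Gaussian
#' spots drawn per nucleus from a Poisson distribution. Every spot's
#' subpixel center, channel and owning nucleus are returned as ground truth
#' so detection, per-cell counting and colocalization can be scored without
#' external data.
#'
#' @param config A [sim_image_config()].
#' @return A list with elements
#'   \describe{
#'     \item{fields}{list of [image_stack()] objects, one per field;}
#'     \item{truth}{tibble of true spots (`field`, `channel`, `x`, `y`,
#'       `cell`, `colocalized_with` for paired second-channel spots);}
#'     \item{nuclei}{tibble of nucleus centers and radii (`field`, `cell`,
#'       `cx`, `cy`, `radius`).}
#'   }
#' @examples
#' sim <- simulate_images(sim_image_config(seed = 7))
#' sim$fields[[1]]
#' head(sim$truth)
#' @export
simulate_images <- function(config) {
  stopifnot(inherits(config, "sim_image_config"))
  validate_sim_image_config(config)
  set.seed(config$seed)
  shape <- config$image_shape
  fish_channels <- names(config$spots_per_cell_rate)

  fields <- vector("list", config$n_fields)
  truth <- list()
  nuclei_tab <- list()

  for (f in seq_len(config$n_fields)) {
    centers <- place_nuclei(shape, config$n_nuclei_per_field,
                            config$nucleus_radius)
    dapi <- matrix(0, shape[1], shape[2])
    for (k in seq_len(nrow(centers))) {
      dapi <- render_disk(dapi, centers[k, 1], centers[k, 2],
                          config$nucleus_radius, config$nucleus_amplitude)
    }
    nuclei_tab[[f]] <- tibble::tibble(
      field = f, cell = seq_len(nrow(centers)),
      cx = centers[, 1], cy = centers[, 2],
      radius = config$nucleus_radius
    )

    spot_imgs <- lapply(fish_channels, function(ch) matrix(0, shape[1], shape[2]))
    names(spot_imgs) <- fish_channels
    field_spots <- list()

    for (k in seq_len(nrow(centers))) {
      per_channel <- list()
      for (ci in seq_along(fish_channels)) {
        ch <- fish_channels[ci]
        n_spots <- rpois(1, config$spots_per_cell_rate[[ch]])
        pos <- matrix(numeric(0), ncol = 2)
        coloc_src <- integer(0)
        for (s in seq_len(n_spots)) {
          paired <- NA_integer_
          if (ci == 2L && config$coloc_fraction > 0 &&
              nrow(per_channel[[1]] %||% matrix(numeric(0), ncol = 2)) > 0 &&
              runif(1) < config$coloc_fraction) {
            anchor_i <- sample.int(nrow(per_channel[[1]]), 1)
            anchor <- per_channel[[1]][anchor_i, ]
            a <- runif(1, 0, 2 * pi)
            r <- config$coloc_offset * sqrt(runif(1))
            p <- c(anchor[1] + r * cos(a), anchor[2] + r * sin(a))
            paired <- anchor_i
          } else {
            p <- sample_in_nucleus(centers[k, 1], centers[k, 2],
                                   config$nucleus_radius, pos,
                                   config$min_spot_separation)
          }
          pos <- rbind(pos, p)
          coloc_src <- c(coloc_src, paired)
          spot_imgs[[ch]] <- render_spot(spot_imgs[[ch]], p[1], p[2],
                                         config$spot_sigma,
                                         config$spot_amplitude)
        }
        per_channel[[ci]] <- pos
        if (n_spots > 0) {
          field_spots[[length(field_spots) + 1]] <- tibble::tibble(
            field = f, channel = ch,
            x = pos[, 1], y = pos[, 2], cell = k,
            colocalized_with = coloc_src
          )
        }
      }
    }

    channels <- c(list(DAPI = dapi), spot_imgs)
    channels <- lapply(channels, function(m) {
      m <- m + config$background_level
      if (config$noise_sd > 0) {
        m <- m + matrix(rnorm(length(m), 0, config$noise_sd),
                        nrow(m), ncol(m))
      }
      pmax(m, 0)
    })
    fields[[f]] <- image_stack(channels, pixel_size = config$pixel_size)
    truth[[f]] <- dplyr::bind_rows(field_spots)
  }

  truth_tab <- dplyr::bind_rows(truth)
  if (nrow(truth_tab) == 0) {
    truth_tab <- tibble::tibble(field = integer(), channel = character(),
                                x = numeric(), y = numeric(),
                                cell = integer(),
                                colocalized_with = integer())
  }
  list(fields = fields,
       truth = truth_tab,
       nuclei = dplyr::bind_rows(nuclei_tab))
}
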