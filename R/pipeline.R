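#' Run the full demonstration pipeline
#'
#' Simulates all four assay types with one master seed, runs the matching
#' analysis arms -- spot detection/counting/colocalization, label-free
#' enrichment, polysome-recruitment quantification, reporter statistics --
#' and writes every result as CSV into `outdir` together with a
#' provenance record (package version, seed, parameters). The same stages
#' are exported individually; the orchestrator only wires them together,
#' so standalone and orchestrated runs give identical results for a given
#' seed.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param config Optional named list (or path to a YAML file) overriding
#'   stage parameter blocks `images`, `lfq`, `ct`, `plate`, `spots`
#'   (detection sigma/threshold, colocalization max_dist). Unknown keys
#'   are rejected.
#' @return Invisibly, a named list of the stage results.
#' @export
run_demo <- function(outdir, seed = 1, config = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- load_run_config(config)
  seed <- as.integer(seed)
  stage_seed <- function(k) (seed * 1000L + k) %% .Machine$integer.max

  # imaging arm -------------------------------------------------------
  img_args <- utils::modifyList(
    list(n_fields = 4, n_nuclei_per_field = 8,
         spots_per_cell_rate = c(Cy3 = 2, Cy5 = 2),
         coloc_fraction = 0.5, noise_sd = 5,
         seed = stage_seed(1)),
    cfg$images)
  sim_img <- simulate_images(do.call(sim_image_config, img_args))
  sp <- cfg$spots
  spot_rows <- list()
  coloc_rows <- list()
  foci <- list()
  for (f in seq_along(sim_img$fields)) {
    field <- sim_img$fields[[f]]
    mask <- segment_nuclei(field)
    s3 <- detect_spots(field, "Cy3", sigma = sp$sigma,
                       threshold = sp$threshold, mask = mask)
    s5 <- detect_spots(field, "Cy5", sigma = sp$sigma,
                       threshold = sp$threshold, mask = mask)
    spot_rows[[f]] <- dplyr::mutate(dplyr::bind_rows(s3, s5), field = f)
    fc <- count_foci(s3, mask)
    foci[[f]] <- tibble::tibble(field = f, n_cells = fc$n_cells,
                                mean_foci = fc$mean_foci,
                                fraction_positive = fc$fraction_positive)
    cl <- colocalize(s3, s5, max_dist = sp$max_dist,
                     pixel_size = field$pixel_size)
    coloc_rows[[f]] <- tibble::tibble(field = f, n_pairs = cl$n_pairs)
  }
  spots_tab <- dplyr::bind_rows(spot_rows)
  foci_tab <- dplyr::bind_rows(foci)
  coloc_tab <- dplyr::bind_rows(coloc_rows)

  # proteomics arm ----------------------------------------------------
  lfq_args <- utils::modifyList(
    list(n_proteins = 400,
         spiked = tibble::tibble(protein = 1:10, condition = "hypoxia",
                                 compartment = "nucleus", log2_fc = 2),
         seed = stage_seed(2)),
    cfg$lfq)
  sim_lfq_out <- simulate_lfq(do.call(sim_lfq_config, lfq_args))
  enrich <- run_enrichment(sim_lfq_out$lfq)
  overlap <- annotate_paraspeckle(mode = "fixture")

  # translatome arm ---------------------------------------------------
  ct_args <- utils::modifyList(list(seed = stage_seed(3)), cfg$ct)
  if (is.null(ct_args$true_recruitment_log2fc)) {
    genes <- sim_ct_config()$genes
    ct_args$true_recruitment_log2fc <- tibble::tibble(
      gene = rep(genes$gene[genes$gene != "Gapdh"], 2),
      treatment = rep(c("gapmer_Neat1", "gapmer_Neat1_2"),
                      each = sum(genes$gene != "Gapdh")),
      log2_fc = c(seq(-1, 1, length.out = sum(genes$gene != "Gapdh")),
                  seq(-2, 0.2, length.out = sum(genes$gene != "Gapdh"))))
  }
  sim_ct_out <- simulate_ct(do.call(sim_ct_config, ct_args))
  recr <- recruitment(sim_ct_out$ct)
  class_summary <- summarize_classes(recr)

  # reporter arm ------------------------------------------------------
  plate_args <- utils::modifyList(list(seed = stage_seed(4)), cfg$plate)
  sim_plate_out <- simulate_plate(do.call(sim_plate_config, plate_args))
  activities <- sim_plate_out$readings |>
    subtract_background() |>
    ires_activity() |>
    normalize_to_reference(list(condition = "normoxia"))
  comparison <- compare_groups(activities,
                               list(condition = "hypoxia"),
                               list(condition = "normoxia"),
                               value = "normalized_ratio")

  # outputs -----------------------------------------------------------
  outputs <- list(
    spots = spots_tab, foci = foci_tab, colocalization = coloc_tab,
    enrichment = enrich, paraspeckle_overlap = overlap,
    recruitment = recr, class_summary = class_summary,
    activities = activities, reporter_comparison = comparison)
  for (nm in names(outputs)) {
    write.csv(outputs[[nm]], file.path(outdir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  provenance <- list(package = "speckletools",
                     version = as.character(packageVersion("speckletools")),
                     seed = seed,
                     timestamp = format(Sys.time(), tz = "UTC"),
                     spots = sp)
  jsonlite::write_json(provenance, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outputs)
}

# merge a user config (list or YAML path) over stage defaults
load_run_config <- function(config) {
  defaults <- list(images = list(), lfq = list(), ct = list(),
                   plate = list(),
                   spots = list(sigma = 1.5, threshold = 50,
                                max_dist = 0.3))
  if (is.null(config)) return(defaults)
  if (is.character(config)) {
    if (!file.exists(config)) abort_input("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort_input("unknown config block(s): %s", paste(unknown, collapse = ", "))
  }
  for (nm in names(config)) {
    defaults[[nm]] <- utils::modifyList(defaults[[nm]],
                                        as.list(config[[nm]]))
  }
  defaults
}
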