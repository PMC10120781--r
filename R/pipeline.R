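# Workflow entry points: each wraps the module functions into a
# file-in / file-out run with provenance (config echo, package version,
# seed) written next to the outputs. Configs are plain named lists, or a
# YAML file path; unknown keys are rejected by name.

resolve_config <- function(config, defaults, what) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) abort(sprintf("%s config must be a list or YAML path.", what))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown %s config key(s): %s", what,
                  paste(unknown, collapse = ", ")))
  }
  modifyList(defaults, config)
}

write_provenance <- function(config, out_dir) {
  prov <- list(
    package = "collagenkit",
    version = as.character(packageVersion("collagenkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
}

#' Simulate a cohort and write it to disk
#'
#' @param config List (or YAML path) with keys `out_dir` and `params`
#'   (arguments forwarded to [cohort_params()]).
#' @return Invisibly, the written file paths.
#' @export
run_cohort_simulation <- function(config = list()) {
  cfg <- resolve_config(config, list(out_dir = "cohort_out", params = list()),
                        "simulate-cohort")
  params <- do.call(cohort_params, cfg$params)
  cohort <- generate_cohort(params)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_cohort(cohort, cfg$out_dir)
  write_provenance(cfg, cfg$out_dir)
  inform(sprintf("cohort of %d samples written to %s (seed %d).",
                 params$n_samples, cfg$out_dir, params$seed))
  invisible(paths)
}

#' Run the full expression-ratio survival workflow
#'
#' Reads expression and clinical TSVs, applies the log2(x+1) transform if
#' the input is on the raw scale, runs the purity correlation screen, the
#' ratio features, the dual-ratio quartile classification, survival
#' analysis per endpoint (optionally stratified), and the subtype
#' association tests. Writes `screen.tsv`, `classification.tsv`,
#' `survival.tsv`, `subtype_association.tsv`, KM plot PNGs and a
#' provenance file into `out_dir`.
#'
#' @param config List (or YAML path); keys: `expression_file`,
#'   `clinical_file`, `out_dir`, `expression_scale` ("log2p1" or "raw"),
#'   `ratio_scale` ("log" or "linear"), `endpoints`, `strata`,
#'   `gene_aliases`, `endpoint_aliases`, `plots` (logical).
#' @return Invisibly, a list with the in-memory results (`screen`,
#'   `features`, `labels`, `survival`, `subtypes`).
#' @export
run_ratio_survival <- function(config) {
  defaults <- list(
    expression_file = NULL, clinical_file = NULL, out_dir = "ratio_out",
    expression_scale = "log2p1", ratio_scale = "log",
    endpoints = c("OS", "DSS", "DFS", "PFS"), strata = NULL,
    gene_aliases = as.list(default_ratio_genes),
    endpoint_aliases = list(DFI = "DFS", PFI = "PFS"),
    plots = TRUE
  )
  cfg <- resolve_config(config, defaults, "ratio-survival")
  for (f in c("expression_file", "clinical_file")) {
    if (is.null(cfg[[f]])) abort(sprintf("config key `%s` is required.", f))
    if (!file.exists(cfg[[f]])) abort(sprintf("%s not found: %s", f, cfg[[f]]))
  }
  dat <- read_cohort(cfg$expression_file, cfg$clinical_file,
                     scale = cfg$expression_scale)
  expr <- dat$expression
  if (identical(expr_scale(expr), "raw")) expr <- log2p1_transform(expr)

  screen <- purity_correlation_screen(expr, dat$clinical)
  features <- compute_ratio_features(
    expr, genes = unlist(cfg$gene_aliases), ratio_scale = cfg$ratio_scale)
  labels <- classify_patients(features)
  surv <- survival_by_group(dat$clinical, labels,
                            endpoints = cfg$endpoints, strata = cfg$strata,
                            aliases = unlist(cfg$endpoint_aliases))
  subtypes <- if ("subtype" %in% names(dat$clinical)) {
    subtype_association(labels, dat$clinical)
  } else {
    NULL
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(screen, file.path(cfg$out_dir, "screen.tsv"))
  readr::write_tsv(labels[, c("sample_id", "r1", "r2", "label")],
                   file.path(cfg$out_dir, "classification.tsv"))
  readr::write_tsv(dplyr::select(surv, -"curves", -"test"),
                   file.path(cfg$out_dir, "survival.tsv"))
  if (!is.null(subtypes)) {
    readr::write_tsv(subtypes, file.path(cfg$out_dir, "subtype_association.tsv"))
  }
  if (isTRUE(cfg$plots)) {
    for (i in seq_len(nrow(surv))) {
      if (!length(surv$curves[[i]])) next
      pl <- plot_km_groups(surv$curves[[i]],
                           title = sprintf("%s (%s)", surv$endpoint[i],
                                           surv$stratum[i]))
      ggplot2::ggsave(
        file.path(cfg$out_dir,
                  sprintf("km_%s_%s.png", surv$endpoint[i], surv$stratum[i])),
        pl, width = 6, height = 4, dpi = 120)
    }
  }
  write_provenance(cfg, cfg$out_dir)
  invisible(list(screen = screen, features = features, labels = labels,
                 survival = surv, subtypes = subtypes))
}

#' Batch fiber-architecture metrics over a directory of TIFFs
#'
#' @param config List (or YAML path); keys: `image_dir` or `files`,
#'   `out_dir`, `min_length_px`, `bin_deg`.
#' @return Invisibly, the per-image metrics tibble.
#' @export
run_fiber_metrics <- function(config) {
  defaults <- list(image_dir = NULL, files = NULL, out_dir = "fiber_out",
                   min_length_px = 30, bin_deg = 2)
  cfg <- resolve_config(config, defaults, "fiber-metrics")
  files <- cfg$files
  if (is.null(files)) {
    if (is.null(cfg$image_dir)) abort("give `image_dir` or `files`.")
    files <- list.files(cfg$image_dir, pattern = "\\.tiff?$",
                        full.names = TRUE, ignore.case = TRUE)
  }
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    abort(paste0("missing image file(s): ", paste(missing, collapse = ", ")))
  }
  if (!length(files)) abort("no TIFF files to process.")
  metrics <- summarize_images(files, min_length_px = cfg$min_length_px,
                              bin_deg = cfg$bin_deg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(metrics, file.path(cfg$out_dir, "fiber_metrics.tsv"))
  write_provenance(cfg, cfg$out_dir)
  invisible(metrics)
}

#' Render synthetic fiber fields to TIFFs with ground truth
#'
#' @param config List (or YAML path); keys: `out_dir`, `n_images`,
#'   `params` (forwarded to [fiber_field_params()]; the seed is advanced
#'   by one per image).
#' @return Invisibly, the combined ground-truth tibble.
#' @export
run_fiber_simulation <- function(config = list()) {
  defaults <- list(out_dir = "fiber_sim", n_images = 1, params = list())
  cfg <- resolve_config(config, defaults, "simulate-fibers")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  base <- do.call(fiber_field_params, cfg$params)
  for (i in seq_len(cfg$n_images)) {
    prm <- base
    prm$seed <- base$seed + i - 1L
    field <- render_fiber_field(prm)
    write_image_tiff(field$image,
                     file.path(cfg$out_dir, sprintf("field_%03d.tif", i)))
    truth[[i]] <- dplyr::mutate(field$fibers,
                                image = sprintf("field_%03d.tif", i),
                                .before = 1)
  }
  truth <- list_rbind(truth)
  readr::write_csv(truth, file.path(cfg$out_dir, "ground_truth.csv"))
  write_provenance(cfg, cfg$out_dir)
  invisible(truth)
}
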