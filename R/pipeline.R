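#' @title End-to-end pipeline runs
#' @name pipeline
#' @description
#' [run_pipeline()] executes the full workflow (curate, split, train base
#' classifiers, enumerate juries, select and retrain, optionally dissect a
#' reference epitope) from a single validated configuration with one
#' top-level seed, and writes all artifacts (model archive, per-jury MCC
#' table, core-set predictions, run manifest) to an output directory.
NULL

#' Default run configuration
#'
#' @return Named list of defaults; see [run_pipeline()] for the fields.
#' @export
default_run_config <- function() {
  list(seed = 1,
       data = list(synthetic = TRUE),
       target_length = 8,
       descriptors = DESCRIPTOR_IDS,
       schemes = SCHEME_IDS,
       grid = "full",
       n_folds = 10,
       external_fraction = 1 / 5,
       jury_hidden = 3,
       search = "exhaustive",
       stacking = "faithful",
       scan = NULL)
}

#' Validate a run configuration
#'
#' Merges the supplied configuration over [default_run_config()] and
#' checks every field before any computation: seed presence, split
#' fractions (a zero external fraction is rejected because the jury
#' selection rule requires an external estimate), slot definitions, search
#' and stacking modes, and existence of any referenced input file.
#'
#' @param config Named list, or path to a YAML file.
#' @return The merged, validated configuration.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop("config error: 'seed' is mandatory and numeric")
  if (!is.numeric(cfg$external_fraction) || cfg$external_fraction <= 0 ||
      cfg$external_fraction >= 1)
    stop("config error: 'external_fraction' must be in (0, 1); the jury ",
         "selection rule requires a non-empty external validation set")
  if (!is.numeric(cfg$n_folds) || cfg$n_folds < 2)
    stop("config error: 'n_folds' must be >= 2")
  if (!all(cfg$descriptors %in% DESCRIPTOR_IDS))
    stop("config error: unknown descriptor id")
  if (!all(cfg$schemes %in% SCHEME_IDS))
    stop("config error: unknown learning scheme")
  cfg$search <- match.arg(cfg$search, c("exhaustive", "greedy"))
  cfg$stacking <- match.arg(cfg$stacking, c("faithful", "cv"))
  if (!is.null(cfg$data$path) && !file.exists(cfg$data$path))
    stop("config error: data file not found: ", cfg$data$path)
  if (is.null(cfg$data$path) && !isTRUE(cfg$data$synthetic))
    stop("config error: 'data' must give a 'path' or 'synthetic: true'")
  if (!is.null(cfg$scan)) {
    if (is.null(cfg$scan$reference))
      stop("config error: scan block needs a 'reference' peptide")
    validate_peptides(cfg$scan$reference, cfg$target_length)
  }
  cfg
}

resolve_grid <- function(grid) {
  if (inherits(grid, "grid_spec")) return(grid)
  if (is.character(grid))
    return(switch(grid, full = grid_spec(), reduced = reduced_grid_spec(),
                  stop("config error: grid must be 'full' or 'reduced'")))
  do.call(grid_spec, grid)
}

#' Run the full cascaded-model pipeline
#'
#' @param config Configuration list or YAML path; see
#'   [validate_run_config()]. Key fields: `seed` (mandatory), `data`
#'   (either `path` to a sequence/label CSV-TSV or `synthetic: true` plus
#'   optional [motif_spec()] arguments under `data$motif`), `descriptors`,
#'   `schemes`, `grid` (`"full"`, `"reduced"`, or a list of [grid_spec()]
#'   arguments), `n_folds`, `external_fraction`, `jury_hidden`, `search`,
#'   `stacking`, and an optional `scan` block (`reference`, `min_len`,
#'   `cap`) for epitope dissection with the trained model.
#' @param output_dir Directory for artifacts (created if missing).
#' @return The trained `"jury_model"`, invisibly; artifacts on disk:
#'   `model.rds`, `jury_mcc.tsv`, `predictions.tsv`, `manifest.json`, and
#'   `dissection.tsv` when a scan block is configured.
#' @export
run_pipeline <- function(config, output_dir) {
  cfg <- validate_run_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed

  raw <- if (!is.null(cfg$data$path)) {
    read_peptide_table(cfg$data$path)
  } else {
    margs <- cfg$data$motif
    if (is.null(margs)) margs <- list()
    margs$seed <- child_seed(seed, 1)
    margs$length <- cfg$target_length
    generate_peptides(do.call(motif_spec, margs))
  }
  core <- curate_peptides(raw, cfg$target_length, quiet = TRUE)
  context <- descriptor_context()
  grid <- resolve_grid(cfg$grid)
  model <- cascade_fit(core, cfg$descriptors, cfg$schemes, grid,
                       cfg$n_folds, cfg$external_fraction, cfg$jury_hidden,
                       cfg$search, cfg$stacking,
                       seed = child_seed(seed, 2), context = context)

  save_jury_model(model, file.path(output_dir, "model.rds"))
  utils::write.table(model$jury_table,
                     file.path(output_dir, "jury_mcc.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  preds <- predict(model, core)
  preds$label <- core$label
  utils::write.table(preds, file.path(output_dir, "predictions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  dissection <- NULL
  if (!is.null(cfg$scan)) {
    dissection <- dissect_epitope(model, cfg$scan$reference,
                                  min_len = cfg$scan$min_len %||% 3,
                                  cap = cfg$scan$cap %||% 160000,
                                  seed = child_seed(seed, 3))
    utils::write.table(dissection, file.path(output_dir, "dissection.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  # deterministic manifest: full effective config (the defaults actually
  # used), derived seeds, selection summary, curation counts
  manifest <- list(
    package = "pepcascade",
    version = as.character(utils::packageVersion("pepcascade")),
    config = cfg,
    derived_seeds = list(data = child_seed(seed, 1),
                         fit = child_seed(seed, 2),
                         scan = child_seed(seed, 3)),
    curation = as.list(attr(core, "curation")),
    pharmacophore_table = lapply(context$table, paste, collapse = ","),
    grid = list(ann = nrow(grid$ann), svm = nrow(grid$svm),
                inner_folds = grid$inner_folds),
    selected = list(members = model$slots$slot,
                    mcc_cv = model$mcc_cv, mcc_ext = model$mcc_ext,
                    n_subsets_evaluated =
                      attr(model$jury_table, "n_evaluated")))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
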