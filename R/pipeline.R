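# End-to-end driver: featurize -> fit -> predict -> atom-attribution map
# for a query molecule, with JSON provenance sidecars for every artifact.

#' Assemble and validate a pipeline configuration
#'
#' @param input Path to a training CSV with columns `id,smiles,logS`.
#' @param query Query molecule SMILES.
#' @param out_dir Output directory (created if missing).
#' @param radius,nbits Fingerprint settings.
#' @param cv Cross-validation folds (0 = none).
#' @param seed Integer seed governing every stochastic step.
#' @param attribution_mode `"center"` or `"spread"` (see
#'   [atom_attribution()]).
#' @return A validated `run_config` list.
#' @export
run_config <- function(input, query, out_dir, radius = 2L, nbits = 2048L,
                       cv = 0L, seed = 1L, attribution_mode = "center") {
  if (!(is.numeric(radius) && length(radius) == 1L && radius >= 0)) {
    stop("invalid config: `radius` must be a non-negative integer",
         call. = FALSE)
  }
  if (!(is.numeric(nbits) && length(nbits) == 1L && nbits >= 16)) {
    stop("invalid config: `nbits` must be at least 16", call. = FALSE)
  }
  if (!file.exists(input)) {
    stop(sprintf("invalid config: training table '%s' does not exist", input),
         call. = FALSE)
  }
  if (!attribution_mode %in% c("center", "spread")) {
    stop("invalid config: `attribution_mode` must be 'center' or 'spread'",
         call. = FALSE)
  }
  list(input = input, query = query, out_dir = out_dir,
       radius = as.integer(radius), nbits = as.integer(nbits),
       cv = as.integer(cv), seed = as.integer(seed),
       attribution_mode = attribution_mode)
}

.provenance <- function(config, extra = list()) {
  c(list(
    package = "soluprint",
    package_version = as.character(utils::packageVersion("soluprint")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    input_md5 = unname(tools::md5sum(config$input))
  ), extra)
}

#' Run the full train/predict/map pipeline
#'
#' Reads the training table, fits the solubility model, predicts the query
#' molecule's logS, renders its atom-attribution map, and writes
#' `model.json`, `prediction.json`, `map.svg` and `atoms.csv` with a
#' shared `provenance.json` sidecar. On failure all partial outputs are
#' removed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted `model`, the query
#'   `prediction`, the `attribution`, and the output `paths`.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out, c("model.json", "prediction.json", "map.svg",
                            "atoms.csv", "provenance.json"))
  names(paths) <- c("model", "prediction", "map", "atoms", "provenance")
  ok <- FALSE
  on.exit(if (!ok) unlink(paths[file.exists(paths)]))

  query_mol <- parse_smiles(config$query)   # validate before the slow fit
  table <- read.csv(config$input, stringsAsFactors = FALSE)
  if (!all(c("smiles", "logS") %in% names(table))) {
    stop("training table must have columns smiles and logS", call. = FALSE)
  }
  model <- .with_seed(config$seed,
    fit_solubility(table, radius = config$radius, nbits = config$nbits,
                   cv = config$cv, cv_seed = config$seed))

  sf <- structural_fingerprint(model, query_mol,
                               mode = config$attribution_mode)
  render_molecule_map(query_mol, sf$attribution$weights,
                      file = paths[["map"]])
  write_attribution_csv(query_mol, sf$attribution, paths[["atoms"]])
  write_model_json(model, paths[["model"]], training_file = config$input)
  jsonlite::write_json(
    list(query = config$query, predicted_logS = sf$prediction,
         intercept = model$fit$intercept,
         atom_contribution_sum = sum(sf$attribution$weights)),
    paths[["prediction"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    .provenance(config, list(outputs = as.list(unname(paths)))),
    paths[["provenance"]], auto_unbox = TRUE, digits = NA)
  ok <- TRUE
  invisible(list(model = model, prediction = sf$prediction,
                 attribution = sf$attribution, paths = paths))
}
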