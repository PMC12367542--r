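#' Read a cohort configuration from YAML or JSON
#'
#' Keys map one-to-one onto the arguments of [cohort_config()]; unknown
#' keys are rejected so silent typos cannot change a simulation.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#'
#' @return A validated `"cohort_config"`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(cohort_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(unknown, collapse = ", "), "."))
  }
  do.call(cohort_config, vals)
}

#' Reconstruct a design surface from its exported files
#'
#' Reads the JSON provenance sidecar written by [write_surface()] and
#' rebuilds the analytic surface from the stored phenotype fits.
#'
#' @param path The table path passed to [write_surface()] (the sidecar is
#'   `<path>.json`).
#'
#' @return A `"bwas_surface"`.
#' @export
read_surface <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(sprintf("Provenance sidecar not found: %s", sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  fits <- tibble::as_tibble(meta$source_phenotypes)
  design_surface(fits, train_fraction = meta$train_fraction)
}

# Write the manifest every CLI command leaves beside its outputs: the
# effective configuration, seed, package version and a config hash so
# pipeline steps can be linked.
write_manifest <- function(dir, command, config, seed) {
  manifest <- list(
    command = command,
    config = config,
    config_hash = rlang::hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("bwasplan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Import an accuracy table in a foreign layout
#'
#' Adapter for accuracy tables whose columns are named differently from
#' the package schema (for example, released per-dataset tables using
#' `N`/`T`/`score` style headers). Columns are renamed according to
#' `mapping` and the result validated by [as_accuracy_grid()].
#'
#' @param path Delimited file.
#' @param mapping Named character vector `c(schema_name = foreign_name)`
#'   for any columns whose names differ.
#' @param dataset,metric Constants to fill in when the foreign table lacks
#'   these columns.
#'
#' @return A validated accuracy tibble.
#' @export
import_accuracy_table <- function(path, mapping = character(),
                                  dataset = NULL, metric = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (schema_name in names(mapping)) {
    foreign <- mapping[[schema_name]]
    if (!foreign %in% names(raw)) {
      abort(sprintf("Mapped column `%s` not found in %s.", foreign, path))
    }
    names(raw)[names(raw) == foreign] <- schema_name
  }
  if (!is.null(dataset) && !"dataset" %in% names(raw)) raw$dataset <- dataset
  if (!is.null(metric) && !"metric" %in% names(raw)) raw$metric <- metric
  as_accuracy_grid(raw)
}
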