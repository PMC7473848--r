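#' Read a phenotypic assay table from delimited text
#'
#' Expects a comma- (or tab-) separated file with a header; see
#' [validate_assay_records()] for the column contract.
#'
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @return A validated assay data.frame.
#' @export
read_assay_table <- function(path, sep = ",") {
  validate_assay_records(utils::read.table(path, header = TRUE, sep = sep,
                                           stringsAsFactors = FALSE))
}

#' Write simulation results to disk
#'
#' Writes any of the package's trajectory objects as a CSV (one row per
#' generation or time point) together with a JSON metadata sidecar
#' recording the parameters, seed and summary statistics, sufficient to
#' reproduce the run. Reading the CSV back yields the same values.
#'
#' @param result A `sdgd_trajectory`, `cage_trajectory`,
#'   `sdgd_ode_trajectory`, or the list returned by
#'   [collapse_probability()].
#' @param out_dir Output directory (created if needed).
#' @param stem File stem; files are `<stem>.csv` (if tabular) and
#'   `<stem>.json`.
#' @param params Optional [sdgd_params()] to embed in the metadata.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, out_dir, stem = "run", params = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- character()
  # no wall-clock timestamp: outputs must be byte-reproducible from
  # (parameters, seed) alone
  meta <- list(package = "sdgdrive",
               version = as.character(utils::packageVersion("sdgdrive")))
  if (!is.null(params)) {
    meta$parameters <- unclass_params(params)
    prov <- attr(params, "provenance")
    if (!is.null(prov)) meta$provenance <- as.list(prov)
  }
  tab <- NULL
  if (inherits(result, "cage_trajectory")) {
    tab <- result$summary
    meta$collapsed <- result$collapsed
    meta$collapse_generation <- result$collapse_generation
    meta$seed <- result$seed
  } else if (is.data.frame(result)) {
    tab <- as.data.frame(result)
  } else if (is.list(result) && !is.null(result$probability)) {
    meta$collapse_probability <- result$probability
    meta$ci <- as.list(result$ci)
    meta$n_reps <- result$n_reps
    meta$n_collapsed <- result$n_collapsed
    meta$horizon <- result$horizon
    meta$seed <- result$seed
  } else stop("unsupported result object")
  if (!is.null(tab)) {
    csv <- file.path(out_dir, paste0(stem, ".csv"))
    utils::write.csv(tab, csv, row.names = FALSE)
    paths <- c(paths, csv)
  }
  js <- file.path(out_dir, paste0(stem, ".json"))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, js)
  invisible(paths)
}

# parameter set as plain nested list for serialization
unclass_params <- function(p) {
  out <- unclass(p)
  attributes(out) <- list(names = names(out))
  out$female_fitness <- as.list(out$female_fitness)
  out$male_fitness <- as.list(out$male_fitness)
  out$cage <- lapply(out$cage, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
  out
}
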