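# Feature registry: the catalogue of per-SNP annotation features, their value
# kinds (binary / categorical / continuous), optional context axis
# (tissue / cell line), value ranges and default weights.

#' Load a feature registry
#'
#' A feature registry is a TSV with columns `name`, `section`, `value_kind`
#' (`binary`, `categorical` or `continuous`), `context_axis` (empty when the
#' feature has no tissue/cell-line dimension), `min`/`max` (continuous
#' features only) and `weight` (the default coefficient in `[0,1]`).
#'
#' @param path path to a registry TSV.
#' @return a `feature_registry` data frame.
#' @export
load_feature_registry <- function(path) {
  reg <- read_tsv(path)
  required <- c("name", "section", "value_kind", "weight")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols) > 0)
    stop_usage("registry is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(reg$name))
    stop_integrity("duplicate feature names in registry")
  if (!all(reg$value_kind %in% c("binary", "categorical", "continuous")))
    stop_usage("value_kind must be binary, categorical or continuous")
  if (is.null(reg$context_axis)) reg$context_axis <- ""
  reg$context_axis[is.na(reg$context_axis)] <- ""
  reg$context_axis <- trimws(reg$context_axis)
  for (col in c("min", "max")) {
    if (is.null(reg[[col]])) reg[[col]] <- NA_real_
    reg[[col]] <- suppressWarnings(as.numeric(reg[[col]]))
  }
  reg$weight <- as.numeric(reg$weight)
  if (any(reg$weight < 0 | reg$weight > 1))
    stop_usage("feature weights must lie in [0, 1]")
  cont <- reg$value_kind == "continuous"
  if (any(cont & (is.na(reg$min) | is.na(reg$max) | reg$min >= reg$max)))
    stop_usage("continuous features need min < max")
  class(reg) <- c("feature_registry", "data.frame")
  reg
}

#' Default feature registry
#'
#' The registry shipped with the package: 31 features grouped in five semantic
#' sections (SNP/gene, epigenetics and transcription regulation, translation
#' regulation, protein, disease), with the default weights learned by the
#' genetic-algorithm optimizer against disease benchmarks.
#'
#' @return a `feature_registry` data frame with 31 rows.
#' @export
default_feature_registry <- function() {
  load_feature_registry(system.file("extdata", "default_features.tsv",
                                    package = "snpprio", mustWork = TRUE))
}

#' Category score map for categorical features
#'
#' Categorical features (SNP localization classes) map labels to scores in
#' `[0,1]`. The shipped default ranks coding-disruptive classes (frame shift,
#' missense, start codon) above UTRs, near-gene regions and introns. The map
#' is plain editable config, never hard-coded.
#'
#' @param path TSV with columns `category` and `score`; default is the shipped
#'   localization map.
#' @return named numeric vector of scores.
#' @export
load_category_scores <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "localization_scores.tsv",
                        package = "snpprio", mustWork = TRUE)
  tab <- read_tsv(path)
  scores <- as.numeric(tab$score)
  if (any(scores < 0 | scores > 1))
    stop_usage("category scores must lie in [0, 1]")
  stats::setNames(scores, tab$category)
}

#' Extract the default weight vector from a registry
#'
#' @param registry a `feature_registry`.
#' @return named numeric vector of weights aligned to registry order.
#' @export
registry_weights <- function(registry) {
  stats::setNames(registry$weight, registry$name)
}

#' Write learned weights in registry format
#'
#' Emits a full registry TSV whose `weight` column carries the supplied
#' weights, so learned weights can be consumed anywhere a registry is.
#'
#' @param registry a `feature_registry`.
#' @param weights named numeric vector aligned to the registry features.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_weight_config <- function(registry, weights, path) {
  if (!all(registry$name %in% names(weights)))
    stop_usage("weights must cover every registry feature")
  out <- registry
  out$weight <- round(unname(weights[registry$name]), 6)
  write_tsv(as.data.frame(out), path)
}
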