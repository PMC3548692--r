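# Scoring: raw annotation -> per-feature score f in [0,1], weighted linear
# SNP score sigma = sum_i w_i * f_i over the selected features, deterministic
# ranking and percentile truncation.

#' Normalize a raw feature value to a score in [0, 1]
#'
#' Binary features pass through as 0/1; categorical features are looked up in
#' the category score map; continuous features are min-max scaled to the
#' registry's declared range and clipped to `[0,1]`. Missing raw values score
#' 0 (absence of evidence contributes no score mass). For a contextual
#' feature, a vector of per-context scores is averaged unless a single
#' context is selected.
#'
#' @param raw raw value(s); a vector is treated as per-context sub-values.
#' @param feature one registry row (list or single-row data frame).
#' @param category_scores named score map, required for categorical features.
#' @param context optional context label; when supplied, `raw` must be named
#'   by context and only that context's score is returned.
#' @return a score in `[0,1]`.
#' @export
normalize_feature <- function(raw, feature, category_scores = NULL,
                              context = NULL) {
  if (is.data.frame(feature)) feature <- as.list(feature)
  if (!is.null(context)) {
    if (is.null(names(raw)) || !(context %in% names(raw)))
      stop_usage("context '", context, "' not present for feature ",
                 feature$name)
    raw <- raw[[context]]
  }
  if (length(raw) > 1) {   # per-context sub-values: average the scores
    scores <- vapply(raw, normalize_feature, numeric(1), feature = feature,
                     category_scores = category_scores)
    return(mean(scores))
  }
  if (length(raw) == 0 || is.na(raw)) return(0)
  switch(feature$value_kind,
    binary = as.numeric(as.numeric(raw) > 0),
    categorical = {
      if (is.null(category_scores) || !(raw %in% names(category_scores)))
        stop_usage("category '", raw, "' absent from score map for feature ",
                   feature$name)
      unname(category_scores[[raw]])
    },
    continuous = {
      f <- (as.numeric(raw) - feature$min) / (feature$max - feature$min)
      min(max(f, 0), 1)
    },
    stop_usage("unknown value_kind: ", feature$value_kind))
}

#' Normalize a whole feature matrix
#'
#' @param fm a `feature_matrix`.
#' @param registry a `feature_registry`.
#' @param category_scores named category score map (default: shipped
#'   localization map).
#' @param context optional context label applied to contextual features that
#'   carry it; features without that context fall back to the context mean.
#' @return numeric matrix (SNPs x features) of scores in `[0,1]`.
#' @export
normalize_matrix <- function(fm, registry,
                             category_scores = load_category_scores(),
                             context = NULL) {
  out <- matrix(0, length(fm$snps), nrow(registry),
                dimnames = list(fm$snps, registry$name))
  for (j in seq_len(nrow(registry))) {
    feature <- as.list(registry[j, ])
    feat <- feature$name
    if (feat %in% names(fm$contexts)) {
      m <- fm$contexts[[feat]]
      use_ctx <- !is.null(context) && context %in% colnames(m)
      for (i in seq_along(fm$snps)) {
        row <- m[i, ]
        row <- row[!is.na(row)]
        out[i, j] <- if (length(row) == 0) 0
          else if (use_ctx && !is.na(m[i, context]))
            normalize_feature(m[i, context], feature)
          else normalize_feature(row, feature)
      }
    } else {
      v <- fm$raw[[feat]]
      out[, j] <- switch(feature$value_kind,
        binary = ifelse(is.na(v), 0, as.numeric(as.numeric(v) > 0)),
        continuous = {
          s <- (as.numeric(v) - feature$min) / (feature$max - feature$min)
          ifelse(is.na(s), 0, pmin(pmax(s, 0), 1))
        },
        categorical = {
          present <- !is.na(v)
          if (any(present & !(v %in% names(category_scores)))) {
            bad <- v[present & !(v %in% names(category_scores))][1]
            stop_usage("category '", bad, "' absent from score map for ",
                       "feature ", feat)
          }
          ifelse(present, unname(category_scores[v]), 0)
        })
    }
  }
  out
}

#' Weighted linear SNP score
#'
#' `sigma = sum over selected features of w_i * f_i`. Deselected features
#' contribute exactly zero. `f` may be a single score vector or a matrix
#' (SNPs x features), in which case a vector of scores is returned.
#'
#' @param f feature score vector (values in `[0,1]`) or matrix with feature
#'   column names.
#' @param w named weight vector in `[0,1]^n`, aligned to the same registry.
#' @param selected character vector of selected feature names
#'   (default: all features of `w`).
#' @return numeric score(s).
#' @export
score_snp <- function(f, w, selected = NULL) {
  if (is.null(selected)) selected <- names(w)
  if (is.null(names(w))) stop_usage("weights must be named by feature")
  unknown <- setdiff(selected, names(w))
  if (length(unknown) > 0)
    stop_usage("selected features not in weight vector: ",
               paste(unknown, collapse = ", "))
  if (is.matrix(f)) {
    if (!all(selected %in% colnames(f)))
      stop_usage("feature score matrix misaligned with weights")
    return(drop(f[, selected, drop = FALSE] %*% w[selected]))
  }
  if (is.null(names(f))) {
    if (length(f) != length(w))
      stop_usage("feature scores and weights have different lengths")
    names(f) <- names(w)
  }
  if (!all(selected %in% names(f)))
    stop_usage("feature scores misaligned with weights")
  sum(w[selected] * f[selected])
}

#' Rank SNPs by score
#'
#' Stable deterministic ordering: score descending, ties broken by rsid
#' ascending (C-locale radix sort), so permuting the input never changes the
#' output.
#'
#' @param scored data frame with at least `rsid` and `sigma` columns.
#' @return a `ranked_snps` data frame with a `rank` column.
#' @export
rank_snps <- function(scored) {
  ord <- order(-scored$sigma, scored$rsid, method = "radix")
  out <- scored[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "tie_rule") <- "sigma descending, then rsid ascending"
  class(out) <- c("ranked_snps", "data.frame")
  out
}

#' Truncate a ranked list at a percentile
#'
#' Retains the top `ceiling(percentile/100 * n)` entries.
#'
#' @param ranked a `ranked_snps` data frame.
#' @param percentile value in `(0, 100]`.
#' @return the truncated `ranked_snps`.
#' @export
percentile_cut <- function(ranked, percentile) {
  if (length(percentile) != 1 || is.na(percentile) ||
      percentile <= 0 || percentile > 100)
    stop_usage("percentile must lie in (0, 100]")
  if (nrow(ranked) == 0) stop_usage("ranked list is empty")
  keep <- ceiling(percentile / 100 * nrow(ranked))
  out <- ranked[seq_len(keep), , drop = FALSE]
  class(out) <- class(ranked)
  attr(out, "tie_rule") <- attr(ranked, "tie_rule")
  out
}

#' Write a ranked SNP table
#'
#' Emits the final TSV: `rsid`, associated gene(s), position, `sigma`, then
#' one raw-value and one score column per selected feature, so both the
#' original annotation and the derived score are auditable. A `.gz` path
#' produces the compressed variant.
#'
#' @param ranked a `ranked_snps` data frame.
#' @param path output TSV (optionally `.gz`).
#' @return the path, invisibly.
#' @export
write_ranked_table <- function(ranked, path) {
  write_tsv(as.data.frame(ranked), path)
  invisible(path)
}
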