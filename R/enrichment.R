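# Enrichment of the genes carrying top-ranked SNPs against pathway, ontology
# or disorder category maps: hypergeometric upper-tail tests with
# Benjamini-Hochberg FDR correction. Counting is strictly gene-level: many
# SNPs in one gene count that gene once.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn from a universe of
#' `N` containing `K` annotated ones. Computed via [stats::phyper()].
#'
#' @param k observed overlap.
#' @param K annotated genes in the universe.
#' @param n drawn genes.
#' @param N universe size.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(n, K))
    stop_usage("invalid hypergeometric parameters: need 0 <= k <= min(n, K)",
               " and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR correction via [stats::p.adjust()]; output is in input order
#' and clipped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_usage("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Load a category map
#'
#' GMT format (`category<TAB>description<TAB>gene1<TAB>gene2...`) or
#' two-column TSV (`category_id`, `gene_id`). The background universe is the
#' union of all category gene sets.
#'
#' @param path input file.
#' @param source category family label: `"pathway"`, `"ontology_term"` or
#'   `"disorder"`.
#' @param format `"gmt"` or `"tsv"`.
#' @return a `category_map`: list with `source`, `categories` (named list of
#'   gene-id vectors) and `universe`.
#' @export
load_category_map <- function(path, source = c("pathway", "ontology_term",
                                               "disorder"),
                              format = c("gmt", "tsv")) {
  source <- match.arg(source)
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    categories <- stats::setNames(
      lapply(fields, function(f) unique(f[-(1:2)])),
      vapply(fields, `[[`, "", 1))
  } else {
    tab <- read_tsv(path)
    categories <- lapply(split(as.character(tab[[2]]), tab[[1]]), unique)
  }
  categories <- categories[lengths(categories) > 0]
  if (length(categories) == 0) stop_usage("category map is empty: ", path)
  category_map(categories, source)
}

#' @rdname load_category_map
#' @param categories named list of gene-id vectors.
#' @param universe optional explicit background; default is the union of all
#'   categories.
#' @export
category_map <- function(categories, source = "pathway", universe = NULL) {
  if (is.null(universe))
    universe <- sort(unique(unlist(categories, use.names = FALSE)))
  stray <- setdiff(unlist(categories, use.names = FALSE), universe)
  if (length(stray) > 0)
    stop_integrity("category genes outside the universe: ",
                   paste(utils::head(stray, 3), collapse = ", "))
  structure(list(source = source, categories = categories,
                 universe = universe),
            class = "category_map")
}

#' Enrichment of genes carrying top-ranked SNPs
#'
#' Truncates the ranked list at the percentile, collects the distinct genes
#' carrying the surviving SNPs (via the gene-SNP map), and tests each
#' category holding at least one such gene for over-representation with a
#' hypergeometric upper tail; BH correction is applied across all tests of
#' the map's source. Results are sorted by q, then p.
#'
#' @param ranked a `ranked_snps` data frame.
#' @param percentile cut in `(0, 100]`.
#' @param map a `category_map`.
#' @param gene_snp_map a `gene_snp_map`.
#' @param include_empty also test categories with zero top-gene overlap at
#'   `k = 0` (default `FALSE`: they are skipped).
#' @return an `enrichment_result` data frame with columns `category`, `k`,
#'   `K`, `n`, `N`, `p_value`, `q_value`; zero rows (with attribute
#'   `n_top_genes = 0`) when no top gene is in the universe.
#' @export
enrich_top <- function(ranked, percentile, map, gene_snp_map,
                       include_empty = FALSE) {
  if (nrow(ranked) == 0) stop_usage("ranked list is empty")
  top <- percentile_cut(ranked, percentile)
  top_genes <- unique(gene_snp_map$gene_id[gene_snp_map$rsid %in% top$rsid])
  top_genes <- intersect(top_genes, map$universe)
  empty <- data.frame(category = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
  attr(empty, "source") <- map$source
  class(empty) <- c("enrichment_result", "data.frame")
  if (length(top_genes) == 0) {
    attr(empty, "n_top_genes") <- 0L
    return(empty)
  }
  N <- length(map$universe)
  n <- length(top_genes)
  rows <- lapply(names(map$categories), function(cat) {
    members <- intersect(map$categories[[cat]], map$universe)
    k <- length(intersect(top_genes, members))
    if (k == 0 && !include_empty) return(NULL)
    K <- length(members)
    data.frame(category = cat, k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    attr(empty, "n_top_genes") <- n
    return(empty)
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$q_value, out$p_value, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- map$source
  attr(out, "n_top_genes") <- n
  class(out) <- c("enrichment_result", "data.frame")
  out
}
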