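# Ontology layer: OBO 1.2 parsing into a term DAG, annotation corpus with
# ancestor propagation, Wang and relevance (Rel) semantic similarity,
# best-match-average gene similarity, and threshold-based gene-set expansion.
#
# The OBO reader is a minimal stanza parser (id / name / namespace / is_a /
# relationship / is_obsolete): only is_a and part_of edges are retained,
# everything else is dropped with a count.

#' Parse an OBO 1.2 ontology file into a term DAG
#'
#' Obsolete terms are excluded; `is_a` and `part_of` edges are retained and
#' typed, other relationship types are dropped (count in attribute
#' `n_dropped_edges`). The graph is verified acyclic.
#'
#' @param path OBO file.
#' @return an `ontology_dag`: list with `terms` (data frame `id`, `name`,
#'   `namespace`), `edges` (data frame `child`, `parent`, `type`), `roots`,
#'   and a precomputed `parents` adjacency list.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list(); edges <- list(); n_dropped <- 0L
  flush <- function() {
    if (is.null(cur) || isTRUE(cur$obsolete) || is.null(cur$id)) return()
    terms[[length(terms) + 1]] <<- data.frame(
      id = cur$id, name = cur$name %||% cur$id,
      namespace = cur$namespace %||% "", stringsAsFactors = FALSE)
    for (e in cur$edges)
      edges[[length(edges) + 1]] <<- data.frame(
        child = cur$id, parent = e[2], type = e[1], stringsAsFactors = FALSE)
  }
  for (line in lines) {
    line <- sub("!.*$", "", line)          # strip trailing comments
    line <- trimws(line)
    if (line == "[Term]") { flush(); cur <- list(edges = list()); in_term <- TRUE; next }
    if (grepl("^\\[", line)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(line)) next
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) != 2) next
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (key == "is_a") cur$edges[[length(cur$edges) + 1]] <- c("is_a", val)
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of")
        cur$edges[[length(cur$edges) + 1]] <- c("part_of", parts[2])
      else n_dropped <- n_dropped + 1L
    }
  }
  flush()
  terms <- if (length(terms) > 0) do.call(rbind, terms) else
    data.frame(id = character(), name = character(), namespace = character())
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(), type = character())
  edges <- edges[edges$parent %in% terms$id & edges$child %in% terms$id, ,
                 drop = FALSE]
  dag <- build_dag(terms, edges)
  attr(dag, "n_dropped_edges") <- n_dropped
  dag
}

#' Construct an ontology DAG from term and edge tables
#'
#' @param terms data frame with `id`, `name`, `namespace`.
#' @param edges data frame with `child`, `parent`, `type` in
#'   `{is_a, part_of}`.
#' @return an `ontology_dag`.
#' @export
build_dag <- function(terms, edges) {
  if (anyDuplicated(terms$id)) stop_integrity("duplicate term ids")
  # Cycle check: iterative depth-first search with colors over parent links.
  color <- stats::setNames(rep(0L, nrow(terms)), terms$id)  # 0 new 1 open 2 done
  parent_list <- split(edges$parent, factor(edges$child, terms$id))
  visit <- function(t) {
    stack <- list(list(id = t, next_i = 1L))
    color[t] <<- 1L
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      ps <- parent_list[[top$id]]
      if (is.null(ps) || top$next_i > length(ps)) {
        color[top$id] <<- 2L
        stack[[length(stack)]] <- NULL
      } else {
        stack[[length(stack)]]$next_i <- top$next_i + 1L
        p <- ps[top$next_i]
        if (color[p] == 1L) stop_integrity("ontology graph is cyclic at ", p)
        if (color[p] == 0L) {
          color[p] <<- 1L
          stack[[length(stack) + 1]] <- list(id = p, next_i = 1L)
        }
      }
    }
  }
  for (t in terms$id) if (color[t] == 0L) visit(t)
  roots <- setdiff(terms$id, edges$child)
  structure(list(terms = terms, edges = edges, roots = roots,
                 parents = parent_list),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", nrow(x$terms), "terms,", nrow(x$edges), "edges,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

# All ancestors of a term (excluding itself), following child -> parent links.
term_ancestors <- function(dag, term) {
  seen <- character()
  frontier <- dag$parents[[term]]
  while (length(frontier) > 0) {
    new <- setdiff(unique(frontier), seen)
    seen <- c(seen, new)
    frontier <- unlist(dag$parents[new], use.names = FALSE)
  }
  seen
}

#' Build an annotation corpus with ancestor propagation
#'
#' Direct gene-to-term assignments are closed over the DAG's ancestors
#' (the true-path rule), so a gene annotated to a term is implicitly
#' annotated to every ancestor.
#'
#' @param dag an `ontology_dag`.
#' @param annotations data frame with columns `gene_id`, `term_id`
#'   (a GAF 2.x file can be reduced to these two columns; see
#'   [load_annotations()]).
#' @param namespace restrict to one namespace (default
#'   `"biological_process"`); `NULL` keeps all.
#' @return an `annotation_corpus`: list with `direct` and `propagated`
#'   gene -> term-set maps and the `dag`.
#' @export
annotation_corpus <- function(dag, annotations, namespace = "biological_process") {
  keep_terms <- dag$terms$id
  if (!is.null(namespace) && any(nzchar(dag$terms$namespace)))
    keep_terms <- dag$terms$id[dag$terms$namespace == namespace |
                                 !nzchar(dag$terms$namespace)]
  ann <- annotations[annotations$term_id %in% keep_terms, , drop = FALSE]
  ann$gene_id <- as.character(ann$gene_id)
  direct <- lapply(split(ann$term_id, ann$gene_id), unique)
  anc_cache <- new.env(parent = emptyenv())
  anc_of <- function(t) {
    if (is.null(anc_cache[[t]])) anc_cache[[t]] <- term_ancestors(dag, t)
    anc_cache[[t]]
  }
  propagated <- lapply(direct, function(ts)
    unique(c(ts, unlist(lapply(ts, anc_of), use.names = FALSE))))
  structure(list(direct = direct, propagated = propagated, dag = dag),
            class = "annotation_corpus")
}

#' Read a gene-to-term annotation table
#'
#' @param path TSV with columns `gene_id`, `term_id` (optionally `evidence`),
#'   or a GAF 2.x file (`format = "gaf"`: column 2 is the gene, column 5 the
#'   term; comment lines start with `!`).
#' @param format `"tsv"` or `"gaf"`.
#' @return data frame `gene_id`, `term_id`.
#' @export
load_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "gaf") {
    tab <- utils::read.delim(path, header = FALSE, comment.char = "!",
                             stringsAsFactors = FALSE)
    data.frame(gene_id = as.character(tab[[2]]), term_id = as.character(tab[[5]]),
               stringsAsFactors = FALSE)
  } else {
    tab <- read_tsv(path)
    data.frame(gene_id = as.character(tab$gene_id),
               term_id = as.character(tab$term_id), stringsAsFactors = FALSE)
  }
}

# Wang S-values of a term: contribution of each ancestor to the term's
# semantics. S(term) = 1; S weakens multiplicatively through each edge by the
# edge-type factor, keeping the maximum over paths.
wang_svalues <- function(dag, term, contrib = c(is_a = 0.8, part_of = 0.6)) {
  if (!(term %in% dag$terms$id)) stop_usage("unknown term: ", term)
  s <- stats::setNames(1, term)
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- character()
    for (t in frontier) {
      idx <- which(dag$edges$child == t)
      for (i in idx) {
        p <- dag$edges$parent[i]
        cand <- s[[t]] * contrib[[dag$edges$type[i]]]
        if (is.null(s[p]) || is.na(s[p]) || cand > s[[p]]) {
          s[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  s
}

#' Wang semantic similarity between two terms
#'
#' S-values propagate from each term to its ancestors (1 at the term itself,
#' multiplied by an edge-type factor per step, maximum over paths); the
#' similarity is the sum of both terms' S-values over their shared ancestors
#' (terms included), divided by the sum of all S-values of both terms.
#'
#' @param dag an `ontology_dag`.
#' @param t1,t2 term ids.
#' @param contrib named edge-type contribution factors
#'   (default `is_a` 0.8, `part_of` 0.6).
#' @return similarity in `[0, 1]`.
#' @export
wang_term_sim <- function(dag, t1, t2, contrib = c(is_a = 0.8, part_of = 0.6)) {
  s1 <- wang_svalues(dag, t1, contrib)
  s2 <- wang_svalues(dag, t2, contrib)
  shared <- intersect(names(s1), names(s2))
  if (length(shared) == 0) return(0)
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

#' Information content of terms from corpus frequencies
#'
#' `p(t)` is the fraction of annotated genes whose propagated annotations
#' include `t`; `ic(t) = -log(p(t))`. Roots of a connected annotated corpus
#' get `p = 1`, `ic = 0`; `ic` never decreases from parent to child.
#'
#' @param corpus an `annotation_corpus`.
#' @return a `term_ic`: list with numeric vectors `p` and `ic` over all DAG
#'   terms (terms outside the corpus support have `p = 0`, `ic = Inf`).
#' @export
term_ic <- function(corpus) {
  n_genes <- length(corpus$propagated)
  if (n_genes == 0) stop_usage("empty annotation corpus")
  counts <- table(factor(unlist(corpus$propagated, use.names = FALSE),
                         levels = corpus$dag$terms$id))
  p <- as.numeric(counts) / n_genes
  names(p) <- corpus$dag$terms$id
  structure(list(p = p, ic = -log(p)), class = "term_ic")
}

#' Relevance (Rel) semantic similarity between two terms
#'
#' Schlicker's relevance measure: with `c*` the common ancestor (terms
#' included) of maximum information content, the similarity is
#' `2 ic(c*) / (ic(t1) + ic(t2)) * (1 - p(c*))`. The `(1 - p)` factor
#' vanishes when the only common ancestor is the root, so unrelated terms
#' score 0.
#'
#' @param dag an `ontology_dag`.
#' @param ic a `term_ic`.
#' @param t1,t2 term ids with corpus support (`p > 0`); a term without
#'   support yields 0 with a warning.
#' @return similarity in `[0, 1]`.
#' @export
rel_term_sim <- function(dag, ic, t1, t2) {
  for (t in c(t1, t2)) {
    if (!(t %in% dag$terms$id)) stop_usage("unknown term: ", t)
    if (ic$p[[t]] == 0) {
      warning("term ", t, " has no corpus support; similarity set to 0",
              call. = FALSE)
      return(0)
    }
  }
  common <- intersect(c(t1, term_ancestors(dag, t1)),
                      c(t2, term_ancestors(dag, t2)))
  common <- common[ic$p[common] > 0]
  if (length(common) == 0) return(0)
  cstar <- common[which.max(ic$ic[common])]
  denom <- ic$ic[[t1]] + ic$ic[[t2]]
  if (denom == 0) return(0)   # both terms are roots
  max(0, 2 * ic$ic[[cstar]] / denom * (1 - ic$p[[cstar]]))
}

#' Semantic similarity between two genes (best-match average)
#'
#' Each term of gene A is matched to its most similar term of gene B; the
#' per-side means are averaged symmetrically.
#'
#' @param gA,gB gene ids.
#' @param corpus an `annotation_corpus`.
#' @param measure `"wang"` or `"rel"`.
#' @param ic a `term_ic` (required for `measure = "rel"`).
#' @param contrib Wang edge contribution factors.
#' @param .term_sim_cache optional environment memoizing term-pair
#'   similarities across calls.
#' @return similarity in `[0, 1]`, or `NA` with a warning for an unannotated
#'   gene.
#' @export
gene_sim <- function(gA, gB, corpus, measure = c("wang", "rel"), ic = NULL,
                     contrib = c(is_a = 0.8, part_of = 0.6),
                     .term_sim_cache = NULL) {
  measure <- match.arg(measure)
  tA <- corpus$direct[[gA]]
  tB <- corpus$direct[[gB]]
  if (is.null(tA) || is.null(tB) || length(tA) == 0 || length(tB) == 0) {
    warning("gene without annotation: ",
            if (is.null(tA) || length(tA) == 0) gA else gB, call. = FALSE)
    return(NA_real_)
  }
  if (measure == "rel" && is.null(ic)) ic <- term_ic(corpus)
  pair_sim <- function(u, v) {
    key <- paste(measure, min(u, v), max(u, v))
    if (!is.null(.term_sim_cache) && !is.null(.term_sim_cache[[key]]))
      return(.term_sim_cache[[key]])
    val <- if (measure == "wang") wang_term_sim(corpus$dag, u, v, contrib)
           else rel_term_sim(corpus$dag, ic, u, v)
    if (!is.null(.term_sim_cache)) .term_sim_cache[[key]] <- val
    val
  }
  m <- matrix(0, length(tA), length(tB))
  for (i in seq_along(tA)) for (j in seq_along(tB))
    m[i, j] <- pair_sim(tA[i], tB[j])
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

#' Expand a gene set by semantic similarity
#'
#' Adds every annotated gene outside the input set whose best similarity to a
#' seed gene reaches the threshold: `g2 = g1 + {x : max_s gene_sim(x, s) >=
#' threshold}`, so `g2` always contains `g1` and expansion shrinks as the
#' threshold grows. An optional `top_k` keeps only the k most similar added
#' genes.
#'
#' @param g1 input gene ids (seeds without annotation are skipped with a
#'   warning).
#' @param corpus an `annotation_corpus`.
#' @param measure `"wang"` or `"rel"`.
#' @param threshold similarity threshold in `[0, 1]`.
#' @param top_k optional cap on the number of added genes.
#' @param contrib Wang edge contribution factors.
#' @return an `expansion_result`: list with `g1`, `g2` and `added`
#'   (data frame `gene`, `seed`, `similarity`).
#' @export
expand_gene_set <- function(g1, corpus, measure = c("wang", "rel"),
                            threshold = 0.5, top_k = NULL,
                            contrib = c(is_a = 0.8, part_of = 0.6)) {
  measure <- match.arg(measure)
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0 ||
      threshold > 1)
    stop_usage("threshold must lie in [0, 1]")
  annotated <- names(corpus$direct)[lengths(corpus$direct) > 0]
  seeds <- intersect(g1, annotated)
  skipped <- setdiff(g1, seeds)
  if (length(skipped) > 0)
    warning("seed gene(s) without annotation skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (length(seeds) == 0) stop_usage("no annotated seed genes in g1")
  ic <- if (measure == "rel") term_ic(corpus) else NULL
  cache <- new.env(parent = emptyenv())
  candidates <- setdiff(annotated, g1)
  added <- list()
  for (x in candidates) {
    sims <- vapply(seeds, function(s)
      gene_sim(x, s, corpus, measure, ic = ic, contrib = contrib,
               .term_sim_cache = cache), numeric(1))
    best <- which.max(sims)
    if (length(best) > 0 && sims[best] >= threshold)
      added[[length(added) + 1]] <- data.frame(
        gene = x, seed = seeds[best], similarity = unname(sims[best]),
        stringsAsFactors = FALSE)
  }
  added <- if (length(added) > 0) do.call(rbind, added) else
    data.frame(gene = character(), seed = character(), similarity = numeric())
  added <- added[order(-added$similarity, added$gene), , drop = FALSE]
  if (!is.null(top_k) && nrow(added) > top_k)
    added <- added[seq_len(top_k), , drop = FALSE]
  rownames(added) <- NULL
  structure(list(g1 = g1, g2 = union(g1, added$gene), added = added,
                 measure = measure, threshold = threshold),
            class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat("expansion_result:", length(x$g1), "seed gene(s) ->", length(x$g2),
      "gene(s) [", x$measure, ", threshold", x$threshold, "]\n")
  invisible(x)
}

#' Genes annotated to an ontology term
#'
#' Resolves a term by exact id, else exact (case-insensitive) name; an
#' ambiguous name raises an error listing the candidates. Returns every gene
#' whose propagated annotations include the term (direct annotations plus
#' those of all descendants).
#'
#' @param term term id or name.
#' @param corpus an `annotation_corpus`.
#' @return character vector of gene ids.
#' @export
genes_for_process <- function(term, corpus) {
  dag <- corpus$dag
  if (!(term %in% dag$terms$id)) {
    hits <- dag$terms$id[tolower(dag$terms$name) == tolower(term)]
    if (length(hits) == 0)
      stop_usage("term not found: ", term)
    if (length(hits) > 1)
      stop_usage("ambiguous term name '", term, "'; candidates: ",
                 paste(hits, collapse = ", "))
    term <- hits
  }
  sort(names(corpus$propagated)[vapply(corpus$propagated,
                                       function(ts) term %in% ts,
                                       logical(1))])
}
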