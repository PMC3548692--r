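# Fixture builders and independent brute-force oracles shared by the suite.
# Everything is generated in code at test time; no stored binary fixtures.

write_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_gene_tsv <- function() write_fixture(c(
  "gene_id\tsymbol\taliases\tchrom\tstart\tend\tstrand",
  "101\tBCL2\tPPP1R50|BCL-2\tchr18\t63123346\t63320128\t-",
  "102\tKLF12\tAP-2rep\tchr13\t73700000\t74100000\t+",
  "103\tTP53\tLFS1|P53\tchr17\t7668402\t7687550\t-"))

tiny_snp_tsv <- function() write_fixture(c(
  "rsid\tchrom\tstart\tend\tstrand\talleles\tfunction_class",
  "rs1886512\t13\t73418186\t73418187\t+\tA/T\tintron",
  "rs900145\t11\t13250480\t13250481\t-\tA/G\tunknown",
  "rs340029\t15\t58682256\t58682257\t+\tC/T\tintron"))

# Toy ontology: root A; B, C is_a A; D is_a B; E part_of C.
toy_dag <- function() {
  terms <- data.frame(id = c("A", "B", "C", "D", "E"),
                      name = paste("term", c("A", "B", "C", "D", "E")),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = c("B", "C", "D", "E"),
                      parent = c("A", "A", "B", "C"),
                      type = c("is_a", "is_a", "is_a", "part_of"),
                      stringsAsFactors = FALSE)
  build_dag(terms, edges)
}

toy_obo <- function() write_fixture(ext = ".obo", c(
  "format-version: 1.2", "",
  "[Term]", "id: A", "name: term A", "namespace: biological_process", "",
  "[Term]", "id: B", "name: term B", "namespace: biological_process",
  "is_a: A ! term A", "",
  "[Term]", "id: C", "name: term C", "namespace: biological_process",
  "is_a: A ! term A", "",
  "[Term]", "id: D", "name: term D", "namespace: biological_process",
  "is_a: B ! term B", "",
  "[Term]", "id: E", "name: term E", "namespace: biological_process",
  "relationship: part_of C ! term C", ""))

# --- independent oracles ---------------------------------------------------

# all-pairs interval scan, no GenomicRanges
bf_map_snps_to_genes <- function(snps, genes, flank) {
  pairs <- list()
  for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(genes))) {
    lo <- max(genes$start[j] - flank, 0)
    hi <- genes$end[j] + flank
    same <- snps$chrom[i] == genes$chrom[j]
    if (same && snps$start[i] >= lo && snps$start[i] < hi)
      pairs[[length(pairs) + 1]] <- data.frame(
        gene_id = genes$gene_id[j], rsid = snps$rsid[i],
        stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0)
    return(data.frame(gene_id = character(), rsid = character()))
  out <- do.call(rbind, pairs)
  out[order(out$gene_id, out$rsid), , drop = FALSE]
}

# exhaustive enumeration of all n-subsets of an N-universe with K marked
bf_hypergeom_upper <- function(k, K, n, N) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

# set-membership confusion tally
bf_confusion <- function(Y, S, A) {
  list(P = length(intersect(A, Y)),
       N = length(setdiff(A, Y)),
       FP = length(setdiff(intersect(Y, S), A)),
       TN = length(setdiff(S, union(A, Y))))
}

# BH step-up by the definition: q_i = min_{j >= i} p_(j) * m / j, clipped
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  pmin(q_sorted, 1)[order(ord)]
}

# ancestors by naive repeated edge expansion
bf_ancestors <- function(edges, term) {
  anc <- character()
  frontier <- term
  repeat {
    parents <- unique(edges$parent[edges$child %in% frontier])
    new <- setdiff(parents, anc)
    if (length(new) == 0) return(anc)
    anc <- c(anc, new)
    frontier <- new
  }
}

# shared small simulation reused across test files (built once per session)
.fixture_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    spec <- simulation_spec(n_diseases = 4, genes_per_disease = 3,
                            n_snps_per_gene = 30, certified_per_disease = 8,
                            seed = 42)
    dir <- file.path(tempdir(), "snpprio-shared-store")
    store <- simulate_store(spec, dir)
    st <- load_store(dir)
    map <- map_snps_to_genes(st$snps, st$genes, spec$flank_bp)
    bdir <- file.path(tempdir(), "snpprio-shared-bench")
    simulate_benchmarks(store, bdir)
    benchmarks <- load_benchmarks(bdir, map)
    fnorm <- snpprio:::store_feature_scores(st, st$snps,
                                            load_category_scores())
    .fixture_cache$sim <- list(spec = spec, dir = dir, store = store,
                               st = st, map = map, bdir = bdir,
                               benchmarks = benchmarks, fnorm = fnorm,
                               data = prepare_ga_data(benchmarks, fnorm))
  }
  .fixture_cache$sim
}
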