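# OBO parsing, annotation propagation, Wang / Rel similarity, gene-level
# best-match-average and threshold expansion.

test_that("OBO parsing keeps is_a/part_of, drops obsolete terms and other edges", {
  dag <- parse_obo(toy_obo())
  expect_equal(nrow(dag$terms), 5)
  expect_equal(nrow(dag$edges), 4)
  expect_equal(dag$roots, "A")

  obo2 <- write_fixture(ext = ".obo", c(
    "[Term]", "id: A", "name: a", "",
    "[Term]", "id: B", "name: b", "is_a: A", "",
    "[Term]", "id: OLD", "name: gone", "is_obsolete: true", "",
    "[Term]", "id: C", "name: c", "relationship: regulates A", ""))
  dag2 <- parse_obo(obo2)
  expect_false("OLD" %in% dag2$terms$id)
  expect_equal(attr(dag2, "n_dropped_edges"), 1)

  cyc <- write_fixture(ext = ".obo", c(
    "[Term]", "id: A", "is_a: B", "",
    "[Term]", "id: B", "is_a: A", ""))
  expect_error(parse_obo(cyc), "cyclic", class = "snpprio_integrity_error")
})

test_that("Wang similarity matches hand-propagated S-values", {
  dag <- toy_dag()
  expect_equal(wang_term_sim(dag, "B", "B"), 1)
  # B is_a A: S_B = {B: 1, A: 0.8}; S_A = {A: 1};
  # sim = (S_A(A) + S_B(A)) / (SV_A + SV_B) = 1.8 / 2.8
  expect_equal(wang_term_sim(dag, "A", "B"), 1.8 / 2.8, tolerance = 1e-12)
  # E part_of C (factor 0.6): S_E = {E: 1, C: 0.6, A: 0.48},
  # S_C = {C: 1, A: 0.8}; shared {C, A} -> (1.6 + 1.28) / (2.08 + 1.8)
  expect_equal(wang_term_sim(dag, "C", "E"), 2.88 / 3.88, tolerance = 1e-12)
  expect_equal(wang_term_sim(dag, "B", "D"), wang_term_sim(dag, "D", "B"))
  # forest with two roots: disjoint ancestor sets score zero
  forest <- build_dag(
    data.frame(id = c("R1", "R2", "X", "Y"), name = "", namespace = ""),
    data.frame(child = c("X", "Y"), parent = c("R1", "R2"), type = "is_a"))
  expect_equal(wang_term_sim(forest, "X", "Y"), 0)
  expect_error(wang_term_sim(dag, "A", "ZZ"), "unknown term",
               class = "snpprio_usage_error")
})

test_that("annotation propagation equals brute-force ancestor traversal", {
  dag <- toy_dag()
  ann <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                    term_id = c("D", "E", "B", "A"))
  corpus <- annotation_corpus(dag, ann)
  expect_setequal(corpus$propagated$g1,
                  unique(c("D", "E", bf_ancestors(dag$edges, "D"),
                           bf_ancestors(dag$edges, "E"))))
  expect_true(all(unlist(corpus$direct) %in% unlist(corpus$propagated)))
  # IC: p(root) = 1, ic(root) = 0, ic non-decreasing parent -> child
  ic <- term_ic(corpus)
  expect_equal(ic$p[["A"]], 1)
  expect_equal(ic$ic[["A"]], 0)
  for (i in seq_len(nrow(dag$edges))) {
    child <- dag$edges$child[i]; parent <- dag$edges$parent[i]
    if (ic$p[[child]] > 0)
      expect_gte(ic$ic[[child]], ic$ic[[parent]])
  }
})

test_that("Rel similarity follows the MICA closed form", {
  dag <- toy_dag()
  # 10 genes with hand-set frequencies: D on 1 gene, B on 5 (4 + D), etc.
  ann <- data.frame(
    gene_id = paste0("g", c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)),
    term_id = c("D", "B", "B", "B", "B", "C", "C", "E", "A", "A"))
  corpus <- annotation_corpus(dag, ann)
  ic <- term_ic(corpus)
  # identity: sim(t, t) = 1 - p(t); p(B) = 5/10 (g1 via D + g2..g5)
  expect_equal(ic$p[["B"]], 0.5)
  expect_equal(rel_term_sim(dag, ic, "B", "B"), 0.5)
  # MICA = root -> 0
  expect_equal(rel_term_sim(dag, ic, "B", "C"), 0)
  # general case against an independent exhaustive search over common
  # ancestors using brute-force ancestor sets
  for (pair in list(c("D", "B"), c("E", "C"), c("D", "E"))) {
    t1 <- pair[1]; t2 <- pair[2]
    common <- intersect(c(t1, bf_ancestors(dag$edges, t1)),
                        c(t2, bf_ancestors(dag$edges, t2)))
    common <- common[ic$p[common] > 0]
    cstar <- common[which.max(ic$ic[common])]
    expected <- 2 * ic$ic[[cstar]] / (ic$ic[[t1]] + ic$ic[[t2]]) *
      (1 - ic$p[[cstar]])
    expect_equal(rel_term_sim(dag, ic, t1, t2), max(0, expected))
  }
  # no corpus support -> 0 with warning
  ann2 <- ann[ann$term_id != "E", ]
  corpus2 <- annotation_corpus(dag, ann2)
  ic2 <- term_ic(corpus2)
  expect_warning(v <- rel_term_sim(dag, ic2, "E", "B"), "support")
  expect_equal(v, 0)
})

test_that("gene similarity is a symmetric best-match average", {
  dag <- toy_dag()
  ann <- data.frame(gene_id = c("gA", "gB", "gB", "gC"),
                    term_id = c("D", "D", "E", "C"))
  corpus <- annotation_corpus(dag, ann)
  # identical annotation sets -> 1
  ann_same <- data.frame(gene_id = c("x", "y"), term_id = c("D", "D"))
  corpus_same <- annotation_corpus(dag, ann_same)
  expect_equal(gene_sim("x", "y", corpus_same, "wang"), 1)
  # gA = {D}, gB = {D, E}: BMA = (1 + (1 + s)/2) / 2 with s = sim(D, E)
  s <- wang_term_sim(dag, "D", "E")
  expect_equal(gene_sim("gA", "gB", corpus, "wang"),
               (1 + (1 + s) / 2) / 2, tolerance = 1e-12)
  # symmetry under both measures
  expect_equal(gene_sim("gA", "gB", corpus, "wang"),
               gene_sim("gB", "gA", corpus, "wang"))
  expect_equal(gene_sim("gA", "gC", corpus, "rel"),
               gene_sim("gC", "gA", corpus, "rel"))
  expect_warning(v <- gene_sim("gA", "unannotated", corpus, "wang"),
                 "without annotation")
  expect_true(is.na(v))
})

test_that("gene-set expansion respects the threshold and is monotone", {
  sim <- shared_sim()
  onto <- simulate_ontology(sim$spec, sim$store, file.path(tempdir(), "onto"))
  dag <- parse_obo(onto$obo)
  corpus <- annotation_corpus(dag, load_annotations(onto$annotations))
  g1 <- sim$store$diseases[[1]]$genes
  expect_error(expand_gene_set(g1, corpus, "wang", threshold = 1.5),
               class = "snpprio_usage_error")
  # threshold 0 admits every annotated gene
  all_genes <- expand_gene_set(g1, corpus, "wang", threshold = 0)
  expect_setequal(all_genes$g2, names(corpus$direct))
  # monotone: higher threshold -> subset
  lo <- expand_gene_set(g1, corpus, "wang", threshold = 0.3)
  hi <- expand_gene_set(g1, corpus, "wang", threshold = 0.7)
  expect_true(all(hi$g2 %in% lo$g2))
  expect_true(all(lo$g1 %in% lo$g2))          # g2 always contains g1
  expect_true(all(lo$added$similarity >= 0.3))
  # top_k caps the number of added genes
  capped <- expand_gene_set(g1, corpus, "wang", threshold = 0, top_k = 2)
  expect_lte(nrow(capped$added), 2)
})

test_that("process terms resolve to their propagated gene sets", {
  dag <- toy_dag()
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    term_id = c("D", "B", "E"))
  corpus <- annotation_corpus(dag, ann)
  # root term covers every annotated gene
  expect_setequal(genes_for_process("A", corpus), c("g1", "g2", "g3"))
  # leaf term: direct annotations only
  expect_equal(genes_for_process("D", corpus), "g1")
  # mid-level term: direct plus descendants, resolved by name too
  expect_setequal(genes_for_process("term B", corpus), c("g1", "g2"))
  expect_error(genes_for_process("no such term", corpus), "not found",
               class = "snpprio_usage_error")
  dag2 <- build_dag(data.frame(id = c("X1", "X2"), name = "same name",
                               namespace = ""),
                    data.frame(child = character(), parent = character(),
                               type = character()))
  corpus2 <- annotation_corpus(dag2, data.frame(gene_id = "g",
                                                term_id = "X1"))
  expect_error(genes_for_process("same name", corpus2), "ambiguous",
               class = "snpprio_usage_error")
})
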