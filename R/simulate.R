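# Synthetic fixture generator: a toy genome with tiled genes, SNPs with
# planted disease signal in a configurable feature registry, per-disease
# benchmarks and a toy ontology with disease-clustered annotations. All
# outputs use the exact reader formats of the annotation store, the ontology
# layer and the optimizer, and are byte-identical under a fixed seed.

#' Simulation specification
#'
#' Defaults emulate the study conditions the optimizer is meant for: a
#' 16-disease panel, 31 binary features of which 5 are informative, certified
#' SNPs carrying an informative feature at rate `p_informative = 0.8` against
#' a background rate `p_background = 0.2`, 40 SNPs per gene, 4 genes per
#' disease and a 100 kb flanking region. Genes tile one chromosome with
#' spacing above twice the flank, so per-disease candidate SNP sets are
#' disjoint (an `overlap_diseases` fraction can relax this by sharing genes
#' between consecutive diseases).
#'
#' @param n_diseases number of disease benchmarks.
#' @param genes_per_disease genes assigned to each disease (disjoint blocks).
#' @param n_genes total genes (default: exactly the disease genes).
#' @param n_snps_per_gene SNPs simulated per gene.
#' @param n_features total features; the first `n_informative` carry signal.
#' @param n_informative informative features.
#' @param p_informative,p_background informative-feature carrier rates for
#'   certified vs other SNPs (`0 <= p_background < p_informative <= 1`).
#' @param certified_per_disease certified SNPs drawn per disease.
#' @param gene_length,gene_gap,flank_bp genome geometry in base pairs.
#' @param continuous_features plant the signal in continuous tracks
#'   (Gaussians shifted between certified and background, min-max normalized)
#'   instead of binary membership tracks.
#' @param overlap_diseases fraction of each disease's genes shared with the
#'   next disease (default 0: disjoint, keeping LOOCV honest).
#' @param ontology_depth,branching toy ontology geometry.
#' @param seed RNG seed.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_diseases = 16, genes_per_disease = 4,
                            n_genes = n_diseases * genes_per_disease,
                            n_snps_per_gene = 40, n_features = 31,
                            n_informative = 5, p_informative = 0.8,
                            p_background = 0.2, certified_per_disease = 10,
                            gene_length = 20000, gene_gap = 10000,
                            flank_bp = 100000, continuous_features = FALSE,
                            overlap_diseases = 0, ontology_depth = 3,
                            branching = 3, seed = 1) {
  if (p_background < 0 || p_background >= p_informative || p_informative > 1)
    stop_usage("need 0 <= p_background < p_informative <= 1")
  counts <- c(n_diseases, genes_per_disease, n_genes, n_snps_per_gene,
              n_features, n_informative, certified_per_disease,
              gene_length, flank_bp)
  if (any(counts <= 0)) stop_usage("all counts must be positive")
  if (n_genes < n_diseases * genes_per_disease * (1 - overlap_diseases))
    stop_usage("n_genes too small for the requested disease panel")
  if (n_informative > n_features)
    stop_usage("n_informative cannot exceed n_features")
  rm(counts)
  structure(as.list(environment()), class = "simulation_spec")
}

sim_feature_names <- function(spec)
  sprintf("feat_%02d", seq_len(spec$n_features))

#' Simulate the annotation store fixtures
#'
#' Writes, under `dir`: `genes.tsv`, `snps.tsv`, one feature track per
#' registry feature under `tracks/` (BED membership tracks for binary
#' features, TSV value tracks for continuous ones), `registry.tsv` and a
#' `manifest.json` recording the spec, the seed and the planted disease
#' assignments. Certified SNPs carry each informative feature at rate
#' `p_informative`; every other SNP (and every noise feature) at
#' `p_background`.
#'
#' @param spec a `simulation_spec`.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the loaded-form `genes`, `snps`,
#'   `registry`, the `diseases` assignment (gene and certified-SNP sets) and
#'   all file `paths`.
#' @export
simulate_store <- function(spec, dir) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  spacing <- spec$gene_length + 2 * spec$flank_bp + spec$gene_gap
  gstart <- spec$flank_bp + (seq_len(spec$n_genes) - 1) * spacing
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(spec$n_genes)),
    symbol = sprintf("GENE%04d", seq_len(spec$n_genes)),
    aliases = sprintf("ALIAS%04d", seq_len(spec$n_genes)),
    chrom = "chr1", start = as.integer(gstart),
    end = as.integer(gstart + spec$gene_length),
    strand = rep(c("+", "-"), length.out = spec$n_genes),
    stringsAsFactors = FALSE)

  # disease gene blocks, optionally sharing a head of the next block
  step <- max(1L, round(spec$genes_per_disease * (1 - spec$overlap_diseases)))
  diseases <- lapply(seq_len(spec$n_diseases), function(d) {
    idx <- ((d - 1) * step) + seq_len(spec$genes_per_disease)
    idx <- ((idx - 1) %% spec$n_genes) + 1
    list(disease_id = sprintf("D%02d", d), gene_idx = idx,
         genes = genes$gene_id[idx])
  })

  n_snps <- spec$n_genes * spec$n_snps_per_gene
  gene_of_snp <- rep(seq_len(spec$n_genes), each = spec$n_snps_per_gene)
  pos <- unlist(lapply(seq_len(spec$n_genes), function(i) {
    lo <- max(genes$start[i] - spec$flank_bp, 0)
    hi <- genes$end[i] + spec$flank_bp - 1
    sort(sample(seq(lo, hi), spec$n_snps_per_gene, replace = FALSE))
  }))
  snps <- data.frame(
    rsid = sprintf("rs%06d", seq_len(n_snps)),
    chrom = "chr1", start = as.integer(pos), end = as.integer(pos + 1),
    strand = "+",
    alleles = paste(sample(c("A", "C", "G", "T"), n_snps, replace = TRUE),
                    sample(c("A", "C", "G", "T"), n_snps, replace = TRUE),
                    sep = "/"),
    function_class = "unknown", stringsAsFactors = FALSE)

  certified <- rep(FALSE, n_snps)
  for (d in seq_along(diseases)) {
    pool <- which(gene_of_snp %in% diseases[[d]]$gene_idx & !certified)
    pick <- sample(pool, min(spec$certified_per_disease, length(pool)))
    certified[pick] <- TRUE
    diseases[[d]]$certified <- snps$rsid[sort(pick)]
  }

  feat_names <- sim_feature_names(spec)
  informative <- feat_names[seq_len(spec$n_informative)]
  kind <- if (spec$continuous_features) "continuous" else "binary"
  registry <- data.frame(
    name = feat_names, section = ifelse(feat_names %in% informative,
                                        "Informative", "Noise"),
    value_kind = kind, context_axis = "",
    min = if (kind == "continuous") 0 else NA_real_,
    max = if (kind == "continuous") 1 else NA_real_,
    weight = 0.5, stringsAsFactors = FALSE)

  track_paths <- character(0)
  for (f in feat_names) {
    rate <- if (f %in% informative)
      ifelse(certified, spec$p_informative, spec$p_background)
    else rep(spec$p_background, n_snps)
    if (spec$continuous_features) {
      # shifted Gaussians: carriers high, the rest low, clipped to [0, 1]
      mu <- 0.25 + 0.5 * rate / spec$p_informative
      value <- round(pmin(pmax(stats::rnorm(n_snps, mu, 0.15), 0), 1), 6)
      path <- file.path(dir, "tracks", paste0(f, ".tsv"))
      write_tsv(data.frame(rsid = snps$rsid, value = value), path)
    } else {
      carrier <- stats::runif(n_snps) < rate
      path <- file.path(dir, "tracks", paste0(f, ".bed"))
      bed <- data.frame(chrom = snps$chrom[carrier],
                        start = snps$start[carrier],
                        end = snps$end[carrier],
                        name = f)
      con <- file(path, "wb")
      utils::write.table(bed, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE, eol = "\n")
      close(con)
    }
    track_paths[f] <- path
  }

  paths <- list(genes = file.path(dir, "genes.tsv"),
                snps = file.path(dir, "snps.tsv"),
                registry = file.path(dir, "registry.tsv"),
                tracks = track_paths,
                manifest = file.path(dir, "manifest.json"))
  write_tsv(genes, paths$genes)
  write_tsv(snps, paths$snps)
  write_tsv(registry, paths$registry)
  manifest <- list(
    spec = unclass(spec), seed = spec$seed,
    informative_features = informative,
    diseases = lapply(diseases, function(d)
      list(disease_id = d$disease_id, genes = d$genes,
           certified = d$certified)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  class(registry) <- c("feature_registry", "data.frame")
  class(genes) <- c("gene_table", "data.frame")
  class(snps) <- c("snp_table", "data.frame")
  invisible(list(spec = spec, genes = genes, snps = snps,
                 registry = registry, diseases = diseases,
                 informative = informative, paths = paths))
}

#' Write per-disease benchmark files
#'
#' One TSV per disease (`disease_id`, comma-separated `genes`, `certified`),
#' in the format [load_benchmarks()] reads. Certified SNPs lie within the
#' flank of the disease's genes by construction, so `A` is a subset of `S`.
#'
#' @param store result of [simulate_store()].
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
simulate_benchmarks <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(store$diseases, function(d) {
    path <- file.path(dir, paste0(d$disease_id, ".tsv"))
    write_tsv(data.frame(disease_id = d$disease_id,
                         genes = paste(d$genes, collapse = ","),
                         certified = paste(d$certified, collapse = ",")),
              path)
    path
  }, "")
  invisible(paths)
}

#' Simulate a toy ontology and annotation corpus
#'
#' Builds a rooted balanced DAG (`1 + b + ... + b^depth` terms, mostly
#' `is_a` edges with a sprinkling of `part_of`) and annotates each disease's
#' genes around a disease-specific anchor leaf, so within-disease gene
#' similarity exceeds between-disease similarity in expectation. Written as
#' an OBO 1.2 file plus a `gene_id`/`term_id` TSV.
#'
#' @param spec a `simulation_spec` (`ontology_depth >= 2`).
#' @param store result of [simulate_store()].
#' @param dir output directory.
#' @return invisibly, list with `obo` and `annotations` paths.
#' @export
simulate_ontology <- function(spec, store, dir) {
  if (spec$ontology_depth < 2) stop_usage("ontology_depth must be >= 2")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(spec$seed, "ontology"))
  b <- spec$branching
  levels <- lapply(0:spec$ontology_depth, function(l) b^l)
  n_terms <- sum(unlist(levels))
  ids <- sprintf("TOY:%07d", seq_len(n_terms))
  parent <- rep(NA_integer_, n_terms)
  level_of <- integer(n_terms)
  offset <- 1L
  for (l in seq_len(spec$ontology_depth)) {
    prev_start <- offset - b^(l - 1) + 1L
    for (j in seq_len(b^l)) {
      node <- offset + j
      parent[node] <- prev_start + ((j - 1) %/% b)
      level_of[node] <- l
    }
    offset <- offset + b^l
  }
  edge_type <- ifelse(seq_len(n_terms) %% 7 == 0, "part_of", "is_a")

  obo_path <- file.path(dir, "ontology.obo")
  con <- file(obo_path, "wb")
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(n_terms)) {
    stanza <- c("[Term]",
                paste0("id: ", ids[i]),
                paste0("name: toy term ", i),
                "namespace: biological_process")
    if (!is.na(parent[i])) {
      stanza <- c(stanza, if (edge_type[i] == "is_a")
        paste0("is_a: ", ids[parent[i]], " ! toy term ", parent[i])
        else paste0("relationship: part_of ", ids[parent[i]]))
    }
    writeLines(c(stanza, ""), con)
  }
  close(con)

  leaves <- which(level_of == spec$ontology_depth)
  if (length(leaves) < spec$n_diseases)
    stop_usage("too few leaf terms for the disease panel; increase depth or ",
               "branching")
  anchors <- leaves[seq_len(spec$n_diseases)]
  rows <- list()
  annotate <- function(gene, terms)
    rows[[length(rows) + 1]] <<- data.frame(gene_id = gene,
                                            term_id = ids[terms],
                                            stringsAsFactors = FALSE)
  assigned <- unique(unlist(lapply(store$diseases, `[[`, "genes")))
  for (d in seq_along(store$diseases)) {
    anchor <- anchors[d]
    siblings <- setdiff(leaves[parent[leaves] == parent[anchor]], anchor)
    for (gene in store$diseases[[d]]$genes) {
      extra <- c(if (length(siblings) > 0) sample(siblings, 1),
                 sample(leaves, 1))
      annotate(gene, unique(c(anchor, extra)))
    }
  }
  for (gene in setdiff(store$genes$gene_id, assigned))
    annotate(gene, sample(leaves, 2))
  ann <- unique(do.call(rbind, rows))
  ann_path <- file.path(dir, "annotations.tsv")
  write_tsv(ann, ann_path)
  invisible(list(obo = obo_path, annotations = ann_path))
}
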