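# Pipeline entry points tying the modules together: rank (extract ->
# optional ontological expansion -> score -> rank -> cut), optimize (LOOCV
# grid + final weight learning) and enrich. Every run writes a provenance
# log (config, seed, input manifests) next to its outputs.

#' Validate a run configuration
#'
#' A configuration is a plain list; this checks the fields shared by the
#' pipeline commands: exactly one input mode (`genes`, `snps` or `process`),
#' flanking distance, expansion settings and weight overrides in `[0, 1]`.
#'
#' @param config named list; see [cmd_rank()] for recognized fields.
#' @return the validated config (with defaults filled in).
#' @export
run_config <- function(config) {
  config$input_mode <- match.arg(config$input_mode %||% "genes",
                                 c("genes", "snps", "process"))
  config$flank_bp <- config$flank_bp %||% 100000
  config$expansion <- match.arg(config$expansion %||% "off",
                                c("off", "wang", "rel"))
  config$threshold <- config$threshold %||% 0.5
  if (config$threshold < 0 || config$threshold > 1)
    stop_usage("expansion threshold must lie in [0, 1]")
  config$percentile <- config$percentile %||% 100
  config$seed <- as.integer(config$seed %||% 1)
  if (!is.null(config$weight_overrides)) {
    w <- unlist(config$weight_overrides)
    if (any(w < 0 | w > 1)) stop_usage("weight overrides must lie in [0, 1]")
  }
  config
}

#' Load an annotation store directory
#'
#' Expects the layout written by [simulate_store()] (or assembled by hand):
#' `genes.tsv`, `snps.tsv`, `registry.tsv` and one track per feature under
#' `tracks/` (`<feature>.bed` or `<feature>.tsv`).
#'
#' @param dir store directory.
#' @return list with `genes`, `snps`, `registry` and `track_paths`.
#' @export
load_store <- function(dir) {
  for (f in c("genes.tsv", "snps.tsv", "registry.tsv"))
    if (!file.exists(file.path(dir, f)))
      stop_usage("annotation store is missing ", f, " under ", dir)
  registry <- load_feature_registry(file.path(dir, "registry.tsv"))
  track_paths <- stats::setNames(vapply(registry$name, function(f) {
    for (ext in c(".bed", ".tsv")) {
      p <- file.path(dir, "tracks", paste0(f, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }, ""), registry$name)
  list(genes = load_gene_table(file.path(dir, "genes.tsv")),
       snps = load_snp_table(file.path(dir, "snps.tsv")),
       registry = registry,
       track_paths = track_paths[!is.na(track_paths)])
}

# Assemble + normalize the feature matrix for a SNP subset of a store.
store_feature_scores <- function(store, snps, category_scores, context = NULL) {
  tracks <- lapply(names(store$track_paths), function(f)
    load_feature_track(store$track_paths[[f]],
                       store$registry[store$registry$name == f, ], snps))
  fm <- build_feature_matrix(snps, tracks, store$registry)
  normalize_matrix(fm, store$registry, category_scores, context)
}

write_provenance <- function(out_dir, command, config, extra = list()) {
  log <- c(list(command = command, timestamp = format(Sys.time(), tz = "UTC"),
                package_version = as.character(utils::packageVersion("snpprio")),
                config = config[!vapply(config, is.function, logical(1))]),
           extra)
  path <- file.path(out_dir, paste0(command, "_provenance.json"))
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' Rank SNPs for an input gene list, SNP list or process term
#'
#' Pipeline: extract the SNPs related to the selected genes (or biological
#' process), run the ontological expansion if requested, then score every
#' SNP with the selected features and weights, rank, cut at the percentile
#' and write the output table (plus a gzip variant when `gzip = TRUE`).
#'
#' Config fields: `store_dir`, `input_mode`, `input_tokens`, `flank_bp`,
#' `expansion` + `threshold` (+ `obo`, `annotations` paths when expansion or
#' process input is used), `selected_features`, `weight_overrides`,
#' `weights_path` (registry-format TSV replacing the store defaults),
#' `percentile`, `context`, `gzip`, `seed`, `out_dir`.
#'
#' @param config validated by [run_config()].
#' @return invisibly, list with the `ranked` table and output `paths`.
#' @export
cmd_rank <- function(config) {
  config <- run_config(config)
  store <- load_store(config$store_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- NULL
  if (config$expansion != "off" || config$input_mode == "process") {
    if (is.null(config$obo) || is.null(config$annotations))
      stop_usage("expansion/process input needs obo and annotations paths")
    dag <- parse_obo(config$obo)
    corpus <- annotation_corpus(dag, load_annotations(config$annotations))
  }
  expansion <- NULL
  if (config$input_mode == "snps") {
    rsids <- trimws_split(config$input_tokens)
    missing_rs <- setdiff(rsids, store$snps$rsid)
    if (length(missing_rs) > 0)
      stop_usage("unknown SNP id(s): ", paste(missing_rs, collapse = ", "))
    snps <- store$snps[store$snps$rsid %in% rsids, , drop = FALSE]
    gene_ids <- character(0)
    map <- map_snps_to_genes(snps, store$genes, config$flank_bp)
  } else {
    gene_ids <- if (config$input_mode == "genes") {
      res <- resolve_gene_ids(config$input_tokens, store$genes)
      if (length(res$unresolved) > 0)
        warning("unresolved gene token(s): ",
                paste(res$unresolved, collapse = ", "), call. = FALSE)
      res$resolved$gene_id
    } else {
      genes_for_process(config$input_tokens, corpus)
    }
    if (config$expansion != "off") {
      expansion <- expand_gene_set(gene_ids, corpus,
                                   measure = config$expansion,
                                   threshold = config$threshold)
      gene_ids <- expansion$g2
    }
    gene_ids <- intersect(gene_ids, store$genes$gene_id)
    if (length(gene_ids) == 0) stop_usage("no input genes found in the store")
    genes <- store$genes[store$genes$gene_id %in% gene_ids, , drop = FALSE]
    map <- map_snps_to_genes(store$snps, genes, config$flank_bp)
    snps <- store$snps[store$snps$rsid %in% map$rsid, , drop = FALSE]
    if (nrow(snps) == 0) stop_usage("no SNPs fall within the input genes")
  }
  category_scores <- if (is.null(config$category_scores))
    load_category_scores() else load_category_scores(config$category_scores)
  fnorm <- store_feature_scores(store, snps, category_scores, config$context)
  weights <- if (!is.null(config$weights_path))
    registry_weights(load_feature_registry(config$weights_path))
  else registry_weights(store$registry)
  for (f in names(config$weight_overrides))
    weights[f] <- config$weight_overrides[[f]]
  selected <- config$selected_features %||% names(weights)
  sigma <- score_snp(fnorm, weights, selected)
  gene_col <- vapply(snps$rsid, function(rs)
    paste(sort(map$gene_id[map$rsid == rs]), collapse = ","), "")
  scored <- data.frame(rsid = snps$rsid, genes = gene_col,
                       chrom = snps$chrom, position = snps$start,
                       function_class = snps$function_class,
                       sigma = unname(sigma), stringsAsFactors = FALSE)
  scored <- cbind(scored, as.data.frame(fnorm[, selected, drop = FALSE],
                                        check.names = FALSE))
  ranked <- percentile_cut(rank_snps(scored), config$percentile)
  out <- file.path(config$out_dir, "ranked_snps.tsv")
  write_ranked_table(ranked, out)
  paths <- list(ranked = out)
  if (isTRUE(config$gzip)) {
    paths$gz <- paste0(out, ".gz")
    write_ranked_table(ranked, paths$gz)
  }
  paths$provenance <- write_provenance(
    config$out_dir, "rank", config,
    list(n_snps = nrow(ranked), n_genes = length(unique(map$gene_id)),
         expansion_added = if (is.null(expansion)) 0
                           else nrow(expansion$added)))
  invisible(list(ranked = ranked, expansion = expansion, paths = paths))
}

#' Learn feature weights against disease benchmarks
#'
#' Runs the LOOCV (epsilon, Tr) grid over the benchmark panel, writes the
#' per-cell grid report, then learns final weights on the full panel at the
#' configured `epsilon`/`Tr` and writes them in registry format.
#'
#' Config fields: `store_dir`, `benchmark_dir`, `flank_bp`, `epsilon_grid`,
#' `tr_grid`, `ga` (a [ga_config()]), `seed`, `out_dir`.
#'
#' @param config validated by [run_config()].
#' @return invisibly, list with the `report`, learned `weights` and output
#'   `paths`.
#' @export
cmd_optimize <- function(config) {
  config <- run_config(config)
  store <- load_store(config$store_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  map <- map_snps_to_genes(store$snps, store$genes, config$flank_bp)
  benchmarks <- load_benchmarks(config$benchmark_dir, map)
  if (length(benchmarks) < 2)
    stop_usage("optimization needs at least 2 disease benchmarks")
  fnorm <- store_feature_scores(store, store$snps, load_category_scores())
  data <- prepare_ga_data(benchmarks, fnorm)
  ga <- config$ga %||% ga_config(seed = config$seed)
  report <- loocv_grid(data,
                       epsilon_grid = config$epsilon_grid %||%
                         seq(0.1, 1.0, by = 0.1),
                       tr_grid = config$tr_grid %||% c(0.25, 0.5, 0.75, 1.0),
                       config = ga)
  paths <- list(grid = file.path(config$out_dir, "grid_report.tsv"),
                runs = file.path(config$out_dir, "grid_runs.tsv"),
                weights = file.path(config$out_dir, "learned_weights.tsv"))
  write_grid_report(report, paths$grid)
  write_tsv(report$runs, paths$runs)
  final <- run_ga(data, ga)
  weights <- stats::setNames(final$best, store$registry$name)
  write_weight_config(store$registry, weights, paths$weights)
  paths$provenance <- write_provenance(
    config$out_dir, "optimize", config,
    list(n_runs = nrow(report$runs), best_fitness = final$best_fitness))
  invisible(list(report = report, weights = weights, best = final,
                 paths = paths))
}

#' Enrichment of a ranked SNP table
#'
#' Reads a ranked table written by [cmd_rank()], truncates at the percentile
#' and tests the genes carrying the surviving SNPs against each configured
#' category map (one output TSV per source).
#'
#' Config fields: `store_dir`, `flank_bp`, `percentile`, `category_maps`
#' (named list of lists with `path`, `source`, `format`), `out_dir`.
#'
#' @param config validated by [run_config()].
#' @param ranked_path path to a ranked table TSV.
#' @return invisibly, named list of `enrichment_result` objects.
#' @export
cmd_enrich <- function(config, ranked_path) {
  config <- run_config(config)
  if (!file.exists(ranked_path))
    stop_usage("ranked table not found: ", ranked_path)
  if (is.null(config$category_maps) || length(config$category_maps) == 0)
    stop_usage("no category maps configured")
  store <- load_store(config$store_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ranked <- read_tsv(ranked_path)
  class(ranked) <- c("ranked_snps", "data.frame")
  snps <- store$snps[store$snps$rsid %in% ranked$rsid, , drop = FALSE]
  map <- map_snps_to_genes(snps, store$genes, config$flank_bp)
  results <- list()
  for (name in names(config$category_maps)) {
    cm_cfg <- config$category_maps[[name]]
    cm <- load_category_map(cm_cfg$path, source = cm_cfg$source %||% "pathway",
                            format = cm_cfg$format %||% "gmt")
    res <- enrich_top(ranked, config$percentile, cm, map)
    write_tsv(as.data.frame(res),
              file.path(config$out_dir, paste0("enrichment_", name, ".tsv")))
    results[[name]] <- res
  }
  write_provenance(config$out_dir, "enrich", config,
                   list(sources = names(results),
                        n_tests = vapply(results, nrow, 0L)))
  invisible(results)
}
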