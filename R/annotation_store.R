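# Annotation store: gene and SNP tables, flanking-region SNP-gene association
# and assembly of the raw feature matrix. Internal coordinates are 0-based
# half-open throughout; readers convert on the way in.

#' Load a gene interval table
#'
#' Accepts either a BED4+ file (0-based half-open, as produced by UCSC-style
#' tools; the `name` column is taken as the gene symbol) or a TSV with header
#' columns `gene_id`, `symbol`, `aliases` (pipe-separated), `chrom`, `start`,
#' `end`, `strand` and optionally `coordinate_convention`
#' (`0based-halfopen`, the default, or `1based-inclusive`).
#'
#' @param path input file.
#' @param format `"tsv"` or `"bed"`.
#' @return a `gene_table` data frame with 0-based half-open `start`/`end`.
#' @export
load_gene_table <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_usage("gene table not found: ", path)
  if (format == "bed") {
    if (file.size(path) == 0) return(empty_gene_table())
    gr <- rtracklayer::import(path, format = "bed")
    genes <- data.frame(
      gene_id = as.character(gr$name),
      symbol = as.character(gr$name),
      aliases = "",
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based inclusive
      end = GenomicRanges::end(gr),
      strand = sub("\\*", "?", as.character(GenomicRanges::strand(gr))),
      stringsAsFactors = FALSE)
  } else {
    tab <- read_tsv(path)
    if (nrow(tab) == 0) return(empty_gene_table())
    required <- c("gene_id", "symbol", "chrom", "start", "end")
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols) > 0)
      stop_usage("gene table is missing columns: ",
                 paste(missing_cols, collapse = ", "))
    start <- suppressWarnings(as.integer(tab$start))
    end <- suppressWarnings(as.integer(tab$end))
    bad <- which(is.na(start) | is.na(end) | !nzchar(tab$chrom) |
                   !nzchar(tab$symbol))
    if (length(bad) > 0)
      stop_usage("malformed gene row at line ", bad[1] + 1L)  # +1 for header
    convention <- if ("coordinate_convention" %in% names(tab))
      tab$coordinate_convention else rep("0based-halfopen", nrow(tab))
    genes <- tab[, intersect(c("gene_id", "symbol", "aliases", "chrom",
                               "strand"), names(tab)), drop = FALSE]
    if (is.null(genes$aliases)) genes$aliases <- ""
    if (is.null(genes$strand)) genes$strand <- "?"
    genes$aliases[is.na(genes$aliases)] <- ""
    for (i in seq_len(nrow(tab))) {
      cc <- to_internal_coords(start[i], end[i], convention[i])
      start[i] <- cc$start; end[i] <- cc$end
    }
    genes$start <- start
    genes$end <- end
    genes <- genes[, c("gene_id", "symbol", "aliases", "chrom", "start",
                       "end", "strand")]
  }
  genes$gene_id <- as.character(genes$gene_id)
  if (anyDuplicated(genes$gene_id))
    stop_integrity("duplicate gene_id in gene table: ",
                   genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(genes$start < 0) || any(genes$end <= genes$start))
    stop_integrity("invalid gene interval (need 0 <= start < end)")
  class(genes) <- c("gene_table", "data.frame")
  genes
}

empty_gene_table <- function() {
  genes <- data.frame(gene_id = character(), symbol = character(),
                      aliases = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  class(genes) <- c("gene_table", "data.frame")
  genes
}

#' Load a SNP table
#'
#' TSV input has header columns `rsid`, `chrom`, `start`, `end`, `strand`,
#' `alleles` (slash-separated), `function_class`; coordinates are the internal
#' 0-based half-open pair, so every SNP has `end - start = 1`. VCF input
#' (1-based `POS`, converted on read) requires a non-missing `ID`; records
#' with `ID == "."` are rejected and counted. Rejected-row counts are attached
#' as attribute `n_rejected` and reported via a warning, never silently
#' dropped.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return a `snp_table` data frame.
#' @export
load_snp_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_usage("SNP table not found: ", path)
  if (format == "tsv") {
    tab <- read_tsv(path)
    required <- c("rsid", "chrom", "start", "end")
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols) > 0)
      stop_usage("SNP table is missing columns: ",
                 paste(missing_cols, collapse = ", "))
    if (is.null(tab$strand)) tab$strand <- "?"
    if (is.null(tab$alleles)) tab$alleles <- ""
    if (is.null(tab$function_class)) tab$function_class <- "unknown"
    keep <- !is.na(tab$rsid) & nzchar(trimws(tab$rsid))
    n_rejected <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    snps <- data.frame(rsid = as.character(tab$rsid),
                       chrom = as.character(tab$chrom),
                       start = as.integer(tab$start),
                       end = as.integer(tab$end),
                       strand = as.character(tab$strand),
                       alleles = as.character(tab$alleles),
                       function_class = as.character(tab$function_class),
                       stringsAsFactors = FALSE)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    keep <- !is.na(fix$ID) & fix$ID != "." & nzchar(fix$ID)
    n_rejected <- sum(!keep)
    fix <- fix[keep, , drop = FALSE]
    pos <- as.integer(fix$POS)
    alt <- gsub(",", "/", ifelse(is.na(fix$ALT), "", fix$ALT))
    snps <- data.frame(rsid = fix$ID,
                       chrom = fix$CHROM,
                       start = pos - 1L,  # VCF POS is 1-based
                       end = pos,
                       strand = "?",
                       alleles = paste(fix$REF, alt, sep = "/"),
                       function_class = "unknown",
                       stringsAsFactors = FALSE)
  }
  if (anyDuplicated(snps$rsid))
    stop_integrity("duplicate rsid in SNP table: ",
                   snps$rsid[duplicated(snps$rsid)][1])
  if (nrow(snps) > 0 && any(snps$end - snps$start != 1L))
    stop_integrity("SNP loci must have length 1")
  if (n_rejected > 0)
    warning(n_rejected, " SNP row(s) without an identifier were rejected",
            call. = FALSE)
  attr(snps, "n_rejected") <- n_rejected
  class(snps) <- c("snp_table", "data.frame")
  snps
}

#' Resolve gene identifier tokens against a gene table
#'
#' Tokens (comma-separated gene IDs or symbols) are matched
#' case-insensitively against `gene_id` first, then `symbol`, then the
#' pipe-separated `aliases`, in that priority. Unmatched tokens are returned,
#' never silently dropped.
#'
#' @param tokens comma-separated identifier string (or character vector).
#' @param genes a `gene_table`.
#' @return `list(resolved = gene_table rows, unresolved = character)`.
#' @export
resolve_gene_ids <- function(tokens, genes) {
  toks <- if (length(tokens) == 1) trimws_split(tokens) else trimws(tokens)
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) stop_usage("no input genes: empty token string")
  lower_id <- tolower(genes$gene_id)
  lower_sym <- tolower(genes$symbol)
  alias_list <- lapply(strsplit(genes$aliases %||% "", "|", fixed = TRUE),
                       function(a) tolower(trimws(a)))
  hit <- vapply(tolower(toks), function(tok) {
    i <- match(tok, lower_id)
    if (is.na(i)) i <- match(tok, lower_sym)
    if (is.na(i)) {
      j <- which(vapply(alias_list, function(a) tok %in% a, logical(1)))
      i <- if (length(j) > 0) j[1] else NA_integer_
    }
    i
  }, integer(1))
  unresolved <- toks[is.na(hit)]
  resolved <- genes[unique(hit[!is.na(hit)]), , drop = FALSE]
  if (nrow(resolved) == 0)
    stop_usage("no input genes: none of the tokens resolved (",
               paste(unresolved, collapse = ", "), ")")
  rownames(resolved) <- NULL
  list(resolved = resolved, unresolved = unresolved)
}

#' Associate SNPs with genes through flanking regions
#'
#' A SNP is paired with every gene whose interval, extended by `flank_bp`
#' bases on each side (clipped at zero), overlaps the SNP position. Strand is
#' ignored; a SNP inside two genes' flanks keeps both associations.
#'
#' @param snps a `snp_table`.
#' @param genes a `gene_table`.
#' @param flank_bp non-negative flanking distance in base pairs
#'   (default 100000).
#' @return a `gene_snp_map` data frame with columns `gene_id`, `rsid`.
#' @export
map_snps_to_genes <- function(snps, genes, flank_bp = 100000) {
  if (length(flank_bp) != 1 || is.na(flank_bp) || flank_bp < 0)
    stop_usage("flank_bp must be a single non-negative number")
  empty <- data.frame(gene_id = character(), rsid = character(),
                      stringsAsFactors = FALSE)
  if (nrow(snps) == 0 || nrow(genes) == 0) {
    attr(empty, "flank_bp") <- flank_bp
    class(empty) <- c("gene_snp_map", "data.frame")
    return(empty)
  }
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$start - flank_bp, 0) + 1L,
                     end = genes$end + flank_bp))
  snp_gr <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(start = snps$start + 1L, end = snps$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr, ignore.strand = TRUE)
  map <- data.frame(
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    rsid = snps$rsid[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  map <- map[order(map$gene_id, map$rsid), , drop = FALSE]
  rownames(map) <- NULL
  attr(map, "flank_bp") <- flank_bp
  class(map) <- c("gene_snp_map", "data.frame")
  map
}

#' Load a feature annotation track
#'
#' Binary features come as BED interval tracks: a SNP overlapping any interval
#' gets raw value 1, otherwise 0. When the feature has a context axis
#' (tissue / cell line), the BED `name` column labels the context and one
#' membership value is produced per context. Continuous and categorical
#' features come as TSV tracks with columns `rsid`, `value` and optionally
#' `context`.
#'
#' @param path track file.
#' @param feature one registry row (data frame or list) for the feature.
#' @param snps a `snp_table` (needed to evaluate interval membership).
#' @return long data frame `rsid`, `value`, `context` with attribute
#'   `feature`.
#' @export
load_feature_track <- function(path, feature, snps) {
  if (is.data.frame(feature)) {
    if (nrow(feature) != 1) stop_usage("feature must be a single registry row")
    feature <- as.list(feature)
  }
  if (is.null(feature$name) || is.null(feature$value_kind))
    stop_integrity("unknown feature: not a registry entry")
  kind <- feature$value_kind
  has_context <- !is.null(feature$context_axis) &&
    nzchar(feature$context_axis %||% "")
  if (kind == "binary") {
    snp_gr <- GenomicRanges::GRanges(
      snps$chrom, IRanges::IRanges(start = snps$start + 1L, end = snps$end))
    gr <- if (file.size(path) > 0) rtracklayer::import(path, format = "bed")
          else GenomicRanges::GRanges()
    if (has_context && length(gr) > 0) {
      contexts <- sort(unique(as.character(gr$name)))
      out <- do.call(rbind, lapply(contexts, function(ctx) {
        sub <- gr[as.character(gr$name) == ctx]
        hit <- IRanges::overlapsAny(snp_gr, sub, ignore.strand = TRUE)
        data.frame(rsid = snps$rsid, value = as.numeric(hit), context = ctx,
                   stringsAsFactors = FALSE)
      }))
    } else {
      hit <- if (length(gr) > 0)
        IRanges::overlapsAny(snp_gr, gr, ignore.strand = TRUE)
      else rep(FALSE, nrow(snps))
      out <- data.frame(rsid = snps$rsid, value = as.numeric(hit),
                        context = "", stringsAsFactors = FALSE)
    }
  } else {
    tab <- read_tsv(path)
    if (!all(c("rsid", "value") %in% names(tab)))
      stop_usage("value track needs columns rsid, value: ", path)
    out <- data.frame(rsid = as.character(tab$rsid),
                      value = if (kind == "continuous") as.numeric(tab$value)
                              else as.character(tab$value),
                      context = as.character(tab$context %||% ""),
                      stringsAsFactors = FALSE)
    out$context[is.na(out$context)] <- ""
  }
  attr(out, "feature") <- feature$name
  out
}

#' Assemble the raw feature matrix
#'
#' Builds the SNPs-by-features matrix of raw annotation values. Features
#' without any loaded track stay missing (`NA`), never zero: the distinction
#' between "no evidence collected" and "evidence of absence" collapses only
#' at normalization. Contextual sub-values (per tissue / cell line) are kept
#' on a separate axis.
#'
#' The categorical localization feature is filled directly from the SNP
#' table's `function_class` unless a track overrides it.
#'
#' @param snps a `snp_table`.
#' @param tracks list of long track data frames from [load_feature_track()].
#' @param registry a `feature_registry`.
#' @return a `feature_matrix`: list with `raw` (data frame, one typed column
#'   per feature), `contexts` (per-feature numeric matrices) and `snps`.
#' @export
build_feature_matrix <- function(snps, tracks, registry) {
  track_names <- vapply(tracks, function(t) attr(t, "feature"), "")
  unknown <- setdiff(track_names, registry$name)
  if (length(unknown) > 0)
    stop_integrity("track(s) reference unregistered feature(s): ",
                   paste(unknown, collapse = ", "))
  n <- nrow(snps)
  raw <- as.data.frame(stats::setNames(
    lapply(registry$value_kind,
           function(k) if (k == "categorical") rep(NA_character_, n)
                       else rep(NA_real_, n)),
    registry$name), check.names = FALSE, stringsAsFactors = FALSE)
  contexts <- list()
  loc <- registry$name[registry$value_kind == "categorical"]
  for (feat in loc)      # localization classes travel with the SNP table
    raw[[feat]] <- snps$function_class
  for (t in tracks) {
    feat <- attr(t, "feature")
    ctx_vals <- unique(t$context)
    if (length(ctx_vals) == 1 && ctx_vals == "") {
      idx <- match(t$rsid, snps$rsid)
      ok <- !is.na(idx)
      raw[[feat]][idx[ok]] <- t$value[ok]
    } else {
      ctx_vals <- sort(ctx_vals[nzchar(ctx_vals)])
      m <- matrix(NA_real_, n, length(ctx_vals),
                  dimnames = list(snps$rsid, ctx_vals))
      for (ctx in ctx_vals) {
        sub <- t[t$context == ctx, , drop = FALSE]
        idx <- match(sub$rsid, snps$rsid)
        ok <- !is.na(idx)
        m[idx[ok], ctx] <- as.numeric(sub$value[ok])
      }
      contexts[[feat]] <- m
      raw[[feat]] <- rowMeans(m, na.rm = TRUE)  # headline value; axis kept
      raw[[feat]][is.nan(raw[[feat]])] <- NA_real_
    }
  }
  structure(list(raw = raw, contexts = contexts, snps = snps$rsid,
                 features = registry$name),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", length(x$snps), "SNPs x", length(x$features),
      "features;", length(x$contexts), "contextual feature(s)\n")
  invisible(x)
}

#' Write / read a feature matrix as long TSV
#'
#' Serialization is long-format (`rsid`, `feature`, `value`, `context`) so
#' mixed value types and the context axis survive a round trip. Missing
#' values are omitted from the file and reappear as `NA` on read.
#'
#' @param fm a `feature_matrix`.
#' @param path TSV path.
#' @param snps,registry the SNP table and registry used to rebuild.
#' @return the path / the rebuilt `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  rows <- list()
  for (feat in fm$features) {
    if (feat %in% names(fm$contexts)) {
      m <- fm$contexts[[feat]]
      for (ctx in colnames(m)) {
        v <- m[, ctx]
        keep <- !is.na(v)
        if (any(keep))
          rows[[length(rows) + 1]] <- data.frame(
            rsid = fm$snps[keep], feature = feat, value = v[keep],
            context = ctx, stringsAsFactors = FALSE)
      }
    } else {
      v <- fm$raw[[feat]]
      keep <- !is.na(v)
      if (any(keep))
        rows[[length(rows) + 1]] <- data.frame(
          rsid = fm$snps[keep], feature = feat, value = as.character(v[keep]),
          context = "", stringsAsFactors = FALSE)
    }
  }
  long <- if (length(rows) > 0) do.call(rbind, rows)
    else data.frame(rsid = character(), feature = character(),
                    value = character(), context = character())
  write_tsv(long, path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, snps, registry) {
  long <- read_tsv(path, colClasses = "character")
  if (nrow(long) == 0)
    return(build_feature_matrix(snps, list(), registry))
  long$context[is.na(long$context)] <- ""
  tracks <- lapply(split(long, long$feature), function(sub) {
    kind <- registry$value_kind[match(sub$feature[1], registry$name)]
    out <- data.frame(rsid = sub$rsid,
                      value = if (kind == "categorical") sub$value
                              else as.numeric(sub$value),
                      context = sub$context, stringsAsFactors = FALSE)
    attr(out, "feature") <- sub$feature[1]
    out
  })
  fm <- build_feature_matrix(snps, unname(tracks), registry)
  fm
}
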