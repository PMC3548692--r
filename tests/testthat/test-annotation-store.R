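# Gene/SNP table loading, identifier resolution, flanking-region mapping and
# feature-matrix assembly.

test_that("gene tables load from BED and TSV with coordinate conversion", {
  bed <- write_fixture("chr13\t72000000\t73500000\tKLF12", ext = ".bed")
  genes <- load_gene_table(bed, format = "bed")
  expect_equal(genes$symbol, "KLF12")
  expect_equal(genes$start, 72000000)
  expect_equal(genes$end, 73500000)

  empty <- write_fixture(character(0), ext = ".bed")
  expect_equal(nrow(load_gene_table(empty, format = "bed")), 0)

  # 1-based inclusive TSV: internal start = column start - 1, end unchanged
  tsv1 <- write_fixture(c(
    "gene_id\tsymbol\taliases\tchrom\tstart\tend\tstrand\tcoordinate_convention",
    "1\tGA\t\tchr1\t101\t200\t+\t1based-inclusive",
    "2\tGB\t\tchr1\t501\t600\t-\t1based-inclusive",
    "3\tGC\t\tchr2\t11\t40\t+\t1based-inclusive"))
  genes1 <- load_gene_table(tsv1)
  expect_equal(genes1$start, c(100, 500, 10))
  expect_equal(genes1$end, c(200, 600, 40))
  # converting back to 1-based inclusive is the identity on the columns
  back <- from_internal <- Map(function(s, e)
    snpprio:::from_internal_coords(s, e, "1based-inclusive"),
    genes1$start, genes1$end)
  expect_equal(vapply(back, `[[`, 0L, "start"), c(101L, 501L, 11L))
  expect_equal(vapply(back, `[[`, 0L, "end"), c(200L, 600L, 40L))
})

test_that("gene table integrity errors name the problem", {
  dup <- write_fixture(c("gene_id\tsymbol\taliases\tchrom\tstart\tend\tstrand",
                         "1\tGA\t\tchr1\t0\t10\t+",
                         "1\tGB\t\tchr1\t20\t30\t+"))
  expect_error(load_gene_table(dup), "duplicate gene_id",
               class = "snpprio_integrity_error")
  bad <- write_fixture(c("gene_id\tsymbol\taliases\tchrom\tstart\tend\tstrand",
                         "1\tGA\t\tchr1\tzzz\t10\t+"))
  expect_error(load_gene_table(bad), "line 2", class = "snpprio_usage_error")
})

test_that("SNP tables load from TSV and VCF, rejecting rows without an id", {
  snps <- load_snp_table(tiny_snp_tsv())
  expect_equal(nrow(snps), 3)
  row <- snps[snps$rsid == "rs1886512", ]
  expect_equal(row$chrom, "13")
  expect_equal(row$start, 73418186)
  expect_equal(row$end, 73418187)
  expect_equal(row$alleles, "A/T")
  expect_equal(row$function_class, "intron")

  vcf <- write_fixture(ext = ".vcf", c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "13\t73418187\trs1886512\tA\tT\t.\t.\t.",
    "13\t73418200\t.\tG\tC\t.\t.\t.",
    "11\t13250481\trs900145\tA\tG,T\t.\t.\t."))
  expect_warning(vsnps <- load_snp_table(vcf, format = "vcf"),
                 "1 SNP row")
  expect_equal(attr(vsnps, "n_rejected"), 1)          # ID "." rejected
  expect_equal(nrow(vsnps), 2)                        # no silent drops
  expect_equal(vsnps$start[vsnps$rsid == "rs1886512"], 73418186)
  expect_equal(vsnps$alleles[vsnps$rsid == "rs900145"], "A/G/T")

  dup <- write_fixture(c("rsid\tchrom\tstart\tend",
                         "rs1\tchr1\t5\t6", "rs2\tchr1\t9\t10",
                         "rs1\tchr1\t15\t16"))
  expect_error(load_snp_table(dup), "duplicate rsid",
               class = "snpprio_integrity_error")
})

test_that("gene id resolution is case-insensitive with id > symbol > alias priority", {
  genes <- load_gene_table(tiny_gene_tsv())
  r <- resolve_gene_ids("BCL2", genes)
  expect_equal(nrow(r$resolved), 1)
  expect_equal(r$resolved$symbol, "BCL2")
  expect_length(r$unresolved, 0)

  r2 <- resolve_gene_ids("bcl2 , 999999", genes)
  expect_equal(nrow(r2$resolved), 1)
  expect_equal(r2$unresolved, "999999")

  # a token that is an alias of one gene and the symbol of another resolves
  # to the symbol
  tsv <- write_fixture(c("gene_id\tsymbol\taliases\tchrom\tstart\tend\tstrand",
                         "1\tGX\tSHARED\tchr1\t0\t10\t+",
                         "2\tSHARED\t\tchr1\t20\t30\t+"))
  g2 <- load_gene_table(tsv)
  expect_equal(resolve_gene_ids("shared", g2)$resolved$gene_id, "2")

  expect_error(resolve_gene_ids("nope1, nope2", genes), "no input genes",
               class = "snpprio_usage_error")
})

test_that("flanking-region mapping matches a brute-force all-pairs scan", {
  genes <- load_gene_table(tiny_gene_tsv())
  # boundary: SNP exactly flank_bp upstream of gene start pairs; one base
  # further does not
  flank <- 1000
  gstart <- genes$start[genes$symbol == "KLF12"]
  snps_at <- data.frame(
    rsid = c("rs_at", "rs_past"), chrom = "chr13",
    start = c(gstart - flank, gstart - flank - 1),
    end = c(gstart - flank + 1, gstart - flank),
    strand = "+", alleles = "A/T", function_class = "unknown",
    stringsAsFactors = FALSE)
  class(snps_at) <- c("snp_table", "data.frame")
  m <- map_snps_to_genes(snps_at, genes, flank)
  expect_equal(m$rsid, "rs_at")

  # randomized 5 genes x 20 SNPs fixture equals the oracle at several flanks
  set.seed(99)
  rg <- data.frame(gene_id = paste0("g", 1:5), symbol = paste0("g", 1:5),
                   aliases = "", chrom = sample(c("chr1", "chr2"), 5, TRUE),
                   start = sample(0:5000, 5), stringsAsFactors = FALSE)
  rg$end <- rg$start + sample(200:2000, 5)
  rg$strand <- "+"
  class(rg) <- c("gene_table", "data.frame")
  rs <- data.frame(rsid = sprintf("rs%02d", 1:20),
                   chrom = sample(c("chr1", "chr2"), 20, TRUE),
                   start = sample(0:8000, 20), stringsAsFactors = FALSE)
  rs$end <- rs$start + 1L
  rs$strand <- "+"; rs$alleles <- "A/G"; rs$function_class <- "unknown"
  class(rs) <- c("snp_table", "data.frame")
  for (fl in c(0, 150, 1000)) {
    got <- map_snps_to_genes(rs, rg, fl)
    oracle <- bf_map_snps_to_genes(rs, rg, fl)
    expect_equal(got$gene_id, oracle$gene_id)
    expect_equal(got$rsid, oracle$rsid)
  }
  # flank monotonicity: pairs at a smaller flank are a subset
  small <- map_snps_to_genes(rs, rg, 100)
  large <- map_snps_to_genes(rs, rg, 500)
  key <- function(m) paste(m$gene_id, m$rsid)
  expect_true(all(key(small) %in% key(large)))
})

test_that("feature tracks yield membership and context values", {
  snps <- load_snp_table(tiny_snp_tsv())
  feature <- data.frame(name = "DNase clusters", section = "Epi",
                        value_kind = "binary", context_axis = "",
                        min = NA_real_, max = NA_real_, weight = 0.9,
                        stringsAsFactors = FALSE)
  bed <- write_fixture("13\t73418000\t73419000\tcluster1", ext = ".bed")
  tr <- load_feature_track(bed, feature, snps)
  expect_equal(tr$value[tr$rsid == "rs1886512"], 1)   # inside the interval
  expect_equal(tr$value[tr$rsid == "rs900145"], 0)    # overlaps nothing

  # three tissue contexts, SNP present in two -> values (1, 1, 0) retained
  feature$context_axis <- "tissue"
  bed3 <- write_fixture(ext = ".bed", c(
    "13\t73418000\t73419000\tliver",
    "13\t73418000\t73419000\tlung",
    "15\t58682000\t58683000\tbrain"))
  tr3 <- load_feature_track(bed3, feature, snps)
  vals <- tr3[tr3$rsid == "rs1886512", ]
  expect_equal(vals$value[order(vals$context)], c(0, 1, 1))  # brain,liver,lung
})

test_that("feature matrices keep missing distinct from zero and round-trip", {
  snps <- load_snp_table(tiny_snp_tsv())
  registry <- default_feature_registry()
  bed <- write_fixture("13\t73418000\t73419000\tx", ext = ".bed")
  tr <- load_feature_track(bed, registry[registry$name == "DNase clusters", ],
                           snps)
  fm <- build_feature_matrix(snps, list(tr), registry)
  expect_equal(length(fm$snps), 3)
  expect_equal(length(fm$features), 31)
  expect_equal(fm$raw[["DNase clusters"]][snps$rsid == "rs1886512"], 1)
  # a feature with no track stays missing, not zero
  expect_true(all(is.na(fm$raw[["MAF"]])))

  # a registry without categorical features leaves an unannotated SNP all-NA
  reg2 <- registry[registry$value_kind != "categorical", ]
  class(reg2) <- class(registry)
  fm2 <- build_feature_matrix(snps, list(), reg2)
  expect_true(all(is.na(as.matrix(fm2$raw))))

  # TSV round trip is the identity
  path <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  fm_back <- read_feature_matrix(path, snps, registry)
  expect_equal(fm_back$raw, fm$raw)
  expect_equal(fm_back$contexts, fm$contexts)

  bad <- tr; attr(bad, "feature") <- "not registered"
  expect_error(build_feature_matrix(snps, list(bad), registry),
               "unregistered", class = "snpprio_integrity_error")
})
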