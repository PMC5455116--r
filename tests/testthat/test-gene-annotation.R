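test_that("region assignment matches a brute-force scan of gene spans", {
  ref <- tiny_reference()
  gm <- ref$gene_models
  lens <- setNames(Biostrings::width(ref$reference), names(ref$reference))
  set.seed(13)
  v <- data.table::data.table(
    chrom = sample(names(lens), 1000, TRUE))
  v[, pos := as.integer(runif(.N, 1, lens[chrom]))]
  got <- assign_region(v, gm, flank = 2000L)

  genes <- gm$genes
  brute <- vapply(seq_len(nrow(v)), function(i) {
    g <- genes[chrom == v$chrom[i]]
    if (any(v$pos[i] >= g$start & v$pos[i] <= g$end)) return("genic")
    up <- ifelse(g$strand == "+",
                 v$pos[i] >= g$start - 2000 & v$pos[i] < g$start,
                 v$pos[i] > g$end & v$pos[i] <= g$end + 2000)
    dn <- ifelse(g$strand == "+",
                 v$pos[i] > g$end & v$pos[i] <= g$end + 2000,
                 v$pos[i] >= g$start - 2000 & v$pos[i] < g$start)
    if (any(up)) return("flank_up_2kb")
    if (any(dn)) return("flank_down_2kb")
    "intergenic"
  }, "")
  expect_identical(got$region, brute)
  # every variant gets exactly one primary region label
  expect_true(all(got$region %in% c("genic", "flank_up_2kb",
                                    "flank_down_2kb", "intergenic")))
  expect_true(all(!is.na(got$gene_id[got$region != "intergenic"])))
})

test_that("flank boundaries are strand-aware and exclusive of the gene span", {
  gm <- structure(list(
    genes = data.table::data.table(
      gene_id = c("gP", "gM"), chrom = "chr1", strand = c("+", "-"),
      start = c(10000L, 50000L), end = c(12000L, 52000L),
      annotation = "", cds_len = 0L, cds_complete = FALSE),
    cds = data.table::data.table(gene_id = character(), chrom = character(),
                                 strand = character(), start = integer(),
                                 end = integer(), phase = integer(),
                                 exon_rank = integer())),
    class = "gene_models")
  v <- data.table::data.table(
    chrom = "chr1",
    pos = c(9999L, 10000L, 12001L, 49999L, 52001L, 30000L))
  got <- assign_region(v, gm)
  expect_identical(got$region,
                   c("flank_up_2kb", "genic", "flank_down_2kb",
                     "flank_down_2kb", "flank_up_2kb", "intergenic"))
})

test_that("single-codon classification reproduces genetic-code cases", {
  # gene: ATG | TGG | TAC | TAA on the plus strand, positions 11..22
  chrom <- paste0(strrep("C", 10), "ATGTGGTACTAA", strrep("C", 10))
  ref <- Biostrings::DNAStringSet(c(chr1 = chrom))
  gm <- structure(list(
    genes = data.table::data.table(gene_id = "g", chrom = "chr1",
                                   strand = "+", start = 11L, end = 22L,
                                   annotation = "", cds_len = 12L,
                                   cds_complete = TRUE),
    cds = data.table::data.table(gene_id = "g", chrom = "chr1", strand = "+",
                                 start = 11L, end = 22L, phase = 0L,
                                 exon_rank = 1L)), class = "gene_models")
  eff <- function(pos, refb, altb)
    predict_effect("chr1", pos, refb, altb, "g", gm, ref)
  # TGG -> TGA: new stop
  e <- eff(16L, "G", "A")
  expect_identical(e$effect, "stop_gained")
  expect_identical(e$impact, "HIGH")
  # terminal TAA -> CAA: lost stop
  e <- eff(20L, "T", "C")
  expect_identical(e$effect, "stop_lost")
  expect_identical(e$impact, "HIGH")
  # ATG -> ACG: lost start
  e <- eff(12L, "T", "C")
  expect_identical(e$effect, "start_lost")
  # TAC -> TAT: synonymous (both Tyr)
  e <- eff(19L, "C", "T")
  expect_identical(e$effect, "synonymous")
  expect_identical(e$impact, "LOW")
  # TGG -> TGC: Trp -> Cys missense
  e <- eff(16L, "G", "C")
  expect_identical(e$effect, "missense")
  expect_identical(e$impact, "MODERATE")
})

test_that("incremental codon classification equals whole-CDS re-translation", {
  ref <- tiny_reference()
  gm <- ref$gene_models
  chrom_str <- setNames(as.character(ref$reference), names(ref$reference))
  set.seed(17)
  cache <- new.env()
  n_checked <- 0L
  for (rep in 1:300) {
    g <- gm$genes[sample(nrow(gm$genes), 1)]
    cds <- gm$cds[gene_id == g$gene_id]
    # random genic position (CDS, intron or UTR)
    pos <- sample(g$start:g$end, 1)
    refb <- substr(chrom_str[g$chrom], pos, pos)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    got <- predict_effect(g$chrom, pos, refb, altb, g$gene_id, gm,
                          ref$reference, cache = cache)
    want <- oracle_snp_effect(chrom_str[g$chrom],
                              as.data.frame(cds[, .(start, end)]),
                              g$strand, pos, altb)
    expect_identical(got$effect, want,
                     info = sprintf("%s %s:%d %s>%s", g$gene_id, g$chrom,
                                    pos, refb, altb))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 300L)
})

test_that("indel classification follows frame arithmetic inside CDS", {
  ref <- tiny_reference()
  gm <- ref$gene_models
  chrom_str <- setNames(as.character(ref$reference), names(ref$reference))
  set.seed(19)
  for (rep in 1:100) {
    g <- gm$genes[sample(nrow(gm$genes), 1)]
    cds <- gm$cds[gene_id == g$gene_id]
    pos <- sample(g$start:(g$end - 5L), 1)
    if (runif(1) < 0.5) {
      r <- substr(chrom_str[g$chrom], pos, pos)
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1), TRUE),
                   collapse = "")
      v <- list(ref = r, alt = paste0(r, ins))
    } else {
      len <- sample(1:4, 1)
      v <- list(ref = substr(chrom_str[g$chrom], pos, pos + len),
                alt = substr(chrom_str[g$chrom], pos, pos))
    }
    got <- predict_effect(g$chrom, pos, v$ref, v$alt, g$gene_id, gm,
                          ref$reference)
    want <- oracle_indel_effect(as.data.frame(cds[, .(start, end)]),
                                pos, v$ref, v$alt)
    expect_identical(got$effect, want)
  }
})

test_that("effect labels are invariant under reverse-complementing the genome", {
  # a two-exon plus-strand gene and its mirrored minus-strand twin
  utr <- strrep("C", 20)
  exon1 <- "ATGTGGTAC"        # M W Y
  intron <- paste0("GT", strrep("A", 26), "AG")
  exon2 <- "CCTGGGTAA"        # P G *
  fwd <- paste0(utr, exon1, intron, exon2, utr)
  L <- nchar(fwd)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  ref_f <- Biostrings::DNAStringSet(c(chr = fwd))
  ref_r <- Biostrings::DNAStringSet(c(chr = rev))
  cds_f <- data.table::data.table(
    gene_id = "g", chrom = "chr", strand = "+",
    start = c(21L, 21L + 9L + 30L), end = c(29L, 59L + 9L),
    phase = 0L, exon_rank = 1:2)
  gm_f <- structure(list(
    genes = data.table::data.table(gene_id = "g", chrom = "chr",
                                   strand = "+", start = 21L, end = 68L,
                                   annotation = "", cds_len = 18L,
                                   cds_complete = TRUE),
    cds = cds_f), class = "gene_models")
  mirror <- function(p) L - p + 1L
  cds_r <- data.table::data.table(
    gene_id = "g", chrom = "chr", strand = "-",
    start = mirror(cds_f$end), end = mirror(cds_f$start),
    phase = 0L, exon_rank = 1:2)
  data.table::setorder(cds_r, start)
  gm_r <- structure(list(
    genes = data.table::data.table(gene_id = "g", chrom = "chr",
                                   strand = "-", start = mirror(68L),
                                   end = mirror(21L), annotation = "",
                                   cds_len = 18L, cds_complete = TRUE),
    cds = cds_r), class = "gene_models")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(23)
  for (rep in 1:60) {
    pos <- sample(21:68, 1)
    refb <- substr(fwd, pos, pos)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    e_f <- predict_effect("chr", pos, refb, altb, "g", gm_f, ref_f)
    e_r <- predict_effect("chr", mirror(pos), comp[[refb]], comp[[altb]],
                          "g", gm_r, ref_r)
    expect_identical(e_f$effect, e_r$effect,
                     info = sprintf("pos %d %s>%s", pos, refb, altb))
  }
})

test_that("genic ratio counts gene-span variants exactly", {
  ref <- tiny_reference()
  gm <- ref$gene_models
  g1 <- gm$genes[1]
  inside <- data.table::data.table(chrom = g1$chrom,
                                   pos = g1$start + 0:42)
  outside <- data.table::data.table(chrom = g1$chrom, pos = 1:57)
  r <- genic_ratio(rbind(inside, outside), gm, species = "spX")
  expect_equal(r$n_genic, 43L)
  expect_equal(r$n_total, 100L)
  expect_equal(r$ratio, 0.43)
  expect_equal(genic_ratio(inside, gm)$ratio, 1)
  expect_equal(genic_ratio(outside, gm)$ratio, 0)
  expect_true(is.na(genic_ratio(inside[0], gm)$ratio))
})

test_that("keyword filtering matches annotation text case-insensitively", {
  gm <- structure(list(
    genes = data.table::data.table(
      gene_id = sprintf("g%02d", 1:10), chrom = "chr1", strand = "+",
      start = seq(1000L, by = 10000L, length.out = 10),
      end = seq(3000L, by = 10000L, length.out = 10),
      annotation = c("TMV resistance N-like protein", "hypothetical protein",
                     "NBS-LRR disease RESISTANCE protein", "cytochrome P450",
                     "receptor like kinase", "Mlo-like protein",
                     "heat shock protein", "late blight resistance homolog",
                     "MADS box protein", "ubiquitin ligase"),
      cds_len = 0L, cds_complete = FALSE),
    cds = data.table::data.table()), class = "gene_models")
  hits <- filter_genes_by_keyword(gm, c("resistance", "receptor like kinase",
                                        "Mlo"))
  expect_setequal(hits$gene_id, c("g01", "g03", "g05", "g06", "g08"))
  expect_warning(none <- filter_genes_by_keyword(gm, character()), "empty")
  expect_equal(nrow(none), 0L)
  expect_equal(nrow(filter_genes_by_keyword(gm, "zinc finger")), 0L)
})
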