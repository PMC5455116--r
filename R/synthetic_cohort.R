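DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n, gc = 0.36) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Default wild-species panel for the simulator
#'
#' Twelve wild species with one to seven accessions each (29 in total),
#' mirroring a mixed panel of self-compatible species (high within-species
#' allele sharing) and self-incompatible outcrossers (low sharing). The
#' `genic_frac` column sets the planted fraction of genic variants among
#' each species' species-specific set, rising for the more divergent
#' species.
#'
#' @return data.table: `species`, `n_acc`, `share_prob`, `genic_frac`.
#' @export
default_species_panel <- function() {
  data.table(
    species = c("S_pimpinellifolium", "S_cheesmaniae", "S_galapagense",
                "S_chmielewskii", "S_neorickii", "S_corneliomuelleri",
                "S_arcanum", "S_huaylasense", "S_pennellii",
                "S_habrochaites", "S_peruvianum", "S_chilense"),
    n_acc = c(3L, 2L, 1L, 2L, 2L, 1L, 3L, 2L, 3L, 4L, 4L, 2L),
    share_prob = c(0.85, 0.90, 1.00, 0.92, 0.85, 1.00,
                   0.30, 0.35, 0.20, 0.30, 0.55, 0.55),
    genic_frac = c(0.08, 0.08, 0.10, 0.20, 0.22, 0.24,
                   0.26, 0.28, 0.34, 0.43, 0.30, 0.32))
}

#' Simulation configuration
#'
#' Defines the study conditions the synthetic cohort emulates: a 12-species
#' wild panel (29 accessions) with species-dependent allele sharing, a
#' 40-accession low-diversity cultivated panel, planted variant categories
#' with known truth for every downstream stage, and one selective-sweep
#' segment whose cultivated site-frequency spectrum is all singletons,
#' forcing strongly negative windowed Tajima's D.
#'
#' @param seed Integer seed; the same seed reproduces byte-identical output.
#' @param chrom_lengths Named integer vector (default 3 x 5 Mb).
#' @param n_genes Number of non-overlapping gene models (default 150).
#' @param species Species panel table ([default_species_panel()]).
#' @param n_cultivated Cultivated accessions (default 40).
#' @param bg_per_species Background variants drawn per wild species.
#' @param n_cultivated_bg Background variant sites of the cultivated panel.
#' @param n_species_specific Planted species-specific variants per wild
#'   species with >= 2 accessions.
#' @param differential_mix Named counts of planted common-wild alleles
#'   absent from all cultivated accessions, keyed by designed class.
#' @param n_shared_common Planted common-wild alleles also present in the
#'   cultivated panel (differential negatives).
#' @param n_discordant Planted positions variant in every wild accession
#'   with species-dependent alternate alleles (no universal allele).
#' @param n_negative_controls Planted all-wild variants whose every call
#'   fails the confidence filter.
#' @param sweep list(chrom, start, end, n_sites): the swept segment; its
#'   sites are cultivated singletons and no other variant is placed inside.
#' @param depth_mean Mean of the shifted-Poisson read depth (5 + Pois).
#' @param qual_range Uniform range of confident site qualities.
#' @param cultivated_missing_rate Rate of explicit missing cultivated calls.
#' @param resistance_frac Fraction of genes annotated with
#'   resistance-related keywords.
#' @param truth_genotypes Keep the full per-accession record table in the
#'   returned truth object (memory-heavy at full scale; default FALSE).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    chrom_lengths = c(ch01 = 5000000L, ch02 = 5000000L, ch03 = 5000000L),
    n_genes = 150L,
    species = default_species_panel(),
    n_cultivated = 40L,
    bg_per_species = 2000L,
    n_cultivated_bg = 10000L,
    n_species_specific = 50L,
    differential_mix = list(
      stop_gained = 6L, stop_lost = 4L, start_lost = 3L, splice_site = 5L,
      frameshift = 2L, inframe_indel = 3L, missense = 8L, synonymous = 8L,
      start_gained = 1L, genic_noncoding = 14L, flank_up = 12L,
      flank_down = 8L, intergenic_snp = 36L, intergenic_indel = 10L),
    n_shared_common = 80L,
    n_discordant = 30L,
    n_negative_controls = 40L,
    sweep = list(chrom = "ch03", start = 1500000L, end = 3500000L,
                 n_sites = 700L),
    depth_mean = 20,
    qual_range = c(40, 90),
    cultivated_missing_rate = 0.005,
    resistance_frac = 0.10,
    truth_genotypes = FALSE) {
  stopifnot(all(chrom_lengths > 0), n_genes >= 0,
            sweep$chrom %in% names(chrom_lengths),
            sweep$start >= 1, sweep$end <= chrom_lengths[[sweep$chrom]])
  structure(as.list(environment()), class = "simulation_config")
}

# ---- gene construction -----------------------------------------------------

NONSTOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

ANNOTATION_POOL <- c(
  "hypothetical protein", "cytochrome P450 monooxygenase",
  "heat shock protein 70", "E3 ubiquitin ligase", "MADS box protein",
  "auxin response factor", "gibberellin 2-oxidase",
  "wax synthase isoform", "pectinesterase inhibitor",
  "pentatricopeptide repeat protein", "acyl carrier protein",
  "ABC transporter family protein", "glycosyl hydrolase",
  "zinc finger protein", "serine carboxypeptidase")

RESISTANCE_POOL <- c(
  "NBS-LRR disease resistance protein",
  "TMV resistance N-like protein",
  "receptor like kinase",
  "Mlo-like protein",
  "late blight resistance protein homolog")

# build one gene in coding orientation, then mirror for minus strand;
# returns the genomic subsequence to splice into the chromosome plus the
# coding geometry used for effect planting
build_gene <- function(gene_id, chrom, strand, annotation) {
  n_cds <- sample(1:5, 1L)
  ncod <- sample(60:300, 1L)
  L <- 3L * ncod
  codons <- c("ATG", sample(NONSTOP_CODONS, ncod - 2L, replace = TRUE),
              sample(STOP_CODONS, 1L))
  coding <- paste(codons, collapse = "")
  if (n_cds == 1L) {
    exon_len <- L
  } else {
    repeat {
      cuts <- sort(sample(9:(L - 9L), n_cds - 1L))
      exon_len <- diff(c(0L, cuts, L))
      if (all(exon_len >= 9L)) break
    }
  }
  intron_len <- if (n_cds > 1L) sample(60:400, n_cds - 1L, replace = TRUE) else integer()
  utr5 <- sample(80:200, 1L)
  utr3 <- sample(50:150, 1L)

  # offsets of coding bases within the gene (coding orientation)
  off <- utr5
  exon_off <- matrix(0L, nrow = n_cds, ncol = 2L)
  for (j in seq_len(n_cds)) {
    exon_off[j, 1L] <- off + 1L
    off <- off + exon_len[j]
    exon_off[j, 2L] <- off
    if (j < n_cds) off <- off + intron_len[j]
  }
  glen <- off + utr3

  # assemble the coding-orientation gene sequence
  parts <- character(2L * n_cds + 1L)
  parts[1L] <- random_dna(utr5)
  cpos <- 0L
  for (j in seq_len(n_cds)) {
    parts[2L * j] <- substr(coding, cpos + 1L, cpos + exon_len[j])
    cpos <- cpos + exon_len[j]
    if (j < n_cds) parts[2L * j + 1L] <- random_dna(intron_len[j])
  }
  parts[2L * n_cds + 1L] <- random_dna(utr3)
  seq_fwd <- paste(parts, collapse = "")

  list(gene_id = gene_id, chrom = chrom, strand = strand,
       annotation = annotation, glen = glen, seq_fwd = seq_fwd,
       coding = coding, ncod = ncod, exon_off = exon_off,
       exon_len = exon_len)
}

# finalize genomic coordinates once the gene start is known
place_gene <- function(g, gene_start) {
  gene_end <- gene_start + g$glen - 1L
  if (g$strand == "+") {
    g$seq_genomic <- g$seq_fwd
    cds_start <- gene_start + g$exon_off[, 1L] - 1L
    cds_end <- gene_start + g$exon_off[, 2L] - 1L
    coding_pos <- unlist(Map(seq.int, cds_start, cds_end), use.names = FALSE)
  } else {
    g$seq_genomic <- revcomp(g$seq_fwd)
    cds_end <- gene_end - g$exon_off[, 1L] + 1L
    cds_start <- gene_end - g$exon_off[, 2L] + 1L
    coding_pos <- unlist(Map(function(s, e) seq.int(e, s),
                             cds_start, cds_end), use.names = FALSE)
  }
  ord <- order(cds_start)
  cum <- cumsum(c(0L, head(g$exon_len, -1L)))
  phase <- (3L - cum %% 3L) %% 3L   # phase per segment in coding order
  g$start <- gene_start
  g$end <- gene_end
  g$cds <- data.table(start = cds_start[ord], end = cds_end[ord],
                      phase = phase[ord], coding_rank = seq_len(nrow(g$exon_off))[ord])
  g$coding_pos <- coding_pos
  g
}

#' Generate a synthetic reference genome and gene annotation
#'
#' Random chromosomes at ~36% GC carrying non-overlapping gene models
#' (1-5 CDS segments, valid ATG start, terminal stop, no internal stop,
#' mixed strands, flanking UTR regions). Genes are spaced at least 5 kb
#' apart so 2-kb flanks never collide. A configured fraction of genes gets
#' resistance-related annotation text.
#'
#' @param config A [simulation_config()]. Uses `config$seed` to seed the
#'   generator, so a given config reproduces its genome exactly.
#' @return list with `reference` ([Biostrings::DNAStringSet]), `genes`
#'   (internal gene list), `gene_models` (a `gene_models` object), and
#'   `n_resistance`.
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  chroms <- lapply(config$chrom_lengths, random_dna)
  n_genes <- config$n_genes
  genes <- list()
  n_res <- 0L
  if (n_genes > 0L) {
    n_per <- round(n_genes * config$chrom_lengths / sum(config$chrom_lengths))
    n_per[1L] <- n_genes - sum(n_per[-1L])
    res_ids <- sample(n_genes, round(config$resistance_frac * n_genes))
    gid <- 0L
    for (ch in names(config$chrom_lengths)) {
      k <- n_per[[ch]]
      if (k == 0L) next
      built <- lapply(seq_len(k), function(i) {
        gid_i <- gid + i
        ann_pool <- if (gid_i %in% res_ids) RESISTANCE_POOL else ANNOTATION_POOL
        build_gene(sprintf("gene%03d", gid_i), ch,
                   sample(c("+", "-"), 1L),
                   sample(ann_pool, 1L))
      })
      spans <- vapply(built, `[[`, 0L, "glen")
      min_gap <- 5000L
      slack <- config$chrom_lengths[[ch]] - sum(spans) - (k + 1L) * min_gap
      if (slack < 0L) stop("gene placement infeasible on ", ch)
      u <- sort(runif(k))
      gaps <- min_gap + floor(diff(c(0, u, 1)) * slack)
      start <- 0L
      for (j in seq_len(k)) {
        start <- start + gaps[j] + if (j > 1L) spans[j - 1L] else 0L
        g <- place_gene(built[[j]], as.integer(start + 1L))
        substr(chroms[[ch]], g$start, g$end) <- g$seq_genomic
        genes[[g$gene_id]] <- g
      }
      gid <- gid + k
    }
    n_res <- sum(vapply(genes, function(g)
      any(vapply(RESISTANCE_POOL, grepl, TRUE, x = g$annotation, fixed = TRUE)),
      TRUE))
  }
  reference <- Biostrings::DNAStringSet(unlist(chroms))
  names(reference) <- names(config$chrom_lengths)
  gm_genes <- rbindlist(lapply(genes, function(g)
    data.table(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = g$start, end = g$end, annotation = g$annotation,
               cds_len = sum(g$exon_len), cds_complete = TRUE)))
  gm_cds <- rbindlist(lapply(genes, function(g) {
    cds <- copy(g$cds)
    cds[, `:=`(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand)]
    cds[, .(gene_id, chrom, strand, start, end, phase,
            exon_rank = seq_len(.N))]
  }))
  if (is.null(gm_genes)) gm_genes <- data.table()
  gene_models <- structure(list(genes = gm_genes, cds = gm_cds),
                           class = "gene_models")
  list(reference = reference, genes = genes, gene_models = gene_models,
       n_resistance = n_res)
}

#' Write the synthetic reference and annotation to disk
#'
#' @param ref Result of [generate_reference()].
#' @param dir Output directory (created if needed).
#' @return list of paths (`fasta`, `gff`).
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(ref$reference, fasta, width = 80L)
  gff <- file.path(dir, "genes.gff3")
  lines <- c("##gff-version 3")
  for (g in ref$genes) {
    tx <- paste0(g$gene_id, ".1")
    lines <- c(lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;description=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id, g$annotation),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, g$start, g$end, g$strand, tx, g$gene_id),
      sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds-%s;Parent=%s",
              g$chrom, g$cds$start, g$cds$end, g$strand, g$cds$phase,
              tx, tx))
  }
  writeLines(lines, gff)
  list(fasta = fasta, gff = gff)
}
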