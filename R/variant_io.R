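#' @import data.table
#' @importFrom stats rpois runif setNames median
#' @importFrom utils head tail
NULL

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Classify a variant as SNP, insertion or deletion
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return Character vector with values `"SNP"`, `"INS"` or `"DEL"`.
#' @export
classify_vtype <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  fifelse(lr == 1L & la == 1L, "SNP", fifelse(la > lr, "INS", "DEL"))
}

#' Canonical variant key
#'
#' Two records are the same variant iff chromosome, position, reference
#' allele and alternate allele are all equal; the "same position" relation
#' (see [position_key()]) compares only chromosome and position.
#'
#' @param chrom,pos,ref,alt Vectors of the four identity fields.
#' @return Character vector `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @rdname variant_key
#' @export
position_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' Read a per-accession VCF into a variant table
#'
#' Reads a VCF v4.x file (plain or bgzipped) and returns one row per
#' (position, alternate allele) pair. Multi-allelic rows are split into one
#' record per alternate allele with the genotype re-coded against that
#' allele: a genotype carrying two copies of the allele is `hom_alt`, one
#' copy `het`, no copies `hom_ref`, and any genotype containing `.` is
#' `missing`. Depth is taken from the per-sample `DP` field, falling back
#' to `INFO/DP`; site quality from the `QUAL` column; reference-supporting
#' reads from the first `AD` field when present.
#'
#' @param path Path to the VCF file.
#' @param accession_id Sample column to read. Defaults to the single sample
#'   present; an error is raised if the file has several samples and no
#'   `accession_id` is given, or if the named sample is absent.
#' @return A `data.table` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `vtype`, `gt`, `dp`, `qual`, `ad_ref`, sorted by (chrom, pos).
#' @export
read_vcf <- function(path, accession_id = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0L) {
    return(data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vtype = character(), gt = character(),
                      dp = integer(), qual = numeric(), ad_ref = integer()))
  }
  samples <- colnames(v@gt)[-1L]
  if (is.null(accession_id)) {
    if (length(samples) != 1L)
      stop("VCF ", path, " has ", length(samples),
           " sample columns; specify accession_id")
    accession_id <- samples[1L]
  }
  if (!accession_id %in% samples)
    stop("genotype column '", accession_id, "' not found in ", path)

  gt_raw <- vcfR::extract.gt(v, element = "GT")[, accession_id]
  dp_raw <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[, accession_id])
  ad_raw <- vcfR::extract.gt(v, element = "AD")[, accession_id]
  info_dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "DP")))

  dt <- data.table(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt_all = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    gt_raw = unname(gt_raw),
    dp = as.integer(ifelse(is.na(dp_raw), info_dp, dp_raw)),
    ad_raw = unname(ad_raw),
    line = seq_len(nrow(fix))
  )
  bad <- dt[is.na(pos) | is.na(ref) | ref == "" | is.na(alt_all) | alt_all == ""]
  if (nrow(bad) > 0L)
    stop("malformed VCF record in ", path, " at data line ", bad$line[1L])

  # split multi-allelic rows: one record per alt allele
  multi <- grepl(",", dt$alt_all, fixed = TRUE)
  uni <- dt[!multi]
  uni[, `:=`(alt = alt_all, alt_idx = 1L)]
  if (any(multi)) {
    mdt <- dt[multi]
    alts <- strsplit(mdt$alt_all, ",", fixed = TRUE)
    nn <- lengths(alts)
    mdt <- mdt[rep(seq_len(nrow(mdt)), nn)]
    mdt[, alt := unlist(alts)]
    mdt[, alt_idx := unlist(lapply(nn, seq_len))]
    dt <- rbind(uni, mdt)
  } else dt <- uni
  dt[, gt := recode_gt(gt_raw, alt_idx)]
  dt[, ad_ref := ad_first(ad_raw)]
  ok <- grepl("^[ACGT]+$", dt$ref) & grepl("^[ACGT]+$", dt$alt)
  if (any(!ok))
    stop("malformed allele string in ", path, " at data line ", dt$line[!ok][1L])
  dt[, vtype := classify_vtype(ref, alt)]
  out <- dt[, .(chrom, pos, ref, alt, vtype, gt, dp, qual, ad_ref)]
  setorder(out, chrom, pos, ref, alt)
  out[]
}

# Re-code a raw GT string against one alternate-allele index (1-based within
# the ALT column): copies of that allele determine hom_alt/het/hom_ref.
# Fast path for the overwhelmingly common biallelic diploid strings.
recode_gt <- function(gt_raw, alt_idx) {
  out <- rep(NA_character_, length(gt_raw))
  fast <- alt_idx == 1L
  g <- gt_raw
  out[fast & (is.na(g) | g %in% c("", "./.", ".|.", "."))] <- "missing"
  out[fast & g %in% c("0/0", "0|0")] <- "hom_ref"
  out[fast & g %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  out[fast & g %in% c("1/1", "1|1")] <- "hom_alt"
  todo <- which(is.na(out))
  if (length(todo)) {
    out[todo] <- mapply(function(gg, i) {
      if (is.na(gg) || gg == "") return("missing")
      al <- strsplit(gg, "[/|]")[[1L]]
      if (any(al == ".")) return("missing")
      n_alt <- sum(al == as.character(i))
      if (n_alt >= length(al)) "hom_alt" else if (n_alt >= 1L) "het" else "hom_ref"
    }, gt_raw[todo], alt_idx[todo], USE.NAMES = FALSE)
  }
  out
}

ad_first <- function(ad_raw) {
  out <- rep(NA_integer_, length(ad_raw))
  has <- !is.na(ad_raw) & ad_raw != "."
  out[has] <- suppressWarnings(
    as.integer(vapply(strsplit(ad_raw[has], ",", fixed = TRUE), `[`, "", 1L)))
  out
}

#' High-confidence filter policy
#'
#' The stringent wild-accession criterion: minimum read depth 5, site
#' quality 30 and a fully non-reference (homozygous-alternate) genotype.
#' Cultivated accessions are read with all criteria disabled so that the
#' maximum number of allele observations is retained.
#'
#' @param min_depth Minimum per-sample read depth (reads).
#' @param min_qual Minimum phred-scaled site quality.
#' @param require_fixed_nonref Require a homozygous-alternate genotype with
#'   zero reference-supporting reads when `AD` is present.
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(min_depth = 5, min_qual = 30,
                          require_fixed_nonref = TRUE) {
  structure(list(min_depth = min_depth, min_qual = min_qual,
                 require_fixed_nonref = require_fixed_nonref),
            class = "filter_policy")
}

#' Policy with every criterion disabled (cultivated accessions)
#' @rdname filter_policy
#' @export
no_filter_policy <- function() {
  filter_policy(min_depth = 0, min_qual = -Inf, require_fixed_nonref = FALSE)
}

#' Apply a filter policy to a variant table
#'
#' A record passes iff depth >= `min_depth`, quality >= `min_qual` and,
#' when `require_fixed_nonref` is set, the genotype is homozygous-alternate
#' with no reference-supporting reads in the allele-depth field (a missing
#' `AD` field is not held against the call). A record with missing depth or
#' quality fails when the policy requires them.
#'
#' @param variants Variant `data.table` from [read_vcf()].
#' @param policy A [filter_policy()].
#' @return Logical vector, one element per record.
#' @export
apply_filter <- function(variants, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  dp_ok <- if (policy$min_depth > 0) {
    !is.na(variants$dp) & variants$dp >= policy$min_depth
  } else rep(TRUE, nrow(variants))
  q_ok <- if (is.finite(policy$min_qual)) {
    !is.na(variants$qual) & variants$qual >= policy$min_qual
  } else rep(TRUE, nrow(variants))
  gt_ok <- if (policy$require_fixed_nonref) {
    variants$gt == "hom_alt" &
      (is.na(variants$ad_ref) | variants$ad_ref == 0L)
  } else rep(TRUE, nrow(variants))
  dp_ok & q_ok & gt_ok
}

#' Normalize variant representations against the reference
#'
#' Indels are trimmed to their minimal representation and left-aligned
#' (the shared leading base is retained, per VCF convention): while the
#' rightmost bases of both alleles agree they are dropped, extending both
#' alleles leftwards with the reference base when either allele would
#' become empty; shared leading bases beyond the first are then removed.
#' SNPs are returned unchanged. The operation is idempotent, so two
#' representations of the same haplotypic change map to the same key.
#'
#' @param variants Variant `data.table` (any table with `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param reference A [Biostrings::DNAStringSet] named by chromosome.
#' @return The table with `pos`, `ref`, `alt`, `vtype` rewritten.
#' @export
normalize_variants <- function(variants, reference) {
  if (nrow(variants) == 0L) return(copy(variants))
  out <- copy(variants)
  idx <- which(nchar(out$ref) != nchar(out$alt) |
                 nchar(out$ref) > 1L)
  for (i in idx) {
    norm <- normalize_one(out$chrom[i], out$pos[i], out$ref[i], out$alt[i],
                          reference)
    set(out, i, "pos", norm$pos)
    set(out, i, "ref", norm$ref)
    set(out, i, "alt", norm$alt)
  }
  if ("vtype" %in% names(out)) out[, vtype := classify_vtype(ref, alt)]
  setorder(out, chrom, pos, ref, alt)
  out[]
}

normalize_one <- function(chrom, pos, ref, alt, reference) {
  if (!chrom %in% names(reference))
    stop("chromosome ", chrom, " absent from reference")
  chrseq <- reference[[chrom]]
  obs <- as.character(Biostrings::subseq(chrseq, pos, pos + nchar(ref) - 1L))
  if (obs != ref)
    stop("reference mismatch at ", chrom, ":", pos, " (VCF ", ref,
         ", reference ", obs, ")")
  r <- strsplit(ref, "")[[1L]]
  a <- strsplit(alt, "")[[1L]]
  repeat {
    if (length(r) > 0L && length(a) > 0L && tail(r, 1L) == tail(a, 1L)) {
      if (length(r) == 1L || length(a) == 1L) {
        if (pos == 1L) break
        pos <- pos - 1L
        b <- as.character(Biostrings::subseq(chrseq, pos, pos))
        r <- c(b, r)
        a <- c(b, a)
      }
      r <- r[-length(r)]
      a <- a[-length(a)]
    } else break
  }
  while (length(r) >= 2L && length(a) >= 2L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Read gene models from a GFF3 file
#'
#' Parses gene, mRNA and CDS features. One model is kept per gene; when a
#' gene has several mRNAs the representative is the first, ties broken by
#' lexicographic transcript id. Attribute text of the gene feature is
#' retained verbatim for keyword searches.
#'
#' @param gff_path Path to a GFF3 file with 1-based inclusive coordinates.
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   given, a feature beyond its chromosome end is a hard error.
#' @return A `gene_models` object: list with `genes` (data.table: `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `annotation`, `cds_len`,
#'   `cds_complete`) and `cds` (data.table: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `phase`, `exon_rank` in genomic order).
#' @export
read_gene_models <- function(gff_path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  get_attr <- function(field, default = NA_character_) {
    if (field %in% names(md)) as.character(md[[field]]) else
      rep(default, length(gr))
  }
  id <- get_attr("ID")
  parent <- md$Parent
  parent <- if (is.null(parent)) rep(NA_character_, length(gr)) else
    vapply(as.list(parent), function(p) if (length(p)) p[[1L]] else NA_character_, "")

  gi <- which(type == "gene")
  ann <- get_attr("description")
  note <- get_attr("Note")
  ann <- ifelse(is.na(ann), note, ann)
  genes <- data.table(
    gene_id = id[gi],
    chrom = as.character(GenomicRanges::seqnames(gr))[gi],
    strand = as.character(GenomicRanges::strand(gr))[gi],
    start = GenomicRanges::start(gr)[gi],
    end = GenomicRanges::end(gr)[gi],
    annotation = ifelse(is.na(ann[gi]), "", ann[gi])
  )
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in ", gff_path)
  if (!is.null(chrom_lengths)) {
    over <- genes[end > chrom_lengths[chrom] | start < 1L]
    if (nrow(over) > 0L)
      stop("gene ", over$gene_id[1L], " extends beyond its chromosome")
  }

  mi <- which(type == "mRNA")
  mrna <- data.table(tx_id = id[mi], gene_id = parent[mi], ord = seq_along(mi))
  mrna <- mrna[!is.na(gene_id)]
  setorder(mrna, gene_id, ord, tx_id)
  rep_tx <- mrna[, .SD[1L], by = gene_id]
  tx2gene <- setNames(rep_tx$gene_id, rep_tx$tx_id)

  ci <- which(type == "CDS")
  cds <- data.table(
    parent = parent[ci],
    chrom = as.character(GenomicRanges::seqnames(gr))[ci],
    strand = as.character(GenomicRanges::strand(gr))[ci],
    start = GenomicRanges::start(gr)[ci],
    end = GenomicRanges::end(gr)[ci],
    phase = as.integer(get_attr("phase", NA_character_)[ci])
  )
  orphan <- cds[is.na(parent) | !(parent %in% names(tx2gene) | parent %in% genes$gene_id)]
  if (nrow(orphan) > 0L) {
    warning(nrow(orphan), " CDS feature(s) without a known parent skipped")
    cds <- cds[!is.na(parent) & (parent %in% names(tx2gene) | parent %in% genes$gene_id)]
  }
  cds[, gene_id := ifelse(parent %in% names(tx2gene), tx2gene[parent], parent)]
  cds[, parent := NULL]
  setorder(cds, gene_id, start)
  cds[, exon_rank := seq_len(.N), by = gene_id]

  cl <- cds[, .(cds_len = sum(end - start + 1L)), by = gene_id]
  genes[cl, cds_len := i.cds_len, on = "gene_id"]
  genes[is.na(cds_len), cds_len := 0L]
  genes[, cds_complete := cds_len > 0L & cds_len %% 3L == 0L]
  structure(list(genes = genes[], cds = cds[]), class = "gene_models")
}

#' Read a reference genome
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first word of each header.
#' @export
read_reference <- function(fasta_path) {
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Write a tab-delimited variant table
#'
#' Tables use a header row and `.` for NA, the convention shared by all
#' text outputs of the pipeline.
#'
#' @param dt A data.table/data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(dt, path) {
  fwrite(dt, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' Internal coordinates are 1-based inclusive; the conversion to BED's
#' 0-based half-open convention happens only here.
#'
#' @param dt Table with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `name` and `score`.
#' @param path Output path.
#' @export
write_bed <- function(dt, path) {
  out <- data.table(chrom = dt$chrom, start = dt$start - 1L, end = dt$end)
  if ("name" %in% names(dt)) out[, name := dt$name]
  if ("score" %in% names(dt)) {
    if (!"name" %in% names(out)) out[, name := "."]
    out[, score := dt$score]
  }
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#' @param dt Table with `chrom`, `start`, `end` (1-based inclusive), `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(dt, path) {
  out <- data.table(chrom = dt$chrom, start = dt$start - 1L, end = dt$end,
                    value = dt$value)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
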