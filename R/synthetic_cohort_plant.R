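# ---- designed coding-effect variants --------------------------------------

codon_at <- function(g, ci) substr(g$coding, 3L * ci - 2L, 3L * ci)

aa_of <- function(codon) Biostrings::GENETIC_CODE[[codon]]

# map a substitution at coding offset to genomic (pos, ref, alt)
coding_sub_to_genomic <- function(g, coding_off, alt_coding) {
  pos <- g$coding_pos[coding_off]
  cbase <- substr(g$coding, coding_off, coding_off)
  if (g$strand == "+") {
    list(pos = pos, ref = cbase, alt = alt_coding)
  } else {
    list(pos = pos, ref = COMPLEMENT[[cbase]], alt = COMPLEMENT[[alt_coding]])
  }
}

resample <- function(x) x[sample.int(length(x))]

find_codon_sub <- function(g, ci_range, pred) {
  for (ci in resample(ci_range)) {
    cod <- codon_at(g, ci)
    for (off in resample(1:3)) {
      for (b in resample(setdiff(DNA_BASES, substr(cod, off, off)))) {
        new <- cod
        substr(new, off, off) <- b
        if (pred(cod, new))
          return(list(ci = ci, off = off, b = b))
      }
    }
  }
  NULL
}

design_snp_effect <- function(class, g) {
  ncod <- g$ncod
  hit <- switch(class,
    stop_gained = find_codon_sub(g, 2:(ncod - 1L), function(r, n)
      !(r %in% STOP_CODONS) && n %in% STOP_CODONS),
    stop_lost = find_codon_sub(g, ncod, function(r, n)
      r %in% STOP_CODONS && !(n %in% STOP_CODONS)),
    start_lost = find_codon_sub(g, 1L, function(r, n)
      r == "ATG" && n != "ATG"),
    missense = find_codon_sub(g, 2:(ncod - 1L), function(r, n)
      !(r %in% STOP_CODONS) && !(n %in% STOP_CODONS) &&
        aa_of(r) != aa_of(n)),
    synonymous = find_codon_sub(g, 2:(ncod - 1L), function(r, n)
      !(n %in% STOP_CODONS) && aa_of(r) == aa_of(n)),
    stop("unknown class ", class))
  if (is.null(hit)) return(NULL)
  gsub_ <- coding_sub_to_genomic(g, 3L * (hit$ci - 1L) + hit$off, hit$b)
  data.table(chrom = g$chrom, pos = gsub_$pos, ref = gsub_$ref,
             alt = gsub_$alt, vtype = "SNP")
}

design_splice <- function(g, chrom_str, splice_window = 2L) {
  if (nrow(g$cds) < 2L) return(NULL)
  donors <- g$cds$end[-nrow(g$cds)]
  acceptors <- g$cds$start[-1L]
  cand <- c(rep(donors, each = splice_window) +
              rep(seq_len(splice_window), length(donors)),
            rep(acceptors, each = splice_window) -
              rep(seq_len(splice_window), length(acceptors)))
  pos <- sample(cand, 1L)
  ref <- ref_base_at(chrom_str, g$chrom, pos)
  data.table(chrom = g$chrom, pos = pos, ref = ref,
             alt = other_base(ref), vtype = "SNP")
}

design_cds_indel <- function(g, chrom_str, frameshift = TRUE) {
  for (tries in 1:50) {
    seg <- g$cds[sample(.N, 1L)]
    if (frameshift) {
      if (seg$end - seg$start < 2L) next
      pos <- sample(seg$start:(seg$end - 1L), 1L)
      ref <- ref_base_at(chrom_str, g$chrom, pos)
      ins_len <- sample(1:2, 1L)
      ins <- sample(DNA_BASES, ins_len, replace = TRUE)
      ins[ins_len] <- sample(setdiff(DNA_BASES, ref), 1L)
      return(data.table(chrom = g$chrom, pos = pos, ref = ref,
                        alt = paste(c(ref, ins), collapse = ""),
                        vtype = "INS"))
    } else {
      if (seg$end - seg$start < 8L) next
      pos <- sample(seg$start:(seg$end - 4L), 1L)
      refseq <- ref_seq_at(chrom_str, g$chrom, pos, 4L)
      if (substr(refseq, 4L, 4L) == substr(refseq, 1L, 1L)) next
      return(data.table(chrom = g$chrom, pos = pos, ref = refseq,
                        alt = substr(refseq, 1L, 1L), vtype = "DEL"))
    }
  }
  NULL
}

design_start_gained <- function(g) {
  utr5 <- g$exon_off[1L, 1L] - 1L
  if (utr5 < 10L) return(NULL)
  for (i in sample(3:(utr5 - 4L))) {
    trip <- strsplit(substr(g$seq_fwd, i, i + 2L), "")[[1L]]
    d <- which(trip != c("A", "T", "G"))
    if (length(d) != 1L) next
    if (grepl("ATG", substr(g$seq_fwd, max(1L, i - 2L), i + 4L), fixed = TRUE))
      next
    o <- i + d - 1L
    base_coding <- c("A", "T", "G")[d]
    ref_coding <- substr(g$seq_fwd, o, o)
    if (g$strand == "+") {
      return(data.table(chrom = g$chrom, pos = g$start + o - 1L,
                        ref = ref_coding, alt = base_coding, vtype = "SNP"))
    } else {
      return(data.table(chrom = g$chrom, pos = g$end - o + 1L,
                        ref = COMPLEMENT[[ref_coding]],
                        alt = COMPLEMENT[[base_coding]], vtype = "SNP"))
    }
  }
  NULL
}

# does substituting alt at pos create a coding-strand ATG in the +-2 context?
creates_atg <- function(chrom_str, chrom, pos, alt, strand) {
  lo <- max(1L, pos - 2L)
  ctx <- ref_seq_at(chrom_str, chrom, lo, pos + 2L - lo + 1L)
  ctx_alt <- ctx
  substr(ctx_alt, pos - lo + 1L, pos - lo + 1L) <- alt
  target <- if (strand == "+") "ATG" else "CAT"
  grepl(target, ctx_alt, fixed = TRUE) && !grepl(target, ctx, fixed = TRUE)
}

# intergenic indel with a normalization-stable minimal representation
design_intergenic_indel <- function(chrom_str, chrom, pos) {
  if (runif(1) < 0.5) {
    ref <- ref_base_at(chrom_str, chrom, pos)
    ins_len <- sample(1:3, 1L)
    ins <- sample(DNA_BASES, ins_len, replace = TRUE)
    ins[ins_len] <- sample(setdiff(DNA_BASES, ref), 1L)
    data.table(chrom = chrom, pos = pos, ref = ref,
               alt = paste(c(ref, ins), collapse = ""), vtype = "INS")
  } else {
    del_len <- sample(1:3, 1L)
    refseq <- ref_seq_at(chrom_str, chrom, pos, del_len + 1L)
    if (substr(refseq, del_len + 1L, del_len + 1L) == substr(refseq, 1L, 1L))
      return(NULL)
    data.table(chrom = chrom, pos = pos, ref = refseq,
               alt = substr(refseq, 1L, 1L), vtype = "DEL")
  }
}

# ---- cohort assembly -------------------------------------------------------

#' Accession table implied by a simulation configuration
#' @param config A [simulation_config()].
#' @return [cohort_spec()] with wild accessions (per species) and the
#'   cultivated panel (`S_lycopersicum`).
#' @export
sim_cohort_table <- function(config) {
  wild <- config$species[, .(accession = sprintf("%s_a%02d", species,
                                                 seq_len(n_acc)),
                             group = "wild"), by = species]
  cult <- data.table(species = "S_lycopersicum",
                     accession = sprintf("cultivated_%02d",
                                         seq_len(config$n_cultivated)),
                     group = "cultivated")
  cohort_spec(rbind(wild, cult)[, .(accession, species, group)])
}

# expand a planted variant table across a set of accessions with confident
# homozygous-alternate calls
expand_confident <- function(vdt, accessions, config, category) {
  n_v <- nrow(vdt)
  n_a <- length(accessions)
  if (n_v == 0L) return(NULL)
  rows <- vdt[rep(seq_len(n_v), each = n_a),
              .(chrom, pos, ref, alt, vtype)]
  rows[, accession := rep(accessions, times = n_v)]
  cbind(rows, confident_fields(nrow(rows), config))[, category := category]
}
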