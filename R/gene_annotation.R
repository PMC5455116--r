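REGION_LEVELS <- c("genic", "flank_up_2kb", "flank_down_2kb", "intergenic")

HIGH_EFFECTS <- c("stop_gained", "stop_lost", "start_lost", "splice_site",
                  "frameshift")

effect_impact <- function(effect, start_gained_high = FALSE) {
  high <- HIGH_EFFECTS
  if (start_gained_high) high <- c(high, "start_gained")
  fifelse(effect %in% high, "HIGH",
          fifelse(effect %in% c("missense", "inframe_indel"), "MODERATE",
                  fifelse(effect == "synonymous", "LOW", "MODIFIER")))
}

#' Assign variants to genic, flank or intergenic regions
#'
#' A variant is genic iff its position lies within an annotated gene span
#' (UTRs and introns included); in a flank iff it lies within `flank` bp
#' upstream or downstream of a gene span on the gene's strand and is not
#' genic for any gene; otherwise intergenic. When several genes or flanks
#' overlap a position, all hits are recorded and the primary hit is the
#' gene with the smallest span, ties broken by lexicographic gene id.
#'
#' @param variants Table with `chrom`, `pos` (and usually `ref`, `alt`).
#' @param gene_models A [read_gene_models()] object.
#' @param flank Flank width in bp (default 2000).
#' @return Input columns plus `region`, `gene_id` (primary hit; NA when
#'   intergenic) and `n_gene_hits`.
#' @export
assign_region <- function(variants, gene_models, flank = 2000L) {
  v <- as.data.table(variants)
  genes <- gene_models$genes
  out <- copy(v)
  out[, `:=`(region = "intergenic", gene_id = NA_character_, n_gene_hits = 0L)]
  if (nrow(v) == 0L || nrow(genes) == 0L) return(out[])

  vr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  pick_primary <- function(hits) {
    # hits: data.table(vi, gene_id, span, region)
    setorder(hits, vi, span, gene_id)
    hits[, n := .N, by = vi]
    hits[, .SD[1L], by = vi]
  }

  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(vr, gr)
  if (length(ov) > 0L) {
    hits <- data.table(vi = S4Vectors::queryHits(ov),
                       gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
                       span = genes$end[S4Vectors::subjectHits(ov)] -
                         genes$start[S4Vectors::subjectHits(ov)])
    prim <- pick_primary(hits)
    out[prim$vi, `:=`(region = "genic", gene_id = prim$gene_id,
                      n_gene_hits = prim$n)]
  }

  # strand-aware flanks, exclusive of all gene spans
  up_start <- ifelse(genes$strand == "+", genes$start - flank, genes$end + 1L)
  up_end <- ifelse(genes$strand == "+", genes$start - 1L, genes$end + flank)
  dn_start <- ifelse(genes$strand == "+", genes$end + 1L, genes$start - flank)
  dn_end <- ifelse(genes$strand == "+", genes$end + flank, genes$start - 1L)
  fl <- data.table(
    chrom = rep(genes$chrom, 2L),
    start = pmax(1L, c(up_start, dn_start)),
    end = c(up_end, dn_end),
    gene_id = rep(genes$gene_id, 2L),
    span = rep(genes$end - genes$start, 2L),
    region = rep(c("flank_up_2kb", "flank_down_2kb"), each = nrow(genes)))
  fl <- fl[end >= start]
  fr <- GenomicRanges::GRanges(fl$chrom, IRanges::IRanges(fl$start, fl$end))
  nong <- which(out$region == "intergenic")
  if (length(nong) > 0L && length(fr) > 0L) {
    ovf <- GenomicRanges::findOverlaps(vr[nong], fr)
    if (length(ovf) > 0L) {
      hits <- data.table(vi = nong[S4Vectors::queryHits(ovf)],
                         gene_id = fl$gene_id[S4Vectors::subjectHits(ovf)],
                         span = fl$span[S4Vectors::subjectHits(ovf)],
                         fregion = fl$region[S4Vectors::subjectHits(ovf)])
      setorder(hits, vi, span, gene_id)
      hits[, n := .N, by = vi]
      prim <- hits[, .SD[1L], by = vi]
      out[prim$vi, `:=`(region = prim$fregion, gene_id = prim$gene_id,
                        n_gene_hits = prim$n)]
    }
  }
  out[]
}

# Per-gene coding geometry, cached per gene_models object in an environment.
gene_coding_cache <- function(gene_models) {
  env <- attr(gene_models, "coding_cache")
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    attr(gene_models, "coding_cache") <- env
  }
  env
}

# genome positions of the coding sequence in translation order, plus the
# coding nucleotide sequence (reverse-complemented for minus-strand genes)
gene_coding <- function(gene_id, gene_models, reference, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[gene_id]])) return(cache[[gene_id]])
  gid <- gene_id
  cds <- gene_models$cds[gene_id == gid]
  if (nrow(cds) == 0L) return(NULL)
  setorder(cds, start)
  gpos <- unlist(Map(seq.int, cds$start, cds$end), use.names = FALSE)
  seqs <- paste(vapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(reference[[cds$chrom[1L]]],
                                    cds$start[i], cds$end[i])), ""),
    collapse = "")
  strand <- cds$strand[1L]
  if (strand == "-") {
    gpos <- rev(gpos)
    seqs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs)))
  }
  res <- list(gpos = gpos, coding = seqs, strand = strand,
              chrom = cds$chrom[1L], cds = cds)
  if (!is.null(cache)) cache[[gene_id]] <- res
  res
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Predict the coding effect of one variant on one gene
#'
#' SNPs inside the coding sequence are classified by translating the
#' affected codon before and after the substitution (standard nuclear
#' code, strand-aware): a new stop codon where none was is `stop_gained`;
#' a lost terminal stop is `stop_lost`; a destroyed initiator ATG is
#' `start_lost`; otherwise `synonymous` or `missense` by amino-acid
#' identity. Intronic SNPs within `splice_window` bp of an internal
#' CDS/intron boundary are `splice_site`. CDS indels are `frameshift` when
#' the length change is not a multiple of three, else `inframe_indel`.
#' Everything else is `non_coding`. With `assess_start_gained`, a SNP in
#' the genic region 5' of the annotated start that creates an ATG on the
#' coding strand is `start_gained`.
#'
#' Genes whose concatenated CDS length is not a multiple of three are
#' classified on the available frame and flagged (`incomplete_cds`).
#'
#' @param chrom,pos,ref,alt The (normalized) variant.
#' @param gene_id Gene to assess; the variant must lie in its span.
#' @param gene_models A [read_gene_models()] object.
#' @param reference [Biostrings::DNAStringSet].
#' @param splice_window Intronic bases adjacent to a CDS boundary treated
#'   as splice sites (default 2, the canonical donor/acceptor dinucleotide).
#' @param assess_start_gained Also test for start-gain (default FALSE).
#' @param cache Optional environment used to memoize per-gene geometry.
#' @return list(effect, impact, codon_ref, codon_alt, aa_ref, aa_alt,
#'   incomplete_cds)
#' @export
predict_effect <- function(chrom, pos, ref, alt, gene_id, gene_models,
                           reference, splice_window = 2L,
                           assess_start_gained = FALSE, cache = NULL) {
  gc <- gene_coding(gene_id, gene_models, reference, cache)
  res <- list(effect = "non_coding", impact = "MODIFIER",
              codon_ref = NA_character_, codon_alt = NA_character_,
              aa_ref = NA_character_, aa_alt = NA_character_,
              incomplete_cds = FALSE)
  if (is.null(gc)) return(res)
  is_snp <- nchar(ref) == 1L && nchar(alt) == 1L
  cds <- gc$cds
  in_cds_seg <- any(pos >= cds$start & pos <= cds$end)
  len_diff <- nchar(alt) - nchar(ref)

  if (!is_snp) {
    # indel: affected bases are those after the shared anchor base
    touch_start <- pos + 1L
    touch_end <- if (len_diff < 0L) pos + nchar(ref) - 1L else pos + 1L
    touches_cds <- any(cds$start <= touch_end & cds$end >= touch_start)
    if (touches_cds) {
      res$effect <- if (len_diff %% 3L != 0L) "frameshift" else "inframe_indel"
      res$impact <- effect_impact(res$effect)
      res$incomplete_cds <- nchar(gc$coding) %% 3L != 0L
    }
    return(res)
  }

  # splice site: intronic base within splice_window of an internal boundary
  if (!in_cds_seg && nrow(cds) >= 2L) {
    internal_left <- cds$start[-1L]              # acceptor side boundaries
    internal_right <- cds$end[-nrow(cds)]        # donor side boundaries
    near <- any(pos >= internal_right + 1L & pos <= internal_right + splice_window) ||
      any(pos <= internal_left - 1L & pos >= internal_left - splice_window)
    if (near) {
      res$effect <- "splice_site"
      res$impact <- "HIGH"
      return(res)
    }
  }

  if (in_cds_seg) {
    cpos <- match(pos, gc$gpos)
    coding <- gc$coding
    clen <- nchar(coding)
    res$incomplete_cds <- clen %% 3L != 0L
    base_alt <- if (gc$strand == "-") COMPLEMENT[[alt]] else alt
    ci <- (cpos - 1L) %/% 3L + 1L
    c0 <- 3L * ci - 2L
    if (c0 + 2L > clen) return(res)   # dangling partial codon of an incomplete model
    codon_ref <- substr(coding, c0, c0 + 2L)
    off <- cpos - c0 + 1L
    codon_alt <- codon_ref
    substr(codon_alt, off, off) <- base_alt
    aa_ref <- translate_codon(codon_ref)
    aa_alt <- translate_codon(codon_alt)
    res[c("codon_ref", "codon_alt", "aa_ref", "aa_alt")] <-
      list(codon_ref, codon_alt, aa_ref, aa_alt)
    if (aa_ref == "*" && aa_alt != "*") {
      res$effect <- "stop_lost"
    } else if (aa_alt == "*" && aa_ref != "*") {
      res$effect <- "stop_gained"
    } else if (ci == 1L && codon_ref == "ATG" && codon_alt != "ATG") {
      res$effect <- "start_lost"
    } else if (aa_ref == aa_alt) {
      res$effect <- "synonymous"
    } else {
      res$effect <- "missense"
    }
    res$impact <- effect_impact(res$effect)
    return(res)
  }

  if (assess_start_gained) {
    # genic, 5' of the CDS start on the coding strand, not in CDS/splice
    cds_start_coding <- if (gc$strand == "+") min(cds$start) else max(cds$end)
    five_prime <- if (gc$strand == "+") pos < cds_start_coding else
      pos > cds_start_coding
    if (five_prime && gains_atg(chrom, pos, alt, gc$strand, reference)) {
      res$effect <- "start_gained"
      res$impact <- effect_impact("start_gained", start_gained_high = TRUE)
      return(res)
    }
  }
  res
}

# does substituting `alt` at pos create an ATG (coding strand) in any of the
# three windows covering pos?
gains_atg <- function(chrom, pos, alt, strand, reference) {
  chrseq <- reference[[chrom]]
  lo <- max(1L, pos - 2L)
  hi <- min(length(chrseq), pos + 2L)
  ctx <- strsplit(as.character(Biostrings::subseq(chrseq, lo, hi)), "")[[1L]]
  ctx_alt <- ctx
  ctx_alt[pos - lo + 1L] <- alt
  target <- if (strand == "+") "ATG" else "CAT"
  ref_str <- paste(ctx, collapse = "")
  alt_str <- paste(ctx_alt, collapse = "")
  grepl(target, alt_str, fixed = TRUE) && !grepl(target, ref_str, fixed = TRUE)
}

#' Annotate a variant table with regions and coding effects
#'
#' Convenience wrapper: [assign_region()] for every variant, then
#' [predict_effect()] for the genic ones against their primary gene.
#'
#' @inheritParams assign_region
#' @inheritParams predict_effect
#' @return Input plus `region`, `gene_id`, `effect`, `impact`.
#' @export
annotate_variants <- function(variants, gene_models, reference,
                              flank = 2000L, splice_window = 2L,
                              assess_start_gained = FALSE) {
  out <- assign_region(variants, gene_models, flank = flank)
  out[, `:=`(effect = "non_coding", impact = "MODIFIER")]
  gidx <- which(out$region == "genic")
  cache <- new.env(parent = emptyenv())
  for (i in gidx) {
    eff <- predict_effect(out$chrom[i], out$pos[i], out$ref[i], out$alt[i],
                          out$gene_id[i], gene_models, reference,
                          splice_window = splice_window,
                          assess_start_gained = assess_start_gained,
                          cache = cache)
    set(out, i, "effect", eff$effect)
    set(out, i, "impact", eff$impact)
  }
  out[]
}

#' Genic / total variant ratio
#'
#' Counts variants whose position lies within any annotated gene span.
#'
#' @param variants Table with `chrom`, `pos` (optionally `vtype`).
#' @param gene_models A [read_gene_models()] object.
#' @param species Optional label copied to the output.
#' @return One-row data.table: `species`, `n_genic`, `n_total`, `ratio`
#'   (NA when `n_total` is 0).
#' @export
genic_ratio <- function(variants, gene_models, species = NA_character_) {
  v <- as.data.table(variants)
  n_total <- nrow(v)
  if (n_total == 0L)
    return(data.table(species = species, n_genic = 0L, n_total = 0L,
                      ratio = NA_real_))
  reg <- assign_region(v, gene_models, flank = 0L)
  n_genic <- sum(reg$region == "genic")
  data.table(species = species, n_genic = n_genic, n_total = n_total,
             ratio = n_genic / n_total)
}

#' Filter gene models by annotation keywords
#'
#' Case-insensitive substring/regex match of each keyword against the
#' verbatim annotation text, used e.g. to pull stress-resistance gene
#' families ("NBS-LRR", "receptor like kinase", "Mlo", "resistance").
#'
#' @param gene_models A [read_gene_models()] object.
#' @param keywords Character vector of patterns.
#' @return data.table of matching genes with a `matched_keyword` column.
#' @export
filter_genes_by_keyword <- function(gene_models, keywords) {
  genes <- gene_models$genes
  if (length(keywords) == 0L) {
    warning("empty keyword list; returning no genes")
    return(genes[0L][, matched_keyword := character()])
  }
  hit <- lapply(keywords, function(k)
    genes[grepl(k, annotation, ignore.case = TRUE)][, matched_keyword := k])
  out <- unique(rbindlist(hit), by = "gene_id")
  setorder(out, gene_id)
  out[]
}
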