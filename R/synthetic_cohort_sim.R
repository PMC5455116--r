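# ---- position bookkeeping --------------------------------------------------

# one logical "claimed" vector per chromosome; planted categories are
# mutually exclusive by position by construction
new_pos_pool <- function(chrom_lengths) {
  env <- new.env(parent = emptyenv())
  env$used <- lapply(chrom_lengths, function(L) logical(L))
  env$lengths <- chrom_lengths
  env
}

claim <- function(pool, chrom, pos) {
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(pool$used[[ch]][p])) stop("position collision on ", ch)
    pool$used[[ch]][p] <- TRUE
  }
  invisible(NULL)
}

is_used <- function(pool, chrom, pos) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- pool$used[[ch]][pos[i]]
  }
  out
}

# membership of positions in sorted non-overlapping spans
in_spans <- function(pos, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, starts)
  idx > 0L & pos <= ends[pmax(idx, 1L)]
}

# rejection-sample n unclaimed positions satisfying `ok(chrom, pos)`
draw_positions <- function(pool, n, ok = NULL, chroms = NULL, margin = 10L) {
  if (n == 0L)
    return(data.table(chrom = character(), pos = integer()))
  lens <- pool$lengths
  if (!is.null(chroms)) lens <- lens[chroms]
  got <- data.table(chrom = character(), pos = integer())
  tries <- 0L
  while (nrow(got) < n) {
    tries <- tries + 1L
    if (tries > 200L) stop("position sampling failed to converge")
    m <- max(2L * (n - nrow(got)), 64L)
    ch <- sample(names(lens), m, replace = TRUE,
                 prob = as.numeric(lens) / sum(as.numeric(lens)))
    p <- as.integer(floor(runif(m, margin, lens[ch] - margin))) + 1L
    cand <- unique(data.table(chrom = ch, pos = p))
    cand <- cand[!is_used(pool, chrom, pos)]
    if (!is.null(ok) && nrow(cand) > 0L) cand <- cand[ok(chrom, pos)]
    got <- unique(rbind(got, cand))
  }
  got <- got[seq_len(n)]
  claim(pool, got$chrom, got$pos)
  got
}

# ---- allele construction ---------------------------------------------------

ref_base_at <- function(chrom_str, chrom, pos) {
  substring(chrom_str[chrom], pos, pos)
}

ref_seq_at <- function(chrom_str, chrom, pos, len) {
  substring(chrom_str[chrom], pos, pos + len - 1L)
}

other_base <- function(ref, shift = NULL) {
  idx <- match(ref, DNA_BASES)
  if (is.null(shift)) shift <- sample(1:3, length(ref), replace = TRUE)
  DNA_BASES[(idx - 1L + shift) %% 4L + 1L]
}

# ---- genotype fields -------------------------------------------------------

confident_fields <- function(n, config) {
  dp <- 5L + rpois(n, config$depth_mean - 5)
  data.table(gt = "hom_alt", dp = dp,
             qual = round(runif(n, config$qual_range[1L],
                                config$qual_range[2L]), 1),
             ad_ref = 0L, ad_alt = dp)
}

negative_fields <- function(n, config) {
  f <- confident_fields(n, config)
  mode <- sample(c("low_dp", "low_qual", "het", "ref_reads"), n, replace = TRUE)
  f[mode == "low_dp", `:=`(dp = sample(0:4, .N, TRUE))]
  f[mode == "low_dp", ad_alt := dp]
  f[mode == "low_qual", qual := round(runif(.N, 5, 29.9), 1)]
  f[mode == "het", `:=`(gt = "het", ad_ref = pmax(1L, dp %/% 2L))]
  f[mode == "het", ad_alt := dp - ad_ref]
  f[mode == "ref_reads", ad_ref := sample(1:3, .N, TRUE)]
  f[mode == "ref_reads", ad_alt := pmax(0L, dp - ad_ref)]
  f
}

cultivated_fields <- function(gt, config) {
  n <- length(gt)
  dp <- 5L + rpois(n, config$depth_mean - 5)
  ad_ref <- fifelse(gt == "het", pmax(1L, dp %/% 2L), 0L)
  data.table(gt = gt, dp = dp,
             qual = round(runif(n, 20, config$qual_range[2L]), 1),
             ad_ref = ad_ref, ad_alt = dp - ad_ref)
}

# neutral site-frequency spectrum: P(k) proportional to 1/k, the standard
# coalescent expectation, so windowed pi and theta_W agree in expectation
# and background Tajima's D stays near zero
sfs_counts <- function(m, n_chrom) {
  ks <- seq_len(n_chrom - 1L)
  sample(ks, m, replace = TRUE, prob = 1 / ks)
}

# expand per-site carrier counts into per-accession diploid genotypes
sfs_genotypes <- function(site_id, k, n_acc) {
  if (length(site_id) == 0L)
    return(data.table(site = integer(), acc = integer(), gt = character()))
  long <- data.table(
    site = rep.int(site_id, k),
    chr = unlist(lapply(k, sample.int, n = 2L * n_acc), use.names = FALSE))
  long[, acc := (chr + 1L) %/% 2L]
  g <- long[, .(copies = .N), by = .(site, acc)]
  g[, gt := fifelse(copies == 2L, "hom_alt", "het")]
  g[, .(site, acc, gt)]
}
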