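# Independent reference implementations used to cross-check the package.
# These deliberately take different computational routes than the package
# (pairwise enumeration, whole-protein re-translation, naive loops).

# haplotype matrix consistent with per-site counts: site s gets k[s] ones
# among n chromosomes, in random columns
oracle_hap_matrix <- function(k, n) {
  H <- matrix(0L, nrow = length(k), ncol = n)
  for (s in seq_along(k)) H[s, sample.int(n, k[s])] <- 1L
  H
}

# mean pairwise hamming distance over all C(n,2) chromosome pairs
oracle_pi_pairwise <- function(H) {
  n <- ncol(H)
  cs <- colSums(H)
  M <- crossprod(H)                       # shared 1s per pair
  mism <- outer(cs, cs, "+") - 2 * M      # |h_i - h_j| summed over sites
  sum(mism[upper.tri(mism)]) / choose(n, 2)
}

oracle_theta_w <- function(S, n) {
  a1 <- 0
  for (i in 1:(n - 1)) a1 <- a1 + 1 / i
  S / a1
}

# Tajima (1989) constants, written out independently
oracle_tajima_d <- function(pi, S, n) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Hudson Fst: per-site within/between heterozygosity terms computed site by
# site in a plain loop, then averaged and ratioed
oracle_fst <- function(k1, n1, k2, n2) {
  hw <- hb <- numeric(0)
  for (s in seq_along(k1)) {
    if (n1[s] < 2 || n2[s] < 2) next
    p1 <- k1[s] / n1[s]
    p2 <- k2[s] / n2[s]
    b <- p1 * (1 - p2) + p2 * (1 - p1)
    if (b == 0) next
    hw <- c(hw, (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2)
    hb <- c(hb, b)
  }
  if (length(hb) == 0) return(NA_real_)
  1 - mean(hw) / mean(hb)
}

# ---- naive set algebra on key vectors --------------------------------------

naive_common <- function(key_list) {
  out <- key_list[[1]]
  for (ks in key_list[-1]) out <- out[out %in% ks]
  unique(out)
}

naive_specific <- function(target_keys_list, other_keys_list) {
  common <- naive_common(target_keys_list)
  others <- unique(unlist(other_keys_list))
  common[!(common %in% others)]
}

split_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1),
             pos = as.integer(vapply(parts, `[`, "", 2)),
             ref = vapply(parts, `[`, "", 3),
             alt = vapply(parts, `[`, "", 4),
             key = keys, stringsAsFactors = FALSE)
}

# positions variant in every accession, split by universal-allele status
naive_partition <- function(key_list) {
  n <- length(key_list)
  pos_of <- lapply(key_list, function(ks) {
    d <- split_key(ks)
    unique(paste(d$chrom, d$pos, sep = ":"))
  })
  all_pos <- pos_of[[1]]
  for (p in pos_of[-1]) all_pos <- all_pos[all_pos %in% p]
  same <- naive_common(key_list)
  same_pos <- unique(with(split_key(same), paste(chrom, pos, sep = ":")))
  list(same_allele = sort(same),
       same_positions = sort(same_pos),
       variable_positions = sort(all_pos[!(all_pos %in% same_pos)]),
       all_positions = sort(all_pos))
}

naive_differential <- function(same_keys, cult_allele_obs) {
  # cult_allele_obs: data.frame(chrom, pos, allele) of every allele seen in
  # any cultivated genotype call
  d <- split_key(same_keys)
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    hits <- cult_allele_obs$chrom == d$chrom[i] &
      cult_allele_obs$pos == d$pos[i] & cult_allele_obs$allele == d$alt[i]
    keep[i] <- !any(hits)
  }
  sort(d$key[keep])
}

# ---- whole-CDS re-translation effect oracle --------------------------------

oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3
  vapply(seq_len(n), function(i) {
    cod <- substr(dna, 3 * i - 2, 3 * i)
    Biostrings::GENETIC_CODE[[cod]]
  }, "")
}

# classify a SNP inside a gene by re-translating the entire CDS before and
# after applying it to the genome
oracle_snp_effect <- function(chrom_seq, cds, strand, pos, alt,
                              splice_window = 2) {
  cds <- cds[order(cds$start), ]
  in_cds <- any(pos >= cds$start & pos <= cds$end)
  if (!in_cds) {
    if (nrow(cds) >= 2) {
      donors <- cds$end[-nrow(cds)]
      acceptors <- cds$start[-1]
      if (any(pos > donors & pos <= donors + splice_window) ||
          any(pos < acceptors & pos >= acceptors - splice_window))
        return("splice_site")
    }
    return("non_coding")
  }
  mutate <- function(s) {
    substr(s, pos, pos) <- alt
    s
  }
  extract <- function(s) {
    parts <- vapply(seq_len(nrow(cds)), function(j)
      substr(s, cds$start[j], cds$end[j]), "")
    joined <- paste(parts, collapse = "")
    if (strand == "-")
      joined <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(joined)))
    joined
  }
  cds_ref <- extract(chrom_seq)
  cds_alt <- extract(mutate(chrom_seq))
  p_ref <- oracle_translate(cds_ref)
  p_alt <- oracle_translate(cds_alt)
  L <- length(p_ref)
  if (substr(cds_ref, 1, 3) == "ATG" && substr(cds_alt, 1, 3) != "ATG" &&
      p_alt[1] != "*")
    return("start_lost")
  if (p_ref[L] == "*" && p_alt[L] != "*") return("stop_lost")
  changed <- which(p_ref != p_alt)
  if (length(changed) == 0) return("synonymous")
  if (any(p_alt[changed] == "*")) return("stop_gained")
  "missense"
}

oracle_indel_effect <- function(cds, pos, ref, alt) {
  cds <- cds[order(cds$start), ]
  len_diff <- nchar(alt) - nchar(ref)
  touch_start <- pos + 1
  touch_end <- if (len_diff < 0) pos + nchar(ref) - 1 else pos + 1
  touches <- any(cds$start <= touch_end & cds$end >= touch_start)
  if (!touches) return("non_coding")
  if (len_diff %% 3 != 0) "frameshift" else "inframe_indel"
}
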