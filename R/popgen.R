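#' Harmonic numbers used by the diversity estimators
#'
#' `a1 = sum(1/i)` and `a2 = sum(1/i^2)` for `i` in `1..(n-1)`, where `n`
#' is the number of sampled allele copies.
#'
#' @param n Sample size in allele copies (>= 2).
#' @return Numeric scalar.
#' @export
a1_harmonic <- function(n) sum(1 / seq_len(n - 1L))

#' @rdname a1_harmonic
#' @export
a2_harmonic <- function(n) sum(1 / seq_len(n - 1L)^2)

#' Watterson's estimator of theta
#'
#' `theta_W = S / a1` with `a1 = sum_{i=1}^{n-1} 1/i`. Optionally
#' normalized per site by a window span in bp.
#'
#' @param S Number of segregating sites.
#' @param n Sample size in allele copies.
#' @param span_bp Optional window span for per-site normalization.
#' @return `theta_W` (NA when `n < 2`).
#' @export
watterson_theta <- function(S, n, span_bp = NULL) {
  if (is.na(n) || n < 2L) return(NA_real_)
  th <- S / a1_harmonic(n)
  if (!is.null(span_bp)) th <- th / span_bp
  th
}

#' Per-site contribution to nucleotide diversity
#'
#' The unbiased mean-pairwise-difference term `2 k (n - k) / (n (n - 1))`
#' for a site with `k` alternate alleles among `n` sampled copies. Summed
#' over the sites of a window this equals the average number of pairwise
#' differences between the window's sequences when `n` is constant.
#'
#' @param k Alternate-allele counts (vector).
#' @param n Allele-copy counts (vector, recycled).
#' @return Per-site diversity terms.
#' @export
pi_site <- function(k, n) 2 * k * (n - k) / (n * (n - 1))

#' Tajima's D
#'
#' The standardized difference between nucleotide diversity and
#' Watterson's theta,
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))`, with the usual constants
#' `a1 = sum 1/i`, `a2 = sum 1/i^2`, `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`. Strongly negative values flag an excess of rare
#' alleles (purifying selection, sweeps); positive values an excess of
#' intermediate-frequency alleles (balancing selection).
#'
#' @param pi Sum of per-site diversity over the window.
#' @param S Number of segregating sites (>= 1 for a defined value).
#' @param n Sample size in allele copies (>= 4 for a defined value).
#' @return `D`, or NA when `S = 0` or `n < 4`.
#' @export
tajimas_d <- function(pi, S, n) {
  if (is.na(S) || is.na(n) || S < 1L || n < 4L) return(NA_real_)
  a1 <- a1_harmonic(n)
  a2 <- a2_harmonic(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Hudson's Fst between two groups over a set of sites
#'
#' Ratio-of-averages estimator `1 - mean(Hw) / mean(Hb)` with per-site
#' within-group heterozygosity `Hw = (2 p1 (1-p1) + 2 p2 (1-p2)) / 2` and
#' between-group heterozygosity `Hb = p1 (1-p2) + p2 (1-p1)`, where `p`
#' are sample allele frequencies. Sites with fewer than two allele copies
#' in either group, or monomorphic across both groups, are skipped.
#'
#' @param k1,n1 Alternate counts and allele copies in group 1 (vectors).
#' @param k2,n2 Same for group 2.
#' @return Fst (typically in `[-eps, 1]`), or NA when no usable site.
#' @export
fst_hudson <- function(k1, n1, k2, n2) {
  ok <- !is.na(k1) & !is.na(k2) & n1 >= 2L & n2 >= 2L
  p1 <- k1[ok] / n1[ok]
  p2 <- k2[ok] / n2[ok]
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  hw <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  use <- hb > 0
  if (!any(use)) return(NA_real_)
  1 - mean(hw[use]) / mean(hb[use])
}

#' Per-site allele frequencies for a panel of accessions
#'
#' Reduces per-accession diploid genotype calls to per-site counts
#' `(n, k)`: each called genotype contributes two allele copies (hom-ref
#' 0, het 1, hom-alt 2 alternate copies); an explicitly missing genotype
#' contributes none; an accession with no record at a site is treated as
#' hom-ref when `absent = "hom_ref"` (the convention for single-sample
#' VCFs that emit variant sites only) or as missing when
#' `absent = "missing"`. Only biallelic SNP sites are retained: positions
#' showing more than one alternate allele across the panel are dropped,
#' as are sites with fewer than `min_calls` allele copies; both counts
#' are reported as attributes `n_multiallelic` and `n_low_call`.
#'
#' @param tables Named list (by accession) of variant tables carrying
#'   `chrom`, `pos`, `ref`, `alt`, `vtype`, `gt`.
#' @param absent Treatment of sites absent from an accession's table.
#' @param min_calls Minimum allele copies for a site to be kept (default 4).
#' @return data.table (`chrom`, `pos`, `ref`, `alt`, `n`, `k`) sorted by
#'   position.
#' @export
site_frequencies <- function(tables, absent = c("hom_ref", "missing"),
                             min_calls = 4L) {
  absent <- match.arg(absent)
  n_acc <- length(tables)
  long <- rbindlist(lapply(names(tables), function(a) {
    t <- as.data.table(tables[[a]])
    t[vtype == "SNP", .(chrom, pos, ref, alt, gt)]
  }))
  empty <- data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), n = integer(), k = integer())
  if (nrow(long) == 0L) return(empty)

  n_allele <- unique(long[gt != "missing", .(chrom, pos, alt)])[
    , .N, by = .(chrom, pos)]
  multi <- n_allele[N > 1L, .(chrom, pos)]
  long2 <- long[!multi, on = .(chrom, pos)]

  per_site <- long2[, .(
    k = sum(fifelse(gt == "hom_alt", 2L, fifelse(gt == "het", 1L, 0L))),
    n_missing = sum(gt == "missing"),
    n_records = .N,
    ref = ref[1L], alt = alt[gt != "missing"][1L]
  ), by = .(chrom, pos)]
  if (absent == "hom_ref") {
    per_site[, n := 2L * (n_acc - n_missing)]
  } else {
    per_site[, n := 2L * (n_records - n_missing)]
  }
  per_site <- per_site[!is.na(alt)]
  low <- per_site[n < min_calls]
  out <- per_site[n >= min_calls, .(chrom, pos, ref, alt, n, k)]
  setorder(out, chrom, pos)
  setattr(out, "n_multiallelic", nrow(multi))
  setattr(out, "n_low_call", nrow(low))
  out[]
}

#' Sliding windows over the SNP stream with diversity statistics
#'
#' Windows are defined in SNP-index space per chromosome: the w-th window
#' covers sites `(w-1)*step + 1 .. (w-1)*step + window`. Trailing windows
#' shorter than `window` sites are emitted with their true statistics and
#' flagged `partial`. For each window the segregating-site count `S`,
#' window `pi`, Watterson's `theta_w` and Tajima's `D` are attached; `D`
#' uses the rounded mean allele-copy count over the window's segregating
#' sites (per-site `n` may vary with missingness). When the site table
#' carries a second group's counts as `n2`/`k2`, Hudson's Fst between the
#' two groups is added.
#'
#' @param sites Site table from [site_frequencies()], sorted by position.
#' @param window,step Window size and step in SNPs (defaults 500 / 100).
#' @param emit_partial Emit trailing partial windows (default TRUE).
#' @return data.table: `chrom`, `win`, `start_idx`, `end_idx`, `span_start`,
#'   `span_end`, `n_sites`, `S`, `pi`, `theta_w`, `tajima_d`, `fst`
#'   (NA-filled when no group 2), `partial`.
#' @export
snp_windows <- function(sites, window = 500L, step = 100L,
                        emit_partial = TRUE) {
  stopifnot(window >= 1L, step >= 1L, step <= window)
  s <- as.data.table(sites)
  has_fst <- all(c("n2", "k2") %in% names(s))
  out_list <- list()
  for (ch in unique(s$chrom)) {
    sc <- s[chrom == ch]
    m <- nrow(sc)
    if (m == 0L) next
    starts <- seq.int(1L, m, by = step)
    ends <- pmin(starts + window - 1L, m)
    keep <- if (emit_partial) rep(TRUE, length(starts)) else
      (ends - starts + 1L) == window
    # drop duplicate trailing windows that add no new sites
    if (length(starts) > 1L) keep <- keep & starts <= m
    wdt <- rbindlist(lapply(which(keep), function(j) {
      i1 <- starts[j]; i2 <- ends[j]
      w <- sc[i1:i2]
      seg <- w$k > 0L & w$k < w$n
      S <- sum(seg)
      pi <- sum(pi_site(w$k, w$n))
      n_eff <- if (S > 0L) as.integer(round(mean(w$n[seg]))) else
        as.integer(round(mean(w$n)))
      data.table(
        chrom = ch, win = j, start_idx = i1, end_idx = i2,
        span_start = w$pos[1L], span_end = w$pos[nrow(w)],
        n_sites = nrow(w), S = S, pi = pi,
        theta_w = if (S > 0L) watterson_theta(S, n_eff) else 0,
        tajima_d = tajimas_d(pi, S, n_eff),
        fst = if (has_fst) fst_hudson(w$k, w$n, w$k2, w$n2) else NA_real_,
        partial = (i2 - i1 + 1L) < window)
    }))
    out_list[[ch]] <- wdt
  }
  if (length(out_list) == 0L)
    return(data.table(chrom = character(), win = integer(),
                      start_idx = integer(), end_idx = integer(),
                      span_start = integer(), span_end = integer(),
                      n_sites = integer(), S = integer(), pi = numeric(),
                      theta_w = numeric(), tajima_d = numeric(),
                      fst = numeric(), partial = logical()))
  rbindlist(out_list)
}

#' Variant density over fixed genomic bins
#'
#' Counts variants per fixed bin (default 1 Mb); bins are 1-based
#' inclusive, so a variant at exactly `binsize` falls in bin 1.
#'
#' @param variants Table with `chrom`, `pos`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param binsize Bin width in bp.
#' @return data.table: `chrom`, `bin`, `start`, `end`, `value` (count),
#'   covering every bin of every chromosome.
#' @export
density_track <- function(variants, chrom_lengths, binsize = 1e6) {
  v <- as.data.table(variants)
  grid <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / binsize)
    data.table(chrom = ch, bin = seq_len(nb))
  }))
  grid[, `:=`(start = as.integer((bin - 1L) * binsize + 1L),
              end = as.integer(pmin(bin * binsize,
                                    chrom_lengths[chrom])))]
  if (nrow(v) > 0L) {
    cnt <- v[, .(value = .N),
             by = .(chrom, bin = as.integer((pos - 1L) %/% binsize + 1L))]
    grid[cnt, value := i.value, on = .(chrom, bin)]
  }
  grid[is.na(value), value := 0L]
  grid[]
}

#' Threshold-passing windows merged into selection regions
#'
#' Windows with `D < low` are candidate purifying-selection regions,
#' windows with `D >= high` candidate balancing-selection regions (the
#' asymmetric comparisons are deliberate). Passing windows are projected
#' to their bp spans (first to last SNP of the window) and overlapping or
#' adjacent spans of one direction are merged. Partial trailing windows
#' are excluded by default (their variance at small `S` is unstable).
#'
#' @param windows Window table from [snp_windows()].
#' @param low,high Tajima's D thresholds (defaults -3 and 2).
#' @param gene_models Optional [read_gene_models()] object; when supplied,
#'   resident genes (gene span overlapping the region) are reported.
#' @param include_partial Include partial windows (default FALSE).
#' @return data.table: `chrom`, `start`, `end`, `direction`, `length`,
#'   `n_windows`, `genes` (comma-separated ids, "." when none or no models).
#' @export
selection_regions <- function(windows, low = -3, high = 2,
                              gene_models = NULL, include_partial = FALSE) {
  w <- as.data.table(windows)
  if (!include_partial) w <- w[partial == FALSE]
  w <- w[!is.na(tajima_d)]
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      direction = character(), length = integer(),
                      n_windows = integer(), genes = character())
  pass <- rbind(w[tajima_d < low][, direction := "purifying"],
                w[tajima_d >= high][, direction := "balancing"])
  if (nrow(pass) == 0L) return(empty)
  regions <- rbindlist(lapply(split(pass, by = c("chrom", "direction")),
                              function(p) {
    ir <- IRanges::reduce(IRanges::IRanges(p$span_start, p$span_end),
                          min.gapwidth = 1L)
    cov <- IRanges::countOverlaps(ir, IRanges::IRanges(p$span_start, p$span_end))
    data.table(chrom = p$chrom[1L], start = IRanges::start(ir),
               end = IRanges::end(ir), direction = p$direction[1L],
               length = IRanges::width(ir), n_windows = cov)
  }))
  regions[, genes := "."]
  if (!is.null(gene_models) && nrow(gene_models$genes) > 0L) {
    g <- gene_models$genes
    gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
    rr <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start, regions$end))
    ov <- GenomicRanges::findOverlaps(rr, gr)
    if (length(ov) > 0L) {
      hits <- data.table(ri = S4Vectors::queryHits(ov),
                         gene_id = g$gene_id[S4Vectors::subjectHits(ov)])
      gl <- hits[, .(genes = paste(sort(gene_id), collapse = ",")), by = ri]
      regions[gl$ri, genes := gl$genes]
    }
  }
  setorder(regions, chrom, start)
  regions[]
}
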