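test_that("Watterson's theta follows S / a1", {
  expect_equal(watterson_theta(0, 10), 0)
  expect_equal(watterson_theta(7, 2), 7)           # a1(2) = 1
  expect_equal(watterson_theta(10, 10), 10 / sum(1 / (1:9)))
  expect_true(is.na(watterson_theta(5, 1)))
  expect_equal(watterson_theta(10, 10, span_bp = 1000),
               10 / sum(1 / (1:9)) / 1000)
})

test_that("per-site pi matches pairwise enumeration", {
  expect_equal(pi_site(0, 8), 0)
  expect_equal(pi_site(1, 2), 1)                   # the single pair differs
  set.seed(31)
  k <- sample(1:7, 20, TRUE)
  H <- oracle_hap_matrix(k, 8)
  expect_equal(sum(pi_site(k, 8)), oracle_pi_pairwise(H), tolerance = 1e-12)
})

test_that("Tajima's D is zero at pi = S/a1 and signed by the spectrum", {
  n <- 80L
  a1 <- a1_harmonic(n)
  expect_equal(tajimas_d(50 / a1, 50, n), 0)
  # all singletons: excess rare variants force D < 0
  pi_singletons <- sum(pi_site(rep(1, 50), n))
  expect_lt(tajimas_d(pi_singletons, 50, n), 0)
  # all intermediate-frequency sites force D > 0
  pi_half <- sum(pi_site(rep(n / 2, 50), n))
  expect_gt(tajimas_d(pi_half, 50, n), 0)
  # undefined cases
  expect_true(is.na(tajimas_d(0, 0, n)))
  expect_true(is.na(tajimas_d(1, 1, 3)))
  # sign(D) = sign(pi - S/a1) whenever defined
  set.seed(5)
  for (i in 1:50) {
    nn <- 2L * sample(2:40, 1)
    S <- sample(1:100, 1)
    pi <- sum(pi_site(sample(nn - 1L, S, TRUE), nn))
    d <- tajimas_d(pi, S, nn)
    expect_equal(sign(d), sign(pi - S / a1_harmonic(nn)))
  }
})

test_that("theta, pi and S coincide for a sample of two chromosomes", {
  set.seed(41)
  for (i in 1:20) {
    S <- sample(1:30, 1)
    k <- rep(1L, S)             # every segregating site splits the pair
    expect_equal(sum(pi_site(k, 2)), S)
    expect_equal(watterson_theta(S, 2), S)
  }
})

test_that("Hudson Fst hits its fixed points and matches per-site enumeration", {
  # identical frequencies -> 0
  expect_equal(fst_hudson(c(4, 10), c(20, 20), c(4, 10), c(20, 20)), 0)
  # fixed differences -> 1
  expect_equal(fst_hudson(c(20, 0), c(20, 20), c(0, 18), c(20, 18)), 1)
  # random sites vs the per-site oracle
  set.seed(53)
  for (i in 1:20) {
    S <- 50
    n1 <- rep(2L * sample(3:20, 1), S)
    n2 <- rep(2L * sample(3:20, 1), S)
    k1 <- vapply(n1, function(n) sample(0:n, 1), 0L)
    k2 <- vapply(n2, function(n) sample(0:n, 1), 0L)
    got <- fst_hudson(k1, n1, k2, n2)
    want <- oracle_fst(k1, n1, k2, n2)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
  expect_true(is.na(fst_hudson(1, 1, 5, 10)))
})

test_that("site frequencies tally diploid calls and drop unusable sites", {
  tabs <- list(
    a1 = data.table::data.table(chrom = "ch01", pos = c(10L, 20L, 30L),
                                ref = "A", alt = "G", vtype = "SNP",
                                gt = c("hom_alt", "het", "missing")),
    a2 = data.table::data.table(chrom = "ch01", pos = c(10L, 20L, 30L),
                                ref = "A", alt = "G", vtype = "SNP",
                                gt = c("het", "hom_ref", "missing")),
    a3 = data.table::data.table(chrom = "ch01", pos = c(10L, 30L),
                                ref = "A", alt = "G", vtype = "SNP",
                                gt = c("hom_ref", "missing")))
  sf <- site_frequencies(tabs)
  # 3 accessions: 1/1 + 0/1 + 0/0 -> n = 6, k = 3
  expect_equal(sf[pos == 10L]$n, 6L)
  expect_equal(sf[pos == 10L]$k, 3L)
  # absent records count as hom-ref
  expect_equal(sf[pos == 20L]$n, 6L)
  expect_equal(sf[pos == 20L]$k, 1L)
  # all genotypes missing -> site dropped
  expect_false(30L %in% sf$pos)
  # a multi-allelic position is dropped and counted
  tabs$a1 <- rbind(tabs$a1,
                   data.table::data.table(chrom = "ch01", pos = 40L,
                                          ref = "A", alt = "C",
                                          vtype = "SNP", gt = "het"))
  tabs$a2 <- rbind(tabs$a2,
                   data.table::data.table(chrom = "ch01", pos = 40L,
                                          ref = "A", alt = "T",
                                          vtype = "SNP", gt = "het"))
  sf2 <- site_frequencies(tabs)
  expect_false(40L %in% sf2$pos)
  expect_equal(attr(sf2, "n_multiallelic"), 1L)
})

test_that("site frequencies match a brute-force genotype tally", {
  set.seed(61)
  n_acc <- 12
  pos <- sort(sample(1e5, 80))
  gts <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"),
                       80 * n_acc, TRUE), nrow = 80)
  tabs <- lapply(seq_len(n_acc), function(a)
    data.table::data.table(chrom = "chr", pos = pos, ref = "A", alt = "G",
                           vtype = "SNP", gt = gts[, a]))
  names(tabs) <- paste0("acc", seq_len(n_acc))
  sf <- site_frequencies(tabs, absent = "missing", min_calls = 0L)
  copies <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  for (s in seq_along(pos)) {
    g <- gts[s, ]
    want_n <- 2L * sum(g != "missing")
    want_k <- sum(copies[g[g != "missing"]])
    row <- sf[pos == pos[s]]
    if (want_n == 0) {
      expect_equal(nrow(row), 0L)
    } else {
      expect_equal(row$n, want_n)
      expect_equal(row$k, want_k)
    }
  }
})

test_that("SNP-index windows enumerate starts and spans correctly", {
  mk_sites <- function(m) data.table::data.table(
    chrom = "chr", pos = seq(100L, by = 10L, length.out = m),
    ref = "A", alt = "G", n = 20L, k = 5L)
  w1 <- snp_windows(mk_sites(500), window = 500, step = 100)
  expect_equal(nrow(w1[partial == FALSE]), 1L)
  expect_equal(w1$span_start[1], 100L)
  expect_equal(w1$span_end[1], 100L + 499L * 10L)
  w2 <- snp_windows(mk_sites(700), window = 500, step = 100)
  expect_equal(w2[partial == FALSE]$start_idx, c(1L, 101L, 201L))
  expect_equal(w2[partial == TRUE]$start_idx, c(301L, 401L, 501L, 601L))
  expect_equal(w2[partial == TRUE]$end_idx, rep(700L, 4))
  w0 <- snp_windows(mk_sites(0))
  expect_equal(nrow(w0), 0L)
  # coverage: every SNP index is in at least one window
  covered <- logical(700)
  for (j in seq_len(nrow(w2))) covered[w2$start_idx[j]:w2$end_idx[j]] <- TRUE
  expect_true(all(covered))
  # statistics attach per window
  expect_equal(w2$S[1], 500L)
  expect_equal(w2$pi[1], sum(pi_site(rep(5L, 500), 20L)))
  expect_equal(w2$theta_w[1], watterson_theta(500, 20))
})

test_that("density bins are 1-based inclusive and sum to the variant count", {
  lens <- c(chr1 = 2500000L, chr2 = 1200000L)
  v <- data.table::data.table(
    chrom = c(rep("chr1", 10), "chr1", "chr2"),
    pos = c(sample(1:999999, 10), 1000000L, 1500001L))
  d <- density_track(v, lens, binsize = 1e6)
  expect_equal(d[chrom == "chr1" & bin == 1]$value, 11L)  # 1e6 falls in bin 1
  expect_equal(sum(d$value), nrow(v))
  expect_equal(nrow(d[chrom == "chr1"]), 3L)
  expect_equal(nrow(d[chrom == "chr2"]), 2L)
  expect_equal(d[chrom == "chr2" & bin == 2]$start, 1000001L)
  expect_equal(d[chrom == "chr2" & bin == 2]$end, 1200000L)
  set.seed(71)
  v2 <- data.table::data.table(chrom = "chr1", pos = sample(2500000L, 5000))
  d2 <- density_track(v2, lens["chr1"], binsize = 1e6)
  want <- table(cut(v2$pos, breaks = c(0, 1e6, 2e6, 2.5e6)))
  expect_equal(d2$value, as.integer(want))
})

test_that("selection regions merge passing windows and respect thresholds", {
  w <- data.table::data.table(
    chrom = "chr1", win = 1:4, start_idx = 1L, end_idx = 2L,
    span_start = c(1000L, 4000L, 20000L, 50000L),
    span_end = c(5000L, 9000L, 30000L, 51000L),
    n_sites = 500L, S = 10L, pi = 1,
    theta_w = 1, tajima_d = c(-3.5, -3.01, 2.0, 0),
    fst = NA_real_, partial = FALSE)
  r <- selection_regions(w, low = -3, high = 2)
  pur <- r[direction == "purifying"]
  expect_equal(nrow(pur), 1L)
  expect_equal(pur$start, 1000L)
  expect_equal(pur$end, 9000L)
  expect_equal(pur$length, 8001L)
  expect_equal(pur$n_windows, 2L)
  bal <- r[direction == "balancing"]
  expect_equal(bal$start, 20000L)   # D >= 2 is inclusive
  # strict boundaries: D exactly at the low threshold does not pass
  w2 <- data.table::copy(w)[, tajima_d := c(-3.0, -2.99, 1.99, NA)]
  expect_equal(nrow(selection_regions(w2, low = -3, high = 2)), 0L)
  # partial windows are excluded by default, included on request
  w3 <- data.table::copy(w)[, partial := TRUE]
  expect_equal(nrow(selection_regions(w3)), 0L)
  expect_gt(nrow(selection_regions(w3, include_partial = TRUE)), 0L)
})

test_that("resident genes are reported for merged regions", {
  gm <- structure(list(
    genes = data.table::data.table(
      gene_id = c("gIn", "gOut"), chrom = "chr1", strand = "+",
      start = c(2000L, 40000L), end = c(3000L, 41000L), annotation = "",
      cds_len = 0L, cds_complete = FALSE),
    cds = data.table::data.table()), class = "gene_models")
  w <- data.table::data.table(
    chrom = "chr1", win = 1L, start_idx = 1L, end_idx = 2L,
    span_start = 1000L, span_end = 5000L, n_sites = 500L, S = 10L,
    pi = 1, theta_w = 1, tajima_d = -4, fst = NA_real_, partial = FALSE)
  r <- selection_regions(w, gene_models = gm)
  expect_identical(r$genes, "gIn")
})
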