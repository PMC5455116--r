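# Shared fixtures: scaled-down simulation configs and cached study runs.

small_sim_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed,
    chrom_lengths = c(ch01 = 400000L, ch02 = 400000L, ch03 = 400000L),
    n_genes = 30L,
    bg_per_species = 100L,
    n_cultivated_bg = 500L,
    n_species_specific = 10L,
    differential_mix = list(
      stop_gained = 2L, stop_lost = 1L, start_lost = 1L, splice_site = 2L,
      frameshift = 1L, inframe_indel = 1L, missense = 2L, synonymous = 2L,
      start_gained = 1L, genic_noncoding = 3L, flank_up = 2L,
      flank_down = 2L, intergenic_snp = 25L, intergenic_indel = 2L),
    n_shared_common = 12L,
    n_discordant = 8L,
    n_negative_controls = 6L,
    sweep = list(chrom = "ch03", start = 100000L, end = 300000L,
                 n_sites = 700L))
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

.study_cache <- new.env(parent = emptyenv())

# simulate a small study and run the pipeline on it, cached per seed for the
# duration of the test run
small_study <- function(seed = 1L) {
  tag <- paste0("s", seed)
  if (!is.null(.study_cache[[tag]])) return(.study_cache[[tag]])
  dir <- file.path(tempdir(), paste0("domesticscan_study_", seed))
  sim <- simulate_study(small_sim_config(seed), dir)
  cfg <- pipeline_config(
    reference = file.path(dir, "reference.fa"),
    gff = file.path(dir, "genes.gff3"),
    vcf_dir = file.path(dir, "vcf"),
    cohort = file.path(dir, "cohort.tsv"),
    out_dir = file.path(dir, "out"),
    verbose = FALSE)
  res <- run_all(cfg)
  out <- list(dir = dir, sim = sim, cfg = cfg, res = res)
  .study_cache[[tag]] <- out
  out
}

# a tiny handmade reference with one plus- and one minus-strand two-exon gene
tiny_reference <- function() {
  cfg <- simulation_config(
    seed = 99L, chrom_lengths = c(chrA = 60000L, chrB = 60000L),
    n_genes = 8L, sweep = list(chrom = "chrB", start = 40000L,
                               end = 50000L, n_sites = 10L))
  generate_reference(cfg)
}

# write a minimal single-sample VCF from text rows
write_mini_vcf <- function(rows, path, sample = "acc1") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

make_avs <- function(keys, accession, species, group = "wild") {
  d <- split_key(keys)
  accession_variant_set(
    data.table::data.table(chrom = d$chrom, pos = d$pos, ref = d$ref,
                           alt = d$alt, gt = "hom_alt"),
    accession, species, group)
}

# random mini-cohort for set-algebra cross-checks: keys drawn from a small
# universe so that intersections are non-trivial
random_mini_cohort <- function(n_wild_species = 3, max_acc = 3,
                               n_cult = 3, universe = 200) {
  pool <- paste0("ch0", sample(1:2, universe, TRUE), ":",
                 sample(1e4, universe), ":A:",
                 sample(c("C", "G", "T"), universe, TRUE))
  pool <- unique(pool)
  sets <- list()
  idx <- 1
  for (s in seq_len(n_wild_species)) {
    n_acc <- sample(max_acc, 1)
    for (a in seq_len(n_acc)) {
      keys <- sample(pool, sample(20:min(500, length(pool)), 1))
      sets[[paste0("w", s, "_", a)]] <-
        make_avs(keys, paste0("w", s, "_", a), paste0("sp", s), "wild")
    }
  }
  for (a in seq_len(n_cult)) {
    keys <- sample(pool, sample(20:min(500, length(pool)), 1))
    sets[[paste0("c", a)]] <-
      make_avs(keys, paste0("c", a), "cult", "cultivated")
  }
  sets
}
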