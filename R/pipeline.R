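#' Pipeline configuration
#'
#' Collects every path and tunable of the full scan. All coordinates are
#' 1-based inclusive internally; BED/bedGraph writers convert on output.
#'
#' @param reference Path to the reference FASTA.
#' @param gff Path to the GFF3 gene annotation.
#' @param vcf_dir Directory holding one VCF per accession, named
#'   `<accession>.vcf` (or `.vcf.gz`).
#' @param cohort Path to the cohort table (TSV: accession, species, group).
#' @param out_dir Output directory.
#' @param min_depth,min_qual Wild-accession confidence filter thresholds.
#' @param window,step SNP-index window size and step.
#' @param d_low,d_high Tajima's D thresholds for purifying (`D < d_low`)
#'   and balancing (`D >= d_high`) regions.
#' @param flank Gene flank width in bp.
#' @param rgene_keywords Annotation keywords defining the resistance-gene
#'   subset.
#' @param fst Compute wild-vs-cultivated Hudson Fst per window.
#' @param density_bin Bin width of the density tracks (bp).
#' @param assess_start_gained Test differential variants for start-gain.
#' @param include_partial_windows Let partial windows enter region calls.
#' @param percent_denominator Denominator of the percent-common statistic.
#' @param verbose Log stage progress to stderr.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reference, gff, vcf_dir, cohort, out_dir,
                            min_depth = 5, min_qual = 30,
                            window = 500L, step = 100L,
                            d_low = -3, d_high = 2, flank = 2000L,
                            rgene_keywords = c("NBS-LRR", "resistance",
                                               "receptor like kinase", "Mlo"),
                            fst = TRUE, density_bin = 1e6,
                            assess_start_gained = TRUE,
                            include_partial_windows = FALSE,
                            percent_denominator = "union",
                            verbose = TRUE) {
  stopifnot(window >= 1L, step >= 1L, step <= window)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Every key of [pipeline_config()] may appear in the file; entries in
#' `overrides` (e.g. parsed command-line flags) take precedence over the
#' file, which takes precedence over the defaults.
#'
#' @param path YAML file.
#' @param overrides Named list of overriding values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

log_msg <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[domesticscan] ", ...)
}

#' Load, normalize and filter every accession's variant set
#'
#' Wild accessions pass through the stringent confidence filter (depth,
#' quality, fixed non-reference genotype); cultivated accessions are kept
#' unfiltered. Records failing normalization or the filter are counted.
#'
#' @param config A [pipeline_config()].
#' @return list with `sets` (named list of [accession_variant_set()]),
#'   `tables` (named list of normalized unfiltered tables), `cohort`,
#'   `reference`, `gene_models`, `chrom_lengths`, `n_dropped` (per
#'   accession filtered-out counts).
#' @export
load_cohort_sets <- function(config) {
  cohort <- read_cohort_spec(config$cohort)
  if (!any(cohort$group == "wild"))
    stop("cohort has no wild accessions")
  if (!any(cohort$group == "cultivated"))
    stop("cohort has no cultivated accessions")
  reference <- read_reference(config$reference)
  chrom_lengths <- setNames(Biostrings::width(reference), names(reference))
  gene_models <- read_gene_models(config$gff, chrom_lengths)
  policy <- filter_policy(min_depth = config$min_depth,
                          min_qual = config$min_qual)
  sets <- list()
  tables <- list()
  n_dropped <- integer()
  for (i in seq_len(nrow(cohort))) {
    acc <- cohort$accession[i]
    path <- file.path(config$vcf_dir, paste0(acc, ".vcf"))
    if (!file.exists(path)) path <- paste0(path, ".gz")
    if (!file.exists(path)) stop("no VCF for accession ", acc)
    v <- read_vcf(path, acc)
    v <- normalize_variants(v, reference)
    tables[[acc]] <- v
    if (cohort$group[i] == "wild") {
      keep <- apply_filter(v, policy)
      n_dropped[[acc]] <- sum(!keep)
      v <- v[keep]
    } else {
      n_dropped[[acc]] <- 0L
    }
    sets[[acc]] <- accession_variant_set(v, acc, cohort$species[i],
                                         cohort$group[i])
  }
  list(sets = sets, tables = tables, cohort = cohort, reference = reference,
       gene_models = gene_models, chrom_lengths = chrom_lengths,
       n_dropped = n_dropped)
}

#' Run the full domestication scan
#'
#' Executes every stage in order and writes the report tables and track
#' files to `config$out_dir`: per-species common/percent-common summary;
#' species-specific variant tables; the common-wild partition summary;
#' the differential-variant table with region and effect annotation plus
#' a HIGH-impact class summary; per-species genic ratios; per-window
#' diversity statistics with density tracks; merged selection regions
#' (BED and TSV with resident genes and per-chromosome totals); the
#' resistance-gene report; and a JSON run manifest with parameters and
#' per-stage counts. Any stage failure writes a `FAILED` marker naming
#' the stage and rethrows.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the main in-memory results.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  res <- tryCatch({
    log_msg(config, "stage load: reading cohort")
    data <- load_cohort_sets(config)
    sets <- data$sets
    cohort <- data$cohort
    gm <- data$gene_models
    out <- config$out_dir

    stage <- "common"
    log_msg(config, "stage common: within-species commonality")
    wild_species <- unique(cohort[group == "wild"]$species)
    by_species <- lapply(wild_species, function(sp)
      sets[cohort[species == sp]$accession])
    names(by_species) <- wild_species
    common_tab <- rbindlist(lapply(wild_species, function(sp) {
      ss <- by_species[[sp]]
      ck <- common_within_species(ss)
      data.table(species = sp, n_accessions = length(ss),
                 n_common = length(ck),
                 n_common_snp = length(common_within_species(ss, "SNP")),
                 n_common_indel = length(common_within_species(ss, "INDEL")),
                 percent_common_snp = if (length(ss) >= 2L)
                   percent_common(ss, config$percent_denominator) else NA_real_)
    }))
    write_tsv(common_tab, file.path(out, "species_common.tsv"))

    stage <- "specific"
    log_msg(config, "stage specific: species-specific variants")
    specific <- list()
    for (sp in wild_species) {
      if (length(by_species[[sp]]) < 2L) next
      specific[[sp]] <- species_specific(sp, sets)
    }
    spec_tab <- rbindlist(lapply(names(specific), function(sp)
      if (length(specific[[sp]]))
        data.table(species = sp, variant = specific[[sp]]) else NULL))
    if (nrow(spec_tab) == 0L)
      spec_tab <- data.table(species = character(), variant = character())
    write_tsv(spec_tab, file.path(out, "species_specific.tsv"))

    stage <- "differential"
    log_msg(config, "stage differential: common-wild partition")
    wild_sets <- sets[cohort[group == "wild"]$accession]
    cult_sets <- sets[cohort[group == "cultivated"]$accession]
    part <- common_wild_partition(wild_sets)
    part_tab <- data.table(metric = names(part$counts),
                           value = unlist(part$counts))
    write_tsv(part_tab, file.path(out, "partition_summary.tsv"))
    diff <- wild_differential(part, cult_sets)

    stage <- "annotate"
    log_msg(config, "stage annotate: regions and effects for ",
            nrow(diff), " differential variants")
    ann <- annotate_variants(diff, gm, data$reference, flank = config$flank,
                             assess_start_gained = config$assess_start_gained)
    write_tsv(ann, file.path(out, "differential.tsv"))
    high <- ann[impact == "HIGH", .N, by = effect]
    setorder(high, effect)
    write_tsv(high, file.path(out, "high_impact_summary.tsv"))
    region_counts <- ann[, .N, by = .(region, vtype)]
    write_tsv(region_counts, file.path(out, "differential_regions.tsv"))

    stage <- "genic_ratio"
    ratio_tab <- rbindlist(lapply(wild_species, function(sp) {
      ck <- common_within_species(by_species[[sp]])
      v <- wild_sets[[cohort[species == sp]$accession[1L]]]$variants[key %in% ck]
      rbind(cbind(genic_ratio(v[vtype == "SNP"], gm, sp), vtype = "SNP"),
            cbind(genic_ratio(v[vtype != "SNP"], gm, sp), vtype = "INDEL"))
    }))
    write_tsv(ratio_tab, file.path(out, "genic_ratio.tsv"))

    stage <- "popgen"
    log_msg(config, "stage popgen: windowed statistics")
    cult_acc <- cohort[group == "cultivated"]$accession
    sf <- site_frequencies(data$tables[cult_acc])
    if (isTRUE(config$fst)) {
      wild_acc <- cohort[group == "wild"]$accession
      sfw <- site_frequencies(data$tables[wild_acc])
      sf[sfw, `:=`(n2 = i.n, k2 = i.k), on = .(chrom, pos, alt)]
      sf[is.na(n2), `:=`(n2 = 2L * length(wild_acc), k2 = 0L)]
    }
    wins <- snp_windows(sf, window = config$window, step = config$step)
    write_tsv(wins, file.path(out, "windows.tsv"))
    dens_cult <- density_track(sf, data$chrom_lengths, config$density_bin)
    write_bedgraph(dens_cult, file.path(out, "density_cultivated.bedgraph"))
    dens_wild <- density_track(part$same_allele[vtype == "SNP"],
                               data$chrom_lengths, config$density_bin)
    write_bedgraph(dens_wild, file.path(out, "density_common_wild.bedgraph"))

    stage <- "regions"
    regions <- selection_regions(wins, low = config$d_low,
                                 high = config$d_high, gene_models = gm,
                                 include_partial = config$include_partial_windows)
    write_tsv(regions, file.path(out, "selection_regions.tsv"))
    if (nrow(regions) > 0L)
      write_bed(regions[, .(chrom, start, end, name = direction)],
                file.path(out, "selection_regions.bed"))
    region_len <- regions[, .(total_bp = sum(length)),
                          by = .(chrom, direction)]
    write_tsv(region_len, file.path(out, "selection_region_lengths.tsv"))

    stage <- "rgenes"
    rgenes <- filter_genes_by_keyword(gm, config$rgene_keywords)
    rg_hits <- ann[region == "genic" & gene_id %in% rgenes$gene_id]
    rg_report <- merge(rg_hits, rgenes[, .(gene_id, annotation)],
                       by = "gene_id")
    write_tsv(rg_report, file.path(out, "rgene_report.tsv"))

    stage <- "manifest"
    manifest <- list(
      package = "domesticscan",
      version = as.character(utils::packageVersion("domesticscan")),
      parameters = config[setdiff(names(config), "verbose")],
      counts = list(
        accessions = nrow(cohort),
        wild_accessions = sum(cohort$group == "wild"),
        cultivated_accessions = sum(cohort$group == "cultivated"),
        filtered_out_wild = sum(data$n_dropped),
        positions_all_wild = part$counts$positions_all_wild,
        same_allele_positions = part$counts$same_allele_positions,
        variable_allele_positions = part$counts$variable_allele_positions,
        same_allele_snp = part$counts$same_allele_snp,
        same_allele_indel = part$counts$same_allele_indel,
        differential = nrow(diff),
        differential_snp = sum(diff$vtype == "SNP"),
        differential_indel = sum(diff$vtype != "SNP"),
        differential_genic = sum(ann$region == "genic"),
        differential_flank = sum(ann$region %in% c("flank_up_2kb",
                                                   "flank_down_2kb")),
        high_impact = sum(ann$impact == "HIGH"),
        species_specific = as.list(table(spec_tab$species)),
        popgen_sites = nrow(sf),
        windows = nrow(wins),
        selection_regions = nrow(regions),
        resistance_genes = nrow(rgenes)))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(common = common_tab, specific = specific, partition = part,
         differential = ann, genic_ratio = ratio_tab, sites = sf,
         windows = wins, regions = regions, rgenes = rg_report,
         manifest = manifest)
  }, error = function(e) {
    writeLines(paste0("stage ", stage, ": ", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
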