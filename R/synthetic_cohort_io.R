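GT_STRINGS <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                missing = "./.")

#' Write one accession's calls as a VCF v4.2 file
#'
#' @param recs Record table for one accession (`chrom`, `pos`, `ref`,
#'   `alt`, `gt`, `dp`, `qual`, `ad_ref`, `ad_alt`), sorted by position.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @param contigs Named vector of chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
write_accession_vcf <- function(recs, path, sample_name, contigs) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=domesticscan-simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  if (nrow(recs) > 0L) {
    gt_str <- GT_STRINGS[recs$gt]
    dp_str <- ifelse(is.na(recs$dp), ".", as.character(recs$dp))
    ad_str <- ifelse(is.na(recs$ad_ref), ".",
                     paste0(recs$ad_ref, ",", recs$ad_alt))
    body <- paste(recs$chrom, recs$pos, ".", recs$ref, recs$alt,
                  sprintf("%.1f", recs$qual), "PASS",
                  ifelse(is.na(recs$dp), ".", paste0("DP=", recs$dp)),
                  "GT:DP:AD",
                  paste(gt_str, dp_str, ad_str, sep = ":"),
                  sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate and write a complete synthetic study to disk
#'
#' Runs [generate_reference()] and [simulate_cohort()] and writes the
#' reference FASTA, GFF3 annotation, one VCF per accession (under `vcf/`),
#' the cohort specification (`cohort.tsv`) and the planted truth
#' (`truth.json`). Output is deterministic: the same config yields
#' byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created).
#' @return list with `paths` (fasta, gff, vcf_dir, cohort, truth), `truth`,
#'   `cohort`, `gene_models`, and `config`.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(config)
  paths <- write_reference(ref, out_dir)
  sim <- simulate_cohort(config, ref)

  vcf_dir <- file.path(out_dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  for (acc in sim$cohort$accession) {
    recs <- sim$records[accession == acc]
    write_accession_vcf(recs, file.path(vcf_dir, paste0(acc, ".vcf")),
                        acc, config$chrom_lengths)
  }
  cohort_path <- file.path(out_dir, "cohort.tsv")
  write_tsv(sim$cohort, cohort_path)
  truth_path <- file.path(out_dir, "truth.json")
  truth_out <- sim$truth
  truth_out$records <- NULL
  jsonlite::write_json(truth_out, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  list(paths = c(paths, list(vcf_dir = vcf_dir, cohort = cohort_path,
                             truth = truth_path)),
       truth = sim$truth, cohort = sim$cohort,
       gene_models = ref$gene_models, records = sim$records,
       config = config)
}
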