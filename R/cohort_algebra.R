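#' Cohort specification
#'
#' The accession -> species -> group mapping that drives every set
#' operation. Groups are `"wild"` or `"cultivated"`; each wild species may
#' hold one or more accessions.
#'
#' @param df Data frame with columns `accession`, `species`, `group`.
#' @return A `cohort_spec` object (validated data.table).
#' @export
cohort_spec <- function(df) {
  dt <- as.data.table(df)[, .(accession = as.character(accession),
                              species = as.character(species),
                              group = as.character(group))]
  if (anyDuplicated(dt$accession)) stop("accession ids must be unique")
  if (!all(dt$group %in% c("wild", "cultivated")))
    stop("group must be 'wild' or 'cultivated'")
  structure(dt, class = c("cohort_spec", class(dt)))
}

#' @rdname cohort_spec
#' @param path Tab-delimited file with a header row naming the three columns.
#' @export
read_cohort_spec <- function(path) {
  cohort_spec(fread(path, sep = "\t", colClasses = "character"))
}

#' Per-accession variant set
#'
#' Wraps an accession's (filtered) variant table with its cohort identity
#' and the keyed views the set algebra works on. SNP and indel views are
#' disjoint and their union is the full set.
#'
#' @param variants Variant table (`chrom`, `pos`, `ref`, `alt`, `vtype`,
#'   and optionally `gt`); duplicate keys are collapsed.
#' @param accession_id,species,group Cohort identity of the accession.
#' @return An `accession_variant_set`: list with `accession_id`, `species`,
#'   `group`, and `variants` (data.table keyed by the `key` column).
#' @export
accession_variant_set <- function(variants, accession_id, species, group) {
  v <- as.data.table(variants)
  keep <- intersect(c("chrom", "pos", "ref", "alt", "vtype", "gt"), names(v))
  v <- v[, ..keep]
  if (!"vtype" %in% names(v)) v[, vtype := classify_vtype(ref, alt)]
  v[, key := variant_key(chrom, pos, ref, alt)]
  v <- unique(v, by = "key")
  setorder(v, chrom, pos, ref, alt)
  structure(list(accession_id = accession_id, species = species,
                 group = group, variants = v),
            class = "accession_variant_set")
}

#' @export
print.accession_variant_set <- function(x, ...) {
  cat(sprintf("<accession_variant_set> %s (%s, %s): %d variants (%d SNP, %d InDel)\n",
              x$accession_id, x$species, x$group, nrow(x$variants),
              sum(x$variants$vtype == "SNP"),
              sum(x$variants$vtype != "SNP")))
  invisible(x)
}

avs_keys <- function(set, vtype = NULL) {
  v <- set$variants
  if (!is.null(vtype)) {
    v <- if (vtype == "SNP") v[vtype == "SNP"] else v[vtype != "SNP"]
  }
  v$key
}

#' Variants common to all accessions of one species
#'
#' Intersection under full variant-key equality (position AND allele): a
#' position carried by every accession but with different alternate
#' alleles is not common. A single-accession species returns its own set
#' unchanged.
#'
#' @param sets List of [accession_variant_set()] objects, all of one species.
#' @param vtype Optional `"SNP"` or `"INDEL"` restriction.
#' @return Character vector of variant keys.
#' @export
common_within_species <- function(sets, vtype = NULL) {
  if (length(sets) == 0L) stop("empty set list")
  sp <- unique(vapply(sets, `[[`, "", "species"))
  if (length(sp) != 1L)
    stop("common_within_species requires accessions of a single species; got: ",
         paste(sp, collapse = ", "))
  Reduce(intersect, lapply(sets, avs_keys, vtype = vtype))
}

#' Percentage of SNPs common to all accessions of a species
#'
#' 100 x |intersection| / |denominator|, computed on the SNP views. The
#' denominator defaults to the union of all accessions' SNPs; the mean
#' set size and the smallest set are available as alternatives because
#' the statistic's normalization is a modelling choice.
#'
#' @param sets List of [accession_variant_set()] for one species (>= 2).
#' @param denominator `"union"` (default), `"mean"` or `"min"`.
#' @return Percentage in `[0, 100]`, or `NA` for an empty denominator or a
#'   single-accession species.
#' @export
percent_common <- function(sets, denominator = c("union", "mean", "min")) {
  denominator <- match.arg(denominator)
  if (length(sets) < 2L) return(NA_real_)
  keys <- lapply(sets, avs_keys, vtype = "SNP")
  denom <- switch(denominator,
                  union = length(unique(unlist(keys))),
                  mean = mean(lengths(keys)),
                  min = min(lengths(keys)))
  if (denom == 0) return(NA_real_)
  100 * length(Reduce(intersect, keys)) / denom
}

#' Species-specific variants
#'
#' Variants common to every accession of the target species and absent
#' (as position+allele) from every other accession in the cohort, wild or
#' cultivated. By default the target species must have at least two
#' accessions, since a single accession cannot distinguish a
#' species-specific allele from an accession-private one.
#'
#' @param target_species Species name.
#' @param sets Named list of [accession_variant_set()] for the whole cohort.
#' @param allow_single Permit a single-accession target species.
#' @param vtype Optional `"SNP"`/`"INDEL"` restriction.
#' @return Character vector of variant keys.
#' @export
species_specific <- function(target_species, sets, allow_single = FALSE,
                             vtype = NULL) {
  in_target <- vapply(sets, function(s) s$species == target_species, TRUE)
  if (!any(in_target)) stop("species not in cohort: ", target_species)
  if (sum(in_target) < 2L && !allow_single)
    stop("species ", target_species,
         " has a single accession; set allow_single = TRUE to override")
  common <- common_within_species(sets[in_target], vtype = vtype)
  others <- unique(unlist(lapply(sets[!in_target], avs_keys, vtype = NULL)))
  setdiff(common, others)
}

#' Partition positions variant in every wild accession
#'
#' Finds the positions at which every wild accession carries a variant and
#' splits them by allele identity: `same_allele` holds the variant keys
#' present identically in every wild accession, `variable_allele` the
#' positions where all accessions are variant but no single allele is
#' universal.
#'
#' @param wild_sets List of filtered [accession_variant_set()] for all
#'   wild accessions.
#' @return A `common_wild_partition`: list with `same_allele` (data.table:
#'   `key`, `chrom`, `pos`, `ref`, `alt`, `vtype`), `variable_allele`
#'   (data.table: `chrom`, `pos`), `n_wild`, and `counts` (positions all
#'   wild / same-allele positions / variable-allele positions / same-allele
#'   SNP and InDel keys).
#' @export
common_wild_partition <- function(wild_sets) {
  n_wild <- length(wild_sets)
  if (n_wild == 0L) stop("no wild accession sets supplied")
  long <- rbindlist(lapply(wild_sets, function(s)
    s$variants[, .(chrom, pos, ref, alt, vtype, key,
                   accession = s$accession_id)]))
  pos_acc <- long[, .(n_acc = uniqueN(accession)), by = .(chrom, pos)]
  all_pos <- pos_acc[n_acc == n_wild, .(chrom, pos)]
  in_all <- long[all_pos, on = .(chrom, pos)]
  key_acc <- in_all[, .(n_acc = uniqueN(accession)),
                    by = .(chrom, pos, ref, alt, vtype, key)]
  same <- key_acc[n_acc == n_wild,
                  .(key, chrom, pos, ref, alt, vtype)]
  setorder(same, chrom, pos, ref, alt)
  same_pos <- unique(same[, .(chrom, pos)])
  variable <- all_pos[!same_pos, on = .(chrom, pos)]
  setorder(variable, chrom, pos)
  structure(list(
    same_allele = same,
    variable_allele = variable,
    n_wild = n_wild,
    counts = list(
      positions_all_wild = nrow(all_pos),
      same_allele_positions = nrow(same_pos),
      variable_allele_positions = nrow(variable),
      same_allele_snp = sum(same$vtype == "SNP"),
      same_allele_indel = sum(same$vtype != "SNP"))),
    class = "common_wild_partition")
}

#' @export
print.common_wild_partition <- function(x, ...) {
  with(x$counts, cat(sprintf(
    paste0("<common_wild_partition> %d wild accessions\n",
           "  positions variant in all wild: %d\n",
           "  same-allele positions: %d (%d SNP, %d InDel keys)\n",
           "  variable-allele positions: %d\n"),
    x$n_wild, positions_all_wild, same_allele_positions,
    same_allele_snp, same_allele_indel, variable_allele_positions)))
  invisible(x)
}

# Alleles observed in cultivated genotype calls, per position: a het call
# contributes both its reference and alternate allele, a hom-alt call its
# alternate allele; an explicitly missing genotype contributes nothing.
cultivated_allele_table <- function(cultivated_sets) {
  long <- rbindlist(lapply(cultivated_sets, function(s) {
    v <- s$variants
    if (!"gt" %in% names(v)) v <- copy(v)[, gt := "hom_alt"]
    v[, .(chrom, pos, ref, alt, gt)]
  }))
  long <- long[gt != "missing"]
  alt_side <- long[gt %in% c("het", "hom_alt"), .(chrom, pos, allele = alt)]
  ref_side <- long[gt %in% c("het", "hom_ref"), .(chrom, pos, allele = ref)]
  unique(rbind(alt_side, ref_side))
}

#' Common wild alleles absent from every cultivated accession
#'
#' Subset of the partition's same-allele keys whose alternate allele does
#' not occur as any allele call (either allele of a het, the allele of a
#' hom call) at that position in any cultivated accession. A cultivated
#' accession with a missing call at a position contributes no alleles
#' there and does not veto inclusion; a position absent from a cultivated
#' VCF likewise contributes nothing beyond the implicit reference, which
#' can never equal the wild alternate allele.
#'
#' Comparison is allele-level on normalized representations; SNPs and
#' indels are processed identically and distinguished by `vtype`.
#'
#' @param partition A [common_wild_partition()].
#' @param cultivated_sets List of unfiltered cultivated
#'   [accession_variant_set()] objects.
#' @return data.table of differential variants (`key`, `chrom`, `pos`,
#'   `ref`, `alt`, `vtype`).
#' @export
wild_differential <- function(partition, cultivated_sets) {
  stopifnot(inherits(partition, "common_wild_partition"))
  same <- partition$same_allele
  if (nrow(same) == 0L) return(copy(same))
  cult <- cultivated_allele_table(cultivated_sets)
  hit <- cult[same, on = .(chrom, pos, allele = alt), nomatch = NULL,
              .(chrom, pos, alt = allele)]
  out <- same[!unique(hit), on = .(chrom, pos, alt)]
  setorder(out, chrom, pos, ref, alt)
  out[]
}
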