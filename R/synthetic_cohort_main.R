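#' Simulate the full variant cohort with planted ground truth
#'
#' Plants, on top of species-structured background variation: per-species
#' species-specific variants (with a controlled genic fraction); common
#' wild alleles split into cultivated-absent (differential, including
#' designed coding-effect variants of every HIGH-impact class) and
#' cultivated-shared; discordant all-wild positions with species-dependent
#' alleles; filter-failing negative controls; and a selective-sweep
#' segment whose cultivated sites are all singletons. Background wild
#' variants are shared by all accessions of a species with the species'
#' sharing probability (and then also segregate in the cultivated panel)
#' or by a proper subset; cultivated background sites follow the neutral
#' 1/k site-frequency spectrum.
#'
#' @param config A [simulation_config()].
#' @param ref Result of [generate_reference()] for the same config.
#' @return list with `records` (per-accession call table), `cohort`
#'   ([cohort_spec()]), and `truth` (planted categories, per-species
#'   common-set counts, sweep span and genes).
#' @export
simulate_cohort <- function(config, ref) {
  set.seed(config$seed + 1L)
  chrom_str <- setNames(as.character(ref$reference), names(ref$reference))
  genes <- ref$genes
  gm <- ref$gene_models
  cohort <- sim_cohort_table(config)
  wild_acc <- cohort[group == "wild"]$accession
  cult_acc <- cohort[group == "cultivated"]$accession
  n_cult <- length(cult_acc)

  pool <- new_pos_pool(config$chrom_lengths)
  sw <- config$sweep
  pool$used[[sw$chrom]][sw$start:sw$end] <- TRUE   # reserve the swept segment

  # span lookups (genes never overlap and sit >= 5 kb apart)
  by_chrom_spans <- function(dt) {
    if (nrow(dt) == 0L) return(list())
    lapply(split(dt, by = "chrom", keep.by = FALSE), function(d) {
      setorder(d, start)
      list(starts = d$start, ends = d$end)
    })
  }
  gene_sp <- by_chrom_spans(gm$genes[, .(chrom, start, end)])
  gene_wide_sp <- by_chrom_spans(gm$genes[, .(chrom, start = start - 2000L,
                                              end = end + 2000L)])
  cds_sp <- by_chrom_spans(gm$cds[, .(chrom, start = start - 2L,
                                      end = end + 2L)])
  pred_in <- function(sp) function(chrom, pos) {
    out <- logical(length(pos))
    for (ch in unique(chrom)) {
      i <- chrom == ch
      out[i] <- if (is.null(sp[[ch]])) FALSE else
        in_spans(pos[i], sp[[ch]]$starts, sp[[ch]]$ends)
    }
    out
  }
  ok_genic <- pred_in(gene_sp)
  ok_cds <- pred_in(cds_sp)
  ok_intergenic <- function(chrom, pos) !pred_in(gene_wide_sp)(chrom, pos)
  gene_of <- function(chrom_v, pos_v) {
    gdt <- gm$genes
    vapply(seq_along(pos_v), function(i) {
      w <- which(gdt$chrom == chrom_v[i] & gdt$start <= pos_v[i] &
                   gdt$end >= pos_v[i])
      if (length(w)) gdt$gene_id[w[1L]] else NA_character_
    }, "")
  }

  mix <- config$differential_mix
  snp_at <- function(posdt) {
    ref_ <- ref_base_at(chrom_str, posdt$chrom, posdt$pos)
    data.table(chrom = posdt$chrom, pos = posdt$pos, ref = ref_,
               alt = other_base(ref_), vtype = "SNP")
  }

  # --- designed effect variants, one gene each -----------------------------
  gene_ids <- resample(names(genes))
  gi <- 1L
  next_gene <- function(need_multi_cds = FALSE, need_utr = 0L) {
    while (gi <= length(gene_ids)) {
      g <- genes[[gene_ids[gi]]]
      gi <<- gi + 1L
      if (need_multi_cds && nrow(g$cds) < 2L) next
      if (need_utr > 0L && g$exon_off[1L, 1L] - 1L < need_utr) next
      return(g)
    }
    stop("ran out of genes for effect planting")
  }
  plant_effect <- function(class, n) {
    out <- vector("list", n)
    for (j in seq_len(n)) {
      repeat {
        v <- switch(class,
          splice_site = design_splice(next_gene(need_multi_cds = TRUE),
                                      chrom_str),
          frameshift = design_cds_indel(next_gene(), chrom_str,
                                        frameshift = TRUE),
          inframe_indel = design_cds_indel(next_gene(), chrom_str,
                                           frameshift = FALSE),
          start_gained = design_start_gained(next_gene(need_utr = 12L)),
          design_snp_effect(class, next_gene()))
        if (!is.null(v) &&
            !any(is_used(pool, v$chrom, v$pos:(v$pos + nchar(v$ref))))) break
      }
      claim(pool, rep(v$chrom, nchar(v$ref) + 1L), v$pos:(v$pos + nchar(v$ref)))
      out[[j]] <- v
    }
    rbindlist(out)[, class := class]
  }
  effect_classes <- c("stop_gained", "stop_lost", "start_lost", "splice_site",
                      "frameshift", "inframe_indel", "missense", "synonymous",
                      "start_gained")
  eff <- rbindlist(lapply(effect_classes, function(cl)
    plant_effect(cl, mix[[cl]])))

  # --- remaining differential classes --------------------------------------
  gnc <- local({
    out <- NULL
    while (is.null(out) || nrow(out) < mix$genic_noncoding) {
      need <- mix$genic_noncoding - if (is.null(out)) 0L else nrow(out)
      p <- draw_positions(pool, need, function(chrom, pos)
        ok_genic(chrom, pos) & !ok_cds(chrom, pos))
      v <- snp_at(p)
      gid <- gene_of(v$chrom, v$pos)
      strand <- gm$genes$strand[match(gid, gm$genes$gene_id)]
      keep <- !mapply(creates_atg, v$chrom, v$pos, v$alt, strand,
                      MoreArgs = list(chrom_str = chrom_str))
      out <- rbind(out, v[keep])
    }
    out[, class := "genic_noncoding"]
  })
  plant_flank <- function(n, side) {
    out <- vector("list", n)
    gdt <- gm$genes
    j <- 1L
    while (j <= n) {
      g <- gdt[sample(nrow(gdt), 1L)]
      # upstream is 5' of the gene span on its strand
      left <- (side == "flank_up") == (g$strand == "+")
      if (left) {
        lo <- max(1L, g$start - 2000L)
        hi <- g$start - 1L
      } else {
        lo <- g$end + 1L
        hi <- min(config$chrom_lengths[[g$chrom]], g$end + 2000L)
      }
      pos <- sample(lo:hi, 1L)
      if (is_used(pool, g$chrom, pos)) next
      claim(pool, g$chrom, pos)
      out[[j]] <- data.table(chrom = g$chrom, pos = pos)
      j <- j + 1L
    }
    snp_at(rbindlist(out))[, class := side]
  }
  fup <- plant_flank(mix$flank_up, "flank_up")
  fdn <- plant_flank(mix$flank_down, "flank_down")
  ig_snp <- snp_at(draw_positions(pool, mix$intergenic_snp,
                                  ok_intergenic))[, class := "intergenic_snp"]
  ig_ind <- local({
    out <- NULL
    while (is.null(out) || nrow(out) < mix$intergenic_indel) {
      p <- draw_positions(pool, 1L, ok_intergenic)
      v <- design_intergenic_indel(chrom_str, p$chrom, p$pos)
      if (is.null(v)) next
      extra <- (v$pos + 1L):(v$pos + nchar(v$ref))
      if (any(is_used(pool, rep(v$chrom, length(extra)), extra))) next
      claim(pool, rep(v$chrom, length(extra)), extra)
      out <- rbind(out, v)
    }
    out[, class := "intergenic_indel"]
  })

  differential <- rbind(eff, gnc, fup, fdn, ig_snp, ig_ind)
  differential[, genic := class %in% c("stop_gained", "stop_lost",
                                       "start_lost", "splice_site",
                                       "frameshift", "inframe_indel",
                                       "missense", "synonymous",
                                       "start_gained", "genic_noncoding")]
  differential[, key := variant_key(chrom, pos, ref, alt)]

  # --- cultivated-shared common wild alleles --------------------------------
  n_sh_indel <- round(config$n_shared_common / 8)
  sh_pos <- draw_positions(pool, config$n_shared_common, NULL)
  shared <- snp_at(sh_pos[seq_len(config$n_shared_common - n_sh_indel)])
  sh_ind <- local({
    out <- NULL
    i <- config$n_shared_common - n_sh_indel
    while (is.null(out) || nrow(out) < n_sh_indel) {
      i <- i + 1L
      p <- if (i <= nrow(sh_pos)) sh_pos[i] else draw_positions(pool, 1L, NULL)
      v <- design_intergenic_indel(chrom_str, p$chrom, p$pos)
      if (is.null(v)) next
      extra <- (v$pos + 1L):(v$pos + nchar(v$ref))
      if (any(is_used(pool, rep(v$chrom, length(extra)), extra))) next
      claim(pool, rep(v$chrom, length(extra)), extra)
      out <- rbind(out, v)
    }
    out
  })
  shared <- rbind(shared, sh_ind)
  shared[, genic := ok_genic(chrom, pos)]
  shared[, key := variant_key(chrom, pos, ref, alt)]

  # --- discordant all-wild positions (no universal allele) ------------------
  disc_pos <- draw_positions(pool, config$n_discordant, ok_intergenic)
  disc_ref <- ref_base_at(chrom_str, disc_pos$chrom, disc_pos$pos)
  sh12 <- sample(rep(1:3, length.out = nrow(disc_pos)))
  sh2 <- (sh12 %% 3L) + 1L   # guaranteed different shift => different allele
  discordant <- data.table(chrom = disc_pos$chrom, pos = disc_pos$pos,
                           ref = disc_ref,
                           alt_a = other_base(disc_ref, sh12),
                           alt_b = other_base(disc_ref, sh2))
  species_names <- config$species$species
  group_a <- sample(species_names, ceiling(length(species_names) / 2))

  # --- species-specific variants -------------------------------------------
  eligible <- config$species[n_acc >= 2L]
  spec_list <- list()
  for (si in seq_len(nrow(eligible))) {
    sp <- eligible$species[si]
    n_sp <- config$n_species_specific
    n_gen <- round(eligible$genic_frac[si] * n_sp)
    pg <- draw_positions(pool, n_gen, ok_genic)
    pn <- draw_positions(pool, n_sp - n_gen, function(chrom, pos)
      !ok_genic(chrom, pos))
    v <- rbind(snp_at(pg)[, genic := TRUE], snp_at(pn)[, genic := FALSE])
    v[, species := sp]
    spec_list[[sp]] <- v
  }
  specifics <- rbindlist(spec_list)
  specifics[, key := variant_key(chrom, pos, ref, alt)]

  # --- negative controls (every wild call fails the filter) -----------------
  negs <- snp_at(draw_positions(pool, config$n_negative_controls, NULL))
  negs[, key := variant_key(chrom, pos, ref, alt)]

  # --- wild background -------------------------------------------------------
  bg_list <- list()
  bg_shared_summary <- list()
  for (si in seq_len(nrow(config$species))) {
    sp <- config$species$species[si]
    n_a <- config$species$n_acc[si]
    p_share <- config$species$share_prob[si]
    accs <- cohort[species == sp]$accession
    m <- config$bg_per_species
    pos <- draw_positions(pool, m, NULL)
    v <- snp_at(pos)
    is_shared <- if (n_a == 1L) rep(TRUE, m) else runif(m) < p_share
    sh_rows <- v[is_shared][rep(seq_len(sum(is_shared)), each = n_a)]
    sh_rows[, accession := rep(accs, times = sum(is_shared))]
    ns_idx <- which(!is_shared)
    if (length(ns_idx) > 0L) {
      ssize <- sample(n_a - 1L, length(ns_idx), replace = TRUE)
      ns_rows <- v[ns_idx][rep(seq_along(ns_idx), times = ssize)]
      ns_rows[, accession := unlist(lapply(ssize, function(s)
        accs[sample.int(n_a, s)])) ]
      bg_sp <- rbind(sh_rows, ns_rows)
    } else bg_sp <- sh_rows
    bg_list[[sp]] <- bg_sp
    sh <- v[is_shared]
    sh[, genic := ok_genic(chrom, pos)]
    sh[, species := sp]
    bg_shared_summary[[sp]] <- sh
  }
  wild_bg <- rbindlist(bg_list)
  bg_shared <- rbindlist(bg_shared_summary)

  # --- cultivated panel ------------------------------------------------------
  cult_bg_pos <- draw_positions(pool, config$n_cultivated_bg, NULL)
  cult_bg <- snp_at(cult_bg_pos)

  # cultivated alleles shared with wild material: the within-species common
  # background and the planted shared-common set segregate in the panel
  # some cultivated accessions carry a third allele at a differential
  # position: the wild allele still counts as absent from the panel
  n_alt2 <- min(20L, nrow(ig_snp))
  alt2 <- ig_snp[seq_len(n_alt2), .(chrom, pos, ref, wild_alt = alt)]
  alt2[, alt := mapply(function(r, a) setdiff(DNA_BASES, c(r, a))[1L],
                       ref, wild_alt)]
  alt2 <- alt2[, .(chrom, pos, ref, alt, vtype = "SNP")]

  cult_sites <- rbind(
    bg_shared[, .(chrom, pos, ref, alt, vtype)],
    shared[, .(chrom, pos, ref, alt, vtype)],
    alt2,
    cult_bg)
  k <- sfs_counts(nrow(cult_sites), 2L * n_cult)
  geno <- sfs_genotypes(seq_len(nrow(cult_sites)), k, n_cult)
  cult_rows <- cult_sites[geno$site]
  cult_rows[, accession := cult_acc[geno$acc]]
  cult_rows <- cbind(cult_rows, cultivated_fields(geno$gt, config))
  cult_rows[, category := "cultivated"]

  # explicit missing cultivated calls: background sites and a handful of
  # differential positions (a missing call must not veto a differential)
  n_miss <- round(config$cultivated_missing_rate * nrow(cult_bg) * n_cult)
  miss_bg <- data.table(
    site = sample(nrow(cult_bg), n_miss, replace = TRUE),
    accession = cult_acc[sample(n_cult, n_miss, replace = TRUE)])
  miss_bg <- unique(miss_bg)
  miss_rows <- cult_bg[miss_bg$site]
  miss_rows[, accession := miss_bg$accession]
  ig_all <- differential[class == "intergenic_snp"]
  dm_idx <- if (nrow(ig_all) > n_alt2)
    seq.int(n_alt2 + 1L, min(nrow(ig_all), n_alt2 + 10L)) else integer()
  dm <- ig_all[dm_idx, .(chrom, pos, ref, alt, vtype)]
  if (nrow(dm) > 0L)
    dm[, accession := cult_acc[sample(n_cult, .N, replace = TRUE)]]
  miss_rows <- rbind(miss_rows, dm, fill = TRUE)
  miss_rows[, `:=`(gt = "missing", dp = NA_integer_,
                   qual = round(runif(.N, 20, 60), 1),
                   ad_ref = NA_integer_, ad_alt = NA_integer_,
                   category = "cultivated_missing")]
  # drop any collision with carrier records
  miss_rows <- miss_rows[!cult_rows, on = .(chrom, pos, accession)]

  # --- swept segment: cultivated singletons ---------------------------------
  sw_pos <- sort(sample((sw$start + 5L):(sw$end - 5L), sw$n_sites))
  sw_ref <- ref_base_at(chrom_str, rep(sw$chrom, sw$n_sites), sw_pos)
  sweep_sites <- data.table(chrom = sw$chrom, pos = sw_pos, ref = sw_ref,
                            alt = other_base(sw_ref), vtype = "SNP")
  sweep_rows <- copy(sweep_sites)
  sweep_rows[, accession := cult_acc[sample(n_cult, .N, replace = TRUE)]]
  sweep_rows <- cbind(sweep_rows,
                      cultivated_fields(rep("het", nrow(sweep_sites)), config))
  sweep_rows[, category := "sweep"]

  # --- wild-side record assembly --------------------------------------------
  wild_rows <- rbind(
    expand_confident(differential, wild_acc, config, "differential"),
    expand_confident(shared, wild_acc, config, "shared_common"),
    {
      da <- rbindlist(lapply(species_names, function(sp) {
        al <- if (sp %in% group_a) discordant$alt_a else discordant$alt_b
        accs <- cohort[species == sp]$accession
        vd <- data.table(chrom = discordant$chrom, pos = discordant$pos,
                         ref = discordant$ref, alt = al, vtype = "SNP")
        expand_confident(vd, accs, config, "discordant")
      }))
      da
    },
    rbindlist(lapply(split(specifics, by = "species"), function(v)
      expand_confident(v, cohort[species == v$species[1L]]$accession,
                       config, "species_specific"))),
    {
      nr <- negs[rep(seq_len(nrow(negs)), each = length(wild_acc)),
                 .(chrom, pos, ref, alt, vtype)]
      nr[, accession := rep(wild_acc, times = nrow(negs))]
      cbind(nr, negative_fields(nrow(nr), config))[, category := "negative_control"]
    },
    cbind(wild_bg, confident_fields(nrow(wild_bg), config))[
      , category := "background"],
    fill = TRUE)

  records <- rbind(wild_rows, cult_rows, miss_rows, sweep_rows, fill = TRUE)
  setorder(records, accession, chrom, pos)

  # --- truth ------------------------------------------------------------------
  sweep_genes <- gm$genes[chrom == sw$chrom & start <= max(sw_pos) &
                            end >= min(sw_pos)]$gene_id
  per_species <- rbindlist(lapply(seq_len(nrow(config$species)), function(si) {
    sp <- config$species$species[si]
    bg_sp <- bg_shared[species == sp]
    spx <- specifics[species == sp]
    n_snp <- nrow(differential[vtype == "SNP"]) + sum(shared$vtype == "SNP") +
      nrow(discordant) + nrow(spx) + nrow(bg_sp)
    n_snp_genic <- sum(differential$genic & differential$vtype == "SNP") +
      sum(shared$genic & shared$vtype == "SNP") + sum(spx$genic) +
      sum(bg_sp$genic)
    n_ind <- sum(differential$vtype != "SNP") + sum(shared$vtype != "SNP")
    n_ind_genic <- sum(differential$genic & differential$vtype != "SNP") +
      sum(shared$genic & shared$vtype != "SNP")
    data.table(species = sp, n_acc = config$species$n_acc[si],
               n_common_snp = n_snp, n_common_snp_genic = n_snp_genic,
               n_common_indel = n_ind, n_common_indel_genic = n_ind_genic,
               n_specific = nrow(spx), n_specific_genic = sum(spx$genic))
  }))

  truth <- list(
    seed = config$seed,
    species_specific = lapply(split(specifics, by = "species"),
                              function(v) v$key),
    differential = differential[, .(key, chrom, pos, ref, alt, vtype,
                                    class, genic)],
    effects = lapply(split(differential[class %in% effect_classes],
                           by = "class"), function(v) v$key),
    shared_common = shared$key,
    discordant_positions = position_key(discordant$chrom, discordant$pos),
    negative_controls = negs$key,
    per_species = per_species,
    sweep = list(chrom = sw$chrom, span_start = min(sw_pos),
                 span_end = max(sw_pos), n_sites = sw$n_sites,
                 genes = sweep_genes),
    n_resistance_genes = ref$n_resistance)
  if (config$truth_genotypes) truth$records <- records

  list(records = records, cohort = cohort, truth = truth)
}
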