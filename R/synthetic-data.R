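# Seeded generator of synthetic sibling cohorts and exome-like variant
# tables with planted modifier variants, so the scoring engine and the
# prioritization cascade can be tested end to end without patient data.
# The generator emulates the *structure* the analysis assumes - an
# 11-sibling two-family cohort and a variant table whose counts shrink
# under the filter cascade - not the marginal realism of true WES data
# (no linkage disequilibrium, no site-frequency-spectrum realism, no
# Mendelian transmission; siblings are genotyped independently).

# Finite sampling intervals per item grade (replacing open published
# edges with realistic caps). Values are sampled uniformly inside the
# target-grade interval, then perturbed by noise bounded by
# noise_frac * interval width, so a measurement's grade can differ from
# its target grade by at most one (noise_frac <= 0.5).
SIM_BINS <- list(
  AAO = data.frame(grade = 1:6,
                   lo = c(50, 40, 30, 15, 10, 1),
                   hi = c(60, 49, 39, 29, 14, 9)),
  MMT = data.frame(grade = 0:4,
                   lo = c(100, 90, 80, 70, 40), hi = c(100, 99, 89, 79, 69)),
  SIXMWT_F = data.frame(grade = 0:6,
                        lo = c(423, 362, 301, 240, 179, 118, 5),
                        hi = c(520, 422, 361, 300, 239, 178, 117)),
  SIXMWT_M = data.frame(grade = 0:6,
                        lo = c(536, 476, 395, 315, 234, 150, 5),
                        hi = c(640, 535, 475, 394, 314, 233, 149)),
  GSCG = data.frame(grade = 0:4,
                    lo = c(4, 5, 9, 16, 22), hi = c(4, 8, 15, 21, 27)),
  FVC = data.frame(grade = 0:4,
                   lo = c(80, 70, 60, 50, 30), hi = c(110, 79, 69, 59, 49)),
  DFVC = data.frame(grade = 0:4,
                    lo = c(0, 10, 16, 21, 31), hi = c(9, 15, 20, 30, 60)),
  BMI = data.frame(grade = 0:4,
                   lo = c(19.5, 25, 30, 36, 40.1),
                   hi = c(24.9, 29.9, 35.9, 40, 50)),
  VDD = data.frame(grade = 0:2, lo = c(30, 20, 2), hi = c(60, 29.9, 19.9))
)

#' Default planted-modifier specifications
#'
#' Three plants exercising the three carrier rules: a novel non-synonymous
#' variant carried by every moderate-or-worse patient of both families, a
#' rare non-synonymous variant private to (and shared by all of) family 1,
#' and a rare splicing variant carried by all affected siblings.
#'
#' @return list of plant specs (`gene`, `func_class`, `maf`, `cadd`,
#'   `rule`, optional `family`).
#' @export
default_plants <- function() {
  list(
    list(gene = "PLANTA", func_class = "nonsynonymous_SNV", maf = NA_real_,
         cadd = 28, rule = "both_families_high_severity"),
    list(gene = "PLANTB", func_class = "nonsynonymous_SNV", maf = 0.01,
         cadd = 25, rule = "family_specific", family = "F1"),
    list(gene = "PLANTC", func_class = "splicing", maf = 0.05,
         cadd = 24, rule = "all_affected")
  )
}

#' Simulation parameters
#'
#' The defaults state the emulated world: two families of 7 and 4 affected
#' siblings (the published cohort layout), latent per-patient severities
#' `s` drawn from Beta(2, 2) on `[0, 1]` (a unimodal spread around
#' moderate severity, so both severity groups are usually populated),
#' item-level noise bounded at a quarter of a grade-bin width, 1,000
#' background variants with population frequency from Beta(0.5, 5)
#' truncated to `[0, 0.5]` (a rare-skewed folded site-frequency spectrum),
#' CADD phred from Gamma(shape 2, scale 6) (mode around 6, a long
#' deleterious tail reaching past 20), and half of the background coding
#' variants synonymous.
#'
#' @param seed mandatory integer master seed; every component derives its
#'   own substream from it.
#' @param n_families,n_siblings cohort layout.
#' @param severity_beta Beta parameters of the latent severity.
#' @param noise_frac measurement noise as a fraction of the target bin
#'   width, in `[0, 0.5]`.
#' @param n_background number of background variants.
#' @param maf_beta,maf_trunc Beta parameters and truncation of background
#'   population frequency.
#' @param cadd_gamma shape and scale of background CADD phred.
#' @param frac_synonymous fraction of background variants that are
#'   synonymous.
#' @param plants list of plant specs, see [default_plants()].
#' @return validated list of class `lopd_sim_params`.
#' @export
sim_params <- function(seed,
                       n_families = 2L,
                       n_siblings = c(7L, 4L),
                       severity_beta = c(2, 2),
                       noise_frac = 0.25,
                       n_background = 1000L,
                       maf_beta = c(0.5, 5),
                       maf_trunc = 0.5,
                       cadd_gamma = c(shape = 2, scale = 6),
                       frac_synonymous = 0.5,
                       plants = default_plants()) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_families >= 1, length(n_siblings) == n_families,
            all(n_siblings >= 1), all(severity_beta > 0),
            noise_frac >= 0, noise_frac <= 0.5, n_background >= 0,
            all(maf_beta > 0), maf_trunc > 0, maf_trunc <= 1,
            all(cadd_gamma > 0), frac_synonymous >= 0, frac_synonymous <= 1)
  for (pl in plants) {
    if (pl$rule %in% c("both_families_high_severity") && n_families < 2) {
      stop("plant rule ", pl$rule, " needs at least two families",
           call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 n_siblings = as.integer(n_siblings),
                 severity_beta = severity_beta, noise_frac = noise_frac,
                 n_background = as.integer(n_background),
                 maf_beta = maf_beta, maf_trunc = maf_trunc,
                 cadd_gamma = cadd_gamma,
                 frac_synonymous = frac_synonymous, plants = plants),
            class = "lopd_sim_params")
}

# Sample a measurement whose grade equals `target` up to +/- 1 bin.
# Degenerate severities (s exactly 0 or 1) return the bin midpoint so the
# floor and ceiling of the rubric are hit exactly.
sample_in_bin <- function(bins, target, noise_frac, s, digits = 0,
                          dom_lo = -Inf, dom_hi = Inf) {
  b <- bins[bins$grade == target, ]
  w <- b$hi - b$lo
  if (s <= 1e-6 || s >= 1 - 1e-6 || w == 0) {
    v <- (b$lo + b$hi) / 2
  } else {
    v <- stats::runif(1, b$lo, b$hi) +
      stats::runif(1, -1, 1) * noise_frac * w
  }
  v <- min(max(v, dom_lo), dom_hi)
  round_half_up(v, digits)
}

#' Simulate a clinical sibling cohort
#'
#' Draws a latent severity `s` in `[0, 1]` per patient and generates every
#' clinical item by mapping `s` onto the item's grade range, sampling a
#' measurement inside the selected grade bin, and adding bounded noise
#' that cannot move the measurement across more than one bin edge. Boolean
#' findings are Bernoulli with probability `s`, so a severity of 0 yields
#' an all-normal record (every gradeable item at grade 0 except age at
#' onset, which always grades at least 1) and a severity of 1 yields the
#' structural maximum.
#'
#' @param p an `lopd_sim_params` object.
#' @return list with `dataset` (an `lopd_clinical`) and `truth` (latent
#'   severities and per-item target grades).
#' @export
simulate_cohort <- function(p) {
  stopifnot(inherits(p, "lopd_sim_params"))
  with_substream(p$seed, "cohort", {
    ids <- unlist(lapply(seq_len(p$n_families), function(f) {
      sprintf("F%dII-%d", f, seq_len(p$n_siblings[f]))
    }))
    fams <- rep(sprintf("F%d", seq_len(p$n_families)), p$n_siblings)
    n <- length(ids)
    s <- stats::rbeta(n, p$severity_beta[1], p$severity_beta[2])
    sex <- sample(c("F", "M"), n, replace = TRUE)
    target <- function(si, min_g, max_g) {
      as.integer(min_g + round_half_up(si * (max_g - min_g)))
    }
    rec <- data.frame(patient_id = ids, family_id = fams, sex = sex,
                      stringsAsFactors = FALSE)
    for (f in c("aao", "age_dx", "mmt_mrc", "six_mwt", "gscg",
                "fvc_upright", "delta_fvc", "bmi", "vdd", "bmd_tb",
                "bmd_fn", "bmd_ls", "igg_rhgaa", "dbs_gaa", "ppl", "vmf")) {
      rec[[f]] <- NA_real_
    }
    for (f in c("bf", "bad", "mvp", "ert_ae")) rec[[f]] <- NA
    tg <- matrix(NA_integer_, nrow = length(SI_ITEMS), ncol = n,
                 dimnames = list(SI_ITEMS, ids))
    for (i in seq_len(n)) {
      si <- s[i]; nf <- p$noise_frac
      tg["AAO", i] <- target(si, 1, 6)
      rec$aao[i] <- sample_in_bin(SIM_BINS$AAO, tg["AAO", i], nf, si,
                                  dom_lo = 1)
      rec$age_dx[i] <- rec$aao[i] + sample(8:18, 1)
      tg["MMT", i] <- target(si, 0, 4)
      rec$mmt_mrc[i] <- sample_in_bin(SIM_BINS$MMT, tg["MMT", i], nf, si,
                                      dom_lo = 0, dom_hi = 100)
      tg["SIXMWT", i] <- target(si, 0, 6)
      wb <- if (sex[i] == "F") SIM_BINS$SIXMWT_F else SIM_BINS$SIXMWT_M
      rec$six_mwt[i] <- sample_in_bin(wb, tg["SIXMWT", i], nf, si,
                                      dom_lo = 0)
      tg["GSCG", i] <- target(si, 0, 4)
      rec$gscg[i] <- sample_in_bin(SIM_BINS$GSCG, tg["GSCG", i], nf, si,
                                   dom_lo = 4, dom_hi = 27)
      tg["FVC", i] <- target(si, 0, 4)
      rec$fvc_upright[i] <- sample_in_bin(SIM_BINS$FVC, tg["FVC", i], nf, si,
                                          dom_lo = 0)
      tg["DFVC", i] <- target(si, 0, 4)
      rec$delta_fvc[i] <- sample_in_bin(SIM_BINS$DFVC, tg["DFVC", i], nf, si,
                                        dom_lo = 0, dom_hi = 100)
      tg["BMI", i] <- target(si, 0, 4)
      rec$bmi[i] <- sample_in_bin(SIM_BINS$BMI, tg["BMI", i], nf, si,
                                  digits = 1, dom_lo = 15)
      tg["VDD", i] <- target(si, 0, 2)
      rec$vdd[i] <- sample_in_bin(SIM_BINS$VDD, tg["VDD", i], nf, si,
                                  digits = 1, dom_lo = 1)
      tg["BMD", i] <- target(si, 0, 2)
      ts <- switch(tg["BMD", i] + 1L,
        stats::runif(3, -0.9, 1.5),
        c(stats::runif(1, -2.4, -1.0), stats::runif(2, -0.9, 1.5)),
        c(stats::runif(2, -4.0, -2.5), stats::runif(1, -4.0, 1.5)))
      ts <- round_half_up(ts, 1)
      rec$bmd_tb[i] <- ts[1]; rec$bmd_fn[i] <- ts[2]; rec$bmd_ls[i] <- ts[3]
      for (it in c("BF", "BAD", "MVP", "ERTAE")) {
        val <- stats::runif(1) < si
        tg[it, i] <- as.integer(val)
        rec[[ITEM_FIELDS[[it]]]][i] <- val
      }
      pres <- stats::runif(1) < si
      tg["IGG", i] <- as.integer(pres)
      rec$igg_rhgaa[i] <- if (pres) round(stats::runif(1, 500, 7000)) else 0
      rec$dbs_gaa[i] <- round_half_up(0.02 + stats::runif(1) * 1.8 * (1 - 0.7 * si), 2)
      rec$ppl[i] <- round(stats::runif(1, 40 * si, 40 * si + 40))
      rec$vmf[i] <- round_half_up(stats::runif(1, 0, 5 + 10 * si), 2)
    }
    rec$gaa_genotype <- paste0("mutA/mutB-", rec$family_id)
    ds <- new_clinical(rec,
                       missing = data.frame(patient_id = character(),
                                            field = character(),
                                            reason = character(),
                                            stringsAsFactors = FALSE),
                       provenance = sprintf("simulated(seed=%d)", p$seed))
    list(dataset = ds,
         truth = list(severity = stats::setNames(s, ids),
                      target_grades = tg))
  })
}

# Inverse-CDF draw from Beta truncated to [0, trunc].
rbeta_trunc <- function(n, shape1, shape2, trunc) {
  u <- stats::runif(n) * stats::pbeta(trunc, shape1, shape2)
  stats::qbeta(u, shape1, shape2)
}

plant_carriers <- function(rule, family, groups, pedigree) {
  switch(rule,
    both_families_high_severity = {
      carr <- names(groups)[groups == "M_S"]
      ok <- all(vapply(split(pedigree$sample, pedigree$family),
                       function(f) any(f %in% carr), logical(1)))
      list(carriers = carr, satisfiable = ok && length(carr) > 0)
    },
    family_specific = {
      carr <- pedigree$sample[pedigree$family == family]
      list(carriers = carr, satisfiable = length(carr) > 0)
    },
    all_affected = {
      carr <- pedigree$sample[pedigree$affected == 1]
      list(carriers = carr, satisfiable = length(carr) > 0)
    },
    stop("unknown plant rule: ", rule, call. = FALSE))
}

#' Simulate an annotated variant table with planted modifiers
#'
#' Background variants draw a population frequency from the stated
#' truncated Beta (the annotated `af_pop1` equals the generating
#' frequency), a CADD phred from the stated Gamma, and a functional class
#' from the stated mixture; genotypes are Binomial(2, frequency),
#' independently per sibling. Planted variants receive genotypes matching
#' their carrier rule exactly (dosage 1 for every target carrier, 0
#' elsewhere). The returned truth records, for every variant, which
#' cascade stages it should survive under the default thresholds, and for
#' every plant its intended carrier set, target dichotomized trait and
#' whether the rule was satisfiable in this cohort (a rule left without
#' eligible carriers by the cohort draw - e.g. a family with no
#' moderate-or-worse member - is recorded unsatisfiable and not emitted;
#' a structurally impossible rule errors at parameter construction).
#'
#' @param p an `lopd_sim_params` object.
#' @param cohort result of [simulate_cohort()].
#' @return list with `variants`, `genotypes`, `pedigree`, `truth`.
#' @export
simulate_variants <- function(p, cohort) {
  stopifnot(inherits(p, "lopd_sim_params"))
  ds <- cohort$dataset
  pedigree <- data.frame(sample = ds$records$patient_id,
                         family = ds$records$family_id,
                         affected = 1L, stringsAsFactors = FALSE)
  grades <- score_cohort(default_scheme(), ds)
  si <- colSums(grades)
  groups <- dichotomize(si)

  with_substream(p$seed, "variants", {
    nb <- p$n_background
    ns <- nrow(ds$records)
    samples <- ds$records$patient_id
    genes <- sprintf("BG%04d", seq_len(max(1, ceiling(nb / 5))))
    n_nonsyn_classes <- c("nonsynonymous_SNV", "splicing", "stopgain",
                          "nonframeshift_indel", "frameshift_indel")
    cls <- ifelse(stats::runif(nb) < p$frac_synonymous, "synonymous_SNV",
                  sample(n_nonsyn_classes, nb, replace = TRUE,
                         prob = c(0.88, 0.04, 0.02, 0.03, 0.03)))
    maf <- rbeta_trunc(nb, p$maf_beta[1], p$maf_beta[2], p$maf_trunc)
    cadd <- round_half_up(stats::rgamma(nb, shape = p$cadd_gamma[["shape"]],
                                        scale = p$cadd_gamma[["scale"]]), 2)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nb, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    bg <- data.frame(
      variant_id = sprintf("bg%05d", seq_len(nb)),
      chrom = as.character(sample(1:22, nb, replace = TRUE)),
      pos = cumsum(sample(1000:5000, nb, replace = TRUE)),
      ref = ref, alt = unname(alt),
      gene = sample(genes, nb, replace = TRUE),
      func_class = cls,
      cadd_phred = cadd,
      af_pop1 = round_half_up(maf, 6),
      planted = FALSE,
      stringsAsFactors = FALSE)
    gm <- matrix(stats::rbinom(nb * ns, 2, rep(maf, ns)), nrow = nb,
                 dimnames = list(bg$variant_id, samples))

    plants <- list()
    plant_rows <- list()
    plant_gm <- list()
    for (k in seq_along(p$plants)) {
      pl <- p$plants[[k]]
      pc <- plant_carriers(pl$rule, pl$family %||% NA_character_,
                           groups, pedigree)
      vid <- sprintf("plant%02d_%s", k, pl$gene)
      fams_hit <- unique(pedigree$family[pedigree$sample %in% pc$carriers])
      expected_sharing <- if (!pc$satisfiable) NA_character_
        else if (length(fams_hit) == p$n_families) "both_families"
        else "family_specific"
      trait <- switch(pl$rule,
        both_families_high_severity =
          stats::setNames(as.integer(groups == "M_S"), names(groups)),
        family_specific =
          stats::setNames(as.integer(pedigree$family == pl$family),
                          pedigree$sample),
        all_affected =
          stats::setNames(pedigree$affected, pedigree$sample))
      plants[[k]] <- list(variant_id = vid, gene = pl$gene, rule = pl$rule,
                          carriers = pc$carriers,
                          satisfiable = pc$satisfiable,
                          expected_sharing = expected_sharing,
                          trait = as.list(trait))
      if (!pc$satisfiable) next
      plant_rows[[length(plant_rows) + 1L]] <- data.frame(
        variant_id = vid, chrom = "23",
        pos = 1e6 + k, ref = "A",
        alt = if (pl$func_class %in% INDEL_CLASSES) "ACTG" else "G",
        gene = pl$gene, func_class = pl$func_class,
        cadd_phred = pl$cadd, af_pop1 = pl$maf, planted = TRUE,
        stringsAsFactors = FALSE)
      plant_gm[[length(plant_gm) + 1L]] <-
        as.integer(samples %in% pc$carriers)
    }
    variants <- rbind(bg, do.call(rbind, plant_rows))
    if (length(plant_gm)) {
      pgm <- do.call(rbind, plant_gm)
      rownames(pgm) <- vapply(plant_rows, function(r) r$variant_id, "")
      colnames(pgm) <- samples
      gm <- rbind(gm, pgm)
    }
    storage.mode(gm) <- "integer"

    called <- rowSums(!is.na(gm))
    ac <- rowSums(gm, na.rm = TRUE)
    mac <- pmin(ac, 2 * called - ac)
    truth <- list(
      seed = p$seed,
      severity = as.list(cohort$truth$severity),
      si = as.list(si),
      groups = as.list(groups),
      survives = list(
        qc = as.list(stats::setNames(mac > 0, variants$variant_id)),
        functional = as.list(stats::setNames(
          variants$func_class %in% FUNC_CLASSES_KEEP, variants$variant_id)),
        rarity = as.list(stats::setNames(
          is.na(variants$af_pop1) | variants$af_pop1 < 0.2,
          variants$variant_id)),
        deleteriousness = as.list(stats::setNames(
          (!is.na(variants$cadd_phred) & variants$cadd_phred >= 20) |
            (is.na(variants$cadd_phred) &
               variants$func_class %in% INDEL_CLASSES),
          variants$variant_id))),
      plants = plants)
    list(variants = variants, genotypes = gm, pedigree = pedigree,
         truth = truth)
  })
}

#' Simulate a complete bundle
#'
#' Convenience wrapper running [simulate_cohort()] then
#' [simulate_variants()].
#'
#' @param p an `lopd_sim_params` object.
#' @return list with `params`, `cohort`, `variants`, `genotypes`,
#'   `pedigree`, `truth`.
#' @export
simulate_bundle <- function(p) {
  cohort <- simulate_cohort(p)
  vs <- simulate_variants(p, cohort)
  list(params = p, cohort = cohort, variants = vs$variants,
       genotypes = vs$genotypes, pedigree = vs$pedigree, truth = vs$truth)
}

write_annotation_tsv <- function(variants, path) {
  out <- variants
  for (col in c("pos", "cadd_phred", "af_pop1")) {
    if (col %in% names(out)) {
      v <- fmt_num(out[[col]])
      v[is.na(v)] <- "na"
      out[[col]] <- v
    }
  }
  out$planted <- NULL
  write_tsv_plain(out, path)
}

write_genotype_vcf <- function(gm, variants, path) {
  idx <- match(rownames(gm), variants$variant_id)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lopdkit-simulator",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gm)), collapse = "\t"))
  gt <- matrix(c("0/0", "0/1", "1/1")[gm + 1L], nrow = nrow(gm))
  gt[is.na(gm)] <- "./."
  body <- vapply(seq_len(nrow(gm)), function(i) {
    paste(c(variants$chrom[idx[i]], variants$pos[idx[i]], rownames(gm)[i],
            variants$ref[idx[i]], variants$alt[idx[i]], ".", "PASS", ".",
            "GT", gt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated bundle to disk
#'
#' Emits `clinical.tsv`, `variants.tsv`, `genotypes.vcf`, `pedigree.tsv`
#' and `truth.json` into `dir`. The files are byte-deterministic for a
#' given parameter set (same seed, same bytes) and re-loadable by
#' [load_clinical_table()] / [load_variant_table()] / [read_pedigree()].
#'
#' @param bundle result of [simulate_bundle()].
#' @param dir output directory (created if absent).
#' @return named character vector of the five file paths.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(clinical = file.path(dir, "clinical.tsv"),
             variants = file.path(dir, "variants.tsv"),
             genotypes = file.path(dir, "genotypes.vcf"),
             pedigree = file.path(dir, "pedigree.tsv"),
             truth = file.path(dir, "truth.json"))
  write_clinical_table(bundle$cohort$dataset, paths["clinical"])
  write_annotation_tsv(bundle$variants, paths["variants"])
  write_genotype_vcf(bundle$genotypes, bundle$variants, paths["genotypes"])
  write_tsv_plain(bundle$pedigree, paths["pedigree"])
  writeLines(jsonlite::toJSON(bundle$truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"),
             paths["truth"])
  paths
}

#' Reload a simulated bundle
#'
#' @param dir directory written by [write_bundle()].
#' @return list with `clinical`, `variants`, `genotypes`, `pedigree`,
#'   `truth`.
#' @export
read_bundle <- function(dir) {
  lv <- load_variant_table(file.path(dir, "variants.tsv"),
                           file.path(dir, "genotypes.vcf"))
  list(clinical = load_clinical_table(file.path(dir, "clinical.tsv")),
       variants = lv$variants, genotypes = lv$genotypes,
       pedigree = read_pedigree(file.path(dir, "pedigree.tsv")),
       truth = jsonlite::fromJSON(file.path(dir, "truth.json"),
                                  simplifyVector = TRUE))
}
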