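# The modifier-gene prioritization cascade: variant QC, functional-class
# selection, rarity (max population MAF) and deleteriousness (CADD phred)
# filters, between-family / within-family carrier sharing, cosegregation
# with dichotomized clinical traits, and hypergeometric gene-set enrichment.

FUNC_CLASSES_KEEP <- c("nonsynonymous_SNV", "stopgain", "stoploss",
                       "frameshift_indel", "nonframeshift_indel", "splicing")
FUNC_CLASSES_ALL <- c(FUNC_CLASSES_KEEP, "synonymous_SNV", "other")
INDEL_CLASSES <- c("frameshift_indel", "nonframeshift_indel")

#' Normalize annotation dialect functional classes
#'
#' Maps ANNOVAR-style exonic-function labels (and the abbreviations used in
#' published candidate tables, e.g. `NSV`, `NFins`) onto the canonical class
#' vocabulary.
#'
#' @param x character vector of raw class labels.
#' @return character vector over the canonical classes; unrecognized labels
#'   become `"other"`.
#' @export
normalize_func_class <- function(x) {
  key <- tolower(gsub("[ _-]", "", x))
  map <- c(
    "nsv" = "nonsynonymous_SNV", "nonsynonymoussnv" = "nonsynonymous_SNV",
    "missense" = "nonsynonymous_SNV",
    "stopgain" = "stopgain", "stopgainsnv" = "stopgain",
    "stoploss" = "stoploss", "stoplosssnv" = "stoploss",
    "frameshiftinsertion" = "frameshift_indel",
    "frameshiftdeletion" = "frameshift_indel",
    "frameshiftindel" = "frameshift_indel", "fs" = "frameshift_indel",
    "nonframeshiftinsertion" = "nonframeshift_indel",
    "nonframeshiftdeletion" = "nonframeshift_indel",
    "nonframeshiftindel" = "nonframeshift_indel",
    "nfins" = "nonframeshift_indel", "nfdel" = "nonframeshift_indel",
    "splicing" = "splicing", "splicesite" = "splicing",
    "synonymoussnv" = "synonymous_SNV", "synonymous" = "synonymous_SNV",
    "ssv" = "synonymous_SNV")
  out <- unname(map[key])
  out[is.na(out) & key %in% tolower(FUNC_CLASSES_ALL)] <-
    FUNC_CLASSES_ALL[match(key[is.na(out) & key %in% tolower(FUNC_CLASSES_ALL)],
                           tolower(FUNC_CLASSES_ALL))]
  out[is.na(out)] <- "other"
  out
}

VARIANT_MISSING <- c("na", "nr", ".", "", "NA", "NR")

#' Read an annotated variant table
#'
#' Reads a TSV in an ANNOVAR-like dialect. Recognized columns:
#' `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, `transcript`,
#' `func_class`, `nt_change`, `aa_change`, `dbsnp`, `cadd_phred`, `sift`,
#' `polyphen`, and any number of population frequency columns prefixed
#' `af_` (e.g. `af_nfe`, `af_max`). Cells `na`/`nr`/`.` are treated as
#' absent annotations (an absent frequency means the variant is unreported
#' in that population, not frequency zero). Multi-allelic records (commas
#' in `alt`) are refused: records must be pre-split upstream.
#'
#' @param path TSV path.
#' @param dialect optional named vector mapping file headers to recognized
#'   column names.
#' @return data frame of annotated variants with normalized `func_class`.
#' @export
read_variant_annotations <- function(path, dialect = NULL) {
  raw <- read_tsv_plain(path)
  if (!is.null(dialect)) {
    hit <- names(raw) %in% names(dialect)
    names(raw)[hit] <- unname(dialect[names(raw)[hit]])
  }
  if (!"variant_id" %in% names(raw)) {
    if (all(c("chrom", "pos", "ref", "alt") %in% names(raw))) {
      raw$variant_id <- paste(raw$chrom, raw$pos, raw$ref, raw$alt, sep = ":")
    } else {
      stop("annotation table needs variant_id or chrom/pos/ref/alt columns",
           call. = FALSE)
    }
  }
  if ("alt" %in% names(raw) && any(grepl(",", raw$alt))) {
    stop("multi-allelic records must be pre-split (comma in alt): ",
         paste(raw$variant_id[grepl(",", raw$alt)], collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("pos", "cadd_phred", grep("^af_", names(raw), value = TRUE))
  for (col in intersect(num_cols, names(raw))) {
    cells <- raw[[col]]
    cells[cells %in% VARIANT_MISSING] <- NA
    v <- suppressWarnings(as.numeric(cells))
    bad <- which(!is.na(cells) & is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column %s row %d",
                   cells[bad[1]], col, bad[1]), call. = FALSE)
    }
    raw[[col]] <- v
  }
  for (col in setdiff(names(raw), num_cols)) {
    raw[[col]][raw[[col]] %in% VARIANT_MISSING] <- NA
  }
  if ("func_class" %in% names(raw)) {
    raw$func_class <- normalize_func_class(raw$func_class)
  }
  af <- grep("^af_", names(raw), value = TRUE)
  if (length(af)) {
    bad <- unlist(raw[af])
    bad <- bad[!is.na(bad)]
    if (any(bad < 0 | bad > 1)) {
      stop("population frequencies must lie in [0, 1]", call. = FALSE)
    }
  }
  raw
}

#' Maximum annotated population frequency per variant
#'
#' @param variants annotated variant data frame.
#' @return numeric vector; `NA` when no population reports the variant
#'   (a "novel" variant).
#' @export
maf_max <- function(variants) {
  af <- grep("^af_", names(variants), value = TRUE)
  if (!length(af)) return(rep(NA_real_, nrow(variants)))
  apply(as.matrix(variants[af]), 1, function(r) {
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  })
}

#' Read a genotype dosage matrix from TSV
#'
#' First column `variant_id`, remaining columns one per sample holding
#' alt-allele dosages 0/1/2 (missing as `NA`, `.` or `./.`).
#'
#' @param path TSV path.
#' @return integer matrix, variants x samples.
#' @export
read_genotype_matrix <- function(path) {
  raw <- read_tsv_plain(path)
  if (names(raw)[1] != "variant_id") {
    stop("genotype matrix must start with a variant_id column", call. = FALSE)
  }
  samples <- names(raw)[-1]
  m <- matrix(NA_integer_, nrow = nrow(raw), ncol = length(samples),
              dimnames = list(raw$variant_id, samples))
  for (j in seq_along(samples)) {
    cells <- raw[[j + 1]]
    cells[cells %in% c(".", "./.", "", "NA")] <- NA
    v <- suppressWarnings(as.integer(cells))
    bad <- which(!is.na(cells) & (is.na(v) | !v %in% 0:2))
    if (length(bad)) {
      stop(sprintf("malformed genotype '%s' for sample %s, variant %s",
                   cells[bad[1]], samples[j], raw$variant_id[bad[1]]),
           call. = FALSE)
    }
    m[, j] <- v
  }
  m
}

#' Read genotypes from a VCF
#'
#' Parses the GT field of a (single-block, pre-split) VCF into an
#' alt-allele dosage matrix; all other FORMAT fields are ignored. Requires
#' the Bioconductor package VariantAnnotation.
#'
#' @param path VCF path.
#' @return integer matrix, variants x samples; rownames are the VCF ID
#'   column where present.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dosage <- function(g) {
    if (g %in% c("./.", ".", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (!all(alleles %in% c("0", "1"))) {
      stop("malformed or multi-allelic GT: ", g, call. = FALSE)
    }
    sum(alleles == "1")
  }
  m <- apply(gt, c(1, 2), dosage)
  storage.mode(m) <- "integer"
  m
}

#' Load and join an annotation table with genotypes
#'
#' @param annot_path annotation TSV (see [read_variant_annotations()]).
#' @param geno_path genotype TSV matrix or VCF (by extension).
#' @param dialect passed to [read_variant_annotations()].
#' @return list with `variants` (data frame) and `genotypes` (integer
#'   matrix) aligned on `variant_id`.
#' @export
load_variant_table <- function(annot_path, geno_path, dialect = NULL) {
  variants <- read_variant_annotations(annot_path, dialect = dialect)
  gm <- if (grepl("\\.vcf$", geno_path, ignore.case = TRUE)) {
    read_genotype_vcf(geno_path)
  } else {
    read_genotype_matrix(geno_path)
  }
  only_a <- setdiff(variants$variant_id, rownames(gm))
  only_g <- setdiff(rownames(gm), variants$variant_id)
  if (length(only_a) || length(only_g)) {
    stop("variant id mismatch between annotation and genotypes;",
         if (length(only_a)) paste0(" annotation-only: ",
                                    paste(only_a, collapse = ", ")),
         if (length(only_g)) paste0(" genotype-only: ",
                                    paste(only_g, collapse = ", ")),
         call. = FALSE)
  }
  gm <- gm[variants$variant_id, , drop = FALSE]
  list(variants = variants, genotypes = gm)
}

#' Read a pedigree/sample table
#'
#' Three-column TSV: `sample`, `family`, `affected` (0/1).
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_pedigree <- function(path) {
  ped <- read_tsv_plain(path)
  need <- c("sample", "family", "affected")
  if (!all(need %in% names(ped))) {
    stop("pedigree must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ped$affected <- as.integer(ped$affected)
  ped
}

stage_entry <- function(name, n_in, n_out, removed) {
  list(stage = name, n_in = n_in, n_out = n_out, removed = removed)
}

with_stage <- function(variants, keep, name) {
  out <- variants[keep, , drop = FALSE]
  attr(out, "stage") <- stage_entry(name, length(keep), sum(keep),
                                    variants$variant_id[!keep])
  out
}

#' Variant-level quality control
#'
#' Drops monomorphic variants (minor allele count 0 in the cohort, counting
#' the rarer of the alt and ref alleles among called genotypes) and variants
#' with a call rate below `min_call_rate`. Multi-allelic records never reach
#' this stage: the loader refuses them.
#'
#' @param variants annotated variant data frame.
#' @param gm dosage matrix aligned with `variants`.
#' @param min_call_rate minimum fraction of called samples (default 0.95).
#' @return filtered variant data frame with a `"stage"` attribute recording
#'   counts and removed ids.
#' @export
qc_filter <- function(variants, gm, min_call_rate = 0.95) {
  gm <- gm[variants$variant_id, , drop = FALSE]
  called <- rowSums(!is.na(gm))
  ac <- rowSums(gm, na.rm = TRUE)
  mac <- pmin(ac, 2 * called - ac)
  call_rate <- called / ncol(gm)
  keep <- mac > 0 & call_rate >= min_call_rate
  with_stage(variants, keep, "qc")
}

#' Functional-class selection
#'
#' Keeps splicing and protein-altering exonic classes (non-synonymous SNVs,
#' stop gain/loss, coding indels); drops synonymous and everything else.
#'
#' @param variants annotated variant data frame.
#' @return filtered data frame with a `"stage"` attribute.
#' @export
functional_class_filter <- function(variants) {
  keep <- variants$func_class %in% FUNC_CLASSES_KEEP
  with_stage(variants, keep, "functional_class")
}

#' Rarity filter on maximum population frequency
#'
#' Excludes common variants: a variant is kept iff its maximum frequency
#' over all annotated populations is strictly below the cutoff. Variants
#' reported in no population are treated as novel and kept.
#'
#' @param variants annotated variant data frame.
#' @param maf_cutoff exclusion threshold; the cascade default excludes
#'   MAF >= 0.2.
#' @return filtered data frame with a `"stage"` attribute.
#' @export
rarity_filter <- function(variants, maf_cutoff = 0.2) {
  mm <- maf_max(variants)
  keep <- is.na(mm) | mm < maf_cutoff
  with_stage(variants, keep, "rarity")
}

#' Deleteriousness filter on CADD phred
#'
#' Keeps variants with CADD phred at or above the cutoff (>= 20 marks the
#' 1% most deleterious substitutions genome-wide). CADD is undefined for
#' many indels, so an absent score passes only for indel classes; an absent
#' score on an SNV class fails.
#'
#' @param variants annotated variant data frame.
#' @param cadd_cutoff phred-scaled threshold, default 20.
#' @return filtered data frame with a `"stage"` attribute.
#' @export
deleteriousness_filter <- function(variants, cadd_cutoff = 20) {
  cadd <- if ("cadd_phred" %in% names(variants)) variants$cadd_phred
          else rep(NA_real_, nrow(variants))
  keep <- (!is.na(cadd) & cadd >= cadd_cutoff) |
    (is.na(cadd) & variants$func_class %in% INDEL_CLASSES)
  with_stage(variants, keep, "deleteriousness")
}

carrier_sets <- function(gm) {
  samples <- colnames(gm)
  lapply(seq_len(nrow(gm)), function(i) {
    samples[!is.na(gm[i, ]) & gm[i, ] >= 1]
  })
}

#' Carrier sharing between or within families
#'
#' Analysis I (`between_families`) keeps variants with at least one carrier
#' (alt dosage >= 1, a dominant modifier model) in every family. Analysis II
#' (`within_family`) keeps variants carried by every member of a specified
#' subset of one family's affected siblings (default: all of them); which
#' subset is biologically right depends on the dichotomized sign under
#' study, so the subset is always explicit.
#'
#' @param variants annotated variant data frame.
#' @param gm dosage matrix.
#' @param pedigree data frame from [read_pedigree()].
#' @param mode `"between_families"` or `"within_family"`.
#' @param family required in within-family mode.
#' @param members optional character vector restricting the within-family
#'   carrier requirement to a subset of the family's samples.
#' @return data frame `variant_id`, `n_carriers`, `carriers`
#'   (comma-separated), `keep`, `label` (`"both_families"`,
#'   `"family_specific"` or `NA`).
#' @export
shared_carrier_analysis <- function(variants, gm, pedigree,
                                    mode = c("between_families",
                                             "within_family"),
                                    family = NULL, members = NULL) {
  mode <- match.arg(mode)
  gm <- gm[variants$variant_id, , drop = FALSE]
  fams <- split(pedigree$sample, pedigree$family)
  cs <- carrier_sets(gm)
  if (mode == "between_families") {
    keep <- vapply(cs, function(carr) {
      all(vapply(fams, function(f) any(f %in% carr), logical(1)))
    }, logical(1))
    label <- ifelse(keep, "both_families", NA_character_)
  } else {
    if (is.null(family)) {
      stop("family is required in within_family mode", call. = FALSE)
    }
    if (!family %in% names(fams)) {
      stop("unknown family: ", family, call. = FALSE)
    }
    members <- members %||% fams[[family]]
    keep <- vapply(cs, function(carr) {
      length(carr) > 0 && all(members %in% carr)
    }, logical(1))
    label <- ifelse(keep, "family_specific", NA_character_)
  }
  data.frame(variant_id = variants$variant_id,
             n_carriers = lengths(cs),
             carriers = vapply(cs, paste, "", collapse = ","),
             keep = keep, label = label, stringsAsFactors = FALSE)
}

#' Cosegregation of carrier status with a dichotomized trait
#'
#' Concordance is the fraction of genotyped samples whose carrier status
#' (dosage >= 1) equals the binary trait. A concordance of 1 flags perfect
#' cosegregation; 0 flags a perfect inverse association (the variant tracks
#' the unaffected group).
#'
#' @param variants annotated variant data frame.
#' @param gm dosage matrix.
#' @param trait named 0/1 vector, one entry per genotyped sample.
#' @return data frame `variant_id`, `concordance`, `perfect`, `inverse`,
#'   sorted by decreasing concordance.
#' @export
phenotype_segregation <- function(variants, gm, trait) {
  gm <- gm[variants$variant_id, , drop = FALSE]
  samples <- colnames(gm)
  missing <- setdiff(samples, names(trait))
  if (length(missing)) {
    stop("trait missing for genotyped sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tr <- as.integer(trait[samples])
  conc <- vapply(seq_len(nrow(gm)), function(i) {
    carr <- as.integer(!is.na(gm[i, ]) & gm[i, ] >= 1)
    mean(carr == tr)
  }, numeric(1))
  out <- data.frame(variant_id = variants$variant_id, concordance = conc,
                    perfect = conc == 1, inverse = conc == 0,
                    stringsAsFactors = FALSE)
  out[order(-out$concordance), ]
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "")
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per set: with `N` genes in the universe,
#' `K` of them in the set and `n` candidate genes, the p-value is
#' `P(X >= k)` for the observed overlap `k`, `X ~ Hypergeom(N, K, n)`.
#' This is the generic stand-in for database-backed enrichment services:
#' it tests the same null (random draw of `n` genes from the universe)
#' against user-supplied gene sets.
#'
#' @param candidate_genes character vector (deduplicated internally).
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param universe either an integer universe size or a character vector of
#'   universe genes. When a gene list is given, set and candidate genes
#'   outside it are dropped with a warning.
#' @return data frame `set`, `k`, `K`, `n`, `N`, `p`, sorted by `p`.
#' @export
pathway_enrichment <- function(candidate_genes, gene_sets, universe) {
  genes <- unique(candidate_genes)
  if (is.character(universe)) {
    uni <- unique(universe)
    n_total <- length(uni)
    out_of <- unique(unlist(gene_sets))
    out_of <- out_of[!out_of %in% uni]
    if (length(out_of)) {
      warning("gene(s) in sets absent from universe: ",
              paste(utils::head(out_of, 5), collapse = ", "),
              if (length(out_of) > 5) ", ...", call. = FALSE)
    }
    gene_sets <- lapply(gene_sets, intersect, uni)
    genes <- intersect(genes, uni)
  } else {
    n_total <- as.integer(universe)
  }
  n <- length(genes)
  if (n_total < n || any(lengths(gene_sets) > n_total)) {
    stop("universe smaller than a gene set or the candidate list",
         call. = FALSE)
  }
  rows <- lapply(names(gene_sets), function(s) {
    K <- length(gene_sets[[s]])
    k <- length(intersect(genes, gene_sets[[s]]))
    p <- stats::phyper(k - 1, K, n_total - K, n, lower.tail = FALSE)
    data.frame(set = s, k = k, K = K, n = n, N = n_total, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), ]
}

#' Count genotypes at a polymorphism
#'
#' @param rows genotype-row data frame (one row per patient, one column per
#'   rsID holding two-letter genotype strings), e.g.
#'   `bundled_fixture("table6")`.
#' @param rsid column name to count.
#' @return list with `genotypes` (table of genotype strings) and `alleles`
#'   (table of single alleles).
#' @export
count_genotypes <- function(rows, rsid) {
  if (!nrow(rows)) stop("empty genotype row list", call. = FALSE)
  if (!rsid %in% names(rows)) stop("unknown rsid: ", rsid, call. = FALSE)
  g <- rows[[rsid]]
  bad <- g[!grepl("^[ACGT]{2}$", g)]
  if (length(bad)) {
    stop("malformed genotype string(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  list(genotypes = table(g),
       alleles = table(unlist(strsplit(g, ""))))
}

#' Flag genes with compound-heterozygous candidate carriage
#'
#' A gene is flagged for a sample that carries two or more distinct
#' candidate variants of that gene (dominant-model carrier calls; phasing
#' is not attempted).
#'
#' @param candidates candidate data frame (must have `variant_id`, `gene`).
#' @param gm dosage matrix covering the candidate variants.
#' @return data frame `gene`, `sample`, `n_variants`.
#' @export
compound_het_genes <- function(candidates, gm) {
  rows <- list()
  for (g in unique(candidates$gene)) {
    vids <- candidates$variant_id[candidates$gene == g]
    if (length(vids) < 2) next
    sub <- gm[vids, , drop = FALSE]
    cnt <- colSums(!is.na(sub) & sub >= 1)
    for (s in names(cnt)[cnt >= 2]) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample = s, n_variants = unname(cnt[s]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), sample = character(),
                      n_variants = integer()))
  }
  do.call(rbind, rows)
}

#' Run the full prioritization cascade
#'
#' Executes QC, functional-class, rarity and deleteriousness filters, then
#' carrier sharing (Analysis I between families and Analysis II within each
#' family), cosegregation against every supplied dichotomized trait, and
#' optional gene-set enrichment of the candidate genes. Variants surviving
#' the filters but shared in neither sense are dropped at the sharing
#' stage.
#'
#' @param variants annotated variant data frame.
#' @param gm dosage matrix aligned with `variants`.
#' @param pedigree data frame from [read_pedigree()].
#' @param traits named list of dichotomized traits (each a named 0/1 vector
#'   over the genotyped samples).
#' @param gene_sets optional named list (see [read_gmt()]).
#' @param universe universe for enrichment (size or gene list); required
#'   when `gene_sets` is given.
#' @param maf_cutoff,cadd_cutoff,min_call_rate filter thresholds.
#' @param within_members optional named list, family -> member subset for
#'   Analysis II.
#' @return list with `candidates` (data frame: annotation columns plus
#'   `maf_max`, `carriers`, `sharing`, one `conc_<trait>` column per trait),
#'   `report` (data frame `stage`, `n_variants`) and `enrichment` (data
#'   frame or `NULL`).
#' @export
prioritize <- function(variants, gm, pedigree, traits = list(),
                       gene_sets = NULL, universe = NULL,
                       maf_cutoff = 0.2, cadd_cutoff = 20,
                       min_call_rate = 0.95, within_members = NULL) {
  stages <- list(stage_entry("loaded", nrow(variants), nrow(variants),
                             character()))
  v <- qc_filter(variants, gm, min_call_rate = min_call_rate)
  stages <- c(stages, list(attr(v, "stage")))
  v <- functional_class_filter(v)
  stages <- c(stages, list(attr(v, "stage")))
  v <- rarity_filter(v, maf_cutoff = maf_cutoff)
  stages <- c(stages, list(attr(v, "stage")))
  v <- deleteriousness_filter(v, cadd_cutoff = cadd_cutoff)
  stages <- c(stages, list(attr(v, "stage")))

  if (nrow(v)) {
    between <- shared_carrier_analysis(v, gm, pedigree,
                                       mode = "between_families")
    label <- between$label
    carriers <- between$carriers
    for (fam in unique(pedigree$family)) {
      within <- shared_carrier_analysis(
        v, gm, pedigree, mode = "within_family", family = fam,
        members = within_members[[fam]])
      # family-specific means shared by the family's members and absent
      # from every other family
      other <- pedigree$sample[pedigree$family != fam]
      cs <- strsplit(within$carriers, ",", fixed = TRUE)
      fam_only <- vapply(cs, function(x) !any(x %in% other), logical(1))
      upgrade <- is.na(label) & within$keep & fam_only
      label[upgrade] <- "family_specific"
    }
    keep <- !is.na(label)
    sharing <- data.frame(variant_id = v$variant_id, carriers = carriers,
                          sharing = label, stringsAsFactors = FALSE)
    v2 <- v[keep, , drop = FALSE]
    stages <- c(stages, list(stage_entry("sharing", nrow(v), nrow(v2),
                                         v$variant_id[!keep])))
    cand <- merge(v2, sharing[keep, , drop = FALSE], by = "variant_id",
                  sort = FALSE)
  } else {
    stages <- c(stages, list(stage_entry("sharing", 0L, 0L, character())))
    cand <- cbind(v, data.frame(carriers = character(),
                                sharing = character()))
  }
  cand$maf_max <- if (nrow(cand)) maf_max(cand) else numeric(0)

  for (tn in names(traits)) {
    col <- paste0("conc_", tn)
    if (nrow(cand)) {
      seg <- phenotype_segregation(cand, gm, traits[[tn]])
      cand[[col]] <- seg$concordance[match(cand$variant_id, seg$variant_id)]
    } else {
      cand[[col]] <- numeric(0)
    }
  }

  enrichment <- NULL
  if (!is.null(gene_sets) && nrow(cand)) {
    if (is.null(universe)) {
      stop("universe required for gene-set enrichment", call. = FALSE)
    }
    enrichment <- pathway_enrichment(unique(cand$gene), gene_sets, universe)
    tags <- vapply(cand$gene, function(g) {
      paste(names(gene_sets)[vapply(gene_sets, function(s) g %in% s,
                                    logical(1))], collapse = ",")
    }, "")
    cand$pathways <- unname(tags)
  }

  report <- data.frame(
    stage = vapply(stages, `[[`, "", "stage"),
    n_variants = vapply(stages, function(s) as.integer(s$n_out), integer(1)),
    stringsAsFactors = FALSE)
  if (any(diff(report$n_variants) > 0)) {
    stop("internal error: cascade counts increased", call. = FALSE)
  }
  list(candidates = cand, report = report, enrichment = enrichment)
}
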