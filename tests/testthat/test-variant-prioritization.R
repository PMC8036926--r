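test_that("table5 fixture parses with normalized classes and missing MAFs", {
  t5 <- bundled_fixture("table5")
  expect_equal(nrow(t5), 16)
  expect_equal(sum(t5$func_class == "nonsynonymous_SNV"), 14)
  expect_equal(sum(t5$func_class == "nonframeshift_indel"), 1)
  expect_equal(sum(t5$func_class == "splicing"), 1)
  expect_equal(length(unique(t5$gene)), 12)
  # "na" frequency cells are absent annotations, not zeros
  expect_true(is.na(t5$af_max[t5$variant_id == "PLIN2_E206K"]))
  expect_equal(t5$af_max[t5$variant_id == "RILP_G284S"], 0.04)
  # CADD "nr" for the insertion
  expect_true(is.na(t5$cadd_phred[t5$variant_id == "DCHS1_G34insLG"]))
})

test_that("maf_max takes the maximum over populated frequency columns", {
  v <- data.frame(variant_id = c("a", "b", "c"),
                  af_p1 = c(0.1, NA, NA), af_p2 = c(0.3, 0.05, NA))
  expect_equal(maf_max(v), c(0.3, 0.05, NA))
  expect_true(all(is.na(maf_max(data.frame(variant_id = "a")))))
})

test_that("annotation loader refuses malformed input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\talt\tfunc_class", "v1\tA,G\tNSV"), tmp)
  expect_error(read_variant_annotations(tmp), "pre-split")
  writeLines(c("variant_id\taf_p1", "v1\toops"), tmp)
  expect_error(read_variant_annotations(tmp), "non-numeric")
  writeLines(c("variant_id\taf_p1", "v1\t1.4"), tmp)
  expect_error(read_variant_annotations(tmp), "\\[0, 1\\]")
})

test_that("genotype loaders: TSV dosages, VCF GT, join checks", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tS1\tS2\tS3", "v1\t0\t1\t2", "v2\t.\t0\t1"), tmp)
  gm <- read_genotype_matrix(tmp)
  expect_equal(gm["v1", ], c(S1 = 0L, S2 = 1L, S3 = 2L))
  expect_true(is.na(gm["v2", "S1"]))
  writeLines(c("variant_id\tS1", "v1\t3"), tmp)
  expect_error(read_genotype_matrix(tmp), "malformed genotype")

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t./."), vcf)
  gv <- read_genotype_vcf(vcf)
  expect_equal(unname(gv["v1", ]), c(1L, 2L, NA))

  ann <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tgene\tfunc_class", "v1\tG1\tNSV",
               "v9\tG2\tNSV"), ann)
  expect_error(load_variant_table(ann, vcf), "v9")
})

test_that("qc_filter drops monomorphic and low-call-rate variants", {
  samples <- paste0("S", 1:11)
  v <- data.frame(variant_id = c("allref", "allalt", "onehet", "onemiss"),
                  func_class = "nonsynonymous_SNV",
                  stringsAsFactors = FALSE)
  gm <- rbind(
    allref = rep(0L, 11),
    allalt = rep(2L, 11),                     # minor (ref) count is 0
    onehet = c(1L, rep(0L, 10)),
    onemiss = c(NA, rep(1L, 10)))             # call rate 10/11 = 0.909
  colnames(gm) <- samples
  out <- qc_filter(v, gm)
  expect_equal(out$variant_id, "onehet")
  st <- attr(out, "stage")
  expect_setequal(st$removed, c("allref", "allalt", "onemiss"))
  # a permissive call-rate threshold readmits the part-missing variant
  expect_setequal(qc_filter(v, gm, min_call_rate = 0.9)$variant_id,
                  c("onehet", "onemiss"))
})

test_that("functional, rarity and deleteriousness filters follow the rules", {
  t5 <- bundled_fixture("table5")
  expect_equal(nrow(functional_class_filter(t5)), 16)

  v <- data.frame(variant_id = c("keep", "syn", "othr"),
                  func_class = c("splicing", "synonymous_SNV", "other"))
  expect_equal(functional_class_filter(v)$variant_id, "keep")

  v <- data.frame(variant_id = c("rare", "edge", "common", "novel"),
                  func_class = "nonsynonymous_SNV",
                  af_max = c(0.04, 0.2, 0.35, NA))
  expect_setequal(rarity_filter(v)$variant_id, c("rare", "novel"))
  v2 <- data.frame(variant_id = "kl", func_class = "nonsynonymous_SNV",
                   af_max = 0.19)
  expect_equal(nrow(rarity_filter(v2)), 1)

  v <- data.frame(
    variant_id = c("hi", "lo", "indelna", "snvna"),
    func_class = c("nonsynonymous_SNV", "nonsynonymous_SNV",
                   "nonframeshift_indel", "nonsynonymous_SNV"),
    cadd_phred = c(23, 19.9, NA, NA))
  expect_setequal(deleteriousness_filter(v)$variant_id, c("hi", "indelna"))
})

test_that("filters are idempotent and rarity/deleteriousness commute", {
  set.seed(42)
  tv <- toy_variant_table(150)
  for (f in list(functional_class_filter, rarity_filter,
                 deleteriousness_filter)) {
    once <- f(tv$variants)
    expect_equal(f(once)$variant_id, once$variant_id)
  }
  rd <- deleteriousness_filter(rarity_filter(tv$variants))
  dr <- rarity_filter(deleteriousness_filter(tv$variants))
  expect_setequal(rd$variant_id, dr$variant_id)
})

test_that("carrier sharing distinguishes the two analyses", {
  samples <- c(paste0("A", 1:7), paste0("B", 1:4))
  ped <- data.frame(sample = samples,
                    family = rep(c("F1", "F2"), c(7, 4)), affected = 1L)
  gm <- carrier_matrix(list(
    shared = c("A1", "B2"),
    f1all = paste0("A", 1:7),
    f1some = c("A1", "A2"),
    mono = character(0)), samples)
  v <- data.frame(variant_id = rownames(gm), func_class = "splicing",
                  stringsAsFactors = FALSE)

  btw <- shared_carrier_analysis(v, gm, ped, mode = "between_families")
  expect_equal(btw$variant_id[btw$keep], "shared")
  expect_equal(btw$label[btw$variant_id == "shared"], "both_families")

  win <- shared_carrier_analysis(v, gm, ped, mode = "within_family",
                                 family = "F1")
  expect_equal(win$variant_id[win$keep], "f1all")
  expect_false(win$keep[win$variant_id == "mono"])

  sub <- shared_carrier_analysis(v, gm, ped, mode = "within_family",
                                 family = "F1", members = c("A1", "A2"))
  expect_setequal(sub$variant_id[sub$keep], c("f1all", "f1some"))

  expect_error(shared_carrier_analysis(v, gm, ped, mode = "within_family"),
               "family is required")
  expect_error(shared_carrier_analysis(v, gm, ped, mode = "within_family",
                                       family = "F9"), "unknown family")
})

test_that("phenotype segregation concordance", {
  samples <- paste0("S", 1:11)
  trait <- stats::setNames(c(rep(1L, 5), rep(0L, 6)), samples)
  gm <- carrier_matrix(list(
    perfect = samples[1:5],
    constant = samples,
    inverse = samples[6:11]), samples)
  v <- data.frame(variant_id = rownames(gm))
  seg <- phenotype_segregation(v, gm, trait)
  expect_equal(seg$concordance[seg$variant_id == "perfect"], 1)
  expect_true(seg$perfect[seg$variant_id == "perfect"])
  expect_equal(seg$concordance[seg$variant_id == "constant"], 5 / 11)
  expect_equal(seg$concordance[seg$variant_id == "inverse"], 0)
  expect_true(seg$inverse[seg$variant_id == "inverse"])
  expect_error(phenotype_segregation(v, gm, trait[-1]), "trait missing")
})

test_that("hypergeometric enrichment: frozen values and oracle", {
  e <- pathway_enrichment("g1", list(s = "g1"), universe = 10)
  expect_equal(e$p, 0.1)  # single draw hits the single set gene

  e0 <- pathway_enrichment("gX", list(s = c("g1", "g2")), universe = 10)
  expect_equal(e0$p, 1)   # k = 0: P(X >= 0) = 1

  genes <- paste0("g", 1:5)
  e5 <- pathway_enrichment(genes, list(s = genes), universe = 20)
  expect_equal(e5$p, 1 / choose(20, 5))

  # exhaustive enumeration oracle across N, K, n, k
  for (N in c(8, 12, 16)) {
    for (K in c(2, 4)) {
      for (n in c(3, 5)) {
        cand <- c(paste0("in", seq_len(min(2, K, n))),
                  paste0("out", seq_len(n - min(2, K, n))))
        sets <- list(s = paste0("in", seq_len(K)))
        k <- sum(cand %in% sets$s)
        got <- pathway_enrichment(cand, sets, universe = N)$p
        expect_equal(got, oracle_hyper_upper(N, K, n, k),
                     label = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }

  expect_warning(
    pathway_enrichment("g1", list(s = c("g1", "zzz")),
                       universe = paste0("g", 1:9)),
    "absent from universe")
  expect_error(pathway_enrichment(paste0("g", 1:9), list(s = "g1"),
                                  universe = 5), "universe smaller")
})

test_that("count_genotypes reproduces the published genotype excess", {
  t6 <- bundled_fixture("table6")
  r <- count_genotypes(t6, "rs2228570")
  expect_equal(as.integer(r$genotypes[c("CC", "TC")]), c(9L, 2L))
  expect_equal(as.integer(r$alleles[c("C", "T")]), c(20L, 2L))
  r <- count_genotypes(t6, "rs4588")
  expect_equal(as.integer(r$genotypes[c("CC", "CA")]), c(10L, 1L))
  expect_error(count_genotypes(t6, "rs999"), "unknown rsid")
  expect_error(count_genotypes(t6[0, ], "rs4588"), "empty")
})

test_that("GMT parsing", {
  sets <- read_gmt(system.file("extdata", "pathways.gmt",
                               package = "lopdkit"))
  expect_equal(length(sets), 4)
  expect_true("RILP" %in% sets$autophagy_lysosomal)
  expect_true("FAM26F" %in% sets$immunity)
})

test_that("prioritize equals a naive per-variant predicate (oracle)", {
  set.seed(77)
  tv <- toy_variant_table(200)
  res <- prioritize(tv$variants, tv$genotypes, tv$pedigree)

  # naive one-pass re-evaluation, written independently of the cascade
  v <- tv$variants; gm <- tv$genotypes; ped <- tv$pedigree
  keep <- character(0)
  for (i in seq_len(nrow(v))) {
    d <- gm[v$variant_id[i], ]
    called <- sum(!is.na(d)); ac <- sum(d, na.rm = TRUE)
    if (min(ac, 2 * called - ac) == 0) next
    if (called / length(d) < 0.95) next
    if (!v$func_class[i] %in% c("nonsynonymous_SNV", "stopgain", "stoploss",
                                "frameshift_indel", "nonframeshift_indel",
                                "splicing")) next
    afs <- c(v$af_p1[i], v$af_p2[i])
    if (!all(is.na(afs)) && max(afs, na.rm = TRUE) >= 0.2) next
    cadd_ok <- if (!is.na(v$cadd_phred[i])) v$cadd_phred[i] >= 20
               else v$func_class[i] %in% c("frameshift_indel",
                                           "nonframeshift_indel")
    if (!cadd_ok) next
    carr <- names(d)[!is.na(d) & d >= 1]
    fams <- split(ped$sample, ped$family)
    both <- all(vapply(fams, function(f) any(f %in% carr), logical(1)))
    fam_spec <- any(vapply(names(fams), function(fn) {
      all(fams[[fn]] %in% carr) && !any(carr %in% unlist(fams[-match(fn, names(fams))]))
    }, logical(1)))
    if (both || fam_spec) keep <- c(keep, v$variant_id[i])
  }
  expect_setequal(res$candidates$variant_id, keep)

  # cascade counts never increase
  expect_true(all(diff(res$report$n_variants) <= 0))
})

test_that("prioritize handles an empty variant table", {
  tv <- toy_variant_table(4)
  empty <- tv$variants[0, ]
  res <- prioritize(empty, tv$genotypes[0, , drop = FALSE], tv$pedigree)
  expect_equal(nrow(res$candidates), 0)
  expect_true(all(res$report$n_variants == 0))
})

test_that("compound heterozygous carriage is flagged at the gene level", {
  samples <- paste0("S", 1:4)
  gm <- carrier_matrix(list(v1 = c("S1", "S2"), v2 = c("S1", "S3"),
                            v3 = "S4"), samples)
  cand <- data.frame(variant_id = c("v1", "v2", "v3"),
                     gene = c("DCHS1", "DCHS1", "OTHER"))
  ch <- compound_het_genes(cand, gm)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$gene, "DCHS1")
  expect_equal(ch$sample, "S1")
})
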