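test_that("the trinucleotide classifier defines exactly 96 categories", {
  levels <- category_levels_96()
  expect_length(levels, 96)
  expect_false(anyDuplicated(levels) > 0)
  # every label is a pyrimidine-referenced substitution in context
  expect_true(all(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", levels)))
})

test_that("classification collapses to the pyrimidine strand", {
  # C>T at context ACA stays as is
  v <- vrec(pos = 2, ref = "C", alt = "T")
  expect_identical(classify_96(v, "ACA")$category, "A[C>T]A")
  # G>A at context TGT is the reverse complement of the same event
  v2 <- vrec(pos = 2, ref = "G", alt = "A")
  expect_identical(classify_96(v2, "TGT")$category, "A[C>T]A")
})

test_that("enumerating every context and substitution hits all 96 once", {
  labels_fwd <- character(0)
  labels_rc <- character(0)
  for (lab in category_levels_96()) {
    ctx <- paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
    alt <- substr(lab, 5, 5)
    labels_fwd <- c(labels_fwd,
                    classify_96(vrec(pos = 2, ref = substr(ctx, 2, 2),
                                     alt = alt), ctx)$category)
    # same SNV written on the purine strand
    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
    ctx_rc <- rc(ctx)
    labels_rc <- c(labels_rc,
                   classify_96(vrec(pos = 2, ref = substr(ctx_rc, 2, 2),
                                    alt = rc(alt)), ctx_rc)$category)
  }
  expect_identical(sort(unique(labels_fwd)), sort(category_levels_96()))
  expect_identical(labels_rc, labels_fwd)   # strand involution
})

test_that("classifier validates the reference and handles ambiguity", {
  expect_error(classify_96(vrec(pos = 2, ref = "C", alt = "T"), "AAA"),
               "does not match")
  expect_warning(out <- classify_96(vrec(pos = 2, ref = "C", alt = "T"),
                                    "NCA"), "ambiguous")
  expect_true(is.na(out$category))
  # indels pass through unclassified
  ind <- classify_96(vrec(pos = 2, ref = "C", alt = "CA"), "ACA")
  expect_true(is.na(ind$category))
})

test_that("region stratification is exact set algebra", {
  central <- vrec(pos = c(10, 20))
  peripheral <- vrec(region = "peripheral", pos = c(20, 30))
  s <- stratify_regions(central, peripheral)
  expect_identical(s$central_only$pos, 10)
  expect_identical(s$peripheral_only$pos, 30)
  expect_identical(s$shared$pos, 20)
  # identical sets: nothing region-specific
  s2 <- stratify_regions(central, vrec(region = "peripheral",
                                       pos = c(10, 20)))
  expect_identical(nrow(s2$central_only), 0L)
  expect_identical(nrow(s2$peripheral_only), 0L)
  expect_error(stratify_regions(vrec(pos = c(5, 5)), peripheral),
               "duplicate")
})

test_that("recurrence and dbSNP filtering follow the cohort-wide rule", {
  mk <- function(patients, pos, dbsnp = FALSE) {
    do.call(rbind, lapply(patients, function(p)
      cbind(vrec(patient = p, pos = pos, dbsnp = dbsnp),
            stratum = "central")))
  }
  six <- mk(sprintf("P%02d", 1:6), 100)
  five <- mk(sprintf("P%02d", 1:5), 200)
  flagged <- mk("P01", 300, dbsnp = TRUE)
  all_v <- rbind(six, five, flagged)
  r <- recurrence_filter(all_v, n_patients = 8, threshold = 6)
  expect_identical(sort(unique(r$kept$pos)), 200)
  expect_setequal(unique(r$removed$pos), c(100, 300))
  expect_setequal(unique(r$removed$removal_reason), c("recurrent", "dbsnp"))
  expect_error(recurrence_filter(all_v, n_patients = 4, threshold = 6),
               "exceeds")
})

test_that("functional filter keeps the four SNV classes and carries indels", {
  v <- rbind(
    vrec(pos = 1:6,
         fclass = c("synonymous", "stopgain", "splice_site", "nonsynonymous",
                    "stoploss", "other")),
    vrec(pos = 7, ref = "C", alt = "CAT", fclass = "frameshift"))
  out <- functional_filter(v)
  expect_setequal(out$pos, c(2:5, 7))
  expect_warning(out2 <- functional_filter(vrec(pos = 8, fclass = NA)),
                 "missing functional class")
  expect_identical(nrow(out2), 0L)
})

test_that("strand-bias filter removes low-opposite-strand SNVs in biased classes", {
  # reference is ACA repeated: every position = 2 (mod 3) is a C in an
  # A.A context
  biased <- rbind(
    vrec(pos = 3 * (1:8) + 2, fwd = 20L, rev = 0L),  # drive the pooled bias
    vrec(pos = 89, fwd = 7L, rev = 1L),
    vrec(pos = 92, fwd = 7L, rev = 2L))
  biased <- classify_96(cbind(biased, stratum = "central"),
                        strrep("ACA", 40))
  unbiased <- classify_96(cbind(vrec(pos = 95, ref = "T", alt = "G",
                                     fwd = 9L, rev = 1L),
                                stratum = "central"),
                          strrep("ATA", 40))
  unbiased$category  # T-centred category, pooled counts too small for bias
  out <- strand_bias_filter(rbind(biased, unbiased))
  expect_true(all(out$removed$rev < 2))
  expect_true(89 %in% out$removed$pos)            # rev = 1 < 2: removed
  expect_true(92 %in% out$kept$pos)               # rev = 2: boundary kept
  expect_true(95 %in% out$kept$pos)               # unbiased class untouched
  bt <- out$bias_table
  expect_true(bt$biased[bt$category == "A[C>T]A"])
  expect_false(bt$biased[bt$category == "A[T>G]A"])
})

test_that("triplet background counts centred 3-mers with strand collapsing", {
  bg <- exome_triplet_background("ACGT",
                                 data.frame(start = 0L, end = 4L))
  expect_equal(unname(bg["ACG"]), 2)   # ACG + its reverse complement CGT
  expect_equal(unname(bg["CGT"]), 2)
  expect_equal(sum(bg > 0), 2)
  # poly-A reference: no pyrimidine-centred mass, normalization fails loudly
  bgA <- exome_triplet_background(strrep("A", 50),
                                  data.frame(start = 0L, end = 50L))
  counts <- spectrum_counts("A[C>T]A")
  expect_error(normalize_spectrum(counts, bgA), "zero triplet background")
  expect_error(exome_triplet_background("ACGT",
                                        data.frame(start = integer(0),
                                                   end = integer(0))),
               "empty target")
  # a long random reference has a near-uniform collapsed background
  set.seed(10)
  refstr <- paste(sample(c("A", "C", "G", "T"), 50000, TRUE), collapse = "")
  bgU <- exome_triplet_background(refstr,
                                  data.frame(start = 0L, end = 50000L))
  pyr <- bgU[grepl("^[ACGT][CT][ACGT]$", names(bgU))]
  expect_gt(suppressWarnings(
    chisq.test(pyr, p = rep(1 / 32, 32))$p.value), 0.01)
})

test_that("spectrum normalization corrects for the triplet background", {
  counts <- spectrum_counts(c("A[C>T]A", "A[C>T]A", "T[T>G]C"))
  uniform_bg <- setNames(rep(100, 64),
                         names(exome_triplet_background("ACGT",
                           data.frame(start = 0L, end = 4L))))
  norm <- normalize_spectrum(counts, uniform_bg)
  expect_equal(unname(norm["A[C>T]A"]), 2 / 3)
  expect_equal(sum(norm), 1)
  # scale invariance of the background
  expect_equal(normalize_spectrum(counts, uniform_bg * 2), norm)
  # counts in a rare context get up-weighted relative to raw proportions
  bg2 <- uniform_bg
  bg2["TTC"] <- 10   # TTC context (of T[T>G]C) ten-fold rarer
  norm2 <- normalize_spectrum(counts, bg2)
  expect_gt(unname(norm2["T[T>G]C"]), 1 / 3)
  expect_equal(unname(norm2["T[T>G]C"]), (1 / 10) / (2 / 100 + 1 / 10))
})

test_that("cosine similarity follows the closed form", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 2)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(-1, 1), c(1, 1)), "non-negative")
  # property: agreement with a plain-loop oracle
  set.seed(17)
  for (i in 1:25) {
    u <- runif(96); v <- runif(96)
    expect_equal(cosine_similarity(u, v), cosine_brute(u, v))
  }
})

test_that("similarity report compares patients and merged strata", {
  uniform_bg <- setNames(rep(100, 64),
                         names(exome_triplet_background("ACGT",
                           data.frame(start = 0L, end = 4L))))
  # two patients with orthogonal spectra, one patient missing a stratum
  v <- rbind(
    cbind(vrec(patient = "P01", pos = 1:20), stratum = "central",
          category = "A[C>A]A"),
    cbind(vrec(patient = "P01", pos = 21:40), stratum = "peripheral",
          category = "A[C>A]A"),
    cbind(vrec(patient = "P02", pos = 41:60), stratum = "central",
          category = "T[T>C]T"),
    cbind(vrec(patient = "P02", pos = 61:80), stratum = "peripheral",
          category = "T[T>C]T"),
    cbind(vrec(patient = "P03", pos = 81), stratum = "central",
          category = "A[C>G]G"))
  rep <- similarity_report(v, uniform_bg)
  expect_equal(rep$patient_matrix["P01", "P01"], 1)
  expect_equal(rep$patient_matrix["P01", "P02"], 0)  # orthogonal signatures
  expect_equal(rep$per_patient_strata[["P01"]], 1)
  expect_true(is.na(rep$per_patient_strata[["P03"]]))  # missing stratum
  expect_true(rep$merged_similarity > 0.9)  # both strata same mixture
  # single patient: 1x1 matrix, merged comparison still defined
  rep1 <- similarity_report(v[v$patient == "P01", ], uniform_bg)
  expect_identical(dim(rep1$patient_matrix), c(1L, 1L))
  expect_equal(rep1$merged_similarity, 1)
})

test_that("pipeline runs recurrence filtering cohort-wide before spectra", {
  sim <- simulate_variant_tables(variant_sim_config(seed = 41))
  out <- mutsig_pipeline(sim$records, sim$reference, sim$targets)
  # recurrent planted artifacts never reach the kept set
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  rec_keys <- key(sim$truth[sim$truth$artifact == "recurrent", ])
  expect_false(any(key(out$kept) %in% rec_keys))
  expect_true(all(out$kept$stratum %in% c("central", "peripheral")))
  expect_true(nrow(out$removed$recurrence) > 0)
})
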