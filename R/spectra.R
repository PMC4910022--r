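#' Canonical 96 trinucleotide substitution categories
#'
#' Substitutions are referred to the pyrimidine strand (C>A, C>G, C>T, T>A,
#' T>C, T>G), each in its 16 flanking-base contexts, ordered by substitution,
#' then 5' base, then 3' base. Labels look like `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
category_levels_96 <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(f, t3)
      paste0(f, "[", s, "]", t3))))))
}

.rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.category_context <- function(labels) {
  paste0(substr(labels, 1, 1), substr(labels, 3, 3), substr(labels, 7, 7))
}

.ref_string <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    if (length(reference) != 1) {
      stop_ith("expected a single-contig reference")
    }
    as.character(reference[[1L]])
  } else if (inherits(reference, "DNAString")) {
    as.character(reference)
  } else if (is.character(reference) && length(reference) == 1L) {
    reference
  } else {
    stop_ith("reference must be a DNAString(Set) or a single string")
  }
}

#' Classify SNVs into the 96 trinucleotide categories
#'
#' Looks up each SNV's flanking bases in the reference; substitutions with a
#' purine reference base are reverse-complemented to the pyrimidine strand,
#' so an SNV and its reverse-complement representation always map to the
#' same category.
#'
#' @param variants Data frame with `pos` (1-based), `ref`, `alt` and
#'   logical `is_snv` columns; non-SNVs get `NA` categories.
#' @param reference Single-contig reference (`DNAStringSet`, `DNAString` or
#'   string).
#' @return `variants` with a `category` character column added; SNVs whose
#'   context contains an ambiguous base are excluded (category `NA`) with a
#'   warning.
#' @export
classify_96 <- function(variants, reference) {
  refstr <- .ref_string(reference)
  n <- nrow(variants)
  category <- rep(NA_character_, n)
  snv <- which(variants$is_snv)
  if (length(snv)) {
    pos <- variants$pos[snv]
    if (any(pos < 2 | pos > nchar(refstr) - 1)) {
      stop_ith("SNV position lacks flanking context in the reference")
    }
    ref_base <- substring(refstr, pos, pos)
    if (any(ref_base != variants$ref[snv])) {
      stop_ith("variant ref allele does not match the reference sequence")
    }
    trip <- substring(refstr, pos - 1, pos + 1)
    amb <- grepl("[^ACGT]", trip) | !(variants$alt[snv] %in%
                                        c("A", "C", "G", "T"))
    if (any(amb)) {
      warning(sum(amb), " SNV(s) with ambiguous context excluded")
    }
    use <- !amb
    ref_u <- ref_base[use]
    alt_u <- variants$alt[snv][use]
    trip_u <- trip[use]
    pur <- ref_u %in% c("A", "G")
    if (any(pur)) {
      trip_u[pur] <- .rc(trip_u[pur])
      ref_u[pur] <- substr(trip_u[pur], 2, 2)
      alt_u[pur] <- .rc(alt_u[pur])
    }
    category[snv[use]] <- paste0(substr(trip_u, 1, 1), "[", ref_u, ">",
                                 alt_u, "]", substr(trip_u, 3, 3))
  }
  variants$category <- category
  variants
}

#' Stratify one patient's variants into region-specific and shared sets
#'
#' Variant identity is `(chrom, pos, ref, alt)`. Variants seen only in the
#' peripheral-zone sample are peripheral-specific, those seen only in the
#' central-zone sample central-specific, and the intersection is shared.
#'
#' @param central,peripheral Data frames of the two region samples' variants
#'   (columns `chrom`, `pos`, `ref`, `alt`, ...).
#' @return List of data frames `central_only`, `peripheral_only`, `shared`
#'   (shared rows taken from the central sample).
#' @export
stratify_regions <- function(central, peripheral) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  kc <- key(central)
  kp <- key(peripheral)
  if (anyDuplicated(kc) || anyDuplicated(kp)) {
    stop_ith("duplicate variant records within one region set")
  }
  list(central_only = central[!(kc %in% kp), , drop = FALSE],
       peripheral_only = peripheral[!(kp %in% kc), , drop = FALSE],
       shared = central[kc %in% kp, , drop = FALSE])
}

#' Stratify a cohort variant table by patient and region
#'
#' @param variants Data frame with one row per variant call per region
#'   sample: columns `patient`, `region` (`"central"`/`"peripheral"`),
#'   `chrom`, `pos`, `ref`, `alt` and any annotation columns.
#' @return Data frame with one row per distinct variant per patient and a
#'   `stratum` column in `central`, `peripheral`, `shared`.
#' @export
stratify_cohort <- function(variants) {
  out <- lapply(split(variants, variants$patient), function(d) {
    s <- stratify_regions(d[d$region == "central", , drop = FALSE],
                          d[d$region == "peripheral", , drop = FALSE])
    strata <- c("central", "peripheral", "shared")
    sets <- list(s$central_only, s$peripheral_only, s$shared)
    do.call(rbind, Map(function(set, lab) {
      if (nrow(set)) set$stratum <- lab
      else set$stratum <- character(0)
      set
    }, sets, strata))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove recurrent and dbSNP-flagged variants cohort-wide
#'
#' A variant present (in either region) in at least `threshold` of the
#' cohort's patients is treated as a probable artifact or germline leak and
#' removed, as are variants carrying a dbSNP flag without clinical context.
#' This filter must run cohort-wide before any per-patient spectra are
#' computed.
#'
#' @param variants Stratified cohort data frame (see [stratify_cohort()])
#'   with `patient`, `chrom`, `pos`, `ref`, `alt` and optional logical/0-1
#'   `dbsnp` columns.
#' @param n_patients Number of patients in the cohort.
#' @param threshold Patient-recurrence threshold (default 6, for an
#'   8-patient cohort).
#' @return List `kept` / `removed` of data frames; `removed` carries a
#'   `removal_reason` column (`"recurrent"` or `"dbsnp"`).
#' @export
recurrence_filter <- function(variants, n_patients = 8L, threshold = 6L) {
  if (threshold > n_patients) {
    stop_ith("recurrence threshold exceeds the number of patients")
  }
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":")
  carriers <- tapply(variants$patient, key, function(p) length(unique(p)))
  recurrent <- key %in% names(carriers)[carriers >= threshold]
  dbsnp <- if (!is.null(variants$dbsnp)) as.logical(variants$dbsnp) else
    rep(FALSE, nrow(variants))
  dbsnp[is.na(dbsnp)] <- FALSE
  drop <- recurrent | dbsnp
  removed <- variants[drop, , drop = FALSE]
  if (nrow(removed)) {
    removed$removal_reason <- ifelse(recurrent[drop], "recurrent", "dbsnp")
  }
  list(kept = variants[!drop, , drop = FALSE], removed = removed)
}

#' Keep functional variants
#'
#' SNVs are functional when nonsynonymous, within splice sites, or causing
#' stop gain/loss. Indels are carried through with their own class labels
#' for the region-specific tabulation (they never enter the SNV-defined
#' spectra).
#'
#' @param variants Data frame with `is_snv` and `fclass` columns.
#' @return The functional subset; records with missing class are skipped
#'   with a warning giving their count.
#' @export
functional_filter <- function(variants) {
  functional <- c("nonsynonymous", "splice_site", "stopgain", "stoploss")
  miss <- is.na(variants$fclass) | variants$fclass == ""
  if (any(miss)) {
    warning(sum(miss), " record(s) with missing functional class skipped")
  }
  keep <- !miss & ((variants$is_snv & variants$fclass %in% functional) |
                     !variants$is_snv)
  variants[keep, , drop = FALSE]
}

#' Filter strand-biased SNVs within their trinucleotide category
#'
#' For each 96-category, pooled forward/reverse supporting-read counts are
#' tested for strand bias (two-sided binomial test against 0.5). In biased
#' categories, an SNV is removed when it has fewer than two supporting reads
#' on the strand opposite to the bias.
#'
#' @param variants Data frame with `category`, `fwd` and `rev` columns
#'   (categories `NA` for indels are left untouched).
#' @param alpha Significance level for declaring a category biased.
#' @return List: `kept`, `removed`, and `bias_table` (per-category pooled
#'   counts, p-value, biased flag and bias direction).
#' @export
strand_bias_filter <- function(variants, alpha = 0.01) {
  has_cat <- !is.na(variants$category)
  cats <- unique(variants$category[has_cat])
  bias <- lapply(cats, function(cat) {
    rows <- variants$category == cat & has_cat
    fwd <- sum(variants$fwd[rows])
    rev <- sum(variants$rev[rows])
    p <- if (fwd + rev == 0) 1 else
      stats::binom.test(fwd, fwd + rev, 0.5)$p.value
    data.frame(category = cat, fwd = fwd, rev = rev, p.value = p,
               biased = p < alpha,
               direction = if (fwd >= rev) "fwd" else "rev")
  })
  bias_table <- if (length(bias)) do.call(rbind, bias) else
    data.frame(category = character(0), fwd = integer(0), rev = integer(0),
               p.value = numeric(0), biased = logical(0),
               direction = character(0))
  drop <- rep(FALSE, nrow(variants))
  for (i in which(bias_table$biased)) {
    cat <- bias_table$category[i]
    minority <- if (bias_table$direction[i] == "fwd") variants$rev else
      variants$fwd
    drop <- drop | (has_cat & variants$category == cat & minority < 2)
  }
  list(kept = variants[!drop, , drop = FALSE],
       removed = variants[drop, , drop = FALSE],
       bias_table = bias_table)
}

#' Triplet background of the target regions
#'
#' Counts every 3-mer of the reference whose centre base lies inside a
#' target interval, then collapses each triplet with its reverse complement
#' into 32 pyrimidine-centred classes, stored in a 64-slot table with
#' mirrored slots equal so any of the 96 categories can be divided by its
#' context directly.
#'
#' @param reference Single-contig reference.
#' @param targets `GRanges` of target intervals (or a data frame with
#'   0-based half-open `start`, `end` columns).
#' @return Named numeric vector over the 64 triplets.
#' @export
exome_triplet_background <- function(reference, targets) {
  refstr <- .ref_string(reference)
  len <- nchar(refstr)
  if (inherits(targets, "GRanges")) {
    targets <- GenomicRanges::reduce(targets)
    starts <- GenomicRanges::start(targets)
    ends <- GenomicRanges::end(targets)
  } else {
    if (!nrow(targets)) stop_ith("empty target regions")
    starts <- targets$start + 1L  # 0-based half-open BED to 1-based
    ends <- targets$end
  }
  if (!length(starts)) stop_ith("empty target regions")
  if (any(starts < 1) || any(ends > len)) {
    stop_ith("target intervals exceed reference bounds")
  }
  bases <- c("A", "C", "G", "T")
  trip64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  counts <- stats::setNames(numeric(64), sort(trip64))
  for (i in seq_along(starts)) {
    cs <- max(starts[i], 2L)
    ce <- min(ends[i], len - 1L)
    if (ce < cs) next
    seg <- Biostrings::DNAString(substring(refstr, cs - 1L, ce + 1L))
    f <- Biostrings::oligonucleotideFrequency(seg, width = 3, step = 1)
    counts[names(f)] <- counts[names(f)] + f
  }
  collapsed <- counts
  for (t in names(counts)) {
    collapsed[t] <- counts[t] + counts[.rc(t)]
  }
  collapsed
}

#' Tabulate SNV categories into a 96-component spectrum
#'
#' @param categories Character vector of category labels (NAs dropped).
#' @return Named integer vector over [category_levels_96()].
#' @export
spectrum_counts <- function(categories) {
  categories <- categories[!is.na(categories)]
  levels <- category_levels_96()
  bad <- setdiff(unique(categories), levels)
  if (length(bad)) stop_ith("unknown categories: ", paste(bad, collapse = ", "))
  table(factor(categories, levels = levels))
}

#' Normalize a 96-spectrum by the target-region triplet background
#'
#' Each category's count is divided by the background count of its
#' trinucleotide context and the 96 rates are rescaled to sum to 1,
#' correcting the spectrum for the triplet composition of the sequenced
#' target regions.
#'
#' @param counts 96-vector of SNV counts (named by category, or in
#'   [category_levels_96()] order).
#' @param background 64-triplet background from
#'   [exome_triplet_background()].
#' @return Normalized 96-vector summing to 1.
#' @export
normalize_spectrum <- function(counts, background) {
  levels <- category_levels_96()
  if (length(counts) != 96) stop_ith("counts must have 96 components")
  counts <- as.numeric(counts)
  names(counts) <- levels
  ctx <- .category_context(levels)
  bg <- background[ctx]
  if (any(is.na(bg))) stop_ith("background lacks required triplet contexts")
  if (any(counts > 0 & bg == 0)) {
    stop_ith("zero triplet background for a category with nonzero counts")
  }
  rate <- ifelse(bg > 0, counts / bg, 0)
  names(rate) <- levels
  total <- sum(rate)
  if (total == 0) stop_ith("empty spectrum: nothing to normalize")
  rate / total
}

#' Cosine similarity of two non-negative spectra
#'
#' @param u,v Non-negative numeric vectors of equal length, neither all-zero.
#' @return `u . v / (|u| |v|)`, in `[0, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop_ith("vectors must have equal length")
  if (any(u < 0) || any(v < 0)) stop_ith("spectra must be non-negative")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_ith("zero vector has no direction")
  sum(u * v) / (nu * nv)
}

#' Patient-wise and stratum-wise spectrum similarity report
#'
#' Builds the eight (or n) patient-specific normalized spectra from each
#' patient's region-specific SNVs, the two stratum-specific spectra from the
#' merged central and merged peripheral SNV sets, and compares them by
#' pairwise cosine similarity.
#'
#' @param variants Classified, filtered, region-specific SNV data frame with
#'   `patient`, `stratum` (`central`/`peripheral`) and `category` columns.
#' @param background 64-triplet background for normalization.
#' @return List: `patient_spectra` (matrix, one column per patient),
#'   `patient_matrix` (pairwise cosine similarities), `merged_similarity`
#'   (merged central vs merged peripheral), `per_patient_strata` (each
#'   patient's central-vs-peripheral similarity; `NA` where a stratum is
#'   empty after filtering), and `strata_spectra`.
#' @export
similarity_report <- function(variants, background) {
  snv <- variants[!is.na(variants$category) &
                    variants$stratum %in% c("central", "peripheral"), ,
                  drop = FALSE]
  patients <- sort(unique(snv$patient))
  if (length(patients) < 1) stop_ith("no patients with classified SNVs")
  norm_or_na <- function(cats) {
    if (!length(cats)) return(rep(NA_real_, 96))
    normalize_spectrum(spectrum_counts(cats), background)
  }
  patient_spectra <- vapply(patients, function(p)
    norm_or_na(snv$category[snv$patient == p]), numeric(96))
  colnames(patient_spectra) <- patients
  np <- length(patients)
  pm <- matrix(NA_real_, np, np, dimnames = list(patients, patients))
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (!anyNA(patient_spectra[, i]) && !anyNA(patient_spectra[, j])) {
      pm[i, j] <- cosine_similarity(patient_spectra[, i],
                                    patient_spectra[, j])
    }
  }
  strata_spectra <- vapply(c("central", "peripheral"), function(s)
    norm_or_na(snv$category[snv$stratum == s]), numeric(96))
  merged_similarity <- if (anyNA(strata_spectra)) NA_real_ else
    cosine_similarity(strata_spectra[, "central"],
                      strata_spectra[, "peripheral"])
  per_patient <- vapply(patients, function(p) {
    cc <- snv$category[snv$patient == p & snv$stratum == "central"]
    cp <- snv$category[snv$patient == p & snv$stratum == "peripheral"]
    if (!length(cc) || !length(cp)) return(NA_real_)
    cosine_similarity(norm_or_na(cc), norm_or_na(cp))
  }, numeric(1))
  list(patient_spectra = patient_spectra, patient_matrix = pm,
       merged_similarity = merged_similarity,
       per_patient_strata = per_patient, strata_spectra = strata_spectra)
}

#' Run the full region-stratified mutational-spectrum pipeline
#'
#' Stratifies each patient's central and peripheral variant calls, removes
#' recurrent and dbSNP-flagged variants cohort-wide, keeps functional
#' variants, classifies SNVs into the 96 trinucleotide categories, applies
#' the per-category strand-bias filter, and compares the
#' background-normalized spectra by cosine similarity.
#'
#' @param variants Cohort variant table (see [stratify_cohort()]).
#' @param reference Single-contig reference sequence.
#' @param targets Target regions (GRanges or 0-based `start`/`end` data
#'   frame).
#' @param n_patients Cohort size; defaults to the number of distinct
#'   patients.
#' @param recurrence_threshold Patient-recurrence removal threshold.
#' @param bias_alpha Significance level of the strand-bias declaration.
#' @return List: `stratified` (pre-filter), `kept` (final region-specific
#'   functional SNVs/indels), `removed` (with reasons), `bias_table`,
#'   `background`, and `similarity` (see [similarity_report()]).
#' @export
mutsig_pipeline <- function(variants, reference, targets,
                            n_patients = NULL, recurrence_threshold = 6L,
                            bias_alpha = 0.01) {
  n_patients <- n_patients %||% length(unique(variants$patient))
  strat <- stratify_cohort(variants)
  rec <- recurrence_filter(strat, n_patients, recurrence_threshold)
  region_specific <- rec$kept[rec$kept$stratum != "shared", , drop = FALSE]
  fun <- functional_filter(region_specific)
  cls <- classify_96(fun, reference)
  sb <- strand_bias_filter(cls, alpha = bias_alpha)
  background <- exome_triplet_background(reference, targets)
  removed <- list(recurrence = rec$removed, strand_bias = sb$removed)
  sim <- similarity_report(sb$kept, background)
  list(stratified = strat, kept = sb$kept, removed = removed,
       bias_table = sb$bias_table, background = background,
       similarity = sim)
}
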