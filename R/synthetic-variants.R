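#' Default trinucleotide signature for variant simulation
#'
#' A mildly structured 96-category signature: a uniform floor over all
#' categories plus extra C>T mass concentrated at CpG contexts (`N[C>T]G`),
#' the dominant feature of the ubiquitous deamination signature, so that
#' simulated spectra have recognisable but not degenerate structure.
#'
#' @param cpg_weight Fraction of total mass placed on the four `N[C>T]G`
#'   categories.
#' @param ct_weight Additional fraction spread over the remaining C>T
#'   categories.
#' @return Named probability vector over [category_levels_96()] summing
#'   to 1.
#' @export
default_signature <- function(cpg_weight = 0.25, ct_weight = 0.15) {
  levels <- category_levels_96()
  p <- stats::setNames(rep(1, 96), levels)
  ct <- grepl("\\[C>T\\]", levels)
  cpg <- ct & grepl("\\]G$", levels)
  p <- p / sum(p) * (1 - cpg_weight - ct_weight)
  p[cpg] <- p[cpg] + cpg_weight / sum(cpg)
  p[ct & !cpg] <- p[ct & !cpg] + ct_weight / sum(ct & !cpg)
  p / sum(p)
}

#' Configuration for a synthetic region-stratified variant set
#'
#' Emulates an eight-patient cohort with matched central and peripheral
#' tumour exomes: shared (truncal) variants present in both region samples,
#' region-private functional SNVs and indels, SNV contexts drawn from a
#' known trinucleotide signature, planted strand-bias artifacts concentrated
#' in designated categories, and recurrent cross-patient artifacts.
#'
#' @param n_patients Number of patients.
#' @param n_shared_per_patient Truncal variants per patient (in both region
#'   files).
#' @param n_central_private,n_peripheral_private Region-private variants per
#'   patient; defaults follow the study's central-heavy imbalance (about 8.5
#'   vs 2.5 specific variants per specimen).
#' @param signature 96-vector of category probabilities (sums to 1), or a
#'   list of one such vector per patient.
#' @param strand_bias_fraction Planted strand-bias artifacts, as a fraction
#'   of the cohort's private variants; artifacts are drawn from
#'   `biased_categories` and given fewer than two reads on one strand.
#' @param biased_categories Categories hosting the planted bias artifacts.
#' @param recurrent_artifact_count Variants planted identically in at least
#'   six patients (at least `min(6, n_patients)`).
#' @param indel_fraction Fraction of private variants emitted as 1-bp
#'   insertions (class `frameshift`) rather than SNVs.
#' @param ref_length Length of the synthetic reference contig.
#' @param seed Integer seed.
#' @return A `variant_sim_config` list.
#' @export
variant_sim_config <- function(n_patients = 8L, n_shared_per_patient = 20L,
                               n_central_private = 9L,
                               n_peripheral_private = 3L,
                               signature = default_signature(),
                               strand_bias_fraction = 0.1,
                               biased_categories = c("T[T>G]T", "A[T>G]A"),
                               recurrent_artifact_count = 3L,
                               indel_fraction = 0.1,
                               ref_length = 60000L, seed = 1L) {
  check_sig <- function(s) {
    stopifnot(length(s) == 96, all(s >= 0))
    if (abs(sum(s) - 1) > 1e-6) stop_ith("signature must sum to 1")
  }
  if (is.list(signature)) {
    if (length(signature) != n_patients) {
      stop_ith("need one signature per patient")
    }
    lapply(signature, check_sig)
  } else {
    check_sig(signature)
  }
  stopifnot(n_patients >= 1, n_shared_per_patient >= 0,
            n_central_private >= 0, n_peripheral_private >= 0,
            strand_bias_fraction >= 0, strand_bias_fraction <= 1,
            recurrent_artifact_count >= 0, indel_fraction >= 0,
            indel_fraction <= 1, ref_length >= 100)
  structure(
    list(n_patients = as.integer(n_patients),
         n_shared_per_patient = as.integer(n_shared_per_patient),
         n_central_private = as.integer(n_central_private),
         n_peripheral_private = as.integer(n_peripheral_private),
         signature = signature,
         strand_bias_fraction = strand_bias_fraction,
         biased_categories = biased_categories,
         recurrent_artifact_count = as.integer(recurrent_artifact_count),
         indel_fraction = indel_fraction,
         ref_length = as.integer(ref_length), seed = as.integer(seed)),
    class = "variant_sim_config"
  )
}

## Pools of reference positions indexed by pyrimidine-collapsed triplet;
## positions are consumed without replacement so all variants get distinct
## sites.
.context_pools <- function(refstr) {
  len <- nchar(refstr)
  pos <- 2:(len - 1L)
  trip <- substring(refstr, pos - 1L, pos + 1L)
  centre <- substring(refstr, pos, pos)
  pur <- centre %in% c("A", "G")
  collapsed <- trip
  collapsed[pur] <- .rc(trip[pur])
  pools <- split(pos, collapsed)
  lapply(pools, sample)  # shuffle once; draw sequentially
}

.pool_env <- function(pools) {
  e <- new.env()
  e$pools <- pools
  e$draw <- function(ctx) {
    p <- e$pools[[ctx]]
    if (is.null(p) || !length(p)) {
      stop_ith("reference exhausted for context ", ctx,
               ": increase ref_length")
    }
    e$pools[[ctx]] <- p[-1L]
    p[[1L]]
  }
  e
}

.snv_at <- function(refstr, pos, category) {
  ref <- substring(refstr, pos, pos)
  target <- substr(category, 5, 5)  # pyrimidine-strand alt
  if (ref %in% c("C", "T")) list(ref = ref, alt = target)
  else list(ref = ref, alt = .rc(target))
}

#' Simulate per-patient central/peripheral variant sets with ground truth
#'
#' @param cfg A [variant_sim_config()].
#' @param out_dir Optional directory; when given, writes per-patient
#'   central/peripheral VCF 4.2 files, the reference FASTA, the target BED
#'   and the truth table TSV.
#' @return List: `records` (one row per variant call per region file),
#'   `truth` (one row per distinct variant per patient with its stratum,
#'   category and artifact status), `reference` (`DNAStringSet`), `targets`
#'   (`GRanges` covering the contig), `cfg`, and `files` (paths, or `NULL`).
#' @export
simulate_variant_tables <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "variant_sim_config"))
  with_seed(cfg$seed, {
    refstr <- paste(sample(c("A", "C", "G", "T"), cfg$ref_length,
                           replace = TRUE), collapse = "")
    pools <- .pool_env(.context_pools(refstr))
    levels <- category_levels_96()
    sig_for <- function(i) {
      if (is.list(cfg$signature)) cfg$signature[[i]] else cfg$signature
    }
    fclasses <- c("nonsynonymous", "splice_site", "stopgain", "stoploss")
    fprobs <- c(0.8, 0.1, 0.05, 0.05)
    reads <- function() c(fwd = 5L + stats::rpois(1, 10),
                          rev = 5L + stats::rpois(1, 10))
    truth <- list()
    add <- function(patient, region, pos, ref, alt, is_snv, category,
                    fclass, fwd, rev, artifact) {
      truth[[length(truth) + 1L]] <<- data.frame(
        patient = patient, region = region, chrom = "chrS", pos = pos,
        ref = ref, alt = alt, is_snv = is_snv, category = category,
        fclass = fclass, fwd = unname(as.integer(fwd)),
        rev = unname(as.integer(rev)), dbsnp = FALSE,
        artifact = artifact, stringsAsFactors = FALSE)
    }
    patients <- sprintf("P%02d", seq_len(cfg$n_patients))
    make_snv <- function(sig) {
      cat <- sample(levels, 1, prob = sig)
      pos <- pools$draw(.category_context(cat))
      c(list(pos = pos, category = cat), .snv_at(refstr, pos, cat))
    }
    for (i in seq_along(patients)) {
      p <- patients[i]
      sig <- sig_for(i)
      for (k in seq_len(cfg$n_shared_per_patient)) {
        v <- make_snv(sig)
        r <- reads()
        add(p, "shared", v$pos, v$ref, v$alt, TRUE, v$category,
            "nonsynonymous", r["fwd"], r["rev"], "none")
      }
      for (region in c("central", "peripheral")) {
        n_priv <- if (region == "central") cfg$n_central_private else
          cfg$n_peripheral_private
        n_ind <- round(cfg$indel_fraction * n_priv)
        for (k in seq_len(n_priv)) {
          r <- reads()
          if (k <= n_ind) {
            pos <- pools$draw(sample(names(pools$pools), 1))
            ref <- substring(refstr, pos, pos)
            alt <- paste0(ref, sample(c("A", "C", "G", "T"), 1))
            add(p, region, pos, ref, alt, FALSE, NA_character_,
                "frameshift", r["fwd"], r["rev"], "none")
          } else {
            v <- make_snv(sig)
            add(p, region, v$pos, v$ref, v$alt, TRUE, v$category,
                sample(fclasses, 1, prob = fprobs), r["fwd"], r["rev"],
                "none")
          }
        }
      }
    }
    # planted strand-bias artifacts, concentrated in the designated classes
    n_priv_total <- cfg$n_patients *
      (cfg$n_central_private + cfg$n_peripheral_private)
    n_bias <- round(cfg$strand_bias_fraction * n_priv_total)
    for (k in seq_len(n_bias)) {
      cat <- sample(cfg$biased_categories, 1)
      pos <- pools$draw(.category_context(cat))
      sv <- .snv_at(refstr, pos, cat)
      add(sample(patients, 1), sample(c("central", "peripheral"), 1),
          pos, sv$ref, sv$alt, TRUE, cat,
          sample(fclasses, 1, prob = fprobs),
          20L + stats::rpois(1, 10), stats::rbinom(1, 1, 0.4),
          "strand_bias")
    }
    # recurrent cross-patient artifacts (>= 6 of 8 carriers)
    for (k in seq_len(cfg$recurrent_artifact_count)) {
      sig <- sig_for(1L)
      v <- make_snv(sig)
      lo <- min(6L, cfg$n_patients)
      n_car <- if (lo == cfg$n_patients) cfg$n_patients else
        sample(lo:cfg$n_patients, 1)
      carriers <- sample(patients, n_car)
      for (p in carriers) {
        r <- reads()
        add(p, sample(c("central", "peripheral"), 1), v$pos, v$ref, v$alt,
            TRUE, v$category, "nonsynonymous", r["fwd"], r["rev"],
            "recurrent")
      }
    }
    truth <- do.call(rbind, truth)
    # expand to per-file records (shared variants go to both region files)
    shared <- truth[truth$region == "shared", , drop = FALSE]
    single <- truth[truth$region != "shared", , drop = FALSE]
    records <- rbind(
      single,
      transform(shared, region = "central"),
      transform(shared, region = "peripheral"))
    records <- records[order(records$patient, records$region, records$pos),
                       c("patient", "region", "chrom", "pos", "ref", "alt",
                         "is_snv", "fwd", "rev", "fclass", "dbsnp")]
    rownames(records) <- NULL
    reference <- Biostrings::DNAStringSet(stats::setNames(refstr, "chrS"))
    targets <- GenomicRanges::GRanges("chrS",
                                      IRanges::IRanges(1, cfg$ref_length))
    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      fa <- file.path(out_dir, "reference.fa")
      Biostrings::writeXStringSet(reference, fa)
      bed <- file.path(out_dir, "targets.bed")
      rtracklayer::export(targets, bed, format = "BED")
      tt <- file.path(out_dir, "truth.tsv")
      utils::write.table(truth, tt, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      vcfs <- character(0)
      for (p in patients) for (region in c("central", "peripheral")) {
        path <- file.path(out_dir, sprintf("%s_%s.vcf", p, region))
        write_variant_vcf(
          records[records$patient == p & records$region == region, ,
                  drop = FALSE],
          path, contig = "chrS", contig_length = cfg$ref_length)
        vcfs <- c(vcfs, path)
      }
      files <- list(reference = fa, targets = bed, truth = tt, vcfs = vcfs)
    }
    list(records = records, truth = truth, reference = reference,
         targets = targets, cfg = cfg, files = files)
  })
}

#' Write a minimal VCF 4.2 file of variant records
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO records with the supporting
#' strand reads as INFO keys `FWD` and `REV`, the functional class as
#' `FCLASS` and the dbSNP flag as `DBSNP`.
#'
#' @param records Data frame with `chrom`, `pos`, `ref`, `alt`, `fwd`,
#'   `rev`, `fclass`, `dbsnp` columns.
#' @param path Output path.
#' @param contig,contig_length Contig header metadata.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(records, path, contig = "chrS",
                              contig_length = NA) {
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.na(contig_length)) {
      sprintf("##contig=<ID=%s,length=%d>", contig, as.integer(contig_length))
    } else sprintf("##contig=<ID=%s>", contig),
    "##INFO=<ID=FWD,Number=1,Type=Integer,Description=\"Supporting reads on the forward sequencing strand\">",
    "##INFO=<ID=REV,Number=1,Type=Integer,Description=\"Supporting reads on the reverse sequencing strand\">",
    "##INFO=<ID=FCLASS,Number=1,Type=String,Description=\"Functional class of the variant\">",
    "##INFO=<ID=DBSNP,Number=1,Type=Integer,Description=\"Known dbSNP variant without clinical context (0/1)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  records <- records[order(records$pos), , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tFWD=%d;REV=%d;FCLASS=%s;DBSNP=%d",
                  records$chrom, records$pos, records$ref, records$alt,
                  as.integer(records$fwd), as.integer(records$rev),
                  records$fclass, as.integer(records$dbsnp))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a variant VCF written by this package into a record data frame
#'
#' @param path VCF path.
#' @param patient,region Labels attached to the records.
#' @return Data frame in the layout consumed by [stratify_cohort()].
#' @export
read_variant_vcf <- function(path, patient = NA_character_,
                             region = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(patient = character(0), region = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      is_snv = logical(0), fwd = integer(0),
                      rev = integer(0), fclass = character(0),
                      dbsnp = logical(0)))
  }
  data.frame(
    patient = patient, region = region,
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    is_snv = nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L,
    fwd = as.integer(vcfR::extract.info(v, "FWD")),
    rev = as.integer(vcfR::extract.info(v, "REV")),
    fclass = vcfR::extract.info(v, "FCLASS"),
    dbsnp = as.integer(vcfR::extract.info(v, "DBSNP")) == 1L,
    stringsAsFactors = FALSE)
}
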