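#' Variant allele frequency
#'
#' VAF is the fraction of reads supporting the variant allele out of the
#' total depth at the site. Sites with zero depth have no defined VAF and
#' are returned as \code{NA} (not callable).
#'
#' @param altReads variant-supporting read counts.
#' @param depth total read depths.
#' @return Numeric vector of fractions (NA where depth is 0).
#' @examples
#' computeVaf(c(12, 0, 30), c(30, 30, 30))
#' @export
computeVaf <- function(altReads, depth) {
  stopifnot(length(altReads) == length(depth))
  if (any(depth < 0) || any(altReads < 0) || any(altReads > depth))
    stop("need 0 <= altReads <= depth")
  ifelse(depth > 0, altReads / depth, NA_real_)
}

#' Count uncallable samples at a site ("Samples NC")
#'
#' A sample is uncallable when its depth at the site is below
#' \code{minCallableDepth}; screening criterion (1) requires this count to
#' be zero across the whole detection group.
#'
#' @param depths per-sample depths at one site.
#' @param config a \linkS4class{ScreenConfig}.
#' @return Integer count of uncallable samples.
#' @examples
#' countUncallable(c(30, 25, 3, 12), ScreenConfig())
#' @export
countUncallable <- function(depths, config = ScreenConfig()) {
  stopifnot(length(depths) >= 1)
  sum(depths < config@minCallableDepth)
}

#' Classify call zygosity from VAF
#'
#' A call is homozygous when its VAF reaches \code{homVafThreshold}
#' (inclusive, default 0.75) and heterozygous otherwise. Only defined for
#' VAFs that passed the focal threshold.
#'
#' @param vaf variant allele frequencies of accepted calls.
#' @param config a \linkS4class{ScreenConfig}.
#' @return Character vector "heterozygous"/"homozygous".
#' @examples
#' classifyZygosity(c(0.4, 0.75, 0.8))
#' @export
classifyZygosity <- function(vaf, config = ScreenConfig()) {
  if (any(vaf < config@minFocalVaf))
    stop("zygosity is only defined for calls with VAF >= minFocalVaf")
  ifelse(vaf >= config@homVafThreshold, "homozygous", "heterozygous")
}

#' Classify a variant by its alleles
#'
#' Anchor-base (VCF) convention: equal-length single-base alleles are
#' single-base substitutions, a longer reference is a deletion, a longer
#' alternate an insertion. Multi-nucleotide substitutions are rejected.
#'
#' @param ref,alt reference and alternate allele strings (vectorized).
#' @return data.frame with columns \code{var_type} (SBS/DEL/INS) and
#'   \code{indel_len} (0 for SBS).
#' @examples
#' classifyVariantType(c("G", "GAT", "G"), c("A", "G", "GTTTT"))
#' @export
classifyVariantType <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  lr <- nchar(ref); la <- nchar(alt)
  if (any(lr == 0 | la == 0)) stop("alleles must be non-empty")
  if (any(lr == la & lr > 1))
    stop("multi-nucleotide substitutions (MNPs) are not supported")
  if (any(lr == la & ref == alt)) stop("ref and alt alleles must differ")
  var_type <- ifelse(lr == la, "SBS", ifelse(lr > la, "DEL", "INS"))
  data.frame(var_type = var_type, indel_len = abs(lr - la))
}

# Wide depth/alt matrices (sites x samples) from a long counts table.
.countMatrices <- function(counts, samples) {
  key <- .variantKey(counts$chrom, counts$pos, counts$ref, counts$alt_allele)
  ukey <- unique(key)
  si <- match(key, ukey); sj <- match(counts$sample_id, samples)
  keep <- !is.na(sj)
  D <- matrix(NA_real_, length(ukey), length(samples),
              dimnames = list(ukey, samples))
  A <- D
  D[cbind(si[keep], sj[keep])] <- counts$depth[keep]
  A[cbind(si[keep], sj[keep])] <- counts$alt_reads[keep]
  first <- !duplicated(key)
  list(D = D, A = A,
       sites = data.frame(chrom = counts$chrom[first],
                          pos = counts$pos[first],
                          ref = counts$ref[first],
                          alt = counts$alt_allele[first]))
}

# Screen one detection group given wide matrices. Returns call rows.
.screenMatrices <- function(D, A, sites, samples, config) {
  if (anyNA(D)) stop("counts table is missing sample/site combinations")
  callable <- rowSums(D < config@minCallableDepth) == 0
  V <- A / ifelse(D > 0, D, NA)
  V[is.na(V)] <- 0                      # depth-0 rows are not callable anyway
  # top-2 VAF per row to get max-over-others cheaply
  ns <- ncol(V)
  m1 <- apply(V, 1, max)
  w1 <- max.col(V, ties.method = "first")
  Vmask <- V
  Vmask[cbind(seq_len(nrow(V)), w1)] <- -Inf
  m2 <- apply(Vmask, 1, max)
  maxOther <- matrix(m1, nrow(V), ns)
  maxOther[cbind(seq_len(nrow(V)), w1)] <- m2[seq_len(nrow(V))]
  show <- A > 0
  nShow <- rowSums(show)
  if (config@criterion2Mode == "interpreted") {
    c2 <- (nShow - show) <= config@maxOtherVariantSamples
  } else {
    nRefCalled <- rowSums(V < config@maxOtherVaf)
    c2 <- matrix(nRefCalled <= 1, nrow(V), ns)
  }
  pass <- callable & (V >= config@minFocalVaf) &
    (maxOther < config@maxOtherVaf) & c2
  idx <- which(pass, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), depth = numeric(0),
                      alt_reads = numeric(0), vaf = numeric(0)))
  data.frame(sample_id = samples[idx[, 2]],
             chrom = sites$chrom[idx[, 1]], pos = sites$pos[idx[, 1]],
             ref = sites$ref[idx[, 1]], alt = sites$alt[idx[, 1]],
             depth = D[idx], alt_reads = A[idx], vaf = V[idx])
}

#' Screen one detection group for induced mutations
#'
#' Applies the three multi-sample criteria to every site of a counts table
#' treated as a single detection group: (1) no uncallable sample at the
#' site; (2) background-sample cap (see \linkS4class{ScreenConfig}); (3)
#' focal VAF at least \code{minFocalVaf} while below \code{maxOtherVaf} in
#' every other sample of the group. Each alternate allele is evaluated
#' independently; a sample keeps at most one call per site (highest VAF,
#' ties broken by allele order). Zygosity and variant type are attached.
#'
#' @param counts long-format counts data.frame (chrom, pos, ref, alt_allele,
#'   sample_id, depth, alt_reads) covering every sample of the group.
#' @param samples character vector of the group's sample ids (defaults to
#'   all samples present in \code{counts}).
#' @param config a \linkS4class{ScreenConfig}.
#' @return Calls data.frame (sample_id, chrom, pos, ref, alt, depth,
#'   alt_reads, vaf, zygosity, var_type, indel_len).
#' @export
screenGroup <- function(counts, samples = unique(counts$sample_id),
                        config = ScreenConfig()) {
  validObject(config)
  if (!all(unique(counts$sample_id) %in% samples))
    stop("counts contain samples absent from the group definition")
  cm <- .countMatrices(counts, samples)
  calls <- .screenMatrices(cm$D, cm$A, cm$sites, samples, config)
  .finalizeCalls(calls, config)
}

# per-(sample, site) dedup + zygosity + variant type
.finalizeCalls <- function(calls, config) {
  if (nrow(calls)) {
    o <- order(calls$sample_id, calls$chrom, calls$pos, -calls$vaf, calls$alt)
    calls <- calls[o, ]
    dup <- duplicated(calls[, c("sample_id", "chrom", "pos")])
    calls <- calls[!dup, ]
    calls$zygosity <- classifyZygosity(calls$vaf, config)
    vt <- classifyVariantType(calls$ref, calls$alt)
    calls$var_type <- vt$var_type
    calls$indel_len <- vt$indel_len
  } else {
    calls$zygosity <- character(0)
    calls$var_type <- character(0)
    calls$indel_len <- integer(0)
  }
  rownames(calls) <- NULL
  calls
}

#' Remove variants with parental (control) evidence
#'
#' Any variant supported in a non-irradiated control sample at
#' \code{maxOtherVaf} or above is considered pre-existing and removed from
#' every sample. Isolated control error reads below the threshold do not
#' remove a variant.
#'
#' @param calls calls data.frame.
#' @param counts long-format counts table including the control samples.
#' @param sheet sample sheet with \code{sample_id} and \code{role}.
#' @param config a \linkS4class{ScreenConfig}.
#' @return Filtered calls data.frame.
#' @export
removeParental <- function(calls, counts, sheet, config = ScreenConfig()) {
  ctrl <- sheet$sample_id[sheet$role == "control"]
  if (!length(ctrl)) {
    warning("no control samples in sheet; parental filter skipped")
    return(calls)
  }
  cc <- counts[counts$sample_id %in% ctrl, ]
  vaf <- computeVaf(cc$alt_reads, cc$depth)
  bad <- !is.na(vaf) & vaf >= config@maxOtherVaf
  badKey <- unique(.variantKey(cc$chrom[bad], cc$pos[bad], cc$ref[bad],
                               cc$alt_allele[bad]))
  keep <- !.variantKey(calls$chrom, calls$pos, calls$ref, calls$alt) %in% badKey
  calls[keep, , drop = FALSE]
}

#' Remove variants shared across different M1 plants
#'
#' An identical variant called in samples from two or more distinct M1
#' plants cannot be an independent induced mutation and is removed from all
#' samples. Variants shared only among panicles of the same plant are kept
#' (same germline lineage).
#'
#' @param calls calls data.frame.
#' @param sheet sample sheet mapping \code{sample_id} to \code{plant_id}.
#' @return Filtered calls data.frame.
#' @export
removeCrossPlantShared <- function(calls, sheet) {
  if (!nrow(calls)) return(calls)
  plant <- sheet$plant_id[match(calls$sample_id, sheet$sample_id)]
  key <- .variantKey(calls$chrom, calls$pos, calls$ref, calls$alt)
  nPlants <- vapply(split(plant, key), function(p) length(unique(p)),
                    integer(1))
  keep <- nPlants[key] < 2L
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen a whole cohort for induced mutations
#'
#' Runs the full detection procedure: samples are partitioned into
#' detection groups of one panicle per M1 plant within each dose (so
#' mutations shared by panicles of one plant never co-occur in a group and
#' are not lost to the background-VAF criterion), with every control sample
#' added to every group. Group-level screening is followed by the parental
#' filter and the cross-plant shared-variant filter applied cohort-wide.
#'
#' @param counts long-format counts data.frame over all cohort samples.
#' @param sheet sample sheet (sample_id, role, dose_gy, plant_id,
#'   panicle_id).
#' @param config a \linkS4class{ScreenConfig}.
#' @return Calls data.frame with dose and plant metadata joined.
#' @examples
#' coh <- simulateCohort(GenomeSpec(1, 2e5, nGenes = 10),
#'                       doses = 100, plantsPerDose = 3, seed = 2)
#' calls <- screenCohort(cohortCounts(coh), cohortSheet(coh))
#' head(calls)
#' @export
screenCohort <- function(counts, sheet, config = ScreenConfig()) {
  validObject(config)
  if (!all(unique(counts$sample_id) %in% sheet$sample_id))
    stop("counts contain samples absent from the sample sheet")
  ctrl <- sheet$sample_id[sheet$role == "control"]
  mut <- sheet[sheet$role == "mutant", ]
  groups <- split(mut$sample_id, list(mut$dose_gy, mut$panicle_id),
                  drop = TRUE)
  cm <- .countMatrices(counts, sheet$sample_id)
  callList <- lapply(groups, function(g) {
    samples <- c(g, ctrl)
    calls <- .screenMatrices(cm$D[, samples, drop = FALSE],
                             cm$A[, samples, drop = FALSE],
                             cm$sites, samples, config)
    calls[calls$sample_id %in% g, , drop = FALSE]
  })
  calls <- .finalizeCalls(do.call(rbind, callList), config)
  calls <- removeParental(calls, counts, sheet, config)
  calls <- removeCrossPlantShared(calls, sheet)
  meta <- match(calls$sample_id, sheet$sample_id)
  calls$dose_gy <- sheet$dose_gy[meta]
  calls$plant_id <- sheet$plant_id[meta]
  calls$panicle_id <- sheet$panicle_id[meta]
  rownames(calls) <- NULL
  calls
}
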