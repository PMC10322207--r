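.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
.TRANSITION_CLASSES <- c("G:C>A:T", "A:T>G:C")

#' Strand-collapsed substitution class
#'
#' Maps a base substitution to one of the six classes of base-pair change
#' (G:C>A:T, A:T>G:C, A:T>T:A, G:C>T:A, A:T>C:G, C:G>G:C); a substitution
#' and its reverse complement fall in the same class. Transitions are
#' purine-purine or pyrimidine-pyrimidine exchanges.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @return data.frame with columns \code{class} and \code{is_transition}.
#' @examples
#' classifySbs(c("C", "G", "A"), c("T", "A", "T"))
#' @export
classifySbs <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% .BASES) || any(!alt %in% .BASES))
    stop("bases must be one of A, C, G, T")
  if (any(ref == alt)) stop("ref and alt bases must differ")
  # collapse to the A/G-reference representation used in the class names
  cls <- character(length(ref))
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    hit <- which(!is.na(.SBS_ALT_LOOKUP[, r]) & .SBS_ALT_LOOKUP[, r] == a)
    cls[i] <- rownames(.SBS_ALT_LOOKUP)[hit]
  }
  data.frame(class = cls, is_transition = cls %in% .TRANSITION_CLASSES)
}

#' Transition/transversion ratio
#'
#' @param calls calls data.frame with \code{ref}, \code{alt} and
#'   \code{var_type} columns; only SBS rows are used.
#' @return Ts/Tv as a single number; an error is raised when there are no
#'   transversions (the ratio is not a number).
#' @examples
#' calls <- data.frame(ref = c("C", "C", "A"), alt = c("T", "A", "T"),
#'                     var_type = "SBS")
#' tsTvRatio(calls)
#' @export
tsTvRatio <- function(calls) {
  sbs <- calls[calls$var_type == "SBS", ]
  cl <- classifySbs(sbs$ref, sbs$alt)
  tv <- sum(!cl$is_transition)
  if (tv == 0) stop("no transversions: Ts/Tv ratio is undefined (infinite)")
  sum(cl$is_transition) / tv
}

#' Bin an InDel by size
#'
#' Size bins as conventionally reported for induced InDels: exactly 1 bp,
#' 2-10 bp, and more than 10 bp.
#'
#' @param indelLen InDel lengths in bp (vectorized, must be >= 1).
#' @return Character vector in \{"1", "2-10", ">10"\}.
#' @examples
#' binIndelSize(c(1, 10, 38))
#' @export
binIndelSize <- function(indelLen) {
  if (any(indelLen < 1)) stop("indelLen must be >= 1 (0 denotes an SBS)")
  ifelse(indelLen == 1, "1", ifelse(indelLen <= 10, "2-10", ">10"))
}

#' Per-bp mutation frequency
#'
#' Mean mutation count per line divided by genome length, the convention
#' used to report induced-mutation density (e.g. 2.66e-7/bp at 100 Gy for
#' a ~3.96e8 bp rice genome).
#'
#' @param meanCount mean mutations per line.
#' @param genomeLen genome length in bp.
#' @return Frequency per bp.
#' @examples
#' mutationFrequency(105.23, 3.956e8)
#' @export
mutationFrequency <- function(meanCount, genomeLen) {
  if (any(genomeLen <= 0)) stop("genomeLen must be > 0")
  meanCount / genomeLen
}

#' Spectrum summary of a call set
#'
#' Counts and fractions per substitution class, Ts/Tv, counts per variant
#' type, deletion/insertion size-bin fractions, het:hom ratio and the
#' SBS:InDel ratio (pooled).
#'
#' @param calls calls data.frame.
#' @return Named list of summary components.
#' @export
spectrumSummary <- function(calls) {
  sbs <- calls[calls$var_type == "SBS", ]
  clCounts <- setNames(rep(0, 6), .SBS_CLASSES)
  tstv <- NA_real_
  if (nrow(sbs)) {
    cl <- classifySbs(sbs$ref, sbs$alt)
    tab <- table(factor(cl$class, levels = .SBS_CLASSES))
    clCounts[names(tab)] <- as.numeric(tab)
    tv <- sum(!cl$is_transition)
    tstv <- if (tv > 0) sum(cl$is_transition) / tv else NA_real_
  }
  typeCounts <- table(factor(calls$var_type, levels = c("SBS", "DEL", "INS")))
  binTab <- function(type) {
    x <- calls[calls$var_type == type, "indel_len"]
    tab <- table(factor(binIndelSize(x), levels = c("1", "2-10", ">10")))
    if (length(x)) as.numeric(tab) / length(x) else as.numeric(tab) * NA
  }
  het <- sum(calls$zygosity == "heterozygous")
  hom <- sum(calls$zygosity == "homozygous")
  nIndel <- sum(calls$var_type != "SBS")
  list(sbs_class_counts = clCounts,
       sbs_class_fractions = if (sum(clCounts) > 0) clCounts / sum(clCounts)
                             else clCounts * NA,
       ts_tv_ratio = tstv,
       type_counts = setNames(as.numeric(typeCounts), names(typeCounts)),
       del_size_fractions = setNames(binTab("DEL"), c("1", "2-10", ">10")),
       ins_size_fractions = setNames(binTab("INS"), c("1", "2-10", ">10")),
       het_hom_ratio = if (hom > 0) het / hom else NA_real_,
       sbs_indel_ratio = if (nIndel > 0) sum(calls$var_type == "SBS") / nIndel
                         else NA_real_)
}

#' Per-dose summary of a screened cohort
#'
#' For each dose: number of lines (one line = one sequenced M2 panicle
#' sample, lines with zero calls included), mean and SD (n-1 denominator)
#' of per-line mutation counts, per-bp mutation frequency (mean count over
#' genome length), het:hom ratio, and the SBS:InDel ratio computed both
#' per line then averaged and pooled over the dose group.
#'
#' @param calls calls data.frame with \code{sample_id}.
#' @param sheet sample sheet; mutant rows define the lines at each dose.
#' @param genomeLen genome length in bp.
#' @return data.frame, one row per dose.
#' @export
perDoseSummary <- function(calls, sheet, genomeLen) {
  if (any(genomeLen <= 0)) stop("genomeLen must be > 0")
  mut <- sheet[sheet$role == "mutant", ]
  if (!all(calls$sample_id %in% mut$sample_id))
    stop("calls contain samples missing from the sheet's mutant lines")
  doses <- sort(unique(mut$dose_gy))
  rows <- lapply(doses, function(d) {
    lines <- mut$sample_id[mut$dose_gy == d]
    if (!length(lines)) {
      warning("dose ", d, " has no lines; omitted")
      return(NULL)
    }
    dc <- calls[calls$sample_id %in% lines, ]
    perLine <- setNames(rep(0L, length(lines)), lines)
    tab <- table(dc$sample_id)
    perLine[names(tab)] <- as.integer(tab)
    het <- sum(dc$zygosity == "heterozygous")
    hom <- sum(dc$zygosity == "homozygous")
    nSbs <- vapply(lines, function(s)
      sum(dc$sample_id == s & dc$var_type == "SBS"), numeric(1))
    nInd <- vapply(lines, function(s)
      sum(dc$sample_id == s & dc$var_type != "SBS"), numeric(1))
    ratioPerLine <- ifelse(nInd > 0, nSbs / nInd, NA_real_)
    data.frame(dose_gy = d, n_lines = length(lines),
               mean_count = mean(perLine),
               sd_count = if (length(lines) > 1) sd(perLine) else 0,
               single_line = length(lines) == 1,
               mutation_frequency = mean(perLine) / genomeLen,
               het_hom_ratio = if (hom > 0) het / hom else NA_real_,
               sbs_indel_ratio_per_line = mean(ratioPerLine, na.rm = TRUE),
               sbs_indel_ratio_pooled = if (sum(nInd) > 0)
                 sum(nSbs) / sum(nInd) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
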