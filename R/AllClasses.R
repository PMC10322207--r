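#' @import methods
#' @importFrom stats rbinom rpois rnbinom rmultinom runif sd pbinom uniroot
#'   na.omit aggregate chisq.test complete.cases coef resid setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

.SBS_CLASSES <- c("G:C>A:T", "A:T>G:C", "A:T>T:A",
                  "G:C>T:A", "A:T>C:G", "C:G>G:C")

.checkProbVector <- function(p, what, n = NULL, tol = 1e-12) {
  msg <- character()
  if (!is.null(n) && length(p) != n)
    msg <- c(msg, sprintf("'%s' must have length %d", what, n))
  if (any(p < 0))
    msg <- c(msg, sprintf("'%s' must be non-negative", what))
  if (abs(sum(p) - 1) > tol)
    msg <- c(msg, sprintf("'%s' must sum to 1 (got %.15g)", what, sum(p)))
  msg
}

#' Parameters of the miniature reference genome
#'
#' Describes the synthetic stand-in for a plant reference genome used to
#' exercise the pipeline: chromosome number and lengths, base composition,
#' and the number and structure of protein-coding genes. Generated genes are
#' non-overlapping, their CDS lengths are multiples of 3, start with ATG and
#' end with a stop codon, and introns carry canonical GT..AG dinucleotides.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromLengths integer vector of chromosome lengths (bp), recycled to
#'   \code{nChromosomes}.
#' @slot gcFraction genome GC content in (0, 1).
#' @slot nGenes number of genes to place (distributed across chromosomes
#'   proportionally to length).
#' @slot geneStructure named list with integer ranges (2-vectors) controlling
#'   gene anatomy: \code{nExons}, \code{cdsCodons}, \code{intronLen},
#'   \code{utr5Len}, \code{utr3Len}.
#' @slot seed integer seed making genome generation reproducible.
#' @export
setClass("GenomeSpec",
  representation(nChromosomes = "integer", chromLengths = "integer",
                 gcFraction = "numeric", nGenes = "integer",
                 geneStructure = "list", seed = "integer"),
  prototype(nChromosomes = 2L, chromLengths = c(500000L, 500000L),
            gcFraction = 0.44, nGenes = 120L,
            geneStructure = list(nExons = c(1L, 4L), cdsCodons = c(60L, 200L),
                                 intronLen = c(80L, 400L), utr5Len = c(30L, 150L),
                                 utr3Len = c(50L, 250L)),
            seed = 1L))

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (object@nChromosomes < 1L) msg <- c(msg, "need at least one chromosome")
  if (length(object@chromLengths) != object@nChromosomes)
    msg <- c(msg, "chromLengths must match nChromosomes")
  if (any(object@chromLengths <= 0L)) msg <- c(msg, "chromLengths must be > 0")
  if (object@gcFraction <= 0 || object@gcFraction >= 1)
    msg <- c(msg, "gcFraction must lie in (0, 1)")
  needed <- c("nExons", "cdsCodons", "intronLen", "utr5Len", "utr3Len")
  if (!all(needed %in% names(object@geneStructure)))
    msg <- c(msg, paste("geneStructure must name:", paste(needed, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{GenomeSpec}
#'
#' @param nChromosomes,chromLengths,gcFraction,nGenes,geneStructure,seed see
#'   the class documentation.
#' @return A \linkS4class{GenomeSpec}.
#' @examples
#' GenomeSpec(nChromosomes = 1, chromLengths = 1e5, nGenes = 10, seed = 1)
#' @export
GenomeSpec <- function(nChromosomes = 2, chromLengths = c(5e5, 5e5),
                       gcFraction = 0.44, nGenes = 120,
                       geneStructure = list(nExons = c(1L, 4L),
                                            cdsCodons = c(60L, 200L),
                                            intronLen = c(80L, 400L),
                                            utr5Len = c(30L, 150L),
                                            utr3Len = c(50L, 250L)),
                       seed = 1) {
  new("GenomeSpec", nChromosomes = as.integer(nChromosomes),
      chromLengths = as.integer(rep_len(chromLengths, nChromosomes)),
      gcFraction = gcFraction, nGenes = as.integer(nGenes),
      geneStructure = lapply(geneStructure, as.integer),
      seed = as.integer(seed))
}

#' Dose-dependent mutation-induction model
#'
#' Mean mutation load per line follows a saturating curve
#' \eqn{m(D) = m_{max} (1 - e^{-D/\tau})}, reproducing the rise from low
#' doses to a plateau near 100 Gy seen in carbon-ion-beam rice cohorts.
#' Mutation types, strand-collapsed substitution classes and InDel size bins
#' are drawn from the configured probability vectors. Defaults reflect an
#' M2 CIB spectrum: >70\% single-base substitutions, deletions mostly 1 bp
#' or 2-10 bp with a maximum of 38 bp, insertions mostly 1 bp with a
#' maximum of 17 bp, and G:C>A:T the dominant substitution class.
#'
#' @slot mMax asymptotic mutations per line.
#' @slot tau dose constant (Gy) of the saturating exponential.
#' @slot typeProbs named fractions over \code{c("SBS","DEL","INS")}.
#' @slot sbsClassProbs named fractions over the six strand-collapsed
#'   substitution classes.
#' @slot delSizeProbs,insSizeProbs named fractions over size bins
#'   \code{c("1","2-10",">10")}.
#' @slot maxDelSize,maxInsSize largest simulated deletion/insertion (bp).
#' @slot seed integer seed.
#' @export
setClass("InductionModel",
  representation(mMax = "numeric", tau = "numeric", typeProbs = "numeric",
                 sbsClassProbs = "numeric", delSizeProbs = "numeric",
                 insSizeProbs = "numeric", maxDelSize = "integer",
                 maxInsSize = "integer", seed = "integer"))

setValidity("InductionModel", function(object) {
  msg <- character()
  if (object@mMax <= 0) msg <- c(msg, "mMax must be > 0")
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  msg <- c(msg, .checkProbVector(object@typeProbs, "typeProbs", 3L))
  msg <- c(msg, .checkProbVector(object@sbsClassProbs, "sbsClassProbs", 6L))
  msg <- c(msg, .checkProbVector(object@delSizeProbs, "delSizeProbs", 3L))
  msg <- c(msg, .checkProbVector(object@insSizeProbs, "insSizeProbs", 3L))
  if (!identical(names(object@typeProbs), c("SBS", "DEL", "INS")))
    msg <- c(msg, "typeProbs must be named SBS, DEL, INS")
  if (!identical(names(object@sbsClassProbs), .SBS_CLASSES))
    msg <- c(msg, "sbsClassProbs must be named with the six SBS classes")
  if (object@maxDelSize < 1L || object@maxInsSize < 1L)
    msg <- c(msg, "maximum InDel sizes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{InductionModel}
#'
#' Default \code{mMax} and \code{tau} are calibrated so that saturation (95\%
#' of \code{mMax}) is reached at 100 Gy and the curve least-squares matches
#' the per-line mutation loads reported at 100 and 150 Gy in CIB rice
#' (105.23 and 98.17 mutations/line).
#'
#' @param mMax,tau,typeProbs,sbsClassProbs,delSizeProbs,insSizeProbs,maxDelSize,maxInsSize,seed
#'   see the class documentation.
#' @return An \linkS4class{InductionModel}.
#' @examples
#' m <- InductionModel()
#' inductionMean(100, m)
#' @export
InductionModel <- function(mMax = 104.78, tau = 100 / 3,
                           typeProbs = c(SBS = 0.723, DEL = 0.235, INS = 0.042),
                           sbsClassProbs = c("G:C>A:T" = 0.35, "A:T>G:C" = 0.20,
                                             "A:T>T:A" = 0.17, "G:C>T:A" = 0.12,
                                             "A:T>C:G" = 0.08, "C:G>G:C" = 0.08),
                           delSizeProbs = c("1" = 0.4516, "2-10" = 0.4803,
                                            ">10" = 0.0681),
                           insSizeProbs = c("1" = 0.7575, "2-10" = 0.2343,
                                            ">10" = 0.0082),
                           maxDelSize = 38, maxInsSize = 17, seed = 1) {
  new("InductionModel", mMax = mMax, tau = tau, typeProbs = typeProbs,
      sbsClassProbs = sbsClassProbs, delSizeProbs = delSizeProbs,
      insSizeProbs = insSizeProbs, maxDelSize = as.integer(maxDelSize),
      maxInsSize = as.integer(maxInsSize), seed = as.integer(seed))
}

#' Panicle-lineage sharing model
#'
#' Under the progenitor-cell hypothesis, different panicles of one
#' mutagenized M1 plant derive from different embryonic cells and therefore
#' share few induced mutations. Each mutation is carried by one, two or all
#' three sampled panicles with the configured probabilities. Defaults are
#' the observed CIB rice sharing rates (66.9\% unique, 20\% shared by two,
#' 7.5\% shared by three) normalized to sum to one.
#'
#' @slot paniclesPerPlant panicles sampled per M1 plant (default 3).
#' @slot sharingProbs named fractions \code{c(unique=, shared2=, shared3=)}.
#' @export
setClass("LineageModel",
  representation(paniclesPerPlant = "integer", sharingProbs = "numeric"))

setValidity("LineageModel", function(object) {
  msg <- character()
  if (object@paniclesPerPlant < 2L)
    msg <- c(msg, "paniclesPerPlant must be >= 2")
  msg <- c(msg, .checkProbVector(object@sharingProbs, "sharingProbs", 3L))
  if (!identical(names(object@sharingProbs), c("unique", "shared2", "shared3")))
    msg <- c(msg, "sharingProbs must be named unique, shared2, shared3")
  if (object@paniclesPerPlant < 3L && object@sharingProbs[["shared3"]] > 0)
    msg <- c(msg, "shared3 probability must be 0 when fewer than 3 panicles")
  if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{LineageModel}
#'
#' @param paniclesPerPlant,sharingProbs see the class documentation.
#' @return A \linkS4class{LineageModel}.
#' @examples
#' LineageModel()
#' @export
LineageModel <- function(paniclesPerPlant = 3,
                         sharingProbs = c(unique = 66.9, shared2 = 20,
                                          shared3 = 7.5) / 94.4) {
  new("LineageModel", paniclesPerPlant = as.integer(paniclesPerPlant),
      sharingProbs = sharingProbs / sum(sharingProbs))
}

#' Sequencing read-count model
#'
#' Per-site per-sample depths are negative-binomial (mean
#' \code{meanDepth}, size \code{depthDispersion}; coverage variability of
#' short-read WGS), and variant-supporting reads are binomial given depth:
#' p = 0.5 for heterozygous carriers, 1 - error for homozygous carriers and
#' error for non-carriers.
#'
#' @slot meanDepth mean sequencing depth (reads).
#' @slot depthDispersion negative-binomial size parameter; larger is closer
#'   to Poisson.
#' @slot perBaseErrorRate fraction of reads miscalled to the variant allele
#'   at a non-carrier site, in [0, 0.05].
#' @slot seed integer seed.
#' @export
setClass("SequencingModel",
  representation(meanDepth = "numeric", depthDispersion = "numeric",
                 perBaseErrorRate = "numeric", seed = "integer"))

setValidity("SequencingModel", function(object) {
  msg <- character()
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@depthDispersion <= 0) msg <- c(msg, "depthDispersion must be > 0")
  if (object@perBaseErrorRate < 0 || object@perBaseErrorRate > 0.05)
    msg <- c(msg, "perBaseErrorRate must lie in [0, 0.05]")
  if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{SequencingModel}
#'
#' @param meanDepth,depthDispersion,perBaseErrorRate,seed see the class
#'   documentation.
#' @return A \linkS4class{SequencingModel}.
#' @examples
#' SequencingModel(meanDepth = 30)
#' @export
SequencingModel <- function(meanDepth = 30, depthDispersion = 25,
                            perBaseErrorRate = 0.001, seed = 1) {
  new("SequencingModel", meanDepth = meanDepth,
      depthDispersion = depthDispersion,
      perBaseErrorRate = perBaseErrorRate, seed = as.integer(seed))
}

#' Multi-sample mutation screening thresholds
#'
#' Encodes the induced-mutation detection criteria applied to a group of
#' jointly sequenced samples: (1) every sample callable (depth at least
#' \code{minCallableDepth}); (2) at most \code{maxOtherVariantSamples} other
#' samples show the variant allele (\code{criterion2Mode = "interpreted"}),
#' or, verbatim, at most one sample in the group is reference-called
#' (\code{"literal"}); (3) focal variant allele frequency (VAF) at least
#' \code{minFocalVaf} while below \code{maxOtherVaf} in every other sample.
#' A call with VAF at least \code{homVafThreshold} is homozygous.
#'
#' @slot minFocalVaf minimum VAF in the focal sample (default 0.30).
#' @slot maxOtherVaf maximum VAF tolerated in any other sample (default 0.10).
#' @slot homVafThreshold VAF at or above which a call is homozygous
#'   (default 0.75).
#' @slot minCallableDepth minimum depth for a sample to count as callable
#'   (default 8).
#' @slot maxOtherVariantSamples interpreted-mode cap on other samples with
#'   any variant-supporting reads (default 1).
#' @slot criterion2Mode \code{"interpreted"} or \code{"literal"}.
#' @export
setClass("ScreenConfig",
  representation(minFocalVaf = "numeric", maxOtherVaf = "numeric",
                 homVafThreshold = "numeric", minCallableDepth = "integer",
                 maxOtherVariantSamples = "integer", criterion2Mode = "character"))

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (!(object@maxOtherVaf > 0 && object@maxOtherVaf < object@minFocalVaf &&
        object@minFocalVaf <= object@homVafThreshold &&
        object@homVafThreshold <= 1))
    msg <- c(msg, "need 0 < maxOtherVaf < minFocalVaf <= homVafThreshold <= 1")
  if (object@minCallableDepth < 1L) msg <- c(msg, "minCallableDepth must be >= 1")
  if (object@maxOtherVariantSamples < 0L)
    msg <- c(msg, "maxOtherVariantSamples must be >= 0")
  if (!object@criterion2Mode %in% c("interpreted", "literal"))
    msg <- c(msg, "criterion2Mode must be 'interpreted' or 'literal'")
  if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{ScreenConfig}
#'
#' @param minFocalVaf,maxOtherVaf,homVafThreshold,minCallableDepth,maxOtherVariantSamples,criterion2Mode
#'   see the class documentation.
#' @return A \linkS4class{ScreenConfig}.
#' @examples
#' ScreenConfig()
#' @export
ScreenConfig <- function(minFocalVaf = 0.30, maxOtherVaf = 0.10,
                         homVafThreshold = 0.75, minCallableDepth = 8,
                         maxOtherVariantSamples = 1,
                         criterion2Mode = c("interpreted", "literal")) {
  new("ScreenConfig", minFocalVaf = minFocalVaf, maxOtherVaf = maxOtherVaf,
      homVafThreshold = homVafThreshold,
      minCallableDepth = as.integer(minCallableDepth),
      maxOtherVariantSamples = as.integer(maxOtherVariantSamples),
      criterion2Mode = match.arg(criterion2Mode))
}

#' A simulated mutagenized cohort
#'
#' Container produced by \code{\link{simulateCohort}} holding everything a
#' screening run needs: the miniature genome with gene models, the truth
#' mutation table with panicle lineage and per-sample M2 genotypes, the
#' noisy per-site read-count table, and the sample sheet.
#'
#' @slot genome a \link[Biostrings]{DNAStringSet}.
#' @slot genes a \link[GenomicRanges]{GRanges} of gene/exon/CDS/UTR features.
#' @slot truth data.frame of distinct truth mutations (plant, panicle set,
#'   locus, alleles, type, sharing category).
#' @slot truthGenotypes data.frame of per-sample genotypes at truth loci
#'   (absent / heterozygous / homozygous).
#' @slot counts long-format data.frame of per-site per-sample read counts.
#' @slot sheet sample sheet data.frame.
#' @slot seed integer seed the cohort was generated with.
#' @export
setClass("SyntheticCohort",
  representation(genome = "DNAStringSet", genes = "GRanges",
                 truth = "data.frame", truthGenotypes = "data.frame",
                 counts = "data.frame", sheet = "data.frame",
                 seed = "integer"))

#' Fitted single-hit multi-target survival model
#'
#' The SHMT model \eqn{S(D) = 1 - (1 - e^{-D/D_0})^N} describes survival of
#' an organism whose N radiation targets must each be hit; \code{D0} is the
#' mean lethal dose per target and \code{N} the extrapolation number. The
#' shoulder dose is \eqn{D_q = D_0 \ln N} and LD50 solves S(D) = 1/2.
#'
#' @slot D0 mean lethal dose per target (Gy).
#' @slot N extrapolation number (>= 1).
#' @slot Dq shoulder dose (Gy).
#' @slot LD50 dose with 50\% survival (Gy).
#' @slot rss residual sum of squares of the fit.
#' @slot converged logical convergence flag.
#' @slot data the dose-response data.frame used in the fit.
#' @export
setClass("SHMTFit",
  representation(D0 = "numeric", N = "numeric", Dq = "numeric",
                 LD50 = "numeric", rss = "numeric", converged = "logical",
                 data = "data.frame"))

setValidity("SHMTFit", function(object) {
  msg <- character()
  if (object@D0 <= 0) msg <- c(msg, "D0 must be > 0")
  if (object@N < 1) msg <- c(msg, "N must be >= 1")
  if (abs(object@Dq - object@D0 * log(object@N)) > 1e-6)
    msg <- c(msg, "Dq must equal D0 * log(N)")
  if (abs(shmtSurvival(object@LD50, object@D0, object@N) - 0.5) > 1e-9)
    msg <- c(msg, "S(LD50) must equal 0.5")
  if (length(msg)) msg else TRUE
})

#' Fitted hormesis (low-dose stimulation) curve
#'
#' Brain-Cousens modification of the four-parameter log-logistic:
#' \eqn{y(D) = c + (d - c + f D) / (1 + e^{b (\ln D - \ln e)})}, which
#' allows a rise above the control response at low doses before the decline.
#' \code{fallback = TRUE} indicates the data showed no stimulation signal
#' and the monotone log-logistic (f = 0) was fitted instead.
#'
#' @slot b,c,d,e,f model parameters (slope, lower limit, control response,
#'   inflection dose, stimulation coefficient).
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot fallback TRUE when the monotone (f = 0) model was used.
#' @slot data the dose-response data.frame used in the fit.
#' @export
setClass("HormesisFit",
  representation(b = "numeric", c = "numeric", d = "numeric", e = "numeric",
                 f = "numeric", rss = "numeric", converged = "logical",
                 fallback = "logical", data = "data.frame"))
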