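# alt allele implied by (class, ref); rows = SBS classes, cols = A,C,G,T
.SBS_ALT_LOOKUP <- local({
  m <- matrix(NA_character_, 6, 4,
              dimnames = list(.SBS_CLASSES, c("A", "C", "G", "T")))
  m["G:C>A:T", c("G", "C")] <- c("A", "T")
  m["A:T>G:C", c("A", "T")] <- c("G", "C")
  m["A:T>T:A", c("A", "T")] <- c("T", "A")
  m["G:C>T:A", c("G", "C")] <- c("T", "A")
  m["A:T>C:G", c("A", "T")] <- c("C", "G")
  m["C:G>G:C", c("C", "G")] <- c("G", "C")
  m
})

#' Place truth mutations on a genome
#'
#' Draws mutation types, substitution classes and InDel sizes from an
#' \linkS4class{InductionModel} and assigns uniform genomic positions
#' (rejection-sampled so substitution classes are compatible with the local
#' reference base, deletions fit on the chromosome, and positions within the
#' set are distinct). InDels are encoded VCF-style with an anchor base.
#' Inserted sequence is uniform over A/C/G/T; InDel sizes are uniform within
#' their size bin.
#'
#' @param count number of mutations to draw.
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param model an \linkS4class{InductionModel}.
#' @return data.frame with columns chrom, pos, ref, alt, var_type,
#'   indel_len, sbs_class (NA for InDels).
#' @examples
#' ref <- generateReference(GenomeSpec(1, 5e4, nGenes = 3, seed = 1))
#' set.seed(7)
#' head(placeMutations(20, ref$genome, InductionModel()))
#' @export
placeMutations <- function(count, genome, model = InductionModel()) {
  stopifnot(count >= 0)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      var_type = character(0), indel_len = integer(0),
                      sbs_class = character(0))
  if (count == 0) return(empty)
  chromStr <- as.character(genome)
  chromLen <- Biostrings::width(genome)
  chromNames <- names(genome)
  types <- sample(names(model@typeProbs), count, replace = TRUE,
                  prob = model@typeProbs)
  sizes <- integer(count)
  isDel <- types == "DEL"; isIns <- types == "INS"; isSbs <- types == "SBS"
  sizes[isDel] <- .drawIndelSizes(sum(isDel), model@delSizeProbs,
                                  model@maxDelSize)
  sizes[isIns] <- .drawIndelSizes(sum(isIns), model@insSizeProbs,
                                  model@maxInsSize)
  classes <- rep(NA_character_, count)
  classes[isSbs] <- sample(.SBS_CLASSES, sum(isSbs), replace = TRUE,
                           prob = model@sbsClassProbs)
  chromIdx <- integer(count); pos <- integer(count)
  need <- seq_len(count)
  span <- ifelse(isDel, sizes, 0L)     # deletion must fit downstream of anchor
  repeat {
    ci <- sample(length(chromLen), length(need), replace = TRUE,
                 prob = chromLen)
    pp <- floor(runif(length(need)) * (chromLen[ci] - span[need])) + 1L
    chromIdx[need] <- ci; pos[need] <- as.integer(pp)
    refBase <- substring(chromStr[chromIdx[need]], pos[need], pos[need])
    bad <- isSbs[need] & is.na(.SBS_ALT_LOOKUP[cbind(classes[need], refBase)])
    # distinct positions within the set
    keyAll <- paste(chromIdx, pos)
    bad <- bad | duplicated(keyAll)[need]
    if (!any(bad)) break
    need <- need[bad]
  }
  chrom <- chromNames[chromIdx]
  refBase <- substring(chromStr[chromIdx], pos, pos)
  ref <- refBase; alt <- refBase
  alt[isSbs] <- .SBS_ALT_LOOKUP[cbind(classes[isSbs], refBase[isSbs])]
  if (any(isDel)) {
    ref[isDel] <- substring(chromStr[chromIdx[isDel]], pos[isDel],
                            pos[isDel] + sizes[isDel])
    alt[isDel] <- refBase[isDel]
  }
  if (any(isIns)) {
    insSeq <- vapply(sizes[isIns], function(s)
      paste(sample(.BASES, s, replace = TRUE), collapse = ""), character(1))
    alt[isIns] <- paste0(refBase[isIns], insSeq)
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             var_type = types, indel_len = sizes, sbs_class = classes)
}

.drawIndelSizes <- function(n, binProbs, maxSize) {
  if (n == 0L) return(integer(0))
  bins <- sample(names(binProbs), n, replace = TRUE, prob = binProbs)
  out <- integer(n)
  out[bins == "1"] <- 1L
  n2 <- sum(bins == "2-10")
  if (n2) out[bins == "2-10"] <- sample(2:10, n2, replace = TRUE)
  n3 <- sum(bins == ">10")
  if (n3) out[bins == ">10"] <- sample(11:maxSize, n3, replace = TRUE)
  out
}

#' Assign mutations to panicle lineages
#'
#' Each mutation of an M1 plant is carried by one, two or all three of its
#' panicles with the probabilities in the \linkS4class{LineageModel}
#' (progenitor-cell hypothesis: panicles derive from different embryonic
#' cells). For plants with only two sampled panicles the shared-by-3
#' category is unavailable and the remaining probabilities are renormalized.
#' Panicle identities are uniform over subsets of the chosen size.
#'
#' @param mutations data.frame as from \code{\link{placeMutations}}.
#' @param model a \linkS4class{LineageModel}.
#' @param nPanicles panicles sampled for this plant (default from model).
#' @return \code{mutations} with added columns \code{sharing} (unique /
#'   shared2 / shared3) and \code{panicle_set} (comma-separated indices).
#' @export
assignLineage <- function(mutations, model = LineageModel(),
                          nPanicles = model@paniclesPerPlant) {
  if (nPanicles < 2) stop("need at least 2 panicles")
  p <- model@sharingProbs
  if (nPanicles == 2L) {
    p <- p[c("unique", "shared2")]
    p <- p / sum(p)
  }
  n <- nrow(mutations)
  sharing <- if (n) sample(names(p), n, replace = TRUE, prob = p) else character(0)
  size <- c(unique = 1L, shared2 = 2L, shared3 = 3L)[sharing]
  sets <- vapply(size, function(s)
    paste(sort(sample(seq_len(nPanicles), s)), collapse = ","), character(1))
  mutations$sharing <- unname(sharing)
  mutations$panicle_set <- unname(sets)
  mutations
}

#' Mendelian segregation of M1 germline heterozygotes into M2
#'
#' One selfed seed per carrying panicle: genotypes are drawn as absent with
#' probability 1/4, heterozygous 1/2, homozygous 1/4, so the expected
#' het:hom ratio among detected (non-absent) carriers is exactly 2:1.
#'
#' @param n number of independent seeds to segregate.
#' @return Character vector in \{absent, heterozygous, homozygous\}.
#' @examples
#' set.seed(1)
#' table(segregateToM2(1000))
#' @export
segregateToM2 <- function(n) {
  sample(c("absent", "heterozygous", "homozygous"), n, replace = TRUE,
         prob = c(0.25, 0.5, 0.25))
}

#' Emit noisy per-site read counts for a cohort
#'
#' Depth per site and sample is negative-binomial; variant-supporting reads
#' are binomial given depth with success probability 0.5 for heterozygous
#' carriers, 1 - error for homozygous carriers and error for non-carriers
#' (controls are always non-carriers).
#'
#' @param sites data.frame of distinct variants (chrom, pos, ref, alt).
#' @param genotypes data.frame (sample_id, chrom, pos, ref, alt, genotype)
#'   of carrier genotypes; samples/sites not listed are absent.
#' @param sheet sample sheet data.frame with a \code{sample_id} column.
#' @param model a \linkS4class{SequencingModel}.
#' @return Long-format data.frame (chrom, pos, ref, alt, sample_id, depth,
#'   ref_reads, alt_reads).
#' @export
emitReadCounts <- function(sites, genotypes, sheet,
                           model = SequencingModel()) {
  validObject(model)
  nS <- nrow(sites); nK <- nrow(sheet)
  if (nS == 0L) stop("no sites to emit")
  key <- .variantKey(sites$chrom, sites$pos, sites$ref, sites$alt)
  err <- model@perBaseErrorRate
  depth <- as.integer(rnbinom(nS * nK, size = model@depthDispersion,
                              mu = model@meanDepth))
  p <- rep(err, nS * nK)
  if (nrow(genotypes)) {
    gi <- match(.variantKey(genotypes$chrom, genotypes$pos, genotypes$ref,
                            genotypes$alt), key)
    gj <- match(genotypes$sample_id, sheet$sample_id)
    keep <- !is.na(gi) & !is.na(gj) & genotypes$genotype != "absent"
    idx <- (gj[keep] - 1L) * nS + gi[keep]
    p[idx] <- ifelse(genotypes$genotype[keep] == "heterozygous", 0.5, 1 - err)
  }
  alt <- as.integer(rbinom(nS * nK, depth, p))
  data.frame(chrom = rep(sites$chrom, nK), pos = rep(sites$pos, nK),
             ref = rep(sites$ref, nK), alt_allele = rep(sites$alt, nK),
             sample_id = rep(sheet$sample_id, each = nS),
             depth = depth, ref_reads = depth - alt, alt_reads = alt)
}

#' Simulate a full mutagenized cohort
#'
#' End-to-end generator: miniature genome with gene models, per-plant
#' dose-dependent mutation loads, panicle lineage assignment, Mendelian
#' segregation into one M2 seed per panicle, and noisy read counts for every
#' sample (mutant panicle samples plus non-irradiated controls). The default
#' design mirrors an M2 screening cohort: six doses, ten M1 plants per dose,
#' three panicles per plant and three controls at 30x coverage.
#'
#' @param genomeSpec a \linkS4class{GenomeSpec}; its seed is overridden by
#'   \code{seed} so the whole cohort is a function of one seed.
#' @param induction an \linkS4class{InductionModel}.
#' @param lineage a \linkS4class{LineageModel}.
#' @param sequencing a \linkS4class{SequencingModel}.
#' @param doses dose grid in Gy.
#' @param plantsPerDose M1 plants sampled per dose.
#' @param nControls non-irradiated control samples.
#' @param seed integer seed controlling every draw.
#' @return A \linkS4class{SyntheticCohort}.
#' @examples
#' coh <- simulateCohort(GenomeSpec(1, 2e5, nGenes = 20),
#'                       doses = c(50, 100), plantsPerDose = 2, seed = 1)
#' coh
#' @export
simulateCohort <- function(genomeSpec = GenomeSpec(),
                           induction = InductionModel(),
                           lineage = LineageModel(),
                           sequencing = SequencingModel(),
                           doses = c(25, 50, 75, 100, 125, 150),
                           plantsPerDose = 10, nControls = 3, seed = 1) {
  validObject(induction); validObject(lineage); validObject(sequencing)
  .withSeed(seed, {
    gs <- genomeSpec
    gs@seed <- as.integer(seed)
    ref <- generateReference(gs)
    np <- lineage@paniclesPerPlant
    sheet <- rbind(
      data.frame(sample_id = sprintf("ctrl%d", seq_len(nControls)),
                 role = "control", dose_gy = 0,
                 plant_id = NA_character_, panicle_id = NA_integer_),
      do.call(rbind, lapply(doses, function(d) {
        do.call(rbind, lapply(seq_len(plantsPerDose), function(pl) {
          pid <- sprintf("D%03d_P%02d", d, pl)
          data.frame(sample_id = sprintf("%s_S%d", pid, seq_len(np)),
                     role = "mutant", dose_gy = d, plant_id = pid,
                     panicle_id = seq_len(np))
        }))
      })))
    truthList <- list(); genoList <- list()
    for (d in doses) {
      for (pl in seq_len(plantsPerDose)) {
        pid <- sprintf("D%03d_P%02d", d, pl)
        cnt <- drawMutationCount(d, induction)
        if (cnt == 0) next
        mut <- placeMutations(cnt, ref$genome, induction)
        mut <- assignLineage(mut, lineage, np)
        mut$plant_id <- pid
        truthList[[length(truthList) + 1L]] <- mut
        pans <- strsplit(mut$panicle_set, ",")
        reps <- lengths(pans)
        geno <- data.frame(
          sample_id = sprintf("%s_S%s", pid, unlist(pans)),
          chrom = rep(mut$chrom, reps), pos = rep(mut$pos, reps),
          ref = rep(mut$ref, reps), alt = rep(mut$alt, reps),
          genotype = segregateToM2(sum(reps)))
        genoList[[length(genoList) + 1L]] <- geno
      }
    }
    truth <- do.call(rbind, truthList)
    genotypes <- do.call(rbind, genoList)
    rownames(truth) <- NULL
    rownames(genotypes) <- NULL
    sites <- unique(truth[, c("chrom", "pos", "ref", "alt")])
    counts <- emitReadCounts(sites, genotypes, sheet, sequencing)
    new("SyntheticCohort", genome = ref$genome, genes = ref$genes,
        truth = truth, truthGenotypes = genotypes, counts = counts,
        sheet = sheet, seed = as.integer(seed))
  })
}
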