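#' Generate a miniature reference genome with gene models
#'
#' Builds a random genome (base composition set by \code{gcFraction}) and
#' places non-overlapping protein-coding genes on it. Every gene has a
#' 5' UTR, one or more CDS segments separated by introns with canonical
#' GT..AG splice dinucleotides, and a 3' UTR; the spliced CDS starts with
#' ATG, ends with a stop codon, contains no internal in-frame stop and its
#' length is a multiple of 3. Strands are assigned at random. Output is
#' deterministic for a fixed seed in the \code{GenomeSpec}.
#'
#' @param spec a \linkS4class{GenomeSpec}.
#' @return A list with elements \code{genome} (a named
#'   \link[Biostrings]{DNAStringSet}) and \code{genes} (a
#'   \link[GenomicRanges]{GRanges} with columns \code{type} in
#'   \{gene, exon, CDS, five_prime_UTR, three_prime_UTR\}, \code{gene_id}
#'   and GFF3 \code{phase} for CDS).
#' @examples
#' ref <- generateReference(GenomeSpec(1, 1e5, nGenes = 10, seed = 1))
#' ref$genome
#' @export
generateReference <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, {
    gc <- spec@gcFraction
    chromNames <- paste0("chr", seq_len(spec@nChromosomes))
    # genes per chromosome, proportional to length
    w <- spec@chromLengths / sum(spec@chromLengths)
    nPer <- floor(spec@nGenes * w)
    rem <- spec@nGenes - sum(nPer)
    if (rem > 0) {
      o <- order(spec@chromLengths * w - nPer, decreasing = TRUE)
      nPer[o[seq_len(rem)]] <- nPer[o[seq_len(rem)]] + 1L
    }
    gid <- 0L
    chromSeqs <- character(spec@nChromosomes)
    feats <- list()
    for (ci in seq_len(spec@nChromosomes)) {
      len <- spec@chromLengths[ci]
      bases <- .sampleBases(len, gc)
      n <- nPer[ci]
      if (n > 0L) {
        plans <- lapply(seq_len(n), function(i) .planGene(spec@geneStructure))
        tot <- sum(vapply(plans, function(p) p$len, numeric(1)))
        if (tot + n > len)
          stop("cannot place ", n, " genes of total length ", tot,
               " on a ", len, " bp chromosome")
        slack <- len - tot
        gaps <- as.vector(rmultinom(1, slack, rep(1, n + 1L)))
        lens <- vapply(plans, function(p) p$len, numeric(1))
        start <- 1L + cumsum(gaps[seq_len(n)]) +
          cumsum(c(0L, lens))[seq_len(n)]
        for (i in seq_len(n)) {
          gid <- gid + 1L
          g <- .realizeGene(plans[[i]], gc,
                            geneId = sprintf("gene%03d", gid),
                            chrom = chromNames[ci], start = start[i],
                            strand = sample(c("+", "-"), 1))
          bases[start[i]:(start[i] + plans[[i]]$len - 1L)] <- g$seq
          feats[[length(feats) + 1L]] <- g$features
        }
      }
      chromSeqs[ci] <- paste(bases, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(setNames(chromSeqs, chromNames))
    featDf <- do.call(rbind, feats)
    genes <- GenomicRanges::GRanges(
      seqnames = featDf$chrom,
      ranges = IRanges::IRanges(featDf$start, featDf$end),
      strand = featDf$strand,
      type = featDf$type, gene_id = featDf$gene_id, phase = featDf$phase,
      seqinfo = GenomeInfoDb::Seqinfo(chromNames, spec@chromLengths))
    genes <- sort(genes, ignore.strand = TRUE)
    list(genome = genome, genes = genes)
  })
}

# Draw the anatomy of one gene: UTR lengths, CDS split over exons,
# intron lengths. Local coordinates, transcript (5'->3') orientation.
.planGene <- function(gs) {
  rint <- function(r) if (r[1] >= r[2]) r[1] else sample(r[1]:r[2], 1)
  nex <- rint(gs$nExons)
  k <- rint(gs$cdsCodons)            # codons incl. start and stop
  cdsLen <- 3L * k
  if (nex > 1L) {
    cuts <- sort(sample(seq_len(cdsLen - 1L), nex - 1L))
    cdsPieces <- diff(c(0L, cuts, cdsLen))
    introns <- vapply(seq_len(nex - 1L), function(i) rint(gs$intronLen),
                      integer(1))
    introns <- pmax(introns, 4L)     # room for GT..AG
  } else {
    cdsPieces <- cdsLen
    introns <- integer(0)
  }
  u5 <- rint(gs$utr5Len); u3 <- rint(gs$utr3Len)
  list(nex = nex, k = k, cdsPieces = cdsPieces, introns = introns,
       u5 = u5, u3 = u3, len = u5 + cdsLen + u3 + sum(introns))
}

# Materialize a planned gene: local sequence (genomic forward strand) and
# a data.frame of genomic features.
.realizeGene <- function(plan, gc, geneId, chrom, start, strand) {
  L <- plan$len
  seq <- .sampleBases(L, gc)
  # transcript-orientation layout
  cdsSeq <- c("ATG", .sampleCodons(plan$k - 2L, gc), sample(.stopCodons, 1))
  cdsChars <- unlist(strsplit(paste(cdsSeq, collapse = ""), ""))
  pos <- plan$u5 + 1L                 # cursor in local transcript coords
  cdsRanges <- matrix(0L, plan$nex, 2)
  intronRanges <- if (plan$nex > 1L) matrix(0L, plan$nex - 1L, 2) else NULL
  ci <- 0L
  for (i in seq_len(plan$nex)) {
    pl <- plan$cdsPieces[i]
    cdsRanges[i, ] <- c(pos, pos + pl - 1L)
    seq[pos:(pos + pl - 1L)] <- cdsChars[(ci + 1L):(ci + pl)]
    ci <- ci + pl
    pos <- pos + pl
    if (i < plan$nex) {
      il <- plan$introns[i]
      intronRanges[i, ] <- c(pos, pos + il - 1L)
      seq[pos:(pos + 1L)] <- c("G", "T")
      seq[(pos + il - 2L):(pos + il - 1L)] <- c("A", "G")
      pos <- pos + il
    }
  }
  # exons: UTR5 glued to first CDS piece, UTR3 to last
  exonRanges <- cdsRanges
  exonRanges[1, 1] <- 1L
  exonRanges[plan$nex, 2] <- L
  utr5 <- c(1L, plan$u5)
  utr3 <- c(L - plan$u3 + 1L, L)
  # GFF3 phase of CDS pieces in translation order
  before <- cumsum(c(0L, plan$cdsPieces))[seq_len(plan$nex)]
  phase <- (3L - before %% 3L) %% 3L
  loc <- rbind(
    data.frame(type = "gene", s = 1L, e = L, phase = NA_integer_),
    data.frame(type = "exon", s = exonRanges[, 1], e = exonRanges[, 2],
               phase = NA_integer_),
    data.frame(type = "CDS", s = cdsRanges[, 1], e = cdsRanges[, 2],
               phase = phase),
    data.frame(type = "five_prime_UTR", s = utr5[1], e = utr5[2],
               phase = NA_integer_),
    data.frame(type = "three_prime_UTR", s = utr3[1], e = utr3[2],
               phase = NA_integer_))
  if (plan$u5 == 0L)
    loc <- loc[loc$type != "five_prime_UTR", ]
  if (plan$u3 == 0L)
    loc <- loc[loc$type != "three_prime_UTR", ]
  if (strand == "-") {
    seq <- rev(chartr("ACGT", "TGCA", seq))
    news <- L - loc$e + 1L; newe <- L - loc$s + 1L
    loc$s <- news; loc$e <- newe
  }
  features <- data.frame(chrom = chrom, start = start + loc$s - 1L,
                         end = start + loc$e - 1L, strand = strand,
                         type = loc$type, gene_id = geneId,
                         phase = loc$phase)
  list(seq = seq, features = features)
}

#' Mean induced mutation load at a dose
#'
#' The saturating induction curve \eqn{m(D) = m_{max}(1 - e^{-D/\tau})}:
#' mutation counts rise with dose and plateau near saturation, as observed
#' for carbon-ion-beam mutagenesis around 100 Gy.
#'
#' @param dose dose in Gy (vectorized, must be >= 0).
#' @param model an \linkS4class{InductionModel}.
#' @return Expected mutations per line at each dose.
#' @examples
#' inductionMean(c(0, 50, 100, 150), InductionModel())
#' @export
inductionMean <- function(dose, model = InductionModel()) {
  if (any(dose < 0)) stop("dose must be >= 0")
  model@mMax * (1 - exp(-dose / model@tau))
}

#' Draw per-line mutation counts
#'
#' Poisson draws with mean \code{\link{inductionMean}(dose, model)}; a dose
#' of zero always yields zero mutations.
#'
#' @param dose dose in Gy (vectorized).
#' @param model an \linkS4class{InductionModel}.
#' @param n number of draws per dose element (default 1).
#' @return Integer vector of counts.
#' @examples
#' set.seed(1)
#' drawMutationCount(100, InductionModel(), n = 5)
#' @export
drawMutationCount <- function(dose, model = InductionModel(), n = 1) {
  if (any(dose < 0)) stop("dose must be >= 0")
  m <- rep(inductionMean(dose, model), each = n)
  rpois(length(m), m)
}
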