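.REGION_LEVELS <- c("exon", "five_prime_UTR", "three_prime_UTR",
                    "splice_site", "intron", "upstream", "downstream",
                    "intergenic")

.IMPACT_TABLE <- c(stop_gained = "HIGH", stop_lost = "HIGH",
                   start_lost = "HIGH", frameshift = "HIGH",
                   splice_disruptor = "HIGH",
                   missense = "MODERATE", inframe_indel = "MODERATE",
                   synonymous = "LOW", noncoding = "MODIFIER")

#' Impact class of a coding effect
#'
#' Fixed mapping following the usual annotation convention: HIGH for
#' nonsense (stop gained/lost), start loss, frameshift and splice
#' disruption; MODERATE for missense and in-frame InDels; LOW for
#' synonymous; MODIFIER for non-coding.
#'
#' @param effect effect labels (vectorized).
#' @return Character vector of impact classes.
#' @examples
#' impactOf(c("stop_gained", "missense", "synonymous"))
#' @export
impactOf <- function(effect) {
  bad <- !effect %in% names(.IMPACT_TABLE)
  if (any(bad)) stop("unknown effect: ", paste(unique(effect[bad]), collapse = ", "))
  unname(.IMPACT_TABLE[effect])
}

# Disjoint per-class feature ranges (strand-kept for genes, overlaps
# resolved by priority when summing composition).
.featureRanges <- function(genes, window) {
  g <- genes[genes$type == "gene"]
  exons <- genes[genes$type == "exon"]
  cds <- genes[genes$type == "CDS"]
  utr5 <- genes[genes$type == "five_prime_UTR"]
  utr3 <- genes[genes$type == "three_prime_UTR"]
  intronList <- lapply(unique(g$gene_id), function(id) {
    ex <- IRanges::reduce(IRanges::ranges(exons[exons$gene_id == id]))
    body <- range(ex)
    gaps <- IRanges::setdiff(body, ex)
    if (!length(gaps)) return(NULL)
    GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(g[g$gene_id == id])[1], gaps,
      strand = BiocGenerics::strand(g[g$gene_id == id])[1], gene_id = id)
  })
  intronList <- intronList[!vapply(intronList, is.null, logical(1))]
  introns <- if (length(intronList)) do.call(c, intronList) else {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_id <- character(0)
    gr
  }
  if (length(introns)) {
    donor <- GenomicRanges::resize(introns, 2, fix = "start",
                                   ignore.strand = TRUE)
    acceptor <- GenomicRanges::resize(introns, 2, fix = "end",
                                      ignore.strand = TRUE)
    splice <- c(donor, acceptor)
  } else splice <- introns
  # strand-aware flanks built manually (clipped at chromosome bounds)
  sl <- GenomeInfoDb::seqlengths(g)
  gs <- BiocGenerics::start(g); ge <- BiocGenerics::end(g)
  plus <- as.character(BiocGenerics::strand(g)) != "-"
  chrEnd <- unname(sl[as.character(GenomeInfoDb::seqnames(g))])
  chrEnd[is.na(chrEnd)] <- .Machine$integer.max
  mkFlank <- function(before) {
    left <- xor(plus, !before)        # TRUE: interval on the low side
    s <- ifelse(left, pmax(1L, gs - window), ge + 1L)
    e <- ifelse(left, gs - 1L, pmin(chrEnd, ge + window))
    keep <- e >= s
    gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(g)[keep],
                                 IRanges::IRanges(s[keep], e[keep]),
                                 strand = BiocGenerics::strand(g)[keep])
    gr$gene_id <- g$gene_id[keep]
    gr
  }
  up <- mkFlank(TRUE); down <- mkFlank(FALSE)
  list(gene = g, exon = exons, cds = cds, five_prime_UTR = utr5,
       three_prime_UTR = utr3, intron = introns, splice_site = splice,
       upstream = up, downstream = down)
}

# genomic footprint of a call: SBS = its base; DEL = deleted bases;
# INS = the two bases flanking the insertion point (trimmed at chrom end)
.callRanges <- function(calls, seqinfo = NULL) {
  lr <- nchar(calls$ref); la <- nchar(calls$alt)
  start <- ifelse(lr > la, calls$pos + 1L, calls$pos)
  end <- ifelse(lr > la, calls$pos + (lr - 1L),
                ifelse(la > lr, calls$pos + 1L, calls$pos))
  gr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(start, end))
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
    gr <- GenomicRanges::trim(gr)
  }
  gr
}

#' Assign genomic regions to calls
#'
#' Region precedence: exon (CDS) > 5'/3' UTR > splice site (2 bp at each
#' intron end) > intron > upstream/downstream (within \code{window} bp of
#' the gene) > intergenic. For up/downstream assignments the nearest gene
#' wins, ties broken by gene id.
#'
#' @param calls calls data.frame (chrom, pos, ref, alt).
#' @param genes gene-model \link[GenomicRanges]{GRanges}.
#' @param window up/downstream window in bp (default 5000).
#' @return data.frame with columns \code{region} and \code{gene_id}
#'   (NA for intergenic).
#' @export
assignRegion <- function(calls, genes, window = 5000) {
  fr <- .featureRanges(genes, window)
  cr <- .callRanges(calls)
  n <- nrow(calls)
  region <- rep("intergenic", n)
  geneId <- rep(NA_character_, n)
  # lowest priority first; later classes overwrite
  assign1 <- function(featGr, label, current) {
    if (!length(featGr)) return(current)
    featGr <- featGr[order(featGr$gene_id)]
    hits <- GenomicRanges::findOverlaps(cr, featGr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    first <- !duplicated(qh)
    current$region[qh[first]] <- label
    current$gene_id[qh[first]] <- featGr$gene_id[sh[first]]
    current
  }
  # upstream/downstream handled jointly: the nearest gene body wins,
  # ties broken by gene id
  assignFlank <- function(current) {
    flank <- c(fr$upstream, fr$downstream)
    if (!length(flank)) return(current)
    label <- rep(c("upstream", "downstream"),
                 c(length(fr$upstream), length(fr$downstream)))
    hits <- GenomicRanges::findOverlaps(cr, flank, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (!length(qh)) return(current)
    gb <- fr$gene[match(flank$gene_id[sh], fr$gene$gene_id)]
    d <- GenomicRanges::distance(cr[qh], gb, ignore.strand = TRUE)
    ord <- order(qh, d, flank$gene_id[sh])
    qh <- qh[ord]; sh <- sh[ord]
    first <- !duplicated(qh)
    current$region[qh[first]] <- label[sh[first]]
    current$gene_id[qh[first]] <- flank$gene_id[sh[first]]
    current
  }
  cur <- list(region = region, gene_id = geneId)
  cur <- assignFlank(cur)
  cur <- assign1(fr$intron, "intron", cur)
  cur <- assign1(fr$splice_site, "splice_site", cur)
  cur <- assign1(fr$three_prime_UTR, "three_prime_UTR", cur)
  cur <- assign1(fr$five_prime_UTR, "five_prime_UTR", cur)
  cur <- assign1(fr$cds, "exon", cur)
  data.frame(region = cur$region, gene_id = cur$gene_id)
}

# map genomic positions to CDS coordinates (1-based, translation order)
.cdsCoord <- function(pos, cds) {
  cds <- sort(cds)
  minus <- as.character(BiocGenerics::strand(cds))[1] == "-"
  w <- BiocGenerics::width(cds)
  starts <- BiocGenerics::start(cds); ends <- BiocGenerics::end(cds)
  piece <- pmax(findInterval(pos, starts), 1L)
  ok <- pos >= starts[piece] & pos <= ends[piece]
  off <- cumsum(c(0L, w))[piece] + (pos - starts[piece]) + 1L
  coord <- if (minus) sum(w) - off + 1L else off
  ifelse(ok, coord, NA_integer_)
}

#' Coding effect of a call inside a CDS
#'
#' For substitutions the affected codon is translated on the coding strand
#' (standard genetic code): same amino acid gives synonymous, a new stop
#' gives stop_gained, a lost stop stop_lost, a destroyed ATG start
#' start_lost, otherwise missense. CDS InDels are frameshift when their
#' length is not a multiple of 3 and inframe_indel otherwise.
#'
#' @param calls calls data.frame rows lying in the CDS of \code{geneId}.
#' @param geneId the gene to annotate against.
#' @param genes gene-model \link[GenomicRanges]{GRanges}.
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @return data.frame with \code{effect}, \code{ref_aa}, \code{alt_aa}
#'   (single-letter, "*" for stop, NA where not applicable).
#' @export
codingEffect <- function(calls, geneId, genes, genome) {
  cds <- sort(genes[genes$type == "CDS" & genes$gene_id == geneId])
  if (!length(cds)) stop("gene ", geneId, " has no CDS")
  minus <- as.character(BiocGenerics::strand(cds))[1] == "-"
  cdsSeq <- as.character(cdsSequence(genome, genes, geneId))
  nAA <- nchar(cdsSeq) / 3
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(cdsSeq)))
  if (grepl("\\*", substring(prot, 1, nAA - 1)))
    stop("reference CDS of ", geneId, " has a premature stop codon")
  n <- nrow(calls)
  effect <- character(n); refAA <- rep(NA_character_, n)
  altAA <- rep(NA_character_, n)
  vt <- classifyVariantType(calls$ref, calls$alt)
  for (i in seq_len(n)) {
    if (vt$var_type[i] != "SBS") {
      effect[i] <- if (vt$indel_len[i] %% 3 == 0) "inframe_indel" else "frameshift"
      next
    }
    cpos <- .cdsCoord(calls$pos[i], cds)
    if (is.na(cpos)) stop("call position not inside the CDS of ", geneId)
    base <- calls$alt[i]
    if (minus) base <- .COMPLEMENT[[base]]
    ci <- (cpos - 1L) %/% 3L + 1L
    within <- (cpos - 1L) %% 3L + 1L
    refCodon <- substring(cdsSeq, 3L * (ci - 1L) + 1L, 3L * ci)
    altCodon <- refCodon
    substring(altCodon, within, within) <- base
    ra <- unname(Biostrings::GENETIC_CODE[refCodon])
    aa <- unname(Biostrings::GENETIC_CODE[altCodon])
    refAA[i] <- ra; altAA[i] <- aa
    effect[i] <-
      if (ci == 1L && altCodon != "ATG") "start_lost"
      else if (ra != "*" && aa == "*") "stop_gained"
      else if (ra == "*" && aa != "*") "stop_lost"
      else if (ra == aa) "synonymous"
      else "missense"
  }
  data.frame(effect = effect, ref_aa = refAA, alt_aa = altAA)
}

#' Annotate a call set against gene models
#'
#' Combines \code{\link{assignRegion}} and \code{\link{codingEffect}}: each
#' call receives its primary region, gene, effect and impact. CDS InDels
#' that extend beyond the CDS into intronic sequence are classified
#' splice_disruptor, as are calls in splice sites.
#'
#' @param calls calls data.frame.
#' @param genes gene-model \link[GenomicRanges]{GRanges}.
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param window up/downstream window in bp (default 5000).
#' @return \code{calls} with added columns region, gene_id, effect, impact,
#'   ref_aa, alt_aa.
#' @export
annotateCalls <- function(calls, genes, genome, window = 5000) {
  reg <- assignRegion(calls, genes, window)
  n <- nrow(calls)
  out <- cbind(calls, reg,
               data.frame(effect = rep("noncoding", n),
                          ref_aa = rep(NA_character_, n),
                          alt_aa = rep(NA_character_, n)))
  out$effect[out$region == "splice_site"] <- "splice_disruptor"
  exonIdx <- which(out$region == "exon")
  if (length(exonIdx)) {
    cr <- .callRanges(calls[exonIdx, , drop = FALSE])
    cds <- genes[genes$type == "CDS"]
    # InDel footprint reaching outside the CDS disrupts splicing
    within <- rep(FALSE, length(exonIdx))
    ov <- GenomicRanges::findOverlaps(cr, cds, type = "within",
                                      ignore.strand = TRUE)
    within[unique(S4Vectors::queryHits(ov))] <- TRUE
    boundary <- exonIdx[!within]
    out$effect[boundary] <- "splice_disruptor"
    inside <- exonIdx[within]
    for (id in unique(out$gene_id[inside])) {
      sel <- inside[out$gene_id[inside] == id]
      ce <- codingEffect(out[sel, , drop = FALSE], id, genes, genome)
      out$effect[sel] <- ce$effect
      out$ref_aa[sel] <- ce$ref_aa
      out$alt_aa[sel] <- ce$alt_aa
    }
  }
  out$impact <- impactOf(out$effect)
  out
}

#' Amino-acid change matrix
#'
#' 20 x 20 counts of ordered (reference aa, variant aa) pairs over the
#' missense annotations of a call set; the diagonal is structurally zero.
#' The number of distinct induced amino-acid variations is the count of
#' nonzero cells and coverage is that count over the 380 possible ordered
#' changes.
#'
#' @param annotations output of \code{\link{annotateCalls}}.
#' @return List with \code{counts} (20 x 20 matrix), \code{frequencies},
#'   \code{n_distinct} and \code{coverage}.
#' @export
aaChangeMatrix <- function(annotations) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- matrix(0, 20, 20, dimnames = list(from = aa, to = aa))
  sel <- annotations$effect == "missense" &
    annotations$ref_aa %in% aa & annotations$alt_aa %in% aa
  if (any(sel)) {
    tab <- table(factor(annotations$ref_aa[sel], aa),
                 factor(annotations$alt_aa[sel], aa))
    m <- m + unclass(tab)
  }
  diag(m) <- 0
  tot <- sum(m)
  list(counts = m,
       frequencies = if (tot > 0) m / tot else m,
       n_distinct = sum(m > 0),
       coverage = sum(m > 0) / 380)
}

#' Select candidate genes
#'
#' In phenotypically stable lines only homozygous mutations with HIGH or
#' MODERATE impact are regarded as candidates for the causal gene. One
#' candidate row is kept per (line, gene), preferring the higher-impact
#' hit.
#'
#' @param annotations output of \code{\link{annotateCalls}} carrying
#'   \code{sample_id}, \code{zygosity}, \code{gene_id}, \code{effect},
#'   \code{impact}.
#' @return data.frame with columns line_id, gene_id, effect, impact, chrom,
#'   pos, ref, alt.
#' @export
selectCandidates <- function(annotations) {
  sel <- annotations$zygosity == "homozygous" &
    annotations$impact %in% c("HIGH", "MODERATE") &
    !is.na(annotations$gene_id)
  cand <- annotations[sel, , drop = FALSE]
  if (!nrow(cand))
    return(data.frame(line_id = character(0), gene_id = character(0),
                      effect = character(0), impact = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  o <- order(cand$sample_id, cand$gene_id,
             match(cand$impact, c("HIGH", "MODERATE")), cand$pos)
  cand <- cand[o, ]
  cand <- cand[!duplicated(cand[, c("sample_id", "gene_id")]), ]
  out <- data.frame(line_id = cand$sample_id, gene_id = cand$gene_id,
                    effect = cand$effect, impact = cand$impact,
                    chrom = cand$chrom, pos = cand$pos, ref = cand$ref,
                    alt = cand$alt)
  rownames(out) <- NULL
  out
}

#' Count affected genes per line
#'
#' A gene counts as affected in a line when at least one call of that line
#' is annotated to it (exon, UTR, splice site, intron, or the up/downstream
#' window).
#'
#' @param annotations output of \code{\link{annotateCalls}}.
#' @return data.frame with sample_id and n_affected_genes.
#' @export
affectedGenes <- function(annotations) {
  hit <- annotations[!is.na(annotations$gene_id), ]
  tab <- vapply(split(hit$gene_id, hit$sample_id),
                function(g) length(unique(g)), integer(1))
  data.frame(sample_id = names(tab), n_affected_genes = unname(tab))
}

#' Genomic region composition
#'
#' Base-pair share of each region class over the genome under the same
#' precedence as \code{\link{assignRegion}}; the expected distribution of
#' uniformly placed mutations.
#'
#' @param genes gene-model \link[GenomicRanges]{GRanges}.
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param window up/downstream window in bp.
#' @return Named numeric vector of bp per region class.
#' @export
regionComposition <- function(genes, genome, window = 5000) {
  out <- setNames(numeric(length(.REGION_LEVELS)), .REGION_LEVELS)
  for (chrom in names(genome)) {
    len <- Biostrings::width(genome[chrom])
    pos <- seq_len(len)
    fake <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C")
    reg <- assignRegion(fake, genes, window)
    tab <- table(factor(reg$region, levels = .REGION_LEVELS))
    out <- out + as.numeric(tab)
  }
  out
}
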