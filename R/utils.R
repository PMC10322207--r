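# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. seed = NULL leaves the
# current stream untouched (draws advance it).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.BASES <- c("A", "C", "G", "T")

.baseProbs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

.sampleBases <- function(n, gc) {
  sample(.BASES, n, replace = TRUE, prob = .baseProbs(gc))
}

.revcompChar <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# key uniquely identifying a variant
.variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.stopCodons <- c("TAA", "TAG", "TGA")

# sample n codons that are not stop codons, base composition ~ gc
.sampleCodons <- function(n, gc) {
  if (n == 0L) return(character(0))
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- paste0(.sampleBases(length(need), gc),
                   .sampleBases(length(need), gc),
                   .sampleBases(length(need), gc))
    ok <- !cand %in% .stopCodons
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Spliced CDS sequence of a gene
#'
#' Concatenates the CDS intervals of a gene in translation order
#' (reverse-complemented for minus-strand genes).
#'
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param genes gene-model \link[GenomicRanges]{GRanges} as produced by
#'   \code{\link{generateReference}} or \code{\link{readGenesGff3}}.
#' @param geneId gene identifier.
#' @return A \link[Biostrings]{DNAString} of the coding sequence.
#' @export
cdsSequence <- function(genome, genes, geneId) {
  cds <- genes[genes$type == "CDS" & genes$gene_id == geneId]
  if (!length(cds)) stop("no CDS for gene ", geneId)
  cds <- sort(cds)
  chrom <- as.character(GenomeInfoDb::seqnames(cds))[1]
  pieces <- Biostrings::extractAt(genome[[chrom]], IRanges::ranges(cds))
  seq <- Biostrings::DNAString(paste(vapply(as.list(pieces), as.character,
                                            character(1)), collapse = ""))
  if (as.character(BiocGenerics::strand(cds))[1] == "-")
    seq <- Biostrings::reverseComplement(seq)
  seq
}
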