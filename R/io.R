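#' Read and write pipeline files
#'
#' Plain-text interchange formats used by the pipeline: reference FASTA,
#' gene models as GFF3 (1-based, inclusive), the truth mutation table, the
#' long-format site-counts table (one row per site x alternate allele x
#' sample on disk stored wide as \code{depth:ref:alt} triplets), the sample
#' sheet, and screened calls as TSV or VCFv4.2 (anchor-base InDels, INFO
#' fields ZYG and VARTYPE, per-sample GT/DP/VF).
#'
#' @param x object to write (see individual functions).
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @export
writeReferenceFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname io
#' @export
readReferenceFasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname io
#' @param genes gene-model \link[GenomicRanges]{GRanges}.
#' @export
writeGenesGff3 <- function(genes, path) {
  rtracklayer::export(genes, path, format = "gff3")
  invisible(path)
}

#' @rdname io
#' @export
readGenesGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- c("type", "gene_id", "phase")
  mc <- S4Vectors::mcols(gr)
  S4Vectors::mcols(gr) <- mc[, intersect(keep, colnames(mc)), drop = FALSE]
  gr$type <- as.character(gr$type)
  gr
}

#' @rdname io
#' @param truth truth mutation data.frame from a
#'   \linkS4class{SyntheticCohort}.
#' @export
writeTruth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readTruth <- function(path) {
  read.delim(path, colClasses = c(pos = "integer"))
}

#' @rdname io
#' @param sheet sample sheet data.frame.
#' @export
writeSampleSheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readSampleSheet <- function(path) {
  read.delim(path, colClasses = c(dose_gy = "numeric"))
}

#' @rdname io
#' @param counts long-format counts data.frame.
#' @export
writeSiteCounts <- function(counts, path) {
  samples <- unique(counts$sample_id)
  key <- .variantKey(counts$chrom, counts$pos, counts$ref, counts$alt_allele)
  ukey <- unique(key)
  si <- match(key, ukey); sj <- match(counts$sample_id, samples)
  cell <- matrix(NA_character_, length(ukey), length(samples),
                 dimnames = list(NULL, samples))
  cell[cbind(si, sj)] <- paste(counts$depth, counts$ref_reads,
                               counts$alt_reads, sep = ":")
  first <- !duplicated(key)
  out <- data.frame(chrom = counts$chrom[first], pos = counts$pos[first],
                    ref = counts$ref[first], alt = counts$alt_allele[first],
                    cell, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readSiteCounts <- function(path) {
  wide <- read.delim(path, check.names = FALSE,
                     colClasses = c(pos = "integer"))
  samples <- setdiff(names(wide), c("chrom", "pos", "ref", "alt"))
  nS <- nrow(wide)
  parts <- lapply(samples, function(s) {
    trip <- do.call(rbind, strsplit(wide[[s]], ":", fixed = TRUE))
    data.frame(chrom = wide$chrom, pos = wide$pos, ref = wide$ref,
               alt_allele = wide$alt, sample_id = rep(s, nS),
               depth = as.integer(trip[, 1]),
               ref_reads = as.integer(trip[, 2]),
               alt_reads = as.integer(trip[, 3]))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' @rdname io
#' @param calls calls data.frame.
#' @export
writeCallsTsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readCallsTsv <- function(path) {
  read.delim(path, colClasses = c(pos = "integer"))
}

#' Write screened calls as VCFv4.2
#'
#' One record per distinct variant with a genotype column for every cohort
#' sample: GT (0/1 heterozygous, 1/1 homozygous, 0/0 otherwise), DP (depth
#' in the calling sample) and VF (variant allele frequency). INFO carries
#' ZYG (zygosity of the carrying samples) and VARTYPE (SBS/DEL/INS).
#'
#' @param calls calls data.frame.
#' @param sheet sample sheet defining the cohort's sample columns.
#' @param path output path (plain \code{.vcf}).
#' @param genome optional \link[Biostrings]{DNAStringSet} supplying contig
#'   lengths for the header.
#' @return The path, invisibly.
#' @export
writeCallsVcf <- function(calls, sheet, path, genome = NULL) {
  samples <- sheet$sample_id
  key <- .variantKey(calls$chrom, calls$pos, calls$ref, calls$alt)
  o <- order(calls$chrom, calls$pos, calls$alt)
  calls <- calls[o, ]; key <- key[o]
  first <- !duplicated(key)
  vars <- calls[first, ]
  vi <- match(key, key[first])
  sj <- match(calls$sample_id, samples)
  n <- nrow(vars)
  gt <- matrix("0/0", n, length(samples), dimnames = list(NULL, samples))
  dp <- matrix(NA_integer_, n, length(samples), dimnames = list(NULL, samples))
  vf <- matrix(NA_real_, n, length(samples), dimnames = list(NULL, samples))
  gt[cbind(vi, sj)] <- ifelse(calls$zygosity == "homozygous", "1/1", "0/1")
  dp[cbind(vi, sj)] <- as.integer(calls$depth)
  vf[cbind(vi, sj)] <- round(calls$vaf, 4)
  zyg <- vapply(split(calls$zygosity, vi), function(z)
    paste(sort(unique(z)), collapse = ","), character(1))
  rr <- GenomicRanges::GRanges(
    vars$chrom, IRanges::IRanges(vars$pos, vars$pos + nchar(vars$ref) - 1L))
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(rr) <- names(genome)
    GenomeInfoDb::seqlengths(rr) <- Biostrings::width(genome)
  }
  names(rr) <- NULL
  hdr <- VariantAnnotation::VCFHeader(samples = samples)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    META = S4Vectors::DataFrame(Value = "VCFv4.2",
                                row.names = "fileformat"))
  VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1"), Type = c("String", "String"),
    Description = c("Zygosity of carrying samples", "Variant type"),
    row.names = c("ZYG", "VARTYPE"))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1", "1"), Type = c("String", "Integer", "Float"),
    Description = c("Genotype", "Read depth in calling sample",
                    "Variant allele frequency"),
    row.names = c("GT", "DP", "VF"))
  vcf <- VariantAnnotation::VCF(
    rowRanges = rr,
    colData = S4Vectors::DataFrame(Samples = seq_along(samples),
                                   row.names = samples),
    exptData = list(header = hdr),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(vars$ref),
      ALT = Biostrings::DNAStringSetList(as.list(vars$alt)),
      QUAL = rep(NA_real_, n), FILTER = rep("PASS", n)),
    info = S4Vectors::DataFrame(ZYG = unname(zyg),
                                VARTYPE = vars$var_type),
    geno = S4Vectors::SimpleList(GT = gt, DP = dp, VF = vf))
  VariantAnnotation::writeVcf(vcf, path)
  # htslib requires ##fileformat as the very first line
  lines <- readLines(path)
  lines <- lines[!grepl("^##fileformat", lines)]
  lines <- lines[!duplicated(lines) | !grepl("^##fileDate", lines)]
  writeLines(c("##fileformat=VCFv4.2", lines), path)
  invisible(path)
}

#' Read calls back from a VCF written by \code{\link{writeCallsVcf}}
#'
#' @param path VCF path.
#' @return Calls data.frame (sample_id, chrom, pos, ref, alt, depth, vaf,
#'   zygosity, var_type, indel_len).
#' @export
readCallsVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  dp <- VariantAnnotation::geno(vcf)$DP
  vf <- VariantAnnotation::geno(vcf)$VF
  hit <- which(gt == "0/1" | gt == "1/1", arr.ind = TRUE)
  ref <- as.character(rr$REF)
  alt <- vapply(rr$ALT, function(a) as.character(a)[1], character(1))
  vi <- hit[, 1]
  calls <- data.frame(
    sample_id = colnames(gt)[hit[, 2]],
    chrom = as.character(GenomeInfoDb::seqnames(rr))[vi],
    pos = BiocGenerics::start(rr)[vi],
    ref = ref[vi], alt = alt[vi],
    depth = dp[hit], vaf = vf[hit],
    zygosity = ifelse(gt[hit] == "1/1", "homozygous", "heterozygous"))
  vt <- classifyVariantType(calls$ref, calls$alt)
  calls$var_type <- vt$var_type
  calls$indel_len <- vt$indel_len
  rownames(calls) <- NULL
  calls
}
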