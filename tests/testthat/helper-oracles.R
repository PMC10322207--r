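# Independent brute-force re-implementations used as oracles, plus small
# fixture builders. These deliberately use plain loops and their own logic,
# not the package's vectorized code paths.

# ---- screening oracle -------------------------------------------------

# counts: long df (chrom, pos, ref, alt_allele, sample_id, depth, alt_reads)
# Applies criteria (1)-(3) within one detection group by exhaustive loops.
oracleScreenGroup <- function(counts, samples, cfg) {
  minVaf <- cfg@minFocalVaf; maxOther <- cfg@maxOtherVaf
  minDepth <- cfg@minCallableDepth
  out <- list()
  siteKey <- paste(counts$chrom, counts$pos)
  for (sk in unique(siteKey)) {
    siteRows <- counts[siteKey == sk, ]
    # criterion 1: every sample callable at the site
    ok <- TRUE
    for (s in samples) {
      d <- unique(siteRows$depth[siteRows$sample_id == s])
      if (length(d) == 0 || any(d < minDepth)) { ok <- FALSE; break }
    }
    if (!ok) next
    for (allele in unique(siteRows$alt_allele)) {
      rows <- siteRows[siteRows$alt_allele == allele, ]
      for (s in samples) {
        r <- rows[rows$sample_id == s, ]
        if (nrow(r) != 1 || r$depth == 0) next
        vaf <- r$alt_reads / r$depth
        if (vaf < minVaf) next
        others <- rows[rows$sample_id != s, ]
        if (any(others$alt_reads / pmax(others$depth, 1) >= maxOther)) next
        if (cfg@criterion2Mode == "interpreted") {
          nOther <- sum(others$alt_reads > 0)
          if (nOther > cfg@maxOtherVariantSamples) next
        } else {
          nRef <- sum(rows$alt_reads / pmax(rows$depth, 1) < maxOther)
          if (nRef > 1) next
        }
        out[[length(out) + 1]] <- data.frame(
          sample_id = s, chrom = r$chrom, pos = r$pos, ref = r$ref,
          alt = allele, vaf = vaf)
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), vaf = numeric(0)))
  res <- do.call(rbind, out)
  # one call per sample and site: highest VAF, then allele order
  res <- res[order(res$sample_id, res$chrom, res$pos, -res$vaf, res$alt), ]
  res <- res[!duplicated(res[, c("sample_id", "chrom", "pos")]), ]
  rownames(res) <- NULL
  res
}

callKeys <- function(df) {
  sort(paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt))
}

# Random multi-sample counts fixture with planted variants, including
# multi-allelic sites, shared variants and low-depth samples.
makeCountsFixture <- function(nSites = 50, nSamples = 13, seed = 1) {
  set.seed(seed)
  sites <- data.frame(chrom = "chr1",
                      pos = sort(sample(1e5, nSites)),
                      ref = sample(c("A", "C", "G", "T"), nSites, TRUE))
  rows <- list()
  samples <- sprintf("s%02d", seq_len(nSamples))
  for (i in seq_len(nSites)) {
    nAlt <- sample(1:2, 1, prob = c(0.85, 0.15))
    alts <- sample(setdiff(c("A", "C", "G", "T"), sites$ref[i]), nAlt)
    depth <- sample(c(0:3, 8:40), nSamples, TRUE,
                    prob = c(rep(0.008, 4), rep(0.968 / 33, 33)))
    for (a in alts) {
      alt <- integer(nSamples)
      scenario <- sample(c("none", "het", "hom", "shared", "noise"), 1,
                         prob = c(0.2, 0.3, 0.15, 0.2, 0.15))
      if (scenario == "het") {
        k <- sample(nSamples, 1)
        alt[k] <- rbinom(1, depth[k], 0.5)
      } else if (scenario == "hom") {
        k <- sample(nSamples, 1)
        alt[k] <- depth[k]
      } else if (scenario == "shared") {
        k <- sample(nSamples, sample(2:4, 1))
        alt[k] <- rbinom(length(k), depth[k], runif(1, 0.2, 0.9))
      } else if (scenario == "noise") {
        alt <- rbinom(nSamples, depth, 0.04)
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = "chr1", pos = sites$pos[i], ref = sites$ref[i],
        alt_allele = a, sample_id = samples,
        depth = depth, ref_reads = pmax(depth - alt, 0), alt_reads = alt)
    }
  }
  list(counts = do.call(rbind, rows), samples = samples)
}

# ---- annotation oracle ------------------------------------------------

# Whole-protein translation comparison: apply the substitution to the
# genome, re-extract and translate the full CDS, and classify by diffing
# the two proteins.
oracleCodingEffect <- function(call, geneId, genes, genome) {
  cds <- genes[genes$type == "CDS" & genes$gene_id == geneId]
  cds <- sort(cds)
  strand <- as.character(BiocGenerics::strand(cds))[1]
  chrom <- as.character(GenomeInfoDb::seqnames(cds))[1]
  chromSeq <- as.character(genome[[chrom]])
  mutSeq <- chromSeq
  substring(mutSeq, call$pos, call$pos) <- call$alt
  extract <- function(s) {
    pieces <- character(length(cds))
    for (i in seq_along(cds))
      pieces[i] <- substring(s, BiocGenerics::start(cds)[i],
                             BiocGenerics::end(cds)[i])
    x <- paste(pieces, collapse = "")
    if (strand == "-")
      x <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    x
  }
  refProt <- as.character(Biostrings::translate(
    Biostrings::DNAString(extract(chromSeq)), no.init.codon = TRUE))
  altProt <- as.character(Biostrings::translate(
    Biostrings::DNAString(extract(mutSeq)), no.init.codon = TRUE))
  n <- nchar(refProt)
  diffAt <- which(strsplit(refProt, "")[[1]] != strsplit(altProt, "")[[1]])
  if (!length(diffAt))
    return(list(effect = "synonymous"))
  i <- diffAt[1]
  ra <- substring(refProt, i, i); aa <- substring(altProt, i, i)
  effect <-
    if (i == 1 && ra == "M") "start_lost"
    else if (ra != "*" && aa == "*") "stop_gained"
    else if (ra == "*" && aa != "*") "stop_lost"
    else "missense"
  list(effect = effect, ref_aa = ra, alt_aa = aa)
}

# quick truth-vs-calls scoring of a cohort screen
scoreCalls <- function(calls, cohort) {
  tg <- cohortTruthGenotypes(cohort)
  truth <- unique(paste(tg$sample_id, tg$chrom, tg$pos, tg$ref,
                        tg$alt)[tg$genotype != "absent"])
  got <- paste(calls$sample_id, calls$chrom, calls$pos, calls$ref, calls$alt)
  list(recall = mean(truth %in% got), precision = mean(got %in% truth))
}
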