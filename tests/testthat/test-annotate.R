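# Hand-built toy genome with three genes whose coding content is known
# exactly, independent of the generator.
buildToyGenome <- function() {
  filler16 <- paste(rep("GCT", 16), collapse = "")
  cds1 <- paste0("ATG", "CCT", "GGC", "TGG", filler16, "TAA")  # 63 bp
  stopifnot(nchar(cds1) == 63)
  cds3 <- paste0("ATG", paste(rep("GAT", 31), collapse = ""), "TAA") # 99 bp
  chrom <- rep("C", 10000)
  put <- function(chrom, at, s) {
    chrom[at:(at + nchar(s) - 1)] <- strsplit(s, "")[[1]]
    chrom
  }
  chrom <- put(chrom, 101, cds1)                         # g1, + strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds1)))
  chrom <- put(chrom, 301, rc)                           # g2, - strand
  chrom <- put(chrom, 521, substring(cds3, 1, 40))       # g3 CDS piece 1
  chrom <- put(chrom, 621, substring(cds3, 41, 99))      # g3 CDS piece 2
  chrom <- put(chrom, 561, "GT")                         # donor
  chrom <- put(chrom, 619, "AG")                         # acceptor
  genome <- Biostrings::DNAStringSet(
    setNames(paste(chrom, collapse = ""), "chr1"))
  feat <- rbind(
    data.frame(type = "gene", s = 101, e = 163, strand = "+", gene = "g1",
               phase = NA),
    data.frame(type = "exon", s = 101, e = 163, strand = "+", gene = "g1",
               phase = NA),
    data.frame(type = "CDS", s = 101, e = 163, strand = "+", gene = "g1",
               phase = 0),
    data.frame(type = "gene", s = 301, e = 363, strand = "-", gene = "g2",
               phase = NA),
    data.frame(type = "exon", s = 301, e = 363, strand = "-", gene = "g2",
               phase = NA),
    data.frame(type = "CDS", s = 301, e = 363, strand = "-", gene = "g2",
               phase = 0),
    data.frame(type = "gene", s = 501, e = 686, strand = "+", gene = "g3",
               phase = NA),
    data.frame(type = "exon", s = 501, e = 560, strand = "+", gene = "g3",
               phase = NA),
    data.frame(type = "exon", s = 621, e = 686, strand = "+", gene = "g3",
               phase = NA),
    data.frame(type = "five_prime_UTR", s = 501, e = 520, strand = "+",
               gene = "g3", phase = NA),
    data.frame(type = "CDS", s = 521, e = 560, strand = "+", gene = "g3",
               phase = 0),
    data.frame(type = "CDS", s = 621, e = 679, strand = "+", gene = "g3",
               phase = 2),
    data.frame(type = "three_prime_UTR", s = 680, e = 686, strand = "+",
               gene = "g3", phase = NA))
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(feat$s, feat$e), strand = feat$strand,
    type = feat$type, gene_id = feat$gene, phase = feat$phase,
    seqinfo = GenomeInfoDb::Seqinfo("chr1", 10000L))
  list(genome = genome, genes = genes)
}

toy <- buildToyGenome()

toyCall <- function(pos, ref, alt, zyg = "heterozygous") {
  data.frame(sample_id = "l1", chrom = "chr1", pos = as.integer(pos),
             ref = ref, alt = alt, vaf = 0.5, zygosity = zyg)
}

test_that("the toy gene models are internally consistent", {
  for (id in c("g1", "g2", "g3")) {
    cds <- as.character(cdsSequence(toy$genome, toy$genes, id))
    expect_equal(substring(cds, 1, 3), "ATG")
    expect_equal(nchar(cds) %% 3, 0)
    expect_true(substring(cds, nchar(cds) - 2) %in% c("TAA", "TAG", "TGA"))
  }
})

test_that("impact classes follow the fixed effect table", {
  expect_equal(impactOf(c("stop_gained", "missense", "synonymous",
                          "frameshift", "inframe_indel", "noncoding",
                          "splice_disruptor", "stop_lost", "start_lost")),
               c("HIGH", "MODERATE", "LOW", "HIGH", "MODERATE", "MODIFIER",
                 "HIGH", "HIGH", "HIGH"))
  expect_error(impactOf("nonsense_label"), "unknown")
})

test_that("regions are assigned by precedence with a distance tie-break", {
  calls <- toyCall(c(110, 510, 681, 561, 590, 619, 450, 9000),
                   "C", "A")
  reg <- assignRegion(calls, toy$genes)
  expect_equal(reg$region,
               c("exon", "five_prime_UTR", "three_prime_UTR", "splice_site",
                 "intron", "splice_site", "upstream", "intergenic"))
  expect_equal(reg$gene_id[7], "g3")   # 51 bp to g3 beats 87 bp to g2
  expect_true(is.na(reg$gene_id[8]))
})

test_that("coding effects match hand-computed codon changes", {
  # codon 2 CCT -> TCT: proline to serine missense
  eff <- codingEffect(toyCall(104, "C", "T"), "g1", toy$genes, toy$genome)
  expect_equal(eff$effect, "missense")
  expect_equal(eff$ref_aa, "P"); expect_equal(eff$alt_aa, "S")
  # codon 3 wobble GGC -> GGT stays glycine
  eff <- codingEffect(toyCall(109, "C", "T"), "g1", toy$genes, toy$genome)
  expect_equal(eff$effect, "synonymous")
  expect_equal(eff$ref_aa, "G"); expect_equal(eff$alt_aa, "G")
  # codon 4 TGG -> TGA nonsense
  eff <- codingEffect(toyCall(112, "G", "A"), "g1", toy$genes, toy$genome)
  expect_equal(eff$effect, "stop_gained")
  # ATG start destroyed
  eff <- codingEffect(toyCall(101, "A", "G"), "g1", toy$genes, toy$genome)
  expect_equal(eff$effect, "start_lost")
  # stop codon TAA -> TCA read-through
  eff <- codingEffect(toyCall(162, "A", "C"), "g1", toy$genes, toy$genome)
  expect_equal(eff$effect, "stop_lost")
})

test_that("reverse-strand annotation equals the forward construct", {
  # g2 is the reverse complement of g1: the complementary substitution at
  # the mirrored position must give the identical amino-acid change
  mirror <- function(p) 363 - (p - 101)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cases <- list(c(104, "C", "T"), c(109, "C", "T"), c(112, "G", "A"),
                c(162, "A", "C"))
  for (cs in cases) {
    p <- as.integer(cs[1])
    fwd <- codingEffect(toyCall(p, cs[2], cs[3]), "g1", toy$genes, toy$genome)
    rev <- codingEffect(toyCall(mirror(p), comp[[cs[2]]], comp[[cs[3]]]),
                        "g2", toy$genes, toy$genome)
    expect_equal(rev, fwd)
  }
})

test_that("CDS InDels are frameshift exactly when length is not 3k", {
  chrom <- as.character(toy$genome[[1]])
  for (len in 1:38) {
    del <- toyCall(110, substring(chrom, 110, 110 + len), "C")
    del$ref <- substring(chrom, 110, 110 + len)
    del$alt <- substring(chrom, 110, 110)
    ins <- toyCall(110, substring(chrom, 110, 110),
                   paste0(substring(chrom, 110, 110),
                          paste(rep("A", len), collapse = "")))
    for (call in list(del, ins)) {
      eff <- codingEffect(call, "g1", toy$genes, toy$genome)
      expect_equal(eff$effect,
                   if (len %% 3 == 0) "inframe_indel" else "frameshift")
    }
  }
})

test_that("a 1-bp CDS deletion annotates as a HIGH-impact frameshift", {
  chrom <- as.character(toy$genome[[1]])
  call <- toyCall(110, substring(chrom, 110, 111), substring(chrom, 110, 110),
                  zyg = "homozygous")
  ann <- annotateCalls(call, toy$genes, toy$genome)
  expect_equal(ann$effect, "frameshift")
  expect_equal(ann$impact, "HIGH")
  expect_equal(ann$region, "exon")
  cand <- selectCandidates(ann)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$gene_id, "g1")
})

test_that("an InDel spanning the exon-intron boundary disrupts splicing", {
  chrom <- as.character(toy$genome[[1]])
  call <- toyCall(555, substring(chrom, 555, 565), substring(chrom, 555, 555))
  ann <- annotateCalls(call, toy$genes, toy$genome)
  expect_equal(ann$effect, "splice_disruptor")
  expect_equal(ann$impact, "HIGH")
})

test_that("effect labels agree with whole-protein translation brute force", {
  ref <- generateReference(GenomeSpec(1, 5e4, nGenes = 6, seed = 13))
  cds <- ref$genes[ref$genes$type == "CDS"]
  chrom <- as.character(ref$genome[[1]])
  set.seed(14)
  for (i in seq_len(1000)) {
    j <- sample(length(cds), 1)
    pos <- sample(BiocGenerics::start(cds)[j]:BiocGenerics::end(cds)[j], 1)
    refBase <- substring(chrom, pos, pos)
    altBase <- sample(setdiff(c("A", "C", "G", "T"), refBase), 1)
    id <- cds$gene_id[j]
    call <- toyCall(pos, refBase, altBase)
    mine <- codingEffect(call, id, ref$genes, ref$genome)
    orac <- oracleCodingEffect(call, id, ref$genes, ref$genome)
    expect_equal(mine$effect, orac$effect,
                 info = sprintf("pos %d %s>%s gene %s", pos, refBase,
                                altBase, id))
    if (mine$effect %in% c("missense", "stop_gained", "stop_lost")) {
      expect_equal(mine$ref_aa, orac$ref_aa)
      expect_equal(mine$alt_aa, orac$alt_aa)
    }
  }
})

test_that("uniformly placed mutations reproduce the region composition", {
  ref <- generateReference(GenomeSpec(1, 1e5, nGenes = 8, seed = 23))
  comp <- regionComposition(ref$genes, ref$genome)
  set.seed(24)
  pos <- sample(1e5, 10000, replace = TRUE)
  calls <- data.frame(sample_id = "l1", chrom = "chr1", pos = pos,
                      ref = "A", alt = "C")
  reg <- assignRegion(calls, ref$genes)
  obs <- table(factor(reg$region, names(comp)))
  keep <- comp > 0
  p <- suppressWarnings(
    chisq.test(obs[keep], p = comp[keep] / sum(comp))$p.value)
  expect_gt(p, 0.01)
})

test_that("amino-acid change matrix counts distinct ordered pairs", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pairs <- expand.grid(from = aa, to = aa, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  fabricate <- function(k) {
    data.frame(effect = "missense", ref_aa = pairs$from[seq_len(k)],
               alt_aa = pairs$to[seq_len(k)])
  }
  m131 <- aaChangeMatrix(fabricate(131))
  expect_equal(m131$n_distinct, 131)
  expect_equal(m131$coverage, 131 / 380)
  expect_equal(round(100 * m131$coverage, 1), 34.5)
  m36 <- aaChangeMatrix(fabricate(36))
  expect_equal(round(100 * m36$coverage, 1), 9.5)
  empty <- aaChangeMatrix(data.frame(effect = character(0),
                                     ref_aa = character(0),
                                     alt_aa = character(0)))
  expect_equal(sum(empty$counts), 0)
  expect_equal(empty$coverage, 0)
  expect_true(all(diag(m131$counts) == 0))
  expect_equal(sum(m131$frequencies), 1)
})

test_that("candidate genes require homozygosity and HIGH/MODERATE impact", {
  ann <- data.frame(
    sample_id = c("l1", "l1", "l1", "l2"),
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L), ref = "A", alt = "T",
    gene_id = c("gX", "gY", "gZ", "gX"),
    effect = c("frameshift", "stop_gained", "synonymous", "missense"),
    impact = c("HIGH", "HIGH", "LOW", "MODERATE"),
    zygosity = c("homozygous", "heterozygous", "homozygous", "homozygous"))
  cand <- selectCandidates(ann)
  expect_equal(nrow(cand), 2)
  expect_setequal(paste(cand$line_id, cand$gene_id), c("l1 gX", "l2 gX"))
})

test_that("affected genes are counted once per line and gene", {
  ann <- data.frame(sample_id = c("l1", "l1", "l1", "l2"),
                    gene_id = c("gX", "gX", "gY", NA))
  out <- affectedGenes(ann)
  expect_equal(out$n_affected_genes[out$sample_id == "l1"], 2)
  expect_false("l2" %in% out$sample_id)
})
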