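refFix <- generateReference(GenomeSpec(1, 1e5, nGenes = 10, seed = 1))

test_that("induction curve rises to a plateau calibrated near reported loads", {
  m <- InductionModel()
  expect_equal(inductionMean(0, m), 0)
  d <- seq(0, 300, 5)
  expect_true(all(diff(inductionMean(d, m)) >= 0))
  # anchors: 105.23/line at 100 Gy, 98.17 at 150 Gy with plateau behavior
  expect_lt(abs(inductionMean(100, m) - 105.23) / 105.23, 0.1)
  expect_lte(inductionMean(150, m), 1.05 * inductionMean(100, m))
  expect_error(inductionMean(-5, m), "dose")
})

test_that("mutation counts are Poisson draws with dose-dependent mean", {
  expect_identical(drawMutationCount(0, n = 100), rep(0L, 100))
  set.seed(42)
  x <- drawMutationCount(100, n = 2000)
  m <- inductionMean(100, InductionModel())
  expect_lt(abs(mean(x) - m) / m, 0.05)
  expect_lt(abs(var(x) / mean(x) - 1), 0.15)   # Poisson dispersion
  expect_error(drawMutationCount(-1), "dose")
})

test_that("placed mutations reproduce the configured type and size spectrum", {
  set.seed(7)
  mut <- placeMutations(10000, refFix$genome, InductionModel())
  expect_equal(nrow(mut), 10000)
  # SBS fraction close to the >70% reported share
  expect_lt(abs(mean(mut$var_type == "SBS") - 0.72), 0.02)
  del <- mut[mut$var_type == "DEL", ]
  ins <- mut[mut$var_type == "INS", ]
  expect_lt(abs(mean(del$indel_len == 1) - 0.4516), 0.03)
  expect_true(all(del$indel_len <= 38))
  expect_true(all(ins$indel_len <= 17))
  # chi-square goodness of fit of the six SBS classes
  sbs <- mut[mut$var_type == "SBS", ]
  tab <- table(factor(sbs$sbs_class, levels = names(InductionModel()@sbsClassProbs)))
  p <- chisq.test(tab, p = InductionModel()@sbsClassProbs)$p.value
  expect_gt(p, 0.01)
})

test_that("placed mutations are anchored on the reference sequence", {
  set.seed(8)
  mut <- placeMutations(500, refFix$genome, InductionModel())
  chrom <- as.character(refFix$genome[[1]])
  expect_identical(substring(chrom, mut$pos, mut$pos + nchar(mut$ref) - 1L),
                   mut$ref)
  expect_false(any(duplicated(paste(mut$chrom, mut$pos))))
  del <- mut$var_type == "DEL"; ins <- mut$var_type == "INS"
  expect_identical(mut$alt[del], substring(mut$ref[del], 1, 1))
  expect_identical(substring(mut$alt[ins], 1, 1), mut$ref[ins])
})

test_that("degenerate type vector yields only substitutions", {
  m <- InductionModel(typeProbs = c(SBS = 1, DEL = 0, INS = 0))
  set.seed(1)
  mut <- placeMutations(200, refFix$genome, m)
  expect_true(all(mut$var_type == "SBS"))
  expect_true(all(mut$indel_len == 0))
})

test_that("lineage assignment follows the sharing model", {
  set.seed(5)
  mut <- placeMutations(10000, refFix$genome, InductionModel())
  lm <- LineageModel()
  withSets <- assignLineage(mut, lm)
  expect_equal(lengths(strsplit(withSets$panicle_set, ",")),
               unname(c(unique = 1L, shared2 = 2L,
                        shared3 = 3L)[withSets$sharing]))
  # realized shared-by-3 fraction near the normalized 0.079
  expect_lt(abs(mean(withSets$sharing == "shared3") - 0.079), 0.008)
  tab <- table(factor(withSets$sharing, c("unique", "shared2", "shared3")))
  expect_gt(chisq.test(tab, p = lm@sharingProbs)$p.value, 0.01)
  # degenerate: everything unique
  allU <- assignLineage(mut, LineageModel(
    sharingProbs = c(unique = 1, shared2 = 0, shared3 = 0)))
  expect_true(all(allU$sharing == "unique"))
  # two-panicle plants cannot share by three
  two <- assignLineage(mut, lm, nPanicles = 2)
  expect_true(all(two$sharing %in% c("unique", "shared2")))
  expect_error(LineageModel(paniclesPerPlant = 2,
                            sharingProbs = c(unique = 0.7, shared2 = 0.2,
                                             shared3 = 0.1)),
               "shared3")
})

test_that("M2 segregation is exactly Mendelian with 2:1 het:hom carriers", {
  set.seed(9)
  g <- segregateToM2(40000)
  tab <- table(factor(g, c("absent", "heterozygous", "homozygous")))
  expect_gt(chisq.test(tab, p = c(0.25, 0.5, 0.25))$p.value, 0.01)
  carriers <- g[g != "absent"]
  ratio <- sum(carriers == "heterozygous") / sum(carriers == "homozygous")
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("read counts follow the genotype-conditional binomial model", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                      ref = "A", alt = "T")
  sheet <- data.frame(sample_id = c("m1", "ctrl1"),
                      role = c("mutant", "control"),
                      dose_gy = c(100, 0), plant_id = c("p1", NA),
                      panicle_id = c(1L, NA))
  geno <- data.frame(sample_id = "m1", chrom = "chr1",
                     pos = c(100L, 200L), ref = "A", alt = "T",
                     genotype = c("homozygous", "heterozygous"))
  noErr <- SequencingModel(meanDepth = 30, perBaseErrorRate = 0)
  set.seed(2)
  cnt <- emitReadCounts(sites, geno, sheet, noErr)
  hom <- cnt[cnt$sample_id == "m1" & cnt$pos == 100, ]
  expect_equal(hom$alt_reads, hom$depth)
  ctrl <- cnt[cnt$sample_id == "ctrl1", ]
  expect_true(all(ctrl$alt_reads == 0))
  absent <- cnt[cnt$sample_id == "m1" & cnt$pos == 300, ]
  expect_true(all(absent$alt_reads == 0))
  # heterozygous mean alt fraction ~ 0.5
  set.seed(3)
  many <- do.call(rbind, lapply(1:400, function(i) {
    x <- emitReadCounts(sites[2, ], geno[2, ], sheet[1, , drop = FALSE], noErr)
    x[x$depth > 0, ]
  }))
  vaf <- many$alt_reads / many$depth
  expect_lt(abs(mean(vaf) - 0.5), 3 * sd(vaf) / sqrt(length(vaf)) + 0.01)
  expect_error(SequencingModel(meanDepth = 0), "meanDepth")
})

test_that("cohort simulation is deterministic and truth round-trips", {
  c1 <- simulateCohort(GenomeSpec(1, 1e5, nGenes = 10),
                       doses = c(50, 100), plantsPerDose = 2, seed = 21)
  c2 <- simulateCohort(GenomeSpec(1, 1e5, nGenes = 10),
                       doses = c(50, 100), plantsPerDose = 2, seed = 21)
  expect_identical(cohortTruth(c1), cohortTruth(c2))
  expect_identical(cohortCounts(c1), cohortCounts(c2))
  expect_identical(as.character(cohortGenome(c1)),
                   as.character(cohortGenome(c2)))
  p <- tempfile(fileext = ".tsv")
  writeTruth(cohortTruth(c1), p)
  back <- readTruth(p)
  expect_equal(back, cohortTruth(c1))
  # counts writer/reader round trip
  pc <- tempfile(fileext = ".tsv")
  writeSiteCounts(cohortCounts(c1), pc)
  cc <- readSiteCounts(pc)
  ord <- function(x) {
    x <- x[order(x$chrom, x$pos, x$alt_allele, x$sample_id), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(cc), ord(cohortCounts(c1)))
})
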