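# one site, 13 samples, configurable focal/background alt reads
siteFixture <- function(focalAlt, otherAlt = 0, depth = 30, nSamples = 13,
                        ref = "G", alt = "A") {
  samples <- sprintf("s%02d", seq_len(nSamples))
  altReads <- c(focalAlt, rep(otherAlt, nSamples - 1))
  data.frame(chrom = "chr1", pos = 1000L, ref = ref, alt_allele = alt,
             sample_id = samples, depth = depth,
             ref_reads = depth - altReads, alt_reads = altReads)
}

test_that("VAF is alt reads over depth, undefined at zero depth", {
  expect_equal(computeVaf(12, 30), 0.4)
  expect_equal(computeVaf(0, 30), 0)
  expect_equal(computeVaf(30, 30), 1)
  expect_true(is.na(computeVaf(0, 0)))
  expect_error(computeVaf(31, 30), "altReads")
})

test_that("uncallable samples are counted against the depth threshold", {
  expect_equal(countUncallable(rep(30, 13)), 0)
  expect_equal(countUncallable(c(3, rep(30, 12))), 1)
  expect_equal(countUncallable(rep(1, 5), ScreenConfig(minCallableDepth = 1)), 0)
})

test_that("screening applies the focal and background VAF criteria", {
  cfg <- ScreenConfig()
  # focal VAF 0.40, all others clean -> one heterozygous call
  calls <- screenGroup(siteFixture(12), config = cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$sample_id, "s01")
  expect_equal(calls$vaf, 0.4)
  expect_equal(calls$zygosity, "heterozygous")
  # focal VAF 0.25 fails the >= 30% rule
  expect_equal(nrow(screenGroup(siteFixture(7, depth = 28), config = cfg)), 0)
  # another sample at VAF 0.15 fails the < 10% background rule
  cnt <- siteFixture(12)
  cnt$alt_reads[2] <- 5; cnt$ref_reads[2] <- 25
  expect_equal(nrow(screenGroup(cnt, config = cfg)), 0)
  # an uncallable sample suppresses the whole site
  cnt2 <- siteFixture(12)
  cnt2$depth[13] <- 3; cnt2$ref_reads[13] <- 3
  expect_equal(nrow(screenGroup(cnt2, config = cfg)), 0)
})

test_that("interpreted criterion 2 caps other samples showing the allele", {
  cfg <- ScreenConfig()
  cnt <- siteFixture(12)
  cnt$alt_reads[2] <- 1   # one other sample with a stray read: allowed
  calls <- screenGroup(cnt, config = cfg)
  expect_equal(nrow(calls), 1)
  cnt$alt_reads[3] <- 1   # two other samples: rejected
  expect_equal(nrow(screenGroup(cnt, config = cfg)), 0)
  # literal mode applies "Samples Ref <= 1" verbatim and rejects a
  # sample-unique variant (12 reference samples remain)
  lit <- ScreenConfig(criterion2Mode = "literal")
  expect_equal(nrow(screenGroup(siteFixture(12), config = lit)), 0)
})

test_that("zygosity threshold is inclusive at 75%", {
  expect_equal(classifyZygosity(0.80), "homozygous")
  expect_equal(classifyZygosity(0.40), "heterozygous")
  expect_equal(classifyZygosity(0.75), "homozygous")
  expect_error(classifyZygosity(0.2), "minFocalVaf")
})

test_that("homozygous calls come out of screening at high VAF", {
  calls <- screenGroup(siteFixture(30), config = ScreenConfig())
  expect_equal(calls$zygosity, "homozygous")
  expect_equal(calls$vaf, 1)
})

test_that("variant types follow the anchor-base convention", {
  vt <- classifyVariantType(c("G", "GAT", "G"), c("A", "G", "GTTTT"))
  expect_equal(vt$var_type, c("SBS", "DEL", "INS"))
  expect_equal(vt$indel_len, c(0L, 2L, 4L))
  expect_error(classifyVariantType("AT", "GC"), "MNP")
  expect_error(classifyVariantType("A", "A"), "differ")
})

test_that("parental variants are removed wherever they were called", {
  sheet <- data.frame(sample_id = c("m1", "m2", "ctrl1"),
                      role = c("mutant", "mutant", "control"),
                      dose_gy = c(100, 100, 0),
                      plant_id = c("p1", "p2", NA),
                      panicle_id = c(1L, 1L, NA))
  calls <- data.frame(sample_id = c("m1", "m2"), chrom = "chr1",
                      pos = c(10L, 20L), ref = "A", alt = "T",
                      vaf = 0.5, zygosity = "heterozygous")
  mkCounts <- function(ctrlAlt10) {
    data.frame(chrom = "chr1", pos = rep(c(10L, 20L), each = 3), ref = "A",
               alt_allele = "T",
               sample_id = rep(c("m1", "m2", "ctrl1"), 2),
               depth = 30,
               ref_reads = 30 - c(15, 0, ctrlAlt10, 0, 15, 0),
               alt_reads = c(15, 0, ctrlAlt10, 0, 15, 0))
  }
  # control carries pos 10 at VAF 0.5 -> dropped everywhere
  out <- removeParental(calls, mkCounts(15), sheet)
  expect_equal(out$pos, 20L)
  # a single control error read (VAF 0.03) does not drop the variant
  out2 <- removeParental(calls, mkCounts(1), sheet)
  expect_equal(nrow(out2), 2)
  # without controls: warning and pass-through
  noCtrl <- sheet[sheet$role == "mutant", ]
  expect_warning(out3 <- removeParental(calls, mkCounts(15), noCtrl),
                 "control")
  expect_equal(nrow(out3), 2)
})

test_that("cross-plant shared variants are removed, same-plant kept", {
  sheet <- data.frame(sample_id = c("a1", "a2", "b1"),
                      role = "mutant", dose_gy = 100,
                      plant_id = c("p7", "p7", "p9"),
                      panicle_id = c(1L, 2L, 1L))
  calls <- data.frame(
    sample_id = c("a1", "a2",   # same plant, two panicles -> kept
                  "a1", "b1",   # two plants -> dropped from both
                  "b1"),        # single panicle -> kept
    chrom = "chr1", pos = c(5L, 5L, 9L, 9L, 30L), ref = "C", alt = "G")
  out <- removeCrossPlantShared(calls, sheet)
  expect_setequal(paste(out$sample_id, out$pos),
                  c("a1 5", "a2 5", "b1 30"))
})

test_that("screening matches a brute-force oracle on random tables", {
  for (seed in c(2, 3)) {
    fx <- makeCountsFixture(nSites = 60, nSamples = 13, seed = seed)
    for (mode in c("interpreted", "literal")) {
      cfg <- ScreenConfig(criterion2Mode = mode)
      mine <- screenGroup(fx$counts, fx$samples, cfg)
      oracle <- oracleScreenGroup(fx$counts, fx$samples, cfg)
      expect_identical(callKeys(mine), callKeys(oracle))
    }
  }
})

test_that("screening thresholds act monotonically", {
  fx <- makeCountsFixture(nSites = 80, nSamples = 10, seed = 4)
  base <- screenGroup(fx$counts, fx$samples, ScreenConfig())
  stricterFocal <- screenGroup(fx$counts, fx$samples,
                               ScreenConfig(minFocalVaf = 0.4))
  expect_true(all(callKeys(stricterFocal) %in% callKeys(base)))
  stricterOther <- screenGroup(fx$counts, fx$samples,
                               ScreenConfig(maxOtherVaf = 0.05))
  expect_true(all(callKeys(stricterOther) %in% callKeys(base)))
})

test_that("screening already-screened evidence changes nothing", {
  fx <- makeCountsFixture(nSites = 60, nSamples = 13, seed = 6)
  cfg <- ScreenConfig()
  calls <- screenGroup(fx$counts, fx$samples, cfg)
  calledSites <- unique(paste(calls$chrom, calls$pos))
  sub <- fx$counts[paste(fx$counts$chrom, fx$counts$pos) %in% calledSites, ]
  again <- screenGroup(sub, fx$samples, cfg)
  expect_identical(callKeys(again), callKeys(calls))
})

test_that("multi-allelic sites yield one call per sample with allele tie-break", {
  samples <- sprintf("s%02d", 1:13)
  mk <- function(alt, reads) {
    data.frame(chrom = "chr1", pos = 500L, ref = "G", alt_allele = alt,
               sample_id = samples, depth = 30,
               ref_reads = 30 - reads, alt_reads = reads)
  }
  cnt <- rbind(mk("A", c(12, rep(0, 12))), mk("T", c(12, rep(0, 12))))
  calls <- screenGroup(cnt, samples, ScreenConfig())
  expect_equal(nrow(calls), 1)
  expect_equal(calls$alt, "A")   # lexicographic tie-break
  cnt2 <- rbind(mk("A", c(12, rep(0, 12))), mk("T", c(15, rep(0, 12))))
  expect_equal(screenGroup(cnt2, samples, ScreenConfig())$alt, "T")
})

test_that("cohort screening rejects unknown samples", {
  coh <- simulateCohort(GenomeSpec(1, 5e4, nGenes = 5),
                        doses = 100, plantsPerDose = 1, seed = 1)
  cnt <- cohortCounts(coh)
  cnt$sample_id[1] <- "ghost"
  expect_error(screenCohort(cnt, cohortSheet(coh)), "absent")
})
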