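#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> screen -> spectrum -> lineage -> annotate ->
#' dose-response and writes every stage product plus a consolidated JSON
#' report to \code{outdir}. All randomness derives from \code{seed}; two
#' runs with the same configuration and seed produce identical outputs.
#' Each stage can be skipped, and a pre-computed call set can be supplied
#' (e.g. the truth calls) to run the downstream stages on it.
#'
#' @param outdir output directory (created if missing).
#' @param seed integer seed for the whole run.
#' @param genomeSpec a \linkS4class{GenomeSpec}.
#' @param induction an \linkS4class{InductionModel}.
#' @param lineage a \linkS4class{LineageModel}.
#' @param sequencing a \linkS4class{SequencingModel}.
#' @param screenConfig a \linkS4class{ScreenConfig}.
#' @param doses dose grid (Gy).
#' @param plantsPerDose M1 plants per dose.
#' @param nControls control samples.
#' @param window annotation up/downstream window (bp).
#' @param doseResponse optional data.frame (dose_gy, response) for the SHMT
#'   stage; omitted when NULL.
#' @param stages character vector of stages to run, a subset of
#'   \code{c("screen", "spectrum", "lineage", "annotate", "doseresponse")}.
#' @param calls optional externally supplied calls data.frame; when given,
#'   the screen stage is skipped and downstream stages use it.
#' @return Invisibly, a list with the cohort, calls and the report list.
#' @examples
#' \donttest{
#' res <- runPipeline(tempfile("run"), seed = 42,
#'                    genomeSpec = GenomeSpec(1, 2e5, nGenes = 20),
#'                    doses = c(50, 100), plantsPerDose = 2)
#' names(res$report)
#' }
#' @export
runPipeline <- function(outdir, seed = 1,
                        genomeSpec = GenomeSpec(),
                        induction = InductionModel(),
                        lineage = LineageModel(),
                        sequencing = SequencingModel(),
                        screenConfig = ScreenConfig(),
                        doses = c(25, 50, 75, 100, 125, 150),
                        plantsPerDose = 10, nControls = 3,
                        window = 5000, doseResponse = NULL,
                        stages = c("screen", "spectrum", "lineage",
                                   "annotate", "doseresponse"),
                        calls = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("##IonMut=%s seed=%d", packageVersion("IonMut"), seed)
  logLines <- c(stamp)
  report <- list(seed = seed, package_version = as.character(
    packageVersion("IonMut")))
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  coh <- runStage("simulate",
    simulateCohort(genomeSpec, induction, lineage, sequencing,
                   doses = doses, plantsPerDose = plantsPerDose,
                   nControls = nControls, seed = seed))
  writeReferenceFasta(cohortGenome(coh), file.path(outdir, "reference.fa"))
  writeGenesGff3(cohortGenes(coh), file.path(outdir, "genes.gff3"))
  writeTruth(cohortTruth(coh), file.path(outdir, "truth.tsv"))
  writeSampleSheet(cohortSheet(coh), file.path(outdir, "samples.tsv"))
  writeSiteCounts(cohortCounts(coh), file.path(outdir, "site_counts.tsv"))
  genomeLen <- sum(Biostrings::width(cohortGenome(coh)))
  report$genome_length_bp <- genomeLen
  report$n_truth_mutations <- nrow(cohortTruth(coh))

  if (is.null(calls) && "screen" %in% stages)
    calls <- runStage("screen",
      screenCohort(cohortCounts(coh), cohortSheet(coh), screenConfig))
  if (!is.null(calls)) {
    writeCallsTsv(calls, file.path(outdir, "calls.tsv"))
    writeCallsVcf(calls, cohortSheet(coh), file.path(outdir, "calls.vcf"),
                  genome = cohortGenome(coh))
    report$n_calls <- nrow(calls)
  }

  if (!is.null(calls) && "spectrum" %in% stages) {
    spec <- runStage("spectrum", spectrumSummary(calls))
    perDose <- runStage("spectrum",
      perDoseSummary(calls, cohortSheet(coh), genomeLen))
    write.table(perDose, file.path(outdir, "per_dose_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$spectrum <- spec
    report$per_dose <- perDose
  }

  if (!is.null(calls) && "lineage" %in% stages) {
    parts <- runStage("lineage",
      partitionMutations(calls, cohortSheet(coh), cohortGenome(coh)))
    shares <- runStage("lineage", aggregateSharing(parts))
    write.table(parts, file.path(outdir, "sharing_partitions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(shares, file.path(outdir, "sharing_rates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$sharing <- shares
  }

  if (!is.null(calls) && "annotate" %in% stages) {
    ann <- runStage("annotate",
      annotateCalls(calls, cohortGenes(coh), cohortGenome(coh), window))
    write.table(ann, file.path(outdir, "annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    aam <- aaChangeMatrix(ann)
    write.table(aam$counts, file.path(outdir, "aa_change_matrix.tsv"),
                sep = "\t", quote = FALSE)
    cand <- selectCandidates(ann)
    write.table(cand, file.path(outdir, "candidate_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$region_tally <- as.list(table(ann$region))
    report$impact_tally <- as.list(table(ann$impact))
    report$aa_variants_distinct <- aam$n_distinct
    report$aa_coverage <- aam$coverage
    report$n_candidate_genes <- nrow(cand)
    report$affected_genes <- affectedGenes(ann)
  }

  if (!is.null(doseResponse) && "doseresponse" %in% stages) {
    fit <- runStage("doseresponse", fitShmt(doseResponse))
    report$shmt <- list(D0 = fitD0(fit), N = fitN(fit), Dq = fitDq(fit),
                        LD50 = fitLD50(fit), rss = fitRSS(fit))
    pred <- data.frame(dose_gy = seq(0, max(doseResponse$dose_gy),
                                     length.out = 101))
    pred$response <- shmtSurvival(pred$dose_gy, fitD0(fit), fitN(fit))
    write.table(pred, file.path(outdir, "shmt_curve.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  writeLines(c(logLines, "##stages complete"),
             file.path(outdir, "pipeline.log"))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(list(cohort = coh, calls = calls, report = report))
}
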