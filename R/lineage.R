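#' Normalize InDel representation by left alignment
#'
#' Trims shared suffixes (then re-extends the anchor from the reference)
#' and shifts anchor-base InDels left while the shifted representation is
#' consistent with the genome, so that equivalent InDel descriptions at
#' repeat stretches compare equal. SBS calls are returned unchanged.
#'
#' @param chrom,pos,ref,alt parallel vectors describing variants.
#' @param genome optional \link[Biostrings]{DNAStringSet}; without it only
#'   suffix trimming is performed.
#' @return data.frame with normalized chrom, pos, ref, alt.
#' @export
leftAlignVariants <- function(chrom, pos, ref, alt, genome = NULL) {
  chromStr <- if (!is.null(genome)) as.character(genome) else NULL
  pos <- as.integer(pos)
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    if (nchar(r) == nchar(a)) next
    repeat {
      # drop a shared last base; re-extend from the genome if an allele
      # would become empty (this is the leftward shift)
      if (nchar(r) > 0 && nchar(a) > 0 &&
          substring(r, nchar(r)) == substring(a, nchar(a))) {
        if (min(nchar(r), nchar(a)) == 1L) {
          if (is.null(chromStr) || p <= 1L) break
          prev <- substring(chromStr[[chrom[i]]], p - 1L, p - 1L)
          r <- paste0(prev, substring(r, 1, nchar(r) - 1L))
          a <- paste0(prev, substring(a, 1, nchar(a) - 1L))
          p <- p - 1L
        } else {
          r <- substring(r, 1, nchar(r) - 1L)
          a <- substring(a, 1, nchar(a) - 1L)
        }
      } else if (nchar(r) > 1 && nchar(a) > 1 &&
                 substring(r, 1, 1) == substring(a, 1, 1)) {
        r <- substring(r, 2); a <- substring(a, 2); p <- p + 1L
      } else break
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Partition each plant's mutations by panicle multiplicity
#'
#' Distinct mutations within an M1 plant are classified by how many of its
#' sequenced panicles carry them: unique (one panicle), shared2 (two) or
#' shared3 (all three). Plants without any mutation are flagged undefined
#' and excluded from rate averaging.
#'
#' @param calls calls data.frame (sample_id, chrom, pos, ref, alt).
#' @param sheet sample sheet mapping samples to (plant_id, panicle_id);
#'   two samples on the same (plant, panicle) are an error.
#' @param genome optional genome for InDel left alignment before matching.
#' @return data.frame with one row per plant: plant_id, dose_gy,
#'   n_panicles, counts and rates per category, and \code{defined}.
#' @export
partitionMutations <- function(calls, sheet, genome = NULL) {
  mut <- sheet[sheet$role == "mutant", ]
  if (anyDuplicated(mut[, c("plant_id", "panicle_id")]))
    stop("two samples map to the same (plant, panicle)")
  calls <- calls[calls$sample_id %in% mut$sample_id, ]
  norm <- leftAlignVariants(calls$chrom, calls$pos, calls$ref, calls$alt,
                            genome)
  key <- .variantKey(norm$chrom, norm$pos, norm$ref, norm$alt)
  idx <- match(calls$sample_id, mut$sample_id)
  plant <- mut$plant_id[idx]
  panicle <- mut$panicle_id[idx]
  plants <- unique(mut$plant_id)
  rows <- lapply(plants, function(pl) {
    nPan <- length(unique(mut$panicle_id[mut$plant_id == pl]))
    sel <- plant == pl
    mult <- vapply(split(panicle[sel], key[sel]),
                   function(p) length(unique(p)), integer(1))
    counts <- c(unique = sum(mult == 1L), shared2 = sum(mult == 2L),
                shared3 = sum(mult >= 3L))
    tot <- sum(counts)
    dose <- mut$dose_gy[mut$plant_id == pl][1]
    data.frame(plant_id = pl, dose_gy = dose, n_panicles = nPan,
               n_mutations = tot,
               n_unique = counts[["unique"]], n_shared2 = counts[["shared2"]],
               n_shared3 = counts[["shared3"]],
               rate_unique = if (tot) counts[["unique"]] / tot else NA_real_,
               rate_shared2 = if (tot) counts[["shared2"]] / tot else NA_real_,
               rate_shared3 = if (tot) counts[["shared3"]] / tot else NA_real_,
               defined = tot > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate sharing partitions to dose level and overall
#'
#' Reports both the unweighted mean of per-plant rates (each plant counts
#' equally) and pooled-count rates (mutations pooled before dividing), per
#' dose and overall. Undefined partitions (plants without mutations) are
#' excluded.
#'
#' @param partitions output of \code{\link{partitionMutations}}.
#' @return data.frame with one row per dose plus an "overall" row; columns
#'   \code{mean_*} are per-plant averages, \code{pooled_*} pooled rates.
#' @export
aggregateSharing <- function(partitions) {
  def <- partitions[partitions$defined, ]
  if (!nrow(def)) stop("no defined sharing partitions")
  agg <- function(df, label) {
    data.frame(scope = label, n_plants = nrow(df),
               mean_unique = mean(df$rate_unique),
               mean_shared2 = mean(df$rate_shared2),
               mean_shared3 = mean(df$rate_shared3),
               pooled_unique = sum(df$n_unique) / sum(df$n_mutations),
               pooled_shared2 = sum(df$n_shared2) / sum(df$n_mutations),
               pooled_shared3 = sum(df$n_shared3) / sum(df$n_mutations))
  }
  perDose <- lapply(split(def, def$dose_gy), function(df)
    agg(df, as.character(df$dose_gy[1])))
  out <- rbind(do.call(rbind, perDose), agg(def, "overall"))
  rownames(out) <- NULL
  out
}
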