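# Coverage-based screens: genes deleted from the X haplotype, and Y copies
# that are deleted versus merely silenced.

#' Per-transcript genomic coverage profiles
#'
#' Mean depth and fraction of positions covered, per sex, from genomic
#' alignments.
#'
#' @param alignments alignment data.table (carries `sex`).
#' @param targets [transcript_set()].
#' @return data.table: `transcript_id`, `mean_depth_m`, `frac_covered_m`,
#'   `mean_depth_f`, `frac_covered_f`.
#' @export
coverage_profile <- function(alignments, targets) {
  lens <- setNames(nchar(targets$bases), targets$id)
  out <- data.table(transcript_id = targets$id,
                    mean_depth_m = 0, frac_covered_m = 0,
                    mean_depth_f = 0, frac_covered_f = 0)
  if (nrow(alignments) == 0L) return(out)
  al <- data.table(target_id = alignments$target_id,
                   start = alignments$target_start,
                   end = alignments$target_end,
                   sex = alignments$sex)
  prof <- al[, {
    L <- lens[[.BY[[1]]]]
    res <- lapply(c("male", "female"), function(sx) {
      s <- start[sex == sx]; e <- end[sex == sx]
      if (length(s) == 0L) return(c(0, 0))
      cov <- cumsum(tabulate(s + 1L, nbins = L + 1L) -
                      tabulate(e + 1L, nbins = L + 1L))[seq_len(L)]
      c(sum(cov) / L, mean(cov > 0L))
    })
    .(mean_depth_m = res[[1]][1], frac_covered_m = res[[1]][2],
      mean_depth_f = res[[2]][1], frac_covered_f = res[[2]][2])
  }, by = target_id]
  setnames(prof, "target_id", "transcript_id")
  out <- merge(out[, .(transcript_id)], prof, by = "transcript_id",
               all.x = TRUE)
  for (j in names(out)[-1]) set(out, which(is.na(out[[j]])), j, 0)
  out[]
}

#' Screen for genes deleted from the X haplotype
#'
#' A male transcript is a deletion candidate iff its female genomic read
#' coverage is exactly zero (the gene is absent from the female genome) and
#' male genomic reads show no polymorphic site (a single haplotype present).
#' Both clauses are reported separately.
#'
#' @param profiles [coverage_profile()] over male transcripts (female
#'   alignments included).
#' @param n_polymorphic_sites_male named integer vector (or data.table with
#'   `transcript_id`, `n_polymorphic_sites_male`): per-transcript count of
#'   male-polymorphic sites.
#' @return data.table: `transcript_id`, `zero_female_coverage`,
#'   `male_monomorphic`, `candidate`.
#' @export
neoX_deletion_screen <- function(profiles, n_polymorphic_sites_male) {
  if (is.data.frame(n_polymorphic_sites_male)) {
    np <- setNames(n_polymorphic_sites_male$n_polymorphic_sites_male,
                   n_polymorphic_sites_male$transcript_id)
  } else {
    np <- n_polymorphic_sites_male
  }
  out <- data.table(
    transcript_id = profiles$transcript_id,
    n_polymorphic_sites_male =
      as.integer(ifelse(is.na(np[profiles$transcript_id]), 0L,
                        np[profiles$transcript_id])),
    zero_female_coverage = profiles$frac_covered_f == 0,
    female_frac_covered = profiles$frac_covered_f)
  out[, male_monomorphic := n_polymorphic_sites_male == 0L]
  out[, candidate := zero_female_coverage & male_monomorphic]
  out[]
}

#' Screen Y copies for deletion versus silencing
#'
#' The male/female genomic coverage ratio on an X-haplotype transcript,
#' normalized per sex by a sequencing-depth normalizer (typically the
#' autosomal median depth), is approximately 1 when the Y copy is present
#' (both male copies map) and approximately 0.5 when the Y copy is deleted
#' (one male copy versus two mappable female copies). Verdicts by
#' thresholds: ratio below `thresholds[1]` is `Y_deleted`, at or above
#' `thresholds[2]` is `Y_present_silenced`, in between `ambiguous`.
#'
#' @param profiles [coverage_profile()] over X transcripts, both sexes.
#' @param male_normalizer,female_normalizer per-sex depth normalizers (> 0).
#' @param thresholds length-2 numeric, default `c(0.7, 0.85)`.
#' @return data.table: `transcript_id`, raw and normalized coverages,
#'   `normalized_ratio`, `verdict`.
#' @export
neoY_absence_screen <- function(profiles, male_normalizer, female_normalizer,
                                thresholds = c(0.7, 0.85)) {
  if (male_normalizer <= 0 || female_normalizer <= 0) {
    stop("depth normalizers must be positive")
  }
  out <- data.table(
    transcript_id = profiles$transcript_id,
    mean_depth_m = profiles$mean_depth_m,
    mean_depth_f = profiles$mean_depth_f,
    norm_depth_m = profiles$mean_depth_m / male_normalizer,
    norm_depth_f = profiles$mean_depth_f / female_normalizer)
  out[, normalized_ratio := ifelse(norm_depth_f > 0,
                                   norm_depth_m / norm_depth_f, NA_real_)]
  out[, verdict := fifelse(is.na(normalized_ratio), "ambiguous",
                    fifelse(normalized_ratio < thresholds[1], "Y_deleted",
                      fifelse(normalized_ratio >= thresholds[2],
                              "Y_present_silenced", "ambiguous")))]
  out[]
}
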