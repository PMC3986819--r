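# Summary statistics and the end-of-run report.

#' N50 of a set of sequence lengths
#'
#' Standard convention: sort lengths descending, accumulate, and return the
#' length at which the cumulative sum first reaches half the total.
#'
#' @param lengths positive integer vector.
#' @return integer N50.
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  as.integer(s[which(cs >= sum(s) / 2)[1]])
}

#' Per-category site fractions, neo-sex versus autosomal control
#'
#' Percentages of assayed sites per category for the neo-sex and control
#' transcript sets, plus the control-to-neo ratio per category (how much of
#' the neo-sex signal could be explained by noise).
#'
#' @param categorized_sites data.table of categorized sites with a
#'   `chrom_class` column (`"neoX"`/`"neoY"` = neo-sex, `"autosome"` =
#'   control).
#' @param site_universe named numeric vector with elements `neo` and
#'   `autosome`: total assayed site counts per set (> 0 for `neo`).
#' @return data.table: `category`, `n_neo`, `pct_neo`, `n_autosome`,
#'   `pct_autosome`, `control_to_neo_ratio_pct`.
#' @export
summarize_categories <- function(categorized_sites, site_universe) {
  if (is.null(site_universe["neo"]) || is.na(site_universe["neo"]) ||
      site_universe["neo"] <= 0) {
    stop("site universe for the neo-sex set must be positive")
  }
  cats <- c("CAT1", "CAT2", "CAT3")
  dt <- as.data.table(categorized_sites)
  neo <- dt[chrom_class %in% c("neoX", "neoY")]
  aut <- dt[chrom_class == "autosome"]
  n_neo <- vapply(cats, function(cc) sum(neo$category == cc), numeric(1))
  n_aut <- vapply(cats, function(cc) sum(aut$category == cc), numeric(1))
  pct_neo <- 100 * n_neo / site_universe[["neo"]]
  pct_aut <- if (!is.na(site_universe["autosome"]) &&
                 site_universe[["autosome"]] > 0) {
    100 * n_aut / site_universe[["autosome"]]
  } else rep(NA_real_, 3L)
  data.table(category = cats, n_neo = as.integer(n_neo), pct_neo = pct_neo,
             n_autosome = as.integer(n_aut), pct_autosome = pct_aut,
             control_to_neo_ratio_pct =
               ifelse(pct_neo > 0, 100 * pct_aut / pct_neo, NA_real_))
}

#' Assemble the pipeline report from stage tables
#'
#' Pure function of persisted stage outputs, so a report regenerated from
#' disk is identical to the in-run report.
#'
#' @param tables list with elements `assembly_info` (data.table: `id`,
#'   `chrom_class`, `length_bp`), `neoY_info` (data.table: `id`, `parent`,
#'   `length_bp`), `orf` (ORF annotation table), `sites` (categorized
#'   sites with `chrom_class`), `n_assayed` (named: `neo`, `autosome`),
#'   `abundance` (named list of EM tables), `divergence`
#'   ([divergence_table()] output), `screens` (list `neoX_deletion`,
#'   `neoY_absence`).
#' @return list of class `pipeline_report`.
#' @export
assemble_report <- function(tables) {
  ai <- as.data.table(tables$assembly_info)
  ny <- as.data.table(tables$neoY_info)
  orf <- as.data.table(tables$orf)
  if (ncol(orf) == 0L) {
    orf <- data.table(transcript_id = character(), status = character(),
                      first_ptc_relative = numeric(),
                      utr3_from_first_stop_bp = integer(),
                      utr3_from_ancestral_stop_bp = integer())
  }
  neoX_ids <- ai[chrom_class == "neoX", id]
  shared <- intersect(neoX_ids, ny$parent)
  x_only <- setdiff(neoX_ids, ny$parent)
  y_only <- setdiff(ny$parent, neoX_ids)
  n50 <- list(
    neoX = if (length(neoX_ids)) {
      compute_n50(ai[chrom_class == "neoX", length_bp])
    } else NA_integer_,
    neoY = if (nrow(ny)) compute_n50(ny$length_bp) else NA_integer_,
    autosome = if (nrow(ai[chrom_class == "autosome"])) {
      compute_n50(ai[chrom_class == "autosome", length_bp])
    } else NA_integer_)
  orf_counts <- if (nrow(orf)) {
    as.list(table(factor(orf$status,
                         levels = c("intact", "frameshift_only", "ptc",
                                    "frameshift_and_ptc", "unalignable"))))
  } else list()
  n_nonfunc <- sum(orf$status %in% c("frameshift_only", "ptc",
                                     "frameshift_and_ptc"))
  n_classified <- sum(orf$status != "unalignable")
  ptc_rel <- orf[!is.na(first_ptc_relative), first_ptc_relative]
  ptc_bins <- if (length(ptc_rel)) {
    as.integer(table(cut(ptc_rel, breaks = seq(0, 1, 0.1),
                         include.lowest = TRUE)))
  } else integer(10)
  cat_summary <- if (nrow(as.data.table(tables$sites))) {
    summarize_categories(tables$sites, tables$n_assayed)
  } else NULL
  utr <- list(
    neoY_median_utr3 = if (nrow(orf[!is.na(utr3_from_first_stop_bp)])) {
      median(orf[!is.na(utr3_from_first_stop_bp), utr3_from_first_stop_bp])
    } else NA_real_,
    neoY_ptc_median_utr3_from_ptc = if (nrow(orf[!is.na(first_ptc_relative) &
                                                 !is.na(utr3_from_first_stop_bp)])) {
      median(orf[!is.na(first_ptc_relative), utr3_from_first_stop_bp])
    } else NA_real_,
    neoY_ptc_median_utr3_from_ancestral =
      if (nrow(orf[!is.na(utr3_from_ancestral_stop_bp)])) {
        median(orf[!is.na(utr3_from_ancestral_stop_bp),
                   utr3_from_ancestral_stop_bp])
      } else NA_real_)
  fpkm_summary <- lapply(tables$abundance, function(ab) {
    ab <- as.data.table(ab)
    ab[, .(n = .N, median_fpkm = median(fpkm), total_fragments =
             sum(assigned_fragments))]
  })
  div <- as.data.table(tables$divergence)
  div_summary <- if (nrow(div)) {
    list(n_triples = nrow(div),
         median_d_XY = median(div$d_XY, na.rm = TRUE),
         median_d_Y_outgroup = median(div$d_Y_outgroup, na.rm = TRUE),
         median_d_X_outgroup = median(div$d_X_outgroup, na.rm = TRUE))
  } else NULL
  rep <- list(
    counts = list(
      n_neoX = length(neoX_ids), n_neoY = nrow(ny),
      n_autosome = nrow(ai[chrom_class == "autosome"]),
      n_shared = length(shared), n_neoX_only = length(x_only),
      n_neoY_only = length(y_only)),
    n50 = n50,
    orf = c(orf_counts,
            list(n_nonfunctional = n_nonfunc, n_classified = n_classified,
                 pct_nonfunctional = if (n_classified > 0) {
                   100 * n_nonfunc / n_classified
                 } else NA_real_)),
    ptc_relative_position_bins = ptc_bins,
    category_summary = cat_summary,
    utr = utr,
    fpkm = fpkm_summary,
    divergence = div_summary,
    screens = list(
      n_neoX_deletion_candidates =
        if (!is.null(tables$screens$neoX_deletion)) {
          sum(tables$screens$neoX_deletion$candidate)
        } else NA_integer_,
      neoY_verdicts = if (!is.null(tables$screens$neoY_absence)) {
        as.list(table(tables$screens$neoY_absence$verdict))
      } else NULL))
  class(rep) <- "pipeline_report"
  rep
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== pipeline report ==\n")
  with(x$counts, cat(sprintf(
    "transcripts: neoX %d, neoY %d, autosome %d (shared %d, neoX-only %d, neoY-only %d)\n",
    n_neoX, n_neoY, n_autosome, n_shared, n_neoX_only, n_neoY_only)))
  cat(sprintf("N50: neoX %s, neoY %s, autosome %s\n",
              x$n50$neoX, x$n50$neoY, x$n50$autosome))
  if (!is.null(x$orf$n_classified) && x$orf$n_classified > 0) {
    cat(sprintf(
      "ORFs: %d classified; intact %s, frameshift-only %s, PTC %s, both %s (non-functional %.1f%%)\n",
      x$orf$n_classified, x$orf$intact, x$orf$frameshift_only, x$orf$ptc,
      x$orf$frameshift_and_ptc, x$orf$pct_nonfunctional))
  }
  if (!is.null(x$category_summary)) {
    cs <- x$category_summary
    for (i in seq_len(nrow(cs))) {
      cat(sprintf("  %s: neo %.3f%% of sites, control %.3f%% (ratio %.0f%%)\n",
                  cs$category[i], cs$pct_neo[i], cs$pct_autosome[i],
                  cs$control_to_neo_ratio_pct[i]))
    }
  }
  if (!is.null(x$divergence)) {
    cat(sprintf("divergence (n=%d): median X/Y %.4f, Y/outgroup %.4f\n",
                x$divergence$n_triples, x$divergence$median_d_XY,
                x$divergence$median_d_Y_outgroup))
  }
  invisible(x)
}
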