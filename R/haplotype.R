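# Haplotype separation: exon splitting by read tiling, sex-aware variant
# calling and categorization, transcript rewriting, and RNA-support
# filtering.
#
# Allele encoding at a site: a plain base ("A") for SNVs, "-L" for a
# deletion of L target bases anchored at the site, "+XYZ" for an insertion
# of XYZ after the site.

#' Variant caller thresholds
#'
#' An allele is called when its quality-passing support (base quality
#' strictly greater than `min_bq`) reaches `min_alt_reads`, relaxed to
#' `min_alt_reads_lowcov` when the total raw depth at the site is at most
#' `lowcov_threshold`. The reference allele is subject to the same rule.
#'
#' @param min_alt_reads support needed at normal coverage (default 3).
#' @param min_alt_reads_lowcov support needed at low coverage (default 2).
#' @param lowcov_threshold raw-depth bound defining low coverage (default 9).
#' @param min_bq exclusive base-quality bound (default 13).
#' @return list of validated parameters.
#' @export
caller_params <- function(min_alt_reads = 3L, min_alt_reads_lowcov = 2L,
                          lowcov_threshold = 9L, min_bq = 13L) {
  stopifnot(min_alt_reads_lowcov <= min_alt_reads, lowcov_threshold >= 0)
  list(min_alt_reads = as.integer(min_alt_reads),
       min_alt_reads_lowcov = as.integer(min_alt_reads_lowcov),
       lowcov_threshold = as.integer(lowcov_threshold),
       min_bq = as.integer(min_bq))
}

#' Split a transcript into exons at low-overlap read junctions
#'
#' Zero-mismatch genomic read placements tile the transcript; wherever the
#' maximum pairwise overlap between adjacent tiling reads falls below
#' `min_overlap` the transcript is cut (a hypothetical exon-exon junction).
#' Uncovered stretches are dropped. The cut is placed at the end of the
#' left-hand read; overlap bases stay with the left piece.
#'
#' @param transcript_bases transcript sequence (single string).
#' @param alignments exact alignments of genomic reads on this transcript
#'   (only `target_start`/`target_end` are used).
#' @param min_overlap junction threshold in bp (default 6).
#' @return data.table with `start`, `end` (0-based half-open coordinates on
#'   the parent) and `bases`; zero rows when the transcript has no genomic
#'   support.
#' @export
split_into_exons <- function(transcript_bases, alignments, min_overlap = 6L) {
  empty <- data.table(start = integer(), end = integer(), bases = character())
  if (is.null(alignments) || nrow(alignments) == 0L) return(empty)
  iv <- unique(data.table(start = alignments$target_start,
                          end = alignments$target_end))
  setorder(iv, start, end)
  pieces_start <- integer()
  pieces_end <- integer()
  cur_start <- iv$start[1]
  cur_end <- iv$end[1]
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      s <- iv$start[i]; e <- iv$end[i]
      ov <- cur_end - s
      if (ov >= min_overlap) {
        cur_end <- max(cur_end, e)
      } else {
        pieces_start <- c(pieces_start, cur_start)
        pieces_end <- c(pieces_end, cur_end)
        cur_start <- if (ov > 0L) cur_end else s
        cur_end <- max(cur_end, e)
        if (cur_end <= cur_start) { # read fully inside the closed piece
          cur_start <- pieces_start[length(pieces_start)]
          cur_end <- pieces_end[length(pieces_end)]
          pieces_start <- pieces_start[-length(pieces_start)]
          pieces_end <- pieces_end[-length(pieces_end)]
        }
      }
    }
  }
  pieces_start <- c(pieces_start, cur_start)
  pieces_end <- c(pieces_end, cur_end)
  data.table(start = pieces_start, end = pieces_end,
             bases = substring(transcript_bases, pieces_start + 1L,
                               pieces_end))
}

#' Call alleles at one site
#'
#' @param counts_q named integer vector of quality-passing support per
#'   allele (reference included), e.g. `c(A = 20, G = 3)`.
#' @param depth_raw total raw depth at the site (all covering reads).
#' @param params [caller_params()].
#' @return character vector of called alleles (possibly empty).
#' @export
call_site <- function(counts_q, depth_raw, params = caller_params()) {
  thr <- if (depth_raw <= params$lowcov_threshold) {
    params$min_alt_reads_lowcov
  } else {
    params$min_alt_reads
  }
  names(counts_q)[counts_q >= thr]
}

#' Categorize one site from its per-sex calls
#'
#' Categories follow the sex-specific allele patterns that distinguish
#' neo-X/neo-Y divergence from noise:
#' * CAT1 - males polymorphic (reference plus one alternative called), all
#'   quality-passing female bases carry a single called non-reference
#'   allele: the transcript already holds the Y allele; the female allele is
#'   stored for X-ward rewriting.
#' * CAT2 - both sexes show a non-reference allele (or males show two
#'   alternatives): polymorphism, error, or collapsed paralogs; left
#'   unchanged.
#' * CAT3 - males polymorphic, females show no non-reference allele: the
#'   transcript holds the X allele; the male-specific allele is stored as
#'   the substitution for Y-ward rewriting.
#' * INVARIANT - anything else.
#'
#' @param male_called,female_called character vectors of called alleles.
#' @param ref_allele reference base at the site.
#' @param female_ref_qual quality-passing female support for the reference
#'   (used by the strict "all female reads show the variant" clause of CAT1).
#' @param female_ref_tolerance maximum female reference support still
#'   compatible with CAT1 (default 0 = strict).
#' @return list with `category` and `substitution_allele` (NA unless CAT1 or
#'   CAT3).
#' @export
categorize_site <- function(male_called, female_called, ref_allele,
                            female_ref_qual = 0L, female_ref_tolerance = 0L) {
  m_nonref <- setdiff(male_called, ref_allele)
  f_nonref <- setdiff(female_called, ref_allele)
  male_poly <- (ref_allele %in% male_called) && length(m_nonref) >= 1L
  if (male_poly && length(f_nonref) == 1L &&
      !(ref_allele %in% female_called) &&
      length(female_called) == 1L &&
      female_ref_qual <= female_ref_tolerance) {
    return(list(category = "CAT1", substitution_allele = f_nonref))
  }
  if ((length(m_nonref) >= 1L && length(f_nonref) >= 1L) ||
      length(m_nonref) >= 2L) {
    return(list(category = "CAT2", substitution_allele = NA_character_))
  }
  if (male_poly && length(m_nonref) == 1L && length(f_nonref) == 0L) {
    return(list(category = "CAT3", substitution_allele = m_nonref))
  }
  list(category = "INVARIANT", substitution_allele = NA_character_)
}

#' Call and categorize all variant sites of a pileup
#'
#' Applies [call_site()] per sex at every covered position (SNV alleles from
#' the base-count matrices, indel alleles from the indel table) and
#' [categorize_site()] to the resulting calls. Only sites with at least one
#' called non-reference allele in either sex are materialized; remaining
#' assayed sites are INVARIANT by construction.
#'
#' @param pileup a [build_pileup()] result.
#' @param ref_bases reference sequence of the target (string).
#' @param params [caller_params()].
#' @return data.table: `target_id`, `pos`, `ref_allele`, `male_alleles`,
#'   `female_alleles` (comma-joined), `category`, `substitution_allele`,
#'   `depth_m`, `depth_f`. Attribute `n_assayed` counts positions with
#'   nonzero depth in both sexes.
#' @export
categorize_pileup <- function(pileup, ref_bases, params = caller_params()) {
  st <- pileup$sites
  bases <- c("A", "C", "G", "T")
  out <- data.table(target_id = character(), pos = integer(),
                    ref_allele = character(), male_alleles = character(),
                    female_alleles = character(), category = character(),
                    substitution_allele = character(), depth_m = integer(),
                    depth_f = integer())
  n_assayed <- if (nrow(st)) sum(st$depth_m > 0L & st$depth_f > 0L) else 0L
  if (nrow(st) == 0L) {
    setattr(out, "n_assayed", n_assayed)
    return(out)
  }
  refv <- strsplit(ref_bases, "")[[1]]
  mq <- as.matrix(st[, paste0("mq_", bases), with = FALSE])
  fq <- as.matrix(st[, paste0("fq_", bases), with = FALSE])
  colnames(mq) <- bases; colnames(fq) <- bases
  thr_m <- ifelse(st$depth_m <= params$lowcov_threshold,
                  params$min_alt_reads_lowcov, params$min_alt_reads)
  thr_f <- ifelse(st$depth_f <= params$lowcov_threshold,
                  params$min_alt_reads_lowcov, params$min_alt_reads)
  called_m <- mq >= thr_m
  called_f <- fq >= thr_f
  # indel alleles per position/sex
  ind <- pileup$indels
  ind_m <- ind[sex == "male"]
  ind_f <- ind[sex == "female"]
  # candidate positions: any called allele differing from the reference, or
  # any indel allele with callable support
  refidx <- match(refv, bases) # NA for N
  nonref_called_m <- rowSums(called_m) -
    ifelse(!is.na(refidx), called_m[cbind(seq_len(nrow(st)), refidx)], 0L)
  nonref_called_f <- rowSums(called_f) -
    ifelse(!is.na(refidx), called_f[cbind(seq_len(nrow(st)), refidx)], 0L)
  cand_pos <- which(nonref_called_m > 0L | nonref_called_f > 0L)
  ind_cand <- unique(ind$pos)
  cand_pos <- sort(union(cand_pos - 1L, ind_cand)) # to 0-based
  rows <- vector("list", length(cand_pos))
  for (k in seq_along(cand_pos)) {
    p <- cand_pos[k]
    i <- p + 1L
    ref <- refv[i]
    cm <- mq[i, ]
    cf <- fq[i, ]
    im <- ind_m[pos == p]
    f_ <- ind_f[pos == p]
    counts_m <- c(cm[cm > 0L],
                  if (nrow(im)) setNames(im$count, im$allele))
    counts_f <- c(cf[cf > 0L],
                  if (nrow(f_)) setNames(f_$count, f_$allele))
    mc <- call_site(counts_m, st$depth_m[i], params)
    fc <- call_site(counts_f, st$depth_f[i], params)
    if (ref == "N") next # never call alleles against an N reference
    cat_ <- categorize_site(mc, fc, ref,
                            female_ref_qual = fq[i, ][ref][[1]] %||% 0L)
    rows[[k]] <- data.table(
      target_id = pileup$target_id, pos = p, ref_allele = ref,
      male_alleles = paste(mc, collapse = ","),
      female_alleles = paste(fc, collapse = ","),
      category = cat_$category,
      substitution_allele = cat_$substitution_allele[1],
      depth_m = st$depth_m[i], depth_f = st$depth_f[i])
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) out <- rbindlist(rows)
  setattr(out, "n_assayed", n_assayed)
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Rewrite a transcript into the Y (or X) haplotype
#'
#' Y-ward: every CAT3 site's reference allele is replaced by the male-
#' specific substitution allele (SNV, deletion or insertion); CAT1 and CAT2
#' sites are untouched. X-ward: every CAT1 site is replaced by the female
#' allele, and a CAT3 site is replaced by the reference allele if the
#' transcript carries the male-specific variant.
#'
#' A SNV whose current base already equals the substitution allele is
#' skipped (making SNV rewriting idempotent); a base matching neither the
#' recorded reference nor the substitution raises a stale-site-list error.
#' Indel sites whose reference context no longer matches are skipped.
#'
#' @param transcript_bases sequence to rewrite.
#' @param categorized_sites data.table from [categorize_pileup()] (positions
#'   on `transcript_bases`).
#' @param direction `"toY"` or `"toX"`.
#' @return list with `bases` (rewritten sequence) and `coord_map` (integer
#'   vector: for each 0-based old position, its 0-based new position, NA if
#'   deleted).
#' @export
rewrite_haplotype <- function(transcript_bases, categorized_sites,
                              direction = c("toY", "toX")) {
  direction <- match.arg(direction)
  n <- nchar(transcript_bases)
  coord_map <- seq_len(n) - 1L
  sites <- categorized_sites[
    if (direction == "toY") category == "CAT3" else category %in% c("CAT1", "CAT3")]
  if (nrow(sites) == 0L) {
    return(list(bases = transcript_bases, coord_map = coord_map))
  }
  setorder(sites, pos)
  segs <- character(0)
  map_pieces <- vector("list", nrow(sites) + 1L)
  cursor <- 0L # 0-based position in old sequence, next unconsumed
  new_len <- 0L
  cm <- rep(NA_integer_, n)
  for (r in seq_len(nrow(sites))) {
    p <- sites$pos[r]
    if (p < cursor) next # overlapping with a previously applied indel
    sub <- sites$substitution_allele[r]
    cat_r <- sites$category[r]
    ref_allowed <- sites$ref_allele[r]
    if (direction == "toX" && cat_r == "CAT3") {
      # replace the male-specific variant with the reference if present
      cur <- substr(transcript_bases, p + 1L, p + 1L)
      if (startsWith(sub, "+") || startsWith(sub, "-")) next
      if (cur == sub) {
        ref_allowed <- cur # the male variant is the expected observed base
        sub <- sites$ref_allele[r]
      } else next
    }
    if (is.na(sub)) next
    # untouched segment before the site
    if (p > cursor) {
      segs <- c(segs, substring(transcript_bases, cursor + 1L, p))
      cm[(cursor + 1L):p] <- new_len + 0L:(p - cursor - 1L)
      new_len <- new_len + (p - cursor)
      cursor <- p
    }
    if (startsWith(sub, "-")) { # deletion of L bases at p
      L <- as.integer(substring(sub, 2L))
      if (p + L > n) next
      cursor <- cursor + L # deleted bases map to NA
    } else if (startsWith(sub, "+")) { # insertion after base at p
      ins <- substring(sub, 2L)
      segs <- c(segs, substr(transcript_bases, p + 1L, p + 1L), ins)
      cm[p + 1L] <- new_len
      new_len <- new_len + 1L + nchar(ins)
      cursor <- cursor + 1L
    } else { # SNV
      cur <- substr(transcript_bases, p + 1L, p + 1L)
      if (cur == sub || cur == ref_allowed) {
        segs <- c(segs, sub)
      } else {
        stop(sprintf(
          "stale site list: %s pos %d has '%s', expected ref '%s' or substitution '%s'",
          sites$target_id[r] %||% "?", p, cur, ref_allowed, sub))
      }
      cm[p + 1L] <- new_len
      new_len <- new_len + 1L
      cursor <- cursor + 1L
    }
  }
  if (cursor < n) {
    segs <- c(segs, substring(transcript_bases, cursor + 1L, n))
    cm[(cursor + 1L):n] <- new_len + 0L:(n - cursor - 1L)
    new_len <- new_len + (n - cursor)
  }
  list(bases = paste(segs, collapse = ""), coord_map = cm)
}

#' Keep RNA-supported regions carrying diagnostic variants
#'
#' Maximal runs of the rewritten transcript with zero-mismatch RNA coverage
#' of at least one read are emitted if and only if they contain at least one
#' diagnostic site (CAT3 or CAT1 - both are divergent sites between the
#' haplotypes). Runs without diagnostic sites are dropped: this is what
#' removes homomorphic and silenced-Y genes from the Y assembly.
#'
#' @param rewritten_len length of the rewritten transcript.
#' @param rna_alignments exact alignments of RNA reads on the rewritten
#'   transcript.
#' @param diagnostic_positions 0-based positions of diagnostic sites on the
#'   rewritten transcript.
#' @return data.table: `start`, `end` (0-based half-open),
#'   `n_diagnostic_sites`, `rna_min_coverage`.
#' @export
filter_supported_regions <- function(rewritten_len, rna_alignments,
                                     diagnostic_positions) {
  empty <- data.table(start = integer(), end = integer(),
                      n_diagnostic_sites = integer(),
                      rna_min_coverage = integer())
  if (is.null(rna_alignments) || nrow(rna_alignments) == 0L) return(empty)
  cov <- integer(rewritten_len + 1L)
  s <- rna_alignments$target_start
  e <- rna_alignments$target_end
  tb <- tabulate(s + 1L, nbins = rewritten_len + 1L)
  te <- tabulate(e + 1L, nbins = rewritten_len + 1L)
  cov <- cumsum(tb - te)[seq_len(rewritten_len)]
  covered <- cov > 0L
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  runs <- data.table(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) return(empty)
  runs[, n_diagnostic_sites := vapply(seq_len(.N), function(i) {
    sum(diagnostic_positions >= start[i] & diagnostic_positions < end[i])
  }, integer(1))]
  runs[, rna_min_coverage := vapply(seq_len(.N), function(i) {
    min(cov[(start[i] + 1L):end[i]])
  }, integer(1))]
  runs[n_diagnostic_sites >= 1L]
}
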