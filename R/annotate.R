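# Reference-guided annotation: reciprocal-best-hit ID assignment,
# fragment merging and protein-coordinate scaffolding, alignment to the
# homologous reference CDS, and ORF-integrity classification (frameshifts,
# premature termination codons, 3'UTR lengths).

STOP_CODONS <- c("TAA", "TAG", "TGA")

# shared-kmer candidate pairs between two transcript sets (prefilter for
# all-vs-all scoring); returns data.table(query_id, ref_id, shared)
shared_kmer_pairs <- function(queries, references, k = 20L, min_shared = 3L) {
  qk <- kmer_index(queries, k)
  rk <- kmer_index(references, k)
  setnames(qk, "target_id", "query_id")
  setnames(rk, "target_id", "ref_id")
  m <- rk[qk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(m) == 0L) {
    return(data.table(query_id = character(), ref_id = character(),
                      shared = integer()))
  }
  pairs <- m[, .(shared = uniqueN(kmer)), by = .(query_id, ref_id)]
  pairs[shared >= min_shared]
}

# affine local alignment score between two sequences (Biostrings backend)
pairwise_score <- function(a, b, params = mapper_params()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match_score, mismatch = params$mismatch_score,
    baseOnly = FALSE)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = params$gap_open_penalty,
    gapExtension = params$gap_extend_penalty, scoreOnly = TRUE))
}

#' Assign reference IDs by reciprocal best hit
#'
#' A query is assigned to a reference iff each is the other's best hit.
#' Candidate pairs are prefiltered by shared k-mers; each candidate pair is
#' scored with a symmetric affine local alignment. Score ties are broken by
#' lexicographically smaller id and flagged.
#'
#' @param queries,references [transcript_set()]s.
#' @param scorer optional `function(query_bases, ref_bases) -> numeric`
#'   similarity score; defaults to an affine local alignment score.
#' @param k,min_shared k-mer prefilter: only pairs sharing at least
#'   `min_shared` k-mers are scored.
#' @return data.table: `transcript_id`, `reference_id`, `forward_score`,
#'   `reverse_score`, `tie_broken`.
#' @export
assign_ids_rbh <- function(queries, references, scorer = NULL, k = 20L,
                           min_shared = 3L) {
  empty <- data.table(transcript_id = character(), reference_id = character(),
                      forward_score = numeric(), reverse_score = numeric(),
                      tie_broken = logical())
  pairs <- shared_kmer_pairs(queries, references, k = k,
                             min_shared = min_shared)
  if (nrow(pairs) == 0L) return(empty)
  if (is.null(scorer)) scorer <- function(a, b) pairwise_score(a, b)
  qseq <- setNames(queries$bases, queries$id)
  rseq <- setNames(references$bases, references$id)
  pairs[, score := vapply(seq_len(.N), function(i) {
    scorer(qseq[[query_id[i]]], rseq[[ref_id[i]]])
  }, numeric(1))]
  # best reference per query (strict best; ties -> lexicographic, flagged)
  best_of <- function(dt, by_col, other_col) {
    setorderv(dt, c(by_col, "score", other_col), order = c(1L, -1L, 1L))
    dt[, {
      tie <- .N > 1L && abs(score[1] - score[2]) < 1e-9
      .(pick = .SD[[other_col]][1], score = score[1], tie = tie)
    }, by = by_col]
  }
  bq <- best_of(copy(pairs), "query_id", "ref_id")
  br <- best_of(copy(pairs), "ref_id", "query_id")
  merged <- bq[br, on = c(query_id = "pick"), nomatch = NULL]
  # mutual: the query's best reference is the reference whose best query it is
  mutual <- merged[pick == ref_id]
  if (nrow(mutual) == 0L) return(empty)
  out <- mutual[, .(transcript_id = query_id, reference_id = pick,
                    forward_score = score, reverse_score = i.score,
                    tie_broken = tie | i.tie)]
  setorder(out, transcript_id)
  out[]
}

#' Greedily merge overlapping fragments
#'
#' Fragments whose suffix/prefix overlap is at least `min_overlap_bp` long at
#' identity at least `min_identity` are merged, longest overlap first;
#' disagreeing overlaps are left unmerged. Fragments are assumed to share an
#' orientation. Overlap mismatches keep the left fragment's bases.
#'
#' @param fragments character vector of sequences (names kept if present).
#' @param min_overlap_bp minimum overlap length (default 40).
#' @param min_identity minimum overlap identity (default 0.99).
#' @return character vector of merged contigs.
#' @export
merge_fragments <- function(fragments, min_overlap_bp = 40L,
                            min_identity = 0.99) {
  frags <- fragments
  if (is.null(names(frags))) names(frags) <- paste0("f", seq_along(frags))
  repeat {
    n <- length(frags)
    if (n < 2L) break
    best_ov <- 0L; best_i <- 0L; best_j <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        ov <- cpp_best_overlap(frags[[i]], frags[[j]], min_overlap_bp,
                               min_identity)
        if (ov[1] > best_ov) { best_ov <- ov[1]; best_i <- i; best_j <- j }
      }
    }
    if (best_ov < min_overlap_bp) break
    merged <- paste0(frags[[best_i]],
                     substring(frags[[best_j]], best_ov + 1L))
    nm <- paste0(names(frags)[best_i], "+", names(frags)[best_j])
    frags <- frags[-c(best_i, best_j)]
    frags[nm] <- merged
  }
  frags
}

# local alignment of a fragment against a reference CDS, trying both
# strands; returns ref interval (0-based), strand and score
cds_anchor <- function(fragment, reference_cds, params = mapper_params()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match_score, mismatch = params$mismatch_score,
    baseOnly = FALSE)
  score_one <- function(s) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(reference_cds),
      type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open_penalty,
      gapExtension = params$gap_extend_penalty)
  }
  fw <- score_one(fragment)
  rv <- score_one(revcomp(fragment))
  use_rev <- Biostrings::score(rv) > Biostrings::score(fw)
  pa <- if (use_rev) rv else fw
  rng <- pa@subject@range
  list(ref_start = BiocGenerics::start(rng) - 1L,
       ref_end = BiocGenerics::end(rng),
       strand = if (use_rev) "-" else "+",
       score = Biostrings::score(pa))
}

#' Scaffold fragments along a reference coding sequence
#'
#' Fragments are merged where they overlap, anchored on the homologous
#' reference CDS by local alignment (reverse-frame fragments are
#' reverse-complemented), ordered by their aligned reference start, and
#' joined with `N` runs sized to the unaligned intervening reference
#' nucleotides (three per intervening residue). Fragments with conflicting
#' orders are returned unscaffolded with a warning.
#'
#' @param fragments character vector of fragment sequences.
#' @param reference_cds homologous reference CDS (string).
#' @param min_overlap_bp,min_identity passed to [merge_fragments()].
#' @return single scaffold string, or the unscaffolded fragments (with a
#'   warning) on conflicting orders.
#' @export
scaffold_by_protein <- function(fragments, reference_cds,
                                min_overlap_bp = 40L, min_identity = 0.99) {
  frags <- merge_fragments(fragments, min_overlap_bp, min_identity)
  if (length(frags) == 1L) return(unname(frags[[1]]))
  anch <- lapply(frags, cds_anchor, reference_cds = reference_cds)
  oriented <- vapply(seq_along(frags), function(i) {
    if (anch[[i]]$strand == "-") revcomp(frags[[i]]) else frags[[i]]
  }, character(1))
  rs <- vapply(anch, `[[`, numeric(1), "ref_start")
  re <- vapply(anch, `[[`, numeric(1), "ref_end")
  ord <- order(rs)
  oriented <- oriented[ord]; rs <- rs[ord]; re <- re[ord]
  # conflicting (interleaved) anchors: a later fragment starting well before
  # the previous fragment's anchored end was not mergeable -> unresolvable
  if (any(rs[-1] < re[-length(re)] - min_overlap_bp)) {
    warning("conflicting fragment order against reference; left unscaffolded")
    return(unname(frags))
  }
  out <- oriented[1]
  for (i in seq_along(oriented)[-1]) {
    gap <- max(0L, as.integer(rs[i] - re[i - 1L]))
    out <- paste0(out, strrep("N", gap), oriented[i])
  }
  out
}

#' Align a transcript to its homologous reference CDS
#'
#' Affine-gap local alignment (the transcript may carry UTR sequence and may
#' be fragmentary). The result records the aligned strings with gaps and the
#' coordinates of the aligned region on both sequences so that codon phase
#' can be tracked. Alignments below the identity floor (identity measured
#' over all alignment columns, gaps included), or covering too little of
#' the shorter sequence, are flagged unalignable.
#'
#' @param transcript_bases transcript sequence.
#' @param reference_cds homologous CDS (length divisible by 3, ending in a
#'   stop codon).
#' @param min_identity identity floor (default 0.6).
#' @param min_cover minimum aligned fraction of the shorter sequence.
#' @param params scoring; the default raises the gap-open cost to 25 so
#'   that a pair of spurious 1-bp gaps (33.2 + lost matches under the
#'   mapper's 10) can never outscore a cluster of up to four mismatches -
#'   fake frameshifts would silently shift every downstream codon index,
#'   while true frameshift indels still align as gaps easily.
#' @return list: `tx_aln`, `ref_aln` (aligned strings with `-` gaps),
#'   `tx_start`, `tx_end`, `ref_start`, `ref_end` (0-based half-open),
#'   `identity`, `score`, `unalignable`.
#' @export
align_to_reference_cds <- function(transcript_bases, reference_cds,
                                   min_identity = 0.6, min_cover = 0.3,
                                   params = mapper_params(gap_open_penalty = 25)) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match_score, mismatch = params$mismatch_score,
    baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(transcript_bases),
    Biostrings::DNAString(reference_cds),
    type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open_penalty,
    gapExtension = params$gap_extend_penalty)
  tx_aln <- as.character(Biostrings::alignedPattern(pa))
  ref_aln <- as.character(Biostrings::alignedSubject(pa))
  prng <- pa@pattern@range
  srng <- pa@subject@range
  cols <- strsplit(tx_aln, "")[[1]]
  colr <- strsplit(ref_aln, "")[[1]]
  comparable <- cols != "-" & colr != "-"
  # gap-inclusive identity: matches over ALL alignment columns, so gappy
  # spurious local alignments of unrelated sequences fall below the floor
  ident <- if (length(cols)) {
    sum(cols == colr & cols != "-") / length(cols)
  } else 0
  short_len <- min(nchar(transcript_bases), nchar(reference_cds))
  cover <- sum(comparable) / short_len
  list(tx_aln = tx_aln, ref_aln = ref_aln,
       tx_start = BiocGenerics::start(prng) - 1L,
       tx_end = BiocGenerics::end(prng),
       ref_start = BiocGenerics::start(srng) - 1L,
       ref_end = BiocGenerics::end(srng),
       identity = ident, score = Biostrings::score(pa),
       unalignable = (ident < min_identity || cover < min_cover))
}

#' Classify ORF integrity from a CDS alignment
#'
#' Indels whose length is not a multiple of three are recorded as
#' frameshifts. The transcript is then read codon-wise in the reference
#' frame - the phase follows the transcript (so it shifts after each
#' frameshift) - and any stop codon whose reference position falls strictly
#' before the reference's stop codon is a premature termination codon (PTC).
#' The first PTC's reference codon index is normalized by the reference
#' codon count.
#'
#' @param alignment result of [align_to_reference_cds()].
#' @param reference_cds the reference CDS used in the alignment.
#' @param transcript_id id recorded in the annotation.
#' @return list of class `orf_annotation`: `transcript_id`, `status`
#'   (`intact`, `frameshift_only`, `ptc`, `frameshift_and_ptc`,
#'   `unalignable`), `frameshift_positions` (0-based transcript coords),
#'   `first_ptc_codon_index` (1-based reference codon), `first_ptc_relative`,
#'   `first_stop_tx_end`, `ancestral_stop_tx_end` (0-based half-open ends on
#'   the transcript, NA when absent).
#' @export
classify_orf <- function(alignment, reference_cds, transcript_id = NA_character_) {
  ref_len <- nchar(reference_cds)
  stopifnot(ref_len %% 3L == 0L)
  n_codons <- ref_len %/% 3L
  ann <- list(transcript_id = transcript_id, status = "unalignable",
              frameshift_positions = integer(),
              first_ptc_codon_index = NA_integer_,
              first_ptc_relative = NA_real_,
              first_stop_tx_end = NA_integer_,
              ancestral_stop_tx_end = NA_integer_)
  class(ann) <- "orf_annotation"
  if (alignment$unalignable) return(ann)
  tx <- strsplit(alignment$tx_aln, "")[[1]]
  rf <- strsplit(alignment$ref_aln, "")[[1]]
  t_pos <- alignment$tx_start # 0-based coord of next transcript base
  r_pos <- alignment$ref_start
  # frameshifts: gap runs with length %% 3 != 0
  gaps <- rle(ifelse(tx == "-", "D", ifelse(rf == "-", "I", "M")))
  fs_pos <- integer()
  # walk runs to get transcript coordinates of each gap run
  tp <- alignment$tx_start
  for (g in seq_along(gaps$lengths)) {
    L <- gaps$lengths[g]; typ <- gaps$values[g]
    if (typ != "M" && L %% 3L != 0L) fs_pos <- c(fs_pos, tp)
    if (typ != "D") tp <- tp + L
  }
  # codon walk: phase anchored to the reference frame at the first aligned
  # column, then following the transcript
  phase0 <- alignment$ref_start %% 3L
  buf <- character(0)
  buf_tx0 <- NA_integer_ # tx coord of first base in buffer
  buf_ref <- NA_integer_ # ref coord seen at first base in buffer
  first_ptc_idx <- NA_integer_
  first_stop_end <- NA_integer_
  ancestral_end <- NA_integer_
  last_ref <- alignment$ref_start
  skip <- (3L - phase0) %% 3L # transcript bases to skip to reach frame 0
  # align the walk start to a reference codon boundary
  for (k in seq_along(tx)) {
    tb <- tx[k]; rb <- rf[k]
    if (rb != "-") {
      # transcript end coordinate aligned to the end of the reference stop
      if (r_pos == ref_len - 1L) {
        ancestral_end <- t_pos + (if (tb != "-") 1L else 0L)
      }
      last_ref <- r_pos
      r_pos <- r_pos + 1L
    }
    if (tb != "-") {
      if (skip > 0L) {
        skip <- skip - 1L
        t_pos <- t_pos + 1L
        next
      }
      if (length(buf) == 0L) { buf_tx0 <- t_pos; buf_ref <- last_ref }
      buf <- c(buf, tb)
      t_pos <- t_pos + 1L
      if (length(buf) == 3L) {
        codon <- paste(buf, collapse = "")
        if (codon %in% STOP_CODONS) {
          ref_codon_idx <- buf_ref %/% 3L + 1L
          if (is.na(first_stop_end)) first_stop_end <- t_pos
          if (ref_codon_idx < n_codons && is.na(first_ptc_idx)) {
            first_ptc_idx <- ref_codon_idx
          }
        }
        buf <- character(0)
      }
    }
  }
  has_fs <- length(fs_pos) > 0L
  has_ptc <- !is.na(first_ptc_idx)
  ann$status <- if (!has_fs && !has_ptc) "intact"
  else if (has_fs && !has_ptc) "frameshift_only"
  else if (!has_fs && has_ptc) "ptc"
  else "frameshift_and_ptc"
  ann$frameshift_positions <- fs_pos
  ann$first_ptc_codon_index <- first_ptc_idx
  ann$first_ptc_relative <- if (has_ptc) first_ptc_idx / n_codons else NA_real_
  ann$first_stop_tx_end <- first_stop_end
  ann$ancestral_stop_tx_end <- ancestral_end
  ann
}

#' @export
print.orf_annotation <- function(x, ...) {
  cat(sprintf("orf_annotation %s: %s", x$transcript_id, x$status))
  if (!is.na(x$first_ptc_codon_index)) {
    cat(sprintf(" (first PTC at reference codon %d, relative %.3f)",
                x$first_ptc_codon_index, x$first_ptc_relative))
  }
  if (length(x$frameshift_positions)) {
    cat(sprintf(" [%d frameshift(s)]", length(x$frameshift_positions)))
  }
  cat("\n")
  invisible(x)
}

#' 3'UTR lengths from the first and the ancestral stop codon
#'
#' The 3'UTR is measured from the end of the first stop codon (the PTC when
#' one exists, otherwise the ancestral stop) to the end of the transcript;
#' when a PTC exists the ancestral-stop measure is reported additionally.
#'
#' @param transcript_bases the transcript sequence.
#' @param orf a [classify_orf()] annotation for this transcript.
#' @return list: `utr3_from_first_stop_bp`, `utr3_from_ancestral_stop_bp`
#'   (the latter NA when no PTC exists; both NA when no stop codon was
#'   found).
#' @export
utr3_lengths <- function(transcript_bases, orf) {
  n <- nchar(transcript_bases)
  has_ptc <- !is.na(orf$first_ptc_codon_index)
  first_end <- if (!is.na(orf$first_stop_tx_end)) {
    orf$first_stop_tx_end
  } else if (!is.na(orf$ancestral_stop_tx_end)) {
    orf$ancestral_stop_tx_end
  } else NA_integer_
  if (is.na(first_end)) {
    return(list(utr3_from_first_stop_bp = NA_integer_,
                utr3_from_ancestral_stop_bp = NA_integer_))
  }
  list(utr3_from_first_stop_bp = n - first_end,
       utr3_from_ancestral_stop_bp = if (has_ptc &&
                                         !is.na(orf$ancestral_stop_tx_end)) {
         n - orf$ancestral_stop_tx_end
       } else NA_integer_)
}
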