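# Lightweight read-to-transcript alignment.
#
# Two modes mirror the pipeline's needs: exact (zero-mismatch substring
# placement, both strands, ALL equal placements reported) and scored
# (seed-and-extend with affine-gap DP). Alignment records are data.tables
# with 0-based half-open target coordinates and CIGAR strings over {M,I,D}
# (I = insertion in the read relative to the target).

#' Mapper scoring parameters
#'
#' Affine-gap scoring used by [map_scored()]. The gap-open, gap-extend and
#' mismatch values default to 10, 6.6 and -5; a gap of length L costs
#' `gap_open + L * gap_extend`. The match score and seed length are
#' implementation choices exposed here.
#'
#' @param gap_open_penalty,gap_extend_penalty gap cost magnitudes (>= 0).
#' @param mismatch_score mismatch score (<= 0).
#' @param match_score match score (> 0).
#' @param seed_length exact k-mer seed length.
#' @param min_score_frac alignments scoring below
#'   `min_score_frac * read_length * match_score` are dropped.
#' @param max_hits_reported cap on reported placements per read (`Inf` = all).
#' @return list of validated parameters.
#' @export
mapper_params <- function(gap_open_penalty = 10, gap_extend_penalty = 6.6,
                          mismatch_score = -5, match_score = 10,
                          seed_length = 20L, min_score_frac = 0.4,
                          max_hits_reported = Inf) {
  stopifnot(gap_open_penalty >= 0, gap_extend_penalty >= 0,
            mismatch_score <= 0, match_score > 0, seed_length >= 4)
  list(gap_open_penalty = gap_open_penalty,
       gap_extend_penalty = gap_extend_penalty,
       mismatch_score = mismatch_score, match_score = match_score,
       seed_length = as.integer(seed_length),
       min_score_frac = min_score_frac,
       max_hits_reported = max_hits_reported)
}

# k-mer position index over a transcript set: data.table(kmer, target_id, pos)
# with 0-based pos, keyed by kmer.
kmer_index <- function(targets, k) {
  pieces <- lapply(seq_len(nrow(targets)), function(i) {
    s <- targets$bases[i]
    n <- nchar(s)
    if (n < k) return(NULL)
    data.table(kmer = substring(s, 1:(n - k + 1), k:n),
               target_id = targets$id[i], pos = 0:(n - k))
  })
  dt <- rbindlist(pieces)
  if (nrow(dt) == 0L) {
    dt <- data.table(kmer = character(), target_id = character(),
                     pos = integer())
  }
  setkey(dt, kmer)
  dt
}

empty_alignments <- function() {
  data.table(read_id = character(), target_id = character(),
             target_start = integer(), target_end = integer(),
             strand = character(), n_mismatches = integer(),
             score = numeric(), cigar = character(), is_multi = logical())
}

# oriented read table used by both mappers: one row per (read, strand)
oriented_reads <- function(reads) {
  fwd <- data.table(read_id = reads$id, obases = reads$bases,
                    oqual = reads$qual, sex = reads$sex, strand = "+",
                    len = nchar(reads$bases))
  rev <- data.table(read_id = reads$id, obases = revcomp(reads$bases),
                    oqual = stringi::stri_reverse(reads$qual),
                    sex = reads$sex, strand = "-", len = nchar(reads$bases))
  rbind(fwd, rev)
}

#' Exact (zero-mismatch) read placement
#'
#' Reports every position, on either strand, where the full read is an exact
#' substring of a target. Reads shorter than the seed length are rejected
#' with a warning; reads with no exact placement are simply unreported.
#' `is_multi` marks reads whose placements span more than one target.
#'
#' @param reads a [read_set()].
#' @param targets a [transcript_set()].
#' @param seed_length seed k-mer length (first k bases of the oriented read).
#' @param match_score per-base score used to fill the `score` column.
#' @return alignment data.table (`read_id`, `target_id`, `target_start`,
#'   `target_end`, `strand`, `n_mismatches`, `score`, `cigar`, `is_multi`).
#' @export
map_exact <- function(reads, targets, seed_length = 20L, match_score = 10) {
  k <- as.integer(seed_length)
  short <- nchar(reads$bases) < k
  if (any(short)) {
    warning(sum(short), " read(s) shorter than seed_length rejected")
    reads <- reads[!short]
  }
  if (nrow(reads) == 0L) return(empty_alignments())
  idx <- kmer_index(targets, k)
  orient <- oriented_reads(reads)
  orient[, kmer := substr(obases, 1L, k)]
  cand <- idx[orient, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(cand) == 0L) return(empty_alignments())
  tseq <- setNames(targets$bases, targets$id)
  tlen <- setNames(nchar(targets$bases), targets$id)
  cand[, ok := {
    s <- tseq[[.BY[[1]]]]
    substring(s, pos + 1L, pos + len) == obases
  }, by = target_id]
  hits <- cand[ok == TRUE]
  if (nrow(hits) == 0L) return(empty_alignments())
  out <- hits[, .(read_id, target_id, target_start = pos,
                  target_end = pos + len, strand, sex,
                  n_mismatches = 0L, score = len * match_score,
                  cigar = paste0(len, "M"), obases, oqual)]
  out[, is_multi := uniqueN(target_id) > 1L, by = read_id]
  setcolorder(out, c("read_id", "target_id", "target_start", "target_end",
                     "strand", "n_mismatches", "score", "cigar", "is_multi",
                     "sex", "obases", "oqual"))
  out[]
}

#' Scored read mapping with affine-gap extension
#'
#' Seed-and-extend: exact k-mer seeds are tried at successive read offsets;
#' each candidate diagonal is evaluated either by a gapless mismatch count
#' (accepted when provably optimal, i.e. at most one mismatch) or by
#' affine-gap dynamic programming over a padded target window. All
#' top-scoring placements per read are reported (ties marked via
#' `is_multi` when they span targets); alignments scoring below
#' `min_score_frac * read_length * match_score` are dropped.
#'
#' @param reads a [read_set()].
#' @param targets a [transcript_set()].
#' @param params [mapper_params()].
#' @param pad window padding (bp) around the seed diagonal for the DP.
#' @return alignment data.table as in [map_exact()].
#' @export
map_scored <- function(reads, targets, params = mapper_params(), pad = 15L) {
  k <- params$seed_length
  short <- nchar(reads$bases) < k
  if (any(short)) {
    warning(sum(short), " read(s) shorter than seed_length rejected")
    reads <- reads[!short]
  }
  if (nrow(reads) == 0L) return(empty_alignments())
  idx <- kmer_index(targets, k)
  orient <- oriented_reads(reads)
  orient[, row := .I]
  maxlen <- max(orient$len)
  offsets <- seq(0L, maxlen - k, by = k)
  cand_list <- vector("list", length(offsets))
  for (oi in seq_along(offsets)) {
    off <- offsets[oi]
    sub <- orient[len >= off + k, .(row, kmer = substr(obases, off + 1L, off + k))]
    if (nrow(sub) == 0L) next
    m <- idx[sub, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(m) == 0L) next
    cand_list[[oi]] <- m[, .(row, target_id, diag_ = pos - off)]
  }
  cand_list <- Filter(Negate(is.null), cand_list)
  if (length(cand_list) == 0L) return(empty_alignments())
  cand <- unique(rbindlist(cand_list))
  if (nrow(cand) == 0L) return(empty_alignments())
  cand <- orient[cand, on = "row"]
  tseq <- setNames(targets$bases, targets$id)
  tlenv <- setNames(nchar(targets$bases), targets$id)
  cand[, tlen := tlenv[target_id]]
  # gapless evaluation at the seed-implied diagonal
  cand[, gapless_ok := diag_ >= 0L & diag_ + len <= tlen]
  cand[, mm := NA_integer_]
  cand[gapless_ok == TRUE, mm := {
    s <- tseq[[.BY[[1]]]]
    cpp_hamming(substring(s, diag_ + 1L, diag_ + len), obases)
  }, by = target_id]
  easy <- cand[gapless_ok == TRUE & mm <= 1L]
  res_easy <- if (nrow(easy)) {
    easy[, .(row, read_id, target_id, target_start = diag_,
             target_end = diag_ + len, strand, sex,
             n_mismatches = mm,
             score = (len - mm) * params$match_score +
               mm * params$mismatch_score,
             cigar = paste0(len, "M"), obases, oqual)]
  } else NULL
  hard <- cand[!(gapless_ok == TRUE & mm <= 1L)]
  res_hard <- NULL
  if (nrow(hard)) {
    n <- nrow(hard)
    sc <- numeric(n); ts <- integer(n); te <- integer(n)
    nm <- integer(n); cg <- character(n)
    for (i in seq_len(n)) {
      tl <- hard$tlen[i]
      ws <- max(0L, hard$diag_[i] - pad)
      we <- min(tl, hard$diag_[i] + hard$len[i] + pad)
      if (we - ws < k) { sc[i] <- -Inf; next }
      win <- substring(tseq[[hard$target_id[i]]], ws + 1L, we)
      r <- cpp_fit_align(hard$obases[i], win, params$match_score,
                         params$mismatch_score, params$gap_open_penalty,
                         params$gap_extend_penalty)
      sc[i] <- r$score
      ts[i] <- ws + r$tstart
      te[i] <- ws + r$tend
      nm[i] <- r$n_mismatches
      cg[i] <- r$cigar
    }
    keep <- is.finite(sc)
    if (any(keep)) {
      res_hard <- hard[keep, .(row, read_id, target_id, target_start = ts[keep],
                               target_end = te[keep], strand, sex,
                               n_mismatches = nm[keep], score = sc[keep],
                               cigar = cg[keep], obases, oqual)]
    }
  }
  res <- rbindlist(list(res_easy, res_hard), use.names = TRUE)
  if (is.null(res) || nrow(res) == 0L) return(empty_alignments())
  # same placement can surface via several seeds
  res <- unique(res, by = c("read_id", "target_id", "target_start", "cigar",
                            "strand"))
  # threshold, then keep all top-scoring placements per read
  rl <- setNames(nchar(reads$bases), reads$id)
  res <- res[score >= params$min_score_frac * rl[read_id] * params$match_score]
  if (nrow(res) == 0L) return(empty_alignments())
  res[, best := max(score), by = read_id]
  res <- res[score >= best - 1e-9]
  res[, best := NULL]
  res[, row := NULL]
  if (is.finite(params$max_hits_reported)) {
    res <- res[, head(.SD, params$max_hits_reported), by = read_id]
  }
  res[, is_multi := uniqueN(target_id) > 1L, by = read_id]
  setcolorder(res, c("read_id", "target_id", "target_start", "target_end",
                     "strand", "n_mismatches", "score", "cigar", "is_multi",
                     "sex", "obases", "oqual"))
  res[]
}

#' Build a per-position pileup over one target
#'
#' Tallies base counts per position, split by read sex, with separate
#' quality-passing counts (base quality strictly greater than `min_bq`).
#' Depth at a position is the number of alignments overlapping it (deleted
#' positions included; `N` bases and indels never contribute allele counts to
#' the base matrices). Indel alleles are tallied at their left-aligned
#' anchor position in a separate table.
#'
#' @param alignments alignment data.table from [map_scored()] or
#'   [map_exact()] (must carry `obases`/`oqual`/`sex`).
#' @param target_id target to pile up.
#' @param target_len target length in bp.
#' @param min_bq exclusive base-quality bound (default 13: quality must be
#'   `> 13` to pass).
#' @return list with `sites` (data.table: `pos`, per-sex depth, raw and
#'   quality-passing counts for A/C/G/T) and `indels` (data.table: `pos`,
#'   `allele`, `sex`, `count`), class `"pileup"`.
#' @export
build_pileup <- function(alignments, target_id, target_len, min_bq = 13L) {
  al <- alignments[alignments$target_id == target_id]
  if (nrow(al) == 0L) {
    sites <- data.table(pos = integer(), depth_m = integer(),
                        depth_f = integer())
    for (b in c("A", "C", "G", "T")) {
      sites[, paste0("m_", b) := integer()]
      sites[, paste0("mq_", b) := integer()]
      sites[, paste0("f_", b) := integer()]
      sites[, paste0("fq_", b) := integer()]
    }
    return(structure(list(sites = sites,
                          indels = data.table(pos = integer(),
                                              allele = character(),
                                              sex = character(),
                                              count = integer()),
                          target_id = target_id, target_len = target_len),
                     class = "pileup"))
  }
  if (any(al$target_start < 0L | al$target_end > target_len)) {
    stop("alignment out of target bounds for ", target_id)
  }
  px <- cpp_pileup(al$target_start, al$obases, al$oqual, al$cigar,
                   ifelse(al$sex == "male", 0L, 1L), target_len,
                   as.integer(min_bq))
  sites <- data.table(pos = 0:(target_len - 1L),
                      depth_m = px$depth_m, depth_f = px$depth_f)
  bases <- c("A", "C", "G", "T")
  for (j in 1:4) {
    sites[, paste0("m_", bases[j]) := px$raw_m[, j]]
    sites[, paste0("mq_", bases[j]) := px$q_m[, j]]
    sites[, paste0("f_", bases[j]) := px$raw_f[, j]]
    sites[, paste0("fq_", bases[j]) := px$q_f[, j]]
  }
  indels <- data.table(pos = px$indel_pos,
                       type = px$indel_type, len = px$indel_len,
                       bases = px$indel_bases,
                       sex = ifelse(px$indel_sex == 0L, "male", "female"))
  if (nrow(indels)) {
    indels[, allele := ifelse(type == "del", paste0("-", len),
                              paste0("+", bases))]
    indels <- indels[, .(count = .N), by = .(pos, allele, sex)]
  } else {
    indels <- data.table(pos = integer(), allele = character(),
                         sex = character(), count = integer())
  }
  structure(list(sites = sites, indels = indels, target_id = target_id,
                 target_len = target_len),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup of %s (%d bp): max depth m=%d f=%d, %d indel allele(s)\n",
              x$target_id, x$target_len,
              if (nrow(x$sites)) max(x$sites$depth_m) else 0L,
              if (nrow(x$sites)) max(x$sites$depth_f) else 0L,
              nrow(x$indels)))
  invisible(x)
}
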