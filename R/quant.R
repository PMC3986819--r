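# Probabilistic assignment of zero-mismatch RNA reads between near-identical
# homologs by expectation-maximization, and FPKM computation.

#' EM quantification over ambiguous exact alignments
#'
#' Reads are collapsed into equivalence classes by their candidate target
#' set. Starting from uniform abundances, the E-step distributes each class
#' over its candidates proportional to `abundance / length`, and the M-step
#' sums the fractions. Iteration is fully deterministic and stops when the
#' largest absolute abundance change drops below `tol` (or at `max_iter`).
#' Reads hitting more than `max_candidates` targets are dropped as
#' repetitive and reported.
#'
#' @param alignments exact alignments ([map_exact()]); only
#'   `read_id`/`target_id` pairs are used.
#' @param transcripts [transcript_set()] defining lengths (and the full id
#'   universe: transcripts without reads get zero abundance).
#' @param max_iter,tol convergence controls.
#' @param max_candidates repetitive-read cutoff (default 50).
#' @param n_total_reads optional total input read count, to report reads
#'   with empty candidate sets.
#' @param keep_trace record the EM objective per iteration (attribute
#'   `loglik_trace`).
#' @return data.table: `transcript_id`, `length_bp`, `assigned_fragments`,
#'   `fpkm`, `n_unique_reads`, `n_ambiguous_reads_touching`. Attributes:
#'   `n_reads_used`, `n_dropped_repetitive`, `n_unmapped`, `n_iter`,
#'   optionally `loglik_trace`.
#' @export
em_quantify <- function(alignments, transcripts, max_iter = 1000L,
                        tol = 1e-8, max_candidates = 50L,
                        n_total_reads = NA_integer_, keep_trace = FALSE) {
  lens <- setNames(nchar(transcripts$bases), transcripts$id)
  cand <- unique(data.table(read_id = alignments$read_id,
                            target_id = alignments$target_id))
  cand <- cand[target_id %in% names(lens)]
  ncand <- cand[, .N, by = read_id]
  repetitive <- ncand[N > max_candidates, read_id]
  cand <- cand[!read_id %in% repetitive]
  n_reads <- uniqueN(cand$read_id)
  ids <- transcripts$id
  if (n_reads == 0L) {
    out <- data.table(transcript_id = ids, length_bp = unname(lens[ids]),
                      assigned_fragments = 0, fpkm = 0,
                      n_unique_reads = 0L, n_ambiguous_reads_touching = 0L)
    setattr(out, "n_reads_used", 0L)
    setattr(out, "n_dropped_repetitive", length(repetitive))
    setattr(out, "n_unmapped",
            if (is.na(n_total_reads)) NA_integer_ else n_total_reads)
    setattr(out, "n_iter", 0L)
    return(out)
  }
  # equivalence classes: identical sorted candidate sets
  setorder(cand, read_id, target_id)
  sigs <- cand[, .(sig = paste(target_id, collapse = "\r")), by = read_id]
  classes <- sigs[, .(count = .N), by = sig]
  classes[, class_id := .I]
  memb <- classes[, .(target_id = strsplit(sig, "\r", fixed = TRUE)[[1]]),
                  by = class_id]
  memb[, t_idx := match(target_id, ids)]
  counts <- classes$count
  t_len <- unname(lens[ids])
  n_t_active <- uniqueN(memb$t_idx)
  alpha <- numeric(length(ids))
  alpha[unique(memb$t_idx)] <- n_reads / n_t_active
  cid <- memb$class_id
  tid <- memb$t_idx
  inv_len <- 1 / t_len
  trace <- numeric(0)
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    w <- alpha[tid] * inv_len[tid]
    denom <- rowsum(w, cid)[, 1]
    frac <- w / denom[cid]
    contrib <- frac * counts[cid]
    alpha_new <- numeric(length(ids))
    s <- rowsum(contrib, tid)
    alpha_new[as.integer(rownames(s))] <- s[, 1]
    if (keep_trace) {
      total <- sum(alpha)
      trace <- c(trace, sum(counts * log(rowsum((alpha[tid] / total) *
                                                  inv_len[tid], cid)[, 1])))
    }
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) break
  }
  uniq <- memb[, .N, by = class_id][N == 1L, class_id]
  u_counts <- memb[class_id %in% uniq][, .(n = sum(counts[class_id])),
                                       by = t_idx]
  a_counts <- memb[!class_id %in% uniq][, .(n = sum(counts[class_id])),
                                        by = t_idx]
  out <- data.table(transcript_id = ids, length_bp = t_len,
                    assigned_fragments = alpha,
                    n_unique_reads = 0L, n_ambiguous_reads_touching = 0L)
  if (nrow(u_counts)) out[u_counts$t_idx, n_unique_reads := u_counts$n]
  if (nrow(a_counts)) out[a_counts$t_idx,
                          n_ambiguous_reads_touching := a_counts$n]
  out[, fpkm := compute_fpkm(assigned_fragments, length_bp, n_reads)]
  setcolorder(out, c("transcript_id", "length_bp", "assigned_fragments",
                     "fpkm", "n_unique_reads", "n_ambiguous_reads_touching"))
  setattr(out, "n_reads_used", n_reads)
  setattr(out, "n_dropped_repetitive", length(repetitive))
  setattr(out, "n_unmapped",
          if (is.na(n_total_reads)) NA_integer_
          else n_total_reads - n_reads - length(repetitive))
  setattr(out, "n_iter", n_iter)
  if (keep_trace) setattr(out, "loglik_trace", trace)
  out
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `fpkm = assigned / ((length/1000) * (total/1e6))`.
#'
#' @param assigned_fragments assigned fragment count(s).
#' @param transcript_length_bp transcript length(s) in bp (> 0).
#' @param total_mapped_fragments total mapped fragments (> 0).
#' @return numeric FPKM.
#' @export
compute_fpkm <- function(assigned_fragments, transcript_length_bp,
                         total_mapped_fragments) {
  if (any(transcript_length_bp <= 0)) stop("zero-length transcript")
  stopifnot(total_mapped_fragments > 0)
  assigned_fragments /
    ((transcript_length_bp / 1000) * (total_mapped_fragments / 1e6))
}
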