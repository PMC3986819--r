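# Three-way alignment (X haplotype, Y haplotype, outgroup), block filtering,
# and uncorrected pairwise divergence.

#' Block filter parameters
#'
#' @param min_block_length minimum retained block length in columns
#'   (default 100).
#' @param max_nonconserved_run longest run of non-conserved columns allowed
#'   inside a block (default 4); longer runs break blocks and are excluded.
#' @return list of validated parameters.
#' @export
block_filter_params <- function(min_block_length = 100L,
                                max_nonconserved_run = 4L) {
  stopifnot(min_block_length > 0, max_nonconserved_run > 0)
  list(min_block_length = as.integer(min_block_length),
       max_nonconserved_run = as.integer(max_nonconserved_run))
}

# global affine pairwise alignment; returns aligned character strings
global_pair <- function(a, b, params = mapper_params()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match_score, mismatch = params$mismatch_score,
    baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = params$gap_open_penalty,
    gapExtension = params$gap_extend_penalty)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

# identity over alignment columns with terminal gap runs trimmed: internal
# gaps count as mismatch (so unrelated sequences fall below the floor even
# when their gapped alignment is locally matchy), but length differences at
# the ends (UTR tails, fragmentary sequences) do not
pair_identity <- function(av, bv) {
  comp <- av != "-" & bv != "-"
  if (!any(comp)) return(0)
  span <- range(which(comp))
  idx <- span[1]:span[2]
  sum(av[idx] == bv[idx] & av[idx] != "-") / length(idx)
}

#' Align an X/Y/outgroup sequence triple
#'
#' Center-star around the X sequence: Y and the outgroup are each globally
#' aligned to X, then projected onto common columns (at each X position the
#' larger insertion of the two pairwise alignments sets the column count;
#' shorter insertions are right-padded with gaps). Triples in which either
#' pairwise identity falls below the floor are rejected (`NULL`), mirroring
#' the requirement that an alignment contain all three sequences.
#'
#' @param neoX,neoY,outgroup sequences (non-empty strings).
#' @param min_identity pairwise identity floor (default 0.6).
#' @param params [mapper_params()] scoring.
#' @return list of class `alignment_triple` with `neoX`, `neoY`, `outgroup`
#'   (equal-length aligned strings) and `kept_columns` (all-TRUE mask), or
#'   `NULL` if rejected.
#' @export
align_three_way <- function(neoX, neoY, outgroup, min_identity = 0.6,
                            params = mapper_params()) {
  stopifnot(nzchar(neoX), nzchar(neoY), nzchar(outgroup))
  p1 <- global_pair(neoX, neoY, params)
  p2 <- global_pair(neoX, outgroup, params)
  x1 <- strsplit(p1$a, "")[[1]]; y1 <- strsplit(p1$b, "")[[1]]
  x2 <- strsplit(p2$a, "")[[1]]; o2 <- strsplit(p2$b, "")[[1]]
  if (pair_identity(x1, y1) < min_identity ||
      pair_identity(x2, o2) < min_identity) {
    return(NULL)
  }
  nx <- nchar(neoX)
  # per X-slot insertions: slot i (0..nx) holds columns inserted before X
  # base i (slot nx = after the last base)
  collect <- function(xa, other) {
    ins <- vector("list", nx + 1L)
    base_other <- character(nx)
    slot <- 1L
    pend <- character(0)
    for (k in seq_along(xa)) {
      if (xa[k] == "-") {
        pend <- c(pend, other[k])
      } else {
        ins[[slot]] <- pend
        pend <- character(0)
        base_other[slot] <- other[k]
        slot <- slot + 1L
      }
    }
    ins[[nx + 1L]] <- pend
    list(ins = ins, base = base_other)
  }
  c1 <- collect(x1, y1)
  c2 <- collect(x2, o2)
  xb <- strsplit(neoX, "")[[1]]
  outX <- character(0); outY <- character(0); outO <- character(0)
  bufX <- vector("list", nx + 1L)
  for (i in seq_len(nx + 1L)) {
    n1 <- length(c1$ins[[i]]); n2 <- length(c2$ins[[i]])
    m <- max(n1, n2)
    if (m > 0L) {
      outX <- c(outX, rep("-", m))
      outY <- c(outY, c(c1$ins[[i]], rep("-", m - n1)))
      outO <- c(outO, c(c2$ins[[i]], rep("-", m - n2)))
    }
    if (i <= nx) {
      outX <- c(outX, xb[i])
      outY <- c(outY, c1$base[i])
      outO <- c(outO, c2$base[i])
    }
  }
  structure(list(neoX = paste(outX, collapse = ""),
                 neoY = paste(outY, collapse = ""),
                 outgroup = paste(outO, collapse = ""),
                 kept_columns = rep(TRUE, length(outX))),
            class = "alignment_triple")
}

#' @export
print.alignment_triple <- function(x, ...) {
  cat(sprintf("alignment_triple: %d columns, %d kept\n",
              length(x$kept_columns), sum(x$kept_columns)))
  invisible(x)
}

#' Mask poorly aligned segments of a triple
#'
#' A column is non-conserved iff it holds any gap or any mismatch among the
#' three sequences ('N' counts as mismatch). Runs of more than
#' `max_nonconserved_run` non-conserved columns break blocks and are
#' excluded; the remaining segments are retained whole iff they span at
#' least `min_block_length` columns.
#'
#' @param triple an [align_three_way()] result.
#' @param params [block_filter_params()].
#' @return the triple with an updated `kept_columns` mask.
#' @export
filter_blocks <- function(triple, params = block_filter_params()) {
  x <- strsplit(triple$neoX, "")[[1]]
  y <- strsplit(triple$neoY, "")[[1]]
  o <- strsplit(triple$outgroup, "")[[1]]
  conserved <- x != "-" & y != "-" & o != "-" &
    x == y & x == o & x != "N"
  n <- length(conserved)
  mask <- rep(FALSE, n)
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  breaker <- !r$values & r$lengths > params$max_nonconserved_run
  # segments between breaker runs
  seg_start <- 1L
  seg_id <- integer(n)
  cur <- 1L
  for (g in seq_along(r$lengths)) {
    if (breaker[g]) {
      seg_id[starts[g]:ends[g]] <- 0L
      cur <- cur + 1L
    } else {
      seg_id[starts[g]:ends[g]] <- cur
    }
  }
  for (s in setdiff(unique(seg_id), 0L)) {
    idx <- which(seg_id == s)
    if (length(idx) >= params$min_block_length) mask[idx] <- TRUE
  }
  triple$kept_columns <- mask
  triple
}

#' Uncorrected pairwise distance on masked columns
#'
#' Mismatches over comparable columns; a column is comparable when it is
#' masked-in and gap-free in both sequences.
#'
#' @param seqA_aligned,seqB_aligned equal-length aligned strings.
#' @param mask logical mask (default all columns).
#' @return proportion of mismatching comparable columns, or `NA` (flagged
#'   with a warning) when no column is comparable.
#' @export
p_distance <- function(seqA_aligned, seqB_aligned, mask = NULL) {
  a <- strsplit(seqA_aligned, "")[[1]]
  b <- strsplit(seqB_aligned, "")[[1]]
  stopifnot(length(a) == length(b))
  if (is.null(mask)) mask <- rep(TRUE, length(a))
  comp <- mask & a != "-" & b != "-"
  if (!any(comp)) {
    warning("no comparable columns; p-distance undefined")
    return(NA_real_)
  }
  sum(a[comp] != b[comp]) / sum(comp)
}

#' Per-gene divergence over a set of triples
#'
#' Runs [align_three_way()], [filter_blocks()] and [p_distance()] per gene.
#'
#' @param genes data.frame/list with columns or elements `gene`, `neoX`,
#'   `neoY`, `outgroup` (sequences).
#' @param block_params [block_filter_params()].
#' @param min_identity identity floor for triple acceptance.
#' @return data.table: `gene`, `d_XY`, `d_Y_outgroup`, `d_X_outgroup`,
#'   `comparable_columns` (masked-in columns); rejected triples are absent.
#' @export
divergence_table <- function(genes, block_params = block_filter_params(),
                             min_identity = 0.6) {
  genes <- as.data.frame(genes)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    tr <- align_three_way(genes$neoX[i], genes$neoY[i], genes$outgroup[i],
                          min_identity = min_identity)
    if (is.null(tr)) return(NULL)
    tr <- filter_blocks(tr, block_params)
    if (!any(tr$kept_columns)) return(NULL)
    data.table(
      gene = genes$gene[i],
      d_XY = p_distance(tr$neoX, tr$neoY, tr$kept_columns),
      d_Y_outgroup = p_distance(tr$neoY, tr$outgroup, tr$kept_columns),
      d_X_outgroup = p_distance(tr$neoX, tr$outgroup, tr$kept_columns),
      comparable_columns = sum(tr$kept_columns))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.table(gene = character(), d_XY = numeric(),
                      d_Y_outgroup = numeric(), d_X_outgroup = numeric(),
                      comparable_columns = integer()))
  }
  rbindlist(rows)
}
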