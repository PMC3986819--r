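# Sequence containers and I/O.
#
# Internal convention: all coordinates are 0-based, half-open. 1-based
# positions appear only in rendered report text.

CHROM_CLASSES <- c("neoX", "neoY", "autosome", "unknown")

#' Construct a transcript set
#'
#' A `transcript_set` is a data.frame with one row per transcript and columns
#' `id`, `bases`, `chrom_class` and `ref_protein_id`. Sequences are uppercase
#' DNA over `A,C,G,T,N` (`U` is converted to `T` on input). `N` bases are
#' tolerated in sequences but are never called as alleles downstream.
#'
#' @param id character vector of unique transcript ids.
#' @param bases character vector of nucleotide sequences.
#' @param chrom_class one of `"neoX"`, `"neoY"`, `"autosome"`, `"unknown"`
#'   (recycled).
#' @param ref_protein_id optional reference protein/CDS id (recycled, may be
#'   `NA`).
#' @return A `transcript_set` data.frame.
#' @export
transcript_set <- function(id, bases, chrom_class = "unknown",
                           ref_protein_id = NA_character_) {
  stopifnot(length(id) == length(bases))
  bases <- toupper(bases)
  bases <- gsub("U", "T", bases, fixed = TRUE)
  if (any(!nzchar(bases))) {
    stop("empty sequence for id(s): ",
         paste(id[!nzchar(bases)], collapse = ", "))
  }
  if (anyDuplicated(id)) {
    stop("duplicate transcript id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", bases)
  if (any(bad)) {
    stop("non-ACGTN characters in sequence(s): ",
         paste(id[bad], collapse = ", "))
  }
  chrom_class <- rep_len(as.character(chrom_class), length(id))
  if (!all(chrom_class %in% CHROM_CLASSES)) {
    stop("chrom_class must be one of: ", paste(CHROM_CLASSES, collapse = ", "))
  }
  ref_protein_id <- rep_len(as.character(ref_protein_id), length(id))
  out <- data.frame(
    id = as.character(id), bases = bases, chrom_class = chrom_class,
    ref_protein_id = ref_protein_id, stringsAsFactors = FALSE
  )
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d sequences, total %s bp\n",
              nrow(x), format(sum(nchar(x$bases)), big.mark = ",")))
  cls <- table(x$chrom_class)
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = " "),
      "\n")
  invisible(x)
}

#' Read a FASTA file into a transcript set
#'
#' Sequences are uppercased and `U` is normalized to `T`. Duplicate ids,
#' empty sequences and malformed headers raise errors naming the offending
#' line.
#'
#' @param path FASTA file path.
#' @param chrom_class class label applied to all records.
#' @return A [transcript_set()].
#' @export
read_fasta <- function(path, chrom_class = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(lines[nonempty[1]], ">")) {
    stop(sprintf("malformed FASTA: line %d does not start a record",
                 nonempty[1]))
  }
  hdr <- which(startsWith(lines, ">"))
  # empty-sequence check with line numbers before delegating the parse
  ends <- c(hdr[-1] - 1L, length(lines))
  for (k in seq_along(hdr)) {
    body <- lines[seq.int(hdr[k] + 1L, length.out = max(0L, ends[k] - hdr[k]))]
    if (sum(nchar(trimws(body))) == 0L) {
      stop(sprintf("malformed FASTA: empty sequence at line %d (%s)",
                   hdr[k], sub("^>", "", lines[hdr[k]])))
    }
  }
  dss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  transcript_set(ids, as.character(dss), chrom_class = chrom_class)
}

#' Write a transcript set as FASTA
#'
#' @param ts a [transcript_set()].
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ts, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(setNames(ts$bases, ts$id))
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Construct a read set
#'
#' A `read_set` is a data.table with columns `id`, `bases`, `qual`
#' (Phred+33 ASCII string), `sex` (`"male"`/`"female"`) and `source`
#' (`"genomic"`/`"rna"`).
#'
#' @param id,bases,qual parallel character vectors; `qual` defaults to
#'   Phred 40 throughout.
#' @param sex `"male"` or `"female"`.
#' @param source `"genomic"` or `"rna"`.
#' @return A `read_set` data.table.
#' @export
read_set <- function(id, bases, qual = NULL, sex = "male", source = "genomic") {
  bases <- toupper(bases)
  if (is.null(qual)) qual <- strrep("I", nchar(bases))
  if (any(nchar(bases) != nchar(qual))) {
    stop("bases/qual length mismatch for read(s): ",
         paste(head(id[nchar(bases) != nchar(qual)], 5), collapse = ", "))
  }
  stopifnot(all(sex %in% c("male", "female")),
            all(source %in% c("genomic", "rna")))
  out <- data.table(id = as.character(id), bases = bases, qual = qual,
                    sex = rep_len(sex, length(id)),
                    source = rep_len(source, length(id)))
  setattr(out, "class", c("read_set", class(out)))
  out[]
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual character vector of Phred+33 strings.
#' @return list of integer vectors.
#' @export
decode_quals <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Read a FASTQ file (Sanger Phred+33)
#'
#' Each record must be a well-formed 4-line block; a length mismatch between
#' sequence and quality lines, or a malformed block, raises a parse error
#' naming the line.
#'
#' @param path FASTQ path.
#' @param sex `"male"` or `"female"`.
#' @param source `"genomic"` or `"rna"`.
#' @return A [read_set()].
#' @export
read_fastq <- function(path, sex, source) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ: %d lines is not a multiple of 4 (%s)",
                 length(lines), path))
  }
  n <- length(lines) %/% 4L
  at <- function(k) lines[seq.int(k, by = 4L, length.out = n)]
  hdr <- at(1L); seqs <- at(2L); plus <- at(3L); quals <- at(4L)
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ: line %d does not start with '@'",
                 (bad[1] - 1L) * 4L + 1L))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ: line %d does not start with '+'",
                 (bad[1] - 1L) * 4L + 3L))
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ: sequence/quality length mismatch at line %d",
                 (bad[1] - 1L) * 4L + 2L))
  }
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  read_set(ids, seqs, quals, sex = sex, source = source)
}

#' Write a read set as FASTQ
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * nrow(reads))
  out[seq.int(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$id)
  out[seq.int(2L, by = 4L, length.out = nrow(reads))] <- reads$bases
  out[seq.int(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq.int(4L, by = 4L, length.out = nrow(reads))] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Write a deterministic TSV table
#'
#' Tab-separated with a header row; rows sorted by the first column (or
#' `sort_by`), columns in the given order; numeric (double) fields rendered
#' with fixed 6-decimal formatting for reproducible diffs.
#'
#' @param records data.frame.
#' @param path output path.
#' @param sort_by column name(s) to sort rows by; default first column.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, sort_by = NULL) {
  records <- as.data.frame(records)
  if (is.null(sort_by)) sort_by <- names(records)[1]
  if (nrow(records) > 0L) {
    ord <- do.call(order, unname(records[sort_by]))
    records <- records[ord, , drop = FALSE]
  }
  for (j in seq_along(records)) {
    if (is.double(records[[j]])) {
      records[[j]] <- sprintf("%.6f", records[[j]])
    }
  }
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}
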