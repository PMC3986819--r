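# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force exact placement: scan every window of every target on both
# strands
brute_exact <- function(reads, targets) {
  out <- list()
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }
  for (i in seq_len(nrow(reads))) {
    rd <- reads$bases[i]
    for (str_ in c("+", "-")) {
      q <- if (str_ == "+") rd else rc(rd)
      L <- nchar(q)
      for (j in seq_len(nrow(targets))) {
        s <- targets$bases[j]
        n <- nchar(s)
        if (n < L) next
        for (p in 0:(n - L)) {
          if (substr(s, p + 1L, p + L) == q) {
            out[[length(out) + 1L]] <- data.frame(
              read_id = reads$id[i], target_id = targets$id[j],
              target_start = p, target_end = p + L, strand = str_,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(read_id = character(), target_id = character(),
                      target_start = integer(), target_end = integer(),
                      strand = character()))
  }
  do.call(rbind, out)
}

# affine-gap DP oracle via Biostrings (overlap = free target ends,
# read global) for scoring comparisons
dp_oracle_score <- function(read, target, match = 10, mismatch = -5,
                            gap_open = 10, gap_extend = 6.6) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  # Biostrings charges open+extend for a length-1 gap when gapOpening=open
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(target),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
}

# N50 by direct enumeration over prefixes of the sorted lengths
brute_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(as.numeric(s)) / 2
  tot <- 0
  for (x in s) {
    tot <- tot + x
    if (tot >= half) return(as.integer(x))
  }
}

# truth-table oracle for site categorization, written straight from the
# three category definitions (male polymorphic = ref + alt called; CAT1
# female fixed for a different variant; CAT2 both sexes show a variant;
# CAT3 female shows none)
oracle_categorize <- function(male_called, female_called, ref,
                              female_ref_qual = 0L) {
  m_alt <- setdiff(male_called, ref)
  f_alt <- setdiff(female_called, ref)
  male_poly <- ref %in% male_called && length(m_alt) >= 1L
  if (male_poly && length(female_called) == 1L && length(f_alt) == 1L &&
      female_ref_qual == 0L) {
    return("CAT1")
  }
  if ((length(m_alt) >= 1L && length(f_alt) >= 1L) || length(m_alt) >= 2L) {
    return("CAT2")
  }
  if (male_poly && length(m_alt) == 1L && length(f_alt) == 0L) {
    return("CAT3")
  }
  "INVARIANT"
}

# caller oracle from the stated support rule
oracle_call <- function(counts_q, depth_raw, min_alt = 3L, min_alt_low = 2L,
                        lowcov = 9L) {
  thr <- if (depth_raw <= lowcov) min_alt_low else min_alt
  names(counts_q)[counts_q >= thr]
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a sequence at a per-site substitution rate (test-side)
mutate_dna <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# a random CDS: ATG + sense codons + one stop (test-side construction)
random_cds_test <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste,
                      collapse = "")
  sense <- setdiff(all_codons, stops)
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), sample(stops, 1))
}

# a CDS free of T except its terminal stop: no reading frame of it can
# produce a premature stop codon, so a frameshift stays PTC-free
no_t_cds <- function(n_codons) {
  pool <- c("CCA", "CAC", "ACC", "AAC", "CAA", "ACA", "CCC", "AAA")
  paste0("ATG", paste(sample(pool, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

# uniform error-free reads from one sequence (test-side read generator)
reads_from <- function(bases, depth, L, prefix, sex = "male",
                       source = "genomic") {
  n <- round(depth * nchar(bases) / L)
  starts <- sample.int(nchar(bases) - L + 1L, n, replace = TRUE)
  seqs <- substring(bases, starts, starts + L - 1L)
  read_set(sprintf("%s_%04d", prefix, seq_len(n)), seqs,
           sex = sex, source = source)
}
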