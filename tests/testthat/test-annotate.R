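test_that("assign_ids_rbh assigns mutual best hits only", {
  set.seed(21)
  refs <- transcript_set(c("r1", "r2", "r3"),
                         vapply(1:3, function(i) rand_dna(600), character(1)))
  # q1 ~ r1, q2 ~ r2; q3 is unrelated
  queries <- transcript_set(
    c("q1", "q2", "q3"),
    c(mutate_dna(refs$bases[1], 0.02), mutate_dna(refs$bases[2], 0.02),
      rand_dna(600)))
  got <- assign_ids_rbh(queries, refs)
  expect_equal(got$transcript_id, c("q1", "q2"))
  expect_equal(got$reference_id, c("r1", "r2"))
  expect_false(any(got$tie_broken))
  # symmetry: swapping roles maps the same pairs
  rev_ <- assign_ids_rbh(refs, queries)
  expect_equal(sort(paste(rev_$reference_id, rev_$transcript_id)),
               sort(paste(got$transcript_id, got$reference_id)))
})

test_that("rbh: competition for one reference leaves the loser unassigned, ties are flagged", {
  set.seed(22)
  base <- rand_dna(600)
  refs <- transcript_set("r1", base)
  # q_far's best is r1 but r1's best is q_near
  queries <- transcript_set(c("q_near", "q_far"),
                            c(mutate_dna(base, 0.01), mutate_dna(base, 0.08)))
  got <- assign_ids_rbh(queries, refs)
  expect_equal(got$transcript_id, "q_near")
  # two identical queries: lexicographically smaller id wins, flagged
  queries2 <- transcript_set(c("qb", "qa"), c(base, base))
  got2 <- assign_ids_rbh(queries2, refs)
  expect_equal(got2$transcript_id, "qa")
  expect_true(got2$tie_broken)
})

test_that("merge_fragments honors overlap-length and identity thresholds", {
  set.seed(23)
  a <- rand_dna(150)
  b <- paste0(substr(a, 101, 150), rand_dna(100))
  m <- merge_fragments(c(A = a, B = b))
  expect_equal(length(m), 1L)
  expect_equal(nchar(m[[1]]), 150L + 150L - 50L)
  expect_equal(m[[1]], paste0(a, substr(b, 51, 150)))
  # overlap below the length threshold
  b30 <- paste0(substr(a, 121, 150), rand_dna(100))
  expect_equal(length(merge_fragments(c(A = a, B = b30))), 2L)
  # overlap at 95% identity is a disagreeing overlap
  ov <- substr(a, 101, 150)
  ov_mut <- ov
  for (i in c(5, 15, 25)) substr(ov_mut, i, i) <-
      setdiff(c("A", "C", "G", "T"), substr(ov, i, i))[1]
  b_bad <- paste0(ov_mut, rand_dna(100))
  expect_equal(length(merge_fragments(c(A = a, B = b_bad))), 2L)
})

test_that("scaffold_by_protein joins fragments with N runs sized by the reference gap", {
  set.seed(24)
  cds <- random_cds_test(300)
  # fragments covering residues 1-100 and 151-250
  f1 <- substr(cds, 1, 300)
  f2 <- substr(cds, 451, 750)
  sc <- scaffold_by_protein(c(f1, f2), cds)
  expect_equal(nchar(sc), 300L + 150L + 300L)
  expect_equal(substr(sc, 301, 450), strrep("N", 150))
  # single fragment returned unchanged
  expect_equal(scaffold_by_protein(f1, cds), f1)
  # reverse-frame fragment is reverse-complemented before joining
  sc2 <- scaffold_by_protein(c(f1, revcomp(f2)), cds)
  expect_equal(sc2, sc)
})

test_that("align_to_reference_cds: identity, gaps, and the unalignable floor", {
  set.seed(25)
  cds <- random_cds_test(200)
  al <- align_to_reference_cds(cds, cds)
  expect_equal(al$identity, 1.0)
  expect_false(al$unalignable)
  expect_false(grepl("-", al$tx_aln))
  # a 2-bp deletion shows up as a single gap
  tx <- paste0(substr(cds, 1, 300), substr(cds, 303, nchar(cds)))
  al2 <- align_to_reference_cds(tx, cds)
  expect_equal(sum(gregexpr("-", al2$tx_aln)[[1]] > 0), 2L)
  # unrelated sequence
  al3 <- align_to_reference_cds(rand_dna(600), cds)
  expect_true(al3$unalignable)
})

test_that("classify_orf recovers PTCs and frameshifts from constructed lesions", {
  set.seed(26)
  cds <- random_cds_test(200) # 200 codons incl stop
  # intact
  al <- align_to_reference_cds(cds, cds)
  expect_equal(classify_orf(al, cds)$status, "intact")
  # codon 50 mutated to TAA: ptc with relative position 0.25
  tx <- paste0(substr(cds, 1, 147), "TAA", substr(cds, 151, nchar(cds)))
  orf <- classify_orf(align_to_reference_cds(tx, cds), cds)
  expect_equal(orf$status, "ptc")
  expect_equal(orf$first_ptc_codon_index, 50L)
  expect_equal(orf$first_ptc_relative, 0.25)
  # 1-bp deletion at codon 30 in a T-free CDS: the shifted frame cannot
  # contain a stop, so the status is frameshift-only
  ref2 <- no_t_cds(200)
  tx_fs <- paste0(substr(ref2, 1, 88), substring(ref2, 90))
  orf2 <- classify_orf(align_to_reference_cds(tx_fs, ref2), ref2)
  expect_equal(orf2$status, "frameshift_only")
  expect_equal(length(orf2$frameshift_positions), 1L)
  # the recorded position is near codon 30 (gap placement may drift within
  # repeats; the contract is +/- 1 codon)
  expect_lt(abs(orf2$frameshift_positions[1] - 88), 10)
})

test_that("utr3_lengths measures from the first and the ancestral stop", {
  # 1000-bp transcript whose first stop codon ends at position 700
  orf <- structure(list(first_ptc_codon_index = NA_integer_,
                        first_stop_tx_end = 700L,
                        ancestral_stop_tx_end = 700L),
                   class = "orf_annotation")
  u <- utr3_lengths(strrep("A", 1000), orf)
  expect_equal(u$utr3_from_first_stop_bp, 300L)
  expect_true(is.na(u$utr3_from_ancestral_stop_bp))
  # PTC ending at 300, ancestral stop ending at 900
  orf2 <- structure(list(first_ptc_codon_index = 10L,
                         first_stop_tx_end = 300L,
                         ancestral_stop_tx_end = 900L),
                    class = "orf_annotation")
  u2 <- utr3_lengths(strrep("A", 1000), orf2)
  expect_equal(u2$utr3_from_first_stop_bp, 700L)
  expect_equal(u2$utr3_from_ancestral_stop_bp, 100L)
  # stop in the final 3 bp
  orf3 <- structure(list(first_ptc_codon_index = NA_integer_,
                         first_stop_tx_end = 1000L,
                         ancestral_stop_tx_end = 1000L),
                    class = "orf_annotation")
  expect_equal(utr3_lengths(strrep("A", 1000), orf3)$utr3_from_first_stop_bp,
               0L)
  # no stop found anywhere: both undefined
  orf4 <- structure(list(first_ptc_codon_index = NA_integer_,
                         first_stop_tx_end = NA_integer_,
                         ancestral_stop_tx_end = NA_integer_),
                    class = "orf_annotation")
  expect_true(all(is.na(unlist(utr3_lengths(strrep("A", 100), orf4)))))
})
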