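mk_cand <- function(read_ids, target_ids) {
  data.table::data.table(read_id = read_ids, target_id = target_ids)
}

two_homologs <- function(len = 1000L) {
  transcript_set(c("X", "Y"), c(rand_dna(len), rand_dna(len)))
}

test_that("em_quantify reproduces the closed-form fixed points", {
  tx <- two_homologs()
  # 10 unique to each, 100 ambiguous: symmetric fixed point 60/60
  al <- rbind(
    mk_cand(sprintf("ux%02d", 1:10), "X"),
    mk_cand(sprintf("uy%02d", 1:10), "Y"),
    mk_cand(rep(sprintf("am%03d", 1:100), each = 2), rep(c("X", "Y"), 100)))
  ab <- em_quantify(al, tx)
  expect_equal(ab$assigned_fragments, c(60, 60), tolerance = 1e-6)
  # 30/10 unique, 60 ambiguous: x = 30 + 0.6x -> 75 / 25
  al2 <- rbind(
    mk_cand(sprintf("ux%02d", 1:30), "X"),
    mk_cand(sprintf("uy%02d", 1:10), "Y"),
    mk_cand(rep(sprintf("am%03d", 1:60), each = 2), rep(c("X", "Y"), 60)))
  ab2 <- em_quantify(al2, tx)
  expect_equal(ab2[ab2$transcript_id == "X", ]$assigned_fragments, 75,
               tolerance = 1e-6)
  expect_equal(ab2[ab2$transcript_id == "Y", ]$assigned_fragments, 25,
               tolerance = 1e-6)
  expect_equal(ab2$n_unique_reads, c(30L, 10L))
  expect_equal(ab2$n_ambiguous_reads_touching, c(60L, 60L))
})

test_that("reads are conserved and the EM objective is monotone", {
  set.seed(41)
  tx <- transcript_set(paste0("t", 1:5),
                       vapply(c(500, 800, 1000, 1500, 2000), rand_dna,
                              character(1)))
  # random candidate structure
  al <- data.table::rbindlist(lapply(1:400, function(i) {
    k <- sample(1:3, 1)
    mk_cand(rep(sprintf("r%03d", i), k), sample(tx$id, k))
  }))
  ab <- em_quantify(al, tx, keep_trace = TRUE)
  expect_equal(sum(ab$assigned_fragments), 400, tolerance = 1e-6)
  tr <- attr(ab, "loglik_trace")
  expect_true(all(diff(tr) > -1e-9))
  # all-unique reads reduce to raw counts
  alu <- mk_cand(sprintf("r%03d", 1:50), sample(tx$id, 50, replace = TRUE))
  abu <- em_quantify(alu, tx)
  raw <- table(factor(alu$target_id, levels = tx$id))
  expect_equal(abu$assigned_fragments, as.numeric(raw))
})

test_that("results are invariant to transcript input order", {
  set.seed(42)
  tx <- transcript_set(paste0("t", 1:4),
                       vapply(c(600, 900, 1200, 700), rand_dna, character(1)))
  al <- data.table::rbindlist(lapply(1:200, function(i) {
    k <- sample(1:2, 1)
    mk_cand(rep(sprintf("r%03d", i), k), sample(tx$id, k))
  }))
  ab1 <- em_quantify(al, tx)
  perm <- tx[c(3, 1, 4, 2), ]
  perm <- transcript_set(perm$id, perm$bases)
  ab2 <- em_quantify(al, perm)
  m <- merge(as.data.frame(ab1), as.data.frame(ab2), by = "transcript_id")
  expect_equal(m$assigned_fragments.x, m$assigned_fragments.y,
               tolerance = 1e-9)
})

test_that("repetitive reads are dropped and counted", {
  tx <- transcript_set(paste0("t", 1:60), vapply(rep(500, 60), rand_dna,
                                                 character(1)))
  al <- rbind(mk_cand(rep("rep1", 55), tx$id[1:55]),
              mk_cand("ok1", "t1"))
  ab <- em_quantify(al, tx, max_candidates = 50)
  expect_equal(attr(ab, "n_dropped_repetitive"), 1L)
  expect_equal(attr(ab, "n_reads_used"), 1L)
  expect_equal(sum(ab$assigned_fragments), 1)
})

test_that("compute_fpkm follows the definition", {
  expect_equal(compute_fpkm(100, 2000, 1e6), 50)
  expect_equal(compute_fpkm(0, 2000, 1e6), 0)
  expect_equal(compute_fpkm(250, 500, 5e6), 100)
  expect_error(compute_fpkm(10, 0, 1e6), "zero-length")
})

test_that("allele-ratio recovery within 10% at 50x coverage", {
  set.seed(43)
  L <- 100L
  x <- rand_dna(2000)
  y <- mutate_dna(x, 0.015)
  tx <- transcript_set(c("X", "Y"), c(x, y))
  for (r in c(0.1, 0.5, 1.0)) {
    # 50x coverage of the two-homolog transcriptome, Y:X expression ratio r
    total <- 50 * (2000 + 2000) / L
    nx <- round(total / (1 + r))
    ny <- round(total * r / (1 + r))
    reads <- rbind(reads_from(x, nx * L / 2000, L, "x", source = "rna"),
                   reads_from(y, ny * L / 2000, L, "y", source = "rna"))
    al <- map_exact(reads, tx)
    ab <- em_quantify(al, tx)
    est <- ab[ab$transcript_id == "Y", ]$assigned_fragments /
      ab[ab$transcript_id == "X", ]$assigned_fragments
    expect_lt(abs(est - r) / r, 0.10)
  }
})
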