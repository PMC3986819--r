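test_that("map_exact equals the brute-force all-window scan", {
  set.seed(11)
  for (rep_ in 1:3) {
    targets <- transcript_set(paste0("t", 1:4),
                              vapply(1:4, function(i) rand_dna(300),
                                     character(1)))
    # reads: true substrings, reverse complements, one shared subsequence,
    # and one random (unmappable) read
    shared <- substr(targets$bases[1], 100, 149)
    t2 <- targets$bases[2]
    targets$bases[2] <- paste0(substr(t2, 1, 150), shared,
                               substr(t2, 201, 300))
    reads <- read_set(
      paste0("r", 1:5),
      c(substr(targets$bases[1], 11, 60),
        revcomp(substr(targets$bases[3], 51, 100)),
        shared,
        rand_dna(50),
        substr(targets$bases[4], 251, 300)))
    got <- map_exact(reads, targets, seed_length = 20)
    want <- brute_exact(reads, targets)
    key <- function(d) sort(paste(d$read_id, d$target_id, d$target_start,
                                  d$strand))
    expect_equal(key(got), key(want))
    # multi-target read flagged on every placement
    expect_true(all(got[got$read_id == "r3", ]$is_multi))
    expect_true(all(!got[got$read_id == "r1", ]$is_multi))
  }
})

test_that("map_exact admits zero mismatches and rejects short reads", {
  targets <- transcript_set("t1", rand_dna(500))
  rd <- substr(targets$bases, 101, 200)
  one_off <- paste0("A", substr(rd, 2, 100))
  if (substr(rd, 1, 1) == "A") one_off <- paste0("C", substr(rd, 2, 100))
  reads <- read_set(c("hit", "miss"), c(rd, one_off))
  got <- map_exact(reads, targets)
  expect_equal(got$read_id, "hit")
  expect_equal(got$target_start, 100L)
  expect_equal(got$n_mismatches, 0L)
  expect_warning(map_exact(read_set("s", "ACGT"), targets), "seed_length")
})

test_that("map_scored scores match the affine DP oracle on random pairs", {
  set.seed(12)
  params <- mapper_params()
  for (i in 1:12) {
    target <- rand_dna(400)
    start <- sample(50:250, 1)
    read <- substr(target, start, start + 99)
    kind <- i %% 3
    if (kind == 1) { # mismatches
      read <- mutate_dna(read, 0.03)
    } else if (kind == 2) { # deletion in the read
      p <- sample(30:70, 1)
      read <- paste0(substr(target, start, start + p - 1),
                     substr(target, start + p + 2, start + 101))
    }
    got <- map_scored(read_set("r", read), transcript_set("t", target),
                      params = params)
    expect_gte(nrow(got), 1L)
    oracle <- dp_oracle_score(read, target)
    # the oracle backend keeps scores in single precision
    expect_equal(max(got$score), oracle, tolerance = 1e-6)
  }
})

test_that("map_scored scoring: one mismatch and a 2-bp deletion", {
  set.seed(13)
  target <- rand_dna(400)
  p <- mapper_params()
  rd <- substr(target, 101, 200)
  sub <- substr(rd, 50, 50)
  rd_mm <- paste0(substr(rd, 1, 49),
                  setdiff(c("A", "C", "G", "T"), sub)[1],
                  substr(rd, 51, 100))
  got <- map_scored(read_set("r", rd_mm), transcript_set("t", target))
  expect_equal(got$score, 99 * p$match_score + p$mismatch_score)
  expect_equal(got$n_mismatches, 1L)
  rd_del <- paste0(substr(target, 101, 150), substr(target, 153, 200))
  got2 <- map_scored(read_set("r", rd_del), transcript_set("t", target))
  expect_equal(got2$score,
               98 * p$match_score -
                 (p$gap_open_penalty + 2 * p$gap_extend_penalty),
               tolerance = 1e-9)
  # read matching nowhere above threshold is unreported
  got3 <- map_scored(read_set("r", rand_dna(100)), transcript_set("t", target))
  expect_equal(nrow(got3), 0L)
})

test_that("pileup depth equals covering alignments; quality bound is exclusive", {
  target <- transcript_set("t", rand_dna(200))
  r1 <- substr(target$bases, 1, 100)    # covers [0,100)
  r2 <- substr(target$bases, 51, 150)   # covers [50,150)
  reads <- read_set(c("a", "b"), c(r1, r2), sex = "male")
  al <- map_exact(reads, target)
  pu <- build_pileup(al, "t", 200)
  expect_equal(pu$sites$depth_m[1:50], rep(1L, 50))
  expect_equal(pu$sites$depth_m[51:100], rep(2L, 50))
  expect_equal(pu$sites$depth_m[101:150], rep(1L, 50))
  expect_equal(pu$sites$depth_m[151:200], rep(0L, 50))
  # Phred 13 ('.') counts in raw depth but not the quality-passing tally
  q <- paste0(strrep("I", 9), ".", strrep("I", 90))
  reads2 <- read_set("c", r1, q, sex = "male")
  pu2 <- build_pileup(map_exact(reads2, target), "t", 200, min_bq = 13)
  b10 <- substr(target$bases, 10, 10)
  expect_equal(pu2$sites$depth_m[10], 1L)
  expect_equal(pu2$sites[[paste0("m_", b10)]][10], 1L)
  expect_equal(pu2$sites[[paste0("mq_", b10)]][10], 0L)
})

test_that("pileup counts deletion alleles at their left-aligned anchor", {
  target <- transcript_set("t", paste0(rand_dna(80), "ACGTACGT", rand_dna(80)))
  # read with a 2-bp deletion relative to the target at positions 84-85
  rd <- paste0(substr(target$bases, 21, 84), substr(target$bases, 87, 122))
  al <- map_scored(read_set("d", rd, sex = "female"), target)
  expect_equal(nrow(al), 1L)
  pu <- build_pileup(al, "t", nchar(target$bases))
  expect_equal(nrow(pu$indels), 1L)
  expect_equal(pu$indels$sex, "female")
  expect_match(pu$indels$allele, "^-2$")
  # deleted positions still contribute to depth
  expect_equal(pu$sites$depth_f[pu$indels$pos + 1L], 1L)
})

test_that("alignments out of target bounds raise an error in pileup", {
  al <- data.table::data.table(
    read_id = "r", target_id = "t", target_start = 190L, target_end = 290L,
    strand = "+", n_mismatches = 0L, score = 1000, cigar = "100M",
    is_multi = FALSE, sex = "male", obases = rand_dna(100),
    oqual = strrep("I", 100))
  expect_error(build_pileup(al, "t", 200), "bounds")
})
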