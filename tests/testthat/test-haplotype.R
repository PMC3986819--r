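mk_aln <- function(starts, ends) {
  data.table::data.table(target_start = starts, target_end = ends)
}

test_that("split_into_exons cuts at low-overlap junctions", {
  tx <- rand_dna(220)
  # overlap 5 -> junction at the left read's end; overlap bases stay left
  p <- split_into_exons(substr(tx, 1, 195), mk_aln(c(0L, 95L), c(100L, 195L)))
  expect_equal(p$start, c(0L, 100L))
  expect_equal(p$end, c(100L, 195L))
  expect_equal(p$bases, c(substr(tx, 1, 100), substr(tx, 101, 195)))
  # all overlaps >= 6: a single covered span
  p2 <- split_into_exons(substr(tx, 1, 195),
                         mk_aln(c(0L, 94L), c(100L, 195L)))
  expect_equal(nrow(p2), 1L)
  expect_equal(c(p2$start, p2$end), c(0L, 195L))
  # a gap is also a junction; the uncovered stretch is dropped
  p3 <- split_into_exons(tx, mk_aln(c(0L, 120L), c(100L, 220L)))
  expect_equal(p3$start, c(0L, 120L))
  expect_equal(p3$end, c(100L, 220L))
  # no coverage at all
  expect_equal(nrow(split_into_exons(tx, mk_aln(integer(), integer()))), 0L)
})

test_that("call_site applies the support rule at both coverage regimes", {
  prm <- caller_params()
  expect_true("G" %in% call_site(c(A = 40, G = 3), 45, prm))
  expect_true("G" %in% call_site(c(A = 7, G = 2), 9, prm))
  expect_false("G" %in% call_site(c(A = 8, G = 2), 10, prm))
  # three reads at Phred 13 fail the exclusive bound upstream: the caller
  # sees a quality-passing count of 0
  expect_false("G" %in% call_site(c(A = 40, G = 0), 43, prm))
})

test_that("call_site matches the oracle over exhaustive depth/count grids", {
  prm <- caller_params()
  for (depth in c(1:12, 45L)) {
    for (ref_n in 0:min(depth, 6L)) {
      for (alt_n in 0:min(depth - ref_n, 6L)) {
        counts <- c(A = ref_n, G = alt_n)
        expect_identical(call_site(counts, depth, prm),
                         oracle_call(counts, depth),
                         info = sprintf("d=%d ref=%d alt=%d",
                                        depth, ref_n, alt_n))
      }
    }
  }
})

test_that("categorize_site reproduces the category definitions", {
  # CAT3: males polymorphic, females show nothing non-reference
  r <- categorize_site(c("A", "G"), "A", "A")
  expect_equal(r$category, "CAT3")
  expect_equal(r$substitution_allele, "G")
  # CAT1: males polymorphic, females fixed for the variant
  r <- categorize_site(c("A", "G"), "G", "A")
  expect_equal(r$category, "CAT1")
  expect_equal(r$substitution_allele, "G")
  # CAT2: both sexes show the variant; left unchanged
  r <- categorize_site(c("A", "G"), c("A", "G"), "A")
  expect_equal(r$category, "CAT2")
  expect_true(is.na(r$substitution_allele))
  # invariant
  r <- categorize_site("A", "A", "A")
  expect_equal(r$category, "INVARIANT")
  # residual female reference support defeats the strict CAT1 clause
  r <- categorize_site(c("A", "G"), "G", "A", female_ref_qual = 2L)
  expect_equal(r$category, "CAT2")
  # multi-allelic males cannot define a unique Y allele
  r <- categorize_site(c("A", "G", "T"), "A", "A")
  expect_equal(r$category, "CAT2")
})

test_that("categorize_site agrees with the truth-table oracle on all called-set combos", {
  sets <- list(character(0), "A", "G", c("A", "G"))
  for (m in sets) {
    for (f in sets) {
      for (frq in c(0L, 1L)) {
        got <- categorize_site(m, f, "A", female_ref_qual = frq)$category
        want <- oracle_categorize(m, f, "A", female_ref_qual = frq)
        expect_identical(got, want,
                         info = sprintf("m={%s} f={%s} frq=%d",
                                        paste(m, collapse = ","),
                                        paste(f, collapse = ","), frq))
      }
    }
  }
})

mk_sites <- function(pos, ref, sub, category = "CAT3") {
  data.table::data.table(target_id = "t", pos = pos, ref_allele = ref,
                         male_alleles = "", female_alleles = "",
                         category = category, substitution_allele = sub,
                         depth_m = 20L, depth_f = 30L)
}

test_that("rewrite_haplotype substitutes CAT3 alleles and maps coordinates", {
  # single SNV
  r <- rewrite_haplotype("ACGTACGT", mk_sites(2L, "G", "T"), "toY")
  expect_equal(r$bases, "ACTTACGT")
  expect_equal(r$coord_map, 0:7)
  # no CAT3 sites: identity
  r0 <- rewrite_haplotype("ACGTACGT", mk_sites(2L, "G", "T", "CAT2"), "toY")
  expect_equal(r0$bases, "ACGTACGT")
  # 2-bp deletion at pos 4 on a 100-bp transcript: 98 bp out, pos 50 -> 48
  tx <- rand_dna(100)
  r2 <- rewrite_haplotype(tx, mk_sites(4L, substr(tx, 5, 6), "-2"), "toY")
  expect_equal(nchar(r2$bases), 98L)
  expect_equal(r2$bases, paste0(substr(tx, 1, 4), substr(tx, 7, 100)))
  expect_equal(r2$coord_map[51], 48L)
  expect_true(all(is.na(r2$coord_map[5:6])))
  # insertion shifts downstream coordinates the other way
  r3 <- rewrite_haplotype(tx, mk_sites(9L, substr(tx, 10, 10), "+TT"), "toY")
  expect_equal(nchar(r3$bases), 102L)
  expect_equal(r3$coord_map[51], 52L)
  # stale site list: observed base matches neither ref nor substitution
  others <- setdiff(c("A", "C", "G", "T"), substr(tx, 5, 5))
  expect_error(
    rewrite_haplotype(tx, mk_sites(4L, others[1], others[2]), "toY"),
    "stale")
})

test_that("rewrite_haplotype is idempotent on SNV site lists", {
  set.seed(31)
  tx <- rand_dna(300)
  pos <- sort(sample(0:299, 12))
  refs <- substring(tx, pos + 1, pos + 1)
  subs <- vapply(refs, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                 character(1))
  sites <- mk_sites(pos, refs, subs)
  r1 <- rewrite_haplotype(tx, sites, "toY")
  r2 <- rewrite_haplotype(r1$bases, sites, "toY")
  expect_identical(r1$bases, r2$bases)
})

test_that("rewrite toX restores the female/reference alleles", {
  # CAT1: transcript already carries the Y variant; X-ward takes the female
  # allele
  r <- rewrite_haplotype("ACGTACGT", mk_sites(2L, "G", "A", "CAT1"), "toX")
  expect_equal(r$bases, "ACATACGT")
  # CAT3 site whose transcript base is the male-specific variant reverts to
  # the reference
  sites <- mk_sites(2L, "C", "G")
  r2 <- rewrite_haplotype("ACGTACGT", sites, "toX")
  expect_equal(r2$bases, "ACCTACGT")
})

test_that("filter_supported_regions keeps covered runs with diagnostic sites", {
  al <- function(s, e) data.table::data.table(target_start = s, target_end = e)
  # fully covered with one diagnostic site
  k <- filter_supported_regions(100L, al(c(0L, 60L), c(70L, 100L)), 30L)
  expect_equal(nrow(k), 1L)
  expect_equal(c(k$start, k$end, k$n_diagnostic_sites), c(0L, 100L, 1L))
  # zero RNA coverage
  expect_equal(nrow(filter_supported_regions(100L, al(integer(), integer()),
                                             30L)), 0L)
  # two covered runs, diagnostic site only in the second
  k2 <- filter_supported_regions(200L, al(c(0L, 120L), c(80L, 200L)), 150L)
  expect_equal(nrow(k2), 1L)
  expect_equal(c(k2$start, k2$end), c(120L, 200L))
  expect_equal(k2$rna_min_coverage, 1L)
})
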