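test_that("align_three_way handles identity, indels, and rejection", {
  set.seed(51)
  x <- rand_dna(400)
  # identical sequences: gapless
  tr <- align_three_way(x, x, x)
  expect_equal(nchar(tr$neoX), 400L)
  expect_false(grepl("-", paste0(tr$neoX, tr$neoY, tr$outgroup)))
  # a 3-bp deletion in the Y projects to a single 3-column gap
  y <- paste0(substr(x, 1, 200), substring(x, 204))
  tr2 <- align_three_way(x, y, x)
  expect_equal(nchar(tr2$neoX), 400L)
  gap_runs <- rle(strsplit(tr2$neoY, "")[[1]] == "-")
  expect_equal(sum(gap_runs$values), 1L)
  expect_equal(gap_runs$lengths[gap_runs$values], 3L)
  # unrelated outgroup: triple rejected
  expect_null(align_three_way(x, mutate_dna(x, 0.02), rand_dna(400)))
})

test_that("filter_blocks excludes breaker runs and short blocks", {
  set.seed(52)
  x <- rand_dna(300)
  # a 5-column non-conserved run in the middle: run excluded, both flanks
  # kept (each >= 100)
  y <- x
  for (i in 148:152) substr(y, i, i) <-
      setdiff(c("A", "C", "G", "T"), substr(x, i, i))[1]
  tr <- align_three_way(x, y, x)
  tr <- filter_blocks(tr)
  expect_equal(sum(tr$kept_columns), 295L)
  expect_false(any(tr$kept_columns[148:152]))
  # fully conserved: everything kept
  trc <- filter_blocks(align_three_way(x, x, x))
  expect_true(all(trc$kept_columns))
  # 90 columns total: below the minimum block length
  s <- rand_dna(90)
  tr90 <- filter_blocks(align_three_way(s, s, s))
  expect_false(any(tr90$kept_columns))
  # short (<= 4) non-conserved runs stay inside their block
  y2 <- x
  for (i in 148:151) substr(y2, i, i) <-
      setdiff(c("A", "C", "G", "T"), substr(x, i, i))[1]
  tr4 <- filter_blocks(align_three_way(x, y2, x))
  expect_true(all(tr4$kept_columns))
})

test_that("p_distance counts mismatches over comparable columns", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste0(strrep("A", 98), "CC")
  expect_equal(p_distance(a, b), 0.02)
  expect_equal(p_distance(a, a), 0)
  # gap columns are excluded from the denominator
  a2 <- paste0(strrep("A", 90), strrep("-", 10))
  b2 <- paste0(strrep("A", 87), "CCC", strrep("A", 10))
  expect_equal(p_distance(a2, b2), 3 / 90)
  # symmetry
  expect_equal(p_distance(b2, a2), p_distance(a2, b2))
  # no comparable columns: NA with a warning
  expect_warning(v <- p_distance("---", "AAA"), "undefined")
  expect_true(is.na(v))
})

test_that("median p-distances across simulated triples track the configured divergences", {
  set.seed(53)
  sim <- simulate_gene_set(sim_config(n_genes = 110L, n_autosomes = 0L,
                                      mean_cds_codons = 300L, seed = 53L))
  genes <- data.frame(
    gene = names(sim$truth$neoY_transcripts),
    neoX = unname(sim$truth$neoX_transcripts[
      names(sim$truth$neoY_transcripts)]),
    neoY = unname(sim$truth$neoY_transcripts),
    outgroup = unname(setNames(sim$outgroup_cds$bases, sim$outgroup_cds$id)[
      sub("^g", "r", names(sim$truth$neoY_transcripts))]))
  dv <- divergence_table(genes)
  expect_gte(nrow(dv), 100L)
  expect_lt(abs(median(dv$d_XY) - 0.015) / 0.015, 0.15)
  expect_lt(abs(median(dv$d_Y_outgroup) - 0.021) / 0.021, 0.15)
  # masks are deterministic: a rerun reproduces the table exactly
  dv2 <- divergence_table(genes)
  expect_identical(dv, dv2)
})
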