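# Shared simulation fixtures, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

# small end-to-end bundle: 12 neo genes + 4 autosome controls, seed 7
small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- sim_config(n_genes = 12L, n_autosomes = 4L,
                      mean_cds_codons = 250L, seed = 7L)
    .sim_cache$small <- simulate_all(cfg)
  }
  .sim_cache$small
}

small_run <- function() {
  if (is.null(.sim_cache$small_run)) {
    sim <- small_sim()
    .sim_cache$small_run <- suppressMessages(run_pipeline(list(
      male_assembly = sim$male_assembly,
      female_assembly = sim$female_assembly,
      male_genomic = sim$genomic_reads$male,
      female_genomic = sim$genomic_reads$female,
      rna = sim$rna_reads,
      outgroup_cds = sim$outgroup_cds), verbose = FALSE))
  }
  .sim_cache$small_run
}

# the default-configuration run the acceptance criteria are stated against
# (200 genes, 1.5% divergence, 45x/62x genomic, 50x RNA, error-free, seed 42)
acceptance_sim <- function() {
  if (is.null(.sim_cache$acc)) {
    .sim_cache$acc <- simulate_all(sim_config(seed = 42L))
  }
  .sim_cache$acc
}

acceptance_run <- function() {
  if (is.null(.sim_cache$acc_run)) {
    sim <- acceptance_sim()
    .sim_cache$acc_run <- suppressMessages(run_pipeline(list(
      male_assembly = sim$male_assembly,
      female_assembly = sim$female_assembly,
      male_genomic = sim$genomic_reads$male,
      female_genomic = sim$genomic_reads$female,
      rna = sim$rna_reads,
      outgroup_cds = sim$outgroup_cds), verbose = FALSE))
  }
  .sim_cache$acc_run
}

# categorized CAT1/CAT3 sites of a run, projected to parent-transcript
# coordinates
diagnostic_calls <- function(run) {
  catd <- run$sites[run$sites$category %in% c("CAT1", "CAT3") &
                      run$sites$chrom_class != "autosome"]
  exoff <- run$exons[, c("exon_id", "parent", "start")]
  data.table::setnames(exoff, "start", "estart")
  catd <- merge(catd, exoff, by.x = "target_id", by.y = "exon_id")
  catd$ppos <- catd$pos + catd$estart
  catd
}
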