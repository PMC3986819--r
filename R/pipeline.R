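# End-to-end orchestration: genomic mapping -> exon splitting -> variant
# categorization -> Y-ward rewriting -> RNA-support filtering -> merging /
# scaffolding -> ID assignment -> ORF annotation -> quantification ->
# divergence -> screens -> report.

#' Pipeline parameters
#'
#' Bundles every stage's tunables with the pipeline defaults.
#'
#' @param caller [caller_params()].
#' @param mapper [mapper_params()].
#' @param blocks [block_filter_params()].
#' @param min_exon_overlap junction threshold for [split_into_exons()].
#' @param min_piece_bp exon pieces shorter than this are dropped (they
#'   cannot anchor a seed).
#' @param merge_min_overlap,merge_min_identity [merge_fragments()] settings.
#' @param screen_thresholds [neoY_absence_screen()] ratio thresholds.
#' @param identity_floor minimum identity for reference alignments and
#'   divergence triples.
#' @return parameter list.
#' @export
pipeline_params <- function(caller = caller_params(),
                            mapper = mapper_params(),
                            blocks = block_filter_params(),
                            min_exon_overlap = 6L, min_piece_bp = 20L,
                            merge_min_overlap = 40L,
                            merge_min_identity = 0.99,
                            screen_thresholds = c(0.7, 0.85),
                            identity_floor = 0.6) {
  as.list(environment())
}

input_error <- function(msg) {
  stop(errorCondition(msg, class = c("neophase_input_error", "error")))
}

#' Run the full phasing pipeline
#'
#' Executes the stages in order on in-memory inputs and returns every
#' stage's output plus a [assemble_report()] summary. Per-stage in/out
#' counts are logged to stderr.
#'
#' @param inputs list with `male_assembly` ([transcript_set()]: neo-sex
#'   candidates labeled `neoX`, controls `autosome`), `male_genomic`,
#'   `female_genomic` ([read_set()]s), `rna` (a [read_set()] or named list
#'   per tissue), `outgroup_cds` ([transcript_set()]), and optionally
#'   `female_assembly`.
#' @param params [pipeline_params()].
#' @param outdir if non-NULL, persist all stage artifacts there.
#' @param verbose log per-stage counts.
#' @return list of class `neophase_run` (stages + `report`).
#' @export
run_pipeline <- function(inputs, params = pipeline_params(), outdir = NULL,
                         verbose = TRUE) {
  log_ <- function(...) if (verbose) message(sprintf(...))
  for (req in c("male_assembly", "male_genomic", "female_genomic", "rna",
                "outgroup_cds")) {
    if (is.null(inputs[[req]])) input_error(paste0("missing input: ", req))
  }
  male_assembly <- inputs$male_assembly
  rna <- inputs$rna
  if (is.data.frame(rna)) rna <- list(pooled = rna)
  rna_pooled <- rbindlist(rna)

  # -- stage a: exact genomic mapping and exon splitting --------------------
  log_("[map-exact] %d male genomic reads vs %d transcripts",
       nrow(inputs$male_genomic), nrow(male_assembly))
  aln_gx <- map_exact(inputs$male_genomic, male_assembly,
                      seed_length = params$mapper$seed_length,
                      match_score = params$mapper$match_score)
  setkey(aln_gx, target_id)
  exon_rows <- vector("list", nrow(male_assembly))
  for (i in seq_len(nrow(male_assembly))) {
    tid <- male_assembly$id[i]
    pieces <- split_into_exons(male_assembly$bases[i], aln_gx[J(tid)][!is.na(target_start)],
                               min_overlap = params$min_exon_overlap)
    if (nrow(pieces) == 0L) next
    pieces <- pieces[end - start >= params$min_piece_bp]
    if (nrow(pieces) == 0L) next
    pieces[, `:=`(parent = tid, exon_id = paste0(tid, "|e", seq_len(.N)),
                  chrom_class = male_assembly$chrom_class[i])]
    exon_rows[[i]] <- pieces
  }
  exons <- rbindlist(Filter(Negate(is.null), exon_rows))
  if (nrow(exons) == 0L) input_error("no transcript has genomic support")
  exon_ts <- transcript_set(exons$exon_id, exons$bases, exons$chrom_class)
  log_("[split-exons] %d transcripts -> %d exon pieces",
       nrow(male_assembly), nrow(exons))

  # -- stage b: scored mapping of both sexes and site categorization --------
  genomic_all <- rbind(inputs$male_genomic, inputs$female_genomic)
  log_("[map-scored] %d genomic reads vs %d exons", nrow(genomic_all),
       nrow(exon_ts))
  aln_sc <- map_scored(genomic_all, exon_ts, params = params$mapper)
  setkey(aln_sc, target_id)
  exlen <- setNames(nchar(exon_ts$bases), exon_ts$id)
  site_list <- vector("list", nrow(exons))
  assayed <- c(neo = 0, autosome = 0)
  for (i in seq_len(nrow(exons))) {
    eid <- exons$exon_id[i]
    sub <- aln_sc[J(eid)][!is.na(target_start)]
    pu <- build_pileup(sub, eid, exlen[[eid]],
                       min_bq = params$caller$min_bq)
    sites <- categorize_pileup(pu, exons$bases[i], params$caller)
    cls <- if (exons$chrom_class[i] == "autosome") "autosome" else "neo"
    assayed[cls] <- assayed[cls] + attr(sites, "n_assayed")
    if (nrow(sites)) {
      sites[, chrom_class := exons$chrom_class[i]]
      site_list[[i]] <- sites
    }
  }
  sites_all <- rbindlist(Filter(Negate(is.null), site_list))
  log_("[categorize] %d variant sites over %d assayed (neo) + %d (autosome)",
       nrow(sites_all), round(assayed["neo"]), round(assayed["autosome"]))

  # -- stage c: rewrite exons Y-ward and collect diagnostic positions -------
  neo_exons <- exons[chrom_class != "autosome"]
  rw_ids <- character(0); rw_seqs <- character(0)
  rw_parent <- character(0)
  diag_new <- vector("list", nrow(neo_exons))
  setkeyv(sites_all, c("target_id", "pos"))
  for (i in seq_len(nrow(neo_exons))) {
    eid <- neo_exons$exon_id[i]
    st <- if (nrow(sites_all)) sites_all[J(eid)][!is.na(pos)] else sites_all
    rw <- rewrite_haplotype(neo_exons$bases[i], st, "toY")
    rw_ids <- c(rw_ids, eid)
    rw_seqs <- c(rw_seqs, rw$bases)
    rw_parent <- c(rw_parent, neo_exons$parent[i])
    dg <- st[category %in% c("CAT1", "CAT3"), pos]
    diag_new[[i]] <- rw$coord_map[dg + 1L]
  }
  rewritten <- transcript_set(rw_ids, rw_seqs, "neoY")
  log_("[rewrite] %d neo exons rewritten Y-ward (%d CAT3 substitutions)",
       nrow(rewritten), if (nrow(sites_all)) {
         nrow(sites_all[category == "CAT3" &
                          chrom_class != "autosome"])
       } else 0L)

  # -- stage d: RNA support filtering ---------------------------------------
  log_("[map-rna] %d RNA reads vs %d rewritten exons", nrow(rna_pooled),
       nrow(rewritten))
  aln_rna <- map_exact(rna_pooled, rewritten,
                       seed_length = params$mapper$seed_length,
                       match_score = params$mapper$match_score)
  setkey(aln_rna, target_id)
  frag_ids <- character(0); frag_seqs <- character(0)
  frag_parent <- character(0)
  kept_rows <- vector("list", nrow(rewritten))
  for (i in seq_len(nrow(rewritten))) {
    eid <- rewritten$id[i]
    sub <- aln_rna[J(eid)][!is.na(target_start)]
    dpos <- diag_new[[i]]
    dpos <- dpos[!is.na(dpos)]
    kept <- filter_supported_regions(nchar(rewritten$bases[i]), sub, dpos)
    if (nrow(kept) == 0L) next
    kept[, `:=`(exon_id = eid, parent = rw_parent[i])]
    kept_rows[[i]] <- kept
    for (j in seq_len(nrow(kept))) {
      frag_ids <- c(frag_ids, paste0(eid, "|r", j))
      frag_seqs <- c(frag_seqs, substring(rewritten$bases[i],
                                          kept$start[j] + 1L, kept$end[j]))
      frag_parent <- c(frag_parent, rw_parent[i])
    }
  }
  kept_regions <- rbindlist(Filter(Negate(is.null), kept_rows))
  log_("[rna-filter] %d kept regions across %d parent transcripts",
       length(frag_ids), uniqueN(frag_parent))

  # -- stage e: merge, assign IDs, scaffold ---------------------------------
  parents <- unique(frag_parent)
  merged_by_parent <- lapply(parents, function(p) {
    fr <- frag_seqs[frag_parent == p]
    names(fr) <- frag_ids[frag_parent == p]
    merge_fragments(fr, params$merge_min_overlap, params$merge_min_identity)
  })
  names(merged_by_parent) <- parents
  rep_seq <- vapply(merged_by_parent, function(fr) {
    fr[[which.max(nchar(fr))]]
  }, character(1))
  queries <- transcript_set(parents, rep_seq, "neoY")
  rbh <- assign_ids_rbh(queries, inputs$outgroup_cds, k = params$mapper$seed_length)
  log_("[rbh] %d of %d candidate Y transcripts assigned a reference id",
       nrow(rbh), length(parents))
  refseq <- setNames(inputs$outgroup_cds$bases, inputs$outgroup_cds$id)
  y_ids <- character(0); y_seqs <- character(0); y_parent <- character(0)
  y_ref <- character(0)
  for (p in parents) {
    fr <- merged_by_parent[[p]]
    ref_id <- rbh[transcript_id == p, reference_id]
    seqs <- if (length(fr) == 1L) {
      unname(fr[[1]])
    } else if (length(ref_id) == 1L) {
      scaffold_by_protein(fr, refseq[[ref_id]],
                          params$merge_min_overlap,
                          params$merge_min_identity)
    } else {
      unname(fr[[which.max(nchar(fr))]]) # unassigned multi-fragment: keep best
    }
    if (length(seqs) > 1L) seqs <- seqs[[which.max(nchar(seqs))]]
    y_ids <- c(y_ids, paste0(p, "_Y"))
    y_seqs <- c(y_seqs, seqs)
    y_parent <- c(y_parent, p)
    y_ref <- c(y_ref, if (length(ref_id) == 1L) ref_id else NA_character_)
  }
  neoY <- if (length(y_ids)) {
    transcript_set(y_ids, y_seqs, "neoY", ref_protein_id = y_ref)
  } else NULL
  log_("[scaffold] %d Y transcripts built", length(y_ids))

  # -- stage f: ORF classification ------------------------------------------
  orf_rows <- vector("list", length(y_ids))
  for (i in seq_along(y_ids)) {
    if (is.na(y_ref[i])) next
    aln <- align_to_reference_cds(y_seqs[i], refseq[[y_ref[i]]],
                                  min_identity = params$identity_floor)
    orf <- classify_orf(aln, refseq[[y_ref[i]]], transcript_id = y_ids[i])
    utr <- utr3_lengths(y_seqs[i], orf)
    orf_rows[[i]] <- data.table(
      transcript_id = y_ids[i], parent = y_parent[i],
      reference_id = y_ref[i], status = orf$status,
      n_frameshifts = length(orf$frameshift_positions),
      frameshift_positions = paste(orf$frameshift_positions, collapse = ","),
      first_ptc_codon_index = orf$first_ptc_codon_index,
      first_ptc_relative = orf$first_ptc_relative,
      utr3_from_first_stop_bp = utr$utr3_from_first_stop_bp,
      utr3_from_ancestral_stop_bp = utr$utr3_from_ancestral_stop_bp,
      identity = aln$identity)
  }
  orf_tab <- rbindlist(Filter(Negate(is.null), orf_rows))
  log_("[orf] %d Y transcripts classified", nrow(orf_tab))

  # -- stage g: quantification ----------------------------------------------
  quant_targets <- rbind(
    if (!is.null(inputs$female_assembly)) inputs$female_assembly,
    if (!is.null(neoY)) neoY,
    male_assembly[male_assembly$chrom_class == "autosome", ])
  quant_targets <- transcript_set(quant_targets$id, quant_targets$bases,
                                  quant_targets$chrom_class,
                                  quant_targets$ref_protein_id)
  abundance <- lapply(rna, function(rd) {
    al <- map_exact(rd, quant_targets,
                    seed_length = params$mapper$seed_length,
                    match_score = params$mapper$match_score)
    em_quantify(al, quant_targets, n_total_reads = nrow(rd))
  })
  log_("[quant] %d sample(s) quantified over %d transcripts",
       length(abundance), nrow(quant_targets))

  # -- stage h: divergence --------------------------------------------------
  div <- data.table()
  if (!is.null(inputs$female_assembly) && length(y_ids)) {
    fem <- setNames(inputs$female_assembly$bases, inputs$female_assembly$id)
    trip <- data.table(parent = y_parent, neoY = y_seqs, ref = y_ref)
    trip <- trip[!is.na(ref) & paste0(parent, "_F") %in% names(fem)]
    if (nrow(trip)) {
      genes <- data.frame(gene = trip$parent,
                          neoX = unname(fem[paste0(trip$parent, "_F")]),
                          neoY = trip$neoY,
                          outgroup = unname(refseq[trip$ref]))
      div <- divergence_table(genes, params$blocks,
                              min_identity = params$identity_floor)
    }
  }
  log_("[divergence] %d triples measured", nrow(div))

  # -- stage i: screens -----------------------------------------------------
  # project exon-level scored alignments back to parent coordinates
  exoff <- exons[, .(exon_id, parent, start)]
  alp <- aln_sc[exoff, on = c(target_id = "exon_id"), nomatch = NULL]
  alp <- alp[, .(target_id = parent, target_start = target_start + start,
                 target_end = target_end + start, sex)]
  profiles <- coverage_profile(alp, male_assembly)
  male_poly <- if (nrow(sites_all)) {
    sa <- copy(sites_all)
    sa[, male_poly := mapply(function(a, r) {
      al <- strsplit(a, ",")[[1]]
      r %in% al && length(setdiff(al, r)) >= 1L
    }, male_alleles, ref_allele)]
    sa <- sa[exoff, on = c(target_id = "exon_id"), nomatch = NULL]
    sa[male_poly == TRUE, .(n_polymorphic_sites_male = .N),
       by = .(transcript_id = parent)]
  } else data.table(transcript_id = character(),
                    n_polymorphic_sites_male = integer())
  neo_ids <- male_assembly$id[male_assembly$chrom_class != "autosome"]
  auto_ids <- male_assembly$id[male_assembly$chrom_class == "autosome"]
  scr_del <- neoX_deletion_screen(profiles[transcript_id %in% neo_ids],
                                  male_poly)
  norm_m <- median(profiles[transcript_id %in% auto_ids, mean_depth_m])
  norm_f <- median(profiles[transcript_id %in% auto_ids, mean_depth_f])
  scr_y <- if (isTRUE(norm_m > 0) && isTRUE(norm_f > 0)) {
    neoY_absence_screen(profiles[transcript_id %in% neo_ids],
                        norm_m, norm_f, params$screen_thresholds)
  } else NULL
  log_("[screens] %d X-deletion candidates; normalizers m=%.1f f=%.1f",
       sum(scr_del$candidate), norm_m, norm_f)

  # -- report ---------------------------------------------------------------
  assembly_info <- data.table(id = male_assembly$id,
                              chrom_class = male_assembly$chrom_class,
                              length_bp = nchar(male_assembly$bases))
  neoY_info <- data.table(id = y_ids, parent = y_parent,
                          length_bp = nchar(y_seqs))
  tables <- list(assembly_info = assembly_info, neoY_info = neoY_info,
                 orf = orf_tab, sites = sites_all, n_assayed = assayed,
                 abundance = abundance, divergence = div,
                 screens = list(neoX_deletion = scr_del,
                                neoY_absence = scr_y))
  report <- assemble_report(tables)
  run <- list(
    exons = exons, alignments_exact_genomic = aln_gx,
    sites = sites_all, n_assayed = assayed,
    rewritten_exons = rewritten, kept_regions = kept_regions,
    neoY = neoY, rbh = rbh, orf = orf_tab, abundance = abundance,
    divergence = div, coverage_profiles = profiles,
    screens = tables$screens, report = report, tables = tables,
    params = params)
  class(run) <- "neophase_run"
  if (!is.null(outdir)) write_artifacts(run, outdir)
  run
}

#' @export
print.neophase_run <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Persist pipeline artifacts to a directory
#'
#' Writes the stage tables as deterministic TSVs, sequence sets as FASTA,
#' and the report (plus the assayed-site universe) as JSON.
#'
#' @param run a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_artifacts <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  write_table(run$tables$assembly_info, fp("assembly_info.tsv"))
  write_table(run$tables$neoY_info, fp("neoY_info.tsv"))
  if (nrow(run$orf)) write_table(run$orf, fp("orf_neoY.tsv"))
  if (nrow(run$sites)) {
    write_table(run$sites, fp("sites.tsv"), sort_by = c("target_id", "pos"))
  }
  if (nrow(run$kept_regions)) {
    write_table(run$kept_regions, fp("kept_regions.tsv"),
                sort_by = c("exon_id", "start"))
  }
  if (!is.null(run$neoY)) write_fasta(run$neoY, fp("neoY.fa"))
  write_fasta(run$rewritten_exons, fp("rewritten_exons.fa"))
  if (nrow(run$rbh)) write_table(run$rbh, fp("rbh.tsv"))
  for (tt in names(run$abundance)) {
    write_table(run$abundance[[tt]], fp(paste0("abundance_", tt, ".tsv")))
  }
  if (nrow(run$divergence)) write_table(run$divergence, fp("divergence.tsv"))
  write_table(run$coverage_profiles, fp("coverage_profiles.tsv"))
  write_table(run$screens$neoX_deletion, fp("screen_neoX_deletion.tsv"))
  if (!is.null(run$screens$neoY_absence)) {
    write_table(run$screens$neoY_absence, fp("screen_neoY_absence.tsv"))
  }
  jsonlite::write_json(list(n_assayed = as.list(run$n_assayed)),
                       fp("meta.json"), auto_unbox = TRUE)
  jsonlite::write_json(run$report, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(outdir)
}

#' Rebuild the report from persisted artifacts
#'
#' Reads the stage tables written by [write_artifacts()] and reassembles
#' the report without recomputation; the result is identical to the in-run
#' report.
#'
#' @param outdir directory written by [write_artifacts()].
#' @return a `pipeline_report`.
#' @export
report_from_dir <- function(outdir) {
  fp <- function(f) file.path(outdir, f)
  rd <- function(f, nastring = "NA") {
    if (file.exists(fp(f))) {
      fread(fp(f), sep = "\t", na.strings = nastring)
    } else data.table()
  }
  meta <- jsonlite::read_json(fp("meta.json"))
  ab_files <- list.files(outdir, pattern = "^abundance_.*\\.tsv$")
  abundance <- setNames(
    lapply(ab_files, rd),
    sub("^abundance_(.*)\\.tsv$", "\\1", ab_files))
  tables <- list(
    assembly_info = rd("assembly_info.tsv"),
    neoY_info = rd("neoY_info.tsv"),
    orf = rd("orf_neoY.tsv"),
    sites = rd("sites.tsv"),
    n_assayed = unlist(meta$n_assayed),
    abundance = abundance,
    divergence = rd("divergence.tsv"),
    screens = list(neoX_deletion = rd("screen_neoX_deletion.tsv"),
                   neoY_absence = {
                     s <- rd("screen_neoY_absence.tsv")
                     if (nrow(s)) s else NULL
                   }))
  assemble_report(tables)
}
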