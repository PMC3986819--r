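# Synthetic neo-sex-chromosome datasets with full ground truth.
#
# The generator emulates the data regime the pipeline was built for: a male
# assembly whose neo-sex transcripts carry the X haplotype sequence, male
# genomic reads drawn 50/50 from the X and Y haplotypes, female genomic
# reads from the X only, an outgroup at its own distance, degeneration
# lesions (frameshifts, premature stops) on the Y, silenced/deleted copies,
# and RNA reads with down-regulated non-functional copies. All randomness
# flows from one RNG stream keyed by `seed`.

CODONS <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

#' Simulation configuration
#'
#' Defaults describe the intended data regime: ~1.5% X/Y coding divergence, 2.1%
#' Y/outgroup divergence, 45x male and 62x female genomic coverage, 100-bp
#' reads, lesion fractions matching the observed 356/1863 frameshift and
#' 164/1863 premature-stop rates, silencing at (387-30)/2141 and Y-deletion
#' at 30/1863. The X-deletion fraction is scaled up from the observed 4/2141
#' so that a 200-gene simulation carries a handful of positives.
#'
#' @param n_genes neo-sex gene count.
#' @param n_autosomes autosomal control gene count.
#' @param mean_cds_codons mean CDS length in codons.
#' @param neoXY_divergence expected X/Y per-site divergence.
#' @param outgroup_divergence expected Y/outgroup per-site divergence.
#' @param indel_rate per-site, per-haplotype indel rate outside the CDS.
#' @param frac_ptc,frac_frameshift per-gene lesion probabilities (drawn
#'   independently; a gene can carry both).
#' @param frac_neoY_silenced,frac_neoY_deleted,frac_neoX_deleted mutually
#'   exclusive gene states.
#' @param n_introns introns per gene.
#' @param intron_len_range intron length range (bp).
#' @param utr3_meanlog,utr3_sdlog log-normal 3'UTR length parameters.
#' @param read_length read length (bp).
#' @param male_genomic_depth,female_genomic_depth total genomic depths.
#' @param rna_depth mean RNA coverage of the transcriptome.
#' @param nonfunctional_expression_factor expression multiplier for
#'   lesion-carrying Y copies (< 1).
#' @param expr_meanlog,expr_sdlog log-normal per-gene expression level.
#' @param sequencing_error_rate per-base error rate (0 = error-free).
#' @param tissues sample names for RNA read sets.
#' @param seed RNG seed.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L, n_autosomes = 50L,
                       mean_cds_codons = 400L,
                       neoXY_divergence = 0.015, outgroup_divergence = 0.021,
                       indel_rate = 5e-4,
                       frac_ptc = 0.09, frac_frameshift = 0.19,
                       frac_neoY_silenced = 0.167,
                       frac_neoY_deleted = 0.016,
                       frac_neoX_deleted = 0.02,
                       n_introns = 2L, intron_len_range = c(60L, 400L),
                       utr3_meanlog = log(300), utr3_sdlog = 0.5,
                       read_length = 100L,
                       male_genomic_depth = 45, female_genomic_depth = 62,
                       rna_depth = 50,
                       nonfunctional_expression_factor = 0.5,
                       expr_meanlog = log(50), expr_sdlog = 1,
                       sequencing_error_rate = 0,
                       tissues = "male_body", seed = 42L) {
  cfg <- as.list(environment())
  fr <- c(frac_ptc, frac_frameshift, frac_neoY_silenced, frac_neoY_deleted,
          frac_neoX_deleted)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (frac_neoY_silenced + frac_neoY_deleted + frac_neoX_deleted > 1) {
    stop("exclusive state fractions sum to more than 1")
  }
  if (outgroup_divergence <= neoXY_divergence / 2) {
    stop("outgroup_divergence must exceed half the X/Y divergence")
  }
  stopifnot(male_genomic_depth > 0, female_genomic_depth > 0, rna_depth > 0,
            read_length >= 30, n_genes >= 1)
  class(cfg) <- "sim_config"
  cfg
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

# apply edits (sub/ins/del at 0-based positions on `seq`) and return the new
# sequence plus an old->new coordinate map (NA for deleted positions)
apply_edits <- function(seq, edits) {
  n <- nchar(seq)
  map <- 0:(n - 1L)
  if (is.null(edits) || nrow(edits) == 0L) return(list(seq = seq, map = map))
  setorder(edits, pos)
  segs <- character(0)
  cm <- rep(NA_integer_, n)
  cursor <- 0L; new_len <- 0L
  for (r in seq_len(nrow(edits))) {
    p <- edits$pos[r]
    if (p < cursor) next
    if (p > cursor) {
      segs <- c(segs, substring(seq, cursor + 1L, p))
      cm[(cursor + 1L):p] <- new_len + 0L:(p - cursor - 1L)
      new_len <- new_len + (p - cursor)
      cursor <- p
    }
    typ <- edits$type[r]
    if (typ == "sub") {
      segs <- c(segs, edits$bases[r])
      cm[p + 1L] <- new_len
      new_len <- new_len + 1L
      cursor <- cursor + 1L
    } else if (typ == "del") {
      cursor <- cursor + edits$len[r]
    } else { # ins: insert after base at p
      segs <- c(segs, substr(seq, p + 1L, p + 1L), edits$bases[r])
      cm[p + 1L] <- new_len
      new_len <- new_len + 1L + nchar(edits$bases[r])
      cursor <- cursor + 1L
    }
  }
  if (cursor < n) {
    segs <- c(segs, substring(seq, cursor + 1L, n))
    cm[(cursor + 1L):n] <- new_len + 0L:(n - cursor - 1L)
  }
  list(seq = paste(segs, collapse = ""), map = cm)
}

# substitution edits at `rate` per site; inside a CDS (frame_from = 0-based
# frame anchor) substitutions creating an in-frame stop codon are
# re-sampled, emulating purifying selection against nonsense changes
draw_substitutions <- function(seq, rate, coding = FALSE) {
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (coding && n >= 3L) hit <- hit[hit <= n - 3L | hit > n] # keep stop codon
  if (length(hit) == 0L) {
    return(data.table(pos = integer(), type = character(), len = integer(),
                      bases = character()))
  }
  ch <- strsplit(seq, "")[[1]]
  newb <- character(length(hit))
  keep <- logical(length(hit))
  for (k in seq_along(hit)) {
    i <- hit[k]
    alts <- setdiff(c("A", "C", "G", "T"), ch[i])
    if (coding) {
      c0 <- ((i - 1L) %/% 3L) * 3L + 1L # codon start (1-based)
      ok <- vapply(alts, function(b) {
        cd <- ch[c0:(c0 + 2L)]
        cd[i - c0 + 1L] <- b
        !(paste(cd, collapse = "") %in% STOP_CODONS)
      }, logical(1))
      alts <- alts[ok]
    }
    if (length(alts) == 0L) { keep[k] <- FALSE; next }
    newb[k] <- if (length(alts) == 1L) alts else sample(alts, 1L)
    keep[k] <- TRUE
  }
  data.table(pos = hit[keep] - 1L, type = "sub", len = 1L,
             bases = newb[keep])
}

draw_indels <- function(n, rate) {
  hit <- which(runif(n) < rate)
  if (length(hit) == 0L) {
    return(data.table(pos = integer(), type = character(), len = integer(),
                      bases = character()))
  }
  typ <- ifelse(runif(length(hit)) < 0.5, "del", "ins")
  len <- sample(1:3, length(hit), replace = TRUE)
  bases <- ifelse(typ == "ins",
                  vapply(len, random_seq, character(1)), "")
  dt <- data.table(pos = hit - 1L, type = typ, len = len, bases = bases)
  dt[!(type == "del" & pos + len > n)]
}

#' Simulate a neo-sex gene set with ground truth
#'
#' Builds, per gene, an ancestral CDS with introns and a 3'UTR; derives the
#' X and Y haplotypes by independent per-site substitution at half the
#' configured divergence each (plus indels outside the CDS), the outgroup at
#' its own distance, and injects Y-side lesions and gene states. Returns the
#' assemblies the pipeline consumes plus complete truth tables.
#'
#' Call via [simulate_all()] for a seeded, reproducible bundle including
#' reads; this function draws from the current RNG stream.
#'
#' @param config a [sim_config()].
#' @return list: `male_assembly`, `female_assembly`, `outgroup_cds`
#'   ([transcript_set()]s), `outgroup_protein` (named character), `genome`
#'   (data.table: `gene`, `hap`, `sex_presence`, `bases`, `depth_share`),
#'   and `truth` (gene states, haplotype transcripts, diagnostic SNV sites,
#'   indel differences, lesions, expression levels).
#' @export
simulate_gene_set <- function(config = sim_config()) {
  cfg <- config
  L <- cfg$read_length
  genes <- sprintf("g%03d", seq_len(cfg$n_genes))
  autos <- if (cfg$n_autosomes > 0) {
    sprintf("a%03d", seq_len(cfg$n_autosomes))
  } else character(0)
  # exclusive gene states
  states <- rep("normal", cfg$n_genes)
  u <- runif(cfg$n_genes)
  c1 <- cfg$frac_neoX_deleted
  c2 <- c1 + cfg$frac_neoY_deleted
  c3 <- c2 + cfg$frac_neoY_silenced
  states[u < c1] <- "neoX_deleted"
  states[u >= c1 & u < c2] <- "neoY_deleted"
  states[u >= c2 & u < c3] <- "neoY_silenced"
  has_ptc <- runif(cfg$n_genes) < cfg$frac_ptc
  has_fs <- runif(cfg$n_genes) < cfg$frac_frameshift
  # lesions only make sense when a Y copy exists in the genome
  has_ptc[states == "neoY_deleted"] <- FALSE
  has_fs[states == "neoY_deleted"] <- FALSE

  half <- cfg$neoXY_divergence / 2
  out_rate <- cfg$outgroup_divergence - half

  gene_rows <- list(); diag_rows <- list(); indel_rows <- list()
  lesion_rows <- list(); genome_rows <- list()
  male_ids <- character(0); male_seqs <- character(0); male_cls <- character(0)
  fem_ids <- character(0); fem_seqs <- character(0)
  ref_ids <- character(0); ref_seqs <- character(0)
  x_tx <- character(0); y_tx <- character(0)

  build_gene <- function(gid, is_auto, state, ptc, fs) {
    n_cod <- max(150L, round(rnorm(1, cfg$mean_cds_codons,
                                   0.3 * cfg$mean_cds_codons)))
    cds <- random_cds(n_cod)
    cds_len <- nchar(cds)
    # intron insertion points on the ancestral CDS, away from ends
    k_int <- cfg$n_introns
    pts <- integer(0)
    if (k_int > 0L && cds_len > 300L * (k_int + 1L)) {
      slots <- seq(150L, cds_len - 150L, by = 1L)
      pts <- sort(sample(slots, k_int))
      while (k_int > 1L && min(diff(pts)) < 150L) {
        pts <- sort(sample(slots, k_int))
      }
    }
    introns <- vapply(seq_along(pts), function(i) {
      random_seq(sample(cfg$intron_len_range[1]:cfg$intron_len_range[2], 1L))
    }, character(1))
    utr <- random_seq(max(30L, round(rlnorm(1, cfg$utr3_meanlog,
                                            cfg$utr3_sdlog))))
    utr_len <- nchar(utr)
    anc_tx <- paste0(cds, utr)

    if (is_auto) {
      # no X/Y divergence: single haplotype in both sexes
      list(cds = cds, utr = utr, introns = introns, pts = pts,
           x = list(cds = cds, utr = apply_edits(utr, NULL),
                    cds_map = 0:(cds_len - 1L)),
           y = NULL, out = NULL, anc_tx = anc_tx)
    } else {
      sub_x <- draw_substitutions(cds, half, coding = TRUE)
      sub_y <- draw_substitutions(cds, half, coding = TRUE)
      sub_o <- draw_substitutions(cds, out_rate, coding = TRUE)
      utr_x <- rbind(draw_substitutions(utr, half),
                     draw_indels(utr_len, cfg$indel_rate))
      utr_y <- rbind(draw_substitutions(utr, half),
                     draw_indels(utr_len, cfg$indel_rate))
      # Y lesions on top of the diverged Y CDS (positions on ancestral CDS
      # coordinates, which CDS substitutions do not shift)
      les <- data.table(pos = integer(), type = character(), len = integer(),
                        bases = character())
      ptc_codon <- NA_integer_
      if (ptc) {
        ptc_codon <- sample(2:(n_cod - 2L), 1L)
        les <- rbind(les, data.table(pos = (ptc_codon - 1L) * 3L,
                                     type = "ptc_codon", len = 3L,
                                     bases = sample(STOP_CODONS, 1L)))
      }
      fs_pos <- NA_integer_
      if (fs) {
        lo <- if (!is.na(ptc_codon)) (ptc_codon + 2L) * 3L else 30L
        hi <- cds_len - 33L
        if (lo < hi) {
          fs_pos <- sample(lo:hi, 1L)
          fl <- sample(c(1L, 2L, 4L), 1L)
          if (runif(1) < 0.5) {
            les <- rbind(les, data.table(pos = fs_pos, type = "del",
                                         len = fl, bases = ""))
          } else {
            les <- rbind(les, data.table(pos = fs_pos, type = "ins",
                                         len = fl, bases = random_seq(fl)))
          }
        } else fs <- FALSE
      }
      # X CDS: substitutions only
      x_cds <- apply_edits(cds, sub_x)
      # Y CDS: substitutions, then the PTC overwrite, then the indel lesion
      y_ed <- copy(sub_y)
      ptc_row <- les[type == "ptc_codon"]
      y_cds_seq <- apply_edits(cds, y_ed)
      y_map <- y_cds_seq$map
      y_seq <- y_cds_seq$seq
      if (nrow(ptc_row)) { # overwrite the codon in place (no shift)
        p <- ptc_row$pos
        y_seq <- paste0(substr(y_seq, 1L, p), ptc_row$bases,
                        substring(y_seq, p + 4L))
      }
      fs_row <- les[type %in% c("del", "ins")]
      if (nrow(fs_row)) {
        fr <- apply_edits(y_seq, copy(fs_row))
        y_seq <- fr$seq
        y_map <- ifelse(is.na(y_map), NA_integer_, fr$map[y_map + 1L])
      }
      o_cds <- apply_edits(cds, sub_o)
      list(cds = cds, utr = utr, introns = introns, pts = pts,
           x = list(cds_seq = x_cds$seq, cds_map = x_cds$map,
                    utr_ed = utr_x),
           y = list(cds_seq = y_seq, cds_map = y_map, utr_ed = utr_y),
           out = list(cds_seq = o_cds$seq),
           lesions = les, ptc_codon = ptc_codon, fs_pos = fs_pos,
           n_cod = n_cod, anc_tx = anc_tx)
    }
  }

  assemble_genomic <- function(cds_seq, cds_map, pts, introns, utr_seq) {
    # split CDS at ancestral points mapped through the haplotype map
    if (length(pts) == 0L) return(paste0(cds_seq, utr_seq))
    mp <- vapply(pts, function(p) {
      # first mapped coordinate at or after p
      i <- p
      while (i <= length(cds_map) && is.na(cds_map[i + 1L] %||% NA)) i <- i + 1L
      if (i >= length(cds_map)) nchar(cds_seq) else cds_map[i + 1L]
    }, integer(1))
    bounds <- c(0L, mp, nchar(cds_seq))
    ex <- substring(cds_seq, head(bounds, -1L) + 1L, tail(bounds, -1L))
    paste0(paste0(ex, c(introns, ""), collapse = ""), utr_seq)
  }

  for (gi in seq_len(cfg$n_genes + cfg$n_autosomes)) {
    is_auto <- gi > cfg$n_genes
    gid <- if (is_auto) autos[gi - cfg$n_genes] else genes[gi]
    state <- if (is_auto) "autosome" else states[gi]
    g <- build_gene(gid, is_auto, state,
                    !is_auto && has_ptc[min(gi, cfg$n_genes)],
                    !is_auto && has_fs[min(gi, cfg$n_genes)])
    if (is_auto) {
      tx <- paste0(g$cds, g$utr)
      genomic <- assemble_genomic(g$cds, 0:(nchar(g$cds) - 1L), g$pts,
                                  g$introns, g$utr)
      male_ids <- c(male_ids, gid); male_seqs <- c(male_seqs, tx)
      male_cls <- c(male_cls, "autosome")
      genome_rows[[length(genome_rows) + 1L]] <- data.table(
        gene = gid, hap = "A", sex_presence = "both", bases = genomic,
        depth_share = 1)
      gene_rows[[length(gene_rows) + 1L]] <- data.table(
        gene = gid, class = "autosome", state = "autosome",
        cds_len = nchar(g$cds), tx_len = nchar(tx),
        ptc_codon = NA_integer_, fs_pos = NA_integer_,
        n_cod = nchar(g$cds) %/% 3L)
      x_tx <- c(x_tx, setNames(tx, gid))
      next
    }
    # neo-sex gene: build X/Y transcripts and genomes
    ux <- apply_edits(g$utr, g$x$utr_ed)
    uy <- apply_edits(g$utr, g$y$utr_ed)
    x_transcript <- paste0(g$x$cds_seq, ux$seq)
    y_transcript <- paste0(g$y$cds_seq, uy$seq)
    cds_len <- nchar(g$cds)
    # ancestral-transcript coordinate maps
    xmap <- c(g$x$cds_map, ifelse(is.na(ux$map), NA_integer_,
                                  ux$map + nchar(g$x$cds_seq)))
    ymap <- c(g$y$cds_map, ifelse(is.na(uy$map), NA_integer_,
                                  uy$map + nchar(g$y$cds_seq)))
    # diagnostic SNVs: ancestral positions alive in both haplotypes with
    # differing bases
    xb <- strsplit(x_transcript, "")[[1]]
    yb <- strsplit(y_transcript, "")[[1]]
    alive <- !is.na(xmap) & !is.na(ymap)
    bx <- xb[xmap[alive] + 1L]
    by_ <- yb[ymap[alive] + 1L]
    dif <- which(bx != by_)
    # a site is diagnostic only when both haplotypes exist in the male
    # genome; with a deleted copy there is no divergence to detect
    if (state %in% c("neoX_deleted", "neoY_deleted")) dif <- integer(0)
    if (length(dif)) {
      ap <- which(alive)[dif]
      diag_rows[[length(diag_rows) + 1L]] <- data.table(
        gene = gid, pos = xmap[ap] + 1L - 1L, x_allele = bx[dif],
        y_allele = by_[dif], in_cds = ap <= cds_len)
    }
    # indel differences between haplotypes, on X-transcript coordinates
    ied <- rbind(
      if (nrow(g$y$utr_ed[type != "sub"])) {
        g$y$utr_ed[type != "sub",
                   .(pos = pos + cds_len, type, len, bases, side = "Y")]
      },
      if (nrow(g$x$utr_ed[type != "sub"])) {
        g$x$utr_ed[type != "sub",
                   .(pos = pos + cds_len, type, len, bases, side = "X")]
      },
      if (nrow(g$lesions[type != "ptc_codon"])) {
        g$lesions[type != "ptc_codon",
                  .(pos, type, len, bases, side = "Y")]
      })
    if (!is.null(ied) && nrow(ied)) {
      ied[, pos := vapply(pos, function(p) {
        i <- p
        while (i < length(xmap) && is.na(xmap[i + 1L])) i <- i + 1L
        xmap[i + 1L] %||% NA_integer_
      }, integer(1))]
      indel_rows[[length(indel_rows) + 1L]] <- cbind(gene = gid, ied)
    }
    if (!is.na(g$ptc_codon) || !is.na(g$fs_pos)) {
      lesion_rows[[length(lesion_rows) + 1L]] <- data.table(
        gene = gid,
        ptc_codon = g$ptc_codon,
        fs_pos = g$fs_pos,
        fs_type = if (!is.na(g$fs_pos)) g$lesions[type %in% c("del", "ins"),
                                                  type][1] else NA_character_,
        fs_len = if (!is.na(g$fs_pos)) g$lesions[type %in% c("del", "ins"),
                                                 len][1] else NA_integer_)
    }
    # genomes
    x_genomic <- assemble_genomic(g$x$cds_seq, g$x$cds_map, g$pts,
                                  g$introns, ux$seq)
    y_genomic <- assemble_genomic(g$y$cds_seq, g$y$cds_map, g$pts,
                                  g$introns, uy$seq)
    if (state != "neoX_deleted") {
      genome_rows[[length(genome_rows) + 1L]] <- data.table(
        gene = gid, hap = "X", sex_presence = "both", bases = x_genomic,
        depth_share = 0.5)
    }
    if (state != "neoY_deleted") {
      genome_rows[[length(genome_rows) + 1L]] <- data.table(
        gene = gid, hap = "Y", sex_presence = "male", bases = y_genomic,
        depth_share = 0.5)
    }
    # assemblies: the male assembly transcript carries the X sequence (the
    # mixed assembler resolves the less-degenerate haplotype); for an
    # X-deleted gene the only copy is the Y
    male_ids <- c(male_ids, gid)
    male_seqs <- c(male_seqs,
                   if (state == "neoX_deleted") y_transcript else x_transcript)
    male_cls <- c(male_cls, "neoX")
    if (state != "neoX_deleted") {
      fem_ids <- c(fem_ids, paste0(gid, "_F"))
      fem_seqs <- c(fem_seqs, x_transcript)
    }
    ref_ids <- c(ref_ids, sub("^g", "r", gid))
    ref_seqs <- c(ref_seqs, g$out$cds_seq)
    x_tx <- c(x_tx, setNames(x_transcript, gid))
    y_tx <- c(y_tx, setNames(y_transcript, gid))
    gene_rows[[length(gene_rows) + 1L]] <- data.table(
      gene = gid, class = "neo", state = state, cds_len = cds_len,
      tx_len = nchar(x_transcript), ptc_codon = g$ptc_codon,
      fs_pos = g$fs_pos, n_cod = g$n_cod)
  }

  truth_genes <- rbindlist(gene_rows)
  # expression levels
  lvl <- rlnorm(nrow(truth_genes), cfg$expr_meanlog, cfg$expr_sdlog)
  expr <- truth_genes[, .(gene, state)]
  expr[, level_base := lvl]
  expr[, level_X := fifelse(state == "neoX_deleted", 0, level_base)]
  nonfunc <- expr$gene %in% truth_genes[!is.na(ptc_codon) | !is.na(fs_pos),
                                        gene]
  expr[, level_Y := fifelse(state %in% c("neoY_deleted", "neoY_silenced",
                                         "autosome"),
                            0, level_base)]
  expr[nonfunc & level_Y > 0,
       level_Y := level_Y * cfg$nonfunctional_expression_factor]

  prot <- vapply(ref_seqs, function(s) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1L, nchar(s) - 3L))))
  }, character(1))
  names(prot) <- ref_ids

  list(
    config = cfg,
    male_assembly = transcript_set(male_ids, male_seqs, male_cls),
    female_assembly = if (length(fem_ids)) {
      transcript_set(fem_ids, fem_seqs, "neoX")
    } else NULL,
    outgroup_cds = transcript_set(ref_ids, ref_seqs, "unknown"),
    outgroup_protein = prot,
    genome = rbindlist(genome_rows),
    truth = list(
      genes = truth_genes,
      diagnostic_sites = if (length(diag_rows)) rbindlist(diag_rows)
      else data.table(gene = character(), pos = integer(),
                      x_allele = character(), y_allele = character(),
                      in_cds = logical()),
      indel_diffs = if (length(indel_rows)) rbindlist(indel_rows)
      else data.table(),
      lesions = if (length(lesion_rows)) rbindlist(lesion_rows)
      else data.table(gene = character(), ptc_codon = integer(),
                      fs_pos = integer(), fs_type = character(),
                      fs_len = integer()),
      expression = expr,
      neoX_transcripts = x_tx,
      neoY_transcripts = y_tx))
}

# draw reads from one source sequence
draw_reads <- function(bases, depth, L, prefix, error_rate = 0) {
  n_len <- nchar(bases)
  if (n_len < L) return(NULL)
  n <- round(depth * n_len / L)
  if (n <= 0L) return(NULL)
  starts <- sample.int(n_len - L + 1L, n, replace = TRUE)
  seqs <- substring(bases, starts, starts + L - 1L)
  minus <- runif(n) < 0.5
  seqs[minus] <- revcomp(seqs[minus])
  quals <- rep(strrep("I", L), n)
  if (error_rate > 0) {
    nerr <- rbinom(n, L, error_rate)
    for (i in which(nerr > 0L)) {
      s <- strsplit(seqs[i], "")[[1]]
      q <- strsplit(quals[i], "")[[1]]
      at <- sample.int(L, nerr[i])
      for (p in at) {
        s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        q[p] <- "+" # Phred 10: fails the >13 quality bound
      }
      seqs[i] <- paste(s, collapse = "")
      quals[i] <- paste(q, collapse = "")
    }
  }
  list(id = sprintf("%s_%06d", prefix, seq_len(n)), bases = seqs,
       qual = quals)
}

#' Simulate genomic reads per sex
#'
#' Male reads are drawn 50/50 from the X and Y haplotype genomes at the
#' configured total male depth; female reads come from the X haplotype only.
#' Autosomal genes are sampled at the full per-sex depth. Error-free reads
#' are exact substrings of their source haplotype.
#'
#' @param sim a [simulate_gene_set()] bundle.
#' @param config the same [sim_config()].
#' @return list with `male` and `female` [read_set()]s.
#' @export
simulate_genomic_reads <- function(sim, config = sim$config) {
  L <- config$read_length
  er <- config$sequencing_error_rate
  male_parts <- list(); fem_parts <- list()
  for (i in seq_len(nrow(sim$genome))) {
    row <- sim$genome[i]
    dep_m <- config$male_genomic_depth * row$depth_share
    # the female is homozygous (two identical copies), so her full per-sex
    # depth lands on each present sequence
    dep_f <- config$female_genomic_depth
    pre <- paste0(row$gene, "_", row$hap)
    male_parts[[i]] <- draw_reads(row$bases, dep_m, L,
                                  paste0("m_", pre), er)
    if (row$sex_presence == "both") {
      fem_parts[[i]] <- draw_reads(row$bases, dep_f, L,
                                   paste0("f_", pre), er)
    }
  }
  mk <- function(parts, sex) {
    parts <- Filter(Negate(is.null), parts)
    read_set(unlist(lapply(parts, `[[`, "id")),
             unlist(lapply(parts, `[[`, "bases")),
             unlist(lapply(parts, `[[`, "qual")),
             sex = sex, source = "genomic")
  }
  list(male = mk(male_parts, "male"), female = mk(fem_parts, "female"))
}

#' Simulate RNA-seq reads for the male samples
#'
#' Read counts are multinomial over (transcript, haplotype) proportional to
#' expression level times length; silenced copies yield zero reads and
#' lesion-carrying Y copies are down-weighted by the non-functional
#' expression factor. Reads are exact substrings of the true haplotype
#' transcripts in error-free mode.
#'
#' @param sim a [simulate_gene_set()] bundle.
#' @param config the same [sim_config()].
#' @param tissue sample name (one of `config$tissues`).
#' @return a [read_set()] with `source = "rna"`.
#' @export
simulate_rna_reads <- function(sim, config = sim$config,
                               tissue = config$tissues[1]) {
  L <- config$read_length
  ex <- sim$truth$expression
  units <- list()
  for (i in seq_len(nrow(ex))) {
    gid <- ex$gene[i]
    if (ex$state[i] == "autosome") {
      units[[length(units) + 1L]] <- list(
        id = gid, hap = "A", bases = sim$truth$neoX_transcripts[[gid]],
        level = ex$level_base[i])
      next
    }
    if (ex$level_X[i] > 0) {
      units[[length(units) + 1L]] <- list(
        id = gid, hap = "X", bases = sim$truth$neoX_transcripts[[gid]],
        level = ex$level_X[i])
    }
    if (ex$level_Y[i] > 0) {
      units[[length(units) + 1L]] <- list(
        id = gid, hap = "Y", bases = sim$truth$neoY_transcripts[[gid]],
        level = ex$level_Y[i])
    }
  }
  lens <- vapply(units, function(u) nchar(u$bases), numeric(1))
  lvls <- vapply(units, `[[`, numeric(1), "level")
  total <- round(config$rna_depth * sum(lens) / L)
  w <- lvls * lens
  counts <- as.vector(stats::rmultinom(1, total, w / sum(w)))
  parts <- lapply(seq_along(units), function(i) {
    if (counts[i] == 0L) return(NULL)
    u <- units[[i]]
    draw_reads(u$bases, counts[i] * L / nchar(u$bases), L,
               paste0("r_", u$id, "_", u$hap),
               config$sequencing_error_rate)
  })
  parts <- Filter(Negate(is.null), parts)
  read_set(unlist(lapply(parts, `[[`, "id")),
           unlist(lapply(parts, `[[`, "bases")),
           unlist(lapply(parts, `[[`, "qual")),
           sex = "male", source = "rna")
}

#' Simulate a complete seeded dataset
#'
#' Seeds the RNG from `config$seed`, then generates the gene set, genomic
#' reads for both sexes, and RNA reads per tissue. Identical configurations
#' give byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @return the [simulate_gene_set()] bundle extended with `genomic_reads`
#'   (list `male`/`female`) and `rna_reads` (list per tissue).
#' @export
simulate_all <- function(config = sim_config()) {
  set.seed(config$seed)
  sim <- simulate_gene_set(config)
  sim$genomic_reads <- simulate_genomic_reads(sim, config)
  sim$rna_reads <- setNames(
    lapply(config$tissues, function(tt) simulate_rna_reads(sim, config, tt)),
    config$tissues)
  sim
}
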