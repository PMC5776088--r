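# Synthetic editome dataset generator: toy diploid genome, stranded gene
# models, Alu-like repeats, planted germline SNPs and planted editing
# events with per-sample presence patterns, plus pileup evidence and
# two-caller VCFs derived from it. All randomness flows through per-file
# RNG streams derived from the master seed.

runs_to_intervals <- function(pos) {
  pos <- sort(unique(pos))
  if (length(pos) == 0L) return(empty_df(start = "integer", end = "integer"))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  data.frame(start = pos[brk[-length(brk)] + 1L], end = pos[brk[-1L]])
}

# sample a presence subset of the four samples for a pattern label
presence_for_pattern <- function(pattern) {
  switch(pattern,
         ALL = EDITOME_SAMPLES,
         STN = c("NL", sample(TUMOR_SAMPLES, sample(1:2, 1L))),
         ST = sample(TUMOR_SAMPLES, sample(2:3, 1L)),
         pattern)
}

simulate_transcripts <- function(config) {
  meta <- list(); exons <- list(); cds <- list()
  cursor <- rep(1000L, config$n_chromosomes)
  for (i in seq_len(config$n_transcripts)) {
    ch <- (i - 1L) %% config$n_chromosomes + 1L
    tx_id <- sprintf("tx%04d", i)
    gene_id <- sprintf("g%04d", i)
    n_ex <- sample(2:4, 1L)
    ex_len <- sample(150:500, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(300:900, n_ex - 1L, replace = TRUE)
              else integer(0L)
    start <- cursor[ch] + sample(300:800, 1L)
    ex_start <- start + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len - 1L
    if (max(ex_end) > config$chrom_length - 1000L) {
      stop("invalid simulation configuration: field 'chrom_length' too ",
           "small for n_transcripts", call. = FALSE)
    }
    cursor[ch] <- max(ex_end)
    strand <- sample(c("+", "-"), 1L)
    coding <- stats::runif(1L) >= config$frac_noncoding
    meta[[i]] <- data.frame(transcript_id = tx_id, gene_id = gene_id,
                            chrom = paste0("chr", ch), strand = strand,
                            biotype = if (coding) "coding" else "lncRNA",
                            stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(transcript_id = tx_id, start = ex_start,
                             end = ex_end, stringsAsFactors = FALSE)
    if (coding) {
      spliced <- sum(ex_len)
      utr5 <- sample(40:120, 1L)
      utr3 <- sample(40:120, 1L)
      cds_len <- 3L * ((spliced - utr5 - utr3) %/% 3L)
      # spliced positions in transcription order
      gpos <- unlist(Map(seq.int, ex_start, ex_end), use.names = FALSE)
      if (strand == "-") gpos <- rev(gpos)
      cds_pos <- gpos[(utr5 + 1L):(utr5 + cds_len)]
      iv <- runs_to_intervals(cds_pos)
      cds[[i]] <- data.frame(transcript_id = tx_id, start = iv$start,
                             end = iv$end, stringsAsFactors = FALSE)
    }
  }
  list(meta = do.call(rbind, meta), exons = do.call(rbind, exons),
       cds = do.call(rbind, cds[!vapply(cds, is.null, logical(1L))]))
}

simulate_repeats <- function(config, tx) {
  place <- function(n, len_lo, len_hi, families) {
    if (n == 0L) {
      return(empty_df(chrom = "character", start = "integer",
                      end = "integer", family = "character"))
    }
    lens <- sample(len_lo:len_hi, n, replace = TRUE)
    in_tx <- stats::runif(n) < 0.7 & nrow(tx) > 0L
    chrom <- character(n); start <- integer(n)
    for (i in seq_len(n)) {
      if (in_tx[i]) {
        j <- sample.int(nrow(tx), 1L)
        chrom[i] <- tx$chrom[j]
        lo <- tx$start[j]
        hi <- max(lo, tx$end[j] - lens[i])
        start[i] <- sample(lo:hi, 1L)
      } else {
        chrom[i] <- paste0("chr", sample.int(config$n_chromosomes, 1L))
        start[i] <- sample.int(config$chrom_length - lens[i], 1L)
      }
    }
    data.frame(chrom = chrom, start = start, end = start + lens - 1L,
               family = sample(families, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  alu <- place(config$n_alu, config$alu_length_range[1L],
               config$alu_length_range[2L], c("AluY", "AluSx", "AluJb"))
  rest <- place(config$n_nonalu, 300L, 1500L, c("L1", "L2", "MIR", "LTR"))
  rep_df <- rbind(alu, rest)
  rep_df$is_alu <- startsWith(rep_df$family, "Alu")
  rep_df[order(rep_df$chrom, rep_df$start), , drop = FALSE]
}

simulate_editing_sites <- function(config, db) {
  n <- config$n_editing_sites
  base_cols <- list(chrom = "character", pos = "integer", ref = "character",
                    alt = "character", ref_tx = "character",
                    alt_tx = "character", strand = "character",
                    transcript_id = "character", region = "character",
                    pattern = "character")
  if (n == 0L || nrow(db$transcripts) == 0L) {
    out <- do.call(empty_df, base_cols)
    for (s in EDITOME_SAMPLES) out[[paste0("present_", s)]] <- logical(0L)
    for (s in EDITOME_SAMPLES) out[[paste0("rate_", s)]] <- numeric(0L)
    return(out)
  }
  other_types <- setdiff(EDITING_TYPES, "A-to-G")
  # editing concentrates in 3'UTRs of coding transcripts (ADAR acts on
  # 3'UTR double-stranded structure), so placement samples a region class
  # first rather than a uniform position over the span
  region_weight <- c(UTR3 = 0.45, Intron = 0.3, CDS = 0.2, UTR5 = 0.05,
                     Exon = 0.5)
  used <- character(0L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      j <- sample.int(nrow(db$transcripts), 1L)
      tx <- db$transcripts[j, ]
      tx_reg <- db$regions[db$regions$transcript_id == tx$transcript_id, ]
      classes <- unique(tx_reg$region)
      cls <- sample(classes, 1L, prob = region_weight[classes])
      cand_iv <- tx_reg[tx_reg$region == cls, , drop = FALSE]
      r <- cand_iv[sample.int(nrow(cand_iv), 1L,
                              prob = cand_iv$end - cand_iv$start + 1L), ]
      pos <- sample(r$start:r$end, 1L)
      if (!pos_key(tx$chrom, pos) %in% used) break
    }
    used <- c(used, pos_key(tx$chrom, pos))
    if (stats::runif(1L) < config$frac_a_to_g) {
      type <- "A-to-G"
    } else {
      type <- sample(other_types, 1L)
    }
    ref_tx <- substr(type, 1L, 1L)
    alt_tx <- substr(type, 6L, 6L)
    if (tx$strand == "+") {
      ref <- ref_tx; alt <- alt_tx
    } else {
      ref <- unname(BASE_COMPLEMENT[ref_tx])
      alt <- unname(BASE_COMPLEMENT[alt_tx])
    }
    reg <- db$regions[db$regions$transcript_id == tx$transcript_id &
                        db$regions$start <= pos & db$regions$end >= pos, ]
    pattern <- sample(names(config$pattern_weights), 1L,
                      prob = config$pattern_weights)
    presence <- presence_for_pattern(pattern)
    pres <- EDITOME_SAMPLES %in% presence
    rate <- ifelse(pres,
                   stats::runif(4L, config$editing_rate_range[1L],
                                config$editing_rate_range[2L]),
                   NA_real_)
    row <- data.frame(chrom = tx$chrom, pos = pos, ref = ref, alt = alt,
                      ref_tx = ref_tx, alt_tx = alt_tx, strand = tx$strand,
                      transcript_id = tx$transcript_id,
                      region = reg$region[1L], pattern = pattern,
                      stringsAsFactors = FALSE)
    for (k in seq_along(EDITOME_SAMPLES)) {
      row[[paste0("present_", EDITOME_SAMPLES[k])]] <- pres[k]
    }
    for (k in seq_along(EDITOME_SAMPLES)) {
      row[[paste0("rate_", EDITOME_SAMPLES[k])]] <- rate[k]
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Simulate a pileup evidence table for one sample and modality
#'
#' Generates per-read base observations at every covered position of the
#' ground truth (planted editing sites, planted SNPs and background
#' positions). DNA pileups show only reference and germline alleles plus
#' sequencing error; RNA pileups additionally show the edited base at the
#' planted per-sample editing rate where the site is present. Read
#' placement is uniform over the read, so the distance of the site to the
#' read ends varies; per-position depth is Poisson around the configured
#' mean.
#'
#' @param truth a ground-truth object from [generate_dataset()] (or a list
#'   with elements sites, snps, background, config).
#' @param sample one of [EDITOME_SAMPLES].
#' @param modality "DNA" or "RNA".
#' @param depth mean depth; defaults to the configured dna/rna depth.
#' @param error_rate per-base error probability; defaults to configured.
#' @param seed RNG seed for this pileup.
#' @return pileup data frame (see [read_pileup()]).
#' @export
simulate_pileup <- function(truth, sample, modality,
                            depth = NULL, error_rate = NULL, seed = 1L) {
  if (!sample %in% EDITOME_SAMPLES) {
    stop("unknown sample id: ", sample)
  }
  modality <- match.arg(modality, c("DNA", "RNA"))
  config <- truth$config
  if (is.null(depth)) {
    depth <- if (modality == "DNA") config$dna_depth else config$rna_depth
  }
  if (is.null(error_rate)) error_rate <- config$seq_error_rate
  L <- config$read_length

  sites <- truth$sites
  pres <- if (nrow(sites)) sites[[paste0("present_", sample)]] else logical(0L)
  rate <- if (nrow(sites)) sites[[paste0("rate_", sample)]] else numeric(0L)
  positions <- rbind(
    if (nrow(sites)) data.frame(chrom = sites$chrom, pos = sites$pos,
                                ref = sites$ref, kind = "site",
                                alt = sites$alt,
                                rate = ifelse(pres, rate, 0),
                                stringsAsFactors = FALSE),
    if (nrow(truth$snps)) data.frame(chrom = truth$snps$chrom,
                                     pos = truth$snps$pos,
                                     ref = truth$snps$ref,
                                     kind = paste0("snp_",
                                                   truth$snps$genotype),
                                     alt = truth$snps$alt, rate = 0,
                                     stringsAsFactors = FALSE),
    if (nrow(truth$background)) data.frame(chrom = truth$background$chrom,
                                           pos = truth$background$pos,
                                           ref = truth$background$ref,
                                           kind = "bg", alt = NA_character_,
                                           rate = 0,
                                           stringsAsFactors = FALSE))
  if (is.null(positions) || nrow(positions) == 0L) {
    return(empty_df(chrom = "character", pos = "integer", ref = "character",
                    base = "character", qual = "integer", dist5 = "integer",
                    dist3 = "integer", read_id = "character"))
  }
  set.seed(seed)
  n_reads <- stats::rpois(nrow(positions), depth)
  idx <- rep(seq_len(nrow(positions)), n_reads)
  n <- length(idx)
  offset <- sample.int(L, n, replace = TRUE) - 1L

  base <- positions$ref[idx]
  kind <- positions$kind[idx]
  alt <- positions$alt[idx]
  # germline alleles appear in both modalities
  het <- kind == "snp_het"
  base[het] <- ifelse(stats::runif(sum(het)) < 0.5, base[het], alt[het])
  base[kind == "snp_hom"] <- alt[kind == "snp_hom"]
  if (modality == "RNA") {
    is_site <- kind == "site"
    edited <- is_site & stats::runif(n) < positions$rate[idx]
    base[edited] <- alt[edited]
  }
  err <- stats::runif(n) < error_rate
  if (any(err)) {
    pick <- function(b) sample(setdiff(DNA_BASES, b), 1L)
    base[err] <- vapply(base[err], pick, character(1L))
  }
  # Phred quality estimates the error probability, so erroneous bases carry
  # predominantly low qualities and correct bases high ones
  qual <- as.integer(pmin(40, pmax(2, round(
    ifelse(err, stats::rnorm(n, 12, 6), stats::rnorm(n, 34, 5))))))
  out <- data.frame(chrom = positions$chrom[idx], pos = positions$pos[idx],
                    ref = positions$ref[idx], base = base, qual = qual,
                    dist5 = offset, dist3 = L - 1L - offset,
                    read_id = sprintf("%s_%s_r%07d", modality, sample,
                                      seq_len(n)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive internal pileup caller: stand-in producing the two caller VCF call
# sets with different sensitivity profiles. Caller A calls any alternate
# base with >= 2 supporting reads; caller B additionally requires the
# allele fraction to reach `min_af` (it misses low-fraction variants).
call_pileup_variants <- function(pileup, caller, sample, modality,
                                 min_af = 0.1) {
  rows <- list()
  for (col in pileup_index(pileup)) {
    ref <- col$ref[1L]
    depth <- nrow(col)
    tab <- table(col$base[col$base != ref])
    for (b in names(tab)) {
      n_alt <- as.integer(tab[[b]])
      af <- n_alt / depth
      ok <- if (caller == "callerA") n_alt >= 2L
            else n_alt >= 2L && af >= min_af
      if (!ok) next
      gt <- if (af >= 0.85) gt_string(b, b) else gt_string(ref, b)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = col$chrom[1L], pos = col$pos[1L], ref = ref, alt = b,
        sample = sample, modality = modality, caller = caller, gt = gt,
        depth = depth, alt_support = n_alt,
        base_qual = min(col$qual[col$base == b]), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else variant_call_df()
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# independent plain-loop bookkeeping of which planted site/sample events
# satisfy every detection condition on the realized pileups: callable by
# both RNA callers, adequately DNA-covered with a genotype differing from
# the RNA genotype, single alternate allele, and passing the four evidence
# filters. Used as the denominator of recovery sensitivity.
compute_detectable <- function(sites, rna_pileups, dna_pileups, config,
                               fconf = filter_config()) {
  for (s in EDITOME_SAMPLES) {
    sites[[paste0("detectable_", s)]] <- rep(FALSE, nrow(sites))
  }
  if (nrow(sites) == 0L) return(sites)
  for (s in EDITOME_SAMPLES) {
    rna_idx <- pileup_index(rna_pileups[[s]])
    dna_idx <- pileup_index(dna_pileups[[s]])
    det <- logical(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      if (!sites[[paste0("present_", s)]][i]) next
      pk <- pos_key(sites$chrom[i], sites$pos[i])
      col <- rna_idx[[pk]]
      if (is.null(col)) next
      sup <- col[col$base == sites$alt[i], , drop = FALSE]
      n_alt <- nrow(sup)
      depth <- nrow(col)
      af <- n_alt / depth
      # both simulated callers must fire (RNA merge is an intersection)
      if (!(n_alt >= 2L && af >= config$caller_b_min_af)) next
      # the four evidence filters
      if (min(sup$qual) < fconf$min_base_qual) next
      if (depth < fconf$min_depth) next
      if (min(pmin(sup$dist5, sup$dist3)) < fconf$min_end_distance) next
      if (n_alt < fconf$min_alt_reads) next
      # single alternate allele with real support
      alt_tab <- table(col$base[col$base != sites$ref[i]])
      if (sum(alt_tab >= fconf$min_alt_reads) > 1L) next
      # DNA coverage and genotype difference
      dcol <- dna_idx[[pk]]
      if (is.null(dcol) || nrow(dcol) < fconf$min_depth) next
      rna_gt <- if (af >= 0.85) gt_string(sites$alt[i], sites$alt[i])
                else gt_string(sites$ref[i], sites$alt[i])
      dna_tab <- table(dcol$base[dcol$base != sites$ref[i]])
      dna_gt <- gt_string(sites$ref[i], sites$ref[i])
      if (length(dna_tab)) {
        db_ <- names(dna_tab)[which.max(dna_tab)]
        n_d <- max(dna_tab)
        if (n_d >= 2L) {
          daf <- n_d / nrow(dcol)
          dna_gt <- if (daf >= 0.85) gt_string(db_, db_)
                    else gt_string(sites$ref[i], db_)
        }
      }
      if (identical(dna_gt, rna_gt)) next
      det[i] <- TRUE
    }
    sites[[paste0("detectable_", s)]] <- det
  }
  sites
}

#' Generate the full synthetic editome dataset
#'
#' Writes a self-consistent toy dataset with known ground truth: genome
#' FASTA, transcript GTF, repeat BED, known-SNP VCF, per-sample per-caller
#' DNA and RNA VCFs, per-sample pileup tables, an expression table, a
#' miRNA-target BED and a damaging-annotation table. The same seed yields
#' byte-identical outputs.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a ground-truth object of class `editome_truth`: list
#'   with `sites` (planted events with per-sample presence, rates, expected
#'   pattern and per-sample detectability under the default thresholds),
#'   `snps`, `background`, `config` and `paths` (named file paths).
#' @export
generate_dataset <- function(config = simulation_config(), outdir) {
  validate_simulation_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  seeds <- vapply(1:40, function(k) derive_seed(config$seed, k), integer(1L))

  # genome as per-chromosome character vectors (patched below)
  set.seed(seeds[1L])
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genome_chars <- lapply(chroms, function(ch) {
    sample(DNA_BASES, config$chrom_length, replace = TRUE)
  })
  names(genome_chars) <- chroms

  set.seed(seeds[2L])
  tx_parts <- simulate_transcripts(config)
  db <- transcript_db(tx_parts$meta, tx_parts$exons,
                      if (is.null(tx_parts$cds)) {
                        empty_df(transcript_id = "character",
                                 start = "integer", end = "integer")
                      } else tx_parts$cds)

  set.seed(seeds[3L])
  repeats <- simulate_repeats(config, db$transcripts)

  set.seed(seeds[4L])
  sites <- simulate_editing_sites(config, db)
  # force the planted reference base into the genome
  for (i in seq_len(nrow(sites))) {
    genome_chars[[sites$chrom[i]]][sites$pos[i]] <- sites$ref[i]
  }

  set.seed(seeds[5L])
  taken <- pos_key(sites$chrom, sites$pos)
  snps <- local({
    n <- config$n_germline_snps
    if (n == 0L) {
      return(empty_df(chrom = "character", pos = "integer",
                      ref = "character", alt = "character",
                      genotype = "character"))
    }
    chrom <- paste0("chr", sample.int(config$n_chromosomes, n * 2L,
                                      replace = TRUE))
    pos <- sample.int(config$chrom_length, n * 2L, replace = TRUE)
    keep <- !duplicated(pos_key(chrom, pos)) & !pos_key(chrom, pos) %in% taken
    chrom <- chrom[keep][seq_len(n)]
    pos <- pos[keep][seq_len(n)]
    ref <- vapply(seq_len(n), function(i) genome_chars[[chrom[i]]][pos[i]],
                  character(1L))
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                  character(1L))
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
               genotype = sample(c("het", "hom"), n, replace = TRUE,
                                 prob = c(0.7, 0.3)),
               stringsAsFactors = FALSE)
  })

  set.seed(seeds[6L])
  taken <- c(taken, pos_key(snps$chrom, snps$pos))
  background <- local({
    n <- config$n_background_positions
    if (n == 0L) {
      return(empty_df(chrom = "character", pos = "integer",
                      ref = "character"))
    }
    chrom <- paste0("chr", sample.int(config$n_chromosomes, n * 2L,
                                      replace = TRUE))
    pos <- sample.int(config$chrom_length, n * 2L, replace = TRUE)
    keep <- !duplicated(pos_key(chrom, pos)) & !pos_key(chrom, pos) %in% taken
    chrom <- chrom[keep][seq_len(n)]
    pos <- pos[keep][seq_len(n)]
    ref <- vapply(seq_len(n), function(i) genome_chars[[chrom[i]]][pos[i]],
                  character(1L))
    data.frame(chrom = chrom, pos = pos, ref = ref, stringsAsFactors = FALSE)
  })

  # static annotation files
  genome <- Biostrings::DNAStringSet(
    vapply(genome_chars, paste, character(1L), collapse = ""))
  names(genome) <- chroms
  paths$genome <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(genome, paths$genome)
  paths$gtf <- file.path(outdir, "transcripts.gtf")
  write_gtf(db, paths$gtf)
  paths$repeats <- file.path(outdir, "repeats.bed")
  write_bed6(repeats, repeats$family, paths$repeats)
  paths$snps <- file.path(outdir, "known_snps.vcf")
  snp_calls <- if (nrow(snps)) {
    data.frame(chrom = snps$chrom, pos = snps$pos, ref = snps$ref,
               alt = snps$alt, sample = "POPULATION", modality = "DNA",
               caller = "database",
               gt = ifelse(snps$genotype == "het",
                           gt_string(snps$ref, snps$alt),
                           gt_string(snps$alt, snps$alt)),
               depth = 0L, alt_support = 0L, base_qual = NA_integer_,
               stringsAsFactors = FALSE)
  } else {
    variant_call_df()
  }
  write_vcf(snp_calls, paths$snps,
            contigs = stats::setNames(rep(config$chrom_length,
                                          length(chroms)), chroms))

  # miRNA targets tiling roughly half of each coding 3'UTR
  set.seed(seeds[7L])
  utr3 <- db$regions[db$regions$region == "UTR3", , drop = FALSE]
  mirna_pool <- sprintf("hsa-mir-sim-%02d", seq_len(max(1L, config$n_mirna)))
  targets <- local({
    rows <- list()
    for (i in seq_len(nrow(utr3))) {
      cur <- utr3$start[i]
      repeat {
        cur <- cur + sample(5:25, 1L)
        len <- sample(8:22, 1L)
        if (cur + len - 1L > utr3$end[i]) break
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = utr3$chrom[i], start = cur, end = cur + len - 1L,
          mirna = sample(mirna_pool, 1L), stringsAsFactors = FALSE)
        cur <- cur + len
      }
    }
    if (length(rows)) do.call(rbind, rows)
    else empty_df(chrom = "character", start = "integer", end = "integer",
                  mirna = "character")
  })
  paths$mirna_targets <- file.path(outdir, "mirna_targets.bed")
  write_bed6(targets, targets$mirna, paths$mirna_targets)

  # expression: lognormal baseline with mild per-sample noise
  set.seed(seeds[8L])
  expression <- local({
    tx_ids <- db$transcripts$transcript_id
    baseline <- stats::rlnorm(length(tx_ids), meanlog = 3, sdlog = 1.2)
    do.call(rbind, lapply(EDITOME_SAMPLES, function(s) {
      data.frame(transcript_id = tx_ids, sample = s,
                 fpkm = round(baseline *
                                stats::rlnorm(length(tx_ids), 0, 0.15), 4L),
                 stringsAsFactors = FALSE)
    }))
  })
  paths$expression <- file.path(outdir, "expression.tsv")
  write_stage_tsv(expression, paths$expression)

  # external damaging/tolerated annotation for CDS sites
  set.seed(seeds[9L])
  cds_sites <- sites[sites$region == "CDS", , drop = FALSE]
  damaging <- if (nrow(cds_sites)) {
    data.frame(chrom = cds_sites$chrom, pos = cds_sites$pos,
               effect = sample(c("damaging", "tolerated"),
                               nrow(cds_sites), replace = TRUE),
               stringsAsFactors = FALSE)
  } else {
    empty_df(chrom = "character", pos = "integer", effect = "character")
  }
  paths$damaging <- file.path(outdir, "damaging.tsv")
  write_stage_tsv(damaging, paths$damaging)

  # evidence: pileups, then two-caller VCFs derived from them
  truth <- list(sites = sites, snps = snps, background = background,
                config = config)
  rna_pileups <- list(); dna_pileups <- list()
  k <- 10L
  contigs <- stats::setNames(rep(config$chrom_length, length(chroms)),
                             chroms)
  for (s in EDITOME_SAMPLES) {
    for (mod in c("DNA", "RNA")) {
      pile <- simulate_pileup(truth, s, mod, seed = seeds[k])
      k <- k + 1L
      key <- paste0(tolower(mod), "_pileup_", s)
      paths[[key]] <- file.path(outdir,
                                sprintf("pileup_%s_%s.tsv", tolower(mod), s))
      write_pileup(pile, paths[[key]])
      if (mod == "RNA") rna_pileups[[s]] <- pile else dna_pileups[[s]] <- pile
      for (caller in c("callerA", "callerB")) {
        calls <- call_pileup_variants(pile, caller, s, mod,
                                      min_af = config$caller_b_min_af)
        vkey <- paste0(tolower(mod), "_", caller, "_", s)
        paths[[vkey]] <- file.path(outdir,
                                   sprintf("%s_%s_%s.vcf", tolower(mod),
                                           caller, s))
        write_vcf(calls, paths[[vkey]], contigs = contigs)
      }
    }
  }

  truth$sites <- compute_detectable(sites, rna_pileups, dna_pileups, config)
  truth$paths <- paths
  class(truth) <- "editome_truth"

  paths$ground_truth <- file.path(outdir, "ground_truth.tsv")
  truth$paths <- paths
  gt_out <- truth$sites
  write_stage_tsv(gt_out, paths$ground_truth)
  invisible(truth)
}
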