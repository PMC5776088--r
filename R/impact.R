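# Functional impact: miRNA-target enrichment of 3'UTR sites, codon
# recoding in CDS, expression-change comparison by Kolmogorov-Smirnov.

#' Hypergeometric enrichment of 3'UTR editing sites in miRNA targets
#'
#' Tests whether 3'UTR editing sites fall inside miRNA target intervals
#' more often than expected under uniform placement. The universe is
#' base-resolution: every 3'UTR base is a trial (N), target-covered 3'UTR
#' bases are successes (K), the n sites are draws and k of them hit
#' targets. The p-value is the upper tail P[X >= k] of the hypergeometric
#' distribution. Also ranks miRNAs by the number of distinct edited sites
#' inside their targets (ties broken lexicographically); a site overlapping
#' several miRNAs' targets counts once for k but once per miRNA in the
#' ranking.
#'
#' @param utr3_sites data frame with columns chrom, pos (3'UTR sites only).
#' @param target_intervals data frame with columns chrom, start, end,
#'   mirna (1-based inclusive).
#' @param utr3_universe data frame with columns chrom, start, end: the
#'   3'UTR intervals forming the universe.
#' @return list with elements k, n, K, N, p_value, target_fraction (k/n)
#'   and `ranking` (data frame mirna, edited_targets, sorted).
#' @export
mirna_target_enrichment <- function(utr3_sites, target_intervals,
                                    utr3_universe) {
  uni_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    utr3_universe$chrom,
    IRanges::IRanges(utr3_universe$start, utr3_universe$end)))
  N <- sum(GenomicRanges::width(uni_gr))
  tgt_gr <- GenomicRanges::GRanges(
    target_intervals$chrom,
    IRanges::IRanges(target_intervals$start, target_intervals$end))
  covered <- GenomicRanges::reduce(
    GenomicRanges::intersect(tgt_gr, uni_gr, ignore.strand = TRUE))
  K <- sum(GenomicRanges::width(covered))
  if (K > N) stop("target-covered bases exceed the universe")

  sites <- unique(utr3_sites[, c("chrom", "pos")])
  n <- nrow(sites)
  if (n == 0L) {
    warning("no 3'UTR sites supplied; enrichment undefined")
    return(list(k = 0L, n = 0L, K = K, N = N, p_value = NA_real_,
                target_fraction = NA_real_,
                ranking = empty_df(mirna = "character",
                                   edited_targets = "integer")))
  }
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(site_gr, tgt_gr, ignore.strand = TRUE)
  k <- length(unique(S4Vectors::queryHits(hits)))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)

  per_mirna <- data.frame(
    mirna = target_intervals$mirna[S4Vectors::subjectHits(hits)],
    site = S4Vectors::queryHits(hits), stringsAsFactors = FALSE)
  per_mirna <- unique(per_mirna)
  if (nrow(per_mirna)) {
    counts <- table(per_mirna$mirna)
    ranking <- data.frame(mirna = names(counts),
                          edited_targets = as.integer(counts),
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(-ranking$edited_targets, ranking$mirna), ]
    rownames(ranking) <- NULL
  } else {
    ranking <- empty_df(mirna = "character", edited_targets = "integer")
  }
  list(k = k, n = n, K = K, N = N, p_value = p, target_fraction = k / n,
       ranking = ranking)
}

# spliced CDS genomic positions in translation order for one transcript
spliced_cds_positions <- function(db, tx_id) {
  cd <- db$cds[db$cds$transcript_id == tx_id, , drop = FALSE]
  if (nrow(cd) == 0L) stop("transcript has no CDS: ", tx_id)
  pos <- unlist(Map(seq.int, cd$start, cd$end), use.names = FALSE)
  pos <- sort(pos)
  strand <- db$transcripts$strand[
    db$transcripts$transcript_id == tx_id]
  if (strand == "-") pos <- rev(pos)
  pos
}

#' Call synonymous/non-synonymous recoding for CDS editing sites
#'
#' Locates each site's codon within the spliced CDS of its assigned
#' transcript (minus-strand CDS read on the reverse complement), applies
#' the substitution and translates both codons with the standard genetic
#' code. Codons spanning exon junctions are handled by the spliced
#' coordinates. Transcripts whose spliced CDS length is not a multiple of
#' three are flagged with a warning and their sites skipped.
#'
#' @param cds_sites data frame with columns chrom, pos, ref, alt (genome
#'   strand) and transcript_id.
#' @param db a [transcript_db()].
#' @param genome a named `DNAStringSet`.
#' @return data frame: site columns plus codon_before, codon_after,
#'   aa_before, aa_after, effect ("synonymous"/"non-synonymous").
#' @export
call_recoding <- function(cds_sites, db, genome) {
  out <- vector("list", nrow(cds_sites))
  bad_tx <- character(0L)
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(cds_sites))) {
    s <- cds_sites[i, ]
    tx_row <- db$transcripts[db$transcripts$transcript_id == s$transcript_id, ]
    if (nrow(tx_row) == 0L) stop("unknown transcript: ", s$transcript_id)
    pos_tx <- spliced_cds_positions(db, s$transcript_id)
    if (length(pos_tx) %% 3L != 0L) {
      bad_tx <- c(bad_tx, s$transcript_id)
      next
    }
    idx <- match(s$pos, pos_tx)
    if (is.na(idx)) stop("site ", s$chrom, ":", s$pos,
                         " not in CDS of ", s$transcript_id)
    strand <- tx_row$strand
    # transcribed-strand bases of the codon containing the site
    codon_i <- (idx - 1L) %/% 3L
    codon_pos <- pos_tx[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
    codon_genomic <- genome_bases(genome, rep(s$chrom, 3L),
                                  sort(codon_pos))
    codon <- if (strand == "+") codon_genomic
             else rev(unname(BASE_COMPLEMENT[codon_genomic]))
    within <- (idx - 1L) %% 3L + 1L
    ref_tx <- if (strand == "+") s$ref else unname(BASE_COMPLEMENT[s$ref])
    alt_tx <- if (strand == "+") s$alt else unname(BASE_COMPLEMENT[s$alt])
    if (codon[within] != ref_tx) {
      stop("reference mismatch at ", s$chrom, ":", s$pos,
           " in transcript ", s$transcript_id)
    }
    codon_after <- codon
    codon_after[within] <- alt_tx
    aa_before <- unname(code[paste(codon, collapse = "")])
    aa_after <- unname(code[paste(codon_after, collapse = "")])
    out[[i]] <- data.frame(
      s, codon_before = paste(codon, collapse = ""),
      codon_after = paste(codon_after, collapse = ""),
      aa_before = aa_before, aa_after = aa_after,
      effect = if (aa_before == aa_after) "synonymous" else "non-synonymous",
      stringsAsFactors = FALSE)
  }
  if (length(bad_tx)) {
    warning("CDS length not divisible by 3; skipped site(s) in: ",
            paste(unique(bad_tx), collapse = ", "))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res)) {
    res <- cds_sites[0, , drop = FALSE]
    for (cl in c("codon_before", "codon_after", "aa_before", "aa_after",
                 "effect")) {
      res[[cl]] <- character(0L)
    }
  }
  rownames(res) <- NULL
  res
}

#' Expression-change comparison of edited transcripts vs background
#'
#' For transcripts edited in a tumor sample but not in the non-cancerous
#' liver, compares the distribution of expression changes
#' log2((FPKM_tumor + eps) / (FPKM_normal + eps)) in each editing category
#' against the background of all expressed transcripts, with a two-sample
#' two-sided Kolmogorov-Smirnov test.
#'
#' @param edited_by_category data frame with columns transcript_id,
#'   category.
#' @param expression expression data frame ([read_expression()]).
#' @param tumor_sample,normal_sample sample ids for the ratio.
#' @param eps pseudo-count added to both FPKM values (default 0.01).
#' @return data frame with columns category, n, D, p_value; categories with
#'   fewer than 2 transcripts are reported with NA statistics.
#' @export
expression_change_test <- function(edited_by_category, expression,
                                   tumor_sample, normal_sample, eps = 0.01) {
  et <- expression[expression$sample == tumor_sample, ]
  en <- expression[expression$sample == normal_sample, ]
  common <- intersect(et$transcript_id, en$transcript_id)
  lfc <- log2((et$fpkm[match(common, et$transcript_id)] + eps) /
                (en$fpkm[match(common, en$transcript_id)] + eps))
  names(lfc) <- common

  cats <- unique(edited_by_category$category)
  rows <- lapply(cats, function(cat) {
    tx <- unique(
      edited_by_category$transcript_id[edited_by_category$category == cat])
    tx <- intersect(tx, common)
    if (length(tx) < 2L) {
      return(data.frame(category = cat, n = length(tx), D = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    ks <- suppressWarnings(stats::ks.test(lfc[tx], lfc, exact = FALSE))
    data.frame(category = cat, n = length(tx), D = unname(ks$statistic),
               p_value = ks$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- empty_df(category = "character", n = "integer", D = "numeric",
                    p_value = "numeric")
  }
  out
}

#' Per-sample gene lists with damaging non-synonymous editing
#'
#' For each sample, collects the genes carrying at least one damaging
#' non-synonymous editing site present in that sample and writes them one
#' per line (input for external GO-enrichment tooling).
#'
#' @param recoding recoding calls ([call_recoding()]) with a damaging_label
#'   column ("damaging"/"tolerated"/NA) and a gene_id column.
#' @param presence data frame with columns chrom, pos, ref, alt, sample:
#'   one row per site per sample in which it was detected.
#' @param outdir output directory for `<sample>_damaging_genes.txt` files
#'   (NULL to skip writing).
#' @return named list of character vectors of gene ids, one per sample.
#' @export
damaging_gene_lists <- function(recoding, presence, outdir = NULL) {
  dmg <- recoding[!is.na(recoding$damaging_label) &
                    recoding$damaging_label == "damaging" &
                    recoding$effect == "non-synonymous", , drop = FALSE]
  out <- lapply(EDITOME_SAMPLES, function(s) {
    pres <- presence[presence$sample == s, , drop = FALSE]
    keys <- site_key(pres$chrom, pres$pos, pres$ref, pres$alt)
    hit <- site_key(dmg$chrom, dmg$pos, dmg$ref, dmg$alt) %in% keys
    sort(unique(dmg$gene_id[hit]))
  })
  names(out) <- EDITOME_SAMPLES
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (s in EDITOME_SAMPLES) {
      writeLines(out[[s]], file.path(outdir,
                                     paste0(s, "_damaging_genes.txt")))
    }
  }
  out
}
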