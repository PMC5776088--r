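# Annotation of editing sites: gene context, strand-resolved variant
# typing, repeat context, region distributions.

REGION_PRECEDENCE <- c("CDS", "UTR3", "UTR5", "Exon", "Intron")

#' The 12 strand-resolved substitution type labels
#' @export
EDITING_TYPES <- c("A-to-C", "A-to-G", "A-to-T", "C-to-A", "C-to-G",
                   "C-to-T", "G-to-A", "G-to-C", "G-to-T", "T-to-A",
                   "T-to-C", "T-to-G")

#' Assign gene context (transcript, strand, region) to sites
#'
#' A site is annotated iff it overlaps at least one transcript and all
#' overlapping transcripts lie on one strand. Sites overlapping no
#' transcript are discarded as "unannotated"; sites overlapping transcripts
#' on both strands are discarded as "strand-ambiguous". Among same-strand
#' overlapping transcripts, coding models take precedence over lncRNA, and
#' the region label is the highest-precedence membership
#' (CDS > UTR3 > UTR5 > Exon > Intron) across the considered transcripts.
#'
#' @param sites data frame with columns chrom, pos (other columns carried
#'   through).
#' @param db a [transcript_db()].
#' @return list with `annotated` (sites plus transcript_id, gene_id,
#'   biotype, region, strand) and `discarded` (sites plus discard_reason).
#' @export
assign_gene_context <- function(sites, db) {
  ann_cols <- function(df) {
    df$transcript_id <- character(nrow(df))
    df$gene_id <- character(nrow(df))
    df$biotype <- character(nrow(df))
    df$region <- character(nrow(df))
    df$strand <- character(nrow(df))
    df
  }
  if (nrow(sites) == 0L) {
    disc <- sites
    disc$discard_reason <- character(0L)
    return(list(annotated = ann_cols(sites), discarded = disc))
  }
  tx <- db$transcripts
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  tx_gr <- GenomicRanges::GRanges(tx$chrom,
                                  IRanges::IRanges(tx$start, tx$end))
  hits <- GenomicRanges::findOverlaps(site_gr, tx_gr, ignore.strand = TRUE)
  hit_list <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  reg <- db$regions
  reason <- rep(NA_character_, nrow(sites))
  out_tx <- out_gene <- out_bio <- out_reg <- out_strand <-
    rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    js <- hit_list[[as.character(i)]]
    if (is.null(js)) { reason[i] <- "unannotated"; next }
    strands <- unique(tx$strand[js])
    if (length(strands) > 1L) { reason[i] <- "strand-ambiguous"; next }
    # coding models take precedence over lncRNA
    if (any(tx$biotype[js] == "coding")) {
      js <- js[tx$biotype[js] == "coding"]
    }
    best_rank <- Inf
    best_j <- NA_integer_
    for (j in js) {
      r <- reg[reg$transcript_id == tx$transcript_id[j] &
                 reg$start <= sites$pos[i] & reg$end >= sites$pos[i], ]
      if (nrow(r) == 0L) next  # pos in span but between regions: impossible
      rank <- min(match(r$region, REGION_PRECEDENCE))
      if (rank < best_rank) {
        best_rank <- rank
        best_j <- j
      }
    }
    if (is.na(best_j)) { reason[i] <- "unannotated"; next }
    out_tx[i] <- tx$transcript_id[best_j]
    out_gene[i] <- tx$gene_id[best_j]
    out_bio[i] <- tx$biotype[best_j]
    out_reg[i] <- REGION_PRECEDENCE[best_rank]
    out_strand[i] <- strands
  }
  ok <- is.na(reason)
  annotated <- sites[ok, , drop = FALSE]
  annotated$transcript_id <- out_tx[ok]
  annotated$gene_id <- out_gene[ok]
  annotated$biotype <- out_bio[ok]
  annotated$region <- out_reg[ok]
  annotated$strand <- out_strand[ok]
  discarded <- sites[!ok, , drop = FALSE]
  discarded$discard_reason <- reason[!ok]
  rownames(annotated) <- rownames(discarded) <- NULL
  list(annotated = annotated, discarded = discarded)
}

#' Type a variant on the transcribed strand
#'
#' On the plus strand the type is "ref-to-alt"; on the minus strand both
#' bases are complemented first, so a genomic T-to-C change on a
#' minus-strand transcript is typed A-to-G (the A-to-I signature).
#'
#' @param ref,alt reference and alternate bases (genome strand); vectors.
#' @param strand "+" or "-" per site.
#' @return character vector of the 12 type labels.
#' @export
type_variant <- function(ref, alt, strand) {
  if (any(!strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' for variant typing")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  r <- ifelse(strand == "-", unname(BASE_COMPLEMENT[ref]), ref)
  a <- ifelse(strand == "-", unname(BASE_COMPLEMENT[alt]), alt)
  paste0(r, "-to-", a)
}

#' Attach repeat context to sites
#'
#' A site inside any Alu interval is "Alu"; otherwise inside any repeat it
#' is "repetitive non-Alu"; otherwise "non-repetitive".
#'
#' @param sites data frame with columns chrom, pos.
#' @param repeats repeat data frame from [read_repeats()].
#' @return `sites` with an added repeat_context column.
#' @export
assign_repeat_context <- function(sites, repeats) {
  ctx <- rep("non-repetitive", nrow(sites))
  if (nrow(sites) && nrow(repeats)) {
    site_gr <- GenomicRanges::GRanges(sites$chrom,
                                      IRanges::IRanges(sites$pos, sites$pos))
    rep_gr <- GenomicRanges::GRanges(repeats$chrom,
                                     IRanges::IRanges(repeats$start,
                                                      repeats$end))
    hits <- GenomicRanges::findOverlaps(site_gr, rep_gr, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    alu <- repeats$is_alu[S4Vectors::subjectHits(hits)]
    ctx[unique(q[!alu])] <- "repetitive non-Alu"
    ctx[unique(q[alu])] <- "Alu"
  }
  sites$repeat_context <- ctx
  sites
}

#' Region distribution of annotated sites by pattern
#'
#' Complete contingency table of site counts per (pattern, biotype, region),
#' with zero cells included for every valid combination: coding regions are
#' UTR5/CDS/Intron/UTR3, lncRNA regions are Exon/Intron.
#'
#' @param annotated annotated site data frame carrying pattern, biotype and
#'   region columns.
#' @return data frame with columns pattern, biotype, region, count.
#' @export
region_distribution <- function(annotated) {
  cells <- rbind(
    expand.grid(pattern = PATTERN_LABELS, biotype = "coding",
                region = c("UTR5", "CDS", "Intron", "UTR3"),
                stringsAsFactors = FALSE),
    expand.grid(pattern = PATTERN_LABELS, biotype = "lncRNA",
                region = c("Exon", "Intron"), stringsAsFactors = FALSE))
  key <- paste(cells$pattern, cells$biotype, cells$region)
  obs <- paste(annotated$pattern, annotated$biotype, annotated$region)
  cells$count <- as.integer(table(factor(obs, levels = key))[key])
  cells <- cells[order(match(cells$pattern, PATTERN_LABELS), cells$biotype,
                       cells$region), ]
  rownames(cells) <- NULL
  cells
}
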