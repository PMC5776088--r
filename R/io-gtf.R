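# Transcript models: stranded multi-exon gene models with optional CDS.
# Internally everything is 1-based inclusive (VCF/GTF convention); BED
# inputs are shifted on read.

#' Build a transcript model database
#'
#' Assembles and validates transcript models from component tables and
#' derives per-transcript region intervals (UTR5/CDS/UTR3/Intron for coding
#' models, Exon/Intron for lncRNA).
#'
#' @param transcripts data frame with columns transcript_id, gene_id, chrom,
#'   strand, biotype ("coding" or "lncRNA").
#' @param exons data frame with columns transcript_id, start, end.
#' @param cds data frame with columns transcript_id, start, end (coding
#'   transcripts only; may have zero rows).
#' @return object of class `transcript_db` with elements transcripts, exons,
#'   cds and a flattened `regions` interval table.
#' @export
transcript_db <- function(transcripts, exons, cds) {
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand", "biotype")
                %in% names(transcripts)))
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]

  region_rows <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts$transcript_id[i]
    ex <- exons[exons$transcript_id == tx, , drop = FALSE]
    if (nrow(ex) == 0L) stop("transcript without exons: ", tx)
    if (is.unsorted(ex$start) || any(ex$start > ex$end)) {
      stop("malformed exons for transcript ", tx)
    }
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons for transcript ", tx)
    }
    cd <- cds[cds$transcript_id == tx, , drop = FALSE]
    if (transcripts$biotype[i] == "coding" && nrow(cd) == 0L) {
      stop("coding transcript without CDS: ", tx)
    }
    if (transcripts$biotype[i] == "lncRNA" && nrow(cd) > 0L) {
      stop("lncRNA transcript with CDS: ", tx)
    }
    if (nrow(cd)) {
      inside <- vapply(seq_len(nrow(cd)), function(j) {
        any(cd$start[j] >= ex$start & cd$end[j] <= ex$end)
      }, logical(1L))
      if (!all(inside)) stop("CDS outside exons for transcript ", tx)
    }
    region_rows[[i]] <- derive_regions(
      tx, transcripts$chrom[i], transcripts$strand[i],
      transcripts$biotype[i], ex, cd)
  }
  regions <- do.call(rbind, region_rows)
  rownames(regions) <- NULL

  spans <- do.call(rbind, lapply(seq_len(nrow(transcripts)), function(i) {
    ex <- exons[exons$transcript_id == transcripts$transcript_id[i], ]
    data.frame(start = min(ex$start), end = max(ex$end))
  }))
  transcripts$start <- spans$start
  transcripts$end <- spans$end

  db <- list(transcripts = transcripts, exons = exons, cds = cds,
             regions = regions)
  class(db) <- "transcript_db"
  db
}

# flatten one transcript into labelled region intervals
derive_regions <- function(tx, chrom, strand, biotype, ex, cd) {
  out <- list()
  add <- function(region, start, end) {
    if (length(start)) {
      out[[length(out) + 1L]] <<- data.frame(
        transcript_id = tx, chrom = chrom, strand = strand,
        biotype = biotype, region = region, start = start, end = end,
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(ex) > 1L) {
    add("Intron", ex$end[-nrow(ex)] + 1L, ex$start[-1L] - 1L)
  }
  if (biotype == "lncRNA") {
    add("Exon", ex$start, ex$end)
  } else {
    add("CDS", cd$start, cd$end)
    cds_lo <- min(cd$start)
    cds_hi <- max(cd$end)
    # exonic bases outside the CDS span are UTR; side + strand decide 5' vs 3'
    for (j in seq_len(nrow(ex))) {
      pieces <- interval_subtract(ex$start[j], ex$end[j], cd)
      for (p in pieces) {
        lab <- if (p[2L] < cds_lo) {
          if (strand == "+") "UTR5" else "UTR3"
        } else if (p[1L] > cds_hi) {
          if (strand == "+") "UTR3" else "UTR5"
        } else {
          # exonic gap inside the CDS span (unusual); treat as CDS-adjacent
          # untranslated sequence on the 5' side
          if (strand == "+") "UTR5" else "UTR3"
        }
        add(lab, p[1L], p[2L])
      }
    }
  }
  do.call(rbind, out)
}

# subtract a set of intervals (data frame start/end) from [start, end]
interval_subtract <- function(start, end, sub) {
  pieces <- list(c(start, end))
  for (j in seq_len(nrow(sub))) {
    nxt <- list()
    for (p in pieces) {
      s <- sub$start[j]; e <- sub$end[j]
      if (e < p[1L] || s > p[2L]) { nxt[[length(nxt) + 1L]] <- p; next }
      if (s > p[1L]) nxt[[length(nxt) + 1L]] <- c(p[1L], s - 1L)
      if (e < p[2L]) nxt[[length(nxt) + 1L]] <- c(e + 1L, p[2L])
    }
    pieces <- nxt
  }
  pieces
}

#' Read transcript models from a GTF file
#'
#' Groups exon and CDS features by transcript_id. Transcripts without CDS
#' features are classified as lncRNA; exon lines may appear in any order.
#' UTR features in the file are ignored (UTRs are re-derived as exon minus
#' CDS). A CDS interval outside the exon union is a validation error naming
#' the transcript.
#'
#' @param path GTF file (plain or gzip).
#' @return a [transcript_db()] object.
#' @export
read_gtf <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(g)
  keep <- md$type %in% c("exon", "CDS")
  g <- g[keep]
  md <- S4Vectors::mcols(g)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                   start = GenomicRanges::start(g),
                   end = GenomicRanges::end(g),
                   strand = as.character(GenomicRanges::strand(g)),
                   type = as.character(md$type),
                   transcript_id = as.character(md$transcript_id),
                   gene_id = as.character(md$gene_id),
                   stringsAsFactors = FALSE)
  tx_ids <- unique(df$transcript_id)
  has_cds <- tapply(df$type == "CDS", df$transcript_id, any)[tx_ids]
  meta <- df[!duplicated(df$transcript_id), c("transcript_id", "gene_id",
                                              "chrom", "strand")]
  meta <- meta[match(tx_ids, meta$transcript_id), ]
  meta$biotype <- ifelse(has_cds, "coding", "lncRNA")
  exons <- df[df$type == "exon", c("transcript_id", "start", "end")]
  cds <- df[df$type == "CDS", c("transcript_id", "start", "end")]
  transcript_db(meta, exons, cds)
}

#' Write transcript models to a GTF file
#'
#' Emits exon, CDS and UTR features with gene_id, transcript_id and
#' gene_biotype attributes.
#'
#' @param db a [transcript_db()] object.
#' @param path output path.
#' @export
write_gtf <- function(db, path) {
  feature_name <- c(CDS = "CDS", UTR5 = "five_prime_utr",
                    UTR3 = "three_prime_utr")
  lines <- character(0L)
  for (i in seq_len(nrow(db$transcripts))) {
    tx <- db$transcripts[i, ]
    biotype <- if (tx$biotype == "coding") "protein_coding" else "lncRNA"
    attr_str <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
      tx$gene_id, tx$transcript_id, biotype)
    ex <- db$exons[db$exons$transcript_id == tx$transcript_id, ]
    feats <- data.frame(feature = "exon", start = ex$start, end = ex$end,
                        stringsAsFactors = FALSE)
    reg <- db$regions[db$regions$transcript_id == tx$transcript_id &
                        db$regions$region %in% names(feature_name), ]
    if (nrow(reg)) {
      feats <- rbind(feats, data.frame(
        feature = unname(feature_name[reg$region]),
        start = reg$start, end = reg$end, stringsAsFactors = FALSE))
    }
    feats <- feats[order(feats$start, feats$feature), ]
    lines <- c(lines, sprintf("%s\teditomescan\t%s\t%d\t%d\t.\t%s\t.\t%s",
                              tx$chrom, feats$feature, feats$start,
                              feats$end, tx$strand, attr_str))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read repeat annotations from a BED file
#'
#' BED half-open 0-based coordinates are converted to 1-based inclusive.
#' A repeat is flagged as Alu when its family name starts with "Alu".
#'
#' @param path BED6 file; the name column carries the repeat family.
#' @return data frame with columns chrom, start, end, family, is_alu.
#' @export
read_repeats <- function(path) {
  g <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g),
             family = as.character(S4Vectors::mcols(g)$name),
             is_alu = startsWith(as.character(S4Vectors::mcols(g)$name),
                                 "Alu"),
             stringsAsFactors = FALSE)
}

#' Read miRNA target intervals from a BED file
#'
#' @param path BED6 file; the name column carries the miRNA identifier.
#' @return data frame with columns chrom, start, end, mirna (1-based
#'   inclusive coordinates).
#' @export
read_mirna_targets <- function(path) {
  g <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g),
             mirna = as.character(S4Vectors::mcols(g)$name),
             stringsAsFactors = FALSE)
}

write_bed6 <- function(df, name, path, strand = ".") {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", df$chrom, df$start - 1L,
                   df$end, name, strand)
  writeLines(lines, path)
  invisible(path)
}
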