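#' Read a per-base pileup evidence table
#'
#' The pileup table carries, for every covered position, one row per read
#' observation: observed base, Phred quality, distances of the site to the
#' 5' and 3' ends of the read, and the read identifier. For every
#' observation dist5 + dist3 = read_length - 1.
#'
#' @param path TSV with columns chrom, pos, ref, base, qual, dist5, dist3,
#'   read_id (plain or gzip).
#' @return data frame with those columns.
#' @export
read_pileup <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "ref", "base",
                                        "qual", "dist5", "dist3", "read_id"),
                          colClasses = c("character", "integer", "character",
                                         "character", "integer", "integer",
                                         "integer", "character"),
                          comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) && any(df$dist5 < 0L | df$dist3 < 0L)) {
    stop("negative read-end distance in pileup ", path)
  }
  df
}

write_pileup <- function(df, path) {
  write_stage_tsv(df[, c("chrom", "pos", "ref", "base", "qual",
                         "dist5", "dist3", "read_id")], path)
}

#' Read a transcript expression table
#'
#' @param path TSV with columns transcript_id, sample, fpkm.
#' @return data frame with those columns.
#' @export
read_expression <- function(path) {
  utils::read.table(path, header = FALSE, sep = "\t",
                    col.names = c("transcript_id", "sample", "fpkm"),
                    colClasses = c("character", "character", "numeric"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a damaging/tolerated annotation table
#'
#' External functional predictions for non-synonymous sites, consumed as
#' input (the prediction itself is out of scope).
#'
#' @param path TSV with columns chrom, pos, effect (damaging or tolerated).
#' @return data frame with those columns.
#' @export
read_damaging_annotation <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "effect"),
                          colClasses = c("character", "integer", "character"),
                          comment.char = "#", stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$effect), c("damaging", "tolerated"))
  if (length(bad)) stop("unknown effect label(s): ", paste(bad, collapse = ", "))
  df
}

#' Read-level quality control
#'
#' Removes a read if more than 10% of its bases are unknown (N) or if more
#' than 50% of its bases have Phred quality below 5. Both comparisons are
#' strict ("more than"), so a 90-bp read with exactly 9 Ns (10.0%) or
#' exactly 45 bases below quality 5 (50.0%) is kept.
#'
#' @param bases character vector of read sequences.
#' @param quals list of integer Phred vectors, one per read, each the same
#'   length as its read.
#' @param max_n_frac maximum tolerated fraction of unknown bases (default 0.10).
#' @param max_lowq_frac maximum tolerated fraction of bases with quality
#'   below `lowq` (default 0.50).
#' @param lowq quality below which a base counts as low quality (default 5).
#' @return logical vector: TRUE where the read is kept.
#' @export
filter_reads <- function(bases, quals, max_n_frac = 0.10,
                         max_lowq_frac = 0.50, lowq = 5L) {
  if (length(bases) != length(quals)) {
    stop("bases and quals must have the same length")
  }
  vapply(seq_along(bases), function(i) {
    b <- strsplit(toupper(bases[i]), "")[[1]]
    q <- quals[[i]]
    if (length(b) != length(q)) {
      stop("read ", i, ": base and quality lengths differ")
    }
    n_frac <- mean(b == "N")
    lowq_frac <- mean(q < lowq)
    n_frac <= max_n_frac && lowq_frac <= max_lowq_frac
  }, logical(1L))
}

# split a pileup data frame into per-position observation lists keyed
# "chrom:pos"; used by the detection filters
pileup_index <- function(pileup) {
  if (nrow(pileup) == 0L) return(list())
  split(pileup, pos_key(pileup$chrom, pileup$pos))
}
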