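#' Read SNV calls from a VCF file
#'
#' Parses a VCF 4.x file into a data frame of biallelic SNV calls.
#' Multi-allelic SNV records are split into one row per alternate allele;
#' indels and symbolic alleles are skipped (with a message giving the count);
#' records with a FILTER value other than PASS or '.' are dropped. Genotype,
#' depth, variant-supporting reads and the minimum base quality of supporting
#' reads are taken from the per-sample GT, DP, AD and BQ fields when present;
#' records missing GT/DP/AD are skipped with a warning (a pileup sidecar can
#' supply evidence downstream).
#'
#' @param path VCF file (plain or gzip).
#' @param sample sample identifier to record (e.g. "NL").
#' @param modality "DNA" or "RNA".
#' @param caller caller identifier to record.
#' @return data frame with columns chrom, pos, ref, alt, sample, modality,
#'   caller, gt, depth, alt_support, base_qual.
#' @export
read_vcf <- function(path, sample, modality, caller) {
  modality <- match.arg(modality, c("DNA", "RNA"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(variant_call_df())
  gt_raw <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                     error = function(e) NULL)
  dp_raw <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                     error = function(e) NULL)
  ad_raw <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                     error = function(e) NULL)
  bq_raw <- tryCatch(vcfR::extract.gt(v, element = "BQ", as.numeric = TRUE),
                     error = function(e) NULL)
  first_col <- function(m, i) if (is.null(m)) NA else m[i, 1L]

  rows <- vector("list", nrow(fix))
  n_indel <- 0L
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    filt <- fix$FILTER[i]
    if (!is.na(filt) && !filt %in% c("PASS", ".")) next
    ref <- toupper(fix$REF[i])
    alts <- strsplit(toupper(fix$ALT[i]), ",", fixed = TRUE)[[1]]
    if (!ref %in% DNA_BASES) { n_indel <- n_indel + 1L; next }
    snv_alts_idx <- which(alts %in% DNA_BASES & alts != ref)
    if (length(snv_alts_idx) < length(alts)) n_indel <- n_indel + 1L
    if (length(snv_alts_idx) == 0L) next

    gt <- first_col(gt_raw, i)
    dp <- first_col(dp_raw, i)
    ad <- first_col(ad_raw, i)
    bq <- first_col(bq_raw, i)
    if (is.na(gt) || is.na(dp) || is.na(ad)) {
      n_skipped <- n_skipped + 1L
      next
    }
    ad_parts <- suppressWarnings(
      as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
    gt_idx <- suppressWarnings(
      as.integer(strsplit(gt, "[/|]")[[1]]))
    if (anyNA(gt_idx) || anyNA(ad_parts)) {
      n_skipped <- n_skipped + 1L
      next
    }
    alleles <- c(ref, alts)
    pos <- as.integer(fix$POS[i])
    sub_rows <- lapply(snv_alts_idx, function(j) {
      alt <- alts[j]
      alt_support <- if (length(ad_parts) >= j + 1L) ad_parts[j + 1L] else 0L
      g <- alleles[gt_idx + 1L]
      g <- if (length(g) == 2L && !anyNA(g)) gt_string(g[1L], g[2L])
           else gt_string(ref, alt)
      data.frame(chrom = fix$CHROM[i], pos = pos, ref = ref, alt = alt,
                 sample = sample, modality = modality, caller = caller,
                 gt = g, depth = as.integer(dp),
                 alt_support = as.integer(alt_support),
                 base_qual = if (is.na(bq)) NA_integer_ else as.integer(bq),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, sub_rows)
  }
  if (n_indel > 0L) message(n_indel, " non-SNV record(s) skipped in ", path)
  if (n_skipped > 0L) {
    warning(n_skipped, " record(s) missing GT/DP/AD skipped in ", path)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) return(variant_call_df())
  rownames(out) <- NULL
  validate_variant_calls(out)
  out
}

variant_call_df <- function() {
  empty_df(chrom = "character", pos = "integer", ref = "character",
           alt = "character", sample = "character", modality = "character",
           caller = "character", gt = "character", depth = "integer",
           alt_support = "integer", base_qual = "integer")
}

validate_variant_calls <- function(calls) {
  if (nrow(calls) == 0L) return(invisible(calls))
  stopifnot(all(calls$ref %in% DNA_BASES),
            all(calls$alt %in% DNA_BASES),
            all(calls$ref != calls$alt),
            all(calls$pos >= 1L),
            all(calls$alt_support >= 0L),
            all(calls$alt_support <= calls$depth))
  invisible(calls)
}

#' Write SNV calls to a VCF 4.2 file
#'
#' Emits one record per call with FORMAT GT:DP:AD:BQ for a single sample
#' column. The retained fields round-trip through [read_vcf()].
#'
#' @param calls data frame as produced by [read_vcf()].
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @export
write_vcf <- function(calls, path, contigs = NULL) {
  sample_name <- if (nrow(calls)) calls$sample[1L] else "SAMPLE"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=editomescan",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs)
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("##FORMAT=<ID=BQ,Number=1,Type=Integer,Description=\"Minimum ",
           "base quality of variant-supporting reads\">"),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name))
  lines <- header
  if (nrow(calls)) {
    calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
    gt_field <- vapply(seq_len(nrow(calls)), function(i) {
      a <- strsplit(calls$gt[i], "/", fixed = TRUE)[[1]]
      idx <- ifelse(a == calls$ref[i], 0L, 1L)
      paste(sort(idx), collapse = "/")
    }, character(1L))
    bq <- ifelse(is.na(calls$base_qual), ".", calls$base_qual)
    rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AD:BQ\t%s:%d:%d,%d:%s",
                   calls$chrom, calls$pos, calls$ref, calls$alt, gt_field,
                   calls$depth, calls$depth - calls$alt_support,
                   calls$alt_support, bq)
    lines <- c(lines, rec)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read known-SNP positions from a VCF or two-column table
#'
#' Used for germline subtraction; only chromosome and position are retained
#' (allele-agnostic matching).
#'
#' @param path VCF file, or TSV with columns chrom and pos.
#' @return data frame with columns chrom, pos.
#' @export
read_snp_positions <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF") || grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) return(empty_df(chrom = "character", pos = "integer"))
    out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.table(path, header = FALSE, sep = "\t",
                             col.names = c("chrom", "pos"),
                             colClasses = c("character", "integer"),
                             comment.char = "#", stringsAsFactors = FALSE)
  }
  unique(out)
}
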