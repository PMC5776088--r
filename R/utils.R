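#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Sample identifiers of the four-stage design
#'
#' Non-cancerous liver (NL), primary tumor (PT), intrahepatic metastasis (IM)
#' and portal vein tumor thrombus (PTVV), all from one patient.
#' @export
EDITOME_SAMPLES <- c("NL", "PT", "IM", "PTVV")

TUMOR_SAMPLES <- c("PT", "IM", "PTVV")

#' The seven cross-stage editing pattern labels
#'
#' ALL: present in all four samples; STN: shared by NL and at least one but
#' not all tumor samples; ST: shared by 2-3 tumor samples without NL;
#' NL/PT/IM/PTVV: unique to that sample.
#' @export
PATTERN_LABELS <- c("ALL", "STN", "ST", "NL", "PT", "IM", "PTVV")

complement_base <- function(x) {
  out <- unname(BASE_COMPLEMENT[x])
  if (anyNA(out)) stop("non-ACGT base cannot be complemented")
  out
}

site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

pos_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# unordered genotype as a canonical string, e.g. "A/G"
gt_string <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "/")
}

# independent RNG stream seeds derived from one master seed; kept < 2^31
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 65011 + 1) * 31013 + stream * 7919) %% .Machine$integer.max
}

# bases of `genome` (DNAStringSet) at 1-based positions, vectorized over chroms
genome_bases <- function(genome, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) stop("chromosome not in genome: ", ch)
    i <- which(chrom == ch)
    if (any(pos[i] < 1L | pos[i] > length(genome[[ch]]))) {
      stop("position outside chromosome ", ch)
    }
    hit <- Biostrings::extractAt(genome[[ch]],
                                 IRanges::IRanges(pos[i], pos[i]))
    out[i] <- as.character(hit)
  }
  out
}

# write a data.frame as TSV whose single header line starts with '#'
write_stage_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_stage_tsv <- function(path, colClasses = NA) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, colClasses = colClasses,
                          stringsAsFactors = FALSE, comment.char = "")
  df
}

empty_df <- function(...) {
  spec <- list(...)
  as.data.frame(lapply(spec, function(type) vector(type, 0L)),
                stringsAsFactors = FALSE)
}
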