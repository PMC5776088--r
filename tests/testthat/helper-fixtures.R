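# Shared fixtures built in code: variant calls, pileup columns, toy
# transcript databases and genomes.

make_call <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                      sample = "NL", modality = "RNA", caller = "callerA",
                      gt = NULL, depth = 30L, alt_support = 10L,
                      base_qual = 30L) {
  if (is.null(gt)) gt <- paste(sort(c(ref, alt)), collapse = "/")
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             sample = sample, modality = modality, caller = caller, gt = gt,
             depth = as.integer(depth), alt_support = as.integer(alt_support),
             base_qual = as.integer(base_qual), stringsAsFactors = FALSE)
}

# pileup column with explicit observation vectors; dist3 derived from a
# 90-bp read unless given
make_column <- function(chrom = "chr1", pos = 100L, ref = "A", bases,
                        quals = rep(35L, length(bases)),
                        dist5 = rep(40L, length(bases)),
                        read_length = 90L, dist3 = NULL) {
  n <- length(bases)
  if (is.null(dist3)) dist3 <- read_length - 1L - dist5
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, base = bases,
             qual = as.integer(quals), dist5 = as.integer(dist5),
             dist3 = as.integer(dist3),
             read_id = sprintf("r%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# two-exon plus-strand coding model, minus-strand coding model, a lncRNA
# and an intergenic gap, all on a 3-kb toy chromosome
make_toy_db <- function() {
  tx <- data.frame(
    transcript_id = c("txP", "txM", "txL"),
    gene_id = c("gP", "gM", "gL"),
    chrom = c("chr1", "chr1", "chr1"),
    strand = c("+", "-", "+"),
    biotype = c("coding", "coding", "lncRNA"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = c("txP", "txP", "txM", "txM", "txL", "txL"),
    start = c(101L, 301L, 1001L, 1301L, 2001L, 2301L),
    end = c(200L, 400L, 1100L, 1400L, 2100L, 2400L),
    stringsAsFactors = FALSE)
  cds <- data.frame(
    transcript_id = c("txP", "txP", "txM", "txM"),
    start = c(151L, 301L, 1051L, 1301L),
    end = c(200L, 350L, 1100L, 1350L),
    stringsAsFactors = FALSE)
  transcript_db(tx, exons, cds)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_toy_genome <- function(len = 3000L, seed = 5L) {
  withr::with_seed(seed, {
    g <- Biostrings::DNAStringSet(random_dna(len))
    names(g) <- "chr1"
    g
  })
}

# small, fast simulation settings for pipeline-level tests
small_config <- function(seed = 1L, n_editing_sites = 40L,
                         n_germline_snps = 30L,
                         n_background_positions = 80L, ...) {
  simulation_config(seed = seed, n_chromosomes = 1L, chrom_length = 60000L,
                    n_transcripts = 12L, n_alu = 15L, n_nonalu = 8L,
                    n_germline_snps = n_germline_snps,
                    n_editing_sites = n_editing_sites,
                    n_background_positions = n_background_positions, ...)
}
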