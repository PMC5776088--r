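#' Simulation configuration for the synthetic editome dataset
#'
#' Defines the study conditions emulated by [generate_dataset()]: a small
#' diploid genome, stranded multi-exon gene models (coding and lncRNA),
#' Alu-like and non-Alu repeats, planted germline SNPs, and planted A-to-I
#' (and other) editing events with per-sample presence patterns over the
#' four-sample NL/PT/IM/PTVV design.
#'
#' @param seed master RNG seed; every per-file stream is derived from it.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bases.
#' @param n_transcripts number of gene models.
#' @param frac_noncoding proportion of transcripts that are lncRNA.
#' @param n_alu number of Alu-family repeat intervals.
#' @param n_nonalu number of non-Alu repeat intervals (L1/L2/MIR/LTR-like).
#' @param alu_length_range length range (bases) of Alu repeats.
#' @param n_germline_snps number of planted germline SNPs.
#' @param n_editing_sites number of planted editing events.
#' @param editing_rate_range per-sample editing rate range, in (0, 1].
#' @param dna_depth mean DNA sequencing depth (reads).
#' @param rna_depth mean RNA sequencing depth (reads).
#' @param read_length simulated read length in bases.
#' @param seq_error_rate per-base sequencing error probability.
#' @param pattern_weights sampling probabilities of the seven pattern labels;
#'   default puts 7% mass on ALL so that roughly 93% of planted events are
#'   stage specific.
#' @param frac_a_to_g proportion of planted events that are A-to-I (read as
#'   A-to-G); the remainder are drawn uniformly from the other 11 types.
#' @param n_background_positions non-variant positions that also receive
#'   pileup columns, so that sequencing errors can produce false candidates.
#' @param n_mirna number of distinct simulated miRNAs with 3'UTR targets.
#' @param caller_b_min_af minimum allele fraction below which the second
#'   simulated caller misses a variant (its sensitivity knob).
#' @return a validated object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 100000L,
                              n_transcripts = 40L,
                              frac_noncoding = 0.25,
                              n_alu = 60L,
                              n_nonalu = 30L,
                              alu_length_range = c(250L, 350L),
                              n_germline_snps = 150L,
                              n_editing_sites = 200L,
                              editing_rate_range = c(0.3, 0.9),
                              dna_depth = 30L,
                              rna_depth = 30L,
                              read_length = 90L,
                              seq_error_rate = 0.005,
                              pattern_weights = c(ALL = 0.07, STN = 0.10,
                                                  ST = 0.13, NL = 0.175,
                                                  PT = 0.175, IM = 0.175,
                                                  PTVV = 0.175),
                              frac_a_to_g = 0.8,
                              n_background_positions = 500L,
                              n_mirna = 25L,
                              caller_b_min_af = 0.1) {
  config <- list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 n_transcripts = as.integer(n_transcripts),
                 frac_noncoding = frac_noncoding,
                 n_alu = as.integer(n_alu),
                 n_nonalu = as.integer(n_nonalu),
                 alu_length_range = as.integer(alu_length_range),
                 n_germline_snps = as.integer(n_germline_snps),
                 n_editing_sites = as.integer(n_editing_sites),
                 editing_rate_range = editing_rate_range,
                 dna_depth = as.integer(dna_depth),
                 rna_depth = as.integer(rna_depth),
                 read_length = as.integer(read_length),
                 seq_error_rate = seq_error_rate,
                 pattern_weights = pattern_weights,
                 frac_a_to_g = frac_a_to_g,
                 n_background_positions = as.integer(n_background_positions),
                 n_mirna = as.integer(n_mirna),
                 caller_b_min_af = caller_b_min_af)
  class(config) <- "simulation_config"
  validate_simulation_config(config)
  config
}

validate_simulation_config <- function(config) {
  bad <- function(field, why) {
    stop("invalid simulation configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  prop_fields <- c("frac_noncoding", "seq_error_rate", "frac_a_to_g")
  for (f in prop_fields) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      bad(f, "must be a proportion in [0, 1]")
    }
  }
  w <- config$pattern_weights
  if (!setequal(names(w), PATTERN_LABELS) || length(w) != 7L) {
    bad("pattern_weights", "must name exactly the seven pattern labels")
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    bad("pattern_weights", "must be non-negative and sum to 1 (tol 1e-9)")
  }
  r <- config$editing_rate_range
  if (length(r) != 2L || r[1] > r[2] || any(r <= 0) || any(r > 1)) {
    bad("editing_rate_range", "must satisfy 0 < low <= high <= 1")
  }
  count_fields <- c("n_chromosomes", "chrom_length", "n_transcripts", "n_alu",
                    "n_nonalu", "n_germline_snps", "n_editing_sites",
                    "dna_depth", "rna_depth", "read_length",
                    "n_background_positions", "n_mirna")
  for (f in count_fields) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      bad(f, "must be a non-negative count")
    }
  }
  a <- config$alu_length_range
  if (length(a) != 2L || a[1] > a[2] || a[1] < 1) {
    bad("alu_length_range", "must satisfy 1 <= low <= high")
  }
  # reads must be long enough that a site can sit >= the end-distance
  # threshold away from both ends, else every planted site is unfilterable
  if (config$read_length <= 2L * filter_config()$min_end_distance) {
    bad("read_length", paste0("must exceed twice the read-end distance ",
                              "threshold (", filter_config()$min_end_distance,
                              " bases)"))
  }
  if (config$caller_b_min_af < 0 || config$caller_b_min_af > 1) {
    bad("caller_b_min_af", "must be a proportion in [0, 1]")
  }
  invisible(config)
}

#' Evidence thresholds for editing-site filtering
#'
#' The four site filters applied to RNA pileup evidence: minimum Phred
#' quality of variant-supporting bases, minimum covered depth, minimum
#' distance of the site to the ends of its supporting reads, and minimum
#' number of supporting reads.
#'
#' @param min_base_qual minimum Phred quality among variant-supporting
#'   observations (default 20).
#' @param min_depth minimum total read depth at the site (default 5).
#' @param min_end_distance minimum, over variant-supporting observations, of
#'   the distance from the site to the nearer read end (default 15).
#' @param min_alt_reads minimum number of variant-supporting reads
#'   (default 2).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_base_qual = 20L, min_depth = 5L,
                          min_end_distance = 15L, min_alt_reads = 2L) {
  config <- list(min_base_qual = as.integer(min_base_qual),
                 min_depth = as.integer(min_depth),
                 min_end_distance = as.integer(min_end_distance),
                 min_alt_reads = as.integer(min_alt_reads))
  if (any(vapply(config, function(x) is.na(x) || x < 0, logical(1L)))) {
    stop("all filter thresholds must be >= 0")
  }
  class(config) <- "filter_config"
  config
}
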