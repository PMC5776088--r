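# End-to-end orchestration: simulate (or load) -> detect -> annotate ->
# classify -> analyze, with a run manifest for reproducibility.

required_input_keys <- function() {
  per_sample <- unlist(lapply(EDITOME_SAMPLES, function(s) {
    c(paste0("rna_pileup_", s), paste0("dna_pileup_", s),
      paste0("rna_callerA_", s), paste0("rna_callerB_", s),
      paste0("dna_callerA_", s), paste0("dna_callerB_", s))
  }))
  c("genome", "gtf", "repeats", "snps", "expression", "mirna_targets",
    per_sample)
}

#' Run the full editome pipeline
#'
#' Orchestrates simulation (or loading of user inputs), per-sample
#' detection, annotation, pattern classification and functional analysis,
#' writing every stage table as TSV plus a JSON run manifest whose counts
#' satisfy in = out + removed at every stage.
#'
#' @param outdir output directory.
#' @param config a [simulation_config()]; used when `inputs` is NULL.
#' @param filters a [filter_config()].
#' @param inputs NULL to simulate into `outdir/data`, or a named list of
#'   file paths covering the keys in the simulated layout (genome, gtf,
#'   repeats, snps, expression, mirna_targets, optional damaging, and
#'   per-sample rna/dna pileup and caller VCF paths such as
#'   `rna_pileup_NL`, `dna_callerA_PT`).
#' @return invisibly, a list with the per-stage results (sites_by_sample,
#'   patterns, annotated, discarded, region_distribution, enrichment,
#'   recoding, ks, gene_lists, truth when simulated, manifest).
#' @export
run_pipeline <- function(outdir, config = simulation_config(),
                         filters = filter_config(), inputs = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (is.null(inputs)) {
    truth <- generate_dataset(config, file.path(outdir, "data"))
    inputs <- truth$paths
  }
  missing_keys <- setdiff(required_input_keys(), names(inputs))
  if (length(missing_keys)) {
    stop("missing input(s): ", paste(missing_keys, collapse = ", "))
  }
  for (key in required_input_keys()) {
    if (!file.exists(inputs[[key]])) {
      stop("input file for '", key, "' not found: ", inputs[[key]])
    }
  }

  genome <- Biostrings::readDNAStringSet(inputs$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  db <- read_gtf(inputs$gtf)
  repeats <- read_repeats(inputs$repeats)
  snp_tables <- list(known_snps = read_snp_positions(inputs$snps))
  expression <- read_expression(inputs$expression)
  targets <- read_mirna_targets(inputs$mirna_targets)
  damaging <- if (!is.null(inputs$damaging) && file.exists(inputs$damaging)) {
    read_damaging_annotation(inputs$damaging)
  } else NULL

  # per-sample detection cascade
  sites_by_sample <- list()
  funnels <- list()
  for (s in EDITOME_SAMPLES) {
    rna_calls <- list(
      read_vcf(inputs[[paste0("rna_callerA_", s)]], s, "RNA", "callerA"),
      read_vcf(inputs[[paste0("rna_callerB_", s)]], s, "RNA", "callerB"))
    dna_calls <- list(
      read_vcf(inputs[[paste0("dna_callerA_", s)]], s, "DNA", "callerA"),
      read_vcf(inputs[[paste0("dna_callerB_", s)]], s, "DNA", "callerB"))
    rna_pileup <- read_pileup(inputs[[paste0("rna_pileup_", s)]])
    dna_pileup <- read_pileup(inputs[[paste0("dna_pileup_", s)]])
    det <- detect_sample_sites(rna_calls, dna_calls, rna_pileup, dna_pileup,
                               snp_tables, filters)
    sites_by_sample[[s]] <- det$sites
    funnels[[s]] <- det$funnel
    write_stage_tsv(det$sites, file.path(outdir,
                                         sprintf("sites_%s.tsv", s)))
  }

  # cross-sample presence and pattern classification
  key_sets <- lapply(sites_by_sample, function(df) {
    site_key(df$chrom, df$pos, df$ref, df$alt)
  })
  all_keys <- sort(unique(unlist(key_sets, use.names = FALSE)))
  presence_str <- vapply(all_keys, function(k) {
    paste(EDITOME_SAMPLES[vapply(key_sets, function(ks) k %in% ks,
                                 logical(1L))], collapse = ",")
  }, character(1L))
  parts <- strsplit(all_keys, ":", fixed = TRUE)
  unique_sites <- data.frame(
    chrom = vapply(parts, `[[`, character(1L), 1L),
    pos = as.integer(vapply(parts, `[[`, character(1L), 2L)),
    ref = vapply(parts, `[[`, character(1L), 3L),
    alt = vapply(parts, `[[`, character(1L), 4L),
    presence = unname(presence_str), stringsAsFactors = FALSE)
  unique_sites$pattern <- if (nrow(unique_sites)) {
    classify_patterns(unique_sites$presence)
  } else character(0L)
  write_stage_tsv(unique_sites, file.path(outdir, "patterns.tsv"))
  venn <- overlap_table(key_sets)
  write_stage_tsv(venn, file.path(outdir, "venn_counts.tsv"))

  # annotation
  ctx <- assign_gene_context(unique_sites, db)
  annotated <- ctx$annotated
  if (nrow(annotated)) {
    annotated$editing_type <- type_variant(annotated$ref, annotated$alt,
                                           annotated$strand)
  } else {
    annotated$editing_type <- character(0L)
  }
  annotated <- assign_repeat_context(annotated, repeats)
  write_stage_tsv(annotated, file.path(outdir, "annotated_sites.tsv"))
  write_stage_tsv(ctx$discarded, file.path(outdir, "discarded_sites.tsv"))
  region_dist <- region_distribution(annotated)
  write_stage_tsv(region_dist, file.path(outdir, "region_distribution.tsv"))

  # functional impact
  utr3_sites <- annotated[annotated$region == "UTR3", , drop = FALSE]
  utr3_universe <- db$regions[db$regions$region == "UTR3", , drop = FALSE]
  enrich <- if (nrow(utr3_universe)) {
    suppressWarnings(
      mirna_target_enrichment(utr3_sites, targets, utr3_universe))
  } else NULL
  if (!is.null(enrich)) {
    write_stage_tsv(data.frame(k = enrich$k, n = enrich$n, K = enrich$K,
                               N = enrich$N, p_value = enrich$p_value,
                               target_fraction = enrich$target_fraction),
                    file.path(outdir, "mirna_enrichment.tsv"))
    write_stage_tsv(enrich$ranking, file.path(outdir, "mirna_ranking.tsv"))
  }

  cds_sites <- annotated[annotated$region == "CDS", , drop = FALSE]
  recoding <- call_recoding(
    cds_sites[, c("chrom", "pos", "ref", "alt", "transcript_id", "gene_id",
                  "strand", "presence", "pattern")], db, genome)
  recoding$damaging_label <- if (!is.null(damaging) && nrow(recoding)) {
    damaging$effect[match(pos_key(recoding$chrom, recoding$pos),
                          pos_key(damaging$chrom, damaging$pos))]
  } else rep(NA_character_, nrow(recoding))
  write_stage_tsv(recoding, file.path(outdir, "recoding.tsv"))

  # expression change of transcripts edited in a tumor sample but not NL
  target_gr <- GenomicRanges::GRanges(targets$chrom,
                                      IRanges::IRanges(targets$start,
                                                       targets$end))
  site_category <- function(df) {
    cat <- df$region
    if (any(df$region == "UTR3")) {
      u <- which(df$region == "UTR3")
      gr <- GenomicRanges::GRanges(df$chrom[u],
                                   IRanges::IRanges(df$pos[u], df$pos[u]))
      in_t <- GenomicRanges::countOverlaps(gr, target_gr,
                                           ignore.strand = TRUE) > 0L
      cat[u] <- ifelse(in_t, "UTR3-target", "UTR3-nontarget")
    }
    cat[cat == "Exon"] <- "Intron"  # lncRNA exon sites have no CDS/UTR role
    cat
  }
  ks_rows <- list()
  for (s in TUMOR_SAMPLES) {
    pres_list <- strsplit(annotated$presence, ",", fixed = TRUE)
    eligible <- vapply(pres_list, function(p) s %in% p && !"NL" %in% p,
                       logical(1L))
    df <- annotated[eligible, , drop = FALSE]
    if (nrow(df) == 0L) next
    ebc <- data.frame(transcript_id = df$transcript_id,
                      category = site_category(df),
                      stringsAsFactors = FALSE)
    ks <- expression_change_test(ebc, expression, s, "NL")
    if (nrow(ks)) ks$sample <- s
    ks_rows[[s]] <- ks
  }
  ks_all <- do.call(rbind, ks_rows)
  if (is.null(ks_all)) {
    ks_all <- empty_df(category = "character", n = "integer", D = "numeric",
                       p_value = "numeric", sample = "character")
  }
  rownames(ks_all) <- NULL
  write_stage_tsv(ks_all[, c("sample", "category", "n", "D", "p_value")],
                  file.path(outdir, "ks_expression.tsv"))

  presence_long <- do.call(rbind, lapply(EDITOME_SAMPLES, function(s) {
    df <- sites_by_sample[[s]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
               sample = s, stringsAsFactors = FALSE)
  }))
  if (is.null(presence_long)) {
    presence_long <- empty_df(chrom = "character", pos = "integer",
                              ref = "character", alt = "character",
                              sample = "character")
  }
  gene_lists <- damaging_gene_lists(recoding, presence_long,
                                    file.path(outdir, "gene_lists"))

  manifest <- list(
    package = "editomescan",
    version = as.character(utils::packageVersion("editomescan")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    filters = unclass(filters),
    input_checksums = as.list(stats::setNames(
      unname(tools::md5sum(unlist(inputs))), names(inputs))),
    stages = list(
      detection = funnels,
      unique_sites = nrow(unique_sites),
      annotated = nrow(annotated),
      discarded = nrow(ctx$discarded),
      pattern_counts = as.list(table(factor(unique_sites$pattern,
                                            levels = PATTERN_LABELS)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(sites_by_sample = sites_by_sample,
                 patterns = unique_sites, venn = venn,
                 annotated = annotated, discarded = ctx$discarded,
                 region_distribution = region_dist, enrichment = enrich,
                 recoding = recoding, ks = ks_all,
                 gene_lists = gene_lists, truth = truth,
                 manifest = manifest))
}

#' Recovery statistics of a pipeline run against ground truth
#'
#' Compares detected (site, sample) events with the generator's ground
#' truth. Sensitivity is computed over planted events whose realized
#' evidence satisfies every detection threshold (the `detectable_*` flags);
#' precision over all reported events. Both use the vacuous-truth
#' convention (value 1) when their denominator is empty.
#'
#' @param result return value of [run_pipeline()] (simulated run).
#' @param truth ground truth; defaults to `result$truth`.
#' @return list with sensitivity, precision, n_detectable, n_detected,
#'   n_true_positive and n_germline_reported.
#' @export
evaluate_recovery <- function(result, truth = result$truth) {
  if (is.null(truth)) stop("ground truth required (simulated run)")
  sites <- truth$sites
  detected <- do.call(rbind, lapply(EDITOME_SAMPLES, function(s) {
    df <- result$sites_by_sample[[s]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(key = site_key(df$chrom, df$pos, df$ref, df$alt),
               sample = s, pos_key = pos_key(df$chrom, df$pos),
               stringsAsFactors = FALSE)
  }))
  n_detected <- if (is.null(detected)) 0L else nrow(detected)

  truth_keys <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  detectable_pairs <- character(0L)
  planted_pairs <- character(0L)
  for (s in EDITOME_SAMPLES) {
    pair <- paste(truth_keys, s)
    detectable_pairs <- c(detectable_pairs,
                          pair[sites[[paste0("detectable_", s)]]])
    planted_pairs <- c(planted_pairs,
                       pair[sites[[paste0("present_", s)]]])
  }
  detected_pairs <- if (n_detected) paste(detected$key, detected$sample)
                    else character(0L)
  tp <- sum(detected_pairs %in% planted_pairs)
  recovered <- sum(detectable_pairs %in% detected_pairs)
  germline <- if (n_detected) {
    sum(detected$pos_key %in% pos_key(truth$snps$chrom, truth$snps$pos))
  } else 0L
  list(
    sensitivity = if (length(detectable_pairs)) {
      recovered / length(detectable_pairs)
    } else 1,
    precision = if (n_detected) tp / n_detected else 1,
    n_detectable = length(detectable_pairs),
    n_detected = n_detected,
    n_true_positive = tp,
    n_germline_reported = germline)
}
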