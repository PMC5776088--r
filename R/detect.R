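# Editing-site detection cascade: caller merging, RNA-DNA difference
# identification, four evidence filters, germline subtraction.

merge_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

check_merge_inputs <- function(calls_a, calls_b, modality) {
  for (calls in list(calls_a, calls_b)) {
    if (nrow(calls) && any(calls$modality != modality)) {
      stop("modality mismatch: expected ", modality, " calls")
    }
  }
  samples <- unique(c(calls_a$sample, calls_b$sample))
  if (length(samples) > 1L) {
    stop("calls from more than one sample: ", paste(samples, collapse = ", "))
  }
  invisible(NULL)
}

# shared merge machinery: union or intersection keyed by (chrom,pos,ref,alt);
# where both callers report a site, depth/support take the maximum and the
# genotype comes from the caller with the higher depth
merge_calls <- function(calls_a, calls_b, keep) {
  ka <- merge_key(calls_a)
  kb <- merge_key(calls_b)
  keys <- switch(keep,
                 union = unique(c(ka, kb)),
                 intersection = intersect(ka, kb))
  rows <- lapply(keys, function(k) {
    ia <- match(k, ka)
    ib <- match(k, kb)
    if (!is.na(ia) && !is.na(ib)) {
      a <- calls_a[ia, ]
      b <- calls_b[ib, ]
      best <- if (b$depth > a$depth) b else a
      merged <- best
      merged$depth <- max(a$depth, b$depth)
      merged$alt_support <- max(a$alt_support, b$alt_support)
      merged$base_qual <- suppressWarnings(
        min(a$base_qual, b$base_qual, na.rm = TRUE))
      if (!is.finite(merged$base_qual)) merged$base_qual <- NA_integer_
      merged$caller <- paste(sort(unique(c(a$caller, b$caller))),
                             collapse = ",")
      merged
    } else if (!is.na(ia)) {
      calls_a[ia, ]
    } else {
      calls_b[ib, ]
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else calls_a[0, ]
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge DNA variant calls from two callers (union)
#'
#' DNA variants from the two callers are combined: a site reported by either
#' caller is retained. Where both report it, depth and support take the
#' maximum across callers and the genotype comes from the caller with the
#' higher depth; the caller column records both.
#'
#' @param calls_a,calls_b per-caller call data frames (see [read_vcf()]),
#'   same sample, modality DNA.
#' @return merged call data frame.
#' @export
merge_dna_calls <- function(calls_a, calls_b) {
  check_merge_inputs(calls_a, calls_b, "DNA")
  merge_calls(calls_a, calls_b, "union")
}

#' Merge RNA variant calls from two callers (intersection)
#'
#' Only RNA variants reported by both callers are retained, suppressing
#' caller-specific artifacts.
#'
#' @param calls_a,calls_b per-caller call data frames, same sample,
#'   modality RNA.
#' @return merged call data frame.
#' @export
merge_rna_calls <- function(calls_a, calls_b) {
  check_merge_inputs(calls_a, calls_b, "RNA")
  merge_calls(calls_a, calls_b, "intersection")
}

#' Identify RNA-DNA differences (candidate editing sites)
#'
#' An RNA variant becomes a candidate editing site when (a) its RNA genotype
#' differs from the DNA genotype at the position, and (b) the RNA evidence
#' does not display more than one non-reference base type. The DNA genotype
#' is taken from the merged DNA calls when a DNA variant was called there;
#' otherwise it is homozygous reference, but only when the DNA pileup covers
#' the position at depth >= `config$min_depth` (sites without adequate DNA
#' coverage are discarded as genotype-unknown). The multiple-alternate rule
#' counts alternate alleles with at least `config$min_alt_reads` supporting
#' observations, so a single stray error read does not disqualify a site.
#'
#' @param rna_calls merged RNA calls for one sample ([merge_rna_calls()]).
#' @param dna_calls merged DNA calls for the same sample.
#' @param rna_pileup RNA pileup data frame ([read_pileup()]).
#' @param dna_pileup DNA pileup data frame.
#' @param config a [filter_config()].
#' @return list with `candidates` (data frame: chrom, pos, ref, alt, sample,
#'   dna_gt, rna_gt, provenance) and `audit` (named removal counts:
#'   same_genotype, multi_allelic, dna_uncovered).
#' @export
identify_rdd <- function(rna_calls, dna_calls, rna_pileup, dna_pileup,
                         config = filter_config()) {
  rna_idx <- pileup_index(rna_pileup)
  dna_depth <- vapply(pileup_index(dna_pileup), nrow, integer(1L))
  dna_key <- pos_key(dna_calls$chrom, dna_calls$pos)

  audit <- c(same_genotype = 0L, multi_allelic = 0L, dna_uncovered = 0L)
  rows <- vector("list", nrow(rna_calls))
  for (i in seq_len(nrow(rna_calls))) {
    rc <- rna_calls[i, ]
    pk <- pos_key(rc$chrom, rc$pos)
    col <- rna_idx[[pk]]
    if (is.null(col)) {
      stop("no RNA pileup evidence for candidate at ", pk)
    }
    if (col$ref[1L] != rc$ref) {
      stop("reference base mismatch between call and pileup at ", pk)
    }
    # DNA genotype: called variant, else hom-ref if covered, else unknown
    j <- match(pk, dna_key)
    if (!is.na(j)) {
      dna_gt <- dna_calls$gt[j]
    } else if (!is.na(dna_depth[pk]) && dna_depth[pk] >= config$min_depth) {
      dna_gt <- gt_string(rc$ref, rc$ref)
    } else {
      audit["dna_uncovered"] <- audit["dna_uncovered"] + 1L
      next
    }
    if (identical(dna_gt, rc$gt)) {
      audit["same_genotype"] <- audit["same_genotype"] + 1L
      next
    }
    alt_counts <- table(col$base[col$base != rc$ref])
    if (sum(alt_counts >= config$min_alt_reads) > 1L) {
      audit["multi_allelic"] <- audit["multi_allelic"] + 1L
      next
    }
    rows[[i]] <- data.frame(chrom = rc$chrom, pos = rc$pos, ref = rc$ref,
                            alt = rc$alt, sample = rc$sample,
                            dna_gt = dna_gt, rna_gt = rc$gt,
                            provenance = rc$caller,
                            stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(cand)) {
    cand <- empty_df(chrom = "character", pos = "integer", ref = "character",
                     alt = "character", sample = "character",
                     dna_gt = "character", rna_gt = "character",
                     provenance = "character")
  }
  rownames(cand) <- NULL
  list(candidates = cand, audit = audit)
}

# evidence summary for one candidate from its RNA pileup column
site_evidence <- function(col, alt) {
  sup <- col[col$base == alt, , drop = FALSE]
  list(depth = nrow(col),
       alt_reads = nrow(sup),
       min_qual = if (nrow(sup)) min(sup$qual) else NA_integer_,
       min_end_dist = if (nrow(sup)) min(pmin(sup$dist5, sup$dist3))
                      else NA_integer_)
}

#' Apply the four evidence filters to candidate sites
#'
#' A candidate survives iff all four hold on its RNA pileup column:
#' \itemize{
#'   \item minimum Phred quality among variant-supporting observations
#'     >= `min_base_qual`;
#'   \item total observations (depth) >= `min_depth`;
#'   \item minimum, over variant-supporting observations, of the distance to
#'     the nearer read end >= `min_end_distance`;
#'   \item number of variant-supporting observations >= `min_alt_reads`.
#' }
#' Survival is a conjunction (order-independent); for the audit a removed
#' candidate is charged to the first filter it fails, in the order quality,
#' depth, end distance, support.
#'
#' @param candidates candidate data frame from [identify_rdd()].
#' @param rna_pileup RNA pileup data frame.
#' @param config a [filter_config()].
#' @return list with `sites` (surviving candidates plus evidence columns
#'   depth, alt_reads, min_qual, min_end_dist) and `audit` (named counts:
#'   base_quality, depth, end_distance, alt_support).
#' @export
apply_site_filters <- function(candidates, rna_pileup,
                               config = filter_config()) {
  idx <- pileup_index(rna_pileup)
  audit <- c(base_quality = 0L, depth = 0L, end_distance = 0L,
             alt_support = 0L)
  keep <- logical(nrow(candidates))
  ev_depth <- ev_alt <- ev_q <- ev_d <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    pk <- pos_key(candidates$chrom[i], candidates$pos[i])
    col <- idx[[pk]]
    if (is.null(col)) {
      stop("candidate without pileup column: ", pk)
    }
    ev <- site_evidence(col, candidates$alt[i])
    ev_depth[i] <- ev$depth
    ev_alt[i] <- ev$alt_reads
    ev_q[i] <- ifelse(is.na(ev$min_qual), -1L, ev$min_qual)
    ev_d[i] <- ifelse(is.na(ev$min_end_dist), -1L, ev$min_end_dist)
    if (ev_q[i] < config$min_base_qual) {
      audit["base_quality"] <- audit["base_quality"] + 1L
    } else if (ev$depth < config$min_depth) {
      audit["depth"] <- audit["depth"] + 1L
    } else if (ev_d[i] < config$min_end_distance) {
      audit["end_distance"] <- audit["end_distance"] + 1L
    } else if (ev$alt_reads < config$min_alt_reads) {
      audit["alt_support"] <- audit["alt_support"] + 1L
    } else {
      keep[i] <- TRUE
    }
  }
  sites <- candidates[keep, , drop = FALSE]
  sites$depth <- ev_depth[keep]
  sites$alt_reads <- ev_alt[keep]
  sites$min_qual <- ev_q[keep]
  sites$min_end_dist <- ev_d[keep]
  rownames(sites) <- NULL
  list(sites = sites, audit = audit)
}

#' Subtract germline variants using known SNP position tables
#'
#' Removes any site whose (chrom, pos) appears in any supplied SNP table.
#' Matching is allele-agnostic. A site present in several tables is removed
#' once but counted against each table.
#'
#' @param sites site data frame (needs chrom and pos columns).
#' @param snp_tables named list of data frames with columns chrom, pos.
#' @return list with `sites` (retained) and `removed` (named per-table
#'   counts).
#' @export
subtract_germline <- function(sites, snp_tables = list()) {
  if (length(snp_tables) == 0L) {
    return(list(sites = sites, removed = integer(0L)))
  }
  if (is.null(names(snp_tables)) || any(!nzchar(names(snp_tables)))) {
    names(snp_tables) <- paste0("table", seq_along(snp_tables))
  }
  sk <- pos_key(sites$chrom, sites$pos)
  removed <- vapply(snp_tables, function(tab) {
    sum(sk %in% pos_key(tab$chrom, tab$pos))
  }, integer(1L))
  drop <- rep(FALSE, nrow(sites))
  for (tab in snp_tables) {
    drop <- drop | sk %in% pos_key(tab$chrom, tab$pos)
  }
  out <- sites[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(sites = out, removed = removed)
}

#' Run the full detection cascade for one sample
#'
#' Merges per-caller calls (union for DNA, intersection for RNA), identifies
#' RNA-DNA differences, applies the four evidence filters and subtracts
#' germline SNPs, keeping an audit trail of removal counts at every stage.
#'
#' @param rna_calls_by_caller list of two RNA call data frames.
#' @param dna_calls_by_caller list of two DNA call data frames.
#' @param rna_pileup,dna_pileup pileup data frames for the sample.
#' @param snp_tables named list of SNP position tables.
#' @param config a [filter_config()].
#' @return list with `sites` and `funnel` (stage-by-stage counts).
#' @export
detect_sample_sites <- function(rna_calls_by_caller, dna_calls_by_caller,
                                rna_pileup, dna_pileup, snp_tables = list(),
                                config = filter_config()) {
  stopifnot(length(rna_calls_by_caller) == 2L,
            length(dna_calls_by_caller) == 2L)
  rna <- merge_rna_calls(rna_calls_by_caller[[1L]], rna_calls_by_caller[[2L]])
  dna <- merge_dna_calls(dna_calls_by_caller[[1L]], dna_calls_by_caller[[2L]])
  rdd <- identify_rdd(rna, dna, rna_pileup, dna_pileup, config)
  filt <- apply_site_filters(rdd$candidates, rna_pileup, config)
  germ <- subtract_germline(filt$sites, snp_tables)
  funnel <- list(
    rna_calls = c(caller_a = nrow(rna_calls_by_caller[[1L]]),
                  caller_b = nrow(rna_calls_by_caller[[2L]])),
    rna_merged = nrow(rna),
    dna_merged = nrow(dna),
    rdd_removed = as.list(rdd$audit),
    candidates = nrow(rdd$candidates),
    filter_removed = as.list(filt$audit),
    filtered = nrow(filt$sites),
    germline_removed = as.list(germ$removed),
    germline_dropped = nrow(filt$sites) - nrow(germ$sites),
    final = nrow(germ$sites))
  list(sites = germ$sites, funnel = funnel)
}
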