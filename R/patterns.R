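# Seven-pattern classification of per-sample presence profiles and
# four-set overlap tables.

#' Classify a presence profile into one of the seven cross-stage patterns
#'
#' Given the subset of the four samples (NL, PT, IM, PTVV) in which a site
#' was observed: all four gives ALL; a single sample gives that sample's
#' label; a subset of 2-3 samples containing NL gives STN (shared by tumor
#' and non-cancerous liver); a subset of 2-3 tumor samples gives ST. The 15
#' non-empty subsets partition exactly into the 7 labels.
#'
#' @param presence character vector: the samples in which the site is
#'   present (non-empty subset of [EDITOME_SAMPLES]).
#' @return one of [PATTERN_LABELS].
#' @export
classify_pattern <- function(presence) {
  presence <- unique(presence)
  if (length(presence) == 0L) {
    stop("presence set must be non-empty")
  }
  if (!all(presence %in% EDITOME_SAMPLES)) {
    stop("unknown sample id(s): ",
         paste(setdiff(presence, EDITOME_SAMPLES), collapse = ", "))
  }
  n <- length(presence)
  if (n == 4L) return("ALL")
  if (n == 1L) return(presence)
  if ("NL" %in% presence) "STN" else "ST"
}

#' Classify many presence profiles at once
#'
#' @param presence_list list of presence character vectors, or a character
#'   vector of comma-joined sample ids.
#' @return character vector of pattern labels.
#' @export
classify_patterns <- function(presence_list) {
  if (is.character(presence_list)) {
    presence_list <- strsplit(presence_list, ",", fixed = TRUE)
  }
  vapply(presence_list, classify_pattern, character(1L))
}

#' Four-set overlap (Venn) counts of per-sample site sets
#'
#' Counts sites in every region of the 4-set Venn diagram: for each
#' non-empty subset S of the samples, the number of sites present in
#' exactly the samples of S. The 15 counts sum to the size of the union.
#'
#' @param site_sets named list of four character vectors of site keys,
#'   names being the sample ids.
#' @return data frame with columns subset (comma-joined sample ids, in
#'   NL/PT/IM/PTVV order), n_samples, count.
#' @export
overlap_table <- function(site_sets) {
  stopifnot(setequal(names(site_sets), EDITOME_SAMPLES))
  site_sets <- lapply(site_sets[EDITOME_SAMPLES], unique)
  all_sites <- unique(unlist(site_sets, use.names = FALSE))
  membership <- vapply(site_sets, function(s) all_sites %in% s,
                       logical(length(all_sites)))
  if (length(all_sites) == 1L) membership <- matrix(membership, nrow = 1L)
  subsets <- subset_enumeration()
  counts <- vapply(subsets, function(s) {
    want <- EDITOME_SAMPLES %in% s
    if (length(all_sites) == 0L) return(0L)
    sum(apply(membership, 1L, function(row) all(row == want)))
  }, integer(1L))
  data.frame(subset = vapply(subsets, paste, character(1L), collapse = ","),
             n_samples = lengths(subsets),
             count = counts, stringsAsFactors = FALSE)
}

# the 15 non-empty subsets of the four samples, in canonical order
subset_enumeration <- function() {
  out <- list()
  for (k in 1:4) {
    combos <- utils::combn(EDITOME_SAMPLES, k, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

#' Fraction of stage-specific sites
#'
#' The proportion of sites whose pattern is not ALL, i.e. sites absent from
#' at least one of the four samples.
#'
#' @param patterns character vector of pattern labels.
#' @return proportion in [0, 1].
#' @export
stage_specific_fraction <- function(patterns) {
  if (length(patterns) == 0L) {
    stop("cannot compute a stage-specific fraction of zero sites")
  }
  if (!all(patterns %in% PATTERN_LABELS)) {
    stop("unknown pattern label(s)")
  }
  mean(patterns != "ALL")
}
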