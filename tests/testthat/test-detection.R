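# Detection cascade: caller merging, RNA-DNA difference identification,
# evidence filters, germline subtraction.

calls_at <- function(positions, ...) {
  do.call(rbind, lapply(positions, function(p) make_call(pos = p, ...)))
}

test_that("DNA calls merge by union and RNA calls by intersection", {
  a_dna <- calls_at(c(100L, 200L), modality = "DNA", caller = "callerA")
  b_dna <- calls_at(c(200L, 300L), modality = "DNA", caller = "callerB")
  expect_setequal(merge_dna_calls(a_dna, b_dna)$pos, c(100L, 200L, 300L))

  a_rna <- calls_at(c(100L, 200L), modality = "RNA", caller = "callerA")
  b_rna <- calls_at(c(200L, 300L), modality = "RNA", caller = "callerB")
  expect_equal(merge_rna_calls(a_rna, b_rna)$pos, 200L)

  # empty, idempotent and subset cases
  empty <- a_dna[0L, ]
  expect_equal(nrow(merge_dna_calls(empty, empty)), 0L)
  expect_equal(nrow(merge_rna_calls(a_rna, a_rna)), nrow(a_rna))
  expect_equal(nrow(merge_dna_calls(a_dna, a_dna)), nrow(a_dna))
  sub <- a_rna[1L, ]
  expect_equal(merge_rna_calls(sub, a_rna)$pos, sub$pos)

  expect_error(merge_dna_calls(a_rna, b_dna), "modality")
  expect_error(merge_rna_calls(a_dna, b_rna), "modality")
})

test_that("the union always contains the intersection", {
  withr::with_seed(42L, {
    for (rep in 1:20) {
      pos_a <- sample(1:50, sample(0:20, 1L))
      pos_b <- sample(1:50, sample(0:20, 1L))
      mk <- function(pos, caller, modality) {
        if (length(pos) == 0L) {
          return(make_call(modality = modality)[0L, ])
        }
        calls_at(sort(pos), modality = modality, caller = caller)
      }
      u <- merge_dna_calls(mk(pos_a, "callerA", "DNA"),
                           mk(pos_b, "callerB", "DNA"))
      i <- merge_rna_calls(mk(pos_a, "callerA", "RNA"),
                           mk(pos_b, "callerB", "RNA"))
      expect_true(all(i$pos %in% u$pos))
      expect_setequal(u$pos, union(pos_a, pos_b))
      expect_setequal(i$pos, intersect(pos_a, pos_b))
    }
  })
})

test_that("doubly-reported sites take max evidence and the deeper genotype", {
  a <- make_call(modality = "DNA", depth = 30L, alt_support = 10L,
                 gt = "A/G", caller = "callerA")
  b <- make_call(modality = "DNA", depth = 40L, alt_support = 8L,
                 gt = "G/G", caller = "callerB")
  m <- merge_dna_calls(a, b)
  expect_equal(m$depth, 40L)
  expect_equal(m$alt_support, 10L)
  expect_equal(m$gt, "G/G")
  expect_equal(m$caller, "callerA,callerB")
})

test_that("RNA-DNA difference identification applies the genotype rules", {
  rna_pileup <- rbind(
    make_column(pos = 100L, bases = c(rep("A", 20L), rep("G", 10L))),
    make_column(pos = 200L, bases = c(rep("A", 15L), rep("G", 15L))),
    make_column(pos = 300L, bases = c(rep("A", 20L), rep("G", 5L),
                                      rep("T", 5L))),
    make_column(pos = 400L, bases = c(rep("A", 20L), rep("G", 10L))))
  dna_pileup <- rbind(
    make_column(pos = 100L, bases = rep("A", 30L)),
    make_column(pos = 200L, bases = c(rep("A", 15L), rep("G", 15L))),
    make_column(pos = 300L, bases = rep("A", 30L)),
    make_column(pos = 400L, bases = rep("A", 3L)))  # DNA-uncovered

  rna <- rbind(
    make_call(pos = 100L, gt = "A/G"),   # kept: DNA is hom-ref
    make_call(pos = 200L, gt = "A/G"),   # removed: same genotype in DNA
    make_call(pos = 300L, gt = "A/G"),   # removed: two alternate alleles
    make_call(pos = 400L, gt = "A/G"))   # removed: DNA depth < 5
  dna <- make_call(pos = 200L, modality = "DNA", gt = "A/G")

  res <- identify_rdd(rna, dna, rna_pileup, dna_pileup)
  expect_equal(res$candidates$pos, 100L)
  expect_equal(res$candidates$dna_gt, "A/A")
  expect_equal(unname(res$audit), c(1L, 1L, 1L))
  expect_equal(names(res$audit),
               c("same_genotype", "multi_allelic", "dna_uncovered"))

  # a missing pileup column is an evidence error
  expect_error(identify_rdd(make_call(pos = 999L), dna, rna_pileup,
                            dna_pileup), "999")
})

test_that("a stray error read does not trigger the multi-allele removal", {
  rna_pileup <- make_column(pos = 100L,
                            bases = c(rep("A", 20L), rep("G", 8L), "T"))
  dna_pileup <- make_column(pos = 100L, bases = rep("A", 30L))
  rna <- make_call(pos = 100L, gt = "A/G")
  res <- identify_rdd(rna, make_call(pos = 1L, modality = "DNA")[0L, ],
                      rna_pileup, dna_pileup)
  expect_equal(nrow(res$candidates), 1L)
})

test_that("site filters pass at the boundary and fail one step below it", {
  fc <- filter_config()  # qual 20, depth 5, end distance 15, support 2
  boundary <- make_column(
    bases = c("A", "A", "A", "G", "G"),
    quals = c(35L, 35L, 35L, 20L, 25L),
    dist5 = c(0L, 1L, 2L, 15L, 74L))  # supporting min(d5, d3) = 15
  cand <- make_call(alt_support = 2L)[, c("chrom", "pos", "ref", "alt",
                                          "sample")]
  keep <- apply_site_filters(cand, boundary, fc)
  expect_equal(nrow(keep$sites), 1L)
  expect_equal(keep$sites$min_qual, 20L)
  expect_equal(keep$sites$min_end_dist, 15L)
  expect_equal(sum(keep$audit), 0L)

  drop_case <- function(col, expected_filter) {
    res <- apply_site_filters(cand, col, fc)
    expect_equal(nrow(res$sites), 0L)
    expect_equal(unname(res$audit[expected_filter]), 1L,
                 label = expected_filter)
    expect_equal(sum(res$audit), 1L)
  }
  # quality 19 on one supporting read
  drop_case(make_column(bases = c("A", "A", "A", "G", "G"),
                        quals = c(35L, 35L, 35L, 19L, 25L),
                        dist5 = c(0L, 1L, 2L, 15L, 74L)), "base_quality")
  # depth 4
  drop_case(make_column(bases = c("A", "A", "G", "G"),
                        quals = c(35L, 35L, 20L, 25L),
                        dist5 = c(0L, 1L, 15L, 74L)), "depth")
  # one supporting read 14 bases from its nearer end
  drop_case(make_column(bases = c("A", "A", "A", "G", "G"),
                        quals = c(35L, 35L, 35L, 20L, 25L),
                        dist5 = c(0L, 1L, 2L, 14L, 74L)), "end_distance")
  # single supporting read
  drop_case(make_column(bases = c("A", "A", "A", "A", "G"),
                        quals = c(35L, 35L, 35L, 35L, 25L),
                        dist5 = c(0L, 1L, 2L, 15L, 74L)), "alt_support")
})

test_that("a failing candidate is charged to the first failing filter", {
  # fails quality AND depth: audit charges base_quality (listed first)
  col <- make_column(bases = c("A", "G", "G"), quals = c(35L, 10L, 25L),
                     dist5 = c(40L, 40L, 40L))
  cand <- make_call()[, c("chrom", "pos", "ref", "alt", "sample")]
  res <- apply_site_filters(cand, col)
  expect_equal(unname(res$audit["base_quality"]), 1L)
  expect_equal(sum(res$audit), 1L)
})

test_that("germline subtraction removes known SNP positions per table", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  t1 <- data.frame(chrom = "chr1", pos = c(10L, 20L),
                   stringsAsFactors = FALSE)
  t2 <- data.frame(chrom = "chr1", pos = 20L, stringsAsFactors = FALSE)
  res <- subtract_germline(sites, list(dbsnp = t1, thousand_genomes = t2))
  expect_equal(res$sites$pos, 30L)
  # a site in both tables is removed once but counted against each table
  expect_equal(res$removed, c(dbsnp = 2L, thousand_genomes = 1L))

  # empty tables are the identity
  same <- subtract_germline(sites, list())
  expect_equal(same$sites, sites)
})

test_that("detection output is invariant under input record permutation", {
  cfg <- small_config(seed = 21L)
  out <- withr::local_tempdir()
  truth <- generate_dataset(cfg, out)
  s <- "PT"
  rna <- list(read_vcf(truth$paths[[paste0("rna_callerA_", s)]], s, "RNA",
                       "callerA"),
              read_vcf(truth$paths[[paste0("rna_callerB_", s)]], s, "RNA",
                       "callerB"))
  dna <- list(read_vcf(truth$paths[[paste0("dna_callerA_", s)]], s, "DNA",
                       "callerA"),
              read_vcf(truth$paths[[paste0("dna_callerB_", s)]], s, "DNA",
                       "callerB"))
  rna_pile <- read_pileup(truth$paths[[paste0("rna_pileup_", s)]])
  dna_pile <- read_pileup(truth$paths[[paste0("dna_pileup_", s)]])
  snp <- list(known = read_snp_positions(truth$paths$snps))

  base <- detect_sample_sites(rna, dna, rna_pile, dna_pile, snp)
  withr::with_seed(7L, {
    shuf <- function(df) df[sample.int(nrow(df)), , drop = FALSE]
    perm <- detect_sample_sites(lapply(rna, shuf), lapply(dna, shuf),
                                shuf(rna_pile), shuf(dna_pile), snp)
  })
  key <- function(df) sort(paste(df$chrom, df$pos, df$ref, df$alt))
  expect_equal(key(perm$sites), key(base$sites))
  expect_equal(perm$funnel$final, base$funnel$final)
})

test_that("with no sequencing error and SNP tables, precision is exact", {
  cfg <- small_config(seed = 5L, seq_error_rate = 0)
  out <- withr::local_tempdir()
  res <- run_pipeline(out, config = cfg)
  rec <- evaluate_recovery(res)
  expect_equal(rec$precision, 1)
  expect_equal(rec$n_germline_reported, 0L)
})
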