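# Functional impact statistics: hypergeometric enrichment, codon
# recoding, expression-change KS comparison, damaging gene lists.

test_that("hypergeometric enrichment matches the closed form", {
  # all 10 sites inside targets covering half a 100-base universe:
  # p = C(50,10)/C(100,10)
  universe <- data.frame(chrom = "chr1", start = 1L, end = 100L)
  targets <- data.frame(chrom = "chr1", start = 1L, end = 50L,
                        mirna = "mir-1", stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = 1:10, stringsAsFactors = FALSE)
  res <- mirna_target_enrichment(sites, targets, universe)
  expect_equal(res$k, 10L)
  expect_equal(res$K, 50L)
  expect_equal(res$N, 100L)
  expect_equal(res$p_value, choose(50, 10) / choose(100, 10),
               tolerance = 1e-12)

  # no site in targets: P[X >= 0] = 1
  sites_out <- data.frame(chrom = "chr1", pos = 51:60,
                          stringsAsFactors = FALSE)
  expect_equal(mirna_target_enrichment(sites_out, targets,
                                       universe)$p_value, 1)

  # K > N is an input error; n = 0 is undefined and warned
  big_t <- data.frame(chrom = "chr1", start = 1L, end = 200L,
                      mirna = "m", stringsAsFactors = FALSE)
  expect_equal(mirna_target_enrichment(sites, big_t, universe)$K, 100L)
  expect_warning(res0 <- mirna_target_enrichment(sites[0L, ], targets,
                                                 universe), "undefined")
  expect_true(is.na(res0$p_value))
})

test_that("a 52-in-100 target overlap reports fraction 0.52", {
  universe <- data.frame(chrom = "chr1", start = 1L, end = 1000L)
  targets <- data.frame(chrom = "chr1", start = 1L, end = 400L,
                        mirna = "mir-9", stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = c(1:52, 501:548),
                      stringsAsFactors = FALSE)
  res <- mirna_target_enrichment(sites, targets, universe)
  expect_equal(res$n, 100L)
  expect_equal(res$k, 52L)
  expect_equal(res$target_fraction, 0.52)
})

test_that("miRNA ranking counts distinct edited sites with lexical ties", {
  universe <- data.frame(chrom = "chr1", start = 1L, end = 100L)
  targets <- data.frame(chrom = "chr1",
                        start = c(1L, 1L, 30L, 60L),
                        end = c(10L, 10L, 40L, 70L),
                        mirna = c("mir-b", "mir-a", "mir-a", "mir-c"),
                        stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = c(5L, 35L, 65L),
                      stringsAsFactors = FALSE)
  res <- mirna_target_enrichment(sites, targets, universe)
  # mir-a hits sites 5 and 35; mir-b and mir-c one each, ordered a, b, c
  expect_equal(res$ranking$mirna, c("mir-a", "mir-b", "mir-c"))
  expect_equal(res$ranking$edited_targets, c(2L, 1L, 1L))
  # a site in several miRNAs' targets counts once for k
  expect_equal(res$k, 3L)
  expect_gte(sum(res$ranking$edited_targets), res$k)
})

test_that("hypergeometric p equals direct mass summation within 1e-12", {
  withr::with_seed(31L, {
    for (rep in 1:200) {
      N <- sample(10:10000, 1L)
      K <- sample(0:N, 1L)
      n <- sample(1:min(N, 200L), 1L)
      k <- sample(0:min(n, K), 1L)
      p_pkg <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
      p_oracle <- sum(stats::dhyper(k:min(n, K), K, N - K, n))
      expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
    }
  })
})

# a deterministic 3-codon CDS on a toy genome for recoding tests
recoding_fixture <- function(strand = "+") {
  seq <- Biostrings::DNAStringSet(paste0(
    strrep("T", 100L),             # 1..100 padding
    "CAAGAACGA",                   # 101..109 (plus-strand CDS)
    strrep("T", 91L)))
  names(seq) <- "chr1"
  if (strand == "-") {
    # place the same codons on the minus strand: genome holds the
    # reverse complement at 101..109
    s <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("CAAGAACGA")))
    seq <- Biostrings::DNAStringSet(paste0(strrep("T", 100L), s,
                                           strrep("T", 91L)))
    names(seq) <- "chr1"
  }
  tx <- data.frame(transcript_id = "tx", gene_id = "g", chrom = "chr1",
                   strand = strand, biotype = "coding",
                   stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = "tx", start = 95L, end = 115L,
                      stringsAsFactors = FALSE)
  cds <- data.frame(transcript_id = "tx", start = 101L, end = 109L,
                    stringsAsFactors = FALSE)
  list(db = transcript_db(tx, exons, cds), genome = seq)
}

test_that("recoding identifies synonymous and non-synonymous changes", {
  fx <- recoding_fixture("+")
  # CAA -> CGA at codon position 2: Q -> R (non-synonymous)
  s1 <- data.frame(chrom = "chr1", pos = 102L, ref = "A", alt = "G",
                   transcript_id = "tx", stringsAsFactors = FALSE)
  r1 <- call_recoding(s1, fx$db, fx$genome)
  expect_equal(r1$codon_before, "CAA")
  expect_equal(r1$codon_after, "CGA")
  expect_equal(r1$aa_before, "Q")
  expect_equal(r1$aa_after, "R")
  expect_equal(r1$effect, "non-synonymous")
  # GAA -> GAG at position 3: E -> E (synonymous wobble)
  s2 <- data.frame(chrom = "chr1", pos = 106L, ref = "A", alt = "G",
                   transcript_id = "tx", stringsAsFactors = FALSE)
  r2 <- call_recoding(s2, fx$db, fx$genome)
  expect_equal(r2$codon_before, "GAA")
  expect_equal(r2$codon_after, "GAG")
  expect_equal(r2$effect, "synonymous")
})

test_that("recoding matches a translate-and-compare oracle exhaustively", {
  for (strand in c("+", "-")) {
    fx <- recoding_fixture(strand)
    cds_tx <- "CAAGAACGA"  # transcribed-strand CDS
    aa_ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds_tx), no.init.codon = TRUE))
    for (cds_idx in 1:9) {
      # genomic position of this spliced CDS base
      gpos <- if (strand == "+") 100L + cds_idx else 110L - cds_idx
      ref_tx <- substr(cds_tx, cds_idx, cds_idx)
      for (alt_tx in setdiff(c("A", "C", "G", "T"), ref_tx)) {
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        ref_g <- if (strand == "+") ref_tx else unname(comp[ref_tx])
        alt_g <- if (strand == "+") alt_tx else unname(comp[alt_tx])
        s <- data.frame(chrom = "chr1", pos = gpos, ref = ref_g,
                        alt = alt_g, transcript_id = "tx",
                        stringsAsFactors = FALSE)
        got <- call_recoding(s, fx$db, fx$genome)
        mutated <- cds_tx
        substr(mutated, cds_idx, cds_idx) <- alt_tx
        aa_mut <- as.character(Biostrings::translate(
          Biostrings::DNAString(mutated), no.init.codon = TRUE))
        expected <- if (aa_ref == aa_mut) "synonymous" else "non-synonymous"
        expect_equal(got$effect, expected,
                     label = paste(strand, cds_idx, alt_tx))
      }
    }
  }
})

test_that("codons spanning an exon junction use spliced coordinates", {
  # CDS split 101-105 + 201-204: codon 2 spans the junction
  seq <- Biostrings::DNAStringSet(paste0(
    strrep("T", 100L), "CAAGA", strrep("T", 95L), "ACGA", strrep("T", 96L)))
  names(seq) <- "chr1"
  tx <- data.frame(transcript_id = "tx", gene_id = "g", chrom = "chr1",
                   strand = "+", biotype = "coding",
                   stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = c("tx", "tx"),
                      start = c(95L, 201L), end = c(105L, 210L),
                      stringsAsFactors = FALSE)
  cds <- data.frame(transcript_id = c("tx", "tx"),
                    start = c(101L, 201L), end = c(105L, 204L),
                    stringsAsFactors = FALSE)
  db <- transcript_db(tx, exons, cds)
  # spliced CDS = CAAGA + ACGA = CAA GAA CGA; position 201 is codon 2 pos 3
  s <- data.frame(chrom = "chr1", pos = 201L, ref = "A", alt = "G",
                  transcript_id = "tx", stringsAsFactors = FALSE)
  r <- call_recoding(s, db, seq)
  expect_equal(r$codon_before, "GAA")
  expect_equal(r$codon_after, "GAG")
  expect_equal(r$effect, "synonymous")
})

test_that("a CDS length not divisible by three is flagged and skipped", {
  seq <- Biostrings::DNAStringSet(paste0(strrep("T", 100L), "CAAGAACG",
                                         strrep("T", 92L)))
  names(seq) <- "chr1"
  tx <- data.frame(transcript_id = "tx", gene_id = "g", chrom = "chr1",
                   strand = "+", biotype = "coding",
                   stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = "tx", start = 95L, end = 115L,
                      stringsAsFactors = FALSE)
  cds <- data.frame(transcript_id = "tx", start = 101L, end = 108L,
                    stringsAsFactors = FALSE)
  db <- transcript_db(tx, exons, cds)
  s <- data.frame(chrom = "chr1", pos = 102L, ref = "A", alt = "G",
                  transcript_id = "tx", stringsAsFactors = FALSE)
  expect_warning(r <- call_recoding(s, db, seq), "divisible")
  expect_equal(nrow(r), 0L)
})

test_that("KS comparison is null on identical samples and matches an ECDF oracle", {
  expr <- do.call(rbind, lapply(c("NL", "PT"), function(s) {
    data.frame(transcript_id = paste0("t", 1:40), sample = s,
               fpkm = withr::with_seed(4L, stats::rlnorm(40, 3, 1)),
               stringsAsFactors = FALSE)
  }))
  # category containing every transcript: D = 0, p = 1
  all_cat <- data.frame(transcript_id = paste0("t", 1:40),
                        category = "CDS", stringsAsFactors = FALSE)
  res <- expression_change_test(all_cat, expr, "PT", "NL")
  expect_equal(res$D, 0)
  expect_equal(res$p_value, 1)

  # a proper subset against the brute-force ECDF supremum
  expr2 <- expr
  withr::with_seed(6L, {
    expr2$fpkm[expr2$sample == "PT"] <-
      expr2$fpkm[expr2$sample == "PT"] * stats::rlnorm(40, 0.5, 0.4)
  })
  sub_cat <- data.frame(transcript_id = paste0("t", 1:12),
                        category = "UTR3-target", stringsAsFactors = FALSE)
  res2 <- expression_change_test(sub_cat, expr2, "PT", "NL")
  eps <- 0.01
  pt <- expr2$fpkm[expr2$sample == "PT"]
  nl <- expr2$fpkm[expr2$sample == "NL"]
  lfc <- log2((pt + eps) / (nl + eps))
  x <- lfc[1:12]
  grid <- sort(unique(c(x, lfc)))
  d_oracle <- max(abs(stats::ecdf(x)(grid) - stats::ecdf(lfc)(grid)))
  expect_equal(res2$D, d_oracle, tolerance = 1e-12)

  # categories with fewer than 2 transcripts are reported, not tested
  tiny <- data.frame(transcript_id = "t1", category = "UTR5",
                     stringsAsFactors = FALSE)
  res3 <- expression_change_test(tiny, expr, "PT", "NL")
  expect_true(is.na(res3$D))
  expect_equal(res3$n, 1L)
})

test_that("damaging gene lists follow per-sample presence", {
  recoding <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                         ref = "A", alt = "G",
                         gene_id = c("gA", "gB", "gC"),
                         effect = c("non-synonymous", "non-synonymous",
                                    "synonymous"),
                         damaging_label = c("damaging", "tolerated",
                                            "damaging"),
                         stringsAsFactors = FALSE)
  presence <- data.frame(chrom = "chr1", pos = c(10L, 10L, 20L, 30L),
                         ref = "A", alt = "G",
                         sample = c("PT", "IM", "PT", "NL"),
                         stringsAsFactors = FALSE)
  out <- withr::local_tempdir()
  lists <- damaging_gene_lists(recoding, presence, out)
  # only the damaging non-synonymous site at pos 10 qualifies; it is
  # present in PT and IM
  expect_equal(lists$PT, "gA")
  expect_equal(lists$IM, "gA")
  expect_equal(lists$NL, character(0L))
  expect_equal(readLines(file.path(out, "PT_damaging_genes.txt")), "gA")
  expect_equal(readLines(file.path(out, "NL_damaging_genes.txt")),
               character(0L))
})
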