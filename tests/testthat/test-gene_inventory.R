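test_that("protein length from CDS excludes the stop codon", {
  expect_identical(protein_length_from_cds(729), 242L)
  expect_identical(protein_length_from_cds(885), 294L)
  expect_identical(protein_length_from_cds(798), 265L)
  expect_identical(protein_length_from_cds(6), 1L)
  expect_error(protein_length_from_cds(730), "frameshift")
  expect_error(protein_length_from_cds(3), "at least 6")
  # strictly monotone over valid inputs
  lens <- seq(6, 3000, by = 3)
  expect_true(all(diff(protein_length_from_cds(lens)) > 0))
})

test_that("span reconstruction reproduces the SIP1;1 gene-model arithmetic", {
  rec <- list(cds_len = 720, introns = c(590, 3167), utr5 = 329, utr3 = 562,
              gene_len = 4477, identified_start = 130442,
              identified_end = 125075)
  sp <- reconstruct_spans(rec)
  expect_equal(sp$gene_span, 4477)
  expect_equal(sp$transcript_span, 5368)
  expect_equal(sp$genomic_span, 5368)
  expect_length(sp$flags, 0L)

  # intronless gene: all spans collapse to the CDS
  sp2 <- reconstruct_spans(list(cds_len = 726))
  expect_equal(sp2$gene_span, 726)
  expect_equal(sp2$transcript_span, 726)

  # additivity: intron order never matters
  a <- reconstruct_spans(list(cds_len = 900, introns = c(70, 300, 45)))
  b <- reconstruct_spans(list(cds_len = 900, introns = c(300, 45, 70)))
  expect_equal(a$gene_span, b$gene_span)
})

test_that("span inconsistencies are reported, not raised", {
  # a genomic span that disagrees with the stated transcriptional region
  sp <- reconstruct_spans(list(cds_len = 729, identified_start = 248898,
                               identified_end = 247991))
  expect_equal(sp$genomic_span, 908)
  expect_match(sp$flags, "genomic span 908", all = FALSE)
})

test_that("family summary reproduces the catalog statistics", {
  inv <- load_fixture("table2_inventory")
  fs <- family_summary(inv)
  expect_identical(fs$n_genes, 32L)
  expect_identical(fs$n_scaffolds, 26L)
  expect_setequal(fs$multi_gene_scaffolds,
                  c("Scaffold660", "Scaffold473", "Scaffold595",
                    "Scaffold1149", "Scaffold18"))
  expect_identical(unname(fs$per_chromosome_counts["LG2"]), 8L)
  expect_identical(max(fs$per_chromosome_counts),
                   unname(fs$per_chromosome_counts["LG2"]))
  expect_identical(fs$n_chromosomes_multi, 6L)
  expect_identical(fs$n_est_supported, 15L)
  expect_identical(fs$max_est$gene, "JcTIP1;1")
  expect_identical(fs$max_est$count, 186L)
  expect_identical(fs$n_splice_read, 15L)
  expect_identical(fs$n_splice_est, 4L)
  expect_identical(fs$gene_max, 6716L)
  expect_identical(fs$orf_min, 639L)
  expect_identical(fs$orf_max, 924L)
  expect_identical(unname(fs$subfamily_counts[c("PIP", "TIP", "NIP",
                                                "SIP", "XIP")]),
                   c(9L, 9L, 8L, 4L, 2L))
})

test_that("family summary equals a brute-force recount on simulated catalogs", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    rec <- data.frame(
      name = paste0("g", seq_len(n)),
      scaffold = paste0("s", sample(1:12, n, TRUE)),
      chromosome = paste0("LG", sample(1:6, n, TRUE)),
      cds_len = 3 * sample(200:300, n, TRUE),
      est_hits = rpois(n, 2),
      expressed = sample(c(TRUE, FALSE), n, TRUE),
      splice_est = sample(c(TRUE, FALSE), n, TRUE),
      splice_read = sample(c(TRUE, FALSE), n, TRUE),
      subfamily = sample(c("PIP", "TIP", "NIP"), n, TRUE),
      stringsAsFactors = FALSE)
    rec$gene_len <- rec$cds_len + sample(0:2000, n, TRUE)
    fs <- family_summary(rec)
    expect_identical(fs$n_scaffolds, length(unique(rec$scaffold)))
    expect_identical(fs$n_chromosomes_multi,
                     sum(table(rec$chromosome) > 1))
    expect_identical(fs$n_est_supported, sum(rec$est_hits > 0))
    expect_identical(fs$n_splice_read, sum(rec$splice_read))
    expect_identical(sum(fs$subfamily_counts), n)
    expect_identical(fs$gene_max, max(rec$gene_len))
  }
})

test_that("family summary of an empty catalog is all zeros", {
  fs <- family_summary(data.frame())
  expect_identical(fs$n_genes, 0L)
  expect_identical(fs$n_scaffolds, 0L)
  expect_identical(fs$n_est_supported, 0L)
  expect_length(fs$subfamily_counts, 0L)
})

test_that("pseudogene flagging needs both an ORF disruption and silence", {
  # consensus: 26 lysines, leucine, methionine, then more lysines;
  # the deleted base (82, codon 28 position 1) differs from both
  # neighbours, so the frameshift position is unambiguous
  prot <- paste0(strrep("K", 26), "LM", strrep("K", 80))
  cons <- back_translate(prot)
  expect_false(flag_pseudogene(cons, cons)$pseudogene)

  broken <- paste0(substr(cons, 1, 81), substr(cons, 83, nchar(cons)))
  res <- flag_pseudogene(broken, cons)
  expect_true(res$pseudogene)
  expect_true("frameshift @82" %in% res$evidence)

  # expression evidence vetoes the call
  expect_false(flag_pseudogene(broken, cons, expressed = TRUE)$pseudogene)

  # premature stop codons are caught by direct translation
  stopcds <- paste0(substr(cons, 1, 30), "TAA", substr(cons, 34, nchar(cons)))
  res2 <- flag_pseudogene(stopcds, cons)
  expect_true(res2$pseudogene)
  expect_match(res2$evidence, "premature stop @codon 11", all = FALSE)

  expect_error(flag_pseudogene(strrep("A", 120), strrep("C", 120)),
               "unalignable")
})
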