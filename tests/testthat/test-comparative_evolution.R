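inv <- load_fixture("table2_inventory")

test_that("best-hit tables are exact on planted orthologs and stable", {
  # distinct family members (25% mutual divergence), then planted 1:1
  # orthologs at 10% divergence from each
  sim <- simulate_family(sim_config(n_genes = c(PIP = 2L, TIP = 2L,
                                                NIP = 1L),
                                    substitution_rate = 0.25,
                                    rng_seed = 17L))
  set.seed(18)
  orthologs <- vapply(sim$proteins, function(p) {
    mutate_copy(p, substitution_rate = 0.1)$seq
  }, character(1))
  names(orthologs) <- paste0("sp2_", names(sim$proteins))
  panels <- list(speciesB = orthologs)
  tab <- best_hit_table(sim$proteins, panels, min_similarity = 40)
  expect_identical(nrow(tab), length(sim$proteins))
  expect_identical(tab$best_hit, paste0("sp2_", tab$query))

  # identical member: similarity 100
  tab2 <- best_hit_table(sim$proteins[1], list(self = sim$proteins),
                         min_similarity = 40)
  expect_identical(tab2$best_hit, names(sim$proteins)[1])
  expect_equal(tab2$similarity, 100)

  # permuting panel order leaves the table unchanged
  perm <- list(speciesB = orthologs[rev(seq_along(orthologs))])
  expect_identical(best_hit_table(sim$proteins, perm, 40), tab)

  # queries below the floor are absent
  none <- best_hit_table(c(q = strrep("KGE", 80)), panels,
                         min_similarity = 90)
  expect_identical(nrow(none), 0L)
})

test_that("duplicate pairs are typed tandem / dispersed / wgd-candidate", {
  tandem <- classify_duplicate_pair("JcSIP1;2", "JcSIP1;3", inv)
  expect_identical(tandem$type, "tandem")
  expect_true(tandem$evidence$adjacent)

  dispersed <- classify_duplicate_pair("JcNIP3;1", "JcNIP3;2", inv)
  expect_identical(dispersed$type, "dispersed")

  # same chromosome but different scaffolds -> wgd-candidate
  wgd <- classify_duplicate_pair("JcPIP1;3", "JcPIP2;1", inv)
  expect_identical(wgd$type, "wgd-candidate")

  # same scaffold and strand, but another family gene intervenes
  blocked <- classify_duplicate_pair("JcTIP1;3", "JcTIP1;4", inv)
  expect_identical(blocked$type, "wgd-candidate")
  expect_false(blocked$evidence$adjacent)

  expect_error(classify_duplicate_pair("JcSIP1;2", "JcSIP1;2", inv),
               "must differ")

  # symmetry in the two arguments
  ab <- classify_duplicate_pair("JcNIP3;1", "JcNIP3;2", inv)
  ba <- classify_duplicate_pair("JcNIP3;2", "JcNIP3;1", inv)
  expect_identical(ab$type, ba$type)
  expect_identical(ab$genes, ba$genes)
})

test_that("subgroup count matrices recover the family composition", {
  jc <- data.frame(species = "physic nut", subgroup = inv$subgroup,
                   stringsAsFactors = FALSE)
  m <- subgroup_count_matrix(jc)
  expect_identical(sum(m), 32L)
  expect_identical(unname(attr(m, "totals")[["physic nut"]]), 32)
  bysub <- tapply(m["physic nut", ], substr(colnames(m), 1, 3), sum)
  expect_identical(as.integer(bysub[c("PIP", "TIP", "NIP", "SIP", "XIP")]),
                   c(9L, 9L, 8L, 4L, 2L))
  expect_identical(unname(m["physic nut", "PIP2"]), 5L)

  empty <- subgroup_count_matrix(data.frame(species = character(0),
                                            subgroup = character(0)))
  expect_identical(dim(empty), c(0L, 0L))
})

test_that("the packaged ancestral per-subgroup counts sum to 31", {
  anc <- load_fixture("ancestral_counts")
  expect_identical(nrow(anc), 19L)
  expect_identical(sum(anc$count), 31L)
  expect_identical(anc$count[anc$subgroup == "PIP1"], 3L)
  expect_identical(anc$count[anc$subgroup == "NIP4"], 2L)
})

test_that("ancestral reconstruction applies the presence vote and collapsing", {
  m <- matrix(c(3L, 2L, 0L,
                2L, 2L, 1L,
                0L, 1L, 1L), nrow = 3, byrow = TRUE,
              dimnames = list(c("spA", "spB", "outg"),
                              c("PIP1", "TIP1", "XIP1")))
  res <- ancestral_counts(m, outgroup = "outg")
  # PIP1 absent from outgroup but in 2 ingroup species: max ingroup = 3
  expect_identical(unname(res$per_subgroup["PIP1"]), 3L)
  expect_identical(unname(res$per_subgroup["XIP1"]), 1L)
  expect_identical(res$total, sum(res$per_subgroup))

  # collapsing one annotated pair in spA/PIP1 reduces its contribution
  res2 <- ancestral_counts(m, outgroup = "outg",
                           pairs = data.frame(species = "spA",
                                              subgroup = "PIP1"))
  expect_identical(unname(res2$per_subgroup["PIP1"]), 2L)

  # a pseudogene removal works the same way
  res3 <- ancestral_counts(m, outgroup = "outg",
                           pseudogenes = data.frame(species = "spA",
                                                    subgroup = "PIP1"))
  expect_identical(unname(res3$per_subgroup["PIP1"]), 2L)

  # row permutation never changes the total
  perm <- m[c(3, 1, 2), ]
  expect_identical(ancestral_counts(perm, outgroup = "outg")$total,
                   res$total)
  expect_error(ancestral_counts(m, outgroup = "nope"), "outgroup")

  # single ingroup species: subgroup kept only with outgroup presence
  solo <- m[c("spA", "outg"), ]
  res4 <- ancestral_counts(solo, outgroup = "outg")
  expect_identical(unname(res4$per_subgroup["PIP1"]), 0L)
  expect_identical(unname(res4$per_subgroup["TIP1"]), 2L)
})

test_that("the Arabidopsis XIP column of the species table is zero", {
  fam <- load_fixture("table1_family_sizes")
  expect_identical(fam$XIP[fam$common_name == "Arabidopsis"], 0L)
})
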