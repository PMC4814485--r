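profiles <- load_fixture("table4_profiles")

test_that("SDP matching reproduces the published deviation pattern", {
  obs <- load_fixture("table4_observations")
  # the only rows deviating from their section's profile, with positions
  expected_dev <- list(
    "CO2|JcPIP1;1" = 2L, "CO2|JcPIP1;4" = 2L, "CO2|JcPIP2;1" = 2L,
    "CO2|JcPIP2;2" = 2L, "CO2|JcPIP2;4" = 2L,
    "silicic acid|JcNIP2;1" = c(1L, 3L))
  for (i in seq_len(nrow(obs))) {
    v <- unlist(obs[i, paste0("SDP", 1:9)], use.names = FALSE)
    mm <- match_sdp(v, profiles[[obs$substrate[i]]])
    key <- paste(obs$substrate[i], obs$name[i], sep = "|")
    if (key %in% names(expected_dev)) {
      expect_identical(mm, expected_dev[[key]], label = key)
    } else {
      expect_identical(mm, integer(0), label = key)
    }
  }
})

test_that("SDP matching validates arity and treats missing as mismatch", {
  urea <- profiles[["urea"]]
  expect_error(match_sdp(c("H", "P"), urea), "9 entries")
  v <- c("H", "P", ".", "F", "L", "P", "G", "G", NA)
  expect_identical(match_sdp(v, urea), c(3L, 9L))
  # a fully permissive profile never mismatches a complete vector
  permissive <- sdp_profile("urea", rep(list(LETTERS), 9))
  expect_identical(match_sdp(c("H", "P", "F", "F", "L", "P", "G", "G", "N"),
                             permissive), integer(0))
})

test_that("enlarging allowed sets never increases the mismatch count", {
  set.seed(7)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (rep in 1:25) {
    allowed <- lapply(1:9, function(i) sample(aa, sample(1:4, 1)))
    v <- sample(aa, 9, replace = TRUE)
    small <- sdp_profile("urea", allowed)
    grown <- sdp_profile("urea", lapply(allowed, function(s) {
      union(s, sample(aa, sample(1:5, 1)))
    }))
    n_small <- length(match_sdp(v, small))
    n_grown <- length(match_sdp(v, grown))
    expect_lte(n_grown, n_small)
    # match flag <=> empty mismatch list
    expect_identical(n_small == 0L,
                     length(match_sdp(v, small)) == 0L)
  }
})

test_that("substrate prediction follows the zero-mismatch rule", {
  nip5 <- list(sdp = list(
    "NH3" = rep(".", 9),
    "boric acid" = chars("TIHPELLAP"),
    "CO2" = rep(".", 9),
    "H2O2" = chars("SALVVIYVP"),
    "silicic acid" = rep(".", 9),
    "urea" = chars("HPIALPGSN")))
  pred <- predict_substrates(nip5, profiles)
  expect_setequal(pred$substrates, c("boric acid", "H2O2", "urea"))

  nip2 <- list(sdp = list(
    "NH3" = rep(".", 9),
    "boric acid" = chars("VVHPEIIAP"),
    "CO2" = rep(".", 9),
    "H2O2" = chars("AALLVIYVP"),
    "silicic acid" = chars("GFVHGNRTK"),
    "urea" = chars("HPTAMPGSN")))
  pred2 <- predict_substrates(nip2, profiles)
  expect_setequal(pred2$substrates, c("boric acid", "H2O2", "urea"))
  expect_identical(unname(pred2$mismatch_counts["silicic acid"]), 2L)
  expect_identical(unname(pred2$mismatch_positions[["silicic acid"]]),
                   c(1L, 3L))

  all_missing <- list(sdp = setNames(rep(list(rep(".", 9)), 6),
                                     names(profiles)))
  expect_length(predict_substrates(all_missing, profiles)$substrates, 0L)
})

test_that("Froger classification reasons by exemplar first", {
  expect_identical(froger_classify(c("A", "S", "A", "F", "W"))$class,
                   "aquaporin-like")
  expect_identical(froger_classify(c("Y", "D", "K", "P", "L"))$class,
                   "aquaglyceroporin-like")
  nip1 <- froger_classify(c("F", "S", "A", "Y", "L"))
  expect_identical(nip1$class, "mixed")
  expect_identical(unname(nip1$positions[c("P1", "P5")]),
                   c("glpf-like", "glpf-like"))
  expect_identical(unname(nip1$positions[c("P2", "P3")]),
                   c("aqpz-like", "aqpz-like"))
  expect_error(froger_classify(c("A", "S")), "5 entries")
})

test_that("ar/R water call and silicon spacing rule compose", {
  expect_identical(arR_water_call(c("F", "H", "T", "R")), "high")
  expect_identical(arR_water_call(c("F", "N", "A", "R")), "unknown")
  expect_identical(arR_water_call(rep(NA_character_, 4)), "unknown")
  expect_error(arR_water_call(c("F", "H")), "4 entries")

  s1 <- silicon_feature(108, c("G", "S", "G", "R"))
  expect_true(s1$flag)
  expect_match(s1$note, "supported by G-S-G-R")
  s2 <- silicon_feature(108, c("F", "H", "T", "R"))
  expect_true(s2$flag)
  expect_match(s2$note, "without G-S-G-R")
  expect_false(silicon_feature(107)$flag)
})

test_that("specificity report keeps the evidence channels separate", {
  sim <- simulate_family(sim_config(substitution_rate = 0, rng_seed = 13L))
  i <- which(sim$truth$subgroup == "NIP2")[1]
  ann <- annotate_protein(sim$proteins[[i]])
  rep_ <- specificity_report(ann, profiles)
  expect_true(all(c("boric acid", "H2O2", "urea") %in% rep_$substrates))
  expect_identical(unname(rep_$mismatch_counts["silicic acid"]), 2L)
  expect_true(rep_$silicon$flag)
  expect_identical(rep_$water_call, "unknown")
  j <- which(sim$truth$subgroup == "PIP2")[1]
  rep2 <- specificity_report(annotate_protein(sim$proteins[[j]]), profiles)
  expect_identical(rep2$water_call, "high")
  expect_true(all(c("urea", "H2O2") %in% rep2$substrates))
  # the planted PIP2 CO2 vector is the published single-deviation variant
  expect_identical(unname(rep2$mismatch_counts["CO2"]), 1L)
  expect_true("CO2" %in% names(rep2$near_miss))
})
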