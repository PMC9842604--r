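test_that("the code table covers all 28 codes with prefix-derived defaults", {
  tab <- acmg_code_table()
  expect_identical(nrow(tab), 28L)
  expect_identical(tab$default_strength[tab$code == "PVS1"], "VERY_STRONG")
  expect_identical(tab$default_strength[tab$code == "PS3"], "STRONG")
  expect_identical(tab$default_strength[tab$code == "PM2"], "MODERATE")
  expect_identical(tab$default_strength[tab$code == "PP3"], "SUPPORTING")
  expect_identical(tab$default_strength[tab$code == "BA1"], "STAND_ALONE")
  expect_identical(tab$default_strength[tab$code == "BS1"], "STRONG")
  expect_identical(tab$default_strength[tab$code == "BP4"], "SUPPORTING")
  expect_identical(unique(tab$direction[startsWith(tab$code, "B")]), "benign")
})

test_that("evidence strings parse with overrides, deduplication and validation", {
  ev <- parse_evidence("PVS1 + PM2 + PM4")
  expect_identical(ev$code, c("PVS1", "PM2", "PM4"))
  expect_identical(ev$strength, c("VERY_STRONG", "MODERATE", "MODERATE"))
  ev2 <- parse_evidence("PVS1:STRONG,PM2,PM2")
  expect_identical(nrow(ev2), 2L)
  expect_identical(ev2$strength[1], "STRONG")
  expect_true(ev2$overridden[1])
  expect_error(parse_evidence("PXX9"), class = "fsgs_validation_error")
  expect_error(parse_evidence("PM2:SORTA_STRONG"), class = "fsgs_validation_error")
})

test_that("the published criterion sets classify to the published conclusions", {
  expect_identical(acmg_classify("PVS1+PM2+PM4")$class, "PATHOGENIC")
  expect_identical(acmg_classify("PS3+PM2+PP3")$class, "LIKELY_PATHOGENIC")
  expect_identical(acmg_classify("PM1+PM2+PP3+PP5")$class, "LIKELY_PATHOGENIC")
  expect_identical(acmg_classify("PVS1+PM2")$class, "LIKELY_PATHOGENIC")
})

test_that("edge combinations classify per the combining rules", {
  expect_identical(acmg_classify(character(0))$class, "VUS")
  expect_identical(acmg_classify("PM2")$rule_fired, "none")
  # stronger clause wins: 1 strong + 3 moderate is pathogenic, not LP
  expect_identical(acmg_classify("PS3+PM1+PM2+PM4")$class, "PATHOGENIC")
  expect_identical(acmg_classify("PS1+PS3")$class, "PATHOGENIC")
  # benign side
  expect_identical(acmg_classify("BA1")$class, "BENIGN")
  expect_identical(acmg_classify("BS1+BS2")$class, "BENIGN")
  expect_identical(acmg_classify("BS1+BP4")$class, "LIKELY_BENIGN")
  expect_identical(acmg_classify("BP4+BP7")$class, "LIKELY_BENIGN")
  # conflicting evidence is an explicit VUS state
  cf <- acmg_classify("BA1+PVS1+PM2")
  expect_identical(cf$class, "VUS")
  expect_identical(cf$rule_fired, "conflict")
})

test_that("strength modulation changes which clauses a code can satisfy", {
  # downgraded PVS1 no longer triggers the very-strong clauses: it acts as
  # one strong criterion, so with one moderate the result is LP
  expect_identical(acmg_classify("PVS1:STRONG+PM2")$class, "LIKELY_PATHOGENIC")
  expect_identical(acmg_classify("PVS1:STRONG+PM2")$rule_fired, "LP.II")
  # and with another strong it is pathogenic via the two-strong clause
  expect_identical(acmg_classify("PVS1:STRONG+PS3")$rule_fired, "P.II")
  # upgraded supporting counts at its effective strength
  expect_identical(acmg_classify("PP3:MODERATE+PM1+PM2")$class,
                   "LIKELY_PATHOGENIC")
})

test_that("reputable-source codes can be disabled", {
  expect_identical(acmg_classify("PM1+PM2+PP3+PP5")$class, "LIKELY_PATHOGENIC")
  # without PP5 the set is 2 moderate + 1 supporting -> VUS
  expect_identical(acmg_classify("PM1+PM2+PP3+PP5",
                                 use_reputable_source = FALSE)$class, "VUS")
})

test_that("classification matches the independent clause evaluator on all 1024 subsets", {
  universe <- c("PVS1", "PS3", "PM1", "PM2", "PM4", "PP3", "PP5",
                "BA1", "BS1", "BP4")
  for (mask in 0:1023) {
    codes <- universe[bitwAnd(bitwShiftL(1, 0:9), mask) != 0]
    got <- if (length(codes) == 0) acmg_classify(character(0))$class else
      acmg_classify(paste(codes, collapse = "+"))$class
    expect_identical(got, oracle_classify(codes),
                     label = paste("subset:", paste(codes, collapse = "+")))
  }
})

test_that("adding pathogenic evidence never moves the class toward benign", {
  rank <- c(BENIGN = 1, LIKELY_BENIGN = 2, VUS = 3,
            LIKELY_PATHOGENIC = 4, PATHOGENIC = 5)
  path_codes <- c("PVS1", "PS3", "PM1", "PM2", "PM4", "PP3", "PP5")
  base_sets <- list(character(0), "PM2", c("PM1", "PM2"), c("PS3", "PP3"),
                    c("BS1", "BP4"), "BP4")
  for (base in base_sets) {
    before <- acmg_classify(paste(c(base, "PM6"), collapse = "+"))
    for (add in path_codes) {
      after <- acmg_classify(paste(c(base, "PM6", add), collapse = "+"))
      if (after$rule_fired != "conflict" && before$rule_fired != "conflict") {
        expect_gte(rank[[after$class]], rank[[before$class]])
      }
    }
  }
})

test_that("only pathogenic and likely pathogenic classes are reportable", {
  expect_identical(
    is_reportable(c("PATHOGENIC", "LIKELY_PATHOGENIC", "VUS",
                    "LIKELY_BENIGN", "BENIGN")),
    c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
})

test_that("automatic evidence assigns LoF and rarity codes; the rest is curated", {
  v <- dplyr::bind_rows(
    make_variants(1, gene = "MAFB", contig = "chr20",
                  consequence = "stop_gained", hgvs_c = "c.138C>A"),
    make_variants(1, gene = "COL4A4", contig = "chr2",
                  consequence = "frameshift_variant", hgvs_c = "c.905delG"),
    make_variants(1, gene = "ACTN4", af = 0.02, hgvs_c = "c.9A>G"),
    make_variants(1, gene = "LMX1B", contig = "chr9",
                  consequence = "missense_variant", hgvs_c = "c.737G>A")
  )
  out <- evidence_from_annotations(v, knowledge = fsgs_knowledge_table())
  expect_setequal(out$evidence[[1]], c("PVS1", "PM2"))
  expect_setequal(out$evidence[[2]], c("PVS1", "PM2"))
  # common missense with no curated entry gets nothing
  expect_identical(out$evidence[[3]], character(0))
  # curated assertions merge with the automatic rarity code
  expect_setequal(out$evidence[[4]], c("PS3", "PP3", "PM2"))
  cls <- classify_variants(out)
  expect_identical(cls$class,
                   c("LIKELY_PATHOGENIC", "LIKELY_PATHOGENIC", "VUS",
                     "LIKELY_PATHOGENIC"))
})
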