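test_that("detection rates on the reference cohort match hand arithmetic", {
  rc <- fsgs_reference_cohort()
  expect_identical(nrow(rc), 53L)
  overall <- detection_rate(rc)
  expect_identical(overall$n_solved, 6L)
  expect_identical(overall$n_total, 53L)
  expect_equal(overall$rate, 6 / 53)
  fam <- detection_rate(rc, family_history, label = "familial")
  expect_identical(c(fam$n_solved, fam$n_total), c(2L, 2L))
  expect_equal(fam$rate, 1)
})

test_that("an empty denominator yields an absent rate, not a crash", {
  rc <- fsgs_reference_cohort()
  none <- detection_rate(rc[0, ])
  expect_identical(none$n_total, 0L)
  expect_true(is.na(none$rate))
})

test_that("subgroup numerators partition the overall numerator", {
  rc <- fsgs_reference_cohort()
  r <- subgroup_rates(rc)
  g <- function(s, col) r[[col]][r$subgroup == s]
  expect_identical(g("adult", "n_solved") + g("pediatric", "n_solved"),
                   g("overall", "n_solved"))
  expect_identical(g("adult", "n_total") + g("pediatric", "n_total"),
                   g("overall", "n_total"))
  expect_identical(g("familial", "n_solved") + g("sporadic", "n_solved"),
                   g("overall", "n_solved"))
  expect_identical(g("familial", "n_total") + g("sporadic", "n_total"),
                   g("overall", "n_total"))
})

test_that("rates are scale-free: duplicating every patient changes nothing", {
  rc <- fsgs_reference_cohort()
  doubled <- dplyr::bind_rows(rc, dplyr::mutate(rc, patient_id = paste0(patient_id, "b")))
  r1 <- subgroup_rates(rc)
  r2 <- subgroup_rates(doubled)
  expect_equal(r2$rate, r1$rate)
  expect_identical(r2$n_solved, 2L * r1$n_solved)
})

test_that("gene breakdown counts patients once per causal gene", {
  rc <- fsgs_reference_cohort()
  gb <- gene_breakdown(rc)
  expect_identical(setNames(gb$n_patients, gb$gene),
                   c(COL4A4 = 3L, CLCN5 = 1L, LMX1B = 1L, MAFB = 1L))
  expect_equal(gb$share_of_solved[gb$gene == "COL4A4"], 0.5)
  # a two-gene patient contributes one count to each gene
  two <- rc[1, ]
  two$causal_genes <- list(c("NPHS1", "WT1"))
  gb2 <- gene_breakdown(two)
  expect_identical(gb2$n_patients, c(1L, 1L))
  # no solved patients -> empty map
  expect_identical(nrow(gene_breakdown(rc[rc$verdict == "UNSOLVED", ])), 0L)
})

test_that("median ages use the midpoint convention and skip absent values", {
  rc <- fsgs_reference_cohort()
  m <- median_ages(rc)
  expect_equal(m$median_onset_solved, 42.5)  # {4, 9, 52, 52, 38, 47}
  expect_equal(m$median_esrd_solved, 48)     # {15, 48, 61}
  one <- rc[3, ]
  expect_equal(median_ages(one)$median_onset_all, one$age_at_biopsy)
  expect_true(is.na(median_ages(one[0, ])$median_onset_all))
})

test_that("median_ages agrees with the sort-based oracle on random samples", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(1:40, 1)
      ages <- sample(1:90, n, replace = TRUE)
      esrd <- ifelse(runif(n) < 0.5, NA, ages + sample(0:20, n, replace = TRUE))
      cohort <- tibble::tibble(
        patient_id = as.character(seq_len(n)), age_at_biopsy = ages,
        age_at_esrd = esrd,
        verdict = sample(c("SOLVED", "UNSOLVED"), n, replace = TRUE)
      )
      m <- median_ages(cohort)
      expect_equal(m$median_onset_all, oracle_median(ages))
      expect_equal(m$median_esrd_all, oracle_median(esrd))
      solved <- cohort$verdict == "SOLVED"
      expect_equal(m$median_onset_solved, oracle_median(ages[solved]))
    })
  }
})

test_that("the cohort summary reproduces the reference marginals", {
  rc <- fsgs_reference_cohort()
  s <- summarize_cohort(rc)
  g <- function(cat, lev) s[s$category == cat & s$level == lev, ]
  expect_identical(g("sex", "male")$n, 28L)
  expect_equal(g("sex", "male")$pct, 52.8)
  expect_identical(g("age_band", "1-5")$n, 6L)
  expect_identical(g("age_band", "6-18")$n, 12L)
  expect_identical(g("age_band", "19-45")$n, 19L)
  expect_identical(g("age_band", "45-60")$n, 13L)
  expect_identical(g("age_band", ">60")$n, 3L)
  expect_identical(g("family_history", "positive")$n, 2L)
  expect_identical(g("syndrome", "SRNS")$n, 31L)
  expect_identical(g("syndrome", "SSNS")$n, 5L)
  expect_identical(g("immunosuppression", "received")$n, 40L)
  expect_identical(g("status", "ESRD")$n, 12L)
  # syndrome counts partition the cohort
  expect_identical(sum(s$n[s$category == "syndrome"]), 53L)
  expect_identical(sum(s$n[s$category == "age_band"]), 53L)
})

test_that("a one-patient cohort has only 0 or 100 percentages", {
  rc <- fsgs_reference_cohort()[5, ]
  s <- summarize_cohort(rc)
  expect_true(all(s$pct %in% c(0, 100)))
})

test_that("reported percentages round half up to one decimal", {
  expect_equal(round_half_up(11.35, 1), 11.4)
  expect_equal(round_half_up(7.8431 , 1), 7.8)
  expect_equal(detection_rate(fsgs_reference_cohort())$rate_pct, 11.3)
})

test_that("tidy, glance and autoplot work on a cohort report", {
  rep <- cohort_report(fsgs_reference_cohort())
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_true("overall" %in% td$subgroup)
  gl <- glance(rep)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_solved, 6L)
  expect_identical(gl$n_vus_carriers, 15L)
  expect_s3_class(autoplot(rep), "ggplot")
})
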