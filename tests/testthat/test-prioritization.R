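test_that("criterion I keeps coding terms and drops the rest", {
  v <- make_variants(5, consequence = c("stop_gained", "intron_variant",
                                        "frameshift_variant",
                                        "synonymous_variant",
                                        "missense_variant"))
  out <- filter_coding(v)
  expect_setequal(out$consequence,
                  c("stop_gained", "frameshift_variant", "missense_variant"))
})

test_that("unknown consequence terms follow the strictness flag and are logged", {
  v <- make_variants(2, consequence = c("weird_term", "missense_variant"))
  expect_message(out <- filter_coding(v), "unrecognised")
  expect_identical(out$consequence, "missense_variant")
  cfg <- filter_config(keep_unknown_consequences = TRUE)
  expect_message(out2 <- filter_coding(v, cfg), "kept")
  expect_identical(nrow(out2), 2L)
})

test_that("criterion II is strictly 'more than': 21 passes, 20 and 0 fail", {
  v <- make_variants(3, depth = c(21L, 20L, 0L))
  out <- filter_depth(v)
  expect_identical(out$depth, 21L)
})

test_that("criterion III keeps only panel genes, case-insensitively", {
  panel <- tiny_panel()
  v <- make_variants(3, gene = c("actn4", "TTN", "NPHS2"))
  out <- filter_panel(v, panel)
  expect_setequal(out$gene, c("actn4", "NPHS2"))
  expect_identical(nrow(filter_panel(v, panel[0, ])), 0L)
})

test_that("criterion IV applies strict mode-specific AF ceilings", {
  panel <- tiny_panel()
  v <- make_variants(6,
    gene = c("ACTN4", "ACTN4", "ACTN4", "NPHS2", "NPHS2", "CLCN5"),
    contig = c(rep("chr19", 3), "chr1", "chr1", "chrX"),
    af = c(1e-4, 9.9e-5, NA, 5e-4, 1e-3, 2e-4)
  )
  out <- filter_frequency(v, panel)
  # AD: exactly 1e-4 excluded (strict), 9.9e-5 and absent kept
  # AR: 5e-4 < 1e-3 kept, exactly 1e-3 excluded
  # XL: 2e-4 >= 1e-4 excluded
  expect_identical(out$af, c(9.9e-5, NA, 5e-4))
})

test_that("absent AF is dropped when the absent-means-zero policy is off", {
  panel <- tiny_panel()
  v <- make_variants(2, af = c(NA, 1e-6))
  cfg <- filter_config(treat_absent_af_as_zero = FALSE)
  expect_identical(filter_frequency(v, panel, cfg)$af, 1e-6)
})

test_that("criterion IV on an off-panel gene is a contract violation", {
  panel <- tiny_panel()
  v <- make_variants(1, gene = "TTN")
  expect_error(filter_frequency(v, panel), class = "fsgs_contract_error")
})

test_that("criterion V: one hit suffices for AD/XL, AR needs two hits or a homozygote", {
  panel <- tiny_panel()
  ad1 <- make_variants(1, gene = "ACTN4")
  xl1 <- make_variants(1, patient_id = "T02", contig = "chrX", gene = "CLCN5",
                       gt = "1", zygosity = "HEMI")
  ar1 <- make_variants(1, patient_id = "T03", contig = "chr1", gene = "NPHS2")
  ar2 <- make_variants(2, patient_id = "T04", contig = "chr1", gene = "NPHS2")
  arhom <- make_variants(1, patient_id = "T05", contig = "chr1", gene = "NPHS2",
                         gt = "1/1", zygosity = "HOM_ALT")
  v <- dplyr::bind_rows(ad1, xl1, ar1, ar2, arhom)
  out <- apply_zygosity_rule(v, panel)
  expect_setequal(unique(out$patient_id), c("T01", "T02", "T04", "T05"))
  # compound het keeps both hits
  expect_identical(sum(out$patient_id == "T04"), 2L)
  # the lone heterozygous AR hit is discarded
  expect_false("T03" %in% out$patient_id)
})

test_that("a dual-mode gene retains the union of both retention rules", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\tmode\tchromosome\tphenocopy",
               "COL4A4\tAD\tchr2\ttrue", "COL4A4\tAR\tchr2\ttrue"), f)
  panel <- load_panel(f)
  # one lone het at AF qualifying only under the AR ceiling: no AD pass
  # (too common), no AR pass (single het) -> dropped
  lone <- make_variants(1, contig = "chr2", gene = "COL4A4", af = 5e-4)
  expect_identical(nrow(apply_zygosity_rule(lone, panel)), 0L)
  # two such hits form a compound het under the AR rule -> both kept
  pair <- make_variants(2, contig = "chr2", gene = "COL4A4", af = 5e-4)
  expect_identical(nrow(apply_zygosity_rule(pair, panel)), 2L)
  # a single very rare het qualifies under the AD rule
  rare <- make_variants(1, contig = "chr2", gene = "COL4A4", af = 1e-5)
  expect_identical(nrow(apply_zygosity_rule(rare, panel)), 1L)
})

test_that("the full cascade keeps the six reference variants and drops planted failures", {
  panel <- default_panel()
  good <- fsgs_reference_variants()
  bad <- dplyr::bind_rows(
    make_variants(1, patient_id = "P01", gene = "COL4A4", contig = "chr2",
                  af = 0.01),                      # common
    make_variants(1, patient_id = "P02", gene = "TTN", contig = "chr2"),   # off panel
    make_variants(1, patient_id = "P03", gene = "COL4A4", contig = "chr2",
                  depth = 12L),                    # shallow
    make_variants(1, patient_id = "P04", gene = "COL4A4", contig = "chr2",
                  consequence = "intron_variant"), # non-coding
    make_variants(1, patient_id = "P05", gene = "NPHS2", contig = "chr1")  # lone AR het
  )
  res <- run_cascade(dplyr::bind_rows(good, bad), panel)
  expect_identical(nrow(res$candidates), 6L)
  expect_setequal(res$candidates$hgvs_c, good$hgvs_c)
  # trace is monotone non-increasing and consistent with the survivors
  totals <- dplyr::count(res$trace, criterion, wt = n_out)
  expect_true(all(diff(totals$n[match(c("I", "II", "III", "IV", "V"),
                                      totals$criterion)]) <= 0))
  expect_identical(sum(res$trace$n_out[res$trace$criterion == "V"]), 6L)
})

test_that("cascade on empty input yields empty candidates and a zero trace", {
  res <- run_cascade(make_variants(0), default_panel())
  expect_identical(nrow(res$candidates), 0L)
  expect_identical(sum(res$trace$n_in), 0L)
})

test_that("stages I-IV commute: any order yields the same pre-stage-V set", {
  panel <- tiny_panel()
  cfg <- filter_config()
  v <- random_variant_cohort(400, 8, panel, seed = 11)
  stages <- list(
    function(x) filter_coding(x, cfg),
    function(x) filter_depth(x, cfg),
    function(x) filter_panel(x, panel),
    function(x) {
      # frequency only applies after panel screening; restrict first
      filter_frequency(filter_panel(x, panel), panel, cfg)
    }
  )
  canonical <- suppressMessages(
    stages[[4]](stages[[3]](stages[[2]](stages[[1]](v)))))
  key <- function(d) sort(paste(d$patient_id, d$pos, d$hgvs_c))
  for (perm in list(c(2, 1, 3, 4), c(3, 2, 1, 4), c(4, 3, 2, 1), c(1, 4, 2, 3))) {
    out <- v
    for (s in perm) out <- suppressMessages(stages[[s]](out))
    expect_identical(key(out), key(canonical))
  }
})

test_that("each stage's output is a subset of its input on random cohorts", {
  panel <- tiny_panel()
  v <- random_variant_cohort(300, 6, panel, seed = 5)
  res <- suppressMessages(run_cascade(v, panel))
  tr <- res$trace
  expect_true(all(tr$n_out <= tr$n_in))
  key <- function(d) paste(d$patient_id, d$pos, d$hgvs_c)
  expect_true(all(key(res$candidates) %in% key(v)))
})

test_that("the cascade agrees with the brute-force composite-predicate oracle", {
  cfg <- filter_config()
  for (seed in c(2, 13, 77)) {
    panel <- tiny_panel()
    v <- random_variant_cohort(600, 10, panel, seed = seed)
    got <- suppressMessages(run_cascade(v, panel, cfg))$candidates
    want <- oracle_cascade(v, panel, cfg)
    key <- function(d) sort(paste(d$patient_id, d$contig, d$pos, d$hgvs_c))
    expect_identical(key(got), key(want))
  }
})
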