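#' Simulation parameters for a synthetic FSGS cohort
#'
#' Defaults encode the reference study conditions: 53 patients, a 6/53
#' solved fraction, the published syndrome mix (SRNS 31/53, proteinuric CKD
#' 17/53, SSNS 5/53), 2/53 familial cases, 28/53 males, the published
#' biopsy-age band weights, a mean of 50 panel-region background variants
#' per exome after upstream triage, and 15/53 patients carrying a rare
#' panel variant of uncertain significance.
#'
#' @param n_patients cohort size.
#' @param solved_fraction target fraction of patients planted with a causal
#'   catalog variant.
#' @param syndrome_mix named probabilities over the four syndromes; must
#'   sum to 1.
#' @param familial_fraction target fraction with a positive family history;
#'   familial status is planted preferentially on solved patients, the
#'   structure observed in the reference cohort.
#' @param sex_male_fraction probability of male sex for unconstrained
#'   patients (carriers of X-linked catalog variants are forced male).
#' @param age_band_weights weights over the biopsy-age bands 1-5, 6-18,
#'   19-45, 46-60, >60.
#' @param background_mean Poisson mean of background variants per patient.
#' @param bg_class_probs named mixing proportions of the background
#'   failure classes `off_panel`, `common_af`, `low_depth`, `non_coding`,
#'   `ar_single_het`; each class is constructed to fail exactly that
#'   criterion.
#' @param benign_af_range population-AF interval for common background
#'   variants; its lower bound must sit at or above the AR frequency
#'   ceiling so these variants always fail the frequency criterion.
#' @param vus_fraction fraction of patients given a rare, cascade-surviving
#'   panel variant with no curated evidence (classifies VUS).
#' @return a validated list of class `fsgs_sim_params`.
#' @export
cohort_params <- function(n_patients = 53,
                          solved_fraction = 6 / 53,
                          syndrome_mix = c(ASYMPTOMATIC_PROTEINURIA = 0,
                                           SSNS = 5 / 53,
                                           SRNS = 31 / 53,
                                           PROTEINURIC_CKD = 17 / 53),
                          familial_fraction = 2 / 53,
                          sex_male_fraction = 28 / 53,
                          age_band_weights = c(6, 12, 19, 13, 3),
                          background_mean = 50,
                          bg_class_probs = c(off_panel = 0.35,
                                             common_af = 0.30,
                                             low_depth = 0.15,
                                             non_coding = 0.15,
                                             ar_single_het = 0.05),
                          benign_af_range = c(0.005, 0.05),
                          vus_fraction = 15 / 53) {
  if (n_patients < 1) {
    stop_fsgs("n_patients must be >= 1", "fsgs_validation_error")
  }
  if (solved_fraction < 0 || solved_fraction > 1) {
    stop_fsgs("solved_fraction must lie in [0, 1]", "fsgs_validation_error")
  }
  if (abs(sum(syndrome_mix) - 1) > 1e-8 || any(syndrome_mix < 0)) {
    stop_fsgs("syndrome_mix must be non-negative and sum to 1",
              "fsgs_validation_error")
  }
  if (vus_fraction < 0 || vus_fraction > 1) {
    stop_fsgs("vus_fraction must lie in [0, 1]", "fsgs_validation_error")
  }
  if (length(benign_af_range) != 2 || benign_af_range[1] > benign_af_range[2]) {
    stop_fsgs("benign_af_range must be an increasing interval",
              "fsgs_validation_error")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    solved_fraction = solved_fraction,
    syndrome_mix = syndrome_mix,
    familial_fraction = familial_fraction,
    sex_male_fraction = sex_male_fraction,
    age_band_weights = age_band_weights / sum(age_band_weights),
    background_mean = background_mean,
    bg_class_probs = bg_class_probs / sum(bg_class_probs),
    benign_af_range = benign_af_range,
    vus_fraction = vus_fraction
  ), class = "fsgs_sim_params")
}

# synthetic per-gene coordinate spans: deterministic HG19-like positions so
# no genome annotation download is needed. Within each chromosome, genes
# get disjoint 100 kb windows.
gene_coordinate_map <- function(panel) {
  genes <- distinct(panel, .data$symbol, .data$chromosome)
  genes %>%
    group_by(.data$chromosome) %>%
    mutate(start = 1e6 + (row_number() - 1) * 3e6) %>%
    ungroup() %>%
    mutate(end = .data$start + 1e5 - 1)
}

off_panel_gene_map <- function() {
  tibble(
    symbol = c("TTN", "OBSCN", "MUC16", "PCLO", "SYNE1",
               "NEB", "ABCA4", "DNAH5", "USH2A", "FLG"),
    chromosome = c("chr2", "chr1", "chr19", "chr7", "chr6",
                   "chr2", "chr1", "chr5", "chr1", "chr1"),
    start = 2e8 + seq(0, 9) * 3e6
  ) %>% mutate(end = .data$start + 1e5 - 1)
}

rand_snv <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

draw_site <- function(chromosome, start) {
  pos <- as.integer(start + sample.int(1e5, 1) - 1)
  nt <- rand_snv(1)
  list(contig = chromosome, pos = pos, ref = nt$ref, alt = nt$alt)
}

#' Generate a synthetic annotated-exome cohort
#'
#' Writes one annotated VCF per patient, a clinical metadata CSV, a truth
#' table recording every planted variant with its expected classification,
#' and a JSON manifest. Solved patients receive a causal catalog variant
#' (cycling through the catalog) with matching zygosity: hemizygous for
#' X-linked entries in forced-male carriers, heterozygous for dominant
#' entries, homozygous for recessive ones. Background variants are each
#' constructed to fail exactly one cascade criterion (off-panel gene, too
#' common, too shallow, non-coding, or a lone heterozygous hit in a
#' recessive gene); at most one lone-heterozygous variant is planted per
#' recessive gene per patient so no spurious compound heterozygote can
#' arise. Output is deterministic given `seed`.
#'
#' @param params an [cohort_params()] object.
#' @param catalog plantable causal variants; see [fsgs_causal_catalog()].
#' @param out_dir writable output directory (created if needed).
#' @param seed integer seed controlling every random draw.
#' @param panel panel used for background gene coordinates; the default
#'   bundled panel.
#' @return the manifest as a list (invisibly also written to
#'   `manifest.json`): file paths, seed, and per-patient truth rows.
#' @export
generate_cohort <- function(params = cohort_params(),
                            catalog = fsgs_causal_catalog(),
                            out_dir, seed = 1,
                            panel = default_panel()) {
  stopifnot(inherits(params, "fsgs_sim_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(seed, {
    n <- params$n_patients
    ids <- sprintf("S%03d", seq_len(n))
    n_solved <- round(n * params$solved_fraction)
    solved_idx <- if (n_solved > 0) sort(sample.int(n, n_solved)) else integer(0)
    cat_idx <- if (n_solved > 0) ((seq_len(n_solved) - 1) %% nrow(catalog)) + 1 else integer(0)

    # --- clinical metadata -------------------------------------------------
    sex <- if_else(runif(n) < params$sex_male_fraction, "M", "F")
    band_lims <- list(c(1, 5), c(6, 18), c(19, 45), c(46, 60), c(61, 75))
    band <- sample.int(5, n, replace = TRUE, prob = params$age_band_weights)
    age <- vapply(band, function(b) {
      lim <- band_lims[[b]]
      as.numeric(sample(seq(lim[1], lim[2]), 1))
    }, numeric(1))
    syndrome <- sample(names(params$syndrome_mix), n, replace = TRUE,
                       prob = params$syndrome_mix)
    family_history <- rep(FALSE, n)
    immunosuppression <- runif(n) < 40 / 53
    age_at_esrd <- rep(NA_real_, n)

    for (j in seq_along(solved_idx)) {
      i <- solved_idx[j]
      entry <- catalog[cat_idx[j], ]
      sex[i] <- entry$required_sex
      age[i] <- entry$age_at_biopsy
      syndrome[i] <- entry$syndrome
      family_history[i] <- entry$family_history
      immunosuppression[i] <- entry$immunosuppression
      age_at_esrd[i] <- entry$age_at_esrd
    }
    n_familial <- round(n * params$familial_fraction)
    deficit <- n_familial - sum(family_history)
    if (deficit > 0) {
      pool <- setdiff(seq_len(n), which(family_history))
      family_history[sample(pool, min(deficit, length(pool)))] <- TRUE
    }

    metadata <- tibble(
      patient_id = ids, age_at_biopsy = age, sex = sex, syndrome = syndrome,
      family_history = family_history, extrarenal = FALSE,
      immunosuppression = immunosuppression, age_at_esrd = age_at_esrd
    )

    # --- variant content ---------------------------------------------------
    gmap <- gene_coordinate_map(panel)
    offmap <- off_panel_gene_map()
    ar_genes <- sort(unique(panel$symbol[panel$mode == "AR"]))
    ad_genes <- sort(unique(panel$symbol[panel$mode == "AD"]))
    vus_genes <- setdiff(ad_genes, unique(catalog$gene))

    n_vus <- round(n * params$vus_fraction)
    unsolved_idx <- setdiff(seq_len(n), solved_idx)
    vus_idx <- if (n_vus > 0 && length(unsolved_idx) > 0) {
      sort(sample(unsolved_idx, min(n_vus, length(unsolved_idx))))
    } else integer(0)

    truth <- list()
    vcf_paths <- character(n)
    classes <- names(params$bg_class_probs)

    gmap_chr <- setNames(gmap$chromosome, gmap$symbol)
    gmap_start <- setNames(gmap$start, gmap$symbol)
    panel_genes <- unique(panel$symbol)

    for (i in seq_len(n)) {
      pid <- ids[i]
      planted_genes <- character(0)
      # plain-vector accumulation; one tibble per patient (hot path)
      rows <- list(contig = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), gene = character(0),
                   consequence = character(0), hgvs_c = character(0),
                   hgvs_p = character(0), depth = integer(0), af = double(0),
                   gt = character(0))
      push <- function(contig, pos, ref, alt, gene, cons, hc, hp, dp, af, gt) {
        rows$contig <<- c(rows$contig, contig)
        rows$pos <<- c(rows$pos, as.integer(pos))
        rows$ref <<- c(rows$ref, ref); rows$alt <<- c(rows$alt, alt)
        rows$gene <<- c(rows$gene, gene)
        rows$consequence <<- c(rows$consequence, cons)
        rows$hgvs_c <<- c(rows$hgvs_c, hc); rows$hgvs_p <<- c(rows$hgvs_p, hp)
        rows$depth <<- c(rows$depth, as.integer(dp))
        rows$af <<- c(rows$af, af); rows$gt <<- c(rows$gt, gt)
      }

      if (i %in% solved_idx) {
        entry <- catalog[cat_idx[match(i, solved_idx)], ]
        gt <- c(HEMI = "1", HET = "0/1", HOM_ALT = "1/1")[[entry$zygosity]]
        push(entry$contig, entry$pos, entry$ref, entry$alt, entry$gene,
             entry$consequence, entry$hgvs_c, entry$hgvs_p,
             sample(35:60, 1), NA_real_, gt)
        planted_genes <- entry$gene
        truth <- c(truth, list(tibble(
          patient_id = pid, gene = entry$gene, hgvs_c = entry$hgvs_c,
          contig = entry$contig, pos = entry$pos,
          expected_class = entry$expected_class, role = "causal"
        )))
      }

      if (i %in% vus_idx) {
        g <- sample(vus_genes, 1)
        site <- draw_site(gmap_chr[[g]], gmap_start[[g]])
        hc <- paste0("c.", site$pos %% 997 + 1, site$ref, ">", site$alt)
        push(site$contig, site$pos, site$ref, site$alt, g,
             "missense_variant", hc, "p.?", sample(30:60, 1), NA_real_, "0/1")
        planted_genes <- c(planted_genes, g)
        truth <- c(truth, list(tibble(
          patient_id = pid, gene = g, hgvs_c = hc,
          contig = site$contig, pos = site$pos,
          expected_class = "VUS", role = "vus"
        )))
      }

      n_bg <- rpois(1, params$background_mean)
      bg_class <- if (n_bg > 0) {
        sample(classes, n_bg, replace = TRUE, prob = params$bg_class_probs)
      } else character(0)
      ar_pool <- setdiff(ar_genes, planted_genes)
      n_ar <- sum(bg_class == "ar_single_het")
      if (n_ar > length(ar_pool)) {
        bg_class[bg_class == "ar_single_het"][seq_len(n_ar - length(ar_pool))] <- "common_af"
        n_ar <- length(ar_pool)
      }
      ar_assigned <- if (n_ar > 0) sample(ar_pool, n_ar) else character(0)
      ar_cursor <- 0L
      for (cls in bg_class) {
        af <- NA_real_
        dp <- sample(30:80, 1)
        cons <- "missense_variant"
        if (cls == "off_panel") {
          oi <- sample.int(nrow(offmap), 1)
          g <- offmap$symbol[oi]
          site <- draw_site(offmap$chromosome[oi], offmap$start[oi])
        } else if (cls == "common_af") {
          g <- sample(panel_genes, 1)
          site <- draw_site(gmap_chr[[g]], gmap_start[[g]])
          af <- runif(1, params$benign_af_range[1], params$benign_af_range[2])
        } else if (cls == "low_depth") {
          g <- sample(panel_genes, 1)
          site <- draw_site(gmap_chr[[g]], gmap_start[[g]])
          dp <- sample(1:20, 1)
        } else if (cls == "non_coding") {
          g <- sample(panel_genes, 1)
          site <- draw_site(gmap_chr[[g]], gmap_start[[g]])
          cons <- "intron_variant"
        } else { # ar_single_het
          ar_cursor <- ar_cursor + 1L
          g <- ar_assigned[ar_cursor]
          site <- draw_site(gmap_chr[[g]], gmap_start[[g]])
        }
        hc <- paste0("c.", site$pos %% 997 + 1, site$ref, ">", site$alt)
        push(site$contig, site$pos, site$ref, site$alt, g, cons, hc, "",
             dp, af, "0/1")
      }
      variants <- as_tibble(c(list(patient_id = rep(pid, length(rows$pos))),
                              rows)) %>%
        arrange(contig_rank(.data$contig), .data$pos, .data$alt)
      vcf_paths[i] <- file.path(out_dir, paste0(pid, ".vcf"))
      write_vcf(variants, vcf_paths[i], sample_id = pid,
                provenance = paste0("synthetic cohort seed=", seed))
    }

    truth_tbl <- if (length(truth) > 0) bind_rows(truth) else
      tibble(patient_id = character(0), gene = character(0),
             hgvs_c = character(0), contig = character(0), pos = integer(0),
             expected_class = character(0), role = character(0))
    meta_path <- file.path(out_dir, "metadata.csv")
    readr::write_csv(metadata, meta_path, progress = FALSE)
    truth_path <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(truth_tbl, truth_path, progress = FALSE)
    manifest <- list(
      seed = seed, n_patients = n,
      n_solved_planted = n_solved,
      vcfs = vcf_paths, metadata = meta_path, truth = truth_path
    )
    # the on-disk manifest uses paths relative to out_dir so a cohort
    # directory is relocatable and identical runs are byte-identical
    manifest_disk <- manifest
    manifest_disk$vcfs <- basename(vcf_paths)
    manifest_disk$metadata <- basename(meta_path)
    manifest_disk$truth <- basename(truth_path)
    jsonlite::write_json(manifest_disk, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
  })
}

#' End-to-end recovery check on a synthetic cohort
#'
#' Generates a cohort, runs the full pipeline on the written files (read,
#' cascade, evidence, classification, cohort aggregation), and scores the
#' result against the generator's truth table: the fraction of planted
#' causal variants surviving the cascade, whether the set of flagged
#' solved patients equals the truth-table solved set, and the number of
#' reportable calls among background variants.
#'
#' @inheritParams generate_cohort
#' @param knowledge curated assertions used for classification.
#' @param cfg cascade filter configuration.
#' @param keep_dir optional directory for the generated cohort; a
#'   throw-away temporary directory by default.
#' @return a list of class `fsgs_recovery`: counts, fractions, the
#'   realized detection rate and the underlying `fsgs_run`.
#' @export
run_recovery <- function(params = cohort_params(),
                         catalog = fsgs_causal_catalog(),
                         seed = 1,
                         panel = default_panel(),
                         knowledge = fsgs_knowledge_table(),
                         cfg = filter_config(),
                         keep_dir = NULL) {
  out_dir <- keep_dir %||% tempfile("fsgs_sim_")
  on.exit(if (is.null(keep_dir)) unlink(out_dir, recursive = TRUE))
  generate_cohort(params, catalog, out_dir, seed = seed, panel = panel)
  run <- run_pipeline(list(
    vcf_dir = out_dir,
    metadata = file.path(out_dir, "metadata.csv"),
    panel = panel, knowledge = knowledge, filters = cfg
  ))
  truth <- readr::read_tsv(file.path(out_dir, "truth.tsv"),
                           col_types = readr::cols(pos = readr::col_integer(),
                                                   .default = readr::col_character()),
                           progress = FALSE)
  causal <- truth[truth$role == "causal", , drop = FALSE]
  cand <- run$candidates
  key <- function(d) paste(d$patient_id, d$gene, d$hgvs_c)
  recovered <- key(causal) %in% key(cand)
  reportable <- cand[is_reportable(cand$class), , drop = FALSE]
  false_rep <- sum(!key(reportable) %in% key(causal))
  expected_solved <- sort(unique(causal$patient_id))
  called_solved <- sort(run$cohort$patient_id[run$cohort$verdict == "SOLVED"])
  overall <- detection_rate(run$cohort)
  structure(list(
    n_planted = nrow(causal),
    n_recovered = sum(recovered),
    planted_recovery = if (nrow(causal) == 0) NA_real_ else mean(recovered),
    expected_solved = expected_solved,
    called_solved = called_solved,
    solved_sets_match = identical(expected_solved, called_solved),
    n_false_reportable_background = false_rep,
    detection_rate = overall$rate,
    n_patients = overall$n_total,
    run = run
  ), class = "fsgs_recovery")
}

#' @export
print.fsgs_recovery <- function(x, ...) {
  cat("<fsgs_recovery> planted causal recovered ", x$n_recovered, "/",
      x$n_planted, "; solved sets match: ", x$solved_sets_match,
      "; false reportable background calls: ",
      x$n_false_reportable_background, "\n  realized detection rate ",
      round(x$detection_rate * x$n_patients), "/", x$n_patients,
      " (", as_pct(x$detection_rate), "%)\n", sep = "")
  invisible(x)
}
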