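#' Run the full diagnostic pipeline over a cohort
#'
#' Single entry point wiring every stage: per patient, read the annotated
#' VCF, determine zygosity from the recorded sex, run the five-criteria
#' cascade, assemble ACMG evidence for the candidates, classify, and call
#' the patient solved if at least one variant is pathogenic or likely
#' pathogenic; then aggregate the cohort report.
#'
#' @param config a named list, or a path to a YAML file holding one, with
#'   fields:
#'   \describe{
#'     \item{vcf_dir / vcf_files}{directory scanned for `<patient_id>.vcf`
#'       (or `.vcf.gz`) files, or an explicit character vector of paths
#'       whose basenames (minus extension) are patient ids.}
#'     \item{metadata}{CSV path or tibble with at least `patient_id`,
#'       `sex`, `age_at_biopsy`, `syndrome`, `family_history`.}
#'     \item{panel}{`fsgs_panel`, panel TSV path, or omitted for the
#'       bundled default.}
#'     \item{knowledge}{curated-assertion tibble, TSV path, or omitted.}
#'     \item{filters}{`fsgs_filter_config` or list of arguments for
#'       [filter_config()].}
#'     \item{ann_key, lof_genes, pm2_af_max, use_reputable_source}{optional
#'       overrides.}
#'     \item{out_dir}{if set, JSON and Markdown reports are written there.}
#'   }
#' @return an object of class `fsgs_run`: `cohort` (per-patient metadata
#'   with `verdict`, `causal_genes`, `vus_carrier`, `n_candidates`),
#'   `candidates` (classified candidate variants), `trace` (cascade
#'   funnel), `report` (an `fsgs_report`), `failed_patients`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))

  panel <- config$panel %||% default_panel()
  if (is.character(panel)) panel <- load_panel(panel)
  knowledge <- config$knowledge
  if (is.character(knowledge)) knowledge <- read_knowledge(knowledge)
  cfg <- config$filters %||% filter_config()
  if (!inherits(cfg, "fsgs_filter_config")) cfg <- do.call(filter_config, cfg)
  ann_key <- config$ann_key %||% "ANN"
  lof_genes <- config$lof_genes %||% default_lof_genes()
  pm2_af_max <- config$pm2_af_max %||% 1e-4
  use_pp5 <- config$use_reputable_source %||% TRUE

  metadata <- config$metadata
  if (is.character(metadata)) {
    metadata <- readr::read_csv(metadata, col_types = readr::cols(
      patient_id = readr::col_character(),
      sex = readr::col_character(),
      syndrome = readr::col_character(),
      .default = readr::col_guess()
    ), progress = FALSE)
  }
  metadata <- as_tibble(metadata)
  # pipeline-owned columns are recomputed; drop stale ones if present
  metadata <- metadata[, setdiff(names(metadata),
                                 c("verdict", "causal_genes", "vus_carrier",
                                   "n_candidates")), drop = FALSE]
  stopifnot(all(c("patient_id", "sex") %in% names(metadata)))

  files <- config$vcf_files
  if (is.null(files)) {
    if (is.null(config$vcf_dir)) {
      stop_fsgs("config needs vcf_dir or vcf_files", "fsgs_validation_error")
    }
    files <- list.files(config$vcf_dir, pattern = "\\.vcf(\\.gz)?$",
                        full.names = TRUE)
  }
  if (length(files) == 0) {
    stop_fsgs("no patients found: no VCF files to process",
              "fsgs_validation_error")
  }
  pids <- stringr::str_remove(basename(files), "\\.vcf(\\.gz)?$")
  unknown <- setdiff(pids, metadata$patient_id)
  if (length(unknown) > 0) {
    stop_fsgs(paste0("VCF(s) without metadata rows: ",
                     paste(head(unknown, 3), collapse = ", ")),
              "fsgs_validation_error")
  }

  failed <- character(0)
  all_variants <- vector("list", length(files))
  for (i in seq_along(files)) {
    pid <- pids[i]
    sex <- metadata$sex[match(pid, metadata$patient_id)]
    v <- tryCatch(
      add_zygosity(read_vcf(files[i], patient_id = pid, ann_key = ann_key),
                   sex = sex),
      error = function(e) {
        warn(paste0("patient ", pid, " failed I/O and is excluded: ",
                    conditionMessage(e)))
        NULL
      })
    if (is.null(v)) failed <- c(failed, pid) else all_variants[[i]] <- v
  }
  if (length(failed) == length(files)) {
    stop_fsgs("all patients failed I/O; nothing to analyse", "fsgs_io_error")
  }
  variants <- bind_rows(all_variants)
  ok_pids <- setdiff(pids, failed)

  cascade <- run_cascade(variants, panel, cfg)
  candidates <- cascade$candidates %>%
    evidence_from_annotations(knowledge = knowledge, lof_genes = lof_genes,
                              pm2_af_max = pm2_af_max) %>%
    classify_variants(use_reputable_source = use_pp5)

  per_patient <- tibble(patient_id = ok_pids) %>%
    mutate(
      n_candidates = vapply(.data$patient_id, function(p)
        sum(candidates$patient_id == p), integer(1)),
      causal_genes = lapply(.data$patient_id, function(p)
        sort(unique(candidates$gene[candidates$patient_id == p &
                                      is_reportable(candidates$class)]))),
      verdict = if_else(lengths(.data$causal_genes) > 0, "SOLVED", "UNSOLVED"),
      vus_carrier = vapply(.data$patient_id, function(p)
        any(candidates$patient_id == p & candidates$class == "VUS"),
        logical(1))
    )
  cohort <- metadata %>%
    filter(.data$patient_id %in% ok_pids) %>%
    left_join(per_patient, by = "patient_id")

  run <- structure(list(
    cohort = cohort,
    candidates = candidates,
    trace = cascade$trace,
    report = cohort_report(cohort),
    failed_patients = failed
  ), class = "fsgs_run")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(run, file.path(config$out_dir, "cohort_report.json"))
    write_report_markdown(run, file.path(config$out_dir, "cohort_report.md"))
  }
  run
}

#' @export
print.fsgs_run <- function(x, ...) {
  cat("<fsgs_run> ", nrow(x$cohort), " patient(s), ",
      nrow(x$candidates), " classified candidate variant(s)\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Write the machine-readable cohort report
#'
#' Everything the Markdown report prints is present here; the Markdown
#' rendering performs no arithmetic of its own.
#'
#' @param run an `fsgs_run`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(run, path) {
  rep <- run$report
  payload <- list(
    n_patients = rep$n_patients,
    n_vus_carriers = rep$n_vus_carriers,
    rates = rep$rates,
    gene_breakdown = rep$genes,
    medians = as.list(rep$medians),
    summary = rep$summary,
    candidates = run$candidates %>%
      mutate(evidence = vapply(.data$evidence, paste, character(1),
                               collapse = "+")) %>%
      select(all_of(c("patient_id", "gene", "hgvs_c", "hgvs_p",
                      "evidence", "class", "rule_fired"))),
    trace = run$trace
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a human-readable Markdown cohort report
#'
#' @inheritParams write_report_json
#' @return `path`, invisibly.
#' @export
write_report_markdown <- function(run, path) {
  rep <- run$report
  md_table <- function(df) {
    cols <- names(df)
    fmt <- function(v) vapply(v, function(x) {
      if (is.numeric(x)) format(x, trim = TRUE) else as.character(x)
    }, character(1))
    body <- apply(df, 1, function(r) paste0("| ", paste(fmt(r), collapse = " | "), " |"))
    c(paste0("| ", paste(cols, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
      body)
  }
  lines <- c(
    "# Cohort genetic report",
    "",
    paste0("Patients analysed: ", rep$n_patients,
           "; VUS carriers: ", rep$n_vus_carriers),
    "",
    "## Detection rates", "",
    md_table(rep$rates),
    "",
    "## Causal genes", "",
    if (nrow(rep$genes) > 0) md_table(rep$genes) else "(no solved patients)",
    "",
    "## Median ages (years)", "",
    md_table(rep$medians),
    "",
    "## Clinical summary", "",
    md_table(rep$summary)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
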