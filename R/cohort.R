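#' Diagnostic yield within a patient subgroup
#'
#' Counts solved patients (those with at least one reportable variant)
#' among the patients satisfying a predicate, tidyeval-style:
#' `detection_rate(cohort, age_at_biopsy > 18)`. With no predicate the
#' whole cohort is the denominator.
#'
#' @param cohort patient-level tibble with a `verdict` column
#'   (`"SOLVED"`/`"UNSOLVED"`).
#' @param ... optional filter expressions selecting the subgroup.
#' @param label subgroup name recorded in the output.
#' @return one-row tibble: `subgroup`, `n_solved`, `n_total`, `rate`
#'   (fraction, `NA` for an empty denominator), `rate_pct` (one decimal,
#'   rounded half up).
#' @export
#' @examples
#' detection_rate(fsgs_reference_cohort())
#' detection_rate(fsgs_reference_cohort(), family_history, label = "familial")
detection_rate <- function(cohort, ..., label = "all") {
  sub <- dplyr::filter(cohort, ...)
  n_total <- nrow(sub)
  n_solved <- sum(sub$verdict == "SOLVED")
  rate <- if (n_total == 0) NA_real_ else n_solved / n_total
  tibble(subgroup = label, n_solved = n_solved, n_total = n_total,
         rate = rate, rate_pct = if (is.na(rate)) NA_real_ else as_pct(rate))
}

#' Standard subgroup detection rates
#'
#' The conventional subgroup panel for an FSGS diagnostic cohort: overall,
#' adult (biopsy age over 18 years), pediatric (18 or under), familial,
#' sporadic, and by presenting syndrome.
#'
#' @inheritParams detection_rate
#' @return tibble with one row per subgroup.
#' @export
subgroup_rates <- function(cohort) {
  bind_rows(
    detection_rate(cohort, label = "overall"),
    detection_rate(cohort, .data$age_at_biopsy > 18, label = "adult"),
    detection_rate(cohort, .data$age_at_biopsy <= 18, label = "pediatric"),
    detection_rate(cohort, .data$family_history, label = "familial"),
    detection_rate(cohort, !.data$family_history, label = "sporadic"),
    detection_rate(cohort, .data$syndrome == "SRNS", label = "SRNS"),
    detection_rate(cohort, .data$syndrome == "SSNS", label = "SSNS"),
    detection_rate(cohort, .data$syndrome == "PROTEINURIC_CKD",
                   label = "proteinuric_CKD")
  )
}

#' Solved patients per causal gene
#'
#' Counts patients, not variants: a patient with reportable variants in two
#' genes contributes one count to each gene.
#'
#' @param cohort patient tibble with a `causal_genes` list-column.
#' @return tibble `gene`, `n_patients`, `share_of_solved` (fraction of
#'   solved patients), sorted by decreasing count.
#' @export
gene_breakdown <- function(cohort) {
  solved <- cohort[cohort$verdict == "SOLVED", , drop = FALSE]
  if (nrow(solved) == 0) {
    return(tibble(gene = character(0), n_patients = integer(0),
                  share_of_solved = double(0)))
  }
  tibble(
    patient_id = rep(solved$patient_id, lengths(solved$causal_genes)),
    gene = unlist(solved$causal_genes)
  ) %>%
    distinct() %>%
    count(.data$gene, name = "n_patients") %>%
    mutate(share_of_solved = .data$n_patients / nrow(solved)) %>%
    arrange(dplyr::desc(.data$n_patients), .data$gene)
}

#' Median onset and kidney-failure ages
#'
#' Disease onset is operationalized as age at kidney biopsy, the only
#' per-patient onset proxy routinely available in biopsy cohorts. Medians
#' use the midpoint convention for even sample sizes; absent ages are
#' excluded from the corresponding statistic, and an empty sample yields
#' `NA`.
#'
#' @param cohort patient tibble.
#' @return one-row tibble: `median_onset_all`, `median_esrd_all`,
#'   `median_onset_solved`, `median_esrd_solved`.
#' @export
median_ages <- function(cohort) {
  med <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else median(x)
  }
  solved <- cohort[cohort$verdict == "SOLVED", , drop = FALSE]
  tibble(
    median_onset_all = med(cohort$age_at_biopsy),
    median_esrd_all = med(cohort$age_at_esrd),
    median_onset_solved = med(solved$age_at_biopsy),
    median_esrd_solved = med(solved$age_at_esrd)
  )
}

#' Clinical summary of a cohort
#'
#' Counts and percentages for sex, biopsy-age bands, family history,
#' presenting syndrome, immunosuppression exposure and current status,
#' in the layout conventional for cohort description tables. Percentages
#' are reported to one decimal, rounded half up.
#'
#' @param cohort patient tibble.
#' @return tibble with columns `category`, `level`, `n`, `total`, `pct`.
#' @export
summarize_cohort <- function(cohort) {
  n_all <- nrow(cohort)
  band <- cut(cohort$age_at_biopsy, breaks = c(-Inf, 5, 18, 45, 60, Inf),
              labels = c("1-5", "6-18", "19-45", "45-60", ">60"))
  row_of <- function(category, level, k) {
    tibble(category = category, level = level, n = k, total = n_all,
           pct = if (n_all == 0) NA_real_ else as_pct(k / n_all))
  }
  out <- list(row_of("sex", "male", sum(cohort$sex == "M")))
  for (b in levels(band)) {
    out <- c(out, list(row_of("age_band", b, sum(band == b))))
  }
  out <- c(out, list(row_of("family_history", "positive",
                            sum(cohort$family_history))))
  if ("extrarenal" %in% names(cohort)) {
    out <- c(out, list(row_of("extrarenal", "positive", sum(cohort$extrarenal))))
  }
  for (s in c("ASYMPTOMATIC_PROTEINURIA", "SSNS", "SRNS", "PROTEINURIC_CKD")) {
    out <- c(out, list(row_of("syndrome", s, sum(cohort$syndrome == s))))
  }
  if ("immunosuppression" %in% names(cohort)) {
    out <- c(out, list(row_of("immunosuppression", "received",
                              sum(cohort$immunosuppression))))
  }
  if ("status" %in% names(cohort)) {
    for (s in unique(cohort$status)) {
      out <- c(out, list(row_of("status", s, sum(cohort$status == s))))
    }
  }
  bind_rows(out)
}

#' Build a cohort report
#'
#' Aggregates per-patient verdicts and metadata into the standard report:
#' subgroup detection rates, gene breakdown, median ages and the clinical
#' summary.
#'
#' @param cohort patient tibble with `verdict` and `causal_genes`.
#' @return object of class `fsgs_report`.
#' @export
cohort_report <- function(cohort) {
  if (any(!is.na(cohort$age_at_esrd) &
          cohort$age_at_esrd < cohort$age_at_biopsy)) {
    warn("some patients have age_at_esrd < age_at_biopsy; check metadata")
  }
  structure(list(
    n_patients = nrow(cohort),
    rates = subgroup_rates(cohort),
    genes = gene_breakdown(cohort),
    medians = median_ages(cohort),
    summary = summarize_cohort(cohort),
    n_vus_carriers = if ("vus_carrier" %in% names(cohort)) {
      sum(cohort$vus_carrier)
    } else NA_integer_
  ), class = "fsgs_report")
}

#' @export
print.fsgs_report <- function(x, ...) {
  overall <- x$rates[x$rates$subgroup == "overall", ]
  cat("<fsgs_report> ", x$n_patients, " patients; diagnostic yield ",
      overall$n_solved, "/", overall$n_total, " (", overall$rate_pct, "%)\n",
      sep = "")
  for (i in seq_len(nrow(x$rates))) {
    r <- x$rates[i, ]
    cat(sprintf("  %-16s %2d/%2d  %s%%\n", r$subgroup, r$n_solved, r$n_total,
                ifelse(is.na(r$rate_pct), "NA", format(r$rate_pct))))
  }
  if (nrow(x$genes) > 0) {
    cat("  causal genes: ",
        paste0(x$genes$gene, " (", x$genes$n_patients, ")", collapse = ", "),
        "\n", sep = "")
  }
  m <- x$medians
  cat("  median onset ", m$median_onset_all, "y (solved ",
      m$median_onset_solved, "y); median ESRD age ", m$median_esrd_all,
      "y (solved ", m$median_esrd_solved, "y)\n", sep = "")
  invisible(x)
}
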