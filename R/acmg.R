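#' Table of recognised ACMG evidence codes
#'
#' All 28 ACMG/AMP evidence codes with their default strength class
#' (derived from the code prefix: PVS very strong, PS/BS strong, PM
#' moderate, PP/BP supporting, BA stand-alone) and direction. The
#' reputable-source codes PP5/BP6 are included because published criterion
#' sets use them; [acmg_classify()] can be told to ignore them.
#'
#' @return tibble with columns `code`, `default_strength`, `direction`.
#' @export
acmg_code_table <- function() {
  path_codes <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5))
  ben_codes <- c("BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  tibble(
    code = c(path_codes, ben_codes),
    default_strength = c(
      "VERY_STRONG", rep("STRONG", 4), rep("MODERATE", 6), rep("SUPPORTING", 5),
      "STAND_ALONE", rep("STRONG", 4), rep("SUPPORTING", 7)
    ),
    direction = c(rep("pathogenic", 16), rep("benign", 12))
  )
}

#' Parse an evidence-code string into an evidence set
#'
#' Accepts the compact notation used in clinical reports, e.g.
#' `"PVS1 + PM2 + PM4"` or `"PM1,PM2,PP3,PP5"`. A code may carry an
#' explicit strength override as a `:` suffix (`"PVS1:STRONG"`), the
#' mechanism by which gene-specific refinements (such as expert-consensus
#' collagen-IV adjustments) modulate the default combining arithmetic.
#' Duplicate codes collapse to one entry (the first stated strength wins).
#'
#' @param x character vector of codes, or a single string with codes
#'   separated by `+`, `,` or `;`.
#' @return tibble of class `fsgs_evidence` with columns `code`, `strength`
#'   (effective, after overrides), `direction`, `overridden`.
#' @export
#' @examples
#' parse_evidence("PVS1 + PM2 + PM4")
parse_evidence <- function(x) {
  tokens <- unlist(strsplit(x, "[+,;]"))
  tokens <- stringr::str_trim(tokens)
  tokens <- tokens[tokens != ""]
  tab <- acmg_code_table()
  strengths <- c("STAND_ALONE", "VERY_STRONG", "STRONG", "MODERATE", "SUPPORTING")
  parts <- stringr::str_match(toupper(tokens), "^([A-Z0-9]+)(?::([A-Z_]+))?$")
  if (nrow(parts) > 0 && anyNA(parts[, 1])) {
    stop_fsgs(paste0("unparseable evidence token: ",
                     tokens[which(is.na(parts[, 1]))[1]]),
              "fsgs_validation_error")
  }
  codes <- parts[, 2]
  overrides <- parts[, 3]
  bad <- setdiff(codes, tab$code)
  if (length(bad) > 0) {
    stop_fsgs(paste0("unknown ACMG code: ", bad[1]), "fsgs_validation_error")
  }
  bad_s <- setdiff(stats::na.omit(overrides), strengths)
  if (length(bad_s) > 0) {
    stop_fsgs(paste0("unknown strength override: ", bad_s[1]),
              "fsgs_validation_error")
  }
  ev <- tibble(code = codes, override = overrides) %>%
    distinct(.data$code, .keep_all = TRUE) %>%
    left_join(tab, by = "code") %>%
    mutate(
      strength = if_else(is.na(.data$override), .data$default_strength, .data$override),
      overridden = !is.na(.data$override)
    ) %>%
    select("code", "strength", "direction", "overridden")
  structure(ev, class = c("fsgs_evidence", class(ev)))
}

#' Combine ACMG evidence codes into a classification
#'
#' Implements the standard evidence-combining rules as a pure function of
#' the evidence set. Counting uses effective strengths (after any
#' overrides); the `PVS1`-specific clauses fire on any pathogenic-direction
#' code at VERY_STRONG effective strength, so a downgraded `PVS1:STRONG`
#' counts as an ordinary strong criterion instead.
#'
#' Pathogenic: very strong plus (one strong, or two moderate, or one
#' moderate and one supporting, or two supporting); or two strong; or one
#' strong plus (three moderate, or two moderate and two supporting, or one
#' moderate and four supporting). Two very-strong codes also classify
#' pathogenic. Likely pathogenic: very strong plus one moderate; one strong
#' plus one or two moderate; one strong plus two supporting; three
#' moderate; two moderate plus two supporting; one moderate plus four
#' supporting. Benign: stand-alone, or two benign-strong. Likely benign:
#' one benign-strong plus one benign-supporting, or two benign-supporting.
#' When rules from both directions fire the result is an explicit
#' conflicting VUS. When both a pathogenic and a likely-pathogenic clause
#' are satisfied the stronger class wins.
#'
#' @param evidence an `fsgs_evidence` tibble from [parse_evidence()], or a
#'   string/character vector of codes which will be parsed.
#' @param use_reputable_source if `FALSE`, PP5 and BP6 are removed from the
#'   set before combining (later field guidance deprecates them).
#' @return one-row tibble with `class` (one of `PATHOGENIC`,
#'   `LIKELY_PATHOGENIC`, `VUS`, `LIKELY_BENIGN`, `BENIGN`) and
#'   `rule_fired` (identifier of the satisfied combining rule, `"none"`,
#'   or `"conflict"`).
#' @export
#' @examples
#' acmg_classify("PVS1 + PM2 + PM4")
#' acmg_classify("PS3 + PM2 + PP3")
acmg_classify <- function(evidence, use_reputable_source = TRUE) {
  if (!inherits(evidence, "fsgs_evidence")) {
    evidence <- parse_evidence(evidence)
  }
  if (!use_reputable_source) {
    evidence <- evidence[!evidence$code %in% c("PP5", "BP6"), , drop = FALSE]
  }
  p <- evidence[evidence$direction == "pathogenic", , drop = FALSE]
  b <- evidence[evidence$direction == "benign", , drop = FALSE]
  n_vs <- sum(p$strength == "VERY_STRONG")
  n_st <- sum(p$strength == "STRONG")
  n_mo <- sum(p$strength == "MODERATE")
  n_su <- sum(p$strength == "SUPPORTING")
  n_ba <- sum(b$strength == "STAND_ALONE")
  n_bs <- sum(b$strength == "STRONG")
  n_bp <- sum(b$strength == "SUPPORTING")

  path_rule <- if (n_vs >= 2) "P.VSx2"
  else if (n_vs >= 1 && n_st >= 1) "P.Ia"
  else if (n_vs >= 1 && n_mo >= 2) "P.Ib"
  else if (n_vs >= 1 && n_mo == 1 && n_su >= 1) "P.Ic"
  else if (n_vs >= 1 && n_su >= 2) "P.Id"
  else if (n_st >= 2) "P.II"
  else if (n_st == 1 && n_mo >= 3) "P.IIIa"
  else if (n_st == 1 && n_mo == 2 && n_su >= 2) "P.IIIb"
  else if (n_st == 1 && n_mo == 1 && n_su >= 4) "P.IIIc"
  else NA_character_

  lp_rule <- if (n_vs >= 1 && n_mo >= 1) "LP.I"
  else if (n_st == 1 && n_mo >= 1 && n_mo <= 2) "LP.II"
  else if (n_st == 1 && n_su >= 2) "LP.III"
  else if (n_mo >= 3) "LP.IV"
  else if (n_mo == 2 && n_su >= 2) "LP.V"
  else if (n_mo == 1 && n_su >= 4) "LP.VI"
  else NA_character_

  ben_rule <- if (n_ba >= 1) "B.I"
  else if (n_bs >= 2) "B.II"
  else NA_character_

  lb_rule <- if (n_bs == 1 && n_bp >= 1) "LB.I"
  else if (n_bp >= 2) "LB.II"
  else NA_character_

  path_dir <- !is.na(path_rule) || !is.na(lp_rule)
  ben_dir <- !is.na(ben_rule) || !is.na(lb_rule)

  if (path_dir && ben_dir) {
    return(tibble(class = "VUS", rule_fired = "conflict"))
  }
  if (!is.na(path_rule)) return(tibble(class = "PATHOGENIC", rule_fired = path_rule))
  if (!is.na(lp_rule)) return(tibble(class = "LIKELY_PATHOGENIC", rule_fired = lp_rule))
  if (!is.na(ben_rule)) return(tibble(class = "BENIGN", rule_fired = ben_rule))
  if (!is.na(lb_rule)) return(tibble(class = "LIKELY_BENIGN", rule_fired = lb_rule))
  tibble(class = "VUS", rule_fired = "none")
}

#' Is a classification clinically reportable?
#'
#' Diagnostic-yield statistics count only pathogenic and likely pathogenic
#' findings; VUS carriers are tallied separately, never as solved.
#'
#' @param class character vector of classification values.
#' @return logical vector.
#' @export
is_reportable <- function(class) {
  class %in% c("PATHOGENIC", "LIKELY_PATHOGENIC")
}

#' Genes with an established loss-of-function disease mechanism
#'
#' Used by [evidence_from_annotations()] to decide whether a truncating
#' variant earns the very-strong loss-of-function criterion automatically.
#' The default covers panel genes for which haploinsufficiency or complete
#' loss is a documented mechanism; it is an argument, not a constant, so a
#' site can tighten or extend it.
#'
#' @return character vector of gene symbols.
#' @export
default_lof_genes <- function() {
  c("CLCN5", "OCRL", "GLA", "COL4A3", "COL4A4", "COL4A5", "MAFB",
    "NPHS1", "NPHS2", "PLCE1", "LAMB2", "WT1", "PAX2", "LMX1B",
    "SMARCAL1", "SGPL1", "CTNS", "NUP93", "NUP107", "COQ2", "COQ6",
    "COQ8B")
}

#' Read a curated-assertion table
#'
#' The manual portion of evidence assignment (functional data, hotspot
#' membership, in-silico consensus, reputable-source assertions) lives in a
#' curated TSV with columns `gene`, `hgvs_c`, `codes` (comma-separated,
#' optional `:STRENGTH` suffix per code) and `citation`.
#'
#' @param path TSV path.
#' @return tibble with those four columns.
#' @export
read_knowledge <- function(path) {
  if (!file.exists(path)) {
    stop_fsgs(paste0("knowledge table not found: ", path), "fsgs_io_error")
  }
  k <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  missing <- setdiff(c("gene", "hgvs_c", "codes"), names(k))
  if (length(missing) > 0) {
    stop_fsgs(paste0("knowledge table missing column(s): ",
                     paste(missing, collapse = ", ")), "fsgs_format_error")
  }
  if (!"citation" %in% names(k)) k$citation <- NA_character_
  mutate(k, gene = toupper(.data$gene))
}

#' Assemble the evidence set for each candidate variant
#'
#' Evidence is the union of (a) codes asserted in the curated knowledge
#' table for the exact (gene, hgvs_c) pair, (b) the automatic very-strong
#' loss-of-function code for truncating consequences in genes with a known
#' loss-of-function mechanism, and (c) the automatic moderate
#' absent-from-controls code when the population frequency is absent or
#' below `pm2_af_max`. Everything else must be curated: no in-silico
#' predictors are computed here.
#'
#' @param variants candidate variant tibble.
#' @param knowledge curated-assertion tibble (see [read_knowledge()]) or
#'   `NULL` for automatic codes only.
#' @param lof_genes genes where loss of function is a known mechanism.
#' @param pm2_af_max AF below which the absent-from-controls code applies.
#' @return `variants` with an `evidence` list-column of code strings.
#' @export
evidence_from_annotations <- function(variants, knowledge = NULL,
                                      lof_genes = default_lof_genes(),
                                      pm2_af_max = 1e-4) {
  truncating <- c("stop_gained", "frameshift_variant",
                  "splice_acceptor_variant", "splice_donor_variant")
  lof_genes <- toupper(lof_genes)
  ev <- lapply(seq_len(nrow(variants)), function(i) {
    codes <- character(0)
    if (!is.null(knowledge) && nrow(knowledge) > 0) {
      hit <- knowledge$codes[knowledge$gene == toupper(variants$gene[i]) &
                               knowledge$hgvs_c == variants$hgvs_c[i]]
      if (length(hit) > 0) {
        codes <- c(codes, unlist(strsplit(hit, "[+,;]")))
      }
    }
    if (variants$consequence[i] %in% truncating &&
        toupper(variants$gene[i]) %in% lof_genes) {
      codes <- c(codes, "PVS1")
    }
    af <- variants$af[i]
    if (is.na(af) || af < pm2_af_max) {
      codes <- c(codes, "PM2")
    }
    codes <- stringr::str_trim(codes)
    codes <- codes[codes != ""]
    # first occurrence wins on duplicates (curated strength overrides kept)
    codes[!duplicated(stringr::str_remove(toupper(codes), ":.*$"))]
  })
  mutate(variants, evidence = ev)
}

#' Classify every variant in a tibble
#'
#' Maps [acmg_classify()] over the `evidence` list-column produced by
#' [evidence_from_annotations()].
#'
#' @param variants tibble with an `evidence` list-column.
#' @param use_reputable_source passed to [acmg_classify()].
#' @return `variants` with `class` and `rule_fired` columns appended.
#' @export
classify_variants <- function(variants, use_reputable_source = TRUE) {
  if (nrow(variants) == 0) {
    return(mutate(variants, class = character(0), rule_fired = character(0)))
  }
  res <- purrr::map(variants$evidence, function(codes) {
    if (length(codes) == 0) {
      tibble(class = "VUS", rule_fired = "none")
    } else {
      acmg_classify(paste(codes, collapse = ","),
                    use_reputable_source = use_reputable_source)
    }
  })
  bind_rows(
    lapply(seq_along(res), function(i) res[[i]])
  ) -> cls
  mutate(variants, class = cls$class, rule_fired = cls$rule_fired)
}
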