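#' Default coding-consequence vocabulary
#'
#' Consequence terms counted as "coding" by the first cascade criterion.
#' Panel diagnostics conventionally retain the canonical splice-site terms
#' alongside protein-changing ones; synonymous changes are excluded.
#'
#' @return character vector of consequence terms.
#' @export
coding_consequences <- function() {
  c("missense_variant", "stop_gained", "stop_lost", "start_lost",
    "frameshift_variant", "inframe_insertion", "inframe_deletion",
    "splice_acceptor_variant", "splice_donor_variant")
}

# terms we recognise as valid but non-coding; anything outside the union of
# this and the configured coding set is an "unknown" term
known_noncoding_consequences <- function() {
  c("synonymous_variant", "intron_variant", "intergenic_variant",
    "upstream_gene_variant", "downstream_gene_variant",
    "5_prime_UTR_variant", "3_prime_UTR_variant",
    "non_coding_transcript_variant", "splice_region_variant")
}

#' Cascade filter configuration
#'
#' Bundles the tunable thresholds of the five-criteria prioritization
#' cascade. Defaults encode the published algorithm: coding consequences
#' only; read depth strictly greater than 20; allele frequency strictly
#' below 1/1,000 for autosomal-recessive genes and strictly below 1/10,000
#' for dominant or X-linked genes; absent population frequency treated as 0
#' (a variant never seen in databases is maximally rare, so it passes the
#' frequency criterion).
#'
#' @param coding set of consequence terms accepted by criterion I.
#' @param min_depth_exclusive depth threshold; survivors need `depth >` this.
#' @param af_max_ar exclusive AF ceiling for AR genes.
#' @param af_max_ad_xl exclusive AF ceiling for AD/XL genes.
#' @param treat_absent_af_as_zero if `TRUE` (default) a missing AF counts as
#'   0 and passes; if `FALSE` missing-AF variants are dropped (fail-closed).
#' @param keep_unknown_consequences if `TRUE`, consequence terms outside the
#'   recognised vocabulary survive criterion I; default drops them. Either
#'   way their count is reported via a message.
#' @return a list of class `fsgs_filter_config`.
#' @export
filter_config <- function(coding = coding_consequences(),
                          min_depth_exclusive = 20L,
                          af_max_ar = 1e-3,
                          af_max_ad_xl = 1e-4,
                          treat_absent_af_as_zero = TRUE,
                          keep_unknown_consequences = FALSE) {
  stopifnot(min_depth_exclusive >= 0,
            af_max_ad_xl > 0, af_max_ad_xl <= af_max_ar, af_max_ar < 1)
  structure(list(
    coding = coding,
    min_depth_exclusive = as.integer(min_depth_exclusive),
    af_max_ar = af_max_ar,
    af_max_ad_xl = af_max_ad_xl,
    treat_absent_af_as_zero = isTRUE(treat_absent_af_as_zero),
    keep_unknown_consequences = isTRUE(keep_unknown_consequences)
  ), class = "fsgs_filter_config")
}

#' Criterion I: keep coding consequences
#'
#' @param variants variant tibble.
#' @param cfg an [filter_config()] object.
#' @return surviving variants (subset of rows).
#' @export
filter_coding <- function(variants, cfg = filter_config()) {
  known <- c(cfg$coding, known_noncoding_consequences())
  unknown <- setdiff(unique(variants$consequence), known)
  if (length(unknown) > 0) {
    inform(paste0("criterion I: ", length(unknown),
                  " unrecognised consequence term(s) (",
                  paste(head(unknown, 3), collapse = ", "), ") ",
                  if (cfg$keep_unknown_consequences) "kept" else "dropped"))
  }
  keep <- variants$consequence %in% cfg$coding |
    (cfg$keep_unknown_consequences & variants$consequence %in% unknown)
  variants[keep, , drop = FALSE]
}

#' Criterion II: keep deeply covered calls
#'
#' Read depth must be strictly greater than the threshold ("more than 20"),
#' so a depth of exactly 20 is dropped. Variants whose depth could not be
#' determined carry depth 0 from [read_vcf()] and fail here.
#'
#' @inheritParams filter_coding
#' @return surviving variants.
#' @export
filter_depth <- function(variants, cfg = filter_config()) {
  variants[variants$depth > cfg$min_depth_exclusive, , drop = FALSE]
}

#' Criterion III: keep variants in panel genes
#'
#' @inheritParams filter_coding
#' @param panel an `fsgs_panel`.
#' @return surviving variants.
#' @export
filter_panel <- function(variants, panel) {
  variants[toupper(variants$gene) %in% unique(panel$symbol), , drop = FALSE]
}

#' Criterion IV: inheritance-mode-aware allele-frequency filter
#'
#' AR-gene variants survive iff AF < `af_max_ar`; AD/XL-gene variants iff
#' AF < `af_max_ad_xl` (both strict). Calling this on a variant whose gene
#' is not on the panel is a contract violation (criterion III must run
#' first). For a dual-mode gene a variant survives if it passes under
#' either mode; the zygosity rule then re-checks mode-specific
#' qualification.
#'
#' @inheritParams filter_panel
#' @param cfg an [filter_config()].
#' @return surviving variants.
#' @export
filter_frequency <- function(variants, panel, cfg = filter_config()) {
  off <- setdiff(toupper(variants$gene), unique(panel$symbol))
  if (length(off) > 0) {
    stop_fsgs(paste0("filter_frequency() saw gene(s) not on the panel (",
                     paste(head(off, 3), collapse = ", "),
                     "); run filter_panel() first"),
              "fsgs_contract_error")
  }
  if (nrow(variants) == 0) return(variants)
  keep <- vapply(seq_len(nrow(variants)), function(i) {
    passes_frequency(variants$af[i], mode_of(panel, variants$gene[i]), cfg)
  }, logical(1))
  variants[keep, , drop = FALSE]
}

# TRUE if af qualifies under any of the given modes
passes_frequency <- function(af, modes, cfg) {
  if (is.na(af)) {
    return(cfg$treat_absent_af_as_zero)
  }
  any(vapply(modes, function(m) {
    ceiling_af <- if (m == "AR") cfg$af_max_ar else cfg$af_max_ad_xl
    af < ceiling_af
  }, logical(1)))
}

#' Criterion V: mono-/biallelic retention rule
#'
#' One retained variant suffices in a dominant or X-linked gene (a
#' hemizygous call in a male satisfies the one-variant rule); a recessive
#' gene yields candidates only when the patient carries at least two
#' distinct retained variants in that gene or at least one homozygous-ALT
#' variant (a homozygote counts as two alleles). Otherwise that gene's
#' variants are discarded for that patient. Phase is not modelled: two
#' heterozygous hits in one AR gene are assumed in trans, a documented
#' limitation of singleton exomes.
#'
#' For dual-mode genes each mode's retention rule is evaluated over the
#' variants frequency-qualified for that mode (requires `cfg`); the union
#' of survivors is kept.
#'
#' @param variants frequency-filtered variants carrying a `zygosity` column.
#' @param panel an `fsgs_panel`.
#' @param cfg the [filter_config()] used upstream; needed only to resolve
#'   per-mode frequency qualification for dual-mode genes.
#' @return candidate variants.
#' @export
apply_zygosity_rule <- function(variants, panel, cfg = filter_config()) {
  if (nrow(variants) == 0) return(variants)
  if (!"zygosity" %in% names(variants)) {
    stop_fsgs("variants must carry a zygosity column; call add_zygosity() first",
              "fsgs_contract_error")
  }
  variants %>%
    mutate(.row = row_number()) %>%
    group_by(.data$patient_id, .data$gene) %>%
    group_modify(function(g, key) {
      modes <- mode_of(panel, key$gene)
      kept <- integer(0)
      for (m in modes) {
        qual <- vapply(g$af, passes_frequency, logical(1), modes = m, cfg = cfg)
        gq <- g[qual, , drop = FALSE]
        if (nrow(gq) == 0) next
        if (m %in% c("AD", "XL")) {
          kept <- union(kept, gq$.row)
        } else {
          allele_ok <- nrow(gq) >= 2 || any(gq$zygosity == "HOM_ALT")
          if (allele_ok) kept <- union(kept, gq$.row)
        }
      }
      g[g$.row %in% kept, , drop = FALSE]
    }) %>%
    ungroup() %>%
    select(-".row") %>%
    select(all_of(names(variants))) %>%
    arrange(.data$patient_id, contig_rank(.data$contig), .data$pos, .data$alt)
}

#' Run the full five-criteria prioritization cascade
#'
#' Composes [filter_coding()], [filter_depth()], [filter_panel()],
#' [filter_frequency()] and [apply_zygosity_rule()] in order, recording a
#' per-patient, per-criterion survivor count (the audit trail of the
#' filtering funnel).
#'
#' @param variants variant tibble with `zygosity` (see [add_zygosity()]).
#' @param panel an `fsgs_panel`.
#' @param cfg an [filter_config()].
#' @return an object of class `fsgs_cascade`: a list with `candidates` (the
#'   surviving variant tibble) and `trace` (tibble of `patient_id`,
#'   `criterion`, `n_in`, `n_out`).
#' @export
run_cascade <- function(variants, panel, cfg = filter_config()) {
  patients <- unique(variants$patient_id)
  stages <- list(
    I = function(v) filter_coding(v, cfg),
    II = function(v) filter_depth(v, cfg),
    III = function(v) filter_panel(v, panel),
    IV = function(v) filter_frequency(v, panel, cfg),
    V = function(v) apply_zygosity_rule(v, panel, cfg)
  )
  current <- variants
  trace <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    nxt <- stages[[s]](current)
    trace[[s]] <- tibble(
      patient_id = patients,
      criterion = names(stages)[s],
      n_in = vapply(patients, function(p) sum(current$patient_id == p), integer(1)),
      n_out = vapply(patients, function(p) sum(nxt$patient_id == p), integer(1))
    )
    current <- nxt
  }
  structure(list(candidates = current, trace = bind_rows(trace)),
            class = "fsgs_cascade")
}

#' @export
print.fsgs_cascade <- function(x, ...) {
  totals <- x$trace %>%
    group_by(.data$criterion) %>%
    summarise(n_in = sum(.data$n_in), n_out = sum(.data$n_out))
  cat("<fsgs_cascade> ", nrow(x$candidates), " candidate variant(s) in ",
      length(unique(x$trace$patient_id)), " patient(s)\n", sep = "")
  for (i in seq_len(nrow(totals))) {
    cat(sprintf("  criterion %-3s %5d -> %5d\n", totals$criterion[i],
                totals$n_in[i], totals$n_out[i]))
  }
  invisible(x)
}
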