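# independent reference implementations used only to check the package's
# results; deliberately written in a different style (base R, clause by
# clause) and never sharing code with the implementation under test

# evidence combiner oracle over plain code strings (default strengths only)
oracle_classify <- function(codes) {
  vs <- sum(grepl("^PVS", codes))
  st <- sum(grepl("^PS[0-9]", codes))
  mo <- sum(grepl("^PM[0-9]", codes))
  su <- sum(grepl("^PP[0-9]", codes))
  ba <- any(codes == "BA1")
  bs <- sum(grepl("^BS[0-9]", codes))
  bp <- sum(grepl("^BP[0-9]", codes))

  pathogenic <-
    (vs >= 2) ||
    (vs >= 1 && (st >= 1 || mo >= 2 || (mo >= 1 && su >= 1) || su >= 2)) ||
    (st >= 2) ||
    (st >= 1 && (mo >= 3 || (mo == 2 && su >= 2) || (mo == 1 && su >= 4)))
  likely_pathogenic <-
    (vs >= 1 && mo >= 1) ||
    (st == 1 && (mo == 1 || mo == 2)) ||
    (st >= 1 && su >= 2) ||
    (mo >= 3) ||
    (mo == 2 && su >= 2) ||
    (mo == 1 && su >= 4)
  benign <- ba || bs >= 2
  likely_benign <- (bs == 1 && bp >= 1) || bp >= 2

  path_dir <- pathogenic || likely_pathogenic
  ben_dir <- benign || likely_benign
  if (path_dir && ben_dir) return("VUS")
  if (pathogenic) return("PATHOGENIC")
  if (likely_pathogenic) return("LIKELY_PATHOGENIC")
  if (benign) return("BENIGN")
  if (likely_benign) return("LIKELY_BENIGN")
  "VUS"
}

# one-pass composite-predicate cascade oracle (single-mode panels)
oracle_cascade <- function(variants, panel, cfg) {
  n <- nrow(variants)
  if (n == 0) return(variants)
  mode_lookup <- setNames(panel$mode, panel$symbol)
  pass <- logical(n)
  for (i in seq_len(n)) {
    g <- toupper(variants$gene[i])
    on_panel <- g %in% names(mode_lookup)
    coding <- variants$consequence[i] %in% cfg$coding
    deep <- variants$depth[i] > cfg$min_depth_exclusive
    af <- variants$af[i]
    freq_ok <- FALSE
    if (on_panel) {
      lim <- if (mode_lookup[[g]] == "AR") cfg$af_max_ar else cfg$af_max_ad_xl
      if (is.na(af)) {
        freq_ok <- cfg$treat_absent_af_as_zero
      } else {
        freq_ok <- af < lim
      }
    }
    pass[i] <- coding && deep && on_panel && freq_ok
  }
  kept <- logical(n)
  for (p in unique(variants$patient_id)) {
    for (g in unique(toupper(variants$gene[variants$patient_id == p & pass]))) {
      rows <- which(variants$patient_id == p & toupper(variants$gene) == g & pass)
      if (mode_lookup[[g]] %in% c("AD", "XL")) {
        kept[rows] <- TRUE
      } else {
        if (length(rows) >= 2 || any(variants$zygosity[rows] == "HOM_ALT")) {
          kept[rows] <- TRUE
        }
      }
    }
  }
  variants[kept, , drop = FALSE]
}

# sort-based median for checking median_ages
oracle_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}
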