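#' Read an annotated single-sample VCF into a variant tibble
#'
#' Ingests one patient's annotated exome calls. Annotation is expected in a
#' single INFO key (default `ANN`, `Number=A`) holding one `|`-separated
#' block per ALT allele with the five subfields
#' `gene|consequence|hgvs_c|hgvs_p|population_af`. This deliberately narrow
#' dialect carries exactly the attributes the prioritization cascade needs;
#' full VEP/SnpEff CSQ parsing is out of scope.
#'
#' Multi-allelic records are split into one row per carried ALT allele.
#' Records without a usable genotype, or homozygous-reference, are dropped.
#' Genotypes are canonicalized per emitted ALT: `1` (hemizygous single
#' allele), `1/1` (both alleles are this ALT) or `0/1` (one copy). A missing
#' population-AF subfield becomes `NA` ("absent from databases"), which is
#' distinct from 0 at this layer; the filter layer decides its meaning.
#'
#' Read depth is taken from FORMAT/DP of the first sample; if absent, from
#' INFO/DP; if both are absent the depth is 0, so the variant fails the
#' depth criterion rather than passing silently.
#'
#' @param path VCF path (plain or bgzip/gzip).
#' @param patient_id identifier recorded on every emitted row.
#' @param ann_key INFO key holding the annotation blocks.
#' @return tibble with columns `patient_id`, `contig`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `hgvs_c`, `hgvs_p`, `depth`, `af`, `gt`, sorted
#'   by contig and position, with a `parse_report` attribute counting
#'   skipped records/blocks.
#' @export
read_vcf <- function(path, patient_id, ann_key = "ANN") {
  if (!file.exists(path)) {
    stop_fsgs(paste0("VCF not found: ", path), "fsgs_io_error")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  info_ids <- vcfR::queryMETA(vcf, element = "INFO")
  has_ann <- any(grepl(paste0("INFO=<ID=", ann_key, "\\b"), unlist(info_ids))) ||
    any(grepl(paste0("ID=", ann_key, "$"), unlist(info_ids)))
  if (!has_ann) {
    stop_fsgs(paste0("annotation INFO key '", ann_key,
                     "' is not declared in the VCF header of ", path),
              "fsgs_format_error")
  }

  empty <- tibble(
    patient_id = character(), contig = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    consequence = character(), hgvs_c = character(), hgvs_p = character(),
    depth = integer(), af = double(), gt = character()
  )
  n_rec <- nrow(vcf@fix)
  report <- list(n_records = n_rec, n_no_genotype = 0L,
                 n_skipped_records = 0L, n_skipped_blocks = 0L,
                 n_variants = 0L)
  if (n_rec == 0) {
    attr(empty, "parse_report") <- report
    return(empty)
  }

  ann_vals <- vcfR::extract.info(vcf, element = ann_key)
  info_dp <- suppressWarnings(vcfR::extract.info(vcf, element = "DP",
                                                 as.numeric = TRUE))
  has_gt_section <- ncol(vcf@gt) >= 2
  gt_vals <- if (has_gt_section) {
    vcfR::extract.gt(vcf, element = "GT")[, 1]
  } else rep(NA_character_, n_rec)
  dp_vals <- if (has_gt_section) {
    suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                      as.numeric = TRUE)[, 1])
  } else rep(NA_real_, n_rec)

  # accumulate plain vectors; one tibble at the end (hot path)
  cap <- n_rec * 2L
  acc <- list(contig = character(cap), pos = integer(cap), ref = character(cap),
              alt = character(cap), gene = character(cap),
              consequence = character(cap), hgvs_c = character(cap),
              hgvs_p = character(cap), depth = integer(cap), af = double(cap),
              gt = character(cap))
  m <- 0L
  for (i in seq_len(n_rec)) {
    gt_str <- gt_vals[i]
    if (is.na(gt_str) || gt_str %in% c(".", "./.", ".|.")) {
      report$n_no_genotype <- report$n_no_genotype + 1L
      next
    }
    toks <- strsplit(gt_str, "[/|]")[[1]]
    if (any(toks == ".") || length(toks) == 0) {
      report$n_no_genotype <- report$n_no_genotype + 1L
      next
    }
    idx <- suppressWarnings(as.integer(toks))
    alt_field <- vcf@fix[i, "ALT"]
    if (anyNA(idx) || is.na(alt_field) || alt_field == ".") {
      report$n_skipped_records <- report$n_skipped_records + 1L
      next
    }
    alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
    if (max(idx) > length(alts)) {
      report$n_skipped_records <- report$n_skipped_records + 1L
      next
    }
    carried <- sort(unique(idx[idx > 0]))
    if (length(carried) == 0) next  # homozygous reference
    if (is.na(ann_vals[i])) {
      report$n_skipped_records <- report$n_skipped_records + 1L
      next
    }
    blocks <- strsplit(ann_vals[i], ",", fixed = TRUE)[[1]]
    if (length(blocks) != length(alts)) {
      report$n_skipped_records <- report$n_skipped_records + 1L
      next
    }
    depth_i <- dp_vals[i]
    if (is.na(depth_i)) depth_i <- info_dp[i]
    if (is.na(depth_i)) depth_i <- 0
    for (k in carried) {
      fields <- strsplit(blocks[k], "|", fixed = TRUE)[[1]]
      if (length(fields) > 5 || length(fields) < 1) {
        report$n_skipped_blocks <- report$n_skipped_blocks + 1L
        next
      }
      length(fields) <- 5
      fields[is.na(fields)] <- ""
      af_str <- fields[5]
      af <- NA_real_
      if (!af_str %in% c("", ".")) {
        af <- suppressWarnings(as.numeric(af_str))
        if (is.na(af) || af < 0 || af > 1) {
          report$n_skipped_blocks <- report$n_skipped_blocks + 1L
          next
        }
      }
      copies <- sum(idx == k)
      gt_canon <- if (length(idx) == 1) "1" else if (copies == length(idx)) "1/1" else "0/1"
      m <- m + 1L
      if (m > cap) {  # grow if many multi-allelic records
        acc <- lapply(acc, function(col) { length(col) <- 2L * cap; col })
        cap <- 2L * cap
      }
      acc$contig[m] <- vcf@fix[i, "CHROM"]
      acc$pos[m] <- as.integer(vcf@fix[i, "POS"])
      acc$ref[m] <- vcf@fix[i, "REF"]
      acc$alt[m] <- alts[k]
      acc$gene[m] <- toupper(fields[1])
      acc$consequence[m] <- fields[2]
      acc$hgvs_c[m] <- fields[3]
      acc$hgvs_p[m] <- fields[4]
      acc$depth[m] <- as.integer(depth_i)
      acc$af[m] <- af
      acc$gt[m] <- gt_canon
    }
  }
  res <- if (m == 0) empty else tibble(
    patient_id = patient_id,
    contig = normalize_contig(acc$contig[seq_len(m)]),
    pos = acc$pos[seq_len(m)], ref = acc$ref[seq_len(m)],
    alt = acc$alt[seq_len(m)], gene = acc$gene[seq_len(m)],
    consequence = acc$consequence[seq_len(m)],
    hgvs_c = acc$hgvs_c[seq_len(m)], hgvs_p = acc$hgvs_p[seq_len(m)],
    depth = acc$depth[seq_len(m)], af = acc$af[seq_len(m)],
    gt = acc$gt[seq_len(m)]
  )
  res <- res %>% arrange(contig_rank(.data$contig), .data$pos, .data$alt)
  report$n_variants <- nrow(res)
  if (report$n_skipped_records + report$n_skipped_blocks > 0) {
    warn(paste0("read_vcf(", basename(path), "): skipped ",
                report$n_skipped_records, " record(s) and ",
                report$n_skipped_blocks,
                " annotation block(s) that were malformed"))
  }
  attr(res, "parse_report") <- report
  res
}

#' Zygosity of each variant given the patient's sex
#'
#' Determines `HET`, `HOM_ALT` or `HEMI` from the canonical genotype, the
#' contig and the patient's sex. Singleton genotypes are hemizygous by
#' definition; a diploid-coded homozygous ALT call on chromosome X in a male
#' is also treated as hemizygous, because callers commonly emit `1/1` on X
#' for males. A heterozygous-coded X call in a male is left `HET`
#' (pseudo-autosomal regions and mosaic calls make demotion unsafe).
#'
#' @param variants variant tibble from [read_vcf()].
#' @param sex `"M"` or `"F"`.
#' @return character vector of zygosities, one per row.
#' @export
zygosity_of <- function(variants, sex) {
  sex <- match.arg(sex, c("M", "F"))
  contig <- normalize_contig(variants$contig)
  case_when(
    variants$gt == "1" ~ "HEMI",
    contig == "chrY" ~ "HEMI",
    variants$gt == "1/1" & contig == "chrX" & sex == "M" ~ "HEMI",
    variants$gt == "1/1" ~ "HOM_ALT",
    TRUE ~ "HET"
  )
}

#' Add a zygosity column to a variant tibble
#'
#' @inheritParams zygosity_of
#' @return `variants` with a `zygosity` column appended.
#' @export
add_zygosity <- function(variants, sex) {
  mutate(variants, zygosity = zygosity_of(variants, sex))
}

#' Write a variant tibble as a single-sample VCF
#'
#' Emits VCF v4.2 with the same annotation dialect [read_vcf()] consumes,
#' one record per row (records are written biallelic; upstream splitting is
#' not re-joined), sorted by contig and position. A provenance header line
#' records how the subset was produced.
#'
#' @param variants variant tibble (rows from one patient).
#' @param path output path; written plain-text regardless of extension.
#' @param sample_id sample column name; defaults to the patient id found in
#'   `variants`, or `"SAMPLE"` for an empty set.
#' @param ann_key INFO key to write annotation under.
#' @param provenance optional string stored in a `##fsgsprio_filter=` line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_id = NULL, ann_key = "ANN",
                      provenance = NULL) {
  if (is.null(sample_id)) {
    ids <- unique(variants$patient_id)
    if (length(ids) > 1) {
      stop_fsgs("write_vcf() writes one patient per file; got multiple patient ids",
                "fsgs_validation_error")
    }
    sample_id <- if (length(ids) == 1) ids else "SAMPLE"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=fsgsprio-", as.character(utils::packageVersion("fsgsprio"))),
    if (!is.null(provenance)) paste0("##fsgsprio_filter=", provenance),
    paste0("##INFO=<ID=", ann_key, ",Number=A,Type=String,Description=",
           "\"gene|consequence|hgvs_c|hgvs_p|population_af\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- character(0)
  if (nrow(variants) > 0) {
    v <- variants %>% arrange(contig_rank(.data$contig), .data$pos, .data$alt)
    af_str <- if_else(is.na(v$af), "", as.character(v$af))
    ann <- paste(v$gene, v$consequence, v$hgvs_c, v$hgvs_p, af_str, sep = "|")
    body <- paste(v$contig, v$pos, ".", v$ref, v$alt, ".", ".",
                  paste0(ann_key, "=", ann), "GT:DP",
                  paste0(v$gt, ":", v$depth), sep = "\t")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
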