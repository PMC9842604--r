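# fixture builders shared across the suite; everything is constructed in
# code so tests run without any bundled binary data

# a variant row with sensible defaults that pass every cascade criterion
# for a heterozygous call in an AD panel gene
make_variants <- function(n = 1, patient_id = "T01", contig = "chr19",
                          pos = seq(1e6, by = 1000, length.out = n),
                          ref = "A", alt = "G", gene = "ACTN4",
                          consequence = "missense_variant",
                          hgvs_c = paste0("c.", seq_len(n), "A>G"),
                          hgvs_p = "", depth = 50L, af = NA_real_,
                          gt = "0/1", zygosity = "HET") {
  tibble::tibble(
    patient_id = patient_id, contig = contig, pos = as.integer(pos),
    ref = ref, alt = alt, gene = gene, consequence = consequence,
    hgvs_c = hgvs_c, hgvs_p = hgvs_p, depth = as.integer(depth), af = af,
    gt = gt, zygosity = zygosity
  )
}

# minimal panel with one gene per mode
tiny_panel <- function() {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(c(
    "symbol\tmode\tchromosome\tphenocopy",
    "ACTN4\tAD\tchr19\tfalse",
    "NPHS2\tAR\tchr1\tfalse",
    "CLCN5\tXL\tchrX\ttrue"
  ), f)
  load_panel(f, name = "tiny", version = "test")
}

# write raw VCF text (independent of write_vcf) and return the path
write_vcf_text <- function(records, ann_header = TRUE,
                           env = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".vcf", .local_envir = env)
  header <- c(
    "##fileformat=VCFv4.2",
    if (ann_header)
      "##INFO=<ID=ANN,Number=A,Type=String,Description=\"ann\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"
  )
  writeLines(c(header, records), f)
  f
}

# random mixed cohort of variants for property tests: a blend of passing
# and failing rows across panel and off-panel genes
random_variant_cohort <- function(n_variants, n_patients, panel,
                                  seed = 1) {
  withr::with_seed(seed, {
    genes <- c(unique(panel$symbol), "TTN", "OBSCN", "MUC16")
    consequences <- c("missense_variant", "stop_gained", "frameshift_variant",
                      "intron_variant", "synonymous_variant")
    gene <- sample(genes, n_variants, replace = TRUE)
    chrom <- ifelse(gene %in% panel$symbol,
                    panel$chromosome[match(gene, panel$symbol)], "chr2")
    gt <- sample(c("0/1", "1/1", "1"), n_variants, replace = TRUE,
                 prob = c(0.8, 0.15, 0.05))
    v <- tibble::tibble(
      patient_id = sample(sprintf("R%02d", seq_len(n_patients)), n_variants,
                          replace = TRUE),
      contig = chrom,
      pos = sample.int(5e7, n_variants),
      ref = "A", alt = "G",
      gene = gene,
      consequence = sample(consequences, n_variants, replace = TRUE),
      hgvs_c = paste0("c.", seq_len(n_variants), "A>G"),
      hgvs_p = "",
      depth = sample(0:60, n_variants, replace = TRUE),
      af = ifelse(runif(n_variants) < 0.3, NA_real_,
                  runif(n_variants)^3),  # skewed toward rare
      gt = gt
    )
    sex <- ifelse(as.integer(sub("R", "", v$patient_id)) %% 2 == 0, "M", "F")
    v$zygosity <- mapply(function(i, s) zygosity_of(v[i, ], s),
                         seq_len(n_variants), sex)
    v
  })
}
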