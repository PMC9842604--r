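#' Load a disease-gene screening panel
#'
#' Reads a tab-separated panel file into a panel tibble. The panel is the
#' object of the third, fourth and fifth prioritization criteria: it decides
#' which genes are screened at all, which allele-frequency ceiling applies
#' (autosomal-recessive genes tolerate more common variants than dominant or
#' X-linked genes), and whether one or two retained variants are required for
#' a gene to yield a candidate.
#'
#' The file must be UTF-8 TSV with header columns `symbol`, `mode`,
#' `chromosome`, `phenocopy`; `mode` must be one of `AD`, `AR`, `XL` and
#' `phenocopy` one of `true`/`false`. A gene may appear on two rows with
#' *distinct* modes (dual-inheritance genes); repeating a (symbol, mode) pair
#' is rejected. X-linked rows must sit on chromosome X.
#'
#' @param path path to the panel TSV.
#' @param name,version optional panel identity strings stored as attributes.
#' @return a tibble of class `fsgs_panel` with columns `symbol`, `mode`,
#'   `chromosome` (normalized to `chr`-prefixed), `phenocopy`.
#' @seealso [default_panel()], [mode_of()], [write_panel()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("symbol\tmode\tchromosome\tphenocopy",
#'              "NPHS2\tAR\tchr1\tfalse"), f)
#' load_panel(f, name = "mini")
load_panel <- function(path, name = basename(path), version = "unversioned") {
  if (!file.exists(path)) {
    stop_fsgs(paste0("panel file not found: ", path), "fsgs_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("symbol", "mode", "chromosome", "phenocopy")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_fsgs(paste0("panel file is missing required column(s): ",
                     paste(missing, collapse = ", ")),
              "fsgs_format_error")
  }
  bad_mode <- which(!raw$mode %in% c("AD", "AR", "XL"))
  if (length(bad_mode) > 0) {
    stop_fsgs(paste0("unknown inheritance mode '", raw$mode[bad_mode[1]],
                     "' on panel data line ", bad_mode[1]),
              "fsgs_validation_error")
  }
  bad_ph <- which(!tolower(raw$phenocopy) %in% c("true", "false"))
  if (length(bad_ph) > 0) {
    stop_fsgs(paste0("phenocopy must be true/false; got '",
                     raw$phenocopy[bad_ph[1]], "' on panel data line ", bad_ph[1]),
              "fsgs_validation_error")
  }
  panel <- tibble(
    symbol = toupper(raw$symbol),
    mode = raw$mode,
    chromosome = normalize_contig(raw$chromosome),
    phenocopy = tolower(raw$phenocopy) == "true"
  )
  dup <- panel %>% count(.data$symbol, .data$mode) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    stop_fsgs(paste0("duplicate panel entry for gene ", dup$symbol[1],
                     " with mode ", dup$mode[1]),
              "fsgs_validation_error")
  }
  bad_xl <- panel %>% filter(.data$mode == "XL", .data$chromosome != "chrX")
  if (nrow(bad_xl) > 0) {
    stop_fsgs(paste0("X-linked gene ", bad_xl$symbol[1],
                     " is not on chromosome X (", bad_xl$chromosome[1], ")"),
              "fsgs_validation_error")
  }
  new_panel(panel, name = name, version = version)
}

new_panel <- function(tbl, name = "panel", version = "unversioned") {
  structure(as_tibble(tbl),
            panel_name = name, panel_version = version,
            class = c("fsgs_panel", class(as_tibble(tbl))))
}

#' Default bundled FSGS screening panel
#'
#' An 87-gene panel of established FSGS / steroid-resistant nephrotic
#' syndrome genes plus phenocopy-disease genes (Alport syndrome, Dent
#' disease, Lowe syndrome, Fabry disease and other conditions whose renal
#' histology can mimic FSGS), each with a single declared inheritance mode.
#' Dual-inheritance genes (for example the collagen IV genes, reported both
#' dominant and recessive) carry the mode used for cohort reporting; users
#' needing both retention rules can supply a custom panel listing the gene
#' twice. The panel is fully user-replaceable via [load_panel()].
#'
#' @return an `fsgs_panel` tibble of 87 genes.
#' @export
#' @examples
#' nrow(default_panel())
default_panel <- function() {
  load_panel(system.file("extdata", "fsgs_panel_v1.tsv", package = "fsgsprio"),
             name = "FSGS-87", version = "1.0")
}

#' Write a panel back to TSV
#'
#' Inverse of [load_panel()]: emits the same four-column TSV dialect, so a
#' load/write cycle reproduces a normalized panel file byte-for-byte.
#'
#' @param panel an `fsgs_panel` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "fsgs_panel"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    "symbol\tmode\tchromosome\tphenocopy",
    paste(panel$symbol, panel$mode, panel$chromosome,
          if_else(panel$phenocopy, "true", "false"), sep = "\t")
  ), con, sep = "\n")
  invisible(path)
}

#' Inheritance mode(s) of a panel gene
#'
#' @param panel an `fsgs_panel` tibble.
#' @param symbol gene symbol (case-insensitive).
#' @return character vector of declared modes (length one for ordinary
#'   genes, two for dual-inheritance entries). Absence from the panel is an
#'   error of class `fsgs_lookup_error`; prioritization callers treat that
#'   as "gene not screened", not as a crash.
#' @export
#' @examples
#' mode_of(default_panel(), "LMX1B")
mode_of <- function(panel, symbol) {
  stopifnot(inherits(panel, "fsgs_panel"), length(symbol) == 1)
  hits <- panel$mode[panel$symbol == toupper(symbol)]
  if (length(hits) == 0) {
    stop_fsgs(paste0("gene ", toupper(symbol), " is not on panel '",
                     attr(panel, "panel_name"), "'"),
              "fsgs_lookup_error")
  }
  unique(hits)
}

#' @export
print.fsgs_panel <- function(x, ...) {
  cat("<fsgs_panel> ", attr(x, "panel_name"), " v", attr(x, "panel_version"),
      ": ", length(unique(x$symbol)), " genes (",
      sum(x$mode == "AD"), " AD, ", sum(x$mode == "AR"), " AR, ",
      sum(x$mode == "XL"), " XL)\n", sep = "")
  NextMethod()
}
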