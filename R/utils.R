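# shared small helpers

#' Round half away from zero
#'
#' Commercial ("round half up") rounding used for all reported percentages,
#' as opposed to the banker's rounding of [base::round()]. Operates on the
#' absolute value so -0.05 rounds to -0.1.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(11.35, 1)  # 11.4, where round() would give 11.3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# percentage on the 0-100 scale, one decimal by convention
as_pct <- function(x, digits = 1) round_half_up(100 * x, digits)

# normalize contig names to the "chr" prefixed spelling
normalize_contig <- function(x) {
  x <- as.character(x)
  if_else(stringr::str_starts(x, "chr"), x, paste0("chr", x))
}

# contig sort rank: chr1..chr22, chrX, chrY, then everything else
contig_rank <- function(x) {
  core <- stringr::str_remove(normalize_contig(x), "^chr")
  num <- suppressWarnings(as.integer(core))
  case_when(
    !is.na(num) ~ num,
    core == "X" ~ 23L,
    core == "Y" ~ 24L,
    core %in% c("M", "MT") ~ 25L,
    TRUE ~ 26L
  )
}

# stop with a classed condition so callers can handle specific failures
stop_fsgs <- function(message, class) {
  abort(message, class = c(class, "fsgsprio_error"))
}
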