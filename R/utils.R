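# Shared helpers: rounding conventions, interval arithmetic, random sequence.

#' Round half away from zero
#'
#' Percentages in all reports are rounded to a fixed number of decimals with
#' ties going away from zero (so 79.495 -> 79.50), the convention that
#' reproduces printed two-decimal percentages from their exact ratios.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Two-decimal percentage of a ratio
#'
#' @param num,den numerator and denominator.
#' @param digits decimal places (default 2).
#' @return numeric percentage.
#' @export
pct <- function(num, den, digits = 2) {
  round_half_away(100 * num / den, digits)
}

#' Percent change between two values
#'
#' @param from,to old and new value.
#' @param digits decimal places (default 2).
#' @return numeric percentage change.
#' @export
pct_change <- function(from, to, digits = 2) {
  round_half_away(100 * (to - from) / from, digits)
}

# tibble(start, end) -> IRanges
iranges_of <- function(df) {
  if (nrow(df) == 0) return(IRanges::IRanges())
  IRanges::IRanges(start = df$start, end = df$end)
}

# IRanges -> tibble(start, end)
tbl_of_iranges <- function(ir) {
  tibble(start = IRanges::start(ir), end = IRanges::end(ir))
}

# Per-scaffold reduced interval list from a tibble(scaffold, start, end).
split_iranges <- function(df) {
  if (nrow(df) == 0) return(list())
  lapply(split(df, df$scaffold), iranges_of)
}

# Total overlap width between two tibbles of (scaffold, start, end)
overlap_bases <- function(a, b) {
  la <- split_iranges(a)
  lb <- split_iranges(b)
  tot <- 0
  for (s in intersect(names(la), names(lb))) {
    tot <- tot + sum(IRanges::width(IRanges::intersect(
      IRanges::reduce(la[[s]]), IRanges::reduce(lb[[s]])
    )))
  }
  tot
}

DNA_RAW <- charToRaw("ACGT")

#' Random DNA sequence
#'
#' Uniform A/C/G/T string, used by the simulator.
#'
#' @param n length in nucleotides.
#' @return a single character string.
#' @export
random_dna <- function(n) {
  rawToChar(DNA_RAW[sample.int(4L, n, replace = TRUE)])
}

# Reverse complement of a plain character string (case-insensitive, keeps N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# First position at which two equal-length raw vectors differ; 0 if identical.
first_mismatch <- function(a, b) {
  d <- which(a != b)
  if (length(d) == 0) 0L else d[1]
}

assert_assembly <- function(x, arg = "assembly") {
  if (!is.data.frame(x) || !all(c("scaffold", "sequence") %in% names(x))) {
    stop(sprintf("`%s` must be a tibble with columns `scaffold` and `sequence`", arg),
         call. = FALSE)
  }
  invisible(x)
}

scaffold_lengths <- function(assembly) {
  tibble(scaffold = assembly$scaffold, length = nchar(assembly$sequence))
}
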