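#' @useDynLib troykascan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 0-based half-open substring; start/end in [0, nchar(x)]
subseq0 <- function(x, start, end) {
  stopifnot(start >= 0, end >= start)
  substr(x, start + 1, end)
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over the alphabet ACGTN.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# uniform random DNA at a given GC fraction, as a single string
random_dna <- function(n, gc_fraction = 0.41) {
  if (n <= 0) return("")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# split a string into a character vector of single characters
chars <- function(x) strsplit(x, NULL, fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw n integers uniformly from an inclusive range (safe for 1-point ranges,
# unlike sample())
draw_int <- function(range, n = 1L) {
  vals <- seq(range[1], range[length(range)])
  vals[sample.int(length(vals), n, replace = TRUE)]
}
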