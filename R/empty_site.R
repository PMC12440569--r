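# Pre-insertion allele reconstruction and orthologous-locus validation.

#' Reconstruct the pre-insertion allele of an occupied locus
#'
#' The entire element plus exactly one TSD copy -- the downstream one -- is
#' removed and the flanks are joined; when the two TSD copies match exactly
#' the resulting allele is identical whichever copy is removed. The retained
#' upstream copy is recorded as \code{tsd_seq}.
#'
#' @param genome genome_set.
#' @param contig_id contig of the element.
#' @param element_interval length-2 integer vector, 0-based half-open.
#' @param tsd_len TSD length (bp).
#' @param flank_len flank length retained on each side (default 500 bp;
#'   shrunk with a warning when the contig ends earlier).
#' @return an \code{insertion_locus}: list with left_flank, right_flank,
#'   tsd_seq, preinserted_seq (= left_flank + tsd_seq + right_flank),
#'   tsd_mismatch flag, coordinates, and placeholders for the sibling
#'   verdict.
#' @export
reconstruct_preinsertion <- function(genome, contig_id, element_interval,
                                     tsd_len, flank_len = 500L) {
  seq <- unclass(genome)[[contig_id]]
  s <- element_interval[1]; e <- element_interval[2]
  stopifnot(s >= 0, e > s, e <= nchar(seq))
  lf0 <- max(0L, s - tsd_len - flank_len)
  rf1 <- min(nchar(seq), e + tsd_len + flank_len)
  if (s - tsd_len - flank_len < 0 || e + tsd_len + flank_len > nchar(seq))
    warning("reconstruct_preinsertion: flank shrunk at contig boundary")
  left_flank <- subseq0(seq, lf0, s - tsd_len)
  tsd <- subseq0(seq, s - tsd_len, s)
  tsd_down <- subseq0(seq, e, min(e + tsd_len, nchar(seq)))
  mism <- sum(chars(tsd) != chars(tsd_down))
  if (mism > 1)
    warning("reconstruct_preinsertion: TSD copies disagree at ", mism,
            " positions")
  right_flank <- subseq0(seq, e + tsd_len, rf1)
  structure(list(contig_id = contig_id,
                 element_interval = c(s, e),
                 left_flank = left_flank,
                 right_flank = right_flank,
                 tsd_seq = tsd, tsd_len = tsd_len,
                 tsd_mismatch = mism > 0,
                 preinserted_seq = paste0(left_flank, tsd, right_flank),
                 sibling_match = NA_character_,
                 sibling_tsd_check = NA),
            class = "insertion_locus")
}

#' Locate the orthologous locus in a sibling genome
#'
#' The two halves of the pre-insertion allele (left flank + TSD, and right
#' flank) are aligned to the sibling independently. The locus is
#' \code{empty_confirmed} when both align at \code{min_flank_identity} or
#' better and their projected junctions are contiguous (gap of at most 2 bp),
#' \code{occupied} when they align separated by at least an LTR length of
#' intervening sequence, and \code{not_found} otherwise. At an empty locus
#' the junction is additionally checked for exactly one TSD copy.
#'
#' @param locus an \code{insertion_locus}.
#' @param sibling genome_set of the sibling species.
#' @param params \code{\link{pipeline_params}}.
#' @param min_flank_identity minimum flank alignment identity.
#' @param junction_tol maximum junction gap (bp) for an empty call.
#' @return the locus updated with sibling_match, sibling_tsd_check and the
#'   sibling junction coordinates.
#' @export
find_ortholog <- function(locus, sibling, params = pipeline_params(),
                          min_flank_identity = 0.85, junction_tol = 2L) {
  left_q <- paste0(locus$left_flank, locus$tsd_seq)
  right_q <- locus$right_flank
  best_hit <- function(q) {
    h <- scan_repeats(q, sibling, min_identity = min_flank_identity,
                      min_length = max(30L, round(0.5 * nchar(q))),
                      min_seeds = 2L, max_hits = 1L)
    if (nrow(h) == 0) NULL else h[1, ]
  }
  lh <- best_hit(left_q); rh <- best_hit(right_q)
  locus$sibling_match <- "not_found"
  locus$sibling_tsd_check <- FALSE
  if (is.null(lh) || is.null(rh) || lh$contig_id != rh$contig_id ||
      lh$strand != "+" || rh$strand != "+") {
    return(locus)
  }
  # project the unaligned query tails so local-alignment end trimming does
  # not perturb the junction estimate
  lres <- align_seqs(left_q, unclass(sibling)[[lh$contig_id]])
  rres <- align_seqs(right_q, unclass(sibling)[[rh$contig_id]])
  left_end <- lres$b_end + (nchar(left_q) - lres$a_end)
  right_start <- rres$b_start - rres$a_start
  gap <- right_start - left_end
  locus$sibling_junction <- c(left_end, right_start)
  if (abs(gap) <= junction_tol) {
    locus$sibling_match <- "empty_confirmed"
    sib <- unclass(sibling)[[lh$contig_id]]
    k <- locus$tsd_len
    junction_tsd <- subseq0(sib, max(0L, left_end - k), left_end)
    locus$sibling_tsd_check <- identical(junction_tsd, locus$tsd_seq)
  } else if (gap >= params$ltr_min_len) {
    locus$sibling_match <- "occupied"
  }
  locus
}

#' Confirm a TSD from an occupied locus and its empty ortholog
#'
#' The duplicated k-mer is scanned longest-first (k from \code{tsd_max} down
#' to \code{tsd_min}): the suffix of the upstream flank must equal the prefix
#' of the downstream flank (the two element-flanking copies), and, when the
#' empty allele is supplied with its junction position, that k-mer must be
#' present exactly once across the junction. Longest-first scanning prefers a
#' 4 bp duplication over a 3-mer nested inside it.
#'
#' @param left_flank sequence immediately upstream of the element (its suffix
#'   is the upstream TSD copy).
#' @param right_flank sequence immediately downstream of the element.
#' @param empty_seq optional empty-allele sequence.
#' @param empty_junction 0-based position of the insertion point in
#'   \code{empty_seq} (the base count to the left of the junction, including
#'   the single TSD copy).
#' @param params \code{\link{pipeline_params}}.
#' @return list(tsd_seq, tsd_len), or NULL when no k qualifies.
#' @export
confirm_tsd <- function(left_flank, right_flank, empty_seq = NULL,
                        empty_junction = NULL, params = pipeline_params()) {
  nl <- nchar(left_flank)
  for (k in seq(params$tsd_max, params$tsd_min)) {
    if (nl < k || nchar(right_flank) < k) next
    cand <- subseq0(left_flank, nl - k, nl)
    if (cand != subseq0(right_flank, 0, k)) next
    if (!is.null(empty_seq) && !is.null(empty_junction)) {
      # exactly one copy across the junction window of the empty allele
      win <- subseq0(empty_seq, max(0L, empty_junction - 2L * k),
                     min(nchar(empty_seq), empty_junction + k))
      n_occ <- length(gregexpr(cand, win, fixed = TRUE)[[1]])
      if (attr(regexpr(cand, win, fixed = TRUE), "match.length") < 0 ||
          n_occ != 1) next
    }
    return(list(tsd_seq = cand, tsd_len = k))
  }
  NULL
}
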