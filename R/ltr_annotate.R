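# LTR pair detection and joint boundary/TSD calling.

# Hamming distance between two 5-mers
hamming5 <- function(a, b) sum(chars(a) != chars(b))

#' Find candidate LTR pairs in a sequence
#'
#' Exact 11-mer seeds restricted to the outer 45% windows at each end are
#' grouped by diagonal and each group is refined by a banded local alignment,
#' yielding maximal near-identical repeat pairs. Candidates must reach
#' \code{ltr_min_identity} and have lengths in
#' [\code{ltr_min_len}, \code{ltr_max_len}] (a few bases of slack are allowed
#' at the top end for stochastic alignment end-extension). Candidates are
#' sorted by identity x length, best first.
#'
#' @param sequence DNA string (an elongated consensus or a genomic locus with
#'   flanks); must be at least twice \code{ltr_min_len} long.
#' @param params \code{\link{pipeline_params}}.
#' @return data.frame with 0-based half-open intervals start5, end5, start3,
#'   end3 plus identity; zero rows when no admissible pair exists.
#' @export
find_ltr_pair <- function(sequence, params = pipeline_params()) {
  L <- nchar(sequence)
  empty <- data.frame(start5 = integer(), end5 = integer(),
                      start3 = integer(), end3 = integer(),
                      identity = numeric())
  if (L < 2 * params$ltr_min_len) return(empty)
  w <- floor(0.45 * L)
  s5 <- subseq0(sequence, 0, w)
  off3 <- L - w
  s3 <- subseq0(sequence, off3, L)
  seeds <- seed_hits(s5, s3, 11L)
  if (nrow(seeds) == 0) return(empty)
  d <- seeds[, 2] - seeds[, 1]
  ord <- order(d)
  seeds <- seeds[ord, , drop = FALSE]; d <- d[ord]
  grp <- cumsum(c(1L, diff(d) > 15L))
  cand <- list()
  for (g in order(-tabulate(grp))[seq_len(min(5, max(grp)))]) {
    sel <- grp == g
    a_rng <- range(seeds[sel, 1]); b_rng <- range(seeds[sel, 2])
    a0 <- max(0L, a_rng[1] - 30L); a1 <- min(w, a_rng[2] + 11L + 30L)
    b0 <- max(0L, b_rng[1] - 30L); b1 <- min(w, b_rng[2] + 11L + 30L)
    seg5 <- subseq0(s5, a0, a1); seg3 <- subseq0(s3, b0, b1)
    dr <- range(d[sel]) - (b0 - a0)
    res <- align_seqs(seg5, seg3, band = c(dr[1] - 25L, dr[2] + 25L))
    if (is.null(res)) next
    len5 <- res$a_end - res$a_start
    len3 <- res$b_end - res$b_start
    if (min(len5, len3) < params$ltr_min_len) next
    if (min(len5, len3) > params$ltr_max_len + 5L) next
    if (res$identity < params$ltr_min_identity) next
    cand[[length(cand) + 1]] <- data.frame(
      start5 = a0 + res$a_start, end5 = a0 + res$a_end,
      start3 = off3 + b0 + res$b_start, end3 = off3 + b0 + res$b_end,
      identity = res$identity)
  }
  if (length(cand) == 0) return(empty)
  out <- do.call(rbind, cand)
  # drop duplicate discoveries of the same repeat pair
  out <- out[!duplicated(out[, c("start5", "start3")]), , drop = FALSE]
  score <- out$identity * (out$end5 - out$start5)
  out <- out[order(-score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refine element boundaries jointly with TSD evidence
#'
#' Starting from an LTR-pair candidate, the outer boundaries are moved over
#' all offsets within \code{boundary_window} and each placement is scored:
#' the exact-match TSD length at the implied junctions (admissible lengths
#' \code{tsd_min}..\code{tsd_max}), plus \code{pentamer_bonus} when the
#' implied termini match the reference pentamer pair (the canonical
#' CGCCA...TGGCG by default; a family's own reconstructed termini when
#' re-annotating its copies, optionally tolerating mutations accumulated
#' after insertion via \code{pentamer_mismatch_tol}), plus
#' \code{dinucleotide_bonus} when the terminal dinucleotides match either
#' superfamily signature (CG...CG or canonical TG...CA), minus
#' \code{offset_penalty} per base moved from the candidate. The best-scoring
#' placement wins; ties break toward the longest TSD, then leftmost. When no
#' placement shows a TSD or a terminal motif, the element is reported with
#' \code{tsd_len = NA} and superfamily "unclassified".
#'
#' @param sequence DNA string with flanks around the candidate.
#' @param cand one row of \code{\link{find_ltr_pair}} output.
#' @param params \code{\link{pipeline_params}}.
#' @param family_id name recorded in the model.
#' @param ref_pentamer5,ref_pentamer3 reference termini earning
#'   \code{pentamer_bonus}.
#' @param pentamer_mismatch_tol maximum per-terminus Hamming distance to the
#'   reference that still earns the bonus.
#' @return an \code{ltr_element} model: list with intervals ltr5, internal,
#'   ltr3 (0-based half-open, adjacent), ltr_identity, tsd_len, tsd5_seq,
#'   tsd3_seq, pentamer5, pentamer3, superfamily_call, anomalies.
#' @export
call_boundaries <- function(sequence, cand, params = pipeline_params(),
                            family_id = "fam",
                            ref_pentamer5 = "CGCCA", ref_pentamer3 = "TGGCG",
                            pentamer_mismatch_tol = 0L) {
  L <- nchar(sequence)
  W <- params$boundary_window
  s0 <- as.integer(cand$start5); e0 <- as.integer(cand$end3)
  dLs <- seq(-W, W); dRs <- seq(-W, W)
  best <- NULL
  for (dL in dLs) {
    s <- s0 + dL
    if (s < 0 || s + 5 > L) next
    left_suf <- lapply(params$tsd_min:params$tsd_max, function(k)
      if (s - k >= 0) subseq0(sequence, s - k, s) else NA_character_)
    pent5 <- subseq0(sequence, s, s + 5)
    for (dR in dRs) {
      e <- e0 + dR
      if (e > L || e - 5 < 0 || e <= s) next
      m <- 0L
      for (ki in rev(seq_along(left_suf))) {       # longest exact match first
        k <- (params$tsd_min:params$tsd_max)[ki]
        if (e + k <= L && !is.na(left_suf[[ki]]) &&
            left_suf[[ki]] == subseq0(sequence, e, e + k)) { m <- k; break }
      }
      pent3 <- subseq0(sequence, e - 5, e)
      pent_ok <- hamming5(pent5, ref_pentamer5) <= pentamer_mismatch_tol &&
        hamming5(pent3, ref_pentamer3) <= pentamer_mismatch_tol
      d5 <- substr(pent5, 1, 2); d3 <- substr(pent3, 4, 5)
      dinuc_ok <- (d5 == "TG" && d3 == "CA") || (d5 == "CG" && d3 == "CG")
      score <- m + params$pentamer_bonus * pent_ok +
        params$dinucleotide_bonus * dinuc_ok -
        params$offset_penalty * (abs(dL) + abs(dR))
      if (is.null(best) || score > best$score + 1e-9 ||
          (abs(score - best$score) <= 1e-9 &&
           (m > best$m ||
            (m == best$m && (s < best$s || (s == best$s && e < best$e)))))) {
        best <- list(score = score, m = m, s = s, e = e, dL = dL, dR = dR,
                     pent5 = pent5, pent3 = pent3,
                     motif = pent_ok || dinuc_ok)
      }
    }
  }
  no_evidence <- is.null(best) || (best$m < params$tsd_min && !best$motif)
  if (no_evidence) best <- list(score = 0, m = 0L, s = s0, e = e0, dL = 0L,
                                dR = 0L,
                                pent5 = subseq0(sequence, s0, min(L, s0 + 5)),
                                pent3 = subseq0(sequence, max(0, e0 - 5), e0))
  s <- best$s; e <- best$e
  # inner edges follow the repeat correspondence: the refined outer 5' start
  # is the LTR start, so the inner 3' start moves with dL; the refined outer
  # 3' end is the LTR end, so the inner 5' end moves with dR (this also
  # undoes chance end-extension of the candidate alignment on either side)
  end5 <- as.integer(cand$end5 + best$dR)
  start3 <- as.integer(cand$start3 + best$dL)
  len5 <- end5 - s; len3 <- e - start3
  if (len5 - len3 > 2) end5 <- as.integer(end5 - (len5 - len3 - 2L))
  if (len3 - len5 > 2) start3 <- as.integer(start3 + (len3 - len5 - 2L))
  s <- as.integer(s); e <- as.integer(e)
  tsd_len <- if (best$m >= params$tsd_min) best$m else NA_integer_
  tsd5 <- if (!is.na(tsd_len)) subseq0(sequence, s - tsd_len, s) else NA_character_
  tsd3 <- if (!is.na(tsd_len)) subseq0(sequence, e, e + tsd_len) else NA_character_
  cls <- if (no_evidence)
    list(superfamily = "unclassified", anomalies = character(0))
  else call_superfamily(best$pent5, best$pent3, tsd_len, params)
  structure(list(family_id = family_id,
                 ltr5 = c(s, end5),
                 internal = c(end5, start3),
                 ltr3 = c(start3, e),
                 ltr_identity = cand$identity,
                 tsd_len = tsd_len, tsd5_seq = tsd5, tsd3_seq = tsd3,
                 pentamer5 = best$pent5, pentamer3 = best$pent3,
                 superfamily_call = cls$superfamily,
                 anomalies = cls$anomalies),
            class = "ltr_element")
}

#' Split an element into Repbase-style LTR and internal records
#'
#' @param model an \code{ltr_element}.
#' @param sequence the DNA string the model's intervals refer to.
#' @param min_internal internal lengths below this are flagged sub-minimum
#'   (candidate non-autonomous elements).
#' @return list with \code{ltr} and \code{internal} named sequences plus
#'   \code{sub_minimum_internal}; concatenating LTR + internal + LTR
#'   reconstructs the element when the two LTR copies are identical.
#' @export
split_repbase_parts <- function(model, sequence, min_internal = 1553L) {
  ltr <- subseq0(sequence, model$ltr5[1], model$ltr5[2])
  internal <- subseq0(sequence, model$internal[1], model$internal[2])
  list(ltr = stats::setNames(ltr, paste0(model$family_id, "-LTR")),
       internal = stats::setNames(internal, paste0(model$family_id, "-I")),
       sub_minimum_internal = nchar(internal) < min_internal)
}

#' Annotate one genomic locus
#'
#' Extracts a hit region with flanks, finds the best LTR pair and calls
#' boundaries with TSD evidence, then maps the model back to contig
#' coordinates.
#'
#' @param genome genome_set.
#' @param hit one hit-table row (plus strand).
#' @param params \code{\link{pipeline_params}}.
#' @param flank flanking bases used for TSD/boundary evidence.
#' @param ... passed on to \code{\link{call_boundaries}} (family-specific
#'   reference termini and mismatch tolerance).
#' @return an \code{ltr_element} with element interval in contig coordinates
#'   (fields \code{contig_id}, \code{start}, \code{end}), or NULL when no
#'   admissible LTR pair is found.
#' @export
annotate_locus <- function(genome, hit, params = pipeline_params(),
                           flank = 100L, ...) {
  contig <- unclass(genome)[[hit$contig_id]]
  a <- max(0L, hit$start - flank)
  b <- min(nchar(contig), hit$end + flank)
  region <- subseq0(contig, a, b)
  cands <- find_ltr_pair(region, params)
  if (nrow(cands) == 0) return(NULL)
  model <- call_boundaries(region, cands[1, ], params,
                           family_id = hit$query_id, ...)
  model$contig_id <- hit$contig_id
  model$start <- a + model$ltr5[1]
  model$end <- a + model$ltr3[2]
  model
}
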