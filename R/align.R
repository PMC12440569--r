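# Seed-and-extend banded alignment: the workhorse behind copy linking,
# consensus stacking, genome scanning and ortholog search. Exact k-mer seeds
# locate the dominant diagonal(s); a banded local (Smith-Waterman) alignment
# with linear gap penalty refines each. Match +1 / mismatch -2 / gap -3, so
# regions below ~2/3 identity score negative on average and the local
# alignment stops sharply at homology boundaries (random sequence drifts at
# -1.25/base, so chance end-extension is a couple of bases at most).

# Seeds between two strings as a 2-column 0-based matrix (apos, bpos).
seed_hits <- function(a, b, k = 13L) {
  kmer_seeds_cpp(a, b, as.integer(k))
}

# Given sorted diagonal values, find the window of width `width` holding the
# most seeds. Returns c(lo, hi, count) or NULL.
dominant_window <- function(d, width = 40L) {
  if (length(d) == 0) return(NULL)
  d <- sort(d)
  hi_idx <- findInterval(d + width, d)
  cnt <- hi_idx - seq_along(d) + 1L
  i <- which.max(cnt)
  c(lo = d[i], hi = min(d[i] + width, d[hi_idx[i]]), count = cnt[i])
}

# Banded local alignment of a vs b around the dominant seed diagonal.
# Returns NULL when the two sequences share no k-mer seed. The result carries
# 0-based half-open aligned ranges, identity over alignment columns, and the
# per-position projection of `a` onto `b`.
align_seqs <- function(a, b, k = 13L, pad = 40L,
                       match = 1, mismatch = -2, gap = -3,
                       band = NULL) {
  if (is.null(band)) {
    s <- seed_hits(a, b, k)
    if (nrow(s) == 0) return(NULL)
    w <- dominant_window(s[, 2] - s[, 1], width = pad)
    band <- c(w[["lo"]] - pad, w[["hi"]] + pad)
  }
  res <- band_align_cpp(a, b, as.integer(band[1]), as.integer(band[2]),
                        match, mismatch, gap)
  if (res$n_cols == 0) return(NULL)
  res$identity <- res$n_match / res$n_cols
  res
}

#' Scan a genome for copies of a query sequence
#'
#' A seed-and-extend scanner: exact 13-mer seeds between the query and each
#' contig are grouped into diagonal windows, and each window is refined by a
#' banded local alignment. Both strands are searched; minus-strand hits are
#' reported in plus-strand coordinates. This fills the role an external
#' homology search tool (Censor/BLAST) plays when real genomes are screened;
#' hit tables from such tools can equally be imported with
#' \code{\link{read_hit_table}}.
#'
#' @param query DNA string.
#' @param genome named character vector of contigs (e.g. from
#'   \code{\link{read_fasta}}).
#' @param min_identity minimum alignment identity to report.
#' @param min_length minimum hit length (bp).
#' @param min_seeds minimum seeds in a diagonal window to attempt extension.
#' @param max_hits maximum number of hits returned (best first).
#' @param both_strands search the reverse complement as well.
#' @param query_id query name recorded in the hit table.
#' @return a hit-table data.frame (possibly empty), sorted by alignment score.
#' @export
scan_repeats <- function(query, genome, min_identity = 0.7,
                         min_length = 50L, min_seeds = 4L,
                         max_hits = Inf, both_strands = TRUE,
                         query_id = "query") {
  hits <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (contig in names(genome)) {
    seq <- unclass(genome)[[contig]]
    for (strand in strands) {
      q <- if (strand == "+") query else revcomp(query)
      s <- seed_hits(q, seq, 13L)
      if (nrow(s) == 0) next
      d <- s[, 2] - s[, 1]
      remaining <- rep(TRUE, nrow(s))
      for (iter in seq_len(200)) {
        if (!any(remaining)) break
        w <- dominant_window(d[remaining], width = 60L)
        if (is.null(w) || w[["count"]] < min_seeds) break
        band <- c(w[["lo"]] - 60L, w[["hi"]] + 60L)
        res <- align_seqs(q, seq, band = band)
        drop <- remaining & d >= band[1] & d <= band[2]
        if (!is.null(res) && res$n_cols >= min_length &&
            res$identity >= min_identity) {
          hits[[length(hits) + 1]] <- data.frame(
            hit_id = NA_character_, query_id = query_id, contig_id = contig,
            start = res$b_start, end = res$b_end, strand = strand,
            identity_pct = round(100 * res$identity, 2),
            score = res$score, stringsAsFactors = FALSE)
          drop <- drop | (remaining & s[, 2] >= res$b_start &
                            s[, 2] < res$b_end)
        }
        if (!any(drop)) break
        remaining <- remaining & !drop
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(hit_id = character(), query_id = character(),
                      contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity_pct = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(-out$score, out$contig_id, out$start), , drop = FALSE]
  # overlapping hits on the same contig: keep the best-scoring one
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      for (j in seq(i + 1L, nrow(out))) {
        if (!keep[j] || out$contig_id[j] != out$contig_id[i]) next
        ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j])
        if (ov > 0.5 * (out$end[j] - out$start[j])) keep[j] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  if (nrow(out) > max_hits) out <- out[seq_len(max_hits), , drop = FALSE]
  out$hit_id <- sprintf("%s_h%03d", query_id, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# Extract the sequence of a hit (reverse-complemented for minus strand),
# optionally with flanks clipped at contig boundaries.
hit_sequence <- function(hit, genome, flank = 0L) {
  seq <- unclass(genome)[[hit$contig_id]]
  s <- max(0L, hit$start - flank)
  e <- min(nchar(seq), hit$end + flank)
  x <- subseq0(seq, s, e)
  if (hit$strand == "-") x <- revcomp(x)
  x
}
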