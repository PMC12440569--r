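# Terminal pentamer classification, superfamily calling, zinc-finger motif
# scanning and recent-activity screening.

#' Classify a terminal pentamer against its reference
#'
#' Position-by-position comparison against the reference terminus (CGCCA for
#' 5' ends, TGGCG for 3' ends). A pentamer is canonical with zero
#' substitutions, a single transition (A<->G, C<->T) or single transversion
#' with exactly one, and multi with two or more; any N makes it ambiguous.
#' Positions are labelled +1..+5 left-to-right at the 5' end and -5..-1 at
#' the 3' end (-1 the terminal base), so the relaxed positions of the 3'
#' terminus TGGCG -- its two central G's -- are -4 and -3.
#'
#' @param observed,reference 5-mers.
#' @param end "five" or "three"; controls the position labels.
#' @return list with class ("canonical", "transition", "transversion",
#'   "multi" or "ambiguous"), integer positions (labelled), and kinds
#'   ("transition"/"transversion" per substitution).
#' @export
classify_pentamer <- function(observed, reference, end = c("five", "three")) {
  end <- match.arg(end)
  if (nchar(observed) != 5 || nchar(reference) != 5)
    stop("classify_pentamer: pentamers must have length 5", call. = FALSE)
  if (grepl("[^ACGT]", observed))
    return(list(class = "ambiguous", positions = integer(0),
                kinds = character(0)))
  o <- chars(observed); r <- chars(reference)
  pos <- which(o != r)
  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  kinds <- vapply(pos, function(i)
    if (is_transition(o[i], r[i])) "transition" else "transversion", "")
  cls <- if (length(pos) == 0) "canonical"
  else if (length(pos) == 1) kinds
  else "multi"
  labels <- if (end == "five") pos else pos - 6L
  list(class = cls, positions = as.integer(labels), kinds = kinds)
}

#' Tally terminal signatures over a set of LTRs
#'
#' @param records data.frame with columns entry_id, pentamer5, pentamer3.
#' @param ref5,ref3 reference termini.
#' @return list with pentamer counts, class counts and substituted-position
#'   counts per end, and the 3'-end positional concentration statistic in
#'   both interpretations: \code{concentration3_events} counts substitution
#'   events at positions -4/-3 over all 3' substitution events, and
#'   \code{concentration3_ltrs} counts variant LTRs whose substitutions are
#'   confined to -4/-3 over all variant 3' LTRs.
#' @export
tally_signatures <- function(records, ref5 = "CGCCA", ref3 = "TGGCG") {
  stopifnot(nrow(records) >= 1)
  cl5 <- lapply(records$pentamer5, classify_pentamer, reference = ref5,
                end = "five")
  cl3 <- lapply(records$pentamer3, classify_pentamer, reference = ref3,
                end = "three")
  class_table <- function(cl) {
    lv <- c("canonical", "transition", "transversion", "multi", "ambiguous")
    table(factor(vapply(cl, `[[`, "", "class"), levels = lv))
  }
  pos_table <- function(cl, levels) {
    table(factor(unlist(lapply(cl, `[[`, "positions")), levels = levels))
  }
  pos3 <- pos_table(cl3, levels = -5:-1)
  ev3 <- sum(pos3)
  conf3 <- vapply(cl3, function(x)
    length(x$positions) > 0 && all(x$positions %in% c(-4L, -3L)), NA)
  variant3 <- vapply(cl3, function(x) x$class != "canonical", NA)
  list(pentamer5 = sort(table(records$pentamer5), decreasing = TRUE),
       pentamer3 = sort(table(records$pentamer3), decreasing = TRUE),
       class5 = class_table(cl5),
       class3 = class_table(cl3),
       positions5 = pos_table(cl5, levels = 1:5),
       positions3 = pos3,
       concentration3_events =
         c(n_focal = unname(pos3[["-4"]] + pos3[["-3"]]), n_total = ev3),
       concentration3_ltrs =
         c(n_focal = sum(conf3), n_total = sum(variant3)))
}

#' Call the superfamily from terminal signatures and TSD length
#'
#' The classifier works at dinucleotide level: Troyka elements start and end
#' their LTRs with 5'-CG...CG-3' and generate 3 bp TSDs, while canonical LTR
#' retrotransposons terminate 5'-TG...CA-3' with 4-6 bp TSDs. Partial
#' matches (right termini with the wrong TSD length) keep the terminus-based
#' class and carry an anomaly flag.
#'
#' @param pentamer5,pentamer3 terminal 5-mers.
#' @param tsd_len integer TSD length or NA.
#' @param params \code{\link{pipeline_params}}.
#' @return list with superfamily ("troyka", "canonical_ltr", "unclassified")
#'   and a character vector of anomaly flags.
#' @export
call_superfamily <- function(pentamer5, pentamer3, tsd_len,
                             params = pipeline_params()) {
  stopifnot(nchar(pentamer5) == 5, nchar(pentamer3) == 5)
  d5 <- substr(pentamer5, 1, 2); d3 <- substr(pentamer3, 4, 5)
  troyka_termini <- d5 == "CG" && d3 == "CG"
  canon_termini <- d5 == "TG" && d3 == "CA"
  tsd3 <- !is.na(tsd_len) && tsd_len == 3
  tsd46 <- !is.na(tsd_len) && tsd_len >= 4 && tsd_len <= 6
  anomalies <- character(0)
  if (troyka_termini) {
    if (!tsd3) anomalies <- "tsd_length"
    return(list(superfamily = "troyka", anomalies = anomalies))
  }
  if (canon_termini) {
    if (!tsd46) anomalies <- "tsd_length"
    return(list(superfamily = "canonical_ltr", anomalies = anomalies))
  }
  list(superfamily = "unclassified", anomalies = "termini")
}

#' Scan a protein for Gag-type CCHC zinc-finger motifs
#'
#' Reports all matches, overlapping ones included, of the Troyka Gag knuckle
#' C-x(2)-C-x(8,10)-H-x(4)-C and the retroviral-type knuckle
#' C-x(2)-C-x(4)-H-x(4)-C. X in the protein is a wildcard and matches any
#' pattern position.
#'
#' @param protein amino-acid string (20-letter alphabet plus X).
#' @param protein_id id recorded in the hits.
#' @return data.frame with protein_id, pattern ("troyka_zf"/"retroviral_zf"),
#'   0-based start, and the matched span.
#' @export
scan_zinc_finger <- function(protein, protein_id = "protein") {
  hits <- list()
  spacers <- list(troyka_zf = 8:10, retroviral_zf = 4)
  for (pat in names(spacers)) {
    for (sp in spacers[[pat]]) {
      rx <- sprintf("(?=([CX].{2}[CX].{%d}[HX].{4}[CX]))", sp)
      m <- gregexpr(rx, protein, perl = TRUE)[[1]]
      if (m[1] == -1) next
      starts <- attr(m, "capture.start")[, 1]
      lens <- attr(m, "capture.length")[, 1]
      hits[[length(hits) + 1]] <- data.frame(
        protein_id = protein_id, pattern = pat, start = starts - 1L,
        matched_span = substring(protein, starts, starts + lens - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(protein_id = character(), pattern = character(),
                      start = integer(), matched_span = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen a family for recent transposition activity
#'
#' Mean per-copy alignment identity against the consensus; families whose
#' mean identity is strictly greater than
#' \code{recent_identity_threshold} (99.9% by default) are flagged as
#' recently active.
#'
#' @param consensus consensus DNA string (or consensus model).
#' @param copies character vector of copy sequences (at least 2).
#' @param params \code{\link{pipeline_params}}.
#' @return list with mean_identity, flagged, n_copies and the per-copy
#'   identities.
#' @export
screen_recent_activity <- function(consensus, copies,
                                   params = pipeline_params()) {
  seq <- if (is.list(consensus)) consensus$sequence else consensus
  if (length(copies) < 2)
    stop("screen_recent_activity: at least 2 copies required", call. = FALSE)
  ids <- vapply(copies, function(cp) {
    res <- align_seqs(seq, cp)
    if (is.null(res)) return(0)
    res$identity
  }, 0)
  mean_id <- mean(ids)
  list(mean_identity = mean_id,
       flagged = mean_id > params$recent_identity_threshold,
       n_copies = length(copies),
       identities = unname(ids))
}
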