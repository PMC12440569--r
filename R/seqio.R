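# Sequence and table I/O. All public coordinates in this package are 0-based
# half-open; 1-based coordinates appear only in human-readable reports.

#' Read a FASTA file as a canonicalized genome set
#'
#' Sequences are uppercased and every IUPAC ambiguity code other than N is
#' mapped to N (real assemblies contain them; downstream operations treat N as
#' mismatching everything). The header token before the first whitespace
#' becomes the contig id.
#'
#' @param path FASTA file path.
#' @return a named character vector of sequences (class \code{genome_set})
#'   with attribute \code{n_canonicalized}, the number of residues that were
#'   mapped to N.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0)
    stop("FASTA format error: no records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("FASTA format error: duplicate contig id '", dup[1], "' in ", path,
         call. = FALSE)
  seqs <- toupper(as.character(set))
  canon <- gsub("[^ACGTN]", "N", seqs)
  n_events <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  names(canon) <- ids
  structure(canon, class = "genome_set", n_canonicalized = n_events)
}

#' Write a genome set as wrapped FASTA
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param wrap line width (default 60).
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(length(records) > 0, !is.null(names(records)))
  set <- Biostrings::DNAStringSet(unclass(records))
  Biostrings::writeXStringSet(set, path, width = wrap)
  invisible(path)
}

hit_table_cols <- c("hit_id", "query_id", "contig_id", "start", "end",
                    "strand", "identity_pct")

#' Read a repeat hit table
#'
#' Hits are 7-column TSV with a header row: hit_id, query_id, contig_id,
#' start, end, strand, identity_pct. Coordinates are 0-based half-open;
#' minus-strand hits are stored in plus-strand coordinates.
#'
#' @param path TSV path.
#' @return data.frame of repeat hits.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "integer", "integer", "character",
                                         "numeric"))
  if (!identical(names(df), hit_table_cols))
    stop("hit table format error: expected columns ",
         paste(hit_table_cols, collapse = ", "), call. = FALSE)
  validate_hits(df, line_offset = 1L)
  df
}

validate_hits <- function(df, line_offset = 0L) {
  bad <- which(!(df$start >= 0 & df$end > df$start) |
                 !(df$strand %in% c("+", "-")) |
                 !(df$identity_pct >= 0 & df$identity_pct <= 100) |
                 is.na(df$start) | is.na(df$end))
  if (length(bad) > 0)
    stop("hit table format error at line ", bad[1] + line_offset,
         ": require 0 <= start < end, strand in {+,-}, identity in [0,100]",
         call. = FALSE)
  invisible(df)
}

#' Write a repeat hit table
#' @param hits data.frame with the hit-table columns.
#' @param path output TSV path.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(hit_table_cols %in% names(hits)))
  validate_hits(hits[hit_table_cols])
  utils::write.table(hits[hit_table_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export annotated elements as BED6
#'
#' One line per element: contig, start, end, name (family), score
#' (identity x 10, capped at 1000), strand.
#'
#' @param elements data.frame with columns contig_id, start, end, family_id,
#'   identity_pct and optionally strand.
#' @param path output path.
#' @export
write_bed <- function(elements, path) {
  strand <- elements$strand %||% rep("+", nrow(elements))
  bed <- data.frame(elements$contig_id, elements$start, elements$end,
                    elements$family_id,
                    pmin(1000L, as.integer(round(elements$identity_pct * 10))),
                    strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pair Repbase-style LTR and internal entries
#'
#' Repbase keeps LTR retrotransposons split into an internal portion
#' (suffix \code{-I}) and an LTR portion (suffix \code{-LTR}) sharing a family
#' stem, e.g. \code{Troyka-1_MagHon-I} / \code{Troyka-1_MagHon-LTR}. Entries
#' with neither suffix are treated as full-length records.
#'
#' @param names character vector of entry names.
#' @return list with \code{pairs} (data.frame: stem, internal, ltr) and
#'   \code{orphans} (data.frame: name, part).
#' @export
pair_repbase_entries <- function(names) {
  stopifnot(is.character(names))
  part <- ifelse(endsWith(names, "-LTR"), "LTR",
                 ifelse(endsWith(names, "-I"), "internal", "full"))
  stem <- names
  stem[part == "LTR"] <- sub("-LTR$", "", stem[part == "LTR"])
  stem[part == "internal"] <- sub("-I$", "", stem[part == "internal"])
  both <- part == "LTR" & endsWith(stem, "-I")
  if (any(both))
    stop("entry name format error: '", names[both][1],
         "' carries both -I and -LTR suffixes", call. = FALSE)
  int_stems <- stem[part == "internal"]
  ltr_stems <- stem[part == "LTR"]
  shared <- sort(intersect(int_stems, ltr_stems))
  pairs <- if (length(shared) > 0)
    data.frame(stem = shared,
               internal = paste0(shared, "-I"),
               ltr = paste0(shared, "-LTR"),
               stringsAsFactors = FALSE)
  else data.frame(stem = character(0), internal = character(0),
                  ltr = character(0), stringsAsFactors = FALSE)
  orphan_idx <- !(part %in% c("internal", "LTR")) | !(stem %in% shared)
  orphans <- data.frame(name = names[orphan_idx], part = part[orphan_idx],
                        stringsAsFactors = FALSE)
  list(pairs = pairs, orphans = orphans)
}
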