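# Family clustering and majority-rule consensus reconstruction.

#' Decide whether two repeat copies belong to the same family
#'
#' Two copies are linked when a local alignment covers at least
#' \code{coverage_threshold} of the shorter sequence (BLASTCLUST's -L
#' semantics) at identity at least \code{identity_threshold}. The relation is
#' symmetric; sequences sharing no 13-mer seed are never linked.
#'
#' @param a,b DNA strings.
#' @param params \code{\link{pipeline_params}}.
#' @return logical.
#' @export
pairwise_link <- function(a, b, params = pipeline_params()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  # align the shorter onto the longer so coverage is measured on the shorter
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  res <- align_seqs(a, b)
  if (is.null(res)) return(FALSE)
  coverage <- (res$a_end - res$a_start) / nchar(a)
  coverage >= params$coverage_threshold &&
    res$identity >= params$identity_threshold
}

#' Cluster repeat copies into families by single linkage
#'
#' Connected components of the \code{\link{pairwise_link}} graph, matching
#' the 75%/75% single-linkage clustering used to define families. Input order
#' does not matter: sequences are canonically ordered before the component
#' search, and clusters are numbered by (size descending, representative id
#' ascending). The representative of a cluster is its longest member.
#'
#' @param seqs named character vector of copy sequences.
#' @param params \code{\link{pipeline_params}}.
#' @return list of clusters, each a list with cluster_id, member_ids,
#'   representative_id.
#' @export
cluster_hits <- function(seqs, params = pipeline_params()) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  ids <- sort(names(seqs))
  seqs <- seqs[ids]
  n <- length(ids)
  # union-find over canonically ordered members
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (find(i) != find(j) &&
            pairwise_link(seqs[[i]], seqs[[j]], params)) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  groups <- split(ids, comp)
  reps <- vapply(groups, function(g) g[which.max(nchar(seqs[g]))], "")
  ord <- order(-lengths(groups), reps)
  groups <- groups[ord]; reps <- reps[ord]
  lapply(seq_along(groups), function(i)
    list(cluster_id = sprintf("cluster%03d", i),
         member_ids = groups[[i]],
         representative_id = reps[[i]]))
}

#' Stack repeat copies onto a reference sequence
#'
#' Star alignment: each copy is locally aligned to the reference and
#' projected onto reference coordinates, giving equal-length gapped rows
#' ('-' = deletion relative to the reference, '.' = outside the aligned
#' region; copy insertions relative to the reference are dropped). The
#' reference itself is row 1.
#'
#' @param reference DNA string.
#' @param copies character vector of copy sequences.
#' @return character vector of gapped rows (reference first), all of
#'   reference length.
#' @export
stack_copies <- function(reference, copies) {
  L <- nchar(reference)
  rows <- c(reference, vapply(copies, function(cp) {
    res <- align_seqs(reference, cp)
    if (is.null(res)) return(strrep(".", L))
    row <- rep(".", L)
    idx <- res$b_for_a
    covered <- seq_len(L) > res$a_start & seq_len(L) <= res$a_end
    cpv <- chars(cp)
    sel <- covered & idx >= 0
    row[sel] <- cpv[idx[sel] + 1L]
    row[covered & idx == -1L] <- "-"
    paste(row, collapse = "")
  }, ""))
  unname(rows)
}

#' Build a 50% majority-rule consensus from aligned copies
#'
#' Per column: the most frequent symbol (gap included) among non-missing rows
#' is emitted if its frequency reaches \code{majority_fraction}; a winning
#' gap drops the column; no majority emits N. A tie at exactly the majority
#' fraction emits the alphabetically first qualifying base and flags the
#' column as ambiguous.
#'
#' @param rows equal-length gapped strings (alphabet ACGTN, '-' gap,
#'   '.' missing).
#' @param params \code{\link{pipeline_params}}.
#' @return a consensus model: list with sequence, column_depth,
#'   ambiguous_columns (indices into the emitted sequence), source_copies,
#'   elongation_rounds.
#' @export
build_consensus <- function(rows, params = pipeline_params()) {
  stopifnot(length(rows) >= 2)
  if (length(unique(nchar(rows))) != 1)
    stop("build_consensus: rows of unequal length", call. = FALSE)
  M <- do.call(rbind, strsplit(rows, NULL, fixed = TRUE))
  syms <- c("A", "C", "G", "T", "N", "-")
  counts <- vapply(syms, function(s) colSums(M == s),
                   numeric(ncol(M)))
  if (ncol(M) == 1) counts <- matrix(counts, nrow = 1,
                                     dimnames = list(NULL, syms))
  depth <- rowSums(counts)                       # non-missing rows per column
  maxc <- apply(counts, 1, max)
  eps <- 1e-9
  emit <- character(ncol(M))
  ambiguous <- logical(ncol(M))
  for (i in seq_len(ncol(M))) {
    if (depth[i] == 0) { emit[i] <- ""; next }
    if (maxc[i] / depth[i] < params$majority_fraction - eps) {
      emit[i] <- "N"; next
    }
    winners <- syms[counts[i, ] == maxc[i]]
    ambiguous[i] <- length(winners) > 1
    bases <- setdiff(winners, "-")
    emit[i] <- if (length(bases) > 0) sort(bases)[1] else ""
  }
  kept <- which(emit != "")
  seq <- paste(emit[kept], collapse = "")
  list(sequence = seq,
       column_depth = as.integer(depth[kept]),
       ambiguous_columns = which(ambiguous[kept]),
       source_copies = length(rows),
       elongation_rounds = 0L)
}

#' Elongate a consensus with flanking sequence until the LTRs are covered
#'
#' Re-locates up to \code{max_copies} best genomic copies of the consensus,
#' extracts each with \code{flank_bp} of flanking sequence on both sides,
#' re-stacks them on the best copy and rebuilds the majority consensus. The
#' extension stops on a side where fewer than 2 copies still align (flanking
#' sequence is locus-specific background, so coverage collapses at the true
#' element boundary), and rounds stop when the consensus no longer grows.
#'
#' @param consensus a consensus model (or DNA string).
#' @param genome genome_set to re-scan.
#' @param params \code{\link{pipeline_params}}.
#' @param max_rounds upper bound on elongation rounds.
#' @return elongated consensus model; also carries \code{hits}, the hit table
#'   of the copies used in the final round.
#' @export
elongate_consensus <- function(consensus, genome, params = pipeline_params(),
                               max_rounds = 3L) {
  seq <- if (is.list(consensus)) consensus$sequence else consensus
  rounds <- if (is.list(consensus)) consensus$elongation_rounds else 0L
  model <- NULL
  for (r in seq_len(max_rounds)) {
    hits <- scan_repeats(seq, genome, min_identity = 0.7,
                         min_length = max(50L, round(0.3 * nchar(seq))))
    if (nrow(hits) < 2)
      stop("cannot elongate: fewer than 2 genomic copies found", call. = FALSE)
    hits <- hits[seq_len(min(nrow(hits), params$max_copies)), , drop = FALSE]
    ext <- vapply(seq_len(nrow(hits)), function(i)
      hit_sequence(hits[i, ], genome, flank = params$flank_bp), "")
    rows <- stack_copies(ext[1], ext[-1])
    # trim each side to columns still covered by >= 2 copies
    depth <- colSums(do.call(rbind, strsplit(rows, NULL, fixed = TRUE)) != ".")
    cov <- which(depth >= 2)
    if (length(cov) == 0)
      stop("cannot elongate: no multi-copy columns", call. = FALSE)
    rows <- substr(rows, min(cov), max(cov))
    model <- build_consensus(rows, params)
    rounds <- rounds + 1L
    model$elongation_rounds <- rounds
    model$hits <- hits
    if (nchar(model$sequence) <= nchar(seq)) { break }
    seq <- model$sequence
  }
  model
}
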