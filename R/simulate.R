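# Synthetic genomes with planted LTR retrotransposons and machine-readable
# ground truth. Every downstream stage of the pipeline is tested against the
# coordinates this module records.

# Default terminal pentamer spectra. Canonical Troyka termini dominate;
# variants and their relative frequencies follow the observed distribution
# over 603 characterized LTRs (573/603 canonical 5' termini, 522/603
# canonical 3' termini).
default_spectrum5 <- c(CGCCA = 573, CACCA = 9, CGTCA = 5, CGCCG = 4,
                       CGCTA = 3, CGCCC = 2, CGCCT = 1, CGCAA = 1,
                       CGGCA = 1, CATCA = 1, CGCTG = 1, CGGCC = 1,
                       CGGTG = 1) / 603
default_spectrum3 <- c(TGGCG = 522, TGTCG = 23, TGACG = 18, TTGCG = 8,
                       TGGTG = 4, TGGCA = 2, TGCCG = 1, TGGCT = 1,
                       TAACG = 19, TGACT = 5) / 603

#' Simulation configuration
#'
#' Parameters of the synthetic-genome generator. Defaults describe the study
#' conditions the pipeline is validated under: LTR lengths uniform in 100-400
#' bp and internal lengths uniform in 1,553-7,691 bp (the observed ranges for
#' the superfamily), 3 bp target site duplications, canonical-dominant
#' terminal pentamer spectra, 5-10 copies per family at 1% per-copy
#' substitutions and 0.1% single-base indels, and a sibling genome diverged
#' at 1% in which half the orthologous loci are empty.
#'
#' @param seed integer; fully determines the output of
#'   \code{\link{simulate_genome}}.
#' @param n_families number of element families planted.
#' @param copies_per_family integer vector of length 1 or 2; a range is drawn
#'   uniformly per family.
#' @param substitution_rate,indel_rate per-base per-copy mutation rates.
#'   Indels are single-base, so ground-truth coordinates stay exact.
#' @param background_length background (insertion-free) genome length.
#' @param gc_fraction background and element GC content.
#' @param tsd_length target-site-duplication length in 3..6.
#' @param tsd_seq optional forced TSD sequence (length \code{tsd_length});
#'   by default the duplicated bases are taken from the background.
#' @param ltr_len_range,internal_len_range template length ranges; override
#'   \code{internal_len_range} below 1553 bp for non-autonomous elements
#'   (minimum 10 bp).
#' @param pentamer5,pentamer3 optional forced terminal pentamers; by default
#'   drawn from \code{spectrum5}/\code{spectrum3}.
#' @param spectrum5,spectrum3 named probability vectors over terminal
#'   pentamers.
#' @param sibling_divergence background substitution rate of the sibling
#'   genome.
#' @param fraction_empty_in_sibling fraction of loci excised (element plus
#'   exactly one TSD copy) in the sibling.
#' @param min_gap minimum distance between insertion points (bp).
#' @param allow_nested permit insertions inside earlier elements (off by
#'   default; loci are analyzed as independent).
#' @return a validated list of class \code{troyka_sim_config}.
#' @export
simulation_config <- function(seed = 1L,
                              n_families = 5L,
                              copies_per_family = c(5L, 10L),
                              substitution_rate = 0.01,
                              indel_rate = 0.001,
                              background_length = 60000L,
                              gc_fraction = 0.41,
                              tsd_length = 3L,
                              tsd_seq = NULL,
                              ltr_len_range = c(100L, 400L),
                              internal_len_range = c(1553L, 7691L),
                              pentamer5 = NULL,
                              pentamer3 = NULL,
                              spectrum5 = default_spectrum5,
                              spectrum3 = default_spectrum3,
                              sibling_divergence = 0.01,
                              fraction_empty_in_sibling = 0.5,
                              min_gap = 1000L,
                              allow_nested = FALSE) {
  cfg <- as.list(environment())
  for (f in c("substitution_rate", "indel_rate", "gc_fraction",
              "sibling_divergence", "fraction_empty_in_sibling")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("simulation config error: `", f, "` must be in [0,1]", call. = FALSE)
  }
  if (!(tsd_length %in% 3:6))
    stop("simulation config error: tsd_length must be in 3..6", call. = FALSE)
  if (min(internal_len_range) < 10 || min(ltr_len_range) < 10)
    stop("simulation config error: template length overrides below 10 bp",
         call. = FALSE)
  if (!is.null(tsd_seq) && nchar(tsd_seq) != tsd_length)
    stop("simulation config error: tsd_seq length != tsd_length", call. = FALSE)
  structure(cfg, class = "troyka_sim_config")
}

#' Build an element template
#'
#' Draws LTR and internal lengths uniformly from the configured ranges, sets
#' the terminal pentamers (drawn from the variant spectra unless forced), and
#' fills the rest i.i.d. at the configured GC fraction. Both LTRs of a fresh
#' insertion are identical by construction, as reverse transcription makes
#' them.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param family_id template name.
#' @return list with fields family_id, ltr_seq, internal_seq, pentamer5,
#'   pentamer3, tsd_length.
#' @export
make_template <- function(config, family_id = "fam1") {
  p5 <- config$pentamer5 %||%
    sample(names(config$spectrum5), 1, prob = config$spectrum5)
  p3 <- config$pentamer3 %||%
    sample(names(config$spectrum3), 1, prob = config$spectrum3)
  stopifnot(nchar(p5) == 5, nchar(p3) == 5)
  ltr_len <- draw_int(config$ltr_len_range)
  int_len <- draw_int(config$internal_len_range)
  mid <- random_dna(ltr_len - 10L, config$gc_fraction)
  list(family_id = family_id,
       ltr_seq = paste0(p5, mid, p3),
       internal_seq = random_dna(int_len, config$gc_fraction),
       pentamer5 = p5, pentamer3 = p3,
       tsd_length = config$tsd_length)
}

# Mutate a sequence: substitutions to a different base, plus single-base
# indels (insertion or deletion, equal odds). Returns the sequence and the
# number of mutation events.
mutate_seq <- function(seq, sub_rate, indel_rate) {
  v <- chars(seq)
  n <- length(v)
  nsub <- stats::rbinom(1, n, sub_rate)
  if (nsub > 0) {
    pos <- sample.int(n, nsub)
    for (i in pos) {
      v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    }
  }
  nind <- stats::rbinom(1, n, indel_rate)
  if (nind > 0) {
    pos <- sort(sample.int(length(v), min(nind, length(v))), decreasing = TRUE)
    for (i in pos) {
      if (stats::runif(1) < 0.5) {
        v <- v[-i]
      } else {
        v <- append(v, sample(c("A", "C", "G", "T"), 1), after = i)
      }
    }
  }
  list(seq = paste(v, collapse = ""), n_mutations = nsub + nind)
}

# Plant copies of one or more templates into a background at non-overlapping
# positions (rejection sampling with bounded retries). Returns the final
# genome string and the ground-truth table with exact post-mutation
# coordinates.
plant_multi <- function(background, templates, n_copies, config,
                        contig_id = "chr1") {
  stopifnot(length(templates) == length(n_copies))
  total <- sum(n_copies)
  tlen <- config$tsd_length
  L <- nchar(background)
  margin <- 200L
  pts <- integer(0)
  tries <- 0L
  while (length(pts) < total && tries < 200L * total) {
    tries <- tries + 1L
    p <- draw_int(c(margin + tlen, L - margin))
    if (all(abs(p - pts) >= config$min_gap)) pts <- c(pts, p)
  }
  if (length(pts) < total)
    stop("insertion overlap exhaustion: only ", length(pts), " of ", total,
         " copies placeable at min_gap=", config$min_gap,
         " in a ", L, " bp background", call. = FALSE)
  pts <- sort(pts)
  fam_of <- sample(rep(seq_along(templates), times = n_copies))

  pieces <- character(0)
  rows <- list()
  cursor <- 0L   # position in background already emitted
  offset <- 0L   # length emitted so far
  for (i in seq_along(pts)) {
    p <- pts[i]
    tpl <- templates[[fam_of[i]]]
    tsd <- if (!is.null(config$tsd_seq)) config$tsd_seq else
      subseq0(background, p - tlen, p)
    m5 <- mutate_seq(tpl$ltr_seq, config$substitution_rate, config$indel_rate)
    mi <- mutate_seq(tpl$internal_seq, config$substitution_rate,
                     config$indel_rate)
    m3 <- mutate_seq(tpl$ltr_seq, config$substitution_rate, config$indel_rate)
    elem <- paste0(m5$seq, mi$seq, m3$seq)
    left <- subseq0(background, cursor, p)
    if (!is.null(config$tsd_seq)) {
      # overwrite the background bases that act as the upstream TSD copy
      substr(left, nchar(left) - tlen + 1, nchar(left)) <- config$tsd_seq
    }
    pieces <- c(pieces, left, elem, tsd)
    start <- offset + nchar(left)
    rows[[i]] <- data.frame(
      family_id = tpl$family_id, contig_id = contig_id,
      start = start, end = start + nchar(elem),
      ltr5_len = nchar(m5$seq), internal_len = nchar(mi$seq),
      ltr3_len = nchar(m3$seq),
      tsd_len = tlen, tsd_seq = tsd,
      n_mutations = m5$n_mutations + mi$n_mutations + m3$n_mutations,
      sibling_status = NA_character_, stringsAsFactors = FALSE)
    offset <- start + nchar(elem) + tlen
    cursor <- p
  }
  pieces <- c(pieces, subseq0(background, cursor, L))
  genome <- structure(stats::setNames(paste(pieces, collapse = ""), contig_id),
                      class = "genome_set")
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$start), , drop = FALSE]
  truth$locus_id <- sprintf("locus%03d", seq_len(nrow(truth)))
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

#' Plant copies of a template into a background sequence
#'
#' At each insertion point the \code{tsd_length} bases immediately upstream
#' are duplicated downstream of the element (staggered-cut integration), and
#' each copy is independently mutated at the configured rates. Ground truth
#' records exact post-mutation coordinates in the final genome.
#'
#' @param background DNA string (or 1-element named vector).
#' @param template from \code{\link{make_template}}.
#' @param config a \code{\link{simulation_config}}; \code{copies_per_family}
#'   gives the copy number (a range is drawn uniformly).
#' @param contig_id name of the output contig.
#' @return list with \code{genome} (named character, class genome_set) and
#'   \code{truth} (data.frame of planted insertions).
#' @export
plant_insertions <- function(background, template, config,
                             contig_id = "chr1") {
  bg <- if (!is.null(names(background))) unclass(background)[[1]] else background
  n <- draw_int(config$copies_per_family)
  plant_multi(bg, list(template), n, config, contig_id)
}

#' Derive a sibling genome with occupied and empty orthologous loci
#'
#' A configured fraction of the planted insertions is excised -- the element
#' plus exactly one TSD copy, inverting the insertion reaction -- and the
#' whole sibling is then diverged by background substitutions. With zero
#' divergence and all loci excised, the sibling equals the pre-insertion
#' background exactly.
#'
#' @param genome genome_set from \code{\link{plant_insertions}}.
#' @param truth its ground-truth table.
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{sibling} (genome_set) and \code{truth} updated
#'   with \code{sibling_status} (occupied/empty).
#' @export
make_sibling <- function(genome, truth, config) {
  seq <- unclass(genome)[[1]]
  n <- nrow(truth)
  n_empty <- round(config$fraction_empty_in_sibling * n)
  empty_idx <- if (n_empty > 0) sort(sample.int(n, n_empty)) else integer(0)
  truth$sibling_status <- ifelse(seq_len(n) %in% empty_idx, "empty", "occupied")
  for (i in rev(empty_idx)) {
    # remove element plus the downstream TSD copy
    seq <- paste0(subseq0(seq, 0, truth$start[i]),
                  subseq0(seq, truth$end[i] + truth$tsd_len[i], nchar(seq)))
  }
  if (config$sibling_divergence > 0) {
    seq <- mutate_seq(seq, config$sibling_divergence, 0)$seq
  }
  sibling <- structure(stats::setNames(seq, paste0(names(genome)[1], "_sib")),
                       class = "genome_set")
  list(sibling = sibling, truth = truth)
}

#' Simulate a genome, its ground truth and a sibling genome
#'
#' Seeds the RNG from \code{config$seed} (identical configs give
#' byte-identical output), draws one template per family, plants all copies
#' jointly without overlap, and derives the sibling.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with genome, sibling, truth, templates, background and the
#'   config.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  templates <- lapply(seq_len(config$n_families), function(i)
    make_template(config, sprintf("fam%02d", i)))
  n_copies <- draw_int(config$copies_per_family, config$n_families)
  bg <- random_dna(config$background_length, config$gc_fraction)
  planted <- plant_multi(bg, templates, n_copies, config)
  sib <- make_sibling(planted$genome, planted$truth, config)
  list(genome = planted$genome, sibling = sib$sibling, truth = sib$truth,
       templates = templates, background = bg, config = config)
}

#' Emulated initial hit table for a simulated genome
#'
#' Produces the hits a protein-level homology search would yield: one
#' interval per planted copy covering the internal portion (LTRs truncated),
#' with a small random jitter at both ends. This is the entry point of the
#' characterization pipeline on real genomes, where an external search tool
#' seeds the clustering.
#'
#' @param sim result of \code{\link{simulate_genome}}.
#' @param jitter maximum random truncation (bp) beyond each LTR.
#' @return a hit-table data.frame.
#' @export
initial_hit_table <- function(sim, jitter = 30L) {
  tr <- sim$truth
  n <- nrow(tr)
  j1 <- sample.int(jitter + 1L, n, replace = TRUE) - 1L
  j2 <- sample.int(jitter + 1L, n, replace = TRUE) - 1L
  data.frame(hit_id = sprintf("init_h%03d", seq_len(n)),
             query_id = tr$family_id,
             contig_id = tr$contig_id,
             start = tr$start + tr$ltr5_len + j1,
             end = tr$end - tr$ltr3_len - j2,
             strand = "+",
             identity_pct = round(100 * (1 - sim$config$substitution_rate), 2),
             stringsAsFactors = FALSE)
}

#' Write a simulation to disk
#'
#' Emits \code{<prefix>.fasta}, \code{<prefix>.sibling.fasta},
#' \code{<prefix>.truth.tsv} and \code{<prefix>.config.json}, so any run is
#' reproducible from two text files.
#'
#' @param sim result of \code{\link{simulate_genome}}.
#' @param prefix output path prefix.
#' @export
write_simulation <- function(sim, prefix) {
  write_fasta(sim$genome, paste0(prefix, ".fasta"))
  write_fasta(sim$sibling, paste0(prefix, ".sibling.fasta"))
  utils::write.table(sim$truth, paste0(prefix, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$spectrum5 <- as.list(cfg$spectrum5)
  cfg$spectrum3 <- as.list(cfg$spectrum3)
  jsonlite::write_json(unclass(cfg), paste0(prefix, ".config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}
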