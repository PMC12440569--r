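#' Pipeline parameters
#'
#' Bundles the constants the characterization pipeline runs with. The defaults
#' are the published operating point of the procedure: repeat copies are
#' clustered at 75% length coverage of the shorter sequence and 75% alignment
#' identity, consensus sequences follow the 50% majority rule, up to 10 copies
#' are extracted with 10,000 bp flanks for consensus elongation, full-length
#' elements require LTRs at both ends flanked by 3-6 bp target site
#' duplications, LTR lengths fall in 100-400 bp, and families whose copies
#' average more than 99.9% identity to the consensus are flagged as recently
#' active. \code{ltr_min_identity} (0.80) and the boundary-scoring weights are
#' package choices, exposed here so they can be audited and changed.
#'
#' @param coverage_threshold minimum fraction of the shorter sequence covered
#'   by the pairwise alignment for two copies to be linked.
#' @param identity_threshold minimum alignment identity for linking.
#' @param majority_fraction column majority fraction for consensus building.
#' @param flank_bp flanking bases extracted around each copy when elongating a
#'   consensus.
#' @param max_copies maximum number of genomic copies used per consensus.
#' @param tsd_min,tsd_max admissible target-site-duplication lengths (bp).
#' @param ltr_min_len,ltr_max_len admissible LTR lengths (bp).
#' @param ltr_min_identity minimum identity between the two LTR copies of a
#'   candidate pair.
#' @param recent_identity_threshold mean copy-to-consensus identity above
#'   which (strictly) a family is flagged recently active.
#' @param pentamer_bonus,dinucleotide_bonus,offset_penalty weights of the
#'   joint boundary/TSD score: bonus for termini matching the
#'   CGCCA...TGGCG pentamer pair, bonus for canonical TG...CA dinucleotides,
#'   and per-base penalty for moving away from the alignment-derived
#'   candidate boundary.
#' @param boundary_window maximum boundary refinement offset (bp).
#' @return an object of class \code{troyka_params} (a validated list).
#' @export
pipeline_params <- function(coverage_threshold = 0.75,
                            identity_threshold = 0.75,
                            majority_fraction = 0.50,
                            flank_bp = 10000L,
                            max_copies = 10L,
                            tsd_min = 3L,
                            tsd_max = 6L,
                            ltr_min_len = 100L,
                            ltr_max_len = 400L,
                            ltr_min_identity = 0.80,
                            recent_identity_threshold = 0.999,
                            pentamer_bonus = 2,
                            dinucleotide_bonus = 1,
                            offset_penalty = 0.15,
                            boundary_window = 10L) {
  p <- list(coverage_threshold = coverage_threshold,
            identity_threshold = identity_threshold,
            majority_fraction = majority_fraction,
            flank_bp = as.integer(flank_bp),
            max_copies = as.integer(max_copies),
            tsd_min = as.integer(tsd_min),
            tsd_max = as.integer(tsd_max),
            ltr_min_len = as.integer(ltr_min_len),
            ltr_max_len = as.integer(ltr_max_len),
            ltr_min_identity = ltr_min_identity,
            recent_identity_threshold = recent_identity_threshold,
            pentamer_bonus = pentamer_bonus,
            dinucleotide_bonus = dinucleotide_bonus,
            offset_penalty = offset_penalty,
            boundary_window = as.integer(boundary_window))
  validate_params(p)
  structure(p, class = "troyka_params")
}

validate_params <- function(p) {
  for (f in c("coverage_threshold", "identity_threshold", "majority_fraction",
              "ltr_min_identity", "recent_identity_threshold")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1)
      stop("parameter schema error: `", f, "` must be a fraction in (0, 1], got ",
           v, call. = FALSE)
  }
  if (p$flank_bp < 0) stop("parameter schema error: flank_bp must be >= 0",
                           call. = FALSE)
  if (p$tsd_min > p$tsd_max)
    stop("parameter schema error: tsd_min > tsd_max", call. = FALSE)
  if (p$ltr_min_len <= 0 || p$ltr_min_len > p$ltr_max_len)
    stop("parameter schema error: require 0 < ltr_min_len <= ltr_max_len",
         call. = FALSE)
  if (p$max_copies < 1)
    stop("parameter schema error: max_copies must be >= 1", call. = FALSE)
  invisible(p)
}
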