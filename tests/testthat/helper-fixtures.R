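# Shared fixture builders. Everything is generated in code under fixed seeds.

rand_seq <- function(n, gc = 0.41) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# substitute a fraction of bases (always to a different base)
mutate_frac <- function(seq, rate) {
  v <- strsplit(seq, NULL)[[1]]
  idx <- which(stats::runif(length(v)) < rate)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# A clean planted locus: flank | TSD | LTR internal LTR | TSD | flank.
# Returns the locus string plus truth coordinates of the element within it.
clean_locus <- function(ltr_len = 200, internal_len = 2000, tsd = "ACT",
                        flank = 150, pent5 = "CGCCA", pent3 = "TGGCG",
                        ltr_mut = 0, gc = 0.41) {
  ltr <- paste0(pent5, rand_seq(ltr_len - 10, gc), pent3)
  ltr3 <- if (ltr_mut > 0) mutate_frac(ltr, ltr_mut) else ltr
  internal <- rand_seq(internal_len, gc)
  lf <- rand_seq(flank, gc)
  rf <- rand_seq(flank, gc)
  seq <- paste0(lf, tsd, ltr, internal, ltr3, tsd, rf)
  start <- as.integer(flank + nchar(tsd))
  end <- as.integer(start + nchar(ltr) + internal_len + nchar(ltr3))
  list(seq = seq, start = start, end = end,
       ltr_len = ltr_len, internal_len = internal_len,
       ltr = ltr, internal = internal, tsd = tsd)
}

# Independent alignment-identity oracle (Levenshtein): 1 - edits/max length.
adist_identity <- function(a, b) {
  1 - utils::adist(a, b)[1, 1] / max(nchar(a), nchar(b))
}

# Brute-force connected components over an explicit link function, used as
# the clustering oracle (breadth-first search; no union-find).
bfs_components <- function(ids, link) {
  n <- length(ids)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (v in seq_len(n)) {
        if (is.na(comp[v]) && link(u, v)) { comp[v] <- cur; queue <- c(queue, v) }
      }
    }
  }
  split(ids, comp)
}
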