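test_that("pentamer classification distinguishes substitution kinds", {
  r <- classify_pentamer("CGCCA", "CGCCA", end = "five")
  expect_identical(r$class, "canonical")
  expect_length(r$positions, 0)

  r <- classify_pentamer("CACCA", "CGCCA", end = "five")
  expect_identical(r$class, "transition")
  expect_identical(r$positions, 2L)

  r <- classify_pentamer("TGTCG", "TGGCG", end = "three")
  expect_identical(r$class, "transversion")
  expect_identical(r$positions, -3L)

  r <- classify_pentamer("CGGTG", "CGCCA", end = "five")
  expect_identical(r$class, "multi")
  expect_identical(r$positions, c(3L, 4L, 5L))

  expect_identical(classify_pentamer("CGNCA", "CGCCA")$class, "ambiguous")
  expect_error(classify_pentamer("CGCC", "CGCCA"), "length 5")
})

test_that("substitution counting is symmetric and exhaustive", {
  set.seed(51)
  for (i in 1:50) {
    a <- rand_seq(5); b <- rand_seq(5)
    ra <- classify_pentamer(a, b); rb <- classify_pentamer(b, a)
    expect_identical(length(ra$positions), length(rb$positions))
    n_match <- sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    expect_identical(length(ra$positions) + n_match, 5L)
  }
})

test_that("signature tallies count pentamers, classes and positions", {
  recs <- data.frame(entry_id = paste0("e", 1:10),
                     pentamer5 = rep("CGCCA", 10),
                     pentamer3 = rep("TGGCG", 10))
  tl <- tally_signatures(recs)
  expect_equal(unname(tl$pentamer5[["CGCCA"]]), 10)
  expect_equal(unname(tl$class5[["canonical"]]), 10)
  expect_equal(sum(tl$positions3), 0)

  # hand-counted: TGACG twice (one event each at -3), TGGCT once (-1)
  recs <- data.frame(entry_id = paste0("e", 1:3),
                     pentamer5 = rep("CGCCA", 3),
                     pentamer3 = c("TGACG", "TGACG", "TGGCT"))
  tl <- tally_signatures(recs)
  expect_equal(unname(tl$positions3[["-3"]]), 2)
  expect_equal(unname(tl$positions3[["-1"]]), 1)
  expect_equal(unname(tl$concentration3_events),  c(2, 3))
  expect_equal(unname(tl$concentration3_ltrs), c(2, 3))
  # class totals always partition the records
  expect_equal(sum(tl$class3), nrow(recs))
})

test_that("tallies match a configured variant spectrum within sampling error", {
  set.seed(52)
  n <- 600
  spec <- c(TGGCG = 0.85, TGTCG = 0.1, TGACG = 0.05)
  draws <- sample(names(spec), n, replace = TRUE, prob = spec)
  tl <- tally_signatures(data.frame(entry_id = paste0("e", 1:n),
                                    pentamer5 = "CGCCA", pentamer3 = draws))
  obs <- as.vector(tl$pentamer3[names(spec)])
  expect_gt(stats::chisq.test(obs, p = spec)$p.value, 0.001)
})

test_that("superfamily calls follow termini dinucleotides plus TSD length", {
  r <- call_superfamily("CGCCA", "TGGCG", 3)
  expect_identical(r$superfamily, "troyka")
  expect_length(r$anomalies, 0)

  r <- call_superfamily("TGTTA", "ACTCA", 5)
  expect_identical(r$superfamily, "canonical_ltr")
  expect_length(r$anomalies, 0)

  r <- call_superfamily("CGCCA", "TGGCG", 4)
  expect_identical(r$superfamily, "troyka")
  expect_identical(r$anomalies, "tsd_length")

  expect_identical(call_superfamily("CGCCA", "ACTCA", 3)$superfamily,
                   "unclassified")

  # only the first and last two bases and the TSD length matter
  set.seed(53)
  for (i in 1:20) {
    mid5 <- rand_seq(3); mid3 <- rand_seq(3)
    expect_identical(
      call_superfamily(paste0("CG", mid5), paste0(mid3, "CG"), 3)$superfamily,
      "troyka")
    expect_identical(
      call_superfamily(paste0("TG", mid5), paste0(mid3, "CA"), 5)$superfamily,
      "canonical_ltr")
  }
})

test_that("zinc-finger scanning matches both knuckle spacings", {
  hits <- scan_zinc_finger("CAACAAAAAAAAHAAAAC")
  expect_equal(nrow(hits), 1)
  expect_identical(hits$pattern, "troyka_zf")
  expect_identical(hits$start, 0L)

  # spacers 9 and 10 also qualify as the Troyka knuckle
  expect_equal(scan_zinc_finger("CAACAAAAAAAAAHAAAAC")$pattern, "troyka_zf")
  expect_equal(scan_zinc_finger("CAACAAAAAAAAAAHAAAAC")$pattern, "troyka_zf")

  hits <- scan_zinc_finger("CAACAAAAHAAAAC")
  expect_identical(hits$pattern, "retroviral_zf")

  expect_equal(nrow(scan_zinc_finger("CAACAAAAAAAAQAAAAC")), 0)

  # overlapping matches are all reported; X is a wildcard
  two <- scan_zinc_finger("CAACAAAAHAAAACAACAAAAHAAAAC")
  expect_equal(nrow(two), 2)
  expect_equal(nrow(scan_zinc_finger("XAAXAAAAHAAAAX")), 1)
})

test_that("recent-activity screening requires strictly more than 99.9%", {
  set.seed(54)
  cons <- rand_seq(1000)
  r <- screen_recent_activity(cons, c(cons, cons, cons))
  expect_equal(r$mean_identity, 1.0)
  expect_true(r$flagged)

  copies <- replicate(10, mutate_frac(cons, 0.01))
  r <- screen_recent_activity(cons, copies)
  oracle <- mean(vapply(copies, adist_identity, 0, b = cons))
  expect_lt(abs(r$mean_identity - oracle), 0.005)
  expect_false(r$flagged)

  # exactly one substitution in each of several 1000 bp copies: mean 0.999,
  # not strictly greater, so not flagged
  one_sub <- vapply(1:5, function(i) {
    v <- strsplit(cons, "")[[1]]
    v[100 + 150 * i] <- setdiff(c("A", "C", "G", "T"), v[100 + 150 * i])[1]
    paste(v, collapse = "")
  }, "")
  r <- screen_recent_activity(cons, one_sub)
  expect_equal(r$mean_identity, 0.999)
  expect_false(r$flagged)

  expect_error(screen_recent_activity(cons, cons), "at least 2")
})
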