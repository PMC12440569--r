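params <- pipeline_params()

test_that("copy linking follows the 75% coverage / 75% identity rule", {
  set.seed(31)
  a <- rand_seq(1000)
  expect_true(pairwise_link(a, a, params))
  # an exact substring covers 100% of the shorter sequence
  expect_true(pairwise_link(substr(a, 251, 750), a, params))
  # ~70% identity falls below the identity threshold
  expect_false(pairwise_link(a, mutate_frac(a, 0.30), params))
  # unrelated sequences share no seeds
  expect_false(pairwise_link(a, rand_seq(1000), params))
})

test_that("clustering gives order-invariant single-linkage components", {
  set.seed(32)
  base <- rand_seq(1200)
  seqs <- c(A = mutate_frac(base, 0.01), B = mutate_frac(base, 0.01),
            C = mutate_frac(base, 0.01))
  cl <- cluster_hits(seqs, params)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$member_ids, c("A", "B", "C"))

  # transitive chain: A~B and B~C linked, A and C too far apart directly
  b <- rand_seq(1200)
  chain <- c(A = mutate_frac(b, 0.16), B = b, C = mutate_frac(b, 0.16))
  expect_true(pairwise_link(chain[["A"]], chain[["B"]], params))
  expect_true(pairwise_link(chain[["B"]], chain[["C"]], params))
  cl <- cluster_hits(chain, params)
  oracle <- bfs_components(names(chain), function(i, j)
    pairwise_link(chain[[i]], chain[[j]], params))
  expect_length(cl, length(oracle))
  expect_setequal(cl[[1]]$member_ids, unlist(oracle[lengths(oracle) ==
                                                      max(lengths(oracle))]))

  # two well-separated families stay apart and ordering is canonical
  f2 <- rand_seq(900)
  two <- c(x1 = mutate_frac(base, 0.02), x2 = mutate_frac(base, 0.02),
           y1 = mutate_frac(f2, 0.02), y2 = mutate_frac(f2, 0.02),
           y3 = mutate_frac(f2, 0.02))
  cl <- cluster_hits(two, params)
  expect_length(cl, 2)
  expect_length(cl[[1]]$member_ids, 3)    # larger cluster first
  cl_rev <- cluster_hits(two[rev(names(two))], params)
  expect_identical(lapply(cl, `[[`, "member_ids"),
                   lapply(cl_rev, `[[`, "member_ids"))
})

test_that("majority-rule consensus follows the 50% column rule", {
  rows5 <- rep("ACGTT", 5)
  cons <- build_consensus(rows5, params)
  expect_identical(cons$sequence, "ACGTT")
  expect_identical(cons$column_depth, rep(5L, 5))

  # column {A,A,A,C,C}: A at 60% wins
  cons <- build_consensus(c("A", "A", "A", "C", "C"), params)
  expect_identical(cons$sequence, "A")

  # tie at exactly 50%: alphabetically first qualifying base, flagged
  cons <- build_consensus(c("A", "A", "C", "C"), params)
  expect_identical(cons$sequence, "A")
  expect_identical(cons$ambiguous_columns, 1L)

  # no symbol reaches 50%: N
  cons <- build_consensus(c("A", "C", "G", "T"), params)
  expect_identical(cons$sequence, "N")

  # gap-majority columns are dropped; missing rows don't count
  cons <- build_consensus(c("A-G", "A-G", "A-G", "ACG", ".CG"), params)
  expect_identical(cons$sequence, "AG")
  expect_identical(cons$column_depth, c(4L, 5L))

  expect_error(build_consensus(c("AC", "A"), params), "unequal")
})

test_that("consensus building is idempotent", {
  set.seed(33)
  seq <- paste0(rand_seq(100), "N", rand_seq(50))
  cons <- build_consensus(rep(seq, 4), params)
  expect_identical(cons$sequence, seq)
})

test_that("stacked copies reproduce the reference layout", {
  set.seed(34)
  ref <- rand_seq(600)
  copies <- c(mutate_frac(ref, 0.02), mutate_frac(ref, 0.02))
  rows <- stack_copies(ref, copies)
  expect_identical(nchar(rows), rep(600L, 3))
  expect_identical(rows[1], ref)
  cons <- build_consensus(rows, params)
  # majority of 3 near-identical rows recovers the reference almost everywhere
  expect_gt(adist_identity(cons$sequence, ref), 0.99)
})

test_that("elongation recovers full elements from LTR-truncated hits", {
  set.seed(35)
  cfg <- simulation_config(seed = 35, n_families = 1, copies_per_family = 5L,
                           substitution_rate = 0, indel_rate = 0,
                           background_length = 50000)
  sim <- simulate_genome(cfg)
  tpl <- sim$templates[[1]]
  elem <- paste0(tpl$ltr_seq, tpl$internal_seq, tpl$ltr_seq)
  hits <- initial_hit_table(sim)
  seqs <- stats::setNames(vapply(seq_len(nrow(hits)), function(i)
    troykascan:::hit_sequence(hits[i, ], sim$genome), ""), hits$hit_id)
  p <- pipeline_params(flank_bp = 500)
  cons0 <- build_consensus(stack_copies(seqs[[1]], seqs[-1]), p)
  # initial consensus lacks the LTRs entirely
  expect_lt(nchar(cons0$sequence), nchar(elem) - nchar(tpl$ltr_seq))
  cons <- elongate_consensus(cons0, sim$genome, p)
  expect_gte(cons$elongation_rounds, 1L)
  # noiseless copies: the elongated consensus contains the template exactly
  expect_true(grepl(elem, cons$sequence, fixed = TRUE))
  expect_lte(nchar(cons$sequence), nchar(elem) + 10)
})

test_that("elongation requires at least two genomic copies", {
  set.seed(36)
  q <- rand_seq(1500)
  genome <- structure(c(c1 = paste0(rand_seq(4000), q, rand_seq(4000))),
                      class = "genome_set")
  expect_error(elongate_consensus(q, genome, pipeline_params(flank_bp = 300)),
               "cannot elongate")
})
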