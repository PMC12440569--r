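test_that("templates respect length ranges and terminal pentamers", {
  set.seed(1)
  cfg <- simulation_config(seed = 1)
  for (i in 1:20) {
    tpl <- make_template(cfg)
    expect_gte(nchar(tpl$ltr_seq), 100)
    expect_lte(nchar(tpl$ltr_seq), 400)
    expect_gte(nchar(tpl$internal_seq), 1553)
    expect_lte(nchar(tpl$internal_seq), 7691)
    expect_identical(substr(tpl$ltr_seq, 1, 5), tpl$pentamer5)
    expect_identical(substr(tpl$ltr_seq, nchar(tpl$ltr_seq) - 4,
                            nchar(tpl$ltr_seq)), tpl$pentamer3)
  }
  cfg2 <- simulation_config(seed = 1, pentamer5 = "CACCA")
  tpl <- make_template(cfg2)
  expect_identical(substr(tpl$ltr_seq, 1, 5), "CACCA")
  expect_error(simulation_config(internal_len_range = c(5, 8)), "below 10")
})

test_that("planting duplicates the target site and records exact coordinates", {
  set.seed(2)
  cfg <- simulation_config(seed = 2, substitution_rate = 0, indel_rate = 0,
                           copies_per_family = 4L, background_length = 40000)
  tpl <- make_template(cfg)
  res <- plant_insertions(rand_seq(40000), tpl, cfg)
  g <- unclass(res$genome)[[1]]
  for (i in seq_len(nrow(res$truth))) {
    tr <- res$truth[i, ]
    expect_identical(substr(g, tr$start - tr$tsd_len + 1, tr$start),
                     substr(g, tr$end + 1, tr$end + tr$tsd_len))
    expect_identical(substr(g, tr$start + 1, tr$end),
                     paste0(tpl$ltr_seq, tpl$internal_seq, tpl$ltr_seq))
  }
})

test_that("a forced 4 bp CATG target site appears on both element sides", {
  set.seed(3)
  cfg <- simulation_config(seed = 3, tsd_length = 4L, tsd_seq = "CATG",
                           substitution_rate = 0, indel_rate = 0,
                           copies_per_family = 2L, background_length = 20000)
  tpl <- make_template(cfg)
  res <- plant_insertions(rand_seq(20000), tpl, cfg)
  g <- unclass(res$genome)[[1]]
  tr <- res$truth[1, ]
  expect_identical(substr(g, tr$start - 3, tr$start), "CATG")
  expect_identical(substr(g, tr$end + 1, tr$end + 4), "CATG")
})

test_that("per-copy divergence matches the configured substitution rate", {
  set.seed(4)
  cfg <- simulation_config(seed = 4, substitution_rate = 0.01, indel_rate = 0,
                           copies_per_family = 20L, background_length = 150000,
                           internal_len_range = c(1553, 2500))
  tpl <- make_template(cfg)
  res <- plant_insertions(rand_seq(150000), tpl, cfg)
  g <- unclass(res$genome)[[1]]
  elem <- paste0(tpl$ltr_seq, tpl$internal_seq, tpl$ltr_seq)
  ids <- vapply(seq_len(nrow(res$truth)), function(i) {
    tr <- res$truth[i, ]
    adist_identity(substr(g, tr$start + 1, tr$end), elem)
  }, 0)
  # mean copy identity ~ 99%, binomial error over 20 copies x ~3 kb
  expect_lt(abs(mean(ids) - 0.99), 0.003)
})

test_that("the simulation is fully determined by its seed", {
  cfg <- simulation_config(seed = 99, n_families = 2, background_length = 30000)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$sibling, s2$sibling)
  expect_identical(s1$truth, s2$truth)
})

test_that("sibling excision inverts insertion and hits the configured fraction", {
  cfg <- simulation_config(seed = 5, n_families = 2,
                           copies_per_family = 5L,
                           substitution_rate = 0, indel_rate = 0,
                           sibling_divergence = 0,
                           fraction_empty_in_sibling = 1.0,
                           background_length = 60000)
  sim <- simulate_genome(cfg)
  # all loci excised, no divergence: the sibling IS the pre-insertion background
  expect_identical(unname(unclass(sim$sibling)[[1]]), sim$background)

  cfg2 <- simulation_config(seed = 6, n_families = 1, copies_per_family = 10L,
                            fraction_empty_in_sibling = 0.5,
                            background_length = 80000)
  sim2 <- simulate_genome(cfg2)
  expect_equal(sum(sim2$truth$sibling_status == "empty"), 5)

  # an excised locus retains exactly one TSD copy at the junction
  cfg3 <- simulation_config(seed = 7, n_families = 1, copies_per_family = 4L,
                            substitution_rate = 0, indel_rate = 0,
                            sibling_divergence = 0,
                            fraction_empty_in_sibling = 1.0,
                            background_length = 40000)
  sim3 <- simulate_genome(cfg3)
  g <- unclass(sim3$genome)[[1]]
  tr <- sim3$truth[1, ]
  left_with_tsd <- substr(g, tr$start - 200, tr$start)      # ends in the TSD
  right_no_tsd <- substr(g, tr$end + tr$tsd_len + 1, tr$end + tr$tsd_len + 200)
  expect_true(grepl(paste0(left_with_tsd, right_no_tsd),
                    unclass(sim3$sibling)[[1]], fixed = TRUE))
})

test_that("simulation files round-trip through the text formats", {
  prefix <- file.path(withr::local_tempdir(), "sim")
  cfg <- simulation_config(seed = 8, n_families = 1, copies_per_family = 3L,
                           background_length = 20000)
  sim <- simulate_genome(cfg)
  write_simulation(sim, prefix)
  g <- read_fasta(paste0(prefix, ".fasta"))
  expect_identical(unclass(g)[[1]], unname(unclass(sim$genome)[[1]]))
  tr <- read.delim(paste0(prefix, ".truth.tsv"))
  expect_equal(nrow(tr), nrow(sim$truth))
  cfg_back <- jsonlite::read_json(paste0(prefix, ".config.json"))
  expect_equal(cfg_back$seed, 8)
})
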