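# synthetic_data: the ground-truth engine.

test_that("toy construction satisfies its stated recipe", {
  toy <- make_toy_plastome(
    toy_spec(len_a = 111, len_b = 20, len_c = 69, arm_len = 11,
             len_ssc = 150, len_ir = 200, seed = 5)
  )
  expect_equal(toy$structure$length, 111 + 20 + 69 + 150 + 2 * 200)

  # detection recovers the spec's region lengths exactly
  st <- detect_quadripartite(toy$structure$sequence, min_ir_len = 100)
  expect_equal(interval_len(st$lsc), 200L)
  expect_equal(interval_len(st$irb), 200L)
  expect_equal(interval_len(st$ssc), 150L)
  expect_identical(st$sequence, toy$structure$sequence)

  # the LSC holds exactly one inverted pair >= arm_len, at the planted spot
  lsc <- interval_seq(toy$structure$sequence, toy$structure$lsc)
  found <- find_repeat_pairs(lsc, min_arm = 11, max_spacer = nchar(lsc),
                             orientation = "inverted")
  expect_equal(nrow(found), 1L)
  expect_equal(found$arm_len, 11L)
  expect_equal(found$spacer_len, 20L)
  expect_equal(found$left_start, 100L)
})

test_that("same seed gives byte-identical genomes and reads", {
  t1 <- make_toy_plastome(toy_spec(seed = 33))
  t2 <- make_toy_plastome(toy_spec(seed = 33))
  expect_identical(t1$structure$sequence, t2$structure$sequence)
  expect_identical(t1$pieces, t2$pieces)

  s1 <- simulate_reads(c(p = t1$structure$sequence), 1, depth = 20, seed = 7)
  s2 <- simulate_reads(c(p = t2$structure$sequence), 1, depth = 20, seed = 7)
  expect_identical(s1$reads1, s2$reads1)
  expect_identical(s1$reads2, s2$reads2)
  expect_identical(s1$truth, s2$truth)
})

test_that("splice closed forms: sizes and content", {
  toy <- make_toy_plastome(
    toy_spec(len_a = 111, len_b = 20, len_c = 69, arm_len = 11,
             len_ssc = 150, len_ir = 200, seed = 5)
  )
  parent_len <- toy$structure$length
  expect_equal(nchar(splice_conformer(toy, "A-type")), 750 + 111 - 69)
  expect_equal(nchar(splice_conformer(toy, "intermediate-dimer")), 2 * parent_len)

  binv <- splice_conformer(toy, "B-inversion")
  expect_equal(nchar(binv), parent_len)
  # inversion conserves double-stranded content: A:T and G:C pair counts
  pair_counts <- function(s) {
    tb <- table(factor(strsplit(s, "")[[1]], c("A", "C", "G", "T")))
    c(at = tb[["A"]] + tb[["T"]], gc = tb[["C"]] + tb[["G"]])
  }
  expect_equal(pair_counts(binv), pair_counts(toy$structure$sequence))

  expect_error(splice_conformer(toy, "no-such-label"), class = "psv_bad_input")
})

test_that("event-driven assembly and formulaic splicing agree on random specs", {
  set.seed(77)
  for (rep in 1:10) {
    sp <- toy_spec(
      len_a = sample(100:300, 1), len_b = sample(20:120, 1),
      len_c = sample(80:250, 1), arm_len = sample(8:14, 1),
      len_ssc = sample(100:300, 1), len_ir = sample(150:300, 1),
      gc = sample(c(0.3, 0.375, 0.45), 1), seed = sample.int(1e6, 1)
    )
    toy <- make_toy_plastome(sp)
    confs <- enumerate_conformers(toy$structure, toy$partition, metrics = FALSE)
    for (cf in confs) {
      expect_identical(cf$sequence, splice_conformer(toy, cf$label))
    }
    n <- toy$structure$length
    sizes <- setNames(
      vapply(confs, `[[`, integer(1), "length"),
      vapply(confs, `[[`, character(1), "label")
    )
    expect_equal(unname(sizes["A-type"] + sizes["reciprocal"]), 2L * n)
  }
})

test_that("error-free reads are exact circular substrings at the right depth", {
  toy <- shared_toy()
  g <- toy$structure$sequence
  sim <- simulate_reads(c(parent = g), 1, depth = 100, error_rate = 0, seed = 8)
  doubled <- paste0(g, g)
  rc_doubled <- reverse_complement(doubled)
  all_reads <- c(sim$reads1, sim$reads2)
  ok <- vapply(all_reads, function(r) {
    grepl(r, doubled, fixed = TRUE) || grepl(r, rc_doubled, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))

  realized <- length(all_reads) * 150 / nchar(g)
  expect_lt(abs(realized - 100), 1)
})

test_that("mixture origin tags are multinomially consistent", {
  toy <- shared_toy()
  atype <- splice_conformer(toy, "A-type")
  mix <- c(parent = 0.3, atype = 0.7)
  sim <- simulate_reads(c(parent = toy$structure$sequence, atype = atype),
                        mix, depth = 150, seed = 9)
  n <- nrow(sim$truth)
  lens <- c(nchar(toy$structure$sequence), nchar(atype))
  p_expected <- (0.7 * lens[2]) / (0.3 * lens[1] + 0.7 * lens[2])
  frac <- mean(sim$truth$conformer == "atype")
  # binomial 99.9% bound
  expect_lt(abs(frac - p_expected), 3.3 * sqrt(p_expected * (1 - p_expected) / n))
})

test_that("truth tags locate every error-free read on its conformer", {
  toy <- shared_toy()
  g <- toy$structure$sequence
  sim <- simulate_reads(c(parent = g), 1, depth = 10, error_rate = 0, seed = 14)
  doubled <- paste0(g, g)
  for (i in seq_len(nrow(sim$truth))) {
    start <- sim$truth$start[i]           # 1-based fragment start, forward strand
    flen <- sim$truth$frag_len[i]
    frag <- substr(doubled, start, start + flen - 1)
    if (sim$truth$strand[i] == "-") frag <- reverse_complement(frag)
    expect_identical(sim$reads1[[i]], substr(frag, 1, 150))
  }
})

test_that("read simulation contracts: bad mixtures and lengths are rejected", {
  toy <- shared_toy()
  g <- toy$structure$sequence
  expect_error(simulate_reads(c(p = g), c(0.5, 0.5), depth = 10),
               class = "psv_bad_input")
  expect_error(simulate_reads(c(p = g), 0.9, depth = 10), class = "psv_bad_input")
  expect_error(simulate_reads(c(p = "ACGT"), 1, depth = 10), class = "psv_bad_input")
})

test_that("paired FASTQ round-trips through the reader", {
  toy <- shared_toy()
  sim <- simulate_reads(c(parent = toy$structure$sequence), 1, depth = 5, seed = 15)
  prefix <- withr::local_tempfile()
  paths <- write_read_set(sim, prefix)
  r1 <- read_fastq(paths[1])
  expect_identical(unname(r1), unname(sim$reads1))
  expect_identical(names(r1), names(sim$reads1))
  truth <- utils::read.table(paths[3], header = TRUE, sep = "\t")
  expect_equal(nrow(truth), length(sim$reads1))
  # quality filter keeps constant-quality reads
  expect_length(read_fastq(paths[1], min_mean_quality = 30), length(sim$reads1))
})

test_that("toy_spec validates its invariants", {
  expect_error(toy_spec(arm_len = 3), class = "psv_bad_input")
  expect_error(toy_spec(len_a = 5, arm_len = 11), class = "psv_bad_input")
})
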