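# junction_support: reference construction and spanning-read counting.

test_that("junction references have the expected composition", {
  toy <- shared_toy()
  refs <- build_junction_refs(toy$structure, toy$partition, flank_len = 300)
  expect_setequal(names(refs), c("parent", "inversion", "a-type", "c-deletion", "reciprocal"))

  s <- toy$structure$sequence
  b <- interval_seq(s, toy$partition$area_b)

  # parent junction is the contiguous parent subsequence flank + B + flank
  par <- refs[["parent"]]
  bstart <- toy$partition$area_b$start
  expect_identical(par$sequence, substr(s, bstart - 300 + 1, bstart + nchar(b) + 300))
  expect_equal(nchar(par$sequence), 92 + 2 * 300)

  # inversion junction differs from the parent junction exactly on the core
  inv <- refs[["inversion"]]
  expect_identical(substr(inv$sequence, 1, 300), substr(par$sequence, 1, 300))
  expect_identical(substr(inv$sequence, 393, 692), substr(par$sequence, 393, 692))
  expect_false(identical(substr(inv$sequence, 301, 392), substr(par$sequence, 301, 392)))
  expect_identical(substr(inv$sequence, 301, 392), reverse_complement(b))

  # A-type junction: B flanked by area-A context on both sides (A-B-A)
  at <- refs[["a-type"]]
  expect_identical(substr(at$sequence, 1, 300), substr(par$sequence, 1, 300))
  expect_identical(substr(at$sequence, 393, 692),
                   reverse_complement(substr(at$sequence, 1, 300)))

  # each diagnostic reference occurs in its conformer
  atype_seq <- splice_conformer(toy, "A-type")
  expect_true(grepl(at$sequence, paste0(atype_seq, atype_seq), fixed = TRUE))
  rec <- refs[["reciprocal"]]
  rec_seq <- splice_conformer(toy, "reciprocal")
  expect_true(grepl(rec$sequence, paste0(rec_seq, rec_seq), fixed = TRUE))
})

test_that("flanks truncate (with a flag) at region boundaries", {
  toy <- make_toy_plastome(
    toy_spec(len_a = 120, len_b = 30, len_c = 80, arm_len = 11,
             len_ssc = 200, len_ir = 250, seed = 13)
  )
  refs <- build_junction_refs(toy$structure, toy$partition, flank_len = 300)
  at <- refs[["a-type"]]
  expect_true(at$truncated)
  expect_equal(at$flank_left, 120L)  # all of area A
  expect_equal(nchar(at$sequence), 120 + 30 + 120)
})

test_that("zero reads give zero support; overhang must fit the flanks", {
  toy <- shared_toy()
  refs <- build_junction_refs(toy$structure, toy$partition)
  sc <- count_spanning_reads(refs[["parent"]], character(0))
  expect_equal(sc$n_spanning, 0L)
  expect_equal(sc$n_partial, 0L)
  expect_error(
    count_spanning_reads(refs[["parent"]], character(0), min_overhang = 500),
    class = "psv_bad_input"
  )
})

test_that("parent-only reads never span conformer-diagnostic junctions", {
  toy <- shared_toy()
  refs <- build_junction_refs(toy$structure, toy$partition)
  sim <- simulate_reads(c(parent = toy$structure$sequence), 1,
                        depth = 50, error_rate = 0, seed = 2)
  for (lab in c("inversion", "a-type", "c-deletion", "reciprocal")) {
    sc <- count_spanning_reads(refs[[lab]], sim, max_mismatch = 0)
    expect_equal(sc$n_spanning, 0L)
  }
  # while the parent junction is supported at about the closed-form rate
  par <- count_spanning_reads(refs[["parent"]], sim, max_mismatch = 0)
  E <- expected_spanning(50, 150, 92 + 2 * 20)
  expect_gt(par$n_spanning, 0L)
  expect_lt(abs(par$n_spanning - E), 4 * sqrt(E) + 1)
})

test_that("conformer reads support their own junction at the closed-form rate", {
  toy <- shared_toy()
  refs <- build_junction_refs(toy$structure, toy$partition)
  atype <- splice_conformer(toy, "A-type")
  D <- 60
  sim <- simulate_reads(c(atype = atype), 1, depth = D, error_rate = 0, seed = 3)
  sc <- count_spanning_reads(refs[["a-type"]], sim, max_mismatch = 0)
  E <- expected_spanning(D, 150, 92 + 2 * 20)
  expect_lt(abs(sc$n_spanning - E), 4 * sqrt(E) + 1)
  # and fail to support junctions whose core-plus-overhang their genome
  # lacks. NB at the default inversion overhang (11 = the arm length) the
  # window tailA|rc(B)|arm* does occur on the A-type reverse strand, so
  # the inversion junction discriminates against A-type reads only with
  # overhang > arm length; 20 is used here.
  expect_equal(
    count_spanning_reads(refs[["inversion"]], sim, min_overhang = 20, max_mismatch = 0)$n_spanning, 0L
  )
  expect_equal(count_spanning_reads(refs[["c-deletion"]], sim, max_mismatch = 0)$n_spanning, 0L)
})

test_that("counts are strand-symmetric and monotone in overhang/mismatch", {
  toy <- shared_toy()
  refs <- build_junction_refs(toy$structure, toy$partition)
  atype <- splice_conformer(toy, "A-type")
  sim <- simulate_reads(c(atype = atype), 1, depth = 40, error_rate = 0.002, seed = 6)
  reads <- c(sim$reads1, sim$reads2)
  ref <- refs[["a-type"]]

  fwd <- count_spanning_reads(ref, reads, max_mismatch = 2)
  rc <- count_spanning_reads(ref, revcomp_many(reads), max_mismatch = 2)
  expect_equal(fwd$n_spanning, rc$n_spanning)

  over <- vapply(c(11, 20, 40, 80), function(oh) {
    count_spanning_reads(ref, reads, min_overhang = oh, max_mismatch = 2)$n_spanning
  }, integer(1))
  expect_true(all(diff(over) <= 0))

  mm <- vapply(c(0, 1, 2), function(m) {
    count_spanning_reads(ref, reads, max_mismatch = m)$n_spanning
  }, integer(1))
  expect_true(all(diff(mm) >= 0))
})

test_that("short reads count as partial candidates only", {
  toy <- shared_toy()
  refs <- build_junction_refs(toy$structure, toy$partition)
  par <- refs[["parent"]]
  # a read equal to the core alone touches but cannot span
  core_read <- substr(par$sequence, 301, 392)
  sc <- count_spanning_reads(par, core_read, max_mismatch = 0)
  expect_equal(sc$n_spanning, 0L)
  expect_equal(sc$n_partial, 1L)
})

test_that("junction FASTA and support TSV are written", {
  toy <- shared_toy()
  refs <- build_junction_refs(toy$structure, toy$partition)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_junctions_fasta(refs, fa)
  back <- read_fasta(fa)
  expect_setequal(names(back), names(refs))

  sim <- simulate_reads(c(parent = toy$structure$sequence), 1, depth = 20,
                        error_rate = 0, seed = 8)
  tab <- junction_support_table(refs, sim)
  expect_equal(nrow(tab), 5L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_support_tsv(tab, tsv)
  expect_equal(nrow(utils::read.table(tsv, header = TRUE, sep = "\t")), 5L)
})
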