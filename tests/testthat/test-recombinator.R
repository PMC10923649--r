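# recombinator: LSC partition, conformer enumeration, gene changes.

test_that("partition_lsc reproduces the construction recipe", {
  # LSC = 100 random bp + arm(11) + B(20) + revcomp(arm) + 58 bp
  toy <- make_toy_plastome(
    toy_spec(len_a = 111, len_b = 20, len_c = 69, arm_len = 11,
             len_ssc = 150, len_ir = 200, seed = 5)
  )
  part <- toy$partition
  expect_equal(interval_len(part$area_a), 111L)
  expect_equal(interval_len(part$area_b), 20L)
  expect_equal(interval_len(part$area_c), 69L)
  expect_equal(
    interval_len(part$area_a) + interval_len(part$area_b) + interval_len(part$area_c),
    interval_len(toy$structure$lsc)
  )
  expect_equal(toy$structure$length, 111 + 20 + 69 + 150 + 2 * 200)
})

test_that("partition boundary case: left arm abutting the LSC start", {
  set.seed(41)
  arm <- "ACGGTCAATCG"
  b <- "TTGACCAGTCAGGTCCAATG"
  ctail <- random_dna(60)
  lsc <- paste0(arm, b, reverse_complement(arm), ctail)
  ir <- random_dna(200); ssc <- random_dna(150)
  if (reverse_complement(ssc) < ssc) ssc <- reverse_complement(ssc)
  st <- plastome_structure(paste0(lsc, ir, ssc, reverse_complement(ir)),
                           lsc_len = nchar(lsc), ir_len = 200, ssc_len = 150)
  part <- partition_lsc(st, list(left_start = 0, right_start = nchar(arm) + nchar(b),
                                 arm_len = nchar(arm), orientation = "inverted"))
  expect_equal(interval_len(part$area_a), nchar(arm))
})

test_that("partition rejects direct pairs and arms outside the LSC", {
  toy <- shared_toy()
  rp <- toy$partition$repeat_pair
  expect_error(
    partition_lsc(toy$structure, modifyList(rp, list(orientation = "direct"))),
    class = "psv_bad_input"
  )
  expect_error(
    partition_lsc(toy$structure, modifyList(rp, list(right_start = 2000))),
    class = "psv_bad_input"
  )
})

test_that("conformer sizes follow the closed forms and conserve mass", {
  toy <- shared_toy()
  n <- toy$structure$length
  la <- interval_len(toy$partition$area_a)
  lb <- interval_len(toy$partition$area_b)
  lc <- interval_len(toy$partition$area_c)
  ir <- interval_len(toy$structure$irb)

  confs <- enumerate_conformers(toy$structure, toy$partition)
  by_label <- setNames(confs, vapply(confs, `[[`, character(1), "label"))

  expect_equal(by_label[["A-type"]]$length, n + la - lc)
  expect_equal(by_label[["reciprocal"]]$length, n + lc - la)
  expect_equal(by_label[["B-inversion"]]$length, n)
  expect_equal(by_label[["flipflop-isomer"]]$length, n)
  expect_equal(by_label[["intermediate-dimer"]]$length, 2L * n)
  # mass conservation of the resolution
  expect_equal(by_label[["A-type"]]$length + by_label[["reciprocal"]]$length, 2L * n)

  # re-detection of the A-type: IR grows by |A|, residual single copy is B
  am <- by_label[["A-type"]]$predicted_metrics
  expect_equal(am$ir_size, ir + la)
  expect_equal(am$lsc_size, lb)
  expect_equal(am$ssc_size, interval_len(toy$structure$ssc))
})

test_that("B-inversion is an involution and the dimer is partitioned by P1/P2", {
  toy <- shared_toy()
  confs <- enumerate_conformers(toy$structure, toy$partition, metrics = FALSE)
  by_label <- setNames(confs, vapply(confs, `[[`, character(1), "label"))

  binv <- by_label[["B-inversion"]]$sequence
  st2 <- plastome_structure(binv, interval_len(toy$structure$lsc),
                            interval_len(toy$structure$irb), interval_len(toy$structure$ssc))
  part2 <- partition_lsc(st2, list(
    left_start = toy$partition$repeat_pair$left_start,
    right_start = toy$partition$repeat_pair$right_start,
    arm_len = toy$partition$repeat_pair$arm_len, orientation = "inverted"
  ))
  twice <- enumerate_conformers(st2, part2, metrics = FALSE)
  binv2 <- twice[[which(vapply(twice, `[[`, character(1), "label") == "B-inversion")]]
  expect_identical(binv2$sequence, toy$structure$sequence)

  # every base of the dimer lands in exactly one product. The reciprocal
  # is emitted on the opposite strand, so base-PAIR classes (A:T, G:C)
  # are the conserved quantity, together with the exact split at the
  # sequence level (the two split halves concatenate to the dimer up to
  # rotation/strand, checked via length and class counts).
  pair_counts <- function(s) {
    tb <- table(factor(strsplit(s, "")[[1]], c("A", "C", "G", "T")))
    c(at = tb[["A"]] + tb[["T"]], gc = tb[["C"]] + tb[["G"]])
  }
  d <- pair_counts(by_label[["intermediate-dimer"]]$sequence)
  p1 <- pair_counts(by_label[["A-type"]]$sequence)
  p2 <- pair_counts(by_label[["reciprocal"]]$sequence)
  expect_equal(d, p1 + p2)
})

test_that("gene changes: toy annotation with one gene per area", {
  genes <- data.frame(
    name = c("geneA", "geneB", "geneC"),
    area = c("A", "B", "C"),
    type = "protein"
  )
  toy <- make_toy_plastome(toy_spec(seed = 9, genes = genes))
  rep <- predict_gene_changes(toy$partition, "A-type", toy$annotation,
                              genome_length = toy$structure$length)
  expect_identical(rep$deleted$name, "geneC")
  expect_identical(rep$duplicated$name, "geneA")
  expect_equal(rep$unchanged_count, 1L)
  expect_equal(nrow(rep$disrupted), 0L)
  # exclusivity: deleted + duplicated + unchanged == all
  expect_equal(nrow(rep$deleted) + nrow(rep$duplicated) + rep$unchanged_count, 3L)

  # the reciprocal product mirrors the deletion
  rec <- predict_gene_changes(toy$partition, "reciprocal", toy$annotation)
  expect_identical(rec$deleted$name, "geneA")
  expect_identical(rec$duplicated$name, "geneC")
})

test_that("gene changes: empty annotation, bad labels, out-of-range genes", {
  toy <- shared_toy()
  empty <- predict_gene_changes(toy$partition, "A-type", data.frame())
  expect_equal(nrow(empty$deleted), 0L)
  expect_equal(empty$unchanged_count, 0L)
  expect_error(predict_gene_changes(toy$partition, "Z-type", data.frame()),
               class = "psv_bad_input")
  bad <- data.frame(name = "g", start = 1, end = 99999, type = "protein")
  expect_error(
    predict_gene_changes(toy$partition, "A-type", bad, genome_length = toy$structure$length),
    class = "psv_bad_input"
  )
})

test_that("boundary-spanning genes are reported as disrupted", {
  toy <- shared_toy()
  bstart <- toy$partition$area_b$start
  ann <- data.frame(
    name = "span_ab", start = bstart - 5L, end = bstart + 6L, type = "protein"
  )
  rep <- predict_gene_changes(toy$partition, "A-type", ann)
  expect_identical(rep$disrupted$name, "span_ab")
})

test_that("unique gene counts drop by the distinct deleted names per type", {
  # gene complement with four genes in area C (3 protein + 1 tRNA)
  genes <- rbind(
    data.frame(name = sprintf("gene%02d", 1:10), area = "A", type = "protein"),
    data.frame(name = c("psbA", "matK", "rps16"), area = "C", type = "protein"),
    data.frame(name = "trnK", area = "C", type = "tRNA"),
    data.frame(name = c("trn1", "trn2"), area = "SSC", type = "tRNA"),
    data.frame(name = "rrn16", area = "SSC", type = "rRNA")
  )
  toy <- make_toy_plastome(toy_spec(seed = 21, genes = genes))
  rep <- predict_gene_changes(toy$partition, "A-type", toy$annotation)
  expect_setequal(rep$deleted$name, c("psbA", "matK", "rps16", "trnK"))
  expect_equal(unname(rep$unique_counts_before), c(13L, 3L, 1L))
  expect_equal(unname(rep$unique_counts_after), c(10L, 2L, 1L))
})
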