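# interface: configuration, pipeline composition, report rendering, CLI.

write_toy_inputs <- function(toy, dir, prop_a = NULL, depth = 150, seed = 20) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "parent.fasta")
  write_fasta(c(toyref = toy$structure$sequence), fa)
  out <- list(fasta = fa)
  if (!is.null(prop_a)) {
    atype <- splice_conformer(toy, "A-type")
    sim <- simulate_reads(c(parent = toy$structure$sequence, atype = atype),
                          c(1 - prop_a, prop_a), depth = depth, seed = seed)
    paths <- write_read_set(sim, file.path(dir, "sim"))
    out$reads1 <- paths[1]; out$reads2 <- paths[2]
  }
  out
}

test_that("config validates bounds and round-trips through its file form", {
  expect_error(run_config(min_arm = 2), class = "psv_bad_config")
  expect_error(run_config(min_spacer = 10, max_spacer = 5), class = "psv_bad_config")
  expect_error(run_config(reference = "nope.fasta"), class = "psv_missing_file")

  dir <- withr::local_tempdir()
  toy <- shared_toy()
  inputs <- write_toy_inputs(toy, dir)
  cfg <- run_config(reference = inputs$fasta, outdir = file.path(dir, "out"),
                    min_ir_len = 200, min_arm = 9, trim = 25, seed = 4)
  path <- file.path(dir, "cfg.txt")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("pipeline on a reference alone reports structure and predictions only", {
  dir <- withr::local_tempdir()
  toy <- shared_toy()
  inputs <- write_toy_inputs(toy, dir)
  cfg <- run_config(reference = inputs$fasta, outdir = file.path(dir, "out"),
                    min_ir_len = 200, max_spacer = 400)
  report <- suppressMessages(run_pipeline(cfg))

  expect_true(any(grepl("no reads provided", report$notices)))
  expect_true(any(grepl("heteroplasmy skipped", report$notices)))
  expect_null(report$stages$heteroplasmy)
  expect_equal(report$stages$structure$genome_size, toy$structure$length)
  expect_equal(report$stages$conformers$partition[["area_b"]], 92L)
  atype_size <- report$stages$conformers$table$size[
    report$stages$conformers$table$label == "A-type"
  ]
  expect_equal(atype_size, toy$structure$length + 600 - 500)
  expect_true(file.exists(file.path(cfg$outdir, "structure.json")))
  expect_true(file.exists(file.path(cfg$outdir, "conformers.fasta")))
  expect_true(file.exists(file.path(cfg$outdir, "report.json")))

  lines <- render_report(report)
  expect_false(any(grepl("-- heteroplasmy --", lines, fixed = TRUE)))
  expect_identical(render_report(report), lines)  # deterministic regeneration
})

test_that("toy end-to-end run recovers the mixture and junction support", {
  dir <- withr::local_tempdir()
  toy <- shared_toy()
  inputs <- write_toy_inputs(toy, dir, prop_a = 0.7, depth = 150, seed = 20)
  cfg <- run_config(
    reference = inputs$fasta, reads1 = inputs$reads1, reads2 = inputs$reads2,
    outdir = file.path(dir, "out"), min_ir_len = 200, max_spacer = 400,
    trim = 25, max_mismatch = 1, min_overhang = 20
  )
  report <- suppressMessages(run_pipeline(cfg))

  h <- report$stages$heteroplasmy
  expect_lt(abs(h$prop_a - 0.7), 0.12)
  sup <- report$stages$junction_support
  expect_gt(sup$n_spanning[sup$junction == "a-type"], 0L)
  expect_gt(sup$n_spanning[sup$junction == "parent"], 0L)
  expect_equal(sup$n_spanning[sup$junction == "inversion"], 0L)
  expect_true(all(h$presence$present))

  lines <- render_report(report)
  expect_true(any(grepl("rearranged depth", lines)))
  # every rendered number is traceable: spot-check the A-type size line
  expect_true(any(grepl(
    as.character(report$stages$conformers$table$size[
      report$stages$conformers$table$label == "A-type"
    ]), lines
  )))
})

test_that("a depth table can replace reads, with reference-name checking", {
  dir <- withr::local_tempdir()
  toy <- shared_toy()
  inputs <- write_toy_inputs(toy, dir)
  prof <- depth_profile(rep(80, toy$structure$length), name = "toyref")
  dt <- file.path(dir, "depth.tsv")
  write_depth_table(prof, dt)
  cfg <- run_config(reference = inputs$fasta, depth_table = dt,
                    outdir = file.path(dir, "out"), min_ir_len = 200,
                    max_spacer = 400, trim = 25)
  report <- suppressMessages(run_pipeline(cfg))
  expect_equal(report$stages$heteroplasmy$depth_g, 80)
  expect_equal(report$stages$heteroplasmy$prop_g, 1)

  bad <- depth_profile(rep(80, toy$structure$length), name = "wrongname")
  write_depth_table(bad, dt)
  expect_error(suppressMessages(run_pipeline(cfg)), class = "psv_bad_input")
})

test_that("GFF3 and TSV annotations are read equivalently", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "ann.gff3")
  writeLines(c(
    "##gff-version 3",
    "toyref\tsrc\tgene\t10\t50\t.\t+\t.\tID=g1;Name=psbA",
    "toyref\tsrc\tgene\t60\t90\t.\t-\t.\tID=g2;Name=trnK",
    "toyref\tsrc\texon\t10\t30\t.\t+\t.\tID=e1"
  ), gff)
  ann <- read_annotation(gff)
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$name, c("psbA", "trnK"))
  expect_equal(ann$type[ann$name == "trnK"], "tRNA")
  expect_equal(ann$type[ann$name == "psbA"], "protein")

  tsv <- file.path(dir, "ann.tsv")
  utils::write.table(ann, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_annotation(tsv), ann)
})

test_that("the CLI runs the pipeline end to end in-process", {
  dir <- withr::local_tempdir()
  toy <- shared_toy()
  inputs <- write_toy_inputs(toy, dir)
  out <- capture.output(status <- suppressMessages(psv_main(c(
    "run", "--reference", inputs$fasta, "--outdir", file.path(dir, "cli_out"),
    "--min_ir_len", "200", "--max_spacer", "400"
  ))))
  expect_equal(status, 0L)
  expect_true(any(grepl("A-type", out)))
  capture.output(bad_status <- suppressMessages(psv_main("no-such-subcommand")))
  expect_equal(bad_status, 1L)
})
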