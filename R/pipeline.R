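# End-to-end pipeline: structure -> repeats -> partition -> conformers ->
# gene changes -> junctions -> heteroplasmy, with stages skipped when their
# inputs are absent. All results land in a machine-readable run report;
# rendering to a human-readable table is a separate, deterministic step.

#' Assemble and validate a pipeline configuration
#'
#' @param reference Path to the parent plastome FASTA (required for
#'   [run_pipeline()]).
#' @param annotation Optional gene annotation (GFF3 or TSV with columns
#'   name, start, end, type).
#' @param reads1,reads2 Optional FASTQ paths (single or paired).
#' @param depth_table Optional three-column per-base depth table; used
#'   instead of mapping `reads1`/`reads2` when present.
#' @param outdir Output directory (created if missing).
#' @param min_ir_len Minimum large-IR arm length for structure detection.
#' @param min_arm,max_arm,min_spacer,max_spacer Short-repeat scan bounds.
#' @param flank_len Junction flank length.
#' @param min_overhang Override for the per-junction spanning overhang
#'   (`NULL` keeps the per-junction defaults).
#' @param max_mismatch Mismatch tolerance for junction matching and read
#'   mapping.
#' @param trim Region end-trim for depth estimation.
#' @param threshold_depth,threshold_reads Presence-call thresholds.
#' @param seed Seed for any randomized step.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(reference = NULL, annotation = NULL, reads1 = NULL,
                       reads2 = NULL, depth_table = NULL, outdir = tempfile("psv_run_"),
                       min_ir_len = 1000L, min_arm = 8L, max_arm = 50L,
                       min_spacer = 0L, max_spacer = 10000L, flank_len = 300L,
                       min_overhang = NULL, max_mismatch = 0L, trim = 50L,
                       threshold_depth = 2, threshold_reads = 2L, seed = 1L) {
  cfg <- list(
    reference = reference, annotation = annotation, reads1 = reads1,
    reads2 = reads2, depth_table = depth_table, outdir = outdir,
    min_ir_len = as.integer(min_ir_len), min_arm = as.integer(min_arm),
    max_arm = as.integer(max_arm), min_spacer = as.integer(min_spacer),
    max_spacer = as.integer(max_spacer), flank_len = as.integer(flank_len),
    min_overhang = if (is.null(min_overhang)) NULL else as.integer(min_overhang),
    max_mismatch = as.integer(max_mismatch), trim = as.integer(trim),
    threshold_depth = as.numeric(threshold_depth),
    threshold_reads = as.integer(threshold_reads), seed = as.integer(seed)
  )
  if (cfg$min_arm < 4L || cfg$min_arm > cfg$max_arm) {
    psv_error("psv_bad_config", "need 4 <= min_arm <= max_arm")
  }
  if (cfg$min_spacer < 0L || cfg$min_spacer > cfg$max_spacer) {
    psv_error("psv_bad_config", "need 0 <= min_spacer <= max_spacer")
  }
  if (cfg$min_ir_len < 50L) psv_error("psv_bad_config", "min_ir_len must be >= 50")
  if (cfg$flank_len < 1L) psv_error("psv_bad_config", "flank_len must be >= 1")
  for (f in c("reference", "annotation", "reads1", "reads2", "depth_table")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      psv_error("psv_missing_file", sprintf("%s file not found: %s", f, cfg[[f]]))
    }
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as key=value text
#'
#' The on-disk form round-trips losslessly through [read_run_config()].
#'
#' @param config A [run_config()].
#' @param path Config file path.
#' @return Invisibly, `path` (write) or the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1))
  writeLines(sprintf("%s=%s", names(config)[keep], unlist(config[keep])), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  args <- stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, character(1), 1L))
  num <- c("min_ir_len", "min_arm", "max_arm", "min_spacer", "max_spacer",
           "flank_len", "min_overhang", "max_mismatch", "trim",
           "threshold_depth", "threshold_reads", "seed")
  args[names(args) %in% num] <- lapply(args[names(args) %in% num], as.numeric)
  do.call(run_config, args)
}

psv_log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Read a gene annotation (GFF3 or TSV)
#'
#' GFF3 files (`.gff`/`.gff3`) are parsed with [ape::read.gff()]; `gene`
#' features are kept, named from the `Name`/`ID`/`gene` attribute, and
#' typed by the plastid naming convention (`trn*` tRNA, `rrn*` rRNA,
#' otherwise protein). Any other extension is read as TSV with columns
#' `name`, `start`, `end`, `type`.
#'
#' @param path Annotation path.
#' @return Data frame: name, start, end (1-based inclusive), type.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) psv_error("psv_missing_file", sprintf("annotation not found: %s", path))
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- tryCatch(ape::read.gff(path), error = function(e) {
      psv_error("psv_parse_error", sprintf("malformed GFF3 %s: %s", path, conditionMessage(e)))
    })
    g <- g[g$type == "gene", , drop = FALSE]
    name <- sub(".*(?:Name|gene)=([^;]+).*", "\\1", g$attributes)
    noname <- !grepl("(?:Name|gene)=", g$attributes)
    name[noname] <- sub(".*ID=([^;]+).*", "\\1", g$attributes[noname])
    type <- ifelse(grepl("^trn", name, ignore.case = TRUE), "tRNA",
                   ifelse(grepl("^rrn", name, ignore.case = TRUE), "rRNA", "protein"))
    return(data.frame(name = name, start = g$start, end = g$end, type = type))
  }
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) psv_error("psv_parse_error", sprintf(
      "malformed annotation table %s: %s", path, conditionMessage(e)
    ))
  )
  if (!all(c("name", "start", "end", "type") %in% names(tab))) {
    psv_error("psv_parse_error", sprintf("annotation %s needs columns name, start, end, type", path))
  }
  tab[c("name", "start", "end", "type")]
}

#' Run the full analysis pipeline
#'
#' Executes structure detection, short-repeat scanning, LSC partitioning,
#' conformer enumeration (with gene changes when an annotation is given),
#' junction construction and - when reads or a depth table are supplied -
#' junction support counting and heteroplasmy estimation. Stages whose
#' inputs are absent are skipped with a notice in the report. Outputs are
#' written under `config$outdir`; the machine-readable run report is
#' returned and saved as `report.json`.
#'
#' @param config A [run_config()].
#' @return The run report (list of class `run_report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$reference)) psv_error("psv_bad_config", "a reference FASTA is required")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config), notices = character(0), stages = list())

  psv_log("stage structure: %s", config$reference)
  seqs <- read_fasta(config$reference)
  ref_name <- names(seqs)[1]
  st <- detect_quadripartite(seqs[1], min_ir_len = config$min_ir_len, name = ref_name)
  metrics <- compute_metrics(st)
  write_structure_json(st, file.path(config$outdir, "structure.json"))
  write_structure_bed(st, file.path(config$outdir, "structure.bed"))
  report$stages$structure <- list(
    name = st$name, regions = structure_region_table(st, metrics),
    genome_size = metrics$genome_size, gc_total = metrics$gc_total
  )

  psv_log("stage repeats: scanning LSC (min_arm %d)", config$min_arm)
  lsc_seq <- interval_seq(st$sequence, st$lsc)
  pairs <- find_repeat_pairs(
    lsc_seq, min_arm = config$min_arm, max_arm = config$max_arm,
    min_spacer = config$min_spacer, max_spacer = config$max_spacer,
    orientation = "inverted"
  )
  write_repeat_report(pairs, file.path(config$outdir, "repeats.tsv"))
  report$stages$repeats <- list(n_pairs = nrow(pairs), table = write_repeat_report(pairs))

  if (nrow(pairs) == 0L) {
    report$notices <- c(report$notices, "no inverted repeat pair in the LSC: conformer stages skipped")
    return(finish_report(report, config))
  }

  # substrate choice: longest arm, then smallest spacer, then leftmost
  best <- pairs[order(-pairs$arm_len, pairs$spacer_len, pairs$left_start), ][1L, ]
  part <- partition_lsc(st, best)
  ann <- if (!is.null(config$annotation)) read_annotation(config$annotation) else NULL

  psv_log("stage conformers: partition |A| %d |B| %d |C| %d",
          interval_len(part$area_a), interval_len(part$area_b), interval_len(part$area_c))
  confs <- enumerate_conformers(st, part, annotation = ann)
  write_conformers_fasta(confs, file.path(config$outdir, "conformers.fasta"))
  report$stages$conformers <- list(
    partition = c(
      area_a = interval_len(part$area_a), area_b = interval_len(part$area_b),
      area_c = interval_len(part$area_c)
    ),
    repeat_pair = part$repeat_pair[c("arm_len", "left_start", "right_start", "spacer_len", "left_seq")],
    table = data.frame(
      label = vapply(confs, `[[`, character(1), "label"),
      size = vapply(confs, `[[`, integer(1), "length"),
      lsc = vapply(confs, function(x) as.integer(x$predicted_metrics$lsc_size), integer(1)),
      ssc = vapply(confs, function(x) as.integer(x$predicted_metrics$ssc_size), integer(1)),
      ir = vapply(confs, function(x) as.integer(x$predicted_metrics$ir_size), integer(1))
    )
  )
  if (!is.null(ann)) {
    gch <- predict_gene_changes(part, "A-type", ann, genome_length = st$length)
    write_gene_changes_tsv(gch, file.path(config$outdir, "gene_changes_a_type.tsv"))
    report$stages$gene_changes <- list(
      deleted = gch$deleted$name,
      unique_before = gch$unique_counts_before,
      unique_after = gch$unique_counts_after
    )
  }

  psv_log("stage junctions: flank %d bp", config$flank_len)
  refs <- build_junction_refs(st, part, flank_len = config$flank_len)
  write_junctions_fasta(refs, file.path(config$outdir, "junctions.fasta"))
  report$stages$junctions <- list(labels = names(refs))

  reads <- NULL
  if (!is.null(config$reads1)) {
    reads <- read_fastq(config$reads1)
    if (!is.null(config$reads2)) reads <- c(reads, read_fastq(config$reads2))
  }

  if (!is.null(reads)) {
    psv_log("stage junction support: %d reads", length(reads))
    sup <- junction_support_table(
      refs, reads, min_overhang = config$min_overhang, max_mismatch = config$max_mismatch
    )
    write_support_tsv(sup, file.path(config$outdir, "junction_support.tsv"))
    report$stages$junction_support <- sup
  } else {
    report$notices <- c(report$notices, "no reads provided: junction support skipped")
  }

  profile <- NULL
  if (!is.null(config$depth_table)) {
    profile <- read_depth_table(config$depth_table, ref_len = st$length)
    if (profile$name != ref_name) {
      psv_error("psv_bad_input", sprintf(
        "depth table reference '%s' does not match FASTA record '%s'", profile$name, ref_name
      ))
    }
  } else if (!is.null(reads)) {
    psv_log("stage depth: mapping %d reads", length(reads))
    profile <- map_reads_depth(reads, st$sequence, max_mismatch = max(2L, config$max_mismatch),
                               name = ref_name)
  }

  if (!is.null(profile)) {
    psv_log("stage heteroplasmy: trim %d", config$trim)
    est <- estimate_heteroplasmy(profile, part, st, trim = config$trim)
    write_estimate_report(est, file.path(config$outdir, "heteroplasmy.json"))
    sup_list <- NULL
    if (!is.null(reads)) {
      sup_list <- list(
        parent = count_spanning_reads(refs[["parent"]], reads, max_mismatch = config$max_mismatch),
        alt = count_spanning_reads(refs[["a-type"]], reads, max_mismatch = config$max_mismatch)
      )
    }
    presence <- detect_presence(
      est, sup_list, threshold_depth = config$threshold_depth,
      threshold_reads = config$threshold_reads
    )
    report$stages$heteroplasmy <- list(
      depth_g = est$depth_g, depth_a = est$depth_a,
      prop_g = est$prop_g, prop_a = est$prop_a,
      se_prop_a = est$se_prop_a, flags = est$flags,
      presence = presence
    )
  } else {
    report$notices <- c(report$notices, "no reads or depth table: heteroplasmy skipped")
  }

  finish_report(report, config)
}

finish_report <- function(report, config) {
  report <- structure(report, class = "run_report")
  path <- file.path(config$outdir, "report.json")
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, force = TRUE, null = "null"), path)
  report
}

#' Render a run report as a human-readable summary
#'
#' Deterministic, two-column (parent vs rearranged) table in the style of
#' a plastome summary table; sections whose stages were skipped are
#' omitted. Regenerating from the same report is byte-identical.
#'
#' @param report A [run_pipeline()] result.
#' @return Character vector of lines (also printed invisibly friendly).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  out <- character(0)
  add <- function(...) out <<- c(out, sprintf(...))
  stg <- report$stages

  add("== plastome structural variation report ==")
  if (!is.null(stg$structure)) {
    add("-- structure: %s --", stg$structure$name)
    reg <- stg$structure$regions
    for (i in seq_len(nrow(reg))) {
      add("  %-4s %8d..%-8d %7d bp  GC %.3f",
          reg$region[i], reg$start[i], reg$end[i], reg$length[i], reg$gc[i])
    }
    add("  genome %d bp, GC %.3f", stg$structure$genome_size, stg$structure$gc_total)
  }
  if (!is.null(stg$repeats)) {
    add("-- short inverted repeats in LSC: %d pair(s) --", stg$repeats$n_pairs)
  }
  if (!is.null(stg$conformers)) {
    p <- stg$conformers$partition
    add("-- partition: |A| %d, |B| %d, |C| %d (arm %s: %s) --",
        p[["area_a"]], p[["area_b"]], p[["area_c"]],
        stg$conformers$repeat_pair$arm_len, stg$conformers$repeat_pair$left_seq)
    tab <- stg$conformers$table
    add("  %-18s %9s %9s %9s %9s", "conformer", "size", "LSC", "SSC", "IR")
    parent_row <- sprintf("  %-18s %9d %9d %9d %9d", "parent",
                          stg$structure$genome_size,
                          stg$structure$regions$length[1],
                          stg$structure$regions$length[3],
                          stg$structure$regions$length[2])
    out <- c(out, parent_row)
    for (i in seq_len(nrow(tab))) {
      add("  %-18s %9d %9s %9s %9s", tab$label[i], tab$size[i],
          ifelse(is.na(tab$lsc[i]), "-", tab$lsc[i]),
          ifelse(is.na(tab$ssc[i]), "-", tab$ssc[i]),
          ifelse(is.na(tab$ir[i]), "-", tab$ir[i]))
    }
  }
  if (!is.null(stg$gene_changes)) {
    add("-- A-type gene changes --")
    add("  deleted: %s", paste(stg$gene_changes$deleted, collapse = ", "))
    add("  unique protein/tRNA/rRNA: %s -> %s",
        paste(stg$gene_changes$unique_before, collapse = "/"),
        paste(stg$gene_changes$unique_after, collapse = "/"))
  }
  if (!is.null(stg$junction_support)) {
    add("-- junction support --")
    js <- stg$junction_support
    for (i in seq_len(nrow(js))) {
      add("  %-12s spanning %6d  partial %6d (overhang %d)",
          js$junction[i], js$n_spanning[i], js$n_partial[i], js$min_overhang[i])
    }
  }
  if (!is.null(stg$heteroplasmy)) {
    h <- stg$heteroplasmy
    add("-- heteroplasmy --")
    add("  parent depth %.1fx (prop %.3f)", h$depth_g, h$prop_g)
    add("  rearranged depth %.1fx (prop %.3f, se %.3f)", h$depth_a, h$prop_a, h$se_prop_a)
    pres <- h$presence
    for (i in seq_len(nrow(pres))) {
      add("  %s: %s", pres$conformer[i], ifelse(pres$present[i], "present", "absent"))
    }
  }
  for (n in report$notices) add("note: %s", n)
  out
}

# ---- minimal CLI -----------------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `structure`, `repeats`, `conformers`, `junctions`,
#' `heteroplasmy`, `simulate`, `run`, `report`. Flags mirror
#' [run_config()] fields (`--reference x.fa --outdir out ...`); `--config
#' file` loads a key=value config first. Installed as
#' `inst/cli/plastomesv.R`; callable in-process for testing.
#'
#' @param args Character vector of CLI arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
psv_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: plastomesv <structure|repeats|conformers|junctions|heteroplasmy|simulate|run|report> [--flag value ...]\n")
    return(invisible(1L))
  }
  sub <- args[1L]
  flags <- parse_flags(args[-1L])

  cfg_args <- flags[names(flags) %in% names(formals(run_config))]
  if (!is.null(flags$config)) {
    base_cfg <- unclass(read_run_config(flags$config))
    cfg_args <- utils::modifyList(base_cfg[!vapply(base_cfg, is.null, logical(1))], cfg_args)
  }
  cfg <- do.call(run_config, cfg_args)

  status <- tryCatch({
    switch(sub,
      run = {
        rep <- run_pipeline(cfg)
        cat(render_report(rep), sep = "\n")
        0L
      },
      structure = {
        seqs <- read_fasta(cfg$reference)
        st <- detect_quadripartite(seqs[1], min_ir_len = cfg$min_ir_len, name = names(seqs)[1])
        cat(write_structure_json(st), "\n")
        0L
      },
      repeats = {
        seqs <- read_fasta(cfg$reference)
        st <- detect_quadripartite(seqs[1], min_ir_len = cfg$min_ir_len, name = names(seqs)[1])
        pairs <- find_repeat_pairs(
          interval_seq(st$sequence, st$lsc), min_arm = cfg$min_arm, max_arm = cfg$max_arm,
          min_spacer = cfg$min_spacer, max_spacer = cfg$max_spacer, orientation = "inverted"
        )
        utils::write.table(write_repeat_report(pairs), sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      conformers = , junctions = , heteroplasmy = {
        rep <- run_pipeline(cfg)
        cat(render_report(rep), sep = "\n")
        0L
      },
      simulate = {
        toy <- make_toy_plastome(toy_spec(seed = cfg$seed))
        prop_a <- if (is.null(flags$prop_a)) 0.5 else as.numeric(flags$prop_a)
        depth <- if (is.null(flags$depth)) 100 else as.numeric(flags$depth)
        sim <- simulate_reads(
          c(parent = toy$structure$sequence, `A-type` = splice_conformer(toy, "A-type")),
          mixture = c(1 - prop_a, prop_a), depth = depth, seed = cfg$seed
        )
        dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
        write_fasta(c(parent = toy$structure$sequence), file.path(cfg$outdir, "parent.fasta"))
        write_read_set(sim, file.path(cfg$outdir, "sim"))
        psv_log("wrote simulated reads to %s", cfg$outdir)
        0L
      },
      report = {
        rep <- jsonlite::fromJSON(file.path(cfg$outdir, "report.json"), simplifyVector = TRUE)
        cat(sprintf("run report with %d stage(s)\n", length(rep$stages)))
        0L
      },
      {
        cat(sprintf("unknown subcommand '%s'\n", sub))
        1L
      }
    )
  }, plastomeSV_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        out[[key]] <- args[i + 1L]; i <- i + 2L
      } else {
        out[[key]] <- TRUE; i <- i + 1L
      }
    } else i <- i + 1L
  }
  out
}
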