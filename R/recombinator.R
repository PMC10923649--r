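# Recombination conformers of a quadripartite plastome.
#
# A short inverted repeat pair inside the LSC partitions it into area A
# (LSC start through the left arm), area B (the spacer) and area C (the
# right arm through the LSC end). Recombination at that pair, alone or
# combined with recombination at the large IR, generates a family of
# circular conformers:
#
#   B-inversion        intramolecular crossover at the short pair; area B
#                      is reverse-complemented in place (size unchanged)
#   intermediate-dimer head-to-head fusion of two parent circles through
#                      the short pair (size 2 x parent)
#   A-type             resolution product duplicating area A into the IR;
#                      area C is lost, area B is the residual single-copy
#                      (size parent + |A| - |C|)
#   reciprocal         the mass-conservation partner, duplicating area C
#                      and losing area A (size parent + |C| - |A|)
#   flipflop-isomer    intramolecular crossover at the large IR; the SSC
#                      is reverse-complemented (size unchanged)
#
# Crossover conventions (the printed-size bookkeeping): breakpoints sit at
# the arm's left edge and one arm copy survives in each product, so
# |A| + |B| + |C| = LSC with the arms counted inside A and C.

#' Partition an LSC around an inverted repeat pair into areas A, B, C
#'
#' Area A runs from the LSC start through the end of the left arm
#' (inclusive of the arm), area B is the spacer between the arms, and area
#' C runs from the start of the right arm through the LSC end. Both arms
#' must lie wholly inside the LSC and the pair must be inverted (direct
#' pairs mediate a different event class).
#'
#' @param structure A [plastome_structure()] in canonical rotation.
#' @param repeat_pair A one-row `repeat_table` row or list with 0-based
#'   `left_start`, `right_start`, `arm_len`, `orientation`, in LSC
#'   coordinates (equal to genome coordinates in canonical rotation).
#' @return An object of class `segment_partition` with intervals `area_a`,
#'   `area_b`, `area_c` (genome coordinates) and the repeat pair.
#' @export
partition_lsc <- function(structure, repeat_pair) {
  stopifnot(inherits(structure, "plastome_structure"))
  p <- as.list(repeat_pair)
  if (!identical(p$orientation, "inverted")) {
    psv_error("psv_bad_input", "partitioning requires an inverted repeat pair (direct pairs are out of scope)")
  }
  lsc_len <- interval_len(structure$lsc)
  i <- as.integer(p$left_start); j <- as.integer(p$right_start); m <- as.integer(p$arm_len)
  if (i < 0L || j + m > lsc_len || i + m > j) {
    psv_error("psv_bad_input", "repeat arms must lie wholly inside the LSC, left arm strictly first")
  }
  left_seq <- substr(structure$sequence, i + 1L, i + m)
  right_seq <- substr(structure$sequence, j + 1L, j + m)
  if (!identical(right_seq, reverse_complement(left_seq))) {
    psv_error("psv_bad_input", "right arm is not the reverse complement of the left arm")
  }
  part <- structure(list(
    area_a = interval(0L, i + m),
    area_b = interval(i + m, j),
    area_c = interval(j, lsc_len),
    repeat_pair = list(
      arm_len = m, left_start = i, left_end = i + m,
      right_start = j, right_end = j + m,
      orientation = "inverted", spacer_len = j - (i + m),
      left_seq = left_seq, right_seq = right_seq
    )
  ), class = "segment_partition")
  stopifnot(
    interval_len(part$area_a) + interval_len(part$area_b) + interval_len(part$area_c) == lsc_len
  )
  part
}

#' @export
print.segment_partition <- function(x, ...) {
  cat(sprintf(
    "<segment_partition> |A| %d, |B| %d, |C| %d (arm %d bp: %s / %s)\n",
    interval_len(x$area_a), interval_len(x$area_b), interval_len(x$area_c),
    x$repeat_pair$arm_len, x$repeat_pair$left_seq, x$repeat_pair$right_seq
  ))
  invisible(x)
}

# ---- recombination event operators ----------------------------------------
# These operate on explicit sequences + coordinates; enumerate_conformers
# composes them. The independent splice_conformer() in the synthetic-data
# module rebuilds the same molecules by formulaic concatenation of the
# generator's ground-truth pieces, so each construction checks the other.

# Intramolecular crossover at an inverted pair: reverse-complement the
# spacer [sp_start, sp_end) in place.
event_invert_spacer <- function(seq, sp_start, sp_end) {
  n <- nchar(seq)
  paste0(
    substr(seq, 1L, sp_start),
    reverse_complement(substr(seq, sp_start + 1L, sp_end)),
    substr(seq, sp_end + 1L, n)
  )
}

# Intermolecular crossover between two copies of a circle at an inverted
# pair: open copy 1 at the right arm's left edge, open copy 2 at the left
# arm's end and take its other strand, then join head-to-head.
event_fuse_at_inverted_pair <- function(seq, left_arm_end, right_arm_start) {
  lin1 <- rotate_seq(seq, right_arm_start)
  lin2 <- reverse_complement(rotate_seq(seq, left_arm_end))
  paste0(lin1, lin2)
}

# Intramolecular crossover at a direct pair: split the circle into two.
# Arms at [x, x+L) and [y, y+L) in the same orientation; each product
# keeps one arm copy.
event_resolve_at_direct_pair <- function(seq, x, y) {
  n <- nchar(seq)
  stopifnot(x < y, y <= n)
  list(
    substr(seq, x + 1L, y),                     # [x, y)
    paste0(substr(seq, y + 1L, n), substr(seq, 1L, x))  # [y, x) around the circle
  )
}

#' Enumerate the recombination conformers of a partitioned plastome
#'
#' Builds each conformer by composing explicit recombination events (see
#' the package vignette for the crossover conventions) and, optionally,
#' re-detects each product's quadripartite structure to obtain predicted
#' metrics. Products are emitted regardless of biological viability; if an
#' annotation is supplied, products whose lost region carries genes are
#' flagged, never suppressed. Degenerate products (empty area A or C) are
#' emitted with a `degenerate` flag.
#'
#' @param structure Parent [plastome_structure()].
#' @param partition A [partition_lsc()] result.
#' @param annotation Optional gene table (`name`, `start`, `end`, `type`,
#'   1-based inclusive on the parent canonical linearization) used for the
#'   viability flag and per-conformer gene-change reports.
#' @param metrics Re-detect quadripartite structure of each product
#'   (default `TRUE`). The single-copy region homologous to the parent SSC
#'   keeps the SSC label regardless of length (the A-type's residual LSC is
#'   far shorter than its SSC).
#' @return A list of `conformer` objects: `label`, `events`, `sequence`,
#'   `length`, `predicted_size` (closed form), `predicted_metrics`,
#'   `degenerate`, `viability`, `gene_changes`.
#' @export
enumerate_conformers <- function(structure, partition, annotation = NULL,
                                 metrics = TRUE) {
  stopifnot(inherits(structure, "plastome_structure"), inherits(partition, "segment_partition"))
  s <- structure$sequence
  n <- structure$length
  rp <- partition$repeat_pair
  la <- interval_len(partition$area_a)
  lb <- interval_len(partition$area_b)
  lc <- interval_len(partition$area_c)
  ir <- interval_len(structure$irb)
  ssc <- interval_len(structure$ssc)
  ssc_seq <- interval_seq(s, structure$ssc)

  # B-inversion: crossover at the short pair
  b_inv <- event_invert_spacer(s, partition$area_b$start, partition$area_b$end)

  # flip-flop isomer: crossover at the large IR (spacer = SSC)
  flip <- event_invert_spacer(s, structure$ssc$start, structure$ssc$end)

  # dimer: intermolecular crossover at the short pair
  dimer <- event_fuse_at_inverted_pair(s, partition$area_a$end, partition$area_c$start)

  # resolution at the two direct-orientation IRb copies of the dimer.
  # Dimer layout (by the fusion convention): C Ib S Ia A B rc(A) Ib rc(S)
  # Ia rc(C) rc(B); the IRb copies start at |C| and at |C|+ir+ssc+ir+la.
  x <- lc
  y <- lc + ir + ssc + ir + la + lb + la
  prods <- event_resolve_at_direct_pair(dimer, x, y)
  # product 1 = Ib S Ia A B rc(A): rotate to start at area A
  a_type <- rotate_seq(prods[[1L]], 2L * ir + ssc)
  # product 2 = Ib rc(S) Ia rc(C) rc(B) C: emit on the strand where the
  # parent SSC reads forward; that strand starts at rc(C)
  reciprocal <- reverse_complement(prods[[2L]])

  specs <- list(
    list(
      label = "B-inversion", sequence = b_inv, predicted_size = n,
      events = list(list(mechanism = "intramolecular", repeat_used = "short_pair",
                         crossover = "spacer inversion")),
      lost = NULL, gained = NULL
    ),
    list(
      label = "intermediate-dimer", sequence = dimer, predicted_size = 2L * n,
      events = list(list(mechanism = "intermolecular", repeat_used = "short_pair",
                         crossover = "head-to-head fusion, breakpoint at arm left edge")),
      lost = NULL, gained = NULL
    ),
    list(
      label = "A-type", sequence = a_type, predicted_size = n + la - lc,
      events = list(
        list(mechanism = "intermolecular", repeat_used = "short_pair",
             crossover = "head-to-head fusion, breakpoint at arm left edge"),
        list(mechanism = "intramolecular", repeat_used = "large_IR",
             crossover = "dimer resolution at direct IRb copies")
      ),
      lost = "area_c", gained = "area_a"
    ),
    list(
      label = "reciprocal", sequence = reciprocal, predicted_size = n + lc - la,
      events = list(
        list(mechanism = "intermolecular", repeat_used = "short_pair",
             crossover = "head-to-head fusion, breakpoint at arm left edge"),
        list(mechanism = "intramolecular", repeat_used = "large_IR",
             crossover = "dimer resolution at direct IRb copies")
      ),
      lost = "area_a", gained = "area_c"
    ),
    list(
      label = "flipflop-isomer", sequence = flip, predicted_size = n,
      events = list(list(mechanism = "intramolecular", repeat_used = "large_IR",
                         crossover = "SSC inversion")),
      lost = NULL, gained = NULL
    )
  )

  lapply(specs, function(sp) {
    conf <- structure(list(
      label = sp$label,
      events = sp$events,
      sequence = sp$sequence,
      length = nchar(sp$sequence),
      predicted_size = sp$predicted_size,
      parent = structure$name,
      degenerate = (identical(sp$lost, "area_c") && lc == 0L) ||
        (identical(sp$lost, "area_a") && la == 0L),
      predicted_metrics = NULL,
      viability = NULL,
      gene_changes = NULL
    ), class = "conformer")
    stopifnot(conf$length == conf$predicted_size)
    if (metrics) {
      conf$predicted_metrics <- conformer_metrics(sp$sequence, ir, ssc_seq, sp$label)
    }
    if (!is.null(annotation)) {
      gc <- predict_gene_changes(partition, sp$label, annotation)
      conf$gene_changes <- gc
      conf$viability <- list(
        n_genes_lost = length(gc$deleted$name),
        flagged = length(gc$deleted$name) > 0L
      )
    }
    conf
  })
}

# Quadripartite metrics of a conformer sequence, with the homology-based
# SSC label override. The dimer carries four IR copies and has no single
# quadripartite reading: its ambiguity condition is caught and reported.
conformer_metrics <- function(seq, parent_ir_len, parent_ssc_seq, label) {
  min_ir <- max(50L, parent_ir_len %/% 2L)
  st <- tryCatch(
    detect_quadripartite(seq, min_ir_len = min_ir, ssc_ref = parent_ssc_seq, name = label),
    psv_quadripartite_ambiguous = function(e) e,
    psv_no_quadripartite = function(e) e
  )
  if (inherits(st, "condition")) {
    return(structure(list(
      genome_size = nchar(seq), lsc_size = NA_integer_, ssc_size = NA_integer_,
      ir_size = NA_integer_, gc_total = gc_fraction(seq), gc_lsc = NA_real_,
      gc_ssc = NA_real_, gc_ir = NA_real_, note = conditionMessage(st)
    ), class = "structure_metrics"))
  }
  compute_metrics(st)
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf(
    "<conformer> %s: %d bp (parent %s)%s\n", x$label, x$length, x$parent,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""
  ))
  if (!is.null(x$predicted_metrics) && !is.na(x$predicted_metrics$lsc_size)) {
    print(x$predicted_metrics)
  }
  invisible(x)
}

# ---- gene gain/loss --------------------------------------------------------

#' Predict gene changes for a conformer
#'
#' For the A-type: genes overlapping area C by at least one base are
#' deleted; genes wholly inside area A are duplicated (area A moves into
#' the doubled IR); genes spanning an A/B or B/C boundary are additionally
#' reported as disrupted. The reciprocal product is the mirror image (area
#' A deleted, area C duplicated). Size-neutral conformers (B-inversion,
#' flip-flop isomer, dimer) delete nothing; for the B-inversion, genes
#' spanning an area-B boundary are reported as disrupted.
#'
#' @param partition A [partition_lsc()] result.
#' @param conformer_label One of `"A-type"`, `"reciprocal"`,
#'   `"B-inversion"`, `"intermediate-dimer"`, `"flipflop-isomer"`.
#' @param annotation Data frame with `name`, `start`, `end` (1-based
#'   inclusive, parent canonical linearization) and `type` (`protein`,
#'   `tRNA`, `rRNA`).
#' @param genome_length Optional parent genome length for coordinate
#'   validation.
#' @return An object of class `gene_change_report`: `deleted`,
#'   `duplicated`, `disrupted` gene tables, `unchanged_count`, and
#'   `unique_counts_before` / `unique_counts_after` per gene type.
#' @export
predict_gene_changes <- function(partition, conformer_label, annotation,
                                 genome_length = NULL) {
  stopifnot(inherits(partition, "segment_partition"))
  labels <- c("A-type", "reciprocal", "B-inversion", "intermediate-dimer", "flipflop-isomer")
  if (!conformer_label %in% labels) {
    psv_error("psv_bad_input", sprintf("unknown conformer label '%s'", conformer_label))
  }
  ann <- as.data.frame(annotation)
  required <- c("name", "start", "end", "type")
  if (nrow(ann) > 0L && !all(required %in% names(ann))) {
    psv_error("psv_bad_input", "annotation needs columns name, start, end, type")
  }
  if (nrow(ann) == 0L) {
    ann <- data.frame(name = character(0), start = integer(0), end = integer(0),
                      type = character(0))
  }
  if (!is.null(genome_length) && nrow(ann) > 0L &&
      (any(ann$start < 1L) || any(ann$end > genome_length))) {
    psv_error("psv_bad_input", "gene interval outside the genome")
  }
  # to 0-based half-open
  g_start <- as.integer(ann$start) - 1L
  g_end <- as.integer(ann$end)

  a <- partition$area_a; b <- partition$area_b; cc <- partition$area_c
  ov <- function(iv) g_start < iv$end & g_end > iv$start
  inside <- function(iv) g_start >= iv$start & g_end <= iv$end
  crosses <- function(x) g_start < x & g_end > x  # spans the boundary point x
  none <- rep(FALSE, nrow(ann))

  if (conformer_label == "A-type") {
    deleted <- ov(cc)
    duplicated_ <- !deleted & inside(a)
    disrupted <- crosses(a$end) | crosses(b$end)
  } else if (conformer_label == "reciprocal") {
    deleted <- ov(a)
    duplicated_ <- !deleted & inside(cc)
    disrupted <- crosses(a$end) | crosses(b$end)
  } else if (conformer_label == "B-inversion") {
    deleted <- none
    duplicated_ <- none
    disrupted <- crosses(b$start) | crosses(b$end)
  } else {  # dimer, flip-flop: content-neutral
    deleted <- none
    duplicated_ <- none
    disrupted <- none
  }
  unchanged <- !deleted & !duplicated_

  types <- c("protein", "tRNA", "rRNA")
  uniq_count <- function(mask) {
    vapply(types, function(tp) length(unique(ann$name[mask & ann$type == tp])), integer(1))
  }
  before <- uniq_count(rep(TRUE, nrow(ann)))
  after <- before - uniq_count(deleted)

  pick <- function(mask) ann[mask, c("name", "start", "end", "type"), drop = FALSE]
  structure(list(
    label = conformer_label,
    deleted = pick(deleted),
    duplicated = pick(duplicated_),
    disrupted = pick(disrupted),
    unchanged_count = sum(unchanged),
    unique_counts_before = before,
    unique_counts_after = after
  ), class = "gene_change_report")
}

#' @export
print.gene_change_report <- function(x, ...) {
  cat(sprintf(
    "<gene_change_report> %s: %d deleted, %d duplicated, %d disrupted, %d unchanged\n",
    x$label, nrow(x$deleted), nrow(x$duplicated), nrow(x$disrupted), x$unchanged_count
  ))
  if (nrow(x$deleted) > 0L) {
    cat("  deleted:", paste(x$deleted$name, collapse = ", "), "\n")
  }
  cat(sprintf(
    "  unique counts (protein/tRNA/rRNA): %s -> %s\n",
    paste(x$unique_counts_before, collapse = "/"),
    paste(x$unique_counts_after, collapse = "/")
  ))
  invisible(x)
}

#' Write conformers as multi-record FASTA
#'
#' @param conformers List from [enumerate_conformers()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_conformers_fasta <- function(conformers, path) {
  seqs <- vapply(conformers, `[[`, character(1), "sequence")
  names(seqs) <- vapply(conformers, `[[`, character(1), "label")
  write_fasta(seqs, path)
}

#' Write a gene-change report as TSV
#'
#' @param report A [predict_gene_changes()] result.
#' @param path Output path, or `NULL` to return the data frame.
#' @return The path (invisibly) or the data frame.
#' @export
write_gene_changes_tsv <- function(report, path = NULL) {
  rows <- rbind(
    cbind(report$deleted, status = if (nrow(report$deleted)) "deleted" else character(0)),
    cbind(report$duplicated, status = if (nrow(report$duplicated)) "duplicated" else character(0)),
    cbind(report$disrupted, status = if (nrow(report$disrupted)) "disrupted" else character(0))
  )
  if (is.null(path)) return(rows)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
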