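# Conformer-diagnostic junctions and junction-spanning read support.
#
# Each candidate conformation predicts a breakpoint adjacency absent from
# the other conformations. The existence test is read-based: build a short
# reference centred on the diagnostic core (area B, its reverse
# complement, or a deletion adjacency) with flanking sequence on each
# side, then count reads that cover the whole core plus a minimum overhang
# on both sides. The spanning criterion, not the mapper, is the method:
# matching is internal (k-mer anchor plus ungapped extension), no external
# aligner is required.

JUNCTION_DEFAULT_OVERHANG <- c(
  "parent" = 20L, "inversion" = 11L, "a-type" = 20L,
  "c-deletion" = 20L, "reciprocal" = 20L
)

#' Build junction reference sequences for a partitioned plastome
#'
#' Emits one reference per diagnostic breakpoint:
#' \describe{
#'   \item{parent}{area B in its parent context, `A-flank | B | C-flank`
#'     (supports the unrearranged molecule).}
#'   \item{inversion}{`A-flank | revcomp(B) | C-flank`, the intramolecular
#'     B-inversion hypothesis; default overhang 11 bp (the flanking short
#'     arms).}
#'   \item{a-type}{`A-flank | B | revcomp(A)-flank`, area B flanked on both
#'     sides by area-A context per the rearranged A-B-A structure.}
#'   \item{c-deletion}{the adjacency joining the sequences flanking area C
#'     (left context ending at the C start, right context starting at the
#'     C end); the diagnostic core is the zero-length join itself.}
#'   \item{reciprocal}{`revcomp(C)-flank | B | C-flank`, area B flanked by
#'     area-C context (the undetected reciprocal product).}
#' }
#' Flanks that would extend past their source region are truncated to the
#' available sequence and flagged.
#'
#' @param parent Parent [plastome_structure()].
#' @param partition A [partition_lsc()] result.
#' @param flank_len Flank length on each side of the core (default 300).
#' @return A named list of `junction_ref` objects (`label`, `sequence`,
#'   `core` interval on the reference, `flank_left`, `flank_right`,
#'   `truncated`, `default_overhang`).
#' @export
build_junction_refs <- function(parent, partition, flank_len = 300L) {
  stopifnot(inherits(parent, "plastome_structure"), inherits(partition, "segment_partition"))
  flank_len <- as.integer(flank_len)
  s <- parent$sequence
  a_seq <- interval_seq(s, partition$area_a)
  b_seq <- interval_seq(s, partition$area_b)
  c_seq <- interval_seq(s, partition$area_c)
  la <- nchar(a_seq); lb <- nchar(b_seq); lc <- nchar(c_seq)

  tail_a <- substr(a_seq, max(1L, la - flank_len + 1L), la)
  head_c <- substr(c_seq, 1L, min(flank_len, lc))
  fl_a <- nchar(tail_a); fl_c <- nchar(head_c)

  mk <- function(label, left, core, right) {
    structure(list(
      label = label,
      sequence = paste0(left, core, right),
      core = interval(nchar(left), nchar(left) + nchar(core)),
      flank_left = nchar(left), flank_right = nchar(right),
      truncated = nchar(left) < flank_len || nchar(right) < flank_len,
      default_overhang = unname(JUNCTION_DEFAULT_OVERHANG[label])
    ), class = "junction_ref")
  }

  # c-deletion: contexts adjacent to area C on the parent linearization
  # (left context may run back through B into A; right context runs into
  # the IRb, which starts at the LSC end)
  cstart <- partition$area_c$start
  cend <- partition$area_c$end
  del_left <- substr(s, max(1L, cstart - flank_len + 1L), cstart)
  del_right <- substr(s, cend + 1L, min(nchar(s), cend + flank_len))

  refs <- list(
    mk("parent", tail_a, b_seq, head_c),
    mk("inversion", tail_a, reverse_complement(b_seq), head_c),
    mk("a-type", tail_a, b_seq, reverse_complement(tail_a)),
    mk("c-deletion", del_left, "", del_right),
    mk("reciprocal", reverse_complement(head_c), b_seq, head_c)
  )
  stats::setNames(refs, vapply(refs, `[[`, character(1), "label"))
}

#' @export
print.junction_ref <- function(x, ...) {
  cat(sprintf(
    "<junction_ref> %s: %d bp (core %d bp, flanks %d/%d%s)\n",
    x$label, nchar(x$sequence), interval_len(x$core), x$flank_left, x$flank_right,
    if (x$truncated) ", truncated" else ""
  ))
  invisible(x)
}

#' Count reads spanning a junction
#'
#' A read supports the junction if it, or its reverse complement, aligns
#' ungapped to the junction reference so that the alignment covers the
#' full diagnostic core plus at least `min_overhang` bases on each side,
#' with at most `max_mismatch` substitutions over the whole aligned
#' intersection (read bases hanging off the reference ends are clipped).
#' Scoring the full intersection matters: the short repeat arms flanking
#' the core are shared between conformations, so reads from the wrong
#' conformation match exactly core + arms and are rejected only by the
#' sequence beyond the arms.
#' Alignment candidates come from exact k-mer anchors (k = 15) at
#' the read start, middle and end. Each read is counted at most once.
#' Reads that touch the core without satisfying the spanning criterion
#' (including reads shorter than the window) count as partial.
#'
#' @param ref A `junction_ref` from [build_junction_refs()].
#' @param reads Character vector of read sequences (orientation unknown),
#'   or a `simulated_reads` object (both mates are scored independently).
#' @param min_overhang Required overhang on each side of the core;
#'   defaults to the junction's `default_overhang` (20 bp, or 11 bp for the
#'   inversion junction).
#' @param max_mismatch Substitution tolerance inside the scored window
#'   (default 0).
#' @param anchor_k Anchor k-mer size (default 15).
#' @return An object of class `support_count`: `junction`, `n_spanning`,
#'   `n_partial`, `min_overhang`, `max_mismatch`, `n_reads`.
#' @export
count_spanning_reads <- function(ref, reads, min_overhang = NULL, max_mismatch = 0L,
                                 anchor_k = 15L) {
  stopifnot(inherits(ref, "junction_ref"))
  if (inherits(reads, "simulated_reads")) reads <- c(reads$reads1, reads$reads2)
  reads <- unname(as.character(reads))
  if (is.null(min_overhang)) min_overhang <- ref$default_overhang
  min_overhang <- as.integer(min_overhang)
  if (min_overhang > min(ref$flank_left, ref$flank_right)) {
    psv_error("psv_bad_input", "min_overhang exceeds an available flank")
  }

  rseq <- ref$sequence
  nref <- nchar(rseq)
  rraw <- charToRaw(rseq)
  k <- min(anchor_k, nref)
  index <- split(0:(nref - k), substring(rseq, 1:(nref - k + 1L), k:nref))

  win_start <- ref$core$start - min_overhang        # 0-based window on ref
  win_end <- ref$core$end + min_overhang
  win_len <- win_end - win_start

  n_spanning <- 0L
  n_partial <- 0L
  if (length(reads) > 0L) {
    rc_reads <- revcomp_many(reads)
    for (ri in seq_along(reads)) {
      verdict <- 0L  # 0 none, 1 partial, 2 spanning
      for (read in c(reads[ri], rc_reads[ri])) {
        L <- nchar(read)
        if (L < k) next
        offs <- unique(c(0L, (L - k) %/% 2L, L - k))
        cand <- integer(0)
        for (off in offs) {
          hits <- index[[substr(read, off + 1L, off + k)]]
          if (!is.null(hits)) cand <- c(cand, hits - off)
        }
        for (o in unique(cand)) {
          al_start <- max(0L, o)            # aligned interval on ref
          al_end <- min(nref, o + L)
          if (al_end <= al_start) next
          touches_core <- al_start < ref$core$end && al_end > ref$core$start
          spans <- al_start <= win_start && al_end >= win_end
          # mismatches are scored over the full aligned intersection: the
          # short arms flanking the core are shared between conformations,
          # so a window-only score would let reads from the other
          # conformation "span" exactly core + arms; the sequence beyond
          # the arms is what discriminates
          mm <- count_mismatches_raw(
            rraw, al_start, read, al_start - o, al_end - al_start
          )
          if (spans && mm <= max_mismatch) { verdict <- 2L; break }
          if (touches_core && verdict < 1L &&
              mm <= max(max_mismatch, ceiling((al_end - al_start) * 0.05))) {
            verdict <- 1L
          }
        }
        if (verdict == 2L) break
      }
      if (verdict == 2L) n_spanning <- n_spanning + 1L
      if (verdict == 1L) n_partial <- n_partial + 1L
    }
  }

  structure(list(
    junction = ref$label, n_spanning = n_spanning, n_partial = n_partial,
    min_overhang = min_overhang, max_mismatch = as.integer(max_mismatch),
    n_reads = length(reads)
  ), class = "support_count")
}

# Mismatches between ref[ref_start, ref_start+len) and
# read[read_start, read_start+len) (both 0-based starts).
count_mismatches_raw <- function(rraw, ref_start, read, read_start, len) {
  if (len <= 0L) return(0L)
  a <- rraw[(ref_start + 1L):(ref_start + len)]
  b <- charToRaw(substr(read, read_start + 1L, read_start + len))
  sum(a != b)
}

#' @export
print.support_count <- function(x, ...) {
  cat(sprintf(
    "<support_count> %s: %d spanning, %d partial (overhang %d, mismatch <= %d, %d reads)\n",
    x$junction, x$n_spanning, x$n_partial, x$min_overhang, x$max_mismatch, x$n_reads
  ))
  invisible(x)
}

#' Score a read set against several junctions
#'
#' Junctions are hypotheses tested independently: a read may support more
#' than one junction when cores share sequence; `cross_match` flags
#' junction pairs whose spanning sets could overlap (same core length and
#' shared flank).
#'
#' @param refs Named list from [build_junction_refs()].
#' @param reads Read set (see [count_spanning_reads()]).
#' @param min_overhang Optional single overhang overriding each junction's
#'   default.
#' @param max_mismatch Substitution tolerance (default 0).
#' @return Data frame: junction, n_spanning, n_partial, min_overhang,
#'   max_mismatch.
#' @export
junction_support_table <- function(refs, reads, min_overhang = NULL, max_mismatch = 0L) {
  rows <- lapply(refs, function(r) {
    sc <- count_spanning_reads(r, reads, min_overhang = min_overhang, max_mismatch = max_mismatch)
    data.frame(
      junction = sc$junction, n_spanning = sc$n_spanning, n_partial = sc$n_partial,
      min_overhang = sc$min_overhang, max_mismatch = sc$max_mismatch
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write junction references as FASTA
#'
#' @param refs Named list from [build_junction_refs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_junctions_fasta <- function(refs, path) {
  seqs <- vapply(refs, `[[`, character(1), "sequence")
  names(seqs) <- vapply(refs, `[[`, character(1), "label")
  write_fasta(seqs, path)
}

#' Write a junction support table as TSV
#'
#' @param table A [junction_support_table()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_support_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
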