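# Quadripartite structure of circular plastomes.
#
# A typical angiosperm plastome is a circle partitioned into a large
# single-copy region (LSC), one inverted-repeat copy (IRb), a small
# single-copy region (SSC) and the second, reverse-complementary repeat
# copy (IRa). Detection below finds the maximal-arm exact inverted repeat
# on the circle; the two gaps between its arms are the single-copy regions.

# ---- maximal circular inverted repeat pairs -------------------------------

# All maximal exact inverted-repeat pairs on a circular sequence with arm
# length >= min_len. Seed-and-extend over shared k-mers between the forward
# strand and its reverse complement; seeds on the same anti-diagonal
# ((a + b) mod n is constant along a pair) are collapsed so each physical
# pair is extended once. Returns a list of list(i, j, len) with 0-based arm
# start positions on the circle.
find_circular_inverted_pairs <- function(seq, min_len, k = 21L) {
  n <- nchar(seq)
  k <- min(k, min_len)
  if (n < 2L * k) return(list())
  sraw <- charToRaw(seq)

  doubled <- paste0(seq, substr(seq, 1L, k - 1L))
  km <- substring(doubled, 1:n, k:(n + k - 1L))
  # reverse complement of each circular k-mer, read off the reverse
  # complement of the doubled string (cheaper than per-k-mer revcomp)
  rc_doubled <- reverse_complement(doubled)
  rkm <- substring(rc_doubled, n - (1:n) + 1L, n - (1:n) + k)

  # seed pairs (a, b): seq[b..b+k) == revcomp(seq[a..a+k))
  by_km <- split(0:(n - 1L), km)
  partners <- by_km[rkm]
  na <- lengths(partners)
  if (sum(na) == 0L) return(list())
  a <- rep.int(0:(n - 1L), na)
  b <- unlist(partners, use.names = FALSE)
  keep <- a <= b
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(list())

  cc <- (a + b) %% n
  ord <- order(cc, a)
  a <- a[ord]; b <- b[ord]; cc <- cc[ord]

  maxarm <- n %/% 2L
  pairs <- list()
  grp_start <- c(1L, which(diff(cc) != 0L) + 1L)
  grp_end <- c(grp_start[-1L] - 1L, length(cc))
  for (g in seq_along(grp_start)) {
    ga <- a[grp_start[g]:grp_end[g]]
    gb <- b[grp_start[g]:grp_end[g]]
    keep <- ga != gb
    ga <- ga[keep]; gb <- gb[keep]
    while (length(ga) > 0L) {
      ext <- extend_inverted_circular(sraw, n, ga[1L], gb[1L], k, maxarm)
      if (is.null(ext)) {
        ga <- ga[-1L]; gb <- gb[-1L]
        next
      }
      pairs[[length(pairs) + 1L]] <- ext
      # only seeds wholly inside an arm belong to this placement
      lo <- c(ext$i, ext$j, ext$i + n, ext$j + n)
      hi <- lo + ext$len - k
      inside <- (ga >= lo[1] & ga <= hi[1]) | (ga >= lo[2] & ga <= hi[2]) |
        (ga + n >= lo[1] & ga + n <= hi[1]) | (ga + n >= lo[2] & ga + n <= hi[2]) |
        (ga >= lo[3] & ga <= hi[3]) | (ga >= lo[4] & ga <= hi[4])
      inside[1L] <- TRUE
      ga <- ga[!inside]; gb <- gb[!inside]
    }
  }

  if (length(pairs) == 0L) return(list())
  key <- vapply(pairs, function(p) paste(sort(c(p$i, p$j))[1], sort(c(p$i, p$j))[2], p$len), character(1))
  pairs <- pairs[!duplicated(key)]
  pairs[vapply(pairs, function(p) p$len >= min_len, logical(1))]
}

# Vectorized maximal extension of an inverted seed on the circle.
# Seed: seq[a..a+k) pairs seq[b..b+k) (arm2 = revcomp(arm1)).
extend_inverted_circular <- function(sraw, n, a, b, k, maxarm) {
  m <- maxarm - k
  ext_right <- 0L
  ext_left <- 0L
  if (m > 0L) {
    # grow arm1 rightward, arm2 leftward
    u <- 0:(m - 1L)
    i1 <- ((a + k + u) %% n) + 1L
    i2 <- (((b - 1L - u) %% n + n) %% n) + 1L
    eq <- sraw[i1] == comp_raw(sraw[i2])
    ext_right <- match(FALSE, eq, nomatch = m + 1L) - 1L
    # grow arm1 leftward, arm2 rightward
    i1 <- (((a - 1L - u) %% n + n) %% n) + 1L
    i2 <- ((b + k + u) %% n) + 1L
    eq <- sraw[i1] == comp_raw(sraw[i2])
    ext_left <- match(FALSE, eq, nomatch = m + 1L) - 1L
  }
  len <- k + ext_left + ext_right
  i <- ((a - ext_left) %% n + n) %% n
  j <- (b - ext_right) %% n
  j <- ((j %% n) + n) %% n
  if (len > maxarm) return(NULL)
  # arms must be disjoint on the circle
  gap1 <- ((j - (i + len)) %% n + n) %% n
  gap2 <- ((i - (j + len)) %% n + n) %% n
  if (gap1 + gap2 + 2L * len != n) return(NULL)
  list(i = i, j = j, len = len)
}

# ---- plastome structure ----------------------------------------------------

#' Construct a plastome structure from known region lengths
#'
#' Builds the canonical LSC-IRb-SSC-IRa representation directly from a
#' sequence already linearized in that order, validating the quadripartite
#' invariants (tiling, equal IR lengths, IRa == revcomp(IRb)).
#'
#' @param sequence Canonical-rotation sequence (LSC first).
#' @param lsc_len,ir_len,ssc_len Region lengths in bp.
#' @param name Molecule label.
#' @param canonical_offset Rotation that was applied to reach this
#'   linearization (bookkeeping only).
#' @param ssc_flipped Was the SSC reverse-complemented during
#'   canonicalization?
#' @return An object of class `plastome_structure`.
#' @export
plastome_structure <- function(sequence, lsc_len, ir_len, ssc_len,
                               name = "plastome", canonical_offset = 0L,
                               ssc_flipped = FALSE) {
  check_dna(sequence)
  n <- nchar(sequence)
  lsc_len <- as.integer(lsc_len); ir_len <- as.integer(ir_len); ssc_len <- as.integer(ssc_len)
  if (lsc_len + ssc_len + 2L * ir_len != n) {
    psv_error("psv_bad_structure", sprintf(
      "region lengths (%d + %d + 2*%d) do not tile the %d bp genome",
      lsc_len, ssc_len, ir_len, n
    ))
  }
  st <- structure(list(
    name = name,
    sequence = sequence,
    length = n,
    lsc = interval(0L, lsc_len),
    irb = interval(lsc_len, lsc_len + ir_len),
    ssc = interval(lsc_len + ir_len, lsc_len + ir_len + ssc_len),
    ira = interval(lsc_len + ir_len + ssc_len, n),
    canonical_offset = as.integer(canonical_offset),
    ssc_flipped = isTRUE(ssc_flipped)
  ), class = "plastome_structure")
  irb_seq <- interval_seq(sequence, st$irb)
  if (!identical(interval_seq(sequence, st$ira), reverse_complement(irb_seq))) {
    psv_error("psv_bad_structure", "IRa is not the exact reverse complement of IRb")
  }
  st
}

#' Detect the quadripartite structure of a circular plastome
#'
#' Finds the maximal-arm exact inverted repeat partitioning the circle into
#' two single-copy regions and returns the structure in canonical rotation
#' (LSC at position 0, region order LSC-IRb-SSC-IRa). Among the two
#' flip-flop isomers, the one whose SSC forward strand is lexicographically
#' smaller is canonical, so detection of any rotation of the same molecule
#' returns an identical object (up to `canonical_offset`).
#'
#' @param seq Circular genome as a character string (or named length-1
#'   vector).
#' @param min_ir_len Minimum IR arm length in bp (default 1000; must be
#'   >= 50).
#' @param allow_mismatch Mismatch tolerance; only exact matching
#'   (`allow_mismatch = 0`) is implemented.
#' @param ssc_ref Optional homology override: a DNA string (e.g. the SSC of
#'   a reference conformation). The single-copy gap more similar to it is
#'   labelled SSC regardless of length. By default the longer gap is the
#'   LSC.
#' @param on_ambiguity `"error"` (default) signals a classed condition
#'   (`psv_quadripartite_ambiguous`) when more than one non-nested
#'   maximal-arm candidate exists; `"leftmost"` deterministically keeps the
#'   candidate whose arm starts leftmost.
#' @param name Molecule label for the result.
#' @return A [plastome_structure()].
#' @export
detect_quadripartite <- function(seq, min_ir_len = 1000L, allow_mismatch = 0L,
                                 ssc_ref = NULL, on_ambiguity = c("error", "leftmost"),
                                 name = NULL) {
  on_ambiguity <- match.arg(on_ambiguity)
  if (!is.null(names(seq)) && is.null(name)) name <- names(seq)[1]
  if (is.null(name)) name <- "plastome"
  seq <- unname(seq)
  check_dna(seq)
  if (allow_mismatch != 0L) {
    psv_error("psv_unsupported", "only exact IR matching (allow_mismatch = 0) is implemented")
  }
  min_ir_len <- as.integer(min_ir_len)
  if (min_ir_len < 50L) psv_error("psv_bad_input", "min_ir_len must be >= 50")
  n <- nchar(seq)
  if (n <= 2L * min_ir_len) psv_error("psv_bad_input", "genome length must exceed 2*min_ir_len")

  pairs <- find_circular_inverted_pairs(seq, min_ir_len)
  if (length(pairs) == 0L) {
    psv_error("psv_no_quadripartite", sprintf(
      "no quadripartite structure: no inverted repeat with arms >= %d bp", min_ir_len
    ))
  }
  lens <- vapply(pairs, `[[`, integer(1), "len")
  best <- pairs[lens == max(lens)]
  if (length(best) > 1L) {
    if (on_ambiguity == "error") {
      psv_error("psv_quadripartite_ambiguous", sprintf(
        "ambiguous quadripartite structure: %d non-nested maximal inverted repeats of %d bp",
        length(best), max(lens)
      ), data = list(candidates = best))
    }
    starts <- vapply(best, function(p) min(p$i, p$j), integer(1))
    best <- best[order(starts)]
  }
  p <- best[[1L]]

  i <- p$i; j <- p$j; L <- p$len
  gap1 <- list(start = (i + L) %% n, len = ((j - i - L) %% n + n) %% n)  # between arm i and arm j
  gap2 <- list(start = (j + L) %% n, len = ((i - j - L) %% n + n) %% n)
  g1_seq <- circ_substr(seq, gap1$start, gap1$len)
  g2_seq <- circ_substr(seq, gap2$start, gap2$len)

  if (!is.null(ssc_ref)) {
    sim1 <- region_similarity(g1_seq, ssc_ref)
    sim2 <- region_similarity(g2_seq, ssc_ref)
    gap1_is_ssc <- if (sim1 != sim2) sim1 > sim2 else gap1$len < gap2$len
  } else {
    gap1_is_ssc <- gap1$len < gap2$len ||
      (gap1$len == gap2$len && gap1$start > gap2$start)
  }
  lsc <- if (gap1_is_ssc) gap2 else gap1
  ssc <- if (gap1_is_ssc) gap1 else gap2

  canonical <- rotate_seq(seq, lsc$start)
  st <- plastome_structure(
    canonical,
    lsc_len = lsc$len, ir_len = L, ssc_len = ssc$len,
    name = name, canonical_offset = lsc$start
  )
  canonicalize_isomer(st)
}

# Shared k-mer similarity used by the homology-based LSC/SSC label override.
region_similarity <- function(seq, ref, k = 21L) {
  if (identical(seq, ref)) return(Inf)
  if (nchar(seq) < k || nchar(ref) < k) {
    return(-abs(nchar(seq) - nchar(ref)))  # fall back on length similarity
  }
  kms <- substring(seq, 1:(nchar(seq) - k + 1L), k:nchar(seq))
  kmr <- unique(substring(ref, 1:(nchar(ref) - k + 1L), k:nchar(ref)))
  sum(kms %in% kmr)
}

# Canonical flip-flop isomer: SSC forward strand lexicographically smaller
# than its reverse complement.
canonicalize_isomer <- function(st) {
  ssc_seq <- interval_seq(st$sequence, st$ssc)
  rc <- reverse_complement(ssc_seq)
  if (rc < ssc_seq) {
    seq2 <- paste0(
      interval_seq(st$sequence, st$lsc),
      interval_seq(st$sequence, st$irb),
      rc,
      interval_seq(st$sequence, st$ira)
    )
    st2 <- plastome_structure(
      seq2,
      lsc_len = interval_len(st$lsc), ir_len = interval_len(st$irb),
      ssc_len = interval_len(st$ssc),
      name = st$name, canonical_offset = st$canonical_offset, ssc_flipped = TRUE
    )
    return(st2)
  }
  st
}

#' Compute size and GC metrics of a plastome structure
#'
#' Sizes come from the region intervals; GC is (#G + #C) / (#A + #C + #G +
#' #T) per region, with N excluded from numerator and denominator. A region
#' consisting only of N has undefined GC, reported as `NA`.
#'
#' @param structure A [plastome_structure()].
#' @return An object of class `structure_metrics` (a list with
#'   `genome_size`, `lsc_size`, `ssc_size`, `ir_size` and the four GC
#'   fractions).
#' @export
compute_metrics <- function(structure) {
  stopifnot(inherits(structure, "plastome_structure"))
  s <- structure$sequence
  out <- list(
    genome_size = structure$length,
    lsc_size = interval_len(structure$lsc),
    ssc_size = interval_len(structure$ssc),
    ir_size = interval_len(structure$irb),
    gc_total = gc_fraction(s),
    gc_lsc = gc_fraction(interval_seq(s, structure$lsc)),
    gc_ssc = gc_fraction(interval_seq(s, structure$ssc)),
    gc_ir = gc_fraction(interval_seq(s, structure$irb))
  )
  structure(out, class = "structure_metrics")
}

#' @export
print.plastome_structure <- function(x, ...) {
  cat(sprintf("<plastome_structure> %s: %d bp circular\n", x$name, x$length))
  regs <- list(LSC = x$lsc, IRb = x$irb, SSC = x$ssc, IRa = x$ira)
  for (r in names(regs)) {
    iv <- regs[[r]]
    cat(sprintf(
      "  %-3s %8d..%-8d (%d bp)\n", r, iv$start + 1L, iv$end, interval_len(iv)
    ))
  }
  if (x$ssc_flipped) cat("  (SSC flipped to canonical flip-flop isomer)\n")
  invisible(x)
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat(sprintf(
    "genome %d bp (LSC %d, SSC %d, IR %d); GC %.1f%% (LSC %.1f, SSC %.1f, IR %.1f)\n",
    x$genome_size, x$lsc_size, x$ssc_size, x$ir_size,
    100 * x$gc_total, 100 * x$gc_lsc, 100 * x$gc_ssc, 100 * x$gc_ir
  ))
  invisible(x)
}

# ---- reports ---------------------------------------------------------------

structure_region_table <- function(structure, metrics = NULL) {
  if (is.null(metrics)) metrics <- compute_metrics(structure)
  regs <- list(LSC = structure$lsc, IRb = structure$irb, SSC = structure$ssc, IRa = structure$ira)
  gc <- c(metrics$gc_lsc, metrics$gc_ir, metrics$gc_ssc, metrics$gc_ir)
  data.frame(
    region = names(regs),
    start = vapply(regs, function(iv) iv$start + 1L, integer(1)),  # 1-based inclusive
    end = vapply(regs, function(iv) iv$end, integer(1)),
    length = vapply(regs, interval_len, integer(1)),
    gc = gc,
    row.names = NULL
  )
}

#' Write a structure report as JSON
#'
#' Region table (1-based inclusive coordinates) plus genome-level metrics.
#'
#' @param structure A [plastome_structure()].
#' @param path Output path, or `NULL` to return the JSON text.
#' @return The path (invisibly) or the JSON string.
#' @export
write_structure_json <- function(structure, path = NULL) {
  metrics <- compute_metrics(structure)
  obj <- list(
    name = structure$name,
    genome_size = metrics$genome_size,
    gc_total = metrics$gc_total,
    regions = structure_region_table(structure, metrics)
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Write structure regions as BED (0-based half-open)
#'
#' @param structure A [plastome_structure()].
#' @param path Output path, or `NULL` to return the data frame.
#' @return The path (invisibly) or a data frame with BED columns.
#' @export
write_structure_bed <- function(structure, path = NULL) {
  regs <- list(LSC = structure$lsc, IRb = structure$irb, SSC = structure$ssc, IRa = structure$ira)
  bed <- data.frame(
    chrom = structure$name,
    chromStart = vapply(regs, function(iv) iv$start, integer(1)),
    chromEnd = vapply(regs, function(iv) iv$end, integer(1)),
    name = names(regs),
    row.names = NULL
  )
  if (is.null(path)) return(bed)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
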