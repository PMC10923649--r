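# Synthetic ground-truth engine: toy quadripartite plastomes with a planted
# short inverted repeat in the LSC, independently spliced conformers, and
# simulated paired-end reads from conformer mixtures.
#
# Defaults describe a desk-scale genome with the geometry of a typical
# rearrangement substrate: |A| 600, |B| 92 (the spacer length of the
# motivating system), |C| 500, 11-bp arms, SSC 600, IR 500 (~2.8 kb
# total), GC 0.375, 150-bp paired reads with a 0.1% substitution error.

#' Specify a toy quadripartite plastome
#'
#' Lengths are in bp; the LSC is `len_a + len_b + len_c`, with the planted
#' inverted arms occupying the last `arm_len` bases of area A and the first
#' `arm_len` bases of area C.
#'
#' @param len_a,len_b,len_c Area lengths (arms included in A and C).
#' @param arm_len Planted arm length (>= 4).
#' @param len_ssc,len_ir SSC and IR lengths.
#' @param gc GC fraction of the random sequence.
#' @param seed Integer seed; the whole construction is reproducible from
#'   it.
#' @param genes Optional data frame (`name`, `area`, `type`) placing genes
#'   in areas `A`, `B`, `C`, `SSC` or `IR`.
#' @return A list of class `toy_spec`.
#' @export
toy_spec <- function(len_a = 600L, len_b = 92L, len_c = 500L, arm_len = 11L,
                     len_ssc = 600L, len_ir = 500L, gc = 0.375, seed = 1L,
                     genes = NULL) {
  sp <- list(
    len_a = as.integer(len_a), len_b = as.integer(len_b), len_c = as.integer(len_c),
    arm_len = as.integer(arm_len), len_ssc = as.integer(len_ssc),
    len_ir = as.integer(len_ir), gc = gc, seed = as.integer(seed), genes = genes
  )
  if (sp$arm_len < 4L) psv_error("psv_bad_input", "arm_len must be >= 4")
  if (sp$arm_len > sp$len_a || sp$arm_len > sp$len_c) {
    psv_error("psv_bad_input", "arms live at the A/B and B/C boundaries: arm_len <= |A| and <= |C|")
  }
  if (any(unlist(sp[1:6]) < 0L)) psv_error("psv_bad_input", "lengths must be >= 0")
  structure(sp, class = "toy_spec")
}

#' Build a toy plastome with a planted inverted repeat pair
#'
#' Random sequence per region at the stated GC and seed; the right arm is
#' the exact reverse complement of the planted left arm. Rejection sampling
#' enforces that (i) the planted pair is exactly maximal (no accidental
#' outward/inward extension), (ii) when `check_unique_repeat = TRUE`, no
#' other inverted pair with arms `>= arm_len` occurs in the LSC, (iii)
#' area B is not its own reverse complement (so inversion junctions are
#' diagnostic), and (iv) the large IR is exactly maximal. The SSC is
#' emitted in canonical flip-flop orientation, so [detect_quadripartite()]
#' reproduces the construction byte for byte.
#'
#' @param spec A [toy_spec()].
#' @param check_unique_repeat Enforce LSC repeat uniqueness by rejection
#'   sampling (default `TRUE`). Infeasible for full-scale LSCs, where
#'   spurious 11-bp inverted pairs are expected by chance; disable it there
#'   and identify the planted pair by coordinates.
#' @param max_attempts Rejection-sampling budget (default 100).
#' @return A list of class `toy_plastome`: `structure`
#'   ([plastome_structure()]), `partition` ([partition_lsc()] result),
#'   `annotation` (gene table, possibly empty), `pieces` (ground-truth
#'   region strings `A`, `B`, `C`, `Ib`, `S`, `Ia`, `arm`), and `spec`.
#' @export
make_toy_plastome <- function(spec, check_unique_repeat = TRUE, max_attempts = 100L) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  m <- spec$arm_len
  for (attempt in seq_len(max_attempts)) {
    arm <- random_dna(m, spec$gc)
    a_head <- random_dna(spec$len_a - m, spec$gc)
    b <- random_dna(spec$len_b, spec$gc)
    c_tail <- random_dna(spec$len_c - m, spec$gc)
    ssc <- random_dna(spec$len_ssc, spec$gc)
    ir <- random_dna(spec$len_ir, spec$gc)
    if (reverse_complement(ssc) < ssc) ssc <- reverse_complement(ssc)

    area_a <- paste0(a_head, arm)
    area_c <- paste0(reverse_complement(arm), c_tail)
    lsc <- paste0(area_a, b, area_c)
    genome <- paste0(lsc, ir, ssc, reverse_complement(ir))

    if (!toy_guards_ok(a_head, b, c_tail, lsc, ssc, m)) next
    if (check_unique_repeat) {
      found <- find_repeat_pairs(
        lsc, min_arm = m, max_spacer = nchar(lsc), orientation = "inverted"
      )
      ok <- nrow(found) == 1L &&
        found$arm_len == m &&
        found$left_start == spec$len_a - m &&
        found$right_start == spec$len_a + spec$len_b
      if (!ok) next
    }

    st <- plastome_structure(
      genome,
      lsc_len = nchar(lsc), ir_len = spec$len_ir, ssc_len = spec$len_ssc,
      name = sprintf("toy_seed%d", spec$seed)
    )
    part <- partition_lsc(st, list(
      left_start = spec$len_a - m, right_start = spec$len_a + spec$len_b,
      arm_len = m, orientation = "inverted"
    ))
    ann <- place_toy_genes(spec, st, part)
    return(structure(list(
      structure = st, partition = part, annotation = ann,
      pieces = list(
        A = area_a, B = b, C = area_c, Ib = ir, S = ssc,
        Ia = reverse_complement(ir), arm = arm
      ),
      spec = spec
    ), class = "toy_plastome"))
  }
  psv_error("psv_rejection_failed", sprintf(
    "could not satisfy the toy constraints in %d attempts (spec too repetitive?)", max_attempts
  ))
}

# Boundary guards: planted repeats must be exactly maximal, and area B must
# not be palindromic (its inversion must be observable).
toy_guards_ok <- function(a_head, b, c_tail, lsc, ssc, arm_len) {
  ch <- function(s, i) substr(s, i, i)
  comp1 <- function(x) chartr("ACGTN", "TGCAN", x)
  # short pair, outward: base before left arm vs base after right arm
  if (nchar(a_head) > 0L && nchar(c_tail) > 0L &&
      ch(a_head, nchar(a_head)) == comp1(ch(c_tail, 1L))) return(FALSE)
  # short pair, inward: first and last base of the spacer
  if (nchar(b) >= 2L && ch(b, 1L) == comp1(ch(b, nchar(b)))) return(FALSE)
  # area B must not be its own reverse complement
  if (nchar(b) > 0L && identical(b, reverse_complement(b))) return(FALSE)
  # large IR, outward: LSC last base vs complement of LSC first base
  if (ch(lsc, nchar(lsc)) == comp1(ch(lsc, 1L))) return(FALSE)
  # large IR, inward: SSC first vs complement of SSC last
  if (nchar(ssc) >= 2L && ch(ssc, 1L) == comp1(ch(ssc, nchar(ssc)))) return(FALSE)
  TRUE
}

# Deterministic gene placement: genes assigned to an area are tiled across
# it without overlap.
place_toy_genes <- function(spec, st, part) {
  empty <- data.frame(name = character(0), start = integer(0), end = integer(0),
                      type = character(0))
  if (is.null(spec$genes)) return(empty)
  g <- as.data.frame(spec$genes)
  stopifnot(all(c("name", "area", "type") %in% names(g)))
  areas <- list(
    A = part$area_a, B = part$area_b, C = part$area_c,
    SSC = st$ssc, IR = st$irb
  )
  out <- lapply(names(areas), function(ar) {
    gi <- g[g$area == ar, , drop = FALSE]
    if (nrow(gi) == 0L) return(empty)
    iv <- areas[[ar]]
    len <- interval_len(iv)
    slot <- len %/% nrow(gi)
    width <- max(1L, min(slot - 1L, slot * 2L %/% 3L))
    if (slot < 1L) psv_error("psv_bad_input", sprintf("too many genes for area %s", ar))
    start0 <- iv$start + (seq_len(nrow(gi)) - 1L) * slot
    data.frame(
      name = gi$name, start = start0 + 1L, end = start0 + width, type = gi$type
    )
  })
  do.call(rbind, out)
}

#' Splice a conformer by formula (independent oracle)
#'
#' Rebuilds each conformer by direct cut-and-paste of the generator's
#' ground-truth region strings, independently of the event-driven assembly
#' in [enumerate_conformers()]. The two constructions must agree byte for
#' byte; each is the other's oracle.
#'
#' @param toy A `toy_plastome` (or a list with the `pieces` element).
#' @param label Conformer label: `"parent"`, `"B-inversion"`,
#'   `"intermediate-dimer"`, `"A-type"`, `"reciprocal"`,
#'   `"flipflop-isomer"`.
#' @return The spliced circular sequence as a character string.
#' @export
splice_conformer <- function(toy, label) {
  p <- toy$pieces
  stopifnot(!is.null(p))
  rc <- reverse_complement
  switch(label,
    "parent" = paste0(p$A, p$B, p$C, p$Ib, p$S, p$Ia),
    "B-inversion" = paste0(p$A, rc(p$B), p$C, p$Ib, p$S, p$Ia),
    "flipflop-isomer" = paste0(p$A, p$B, p$C, p$Ib, rc(p$S), p$Ia),
    "A-type" = paste0(p$A, p$B, rc(p$A), p$Ib, p$S, p$Ia),
    "reciprocal" = paste0(rc(p$C), p$B, p$C, p$Ib, p$S, p$Ia),
    "intermediate-dimer" = paste0(
      p$C, p$Ib, p$S, p$Ia, p$A, p$B,
      rc(p$A), p$Ib, rc(p$S), p$Ia, rc(p$C), rc(p$B)
    ),
    psv_error("psv_bad_input", sprintf("unknown conformer label '%s'", label))
  )
}

# ---- read simulation -------------------------------------------------------

#' Simulate paired-end reads from a mixture of circular conformers
#'
#' Fragment start positions are uniform on each circle (fragments crossing
#' the linearization origin wrap); fragment lengths are normal
#' (`insert_mean`, `insert_sd`) clamped to `[read_len, conformer length]`;
#' substitution errors are i.i.d. per base. The number of fragments per
#' conformer is multinomial with probabilities proportional to
#' `mixture * length`, so the expected depth of conformer i is
#' `depth * mixture[i]` on its own sequence. Fully reproducible from
#' `seed`.
#'
#' @param conformers Named character vector of circular sequences.
#' @param mixture Numeric vector of molecule proportions (sums to 1).
#' @param depth Total target depth (x coverage) of the mixture.
#' @param read_len Read length in bp (default 150).
#' @param error_rate Per-base substitution probability (default 0.001).
#' @param insert_mean,insert_sd Fragment length distribution (defaults 350,
#'   35).
#' @param seed Integer seed.
#' @return A list of class `simulated_reads`: `reads1`, `reads2` (named
#'   character vectors, mate suffixes `/1` `/2`), `truth` (data frame: id,
#'   conformer, 1-based fragment start on the conformer's forward strand,
#'   strand, fragment length), and `params`.
#' @export
simulate_reads <- function(conformers, mixture, depth, read_len = 150L,
                           error_rate = 0.001, insert_mean = 350L, insert_sd = 35L,
                           seed = 1L) {
  conformers <- unlist(conformers)
  if (is.null(names(conformers))) names(conformers) <- paste0("conf", seq_along(conformers))
  if (length(mixture) != length(conformers)) {
    psv_error("psv_bad_input", "mixture must have one proportion per conformer")
  }
  if (abs(sum(mixture) - 1) > 1e-8) psv_error("psv_bad_input", "mixture proportions must sum to 1")
  if (depth <= 0) psv_error("psv_bad_input", "depth must be > 0")
  lens <- nchar(conformers)
  if (any(read_len > lens & mixture > 0)) {
    psv_error("psv_bad_input", "read_len exceeds a conformer length")
  }
  set.seed(seed)

  expected <- depth * mixture * lens / (2 * read_len)
  n_total <- max(1L, round(sum(expected)))
  origin <- if (sum(expected) > 0) {
    sample.int(length(conformers), n_total, replace = TRUE, prob = expected / sum(expected))
  } else integer(0)

  ids <- sprintf("read%06d", seq_len(n_total))
  frag_start <- integer(n_total)   # 0-based on the conformer forward strand
  frag_len <- pmin(
    pmax(as.integer(round(stats::rnorm(n_total, insert_mean, insert_sd))), read_len),
    lens[origin]
  )
  strand <- sample(c("+", "-"), n_total, replace = TRUE)

  reads1 <- character(n_total); reads2 <- character(n_total)
  for (ci in seq_along(conformers)) {
    idx <- which(origin == ci)
    if (length(idx) == 0L) next
    n <- lens[ci]
    doubled <- paste0(conformers[ci], substr(conformers[ci], 1L, min(n, max(frag_len[idx]))))
    starts <- sample.int(n, length(idx), replace = TRUE) - 1L
    frag_start[idx] <- starts
    frags <- substring(doubled, starts + 1L, starts + frag_len[idx])
    minus <- strand[idx] == "-"
    if (any(minus)) frags[minus] <- revcomp_many(frags[minus])
    reads1[idx] <- substr(frags, 1L, read_len)
    reads2[idx] <- revcomp_many(substring(frags, frag_len[idx] - read_len + 1L, frag_len[idx]))
  }

  if (error_rate > 0) {
    reads1 <- add_substitution_errors(reads1, error_rate)
    reads2 <- add_substitution_errors(reads2, error_rate)
  }
  names(reads1) <- paste0(ids, "/1")
  names(reads2) <- paste0(ids, "/2")

  structure(list(
    reads1 = reads1, reads2 = reads2,
    truth = data.frame(
      id = ids, conformer = names(conformers)[origin],
      start = frag_start + 1L, strand = strand, frag_len = frag_len
    ),
    params = list(
      depth = depth, mixture = stats::setNames(mixture, names(conformers)),
      read_len = read_len, error_rate = error_rate,
      insert_mean = insert_mean, insert_sd = insert_sd, seed = seed
    )
  ), class = "simulated_reads")
}

# Vectorized i.i.d. substitution errors over a same-length read batch.
add_substitution_errors <- function(reads, rate) {
  if (length(reads) == 0L) return(reads)
  L <- nchar(reads[1])
  total <- length(reads) * L
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(reads)
  pos <- sample.int(total, n_err)
  blob <- charToRaw(paste(reads, collapse = ""))
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    cur <- rawToChar(blob[p])
    blob[p] <- charToRaw(sample(setdiff(bases, cur), 1L))
  }
  blob_str <- rawToChar(blob)
  out <- substring(blob_str, seq(1L, total, by = L), seq(L, total, by = L))
  names(out) <- names(reads)
  out
}

#' Write a simulated read set as paired FASTQ plus ground truth TSV
#'
#' @param sim A [simulate_reads()] result.
#' @param prefix Output prefix; writes `<prefix>_1.fastq`,
#'   `<prefix>_2.fastq` and `<prefix>_truth.tsv`.
#' @return Invisibly, the three paths.
#' @export
write_read_set <- function(sim, prefix) {
  paths <- c(
    paste0(prefix, "_1.fastq"), paste0(prefix, "_2.fastq"),
    paste0(prefix, "_truth.tsv")
  )
  write_fastq_plain(sim$reads1, paths[1])
  write_fastq_plain(sim$reads2, paths[2])
  utils::write.table(sim$truth, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Constant high quality: no operation in this package consumes qualities
# beyond the optional mean filter.
write_fastq_plain <- function(reads, path) {
  qual <- strrep("I", nchar(reads))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads), "+", qual))
  writeLines(lines, path)
  invisible(path)
}
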