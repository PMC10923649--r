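# Short direct and inverted repeat pairs: the recombination substrates.
#
# A pair is two equal-length, non-overlapping arms on the same (linear)
# sequence. For inverted pairs the right arm is the exact reverse
# complement of the left arm; for direct pairs the arms are identical.
# "Maximal" means the arms can be extended neither outward nor inward
# (toward each other) while preserving the orientation relation. Matching
# is exact: no mismatch tolerance, which keeps the brute-force oracle exact.

#' Find maximal short repeat pairs in a sequence
#'
#' Seed-and-extend scan over shared k-mers (k = `min_arm`). All maximal
#' pairs whose arm length lies in `[min_arm, max_arm]` and whose spacer
#' (gap between the arms) lies in `[min_spacer, max_spacer]` are returned,
#' sorted by (left arm start, spacer length). Arms within a homopolymer run
#' can have several equivalent maximal placements; all are reported, and
#' `n_equivalent` gives the size of each placement group (pairs sharing
#' orientation, arm length and alignment diagonal).
#'
#' @param seq DNA string (a linear region, e.g. an extracted LSC).
#' @param min_arm Minimum arm length in bp; must be >= 4 (shorter arms are
#'   in the spurious-match regime). Default 8.
#' @param max_arm Maximum arm length (default `Inf`).
#' @param min_spacer,max_spacer Bounds on the gap between the arms
#'   (defaults 0 and 10000). Overlapping arms (negative spacer) are never
#'   reported.
#' @param orientation `"inverted"`, `"direct"` or `"both"`.
#' @return A data frame of class `repeat_table` with columns `arm_len`,
#'   `left_start`, `left_end`, `right_start`, `right_end` (0-based
#'   half-open), `orientation`, `spacer_len`, `left_seq`, `right_seq`,
#'   `n_equivalent`.
#' @export
find_repeat_pairs <- function(seq, min_arm = 8L, max_arm = Inf,
                              min_spacer = 0L, max_spacer = 10000L,
                              orientation = c("both", "inverted", "direct")) {
  orientation <- match.arg(orientation)
  check_dna(seq)
  min_arm <- as.integer(min_arm)
  if (min_arm < 4L) psv_error("psv_bad_input", "min_arm must be >= 4 (spurious-match regime below)")
  if (min_arm > max_arm) psv_error("psv_bad_input", "min_arm must be <= max_arm")
  if (min_spacer < 0L || min_spacer > max_spacer) {
    psv_error("psv_bad_input", "need 0 <= min_spacer <= max_spacer")
  }
  n <- nchar(seq)
  empty <- repeat_table_skeleton()
  if (n < 2L * min_arm) return(empty)

  rows <- list()
  if (orientation %in% c("both", "inverted")) {
    rows <- c(rows, scan_pairs(seq, min_arm, inverted = TRUE))
  }
  if (orientation %in% c("both", "direct")) {
    rows <- c(rows, scan_pairs(seq, min_arm, inverted = FALSE))
  }
  if (length(rows) == 0L) return(empty)

  df <- do.call(rbind, lapply(rows, as.data.frame))
  df <- df[!duplicated(df[c("left_start", "right_start", "arm_len", "orientation")]), , drop = FALSE]
  df <- df[df$arm_len <= max_arm & df$spacer_len >= min_spacer & df$spacer_len <= max_spacer, , drop = FALSE]
  if (nrow(df) == 0L) return(empty)

  # equivalent-placement groups: same orientation, arm length and diagonal
  diag_key <- ifelse(
    df$orientation == "inverted",
    df$left_start + df$right_start + df$arm_len,  # anti-diagonal
    df$right_start - df$left_start               # diagonal
  )
  grp <- paste(df$orientation, df$arm_len, diag_key)
  df$n_equivalent <- as.integer(ave(seq_len(nrow(df)), grp, FUN = length))

  df$left_seq <- substring(seq, df$left_start + 1L, df$left_start + df$arm_len)
  df$right_seq <- substring(seq, df$right_start + 1L, df$right_start + df$arm_len)
  df <- df[order(df$left_start, df$spacer_len, df$orientation), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("repeat_table", "data.frame")
  df
}

repeat_table_skeleton <- function() {
  df <- data.frame(
    arm_len = integer(0), left_start = integer(0), left_end = integer(0),
    right_start = integer(0), right_end = integer(0),
    orientation = character(0), spacer_len = integer(0),
    left_seq = character(0), right_seq = character(0), n_equivalent = integer(0)
  )
  class(df) <- c("repeat_table", "data.frame")
  df
}

# Seed-and-extend enumeration of maximal pairs of one orientation.
scan_pairs <- function(seq, k, inverted) {
  n <- nchar(seq)
  sraw <- charToRaw(seq)
  km <- substring(seq, 1:(n - k + 1L), k:n)
  if (inverted) {
    rc_seq <- reverse_complement(seq)
    p <- 1:(n - k + 1L)
    target <- substring(rc_seq, n - p - k + 2L, n - p + 1L)
  } else {
    target <- km
  }
  by_km <- split(0:(n - k), km)   # 0-based kmer starts by kmer value
  partners <- by_km[target]
  cnt <- lengths(partners)
  if (sum(cnt) == 0L) return(list())
  a <- rep.int(0:(n - k), cnt)
  b <- unlist(partners, use.names = FALSE)
  keep <- if (inverted) a < b else a < b   # left arm strictly precedes
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(list())

  dg <- if (inverted) a + b else b - a
  ord <- order(dg, a)
  a <- a[ord]; b <- b[ord]; dg <- dg[ord]

  out <- list()
  grp_start <- c(1L, which(diff(dg) != 0L) + 1L)
  grp_end <- c(grp_start[-1L] - 1L, length(dg))
  for (g in seq_along(grp_start)) {
    covered_hi <- -1L
    for (s in grp_start[g]:grp_end[g]) {
      # a seed belongs to an already-found placement on this diagonal only
      # if its whole k-mer lies inside that placement's left arm; seeds
      # overhanging the arm end start a shifted (equivalent) placement
      if (a[s] <= covered_hi) next
      p <- extend_linear(sraw, n, a[s], b[s], k, inverted)
      if (is.null(p)) next
      out[[length(out) + 1L]] <- p
      covered_hi <- p$left_end - k
    }
  }
  out
}

# Maximal extension of a linear seed; returns NULL if arms end up
# overlapping (spacer < 0 is excluded by construction).
extend_linear <- function(sraw, n, a, b, k, inverted) {
  i <- a; j <- b; L <- k
  if (inverted) {
    # outward: left arm grows left, right arm grows right
    while (i > 0L && j + L < n && sraw[i] == comp_raw(sraw[j + L + 1L])) {
      i <- i - 1L; L <- L + 1L
    }
    # inward: left arm grows right, right arm grows left (needs spacer >= 2)
    while (j - (i + L) >= 2L && sraw[i + L + 1L] == comp_raw(sraw[j])) {
      j <- j - 1L; L <- L + 1L
    }
  } else {
    # grow left edges (right arm eats into the spacer, keep spacer >= 0)
    while (i > 0L && j - (i + L) >= 1L && sraw[i] == sraw[j]) {
      i <- i - 1L; j <- j - 1L; L <- L + 1L
    }
    while (i + L < j && j + L < n && sraw[i + L + 1L] == sraw[j + L + 1L]) {  # grow right edges
      L <- L + 1L
    }
  }
  spacer <- j - (i + L)
  if (spacer < 0L) return(NULL)
  list(
    arm_len = L, left_start = i, left_end = i + L,
    right_start = j, right_end = j + L,
    orientation = if (inverted) "inverted" else "direct",
    spacer_len = spacer
  )
}

#' Maximalize a repeat pair
#'
#' Extends the arms outward then inward as far as the orientation relation
#' holds; among equal-length maximal placements within a homopolymer run,
#' the placement with the leftmost left arm is returned. Idempotent.
#'
#' @param pair A list or one-row data frame with `left_start`,
#'   `right_start`, `arm_len` (0-based) and `orientation`.
#' @param seq The sequence the pair lives on.
#' @return A one-row `repeat_table` data frame.
#' @export
maximalize <- function(pair, seq) {
  check_dna(seq)
  pair <- as.list(pair)
  n <- nchar(seq)
  sraw <- charToRaw(seq)
  i <- as.integer(pair$left_start); j <- as.integer(pair$right_start)
  L <- as.integer(pair$arm_len)
  inverted <- identical(pair$orientation, "inverted")
  left <- substr(seq, i + 1L, i + L)
  right <- substr(seq, j + 1L, j + L)
  rel_ok <- if (inverted) identical(right, reverse_complement(left)) else identical(right, left)
  if (!rel_ok) psv_error("psv_bad_input", "pair arms do not match under the stated orientation")

  p <- extend_linear(sraw, n, i, j, L, inverted)
  if (is.null(p)) psv_error("psv_bad_input", "arms overlap after extension")

  if (inverted) {
    # shift the whole placement left along the anti-diagonal while it stays
    # a valid maximal pair (canonical leftmost placement in homopolymers)
    repeat {
      i2 <- p$left_start - 1L; j2 <- p$right_start + 1L; L2 <- p$arm_len
      if (i2 < 0L || j2 + L2 > n) break
      left2 <- substr(seq, i2 + 1L, i2 + L2)
      right2 <- substr(seq, j2 + 1L, j2 + L2)
      if (!identical(right2, reverse_complement(left2))) break
      cand <- extend_linear(sraw, n, i2, j2, L2, TRUE)
      if (is.null(cand) || cand$arm_len != L2 ||
          cand$left_start != i2 || cand$right_start != j2) break
      p <- cand
    }
  } else {
    repeat {
      i2 <- p$left_start - 1L; j2 <- p$right_start - 1L; L2 <- p$arm_len
      if (i2 < 0L || j2 < 0L) break
      left2 <- substr(seq, i2 + 1L, i2 + L2)
      right2 <- substr(seq, j2 + 1L, j2 + L2)
      if (!identical(right2, left2)) break
      cand <- extend_linear(sraw, n, i2, j2, L2, FALSE)
      if (is.null(cand) || cand$arm_len != L2 ||
          cand$left_start != i2 || cand$right_start != j2) break
      p <- cand
    }
  }

  df <- as.data.frame(p)
  df$left_seq <- substr(seq, df$left_start + 1L, df$left_start + df$arm_len)
  df$right_seq <- substr(seq, df$right_start + 1L, df$right_start + df$arm_len)
  df$n_equivalent <- NA_integer_
  class(df) <- c("repeat_table", "data.frame")
  df
}

#' Write a repeat report as TSV (1-based coordinates) or JSON
#'
#' @param pairs A `repeat_table` from [find_repeat_pairs()].
#' @param path Output path; extension `.json` selects JSON, anything else
#'   TSV. `NULL` returns the interface-coordinate data frame.
#' @return The path (invisibly) or the converted data frame.
#' @export
write_repeat_report <- function(pairs, path = NULL) {
  out <- data.frame(
    arm_len = pairs$arm_len,
    left_start = pairs$left_start + 1L, left_end = pairs$left_end,
    right_start = pairs$right_start + 1L, right_end = pairs$right_end,
    orientation = pairs$orientation,
    spacer_len = pairs$spacer_len,
    left_seq = pairs$left_seq,
    n_equivalent_placements = pairs$n_equivalent
  )
  if (is.null(path)) return(out)
  if (grepl("\\.json$", path)) {
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  } else {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
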