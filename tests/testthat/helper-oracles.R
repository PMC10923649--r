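# Independent oracles and shared fixtures. The oracles deliberately avoid
# the package's seed-and-extend machinery: repeat pairs are enumerated
# exhaustively over all (i, j, L), and expected spanning-read counts come
# from the closed-form uniform-placement formula.

# Exhaustive enumeration of maximal repeat pairs: for every arm length L,
# every pair of equal-length substrings is tested for the orientation
# relation and for maximality by direct character comparison. Vectorized
# per L, but still a full scan over all (i, j, L).
oracle_repeat_pairs <- function(seq, min_arm, max_arm = Inf, min_spacer = 0,
                                max_spacer = nchar(seq),
                                orientation = c("both", "inverted", "direct")) {
  orientation <- match.arg(orientation)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rcseq <- plastomeSV::reverse_complement(seq)
  out <- list()
  Lmax <- min(n %/% 2L, if (is.finite(max_arm)) max_arm else n %/% 2L)
  for (L in seq.int(min_arm, max(min_arm, Lmax))) {
    if (L > Lmax) break
    starts <- 0:(n - L)                                   # 0-based
    subs <- substring(seq, starts + 1L, starts + L)
    rcsubs <- substring(rcseq, n - starts - L + 1L, n - starts)
    pos_by_val <- split(starts, subs)
    rc_of <- tapply(rcsubs, subs, `[`, 1L)
    for (ori in c("inverted", "direct")) {
      if (orientation != "both" && orientation != ori) next
      inv <- ori == "inverted"
      pair_list <- lapply(names(pos_by_val), function(v) {
        right_val <- if (inv) rc_of[[v]] else v
        q <- pos_by_val[[right_val]]
        if (is.null(q)) return(NULL)
        expand.grid(i = pos_by_val[[v]], j = q)
      })
      pairs <- do.call(rbind, pair_list)
      if (is.null(pairs) || nrow(pairs) == 0L) next
      i <- pairs$i; j <- pairs$j
      keep <- i + L <= j
      i <- i[keep]; j <- j[keep]
      if (length(i) == 0L) next
      # NB: i, j are 0-based; ch is 1-based, so ch[i] is the base before
      # the left arm. pmax keeps vector lengths aligned when i == 0; the
      # boundary conditions (i > 0 etc.) make those rows FALSE anyway.
      if (inv) {
        out_ext <- i > 0L & j + L < n & ch[pmax(i, 1L)] == comp[ch[pmin(j + L + 1L, n)]]
        in_ext <- (j - (i + L)) >= 2L & ch[pmin(i + L + 1L, n)] == comp[ch[pmax(j, 1L)]]
      } else {
        out_ext <- i > 0L & (j - (i + L)) >= 1L & ch[pmax(i, 1L)] == ch[pmax(j, 1L)]
        in_ext <- i + L < j & j + L < n & ch[pmin(i + L + 1L, n)] == ch[pmin(j + L + 1L, n)]
      }
      maximal <- !(out_ext | in_ext)
      sp <- j - (i + L)
      sel <- maximal & sp >= min_spacer & sp <= max_spacer
      if (any(sel)) {
        out[[length(out) + 1L]] <- data.frame(
          arm_len = L, left_start = i[sel], right_start = j[sel],
          orientation = ori, spacer_len = sp[sel]
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(arm_len = integer(0), left_start = integer(0),
                      right_start = integer(0), orientation = character(0),
                      spacer_len = integer(0)))
  }
  do.call(rbind, out)
}

pair_keys <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  paste(df$arm_len, df$left_start, df$right_start, df$orientation)
}

# Expected junction-spanning reads under uniform placement of N reads of
# length L on a circle of length G: each position is a read start with
# equal probability, and a window of `span` bases is covered with
# L - span + 1 admissible starts.
expected_spanning <- function(depth, read_len, span) {
  depth * max(0L, read_len - span + 1L) / read_len
}

# Shared default toy (memoized): ~2.8 kb quadripartite genome, planted
# 11-bp arms around a 92-bp area B.
.toy_cache <- new.env(parent = emptyenv())
shared_toy <- function(seed = 5L) {
  key <- as.character(seed)
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- make_toy_plastome(toy_spec(seed = seed))
  }
  .toy_cache[[key]]
}

# Toy genome for the structure-detection recipe test: explicit
# LSC + IRb + SSC + revcomp(IRb) construction with boundary bases pinned
# so the planted IR is exactly maximal (the recipe is the oracle).
recipe_genome <- function(lsc_len = 400L, ir_len = 200L, ssc_len = 150L, seed = 7L) {
  set.seed(seed)
  lsc <- random_dna(lsc_len)
  ir <- random_dna(ir_len)
  ssc <- random_dna(ssc_len)
  # pin boundaries: no outward (LSC last vs comp(LSC first)) or inward
  # (SSC first vs comp(SSC last)) extension of the planted IR
  substr(lsc, 1L, 1L) <- "A"; substr(lsc, lsc_len, lsc_len) <- "A"
  substr(ssc, 1L, 1L) <- "A"; substr(ssc, ssc_len, ssc_len) <- "A"
  if (reverse_complement(ssc) < ssc) {
    ssc <- reverse_complement(ssc)  # canonical isomer, keeps pins (A..A)
  }
  list(
    genome = paste0(lsc, ir, ssc, reverse_complement(ir)),
    lsc = lsc, ir = ir, ssc = ssc
  )
}
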