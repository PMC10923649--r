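# Conformer heteroplasmy from region-wise read depth.
#
# On the parent (unrearranged) reference, area C is present only in the
# parent conformer while the SSC is present, single copy, in both the
# parent and the rearranged molecule. The mixture arithmetic is therefore:
#
#   depth(parent)     = depth(area C)
#   depth(rearranged) = depth(SSC) - depth(area C)
#
# with proportions obtained by normalization. Area B is excluded from all
# depth estimation by default: when flanked by long inverted arms it can
# form a hairpin that suppresses sequencing depth, a known artifact that
# is not modelled here. Depth must come from a reference with a fixed IR
# convention (both IR copies present; the IR then shows half per-copy
# depth under unique-best mapping, which does not enter the arithmetic).

#' Create a per-base depth profile
#'
#' @param depth Numeric vector of per-position depths (position i is the
#'   1-based reference position i).
#' @param name Reference name.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(depth, name = "ref") {
  depth <- as.numeric(depth)
  if (any(depth < 0 | is.na(depth))) psv_error("psv_bad_input", "depths must be non-negative")
  structure(list(name = name, depth = depth, length = length(depth)),
            class = "depth_profile")
}

#' Read a three-column per-base depth table
#'
#' The format produced by standard depth utilities: reference name,
#' 1-based position, depth, whitespace-separated, no header. Positions
#' absent from the table are depth 0.
#'
#' @param path Path to the table.
#' @param ref_name Reference to extract (default: the first one seen).
#' @param ref_len Reference length; defaults to the maximum position
#'   listed.
#' @return A [depth_profile()].
#' @export
read_depth_table <- function(path, ref_name = NULL, ref_len = NULL) {
  if (!file.exists(path)) psv_error("psv_missing_file", sprintf("depth table not found: %s", path))
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, col.names = c("ref", "pos", "depth"),
                      colClasses = c("character", "integer", "numeric")),
    error = function(e) psv_error("psv_parse_error", sprintf(
      "malformed depth table %s: %s", path, conditionMessage(e)
    ))
  )
  if (is.null(ref_name)) ref_name <- tab$ref[1]
  tab <- tab[tab$ref == ref_name, , drop = FALSE]
  if (nrow(tab) == 0L) psv_error("psv_bad_input", sprintf("reference '%s' absent from depth table", ref_name))
  if (is.null(ref_len)) ref_len <- max(tab$pos)
  if (any(tab$pos < 1L | tab$pos > ref_len)) {
    psv_error("psv_parse_error", "depth table position outside the reference")
  }
  depth <- numeric(ref_len)
  depth[tab$pos] <- tab$depth
  depth_profile(depth, name = ref_name)
}

#' Write a depth profile as a three-column table
#'
#' @param profile A [depth_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_depth_table <- function(profile, path) {
  utils::write.table(
    data.frame(ref = profile$name, pos = seq_len(profile$length), depth = profile$depth),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Mean and standard deviation of depth over a region
#'
#' `trim` bases are discarded from each end of the region before averaging
#' (a guard against mapping edge effects at region boundaries).
#'
#' @param profile A [depth_profile()].
#' @param region A [interval()] (0-based half-open) on the profile's
#'   reference.
#' @param trim Bases trimmed from each region end (default 0).
#' @return List with `mean`, `sd`, `n` (positions used).
#' @export
region_depth <- function(profile, region, trim = 0L) {
  stopifnot(inherits(profile, "depth_profile"), inherits(region, "psv_interval"))
  trim <- as.integer(trim)
  if (region$end > profile$length) psv_error("psv_bad_input", "region outside the reference")
  start <- region$start + trim
  end <- region$end - trim
  if (2L * trim >= interval_len(region) || start >= end) {
    psv_error("psv_bad_input", "region empty after trimming")
  }
  x <- profile$depth[(start + 1L):end]
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Estimate conformer heteroplasmy from a depth profile
#'
#' Implements the region-depth arithmetic above on a profile computed
#' against the parent reference. Standard errors use a normal
#' approximation with an effective sample size of region length /
#' `corr_len` (neighbouring positions covered by the same reads are not
#' independent; `corr_len` defaults to a 150-bp read length).
#'
#' @param profile [depth_profile()] on the parent reference.
#' @param partition A [partition_lsc()] result (defines area C).
#' @param structure Parent [plastome_structure()] (defines the SSC).
#' @param trim Bases trimmed from each region end (default 50).
#' @param corr_len Depth autocorrelation length for the effective sample
#'   size (default 150).
#' @return An object of class `heteroplasmy_estimate`: `depth_g`,
#'   `depth_a`, `prop_g`, `prop_a`, standard errors, `z_a` (evidence that
#'   the rearranged conformer's depth exceeds 0), `regions_used`,
#'   `dispersion` and `flags`.
#' @export
estimate_heteroplasmy <- function(profile, partition, structure, trim = 50L,
                                  corr_len = 150L) {
  stopifnot(inherits(partition, "segment_partition"), inherits(structure, "plastome_structure"))
  if (profile$length != structure$length) {
    psv_error("psv_bad_input", "profile length does not match the parent reference")
  }
  dc <- region_depth(profile, partition$area_c, trim = trim)
  ds <- region_depth(profile, structure$ssc, trim = trim)
  se <- function(d) d$sd / sqrt(max(1, d$n / corr_len))
  se_c <- se(dc); se_s <- se(ds)
  pooled <- sqrt(se_c^2 + se_s^2)

  depth_g <- dc$mean
  raw_a <- ds$mean - dc$mean
  flags <- character(0)
  if (raw_a < 0) flags <- c(flags, "negative_floored")
  # an SSC deficit beyond 3 pooled sd (or any deficit at zero dispersion)
  # violates the two-conformer model
  if (raw_a < 0 && (pooled == 0 || raw_a < -3 * pooled)) flags <- c(flags, "inconsistent")
  depth_a <- max(0, raw_a)

  total <- depth_g + depth_a
  if (total > 0) {
    prop_g <- depth_g / total
    prop_a <- depth_a / total
    se_prop_a <- sqrt(depth_g^2 * (se_c^2 + se_s^2) + depth_a^2 * se_c^2) / total^2
  } else {
    prop_g <- NA_real_; prop_a <- NA_real_; se_prop_a <- NA_real_
  }
  z_a <- if (pooled > 0) raw_a / pooled else 0

  structure(list(
    depth_g = depth_g, depth_a = depth_a,
    prop_g = prop_g, prop_a = prop_a,
    se_depth_g = se_c, se_depth_a = pooled, se_prop_a = se_prop_a,
    z_a = z_a,
    regions_used = list(area_c = partition$area_c, ssc = structure$ssc, trim = trim),
    dispersion = c(area_c = dc$sd, ssc = ds$sd),
    flags = flags
  ), class = "heteroplasmy_estimate")
}

#' @export
print.heteroplasmy_estimate <- function(x, ...) {
  cat(sprintf(
    "<heteroplasmy_estimate> parent %.1fx (%.0f%%), rearranged %.1fx (%.0f%%)%s\n",
    x$depth_g, 100 * x$prop_g, x$depth_a, 100 * x$prop_a,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""
  ))
  invisible(x)
}

#' Presence call per conformer
#'
#' A conformer is called present if its diagnostic depth passes
#' `threshold_depth` (and, as a statistical guard, its depth is at least
#' `min_z` standard errors above zero) or its diagnostic junction has at
#' least `threshold_reads` spanning reads. Both evidence values are always
#' reported.
#'
#' @param estimate A [estimate_heteroplasmy()] result.
#' @param support Optional named list of `support_count` objects; entries
#'   `parent` and `alt` (or `a-type`) feed the two calls.
#' @param threshold_depth Minimum diagnostic depth (default 2).
#' @param threshold_reads Minimum junction-spanning reads (default 2).
#' @param min_z Minimum z-score of the depth evidence (default 4).
#' @return Data frame with one row per conformer (`parent`, `alt`):
#'   depth, z, junction reads and the presence call.
#' @export
detect_presence <- function(estimate, support = NULL, threshold_depth = 2,
                            threshold_reads = 2L, min_z = 4) {
  stopifnot(inherits(estimate, "heteroplasmy_estimate"))
  if (threshold_depth < 0 || threshold_reads < 0) {
    psv_error("psv_bad_input", "thresholds must be >= 0")
  }
  get_reads <- function(keys) {
    for (k in keys) {
      if (!is.null(support[[k]])) return(support[[k]]$n_spanning)
    }
    NA_integer_
  }
  jr_parent <- get_reads(c("parent"))
  jr_alt <- get_reads(c("alt", "a-type"))
  z_g <- if (estimate$se_depth_g > 0) estimate$depth_g / estimate$se_depth_g else
    (if (estimate$depth_g > 0) Inf else 0)
  z_a <- estimate$z_a

  call_one <- function(depth, z, jr) {
    depth_ev <- depth >= threshold_depth && z >= min_z
    read_ev <- !is.na(jr) && jr >= threshold_reads
    isTRUE(depth_ev || read_ev)
  }
  data.frame(
    conformer = c("parent", "alt"),
    depth = c(estimate$depth_g, estimate$depth_a),
    z = c(z_g, z_a),
    junction_reads = c(jr_parent, jr_alt),
    present = c(
      call_one(estimate$depth_g, z_g, jr_parent),
      call_one(estimate$depth_a, z_a, jr_alt)
    )
  )
}

#' Write a heteroplasmy estimate as JSON or TSV
#'
#' @param estimate A [estimate_heteroplasmy()] result.
#' @param path Output path; `.json` selects JSON, anything else TSV.
#' @return Invisibly, `path`.
#' @export
write_estimate_report <- function(estimate, path) {
  df <- data.frame(
    conformer = c("parent", "rearranged"),
    depth = c(estimate$depth_g, estimate$depth_a),
    se = c(estimate$se_depth_g, estimate$se_depth_a),
    proportion = c(estimate$prop_g, estimate$prop_a)
  )
  if (grepl("\\.json$", path)) {
    obj <- list(
      depth_g = estimate$depth_g, depth_a = estimate$depth_a,
      prop_g = estimate$prop_g, prop_a = estimate$prop_a,
      se_prop_a = estimate$se_prop_a, flags = estimate$flags
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---- internal read mapper for self-contained depth profiles ---------------

#' Compute a depth profile by mapping reads to a circular reference
#'
#' Ungapped, k-mer-anchored mapping sufficient for substitution-only
#' reads: each read (or its reverse complement) is placed at the first
#' anchor position where it matches the circular reference with at most
#' `max_mismatch` substitutions over its full length. Reads from regions
#' absent from the reference (e.g. novel junctions of another conformer)
#' stay unmapped and contribute no depth — the behaviour the region-depth
#' arithmetic expects. Not a general-purpose aligner.
#'
#' @param reads Character vector of reads, or a `simulated_reads` object.
#' @param ref_seq Circular reference sequence (character string).
#' @param max_mismatch Per-read substitution budget (default 2; use 0 for
#'   error-free simulations).
#' @param k Anchor k-mer length (default 25).
#' @param name Reference name for the profile.
#' @return A [depth_profile()] with attributes `n_mapped`, `n_unmapped`.
#' @export
map_reads_depth <- function(reads, ref_seq, max_mismatch = 2L, k = 25L, name = "ref") {
  if (inherits(reads, "simulated_reads")) reads <- c(reads$reads1, reads$reads2)
  reads <- unname(as.character(reads))
  check_dna(ref_seq, "reference")
  n <- nchar(ref_seq)
  if (length(reads) == 0L) {
    prof <- depth_profile(numeric(n), name = name)
    attr(prof, "n_mapped") <- 0L; attr(prof, "n_unmapped") <- 0L
    return(prof)
  }
  depth <- numeric(n)
  n_mapped <- 0L
  for (L in sort(unique(nchar(reads)))) {
    batch <- reads[nchar(reads) == L]
    if (L < k) next
    res <- map_batch_circular(batch, ref_seq, n, L, k, max_mismatch)
    if (length(res$offsets) > 0L) {
      depth <- depth + coverage_from_offsets(res$offsets, L, n)
      n_mapped <- n_mapped + length(res$offsets)
    }
  }
  prof <- depth_profile(depth, name = name)
  attr(prof, "n_mapped") <- n_mapped
  attr(prof, "n_unmapped") <- length(reads) - n_mapped
  prof
}

# Vectorized batch mapping of fixed-length reads to a circular reference.
# Passes over (strand x anchor position) resolve reads greedily; returns
# accepted 0-based circular offsets.
map_batch_circular <- function(batch, ref_seq, n, L, k, max_mismatch) {
  ref2 <- paste0(ref_seq, substr(ref_seq, 1L, min(n, L)))
  ref_kmers <- substring(ref2, 1:n, k:(n + k - 1L))
  anchors <- unique(c(0L, (L - k) %/% 2L, L - k))

  pending <- batch
  pending_rc <- NULL
  offsets <- integer(0)
  for (strand in c("+", "-")) {
    cur <- if (strand == "+") pending else {
      pending_rc <- revcomp_many(pending)
      pending_rc
    }
    resolved <- logical(length(cur))
    for (off in anchors) {
      todo <- which(!resolved)
      if (length(todo) == 0L) break
      keys <- substr(cur[todo], off + 1L, off + k)
      pos <- match(keys, ref_kmers)            # first circular occurrence
      hit <- which(!is.na(pos))
      if (length(hit) == 0L) next
      o <- ((pos[hit] - 1L - off) %% n + n) %% n
      refwin <- substring(ref2, o + 1L, o + L)
      cand_reads <- cur[todo[hit]]
      ok <- refwin == cand_reads
      if (max_mismatch > 0L && any(!ok)) {
        chk <- which(!ok)
        mm <- count_mismatches_bulk(cand_reads[chk], refwin[chk], L)
        ok[chk] <- mm <= max_mismatch
      }
      acc <- which(ok)
      if (length(acc) > 0L) {
        offsets <- c(offsets, o[acc])
        resolved[todo[hit[acc]]] <- TRUE
      }
    }
    pending <- pending[!resolved]
    if (length(pending) == 0L) break
  }
  list(offsets = offsets)
}

# Bulk Hamming distance between equal-length string vectors.
count_mismatches_bulk <- function(a, b, L) {
  if (length(a) == 0L) return(integer(0))
  ra <- charToRaw(paste(a, collapse = ""))
  rb <- charToRaw(paste(b, collapse = ""))
  ne <- ra != rb
  as.integer(colSums(matrix(ne, nrow = L)))
}

# Fold linear coverage of reads at 0-based circular offsets back onto the
# circle with a difference array.
coverage_from_offsets <- function(offsets, L, n) {
  m <- n + L
  d <- numeric(m + 1L)
  tab_s <- tabulate(offsets + 1L, nbins = m)
  tab_e <- tabulate(offsets + L + 1L, nbins = m + 1L)
  d[1:m] <- tab_s
  cum <- cumsum(d[1:m] - tab_e[1:m])
  cov <- cum[1:n]
  extra <- cum[(n + 1L):m]
  cov[seq_along(extra)] <- cov[seq_along(extra)] + extra
  cov
}
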