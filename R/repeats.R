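#' Find long exact intragenomic repeats
#'
#' Detects all maximal exact repeat pairs of at least `min_len` bp within
#' one sequence, in direct and inverted (reverse-complement) orientation,
#' by k-mer seeding followed by full scanning of every seeded diagonal
#' (direct) or anti-diagonal (inverted); the result is therefore identical
#' to a quadratic brute-force scan whenever every repeat contains a shared
#' k-mer, which holds by construction for `k <= min_len`. Maximal pairs
#' whose both intervals are contained in another reported pair's intervals
#' are suppressed.
#'
#' @param seq Sequence string.
#' @param min_len Minimum repeat length (default 1000; must be >= 20).
#' @param orientations Subset of `c("direct", "inverted")`.
#' @return data.frame of class `repeat_pairs`: `startA`, `startB` (0-based,
#'   `startA < startB`), `length`, `orientation`, sorted by decreasing
#'   length.
#' @export
find_exact_repeats <- function(seq, min_len = 1000L,
                               orientations = c("direct", "inverted")) {
  stopifnot(min_len >= 20L)
  seq <- toupper(seq)
  n <- nchar(seq)
  k <- min(31L, min_len)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- list()

  if (n >= k) {
    km <- substring(seq, seq_len(n - k + 1L), seq.int(k, n))
    if ("direct" %in% orientations && length(km)) {
      dup_mask <- duplicated(km) | duplicated(km, fromLast = TRUE)
      pos <- which(dup_mask)
      if (length(pos)) {
        grp <- split(pos, km[pos])
        diags <- unique(unlist(lapply(grp, function(p) {
          if (length(p) < 2L) return(integer(0))
          as.vector(outer(p, p, "-"))
        }), use.names = FALSE))
        diags <- diags[diags > 0L]
        for (d in diags) {
          eq <- chars[seq_len(n - d)] == chars[seq_len(n - d) + d]
          r <- rle(eq)
          ends <- cumsum(r$lengths)
          for (i in which(r$values & r$lengths >= min_len)) {
            s <- ends[i] - r$lengths[i]      # 0-based start on first copy
            out[[length(out) + 1L]] <- data.frame(
              startA = s, startB = s + d, length = r$lengths[i],
              orientation = "direct", stringsAsFactors = FALSE)
          }
        }
      }
    }
    if ("inverted" %in% orientations && length(km)) {
      rckm <- vapply(km, revcomp_fast, character(1), USE.NAMES = FALSE)
      hit <- match(rckm, km)
      cand <- which(!is.na(hit))
      if (length(cand)) {
        # pairing i <-> j with seq[i] == comp(seq[j]) lies on the
        # anti-diagonal c = i + j; a seeded arm pair gives c = (i0 + k - 1) + j0
        cs <- unique((cand - 1L) + (hit[cand] - 1L) + k - 1L)
        for (cc in cs) {
          pairs <- antidiagonal_arm_pairs(chars, cc, min_len)
          out <- c(out, pairs)
        }
      }
    }
  }
  finalize_repeat_pairs(out)
}

# Maximal inverted arm pairs along one anti-diagonal c = i + j (0-based).
# The indicator eq(i) = [seq[i] == comp(seq[c-i])] is symmetric under
# i -> c - i, so each maximal run either mirrors a second run (a spacered
# inverted repeat: report arms run / mirror) or spans the centre (a
# contiguous palindrome: report the two non-overlapping half-arms).
antidiagonal_arm_pairs <- function(chars, cc, min_len) {
  n <- length(chars)
  i_lo <- max(0L, cc - n + 1L)
  i_hi <- min(n - 1L, cc)
  if (i_hi - i_lo + 1L < 2L * min_len) return(list())
  i_idx <- i_lo:i_hi
  eq <- chars[i_idx + 1L] == comp_base(chars[cc - i_idx + 1L])
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  out <- list()
  for (ri in which(r$values)) {
    lo <- i_idx[ends[ri] - r$lengths[ri] + 1L]   # first TRUE position
    hi <- i_idx[ends[ri]]                        # last TRUE position
    mlo <- cc - hi                               # mirror run
    if (lo < mlo) {                              # spacered pair
      arm <- hi - lo + 1L
      if (arm >= min_len) {
        out[[length(out) + 1L]] <- data.frame(
          startA = lo, startB = mlo, length = arm,
          orientation = "inverted", stringsAsFactors = FALSE)
      }
    } else if (lo == mlo) {                      # palindrome spanning centre
      arm <- (hi - lo + 1L) %/% 2L
      if (arm >= min_len) {
        out[[length(out) + 1L]] <- data.frame(
          startA = lo, startB = hi - arm + 1L, length = arm,
          orientation = "inverted", stringsAsFactors = FALSE)
      }
    }                                            # lo > mlo: mirror, skip
  }
  out
}

finalize_repeat_pairs <- function(out) {
  empty <- data.frame(startA = integer(0), startB = integer(0),
                      length = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE)
  if (!length(out)) { class(empty) <- c("repeat_pairs", "data.frame"); return(empty) }
  res <- unique(do.call(rbind, out))
  # suppress pairs contained in another pair (both intervals)
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (i == j || !keep[i]) next
      if (res$orientation[i] == res$orientation[j] &&
          res$length[i] < res$length[j] &&
          res$startA[i] >= res$startA[j] &&
          res$startA[i] + res$length[i] <= res$startA[j] + res$length[j] &&
          res$startB[i] >= res$startB[j] &&
          res$startB[i] + res$length[i] <= res$startB[j] + res$length[j]) {
        keep[i] <- FALSE
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(-res$length, res$startA, res$startB), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("repeat_pairs", "data.frame")
  res
}

comp_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]
}

revcomp_fast <- function(x) {
  paste(rev(comp_base(strsplit(x, "", fixed = TRUE)[[1]])), collapse = "")
}

#' Find regions flanked by inverted-repeat arms
#'
#' Reports regions whose two flanks are maximal exact inverted repeats
#' (arms) of at least `min_arm` bp, with the enclosed region no longer than
#' `max_region`. Overlapping candidates are resolved longest arm first.
#'
#' @param seq Sequence string.
#' @param min_arm Minimum arm length (default 20; must be >= 20).
#' @param max_region Maximum enclosed region length (default 50000).
#' @return data.frame of class `flanked_regions`: `region_start`,
#'   `region_end` (0-based half-open, between the arms), `region_length`,
#'   `arm_length`, `arm1_start`, `arm2_start`, `arm_seq`.
#' @export
find_ir_flanked_regions <- function(seq, min_arm = 20L, max_region = 50000L) {
  stopifnot(min_arm >= 20L)
  seq <- toupper(seq)
  irs <- find_exact_repeats(seq, min_len = min_arm, orientations = "inverted")
  if (!nrow(irs)) {
    empty <- data.frame(region_start = integer(0), region_end = integer(0),
                        region_length = integer(0), arm_length = integer(0),
                        arm1_start = integer(0), arm2_start = integer(0),
                        arm_seq = character(0), stringsAsFactors = FALSE)
    class(empty) <- c("flanked_regions", "data.frame")
    return(empty)
  }
  irs$region_start <- irs$startA + irs$length
  irs$region_end <- irs$startB
  irs$region_length <- irs$region_end - irs$region_start
  irs <- irs[irs$region_length >= 1L & irs$region_length <= max_region, , drop = FALSE]
  irs <- irs[order(-irs$length, irs$startA), , drop = FALSE]
  keep <- logical(nrow(irs))
  covered <- integer(0)
  for (i in seq_len(nrow(irs))) {
    span <- irs$startA[i]:(irs$startB[i] + irs$length[i] - 1L)
    if (!length(intersect(span, covered))) {
      keep[i] <- TRUE
      covered <- c(covered, span)
    }
  }
  irs <- irs[keep, , drop = FALSE]
  out <- data.frame(
    region_start = irs$region_start, region_end = irs$region_end,
    region_length = irs$region_length, arm_length = irs$length,
    arm1_start = irs$startA, arm2_start = irs$startB,
    arm_seq = vapply(seq_len(nrow(irs)), function(i)
      subseq0(seq, irs$startA[i], irs$startA[i] + irs$length[i]), character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("flanked_regions", "data.frame")
  out
}

#' Write repeat pairs as BED-like TSV
#' @param repeats A [find_exact_repeats()] table.
#' @param chrom Chromosome label.
#' @param path Output path.
#' @export
write_repeats_tsv <- function(repeats, chrom, path) {
  out <- data.frame(chrom = chrom,
                    startA_1based = repeats$startA + 1L,
                    endA_1based = repeats$startA + repeats$length,
                    startB_1based = repeats$startB + 1L,
                    endB_1based = repeats$startB + repeats$length,
                    length = repeats$length,
                    orientation = repeats$orientation)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
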