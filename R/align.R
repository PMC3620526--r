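#' Anchored global alignment of a near-identical strain pair
#'
#' Aligns two genomes end-to-end by chaining maximal shared unique k-mer
#' matches (co-linear chaining, longest first, leftmost tie-break) and
#' closing every inter-anchor gap with full affine-gap dynamic programming
#' (match +1, mismatch -2, gap open -4, gap extend -1; a gap of length L
#' costs 4 + L). Intended for strain pairs at very high identity, where the
#' chained result attains the full dynamic-programming optimum.
#'
#' @param a,b [genome_record()]s or plain sequences over `{A,C,G,T,N}`.
#' @param k Anchor seed length (default 31).
#' @param anchor_trim Bases trimmed from each anchor end adjacent to a gap
#'   before dynamic-programming fill, so that event boundaries are placed by
#'   the aligner rather than the seed heuristic.
#' @return An object of class `alignment_map`: run-length encoded alignment
#'   columns (`ops` with op in M/I/D), sequence lengths, the alignment
#'   score, `identical_positions` (matched columns with equal, non-N bases)
#'   and `identity_percent` (identical positions over alignment columns).
#' @export
align_strain_pair <- function(a, b, k = 31L, anchor_trim = 5L) {
  sa <- if (inherits(a, "genome_record")) a$sequence else toupper(a)
  sb <- if (inherits(b, "genome_record")) b$sequence else toupper(b)
  na <- nchar(sa); nb <- nchar(sb)

  anchors <- find_unique_anchors(sa, sb, k)
  if (nrow(anchors) == 0L) {
    if (as.double(na + 1) * (nb + 1) <= 4e6) {
      nw <- .nw_align_cpp(sa, sb)
      return(build_alignment_map(a, b, sa, sb, data.frame(op = nw$op, len = nw$len)))
    }
    stop("not collinear: no shared unique ", k, "-mer anchors between '",
         if (inherits(a, "genome_record")) a$id else "A", "' and '",
         if (inherits(b, "genome_record")) b$id else "B", "'")
  }
  keep <- .chain_anchors_cpp(anchors$sa, anchors$sb, anchors$len)
  dropped <- sum(anchors$len[!keep]) / sum(anchors$len)
  if (dropped > 0.25) {
    stop("not collinear: co-linear chaining discards ",
         round(100 * dropped), "% of anchored bases (rearranged genomes?)")
  }
  ch <- anchors[keep, , drop = FALSE]
  ch <- ch[order(ch$sa), , drop = FALSE]

  # trim overlaps between consecutive chained anchors (anchors around an
  # indel inside a repeated context overlap in one genome's coordinates)
  if (nrow(ch) > 1L) {
    end_a <- ch$sa[1] + ch$len[1]
    end_b <- ch$sb[1] + ch$len[1]
    for (i in 2:nrow(ch)) {
      o <- max(end_a - ch$sa[i], end_b - ch$sb[i], 0L)
      ch$sa[i] <- ch$sa[i] + o
      ch$sb[i] <- ch$sb[i] + o
      ch$len[i] <- ch$len[i] - o
      if (ch$len[i] > 0L) {
        end_a <- ch$sa[i] + ch$len[i]
        end_b <- ch$sb[i] + ch$len[i]
      }
    }
    ch <- ch[ch$len > 0L, , drop = FALSE]
  }

  # trim anchor ends that abut an inter-anchor gap
  m <- nrow(ch)
  gap_before_a <- c(ch$sa[1] > 0L || ch$sb[1] > 0L,
                    ch$sa[-1] > (ch$sa + ch$len)[-m] | ch$sb[-1] > (ch$sb + ch$len)[-m])
  gap_after_a <- c(gap_before_a[-1],
                   ch$sa[m] + ch$len[m] < na || ch$sb[m] + ch$len[m] < nb)
  tl <- ifelse(gap_before_a, pmin(anchor_trim, (ch$len - 1L) %/% 2L), 0L)
  tr <- ifelse(gap_after_a, pmin(anchor_trim, ch$len - tl - 1L), 0L)
  ch$sa <- ch$sa + tl; ch$sb <- ch$sb + tl; ch$len <- ch$len - tl - tr

  ops_op <- character(0); ops_len <- integer(0)
  add_ops <- function(op, len) {
    keep <- len > 0L
    ops_op <<- c(ops_op, op[keep]); ops_len <<- c(ops_len, len[keep])
  }
  pa <- 0L; pb <- 0L
  for (i in seq_len(m)) {
    ga <- ch$sa[i] - pa; gb <- ch$sb[i] - pb
    add_segment_ops <- align_gap_segment(sa, sb, pa, pb, ga, gb)
    add_ops(add_segment_ops$op, add_segment_ops$len)
    add_ops("M", ch$len[i])
    pa <- ch$sa[i] + ch$len[i]; pb <- ch$sb[i] + ch$len[i]
  }
  tail_ops <- align_gap_segment(sa, sb, pa, pb, na - pa, nb - pb)
  add_ops(tail_ops$op, tail_ops$len)

  build_alignment_map(a, b, sa, sb, data.frame(op = ops_op, len = ops_len,
                                               stringsAsFactors = FALSE))
}

# Align the region between two anchors (or a flank). Returns RLE ops.
align_gap_segment <- function(sa, sb, pa, pb, ga, gb) {
  if (ga == 0L && gb == 0L) return(list(op = character(0), len = integer(0)))
  if (ga == 0L) return(list(op = "I", len = gb))
  if (gb == 0L) return(list(op = "D", len = ga))
  nw <- .nw_align_cpp(subseq0(sa, pa, pa + ga), subseq0(sb, pb, pb + gb))
  list(op = nw$op, len = nw$len)
}

# Maximal shared unique k-mer matches, merged along diagonals.
find_unique_anchors <- function(sa, sb, k) {
  na <- nchar(sa); nb <- nchar(sb)
  empty <- data.frame(sa = integer(0), sb = integer(0), len = integer(0))
  if (na < k || nb < k) return(empty)
  ka <- substring(sa, seq_len(na - k + 1L), seq.int(k, na))
  kb <- substring(sb, seq_len(nb - k + 1L), seq.int(k, nb))
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE)) & !grepl("N", ka, fixed = TRUE)
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  ia <- which(ua)
  hit <- match(ka[ia], kb)
  ok <- !is.na(hit) & ub[ifelse(is.na(hit), 1L, hit)]
  pa <- ia[ok] - 1L; pb <- hit[ok] - 1L       # 0-based
  if (!length(pa)) return(empty)
  d <- pb - pa
  o <- order(d, pa)
  pa <- pa[o]; pb <- pb[o]; d <- d[o]
  new_run <- c(TRUE, !(diff(pa) == 1L & diff(d) == 0L))
  run_id <- cumsum(new_run)
  starts <- which(new_run)
  run_len <- tabulate(run_id)
  data.frame(sa = pa[starts], sb = pb[starts], len = run_len + k - 1L)
}

build_alignment_map <- function(a, b, sa, sb, ops) {
  # merge adjacent identical ops
  if (nrow(ops) > 1L) {
    grp <- cumsum(c(TRUE, ops$op[-1] != ops$op[-nrow(ops)]))
    ops <- data.frame(op = ops$op[!duplicated(grp)],
                      len = as.integer(tapply(ops$len, grp, sum)),
                      stringsAsFactors = FALSE)
  }
  cols <- expand_columns(ops)
  m <- cols$op == "M"
  ba <- chars_at(sa, cols$apos[m])
  bb <- chars_at(sb, cols$bpos[m])
  ident <- sum(ba == bb & ba != "N" & bb != "N")
  n_cols <- sum(ops$len)
  match_score <- sum(ba == bb) * 1 + sum(ba != bb) * (-2)
  gap_runs <- ops$len[ops$op != "M"]
  score <- match_score - sum(4 + gap_runs)
  structure(list(
    a_id = if (inherits(a, "genome_record")) a$id else "A",
    b_id = if (inherits(b, "genome_record")) b$id else "B",
    a_len = nchar(sa), b_len = nchar(sb),
    ops = ops, n_columns = n_cols, score = score,
    identical_positions = ident,
    identity_percent = 100 * ident / n_cols
  ), class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("alignment_map %s (%d bp) ~ %s (%d bp): %d columns, %d identical (%.2f%%), score %g\n",
              x$a_id, x$a_len, x$b_id, x$b_len, x$n_columns,
              x$identical_positions, x$identity_percent, x$score))
  invisible(x)
}

# Per-column expansion of RLE ops: apos/bpos are 0-based positions consumed
# at each column (NA when the column is a gap in that genome).
expand_columns <- function(ops) {
  op <- rep(ops$op, ops$len)
  consume_a <- op != "I"
  consume_b <- op != "D"
  apos <- ifelse(consume_a, cumsum(consume_a) - 1L, NA_integer_)
  bpos <- ifelse(consume_b, cumsum(consume_b) - 1L, NA_integer_)
  list(op = op, apos = apos, bpos = bpos)
}

chars_at <- function(seq, pos0) {
  substring(seq, pos0 + 1L, pos0 + 1L)
}
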