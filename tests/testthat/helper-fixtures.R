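# Small fixtures built in code, shared across test files.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

# Introduce point mutations / tiny indels into a sequence at a given rate;
# used for alignment oracle tests (identity >= 1 - rate).
mutate_sequence <- function(seq, sub_rate = 0.03, indel_rate = 0.005) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- character(0)
  bases <- c("A", "C", "G", "T")
  for (ch in chars) {
    r <- runif(1)
    if (r < indel_rate / 2) {
      next                                   # deletion
    } else if (r < indel_rate) {
      out <- c(out, ch, sample(bases, 1))    # insertion
    } else if (r < indel_rate + sub_rate) {
      out <- c(out, sample(setdiff(bases, ch), 1))
    } else {
      out <- c(out, ch)
    }
  }
  paste(out, collapse = "")
}

# A hand-written 300 bp GenBank fixture: 2 CDS (one minus-strand join) and
# one pseudogene, with known coordinates.
fixture_genbank_text <- function() {
  set.seed(42)
  seq <- random_dna(300)
  substr(seq, 11, 13) <- "ATG"   # cosmetic; coordinates are what matter
  paste(c(
    "LOCUS       FIX0001                300 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  hand-written fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..300",
    "     CDS             11..70",
    "                     /gene=\"alpha\"",
    "                     /product=\"protein alpha\"",
    "     CDS             complement(join(101..130,141..170))",
    "                     /locus_tag=\"beta\"",
    "     gene            201..260",
    "                     /locus_tag=\"gamma\"",
    "                     /pseudo",
    "ORIGIN",
    symbiodiff:::format_origin(seq),
    "//"), collapse = "\n")
}

# Tiny annotated record built directly (no parsing) for partition tests.
toy_record <- function(seq = NULL, features = list(), id = "toy", len = 100) {
  if (is.null(seq)) seq <- strrep("A", len)
  genome_record(id, seq, features = features)
}

# Brute-force maximal repeat finder: scans every diagonal (direct) and
# every anti-diagonal (inverted) of the self-comparison matrix.
brute_force_repeats <- function(seq, min_len,
                                orientations = c("direct", "inverted")) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- list()
  if ("direct" %in% orientations) {
    for (d in seq_len(n - 1)) {
      if (n - d < min_len) break
      eq <- chars[seq_len(n - d)] == chars[seq_len(n - d) + d]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      for (i in which(r$values & r$lengths >= min_len)) {
        s <- ends[i] - r$lengths[i]
        out[[length(out) + 1L]] <- data.frame(
          startA = s, startB = s + d, length = r$lengths[i],
          orientation = "direct", stringsAsFactors = FALSE)
      }
    }
  }
  if ("inverted" %in% orientations) {
    for (cc in 0:(2L * n - 2L)) {
      i_lo <- max(0L, cc - n + 1L); i_hi <- min(n - 1L, cc)
      if (i_hi - i_lo + 1L < 2L * min_len) next
      i_idx <- i_lo:i_hi
      eq <- chars[i_idx + 1L] == comp[chars[cc - i_idx + 1L]]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      for (ri in which(r$values)) {
        lo <- i_idx[ends[ri] - r$lengths[ri] + 1L]
        hi <- i_idx[ends[ri]]
        mlo <- cc - hi
        if (lo < mlo && hi - lo + 1L >= min_len) {
          out[[length(out) + 1L]] <- data.frame(
            startA = lo, startB = mlo, length = hi - lo + 1L,
            orientation = "inverted", stringsAsFactors = FALSE)
        } else if (lo == mlo && (hi - lo + 1L) %/% 2L >= min_len) {
          arm <- (hi - lo + 1L) %/% 2L
          out[[length(out) + 1L]] <- data.frame(
            startA = lo, startB = hi - arm + 1L, length = arm,
            orientation = "inverted", stringsAsFactors = FALSE)
        }
      }
    }
  }
  symbiodiff:::finalize_repeat_pairs(out)
}

# Brute-force NG86 difference counter: explicit enumeration of every
# ordering of the differing positions, independent of the package path.
brute_force_ng86_diffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  orders <- if (length(pos) == 1) list(pos) else {
    idx <- expand.grid(rep(list(seq_along(pos)), length(pos)))
    idx <- idx[apply(idx, 1, function(r) length(unique(r)) == length(pos)), , drop = FALSE]
    lapply(seq_len(nrow(idx)), function(r) pos[as.integer(idx[r, ])])
  }
  tot_s <- 0; tot_n <- 0; valid <- 0
  for (ord in orders) {
    cur <- c1; s <- 0; nn <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") { ok <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) s <- s + 1 else nn <- nn + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + nn; valid <- valid + 1 }
  }
  if (!valid) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = tot_s / valid, nd = tot_n / valid)
}

revcomp_manual <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

random_nonstop_codon <- function() {
  repeat {
    cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    if (!cd %in% c("TAA", "TAG", "TGA")) return(cd)
  }
}
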