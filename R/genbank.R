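#' Read a GenBank flat file
#'
#' Parses a GenBank record into a [genome_record()]. One feature is retained
#' per `CDS`, `rRNA`, `tRNA`, `ncRNA`/`misc_RNA`/`tmRNA` (mapped to
#' `smallRNA`) feature-table entry; any entry flagged `/pseudo` or
#' `/pseudogene` is classed `pseudogene` regardless of its original key, and
#' `gene` entries are consulted only when they carry that flag. Locations
#' spanning the origin of a circular molecule are split into two intervals at
#' parse time. IUPAC ambiguity codes other than `N` are rejected.
#'
#' @param path Path to a GenBank flat file, or a character vector of lines
#'   via `text =`.
#' @param text Optional character scalar/vector holding the record itself.
#' @return A [genome_record()].
#' @export
read_genbank <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  if (!length(lines) || !grepl("^LOCUS", lines[[1]])) {
    stop("malformed GenBank record: first line is not a LOCUS line: '",
         if (length(lines)) lines[[1]] else "", "'")
  }
  locus <- strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]]
  id <- locus[[2]]
  declared_len <- suppressWarnings(as.integer(locus[[3]]))
  circular <- any(tolower(locus) == "circular")

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (!length(origin_start)) {
    stop("malformed GenBank record: missing ORIGIN sequence block")
  }
  origin_start <- origin_start[[1]]

  # --- sequence ---
  end_rec <- grep("^//", lines)
  end_rec <- if (length(end_rec)) end_rec[[1]] else length(lines) + 1L
  seq_lines <- lines[seq.int(origin_start + 1L, end_rec - 1L)]
  sequence <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("malformed GenBank record: empty ORIGIN block")
  if (!is.na(declared_len) && nchar(sequence) != declared_len) {
    stop("LOCUS declares ", declared_len, " bp but ORIGIN holds ",
         nchar(sequence), " bp")
  }

  # --- feature table ---
  feats <- list()
  if (length(feat_start)) {
    ftab <- lines[seq.int(feat_start[[1]] + 1L, origin_start - 1L)]
    entries <- parse_feature_entries(ftab)
    feats <- feature_entries_to_features(entries, nchar(sequence))
  }
  genome_record(id, sequence, features = feats, circular = circular)
}

# Split the raw feature-table lines into (key, location, qualifiers) entries.
parse_feature_entries <- function(ftab) {
  entries <- list()
  cur <- NULL
  for (ln in ftab) {
    if (!nzchar(trimws(ln))) next
    indent <- nchar(ln) - nchar(sub("^ +", "", ln))
    body <- trimws(ln)
    if (indent == 5L) {                     # new feature key
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      parts <- strsplit(body, "[[:space:]]+")[[1]]
      if (length(parts) < 2L) {
        stop("malformed feature line: '", ln, "'")
      }
      cur <- list(key = parts[[1]],
                  location = paste(parts[-1L], collapse = ""),
                  quals = character(0), in_location = TRUE)
    } else if (indent >= 21L) {
      if (is.null(cur)) stop("malformed feature table at line: '", ln, "'")
      if (startsWith(body, "/")) {
        cur$quals <- c(cur$quals, body)
        cur$in_location <- FALSE
      } else if (cur$in_location) {         # continued location
        cur$location <- paste0(cur$location, body)
      } else {                              # continued qualifier value
        k <- length(cur$quals)
        sep <- if (endsWith(cur$quals[[k]], "\"") ||
                   grepl("translation", cur$quals[[k]])) "" else " "
        cur$quals[[k]] <- paste0(sub("\"$", "", cur$quals[[k]]), sep, body)
      }
    } else {
      stop("malformed feature table at line: '", ln, "'")
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
  entries
}

parse_qualifiers <- function(quals) {
  out <- list()
  for (q in quals) {
    q <- sub("^/", "", q)
    if (grepl("=", q)) {
      key <- sub("=.*$", "", q)
      val <- sub("^[^=]*=", "", q)
      val <- gsub("^\"|\"$", "", val)
    } else {
      key <- q
      val <- ""
    }
    out[[key]] <- val
  }
  out
}

GENBANK_KIND_MAP <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                      ncRNA = "smallRNA", misc_RNA = "smallRNA",
                      tmRNA = "smallRNA")

feature_entries_to_features <- function(entries, genome_length) {
  feats <- list()
  seen_loc <- character(0)
  for (e in entries) {
    quals <- parse_qualifiers(e$quals)
    pseudo <- any(c("pseudo", "pseudogene") %in% names(quals))
    kind <- GENBANK_KIND_MAP[e$key]
    if (is.na(kind)) {
      if (!(identical(e$key, "gene") && pseudo)) next
      kind <- "pseudogene"
    }
    if (pseudo) kind <- "pseudogene"
    loc <- parse_location(e$location, genome_length)
    sig <- paste(kind, paste(loc$intervals, collapse = ","))
    if (identical(e$key, "gene") && sig %in% seen_loc) next
    seen_loc <- c(seen_loc, sig)
    name <- quals[["gene"]] %||% quals[["locus_tag"]] %||% ""
    feats[[length(feats) + 1L]] <- feature(
      kind = kind, strand = loc$strand, intervals = loc$intervals,
      name = name, qualifiers = quals
    )
  }
  feats
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# GenBank location string -> list(strand, intervals) with intervals 0-based
# half-open, ordered in translation order on the feature strand. A span with
# start > end wraps the origin of a circular molecule and is split in two.
parse_location <- function(loc, genome_length) {
  strand <- "+"
  x <- gsub("[[:space:]]", "", loc)
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^(join|order)\\(", x)) {
    x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
  }
  spans <- strsplit(x, ",", fixed = TRUE)[[1]]
  ivs <- list()
  for (s in spans) {
    s2 <- gsub("[<>]", "", s)
    if (grepl("^complement\\(", s2)) {
      # per-span complement inside join: treat whole feature as minus strand
      strand <- "-"
      s2 <- sub("^complement\\((.*)\\)$", "\\1", s2)
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", s2)) {
      ab <- as.integer(strsplit(s2, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", s2)) {
      ab <- c(as.integer(s2), as.integer(s2))
    } else {
      stop("cannot parse location span: '", s, "'")
    }
    if (ab[1] <= ab[2]) {
      ivs[[length(ivs) + 1L]] <- c(ab[1] - 1L, ab[2])
    } else {                               # wraps the origin: split
      ivs[[length(ivs) + 1L]] <- c(ab[1] - 1L, genome_length)
      ivs[[length(ivs) + 1L]] <- c(0L, ab[2])
    }
  }
  intervals <- do.call(rbind, ivs)
  if (strand == "-") intervals <- intervals[rev(seq_len(nrow(intervals))), , drop = FALSE]
  list(strand = strand, intervals = intervals)
}

#' Write a genome record as a GenBank flat file
#'
#' Emits a minimal, round-trippable GenBank record: `CDS`, `rRNA`, `tRNA`
#' features under their own keys, `smallRNA` as `ncRNA`, and pseudogenes as
#' `gene` entries flagged `/pseudo`.
#'
#' @param record A [genome_record()].
#' @param path Output path; when `NULL` the lines are returned invisibly
#'   without writing.
#' @return Invisibly, the character vector of lines.
#' @export
write_genbank <- function(record, path = NULL) {
  n <- genome_length(record)
  topo <- if (record$circular) "circular" else "linear"
  lines <- c(sprintf("LOCUS       %-16s %10d bp    DNA     %-8s BCT 01-JAN-2000",
                     record$id, n, topo),
             sprintf("DEFINITION  %s.", record$id),
             sprintf("ACCESSION   %s", record$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", n))
  for (f in record$features) {
    key <- switch(f$kind, CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                  smallRNA = "ncRNA", pseudogene = "gene")
    loc <- format_location(f)
    lines <- c(lines, wrap_feature_line(key, loc))
    quals <- f$qualifiers
    if (f$kind == "pseudogene") quals$pseudo <- ""
    if (nzchar(f$name) && is.null(quals$gene) && is.null(quals$locus_tag)) {
      quals$locus_tag <- f$name
    }
    for (k in names(quals)) {
      v <- quals[[k]]
      q <- if (identical(v, "")) paste0("/", k)
           else if (grepl("^[0-9]+$", v)) sprintf("/%s=%s", k, v)
           else sprintf("/%s=\"%s\"", k, v)
      lines <- c(lines, wrap_qualifier_line(q))
    }
  }
  lines <- c(lines, "ORIGIN", format_origin(record$sequence), "//")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

format_location <- function(f) {
  iv <- f$intervals
  if (f$strand == "-") iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
  spans <- sprintf("%d..%d", iv[, 1L] + 1L, iv[, 2L])
  loc <- if (length(spans) > 1L) sprintf("join(%s)", paste(spans, collapse = ",")) else spans
  if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

wrap_feature_line <- function(key, loc) {
  head <- sprintf("     %-16s", key)
  wrap_at <- 79L - 21L
  if (nchar(loc) <= wrap_at) return(paste0(head, loc))
  pieces <- substring(loc, seq(1L, nchar(loc), wrap_at),
                      pmin(seq(wrap_at, nchar(loc) + wrap_at - 1L, wrap_at), nchar(loc)))
  c(paste0(head, pieces[[1]]),
    paste0(strrep(" ", 21L), pieces[-1L]))
}

wrap_qualifier_line <- function(q) {
  wrap_at <- 79L - 21L
  pieces <- substring(q, seq(1L, nchar(q), wrap_at),
                      pmin(seq(wrap_at, nchar(q) + wrap_at - 1L, wrap_at), nchar(q)))
  paste0(strrep(" ", 21L), pieces)
}

format_origin <- function(sequence) {
  n <- nchar(sequence)
  starts <- seq(1L, n, 60L)
  vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(s + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(groups, collapse = " ")))
  }, character(1))
}

#' Read/write bare sequences as FASTA
#'
#' Thin wrappers over Biostrings for plain sequence I/O.
#' @param path File path.
#' @return `read_fasta`: named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
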