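#' Sequence records
#'
#' A `seq_record` is the package's light-weight sequence container: an id (the
#' FASTA/FASTQ header token before the first whitespace), an uppercase
#' sequence string, and optional per-base quality (FASTQ only). Nucleotide
#' sequences use the alphabet `ACGTN`; peptide sequences the 20 amino acids
#' plus `X` and `*`.
#'
#' @param id Non-empty, whitespace-free identifier.
#' @param sequence Non-empty sequence string.
#' @param quality Optional quality string of the same length (FASTQ).
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, quality = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id))
    stop("record id must be a non-empty, whitespace-free string")
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("empty record: '", id, "'")
  if (!is.null(quality) && nchar(quality) != nchar(sequence))
    stop("malformed FASTQ: quality length differs from sequence length for '",
         id, "'")
  structure(list(id = id, sequence = sequence, quality = quality),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s: %d letters>\n", x$id, nchar(x$sequence)))
  invisible(x)
}

# Normalise a raw nucleotide string: uppercase, U->T, IUPAC ambiguity codes
# other than N collapsed to N (with one warning per call site), anything else
# rejected. Soft-masked (lowercase) bases are treated as ordinary bases.
normalize_nucleotide <- function(x, id = "?") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  if (grepl("[RYSWKMBDHV]", x)) {
    warning("ambiguity codes in '", id, "' replaced by N", call. = FALSE)
    x <- gsub("[RYSWKMBDHV]", "N", x)
  }
  if (grepl("[^ACGTN]", x))
    stop("invalid nucleotide characters in record '", id, "'")
  x
}

normalize_peptide <- function(x, id = "?") {
  x <- toupper(x)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", x))
    stop("invalid amino-acid characters in record '", id, "'")
  x
}

.header_token <- function(line) sub("\\s.*$", "", sub("^[>@]", "", line))

#' Read a FASTA file or string
#'
#' Headers are truncated at the first whitespace to form stable record ids;
#' multi-line sequences are concatenated and uppercased. Nucleotide input has
#' `U` mapped to `T` and ambiguity codes other than `N` mapped to `N` with a
#' warning; lowercase (soft-masked) letters are uppercased, not masked.
#'
#' @param x A file path, a connection, or a literal FASTA string (containing a
#'   newline).
#' @param alphabet `"dna"` or `"protein"`.
#' @return A list of [seq_record()] objects, named by id.
#' @export
read_fasta <- function(x, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  lines <- .as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records")
  if (!startsWith(lines[[1L]], ">")) stop("malformed FASTA: sequence before header")
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) stop("no records")
  ends <- c(hdr[-1L] - 1L, length(lines))
  norm <- if (alphabet == "dna") normalize_nucleotide else normalize_peptide
  recs <- vector("list", length(hdr))
  ids <- character(length(hdr))
  for (i in seq_along(hdr)) {
    id <- .header_token(lines[[hdr[i]]])
    if (!nzchar(id)) stop("malformed FASTA: empty header")
    seq_lines <- if (ends[i] >= hdr[i] + 1L) lines[(hdr[i] + 1L):ends[i]] else character()
    s <- paste(seq_lines, collapse = "")
    if (!nzchar(s)) stop("empty record: '", id, "'")
    recs[[i]] <- seq_record(id, norm(s, id))
    ids[i] <- id
  }
  if (anyDuplicated(ids))
    stop("duplicate record ids after header truncation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(recs) <- ids
  recs
}

.as_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  if (is.character(x)) return(x)
  stop("cannot read sequences from object of class ", class(x)[1L])
}

#' Write records as FASTA
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path, or `NULL` to return the text.
#' @param width Line-wrap width.
#' @return The FASTA text, invisibly when written to a file.
#' @export
write_fasta <- function(records, path = NULL, width = 60L) {
  out <- unlist(lapply(records, function(r) {
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", r$id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(out, path)
  invisible(txt)
}

#' Write records as FASTQ
#'
#' Records lacking quality get a flat quality string.
#' @inheritParams write_fasta
#' @export
write_fastq <- function(records, path = NULL) {
  out <- unlist(lapply(records, function(r) {
    q <- if (is.null(r$quality)) strrep("I", nchar(r$sequence)) else r$quality
    c(paste0("@", r$id), r$sequence, "+", q)
  }))
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(out, path)
  invisible(txt)
}

#' Stream records from a FASTA or FASTQ source
#'
#' Returns a zero-argument function that yields one [seq_record()] per call
#' and `NULL` at end of input, so arbitrarily large read sets are processed
#' one record at a time. The format is sniffed from the first character
#' (`>` FASTA, `@` FASTQ); on FASTA input the records are identical to
#' [read_fasta()]'s. FASTQ qualities are retained but unused downstream.
#'
#' @param x File path, connection, or literal FASTA/FASTQ text.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A function: the record stream.
#' @export
read_fastx <- function(x, alphabet = "dna") {
  src <- .line_source(x)
  first <- src$peek()
  if (is.null(first)) stop("no records")
  ch <- substr(first, 1L, 1L)
  if (ch == ">") return(.fasta_stream(src, alphabet))
  if (ch == "@") return(.fastq_stream(src, alphabet))
  stop("malformed input: expected '>' or '@' at start")
}

# Incremental line source with one-line lookahead. File paths and connections
# are read a line at a time, so memory stays bounded by one record; literal
# text is already in memory and is just split.
.line_source <- function(x) {
  if (inherits(x, "connection") ||
      (is.character(x) && length(x) == 1L && !grepl("\n", x) &&
       file.exists(x))) {
    con <- if (inherits(x, "connection")) x else file(x, "r")
    pending <- NULL
    done <- FALSE
    fetch <- function() {
      if (done) return(NULL)
      repeat {
        ln <- readLines(con, n = 1L, warn = FALSE)
        if (length(ln) == 0L) {
          done <<- TRUE
          try(close(con), silent = TRUE)
          return(NULL)
        }
        if (nzchar(trimws(ln))) return(ln)
      }
    }
    list(peek = function() {
           if (is.null(pending)) pending <<- fetch()
           pending
         },
         take = function() {
           out <- if (is.null(pending)) fetch() else pending
           pending <<- NULL
           out
         })
  } else {
    lines <- .as_lines(x)
    lines <- lines[nzchar(trimws(lines))]
    pos <- 0L
    list(peek = function() {
           if (pos < length(lines)) lines[[pos + 1L]] else NULL
         },
         take = function() {
           if (pos >= length(lines)) return(NULL)
           pos <<- pos + 1L
           lines[[pos]]
         })
  }
}

.fasta_stream <- function(src, alphabet) {
  norm <- if (alphabet == "dna") normalize_nucleotide else normalize_peptide
  function() {
    hdr <- src$take()
    if (is.null(hdr)) return(NULL)
    if (!startsWith(hdr, ">")) stop("malformed FASTA: sequence before header")
    id <- .header_token(hdr)
    parts <- character()
    repeat {
      nxt <- src$peek()
      if (is.null(nxt) || startsWith(nxt, ">")) break
      parts <- c(parts, src$take())
    }
    s <- paste(parts, collapse = "")
    if (!nzchar(s)) stop("empty record: '", id, "'")
    seq_record(id, norm(s, id))
  }
}

.fastq_stream <- function(src, alphabet) {
  norm <- if (alphabet == "dna") normalize_nucleotide else normalize_peptide
  function() {
    hdr <- src$take()
    if (is.null(hdr)) return(NULL)
    if (!startsWith(hdr, "@")) stop("malformed FASTQ: expected '@' header")
    id <- .header_token(hdr)
    s <- src$take()
    plus <- src$take()
    q <- src$take()
    if (is.null(s) || is.null(plus) || is.null(q))
      stop("malformed FASTQ: truncated record")
    if (!startsWith(plus, "+")) stop("malformed FASTQ: expected '+' line")
    if (nchar(q) != nchar(s))
      stop("malformed FASTQ: quality length differs from sequence length for '",
           id, "'")
    seq_record(id, norm(s, id), quality = q)
  }
}

#' Turn an in-memory record list into a stream
#' @param records List of [seq_record()] objects.
#' @return A function yielding one record per call, then `NULL`.
#' @export
stream_from_records <- function(records) {
  pos <- 0L
  function() {
    pos <<- pos + 1L
    if (pos > length(records)) NULL else records[[pos]]
  }
}

#' Collect a record stream into a list
#' @param stream A record stream as returned by [read_fastx()].
#' @param n Maximum number of records to take (`Inf` for all).
#' @return List of [seq_record()] objects.
#' @export
stream_collect <- function(stream, n = Inf) {
  out <- list()
  while (length(out) < n) {
    r <- stream()
    if (is.null(r)) break
    out[[length(out) + 1L]] <- r
  }
  out
}
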