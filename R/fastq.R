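#' @useDynLib blockfq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

NL <- as.raw(10L)

#' Construct a FASTQ record
#'
#' A record is one 4-line sequencing read. Pad spaces belong to the blocked
#' dialect and live on the quality line only; they are never part of a
#' parsed record, so `nchar(sequence) == nchar(quality)` always holds.
#'
#' @param name Read name, without the leading `@` (non-empty, no whitespace).
#' @param sequence Base string; must not contain whitespace.
#' @param quality Quality string of the same length as `sequence`.
#' @param comment Optional text after the first whitespace of the header.
#' @param plus_text Optional text after `+` on line 3 (kept for round
#'   trips; canonical output writes a bare `+`).
#' @return An object of class `fastq_record`.
#' @examples
#' r <- fastq_record("r1", "ACGT", "IIII")
#' rawToChar(serialize_fastq_record(r))
#' @export
fastq_record <- function(name, sequence, quality, comment = NA_character_,
                         plus_text = NA_character_) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(name)) {
    stop("malformed record: read name must be a non-empty string")
  }
  if (grepl("[ \t\n]", name)) {
    stop("malformed record: whitespace in read name")
  }
  if (grepl("[ \t\n]", sequence)) {
    stop("malformed record: whitespace in sequence")
  }
  if (nchar(sequence) != nchar(quality)) {
    stop("malformed record: sequence/quality length mismatch for '",
         name, "'")
  }
  structure(
    list(name = name, comment = comment, sequence = sequence,
         quality = quality, plus_text = plus_text),
    class = "fastq_record"
  )
}

#' @export
print.fastq_record <- function(x, ...) {
  cat("<fastq_record> @", x$name,
      if (!is.na(x$comment)) paste0(" ", x$comment), "\n", sep = "")
  cat("  ", x$sequence, "\n  ", x$quality, "\n", sep = "")
  invisible(x)
}

#' @export
format.fastq_record <- function(x, ...) {
  paste0("@", x$name, if (!is.na(x$comment)) paste0(" ", x$comment),
         " [", nchar(x$sequence), " nt]")
}

as_raw_bytes <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x)) {
      return(readBin(x, what = "raw", n = file.size(x)))
    }
    return(charToRaw(x))
  }
  stop("expected a raw vector, file path or single string")
}

#' Open a byte stream over FASTQ input
#'
#' The stream tracks a cursor into the underlying bytes; newline offsets are
#' indexed once so boundary scanning is O(1) per record.
#'
#' @param x A file path, a raw vector, or a single string of FASTQ bytes.
#' @return An environment of class `fastq_stream`.
#' @seealso [scan_record_boundary()]
#' @export
fastq_stream <- function(x) {
  bytes <- as_raw_bytes(x)
  s <- new.env(parent = emptyenv())
  s$bytes <- bytes
  s$nl <- which(bytes == NL)
  s$pos <- 1L          # next unread byte (1-based)
  s$nl_ptr <- 1L       # index of next unconsumed newline in s$nl
  class(s) <- "fastq_stream"
  s
}

#' Scan one raw record off a stream
#'
#' Finds the record boundary by counting four newlines; no parsing happens.
#' This is exactly the amount of work the deferred strategies perform inside
#' their input critical section.
#'
#' @param stream A [fastq_stream()].
#' @return The raw bytes of one 4-line record (up to and including the 4th
#'   newline), or `NULL` at end of stream. A whitespace-only tail is
#'   consumed silently as end of stream.
#' @export
scan_record_boundary <- function(stream) {
  stopifnot(inherits(stream, "fastq_stream"))
  n <- length(stream$bytes)
  if (stream$pos > n) return(NULL)
  if (stream$nl_ptr + 3L > length(stream$nl)) {
    tail_bytes <- stream$bytes[stream$pos:n]
    if (all(tail_bytes %in% as.raw(c(32L, 10L, 9L, 13L)))) {
      stream$pos <- n + 1L
      return(NULL)
    }
    stop("truncated record: end of input inside a 4-line record")
  }
  end <- stream$nl[stream$nl_ptr + 3L]
  buf <- stream$bytes[stream$pos:end]
  stream$pos <- end + 1L
  stream$nl_ptr <- stream$nl_ptr + 4L
  buf
}

#' Parse one raw 4-line record
#'
#' Splits the header into name and comment at the first whitespace, strips
#' trailing pad spaces from the quality line (the blocked-FASTQ dialect puts
#' its padding there), and enforces the length invariant. Carriage returns
#' anywhere are rejected: block arithmetic requires one newline byte.
#'
#' @param buf Raw bytes (or a single string) of exactly one 4-line record.
#' @return A [fastq_record()].
#' @examples
#' parse_fastq_record("@r1\nACGT\n+\nIIII\n")
#' # pad spaces on the quality line are transparent:
#' parse_fastq_record("@r1\nACGT\n+\nIIII        \n")
#' @export
parse_fastq_record <- function(buf) {
  if (is.character(buf)) buf <- charToRaw(paste(buf, collapse = "\n"))
  stopifnot(is.raw(buf))
  if (length(buf) == 0L) stop("malformed record: empty buffer")
  if (any(buf == as.raw(13L))) {
    stop("malformed record: carriage return in record")
  }
  if (buf[length(buf)] != NL || sum(buf == NL) != 4L) {
    stop("malformed record: expected exactly 4 newline-terminated lines")
  }
  txt <- rawToChar(buf)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  if (length(lines) != 4L) {
    stop("malformed record: expected 4 lines")
  }
  if (!startsWith(lines[1L], "@")) {
    stop("malformed record: header must start with '@'")
  }
  if (!startsWith(lines[3L], "+")) {
    stop("malformed record: line 3 must start with '+'")
  }
  hdr <- substring(lines[1L], 2L)
  sp <- regexpr("[ \t]", hdr)
  if (sp > 0L) {
    name <- substr(hdr, 1L, sp - 1L)
    comment <- substring(hdr, sp + 1L)
  } else {
    name <- hdr
    comment <- NA_character_
  }
  if (!nzchar(name)) stop("malformed record: empty read name")
  seq <- lines[2L]
  if (grepl("[ \t]", seq)) {
    stop("malformed record: whitespace in sequence")
  }
  qual <- sub(" +$", "", lines[4L])
  if (nchar(qual) != nchar(seq)) {
    stop("malformed record: sequence/quality length mismatch for '",
         name, "'")
  }
  plus <- substring(lines[3L], 2L)
  fastq_record(name, seq, qual,
               comment = comment,
               plus_text = if (nzchar(plus)) plus else NA_character_)
}

#' Serialize a record, optionally padded to an exact byte count
#'
#' Pad spaces are inserted on the quality line immediately before its final
#' newline, so a padded record still contains exactly four newlines and
#' deferred boundary scanning is unaffected.
#'
#' @param rec A [fastq_record()].
#' @param pad_to Optional total byte count; must be at least the unpadded
#'   length, otherwise an infeasible-padding error is raised.
#' @param keep_plus_text Emit `plus_text` on line 3 if present. The default
#'   writes a bare `+` (canonical output).
#' @return A raw vector.
#' @export
serialize_fastq_record <- function(rec, pad_to = NULL,
                                   keep_plus_text = FALSE) {
  stopifnot(inherits(rec, "fastq_record"))
  hdr <- paste0("@", rec$name,
                if (!is.na(rec$comment)) paste0(" ", rec$comment))
  plus <- paste0("+", if (keep_plus_text && !is.na(rec$plus_text))
    rec$plus_text)
  body <- paste0(hdr, "\n", rec$sequence, "\n", plus, "\n", rec$quality)
  base_len <- nchar(body, type = "bytes") + 1L
  pad <- 0L
  if (!is.null(pad_to)) {
    pad <- as.integer(pad_to) - base_len
    if (pad < 0L) {
      stop("infeasible padding: record needs ", base_len,
           " bytes but pad_to is ", pad_to)
    }
  }
  charToRaw(paste0(body, strrep(" ", pad), "\n"))
}

serialized_size <- function(rec) {
  length(serialize_fastq_record(rec))
}

#' Read a FASTQ file into a list of records
#'
#' @param x File path, raw vector or string. Trailing quality-line pad
#'   spaces (the blocked dialect) are stripped transparently.
#' @return A list of [fastq_record()] objects.
#' @export
read_fastq <- function(x) {
  s <- fastq_stream(x)
  out <- list()
  i <- 0L
  repeat {
    buf <- scan_record_boundary(s)
    if (is.null(buf)) break
    i <- i + 1L
    out[[i]] <- parse_fastq_record(buf)
  }
  out
}

#' Write records as canonical FASTQ
#'
#' @param records List of [fastq_record()] objects.
#' @param path Output path, or `NULL` to return the bytes.
#' @param pad_to Optional per-record byte counts (recycled).
#' @return The raw bytes, invisibly when written to `path`.
#' @export
write_fastq <- function(records, path = NULL, pad_to = NULL) {
  if (length(records) == 0L) {
    bytes <- raw(0)
  } else {
    pads <- if (is.null(pad_to)) vector("list", length(records)) else
      as.list(rep_len(pad_to, length(records)))
    chunks <- mapply(function(r, p) serialize_fastq_record(r, pad_to = p),
                     records, pads, SIMPLIFY = FALSE)
    bytes <- do.call(c, chunks)
  }
  if (is.null(path)) return(bytes)
  writeBin(bytes, path)
  invisible(bytes)
}

#' Tabulate records for comparison and joins
#'
#' @param records List of [fastq_record()] objects.
#' @return A data frame with columns `name`, `comment`, `sequence`,
#'   `quality`.
#' @export
fastq_table <- function(records) {
  data.frame(
    name = vapply(records, `[[`, "", "name"),
    comment = vapply(records, `[[`, "", "comment"),
    sequence = vapply(records, `[[`, "", "sequence"),
    quality = vapply(records, `[[`, "", "quality"),
    stringsAsFactors = FALSE
  )
}

# Mate-suffix-insensitive read name ("/1", "/2" stripped).
strip_mate_suffix <- function(names) {
  sub("/[12]$", "", names)
}
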