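#' Block specification for blocked FASTQ
#'
#' A blocked FASTQ file is divided into blocks of exactly `block_bytes` (B)
#' bytes; every block starts a record and holds exactly `reads_per_block`
#' (N) records, except possibly the last, which may hold fewer but is still
#' padded out to B bytes. Space padding is carried on the quality line of
#' each block's final record.
#'
#' @param block_bytes Positive integer B, the fixed block size in bytes.
#' @param reads_per_block Positive integer N, records per full block.
#' @return An object of class `block_spec`.
#' @examples
#' block_spec(12288, 44)
#' @export
block_spec <- function(block_bytes, reads_per_block) {
  block_bytes <- as.integer(block_bytes)
  reads_per_block <- as.integer(reads_per_block)
  if (is.na(block_bytes) || block_bytes < 1L) {
    stop("block_bytes must be a positive integer")
  }
  if (is.na(reads_per_block) || reads_per_block < 1L) {
    stop("reads_per_block must be a positive integer")
  }
  # smallest possible record ("@x\nA\n+\nI\n") is 9 bytes
  if (block_bytes < reads_per_block * 9L) {
    stop("infeasible spec: block_bytes (", block_bytes,
         ") cannot hold ", reads_per_block, " records of >= 9 bytes")
  }
  structure(list(block_bytes = block_bytes,
                 reads_per_block = reads_per_block),
            class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat("<block_spec> B =", x$block_bytes, "bytes, N =", x$reads_per_block,
      "reads per block\n")
  invisible(x)
}

blocks_of <- function(records, spec) {
  n <- length(records)
  if (n == 0L) return(list())
  split(records, (seq_len(n) - 1L) %/% spec$reads_per_block)
}

#' Convert standard FASTQ to blocked FASTQ
#'
#' Records are re-serialized canonically, grouped N at a time, and each
#' group's final record is padded with spaces (before its terminating
#' newline) so the group occupies exactly B bytes. The final, possibly
#' short, group is also padded to a full B bytes so a reader can always
#' request exactly B bytes.
#'
#' @param input File path, raw vector, string, or list of
#'   [fastq_record()] objects.
#' @param spec A [block_spec()].
#' @param output Optional path to write; otherwise the bytes are returned.
#' @return Raw vector of blocked FASTQ bytes (invisibly when written).
#' @examples
#' recs <- generate_fastq(4, read_length = 10, seed = 1)
#' blocked <- pad_fastq(recs, block_spec(64, 2))
#' length(blocked)  # 2 blocks x 64 bytes
#' @export
pad_fastq <- function(input, spec, output = NULL) {
  stopifnot(inherits(spec, "block_spec"))
  records <- if (is.list(input)) input else read_fastq(input)
  groups <- blocks_of(records, spec)
  chunks <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    grp <- groups[[i]]
    sizes <- vapply(grp, serialized_size, 0L)
    if (sum(sizes) > spec$block_bytes) {
      stop("infeasible spec: block ", i - 1L, " needs ", sum(sizes),
           " bytes but block_bytes is ", spec$block_bytes)
    }
    head_bytes <- if (length(grp) > 1L) {
      do.call(c, lapply(grp[-length(grp)], serialize_fastq_record))
    } else {
      raw(0)
    }
    last_pad <- spec$block_bytes - sum(sizes[-length(sizes)])
    chunks[[i]] <- c(head_bytes,
                     serialize_fastq_record(grp[[length(grp)]],
                                            pad_to = last_pad))
  }
  bytes <- if (length(chunks)) do.call(c, chunks) else raw(0)
  if (is.null(output)) return(bytes)
  writeBin(bytes, output)
  invisible(bytes)
}

#' Convert a pair of FASTQ files to blocked FASTQ with matched blocks
#'
#' Both files are blocked independently under the same spec. Because both
#' place record `i` in block `i %/% N`, corresponding B-byte blocks of the
#' two outputs are guaranteed to contain N corresponding reads; the two
#' files generally need different amounts of padding when the two ends
#' differ in length.
#'
#' @param end1,end2 Inputs as in [pad_fastq()]; equal record counts, record
#'   `i` of each the two mates of fragment `i`.
#' @param spec A [block_spec()].
#' @param out1,out2 Optional output paths.
#' @return List with elements `end1` and `end2` (raw vectors).
#' @export
pad_fastq_paired <- function(end1, end2, spec, out1 = NULL, out2 = NULL) {
  r1 <- if (is.list(end1)) end1 else read_fastq(end1)
  r2 <- if (is.list(end2)) end2 else read_fastq(end2)
  if (length(r1) != length(r2)) {
    stop("pairing error: record counts differ (", length(r1), " vs ",
         length(r2), ")")
  }
  n1 <- strip_mate_suffix(vapply(r1, `[[`, "", "name"))
  n2 <- strip_mate_suffix(vapply(r2, `[[`, "", "name"))
  bad <- which(n1 != n2)
  if (length(bad)) {
    stop("pairing error: mate names differ at record ", bad[1L], " ('",
         n1[bad[1L]], "' vs '", n2[bad[1L]], "')")
  }
  b1 <- pad_fastq(r1, spec, output = out1)
  b2 <- pad_fastq(r2, spec, output = out2)
  invisible(list(end1 = b1, end2 = b2))
}

# Parse a blocked file block by block. Returns records plus a violations
# data frame (block is 0-based, matching byte offset block * B).
parse_blocked <- function(bytes, spec) {
  B <- spec$block_bytes
  N <- spec$reads_per_block
  violations <- list()
  add <- function(block, desc) {
    violations[[length(violations) + 1L]] <<-
      data.frame(block = block, description = desc,
                 stringsAsFactors = FALSE)
  }
  n <- length(bytes)
  records <- list()
  if (n %% B != 0L) {
    add(NA_integer_, sprintf(
      "file size %d is not a multiple of block_bytes %d", n, B))
  }
  n_blocks <- n %/% B
  for (k in seq_len(n_blocks) - 1L) {
    blk <- bytes[(k * B + 1L):((k + 1L) * B)]
    if (blk[1L] != charToRaw("@")) {
      add(k, sprintf("byte offset %d does not begin with '@'", k * B))
      next
    }
    s <- fastq_stream(blk)
    blk_records <- list()
    consumed <- 0L
    ok <- TRUE
    repeat {
      buf <- tryCatch(scan_record_boundary(s),
                      error = function(e) conditionMessage(e))
      if (is.character(buf)) {
        add(k, buf)
        ok <- FALSE
        break
      }
      if (is.null(buf)) break
      rec <- tryCatch(parse_fastq_record(buf),
                      error = function(e) conditionMessage(e))
      if (is.character(rec)) {
        add(k, rec)
        ok <- FALSE
        break
      }
      # padding is legal only as trailing spaces on the quality line
      lines <- strsplit(rawToChar(buf), "\n", fixed = TRUE)[[1L]]
      if (any(grepl(" $", lines[1:3]))) {
        add(k, "padding outside the quality line")
        ok <- FALSE
        break
      }
      consumed <- consumed + length(buf)
      blk_records[[length(blk_records) + 1L]] <- rec
    }
    if (!ok) next
    if (consumed != B) {
      add(k, sprintf(
        "block has %d trailing bytes after the final record's newline",
        B - consumed))
    }
    n_rec <- length(blk_records)
    if (k < n_blocks - 1L && n_rec != N) {
      add(k, sprintf("full block holds %d records, expected %d", n_rec, N))
    }
    if (k == n_blocks - 1L && (n_rec < 1L || n_rec > N)) {
      add(k, sprintf("final block holds %d records, expected 1..%d",
                     n_rec, N))
    }
    records <- c(records, blk_records)
  }
  viol <- if (length(violations)) do.call(rbind, violations) else
    data.frame(block = integer(), description = character(),
               stringsAsFactors = FALSE)
  list(records = records, violations = viol, blocks_checked = n_blocks)
}

#' Validate a blocked FASTQ file against its spec
#'
#' Checks, without throwing: file size divisible by B; `@` at every
#' multiple-of-B offset; exactly N parseable records per full block (1..N
#' in the final block); padding only as trailing quality-line spaces; no
#' bytes after each block's final newline.
#'
#' @param input File path, raw vector or string of blocked FASTQ bytes.
#' @param spec A [block_spec()].
#' @return An object of class `validation_report` with fields
#'   `blocks_checked`, `records_found`, `violations` (data frame with
#'   0-based `block` and `description`) and `conforming`.
#' @export
validate_blocked <- function(input, spec) {
  stopifnot(inherits(spec, "block_spec"))
  bytes <- as_raw_bytes(input)
  res <- parse_blocked(bytes, spec)
  structure(
    list(blocks_checked = res$blocks_checked,
         records_found = length(res$records),
         violations = res$violations,
         conforming = nrow(res$violations) == 0L),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$blocks_checked, "blocks,",
      x$records_found, "records,",
      nrow(x$violations), "violation(s)\n")
  if (nrow(x$violations)) {
    print(utils::head(x$violations, 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Recover standard FASTQ from a blocked file
#'
#' The inverse of [pad_fastq()]: validates the input and emits the records
#' in canonical serialization, so `unpad_fastq(pad_fastq(F))` is
#' byte-identical to the canonical serialization of `F`.
#'
#' @inheritParams validate_blocked
#' @param output Optional path to write.
#' @return Raw FASTQ bytes (invisibly when written).
#' @export
unpad_fastq <- function(input, spec, output = NULL) {
  stopifnot(inherits(spec, "block_spec"))
  bytes <- as_raw_bytes(input)
  res <- parse_blocked(bytes, spec)
  if (nrow(res$violations)) {
    v <- res$violations[1L, ]
    stop("validation error in block ", v$block, ": ", v$description)
  }
  write_fastq(res$records, path = output)
}

#' Largest feasible reads-per-block for a sample of records
#'
#' Returns the largest N such that every window of N consecutive sample
#' records fits in `block_bytes` when serialized canonically (the block
#' feasibility rule used by [pad_fastq()]). N is capped at the sample size,
#' the largest count the sample can justify.
#'
#' @param sample Non-empty list of [fastq_record()] objects.
#' @param block_bytes Block size B in bytes.
#' @return Integer N >= 1.
#' @export
max_reads_per_block <- function(sample, block_bytes) {
  if (!length(sample)) stop("sample must be non-empty")
  sizes <- vapply(sample, serialized_size, 0L)
  if (max(sizes) > block_bytes) {
    stop("infeasible spec: largest record (", max(sizes),
         " bytes) exceeds block_bytes (", block_bytes, ")")
  }
  cs <- cumsum(c(0L, sizes))
  len <- length(sizes)
  best <- 1L
  for (n in seq_len(len)) {
    win_max <- max(cs[(n + 1L):(len + 1L)] - cs[1L:(len - n + 1L)])
    if (win_max <= block_bytes) best <- n else break
  }
  best
}

#' Uncompressed and gzip size inflation from padding
#'
#' Reports how much the space padding grows the file, raw and after gzip
#' (pad runs compress well). Informational; used by the CLI.
#'
#' @param plain Raw bytes of the standard file.
#' @param blocked Raw bytes of the blocked file.
#' @return Named list of sizes and percent inflation.
#' @export
padding_inflation <- function(plain, blocked) {
  plain <- as_raw_bytes(plain)
  blocked <- as_raw_bytes(blocked)
  gz_p <- length(memCompress(plain, type = "gzip"))
  gz_b <- length(memCompress(blocked, type = "gzip"))
  list(
    plain_bytes = length(plain),
    blocked_bytes = length(blocked),
    raw_inflation_pct = if (length(plain)) {
      100 * (length(blocked) - length(plain)) / length(plain)
    } else 0,
    plain_gzip_bytes = gz_p,
    blocked_gzip_bytes = gz_b,
    gzip_inflation_pct = if (gz_p) 100 * (gz_b - gz_p) / gz_p else 0
  )
}
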