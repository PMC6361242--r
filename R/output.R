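#' Stripe plan for multi-file output
#'
#' Striped output spreads result writing over `stripe_count` files, each
#' with its own lock; thread `t` writes to stripe `t %% stripe_count`.
#' Stripe files are named `<prefix>.<index>.sam` with 0-based indices.
#'
#' @param stripe_count Number of stripes S (default 16).
#' @return Object of class `stripe_plan`.
#' @export
stripe_plan <- function(stripe_count = 16L) {
  stripe_count <- as.integer(stripe_count)
  stopifnot(stripe_count >= 1L)
  structure(list(stripe_count = stripe_count), class = "stripe_plan")
}

#' @rdname stripe_plan
#' @param plan A [stripe_plan()].
#' @param thread_id 0-based thread id(s).
#' @return `stripe_for_thread()`: 0-based stripe index, `thread_id mod S`.
#' @export
stripe_for_thread <- function(plan, thread_id) {
  stopifnot(inherits(plan, "stripe_plan"))
  as.integer(thread_id) %% plan$stripe_count
}

stripe_paths <- function(prefix, stripes) {
  if (stripes > 0L) {
    paste0(prefix, ".", seq_len(stripes) - 1L, ".sam")
  } else {
    paste0(prefix, ".sam")
  }
}

sam_header_lines <- "@HD\tVN:1.6\tSO:unknown"

#' Open a single or striped output sink
#'
#' Creates the output file(s) up front (so every stripe exists even if some
#' threads never write) and writes the header once per file.
#'
#' @param prefix Output path prefix; files are `<prefix>.sam` or
#'   `<prefix>.<i>.sam`.
#' @param stripes Number of stripes; 0 means a single output file.
#' @param header Write a SAM `@HD` header line per file.
#' @return Object of class `output_sink`.
#' @export
output_sink <- function(prefix, stripes = 0L, header = TRUE) {
  stripes <- as.integer(stripes)
  stopifnot(stripes >= 0L)
  paths <- stripe_paths(prefix, stripes)
  for (p in paths) {
    writeLines(if (header) sam_header_lines else character(0), p)
  }
  structure(list(prefix = prefix, stripes = stripes, paths = paths,
                 header = header),
            class = "output_sink")
}

#' Append complete result lines for one thread
#'
#' Single sink: all threads append to one file (serialized by the caller or
#' by single-threaded use). Striped sink: the thread writes only to its
#' mapped stripe. Lines must be complete records; the newline is added.
#' This is the R-level (single-threaded) counterpart of the writer built
#' into the threaded engine of [run_job()].
#'
#' @param sink An [output_sink()].
#' @param thread_id 0-based id of the writing thread.
#' @param lines Character vector of complete, newline-free records.
#' @return The path written to, invisibly.
#' @export
write_results <- function(sink, thread_id, lines) {
  stopifnot(inherits(sink, "output_sink"))
  if (any(grepl("\n", lines, fixed = TRUE))) {
    stop("lines must be single complete records without interior newlines")
  }
  idx <- if (sink$stripes > 0L) {
    as.integer(thread_id) %% sink$stripes + 1L
  } else {
    1L
  }
  path <- sink$paths[idx]
  con <- file(path, open = "ab")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Concatenate stripe files into one output
#'
#' Stripes are concatenated in stripe order. Headers (leading `@` lines)
#' are checked to be identical copies across stripes and written once;
#' every non-header line of every stripe is preserved.
#'
#' @param prefix Stripe path prefix used when writing, or `NULL` if
#'   `files` is given.
#' @param stripes Number of stripes expected under `prefix`.
#' @param files Explicit character vector of stripe files (in order).
#' @param out Output path, or `NULL` to return the lines.
#' @return Character vector of merged lines (invisibly when written).
#' @export
merge_stripes <- function(prefix = NULL, stripes = 16L, files = NULL,
                          out = NULL) {
  if (is.null(files)) {
    stopifnot(!is.null(prefix))
    files <- stripe_paths(prefix, as.integer(stripes))
  }
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("missing stripe file(s): ", paste(missing, collapse = ", "))
  }
  per <- lapply(files, readLines)
  headers <- lapply(per, function(x) x[startsWith(x, "@")])
  bodies <- lapply(per, function(x) x[!startsWith(x, "@")])
  hdr <- headers[[1L]]
  same <- vapply(headers, identical, NA, hdr)
  if (!all(same)) {
    stop("stripe headers are not identical copies; refusing to merge")
  }
  merged <- c(hdr, unlist(bodies, use.names = FALSE))
  if (is.null(out)) return(merged)
  writeLines(merged, out)
  invisible(merged)
}
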