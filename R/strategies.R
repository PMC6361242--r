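as_input_path <- function(x, dir = tempdir()) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(x)
  p <- tempfile("blockfq_in_", tmpdir = dir, fileext = ".fastq")
  if (is.list(x)) {
    write_fastq(x, p)
  } else {
    writeBin(as_raw_bytes(x), p)
  }
  p
}

#' Consume a FASTQ file with a synchronized parsing strategy
#'
#' Runs `threads` OS worker threads over the input under the chosen lock
#' discipline, each looping: enter the input critical section (CS), take
#' the strategy's unit of input, leave the CS, then parse (where deferred)
#' outside the CS. The four strategies differ only in what the CS does:
#' \describe{
#'   \item{`O` (original)}{read one record and parse it inside the CS.}
#'   \item{`D` (deferred)}{one 4-newline boundary scan inside the CS;
#'     parsing happens outside.}
#'   \item{`B` (batch deferred)}{`batch_size` boundary scans per CS entry
#'     (default 32), cutting CS entries by that factor.}
#'   \item{`L` (block deferred)}{one fixed-size read of exactly B bytes;
#'     requires blocked input conforming to `block_spec`.}
#' }
#' A CS entry is counted only when it yields input, so the entry counts
#' obey: entries(O) = entries(D) = records, entries(B) =
#' `ceiling(records / batch_size)`, entries(L) = blocks.
#'
#' @param input FASTQ input (path, raw, string, or record list).
#' @param strategy One of `"O"`, `"D"`, `"B"`, `"L"`.
#' @param threads Number of worker threads.
#' @param lock Lock discipline for the input CS (see [bq_lock()]).
#' @param batch_size Records per CS entry for B-parsing.
#' @param block_spec A [block_spec()]; required for (and only for) `"L"`.
#' @param input2 Optional second (mate) input for paired reading. Paired
#'   `L` reads a B-byte block from the same offset of both files in one CS
#'   entry, which the blocked-FASTQ guarantee makes mate-consistent.
#' @param max_records Optional cap on records consumed per file.
#' @param spin_budget_us Spin budget for the spin discipline.
#' @return List with `records` (data frame: name, comment, sequence,
#'   quality, mate, thread), `cs` (entries, wait_us, hold_us), `blocks`,
#'   and `lock_stats`.
#' @examples
#' recs <- generate_fastq(64, read_length = 20, seed = 1)
#' out <- consume_fastq(recs, strategy = "B", threads = 2)
#' out$cs$entries  # ceiling(64 / 32)
#' @export
consume_fastq <- function(input, strategy = c("B", "O", "D", "L"),
                          threads = 1L, lock = "queueing",
                          batch_size = 32L, block_spec = NULL,
                          input2 = NULL, max_records = NULL,
                          spin_budget_us = 50) {
  strategy <- match.arg(strategy)
  lock <- normalize_lock_kind(lock)
  if (strategy == "L" && is.null(block_spec)) {
    stop("configuration error: L-parsing requires a block_spec")
  }
  if (!is.null(block_spec)) stopifnot(inherits(block_spec, "block_spec"))
  p1 <- as_input_path(input)
  p2 <- if (is.null(input2)) "" else as_input_path(input2)
  res <- cpp_run(
    p1, p2, strategy, as.integer(threads), lock, spin_budget_us,
    as.integer(batch_size),
    if (is.null(block_spec)) -1 else block_spec$block_bytes,
    if (is.null(block_spec)) -1L else block_spec$reads_per_block,
    if (is.null(max_records)) -1 else as.numeric(max_records),
    0L, 0, "", 0L, FALSE, TRUE
  )
  list(
    records = as.data.frame(res$records, stringsAsFactors = FALSE),
    cs = list(entries = res$entries, wait_us = res$wait_us,
              hold_us = res$hold_us),
    blocks = res$blocks,
    lock_stats = list(acquisitions = res$lock_acquisitions,
                      contended = res$lock_contended,
                      wait_us = res$lock_wait_us)
  )
}
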