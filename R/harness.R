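#' Run one benchmark job
#'
#' Executes the embarrassingly parallel thread model: `threads` workers
#' loop get-batch (under the chosen strategy and lock discipline) ->
#' stand-in per-read workload -> write a result line (single or striped
#' sink). One-time setup (file loading, sink creation, thread spawn) is
#' excluded from the timed region; each worker reports its own wall time
#' with microsecond accuracy, and throughput uses the per-thread maximum
#' as denominator.
#'
#' The stand-in workload is a seeded integer mixer applied to the read
#' bytes `workload_cost` times; its result is folded into the output line
#' so the computation cannot be elided. It stands in for an aligner's
#' per-read CPU cost, which is the quantity that matters for the
#' synchronization mechanisms measured here.
#'
#' @inheritParams consume_fastq
#' @param reads_per_thread If given, the job consumes exactly
#'   `threads * reads_per_thread` records; excess input is ignored.
#' @param workload_cost Iterations of the stand-in per-read computation.
#' @param output_prefix Path prefix for SAM-dialect output, or `NULL` to
#'   write to a temporary prefix.
#' @param stripes 0 for a single output file, otherwise the stripe count
#'   (each thread writes to stripe `thread %% stripes`).
#' @param seed Seed folded into the stand-in workload.
#' @param sam_header Write an `@HD` header line per output file.
#' @param collect_records Also return the consumed records (for
#'   conservation checks; adds memory).
#' @return Object of class `job_result`: `threads`, `total_records`,
#'   `per_thread_us`, `max_thread_us`, `throughput_rps`, `cs`,
#'   `lock_stats`, `output_files`, and optionally `records`.
#' @examples
#' recs <- generate_fastq(200, read_length = 30, seed = 2)
#' job <- run_job(recs, strategy = "B", threads = 2, workload_cost = 1)
#' job$cs$entries  # ceiling(200 / 32)
#' @export
run_job <- function(input, input2 = NULL, strategy = c("B", "O", "D", "L"),
                    lock = "queueing", threads = 1L,
                    reads_per_thread = NULL, workload_cost = 1L,
                    batch_size = 32L, block_spec = NULL,
                    output_prefix = NULL, stripes = 0L, seed = 1L,
                    spin_budget_us = 50, sam_header = TRUE,
                    collect_records = FALSE) {
  strategy <- match.arg(strategy)
  lock <- normalize_lock_kind(lock)
  threads <- as.integer(threads)
  stopifnot(threads >= 1L)
  if (strategy == "L" && is.null(block_spec)) {
    stop("configuration error: L-parsing requires a block_spec")
  }
  p1 <- as_input_path(input)
  p2 <- if (is.null(input2)) "" else as_input_path(input2)
  if (is.null(output_prefix)) {
    output_prefix <- tempfile("blockfq_out_")
  }
  max_records <- if (is.null(reads_per_thread)) -1 else
    threads * as.numeric(reads_per_thread)
  t0 <- proc.time()[["elapsed"]]
  res <- cpp_run(
    p1, p2, strategy, threads, lock, spin_budget_us,
    as.integer(batch_size),
    if (is.null(block_spec)) -1 else block_spec$block_bytes,
    if (is.null(block_spec)) -1L else block_spec$reads_per_block,
    max_records, as.integer(workload_cost), as.numeric(seed),
    output_prefix, as.integer(stripes), sam_header, collect_records
  )
  wall_s <- proc.time()[["elapsed"]] - t0
  out_files <- res$output_files
  n_lines <- sum(vapply(out_files, function(p) {
    length(readLines(p)) - if (sam_header) 1L else 0L
  }, 0L))
  total <- if (p2 == "") n_lines else n_lines / 2
  max_us <- max(res$per_thread_us)
  structure(list(
    strategy = strategy, lock = lock, threads = threads,
    total_records = total,
    per_thread_us = as.numeric(res$per_thread_us),
    max_thread_us = max_us,
    wall_s = wall_s,
    throughput_rps = total / (max_us / 1e6),
    cs = list(entries = res$entries, wait_us = res$wait_us,
              hold_us = res$hold_us),
    blocks = res$blocks,
    lock_stats = list(acquisitions = res$lock_acquisitions,
                      contended = res$lock_contended,
                      wait_us = res$lock_wait_us),
    output_files = out_files,
    records = if (collect_records) {
      as.data.frame(res$records, stringsAsFactors = FALSE)
    }
  ), class = "job_result")
}

#' @export
print.job_result <- function(x, ...) {
  cat("<job_result> ", x$strategy, "-parsing, ", x$lock, " lock, T = ",
      x$threads, "\n", sep = "")
  cat("  records: ", x$total_records,
      "; CS entries: ", x$cs$entries, "\n", sep = "")
  cat(sprintf("  max per-thread time: %.3f s; throughput: %.0f reads/s\n",
              x$max_thread_us / 1e6, x$throughput_rps))
  invisible(x)
}

#' Weak-scaling experiment over a grid of thread counts
#'
#' For each thread count T the job consumes `T * reads_per_thread` reads,
#' so per-thread workload is constant; ideal scaling is a flat per-thread
#' time. Inputs are synthesized deterministically per grid point (and
#' blocked on the fly for L-parsing). Jobs whose wall time exceeds
#' `time_limit` seconds are marked aborted and excluded from peak
#' selection.
#'
#' @param threads Integer vector of thread counts.
#' @param reads_per_thread Reads consumed per thread at every grid point.
#' @param strategy,lock,workload_cost,batch_size,stripes Passed to
#'   [run_job()].
#' @param read_length Synthetic read length.
#' @param paired Generate and consume mated files.
#' @param block_bytes Block size when `strategy = "L"`.
#' @param time_limit Per-job wall-time limit in seconds (default 1200).
#' @param seed Base seed for input synthesis and the workload.
#' @return A `scaling_table` data frame with one row per thread count:
#'   `threads`, `reads`, `max_thread_s`, `wall_s`, `throughput_rps`,
#'   `cs_entries`, `aborted`, plus an `mp_throughput_rps` column (NA) for
#'   recording externally measured multiprocessing baselines.
#' @export
weak_scaling <- function(threads = c(1L, 2L, 4L), reads_per_thread = 1000L,
                         strategy = "B", lock = "queueing",
                         workload_cost = 1L, batch_size = 32L,
                         read_length = 100L, paired = FALSE,
                         stripes = 0L, block_bytes = 12288L,
                         time_limit = 1200, seed = 1L) {
  rows <- lapply(seq_along(threads), function(i) {
    t_i <- as.integer(threads[i])
    n <- t_i * as.integer(reads_per_thread)
    gen <- generate_fastq(n, read_length = read_length,
                          seed = as.integer(seed) + i, paired = paired)
    spec <- NULL
    if (strategy == "L") {
      sample_recs <- if (paired) c(gen$end1, gen$end2) else gen
      n_per_block <- max_reads_per_block(sample_recs, block_bytes)
      spec <- block_spec(block_bytes, n_per_block)
      if (paired) {
        b <- pad_fastq_paired(gen$end1, gen$end2, spec)
        in1 <- b$end1
        in2 <- b$end2
      } else {
        in1 <- pad_fastq(gen, spec)
        in2 <- NULL
      }
    } else {
      in1 <- if (paired) gen$end1 else gen
      in2 <- if (paired) gen$end2 else NULL
    }
    job <- run_job(in1, input2 = in2, strategy = strategy, lock = lock,
                   threads = t_i, reads_per_thread = reads_per_thread,
                   workload_cost = workload_cost, batch_size = batch_size,
                   block_spec = spec, stripes = stripes,
                   seed = as.integer(seed) + i)
    # wall clock floored by the slowest thread: proc.time() resolution is
    # coarser than the per-thread microsecond timers at trivial scale
    wall_s <- max(job$wall_s, job$max_thread_us / 1e6)
    data.frame(
      threads = t_i,
      reads = job$total_records,
      max_thread_s = job$max_thread_us / 1e6,
      wall_s = wall_s,
      throughput_rps = job$throughput_rps,
      cs_entries = job$cs$entries,
      aborted = wall_s > time_limit,
      mp_throughput_rps = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  tbl <- do.call(rbind, rows)
  class(tbl) <- c("scaling_table", class(tbl))
  tbl
}

#' Peak throughput of a weak-scaling table
#'
#' @param table A `scaling_table` from [weak_scaling()], or any data frame
#'   with `threads`, `throughput_rps` and `aborted` columns.
#' @return List with `threads` and `throughput_rps` of the non-aborted row
#'   maximizing throughput; ties resolve to the lowest thread count.
#' @export
peak_throughput <- function(table) {
  ok <- table[!table$aborted, , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop("no data: every row of the scaling table was aborted")
  }
  ok <- ok[order(-ok$throughput_rps, ok$threads), , drop = FALSE]
  list(threads = ok$threads[1L], throughput_rps = ok$throughput_rps[1L])
}

#' Serialize a scaling table to tab-delimited text
#'
#' @param table A `scaling_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_scaling_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
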