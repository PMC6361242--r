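test_that("a single-threaded job emits input names in order", {
  recs <- generate_fastq(120, read_length = 25L, seed = 6)
  job <- run_job(recs, strategy = "O", threads = 1,
                 output_prefix = tempfile())
  body <- readLines(job$output_files[1])[-1L]
  expect_identical(vapply(strsplit(body, "\t"), `[[`, "", 1L),
                   vapply(recs, `[[`, "", "name"))
})

test_that("job results obey the throughput identity and entry law", {
  recs <- generate_fastq(3200, read_length = 40L, seed = 44)
  job <- run_job(recs, strategy = "B", threads = 4, workload_cost = 2)
  expect_identical(job$cs$entries, 100)          # ceiling(3200 / 32)
  expect_identical(job$max_thread_us, max(job$per_thread_us))
  expect_equal(job$throughput_rps,
               job$total_records / (job$max_thread_us / 1e6))
  expect_identical(job$total_records, 3200L)
})

test_that("reads_per_thread caps consumption and T=4 matches T=1 output", {
  recs <- generate_fastq(1000, read_length = 30L, seed = 50)
  p4 <- tempfile(); p1 <- tempfile()
  j4 <- run_job(recs, strategy = "B", threads = 4, reads_per_thread = 200,
                output_prefix = p4, seed = 9)
  j1 <- run_job(recs, strategy = "B", threads = 1, reads_per_thread = 800,
                output_prefix = p1, seed = 9)
  expect_identical(j4$total_records, 800L)
  expect_identical(j1$total_records, 800L)
  strip_tag <- function(x) sub("\tXW:i:[0-9]+$", "", x)
  l4 <- strip_tag(readLines(paste0(p4, ".sam"))[-1L])
  l1 <- strip_tag(readLines(paste0(p1, ".sam"))[-1L])
  expect_identical(sort(l4), sort(l1))
})

test_that("weak scaling holds per-thread reads constant and marks aborts", {
  tbl <- weak_scaling(threads = c(1L, 2L, 4L), reads_per_thread = 250L,
                      strategy = "B", workload_cost = 1L,
                      read_length = 40L, seed = 3)
  expect_identical(tbl$reads, c(250L, 500L, 1000L))
  expect_false(any(tbl$aborted))
  expect_true(all(is.na(tbl$mp_throughput_rps)))

  # L-parsing route pads on the fly
  tbl_l <- weak_scaling(threads = c(1L, 2L), reads_per_thread = 100L,
                        strategy = "L", read_length = 60L,
                        block_bytes = 4096L, seed = 4)
  expect_identical(tbl_l$reads, c(100L, 200L))

  # time limit 0: every row aborted
  tbl0 <- weak_scaling(threads = c(1L, 2L), reads_per_thread = 50L,
                       time_limit = 0, seed = 5)
  expect_true(all(tbl0$aborted))
  expect_error(peak_throughput(tbl0), "no data")
})

test_that("peak throughput picks the argmax with low-thread tie break", {
  tbl <- data.frame(threads = c(8L, 16L, 32L),
                    throughput_rps = c(100e3, 150e3, 140e3),
                    aborted = FALSE)
  expect_identical(peak_throughput(tbl),
                   list(threads = 16L, throughput_rps = 150e3))
  tie <- data.frame(threads = c(16L, 32L),
                    throughput_rps = c(150e3, 150e3), aborted = FALSE)
  expect_identical(peak_throughput(tie)$threads, 16L)
  one <- data.frame(threads = 2L, throughput_rps = 5, aborted = FALSE)
  expect_identical(peak_throughput(one)$threads, 2L)
})

test_that("scaling tables serialize to delimited text", {
  tbl <- weak_scaling(threads = 1L, reads_per_thread = 50L, seed = 8)
  p <- tempfile(fileext = ".tsv")
  write_scaling_table(tbl, p)
  back <- utils::read.delim(p)
  expect_identical(nrow(back), 1L)
  expect_identical(back$reads, 50L)
})

test_that("conservation holds across the strategy/lock/thread grid", {
  recs <- generate_fastq(400, read_length = 50L, seed = 60)
  want <- sort(vapply(recs, `[[`, "", "name"))
  spec <- block_spec(2048, max_reads_per_block(recs, 2048))
  blocked <- pad_fastq(recs, spec)
  for (strategy in c("O", "B", "L")) {
    for (lock in c("pessimistic", "queueing")) {
      for (threads in c(1L, 4L)) {
        prefix <- tempfile()
        run_job(if (strategy == "L") blocked else recs,
                strategy = strategy, lock = lock, threads = threads,
                block_spec = if (strategy == "L") spec,
                output_prefix = prefix)
        body <- readLines(paste0(prefix, ".sam"))[-1L]
        got <- sort(vapply(strsplit(body, "\t"), `[[`, "", 1L))
        expect_identical(got, want,
                         label = paste(strategy, lock, threads))
      }
    }
  }
})
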