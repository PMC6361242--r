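# Independent single-threaded FASTQ oracle: readLines + direct string ops,
# sharing no code with the package's raw-vector scanner or the C++ engine.
oracle_read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stopifnot(length(lines) %% 4 == 0)
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- sub("^@", "", lines[idx])
  data.frame(
    name = sub("[ \t].*$", "", hdr),
    sequence = lines[idx + 1L],
    quality = sub(" +$", "", lines[idx + 3L]),
    stringsAsFactors = FALSE
  )
}

# Oracle block scan: read names per B-byte block by direct substring work.
oracle_block_names <- function(bytes, B) {
  stopifnot(length(bytes) %% B == 0)
  lapply(seq_len(length(bytes) %/% B), function(k) {
    blk <- rawToChar(bytes[((k - 1L) * B + 1L):(k * B)])
    lines <- strsplit(blk, "\n", fixed = TRUE)[[1L]]
    hdr <- lines[seq(1L, length(lines), by = 4L)]
    sub("[ \t].*$", "", sub("^@", "", hdr))
  })
}

sorted_triples <- function(df) {
  key <- paste(df$name, df$sequence, df$quality, sep = "\r")
  sort(key)
}

write_tmp_fastq <- function(records) {
  p <- tempfile(fileext = ".fastq")
  write_fastq(records, p)
  p
}

make_uniform_records <- function(n, len = 10L, prefix = "r") {
  lapply(seq_len(n), function(i) {
    fastq_record(paste0(prefix, i),
                 strrep(c("A", "C", "G", "T")[(i %% 4) + 1L], len),
                 strrep("I", len))
  })
}
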