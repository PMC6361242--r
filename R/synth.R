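with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_sequences <- function(n, lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
}

#' Generate deterministic synthetic FASTQ
#'
#' Emulates the structure of short-read Illumina sets (default 100 nt,
#' paired available) for testing parsing and blocking without downloads.
#' Sequences are uniform over A/C/G/T; content realism is irrelevant to the
#' byte-level machinery exercised here. The same spec and seed always yield
#' byte-identical output.
#'
#' @param n Number of fragments (record count per file).
#' @param read_length Fixed length, or a length-2 range sampled uniformly
#'   per read.
#' @param seed Integer seed; all randomness is local to this call.
#' @param paired Generate two mated files with `/1`, `/2` name suffixes.
#' @param prefix Read-name prefix; names are `<prefix><ordinal>`.
#' @param comment Optional header comment appended to every record.
#' @param quality `"fixed"` (all `quality_char`) or `"random"` (seeded
#'   draw over Phred+33 characters `!`..`I`, which excludes space).
#' @param quality_char Character used when `quality = "fixed"`.
#' @param out Optional output path (single) or two paths (paired).
#' @return A list of [fastq_record()]s, or for `paired` a list with
#'   elements `end1` and `end2`.
#' @examples
#' p <- generate_fastq(3, read_length = 10, seed = 7, paired = TRUE)
#' vapply(p$end1, `[[`, "", "name")
#' @export
generate_fastq <- function(n, read_length = 100L, seed = 1L,
                           paired = FALSE, prefix = "read", comment = NULL,
                           quality = c("fixed", "random"),
                           quality_char = "I", out = NULL) {
  quality <- match.arg(quality)
  n <- as.integer(n)
  stopifnot(n >= 0L)
  qual_alphabet <- strsplit(rawToChar(as.raw(33:73)), "")[[1L]]
  make_end <- function(names) {
    lens <- if (length(read_length) == 2L) {
      sample(read_length[1L]:read_length[2L], n, replace = TRUE)
    } else {
      rep_len(as.integer(read_length), n)
    }
    seqs <- random_sequences(n, lens)
    quals <- if (quality == "fixed") {
      strrep(quality_char, lens)
    } else {
      vapply(lens, function(L) {
        paste(sample(qual_alphabet, L, replace = TRUE), collapse = "")
      }, "")
    }
    lapply(seq_len(n), function(i) {
      fastq_record(names[i], seqs[i], quals[i],
                   comment = if (is.null(comment)) NA_character_ else
                     comment)
    })
  }
  with_local_seed(seed, {
    base <- paste0(prefix, seq_len(n))
    if (paired) {
      res <- list(end1 = make_end(paste0(base, "/1")),
                  end2 = make_end(paste0(base, "/2")))
      if (!is.null(out)) {
        stopifnot(length(out) == 2L)
        write_fastq(res$end1, out[1L])
        write_fastq(res$end2, out[2L])
      }
      res
    } else {
      res <- make_end(base)
      if (!is.null(out)) write_fastq(res, out[1L])
      res
    }
  })
}

#' Truncate reads at the 3' end
#'
#' Cuts every sequence and quality string down to `new_length`, removing the
#' suffix (the 3' end for forward-orientation records); read names are
#' unchanged. Mirrors the common practice of deriving a short-read set from
#' a longer one.
#'
#' @param x List of [fastq_record()]s, or a FASTQ path/raw vector.
#' @param new_length Target length; every read must be at least this long.
#' @return A list of truncated [fastq_record()]s.
#' @export
truncate_reads <- function(x, new_length) {
  records <- if (is.list(x)) x else read_fastq(x)
  new_length <- as.integer(new_length)
  lapply(records, function(r) {
    if (nchar(r$sequence) < new_length) {
      stop("read '", r$name, "' is ", nchar(r$sequence),
           " nt, shorter than new_length ", new_length)
    }
    fastq_record(r$name,
                 substr(r$sequence, 1L, new_length),
                 substr(r$quality, 1L, new_length),
                 comment = r$comment, plus_text = r$plus_text)
  })
}
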