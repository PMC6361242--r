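Package: blockfq
Title: Blocked FASTQ and Lock-Disciplined Multithreaded Read Ingestion
Version: 0.1.0
Authors@R:
    person("Avery", "Quinn", email = "avery.quinn@example.org",
           role = c("aut", "cre"))
Description: Tools for studying and removing the input/output bottlenecks of
    multithreaded, embarrassingly parallel sequence analysis. Implements the
    padded "blocked FASTQ" dialect, in which space padding forces every
    B-byte block of the file to begin a record and contain a fixed number of
    reads, together with converters, validators and paired-end guarantees.
    Provides four synchronized input strategies (original, deferred, batch
    deferred and block deferred parsing) running on real operating-system
    threads under three mutual-exclusion disciplines (standard, spin and
    FIFO queueing locks), instrumented with critical-section entry counts
    and microsecond timings. Includes striped SAM-dialect output with stripe
    merging, a deterministic synthetic FASTQ generator, and a weak-scaling
    benchmark harness with a tunable stand-in per-read workload.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    optparse,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
SystemRequirements: C++17, POSIX threads
Config/testthat/edition: 3
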