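---
title: "Blocked FASTQ and synchronized multithreaded ingestion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blocked FASTQ and synchronized multithreaded ingestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockfq)
```

## The problem

Read-level sequence analysis is embarrassingly parallel: each worker
thread repeatedly (a) takes the next read from the shared input, (b)
computes on it, and (c) writes a result. Steps (a) and (c) touch shared
file streams and must be serialized inside critical sections (CS) guarded
by locks. As thread counts grow, the input CS becomes the bottleneck, for
two separable reasons: the *time spent inside* the CS, and the *number of
times* it is entered (each entry pays lock/unlock overhead and, on
many-core NUMA machines, cache-coherence traffic).

FASTQ makes this worse than it needs to be. Records are
variable-length, so even discovering where the next record ends — four
newlines ahead — is work that must happen under the lock. `blockfq`
implements and instruments the two complementary remedies: restructure
the CS to do less (deferred and batched parsing), and restructure the
*file* so the CS can be a single fixed-size read (blocked FASTQ).

## The blocked FASTQ dialect

Given a block size $B$ (bytes) and a reads-per-block count $N$, a blocked
file satisfies two invariants: no record spans a $B$-byte boundary, and
every $B$-byte block holds exactly $N$ records — except possibly the last
block, which may hold $1..N$. Both are achieved by appending run(s) of
space characters to every $N$-th read until the next read begins at a
multiple of $B$. A consumer can then read exactly $B$ bytes per CS entry
and parse outside the lock.

Concrete choices this package makes, where the format description leaves
room:

* **Padding lives on the quality line**, inserted immediately before its
  terminating newline. A padded record therefore still has exactly four
  newlines, so newline-counting boundary scans (the D and B strategies)
  work unchanged on blocked files, and parsers that trim trailing
  whitespace ignore the pad. Padding is *forbidden* elsewhere
  (header/sequence/plus lines); `validate_blocked()` flags it. Confining
  the pad to one line keeps the validator simple and the dialect
  unambiguous.
* **The final block is padded to a full $B$ bytes** even though it may
  hold fewer than $N$ records. The reader can then always request exactly
  $B$ bytes and detect the end of input by exhaustion rather than a short
  read. Blocks always end with a newline; bytes after a block's final
  newline are a validation error.
* **Feasibility is checked per concrete block**, not via a worst-case
  bound: a conversion fails (naming the 0-based offending block) only if
  an actual group of $N$ consecutive records exceeds $B$ bytes.
  `max_reads_per_block()` returns the largest $N$ a sample can justify,
  defined over all windows of $N$ consecutive records and capped at the
  sample size.
* **Canonical serialization** writes a bare `+` on line 3 and a single
  space between name and comment. `unpad_fastq(pad_fastq(F))` is
  byte-identical to the canonical serialization of `F`; the `(name,
  sequence, quality)` multiset is always conserved exactly.
* Line endings are LF only; a CR anywhere is a malformed record, because
  the block arithmetic requires newlines to be one byte.

For paired-end data the same $(B, N)$ spec applied to both files places
fragment $i$ in block $\lfloor i/N \rfloor$ of each, so corresponding
blocks contain corresponding mates — the property that makes synchronized
paired reading trivial under block parsing: one CS entry takes the block
at the same offset from both files. Because the two ends may differ in
length, the two files generally carry different amounts of padding.

Padding costs file size. On synthetic 100-nt reads at $(B, N) = (12288,
44)$ the raw inflation is on the order of 10% but the gzip inflation is
far smaller, since pad runs compress to almost nothing; the CLI `pad`
subcommand reports both numbers for the files at hand. Inflation is
reported, never asserted: it depends on read length and name length.

## The four parsing strategies

All four run the same worker loop — lock, take input, unlock, compute,
write — and differ only in the work done under the input lock:

| strategy | inside the CS | per CS entry |
|---|---|---|
| O | read one record **and parse it** | 1 record |
| D | one 4-newline boundary scan | 1 record |
| B | `batch_size` boundary scans (default 32) | up to `batch_size` |
| L | one `read(B)` | one block ($N$ records) |

Parsing for D/B/L happens outside the CS, which also means malformed
records are detected and attributed by the *consuming* thread, outside
the lock — the CS cannot validate without giving up its minimality. A CS
entry is counted only when it yields input; end-of-stream probes are not
entries, so the entry laws hold exactly: `entries(O) = entries(D) =
records`, `entries(B) = ceil(records/batch_size)`, `entries(L) =
blocks`. B-parsing's final batch may be short; L-parsing tolerates one
short block (relevant only for externally produced files, since this
package pads the final block to full size). Output is written in batches
matching the input batch, so B and L reduce output-lock entries by the
same factor.

Batch assignment is demand-driven: whichever thread acquires the input
lock next takes the next batch. Nothing is statically partitioned, which
is what gives multithreading its built-in load balancing.

## Lock disciplines

Three mutual-exclusion disciplines are selectable at run time (a runtime
knob rather than a compile-time switch, so one artifact can run the whole
test matrix):

* **pessimistic** (standard): a failed attempt sleeps in the kernel
  immediately (futex on Linux) and is woken on release. Cannot starve the
  holder; pays wake-up latency.
* **spin**: busy-waits on an atomic flag for `spin_budget_us`
  microseconds, then sleeps. Optimistic — cheapest when the lock is
  almost always free; the budget bounds how much CPU a waiter can burn
  stealing cycles from the holder. The budget default (50 µs) is a
  package choice — the prescribed interval is inherently
  implementation-specific — and is exposed as a knob.
* **queueing** (MCS-style FIFO): waiters join an in-memory queue and the
  lock is handed to the queue head on release, each waiter signaled
  individually. The package implements the *contract* — FIFO grant order,
  per-waiter hand-off — with a mutex/condition-variable queue rather than
  promising the cache-line behavior of a literal MCS lock; the
  cache-coherence rationale (each waiter spinning on its own cache line,
  only two threads involved in a hand-off) is documentation of why the
  discipline matters at scale, not a testable property at this level.

The contract tests are behavioral: all disciplines conserve every update
of a contended shared counter; the FIFO discipline shows zero inversions
between timestamped arrival and grant logs over randomized contention
trials; a spin waiter's thread-CPU time stays far below its wall wait
when the holder sleeps. The *unsynchronized* baseline counter
demonstrates lost updates; because this environment may schedule all
threads on a single CPU (where a tight unsynchronized loop rarely gets
preempted mid-increment), the racy loop yields between its load and its
store every 16th iteration to make the lost-update interleaving reliably
observable. This changes when updates are lost, not whether the code is
racy.

## The benchmark harness

`run_job()` implements the thread model end to end. Reads are consumed
under a strategy and lock; each read passes through a stand-in workload —
`workload_cost` passes of a 64-bit integer mixer over the read bytes,
seeded per job, its result folded into the output line as an `XW:i:` tag
so the compiler cannot elide it; results are written as minimal unaligned
SAM-dialect lines (QNAME, FLAG 4, `*` placeholders, SEQ, QUAL) so
standard tooling can parse the output. No alignment is computed: the
harness asserts the *mechanism* (every consumed read appears exactly
once, entry counts, FIFO order, stripe routing), for which a tunable CPU
cost per read is all that matters.

Timing follows the weak-scaling design: reads per thread are held
constant as the thread count grows, one-time setup (file loading, sink
creation, thread spawn) is excluded, each worker reports its own wall
time in microseconds, and throughput is total reads divided by the
*maximum* per-thread time. The job-level wall clock is also reported —
the two can differ (the per-thread maximum excludes setup and join), and
the per-thread maximum is the one used for throughput. Jobs exceeding a
time limit (default 20 minutes) are marked aborted and excluded from
`peak_throughput()`, which returns the argmax row with ties broken toward
the lower thread count. The scaling table carries an `mp_throughput_rps`
column, deliberately left `NA`, for recording externally measured
multiprocessing baselines: multiprocessing is an orchestration pattern
around the artifact, not inside it.

Output striping maps thread $t$ to stripe file `prefix.<t mod S>.sam`
(0-based, default $S = 16$), each stripe under its own lock; all $S$
files are created at job start so the stripe set is complete even when $T
< S$. `merge_stripes()` concatenates bodies in stripe order after
checking the per-file headers are identical copies, writing the header
once; every non-header line of every stripe is preserved.

## Synthetic data: what it emulates, what it does not

`generate_fastq()` emulates the *shape* of Illumina short-read sets:
fixed (default 100 nt) or ranged read lengths, paired files with `/1`,
`/2` name suffixes at matching ordinals, and 3'-truncation
(`truncate_reads()`) to derive a shorter set (e.g. 50 nt) from a longer
one. Sequences are uniform over A/C/G/T and qualities are either a fixed
character or a uniform seeded draw; there is no error model, no quality
profile, no duplication structure — the parsing and blocking machinery is
content-agnostic, so realism there would test nothing additional. Names
default to `read<ordinal>`, short enough that 12 KB blocks comfortably
hold 44+ reads of 100 nt. Generation is deterministic per seed (the RNG
state is saved and restored around each call), so all fixtures are built
in code.

A green test here establishes that the formats, strategies, locks and
striping behave as specified on a desk-scale machine. It does *not*
establish hardware scaling curves: absolute throughputs, contention
behavior at hundreds of threads, and NUMA effects are machine properties,
and the reference experiments for those require many-core servers. That
is why the acceptance suite pins structural quantities (sizes, entry
counts, conservation, ordering) and leaves throughput tables out of
scope.

## Numerical and degenerate-input choices

* Block indices, thread ids and stripe indices are 0-based everywhere
  (stripe `prefix.0.sam`, "block 0" in errors), matching byte-offset
  arithmetic.
* An empty input pads to an empty blocked file, unpads back to empty, and
  yields empty (but existing, headered) output files.
* `peak_throughput()` on an all-aborted table is a no-data error, not an
  empty result.
* Per-thread timers have a 1 µs floor so throughput is always finite at
  trivial scale.
* Comments are split at the first space or tab and re-serialized with a
  single space; a tab-separated comment therefore does not round-trip
  byte-identically (the records compare equal). Documented, considered
  acceptable for a padding dialect.
* The engine loads inputs fully into memory before the timed region;
  at the package's scale (≤ tens of MB) this is the same simplification
  as excluding index loading from timing. Streaming from disk inside the
  CS would change constants, not the contracts under test.

## Known limitations

Compressed (gzip/BGZF) inputs and outputs are out of scope, as are
multi-line FASTA/FASTQ, SAM header reconciliation beyond the
identical-copy check, CPU pinning and NUMA placement, and the
separate-input/output-thread queueing model — the last is a documented
alternative architecture that removes the input lock entirely at the cost
of a hand-off queue, and interacts differently with compression; it is
not implemented here.
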