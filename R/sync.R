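lock_kinds <- c("pessimistic", "spin", "queueing")

normalize_lock_kind <- function(kind) {
  kind <- match.arg(kind, c(lock_kinds, "standard", "none"))
  if (kind == "standard") "pessimistic" else kind
}

#' Create a mutual-exclusion lock
#'
#' Three disciplines are available, selected at run time:
#' \describe{
#'   \item{`pessimistic`}{standard lock: a failed attempt sleeps in the
#'     kernel immediately and is revived on release (futex on Linux).}
#'   \item{`spin`}{optimistic lock: busy-waits up to `spin_budget_us`
#'     microseconds, then sleeps, bounding the CPU a waiter can burn while
#'     the holder is slow (starvation control).}
#'   \item{`queueing`}{FIFO MCS-style lock: waiters join an in-memory
#'     queue, the lock is granted in arrival order, and each hand-off
#'     signals a single waiter.}
#' }
#'
#' @param kind One of `"pessimistic"` (alias `"standard"`), `"spin"`,
#'   `"queueing"`.
#' @param spin_budget_us Spin budget in microseconds (spin discipline
#'   only; must be positive).
#' @return An object of class `bq_lock`.
#' @examples
#' lk <- bq_lock("queueing")
#' lock_acquire(lk)
#' lock_release(lk)
#' lock_stats(lk)$acquisitions
#' @export
bq_lock <- function(kind = "pessimistic", spin_budget_us = 50) {
  kind <- normalize_lock_kind(kind)
  if (kind == "none") stop("'none' is not a lock discipline")
  if (kind == "spin" && spin_budget_us <= 0) {
    stop("spin_budget_us must be positive for the spin discipline")
  }
  structure(list(ptr = cpp_lock_new(kind, spin_budget_us), kind = kind,
                 spin_budget_us = spin_budget_us),
            class = "bq_lock")
}

#' @rdname bq_lock
#' @param lock A [bq_lock()].
#' @export
lock_acquire <- function(lock) {
  stopifnot(inherits(lock, "bq_lock"))
  cpp_lock_acquire(lock$ptr)
  invisible(lock)
}

#' @rdname bq_lock
#' @export
lock_release <- function(lock) {
  stopifnot(inherits(lock, "bq_lock"))
  if (!cpp_lock_release(lock$ptr)) {
    stop("contract violation: release of a lock the caller does not hold")
  }
  invisible(lock)
}

#' @rdname bq_lock
#' @return `lock_stats()`: list with `acquisitions`, `contended` and
#'   `wait_us` (cumulative microseconds blocked).
#' @export
lock_stats <- function(lock) {
  stopifnot(inherits(lock, "bq_lock"))
  cpp_lock_stats(lock$ptr)
}

#' Shared-counter demonstration of mutual exclusion
#'
#' `threads` workers each perform `increments` protected increments of one
#' shared counter. Under any lock discipline the final count equals
#' `threads * increments`; with `kind = "none"` the increments are
#' intentionally unprotected read-modify-write races and updates are lost
#' under contention.
#'
#' @param threads Number of OS worker threads.
#' @param increments Increments per worker.
#' @param kind Lock discipline, or `"none"` for the racy baseline.
#' @param spin_budget_us Spin budget for the spin discipline.
#' @return List with `counter`, `expected`, and lock statistics.
#' @export
counter_demo <- function(threads, increments, kind = "pessimistic",
                         spin_budget_us = 50) {
  kind <- normalize_lock_kind(kind)
  cpp_counter_demo(as.integer(threads), as.integer(increments), kind,
                   spin_budget_us)
}

#' FIFO grant order under contention
#'
#' Runs `trials` independent contention trials on the queueing lock: a
#' blocker thread holds the lock for `hold_us` microseconds while `waiters`
#' labeled threads arrive after random per-thread delays; the queue then
#' drains. For each trial the arrival order (the order waiters joined the
#' queue) and grant order (the order they obtained the lock) are returned;
#' the queueing contract requires them to be identical.
#'
#' @param waiters Number of waiting threads per trial.
#' @param trials Number of trials.
#' @param hold_us Microseconds the blocker holds the lock.
#' @param seed Seed for the arrival-delay randomization.
#' @return List of trials, each `list(arrival =, grant =)` of 0-based
#'   waiter labels.
#' @export
grant_order_trials <- function(waiters = 16L, trials = 1L, hold_us = 500,
                               seed = 1L) {
  lapply(seq_len(trials), function(i) {
    cpp_grant_trial(as.integer(waiters), hold_us,
                    as.integer(seed) + i - 1L)
  })
}

#' CPU burned by a spin-lock waiter while the holder sleeps
#'
#' The holder takes a spin lock and sleeps for `hold_ms` milliseconds; a
#' waiter attempts the lock at once. A correct bounded-spin implementation
#' hands the waiter to the scheduler after `spin_budget_us`, so the
#' waiter's thread CPU time stays far below its wall wait.
#'
#' @param spin_budget_us Spin budget in microseconds.
#' @param hold_ms How long the holder sleeps, in milliseconds.
#' @return List with `waiter_cpu_us` and `waiter_wall_us`.
#' @export
spin_wait_probe <- function(spin_budget_us = 50, hold_ms = 50) {
  cpp_spin_probe(spin_budget_us, hold_ms)
}
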