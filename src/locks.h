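#ifndef BLOCKFQ_LOCKS_H
#define BLOCKFQ_LOCKS_H

#include <atomic>
#include <chrono>
#include <condition_variable>
#include <deque>
#include <memory>
#include <mutex>
#include <string>
#include <thread>
#include <vector>

namespace blockfq {

using steady = std::chrono::steady_clock;

inline long long elapsed_ns(steady::time_point t0) {
    return std::chrono::duration_cast<std::chrono::nanoseconds>(
        steady::now() - t0).count();
}

// Mutual-exclusion discipline. try_acquire() is the uncontended fast path;
// acquire_slow() is entered only after a failed try and must block until
// the lock is owned.
class Lock {
public:
    virtual ~Lock() = default;
    virtual bool try_acquire() = 0;
    virtual void acquire_slow() = 0;
    virtual void release() = 0;
};

// Pessimistic (standard) lock: a failed attempt sleeps immediately in the
// kernel (futex on Linux) until woken.
class StandardLock : public Lock {
    std::mutex m_;
public:
    bool try_acquire() override { return m_.try_lock(); }
    void acquire_slow() override { m_.lock(); }
    void release() override { m_.unlock(); }
};

// Optimistic lock: busy-wait on an atomic flag for spin_budget_us, then
// fall back to sleeping on a condition variable so a slow holder cannot be
// starved by its waiters.
class SpinLock : public Lock {
    std::atomic<bool> held_{false};
    std::mutex m_;
    std::condition_variable cv_;
    long long budget_us_;
public:
    explicit SpinLock(double budget_us)
        : budget_us_(static_cast<long long>(budget_us)) {}
    bool try_acquire() override {
        bool e = false;
        return held_.compare_exchange_strong(e, true,
                                             std::memory_order_acquire);
    }
    void acquire_slow() override {
        steady::time_point t0 = steady::now();
        for (;;) {
            bool e = false;
            if (held_.compare_exchange_weak(e, true,
                                            std::memory_order_acquire))
                return;
            if (elapsed_ns(t0) / 1000 > budget_us_) break;
        }
        // sleep phase: wait on the cv, re-probing on wake / timeout
        std::unique_lock<std::mutex> lk(m_);
        for (;;) {
            bool e = false;
            if (held_.compare_exchange_strong(e, true,
                                              std::memory_order_acquire))
                return;
            cv_.wait_for(lk, std::chrono::microseconds(200));
        }
    }
    void release() override {
        held_.store(false, std::memory_order_release);
        cv_.notify_one();
    }
};

// FIFO queueing (MCS-style) lock: waiters form an in-memory queue; the lock
// is handed to the head of the queue on release and each waiter is signaled
// individually, so only the two threads in the hand-off communicate.
class QueueLock : public Lock {
    struct Node {
        std::condition_variable cv;
        bool granted = false;
        int label = -1;
    };
    std::mutex m_;
    std::deque<Node*> q_;
    bool held_ = false;
public:
    bool log_enabled = false;
    std::vector<int> arrivals;   // order waiters joined the queue
    std::vector<int> grants;     // order waiters obtained the lock

    bool try_acquire() override {
        std::lock_guard<std::mutex> lk(m_);
        if (!held_ && q_.empty()) { held_ = true; return true; }
        return false;
    }
    void acquire_slow() override { acquire_labeled(-1); }
    void acquire_labeled(int label) {
        std::unique_lock<std::mutex> lk(m_);
        if (!held_ && q_.empty()) {
            held_ = true;
            if (log_enabled && label >= 0) {
                arrivals.push_back(label);
                grants.push_back(label);
            }
            return;
        }
        Node n;
        n.label = label;
        q_.push_back(&n);
        if (log_enabled && label >= 0) arrivals.push_back(label);
        n.cv.wait(lk, [&n] { return n.granted; });
        if (log_enabled && label >= 0) grants.push_back(label);
    }
    void release() override {
        std::unique_lock<std::mutex> lk(m_);
        if (q_.empty()) { held_ = false; return; }
        Node* n = q_.front();
        q_.pop_front();
        // ownership transfers directly; held_ stays true
        n->granted = true;
        n->cv.notify_one();   // notified under m_: the node outlives this call
    }
};

// Discipline wrapper adding acquisition statistics and holder tracking for
// the release-without-hold contract check.
class InstrumentedLock {
    std::unique_ptr<Lock> impl_;
public:
    std::atomic<long long> acquisitions{0};
    std::atomic<long long> contended{0};
    std::atomic<long long> wait_ns{0};
    std::atomic<bool> held{false};
    std::thread::id owner;

    explicit InstrumentedLock(const std::string& kind,
                              double spin_budget_us = 50.0) {
        if (kind == "pessimistic" || kind == "standard")
            impl_.reset(new StandardLock());
        else if (kind == "spin")
            impl_.reset(new SpinLock(spin_budget_us));
        else if (kind == "queueing")
            impl_.reset(new QueueLock());
        else
            throw std::runtime_error("unknown lock discipline: " + kind);
    }
    QueueLock* as_queue() { return dynamic_cast<QueueLock*>(impl_.get()); }

    void acquire() {
        acquisitions.fetch_add(1, std::memory_order_relaxed);
        if (!impl_->try_acquire()) {
            contended.fetch_add(1, std::memory_order_relaxed);
            steady::time_point t0 = steady::now();
            impl_->acquire_slow();
            wait_ns.fetch_add(elapsed_ns(t0), std::memory_order_relaxed);
        }
        owner = std::this_thread::get_id();
        held.store(true, std::memory_order_release);
    }
    // false if the caller does not hold the lock (contract violation)
    bool release() {
        if (!held.load(std::memory_order_acquire) ||
            owner != std::this_thread::get_id())
            return false;
        held.store(false, std::memory_order_release);
        impl_->release();
        return true;
    }
};

} // namespace blockfq

#endif
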