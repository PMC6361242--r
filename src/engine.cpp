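// Threaded ingestion engine: four synchronized input strategies (O/D/B/L)
// over one or two FASTQ files, a tunable stand-in per-read workload, and
// single or striped SAM-dialect output. Worker threads never touch the R
// API; all results are collected with std:: containers and converted on the
// main thread after join.

#include <Rcpp.h>

#include <atomic>
#include <cstdint>
#include <cstdio>
#include <fstream>
#include <random>
#include <sstream>
#include <thread>

#include "locks.h"

using namespace blockfq;

namespace {

// ---------------------------------------------------------------- fastq ---

struct Rec {
    std::string name, comment, seq, qual;
    int mate = 0;       // 0 unpaired, 1/2 for paired ends
    int thread = 0;
};

// Scan one raw 4-line record starting at pos: advance pos past the 4th
// newline. Returns false at end of stream (possibly after consuming
// trailing whitespace). Throws std::runtime_error on a truncated record.
bool scan_raw(const std::string& d, size_t& pos, size_t& beg, size_t& end) {
    if (pos >= d.size()) return false;
    size_t p = pos;
    int nl = 0;
    size_t i = p;
    for (; i < d.size() && nl < 4; ++i)
        if (d[i] == '\n') ++nl;
    if (nl < 4) {
        // whitespace-only tail counts as end-of-stream
        for (size_t j = p; j < d.size(); ++j) {
            char c = d[j];
            if (c != ' ' && c != '\n' && c != '\t' && c != '\r')
                throw std::runtime_error(
                    "truncated record: end of input inside a 4-line record");
        }
        pos = d.size();
        return false;
    }
    beg = p;
    end = i;        // one past the 4th newline
    pos = i;
    return true;
}

// Parse a raw record (same rules as the R parser): '@' header, name split
// at first whitespace, '+' line, trailing spaces stripped from quality,
// length equality, no CR, no whitespace in sequence.
Rec parse_rec(const char* b, size_t n) {
    size_t ls[5];     // line start offsets; ls[4] == n
    ls[0] = 0;
    int nl = 0;
    for (size_t i = 0; i < n; ++i) {
        if (b[i] == '\r')
            throw std::runtime_error("malformed record: carriage return");
        if (b[i] == '\n') {
            ++nl;
            if (nl > 4)
                throw std::runtime_error("malformed record: too many lines");
            ls[nl] = i + 1;
        }
    }
    if (nl != 4 || ls[4] != n)
        throw std::runtime_error("malformed record: expected 4 lines");
    std::string l1(b, ls[1] - 1);
    std::string l2(b + ls[1], ls[2] - ls[1] - 1);
    std::string l3(b + ls[2], ls[3] - ls[2] - 1);
    std::string l4(b + ls[3], ls[4] - ls[3] - 1);
    if (l1.empty() || l1[0] != '@')
        throw std::runtime_error("malformed record: header must start '@'");
    if (l3.empty() || l3[0] != '+')
        throw std::runtime_error("malformed record: line 3 must start '+'");
    Rec r;
    size_t sp = l1.find_first_of(" \t");
    if (sp == std::string::npos) {
        r.name = l1.substr(1);
    } else {
        r.name = l1.substr(1, sp - 1);
        r.comment = l1.substr(sp + 1);
    }
    if (r.name.empty())
        throw std::runtime_error("malformed record: empty read name");
    if (l2.find_first_of(" \t") != std::string::npos)
        throw std::runtime_error("malformed record: whitespace in sequence");
    size_t qe = l4.find_last_not_of(' ');
    r.qual = (qe == std::string::npos) ? std::string() : l4.substr(0, qe + 1);
    r.seq = std::move(l2);
    if (r.seq.size() != r.qual.size())
        throw std::runtime_error(
            "malformed record: sequence/quality length mismatch for '" +
            r.name + "'");
    return r;
}

std::string strip_mate(const std::string& name) {
    size_t n = name.size();
    if (n >= 2 && name[n - 2] == '/' && (name[n - 1] == '1' ||
                                         name[n - 1] == '2'))
        return name.substr(0, n - 2);
    return name;
}

std::string slurp(const std::string& path) {
    std::ifstream f(path, std::ios::binary);
    if (!f) throw std::runtime_error("cannot open input file: " + path);
    std::ostringstream ss;
    ss << f.rdbuf();
    return ss.str();
}

// ------------------------------------------------------------- workload ---

inline uint64_t mix64(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
    x ^= x >> 27; x *= 0x94d049bb133111ebULL;
    x ^= x >> 31;
    return x;
}

// Stand-in per-read computation: cost passes of an integer mixer over the
// read bytes; the result is folded into the output line so the work cannot
// be optimized away.
uint64_t workload(const Rec& r, int cost, uint64_t seed) {
    uint64_t h = seed ^ (uint64_t)r.seq.size();
    for (int c = 0; c < cost; ++c)
        for (unsigned char ch : r.seq)
            h = mix64(h ^ ch);
    return h;
}

// ----------------------------------------------------------------- sink ---

struct Sink {
    std::FILE* f = nullptr;
    InstrumentedLock lock;
    explicit Sink(const std::string& lk, double sb) : lock(lk, sb) {}
};

std::string sam_line(const Rec& r, uint64_t h, bool tag) {
    std::string s;
    s.reserve(r.name.size() + r.seq.size() + r.qual.size() + 48);
    s += r.name;
    s += "\t4\t*\t0\t0\t*\t*\t0\t0\t";
    s += r.seq.empty() ? "*" : r.seq;
    s += '\t';
    s += r.qual.empty() ? "*" : r.qual;
    if (tag) {
        s += "\tXW:i:";
        s += std::to_string((long long)(h & 0x7fffffffULL));
    }
    s += '\n';
    return s;
}

// ----------------------------------------------------------- run engine ---

struct SharedInput {
    const std::string* d1 = nullptr;
    const std::string* d2 = nullptr;
    bool paired = false;
    size_t pos1 = 0, pos2 = 0;
    long long remaining = -1;      // records still to hand out (O/D/B)
    std::atomic<long long> consumed{0};   // records kept (L cap)
    bool short_block_seen = false;
    int blocks_taken = 0;
};

struct PerThread {
    std::vector<Rec> recs;
    long long entries = 0;
    long long wait_ns = 0;
    long long hold_ns = 0;
    long long wall_us = 0;
    std::string error;
};

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_run(std::string path1, std::string path2,
                   std::string strategy, int threads,
                   std::string lock_kind, double spin_budget_us,
                   int batch_size, double block_bytes, int reads_per_block,
                   double max_records, int workload_cost, double seed,
                   std::string out_prefix, int stripes, bool sam_header,
                   bool collect) {
    const std::string d1 = slurp(path1);
    const bool paired = !path2.empty();
    const std::string d2 = paired ? slurp(path2) : std::string();
    const char strat = strategy.empty() ? 'B' : strategy[0];
    const long long B = (long long)block_bytes;
    const uint64_t wseed = (uint64_t)seed;

    if (strat == 'L' && B <= 0)
        Rcpp::stop("configuration error: L-parsing requires block-bytes");
    if (threads < 1) Rcpp::stop("threads must be >= 1");

    SharedInput sh;
    sh.d1 = &d1;
    sh.d2 = paired ? &d2 : nullptr;
    sh.paired = paired;
    sh.remaining = max_records < 0 ? -1 : (long long)max_records;

    InstrumentedLock in_lock(lock_kind, spin_budget_us);

    // output sinks (created up front; one-time setup excluded from timing)
    const bool writing = !out_prefix.empty();
    std::vector<std::unique_ptr<Sink>> sinks;
    std::vector<std::string> sink_paths;
    if (writing) {
        int nsink = stripes > 0 ? stripes : 1;
        for (int i = 0; i < nsink; ++i) {
            std::string p = stripes > 0
                ? out_prefix + "." + std::to_string(i) + ".sam"
                : out_prefix + ".sam";
            sinks.emplace_back(new Sink(lock_kind, spin_budget_us));
            sinks.back()->f = std::fopen(p.c_str(), "wb");
            if (!sinks.back()->f)
                Rcpp::stop("I/O error: cannot open output stripe " +
                           std::to_string(i) + " (" + p + ")");
            if (sam_header)
                std::fputs("@HD\tVN:1.6\tSO:unknown\n", sinks.back()->f);
            sink_paths.push_back(p);
        }
    }

    std::vector<PerThread> pt(threads);
    std::atomic<bool> abort_flag{false};
    std::atomic<int> start_gate{0};

    auto worker = [&](int tid) {
        PerThread& me = pt[tid];
        while (start_gate.load(std::memory_order_acquire) == 0) {}
        steady::time_point w0 = steady::now();
        try {
            std::vector<std::pair<std::string, std::string>> raw;  // (end1, end2)
            std::vector<Rec> batch;
            for (;;) {
                if (abort_flag.load(std::memory_order_relaxed)) break;
                raw.clear();
                batch.clear();
                long long block_take = 0;
                bool last_block = false;
                std::string blk1, blk2;

                steady::time_point t0 = steady::now();
                in_lock.acquire();
                steady::time_point t1 = steady::now();
                bool got = false;
                // ---- input critical section --------------------------------
                if (strat == 'L') {
                    if (sh.pos1 < d1.size() &&
                        (sh.remaining < 0 ||
                         sh.consumed.load(std::memory_order_relaxed) <
                             sh.remaining)) {
                        size_t take = (size_t)std::min<long long>(
                            B, (long long)(d1.size() - sh.pos1));
                        blk1.assign(d1, sh.pos1, take);
                        if (paired) {
                            size_t take2 = (size_t)std::min<long long>(
                                B, (long long)(d2.size() - sh.pos2));
                            blk2.assign(d2, sh.pos2, take2);
                            sh.pos2 += take2;
                        }
                        sh.pos1 += take;
                        if ((long long)take < B) {
                            if (sh.short_block_seen) {
                                in_lock.release();
                                throw std::runtime_error(
                                    "boundary violation: more than one short "
                                    "block");
                            }
                            sh.short_block_seen = true;
                        }
                        sh.blocks_taken++;
                        block_take = (long long)take;
                        last_block = sh.pos1 >= d1.size();
                        got = true;
                    }
                } else {
                    int want = (strat == 'B') ? batch_size : 1;
                    for (int k = 0; k < want; ++k) {
                        if (sh.remaining == 0) break;
                        size_t b1, e1;
                        if (!scan_raw(d1, sh.pos1, b1, e1)) break;
                        std::string r1 = d1.substr(b1, e1 - b1);
                        std::string r2;
                        if (paired) {
                            size_t b2, e2;
                            if (!scan_raw(d2, sh.pos2, b2, e2))
                                throw std::runtime_error(
                                    "pairing error: end-2 file exhausted "
                                    "before end-1");
                            r2 = d2.substr(b2, e2 - b2);
                        }
                        if (strat == 'O') {
                            // O-parsing: parse inside the critical section
                            Rec a = parse_rec(r1.data(), r1.size());
                            a.mate = paired ? 1 : 0;
                            a.thread = tid;
                            batch.push_back(std::move(a));
                            if (paired) {
                                Rec b = parse_rec(r2.data(), r2.size());
                                b.mate = 2;
                                b.thread = tid;
                                batch.push_back(std::move(b));
                            }
                        } else {
                            raw.emplace_back(std::move(r1), std::move(r2));
                        }
                        if (sh.remaining > 0) sh.remaining--;
                        got = true;
                    }
                }
                if (got) me.entries++;
                in_lock.release();
                // ---- end critical section ----------------------------------
                steady::time_point t2 = steady::now();
                me.wait_ns += std::chrono::duration_cast<
                    std::chrono::nanoseconds>(t1 - t0).count();
                if (got)
                    me.hold_ns += std::chrono::duration_cast<
                        std::chrono::nanoseconds>(t2 - t1).count();
                if (!got) break;

                // deferred parsing (D/B): outside the critical section
                if (strat == 'D' || strat == 'B') {
                    for (auto& pr : raw) {
                        Rec a = parse_rec(pr.first.data(), pr.first.size());
                        a.mate = paired ? 1 : 0;
                        a.thread = tid;
                        batch.push_back(std::move(a));
                        if (paired) {
                            Rec b = parse_rec(pr.second.data(),
                                              pr.second.size());
                            b.mate = 2;
                            b.thread = tid;
                            batch.push_back(std::move(b));
                        }
                    }
                } else if (strat == 'L') {
                    // split the block(s) into records, outside the CS
                    if (!blk1.empty() && blk1[0] != '@')
                        throw std::runtime_error(
                            "boundary violation: block does not start with "
                            "'@'");
                    if (paired && !blk2.empty() && blk2[0] != '@')
                        throw std::runtime_error(
                            "boundary violation: end-2 block does not start "
                            "with '@'");
                    std::vector<Rec> r1s, r2s;
                    size_t p = 0, b, e;
                    while (scan_raw(blk1, p, b, e)) {
                        Rec a = parse_rec(blk1.data() + b, e - b);
                        a.mate = paired ? 1 : 0;
                        a.thread = tid;
                        r1s.push_back(std::move(a));
                    }
                    if (paired) {
                        p = 0;
                        while (scan_raw(blk2, p, b, e)) {
                            Rec a = parse_rec(blk2.data() + b, e - b);
                            a.mate = 2;
                            a.thread = tid;
                            r2s.push_back(std::move(a));
                        }
                        if (r1s.size() != r2s.size())
                            throw std::runtime_error(
                                "pairing error: blocks at the same offset "
                                "hold different read counts");
                    }
                    // every block must hold exactly N records, except the
                    // final block which may hold 1..N
                    if (reads_per_block > 0 &&
                        (long long)r1s.size() > reads_per_block)
                        throw std::runtime_error(
                            "boundary violation: block holds " +
                            std::to_string(r1s.size()) +
                            " records, more than reads-per-block " +
                            std::to_string(reads_per_block));
                    if (reads_per_block > 0 && block_take == B &&
                        !last_block &&
                        (long long)r1s.size() != reads_per_block)
                        throw std::runtime_error(
                            "boundary violation: full block holds " +
                            std::to_string(r1s.size()) + " records, expected " +
                            std::to_string(reads_per_block));
                    long long cnt = (long long)r1s.size();
                    long long keep = cnt;
                    if (sh.remaining >= 0) {
                        long long prev = sh.consumed.fetch_add(cnt);
                        keep = std::max<long long>(
                            0, std::min<long long>(cnt, sh.remaining - prev));
                    }
                    for (long long i = 0; i < keep; ++i) {
                        batch.push_back(std::move(r1s[(size_t)i]));
                        if (paired)
                            batch.push_back(std::move(r2s[(size_t)i]));
                    }
                }

                // paired mate-name check (outside the CS for all strategies)
                if (paired) {
                    for (size_t i = 0; i + 1 < batch.size(); i += 2) {
                        if (strip_mate(batch[i].name) !=
                            strip_mate(batch[i + 1].name))
                            throw std::runtime_error(
                                "pairing error: mate names differ ('" +
                                batch[i].name + "' vs '" + batch[i + 1].name +
                                "')");
                    }
                }

                // stand-in workload + output
                if (writing) {
                    std::string out;
                    for (const Rec& r : batch) {
                        uint64_t h = workload(r, workload_cost,
                                              wseed + (uint64_t)tid);
                        out += sam_line(r, h, true);
                    }
                    Sink& s = stripes > 0 ? *sinks[tid % stripes] : *sinks[0];
                    s.lock.acquire();
                    std::fwrite(out.data(), 1, out.size(), s.f);
                    s.lock.release();
                } else if (workload_cost > 0) {
                    volatile uint64_t sink_h = 0;
                    for (const Rec& r : batch)
                        sink_h ^= workload(r, workload_cost,
                                           wseed + (uint64_t)tid);
                    (void)sink_h;
                }

                if (collect)
                    for (Rec& r : batch) me.recs.push_back(std::move(r));
            }
        } catch (const std::exception& ex) {
            me.error = std::string(ex.what()) + " [thread " +
                       std::to_string(tid) + "]";
            abort_flag.store(true, std::memory_order_relaxed);
            if (in_lock.held.load() &&
                in_lock.owner == std::this_thread::get_id())
                in_lock.release();
        }
        me.wall_us = std::chrono::duration_cast<std::chrono::microseconds>(
            steady::now() - w0).count();
        if (me.wall_us < 1) me.wall_us = 1;   // timer granularity floor
    };

    std::vector<std::thread> pool;
    pool.reserve(threads);
    for (int t = 0; t < threads; ++t) pool.emplace_back(worker, t);
    start_gate.store(1, std::memory_order_release);
    for (auto& th : pool) th.join();

    for (auto& s : sinks)
        if (s->f) std::fclose(s->f);

    for (const PerThread& p : pt)
        if (!p.error.empty()) Rcpp::stop(p.error);

    long long entries = 0, wait_ns = 0, hold_ns = 0, nrec = 0;
    Rcpp::NumericVector wall_us(threads);
    for (int t = 0; t < threads; ++t) {
        entries += pt[t].entries;
        wait_ns += pt[t].wait_ns;
        hold_ns += pt[t].hold_ns;
        nrec += (long long)pt[t].recs.size();
        wall_us[t] = (double)pt[t].wall_us;
    }

    Rcpp::List recs = R_NilValue;
    if (collect) {
        size_t n = 0;
        for (const auto& p : pt) n += p.recs.size();
        Rcpp::CharacterVector name(n), comment(n), seq(n), qual(n);
        Rcpp::IntegerVector mate(n), thread(n);
        size_t i = 0;
        for (const auto& p : pt)
            for (const Rec& r : p.recs) {
                name[i] = r.name;
                comment[i] = r.comment.empty() ? NA_STRING
                                               : Rcpp::String(r.comment);
                seq[i] = r.seq;
                qual[i] = r.qual;
                mate[i] = r.mate;
                thread[i] = r.thread;
                ++i;
            }
        recs = Rcpp::List::create(
            Rcpp::Named("name") = name, Rcpp::Named("comment") = comment,
            Rcpp::Named("sequence") = seq, Rcpp::Named("quality") = qual,
            Rcpp::Named("mate") = mate, Rcpp::Named("thread") = thread);
    }

    return Rcpp::List::create(
        Rcpp::Named("records") = recs,
        Rcpp::Named("entries") = (double)entries,
        Rcpp::Named("wait_us") = wait_ns / 1e3,
        Rcpp::Named("hold_us") = hold_ns / 1e3,
        Rcpp::Named("blocks") = sh.blocks_taken,
        Rcpp::Named("per_thread_us") = wall_us,
        Rcpp::Named("lock_acquisitions") = (double)in_lock.acquisitions.load(),
        Rcpp::Named("lock_contended") = (double)in_lock.contended.load(),
        Rcpp::Named("lock_wait_us") = in_lock.wait_ns.load() / 1e3,
        Rcpp::Named("output_files") = Rcpp::wrap(sink_paths));
}

// ------------------------------------------------------------ lock demos ---

// [[Rcpp::export]]
Rcpp::List cpp_counter_demo(int threads, int iters, std::string kind,
                            double spin_budget_us) {
    const long long expected = (long long)threads * iters;
    long long counter = 0;
    if (kind == "none") {
        // intentionally racy load/increment/store on a shared counter; the
        // yield between load and store makes the lost-update interleaving
        // observable even when all threads share one CPU
        volatile long long racy = 0;
        std::atomic<int> gate{0};
        std::vector<std::thread> pool;
        for (int t = 0; t < threads; ++t)
            pool.emplace_back([&] {
                while (gate.load() == 0) {}
                for (int i = 0; i < iters; ++i) {
                    long long v = racy;
                    if ((i & 0xf) == 0) std::this_thread::yield();
                    racy = v + 1;
                }
            });
        gate.store(1);
        for (auto& th : pool) th.join();
        counter = racy;
        return Rcpp::List::create(
            Rcpp::Named("counter") = (double)counter,
            Rcpp::Named("expected") = (double)expected,
            Rcpp::Named("acquisitions") = 0.0,
            Rcpp::Named("contended") = 0.0,
            Rcpp::Named("wait_us") = 0.0);
    }
    InstrumentedLock lk(kind, spin_budget_us);
    std::atomic<int> gate{0};
    std::vector<std::thread> pool;
    for (int t = 0; t < threads; ++t)
        pool.emplace_back([&] {
            while (gate.load() == 0) {}
            for (int i = 0; i < iters; ++i) {
                lk.acquire();
                ++counter;
                lk.release();
            }
        });
    gate.store(1);
    for (auto& th : pool) th.join();
    return Rcpp::List::create(
        Rcpp::Named("counter") = (double)counter,
        Rcpp::Named("expected") = (double)expected,
        Rcpp::Named("acquisitions") = (double)lk.acquisitions.load(),
        Rcpp::Named("contended") = (double)lk.contended.load(),
        Rcpp::Named("wait_us") = lk.wait_ns.load() / 1e3);
}

// One contention trial on the FIFO queueing lock: the main thread holds the
// lock while `waiters` labeled threads arrive after per-thread random
// delays; on release the queue drains. Returns arrival and grant orders.
// [[Rcpp::export]]
Rcpp::List cpp_grant_trial(int waiters, double hold_us, int seed) {
    QueueLock ql;
    ql.log_enabled = true;
    ql.acquire_labeled(-1);   // blocker holds; arrivals queue behind it
    std::mt19937 rng((uint32_t)seed);
    std::uniform_int_distribution<int> delay(0, 200);
    std::vector<int> delays(waiters);
    for (int i = 0; i < waiters; ++i) delays[i] = delay(rng);
    std::atomic<int> gate{0};
    std::vector<std::thread> pool;
    for (int i = 0; i < waiters; ++i)
        pool.emplace_back([&, i] {
            while (gate.load() == 0) {}
            std::this_thread::sleep_for(std::chrono::microseconds(delays[i]));
            ql.acquire_labeled(i);
            ql.release();
        });
    gate.store(1);
    std::this_thread::sleep_for(
        std::chrono::microseconds((long long)hold_us));
    ql.release();
    for (auto& th : pool) th.join();
    return Rcpp::List::create(Rcpp::Named("arrival") = Rcpp::wrap(ql.arrivals),
                              Rcpp::Named("grant") = Rcpp::wrap(ql.grants));
}

// CPU time consumed by a thread waiting on a spin lock whose holder sleeps
// for hold_ms: bounded spinning must hand the waiter to the scheduler.
// [[Rcpp::export]]
Rcpp::List cpp_spin_probe(double spin_budget_us, double hold_ms) {
    InstrumentedLock lk("spin", spin_budget_us);
    lk.acquire();
    double cpu_us = -1, wall_us = -1;
    std::thread waiter([&] {
        struct timespec c0, c1;
        clock_gettime(CLOCK_THREAD_CPUTIME_ID, &c0);
        steady::time_point t0 = steady::now();
        lk.acquire();
        clock_gettime(CLOCK_THREAD_CPUTIME_ID, &c1);
        wall_us = elapsed_ns(t0) / 1e3;
        cpu_us = (c1.tv_sec - c0.tv_sec) * 1e6 +
                 (c1.tv_nsec - c0.tv_nsec) / 1e3;
        lk.release();
    });
    std::this_thread::sleep_for(
        std::chrono::microseconds((long long)(hold_ms * 1000)));
    lk.release();
    waiter.join();
    return Rcpp::List::create(Rcpp::Named("waiter_cpu_us") = cpu_us,
                              Rcpp::Named("waiter_wall_us") = wall_us);
}

// ----------------------------------------------------- R-level lock API ---

// [[Rcpp::export]]
SEXP cpp_lock_new(std::string kind, double spin_budget_us) {
    Rcpp::XPtr<InstrumentedLock> p(
        new InstrumentedLock(kind, spin_budget_us), true);
    return p;
}

// [[Rcpp::export]]
void cpp_lock_acquire(SEXP xp) {
    Rcpp::XPtr<InstrumentedLock> p(xp);
    p->acquire();
}

// [[Rcpp::export]]
bool cpp_lock_release(SEXP xp) {
    Rcpp::XPtr<InstrumentedLock> p(xp);
    return p->release();
}

// [[Rcpp::export]]
Rcpp::List cpp_lock_stats(SEXP xp) {
    Rcpp::XPtr<InstrumentedLock> p(xp);
    return Rcpp::List::create(
        Rcpp::Named("acquisitions") = (double)p->acquisitions.load(),
        Rcpp::Named("contended") = (double)p->contended.load(),
        Rcpp::Named("wait_us") = p->wait_ns.load() / 1e3);
}
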