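#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// 2-bit base code; -1 for N / anything else. Case-insensitive.
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    }
    return -1;
}

static inline int comp_code(int c) { return 3 - c; }

// Odd multiplier => invertible mod 2^64, so the reverse-complement hash can
// be rolled with an exact modular inverse.
static const uint64_t HASH_MULT = 0x100000001b3ULL; // FNV-1a prime

static uint64_t mod_inverse_pow2(uint64_t a) {
    // Newton iteration: x_{k+1} = x_k * (2 - a * x_k) doubles correct bits.
    uint64_t x = a; // 3 correct bits to start (a odd)
    for (int i = 0; i < 6; ++i) x *= 2 - a * x;
    return x;
}

// Fold-coverage of error-free fragments tiled every `frag_len / fold` bases,
// each weighted by the reciprocal of its exact-match multiplicity in the
// assembly (both strands). Returns per-base depth, one numeric vector per
// scaffold.
// [[Rcpp::export(name = ".mappability_depth_cpp")]]
List mappability_depth_cpp(CharacterVector seqs, int frag_len, int fold) {
    if (frag_len < 1) stop("frag_len must be >= 1");
    if (fold < 1) stop("fold must be >= 1");
    const int L = frag_len;
    const int step = std::max(1, L / fold);
    const uint64_t M = HASH_MULT;
    uint64_t Mpow = 1; // M^(L-1)
    for (int i = 1; i < L; ++i) Mpow *= M;
    const uint64_t Minv = mod_inverse_pow2(M);

    const int n_scaf = seqs.size();
    std::vector<std::string> chrs(n_scaf);
    for (int s = 0; s < n_scaf; ++s) chrs[s] = as<std::string>(seqs[s]);

    // Pass 1: multiplicity of every forward-strand L-mer (N-free) in the genome.
    std::unordered_map<uint64_t, uint32_t> counts;
    for (int s = 0; s < n_scaf; ++s) {
        const std::string& x = chrs[s];
        const long n = (long)x.size();
        if (n < L) continue;
        uint64_t h = 0;
        int n_bad = 0; // N's in current window
        for (long i = 0; i < n; ++i) {
            int c = base_code(x[i]);
            if (c < 0) ++n_bad;
            h = h * M + (uint64_t)(c + 2); // N maps to 1, bases to 2..5
            if (i >= L) {
                int c_out = base_code(x[i - L]);
                if (c_out < 0) --n_bad;
                h -= (uint64_t)(c_out + 2) * Mpow * M;
            }
            if (i >= L - 1 && n_bad == 0) ++counts[h];
        }
    }

    // Pass 2: tile fragments, accumulate 1/multiplicity over covered bases.
    List out(n_scaf);
    for (int s = 0; s < n_scaf; ++s) {
        const std::string& x = chrs[s];
        const long n = (long)x.size();
        NumericVector depth(n);
        if (n < L) { out[s] = depth; continue; }
        std::vector<double> diff(n + 1, 0.0);
        // forward hash h and reverse-complement hash g, both rolled
        // h_p = sum_i (code_{p+i}+2) M^{L-1-i}; g_p = sum_i (comp(code_{p+i})+2) M^i
        uint64_t h = 0, g = 0;
        int n_bad = 0;
        uint64_t Mi = 1;
        for (int i = 0; i < L; ++i) {
            int c = base_code(x[i]);
            if (c < 0) ++n_bad;
            h = h * M + (uint64_t)(c + 2);
            int cc = (c < 0) ? -1 : comp_code(c);
            g += (uint64_t)(cc + 2) * Mi;
            Mi *= M;
        }
        for (long p = 0; p + L <= n; ++p) {
            if (p > 0) {
                int c_out = base_code(x[p - 1]);
                int c_in = base_code(x[p + L - 1]);
                if (c_out < 0) --n_bad;
                if (c_in < 0) ++n_bad;
                h = (h - (uint64_t)(c_out + 2) * Mpow) * M + (uint64_t)(c_in + 2);
                int cco = (c_out < 0) ? -1 : comp_code(c_out);
                int cci = (c_in < 0) ? -1 : comp_code(c_in);
                g = (g - (uint64_t)(cco + 2)) * Minv + (uint64_t)(cci + 2) * Mpow;
            }
            if (p % step != 0) continue;
            if (n_bad > 0) continue; // fragments containing N are skipped
            uint64_t m = 0;
            std::unordered_map<uint64_t, uint32_t>::const_iterator it = counts.find(h);
            if (it != counts.end()) m += it->second;
            if (g != h) {
                it = counts.find(g);
                if (it != counts.end()) m += it->second;
            }
            if (m == 0) continue; // cannot happen for N-free fragments
            double w = 1.0 / (double)m;
            diff[p] += w;
            diff[p + L] -= w;
        }
        double acc = 0.0;
        for (long i = 0; i < n; ++i) { acc += diff[i]; depth[i] = acc; }
        out[s] = depth;
    }
    return out;
}

// Fraction of each window covered by maximal perfect tandem runs with unit
// size u in 1..max_unit: positions i with seq[i] == seq[i-u] sustained for a
// run of length r >= u cover the repeat region [i0-u, i0+r-1] (>= 2u bases).
// Runs over all u are merged. N never matches.
// [[Rcpp::export(name = ".tandem_repeat_fraction_cpp")]]
NumericVector tandem_repeat_fraction_cpp(CharacterVector seqs, int max_unit) {
    const int n = seqs.size();
    NumericVector out(n);
    for (int w = 0; w < n; ++w) {
        const std::string x = as<std::string>(seqs[w]);
        const long len = (long)x.size();
        if (len == 0) { out[w] = 0.0; continue; }
        std::vector<char> mask(len, 0);
        std::vector<int> code(len);
        for (long i = 0; i < len; ++i) code[i] = base_code(x[i]);
        for (int u = 1; u <= max_unit; ++u) {
            if (2L * u > len) break;
            long run = 0;
            for (long i = u; i <= len; ++i) {
                bool match = (i < len) && code[i] >= 0 && code[i] == code[i - u];
                if (match) { ++run; continue; }
                if (run >= u) {
                    long hi = i - 1;          // last matching position
                    long lo = i - run - u;    // start of the repeat region
                    for (long j = lo; j <= hi; ++j) mask[j] = 1;
                }
                run = 0;
            }
        }
        long covered = 0;
        for (long i = 0; i < len; ++i) covered += mask[i];
        out[w] = (double)covered / (double)len;
    }
    return out;
}

// DUST-style low-complexity masking: scan windows of `scan` bases every
// `step` bases (plus a final right-aligned window); score a scan window by
// 10 * sum_t c_t (c_t - 1) / 2 / (T - 1) over its triplet counts c_t
// (triplets containing N are skipped, T = number of counted triplets);
// windows scoring > threshold are masked whole. Returns the masked fraction
// of each input sequence.
// [[Rcpp::export(name = ".low_complexity_fraction_cpp")]]
NumericVector low_complexity_fraction_cpp(CharacterVector seqs, int scan,
                                          int step, double threshold) {
    const int n = seqs.size();
    NumericVector out(n);
    std::vector<int> trip_counts(64);
    for (int w = 0; w < n; ++w) {
        const std::string x = as<std::string>(seqs[w]);
        const long len = (long)x.size();
        if (len < 3) { out[w] = 0.0; continue; }
        std::vector<int> code(len);
        for (long i = 0; i < len; ++i) code[i] = base_code(x[i]);
        std::vector<char> mask(len, 0);
        std::vector<long> starts;
        for (long s = 0; s + scan <= len; s += step) starts.push_back(s);
        if (starts.empty() || starts.back() + scan < len)
            starts.push_back(std::max(0L, len - scan)); // right-aligned tail
        for (size_t si = 0; si < starts.size(); ++si) {
            long s = starts[si];
            long e = std::min(len, s + (long)scan);
            std::fill(trip_counts.begin(), trip_counts.end(), 0);
            long T = 0;
            for (long i = s; i + 3 <= e; ++i) {
                if (code[i] < 0 || code[i + 1] < 0 || code[i + 2] < 0) continue;
                ++trip_counts[(code[i] << 4) | (code[i + 1] << 2) | code[i + 2]];
                ++T;
            }
            if (T < 2) continue;
            double S = 0.0;
            for (int t = 0; t < 64; ++t) {
                double c = (double)trip_counts[t];
                S += c * (c - 1.0) / 2.0;
            }
            double score = 10.0 * S / (double)(T - 1);
            if (score > threshold)
                for (long i = s; i < e; ++i) mask[i] = 1;
        }
        long covered = 0;
        for (long i = 0; i < len; ++i) covered += mask[i];
        out[w] = (double)covered / (double)len;
    }
    return out;
}
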