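#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Bit-level kernels for hypervector encoding and single-pass training.
// R-level storage is unpacked 0/1 integers; words are packed transiently
// here so Hamming distances run on 64-bit popcounts.

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static std::vector<uint64_t> pack_bits(const int* bits, int D) {
  int W = (D + 63) / 64;
  std::vector<uint64_t> out(W, 0);
  for (int i = 0; i < D; ++i)
    if (bits[i]) out[i >> 6] |= (uint64_t(1) << (i & 63));
  return out;
}

static int hamming_packed(const std::vector<uint64_t>& a,
                          const std::vector<uint64_t>& b) {
  int s = 0;
  for (size_t w = 0; w < a.size(); ++w) s += popcount64(a[w] ^ b[w]);
  return s;
}

// Per-bit counts of ones over all bound pairs HDV_Val[level(n,m)] XOR
// HDV_ChFeat[n,m]; majority vote happens in the caller so ties stay visible.
// levels: N x M, 0-based level indices. Codebooks arrive TRANSPOSED
// (cfm_t: D x (N*M), column (n-1)*M+m; vlm_t: D x L) so each bound pair
// walks two contiguous columns.
// [[Rcpp::export]]
IntegerVector hd_encode_counts_cpp(IntegerMatrix levels, IntegerMatrix cfm_t,
                                   IntegerMatrix vlm_t) {
  int N = levels.nrow(), M = levels.ncol(), D = cfm_t.nrow();
  IntegerVector counts(D);
  int* cp = INTEGER(counts);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      int lev = levels(n, m);
      const int* cc = &cfm_t(0, n * M + m);
      const int* vv = &vlm_t(0, lev);
      for (int dd = 0; dd < D; ++dd)
        cp[dd] += cc[dd] ^ vv[dd];
    }
  }
  return counts;
}

// Encode a batch of windows; ties (count == NM/2) copy the tiebreak bit.
// Returns n x D matrix of 0/1 bits.
// [[Rcpp::export]]
IntegerMatrix hd_encode_dataset_cpp(List levels_list, IntegerMatrix cfm_t,
                                    IntegerMatrix vlm_t,
                                    IntegerVector tiebreak) {
  int n = levels_list.size(), D = cfm_t.nrow();
  IntegerMatrix out(n, D);
  for (int i = 0; i < n; ++i) {
    IntegerMatrix lv = levels_list[i];
    IntegerVector counts = hd_encode_counts_cpp(lv, cfm_t, vlm_t);
    int nm = lv.nrow() * lv.ncol();
    for (int dd = 0; dd < D; ++dd) {
      int c2 = 2 * counts[dd];
      out(i, dd) = (c2 > nm) ? 1 : (c2 == nm ? tiebreak[dd] : 0);
    }
  }
  return out;
}

// Single-pass (multi-)centroid trainer.
// X: n x D window bits; y: 0/1 labels (1 = ictal). When multicentroid is
// false every window is folded into its label's sole accumulator (classic
// 2-class bundling). Otherwise: first window of a label opens its sub-class;
// later windows go to the nearest same-label sub-class if the globally
// nearest prototype has the right label, else open a new sub-class.
// Prototypes are majority-binarised accumulators; ties copy tiebreak bits.
// [[Rcpp::export]]
List hd_train_cpp(IntegerMatrix X, IntegerVector y, IntegerVector tiebreak,
                  bool multicentroid) {
  int n = X.nrow(), D = X.ncol();
  std::vector<uint64_t> tb = pack_bits(INTEGER(tiebreak), D);

  std::vector<std::vector<int> > acc;     // per-subclass bit sums
  std::vector<int> count, label;
  std::vector<std::vector<uint64_t> > proto;
  std::vector<int> log_action(n), log_subclass(n); // 0 = assigned, 1 = created

  std::vector<int> wbits(D);
  std::vector<uint64_t> wpacked;

  for (int i = 0; i < n; ++i) {
    for (int dd = 0; dd < D; ++dd) wbits[dd] = X(i, dd);
    wpacked = pack_bits(wbits.data(), D);
    int lab = y[i];

    // does this label have any subclass yet?
    int target = -1;
    bool have_label = false;
    for (size_t k = 0; k < label.size(); ++k)
      if (label[k] == lab) { have_label = true; break; }

    bool create = false;
    if (!have_label) {
      create = true;
    } else if (!multicentroid) {
      for (size_t k = 0; k < label.size(); ++k)
        if (label[k] == lab) { target = (int)k; break; }
    } else {
      // globally nearest prototype (ties -> lowest index)
      int best = -1, bestd = D + 1;
      for (size_t k = 0; k < proto.size(); ++k) {
        int d = hamming_packed(wpacked, proto[k]);
        if (d < bestd) { bestd = d; best = (int)k; }
      }
      if (label[best] != lab) {
        create = true;
      } else {
        // nearest subclass of the correct label (== global nearest here)
        int bl = -1, bld = D + 1;
        for (size_t k = 0; k < proto.size(); ++k) {
          if (label[k] != lab) continue;
          int d = hamming_packed(wpacked, proto[k]);
          if (d < bld) { bld = d; bl = (int)k; }
        }
        target = bl;
      }
    }

    if (create) {
      acc.push_back(wbits);
      count.push_back(1);
      label.push_back(lab);
      proto.push_back(wpacked); // count 1: proto == window
      log_action[i] = 1;
      log_subclass[i] = (int)acc.size(); // 1-based
    } else {
      std::vector<int>& a = acc[target];
      int c = ++count[target];
      std::vector<uint64_t>& p = proto[target];
      std::fill(p.begin(), p.end(), 0);
      for (int dd = 0; dd < D; ++dd) {
        a[dd] += wbits[dd];
        int c2 = 2 * a[dd];
        int bit = (c2 > c) ? 1 : (c2 == c ? ((tb[dd >> 6] >> (dd & 63)) & 1) : 0);
        if (bit) p[dd >> 6] |= (uint64_t(1) << (dd & 63));
      }
      log_action[i] = 0;
      log_subclass[i] = target + 1;
    }
  }

  int K = (int)acc.size();
  IntegerMatrix accm(K, D), protom(K, D);
  for (int k = 0; k < K; ++k)
    for (int dd = 0; dd < D; ++dd) {
      accm(k, dd) = acc[k][dd];
      protom(k, dd) = (proto[k][dd >> 6] >> (dd & 63)) & 1;
    }
  return List::create(_["acc"] = accm, _["proto"] = protom,
                      _["count"] = wrap(count), _["label"] = wrap(label),
                      _["log_action"] = wrap(log_action),
                      _["log_subclass"] = wrap(log_subclass));
}
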