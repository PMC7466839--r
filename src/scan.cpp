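#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <vector>
#include <tuple>
using namespace Rcpp;

// Seed-and-extend scan for maximal approximate matching segment pairs between
// two strings a and b. A reported pair (i, j, len) aligns a[i..i+len-1] with
// b[j..j+len-1] (0-based here, 1-based in the returned frame) with at most
// max_mm mismatches, and is maximal: extending one column on either side
// either leaves the sequence bounds or exceeds the mismatch budget.
//
// Seeds are exact matches of length seed_len shared between a and b; with
// seed_len <= floor(min_len / (max_mm + 1)) the pigeonhole principle
// guarantees every qualifying pair contains an exact seed, so nothing within
// the budget is missed.

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N and friends never match
  }
}

// [[Rcpp::export(rng = false)]]
DataFrame cpp_pair_scan(std::string a, std::string b, int min_len, int max_mm,
                        int seed_len, bool self_forward) {
  const int na = (int)a.size(), nb = (int)b.size();
  DataFrame empty = DataFrame::create(
      Named("start_a") = IntegerVector(0), Named("start_b") = IntegerVector(0),
      Named("len") = IntegerVector(0), Named("mm") = IntegerVector(0));
  if (na < seed_len || nb < seed_len || min_len < seed_len) {
    if (min_len < seed_len) stop("seed_len must not exceed min_len");
    return empty;
  }

  // hash all clean seed_len-mers of b
  std::unordered_map<uint64_t, std::vector<int> > index;
  {
    uint64_t code = 0, mask = (seed_len >= 32) ? ~0ULL
                      : ((1ULL << (2 * seed_len)) - 1);
    int run = 0; // clean bases accumulated
    for (int j = 0; j < nb; ++j) {
      int c = base_code(b[j]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++run >= seed_len) index[code].push_back(j - seed_len + 1);
    }
  }

  // per-diagonal cache of the exact-match run around the last processed seed
  std::unordered_map<long long, std::pair<int,int> > run_cache;
  std::set<std::tuple<int,int,int> > seen; // (start_a, start_b, len)
  std::vector<int> out_i, out_j, out_len, out_mm;

  uint64_t code = 0, mask = (seed_len >= 32) ? ~0ULL
                    : ((1ULL << (2 * seed_len)) - 1);
  int run = 0;
  std::vector<int> lm, rm; // mismatch columns (in a-coordinates) left / right
  for (int i = 0; i < na; ++i) {
    int c = base_code(a[i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++run < seed_len) continue;
    int si = i - seed_len + 1; // seed start in a
    auto it = index.find(code);
    if (it == index.end()) continue;
    for (int sj : it->second) {
      long long d = (long long)sj - (long long)si;
      if (self_forward && d == 0) continue;
      // valid alignment column range on this diagonal (a-coordinates)
      int lo = (d < 0) ? (int)(-d) : 0;
      int hi = (d > 0) ? (nb - 1 - (int)d) : (na - 1);
      if (hi > na - 1) hi = na - 1;
      auto rc = run_cache.find(d);
      if (rc != run_cache.end() && si >= rc->second.first &&
          si + seed_len - 1 <= rc->second.second)
        continue; // same exact run as an already-processed seed
      // walk left collecting up to max_mm+1 mismatch columns
      lm.clear(); rm.clear();
      int p = si - 1;
      while (p >= lo && (int)lm.size() <= max_mm) {
        int ca = base_code(a[p]), cb = base_code(b[p + d]);
        if (ca < 0 || cb < 0 || ca != cb) lm.push_back(p);
        --p;
      }
      int exact_lo = lm.empty() ? lo : lm.front() + 1;
      p = si + seed_len;
      while (p <= hi && (int)rm.size() <= max_mm) {
        int ca = base_code(a[p]), cb = base_code(b[p + d]);
        if (ca < 0 || cb < 0 || ca != cb) rm.push_back(p);
        ++p;
      }
      int exact_hi = rm.empty() ? hi : rm.front() - 1;
      run_cache[d] = std::make_pair(exact_lo, exact_hi);
      // enumerate maximal windows containing the seed: exactly l mismatches
      // taken on the left, up to max_mm - l on the right
      for (int l = 0; l <= max_mm && l <= (int)lm.size(); ++l) {
        int r_avail = max_mm - l;
        int s = (l < (int)lm.size()) ? lm[l] + 1 : lo;
        int r_used = std::min(r_avail, (int)rm.size());
        int e = (r_avail < (int)rm.size()) ? rm[r_avail] - 1 : hi;
        int used = l + r_used;
        // maximal iff each side is blocked by the sequence bounds or the
        // budget is exhausted; otherwise a strictly larger window exists and
        // is emitted at another l split
        if (!((s == lo || used == max_mm) && (e == hi || used == max_mm)))
          continue;
        int len = e - s + 1;
        if (len < min_len) continue;
        auto key = std::make_tuple(s, (int)(s + d), len);
        if (seen.insert(key).second) {
          out_i.push_back(s + 1);
          out_j.push_back((int)(s + d) + 1);
          out_len.push_back(len);
          out_mm.push_back(used);
        }
      }
    }
  }
  return DataFrame::create(Named("start_a") = wrap(out_i),
                           Named("start_b") = wrap(out_j),
                           Named("len") = wrap(out_len),
                           Named("mm") = wrap(out_mm));
}
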