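#include <Rcpp.h>
#include <set>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string rc(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp(out[i]);
  return out;
}

// Full-length ungapped scan of every read against every window at every
// offset, both orientations. Returns, per read, the minimum mismatch count
// (max_mm + 1 when no alignment reaches max_mm) and the 1-based indices of
// all windows attaining it. 'N' in either sequence counts as a mismatch.
// This exhaustive scan is the reference matching contract; there is no
// index to diverge from it.
// [[Rcpp::export(rng = false)]]
List scan_reads_cpp(CharacterVector reads, CharacterVector windows,
                    int max_mm) {
  int nw = windows.size();
  std::vector<std::string> win(nw);
  for (int w = 0; w < nw; ++w) win[w] = as<std::string>(windows[w]);

  int nr = reads.size();
  IntegerVector best_mm(nr);
  List hits(nr);

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = rc(fwd);
    int L = (int)fwd.size();
    int best = max_mm + 1;
    std::set<int> hit;
    for (int orient = 0; orient < 2; ++orient) {
      const std::string &seq = orient == 0 ? fwd : rev;
      for (int w = 0; w < nw; ++w) {
        const std::string &ws = win[w];
        int W = (int)ws.size();
        if (L > W) continue;
        int cap = best < max_mm ? best : max_mm;
        for (int off = 0; off <= W - L; ++off) {
          int mm = 0;
          for (int i = 0; i < L; ++i) {
            char a = seq[i], b = ws[off + i];
            if (a != b || a == 'N') {
              if (++mm > cap) break;
            }
          }
          if (mm > max_mm || mm > best) continue;
          if (mm < best) {
            best = mm;
            hit.clear();
            cap = best < max_mm ? best : max_mm;
          }
          hit.insert(w + 1);
        }
      }
    }
    best_mm[r] = best;
    hits[r] = IntegerVector(hit.begin(), hit.end());
  }
  return List::create(_["best_mm"] = best_mm, _["hits"] = hits);
}
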