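#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Label every grid cell (crossing of an x- and a y-interval window) with the
// set of distinct participants whose recordings cover it.
//
// Inputs are 1-based inclusive window-index ranges per rectangle (ix0..ix1,
// iy0..iy1) and integer participant codes pid (1..np). Cost is the total
// number of (rectangle, cell) incidences, which is what makes the overlap
// computation near-linear in the input size on click-scale workloads.
//
// Returns set_id: an nx x ny integer matrix (0 = cell covered by nothing)
// and sets: the distinct participant sets, as sorted integer code vectors,
// indexed by set id.
// [[Rcpp::export]]
List grid_label_cpp(IntegerVector ix0, IntegerVector ix1,
                    IntegerVector iy0, IntegerVector iy1,
                    IntegerVector pid, int nx, int ny) {
  const R_xlen_t n = ix0.size();
  const long long ncell = (long long)nx * (long long)ny;
  if (ncell > 400000000LL)
    stop("overlap grid too large (%d x %d cells)", nx, ny);

  // pass 1: incidences per cell
  std::vector<long long> cnt(ncell + 1, 0);
  long long total = 0;
  for (R_xlen_t r = 0; r < n; ++r) {
    if (ix0[r] < 1 || ix1[r] > nx || iy0[r] < 1 || iy1[r] > ny ||
        ix0[r] > ix1[r] || iy0[r] > iy1[r])
      stop("rectangle %d maps to an invalid window range", (int)(r + 1));
    for (int iy = iy0[r]; iy <= iy1[r]; ++iy) {
      long long base = (long long)(iy - 1) * nx;
      for (int ix = ix0[r]; ix <= ix1[r]; ++ix) {
        ++cnt[base + ix - 1];
        ++total;
      }
    }
  }
  if (total > 1500000000LL)
    stop("input rectangles cover too many grid cells (%lld incidences)",
         total);

  // prefix offsets, then fill participant codes per cell
  std::vector<long long> off(ncell + 1, 0);
  for (long long c = 0; c < ncell; ++c) off[c + 1] = off[c] + cnt[c];
  std::vector<int> buf(total);
  std::vector<long long> cur(off.begin(), off.end() - 1);
  for (R_xlen_t r = 0; r < n; ++r) {
    for (int iy = iy0[r]; iy <= iy1[r]; ++iy) {
      long long base = (long long)(iy - 1) * nx;
      for (int ix = ix0[r]; ix <= ix1[r]; ++ix)
        buf[cur[base + ix - 1]++] = pid[r];
    }
  }

  // canonicalize each nonempty cell's participant set to an id
  IntegerMatrix set_id(nx, ny);
  std::map<std::vector<int>, int> ids;
  std::vector<std::vector<int> > sets;
  std::vector<int> key;
  for (long long c = 0; c < ncell; ++c) {
    long long a = off[c], b = off[c + 1];
    if (a == b) continue;
    key.assign(buf.begin() + a, buf.begin() + b);
    std::sort(key.begin(), key.end());
    key.erase(std::unique(key.begin(), key.end()), key.end());
    std::map<std::vector<int>, int>::iterator it = ids.find(key);
    int id;
    if (it == ids.end()) {
      id = (int)sets.size() + 1;
      ids.insert(std::make_pair(key, id));
      sets.push_back(key);
    } else {
      id = it->second;
    }
    set_id[c] = id;
  }

  List out_sets(sets.size());
  for (size_t i = 0; i < sets.size(); ++i)
    out_sets[i] = IntegerVector(sets[i].begin(), sets[i].end());
  return List::create(Named("set_id") = set_id, Named("sets") = out_sets);
}
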