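#include <Rcpp.h>
#include <vector>
#include <functional>
#include <cstdlib>
using namespace Rcpp;

// Exact signed reversal distance for a linear signed permutation
// (Hannenhalli-Pevzner): d = (n+1) - c + h + f on the capped breakpoint
// graph, with full hurdle and fortress handling.
//
// Breakpoint graph encoding: element +x -> (2x-1, 2x), -x -> (2x, 2x-1),
// capped by 0 and 2n+1. Black edges join positions (2i, 2i+1); gray edges
// join values (2e, 2e+1). A gray edge is oriented iff its endpoint
// positions share parity. Components are the crossing-closure of gray
// edges; an unoriented component containing a non-trivial cycle is a
// hurdle candidate. Hurdles are the minimal unoriented components plus
// the greatest one when it contains all others. A hurdle is a
// super-hurdle when deleting it does not lower the hurdle count; a
// fortress is an odd number of hurdles, all of them super.

static int count_hurdles(const std::vector<std::pair<int,int> >& spans) {
  int m = spans.size();
  if (m == 0) return 0;
  int h = 0;
  for (int i = 0; i < m; ++i) {
    bool contains_any = false;
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      if (spans[i].first <= spans[j].first && spans[j].second <= spans[i].second)
        contains_any = true;
    }
    if (!contains_any) { ++h; continue; }
    bool contains_all = true;
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      if (!(spans[i].first <= spans[j].first && spans[j].second <= spans[i].second)) {
        contains_all = false; break;
      }
    }
    if (contains_all) ++h;
  }
  return h;
}

// [[Rcpp::export]]
int hp_distance_linear_cpp(IntegerVector perm) {
  int n = perm.size();
  if (n == 0) return 0;
  int m2 = 2 * n + 2;
  std::vector<int> b(m2), pos(m2);
  b[0] = 0;
  b[m2 - 1] = 2 * n + 1;
  for (int i = 0; i < n; ++i) {
    int x = perm[i];
    if (x == 0 || std::abs(x) > n) stop("invalid signed permutation");
    if (x > 0) { b[2 * i + 1] = 2 * x - 1; b[2 * i + 2] = 2 * x; }
    else { int a = -x; b[2 * i + 1] = 2 * a; b[2 * i + 2] = 2 * a - 1; }
  }
  std::vector<char> seen_val(m2, 0);
  for (int p = 0; p < m2; ++p) {
    if (seen_val[b[p]]) stop("invalid signed permutation (repeated element)");
    seen_val[b[p]] = 1;
    pos[b[p]] = p;
  }

  // cycles: traverse alternating black (p ^ 1) and gray (pos[b[p] ^ 1])
  int ne = n + 1; // gray edges
  std::vector<int> cyc_of_edge(ne, -1);
  std::vector<int> cyc_len; // gray edges per cycle
  std::vector<char> visited(m2, 0);
  int c = 0;
  for (int start = 0; start < m2; ++start) {
    if (visited[start]) continue;
    int cid = c++;
    cyc_len.push_back(0);
    int p = start;
    while (!visited[p]) {
      visited[p] = 1;
      int pb = p ^ 1;          // black partner
      visited[pb] = 1;
      int v = b[pb];
      int ge = v / 2;          // gray edge id of (v, v^1)
      cyc_of_edge[ge] = cid;
      cyc_len[cid] += 1;
      p = pos[v ^ 1];          // gray partner
    }
  }

  // gray edge geometry
  std::vector<int> lo(ne), hi(ne);
  std::vector<char> oriented(ne);
  for (int e = 0; e < ne; ++e) {
    int p1 = pos[2 * e], p2 = pos[2 * e + 1];
    if (p1 > p2) std::swap(p1, p2);
    lo[e] = p1; hi[e] = p2;
    oriented[e] = ((p2 - p1) % 2 == 0) ? 1 : 0;
  }

  // union-find over gray edges by interval crossing
  std::vector<int> uf(ne);
  for (int e = 0; e < ne; ++e) uf[e] = e;
  std::function<int(int)> find = [&](int x) {
    while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
    return x;
  };
  // edges of the same cycle are one unit
  for (int e = 0; e < ne; ++e) {
    for (int e2 = e + 1; e2 < ne; ++e2) {
      if (cyc_of_edge[e] == cyc_of_edge[e2] ||
          (lo[e] < lo[e2] && lo[e2] < hi[e] && hi[e] < hi[e2]) ||
          (lo[e2] < lo[e] && lo[e] < hi[e2] && hi[e2] < hi[e])) {
        int r1 = find(e), r2 = find(e2);
        if (r1 != r2) uf[r1] = r2;
      }
    }
  }

  // component properties
  std::vector<int> comp_lo(ne, m2), comp_hi(ne, -1);
  std::vector<char> comp_oriented(ne, 0), comp_nontrivial(ne, 0);
  for (int e = 0; e < ne; ++e) {
    int r = find(e);
    if (lo[e] < comp_lo[r]) comp_lo[r] = lo[e];
    if (hi[e] > comp_hi[r]) comp_hi[r] = hi[e];
    if (oriented[e]) comp_oriented[r] = 1;
    if (cyc_len[cyc_of_edge[e]] > 1) comp_nontrivial[r] = 1;
  }

  std::vector<std::pair<int,int> > spans;
  for (int e = 0; e < ne; ++e) {
    if (find(e) == e && comp_nontrivial[e] && !comp_oriented[e])
      spans.push_back(std::make_pair(comp_lo[e], comp_hi[e]));
  }

  int h = count_hurdles(spans);

  int f = 0;
  if (h % 2 == 1 && (int)spans.size() >= 1) {
    // which components are hurdles, and are all of them super-hurdles?
    bool all_super = true;
    int m = spans.size();
    for (int i = 0; i < m && all_super; ++i) {
      // is spans[i] a hurdle?
      std::vector<std::pair<int,int> > rest;
      for (int j = 0; j < m; ++j) if (j != i) rest.push_back(spans[j]);
      int h_without = count_hurdles(rest);
      bool is_hurdle;
      {
        bool contains_any = false, contains_all = true;
        for (int j = 0; j < m; ++j) {
          if (j == i) continue;
          bool cont = spans[i].first <= spans[j].first &&
                      spans[j].second <= spans[i].second;
          if (cont) contains_any = true; else contains_all = false;
        }
        is_hurdle = !contains_any || (m > 1 && contains_all);
      }
      if (is_hurdle && h_without < h) all_super = false;
    }
    if (all_super && h >= 3) f = 1;
  }

  return (n + 1) - c + h + f;
}
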