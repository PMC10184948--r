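// Enumeration / sampling of directed simple paths used as the autoencoder
// training corpus.
#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

namespace {

std::vector<std::vector<int> > adj_from_list2(const List& adj) {
  const int n = adj.size();
  std::vector<std::vector<int> > A(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    A[i].reserve(nb.size());
    for (int j = 0; j < nb.size(); ++j) A[i].push_back(nb[j] - 1);
  }
  return A;
}

void count_dfs(const std::vector<std::vector<int> >& A, std::vector<char>& vis,
               int v, int depth, int lmin, int lmax, double& count) {
  if (depth >= lmin) count += 1.0;
  if (depth == lmax) return;
  vis[v] = 1;
  for (size_t k = 0; k < A[v].size(); ++k) {
    const int u = A[v][k];
    if (!vis[u]) count_dfs(A, vis, u, depth + 1, lmin, lmax, count);
  }
  vis[v] = 0;
}

void enum_dfs(const std::vector<std::vector<int> >& A, std::vector<char>& vis,
              std::vector<int>& path, int lmin, int lmax,
              std::vector<int>& flat, std::vector<int>& lens) {
  const int v = path.back();
  if ((int)path.size() >= lmin) {
    flat.insert(flat.end(), path.begin(), path.end());
    lens.push_back((int)path.size());
  }
  if ((int)path.size() == lmax) return;
  vis[v] = 1;
  for (size_t k = 0; k < A[v].size(); ++k) {
    const int u = A[v][k];
    if (!vis[u]) {
      path.push_back(u);
      enum_dfs(A, vis, path, lmin, lmax, flat, lens);
      path.pop_back();
    }
  }
  vis[v] = 0;
}

}  // namespace

// [[Rcpp::export(name = "cpp_count_paths")]]
double cpp_count_paths(List adj, int lmin, int lmax) {
  std::vector<std::vector<int> > A = adj_from_list2(adj);
  const int n = (int)A.size();
  std::vector<char> vis(n, 0);
  double count = 0.0;
  for (int v = 0; v < n; ++v) count_dfs(A, vis, v, 1, lmin, lmax, count);
  return count;
}

// Exhaustive enumeration when the total count fits under `cap`; otherwise
// uniform random-walk sampling (no immediate backtracking, simple paths only),
// deduplicated up to `cap`. Returns a matrix padded with NA plus true lengths.
// [[Rcpp::export(name = "cpp_enum_paths")]]
List cpp_enum_paths(List adj, int lmin, int lmax, double cap) {
  std::vector<std::vector<int> > A = adj_from_list2(adj);
  const int n = (int)A.size();
  if (n == 0) stop("empty graph");
  std::vector<int> flat, lens;

  const double total = cpp_count_paths(adj, lmin, lmax);
  if (total <= cap) {
    std::vector<char> vis(n, 0);
    std::vector<int> path;
    for (int v = 0; v < n; ++v) {
      path.assign(1, v);
      enum_dfs(A, vis, path, lmin, lmax, flat, lens);
      if (v % 64 == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    const long icap = (long)cap;
    std::set<std::vector<int> > got;
    long tries = 0;
    const long max_tries = 200L * icap;
    while ((long)got.size() < icap && tries < max_tries) {
      ++tries;
      if (tries % 4096 == 0) Rcpp::checkUserInterrupt();
      int L = lmin + (int)(unif_rand() * (lmax - lmin + 1));
      if (L > lmax) L = lmax;
      std::vector<int> path;
      path.push_back((int)(unif_rand() * n) % n);
      bool ok = true;
      while ((int)path.size() < L) {
        const int v = path.back();
        const int prev = path.size() > 1 ? path[path.size() - 2] : -1;
        std::vector<int> cand;
        for (size_t k = 0; k < A[v].size(); ++k)
          if (A[v][k] != prev) cand.push_back(A[v][k]);
        if (cand.empty()) { ok = false; break; }
        const int u = cand[(int)(unif_rand() * cand.size()) % cand.size()];
        // simple-path requirement: reject walks revisiting a node
        bool seen = false;
        for (size_t j = 0; j < path.size(); ++j)
          if (path[j] == u) { seen = true; break; }
        if (seen) { ok = false; break; }
        path.push_back(u);
      }
      if (ok && (int)path.size() >= lmin) got.insert(path);
    }
    for (std::set<std::vector<int> >::const_iterator it = got.begin();
         it != got.end(); ++it) {
      flat.insert(flat.end(), it->begin(), it->end());
      lens.push_back((int)it->size());
    }
  }

  const int m = (int)lens.size();
  IntegerMatrix idx(m, lmax);
  std::fill(idx.begin(), idx.end(), NA_INTEGER);
  size_t pos = 0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < lens[i]; ++j) idx(i, j) = flat[pos++] + 1;
  return List::create(_["idx"] = idx, _["lens"] = IntegerVector(lens.begin(), lens.end()));
}
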