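// Event-driven continuous-time diffusion simulator and snapshot feature
// construction. All randomness goes through R's RNG so set.seed() on the R
// side fully determines the output.
#include <Rcpp.h>
#include <queue>
#include <map>
#include <set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Event {
  double t;
  int node;
  int sender;
};

// min-heap on time; ties broken by smallest sender id
struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.sender > b.sender;
  }
};

std::vector<std::vector<int> > adj_from_list(const List& adj) {
  const int n = adj.size();
  std::vector<std::vector<int> > A(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    A[i].reserve(nb.size());
    for (int j = 0; j < nb.size(); ++j) A[i].push_back(nb[j] - 1);
  }
  return A;
}

double draw_delay(double mu, double sigma) {
  // Gaussian delay truncated to positive support by resampling
  double th;
  do {
    th = mu + sigma * norm_rand();
  } while (th <= 0.0);
  return th;
}

// With single_attempt = false (the default model), a failed Bernoulli attempt
// towards a neighbour is retried after a further delay until it succeeds, so
// the effective per-contact delay is a Geometric(beta)-stopped sum of Gaussian
// draws and the process terminates only when no ignorant node is reachable.
// With single_attempt = true each directed contact gets exactly one attempt
// and cascades can die out early for beta < 1.
// edelay, when non-null, holds one fixed delay per directed contact aligned
// with A (symmetric across the two directions of an edge): the delays are a
// property of the network, shared by every diffusion run on it. A failed
// attempt then repeats after the same edge delay. When null, every attempt
// draws a fresh delay.
void run_sim(const std::vector<std::vector<int> >& A, int src, double beta,
             double mu, double sigma, bool single_attempt,
             const std::vector<std::vector<double> >* edelay,
             std::vector<double>& t, std::vector<int>& inf,
             std::vector<double>* contacts) {
  const int n = (int)A.size();
  t.assign(n, NA_REAL);
  inf.assign(n, -1);
  std::priority_queue<Event, std::vector<Event>, EventCmp> q;
  q.push(Event{0.0, src, -1});
  while (!q.empty()) {
    Event e = q.top();
    q.pop();
    if (!ISNA(t[e.node])) continue;  // earliest successful arrival wins
    t[e.node] = e.t;
    inf[e.node] = e.sender;
    if (beta <= 0.0) continue;
    for (size_t k = 0; k < A[e.node].size(); ++k) {
      const int u = A[e.node][k];
      if (u == e.sender) continue;  // no attempt back to own infector
      const double step = edelay ? (*edelay)[e.node][k] : 0.0;
      double th = edelay ? step : draw_delay(mu, sigma);
      bool success = unif_rand() < beta;
      if (!single_attempt) {
        while (!success) {
          th += edelay ? step : draw_delay(mu, sigma);
          success = unif_rand() < beta;
        }
      }
      if (success) {
        if (contacts) {
          contacts->push_back(e.node + 1);
          contacts->push_back(u + 1);
          contacts->push_back(th);
        }
        q.push(Event{e.t + th, u, e.node});
      }
    }
  }
}

// ---- Snapshot feature construction (infector-chain tracing) ----

// strict weak order on sequences: by length (direction configurable), ties by
// lexicographic node order
struct SeqOrder {
  bool shortest_first;
  explicit SeqOrder(bool sf = false) : shortest_first(sf) {}
  bool operator()(const std::vector<int>& a, const std::vector<int>& b) const {
    if (a.size() != b.size())
      return shortest_first ? a.size() < b.size() : a.size() > b.size();
    return a < b;
  }
};

typedef std::set<std::vector<int>, SeqOrder> SeqSet;

struct AreaInfo {
  std::vector<int> members;        // sorted ascending, 0-based
  std::vector<char> mask;          // length n membership indicator
};

std::vector<AreaInfo> areas_from_list(const List& areas, int n) {
  std::vector<AreaInfo> out(areas.size());
  for (int i = 0; i < areas.size(); ++i) {
    IntegerVector a = areas[i];
    out[i].mask.assign(n, 0);
    out[i].members.reserve(a.size());
    for (int j = 0; j < a.size(); ++j) {
      int v = a[j] - 1;
      if (v < 0 || v >= n) stop("area member out of range");
      if (!out[i].mask[v]) {
        out[i].mask[v] = 1;
        out[i].members.push_back(v);
      }
    }
    std::sort(out[i].members.begin(), out[i].members.end());
  }
  return out;
}

// Trace the infector chain backwards from an observer while it stays inside
// the area and informed; returned earliest-first, truncated to the earliest
// l_max nodes. Empty vector when fewer than 2 nodes were collected.
std::vector<int> trace_one(const std::vector<double>& t, const std::vector<int>& inf,
                           const AreaInfo& area, int observer, int lmax) {
  std::vector<int> seq;
  int c = observer;
  int guard = (int)t.size() + 1;
  while (c >= 0 && area.mask[c] && !ISNA(t[c]) && guard-- > 0) {
    seq.push_back(c);
    c = inf[c];
  }
  std::reverse(seq.begin(), seq.end());
  if ((int)seq.size() > lmax) seq.resize(lmax);  // drop latest-informed nodes
  if (seq.size() < 2) seq.clear();
  return seq;
}

// Full feature build: sort areas by mean informed observer time (ascending,
// areas with no informed observer last, stable by area index), trace every
// observer, deduplicate, keep the eta longest sequences per group.
void build_feature_core(const std::vector<double>& t, const std::vector<int>& inf,
                        const std::vector<AreaInfo>& areas, int lmax, int eta,
                        bool keep_shortest,
                        std::vector<std::vector<std::vector<int> > >& groups,
                        std::vector<int>& order) {
  const int K = (int)areas.size();
  std::vector<double> key(K);
  for (int i = 0; i < K; ++i) {
    double s = 0.0;
    int m = 0;
    for (size_t j = 0; j < areas[i].members.size(); ++j) {
      const int v = areas[i].members[j];
      if (!ISNA(t[v])) {
        s += t[v];
        ++m;
      }
    }
    key[i] = (m > 0) ? s / m : R_PosInf;
  }
  order.resize(K);
  for (int i = 0; i < K; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&key](int a, int b) { return key[a] < key[b]; });

  groups.assign(K, std::vector<std::vector<int> >());
  for (int gi = 0; gi < K; ++gi) {
    const AreaInfo& area = areas[order[gi]];
    SeqSet uniq((SeqOrder(keep_shortest)));
    for (size_t j = 0; j < area.members.size(); ++j) {
      std::vector<int> seq = trace_one(t, inf, area, area.members[j], lmax);
      if (!seq.empty()) uniq.insert(seq);
    }
    int kept = 0;
    for (SeqSet::const_iterator it = uniq.begin(); it != uniq.end() && kept < eta;
         ++it, ++kept) {
      groups[gi].push_back(*it);
    }
  }
}

std::vector<double> times_from_R(const NumericVector& tt) {
  return std::vector<double>(tt.begin(), tt.end());
}

std::vector<std::vector<double> > edelay_from_list(const List& ed, int n) {
  std::vector<std::vector<double> > D(n);
  if (ed.size() != n) stop("edge delay list does not match the adjacency list");
  for (int i = 0; i < n; ++i) {
    NumericVector v = ed[i];
    D[i].assign(v.begin(), v.end());
  }
  return D;
}

std::vector<int> infector_from_R(const IntegerVector& ii) {
  std::vector<int> inf(ii.size());
  for (int i = 0; i < ii.size(); ++i)
    inf[i] = (ii[i] == NA_INTEGER) ? -1 : ii[i] - 1;
  return inf;
}

}  // namespace

// [[Rcpp::export(name = "cpp_simulate")]]
List cpp_simulate(List adj, int source, double beta, double mu, double sigma,
                  bool single_attempt, Nullable<List> edge_delays,
                  bool record_contacts) {
  std::vector<std::vector<int> > A = adj_from_list(adj);
  const int n = (int)A.size();
  if (source < 1 || source > n) stop("source node not in the graph");
  std::vector<std::vector<double> > D;
  bool has_d = edge_delays.isNotNull();
  if (has_d) {
    D = edelay_from_list(List(edge_delays), n);
    for (int i = 0; i < n; ++i)
      if (D[i].size() != A[i].size()) stop("edge delay list does not match the adjacency list");
  }
  std::vector<double> t;
  std::vector<int> inf;
  std::vector<double> contacts;
  run_sim(A, source - 1, beta, mu, sigma, single_attempt,
          has_d ? &D : (std::vector<std::vector<double> >*)0, t, inf,
          record_contacts ? &contacts : (std::vector<double>*)0);
  NumericVector tt(t.begin(), t.end());
  IntegerVector ii(n);
  for (int i = 0; i < n; ++i) ii[i] = (inf[i] < 0) ? NA_INTEGER : inf[i] + 1;
  List out = List::create(_["time"] = tt, _["infector"] = ii);
  if (record_contacts) {
    const int m = (int)contacts.size() / 3;
    NumericMatrix cm(m, 3);
    for (int i = 0; i < m; ++i) {
      cm(i, 0) = contacts[3 * i];
      cm(i, 1) = contacts[3 * i + 1];
      cm(i, 2) = contacts[3 * i + 2];
    }
    colnames(cm) = CharacterVector::create("from", "to", "delay");
    out["contacts"] = cm;
  }
  return out;
}

// [[Rcpp::export(name = "cpp_trace_sequence")]]
IntegerVector cpp_trace_sequence(NumericVector time, IntegerVector infector,
                                 IntegerVector area, int observer, int lmax) {
  const int n = time.size();
  std::vector<double> t = times_from_R(time);
  std::vector<int> inf = infector_from_R(infector);
  List al = List::create(area);
  std::vector<AreaInfo> ai = areas_from_list(al, n);
  std::vector<int> seq = trace_one(t, inf, ai[0], observer - 1, lmax);
  IntegerVector out(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) out[i] = seq[i] + 1;
  return out;
}

// [[Rcpp::export(name = "cpp_build_feature")]]
List cpp_build_feature(NumericVector time, IntegerVector infector, List areas,
                       int lmax, int eta, bool keep_shortest) {
  const int n = time.size();
  std::vector<double> t = times_from_R(time);
  std::vector<int> inf = infector_from_R(infector);
  std::vector<AreaInfo> ai = areas_from_list(areas, n);
  std::vector<std::vector<std::vector<int> > > groups;
  std::vector<int> order;
  build_feature_core(t, inf, ai, lmax, eta, keep_shortest, groups, order);
  List gl(groups.size());
  for (size_t g = 0; g < groups.size(); ++g) {
    List sl(groups[g].size());
    for (size_t s = 0; s < groups[g].size(); ++s) {
      IntegerVector v(groups[g][s].size());
      for (size_t j = 0; j < groups[g][s].size(); ++j) v[j] = groups[g][s][j] + 1;
      sl[s] = v;
    }
    gl[g] = sl;
  }
  IntegerVector ord(order.size());
  for (size_t i = 0; i < order.size(); ++i) ord[i] = order[i] + 1;
  return List::create(_["groups"] = gl, _["area_order"] = ord);
}

// Batched generation for classifier training: for each (source, beta) record,
// simulate a fresh snapshot, build its feature, and return sequence placements
// against a global table of unique sequences (kept small by heavy repetition
// across snapshots).
// [[Rcpp::export(name = "cpp_collect_features")]]
List cpp_collect_features(List adj, List areas, IntegerVector sources,
                          NumericVector betas, double mu, double sigma,
                          bool single_attempt, Nullable<List> edge_delays,
                          int lmax, int eta, bool keep_shortest) {
  std::vector<std::vector<int> > A = adj_from_list(adj);
  const int n = (int)A.size();
  std::vector<std::vector<double> > D;
  bool has_d = edge_delays.isNotNull();
  if (has_d) D = edelay_from_list(List(edge_delays), n);
  const int nrec = sources.size();
  if (betas.size() != nrec) stop("sources and betas must have equal length");
  std::vector<AreaInfo> ai = areas_from_list(areas, n);

  std::map<std::vector<int>, int> seq_id;
  std::vector<const std::vector<int>*> seq_store;
  std::vector<int> p_rec, p_grp, p_slot, p_seq;

  std::vector<double> t;
  std::vector<int> inf;
  std::vector<std::vector<std::vector<int> > > groups;
  std::vector<int> order;

  for (int r = 0; r < nrec; ++r) {
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
    const int src = sources[r] - 1;
    if (src < 0 || src >= n) stop("source node not in the graph");
    run_sim(A, src, betas[r], mu, sigma, single_attempt,
            has_d ? &D : (std::vector<std::vector<double> >*)0, t, inf,
            (std::vector<double>*)0);
    build_feature_core(t, inf, ai, lmax, eta, keep_shortest, groups, order);
    for (size_t g = 0; g < groups.size(); ++g) {
      for (size_t s = 0; s < groups[g].size(); ++s) {
        std::map<std::vector<int>, int>::iterator it = seq_id.find(groups[g][s]);
        int id;
        if (it == seq_id.end()) {
          id = (int)seq_id.size();
          it = seq_id.insert(std::make_pair(groups[g][s], id)).first;
          seq_store.push_back(&it->first);
        } else {
          id = it->second;
        }
        p_rec.push_back(r + 1);
        p_grp.push_back((int)g + 1);
        p_slot.push_back((int)s + 1);
        p_seq.push_back(id + 1);
      }
    }
  }

  const int m = (int)p_rec.size();
  IntegerMatrix placements(m, 4);
  for (int i = 0; i < m; ++i) {
    placements(i, 0) = p_rec[i];
    placements(i, 1) = p_grp[i];
    placements(i, 2) = p_slot[i];
    placements(i, 3) = p_seq[i];
  }
  colnames(placements) = CharacterVector::create("record", "group", "slot", "seq");
  List seqs(seq_store.size());
  for (size_t i = 0; i < seq_store.size(); ++i) {
    const std::vector<int>& s = *seq_store[i];
    IntegerVector v(s.size());
    for (size_t j = 0; j < s.size(); ++j) v[j] = s[j] + 1;
    seqs[i] = v;
  }
  return List::create(_["placements"] = placements, _["sequences"] = seqs);
}
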