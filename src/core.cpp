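// Core sequence primitives: canonical k-mer counting, de Bruijn unitig
// construction, fixed-length seed read mapping, exact pattern location.
// Everything here is desk-scale (hundreds of kbp): hash maps keyed by
// plain strings are fast enough and keep k unrestricted (k can exceed 64).
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <set>
#include <tuple>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string rc_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = rc_str(s);
  }
  return out;
}

// ---- canonical k-mer counting ------------------------------------------

// Count every length-k window free of non-ACGT characters once, under the
// canonical form (lexicographic min of window and reverse complement).
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> tab;
  tab.reserve(1 << 20);
  long long windows = 0;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    int n = (int)s.size();
    if (n < k) continue;
    std::string r = rc_str(s);
    int run = 0; // length of current valid run ending at i
    for (int i = 0; i < n; ++i) {
      run = valid_base(s[i]) ? run + 1 : 0;
      if (run >= k) {
        int start = i - k + 1;
        std::string f = s.substr(start, k);
        std::string b = r.substr(n - k - start, k);
        ++windows;
        ++tab[(b < f) ? b : f];
      }
    }
  }
  R_xlen_t m = tab.size();
  CharacterVector kmer(m);
  IntegerVector count(m);
  R_xlen_t i = 0;
  for (auto& kv : tab) { kmer[i] = kv.first; count[i] = kv.second; ++i; }
  return List::create(_["kmer"] = kmer, _["count"] = count,
                      _["windows"] = (double)windows);
}

// ---- de Bruijn graph construction --------------------------------------

struct OrientedKmer { int id; bool rev; };

// [[Rcpp::export]]
List cpp_build_dbg(CharacterVector kmer, NumericVector count, int k) {
  int n = kmer.size();
  std::vector<std::string> fwd(n), bwd(n);
  std::unordered_map<std::string, int> idx;
  idx.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(kmer[i]);
    bwd[i] = rc_str(fwd[i]);
    idx[fwd[i]] = i;
  }
  static const char BASES[4] = {'A', 'C', 'G', 'T'};

  // successor in a given orientation: extend 3' by one base
  auto find_next = [&](const std::string& s, char b, OrientedKmer* out) -> bool {
    std::string t = s.substr(1) + b;
    std::string tr = rc_str(t);
    bool rev = tr < t;
    auto it = idx.find(rev ? tr : t);
    if (it == idx.end()) return false;
    out->id = it->second; out->rev = rev;
    return true;
  };

  // successors in both orientations, computed once (succ of the stored
  // orientation; predecessors are successors of the reverse complement)
  std::vector<std::vector<OrientedKmer> > succ_f(n), succ_r(n);
  std::vector<bool> junction(n, false);
  for (int i = 0; i < n; ++i) {
    OrientedKmer t;
    for (int b = 0; b < 4; ++b) {
      if (find_next(fwd[i], BASES[b], &t)) succ_f[i].push_back(t);
      if (find_next(bwd[i], BASES[b], &t)) succ_r[i].push_back(t);
    }
    junction[i] = (succ_f[i].size() > 1) || (succ_r[i].size() > 1) ||
      (fwd[i] == bwd[i]);
  }

  auto unique_next = [&](int id, bool rev, OrientedKmer* out) -> bool {
    const std::vector<OrientedKmer>& s = rev ? succ_r[id] : succ_f[id];
    if (s.size() != 1) return false;
    *out = s[0]; return true;
  };

  // unitigs of non-junction k-mers
  std::vector<int> visited(n, 0);
  std::vector<std::string> useq;
  std::vector<double> ucov;
  // terminal oriented k-mer strings for entry matching
  std::vector<std::string> ufirst, ulast; // oriented as they appear in unitig
  std::vector<int> ufirst_id, ulast_id;
  std::unordered_map<int, int> kmer2unitig;

  for (int i = 0; i < n; ++i) {
    if (junction[i] || visited[i]) continue;
    // walk backward to find the start of the chain
    OrientedKmer cur{i, false};
    std::unordered_set<int> seen;
    seen.insert(i);
    bool circular = false;
    while (true) {
      OrientedKmer prev;
      // predecessor of cur = successor in flipped orientation, flipped back
      if (!unique_next(cur.id, !cur.rev, &prev)) break;
      if (junction[prev.id]) break;
      // require the step back to be mutual (prev's unique successor is cur)
      OrientedKmer chk;
      if (!unique_next(prev.id, !prev.rev, &chk) || chk.id != cur.id) break;
      if (seen.count(prev.id)) { circular = true; break; }
      cur = OrientedKmer{prev.id, !prev.rev};
      seen.insert(cur.id);
    }
    // walk forward from chain start, collecting
    std::vector<OrientedKmer> chain;
    OrientedKmer p = cur;
    std::unordered_set<int> inchain;
    while (true) {
      chain.push_back(p);
      inchain.insert(p.id);
      visited[p.id] = 1;
      OrientedKmer nx;
      if (!unique_next(p.id, p.rev, &nx)) break;
      if (junction[nx.id] || inchain.count(nx.id)) break;
      OrientedKmer back;
      if (!unique_next(nx.id, !nx.rev, &back) || back.id != p.id) break;
      p = nx;
    }
    (void)circular;
    std::string s = chain[0].rev ? bwd[chain[0].id] : fwd[chain[0].id];
    double covsum = count[chain[0].id];
    for (size_t j = 1; j < chain.size(); ++j) {
      const std::string& t = chain[j].rev ? bwd[chain[j].id] : fwd[chain[j].id];
      s.push_back(t[k - 1]);
      covsum += count[chain[j].id];
    }
    int uidx = (int)useq.size();
    useq.push_back(s);
    ucov.push_back(covsum / chain.size());
    ufirst.push_back(chain.front().rev ? bwd[chain.front().id] : fwd[chain.front().id]);
    ulast.push_back(chain.back().rev ? bwd[chain.back().id] : fwd[chain.back().id]);
    ufirst_id.push_back(chain.front().id);
    ulast_id.push_back(chain.back().id);
    for (auto& ok : chain) kmer2unitig[ok.id] = uidx;
  }

  int U = (int)useq.size();
  // junction node ids: U+1 .. U+J (1-based on return)
  std::vector<int> jid(n, -1);
  std::vector<int> jlist;
  for (int i = 0; i < n; ++i)
    if (junction[i]) { jid[i] = U + (int)jlist.size(); jlist.push_back(i); }

  // edges: emitted from junction side (straight-straight adjacency cannot
  // occur: a non-junction pair with mutual unique links is merged)
  std::set<std::tuple<int,int,int,int> > edges;
  auto add_edge = [&](int a, int ea, int b, int eb) {
    if (std::make_pair(a, ea) <= std::make_pair(b, eb))
      edges.insert(std::make_tuple(a, ea, b, eb));
    else
      edges.insert(std::make_tuple(b, eb, a, ea));
  };
  for (size_t jj = 0; jj < jlist.size(); ++jj) {
    int i = jlist[jj];
    int self = jid[i];
    for (int end = 0; end <= 1; ++end) {
      const std::vector<OrientedKmer>& succs = (end == 1) ? succ_f[i] : succ_r[i];
      for (size_t bi = 0; bi < succs.size(); ++bi) {
        OrientedKmer t = succs[bi];
        std::string t_o = t.rev ? bwd[t.id] : fwd[t.id];
        if (junction[t.id]) {
          int entry = (t_o == fwd[t.id]) ? 0 : 1;
          add_edge(self, end, jid[t.id], entry);
        } else {
          auto it = kmer2unitig.find(t.id);
          if (it == kmer2unitig.end()) continue;
          int u = it->second;
          if (t.id == ufirst_id[u] && t_o == ufirst[u]) {
            add_edge(self, end, u, 0);
          } else if (t.id == ulast_id[u] && t_o == rc_str(ulast[u])) {
            add_edge(self, end, u, 1);
          } else if (t.id == ufirst_id[u] && t_o == rc_str(ufirst[u]) &&
                     (int)useq[u].size() == k) {
            add_edge(self, end, u, 1); // single-kmer unitig, flipped entry
          }
        }
      }
    }
  }

  int J = (int)jlist.size();
  CharacterVector nseq(U + J);
  NumericVector ncov(U + J);
  LogicalVector njun(U + J);
  for (int u = 0; u < U; ++u) { nseq[u] = useq[u]; ncov[u] = ucov[u]; njun[u] = false; }
  for (int j = 0; j < J; ++j) {
    nseq[U + j] = fwd[jlist[j]]; ncov[U + j] = count[jlist[j]]; njun[U + j] = true;
  }
  int ne = (int)edges.size();
  IntegerVector a(ne), ea(ne), bb(ne), eb(ne);
  int e = 0;
  for (auto& t : edges) {
    a[e] = std::get<0>(t) + 1; ea[e] = std::get<1>(t);
    bb[e] = std::get<2>(t) + 1; eb[e] = std::get<3>(t);
    ++e;
  }
  return List::create(
    _["seq"] = nseq, _["cov"] = ncov, _["junction"] = njun,
    _["edge_a"] = a, _["edge_ea"] = ea, _["edge_b"] = bb, _["edge_eb"] = eb);
}

// ---- seed index over node sequences ------------------------------------

typedef std::unordered_map<std::string, std::vector<std::pair<int,int> > > SeedIndex;

static void build_seed_index(const std::vector<std::string>& seqs, int L,
                             SeedIndex& ix) {
  ix.reserve(1 << 20);
  for (size_t si = 0; si < seqs.size(); ++si) {
    const std::string& s = seqs[si];
    int n = (int)s.size();
    int run = 0;
    for (int i = 0; i < n; ++i) {
      run = valid_base(s[i]) ? run + 1 : 0;
      if (run >= L) {
        int start = i - L + 1;
        ix[s.substr(start, L)].push_back(std::make_pair((int)si, start));
      }
    }
  }
}

// check extension of a candidate occurrence to length `len`
static bool check_ext(const std::string& node, int p, bool rev,
                      const std::string& read, int o, int len, int seedL) {
  if (!rev) {
    if (p + len > (int)node.size()) return false;
    return node.compare(p, len, read, o, len) == 0;
  } else {
    // rc(read[o..o+len)) == node[p-(len-seedL) .. p+seedL)
    int start = p - (len - seedL);
    if (start < 0 || start + len > (int)node.size()) return false;
    for (int j = 0; j < len; ++j) {
      if (node[start + j] != comp_base(read[o + len - 1 - j])) return false;
    }
    return true;
  }
}

// Map reads onto node sequences by exact, unique fixed-length seeds
// (lengths 32/64/96, shortest unique accepted), at offsets 0,32,64,...
// Returns 0-based projected node coordinate of read base 0 (`rstart`).
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector node_seqs, CharacterVector reads,
                        int seed_len = 32, int max_offsets = 64) {
  std::vector<std::string> nodes(node_seqs.size());
  for (R_xlen_t i = 0; i < node_seqs.size(); ++i)
    nodes[i] = as<std::string>(node_seqs[i]);
  SeedIndex ix;
  build_seed_index(nodes, seed_len, ix);

  std::vector<int> r_read, r_node, r_rstart, r_off, r_sl;
  std::vector<int> r_strand; // 1 = +, -1 = -

  int lens[3] = {seed_len, seed_len * 2, seed_len * 3};
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    int n = (int)rd.size();
    int noff = 0;
    for (int o = 0; o + seed_len <= n && noff < max_offsets; o += seed_len, ++noff) {
      bool ok = true;
      for (int j = o; j < o + seed_len; ++j)
        if (!valid_base(rd[j])) { ok = false; break; }
      if (!ok) continue;
      std::string seed = rd.substr(o, seed_len);
      std::string seedrc = rc_str(seed);
      // candidates: (node, pos, rev)
      std::vector<std::tuple<int,int,bool> > cand;
      auto itf = ix.find(seed);
      if (itf != ix.end())
        for (auto& pr : itf->second) cand.push_back(std::make_tuple(pr.first, pr.second, false));
      auto itr = ix.find(seedrc);
      if (itr != ix.end())
        for (auto& pr : itr->second) cand.push_back(std::make_tuple(pr.first, pr.second, true));
      if (cand.empty()) continue;
      int chosen = -1, chosen_len = -1;
      for (int li = 0; li < 3; ++li) {
        int len = lens[li];
        if (o + len > n) break;
        int nsurv = 0, surv = -1;
        for (size_t ci = 0; ci < cand.size(); ++ci) {
          int nd = std::get<0>(cand[ci]), p = std::get<1>(cand[ci]);
          bool rev = std::get<2>(cand[ci]);
          if (check_ext(nodes[nd], p, rev, rd, o, len, seed_len)) {
            ++nsurv; surv = (int)ci;
            if (nsurv > 1) break;
          }
        }
        if (nsurv == 1) { chosen = surv; chosen_len = len; break; }
        if (nsurv == 0) break; // longer extension cannot resurrect matches
      }
      if (chosen < 0) continue;
      int nd = std::get<0>(cand[chosen]), p = std::get<1>(cand[chosen]);
      bool rev = std::get<2>(cand[chosen]);
      int rstart = rev ? (p + seed_len - 1 + o) : (p - o);
      r_read.push_back((int)ri + 1);
      r_node.push_back(nd + 1);
      r_strand.push_back(rev ? -1 : 1);
      r_rstart.push_back(rstart);
      r_off.push_back(o);
      r_sl.push_back(chosen_len);
    }
  }
  return DataFrame::create(
    _["read"] = r_read, _["node"] = r_node, _["strand"] = r_strand,
    _["rstart"] = r_rstart, _["offset"] = r_off, _["seed_len"] = r_sl);
}

// Exact occurrences (both strands) of each pattern in the subject set.
// Patterns must be >= seed_len long and ACGT-only to be findable.
// [[Rcpp::export]]
DataFrame cpp_locate(CharacterVector patterns, CharacterVector subjects,
                     int seed_len = 32, int max_hits = 1000) {
  std::vector<std::string> subs(subjects.size());
  for (R_xlen_t i = 0; i < subjects.size(); ++i)
    subs[i] = as<std::string>(subjects[i]);
  SeedIndex ix;
  build_seed_index(subs, seed_len, ix);

  std::vector<int> r_pat, r_sub, r_pos, r_strand;
  for (R_xlen_t pi = 0; pi < patterns.size(); ++pi) {
    std::string p = as<std::string>(patterns[pi]);
    if ((int)p.size() < seed_len) continue;
    bool ok = true;
    for (char c : p) if (!valid_base(c)) { ok = false; break; }
    if (!ok) continue;
    int hits = 0;
    for (int strand = 0; strand < 2 && hits < max_hits; ++strand) {
      std::string q = (strand == 0) ? p : rc_str(p);
      auto it = ix.find(q.substr(0, seed_len));
      if (it == ix.end()) continue;
      for (auto& pr : it->second) {
        const std::string& s = subs[pr.first];
        int pos = pr.second;
        if (pos + (int)q.size() > (int)s.size()) continue;
        if (s.compare(pos, q.size(), q) == 0) {
          r_pat.push_back((int)pi + 1);
          r_sub.push_back(pr.first + 1);
          r_pos.push_back(pos);
          r_strand.push_back(strand == 0 ? 1 : -1);
          if (++hits >= max_hits) break;
        }
      }
    }
  }
  return DataFrame::create(
    _["pattern"] = r_pat, _["subject"] = r_sub,
    _["pos"] = r_pos, _["strand"] = r_strand);
}
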