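// Core shingle engine: rooted canonical fragment SMILES.
//
// A shingle is the connected fragment induced by all bonds within r bonds of a
// root atom, written as a canonical SMILES string whose first atom is the root,
// with aromatic atoms in lowercase and all stereochemistry discarded.
//
// Canonicalization: iterative invariant refinement (element, aromaticity,
// charge, isotope, explicit H, degree; refined by sorted neighbour
// rank/bond-code pairs) followed by canonical individualization: while a
// non-singleton cell remains, each member of the lowest-ranked such cell is
// individualized in turn and the lexicographically smallest resulting string
// is kept. This is exact (no heuristic tie-break) and cheap at fragment sizes.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <array>
#include <algorithm>
#include <unordered_set>
#include <unordered_map>

using namespace Rcpp;

namespace {

struct AdjEntry {
  int nbr;   // neighbour local index
  int code;  // bond code: 1 single, 2 double, 3 triple, 4 aromatic
  int bid;   // bond local index
};

struct Frag {
  int n;
  std::vector<std::string> token;  // rendered atom token
  std::vector<char> arom;
  std::vector<long long> inv;      // packed scalar invariant
  std::vector<std::vector<AdjEntry>> adj;
  int nbonds;
};

bool isOrganicSubset(const std::string& s) {
  return s == "B" || s == "C" || s == "N" || s == "O" || s == "P" ||
         s == "S" || s == "F" || s == "Cl" || s == "Br" || s == "I";
}

std::string atomToken(const std::string& sym, bool arom, int charge,
                      int isotope, int hexp) {
  std::string s = sym;
  if (arom)
    for (auto& c : s) c = (char) std::tolower(c);
  if (charge == 0 && isotope == 0 && hexp < 0 && isOrganicSubset(sym))
    return s;
  std::string out = "[";
  if (isotope > 0) out += std::to_string(isotope);
  out += s;
  if (hexp > 0) {
    out += "H";
    if (hexp > 1) out += std::to_string(hexp);
  }
  if (charge > 0) {
    out += "+";
    if (charge > 1) out += std::to_string(charge);
  } else if (charge < 0) {
    out += "-";
    if (charge < -1) out += std::to_string(-charge);
  }
  out += "]";
  return out;
}

std::string bondChar(int code, bool aromA, bool aromB) {
  switch (code) {
    case 4: return (aromA && aromB) ? "" : ":";
    case 1: return (aromA && aromB) ? "-" : "";
    case 2: return "=";
    case 3: return "#";
  }
  return "";
}

long long packInvariant(int elem, int arom, int charge, int isotope, int hexp,
                        int deg) {
  long long v = elem;                 // element code, < 256
  v = (v << 1) | (arom ? 1 : 0);
  v = (v << 5) | (long long)(charge + 10);
  v = (v << 10) | (long long) std::min(isotope, 1000);
  v = (v << 5) | (long long)(std::min(hexp, 20) + 1);
  v = (v << 5) | (long long) std::min(deg, 20);
  return v;
}

// Dense-rank atoms by lexicographic key; returns number of classes.
int denseRank(const std::vector<std::vector<long long>>& key,
              std::vector<int>& ranks) {
  int n = (int) key.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return key[a] < key[b]; });
  int r = 0;
  ranks[idx[0]] = 0;
  for (int i = 1; i < n; ++i) {
    if (key[idx[i]] != key[idx[i - 1]]) ++r;
    ranks[idx[i]] = r;
  }
  return r + 1;
}

// Refine ranks to a stable equitable partition; returns class count.
int refine(const Frag& f, std::vector<int>& ranks) {
  int ncls = -1;
  for (;;) {
    std::vector<std::vector<long long>> key(f.n);
    for (int i = 0; i < f.n; ++i) {
      key[i].reserve(1 + f.adj[i].size());
      key[i].push_back(ranks[i]);
      std::vector<long long> ns;
      ns.reserve(f.adj[i].size());
      for (const auto& e : f.adj[i])
        ns.push_back((long long) ranks[e.nbr] * 8 + e.code);
      std::sort(ns.begin(), ns.end());
      key[i].insert(key[i].end(), ns.begin(), ns.end());
    }
    std::vector<int> nr(f.n);
    int k = denseRank(key, nr);
    ranks = nr;
    if (k == ncls) break;
    ncls = k;
  }
  return ncls;
}

std::string digitStr(int d) {
  if (d < 10) return std::to_string(d);
  if (d < 100) return "%" + std::to_string(d);
  stop("fragment has too many ring closures");
  return "";
}

struct Writer {
  const Frag& f;
  const std::vector<int>& ranks;
  std::vector<char> visited;
  std::vector<char> bused;
  std::vector<std::vector<std::pair<int, std::string>>> closures;
  std::vector<std::vector<std::pair<int, int>>> children;  // (child, code)
  int digit;

  Writer(const Frag& frag, const std::vector<int>& rk)
      : f(frag), ranks(rk), visited(frag.n, 0), bused(frag.nbonds, 0),
        closures(frag.n), children(frag.n), digit(0) {}

  void dfs(int u) {
    visited[u] = 1;
    std::vector<AdjEntry> nb = f.adj[u];
    std::sort(nb.begin(), nb.end(), [&](const AdjEntry& a, const AdjEntry& b) {
      return ranks[a.nbr] < ranks[b.nbr];
    });
    for (const auto& e : nb) {
      if (bused[e.bid]) continue;
      bused[e.bid] = 1;
      if (visited[e.nbr]) {
        ++digit;
        // earlier-visited endpoint opens the ring closure, carries bond symbol
        closures[e.nbr].push_back(
            {digit, bondChar(e.code, f.arom[e.nbr], f.arom[u])});
        closures[u].push_back({digit, ""});
      } else {
        children[u].push_back({e.nbr, e.code});
        dfs(e.nbr);
      }
    }
  }

  std::string out(int u) {
    std::string s = f.token[u];
    for (const auto& c : closures[u]) s += c.second + digitStr(c.first);
    const auto& ch = children[u];
    for (size_t k = 0; k < ch.size(); ++k) {
      std::string bc = bondChar(ch[k].second, f.arom[u], f.arom[ch[k].first]);
      std::string sub = bc + out(ch[k].first);
      if (k + 1 < ch.size())
        s += "(" + sub + ")";
      else
        s += sub;
    }
    return s;
  }
};

std::string writeCanon(const Frag& f, const std::vector<int>& ranks, int root) {
  Writer w(f, ranks);
  w.dfs(root);
  return w.out(root);
}

std::string canonRec(const Frag& f, std::vector<int> ranks, int root) {
  int ncls = refine(f, ranks);
  if (ncls == f.n) return writeCanon(f, ranks, root);
  std::vector<int> cnt(ncls, 0);
  for (int r : ranks) cnt[r]++;
  int c = 0;
  while (cnt[c] < 2) ++c;
  std::string best;
  bool have = false;
  for (int i = 0; i < f.n; ++i) {
    if (ranks[i] != c) continue;
    std::vector<int> r2(f.n);
    for (int j = 0; j < f.n; ++j)
      r2[j] = ranks[j] * 2 + ((ranks[j] == c && j != i) ? 1 : 0);
    std::string s = canonRec(f, r2, root);
    if (!have || s < best) {
      best = s;
      have = true;
    }
  }
  return best;
}

// Molecule arrays coming from R (0-based after conversion).
struct MolView {
  int n;
  std::vector<std::string> sym;
  const int *elem, *arom, *charge, *isotope, *hexp;
  std::vector<int> ba, bb, bcode;
  std::vector<std::vector<AdjEntry>> adj;
};

MolView makeMol(const CharacterVector& sym, const IntegerVector& elem,
                const IntegerVector& arom, const IntegerVector& charge,
                const IntegerVector& isotope, const IntegerVector& hexp,
                const IntegerVector& bondA, const IntegerVector& bondB,
                const IntegerVector& border, const IntegerVector& barom) {
  MolView m;
  m.n = sym.size();
  m.sym.reserve(m.n);
  for (int i = 0; i < m.n; ++i) m.sym.push_back(as<std::string>(sym[i]));
  m.elem = INTEGER(elem);
  m.arom = INTEGER(arom);
  m.charge = INTEGER(charge);
  m.isotope = INTEGER(isotope);
  m.hexp = INTEGER(hexp);
  int nb = bondA.size();
  m.ba.resize(nb);
  m.bb.resize(nb);
  m.bcode.resize(nb);
  m.adj.assign(m.n, {});
  for (int b = 0; b < nb; ++b) {
    int u = bondA[b] - 1, v = bondB[b] - 1;
    if (u < 0 || u >= m.n || v < 0 || v >= m.n)
      stop("bond endpoint out of range");
    int code = barom[b] ? 4 : border[b];
    m.ba[b] = u;
    m.bb[b] = v;
    m.bcode[b] = code;
    m.adj[u].push_back({v, code, b});
    m.adj[v].push_back({u, code, b});
  }
  return m;
}

// Build a fragment from a molecule given atom subset and bond subset.
Frag buildFrag(const MolView& m, const std::vector<int>& atoms,
               const std::vector<int>& bonds) {
  Frag f;
  f.n = (int) atoms.size();
  std::unordered_map<int, int> loc;
  loc.reserve(atoms.size() * 2);
  for (int i = 0; i < f.n; ++i) loc[atoms[i]] = i;
  f.token.resize(f.n);
  f.arom.resize(f.n);
  f.inv.resize(f.n);
  f.adj.assign(f.n, {});
  f.nbonds = (int) bonds.size();
  std::vector<int> deg(f.n, 0);
  for (size_t k = 0; k < bonds.size(); ++k) {
    int b = bonds[k];
    int u = loc.at(m.ba[b]), v = loc.at(m.bb[b]);
    f.adj[u].push_back({v, m.bcode[b], (int) k});
    f.adj[v].push_back({u, m.bcode[b], (int) k});
    deg[u]++;
    deg[v]++;
  }
  for (int i = 0; i < f.n; ++i) {
    int a = atoms[i];
    f.token[i] = atomToken(m.sym[a], m.arom[a] != 0, m.charge[a], m.isotope[a],
                           m.hexp[a]);
    f.arom[i] = (char) (m.arom[a] != 0);
    f.inv[i] = packInvariant(m.elem[a], m.arom[a], m.charge[a], m.isotope[a],
                             m.hexp[a], deg[i]);
  }
  return f;
}

std::string canonicalFrag(const Frag& f, int root) {
  std::vector<std::vector<long long>> key(f.n);
  for (int i = 0; i < f.n; ++i) {
    key[i].push_back(i == root ? 0 : 1);
    key[i].push_back(f.inv[i]);
  }
  std::vector<int> ranks(f.n);
  denseRank(key, ranks);
  return canonRec(f, ranks, root);
}

}  // namespace

// [[Rcpp::export]]
List cpp_extract_shingles(CharacterVector sym, IntegerVector elem,
                          IntegerVector arom, IntegerVector charge,
                          IntegerVector isotope, IntegerVector hexp,
                          IntegerVector bondA, IntegerVector bondB,
                          IntegerVector border, IntegerVector barom,
                          int minRadius, int maxRadius) {
  if (minRadius < 1 || minRadius > maxRadius)
    stop("require 1 <= minRadius <= maxRadius");
  MolView m = makeMol(sym, elem, arom, charge, isotope, hexp, bondA, bondB,
                      border, barom);
  std::vector<std::string> texts;
  std::vector<int> radii;
  std::unordered_set<std::string> seen;
  std::vector<int> dist(m.n);
  std::vector<int> queue(m.n);
  for (int a = 0; a < m.n; ++a) {
    std::fill(dist.begin(), dist.end(), -1);
    int qh = 0, qt = 0;
    dist[a] = 0;
    queue[qt++] = a;
    int maxd = 0;
    while (qh < qt) {
      int u = queue[qh++];
      for (const auto& e : m.adj[u]) {
        if (dist[e.nbr] < 0) {
          dist[e.nbr] = dist[u] + 1;
          if (dist[e.nbr] > maxd) maxd = dist[e.nbr];
          queue[qt++] = e.nbr;
        }
      }
    }
    int rmax = std::min(maxRadius, maxd);
    for (int r = minRadius; r <= rmax; ++r) {
      std::vector<int> bonds;
      std::vector<int> atoms;
      std::vector<char> inball(m.n, 0);
      for (size_t b = 0; b < m.ba.size(); ++b) {
        int du = dist[m.ba[b]], dv = dist[m.bb[b]];
        if (du < 0 || dv < 0) continue;
        if (std::min(du, dv) <= r - 1) {
          bonds.push_back((int) b);
          inball[m.ba[b]] = 1;
          inball[m.bb[b]] = 1;
        }
      }
      inball[a] = 1;
      for (int i = 0; i < m.n; ++i)
        if (inball[i]) atoms.push_back(i);
      Frag f = buildFrag(m, atoms, bonds);
      int rootLocal = 0;
      for (size_t i = 0; i < atoms.size(); ++i)
        if (atoms[i] == a) rootLocal = (int) i;
      std::string s = canonicalFrag(f, rootLocal);
      if (seen.insert(s).second) {
        texts.push_back(s);
        radii.push_back(r);
      }
    }
  }
  return List::create(_["text"] = wrap(texts), _["radius"] = wrap(radii));
}

// [[Rcpp::export]]
std::string cpp_canonical_fragment(CharacterVector sym, IntegerVector elem,
                                   IntegerVector arom, IntegerVector charge,
                                   IntegerVector isotope, IntegerVector hexp,
                                   IntegerVector bondA, IntegerVector bondB,
                                   IntegerVector border, IntegerVector barom,
                                   IntegerVector atomIds, int rootId,
                                   IntegerVector bondIds) {
  MolView m = makeMol(sym, elem, arom, charge, isotope, hexp, bondA, bondB,
                      border, barom);
  std::vector<char> in(m.n, 0);
  std::vector<int> atoms;
  for (int k = 0; k < atomIds.size(); ++k) {
    int a = atomIds[k] - 1;
    if (a < 0 || a >= m.n) stop("atom id out of range");
    if (!in[a]) {
      in[a] = 1;
      atoms.push_back(a);
    }
  }
  std::sort(atoms.begin(), atoms.end());
  std::vector<int> bonds;
  if (bondIds.size() > 0) {
    // explicit bond subset (a ball need not contain every bond its atom set
    // induces: the closing bond of an odd ring joins only at larger radius)
    for (int k = 0; k < bondIds.size(); ++k) {
      int b = bondIds[k] - 1;
      if (b < 0 || b >= (int) m.ba.size()) stop("bond id out of range");
      if (!in[m.ba[b]] || !in[m.bb[b]])
        stop("bond endpoint outside the fragment atom set");
      bonds.push_back(b);
    }
    std::sort(bonds.begin(), bonds.end());
    bonds.erase(std::unique(bonds.begin(), bonds.end()), bonds.end());
  } else {
    for (size_t b = 0; b < m.ba.size(); ++b)
      if (in[m.ba[b]] && in[m.bb[b]]) bonds.push_back((int) b);
  }
  int root = rootId - 1;
  if (root < 0 || root >= m.n || !in[root])
    stop("root atom must belong to the fragment");
  Frag f = buildFrag(m, atoms, bonds);
  int rootLocal = 0;
  for (size_t i = 0; i < atoms.size(); ++i)
    if (atoms[i] == root) rootLocal = (int) i;
  // fragment must be connected from the root
  std::vector<char> seen(f.n, 0);
  std::vector<int> st;
  st.push_back(rootLocal);
  seen[rootLocal] = 1;
  int nseen = 1;
  while (!st.empty()) {
    int u = st.back();
    st.pop_back();
    for (const auto& e : f.adj[u])
      if (!seen[e.nbr]) {
        seen[e.nbr] = 1;
        ++nseen;
        st.push_back(e.nbr);
      }
  }
  if (nseen != f.n) stop("fragment is not connected from the root atom");
  return canonicalFrag(f, rootLocal);
}

// [[Rcpp::export]]
IntegerVector cpp_symmetry_classes(CharacterVector sym, IntegerVector elem,
                                   IntegerVector arom, IntegerVector charge,
                                   IntegerVector isotope, IntegerVector hexp,
                                   IntegerVector bondA, IntegerVector bondB,
                                   IntegerVector border, IntegerVector barom) {
  MolView m = makeMol(sym, elem, arom, charge, isotope, hexp, bondA, bondB,
                      border, barom);
  std::vector<int> allAtoms(m.n), allBonds(m.ba.size());
  for (int i = 0; i < m.n; ++i) allAtoms[i] = i;
  for (size_t b = 0; b < m.ba.size(); ++b) allBonds[b] = (int) b;
  Frag f = buildFrag(m, allAtoms, allBonds);
  std::vector<std::vector<long long>> key(f.n);
  for (int i = 0; i < f.n; ++i) key[i].push_back(f.inv[i]);
  std::vector<int> ranks(f.n);
  denseRank(key, ranks);
  refine(f, ranks);
  IntegerVector out(f.n);
  for (int i = 0; i < f.n; ++i) out[i] = ranks[i] + 1;
  return out;
}
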