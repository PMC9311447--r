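// Compiled kernels for the two hot loops: paired-end overlap merging and
// seed-and-extend placement of encoded reads on the converted reference.

#include <Rcpp.h>
#include <unordered_map>
#include <climits>
using namespace Rcpp;

// Best overlap merge of r1 against rc(r2). The alignment offset o places
// rc(r2)[j] under r1[j + o]. Read-through bases extending past the other
// mate's fragment end are excluded from the merge; pairs without an
// acceptable overlap are joined with an 8-N spacer. On mismatch columns the
// higher-quality base wins (r1 on ties).
// [[Rcpp::export]]
CharacterVector merge_pairs_cpp(CharacterVector r1, CharacterVector rcr2,
                                CharacterVector q1, CharacterVector rq2,
                                int min_overlap, double max_mismatch_frac) {
  int n = r1.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(r1[i]);
    std::string b = as<std::string>(rcr2[i]);
    std::string qa = as<std::string>(q1[i]);
    std::string qb = as<std::string>(rq2[i]);
    int l1 = a.size(), l2 = b.size();
    int best_o = 0;
    long best_score = LONG_MIN;
    bool found = false;
    for (int o = -(l2 - min_overlap); o <= l1 - min_overlap; ++o) {
      int j1 = std::max(1, 1 - o), j2 = std::min(l2, l1 - o);
      int ov = j2 - j1 + 1;
      if (ov < min_overlap) continue;
      int allowed = (int)std::floor(max_mismatch_frac * ov);
      int mism = 0;
      bool fail = false;
      for (int j = j1; j <= j2; ++j) {
        if (a[j + o - 1] != b[j - 1] && ++mism > allowed) { fail = true; break; }
      }
      if (fail) continue;
      long score = (long)ov - 2L * mism;
      if (score > best_score) { best_score = score; best_o = o; found = true; }
    }
    if (!found) {
      out[i] = a + "NNNNNNNN" + b;
      continue;
    }
    int o = best_o;
    int j1 = std::max(1, 1 - o), j2 = std::min(l2, l1 - o);
    std::string cons = b.substr(j1 - 1, j2 - j1 + 1);
    for (int j = j1; j <= j2; ++j) {
      char ca = a[j + o - 1];
      if (ca != cons[j - j1] && qa[j + o - 1] >= qb[j - 1])
        cons[j - j1] = ca;
    }
    std::string merged;
    if (o > 0) merged = a.substr(0, o);
    merged += cons;
    if (l2 > l1 - o) merged += b.substr(l1 - o);
    out[i] = merged;
  }
  return out;
}

static inline long placement_score(const std::string &eread,
                                   const std::string &ref, int start0) {
  // start0: 0-based placement of read base 0 on ref; bases hanging over the
  // reference ends are clipped (score 0); reference N columns are neutral
  int L = eread.size(), R = ref.size();
  int s0 = std::max(0, start0);
  int e0 = std::min(start0 + L - 1, R - 1);
  if (e0 < s0) return LONG_MIN;
  long sc = 0;
  for (int p = s0; p <= e0; ++p) {
    char rc = ref[p];
    if (rc == 'N') continue;
    sc += (rc == eread[p - start0]) ? 1 : -1;
  }
  return sc;
}

typedef std::unordered_map<std::string, std::vector<std::pair<int, int> > >
    KmerIndex;

static void seed_read(const std::string &e, const KmerIndex &idx, int k,
                      std::vector<std::pair<int, int> > &cand) {
  cand.clear();
  int L = e.size();
  if (L < k) return;
  for (int off = 0; off <= L - k; off += 7) {
    KmerIndex::const_iterator it = idx.find(e.substr(off, k));
    if (it != idx.end()) {
      for (size_t j = 0; j < it->second.size(); ++j)
        cand.push_back(std::make_pair(it->second[j].first,
                                      it->second[j].second - off));
      return;
    }
    if (off + 7 > L - k && off != L - k) {
      // final seed flush at the read end
      it = idx.find(e.substr(L - k, k));
      if (it != idx.end()) {
        for (size_t j = 0; j < it->second.size(); ++j)
          cand.push_back(std::make_pair(it->second[j].first,
                                        it->second[j].second - (L - k)));
      }
      return;
    }
  }
}

// Place encoded mate pairs on one converted reference set. For every pair,
// candidate placements are seeded by exact k-mers and scored by ungapped
// extension; both mates must land on the same reference. Returns one row
// per pair: ref index (1-based, 0 = none), start1, start2 (1-based,
// unclipped), per-mate scores, joint score, and a tie flag for equal best
// joint scores at distinct placements.
// [[Rcpp::export]]
IntegerMatrix align_orientation_cpp(CharacterVector e1, CharacterVector e2,
                                    CharacterVector conv_ref, int k) {
  int nref = conv_ref.size();
  std::vector<std::string> refs(nref);
  KmerIndex idx;
  for (int i = 0; i < nref; ++i) {
    refs[i] = as<std::string>(conv_ref[i]);
    const std::string &s = refs[i];
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      std::string km = s.substr(p, k);
      if (km.find('N') != std::string::npos) continue;
      idx[km].push_back(std::make_pair(i, p));
    }
  }
  int n = e1.size();
  IntegerMatrix out(n, 6);
  std::vector<std::pair<int, int> > c1, c2;
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(e1[i]);
    std::string b = as<std::string>(e2[i]);
    seed_read(a, idx, k, c1);
    seed_read(b, idx, k, c2);
    long best = LONG_MIN, bs1 = 0, bs2 = 0;
    int bcl = -1, bp1 = 0, bp2 = 0, tie = 0;
    for (size_t x = 0; x < c1.size(); ++x) {
      for (size_t y = 0; y < c2.size(); ++y) {
        if (c1[x].first != c2[y].first) continue;
        int cl = c1[x].first;
        long s1 = placement_score(a, refs[cl], c1[x].second);
        if (s1 == LONG_MIN) continue;
        long s2 = placement_score(b, refs[cl], c2[y].second);
        if (s2 == LONG_MIN) continue;
        long sc = s1 + s2;
        if (sc > best) {
          best = sc; bcl = cl; bp1 = c1[x].second; bp2 = c2[y].second;
          bs1 = s1; bs2 = s2; tie = 0;
        } else if (sc == best &&
                   (cl != bcl || c1[x].second != bp1 || c2[y].second != bp2)) {
          tie = 1;
        }
      }
    }
    if (bcl >= 0) {
      out(i, 0) = bcl + 1;
      out(i, 1) = bp1 + 1;
      out(i, 2) = bp2 + 1;
      out(i, 3) = (int)bs1;
      out(i, 4) = (int)bs2;
      out(i, 5) = tie;
    }
  }
  return out;
}

// Global (Needleman-Wunsch) alignment identity of two sequences:
// matches / alignment columns, N never matching. Match +1, mismatch -1,
// gap -2 scoring steers the traceback; only the identity is returned.
// [[Rcpp::export]]
double global_identity_cpp(std::string a, std::string b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<std::vector<int> > S(n + 1, std::vector<int>(m + 1));
  const int GAP = -2, MATCH = 1, MISM = -1;
  for (int i = 0; i <= n; ++i) S[i][0] = i * GAP;
  for (int j = 0; j <= m; ++j) S[0][j] = j * GAP;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      int d = S[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? MATCH : MISM);
      int u = S[i - 1][j] + GAP;
      int l = S[i][j - 1] + GAP;
      S[i][j] = std::max(d, std::max(u, l));
    }
  // traceback counting matches and columns
  int i = n, j = m;
  long matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i][j] == S[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? MATCH : MISM)) {
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches;
      --i; --j;
    } else if (i > 0 && S[i][j] == S[i - 1][j] + GAP) {
      --i;
    } else {
      --j;
    }
    ++cols;
  }
  return (double)matches / (double)cols;
}
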