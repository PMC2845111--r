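// Maximal identical repeat pair detection (direct and inverted, intra- and
// interchromosomal) by seeded rolling-hash with leftmost-seed extension.
//
// Definition implemented: a pair of equal-length intervals X, Y (distinct as
// coordinate tuples) with seq(X) == seq(Y) (direct) or seq(X) == revcomp(seq(Y))
// (inverted), such that no orientation-consistent one-base extension of both
// members preserves identity within eligible (A/C/G/T, unmasked) sequence.
// Direct matches are maximal runs along diagonals of the self-comparison;
// inverted matches are maximal runs along anti-diagonals. A symmetric
// anti-diagonal run (a reverse-complement palindrome matching itself, X == Y)
// is a self-pair and is excluded.
//
// Input sequences must be uppercase; any character outside {A,C,G,T} is
// ineligible and can neither start, extend, nor be contained in a match
// (callers mask excluded regions with a non-ACGT sentinel).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <set>
#include <array>
#include <string>
#include <cstring>

using namespace Rcpp;

typedef unsigned long long u64;
static const u64 HB = 1099511628211ULL; // FNV prime as polynomial base

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}
static inline char compl_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'T': return 'A';
    case 'C': return 'G';
    case 'G': return 'C';
  }
  return '\0';
}
static inline u64 code(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 3; case 'T': return 4;
  }
  return 0;
}

// one emitted pair: {c1, s1, e1, c2, s2, e2, inverted}; 0-based half-open
typedef std::array<int, 7> PairRec;

static inline PairRec make_rec(int c1, int s1, int e1, int c2, int s2, int e2,
                               bool inverted) {
  // canonical order: member with smaller (chrom, start, end) first
  if (std::make_tuple(c1, s1, e1) > std::make_tuple(c2, s2, e2)) {
    std::swap(c1, c2); std::swap(s1, s2); std::swap(e1, e2);
  }
  return PairRec{c1, s1, e1, c2, s2, e2, inverted ? 1 : 0};
}

// [[Rcpp::export(name = ".find_pairs_cpp")]]
DataFrame find_pairs_cpp(CharacterVector seqs, int min_len) {
  const int nchrom = seqs.size();
  std::vector<std::string> S(nchrom);
  for (int c = 0; c < nchrom; ++c) S[c] = as<std::string>(seqs[c]);
  const int k = min_len;

  // eligible window flags and rolling hashes per chromosome
  // win_ok[c][p]: window [p, p+k) all ACGT
  std::vector<std::vector<char>> win_ok(nchrom);
  std::vector<std::vector<u64>> fh(nchrom);   // forward hash of window
  std::vector<std::vector<u64>> rch(nchrom);  // hash of revcomp(window)

  u64 Bk = 1; // HB^(k-1)
  for (int i = 1; i < k; ++i) Bk *= HB;

  for (int c = 0; c < nchrom; ++c) {
    const std::string &s = S[c];
    const int n = (int)s.size();
    const int nw = n - k + 1;
    if (nw <= 0) continue;
    win_ok[c].assign(nw, 0);
    fh[c].assign(nw, 0);
    rch[c].assign(nw, 0);
    // run-length of ACGT ending at each position -> window eligibility
    int run = 0;
    std::vector<int> acgt_run(n, 0);
    for (int i = 0; i < n; ++i) {
      run = is_acgt(s[i]) ? run + 1 : 0;
      acgt_run[i] = run;
    }
    // forward rolling hash
    u64 h = 0;
    for (int i = 0; i < k; ++i) h = h * HB + code(s[i]);
    fh[c][0] = h;
    for (int p = 1; p < nw; ++p) {
      h = (h - code(s[p - 1]) * Bk) * HB + code(s[p + k - 1]);
      fh[c][p] = h;
    }
    // revcomp-window hash: rolling over revcomp of the whole chromosome.
    // rc window at p equals T[n-k-p .. n-p) where T = revcomp(s).
    {
      std::string T(n, 'N');
      for (int i = 0; i < n; ++i) {
        char b = compl_base(s[n - 1 - i]);
        T[i] = b ? b : 'N';
      }
      u64 th = 0;
      for (int i = 0; i < k; ++i) th = th * HB + code(T[i]);
      std::vector<u64> thv(nw, 0);
      thv[0] = th;
      for (int p = 1; p < nw; ++p) {
        th = (th - code(T[p - 1]) * Bk) * HB + code(T[p + k - 1]);
        thv[p] = th;
      }
      for (int p = 0; p < nw; ++p) rch[c][p] = thv[n - k - p];
    }
    for (int p = 0; p < nw; ++p)
      win_ok[c][p] = (acgt_run[p + k - 1] >= k) ? 1 : 0;
  }

  // bucket eligible windows by forward hash, in (chrom, pos) scan order
  std::unordered_map<u64, std::vector<std::pair<int, int>>> buckets;
  for (int c = 0; c < nchrom; ++c)
    for (int p = 0; p < (int)win_ok[c].size(); ++p)
      if (win_ok[c][p]) buckets[fh[c][p]].push_back(std::make_pair(c, p));

  std::set<PairRec> out;

  // ---- direct matches ----
  for (auto &kv : buckets) {
    std::vector<std::pair<int, int>> &v = kv.second;
    const size_t m = v.size();
    if (m < 2) continue;
    for (size_t a = 0; a + 1 < m; ++a) {
      for (size_t b = a + 1; b < m; ++b) {
        int c1 = v[a].first, p1 = v[a].second;
        int c2 = v[b].first, p2 = v[b].second;
        const std::string &s1 = S[c1], &s2 = S[c2];
        // leftmost-seed rule: if both seeds can shift one base left while the
        // preceding bases match, the extension is covered by that seed
        if (p1 > 0 && p2 > 0) {
          char x = s1[p1 - 1], y = s2[p2 - 1];
          if (x == y && is_acgt(x)) continue;
        }
        // verify seed (guards against hash collisions)
        if (std::memcmp(s1.data() + p1, s2.data() + p2, k) != 0) continue;
        // extend right
        int e1 = p1 + k, e2 = p2 + k;
        const int n1 = (int)s1.size(), n2 = (int)s2.size();
        while (e1 < n1 && e2 < n2) {
          char x = s1[e1], y = s2[e2];
          if (x != y || !is_acgt(x)) break;
          ++e1; ++e2;
        }
        out.insert(make_rec(c1, p1, e1, c2, p2, e2, false));
      }
    }
  }

  // ---- inverted matches ----
  // seed: window X0 = [i, i+k) on c1 and Y0 = [j, j+k) on c2 with
  // S1[i+t] == comp(S2[j+k-1-t]); found via fh[c1][i] == rch[c2][j].
  for (int c2 = 0; c2 < nchrom; ++c2) {
    for (int j = 0; j < (int)win_ok[c2].size(); ++j) {
      if (!win_ok[c2][j]) continue;
      auto it = buckets.find(rch[c2][j]);
      if (it == buckets.end()) continue;
      const std::string &s2 = S[c2];
      const int n2 = (int)s2.size();
      for (auto &cand : it->second) {
        int c1 = cand.first, i = cand.second;
        const std::string &s1 = S[c1];
        const int n1 = (int)s1.size();
        // leftmost-seed rule along the anti-diagonal: growing X left pairs
        // with growing Y right
        if (i > 0 && j + k < n2) {
          char x = s1[i - 1], y = s2[j + k];
          if (is_acgt(x) && x == compl_base(y)) continue;
        }
        // verify seed
        bool ok = true;
        for (int t = 0; t < k; ++t) {
          char x = s1[i + t], y = s2[j + k - 1 - t];
          if (!is_acgt(x) || x != compl_base(y)) { ok = false; break; }
        }
        if (!ok) continue;
        // extend: X right pairs with Y left
        int x2 = i + k, y1 = j;
        while (x2 < n1 && y1 > 0) {
          char x = s1[x2], y = s2[y1 - 1];
          if (!is_acgt(x) || x != compl_base(y)) break;
          ++x2; --y1;
        }
        int x1 = i, y2 = j + k; // X left already maximal by leftmost-seed rule,
        // except when the seed sits at a boundary: re-extend to be safe
        while (x1 > 0 && y2 < n2) {
          char x = s1[x1 - 1], y = s2[y2];
          if (!is_acgt(x) || x != compl_base(y)) break;
          --x1; ++y2;
        }
        if (c1 == c2 && x1 == y1 && x2 == y2) continue; // palindromic self-pair
        out.insert(make_rec(c1, x1, x2, c2, y1, y2, true));
      }
    }
  }

  const int np = (int)out.size();
  IntegerVector C1(np), St1(np), E1(np), C2(np), St2(np), E2(np), Len(np);
  LogicalVector Inv(np);
  int r = 0;
  for (const PairRec &pr : out) {
    C1[r] = pr[0] + 1; St1[r] = pr[1]; E1[r] = pr[2];
    C2[r] = pr[3] + 1; St2[r] = pr[4]; E2[r] = pr[5];
    Len[r] = pr[2] - pr[1];
    Inv[r] = pr[6] == 1;
    ++r;
  }
  return DataFrame::create(
    _["chrom1"] = C1, _["start1"] = St1, _["end1"] = E1,
    _["chrom2"] = C2, _["start2"] = St2, _["end2"] = E2,
    _["length"] = Len, _["inverted"] = Inv);
}
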