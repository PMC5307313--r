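#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Best-overlap merge of mate1 with the reverse-complemented mate2.
// s2rc/q2rc must already be reverse-complemented / reversed by the caller.
// Score of a candidate offset = matches - mismatches over the overlap; the
// best offset maximizes the score, ties broken toward the larger overlap,
// then the leftmost offset (order-independent rule).  The reported score is
// floored at zero.  Consensus at a disagreement takes the base with the
// higher quality (mate1 wins exact quality ties).
static inline int overlap_len(int d, int L1, int L2) {
  return std::min(L1, d + L2) - std::max(0, d);
}

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector s1, CharacterVector q1,
                     CharacterVector s2rc, CharacterVector q2rc,
                     int min_overlap = 10) {
  int n = s1.size();
  CharacterVector out_seq(n);
  IntegerVector out_score(n);
  for (int r = 0; r < n; ++r) {
    std::string a = as<std::string>(s1[r]);
    std::string qa = as<std::string>(q1[r]);
    std::string b = as<std::string>(s2rc[r]);
    std::string qb = as<std::string>(q2rc[r]);
    int L1 = a.size(), L2 = b.size();
    if (L1 < min_overlap || L2 < min_overlap) {
      out_seq[r] = a;
      out_score[r] = 0;
      continue;
    }
    int dmin = -(L2 - min_overlap), dmax = L1 - min_overlap;
    int best_score = INT_MIN, best_d = 0, best_ov = -1;
    // scoring of one offset with branch-and-bound against the current best
    auto eval = [&](int d) {
      int lo = std::max(0, d), hi = std::min(L1, d + L2);
      int ov = hi - lo;
      if (ov < min_overlap || ov < best_score) return;  // cannot reach best
      int score = 0;
      for (int i = lo; i < hi; ++i) {
        score += (a[i] == b[i - d]) ? 1 : -1;
        if (score + (hi - 1 - i) < best_score) return;   // early abandon
      }
      bool better = score > best_score ||
        (score == best_score && (ov > best_ov ||
                                 (ov == best_ov && d < best_d)));
      if (better) { best_score = score; best_d = d; best_ov = ov; }
    };
    // seed heuristic: exact hits of the start of b inside a suggest the
    // true offset; evaluating them first makes the bound prune the rest
    int k = 16;
    if (L2 >= k) {
      for (int d = 0; d <= L1 - k; ++d) {
        if (a.compare(d, k, b, 0, k) == 0) eval(d);
      }
    }
    for (int d = dmin; d <= dmax; ++d) eval(d);
    int d = best_d;
    int lo = std::min(0, d), hi = std::max(L1, d + L2);
    std::string m;
    m.reserve(hi - lo);
    for (int p = lo; p < hi; ++p) {
      bool in1 = (p >= 0 && p < L1);
      bool in2 = (p >= d && p < d + L2);
      if (in1 && in2) {
        char c1 = a[p], c2 = b[p - d];
        if (c1 == c2) m.push_back(c1);
        else m.push_back(qa[p] >= qb[p - d] ? c1 : c2);
      } else if (in1) {
        m.push_back(a[p]);
      } else {
        m.push_back(b[p - d]);
      }
    }
    out_seq[r] = m;
    out_score[r] = best_score > 0 ? best_score : 0;
  }
  return List::create(_["sequence"] = out_seq, _["score"] = out_score);
}

// Global alignment identity: maximize matches (match +1, mismatch 0, gaps
// free), breaking ties by the minimum number of alignment columns, so
// substitutions are preferred over paired indels.  identity = matches /
// alignment columns; symmetric and deterministic.
static void identity_dp(const std::string &a, const std::string &b,
                        int &matches, int &columns) {
  int n = a.size(), m = b.size();
  std::vector<int> M(m + 1), C(m + 1), Mp(m + 1), Cp(m + 1);
  for (int j = 0; j <= m; ++j) { Mp[j] = 0; Cp[j] = j; }
  for (int i = 1; i <= n; ++i) {
    M[0] = 0; C[0] = i;
    for (int j = 1; j <= m; ++j) {
      int dM = Mp[j - 1] + (a[i - 1] == b[j - 1] ? 1 : 0), dC = Cp[j - 1] + 1;
      int uM = Mp[j], uC = Cp[j] + 1;
      int lM = M[j - 1], lC = C[j - 1] + 1;
      int bestM = dM, bestC = dC;
      if (uM > bestM || (uM == bestM && uC < bestC)) { bestM = uM; bestC = uC; }
      if (lM > bestM || (lM == bestM && lC < bestC)) { bestM = lM; bestC = lC; }
      M[j] = bestM; C[j] = bestC;
    }
    std::swap(M, Mp); std::swap(C, Cp);
  }
  matches = Mp[m];
  columns = Cp[m];
}

// [[Rcpp::export]]
double cpp_identity(std::string a, std::string b) {
  if (a.empty() || b.empty()) stop("sequences must be nonempty");
  int matches, columns;
  identity_dp(a, b, matches, columns);
  return (double)matches / (double)columns;
}

// queries x refs identity matrix
// [[Rcpp::export]]
NumericMatrix cpp_identity_matrix(CharacterVector queries, CharacterVector refs) {
  int nq = queries.size(), nr = refs.size();
  NumericMatrix out(nq, nr);
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    if (q.empty()) stop("sequences must be nonempty");
    for (int j = 0; j < nr; ++j) {
      if (rs[j].empty()) stop("sequences must be nonempty");
      int matches, columns;
      identity_dp(q, rs[j], matches, columns);
      out(i, j) = (double)matches / (double)columns;
    }
  }
  return out;
}

// TRUE when a and b differ by exactly one substitution or one indel.
// [[Rcpp::export]]
bool cpp_one_diff(std::string a, std::string b) {
  int n = a.size(), m = b.size();
  if (n == m) {
    int diff = 0;
    for (int i = 0; i < n; ++i) if (a[i] != b[i] && ++diff > 1) return false;
    return diff == 1;
  }
  if (std::abs(n - m) != 1) return false;
  const std::string &s = (n < m) ? a : b;  // shorter
  const std::string &l = (n < m) ? b : a;  // longer
  size_t i = 0;
  while (i < s.size() && s[i] == l[i]) ++i;
  // skip one char of the longer string, rest must match
  return l.compare(i + 1, std::string::npos, s, i, std::string::npos) == 0;
}

// Uniform per-base substitution errors using R's RNG; returns the mutated
// sequences and 1-based error positions (needed for the two-level quality
// model).
// [[Rcpp::export]]
List cpp_add_errors(CharacterVector seqs, double rate) {
  RNGScope scope;
  int n = seqs.size();
  CharacterVector out(n);
  List pos(n);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::vector<int> p;
    if (rate > 0) {
      for (size_t i = 0; i < s.size(); ++i) {
        if (unif_rand() < rate) {
          char cur = s[i];
          char sub = cur;
          while (sub == cur) sub = bases[(int)(unif_rand() * 4) % 4];
          s[i] = sub;
          p.push_back((int)i + 1);
        }
      }
    }
    out[r] = s;
    pos[r] = wrap(p);
  }
  return List::create(_["sequence"] = out, _["positions"] = pos);
}

// Per-string mismatch count against a fixed-length pattern at offset 0.
// Strings shorter than the pattern get pattern-length mismatches.
// [[Rcpp::export]]
IntegerVector cpp_mismatch_count(CharacterVector x, std::string pattern) {
  int n = x.size(), L = pattern.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(x[r]);
    if ((int)s.size() < L) { out[r] = L; continue; }
    int mm = 0;
    for (int i = 0; i < L; ++i) if (s[i] != pattern[i]) ++mm;
    out[r] = mm;
  }
  return out;
}
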