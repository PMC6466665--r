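#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Best local alignment score of an encoded peptide against a PSSM under a
// dynamic programme that allows skipping profile columns or peptide residues
// at a flat per-position penalty. Scores are in bits; the empty alignment
// (score 0) is always admissible.
//
// pep:  0-based residue codes indexing rows of prof
// prof: scoring matrix, one column per profile position
// [[Rcpp::export(name = ".pssm_local_score")]]
double pssm_local_score(IntegerVector pep, NumericMatrix prof, double skip_pen) {
  int n = pep.size(), L = prof.ncol();
  if (n == 0 || L == 0) return 0.0;
  std::vector<double> prev(L + 1, 0.0), cur(L + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    int r = pep[i - 1];
    for (int j = 1; j <= L; ++j) {
      double v = prev[j - 1] + prof(r, j - 1);   // align residue to column
      double up = prev[j] - skip_pen;            // skip residue
      double left = cur[j - 1] - skip_pen;       // skip column
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0.0) v = 0.0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// Seeded ungapped diagonal extension of one encoded target sequence against a
// set of family profiles. Seeds are exact k-mers taken from family members,
// each anchored at a profile column; matches are extended left and right with
// X-drop termination. Returns 0-based half-open spans in target (fs,fe) and
// profile (ps,pe) coordinates.
//
// target:     residue codes; codes >= seed_alpha never participate in seeds
//             (ambiguity, stop, block-separator sentinels) but are scored via
//             their profile row during extension.
// profs:      list of scoring matrices (nrow covers every code in target)
// seeds:      k x nseed matrix of seed residue codes
// seed_fam:   1-based family index per seed
// seed_col:   0-based profile column of the seed start
// [[Rcpp::export(name = ".seed_extend_multi")]]
DataFrame seed_extend_multi(IntegerVector target, List profs,
                            IntegerMatrix seeds, IntegerVector seed_fam,
                            IntegerVector seed_col, int seed_alpha,
                            double xdrop, double min_score) {
  const int k = seeds.nrow(), ns = seeds.ncol(), n = target.size();
  const int nf = profs.size();
  std::vector<NumericMatrix> P;
  P.reserve(nf);
  for (int f = 0; f < nf; ++f) P.push_back(as<NumericMatrix>(profs[f]));

  std::unordered_multimap<long long, int> tab;
  tab.reserve(ns * 2 + 1);
  for (int s = 0; s < ns; ++s) {
    long long key = 0;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      int c = seeds(t, s);
      if (c < 0 || c >= seed_alpha) { ok = false; break; }
      key = key * seed_alpha + c;
    }
    if (ok) tab.insert({key, s});
  }

  // per (family, diagonal) rightmost target position already covered by an
  // extension, so repeated seeds inside one HSP are not re-extended
  std::unordered_map<long long, int> covered;

  std::vector<int> rfam, rfs, rfe, rps, rpe;
  std::vector<double> rsc;

  long long key = 0, mod = 1;
  for (int t = 0; t < k - 1; ++t) mod *= seed_alpha;
  int run = 0;

  for (int i = 0; i < n; ++i) {
    int c = target[i];
    if (c < 0 || c >= seed_alpha) { run = 0; key = 0; continue; }
    key = (key % mod) * seed_alpha + c;
    if (++run < k) continue;
    auto range = tab.equal_range(key);
    for (auto it = range.first; it != range.second; ++it) {
      const int s = it->second;
      const int f = seed_fam[s] - 1;
      const int j0 = seed_col[s];
      const int i0 = i - k + 1;
      NumericMatrix& prof = P[f];
      const int L = prof.ncol();
      if (j0 + k > L) continue;
      long long dkey = (long long)f * 4000000000LL + (i0 - j0 + 2000000000LL);
      auto cv = covered.find(dkey);
      if (cv != covered.end() && i0 < cv->second) continue;

      double s0 = 0.0;
      for (int t = 0; t < k; ++t) s0 += prof(target[i0 + t], j0 + t);

      double run_s = 0.0, best_r = 0.0;
      int ext_r = 0;
      for (int t = k; i0 + t < n && j0 + t < L; ++t) {
        run_s += prof(target[i0 + t], j0 + t);
        if (run_s > best_r) { best_r = run_s; ext_r = t - k + 1; }
        if (run_s < best_r - xdrop) break;
      }
      run_s = 0.0;
      double best_l = 0.0;
      int ext_l = 0;
      for (int t = 1; i0 - t >= 0 && j0 - t >= 0; ++t) {
        run_s += prof(target[i0 - t], j0 - t);
        if (run_s > best_l) { best_l = run_s; ext_l = t; }
        if (run_s < best_l - xdrop) break;
      }

      double sc = s0 + best_r + best_l;
      int fs = i0 - ext_l, fe = i0 + k + ext_r;
      covered[dkey] = fe;
      if (sc >= min_score) {
        rfam.push_back(f + 1);
        rfs.push_back(fs);
        rfe.push_back(fe);
        rps.push_back(j0 - ext_l);
        rpe.push_back(j0 + k + ext_r);
        rsc.push_back(sc);
      }
    }
  }
  return DataFrame::create(_["fam"] = rfam, _["fs"] = rfs, _["fe"] = rfe,
                           _["ps"] = rps, _["pe"] = rpe, _["score"] = rsc);
}

// Quadratic chaining DP over HSPs sorted by profile start. Coordinates are
// "transcript" coordinates (strand-flipped so chains always run left to
// right). Returns best predecessor (1-based, 0 = none) and cumulative score.
// [[Rcpp::export(name = ".chain_dp")]]
List chain_dp(NumericVector ps, NumericVector pe, NumericVector ts,
              NumericVector te, NumericVector score, double max_gap,
              double max_ov) {
  const int n = ps.size();
  NumericVector dp(n);
  IntegerVector pred(n);
  std::vector<double> percol(n);
  for (int i = 0; i < n; ++i) {
    dp[i] = score[i];
    pred[i] = 0;
    percol[i] = score[i] / std::max(1.0, pe[i] - ps[i]);
  }
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < j; ++i) {
      if (ps[i] >= ps[j] || pe[i] >= pe[j]) continue;
      double ov = pe[i] - ps[j];
      if (ov < 0.0) ov = 0.0;
      if (ov > max_ov) continue;
      double gap = ts[j] - te[i];
      if (gap < 0.0 || gap > max_gap) continue;
      double cand = dp[i] + score[j] - ov * std::min(percol[i], percol[j]);
      if (cand > dp[j] + 1e-9) { dp[j] = cand; pred[j] = i + 1; }
    }
  }
  return List::create(_["dp"] = dp, _["pred"] = pred);
}
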