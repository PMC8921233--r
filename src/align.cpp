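#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment with full traceback.
//
// mode 0: local (Smith-Waterman) — both sequences may be clipped.
// mode 1: query-global / subject-local — the whole query is consumed,
//         the subject contributes a local window (used by the homology
//         search, where identity must reflect full-length divergence).
//
// Gap cost for a k-long gap is gap_open + k * gap_ext (the convention of
// the classic affine formulation with the opening charge on the first
// gapped position).

static const double NEG_INF = -1e30;

struct AlnResult {
  double score;
  int q_start, q_end, s_start, s_end; // 1-based inclusive, 0 if empty
  std::string cigar;
  int n_match, n_mismatch, n_gap_open, n_gap_cols, aligned_cols;
};

static void push_op(std::string &cig, char op, int len) {
  cig += std::to_string(len);
  cig += op;
}

static AlnResult align_one(const std::string &q, const std::string &s,
                           double match, double mismatch,
                           double gap_open, double gap_ext, int mode) {
  const int m = (int)q.size(), n = (int)s.size();
  // H: best score ending at (i,j) with alignment of q[1..i], s[1..j]
  // E: ... ending in a gap in the subject (consumes query, op I)
  // F: ... ending in a gap in the query (consumes subject, op D)
  std::vector<double> Hprev(n + 1), Hcur(n + 1), Eprev(n + 1), Ecur(n + 1);
  std::vector<double> Fcur(n + 1);
  // traceback: 2 bits per matrix cell
  // tbH: 0 stop, 1 diag, 2 from E, 3 from F
  // tbE: 0 open (from H above), 1 extend;  tbF: 0 open (from H left), 1 extend
  std::vector<unsigned char> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbF((size_t)(m + 1) * (n + 1), 0);
  const size_t W = (size_t)(n + 1);

  double best = (mode == 0) ? 0.0 : NEG_INF;
  int best_i = 0, best_j = 0;

  for (int j = 0; j <= n; ++j) {
    Hprev[j] = 0.0;            // free subject prefix in both modes
    Eprev[j] = NEG_INF;
  }
  for (int i = 1; i <= m; ++i) {
    // j = 0 column
    if (mode == 0) {
      Hcur[0] = 0.0;
      Ecur[0] = NEG_INF;
    } else {
      // query must be consumed: leading query bases gap against nothing
      Ecur[0] = -(gap_open + i * gap_ext);
      Hcur[0] = Ecur[0];
      tbH[i * W + 0] = 2;
      tbE[i * W + 0] = (i > 1) ? 1 : 0;
    }
    Fcur[0] = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      // E: gap in subject (op I), consumes q[i]
      double e_open = Hprev[j] - (gap_open + gap_ext);
      double e_ext = Eprev[j] - gap_ext;
      if (e_open >= e_ext) { Ecur[j] = e_open; tbE[i * W + j] = 0; }
      else { Ecur[j] = e_ext; tbE[i * W + j] = 1; }
      // F: gap in query (op D), consumes s[j]
      double f_open = Hcur[j - 1] - (gap_open + gap_ext);
      double f_ext = Fcur[j - 1] - gap_ext;
      if (f_open >= f_ext) { Fcur[j] = f_open; tbF[i * W + j] = 0; }
      else { Fcur[j] = f_ext; tbF[i * W + j] = 1; }
      // H
      double sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + sub;
      double h = diag;
      unsigned char tb = 1;
      if (Ecur[j] > h) { h = Ecur[j]; tb = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; tb = 3; }
      if (mode == 0 && h <= 0.0) { h = 0.0; tb = 0; }
      Hcur[j] = h;
      tbH[i * W + j] = tb;
      if (mode == 0) {
        if (h > best) { best = h; best_i = i; best_j = j; }
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  if (mode == 1) {
    // best over the last query row (subject suffix is free)
    for (int j = 0; j <= n; ++j)
      if (Hprev[j] > best) { best = Hprev[j]; best_i = m; best_j = j; }
  }

  AlnResult r;
  r.score = best;
  r.n_match = r.n_mismatch = r.n_gap_open = r.n_gap_cols = 0;
  r.aligned_cols = 0;
  if (mode == 0 && best <= 0.0) { // empty alignment
    r.q_start = r.q_end = r.s_start = r.s_end = 0;
    r.cigar = "";
    return r;
  }

  // traceback (ops collected in reverse order)
  int i = best_i, j = best_j;
  int state = 0; // 0 = H, 1 = E, 2 = F
  std::string ops;
  while (i > 0) {
    if (state == 0) {
      unsigned char tb = tbH[i * W + j];
      if (tb == 0) break;                       // local alignment start
      if (tb == 1) { ops += (q[i - 1] == s[j - 1]) ? '=' : 'X'; --i; --j; }
      else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char tb = tbE[i * W + j];
      ops += 'I';
      --i;
      state = (tb == 1) ? 1 : 0;
    } else {
      unsigned char tb = tbF[i * W + j];
      ops += 'D';
      --j;
      state = (tb == 1) ? 2 : 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // a boundary D never improves the score; trim any tie artefact
  size_t b = 0, e = ops.size();
  while (b < e && ops[b] == 'D') ++b;
  size_t tail_D = 0;
  while (e > b && ops[e - 1] == 'D') { --e; ++tail_D; }
  std::string kept = ops.substr(b, e - b);

  r.q_start = i + 1;
  r.q_end = best_i;
  r.s_start = j + 1 + (int)b;
  r.s_end = best_j - (int)tail_D;

  // run-length encode and tally
  std::string cig;
  int run = 0; char cur = 0, prev = 0;
  for (char c : kept) {
    ++r.aligned_cols;
    if (c == '=') ++r.n_match;
    else if (c == 'X') ++r.n_mismatch;
    else {
      ++r.n_gap_cols;
      if (c != prev) ++r.n_gap_open;  // an I->D transition opens a new gap
    }
    prev = c;
    if (c == cur) { ++run; continue; }
    if (run) push_op(cig, cur, run);
    cur = c; run = 1;
  }
  if (run) push_op(cig, cur, run);
  r.cigar = cig;
  return r;
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(CharacterVector queries, std::string subject,
              double match, double mismatch,
              double gap_open, double gap_ext, int mode) {
  const int n = queries.size();
  NumericVector score(n);
  IntegerVector q_start(n), q_end(n), s_start(n), s_end(n),
      n_match(n), n_mismatch(n), n_gap_open(n), n_gap_cols(n),
      aligned_cols(n);
  CharacterVector cigar(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(queries[i]);
    AlnResult r = align_one(q, subject, match, mismatch, gap_open, gap_ext,
                            mode);
    score[i] = r.score;
    q_start[i] = r.q_start; q_end[i] = r.q_end;
    s_start[i] = r.s_start; s_end[i] = r.s_end;
    n_match[i] = r.n_match; n_mismatch[i] = r.n_mismatch;
    n_gap_open[i] = r.n_gap_open; n_gap_cols[i] = r.n_gap_cols;
    aligned_cols[i] = r.aligned_cols;
    cigar[i] = r.cigar;
  }
  return List::create(
      _["score"] = score, _["q_start"] = q_start, _["q_end"] = q_end,
      _["s_start"] = s_start, _["s_end"] = s_end, _["n_match"] = n_match,
      _["n_mismatch"] = n_mismatch, _["n_gap_open"] = n_gap_open,
      _["n_gap_cols"] = n_gap_cols, _["aligned_cols"] = aligned_cols,
      _["cigar"] = cigar);
}
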