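#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Affine-gap "fit" alignment: the read is aligned globally, the target window
// locally (unaligned window prefix/suffix is free). Gap of length L costs
// gap_open + L * gap_extend. Returns score, 0-based half-open target
// coordinates within the window, mismatch count and a CIGAR over {M,I,D}
// (I = insertion in the read relative to the target).
//
// Indels are left-shifted against the target after traceback so that
// equivalent placements produce identical site keys downstream.

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// [[Rcpp::export]]
List cpp_fit_align(std::string read, std::string window,
                   double match, double mismatch,
                   double gap_open, double gap_extend) {
  const int m = (int) read.size();
  const int n = (int) window.size();
  const double NEG = -1e18;
  // DP matrices: M aligned, I gap-in-target (read base consumed),
  // D gap-in-read (window base consumed).
  std::vector<double> Mm((m + 1) * (n + 1), NEG), Ii((m + 1) * (n + 1), NEG),
      Dd((m + 1) * (n + 1), NEG);
  std::vector<unsigned char> tbM((m + 1) * (n + 1), 0), tbI((m + 1) * (n + 1), 0),
      tbD((m + 1) * (n + 1), 0);
  #define IDX(i, j) ((i) * (n + 1) + (j))
  // Row 0: free leading window columns (state M with score 0 acts as "start").
  for (int j = 0; j <= n; ++j) Mm[IDX(0, j)] = 0.0;
  Ii[IDX(0, 0)] = NEG;
  for (int i = 1; i <= m; ++i) {
    // Read must be fully aligned: leading gap-in-target allowed (I state).
    Ii[IDX(i, 0)] = -(gap_open + i * gap_extend);
    tbI[IDX(i, 0)] = 1; // came from I
    for (int j = 1; j <= n; ++j) {
      const char rc = read[i - 1], wc = window[j - 1];
      const double s = (rc == wc && rc != 'N') ? match : mismatch;
      // M: diagonal from best of M/I/D at (i-1, j-1)
      double a = Mm[IDX(i - 1, j - 1)], b = Ii[IDX(i - 1, j - 1)],
             c = Dd[IDX(i - 1, j - 1)];
      double best = max3(a, b, c);
      Mm[IDX(i, j)] = best + s;
      tbM[IDX(i, j)] = (best == a) ? 0 : (best == b ? 1 : 2);
      // I: consume read base, gap in target
      double iM = Mm[IDX(i - 1, j)] - (gap_open + gap_extend);
      double iI = Ii[IDX(i - 1, j)] - gap_extend;
      if (iM >= iI) { Ii[IDX(i, j)] = iM; tbI[IDX(i, j)] = 0; }
      else          { Ii[IDX(i, j)] = iI; tbI[IDX(i, j)] = 1; }
      // D: consume window base, gap in read
      double dM = Mm[IDX(i, j - 1)] - (gap_open + gap_extend);
      double dD = Dd[IDX(i, j - 1)] - gap_extend;
      if (dM >= dD) { Dd[IDX(i, j)] = dM; tbD[IDX(i, j)] = 0; }
      else          { Dd[IDX(i, j)] = dD; tbD[IDX(i, j)] = 2; }
    }
  }
  // Termination: best over last read row, any window column, states M/I.
  double best = NEG; int bj = 0; int bstate = 0;
  for (int j = 0; j <= n; ++j) {
    if (Mm[IDX(m, j)] > best) { best = Mm[IDX(m, j)]; bj = j; bstate = 0; }
    if (Ii[IDX(m, j)] > best) { best = Ii[IDX(m, j)]; bj = j; bstate = 1; }
  }
  // Traceback
  std::string ops; ops.reserve(m + 16);
  int i = m, j = bj, st = bstate;
  while (i > 0) {
    if (st == 0) { // M
      if (j == 0) break;
      int prev = tbM[IDX(i, j)];
      ops.push_back('M');
      --i; --j; st = prev;
    } else if (st == 1) { // I
      int prev = tbI[IDX(i, j)];
      ops.push_back('I');
      --i; st = prev;
    } else { // D
      int prev = tbD[IDX(i, j)];
      ops.push_back('D');
      --j; st = prev;
    }
  }
  int tstart = j; // 0-based start in window
  std::reverse(ops.begin(), ops.end());
  // Left-align indel runs against the target.
  // A run of I (or D) preceded by M can shift left if the window/read base
  // content allows; do simple repeated single-step shifts.
  bool moved = true;
  while (moved) {
    moved = false;
    int ri = 0, wj = tstart; // read idx, window idx at op k
    for (size_t k = 0; k < ops.size(); ++k) {
      char op = ops[k];
      if ((op == 'I' || op == 'D') && k > 0 && ops[k - 1] == 'M') {
        // locate run end
        size_t e = k; while (e < ops.size() && ops[e] == op) ++e;
        if (op == 'D') {
          // shifting a deletion left by one: window base at wj-1 must equal
          // window base at (wj + runlen - 1)
          int run = (int)(e - k);
          if (window[wj - 1] == window[wj + run - 1]) {
            std::swap(ops[k - 1], ops[e - 1]);
            moved = true; break;
          }
        } else {
          int run = (int)(e - k);
          if (read[ri - 1] == read[ri + run - 1]) {
            std::swap(ops[k - 1], ops[e - 1]);
            moved = true; break;
          }
        }
      }
      if (op == 'M') { ++ri; ++wj; }
      else if (op == 'I') ++ri;
      else ++wj;
    }
  }
  // Compress CIGAR, count mismatches, compute end
  std::string cigar; cigar.reserve(16);
  int nmm = 0; i = 0; j = tstart;
  size_t k = 0;
  while (k < ops.size()) {
    size_t e = k; while (e < ops.size() && ops[e] == ops[k]) ++e;
    int len = (int)(e - k);
    cigar += std::to_string(len); cigar.push_back(ops[k]);
    if (ops[k] == 'M') {
      for (int t = 0; t < len; ++t)
        if (read[i + t] != window[j + t] || read[i + t] == 'N') ++nmm;
      i += len; j += len;
    } else if (ops[k] == 'I') i += len;
    else j += len;
    k = e;
  }
  return List::create(_["score"] = best, _["tstart"] = tstart,
                      _["tend"] = j, _["n_mismatches"] = nmm,
                      _["cigar"] = cigar);
  #undef IDX
}

// Vectorized Hamming distance between equal-length string pairs ('N' counts
// as mismatch). Returns -1 on length mismatch.
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *x = CHAR(STRING_ELT(a, i));
    const char *y = CHAR(STRING_ELT(b, i));
    int la = (int) std::strlen(x), lb = (int) std::strlen(y);
    if (la != lb) { out[i] = -1; continue; }
    int d = 0;
    for (int k = 0; k < la; ++k)
      if (x[k] != y[k] || x[k] == 'N') ++d;
    out[i] = d;
  }
  return out;
}

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

// Pileup accumulation over one target. Reads are already oriented to the
// target forward strand. sex: 0 = male, 1 = female. Returns base-count
// matrices (raw and base-quality-passing, per sex), per-position depth, and
// an indel event table anchored at left-aligned target positions (0-based).
// Deletion positions contribute to depth; 'N' read bases contribute to depth
// but never to allele counts.
// [[Rcpp::export]]
List cpp_pileup(IntegerVector tstart, CharacterVector rseq, CharacterVector rqual,
                CharacterVector cigar, IntegerVector sex, int tlen, int min_bq) {
  IntegerMatrix raw_m(tlen, 4), raw_f(tlen, 4), q_m(tlen, 4), q_f(tlen, 4);
  IntegerVector depth_m(tlen), depth_f(tlen);
  std::vector<int> ev_pos, ev_len, ev_sex;
  std::vector<std::string> ev_type, ev_bases;
  int n = tstart.size();
  for (int r = 0; r < n; ++r) {
    const char *seq = CHAR(STRING_ELT(rseq, r));
    const char *qul = CHAR(STRING_ELT(rqual, r));
    const char *cg = CHAR(STRING_ELT(cigar, r));
    int sx = sex[r];
    int j = tstart[r]; // target pos (0-based)
    int i = 0;         // read pos
    const char *p = cg;
    while (*p) {
      int len = 0;
      while (*p >= '0' && *p <= '9') { len = len * 10 + (*p - '0'); ++p; }
      char op = *p ? *p++ : 'M';
      if (op == 'M') {
        for (int t = 0; t < len; ++t) {
          int pos = j + t;
          if (pos < 0 || pos >= tlen) stop("alignment out of target bounds");
          if (sx == 0) depth_m[pos]++; else depth_f[pos]++;
          int bi = base_idx(seq[i + t]);
          if (bi >= 0) {
            bool qok = ((int) qul[i + t] - 33) > min_bq;
            if (sx == 0) { raw_m(pos, bi)++; if (qok) q_m(pos, bi)++; }
            else         { raw_f(pos, bi)++; if (qok) q_f(pos, bi)++; }
          }
        }
        i += len; j += len;
      } else if (op == 'I') {
        int anchor = j - 1; // inserted before target pos j; anchor at previous base
        if (anchor >= 0 && anchor < tlen) {
          ev_pos.push_back(anchor);
          ev_type.push_back("ins");
          ev_len.push_back(len);
          ev_bases.push_back(std::string(seq + i, (size_t) len));
          ev_sex.push_back(sx);
        }
        i += len;
      } else if (op == 'D') {
        for (int t = 0; t < len; ++t) {
          int pos = j + t;
          if (pos < 0 || pos >= tlen) stop("alignment out of target bounds");
          if (sx == 0) depth_m[pos]++; else depth_f[pos]++;
        }
        ev_pos.push_back(j);
        ev_type.push_back("del");
        ev_len.push_back(len);
        ev_bases.push_back("");
        ev_sex.push_back(sx);
        j += len;
      } else {
        stop("unsupported CIGAR op");
      }
    }
  }
  return List::create(
      _["raw_m"] = raw_m, _["raw_f"] = raw_f, _["q_m"] = q_m, _["q_f"] = q_f,
      _["depth_m"] = depth_m, _["depth_f"] = depth_f,
      _["indel_pos"] = wrap(ev_pos), _["indel_type"] = wrap(ev_type),
      _["indel_len"] = wrap(ev_len), _["indel_bases"] = wrap(ev_bases),
      _["indel_sex"] = wrap(ev_sex));
}

// Best suffix(a)/prefix(b) overlap of length >= min_ov with per-overlap
// identity >= min_identity. Returns c(overlap_len, n_mismatches) or c(0, 0).
// [[Rcpp::export]]
IntegerVector cpp_best_overlap(std::string a, std::string b, int min_ov,
                               double min_identity) {
  int la = (int) a.size(), lb = (int) b.size();
  int maxov = std::min(la, lb);
  for (int ov = maxov; ov >= min_ov; --ov) {
    int allowed = (int) std::floor((1.0 - min_identity) * ov);
    int mm = 0; bool ok = true;
    const char *pa = a.c_str() + (la - ov);
    for (int k = 0; k < ov; ++k) {
      if (pa[k] != b[k] || pa[k] == 'N') {
        if (++mm > allowed) { ok = false; break; }
      }
    }
    if (ok) return IntegerVector::create(ov, mm);
  }
  return IntegerVector::create(0, 0);
}
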