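#include <Rcpp.h>
#include <cstring>
#include <map>
using namespace Rcpp;

// Banded semi-global alignment: the query is aligned end-to-end, leading and
// trailing reference bases are free. The band is centred on a seed-derived
// diagonal (`diag` = estimated 0-based ref position of query[0]).
//
// Offset bookkeeping: at query row i, reference boundary j is restricted to
// [diag + i - band, diag + i + band]; k = j - (diag + i) + band indexes the
// band so that a diagonal move keeps k constant.

static const int NEG = -1000000000;

struct TB { // traceback matrices, one byte per state per cell
  std::vector<uint8_t> m, ins, del;
};

// state codes for traceback: 0 = from M, 1 = from I, 2 = from D, 3 = start
// [[Rcpp::export]]
List cpp_band_align(std::string query, std::string ref, int diag, int band,
                    int match = 2, int mismatch = -4,
                    int gap_open = 4, int gap_ext = 2,
                    bool ref_match_vec = false) {
  const int n = (int)query.size(), m = (int)ref.size();
  const int W = 2 * band + 1;
  std::vector<int> Mprev(W, NEG), Iprev(W, NEG), Dprev(W, NEG);
  std::vector<int> Mcur(W, NEG), Icur(W, NEG), Dcur(W, NEG);
  TB tb;
  tb.m.assign((size_t)(n + 1) * W, 255);
  tb.ins.assign((size_t)(n + 1) * W, 255);
  tb.del.assign((size_t)(n + 1) * W, 255);

  // byte-encode once; 'N' never matches
  std::vector<int8_t> qv(n), rv(m);
  for (int i = 0; i < n; ++i) {
    char c = query[i];
    qv[i] = (c == 'A') ? 0 : (c == 'C') ? 1 : (c == 'G') ? 2 : (c == 'T') ? 3 : 4;
  }
  for (int j = 0; j < m; ++j) {
    char c = ref[j];
    rv[j] = (c == 'A') ? 0 : (c == 'C') ? 1 : (c == 'G') ? 2 : (c == 'T') ? 3 : 5;
  }

  // row 0: free leading reference gap
  for (int k = 0; k < W; ++k) {
    int j = diag - band + k;
    if (j >= 0 && j <= m) { Mprev[k] = 0; tb.m[k] = 3; }
  }
  const int go = gap_open + gap_ext; // first gap base

  int *Mp = Mprev.data(), *Ip = Iprev.data(), *Dp = Dprev.data();
  int *Mc = Mcur.data(), *Ic = Icur.data(), *Dc = Dcur.data();
  for (int i = 1; i <= n; ++i) {
    const int base = diag + i - band; // ref boundary at k = 0
    int klo = -base; if (klo < 0) klo = 0; // j = base + k >= 0
    int khi = m - base; if (khi > W - 1) khi = W - 1;
    std::fill(Mc, Mc + W, NEG);
    std::fill(Ic, Ic + W, NEG);
    std::fill(Dc, Dc + W, NEG);
    if (klo > khi) { std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc); continue; }
    const int8_t qc = qv[i - 1];
    uint8_t *tm = tb.m.data() + (size_t)i * W;
    uint8_t *ti = tb.ins.data() + (size_t)i * W;
    uint8_t *td = tb.del.data() + (size_t)i * W;
    const int8_t *rp = rv.data() + base - 1; // ref base consumed at offset k
    for (int k = klo; k <= khi; ++k) {
      // M: diagonal move keeps k (needs a ref base, j >= 1)
      if (base + k >= 1) {
        int best = Mp[k]; uint8_t src = 0;
        if (Ip[k] > best) { best = Ip[k]; src = 1; }
        if (Dp[k] > best) { best = Dp[k]; src = 2; }
        if (best > NEG) {
          Mc[k] = best + ((qc == rp[k]) ? match : mismatch);
          tm[k] = src;
        }
      }
      // I: consume query only; from row i-1 offset k+1
      if (k + 1 < W) {
        int a = Mp[k + 1] - go;
        int b = Ip[k + 1] - gap_ext;
        int c = Dp[k + 1] - go;
        int bi = a; uint8_t si = 0;
        if (b > bi) { bi = b; si = 1; }
        if (c > bi) { bi = c; si = 2; }
        if (bi > NEG / 2) { Ic[k] = bi; ti[k] = si; }
      }
      // D: consume ref only; same row, offset k-1 (needs a ref base)
      if (k > 0 && base + k >= 1) {
        int a = Mc[k - 1] - go;
        int b = Dc[k - 1] - gap_ext;
        int c = Ic[k - 1] - go;
        int bd = a; uint8_t sd = 2;
        if (a >= b && a >= c) { bd = a; sd = 0; }
        else if (b >= c) { bd = b; sd = 2; }
        else { bd = c; sd = 1; }
        if (bd > NEG / 2) { Dc[k] = bd; td[k] = sd; }
      }
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }

  // end: free trailing reference gap; best over final row of M or I
  int best = NEG, bestk = -1; uint8_t bstate = 0;
  for (int k = 0; k < W; ++k) {
    int j = diag + n - band + k;
    if (j < 0 || j > m) continue;
    if (Mp[k] > best) { best = Mp[k]; bestk = k; bstate = 0; }
    if (Ip[k] > best) { best = Ip[k]; bestk = k; bstate = 1; }
  }
  if (bestk < 0)
    return List::create(_["ok"] = false);

  // traceback
  std::string cig;
  cig.reserve(n + 16);
  int i = n, k = bestk;
  uint8_t state = bstate;
  int ref_end = diag + n - band + bestk;
  std::vector<int> rmatch;
  if (ref_match_vec) rmatch.assign(m, -1);
  int nm = 0;
  while (i > 0 || state == 2) {
    size_t row = (size_t)i * W;
    int j = diag + i - band + k;
    if (state == 0) {
      uint8_t src = tb.m[row + k];
      if (src == 3 && i == 0) break;
      // consumed q[i-1], r[j-1]
      bool is_match = (query[i - 1] == ref[j - 1] && query[i - 1] != 'N');
      if (!is_match) ++nm;
      if (ref_match_vec && j - 1 >= 0 && j - 1 < m) rmatch[j - 1] = is_match ? 1 : 0;
      cig.push_back(is_match ? '=' : 'X');
      if (src == 3) { i = i - 1; break; }
      i -= 1; // k unchanged
      state = src;
    } else if (state == 1) { // I: consumed q[i-1] only
      uint8_t src = tb.ins[row + k];
      cig.push_back('I'); ++nm;
      i -= 1; k += 1;
      state = src;
    } else { // D: consumed r[j-1] only
      uint8_t src = tb.del[row + k];
      cig.push_back('D'); ++nm;
      if (ref_match_vec && j - 1 >= 0 && j - 1 < m) rmatch[j - 1] = 0;
      k -= 1;
      state = src;
    }
  }
  int ref_start = diag + i - band + k;
  std::reverse(cig.begin(), cig.end());

  // run-length encode cigar
  std::string cigar;
  size_t p = 0;
  while (p < cig.size()) {
    size_t q = p;
    while (q < cig.size() && cig[q] == cig[p]) ++q;
    cigar += std::to_string(q - p);
    cigar.push_back(cig[p]);
    p = q;
  }

  List out = List::create(_["ok"] = true, _["score"] = best,
                          _["ref_start"] = ref_start, _["ref_end"] = ref_end,
                          _["cigar"] = cigar, _["nm"] = nm);
  if (ref_match_vec) out["ref_match"] = IntegerVector(rmatch.begin(), rmatch.end());
  return out;
}

// Place each read at its seed diagonal: gapless comparison first, banded DP
// fallback when the gapless placement looks indel-like. diags is 0-based,
// NA = no seed (read is discarded by the caller).
// [[Rcpp::export]]
List cpp_place_reads(CharacterVector seqs, std::string ref, IntegerVector diags,
                     int band = 12, int mm_fast = 8,
                     int match = 2, int mismatch = -4,
                     int gap_open = 4, int gap_ext = 2) {
  const int n = seqs.size(), m = (int)ref.size();
  IntegerVector pos(n, NA_INTEGER), nm(n, NA_INTEGER), score(n, NA_INTEGER);
  CharacterVector cigar(n, NA_STRING);
  for (int r = 0; r < n; ++r) {
    if (diags[r] == NA_INTEGER) continue;
    const char *s = CHAR(STRING_ELT(seqs, r));
    int len = (int)std::strlen(s);
    int d = diags[r];
    if (d >= 0 && d + len <= m) {
      int mm = 0;
      for (int t = 0; t < len && mm <= mm_fast; ++t)
        if (s[t] != ref[d + t]) ++mm;
      if (mm <= mm_fast) {
        pos[r] = d;
        nm[r] = mm;
        score[r] = (len - mm) * match + mm * mismatch;
        cigar[r] = std::to_string(len) + std::string("M");
        continue;
      }
    }
    List al = cpp_band_align(std::string(s), ref, d, band, match, mismatch,
                             gap_open, gap_ext, false);
    if (as<bool>(al["ok"])) {
      pos[r] = as<int>(al["ref_start"]);
      nm[r] = as<int>(al["nm"]);
      score[r] = as<int>(al["score"]);
      cigar[r] = as<std::string>(al["cigar"]);
    }
  }
  return List::create(_["pos"] = pos, _["nm"] = nm, _["score"] = score,
                      _["cigar"] = cigar);
}

// Accumulate base counts along the reference from placed reads.
// Returns a 4 x m count matrix (A/C/G/T rows, base quality >= min_bq),
// per-position deletion counts, and insertion event tallies.
// cigar alphabet: M (align, match or mismatch), = , X, I, D.
// [[Rcpp::export]]
List cpp_pileup_acc(int ref_len, CharacterVector seqs, CharacterVector quals,
                    IntegerVector pos, CharacterVector cigars, int min_bq = 30) {
  IntegerMatrix counts(4, ref_len);
  IntegerVector delcnt(ref_len);
  std::map<std::pair<int, std::string>, int> insmap;
  const int n = seqs.size();
  for (int r = 0; r < n; ++r) {
    if (pos[r] == NA_INTEGER || cigars[r] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(seqs, r));
    const char *q = CHAR(STRING_ELT(quals, r));
    const char *cg = CHAR(STRING_ELT(cigars, r));
    int j = pos[r], i = 0;
    const char *p = cg;
    while (*p) {
      int len = 0;
      while (*p >= '0' && *p <= '9') { len = len * 10 + (*p - '0'); ++p; }
      char op = *p ? *p++ : 0;
      if (op == 'M' || op == '=' || op == 'X') {
        for (int t = 0; t < len; ++t, ++i, ++j) {
          if (j < 0 || j >= ref_len) continue;
          if ((int)q[i] - 33 < min_bq) continue;
          int b;
          switch (s[i]) {
            case 'A': b = 0; break; case 'C': b = 1; break;
            case 'G': b = 2; break; case 'T': b = 3; break;
            default: continue;
          }
          counts(b, j) += 1;
        }
      } else if (op == 'I') {
        if (j >= 0 && j <= ref_len) {
          std::string ins(s + i, (size_t)len);
          insmap[std::make_pair(j, ins)] += 1;
        }
        i += len;
      } else if (op == 'D') {
        for (int t = 0; t < len; ++t, ++j)
          if (j >= 0 && j < ref_len) delcnt[j] += 1;
      }
    }
  }
  const int ni = (int)insmap.size();
  IntegerVector ipos(ni), icnt(ni);
  CharacterVector iseq(ni);
  int t = 0;
  for (auto &kv : insmap) {
    ipos[t] = kv.first.first;
    iseq[t] = kv.first.second;
    icnt[t] = kv.second;
    ++t;
  }
  return List::create(_["counts"] = counts, _["del"] = delcnt,
                      _["ins_pos"] = ipos, _["ins_seq"] = iseq,
                      _["ins_count"] = icnt);
}
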