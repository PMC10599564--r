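// Exact-enumeration kernels for the 9-site, 4-letter Potts model.
//
// State encoding: a donor 9-mer maps to an integer in [0, 4^9) with
// position -3 as the most significant base-4 digit and letters ordered
// A=0, C=1, G=2, T=3.  Integer order therefore equals lexicographic
// sequence order (AAAAAAAAA is state 0).
//
// Pair indexing: the 36 unordered position pairs (i<j) are enumerated
// lexicographically: (1,2),(1,3),...,(1,9),(2,3),...,(8,9).  A letter
// pair (a at i, b at j) occupies column a*4+b of the 36x16 tables.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const int NPOS = 9;
static const int NLET = 4;
static const int NPAIR = 36;
static const int NSTATE = 262144; // 4^9

static inline void decode_state(int s, int *d) {
  for (int i = NPOS - 1; i >= 0; --i) {
    d[i] = s & 3;
    s >>= 2;
  }
}

// copy R matrices into flat local arrays (row-major h[9][4], J[36][16])
static void load_params(const NumericMatrix &h, const NumericMatrix &J,
                        double *hh, double *jj) {
  if (h.nrow() != NPOS || h.ncol() != NLET)
    stop("field matrix must be 9 x 4");
  if (J.nrow() != NPAIR || J.ncol() != NLET * NLET)
    stop("coupling matrix must be 36 x 16");
  for (int i = 0; i < NPOS; ++i)
    for (int a = 0; a < NLET; ++a) hh[i * NLET + a] = h(i, a);
  for (int k = 0; k < NPAIR; ++k)
    for (int c = 0; c < 16; ++c) jj[k * 16 + c] = J(k, c);
}

static void fill_energies(const double *hh, const double *jj, double *E) {
  int d[NPOS];
  // pair index lookup for (i,j), i<j
  int pidx[NPOS][NPOS];
  {
    int k = 0;
    for (int i = 0; i < NPOS - 1; ++i)
      for (int j = i + 1; j < NPOS; ++j) pidx[i][j] = k++;
  }
  // iterate over 4^8 prefixes of the first 8 positions, unroll last digit
  for (int p = 0; p < NSTATE / 4; ++p) {
    int t = p;
    for (int i = 7; i >= 0; --i) {
      d[i] = t & 3;
      t >>= 2;
    }
    double base = 0.0;
    for (int i = 0; i < 8; ++i) base -= hh[i * NLET + d[i]];
    for (int i = 0; i < 7; ++i)
      for (int j = i + 1; j < 8; ++j)
        base -= jj[pidx[i][j] * 16 + d[i] * 4 + d[j]];
    double *Ep = E + (size_t)p * 4;
    for (int b = 0; b < 4; ++b) {
      double e = base - hh[8 * NLET + b];
      for (int i = 0; i < 8; ++i)
        e -= jj[pidx[i][8] * 16 + d[i] * 4 + b];
      Ep[b] = e;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_all_energies(NumericMatrix h, NumericMatrix J) {
  static double hh[NPOS * NLET], jj[NPAIR * 16];
  load_params(h, J, hh, jj);
  NumericVector E(NSTATE);
  fill_energies(hh, jj, REAL(E));
  return E;
}

// log Z plus (optionally) exact one- and two-site model marginals.
// [[Rcpp::export]]
List cpp_enumerate(NumericMatrix h, NumericMatrix J, bool want_marginals) {
  static double hh[NPOS * NLET], jj[NPAIR * 16];
  load_params(h, J, hh, jj);
  std::vector<double> E(NSTATE);
  fill_energies(hh, jj, E.data());

  double m = E[0];
  for (int s = 1; s < NSTATE; ++s)
    if (E[s] < m) m = E[s];

  double Zs = 0.0;
  if (!want_marginals) {
    for (int s = 0; s < NSTATE; ++s) Zs += std::exp(m - E[s]);
    return List::create(_["logZ"] = std::log(Zs) - m);
  }

  double P1[NPOS * NLET];
  double P2[NPAIR * 16];
  std::memset(P1, 0, sizeof(P1));
  std::memset(P2, 0, sizeof(P2));
  int pidx[NPOS][NPOS];
  {
    int k = 0;
    for (int i = 0; i < NPOS - 1; ++i)
      for (int j = i + 1; j < NPOS; ++j) pidx[i][j] = k++;
  }
  // accumulate pairs not involving the fastest-varying last position at
  // the 4^8-prefix level, using the summed weight of the 4 inner states
  int d[NPOS];
  for (int p = 0; p < NSTATE / 4; ++p) {
    int t = p;
    for (int i = 7; i >= 0; --i) {
      d[i] = t & 3;
      t >>= 2;
    }
    const double *Ep = E.data() + (size_t)p * 4;
    double w0 = std::exp(m - Ep[0]);
    double w1 = std::exp(m - Ep[1]);
    double w2 = std::exp(m - Ep[2]);
    double w3 = std::exp(m - Ep[3]);
    double wsum = w0 + w1 + w2 + w3;
    Zs += wsum;
    for (int i = 0; i < 8; ++i) P1[i * NLET + d[i]] += wsum;
    P1[8 * NLET + 0] += w0;
    P1[8 * NLET + 1] += w1;
    P1[8 * NLET + 2] += w2;
    P1[8 * NLET + 3] += w3;
    for (int i = 0; i < 7; ++i)
      for (int j = i + 1; j < 8; ++j)
        P2[pidx[i][j] * 16 + d[i] * 4 + d[j]] += wsum;
    for (int i = 0; i < 8; ++i) {
      double *row = P2 + pidx[i][8] * 16 + d[i] * 4;
      row[0] += w0;
      row[1] += w1;
      row[2] += w2;
      row[3] += w3;
    }
  }
  NumericMatrix p1(NPOS, NLET), p2(NPAIR, 16);
  for (int i = 0; i < NPOS; ++i)
    for (int a = 0; a < NLET; ++a) p1(i, a) = P1[i * NLET + a] / Zs;
  for (int k = 0; k < NPAIR; ++k)
    for (int c = 0; c < 16; ++c) p2(k, c) = P2[k * 16 + c] / Zs;
  return List::create(_["logZ"] = std::log(Zs) - m,
                      _["P1"] = p1, _["P2"] = p2);
}

// n i.i.d. draws of state indices (0-based) from an arbitrary probability
// vector over the 262144 states, via inverse-CDF with R's RNG stream.
// [[Rcpp::export]]
IntegerVector cpp_sample_states(NumericVector prob, int n) {
  if (prob.size() != NSTATE) stop("probability vector must have 4^9 entries");
  std::vector<double> cdf(NSTATE);
  double acc = 0.0;
  for (int s = 0; s < NSTATE; ++s) {
    acc += prob[s];
    cdf[s] = acc;
  }
  double total = acc;
  IntegerVector out(n);
  GetRNGstate();
  for (int r = 0; r < n; ++r) {
    double u = unif_rand() * total;
    int lo = 0, hi = NSTATE - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] >= u) hi = mid; else lo = mid + 1;
    }
    out[r] = lo;
  }
  PutRNGstate();
  return out;
}

// Encode 9-mers over {A,C,G,T} to state indices; -1-based error reporting
// is done in R, here we return the offending element via an attribute-free
// stop() naming the index.
// [[Rcpp::export]]
IntegerVector cpp_encode_donor(CharacterVector seqs) {
  int n = seqs.size();
  IntegerVector out(n);
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  lut[(int)'A'] = 0; lut[(int)'C'] = 1; lut[(int)'G'] = 2; lut[(int)'T'] = 3;
  for (int r = 0; r < n; ++r) {
    if (seqs[r] == NA_STRING)
      stop("entry %d: missing sequence", r + 1);
    const char *s = seqs[r];
    if (std::strlen(s) != (size_t)NPOS)
      stop("entry %d: sequence '%s' does not have length 9", r + 1, s);
    int code = 0;
    for (int i = 0; i < NPOS; ++i) {
      int v = lut[(unsigned char)s[i]];
      if (v < 0)
        stop("entry %d: sequence '%s' contains a letter outside {A,C,G,T}",
             r + 1, s);
      code = (code << 2) | v;
    }
    out[r] = code;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_donor(IntegerVector codes) {
  static const char LET[4] = {'A', 'C', 'G', 'T'};
  int n = codes.size();
  CharacterVector out(n);
  char buf[NPOS + 1];
  buf[NPOS] = '\0';
  int d[NPOS];
  for (int r = 0; r < n; ++r) {
    int c = codes[r];
    if (c < 0 || c >= NSTATE) stop("state index out of range at entry %d", r + 1);
    decode_state(c, d);
    for (int i = 0; i < NPOS; ++i) buf[i] = LET[d[i]];
    out[r] = buf;
  }
  return out;
}

// raw one- and two-site counts from encoded donor states
// [[Rcpp::export]]
List cpp_donor_counts(IntegerVector codes) {
  double C1[NPOS * NLET];
  double C2[NPAIR * 16];
  std::memset(C1, 0, sizeof(C1));
  std::memset(C2, 0, sizeof(C2));
  int pidx[NPOS][NPOS];
  {
    int k = 0;
    for (int i = 0; i < NPOS - 1; ++i)
      for (int j = i + 1; j < NPOS; ++j) pidx[i][j] = k++;
  }
  int d[NPOS];
  int n = codes.size();
  for (int r = 0; r < n; ++r) {
    int c = codes[r];
    if (c < 0 || c >= NSTATE) stop("state index out of range at entry %d", r + 1);
    decode_state(c, d);
    for (int i = 0; i < NPOS; ++i) C1[i * NLET + d[i]] += 1.0;
    for (int i = 0; i < NPOS - 1; ++i)
      for (int j = i + 1; j < NPOS; ++j)
        C2[pidx[i][j] * 16 + d[i] * 4 + d[j]] += 1.0;
  }
  NumericMatrix c1(NPOS, NLET), c2(NPAIR, 16);
  for (int i = 0; i < NPOS; ++i)
    for (int a = 0; a < NLET; ++a) c1(i, a) = C1[i * NLET + a];
  for (int k = 0; k < NPAIR; ++k)
    for (int c = 0; c < 16; ++c) c2(k, c) = C2[k * 16 + c];
  return List::create(_["c1"] = c1, _["c2"] = c2);
}
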