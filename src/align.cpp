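// Affine-gap Needleman-Wunsch on residue profiles: the dynamic-programming
// core of the progressive multiple aligner.  Profiles are integer matrices
// (rows = sequences, columns = alignment columns) with 0 = gap and 1..20 =
// amino-acid states.  Column-column score is the mean substitution score
// over all cross pairs, gap-containing pairs contributing zero.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct SparseCols {
  // per column: indices into (state,count) arrays
  std::vector<int> offset;          // size L+1
  std::vector<int> state;           // 0-based states
  std::vector<double> count;
};

static SparseCols sparsify(const IntegerMatrix& prof) {
  int n = prof.nrow(), L = prof.ncol();
  SparseCols s;
  s.offset.resize(L + 1, 0);
  std::vector<double> cnt(20);
  for (int j = 0; j < L; ++j) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int st = prof(i, j);
      if (st > 0) cnt[st - 1] += 1.0;
    }
    for (int a = 0; a < 20; ++a)
      if (cnt[a] > 0) { s.state.push_back(a); s.count.push_back(cnt[a]); }
    s.offset[j + 1] = (int)s.state.size();
  }
  return s;
}

// Traceback codes per layer (2 bits each, 0=M,1=X,2=Y): predecessor layer
// at the cell we came from.  Packed into one byte: M bits 0-1, X bits 2-3,
// Y bits 4-5.  All transitions between gap layers are allowed (a new gap
// opening directly after a gap in the other profile), so the optimum is
// over all global alignments.

// [[Rcpp::export(name = ".align_profiles_cpp")]]
List align_profiles_cpp(IntegerMatrix a, IntegerMatrix b,
                        NumericMatrix subst, double gap_open,
                        double gap_ext) {
  const int la = a.ncol(), lb = b.ncol();
  const double na = a.nrow(), nb = b.nrow();
  if (la == 0 || lb == 0) stop("empty profile");
  const double open = gap_open + gap_ext;   // cost of a length-1 gap
  const double ext = gap_ext;
  const double scale = 1.0 / (na * nb);

  SparseCols sa = sparsify(a);
  SparseCols sb = sparsify(b);

  // T[a_state][j] = sum_b S[a_state, b] * countB[b, j]
  std::vector<double> T((size_t)20 * lb, 0.0);
  for (int j = 0; j < lb; ++j)
    for (int k = sb.offset[j]; k < sb.offset[j + 1]; ++k) {
      int bs = sb.state[k];
      double c = sb.count[k];
      for (int as = 0; as < 20; ++as)
        T[(size_t)as * lb + j] += subst(as, bs) * c;
    }

  RawMatrix tb(la + 1, lb + 1);
  std::vector<double> mPrev(lb + 1), xPrev(lb + 1), yPrev(lb + 1);
  std::vector<double> mCur(lb + 1), xCur(lb + 1), yCur(lb + 1);

  mPrev[0] = 0.0; xPrev[0] = NEG_INF; yPrev[0] = NEG_INF;
  for (int j = 1; j <= lb; ++j) {
    mPrev[j] = NEG_INF;
    xPrev[j] = NEG_INF;
    yPrev[j] = -(gap_open + j * gap_ext);
    tb(0, j) = 2 << 4;                 // Y from Y
  }

  std::vector<double> scoreRow(lb);
  Rbyte* tbp = tb.begin();
  const size_t tbStride = la + 1;

  for (int i = 1; i <= la; ++i) {
    // profile-column score of A column i-1 against every B column,
    // accumulated state-row by state-row for sequential memory access
    std::fill(scoreRow.begin(), scoreRow.end(), 0.0);
    for (int k = sa.offset[i - 1]; k < sa.offset[i]; ++k) {
      const double c = sa.count[k] * scale;
      const double* trow = &T[(size_t)sa.state[k] * lb];
      for (int j = 0; j < lb; ++j) scoreRow[j] += c * trow[j];
    }
    mCur[0] = NEG_INF;
    yCur[0] = NEG_INF;
    xCur[0] = -(gap_open + i * gap_ext);
    tbp[(size_t)0 * tbStride + i] = 1 << 2;   // X from X (2-bit field = 1)
    for (int j = 1; j <= lb; ++j) {
      const double sc = scoreRow[j - 1];
      unsigned char code = 0;
      // M: diagonal move; prefer M >= X >= Y on ties
      double best = mPrev[j - 1]; int from = 0;
      if (xPrev[j - 1] > best) { best = xPrev[j - 1]; from = 1; }
      if (yPrev[j - 1] > best) { best = yPrev[j - 1]; from = 2; }
      mCur[j] = best + sc;
      code |= (unsigned char)from;
      // X: consume column of A against gap in B (vertical)
      double xb = mPrev[j] - open; int xf = 0;
      if (xPrev[j] - ext > xb) { xb = xPrev[j] - ext; xf = 1; }
      if (yPrev[j] - open > xb) { xb = yPrev[j] - open; xf = 2; }
      xCur[j] = xb;
      code |= (unsigned char)(xf << 2);
      // Y: consume column of B against gap in A (horizontal)
      double yb = mCur[j - 1] - open; int yf = 0;
      if (xCur[j - 1] - open > yb) { yb = xCur[j - 1] - open; yf = 1; }
      if (yCur[j - 1] - ext > yb) { yb = yCur[j - 1] - ext; yf = 2; }
      yCur[j] = yb;
      code |= (unsigned char)(yf << 4);
      tbp[(size_t)j * tbStride + i] = code;
    }
    std::swap(mPrev, mCur); std::swap(xPrev, xCur); std::swap(yPrev, yCur);
  }

  double score = mPrev[lb]; int layer = 0;
  if (xPrev[lb] > score) { score = xPrev[lb]; layer = 1; }
  if (yPrev[lb] > score) { score = yPrev[lb]; layer = 2; }

  // traceback
  std::vector<int> pa, pb;
  pa.reserve(la + lb); pb.reserve(la + lb);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    unsigned char code = tb(i, j);
    if (layer == 0) {
      pa.push_back(i); pb.push_back(j);
      layer = code & 3; --i; --j;
    } else if (layer == 1) {
      pa.push_back(i); pb.push_back(0);
      layer = (code >> 2) & 3; --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      layer = (code >> 4) & 3; --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["a_path"] = IntegerVector(pa.begin(), pa.end()),
                      _["b_path"] = IntegerVector(pb.begin(), pb.end()));
}
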