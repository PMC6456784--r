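#include <Rcpp.h>
#include <deque>
#include <vector>
using namespace Rcpp;

// Windowed Pearson correlation for all unordered region pairs.
// X: n x T matrix (regions x time), w: window length in samples, step 1.
// Returns npairs x (T - w + 1); pair rows ordered (1,2),(1,3),...,(2,3),...
// Rolling sums over cumulative arrays keep the cost O(n^2 T).
// [[Rcpp::export]]
NumericMatrix cpp_windowed_pearson(NumericMatrix X, int w) {
  const int n = X.nrow(), T = X.ncol();
  const int npos = T - w + 1;
  if (npos < 1) stop("window longer than series");
  const int npairs = n * (n - 1) / 2;
  NumericMatrix out(npairs, npos);

  // cumulative sums of each row and of each row's squares
  std::vector<double> cs(n * (T + 1)), css(n * (T + 1));
  for (int r = 0; r < n; ++r) {
    double s = 0, ss = 0;
    cs[r * (T + 1)] = 0; css[r * (T + 1)] = 0;
    for (int t = 0; t < T; ++t) {
      double v = X(r, t);
      s += v; ss += v * v;
      cs[r * (T + 1) + t + 1] = s;
      css[r * (T + 1) + t + 1] = ss;
    }
  }

  int p = 0;
  std::vector<double> cxy(T + 1);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++p) {
      double s = 0;
      cxy[0] = 0;
      for (int t = 0; t < T; ++t) {
        s += X(i, t) * X(j, t);
        cxy[t + 1] = s;
      }
      const double *ci = &cs[i * (T + 1)], *cii = &css[i * (T + 1)];
      const double *cj = &cs[j * (T + 1)], *cjj = &css[j * (T + 1)];
      for (int k = 0; k < npos; ++k) {
        double sx = ci[k + w] - ci[k], sy = cj[k + w] - cj[k];
        double sxx = cii[k + w] - cii[k], syy = cjj[k + w] - cjj[k];
        double sxy = cxy[k + w] - cxy[k];
        double vx = sxx - sx * sx / w, vy = syy - sy * sy / w;
        double cv = sxy - sx * sy / w;
        if (vx <= 0.0 || vy <= 0.0)
          stop("constant segment in window %d for pair (%d, %d)", k + 1, i + 1, j + 1);
        out(p, k) = cv / std::sqrt(vx * vy);
      }
    }
  }
  return out;
}

// rolling min and max of a row over windows of length w (monotonic deques)
static void rolling_minmax(const double *x, int T, int w,
                           std::vector<double> &mn, std::vector<double> &mx) {
  std::deque<int> qmin, qmax;
  for (int t = 0; t < T; ++t) {
    while (!qmin.empty() && x[qmin.back()] >= x[t]) qmin.pop_back();
    qmin.push_back(t);
    while (!qmax.empty() && x[qmax.back()] <= x[t]) qmax.pop_back();
    qmax.push_back(t);
    int start = t - w + 1;
    if (start >= 0) {
      if (qmin.front() < start) qmin.pop_front();
      if (qmax.front() < start) qmax.pop_front();
      mn[start] = x[qmin.front()];
      mx[start] = x[qmax.front()];
    }
  }
}

// State for one pair's sliding joint histogram.  Entropy bookkeeping uses
// the identity H = log2(w) - (1/w) * sum_c count_c * log2(count_c), so the
// running sums sx / sy / sxy are updated with O(1) deltas as points enter
// and leave the window; a full O(w) rebuild happens only when a window's
// min or max changes (expected a few times per w shifts).
struct SlidingMiVi {
  int w;
  std::vector<int> cntx, cnty, joint;
  double sx, sy, sxy;
  double mni, mxi, mnj, mxj, si, sj;
  const std::vector<double> &lg;

  SlidingMiVi(int w_, const std::vector<double> &lg_)
      : w(w_), cntx(w_, 0), cnty(w_, 0), joint(w_ * w_, 0),
        sx(0), sy(0), sxy(0), lg(lg_) {}

  inline int binx(double v) const {
    int a = (int)((v - mni) * si);
    return a >= w ? w - 1 : (a < 0 ? 0 : a);
  }
  inline int biny(double v) const {
    int b = (int)((v - mnj) * sj);
    return b >= w ? w - 1 : (b < 0 ? 0 : b);
  }
  inline void add(double vx, double vy) {
    int a = binx(vx), b = biny(vy), code = a * w + b;
    sx += (cntx[a] + 1) * lg[cntx[a] + 1] - cntx[a] * lg[cntx[a]];
    ++cntx[a];
    sy += (cnty[b] + 1) * lg[cnty[b] + 1] - cnty[b] * lg[cnty[b]];
    ++cnty[b];
    sxy += (joint[code] + 1) * lg[joint[code] + 1] - joint[code] * lg[joint[code]];
    ++joint[code];
  }
  inline void remove(double vx, double vy) {
    int a = binx(vx), b = biny(vy), code = a * w + b;
    sx += (cntx[a] - 1) * lg[cntx[a] - 1] - cntx[a] * lg[cntx[a]];
    --cntx[a];
    sy += (cnty[b] - 1) * lg[cnty[b] - 1] - cnty[b] * lg[cnty[b]];
    --cnty[b];
    sxy += (joint[code] - 1) * lg[joint[code] - 1] - joint[code] * lg[joint[code]];
    --joint[code];
  }
  void set_range(double a0, double a1, double b0, double b1) {
    mni = a0; mxi = a1; mnj = b0; mxj = b1;
    si = (mxi > mni) ? w / (mxi - mni) : 0.0;
    sj = (mxj > mnj) ? w / (mxj - mnj) : 0.0;
  }
};

// Windowed plug-in mutual information and variation of information (bits)
// for all unordered pairs.  Binning matches the R reference path: per axis,
// w equal-width bins over the segment's own [min, max], rightmost bin
// closed; entropies from marginal and joint counts of the w in-window
// points.  Returns a list with "mi" and "vi" (npairs x (T - w + 1)).
// [[Rcpp::export]]
List cpp_windowed_mivi(NumericMatrix X, int w) {
  const int n = X.nrow(), T = X.ncol();
  const int npos = T - w + 1;
  if (npos < 1) stop("window longer than series");
  const int npairs = n * (n - 1) / 2;
  NumericMatrix mi(npairs, npos), vi(npairs, npos);

  // per-row data copies and rolling window ranges
  std::vector<std::vector<double>> rows(n, std::vector<double>(T));
  std::vector<std::vector<double>> rmn(n, std::vector<double>(npos)),
      rmx(n, std::vector<double>(npos));
  for (int r = 0; r < n; ++r) {
    for (int t = 0; t < T; ++t) rows[r][t] = X(r, t);
    rolling_minmax(rows[r].data(), T, w, rmn[r], rmx[r]);
  }

  // precomputed log2 table for counts 0..w
  std::vector<double> lg(w + 1);
  lg[0] = 0.0;
  for (int c = 1; c <= w; ++c) lg[c] = std::log2((double)c);
  const double lgw = std::log2((double)w);

  SlidingMiVi st(w, lg);
  int p = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++p) {
      const double *xi = rows[i].data(), *xj = rows[j].data();
      const double *mni = rmn[i].data(), *mxi = rmx[i].data();
      const double *mnj = rmn[j].data(), *mxj = rmx[j].data();
      for (int k = 0; k < npos; ++k) {
        if (k == 0) {
          st.set_range(mni[0], mxi[0], mnj[0], mxj[0]);
          for (int t = 0; t < w; ++t) st.add(xi[t], xj[t]);
        } else if (mni[k] == mni[k - 1] && mxi[k] == mxi[k - 1] &&
                   mnj[k] == mnj[k - 1] && mxj[k] == mxj[k - 1]) {
          st.remove(xi[k - 1], xj[k - 1]);
          st.add(xi[k + w - 1], xj[k + w - 1]);
        } else {
          // range moved: empty under the old scale, rebuild under the new
          for (int t = k - 1; t < k - 1 + w; ++t) st.remove(xi[t], xj[t]);
          st.set_range(mni[k], mxi[k], mnj[k], mxj[k]);
          st.sx = st.sy = st.sxy = 0.0;  // exact zeros after full removal
          for (int t = k; t < k + w; ++t) st.add(xi[t], xj[t]);
        }
        double hx = lgw - st.sx / w, hy = lgw - st.sy / w;
        double hxy = lgw - st.sxy / w;
        double m = hx + hy - hxy;
        if (m < 0) m = 0;
        double v = 2 * hxy - hx - hy;
        if (v < 0) v = 0;
        mi(p, k) = m;
        vi(p, k) = v;
      }
      // clear state for the next pair
      for (int t = npos - 1; t < npos - 1 + w; ++t) st.remove(xi[t], xj[t]);
      st.sx = st.sy = st.sxy = 0.0;
    }
  }
  return List::create(Named("mi") = mi, Named("vi") = vi);
}
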