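#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable periodized orthogonal 3D DWT. Analysis along one axis:
//   a_k = sum_m h[m] x[(2k+m) mod n],  d_k = sum_m g[m] x[(2k+m) mod n]
// with the quadrature-mirror high-pass g[m] = (-1)^m h[L-1-m]. Periodization
// keeps the coefficient count equal to the sample count at every level.

namespace {

std::vector<double> qmf(const std::vector<double>& h) {
  const int L = (int)h.size();
  std::vector<double> g(L);
  for (int m = 0; m < L; ++m) g[m] = ((m % 2) ? -1.0 : 1.0) * h[L - 1 - m];
  return g;
}

// transform along the first (fastest-varying) axis of a (n1, n2) view
// stored column-major: in[i + n1*j]. Writes low into out[k + (n1/2)*j],
// high into out[n1/2 + k + (n1/2)*j] of a second buffer pair.
void analyze_axis(const std::vector<double>& in, int n1, int n2,
                  const std::vector<double>& h, const std::vector<double>& g,
                  std::vector<double>& lo, std::vector<double>& hi) {
  const int half = n1 / 2, L = (int)h.size();
  lo.assign((size_t)half * n2, 0.0);
  hi.assign((size_t)half * n2, 0.0);
  for (int j = 0; j < n2; ++j) {
    const double* col = &in[(size_t)n1 * j];
    for (int k = 0; k < half; ++k) {
      double a = 0.0, d = 0.0;
      for (int m = 0; m < L; ++m) {
        const int i = (2 * k + m) % n1;
        a += h[m] * col[i];
        d += g[m] * col[i];
      }
      lo[k + (size_t)half * j] = a;
      hi[k + (size_t)half * j] = d;
    }
  }
}

// inverse along the first axis: x[(2k+m) mod n] += h[m] a_k + g[m] d_k
void synth_axis(const std::vector<double>& lo, const std::vector<double>& hi,
                int n1, int n2, const std::vector<double>& h,
                const std::vector<double>& g, std::vector<double>& out) {
  const int half = n1 / 2, L = (int)h.size();
  out.assign((size_t)n1 * n2, 0.0);
  for (int j = 0; j < n2; ++j) {
    double* col = &out[(size_t)n1 * j];
    for (int k = 0; k < half; ++k) {
      const double a = lo[k + (size_t)half * j];
      const double d = hi[k + (size_t)half * j];
      for (int m = 0; m < L; ++m) {
        const int i = (2 * k + m) % n1;
        col[i] += h[m] * a + g[m] * d;
      }
    }
  }
}

// permute (d1,d2,d3) column-major array so that axis `ax` (0=z,1=y,2=x)
// becomes the fastest-varying axis; inverse restores.
void move_axis_front(const std::vector<double>& in, int d1, int d2, int d3,
                     int ax, std::vector<double>& out) {
  out.resize(in.size());
  if (ax == 0) { out = in; return; }
  size_t t = 0;
  if (ax == 1) {
    for (int k = 0; k < d3; ++k)
      for (int i = 0; i < d1; ++i)
        for (int j = 0; j < d2; ++j)
          out[t++] = in[i + (size_t)d1 * (j + (size_t)d2 * k)];
  } else {
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i)
        for (int k = 0; k < d3; ++k)
          out[t++] = in[i + (size_t)d1 * (j + (size_t)d2 * k)];
  }
}

void move_axis_back(const std::vector<double>& in, int d1, int d2, int d3,
                    int ax, std::vector<double>& out) {
  out.resize(in.size());
  if (ax == 0) { out = in; return; }
  size_t t = 0;
  if (ax == 1) {
    for (int k = 0; k < d3; ++k)
      for (int i = 0; i < d1; ++i)
        for (int j = 0; j < d2; ++j)
          out[i + (size_t)d1 * (j + (size_t)d2 * k)] = in[t++];
  } else {
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i)
        for (int k = 0; k < d3; ++k)
          out[i + (size_t)d1 * (j + (size_t)d2 * k)] = in[t++];
  }
}

// one analysis level on a (dz,dy,dx) cube -> 8 subbands, each half side.
// Subband order: code = fz*4 + fy*2 + fx with 0 = low, 1 = high, i.e.
// LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH with letters naming (z, y, x).
void dwt3_once(const std::vector<double>& cube, int dz_, int dy_, int dx_,
               const std::vector<double>& h,
               std::vector<std::vector<double> >& bands) {
  const std::vector<double> g = qmf(h);
  // along z (axis 0, already fastest)
  std::vector<double> lo, hi;
  analyze_axis(cube, dz_, dy_ * dx_, h, g, lo, hi);
  const int hz = dz_ / 2;
  // along y for each of lo/hi
  std::vector<double> tmp, l2, h2;
  std::vector<std::vector<double> > zy(4);  // order: LL, LH, HL, HH over (z,y)
  for (int b = 0; b < 2; ++b) {
    const std::vector<double>& src = (b == 0) ? lo : hi;
    move_axis_front(src, hz, dy_, dx_, 1, tmp);  // y fastest: (y, z, x)
    analyze_axis(tmp, dy_, hz * dx_, h, g, l2, h2);
    const int hy = dy_ / 2;
    std::vector<double> back;
    move_axis_back(l2, hz, hy, dx_, 1, back); zy[b * 2 + 0] = back;
    move_axis_back(h2, hz, hy, dx_, 1, back); zy[b * 2 + 1] = back;
  }
  const int hy = dy_ / 2, hx = dx_ / 2;
  bands.assign(8, std::vector<double>());
  for (int b = 0; b < 4; ++b) {
    move_axis_front(zy[b], hz, hy, dx_, 2, tmp);  // x fastest: (x, z, y)
    analyze_axis(tmp, dx_, hz * hy, h, g, l2, h2);
    std::vector<double> back;
    move_axis_back(l2, hz, hy, hx, 2, back); bands[b * 2 + 0] = back;
    move_axis_back(h2, hz, hy, hx, 2, back); bands[b * 2 + 1] = back;
  }
}

void idwt3_once(const std::vector<std::vector<double> >& bands,
                int hz, int hy, int hx, const std::vector<double>& h,
                std::vector<double>& cube) {
  const std::vector<double> g = qmf(h);
  std::vector<double> tmp, lo, hi, back;
  // undo x
  std::vector<std::vector<double> > zy(4);
  for (int b = 0; b < 4; ++b) {
    std::vector<double> blo, bhi;
    move_axis_front(bands[b * 2 + 0], hz, hy, hx, 2, blo);
    move_axis_front(bands[b * 2 + 1], hz, hy, hx, 2, bhi);
    synth_axis(blo, bhi, 2 * hx, hz * hy, h, g, tmp);
    move_axis_back(tmp, hz, hy, 2 * hx, 2, zy[b]);
  }
  // undo y
  std::vector<std::vector<double> > z2(2);
  for (int b = 0; b < 2; ++b) {
    std::vector<double> blo, bhi;
    move_axis_front(zy[b * 2 + 0], hz, hy, 2 * hx, 1, blo);
    move_axis_front(zy[b * 2 + 1], hz, hy, 2 * hx, 1, bhi);
    synth_axis(blo, bhi, 2 * hy, hz * 2 * hx, h, g, tmp);
    move_axis_back(tmp, hz, 2 * hy, 2 * hx, 1, z2[b]);
  }
  // undo z
  synth_axis(z2[0], z2[1], 2 * hz, 2 * hy * 2 * hx, h, g, cube);
}

// multi-resolution features: per level the 7 detail subbands (codes 1..7),
// each flattened column-major; the final level's LLL appended last.
// Total length equals the cube voxel count.
void mwr_vec(const std::vector<double>& cube0, int side, int levels,
             const std::vector<double>& h, std::vector<double>& out) {
  out.clear();
  out.reserve((size_t)side * side * side);
  std::vector<double> cur = cube0;
  int s = side;
  std::vector<std::vector<double> > bands;
  std::vector<double> lll;
  for (int lev = 0; lev < levels; ++lev) {
    dwt3_once(cur, s, s, s, h, bands);
    for (int b = 1; b < 8; ++b)
      out.insert(out.end(), bands[b].begin(), bands[b].end());
    cur = bands[0];
    s /= 2;
  }
  out.insert(out.end(), cur.begin(), cur.end());
}

// symmetric (edge-repeating) reflection of index i into [0, n)
inline int mirror_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

}  // namespace

// [[Rcpp::export]]
List cpp_dwt3(NumericVector cube, NumericVector h) {
  IntegerVector d = cube.attr("dim");
  if (d.size() != 3) stop("need a 3D array");
  if (d[0] % 2 || d[1] % 2 || d[2] % 2) stop("all sides must be even");
  std::vector<double> cin(cube.begin(), cube.end());
  std::vector<double> hv(h.begin(), h.end());
  std::vector<std::vector<double> > bands;
  dwt3_once(cin, d[0], d[1], d[2], hv, bands);
  const char* nm[8] = {"LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"};
  List out(8);
  CharacterVector names(8);
  for (int b = 0; b < 8; ++b) {
    NumericVector v(bands[b].begin(), bands[b].end());
    v.attr("dim") = IntegerVector::create(d[0] / 2, d[1] / 2, d[2] / 2);
    out[b] = v;
    names[b] = nm[b];
  }
  out.attr("names") = names;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_idwt3(List bands, NumericVector h) {
  NumericVector b0 = bands[0];
  IntegerVector d = b0.attr("dim");
  std::vector<std::vector<double> > bv(8);
  for (int b = 0; b < 8; ++b) {
    NumericVector x = bands[b];
    bv[b].assign(x.begin(), x.end());
  }
  std::vector<double> hv(h.begin(), h.end());
  std::vector<double> cube;
  idwt3_once(bv, d[0], d[1], d[2], hv, cube);
  NumericVector out(cube.begin(), cube.end());
  out.attr("dim") = IntegerVector::create(2 * d[0], 2 * d[1], 2 * d[2]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_mwr(NumericVector cube, int levels, NumericVector h) {
  IntegerVector d = cube.attr("dim");
  if (d.size() != 3 || d[0] != d[1] || d[1] != d[2]) stop("need a cubic array");
  const int side = d[0];
  if (side % (1 << levels)) stop("side not divisible by 2^levels");
  std::vector<double> cin(cube.begin(), cube.end());
  std::vector<double> hv(h.begin(), h.end());
  std::vector<double> out;
  mwr_vec(cin, side, levels, hv, out);
  return NumericVector(out.begin(), out.end());
}

// Batched window extraction + MWR features around voxel centers.
// centers: n x 3 matrix of 0-based (z, y, x); windows are mirror-padded
// (edge-repeating reflection) and start at c - side/2 + 1 along each axis.
// sel: 0-based indices into the feature vector (empty = all features).
// [[Rcpp::export]]
NumericMatrix cpp_mwr_batch(NumericVector img, IntegerMatrix centers,
                            int side, int levels, NumericVector h,
                            IntegerVector sel) {
  IntegerVector d = img.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  const int n = centers.nrow();
  const size_t flen = (size_t)side * side * side;
  const int k = sel.size() ? sel.size() : (int)flen;
  std::vector<double> hv(h.begin(), h.end());
  NumericMatrix out(n, k);
  std::vector<double> cube(flen), feats;
  std::vector<int> iz(side), iy(side), ix(side);
  for (int r = 0; r < n; ++r) {
    const int cz = centers(r, 0), cy = centers(r, 1), cx = centers(r, 2);
    for (int o = 0; o < side; ++o) {
      const int off = o - side / 2 + 1;
      iz[o] = mirror_idx(cz + off, nz);
      iy[o] = mirror_idx(cy + off, ny);
      ix[o] = mirror_idx(cx + off, nx);
    }
    size_t t = 0;
    for (int c3 = 0; c3 < side; ++c3)
      for (int c2 = 0; c2 < side; ++c2)
        for (int c1 = 0; c1 < side; ++c1)
          cube[t++] = img[iz[c1] + (size_t)nz * (iy[c2] + (size_t)ny * ix[c3])];
    mwr_vec(cube, side, levels, hv, feats);
    if (sel.size()) {
      for (int j = 0; j < k; ++j) out(r, j) = feats[sel[j]];
    } else {
      for (int j = 0; j < k; ++j) out(r, j) = feats[j];
    }
  }
  return out;
}
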