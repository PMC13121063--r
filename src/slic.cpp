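#include <Rcpp.h>
#include <cmath>
#include <queue>
using namespace Rcpp;

// SLIC superpixels on co-registered feature maps.
//
// feat: npix x nchan matrix, pixels in column-major (row index fastest)
//       order of an H x W image, features already scaled to [0, 1].
// valid: logical vector, length npix; invalid pixels get label 0.
// Distance between pixel p and cluster k:
//   d^2 = sum_c (f_pc - f_kc)^2 + (m/S)^2 * ((y_p-y_k)^2 + (x_p-x_k)^2)
// with S the grid step and m the compactness. Search window 2S x 2S around
// each cluster center. After max_iter assignment/update rounds, connectivity
// is enforced: 4-connected fragments smaller than min_size are merged into
// an adjacent superpixel. Deterministic; labels 1..K.
// [[Rcpp::export(name = ".slic_cpp")]]
IntegerMatrix slic_cpp(NumericMatrix feat, LogicalVector valid,
                       int H, int W, int n_segments, double compactness,
                       int max_iter = 10) {
  const int npix = H * W, nchan = feat.ncol();
  const double S = std::sqrt((double)npix / n_segments);
  const int win = (int)std::ceil(S);

  // grid-initialized centers at valid pixels
  std::vector<double> cy, cx;
  std::vector<std::vector<double>> cf;
  for (double gy = S / 2.0; gy < H; gy += S) {
    for (double gx = S / 2.0; gx < W; gx += S) {
      int iy = (int)gy, ix = (int)gx;
      int p = ix * H + iy;
      if (!valid[p]) continue;
      cy.push_back(gy); cx.push_back(gx);
      std::vector<double> f(nchan);
      for (int c = 0; c < nchan; ++c) f[c] = feat(p, c);
      cf.push_back(f);
    }
  }
  int K = (int)cy.size();
  if (K == 0) stop("no valid pixels to segment");

  std::vector<int> label(npix, -1);
  std::vector<double> dist(npix);
  const double mw = (compactness / S) * (compactness / S);

  for (int it = 0; it < max_iter; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      int y0 = std::max(0, (int)cy[k] - win), y1 = std::min(H - 1, (int)cy[k] + win);
      int x0 = std::max(0, (int)cx[k] - win), x1 = std::min(W - 1, (int)cx[k] + win);
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          int p = x * H + y;
          if (!valid[p]) continue;
          double d = mw * ((y - cy[k]) * (y - cy[k]) + (x - cx[k]) * (x - cx[k]));
          if (d >= dist[p]) continue;
          for (int c = 0; c < nchan; ++c) {
            double df = feat(p, c) - cf[k][c];
            d += df * df;
            if (d >= dist[p]) break;
          }
          if (d < dist[p]) { dist[p] = d; label[p] = k; }
        }
      }
    }
    // update centers
    std::vector<double> sy(K, 0), sx(K, 0), n(K, 0);
    std::vector<std::vector<double>> sf(K, std::vector<double>(nchan, 0));
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        int p = x * H + y, k = label[p];
        if (k < 0) continue;
        sy[k] += y; sx[k] += x; n[k] += 1;
        for (int c = 0; c < nchan; ++c) sf[k][c] += feat(p, c);
      }
    for (int k = 0; k < K; ++k) {
      if (n[k] == 0) continue;
      cy[k] = sy[k] / n[k]; cx[k] = sx[k] / n[k];
      for (int c = 0; c < nchan; ++c) cf[k][c] = sf[k][c] / n[k];
    }
  }

  // sweep up pixels never reached by any window (possible with sparse
  // valid sets): attach to nearest assigned 4-neighbour iteratively
  bool changed = true;
  while (changed) {
    changed = false;
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        int p = x * H + y;
        if (!valid[p] || label[p] >= 0) continue;
        const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int yy = y + dy[d], xx = x + dx[d];
          if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
          int q = xx * H + yy;
          if (label[q] >= 0) { label[p] = label[q]; changed = true; break; }
        }
      }
  }

  // connectivity enforcement: relabel 4-connected components; fragments
  // below min_size are merged into the previously finalized neighbour
  const int min_size = std::max(1, (int)(S * S / 4.0));
  IntegerMatrix out(H, W);
  std::vector<int> comp(npix, 0);
  int next_label = 0;
  const int dy4[4] = {-1, 1, 0, 0}, dx4[4] = {0, 0, -1, 1};
  std::vector<int> members;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int p = x * H + y;
      if (!valid[p] || label[p] < 0 || comp[p] != 0) continue;
      // BFS this component
      members.clear();
      int adj_label = 0; // finalized neighbour label for small-fragment merge
      ++next_label;
      comp[p] = next_label;
      std::queue<int> q;
      q.push(p);
      members.push_back(p);
      while (!q.empty()) {
        int cur = q.front(); q.pop();
        int yy = cur % H, xx = cur / H;
        for (int d = 0; d < 4; ++d) {
          int ny = yy + dy4[d], nx = xx + dx4[d];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          int np = nx * H + ny;
          if (!valid[np] || label[np] < 0) continue;
          if (label[np] == label[p] && comp[np] == 0) {
            comp[np] = next_label;
            q.push(np);
            members.push_back(np);
          } else if (label[np] != label[p] && comp[np] != 0 && comp[np] != next_label) {
            adj_label = comp[np];
          }
        }
      }
      if ((int)members.size() < min_size && adj_label > 0) {
        for (int m : members) comp[m] = adj_label;
        --next_label;
      }
    }
  }
  // compact label ids to 1..K'
  std::vector<int> remap(next_label + 1, 0);
  int K2 = 0;
  for (int p = 0; p < npix; ++p)
    if (comp[p] > 0 && remap[comp[p]] == 0) remap[comp[p]] = ++K2;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int p = x * H + y;
      out(y, x) = comp[p] > 0 ? remap[comp[p]] : 0;
    }
  return out;
}
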