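#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <map>
#include <algorithm>
using namespace Rcpp;

// symmetric (mirror) index: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int mirror_idx(int q, int n) {
  while (q < 0 || q >= n) {
    if (q < 0) q = -q - 1;
    if (q >= n) q = 2 * n - q - 1;
  }
  return q;
}

static inline double ratio_sim(double a, double b, double c) {
  return (2.0 * a * b + c) / (a * a + b * b + c);
}

// structure term between two histogram (density) vectors: |2*cov + c4| / (sd_u*sd_v + c4),
// d-1 denominators, clipped to [0,1]
static double hist_struct_sim(const double* hu, const double* hv, int B, double c4) {
  double mu = 0, mv = 0;
  for (int b = 0; b < B; b++) { mu += hu[b]; mv += hv[b]; }
  mu /= B; mv /= B;
  double suu = 0, svv = 0, suv = 0;
  for (int b = 0; b < B; b++) {
    double du = hu[b] - mu, dv = hv[b] - mv;
    suu += du * du; svv += dv * dv; suv += du * dv;
  }
  double sdu = std::sqrt(suu / (B - 1)), sdv = std::sqrt(svv / (B - 1));
  double cov = suv / (B - 1);
  double s = std::fabs(2.0 * cov + c4) / (sdu * sdv + c4);
  if (s > 1.0) s = 1.0;
  if (s < 0.0) s = 0.0;
  return s;
}

// Per-pixel p x p patch statistics with mirror padding: mean, sd (d-1 denominator)
// and B-bin histogram counts of a [0,1]-normalized image.
// [[Rcpp::export(name = ".cpp_patch_maps")]]
List cpp_patch_maps(NumericMatrix img, int p, int B) {
  int H = img.nrow(), W = img.ncol();
  int half = p / 2, d = p * p;
  NumericMatrix mean_map(H, W), sd_map(H, W);
  NumericMatrix hist(H * (double)W, B);
  for (int c = 0; c < W; c++) {
    for (int r = 0; r < H; r++) {
      double s = 0, s2 = 0;
      int idx = r + c * H;
      for (int dc = -half; dc <= half; dc++) {
        int cc = mirror_idx(c + dc, W);
        for (int dr = -half; dr <= half; dr++) {
          int rr = mirror_idx(r + dr, H);
          double v = img(rr, cc);
          s += v; s2 += v * v;
          int b = (int)(v * B);
          if (b >= B) b = B - 1;
          if (b < 0) b = 0;
          hist(idx, b) += 1.0;
        }
      }
      double m = s / d;
      double var = (s2 - d * m * m) / (d - 1);
      if (var < 0) var = 0;
      mean_map(r, c) = m;
      sd_map(r, c) = std::sqrt(var);
    }
  }
  return List::create(_["mean"] = mean_map, _["sd"] = sd_map, _["hist"] = hist);
}

// SLIC-style assignment driven by the hybrid similarity. Each pixel carries its
// patch statistics (mean/sd/histogram) and phase-congruency value; each seed region
// carries running statistics (mean, sd, mean PC, centroid, histogram). Pixels are
// (re)assigned within a 2g x 2g window around each region centroid to the region of
// maximal hybrid similarity.
// [[Rcpp::export(name = ".cpp_slic_iterate")]]
List cpp_slic_iterate(NumericMatrix img, NumericMatrix pc,
                      NumericMatrix mean_map, NumericMatrix sd_map,
                      NumericMatrix hist_counts, int patch_area,
                      NumericMatrix seeds, double g, double alpha,
                      NumericVector cc, NumericVector betas,
                      int max_iter, double tol) {
  int H = img.nrow(), W = img.ncol(), N = H * W;
  int kreg = seeds.nrow(), B = hist_counts.ncol();
  double c1 = cc[0], c2 = cc[1], c3 = cc[2], c4 = cc[3];
  bool unit_beta = true;
  for (int i = 0; i < 5; i++) if (betas[i] != 1.0) unit_beta = false;

  std::vector<int> labels(N);
  // initial assignment: nearest seed (guarantees full coverage)
  for (int c = 0; c < W; c++) {
    for (int r = 0; r < H; r++) {
      double x = c + 0.5, y = r + 0.5, best = R_PosInf;
      int bk = 0;
      for (int k = 0; k < kreg; k++) {
        double dy = y - seeds(k, 0), dx = x - seeds(k, 1);
        double dd = dy * dy + dx * dx;
        if (dd < best) { best = dd; bk = k; }
      }
      labels[r + c * H] = bk;
    }
  }

  std::vector<double> cnt(kreg), sum(kreg), sumsq(kreg), pcsum(kreg),
      rsum(kreg), csum(kreg);
  std::vector<double> rhist(kreg * (size_t)B);
  std::vector<double> best_sim(N);
  std::vector<int> new_labels(N);
  std::vector<int> changed_trace;
  int iters = 0;

  for (int it = 0; it < max_iter; it++) {
    iters = it + 1;
    // recompute region statistics
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(sumsq.begin(), sumsq.end(), 0.0);
    std::fill(pcsum.begin(), pcsum.end(), 0.0);
    std::fill(rsum.begin(), rsum.end(), 0.0);
    std::fill(csum.begin(), csum.end(), 0.0);
    std::fill(rhist.begin(), rhist.end(), 0.0);
    for (int c = 0; c < W; c++) {
      for (int r = 0; r < H; r++) {
        int i = r + c * H, k = labels[i];
        double v = img(r, c);
        cnt[k] += 1; sum[k] += v; sumsq[k] += v * v; pcsum[k] += pc(r, c);
        rsum[k] += r + 0.5; csum[k] += c + 0.5;
        int b = (int)(v * B); if (b >= B) b = B - 1; if (b < 0) b = 0;
        rhist[k * (size_t)B + b] += 1.0;
      }
    }
    std::fill(best_sim.begin(), best_sim.end(), -1.0);
    for (int i = 0; i < N; i++) new_labels[i] = labels[i];

    std::vector<double> hreg(B), hpix(B);
    for (int k = 0; k < kreg; k++) {
      if (cnt[k] < 1) continue;
      double n = cnt[k];
      double rm = sum[k] / n;
      double rvar = n > 1 ? (sumsq[k] - n * rm * rm) / (n - 1) : 0.0;
      if (rvar < 0) rvar = 0;
      double rsd = std::sqrt(rvar);
      double rpc = pcsum[k] / n;
      double cy = rsum[k] / n, cx = csum[k] / n;
      for (int b = 0; b < B; b++) hreg[b] = rhist[k * (size_t)B + b] / n;
      int r0 = (int)std::floor(cy - g - 0.5), r1 = (int)std::ceil(cy + g - 0.5);
      int c0 = (int)std::floor(cx - g - 0.5), c1i = (int)std::ceil(cx + g - 0.5);
      if (r0 < 0) r0 = 0; if (c0 < 0) c0 = 0;
      if (r1 >= H) r1 = H - 1; if (c1i >= W) c1i = W - 1;
      for (int c = c0; c <= c1i; c++) {
        for (int r = r0; r <= r1; r++) {
          int i = r + c * H;
          double x = c + 0.5, y = r + 0.5;
          double spm = ratio_sim(pc(r, c), rpc, c1);
          double sim = ratio_sim(mean_map(r, c), rm, c2);
          double scm = ratio_sim(sd_map(r, c), rsd, c3);
          for (int b = 0; b < B; b++) hpix[b] = hist_counts(i, b) / patch_area;
          double ssm = hist_struct_sim(hpix.data(), hreg.data(), B, c4);
          double dy = y - cy, dx = x - cx;
          double sdm = std::exp(-alpha * (dy * dy + dx * dx));
          double S;
          if (unit_beta) S = spm * sim * scm * ssm * sdm;
          else S = std::pow(spm, betas[0]) * std::pow(sim, betas[1]) *
                   std::pow(scm, betas[2]) * std::pow(ssm, betas[3]) *
                   std::pow(sdm, betas[4]);
          if (S > best_sim[i]) { best_sim[i] = S; new_labels[i] = k; }
        }
      }
    }
    int changed = 0;
    for (int i = 0; i < N; i++) {
      if (new_labels[i] != labels[i]) changed++;
      labels[i] = new_labels[i];
    }
    changed_trace.push_back(changed);
    if (changed < tol * N) break;
  }

  IntegerMatrix out(H, W);
  for (int c = 0; c < W; c++)
    for (int r = 0; r < H; r++) out(r, c) = labels[r + c * H] + 1;
  return List::create(_["labels"] = out, _["iterations"] = iters,
                      _["changed"] = wrap(changed_trace));
}

// Enforce 4-connectivity: for each label keep its largest connected component;
// every other fragment is relabeled to the dominant (most frequent) adjacent label.
// [[Rcpp::export(name = ".cpp_enforce_connectivity")]]
IntegerMatrix cpp_enforce_connectivity(IntegerMatrix labels) {
  int H = labels.nrow(), W = labels.ncol(), N = H * W;
  std::vector<int> comp(N, -1);
  std::vector<int> comp_label, comp_size;
  int ncomp = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < W; c++) {
    for (int r = 0; r < H; r++) {
      int i = r + c * H;
      if (comp[i] >= 0) continue;
      int lab = labels(r, c);
      std::queue<int> q;
      q.push(i); comp[i] = ncomp;
      int sz = 0;
      while (!q.empty()) {
        int cur = q.front(); q.pop(); sz++;
        int cr = cur % H, ccol = cur / H;
        for (int d = 0; d < 4; d++) {
          int nr = cr + dr[d], nc = ccol + dc[d];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          int ni = nr + nc * H;
          if (comp[ni] < 0 && labels(nr, nc) == lab) { comp[ni] = ncomp; q.push(ni); }
        }
      }
      comp_label.push_back(lab);
      comp_size.push_back(sz);
      ncomp++;
    }
  }
  // largest component per label
  std::map<int, int> best_comp;
  for (int k = 0; k < ncomp; k++) {
    int lab = comp_label[k];
    auto it = best_comp.find(lab);
    if (it == best_comp.end() || comp_size[k] > comp_size[it->second])
      best_comp[lab] = k;
  }
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; c++)
    for (int r = 0; r < H; r++) out(r, c) = labels(r, c);
  // process stranded fragments smallest-first
  std::vector<int> order;
  for (int k = 0; k < ncomp; k++)
    if (best_comp[comp_label[k]] != k) order.push_back(k);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return comp_size[a] < comp_size[b]; });
  for (int k : order) {
    std::map<int, int> neigh;
    for (int c = 0; c < W; c++) {
      for (int r = 0; r < H; r++) {
        if (comp[r + c * H] != k) continue;
        for (int d = 0; d < 4; d++) {
          int nr = r + dr[d], nc = c + dc[d];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (comp[nr + nc * H] != k) neigh[out(nr, nc)]++;
        }
      }
    }
    if (neigh.empty()) continue;
    int bl = -1, bn = -1;
    for (auto& kv : neigh)
      if (kv.second > bn || (kv.second == bn && kv.first < bl)) { bn = kv.second; bl = kv.first; }
    for (int c = 0; c < W; c++)
      for (int r = 0; r < H; r++)
        if (comp[r + c * H] == k) out(r, c) = bl;
  }
  return out;
}
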