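#include <Rcpp.h>
using namespace Rcpp;

// Half-max support statistics around a response peak: flood fill (4-connected)
// from the peak over pixels >= level_frac * peak response, restricted to the
// peak's Voronoi cell among same-scale candidate peaks, inside a square
// window. Returns NumericVector(area, circularity, cy, cx) with the
// circularity as the minor/major equivalent-ellipse axis ratio of the
// response-weighted support, or area = -1 when the support is degenerate or
// reaches the window border (ridge/edge structure).
// [[Rcpp::export(name = ".support_moments")]]
NumericVector support_moments(const NumericMatrix& resp, int pr, int pc,
                              int win, const IntegerMatrix& peers,
                              double level_frac) {
  const int nr = resp.nrow(), nc = resp.ncol();
  NumericVector bad = NumericVector::create(-1.0, 0.0, 0.0, 0.0);
  // R uses 1-based indices
  const int pr0 = pr - 1, pc0 = pc - 1;
  const double peak = resp(pr0, pc0);
  const double level = level_frac * peak;
  if (level <= 0) return bad;
  const int r0 = std::max(0, pr0 - win), r1 = std::min(nr - 1, pr0 + win);
  const int c0 = std::max(0, pc0 - win), c1 = std::min(nc - 1, pc0 + win);
  const int wr = r1 - r0 + 1, wc = c1 - c0 + 1;
  const int npeer = peers.nrow();

  std::vector<char> mark(wr * wc, 0);
  std::vector<int> queue;
  queue.reserve(64);
  const int start = (pr0 - r0) + (pc0 - c0) * wr;
  // candidate peak must sit inside its own Voronoi cell (distance 0)
  queue.push_back(start);
  mark[start] = 1;
  size_t head = 0;
  bool border = false;
  while (head < queue.size()) {
    const int cur = queue[head++];
    const int lr = cur % wr, lc = cur / wr;
    const int gr = lr + r0, gc = lc + c0;
    if (lr == 0 || lr == wr - 1 || lc == 0 || lc == wc - 1) border = true;
    const int dr[4] = {-1, 1, 0, 0};
    const int dc[4] = {0, 0, -1, 1};
    for (int k = 0; k < 4; ++k) {
      const int nlr = lr + dr[k], nlc = lc + dc[k];
      if (nlr < 0 || nlr >= wr || nlc < 0 || nlc >= wc) continue;
      const int ni = nlr + nlc * wr;
      if (mark[ni]) continue;
      const int ngr = nlr + r0, ngc = nlc + c0;
      if (resp(ngr, ngc) < level) { mark[ni] = 2; continue; }
      // Voronoi restriction among same-scale candidate peaks
      const double down = double(ngr - pr0) * (ngr - pr0) +
                          double(ngc - pc0) * (ngc - pc0);
      bool mine = true;
      for (int q = 0; q < npeer; ++q) {
        const double dq = double(ngr - (peers(q, 0) - 1)) * (ngr - (peers(q, 0) - 1)) +
                          double(ngc - (peers(q, 1) - 1)) * (ngc - (peers(q, 1) - 1));
        if (dq < down) { mine = false; break; }
      }
      if (!mine) { mark[ni] = 2; continue; }
      mark[ni] = 1;
      queue.push_back(ni);
    }
    (void)gr; (void)gc;
  }
  if (border) return bad;

  // response-weighted centroid and second moments
  double sw = 0, sy = 0, sx = 0;
  for (size_t i = 0; i < queue.size(); ++i) {
    const int lr = queue[i] % wr, lc = queue[i] / wr;
    double w = resp(lr + r0, lc + c0) - level;
    if (w < 0) w = 0;
    sw += w; sy += w * (lr + r0); sx += w * (lc + c0);
  }
  if (sw <= 0) return bad;
  const double cy = sy / sw, cx = sx / sw;
  double myy = 0, mxx = 0, mxy = 0;
  for (size_t i = 0; i < queue.size(); ++i) {
    const int lr = queue[i] % wr, lc = queue[i] / wr;
    double w = resp(lr + r0, lc + c0) - level;
    if (w < 0) w = 0;
    const double dy = (lr + r0) - cy, dx = (lc + c0) - cx;
    myy += w * dy * dy; mxx += w * dx * dx; mxy += w * dy * dx;
  }
  // + 1/12 pixel-integration variance keeps single-pixel supports finite
  myy = myy / sw + 1.0 / 12.0;
  mxx = mxx / sw + 1.0 / 12.0;
  mxy = mxy / sw;
  const double tr2 = (myy + mxx) / 2.0;
  double disc = (myy - mxx) / 2.0;
  disc = std::sqrt(disc * disc + mxy * mxy);
  const double lmaj = tr2 + disc;
  const double lmin = std::max(tr2 - disc, 0.0);
  const double circ = lmaj > 0 ? std::sqrt(lmin / lmaj) : 0.0;
  // back to 1-based centroids
  return NumericVector::create(double(queue.size()), circ, cy + 1.0, cx + 1.0);
}
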