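#include <Rcpp.h>
using namespace Rcpp;

// Integer-pixel block matching by exhaustive cross-correlation search.
//
// For each node i, the tile of side `tile` around (cy[i], cx[i]) (0-based
// pixel indices, tile spans [c - tile/2, c + tile - tile/2)) in frame `a` is
// compared against every integer shift within +/- `search` of the predicted
// shift (pred_dy, pred_dx) in frame `b`. The score is the pixel-by-pixel sum
// of products, optionally computed on mean-subtracted tiles. Ties are broken
// by smallest squared shift magnitude, then by row-major scan order
// (dy outer, dx inner). Nodes whose tile or full search window leaves either
// frame, or whose tile has zero contrast, are returned invalid.
//
// score: 0 = raw sum of products, 1 = mean-subtracted (zero-mean) product,
// 2 = normalized cross-correlation (zero-mean product / sd_a sd_b).
//
// Returns an n x 3 integer matrix: columns dx, dy, valid.
// [[Rcpp::export]]
IntegerMatrix match_blocks(NumericMatrix a, NumericMatrix b,
                           IntegerVector cy, IntegerVector cx,
                           int tile, int search,
                           IntegerVector pred_dy, IntegerVector pred_dx,
                           int score_mode) {
  const int H = a.nrow(), W = a.ncol();
  const int n = cy.size();
  const double *pa = &a(0, 0);
  const double *pb = &b(0, 0);
  IntegerMatrix out(n, 3);
  const int lo = tile / 2;
  const double N = (double)tile * (double)tile;

  for (int i = 0; i < n; ++i) {
    out(i, 0) = NA_INTEGER; out(i, 1) = NA_INTEGER; out(i, 2) = 0;
    const int y0 = cy[i] - lo, x0 = cx[i] - lo;
    const int py = pred_dy[i], px = pred_dx[i];
    if (y0 < 0 || x0 < 0 || y0 + tile > H || x0 + tile > W) continue;
    if (y0 + py - search < 0 || x0 + px - search < 0 ||
        y0 + py + search + tile > H || x0 + px + search + tile > W) continue;

    double sum_a = 0.0, sum_a2 = 0.0;
    for (int c = 0; c < tile; ++c) {
      const double *col = pa + (size_t)(x0 + c) * H + y0;
      for (int r = 0; r < tile; ++r) { sum_a += col[r]; sum_a2 += col[r] * col[r]; }
    }
    if (sum_a2 - sum_a * sum_a / N <= 1e-12 * N) continue;  // zero contrast

    double best = 0.0; long best_mag = 0; int bdy = 0, bdx = 0; bool first = true;
    for (int dy = py - search; dy <= py + search; ++dy) {
      for (int dx = px - search; dx <= px + search; ++dx) {
        double s_ab = 0.0, s_b = 0.0, s_b2 = 0.0;
        for (int c = 0; c < tile; ++c) {
          const double *ca = pa + (size_t)(x0 + c) * H + y0;
          const double *cb = pb + (size_t)(x0 + dx + c) * H + y0 + dy;
          for (int r = 0; r < tile; ++r) {
            s_ab += ca[r] * cb[r];
            s_b  += cb[r];
            s_b2 += cb[r] * cb[r];
          }
        }
        double score = s_ab;
        if (score_mode >= 1) score = s_ab - sum_a * s_b / N;
        if (score_mode == 2) {
          const double den = std::sqrt((sum_a2 - sum_a * sum_a / N) *
                                       (s_b2 - s_b * s_b / N));
          score = den > 0 ? score / den : -2.0;
        }
        const long mag = (long)dy * dy + (long)dx * dx;
        if (first || score > best || (score == best && mag < best_mag)) {
          best = score; best_mag = mag; bdy = dy; bdx = dx; first = false;
        }
      }
    }
    out(i, 0) = bdx; out(i, 1) = bdy; out(i, 2) = 1;
  }
  return out;
}
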