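// Void-aware denoising kernels for depth frames (0 = void pixel).
// Bilateral: spatial Gaussian truncated at radius ceil(2*sigma); range
// Gaussian on depth normalised to [0,1] over the clip span. Median: odd
// square window, voids excluded. Both leave void pixels void.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix bilateral_depth_cpp(NumericMatrix frame, double spatialSigma,
                                  double rangeSigma, double clipMin,
                                  double clipMax) {
    const int H = frame.nrow(), W = frame.ncol();
    const int r = (int)std::ceil(2.0 * spatialSigma);
    const double span = clipMax - clipMin;
    const double s2 = 2.0 * spatialSigma * spatialSigma;
    const double r2 = 2.0 * rangeSigma * rangeSigma;
    std::vector<double> ws((2 * r + 1) * (2 * r + 1));
    for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx)
            ws[(dy + r) * (2 * r + 1) + (dx + r)] =
                std::exp(-(double)(dx * dx + dy * dy) / s2);
    NumericMatrix out(H, W);
    for (int c = 0; c < W; ++c) {
        for (int rr = 0; rr < H; ++rr) {
            double v0 = frame(rr, c);
            if (v0 <= 0) { out(rr, c) = 0.0; continue; }
            double n0 = (v0 - clipMin) / span;
            double num = 0.0, den = 0.0;
            int ylo = std::max(0, rr - r), yhi = std::min(H - 1, rr + r);
            int xlo = std::max(0, c - r), xhi = std::min(W - 1, c + r);
            for (int x = xlo; x <= xhi; ++x) {
                for (int y = ylo; y <= yhi; ++y) {
                    double v = frame(y, x);
                    if (v <= 0) continue;
                    double dn = (v - clipMin) / span - n0;
                    double w = ws[(y - rr + r) * (2 * r + 1) + (x - c + r)] *
                               std::exp(-(dn * dn) / r2);
                    num += w * v;
                    den += w;
                }
            }
            out(rr, c) = num / den;
        }
    }
    return out;
}

// [[Rcpp::export]]
NumericMatrix median_depth_cpp(NumericMatrix frame, int win) {
    const int H = frame.nrow(), W = frame.ncol();
    const int r = (win - 1) / 2;
    NumericMatrix out(H, W);
    std::vector<double> buf;
    buf.reserve(win * win);
    for (int c = 0; c < W; ++c) {
        for (int rr = 0; rr < H; ++rr) {
            if (frame(rr, c) <= 0) { out(rr, c) = 0.0; continue; }
            buf.clear();
            int ylo = std::max(0, rr - r), yhi = std::min(H - 1, rr + r);
            int xlo = std::max(0, c - r), xhi = std::min(W - 1, c + r);
            for (int x = xlo; x <= xhi; ++x)
                for (int y = ylo; y <= yhi; ++y)
                    if (frame(y, x) > 0) buf.push_back(frame(y, x));
            const size_t n = buf.size();
            std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
            double med = buf[n / 2];
            if (n % 2 == 0) {
                // even count: average the two central order statistics,
                // matching stats::median
                double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
                med = 0.5 * (lo + med);
            }
            out(rr, c) = med;
        }
    }
    return out;
}
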