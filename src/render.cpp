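#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian-beam emission weight, 1/e^2 radius `waist` (pixel units):
// w(r) = exp(-2 r^2 / waist^2)

static inline double wrap(double x, double L) {
    x -= L * std::floor(x / L);
    if (x >= L) x -= L;   // guard against floating rounding at the edge
    return x;
}

// Render a photon-counting confocal stack of Brownian emitters.
//
// Emitters live in a padded periodic box of size (nrow + 2*pad) x
// (ncol + 2*pad) pixels; the imaged field is the central nrow x ncol
// region. Each frame the positions take a Brownian step of per-axis sd
// `stepSd` (pixels), then expected counts are accumulated as
// amp_i * w(r) and observed counts drawn Poisson. Uses R's RNG, so a
// set.seed() on the R side makes output bit-reproducible.
// [[Rcpp::export(name = ".renderStackCpp")]]
IntegerVector renderStackCpp(int nrow, int ncol, int nframes,
                             NumericVector x, NumericVector y,
                             NumericVector amp,
                             NumericVector stepSd, double pad, double waist) {
    const int n = x.size();
    const double W = ncol + 2.0 * pad;   // x extent (columns)
    const double H = nrow + 2.0 * pad;   // y extent (rows)
    const double inv = 2.0 / (waist * waist);
    const int cut = (int)std::ceil(2.5 * waist);

    IntegerVector out(Dimension(nrow, ncol, nframes));
    std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
    std::vector<double> lam((size_t)nrow * ncol);

    for (int f = 0; f < nframes; ++f) {
        std::fill(lam.begin(), lam.end(), 0.0);
        for (int i = 0; i < n; ++i) {
            if (f > 0 && stepSd[i] > 0.0) {
                px[i] = wrap(px[i] + R::rnorm(0.0, stepSd[i]), W);
                py[i] = wrap(py[i] + R::rnorm(0.0, stepSd[i]), H);
            }
            // field coordinates (pixel centers at 0.5, 1.5, ...)
            const double cx = px[i] - pad;
            const double cy = py[i] - pad;
            const int j0 = std::max(0, (int)std::floor(cx - cut));
            const int j1 = std::min(ncol - 1, (int)std::ceil(cx + cut));
            const int i0 = std::max(0, (int)std::floor(cy - cut));
            const int i1 = std::min(nrow - 1, (int)std::ceil(cy + cut));
            for (int c = j0; c <= j1; ++c) {
                const double dx = (c + 0.5) - cx;
                const double ex = std::exp(-inv * dx * dx) * amp[i];
                if (ex <= 0.0) continue;
                for (int r = i0; r <= i1; ++r) {
                    const double dy = (r + 0.5) - cy;
                    lam[(size_t)c * nrow + r] += ex * std::exp(-inv * dy * dy);
                }
            }
        }
        int* slab = INTEGER(out) + (size_t)f * nrow * ncol;
        for (size_t k = 0; k < lam.size(); ++k) {
            if (lam[k] > 1e9)
                stop("expected counts exceed 1e9; reduce density/brightness");
            slab[k] = (int)R::rpois(lam[k]);
        }
    }
    return out;
}

// Render a line-scan kymograph (one or two channels).
//
// Emitters diffuse in a 2D periodic box: x along the scanned line
// (npx + 2*pad pixels) and y perpendicular to it (2*bandHalf pixels, scan
// line at the center). Each line period all emitters take a Brownian step
// and a 1D PSF-weighted snapshot of the scan row is rendered. Channel A
// collects all A emitters; channel B (when nB >= 0) collects the co-labeled
// subset of A (colabel flag) plus `nB` independent emitters appended at the
// end of the coordinate vectors.
// [[Rcpp::export(name = ".renderKymoCpp")]]
List renderKymoCpp(int nlines, int npx,
                   NumericVector x, NumericVector y,
                   NumericVector amp, LogicalVector colabel,
                   NumericVector ampB,
                   int nA, int nB, bool twoChannel,
                   NumericVector stepSd, double pad, double bandHalf,
                   double waist) {
    const int n = x.size();
    if (nA + nB != n) stop("nA + nB must equal length(x)");
    const double W = npx + 2.0 * pad;
    const double H = 2.0 * bandHalf;
    const double yScan = bandHalf;     // scan row at band center
    const double inv = 2.0 / (waist * waist);
    const int cut = (int)std::ceil(2.5 * waist);

    IntegerMatrix A(nlines, npx);
    IntegerMatrix B(twoChannel ? nlines : 1, twoChannel ? npx : 1);
    std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
    std::vector<double> lamA(npx), lamB(npx);

    for (int t = 0; t < nlines; ++t) {
        std::fill(lamA.begin(), lamA.end(), 0.0);
        if (twoChannel) std::fill(lamB.begin(), lamB.end(), 0.0);
        for (int i = 0; i < n; ++i) {
            if (t > 0 && stepSd[i] > 0.0) {
                px[i] = wrap(px[i] + R::rnorm(0.0, stepSd[i]), W);
                py[i] = wrap(py[i] + R::rnorm(0.0, stepSd[i]), H);
            }
            const double dy = py[i] - yScan;
            if (std::fabs(dy) > cut) continue;
            const double wy = std::exp(-inv * dy * dy);
            const double cx = px[i] - pad;
            const int j0 = std::max(0, (int)std::floor(cx - cut));
            const int j1 = std::min(npx - 1, (int)std::ceil(cx + cut));
            const bool inA = i < nA;
            const bool inB = twoChannel && ((inA && colabel[i]) || !inA);
            for (int c = j0; c <= j1; ++c) {
                const double dx = (c + 0.5) - cx;
                const double w = wy * std::exp(-inv * dx * dx);
                if (inA) lamA[c] += amp[i] * w;
                if (inB) lamB[c] += ampB[i] * w;
            }
        }
        for (int c = 0; c < npx; ++c) {
            if (lamA[c] > 1e9 || (twoChannel && lamB[c] > 1e9))
                stop("expected counts exceed 1e9; reduce density/brightness");
            A(t, c) = (int)R::rpois(lamA[c]);
            if (twoChannel) B(t, c) = (int)R::rpois(lamB[c]);
        }
    }
    if (twoChannel) return List::create(_["A"] = A, _["B"] = B);
    return List::create(_["A"] = A);
}
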