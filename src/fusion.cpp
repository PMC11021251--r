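#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline R_xlen_t lidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Patch-based similarity-weighted voting label fusion.
//
// For every voxel v inside `compute`, each atlas searches the offsets of its
// per-voxel search set (near_off where `near_gm` is true, far_off elsewhere)
// for the atlas patch with maximal Pearson correlation to the target patch at
// v (patches clipped at the volume border; correlation over the valid
// overlap; a constant patch has similarity 0). The atlas then votes for its
// label at the best-matching location with weight max(r, 0)^beta. The output
// label is the argmax of summed weights (ties -> lowest code); when all
// weights vanish the majority label of the atlases at v wins (ties -> lowest
// code). Confidence is the winning weight fraction (vote fraction in the
// majority fallback). Outside `compute` the majority fallback is used
// directly. Search offsets must be ordered so earlier offsets win similarity
// ties (callers pass them sorted by distance, origin first).
//
// [[Rcpp::export(name = ".cpp_fuse")]]
List cpp_fuse(NumericVector target, IntegerVector dim, List atlas_int,
              List atlas_lab, IntegerMatrix patch_off, IntegerMatrix near_off,
              IntegerMatrix far_off, LogicalVector near_gm,
              LogicalVector compute, double beta) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int na = atlas_int.size();
  const int np = patch_off.nrow();

  std::vector<const double *> ai(na);
  std::vector<const int *> al(na);
  for (int a = 0; a < na; ++a) {
    NumericVector x = atlas_int[a];
    IntegerVector l = atlas_lab[a];
    ai[a] = REAL(x);
    al[a] = INTEGER(l);
  }

  IntegerVector out_lab(target.size(), 0);
  NumericVector out_conf(target.size(), 0.0);

  std::vector<double> tpatch(np);
  std::vector<int> pvalid(np);
  std::vector<int> vote_lab(na);
  std::vector<double> vote_w(na);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = lidx(i, j, k, nx, ny);

        if (!compute[v]) {
          // plain majority of atlas labels at v
          int bestl = 0, bestc = -1;
          for (int a = 0; a < na; ++a) {
            int l = al[a][v];
            int c = 0;
            for (int a2 = 0; a2 < na; ++a2) if (al[a2][v] == l) ++c;
            if (c > bestc || (c == bestc && l < bestl)) { bestc = c; bestl = l; }
          }
          out_lab[v] = bestl;
          out_conf[v] = na > 0 ? (double)bestc / na : 0.0;
          continue;
        }

        const IntegerMatrix &soff = near_gm[v] ? near_off : far_off;
        const int ns = soff.nrow();

        // target patch (clipped)
        int nv = 0;
        for (int p = 0; p < np; ++p) {
          int ii = i + patch_off(p, 0), jj = j + patch_off(p, 1), kk = k + patch_off(p, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
            pvalid[p] = 0;
            continue;
          }
          pvalid[p] = 1;
          tpatch[p] = target[lidx(ii, jj, kk, nx, ny)];
          ++nv;
        }

        int nvotes = 0;
        for (int a = 0; a < na; ++a) {
          double best_r = -2.0;
          int best_lab = al[a][v];
          for (int s = 0; s < ns; ++s) {
            int si = i + soff(s, 0), sj = j + soff(s, 1), sk = k + soff(s, 2);
            if (si < 0 || sj < 0 || sk < 0 || si >= nx || sj >= ny || sk >= nz)
              continue;
            // correlation over offsets valid in both
            double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
            int m = 0;
            for (int p = 0; p < np; ++p) {
              if (!pvalid[p]) continue;
              int ii = si + patch_off(p, 0), jj = sj + patch_off(p, 1),
                  kk = sk + patch_off(p, 2);
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              double x = tpatch[p];
              double y = ai[a][lidx(ii, jj, kk, nx, ny)];
              sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
              ++m;
            }
            double r = 0.0;
            if (m >= 2) {
              double vx = sxx - sx * sx / m, vy = syy - sy * sy / m;
              if (vx > 1e-12 && vy > 1e-12)
                r = (sxy - sx * sy / m) / std::sqrt(vx * vy);
            }
            if (r > best_r) {
              best_r = r;
              best_lab = al[a][lidx(si, sj, sk, nx, ny)];
            }
          }
          double w = best_r > 0 ? std::pow(best_r, beta) : 0.0;
          if (w > 0) {
            vote_lab[nvotes] = best_lab;
            vote_w[nvotes] = w;
            ++nvotes;
          }
        }

        if (nvotes == 0) {
          int bestl = 0, bestc = -1;
          for (int a = 0; a < na; ++a) {
            int l = al[a][v];
            int c = 0;
            for (int a2 = 0; a2 < na; ++a2) if (al[a2][v] == l) ++c;
            if (c > bestc || (c == bestc && l < bestl)) { bestc = c; bestl = l; }
          }
          out_lab[v] = bestl;
          out_conf[v] = na > 0 ? (double)bestc / na : 0.0;
          continue;
        }

        double total = 0.0;
        for (int t = 0; t < nvotes; ++t) total += vote_w[t];
        int bestl = 0;
        double bestw = -1.0;
        for (int t = 0; t < nvotes; ++t) {
          double wsum = 0.0;
          for (int t2 = 0; t2 < nvotes; ++t2)
            if (vote_lab[t2] == vote_lab[t]) wsum += vote_w[t2];
          if (wsum > bestw || (wsum == bestw && vote_lab[t] < bestl)) {
            bestw = wsum;
            bestl = vote_lab[t];
          }
        }
        out_lab[v] = bestl;
        out_conf[v] = total > 0 ? bestw / total : 0.0;
      }

  return List::create(Named("labels") = out_lab, Named("confidence") = out_conf);
}
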