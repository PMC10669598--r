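// Hot paths of the GA pose search: chromosome decoding (torsion tree
// application + rigid-body placement) and the additive surrogate
// interaction score. Everything else stays in R.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap_deg(double x) {
  double y = x - 360.0 * std::floor((x + 180.0) / 360.0);
  if (y <= -180.0 || y == 180.0) return 180.0;  // half-open (-180, 180]
  return y;
}

static double dihedral4(const NumericMatrix &xyz, int a, int b, int c,
                        int d) {
  double b1[3], b2[3], b3[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = xyz(b, k) - xyz(a, k);
    b2[k] = xyz(c, k) - xyz(b, k);
    b3[k] = xyz(d, k) - xyz(c, k);
  }
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1],
                  b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1],
                  b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double m1[3] = {(n1[1] * b2[2] - n1[2] * b2[1]) / nb2,
                  (n1[2] * b2[0] - n1[0] * b2[2]) / nb2,
                  (n1[0] * b2[1] - n1[1] * b2[0]) / nb2};
  double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double y = m1[0] * n2[0] + m1[1] * n2[1] + m1[2] * n2[2];
  return wrap_deg(std::atan2(y, x) * 180.0 / M_PI);
}

static void rotate_set(NumericMatrix &xyz, const IntegerVector &moved,
                       int ia, int ij, double angle_deg) {
  double ax[3] = {xyz(ij, 0) - xyz(ia, 0), xyz(ij, 1) - xyz(ia, 1),
                  xyz(ij, 2) - xyz(ia, 2)};
  double n = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
  if (n < 1e-12) return;
  for (int k = 0; k < 3; ++k) ax[k] /= n;
  double th = angle_deg * M_PI / 180.0;
  double c = std::cos(th), s = std::sin(th), t = 1 - c;
  double R[3][3] = {
    {t * ax[0] * ax[0] + c, t * ax[0] * ax[1] - s * ax[2],
     t * ax[0] * ax[2] + s * ax[1]},
    {t * ax[0] * ax[1] + s * ax[2], t * ax[1] * ax[1] + c,
     t * ax[1] * ax[2] - s * ax[0]},
    {t * ax[0] * ax[2] - s * ax[1], t * ax[1] * ax[2] + s * ax[0],
     t * ax[2] * ax[2] + c}};
  double piv[3] = {xyz(ia, 0), xyz(ia, 1), xyz(ia, 2)};
  for (int m = 0; m < moved.size(); ++m) {
    int idx = moved[m] - 1;
    double v[3] = {xyz(idx, 0) - piv[0], xyz(idx, 1) - piv[1],
                   xyz(idx, 2) - piv[2]};
    for (int k = 0; k < 3; ++k)
      xyz(idx, k) = R[k][0] * v[0] + R[k][1] * v[1] + R[k][2] * v[2] +
        piv[k];
  }
}

// Apply torsion genes along the tree, then quaternion rotation about
// the template centroid, then translation. tree_* use 1-based atom
// indices; refs rows are (p1,p2,p3,p4) or 0s for inert bonds.
// [[Rcpp::export]]
NumericMatrix cpp_decode(NumericMatrix tpl_xyz, IntegerVector bond_i,
                         IntegerVector bond_j, List moved_list,
                         IntegerMatrix refs, IntegerVector sense,
                         NumericVector target, LogicalVector active,
                         NumericVector quat, NumericVector centroid,
                         NumericVector trans) {
  NumericMatrix xyz = clone(tpl_xyz);
  int nb = bond_i.size();
  for (int k = 0; k < nb; ++k) {
    if (!active[k]) continue;
    if (refs(k, 0) == 0) continue;
    IntegerVector moved = moved_list[k];
    if (moved.size() == 0) continue;
    double cur = dihedral4(xyz, refs(k, 0) - 1, refs(k, 1) - 1,
                           refs(k, 2) - 1, refs(k, 3) - 1);
    double delta = wrap_deg(target[k] - cur) * sense[k];
    rotate_set(xyz, moved, bond_i[k] - 1, bond_j[k] - 1, delta);
  }
  // quaternion to rotation matrix
  double qn = std::sqrt(quat[0] * quat[0] + quat[1] * quat[1] +
                        quat[2] * quat[2] + quat[3] * quat[3]);
  double w = quat[0] / qn, x = quat[1] / qn, y = quat[2] / qn,
         z = quat[3] / qn;
  double R[3][3] = {
    {1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y)},
    {2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x)},
    {2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)}};
  int n = xyz.nrow();
  for (int i = 0; i < n; ++i) {
    double v[3] = {xyz(i, 0) - centroid[0], xyz(i, 1) - centroid[1],
                   xyz(i, 2) - centroid[2]};
    for (int k = 0; k < 3; ++k)
      xyz(i, k) = R[k][0] * v[0] + R[k][1] * v[1] + R[k][2] * v[2] +
        centroid[k] + trans[k];
  }
  return xyz;
}

// Additive surrogate interaction score; returns
// (total, hbond, electrostatic, vdw_att, clash, strain).
// [[Rcpp::export]]
NumericVector cpp_score(NumericMatrix lig, NumericMatrix site,
                        NumericVector ligq, NumericVector siteq,
                        LogicalVector acc, LogicalVector don,
                        NumericMatrix rminmat, IntegerVector strain_i,
                        IntegerVector strain_j, NumericVector strain_thr,
                        NumericMatrix box, double margin,
                        NumericVector weights) {
  int n = lig.nrow(), m = site.nrow();
  // out-of-box sentinel on the ligand centroid
  double ctr[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) ctr[k] += lig(i, k);
  for (int k = 0; k < 3; ++k) ctr[k] /= n;
  for (int k = 0; k < 3; ++k) {
    if (ctr[k] < box(0, k) - 2 * margin || ctr[k] > box(1, k) + 2 * margin) {
      NumericVector bad = NumericVector::create(R_NegInf, 0, 0, 0,
                                                R_PosInf, R_PosInf);
      return bad;
    }
  }
  double ele = 0, hb = 0, vdw_att = 0, clash = 0;
  // per-donor H-bond saturation: an ammonium-like donor contributes at
  // most 3 H-bond equivalents, so crowding acceptors around one donor
  // is not rewarded beyond its hydrogen count
  for (int j = 0; j < m; ++j) {
    double hbj = 0;
    for (int i = 0; i < n; ++i) {
      double dx = lig(i, 0) - site(j, 0);
      double dy = lig(i, 1) - site(j, 1);
      double dz = lig(i, 2) - site(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      // clamp at contact distance: burying charges inside each other
      // must not be rewarded beyond a formed salt bridge
      double dc = d < 2.8 ? 2.8 : d;
      ele += 332.0 * ligq[i] * siteq[j] / (4.0 * dc * dc);
      if (acc[i] && don[j]) {
        if (d <= 3.0) hbj += 1.0;
        else if (d < 3.5) hbj += (3.5 - d) / 0.5;
      }
      double x6 = std::pow(rminmat(i, j) / d, 6.0);
      double elj = 0.2 * (x6 * x6 - 2.0 * x6);
      if (elj > 0) clash += elj > 10.0 ? 10.0 : elj;
      else vdw_att -= elj;
    }
    hb += hbj > 3.0 ? 3.0 : hbj;
  }
  double strain = 0;
  for (int p = 0; p < strain_i.size(); ++p) {
    int a = strain_i[p] - 1, b = strain_j[p] - 1;
    double dx = lig(a, 0) - lig(b, 0);
    double dy = lig(a, 1) - lig(b, 1);
    double dz = lig(a, 2) - lig(b, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double v = strain_thr[p] - d;
    if (v > 0) strain += 5.0 * v * v;
  }
  double ele_att = ele < 0 ? -ele : 0;
  double ele_rep = ele > 0 ? ele : 0;
  double total = weights[0] * hb + weights[1] * ele_att +
    weights[2] * vdw_att - weights[3] * clash - weights[4] * strain -
    weights[1] * ele_rep;
  return NumericVector::create(total, hb, ele, vdw_att, clash, strain);
}
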