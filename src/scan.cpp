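#include <Rcpp.h>
using namespace Rcpp;

// Per-step chromosome x MT interaction scan.
//
// For every chromosome this computes, in one pass over all MTs:
//   * the summed polar ejection force (F_PEF times the unit direction of
//     every MT whose segment crosses the arm cross-section within r_C of
//     the chromosome centre);
//   * the nearest lateral-attachment candidate (minimum point-segment
//     distance <= r_k) among MTs eligible for the chromosome's active
//     motor, ties broken by the smaller MT index; tracks must emanate from
//     the chromosome's nearest pole (chromosomes ride the aster they sit
//     in, so motor transport is pole-ward for dynein and plate-ward for
//     CENP-E);
//   * for chromosomes flagged probe_cenpe (dynein-driven chromosomes held
//     at a pole), the nearest CENP-E-eligible track within r_k, which
//     triggers the dynein-to-CENP-E replacement;
//   * end-on tip contacts (tip within r_k of the centre) with the contacted
//     hemisphere, collected only for chromosomes with want_contacts set.
//
// Geometry is exactly the scalar definition used by the R predicates
// (arm_crossing_test, kinetochore_proximity_test, tip_contact_side); the
// equivalence is asserted by tests on random instances.
//
// arm_mode: 0 = disk normal to the pole-pole axis, 1 = sphere.
// motor:    1 = dynein (all MTs are eligible tracks),
//           2 = CENP-E (only MTs flagged in elig_cenpe).
// side:     1 = LEFT (-x hemisphere), 2 = RIGHT; ties go to the MT's pole.
// [[Rcpp::export]]
List scan_chromosomes_cpp(NumericMatrix origin, NumericMatrix dir,
                          NumericVector len, IntegerVector pole,
                          LogicalVector elig_cenpe,
                          NumericMatrix chrom_pos, IntegerVector motor,
                          IntegerVector near_pole,
                          LogicalVector want_lateral,
                          LogicalVector want_contacts,
                          LogicalVector probe_cenpe, double probe_r,
                          double r_C, double r_k, double F_PEF,
                          int arm_mode) {
  const int N = origin.nrow();
  const int nC = chrom_pos.nrow();
  const double rC2 = r_C * r_C;
  const double rk2 = r_k * r_k;
  const double pr2 = probe_r * probe_r;
  // any interaction needs the segment within rmax of the centre; the
  // segment cannot get closer than |centre - origin| - L, so MTs failing
  // that bound are skipped (exact prefilter, no geometry change)
  double rmax = r_C > r_k ? r_C : r_k;
  if (probe_r > rmax) rmax = probe_r;

  NumericMatrix pef(nC, 3);
  IntegerVector lat_mt(nC);          // 0 = none
  NumericVector lat_dist(nC);
  IntegerVector cenpe_track(nC);     // 0 = none
  std::vector<int> c_chrom, c_mt, c_side;

  // column pointers: contiguous access while sweeping over MTs
  const double *o1 = &origin(0, 0), *o2 = o1 + N, *o3 = o2 + N;
  const double *u1 = &dir(0, 0), *u2 = u1 + N, *u3 = u2 + N;
  const double *Lv = &len[0];
  const int *el = LOGICAL(elig_cenpe);
  const int *pl = &pole[0];

  for (int c = 0; c < nC; ++c) {
    const double cx = chrom_pos(c, 0), cy = chrom_pos(c, 1),
                 cz = chrom_pos(c, 2);
    double px = 0.0, py = 0.0, pz = 0.0;
    double best = R_PosInf, best_c = R_PosInf;
    int best_j = 0, best_cj = 0;
    const bool lat = want_lateral[c];
    const bool con = want_contacts[c];
    const bool prb = probe_cenpe[c];
    const bool cenpe = motor[c] == 2;
    const int npole = near_pole[c];

    for (int j = 0; j < N; ++j) {
      const double L = Lv[j];
      const double ox = o1[j], oy = o2[j], oz = o3[j];
      const double ex = cx - ox, ey = cy - oy, ez = cz - oz;
      const double e2 = ex * ex + ey * ey + ez * ez;
      const double reach = L + rmax;
      if (e2 > reach * reach) continue;
      const double dx = u1[j], dy = u2[j], dz = u3[j];

      // --- polar ejection force: arm crossing
      if (F_PEF > 0.0) {
        if (arm_mode == 0) {
          if (dx != 0.0) {
            const double t = (cx - ox) / dx;
            if (t >= 0.0 && t <= L) {
              const double wy = oy + t * dy - cy;
              const double wz = oz + t * dz - cz;
              if (wy * wy + wz * wz <= rC2) {
                px += dx; py += dy; pz += dz;
              }
            }
          }
        } else {
          // sphere cross-section: point-segment distance <= r_C
          double t = ex * dx + ey * dy + ez * dz;
          if (t < 0.0) t = 0.0; else if (t > L) t = L;
          const double wx = ox + t * dx - cx;
          const double wy = oy + t * dy - cy;
          const double wz = oz + t * dz - cz;
          if (wx * wx + wy * wy + wz * wz <= rC2) {
            px += dx; py += dy; pz += dz;
          }
        }
      }

      if (!lat && !con && !prb) continue;

      // --- point-segment distance to the kinetochore sphere centre
      double t = ex * dx + ey * dy + ez * dz;
      if (t < 0.0) t = 0.0; else if (t > L) t = L;
      const double qx = ox + t * dx - cx;
      const double qy = oy + t * dy - cy;
      const double qz = oz + t * dz - cz;
      const double d2 = qx * qx + qy * qy + qz * qz;

      if (pl[j] == npole) {
        if (lat && d2 <= rk2 && d2 < best && (!cenpe || el[j])) {
          // dynein rides any MT; CENP-E needs a long-lived interior track
          best = d2;
          best_j = j + 1;
        }
        // the pole-region probe reaches through the whole aster
        if (prb && el[j] && d2 <= pr2 && d2 < best_c) {
          best_c = d2;
          best_cj = j + 1;
        }
      }

      // --- end-on tip contact
      if (con) {
        const double tx = ox + L * dx - cx;
        const double ty = oy + L * dy - cy;
        const double tz = oz + L * dz - cz;
        if (tx * tx + ty * ty + tz * tz <= rk2) {
          int side;
          if (tx < 0.0) side = 1;
          else if (tx > 0.0) side = 2;
          else side = pl[j];
          c_chrom.push_back(c + 1);
          c_mt.push_back(j + 1);
          c_side.push_back(side);
        }
      }
    }
    pef(c, 0) = F_PEF * px;
    pef(c, 1) = F_PEF * py;
    pef(c, 2) = F_PEF * pz;
    lat_mt[c] = best_j;
    lat_dist[c] = best_j > 0 ? std::sqrt(best) : NA_REAL;
    cenpe_track[c] = best_cj;
  }

  return List::create(
    _["pef"] = pef,
    _["lat_mt"] = lat_mt,
    _["lat_dist"] = lat_dist,
    _["cenpe_track"] = cenpe_track,
    _["contact_chrom"] = wrap(c_chrom),
    _["contact_mt"] = wrap(c_mt),
    _["contact_side"] = wrap(c_side));
}
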