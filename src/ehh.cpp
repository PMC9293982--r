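#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity engine.
//
// Haplotypes are an n_hap x n_snp integer matrix of 0/1 alleles (0 =
// ancestral after polarization). All statistics extend outward from a core
// SNP, refining a partition of haplotypes into identity classes one SNP at a
// time, and report
//   EHH(s)  = sum_k n_k (n_k - 1) / (n_c (n_c - 1))
// over the carriers of one core allele (allele-specific), or over all
// haplotypes partitioned by the core allele (site EHHS). Site curves come in
// two flavours sharing one extension:
//   normalized   EHHS(s) = H(s) / H(core)      (Tang; 1 at the core)
//   unnormalized H(s)    = sum n_k(n_k-1)/(n(n-1))   (Sabeti)
// Extension stops when the *normalized* value drops below `cutoff` or the
// chromosome ends; integrals are trapezoids over physical distance with
// linear interpolation to the cutoff crossing.

namespace {

struct SideResult {
  double area_norm;    // integral of the normalized curve
  double area_unnorm;  // integral of the unnormalized curve (site mode)
  bool reached;        // cutoff reached before chromosome end?
  std::vector<int> snp;        // visited flanking SNP indices (0-based)
  std::vector<double> val;     // normalized EHH values at those SNPs
  std::vector<double> val_u;   // unnormalized values (site mode)
};

// Refine partition `cls` (length m, ids in [0, ncls)) by the alleles in
// column `col` at positions idx; returns sum over classes of n_k*(n_k-1).
inline double refine(std::vector<int> &cls, int &ncls, const int *col,
                     const std::vector<int> &idx) {
  const int m = (int)idx.size();
  std::vector<int> remap(2 * ncls, -1);
  std::vector<int> counts;
  counts.reserve(ncls + 1);
  int next = 0;
  for (int t = 0; t < m; ++t) {
    int key = 2 * cls[t] + col[idx[t]];
    if (remap[key] < 0) {
      remap[key] = next++;
      counts.push_back(0);
    }
    cls[t] = remap[key];
    counts[cls[t]]++;
  }
  ncls = next;
  double num = 0.0;
  for (int k = 0; k < next; ++k)
    num += (double)counts[k] * (double)(counts[k] - 1);
  return num;
}

// Extend from `core` in direction `dir` (+1/-1). `site` selects EHHS mode.
// `allele` selects carriers in allele mode. `collect` keeps the per-SNP
// curve (for user-facing curve functions); scans leave it off.
SideResult extend_side(const IntegerMatrix &haps, const NumericVector &pos,
                       int core, int dir, int allele, bool site,
                       double cutoff, bool collect) {
  const int nhap = haps.nrow(), nsnp = haps.ncol();
  const int *corecol = &haps(0, core);

  std::vector<int> idx;
  std::vector<int> cls;
  int ncls = 0;
  double denom, h0num = 0.0;

  if (site) {
    idx.resize(nhap);
    cls.resize(nhap);
    int n1 = 0;
    for (int i = 0; i < nhap; ++i) {
      idx[i] = i;
      cls[i] = corecol[i];
      n1 += corecol[i];
    }
    int n0 = nhap - n1;
    ncls = 2;  // ids 0/1 even if one class empty; refine() compresses
    h0num = (double)n0 * (n0 - 1) + (double)n1 * (n1 - 1);
    denom = (double)nhap * (nhap - 1);
    if (h0num <= 0.0) stop("site EHH undefined: fewer than 2 haplotypes");
  } else {
    for (int i = 0; i < nhap; ++i)
      if (corecol[i] == allele) idx.push_back(i);
    const int nc = (int)idx.size();
    if (nc < 2) stop("fewer than 2 carrier haplotypes of the core allele");
    cls.assign(nc, 0);
    ncls = 1;
    denom = (double)nc * (nc - 1);
    h0num = denom;  // normalized value 1 at core by construction
  }

  SideResult res;
  res.area_norm = 0.0;
  res.area_unnorm = 0.0;
  res.reached = false;

  double x_prev = pos[core];
  double vn_prev = 1.0;
  double vu_prev = h0num / denom;  // site: core homozygosity; allele: 1

  for (int s = core + dir; s >= 0 && s < nsnp; s += dir) {
    const int *col = &haps(0, s);
    double num = refine(cls, ncls, col, idx);
    double vn = num / h0num;
    double vu = num / denom;
    double x = pos[s];
    double dx = std::abs(x - x_prev);
    if (collect) {
      res.snp.push_back(s);
      res.val.push_back(vn);
      res.val_u.push_back(vu);
    }
    if (vn >= cutoff) {
      res.area_norm += dx * (vn_prev + vn) / 2.0;
      res.area_unnorm += dx * (vu_prev + vu) / 2.0;
      x_prev = x;
      vn_prev = vn;
      vu_prev = vu;
      if (num == 0.0) {  // all singletons; curve is 0 from here on
        res.reached = true;
        break;
      }
    } else {
      // linear interpolation to the cutoff crossing on the normalized curve
      double frac = (vn_prev - cutoff) / (vn_prev - vn);
      double xstar = x_prev + dir * dx * frac;
      double vustar = vu_prev + (vu - vu_prev) * frac;
      res.area_norm += std::abs(xstar - x_prev) * (vn_prev + cutoff) / 2.0;
      res.area_unnorm += std::abs(xstar - x_prev) * (vu_prev + vustar) / 2.0;
      res.reached = true;
      break;
    }
  }
  return res;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_ehh_side")]]
List cpp_ehh_side(IntegerMatrix haps, NumericVector pos, int core0,
                  int allele, bool site, double cutoff, int dir) {
  SideResult r =
      extend_side(haps, pos, core0, dir, allele, site, cutoff, true);
  return List::create(_["snp"] = wrap(r.snp), _["ehh"] = wrap(r.val),
                      _["ehh_unnorm"] = wrap(r.val_u),
                      _["area"] = r.area_norm,
                      _["area_unnorm"] = r.area_unnorm,
                      _["reached"] = r.reached);
}

// Genome scan: per-SNP two-sided integrals for both allele-specific curves
// (iHH_ancestral, iHH_derived) and the site curves (iES Tang-normalized,
// inES Sabeti-unnormalized), plus carrier counts and edge flags.
// [[Rcpp::export(name = ".cpp_scan_hh")]]
DataFrame cpp_scan_hh(IntegerMatrix haps, NumericVector pos, double cutoff,
                      double maf_min) {
  const int nhap = haps.nrow(), nsnp = haps.ncol();
  NumericVector freq1(nsnp), ihh0(nsnp, NA_REAL), ihh1(nsnp, NA_REAL),
      ies(nsnp, NA_REAL), ines(nsnp, NA_REAL);
  LogicalVector edge_allele(nsnp, false), edge_site(nsnp, false),
      maf_fail(nsnp, false);
  IntegerVector n0v(nsnp), n1v(nsnp);

  for (int j = 0; j < nsnp; ++j) {
    const int *col = &haps(0, j);
    int n1 = 0;
    for (int i = 0; i < nhap; ++i) n1 += col[i];
    int n0 = nhap - n1;
    n0v[j] = n0;
    n1v[j] = n1;
    double f1 = (double)n1 / nhap;
    freq1[j] = f1;
    double maf = f1 < 0.5 ? f1 : 1.0 - f1;

    // site curves: defined whenever >= 2 haplotypes and some homozygosity
    double h0 = (double)n0 * (n0 - 1) + (double)n1 * (n1 - 1);
    if (nhap >= 2 && h0 > 0) {
      SideResult L = extend_side(haps, pos, j, -1, 0, true, cutoff, false);
      SideResult R = extend_side(haps, pos, j, +1, 0, true, cutoff, false);
      ies[j] = L.area_norm + R.area_norm;
      ines[j] = L.area_unnorm + R.area_unnorm;
      edge_site[j] = !(L.reached && R.reached);
    } else {
      edge_site[j] = true;
    }

    // allele-specific curves feed iHS only; respect the core MAF filter
    if (maf < maf_min) {
      maf_fail[j] = true;
      continue;
    }
    if (n0 >= 2 && n1 >= 2) {
      SideResult L0 = extend_side(haps, pos, j, -1, 0, false, cutoff, false);
      SideResult R0 = extend_side(haps, pos, j, +1, 0, false, cutoff, false);
      SideResult L1 = extend_side(haps, pos, j, -1, 1, false, cutoff, false);
      SideResult R1 = extend_side(haps, pos, j, +1, 1, false, cutoff, false);
      ihh0[j] = L0.area_norm + R0.area_norm;
      ihh1[j] = L1.area_norm + R1.area_norm;
      edge_allele[j] = !(L0.reached && R0.reached && L1.reached && R1.reached);
    } else {
      edge_allele[j] = true;
    }
  }
  return DataFrame::create(
      _["freq_der"] = freq1, _["n_anc"] = n0v, _["n_der"] = n1v,
      _["ihh_anc"] = ihh0, _["ihh_der"] = ihh1, _["ies"] = ies,
      _["ines"] = ines, _["edge_allele"] = edge_allele,
      _["edge_site"] = edge_site, _["maf_fail"] = maf_fail);
}
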