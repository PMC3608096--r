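// Two-locus (disease x marker) pedigree likelihood by Elston-Stewart
// nuclear-family peeling.
//
// State space: each individual's ordered genotype is a pair of haplotypes
// (paternal, maternal), each haplotype h in {0..3} encoding
// h = 2*d + m with d the disease allele (0/1) and m the marker allele
// (0/1); genotype g = 4*h_pat + h_mat, 16 states.
//
// Likelihood = sum over all joint genotype configurations of
//   prod(founders)    HWE/linkage-equilibrium haplotype priors
// x prod(non-founders) transmission probs with recombination theta
// x prod(individuals)  penetrance (if phenotyped) and marker-dosage match.
//
// Peeling proceeds family by family over a schedule computed in R
// (valid for zero-loop pedigrees): each step collapses one nuclear family
// onto its pivot member (or to a scalar for the last family of a
// component). Carried with per-step rescaling; totals are returned in
// natural log so that 13-member pedigrees with q = 1e-5 do not underflow.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Step {
  int f, m, pivot;            // 0-based indices; pivot == -1 -> full sum
  std::vector<int> children;  // 0-based
};

// transmission matrix T[g][h]: P(transmit haplotype h | parent genotype g)
void transmission(double theta, double T[16][4]) {
  for (int g = 0; g < 16; ++g) {
    int h1 = g / 4, h2 = g % 4;
    int d1 = h1 >> 1, m1 = h1 & 1, d2 = h2 >> 1, m2 = h2 & 1;
    int r1 = 2 * d1 + m2, r2 = 2 * d2 + m1;
    for (int h = 0; h < 4; ++h) T[g][h] = 0.0;
    T[g][h1] += 0.5 * (1.0 - theta);
    T[g][h2] += 0.5 * (1.0 - theta);
    T[g][r1] += 0.5 * theta;
    T[g][r2] += 0.5 * theta;
  }
}

}  // namespace

// [[Rcpp::export(name = ".twoLocusLogLik")]]
NumericVector twoLocusLogLik(IntegerMatrix dosage,   // individuals x markers
                             NumericVector freq,     // alt freq per marker
                             List steps, IntegerVector rootIdx,
                             IntegerVector founder,   // 1 = founder
                             IntegerVector affection, // 0 unk, 1 unaff, 2 aff
                             NumericVector penetrance, // f0, f1, f2
                             double q, double theta) {
  const int n = dosage.nrow(), nm = dosage.ncol();
  std::vector<Step> sched;
  for (int s = 0; s < steps.size(); ++s) {
    List st = steps[s];
    Step step;
    step.f = as<int>(st["f"]);
    step.m = as<int>(st["m"]);
    step.pivot = as<int>(st["pivot"]);
    IntegerVector ch = st["children"];
    step.children.assign(ch.begin(), ch.end());
    sched.push_back(step);
  }

  double T[16][4];
  transmission(theta, T);

  // genotype-indexed lookups independent of the marker
  int gDisease[16], gMarker[16];
  for (int g = 0; g < 16; ++g) {
    int h1 = g / 4, h2 = g % 4;
    gDisease[g] = (h1 >> 1) + (h2 >> 1);
    gMarker[g] = (h1 & 1) + (h2 & 1);
  }
  double penFac[3][16];  // affection code x genotype
  for (int g = 0; g < 16; ++g) {
    penFac[0][g] = 1.0;
    penFac[1][g] = 1.0 - penetrance[gDisease[g]];
    penFac[2][g] = penetrance[gDisease[g]];
  }
  const double pd[2] = {1.0 - q, q};

  NumericVector out(nm);
  std::vector<double> pot(16 * n);

  for (int mk = 0; mk < nm; ++mk) {
    const double p = freq[mk];
    const double pm[2] = {1.0 - p, p};
    double hprior[4];
    for (int h = 0; h < 4; ++h) hprior[h] = pd[h >> 1] * pm[h & 1];

    double logL = 0.0;
    bool zero = false;

    for (int i = 0; i < n; ++i) {
      const int dos = dosage(i, mk);
      const int aff = affection[i];
      double* pi = &pot[16 * i];
      for (int g = 0; g < 16; ++g) {
        double v = penFac[aff][g];
        if (dos != NA_INTEGER && gMarker[g] != dos) v = 0.0;
        if (founder[i])
          v *= hprior[g / 4] * hprior[g % 4];
        pi[g] = v;
      }
    }

    for (size_t s = 0; s < sched.size() && !zero; ++s) {
      const Step& st = sched[s];
      const double* pf = &pot[16 * st.f];
      const double* pmo = &pot[16 * st.m];

      // per-child collapse A_c[gf][gm] = sum_gc pot[c][gc] T(gc|gf,gm)
      // combined across children into joint[gf*16+gm]
      std::vector<double> joint(256);
      for (int gf = 0; gf < 16; ++gf)
        for (int gm = 0; gm < 16; ++gm)
          joint[gf * 16 + gm] = pf[gf] * pmo[gm];
      for (size_t c = 0; c < st.children.size(); ++c) {
        const int ci = st.children[c];
        if (ci == st.pivot) continue;  // pivot child handled below
        const double* pc = &pot[16 * ci];
        // B[hp][gm] = sum_hm T[gm][hm] * pc[4*hp+hm]
        double B[4][16];
        for (int hp = 0; hp < 4; ++hp)
          for (int gm = 0; gm < 16; ++gm) {
            double acc = 0.0;
            for (int hm = 0; hm < 4; ++hm)
              acc += T[gm][hm] * pc[4 * hp + hm];
            B[hp][gm] = acc;
          }
        for (int gf = 0; gf < 16; ++gf)
          for (int gm = 0; gm < 16; ++gm) {
            double acc = 0.0;
            for (int hp = 0; hp < 4; ++hp)
              acc += T[gf][hp] * B[hp][gm];
            joint[gf * 16 + gm] *= acc;
          }
      }

      if (st.pivot == -1) {
        double tot = 0.0;
        for (int k = 0; k < 256; ++k) tot += joint[k];
        if (tot <= 0.0) { zero = true; break; }
        logL += std::log(tot);
      } else if (st.pivot == st.f || st.pivot == st.m) {
        const bool onF = (st.pivot == st.f);
        double msg[16];
        for (int gp = 0; gp < 16; ++gp) {
          double acc = 0.0;
          for (int go = 0; go < 16; ++go)
            acc += onF ? joint[gp * 16 + go] : joint[go * 16 + gp];
          msg[gp] = acc;
        }
        // joint already contains pot[pivot]; replace pivot potential
        double* pp = &pot[16 * st.pivot];
        double mx = 0.0;
        for (int g = 0; g < 16; ++g) {
          pp[g] = msg[g];
          if (pp[g] > mx) mx = pp[g];
        }
        if (mx <= 0.0) { zero = true; break; }
        for (int g = 0; g < 16; ++g) pp[g] /= mx;
        logL += std::log(mx);
      } else {
        // pivot is a child: fold parents and siblings onto its genotype
        const double* pc = &pot[16 * st.pivot];
        double msg[16];
        for (int g = 0; g < 16; ++g) msg[g] = 0.0;
        for (int gf = 0; gf < 16; ++gf)
          for (int gm = 0; gm < 16; ++gm) {
            const double w = joint[gf * 16 + gm];
            if (w == 0.0) continue;
            for (int hp = 0; hp < 4; ++hp) {
              const double tf = T[gf][hp];
              if (tf == 0.0) continue;
              for (int hm = 0; hm < 4; ++hm)
                msg[4 * hp + hm] += w * tf * T[gm][hm];
            }
          }
        double* pp = &pot[16 * st.pivot];
        double mx = 0.0;
        for (int g = 0; g < 16; ++g) {
          pp[g] = msg[g] * pc[g];
          if (pp[g] > mx) mx = pp[g];
        }
        if (mx <= 0.0) { zero = true; break; }
        for (int g = 0; g < 16; ++g) pp[g] /= mx;
        logL += std::log(mx);
      }
    }

    if (!zero) {
      for (int r = 0; r < rootIdx.size(); ++r) {
        const double* pr = &pot[16 * rootIdx[r]];
        double tot = 0.0;
        for (int g = 0; g < 16; ++g) tot += pr[g];
        if (tot <= 0.0) { zero = true; break; }
        logL += std::log(tot);
      }
    }
    out[mk] = zero ? R_NegInf : logL;
  }
  return out;
}
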