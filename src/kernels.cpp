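#include <Rcpp.h>
using namespace Rcpp;

// Ungapped extension of seed hits: count mismatches between each oriented
// read and the reference window starting at pos (1-based).  A hit whose
// window runs past the reference end is marked invalid (nmm = -1).
// [[Rcpp::export]]
IntegerVector cpp_count_mismatches(CharacterVector refs,
                                   IntegerVector ref_idx,
                                   IntegerVector pos,
                                   CharacterVector reads,
                                   IntegerVector read_idx) {
  const int n = ref_idx.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *ref = CHAR(STRING_ELT(refs, ref_idx[i] - 1));
    const char *rd  = CHAR(STRING_ELT(reads, read_idx[i] - 1));
    const int reflen = LENGTH(STRING_ELT(refs, ref_idx[i] - 1));
    const int rdlen  = LENGTH(STRING_ELT(reads, read_idx[i] - 1));
    const int p = pos[i] - 1;
    if (p < 0 || p + rdlen > reflen) { out[i] = -1; continue; }
    int mm = 0;
    for (int x = 0; x < rdlen; ++x)
      if (ref[p + x] != rd[x]) ++mm;
    out[i] = mm;
  }
  return out;
}

// Sequencer error process applied to fragment-end templates.  Per template
// base: deletion skips it, an insertion emits a uniform random base first,
// a substitution replaces the emitted base by a uniform different base.
// Emission stops at read_len; an exhausted template is padded with random
// bases.  Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_apply_errors(CharacterVector templates,
                                 double sub_err, double ins_err,
                                 double del_err, int read_len) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  const int n = templates.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const char *tpl = CHAR(STRING_ELT(templates, i));
    const int tlen = LENGTH(STRING_ELT(templates, i));
    buf.clear();
    for (int j = 0; j < tlen && (int)buf.size() < read_len; ++j) {
      if (del_err > 0 && unif_rand() < del_err) continue;
      if (ins_err > 0 && unif_rand() < ins_err)
        buf.push_back(BASES[(int)(unif_rand() * 4) & 3]);
      if ((int)buf.size() >= read_len) break;
      char b = tpl[j];
      if (sub_err > 0 && unif_rand() < sub_err) {
        char nb = BASES[(int)(unif_rand() * 4) & 3];
        while (nb == b) nb = BASES[(int)(unif_rand() * 4) & 3];
        b = nb;
      }
      buf.push_back(b);
    }
    while ((int)buf.size() < read_len)
      buf.push_back(BASES[(int)(unif_rand() * 4) & 3]);
    out[i] = buf;
  }
  return out;
}

// One E-step pass.  Candidates are grouped per read by cand_read (1-based,
// non-decreasing).  w holds log p(S|T,H) + log p(R|T,H,S) per candidate.
// Returns responsibilities, the summed pseudo-count increments for the
// Dirichlet/Beta posteriors (accumulated in candidate order, so results do
// not depend on any parallel partitioning), the entropy sum
// sum E_Z log E_Z, and the 1-based indices of reads whose candidates all
// underflowed (these are reassigned to the noise component by the caller).
// [[Rcpp::export]]
List cpp_estep(IntegerVector cand_read, IntegerVector t, IntegerVector h,
               NumericVector w, NumericVector elog_theta,
               NumericVector elog_phi, NumericVector elog_1mphi,
               int n_reads, int T) {
  const int C = cand_read.size();
  NumericVector resp(C);
  NumericVector alpha_add(T + 1), b1_add(T), b2_add(T);
  std::vector<int> underflow;
  double entropy = 0.0;
  int i = 0;
  std::vector<double> logrho;
  while (i < C) {
    int j = i;
    const int rd = cand_read[i];
    while (j < C && cand_read[j] == rd) ++j;
    logrho.resize(j - i);
    double mx = R_NegInf;
    for (int k = i; k < j; ++k) {
      const int tk = t[k];
      double lr = w[k] + elog_theta[tk] +
        (h[k] == 0 ? elog_phi[tk - 1] : elog_1mphi[tk - 1]);
      logrho[k - i] = lr;
      if (lr > mx) mx = lr;
    }
    if (mx == R_NegInf || !R_finite(mx)) {
      underflow.push_back(rd);
      for (int k = i; k < j; ++k) resp[k] = 0.0;
      i = j;
      continue;
    }
    double z = 0.0;
    for (int k = i; k < j; ++k) z += std::exp(logrho[k - i] - mx);
    for (int k = i; k < j; ++k) {
      double r = std::exp(logrho[k - i] - mx) / z;
      resp[k] = r;
      if (r > 0) {
        entropy += r * std::log(r);
        alpha_add[t[k]] += r;
        if (h[k] == 0) b1_add[t[k] - 1] += r; else b2_add[t[k] - 1] += r;
      }
    }
    i = j;
  }
  return List::create(_["resp"] = resp, _["alpha_add"] = alpha_add,
                      _["beta1_add"] = b1_add, _["beta2_add"] = b2_add,
                      _["entropy"] = entropy,
                      _["underflow_reads"] = wrap(underflow));
}

// sum_{n,c} E_Z[Z_nc] * log rho_nc under the expectations passed in;
// used for the ELBO data term after the M-step.  Zero-responsibility
// candidates contribute 0 even when log rho is -Inf.
// [[Rcpp::export]]
double cpp_weighted_logrho(IntegerVector t, IntegerVector h, NumericVector w,
                           NumericVector resp, NumericVector elog_theta,
                           NumericVector elog_phi, NumericVector elog_1mphi) {
  const int C = t.size();
  double s = 0.0;
  for (int k = 0; k < C; ++k) {
    if (resp[k] <= 0) continue;
    const int tk = t[k];
    s += resp[k] * (w[k] + elog_theta[tk] +
      (h[k] == 0 ? elog_phi[tk - 1] : elog_1mphi[tk - 1]));
  }
  return s;
}
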