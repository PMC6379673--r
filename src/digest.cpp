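#include <Rcpp.h>
using namespace Rcpp;

// Weighted sampling without replacement by successive draws, each draw
// proportional to the remaining weights. Marks chosen sites in `cut`.
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().
static void sample_cuts_inplace(const NumericVector& w, std::vector<double>& wk,
                                std::vector<char>& cut, int n_cuts) {
  const int m = w.size();
  double total = 0.0;
  for (int i = 0; i < m; ++i) {
    wk[i] = w[i];
    total += wk[i];
    cut[i] = 0;
  }
  for (int c = 0; c < n_cuts; ++c) {
    double r = unif_rand() * total;
    double acc = 0.0;
    int pick = -1;
    for (int i = 0; i < m; ++i) {
      if (cut[i]) continue;
      acc += wk[i];
      if (r <= acc) { pick = i; break; }
    }
    if (pick < 0) { // numerical slack at the upper edge: take last uncut site
      for (int i = m - 1; i >= 0; --i) {
        if (!cut[i]) { pick = i; break; }
      }
    }
    cut[pick] = 1;
    total -= wk[pick];
  }
}

// Digest templates until `target_fragments` fragments of exactly `keep_len`
// have been accumulated; each kept fragment is trimmed by `trim` on both
// sides and added to the per-base coverage of the template.
// [[Rcpp::export]]
List cpp_digest_coverage(IntegerVector positions, NumericVector weights,
                         int n_cuts, int keep_len, int trim,
                         double target_fragments, double max_templates,
                         int template_length) {
  const int m = positions.size();
  if (n_cuts > m) stop("n_cuts exceeds number of cleavage sites");
  NumericVector cov(template_length);
  std::vector<double> wk(m);
  std::vector<char> cut(m);
  double n_frag = 0.0, templates = 0.0;
  while (n_frag < target_fragments && templates < max_templates) {
    templates += 1.0;
    sample_cuts_inplace(weights, wk, cut, n_cuts);
    int prev = -1;
    for (int i = 0; i < m && n_frag < target_fragments; ++i) {
      if (!cut[i]) continue;
      if (prev >= 0) {
        int len = positions[i] - positions[prev];
        if (len == keep_len) {
          int s = positions[prev] + trim;
          int e = positions[i] - trim;
          for (int b = s; b < e; ++b) cov[b] += 1.0;
          n_frag += 1.0;
        }
      }
      prev = i;
    }
  }
  return List::create(_["values"] = cov, _["n_fragments"] = n_frag,
                      _["templates"] = templates);
}

// Digest `n_templates` copies of one template and return every fragment
// formed between consecutive cut positions, as 1-based site indices
// (from_idx, to_idx) into `positions`. Classification (mono/di, internal
// site kinds) is done by the caller against the site table.
// [[Rcpp::export]]
List cpp_digest_fragments(IntegerVector positions, NumericVector weights,
                          int n_cuts, int n_templates) {
  const int m = positions.size();
  if (n_cuts > m) stop("n_cuts exceeds number of cleavage sites");
  std::vector<int> from, to;
  from.reserve((size_t)n_templates * (n_cuts > 1 ? n_cuts - 1 : 1));
  to.reserve(from.capacity());
  std::vector<double> wk(m);
  std::vector<char> cut(m);
  for (int t = 0; t < n_templates; ++t) {
    sample_cuts_inplace(weights, wk, cut, n_cuts);
    int prev = -1;
    for (int i = 0; i < m; ++i) {
      if (!cut[i]) continue;
      if (prev >= 0) {
        from.push_back(prev + 1);
        to.push_back(i + 1);
      }
      prev = i;
    }
  }
  return List::create(_["from_idx"] = wrap(from), _["to_idx"] = wrap(to));
}
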