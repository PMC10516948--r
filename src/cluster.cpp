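#include <Rcpp.h>
using namespace Rcpp;

// Amino-acid k-mers are packed into 32-bit integers in base 27: residues
// A..Z map to 0..25, anything else (X, *, ...) to 26. k <= 6 keeps the
// largest code (27^6 - 1) below .Machine$integer.max.

// [[Rcpp::export]]
List aa_kmer_codes_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 6)
    stop("kmer_size must be between 1 and 6 for packed amino-acid k-mers");
  int n = seqs.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int len = (int)s.size();
    int nk = len - k + 1;
    if (nk < 1) {
      out[i] = IntegerVector(0);
      continue;
    }
    std::vector<int> codes;
    codes.reserve(nk);
    for (int p = 0; p < nk; ++p) {
      int code = 0;
      for (int j = 0; j < k; ++j) {
        char c = s[p + j];
        if (c >= 'a' && c <= 'z') c = c - 'a' + 'A';
        int v = (c >= 'A' && c <= 'Z') ? (c - 'A') : 26;
        code = code * 27 + v;
      }
      codes.push_back(code);
    }
    std::sort(codes.begin(), codes.end());
    codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
    out[i] = IntegerVector(codes.begin(), codes.end());
  }
  return out;
}

static double jaccard_sorted(const std::vector<int>& a, const std::vector<int>& b) {
  size_t i = 0, j = 0, inter = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { ++inter; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  double uni = (double)a.size() + (double)b.size() - (double)inter;
  return uni > 0 ? (double)inter / uni : 1.0;
}

// Greedy centroid clustering: genes arrive in the caller-supplied order;
// each joins the first centroid (founder k-mer set) with Jaccard >= threshold,
// otherwise founds a new cluster. Returns 1-based cluster indices in founding
// order.

// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(List kmer_sets, double threshold) {
  int n = kmer_sets.size();
  IntegerVector assign(n);
  std::vector<std::vector<int> > centroids;
  for (int i = 0; i < n; ++i) {
    IntegerVector kv = kmer_sets[i];
    std::vector<int> ks(kv.begin(), kv.end());
    double na = (double)ks.size();
    int hit = -1;
    for (size_t c = 0; c < centroids.size(); ++c) {
      double nb = (double)centroids[c].size();
      // size bound on Jaccard: skip centroids that cannot reach the threshold
      double bound = (na < nb ? na : nb) / (na > nb ? na : nb);
      if (na == 0 && nb == 0) bound = 1.0;
      if (bound < threshold) continue;
      if (jaccard_sorted(ks, centroids[c]) >= threshold) { hit = (int)c; break; }
    }
    if (hit < 0) {
      centroids.push_back(ks);
      hit = (int)centroids.size() - 1;
    }
    assign[i] = hit + 1;
  }
  return assign;
}

// [[Rcpp::export]]
double kmer_jaccard_cpp(IntegerVector a, IntegerVector b) {
  std::vector<int> va(a.begin(), a.end()), vb(b.begin(), b.end());
  return jaccard_sorted(va, vb);
}
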