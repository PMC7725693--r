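#include <Rcpp.h>
using namespace Rcpp;

// Overlap merge of one trimmed pair. a = forward mate, b = reverse mate
// already reverse-complemented; qa/qb integer Phred scores. Offset rule:
// among offsets with overlap >= min_overlap and mismatch fraction <=
// max_density, the longest overlap wins; ties go to the lowest mismatch
// count, then to the smallest offset. Consensus: higher-quality base at
// conflicts (tie -> forward base), max quality where mates agree.
// [[Rcpp::export]]
SEXP cpp_merge_pair(std::string a, std::string b,
                    IntegerVector qa, IntegerVector qb,
                    int min_overlap, double max_density) {
  int n1 = a.size(), n2 = b.size();
  if (n1 < min_overlap || n2 < min_overlap) return R_NilValue;
  int best_d = NA_INTEGER, best_o = -1, best_mm = -1;
  // overlap length decreases as |offset from full containment| grows;
  // enumerate offsets grouped by decreasing overlap
  for (int d = -(n2 - min_overlap); d <= n1 - min_overlap; d++) {
    int s = d > 0 ? d : 0;
    int e = (d + n2) < n1 ? (d + n2) : n1;
    int o = e - s;
    if (o < min_overlap) continue;
    if (best_o >= 0 && o < best_o) continue;   // cannot beat current best
    int mm = 0;
    int allowed = (int)std::floor(max_density * o + 1e-9);
    for (int i = s; i < e; i++) {
      if (a[i] != b[i - d]) {
        if (++mm > allowed) break;
      }
    }
    if (mm > allowed) continue;
    if (o > best_o || (o == best_o && (mm < best_mm ||
        (mm == best_mm && d < best_d)))) {
      best_o = o; best_mm = mm; best_d = d;
    }
  }
  if (best_o < 0) return R_NilValue;
  int d = best_d;
  int lo = d < 0 ? d : 0;
  int hi = (d + n2) > n1 ? (d + n2) : n1;
  int len = hi - lo;
  std::string seq(len, 'N');
  std::vector<int> qual(len, 0);
  for (int i = 0; i < n2; i++) {
    seq[i + d - lo] = b[i];
    qual[i + d - lo] = qb[i];
  }
  for (int i = 0; i < n1; i++) {
    int p = i - lo;
    if (d <= i && i < d + n2) {              // both mates cover
      int j = i - d;
      if (a[i] == b[j]) {
        qual[p] = qa[i] > qb[j] ? qa[i] : qb[j];
        seq[p] = a[i];
      } else if (qb[j] > qa[i]) {
        // keep reverse base already placed
      } else {
        seq[p] = a[i];
        qual[p] = qa[i];
      }
    } else {
      seq[p] = a[i];
      qual[p] = qa[i];
    }
  }
  std::string sup(len, '!');
  for (int i = 0; i < len; i++) {
    int q = qual[i] > 60 ? 60 : qual[i];
    sup[i] = (char)(q + 33);
  }
  return List::create(_["sequence"] = seq, _["support"] = sup);
}

// Hamming distances between one query and many equal-length subjects;
// NA where lengths differ.
// [[Rcpp::export]]
IntegerVector cpp_hamming_many(std::string q, CharacterVector subjects) {
  int n = subjects.size();
  IntegerVector out(n);
  int L = q.size();
  for (int k = 0; k < n; k++) {
    const char *s = CHAR(STRING_ELT(subjects, k));
    if ((int)strlen(s) != L) { out[k] = NA_INTEGER; continue; }
    int mm = 0;
    for (int i = 0; i < L; i++) if (q[i] != s[i]) mm++;
    out[k] = mm;
  }
  return out;
}
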