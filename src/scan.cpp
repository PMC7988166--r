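#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sliding-window haplotype homozygosity-deficiency scan over one
// chromosome of a phased panel.
//
// H: integer matrix of 0/1 alleles, 2N rows (two consecutive rows per
// individual), M columns (markers in map order).  For every window of
// k_min..k_max consecutive markers (start stepping by `step`), haplotype
// classes are built by incremental refinement: the class labelling for
// window (s, k) refines the labelling for (s, k-1) using marker s+k-1,
// so each extension costs O(2N).  Every class with at least
// ceil(min_q * 2N) copies is tested for homozygote deficiency with the
// lower-tail binomial probability P(X <= obs_hom), X ~ Bin(N, q^2),
// q = copies / 2N.
//
// Returns all test p-values (needed for Benjamini-Hochberg adjustment
// over every performed test) plus full records for tests with
// p < alpha_keep.
//
// A start position is abandoned early once no class has min_q copies:
// window extension only ever splits classes, so no longer window at that
// start can produce a testable haplotype.
// [[Rcpp::export(name = ".scan_chrom_cpp")]]
List scan_chrom_cpp(IntegerMatrix H, int k_min, int k_max, int step,
                    double min_q, double alpha_keep) {
  const int rows = H.nrow();      // 2N haplotypes
  const int M = H.ncol();
  const int N = rows / 2;
  if (rows % 2 != 0) stop("haplotype matrix must have an even number of rows");
  if (k_min < 2 || k_min > k_max) stop("need 2 <= k_min <= k_max");
  if (step < 1) stop("step must be >= 1");
  const int min_copies = (int)std::ceil(min_q * rows);

  std::vector<int> ids(rows), map_raw(2 * rows + 2, -1), touched;
  std::vector<int> copies(rows), rep_row(rows), hom(rows), car(rows);
  touched.reserve(rows);

  std::vector<double> all_p;          // every performed test, scan order
  std::vector<int> sig_start, sig_k, sig_copies, sig_car, sig_hom, sig_rep, sig_idx;
  std::vector<double> sig_p;
  long long n_windows = 0;

  for (int s = 0; s + k_min - 1 < M; s += step) {
    std::fill(ids.begin(), ids.end(), 0);
    int n_groups = 1;
    copies[0] = rows;
    rep_row[0] = 0;
    int kcap = std::min(k_max, M - s);
    for (int k = 1; k <= kcap; ++k) {
      // refine with marker column s + k - 1; rows retired below (id -1)
      // stay retired: extension only splits groups, so a haplotype class
      // that has dropped under min_copies can never become testable again
      const int *col = H.begin() + (size_t)(s + k - 1) * rows;
      int next_groups = 0, maxc = 0;
      touched.clear();
      for (int r = 0; r < rows; ++r) {
        if (ids[r] < 0) continue;
        int raw = 2 * ids[r] + col[r];
        int g = map_raw[raw];
        if (g < 0) {
          g = next_groups++;
          map_raw[raw] = g;
          touched.push_back(raw);
          copies[g] = 0;
          rep_row[g] = r;
        }
        ids[r] = g;
        if (++copies[g] > maxc) maxc = copies[g];
      }
      for (size_t t = 0; t < touched.size(); ++t) map_raw[touched[t]] = -1;
      n_groups = next_groups;

      if (maxc < min_copies) break;  // no testable haplotype at this or any longer k
      for (int r = 0; r < rows; ++r)
        if (ids[r] >= 0 && copies[ids[r]] < min_copies) ids[r] = -1;
      if (k < k_min) continue;
      ++n_windows;

      // carrier / homozygote counts per group (only groups that qualify)
      for (int g = 0; g < n_groups; ++g) { hom[g] = 0; car[g] = 0; }
      for (int i = 0; i < N; ++i) {
        int a = ids[2 * i], b = ids[2 * i + 1];
        if (a < 0 && b < 0) continue;
        if (a == b) { ++car[a]; ++hom[a]; }
        else {
          if (a >= 0) ++car[a];
          if (b >= 0) ++car[b];
        }
      }
      for (int g = 0; g < n_groups; ++g) {
        if (copies[g] < min_copies) continue;
        double q = (double)copies[g] / rows;
        double p = R::pbinom((double)hom[g], (double)N, q * q, 1, 0);
        all_p.push_back(p);
        if (p < alpha_keep) {
          sig_start.push_back(s + 1);          // 1-based marker index
          sig_k.push_back(k);
          sig_copies.push_back(copies[g]);
          sig_car.push_back(car[g]);
          sig_hom.push_back(hom[g]);
          sig_rep.push_back(rep_row[g] + 1);   // 1-based row
          sig_p.push_back(p);
          sig_idx.push_back((int)all_p.size()); // 1-based test index
        }
      }
    }
  }

  return List::create(
    _["p_all"] = NumericVector(all_p.begin(), all_p.end()),
    _["n_windows"] = (double)n_windows,
    _["start"] = IntegerVector(sig_start.begin(), sig_start.end()),
    _["k"] = IntegerVector(sig_k.begin(), sig_k.end()),
    _["copies"] = IntegerVector(sig_copies.begin(), sig_copies.end()),
    _["carriers"] = IntegerVector(sig_car.begin(), sig_car.end()),
    _["hom"] = IntegerVector(sig_hom.begin(), sig_hom.end()),
    _["rep_row"] = IntegerVector(sig_rep.begin(), sig_rep.end()),
    _["p"] = NumericVector(sig_p.begin(), sig_p.end()),
    _["test_idx"] = IntegerVector(sig_idx.begin(), sig_idx.end()));
}
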