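#include <Rcpp.h>
using namespace Rcpp;

// Median Phred score per read, from Phred+33 quality strings.
// Even-length convention: lower-middle order statistic, so the >=Q30
// screen stays integer-exact.
// [[Rcpp::export]]
IntegerVector cpp_median_phred(CharacterVector quals, int phred_offset = 33) {
  R_xlen_t n = quals.size();
  IntegerVector out(n);
  std::vector<int> buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (quals[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char* s = CHAR(quals[i]);
    size_t L = std::strlen(s);
    if (L == 0) { out[i] = NA_INTEGER; continue; }
    buf.assign(s, s + L);
    size_t k = (L + 1) / 2 - 1;  // lower-middle, 0-based
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    out[i] = buf[k] - phred_offset;
  }
  return out;
}

// Leftmost 1-based position p in each read where the read suffix starting at p
// equals the adapter prefix of length min(read_len - p + 1, adapter_len), with
// that overlap >= min_overlap. 0 when no match (read untouched).
// [[Rcpp::export]]
IntegerVector cpp_adapter_pos(CharacterVector seqs, std::string adapter,
                              int min_overlap) {
  R_xlen_t n = seqs.size();
  int alen = (int) adapter.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char* s = CHAR(seqs[i]);
    int L = (int) std::strlen(s);
    int hit = 0;
    for (int p = 0; p <= L - min_overlap; ++p) {
      int ov = std::min(L - p, alen);
      if (ov < min_overlap) break;
      bool ok = true;
      for (int k = 0; k < ov; ++k) {
        if (s[p + k] != adapter[k]) { ok = false; break; }
      }
      if (ok) { hit = p + 1; break; }
    }
    out[i] = hit;
  }
  return out;
}

// Ungapped <=max_mismatch assignment of query sequences against a mature
// miRNA reference. Containment mode: a query hits an entry if the shorter of
// the two matches somewhere inside the longer with Hamming distance
// <= max_mismatch over the full overlap (overlap = min length). End-to-end
// mode: equal lengths only. Early-exit exhaustive scan over entries/offsets;
// the contract is pinned by a pure-R exhaustive oracle in the test suite.
// Returns, per query: 1-based index of the (first) best entry or NA, the
// minimal mismatch count or NA, the number of tied best entries, and the tied
// candidate index set.
// [[Rcpp::export]]
List cpp_assign(CharacterVector queries, CharacterVector refs,
                int max_mismatch, bool containment) {
  R_xlen_t nq = queries.size(), nr = refs.size();
  std::vector<const char*> rs(nr);
  std::vector<int> rl(nr);
  for (R_xlen_t j = 0; j < nr; ++j) {
    rs[j] = CHAR(refs[j]);
    rl[j] = (int) std::strlen(rs[j]);
  }
  IntegerVector best_idx(nq), best_mm(nq), n_best(nq);
  List cand_list(nq);
  std::vector<int> cands;
  for (R_xlen_t i = 0; i < nq; ++i) {
    const char* q = CHAR(queries[i]);
    int L = (int) std::strlen(q);
    int best = max_mismatch + 1;
    cands.clear();
    for (R_xlen_t j = 0; j < nr; ++j) {
      int M = rl[j];
      if (!containment && L != M) continue;
      const char *inner, *outer;
      int ov, noff;
      if (L <= M) { inner = q; outer = rs[j]; ov = L; noff = M - L; }
      else        { inner = rs[j]; outer = q; ov = M; noff = L - M; }
      int entry_best = max_mismatch + 1;
      for (int off = 0; off <= noff; ++off) {
        int mm = 0;
        const char* w = outer + off;
        for (int k = 0; k < ov; ++k) {
          if (inner[k] != w[k]) { if (++mm > max_mismatch) break; }
        }
        if (mm < entry_best) entry_best = mm;
        if (entry_best == 0) break;
      }
      if (entry_best < best) {
        best = entry_best;
        cands.clear();
        cands.push_back((int) j + 1);
      } else if (entry_best == best && best <= max_mismatch) {
        cands.push_back((int) j + 1);
      }
    }
    if (best <= max_mismatch) {
      best_idx[i] = cands[0];
      best_mm[i] = best;
      n_best[i] = (int) cands.size();
      cand_list[i] = IntegerVector(cands.begin(), cands.end());
    } else {
      best_idx[i] = NA_INTEGER;
      best_mm[i] = NA_INTEGER;
      n_best[i] = 0;
      cand_list[i] = IntegerVector(0);
    }
  }
  return List::create(_["best_idx"] = best_idx, _["mismatches"] = best_mm,
                      _["n_best"] = n_best, _["candidates"] = cand_list);
}
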