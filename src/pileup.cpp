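#include <Rcpp.h>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// Accumulate per-position base counts and base-quality sums for one genome
// from origin-placed reads. Sequences must already be oriented to the plus
// strand of the reference; bases below min_base_qual (or non-ACGT) are
// skipped, mirroring the base-quality floor a pileup engine applies.
//
// When clip_tails is true a read is soft-clipped from the first position at
// which at least 4 of the next 8 bases mismatch the reference (windows
// shorter than 6 bases never trigger). This emulates how a gapped aligner
// absorbs or clips the shifted tail a read carries after an indel
// sequencing error; isolated mismatches (true SNPs, miscalls) are
// unaffected.
// [[Rcpp::export]]
List pileup_accumulate(IntegerVector starts, CharacterVector seqs,
                       CharacterVector quals, std::string ref,
                       int min_base_qual, bool clip_tails) {
  int glen = (int)ref.size();
  IntegerMatrix counts(4, glen);
  NumericMatrix qualsum(4, glen);
  int n = starts.size();
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    const char *q = CHAR(STRING_ELT(quals, i));
    int L = LENGTH(STRING_ELT(seqs, i));
    if (LENGTH(STRING_ELT(quals, i)) != L)
      stop("sequence/quality length mismatch");
    int start = starts[i];
    if (start < 1 || start + L - 1 > glen)
      stop("read origin outside reference bounds");
    const char *r = ref.c_str() + (start - 1);

    int keep = L;
    if (clip_tails) {
      for (int j = 0; j + 6 <= L; ++j) {
        int w = (L - j < 8) ? (L - j) : 8;
        int mm = 0;
        for (int k = 0; k < w; ++k)
          if (s[j + k] != r[j + k]) ++mm;
        if (mm >= 4) { keep = j; break; }
      }
    }
    for (int j = 0; j < keep; ++j) {
      int qv = (int)q[j] - 33;
      if (qv < min_base_qual) continue;
      int b = base_code(s[j]);
      if (b < 0) continue;
      int p = start - 1 + j;
      counts(b, p) += 1;
      qualsum(b, p) += qv;
    }
  }
  return List::create(_["counts"] = counts, _["qualsum"] = qualsum);
}
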