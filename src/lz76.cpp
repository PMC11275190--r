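#include <Rcpp.h>

// LZ76 exhaustive-history parsing (Kaspar & Schindelin's pointer scheme).
// Each new phrase is the shortest prefix of the remaining sequence that
// cannot be reproduced by copying from the already-seen text (the copy
// source may run into the phrase itself).  The terminal phrase counts even
// if it is still reproducible when the sequence ends.
// [[Rcpp::export]]
int lz76_phrases_cpp(Rcpp::IntegerVector bits) {
  const int n = bits.size();
  if (n == 0) return 0;
  int c = 1;       // phrase count (first symbol is always a phrase)
  int u = 1;       // start of the current phrase
  int v = 1;       // length of the current candidate extension
  int i = 0;       // candidate copy-source start
  int vmax = 1;    // longest reproducible extension seen for this phrase
  while (u + v <= n) {
    if (bits[i + v - 1] == bits[u + v - 1]) {
      ++v;
    } else {
      if (v > vmax) vmax = v;
      ++i;
      if (i == u) {            // every source start failed: phrase complete
        ++c;
        u += vmax;
        v = 1;
        i = 0;
        vmax = 1;
      } else {
        v = 1;
      }
    }
  }
  if (v != 1) ++c;             // unfinished (still reproducible) last phrase
  return c;
}
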