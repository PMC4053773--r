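// Dinucleotide-preserving shuffle (Altschul-Erickson Eulerian-walk
// construction). The dinucleotide multigraph of the sequence is walked in a
// random order whose per-vertex last edges form a uniformly sampled
// arborescence into the terminal residue (accept/reject), so every
// dinucleotide-preserving permutation is generated and the original
// dinucleotide multiset is conserved exactly. Uses R's RNG so results are
// reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline int code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
CharacterVector dinuc_shuffle_cpp(std::string seq, int B) {
  const int n = (int)seq.size();
  if (n < 2) stop("sequence must have length >= 2");
  std::vector<int> ch(n);
  for (int i = 0; i < n; ++i) {
    int c = code(seq[i]);
    if (c < 0) stop("non-ACGT character in sequence");
    ch[i] = c;
  }
  std::vector<std::vector<int> > edges(4);
  for (int i = 0; i + 1 < n; ++i) edges[ch[i]].push_back(ch[i + 1]);
  const int s0 = ch[0], last = ch[n - 1];
  const char *letters = "ACGT";

  CharacterVector out(B);
  std::string buf(n, 'A');
  std::vector<int> ord[4];
  for (int b = 0; b < B; ++b) {
    int le[4];
    for (;;) {  // sample last edges until they form a tree into `last`
      for (int v = 0; v < 4; ++v)
        le[v] = (v == last || edges[v].empty())
          ? -1 : edges[v][rand_below((int)edges[v].size())];
      bool ok = true;
      for (int v = 0; v < 4 && ok; ++v) {
        if (v == last || edges[v].empty()) continue;
        int cur = v, steps = 0;
        while (cur != last) {
          if (steps > 4 || le[cur] < 0) { ok = false; break; }
          cur = le[cur];
          ++steps;
        }
      }
      if (ok) break;
    }
    for (int v = 0; v < 4; ++v) {
      ord[v] = edges[v];
      if (ord[v].empty()) continue;
      int keep = (int)ord[v].size();
      if (le[v] >= 0) {  // move one instance of the last edge to the back
        for (int i = 0; i < keep; ++i)
          if (ord[v][i] == le[v]) { std::swap(ord[v][i], ord[v][keep - 1]); break; }
        --keep;
      }
      for (int i = keep - 1; i > 0; --i) {  // Fisher-Yates on the rest
        int j = rand_below(i + 1);
        std::swap(ord[v][i], ord[v][j]);
      }
    }
    int ptr[4] = {0, 0, 0, 0};
    int cur = s0;
    buf[0] = letters[s0];
    for (int i = 1; i < n; ++i) {
      int nxt = ord[cur][ptr[cur]++];
      buf[i] = letters[nxt];
      cur = nxt;
    }
    out[b] = buf;
  }
  return out;
}
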