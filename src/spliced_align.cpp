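#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Spliced protein-to-genome alignment, local in both sequences.
//
// Grammar: an alignment is a chain of exons. Within an exon the protein is
// aligned codon-wise (residue vs codon match, whole-codon deletion in the
// DNA, residue insertion in the protein) under affine gap costs. Introns
// join exons at codon boundaries, must begin GT and end AG, must be at least
// min_intron bases long, and cost a flat penalty. Gap runs never span an
// intron (crossing a junction re-opens a gap) and insertions attach to the
// exon on their left. Codons containing N are impassable, so assembly gap
// runs can only be crossed inside introns. The optimum is found by dynamic
// programming with a per-protein-row running maximum over donor sites, which
// keeps the whole computation O(m * n).

static const float NEG = -1e30f;

struct TB {
  // traceback codes: 0 = local start, 1 = from M, 2 = from Ix, 3 = from Iy,
  // 4 = spliced (donor recorded separately)
  std::vector<unsigned char> m, x, y;
  std::vector<int> dm, dy; // donor positions for spliced transitions
};

// [[Rcpp::export(name = ".cpp_spliced_align")]]
List cpp_spliced_align(IntegerVector prot, IntegerVector codon_aa,
                       LogicalVector is_gt, LogicalVector is_ag_end,
                       IntegerMatrix submat,
                       double gap_open, double gap_extend,
                       double intron_penalty, int min_intron) {
  const int m = prot.size();
  const int n = codon_aa.size(); // one entry per dna position (codon start)
  const size_t W = (size_t)(n + 1);
  const size_t sz = (size_t)(m + 1) * W;

  std::vector<float> M(sz, NEG), Ix(sz, NEG), Iy(sz, NEG);
  TB tb;
  tb.m.assign(sz, 0); tb.x.assign(sz, 0); tb.y.assign(sz, 0);
  tb.dm.assign(sz, -1); tb.dy.assign(sz, -1);

  // running max over donor sites per protein row, and its argmax
  std::vector<float> RM((size_t)m + 1, NEG);
  std::vector<int> DA((size_t)m + 1, -1);

  const float go = (float)gap_open, ge = (float)gap_extend;
  const float ip = (float)intron_penalty;

  float best = 0.0f; int bi = -1, bj = -1;

  for (int j = 0; j <= n; ++j) {
    // admit donor d such that acceptor a = j - 3 satisfies a - d >= min_intron
    int d = j - 3 - min_intron;
    if (d >= 0 && d + 1 < n && is_gt[d]) {
      for (int i = 0; i <= m; ++i) {
        size_t cd = (size_t)i * W + d;
        float e = M[cd] > Iy[cd] ? M[cd] : Iy[cd];
        if (e > RM[i]) { RM[i] = e; DA[i] = d; }
      }
    }
    const int a = j - 3;
    const int cod = (a >= 0 && a < n) ? codon_aa[a] : -1;
    const bool acc = (a >= 2) ? (bool)is_ag_end[a] : false;

    for (int i = 0; i <= m; ++i) {
      const size_t c = (size_t)i * W + j;

      // Ix: consume protein residue i, no DNA
      if (i >= 1) {
        const size_t p = (size_t)(i - 1) * W + j;
        float v = NEG; unsigned char o = 0;
        if (M[p] > NEG / 2 && M[p] + go > v) { v = M[p] + go; o = 1; }
        if (Ix[p] > NEG / 2 && Ix[p] + ge > v) { v = Ix[p] + ge; o = 2; }
        if (Iy[p] > NEG / 2 && Iy[p] + go > v) { v = Iy[p] + go; o = 3; }
        Ix[c] = v; tb.x[c] = o;
      }

      if (cod >= 0) {
        // M: match protein residue i against codon [a, j)
        if (i >= 1) {
          const float s = (float)submat(prot[i - 1], cod);
          const size_t p = (size_t)(i - 1) * W + a;
          float v = 0.0f; unsigned char o = 0; int don = -1; // local start
          if (M[p] > NEG / 2 && M[p] > v) { v = M[p]; o = 1; }
          if (Ix[p] > NEG / 2 && Ix[p] > v) { v = Ix[p]; o = 2; }
          if (Iy[p] > NEG / 2 && Iy[p] > v) { v = Iy[p]; o = 3; }
          if (acc && RM[i - 1] > NEG / 2 && RM[i - 1] + ip > v) {
            v = RM[i - 1] + ip; o = 4; don = DA[i - 1];
          }
          M[c] = v + s; tb.m[c] = o; tb.dm[c] = don;
          if (M[c] > best) { best = M[c]; bi = i; bj = j; }
        }
        // Iy: delete codon [a, j)
        {
          const size_t p = (size_t)i * W + a;
          float v = NEG; unsigned char o = 0; int don = -1;
          if (M[p] > NEG / 2 && M[p] + go > v) { v = M[p] + go; o = 1; }
          if (Ix[p] > NEG / 2 && Ix[p] + go > v) { v = Ix[p] + go; o = 2; }
          if (Iy[p] > NEG / 2 && Iy[p] + ge > v) { v = Iy[p] + ge; o = 3; }
          if (acc && RM[i] > NEG / 2 && RM[i] + ip + go > v) {
            v = RM[i] + ip + go; o = 4; don = DA[i];
          }
          Iy[c] = v; tb.y[c] = o; tb.dy[c] = don;
        }
      }
    }
  }

  if (bi < 0 || best <= 0.0f) {
    return List::create(_["score"] = 0.0,
                        _["exons"] = IntegerMatrix(0, 4),
                        _["n_aligned"] = 0);
  }

  // traceback from best M cell; collect (genomic, protein) steps per exon
  std::vector<std::vector<int>> exons; // each: gstart, gend, pstart, pend
  int i = bi, j = bj, st = 1; // st: 1 = M, 2 = Ix, 3 = Iy
  int g_end = j, p_end = bi, p_start = bi, g_start = j;
  bool open_exon = true;
  int cur_gend = j, cur_pend = bi, cur_gstart = j, cur_pstart = bi;
  (void)g_end; (void)p_end; (void)g_start; (void)p_start; (void)open_exon;

  for (;;) {
    const size_t c = (size_t)i * W + j;
    if (st == 1) { // M consumed residue i and codon [j-3, j)
      cur_gstart = j - 3; cur_pstart = i - 1;
      unsigned char o = tb.m[c];
      if (o == 0) break;
      if (o == 4) {
        int don = tb.dm[c];
        exons.push_back({cur_gstart, cur_gend, cur_pstart, cur_pend});
        j = don; i = i - 1;
        // resume in best E state at donor
        size_t cd = (size_t)i * W + j;
        st = (M[cd] >= Iy[cd]) ? 1 : 3;
        cur_gend = j; cur_pend = i; cur_gstart = j; cur_pstart = i;
        continue;
      }
      i -= 1; j -= 3; st = o;
    } else if (st == 2) { // Ix consumed residue i only
      cur_pstart = i - 1;
      unsigned char o = tb.x[c];
      i -= 1; st = o;
      if (o == 0) break;
    } else { // Iy consumed codon [j-3, j)
      cur_gstart = j - 3;
      unsigned char o = tb.y[c];
      if (o == 4) {
        int don = tb.dy[c];
        exons.push_back({cur_gstart, cur_gend, cur_pstart, cur_pend});
        j = don;
        size_t cd = (size_t)i * W + j;
        st = (M[cd] >= Iy[cd]) ? 1 : 3;
        cur_gend = j; cur_pend = i; cur_gstart = j; cur_pstart = i;
        continue;
      }
      j -= 3; st = o;
      if (o == 0) break; // should not happen (Iy has no start)
    }
  }
  exons.push_back({cur_gstart, cur_gend, cur_pstart, cur_pend});

  const int k = (int)exons.size();
  IntegerMatrix em(k, 4);
  for (int t = 0; t < k; ++t) { // reverse: traceback collected right-to-left
    const std::vector<int>& e = exons[(size_t)(k - 1 - t)];
    em(t, 0) = e[0]; em(t, 1) = e[1]; em(t, 2) = e[2]; em(t, 3) = e[3];
  }
  int n_aligned = exons.back()[3] >= 0 ? (bi - exons.back()[2]) : 0;
  return List::create(_["score"] = (double)best,
                      _["exons"] = em,
                      _["n_aligned"] = n_aligned);
}

// Best ungapped full-overlap match of a short query against a longer
// sequence. N in either sequence never matches. Returns c(best_matches,
// best_offset) with the smallest offset winning ties.
// [[Rcpp::export(name = ".cpp_best_ungapped")]]
IntegerVector cpp_best_ungapped(std::string query, std::string subject) {
  const int m = (int)query.size(), n = (int)subject.size();
  int best = -1, off = -1;
  if (m == 0 || n < m) return IntegerVector::create(0, -1);
  for (int s = 0; s + m <= n; ++s) {
    int hits = 0;
    for (int t = 0; t < m; ++t) {
      char a = query[t], b = subject[s + t];
      if (a != 'N' && b != 'N' && a == b) ++hits;
    }
    if (hits > best) { best = hits; off = s; }
  }
  return IntegerVector::create(best, off);
}
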