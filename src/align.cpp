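// Affine-gap Smith-Waterman local alignment with traceback.
// Scoring convention: match adds +match; mismatch adds -mismatch; a gap of
// length L costs gap_open + L * gap_extend (open charged once, extend per
// base). All penalty arguments are passed as positive numbers.
//
// Score recurrences use rolling rows; the traceback is one packed byte per
// cell (2 bits for the move, 2 flag bits marking where a gap was opened),
// and the workspace is reused across the reads of a batch.

#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

struct AlnResult {
  double score;
  int read_start, read_end;  // 0-based half-open on the read
  int ref_start, ref_end;    // 0-based half-open on the reference
  std::string cigar;         // with leading/trailing S for unaligned ends
  int nm;                    // mismatches + inserted + deleted bases
};

// traceback byte layout
static const unsigned char MOVE_MASK = 0x03;  // 0 stop, 1 diag, 2 up, 3 left
static const unsigned char E_OPEN = 0x04;     // vertical gap opened here
static const unsigned char F_OPEN = 0x08;     // horizontal gap opened here

struct Workspace {
  std::vector<double> Hprev, Hcur, E;
  std::vector<unsigned char> tb;
};

static AlnResult sw_core(const std::string& read, const std::string& ref,
                         double match, double mismatch,
                         double gap_open, double gap_extend,
                         Workspace& ws) {
  const int m = (int)read.size(), n = (int)ref.size();
  const double NEG = -1e18;
  ws.Hprev.assign(n + 1, 0.0);
  ws.Hcur.assign(n + 1, 0.0);
  ws.E.assign(n + 1, NEG);
  ws.tb.assign((size_t)m * n, 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    double f = NEG;               // horizontal gap score within this row
    ws.Hcur[0] = 0.0;
    const char rb = read[i - 1];
    unsigned char* tbrow = &ws.tb[(size_t)(i - 1) * n];
    for (int j = 1; j <= n; ++j) {
      unsigned char flags = 0;
      // E: vertical move (consumes a read base; CIGAR I)
      double e_open = ws.Hprev[j] - gap_open - gap_extend;
      double e_ext  = ws.E[j] - gap_extend;
      if (e_open >= e_ext) { ws.E[j] = e_open; flags |= E_OPEN; }
      else ws.E[j] = e_ext;
      // F: horizontal move (consumes a ref base; CIGAR D)
      double f_open = ws.Hcur[j - 1] - gap_open - gap_extend;
      double f_ext  = f - gap_extend;
      if (f_open >= f_ext) { f = f_open; flags |= F_OPEN; }
      else f = f_ext;
      double h = ws.Hprev[j - 1] + (rb == ref[j - 1] ? match : -mismatch);
      unsigned char mv = 1;
      if (ws.E[j] > h) { h = ws.E[j]; mv = 2; }
      if (f > h) { h = f; mv = 3; }
      if (h <= 0.0) { h = 0.0; mv = 0; }
      ws.Hcur[j] = h;
      tbrow[j - 1] = (unsigned char)(flags | mv);
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(ws.Hprev, ws.Hcur);
  }

  AlnResult res;
  res.score = best;
  if (best <= 0.0) {
    res.read_start = res.read_end = res.ref_start = res.ref_end = 0;
    res.cigar = ""; res.nm = 0;
    return res;
  }
  std::vector<std::pair<char, int> > ops;  // reversed order
  int i = bi, j = bj, nm = 0;
  auto push = [&](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  while (i > 0 && j > 0) {
    unsigned char t = ws.tb[(size_t)(i - 1) * n + (j - 1)];
    unsigned char mv = t & MOVE_MASK;
    if (mv == 0) break;
    if (mv == 1) {
      push('M');
      if (read[i - 1] != ref[j - 1]) ++nm;
      --i; --j;
    } else if (mv == 2) {          // vertical gap: CIGAR I
      while (true) {
        unsigned char tt = ws.tb[(size_t)(i - 1) * n + (j - 1)];
        push('I'); ++nm; --i;
        if (tt & E_OPEN) break;
      }
    } else {                       // horizontal gap: CIGAR D
      while (true) {
        unsigned char tt = ws.tb[(size_t)(i - 1) * n + (j - 1)];
        push('D'); ++nm; --j;
        if (tt & F_OPEN) break;
      }
    }
  }
  res.read_start = i; res.read_end = bi;
  res.ref_start = j;  res.ref_end = bj;
  res.nm = nm;
  std::string cig;
  if (i > 0) cig += std::to_string(i) + "S";
  for (int q = (int)ops.size() - 1; q >= 0; --q)
    cig += std::to_string(ops[q].second) + ops[q].first;
  if (m - bi > 0) cig += std::to_string(m - bi) + "S";
  res.cigar = cig;
  return res;
}

// [[Rcpp::export(name = ".sw_align_batch")]]
DataFrame sw_align_batch(CharacterVector reads, std::string ref,
                         double match, double mismatch,
                         double gap_open, double gap_extend) {
  const int n = reads.size();
  NumericVector score(n);
  IntegerVector read_start(n), read_end(n), ref_start(n), ref_end(n), nm(n);
  CharacterVector cigar(n);
  Workspace ws;
  for (int i = 0; i < n; ++i) {
    AlnResult r = sw_core(as<std::string>(reads[i]), ref,
                          match, mismatch, gap_open, gap_extend, ws);
    score[i] = r.score;
    read_start[i] = r.read_start; read_end[i] = r.read_end;
    ref_start[i] = r.ref_start;   ref_end[i] = r.ref_end;
    cigar[i] = r.cigar; nm[i] = r.nm;
  }
  return DataFrame::create(
    _["score"] = score,
    _["read_start"] = read_start, _["read_end"] = read_end,
    _["ref_start"] = ref_start,   _["ref_end"] = ref_end,
    _["cigar"] = cigar, _["nm"] = nm,
    _["stringsAsFactors"] = false);
}
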