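#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes; -1 for anything outside A/C/G/T
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp_base(c);
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// k-mer index over the (possibly circularly extended) reference.
// Positions are 0-based starts in the extended sequence.
struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<int>> pos;
};

static void build_index(const std::string& ext, int k, KmerIndex& idx) {
  idx.k = k;
  const int n = (int)ext.size();
  if (k > n) return;
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;  // length of current valid (ACGT-only) run
  for (int i = 0; i < n; ++i) {
    int c = base_code(ext[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx.pos[key].push_back(i - k + 1);
  }
}

// Count mismatches of read against ext[start ..]; bail out above cap.
static int count_mm(const std::string& read, const std::string& ext,
                    int start, int cap) {
  int mm = 0;
  const int len = (int)read.size();
  for (int i = 0; i < len; ++i) {
    int a = base_code(read[i]), b = base_code(ext[start + i]);
    if (a < 0 || b < 0 || a != b) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// Collect candidate start positions (0-based, on [0, L)) for one read
// orientation via exact k-mer seeds.
static void seed_candidates(const std::string& read, const KmerIndex& idx,
                            int L, int ext_len, std::vector<int>& cand) {
  const int k = idx.k;
  const int len = (int)read.size();
  if (len < k) return;
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < len; ++i) {
    int c = base_code(read[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      int off = i - k + 1;
      auto it = idx.pos.find(key);
      if (it == idx.pos.end()) continue;
      for (int p : it->second) {
        int start = p - off;
        if (start >= 0 && start < L && start + len <= L + ext_len)
          cand.push_back(start);
      }
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
}

// Map a batch of reads against one reference.
//
// Best ungapped placement over both strands minimising mismatches.
// mapq: 60 if unique or second best has >= 3 more mismatches; 25 * delta
// for delta in {1,2}; 0 on ties.  Placements with mismatch count above
// floor(max_mm_frac * len) are rejected.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, std::string ref, bool circular,
                   int k, double max_mm_frac) {
  const int L = (int)ref.size();
  const int nreads = reads.size();
  int max_len = 0;
  for (int i = 0; i < nreads; ++i) {
    int len = LENGTH(STRING_ELT(reads, i));
    if (len > max_len) max_len = len;
  }
  int ext_len = circular ? std::min(max_len > 0 ? max_len - 1 : 0, L) : 0;
  std::string ext = ref + ref.substr(0, ext_len);

  KmerIndex idx;
  build_index(ext, k, idx);

  IntegerVector out_start(nreads), out_mm(nreads), out_mapq(nreads),
      out_len(nreads);
  LogicalVector out_mapped(nreads);
  CharacterVector out_strand(nreads);

  std::vector<int> cand;
  for (int r = 0; r < nreads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);
    const int len = (int)fwd.size();
    const int cap = (int)std::floor(max_mm_frac * len);

    int best_mm = cap + 1, best_start = -1;
    char best_strand = '+';
    int second_mm = cap + 1;
    bool tie = false;

    for (int s = 0; s < 2; ++s) {
      const std::string& read = (s == 0) ? fwd : rev;
      cand.clear();
      if (len <= L + ext_len) seed_candidates(read, idx, L, ext_len, cand);
      for (int start : cand) {
        int mm = count_mm(read, ext, start, cap);
        if (mm > cap) continue;
        if (mm < best_mm) {
          second_mm = best_mm;
          best_mm = mm; best_start = start; best_strand = (s == 0) ? '+' : '-';
          tie = false;
        } else if (mm == best_mm &&
                   !(start == best_start && ((s == 0) == (best_strand == '+')))) {
          tie = true;
          if (mm < second_mm) second_mm = mm;
        } else if (mm < second_mm) {
          second_mm = mm;
        }
      }
    }

    if (best_start < 0) {
      out_mapped[r] = false;
      out_start[r] = NA_INTEGER; out_mm[r] = NA_INTEGER;
      out_mapq[r] = NA_INTEGER; out_len[r] = len;
      out_strand[r] = NA_STRING;
      continue;
    }
    int mapq;
    if (tie) {
      mapq = 0;
    } else if (second_mm > cap) {
      mapq = 60;  // no competing valid placement
    } else {
      int delta = second_mm - best_mm;
      mapq = (delta >= 3) ? 60 : 25 * delta;
      if (mapq > 60) mapq = 60;
    }
    out_mapped[r] = true;
    out_start[r] = best_start;
    out_mm[r] = best_mm;
    out_mapq[r] = mapq;
    out_len[r] = len;
    out_strand[r] = (best_strand == '+') ? "+" : "-";
  }

  return List::create(_["mapped"] = out_mapped, _["start"] = out_start,
                      _["strand"] = out_strand, _["n_mismatch"] = out_mm,
                      _["mapq"] = out_mapq, _["aligned_len"] = out_len);
}

// Exhaustive all-positions/all-strands scan used as independent check at
// small scale (exported for tests; quadratic, do not use on large refs).
// [[Rcpp::export]]
List cpp_scan_read(std::string read, std::string ref, bool circular) {
  const int L = (int)ref.size();
  const int len = (int)read.size();
  int ext_len = circular ? std::min(len > 0 ? len - 1 : 0, L) : 0;
  std::string ext = ref + ref.substr(0, ext_len);
  std::string rev = revcomp(read);

  std::vector<int> starts, mms;
  std::vector<std::string> strands;
  for (int s = 0; s < 2; ++s) {
    const std::string& q = (s == 0) ? read : rev;
    for (int start = 0; start + len <= (int)ext.size() && start < L; ++start) {
      int mm = count_mm(q, ext, start, len);
      starts.push_back(start);
      mms.push_back(mm);
      strands.push_back(s == 0 ? "+" : "-");
    }
  }
  return List::create(_["start"] = starts, _["strand"] = strands,
                      _["n_mismatch"] = mms);
}

// ---------------------------------------------------------------------------
// Banded global (Needleman-Wunsch) alignment with affine gaps.
// A gap of length g costs gap_open + g * gap_ext.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int band, double match,
                      double mismatch, double gap_open, double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e12;
  if (n == 0 || m == 0) {
    std::string ga(m, '-'), gb(n, '-');
    return List::create(_["a"] = std::string(n, 'x'), _["b"] = ga,
                        _["score"] = NEG);
  }
  const int dmin = std::min(0, m - n) - band;
  const int dmax = std::max(0, m - n) + band;
  const int w = dmax - dmin + 1;

  // two-row score arrays per state, full byte traceback
  std::vector<double> M0(w, NEG), X0(w, NEG), Y0(w, NEG);
  std::vector<double> M1(w, NEG), X1(w, NEG), Y1(w, NEG);
  // tb[state][cell]: predecessor state 0=M,1=X,2=Y,3=invalid
  std::vector<uint8_t> tb((size_t)(n + 1) * w, 0xFF);

  auto cell = [&](int i, int j) -> int { return j - i - dmin; };
  auto pack = [](int pm, int px, int py) -> uint8_t {
    return (uint8_t)((pm & 3) | ((px & 3) << 2) | ((py & 3) << 4));
  };

  // row 0
  {
    int c0 = cell(0, 0);
    if (c0 >= 0 && c0 < w) M0[c0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      int c = cell(0, j);
      if (c < 0 || c >= w) break;
      Y0[c] = gap_open + j * gap_ext;               // gap run in a
      tb[(size_t)0 * w + c] = pack(3, 3, j == 1 ? 0 : 2);
    }
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(M1.begin(), M1.end(), NEG);
    std::fill(X1.begin(), X1.end(), NEG);
    std::fill(Y1.begin(), Y1.end(), NEG);
    int jlo = std::max(0, i + dmin), jhi = std::min(m, i + dmax);
    for (int j = jlo; j <= jhi; ++j) {
      int c = cell(i, j);
      int pm = 3, px = 3, py = 3;
      // X: consume a[i-1] only (gap in b row) -> from (i-1, j), cell c+1
      {
        int cp = c + 1;
        double vM = NEG, vX = NEG, vY = NEG;
        if (cp >= 0 && cp < w) { vM = M0[cp]; vX = X0[cp]; vY = Y0[cp]; }
        double open_from_M = vM + gap_open + gap_ext;
        double extend = vX + gap_ext;
        double open_from_Y = vY + gap_open + gap_ext;
        double best = open_from_M; px = 0;
        if (extend > best) { best = extend; px = 1; }
        if (open_from_Y > best) { best = open_from_Y; px = 2; }
        X1[c] = best;
        if (best <= NEG / 2) px = 3;
      }
      // Y: consume b[j-1] only -> from (i, j-1), same row, cell c-1
      if (j >= 1) {
        int cp = c - 1;
        double vM = NEG, vX = NEG, vY = NEG;
        if (cp >= 0 && cp < w) { vM = M1[cp]; vX = X1[cp]; vY = Y1[cp]; }
        double open_from_M = vM + gap_open + gap_ext;
        double open_from_X = vX + gap_open + gap_ext;
        double extend = vY + gap_ext;
        double best = open_from_M; py = 0;
        if (open_from_X > best) { best = open_from_X; py = 1; }
        if (extend > best) { best = extend; py = 2; }
        Y1[c] = best;
        if (best <= NEG / 2) py = 3;
      }
      // M: consume both -> from (i-1, j-1), cell c
      if (j >= 1) {
        double vM = M0[c], vX = X0[c], vY = Y0[c];
        double best = vM; pm = 0;
        if (vX > best) { best = vX; pm = 1; }
        if (vY > best) { best = vY; pm = 2; }
        int ca = base_code(a[i - 1]), cb = base_code(b[j - 1]);
        double s = (ca >= 0 && cb >= 0 && ca == cb) ? match : mismatch;
        M1[c] = best + s;
        if (best <= NEG / 2) { M1[c] = NEG; pm = 3; }
      }
      tb[(size_t)i * w + c] = pack(pm, px, py);
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }

  int cend = cell(n, m);
  if (cend < 0 || cend >= w) stop("band too narrow for this length difference");
  double sM = M0[cend], sX = X0[cend], sY = Y0[cend];
  int state = 0; double score = sM;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }
  if (score <= NEG / 2) stop("band too narrow: no alignment found");

  // traceback
  std::string out_a, out_b;
  out_a.reserve(n + m); out_b.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t)i * w + cell(i, j)];
    int prev;
    if (state == 0) {
      prev = t & 3;
      out_a.push_back(a[i - 1]); out_b.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = (t >> 2) & 3;
      out_a.push_back(a[i - 1]); out_b.push_back('-');
      --i;
    } else {
      prev = (t >> 4) & 3;
      out_a.push_back('-'); out_b.push_back(b[j - 1]);
      --j;
    }
    if (prev == 3) stop("traceback failed (band too narrow)");
    state = prev;
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
  return List::create(_["a"] = out_a, _["b"] = out_b, _["score"] = score);
}
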