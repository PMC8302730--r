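#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Base-level primitives shared by the simulator, the SNV caller and the
// consensus assembler.  Alignments are represented throughout as parallel
// vectors: reference-oriented read sequence, CIGAR string (M/I/D ops, M
// includes mismatches), and 0-based reference start.

static inline int base_index(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

struct CigarOp {
  char op;
  int len;
};

static std::vector<CigarOp> parse_cigar(const std::string &cig) {
  std::vector<CigarOp> ops;
  int len = 0;
  for (char c : cig) {
    if (c >= '0' && c <= '9') {
      len = len * 10 + (c - '0');
    } else {
      ops.push_back({c, len});
      len = 0;
    }
  }
  return ops;
}

static void append_op(std::string &cig, char op, int len) {
  if (len <= 0) return;
  cig += std::to_string(len);
  cig += op;
}

// Inject sequencing errors into reference windows.  For each read i the
// window genome[start[i], start[i]+len[i]) is copied base by base; each base
// fails with probability err_rate[i] and the failure is a substitution,
// insertion (one random base after the current one) or deletion according to
// sub_frac / ins_frac / remainder.  Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List cpp_simulate_read_errors(std::string genome, IntegerVector start,
                              IntegerVector len, NumericVector err_rate,
                              double sub_frac, double ins_frac) {
  int n = start.size();
  CharacterVector seqs(n), cigars(n);
  for (int i = 0; i < n; ++i) {
    int s = start[i], l = len[i];
    double p_err = err_rate[i];
    std::string out;
    out.reserve(l + 16);
    std::string cig;
    char cur_op = 0;
    int cur_len = 0;
    auto push = [&](char op) {
      if (op == cur_op) {
        ++cur_len;
      } else {
        append_op(cig, cur_op, cur_len);
        cur_op = op;
        cur_len = 1;
      }
    };
    for (int j = 0; j < l; ++j) {
      char ref = genome[s + j];
      double u = unif_rand();
      if (u >= p_err) {
        out += ref;
        push('M');
        continue;
      }
      double v = unif_rand();
      if (v < sub_frac) { // substitution: one of the three other bases
        int bi = base_index(ref);
        int k = (int)(unif_rand() * 3.0);
        if (k > 2) k = 2;
        int alt = (bi < 0) ? k : (bi + 1 + k) % 4;
        out += BASES[alt];
        push('M');
      } else if (v < sub_frac + ins_frac) { // keep base, insert a random one
        out += ref;
        push('M');
        int k = (int)(unif_rand() * 4.0);
        if (k > 3) k = 3;
        out += BASES[k];
        push('I');
      } else { // deletion
        push('D');
      }
    }
    append_op(cig, cur_op, cur_len);
    seqs[i] = out;
    cigars[i] = cig;
  }
  return List::create(_["seq"] = seqs, _["cigar"] = cigars);
}

// Reference span consumed by each CIGAR (sum of M and D lengths).
// [[Rcpp::export]]
IntegerVector cpp_cigar_ref_span(CharacterVector cigars) {
  int n = cigars.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string cig = as<std::string>(cigars[i]);
    int span = 0;
    for (const CigarOp &o : parse_cigar(cig))
      if (o.op == 'M' || o.op == 'D' || o.op == '=' || o.op == 'X') span += o.len;
    out[i] = span;
  }
  return out;
}

// Column-wise base counts over the half-open reference window [win_start,
// win_end).  Returns a 4 x width matrix (rows A,C,G,T) counting aligned (M)
// bases only; soft-clips (S) consume the query, D consumes the reference.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(CharacterVector seqs, CharacterVector cigars,
                         IntegerVector pos, int win_start, int win_end) {
  int width = win_end - win_start;
  IntegerMatrix counts(4, width);
  int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    std::string seq = as<std::string>(seqs[i]);
    std::string cig = as<std::string>(cigars[i]);
    int rpos = pos[i]; // reference cursor
    int qpos = 0;      // query cursor
    for (const CigarOp &o : parse_cigar(cig)) {
      if (o.op == 'M' || o.op == '=' || o.op == 'X') {
        int lo = std::max(rpos, win_start);
        int hi = std::min(rpos + o.len, win_end);
        for (int r = lo; r < hi; ++r) {
          int bi = base_index(seq[qpos + (r - rpos)]);
          if (bi >= 0) counts(bi, r - win_start)++;
        }
        rpos += o.len;
        qpos += o.len;
      } else if (o.op == 'D' || o.op == 'N') {
        rpos += o.len;
      } else if (o.op == 'I' || o.op == 'S') {
        qpos += o.len;
      } // H/P consume nothing
    }
  }
  return counts;
}

// Extract per-read alleles at SNV sites.  site_pos must be sorted 0-based
// positions; returns triplets (read index, site index, allele 0=ref/1=alt),
// 1-based indices, for reads whose aligned base equals the ref or alt allele.
// Bases other than ref/alt, deletions and uncovered sites yield no entry.
// [[Rcpp::export]]
List cpp_read_alleles(CharacterVector seqs, CharacterVector cigars,
                      IntegerVector pos, IntegerVector site_pos,
                      CharacterVector site_ref, CharacterVector site_alt) {
  int n = seqs.size(), m = site_pos.size();
  std::vector<char> ref(m), alt(m);
  for (int j = 0; j < m; ++j) {
    ref[j] = as<std::string>(site_ref[j])[0];
    alt[j] = as<std::string>(site_alt[j])[0];
  }
  std::vector<int> out_read, out_site, out_allele;
  for (int i = 0; i < n; ++i) {
    std::string seq = as<std::string>(seqs[i]);
    std::string cig = as<std::string>(cigars[i]);
    int rpos = pos[i], qpos = 0;
    // first site at or beyond the read start
    int j = std::lower_bound(site_pos.begin(), site_pos.end(), rpos) -
            site_pos.begin();
    for (const CigarOp &o : parse_cigar(cig)) {
      if (j >= m) break;
      if (o.op == 'M' || o.op == '=' || o.op == 'X') {
        while (j < m && site_pos[j] < rpos + o.len) {
          if (site_pos[j] >= rpos) {
            char b = seq[qpos + (site_pos[j] - rpos)];
            if (b >= 'a') b -= 32;
            if (b == ref[j]) {
              out_read.push_back(i + 1);
              out_site.push_back(j + 1);
              out_allele.push_back(0);
            } else if (b == alt[j]) {
              out_read.push_back(i + 1);
              out_site.push_back(j + 1);
              out_allele.push_back(1);
            }
          }
          ++j;
        }
        rpos += o.len;
        qpos += o.len;
      } else if (o.op == 'D' || o.op == 'N') {
        while (j < m && site_pos[j] < rpos + o.len) ++j; // deleted: missing
        rpos += o.len;
      } else if (o.op == 'I' || o.op == 'S') {
        qpos += o.len;
      }
    }
  }
  return List::create(_["read"] = wrap(out_read), _["site"] = wrap(out_site),
                      _["allele"] = wrap(out_allele));
}

// Coordinate-anchored column-wise consensus of aligned reads over the
// half-open window [win_start, win_end).  Per column: majority base; a
// deletion if more than half of the covering reads delete it; the most
// frequent insertion after the column if more than half of the covering
// reads insert there.  Contigs are split wherever coverage < min_cov.
// Each contig carries per-base backbone anchors (insertions anchor to the
// preceding column) so callers can trim by backbone coordinates.
// [[Rcpp::export]]
List cpp_consensus(CharacterVector seqs, CharacterVector cigars,
                   IntegerVector pos, int win_start, int win_end,
                   int min_cov) {
  int width = win_end - win_start;
  if (width <= 0) return List::create();
  std::vector<std::array<int, 4>> counts(width, {0, 0, 0, 0});
  std::vector<int> cov(width, 0), del(width, 0), ins_reads(width, 0);
  std::unordered_map<int, std::map<std::string, int>> ins;
  int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    std::string seq = as<std::string>(seqs[i]);
    std::string cig = as<std::string>(cigars[i]);
    int rpos = pos[i], qpos = 0;
    for (const CigarOp &o : parse_cigar(cig)) {
      if (o.op == 'M' || o.op == '=' || o.op == 'X') {
        int lo = std::max(rpos, win_start);
        int hi = std::min(rpos + o.len, win_end);
        for (int r = lo; r < hi; ++r) {
          cov[r - win_start]++;
          int bi = base_index(seq[qpos + (r - rpos)]);
          if (bi >= 0) counts[r - win_start][bi]++;
        }
        rpos += o.len;
        qpos += o.len;
      } else if (o.op == 'D' || o.op == 'N') {
        int lo = std::max(rpos, win_start);
        int hi = std::min(rpos + o.len, win_end);
        for (int r = lo; r < hi; ++r) {
          cov[r - win_start]++;
          del[r - win_start]++;
        }
        rpos += o.len;
      } else if (o.op == 'I') {
        // insertion after reference column rpos-1
        int col = rpos - 1;
        if (col >= win_start && col < win_end) {
          ins_reads[col - win_start]++;
          ins[col - win_start][seq.substr(qpos, o.len)]++;
        }
        qpos += o.len;
      } else if (o.op == 'S') {
        qpos += o.len;
      }
    }
  }
  List contigs;
  std::string cur;
  std::vector<int> anchors;
  auto flush = [&]() {
    if (!cur.empty()) {
      contigs.push_back(List::create(_["seq"] = cur,
                                     _["anchor"] = wrap(anchors)));
    }
    cur.clear();
    anchors.clear();
  };
  for (int k = 0; k < width; ++k) {
    if (cov[k] < min_cov) {
      flush();
      continue;
    }
    if (2 * del[k] <= cov[k]) { // not a majority deletion
      int best = -1, best_cnt = 0;
      for (int b = 0; b < 4; ++b)
        if (counts[k][b] > best_cnt) { best_cnt = counts[k][b]; best = b; }
      if (best >= 0) {
        cur += BASES[best];
        anchors.push_back(win_start + k);
      }
    }
    if (2 * ins_reads[k] > cov[k]) {
      auto it = ins.find(k);
      if (it != ins.end()) {
        // most frequent insertion, ties to the lexicographically smaller
        const std::string *best_s = nullptr;
        int best_cnt = 0;
        for (const auto &p : it->second)
          if (p.second > best_cnt) { best_cnt = p.second; best_s = &p.first; }
        if (best_s) {
          for (char c : *best_s) {
            cur += c;
            anchors.push_back(win_start + k);
          }
        }
      }
    }
  }
  flush();
  return contigs;
}
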