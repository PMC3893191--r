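#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <string>

using namespace Rcpp;

// Ungapped seed-and-extend nucleotide search used for self-contained synthetic
// runs: exact word seeding on both strands, +1/-2 ungapped x-drop extension,
// Karlin-Altschul e-values with fixed (K, lambda). One row per local
// alignment; coordinates 1-based inclusive; minus-strand hits reported with
// sstart > send (query coordinates always forward).

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': case 'a': c = 'T'; break;
    case 'C': case 'c': c = 'G'; break;
    case 'G': case 'g': c = 'C'; break;
    case 'T': case 't': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct Hit {
  int q0, q1, s0, s1;   // 0-based inclusive, on the searched (possibly rc) query
  int matches, mismatches, score;
};

// Extend a seed ungapped in both directions with x-drop on +1/-2 scoring.
static Hit extend_seed(const std::vector<int>& q, const std::vector<int>& s,
                       int qi, int sj, int w, int x_drop) {
  int score = w, matches = w, mismatches = 0;
  // right extension
  int best = 0, cur = 0, best_len = 0, m_best = 0, mm_best = 0, m_cur = 0, mm_cur = 0;
  for (int a = qi + w, b = sj + w;
       a < (int)q.size() && b < (int)s.size(); ++a, ++b) {
    if (q[a] >= 0 && q[a] == s[b]) { cur += 1; m_cur++; } else { cur -= 2; mm_cur++; }
    if (cur > best) { best = cur; best_len = a - (qi + w) + 1; m_best = m_cur; mm_best = mm_cur; }
    if (best - cur >= x_drop) break;
  }
  int right = best_len;
  score += best; matches += m_best; mismatches += mm_best;
  // left extension
  best = 0; cur = 0; best_len = 0; m_best = 0; mm_best = 0; m_cur = 0; mm_cur = 0;
  for (int a = qi - 1, b = sj - 1; a >= 0 && b >= 0; --a, --b) {
    if (q[a] >= 0 && q[a] == s[b]) { cur += 1; m_cur++; } else { cur -= 2; mm_cur++; }
    if (cur > best) { best = cur; best_len = qi - a; m_best = m_cur; mm_best = mm_cur; }
    if (best - cur >= x_drop) break;
  }
  int left = best_len;
  score += best; matches += m_best; mismatches += mm_best;
  Hit h;
  h.q0 = qi - left; h.q1 = qi + w - 1 + right;
  h.s0 = sj - left; h.s1 = sj + w - 1 + right;
  h.matches = matches; h.mismatches = mismatches; h.score = score;
  return h;
}

typedef std::unordered_map<uint32_t, std::vector<int> > KmerIndex;

static KmerIndex index_subject(const std::vector<int>& s, int w) {
  KmerIndex idx;
  uint32_t code = 0, mask = (w < 16) ? ((1u << (2 * w)) - 1) : 0xFFFFFFFFu;
  int run = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    if (s[i] < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)s[i]) & mask;
    if (++run >= w) idx[code].push_back(i - w + 1);
  }
  return idx;
}

static std::vector<int> encode(const std::string& x) {
  std::vector<int> v(x.size());
  for (size_t i = 0; i < x.size(); ++i) v[i] = base_code(x[i]);
  return v;
}

// [[Rcpp::export(name = ".native_search_cpp")]]
DataFrame native_search_cpp(CharacterVector queries, std::string subject,
                            int word_size, double x_drop,
                            double K, double lambda, double evalue_max) {
  if (word_size < 4 || word_size > 15)
    stop("word_size must be between 4 and 15");
  std::vector<int> senc = encode(subject);
  KmerIndex idx = index_subject(senc, word_size);
  double n_sub = (double)subject.size();

  std::vector<std::string> out_qid;
  std::vector<double> out_pid, out_eval, out_bits;
  std::vector<int> out_len, out_mm, out_qs, out_qe, out_ss, out_se;

  CharacterVector qnames = queries.names();
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string qfwd = as<std::string>(queries[qi]);
    std::string qname = qnames.size() ? as<std::string>(qnames[qi]) : std::to_string(qi + 1);
    double m_q = (double)qfwd.size();
    if ((int)qfwd.size() < word_size) continue;
    for (int strand = 0; strand < 2; ++strand) {
      std::string qs = strand ? revcomp(qfwd) : qfwd;
      std::vector<int> qenc = encode(qs);
      int L = (int)qenc.size();
      // diag -> query end (exclusive) already covered by an extension
      std::unordered_map<long long, int> covered;
      uint32_t code = 0, mask = (word_size < 16) ? ((1u << (2 * word_size)) - 1) : 0xFFFFFFFFu;
      int run = 0;
      for (int i = 0; i < L; ++i) {
        if (qenc[i] < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t)qenc[i]) & mask;
        if (++run < word_size) continue;
        int qpos = i - word_size + 1;
        KmerIndex::const_iterator it = idx.find(code);
        if (it == idx.end()) continue;
        for (int spos : it->second) {
          long long diag = (long long)spos - (long long)qpos + (long long)L;
          std::unordered_map<long long, int>::iterator cv = covered.find(diag);
          if (cv != covered.end() && qpos < cv->second) continue;
          Hit h = extend_seed(qenc, senc, qpos, spos, word_size, (int)x_drop);
          covered[diag] = h.q1 + 1;
          double ev = K * m_q * n_sub * std::exp(-lambda * (double)h.score);
          if (ev > evalue_max) continue;
          int alen = h.q1 - h.q0 + 1;
          int q0 = h.q0, q1 = h.q1, s0 = h.s0, s1 = h.s1;
          int qstart, qend, sstart, send;
          if (!strand) {
            qstart = q0 + 1; qend = q1 + 1; sstart = s0 + 1; send = s1 + 1;
          } else {
            qstart = L - q1; qend = L - q0;      // back to forward query coords
            sstart = s1 + 1; send = s0 + 1;      // sstart > send marks minus strand
          }
          out_qid.push_back(qname);
          out_pid.push_back(100.0 * (double)h.matches / (double)alen);
          out_len.push_back(alen);
          out_mm.push_back(h.mismatches);
          out_qs.push_back(qstart); out_qe.push_back(qend);
          out_ss.push_back(sstart); out_se.push_back(send);
          out_eval.push_back(ev);
          out_bits.push_back((lambda * (double)h.score - std::log(K)) / std::log(2.0));
        }
      }
    }
  }
  return DataFrame::create(
    _["query_id"] = out_qid,
    _["pct_identity"] = out_pid,
    _["aln_len"] = out_len,
    _["mismatches"] = out_mm,
    _["gap_opens"] = IntegerVector(out_qid.size(), 0),
    _["qstart"] = out_qs, _["qend"] = out_qe,
    _["sstart"] = out_ss, _["send"] = out_se,
    _["evalue"] = out_eval, _["bitscore"] = out_bits,
    _["stringsAsFactors"] = false);
}
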