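// Core alignment machinery: affine-gap Smith-Waterman with deterministic
// traceback, a word-seeded batch search with an ungapped-extension gate,
// CD-HIT-style greedy clustering, and k-mer prescreen helpers.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

const int WORD_BASE = 32;  // alphabet codes fit in 5 bits

struct Scoring {
  std::vector<int> mat;   // nA x nA, row-major
  int nA;
  int lookup[256];
  int gap_open;           // charged once per gap, on top of per-residue extend
  int gap_extend;
  int sub(int a, int b) const { return mat[a * nA + b]; }
};

Scoring make_scoring(const IntegerMatrix& m, const std::string& alphabet,
                     int gap_open, int gap_extend) {
  Scoring sc;
  sc.nA = m.nrow();
  if ((int)alphabet.size() != sc.nA)
    stop("alphabet length does not match scoring matrix dimension");
  sc.mat.resize(sc.nA * sc.nA);
  for (int i = 0; i < sc.nA; ++i)
    for (int j = 0; j < sc.nA; ++j)
      sc.mat[i * sc.nA + j] = m(i, j);
  for (int i = 0; i < 256; ++i) sc.lookup[i] = -1;
  for (int i = 0; i < sc.nA; ++i)
    sc.lookup[(unsigned char)alphabet[i]] = i;
  sc.gap_open = gap_open;
  sc.gap_extend = gap_extend;
  return sc;
}

// Encode a sequence; on an unknown residue either stop (policy 0) or emit
// code -2, scored 0 against everything (policy 1).
std::vector<int> encode(const std::string& s, const Scoring& sc,
                        int unknown_policy, const char* what) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = sc.lookup[(unsigned char)s[i]];
    if (c < 0) {
      if (unknown_policy == 0)
        stop("unknown residue '%c' at position %d of %s sequence",
             s[i], (int)(i + 1), what);
      c = -2;
    }
    out[i] = c;
  }
  return out;
}

inline int pair_score(const Scoring& sc, int a, int b) {
  if (a < 0 || b < 0) return 0;
  return sc.sub(a, b);
}

struct AlnResult {
  int score = 0, matches = 0, mismatches = 0, gap_opens = 0, aln_length = 0;
  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;  // 1-based inclusive
  bool found = false;
};

// Score-only affine SW over encoded sequences (rolling arrays).
int sw_score_only(const std::vector<int>& q, const std::vector<int>& s,
                  const Scoring& sc) {
  const int m = q.size(), n = s.size();
  const int GO = sc.gap_open + sc.gap_extend, GE = sc.gap_extend;
  const int NEG = -1000000000;
  std::vector<int> H(n + 1, 0);    // row i-1, overwritten left-to-right
  std::vector<int> V(n + 1, NEG);  // gaps consuming the query (vertical)
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;   // H[i-1][j-1]
    int f = NEG;     // gaps consuming the subject (horizontal), row-local
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      V[j] = std::max(H[j] - GO, V[j] - GE);      // H[j] still row i-1
      f = std::max(H[j - 1] - GO, f - GE);        // H[j-1] already row i
      int h = Hdiag + pair_score(sc, qi, s[j - 1]);
      if (V[j] > h) h = V[j];
      if (f > h) h = f;
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full affine SW with traceback. Tie-breaking: diagonal > up (gap in
// subject, consuming query) > left (gap in query, consuming subject);
// best cell = highest score, then smallest query index, then smallest
// subject index.
AlnResult sw_traceback(const std::vector<int>& q, const std::vector<int>& s,
                       const Scoring& sc) {
  const int m = q.size(), n = s.size();
  const int GO = sc.gap_open + sc.gap_extend, GE = sc.gap_extend;
  const int NEG = -1000000000;
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> Ev((m + 1) * (n + 1), NEG);  // left gaps (consume subject)
  std::vector<int> Fv((m + 1) * (n + 1), NEG);  // up gaps (consume query)
  AlnResult r;
  int besti = 0, bestj = 0, best = 0;
  for (int i = 1; i <= m; ++i) {
    const int qi = q[i - 1];
    const int row = i * (n + 1), prow = (i - 1) * (n + 1);
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[row + j - 1] - GO, Ev[row + j - 1] - GE);
      int f = std::max(H[prow + j] - GO, Fv[prow + j] - GE);
      int d = H[prow + j - 1] + pair_score(sc, qi, s[j - 1]);
      int h = d;
      if (f > h) h = f;
      if (e > h) h = e;
      if (h < 0) h = 0;
      Ev[row + j] = e;
      Fv[row + j] = f;
      H[row + j] = h;
      if (h > best) { best = h; besti = i; bestj = j; }
    }
  }
  r.score = best;
  if (best <= 0) return r;
  r.found = true;
  r.q_end = besti; r.s_end = bestj;
  // Traceback; state 0 = in H, 1 = in E (left), 2 = in F (up).
  int i = besti, j = bestj, state = 0;
  while (true) {
    const int row = i * (n + 1), prow = (i - 1) * (n + 1);
    if (state == 0) {
      int h = H[row + j];
      if (h == 0) break;
      int d = H[prow + j - 1] + pair_score(sc, q[i - 1], s[j - 1]);
      if (d == h) {
        r.aln_length++;
        if (q[i - 1] == s[j - 1] && q[i - 1] >= 0) r.matches++; else r.mismatches++;
        --i; --j;
        if (i == 0 || j == 0) break;
        continue;
      } else if (Fv[row + j] == h) {
        state = 2; continue;
      } else if (Ev[row + j] == h) {
        state = 1; continue;
      } else {
        stop("internal error: inconsistent traceback");
      }
    } else if (state == 2) {  // up: gap in subject, consume query residue
      r.aln_length++;
      int f = Fv[row + j];
      bool open = (H[prow + j] - (sc.gap_open + sc.gap_extend) == f);
      bool ext  = (Fv[prow + j] - sc.gap_extend == f);
      --i;
      if (open || !ext) { r.gap_opens++; state = 0; }
      // prefer closing the gap (open) over extending when both tie:
      // deterministic and yields minimal gap runs
      if (i == 0) break;
    } else {  // left: gap in query, consume subject residue
      r.aln_length++;
      int e = Ev[row + j];
      bool open = (H[row + j - 1] - (sc.gap_open + sc.gap_extend) == e);
      bool ext  = (Ev[row + j - 1] - sc.gap_extend == e);
      --j;
      if (open || !ext) { r.gap_opens++; state = 0; }
      if (j == 0) break;
    }
  }
  r.q_start = i + 1;
  r.s_start = j + 1;
  // The loop above decrements before the zero check; recompute starts from
  // the consumed spans for safety.
  return r;
}

// Distinct word ids (word_size letters, codes < 32) of an encoded sequence.
std::vector<int> distinct_words(const std::vector<int>& s, int w) {
  std::vector<int> out;
  if ((int)s.size() < w) return out;
  for (size_t i = 0; i + w <= s.size(); ++i) {
    int id = 0; bool ok = true;
    for (int k = 0; k < w; ++k) {
      if (s[i + k] < 0) { ok = false; break; }
      id = id * WORD_BASE + s[i + k];
    }
    if (ok) out.push_back(id);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_sw_align(std::string query, std::string subject,
                  IntegerMatrix score_matrix, std::string alphabet,
                  int gap_open, int gap_extend, int unknown_policy) {
  Scoring sc = make_scoring(score_matrix, alphabet, gap_open, gap_extend);
  std::vector<int> q = encode(query, sc, unknown_policy, "query");
  std::vector<int> s = encode(subject, sc, unknown_policy, "subject");
  AlnResult r = sw_traceback(q, s, sc);
  return List::create(
    _["score"] = r.score, _["found"] = r.found,
    _["matches"] = r.matches, _["mismatches"] = r.mismatches,
    _["gap_opens"] = r.gap_opens, _["aln_length"] = r.aln_length,
    _["q_start"] = r.q_start, _["q_end"] = r.q_end,
    _["s_start"] = r.s_start, _["s_end"] = r.s_end);
}

// [[Rcpp::export]]
int cpp_sw_score(std::string query, std::string subject,
                 IntegerMatrix score_matrix, std::string alphabet,
                 int gap_open, int gap_extend, int unknown_policy) {
  Scoring sc = make_scoring(score_matrix, alphabet, gap_open, gap_extend);
  std::vector<int> q = encode(query, sc, unknown_policy, "query");
  std::vector<int> s = encode(subject, sc, unknown_policy, "subject");
  return sw_score_only(q, s, sc);
}

// Batch seeded search. For every (query, subject) pair sharing at least one
// exact word, an ungapped Kadane scan of each seeded diagonal yields a
// chained upper-bound proxy; pairs whose bound reaches the per-query score
// threshold get a full Smith-Waterman, and scoring pairs a traceback.
// smin: per-query minimum raw score for significance (>= 1 enforced).
// self_subject: 1-based subject index to skip for each query (0 = none).
// [[Rcpp::export]]
List cpp_search(std::vector<std::string> queries,
                std::vector<std::string> subjects,
                IntegerMatrix score_matrix, std::string alphabet,
                int gap_open, int gap_extend, int word_size,
                IntegerVector smin, IntegerVector self_subject,
                bool gate) {
  Scoring sc = make_scoring(score_matrix, alphabet, gap_open, gap_extend);
  const int nQ = queries.size(), nS = subjects.size();
  if (nS == 0) stop("empty reference");
  std::vector<std::vector<int>> senc(nS);
  for (int s = 0; s < nS; ++s)
    senc[s] = encode(subjects[s], sc, 0, "subject");

  // word -> (subject, position) postings
  const int nWords = WORD_BASE * WORD_BASE * WORD_BASE;
  if (word_size != 3) stop("word_size must be 3 in this build");
  std::vector<int> bucket_count(nWords, 0);
  for (int s = 0; s < nS; ++s) {
    const std::vector<int>& es = senc[s];
    for (size_t p = 0; p + word_size <= es.size(); ++p) {
      int id = es[p] * WORD_BASE * WORD_BASE + es[p + 1] * WORD_BASE + es[p + 2];
      bucket_count[id]++;
    }
  }
  std::vector<size_t> bucket_start(nWords + 1, 0);
  for (int w = 0; w < nWords; ++w)
    bucket_start[w + 1] = bucket_start[w] + bucket_count[w];
  std::vector<int> post_subj(bucket_start[nWords]);
  std::vector<int> post_pos(bucket_start[nWords]);
  {
    std::vector<size_t> cur(bucket_start.begin(), bucket_start.end() - 1);
    for (int s = 0; s < nS; ++s) {
      const std::vector<int>& es = senc[s];
      for (size_t p = 0; p + word_size <= es.size(); ++p) {
        int id = es[p] * WORD_BASE * WORD_BASE + es[p + 1] * WORD_BASE + es[p + 2];
        post_subj[cur[id]] = s;
        post_pos[cur[id]] = (int)p;
        cur[id]++;
      }
    }
  }

  const int chain_cost = gap_open + gap_extend;
  std::vector<int> out_q, out_s, out_score, out_match, out_mis, out_go,
      out_len, out_qs, out_qe, out_ss, out_se;

  std::vector<std::pair<int,int>> seeds;  // (subject, diagonal)
  for (int qi = 0; qi < nQ; ++qi) {
    if (qi % 64 == 0) Rcpp::checkUserInterrupt();
    std::vector<int> qe = encode(queries[qi], sc, 0, "query");
    const int m = qe.size();
    if (m < word_size) continue;
    const int thr = std::max(1, (int)smin[qi]);
    const int self = self_subject[qi];  // 1-based, 0 = none
    seeds.clear();
    for (int p = 0; p + word_size <= m; ++p) {
      int id = qe[p] * WORD_BASE * WORD_BASE + qe[p + 1] * WORD_BASE + qe[p + 2];
      for (size_t b = bucket_start[id]; b < bucket_start[id + 1]; ++b)
        seeds.push_back(std::make_pair(post_subj[b], post_pos[b] - p));
    }
    std::sort(seeds.begin(), seeds.end());
    seeds.erase(std::unique(seeds.begin(), seeds.end()), seeds.end());
    size_t a = 0;
    std::vector<int> segs;
    while (a < seeds.size()) {
      int sj = seeds[a].first;
      size_t b = a;
      while (b < seeds.size() && seeds[b].first == sj) ++b;
      if (self > 0 && sj == self - 1) { a = b; continue; }
      const std::vector<int>& se = senc[sj];
      const int n = se.size();
      bool do_full = !gate;
      if (gate) {
        segs.clear();
        for (size_t k = a; k < b; ++k) {
          const int d = seeds[k].second;
          int i0 = std::max(0, -d), i1 = std::min(m, n - d);
          int run = 0, bestseg = 0;
          for (int i = i0; i < i1; ++i) {
            run += sc.sub(qe[i], se[i + d]);
            if (run < 0) run = 0;
            if (run > bestseg) bestseg = run;
          }
          if (bestseg > 0) segs.push_back(bestseg);
        }
        if (!segs.empty()) {
          std::sort(segs.begin(), segs.end(), std::greater<int>());
          long bound = segs[0];
          for (size_t k = 1; k < segs.size(); ++k)
            if (segs[k] > chain_cost) bound += segs[k] - chain_cost;
          do_full = bound >= thr;
        }
      }
      if (do_full) {
        int sco = sw_score_only(qe, se, sc);
        if (sco >= thr) {
          AlnResult r = sw_traceback(qe, se, sc);
          out_q.push_back(qi + 1); out_s.push_back(sj + 1);
          out_score.push_back(r.score); out_match.push_back(r.matches);
          out_mis.push_back(r.mismatches); out_go.push_back(r.gap_opens);
          out_len.push_back(r.aln_length);
          out_qs.push_back(r.q_start); out_qe.push_back(r.q_end);
          out_ss.push_back(r.s_start); out_se.push_back(r.s_end);
        }
      }
      a = b;
    }
  }
  return List::create(
    _["query"] = out_q, _["subject"] = out_s, _["score"] = out_score,
    _["matches"] = out_match, _["mismatches"] = out_mis,
    _["gap_opens"] = out_go, _["aln_length"] = out_len,
    _["q_start"] = out_qs, _["q_end"] = out_qe,
    _["s_start"] = out_ss, _["s_end"] = out_se);
}

// Greedy single-pass clustering over sequences already sorted by decreasing
// length. A sequence joins the earliest representative reached at
// >= identity_threshold (matches / shorter length, best local alignment),
// else founds a new cluster. A shared-word count prescreen in the spirit of
// CD-HIT's word filter limits the alignments attempted.
// Returns 1-based representative index per sequence.
// [[Rcpp::export]]
// Empirical probability that two random 3-mers drawn from the dataset's
// word distribution collide (the uniform-composition value 1/8000
// underestimates chance word sharing for realistic compositions).
static double word_collision_prob(const std::vector<std::vector<int>> &wlists,
                                  int nWords) {
  std::vector<double> cnt(nWords, 0.0);
  double total = 0.0;
  for (const auto &wl : wlists)
    for (int w : wl) { cnt[w] += 1.0; total += 1.0; }
  if (total <= 0.0) return 1.0 / 8000.0;
  double sum_sq = 0.0;
  for (const auto &wl : wlists)
    for (int w : wl) sum_sq += cnt[w];
  return sum_sq / (total * total);
}

IntegerVector cpp_greedy_cluster(std::vector<std::string> seqs,
                                 double identity_threshold,
                                 IntegerMatrix score_matrix,
                                 std::string alphabet,
                                 int gap_open, int gap_extend) {
  Scoring sc = make_scoring(score_matrix, alphabet, gap_open, gap_extend);
  const int n = seqs.size();
  const int W = 3;
  IntegerVector rep(n);
  std::vector<std::vector<int>> enc(n);
  std::vector<std::vector<int>> words(n);
  for (int i = 0; i < n; ++i) {
    enc[i] = encode(seqs[i], sc, 0, "input");
    words[i] = distinct_words(enc[i], W);
  }
  const int nWords = WORD_BASE * WORD_BASE * WORD_BASE;
  const double p_coll = word_collision_prob(words, nWords);
  // A pair at identity t conserves ~t^3 of its 3-mers; half that is the
  // sensitivity guard below which a true pair must never be rejected.
  const double t3 = identity_threshold * identity_threshold *
                    identity_threshold;
  std::vector<std::vector<int>> index(nWords);  // word -> rep list (creation order)
  std::vector<int> reps;
  std::vector<int> shared(n, 0);
  std::vector<int> touched;
  for (int i = 0; i < n; ++i) {
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
    touched.clear();
    for (int w : words[i]) {
      for (int r : index[w]) {
        if (shared[r] == 0) touched.push_back(r);
        shared[r]++;
      }
    }
    int assigned = -1;
    if (!touched.empty()) {
      std::sort(touched.begin(), touched.end());  // creation order = index order
      for (int r : touched) {
        int Ls = std::min(enc[i].size(), enc[r].size());
        double Ech = (double)words[i].size() * words[r].size() * p_coll;
        int need = std::min((int)std::floor(0.5 * t3 * Ls),
                            (int)std::ceil(Ech + 4.0 * std::sqrt(Ech + 1.0)));
        if (need < 1) need = 1;
        if (shared[r] < need) continue;
        AlnResult a = sw_traceback(enc[i], enc[r], sc);
        if (a.found && (double)a.matches / Ls >= identity_threshold) {
          assigned = r;
          break;
        }
      }
    }
    for (int r : touched) shared[r] = 0;
    if (assigned < 0) {
      reps.push_back(i);
      for (int w : words[i]) index[w].push_back(i);
      rep[i] = i + 1;
    } else {
      rep[i] = assigned + 1;
    }
  }
  return rep;
}

// For each query, 1-based indices of subjects sharing notably more distinct
// words than expected by chance (prescreen for homology screening).
// [[Rcpp::export]]
List cpp_kmer_candidates(std::vector<std::string> queries,
                         std::vector<std::string> subjects,
                         std::string alphabet) {
  const int W = 3;
  Scoring sc;
  sc.nA = alphabet.size();
  for (int i = 0; i < 256; ++i) sc.lookup[i] = -1;
  for (int i = 0; i < sc.nA; ++i) sc.lookup[(unsigned char)alphabet[i]] = i;
  sc.gap_open = 0; sc.gap_extend = 0;
  const int nS = subjects.size();
  std::vector<std::vector<int>> swords(nS);
  const int nWords = WORD_BASE * WORD_BASE * WORD_BASE;
  std::vector<std::vector<int>> index(nWords);
  for (int s = 0; s < nS; ++s) {
    swords[s] = distinct_words(encode(subjects[s], sc, 1, "subject"), W);
    for (int w : swords[s]) index[w].push_back(s);
  }
  const double p_coll = word_collision_prob(swords, nWords);
  List out(queries.size());
  std::vector<int> shared(nS, 0);
  std::vector<int> touched;
  for (size_t q = 0; q < queries.size(); ++q) {
    if (q % 64 == 0) Rcpp::checkUserInterrupt();
    std::vector<int> qw = distinct_words(encode(queries[q], sc, 1, "query"), W);
    touched.clear();
    for (int w : qw)
      for (int s : index[w]) {
        if (shared[s] == 0) touched.push_back(s);
        shared[s]++;
      }
    std::vector<int> cand;
    for (int s : touched) {
      double Ech = (double)qw.size() * swords[s].size() * p_coll;
      int need = std::max(1, (int)std::ceil(Ech + 3.0 * std::sqrt(Ech + 1.0)));
      if (shared[s] >= need) cand.push_back(s + 1);
      shared[s] = 0;
    }
    std::sort(cand.begin(), cand.end());
    out[q] = IntegerVector(cand.begin(), cand.end());
  }
  return out;
}
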