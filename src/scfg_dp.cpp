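// Dynamic programs over SCFGs in the double emission normal form:
//   BRANCH  T -> U V
//   UNPAIRED T -> .
//   PAIR    T -> ( U )
// Spans are half-open [i,j), 0-based. All probability DPs run in log space;
// R_NegInf encodes impossibility. A "compiled" grammar arrives from R as
// parallel integer vectors (see compile_grammar() on the R side).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int BRANCH = 0, UNPAIRED = 1, PAIR = 2;

// characters of a structure string: 0 = '.', 1 = '(', 2 = ')'
// nucleotides of a sequence: 0=A, 1=C, 2=G, 3=U

static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  if (a < b) std::swap(a, b);
  return a + log1p(std::exp(b - a));
}

struct Gram {
  int nnt, start, nrule;
  IntegerVector lhs, kind, c1, c2;
  NumericVector logp;
  Gram(List g)
    : nnt(as<int>(g["n_nt"])), start(as<int>(g["start"])),
      lhs(g["lhs"]), kind(g["kind"]), c1(g["c1"]), c2(g["c2"]),
      logp(g["logp"]) {
    nrule = lhs.size();
  }
};

// ---------------------------------------------------------------------------
// Structure-level parsing: the input string is over {., (, )}.

// Fills, for every non-terminal T and span [i,j), either
//  * the max-derivation log-probability (mode 0) with backtrack tables, or
//  * the derivation count, saturating at cap (mode 1), or
//  * the log derivation count (mode 2, used for uniform sampling).
struct StructTables {
  int n, nnt;
  std::vector<double> val;
  std::vector<int> bt_rule, bt_k;
  inline size_t id(int t, int i, int j) const {
    return ((size_t)t * (n + 1) + i) * (n + 1) + j;
  }
};

static void structure_fill(const Gram& G, const IntegerVector& s, int mode,
                           double cap, StructTables& T) {
  int n = s.size();
  T.n = n; T.nnt = G.nnt;
  double empty = (mode == 1) ? 0.0 : R_NegInf;
  T.val.assign((size_t)G.nnt * (n + 1) * (n + 1), empty);
  if (mode == 0) {
    T.bt_rule.assign(T.val.size(), -1);
    T.bt_k.assign(T.val.size(), -1);
  }
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len <= n; ++i) {
      int j = i + len;
      for (int r = 0; r < G.nrule; ++r) {
        int t = G.lhs[r], kd = G.kind[r];
        size_t cell = T.id(t, i, j);
        if (kd == UNPAIRED) {
          if (len == 1 && s[i] == 0) {
            if (mode == 0) {
              double v = G.logp[r];
              if (v > T.val[cell]) { T.val[cell] = v; T.bt_rule[cell] = r; }
            } else if (mode == 1) {
              T.val[cell] = std::min(T.val[cell] + 1.0, cap);
            } else T.val[cell] = logadd(T.val[cell], 0.0);
          }
        } else if (kd == PAIR) {
          if (len >= 3 && s[i] == 1 && s[j - 1] == 2) {
            double inner = T.val[T.id(G.c1[r], i + 1, j - 1)];
            if (mode == 0) {
              if (inner > R_NegInf) {
                double v = G.logp[r] + inner;
                if (v > T.val[cell]) { T.val[cell] = v; T.bt_rule[cell] = r; }
              }
            } else if (mode == 1) {
              T.val[cell] = std::min(T.val[cell] + inner, cap);
            } else T.val[cell] = logadd(T.val[cell], inner);
          }
        } else { // BRANCH
          if (len < 2) continue;
          int u = G.c1[r], v = G.c2[r];
          for (int k = i + 1; k < j; ++k) {
            double a = T.val[T.id(u, i, k)], b = T.val[T.id(v, k, j)];
            if (mode == 0) {
              if (a > R_NegInf && b > R_NegInf) {
                double val = G.logp[r] + a + b;
                if (val > T.val[cell]) {
                  T.val[cell] = val; T.bt_rule[cell] = r; T.bt_k[cell] = k;
                }
              }
            } else if (mode == 1) {
              T.val[cell] = std::min(T.val[cell] + a * b, cap);
            } else {
              if (a > R_NegInf && b > R_NegInf)
                T.val[cell] = logadd(T.val[cell], a + b);
            }
          }
        }
      }
    }
  }
}

// pre-order backtrack of the max-probability derivation
static void bt_collect(const Gram& G, const StructTables& T, int t, int i,
                       int j, std::vector<std::array<int,3>>& out) {
  size_t cell = T.id(t, i, j);
  int r = T.bt_rule[cell];
  out.push_back({r, i, j});
  if (G.kind[r] == PAIR) bt_collect(G, T, G.c1[r], i + 1, j - 1, out);
  else if (G.kind[r] == BRANCH) {
    int k = T.bt_k[cell];
    bt_collect(G, T, G.c1[r], i, k, out);
    bt_collect(G, T, G.c2[r], k, j, out);
  }
}

// [[Rcpp::export]]
List cpp_structure_cyk(List grammar, IntegerVector s) {
  Gram G(grammar);
  int n = s.size();
  StructTables T;
  if (n == 0) return List::create(_["logp"] = R_NegInf);
  structure_fill(G, s, 0, 0.0, T);
  double best = T.val[T.id(G.start, 0, n)];
  if (best == R_NegInf) return List::create(_["logp"] = R_NegInf);
  std::vector<std::array<int,3>> der;
  bt_collect(G, T, G.start, 0, n, der);
  IntegerMatrix m(der.size(), 3);
  for (size_t q = 0; q < der.size(); ++q) {
    m(q, 0) = der[q][0]; m(q, 1) = der[q][1]; m(q, 2) = der[q][2];
  }
  return List::create(_["logp"] = best, _["deriv"] = m);
}

// [[Rcpp::export]]
double cpp_count_derivations(List grammar, IntegerVector s, double cap) {
  Gram G(grammar);
  int n = s.size();
  if (n == 0) return 0.0;
  StructTables T;
  structure_fill(G, s, 1, cap, T);
  return T.val[T.id(G.start, 0, n)];
}

// uniform sampling among all derivations via log-count backtrack;
// uses R's RNG so set.seed() governs reproducibility
static void sample_collect(const Gram& G, const StructTables& T,
                           const IntegerVector& s, int t, int i, int j,
                           std::vector<std::array<int,3>>& out) {
  // enumerate options with log-weights; options must respect the string's
  // characters exactly as the fill phase did
  std::vector<std::array<int,2>> opt;   // (rule, k)
  std::vector<double> lw;
  int len = j - i;
  for (int r = 0; r < G.nrule; ++r) {
    if (G.lhs[r] != t) continue;
    int kd = G.kind[r];
    if (kd == UNPAIRED) {
      if (len == 1 && s[i] == 0) {
        opt.push_back({r, -1}); lw.push_back(0.0);
      }
    } else if (kd == PAIR) {
      if (len >= 3 && s[i] == 1 && s[j - 1] == 2) {
        double inner = T.val[T.id(G.c1[r], i + 1, j - 1)];
        if (inner > R_NegInf) { opt.push_back({r, -1}); lw.push_back(inner); }
      }
    } else {
      for (int k = i + 1; k < j; ++k) {
        double a = T.val[T.id(G.c1[r], i, k)], b = T.val[T.id(G.c2[r], k, j)];
        if (a > R_NegInf && b > R_NegInf) {
          opt.push_back({r, k}); lw.push_back(a + b);
        }
      }
    }
  }
  double mx = R_NegInf;
  for (double w : lw) mx = std::max(mx, w);
  double tot = 0.0;
  std::vector<double> p(lw.size());
  for (size_t q = 0; q < lw.size(); ++q) { p[q] = std::exp(lw[q] - mx); tot += p[q]; }
  double u = unif_rand() * tot, acc = 0.0;
  size_t pick = lw.size() - 1;
  for (size_t q = 0; q < lw.size(); ++q) {
    acc += p[q];
    if (u <= acc) { pick = q; break; }
  }
  int r = opt[pick][0], k = opt[pick][1];
  out.push_back({r, i, j});
  if (G.kind[r] == PAIR) sample_collect(G, T, s, G.c1[r], i + 1, j - 1, out);
  else if (G.kind[r] == BRANCH) {
    sample_collect(G, T, s, G.c1[r], i, k, out);
    sample_collect(G, T, s, G.c2[r], k, j, out);
  }
}

// [[Rcpp::export]]
SEXP cpp_sample_derivation(List grammar, IntegerVector s) {
  Gram G(grammar);
  int n = s.size();
  if (n == 0) return R_NilValue;
  StructTables T;
  structure_fill(G, s, 2, 0.0, T);
  if (T.val[T.id(G.start, 0, n)] == R_NegInf) return R_NilValue;
  std::vector<std::array<int,3>> der;
  sample_collect(G, T, s, G.start, 0, n, der);
  IntegerMatrix m(der.size(), 3);
  for (size_t q = 0; q < der.size(); ++q) {
    m(q, 0) = der[q][0]; m(q, 1) = der[q][1]; m(q, 2) = der[q][2];
  }
  return m;
}

// ---------------------------------------------------------------------------
// Sequence-level inference: inside, outside, posteriors, expected counts.

struct SeqTables {
  int n, nnt;
  std::vector<double> in;
  inline size_t id(int t, int i, int j) const {
    return ((size_t)t * (n + 1) + i) * (n + 1) + j;
  }
};

static void inside_fill(const Gram& G, const IntegerVector& x,
                        const NumericVector& lup, const NumericVector& lpp,
                        SeqTables& T) {
  int n = x.size();
  T.n = n; T.nnt = G.nnt;
  T.in.assign((size_t)G.nnt * (n + 1) * (n + 1), R_NegInf);
  for (int len = 1; len <= n; ++len)
    for (int i = 0; i + len <= n; ++i) {
      int j = i + len;
      for (int r = 0; r < G.nrule; ++r) {
        int t = G.lhs[r], kd = G.kind[r];
        size_t cell = T.id(t, i, j);
        if (kd == UNPAIRED) {
          if (len == 1)
            T.in[cell] = logadd(T.in[cell], G.logp[r] + lup[x[i]]);
        } else if (kd == PAIR) {
          if (len >= 3) {
            double inner = T.in[T.id(G.c1[r], i + 1, j - 1)];
            if (inner > R_NegInf)
              T.in[cell] = logadd(T.in[cell],
                                  G.logp[r] + lpp[4 * x[i] + x[j - 1]] + inner);
          }
        } else if (len >= 2) {
          int u = G.c1[r], v = G.c2[r];
          double acc = R_NegInf;
          for (int k = i + 1; k < j; ++k) {
            double a = T.in[T.id(u, i, k)], b = T.in[T.id(v, k, j)];
            if (a > R_NegInf && b > R_NegInf) acc = logadd(acc, a + b);
          }
          if (acc > R_NegInf)
            T.in[cell] = logadd(T.in[cell], G.logp[r] + acc);
        }
      }
    }
}

// [[Rcpp::export]]
List cpp_inside(List grammar, IntegerVector x, NumericVector lup,
                NumericVector lpp) {
  Gram G(grammar);
  int n = x.size();
  SeqTables T;
  if (n == 0) return List::create(_["loglik"] = R_NegInf);
  inside_fill(G, x, lup, lpp, T);
  // inside table exported as [i+1, j+1, t+1] over half-open spans [i, j)
  NumericVector arr((n + 1) * (n + 1) * G.nnt);
  arr.attr("dim") = IntegerVector::create(n + 1, n + 1, G.nnt);
  for (int t = 0; t < G.nnt; ++t)
    for (int i = 0; i <= n; ++i)
      for (int j = 0; j <= n; ++j)
        arr[(size_t)t * (n + 1) * (n + 1) + j * (n + 1) + i] =
          T.in[T.id(t, i, j)];
  return List::create(_["loglik"] = T.in[T.id(G.start, 0, n)],
                      _["inside"] = arr);
}

// inside + outside + posteriors + expected counts in one pass
// [[Rcpp::export]]
List cpp_inside_outside(List grammar, IntegerVector x, NumericVector lup,
                        NumericVector lpp) {
  Gram G(grammar);
  int n = x.size();
  SeqTables T;
  inside_fill(G, x, lup, lpp, T);
  double total = T.in[T.id(G.start, 0, n)];
  NumericMatrix pairpost(n, n);
  NumericVector unpost(n), rule_exp(G.nrule), up_exp(4), pp_exp(16);
  if (total == R_NegInf)
    return List::create(_["loglik"] = total);
  std::vector<double> out((size_t)G.nnt * (n + 1) * (n + 1), R_NegInf);
  out[T.id(G.start, 0, n)] = 0.0;
  for (int len = n; len >= 1; --len)
    for (int i = 0; i + len <= n; ++i) {
      int j = i + len;
      for (int r = 0; r < G.nrule; ++r) {
        int t = G.lhs[r], kd = G.kind[r];
        double o = out[T.id(t, i, j)];
        if (o == R_NegInf) continue;
        if (kd == UNPAIRED) {
          if (len == 1) {
            double w = std::exp(o + G.logp[r] + lup[x[i]] - total);
            rule_exp[r] += w; up_exp[x[i]] += w; unpost[i] += w;
          }
        } else if (kd == PAIR) {
          if (len >= 3) {
            double inner = T.in[T.id(G.c1[r], i + 1, j - 1)];
            if (inner == R_NegInf) continue;
            double e = lpp[4 * x[i] + x[j - 1]];
            out[T.id(G.c1[r], i + 1, j - 1)] =
              logadd(out[T.id(G.c1[r], i + 1, j - 1)], o + G.logp[r] + e);
            double w = std::exp(o + G.logp[r] + e + inner - total);
            rule_exp[r] += w; pp_exp[4 * x[i] + x[j - 1]] += w;
            pairpost(i, j - 1) += w;
          }
        } else if (len >= 2) {
          int u = G.c1[r], v = G.c2[r];
          for (int k = i + 1; k < j; ++k) {
            double a = T.in[T.id(u, i, k)], b = T.in[T.id(v, k, j)];
            if (a == R_NegInf || b == R_NegInf) continue;
            out[T.id(u, i, k)] =
              logadd(out[T.id(u, i, k)], o + G.logp[r] + b);
            out[T.id(v, k, j)] =
              logadd(out[T.id(v, k, j)], o + G.logp[r] + a);
            rule_exp[r] += std::exp(o + G.logp[r] + a + b - total);
          }
        }
      }
    }
  return List::create(_["loglik"] = total, _["pair_prob"] = pairpost,
                      _["unpaired_prob"] = unpost, _["rule_exp"] = rule_exp,
                      _["unpaired_exp"] = up_exp, _["paired_exp"] = pp_exp);
}

// max-probability derivation of a sequence (joint over derivation+emissions)
// [[Rcpp::export]]
List cpp_sequence_cyk(List grammar, IntegerVector x, NumericVector lup,
                      NumericVector lpp) {
  Gram G(grammar);
  int n = x.size();
  if (n == 0) return List::create(_["logp"] = R_NegInf);
  StructTables T;
  T.n = n; T.nnt = G.nnt;
  T.val.assign((size_t)G.nnt * (n + 1) * (n + 1), R_NegInf);
  T.bt_rule.assign(T.val.size(), -1);
  T.bt_k.assign(T.val.size(), -1);
  for (int len = 1; len <= n; ++len)
    for (int i = 0; i + len <= n; ++i) {
      int j = i + len;
      for (int r = 0; r < G.nrule; ++r) {
        int t = G.lhs[r], kd = G.kind[r];
        size_t cell = T.id(t, i, j);
        if (kd == UNPAIRED) {
          if (len == 1) {
            double v = G.logp[r] + lup[x[i]];
            if (v > T.val[cell]) { T.val[cell] = v; T.bt_rule[cell] = r; }
          }
        } else if (kd == PAIR) {
          if (len >= 3) {
            double inner = T.val[T.id(G.c1[r], i + 1, j - 1)];
            if (inner > R_NegInf) {
              double v = G.logp[r] + lpp[4 * x[i] + x[j - 1]] + inner;
              if (v > T.val[cell]) { T.val[cell] = v; T.bt_rule[cell] = r; }
            }
          }
        } else if (len >= 2) {
          for (int k = i + 1; k < j; ++k) {
            double a = T.val[T.id(G.c1[r], i, k)];
            double b = T.val[T.id(G.c2[r], k, j)];
            if (a > R_NegInf && b > R_NegInf) {
              double v = G.logp[r] + a + b;
              if (v > T.val[cell]) {
                T.val[cell] = v; T.bt_rule[cell] = r; T.bt_k[cell] = k;
              }
            }
          }
        }
      }
    }
  double best = T.val[T.id(G.start, 0, n)];
  if (best == R_NegInf) return List::create(_["logp"] = R_NegInf);
  std::vector<std::array<int,3>> der;
  bt_collect(G, T, G.start, 0, n, der);
  IntegerMatrix m(der.size(), 3);
  IntegerVector partner(n, -1);
  for (size_t q = 0; q < der.size(); ++q) {
    m(q, 0) = der[q][0]; m(q, 1) = der[q][1]; m(q, 2) = der[q][2];
    if (G.kind[der[q][0]] == PAIR) {
      partner[der[q][1]] = der[q][2] - 1;
      partner[der[q][2] - 1] = der[q][1];
    }
  }
  return List::create(_["logp"] = best, _["deriv"] = m,
                      _["partner"] = partner);
}

// ---------------------------------------------------------------------------
// Maximum-expected-accuracy decoding over a posterior matrix (Nussinov-style).
// Objective: sum over chosen pairs of gamma*p(i,j) plus sum over unpaired q(i).
// Ties in the objective (within 1e-12) prefer fewer pairs; option order is
// "leave i unpaired" first, then pairing partners k ascending.

// [[Rcpp::export]]
IntegerVector cpp_mea(NumericMatrix p, NumericVector q, double gamma,
                      int min_hairpin) {
  int n = q.size();
  IntegerVector partner(n, -1);
  if (n == 0) return partner;
  std::vector<double> M((size_t)(n + 1) * (n + 1), 0.0);
  std::vector<int> np((size_t)(n + 1) * (n + 1), 0);
  std::vector<int> bk((size_t)(n + 1) * (n + 1), -1); // -1: i unpaired; else k
  auto id = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  const double eps = 1e-12;
  // closed spans [i, j]; iterate by length
  for (int len = 1; len <= n; ++len)
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double bs = q[i] + (len > 1 ? M[id(i + 1, j)] : 0.0);
      int bn = (len > 1 ? np[id(i + 1, j)] : 0), bb = -1;
      for (int k = i + min_hairpin + 1; k <= j; ++k) {
        double inner = (k - 1 >= i + 1) ? M[id(i + 1, k - 1)] : 0.0;
        int inn = (k - 1 >= i + 1) ? np[id(i + 1, k - 1)] : 0;
        double rest = (k + 1 <= j) ? M[id(k + 1, j)] : 0.0;
        int rn = (k + 1 <= j) ? np[id(k + 1, j)] : 0;
        double v = gamma * p(i, k) + inner + rest;
        int nn = 1 + inn + rn;
        if (v > bs + eps || (std::fabs(v - bs) <= eps && nn < bn)) {
          bs = v; bn = nn; bb = k;
        }
      }
      M[id(i, j)] = bs; np[id(i, j)] = bn; bk[id(i, j)] = bb;
    }
  // backtrack
  std::vector<std::array<int,2>> stack{{0, n - 1}};
  while (!stack.empty()) {
    auto [i, j] = stack.back(); stack.pop_back();
    if (i > j) continue;
    int k = bk[id(i, j)];
    if (k < 0) stack.push_back({i + 1, j});
    else {
      partner[i] = k; partner[k] = i;
      stack.push_back({i + 1, k - 1});
      stack.push_back({k + 1, j});
    }
  }
  return partner;
}
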