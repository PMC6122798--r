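// Stack-machine evaluator for postfix-compiled expression trees.
//
// A program is a pair of parallel vectors (code, val): `code` holds opcodes
// in postorder, `val` holds the 1-based terminal column for LOAD_VAR and the
// constant for LOAD_CONST (0 otherwise). Protected-operator semantics are
// kept in exact agreement with the R primitives in R/primitives.R; the unit
// tests assert equality of both evaluation paths on random trees.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

enum Op {
  OP_ADD = 1, OP_SUB = 2, OP_MUL = 3, OP_DIV = 4,
  OP_SIN = 5, OP_COS = 6, OP_TAN = 7, OP_SQRT = 8, OP_EXP = 9, OP_LOG = 10,
  OP_VAR = 11, OP_CONST = 12
};

static inline int op_arity(int op) {
  if (op <= OP_DIV) return 2;
  if (op <= OP_LOG) return 1;
  return 0;
}

static inline double clamp_mag(double x) {
  if (x > 1e150) return 1e150;
  if (x < -1e150) return -1e150;
  return x;
}

static void eval_program(const IntegerVector& code, const NumericVector& val,
                         const NumericMatrix& X, std::vector<double>& out) {
  const int n = X.nrow();
  const int L = code.size();
  // stack of value vectors; depth never exceeds tree depth (<= cap)
  std::vector<std::vector<double>> stack;
  stack.reserve(64);
  int top = -1;

  for (int i = 0; i < L; ++i) {
    const int op = code[i];
    if (op == OP_CONST) {
      ++top;
      if ((int)stack.size() <= top) stack.emplace_back(n);
      std::fill(stack[top].begin(), stack[top].end(), val[i]);
    } else if (op == OP_VAR) {
      ++top;
      if ((int)stack.size() <= top) stack.emplace_back(n);
      const int col = (int)val[i] - 1;
      for (int r = 0; r < n; ++r) stack[top][r] = X(r, col);
    } else if (op_arity(op) == 1) {
      double* a = stack[top].data();
      switch (op) {
      case OP_SIN: for (int r = 0; r < n; ++r) a[r] = std::sin(a[r]); break;
      case OP_COS: for (int r = 0; r < n; ++r) a[r] = std::cos(a[r]); break;
      case OP_TAN:
        for (int r = 0; r < n; ++r) {
          double t = std::tan(a[r]);
          a[r] = t > 1e6 ? 1e6 : (t < -1e6 ? -1e6 : t);
        }
        break;
      case OP_SQRT: for (int r = 0; r < n; ++r) a[r] = std::sqrt(std::fabs(a[r])); break;
      case OP_EXP:
        for (int r = 0; r < n; ++r) {
          double t = a[r] > 50.0 ? 50.0 : (a[r] < -50.0 ? -50.0 : a[r]);
          a[r] = std::exp(t);
        }
        break;
      case OP_LOG:
        for (int r = 0; r < n; ++r)
          a[r] = (a[r] == 0.0) ? 0.0 : std::log(std::fabs(a[r]));
        break;
      }
    } else {
      // binary: operands are the two top stack slots
      double* b = stack[top].data();
      double* a = stack[top - 1].data();
      switch (op) {
      case OP_ADD: for (int r = 0; r < n; ++r) a[r] += b[r]; break;
      case OP_SUB: for (int r = 0; r < n; ++r) a[r] -= b[r]; break;
      case OP_MUL: for (int r = 0; r < n; ++r) a[r] = clamp_mag(a[r] * b[r]); break;
      case OP_DIV:
        for (int r = 0; r < n; ++r) {
          a[r] = (std::fabs(b[r]) < 1e-9) ? 1.0 : clamp_mag(a[r] / b[r]);
        }
        break;
      }
      --top;
    }
  }
  out.assign(stack[0].begin(), stack[0].end());
}

// [[Rcpp::export(name = ".prog_eval")]]
NumericVector prog_eval(IntegerVector code, NumericVector val,
                        NumericMatrix X) {
  std::vector<double> out;
  eval_program(code, val, X, out);
  return NumericVector(out.begin(), out.end());
}

// censored-data negative log-likelihood of a program's log-odds
// [[Rcpp::export(name = ".prog_nll")]]
double prog_nll(IntegerVector code, NumericVector val, NumericMatrix X,
                IntegerVector event) {
  std::vector<double> eps;
  eval_program(code, val, X, eps);
  const int n = X.nrow();
  double total = 0.0;
  for (int r = 0; r < n; ++r) {
    double h = R::plogis(eps[r], 0.0, 1.0, 1, 0);
    if (h < 1e-12) h = 1e-12;
    if (h > 1.0 - 1e-12) h = 1.0 - 1e-12;
    total -= (event[r] == 1) ? std::log(h) : std::log1p(-h);
  }
  return total;
}

// depth of the tree a postfix program encodes (leaf = 1)
// [[Rcpp::export(name = ".prog_depth")]]
int prog_depth(IntegerVector code) {
  std::vector<int> stack;
  stack.reserve(64);
  for (int i = 0; i < code.size(); ++i) {
    const int a = op_arity(code[i]);
    if (a == 0) {
      stack.push_back(1);
    } else if (a == 1) {
      stack.back() += 1;
    } else {
      int right = stack.back();
      stack.pop_back();
      int& left = stack.back();
      left = 1 + (left > right ? left : right);
    }
  }
  return stack.back();
}

// 1-based start index of the subtree whose root sits at position pos;
// in postfix a subtree is the contiguous slice [start, pos]
// [[Rcpp::export(name = ".prog_subtree_start")]]
int prog_subtree_start(IntegerVector code, int pos) {
  int need = 1;
  int i = pos - 1; // 0-based
  while (need > 0) {
    need += op_arity(code[i]) - 1;
    --i;
  }
  return i + 2; // back to 1-based
}
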