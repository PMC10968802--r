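#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Expression programs are flat prefix-order encodings:
//   ops[i] > 0  : operator id (1..14, arity in OP_ARITY)
//   ops[i] == 0 : the time variable t
//   ops[i] == -1: a constant, value in consts[i]
// Operator ids: 1 add, 2 sub, 3 mult, 4 div, 5 max, 6 min,
//               7 sqrt, 8 log, 9 abs, 10 neg, 11 inv, 12 sin, 13 cos, 14 tan

static const int OP_ARITY[15] = {0, 2, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1, 1, 1};

// Protected-evaluation guards: near-zero cutoff for div/log/inv, a clamp for
// tan, and a global magnitude clamp so no finite inputs can overflow to Inf.
static const double EPS = 1e-6;
static const double TAN_CLAMP = 1e6;
static const double VAL_CLAMP = 1e10;

static inline double clampv(double x) {
  if (std::isnan(x)) return 0.0;
  if (x > VAL_CLAMP) return VAL_CLAMP;
  if (x < -VAL_CLAMP) return -VAL_CLAMP;
  return x;
}

static inline double apply_op(int op, double a, double b) {
  double v = 0.0;
  switch (op) {
  case 1: v = a + b; break;
  case 2: v = a - b; break;
  case 3: v = a * b; break;
  case 4: v = (std::fabs(b) < EPS) ? 1.0 : a / b; break;
  case 5: v = (a > b) ? a : b; break;
  case 6: v = (a < b) ? a : b; break;
  case 7: v = std::sqrt(std::fabs(a)); break;
  case 8: v = (std::fabs(a) < EPS) ? 0.0 : std::log(std::fabs(a)); break;
  case 9: v = std::fabs(a); break;
  case 10: v = -a; break;
  case 11: v = (std::fabs(a) < EPS) ? 1.0 : 1.0 / a; break;
  case 12: v = std::sin(a); break;
  case 13: v = std::cos(a); break;
  case 14:
    v = std::tan(a);
    if (v > TAN_CLAMP) v = TAN_CLAMP;
    if (v < -TAN_CLAMP) v = -TAN_CLAMP;
    break;
  default: stop("unknown operator id %d", op);
  }
  return clampv(v);
}

// [[Rcpp::export]]
NumericVector eval_program_cpp(IntegerVector ops, NumericVector consts,
                               NumericVector t) {
  const int n = ops.size();
  const int m = t.size();
  if (n == 0) stop("empty program");
  // Reverse scan of the prefix encoding: the first pop is the first operand.
  std::vector< std::vector<double> > stack;
  stack.reserve(8);
  for (int i = n - 1; i >= 0; --i) {
    int op = ops[i];
    if (op == 0) {
      std::vector<double> v(t.begin(), t.end());
      stack.push_back(v);
    } else if (op == -1) {
      stack.push_back(std::vector<double>(m, consts[i]));
    } else if (op >= 1 && op <= 14) {
      int ar = OP_ARITY[op];
      if ((int)stack.size() < ar) stop("malformed program: missing operands");
      if (ar == 1) {
        std::vector<double> &a = stack.back();
        for (int j = 0; j < m; ++j) a[j] = apply_op(op, a[j], 0.0);
      } else {
        std::vector<double> a = stack.back(); stack.pop_back();
        std::vector<double> &b = stack.back();
        for (int j = 0; j < m; ++j) b[j] = apply_op(op, a[j], b[j]);
      }
    } else {
      stop("invalid op code %d", op);
    }
  }
  if (stack.size() != 1) stop("malformed program: dangling operands");
  return NumericVector(stack.back().begin(), stack.back().end());
}

// End index (1-based, inclusive) of the subtree rooted at `start` (1-based).
// [[Rcpp::export]]
int subtree_end_cpp(IntegerVector ops, int start) {
  const int n = ops.size();
  if (start < 1 || start > n) stop("subtree start out of range");
  int need = 1;
  int i = start - 1;
  while (need > 0) {
    if (i >= n) stop("malformed program: truncated subtree");
    int op = ops[i];
    int ar = (op > 0) ? OP_ARITY[op] : 0;
    need += ar - 1;
    ++i;
  }
  return i;
}

// Depth of the prefix-encoded tree; a single leaf has depth 0.
// [[Rcpp::export]]
int program_depth_cpp(IntegerVector ops) {
  const int n = ops.size();
  if (n == 0) stop("empty program");
  std::vector<int> stack;
  for (int i = n - 1; i >= 0; --i) {
    int op = ops[i];
    if (op <= 0) {
      stack.push_back(0);
    } else {
      int ar = OP_ARITY[op];
      if ((int)stack.size() < ar) stop("malformed program: missing operands");
      int d = stack.back(); stack.pop_back();
      if (ar == 2) {
        int d2 = stack.back(); stack.pop_back();
        if (d2 > d) d = d2;
      }
      stack.push_back(d + 1);
    }
  }
  if (stack.size() != 1) stop("malformed program: dangling operands");
  return stack.back();
}
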