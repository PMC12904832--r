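// Compiled fast path of the simulated distributed reduction engine for
// numeric operators. It realizes exactly the same operation order as the R
// reference engine: per-PE programs are executed in a child-before-parent
// (topological) PE order, stacks hold plain IEEE 754 doubles, and REDUCE
// applies (second-popped op first-popped) with no reassociation, so results
// are bitwise identical to the reference engine and to the sequential
// pairwise oracle.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double combine(int opId, double a, double b) {
  switch (opId) {
    case 1: return a + b;       // float-add
    case 2: return a * b;       // float-mul
    case 3: return std::max(a, b);
    case 4: return a + b;       // int-add (exact below 2^53)
  }
  Rcpp::stop("unknown native operator id");
  return 0.0;                   // not reached
}

// programsOpcode/programsArg: per-PE op lists (opcodes 1=PUSH_LOCAL,
// 2=PUSH_RECV, 3=REDUCE); peOrder: 0-based PE ranks, children before their
// communication-tree parent; values: the length-n input array.
// [[Rcpp::export(name = ".cppExecuteReduce")]]
List cppExecuteReduce(List programsOpcode, List programsArg,
                      IntegerVector peOrder, NumericVector values,
                      int opId) {
  const int p = programsOpcode.size();
  std::vector< std::vector<double> > outbox(p);
  std::vector<size_t> taken(p, 0);
  long reduceCount = 0;

  for (int oi = 0; oi < p; ++oi) {
    const int r = peOrder[oi];
    IntegerVector opc = programsOpcode[r];
    IntegerVector arg = programsArg[r];
    std::vector<double> stack;
    stack.reserve(opc.size());
    for (R_xlen_t i = 0; i < opc.size(); ++i) {
      const int a = arg[i];
      switch (opc[i]) {
        case 1:  // PUSH_LOCAL
          stack.push_back(values[a]);
          break;
        case 2: {  // PUSH_RECV from PE a (its message must exist already)
          if (taken[a] >= outbox[a].size())
            Rcpp::stop("PUSH_RECV from PE %d popped an exhausted message", a);
          stack.push_back(outbox[a][taken[a]++]);
          break;
        }
        case 3: {  // REDUCE
          if (stack.size() < 2)
            Rcpp::stop("REDUCE on PE %d popped an empty stack", r);
          const double top = stack.back(); stack.pop_back();
          const double below = stack.back(); stack.pop_back();
          stack.push_back(combine(opId, below, top));
          ++reduceCount;
          break;
        }
        default:
          Rcpp::stop("unknown opcode");
      }
    }
    outbox[r] = stack;
  }

  // all messages fully consumed?
  for (int r = 1; r < p; ++r)
    if (taken[r] != outbox[r].size())
      Rcpp::stop("PE %d left %d unconsumed received values", r,
                 (int)(outbox[r].size() - taken[r]));
  if (outbox[0].size() != 1)
    Rcpp::stop("root stack holds %d values, expected exactly 1",
               (int)outbox[0].size());

  IntegerVector residual(p);
  for (int r = 0; r < p; ++r) residual[r] = (int)outbox[r].size();
  return List::create(_["value"] = outbox[0][0],
                      _["reduceCount"] = (double)reduceCount,
                      _["residual"] = residual);
}
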