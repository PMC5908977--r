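#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Greedy single-node move sweeps over a symmetric score matrix.
//
// S is a dense symmetric n x n score matrix (entries may be negative);
// the objective being maximized is sum_{i != j} S(i,j) * delta(comm_i, comm_j)
// (the diagonal is partition-invariant and ignored).
//
// order and comm0 are 0-based. Nodes are visited in the fixed `order`;
// for each node the candidate communities are scanned in ascending label,
// so equal-gain ties resolve to the first candidate encountered. Moving to
// an empty label detaches the node into a singleton. A move is accepted
// only when its gain exceeds tol, which guarantees termination.
// [[Rcpp::export(rng = false)]]
List louvain_sweeps(NumericMatrix S, IntegerVector order, IntegerVector comm0,
                    double tol, int maxSweeps) {
  const int n = S.nrow();
  IntegerVector comm = clone(comm0);
  std::vector<double> k(n, 0.0);
  bool any = false, moved = true;
  int sweep = 0;
  while (moved && sweep < maxSweeps) {
    moved = false;
    ++sweep;
    for (int idx = 0; idx < n; ++idx) {
      const int i = order[idx];
      const int a = comm[i];
      std::fill(k.begin(), k.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (j != i) k[comm[j]] += S(j, i);
      }
      int best = a;
      double bestGain = tol;
      for (int c = 0; c < n; ++c) {
        if (c == a) continue;
        const double g = k[c] - k[a];
        if (g > bestGain) {
          bestGain = g;
          best = c;
        }
      }
      if (best != a) {
        comm[i] = best;
        moved = true;
        any = true;
      }
    }
  }
  return List::create(_["comm"] = comm, _["moved"] = any, _["sweeps"] = sweep);
}

// Kernighan-Lin style refinement: repeatedly perform the globally best
// single-node move (even when its gain is negative), locking each moved
// node, and keep the best configuration seen along the move sequence.
// Escapes local optima that require a temporary objective decrease.
// Deterministic: candidates scanned in ascending node and label order.
// A pass aborts once the running objective drops more than maxValleyDepth
// below the best configuration seen, bounding the time spent exploring
// hopeless move sequences (non-positive values disable the bound).
// [[Rcpp::export(rng = false)]]
List kl_refine(NumericMatrix S, IntegerVector comm0, double tol,
               int maxPasses, int maxMovesPerNode = 3,
               double maxValleyDepth = -1.0) {
  const int n = S.nrow();
  IntegerVector comm = clone(comm0);
  std::vector<double> k(n, 0.0);
  std::vector<bool> hasNbr(n, false);
  bool improvedAny = false;
  for (int pass = 0; pass < maxPasses; ++pass) {
    std::vector<int> movesUsed(n, 0);
    std::vector<int> size(n, 0);
    for (int i = 0; i < n; ++i) ++size[comm[i]];
    IntegerVector start = clone(comm);
    IntegerVector best = clone(comm);
    double cum = 0.0, bestCum = 0.0;
    const int maxSteps = n * maxMovesPerNode;
    for (int step = 0; step < maxSteps; ++step) {
      int moveNode = -1, moveTo = -1;
      double moveGain = -std::numeric_limits<double>::infinity();
      for (int i = 0; i < n; ++i) {
        if (movesUsed[i] >= maxMovesPerNode) continue;
        const int a = comm[i];
        std::fill(k.begin(), k.end(), 0.0);
        std::fill(hasNbr.begin(), hasNbr.end(), false);
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          const double s = S(j, i);
          if (s != 0.0) {
            k[comm[j]] += s;
            hasNbr[comm[j]] = true;
          }
        }
        // candidates: communities holding a neighbor of i, plus (for a
        // non-singleton) one empty label = detaching into a singleton;
        // pure label shuffles with zero gain are excluded so they cannot
        // lock nodes without progress
        int detach = -1;
        if (size[a] > 1) {
          for (int c = 0; c < n; ++c) {
            if (size[c] == 0) { detach = c; break; }
          }
        }
        for (int c = 0; c < n; ++c) {
          if (c == a || (!hasNbr[c] && c != detach)) continue;
          const double g = k[c] - k[a];
          if (g > moveGain) {
            moveGain = g;
            moveNode = i;
            moveTo = c;
          }
        }
      }
      if (moveNode < 0) break;
      --size[comm[moveNode]];
      ++size[moveTo];
      comm[moveNode] = moveTo;
      ++movesUsed[moveNode];
      cum += 2.0 * moveGain;
      if (cum > bestCum + tol) {
        bestCum = cum;
        best = clone(comm);
      }
      if (maxValleyDepth > 0.0 && bestCum - cum > maxValleyDepth) break;
    }
    if (bestCum > tol) {
      comm = clone(best);
      improvedAny = true;
    } else {
      comm = start;
      break;
    }
  }
  return List::create(_["comm"] = comm, _["improved"] = improvedAny);
}
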