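// Exact offline ED schedule optimisation.
//
// Depth-first branch-and-bound over slot-level joint assignment decisions.
// State per patient: phase (first exam / lab / second exam / discharged),
// remaining scaled work of the current exam, lab-return slot, the physician
// treating in the previous slot (restart detection), and bitmasks of
// physicians that have already treated each exam (adverse-consequence risk is
// incurred once per patient-physician-exam triple).
//
// Work accounting: each exam requires TT nominal slots; a slot by physician j
// delivers 1/CE(j). Remaining work is stored scaled by the LCM of the CE
// values so all arithmetic is integral; an exam completes at the first slot
// where cumulative delivered work reaches the nominal requirement.
//
// Exactness: the search enumerates every joint action (idling, preemption,
// handoffs) and prunes only with an admissible lower bound -- cost already
// accrued plus presence cost over each patient's minimum achievable remaining
// stay plus, for untouched exams, the cheapest physician's risk. Actions are
// ordered densest-first so a good incumbent is found on the first descent.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const int MAXN = 8; // patients
static const int MAXM = 4; // physicians

struct Prob {
  int n, m, T;
  int a1[MAXN];
  bool needs2[MAXN];
  int full1[MAXN], full2[MAXN], lt[MAXN], tb1[MAXN], tb2[MAXN];
  int red[MAXM]; // scaled work delivered per slot by physician j
  int maxred;
  double riskCost[MAXN][MAXM][2];
  double minRisk[MAXN][2];
  double preCost[MAXN][2];
  double waitCost[MAXN][2]; // per slot waited beyond the triage bound
  double presCost[MAXN];    // per slot present in the ED (LOS + crowding)
  double maxNodes;
};

struct State {
  int8_t ph[MAXN];
  int16_t rem[MAXN];
  int16_t aux[MAXN]; // lab-return slot == second-exam arrival
  int8_t prevj[MAXN];
  uint8_t mask[MAXN][2];
};

typedef std::array<int8_t, MAXM> Action;

class Solver {
public:
  Prob P;
  double nodes = 0;
  double bestCost = R_PosInf;
  int bestLen = 0;
  std::vector<Action> bestPath, curPath;
  std::vector<Action> actBuf; // scratch for per-slot enumeration

  void advance(State& s, int t) const {
    for (int i = 0; i < P.n; ++i)
      if (s.ph[i] == 1 && s.aux[i] <= t) s.ph[i] = 2;
  }

  bool allDone(const State& s) const {
    for (int i = 0; i < P.n; ++i)
      if (s.ph[i] != 3) return false;
    return true;
  }

  double lowerBound(const State& s, int t) const {
    double lb = 0;
    for (int i = 0; i < P.n; ++i) {
      if (s.ph[i] == 3) continue;
      int slots = 0;
      if (s.ph[i] == 0) {
        slots = (s.rem[i] + P.maxred - 1) / P.maxred;
        if (P.needs2[i]) slots += P.lt[i] + (P.full2[i] + P.maxred - 1) / P.maxred;
      } else if (s.ph[i] == 1) {
        int wait = s.aux[i] - t;
        if (wait < 0) wait = 0;
        slots = wait + (s.rem[i] + P.maxred - 1) / P.maxred;
      } else {
        slots = (s.rem[i] + P.maxred - 1) / P.maxred;
      }
      lb += P.presCost[i] * slots;
      if (s.ph[i] == 0 && s.mask[i][0] == 0) lb += P.minRisk[i][0];
      if (P.needs2[i] && s.mask[i][1] == 0) lb += P.minRisk[i][1];
    }
    return lb;
  }

  // Mutates the state; returns the action-dependent slot cost (risk on a new
  // patient-physician-exam start, restart penalties, excess-wait accrual for
  // eligible patients left waiting).
  double applyAction(State& s, int t, const int8_t* act) const {
    double c = 0;
    bool assigned[MAXN];
    std::memset(assigned, 0, sizeof(assigned));
    int8_t newprev[MAXN];
    for (int i = 0; i < P.n; ++i) newprev[i] = 0;
    for (int j = 0; j < P.m; ++j) {
      int i = act[j];
      if (i < 0) continue;
      int e = (s.ph[i] == 0) ? 0 : 1;
      int full = (e == 0) ? P.full1[i] : P.full2[i];
      bool start = (s.prevj[i] != j + 1);
      if (start) {
        if (s.rem[i] < full) c += P.preCost[i][e];
        if (!(s.mask[i][e] & (1 << j))) {
          c += P.riskCost[i][j][e];
          s.mask[i][e] |= (uint8_t)(1 << j);
        }
      }
      s.rem[i] = (int16_t)(s.rem[i] - P.red[j]);
      assigned[i] = true;
      if (s.rem[i] <= 0) {
        if (e == 0) {
          if (P.needs2[i]) {
            s.ph[i] = 1;
            s.aux[i] = (int16_t)(t + 1 + P.lt[i]);
            s.rem[i] = (int16_t)P.full2[i];
          } else {
            s.ph[i] = 3;
          }
        } else {
          s.ph[i] = 3;
        }
        newprev[i] = 0;
      } else {
        newprev[i] = (int8_t)(j + 1);
      }
    }
    for (int i = 0; i < P.n; ++i) {
      if (assigned[i]) continue;
      if (s.ph[i] == 0 && t >= P.a1[i] && s.rem[i] == P.full1[i] &&
          t >= P.a1[i] + P.tb1[i])
        c += P.waitCost[i][0];
      else if (s.ph[i] == 2 && s.rem[i] == P.full2[i] &&
               t >= s.aux[i] + P.tb2[i])
        c += P.waitCost[i][1];
    }
    for (int i = 0; i < P.n; ++i) s.prevj[i] = newprev[i];
    return c;
  }

  // enumerate all injective physician -> {idle} + eligible maps,
  // densest assignments first
  void enumActions(const int* elig, int ne, std::vector<Action>& out) const {
    out.clear();
    Action a;
    a.fill(-1);
    out.push_back(a);
    for (int j = 0; j < P.m; ++j) {
      std::vector<Action> nxt;
      nxt.reserve(out.size() * (ne + 1));
      for (const Action& base : out) {
        for (int q = 0; q < ne; ++q) {
          bool used = false;
          for (int jj = 0; jj < j; ++jj)
            if (base[jj] == elig[q]) { used = true; break; }
          if (used) continue;
          Action b = base;
          b[j] = (int8_t)elig[q];
          nxt.push_back(b);
        }
        Action b = base;
        b[j] = -1;
        nxt.push_back(b);
      }
      out.swap(nxt);
    }
  }

  void dfs(int t, State s, double accrued) {
    advance(s, t);
    if (allDone(s)) {
      if (accrued < bestCost - 1e-12) {
        bestCost = accrued;
        bestLen = t;
        bestPath.assign(curPath.begin(), curPath.begin() + t);
      }
      return;
    }
    if (t >= P.T) return;
    if (accrued + lowerBound(s, t) >= bestCost - 1e-12) return;
    nodes += 1;
    if (nodes > P.maxNodes)
      stop("offline solver exceeded its node limit; instance too large for exact solving");
    double bc = 0;
    for (int i = 0; i < P.n; ++i)
      if (s.ph[i] < 3 && t >= P.a1[i]) bc += P.presCost[i];
    int elig[MAXN], ne = 0;
    for (int i = 0; i < P.n; ++i)
      if ((s.ph[i] == 0 && t >= P.a1[i]) || s.ph[i] == 2) elig[ne++] = i;
    std::vector<Action> actions;
    enumActions(elig, ne, actions);
    for (const Action& act : actions) {
      State s2 = s;
      double c = applyAction(s2, t, act.data());
      if ((int)curPath.size() <= t) curPath.resize(t + 1);
      curPath[t] = act;
      dfs(t + 1, s2, accrued + bc + c);
    }
  }
};

static void fillProb(Solver& S, const List& prob) {
  Prob& P = S.P;
  P.n = as<int>(prob["n"]);
  P.m = as<int>(prob["m"]);
  P.T = as<int>(prob["T"]);
  if (P.n > MAXN) stop("at most %d patients supported by the exact solver", MAXN);
  if (P.m > MAXM) stop("at most %d physicians supported by the exact solver", MAXM);
  IntegerVector a1 = prob["a1"], full1 = prob["full1"], full2 = prob["full2"],
                lt = prob["lt"], tb1 = prob["tb1"], tb2 = prob["tb2"],
                red = prob["red"];
  LogicalVector needs2 = prob["needs2"];
  NumericVector riskCost = prob["riskCost"], preCost = prob["preCost"],
                waitCost = prob["waitCost"], presCost = prob["presCost"];
  for (int i = 0; i < P.n; ++i) {
    P.a1[i] = a1[i];
    P.needs2[i] = needs2[i];
    P.full1[i] = full1[i];
    P.full2[i] = full2[i];
    P.lt[i] = lt[i];
    P.tb1[i] = tb1[i];
    P.tb2[i] = tb2[i];
    P.presCost[i] = presCost[i];
    for (int e = 0; e < 2; ++e) {
      P.preCost[i][e] = preCost[i + P.n * e];
      P.waitCost[i][e] = waitCost[i + P.n * e];
      double mn = R_PosInf;
      for (int j = 0; j < P.m; ++j) {
        P.riskCost[i][j][e] = riskCost[i + P.n * (j + (R_xlen_t)P.m * e)];
        if (P.riskCost[i][j][e] < mn) mn = P.riskCost[i][j][e];
      }
      P.minRisk[i][e] = mn;
    }
  }
  P.maxred = 1;
  for (int j = 0; j < P.m; ++j) {
    P.red[j] = red[j];
    if (P.red[j] > P.maxred) P.maxred = P.red[j];
  }
  P.maxNodes = as<double>(prob["max_nodes"]);
}

// [[Rcpp::export]]
List ed_exact_solve(List prob) {
  Solver S;
  fillProb(S, prob);
  Prob& P = S.P;
  State s0;
  std::memset(&s0, 0, sizeof(s0));
  for (int i = 0; i < P.n; ++i) {
    s0.ph[i] = 0;
    s0.rem[i] = (int16_t)P.full1[i];
  }
  IntegerMatrix pat(P.T, P.m), ex(P.T, P.m);
  if (P.n == 0) {
    return List::create(_["objective"] = 0.0, _["feasible"] = true,
                        _["patient"] = pat, _["exam"] = ex,
                        _["nodes"] = 0.0);
  }
  S.curPath.resize(P.T);
  S.dfs(0, s0, 0.0);
  bool feasible = R_finite(S.bestCost);
  if (feasible) {
    // replay the optimal action path to recover per-slot assignments and
    // which exam each treatment slot served
    State cur = s0;
    for (int t = 0; t < S.bestLen; ++t) {
      S.advance(cur, t);
      const Action& a = S.bestPath[t];
      for (int j = 0; j < P.m; ++j) {
        int i = a[j];
        if (i >= 0) {
          pat(t, j) = i + 1;
          ex(t, j) = (cur.ph[i] == 0) ? 1 : 2;
        }
      }
      S.applyAction(cur, t, a.data());
    }
  }
  return List::create(_["objective"] = S.bestCost, _["feasible"] = feasible,
                      _["patient"] = pat, _["exam"] = ex,
                      _["nodes"] = S.nodes);
}
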