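// Partial-propensity SSA engines: DM (reference), PDM, SPDM, PSSA-CR,
// dPDM (delays), and the next-subvolume reaction-diffusion loop.
//
// Conventions shared with the R reference implementation (ppstate.R):
//  - propensity a = c * prod(choose(n_i, s_i)) over distinct reactants;
//  - partial propensity pi with a = n_pivot * pi; pivot of a two-reactant
//    channel is the stoichiometry-one species when the other has
//    stoichiometry > 1, otherwise the smaller species index; a single
//    reactant of stoichiometry s has pi = c * choose(n-1, s-1) / s;
//  - structure rows: row 0 = source channels, row i+1 = pivot species i;
//    Lambda = row sums, Sigma = n * Lambda, a0 = sum(Sigma).
//
// RNG: per-trajectory mt19937_64 streams seeded via a splitmix64 mix of
// (master seed, trajectory index); uniforms take the top 53 bits so event
// sequences are platform-independent. Each event consumes one uniform for
// the waiting time and one for channel selection (remainder reuse for the
// two-level scan); PSSA-CR additionally consumes uniforms in its
// rejection loop, and the spatial loop one per redraw/choice.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <climits>
#include <random>
#include <limits>
#include <map>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- RNG ----

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct RNG {
  std::mt19937_64 eng;
  RNG(uint64_t master, uint64_t stream) {
    eng.seed(splitmix64(splitmix64(master) ^ (stream * 0x9E3779B97F4A7C15ULL)));
  }
  // uniform in [0, 1)
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform in (0, 1): used for waiting times so Exp draws are positive
  double unifOpen() { return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double expdraw(double rate) { return -std::log(unifOpen()) / rate; }
};

// ------------------------------------------------------------- model ----

static inline double chooseSmall(double n, int k) {
  double r = 1.0;
  for (int i = 0; i < k; ++i) r *= (n - i) / (i + 1);
  return r > 0 ? r : 0.0;
}

struct Rxn {
  std::vector<std::pair<int, int>> reactants, products;
  std::vector<std::pair<int, int>> delta, consumeDelta, produceDelta;
  double c;
  double delay;
  bool consuming, hasDelay;
  int pivot;        // -1 = source row
  int pivotStoich;
  int other;        // -1 = none
  int otherStoich;
};

enum Method { M_DM = 0, M_PDM, M_SPDM, M_PSSACR, M_DPDM };

static int methodCode(const std::string& m) {
  if (m == "dm") return M_DM;
  if (m == "pdm") return M_PDM;
  if (m == "spdm") return M_SPDM;
  if (m == "pssacr") return M_PSSACR;
  if (m == "dpdm") return M_DPDM;
  stop("unknown method '%s'; valid methods: dm, pdm, spdm, pssacr, dpdm, psrd",
       m.c_str());
  return -1;
}

static std::vector<Rxn> parseModel(const List& model, int& S) {
  S = as<int>(model["nSpecies"]);
  List ri = model["reactantIdx"], rs = model["reactantSt"];
  List pi_ = model["productIdx"], ps = model["productSt"];
  NumericVector cc = model["c"], dl = model["delay"];
  LogicalVector cons = model["consuming"];
  int M = cc.size();
  std::vector<Rxn> rxns(M);
  for (int m = 0; m < M; ++m) {
    Rxn& r = rxns[m];
    IntegerVector a = ri[m], b = rs[m], p = pi_[m], q = ps[m];
    for (int i = 0; i < a.size(); ++i) r.reactants.push_back({a[i], b[i]});
    for (int i = 0; i < p.size(); ++i) r.products.push_back({p[i], q[i]});
    r.c = cc[m];
    r.delay = NumericVector::is_na(dl[m]) ? -1.0 : dl[m];
    r.hasDelay = r.delay > 0;
    r.consuming = cons[m];
    // net / consume / produce deltas over species touched
    std::map<int, int> d;
    for (auto& x : r.reactants) {
      d[x.first] -= x.second;
      r.consumeDelta.push_back({x.first, -x.second});
    }
    for (auto& x : r.products) {
      d[x.first] += x.second;
      r.produceDelta.push_back({x.first, x.second});
    }
    for (auto& x : d) if (x.second != 0) r.delta.push_back(x);
    // pivot assignment
    if (r.reactants.empty()) {
      r.pivot = -1; r.pivotStoich = 0; r.other = -1; r.otherStoich = 0;
    } else if (r.reactants.size() == 1) {
      r.pivot = r.reactants[0].first;
      r.pivotStoich = r.reactants[0].second;
      r.other = -1; r.otherStoich = 0;
    } else if (r.reactants.size() == 2) {
      int i0 = r.reactants[0].first, s0 = r.reactants[0].second;
      int i1 = r.reactants[1].first, s1 = r.reactants[1].second;
      if (s0 > 1 && s1 > 1) stop("two reactants with stoichiometry > 1");
      if (s0 > 1) { r.pivot = i1; r.other = i0; r.otherStoich = s0; }
      else if (s1 > 1) { r.pivot = i0; r.other = i1; r.otherStoich = s1; }
      else if (i0 < i1) { r.pivot = i0; r.other = i1; r.otherStoich = 1; }
      else { r.pivot = i1; r.other = i0; r.otherStoich = 1; }
      r.pivotStoich = 1;
    } else {
      stop("more than two distinct reactant species");
    }
  }
  return rxns;
}

static inline double piValue(const Rxn& r, const std::vector<long>& n) {
  if (r.pivot < 0) return r.c;
  if (r.other < 0) {
    if (r.pivotStoich == 1) return r.c;
    long np = n[r.pivot];
    if (np < 1) return 0.0;
    return r.c * chooseSmall((double)(np - 1), r.pivotStoich - 1) / r.pivotStoich;
  }
  return r.c * chooseSmall((double)n[r.other], r.otherStoich);
}

static inline double propValue(const Rxn& r, const std::vector<long>& n) {
  double a = r.c;
  for (auto& p : r.reactants) a *= chooseSmall((double)n[p.first], p.second);
  return a;
}

// ------------------------------------------------------------ engine ----

class Engine {
public:
  int S, M, method;
  std::vector<Rxn> rxns;
  std::vector<long> n;

  // partial-propensity structure
  std::vector<int> rowOf, colOf;
  std::vector<std::vector<int>> rowRxns;   // per row: reaction ids
  std::vector<double> pival;               // per reaction
  std::vector<double> Lambda, Sigma;
  double a0, a0max;
  std::vector<std::vector<int>> dep;       // per species: dependent reactions

  // scan order (PDM fixed, SPDM bubbling)
  std::vector<int> groupOrder, groupPos;           // row <-> scan position
  std::vector<std::vector<int>> colOrder, colPos;  // per row

  // composition-rejection bins (PSSA-CR): bin j holds rows with
  // Sigma in [2^j, 2^{j+1})
  std::map<int, std::vector<int>> bins;
  std::map<int, double> binSum;
  std::vector<int> binOf, posInBin;

  // DM propensity cache
  std::vector<double> aDirect;

  long long events = 0;
  long long rebuildEvery = 1 << 20;

  // scratch
  std::vector<int> touched;
  std::vector<char> touchedFlag;

  Engine(const List& model, const IntegerVector& counts0,
         const std::string& meth) {
    rxns = parseModel(model, S);
    M = (int)rxns.size();
    method = methodCode(meth);
    n.assign(S, 0);
    for (int i = 0; i < S; ++i) n[i] = counts0[i];
    dep.assign(S, {});
    rowOf.assign(M, 0); colOf.assign(M, 0);
    rowRxns.assign(S + 1, {});
    for (int m = 0; m < M; ++m) {
      const Rxn& r = rxns[m];
      int row = r.pivot < 0 ? 0 : r.pivot + 1;
      rowOf[m] = row;
      colOf[m] = (int)rowRxns[row].size();
      rowRxns[row].push_back(m);
      if (r.other >= 0) dep[r.other].push_back(m);
      else if (r.pivot >= 0 && r.pivotStoich > 1) dep[r.pivot].push_back(m);
    }
    groupOrder.resize(S + 1); groupPos.resize(S + 1);
    colOrder.assign(S + 1, {}); colPos.assign(S + 1, {});
    for (int r = 0; r <= S; ++r) {
      groupOrder[r] = r; groupPos[r] = r;
      int L = (int)rowRxns[r].size();
      colOrder[r].resize(L); colPos[r].resize(L);
      for (int j = 0; j < L; ++j) { colOrder[r][j] = j; colPos[r][j] = j; }
    }
    touchedFlag.assign(S + 1, 0);
    pival.assign(M, 0.0);
    Lambda.assign(S + 1, 0.0); Sigma.assign(S + 1, 0.0);
    aDirect.assign(M, 0.0);
    rebuild();
    a0max = a0;
  }

  void rebuild() {
    for (int m = 0; m < M; ++m) pival[m] = piValue(rxns[m], n);
    for (int r = 0; r <= S; ++r) {
      double L = 0;
      for (int m : rowRxns[r]) L += pival[m];
      Lambda[r] = L;
      Sigma[r] = (r == 0) ? L : n[r - 1] * L;
    }
    a0 = 0;
    for (int r = 0; r <= S; ++r) a0 += Sigma[r];
    if (method == M_PSSACR) rebuildBins();
  }

  // --- composition-rejection bins ---
  static int binIndex(double sigma) { return (int)std::floor(std::log2(sigma)); }

  void rebuildBins() {
    bins.clear(); binSum.clear();
    binOf.assign(S + 1, INT_MIN); posInBin.assign(S + 1, -1);
    for (int r = 0; r <= S; ++r) if (Sigma[r] > 0) binInsert(r, Sigma[r]);
  }
  void binInsert(int r, double sigma) {
    int j = binIndex(sigma);
    binOf[r] = j;
    posInBin[r] = (int)bins[j].size();
    bins[j].push_back(r);
    binSum[j] += sigma;
  }
  void binRemove(int r, double sigmaOld) {
    int j = binOf[r];
    std::vector<int>& v = bins[j];
    int p = posInBin[r], last = (int)v.size() - 1;
    if (p != last) { v[p] = v[last]; posInBin[v[p]] = p; }
    v.pop_back();
    binSum[j] -= sigmaOld;
    if (v.empty()) { bins.erase(j); binSum.erase(j); }
    binOf[r] = INT_MIN; posInBin[r] = -1;
  }
  void binSigmaChanged(int r, double oldS, double newS) {
    if (oldS > 0 && newS > 0 && binIndex(newS) == binOf[r]) {
      binSum[binOf[r]] += newS - oldS;
      return;
    }
    if (oldS > 0) binRemove(r, oldS);
    if (newS > 0) binInsert(r, newS);
  }

  // --- incremental update ---
  void touchRow(int r) {
    if (!touchedFlag[r]) { touchedFlag[r] = 1; touched.push_back(r); }
  }

  void applyDelta(const std::vector<std::pair<int, int>>& d, double tnow,
                  int rxnId, bool completion) {
    for (auto& p : d) {
      n[p.first] += p.second;
      if (n[p.first] < 0) {
        if (completion)
          stop("delayed completion of reaction %d at t = %g would make a species count negative (model semantics error)",
               rxnId + 1, tnow);
        stop("internal error: reaction %d fired into a negative count", rxnId + 1);
      }
    }
    if (method == M_DM) return;
    touched.clear();
    for (auto& p : d) {
      int k = p.first;
      for (int m : dep[k]) {
        double np = piValue(rxns[m], n);
        int r = rowOf[m];
        Lambda[r] += np - pival[m];
        pival[m] = np;
        touchRow(r);
      }
      touchRow(k + 1);
    }
    for (int r : touched) {
      touchedFlag[r] = 0;
      double ns = (r == 0) ? Lambda[0] : n[r - 1] * Lambda[r];
      a0 += ns - Sigma[r];
      if (method == M_PSSACR) binSigmaChanged(r, Sigma[r], ns);
      Sigma[r] = ns;
    }
    if (a0 > a0max) a0max = a0;
  }

  void maybeRebuild() {
    if ((events % rebuildEvery) == 0 || (a0 < 1e-12 * a0max && a0 != 0))
      rebuild();
  }

  double directA0() {
    double s = 0;
    for (int m = 0; m < M; ++m) { aDirect[m] = propValue(rxns[m], n); s += aDirect[m]; }
    return s;
  }

  double currentA0() { return method == M_DM ? directA0() : a0; }

  // --- channel selection (one uniform, remainder reuse; PSSA-CR uses
  //     extra uniforms in its rejection loop) ---
  int select(RNG& rng) {
    if (method == M_DM) {
      double s = 0;
      for (int m = 0; m < M; ++m) s += aDirect[m];
      double target = rng.unif() * s, cum = 0;
      int lastPos = -1;
      for (int m = 0; m < M; ++m) {
        if (aDirect[m] > 0) lastPos = m;
        cum += aDirect[m];
        if (cum > target && aDirect[m] > 0) return m;
      }
      return lastPos;
    }
    if (method == M_PSSACR) return selectCR(rng);
    // PDM / SPDM / dPDM: linear scan over groups in scan order
    double target = rng.unif() * a0, cum = 0;
    int row = -1, lastPos = -1, pos = -1;
    for (int p = 0; p <= S; ++p) {
      int r = groupOrder[p];
      if (Sigma[r] > 0) { lastPos = p; }
      cum += Sigma[r];
      if (cum > target && Sigma[r] > 0) { row = r; pos = p; break; }
    }
    if (row < 0) { pos = lastPos; row = groupOrder[pos]; cum = a0; }
    double rem = target - (cum - Sigma[row]);          // in [0, Sigma[row])
    if (rem < 0) rem = 0;
    double colTarget = (row == 0) ? rem : rem / n[row - 1];  // on Lambda scale
    int col = scanRow(row, colTarget);
    if (method == M_SPDM) promote(row, pos, col);
    return rowRxns[row][col];
  }

  int scanRow(int row, double target) {
    const std::vector<int>& ord = colOrder[row];
    double cum = 0; int last = -1;
    for (size_t p = 0; p < ord.size(); ++p) {
      int cIdx = ord[p];
      double v = pival[rowRxns[row][cIdx]];
      if (v > 0) last = cIdx;
      cum += v;
      if (cum > target && v > 0) return cIdx;
    }
    return last;
  }

  void promote(int row, int groupScanPos, int col) {
    if (groupScanPos > 0) {
      int other = groupOrder[groupScanPos - 1];
      groupOrder[groupScanPos - 1] = row; groupOrder[groupScanPos] = other;
      groupPos[row] = groupScanPos - 1; groupPos[other] = groupScanPos;
    }
    std::vector<int>& ord = colOrder[row];
    std::vector<int>& pos = colPos[row];
    int p = pos[col];
    if (p > 0) {
      int other = ord[p - 1];
      ord[p - 1] = col; ord[p] = other;
      pos[col] = p - 1; pos[other] = p;
    }
  }

  int selectCR(RNG& rng) {
    double tot = 0;
    for (auto& b : binSum) tot += b.second;
    double target = rng.unif() * tot, cum = 0;
    int j = 0; bool found = false;
    for (auto& b : binSum) {
      cum += b.second;
      if (cum > target) { j = b.first; found = true; break; }
    }
    if (!found) j = binSum.rbegin()->first;
    const std::vector<int>& members = bins[j];
    double cap = std::ldexp(1.0, j + 1);
    int row = -1;
    for (;;) {
      int idx = (int)(rng.unif() * members.size());
      if (idx >= (int)members.size()) idx = (int)members.size() - 1;
      int r = members[idx];
      if (rng.unif() * cap < Sigma[r]) { row = r; break; }
    }
    double colTarget = rng.unif() * Lambda[row];
    int col = scanRow(row, colTarget);
    return rowRxns[row][col];
  }
};

// ----------------------------------------------------- well-mixed run ----

struct Pending {
  double t; long long seq; int rxn; bool full;  // full delta vs products only
  bool operator>(const Pending& o) const {
    return t > o.t || (t == o.t && seq > o.seq);
  }
};

// Runs one trajectory; if rec is non-null, fills rows 0..K with the state
// at grid times k*dt (state after all events with time <= k*dt).
static long long runOne(Engine& E, double tEnd, double dt, RNG& rng,
                        IntegerMatrix* rec) {
  bool dpdm = (E.method == M_DPDM);
  std::priority_queue<Pending, std::vector<Pending>, std::greater<Pending>> queue;
  long long seq = 0, events0 = E.events;
  long K = rec ? (long)std::floor(tEnd / dt + 1e-9) : -1;
  long kNext = 0;
  double t = 0;
  auto recordBefore = [&](double tlim) {
    if (!rec) return;
    while (kNext <= K && kNext * dt < tlim) {
      for (int s = 0; s < E.S; ++s) (*rec)(kNext, s) = (int)E.n[s];
      ++kNext;
    }
  };
  for (;;) {
    double a0 = E.currentA0();
    double tRxn = (a0 > 0) ? t + rng.expdraw(a0) : INF;
    bool completion = false;
    double tNext = tRxn;
    if (dpdm && !queue.empty() && queue.top().t <= tRxn) {
      tNext = queue.top().t;
      completion = true;
    }
    if (tNext > tEnd) { recordBefore(tEnd + dt * 0.5 + 1e-300); break; }
    recordBefore(tNext);
    if (completion) {
      Pending pd = queue.top(); queue.pop();
      const Rxn& r = E.rxns[pd.rxn];
      E.applyDelta(pd.full ? r.delta : r.produceDelta, tNext, pd.rxn, true);
    } else {
      int m = E.select(rng);
      const Rxn& r = E.rxns[m];
      if (dpdm && r.hasDelay) {
        if (r.consuming) {
          E.applyDelta(r.consumeDelta, tNext, m, false);
          queue.push({tNext + r.delay, seq++, m, false});
        } else {
          queue.push({tNext + r.delay, seq++, m, true});
        }
      } else {
        E.applyDelta(r.delta, tNext, m, false);
      }
    }
    t = tNext;
    ++E.events;
    E.maybeRebuild();
  }
  return E.events - events0;
}

// [[Rcpp::export]]
List cpp_simulate(List model, IntegerVector counts0, std::string method,
                  double tEnd, double dt, double seed, double trajIndex) {
  Engine E(model, counts0, method);
  RNG rng((uint64_t)seed, (uint64_t)trajIndex);
  long K = (long)std::floor(tEnd / dt + 1e-9);
  IntegerMatrix rec(K + 1, E.S);
  long long ev = runOne(E, tEnd, dt, rng, &rec);
  NumericVector times(K + 1);
  for (long k = 0; k <= K; ++k) times[k] = k * dt;
  return List::create(_["times"] = times, _["counts"] = rec,
                      _["events"] = (double)ev);
}

// [[Rcpp::export]]
List cpp_final_states(List model, IntegerVector counts0, std::string method,
                      double tEnd, int nSamples, double seed,
                      double streamOffset) {
  int S = 0;
  { std::vector<Rxn> tmp = parseModel(model, S); }
  IntegerMatrix out(nSamples, S);
  double totalEvents = 0;
  for (int i = 0; i < nSamples; ++i) {
    Engine E(model, counts0, method);
    RNG rng((uint64_t)seed, (uint64_t)(streamOffset + i));
    totalEvents += (double)runOne(E, tEnd, 0.0, rng, nullptr);
    for (int s = 0; s < S; ++s) out(i, s) = (int)E.n[s];
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["states"] = out, _["events"] = totalEvents);
}

// Draw (wait, channel) pairs from a frozen state without applying updates
// (SPDM still reorders its scan lists between draws).
// [[Rcpp::export]]
List cpp_sample_events(List model, IntegerVector counts, std::string method,
                       int nDraws, double seed) {
  Engine E(model, counts, method);
  RNG rng((uint64_t)seed, 0);
  IntegerVector channel(nDraws);
  NumericVector wait(nDraws);
  for (int i = 0; i < nDraws; ++i) {
    double a0 = E.currentA0();
    if (a0 <= 0) stop("system exhausted: total propensity is zero");
    wait[i] = rng.expdraw(a0);
    channel[i] = E.select(rng) + 1;
  }
  return List::create(_["channel"] = channel, _["wait"] = wait,
                      _["a0"] = E.currentA0());
}

// Total propensity bookkeeping check: returns the structure's a0 and the
// directly recomputed sum after `steps` events.
// [[Rcpp::export]]
List cpp_a0_drift(List model, IntegerVector counts0, std::string method,
                  double tEnd, double seed) {
  Engine E(model, counts0, method);
  E.rebuildEvery = (long long)1 << 62;  // disable periodic rebuild for the check
  RNG rng((uint64_t)seed, 0);
  runOne(E, tEnd, 0.0, rng, nullptr);
  double direct = 0;
  for (int m = 0; m < E.M; ++m) direct += propValue(E.rxns[m], E.n);
  return List::create(_["a0"] = E.currentA0(), _["direct"] = direct,
                      _["events"] = (double)E.events);
}

// ------------------------------------------------------- spatial NSM ----

struct IndexedHeap {
  std::vector<int> heap, pos;
  std::vector<double> key;
  void init(int n) {
    heap.resize(n); pos.resize(n); key.assign(n, INF);
    for (int i = 0; i < n; ++i) { heap[i] = i; pos[i] = i; }
  }
  void swapAt(int a, int b) {
    std::swap(heap[a], heap[b]);
    pos[heap[a]] = a; pos[heap[b]] = b;
  }
  void up(int i) {
    while (i > 0) {
      int p = (i - 1) / 2;
      if (key[heap[i]] < key[heap[p]]) { swapAt(i, p); i = p; } else break;
    }
  }
  void down(int i) {
    int n = (int)heap.size();
    for (;;) {
      int l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && key[heap[l]] < key[heap[m]]) m = l;
      if (r < n && key[heap[r]] < key[heap[m]]) m = r;
      if (m == i) break;
      swapAt(i, m); i = m;
    }
  }
  void update(int v, double k) { key[v] = k; up(pos[v]); down(pos[v]); }
  int top() const { return heap[0]; }
};

// [[Rcpp::export]]
List cpp_simulate_spatial(List model, IntegerMatrix counts0,
                          NumericVector jumpRates, List neighbors,
                          std::string method, double tEnd, double dt,
                          double seed, double trajIndex) {
  int nsub = counts0.nrow();
  if (method != "pdm" && method != "dm")
    stop("spatial engine supports per-subvolume methods 'pdm' and 'dm'");
  std::vector<Engine*> eng(nsub);
  std::vector<std::vector<int>> nb(nsub);
  for (int v = 0; v < nsub; ++v) {
    IntegerVector cv = counts0(v, _);
    eng[v] = new Engine(model, cv, method);
    IntegerVector nv = neighbors[v];
    for (int i = 0; i < nv.size(); ++i) nb[v].push_back(nv[i] - 1);
  }
  int S = eng[0]->S;
  RNG rng((uint64_t)seed, (uint64_t)trajIndex);
  long K = (long)std::floor(tEnd / dt + 1e-9);
  IntegerVector rec(Dimension(K + 1, nsub, S));
  long kNext = 0;
  auto diffTotal = [&](int v) {
    double s = 0;
    for (int sp = 0; sp < S; ++sp) s += eng[v]->n[sp] * jumpRates[sp];
    return s * nb[v].size();
  };
  IndexedHeap heap; heap.init(nsub);
  double t = 0;
  auto redraw = [&](int v, double tnow) {
    double tot = eng[v]->currentA0() + diffTotal(v);
    heap.update(v, tot > 0 ? tnow + rng.expdraw(tot) : INF);
  };
  for (int v = 0; v < nsub; ++v) redraw(v, 0.0);
  auto recordBefore = [&](double tlim) {
    while (kNext <= K && kNext * dt < tlim) {
      for (int v = 0; v < nsub; ++v)
        for (int sp = 0; sp < S; ++sp)
          rec[kNext + (long)(K + 1) * (v + (long)nsub * sp)] = (int)eng[v]->n[sp];
      ++kNext;
    }
  };
  double events = 0;
  for (;;) {
    int v = heap.top();
    double tNext = heap.key[v];
    if (tNext > tEnd) { recordBefore(tEnd + dt * 0.5 + 1e-300); break; }
    recordBefore(tNext);
    double aR = eng[v]->currentA0();
    double aD = diffTotal(v);
    double u = rng.unif() * (aR + aD);
    if (u < aR) {
      int m = eng[v]->select(rng);
      eng[v]->applyDelta(eng[v]->rxns[m].delta, tNext, m, false);
      ++eng[v]->events; eng[v]->maybeRebuild();
      redraw(v, tNext);
    } else {
      // diffusion: species proportional to n_s * d_s, neighbor uniform
      double target = (u - aR) / nb[v].size(), cum = 0;
      int sp = -1, last = -1;
      for (int s2 = 0; s2 < S; ++s2) {
        double w = eng[v]->n[s2] * jumpRates[s2];
        if (w > 0) last = s2;
        cum += w;
        if (cum > target && w > 0) { sp = s2; break; }
      }
      if (sp < 0) sp = last;
      int w = nb[v][(int)(rng.unif() * nb[v].size()) % nb[v].size()];
      std::vector<std::pair<int, int>> dOut{{sp, -1}}, dIn{{sp, 1}};
      eng[v]->applyDelta(dOut, tNext, -1, false);
      eng[w]->applyDelta(dIn, tNext, -1, false);
      redraw(v, tNext);
      redraw(w, tNext);
    }
    t = tNext;
    events += 1;
    if (((long long)events & 16383) == 0) Rcpp::checkUserInterrupt();
  }
  for (int v = 0; v < nsub; ++v) delete eng[v];
  NumericVector times(K + 1);
  for (long k = 0; k <= K; ++k) times[k] = k * dt;
  return List::create(_["times"] = times, _["counts"] = rec,
                      _["events"] = events);
}
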