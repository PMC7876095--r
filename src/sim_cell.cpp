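// Event-driven single-cell replication engine.
//
// All randomness is pre-drawn in R and passed in: `fire` holds firing times
// for competent origins only, and `U(origin, barrier)` one arrest uniform per
// origin lineage per barrier, so the engine itself is deterministic and
// consumes no RNG state. Positions are bp, times minutes, velocities bp/min.
//
// Semantics: competent origins fire unless passively replicated first,
// spawning two diverging canonical forks. A fork reaching a barrier it is
// susceptible to (matching blocked direction and fork type) arrests with the
// barrier's probability; pause barriers release it unchanged after the delay,
// restart barriers release it as an HR-restarted fork at position + offset
// (re-replicating the offset window). A converging fork reaching an arrested
// fork's position cancels it (rescue). Converging moving forks terminate
// where their trajectories meet; forks stop at the domain edges. Every bin
// takes (time, direction, fork type) from the fork that last crossed its
// midpoint; at an exact midpoint tie the rightward fork wins (the left-mover
// segment is assigned first and then overwritten).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double TOL = 1e-7;

namespace {

struct Fork {
    double pos, t;            // position and time of last kinematic update
    double lastAssign, lastAssignT; // bin-assignment frontier
    double vel;
    int dir;                  // +1 rightward, -1 leftward
    int type;                 // 0 canonical, 1 restarted
    int status;               // 0 moving, 1 arrested, 2 done
    double resumeT;
    int arrestBarrier;
    int origin;               // row into U
    std::vector<char> decided;
};

struct Engine {
    double gridStart, binSize, gridEnd;
    int nBins;
    NumericVector repTime;
    IntegerVector outDir, outType;

    void assignTo(Fork &f, double newPos, double tNew) {
        double a = f.lastAssign, b = newPos;
        double lo = std::min(a, b), hi = std::max(a, b);
        int kmin = (int)std::ceil((lo - gridStart) / binSize - 0.5 - 1e-9);
        int kmax = (int)std::floor((hi - gridStart) / binSize - 0.5 + 1e-9);
        if (kmin < 0) kmin = 0;
        if (kmax > nBins - 1) kmax = nBins - 1;
        for (int k = kmin; k <= kmax; ++k) {
            double m = gridStart + (k + 0.5) * binSize;
            if (m < lo - TOL || m > hi + TOL) continue;
            repTime[k] = f.lastAssignT + std::fabs(m - a) / f.vel;
            outDir[k] = f.dir;
            outType[k] = f.type;
        }
        f.lastAssign = newPos;
        f.lastAssignT = tNew;
    }
};

} // namespace

// [[Rcpp::export(name = ".simCellEvent")]]
List simCellEvent(double gridStart, double binSize, int nBins, double v,
                  NumericVector origPos, NumericVector origFire,
                  IntegerVector origRow,
                  NumericVector barPos, IntegerVector barDir,
                  IntegerVector barKind, NumericVector barProb,
                  NumericVector barDelay, NumericVector barOffset,
                  IntegerVector barApplies, NumericVector barVel,
                  NumericMatrix U) {
    Engine eng;
    eng.gridStart = gridStart;
    eng.binSize = binSize;
    eng.nBins = nBins;
    eng.gridEnd = gridStart + (double)nBins * binSize;
    eng.repTime = NumericVector(nBins, NA_REAL);
    eng.outDir = IntegerVector(nBins, NA_INTEGER);
    eng.outType = IntegerVector(nBins, NA_INTEGER);

    int nO = origPos.size(), nB = barPos.size();
    std::vector<char> fired(nO, 0), cancelled(nO, 0);
    std::vector<Fork> forks;
    forks.reserve(2 * nO + 4);

    auto susceptible = [&](const Fork &f, int j) {
        if (f.decided[j]) return false;
        if (barDir[j] != f.dir) return false;
        int ap = barApplies[j]; // 0 canonical-only, 1 restarted-only, 2 both
        if (ap == 0 && f.type != 0) return false;
        if (ap == 1 && f.type != 1) return false;
        return true;
    };

    long iter = 0, maxIter = 1000000;
    while (true) {
        if (++iter > maxIter)
            stop("simulation error: event loop failed to terminate");
        // find next event: (time, priority, idx1, idx2)
        double bt = R_PosInf;
        int bpri = 99, bi = -1, bj = -1;
        auto consider = [&](double t, int pri, int i, int j) {
            if (t < bt - TOL || (t < bt + TOL && pri < bpri)) {
                bt = t; bpri = pri; bi = i; bj = j;
            }
        };
        bool anyPending = false;
        for (int k = 0; k < nO; ++k) {
            if (fired[k] || cancelled[k]) continue;
            anyPending = true;
            consider(origFire[k], 0, k, -1);
        }
        bool anyActive = false;
        int nF = (int)forks.size();
        for (int i = 0; i < nF; ++i) {
            Fork &f = forks[i];
            if (f.status == 2) continue;
            anyActive = true;
            if (f.status == 1) {
                consider(f.resumeT, 1, i, -1);
                continue;
            }
            // nearest susceptible barrier strictly ahead
            double bestArr = R_PosInf;
            int bestBar = -1;
            for (int j = 0; j < nB; ++j) {
                if (!susceptible(f, j)) continue;
                double d = (barPos[j] - f.pos) * f.dir;
                if (d <= TOL) continue;
                double ta = f.t + d / f.vel;
                if (ta < bestArr) { bestArr = ta; bestBar = j; }
            }
            if (bestBar >= 0) consider(bestArr, 2, i, bestBar);
            // passive replication of pending origins
            for (int k = 0; k < nO; ++k) {
                if (fired[k] || cancelled[k]) continue;
                double d = (origPos[k] - f.pos) * f.dir;
                if (d <= TOL) continue;
                consider(f.t + d / f.vel, 3, i, k);
            }
            // meetings
            for (int j2 = 0; j2 < nF; ++j2) {
                if (j2 == i) continue;
                Fork &g = forks[j2];
                if (g.status == 2) continue;
                if (g.status == 1) {
                    double d = (g.pos - f.pos) * f.dir;
                    if (d > TOL)
                        consider(f.t + d / f.vel, 4, i, j2);
                } else if (j2 > i && f.dir != g.dir) {
                    const Fork &r = (f.dir > 0) ? f : g; // right-mover
                    const Fork &l = (f.dir > 0) ? g : f;
                    if (l.pos - r.pos > TOL) {
                        double tm = (l.pos + l.vel * l.t - r.pos +
                                     r.vel * r.t) / (r.vel + l.vel);
                        consider(tm, 4, i, j2);
                    }
                }
            }
            // domain edge
            double target = (f.dir > 0) ? eng.gridEnd : eng.gridStart;
            consider(f.t + (target - f.pos) * f.dir / f.vel, 5, i, -1);
        }
        if (!anyPending && !anyActive) break;
        if (!R_FINITE(bt))
            stop("simulation error: no schedulable event with work remaining");

        switch (bpri) {
        case 0: { // origin fires
            fired[bi] = 1;
            for (int dir = -1; dir <= 1; dir += 2) {
                Fork f;
                f.pos = origPos[bi]; f.t = origFire[bi];
                f.lastAssign = f.pos; f.lastAssignT = f.t;
                f.vel = v; f.dir = dir; f.type = 0; f.status = 0;
                f.resumeT = 0; f.arrestBarrier = -1;
                f.origin = origRow[bi];
                f.decided.assign(nB, 0);
                forks.push_back(f);
            }
            break;
        }
        case 1: { // arrested fork resumes
            Fork &f = forks[bi];
            int j = f.arrestBarrier;
            f.t = f.resumeT;
            f.status = 0;
            if (barKind[j] == 1) { // restart
                // the restart point is |offset| bp behind the fork, i.e.
                // within its own already-replicated wake
                double newPos = f.pos + f.dir * barOffset[j];
                if (newPos < eng.gridStart) newPos = eng.gridStart;
                if (newPos > eng.gridEnd) newPos = eng.gridEnd;
                f.pos = newPos;
                f.lastAssign = newPos;
                f.lastAssignT = f.resumeT;
                f.type = 1;
                if (R_FINITE(barVel[j])) f.vel = barVel[j];
            } else {
                f.lastAssignT = f.resumeT;
            }
            f.arrestBarrier = -1;
            break;
        }
        case 2: { // barrier encounter
            Fork &f = forks[bi];
            f.decided[bj] = 1;
            // a pending origin exactly at the barrier has been replicated
            for (int k = 0; k < nO; ++k)
                if (!fired[k] && !cancelled[k] &&
                    std::fabs(origPos[k] - barPos[bj]) <= TOL)
                    cancelled[k] = 1;
            double u = U(f.origin, bj);
            // a zero-delay pause is a no-op; skipping it keeps the
            // trajectory (and its floating-point arithmetic) untouched
            bool nullPause = (barKind[bj] == 0 && barDelay[bj] <= 0.0);
            if (u < barProb[bj] && !nullPause) {
                eng.assignTo(f, barPos[bj], bt);
                f.pos = barPos[bj]; f.t = bt;
                f.status = 1;
                f.resumeT = bt + barDelay[bj];
                f.arrestBarrier = bj;
            }
            // a passed barrier leaves the trajectory (and hence the
            // floating-point arithmetic of later assignments) untouched
            break;
        }
        case 3: { // fork passes a pending origin: passive replication
            cancelled[bj] = 1;
            break;
        }
        case 4: { // meeting / rescue
            Fork &f = forks[bi];
            Fork &g = forks[bj];
            if (g.status == 1) { // rescue: converging fork reaches arrest
                eng.assignTo(f, g.pos, bt);
                f.pos = g.pos; f.t = bt;
                f.status = 2;
                g.status = 2; // cancelled before its restart time
            } else {
                Fork &r = (f.dir > 0) ? f : g;
                Fork &l = (f.dir > 0) ? g : f;
                double x = r.pos + r.vel * (bt - r.t);
                // left-mover first so the right-mover wins a midpoint tie
                eng.assignTo(l, x, bt);
                eng.assignTo(r, x, bt);
                l.pos = x; l.t = bt; l.status = 2;
                r.pos = x; r.t = bt; r.status = 2;
            }
            break;
        }
        case 5: { // domain edge
            Fork &f = forks[bi];
            double target = (f.dir > 0) ? eng.gridEnd : eng.gridStart;
            eng.assignTo(f, target, bt);
            f.pos = target; f.t = bt;
            f.status = 2;
            break;
        }
        }
    }

    for (int k = 0; k < eng.nBins; ++k)
        if (!R_FINITE(eng.repTime[k]))
            stop("simulation error: unreplicated gap at bin %d", k + 1);

    return List::create(_["time"] = eng.repTime, _["dir"] = eng.outDir,
                        _["type"] = eng.outType);
}
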