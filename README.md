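# chainABM

Agent-based simulation of **follow-the-leader cell chain migration** on a
lattice, built around the embryonic neural crest: a few protrusion-rich
*Leader* cells ahead of polarized *Follower* cells, travelling single file
towards a distal target. The package is for computational and developmental
biologists who want to test, quantitatively, which cell behaviours keep
such chains together: a path of least resistance in the extracellular
matrix (ECM), filopodial contact guidance, or both.

## The models and the statistic

Simulations run on a 150 × 45 grid of tri-state sites (*Closed* → matrix
never entered, *Open* → an agent's wake, *Occupied*), with 3 Leaders + 5
Followers starting as a single-file chain. Three rule systems are provided:

* **ECM model** — each update an agent draws a direction *d* from its
  directionality distribution (LDD for Leaders, FDD for Followers; 8
  compass values + *none*). A Closed destination is entered only when
  *false* is drawn from POS ("Prefer an Open Site"); after moving into an
  Open site with another Open site straight ahead, a *true* draw from ATS
  ("Advance Two Sites") grants a second step. Optionally a pre-existing
  *track* of Open sites runs from the chain to the target.
* **Contact model** — agents carry filopodia (rays ≤ 3 sites ≈ 100 µm;
  up to 8 for Leaders, a front-directed ray for Followers). An agent in
  filopodial contact moves towards the contact when *true* is drawn from
  LMC/FMC; otherwise Leaders draw from LDD and Followers step along their
  polarized direction, which is re-drawn from FDD by a stochastic clock
  (maximum interval MDI; protrusion toggling likewise with MPI). Seven
  Boolean parameters (LMC, FMC, PPC, FRP, LRP, FMP, LMP) govern the
  contact behaviours; SID/SIP synchronize initial polarity and clocks.
* **Hybrid model** — Contact-model decisions executed through the ECM
  movement gate.

The outcome of a run is its **chain persistence**: the number of time
steps on which at least six *sequential* agents (|Δy| ≤ 1 and |Δx| ≤ 4
between consecutive members, ordered front to back) kept a collective
velocity of ≥ 1 site per 10 steps towards the target. Parameter sets are
summarized by mean persistence ± s.e.m. over replicate batches (400 by
convention), compared with Tukey–Kramer tests against a baseline, and
explored by exhaustive (ECM: 6400 sets) or random (Contact: sampled from a
~10⁹-set space) parameter sweeps.

## Worked example

```r
library(chainABM)

# default ECM baseline with a pre-existing track
run_replicates(ecm_params(), n = 400, seed = 1)
#> <replicate_summary> ecm, n = 400: mean persistence 5.72 +- 0.12 s.e.m. (min 1, max 19)

# does willingness to forge matter without a track? compare POS-true levels
# at full directional bias
g <- list(
  pos_0   = run_replicates(ecm_params(ldd = 1, fdd = 1, pos = 0,   ats = 0,
                                      track = FALSE), 400, seed = 100)$runs$persistence,
  pos_57  = run_replicates(ecm_params(ldd = 1, fdd = 1, pos = 4/7, ats = 0,
                                      track = FALSE), 400, seed = 101)$runs$persistence,
  pos_100 = run_replicates(ecm_params(ldd = 1, fdd = 1, pos = 1,   ats = 0,
                                      track = FALSE), 400, seed = 102)$runs$persistence
)
sapply(g, mean)
#>   pos_0  pos_57 pos_100
#> 16.3075 44.4275  9.0000
tukey_kramer(g, baseline = "pos_57")
#>     group   n mean  diff   se    q p_value significant
#> 1   pos_0 400 16.3 -28.1 1.21 23.2       0        TRUE
#> 2 pos_100 400  9.0 -35.4 1.21 29.3       0        TRUE
```

Read: with no pre-forged path, chains persist longest (mean ≈ 44 steps)
when agents forge *selectively* (POS-true ≈ 57%). Always forging (POS-true
= 0) lets the front run free and the chain falls apart in ~16 steps; never
forging (POS-true = 100%) traps the chain on its own footprint, the
velocity criterion fails at the first checkpoint, and persistence is
pinned at 9. Both differences are Tukey–Kramer significant.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/chain-abm run --model ecm --track --reps 400 --seed 1 --out results/
Rscript inst/cli/chain-abm sweep --model contact --n-sets 10000 --reps 100 --seed 1 --out sweep/
```

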