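---
title: "Modelling follow-the-leader cell chain migration with chainABM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling follow-the-leader cell chain migration with chainABM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainABM)
```

## The question the models ask

Migratory embryonic cells -- neural crest cells are the canonical example --
are often seen travelling in *chains*: loosely connected single-file arrays
with a few "hairy", protrusion-rich leader cells at the front and polarized
follower cells behind. Two mechanisms are commonly proposed to explain why
such chains hold together: trailing cells may follow a *path of least
resistance* in the extracellular matrix (ECM) forged by the cells ahead, or
they may be steered by *filopodial contact* with their neighbours. chainABM
implements both hypotheses (and their combination) as rule systems on a
shared lattice world, and measures how long a pre-assembled chain persists
under each rule system as model parameters vary. The point of the exercise
is sensitivity analysis of a *pattern-maintenance* statistic, not the
emergence of chains from scratch: every simulation starts from an intact
chain and asks what keeps it intact.

## The world

Space is a 150 x 45 rectangular lattice with non-cyclic boundaries. One
site is 30 µm across, roughly one cell length, and a time step is best
thought of as on the order of hours; both scales are nominal, since the
statistic of interest is a step count, not a physical time. The x axis runs
*proximal to distal*; the migratory target is the entire distal edge
(x = 149). Every site is in one of three states:

* **Closed** -- never yet occupied (un-forged matrix),
* **Open** -- previously occupied and since vacated (an agent's wake),
* **Occupied** -- currently holding an agent.

Sites move through these states in one direction only: Closed sites can
become Occupied, Occupied sites become Open when the agent leaves, Open
sites can be re-occupied, and nothing ever returns to Closed. Agents
(3 Leaders and 5 Followers by default) start in a single file at
mid-height, `x = 1..8`, Leaders distal-most. With a pre-existing *track*
(the "path already forged" condition) all sites in the chain's row between
the front agent and the distal edge start Open; without it the world starts
fully Closed.

## What counts as a chain

Persistence needs a formal chain criterion, and this package uses two
conditions, evaluated every step:

1. **Structure.** Two agents are *sequential* when they are at most one row
   apart (|dy| <= 1) and have at most three empty sites between them along
   x (|dx| <= 4). The configuration contains a chain when at least six
   agents can be ordered front-to-back -- x non-increasing -- with every
   consecutive pair sequential. `detect_chain()` computes the longest such
   sequence exactly (a sorted-order dynamic program, with an exhaustive
   fall-back for the rare tie configurations the fast pass cannot settle).
2. **Velocity.** The chain members' mean x position must advance at least
   one site per ten steps, checked at t = 10, 20, ...; the verdict from the
   last checkpoint carries between checkpoints.

A step on which both conditions hold adds one to the *chain persistence*.
The run ends at the first step on which either condition fails, when any
agent reaches the distal edge, or at `max_steps` (default 1000, several
times the ~150 steps a fast chain needs to cross the grid).

Two design choices here deserve justification, because the criterion is
what turns simulations into numbers:

* *Front-to-back ordering rather than mere connectivity.* Treating any
  connected blob of six agents under the sequential relation as a chain
  systematically over-counts: loose clusters that have visibly stopped
  being single-file arrays still pass. The ordered reading keeps the
  statistic aligned with what "six sequential agents" means for an array
  of cells, and it is what makes the default baselines of the three models
  separate the way they should.
* *A failed velocity checkpoint is terminal.* If the chain may idle
  indefinitely and resume, compact-but-stalled configurations (for
  example, a chain pressed against un-forged matrix that it refuses to
  enter) accumulate effectively unbounded persistence, and the parameter
  sweeps are then dominated by slow crawlers rather than by migrating
  chains. Ending the run when the chain stops travelling keeps
  "persistence" the length of time the agents *travelled* as a chain.

A `cumulative = TRUE` switch is available to count qualifying steps without
any terminal condition, for users who want the alternative accounting.

## Scheduling and stochasticity

Agents update *asynchronously with replacement*: each time step consists of
N uniform random agent selections (N = number of agents), so an agent is
updated once per step on average but may act twice or not at all. This
matters more than it may appear. Under a once-each shuffled schedule, a
fully distally-biased chain on an open track advances deterministically --
inter-agent gaps can never exceed one site, the chain never breaks, and
persistence is simply the grid-crossing time. The update-count noise of
selection with replacement is precisely what lets gaps fluctuate and chains
disassemble, and it reproduces an otherwise puzzling observation: chains
*without* a track persist longer at their best than chains with one,
because the slowly forging front agent compresses the queue behind it and
damps those fluctuations, whereas on an open track every agent runs at full
speed and gaps diffuse freely.

All randomness in the compiled engine flows from one 64-bit splitmix64
stream per replicate, derived deterministically from (master seed,
replicate index); a batch is therefore exactly reproducible from its master
seed, and any single replicate can be re-run in isolation. Degenerate
Bernoulli draws (p = 0 or 1) consume no randomness, which gives a useful
exact identity: the Hybrid model with POS-true = ATS-true = 0 runs the same
stream as the pure Contact model and reproduces it step for step -- the
test suite asserts this.

## The ECM model (4 parameters)

When selected, an agent draws a direction from **LDD** (Leaders) or
**FDD** (Followers) -- eight compass directions plus *none* (stay put). The
destination site's state gates the move:

* Occupied or off-grid: the move is cancelled (no pushing, no swapping).
* Closed: the agent forges in only when *false* is drawn from **POS**
  ("Prefer an Open Site"); a *true* draw vetoes the move.
* Open: the agent moves; if the next site straight ahead is also Open, a
  *true* draw from **ATS** ("Advance Two Sites") grants an immediate second
  step -- faster movement down an open channel.

Directional parameters are swept through a one-parameter family: bias p on
*distal*, the remaining 1 - p spread equally over the seven other
directions and *none*, so p = 1/9 is the fully uniform distribution.

## The Contact model (13 parameters)

Agents carry filopodia, modelled as straight rays of up to 3 sites
(~100 µm, the observed maximum). Leaders are *hairy*: extension gives them
full-length rays in all eight directions. Followers are *polarized*: a
single front-directed ray along the polarized direction (the couple of
protrusions seen on trailing cells point where the cell is going; two per
Follower is the cap the engine enforces). Two stochastic clocks
per agent drive re-randomization: when a Follower's direction clock
reaches zero it redraws its polarized direction from FDD, and when any
agent's protrusion clock reaches zero its protrusion state toggles;
expired clocks reset uniformly on {0, ..., **MDI**} or {0, ..., **MPI**}
(both capped at 50). **SID**/**SIP** start the simulation with,
respectively, all Followers polarized distally and their direction clocks
in phase, and everyone's protrusion clocks in phase; synchronized clocks
start at the full maximum interval, so the first synchronized
re-decision happens as late as possible -- this is what lets SID
compensate for weak distal bias in FDD. All agents start with extended
protrusions.

The update rule: an agent first checks for contact (its rays touching
another agent's body, or another's rays touching it). If in contact and
*true* is drawn from **LMC**/**FMC**, responding to the contact is the
agent's action for this update: it attempts one step towards the contact
-- the displacement to the contacted agent rounded to the nearest compass
octant, simultaneous contacts tie-broken uniformly -- and the attempt may
simply fail when the destination is occupied (often by the contacted cell
itself). There is no second decision after a blocked contact move; the
ordinary movement attempt (Leaders drawing from LDD, Followers stepping
along their polarized direction) happens only when no contact existed or
the agent did not respond to it. A Follower that actually moves towards a
contact re-polarizes to that direction, and after any contact-induced
attempt the agent's filopodia retract when *true* is drawn from
**LRP**/**FRP**. In the pure Contact model site states never impede
movement -- matrix resistance belongs to the ECM hypothesis.

Two maintenance behaviours keep contacts alive: when one end of a
filopodial link moves, a *true* draw from **FMP**/**LMP** (by the
filopodium owner's role) lets the ray lengthen or shorten to keep covering
the partner, within the 3-site clamp -- beyond it the contact breaks. And
when a protrusion-toggle would retract rays currently mediating a contact,
a *true* draw from **PPC** suppresses the retraction. (PPC's precise definition is the least constrained of the thirteen
parameters; this contact-preserving reading is the most conservative one
consistent with its grouping among the protrusion behaviours.)

## The Hybrid model

Decisions follow the Contact rules; execution passes through the ECM gate
(POS veto on Closed sites, ATS double steps, optional track). A vetoed
agent simply stays put -- there is no second decision. The ATS double step
applies to contact-induced moves too, since all movement is gated.

## Resolved ambiguities and numerical choices

Several behavioural details are genuinely open in the model description;
the package resolves them as follows, and treats these choices
as part of the model definition:

* Agents never exchange positions or push; blocked moves are cancelled.
* Diagonal moves need only the destination site to be free.
* One POS draw per movement decision, evaluated at the moment of the move;
  the ATS second step re-checks the channel after arriving.
* Initial clock values are uniform on {0, ..., max} (shared under
  SID/SIP, independent otherwise); initial Follower polarity under
  SID = FALSE is drawn from FDD and may be *none*, in which case the
  Follower attempts no polarized moves until its clock next fires.
* Protrusion extension is instantaneous and at full length; a re-polarized
  Follower re-orients its rays at full length.
* Contact-move retraction (LRP/FRP) is drawn after any contact-induced
  attempt, and retraction removes all of the agent's rays.
* `velocity_ok` compares means of the *current* chain members at the two
  checkpoint ends; membership may differ between checkpoints.
* Octant rounding of contact directions uses exact angular distance;
  integer displacements produce no ties, but ties would be broken
  uniformly.

## Sweeps, their defaults, and what the statistics do

`enumerate_ecm_grid()` builds the exhaustive ECM design: 10 directional
levels evenly spaced from 1/9 to 1 for LDD and FDD, 8 Boolean levels
evenly spaced from 0 to 1 for POS and ATS -- 6400 parameter sets, each run
at 100 replicates with the top decile re-run at 400 to estimate per-set
means (and the maximum) more tightly. These evenly spaced defaults
bracket all the landmark probability values that matter in the analysis
(11%, ~44%, ~60%, ~84%, 100%) and are config-overridable. The same
reasoning fixes the Contact value lists in `default_contact_grid()`
(directional levels as above; Boolean levels 0-100% in 6 steps; MDI/MPI in
{0, 5, 10, 20, 35, 50}; SID/SIP both values), whose full product is of
order 10^9 -- hence uniform random sampling (100 000 sets in the original
study; `sample_contact_sets()` scales this freely).

`run_replicates()` reports mean persistence ± s.e.m. with min and max;
`tukey_kramer()` performs the studentized-range comparisons against a
baseline set (Tukey-Kramer intervals for unequal n); and
`subgroup_analysis()` splits swept sets at mean persistence >= 20,
contrasts per-parameter means between the high and low groups (Welch
two-sample p-values; Welch is the defensible default for unequal sizes
and variances), tabulates value frequencies in the high group, and computes
Pearson correlations (SID/SIP coded 0/1) among parameters there.

## What the simulations do and do not emulate

The generator reproduces the *study conditions*: a pre-assembled 8-agent
chain, a flat featureless matrix (no density fields, gradients, or
degradation kinetics), at most one chain, and phenotypes fixed for life.
Passing tests therefore say nothing about emergent chain formation from
premigratory populations, contact inhibition of locomotion as a distinct
mechanism, chemotaxis proper (directional bias is its lattice proxy), or
cell division, death, and leader/follower plasticity. Quantitatively, the
reproduced persistence statistics are step counts in an arbitrary
timescale; only their orderings and parameter sensitivities carry
biological meaning.

## Problem sizes used in the checks

The packaged acceptance analysis runs the baselines at the conventional
400 replicates, the full 6400-set ECM sweeps at 100 replicates with a
400-replicate top-decile refinement, and a 10 000-set random Contact sweep
at 100 replicates -- a tenth of the original 100 000 sets, which leaves the
high-persistence sub-group (~0.5% of sets) with enough members for stable
directional summaries while keeping the whole analysis in the minutes
range on one CPU. The test suite uses the same designs at further reduced
replicate counts chosen to keep each stochastic check's sampling error
well inside the asserted tolerances.

## Worked example

```{r example, eval = FALSE}
library(chainABM)

# default ECM baseline with a pre-existing track, 400 replicates
base <- run_replicates(ecm_params(), n = 400, seed = 1)
base

# how does willingness to forge change persistence without a track?
pos_levels <- c(0, 0.5, 1)
groups <- lapply(pos_levels, function(p) {
  run_replicates(ecm_params(pos = p, track = FALSE), n = 400,
                 seed = 100 + round(100 * p))$runs$persistence
})
names(groups) <- paste0("pos_", pos_levels)
tukey_kramer(groups, baseline = "pos_0.5")

# snapshot of a contact-model run
rec <- run_simulation(contact_params(sid = TRUE, mdi = 50), seed = 7,
                      return_state = TRUE)
cat(render_snapshot(rec)[18:28], sep = "\n")
```

## Known limitations

* Where the behavioural rules admit more than one reading, the package
  commits to the readings laid out above and validates them against the
  full set of quantitative anchors (baseline and maximum persistences,
  sweep structure). Residual differences from other defensible readings
  show up mostly at the margins of the high-persistence sub-group.
* The chain criterion is evaluated globally once per step; sub-step
  configurations are invisible to it, so a chain that breaks and re-forms
  within one step is never penalized.
* With more than ~20 agents the exact structural fall-back becomes
  expensive; the engine refuses such configurations rather than silently
  approximating.
* The statistic is a survival-type quantity summarized here by means;
  users wanting full survival curves can recover them from the per-run
  tables.
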