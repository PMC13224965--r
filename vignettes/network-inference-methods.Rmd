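---
title: "Inferring level-1 phylogenetic networks from quartet concordance factors"
author: "qcfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring level-1 phylogenetic networks from quartet concordance factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Hybridization, introgression and horizontal transfer leave patterns in
genomes that no single species tree can represent.  `qcfnet` estimates a
*semi-directed level-1 phylogenetic network*: a species tree augmented with
`h` reticulation cycles, where each hybrid node has two parent edges
carrying inheritance probabilities $\gamma$ and $1-\gamma$, branch lengths
are in coalescent units, and the root position is left unresolved (quartet
frequencies carry no information about it).  *Level-1* means reticulation
cycles share no edges; networks with 2-cycles and 3-cycles are excluded
outright, both in validation and in search proposals, because they are not
topologically identifiable from quartet data.

The data are **quartet concordance factors** (CFs).  For each set of four
taxa $\{a,b,c,d\}$ there are three unrooted quartet topologies
($ab|cd$, $ac|bd$, $ad|bc$); the observed CF triple
$X = (X_{q_1}, X_{q_2}, X_{q_3})$ is the frequency of each topology among
the gene trees that contain and resolve the four taxa.  Under the
multispecies network coalescent (MSNC) a candidate network predicts
expected CFs $(CF_{q_1}, CF_{q_2}, CF_{q_3})$ for every 4-taxon set, and
the fit of a network is measured by the composite (pseudo-)likelihood

$$
L \;=\; \prod_{s \in S} CF_{q_1}^{X_{q_1}}\, CF_{q_2}^{X_{q_2}}\,
        CF_{q_3}^{X_{q_3}},
$$

the product running over the scored collection $S$ of 4-taxon sets.  All
computations use $\log L$; expected CFs are clamped to
$[\varepsilon, 1-2\varepsilon]$ with $\varepsilon = 10^{-12}$ before
logging so that an observed topology with predicted probability
$\approx 0$ yields a very poor but finite score rather than $-\infty$.

## Expected concordance factors

For a quartet species *tree* whose internal path has length $t$ coalescent
units, the classical coalescent result gives
$CF_\text{major} = 1 - \tfrac{2}{3}e^{-t}$ and
$CF_\text{minor} = \tfrac{1}{3}e^{-t}$ for each minor topology.

For a 4-taxon *network* (quarnet) `qcfnet` computes expected CFs exactly
and constructively rather than from transcribed case formulas.  The key
observation is that the unrooted topology of a 4-lineage gene tree is fixed
by the first pair of sampled lineages to coalesce, and that two lineage
pairs co-located in time-incomparable populations always imply the same
topology.  The algorithm therefore:

1. enumerates every *routing profile* — each sampled lineage independently
   chooses a parent edge at every hybrid node it can reach, with
   probability given by the inheritance probabilities ($\le 2^h$ choices
   per lineage);
2. given a profile, sweeps the quarnet's edges in topological order,
   tracking the probability that no coalescence has happened yet: an edge
   of length $\ell$ carrying $s$ co-located lineages yields a
   first-coalescence event with probability
   $1 - e^{-\binom{s}{2}\ell}$, split equally over the $\binom{s}{2}$
   pairs, each pair crediting its quartet topology;
3. sends the residual mass to the root population, where exchangeability
   gives each topology $1/3$.

Lineages that coalesce below a hybrid node (probability $1-e^{-\ell}$ on
the subtending edge) never route, which the sweep handles automatically
because decided mass leaves the computation at the coalescence.  When only
one sampled lineage can reach each hybrid node the procedure reduces to the
displayed-tree mixture $\sum_T P(T)\, CF_T$.  Correctness is anchored to an
independent Monte-Carlo oracle — an MSNC gene-tree simulator sharing no
code with the analytic path — with agreement required within 3 binomial
standard errors at $10^5$ simulated genes per quarnet.

Quarnets are obtained from the full network by pruning the other taxa and
suppressing degree-2 nodes (lengths add).  Reticulation cycles that do not
separate the four taxa degenerate and drop out; a cycle degenerating to two
parallel hybrid edges is kept as such, since the sweep handles parallel
edges exactly.  Pendant-edge lengths never affect CFs and are treated as
unidentifiable.

## Search

`qcfnet()` maximizes $\log L$ by strict hill-climbing over topologies.
Five moves are used: nearest-neighbour interchange (NNI), addition of a
reticulation (only while $h$ is below its target), flipping the direction
of a reticulation edge, and moving the origin or the target of a
reticulation edge to a neighbouring edge.  Reticulation removal is never
proposed: under strict ascent, removing a reticulation can only lower (or
tie) the composite likelihood.  Every proposal is validated against the
degree, acyclicity, level-1, no-2-cycle and no-3-cycle rules; invalid
proposals count as failed attempts.  A run ends after `max_failures = 100`
consecutive failures (the stopping rule is configurable; the value is a
desk-scale default, not a tuned constant).

Candidate networks inherit the incumbent's branch lengths and inheritance
probabilities and are scored after optimizing their continuous parameters
(log-transformed lengths, logit-transformed $\gamma$) with BFGS, falling
back to Nelder-Mead if BFGS fails.  Two numerical choices deserve note:

* **Acceptance tolerance.** The acceptance rule is the strict inequality
  $L_1 > L_0$.  Under floating point, re-optimizing an equivalent topology
  drifts upward by $\sim 10^{-9}$, which would turn strict ascent into an
  endless random walk.  Candidates are therefore (i) rejected unscored if
  their canonical semi-directed topology string equals the incumbent's, and
  (ii) accepted only when the improvement exceeds
  `accept_tol = 1e-6` — sub-tolerance differences are treated as the ties
  the strict rule rejects.
* **Boundary starts.** Inherited branch lengths at the 0 boundary are flat
  directions of the log-transformed objective; candidate scoring floors
  them at 0.01 coalescent units (the optimizer is free to push them back).

During search each candidate is optimized from a single start; final
scores (and `optimize_parameters()` by default) use three starts, the
extra ones jittered on the unconstrained scale (SD 0.5), seeded
deterministically.  Because only edges that enter some quarnet's internal
structure are identifiable, only those lengths are free parameters; root
edges straddling the (arbitrary) root are mildly over-parameterized, which
is harmless for scoring but means individual root-edge lengths should not
be interpreted.  For some cycle configurations only combinations of hybrid
edge lengths are identifiable; `coef()` values on such edges inherit that
ambiguity even when the fit is perfect.

Two scalability devices from the inference method are implemented exactly:

* `prop_quartets` $\in (0,1]$: each run draws
  $\lceil k \cdot \texttt{prop\_quartets} \rceil$ of the $k$ 4-taxon sets
  (uniformly, without replacement, from a per-run seeded stream) and scores
  only those; the final network of every run is rescored against all $k$
  CFs, so reported likelihoods are always on the full-table scale.
* `prob_qr` $\in [0,1]$: with this probability the focus edge of a move is
  chosen by weighted selection — a 4-taxon set is drawn with probability
  proportional to its misfit $W = \sum_i |X_{q_i} - CF_{q_i}| \in [0,2]$
  against the current network (recomputed after every acceptance), and the
  focus is drawn uniformly among that quarnet's spanned edges that are
  legal for the move.  `prob_qr = 0` (default) is plain uniform selection;
  all-zero weights fall back to uniform.

Runs are independent, with per-run RNG streams mixed deterministically from
the master seed; within a run the draw order (subsample, then move/focus
choices) is fixed.  Per-quartet computations are order-stable, so results
are identical for any `workers` value.

## The simulator

`simulate_network()` emulates a standard simulation design: a Yule
(pure-birth, rate 1) species tree; `h` reticulations inserted at arbitrary
positions by uniform rejection sampling over ordered edge pairs (subdivided
at uniform points) until the level-1 rules hold, each new minor hybrid edge
given length 0 and inheritance probability $\gamma = 0.5$; and all
non-minor branch lengths rescaled by one constant so their mean is 2.0, 1.0
or 0.5 coalescent units (low / medium / high incomplete lineage sorting).
The birth rate is irrelevant after rescaling.  For tree shapes whose only
reticulation cycles would span the root spine, a level-1 second
reticulation may be genuinely impossible; the generator reports this
rather than silently relaxing the constraints.  `simulate_gene_trees()` is
the exact MSNC generative process (one lineage per taxon, rate-1 pairwise
coalescence within edges, $\gamma$-routing at hybrid nodes, unbounded root
population), implemented in compiled code and shared with the Monte-Carlo
oracle.

What the simulator does *not* emulate: gene-tree estimation error.  Real
analyses estimate gene trees from finite alignments; here the true gene
trees are used directly, so passing recovery tests demonstrates the
correctness of the CF computation and search, not robustness to gene-tree
error or to model misspecification (gene flow, polyploidy, level-2
structure).

## Accuracy metric

Networks are compared with the hardwired cluster dissimilarity (HWCD): both
networks are rooted at the edge of a common feasible leaf, each edge
contributes the cluster of leaves reachable through its child, and the
distance is the size of the symmetric difference of the two cluster *sets*
(not multisets; the choice is recorded here because conventions differ).
For unrooted binary trees HWCD equals the Robinson-Foulds symmetric split
difference, with maximum $2(n-3)$ used for normalization.  A leaf hanging
below a hybrid node is not a feasible root; comparisons use the first leaf
feasible in both networks.

## Validation scale

The test suite and the acceptance script validate the pipeline end to end
at sizes chosen for a desk machine: oracle agreement on 50 random quarnets
at $10^5$ genes; recovery on $n = 8$ taxa, $h = 1$, $\gamma = 0.5$, low ILS
(mean branch length 2.0), $g = 1000$ true gene trees, 10 independent runs
per fit, 10 replicate seeds, repeated with `prop_quartets = 0.5` for the
paired no-degradation comparison; hill-climbing monotonicity on 20 smaller
seeded datasets; and round-trip/property checks on a few dozen random
networks with $n \le 13$, $h \le 3$.  These sizes are the package's own
validation design; nothing in the method limits it to them, and inference
with tens of taxa is practical.

## Known limitations

* Absolute $\log L$ values depend on optimizer details and on the exactness
  of the quarnet CF computation; other implementations of the same model
  may report slightly different absolute scores even when network rankings
  agree.
* Strict hill-climbing can stall below the global optimum on hard
  landscapes; multiple runs mitigate but do not eliminate this.
* Model selection over `h` is out of scope: the number of reticulations is
  a user input.
* At most 31 taxa in `observed_cf()` (taxon sets are bit-packed).
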