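---
title: "Linear-time branch-length gradients for phylogenetic likelihoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-time branch-length gradients for phylogenetic likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylograd)
```

## The model

An alignment $Y = (Y_1, \dots, Y_C)$ of $C$ columns over $N$ taxa is
modelled as conditionally independent draws from a continuous-time Markov
chain (CTMC) acting along the branches of a rooted bifurcating phylogeny.
Tips are labelled $1..N$, internal nodes $N{+}1..2N{-}2$, and the root
$2N{-}1$; each of the $2N-2$ branches is indexed by its child node and
carries a length $b_i$ in expected-substitution units.  An $S \times S$
generator $\mathbf{Q}$ (4 nucleotide states, 61 universal-code codons, or
a Markov-modulated block composition such as $2 \times 61 = 122$) defines
finite-time transition probabilities, modulated per column by a discrete
mixture of rate scalars $\gamma_r$ with weights $P(\gamma_r)$:

$$P^{(r)}(b_i) = \exp(\gamma_r\, b_i\, \mathbf{Q}).$$

The post-order partials $p_{irc,s} = P(Y_{\lfloor ic \rfloor} \mid Y_{ic}
= s, \gamma_r)$ — the probability of the tip data below node $i$ given its
state — follow Felsenstein's pruning recursion: for an internal node $k$
with children $i, j$,

$$p_{krc} = \left[P^{(r)}(b_i)\, p_{irc}\right] \circ
            \left[P^{(r)}(b_j)\, p_{jrc}\right],$$

and the likelihood is the weighted rate mixture of
$p_{2N-1,rc}^\top \pi$ at the root, with $\pi$ the root state prior
(by default the stationary distribution of $\mathbf{Q}$).

The pre-order partials $q_{irc,s} = P(Y_{ic} = s, Y_{\lceil ic \rceil}
\mid \gamma_r)$ — the joint probability of the node state and the data
*not* below the node — start from $q_{2N-1,rc} = \pi$ and descend:

$$q_{irc} = \left[P^{(r)}(b_i)\right]^\top
            \left\{ q_{krc} \circ \left[P^{(r)}(b_j)\, p_{jrc}\right]
            \right\},$$

computed as two sequenced stages (sibling product, then transposed-matrix
product).  The payoff is the any-node identity: $\sum_r
(p_{irc}^\top q_{irc}) P(\gamma_r)$ is the same site likelihood at *every*
node, and the derivative of the site log-likelihood with respect to any
branch length is a ratio of weighted inner products,

$$\frac{\partial}{\partial b_i} \log P(Y_c) =
  \frac{\sum_r \gamma_r\, (p_{irc}^\top \mathbf{Q}^\top q_{irc})\,
        P(\gamma_r)}
       {\sum_r (p_{irc}^\top q_{irc})\, P(\gamma_r)}.$$

One post-order plus one pre-order traversal therefore yields the gradient
with respect to **all** $2N-2$ branch lengths in $O(N)$ work, compared to
$O(N^2)$ for rerunning pruning with a derivative matrix substituted per
branch.  That gradient is what samplers like Hamiltonian Monte Carlo and
quasi-Newton optimizers consume.

## Rescaling and its bookkeeping

Deep trees underflow double precision if partials are propagated raw.
With `scaling = "always"` (the default) every internal node $k$ stores
rescaled partials $\hat p_{krc} = p_{krc} / M_{kc}$ with one scaler per
(node, pattern) — shared across rate categories, because the likelihood
mixes rates per pattern and a per-rate scaler would break that sum.  We
track each node's own $\log M_{kc}$ and its subtree accumulation.  The
pre-order partials are built from rescaled post-order partials and are
never rescaled themselves; they inherit the deficit of all scalers in the
sibling subtrees along the root path (the parent's own scaler divides the
parent's partial, never $q$).  The any-node evaluation adds both ledgers
back and matches the root evaluation exactly; in the gradient ratio the
same constants multiply numerator and denominator and cancel, so scaled
and unscaled gradients agree to machine precision wherever both exist.
`scaling = "auto"` rescales a pattern only when its partial maximum drops
below `1e-100`; `"off"` disables rescaling and reports the first pattern
whose site likelihood reaches zero as a numerical failure naming that
pattern.

A practical note on when unscaled pruning actually fails: for $S$ states
the per-site likelihood of model-typical data cannot fall far below
$S^{-N}$ (the long-branch saturation value), while doubles only flush to
zero below about $e^{-744}$.  At $S = 4$ that crossover sits near
$N \approx 540$, so a 512-taxon nucleotide instance with unit branch
lengths — deep as it is — still evaluates finitely without rescaling
(its worst per-pattern log-likelihood is about $-713$).  The test suite
demonstrates genuine underflow and its detection at $N = 700$ with
branch lengths 1.5, and codon-sized state spaces underflow far earlier.

## Models

* `gtr_generator(exchangeabilities, frequencies)` — the reversible
  4-state nucleotide model; rates $Q_{st} = r_{st}\pi_t$, normalized to
  one expected substitution per unit time at stationarity (so branch
  lengths are in substitutions per site).
* `codon_generator(kappa, omega, codon_frequencies, code)` — a
  Goldman–Yang-style codon model: single-nucleotide codon changes get
  $\pi_{\text{target}} \kappa^{[\text{transition}]}
  \omega^{[\text{nonsynonymous}]}$; multi-position changes are
  forbidden.  The state space is derived from the genetic-code table (61
  sense codons for the universal code, 60 for the vertebrate
  mitochondrial code), ordered lexicographically over (T, C, A, G) — the
  documented state-index convention.  Stop codons are excluded.  Codon
  frequencies are taken as supplied (equal by default); no F3×4-style
  construction is imposed.
* `markov_modulated_generator(components, switching)` — a block
  composition: diagonal blocks are component generators, off-diagonal
  blocks are switching rates times identity (component switches do not
  co-occur with character substitutions).  The composite is normalized
  to mean rate 1 under its own stationary distribution, solved
  numerically, keeping branch lengths in expected-substitution units.
  Composites are treated as non-reversible.
* `discrete_gamma(shape, R)` — equal-weight discrete-gamma rate
  categories using category **means** over equal-probability quantile
  bands (the common choice; medians are the main alternative), computed
  from the incomplete-gamma identity and renormalized so the mixture
  mean is exactly 1, preserving the branch-length units.
* Matrix exponentials: reversible generators use one symmetric
  eigendecomposition via the $\pi^{1/2}$ similarity transform, cached in
  the generator and reused for every (rate, branch) pair; non-reversible
  generators (the Markov-modulated composites) fall back to
  scaling-and-squaring.  Both paths agree to $10^{-10}$ on reversible
  inputs, which the tests assert.
* The engine also accepts arbitrary per-category generators
  $\mathbf{Q}^{(r)}$ (`per_category =`); the default ties
  $\mathbf{Q}^{(r)} = \gamma_r \mathbf{Q}$, and in the generalized path
  the $\gamma_r$ factor is omitted from the gradient numerator because
  it lives inside $\mathbf{Q}^{(r)}$.

## Engine variants

`engine_config(engine_variant =)` selects one of two implementations of
the same contract:

* **reference** — per-rate-category recursion over dense $S \times C$
  partial matrices; never pads.
* **batched** — stores each node's partials as one contiguous
  $S_\text{pad} \times (R \cdot C)$ block (rate-major), precomputes all
  matrix transposes before the pre-order pass, preserves the two-stage
  split of the pre-order product, and accumulates the gradient
  rate-serially into state-specific numerator/denominator matrices
  before a final state reduction.  `pad_states = TRUE` zero-pads the
  state dimension to the next multiple of 16 (61 → 64).  This mirrors
  the memory layout a many-core array backend wants, as a faithful
  single-threaded analog.

Padding adds exact zeros, so all variants agree to $10^{-12}$ on every
exposed output — asserted across the randomized suite.  All reductions
sum in fixed ascending index order, so repeated runs of a given variant
are bit-reproducible.

## Data handling

Site patterns are compressed to unique columns with integer weights
(first-occurrence order, so per-pattern outputs are reproducible); the
likelihood and gradient are computed per unique pattern and reduced by
weights.  Tip states follow the indicator rule: an observed state is a
one-hot vector, IUPAC ambiguity codes set ones at each compatible state,
and gaps/unknowns are all-ones.  Codon alignments are nucleotide text
interpreted in frame-aligned triplets; a triplet containing ambiguous
nucleotides expands to every compatible sense codon, and an unambiguous
stop codon is an error in strict mode (or fully ambiguous otherwise).
Reading frame defaults to 0 and is never auto-detected.

## The synthetic-data generator

`random_tree(N)` draws a topology by random sequential coalescence
(uniform pair joins) with i.i.d. branch lengths, exponential with mean
0.1 by default — a typical within-species to shallow-phylogeny scale.
`simulate_alignment()` draws, per column: a rate category, a root state
from $\pi$, then child states down the tree from the rows of
$P^{(r)}(b)$; one seeded stream in that documented order makes outputs
exactly reproducible.  The simulator emulates the likelihood model
exactly — which is the point, since the validation targets are
mathematical identities of that model.  It does **not** emulate indels,
alignment error, selection heterogeneity along the sequence, or
non-stationary composition; passing tests therefore certify the
computation, not robustness of the model to real-data violations.

Fixture shapes used by tests (chosen to exercise every code path while
keeping a laptop-scale run): a randomized suite spanning
$N \in \{2,4,8,16\}$, $S \in \{4, 61\}$, $R \in \{1,4\}$,
$C \in \{1,10,50\}$ with ambiguous tips and zero-length branches;
exhaustive enumeration up to $N = 5$; timing probes at
$N \in \{64,128,256\}$, $C = 100$; recovery studies on 8 taxa with
$C = 10^4$ (optimization) and $C = 2 \times 10^3$ (HMC).

## Oracles

Three independent computations validate the engine: the $O(N^2)$
matrix-derivative gradient (pruning rerun per branch with
$\mathrm{d}P/\mathrm{d}b$ substituted), central finite differences of the
log-likelihood (default step $10^{-6}$, one-sided at the $b = 0$
boundary — a balance of truncation against cancellation at double
precision), and exhaustive enumeration over internal-node state
assignments (refused above $S^{N-1} > 10^6$).  Agreement targets:
$10^{-8}$ relative against the matrix-derivative oracle, $10^{-5}$
against finite differences, $10^{-10}$ absolute against enumeration.
Relative deviations are measured with a magnitude floor of 1
(`max_rel_dev`), so near-zero gradient entries are compared absolutely.

## Gradient conventions and degenerate cases

Both root-child branches receive gradient entries; for the unrooted
convention (one of them pinned at zero) only their **sum** is
identifiable, and `reduce_branch_set()` provides exactly that reduction —
the same mechanism serves strict-clock-style reductions over arbitrary
branch sets.  The recovery studies below compare the root-child pair
through its sum for this reason.  $C = 1$ and $N = 2$ are supported;
zero-length branches are legal everywhere (they are the unrooted-root
convention).  A pattern whose site likelihood is exactly zero (impossible
data, or unscaled underflow) raises a classed error naming the pattern
rather than returning $-\infty$; a zero gradient denominator does the
same naming the branch and pattern.

## The HMC demonstration

`hmc_run()` is a deliberately minimal sampler showing the gradient's
intended use: leapfrog dynamics on $\theta = \log b$ (the Jacobian term
$\sum_i \theta_i$ added, removing the positivity boundary), independent
exponential priors on branch lengths, identity mass matrix, no
adaptation.  Step size and path length are fixed by the caller; the demo
configuration (ε ≈ 0.06, L = 8) was chosen to give healthy acceptance
rates on the 8-taxon study instances, in line with standard HMC practice.
Reversibility, $O(\varepsilon^2)$ energy error, prior recovery on flat
data, and posterior coverage of simulated branch lengths are all tested.
This is a demonstration, not a replacement for a production Bayesian
phylogenetics stack (no topology moves, clock models, or coalescent
priors).

## Numerical choices, in one place

* Shared-across-rates scalers; rescale every internal node by the max
  partial per (node, pattern) under `"always"`, threshold $10^{-100}$
  under `"auto"`.
* Pre-order partials never independently rescaled; non-finite $q$ raises
  a numerical failure (a documented limitation — the root prior bounds
  $q$ in practice).
* Summation order fixed ascending everywhere; engine variants
  bit-reproducible individually, equal to each other within $10^{-12}$.
* Finite-difference step $10^{-6}$; optimizer works on $\log b$ with
  initial lengths floored at $10^{-4}$.
* Tolerances asserted in tests: $10^{-8}$/$10^{-5}$/$10^{-10}$ as above,
  $10^{-12}$ for variant equivalence, $10^{-8}$ for reroot invariance of
  reversible models.

## Known limitations

* Gradients are with respect to branch lengths only; substitution-model
  parameters (κ, ω, frequencies, gamma shape) and node-height or
  clock-rate reparameterizations are consumed as fixed inputs (chain
  rules are the caller's concern).
* Single partition per run; no amino-acid empirical matrices; no
  topology inference.
* The batched variant is a single-threaded analog of an array-parallel
  layout; it does not itself use a GPU or threads.
* At $S = 4$, genuinely demonstrating unscaled underflow requires more
  than ~540 taxa (see the rescaling section); rescaling is nevertheless
  the default everywhere because codon-sized state spaces and larger
  trees cross that line quickly.
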