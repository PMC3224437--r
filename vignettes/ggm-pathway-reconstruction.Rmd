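---
title: "Reconstructing pathway reactions with Gaussian graphical models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pathway reactions with Gaussian graphical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggmetab)
```

## The statistical model

Let $X \in \mathbb{R}^{n \times m}$ hold natural-log metabolite
concentrations for $n$ individuals and $m$ metabolites. The package
assumes $X$ is approximately multivariate normal on the log scale
(`lognormality_check()` provides a per-metabolite QQ-correlation
diagnostic for raw versus logged data). From the Pearson correlation
matrix $P = (\rho_{ij})$ the full-order partial correlations are

$$\zeta_{ij} = -\,\omega_{ij}/\sqrt{\omega_{ii}\,\omega_{jj}},
  \qquad (\omega_{ij}) = P^{-1}.$$

$\zeta_{ij}$ equals the correlation of the residuals obtained when
regressing metabolites $i$ and $j$ on all remaining metabolites — the
association left after conditioning away every other measured variable.
The test suite asserts this equivalence to $10^{-8}$ against an
independent regression-based construction on random Gaussian data
($n = 200$, $m = 10$, 50 replicates).

Significance uses Fisher's z-transform: with $z = \mathrm{atanh}(\zeta)$
and conditioning order $q$ ($q = m - 2$ for the full GGM, $0$ for Pearson
correlations, 1–3 for the low-order variants),
$p = 2\,\bigl(1 - \Phi(\sqrt{n - q - 3}\,|z|)\bigr)$, two-sided throughout.
"Significantly positive" always means $p \le \tilde\alpha$ *and*
$\zeta > 0$. Bonferroni correction over the $\binom{m}{2}$ pairwise tests
gives $\tilde\alpha = \alpha / \binom{m}{2}$; inverting the test yields
the equivalent absolute-correlation cutoff
$\zeta^\ast = \tanh\!\bigl(\Phi^{-1}(1 - \tilde\alpha/2)/\sqrt{n - q - 3}\bigr)$,
monotone decreasing in $n$. For a 151-metabolite panel at $\alpha = 0.01$
this gives $\tilde\alpha = 0.01/11325 \approx 8.83\cdot10^{-7}$ and, at
$n = 1020$, a cutoff of $\approx 0.1653$.

Numerical choices: $P^{-1}$ is computed through a Cholesky factorization
with a condition-number guard at $10^{12}$; above it the matrix is treated
as singular and the error message points at the $n > m$ requirement. The
diagonal of $Z$, which the formula would set to $-1$, is fixed at $+1$ by
convention and excluded from all downstream statistics. p-values are
clamped to $[0, 1]$; $|\zeta| = 1$ returns an exact zero with a flag. A
significance level of exactly 0 rejects nothing, even where extreme
p-values underflow to 0 in double precision.

### Low-order partial correlations

`low_order_partial()` conditions each pair on every subset of $q \in
\{1,2,3\}$ other metabolites (recursion on the conditioning set). An edge
survives only when *every* conditioning subset leaves it significant at
$\tilde\alpha$ (with the order-$q$ Fisher factor), and the reported value
is the minimum-magnitude partial correlation across subsets — the most
conservative choice. At $m = 3, q = 1$ (and generally $q = m - 2$) this
reproduces the full-order GGM exactly, which the tests assert to
$10^{-10}$. Parallel-path motifs (the diamond benchmark) are the known
failure case: no single conditioning variable separates the two ends, so
the order-1 network keeps an edge the full GGM correctly removes.

## The kinetic validation simulator

The simulator asks: *when does the GGM of steady-state concentrations
recover the generating reaction network?* A reaction network couples a
stoichiometry matrix $S \in \mathbb{Z}^{m \times r}$ (educts negative,
products positive) with per-reaction rate laws:

* mass action, $v_j = k_j \prod_i x_i^{-s^e_{ij}}$ over the educt
  stoichiometries $s^e$ (zeroth-order input reactions return $k_j$);
* reversible Michaelis–Menten,
  $v = \dfrac{V^+/K_{M,s}\,[S] - V^-/K_{M,p}\,[P]}
             {1 + [S]/K_{M,s} + [P]/K_{M,p}}$;
* mixed inhibition, which multiplies the occupancy terms by
  $(1 + [I]/K_{ii})$ and adds $[I]/K_i$ to the denominator; with
  $K_i = K_{ii}$ this is classical non-competitive inhibition.

Population variability enters as independent log-normal fluctuation of
every kinetic constant: $k = k_{\mathrm{nominal}} \cdot e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$, one draw per simulated individual, with
$\sigma = 0.2$ as the default spread. The nominal value is the *median* of
the sampled distribution; `location = "mean"` switches to
$\mu = -\sigma^2/2$ so the nominal is the mean instead. For first-order
systems the two conventions shift log steady states by per-metabolite
constants and leave all correlation structure unchanged, which is why the
median convention is the default. Per-reaction $\sigma$ overrides
(`sigma_map`) and a constant mask (`mask`, e.g. only the $V_{max}$ values
fluctuate) are available; by default all constants of a reaction
fluctuate.

Steady states: for networks of only zeroth- and first-order mass-action
reactions the flux balance $S\,v(x^*) = 0$ is a linear system solved
directly (singularity, i.e. the absence of a unique steady state, and
non-positive solutions are errors). Otherwise the ODEs
$\dot x = S\,v(x,k)$ are integrated with a stiff-capable solver (lsoda,
with an analytically derived Jacobian) over doubling time horizons until
the relative derivative norm satisfies
$\lVert \dot x \rVert < 10^{-9}(1 + \lVert x \rVert)$, with a hard cap of
$10^6$ time units; non-convergence and departures from the positive
orthant are errors carrying the failing draw index.
`verify_monostability()` replaces structural uniqueness proofs with
empirical parameter and initial-value sampling: all initial states must
reach the same equilibrium within tolerance, and solver failures are
reported rather than raised.

### Benchmark networks and their rate constants

`make_network()` ships three-metabolite chains (reversible, irreversible,
irreversible with per-metabolite exchange reactions), a branched module, a
diamond motif, end-product inhibition in closed and open variants, a
cofactor-driven module modeled on the first glycolysis reactions
(ATP/ADP-coupled phosphorylations with cofactor exchange), a reversible
bimolecular split with isomerization, and a four-metabolite reversible
Michaelis–Menten chain with forward maximal rates twice the backward
rates.

The nominal constants deserve comment, because the qualitative behavior
of the benchmarks depends on a *regime*, not on fine tuning:

* **Reversible interconversions are fast ($k = 10$) relative to exchange
  fluxes ($k = 1$).** Partial correlations separate direct from indirect
  neighbors when reversible reactions hold the pathway near mutual
  equilibrium. A linearized analysis of the reversible chain shows why:
  with interconversion rate $K$, the indirect pair retains a structural
  partial correlation through the shared input/output parameters that
  decays as $O(1/K)$ and vanishes in the fast-interconversion limit,
  where the chain becomes conditionally Markov. At $K = 1$ that residual
  is $\approx 0.10$ — detectable at $n = 1000$ — so a slow-interconversion
  parameterization would *not* show the discrimination the reversible
  benchmarks are meant to demonstrate; at $K = 10$ the residual sits well
  below the detection limit (though an unlucky seed can still graze the
  cutoff). The same reasoning applies to the phosphorylation steps of the
  cofactor module, which are therefore modeled as reversible bimolecular
  mass-action pairs: made irreversible, backbone and backbone-skipping
  pairs are both mediated purely by the shared flux and become
  structurally indistinguishable.
* **Input fluxes stay below saturating enzyme capacity.** The
  Michaelis–Menten chain and the inhibition modules use input rate 0.5:
  a unit input flux can exceed the saturating capacity of an inhibited or
  saturated enzyme ($\approx V^+/(1 + [D]/K_i)$) for plausible parameter
  draws, leaving no positive steady state. The cofactor module's ATP
  supply (rate 8) similarly exceeds its net consumption (2) with enough
  margin that $\sigma = 0.2$ fluctuations keep the steady state positive.

The irreversible chain *without* exchange is deliberately kept at unit
constants: its failure — all three partial correlations comparable and
significant, because the single input determines every level — is the
behavior the benchmark exists to show.

## Synthetic panels: what they emulate and what they do not

`generate_synthetic_panel()` stands in for cohort data. The default
`panel_spec()` mirrors a lipid-focused serum panel: 14 amino acids, one
hexose pool, 38 acyl-carnitine species (plain, hydroxy, dicarboxy,
methyl-dicarboxy), 14 sphingomyelins (9 plain + 5 hydroxy) and 87
phosphatidylcholines (36 diacyl, 38 acyl-alkyl, 13 lyso) — 154
identifiers. (Published descriptions of such panels quote $m = 151$
measured metabolites alongside per-class counts that sum to 154; the
generator follows the per-class counts, and all pair-count arithmetic in
the package derives from the actual column count, never from a constant.)

Two generating mechanisms:

* `block_cov` draws log concentrations from a multivariate normal whose
  precision matrix carries within-class chains: consecutive class members
  get partial correlation `strength` (default 0.3; $|{\cdot}| < 0.5$
  keeps the matrix diagonally dominant, hence positive definite), classes
  are independent, and random per-metabolite offsets
  ($N(3, 1)$ on the log scale) set abundances. The requested partial
  correlations are recovered by `ggm()` within 0.05 at $n = 5000$ in the
  tests.
* `simulator` builds each class as an independently simulated reversible
  first-order chain with exchange reactions.

Passing tests on these panels shows the estimator recovers known sparse
conditional-dependence structure at realistic dimensions. It does *not*
show robustness to features of real cohort data that the generator omits:
between-class biochemical coupling (real phospholipid classes share a
fatty-acid pool), measurement error, batch effects, non-normal tails,
missing values (the readers reject rather than impute them), or
confounding by age, sex and medication.

## Graphs, modularity and triads

`threshold_graph()` keeps the significantly positive partial correlations
(sign condition configurable). Class structure is quantified by the
relative out-degree matrix $R_{ij} = A(V_i, V_j)/A(V_i, V)$ (adjacency
sums, so a within-class edge contributes twice to $A(V_i,V_i)$) and the
modularity

$$Q = \sum_i \Bigl[\frac{A(V_i,V_i)}{A(V,V)} -
  \Bigl(\frac{A(V_i,V)}{A(V,V)}\Bigr)^2\Bigr],$$

which applies unchanged to weighted graphs and agrees with the standard
community-detection modularity (asserted against igraph in the tests).
Closed forms pin the implementation: $Q = 0$ for a single class, $1/2$
for two disconnected equal cliques split along their classes, $1/6$ for
the 4-path split in the middle.

The null model is degree-preserving double-edge rewiring: $5e$ swaps
(invalid swaps — self-loops, multi-edges — are redrawn), after which the
degree sequence is identical and the edge-set overlap with the original
drops below one half on sparse graphs. On weighted graphs each edge weight
travels with the stub of its first endpoint, a neighbor-preserving
interpretation of weighted rewiring; alternative conventions exist and
should produce similar nulls, but are not guaranteed identical.
`modularity_zscore()` reports
$z = (Q_{\mathrm{obs}} - \bar Q_{\mathrm{null}})/s_{\mathrm{null}}$;
when the null has zero spread and the observed value equals the null mean
(e.g. a single-class partition, where $Q \equiv 0$) the z-score is 0 by
convention, and `NA` otherwise. Singleton classes are excluded from
partition statistics with a message, since a one-member class contributes
no meaningful modularity.

`anneal_partition()` maximizes $Q$ by simulated annealing with
single-node move proposals and geometric cooling (defaults: $T_0 = 0.05$,
factor 0.95 per sweep, 200 sweeps); the best partition ever visited is
returned, so the result never falls below the initial partition.

`find_triads()` lists the one-negative/two-positive motifs: two
metabolites that are both significantly positively coupled to a hub but
significantly negatively to each other. The mathematics of partial
correlations makes such negative values the signature of pairs exactly
two reaction steps apart; for sensitivity/specificity these pairs remain
in the indirect class (they are predictions of *absence* of a direct
reaction), and their enrichment is reported separately.

## The fatty-acid pathway model and distances

The bundled model (`default_pathway_model()`, also shipped as the
editable plain-text file `inst/extdata/fatty_acid_model.txt`) encodes
three biosynthesis series — de novo synthesis ($C2$ elongations
C2:0 → … → C26:0 with SCD-type desaturations to C16:1 and C18:1) and the
ω-3 and ω-6 polyunsaturated pathways (alternating desaturations and
elongations from the essential fatty acids C18:3 and C18:2, closing with
the peroxisomal shortening steps C24:5 → 22:5 and C24:6 → 22:6) — plus a
separate β-oxidation domain: linear chains of C2 degradation steps over
acyl chain lengths C2–C18, kept per double-bond count (0–2). Double-bond
*positions* are deliberately omitted because brutto-composition mass
spectrometry cannot resolve them; consequently, species of equal mass
arising in both ω-pathways (C18:3, C20:4, C22:5, C24:5) are merged into
single nodes carrying both pathway tags. The de novo and ω series are
disconnected (humans lack the Δ12 desaturation), so distances across them
are infinite by construction.

Distances are breadth-first shortest paths on the undirected reaction
graph — reversibility is ignored, so distances are symmetric. Measured
lipids are projected onto the model through their side chains:
single-residue classes (lyso-PCs, sphingomyelins, carnitines) map
directly; two-residue classes (diacyl- and acyl-alkyl-PCs) enumerate all
unordered fatty-acid pairs consistent with the measured carbon and
double-bond sums, and the reported distance is the minimum over variant
pairs of the best residue-to-residue matching of summed per-residue
distances. This "summed steps under optimal matching" convention is the
natural generalization of taking the shortest possible single-reaction
explanation; whether one should instead allow simultaneous single-step
changes on both residues is not determined by the measurement, and the
summed convention is the conservative choice. For pairs with unequal
residue counts (a lyso-PC against a diacyl-PC) the closest residue pair is
used. Hydroxy-sphingomyelins project identically to plain sphingomyelins
(no hydroxylation reactions are modeled), carnitine modifications
likewise. Amino acids and the hexose have no projection; their pairs are
marked not-applicable and excluded from evaluation rather than scored.

## Evaluation

`stratify_by_distance()` joins the GGM with the distance matrix into a
pair table; `classify_edges()` counts a pair as predicted-positive when
its partial correlation is significantly positive (a switch allows
absolute-value thresholding) and condition-positive when its distance is
exactly 1. Sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$ and their
harmonic mean $F_1$ follow; undefined rates (empty denominators) are
`NA`, never 0. The Wilcoxon rank-sum test compares partial correlations
of distance-1 pairs against distance ≥ 2 (infinity included). On
simulated reversible first-order pathways with exchange reactions
($m = 8$, $n = 1000$, $\sigma = 0.2$, five seeds) the pipeline reaches
$F_1 \ge 0.9$ against the generating topology, the package's end-to-end
benchmark.

## Problem sizes and reproducibility

The test and acceptance computations use $n = 1000$ samples for kinetic
ensembles, $n = 5000$ for planted-precision recovery ($m = 10$, 20
seeds), 50 replicates for the regression-residual oracle and $10^3$
randomizations for the planted-modularity z-score — sizes chosen so each
check is decisive (sampling error well below the asserted margins) while
the whole suite stays quick to run. All stochastic steps take explicit
integer seeds; the command-line interface logs configuration, seeds and
package version for every run, and `scripts/acceptance.R` derives every
random stream from its single `--seed` argument.

## Known limitations

* Estimation requires $n > m$; shrinkage or regularized precision
  estimation for wide panels is out of scope (low-order partial
  correlations are the supported alternative).
* Bonferroni correction is conservative and ignores the dependence
  between pairwise tests; FDR-style alternatives are not implemented.
* Mechanisms that genuinely defeat correlation-based reconstruction —
  antagonistic correlation-generating processes (the bimolecular split
  benchmark), inhibition combined with exchange fluxes (which decouples
  the inhibited metabolite), strongly irreversible cascades — are
  demonstrated by the simulator but cannot be repaired by the estimator.
* The pathway model is a curated simplification: no positional isomers,
  no head-group chemistry, no automated import from reaction databases.
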