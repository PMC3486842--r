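---
title: "Predicting catabolic potential and biomass yield: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting catabolic potential and biomass yield: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catapot)
```

## The problem

Constraint-based metabolic reconstructions can predict whether a nutrient
feeds a microbe and how much biomass it yields, but they are laborious to
build and hard to interpret.  `catapot` implements a phenomenological
alternative: a three-layer model that uses only (i) a nutrient's structure
and class, (ii) the presence of a handful of gating enzymes in the
organism, and (iii) the carbon flow through the pathways that catabolize
the nutrient.  The package also ships a small flux-balance-analysis (FBA)
engine so that in silico ground truth — growth/no-growth labels and molar
biomass yields — can be generated from stoichiometric models, and a
synthetic-fixture generator that plants known structure in toy organisms
so every layer is testable end to end.

The three layers:

1. **Catabolic potential.**  Is nutrient $i$ a carbon source for species
   $s$ (label $G$) or not ($NG$)?
2. **Single-nutrient yield.**  If it is, the maximal biomass is modeled as
   $B_i = y_s \, C^{\mathrm{eff}}_i$: a species-level per-carbon yield
   times the nutrient's *effective* carbon count.
3. **Complex media.**  On a medium $m$ the model is additive:
   $B_m = \sum_{i \in m,\, i \in G} y_{c(i)} \, C^{\mathrm{eff}}_i$,
   with per-class carbon yields $y_c$ averaged over training species.

## The decision cascade

`classify()` resolves a (nutrient, organism) pair through a fixed rule
order:

1. **Uptake gate.**  Nutrients the organism cannot transport are $NG$.
   Fatty acids bypass the gate: they diffuse through the membrane, so
   their fate is decided by enzymes, not transporters.
2. **Class rules.**  Cell-boundary nutrients and cofactors have cellular
   roles that select against catabolic enzymes; inorganic compounds and
   pyrimidines supply no usable organic carbon.  All four classes are
   $NG$.  Sugars and sugar derivatives, the canonical carbon sources, are
   $G$.
3. **Purines** are $G$ exactly when the organism encodes
   5-hydroxyisourate hydrolase (EC 3.5.2.17), the committed step of urate
   degradation to glyoxylate.
4. **Fatty acids** are $G$ exactly when both terminal
   $\beta$-oxidation enzymes are present (EC 1.1.1.35 and EC 2.3.1.16) —
   the two reactions shared by every round of the cycle.
5. **Complex nutrients** of the remaining classes are decomposed into
   their simple components (e.g. a nucleoside into phospho-ribose and a
   base, tryptophan into pyruvate and indole) and labeled $G$ if *any*
   component is catabolizable.  Components are classified without the
   uptake gate because a fragment produced inside the cell needs no
   transporter.  The any-component rule is a design choice aligned with
   the yield model, which credits exactly the catabolizable components.
6. **Everything else** — amino acids, the derivative classes, small
   organic compounds, for which no class-level pattern holds — falls to a
   logistic model over pathway membership.

Ties at the logistic threshold (probability exactly 0.5) are called $NG$:
false positives are the dominant error mode of pathway-based
classification, so the conservative call is to withhold growth.

## The logistic pathway model and its selection

For the residual nutrients the probability of being a carbon source is

$$P(i \in G \mid M) = \frac{1}{1 + e^{-\eta_i}}, \qquad
\eta_i = \beta_0 + \sum_p \beta_p x_{ip} + \sum_{(p,q)} \beta_{pq} x_{ip} x_{iq},$$

where $x_{ip}$ indicates membership of nutrient $i$ in pathway $p$.
`fit_logistic()` maximizes the likelihood with `stats::glm.fit`; because
pathway indicators on small samples separate easily, a diverging fit is
redone as bound-constrained maximum likelihood with $|\beta| \le 20$
(`cap`), and flagged.  At the cap the fitted probabilities are within
$2\times10^{-9}$ of 0/1, so the cap changes no decision at threshold 0.5.

`greedy_select()` grows the model from the null model in three phases that
mirror how such models are assembled by hand: first pathways whose members
are mostly $G$ (they cover many growth calls at once), then pathways rich
in $NG$ nutrients (they supply true negatives), then pairwise interactions
between a selected $G$ pathway and any other pathway (they remove false
positives sitting in the overlap).  Candidates are ranked by balanced
accuracy — the mean of true-positive and true-negative rates, so that the
typically unbalanced class sizes cannot let one class dominate — computed
only on nutrients *not yet covered* by selected $G$ pathways; pathway
overlap is substantial, and without the exclusion a second, largely
redundant pathway looks almost as good as the first.  Pair candidates act
entirely inside covered pathways, so they are ranked on all rows.  A term
is accepted only if it improves **both** AIC ($2k - 2\ln L$) and BIC
($k \ln n - 2\ln L$, $k = 1 + P + z$); requiring both keeps
noise-level terms out on label-independent data.  Ties between candidates
break lexicographically so selection is reproducible.  `score_model()`
reports TP/TN rates, the information criteria, and the area under the ROC
curve built by the ranked-sweep construction (rank nutrients by predicted
probability and trace the fraction of $G$ against the fraction of $NG$
encountered); tied probabilities are swept as one block, which makes the
construction coincide with the Mann–Whitney statistic under midrank ties —
the identity the test suite asserts.

## Single-nutrient yield

Sugars sit at the efficiency envelope of carbon conversion (their hydroxyl
groups are oxidized to regenerate NADH), so the species reference yield
$y_s$ is the mean per-carbon yield of the organism's uptaken $G$ sugars
(`sugar_reference_yield()`).  The yield of any other nutrient is
$y_s\,C^{\mathrm{eff}}_i$, where `effective_carbons()` counts only the
carbons that can reach biomass:

* simple non-purine nutrients: all $C_i$ carbons;
* purines: $C_i - 3$ — three carbons leave as CO$_2$ and urea on the way
  to glyoxylate (adenine, $C=5$, contributes 2);
* complex nutrients: the sum over catabolizable components, with
  multiplicity, purine components again leaking three (a thymidine-like
  nucleoside with a catabolizable 5-carbon phospho-ribose and a
  non-catabolizable base contributes 5 of its 10 carbons).

Species flagged anaerobic are refused by `yield_table()`: anaerobic
energetics change the polymerization cost of biomass and break the
aerobic envelope the model is calibrated on.  A species with no
growth-supporting sugar raises an error directing the caller to the
training-set class-yield table rather than silently inventing a
reference.

## Complex media

Media are restricted to five classes — sugars, fatty acids, amino acids,
purines, pyrimidines — using nucleobases only (nucleosides already mix a
sugar with a base).  Because diauxic regulation lets a microbe use one
sugar at a time, `generate_media_ensemble()` fills a single glucose-only
sugar slot; every other eligible nutrient enters independently with
probability $p$.  The reference ensembles are 1000 media at each of
$p \in \{0.1, 0.5, 0.9\}$ (3000 media total); both the triple and the
ensemble size are configurable.

Per-class carbon yields $y_c$ (`class_yield_table()`) are two-level
averages — within species over that species' $G$ nutrients of the class
(per *effective* carbon), then across training species — so that
species with many measured nutrients do not dominate.  Predictions are
per mole of nutrient; `measure_medium_biomass()` therefore grants each
present nutrient a molar uptake bound of 1 by default, putting the FBA
measurement on the same scale.  `validate_ensemble()` summarizes an
ensemble by the through-origin regression slope
$K = \sum B^{\mathrm{pred}} B^{\mathrm{FBA}} / \sum (B^{\mathrm{FBA}})^2$
and the Spearman rank correlation.  $K < 1$ means the additive model
under-predicts — the signature of synergistic pathway coupling, which the
additive model deliberately omits.

## The FBA engine

A model is a list of reactions with a stoichiometric matrix $S$ (rows =
reactions, columns = metabolites).  `maximize_biomass()` solves

$$\max v_{\mathrm{biomass}} \quad \text{s.t.} \quad S^\top v = 0,\;
\mathrm{lb} \le v \le \mathrm{ub},$$

with exchange bounds taken from the medium.  Reversible reactions are
encoded by negative lower bounds, never by splitting.  `label_growth()`
calls a nutrient $G$ when adding it to the minimal medium lifts the
optimum above `epsilon` (default $10^{-6}$ flux units — tiny numerical
growth is not growth); a "minimal" medium that grows alone is an error,
not a label.  The default uptake bound for a tested carbon source is 10
flux units, the common FBA convention.  `remove_atp_maintenance()` clamps
the maintenance drain to zero before yield analysis, since maintenance is
a fitted, growth-rate-era quantity that distorts maximal conversion; a
biomass-ATP override is intentionally not guessed.

The LP itself is solved by a bounded-variable two-phase primal simplex
written for this package.  Metabolic LPs are extremely degenerate — most
reactions sit at a zero bound at the optimum — and the general-purpose
simplex routines available to R here fail on such bases, so the solver
uses Bland's smallest-index pivoting throughout, which guarantees
termination without perturbation tricks.  Tolerances: $10^{-9}$ on pivots
and feasibility; the basic solution is re-derived from the final basis to
wash out incremental drift.  Correctness is asserted against an
exhaustive vertex-enumeration oracle (every assignment of variables to
{lower, upper, free}) on random toy models, where the two must agree to
$10^{-8}$.

## What the synthetic fixtures emulate — and what they do not

`make_catalog()` builds a 39-nutrient catalog spanning all twelve classes
with four complex nutrients of known decomposition, plus four aerobic
organisms covering the enzyme-flag combinations (three training, one
held-out; an anaerobic specialist on request).  `make_linear_fba_model()`
compiles the cascade's ground truth into a stoichiometric network: one
catabolic chain per catabolizable nutrient delivering exactly
$C^{\mathrm{eff}}$ precursors per mole, decomposition reactions with
excretion drains for dead-end fragments, a 3-carbon waste for purines,
and a biomass reaction consuming $1/y_0$ precursors ($y_0 = 0.1$ biomass
per carbon by default).  Yields are therefore *exactly*
$y_0 C^{\mathrm{eff}}$, and the additive media model is exact — the
zero-synergy limit in which the validation slope must be $K = 1$ and
$\rho = 1$.  With `synergy = TRUE`, sugar and amino-acid chains emit
distinct cofactors and a planted reaction converts one of each into extra
precursor, making mixed media strictly super-additive while leaving
single-nutrient yields untouched; measured biomass then dominates the
additive prediction for every medium, the directional claim the test
suite checks.  `make_labeled_dataset()` draws pathway memberships
(optionally with planted overlap) and Bernoulli labels from a planted
logistic model, so coefficient recovery and selection behavior can be
tested against known truth.

Passing on these fixtures shows the machinery is self-consistent, not
that real organisms obey it: real networks have shared bottlenecks,
partial pathway conservation, noisy annotations, and yields that are only
approximately proportional to carbons.  The fixtures deliberately omit
all of that.

## Numerical choices and problem sizes

* Logistic decision threshold 0.5; ties $NG$.  Coefficient cap 20.
* LP tolerances as above; growth threshold `epsilon` $10^{-6}$; uptake
  bound 10 (single-nutrient tests) and 1 (molar media measurements).
* Spearman validation ranks values quantized at a relative $10^{-9}$:
  ensembles contain many exactly-tied biomass values that the LP
  reproduces only to round-off, and ranking raw doubles would turn those
  ties into noise.
* Reference test sizes: 20-seed replicates at $n = 200$ and $n = 2000$
  for coefficient recovery (medians reported, since single-replicate
  errors at these Fisher informations are of order 0.1–0.3); ensembles of
  1000 media at each of three inclusion probabilities; brute-force model
  enumeration up to three terms on 600-row planted datasets.
* Fixture carbon counts stay at or below 18 so hand LP solutions and the
  vertex oracle remain trivial.

## Limitations

The model predicts maximal biomass per mole under aerobic conditions with
a fixed minimal medium; it says nothing about growth *rates*, uptake
kinetics, regulation beyond the one-sugar constraint, nitrogen/sulfur/
energy limitation, or which minimal-medium components a species needs.
Synergistic pathway coupling is observable in the FBA ground truth but
deliberately absent from the additive prediction.  SBML import covers
Level 3 core with fbc bounds and objectives only; the TSV reaction
dialect is the canonical interchange.
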