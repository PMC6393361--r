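---
title: "Methods: unified pathway networks and active-subnetwork discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unified pathway networks and active-subnetwork discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the network
model, the scoring and search mathematics, the synthetic benchmark, and the
numerical and design choices a maintainer would want spelled out.

## 1. The unified interaction-as-node network

A pathway collection is a set of pathway models, each a list of interaction
records. A record has a type from a six-value vocabulary — `directed`,
`complex_participation`, `catalysis`, `inhibition`, `conversion`,
`undirected` — and one or more role-tagged participants identified by
namespaced ids (gene products, metabolites, complexes). Directed types carry
at least one `source` and one `target`; undirected types only
`participant` roles.

`build_network()` turns a collection into one bipartite graph:

1. **Currency exclusion first.** Participants on the exclusion list
   (ubiquitous small molecules such as ATP, H2O, H+) are removed from every
   record before anything else. These metabolites take part in so many
   reactions that they create biologically meaningless shortcuts; a record
   reduced to a single participant by this step carries no path information
   and is dropped (counted in the build report).
2. **Deduplication.** Records are merged by a canonical key: interaction
   type plus the multiset of (entity id, role) pairs. The key deliberately
   ignores pathway and local ids, so the same biochemical interaction drawn
   in many pathways becomes one interaction node whose *provenance* records
   every contributing pathway and whose *occurrence count* preserves raw
   multiplicity. The two numbers differ exactly when a pathway draws the
   same interaction twice. Including the interaction type in the key is a
   design choice: an A→B inhibition and an A→B catalysis remain distinct
   nodes.
3. **Assembly.** One node per merged interaction, one node per distinct
   participant entity, one edge per distinct (interaction, participant,
   role) triple, the role stored as an edge attribute. A participant
   appearing with two roles in one interaction contributes two edges.
   Complexes are atomic nodes; no member expansion is attempted.

The resulting graph is bipartite by construction (every edge joins an
interaction node to a molecule node) and every interaction node has at least
two distinct molecule neighbours. The build is a pure function: record order
never changes the output (node ids are assigned after sorting canonical
keys; components are ordered by size, ties by smallest member id).

## 2. Module scoring

Expression evidence enters as one z-score per measured gene,
`z_i = qnorm(1 - p_i)`. P-values are clamped into
`[ε, 1 − ε]` with `ε = 1e-12` so that `p = 0` maps to a large but finite z.
Missing p-values are *not* imputed — an unmeasured gene is simply unscored
and invisible to the aggregate; imputing `p = 0.5` would dilute the module
size `k` without adding evidence.

A module with scored members `A`, `|A| = k`, has raw score
`zA = Σ z_i / √k`. Under independent standard-normal node scores this is
size-stable, but real (and synthetic) score populations have non-zero mean
and non-unit spread, and module-size biases creep in. The package therefore
calibrates empirically: for each `k` up to the configured maximum, `μ_k` and
`σ_k` are the mean and standard deviation of `zA` over `n_draws` uniform
random size-`k` subsets of the scored nodes (connectivity not required), and
the corrected score is `sA = (zA − μ_k) / max(σ_k, 1e-9)`. The `σ` floor
guards the degenerate all-equal-score case, where every same-size subset has
identical `zA` and `σ_k = 0`; the corrected score is then 0 rather than a
division blow-up. Calibration draws one uniformly ordered `k_max`-subset per
replicate and uses its length-`k` prefixes for every size, which makes the
table cheap (one pass of cumulative sums) without changing any per-`k`
marginal distribution. All stochastic stages take explicit seeds; a master
seed fans out to per-stage seeds through a fixed derivation.

## 3. Greedy search with pruning

Search depth is counted in *biological steps*: one step is a
gene → interaction → gene hop, i.e. two edges of the bipartite graph, so the
default depth 2 means candidates within four bipartite hops of the growing
module. This interpretation is a documented choice — depth could also be
counted in raw hops, which on this reified representation would halve the
biological reach.

From every scored seed node the search repeatedly:

1. collects all scored non-members within `2 × depth` hops of the current
   module (breadth-first, through any nodes);
2. evaluates, for each candidate, adopting the candidate **plus its entire
   shortest connecting path**. Unscored path nodes (interaction nodes,
   unmeasured genes, metabolites, complexes) are traversable connectors that
   contribute nothing to `zA` and do not count in `k`; scored path nodes are
   adopted and counted together with the candidate, so a strong gene hiding
   behind a weak one can be reached when the pair jointly raises `sA`;
3. adopts the best strictly-improving move (ties: smallest node id), then
   runs a prune pass: repeatedly drop the scored member whose removal most
   increases `sA` while keeping the module connected, trimming connector
   nodes left dangling.

Growth stops when no move improves the score or the scored-size cap
(`max_module_scored`, default 30) is reached. The prune pass is a
hill-climbing refinement on the same objective — early adoptions can turn
unprofitable once the module has grown past them — and since every move
strictly increases `sA`, the procedure terminates. Candidates from all seeds
are ranked by `sA` (ties: fewer members, then smallest seed id) and the
final list is chosen greedily under the overlap filter: a candidate is
rejected when `|A∩B| / min(|A|,|B|)` against any accepted module exceeds the
threshold (default 0.8, five modules). Jaccard overlap is available by
configuration; the min-denominator form is the default because it also
catches a small module nested inside an accepted large one.

On large networks, seeds already absorbed into an earlier module with at
least their singleton score can be skipped (`skip_absorbed_seeds`): such a
seed's own run could only rediscover territory already explored. This is a
speed-up only; it never lowers the best reported score below any singleton.
Simulated annealing, regional score adjustment, and hub correction are out
of scope.

## 4. Expression mapping

Probe tables carry `probe_id`, `log2fc`, `pvalue`, and optional per-sample
detection flags; probes undetected in every sample (detection p-value 1
throughout, i.e. no evidence the transcript is present at all) are removed
before mapping. Probes map to genes through a plain two-column table; a
probe mapping to several genes contributes to all of them (mirroring how
identifier-mapping frameworks fan out), and unmapped probes are dropped with
a count. When several probes measure one gene, one representative row is
kept: by default the smallest p-value (ties: largest |log2FC|, then probe
id), optionally the largest |log2FC| (ties: smallest p, then probe id). The
min-p default preserves the most significant evidence per gene, which is
what the p-value-driven module score consumes downstream. Merging happens
after statistical testing; the package never refits the upstream model.

Criteria are boolean expressions over `log2FC` and `pvalue` with
`<, >, <=, >=, =`, `AND/OR/NOT` and parentheses, evaluated exactly as
written — strict operators stay strict, so a gene at exactly |log2FC| = 0.58
or p = 0.05 is *not* selected by the default criterion. Genes with missing
statistics never satisfy any criterion.

## 5. Overrepresentation statistics

Gene sets are intersected with the measured background before counting;
unmeasured members are invisible. The Z-score is the standardized deviation
of the changed count from its hypergeometric expectation (mean `nR/N`,
variance `n(R/N)(1−R/N)(1−(n−1)/(N−1))`). When the variance is undefined
(`n = 0`, or `R ∈ {0, N}`) the statistic is a "not evaluable" marker, never
a number. Permutation p-values permute the *changed labels* over the
measured background (not set memberships): all sets share one stream of
`n_perm` random `R`-subsets, and the add-one estimator
`(1 + #{z* ≥ z})/(n_perm + 1)` avoids zero p-values. With 2,000 permutations
the smallest reportable p is ≈ 5·10⁻⁴. Because the permuted statistic is
discrete, its p-values are conservative on small sets; they approach
uniformity (under the null) as set sizes and `R` grow. The filter triple —
Z > 1.96, permuted p < 0.05, at least five changed genes (three in the
lenient screen) — is applied after ranking; no further multiple-testing
correction is layered on top.

## 6. The synthetic benchmark

`generate_collection()` emulates the *shape* of a curated human pathway
collection: a right-skewed interactions-per-pathway distribution
(log-normal, median ≈ 22, mean well above it, minimum 1), a participant mix
dominated by gene products and complexes, an interaction-type census
dominated by directed interactions, a handful of high-degree currency
metabolites attached to a fraction of interactions, and controlled rates of
interactions recurring in a second pathway (`cross_pathway_share_rate`,
default 0.08) or duplicated within their own pathway (default 0.04) — the
two mechanisms that make multi-occurrence and multi-pathway counts differ.
Base interactions are drawn so their canonical keys stay unique even after
currency exclusion, which makes the ground truth exact: the generator knows
every expected merge, provenance set, node, edge and component, and the
network builder's summary must reproduce that bookkeeping identically.

`generate_expression()` plants a connected module of gene products
(connectivity through shared interaction nodes, so it is discoverable at
search depth 2): planted genes get `p ~ Beta(α, 1)` (default α = 0.05;
α = 1 embeds a pure null) and strong fold changes; background genes get
uniform p-values and weak fold changes. Gene statistics fan out to probes —
a gene's probes replicate its statistics exactly, so min-p merging recovers
the drawn gene table and recovery failures can always be attributed to the
search, not the plumbing. Decoy probes exercise the detection filter
(undetected everywhere) and the unmapped drop; a small multi-mapping rate
exercises fan-out (genes receiving a foreign probe are flagged in the ground
truth since their merged statistics may legitimately differ).
`permute_labels()` reassigns the (log2FC, p) pairs to a random permutation
of the gene ids — the statistic multiset survives, network-localized signal
does not — which is the package's negative control: permuted runs must score
below matched planted runs.

What the generator does **not** emulate: microarray intensities and their
noise model (only statistics-level tables are produced), correlated
expression between neighbouring genes, realistic pathway size/topology
beyond the skew of the count distribution, identifier messiness beyond the
decoy rates, and any directionality-aware signal (the search ignores edge
direction, as do the methods it follows). Passing tests therefore show the
pipeline machinery is correct and the search recovers localized p-value
signal at realistic densities — not that real tissue data will yield modules
of any particular size or score.

## 7. Test-suite problem sizes and oracles

The suite checks structural invariants on randomly generated collections
(up to 50 pathways) and verifies the builder against generator bookkeeping
on 200 of them. The overrepresentation Z is checked against hypergeometric
moments obtained by direct enumeration of the probability mass for every
admissible configuration up to N = 30. Permutation-p uniformity under a
null plant uses a ~2,000-gene background, 100 random sets of 150–250 genes
and a criterion selecting ~25% of genes, sizes at which the discrete
permutation lattice is fine enough for a two-sided uniformity check.
Calibration normality uses 10,000 standard-normal node scores and 50,000
calibration draws so that estimated-parameter noise is negligible at the
2,000-draw Kolmogorov–Smirnov comparison. Search quality is checked on tiny
instances (≤ 10 scored nodes) against an exhaustive optimum over connected
scored subsets, with reachability decided by an independent best-improvement
hill-climb simulation using the same add/remove move set; and end-to-end on
20 seeded replicates of a ~900-gene-product network with a planted 15-gene
module, paired with permuted-label controls. The full pipeline is run twice
from one master seed and must produce byte-identical outputs.

## 8. Known limitations

* The search is deterministic hill climbing; it can stop short of the
  score-optimal connected subnetwork when every single improving move is
  blocked (the annealing mode of the original module-finding literature
  trades this for stochastic restarts and is deliberately out of scope).
* The corrected score inherits the usual selection bias of best-of-many
  searches: the top score among hundreds of seeds is far above the
  calibration's per-set null even for label-permuted data. Scores should be
  compared between conditions (e.g. observed vs permuted), not read as
  standalone significance.
* Chance-significant background genes adjacent to a genuine module are
  often absorbed when they raise the score; the prune pass trims the worst
  offenders but cannot remove a gene whose inclusion genuinely increases
  `sA`.
* Interaction directionality is recorded (edge roles) but unused by the
  search and the components/summary logic.
* Identifier namespaces are opaque strings; no resolution or cross-database
  mapping is attempted beyond the supplied probe-to-gene table.
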