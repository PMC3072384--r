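---
title: "Methods: PCA-informative marker panels and hierarchical breed assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCA-informative marker panels and hierarchical breed assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedtrace)
```

# The problem

A reference panel of labelled diploid genotypes — individuals from known
breeds, typed at thousands of biallelic SNPs — is to be distilled into small
marker panels that assign an unknown individual to its breed of origin.
`breedtrace` implements the full workflow: encoding and QC, PCA, marker
ranking, redundancy removal, a hierarchical decision tree, five-nearest-
neighbour assignment, and leave-one-out evaluation, together with a
simulator that generates multi-breed data with a planted hierarchy so that
every stage can be tested end to end.

# Encoding and quality control

Raw calls are pairs of allele characters (PLINK PED/MAP text dialect, `0` =
missing). Per SNP the *minor* allele is the less frequent allele among
non-missing calls — an exact 50/50 tie goes to the lexicographically smaller
character so the encoding is deterministic — and each genotype becomes the
count of that allele (0/1/2, `NA` if missing). Because every column is later
centred, PCA is invariant to which of the two alleles is counted, and to any
per-column affine recoding; nothing downstream depends on the tie direction.

QC removes SNPs whose missing fraction is *strictly* above the threshold
(default 10%, so a SNP missing exactly 10% of calls is retained) and SNPs
monomorphic among the remaining calls: zero-variance columns carry no
structure, receive zero PCA score, and would make frequency-based scalings
degenerate. Samples are never dropped; handling outlying samples is the
caller's decision.

Missing entries are then mean-imputed per column and columns centred.
Mean-imputation is neutral for PCA (an imputed entry sits exactly at the
column centroid) and requires no model of the missingness mechanism beyond
missing-completely-at-random, which is also what the simulator generates.
The column means are stored and reused to impute, centre and project
out-of-sample individuals, so a held-out animal never influences the basis
it is projected onto. One deliberate relaxation: during cross-validation a
*training subset* can become monomorphic at a column that is polymorphic in
the full data; `center_impute()` therefore tolerates zero-variance columns
(they centre to exact zeros and get zero loadings) and errors only on
all-missing columns.

# PCA, marker scores and redundancy removal

For a centred training matrix $A$ (samples × SNPs) with SVD
$A = U \Sigma V^\top$, the package keeps the top-$k$ right singular vectors.
The PCA score of SNP $j$ is its leverage on that subspace,

$$p_j \;=\; \sum_{i=1}^{k} V_{ji}^2, \qquad \sum_j p_j = k ,$$

the squared norm of the SNP's loading row — a measure of how strongly the
SNP correlates with the significant principal components. Scores are
unweighted by the singular values (the standard leverage form); a
variance-weighted variant is available via `pcaim_scores(weighted = TRUE)`
but is off by default. The highest-scoring candidates are retained
(`n_top`, default $\min(2000, \lfloor m/3 \rfloor)$ so the candidate step
scales with the dataset), ties broken by SNP id.

Top-scoring SNPs are heavily redundant wherever markers are correlated
(linkage disequilibrium), so panels are chosen by greedy column subset
selection on the centred candidate submatrix: deterministic column-pivoted
QR (Businger–Golub), selecting at each step the column with the largest
residual norm after projecting out the columns already selected, with
residual-norm ties (relative $10^{-9}$) broken by SNP id. An exact or near
duplicate of a selected marker has (near-)zero residual and is skipped while
independent columns remain. Pivoting on the candidate matrix itself — rather
than on the $k \times n$ loading matrix $V_k^\top$ — is essential: the
residuals of a rank-$k$ matrix vanish after $k$ pivots, so a $V_k^\top$
pivot order is uninformative beyond position $k$, while panels must contain
far more than $k$ markers. Greedy pivoting directly minimises the Frobenius
reconstruction objective that defines the column-subset-selection problem,
and the test suite bounds its error against the exhaustive optimum on small
instances.

Because selection order is a pivot order, truncations are nested: the tiers
P1 ⊂ P2 ⊂ P3 are prefixes, sized `p1_size`, `2*p1_size`, `3*p1_size`
(default 50/100/150) or any explicit non-decreasing sizes such as the small
10/25/50 configuration.

# The decision tree

Rather than separating all breeds at once, breeds are organised into nested
groups: the root distinguishes broad groups, deeper nodes distinguish
progressively closer breeds, and each node gets its own basis and panels.
`build_tree()` either accepts an explicit topology — the bundled
`bovine_tree_topology()` reproduces the 19-breed bovine hierarchy with
`bovine_node_settings()` supplying each node's significant-PC count and
panel sizes — or discovers one recursively:

1. **Significant PCs.** `choose_num_pcs()` returns the smallest candidate
   $k$ maximising leave-one-out 5-NN breed-classification accuracy in the
   first $k$ PCs. Two safeguards matter in practice. First, a candidate is
   only *eligible* if the spectrum has a relative gap
   $(\sigma_k - \sigma_{k+1})/\sigma_1 \ge 2\%$: cutting inside a
   near-degenerate multiplet yields axes that rotate freely under
   resampling, an instability that in-sample coordinates cannot reveal.
   Second, after the node's children are known, an auto-chosen $k$ is
   floored at (children − 1): separating $c$ groups in general position
   needs $c-1$ axes, and a smaller $k$ starves the leverage scores of a
   discriminative direction — observable as panels that perform far below
   the full marker set. Explicit per-node $k$ values are used verbatim.
2. **Grouping breeds.** The node's breeds are partitioned by k-means on the
   training individuals' PC coordinates (seeded, 20 restarts, best
   within-cluster sum of squares); each breed is atomic and joins the
   cluster holding the plurality of its members (ties to the lower cluster
   index). The clustering view uses $\min(\max(k, B-1), 6)$ components for
   $B$ breeds, since the between-breed geometry spans up to $B-1$
   dimensions. The default number of clusters is chosen by a multi-scale
   rule: an average-linkage dendrogram of the breed centroids is cut at the
   largest successive merge-height ratio if that ratio is at least 1.5
   (`gap_ratio`); otherwise there is no coarse structure and every breed
   becomes its own child. A per-individual silhouette criterion was
   rejected here: with tight breed clusters nested inside super-groups it
   always prefers splitting every breed apart, so a planted two-level
   hierarchy would never be recovered. The centroid-dendrogram rule asks
   the right question — is there a scale gap *between breeds*? — and the
   threshold 1.5 sits well below the ratio a genuine two-level design
   produces and well above the near-1 ratios of flat breed layouts.
3. **Recursion** continues until every leaf is a single breed; each
   internal node also gets its candidate set, panels, and per-tier PC bases
   refit on the panel SNPs (a deployed assay measures only panel SNPs, so
   classification uses a basis fit to exactly those markers, not the
   full-SNP basis restricted).

# Assignment and evaluation

An unknown sample descends the tree. At each node it is restricted to the
node's SNP set for the chosen mode (`full`, `candidates`, `P1`–`P3`),
imputed and centred with the node's training means, projected, and assigned
by its five nearest training neighbours (Euclidean distance in the node's
PC space; distance ties broken by sample id): a child group holding at
least three of the five neighbours wins, otherwise the sample is
*unassigned* and the descent stops. Unassigned counts as incorrect in every
statistic — the conservative reading of a majority-only rule. With fewer
than five training samples all of them vote with majority
$\lceil m/2 \rceil$.

`loocv()` runs the complete leave-one-out experiment: for each sample, all
nodes on its root-to-leaf reference path are refit on the remaining samples
(topology fixed; PCA, candidate ranking and panels re-derived from the
training set only, so the held-out animal cannot bias marker selection
toward itself), and two statistics are accumulated per node, mode and
breed: classification accuracy (percent of decisions routing the sample
into the child containing its reference breed, denominators being the
samples whose breed belongs to the node) and the average number of
neighbours from the sample's own breed (0–5). Only path nodes are refit:
off-path nodes contribute nothing to the measured statistics.
`knn_sweep()` repeats the root-level experiment for neighbour counts
3/5/7/9/11 to confirm the vote is insensitive to the exact count.

# The simulator

`simulate_dataset()` draws per-SNP ancestral frequencies uniformly from a
range (default 0.1–0.9), then lets frequencies drift independently down
each branch of a declared hierarchy under the Balding–Nichols model: a
child frequency is $\mathrm{Beta}\!\big(p(1-F)/F,\,(1-p)(1-F)/F\big)$
around its parent's $p$, so $\mathbb{E}[(p'-p)^2] = F\,p(1-p)$ and the
branch parameter is interpretable as the branch's F~ST~. Frequencies are
clamped to $[0.01, 0.99]$ to avoid fixation (genotypically monomorphic
columns can still arise and are handled by QC). Genotypes are
$\mathrm{Binomial}(2, p_\text{breed})$; linkage disequilibrium is emulated
by duplicating a fraction of SNPs (`redundancy_fraction`, default 0.2) with
`redundancy_factor − 1` copies placed beside their source and corrupted
per-entry with probability `redundancy_flip_prob`; missing calls are
Bernoulli, completely at random. Identical seeds give bit-identical
datasets, and `wc_fst()` (a multi-SNP ratio-of-averages Weir–Cockerham
estimator) reports the realised differentiation.

What the simulator does *not* emulate: selection, admixture, pedigree
structure, realistic recombination maps, or informative missingness.
Passing tests on simulated data therefore demonstrates that the algorithms
recover planted drift structure under calibrated noise — not that any
particular accuracy carries over to a real genotyping survey, where LD is
block-structured, sample sizes are unbalanced and label errors exist.

## Study conditions used by the tests

The bundled end-to-end conditions are a two-level hierarchy of six breeds
(between-group F~ST~ 0.15, within-group 0.05 — a strongly differentiated
species-level split over moderately distinct breeds), 40 individuals per
breed, 2,000 base SNPs, 5% missingness, and a fifth of SNPs duplicated
twice over with 5% corruption, with 50/100/150-SNP panels. Replicated
experiments (topology recovery, panel-tier ordering) use ten seeds; the
tier-ordering replicates use a reduced 2×2-breed, 15-per-breed, 800-SNP
version of the same design with 20/40/60-SNP panels so that ten full
leave-one-out runs stay desk-scale. These sizes are the package's chosen
reference conditions; all thresholds in the acceptance tests refer to them.

# Numerical choices

- SVD via LAPACK (`svd()`); deterministic for fixed input. Each singular
  vector's sign is fixed so its largest-magnitude loading is positive —
  distances and squared loadings are sign-invariant, this only makes reruns
  byte-stable.
- `fit_pca()` refuses $k$ beyond the numerical rank (relative tolerance
  $10^{-12}$).
- All order-dependent steps break ties deterministically: score ties and
  pivot ties by SNP id, neighbour-distance ties by sample id, k-means vote
  ties by lower cluster index, vote ties between children by child name.
- The only randomness is the simulator and the k-means restarts; both
  derive from a single seed, and `loocv()` itself is deterministic given
  the tree.
- An all-missing sample projects exactly to the origin (imputation with the
  training means); it will typically be unassigned, never an error.

# Known limitations

- "Unassigned" is not novelty detection; breeds absent from the reference
  cannot be flagged.
- Assignment is categorical — no admixture fractions or posterior
  probabilities.
- The auto-topology rule targets clean multi-scale structure; gradated
  isolation-by-distance patterns without a scale gap will simply yield a
  one-level tree (every breed a direct child of the root), which is valid
  but forfeits the per-node panel economy.
- Binary PLINK (BED) and VCF input are out of scope; the text PED/MAP
  dialect is canonical.
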