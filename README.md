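# breedtrace

Small SNP panels for tracing the breed of origin of individual animals.

Given a labelled reference panel of diploid genotypes (e.g. a multi-breed
cattle survey of tens of thousands of SNPs), `breedtrace` answers two
questions:

1. **Which few hundred markers carry the population structure?** SNPs are
   ranked by their *PCA score* — the leverage of each SNP on the top-*k*
   right-singular subspace of the centred genotype matrix. For the basis
   `A = U Σ Vᵀ` of the sample-by-SNP matrix, the score of SNP *j* is

   p_j = Σ_{i=1..k} V[j,i]² ,  with  Σ_j p_j = k,

   which measures the correlation between the SNP and the significant
   principal components. Because linkage disequilibrium makes top-scoring
   SNPs highly redundant, the best candidates are then passed through a
   greedy column-subset-selection step (column-pivoted QR): markers are
   picked in order of residual norm after projecting out those already
   chosen, so near-duplicates are skipped. Panels come in nested tiers
   P1 ⊂ P2 ⊂ P3 (by default sized 1:2:3).
2. **What breed is this animal?** Breeds are organised into a decision tree
   by recursive clustering along the significant PCs (k-means on the node's
   PC coordinates, with whole breeds as atomic units). An unknown sample
   descends the tree: at each node it is projected onto that node's PC
   basis — restricted to the node's panel — and assigned by majority vote
   (≥ 3) among its five nearest training neighbours, or left "unassigned".

Everything is evaluated by complete leave-one-out cross-validation in which
PCA, candidate ranking and panels are re-derived per fold from the training
set only, reporting per-node classification accuracy and the average number
of correct nearest neighbours (out of five). A Balding–Nichols simulator
with a planted breed hierarchy, per-branch F_ST, missing calls and
LD-redundant marker blocks makes the whole pipeline testable without
external data.

Intended users: animal and conservation geneticists designing genotyping
assays for breed assignment and product traceability, and anyone needing a
reproducible ancestry-informative-marker workflow on PLINK-style text data.

## Worked example

Simulate six breeds in a two-level hierarchy (between-group F_ST 0.15,
within-group 0.05, 40 animals per breed, 2,000 base SNPs, 5% missing calls,
a fifth of SNPs duplicated twice over), run QC, build the tree with
50/100/150-SNP panels, and cross-validate:

```r
library(breedtrace)

spec <- breed_tree_spec(
  nodes = list(taurine = c("Angus", "Hereford", "Holstein"),
               zebu    = c("Brahman", "Gir", "Nelore")),
  branch_fst = c(0.15, 0.05), n_per_breed = 40, n_snps = 2000,
  missing_rate = 0.05, redundancy_factor = 3, redundancy_flip_prob = 0.05,
  seed = 42)
sim  <- simulate_dataset(spec)
gm   <- filter_missing(sim$genotypes)   # drops >10%-missing and monomorphic SNPs
tree <- build_tree(gm, p1_size = 50, seed = 42)
tree
#> breed_tree: 6 breeds, 3 internal nodes, root 'root'
#> - root [k=5]
#>   - Angus+Hereford+Holstein [k=2]
#>     - Angus
#>     - Hereford
#>     - Holstein
#>   - Brahman+Gir+Nelore [k=2]
#>     - Brahman
#>     - Gir
#>     - Nelore

report <- loocv(gm, tree, modes = c("full", "P1", "P3"))
report$per_node[, c("node", "mode", "n", "accuracy", "avg_correct_neighbors")]
#>                     node mode   n  accuracy avg_correct_neighbors
#>                     root full 240 100.00000              5.000000
#>                     root   P1 240  98.75000              4.295833
#>                     root   P3 240 100.00000              4.962500
#>  Angus+Hereford+Holstein full 120 100.00000              5.000000
#>  Angus+Hereford+Holstein   P1 120  92.50000              4.575000
#>  Angus+Hereford+Holstein   P3 120 100.00000              4.941667
#>       Brahman+Gir+Nelore full 120 100.00000              5.000000
#>       Brahman+Gir+Nelore   P1 120  95.83333              4.666667
#>       Brahman+Gir+Nelore   P3 120 100.00000              4.966667
```

The auto-built tree recovers the planted hierarchy exactly. `accuracy` is
the percentage of held-out animals routed to the correct child at that
node; `avg_correct_neighbors` is how many of their five nearest neighbours
came from their own breed. With all ~2,800 post-QC markers every decision
is correct; the 150-SNP P3 panel matches that, and even the 50-SNP P1 panel
stays near 99% at the root — the panels trade a 20-fold marker reduction
for at most a few points of accuracy at the harder, closely related nodes.

Classifying one animal shows the decision path:

```r
classify_sample(tree, gm$values["Angus_003", ], mode = "P3",
                sample_id = "Angus_003")
#> classification_result [Angus_003]: final = Angus
#>   root -> Angus+Hereford+Holstein
#>   Angus+Hereford+Holstein -> Angus
```

File-based runs (PED/MAP + label TSV in, panels/reports out) go through
`run_config()` + `run_simulate()` / `run_build()` / `run_evaluate()` /
`run_classify()`; a thin CLI wrapper lives in `inst/scripts/breedtrace`.
`bovine_tree_topology()` and `bovine_node_settings()` bundle the reference
19-breed bovine decision tree with its per-node significant-PC counts and
panel sizes, for replaying that study design on compatible data.

## Limitations

- Breeds absent from the reference panel cannot be detected ("unassigned"
  only means no ≥3-of-5 majority, not "novel breed").
- No admixture fractions: assignment is categorical by design.
- The simulator emulates drift, missingness and LD-redundancy, not
  selection, pedigree structure or realistic recombination maps; see the
  methods vignette for what passing its tests does and does not establish.
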