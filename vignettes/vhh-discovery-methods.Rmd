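---
title: "Methods: repertoire mining, generative design and developability triage for VHH discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire mining, generative design and developability triage for VHH discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Display selections (for example yeast surface display sorted by FACS)
turn an immune VHH repertoire into a series of sequence pools, each round
enriched for antigen binders. Deep sequencing of those pools yields, for
every CDR1/CDR2/CDR3 triplet, a read count per round. `vhhmine`
implements the downstream discovery workflow on such tables: it groups
sequences into CDR3 families, quantifies which families the sorting
enriched, learns a per-family generative model of the enriched sequence
space, proposes new CDR combinations, filters them by sequence-level
developability surrogates, and nominates a small panel (at most ten per
family) for synthesis.

Because the intended library design keeps the framework fixed and
humanised, all information lives in the CDRs; the package therefore
works on CDR triplets throughout and treats the framework as an optional
annotation (used only for human-likeness scoring and pI).

# Clustering by CDR3 identity

Pairwise CDR3 identity is defined as the number of identical aligned
positions under a global alignment (match 1, mismatch 0, linear gap -1),
divided by the length of the longer sequence. Among score-optimal
alignments, the traceback with the most identical positions is used, so
the value is a deterministic function of the pair. Dividing by the
longer length penalises length mismatch, which is the conservative
convention for CDR3 loops where an indel usually implies a different
binding mode.

Clustering is greedy, abundance-ordered centroid clustering in the
CD-HIT style: candidates are visited in descending total read count
(ties broken lexicographically on CDR3, then CDR1/CDR2), each joins the
first centroid at identity at or above the threshold (default 0.5) or
founds a new cluster. The procedure is deterministic, scales linearly in
the number of centroids, and seeds clusters on dominant clones, which is
what a practitioner does when reading a frequency-ranked NGS table. The
0.5 default mirrors the common assumption that families above 50% CDR3
identity share an epitope while remaining diverse enough for
sequence-activity analysis.

# Enrichment statistics

The cluster-level enrichment factor between a baseline round (reads
$n_0$ of $t_0$) and a selected round (reads $n_s$ of $t_s$) is the
pseudocount-stabilised fold change

$$\mathrm{EF} = \frac{(n_s + 1)/(t_s + 1)}{(n_0 + 1)/(t_0 + 1)},$$

reported either unrounded or rounded to the nearest integer (the
conventional printed form). The +1 pseudocounts keep the ratio finite
for clusters unseen in the baseline pool — exactly the rare-but-rising
binders that enrichment ranking exists to surface — at the cost of a
strong dependence on single baseline reads, which is why the package
always reports the baseline counts next to the EF.

Per-residue matrices are computed per cluster and region over the
sequences whose region length equals the count-weighted modal length;
other lengths are excluded and the excluded weight fraction is reported
in the matrix attributes. This keeps column positions fixed without a
per-cluster multiple alignment, which is out of scope. Frequency-mode
matrices are count-weighted and row-stochastic; enrichment-mode matrices
are $(f_\text{sel} + \varepsilon)/(f_\text{base} + \varepsilon)$ with
the default pseudocount $\varepsilon$ equal to one over the smaller
round's total reads. There is no canonical published definition for the
per-residue ratio, so this one is declared here: it is symmetric (so
swapping rounds inverts the matrix entrywise), always positive, and
shrinks ratios supported by few reads.

# The generative model

Each progressed cluster gets its own character-level LSTM over the
concatenated CDR1-3 residues, bracketed by start/end tokens in a
23-token vocabulary (20 amino acids + start + end + pad), one-hot
encoded. The architecture is two stacked LSTM layers of 64 units with
0.2 dropout applied to each layer's output during training, trained for
up to 200 epochs; the reported epoch is the argmin of the mean
validation loss over a five-fold cross-validation split of the unique
sequences, and the returned model is refit on all data for that many
epochs. Training examples are weighted by read count, realised as
in-epoch replication: a sequence with count $c$ appears
$\min(c, \text{cap})$ times (cap 100) with residual weight
$c/\text{replications}$, so the objective equals training on every
redundant read while the epoch size stays bounded.

The optimiser is this implementation's own numerical choice: Adam
(learning rate 0.03, batch 4, global gradient-norm clip 5), with a
bias-corrected exponential moving average of the weights (decay 0.997)
as the reported parameters. The EMA deserves a note: at the small model
and data sizes used here, the last-iterate weights carry substantial
minibatch noise and slightly sharpen the learned distribution; averaging
the trajectory removes most of that variance and makes sampled residue
frequencies track the training distribution much more closely. All
randomness — initialisation, fold assignment, shuffling, dropout masks
and sampling — draws from R's RNG, so results are bit-reproducible from
the config seed. A cosine learning-rate schedule is available but off by
default: the constant rate lets the model keep sharpening when a cluster
really is dominated by one clone.

Sampling is autoregressive from the start token with softmax temperature
(default 1, the reference behaviour; a near-zero temperature reduces to
greedy argmax decoding). Emitted sequences whose total length is not
among the training lengths are discarded and redrawn, up to a total-draw
budget of twenty times the requested count, after which a warning
reports the shortfall. CDR boundaries are re-imposed from the cluster's
count-weighted modal CDR1/CDR2 lengths, which the fixed library design
makes constant within a cluster.

A sequence $x_1 \ldots x_K$ is scored by its negative log-likelihood

$$\mathrm{NLL} = -\sum_{k=1}^{K} \ln p(x_k \mid x_{<k}),$$

including the end token by default, with probabilities floored at
$10^{-12}$ so the score is always finite. Lower NLL means more typical
of the FACS-enriched pool; it is not a binding-affinity predictor, but
within a sorted pool it is a pragmatic prioritisation score. The union
of training and sampled sequences is deduplicated on the CDR triplet
(the NGS provenance label wins) and ranked ascending.

Cross-validation with a single fold (`cv_folds = 1`) is supported and
skips epoch selection; it exists for degenerate-data settings such as
single-sequence overfitting checks, where a validation split is not
meaningful.

# Developability surrogates

The structure-based components of an industrial developability pipeline
(3D model building, aggregation-surface scores, positive-patch
energies) are replaced by declared sequence-level surrogates that
preserve the filtering role:

* **Liability scanning** flags every CDR Asn (deamidation), Asp
  (isomerisation), Met (oxidation) and Cys (unpaired cysteine), plus
  N-X-S/T sequons with X not Pro. Severity is `high` for NG, DG, any
  Met, any Cys and sequons; `moderate` for N{S,T,N,D,H} and D{S,T,D};
  `low` otherwise. Low-tier motifs are flagged rather than ignored
  because non-canonical motifs (for example Asn-Tyr) can still
  deamidate measurably; the tiers are configurable.
* **Isoelectric point** solves the Henderson–Hasselbalch net-charge
  equation (N/C termini plus D, E, C, Y, H, K, R side chains, EMBOSS
  pKa values shipped as a data file) by bisection on pH 0–14 to 1e-4.
* **Hydropathy** is the maximum over sliding windows (default width 5,
  within each CDR independently) of the mean Kyte–Doolittle residue
  value; a CDR shorter than the window contributes its full-length
  mean.
* **Positive charge** is the count of Arg + Lys (+0.1 per His) across
  the CDRs.
* **Human-likeness** is percent identical positions between framework
  and germline over the alignment length of the same global alignment
  used for clustering.

Traffic lights compare a descriptor against a user-supplied reference
set (mean and SD per descriptor): green within one SD above the mean,
yellow within two, red beyond. Both lit descriptors (hydropathy,
positive charge) are "low is good"; pI is reported but never lit,
because it is used as a diversity axis, not a cutoff. The reference
set itself (for example a panel of marketed antibodies) is not shipped;
the pipeline can instead derive reference statistics from the NGS
sequences of the progressed clusters, which makes the lights and
cutoffs relative to the campaign's own sequence space.

# Candidate selection

Selection is a deterministic greedy fill over the NLL-ranked, profiled
pool, stopping at `max_per_cluster` (default 10): first at least three
passing sequences from the top 100 ranks; then the passing sequences
nearest each NLL spread anchor (by default the terciles of the passing
pool's NLL range, or explicit anchor values from the config); then
coverage of empty pI bins (default boundaries 6.5/7.5/8.5); then a
variant free of any soft liability category carried by the panel; then
a top-off with the best remaining ranks; finally, if one provenance
(NGS vs sampled) is absent, the best passing sequence of the missing
source is swapped in. Sequences failing a hard descriptor cutoff are
excluded with a machine-readable reason, and an all-failing pool yields
an empty selection rather than an error.

The four nomination criteria have no inherent total priority order; the
order above is this package's declared convention, chosen so that
earlier steps never depend on later ones.
One subtlety is recorded here deliberately: with pool-derived tercile
anchors, removing the highest-NLL non-selected candidate can move the
anchors and thus the spread picks. With explicit `nll_spread_points`
the selection depends only on the chosen set and per-candidate values,
and is provably independent of irrelevant alternatives; the property
test exercises that mode.

# The synthetic campaign

The simulator generates the study conditions for every end-to-end
check. Each cluster is a position weight matrix (PWM) triple built
from a random consensus with 10% per-position diversity spread over two
alternative residues — matching the strong per-position conservation
seen in real FACS-round-2 clusters — with CDR lengths 10/8/18 and
mutually sub-threshold (<50% identical) CDR3 consensus sequences.
Round 0 draws reads i.i.d. from the cluster PWMs; each subsequent round
resamples multinomially with weight proportional to
`count * exp(fitness)`, fitness being the cluster's base fitness plus
optional per-position residue bonuses. This log-linear model is the
simplest mechanism producing the monotone enrichment the EF statistic
is designed to detect. Default scale is 4 clusters, 10,000 reads per
round and two sorting rounds, with base fitness (1.5, 1.0, 0.5, 0):
ordered strongly enough that enrichment ranking recovers it, while
every cluster keeps a deep round-2 read count, as progressed clusters
do in real campaigns.

What the simulator does **not** emulate: sequencing error, PCR
amplification bias, nucleotide-level effects, chimeras, and
cross-cluster recombination. Passing the synthetic checks therefore
demonstrates the statistical machinery under clean clonal structure,
not robustness to platform noise.

Validation scales (the package's own choices, also used by the test
suite and the acceptance script): generative parameter recovery uses a
single length-20 PWM cluster, 1,000 training sequences, a reduced model
(32 units, 30 epochs, 5 folds) and 2,000 samples; memorisation uses one
sequence at count 100 without cross-validation; enrichment recovery
uses 20 seeded replicates at 50,000 reads per round; the bundled
demonstration pipeline (`inst/extdata/demo_run.yaml`) runs 10,000 reads
per round with a 32-unit, 12-epoch, 3-fold model and 600 samples per
cluster.

# Numerical and degenerate-input choices

* Identity ties in the alignment are resolved by maximising matches at
  optimal score; alignment length is then fully determined, so both
  identity and human-likeness are deterministic.
* Greedy clustering ties (equal counts) break lexicographically.
* EF inputs with cluster reads exceeding round totals are errors, not
  warnings.
* Positional matrices refuse empty member sets after length filtering.
* The NLL probability floor ($10^{-12}$) bounds any single-token
  contribution at about 27.6 nats.
* pI of a sequence with no ionisable side chains is defined by the
  termini alone; bisection tolerance is 1e-4 pH.
* Sampling rejects sequences outside the training length set; if the
  retry budget is exhausted the result is partial plus a warning, never
  silent truncation.
* Progressed clusters with fewer unique training sequences than
  `min_cluster_size` (default 25) or than the number of CV folds skip
  the generative stage and are listed in the run manifest.

# Known limitations

* The NLL is relative to a per-cluster model; scores are not comparable
  across clusters, which is why ranking and selection are per cluster.
* Read counts are used as given; the upstream normalisation applied by
  commercial annotation platforms is not reconstructed, so EF values on
  re-exported tables may differ from a vendor's.
* The sequence-level developability surrogates correlate with, but do
  not reproduce, structure-based scores; they are tie-breakers and
  guard-rails, not predictions of biophysical assays.
* Greedy centroid clustering depends on abundance ordering; pathological
  chains of 40-60% identities can split or merge families that a graph
  clustering would treat differently. The threshold and the full
  identity matrix are exposed so users can audit such cases.
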