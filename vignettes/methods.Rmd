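---
title: "A multiscale stochastic model of epigenetic stem-cell aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale stochastic model of epigenetic stem-cell aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidrift)
```

## What the model describes

`epidrift` simulates how a population of stem cells ages epigenetically.
Each cell carries the same artificial genome but evolves its own
regulatory state across three coupled layers:

1. **Transcription.** Expression of gene $i$ follows
   $\mathrm{d}e_i/\mathrm{d}t = P_{\max}\,\theta_{Pro,i}\,\Theta_i - \delta e_i$,
   integrated with an explicit Euler step. $\theta_{Pro,i}$ is the
   thermodynamic polymerase-II occupancy of the promoter, computed from the
   transcription-factor network of the artificial genome, and $\Theta_i$
   is the binding probability of the protein complex that carries the
   H3K4 histone methyltransferase.
2. **Histone modification.** Each gene owns $N_H = \lfloor L/200 \rfloor$
   cooperative nucleosomes. Over one step, every unmodified nucleosome
   gains the H3K4me3 mark with probability $k_M \Theta \Delta t$ and every
   modified one loses it with probability $k_D \Delta t$. The feedback
   enters through
   $\Theta = \big(1 + e^{\varepsilon_0 - w_{BS}\varepsilon_{BS} - (n_{HM}/N_H)\,\varepsilon_{HM}}\big)^{-1}$:
   existing marks recruit more writer complex, and so does unmethylated
   DNA ($w_{BS}$, the fraction of unmethylated CpG-analog sites).
3. **DNA methylation.** CpG states change at replication only. A
   methylated site survives with the maintenance probability $D_{main}$;
   an unmethylated one is methylated de novo with probability
   $D_{novo} = D_{novo}^{0}\, e^{-\varepsilon_{methyl}\, n_{HM}/N_H}$ —
   the H3K4me3 mark repels the de novo methyltransferase.

At division the mother's modified nucleosomes are distributed binomially
between the daughters and the vacated positions are filled with fresh
unmodified histones. This dilution transiently weakens the mark, opening
the window in which de novo methylation can act; methylation in turn
weakens recruitment, which stabilises the unmodified state. That
replication-coupled ratchet *is* the aging mechanism: it converts active
genes into stably silenced ones, one division at a time.

On top sits a two-compartment population: a niche $\alpha$ where cells
are quiescent and a proliferative compartment $\Omega$ where they divide
(rate $R$) and differentiate out of the system (rate $q_0 N_\Omega$).
Cells leave the niche with probability $\rho_\alpha N_\alpha$ (crowding
pushes them out) and home back with probability $\rho_\Omega / N_\Omega$
(constant total inflow). An age-related phenotype (ARP) switches on
whenever the mean transcription of three designated bistable marker genes
drops below the threshold $TS$; it is re-evaluated every step, so
phenotype switching is reversible. Scenario presets modify aged cells'
differentiation rate ($q_0/3$), proliferation rate ($4R/5$) or niche
affinity ($\rho_\Omega \times 4$, $\rho_\alpha \times 0.25$; the
hematopoietic-stem-cell scenario).

## The artificial genome

Real sequence is unnecessary: the genome is a random string over the
four-digit alphabet `0123`. Genes open at occurrences of the promoter
motif and extend a uniformly drawn length, truncated at the next
promoter. We use a six-digit promoter motif (`010101`). With a four-digit
motif the expected inter-promoter gap in a random digit string is 256
bases, so truncation would essentially eliminate genes longer than 1400
bases; the six-digit motif (mean gap 4096) preserves the whole
nucleosome-count spectrum, including the nucleosome-free genes below 200
bases (class C3) and the eight-plus-nucleosome genes that act as aging
markers. CpG-analog sites are occurrences of `23` inside the gene;
the regulatory region of a gene is its own interval. Each gene encodes a
transcription factor whose binding motif is the digit complement of the
gene's 8-digit prefix; sites matching with at most one mismatch create
signed interactions (the digit after the site sets activation versus
repression). Everything is reproducible from the integer seed, and the
genome round-trips through a FASTA-like sequence file plus a GFF3-style
annotation table.

## Where the parameters come from and what they do

All chromatin defaults are artifact-defined (no measured values exist for
an artificial genome); they were fixed once by the master-equation scans
in `tools/tune_defaults.R` and are not tuned per analysis. The decisive
property is *which states of the histone chain are stable at which
methylation level*:

* At $w_{BS} = 1$ (unmethylated DNA) every chain with $N_H \ge 4$ is
  monostable high: the escape time of a fully modified eight-nucleosome
  gene exceeds $10^9$ steps, while recovery from complete demodification
  takes under $10^2$ steps. Without DNA methylation, silencing is
  transient — this is why knocking out de novo methylation
  ($D_{novo}^0 = 0$) abolishes the aged phenotype entirely.
* At the silenced-state unmethylated fraction
  $w^* = 1 - D_{novo}^0/(1 - D_{main} + D_{novo}^0) = 0.4$, the
  eight-nucleosome chain is bimodal: the silenced basin dominates
  (escape to the active state takes $\sim 10^6$ steps — rare spontaneous
  rejuvenation), while chains with six or fewer nucleosomes are
  monostable low, which is why silencing of the smaller C2 genes is
  irreversible. Bistability therefore depends jointly on the cooperative
  nucleosome number and on the methylation state of the DNA, and the
  package's bimodality flag is evaluated at $w^*$.

The **bimodality flag** of `histone_stationary_distribution()` requires
two local maxima *and* at least 10% of stationary probability in the
minor basin. In this rate family, vestigial local maxima carrying
$10^{-3}$ or less of the mass appear generically; a mode with negligible
mass is not bistability in any operational sense, so the flag uses a
mass floor. The stationary law itself is computed exactly from the
transition matrix of the per-step update. Because several nucleosomes can
flip within one $\Delta t$, that chain generalises the single-jump
birth–death chain with rates $k_M \Theta(n) (N_H - n)$ and $k_D n$; the
two laws coincide as $\Delta t \to 0$ (the test suite checks this
limit), and for feedback-free energies the exact law reduces to the
independent-site binomial.

$\varepsilon_{methyl} = 0.75$ places the division-coupled methylation
creep equilibrium near $w \approx 0.5$. There the committor of the
post-replication half-diluted state into the silenced basin — the step
that actually commits a gene to silencing — is the rate-limiting step of
aging, and it depends strongly on $k_M$ (fall probabilities 0.23 / 0.11 /
0.06 at $0.6 k_M$, $k_M$, $1.4 k_M$ around $w \approx 0.4$–$0.5$). This
is what makes aging speed sensitive to the histone methyltransferase
rate. With much stronger protection the creep stalls above the fall
regime and $k_M$ sensitivity disappears; with much weaker protection the
aged phenotype fixes too fast to observe the long coexistence of young
and aged cells.

The expression scale separates cleanly: an active marker transcribes at
$\sim 1.2 \times 10^3$, an unmethylated transiently silenced one at
$\sim 8$, and a methylated silenced one at $\sim 0.07$ — only the last is
below the phenotype threshold $TS = 2$, so the aged phenotype requires
DNA methylation both kinetically and transcriptionally.

Population defaults put the stationary compartments at
$N_\alpha^* = \sqrt{\rho_\Omega/\rho_\alpha} = 10$ and
$N_\Omega^* = R/q_0 = 10$, with $R = 0.005$ so that one generation is
about 200 steps. These sizes keep every scenario cheap enough to run
thousands of times while still exhibiting the population-level phenomena;
they are deliberately far below tissue scale (see the limitations below).

## Numerical and design choices

* **Division hazard.** Division progress advances by unit jumps with
  probability $R\,\Delta t$, i.e. a memoryless hazard with geometric
  inter-division times of mean $1/R$. A near-deterministic generation
  clock (small-increment accumulators) was rejected because a newborn
  must then survive a full generation before dividing, which shifts the
  stochastic stationary size of the proliferative compartment to
  $\ln 2 \cdot R/q_0$ and starves the niche inflow; the memoryless hazard
  reproduces the mean-field logistic exactly.
* **Update order** per step: intracellular dynamics, phenotype
  evaluation, niche exits, niche entries, divisions, differentiation;
  compartment counts are recomputed between stages. Niche crowding and
  differentiation crowding use total counts across phenotypes (aged cells
  accumulating in the niche raise everyone's exit pressure — the
  mechanism by which the aged HSC phenotype activates young cells); the
  constant-inflow term is phenotype-specific.
* **One RNG stream per run**, seeded once, with a fixed update order:
  runs are bit-reproducible from the configuration and seed.
* **Methylation bookkeeping.** The population engine stores per-gene
  methylated-site *counts*; CpGs of one gene are exchangeable under the
  replication kernel, so counts are a sufficient statistic. The
  single-cell API keeps the full boolean vector; the suite checks the two
  kernels agree in distribution.
* **Phenotype evaluation** is continuous (every step) with a strict
  inequality at the threshold; marker means exactly at $TS$ are young.
* **Degenerate genes.** Nucleosome-free genes (C3) are fully permissive
  for transcription ($\Theta \equiv 1$) and report zero histone and DNA
  methylation levels; genes without CpGs have no methyltransferase DNA
  binding sites ($w_{BS} = 0$).

## What the generator emulates — and what it does not

The synthetic genome and the reduced-scale population reproduce the
*mechanistic* content of the model: gene classes set by cooperative
nucleosome number ($C3 < 1 \le C2 \le 6 < C1$, with the bistable C1a
aging markers inside C1), niche protection from methylation drift,
neutral clonal competition, phenotype selection and the
histone-methyltransferase sensitivity of aging. They do not emulate real
genome architecture (no CpG islands, no position-weight-matrix binding,
no chromatin domains), real tissue scale, or absolute physical time.
Passing tests therefore demonstrate the internal consistency of the
mechanism at desk scale, not quantitative agreement with any measured
stem-cell system.

Two reduced-scale effects deserve explicit mention because they shape the
package's own validation targets:

* **Clone-count decay.** With $\sim 20$ cells, the ensemble-mean clone
  count follows the coalescent $A(t) \approx 1 + 2 N_e \tau / t$: it
  decays to the *absorbing monoclonal floor* of one clone, which a
  log–log fit of raw counts mistakes for a flattening of the power law.
  The faithful desk-scale estimator fits $\log(A - 1)$ — the clone count
  in excess of the absorbing state — once surviving clones are much fewer
  than cells (count below one third of the stationary population), on
  log-spaced points. `fit_clone_decay()` defaults reproduce the plain
  rule; the `survivor_floor`, `min_count` and `n_bins` arguments select
  the reduced-scale form, which recovers exponents within a few percent
  of $-1$ on exact synthetic laws and on simulated ensembles.
* **Mean-field agreement.** The stochastic stationary size of the
  proliferative compartment sits about two cells below $R/q_0$
  (demographic noise enters the quadratic differentiation term), so
  quantitative agreement with the closed forms is checked at
  $R/q_0 \ge 25$ where the relative bias is small; at the default size 10
  the deficit is a real finite-size effect, not an integration error.
* **Interindividual variance.** The across-individual variance of
  stem-cell numbers under heterogeneous $k_M$ exceeds the
  homogeneous-cohort variance in expectation, but at this scale the
  margin is comparable to demographic noise. The informative readout is
  the *niche* count: the proliferative compartment's stationary size
  $R/q_0$ does not depend on the aging rate, so individual differences
  in aging speed materialise as differences in niche filling, while
  total counts dilute that signal with a $k_M$-independent component.
  The sweep reads counts averaged over the final tenth of the run,
  mid-transition, with a balanced multiplier assignment, and the
  comparison replicates independent cohort pairs.

## Worked example

```{r example, eval = FALSE}
library(epidrift)

genome <- generate_genome(seed = 1)
traj <- run_scenario(genome, preset = "hsc", steps = 14000,
                     record_every = 100, seed = 1, n0 = 20)

glance(traj)                       # headline outcomes of the run
classify_genes(traj)$classes       # C1/C1a/C2/C3 per gene
autoplot(traj)                     # compartment occupancy over time
plot_gene_states(traj)             # gene-state heatmap
```

Scenario presets: `no-arp-isolated` (drift without exchange),
`no-arp-exchange` (neutral clonal competition), `low-differentiation`
(dominant ARP), `low-proliferation` (recessive ARP), `hsc` (niche-affinity
ARP). `sensitivity_sweep()` runs cohorts over $k_M$ multipliers;
`load_config()`/`run_config()` and the `inst/cli/epidrift.R` script expose
the same machinery for YAML-driven batch use.

## Known limitations

* Only H3K4me3 is modelled; other marks (H3K9me3, acetylation) and
  hemimethylated CpG states are out of scope.
* Cells do not interact except through compartment counts; there is no
  spatial niche geometry.
* Stem-cell pool exhaustion is not simulated.
* The thermodynamic promoter model is a monotone single-layer occupancy
  form, not a full statistical-weight enumeration over binding
  configurations.
* All problem sizes (20–60 cells, $10^4$–$2 \times 10^4$ steps,
  $\sim 30$ genes) were chosen so that every scenario, test and
  validation runs in seconds to a few minutes; conclusions at tissue
  scale require rescaling.
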