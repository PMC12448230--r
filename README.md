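# haplomix

Direct inference of haplotypes from aligned long sequencing reads.

A K-ploid genome — or bulk sequencing of a cell mixture — carries K
haplotypes: whole consensus sequences that differ from the reference by
substitutions, insertions and deletions. The usual route reconstructs them
in two stages (call variants, then phase them), which discards the
variant-calling uncertainty exactly where long-read error rates make it
matter most. `haplomix` instead fits a single probabilistic model to the
aligned reads, modelling **every** sequenced position, and infers the K
consensus haplotypes, the read-to-haplotype assignment and the sequencing
error profile jointly. It is aimed at people phasing polyploid organisms,
tumor/normal mixtures, or low-coverage long-read panels, and at
methodologists who want a transparent, fully simulated testbed for
read-based phasing.

## Model

A two-stage generative model, indexed against a reference `r` of length
`L0`:

* **Evolution stage** — each consensus `C_k` evolves independently from
  `r`: per position no-mutation / substitution / deletion with
  probabilities `(γ_k1, γ_k2, γ_k3)`, per gap an insertion with
  probability `β_k`:

  `P(C_k | r) = (1−β_k)^(L0−1−N_k) β_k^N_k ∏_j γ_kj^n_kj`

* **Sequencing stage** — a read `R_i` from `C_k` (mixture weight `α_k`)
  covering `[s_i, e_i]` emits each position correctly (`p1`), mismatched
  (`p2`), or as the start of a deletion segment (`p3`, with
  `p1+p2+p3 = 1`); each gap starts an insertion segment with probability
  `p4`. Indel segment lengths are shifted Poisson:
  `L − 1 ~ Poi(λ_del)` or `Poi(λ_ins)`.

The model is fitted by a **Classification Annealing EM** (CAEM): annealed
responsibilities `∝ (α_k P(R_i|C_k,ψ))^(1/T)`, stochastic classification
while `T > 1` cooling geometrically to a deterministic
classification-EM at `T = 1`, and closed-form M-step updates plus an
exact-guarded coordinate update of the consensus sequences. Ploidy is
chosen by five-fold cross-validated **MECR** (minimum error correction
ratio); phasing accuracy against a known truth is scored by **CPR**
(correct phasing ratio) under the optimal one-to-one haplotype matching.
SNV calls fall out of the inferred haplotypes as a byproduct (VCF 4.2).

The matching read simulator (error-level presets, evolution presets,
structural-variant injection, full truth bookkeeping) ships in the
package; see the methods vignette (`vignettes/haplomix-methods.Rmd`) for
the model details, parameter defaults and design decisions.

## Worked example

Simulate a diploid dataset at the Level-1 long-read error profile
(mismatch 1.30%, insertion 0.087%, deletion 0.34%), fit K = 2, and
evaluate against the simulated truth:

```r
library(haplomix)
set.seed(20)
ref <- ReferenceSequence("toy", paste(sample(c("A","C","G","T"), 2000,
                                             TRUE), collapse = ""))
cfg <- SimulationConfig(K = 2, nReads = 80,
                        evolution = evolutionPreset(2),
                        weights = weightsPreset(2),
                        profile = errorProfilePreset(1),
                        readLength = readLengthModel(medianLength = 800,
                                                     min = 400),
                        seed = 42)
ds <- simulateDataset(ref, cfg)
fit <- runCAEM(datasetReads(ds), ref, K = 2, FitConfig(nRestarts = 2, seed = 1))
fit
#> HaplotypeFit: K=2, n=80 reads, objective=-7526.27, converged (restart 1)
stateProfile(fit@state)
#> SequencingErrorProfile: p1=0.984265 p2=0.0139261 p3=0.00180859
#>   p4=0.000572367 lambdaIns=1.24 lambdaDel=1.01
evaluateHaplotypes(fittedHaplotypes(fit), ref,
                   trueHaps = datasetHaplotypes(ds),
                   reads = datasetReads(ds))
#> EvaluationResult: CPR=1 MECR=0.01753 matching=(2,1)
head(callSnvs(fittedHaplotypes(fit), ref)[, 1:5])
#>    pos ref alt class genotype
#> 1  451   T   G   snv      1|0
#> 2  520   A   G   snv      1|0
#> 3 1049   C   A   snv      0|1
```

Reading the output: the fit converged with the haplotype labels swapped
relative to the truth (`matching=(2,1)` — labels are arbitrary), every
true SNV allele was recovered (`CPR=1`), the residual read-vs-haplotype
inconsistency `MECR=0.0175` sits at the irreducible Level-1 error floor,
and the recovered mismatch probability `p2 = 0.0139` is close to the
generating 0.013. The SNV table lists each substitution with its phased
per-haplotype genotype (`1|0` = carried by haplotype 1).

The same workflows are scriptable from a shell via the bundled CLI
(`simulate`, `infer`, `evaluate`, `select-k`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/haplomix.R", package = "haplomix"))')
Rscript "$CLI" infer --reference ref.fasta --reads reads.bam --K 2 \
        --out-dir out/ --seed 1
```

which writes `haplotypes.fasta` (+ per-position state TSV),
`assignments.tsv`, `snvs.vcf`, `fit.json` and a provenance record.

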