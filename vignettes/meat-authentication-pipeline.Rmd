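---
title: "Meat authentication from 16S amplicon sequencing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meat authentication from 16S amplicon sequencing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meatID)
```

## The problem and the estimator

Processed meat products are routinely adulterated with cheaper species,
and once meat is minced or dried the species cannot be identified by
eye. Metabarcoding answers this without guessing a suspect species: a
single degenerate primer pair amplifies a 186-bp fragment of the
mitochondrial 16S rRNA gene across mammals and birds, the amplicons are
sequenced (MiSeq, 2×300 bp paired-end), and the reads are aligned to a
panel of complete mitochondrial genomes.

The quantity on which everything downstream rests is coverage-based,
not read-count-based. For reference $r$ of length $L_r$ receiving
$B_r$ aligned read bases, the average fold coverage is
$\mathrm{avg\_fold}_r = B_r / L_r$; the composition of a sample is each
genus's share of the summed average fold,
$$\mathrm{pct}(g) = 100 \cdot \frac{\sum_{r \in g}
\mathrm{avg\_fold}_r}{\sum_{r} \mathrm{avg\_fold}_r}.$$
Normalising by reference length makes genomes of unequal length
comparable; aggregating to genus level absorbs the fact that
mitochondrial references within a genus are often too similar for
reliable species-level assignment of a 186-bp fragment. The wording
that defines this statistic in surveillance practice is ambiguous about
whether breadth of coverage enters the numerator; this package fixes
the interpretation as the fold-share above, the only reading under
which per-genus percentages sum to ~100 as reported per sample.
Genera with exactly zero fold are omitted, so normalising over all
references and over covered references coincide.

Decision rules on top of the composition:

* **contaminated** — the top genus percentage is *strictly* below 98.
  The strictness matters at the boundary: a sample at 97.9 is called
  contaminated, one at exactly 98.0 is not. Comparisons use full
  precision; one-decimal display is cosmetic.
* **trace vs substantive** — non-dominant genera below 2% are treated
  as cross-contamination or reference-database artefacts rather than
  substitution; at or above 2% they are substantive.
* **mislabelled** — the declared species' genus is not the dominant
  genus. This flag is deliberately independent of contamination: a
  declared-beef sample that is 99% *Sus* is mislabelled but clean
  under the purity rule, and conflating the two would hide exactly the
  fraud case of interest.

## Statistics

Contamination incidence in a group of $n$ samples with $k$ contaminated
is tested with the Pearson chi-square proportion test against a null
proportion $p_0$,
$$\chi^2 = \frac{n\,(k/n - p_0)^2}{p_0 (1 - p_0)}, \qquad df = 1,$$
with the p-value from the upper tail. Two choices here are fixed by
arithmetic rather than taste: **no continuity correction** (with Yates'
correction, $k=1, n=18$ gives $p \approx 4\times10^{-4}$, while the
published value $1.62\times10^{-4}$ is exactly the uncorrected
statistic $\chi^2 = 14.22$) and **$p_0 = 0.5$**, the only null under
which every published p-value reproduces. Group-by-status tables use
the ordinary Pearson $r \times c$ test with Cramér's V,
$V = \sqrt{\chi^2 / (n \min(r-1, c-1))}$. Far-tail p-values (down to
$10^{-18}$ here) come from the regularized incomplete gamma function
via `pchisq(lower.tail = FALSE)`, which is accurate in that regime; the
suite cross-checks it against the closed forms
$\mathrm{sf}(x, 2) = e^{-x/2}$ and
$\mathrm{sf}(x, 1) = 2(1 - \Phi(\sqrt{x}))$.

The published 95% interval for V comes from an unstated method, so the
package makes its own choice and documents it: a nonparametric
bootstrap resampling the $n$ individual (group, status) observations
with replacement, 10,000 resamples under a fixed seed, percentile
interval. Degenerate resamples (an empty margin) score $V = 0$. This CI
is a package design decision, not a reproduction target.

Composition accuracy is summarised by percentage deviations
(expected − observed, sign preserved) and their descriptive statistics.
The mean is taken over absolute deviations; minimum, maximum, median,
standard deviation (sample, $n-1$) and variance are computed on the
absolute scale as well, which keeps variance = sd² internally
consistent. Where the enumerated worked examples of the original survey
disagree with their own summary counts (a "seven contaminated" list of
eight; a 33%-clean category whose test statistic implies six of
twenty-one contaminated), the counts consistent with the published
p-values are used, because those are the values the statistics can
actually be validated against.

## What the simulator emulates — and what it does not

`generate_panel()` builds the reference side: each record is a
2,000-bp stand-in for a complete mitochondrial genome (long enough to
exercise length normalisation, short enough for exhaustive-alignment
oracles) containing exactly one amplicon — forward primer site, 146-bp
variable insert, reverse-complemented reverse primer site — at a random
position. Inserts evolve from a common root with per-base substitution
divergence 0.15 between genera and 0.02 within (typical 16S-scale
separations: congeneric mitochondrial sequences are a few percent
apart, confamilial ones tens of percent). Primer sites are never
mutated, matching the premise of universal primers; the degenerate R
of the reverse primer is resolved alternately to A and G across
records so in-silico PCR must handle both. The default panel has nine
genera, one species each: the nine pure-control meats (pork, beef,
mutton, chevon, chicken, turkey, ostrich, duck, kangaroo).

`simulate_sample()` draws each pair's source reference multinomially at
the design proportions — DNA proportion is equated with read
proportion. Real amplification is biased (the survey this package
emulates saw a 50:50 beef:kangaroo mixture read as 73:25), but no bias
model is published, so the default is unbiased with an optional
per-species efficiency multiplier for sensitivity experiments. Reads
are 300 cycles: the full 186-bp product, then the opposing Nextera
adapter tail (read-through, since the insert is shorter than the
read), then random filler. Substitution errors are i.i.d. per base
(default 0.001; MiSeq-like, no indels); quality decays linearly in
expectation from Q38 to Q25 over 300 cycles with Gaussian noise
(sd 3), clamped to [2, 40].

Consequently, a passing simulation shows that the *pipeline machinery*
— PCR site finding, trimming, assignment, normalisation, calling,
testing — is correct and deterministic. It does not show robustness to
amplification bias, chimeras, indel errors, degraded DNA or an
incomplete reference database, none of which the generator produces.
In particular the large published composition deviations (means around
14%) arise from amplification chemistry the simulator deliberately
does not assert; the error-free emulation recovers designs to within
multinomial sampling error (deviations under 1%), and the published
deviation *magnitudes* are therefore out of reproduction scope, while
their summary *semantics* (absolute scale, variance = sd²) are tested.

## QC and assignment choices

The published pipeline ran BBDuk/BBMap with unstated parameters; this
package re-implements the required behaviour with explicit, exposed
defaults:

* **Adapter trimming** — right-trim at the leftmost exact k-mer match
  (k = 21) against the read-through adapters (the reverse-complemented
  Nextera tails). Right-trim-only is correct for amplicon read-through,
  where adapters always appear 3' of the insert.
* **Quality trimming** — Mott-style: remove the 3' suffix maximising
  $\sum (20 - Q_i)$; ties keep the longer read, a non-positive best
  score keeps the read whole. This is idempotent (the suffix scores of
  a trimmed read are all non-positive by optimality).
* **Length filter** — drop whole pairs when either mate falls below
  50 bases, preserving pair integrity.
* **Assignment** — each pair goes to the single best reference by the
  sum of per-mate Smith–Waterman local scores (match +1, mismatch −1,
  gap of length L scores −2 − L), both pair orientations tried, mates
  required to agree on the reference. Pairs under 0.6 of the maximum
  attainable score stay unassigned and are counted, never dropped
  silently. Ties break to the lexicographically smallest accession so
  reruns are identical. Seeding is a k-mer shortlist (k = 15) over the
  references; an exhaustive mode aligns against every reference and is
  used in the tests to prove the shortlist never changes an
  assignment. Identical pairs are collapsed before alignment, which is
  what makes error-free amplicon batches (thousands of copies of a few
  distinct sequences) fast.

Degenerate inputs have defined behaviour throughout: empty read sets
round-trip as empty FASTQ files, a sample in which nothing aligns
yields a failed profile and a failed call with no flags, an empty
design list yields a valid empty manifest, and a reference with no
primer-site pair is reported non-amplifiable rather than erroring.

## Problem sizes and determinism

The shipped verification runs use the full validation layout — 9 pure
meats × 2 replicates and 13 two-species mixtures × 3 replicates, at
10,000 pairs per sample, error-free — which recovers every design to
within three multinomial standard errors and reproduces the 100%
mixed / 0% pure contamination split; oracle-equivalence fixtures use
up to 50 pairs × 10 references so full-matrix dynamic programming
remains cheap. Every stochastic step (panel, simulation, bootstrap)
takes an explicit seed, per-sample seeds are derived from the master
seed, and reruns with the same configuration are byte-identical.

## Known limitations

* Genus is the terminal reporting unit; true species-level claims
  would need longer markers or multi-locus panels.
* No amplification-bias model is asserted by default; quantitative
  accuracy claims transfer to real data only qualitatively.
* The aligner is a best-hit assigner, not a full mapper: no fractional
  multi-mapping, no SAM/BAM output, no splice or indel-rich modelling.
* The retail arm of the survey (per-sample compositions of 152
  products) is not reconstructible from published information; its
  statistics are reproduced from the published counts, not from reads.
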