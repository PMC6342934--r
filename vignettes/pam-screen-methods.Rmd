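---
title: "Models and methods behind pamscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pamscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamscreen)
```

`pamscreen` implements the computational side of a nuclease
characterization campaign: PAM discovery from a bacterial
plasmid-depletion screen, edit-outcome quantification from amplicon
sequencing, closed-form gel quantitation of cleavage and nicking, and PAM
site surveys. This vignette explains the models each module assumes, the
defaults and why they are set where they are, and what the synthetic-data
generator can and cannot establish about real screens.

## The depletion-screen generative model

A plasmid library carries a randomized 8-base region immediately 5' of a
fixed 31-nt protospacer (`FNPSP1`). In a host expressing an active
nuclease, a plasmid whose PAM supports cleavage is destroyed and its
carrier killed; sequencing the surviving library against an empty-vector
control turns nuclease activity into k-mer depletion.

`nuclease_pam_model()` parameterizes the selective pressure as an 8 x 4
matrix of per-position, per-base activity factors in [0, 1]; the activity
of a PAM is the **product** over positions, and a plasmid is eliminated
with probability `depletion_strength * activity(pam)`. The multiplicative
form is the simplest model that is monotone in every position, yields
clean 0/1 indicator models via `pam_model_from_iupac()`, and makes
"recoverable ground truth" well defined. Additive or epistatic activity
models are deliberately out of scope.

Defaults and their reasoning:

* `n_plasmids = 1e6`. The randomized region spans 4^8 = 65,536 sequences;
  a pool of 1e6 transformants covers it about 15-fold. Real screens aim
  for considerably more, but 15x already separates selection from
  drop-out noise at desk scale; a pool near or below the library
  complexity (say 1e5, 1.5x) would confound depletion with random
  absence, and no experimentalist would accept it.
* `reads_per_sample = 1e5`, i.e. roughly 24 reads per condensed 6-mer.
* `seq_error_rate = 0.001` per base, substitutions only — typical Illumina
  scale. Indel sequencing errors are off by design: they would shift the
  randomized window relative to the anchor and make the extraction-stage
  truth ambiguous. This is a simulator simplification, not a claim about
  sequencers.
* Read layout `upstream_pad (20) + PAM (8) + anchor (31) + downstream_pad
  (16)` = 75 nt, matching a 75-cycle kit. The pad sequences are arbitrary
  constants: the true plasmid backbone context is not modeled.
* The sample library is resampled **with replacement** from the surviving
  plasmids, emulating overnight outgrowth after transformation; the
  control is resampled from the full pool. Replicates draw independent
  pools (independent transformations).

Every simulator consumes one master seed and fans it out to fixed
per-stage streams with `fan_seed(seed, stage)` (a multiplicative
congruential map into [1, 2^31 - 2]); stages are numbered per simulator
(pool, selection, read sampling, errors; replicate r uses stage
`1000 + r`). Adding a stage therefore never perturbs another stage's
draws, and identical configurations are byte-identical across runs.

## PAM extraction

Reads are anchored on the protospacer with a substitution-only sliding
scan (`locate_anchor()`, default tolerance 1 mismatch, leftmost hit on
ties). Gapped matching is deliberately unsupported: the PAM window is
defined by its fixed offset 5' of the anchor, and an indel between window
and anchor would make the extracted 8-mer meaningless. Windows that are
truncated or contain non-ACGT characters are dropped from `valid_reads`
(there is no quality model to arbitrate them; read-filter conventions
vary between screens, so the rule here is declared, not inferred). Reads
are used in the sequenced orientation; `both_strands = TRUE` enables reverse-complement rescue for other library designs.

The screen showed no base preference 7-8 bp upstream of the spacer, so
count tables are condensed to the 6 positions nearest the protospacer
(`condense_pam()` drops the two 5'-most characters). Condensation commutes
with counting — condensed counts equal the 8-mer counts marginalized over
the 16 distal prefixes — and the test suite asserts this identity exactly.

All PAM strings are written 5' to 3' with position -1 adjacent to the
protospacer.

## Depletion scoring and calling

With pseudocount `pc` (default 0.5) and `valid` reads,

```
freq(pam)  = (count(pam) + pc) / (valid + pc * 4^k)
score(pam) = log2(freq_control / freq_sample)
```

There is no community-standard statistic or threshold for depletion
calling, so the defaults here are declared choices: the pseudocounted
log-ratio is the simplest monotone score that stays finite at zero counts (a fully depleted
PAM at 1e5-read depth scores about log2(24.5 / 0.5) ~ 5.6), and the
default call threshold of 2 (4-fold depletion) with the
**all-replicates** rule (score >= threshold in every replicate,
`call_depleted()`) controls the null well: single-replicate read noise at
~24 reads per 6-mer occasionally reaches 4-fold, but rarely twice
independently. The `mean` rule is available for designs with many weak
replicates. The score table covers the union of observed k-mers by
default; `dense = TRUE` expands to all 4^k rows, optional to bound memory
at larger k.

`build_motif()` summarizes a depleted set as a position frequency matrix
(optionally weighted, e.g. by depletion mass), information content
`IC = 2 - H` bits per position, and an IUPAC consensus containing every
base with frequency >= 0.25 (just above uniform background; the
all-uniform limit with frequencies exactly 0.25 reads N). At genuinely
unconstrained positions the sampled frequencies straddle the cutoff, so
the consensus letter there fluctuates between near-degenerate codes — the
IC row, not the letter, is the robust readout. `pam_wheel()` aggregates
counts position by position into the tree that Krona renders; wheels can
be weighted by raw counts or by depletion mass, and both are accepted as
input.

## Amplicon edit calling

`align_read()` is an affine-gap Gotoh alignment, global in the read with
free reference ends (fitting alignment): amplicon reads are routinely
shorter than the reference, and charging terminal gaps would push real
indels around. Scoring defaults are match +2, mismatch -3, gap open -6,
gap extend -1 (a gap of length L costs `open + L * extend`), a
conventional short-read parameterization in which a 1-nt indel (-7) costs
more than a mismatch (-3) but less than two. Among co-optimal alignments
gaps are placed leftmost (5'-most), fixed by the traceback preference for
the diagonal state; indel placement in homopolymers is therefore
deterministic and the test suite verifies it against exhaustive
enumeration. The aligner is validated against an independent
quadratic-time DP on random pairs and against `Biostrings`'s global
aligner on scores.

`classify_read()` applies a fixed precedence: `HDR_PERFECT` (all donor
edits present and the 36-nt HDR window a gap-free exact match to the
donor-edited reference), else `HDR_CONVERTED` (the primary TG-to-CA edit
present; a co-occurring indel is noted but does not change the class, so
conversion and perfect-edit frequencies can be reported separately), else
`INDEL` (nonzero net indel within the cut window), else `WT`. Substitutions outside the HDR window
never change a class, which makes calls robust to sequencing errors. Reads
scoring below half the perfect-match score are `AMBIGUOUS`; reads shorter
than 40 nt are filtered before alignment.

The exact cut position of BhCas12b is not published; the default cut
window is 20 bp over the PAM-distal end of the protospacer (`[77, 97)` on
the bundled 200-nt target), where Cas12 nucleases produce staggered cuts,
and is configurable per target. The bundled `default_amplicon_reference()`
is a **synthetic** stand-in for a genomic target locus — ATTC PAM, 23-nt
protospacer, TG-to-CA conversion at the center of the 36-nt window, plus a
PAM-disrupting donor edit — constructed in code rather than copied from a
genome. The 120-nt donor is the edited reference
restricted to a window centered on the conversion, so its homology arms
match the reference outside the edits by construction.

The amplicon simulator draws each read as WT, single net indel (length
from a configurable distribution, default uniform over 5-15 bp deletions,
placed uniformly inside the cut window), or full donor conversion, then
applies substitution errors. One net indel per read, no mixed outcomes.

## Gel quantitation

The estimator `100 * (1 - sqrt(1 - (b + c)/(a + b + c)))` — implemented in
the algebraically identical form `100 * (1 - sqrt(a / total))` — assumes
the two strands are cut independently with equal probability `p`, so the
undigested fraction is `(1 - p)^2` and the formula returns `100 p`
exactly. `simulate_gel_lanes()` realizes precisely this model
(`a = T(1-p_t)(1-p_nt)`, `b` the singly cut / nicked class, `c` the doubly
cut class, optional truncated Gaussian band noise), and the roundtrip
identity is asserted to 1e-9 over a 101-point grid of `p`. Intensities are
used raw by default, with a constant-offset `background` option in `quantify_lanes()`. Negative
intensities and all-zero lanes are rejected rather than clamped;
`(b + c) / total > 1` cannot arise from valid inputs. Per-strand readouts
from denaturing gels use the plain ratio `100 * cut / (uncut + cut)`
(`strand_fraction_cut()`).

## Site surveys

`scan_sites()` reports every position on either strand where the IUPAC
PAM matches and a full protospacer (default 23 nt) fits immediately 3' of
it. Overlapping sites are all reported — the quantity of interest is the
number of targetable sites, not a tiling. `N` in the subject matches no
pattern code (IUPAC matching is delegated to `Biostrings`, whose
pattern-N-matches-subject-N convention is corrected by post-filtering).
Reverse-strand sites are reported on the forward coordinate axis with a
strand flag. On uniform random sequence the expected ATTN density is
`2 * (1/4)^3 * 1000 = 31.25` sites/kb over both strands, which the test
suite checks within 5% on 1 Mb.

## Coordinates and other conventions

All user-facing coordinates are 0-based half-open (BED-compatible),
converted at the API boundary from R's internal 1-based handling; every
interval in `amplicon_reference()` and `scan_sites()` follows this
convention. Depletion tables sort by decreasing score with ties broken by
PAM string; `call_depleted()` uses an inclusive (`>=`) threshold.

## Problem sizes and what the checks do (and do not) show

The validation suite runs at the generator's default design: 1e6-plasmid
pools, 1e5 reads per library, two replicates for recovery (TTT model,
`depletion_strength` 0.95) and twenty independent null screens for
specificity; 2,000 amplicon reads for rate/length recovery; 500 random
pairs up to 60 nt for the alignment oracle; 1 Mb for site densities. These
sizes were chosen to make the statistical assertions sharp (binomial
error a few tenths of a percent) while remaining desk-scale.

Passing them shows that the pipeline inverts its own generative models —
selection strength into depletion calls, configured outcome mixtures into
rates, strand-independent cutting into cut probabilities. It does not
show robustness to phenomena the generator deliberately omits: PCR and
ligation bias, chimeric reads, quality-score-dependent errors, indel
sequencing errors, paired-end structure, or plasmid fitness effects
unrelated to cleavage. Real-screen defaults (anchor tolerance, call
threshold, cut window) are declared starting points to be reviewed against
each experiment, not fitted values; numerical identity with the output
of other indel callers is not claimed, since that depends on each tool's
read filters and window conventions.
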