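---
title: "Calling and comparing chloroplast C-to-U RNA editing sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing chloroplast C-to-U RNA editing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpedit)
```

## The analysis

In seed-plant plastids, RNA editing is almost exclusively cytidine-to-uridine
conversion: a genomic `C` appears as `T` when the cDNA of the transcript is
sequenced. Given a panel of genomic coding sequences and the matching
transcript sequences, cpedit

1. aligns each transcript globally against its CDS and calls one editing
   site per substitution column (`detect_editing_sites()`);
2. annotates every site with its codon coordinates, codon change, amino-acid
   change and hydropathy-class transition (`classify_codon_change()`);
3. profiles the bases flanking the edited cytidines (`context_profile()`),
   where seed plants show a strong 5'U / 3'A ("U_A") preference;
4. compares observed sites against a prediction tool's list
   (`compare_predicted_sites()`) and across species
   (`shared_site_counts()`);
5. ranks loci for phylogenetic use by parsimony-informative-character
   content and exports concatenated supermatrices (`rank_loci_by_pic()`,
   `concat_supermatrix()`); and
6. screens hydropathy profiles for transmembrane-segment changes between the
   edited and unedited protein forms (`hydropathy_profile()`,
   `call_tm_segments()`).

Every stage takes and returns plain tibbles, so the pieces compose with the
usual tidyverse verbs, and `run_editing_pipeline()` chains them into a
single report object.

## Site calling and coordinates

Transcript and CDS are near-identical — a handful of edited bases and,
rarely, a sequencing indel — so the aligner is a textbook global
Needleman–Wunsch with affine gaps (Gotoh recursion, in compiled code).
The default scoring is match `+2`, mismatch `-1`, gap open `-5`, gap extend
`-1`; with gaps this expensive, any sensible scheme recovers the same
mismatch set on such inputs, which is why the parameters are exposed but
rarely worth touching. Ties in the traceback prefer diagonal over up over
left, making the output deterministic.

Coordinates are 1-based CDS positions. For a gene with frame offset `f`
(from a GenBank `/codon_start` qualifier), a site at position `p` has codon
index `ceiling((p - f) / 3)` and codon position `((p - f - 1) mod 3) + 1`.
Site labels use the codon-indexed convention `gene_<index><refAA><altAA>`
(e.g. `ndhB_50SL`); `parse_site_name()` additionally accepts the
`gene_S159L` variant and separator-free labels seen in published tables.

Three deliberate behaviours at the edges:

* columns involving `N` never call an edit, and `N` flanks are excluded
  from context tallies;
* substitutions other than C-to-T are kept, typed `U-to-C` or `other`,
  because silently dropping them would hide sequencing problems;
* a substitution in a codon that also contains an indel is reported with a
  `frame_disrupted` flag rather than discarded.

## Consequence classes

The consequence kinds are `silent`, `missense`, `stop_gain`,
`start_gain` (codon 1 `ACG` edited to `ATG`, creating a canonical
initiator), plus `stop_loss`, `stop_retained` and `start_loss_candidate` so
the classification is total over all ordered codon pairs. A premature stop's
cost is `truncation_length(k, L) = L - k + 1` residues.

Published discussions of editing describe residue changes with a
three-class vocabulary (neutral / hydrophilic / hydrophobic) without ever
defining the partition. The default here is

* hydrophobic: A, V, L, I, M, F, W
* hydrophilic: R, K, D, E, N, Q, H, P
* neutral: G, S, T, C, Y

chosen to satisfy the three anchors that the vocabulary fixes — serine
neutral, proline hydrophilic, leucine hydrophobic (the classic S-to-L and
P-to-L edits are "neutral to hydrophobic" and "hydrophilic to hydrophobic")
— while keeping each class chemically coherent. It is a design decision,
not a reconstruction of any published scale, and `property_scheme()` makes
it fully overridable; no quantitative check in this package depends on the
unanchored assignments.

## Context profiling

`context_profile()` reads the genomic strand in coding orientation (the
only convention consistent with calling the edited base a "C") and reports
5', 3' and joint flanking-base frequencies in the RNA alphabet. Sites
within `flank` of a CDS end are excluded from all three tallies and
surfaced in `n_excluded_boundary` — exclusion is conservative and keeps the
joint table's marginals exactly equal to the one-sided tables. Published
per-base percentages for small panels do not always back-divide to integer
counts; this module therefore reports exact fractions and never tries to
reproduce any particular rounding dialect. Percentages elsewhere are
rendered half-up to two decimals, with exact fractions retained in stored
JSON.

`extract_windows()` cuts the roughly 30-nt region thought to be recognised
by PPR editing factors, and `column_information()` measures per-column
Shannon information (bits) over the four bases, gaps excluded — the tool
used to show that nothing outside the edited C itself is conserved.

## Locus selection and the supermatrix

`is_parsimony_informative()` uses the standard rule: at least two states
each present in at least two taxa, with gaps and `N` treated as missing
data rather than a fifth state (configurable). The test suite verifies
this against an exhaustive oracle that scores every column on every
unrooted topology (up to 8 taxa) and asks whether the parsimony score
varies. Loci are selected when PIC/length exceeds 0.3; published usage does
not say whether the cutoff is strict, so strict (`>`) is the default with
an `inclusive` flag. `concat_supermatrix()` gap-fills missing taxa,
records partition boundaries, and exports PHYLIP/NEXUS/FASTA plus a
RAxML-style partition file — model selection and ML/Bayesian inference are
deliberately left to external tools, with `nj_tree()` (NJ on uncorrected
p-distances via ape) provided only as a smoke test.

## Hydropathy proxy for transmembrane changes

The TM module is a transparent heuristic, not an HMM topology predictor:
Kyte–Doolittle hydropathy averaged over a 19-residue window, with maximal
runs above 1.6 of at least 15 residues called as segments — the classic
defaults for this scale. It exists to ask a qualitative question (do
S-to-L-type edits extend or create hydrophobic stretches?) and
`compare_tm_maps()` answers it with an interval diff
(gained/extended/lost/shrunk). Signal peptides are out of scope, and no
attempt is made to match the interval coordinates of dedicated TM
predictors.

## What the generator emulates

`sim_config()` defaults are the study conditions for the synthetic
fixtures: 20 genes of 100–300 codons, 46 planted C-to-U edits, codon
position drawn from (0.1521, 0.8043, 0.0436), 5'U context with probability
0.6521 and 3'A with 0.7391, no reverse edits. Genes are uniform random
sense codons between a single `ATG` and a single stop; edits are placed by
rejection sampling over the pool of eligible cytidines matching the drawn
codon position and context classes, with a hard attempt cap — an
infeasible request fails loudly because silently relaxing the constraints
would corrupt the calibration tests. The 5' and 3'
context classes are drawn independently, so the expected joint U_A
frequency is the product of the marginals (about 48% at the defaults);
real panels show a joint preference slightly above independence, which the
generator deliberately does not model. `simulate_species_sites()` evolves
presence/absence along a tree as a two-state Markov chain, which is the
minimal process reproducing the observation that related species share
more editing sites.

What the generator does *not* emulate, and hence what green tests do not
show about real data: partial editing (Sanger traces give binary calls),
sequencing error, real codon usage and GC content, introns and IR regions,
and any correlation between sites. The recovery tests demonstrate that the
detector is exact on indel-free data; they say nothing about chromatogram
quality.

Problem sizes used by the validation suite were chosen to make sampling
checks sharp at three binomial standard deviations: 50 generator seeds for
recovery, 2,000 planted sites for context calibration (hosted on 400 genes
so that the scarcest demand class — codon-position-2 cytidines with 5'T and
3'A — cannot exhaust), 10,000 sites for the two-leaf Markov check, 1,000
random columns against the parsimony oracle, and 500 random pairs of
length at most 12 against the exhaustive alignment-score enumeration.

## Numerical choices and degenerate inputs

* Percentages are rounded half away from zero ("half-up") to two decimals;
  `base::round()`'s half-to-even would disagree on exact halves.
* Empty site lists give zero counts with `NA` (undefined) percentages, and
  an empty predicted set gives `NA` precision — undefined is never reported
  as zero.
* `align_pair()` rejects empty sequences; `translate()` rejects lengths not
  divisible by 3 unless a trailing partial codon is explicitly allowed.
* The alignment enumeration oracle is exponential by construction and
  refuses sequences longer than 14 nt.
* NJ on identical sequences returns a star-like tree whose branch lengths
  are numerically zero; tiny negative NJ branch lengths are clamped to 0.

## Known limitations

Alignment memory is O(nm), fine for normal plastid CDSs but not for
multi-kilobase outliers such as full-length ycf2 against a distant
transcript; editing *extent* (fractional editing from read counts) is not
modelled; orthologous-site identity across species is by label, so
coordinate remapping between genomes is the caller's responsibility; and
the GenBank reader is a minimal flat-file parser for CDS extraction, not a
general feature-table implementation.
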