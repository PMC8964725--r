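---
title: "pegcraft: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pegcraft: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegcraft)
```

## The problem

A prime editor (PE) is a Cas9 nickase fused to a reverse transcriptase. It
nicks the PAM-carrying strand 3 nt 5' of the PAM, the nicked 3' end anneals
to the primer-binding site (PBS) of the pegRNA, and the reverse
transcriptase copies the reverse-transcription template (RTT) into a 3'
DNA flap that carries the intended edit. Whether that flap is installed
depends heavily on mismatch repair (MMR): a single base-base mismatch in
the heteroduplex is repaired inefficiently, while multi-mismatch or indel
heteroduplexes are resolved efficiently. pegcraft implements two guide
engineering strategies that exploit this:

* **spegRNA** — add one or two *same-sense mutations* (SSMs, synonymous
  substitutions) to the RTT near the intended single-base edit, converting
  the single mismatch into a multi-mismatch heteroduplex without changing
  the encoded protein.
* **apegRNA** — stabilize the sgRNA scaffold's small hairpin, which is
  prone to being melted by the free-swinging 3' extension (RTT + PBS), by
  converting a non-C/G pair at its bottom to a C/G pair. This raises
  intended-indel editing efficiency.

Both strategies engineer different parts of the guide and can be combined
(aspegRNA).

## Coordinates

All reference coordinates are 0-based and half-open. Nick-relative offsets
are 1-based signed integers on the PAM strand: +1 is the first base 3' of
the nick (templated by RTT position 1), −1 the first base 5' of it. RTT
positions are counted with the 3'-terminal base as position 1, so RTT
position *p* templates offset +*p*; this makes edit names such as
`+5G-to-T` and "SSM at position 5" share one coordinate system. The
conversion between the two systems lives in a single boundary function,
`offset_to_ref()`.

## The SSM placement rule

Adding up to four extra substitutions to the RTT improves intended
single-base editing; two substitutions in the same reading frame work
best. Profiling single substitutions across RTT positions 1–9 shows
significant gains only at positions 1, 2, 3, 5 and 6, so the scheme
catalog is `{2,5}, {5}, {3,6}, {6}, {1}`, ordered here by reported median
fold-improvement (1.90, 1.62, 1.41, 1.32, 1.28).

Which of these positions can carry a *synonymous* substitution depends on
the register between the gene's codons and the RTT 3' end, summarized as
an ORF phase. Exactly one of offsets +1..+3 falls on a wobble (codon
position 3) base:

| wobble at | phase | recommended schemes |
|-----------|-------|---------------------|
| +3 (+6, +9) | ORF1 | {3,6}, then {6} |
| +1 (+4, +7) | ORF2 | {1} |
| +2 (+5, +8) | ORF3 | {2,5}, then {5} |

The phase labels are assigned so that each phase's recommended
single-substitution positions are its wobble positions; this
reconstruction from the published position lists is a documented
interpretation, since only the positions themselves are stated in text.

`design_spegrnas()` emits one design per feasible scheme, recommended
schemes first (dual before single). With `extended = TRUE` the remaining
catalog schemes are also tried; these necessarily place substitutions at
codon positions 1 or 2, which only some codons permit (e.g. leucine CTG →
TTG). At most 5 designs are emitted per target and no design carries more
than 4 additional substitutions. For each scheme position the codon is
evaluated on the sequence *already carrying the intended edit*, so an edit
that changes the codon changes which substitutions remain synonymous. The
substitution type is immaterial for efficiency, so the alphabetically
smallest synonymous base (on the PAM strand) is chosen for determinism.

```{r}
ref <- paste0(strrep("A", 17), "GGTGCTAAA", strrep("C", 24))
target <- target_spec(ref, 0, 20, "+", pam_pattern = "NNN")
frame <- reading_frame("+", 17, 0, nchar(ref))
designs <- design_spegrnas(target, edit_spec("substitution", 1, "G", "T"),
                           frame)
designs_table(designs)[, c("name", "scheme", "ssms", "rtt", "pbs")]
```

## The scaffold model and apegRNA variants

The scaffold is carried in the DNA alphabet (T→U only at serialization)
and modelled as a sequence plus an explicit base-pair map per hairpin,
bottom pair first. The default is the canonical 76-nt SpCas9 scaffold; its
3'-side elements (nexus, small hairpin, terminal hairpin) were
reconstructed by Watson–Crick complementarity. The small hairpin is
modelled with its bottom A·G mismatch "pair" included (positions 48/61 of
the default scaffold): the stabilized variant apegRNA-2 replaces the first
non-C/G pair bottom-up with C (5') / G (3'), which is precisely "a C/G
pair at the bottom of the small hairpin", and variants 3–5 walk up the
remaining non-C/G pairs. apegRNA-1 instead inserts one C/G pair below the
bottom pair (length +2). The exact published hairpin coordinates are only
available in supplementary material, so the pair map is a constructor
argument (`scaffold_model()`) rather than a hard-coded truth; the default
map is this package's own reconstruction. Secondary-structure free energy
is deliberately out of scope — stability is handled as explicit base-pair
bookkeeping only.

`design_aspegrna()` combines the apegRNA-2 scaffold with every feasible
SSM scheme; without a reading-frame annotation (e.g. non-coding targets)
it emits the stabilized scaffold alone, with a warning.

## Off-target scanning

`scan_offtargets()` mirrors mismatch-only off-target prediction: every
position on both strands where the PAM pattern matches immediately 3' of
the site and the Hamming distance to the spacer is ≤ 5 (default). PAM
bases are a gate, not counted as mismatches; `N` in the pattern matches
A/C/G/T only, and `N` in the subject never matches. No bulge search is
attempted. The implementation is validated against a brute-force
sliding-window oracle and a strand-symmetry property.

## Outcome quantification

Reads are aligned semi-globally (read global, reference local) by a
compiled affine-gap aligner with match +2, mismatch −4 and gap cost
6 + k for a k-nt gap; reads scoring below half the attainable maximum are
excluded from all denominators. The aligner's scores are verified against
both a pure-R dynamic-programming oracle and an independent pairwise
alignment library. Indels are left-aligned against the reference before
comparison so equivalent placements compare equal.

Two consequences of this scoring are handled explicitly. First, three or
more clustered substitutions — exactly what an SSM scheme adjacent to the
intended edit produces — can be score-preferred as an equal-length
deletion + insertion pair; since such a pair is a multi-nucleotide
substitution in disguise, reads whose only indels are one insertion and
one deletion of equal length within 12 nt are re-called gap-free as
substitutions (`mnv_collapse`, configurable). Second, for an equal-length
read a single-base deletion flanked by identical sequence can be optimally
explained as a substitution after trimming the locally aligned reference;
this is the correct maximum-score behaviour, not a defect.

The frequency definitions:

* **Intended substitution** = reads carrying the intended base(s) and no
  indel ÷ reads covering the edit position. The denominator keeps
  indel-carrying reads, per the quoted counting rule.
* **Intended indel** = reads whose *only* indel is exactly the designed
  one ÷ reads covering the nick ± 1 nt. ("Covering the target site" is
  ambiguous in prose; one definition per edit kind is fixed here.)
* **Unintended indel** = reads with ≥ 1 indel inside the quantification
  window ÷ reads aligned across the whole window. The window runs from
  8 nt upstream of the protospacer to 52 nt downstream of its 3' end —
  8 + 20 + 52 = 80 bp for a 20-nt protospacer, PAM inside the downstream
  span — mirrored for minus-strand targets.
* **Incomplete product** = reads with only SSMs (no intended edit, no
  indel) ÷ covering reads. **Byproduct** = reads whose only event class is
  a scaffold-derived insertion ÷ covering reads.
* **Per-position substitutions**: all 12 substitution types at every
  window position, numerator restricted to indel-free reads, reported only
  at depth ≥ 1000 (configurable).

A scaffold-derived insertion is an insertion within 5 nt of the nick, of
length ≥ 3, matching the reverse complement of the scaffold's 3'-terminal
run of equal length with ≤ 1 mismatch; all three thresholds are
configurable inventions. Such insertions are *excluded* from the
unintended-indel flag: if they counted as unintended indels, a read could
never have scaffold incorporation as its "only" event class and the
byproduct definition would be vacuous. This keeps the outcome classes a
partition, which the round-trip tests rely on.

## The read simulator

`simulate_reads()` emulates an amplicon sequencing run over the outcome
classes `unedited`, `intended_only`, `intended_plus_ssm`, `ssm_only`,
`unintended_indel` (one random 1–3-nt indel inside the window, resampled
if it would mimic the intended indel or a scaffold insertion) and
`scaffold_byproduct` (5-nt scaffold-tail insertion at the nick). Class
counts follow largest-remainder rounding of the requested proportions;
sequencing error is uniform per-base substitution at rate *e* (each
alternative base at *e*/3); qualities are constant Q40; a fixed seed gives
byte-identical FASTQ. It does not model cycle-dependent error profiles,
PCR duplicates, paired ends or strand flipping — so passing round-trip
tests demonstrates the correctness of the counting definitions, not
robustness to real Illumina artefacts. Because the substitution numerator
excludes indel-carrying reads, the expected background rate at unedited
positions is *e*/3 scaled by the indel-free read fraction.

## Statistics

`wilcoxon_signed_rank()` is the one-tailed signed-rank test: zero
differences dropped, mid-ranks for ties, exact tail P(W+ ≥ w) (or ≤, for
"less") via convolution over all 2^m sign assignments when m ≤ 25 and the
absolute differences are tie-free, otherwise a normal approximation with
tie and continuity corrections. The "greater" direction (engineered guide
> regular) is the default. `fold_change()` and `normalize_to_reference()`
implement the frequency ratios used for reporting, with an optional
detection-limit floor for zero controls; `median_iqr()` uses linear
interpolation (type 7). No multiple-testing correction is applied.

## Problem sizes and numerical choices

The validation suite runs at desk scale by choice: randomized design
targets use 240-nt references; round-trip quantification uses 2,000
error-free reads (exact equality) and 50,000 reads at error 0.001
(agreement within binomial confidence bounds); aligner and Wilcoxon
implementations are checked against brute-force oracles on instances small
enough to enumerate (≤ 60-nt alignments, m ≤ 12 sign enumerations).
Deterministic tie-breaks throughout: alphabetically smallest synonymous
base, leftmost indel placement, class-order tie-break in
largest-remainder rounding.

## Known limitations

* Synonymy is evaluated in the reading frame of the edited sequence; for
  frame-shifting intended indels the "codons" downstream of the edit are
  those of the shifted frame.
* PAM-disrupting silent edits, 3' structural motifs (epegRNA), twinPE
  designs and thermodynamic folding are out of scope.
* The off-target scanner is exhaustive, not indexed; it is intended for
  amplicon- to plasmid-scale subjects, not whole genomes.
* Cell-based editing efficiencies are wet-lab measurements and are not
  recomputable here; only the desk-scale arithmetic and definitions are.
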