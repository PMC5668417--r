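---
title: "Detecting intra-family recombination in LTR retrotransposon bursts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intra-family recombination in LTR retrotransposon bursts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(retroburst)
```

## The problem

LTR retrotransposons replicate through an RNA intermediate: a full-length
transcript is packaged into a virus-like particle, reverse-transcribed into a
linear, blunt-ended extrachromosomal DNA (ecDNA) terminated by two identical
LTRs, and integrated back into the host genome with a short target-site
duplication (TSD). Like retroviruses, the particle packages *two* transcripts
("pseudodiploidy"), and the reverse transcriptase can switch templates —
both obligatorily, during the first strand transfer that uses the R-region
homology of the LTR ends, and facultatively, by copy-choice switching inside
the coding sequence. When a stress-activated family mobilises many members at
once, old and young members are co-packaged and the progeny insertions are
pairwise recombinants of the parental members.

`retroburst` implements the computational side of detecting and quantifying
this process from short-read DNA sequencing:

1. assignment of reads to individual family members by perfect matching of
   70-bp *address* sequences;
2. an exhaustive *virtual junction library* of all inter-member
   recombination junctions readable in a read-sized window;
3. two null models quantifying how many junction-positive reads sequencing
   error alone would produce;
4. detection of linear ecDNA from read pairs starting exactly at the blunt
   LTR terminus, with parental classification of each mate;
5. insertion calling from discordant pairs and junction reads, LTR
   reconstruction, parental *painting* of recombinant insertions, and a
   12-point parental contribution score.

Because real burst data are not reproducible on demand, the package ships a
fully seeded synthetic-burst simulator whose ground truth exercises every
stage end to end.

## The synthetic family and burst

`family_config()` describes a family; `onsen_like_family_config()` is the
default 8-member configuration used throughout the tests. Its parameters, and
why they have the values they do:

* **Element architecture** — element 5,500 bp with 220-bp LTRs subdivided
  into U3 (150 bp), R (40 bp) and U5 (30 bp). The element size matches a
  typical heat-activated Ty1/copia element; the LTR proportions were chosen
  so that a 150-bp read starting at the blunt ecDNA terminus covers exactly
  the U3 domain. This mirrors the real geometry in which the two mates of a
  sheared ecDNA fragment fall on opposite sides of the R-region junction,
  which is what makes blunt read pairs informative about recombinant LTRs.
* **LTR identity targets** — `{100, 100, 100, 99, 99, 98, 97, 97}` percent
  identity between the 5' and 3' LTR of each member, i.e. three young,
  potentially autonomous members and five old ones. The generator realises
  each target deterministically (`round((1 - t) * ltr_length)` differing
  positions, placed in pairs), so realised identities are always within 0.5
  percentage points of their targets.
* **Inter-member divergence** — 0.00076 substitutions/bp from the common
  ancestor, i.e. 4 member-specific sites per lineage: one paired cluster
  (two substitutions 20–50 bp apart) and two isolated singletons, all in
  the internal (CDS) region so that every member-private site is
  single-copy (a site inside the LTR would be duplicated in both copies,
  which would disqualify its windows as addresses), with the polymorphic
  regions of all lineages jointly spaced well apart.
  The paired-cluster layout emulates the polymorphism hotspots of real
  families and puts the family in the regime assumed by the closed-form
  error model (see *Calibration of the error null*, below). The two most
  similar young members are generated as a *twin pair* — identical lineages
  separated by exactly one distinguishing substitution — reproducing the
  situation where two members must be counted as a pool and then split.
* **U3 sites** — each young lineage additionally carries one
  member-specific substitution in U3. Old members are distinguishable
  within their LTRs through their aging mutations; young members need an
  LTR-borne marker for blunt-end reads to be assignable at all. U3 is the
  fastest-evolving LTR domain in real elements, so this is where such
  markers belong.
* **Conserved LTR termini** — the outermost 20 bp of every LTR are excluded
  from all mutation processes, reflecting the strongly conserved terminal
  motifs required by the integrase, and guaranteeing the family-shared LTR
  start motif that blunt-end detection relies on.
* **Expression weights** — `{20, 15, 20, 8, 6, 1, 0, 15}` follow the
  qualitative heat-induced ecDNA pattern of such families: young members
  dominate, two mid-aged members contribute, one old member is strongly
  reactivated, one member is transcribed but leaves no ecDNA (weight 0) and
  therefore can never appear among progeny parents.

`simulate_burst()` draws, for every molecule, two co-packaged transcripts
independently in proportion to the weights (drawing the same member twice is
legitimate and produces the single-parent progeny seen in real bursts — with
the default weights about 19% of molecules). With probability
`r_transfer_recomb_prob` (default 0.8) the first strand transfer lands on the
partner transcript, placing a junction at a uniform position inside R;
internal copy-choice switches follow a Poisson process at `switch_rate`
(default 0.2/kb of coding sequence). The two defaults together reproduce the
observed preponderance of R-region junctions with a substantial minority of
CDS junctions, and an overall recombinant fraction of roughly three quarters
of hetero-parental molecules. Both output LTRs are identical copies of the
reconstituted LTR — U3 taken from the 3' LTR of the post-transfer template,
R/U5 from the 5' LTR of the starting template — exactly as the
reverse-transcription mechanism dictates; note that for an old member even a
single-parent molecule is therefore a within-member chimera of its two LTR
copies. Reverse-transcriptase errors are uniform substitutions at
6.25e-5/bp, back-calculated from ten polymorphisms per ~160 kb of new
insertions.

`integrate_ecdna()` plants molecules at host positions well away from the
pre-existing chromosomal copies (1.2 kb margin) and from one another (2 kb),
duplicating `tsd_length` host bases (default 5 bp, typical for Copia-type
integrases; the choice is configurable because real TSD lengths vary).
Insertion points are recorded as 0-based half-open intervals over the
duplicated target site, so `end - start` *is* the TSD length and the 5'- and
3'-side junction coordinates differ by exactly that amount.

`sequence_reads()` fragments every template copy by tiling from its 5'
terminus (fragment length Normal(320, 40) by pipeline default), sequencing
both fragment ends. Tiling makes the terminal fragment of a linear ecDNA
molecule start exactly at position zero, so blunt LTR starts arise with
realistic frequency instead of vanishing probability; for a 100-kb
chromosome the same process is indistinguishable from uniform shearing.
Substitution errors are independent per base (default 1/1060, about one
mismatched read in seven); qualities are placeholders, and indel errors,
quality models and PCR duplicates are deliberately out of scope (the assay
modelled is PCR-free).

## Member assignment by addresses

`derive_addresses()` scans all fixed-length windows (default 70 bp) of every
member and keeps those that occur in exactly one member, on either strand,
as a single copy. Three of them, mutually separated by at least one address
length ("independent regions"), become the member's addresses. Members
without three such regions are resolved as near-identical *groups*: group
addresses occur in all and only the group members, and one
distinguishing-polymorphism address per member allows the pooled count to be
split afterwards (`split_group_counts()`); identical members form an
unsplittable group and are flagged. A read increments an address count iff
the address is an exact substring of the read or its reverse complement —
both strands because DNA-seq is unstranded. The member count is the
arithmetic mean over its three addresses, normalised per million mapped
reads; `ecdna_abundance()` subtracts control from heat normalised counts to
isolate the heat-induced ecDNA signal. Candidate windows occurring in more
than one member are discarded during derivation rather than assigned by
priority, so ties cannot bias counts.

## The virtual junction library

`build_consensus()` collapses the family alignment into a degenerate
pattern: every column where at least one member differs (substitutions or
indels; the gap character is a variant) becomes a wildcard with a
lexicographically ordered variant list. `enumerate_fragments()` slides a
window of 145 bp (5 bp less than the read length, so every read contains six
candidate windows) in steps of one column and emits the full cross-product
of variants at the window's wildcards — all sequences any mosaic of parents
could produce there. Deduplication and a both-strand purge against the
reference genome (which carries a copy of every member) remove every
single-parent window, leaving only fragments diagnostic of recombination.
Gap-containing combinations are re-windowed to exactly 145 real bases by
extending through following non-wildcard columns; combinations with no
unambiguous extension are dropped and counted, and both raw and kept counts
are reported, because the fate of indel-containing combinations is a
genuinely open design point. A per-window combination budget (default 1e6)
turns pathological wildcard density into a clear error naming the window
rather than an out-of-memory failure.

On the default synthetic family the library holds 0.4–1.2 million unique
fragments depending on the seed — the same order as the ~500,000 fragments
the equivalent real-family library contains. `search_junctions()` then
declares a read recombination-positive iff it contains at least one library
fragment exactly, on either strand, counting each read once no matter how
many fragments it carries, and reports the rate per 1000 element-mapping
reads. Exact multi-pattern matching is delegated to Biostrings pattern
dictionaries; the contract is exact substring semantics, the engine is an
implementation detail.

## Error null models and their calibration

Sequencing errors can convert a parental read into one that contains a
junction fragment. Two independent estimates bound this artefact rate.

**Closed form.** `expected_false_recombinants()` evaluates

r_expected = n × ℓ × P_error × P_position × P_base

with defaults n = 1000 element-mapping reads, ℓ = 2 (the minimum number of
polymorphic positions involved in a recombination-like read), P_error =
0.1415 (per-read probability of a single random swap; one mismatch per
1060 bp over 150-bp reads, estimable from data with `estimate_p_error()` as
the non-perfect-matching read fraction), P_position = 0.0066 (1/150) and
P_base = 0.3333 (1/3). The defaults give 0.6225, reported as 0.62 reads per
1000; the function performs no internal rounding.

**Permutation null.** `build_read_universe()` enumerates every 150-bp window
of every member at 1-bp resolution and deduplicates;
`permutation_null()` repeatedly draws reads from this universe with
replacement, mutates each with probability P_error — a single swap at a
uniform position to a uniform alternative base, matching the closed form's
"random nucleotide swap" (a multi-swap Poisson mode exists behind
`mutation_model = "poisson"` for sensitivity analysis) — searches only the
mutated reads against the junction library, and reports the
recombination-read rate per 1000 *drawn* reads. 500 permutations give the
null mean and maximum. With P_error = 0 the null is identically zero,
because unmutated universe reads are parental windows, which the library
purge removed by construction.

**Calibration.** The agreement between the two models is a property of the
family's polymorphism density: a single swap creates a junction-positive
read only at a polymorphic column that has a second, pair-distinguishing
column within the same 145-bp window (otherwise the mosaic equals a parental
window and was purged). The generator's divergence was therefore set so that
a typical read covers about two such "completable" sites — the ℓ = 2 regime
that the closed form's ℓ·P_position = 2/150 parameterisation assumes. Two
second-order effects matter and are worth stating. First, isolated
singleton polymorphisms do *not* create artefacts (their single-swap mosaics
are parental), which is why the generator's singletons are harmless while
its paired clusters and the dense LTR-aging blocks dominate the artefact
rate; the LTR aging block is pinned by the identity targets, and the LTR
length is the lever that sets its total size. Second, the deduplicated
universe over-represents polymorphic regions (conserved windows collapse
across members, polymorphic ones do not), which biases the permutation mean
upward relative to the naive density calculation. Under the shipped
defaults the measured permutation means straddle the closed form — 0.56 to
0.74 per 1000 across seeds versus 0.62 — the same regime as the real-data
comparison the method was built to support. Because the generator models substitutions only,
whereas real inter-member polymorphism is partly indels (at which a
substitution swap cannot create the variant), passing this consistency check
on synthetic data does not certify the absolute artefact rate of any real
family; it certifies that the two estimators agree when the density
assumption holds.

`compare_observed_to_null()` reduces the comparison to the two numbers used
in practice: the ratio of the observed rate to the null mean, and whether
the observation exceeds the null maximum.

## Blunt-end ecDNA read pairs

A linear ecDNA molecule has blunt termini, so sequencing it produces reads
whose first base is the first base of the LTR. `find_blunt_ltr_reads()`
keeps pairs in which one mate starts with the family-shared LTR start motif
(default 20 bp, validated to be shared at configuration time) at offset
zero — reads with even one extra upstream base are chromosomal context and
are excluded. `perfect_pair_filter()` then requires both mates to match some
member exactly, removing sequencing-error artefacts, and
`assign_pair_parents()` computes for each mate the set of compatible
members. Both steps match against each member's *reconstituted ecDNA form*
(`member_ecdna_forms()`), not its genomic copy: a single-parent molecule of
an old member already carries a chimeric LTR (U3 from the member's 3' LTR,
R/U5 from its 5' LTR), so reads spanning that internal boundary would
mismatch both genomic LTR copies — and occasionally match a third member —
if the genomic sequence were the reference. Matching the expected ecDNA
form is what makes "discriminatory implies recombinant" structurally true. Disjoint sets make the pair *discriminatory*: its two LTR
domains demonstrably derive from different members, i.e. the underlying
molecule carries a recombinant LTR. Overlapping sets are
*non-discriminatory* (the overlap size is reported but not further
subdivided). Where a mate covers a polymorphism distinguishing an old
member's 5' from its 3' LTR, the matched LTR end is annotated. The mate
orientation convention is FR: the blunt mate is used as sequenced, the
partner reverse-complemented into element orientation before matching.

Two caveats are deliberate. A read that happens to start exactly at the LTR
start of a *chromosomal* copy is indistinguishable from an ecDNA read at the
read level; with ~30× genomes this affects well under one pair per run but
it is not zero, which is why the simulator-backed tests assert specificity
against molecule-level truth rather than pretending the motif test is
perfect. And a reverse-transcriptase error that converts an informative site
to another member's allele can fabricate a discriminatory pair — an
irreducible biological confounder, excluded from the error-free validation
conditions and visible in default-parameter runs at the expected sub-percent
frequency.

## Insertion mapping, painting and scoring

Insertion calling follows the two-evidence strategy. Reads are mapped to
the element-masked genome with the built-in exact mapper
(`map_reads_exact()`; a text SAM from any external aligner can be ingested
with `read_sam()` instead — the built-in mapper is sufficient and fully
deterministic for error-free synthetic genomes up to ~10 Mb, which is the
package's validation domain). `find_discordant_pairs()` keeps pairs with
exactly one uniquely mapped mate whose partner is unmapped yet carries
element LTR sequence (a 60-bp terminal segment occurring inside a member
LTR, so boundary-spanning mates count, as they would for a local aligner);
`find_junction_reads()` recognises unmapped reads carrying an LTR extremity
motif at an internal offset, trims the element part and exactly re-maps the
genomic residual (minimum 25 bp) on either strand — a minus-strand flank
match means the element integrated in reverse orientation and flips the
junction side. The junction coordinate is the genomic base adjacent to the
element edge.

`call_insertions()` replaces the manual assessment of a human analyst with
explicit, logged filters: evidence clusters (maximum gap 500 bp) must carry
at least 2 discordant anchors and at least 1 junction read per edge; modal
left/right junction coordinates define the call interval (0-based
half-open over the duplicated target site); clusters at pre-existing element
copies are the method's positive controls and are excluded; clusters present
in an identically processed control sample are subtracted. All defaults are
arguments. Under the validation conditions (20 planted insertions, 30×
error-free reads, TSD 5) calling is exact: 100% recall, 100% precision,
and every TSD resolved to the base.

`reconstruct_ltr()` assembles the element-side mates anchored near a call
(plus junction-read element parts) by greedy exact-overlap extension
(minimum overlap 40 bp), seeded at the LTR start motif. Since both LTRs of
an integrated element are identical, the 5'-edge assembly *is* the
element's LTR; on simulated data the reconstruction equals the true
molecule's LTR whenever coverage suffices, and incomplete assemblies are
flagged rather than padded.

`paint_parentage()` compares a sequence position-by-position against all
members and, at every informative position, records the compatible member
set. Within LTR territory a member is compatible if the base matches either
of its LTR copies, because reconstituted LTRs mix the two. Runs of constant
compatible set become intervals tiling the sequence — the full ambiguity is
always reported, matching the practice of drawing several colours in one
area. Positions compatible with no member are novel mutations: excluded
from painting and tabulated by `report_novel_polymorphisms()` (under the
default RT error rate, ~10 per 160 kb of painted insertions). A
minimal-switch parent assignment — fewest parent changes, ties broken by
fewest distinct parents, then lexicographically — is computed by
depth-first search over the optimal paths with an exact backward bound
(enumeration capped at 20,000 optimal paths, deterministic order), and is
verified against exhaustive enumeration in the tests. `contribution_scores()`
finally awards each insertion 12 points split equally among its minimal
parents — 12, 6 or 4 points for one, two or three parents — and accumulates
totals and relative frequencies per member.

## Numerical and design choices

* **Coordinates** — BED-style 0-based half-open externally; 1-based
  inclusive internally and in SAM, converted at the boundary.
* **Determinism** — every stochastic function takes a `seed`; identical
  seeds give byte-identical outputs (FASTQ included). The pipeline manifest
  hashes parameters and outputs so reruns are comparable at a glance.
* **Tie-breaks** — variant lists are sorted; address ties are discarded,
  not prioritised; painting tie-breaks are total, as above.
* **Degenerate inputs** — empty read sets count zero rather than erroring;
  empty alignments, zero coverage, zero-length BED intervals, impossible
  identity targets and over-budget windows raise typed errors naming the
  offender; groups without a distinguishing polymorphism are returned
  unsplit with a flag.
* **Problem sizes** — the shipped validation uses the 8-member family
  (44-kb element content in a 116-kb genome), bursts of 29–40 molecules,
  20 insertions at 30×, and 500-permutation nulls at 2,000 draws across
  three seeds; these sizes were chosen as the smallest at which every
  headline property of the method is measurable with comfortable
  statistical margins.

## Known limitations

* Substitution-only divergence: no indel polymorphism in generated
  families (the junction-library code handles gapped alignments, but the
  simulator never produces them), and no indel sequencing errors.
* The built-in mapper is exact: reads carrying errors are treated as
  unmapped rather than aligned with mismatches. This is the behaviour the
  error-free validation conditions rely on; real data should be aligned
  externally and ingested as SAM.
* Pairwise packaging only: three-parent molecules (observed once in real
  data, plausibly via ecDNA–ecDNA recombination) are not simulated, though
  the painting machinery would represent them faithfully.
* Linear ecDNA only; circular intermediates and 3'-terminal blunt-end
  detection are out of scope.
* Absolute artefact rates on real families depend on their indel content
  and alignment; the synthetic consistency checks validate the machinery,
  not any particular organism's numbers.
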