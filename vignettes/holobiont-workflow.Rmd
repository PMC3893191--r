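---
title: "Dissecting a coral holobiont transcriptome: methods and design notes"
author: "holotome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a coral holobiont transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA extracted from a symbiotic coral colony is a mixture: transcripts of the
cnidarian host and of its intracellular dinoflagellate symbionts
(*Symbiodinium* / zooxanthellae) are sequenced and assembled together. Most
downstream biology — polymorphism rates, gene repertoires, metabolic
complementarity — only makes sense after the assembly is split by organism.
`holotome` implements that split and the analyses hanging off it:

1. **Read QC** — quality trimming, adapter stripping, PCR-duplicate removal,
   pair-length filtering.
2. **Contig QC** — length filtering, ORF-level redundancy removal, assembly
   statistics (N50 etc.).
3. **Binning** — exclusive-hit classification against two reference genomes
   with an e-value cutoff scan, validated by GC-content mixture modelling.
4. **Annotation accounting** — per-source evidence counts and the annotated
   union; reciprocal-best-hit orthology with alignment-coverage filtering.
5. **Polymorphism** — variant filtering and a composite within-colony rate.
6. **Marker typing** — recruitment of ITS-2 reads by exact primer match,
   greedy overlap assembly, panel typing, within-marker variant check.
7. **Pathways** — amino-acid producibility per organism from KEGG Orthology
   (KO) presence, and host–symbiont complementarity classes.

A seeded synthetic-data generator ties the stages together so the entire
workflow is testable offline against known truth.

## The binning model

A contig *hits* a reference genome when any local alignment for it has
e-value at or below the cutoff. With two references this induces four
mutually exclusive bins: `HOST` (hits host only), `SYMBIONT` (symbiont
only), `AMBIGUOUS` (both — retained and labelled rather than silently
dropped, for auditability), `UNASSIGNED` (neither). The cutoff is chosen by
scanning a list (defaults `1e-1` … `1e-10`) and maximising the host-only
count; ties resolve toward the stricter cutoff. The symbiont-only counts
are reported alongside so the alternative maximisation is auditable.

The split is validated independently of any reference: coral exons sit near
40% GC while dinoflagellate exons sit near 50–53%, so contig GC content is
bimodal. `gc_mixture()` fits a k-component univariate Gaussian mixture by
EM. The fit is deterministic: means initialise at evenly spaced quantiles
(25th/75th for k = 2), weights equal, common initial standard deviation;
iteration stops when the log-likelihood gain falls below `1e-8` or after
500 iterations; component standard deviations are floored at `1e-4`, and
hitting the floor flags the fit as degenerate. Components are reported in
ascending mean order. A sanity property ties the two views together: the
mean GC of each bin should match the corresponding mixture component to
within ±0.01.

## Alignment stand-in for synthetic runs

Real data would be aligned with an external nucleotide aligner and ingested
as 12-column tabular hit files (`read_hits()`). So that synthetic runs are
fully self-contained, `native_search()` provides a deliberately simple
seed-and-extend search: exact 11-mer seeding on both strands, ungapped
+1/−2 extension with an x-drop of 20, e-values from the Karlin–Altschul
form E = K·m·n·e^(−λS) with fixed K = 0.41, λ = 0.625. Seeds already
covered by a previous extension on the same diagonal are skipped. It does
no gapped or translated alignment and no low-complexity masking, and is not
a general-purpose aligner; on the error-free synthetic contigs it recovers
essentially perfect full-length hits, which is exactly what the binning
stage needs.

## Read and contig QC rules

The QC stages re-implement one deterministic rule per published threshold
rather than wrapping the original external tools:

* `quality_trim()` — remove the maximal trailing run of bases below Q20
  (per-base 3′ scan; whether the original trim was windowed is not
  documented, so the simplest per-base reading was chosen).
* `strip_adapter()` — truncate at the first full adapter occurrence, else
  at a 3′-anchored adapter prefix of ≥ 8 bp.
* `remove_duplicates()` — collapse pairs identical on both mates (the
  simplest deterministic reading of "possible PCR duplicates").
* `pair_length_filter()` — keep pairs with both mates ≥ 80 bp (inclusive).
* `length_filter()` — keep contigs ≥ 200 bp (inclusive: sub-200-bp
  fragments reflect the library's fragmentation size and are likely
  truncated).
* `dedup_contigs()` — greedy clustering, longest contig first; a contig is
  dropped when its longest six-frame ORF is ≥ 95% identical to a retained
  contig's ORF over the shorter of the two.

Two genuinely open choices in the dedup criterion were resolved as follows.
The identity denominator is the *shorter* ORF (the convention of the
clustering tool family this criterion comes from). And the alignment is
ends-free ("overlap") with penalised internal gaps (gap open 5, extend 2
on unit match/mismatch scores) rather than a fully free-gap global
alignment: with free gaps the identity-over-shorter metric degenerates into
a longest-common-subsequence ratio, and unrelated ORFs of very different
lengths can exceed 0.95 purely by chance, which would collapse valid
contigs. Under the ends-free form a truncated copy of the same ORF still
scores exactly 1.0 while unrelated pairs score near 0. A shared-20-aa-word
prescreen limits the alignments attempted on large inputs; ORFs shorter
than 40 aa skip the prescreen and are aligned directly.

`longest_orf()` takes the longest stop-free translated stretch over all six
frames under the standard genetic code, with no start-codon requirement;
ties break by frame order (+1, +2, +3, −1, −2, −3). Note that reverse
frames compete on equal terms, so the winner need not contain an ATG.

## Polymorphism rate

Variants called on the host bin are filtered with inclusive boundaries:
mapping quality ≥ 25, depth within [10, 200], indels ≤ 5 bp. The rate is

> 100 · (SNP sites + indel base pairs) / assessed base pairs,

rounded half-up to one decimal. Using indel *base pairs* (not indel event
counts) in the numerator is deliberate: it is the formula under which the
published counts (425,728 SNPs, 20,213 indel bp, 44,569,031 nt) reproduce
the published 1.0% exactly. Multi-allelic sites count once; the denominator
is the full length of the host contig set, with no exclusion of
depth-failing positions (the printed arithmetic confirms this reading).

## Marker recruitment, assembly and typing

Reads containing a genotyping primer — forward, reverse, or either reverse
complement — as an exact substring are recruited (the original procedure
used an aligner and then required 100% matches; exact substring search is
equivalent and simpler). `assemble_marker()` is a greedy
overlap-layout-consensus assembler: repeatedly merge the pair of sequences
with the longest exact suffix–prefix overlap ≥ 30 bp, both orientations
considered, contained reads absorbed; since merges require exact overlaps
the column-majority consensus equals the concatenated layout. Merged
fragments are canonicalised to the lexicographically smaller orientation so
the result is independent of read input order; `orient_by_primer()` flips
the final consensus so the forward primer reads forward. An optional
extension pool lets the assembly grow beyond primer-containing reads; the
default is recruited reads only.

`type_marker()` globally aligns the consensus against each panel entry
(unit match/mismatch, gap cost 1) and reports the entry with the most
identical bases as `identical_bp / aligned_bp`; ties break by panel order
and are flagged. `marker_variant_check()` places each read at its
best-matching offset and counts columns carrying two alleles each supported
by at least two reads.

The ITS-2 primer pair used for *Symbiodinium* genotyping is cited, not
printed, in the source study, so the generator ships configurable
placeholder primers with the same role (a 20-mer forward and a 21-mer
reverse flanking the 341-bp marker).

## Amino-acid complementarity

Pathway models are a packaged, editable TSV fixture — one row per
(amino acid, route, step, KO), KOs within a step interchangeable —
following standard KEGG module structure in condensed single-route form;
nothing is fetched at run time. A step is present when the organism's KO
set intersects its enzyme set; a pathway with 1–2 missing steps still
counts as producible (`PRODUCIBLE_WITH_GAPS`), reflecting incomplete
transcriptome sampling; where a model carries alternative routes the
fewest-missing route is taken. Producibility is monotone in KO addition by
construction.

`complementarity()` classifies each amino acid as `BOTH`, `HOST_ONLY`,
`SYMBIONT_ONLY`, `SPLIT` (neither partner alone, but the union of their KO
sets suffices — enzymes split across the symbiosis), or `NEITHER`, and
summarises counts overall and for the eight obligate vertebrate-essential
amino acids (Thr, Val, Met, Leu, Ile, Phe, Lys, Trp; Arg/His flagged
conditionally essential). `SPLIT` is kept distinct from `BOTH` because
union-only producibility is a distinct biological claim (metabolic
cooperation) rather than redundancy. Note a structural consequence of the
tolerance: a pathway with ≤ 2 steps can never be `NOT_PRODUCIBLE` at the
default tolerance, so one- and two-step pathways always classify as
producible; meaningful gap designs therefore operate on pathways at least
three steps longer than the tolerance.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions the package validates
under, chosen once:

| parameter | default | rationale |
|---|---|---|
| `host_gc` / `symbiont_gc` | 0.40 / 0.53 | the two GC modes of a mixed coral–dinoflagellate assembly |
| `genome_len` | 500 kb each | large enough for 1,000 contigs per organism at modest (~2.7×) genomic redundancy |
| `n_host_contigs` + `n_symbiont_contigs` | 1,000 + 1,000 | the 2,000-contig scale at which mixture recovery is specified |
| `contig_len_range` | 150–2,500 bp | spans the 200-bp filter boundary deliberately |
| `het_rate` | 0.010 | 1% composite polymorphism between haplotypes |
| `snp_frac` | 0.955 | SNP share of polymorphic bp; the remainder, 1–5 bp indels, matches the published SNP:indel-bp proportions |
| `read_len` / `insert_len` | 100 / 250 bp | short-read paired-end geometry |
| `n_read_pairs` | 4,000 | enough read space for the QC and marker stages |
| defect fractions | 5% duplicates, 3% adapter, 5% short low-Q tail, 4% long low-Q tail | one deterministic defect class per QC rule |
| `marker_len` | 341 bp | the ITS-2 amplicon length |

Diploidy is exactly two haplotypes per contig (the sequenced colony is one
diploid individual); alternate-haplotype edits are SNPs and 1–5 bp indels
with VCF-style left-anchored representation, placed with guaranteed spacing
so edits never collide. Quality strings are constant Q37 except engineered
Q10 tails, so the Q20 rule acts deterministically. The marker is planted
only in symbiont-origin read space (the primers are symbiont-specific), as
error-free tiles at half-read steps with alternating orientations. The
variant VCF carries simulated DP/MQ fields with small fractions (2% + 2%)
engineered to fail each filter.

The generator does **not** simulate rRNA depletion or normalisation
chemistry, expression-level dynamics, sequencing error, bacterial
contamination, or genuine read mapping (the VCF derives from the truth
table). Passing tests therefore demonstrate the correctness of the rules
and arithmetic on data satisfying their assumptions — not robustness to
base-calling error or mapping artefacts on real libraries, where the
external aligner/caller replaces the synthetic truth path.

Problem sizes used by the shipped analyses and tests — 500-kb genomes,
2,000 contigs, 4,000 read pairs, ~2.6 Mb of assessed sequence for the
polymorphism recovery — were chosen as the smallest scales at which the
specified recoveries (mixture means within ±0.01, rate within ±0.1
percentage points) are comfortably identifiable.

## Numerical conventions

* Percentages print with one decimal, rounded half-up (`round()`'s
  half-even rule would disagree with the published tables).
* N50 uses the cumulative-half convention: sorting contigs longest first,
  N50 is the length at which the running total first reaches half the
  assembly size.
* GC fractions exclude ambiguous bases from numerator and denominator.
* Best hits order by (e-value, −bitscore, subject id); the subject-id
  tie-break makes reciprocal-best-hit output deterministic.
* Subject coverage in `coverage_filter()` unions overlapping alignment
  intervals before summing and applies the threshold strictly
  ("more than 80%").
* A contig counts as hitting a reference on the strength of a single local
  alignment below the cutoff (no score combination across alignments).

## Known limitations

* `native_search()` is ungapped; real-data hit tables should come from a
  full aligner.
* The greedy assembler requires exact overlaps; it is intended for clean,
  high-identity amplicon reconstruction, not general assembly.
* The EM mixture fit is univariate with a fixed quantile initialisation;
  heavily unbalanced mixtures may need k or the initialisation revisited.
* Pathway step lists are condensed summaries; swapping in a richer model
  table is supported through `load_pathway_models(path)`.
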