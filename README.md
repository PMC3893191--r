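# holotome

Dissecting a coral **holobiont** transcriptome — an assembly containing
transcripts from both a coral host and its intracellular dinoflagellate
symbionts (*Symbiodinium* / zooxanthellae) — into its two organismal
components, and running the analyses that depend on that split. The package
is aimed at people working with mixed host–symbiont RNA-seq from symbiotic
cnidarians who need a tested, reproducible implementation of the standard
separation-and-downstream workflow, complete with a truth-labelled
synthetic data generator so every stage can be validated offline.

## What it implements

**Exclusive-hit binning.** A contig *hits* a reference genome when some
local alignment for it has e-value ≤ the cutoff. Against a host and a
symbiont reference this yields four exhaustive, mutually exclusive bins:

    HOST       hits the host reference only
    SYMBIONT   hits the symbiont reference only
    AMBIGUOUS  hits both (retained, labelled)
    UNASSIGNED hits neither

The cutoff is chosen by scanning a list (default 1e-1 … 1e-10) and
maximising the host-only count, ties toward the stricter cutoff. The split
is validated without references by fitting a two-component Gaussian mixture
to contig GC content (coral exons ≈ 40% GC, dinoflagellate exons ≈ 53%):
the fitted component means must match the per-bin GC means.

**Around the split:** native re-implementations of the read-QC rules (Q20
3′ trim, adapter stripping, PCR-duplicate removal, 80-bp pair filter) and
contig-QC rules (≥ 200 bp filter, 95%-amino-acid-identity ORF-level
redundancy removal, N50/assembly statistics); annotation-evidence
accounting across sources; reciprocal-best-hit orthology with
interval-union alignment-coverage filtering (> 80%); the within-colony
polymorphism rate

    rate = 100 · (SNP sites + indel bp) / assessed bp      (one decimal)

after filtering variants at MQ ≥ 25, depth 10–200, indels ≤ 5 bp; ITS-2
marker read recruitment by exact primer match, greedy exact-overlap
assembly, typing against a reference panel, and a within-marker variant
check; and amino-acid biosynthetic complementarity from per-organism KEGG
Orthology (KO) tables, tolerating up to two missing enzymes per pathway,
with the classes BOTH / HOST_ONLY / SYMBIONT_ONLY / SPLIT / NEITHER.

See `vignettes/holobiont-workflow.Rmd` for the full methods account.

## Worked example

The numbered scripts under `analysis/` run the whole study on the synthetic
dataset (seed 1, 2,000 contigs, 4,000 read pairs):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/03_binning.R
```

which prints, among other things:

```
Contigs: 2000 -> 1133 after QC
Selected cutoff: 1e-10

      HOST   SYMBIONT  AMBIGUOUS UNASSIGNED
       563        570          0          0
Accuracy vs truth: 1
GC mixture means: 0.4009 / 0.5294 (weights 0.50 / 0.50)
Published-arithmetic check: host-only 26658 symbiont-only 26627
```

Reading this: of 2,000 simulated contigs, 1,133 survive the length filter
and ORF-level dedup; every survivor is binned, none ambiguously, and every
HOST/SYMBIONT call agrees with the generator's truth table. The GC mixture
recovers the configured genome compositions (0.40 / 0.53) to within a
percentage point of GC. The final line re-runs the binning arithmetic on
the published hit counts (30,446 host hits, 30,415 symbiont hits, 3,788
overlapping, universe 74,997) and reproduces the published bin sizes
exactly. The other stages report, for the same seed:

```
rate 1.0%                        # polymorphism, 2.65 Mbp assessed (05)
Best type C15: 340/341 identical bp; 0 variant columns          (06)
Lys NEITHER · Met SPLIT · Cys,Thr HOST_ONLY · Val,Ile,Leu,Phe,Trp
SYMBIONT_ONLY · 11 amino acids BOTH                             (07)
```

i.e. the configured 1% heterozygosity is recovered, the planted 341-bp
marker is reassembled exactly and typed against the panel at 340/341
identity with no within-marker variation, and the designed pathway gaps are
recovered as the intended complementarity classes.

## Layout

    R/              package implementation (all computation lives here)
    src/            Rcpp seed-and-extend nucleotide search
    inst/extdata/   packaged amino-acid pathway models (TSV)
    analysis/       numbered narrative drivers, one per study stage
    tests/testthat/ unit, property and end-to-end suites with independent
                    oracles (N50, RBH, alignment DP, seed-and-extend)
    scripts/        acceptance.R (see above)
    vignettes/      methods vignette
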