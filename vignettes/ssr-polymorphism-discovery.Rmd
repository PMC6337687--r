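---
title: "In-silico discovery of polymorphic microsatellite markers with ssrpolykit"
author: "ssrpolykit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico discovery of polymorphic microsatellite markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpolykit)
```

## The problem

Microsatellites (simple sequence repeats, SSRs) are tandem arrays of a
1--6 bp motif. Replication slippage changes the number of repeat units
at a locus much faster than point mutation changes the surrounding
sequence, so the *length* of a PCR product spanning the tract is a
cheap, co-dominant, multi-allelic marker. When whole-genome assemblies
of several genotypes of a species are available, the wet-lab screening
step can be replaced by computation: mine repeat tracts in a reference,
design primers in the flanking sequence, amplify every genotype *in
silico*, and keep the loci whose predicted product sizes differ.

`ssrpolykit` implements that pipeline end to end, plus the two
companion screens that decide whether a marker is *usable*: a
cross-species transferability filter and a genic-primer screen that
catches intron-containing amplicons and exon--exon junction primers,
and a simulated gel view of the resulting allele matrix.

## Pipeline model and assumptions

1. **Mining** (`mine_genome`). Perfect tandem runs of primitive 1--6 bp
   units are detected per sequence; a run is reported when its repeat
   count reaches the per-unit-length threshold (defaults 10, 6, 5, 5,
   5, 5 for mono- through hexanucleotides, the conventional MISA-style
   defaults; the thresholds are configurable and should be stated with
   any result, since the convention is not universal). A unit that is a
   whole-number repetition of a shorter unit is never reported, a
   longer-unit tract wholly inside a shorter-unit tract is suppressed,
   tracts never span an ambiguous base, and the motif is reported as
   first encountered at the tract start (no reverse-complement
   collapsing). Tracts separated by at most `max_interrupt` (default
   100 bp) merge into one compound locus, because downstream primer
   design treats the locus as an interval. Coordinates are 1-based
   inclusive throughout the package.

2. **Primer design** (`design_primers`). Candidates are enumerated in
   the 500 bp flanks only --- never overlapping the tract --- so that any
   product-size difference between genotypes reflects tract-length
   variation, which is the mechanism the polymorphism caller assumes.
   Hard filters: length 18--24 bp (optimum 20), melting temperature
   57--63 °C (optimum 60), GC fraction 0.20--0.80, no mononucleotide run
   over 4 bp, no ambiguous base, 3'-anchored self-complementarity at
   most 3 bp. Pairs must produce 100--300 bp with at most 5 °C Tm
   difference, and are ranked by
   `|tm_f - 60| + |tm_r - 60| + 0.5(|len_f - 20| + |len_r - 20|) +
   |tm_f - tm_r|`, ties broken by forward then reverse position; the
   up-to-five returned pairs must have pairwise distinct forward 5'
   ends so they are genuine alternatives (five is the conventional
   set size for bulk SSR panels; some pipelines report four --- the
   count is a parameter, `n_pairs`).

   The default Tm model is the salt-adjusted GC formula
   `Tm = 81.5 + 16.6 log10([Na+]) + 0.41(%GC) - 600/L` at 50 mM
   monovalent cation, reported to 0.1 °C. It is deterministic and
   dependency-free; it systematically differs from nearest-neighbor
   thermodynamics (and hence from Primer3's numbers) by a few degrees,
   which matters only in that the acceptance window moves with it. The
   Wallace rule (`2(A+T) + 4(G+C)`) is available as a cross-check via
   `tm_method = "wallace"`.

3. **In-silico PCR** (`epcr`, `epcr_batch`). A primer anneals where it
   matches the template with at most `max_mismatch` mismatches
   (default 0) and no mismatch in the 3'-terminal `three_prime_seed`
   bases (default 5); `N` never matches. Every forward/reverse
   combination in valid orientation with non-overlapping footprints
   and a product within `[min_product, max_product]` (default: sum of
   primer lengths to 5000 bp) is a hit; the mirror orientation on the
   minus strand is searched symmetrically and coordinate-duplicates
   are removed. Exact matching is the right default for same-species
   re-sequencing panels, where a failed locus almost always reflects
   missing sequence rather than primer-site divergence; raise
   `max_mismatch` for heterologous templates. Note that the engine
   reports *all* size-valid combinations: two copies of a locus on one
   sequence yield two (or, within `max_product`, three) products ---
   exactly the multi-band signal the paralogy screen keys on.

4. **Calling** (`detect_polymorphism`). Per genotype, a locus's allele
   is its single product size; no product is MISSING, several are
   MULTI. A locus is PARALOGOUS as soon as any genotype is MULTI
   (multi-locus amplification corrupts length genotyping, so such loci
   should be discarded before synthesis), POLYMORPHIC when at least two
   single-product genotypes disagree in size, MONOMORPHIC when at
   least two agree unanimously, INSUFFICIENT otherwise. Missing
   genotypes are reported but never create polymorphism. The reference
   participates as genotype zero by default, since the comparison is
   between the reference and the re-sequenced genotypes. Every locus
   receives exactly one status, and the summary counts must add up ---
   this is asserted in code on every report.

5. **Transferability** (`evaluate_transferability`). A marker designed
   in a focal species transfers to a host species when both primers
   find sites and a product of at most 500 bp (configurable) results;
   oversized products are filtered as FILTERED_SIZE and one-primer-only
   situations as FILTERED_ASYMMETRIC. "Asymmetric" is interpreted here
   as exactly one of the two primers matching anywhere on the host
   genome; both-primer matches in invalid orientation or beyond
   `max_product` are reported ABSENT with a note, since orientation
   validity is already the e-PCR engine's concern.

6. **Genic screen** (`evaluate_genic_primers`). For transcript-designed
   primers, the expected size is the product on the transcript. On the
   genome: a larger product means the amplicon contains an intron
   (INTRON_CONTAINING, with the excess in bp); at least one primer with
   no genomic site at all is the signature of an exon--exon junction
   primer (JUNCTION_PRIMER); both primers present but no product within
   `max_product` indicates an oversized intron
   (NO_GENOMIC_PRODUCT_OVERSIZE). The two no-product verdicts are
   deliberately distinguished --- they call for different remedies
   (redesign the primer vs. accept a genomic-size marker).

7. **Gel view** (`render_gel`). Band migration is linear in
   log10(fragment size) between the render bounds (25--500 bp by
   default, with a 25--450 bp ladder mimicking common capillary sizing
   markers): `migration = well_offset + lane_height (log10 s_max -
   log10 s) / (log10 s_max - log10 s_min)`. This is the standard
   agarose approximation; it is strictly monotone, which is the only
   property downstream interpretation relies on, and no attempt is
   made to match any particular instrument's pixel output. The SVG is
   deterministic text and a band table is written alongside it, so
   images are diffable in tests.

## What the synthetic fixtures emulate --- and what they do not

`generate_reference` builds a uniform-random background that is
*scrubbed* of incidental threshold-meeting tandem runs, then plants
perfect tracts (default motif pool of common di- to tetranucleotide
plant SSR motifs, 8--15 reference repeats) at least ~1 kb apart with
boundary bases forced so no tract can be extended or phase-shifted
across its edges; a final verify-and-repair mining pass guarantees the
planted table is exactly the genome's mineable locus set.
`generate_genotypes` resizes each tract by a signed per-genotype
repeat-count delta (uniform on -3..+3 by default, truncated at the
mining threshold), optionally knocks out cells by a single substitution
at a rank-1 primer's 3'-terminal base (null alleles), and can sprinkle
substitution SNPs outside the 500 bp flank windows. Duplicated loci are
planted as exact cassette copies (tract plus both flanks), so the same
primer pair amplifies both sites in every genotype. Null alleles are
never assigned to duplicated loci: a one-copy knockout would leave a
single product and silently mask the paralogy signal, making the truth
table ambiguous.

This gives exact, known expectations: an intact locus's allele sizes
differ by exactly `unit length x delta`; nulled cells are MISSING;
duplicated loci are PARALOGOUS. `truth_expected_calls` derives these by
arithmetic on the truth table alone and `compare_to_truth` counts
agreements with the pipeline output.

What the generator does **not** emulate: indels or structural variation
outside the tracts (so observed size differences are purely
repeat-driven by construction), primer-site divergence (SNPs are
excluded from flanks so exact-match e-PCR is valid by construction; a
switch can inject flank SNPs to exercise mismatch-tolerant mode),
sequencing error, diploid heterozygosity (templates are haploid
assemblies), and imperfect/interrupted repeats. Passing recovery tests
therefore demonstrates the pipeline's internal correctness, not its
robustness to assembly artifacts in real re-sequencing data.

## Numerical and design choices

* Default seeds drive every source of randomness in the generator
  through one integer; two calls with the same seed are byte-identical.
* The interplay of `n_pairs` ranking is deterministic: penalty, then
  forward start, then reverse start. `penalty == 0` if and only if
  both primers sit exactly at the optimum length and Tm.
* Degenerate inputs: empty FASTA, missing headers, duplicate ids,
  non-IUPAC residues, unsorted or mixed-sequence tract lists, and
  out-of-bounds loci each raise a distinct error; a locus with
  undesignable flanks yields an empty primer set with a recorded
  reason rather than an error.
* IUPAC ambiguity codes other than N are normalized to N (real
  assemblies contain them; the pipeline treats them as unmatchable).
* Problem sizes used by the shipped checks: oracle equivalence runs on
  100 random 10 kb sequences (mining) and 10 random 100 kb genomes
  (e-PCR); the end-to-end recovery panel is a 1 Mb reference with 50
  planted loci, 4 genotypes, 5% null alleles and 2 duplicated loci;
  the primer round-trip check covers 100 loci on a 200 kb reference.
  These sizes exercise every code path while keeping a full run in the
  minutes range on one core.

## Worked example

```{r example}
gen <- generate_reference(n_loci = 8, genome_len = 40000, seed = 11,
                          n_duplicated = 1)
out <- generate_genotypes(gen$records, gen$truth, n_genotypes = 3,
                          null_rate = 0.1, seed = 11)
res <- run_polymorphism_pipeline(gen$records, out$genotypes)
res$report
head(res$report$matrix)
compare_to_truth(res, out$truth)[c("status_concordance",
                                   "cell_concordance")]
```

```{r gel, eval = FALSE}
render_gel(res$report, gel_params(), "gel.svg")
```

## Known limitations

* Length polymorphism only: sequence-level variation between
  equal-length alleles is invisible, as it is to any sizing assay.
* No thermodynamic annealing model: mismatch counting with a 3' seed
  approximates, but does not reproduce, hybridization energetics; no
  hairpin/dimer free-energy computation is attempted.
* Haploid templates: one allele per genotype per locus. Multi-band
  lanes indicate paralogy, never heterozygosity.
* Circular templates and gapped (indel) primer matching are not
  supported.
* The mining thresholds that define "a microsatellite" are a
  convention; results are only comparable across studies that state
  them.
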