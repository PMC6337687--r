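# ssrpolykit

In-silico discovery of polymorphic microsatellite (SSR) markers from
whole-genome or transcriptome FASTA.

Microsatellites are tandem arrays of 1–6 bp motifs whose repeat count
mutates by replication slippage, so a PCR product spanning the tract is
a cheap co-dominant length marker. Given a reference assembly and
re-sequenced genotypes of the same species (or a related one),
`ssrpolykit` automates the whole marker-development loop that would
otherwise need library construction and wet-lab screening:

1. **mine** perfect and compound SSR loci (MISA-style thresholds:
   ≥10/6/5/5/5/5 repeats for mono- to hexanucleotide units, compound
   merge gap ≤ 100 bp);
2. **design** up to five ranked primer pairs per locus from the 500 bp
   flanks, scored by
   `|Tm_f − Tm_opt| + |Tm_r − Tm_opt| + 0.5(|len_f − len_opt| + |len_r − len_opt|) + |Tm_f − Tm_r|`
   with the salt-adjusted GC melting model
   `Tm = 81.5 + 16.6·log10[Na+] + 0.41·%GC − 600/L`;
3. **e-PCR** each pair across every genotype (both orientations, exact
   3′ seed, configurable mismatch tolerance), enumerating all amplicons
   with coordinates and sizes;
4. **call** each locus POLYMORPHIC / MONOMORPHIC / INSUFFICIENT /
   PARALOGOUS from the allele-size matrix, with null alleles reported
   as missing cells;
5. screen **transferability** to a heterologous host (≤500 bp product,
   both primers matched, asymmetric matches filtered) and **genic
   primers** against a genome (intron-containing amplicons, exon–exon
   junction primers);
6. render a simulated **gel view** (band migration linear in log10
   size) as deterministic SVG plus a band table.

A seeded synthetic-genome generator (`generate_reference`,
`generate_genotypes`) plants repeat loci with known per-genotype
repeat-count deltas, null alleles and duplicated (paralogous) cassettes,
giving every stage an exact, download-free truth table.

## Worked example

```r
library(ssrpolykit)

gen <- generate_reference(n_loci = 8, genome_len = 40000, seed = 11,
                          n_duplicated = 1)
out <- generate_genotypes(gen$records, gen$truth, n_genotypes = 3,
                          null_rate = 0.1, seed = 11)
res <- run_polymorphism_pipeline(gen$records, out$genotypes)
res$report
#> Polymorphism report: 9 loci x 4 genotypes
#>   POLYMORPHIC : 7
#>   PARALOGOUS : 2
head(res$report$matrix)
#>   locus_id     reference         geno1         geno2         geno3
#> 1   chr1_1 MULTI:164;164 MULTI:158;161 MULTI:158;170 MULTI:167;173
#> 2   chr1_2           291           288           297           294
#> 3   chr1_3           262           264           262           258
#> 4   chr1_4           291           287           283           295
#> 5   chr1_5           221           215           212           227
#> 6   chr1_6           150            NA            NA           142
```

Reading the matrix: each cell is the predicted product size (bp) of the
locus's rank-1 primer pair in that genotype. `chr1_1` was planted in
two copies, so every genotype shows two products (`MULTI:…`) and the
locus is called PARALOGOUS — exactly what multi-band genotyping would
show on a gel. `chr1_6` carries a null allele (a substitution under a
primer 3′ end) in `geno1` and `geno2`: those cells are `NA`. The other
loci differ between genotypes by `unit length × repeat-count delta`
(e.g. 291 → 288 is a −1 delta of a trinucleotide), hence POLYMORPHIC.

```r
compare_to_truth(res, out$truth)[c("status_concordance",
                                   "cell_concordance")]
#> $status_concordance
#> [1] 1
#> $cell_concordance
#> [1] 1
```

Both concordances are 1: every status and every allele-size cell equals
what the planted truth implies.

The same stages are scriptable from a shell via `exec/ssrpolykit`:

```sh
ssrpolykit simulate --out fx --n-loci 20 --n-genotypes 4 --seed 7
ssrpolykit poly --ref fx/reference.fasta \
    --genotypes fx/genotype_1.fasta,fx/genotype_2.fasta \
    --out run1 --gel
ssrpolykit transfer --primers run1/primers.tsv --host peach.fasta --out t1
```

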