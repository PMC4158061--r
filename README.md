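# rnaseq2protdb

Build customized proteomic search databases from RNA-Seq evidence, and trace
novel peptide identifications back to their genomic origin.

Standard MS database searching only identifies peptides whose sequences are
present in the reference proteome, so sample-specific variation — amino acid
changes from non-synonymous SNVs, and peptides spanning unannotated splice
junctions — is invisible to it. At the same time the reference database
carries many entries whose transcripts are not expressed at all, inflating
the search space. `rnaseq2protdb` turns standard RNA-Seq derived files into
databases that fix both problems, and post-processes search results:

| Step | Function | Input | Output |
|---|---|---|---|
| SAP database | `build_sap_database()` | annotated VCF (SnpEff `ANN`), GTF, genome FASTA | FASTA of SAP polypeptide windows |
| Splice database | `build_splice_database()` | junction BED (TopHat BED12 or 6-column), GTF, genome FASTA | FASTA of 3/6-frame junction translations |
| Reduced database | `annotate_and_reduce()` | proteome FASTA, RSEM-style TPM table | TPM-annotated + thresholded FASTA |
| Assembly | `assemble_search_database()` | the parts + contaminants | target + reversed-decoy FASTA |
| Novel filtering | `filter_in_reference()`, `annotate_novel_peptides()`, `unique_variant_sites()` | peptide TSV, reference FASTA, custom DBs | reference/novel partition, class + site annotations |

The package consumes the outputs of upstream tools (aligner, variant caller,
SnpEff, RSEM, search engine) and does not reimplement them.

## The core operations, in notation

For a missense variant with annotated substitution p.`r``i``a` on a
transcript with translated protein `P` (|P| = L), the SAP entry is the
window

    P' = P with P'[i] = a,   window = P'[max(1, i−f) .. min(L, i+f)]

with flank `f` (default 20, covering any fully tryptic peptide at ≤2 missed
cleavages). The annotated reference residue is verified against the
package's own CDS translation before substitution; windows containing a stop
are dropped, and identical (window, substitution) pairs are collapsed.

For a junction with intron `[s, e]`, the entry DNA is
`genome[s−ф .. s−1] + genome[e+1 .. e+ф]` (flank ф = 66 nt,
reverse-complemented for minus-strand junctions), translated in frames
0–2 (6 frames when unstranded), then filtered by read depth
(`depth ≥ min_depth`, default 4), translated length (≥ 8 aa) and stop
codons. Only junctions whose intron interval is absent from the gene models
are used.

The reduced database keeps entry `p` iff `TPM(transcript(p)) > t`
(strictly, default t = 1). Decoys are whole-sequence reversals, one per
target. Reference matching of peptides is plain substring presence with I/L
folded together by default.

## Worked example

Everything below runs on the bundled synthetic fixture generator — no
downloads. The printed output is what the code actually produces:

```r
library(rnaseq2protdb)
fx <- generate_fixture_set("demo", seed = 1)   # toy genome + planted truth
genome  <- load_genome(fx$genome_fasta)
models  <- load_gene_models(fx$gtf)
effects <- parse_variant_effects(fx$vcf)

sapdb <- build_sap_database(effects, models, genome, flank = 8)
sapdb
#> FastaDatabase: 12 entries
#>   sap: 12
cat(sapdb$header[1], "\n", sapdb$sequence[1], "\n")
#> sap|TX003|g.chr1:2767C>G|c.83C>G|p.P28R|w.20-36
#> RACSVTESRKDMKCCDP
```

The header records the SNV (`g.` genomic, `c.` CDS), the substitution
(`p.P28R`: proline 28 to arginine) and the window extent (`w.20-36`); the
12 entries are exactly the 12 planted missense variants (the 5 planted
synonymous variants contribute nothing).

```r
spldb <- build_splice_database(fx$observed_bed, models, genome, min_depth = 1)
str(attr(spldb, "report"))
#> List of 7
#>  $ n_observed   : int 18
#>  $ n_novel      : int 10
#>  $ removed_depth: int 0
#>  $ removed_edge : int 0
#>  $ removed_short: int 0
#>  $ removed_stop : int 27
#>  $ n_entries    : int 3
```

Of 18 observed junctions, 10 are absent from the gene models; their 30
three-frame translations lose 27 to the stop-codon filter, leaving 3
entries.

```r
proteome <- read_fasta_db(fx$proteome_fasta)
red <- annotate_and_reduce(proteome, map_proteins_to_transcripts(proteome),
                           load_abundance(fx$tpm_tsv), threshold_tpm = 1)
red$report$n_kept
#> [1] 4

full <- assemble_search_database(list(red$reduced, sapdb, spldb,
                                      synthetic_contaminants()))
full
#> FastaDatabase: 44 entries
#>   contaminant: 3
#>   decoy: 22
#>   reference: 4
#>   sap: 12
#>   splice: 3

parts <- filter_in_reference(read_peptide_ids(fx$peptide_tsv), proteome)
ann <- annotate_novel_peptides(parts$novel, list(sapdb, spldb))
table(ann$class)
#>    sap splice
#>      8      6
us <- unique_variant_sites(ann)
cat(us$n_sap_peptides, "SAP peptides over", us$n_unique_sites, "unique SNP sites\n")
#> 8 SAP peptides over 7 unique SNP sites
```

All 14 simulated novel peptides are recovered with their planted classes;
the 8 SAP peptides collapse to 7 unique SNP sites because two peptides cover
the same variant.

## Command line

The same pipelines are exposed as subcommands (installed at
`exec/rnaseq2protdb`, or call `rnaseq2protdb_cli()` directly):

```sh
rnaseq2protdb fixtures --out-dir demo --seed 1
rnaseq2protdb sap     --vcf demo/variants.vcf --gtf demo/models.gtf \
                      --genome demo/genome.fasta --flank 20 \
                      --out sap.fasta --report sap_report.json
rnaseq2protdb splice  --observed demo/observed_junctions.bed --gtf demo/models.gtf \
                      --genome demo/genome.fasta --min-depth 4 --out splice.fasta
rnaseq2protdb reduce  --proteome demo/proteome.fasta \
                      --tpm demo/abundance.isoforms.results \
                      --threshold 1 --out-annotated ann.fasta --out-reduced red.fasta
rnaseq2protdb assemble --in red.fasta --in sap.fasta --in splice.fasta --out search.fasta
rnaseq2protdb filter-novel --peptides demo/peptides.tsv \
                      --reference demo/proteome.fasta \
                      --custom sap.fasta --custom splice.fasta --out-prefix flt
```

## Scope

Out of scope by design: read alignment, variant calling/annotation,
transcript quantification, MS searching and FDR estimation, indels/MNPs/
fusions, enzyme-aware digestion. See `vignettes/methods.Rmd` for the full
account of the model, parameter defaults, and what the synthetic tests do
and do not establish.
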