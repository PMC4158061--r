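---
title: "Building proteomic search databases from RNA-Seq evidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building proteomic search databases from RNA-Seq evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Shotgun proteomics identifies peptides by matching experimental spectra
against theoretical spectra derived from a reference protein database. A
peptide whose sequence is absent from that database is invisible, no matter
how good its spectrum. Two common sources of such absence are sample-specific
genetic variation (a non-synonymous SNV turns into a single amino acid
polymorphism, SAP, in the protein) and unannotated alternative splicing (a
novel exon–exon junction creates a peptide spanning sequence that no
annotated protein contains). Conversely, the reference database also carries
tens of thousands of entries whose transcripts are simply not expressed in
the sample, inflating the search space.

`rnaseq2protdb` implements the database-construction and post-search halves
of an RNA-Seq-guided proteogenomics workflow:

1. **SAP database** — annotated missense SNVs become short SAP-containing
   polypeptide windows.
2. **Splice-junction database** — junctions observed in RNA-Seq but absent
   from the gene models are translated in three (or six) frames around the
   splice boundary.
3. **Reduced database** — the reference proteome is annotated with transcript
   abundance (TPM) and filtered to entries whose transcript is expressed
   above a threshold.
4. **Assembly** — the parts are concatenated with a contaminant database and
   reversed-sequence decoys are appended for target-decoy FDR estimation.
5. **Novel-peptide filtering** — identified peptides are partitioned into
   reference hits vs novel, and novel peptides are traced back to their
   variant site or junction.

Upstream steps — read alignment, variant calling and annotation, transcript
quantification, the MS search itself and FDR control — are deliberately out
of scope: the package consumes their standard outputs (FASTA, GTF, annotated
VCF, junction BED, RSEM-style TPM tables, thresholded peptide lists).

## Coordinate and translation conventions

All internal genomic coordinates are 1-based inclusive. GTF is read as
1-based inclusive; BED input is converted from 0-based half-open at the file
boundary; VCF is 1-based. The GTF frame/phase column is ignored: the reading
frame is derived from the CDS concatenation starting at offset 0, which the
synthetic fixtures guarantee and which real phase-0 Ensembl models satisfy.
Models whose total CDS length is not a multiple of 3 are flagged and skipped,
never silently translated — the upstream annotation is the only authority
that could resolve such a model, and guessing would fabricate windows.

Translation uses the standard genetic code only (no selenocysteine). Stop
codons are emitted as `*` and retained by `translate_dna()`; truncation is
always an explicit downstream policy, because the splice workflow's
stop-codon filter must see the `*` to act on it. Codons containing `N`
translate to `X`.

## SAP windows

For each missense effect the transcript CDS is spliced, translated, and the
annotated reference residue is checked against our own translation before
the substitution is applied. This verification is mandatory by default
(`trust_annotation = FALSE`): a genome/annotation version mismatch otherwise
produces silently wrong variant peptides, a failure mode with no downstream
symptom. Mismatches are counted in the build report, not repaired.

The window spans `flank` residues either side of the SAP, truncated at the
protein termini. The default `flank = 20` is a declared choice, not an
inherited one: with trypsin and up to two missed cleavages, 20 residues per
side guarantee that every fully tryptic peptide covering the SAP is a
substring of the window, while keeping entries short enough not to inflate
the decoy space. Only the ALT allele generates an entry — the reference
allele is already represented in the reference proteome the SAP database is
concatenated with, so heterozygotes are covered by the pair.

Windows containing `*` (premature stop in the reference translation) are
dropped. Identical windows with identical SAP annotation arising from
different transcripts are collapsed into one entry whose header joins the
per-transcript blocks with `;`; the dedupe key is (window sequence, ref
residue, alt residue, offset-in-window). The report distinguishes *effects*
(annotation pairs), *sites* (distinct genomic alleles) and *entries*
(post-dedupe records), because the three counts genuinely differ and
conflating them has caused published inconsistencies.

## Splice-junction entries

Junction identity is the intron interval `(chrom, intron_start,
intron_end)`; exon-side coordinates reflect read length, not biology, and
are ignored for novelty. Novelty subtraction is strand-blind by default
(`strand_aware = FALSE`) because aligner strand inference is unreliable and
a wrongly stranded known junction would otherwise re-enter as "novel".

Flanking sequence comes from the genome adjacent to the intron — `flank_nt`
bases on each side, intron excised — not from the BED block sizes. The
default `flank_nt = 66` (22 codons per side) spans any plausible fully
tryptic junction peptide. Minus-strand junctions are reverse-complemented
before translation, so frames are always transcript-oriented; unstranded
(`.`) junctions get all six frames with an orientation marker in the header.

Filters, in order: junction read depth (`depth >= min_depth`; the published
mouse runs used 4, which is our default — whether the original tool used
`>=` or `>` is not stated, so we use `>=` and say so), minimum translated
length (`min_len_aa = 8`, the shortest plausibly identifiable tryptic
peptide), and the stop-codon filter (`drop_stop = TRUE`; a
truncate-at-stop mode is an explicit non-goal). The build report counts each
filter's removals separately, and raising any threshold is provably monotone
non-increasing in entry count (tested).

The junction residue recorded in the header (`o.<n>`) is the residue whose
codon contains the last nucleotide 5' of the splice boundary in that frame;
when the boundary falls ahead of the frame offset the index clamps to 1.

## Database reduction

Each protein entry is linked to its transcript (explicit map > GTF
`protein_id`/`transcript_id` pairs > Ensembl-style `transcript:` header
token) and its header suffixed with ` TPM=<value|NA>`. The reduced database
keeps entries with TPM strictly greater than the threshold — "above 1 TPM"
read literally — with the threshold configurable. Entries with no mapped or
quantified transcript are removed by default but preserved by
`keep_unmapped = TRUE`: removing them risks excluding proteins that are
abundant despite low transcript abundance, and the flag is the mitigation
surface for that known risk. Whether the original runs kept such entries is
not documented, so neither behavior is asserted as canonical.

RNA–protein correlation uses Spearman rank correlation (ties mid-ranked)
between per-protein spectral counts and TPM. Counts are PSM-level when
spectrum ids are available, otherwise distinct-peptide counts; the mode used
is recorded in the result. With fewer than 3 paired observations the
coefficient is reported as `NA`.

## Assembly and decoys

Concatenation preserves part order; header collisions get a provenance
suffix. Duplicate-sequence collapse exists but is off by default, matching
the plain concatenation of the original search setup. Decoys are
whole-sequence reversals only — shuffled or pseudo-reverse (K/R-fixing)
decoys are out of scope — one per target, `rev_`-prefixed, order preserved.
Palindromic sequences whose decoy equals the target are allowed and counted.
The bundled contaminant FASTA is synthetic (and named so); real searches
should supply the genuine cRAP file.

## Novel-peptide filtering

A peptide is a reference hit iff it occurs as a contiguous substring of any
reference entry. Matching is plain substring, not enzyme-aware — this is a
presence test, not a digest simulation. I/L are folded together by default
(`equate_il = TRUE`): the two residues are isobaric and indistinguishable to
the MS workflow, and without folding, trivially false "novel" calls arise;
the original tool's choice is undocumented, so ours is declared and
switchable. Modification tokens (bracketed masses, lowercase letters) are
stripped at ingest by a documented grammar.

A novel peptide is classed `sap` only if a match covers the SAP position
within the window — a match in the wild-type stretch of a window proves
nothing and is classed `other`. Any match to a junction entry yields class
`splice`. Site summaries key on `(chrom, genomic_pos, alt_allele)`; peptides
resolving to several sites count toward each and are flagged.

## The synthetic world and what green tests mean

The fixture generator builds a toy genome (default one ~9 kb chromosome,
8 fully coding multi-exon genes on both strands, 40–120 codons each),
plants missense and synonymous SNVs with SnpEff-style `ANN` strings, plants
known and novel junctions (BED12 two-block observed file, depths drawn from
1–20), and simulates a log-uniform TPM table plus a peptide list with known
class labels. Every planted item carries the coordinates needed to recompute
it independently, and the manifest's expected windows and translations are
computed by direct string/codon arithmetic on top of
`Biostrings::GENETIC_CODE`, never by the builder code paths — duplication
here is deliberate, so the manifest is a genuine oracle.

What the fixtures do **not** emulate: realistic expression distributions,
read-level noise, alignment artifacts, UTRs and phase>0 models, indels,
fusion transcripts, or spectra. A green suite therefore establishes
coordinate-exact correctness of the database constructions and filters on
well-formed inputs, plus the declared error behavior on malformed ones — it
does not establish anything about upstream calling quality, and the
published dataset-scale counts (which depend on external raw data and
third-party engines) are explicitly not reproduced.

Determinism is part of the contract: all generator outputs and all database
outputs are byte-identical given identical inputs and seed, which the suite
verifies end to end.

## Numerical and degenerate-input choices

* Duplicate genome record names, empty records, negative or duplicate TPM
  rows, and unknown strand characters are hard errors.
* Malformed `ANN` annotations are skipped with a warning and counted, not
  fatal — one bad annotation should not abort a million-variant VCF.
* A junction whose intron abuts a chromosome end (zero flank on one side) is
  skipped with a warning and counted.
* Window truncation at protein termini is silent by design; the header's
  `w.<start>-<end>` field records the actual extent.
* Spearman ties are mid-ranked via `stats::cor(method = "spearman")`; the
  test suite checks it against an independent rank-then-Pearson oracle.
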