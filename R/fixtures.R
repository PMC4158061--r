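# Deterministic synthetic-data generator with a ground-truth manifest.
#
# Oracle independence is a hard rule here: this module never calls the
# builder code paths (translate_dna, spliced_cds_sequence, sap_window, ...).
# Reverse complement and translation are reimplemented locally on top of
# Biostrings::GENETIC_CODE, and expected windows / translations are derived
# by direct string and codon arithmetic so they can serve as independent
# oracles for the builders.

.fx_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

.fx_translate <- function(dna, frame = 0L) {
  gc_tab <- Biostrings::GENETIC_CODE
  n <- nchar(dna) - frame
  if (n < 3L) return("")
  starts <- frame + 1L + 3L * (seq_len(n %/% 3L) - 1L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(gc_tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.fx_aa1to3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
                "*" = "Ter")

.fx_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.fx_stop_codons <- c("TAA", "TAG", "TGA")

.fx_random_coding <- function(n_codons) {
  # ATG + (n_codons-2) non-stop codons + stop; no in-frame internal stops
  gc_tab <- Biostrings::GENETIC_CODE
  nonstop <- names(gc_tab)[gc_tab != "*"]
  body <- sample(nonstop, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""),
         sample(.fx_stop_codons, 1L))
}

#' Generate a toy genome, gene models and reference proteome
#'
#' Genes are fully coding (CDS = exons), multi-exon, on both strands, with
#' CDS length divisible by 3, starting ATG, ending in a stop and free of
#' in-frame internal stops. All outputs are pure functions of the parameters
#' and seed.
#'
#' @param out_dir Directory for the emitted files (created if needed).
#' @param n_chroms Number of chromosomes.
#' @param n_genes Number of genes (round-robin over chromosomes).
#' @param exons_per_gene_range Two integers, inclusive range of exon counts.
#' @param codons_range Two integers, inclusive range of codon counts per gene.
#' @param chrom_len Maximum chromosome length; an error is raised before
#'   emission if the genes do not fit.
#' @param seed Integer seed.
#' @return List with paths `genome_fasta`, `gtf`, `proteome_fasta` and the
#'   ground-truth `manifest`.
#' @export
generate_toy_reference <- function(out_dir, n_chroms = 1L, n_genes = 8L,
                                   exons_per_gene_range = c(2L, 4L),
                                   codons_range = c(40L, 120L),
                                   chrom_len = 50000L, seed = 1L) {
  stopifnot(n_chroms >= 1L, n_genes >= 1L, all(exons_per_gene_range >= 1L),
            all(codons_range >= 10L))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  chrom_names <- paste0("chr", seq_len(n_chroms))
  cursor <- setNames(rep(1L, n_chroms), chrom_names)
  chrom_parts <- setNames(vector("list", n_chroms), chrom_names)
  transcripts <- list()
  for (g in seq_len(n_genes)) {
    chrom <- chrom_names[((g - 1L) %% n_chroms) + 1L]
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_exons <- sample(seq(exons_per_gene_range[1], exons_per_gene_range[2]), 1L)
    n_codons <- sample(seq(codons_range[1], codons_range[2]), 1L)
    coding <- .fx_random_coding(n_codons)
    clen <- nchar(coding)
    # split the coding sequence into n_exons chunks of >= 12 nt
    if (n_exons > 1L) {
      repeat {
        cuts <- sort(sample(seq(13L, clen - 12L), n_exons - 1L))
        if (all(diff(c(0L, cuts, clen)) >= 12L)) break
      }
    } else cuts <- integer()
    chunk_bounds <- cbind(c(1L, cuts + 1L), c(cuts, clen))
    intron_lens <- if (n_exons > 1L) sample(60:400, n_exons - 1L,
                                            replace = TRUE) else integer()
    # pre-mRNA in transcript orientation
    pre <- character()
    tx_exon_bounds <- matrix(0L, nrow = n_exons, ncol = 2L)  # within pre-mRNA
    off <- 0L
    for (e in seq_len(n_exons)) {
      exon_seq <- substr(coding, chunk_bounds[e, 1L], chunk_bounds[e, 2L])
      tx_exon_bounds[e, ] <- c(off + 1L, off + nchar(exon_seq))
      pre <- c(pre, exon_seq)
      off <- off + nchar(exon_seq)
      if (e < n_exons) {
        pre <- c(pre, .fx_random_dna(intron_lens[e]))
        off <- off + intron_lens[e]
      }
    }
    pre <- paste(pre, collapse = "")
    gap <- sample(300:800, 1L)
    a <- cursor[[chrom]] + gap
    b <- a + nchar(pre) - 1L
    if (b + 300L > chrom_len) {
      stop("chromosome ", chrom, " too short (", chrom_len,
           " bp) for the requested genes")
    }
    segment <- if (strand == "+") pre else .fx_revcomp(pre)
    chrom_parts[[chrom]] <- c(chrom_parts[[chrom]],
                              list(list(start = a, seq = segment)))
    cursor[[chrom]] <- b + 1L
    # genomic exon intervals (ascending)
    exons <- matrix(0L, nrow = n_exons, ncol = 2L)
    for (e in seq_len(n_exons)) {
      if (strand == "+") {
        exons[e, ] <- c(a + tx_exon_bounds[e, 1L] - 1L,
                        a + tx_exon_bounds[e, 2L] - 1L)
      } else {
        exons[e, ] <- c(b - tx_exon_bounds[e, 2L] + 1L,
                        b - tx_exon_bounds[e, 1L] + 1L)
      }
    }
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    # genomic position of each coding base, in transcript order
    pos_by_cds <- if (strand == "+") {
      unlist(lapply(seq_len(nrow(exons)), function(e)
        seq(exons[e, 1L], exons[e, 2L])))
    } else {
      rev(unlist(lapply(seq_len(nrow(exons)), function(e)
        seq(exons[e, 1L], exons[e, 2L]))))
    }
    introns <- if (nrow(exons) > 1L) {
      cbind(exons[-nrow(exons), 2L] + 1L, exons[-1L, 1L] - 1L)
    } else matrix(0L, 0L, 2L)
    tid <- sprintf("TX%03d", g)
    transcripts[[tid]] <- list(
      transcript_id = tid, gene_id = sprintf("GENE%03d", g),
      protein_id = sprintf("PROT%03d", g), chrom = chrom, strand = strand,
      exons = exons, introns = introns, coding = coding,
      protein = sub("\\*$", "", .fx_translate(coding)),
      pos_by_cds = pos_by_cds)
  }
  # assemble chromosome sequences
  genome <- setNames(character(n_chroms), chrom_names)
  for (chrom in chrom_names) {
    total <- cursor[[chrom]] + 299L
    s <- strsplit(.fx_random_dna(total), "")[[1]]
    for (part in chrom_parts[[chrom]]) {
      idx <- seq(part$start, part$start + nchar(part$seq) - 1L)
      s[idx] <- strsplit(part$seq, "")[[1]]
    }
    genome[[chrom]] <- paste(s, collapse = "")
  }
  # write genome FASTA
  genome_fasta <- file.path(out_dir, "genome.fasta")
  con <- file(genome_fasta, "wb")
  for (chrom in chrom_names) {
    writeLines(paste0(">", chrom), con, sep = "\n")
    s <- genome[[chrom]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con,
               sep = "\n")
  }
  close(con)
  # write GTF (exon + CDS features; fully coding models, phase 0)
  gtf <- file.path(out_dir, "models.gtf")
  lines <- character()
  for (tx in transcripts) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; protein_id "%s";',
      tx$gene_id, tx$transcript_id, tx$protein_id)
    for (e in seq_len(nrow(tx$exons))) {
      for (feat in c("exon", "CDS")) {
        lines <- c(lines, paste(tx$chrom, "toy", feat, tx$exons[e, 1L],
                                tx$exons[e, 2L], ".", tx$strand, "0", attrs,
                                sep = "\t"))
      }
    }
  }
  con <- file(gtf, "wb"); writeLines(lines, con, sep = "\n"); close(con)
  # write reference proteome with Ensembl-style headers
  proteome_fasta <- file.path(out_dir, "proteome.fasta")
  con <- file(proteome_fasta, "wb")
  for (tx in transcripts) {
    writeLines(sprintf(">%s pep transcript:%s gene:%s", tx$protein_id,
                       tx$transcript_id, tx$gene_id), con, sep = "\n")
    p <- tx$protein
    starts <- seq(1L, nchar(p), by = 60L)
    writeLines(substring(p, starts, pmin(starts + 59L, nchar(p))), con,
               sep = "\n")
  }
  close(con)
  manifest <- list(
    seed = seed,
    params = list(n_chroms = n_chroms, n_genes = n_genes,
                  exons_per_gene_range = exons_per_gene_range,
                  codons_range = codons_range, chrom_len = chrom_len),
    chrom_lengths = vapply(genome, nchar, integer(1)),
    transcripts = transcripts)
  list(genome_fasta = genome_fasta, gtf = gtf,
       proteome_fasta = proteome_fasta, manifest = manifest,
       genome = genome)
}

.fx_pick_missense <- function(codon) {
  # all single-nt substitutions of codon that change the amino acid without
  # creating a stop; returns a data.frame of candidates
  gc_tab <- Biostrings::GENETIC_CODE
  aa0 <- gc_tab[[codon]]
  out <- list()
  for (i in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, i, i))) {
      alt <- codon
      substr(alt, i, i) <- nt
      aa1 <- gc_tab[[alt]]
      if (aa1 != aa0 && aa1 != "*") {
        out[[length(out) + 1L]] <- data.frame(
          pos_in_codon = i, refnt = substr(codon, i, i), altnt = nt,
          ref_aa = aa0, alt_aa = aa1, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

.fx_pick_synonymous <- function(codon) {
  gc_tab <- Biostrings::GENETIC_CODE
  aa0 <- gc_tab[[codon]]
  out <- list()
  for (i in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, i, i))) {
      alt <- codon
      substr(alt, i, i) <- nt
      if (gc_tab[[alt]] == aa0) {
        out[[length(out) + 1L]] <- data.frame(
          pos_in_codon = i, refnt = substr(codon, i, i), altnt = nt,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Plant annotated SNVs into a toy reference
#'
#' Chooses internal codon positions (never the start or stop codon), derives
#' missense or synonymous single-nucleotide substitutions by direct codon
#' arithmetic, writes a VCF with SnpEff-v4-style `ANN` annotations, and
#' records the expected SAP windows (at the given flank) in the manifest as
#' the independent oracle for the SAP database builder.
#'
#' @param reference Result of [generate_toy_reference()].
#' @param n_missense,n_synonymous Numbers of variants to plant.
#' @param flank Flank used for the expected windows recorded in the manifest.
#' @param seed Integer seed.
#' @return List with `vcf` (path) and the updated `manifest` (element
#'   `variants`: data.frame of missense truth incl. `expected_window`,
#'   `expected_header`, `sap_offset`).
#' @export
plant_variants <- function(reference, n_missense = 12L, n_synonymous = 5L,
                           flank = 8L, seed = 1L) {
  set.seed(seed)
  txs <- reference$manifest$transcripts
  # candidate (transcript, codon index) pairs, internal codons only
  cand <- do.call(rbind, lapply(txs, function(tx) {
    n_cod <- nchar(tx$coding) %/% 3L
    data.frame(tid = tx$transcript_id, codon_idx = seq(2L, n_cod - 1L),
               stringsAsFactors = FALSE)
  }))
  total <- n_missense + n_synonymous
  if (total > nrow(cand)) stop("requested more variants than available codons")
  picked <- cand[sample(nrow(cand), total), , drop = FALSE]
  rows <- list(); vcf_rows <- list()
  for (i in seq_len(total)) {
    is_mis <- i <= n_missense
    tid <- picked$tid[i]; ci <- picked$codon_idx[i]
    tx <- txs[[tid]]
    codon <- substr(tx$coding, 3L * ci - 2L, 3L * ci)
    cands <- if (is_mis) .fx_pick_missense(codon) else .fx_pick_synonymous(codon)
    if (is.null(cands)) {
      # every codon has a missense neighbour, but a few (e.g. TGG) have no
      # synonymous one: fall back to another random codon of the same class
      repeat {
        j <- sample(nrow(cand), 1L)
        tid <- cand$tid[j]; ci <- cand$codon_idx[j]
        tx <- txs[[tid]]
        codon <- substr(tx$coding, 3L * ci - 2L, 3L * ci)
        cands <- if (is_mis) .fx_pick_missense(codon)
                 else .fx_pick_synonymous(codon)
        if (!is.null(cands)) break
      }
    }
    ch <- cands[sample(nrow(cands), 1L), ]
    cds_pos <- 3L * (ci - 1L) + ch$pos_in_codon
    gpos <- tx$pos_by_cds[cds_pos]
    ref_allele <- if (tx$strand == "+") ch$refnt else
      chartr("ACGT", "TGCA", ch$refnt)
    alt_allele <- if (tx$strand == "+") ch$altnt else
      chartr("ACGT", "TGCA", ch$altnt)
    if (is_mis) {
      mut <- tx$protein
      substr(mut, ci, ci) <- ch$alt_aa
      wa <- max(1L, ci - flank); wb <- min(nchar(mut), ci + flank)
      window <- substr(mut, wa, wb)
      hdr <- sprintf("sap|%s|g.%s:%d%s>%s|c.%d%s>%s|p.%s%d%s|w.%d-%d",
                     tid, tx$chrom, gpos, ref_allele, alt_allele,
                     cds_pos, ch$refnt, ch$altnt, ch$ref_aa, ci, ch$alt_aa,
                     wa, wb)
      ann_p <- sprintf("p.%s%d%s", .fx_aa1to3[[ch$ref_aa]], ci,
                       .fx_aa1to3[[ch$alt_aa]])
      effect <- "missense_variant"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, genomic_pos = gpos, ref_allele = ref_allele,
        alt_allele = alt_allele, transcript_id = tid, cds_pos = cds_pos,
        refnt = ch$refnt, altnt = ch$altnt, ref_aa = ch$ref_aa,
        alt_aa = ch$alt_aa, protein_pos = ci, expected_window = window,
        window_start = wa, window_end = wb, sap_offset = ci - wa + 1L,
        expected_header = hdr, stringsAsFactors = FALSE)
    } else {
      aa0 <- Biostrings::GENETIC_CODE[[codon]]
      ann_p <- sprintf("p.%s%d%s", .fx_aa1to3[[aa0]], ci, .fx_aa1to3[[aa0]])
      effect <- "synonymous_variant"
    }
    ann <- sprintf(
      "%s|%s|%s|%s|%s|transcript|%s|protein_coding|1/1|c.%d%s>%s|%s|%d|%d/%d|%d/%d||",
      alt_allele, effect, if (is_mis) "MODERATE" else "LOW",
      tx$gene_id, tx$gene_id, tid, cds_pos, ch$refnt, ch$altnt, ann_p,
      cds_pos, cds_pos, nchar(tx$coding), ci, nchar(tx$protein))
    vcf_rows[[length(vcf_rows) + 1L]] <- data.frame(
      chrom = tx$chrom, pos = gpos, ref = ref_allele, alt = alt_allele,
      ann = ann, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, rows)
  vtab <- do.call(rbind, vcf_rows)
  vtab <- vtab[order(vtab$chrom, vtab$pos), , drop = FALSE]
  vcf_path <- file.path(dirname(reference$genome_fasta), "variants.vcf")
  con <- file(vcf_path, "wb")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0('##INFO=<ID=ANN,Number=.,Type=String,Description="Functional ',
           'annotations: Allele|Annotation|Annotation_Impact|Gene_Name|',
           'Gene_ID|Feature_Type|Feature_ID|Transcript_BioType|Rank|HGVS.c|',
           'HGVS.p|cDNA.pos/cDNA.length|CDS.pos/CDS.length|AA.pos/AA.length|',
           'Distance|ERRORS">'),
    sprintf("##contig=<ID=%s,length=%d>",
            names(reference$manifest$chrom_lengths),
            reference$manifest$chrom_lengths),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tANN=%s",
            vtab$chrom, vtab$pos, vtab$ref, vtab$alt, vtab$ann)),
    con, sep = "\n")
  close(con)
  manifest <- reference$manifest
  manifest$variants <- variants
  manifest$variant_params <- list(n_missense = n_missense,
                                  n_synonymous = n_synonymous,
                                  flank = flank, seed = seed)
  list(vcf = vcf_path, manifest = manifest)
}

.fx_junction_offset_aa <- function(offset_nt, frame) {
  if (offset_nt <= frame) 1L else (offset_nt - frame - 1L) %/% 3L + 1L
}

#' Plant known and novel splice junctions
#'
#' Re-emits a sample of the gene-model introns as "known used" junctions and
#' places novel intron intervals in intergenic space, colliding with no
#' gene-model intron. Writes a 6-column known-junction BED (all gene-model
#' introns) and a BED12 two-block observed BED (known used + novel, each with
#' a read depth drawn from `depth_range`). For every novel junction the
#' manifest stores the flanking DNA and its three-frame translations computed
#' by direct string operations — the independent oracle for the splice
#' builder.
#'
#' @param reference Result of [generate_toy_reference()].
#' @param n_known_used,n_novel Junction counts.
#' @param depth_range Two integers, inclusive depth range.
#' @param flank_nt Flank recorded in the manifest oracle.
#' @param seed Integer seed.
#' @return List with `known_bed`, `observed_bed` and the updated `manifest`
#'   (elements `junctions_novel`, `junctions_known_used`).
#' @export
plant_junctions <- function(reference, n_known_used = 8L, n_novel = 10L,
                            depth_range = c(1L, 20L), flank_nt = 66L,
                            seed = 1L) {
  set.seed(seed)
  txs <- reference$manifest$transcripts
  genome <- reference$genome
  known <- do.call(rbind, lapply(txs, function(tx) {
    if (!nrow(tx$introns)) return(NULL)
    data.frame(chrom = tx$chrom, intron_start = tx$introns[, 1L],
               intron_end = tx$introns[, 2L], strand = tx$strand,
               stringsAsFactors = FALSE)
  }))
  known <- known[!duplicated(paste(known$chrom, known$intron_start,
                                   known$intron_end)), , drop = FALSE]
  if (n_known_used > nrow(known)) {
    stop("only ", nrow(known), " gene-model introns available")
  }
  used <- known[sample(nrow(known), n_known_used), , drop = FALSE]
  used$depth <- sample(seq(depth_range[1], depth_range[2]), n_known_used,
                       replace = TRUE)
  known_keys <- paste(known$chrom, known$intron_start, known$intron_end)
  # place novel junctions in margins clear of chromosome edges
  novel <- list()
  chroms <- names(genome)
  margin <- flank_nt + 25L
  tries <- 0L
  while (length(novel) < n_novel) {
    tries <- tries + 1L
    if (tries > 10000L) stop("cannot place novel junctions without collision")
    chrom <- sample(chroms, 1L)
    clen <- nchar(genome[[chrom]])
    ilen <- sample(80:300, 1L)
    s <- sample(seq(margin, clen - margin - ilen), 1L)
    e <- s + ilen - 1L
    key <- paste(chrom, s, e)
    if (key %in% known_keys) next
    if (length(novel) &&
        key %in% vapply(novel, function(j) paste(j$chrom, j$intron_start,
                                                 j$intron_end),
                        character(1))) next
    novel[[length(novel) + 1L]] <- list(
      chrom = chrom, intron_start = s, intron_end = e,
      strand = sample(c("+", "-"), 1L),
      depth = sample(seq(depth_range[1], depth_range[2]), 1L))
  }
  # oracle: flanking sequence and 3-frame translations per novel junction
  junctions_novel <- lapply(seq_along(novel), function(i) {
    j <- novel[[i]]
    left <- substr(genome[[j$chrom]], j$intron_start - flank_nt,
                   j$intron_start - 1L)
    right <- substr(genome[[j$chrom]], j$intron_end + 1L,
                    j$intron_end + flank_nt)
    dna <- paste0(left, right)
    off <- nchar(left)
    if (j$strand == "-") {
      dna <- .fx_revcomp(dna)
      off <- nchar(right)
    }
    frames <- lapply(0:2, function(f) {
      p <- .fx_translate(dna, f)
      list(frame = f, protein = p,
           junction_offset_aa = min(.fx_junction_offset_aa(off, f), nchar(p)),
           has_stop = grepl("*", p, fixed = TRUE), len = nchar(p))
    })
    c(j, list(name = sprintf("NOVEL%03d", i), flank_nt = flank_nt,
              dna = dna, junction_offset_nt = off, frames = frames))
  })
  out_dir <- dirname(reference$genome_fasta)
  # known BED: 6-column precomputed-intron dialect, 0-based half-open
  known_bed <- file.path(out_dir, "known_junctions.bed")
  con <- file(known_bed, "wb")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", known$chrom,
                     known$intron_start - 1L, known$intron_end,
                     sprintf("KNOWN%03d", seq_len(nrow(known))), 0L,
                     known$strand), con, sep = "\n")
  close(con)
  # observed BED: BED12 two-block dialect with 20 nt overhangs
  oh <- 20L
  obs <- c(lapply(seq_len(nrow(used)), function(i) {
    list(chrom = used$chrom[i], intron_start = used$intron_start[i],
         intron_end = used$intron_end[i], strand = used$strand[i],
         depth = used$depth[i], name = sprintf("USED%03d", i))
  }), lapply(junctions_novel, function(j) {
    j[c("chrom", "intron_start", "intron_end", "strand", "depth", "name")]
  }))
  ord <- order(vapply(obs, `[[`, character(1), "chrom"),
               vapply(obs, `[[`, integer(1), "intron_start"))
  obs <- obs[ord]
  observed_bed <- file.path(out_dir, "observed_junctions.bed")
  con <- file(observed_bed, "wb")
  writeLines(vapply(obs, function(j) {
    chrom_start0 <- j$intron_start - 1L - oh
    block2_start <- j$intron_end - chrom_start0
    chrom_end0 <- chrom_start0 + block2_start + oh
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t2\t%d,%d\t0,%d",
            j$chrom, chrom_start0, chrom_end0, j$name, j$depth, j$strand,
            chrom_start0, chrom_end0, oh, oh, block2_start)
  }, character(1)), con, sep = "\n")
  close(con)
  manifest <- reference$manifest
  manifest$junctions_novel <- junctions_novel
  manifest$junctions_known_used <- used
  manifest$junction_params <- list(n_known_used = n_known_used,
                                   n_novel = n_novel,
                                   depth_range = depth_range,
                                   flank_nt = flank_nt, seed = seed)
  list(known_bed = known_bed, observed_bed = observed_bed,
       manifest = manifest)
}

#' Simulate transcript abundances and an identified-peptide list
#'
#' A fraction `frac_expressed` of transcripts receives a TPM drawn
#' log-uniformly from `[0.1, 1000]`; the rest get exactly 0. Peptides are
#' sampled as substrings of reference proteins, of planted SAP windows
#' (always covering the SAP position) and of stop-free novel junction
#' translations (always covering the junction codon); SAP and junction
#' peptides are rejected if they occur in any reference protein under I/L
#' folding, so planted novel labels are unambiguous.
#'
#' @param reference Result of [generate_toy_reference()].
#' @param manifest Manifest carrying `variants` and/or `junctions_novel`.
#' @param frac_expressed Fraction of transcripts with non-zero TPM.
#' @param n_ref_peptides,n_sap_peptides,n_junction_peptides Peptide counts.
#' @param seed Integer seed.
#' @return List with `tpm_tsv`, `peptide_tsv` and the updated `manifest`
#'   (elements `abundance`, `expected_reduced_proteins`, `peptides`).
#' @export
simulate_abundance_and_peptides <- function(reference, manifest,
                                            frac_expressed = 0.6,
                                            n_ref_peptides = 30L,
                                            n_sap_peptides = 8L,
                                            n_junction_peptides = 6L,
                                            seed = 1L) {
  set.seed(seed)
  txs <- reference$manifest$transcripts
  n <- length(txs)
  tids <- vapply(txs, `[[`, character(1), "transcript_id")
  n_expr <- round(frac_expressed * n)
  expressed <- sample(tids, n_expr)
  tpm <- setNames(rep(0, n), tids)
  tpm[expressed] <- 10^stats::runif(n_expr, -1, 3)
  out_dir <- dirname(reference$genome_fasta)
  tpm_tsv <- file.path(out_dir, "abundance.isoforms.results")
  con <- file(tpm_tsv, "wb")
  writeLines(c(
    paste("transcript_id", "gene_id", "length", "effective_length",
          "expected_count", "TPM", "FPKM", "IsoPct", sep = "\t"),
    sprintf("%s\t%s\t%d\t%.2f\t%.2f\t%.4f\t%.4f\t%.2f", tids,
            vapply(txs, `[[`, character(1), "gene_id"),
            vapply(txs, function(t) nchar(t$coding), integer(1)),
            vapply(txs, function(t) nchar(t$coding), integer(1)) - 150,
            unname(tpm) * 10, unname(tpm), unname(tpm) * 0.9,
            rep(100, n))), con, sep = "\n")
  close(con)
  ref_proteins <- vapply(txs, `[[`, character(1), "protein")
  ref_fold <- chartr("IL", "JJ", ref_proteins)
  in_reference <- function(pep) {
    any(vapply(ref_fold, function(r) grepl(chartr("IL", "JJ", pep), r,
                                           fixed = TRUE), logical(1)))
  }
  sample_substring <- function(s, min_len, max_len, cover = NULL) {
    L <- nchar(s)
    len <- sample(seq(min_len, min(max_len, L)), 1L)
    lo <- 1L; hi <- L - len + 1L
    if (!is.null(cover)) {
      lo <- max(1L, cover - len + 1L)
      hi <- min(cover, L - len + 1L)
      if (hi < lo) return(NULL)
    }
    start <- if (hi == lo) lo else sample(seq(lo, hi), 1L)
    substr(s, start, start + len - 1L)
  }
  peptides <- list()
  add_pep <- function(pep, class, key) {
    peptides[[length(peptides) + 1L]] <<- list(peptide = pep, class = class,
                                               key = key)
  }
  for (i in seq_len(n_ref_peptides)) {
    tx <- txs[[sample(n, 1L)]]
    pep <- sample_substring(tx$protein, 8L, 15L)
    add_pep(pep, "reference", tx$protein_id)
  }
  if (n_sap_peptides > 0L) {
    if (is.null(manifest$variants)) stop("manifest has no planted variants")
    v <- manifest$variants
    placed <- 0L; tries <- 0L
    while (placed < n_sap_peptides) {
      tries <- tries + 1L
      if (tries > 5000L) stop("cannot sample enough novel SAP peptides")
      row <- v[sample(nrow(v), 1L), ]
      pep <- sample_substring(row$expected_window, 8L,
                              nchar(row$expected_window),
                              cover = row$sap_offset)
      if (is.null(pep) || in_reference(pep)) next
      add_pep(pep, "sap", paste(row$chrom, row$genomic_pos, row$alt_allele,
                                sep = ":"))
      placed <- placed + 1L
    }
  }
  if (n_junction_peptides > 0L) {
    if (is.null(manifest$junctions_novel)) {
      stop("manifest has no planted junctions")
    }
    jn <- manifest$junctions_novel
    placed <- 0L; tries <- 0L
    while (placed < n_junction_peptides) {
      tries <- tries + 1L
      if (tries > 5000L) stop("cannot sample enough novel junction peptides")
      j <- jn[[sample(length(jn), 1L)]]
      ok_frames <- Filter(function(f) !f$has_stop && f$len >= 8L, j$frames)
      if (!length(ok_frames)) next
      f <- ok_frames[[sample(length(ok_frames), 1L)]]
      pep <- sample_substring(f$protein, 8L, 15L, cover = f$junction_offset_aa)
      if (is.null(pep) || in_reference(pep)) next
      add_pep(pep, "junction", paste(j$chrom, j$intron_start, j$intron_end,
                                     sep = ":"))
      placed <- placed + 1L
    }
  }
  pep_df <- data.frame(
    peptide = vapply(peptides, `[[`, character(1), "peptide"),
    class = vapply(peptides, `[[`, character(1), "class"),
    key = vapply(peptides, `[[`, character(1), "key"),
    score = round(stats::runif(length(peptides), 1, 6), 3),
    stringsAsFactors = FALSE)
  pep_df$spectrum_id <- sprintf("spec%04d", seq_len(nrow(pep_df)))
  peptide_tsv <- file.path(out_dir, "peptides.tsv")
  con <- file(peptide_tsv, "wb")
  writeLines(c("peptide\tscore\tspectrum_id",
               sprintf("%s\t%.3f\t%s", pep_df$peptide, pep_df$score,
                       pep_df$spectrum_id)), con, sep = "\n")
  close(con)
  manifest$abundance <- data.frame(transcript_id = tids, tpm = unname(tpm),
                                   stringsAsFactors = FALSE)
  # proteins expected in the reduced database at the default 1 TPM threshold
  manifest$expected_reduced_proteins <- vapply(
    txs[tids[tpm > 1]], `[[`, character(1), "protein_id")
  manifest$peptides <- pep_df
  manifest$abundance_params <- list(frac_expressed = frac_expressed,
                                    n_ref_peptides = n_ref_peptides,
                                    n_sap_peptides = n_sap_peptides,
                                    n_junction_peptides = n_junction_peptides,
                                    seed = seed)
  list(tpm_tsv = tpm_tsv, peptide_tsv = peptide_tsv, manifest = manifest)
}

#' Generate a complete fixture set
#'
#' Runs the four generator stages with seeds derived deterministically from
#' `seed` and writes a JSON manifest alongside the data files.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param preset `"small"` (default) or `"medium"`.
#' @return List of file paths plus the full `manifest`.
#' @export
generate_fixture_set <- function(out_dir, seed = 1L, preset = "small") {
  preset <- match.arg(preset, c("small", "medium"))
  p <- if (preset == "small") {
    list(n_genes = 8L, n_missense = 12L, n_synonymous = 5L,
         n_known = 8L, n_novel = 10L)
  } else {
    list(n_genes = 20L, n_missense = 30L, n_synonymous = 10L,
         n_known = 15L, n_novel = 25L)
  }
  ref <- generate_toy_reference(out_dir, n_genes = p$n_genes, seed = seed)
  vr <- plant_variants(ref, n_missense = p$n_missense,
                       n_synonymous = p$n_synonymous, seed = seed + 1L)
  ref$manifest <- vr$manifest
  jr <- plant_junctions(ref, n_known_used = p$n_known, n_novel = p$n_novel,
                        seed = seed + 2L)
  ref$manifest <- jr$manifest
  ar <- simulate_abundance_and_peptides(ref, ref$manifest, seed = seed + 3L)
  manifest <- ar$manifest
  manifest_json <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(genome_fasta = ref$genome_fasta, gtf = ref$gtf,
       proteome_fasta = ref$proteome_fasta, vcf = vr$vcf,
       known_bed = jr$known_bed, observed_bed = jr$observed_bed,
       tpm_tsv = ar$tpm_tsv, peptide_tsv = ar$peptide_tsv,
       manifest_json = manifest_json, manifest = manifest,
       genome = ref$genome)
}
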