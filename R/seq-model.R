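#' @import Biostrings
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
NULL

# Standard genetic code over ACGT, stop = '*'. Codons containing N translate
# to 'X'; no selenocysteine or alternative codes.
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- as.vector(sapply(bases, function(b1)
    sapply(bases, function(b2) paste0(b1, b2, bases))))
  setNames(aas, codons)
})

#' Codon table used for all translation
#'
#' Named character vector mapping the 64 ACGT codons to one-letter amino
#' acids, with `*` for stop. Exposed mainly so callers can inspect the code
#' in use; translation itself goes through [translate_dna()].
#'
#' @return Named character vector of length 64.
#' @export
codon_table <- function() .codon_table

.revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of a DNA string
#'
#' @param seq Character vector of DNA strings over ACGTN.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) .revcomp(seq)

#' Translate DNA to protein
#'
#' Reads codons from offset `frame`; trailing 1-2 nt are dropped. Stop codons
#' are rendered `*` and retained in the output (downstream filters decide
#' policy); codons containing `N` become `X`.
#'
#' @param seq DNA string over ACGTN (single string).
#' @param frame Integer offset 0, 1 or 2.
#' @return Protein string (possibly empty).
#' @export
translate_dna <- function(seq, frame = 0L) {
  stopifnot(length(seq) == 1L, frame %in% 0:2)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("translate_dna: sequence contains characters outside ACGTN")
  }
  n <- nchar(seq) - frame
  if (n < 3L) return("")
  n_codons <- n %/% 3L
  starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(.codon_table[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Load a genome FASTA into a sequence store
#'
#' Sequences are uppercased (soft-masked lowercase preserved as uppercase).
#' Sequence names are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A `GenomeSequence` object: named character vector of uppercase DNA.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("genome FASTA has no records: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name(s) in genome FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L)) stop("empty sequence record in genome FASTA")
  names(seqs) <- nm
  structure(seqs, class = "GenomeSequence")
}

#' Extract a genomic subsequence (1-based inclusive)
#'
#' @param genome A `GenomeSequence`.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return DNA string.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 1L || end > len || start > end) {
    stop(sprintf("coordinates [%d,%d] outside [1,%d] on %s",
                 start, end, len, chrom))
  }
  substr(genome[[chrom]], start, end)
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat("GenomeSequence:", length(x), "sequence(s)\n")
  for (nm in names(x)) cat("  ", nm, ": ", nchar(x[[nm]]), " bp\n", sep = "")
  invisible(x)
}

.new_transcript_model <- function(transcript_id, gene_id, protein_id, chrom,
                                  strand, exons, cds) {
  ord <- order(exons[, 1L])
  exons <- exons[ord, , drop = FALSE]
  if (nrow(cds)) cds <- cds[order(cds[, 1L]), , drop = FALSE]
  cds_len <- if (nrow(cds)) sum(cds[, 2L] - cds[, 1L] + 1L) else 0L
  # CDS intervals must each lie inside some exon
  consistent <- all(vapply(seq_len(nrow(cds)), function(i) {
    any(cds[i, 1L] >= exons[, 1L] & cds[i, 2L] <= exons[, 2L])
  }, logical(1)))
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    protein_id = protein_id, chrom = chrom, strand = strand,
    exons = exons, cds = cds, cds_length = cds_len,
    translatable = cds_len > 0L && cds_len %% 3L == 0L,
    consistent = consistent
  ), class = "TranscriptModel")
}

#' Load gene models from a GTF file
#'
#' Builds one transcript model per `transcript_id` from `exon` and `CDS`
#' features. Exon and CDS interval lists are stored sorted ascending by
#' genomic start regardless of strand. Models whose total CDS length is not a
#' multiple of 3 are flagged `translatable = FALSE` (never silently
#' translated); a CDS outside any exon flags the model inconsistent with a
#' warning.
#'
#' @param path Path to a GTF file (1-based inclusive coordinates).
#' @return Named list of `TranscriptModel` objects, keyed by transcript id.
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gr$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]
  type <- type[keep]
  strand_chr <- as.character(GenomicRanges::strand(gr))
  if (any(!strand_chr %in% c("+", "-"))) {
    stop("gene model with unknown strand character (must be + or -)")
  }
  tid <- as.character(gr$transcript_id)
  if (anyNA(tid)) stop("GTF feature without transcript_id attribute")
  models <- list()
  for (t in unique(tid)) {
    idx <- which(tid == t)
    ex <- idx[type[idx] == "exon"]
    cd <- idx[type[idx] == "CDS"]
    pid <- NA_character_
    if (!is.null(gr$protein_id)) {
      p <- unique(stats::na.omit(gr$protein_id[idx]))
      if (length(p)) pid <- p[[1L]]
    }
    gid <- unique(as.character(gr$gene_id[idx]))[1L]
    m <- .new_transcript_model(
      transcript_id = t, gene_id = gid, protein_id = pid,
      chrom = as.character(GenomicRanges::seqnames(gr))[idx[1L]],
      strand = strand_chr[idx[1L]],
      exons = cbind(GenomicRanges::start(gr)[ex], GenomicRanges::end(gr)[ex]),
      cds = cbind(GenomicRanges::start(gr)[cd], GenomicRanges::end(gr)[cd])
    )
    if (!m$consistent) {
      warning("transcript ", t, ": CDS feature outside exons; model flagged")
    }
    models[[t]] <- m
  }
  models
}

#' Spliced CDS sequence of a transcript
#'
#' Concatenates the CDS interval sequences in genomic order; on the minus
#' strand the reverse complement of that concatenation is returned, so the
#' result is always 5'->3' in transcript orientation.
#'
#' @param model A `TranscriptModel` with non-empty CDS.
#' @param genome A `GenomeSequence`.
#' @return DNA string.
#' @export
spliced_cds_sequence <- function(model, genome) {
  if (!nrow(model$cds)) stop("transcript ", model$transcript_id, " has no CDS")
  parts <- vapply(seq_len(nrow(model$cds)), function(i) {
    genome_subseq(genome, model$chrom, model$cds[i, 1L], model$cds[i, 2L])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") .revcomp(s) else s
}

#' Map a genomic position to CDS and protein coordinates
#'
#' Counts transcript-oriented coding bases: on the minus strand the mapping
#' runs antiparallel to genomic coordinates. Errors distinguish intronic, UTR
#' (exonic non-coding) and outside-transcript positions.
#'
#' @param model A `TranscriptModel`.
#' @param genomic_pos 1-based genomic position inside a CDS interval.
#' @return List with `cds_pos`, `protein_pos` (both 1-based) and
#'   `codon_offset` (0..2).
#' @export
genomic_to_protein_position <- function(model, genomic_pos) {
  cds <- model$cds
  in_cds <- which(genomic_pos >= cds[, 1L] & genomic_pos <= cds[, 2L])
  if (!length(in_cds)) {
    ex <- model$exons
    if (any(genomic_pos >= ex[, 1L] & genomic_pos <= ex[, 2L])) {
      stop("position ", genomic_pos, " is exonic but outside CDS (UTR) on ",
           model$transcript_id)
    }
    if (genomic_pos >= min(ex[, 1L]) && genomic_pos <= max(ex[, 2L])) {
      stop("position ", genomic_pos, " is intronic on ", model$transcript_id)
    }
    stop("position ", genomic_pos, " is outside CDS (outside transcript ",
         model$transcript_id, ")")
  }
  i <- in_cds[1L]
  if (model$strand == "+") {
    before <- if (i > 1L) sum(cds[seq_len(i - 1L), 2L] -
                              cds[seq_len(i - 1L), 1L] + 1L) else 0L
    cds_pos <- before + (genomic_pos - cds[i, 1L] + 1L)
  } else {
    n <- nrow(cds)
    after <- if (i < n) sum(cds[seq(i + 1L, n), 2L] -
                            cds[seq(i + 1L, n), 1L] + 1L) else 0L
    cds_pos <- after + (cds[i, 2L] - genomic_pos + 1L)
  }
  list(cds_pos = as.integer(cds_pos),
       protein_pos = as.integer(ceiling(cds_pos / 3)),
       codon_offset = as.integer((cds_pos - 1L) %% 3L))
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s) %s:%s exons=%d cds=%dbp%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$cds_length,
              if (x$translatable) "" else " [not translatable]"))
  invisible(x)
}
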