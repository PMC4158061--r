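# Splice-junction polypeptide database: junctions absent from the gene models
# are translated in three (stranded) or six (unstranded) frames around the
# splice boundary, then filtered on read depth, length and stop codons.

.empty_junctions <- function() {
  data.frame(chrom = character(), intron_start = integer(),
             intron_end = integer(), strand = character(), depth = integer(),
             left_overhang = integer(), right_overhang = integer(),
             name = character(), stringsAsFactors = FALSE)
}

#' Parse a junction BED file
#'
#' Accepts either the TopHat `junctions.bed` BED12 two-block dialect (the
#' inner block boundaries define the intron; the score column is the read
#' depth) or a 6-column dialect whose interval is the intron itself in BED
#' half-open coordinates. The dialect is auto-detected from the column count.
#' BED12 records with a block count other than 2 are rejected with a warning.
#'
#' @param path BED file path.
#' @return data.frame of junctions with 1-based inclusive `intron_start`,
#'   `intron_end`, plus `strand`, `depth`, overhangs and `name`.
#' @export
parse_junction_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) return(.empty_junctions())
  score <- if (!is.null(gr$score)) as.integer(gr$score) else 0L
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    paste0("J", seq_along(gr))
  strand_chr <- as.character(GenomicRanges::strand(gr))
  strand_chr[strand_chr == "*"] <- "."
  if (!is.null(gr$blocks)) {
    nblk <- lengths(gr$blocks)
    bad <- which(nblk != 2L)
    if (length(bad)) {
      warning(length(bad), " BED12 record(s) with block count != 2 rejected")
    }
    keep <- which(nblk == 2L)
    if (!length(keep)) return(.empty_junctions())
    res <- do.call(rbind, lapply(keep, function(i) {
      blk <- gr$blocks[[i]]  # IRanges relative to range start, 1-based
      w1 <- IRanges::width(blk)[1L]
      w2 <- IRanges::width(blk)[2L]
      s <- GenomicRanges::start(gr)[i]  # 1-based chromStart+1
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[i],
                 intron_start = s + w1,
                 intron_end = s + IRanges::start(blk)[2L] - 2L,
                 strand = strand_chr[i], depth = score[i],
                 left_overhang = w1, right_overhang = w2,
                 name = nm[i], stringsAsFactors = FALSE)
    }))
  } else {
    res <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      intron_start = GenomicRanges::start(gr),
                      intron_end = GenomicRanges::end(gr),
                      strand = strand_chr, depth = score,
                      left_overhang = NA_integer_,
                      right_overhang = NA_integer_,
                      name = nm, stringsAsFactors = FALSE)
  }
  if (any(res$intron_start > res$intron_end)) {
    stop("junction with intron_start > intron_end in ", path)
  }
  rownames(res) <- NULL
  res
}

#' Splice junctions implied by gene models
#'
#' One junction per consecutive exon pair per transcript, deduplicated by
#' `(chrom, intron_start, intron_end)`. Single-exon transcripts contribute
#' nothing.
#'
#' @param models Named list of `TranscriptModel`.
#' @return data.frame of junctions (depth 0).
#' @export
known_junctions_from_models <- function(models) {
  rows <- list()
  for (m in models) {
    ex <- m$exons
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = m$chrom, intron_start = ex[i, 2L] + 1L,
        intron_end = ex[i + 1L, 1L] - 1L, strand = m$strand, depth = 0L,
        left_overhang = NA_integer_, right_overhang = NA_integer_,
        name = paste0(m$transcript_id, ".i", i), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_junctions())
  res <- do.call(rbind, rows)
  res[!duplicated(paste(res$chrom, res$intron_start, res$intron_end)), ,
      drop = FALSE]
}

.junction_key <- function(j, strand_aware) {
  if (strand_aware) paste(j$chrom, j$intron_start, j$intron_end, j$strand)
  else paste(j$chrom, j$intron_start, j$intron_end)
}

#' Junctions absent from a known set
#'
#' @param observed data.frame of observed junctions.
#' @param known data.frame of known junctions.
#' @param strand_aware Include strand in the identity key (default `FALSE`;
#'   aligner strand inference is unreliable, and strand-blind subtraction is
#'   the conservative choice).
#' @return Subset of `observed`, input order preserved.
#' @export
novel_junctions <- function(observed, known, strand_aware = FALSE) {
  if (!nrow(observed)) return(observed)
  keep <- !(.junction_key(observed, strand_aware) %in%
              .junction_key(known, strand_aware))
  res <- observed[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genomic sequence flanking a splice junction
#'
#' Concatenates the `flank_nt` exonic bases immediately 5' of the intron with
#' the `flank_nt` bases immediately 3' of it (intron excised), truncating at
#' chromosome ends. For a minus-strand junction the reverse complement is
#' returned with the junction offset adjusted, so the result is transcript
#' oriented. Returns `NULL` (with a warning) when the intron abuts a
#' chromosome edge leaving zero flank on one side.
#'
#' @param junction One-row junction data.frame (or list with the same fields).
#' @param genome A `GenomeSequence`.
#' @param flank_nt Flank length in nucleotides (>= 3).
#' @return List with `dna` and `junction_offset_nt` (number of nt 5' of the
#'   splice boundary in the returned string), or `NULL`.
#' @export
junction_flanking_sequence <- function(junction, genome, flank_nt = 66L) {
  stopifnot(flank_nt >= 3L)
  chrom_len <- nchar(genome[[junction$chrom]])
  la <- max(1L, junction$intron_start - flank_nt)
  lb <- junction$intron_start - 1L
  ra <- junction$intron_end + 1L
  rb <- min(chrom_len, junction$intron_end + flank_nt)
  if (lb < la || rb < ra) {
    warning("junction ", junction$chrom, ":", junction$intron_start, "-",
            junction$intron_end, " at chromosome edge; skipped")
    return(NULL)
  }
  left <- genome_subseq(genome, junction$chrom, la, lb)
  right <- genome_subseq(genome, junction$chrom, ra, rb)
  dna <- paste0(left, right)
  offset <- nchar(left)
  if (identical(junction$strand, "-")) {
    dna <- .revcomp(dna)
    offset <- nchar(right)
  }
  list(dna = dna, junction_offset_nt = as.integer(offset))
}

# 1-based residue whose codon contains the last nt 5' of the boundary in the
# given frame; residues whose codons were dropped ahead of the frame offset
# clamp to 1.
.junction_offset_aa <- function(offset_nt, frame) {
  if (offset_nt <= frame) return(1L)
  as.integer((offset_nt - frame - 1L) %/% 3L + 1L)
}

#' Translate a junction-flanking sequence
#'
#' For stranded junctions (`+`/`-`) the DNA is assumed already transcript
#' oriented and three frames are produced (orientation marker `+`). For
#' unstranded junctions (`.`) six frames are produced: three of the DNA as
#' given (marker `+`) and three of its reverse complement (marker `-`).
#'
#' @param dna Junction-flanking DNA.
#' @param strand `+`, `-` or `.`.
#' @param junction_offset_nt Nucleotides 5' of the splice boundary in `dna`.
#' @return data.frame with `frame`, `orientation`, `protein`,
#'   `junction_offset_aa`; zero rows if `dna` is shorter than 3 nt.
#' @export
translate_junction <- function(dna, strand, junction_offset_nt) {
  empty <- data.frame(frame = integer(), orientation = character(),
                      protein = character(), junction_offset_aa = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(dna) < 3L) return(empty)
  one_orientation <- function(d, off, marker) {
    do.call(rbind, lapply(0:2, function(f) {
      p <- translate_dna(d, f)
      if (!nchar(p)) return(NULL)
      data.frame(frame = f, orientation = marker, protein = p,
                 junction_offset_aa = min(.junction_offset_aa(off, f),
                                          nchar(p)),
                 stringsAsFactors = FALSE)
    }))
  }
  res <- if (strand %in% c("+", "-")) {
    one_orientation(dna, junction_offset_nt, "+")
  } else {
    rbind(one_orientation(dna, junction_offset_nt, "+"),
          one_orientation(.revcomp(dna), nchar(dna) - junction_offset_nt, "-"))
  }
  if (is.null(res)) empty else res
}

#' Build a splice-junction polypeptide database
#'
#' Pipeline: parse the observed junction BED, subtract known junctions (from
#' a BED or from gene models), extract flanking genomic sequence, translate,
#' and filter. Junctions with `depth < min_depth` are dropped; translations
#' shorter than `min_len_aa` residues, or whose junction codon falls outside
#' the translation, are dropped; with `drop_stop`, translations containing
#' `*` are dropped.
#'
#' @param observed_bed Path to the observed junction BED.
#' @param known Either a path to a known-junction BED or a named list of
#'   `TranscriptModel` (gene models).
#' @param genome A `GenomeSequence`.
#' @param flank_nt Nucleotides of flank on each side (default 66 = 22 codons).
#' @param min_len_aa Minimum translated length in residues (default 8).
#' @param min_depth Minimum junction read depth, compared as
#'   `depth >= min_depth` (default 4, the mouse-islet setting).
#' @param drop_stop Drop translations containing stop codons (default `TRUE`).
#' @param strand_aware Strand-aware novelty subtraction (default `FALSE`).
#' @return A `FastaDatabase` (tag `splice`) with header grammar
#'   `jnc|<chrom>:<start>-<end>|s.<strand>|f.<frame><orientation>|d.<depth>|o.<offset_aa>`
#'   and a `report` attribute with per-filter removal counts.
#' @export
build_splice_database <- function(observed_bed, known, genome,
                                  flank_nt = 66L, min_len_aa = 8L,
                                  min_depth = 4L, drop_stop = TRUE,
                                  strand_aware = FALSE) {
  observed <- parse_junction_bed(observed_bed)
  known_j <- if (is.character(known)) parse_junction_bed(known)
             else known_junctions_from_models(known)
  novel <- novel_junctions(observed, known_j, strand_aware = strand_aware)
  report <- list(n_observed = nrow(observed), n_novel = nrow(novel),
                 removed_depth = 0L, removed_edge = 0L, removed_short = 0L,
                 removed_stop = 0L, n_entries = 0L)
  headers <- character(); seqs <- character()
  for (i in seq_len(nrow(novel))) {
    j <- novel[i, ]
    if (j$depth < min_depth) {
      report$removed_depth <- report$removed_depth + 1L
      next
    }
    fl <- withCallingHandlers(
      junction_flanking_sequence(j, genome, flank_nt),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(fl)) {
      report$removed_edge <- report$removed_edge + 1L
      next
    }
    tr <- translate_junction(fl$dna, j$strand, fl$junction_offset_nt)
    for (k in seq_len(nrow(tr))) {
      p <- tr$protein[k]
      if (nchar(p) < min_len_aa) {
        report$removed_short <- report$removed_short + 1L
        next
      }
      if (drop_stop && grepl("*", p, fixed = TRUE)) {
        report$removed_stop <- report$removed_stop + 1L
        next
      }
      headers <- c(headers, sprintf("jnc|%s:%d-%d|s.%s|f.%d%s|d.%d|o.%d",
                                    j$chrom, j$intron_start, j$intron_end,
                                    j$strand, tr$frame[k], tr$orientation[k],
                                    j$depth, tr$junction_offset_aa[k]))
      seqs <- c(seqs, p)
    }
  }
  db <- fasta_database(headers, seqs, tag = "splice")
  report$n_entries <- nrow(db)
  attr(db, "report") <- report
  db
}
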