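# Single amino acid polymorphism (SAP) database construction: turns annotated
# missense SNVs into short SAP-containing polypeptide windows suitable for MS
# database searching.

.aa3to1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*"
)
.aa1to3 <- setNames(names(.aa3to1), .aa3to1)

.parse_hgvs_p <- function(s) {
  # p.Tyr5Cys -> list(ref="Y", pos=5, alt="C"); NULL on failure
  m <- regmatches(s, regexec("^p\\.([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$", s))[[1]]
  if (length(m) != 4L) return(NULL)
  ref <- .aa3to1[m[2]]; alt <- .aa3to1[m[4]]
  if (is.na(ref) || is.na(alt)) return(NULL)
  list(ref = unname(ref), pos = as.integer(m[3]), alt = unname(alt))
}

#' Parse missense variant effects from an annotated VCF
#'
#' Reads a VCF carrying SnpEff-style `ANN` INFO annotations and returns one
#' effect per (variant, transcript) annotation pair. Only missense effects on
#' single-nucleotide substitutions are retained; multi-allelic sites are
#' expanded per alternate allele. Malformed annotations are skipped with a
#' warning and counted in the `n_skipped_malformed` attribute.
#'
#' @param path VCF file path (v4.x, `ANN` INFO key).
#' @return data.frame with columns `chrom`, `genomic_pos`, `ref_allele`,
#'   `alt_allele`, `transcript_id`, `effect_class`, `ref_aa`, `alt_aa`,
#'   `protein_pos`, `cds_pos`.
#' @export
parse_variant_effects <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  if (!"ANN" %in% colnames(info)) stop("VCF has no ANN INFO field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alts <- lapply(rr$ALT, as.character)
  ann <- info$ANN
  out <- list()
  n_malformed <- 0L
  for (i in seq_along(rr)) {
    for (a in ann[[i]]) {
      f <- strsplit(a, "|", fixed = TRUE)[[1]]
      if (length(f) < 11L) { n_malformed <- n_malformed + 1L; next }
      allele <- f[1]; effect <- f[2]; tid <- f[7]; hgvs_p <- f[11]
      if (!allele %in% alts[[i]]) { n_malformed <- n_malformed + 1L; next }
      if (!grepl("missense", effect)) next
      if (nchar(ref[i]) != 1L || nchar(allele) != 1L) next
      p <- .parse_hgvs_p(hgvs_p)
      if (is.null(p)) { n_malformed <- n_malformed + 1L; next }
      cds_pos <- NA_integer_
      if (length(f) >= 13L && nzchar(f[13])) {
        cds_pos <- suppressWarnings(as.integer(sub("/.*$", "", f[13])))
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom[i], genomic_pos = pos[i], ref_allele = ref[i],
        alt_allele = allele, transcript_id = tid, effect_class = "missense",
        ref_aa = p$ref, alt_aa = p$alt, protein_pos = p$pos,
        cds_pos = cds_pos, stringsAsFactors = FALSE
      )
    }
  }
  if (n_malformed > 0L) {
    warning(n_malformed, " malformed/unmatched ANN annotation(s) skipped")
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    chrom = character(), genomic_pos = integer(), ref_allele = character(),
    alt_allele = character(), transcript_id = character(),
    effect_class = character(), ref_aa = character(), alt_aa = character(),
    protein_pos = integer(), cds_pos = integer(), stringsAsFactors = FALSE
  )
  attr(res, "n_skipped_malformed") <- n_malformed
  res
}

#' Apply a single amino acid substitution to a protein
#'
#' Verifies the annotated reference residue before substituting; a mismatch
#' (annotation/genome build inconsistency) is an error, never a silent edit.
#'
#' @param protein Protein string.
#' @param protein_pos 1-based residue position.
#' @param ref_aa,alt_aa Single-letter amino acids.
#' @return Protein string with `alt_aa` at `protein_pos`.
#' @export
apply_sap <- function(protein, protein_pos, ref_aa, alt_aa) {
  L <- nchar(protein)
  if (protein_pos < 1L || protein_pos > L) {
    stop("protein_pos ", protein_pos, " outside 1..", L)
  }
  found <- substr(protein, protein_pos, protein_pos)
  if (found != ref_aa) {
    stop(sprintf("reference mismatch at position %d: protein has %s, annotation says %s",
                 protein_pos, found, ref_aa))
  }
  paste0(substr(protein, 1L, protein_pos - 1L), alt_aa,
         substr(protein, protein_pos + 1L, L))
}

#' Extract the flanking window around a SAP
#'
#' Returns the residues `[max(1, pos-flank) .. min(L, pos+flank)]`, silently
#' truncated at the protein termini.
#'
#' @param protein Protein string (already carrying the SAP).
#' @param protein_pos 1-based SAP position.
#' @param flank Non-negative number of residues on each side.
#' @return List with `window`, `window_start` (1-based position of the first
#'   window residue in the full protein) and `sap_offset` (1-based SAP
#'   position within the window).
#' @export
sap_window <- function(protein, protein_pos, flank) {
  stopifnot(flank >= 0L)
  L <- nchar(protein)
  if (protein_pos < 1L || protein_pos > L) {
    stop("protein_pos ", protein_pos, " outside 1..", L)
  }
  a <- max(1L, protein_pos - flank)
  b <- min(L, protein_pos + flank)
  list(window = substr(protein, a, b), window_start = as.integer(a),
       sap_offset = as.integer(protein_pos - a + 1L))
}

.complement1 <- function(b) chartr("ACGTN", "TGCAN", b)

.sap_header_block <- function(tid, chrom, gpos, ref, alt, cds_pos, refnt,
                              altnt, ref_aa, ppos, alt_aa, wstart, wend) {
  sprintf("sap|%s|g.%s:%d%s>%s|c.%d%s>%s|p.%s%d%s|w.%d-%d",
          tid, chrom, gpos, ref, alt, cds_pos, refnt, altnt,
          ref_aa, ppos, alt_aa, wstart, wend)
}

#' Build a SAP polypeptide database from missense effects
#'
#' For each missense effect: the transcript CDS is spliced and translated, the
#' annotated reference residue is verified against that translation, the
#' substitution applied, and a window of `flank` residues per side extracted.
#' Windows containing `*` (premature stop in the reference translation) are
#' dropped. Exact duplicate windows with identical SAP annotation are
#' collapsed to one entry whose header lists all source transcript blocks
#' joined by `;`.
#'
#' @param effects data.frame from [parse_variant_effects()].
#' @param models Named list of `TranscriptModel` from [load_gene_models()].
#' @param genome A `GenomeSequence`.
#' @param flank Residues kept either side of the SAP (default 20, enough for
#'   any fully tryptic peptide covering the SAP at two missed cleavages).
#' @param trust_annotation If `TRUE`, skip translation-based verification of
#'   the annotated reference residue (guards against genome/annotation version
#'   skew when `FALSE`, the default).
#' @return A `FastaDatabase` with a `report` attribute counting
#'   `n_effects`, `n_applied`, `n_skipped_missing_model`,
#'   `n_skipped_untranslatable`, `n_mismatch`, `n_dropped_stop_window`,
#'   `n_sites`, `n_entries`.
#' @export
build_sap_database <- function(effects, models, genome, flank = 20L,
                               trust_annotation = FALSE) {
  report <- list(n_effects = nrow(effects), n_applied = 0L,
                 n_skipped_missing_model = 0L, n_skipped_untranslatable = 0L,
                 n_mismatch = 0L, n_dropped_stop_window = 0L)
  recs <- list()
  for (i in seq_len(nrow(effects))) {
    e <- effects[i, ]
    m <- models[[e$transcript_id]]
    if (is.null(m)) {
      warning("transcript ", e$transcript_id, " not in gene models; skipped")
      report$n_skipped_missing_model <- report$n_skipped_missing_model + 1L
      next
    }
    if (!m$translatable || !m$consistent) {
      report$n_skipped_untranslatable <- report$n_skipped_untranslatable + 1L
      next
    }
    coords <- tryCatch(genomic_to_protein_position(m, e$genomic_pos),
                       error = function(err) NULL)
    if (is.null(coords)) {
      report$n_mismatch <- report$n_mismatch + 1L
      next
    }
    protein <- translate_dna(spliced_cds_sequence(m, genome), 0L)
    protein <- sub("\\*$", "", protein)  # drop the terminal stop only
    if (coords$protein_pos > nchar(protein)) {
      report$n_mismatch <- report$n_mismatch + 1L
      next
    }
    if (!trust_annotation &&
        substr(protein, coords$protein_pos, coords$protein_pos) != e$ref_aa) {
      report$n_mismatch <- report$n_mismatch + 1L
      next
    }
    mutated <- tryCatch(
      apply_sap(protein, coords$protein_pos,
                substr(protein, coords$protein_pos, coords$protein_pos),
                e$alt_aa),
      error = function(err) NULL)
    if (is.null(mutated)) {
      report$n_mismatch <- report$n_mismatch + 1L
      next
    }
    w <- sap_window(mutated, coords$protein_pos, flank)
    if (grepl("*", w$window, fixed = TRUE)) {
      report$n_dropped_stop_window <- report$n_dropped_stop_window + 1L
      next
    }
    refnt <- if (m$strand == "+") e$ref_allele else .complement1(e$ref_allele)
    altnt <- if (m$strand == "+") e$alt_allele else .complement1(e$alt_allele)
    hdr <- .sap_header_block(e$transcript_id, e$chrom, e$genomic_pos,
                             e$ref_allele, e$alt_allele, coords$cds_pos,
                             refnt, altnt, e$ref_aa, coords$protein_pos,
                             e$alt_aa, w$window_start,
                             w$window_start + nchar(w$window) - 1L)
    recs[[length(recs) + 1L]] <- list(
      header = hdr, sequence = w$window, sap_offset = w$sap_offset,
      site = paste(e$chrom, e$genomic_pos, e$alt_allele, sep = ":"),
      dedupe_key = paste(w$window, e$ref_aa, e$alt_aa, w$sap_offset,
                         sep = "\x01"))
    report$n_applied <- report$n_applied + 1L
  }
  headers <- character(); seqs <- character()
  if (length(recs)) {
    keys <- vapply(recs, `[[`, character(1), "dedupe_key")
    for (k in unique(keys)) {
      grp <- recs[keys == k]
      headers <- c(headers, paste(vapply(grp, `[[`, character(1), "header"),
                                  collapse = ";"))
      seqs <- c(seqs, grp[[1L]]$sequence)
    }
  }
  db <- fasta_database(headers, seqs, tag = "sap")
  report$n_sites <- length(unique(vapply(recs, `[[`, character(1), "site")))
  report$n_entries <- nrow(db)
  attr(db, "report") <- report
  db
}
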