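# Transcript-abundance guided database reduction: annotate each protein entry
# with the TPM of its transcript and keep entries whose transcript abundance
# is strictly above a threshold ("above 1 TPM" by default).

#' Load an RSEM-style transcript abundance table
#'
#' Expects a tab-separated file with a header row containing `transcript_id`
#' and `TPM` columns (any other columns ignored).
#'
#' @param path TSV path.
#' @return data.frame with `transcript_id` and `tpm`.
#' @export
load_abundance <- function(path) {
  if (!file.exists(path)) stop("abundance table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"transcript_id" %in% colnames(tab)) {
    stop("abundance table lacks a transcript_id column")
  }
  if (!"TPM" %in% colnames(tab)) stop("abundance table lacks a TPM column")
  if (anyDuplicated(tab$transcript_id)) {
    stop("duplicate transcript_id in abundance table: ",
         tab$transcript_id[duplicated(tab$transcript_id)][1L])
  }
  tpm <- as.numeric(tab$TPM)
  if (anyNA(tpm)) stop("non-numeric TPM value in abundance table")
  if (any(tpm < 0)) stop("negative TPM value in abundance table")
  data.frame(transcript_id = as.character(tab$transcript_id), tpm = tpm,
             stringsAsFactors = FALSE)
}

.protein_entry_id <- function(header) sub("\\s.*$", "", header)

#' Link protein entries to transcripts
#'
#' Mapping sources in decreasing precedence: an explicit two-column TSV
#' (`protein_id`, `transcript_id`), GTF `protein_id`/`transcript_id` pairs,
#' and Ensembl-style header parsing (`... transcript:ENSTxxxx ...`). Proteins
#' found in no source are reported, not errors.
#'
#' @param proteome A `FastaDatabase`.
#' @param models Optional named list of `TranscriptModel` (GTF source).
#' @param explicit_map Optional path to a two-column TSV, or a data.frame
#'   with columns `protein_id` and `transcript_id`.
#' @return List with `map` (named character vector protein id -> transcript
#'   id) and `unmapped` (character vector of protein ids).
#' @export
map_proteins_to_transcripts <- function(proteome, models = NULL,
                                        explicit_map = NULL) {
  pids <- .protein_entry_id(proteome$header)
  map <- setNames(rep(NA_character_, length(pids)), pids)
  # lowest precedence first; later sources overwrite
  has_hit <- grepl("transcript:", proteome$header, fixed = TRUE)
  map[has_hit] <- sub("^transcript:", "",
                      regmatches(proteome$header,
                                 regexpr("transcript:[^ |]+",
                                         proteome$header)))
  if (!is.null(models)) {
    for (m in models) {
      if (!is.na(m$protein_id) && m$protein_id %in% pids) {
        map[[m$protein_id]] <- m$transcript_id
      }
    }
  }
  if (!is.null(explicit_map)) {
    em <- if (is.character(explicit_map)) {
      utils::read.delim(explicit_map, stringsAsFactors = FALSE)
    } else explicit_map
    stopifnot(all(c("protein_id", "transcript_id") %in% colnames(em)))
    keep <- em$protein_id %in% pids
    map[em$protein_id[keep]] <- em$transcript_id[keep]
  }
  list(map = map, unmapped = names(map)[is.na(map)])
}

#' Annotate a proteome with TPM and build the reduced database
#'
#' The annotated database carries every entry with its header suffixed
#' ` TPM=<value|NA>`; entry order and sequences are never altered. The
#' reduced database keeps entries whose transcript TPM is strictly greater
#' than `threshold_tpm` ("above" the threshold). Entries that are unmapped or
#' absent from the abundance table are kept only when `keep_unmapped = TRUE`.
#'
#' @param proteome A `FastaDatabase`.
#' @param mapping Result of [map_proteins_to_transcripts()].
#' @param abundance data.frame from [load_abundance()].
#' @param threshold_tpm Abundance threshold (default 1 TPM).
#' @param keep_unmapped Keep entries with no TPM value (default `FALSE`).
#' @return List with `annotated` and `reduced` (both `FastaDatabase`) and
#'   `report` (counts of kept / removed / unmapped).
#' @export
annotate_and_reduce <- function(proteome, mapping, abundance,
                                threshold_tpm = 1, keep_unmapped = FALSE) {
  stopifnot(threshold_tpm >= 0)
  tpm_by_tx <- setNames(abundance$tpm, abundance$transcript_id)
  pids <- .protein_entry_id(proteome$header)
  tx <- unname(mapping$map[pids])
  tpm <- ifelse(is.na(tx), NA_real_, unname(tpm_by_tx[tx]))
  tpm_str <- vapply(tpm, function(x) {
    if (is.na(x)) "NA" else format(x, trim = TRUE, scientific = FALSE)
  }, character(1))
  ann_header <- paste0(proteome$header, " TPM=", tpm_str)
  annotated <- fasta_database(ann_header, proteome$sequence, proteome$tag)
  keep <- ifelse(is.na(tpm), keep_unmapped, tpm > threshold_tpm)
  reduced <- annotated[keep, , drop = FALSE]
  class(reduced) <- class(annotated)
  rownames(reduced) <- NULL
  list(annotated = annotated, reduced = reduced,
       report = list(n_input = nrow(proteome), n_kept = sum(keep),
                     n_removed = sum(!keep), n_unmapped = sum(is.na(tpm)),
                     threshold_tpm = threshold_tpm,
                     keep_unmapped = keep_unmapped))
}

#' Rank correlation between transcript abundance and spectral counts
#'
#' Spectral count per protein is the number of peptide-spectrum matches when
#' spectrum ids are available, otherwise the number of distinct peptide
#' sequences (the mode used is recorded in the result). Spearman rank
#' correlation (ties mid-ranked) is computed over proteins with both a count
#' and a TPM value; with fewer than 3 such proteins the coefficient is
#' reported as `NA` (undefined).
#'
#' @param abundance data.frame from [load_abundance()].
#' @param peptide_ids data.frame with columns `peptide`, `protein_id` and
#'   optionally `spectrum_id`.
#' @param mapping Result of [map_proteins_to_transcripts()].
#' @return List with `rho`, `n`, `count_mode` and a per-protein `table` of
#'   spectral count vs TPM.
#' @export
rna_protein_correlation <- function(abundance, peptide_ids, mapping) {
  stopifnot(nrow(peptide_ids) > 0L)
  has_spectra <- "spectrum_id" %in% colnames(peptide_ids) &&
    !anyNA(peptide_ids$spectrum_id)
  counts <- if (has_spectra) {
    tapply(peptide_ids$spectrum_id, peptide_ids$protein_id,
           function(x) length(x))
  } else {
    tapply(peptide_ids$peptide, peptide_ids$protein_id,
           function(x) length(unique(x)))
  }
  tpm_by_tx <- setNames(abundance$tpm, abundance$transcript_id)
  tx <- mapping$map[names(counts)]
  tpm <- unname(tpm_by_tx[tx])
  tab <- data.frame(protein_id = names(counts),
                    spectral_count = as.integer(counts), tpm = tpm,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  ok <- !is.na(tab$tpm)
  n <- sum(ok)
  rho <- if (n < 3L) NA_real_ else
    stats::cor(tab$spectral_count[ok], tab$tpm[ok], method = "spearman")
  list(rho = rho, n = n,
       count_mode = if (has_spectra) "psm" else "distinct_peptide",
       table = tab)
}
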