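# Search-database assembly: concatenate builder outputs with the reference
# proteome and contaminants, then add reversed-sequence decoys.

#' Merge protein databases
#'
#' Concatenates parts preserving part order. Header collisions are resolved
#' by suffixing the later entry's provenance tag (and an index if still
#' colliding). In `collapse` mode, entries with identical sequences are
#' merged into one entry whose header concatenates the originals with `;`.
#'
#' @param parts List of `FastaDatabase` objects (length >= 1).
#' @param on_duplicate_sequence `"keep_all"` (default) or `"collapse"`.
#' @return A `FastaDatabase`.
#' @export
merge_databases <- function(parts, on_duplicate_sequence = c("keep_all",
                                                             "collapse")) {
  on_duplicate_sequence <- match.arg(on_duplicate_sequence)
  stopifnot(length(parts) >= 1L)
  merged <- do.call(rbind, lapply(parts, function(p) {
    data.frame(header = p$header, sequence = p$sequence, tag = p$tag,
               stringsAsFactors = FALSE)
  }))
  # resolve header collisions with provenance suffixes
  dup <- duplicated(merged$header)
  if (any(dup)) {
    merged$header[dup] <- paste0(merged$header[dup], "|", merged$tag[dup])
    dup2 <- duplicated(merged$header)
    if (any(dup2)) {
      merged$header[dup2] <- paste0(merged$header[dup2], "|",
                                    seq_len(sum(dup2)))
    }
  }
  if (on_duplicate_sequence == "collapse") {
    first <- !duplicated(merged$sequence)
    hdr <- tapply(merged$header,
                  factor(merged$sequence, levels = merged$sequence[first]),
                  paste, collapse = ";")
    merged <- data.frame(header = as.character(hdr),
                         sequence = merged$sequence[first],
                         tag = merged$tag[first], stringsAsFactors = FALSE)
  }
  fasta_database(merged$header, merged$sequence, merged$tag)
}

#' Generate a reversed-sequence decoy database
#'
#' One decoy per target in target order: the sequence fully reversed and the
#' header prefixed `rev_`. Palindromic sequences (decoy equal to target) are
#' allowed and counted in the `n_palindromic` attribute.
#'
#' @param db Non-empty target `FastaDatabase`.
#' @param method Decoy generation method; only `"reverse"` is supported.
#' @return A `FastaDatabase` of decoys (tag `decoy`).
#' @export
generate_decoys <- function(db, method = "reverse") {
  method <- match.arg(method, "reverse")
  stopifnot(nrow(db) > 0L)
  rev_seq <- vapply(db$sequence, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  decoys <- fasta_database(paste0("rev_", db$header), rev_seq, "decoy")
  attr(decoys, "n_palindromic") <- sum(rev_seq == db$sequence)
  decoys
}

#' Assemble a complete target-decoy search database
#'
#' Convenience wrapper: merges the given parts (typically reduced reference +
#' SAP + splice + contaminants) and appends reversed decoys of the merged
#' targets.
#'
#' @inheritParams merge_databases
#' @param decoys Add reversed decoys (default `TRUE`).
#' @return A `FastaDatabase` of targets followed by decoys.
#' @export
assemble_search_database <- function(parts,
                                     on_duplicate_sequence = "keep_all",
                                     decoys = TRUE) {
  targets <- merge_databases(parts, on_duplicate_sequence)
  if (!decoys) return(targets)
  merge_databases(list(targets, generate_decoys(targets)))
}

#' Bundled synthetic contaminant database
#'
#' A small synthetic stand-in for a common-contaminants FASTA (e.g. cRAP),
#' for tests and examples only; real searches should supply the genuine
#' contaminant database.
#'
#' @return A `FastaDatabase` (tag `contaminant`).
#' @export
synthetic_contaminants <- function() {
  path <- system.file("extdata", "contaminants_synthetic.fasta",
                      package = "rnaseq2protdb", mustWork = TRUE)
  read_fasta_db(path, tag = "contaminant")
}
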