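#' Construct a protein FASTA database
#'
#' The common output currency of all database builders: an ordered set of
#' protein records with structured headers and a per-entry provenance tag
#' (`reference`, `sap`, `splice`, `contaminant`, `decoy`).
#'
#' @param header Character vector of headers (without the leading `>`).
#' @param sequence Character vector of protein sequences (20 AA plus X and
#'   `*`).
#' @param tag Provenance tag, recycled to length.
#' @return A `FastaDatabase` (data.frame subclass).
#' @export
fasta_database <- function(header = character(), sequence = character(),
                           tag = "reference") {
  stopifnot(length(header) == length(sequence))
  if (length(sequence) && any(nchar(sequence) == 0L)) {
    stop("FastaDatabase entries must have non-empty sequences")
  }
  if (anyDuplicated(header)) {
    stop("duplicate headers in FastaDatabase: ",
         paste(utils::head(unique(header[duplicated(header)]), 3),
               collapse = ", "))
  }
  db <- data.frame(header = as.character(header),
                   sequence = as.character(sequence),
                   tag = rep_len(as.character(tag), length(header)),
                   stringsAsFactors = FALSE)
  class(db) <- c("FastaDatabase", "data.frame")
  db
}

#' Read a protein FASTA file
#'
#' @param path FASTA file path.
#' @param tag Provenance tag to assign every entry.
#' @return A `FastaDatabase`.
#' @export
read_fasta_db <- function(path, tag = "reference") {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  fasta_database(names(ss), toupper(as.character(ss)), tag)
}

#' Write a protein FASTA file
#'
#' Deterministic output: 60-column wrapped, entries in database order, so
#' identical databases produce byte-identical files.
#'
#' @param db A `FastaDatabase`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta_db <- function(db, path, width = 60L) {
  con <- file(path, open = "wb")  # binary: fixed \n line endings
  on.exit(close(con))
  for (i in seq_len(nrow(db))) {
    writeLines(paste0(">", db$header[i]), con, sep = "\n")
    s <- db$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' @export
print.FastaDatabase <- function(x, ...) {
  cat("FastaDatabase:", nrow(x), "entries\n")
  if (nrow(x)) {
    tab <- table(x$tag)
    cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  }
  invisible(x)
}
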