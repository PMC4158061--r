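# Post-search novel-peptide filtering: partition identified peptides into
# reference-matching vs novel, annotate novel peptides against the custom
# SAP/splice databases, and summarize unique variant sites.

#' Normalize a peptide sequence string
#'
#' Strips common modification notation so only the bare uppercase sequence
#' remains: bracketed tokens `[...]`, `(...)`, `{...}` are removed, then any
#' remaining non-uppercase-letter characters (lowercase modification letters,
#' digits, punctuation) are dropped, and the result is validated against the
#' 20 amino-acid alphabet.
#'
#' @param peptide Character vector of peptide strings.
#' @return Character vector of bare uppercase peptide sequences.
#' @export
normalize_peptide <- function(peptide) {
  s <- gsub("\\[[^]]*\\]|\\([^)]*\\)|\\{[^}]*\\}", "", peptide)
  s <- gsub("[^A-Z]", "", s)
  bad <- grepl("[BJOUXZ]", s) | !nzchar(s)
  if (any(bad)) {
    stop("peptide(s) outside the 20 amino-acid alphabet after normalization: ",
         paste(utils::head(peptide[bad], 3), collapse = ", "))
  }
  s
}

#' Read a peptide identification table
#'
#' TSV with columns `peptide`, `score` and optionally `spectrum_id`.
#' Peptide strings are normalized with [normalize_peptide()].
#'
#' @param path TSV path.
#' @return data.frame of peptide identifications.
#' @export
read_peptide_ids <- function(path) {
  if (!file.exists(path)) stop("peptide table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"peptide" %in% colnames(tab)) stop("peptide column missing in ", path)
  tab$peptide <- normalize_peptide(tab$peptide)
  if (!"score" %in% colnames(tab)) tab$score <- NA_real_
  tab
}

.fold_il <- function(x) chartr("IL", "JJ", x)

#' Partition peptides into reference hits and novel peptides
#'
#' A peptide is a reference hit iff its sequence occurs as a contiguous
#' substring of any reference entry. With `equate_il = TRUE` (default),
#' isoleucine and leucine are treated as equivalent before matching, since
#' they are isobaric and indistinguishable in the MS workflow. The partition
#' is exhaustive and exclusive; input order is preserved within each part.
#'
#' @param peptides data.frame with at least a `peptide` column (e.g. from
#'   [read_peptide_ids()]), or a character vector of peptide sequences.
#' @param reference A `FastaDatabase`.
#' @param equate_il Fold I/L before matching (default `TRUE`).
#' @return List with `reference_hits` and `novel`, both subsets of the input.
#' @export
filter_in_reference <- function(peptides, reference, equate_il = TRUE) {
  stopifnot(nrow(reference) > 0L)
  if (is.character(peptides)) {
    peptides <- data.frame(peptide = peptides, stringsAsFactors = FALSE)
  }
  pep <- peptides$peptide
  refseq <- reference$sequence
  if (equate_il) {
    pep <- .fold_il(pep)
    refseq <- .fold_il(refseq)
  }
  # single scan against a separator-joined reference; '#' cannot occur in
  # either alphabet so no cross-entry matches arise
  haystack <- paste(refseq, collapse = "#")
  hit <- vapply(pep, function(p) grepl(p, haystack, fixed = TRUE),
                logical(1), USE.NAMES = FALSE)
  list(reference_hits = peptides[hit, , drop = FALSE],
       novel = peptides[!hit, , drop = FALSE])
}

.parse_sap_header_blocks <- function(header) {
  # header may be several ';'-joined sap| blocks after deduplication
  blocks <- strsplit(header, ";", fixed = TRUE)[[1]]
  out <- list()
  for (b in blocks) {
    f <- strsplit(b, "|", fixed = TRUE)[[1]]
    if (length(f) < 6L || f[1] != "sap") next
    g <- regmatches(f[3], regexec("^g\\.([^:]+):(\\d+)([A-Z])>([A-Z])$", f[3]))[[1]]
    p <- regmatches(f[5], regexec("^p\\.([A-Z*])(\\d+)([A-Z*])$", f[5]))[[1]]
    w <- regmatches(f[6], regexec("^w\\.(\\d+)-(\\d+)$", f[6]))[[1]]
    if (length(g) != 5L || length(p) != 4L || length(w) != 3L) next
    out[[length(out) + 1L]] <- list(
      chrom = g[2], genomic_pos = as.integer(g[3]), alt_allele = g[5],
      protein_pos = as.integer(p[3]),
      window_start = as.integer(w[2]),
      sap_offset = as.integer(p[3]) - as.integer(w[2]) + 1L)
  }
  out
}

.parse_jnc_header <- function(header) {
  f <- strsplit(header, "|", fixed = TRUE)[[1]]
  if (length(f) < 2L || f[1] != "jnc") return(NULL)
  m <- regmatches(f[2], regexec("^([^:]+):(\\d+)-(\\d+)$", f[2]))[[1]]
  if (length(m) != 4L) return(NULL)
  list(chrom = m[2], intron_start = as.integer(m[3]),
       intron_end = as.integer(m[4]))
}

.match_starts <- function(pep, seq) {
  # all 1-based start positions of fixed-pattern pep in seq
  m <- gregexpr(pep, seq, fixed = TRUE)[[1]]
  m[m > 0L]
}

#' Annotate novel peptides against custom databases
#'
#' Each novel peptide is matched (same substring semantics and I/L setting as
#' [filter_in_reference()]) against the SAP/splice databases used in the
#' search. The class is derived from matched header prefixes: `sap` requires
#' that the peptide overlap the SAP offset within the matched window (a match
#' in the wild-type stretch of a window does not count); any `jnc|` match
#' yields class `splice`; peptides matching nothing (or only wild-type
#' stretches) are class `other`. Variant site keys `(chrom, genomic_pos,
#' alt_allele)` and junction keys `(chrom, intron_start, intron_end)` are
#' parsed from the matched headers.
#'
#' @param novel data.frame with a `peptide` column, or character vector.
#' @param custom_dbs List of `FastaDatabase` objects (SAP and/or splice).
#' @param equate_il Fold I/L before matching (default `TRUE`).
#' @return data.frame with one row per novel peptide: `peptide`, `class`,
#'   `matched_headers` (`;`-joined), `sites` (list column of variant site
#'   keys), `junctions` (list column of junction keys).
#' @export
annotate_novel_peptides <- function(novel, custom_dbs, equate_il = TRUE) {
  if (is.character(novel)) {
    novel <- data.frame(peptide = novel, stringsAsFactors = FALSE)
  }
  all_headers <- unlist(lapply(custom_dbs, function(d) d$header))
  all_seqs <- unlist(lapply(custom_dbs, function(d) d$sequence))
  seqs_cmp <- if (equate_il) .fold_il(all_seqs) else all_seqs
  res <- lapply(seq_len(nrow(novel)), function(i) {
    pep <- novel$peptide[i]
    pep_cmp <- if (equate_il) .fold_il(pep) else pep
    matched <- character()
    sites <- list(); junctions <- list()
    is_sap <- FALSE; is_splice <- FALSE
    for (k in seq_along(all_seqs)) {
      starts <- .match_starts(pep_cmp, seqs_cmp[k])
      if (!length(starts)) next
      hdr <- all_headers[k]
      if (startsWith(hdr, "sap|")) {
        for (blk in .parse_sap_header_blocks(hdr)) {
          covers <- any(starts <= blk$sap_offset &
                          blk$sap_offset <= starts + nchar(pep) - 1L)
          if (covers) {
            is_sap <- TRUE
            matched <- c(matched, hdr)
            sites[[length(sites) + 1L]] <-
              c(chrom = blk$chrom, genomic_pos = blk$genomic_pos,
                alt_allele = blk$alt_allele)
          }
        }
      } else if (startsWith(hdr, "jnc|")) {
        jk <- .parse_jnc_header(hdr)
        if (!is.null(jk)) {
          is_splice <- TRUE
          matched <- c(matched, hdr)
          junctions[[length(junctions) + 1L]] <-
            c(chrom = jk$chrom, intron_start = jk$intron_start,
              intron_end = jk$intron_end)
        }
      }
    }
    cls <- if (is_sap) "sap" else if (is_splice) "splice" else "other"
    list(peptide = pep, class = cls,
         matched_headers = paste(unique(matched), collapse = ";"),
         sites = unique(sites), junctions = unique(junctions))
  })
  out <- data.frame(peptide = vapply(res, `[[`, character(1), "peptide"),
                    class = vapply(res, `[[`, character(1), "class"),
                    matched_headers = vapply(res, `[[`, character(1),
                                             "matched_headers"),
                    stringsAsFactors = FALSE)
  out$sites <- lapply(res, `[[`, "sites")
  out$junctions <- lapply(res, `[[`, "junctions")
  out
}

#' Summarize unique variant sites covered by SAP peptides
#'
#' Sites are keyed by `(chrom, genomic_pos, alt_allele)`. Peptides mapping to
#' multiple sites are counted toward each site and flagged; the sanity check
#' `n_unique_sites <= n_sap_peptides` is enforced only when every peptide
#' maps to a single site.
#'
#' @param annotations data.frame from [annotate_novel_peptides()].
#' @return List with `n_sap_peptides`, `n_unique_sites`,
#'   `n_multi_site_peptides` and a per-site `table`.
#' @export
unique_variant_sites <- function(annotations) {
  sap <- annotations[annotations$class == "sap", , drop = FALSE]
  n_pep <- nrow(sap)
  site_keys <- lapply(sap$sites, function(ss) {
    unique(vapply(ss, function(s) paste(s[["chrom"]], s[["genomic_pos"]],
                                        s[["alt_allele"]], sep = ":"),
                  character(1)))
  })
  n_multi <- sum(lengths(site_keys) > 1L)
  all_keys <- unlist(site_keys)
  uniq <- unique(all_keys)
  if (n_multi == 0L && length(uniq) > n_pep) {
    stop("internal error: more unique sites than SAP peptides")
  }
  tab <- if (length(uniq)) {
    data.frame(site = uniq,
               n_peptides = vapply(uniq, function(k)
                 sum(vapply(site_keys, function(s) k %in% s, logical(1))),
                 integer(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(site = character(), n_peptides = integer(),
               stringsAsFactors = FALSE)
  }
  list(n_sap_peptides = n_pep, n_unique_sites = length(uniq),
       n_multi_site_peptides = n_multi, table = tab)
}
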