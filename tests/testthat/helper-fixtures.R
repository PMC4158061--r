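# Shared helpers: tiny hand-written format fixtures and a cached synthetic
# fixture set so the generator runs once per suite.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  path
}

# one transcript, two exons (1..9, 101..109), fully coding, plus strand
tiny_gtf_lines <- function(strand = "+", tid = "T1", cds_ranges = NULL) {
  attrs <- sprintf('gene_id "G1"; transcript_id "%s"; protein_id "P1";', tid)
  ex <- rbind(c(1, 9), c(101, 109))
  if (is.null(cds_ranges)) cds_ranges <- ex
  c(
    apply(ex, 1, function(r) paste("chr1", "t", "exon", r[1], r[2], ".",
                                   strand, ".", attrs, sep = "\t")),
    apply(cds_ranges, 1, function(r) paste("chr1", "t", "CDS", r[1], r[2],
                                           ".", strand, "0", attrs,
                                           sep = "\t"))
  )
}

.fx_cache <- new.env(parent = emptyenv())

# cached full fixture set (default small preset, seed 1)
get_fx <- function(seed = 1L) {
  key <- paste0("fx", seed)
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- generate_fixture_set(
      file.path(tempdir(), paste0("fxset", seed)), seed = seed)
  }
  .fx_cache[[key]]
}

get_models <- function(fx) {
  key <- paste0("models", fx$manifest$seed)
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- load_gene_models(fx$gtf)
  }
  .fx_cache[[key]]
}

get_genome <- function(fx) {
  key <- paste0("genome", fx$manifest$seed)
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- load_genome(fx$genome_fasta)
  }
  .fx_cache[[key]]
}

# independent translation oracle used by tests (never translate_dna)
oracle_translate <- function(dna, frame = 0L) {
  gc_tab <- Biostrings::GENETIC_CODE
  n <- nchar(dna) - frame
  if (n < 3L) return("")
  starts <- frame + 1L + 3L * (seq_len(n %/% 3L) - 1L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(gc_tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}
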