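test_that("parse_junction_bed handles BED12, BED6 and bad block counts", {
  b12 <- write_tmp(paste("chr1", 100, 300, "J1", 12, "+", 100, 300, "0",
                         2, "20,20", "0,180", sep = "\t"), ".bed")
  j <- parse_junction_bed(b12)
  expect_equal(j$intron_start, 121L)
  expect_equal(j$intron_end, 280L)
  expect_equal(j$depth, 12L)
  expect_equal(j$left_overhang, 20L)

  b6 <- write_tmp("chr1\t120\t280\tJ1\t12\t+", ".bed")
  j6 <- parse_junction_bed(b6)
  expect_equal(j6$intron_start, 121L)
  expect_equal(j6$intron_end, 280L)
  expect_equal(j6$depth, 12L)

  b3 <- write_tmp(paste("chr1", 100, 400, "J1", 5, "+", 100, 400, "0",
                        3, "20,20,20", "0,150,280", sep = "\t"), ".bed")
  expect_warning(j3 <- parse_junction_bed(b3), "rejected")
  expect_equal(nrow(j3), 0L)
})

test_that("known_junctions_from_models emits deduplicated exon gaps", {
  attrs <- function(t) sprintf('gene_id "G"; transcript_id "%s";', t)
  gtf <- unlist(lapply(c("TA", "TB"), function(t) {
    paste("chr1", "t", "exon", c(1, 201), c(100, 300), ".", "+", ".",
          attrs(t), sep = "\t")
  }))
  gtf <- c(gtf, paste("chr1", "t", "exon", 500, 600, ".", "+", ".",
                      attrs("TC"), sep = "\t"))
  models <- load_gene_models(write_tmp(gtf, ".gtf"))
  k <- known_junctions_from_models(models)
  expect_equal(nrow(k), 1L)  # shared intron deduplicated; TC single exon
  expect_equal(k$intron_start, 101L)
  expect_equal(k$intron_end, 200L)
})

test_that("novel_junctions subtracts by intron key", {
  obs <- data.frame(chrom = "chr1", intron_start = c(10L, 50L),
                    intron_end = c(20L, 60L), strand = c("+", "-"),
                    depth = c(5L, 7L), stringsAsFactors = FALSE)
  known <- obs[1, ]
  expect_equal(novel_junctions(obs, known)$intron_start, 50L)
  # strand ignored by default
  flipped <- known
  flipped$strand <- "-"
  expect_equal(nrow(novel_junctions(known, flipped)), 0L)
  expect_equal(nrow(novel_junctions(known, flipped, strand_aware = TRUE)), 1L)
  expect_equal(nrow(novel_junctions(obs, obs)), 0L)
})

test_that("junction_flanking_sequence extracts, orients and truncates", {
  set.seed(42)
  chrseq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  g <- load_genome(write_tmp(c(">chr1", chrseq), ".fasta"))
  j <- list(chrom = "chr1", intron_start = 121L, intron_end = 280L,
            strand = "+")
  r <- junction_flanking_sequence(j, g, 6)
  expect_equal(r$dna, paste0(substr(chrseq, 115, 120),
                             substr(chrseq, 281, 286)))
  expect_equal(r$junction_offset_nt, 6L)

  jm <- j; jm$strand <- "-"
  rm_ <- junction_flanking_sequence(jm, g, 6)
  expect_equal(rm_$dna, oracle_revcomp(r$dna))
  expect_equal(rm_$junction_offset_nt, 6L)

  # left flank truncated to 1 base
  j2 <- list(chrom = "chr1", intron_start = 2L, intron_end = 100L,
             strand = "+")
  r2 <- junction_flanking_sequence(j2, g, 6)
  expect_equal(r2$junction_offset_nt, 1L)
  expect_equal(nchar(r2$dna), 7L)

  # intron at the very edge -> skipped with warning
  j3 <- list(chrom = "chr1", intron_start = 1L, intron_end = 100L,
             strand = "+")
  expect_warning(r3 <- junction_flanking_sequence(j3, g, 6), "edge")
  expect_null(r3)
})

test_that("translate_junction produces 3 stranded or 6 unstranded frames", {
  tr <- translate_junction("ATGTTTTGAAAA", "+", 6L)
  expect_equal(nrow(tr), 3L)
  expect_equal(nchar(tr$protein), c(4L, 3L, 3L))
  expect_equal(tr$protein[tr$frame == 0], "MF*K")

  tr6 <- translate_junction("ATGTTTTGAAAA", ".", 6L)
  expect_equal(nrow(tr6), 6L)
  expect_setequal(unique(tr6$orientation), c("+", "-"))

  expect_equal(nrow(translate_junction("AT", "+", 1L)), 0L)
})

test_that("splice pipeline recovers exactly the planted novel junctions", {
  fx <- get_fx()
  obs <- parse_junction_bed(fx$observed_bed)
  truth <- fx$manifest$junctions_novel
  expect_equal(nrow(obs),
               fx$manifest$junction_params$n_known_used + length(truth))
  nov <- novel_junctions(obs, known_junctions_from_models(get_models(fx)))
  expect_setequal(paste(nov$chrom, nov$intron_start, nov$intron_end),
                  vapply(truth, function(j)
                    paste(j$chrom, j$intron_start, j$intron_end),
                    character(1)))
  # subtraction never leaves a gene-model intron behind
  known <- known_junctions_from_models(get_models(fx))
  expect_length(intersect(paste(nov$intron_start, nov$intron_end),
                          paste(known$intron_start, known$intron_end)), 0L)
  # the known-junction BED is an equivalent subtraction source
  nov2 <- novel_junctions(obs, parse_junction_bed(fx$known_bed))
  expect_equal(nov, nov2)
})

test_that("emitted translations byte-match the manifest oracle", {
  fx <- get_fx()
  truth <- fx$manifest$junctions_novel
  flank <- fx$manifest$junction_params$flank_nt
  db <- build_splice_database(fx$observed_bed, get_models(fx), get_genome(fx),
                              flank_nt = flank, min_len_aa = 0L,
                              min_depth = 0L, drop_stop = FALSE)
  expected <- unlist(lapply(truth, function(j)
    vapply(j$frames, `[[`, character(1), "protein")))
  expect_setequal(db$sequence, expected)
  expect_equal(nrow(db), length(expected))
  # per-entry offsets present in headers
  expect_true(all(grepl("^jnc\\|.*\\|o\\.\\d+$", db$header)))
})

test_that("each filter removes exactly the manifest-predicted entries", {
  fx <- get_fx()
  truth <- fx$manifest$junctions_novel
  flank <- fx$manifest$junction_params$flank_nt
  params <- list(min_depth = 4L, min_len_aa = 8L, drop_stop = TRUE)
  predict <- function(min_depth, min_len_aa, drop_stop) {
    surv <- character(); rd <- 0L; rs <- 0L; rstop <- 0L
    for (j in truth) {
      if (j$depth < min_depth) { rd <- rd + 1L; next }
      for (f in j$frames) {
        if (f$len < min_len_aa) { rs <- rs + 1L; next }
        if (drop_stop && f$has_stop) { rstop <- rstop + 1L; next }
        surv <- c(surv, f$protein)
      }
    }
    list(surv = surv, removed_depth = rd, removed_short = rs,
         removed_stop = rstop)
  }
  db <- build_splice_database(fx$observed_bed, get_models(fx), get_genome(fx),
                              flank_nt = flank, min_len_aa = params$min_len_aa,
                              min_depth = params$min_depth,
                              drop_stop = params$drop_stop)
  exp <- predict(params$min_depth, params$min_len_aa, params$drop_stop)
  rep <- attr(db, "report")
  expect_equal(sort(db$sequence), sort(exp$surv))
  expect_equal(rep$removed_depth, exp$removed_depth)
  expect_equal(rep$removed_short, exp$removed_short)
  expect_equal(rep$removed_stop, exp$removed_stop)
})

test_that("raising any filter threshold is monotone non-increasing", {
  fx <- get_fx()
  n_at <- function(min_depth, min_len) {
    nrow(build_splice_database(fx$observed_bed, get_models(fx),
                               get_genome(fx), min_depth = min_depth,
                               min_len_aa = min_len, drop_stop = TRUE))
  }
  depths <- c(0L, 2L, 4L, 8L, 16L, 32L)
  counts_d <- vapply(depths, n_at, integer(1), min_len = 0L)
  expect_true(all(diff(counts_d) <= 0))
  lens <- c(0L, 8L, 20L, 40L, 50L)
  counts_l <- vapply(lens, function(l) n_at(0L, l), integer(1))
  expect_true(all(diff(counts_l) <= 0))
  # drop_stop only removes
  expect_lte(nrow(build_splice_database(fx$observed_bed, get_models(fx),
                                        get_genome(fx), min_depth = 0L,
                                        min_len_aa = 0L, drop_stop = TRUE)),
             nrow(build_splice_database(fx$observed_bed, get_models(fx),
                                        get_genome(fx), min_depth = 0L,
                                        min_len_aa = 0L, drop_stop = FALSE)))
})

test_that("min_depth above all planted depths leaves nothing", {
  fx <- get_fx()
  db <- build_splice_database(fx$observed_bed, get_models(fx), get_genome(fx),
                              min_depth = 1000L)
  expect_equal(nrow(db), 0L)
})
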