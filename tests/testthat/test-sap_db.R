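make_tiny_vcf <- function(rows) {
  write_tmp(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations">',
    "##contig=<ID=chr1,length=1000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    rows), ".vcf")
}

ann_str <- function(alt, effect, tid, hgvs_c, hgvs_p, cds = "14/300",
                    aa = "5/99") {
  sprintf("%s|%s|MODERATE|G1|G1|transcript|%s|protein_coding|1/1|%s|%s|14|%s|%s||",
          alt, effect, tid, hgvs_c, hgvs_p, cds, aa)
}

test_that("parse_variant_effects keeps missense, expands transcripts", {
  rows <- c(
    paste0("chr1\t100\t.\tA\tG\t.\tPASS\tANN=",
           ann_str("G", "missense_variant", "ENST01", "c.14A>G", "p.Tyr5Cys")),
    paste0("chr1\t200\t.\tC\tT\t.\tPASS\tANN=",
           ann_str("T", "synonymous_variant", "ENST01", "c.30C>T",
                   "p.Gly10Gly")),
    paste0("chr1\t300\t.\tG\tA\t.\tPASS\tANN=",
           ann_str("A", "missense_variant", "ENST02", "c.20G>A", "p.Arg7His"),
           ",",
           ann_str("A", "missense_variant", "ENST03", "c.20G>A", "p.Arg7His"))
  )
  eff <- parse_variant_effects(make_tiny_vcf(rows))
  expect_equal(nrow(eff), 3L)
  e1 <- eff[eff$transcript_id == "ENST01", ]
  expect_equal(e1$ref_aa, "Y")
  expect_equal(e1$alt_aa, "C")
  expect_equal(e1$protein_pos, 5L)
  expect_equal(e1$cds_pos, 14L)
  expect_setequal(eff$transcript_id[eff$genomic_pos == 300],
                  c("ENST02", "ENST03"))
})

test_that("parse_variant_effects skips malformed annotations with warning", {
  rows <- c(
    "chr1\t100\t.\tA\tG\t.\tPASS\tANN=G|missense_variant|broken",
    paste0("chr1\t200\t.\tA\tG\t.\tPASS\tANN=",
           ann_str("G", "missense_variant", "T1", "c.10A>G", "p.Met4Val")))
  expect_warning(eff <- parse_variant_effects(make_tiny_vcf(rows)),
                 "malformed")
  expect_equal(nrow(eff), 1L)
  expect_equal(attr(eff, "n_skipped_malformed"), 1L)
})

test_that("apply_sap substitutes and guards the reference residue", {
  expect_equal(apply_sap("MKTAYIAKQR", 5, "Y", "C"), "MKTACIAKQR")
  expect_equal(apply_sap("M", 1, "M", "V"), "V")
  expect_error(apply_sap("MKTA", 3, "Y", "C"), "mismatch")
  expect_error(apply_sap("MKTA", 9, "Y", "C"), "outside")
})

test_that("sap_window extracts and truncates at termini", {
  expect_equal(sap_window("MKTACIAKQR", 5, 3),
               list(window = "KTACIAK", window_start = 2L, sap_offset = 4L))
  expect_equal(sap_window("MKTACIAKQR", 5, 100),
               list(window = "MKTACIAKQR", window_start = 1L,
                    sap_offset = 5L))
  expect_equal(sap_window("MKTACIAKQR", 5, 0),
               list(window = "C", window_start = 5L, sap_offset = 1L))
})

test_that("build_sap_database recovers every planted window exactly", {
  fx <- get_fx()
  eff <- parse_variant_effects(fx$vcf)
  truth <- fx$manifest$variants
  expect_equal(nrow(eff), nrow(truth))  # synonymous filtered upstream
  db <- build_sap_database(eff, get_models(fx), get_genome(fx),
                           flank = fx$manifest$variant_params$flank)
  expect_setequal(db$sequence, truth$expected_window)
  expect_setequal(db$header, truth$expected_header)
  rep <- attr(db, "report")
  expect_equal(rep$n_applied, nrow(truth))
  expect_equal(rep$n_mismatch, 0L)
  # every window contains the planted alt residue at the recorded offset
  for (i in seq_len(nrow(truth))) {
    hit <- db[db$sequence == truth$expected_window[i], ]
    expect_equal(substr(hit$sequence[1], truth$sap_offset[i],
                        truth$sap_offset[i]), truth$alt_aa[i])
  }
})

test_that("window length law holds for all emitted records", {
  fx <- get_fx()
  truth <- fx$manifest$variants
  flank <- fx$manifest$variant_params$flank
  db <- build_sap_database(parse_variant_effects(fx$vcf), get_models(fx),
                           get_genome(fx), flank = flank)
  for (i in seq_len(nrow(truth))) {
    L <- nchar(fx$manifest$transcripts[[truth$transcript_id[i]]]$protein)
    pos <- truth$protein_pos[i]
    expect_equal(nchar(truth$expected_window[i]),
                 min(pos - 1, flank) + 1 + min(L - pos, flank))
  }
  expect_true(all(db$sequence %in% truth$expected_window))
})

test_that("empty effect list and forced mismatch are handled", {
  fx <- get_fx()
  eff <- parse_variant_effects(fx$vcf)
  empty <- eff[0, ]
  db0 <- build_sap_database(empty, get_models(fx), get_genome(fx))
  expect_equal(nrow(db0), 0L)

  bad <- eff[1, ]
  bad$ref_aa <- setdiff(c("A", "G"), bad$ref_aa)[1]  # force disagreement
  db1 <- build_sap_database(bad, get_models(fx), get_genome(fx))
  expect_equal(nrow(db1), 0L)
  expect_equal(attr(db1, "report")$n_mismatch, 1L)

  missing <- eff[1, ]
  missing$transcript_id <- "NOT_A_TX"
  expect_warning(db2 <- build_sap_database(missing, get_models(fx),
                                           get_genome(fx)), "not in gene")
  expect_equal(attr(db2, "report")$n_skipped_missing_model, 1L)
})

test_that("rebuilding from identical inputs is byte-identical", {
  fx <- get_fx()
  build <- function() {
    db <- build_sap_database(parse_variant_effects(fx$vcf), get_models(fx),
                             get_genome(fx), flank = 8)
    p <- tempfile(fileext = ".fasta")
    write_fasta_db(db, p)
    p
  }
  p1 <- build(); p2 <- build()
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("duplicate windows collapse with merged headers", {
  # two transcripts over the same CDS give identical windows
  g <- load_genome(write_tmp(c(">chr1", "ATGAAAGGGTGTTACTAG"), ".fasta"))
  attrs <- function(t) sprintf('gene_id "G"; transcript_id "%s";', t)
  gtf <- unlist(lapply(c("TA", "TB"), function(t) {
    c(paste("chr1", "t", "exon", 1, 18, ".", "+", ".", attrs(t), sep = "\t"),
      paste("chr1", "t", "CDS", 1, 18, ".", "+", "0", attrs(t), sep = "\t"))
  }))
  models <- load_gene_models(write_tmp(gtf, ".gtf"))
  eff <- do.call(rbind, lapply(c("TA", "TB"), function(t) data.frame(
    chrom = "chr1", genomic_pos = 7L, ref_allele = "G", alt_allele = "A",
    transcript_id = t, effect_class = "missense", ref_aa = "G",
    alt_aa = "R", protein_pos = 3L, cds_pos = 7L, stringsAsFactors = FALSE)))
  db <- build_sap_database(eff, models, g, flank = 2)
  expect_equal(nrow(db), 1L)
  expect_match(db$header, "sap\\|TA\\|.*;sap\\|TB\\|")
})
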