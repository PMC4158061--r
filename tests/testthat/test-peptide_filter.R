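test_that("normalize_peptide strips modification tokens", {
  expect_equal(normalize_peptide("M[+15.995]KTAYIAK"), "MKTAYIAK")
  expect_equal(normalize_peptide("MK(ox)TAC{carb}IAK"), "MKTACIAK")
  expect_equal(normalize_peptide("mKTA"), "KTA")
  expect_error(normalize_peptide("MKXTA"), "alphabet")
  expect_error(normalize_peptide("[mod]"), "alphabet")
})

test_that("filter_in_reference partitions by substring presence", {
  ref <- fasta_database("r1", "MKTAYIAK")
  r <- filter_in_reference(c("TAYIAK", "TACIAK"), ref)
  expect_equal(r$reference_hits$peptide, "TAYIAK")
  expect_equal(r$novel$peptide, "TACIAK")

  # I/L equivalence
  ref2 <- fasta_database("r1", "AMLLKA")
  hit <- filter_in_reference("MILK", ref2, equate_il = TRUE)
  expect_equal(nrow(hit$reference_hits), 1L)
  miss <- filter_in_reference("MILK", ref2, equate_il = FALSE)
  expect_equal(nrow(miss$reference_hits), 0L)
})

test_that("partition is exhaustive, exclusive and order preserving", {
  fx <- get_fx()
  proteome <- read_fasta_db(fx$proteome_fasta)
  peps <- read_peptide_ids(fx$peptide_tsv)
  r <- filter_in_reference(peps, proteome)
  expect_equal(nrow(r$reference_hits) + nrow(r$novel), nrow(peps))
  expect_length(intersect(r$reference_hits$spectrum_id,
                          r$novel$spectrum_id), 0L)
  expect_equal(c(r$reference_hits$spectrum_id, r$novel$spectrum_id)[
    order(match(c(r$reference_hits$spectrum_id, r$novel$spectrum_id),
                peps$spectrum_id))], peps$spectrum_id)
})

test_that("filter_in_reference agrees with a brute-force scan", {
  fx <- get_fx()
  proteome <- read_fasta_db(fx$proteome_fasta)
  peps <- read_peptide_ids(fx$peptide_tsv)
  for (il in c(TRUE, FALSE)) {
    r <- filter_in_reference(peps, proteome, equate_il = il)
    fold <- function(x) if (il) chartr("IL", "JJ", x) else x
    brute <- vapply(peps$peptide, function(p) {
      any(vapply(proteome$sequence, function(s)
        grepl(fold(p), fold(s), fixed = TRUE), logical(1)))
    }, logical(1))
    expect_setequal(r$reference_hits$peptide, peps$peptide[brute])
    expect_setequal(r$novel$peptide, peps$peptide[!brute])
  }
})

test_that("SAP matches must cover the SAP position to be classed sap", {
  # window MKTACIAK with SAP C at offset 5 (protein_pos 5, window from 1)
  sapdb <- fasta_database(
    "sap|T1|g.chr1:500A>G|c.14A>G|p.Y5C|w.1-8", "MKTACIAK", "sap")
  covering <- annotate_novel_peptides("TACIAK", list(sapdb))
  expect_equal(covering$class, "sap")
  expect_equal(covering$sites[[1]][[1]][["genomic_pos"]], "500")
  # wild-type stretch: no coverage of position 5
  wildtype <- annotate_novel_peptides("MKTA", list(sapdb))
  expect_equal(wildtype$class, "other")
  expect_equal(wildtype$matched_headers, "")
  # no match at all
  none <- annotate_novel_peptides("WWWWWW", list(sapdb))
  expect_equal(none$class, "other")
})

test_that("junction matches are classed splice with parsed keys", {
  jdb <- fasta_database("jnc|chr1:121-280|s.+|f.0+|d.12|o.3",
                        "MKWQRTAYPK", "splice")
  ann <- annotate_novel_peptides("WQRTAYPK", list(jdb))
  expect_equal(ann$class, "splice")
  expect_equal(ann$junctions[[1]][[1]][["intron_start"]], "121")
})

test_that("planted peptides are recovered with correct classes and sites", {
  fx <- get_fx()
  proteome <- read_fasta_db(fx$proteome_fasta)
  genome <- get_genome(fx)
  models <- get_models(fx)
  truth <- fx$manifest$peptides
  sapdb <- build_sap_database(parse_variant_effects(fx$vcf), models, genome,
                              flank = fx$manifest$variant_params$flank)
  spldb <- build_splice_database(
    fx$observed_bed, models, genome,
    flank_nt = fx$manifest$junction_params$flank_nt,
    min_depth = fx$manifest$junction_params$depth_range[1])
  parts <- filter_in_reference(read_peptide_ids(fx$peptide_tsv), proteome)
  expect_setequal(parts$reference_hits$peptide,
                  truth$peptide[truth$class == "reference"])
  ann <- annotate_novel_peptides(parts$novel, list(sapdb, spldb))
  got <- setNames(ann$class, ann$peptide)
  expect_true(all(got[truth$peptide[truth$class == "sap"]] == "sap"))
  expect_true(all(got[truth$peptide[truth$class == "junction"]] == "splice"))
  # every planted SAP peptide resolves to its planted site
  for (i in which(truth$class == "sap")) {
    sites <- ann$sites[[which(ann$peptide == truth$peptide[i])[1]]]
    keys <- vapply(sites, function(s) paste(s[["chrom"]], s[["genomic_pos"]],
                                            s[["alt_allele"]], sep = ":"),
                   character(1))
    expect_true(truth$key[i] %in% keys)
  }
})

test_that("unique_variant_sites counts peptides and sites", {
  mk_ann <- function(peptides, keys) {
    df <- data.frame(peptide = peptides, class = "sap",
                     matched_headers = "h", stringsAsFactors = FALSE)
    df$sites <- lapply(keys, function(k)
      list(c(chrom = "chr1", genomic_pos = k, alt_allele = "G")))
    df$junctions <- rep(list(list()), length(peptides))
    df
  }
  two_one <- unique_variant_sites(mk_ann(c("AAAK", "CCCK"), c("5", "5")))
  expect_equal(two_one$n_sap_peptides, 2L)
  expect_equal(two_one$n_unique_sites, 1L)
  three <- unique_variant_sites(mk_ann(c("AAAK", "CCCK", "DDDK"),
                                       c("1", "2", "3")))
  expect_equal(three$n_unique_sites, 3L)

  fx <- get_fx()
  truth <- fx$manifest$peptides
  n_sites <- length(unique(truth$key[truth$class == "sap"]))
  sapdb <- build_sap_database(parse_variant_effects(fx$vcf), get_models(fx),
                              get_genome(fx),
                              flank = fx$manifest$variant_params$flank)
  parts <- filter_in_reference(read_peptide_ids(fx$peptide_tsv),
                               read_fasta_db(fx$proteome_fasta))
  ann <- annotate_novel_peptides(parts$novel, list(sapdb))
  us <- unique_variant_sites(ann)
  expect_equal(us$n_sap_peptides, sum(truth$class == "sap"))
  expect_equal(us$n_unique_sites, n_sites)
})
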