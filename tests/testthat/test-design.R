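# A fixed, hand-written template keeps the structural examples readable:
# 60 nt of mixed flank on each side of a biallelic site.
toy_template <- function(site = "[A/T]") {
  left <- "GATTACCAGATGACCATCGAGTGCCTAAGTCACGGATTCAGCATGGCCATTAGCCTGAAC"
  right <- "TGACCTAGCATGACGATCCGTTAGCCATGAATCCGGATCACTAGCTTGACCATGGAACTC"
  parse_templates(paste0(">toy\n", left, site, right))[[1]]
}

test_that("penultimate and first-base modes place the variable base as
           specified", {
  tpl <- toy_template("[A/T]")
  pos <- tpl$sites[[1]]$position
  pen <- enumerate_asp_candidates(tpl, 1, "plus",
                                  snp_pos_mode = "penultimate")
  for (i in 1:2) {
    allele <- tpl$sites[[1]]$alleles[i]
    for (core in pen[[i]]$core_sequence) {
      L <- nchar(core)
      # terminal base comes from the template, penultimate is the allele
      expect_equal(substr(core, L - 1, L - 1), allele)
      expect_equal(substr(core, L, L),
                   substr(tpl$sequence, pos + 1, pos + 1))
    }
  }
  fst <- enumerate_asp_candidates(tpl, 1, "plus", snp_pos_mode = "first")
  for (i in 1:2) {
    allele <- tpl$sites[[1]]$alleles[i]
    for (core in fst[[i]]$core_sequence)
      expect_equal(substr(core, nchar(core), nchar(core)), allele)
  }
})

test_that("minus-strand candidates target reverse-complement alleles", {
  tpl <- toy_template("[A/T]")
  minus <- enumerate_asp_candidates(tpl, 1, "minus")
  for (i in 1:2) {
    allele_rc <- reverse_complement(tpl$sites[[1]]$alleles[i])
    for (core in minus[[i]]$core_sequence) {
      L <- nchar(core)
      expect_equal(substr(core, L - 1, L - 1), allele_rc)
      # the core must map onto the reverse complement of the
      # allele-substituted template
      sub <- substitute_allele(tpl, 1, i)$sequence
      expect_true(grepl(core, reverse_complement(sub), fixed = TRUE))
    }
  }
})

test_that("flank requirements are enforced with the side named", {
  short <- parse_templates(">s\nACGTACGT[A/T]ACGTACGTACGT")[[1]]
  expect_error(enumerate_asp_candidates(short, 1, "plus"),
               "plus.*flank|flank.*plus")
})

test_that("InDel 3' ends discriminate alleles within 12 nt", {
  s <- variant_site(0, c("", "CT"))
  ends <- generate_indel_3prime_ends(s, "GTACGTACGTAC")
  expect_equal(nrow(ends), 2)
  expect_true(all(ends$end_length <= 12))
  # deletion allele's end crosses the junction into template sequence;
  # insertion allele's end starts with the insertion
  expect_equal(ends$discriminator[1], "G")
  expect_equal(ends$discriminator[2], "C")
  expect_false(ends$discriminator[1] == ends$discriminator[2])

  # SNP-like alleles in penultimate mode: allele base plus the shared
  # next template base
  snp <- variant_site(0, c("A", "T"))
  e2 <- generate_indel_3prime_ends(snp, "GTAC", snp_offset = 2)
  expect_equal(e2$discriminator, c("AG", "TG"))

  # indistinguishable within 12 nt: error
  poly <- variant_site(0, c("A", "AA"))
  expect_error(generate_indel_3prime_ends(poly, strrep("A", 12)),
               "not discriminable")
})

test_that("Tm equalization selects an in-window, minimal-spread set", {
  tpl <- toy_template("[A/T]")
  cands <- enumerate_asp_candidates(tpl, 1, "plus")
  chosen <- equalize_tm(cands, target_tm = 63, window = 1)
  tms <- vapply(chosen, function(df) df$tm, numeric(1))
  expect_true(all(tms >= 62 & tms <= 64))
  # brute force over all in-window combinations: no alternative with the
  # same fixed 3' ends has a smaller pairwise spread
  in_win <- lapply(cands, function(df)
    df$tm[!is.na(df$tm) & df$tm >= 62 & df$tm <= 64])
  best_alt <- min(outer(in_win[[1]], in_win[[2]],
                        function(a, b) abs(a - b)))
  expect_equal(max(tms) - min(tms), best_alt)
  # idempotence: a single-candidate-per-allele set is returned unchanged
  again <- equalize_tm(chosen, target_tm = 63, window = 1)
  expect_equal(vapply(again, function(df) df$core_sequence, ""),
               vapply(chosen, function(df) df$core_sequence, ""))
  # unreachable window errors per allele
  expect_error(equalize_tm(cands, target_tm = 95, window = 1),
               "allele 1")
})

test_that("common primer candidates satisfy the amplicon range and are
           ranked by Tm closeness", {
  fa <- generate_fixture_templates(20, n = 1, site_kinds = "snp2",
                                   flank_len = 200)
  tpl <- parse_templates(fa)[[1]]
  cands <- enumerate_asp_candidates(tpl, 1, "plus")
  chosen <- equalize_tm(cands)
  common <- design_common_primer(tpl, 1, chosen)
  amps <- as.matrix(common[, grep("^amplicon_", names(common))])
  expect_true(all(amps >= 100 & amps <= 200))
  # ranked: first row minimizes |Tm - mean ASP Tm| over all returned
  expect_equal(common$dtm[1], min(common$dtm))
  # impossibility: site too close to the end for a 100-200 bp product
  toy <- toy_template("[A/T]")
  tiny <- parse_templates(paste0(
    ">tiny\n", substr(toy$sequence, 1, 60), "[A/T]",
    substr(toy$sequence, 61, 115)))[[1]]
  expect_error(
    design_common_primer(tiny, 1, equalize_tm(
      enumerate_asp_candidates(tiny, 1, "plus",
                               options = design_options(min_flank = 30)),
      window = 20)),
    "amplicon range")
})

test_that("primer quality is pure, bounded and monotone in structure
           penalties", {
  # a clean in-window primer scores 100
  clean <- "GGTACGTTCTACCATGGGC"
  expect_equal(score_primer(clean), 100)
  # appending a strong 3' self-complement strictly lowers PQ
  dimered <- paste0(substr(clean, 1, 13), "GCGCGCGC")
  expect_lt(score_primer(dimered), score_primer(clean))
  # purity: identical inputs, identical outputs
  expect_identical(score_primer(clean), score_primer(clean))
  expect_true(score_primer(strrep("AT", 10)) >= 0)
  expect_true(score_primer(strrep("AT", 10)) <= 100)
})

test_that("full biallelic design satisfies the structural contract", {
  fa <- generate_fixture_templates(42, n = 1, site_kinds = "snp2")
  tpl <- parse_templates(fa)[[1]]
  d <- design_assay(tpl)
  expect_s3_class(d, "assay_design")
  expect_length(d$asp_set, 2)
  expect_equal(d$common_primer$role, "common")
  expect_true(all(d$amplicon_lengths >= 100 & d$amplicon_lengths <= 200))
  expect_true(d$compatibility$pass)
  # tails attached, distinct channels
  expect_false(anyDuplicated(vapply(d$asp_set, `[[`, "",
                                    "tail_sequence")) > 0)
  # ASP core maps exactly onto its own allele template
  for (i in seq_along(d$asp_set)) {
    sub <- substitute_allele(tpl, 1, i)$sequence
    core <- d$asp_set[[i]]$core_sequence
    found <- grepl(core, sub, fixed = TRUE) ||
      grepl(core, reverse_complement(sub), fixed = TRUE)
    expect_true(found)
    # template_interval maps onto the core via the strand convention
    iv <- d$asp_set[[i]]$template_interval
    piece <- substr(sub, iv[1] + 1, iv[2])
    mapped <- if (d$asp_set[[i]]$strand == "plus") piece
    else reverse_complement(piece)
    expect_equal(mapped, core)
  }
})

test_that("quaternary sites yield four ASPs on four distinct channels", {
  fa <- generate_fixture_templates(101, n = 1, site_kinds = "snp4")
  tpl <- parse_templates(fa)[[1]]
  d <- design_assay(tpl)
  expect_length(d$asp_set, 4)
  expect_equal(anyDuplicated(d$channel_assignment), 0L)
  expect_length(unique(vapply(d$asp_set, `[[`, "", "tail_sequence")), 4)
})

test_that("design is deterministic", {
  fa <- generate_fixture_templates(42, n = 1, site_kinds = "indel")
  tpl <- parse_templates(fa)[[1]]
  d1 <- design_assay(tpl)
  d2 <- design_assay(tpl)
  expect_equal(d1, d2)
})

test_that("auto mode resolves to a fixed offset and stays in the Tm
           window", {
  fa <- generate_fixture_templates(42, n = 1, site_kinds = "snp2")
  tpl <- parse_templates(fa)[[1]]
  d <- design_assay(tpl, options = design_options(snp_pos_mode = "auto"))
  expect_true(d$snp_offset %in% 1:3)
  for (p in d$asp_set)
    expect_true(p$core_metrics$tm >= 62 && p$core_metrics$tm <= 64)
  expect_equal(d, design_assay(tpl,
                               options = design_options(
                                 snp_pos_mode = "auto")))
})

test_that("designed primers avoid masked intervals (cross-module
           contract)", {
  # a G4 motif sits in the left flank; no emitted primer may overlap it
  fa <- generate_fixture_templates(5, n = 1, site_kinds = "snp2",
                                   g4 = TRUE)
  tpl <- parse_templates(fa)[[1]]
  d <- tryCatch(design_assay(tpl), error = function(e) e)
  if (!inherits(d, "error")) {
    for (p in c(d$asp_set, list(d$common_primer))) {
      sub <- substitute_allele(tpl, 1,
                               max(1, p$allele_index, na.rm = TRUE))
      prof <- complexity_profile(sub$sequence)
      iv <- p$template_interval
      overlap <- any(iv[1] < prof$masked_intervals$end &
                       iv[2] > prof$masked_intervals$start)
      expect_false(overlap, info = p$name)
      expect_equal(nrow(find_quadruplex_motifs(p$core_sequence)), 0)
    }
  } else succeed("design declined the G4-flanked template entirely")
})

test_that("a low-complexity site neighbourhood defeats the design in
           both directions", {
  toy <- toy_template("[A/T]")
  bad <- parse_templates(paste0(
    ">lc\n", substr(toy$sequence, 1, 100), strrep("AT", 20), "[A/T]",
    strrep("TA", 20), substr(toy$sequence, 1, 100)))[[1]]
  err <- tryCatch(design_assay(bad), error = function(e) e)
  expect_s3_class(err, "asq_design_failure")
})

test_that("failures are structured with per-direction causes", {
  short <- parse_templates(
    paste0(">short\n", strrep("AC", 10), "[A/T]", strrep("GT", 10)))[[1]]
  err <- tryCatch(design_assay(short), error = function(e) e)
  expect_s3_class(err, "asq_design_failure")
  expect_true(length(err$causes) >= 2)
})

test_that("circular topology rescues a site near the origin", {
  fa <- generate_fixture_templates(42, n = 1, site_kinds = "snp2")
  tpl <- parse_templates(fa)[[1]]
  # move the site next to the origin by rotating the linear backbone
  site <- tpl$sites[[1]]
  rot <- 155L
  seq2 <- paste0(substr(tpl$sequence, rot + 1, nchar(tpl$sequence)),
                 substr(tpl$sequence, 1, rot))
  near_origin <- polymorphic_template(
    "rotated", seq2, list(variant_site(site$position - rot,
                                       site$alleles)), "linear")
  expect_error(design_assay(near_origin))
  circ <- polymorphic_template("rotated", seq2, near_origin$sites,
                               "circular")
  d <- design_assay(circ)
  expect_s3_class(d, "assay_design")
})
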