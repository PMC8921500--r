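test_that("bracket, IUPAC and plain records parse to the same model", {
  a <- parse_templates(">t1\nAACC[C/G]GGTT")[[1]]
  expect_equal(a$sequence, "AACCGGTT")
  expect_length(a$sites, 1)
  expect_equal(a$sites[[1]]$position, 4L)
  expect_setequal(a$sites[[1]]$alleles, c("C", "G"))
  expect_equal(a$sites[[1]]$site_kind, "SNP")

  b <- parse_templates(">t2\nAACCSGGTT")[[1]]
  expect_equal(b$sequence, a$sequence)
  expect_equal(b$sites[[1]]$alleles, a$sites[[1]]$alleles)

  plain <- parse_templates(">t3\nAACCGGTT")[[1]]
  expect_length(plain$sites, 0)
  expect_error(design_assay(plain), "no polymorphism")
})

test_that("every degenerate IUPAC symbol matches its bracket form", {
  degenerate <- c(R = "A/G", Y = "C/T", S = "C/G", W = "A/T", K = "G/T",
                  M = "A/C", B = "C/G/T", D = "A/G/T", H = "A/C/T",
                  V = "A/C/G", N = "A/C/G/T")
  for (sym in names(degenerate)) {
    via_iupac <- parse_templates(paste0(">x\nACGTAC", sym, "GTACGT"))[[1]]
    via_bracket <- parse_templates(
      paste0(">x\nACGTAC[", degenerate[[sym]], "]GTACGT"))[[1]]
    expect_equal(via_iupac$sites[[1]]$alleles,
                 via_bracket$sites[[1]]$alleles, info = sym)
    expect_equal(via_iupac$sites[[1]]$position, 6L, info = sym)
  }
  expect_identical(expand_degenerate("S"), c("C", "G"))
  expect_identical(expand_degenerate("A"), "A")
  expect_error(expand_degenerate("X"), "IUPAC")
})

test_that("variant sites classify and validate alleles", {
  expect_equal(parse_variant_site("[A/T]")$site_kind, "SNP")
  s <- parse_variant_site("[-/CT]")
  expect_equal(s$site_kind, "InDel")
  expect_setequal(s$alleles, c("", "CT"))
  expect_equal(parse_variant_site("[A/T/AGG]")$site_kind, "mixed")
  expect_error(parse_variant_site("[A/T/C/G/A]"), "4")
  expect_error(parse_variant_site("[A/A]"), "distinct")
  expect_error(parse_variant_site("[A/Q]"), "llegal")
  expect_error(parse_variant_site("[A]"), "2-4")
})

test_that("parse errors carry record context", {
  expect_error(parse_templates(""), "empty")
  expect_error(parse_templates(">bad\nAC[GT"), "unclosed")
  expect_error(parse_templates(">bad\nACGT[A/C/G/T/A]ACGT"),
               "bad.*offset 4")
})

test_that("tabular input and multi-record FASTA both work", {
  tab <- parse_templates("t1\tAACC[C/G]GGTT\nt2\tACGTWACGT",
                         format = "tabular")
  expect_length(tab, 2)
  expect_equal(tab[[1]]$name, "t1")
  expect_setequal(tab[[2]]$sites[[1]]$alleles, c("A", "T"))
  multi <- parse_templates(">a\nACG[A/T]ACGT\n>b\nTTGCA[C/G]AA")
  expect_length(multi, 2)
  expect_equal(vapply(multi, `[[`, "", "name"), c("a", "b"))
})

test_that("alignment input collapses to variant blocks", {
  t1 <- templates_from_alignment(c(x = "ACGTA", y = "ACCTA"))
  expect_equal(t1$sites[[1]]$position, 2L)
  expect_setequal(t1$sites[[1]]$alleles, c("G", "C"))

  t2 <- templates_from_alignment(c(x = "ACG-A", y = "ACGTA"))
  expect_setequal(t2$sites[[1]]$alleles, c("", "T"))
  expect_equal(t2$sites[[1]]$site_kind, "InDel")

  t3 <- templates_from_alignment(c(x = "ACGTA", y = "ACGTA"))
  expect_length(t3$sites, 0)

  # adjacent variant columns merge into one block (gap runs survive)
  t4 <- templates_from_alignment(c(x = "AAC--GTT", y = "AACTAGTT"))
  expect_length(t4$sites, 1)
  expect_setequal(t4$sites[[1]]$alleles, c("", "TA"))

  expect_error(templates_from_alignment(c("ACGT", "ACG")), "equal length")
  five <- c("AAAA", "ACAA", "AGAA", "ATAA", "A-AA")
  expect_error(templates_from_alignment(five), "4")

  # auto-detection: gapped equal-length multi-FASTA is one alignment
  ali <- parse_templates(">x\nACG-A\n>y\nACGTA")
  expect_length(ali, 1)
  expect_setequal(ali[[1]]$sites[[1]]$alleles, c("", "T"))
})

test_that("bracket serialization round-trips", {
  set.seed(11)
  for (i in 1:20) {
    fa <- generate_fixture_templates(i, n = 1,
                                     site_kinds = sample(
                                       c("snp2", "snp3", "snp4", "indel",
                                         "mixed"), 1))
    tpl <- parse_templates(fa)[[1]]
    again <- parse_templates(paste0(">", tpl$name, "\n",
                                    format_template(tpl)))[[1]]
    expect_equal(again$sequence, tpl$sequence)
    expect_equal(again$sites, tpl$sites)
  }
})

test_that("site offsets respect the half-open convention", {
  tpl <- parse_templates(">t\nAAAA[C/G]TT[A/-]CC")[[1]]
  pos <- vapply(tpl$sites, `[[`, integer(1), "position")
  expect_equal(pos, c(4L, 6L))
  # prefix length equals position for every site
  expect_equal(nchar(substr(tpl$sequence, 1, pos[1])), pos[1])
  sub <- substitute_allele(tpl, 2, 1)
  expect_equal(substr(sub$sequence, sub$site_start + 1, sub$site_end),
               "A")
  sub2 <- substitute_allele(tpl, 2, 2)
  expect_equal(sub2$site_start, sub2$site_end)  # null allele: empty span
  expect_equal(sub2$sequence, "AAAACTTCC")
})
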