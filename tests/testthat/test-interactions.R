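test_that("self-dimer finds palindromic duplexes and ignores
           non-pairing sequences", {
  h <- self_dimer("GGGATCCC")
  expect_equal(h$run_length, 8)
  expect_true(h$involves_3prime_a)
  expect_true(h$fails)
  none <- self_dimer("AAAAAAAAAA")
  expect_equal(none$run_length, 0)
  expect_equal(none$score_delta_g, 0)
  expect_false(none$fails)
})

test_that("cross-dimer is symmetric and detects full complements", {
  a <- "ACGGATTCAGCAT"
  h <- cross_dimer(a, reverse_complement(a))
  expect_equal(h$run_length, nchar(a))
  expect_true(h$fails)
  expect_equal(cross_dimer("AAAAAAA", "CCCCCCC")$run_length, 0)
  set.seed(17)
  for (i in 1:100) {
    x <- rand_dna(sample(8:20, 1)); y <- rand_dna(sample(8:20, 1))
    expect_equal(cross_dimer(x, y)$score_delta_g,
                 cross_dimer(y, x)$score_delta_g)
  }
})

test_that("hairpin finds designed foldbacks and rejects non-pairing
           stems", {
  h <- hairpin("GGGGGAAAACCCCC")
  expect_equal(h$stem_length, 5)
  expect_equal(h$loop_length, 4)
  expect_true(h$involves_3prime)
  expect_null(hairpin("ACACACACACAC"))
  expect_error(hairpin("ACGTACG"), "shorter")
})

test_that("dimer and hairpin scores agree with exhaustive brute force", {
  set.seed(29)
  for (i in 1:100) {
    a <- rand_dna(sample(8:20, 1))
    b <- rand_dna(sample(8:20, 1))
    expect_equal(self_dimer(a)$score_delta_g, oracle_dimer_dg(a, a),
                 info = a)
    expect_equal(cross_dimer(a, b)$score_delta_g, oracle_dimer_dg(a, b),
                 info = paste(a, b))
  }
  for (i in 1:100) {
    s <- rand_dna(sample(11:16, 1))
    hp <- hairpin(s)
    got <- if (is.null(hp)) 0 else hp$score_delta_g
    expect_equal(got, oracle_hairpin_dg(s), info = s)
  }
})

test_that("binding-site scan matches the naive oracle and handles
           strands", {
  tpl <- paste0(rand_dna(0), "ACGGATTCAGCATGGCCATTA")
  p <- substr(tpl, 3, 14)
  hits <- scan_binding_sites(p, tpl)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 2)
  # a locus plus its exact reverse-complement elsewhere: two opposite
  # strand sites
  tpl2 <- paste0("TTTT", p, "TTTTTT", reverse_complement(p), "TTTT")
  hits2 <- scan_binding_sites(p, tpl2)
  expect_equal(nrow(hits2), 2)
  expect_setequal(hits2$strand, c("+", "-"))
  set.seed(41)
  for (i in 1:60) {
    primer <- rand_dna(sample(8:12, 1))
    template <- rand_dna(sample(25:45, 1))
    expect_equal(nrow(scan_binding_sites(primer, template)),
                 oracle_binding_count(primer, template),
                 info = paste(primer, template))
  }
})

test_that("tightening thresholds never converts a fail into a pass", {
  # constructed palindromic failer under any sensible threshold
  pal <- "GGGGATCCCCAATT"
  expect_true(self_dimer(pal, dimer_thresholds(-12, -9))$fails)
  expect_true(self_dimer(pal, dimer_thresholds(-6, -3))$fails)
  set.seed(53)
  for (i in 1:40) {
    s <- rand_dna(16)
    loose <- self_dimer(s, dimer_thresholds(-12, -9))
    tight <- self_dimer(s, dimer_thresholds(-6, -3))
    if (loose$fails) expect_true(tight$fails, info = s)
  }
})

test_that("compatibility report is symmetric with self-dimers on the
           diagonal and flags size overlaps", {
  primers <- c(p1 = "ACGGATTCAGCATCGA", p2 = "TGCCATGGATCGATCC",
               p3 = "CAGTTAGCAACGGTCA")
  rep <- compatibility_report(list(set1 = primers))
  expect_true(isSymmetric(rep$delta_g))
  for (i in seq_along(primers))
    expect_equal(rep$delta_g[i, i], self_dimer(primers[i])$score_delta_g)
  # duplicated identical target in a 2-plex: identical product sizes
  rep2 <- compatibility_report(
    list(a = primers[1:2], b = primers[1:2]),
    amplicon_sizes = list(a = 150, b = 150))
  expect_gt(nrow(rep2$size_overlaps), 0)
  expect_false(rep2$pass)
})

test_that("a tail-induced dimer is caught on the full sequence", {
  core_a <- "GATTACCAGATGACCAT"
  core_b <- "CATTGACCAGTAGACCA"
  # constructed tail whose 3' half is complementary to core_b's 3' end
  tail <- paste0("CCAGCTG", reverse_complement(substr(core_b, 9, 17)))
  expect_false(cross_dimer(core_a, core_b)$fails)
  expect_true(cross_dimer(paste0(tail, core_a), core_b)$fails)
})
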