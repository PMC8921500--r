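cond_assay <- thermo_conditions()  # 200 nM, 55 mM K+, 2.2 mM free Mg2+

test_that("conditions derive free divalent and validate inputs", {
  expect_equal(cond_assay$free_divalent, 2.2e-3)
  expect_equal(thermo_conditions(mg_total = 1e-3,
                                 dntp_total = 2e-3)$free_divalent, 0)
  expect_error(thermo_conditions(monovalent = -1), ">= 0")
  expect_error(thermo_conditions(oligo_conc = 0), "> 0")
})

test_that("melting temperature and free energy are reverse-complement
           symmetric", {
  set.seed(101)
  for (i in 1:500) {
    s <- rand_dna(sample(8:30, 1))
    rc <- reverse_complement(s)
    expect_equal(melting_temperature(s, cond_assay),
                 melting_temperature(rc, cond_assay), tolerance = 1e-12)
    expect_equal(duplex_delta_g(s), duplex_delta_g(rc),
                 tolerance = 1e-12)
  }
})

test_that("Tm rises with oligo concentration and with free Mg2+ in the
           divalent-dominated regime", {
  s <- "ACGGATCGTTAGCACCAT"
  concs <- c(50, 100, 200, 400, 800, 1600) * 1e-9
  tms <- vapply(concs, function(x)
    melting_temperature(s, thermo_conditions(oligo_conc = x)), numeric(1))
  expect_true(all(diff(tms) > 0))
  # grid through the Mg-dominated regime (sqrt(Mg)/mono > 0.22)
  mg <- seq(0.25e-3, 5e-3, by = 0.25e-3)
  for (s2 in c(s, "GGCGCGCCTTAAGGCC", "ATATATTAGCATCAAT")) {
    tms2 <- vapply(mg, function(m)
      melting_temperature(s2, thermo_conditions(mg_total = m,
                                                dntp_total = 0)),
      numeric(1))
    expect_true(all(diff(tms2) >= 0), info = s2)
    # and salt stabilizes overall relative to the no-divalent condition
    expect_gt(tms2[length(tms2)],
              melting_temperature(s2, thermo_conditions(mg_total = 0,
                                                        dntp_total = 0)))
  }
})

test_that("probe-set reference values are reproduced under assay
           conditions", {
  p <- reference_probe_set()
  expect_equal(melting_temperature(p$uniq, cond_assay), 53.3,
               tolerance = 1 / 53.3)
  expect_equal(melting_temperature(p$up1, cond_assay), 67.4,
               tolerance = 1 / 67.4)
  expect_equal(duplex_delta_g(p$uniq), -16.7, tolerance = 0.5 / 16.7)
  expect_equal(duplex_delta_g(p$up1), -26.4, tolerance = 0.5 / 26.4)
})

test_that("delta-G magnitude grows when any sequence is extended by G", {
  # every nearest-neighbor stack is stabilizing, so appending a base can
  # only deepen the duplex free energy; verified exhaustively on 3-mers
  trimers <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               c("A", "C", "G", "T")), 1, paste,
                   collapse = "")
  for (s in trimers) {
    expect_lt(duplex_delta_g(paste0(s, "G")), duplex_delta_g(s))
  }
})

test_that("input validation rejects short or non-DNA sequences", {
  expect_error(melting_temperature("ACGTACG"), ">= 8")
  expect_error(melting_temperature("ACGTACGX"), "non-ACGT")
  expect_error(duplex_delta_g("A"), ">= 2")
  expect_error(gc_content(""), "non-empty")
})

test_that("GC content matches the probe table", {
  p <- reference_probe_set()
  expect_equal(round(gc_content(p$uniq), 1), 61.5)
  for (up in p[c("up1", "up2", "up3", "up4")])
    expect_equal(round(gc_content(up), 1), 63.2)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
})

test_that("molecular weight follows the linear 5'-OH convention", {
  # single residue: monomer mass minus the phosphate-bridge adjustment
  expect_equal(molecular_weight("A"), 313.21 - 61.96)
  expect_equal(molecular_weight("AC"), molecular_weight("CA"))
  # closed form for homopolymers: n*MW(A) + (n-1)*61.96... rearranged
  for (n in c(2, 5, 13)) {
    expect_equal(molecular_weight(strrep("A", n)),
                 n * molecular_weight("A") + (n - 1) * 61.96)
  }
})

test_that("extinction coefficient satisfies the nearest-neighbor
           splitting identity", {
  # eps(xy) values follow the NN method: eps(s) = eps(s[1..k]) +
  # eps(s[k..n]) - eps(monomer at k), for any split point
  expect_gt(extinction_coefficient("AT"), 0)
  set.seed(77)
  for (i in 1:50) {
    s <- rand_dna(20)
    k <- sample(2:19, 1)
    left <- substr(s, 1, k)
    right <- substr(s, k, 20)
    mono <- c(A = 15400, C = 7400, G = 11500, T = 8700)
    expect_equal(extinction_coefficient(s),
                 extinction_coefficient(left) +
                   extinction_coefficient(right) -
                   mono[[substr(s, k, k)]])
  }
  expect_error(extinction_coefficient("A"), ">= 2")
})

test_that("terminal stability is the 3'-terminal k-mer free energy", {
  expect_equal(terminal_stability("AAAAAGGGGG", 5),
               duplex_delta_g("GGGGG"))
  s <- "ACGTACGTACGT"
  expect_equal(terminal_stability(s, nchar(s)), duplex_delta_g(s))
  expect_error(terminal_stability("ACGT", 5), "exceeds")
  # GC-only pentamer ends are uniformly more stable than AT-only ends
  pent <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 5)), 1,
                paste, collapse = "")
  gc_only <- pent[!grepl("[AT]", pent)]
  at_only <- pent[!grepl("[GC]", pent)]
  worst_gc <- max(vapply(gc_only, duplex_delta_g, numeric(1)))
  best_at <- min(vapply(at_only, duplex_delta_g, numeric(1)))
  expect_lt(worst_gc, best_at)
})
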