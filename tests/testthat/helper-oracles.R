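# Independent brute-force oracles, deliberately written in a different
# style (character-by-character loops) from the package implementations
# they cross-check, plus small fixture utilities.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

pairs_wc <- function(x, y) {
  (x == "A" && y == "T") || (x == "T" && y == "A") ||
    (x == "G" && y == "C") || (x == "C" && y == "G")
}

# Exhaustive-offset dimer oracle: slide b (3'->5') along a, take the
# longest contiguous paired run at each offset, score it with
# duplex_delta_g, return the minimum over everything.
oracle_dimer_dg <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- rev(strsplit(b, "")[[1]])
  best <- 0
  for (off in (-(length(bv) - 1)):(length(av) - 1)) {
    run <- 0
    run_start <- NA
    for (i in seq_along(av)) {
      j <- i - off
      ok <- j >= 1 && j <= length(bv) && pairs_wc(av[i], bv[j])
      if (ok) {
        if (run == 0) run_start <- i
        run <- run + 1
        if (run >= 2) {
          dg <- duplex_delta_g(substr(a, run_start, run_start + run - 1))
          if (dg < best) best <- dg
        }
      } else run <- 0
    }
  }
  best
}

# Exhaustive hairpin oracle: all (stem1 start, stem length, stem2 end)
# triples; returns the minimum stem delta-G or 0 when no fold exists.
oracle_hairpin_dg <- function(seq, min_stem = 4, min_loop = 3) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  best <- 0
  for (i in seq_len(n)) for (s in min_stem:n) for (j in seq_len(n)) {
    if (i + s - 1 > n || j > n || j - s + 1 < 1) next
    loop <- (j - s + 1) - (i + s)
    if (loop < min_loop) next
    all_pair <- TRUE
    for (k in 0:(s - 1)) {
      if (!pairs_wc(b[i + k], b[j - k])) { all_pair <- FALSE; break }
    }
    if (all_pair) {
      dg <- duplex_delta_g(substr(seq, i, i + s - 1))
      if (dg < best) best <- dg
    }
  }
  best
}

# Naive O(n*m) binding-site oracle counting plus and minus strand hits.
oracle_binding_count <- function(primer, template, max_mm = 2, k3 = 3) {
  count_one <- function(p, tpl, three_prime_left) {
    pv <- strsplit(p, "")[[1]]
    tv <- strsplit(tpl, "")[[1]]
    m <- length(pv); n <- length(tv)
    if (m > n) return(0L)
    hits <- 0L
    for (s in 0:(n - m)) {
      mm <- 0L
      ok3 <- TRUE
      for (i in seq_len(m)) {
        match <- tv[s + i] == pv[i]
        if (!match) {
          mm <- mm + 1L
          in3 <- if (three_prime_left) i <= k3 else i > m - k3
          if (in3) ok3 <- FALSE
        }
      }
      if (mm <= max_mm && ok3) hits <- hits + 1L
    }
    hits
  }
  count_one(primer, template, FALSE) +
    count_one(reverse_complement(primer), template, TRUE)
}

# Slow recomputation of linguistic complexity straight from the
# vocabulary-ratio definition.
oracle_lc <- function(seq) {
  n <- nchar(seq)
  obs <- 0; mx <- 0
  for (k in 1:3) {
    words <- character(0)
    for (i in 1:(n - k + 1)) words <- c(words, substr(seq, i, i + k - 1))
    obs <- obs + length(unique(words))
    mx <- mx + min(4^k, n - k + 1)
  }
  100 * obs / mx
}

# Locate a primer core on a template (either strand); returns the
# 0-based half-open interval and strand, or NULL.
locate_core <- function(core, template) {
  p <- regexpr(core, template, fixed = TRUE)
  if (p > 0)
    return(list(start = p - 1L, end = p - 1L + nchar(core),
                strand = "plus"))
  rc <- reverse_complement(core)
  p <- regexpr(rc, template, fixed = TRUE)
  if (p > 0)
    return(list(start = p - 1L, end = p - 1L + nchar(core),
                strand = "minus"))
  NULL
}

reference_probe_set <- function() {
  list(uniq = "ACCGTTCAGCTGG",
       up1 = "CCAGCTGAACGGTACGGCA",
       up2 = "CCAGCTGAACGGTCGTTGC",
       up3 = "CCAGCTGAACGGTAGCCGA",
       up4 = "CCAGCTGAACGGTGCGTCA")
}
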