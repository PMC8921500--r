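# Primer interaction screening: self-/cross-dimers (ungapped antiparallel
# alignment, Watson-Crick pairs only), hairpins, within-template binding
# sites, and the multiplex compatibility matrix.

#' Default interaction-screen thresholds
#'
#' A dimer or hairpin fails the screen when the free energy of its
#' longest perfectly paired run is at or below `delta_g` anywhere, or at
#' or below `delta_g_3prime` when the run involves a 3' terminus (a
#' 3'-anchored duplex is extensible by polymerase and therefore screened
#' more strictly).
#'
#' @param delta_g Internal-duplex fail threshold, kcal/mol (default -9).
#' @param delta_g_3prime 3'-involved fail threshold, kcal/mol (default -6).
#' @return List of thresholds.
#' @export
dimer_thresholds <- function(delta_g = -9, delta_g_3prime = -6) {
  list(delta_g = delta_g, delta_g_3prime = delta_g_3prime)
}

# Core ungapped antiparallel dimer scan between a (5'->3') and b (5'->3').
# Offsets slide reversed b along a; at each offset the longest contiguous
# Watson-Crick run is scored by its duplex delta-G. Returns the hit with
# the most negative delta-G (ties: leftmost offset).
dimer_scan <- function(a, b) {
  av <- seq_chars(a)
  bv <- rev(seq_chars(b))         # b read 3'->5'
  na <- length(av); nb <- length(bv)
  best <- NULL
  for (off in (-(nb - 1L)):(na - 1L)) {
    i1 <- max(1L, 1L + off); i2 <- min(na, nb + off)
    if (i2 - i1 + 1L < 2L) next
    ai <- av[i1:i2]
    bi <- bv[(i1 - off):(i2 - off)]
    paired <- wc_paired(ai, bi)
    if (!any(paired)) next
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= 2L)
    for (k in runs) {
      run_a_start <- i1 + starts[k] - 1L       # 1-based on a
      run_len <- r$lengths[k]
      run_seq <- substr(a, run_a_start, run_a_start + run_len - 1L)
      dg <- duplex_delta_g(run_seq)
      # only stabilizing duplexes count as hits
      if (dg < 0 && (is.null(best) || dg < best$score_delta_g)) {
        # positions of b (original orientation, 1-based) inside the run
        b_rev_idx <- (run_a_start - off):(run_a_start + run_len - 1L - off)
        b_idx <- nb - b_rev_idx + 1L
        best <- list(
          offset = off,
          matched_pairs = sum(paired),
          run_start_a = run_a_start,
          run_length = run_len,
          involves_3prime_a = (run_a_start + run_len - 1L) == na,
          involves_3prime_b = any(b_idx == nb),
          score_delta_g = dg
        )
      }
    }
  }
  best
}

finalize_hit <- function(hit, a, b, thresholds) {
  if (is.null(hit)) {
    hit <- list(offset = NA_integer_, matched_pairs = 0L,
                run_start_a = NA_integer_, run_length = 0L,
                involves_3prime_a = FALSE, involves_3prime_b = FALSE,
                score_delta_g = 0)
  }
  hit$seq_a <- a
  hit$seq_b <- b
  hit$fails <- hit$score_delta_g <= thresholds$delta_g ||
    ((hit$involves_3prime_a || hit$involves_3prime_b) &&
       hit$score_delta_g <= thresholds$delta_g_3prime)
  structure(hit, class = "dimer_hit")
}

#' @export
print.dimer_hit <- function(x, ...) {
  if (x$run_length == 0L) cat("dimer_hit: none\n")
  else cat(sprintf(
    "dimer_hit: run %d bp at offset %d, dG = %.2f kcal/mol, 3' a/b: %s/%s, %s\n",
    x$run_length, x$offset, x$score_delta_g,
    x$involves_3prime_a, x$involves_3prime_b,
    if (x$fails) "FAIL" else "pass"))
  invisible(x)
}

#' Worst self-dimer of a primer
#'
#' Best-scoring ungapped antiparallel alignment of the primer against a
#' second copy of itself; the score is the nearest-neighbor free energy of
#' the longest perfectly paired run.
#'
#' @param seq Primer sequence (length >= 6).
#' @param thresholds See [dimer_thresholds()].
#' @return A `dimer_hit` (run length 0 and dG 0 when nothing pairs).
#' @examples
#' self_dimer("GGGATCCC")  # palindrome: full-length self-duplex
#' @export
self_dimer <- function(seq, thresholds = dimer_thresholds()) {
  seq <- toupper(seq)
  assert_dna(seq)
  if (nchar(seq) < 6L) stop("primer too short (< 6 nt)", call. = FALSE)
  finalize_hit(dimer_scan(seq, seq), seq, seq, thresholds)
}

#' Worst cross-dimer between two primers
#'
#' @param a,b Primer sequences (length >= 6); the result is symmetric in
#'   `a` and `b`.
#' @inheritParams self_dimer
#' @return A `dimer_hit`.
#' @export
cross_dimer <- function(a, b, thresholds = dimer_thresholds()) {
  a <- toupper(a); b <- toupper(b)
  assert_dna(a); assert_dna(b)
  if (nchar(a) < 6L || nchar(b) < 6L)
    stop("primers too short (< 6 nt)", call. = FALSE)
  finalize_hit(dimer_scan(a, b), a, b, thresholds)
}

#' Worst hairpin fold of a primer
#'
#' Enumerates all self-foldbacks with a perfectly paired stem of at least
#' `min_stem` bp and a loop of at least `min_loop` nt; scores the stem
#' duplex free energy and reports whether the 3' terminus is in the stem.
#'
#' @param seq Primer sequence.
#' @param min_stem Minimum stem length in bp.
#' @param min_loop Minimum loop length in nt.
#' @return A `hairpin_hit` list (`stem_length`, `loop_length`,
#'   `stem5_start`, `involves_3prime`, `score_delta_g`), or `NULL` when no
#'   fold satisfies the geometry.
#' @examples
#' hairpin("GGGGGAAAACCCCC")
#' @export
hairpin <- function(seq, min_stem = 4, min_loop = 3) {
  seq <- toupper(seq)
  assert_dna(seq)
  n <- nchar(seq)
  if (n < 2 * min_stem + min_loop)
    stop("sequence shorter than 2*min_stem + min_loop", call. = FALSE)
  b <- seq_chars(seq)
  best <- NULL
  for (i in 1:(n - 2 * min_stem - min_loop + 1L)) {       # stem1 start
    for (j in (i + 2 * min_stem + min_loop - 1L):n) {     # stem2 end
      max_s <- min((j - i + 1L - min_loop) %/% 2L, n)
      for (s in min_stem:max_s) {
        loop <- (j - s + 1L) - (i + s)
        if (loop < min_loop) break
        stem1 <- b[i:(i + s - 1L)]
        stem2 <- rev(b[(j - s + 1L):j])   # read back toward the loop
        if (all(wc_paired(stem1, stem2))) {
          dg <- duplex_delta_g(paste(stem1, collapse = ""))
          if (is.null(best) || dg < best$score_delta_g ||
              (dg == best$score_delta_g && s > best$stem_length)) {
            best <- list(stem_length = s, loop_length = loop,
                         stem5_start = i, stem3_end = j,
                         involves_3prime = (j == n),
                         score_delta_g = dg)
          }
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "hairpin_hit")
}

#' Scan a template for primer binding sites
#'
#' Finds every plus- and minus-strand position where the primer anneals
#' with at most `max_mismatches` mismatches overall and zero mismatches in
#' its 3'-terminal `require_3prime_match` bases.  Intended sites versus
#' extra (non-specific) sites are distinguished by the caller.
#'
#' @param primer Primer sequence, 5'->3'.
#' @param template Template sequence (plus strand).
#' @param max_mismatches Maximum mismatches tolerated (default 2).
#' @param require_3prime_match 3'-terminal bases that must match exactly
#'   (default 3).
#' @param circular Treat the template as circular (the scan wraps by
#'   virtually appending the first `length(primer) - 1` bases).
#' @return Data frame with 0-based half-open `start`/`end` on the plus
#'   strand, `strand` (`+`/`-`) and `mismatches`.
#' @export
scan_binding_sites <- function(primer, template, max_mismatches = 2,
                               require_3prime_match = 3,
                               circular = FALSE) {
  primer <- toupper(primer); template <- toupper(template)
  assert_dna(primer, "primer"); assert_dna(template, "template")
  m <- nchar(primer)
  n0 <- nchar(template)
  scan_tpl <- if (circular && n0 >= m)
    paste0(template, substr(template, 1L, m - 1L)) else template
  n <- nchar(scan_tpl)
  if (m > n)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  tv <- seq_chars(scan_tpl)
  hit_one <- function(pv, k3_idx) {
    starts <- 0:(n - m)
    hits <- lapply(starts, function(s) {
      w <- tv[(s + 1L):(s + m)]
      mm <- sum(w != pv)
      if (mm <= max_mismatches && all(w[k3_idx] == pv[k3_idx]))
        data.frame(start = s, end = s + m, mismatches = mm)
      else NULL
    })
    do.call(rbind, hits)
  }
  k <- min(require_3prime_match, m)
  # plus strand: primer as-is, 3' end at the right
  pv_plus <- seq_chars(primer)
  plus <- hit_one(pv_plus, if (k > 0) (m - k + 1L):m else integer(0))
  if (!is.null(plus) && nrow(plus)) plus$strand <- "+"
  # minus strand: site sequence equals revcomp(primer); primer 3' end maps
  # to the leftmost position of the site
  pv_minus <- seq_chars(reverse_complement(primer))
  minus <- hit_one(pv_minus, if (k > 0) 1L:k else integer(0))
  if (!is.null(minus) && nrow(minus)) minus$strand <- "-"
  out <- rbind(plus, minus)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  if (circular) {
    out <- out[out$start < n0, , drop = FALSE]
    out$end <- ifelse(out$end > n0, out$end - n0, out$end)
  }
  out <- out[order(out$start, out$strand), c("start", "end", "strand",
                                             "mismatches")]
  rownames(out) <- NULL
  out
}

#' Multiplex compatibility report
#'
#' Screens a pooled reaction: every pairwise primer-primer dimer (tails
#' included, diagonal = self-dimers), per-template binding-site counts,
#' and product-size overlap between amplicons of different targets (two
#' amplicons closer than `size_margin` bp are flagged because they cannot
#' be told apart if they share a detection channel).
#'
#' @param primer_sets Named list (one element per target) of named
#'   character vectors of full primer sequences.
#' @param templates Named character vector of template sequences the pool
#'   is used on (allele-substituted where applicable).
#' @param amplicon_sizes Optional named list (parallel to `primer_sets`)
#'   of expected product sizes in bp.
#' @param thresholds See [dimer_thresholds()].
#' @param size_margin Minimum distinguishable product-size difference, bp.
#' @param max_mismatches,require_3prime_match Passed to
#'   [scan_binding_sites()].
#' @return A `compatibility_report`: symmetric `delta_g` matrix, list
#'   matrix of worst `dimer_hit`s, `binding_counts` (primer x template),
#'   `size_overlaps` data frame, and overall `pass`.
#' @export
compatibility_report <- function(primer_sets, templates = character(0),
                                 amplicon_sizes = NULL,
                                 thresholds = dimer_thresholds(),
                                 size_margin = 10,
                                 max_mismatches = 2,
                                 require_3prime_match = 3) {
  stopifnot(length(primer_sets) >= 1L)
  if (is.character(primer_sets)) primer_sets <- list(set1 = primer_sets)
  if (is.null(names(primer_sets)))
    names(primer_sets) <- paste0("set", seq_along(primer_sets))
  primers <- unlist(primer_sets)
  pnames <- names(primers)
  np <- length(primers)
  dgm <- matrix(0, np, np, dimnames = list(pnames, pnames))
  hits <- matrix(list(), np, np, dimnames = list(pnames, pnames))
  dimer_fail <- FALSE
  for (i in seq_len(np)) {
    for (j in i:np) {
      h <- if (i == j) self_dimer(primers[i], thresholds)
      else cross_dimer(primers[i], primers[j], thresholds)
      dgm[i, j] <- dgm[j, i] <- h$score_delta_g
      hits[[i, j]] <- hits[[j, i]] <- h
      if (h$fails) dimer_fail <- TRUE
    }
  }
  binding <- NULL
  nonspecific <- FALSE
  if (length(templates) > 0L) {
    if (is.null(names(templates)))
      names(templates) <- paste0("template", seq_along(templates))
    binding <- matrix(0L, np, length(templates),
                      dimnames = list(pnames, names(templates)))
    for (i in seq_len(np)) {
      for (t in seq_along(templates)) {
        binding[i, t] <- nrow(scan_binding_sites(
          primers[i], templates[[t]], max_mismatches,
          require_3prime_match))
      }
    }
    nonspecific <- any(binding > 1L)
  }
  overlaps <- data.frame(set_a = character(0), set_b = character(0),
                         size_a = numeric(0), size_b = numeric(0))
  if (!is.null(amplicon_sizes) && length(amplicon_sizes) > 1L) {
    sets <- names(amplicon_sizes)
    for (i in seq_along(sets)[-length(sets)]) {
      for (j in (i + 1L):length(sets)) {
        for (sa in amplicon_sizes[[i]]) for (sb in amplicon_sizes[[j]]) {
          if (abs(sa - sb) < size_margin)
            overlaps <- rbind(overlaps, data.frame(
              set_a = sets[i], set_b = sets[j], size_a = sa, size_b = sb))
        }
      }
    }
  }
  structure(list(
    primers = primers,
    delta_g = dgm,
    hits = hits,
    binding_counts = binding,
    size_overlaps = overlaps,
    dimer_fail = dimer_fail,
    nonspecific_binding = nonspecific,
    pass = !dimer_fail && !nonspecific && nrow(overlaps) == 0L
  ), class = "compatibility_report")
}

#' @export
print.compatibility_report <- function(x, ...) {
  cat(sprintf("compatibility_report: %d primers, %s\n",
              length(x$primers), if (x$pass) "PASS" else "FAIL"))
  cat("worst pairwise dimer dG (kcal/mol):\n")
  print(round(x$delta_g, 2))
  if (x$dimer_fail) cat("  dimer threshold exceeded\n")
  if (x$nonspecific_binding) cat("  non-specific binding site(s) found\n")
  if (nrow(x$size_overlaps)) {
    cat("  product-size overlaps:\n"); print(x$size_overlaps)
  }
  invisible(x)
}
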