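# Sequence-quality screens: linguistic complexity (k-mer vocabulary
# richness), windowed low-complexity masking, and G-quadruplex motif
# detection on both strands.

#' Linguistic complexity of a DNA sequence
#'
#' Vocabulary-ratio definition over word sizes 1-3:
#' `LC = 100 * sum_k V_k / sum_k V_k^max`, where `V_k` is the number of
#' distinct k-mers observed and `V_k^max = min(4^k, n - k + 1)` is the
#' maximum possible for a sequence of length `n`.  Repetitive sequences
#' score low; a sequence realizing every possible word scores 100.
#'
#' @param seq DNA string (A/C/G/T), length >= 3.
#' @return Complexity in percent (unrounded; reports print it rounded to
#'   integer).
#' @examples
#' linguistic_complexity("CCAGCTGAACGGTACGGCA")  # ~86
#' linguistic_complexity("AAAAAAAAAAAAA")        # ~11
#' @export
linguistic_complexity <- function(seq) {
  seq <- toupper(seq)
  assert_dna(seq)
  n <- nchar(seq)
  if (n < 3L) stop("sequence must have length >= 3", call. = FALSE)
  b <- seq_chars(seq)
  observed <- 0L
  possible <- 0L
  for (k in 1:3) {
    words <- vapply(seq_len(n - k + 1L),
                    function(i) paste(b[i:(i + k - 1L)], collapse = ""),
                    character(1))
    observed <- observed + length(unique(words))
    possible <- possible + min(4^k, n - k + 1L)
  }
  100 * observed / possible
}

#' Locate low-complexity regions
#'
#' Slides a window over the sequence and reports maximal merged intervals
#' whose windowed linguistic complexity falls below `threshold`.  These
#' intervals are excluded from primer placement by the design pipeline.
#'
#' @param seq DNA string.
#' @param window Window size in nt (>= 3).
#' @param threshold Complexity threshold in percent; windows with
#'   `LC < threshold` are masked.
#' @return Data frame of 0-based half-open intervals (`start`, `end`).
#' @examples
#' find_low_complexity_regions(strrep("AT", 30))
#' @export
find_low_complexity_regions <- function(seq, window = 20, threshold = 70) {
  seq <- toupper(seq)
  assert_dna(seq)
  if (window < 3) stop("window must be >= 3", call. = FALSE)
  n <- nchar(seq)
  if (window > n) stop("window exceeds sequence length", call. = FALSE)
  if (threshold <= 0)
    return(data.frame(start = integer(0), end = integer(0)))
  hits <- lapply(0:(n - window), function(s) {
    if (linguistic_complexity(substr(seq, s + 1L, s + window)) < threshold)
      data.frame(start = s, end = s + window)
    else NULL
  })
  merge_intervals(do.call(rbind, hits))
}

#' Locate potential G-quadruplex motifs
#'
#' Matches the standard quadruplex consensus - four tracts of at least
#' `tract` G's separated by loops of `loop_min`-`loop_max` nt - on the
#' given strand and, via C-tracts, on the complementary strand.  Matches
#' are reported leftmost-greedy and non-overlapping per strand.
#'
#' @param seq DNA string (may be empty).
#' @param tract Minimum G-tract length (default 3).
#' @param loop_min,loop_max Loop length bounds (defaults 1 and 7).
#' @return Data frame of 0-based half-open intervals with a `strand`
#'   column (`+` for G-tract motifs, `-` for C-tract motifs).
#' @examples
#' find_quadruplex_motifs("GGGTTAGGGTTAGGGTTAGGG")
#' @export
find_quadruplex_motifs <- function(seq, tract = 3, loop_min = 1,
                                   loop_max = 7) {
  seq <- toupper(seq)
  assert_dna(seq)
  scan <- function(base, strand) {
    pat <- sprintf("%s{%d,}([ACGT]{%d,%d}%s{%d,}){3}",
                   base, tract, loop_min, loop_max, base, tract)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(start = as.integer(m) - 1L,
               end = as.integer(m) + attr(m, "match.length") - 1L,
               strand = strand)
  }
  out <- rbind(scan("G", "+"), scan("C", "-"))
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Full complexity profile of a sequence
#'
#' Combines the overall linguistic complexity with the masked intervals
#' (low-complexity regions merged with G-quadruplex motifs) that primer
#' placement must avoid.
#'
#' @inheritParams find_low_complexity_regions
#' @param mask_low_complexity,mask_quadruplex Toggle the two screens.
#' @return A `complexity_profile` list: `lc_percent`, `masked_intervals`
#'   (0-based half-open), `quadruplex_intervals`.
#' @export
complexity_profile <- function(seq, window = 20, threshold = 70,
                               mask_low_complexity = TRUE,
                               mask_quadruplex = TRUE) {
  seq <- toupper(seq)
  assert_dna(seq)
  n <- nchar(seq)
  lcr <- if (mask_low_complexity && n >= window)
    find_low_complexity_regions(seq, window, threshold)
  else data.frame(start = integer(0), end = integer(0))
  g4 <- if (mask_quadruplex) find_quadruplex_motifs(seq)
  else data.frame(start = integer(0), end = integer(0),
                  strand = character(0))
  masked <- merge_intervals(rbind(lcr, g4[, c("start", "end")]))
  structure(list(
    lc_percent = if (n >= 3) linguistic_complexity(seq) else NA_real_,
    masked_intervals = masked,
    quadruplex_intervals = g4
  ), class = "complexity_profile")
}
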