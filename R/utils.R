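# Shared low-level sequence helpers. All internal sequence handling is
# uppercase ACGT; coordinates are 0-based half-open, converted to 1-based
# inclusive only at the reporting layer.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA sequence
#'
#' @param seq Character scalar over `A/C/G/T` (case-insensitive).
#' @return Uppercase reverse complement.
#' @examples
#' reverse_complement("ccagctgaacggt")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("acgtACGT", "TGCATGCA", seq)
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

assert_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(seq) > 0L && grepl("[^ACGT]", seq))
    stop(what, " contains non-ACGT symbols: ",
         gsub("[ACGT]", "", seq), call. = FALSE)
  invisible(seq)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Watson-Crick pairing predicate for two same-length character vectors
# (second vector read 3'->5' against the first). G.T wobbles excluded.
wc_paired <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G")
}

# Merge a data.frame of 0-based half-open intervals (start, end) into
# maximal non-overlapping intervals, sorted by start.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  res_s <- integer(0); res_e <- integer(0)
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      if (iv$start[i] <= out_e) {
        out_e <- max(out_e, iv$end[i])
      } else {
        res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
        out_s <- iv$start[i]; out_e <- iv$end[i]
      }
    }
  }
  data.frame(start = c(res_s, out_s), end = c(res_e, out_e))
}

# TRUE if [start, end) overlaps any interval in iv.
overlaps_any <- function(start, end, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(FALSE)
  any(start < iv$end & end > iv$start)
}

# Run a block with a private RNG stream: the global .Random.seed is
# restored afterwards, so seeded package routines never disturb user code.
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fmt_num <- function(x, digits) {
  # Fixed-format numbers for byte-stable exports (no scientific notation,
  # "." decimal separator regardless of locale).
  formatC(x, format = "f", digits = digits, decimal.mark = ".")
}
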