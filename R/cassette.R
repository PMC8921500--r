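# Universal FRET-cassette system: a shared 13-nt tail carried by every
# fluorophore-labelled universal probe (UP), a 6-nt channel barcode per
# fluorophore, and a single quencher oligo (reverse complement of the
# tail) that contact-quenches all channels.  Tail case is annotation
# only: lowercase = universal tail, uppercase = barcode.

#' Construct a FRET cassette
#'
#' @param universal_tail Tail shared by all universal probes (the 5'
#'   region of each UP and of each tailed allele-specific primer).
#' @param channels Data frame with columns `barcode` (6-nt DNA) and
#'   `fluorophore` (label text), at most 4 rows; optional `name` column.
#' @param quencher Quencher oligo sequence (should be the reverse
#'   complement of the tail; checked by [validate_cassette()], not here).
#' @param quencher_label 3' quencher moiety label (annotation).
#' @return A `fret_cassette`; each channel's `up_sequence` is
#'   `tail + barcode` (tail lowercase, barcode uppercase, as annotation).
#' @examples
#' default_cassettes()
#' @export
fret_cassette <- function(universal_tail, channels, quencher,
                          quencher_label = "quencher") {
  tail_up <- toupper(universal_tail)
  assert_dna(tail_up, "universal_tail")
  stopifnot(is.data.frame(channels),
            all(c("barcode", "fluorophore") %in% names(channels)))
  if (nrow(channels) < 1L || nrow(channels) > 4L)
    stop("a cassette carries 1-4 channels", call. = FALSE)
  channels$barcode <- toupper(channels$barcode)
  for (b in channels$barcode) assert_dna(b, "barcode")
  if (anyDuplicated(channels$barcode))
    stop("barcodes must be pairwise distinct", call. = FALSE)
  if (is.null(channels$name))
    channels$name <- paste0("UP", seq_len(nrow(channels)))
  q_up <- toupper(quencher)
  assert_dna(q_up, "quencher")
  channels$up_sequence <- paste0(tolower(tail_up), channels$barcode)
  structure(list(
    universal_tail = tolower(tail_up),
    channels = channels,
    quencher = list(sequence = tolower(q_up), label = quencher_label)
  ), class = "fret_cassette")
}

#' @export
print.fret_cassette <- function(x, ...) {
  cat(sprintf("fret_cassette: %d-nt tail '%s', %d channel(s)\n",
              nchar(x$universal_tail), x$universal_tail,
              nrow(x$channels)))
  for (i in seq_len(nrow(x$channels)))
    cat(sprintf("  %s  %-22s %s\n", x$channels$name[i],
                x$channels$up_sequence[i], x$channels$fluorophore[i]))
  cat(sprintf("  %s  %-22s %s\n", "Uni-Q", x$quencher$sequence,
              x$quencher$label))
  invisible(x)
}

#' The default four-channel cassette
#'
#' The shipped universal reporter set: tail `ccagctgaacggt`; barcodes
#' ACGGCA (FAM), CGTTGC (HEX/JOE/VIC), AGCCGA (Cy3/TAMRA), GCGTCA
#' (Cy5/Liz); quencher `accgttcagctgg` with a 3' BHQ1/Eclipse moiety.
#'
#' @return A `fret_cassette`.
#' @export
default_cassettes <- function() {
  path <- system.file("extdata", "cassette_default.tsv",
                      package = "asqdesign", mustWork = TRUE)
  read_cassette_tsv(path)
}

#' Read / write a cassette TSV
#'
#' Plain-text exchange format with columns `role` (`probe`/`quencher`),
#' `name`, `sequence` (case marks tail vs barcode), `label`.  Probe rows
#' must share a common prefix (the universal tail) identified as the
#' longest common prefix of all probe sequences.
#'
#' @param path File path.
#' @return `read_cassette_tsv`: a `fret_cassette`.
#' @export
read_cassette_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("role", "name", "sequence", "label")
  if (!all(need %in% names(tab)))
    stop("cassette TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  probes <- tab[tab$role == "probe", , drop = FALSE]
  quench <- tab[tab$role == "quencher", , drop = FALSE]
  if (nrow(probes) < 1L || nrow(quench) != 1L)
    stop("cassette TSV needs >= 1 probe row and exactly 1 quencher row",
         call. = FALSE)
  ups <- toupper(probes$sequence)
  tail_len <- 0L
  while (tail_len < min(nchar(ups)) &&
         length(unique(substr(ups, 1L, tail_len + 1L))) == 1L)
    tail_len <- tail_len + 1L
  if (tail_len == 0L)
    stop("probe sequences share no common tail", call. = FALSE)
  fret_cassette(
    universal_tail = substr(ups[1], 1L, tail_len),
    channels = data.frame(name = probes$name,
                          barcode = substr(ups, tail_len + 1L,
                                           nchar(ups)),
                          fluorophore = probes$label,
                          stringsAsFactors = FALSE),
    quencher = quench$sequence,
    quencher_label = quench$label
  )
}

#' @rdname read_cassette_tsv
#' @param cassette A `fret_cassette`.
#' @return `write_cassette_tsv`: the path, invisibly.
#' @export
write_cassette_tsv <- function(cassette, path) {
  stopifnot(inherits(cassette, "fret_cassette"))
  rows <- c("role\tname\tsequence\tlabel",
            sprintf("probe\t%s\t%s\t%s", cassette$channels$name,
                    cassette$channels$up_sequence,
                    cassette$channels$fluorophore),
            sprintf("quencher\tUni-Q\t%s\t%s", cassette$quencher$sequence,
                    cassette$quencher$label))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Attach cassette tails to an allele-specific primer set
#'
#' Prepends each assigned channel's full UP sequence (tail + barcode) to
#' the corresponding ASP core, recomputes the whole-primer metrics, and
#' re-screens the tailed sequences for self-dimers (the tail can create
#' structure the core alone does not have).
#'
#' @param asp_set List of ASP `primer_candidate` objects (one per allele).
#' @param cassette A `fret_cassette`.
#' @param channel_assignment Integer vector mapping allele index ->
#'   channel row; must be injective.  Default: allele order follows
#'   cassette row order (first allele -> first channel).
#' @param cond [thermo_conditions()] for the recomputed metrics.
#' @param thresholds [dimer_thresholds()] for the re-screen.
#' @return The ASP set with `tail_sequence`, `full_sequence`, `channel`,
#'   `fluorophore`, full-sequence `metrics`, and `tail_self_dimer` filled.
#' @export
attach_tails <- function(asp_set, cassette,
                         channel_assignment = seq_along(asp_set),
                         cond = thermo_conditions(),
                         thresholds = dimer_thresholds()) {
  stopifnot(inherits(cassette, "fret_cassette"))
  n <- length(asp_set)
  if (n > nrow(cassette$channels))
    stop("more alleles (", n, ") than cassette channels (",
         nrow(cassette$channels), ")", call. = FALSE)
  if (length(channel_assignment) != n ||
      anyDuplicated(channel_assignment) ||
      any(channel_assignment < 1L) ||
      any(channel_assignment > nrow(cassette$channels)))
    stop("channel_assignment must be an injective map into the cassette",
         call. = FALSE)
  for (i in seq_len(n)) {
    ch <- channel_assignment[i]
    tail_seq <- toupper(cassette$channels$up_sequence[ch])
    asp_set[[i]]$tail_sequence <- tail_seq
    asp_set[[i]]$full_sequence <- paste0(tail_seq,
                                         asp_set[[i]]$core_sequence)
    asp_set[[i]]$channel <- cassette$channels$name[ch]
    asp_set[[i]]$fluorophore <- cassette$channels$fluorophore[ch]
    asp_set[[i]]$core_metrics <- asp_set[[i]]$metrics
    asp_set[[i]]$metrics <- oligo_metrics(asp_set[[i]]$full_sequence, cond)
    asp_set[[i]]$tail_self_dimer <- self_dimer(asp_set[[i]]$full_sequence,
                                               thresholds)
  }
  asp_set
}

#' Validate a FRET cassette
#'
#' Structural and thermodynamic checks: quencher is the reverse
#' complement of the universal tail (so it anneals flush to every UP's
#' first bases, 5' fluorophore opposite 3' quencher for contact
#' quenching); quencher shorter than the UPs; 6-nt pairwise-distinct
#' barcodes; quencher:tail duplex Tm near the signal-read temperature at
#' the quencher concentration; UP Tm within the probe window.
#'
#' @param cassette A `fret_cassette`.
#' @param cond [thermo_conditions()] for UP Tm (probe concentration).
#' @param quencher_conc Quencher strand concentration, mol/L (default
#'   500 nM - quenchers are dosed in excess over each probe).
#' @param read_temp Signal-read temperature in C the quencher duplex
#'   should melt near (default 55).
#' @param read_tol Allowed deviation of quencher duplex Tm from
#'   `read_temp` (default 3 C).
#' @param up_tm_window Required UP Tm window in C (default 66-68).
#' @return A `cassette_validation`: data frame of checks (`check`,
#'   `pass`, `value`, `detail`) with attribute `pass` for the
#'   conjunction.
#' @export
validate_cassette <- function(cassette, cond = thermo_conditions(),
                              quencher_conc = 500e-9, read_temp = 55,
                              read_tol = 3, up_tm_window = c(66, 68)) {
  stopifnot(inherits(cassette, "fret_cassette"))
  tail_up <- toupper(cassette$universal_tail)
  q_up <- toupper(cassette$quencher$sequence)
  checks <- list()
  add <- function(check, pass, value, detail) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, value = value, detail = detail,
      stringsAsFactors = FALSE)
  }
  add("quencher_is_tail_revcomp",
      identical(q_up, reverse_complement(tail_up)), NA_real_,
      sprintf("quencher %s vs revcomp(tail) %s", q_up,
              reverse_complement(tail_up)))
  add("quencher_shorter_than_up",
      nchar(q_up) < min(nchar(cassette$channels$up_sequence)),
      nchar(q_up), "quencher must be shorter than the probes")
  add("barcodes_6nt", all(nchar(cassette$channels$barcode) == 6L),
      NA_real_, paste(cassette$channels$barcode, collapse = ","))
  add("barcodes_distinct", !anyDuplicated(cassette$channels$barcode) > 0,
      NA_real_, "pairwise distinct channel barcodes")
  # barcode 3' ends must not be mutually complementary (probe-probe
  # annealing at the reporter step)
  bc <- toupper(cassette$channels$barcode)
  bc_ok <- TRUE
  if (length(bc) > 1L) {
    for (i in seq_along(bc)[-length(bc)]) for (j in (i + 1L):length(bc)) {
      h <- cross_dimer(paste0("AAAAA", bc[i]), paste0("AAAAA", bc[j]))
      if (h$run_length >= 4L && (h$involves_3prime_a || h$involves_3prime_b))
        bc_ok <- FALSE
    }
  }
  add("barcode_3prime_noncomplementary", bc_ok, NA_real_,
      "no >= 4 bp 3'-anchored barcode-barcode duplex")
  qcond <- thermo_conditions(oligo_conc = quencher_conc,
                             monovalent = cond$monovalent,
                             mg_total = cond$mg_total,
                             dntp_total = cond$dntp_total)
  qtm <- if (nchar(q_up) >= 8L) melting_temperature(q_up, qcond)
  else NA_real_
  add("quencher_duplex_tm_near_read_temp",
      !is.na(qtm) && abs(qtm - read_temp) <= read_tol, qtm,
      sprintf("target %.1f C +/- %.1f at %.0f nM", read_temp, read_tol,
              quencher_conc * 1e9))
  up_tms <- vapply(cassette$channels$up_sequence,
                   function(s) melting_temperature(toupper(s), cond),
                   numeric(1))
  add("up_tm_in_window",
      all(up_tms >= up_tm_window[1] & up_tms <= up_tm_window[2]),
      mean(up_tms),
      paste(sprintf("%.1f", up_tms), collapse = ", "))
  add("contact_quenching_geometry",
      identical(q_up, reverse_complement(tail_up)), NA_real_,
      "UP 5' label sits opposite the quencher 3' label when annealed")
  out <- do.call(rbind, checks)
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("cassette_validation", class(out))
  out
}

#' @export
print.cassette_validation <- function(x, ...) {
  cat("cassette_validation:", if (attr(x, "pass")) "PASS" else "FAIL",
      "\n")
  df <- as.data.frame(x)
  df$value <- ifelse(is.na(df$value), "", sprintf("%.1f", df$value))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Design a custom FRET cassette
#'
#' Deterministic seeded search for a universal tail (12-14 nt whose
#' quencher duplex melts near the read temperature at the quencher
#' concentration) and `n_channels` pairwise-dissimilar 6-nt barcodes such
#' that [validate_cassette()] passes and no UP cross-dimer between
#' channels fails the interaction screen.
#'
#' Barcode candidates are drawn from all 4096 6-mers filtered for GC
#' between `barcode_gc[1]` and `barcode_gc[2]`, no homotrinucleotide, and
#' pairwise Hamming distance of at least `min_hamming`.
#'
#' @param n_channels Number of channels (2-4).
#' @param cond [thermo_conditions()] for probe Tm.
#' @param seed Integer seed making the search reproducible.
#' @param read_temp,read_tol Quencher duplex target Tm and tolerance.
#' @param quencher_conc Quencher concentration, mol/L.
#' @param up_tm_window Required probe Tm window.
#' @param barcode_gc Barcode GC-fraction bounds (default 1/3 - 5/6).
#' @param min_hamming Minimum pairwise barcode Hamming distance.
#' @param max_tries Tail candidates to examine before giving up.
#' @return A validated `fret_cassette`.
#' @export
design_custom_cassette <- function(n_channels = 2,
                                   cond = thermo_conditions(),
                                   seed = 1L,
                                   read_temp = 55, read_tol = 3,
                                   quencher_conc = 500e-9,
                                   up_tm_window = c(66, 68),
                                   barcode_gc = c(1 / 3, 5 / 6),
                                   min_hamming = 3,
                                   max_tries = 2000) {
  if (n_channels < 2 || n_channels > 4)
    stop("n_channels must be 2-4", call. = FALSE)
  fluor <- c("FAM", "HEX/JOE/VIC", "Cy3/TAMRA", "Cy5/Liz")[1:n_channels]
  # barcode pool, fixed order for determinism
  mers <- expand.grid(rep(list(DNA_BASES), 6), stringsAsFactors = FALSE)
  pool <- do.call(paste0, mers)
  gcf <- vapply(pool, function(s) gc_content(s) / 100, numeric(1))
  keep <- gcf >= barcode_gc[1] & gcf <= barcode_gc[2] &
    !grepl("AAA|CCC|GGG|TTT", pool)
  pool <- pool[keep]
  with_private_seed(seed, {
    for (try_i in seq_len(max_tries)) {
      tail_len <- sample(12:14, 1L)
      tail_seq <- paste(sample(DNA_BASES, tail_len, replace = TRUE),
                        collapse = "")
      qcond <- thermo_conditions(oligo_conc = quencher_conc,
                                 monovalent = cond$monovalent,
                                 mg_total = cond$mg_total,
                                 dntp_total = cond$dntp_total)
      qtm <- melting_temperature(tail_seq, qcond)
      if (abs(qtm - read_temp) > read_tol) next
      if (!is.null(hairpin_or_null(tail_seq))) next
      # greedy barcode selection from a shuffled pool
      cand <- sample(pool)
      chosen <- character(0)
      for (b in cand) {
        up <- paste0(tail_seq, b)
        if (melting_temperature(up, cond) < up_tm_window[1] ||
            melting_temperature(up, cond) > up_tm_window[2]) next
        if (length(chosen) > 0) {
          hd <- vapply(chosen, function(x)
            sum(seq_chars(x) != seq_chars(b)), integer(1))
          if (any(hd < min_hamming)) next
          bad <- FALSE
          for (x in chosen) {
            h <- cross_dimer(paste0(tail_seq, x), up)
            if (h$fails) { bad <- TRUE; break }
          }
          if (bad) next
        }
        if (self_dimer(up)$fails) next
        chosen <- c(chosen, b)
        if (length(chosen) == n_channels) break
      }
      if (length(chosen) < n_channels) next
      cas <- fret_cassette(
        universal_tail = tail_seq,
        channels = data.frame(name = paste0("UP", seq_len(n_channels)),
                              barcode = chosen, fluorophore = fluor,
                              stringsAsFactors = FALSE),
        quencher = reverse_complement(tail_seq),
        quencher_label = "BHQ1/Eclipse")
      v <- validate_cassette(cas, cond, quencher_conc, read_temp,
                             read_tol, up_tm_window)
      if (attr(v, "pass")) return(cas)
    }
    stop("custom cassette search exhausted after ", max_tries,
         " tail candidates (constraints too tight)", call. = FALSE)
  })
}

# hairpin() errors below the geometric minimum length; treat that as none.
hairpin_or_null <- function(seq, ...) {
  tryCatch(hairpin(seq, ...), error = function(e) NULL)
}
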