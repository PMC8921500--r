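# Core assay design: allele-specific primers on either strand with the
# variable base at a configurable 3'-end offset, discriminative 3' ends
# for InDels, Tm equalization across the competing primers, and a common
# reverse primer closing a 100-200 bp amplicon.
#
# Internally a design works in a "frame": the flank carrying the ASPs is
# `left` (primers read toward the site), the opposite flank is `right`.
# For minus-strand designs the frame is the reverse complement of the
# template and coordinates are mapped back at reporting time.

#' Design pipeline options
#'
#' @param snp_pos_mode Where the variable base sits relative to the ASP
#'   3' end for SNP sites: `"first"` (terminal base), `"penultimate"`
#'   (default; one template base follows the variable base),
#'   `"antepenultimate"`, or `"auto"` (offsets 1-3 compared by a
#'   3'-destabilization criterion).
#' @param primer_length Candidate core length bounds, nt.
#' @param max_primer_length Hard cap when 5'-extending for Tm
#'   equalization, nt.
#' @param min_flank Minimum usable flank on the ASP side, nt.
#' @param tm_target,tm_window Target primer Tm and half-width of the
#'   accepted window, Celsius (defaults 63 and 1, i.e. 62-64).
#' @param amplicon_range Allowed amplicon sizes, bp.
#' @param max_end_length Longest allele-discriminating 3'-end, nt.
#' @param lc_window,lc_threshold Low-complexity masking parameters.
#' @param mask_low_complexity,mask_quadruplex Toggle placement masks.
#' @param end3_band Acceptable 3'-terminal pentamer free-energy band,
#'   kcal/mol.
#' @param gc_range Unpenalized GC-content range, percent.
#' @param pq_weights Penalty weights (summing to 100) for the primer
#'   quality score: Tm deviation, 3'-end stability, self-structure,
#'   linguistic complexity, GC content.
#' @param thresholds Interaction-screen thresholds, [dimer_thresholds()].
#' @param max_mismatches,require_3prime_match Binding-site scan settings.
#' @param size_margin Multiplex product-size discrimination margin, bp.
#' @param annealing_offset Recommended annealing temperature is
#'   `min(primer Tm) - annealing_offset`.
#' @return Named list of options.
#' @export
design_options <- function(snp_pos_mode = c("penultimate", "first",
                                            "antepenultimate", "auto"),
                           primer_length = c(18, 30),
                           max_primer_length = 36,
                           min_flank = 35,
                           tm_target = 63,
                           tm_window = 1,
                           amplicon_range = c(100, 200),
                           max_end_length = 12,
                           lc_window = 20,
                           lc_threshold = 70,
                           mask_low_complexity = TRUE,
                           mask_quadruplex = TRUE,
                           end3_band = c(-9, -5),
                           gc_range = c(40, 60),
                           pq_weights = c(tm = 30, end3 = 25, dimer = 25,
                                          lc = 10, gc = 10),
                           thresholds = dimer_thresholds(),
                           max_mismatches = 2,
                           require_3prime_match = 3,
                           size_margin = 10,
                           annealing_offset = 2) {
  snp_pos_mode <- match.arg(snp_pos_mode)
  stopifnot(primer_length[1] >= 8, primer_length[2] >= primer_length[1],
            max_primer_length >= primer_length[2],
            tm_window > 0, amplicon_range[2] > amplicon_range[1],
            max_end_length >= 1)
  as.list(environment())
}

offset_for_mode <- function(mode) {
  switch(mode, first = 1L, penultimate = 2L, antepenultimate = 3L,
         stop("snp_pos_mode '", mode, "' has no fixed offset",
              call. = FALSE))
}

# All per-oligo report metrics for one sequence.
oligo_metrics <- function(seq, cond = thermo_conditions(),
                          options = design_options()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  list(
    length = n,
    tm = if (n >= 8) melting_temperature(seq, cond) else NA_real_,
    delta_g = duplex_delta_g(seq),
    gc = gc_content(seq),
    lc = if (n >= 3) linguistic_complexity(seq) else NA_real_,
    mw = molecular_weight(seq),
    extinction = extinction_coefficient(seq),
    terminal_dg = if (n >= 5) terminal_stability(seq, 5) else NA_real_,
    pq = score_primer(seq, cond, options)
  )
}

#' Primer quality score
#'
#' Deterministic composite in [0, 100]: 100 minus weighted penalties for
#' Tm deviation from the target window, a 3'-terminal pentamer outside
#' the stability band, self-dimer/hairpin structure, low linguistic
#' complexity, and extreme GC content.  Depends only on the candidate
#' sequence and the conditions, never on template context.
#'
#' @param candidate A sequence string or a `primer_candidate`.
#' @param cond [thermo_conditions()].
#' @param options [design_options()] (weights, window, bands).
#' @return PQ in percent.
#' @export
score_primer <- function(candidate, cond = thermo_conditions(),
                         options = design_options()) {
  seq <- if (inherits(candidate, "primer_candidate"))
    candidate$core_sequence else toupper(candidate)
  assert_dna(seq)
  w <- options$pq_weights
  n <- nchar(seq)
  win <- options$tm_target + c(-1, 1) * options$tm_window
  pen <- 0
  if (n >= 8) {
    tm <- melting_temperature(seq, cond)
    dev <- max(0, win[1] - tm, tm - win[2])
    pen <- pen + w[["tm"]] * min(1, dev / 5)
  }
  if (n >= 5) {
    t5 <- terminal_stability(seq, 5)
    dist <- max(0, options$end3_band[1] - t5, t5 - options$end3_band[2])
    pen <- pen + w[["end3"]] * min(1, dist / 3)
  }
  worst <- 0
  if (n >= 6) worst <- min(worst, self_dimer(seq)$score_delta_g)
  hp <- hairpin_or_null(seq)
  if (!is.null(hp)) worst <- min(worst, hp$score_delta_g)
  pen <- pen + w[["dimer"]] * min(1, max(0, -worst - 6) / 4)
  if (n >= 3) {
    lc <- linguistic_complexity(seq)
    pen <- pen + w[["lc"]] *
      min(1, max(0, options$lc_threshold - lc) / 30)
  }
  gc <- gc_content(seq)
  pen <- pen + w[["gc"]] *
    min(1, max(0, options$gc_range[1] - gc, gc - options$gc_range[2]) / 20)
  max(0, 100 - pen)
}

#' Construct a primer candidate
#'
#' @param name Primer name.
#' @param core_sequence Target-binding sequence, 5'->3'.
#' @param role `"ASP"`, `"common"`, `"probe"` or `"quencher"`.
#' @param strand `"plus"` or `"minus"` (template strand the primer
#'   matches).
#' @param template_interval 0-based half-open interval covered on the
#'   (allele-substituted) plus-strand template, or `NULL`.
#' @param allele_index 1-based allele index (ASPs only).
#' @param allele Allele string (ASPs only).
#' @param snp_offset_from_3prime Variable-base offset from the 3' end
#'   (1 = terminal base) for SNP-mode ASPs.
#' @param tail_sequence Optional 5' tail (filled by [attach_tails()]).
#' @param cond,options Metric computation settings.
#' @return A `primer_candidate` with computed `metrics`.
#' @export
primer_candidate <- function(name, core_sequence, role = "ASP",
                             strand = "plus", template_interval = NULL,
                             allele_index = NA_integer_,
                             allele = NA_character_,
                             snp_offset_from_3prime = NA_integer_,
                             tail_sequence = NULL,
                             cond = thermo_conditions(),
                             options = design_options()) {
  core_sequence <- toupper(core_sequence)
  assert_dna(core_sequence, "core_sequence")
  full <- paste0(if (is.null(tail_sequence)) "" else toupper(tail_sequence),
                 core_sequence)
  structure(list(
    name = name, core_sequence = core_sequence,
    tail_sequence = if (is.null(tail_sequence)) NULL
    else toupper(tail_sequence),
    full_sequence = full, role = role, strand = strand,
    template_interval = template_interval,
    allele_index = allele_index, allele = allele,
    snp_offset_from_3prime = snp_offset_from_3prime,
    metrics = oligo_metrics(core_sequence, cond, options)
  ), class = "primer_candidate")
}

#' @export
print.primer_candidate <- function(x, ...) {
  m <- x$metrics
  core_note <- if (!is.null(x$core_metrics))
    sprintf(", core Tm %.1f", x$core_metrics$tm) else ""
  cat(sprintf(
    "%s [%s/%s] %s  (%d nt, Tm %.1f%s, dG %.1f, GC %.1f, LC %.0f, PQ %.0f)\n",
    x$name, x$role, x$strand, x$full_sequence, m$length, m$tm, core_note,
    m$delta_g, m$gc, m$lc, m$pq))
  invisible(x)
}

#' Allele-discriminating 3' ends for a variant site
#'
#' For each allele, the shortest 3'-terminal string (at most `max_len`
#' nt) formed from the allele content followed by downstream template
#' sequence, such that every allele's string differs from every other
#' allele's string over its own length - so each allele-specific primer
#' ends in sequence found only on its own allele.  For pure SNP sites the
#' minimum length is 1; `snp_offset` shifts the variable base away from
#' the terminus (2 = penultimate).
#'
#' @param site A [variant_site()].
#' @param downstream Template sequence 3' of the site (the shared flank),
#'   in the design frame.
#' @param snp_offset Offset applied to SNP sites (ignored for
#'   InDel/mixed sites, whose end lengths are determined automatically).
#' @param max_len Longest allowed discriminating end (default 12 nt).
#' @return Data frame with `allele`, `end_length` and `discriminator`
#'   (the 3'-terminal string, 5'->3').
#' @examples
#' generate_indel_3prime_ends(variant_site(0, c("", "CT")), "GTACGT")
#' @export
generate_indel_3prime_ends <- function(site, downstream, snp_offset = 2L,
                                       max_len = 12L) {
  stopifnot(inherits(site, "variant_site"))
  downstream <- toupper(downstream)
  assert_dna(downstream, "downstream")
  s <- paste0(site$alleles, downstream)
  k <- length(s)
  min_e <- integer(k)
  for (i in seq_len(k)) {
    found <- NA_integer_
    for (e in seq_len(min(max_len, min(nchar(s))))) {
      pi <- substr(s[i], 1L, e)
      if (all(substr(s[-i], 1L, e) != pi)) { found <- e; break }
    }
    if (is.na(found))
      stop("alleles not discriminable within ", max_len,
           " nt at site offset ", site$position, call. = FALSE)
    min_e[i] <- found
  }
  e <- if (site$site_kind == "SNP") {
    pmin(min_e + (as.integer(snp_offset) - 1L), max_len)
  } else min_e
  if (any(e > nchar(s)))
    stop("downstream flank too short for the discriminating ends",
         call. = FALSE)
  data.frame(allele = site$alleles, end_length = e,
             discriminator = substr(s, 1L, e),
             stringsAsFactors = FALSE)
}

# Build the design frame for one site/strand. `left` carries the ASPs
# (reading toward the site), `right` is the opposite flank (downstream of
# the site in frame orientation).
site_frame <- function(template, site_index, strand) {
  s <- template$sites[[site_index]]
  seqs <- lapply(seq_along(template$sites), function(i) NULL)
  backbone <- template$sequence
  # neighbouring sites are fixed at their first allele so flanks are
  # concrete sequence
  fixed <- substitute_allele(template, site_index, 1L)
  pos <- fixed$site_start
  full <- fixed$sequence
  left <- substr(full, 1L, pos)
  right <- substr(full, fixed$site_end + 1L, nchar(full))
  alleles <- s$alleles
  if (strand == "minus") {
    tmp <- left
    left <- reverse_complement(right)
    right <- reverse_complement(tmp)
    alleles <- vapply(alleles, reverse_complement, character(1),
                      USE.NAMES = FALSE)
  }
  list(left = left, right = right, alleles = alleles,
       site = s, strand = strand,
       site_kind = s$site_kind)
}

frame_site <- function(frame) {
  # a variant_site in frame orientation (position = end of left flank)
  variant_site(nchar(frame$left), frame$alleles)
}

# Allele-substituted sequence in frame orientation plus its mask.
frame_allele_seq <- function(frame, i, options) {
  seq <- paste0(frame$left, frame$alleles[i], frame$right)
  prof <- complexity_profile(
    seq, window = options$lc_window, threshold = options$lc_threshold,
    mask_low_complexity = options$mask_low_complexity,
    mask_quadruplex = options$mask_quadruplex)
  list(sequence = seq, mask = prof$masked_intervals)
}

#' Enumerate allele-specific primer candidates
#'
#' For each allele of the chosen site, generates core candidates whose 3'
#' end carries the allele's discriminating end (SNP variable base at the
#' requested offset; InDel ends determined automatically) and whose 5'
#' start varies over the configured core-length range.  Candidates that
#' overlap masked (low-complexity / G-quadruplex) intervals are dropped.
#'
#' @param template A [polymorphic_template()].
#' @param site Site index (1-based).
#' @param strand `"plus"` or `"minus"` - the strand the ASPs match.
#' @param snp_pos_mode See [design_options()]; `"auto"` is resolved by
#'   [design_assay()], so a fixed mode is required here.
#' @param cond [thermo_conditions()].
#' @param options [design_options()].
#' @return List (one entry per allele) of candidate data frames with
#'   columns `core_sequence`, `start`, `end` (0-based half-open, frame
#'   orientation on the allele-substituted sequence), `length`,
#'   `end_length`, `tm`, `delta_g`, `gc`, `lc`, `terminal_dg`, `pq`;
#'   attributes `frame` and `ends`.
#' @export
enumerate_asp_candidates <- function(template, site = 1L,
                                     strand = c("plus", "minus"),
                                     snp_pos_mode = "penultimate",
                                     cond = thermo_conditions(),
                                     options = design_options()) {
  strand <- match.arg(strand)
  stopifnot(inherits(template, "polymorphic_template"))
  if (site < 1L || site > length(template$sites))
    stop("no such site: ", site, call. = FALSE)
  frame <- site_frame(template, site, strand)
  if (nchar(frame$left) < options$min_flank)
    stop("insufficient flank on the ", strand,
         "-strand ASP side (", nchar(frame$left), " < ",
         options$min_flank, " nt)", call. = FALSE)
  offset <- if (frame$site_kind == "SNP")
    offset_for_mode(snp_pos_mode) else 2L
  ends <- generate_indel_3prime_ends(frame_site(frame), frame$right,
                                     snp_offset = offset,
                                     max_len = options$max_end_length)
  pos <- nchar(frame$left)
  out <- vector("list", length(frame$alleles))
  for (i in seq_along(frame$alleles)) {
    fa <- frame_allele_seq(frame, i, options)
    e <- ends$end_length[i]
    lens <- options$primer_length[1]:options$max_primer_length
    rows <- lapply(lens, function(L) {
      flank_take <- L - e
      if (flank_take < 1L || flank_take > pos) return(NULL)
      start <- pos - flank_take
      end <- pos + e
      if (overlaps_any(start, end, fa$mask)) return(NULL)
      core <- paste0(substr(frame$left, start + 1L, pos),
                     ends$discriminator[i])
      m <- oligo_metrics(core, cond, options)
      data.frame(core_sequence = core, start = start, end = end,
                 length = L, end_length = e, tm = m$tm,
                 delta_g = m$delta_g, gc = m$gc, lc = m$lc,
                 terminal_dg = m$terminal_dg, pq = m$pq,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
      df <- data.frame(core_sequence = character(0), start = integer(0),
                       end = integer(0), length = integer(0),
                       end_length = integer(0), tm = numeric(0),
                       delta_g = numeric(0), gc = numeric(0),
                       lc = numeric(0), terminal_dg = numeric(0),
                       pq = numeric(0))
    out[[i]] <- df
  }
  names(out) <- ifelse(frame$alleles == "", "-", frame$alleles)
  attr(out, "frame") <- frame
  attr(out, "ends") <- ends
  attr(out, "snp_offset") <- if (frame$site_kind == "SNP") offset
  else NA_integer_
  out
}

#' Equalize melting temperatures across an ASP set
#'
#' Selects one candidate per allele - only ever varying the 5' start, the
#' allele-discriminating 3' ends are fixed - such that every chosen
#' primer's Tm lies within `target_tm +/- window` and the pairwise Tm
#' spread is minimal (a low-Tm allele is 5'-extended toward the Tm of its
#' GC-richer competitors).  Already-conformant sets are returned
#' unchanged.
#'
#' @param candidate_set Output of [enumerate_asp_candidates()].
#' @param target_tm Target Tm, Celsius.
#' @param window Half-width of the accepted window, Celsius.
#' @return The candidate set reduced to one row per allele (attributes
#'   preserved).
#' @export
equalize_tm <- function(candidate_set, target_tm = 63, window = 1) {
  lo <- target_tm - window; hi <- target_tm + window
  filtered <- lapply(seq_along(candidate_set), function(i) {
    df <- candidate_set[[i]]
    df <- df[!is.na(df$tm) & df$tm >= lo & df$tm <= hi, , drop = FALSE]
    if (nrow(df) == 0L)
      stop("cannot reach the Tm window [", lo, ", ", hi,
           "] for allele ", i, " ('", names(candidate_set)[i],
           "') within the maximum primer length", call. = FALSE)
    df
  })
  # cap the exhaustive search: keep the candidates nearest the target
  sizes <- vapply(filtered, nrow, integer(1))
  while (prod(sizes) > 2e5) {
    k <- which.max(sizes)
    df <- filtered[[k]]
    df <- df[order(abs(df$tm - target_tm), df$length), , drop = FALSE]
    filtered[[k]] <- df[seq_len(ceiling(nrow(df) / 2)), , drop = FALSE]
    sizes <- vapply(filtered, nrow, integer(1))
  }
  idx_grid <- expand.grid(lapply(sizes, seq_len))
  tms <- mapply(function(df, col) df$tm[idx_grid[[col]]],
                filtered, seq_along(filtered))
  tms <- matrix(tms, nrow = nrow(idx_grid))
  spread <- apply(tms, 1, max) - apply(tms, 1, min)
  meandev <- abs(rowMeans(tms) - target_tm)
  lens_m <- matrix(mapply(function(df, col) df$length[idx_grid[[col]]],
                          filtered, seq_along(filtered)),
                   nrow = nrow(idx_grid))
  totlen <- rowSums(lens_m)
  best <- order(spread, meandev, totlen)[1]
  out <- lapply(seq_along(filtered), function(i)
    filtered[[i]][idx_grid[best, i], , drop = FALSE])
  names(out) <- names(candidate_set)
  attributes(out)[c("frame", "ends", "snp_offset")] <-
    attributes(candidate_set)[c("frame", "ends", "snp_offset")]
  out
}

#' Design the common (reverse) primer for an ASP set
#'
#' Enumerates opposite-strand candidates downstream of the site such that
#' every allele's amplicon (ASP 5' end through common-primer 5' end on
#' the allele-substituted template) lies within `amplicon_range`, the
#' candidate avoids masked intervals, and its Tm sits in the primer
#' window.  Candidates are ranked by closeness to the mean ASP Tm, then
#' by primer quality, then leftmost.
#'
#' @param template A [polymorphic_template()].
#' @param site Site index.
#' @param asp_set Equalized ASP set from [equalize_tm()].
#' @param amplicon_range Allowed product sizes, bp.
#' @param cond,options See [design_options()].
#' @return Ranked data frame of candidates: `core_sequence`, `rel_start`
#'   (0-based offset into the frame's downstream flank), `length`, `tm`,
#'   `pq`, `dtm`, plus one `amplicon_<k>` column per allele.
#' @export
design_common_primer <- function(template, site = 1L, asp_set,
                                 amplicon_range = c(100, 200),
                                 cond = thermo_conditions(),
                                 options = design_options()) {
  frame <- attr(asp_set, "frame")
  if (is.null(frame))
    stop("asp_set must come from enumerate_asp_candidates()/equalize_tm()",
         call. = FALSE)
  right <- frame$right
  nr <- nchar(right)
  pos <- nchar(frame$left)
  k <- length(asp_set)
  # per-allele offset between common-primer frame coordinates and the
  # ASP 5' start: amplicon_i = allele_len_i + (r + L) + (L_i - e_i)
  asp_len <- vapply(asp_set, function(df) df$length[1], numeric(1))
  asp_e <- vapply(asp_set, function(df) df$end_length[1], numeric(1))
  allele_len <- nchar(frame$alleles)
  base_i <- allele_len + asp_len - asp_e
  prof <- complexity_profile(
    right, window = options$lc_window, threshold = options$lc_threshold,
    mask_low_complexity = options$mask_low_complexity &&
      nr >= options$lc_window,
    mask_quadruplex = options$mask_quadruplex)
  mask <- prof$masked_intervals
  mean_tm <- mean(vapply(asp_set, function(df) df$tm[1], numeric(1)))
  lo <- options$tm_target - options$tm_window
  hi <- options$tm_target + options$tm_window
  lens <- options$primer_length[1]:options$primer_length[2]
  rows <- list()
  achievable <- c(Inf, -Inf)
  for (L in lens) {
    if (L > nr) next
    for (r in 0:(nr - L)) {
      amps <- base_i + r + L
      achievable <- c(min(achievable[1], min(amps)),
                      max(achievable[2], max(amps)))
      if (any(amps < amplicon_range[1]) || any(amps > amplicon_range[2]))
        next
      if (overlaps_any(r, r + L, mask)) next
      core <- reverse_complement(substr(right, r + 1L, r + L))
      tm <- melting_temperature(core, cond)
      if (tm < lo || tm > hi) next
      rows[[length(rows) + 1L]] <- data.frame(
        core_sequence = core, rel_start = r, length = L, tm = tm,
        pq = score_primer(core, cond, options), dtm = abs(tm - mean_tm),
        t(stats::setNames(amps, paste0("amplicon_", seq_len(k)))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    ach <- if (is.finite(achievable[1]))
      sprintf(" (achievable amplicon range %d-%d bp)",
              as.integer(achievable[1]), as.integer(achievable[2]))
    else ""
    stop("no common-primer placement satisfies the amplicon range ",
         amplicon_range[1], "-", amplicon_range[2], " bp", ach,
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$dtm, -out$pq, out$rel_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame") <- frame
  out
}

# ---- orchestration -------------------------------------------------------

# 3'-destabilization proxy used by snp_pos_mode = "auto": for each
# allele pair, the free energy of the ASP 3'-terminal segment that
# mismatches the competing allele (suffix of length offset); the offset
# maximizing the weakest pairwise value gives the most uniformly
# destabilized wrong-allele extensions.
auto_offset_score <- function(asp_set, offset) {
  cores <- vapply(asp_set, function(df) df$core_sequence[1], character(1))
  suf <- vapply(cores, function(s)
    substr(s, nchar(s) - offset, nchar(s)), character(1))
  min(abs(vapply(suf, duplex_delta_g, numeric(1))))
}

attempt_direction <- function(template, site, strand, mode, cond,
                              options, cassette) {
  cands <- enumerate_asp_candidates(template, site, strand, mode, cond,
                                    options)
  chosen <- equalize_tm(cands, options$tm_target, options$tm_window)
  common <- design_common_primer(template, site, chosen,
                                 options$amplicon_range, cond, options)
  list(chosen = chosen, common = common[1, , drop = FALSE],
       frame = attr(cands, "frame"),
       snp_offset = attr(cands, "snp_offset"))
}

# Map a frame interval [s, e) on the allele-substituted frame sequence of
# total length n back to plus-strand coordinates.
frame_to_plus <- function(s, e, n, frame_strand) {
  if (frame_strand == "plus") c(s, e) else c(n - e, n - s)
}

build_design <- function(template, site_index, att, cond, options,
                         cassette) {
  frame <- att$frame
  k <- length(att$chosen)
  pos <- nchar(frame$left)
  alleles <- frame$site$alleles   # original orientation
  allele_names <- ifelse(alleles == "", "del", alleles)
  asp_strand <- frame$strand
  asps <- vector("list", k)
  amplicons <- integer(k)
  for (i in seq_len(k)) {
    row <- att$chosen[[i]]
    n_i <- pos + nchar(frame$alleles[i]) + nchar(frame$right)
    iv <- frame_to_plus(row$start, row$end, n_i, asp_strand)
    asps[[i]] <- primer_candidate(
      name = sprintf("%s_s%d_ASP_%s", template$name, site_index,
                     allele_names[i]),
      core_sequence = row$core_sequence,
      role = "ASP", strand = asp_strand,
      template_interval = iv,
      allele_index = i, allele = alleles[i],
      snp_offset_from_3prime = att$snp_offset,
      cond = cond, options = options)
    asps[[i]]$end_length <- row$end_length
    asps[[i]]$discriminator <- substr(row$core_sequence,
                                      nchar(row$core_sequence) -
                                        row$end_length + 1L,
                                      nchar(row$core_sequence))
    amplicons[i] <- as.integer(att$common[[paste0("amplicon_", i)]])
  }
  names(amplicons) <- allele_names
  # common primer interval, on the allele-1 substituted sequence
  r <- att$common$rel_start
  L <- att$common$length
  n_1 <- pos + nchar(frame$alleles[1]) + nchar(frame$right)
  fs <- pos + nchar(frame$alleles[1]) + r
  iv <- frame_to_plus(fs, fs + L, n_1, asp_strand)
  # frame "right" is read opposite to the ASPs, so the common primer
  # matches the other strand
  common <- primer_candidate(
    name = sprintf("%s_s%d_C", template$name, site_index),
    core_sequence = att$common$core_sequence,
    role = "common",
    strand = if (asp_strand == "plus") "minus" else "plus",
    template_interval = iv, cond = cond, options = options)
  asps <- attach_tails(asps, cassette, seq_len(k), cond,
                       options$thresholds)
  # interaction screens on the pooled reaction: dimers on full (tailed)
  # sequences, binding sites of the cores on every allele template
  fulls <- c(vapply(asps, `[[`, character(1), "full_sequence"),
             common$full_sequence)
  names(fulls) <- c(vapply(asps, `[[`, character(1), "name"), common$name)
  compat <- compatibility_report(list(target = fulls),
                                 thresholds = options$thresholds)
  tpl_seqs <- vapply(seq_len(k), function(i)
    substitute_allele(template, site_index, i)$sequence, character(1))
  names(tpl_seqs) <- paste0("allele_", allele_names)
  cores <- c(vapply(asps, `[[`, character(1), "core_sequence"),
             common$core_sequence)
  names(cores) <- names(fulls)
  binding <- matrix(0L, length(cores), length(tpl_seqs),
                    dimnames = list(names(cores), names(tpl_seqs)))
  for (p in seq_along(cores)) for (t in seq_along(tpl_seqs)) {
    binding[p, t] <- nrow(scan_binding_sites(
      cores[p], tpl_seqs[t], options$max_mismatches,
      options$require_3prime_match,
      circular = template$topology == "circular"))
  }
  nonspecific <- any(binding > 1L)
  amp_seq <- {
    sub1 <- substitute_allele(template, site_index, 1L)
    a1 <- asps[[1]]$template_interval
    c1 <- common$template_interval
    lohi <- range(c(a1, c1))
    substr(sub1$sequence, lohi[1] + 1L, lohi[2])
  }
  min_core_tm <- min(c(vapply(asps, function(p) p$core_metrics$tm,
                              numeric(1)),
                       common$metrics$tm))
  structure(list(
    template_name = template$name,
    site_index = site_index,
    site = template$sites[[site_index]],
    direction = asp_strand,
    asp_set = asps,
    common_primer = common,
    cassette = cassette,
    channel_assignment = stats::setNames(
      cassette$channels$name[seq_len(k)], allele_names),
    amplicon_lengths = amplicons,
    amplicon_tm = product_tm(amp_seq, cond),
    annealing_temp = min_core_tm - options$annealing_offset,
    compatibility = list(dimers = compat, binding = binding,
                         pass = compat$pass && !nonspecific),
    mean_pq = mean(c(vapply(asps, function(p) p$core_metrics$pq,
                            numeric(1)),
                     common$metrics$pq)),
    snp_offset = att$snp_offset
  ), class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("assay_design: %s site %d (%s), ASPs on %s strand\n",
              x$template_name, x$site_index, x$site$site_kind,
              x$direction))
  for (p in x$asp_set) print(p)
  print(x$common_primer)
  cat(sprintf("  amplicons: %s bp; product Tm ~%.1f C; anneal at %.1f C\n",
              paste(x$amplicon_lengths, collapse = "/"), x$amplicon_tm,
              x$annealing_temp))
  cat(sprintf("  channels: %s; screens: %s\n",
              paste(names(x$channel_assignment), x$channel_assignment,
                    sep = "=", collapse = ", "),
              if (x$compatibility$pass) "pass" else "FAIL"))
  invisible(x)
}

# Rotate a circular template so the target site is centered; positions
# of all sites are shifted accordingly (reported coordinates then refer
# to the rotated origin).
center_site <- function(template, site_index) {
  n <- nchar(template$sequence)
  pos <- template$sites[[site_index]]$position
  shift <- (pos - n %/% 2L) %% n
  if (shift == 0L) return(template)
  seq2 <- paste0(substr(template$sequence, shift + 1L, n),
                 substr(template$sequence, 1L, shift))
  sites2 <- lapply(template$sites, function(s)
    variant_site((s$position - shift) %% n, s$alleles))
  ord <- order(vapply(sites2, `[[`, integer(1), "position"))
  polymorphic_template(template$name, seq2, sites2[ord], "circular")
}

#' Design a complete allele-specific PCR assay for one site
#'
#' Orchestrates the full pipeline: placement masking, ASP enumeration on
#' both strands (with automatic or fixed variable-base offset and InDel
#' 3'-end generation), Tm equalization, common-primer design, cassette
#' tail attachment, and interaction screening.  Both directions are
#' attempted; the best passing design is returned with the other
#' direction retained as an alternative.  Deterministic for identical
#' inputs and options.
#'
#' @param template A [polymorphic_template()] with at least one site.
#' @param site Site index to design for.
#' @param options [design_options()].
#' @param cond [thermo_conditions()].
#' @param cassette [default_cassettes()] or a custom `fret_cassette`
#'   with at least as many channels as the site has alleles.
#' @return An `assay_design`; the attribute `alternatives` holds the
#'   other direction's design (or its failure message).
#' @export
design_assay <- function(template, site = 1L, options = design_options(),
                         cond = thermo_conditions(),
                         cassette = default_cassettes()) {
  stopifnot(inherits(template, "polymorphic_template"))
  if (length(template$sites) == 0L)
    stop("template '", template$name,
         "' has no polymorphism - nothing to design", call. = FALSE)
  if (template$topology == "circular")
    template <- center_site(template, site)
  k <- length(template$sites[[site]]$alleles)
  if (k > nrow(cassette$channels))
    stop("site has ", k, " alleles but the cassette has only ",
         nrow(cassette$channels), " channels", call. = FALSE)
  modes <- if (options$snp_pos_mode == "auto" &&
               template$sites[[site]]$site_kind == "SNP")
    c("penultimate", "antepenultimate", "first")
  else if (options$snp_pos_mode == "auto") "penultimate"
  else options$snp_pos_mode
  results <- list()
  failures <- character(0)
  for (strand in c("plus", "minus")) {
    best_att <- NULL
    best_score <- -Inf
    errs <- character(0)
    for (mode in modes) {
      att <- tryCatch(
        attempt_direction(template, site, strand, mode, cond, options,
                          cassette),
        error = function(e) e)
      if (inherits(att, "error")) {
        errs <- c(errs, sprintf("%s/%s: %s", strand, mode,
                                conditionMessage(att)))
        next
      }
      score <- if (length(modes) > 1L)
        auto_offset_score(att$chosen, offset_for_mode(mode)) else 0
      if (score > best_score) { best_score <- score; best_att <- att }
    }
    if (is.null(best_att)) {
      failures <- c(failures, errs)
      next
    }
    d <- build_design(template, site, best_att, cond, options, cassette)
    results[[strand]] <- d
  }
  if (length(results) == 0L) {
    stop(structure(class = c("asq_design_failure", "error", "condition"),
                   list(message = paste0(
                     "assay design failed in both directions:\n  ",
                     paste(failures, collapse = "\n  ")),
                     call = NULL, causes = failures)))
  }
  mid <- mean(options$amplicon_range)
  score_design <- function(d) c(
    pass = as.numeric(d$compatibility$pass),
    pq = d$mean_pq,
    amp = -abs(stats::median(d$amplicon_lengths) - mid),
    plus = as.numeric(d$direction == "plus"))
  ord <- order(vapply(results, function(d) {
    s <- score_design(d)
    # lexicographic via weighted key: pass dominates, then PQ, then
    # amplicon centering, then plus strand
    s[["pass"]] * 1e9 + s[["pq"]] * 1e4 + s[["amp"]] * 10 + s[["plus"]]
  }, numeric(1)), decreasing = TRUE)
  results <- results[ord]
  best <- results[[1]]
  if (!best$compatibility$pass) {
    stop(structure(class = c("asq_design_failure", "error", "condition"),
                   list(message = paste0(
                     "assay design failed: interaction screens failed in ",
                     "every direction (worst dimer dG ",
                     sprintf("%.1f", min(best$compatibility$dimers$delta_g)),
                     " kcal/mol)"),
                     call = NULL,
                     causes = c(failures, "interaction screens failed"))))
  }
  attr(best, "alternatives") <- if (length(results) > 1L) results[-1]
  else failures
  best
}
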