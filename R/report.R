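# Tabular export, synthetic fixture generation, the static wet-lab
# protocol sheet, and run configuration handling.

#' Export assay designs as a primer table
#'
#' One row per primer with the standard export column set (name,
#' sequence, location on target, direction, length, Tm, GC, molecular
#' weight, molar extinction coefficient, linguistic complexity, primer
#' quality) plus role/allele/channel/amplicon columns, followed by one
#' `pair` row per allele giving the recommended annealing temperature,
#' product size and approximate product Tm.  Coordinates are 1-based
#' inclusive; numbers are fixed-format so identical designs export
#' byte-identically.
#'
#' @param designs An `assay_design` or list of them.
#' @param path Optional output file; when given, a TSV (or CSV) is
#'   written and the path returned invisibly.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return Data frame of the table (invisibly when `path` is given).
#' @export
export_table <- function(designs, path = NULL,
                         format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (inherits(designs, "assay_design")) designs <- list(designs)
  stopifnot(length(designs) >= 1L)
  rows <- list()
  add_primer <- function(d, p, amplicon) {
    m <- p$metrics
    iv <- p$template_interval
    shown <- if (is.null(p$tail_sequence)) p$full_sequence
    else paste0(tolower(p$tail_sequence), p$core_sequence)
    rows[[length(rows) + 1L]] <<- data.frame(
      row_type = "primer",
      name = p$name,
      sequence = shown,
      target = d$template_name,
      location = if (is.null(iv)) "" else
        sprintf("%d..%d", iv[1] + 1L, iv[2]),
      direction = if (p$strand == "plus") "forward" else "reverse",
      length = m$length,
      tm = fmt_num(m$tm, 1),
      gc = fmt_num(m$gc, 1),
      mw = fmt_num(m$mw, 2),
      extinction = fmt_num(m$extinction, 0),
      lc = fmt_num(round(m$lc), 0),
      pq = fmt_num(m$pq, 1),
      role = p$role,
      allele = if (is.na(p$allele_index)) "" else
        ifelse(p$allele == "", "-", p$allele),
      channel = if (is.null(p$channel)) "" else p$channel,
      amplicon_bp = if (is.na(amplicon)) "" else as.character(amplicon),
      annealing_c = "", product_bp = "", product_tm = "",
      stringsAsFactors = FALSE)
  }
  for (d in designs) {
    for (i in seq_along(d$asp_set))
      add_primer(d, d$asp_set[[i]], d$amplicon_lengths[i])
    add_primer(d, d$common_primer, NA)
    for (i in seq_along(d$asp_set)) {
      rows[[length(rows) + 1L]] <- data.frame(
        row_type = "pair",
        name = sprintf("%s+%s", d$asp_set[[i]]$name,
                       d$common_primer$name),
        sequence = "", target = d$template_name, location = "",
        direction = "", length = NA_integer_, tm = "", gc = "", mw = "",
        extinction = "", lc = "", pq = "", role = "pair",
        allele = ifelse(d$asp_set[[i]]$allele == "", "-",
                        d$asp_set[[i]]$allele),
        channel = d$asp_set[[i]]$channel,
        amplicon_bp = as.character(d$amplicon_lengths[i]),
        annealing_c = fmt_num(d$annealing_temp, 1),
        product_bp = as.character(d$amplicon_lengths[i]),
        product_tm = fmt_num(d$amplicon_tm, 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    sep <- if (format == "tsv") "\t" else ","
    lines <- c(paste(names(out), collapse = sep),
               vapply(seq_len(nrow(out)), function(i)
                 paste(vapply(out[i, ], function(v)
                   ifelse(is.na(v), "", as.character(v)), character(1)),
                   collapse = sep), character(1)))
    writeLines(enc2utf8(lines), path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

#' Generate synthetic polymorphic templates
#'
#' Deterministic (seeded) FASTA fixtures for testing and examples:
#' random flanks of configurable GC content around one bracket-notation
#' polymorphic site per template, with optional low-complexity or
#' G-quadruplex-bearing flanks for negative tests.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n Number of templates.
#' @param site_kinds Character vector (recycled over templates) from
#'   `"snp2"`, `"snp3"`, `"snp4"`, `"indel"`, `"mixed"`.
#' @param indel_len Length of the inserted allele for `"indel"` sites
#'   (recycled; 1-30).
#' @param flank_len Flank length on each side of the site, nt.
#' @param flank_gc Target flank GC fraction.
#' @param low_complexity Embed a low-complexity (dinucleotide repeat)
#'   stretch in the left flank.
#' @param g4 Embed a G-quadruplex motif in the left flank.
#' @return FASTA text as a single string.
#' @examples
#' cat(generate_fixture_templates(1, n = 1))
#' @export
generate_fixture_templates <- function(seed, n = 1L,
                                       site_kinds = "snp2",
                                       indel_len = 4L,
                                       flank_len = 160L,
                                       flank_gc = 0.5,
                                       low_complexity = FALSE,
                                       g4 = FALSE) {
  stopifnot(flank_len >= 40, flank_gc >= 0, flank_gc <= 1)
  kinds <- rep_len(site_kinds, n)
  ilens <- rep_len(indel_len, n)
  if (any(!kinds %in% c("snp2", "snp3", "snp4", "indel", "mixed")))
    stop("unknown site kind", call. = FALSE)
  if (any(ilens < 1L | ilens > 30L))
    stop("indel_len must be 1-30", call. = FALSE)
  with_private_seed(seed, {
    recs <- vapply(seq_len(n), function(i) {
      base_probs <- c(A = (1 - flank_gc) / 2, C = flank_gc / 2,
                      G = flank_gc / 2, T = (1 - flank_gc) / 2)
      rand_flank <- function(len)
        paste(sample(names(base_probs), len, replace = TRUE,
                     prob = base_probs), collapse = "")
      # fixtures emulate designable loci: resample until the site
      # neighbourhood (where ASP 3' ends are pinned) is free of
      # low-complexity/G4 masking; the toggles below deliberately break
      # this for negative tests
      clean_near_site <- function(left, right, alleles) {
        all(vapply(alleles, function(a) {
          probe <- paste0(substr(left, flank_len - 59L, flank_len), a,
                          substr(right, 1L, 60L))
          nrow(complexity_profile(probe)$masked_intervals) == 0L
        }, logical(1)))
      }
      site_alleles <- function(expr)
        vapply(strsplit(expr, "/", fixed = TRUE)[[1]],
               function(a) if (a == "-") "" else a, character(1),
               USE.NAMES = FALSE)
      site <- switch(kinds[i],
        snp2 = paste(sample(DNA_BASES, 2), collapse = "/"),
        snp3 = paste(sample(DNA_BASES, 3), collapse = "/"),
        snp4 = paste(sample(DNA_BASES, 4), collapse = "/"),
        indel = paste0("-/", paste(sample(DNA_BASES, ilens[i],
                                          replace = TRUE),
                                   collapse = "")),
        mixed = {
          b <- sample(DNA_BASES, 2)
          ins <- paste(sample(DNA_BASES, max(2L, ilens[i]),
                              replace = TRUE), collapse = "")
          paste(b[1], b[2], ins, sep = "/")
        })
      als <- site_alleles(site)
      left <- rand_flank(flank_len)
      right <- rand_flank(flank_len)
      tries <- 0L
      while (!clean_near_site(left, right, als) && tries < 100L) {
        left <- rand_flank(flank_len)
        right <- rand_flank(flank_len)
        tries <- tries + 1L
      }
      if (low_complexity) {
        lcs <- strrep("AT", 15)
        substr(left, 20, 19 + nchar(lcs)) <- lcs
      }
      if (g4) {
        motif <- "GGGTTAGGGTTAGGGTTAGGG"
        substr(left, 20, 19 + nchar(motif)) <- motif
      }
      sprintf(">fixture_%d_%s\n%s[%s]%s", i, kinds[i], left, site, right)
    }, character(1))
    paste0(paste(recs, collapse = "\n"), "\n")
  })
}

#' Emit the wet-lab protocol sheet for a design
#'
#' Static, informational text: the two-round thermal profile (10 cycles
#' 95/55/68 C, then 30 cycles 95 C 10 s / 68 C 30 s / 55 C 30 s with the
#' signal read at the 55 C step) and the reaction cocktail scaled
#' linearly to the requested volume (concentrations unchanged).
#'
#' @param design An `assay_design` (used for primer names only).
#' @param volume Total reaction volume in microliters (default 100).
#' @return Character vector of sheet lines.
#' @export
emit_protocol_sheet <- function(design, volume = 100) {
  stopifnot(inherits(design, "assay_design"), volume > 0)
  f <- volume / 100
  mix <- data.frame(
    component = c("5x buffer (with 9 mM MgCl2)", "MgCl2 (25 mM)",
                  "dNTP (10 mM)",
                  paste0("ASP ", vapply(design$asp_set, `[[`,
                                        character(1), "name"),
                         " (5 uM)"),
                  paste0("common ", design$common_primer$name,
                         " (5 uM)"),
                  paste0("UP (10 uM) x", length(design$asp_set)),
                  "quencher Uni-Q (50 uM)",
                  "Taq DNA polymerase (5 U/ul)",
                  "water", "DNA template (10 ng/ul)"),
    volume_ul = c(20, 4.8, 2, rep(2, length(design$asp_set)), 6,
                  2 * length(design$asp_set), 1, 0.8, NA, 20),
    stringsAsFactors = FALSE)
  fixed <- sum(mix$volume_ul, na.rm = TRUE)
  mix$volume_ul[is.na(mix$volume_ul)] <- 100 - fixed
  mix$volume_ul <- mix$volume_ul * f
  c(
    sprintf("ASQ genotyping protocol sheet - %s site %d",
            design$template_name, design$site_index),
    sprintf("Total reaction volume: %.1f ul", volume),
    "",
    "Reaction mix:",
    sprintf("  %-42s %6.2f ul", mix$component, mix$volume_ul),
    sprintf("  %-42s %6.2f ul", "TOTAL", sum(mix$volume_ul)),
    "",
    "Thermal profile (two rounds):",
    "  1. 95 C 120 s   initial denaturation",
    "  2. 95 C 10 s    round-1 denaturation",
    "  3. 55 C 20 s    round-1 annealing",
    "  4. 68 C 20 s    round-1 extension",
    "     repeat steps 2-4 for 10 cycles",
    "  5. 95 C 10 s    round-2 denaturation",
    "  6. 68 C 30 s    round-2 annealing and extension",
    "  7. 55 C 30 s    FRET cassette annealing and signal read",
    "     repeat steps 5-7 for 30 cycles",
    "",
    sprintf("Recommended round-1 annealing from design: %.1f C",
            design$annealing_temp))
}

#' Assemble a run configuration
#'
#' Merges user settings (and optionally a YAML config file) over the
#' pipeline defaults used by [run_cli()].
#'
#' @param ... Overrides: any of `input`, `format`, `snp_pos_mode`,
#'   `oligo_conc`, `monovalent`, `mg_total`, `dntp_total`,
#'   `amplicon_min`, `amplicon_max`, `tm_target`, `tm_window`,
#'   `cassette`, `seed`, `out`.
#' @param file Optional YAML file with the same keys.
#' @return Named list of configuration values.
#' @export
asq_config <- function(..., file = NULL) {
  cfg <- list(
    input = NULL, format = "auto", snp_pos_mode = "penultimate",
    oligo_conc = 200e-9, monovalent = 0.055, mg_total = 3e-3,
    dntp_total = 0.8e-3, amplicon_min = 100, amplicon_max = 200,
    tm_target = 63, tm_window = 1, cassette = "default", seed = 1L,
    out = NULL)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(from_file)] <- from_file
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$amplicon_max > cfg$amplicon_min, cfg$tm_window > 0)
  cfg
}

config_to_objects <- function(cfg) {
  list(
    cond = thermo_conditions(cfg$oligo_conc, cfg$monovalent,
                             cfg$mg_total, cfg$dntp_total),
    options = design_options(
      snp_pos_mode = cfg$snp_pos_mode,
      amplicon_range = c(cfg$amplicon_min, cfg$amplicon_max),
      tm_target = cfg$tm_target, tm_window = cfg$tm_window),
    cassette = if (identical(cfg$cassette, "default")) default_cassettes()
    else read_cassette_tsv(cfg$cassette)
  )
}
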