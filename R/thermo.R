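# Oligonucleotide physical properties: nearest-neighbor duplex
# thermodynamics (unified SantaLucia 1998 parameter set) with
# monovalent/divalent cation correction after Owczarzy et al., plus
# GC content, molecular weight and molar extinction coefficient.

.thermo_cache <- new.env(parent = emptyenv())

GAS_CONSTANT <- 1.98720425864083  # cal / (mol K)

nn_params <- function() {
  if (!is.null(.thermo_cache$nn)) return(.thermo_cache$nn)
  path <- system.file("extdata", "nn_santalucia1998.tsv",
                      package = "asqdesign", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  steps <- tab$step[nchar(tab$step) == 2L & !grepl("_", tab$step)]
  dh <- stats::setNames(tab$delta_h, tab$step)
  ds <- stats::setNames(tab$delta_s, tab$step)
  # Expand the ten unique stacks to all sixteen dinucleotide keys: a stack
  # not listed is thermodynamically identical to its reverse complement.
  all16 <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  dh16 <- ds16 <- stats::setNames(numeric(16L), all16)
  for (k in all16) {
    key <- if (k %in% steps) k else {
      rc <- paste0(complement_base(substr(k, 2, 2)),
                   complement_base(substr(k, 1, 1)))
      rc
    }
    dh16[k] <- dh[[key]]; ds16[k] <- ds[[key]]
  }
  .thermo_cache$nn <- list(
    dh = dh16, ds = ds16,
    init_gc = c(dh = dh[["init_GC"]], ds = ds[["init_GC"]]),
    init_at = c(dh = dh[["init_AT"]], ds = ds[["init_AT"]]),
    sym = c(dh = dh[["symmetry"]], ds = ds[["symmetry"]])
  )
  .thermo_cache$nn
}

#' Reaction conditions for duplex thermodynamics
#'
#' Bundles the strand and ionic concentrations under which melting
#' temperatures are computed.  The free divalent concentration available
#' for duplex stabilization is the total magnesium minus the dNTP pool
#' (dNTPs chelate Mg2+ essentially stoichiometrically), floored at zero.
#' Defaults correspond to a typical competitive allele-specific PCR read
#' condition: 200 nM oligonucleotide, 55 mM KCl, 3 mM total Mg2+ with
#' 0.8 mM dNTP, i.e. 2.2 mM free Mg2+.
#'
#' @param oligo_conc Oligonucleotide (per-strand) concentration, mol/L.
#' @param monovalent Monovalent cation concentration (K+ plus Na+), mol/L.
#' @param mg_total Total magnesium concentration, mol/L.
#' @param dntp_total Total dNTP concentration, mol/L.
#' @return A `thermo_conditions` object (list with the four inputs and the
#'   derived `free_divalent`).
#' @examples
#' thermo_conditions()                      # assay read defaults
#' thermo_conditions(oligo_conc = 500e-9)   # quencher-excess condition
#' @export
thermo_conditions <- function(oligo_conc = 200e-9, monovalent = 0.055,
                              mg_total = 3e-3, dntp_total = 0.8e-3) {
  vals <- c(oligo_conc, monovalent, mg_total, dntp_total)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all concentrations must be finite and >= 0", call. = FALSE)
  if (oligo_conc <= 0)
    stop("oligo_conc must be > 0", call. = FALSE)
  structure(list(
    oligo_conc = oligo_conc,
    monovalent = monovalent,
    mg_total = mg_total,
    dntp_total = dntp_total,
    free_divalent = max(0, mg_total - dntp_total)
  ), class = "thermo_conditions")
}

#' @export
print.thermo_conditions <- function(x, ...) {
  cat(sprintf(
    "thermo_conditions: %.0f nM oligo, %.0f mM monovalent, %.2f mM free Mg2+ (%.1f mM Mg - %.1f mM dNTP)\n",
    x$oligo_conc * 1e9, x$monovalent * 1e3, x$free_divalent * 1e3,
    x$mg_total * 1e3, x$dntp_total * 1e3))
  invisible(x)
}

# Raw nearest-neighbor sums (kcal/mol, cal/mol/K) incl. initiation and,
# for self-complementary sequences, the symmetry entropy term.
nn_sums <- function(seq) {
  p <- nn_params()
  b <- seq_chars(seq)
  n <- length(b)
  steps <- paste0(b[-n], b[-1])
  dh <- sum(p$dh[steps])
  ds <- sum(p$ds[steps])
  for (t in b[c(1L, n)]) {
    ini <- if (t %in% c("G", "C")) p$init_gc else p$init_at
    dh <- dh + ini[["dh"]]; ds <- ds + ini[["ds"]]
  }
  selfc <- identical(seq, reverse_complement(seq))
  if (selfc) { dh <- dh + p$sym[["dh"]]; ds <- ds + p$sym[["ds"]] }
  list(dh = dh, ds = ds, self_complementary = selfc,
       f_gc = mean(b %in% c("G", "C")), n = n)
}

# Owczarzy divalent/monovalent correction applied to a 1 M NaCl Tm (Kelvin).
# Regime chosen by R = sqrt([Mg2+])/[mon]: monovalent-dominated below 0.22,
# magnesium-dominated above 6, competitive in between (modified a, d, g).
salt_corrected_tm <- function(tm1m_K, f_gc, n_bp, monovalent, free_divalent) {
  if (monovalent <= 0 && free_divalent <= 0)
    return(tm1m_K)
  use_mg <- free_divalent > 0
  if (use_mg && monovalent > 0) {
    ratio <- sqrt(free_divalent) / monovalent
    if (ratio < 0.22) use_mg <- FALSE
  }
  if (!use_mg) {
    # Monovalent-only correction (Owczarzy 2004, reciprocal-Tm form).
    lnM <- log(monovalent)
    inv <- 1 / tm1m_K + (4.29 * f_gc - 3.95) * 1e-5 * lnM +
      9.40e-6 * lnM^2
    return(1 / inv)
  }
  a <- 3.92e-5; b <- -9.11e-6; cc <- 6.26e-5; d <- 1.42e-5
  e <- -4.82e-4; f <- 5.25e-4; g <- 8.31e-5
  if (monovalent > 0) {
    ratio <- sqrt(free_divalent) / monovalent
    if (ratio < 6) {  # competitive regime: ions fitted jointly
      lnM <- log(monovalent)
      a <- a * (0.843 - 0.352 * sqrt(monovalent) * lnM)
      d <- d * (1.279 - 4.03e-3 * lnM - 8.03e-3 * lnM^2)
      g <- g * (0.486 - 0.258 * lnM + 5.25e-3 * lnM^3)
    }
  }
  lnMg <- log(free_divalent)
  inv <- 1 / tm1m_K + a + b * lnMg + f_gc * (cc + d * lnMg) +
    (1 / (2 * (n_bp - 1))) * (e + f * lnMg + g * lnMg^2)
  1 / inv
}

#' Nearest-neighbor duplex profile of an oligonucleotide
#'
#' Computes the two-state hybridization profile of `seq` with its perfect
#' complement: enthalpy and entropy from the unified nearest-neighbor
#' parameter set with initiation terms, the standard free energy at 37 C,
#' and the salt-corrected melting temperature under `cond`.
#'
#' The concentration term uses `R * ln(C/2)` for non-self-complementary
#' duplexes formed from equimolar strands at per-strand concentration `C`
#' (total strand concentration `2C`, so `C_T/4 = C/2`), and `R * ln(C)`
#' for self-complementary sequences.
#'
#' @param seq DNA string (A/C/G/T), length >= 2 (>= 8 for a meaningful Tm).
#' @param cond A [thermo_conditions()] object.
#' @return A `duplex_profile` list: `tm_celsius`, `delta_g37` (kcal/mol),
#'   `delta_h` (kcal/mol), `delta_s` (cal/mol/K).
#' @examples
#' duplex_profile("ACCGTTCAGCTGG")
#' @export
duplex_profile <- function(seq, cond = thermo_conditions()) {
  seq <- toupper(seq)
  assert_dna(seq)
  if (nchar(seq) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  stopifnot(inherits(cond, "thermo_conditions"))
  s <- nn_sums(seq)
  conc <- if (s$self_complementary) cond$oligo_conc else cond$oligo_conc / 2
  tm1m <- s$dh * 1000 / (s$ds + GAS_CONSTANT * log(conc))
  tmK <- salt_corrected_tm(tm1m, s$f_gc, s$n, cond$monovalent,
                           cond$free_divalent)
  structure(list(
    tm_celsius = tmK - 273.15,
    delta_g37 = s$dh - (273.15 + 37) * s$ds / 1000,
    delta_h = s$dh,
    delta_s = s$ds
  ), class = "duplex_profile")
}

#' Melting temperature of a primer/probe duplex
#'
#' Two-state nearest-neighbor melting temperature of `seq` against its
#' perfect complement, corrected for monovalent and free divalent cations.
#'
#' @inheritParams duplex_profile
#' @return Tm in degrees Celsius.
#' @examples
#' melting_temperature("ACCGTTCAGCTGG")  # universal quencher oligo
#' @export
melting_temperature <- function(seq, cond = thermo_conditions()) {
  seq <- toupper(seq)
  assert_dna(seq)
  if (nchar(seq) < 8L)
    stop("two-state nearest-neighbor Tm requires length >= 8", call. = FALSE)
  duplex_profile(seq, cond)$tm_celsius
}

#' Duplex standard free energy
#'
#' Nearest-neighbor Gibbs free energy of the perfect duplex of `seq`,
#' including initiation (and symmetry) terms, at the given temperature.
#'
#' @param seq DNA string, length >= 2.
#' @param temperature Temperature in Celsius (default 37).
#' @return Free energy in kcal/mol (negative for stable duplexes).
#' @examples
#' duplex_delta_g("ACCGTTCAGCTGG")
#' @export
duplex_delta_g <- function(seq, temperature = 37) {
  seq <- toupper(seq)
  assert_dna(seq)
  if (nchar(seq) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  s <- nn_sums(seq)
  s$dh - (273.15 + temperature) * s$ds / 1000
}

#' GC content
#'
#' @param seq Non-empty DNA string.
#' @return Percent G+C (0-100).
#' @examples
#' gc_content("ACCGTTCAGCTGG")
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  assert_dna(seq)
  if (nchar(seq) == 0L) stop("sequence must be non-empty", call. = FALSE)
  b <- seq_chars(seq)
  100 * sum(b %in% c("G", "C")) / length(b)
}

# Monomer contributions (g/mol) for linear 5'-OH DNA:
# MW = sum(residue) - 61.96 (one fewer phosphate bridge than residues).
MW_RESIDUE <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
MW_END_ADJUST <- 61.96

#' Molecular weight of a DNA oligonucleotide
#'
#' Linear, unmodified 5'-OH / 3'-OH convention.
#'
#' @param seq Non-empty DNA string.
#' @return Molecular weight in g/mol.
#' @examples
#' molecular_weight("ACCGTTCAGCTGG")
#' @export
molecular_weight <- function(seq) {
  seq <- toupper(seq)
  assert_dna(seq)
  if (nchar(seq) == 0L) stop("sequence must be non-empty", call. = FALSE)
  sum(MW_RESIDUE[seq_chars(seq)]) - MW_END_ADJUST
}

# 260 nm molar extinction, nearest-neighbor method (L/(mol cm)).
EXT_MONO <- c(A = 15400, C = 7400, G = 11500, T = 8700)
EXT_NN <- c(
  AA = 27400, AC = 21200, AG = 25000, AT = 22800,
  CA = 21200, CC = 14600, CG = 18000, CT = 15200,
  GA = 25200, GC = 17600, GG = 21600, GT = 20000,
  TA = 23400, TC = 16200, TG = 19000, TT = 16800
)

#' Molar extinction coefficient at 260 nm
#'
#' Nearest-neighbor method: sum of dinucleotide extinctions minus the
#' internal monomer extinctions.
#'
#' @param seq DNA string, length >= 2.
#' @return Extinction coefficient in L mol-1 cm-1.
#' @examples
#' extinction_coefficient("ACCGTTCAGCTGG")
#' @export
extinction_coefficient <- function(seq) {
  seq <- toupper(seq)
  assert_dna(seq)
  b <- seq_chars(seq)
  if (length(b) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  steps <- paste0(b[-length(b)], b[-1])
  sum(EXT_NN[steps]) - sum(EXT_MONO[b[-c(1L, length(b))]])
}

#' Stability of a primer 3'-terminal segment
#'
#' Duplex free energy of the 3'-terminal `k`-mer; used to rank
#' allele-specific primer ends (a very stable GC-rich 3' end promotes
#' extension from mismatched templates, a very weak one extends poorly).
#'
#' @param seq DNA string.
#' @param k Number of 3'-terminal bases (default 5).
#' @return Free energy in kcal/mol of the terminal `k`-mer duplex.
#' @examples
#' terminal_stability("AAAAAGGGGG")
#' @export
terminal_stability <- function(seq, k = 5) {
  seq <- toupper(seq)
  assert_dna(seq)
  n <- nchar(seq)
  if (k > n) stop("k exceeds sequence length", call. = FALSE)
  duplex_delta_g(substr(seq, n - k + 1L, n))
}

#' Approximate melting temperature of a PCR product
#'
#' Long-duplex approximation from GC fraction, length and effective
#' monovalent ionic strength (`monovalent + 120*sqrt(free Mg2+ in mM)` mM);
#' reported with amplicon descriptions only, never used for primer design.
#'
#' @param seq Amplicon sequence (DNA string).
#' @param cond A [thermo_conditions()] object.
#' @return Approximate product Tm in Celsius.
#' @export
product_tm <- function(seq, cond = thermo_conditions()) {
  seq <- toupper(seq)
  assert_dna(seq)
  n <- nchar(seq)
  if (n < 2L) stop("sequence must have length >= 2", call. = FALSE)
  eff_mono <- cond$monovalent + 0.120 * sqrt(cond$free_divalent * 1000)
  81.5 + 16.6 * log10(eff_mono) + 0.41 * gc_content(seq) - 675 / n
}
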