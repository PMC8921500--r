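# Template input: FASTA / tabular / multiple-alignment parsing, the
# bracket polymorphism grammar "[variant1/variant2(/variant3/variant4)]",
# IUPAC degenerate bases, and the internal template/site data model.
#
# A PolymorphicTemplate stores the invariant backbone (site contents
# excised) plus an ordered list of VariantSites; `position` is the 0-based
# offset on the backbone where the site's alleles are inserted.

#' Construct a variant site
#'
#' @param position 0-based offset of the site's left edge on the template
#'   backbone (half-open convention).
#' @param alleles Character vector of 2-4 pairwise distinct allele strings
#'   over A/C/G/T; one allele may be the empty string (a null/deletion
#'   allele).
#' @return A `variant_site` object with derived `site_kind`:
#'   `"SNP"` (all alleles single bases), `"InDel"` (allele lengths all
#'   differ), or `"mixed"` (same-length substitutution alleles coexist
#'   with length variants).
#' @examples
#' variant_site(4, c("C", "G"))
#' variant_site(10, c("", "CT"))
#' @export
variant_site <- function(position, alleles) {
  if (!is.numeric(position) || length(position) != 1L || position < 0)
    stop("position must be a single non-negative number", call. = FALSE)
  alleles <- toupper(as.character(alleles))
  n <- length(alleles)
  if (n < 2L || n > 4L)
    stop("a variant site needs 2-4 alleles, got ", n, call. = FALSE)
  if (anyDuplicated(alleles))
    stop("alleles must be pairwise distinct", call. = FALSE)
  if (sum(alleles == "") > 1L)
    stop("at most one null (empty) allele is allowed", call. = FALSE)
  bad <- grepl("[^ACGT]", alleles)
  if (any(bad))
    stop("illegal characters in allele(s): ",
         paste(alleles[bad], collapse = ", "), call. = FALSE)
  lens <- nchar(alleles)
  kind <- if (all(lens == 1L)) "SNP"
  else if (!anyDuplicated(lens)) "InDel"
  else "mixed"
  structure(list(position = as.integer(position), alleles = alleles,
                 site_kind = kind), class = "variant_site")
}

#' Parse a bracket polymorphism expression
#'
#' Grammar: `[v1/v2]` up to `[v1/v2/v3/v4]`, each variant a run of
#' A/C/G/T, or `-`/empty for a null allele (sequence absent in that
#' allele).  Only the differing bases appear inside the brackets.
#'
#' @param bracket_expr The expression including the square brackets.
#' @param position Optional 0-based position to place the site at.
#' @return A [variant_site()] object.
#' @examples
#' parse_variant_site("[A/T]")
#' parse_variant_site("[-/CT]")
#' @export
parse_variant_site <- function(bracket_expr, position = 0L) {
  x <- gsub("\\s", "", bracket_expr)
  if (!grepl("^\\[.*\\]$", x))
    stop("not a bracket expression: ", bracket_expr, call. = FALSE)
  inner <- substr(x, 2L, nchar(x) - 1L)
  parts <- strsplit(inner, "/", fixed = TRUE)[[1]]
  if (endsWith(inner, "/")) parts <- c(parts, "")
  parts <- toupper(parts)
  parts[parts == "-"] <- ""
  if (length(parts) > 4L)
    stop("more than 4 variants in ", bracket_expr, call. = FALSE)
  variant_site(position, parts)
}

#' Expand an IUPAC degenerate base
#'
#' @param base A single symbol from the 15-letter IUPAC DNA alphabet.
#' @return Character vector of the bases the symbol denotes
#'   (singletons for A/C/G/T).
#' @examples
#' expand_degenerate("S")  # C, G
#' expand_degenerate("N")
#' @export
expand_degenerate <- function(base) {
  b <- toupper(base)
  if (!is.character(b) || length(b) != 1L || !nzchar(b) ||
      is.na(match(b, names(IUPAC_MAP))))
    stop("not an IUPAC DNA symbol: ", base, call. = FALSE)
  IUPAC_MAP[[b]]
}

#' Construct a polymorphic template
#'
#' @param name Record identifier.
#' @param sequence Backbone sequence (A/C/G/T) with site contents excised.
#' @param sites List of [variant_site()] objects with strictly increasing
#'   positions on the backbone.
#' @param topology `"linear"` (default) or `"circular"`.
#' @return A `polymorphic_template` object.
#' @export
polymorphic_template <- function(name, sequence, sites = list(),
                                 topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  assert_dna(sequence, paste0("template '", name, "'"))
  if (length(sites) > 0L) {
    stopifnot(all(vapply(sites, inherits, logical(1), "variant_site")))
    pos <- vapply(sites, `[[`, integer(1), "position")
    if (is.unsorted(pos, strictly = TRUE))
      stop("site positions must be strictly increasing", call. = FALSE)
    if (any(pos > nchar(sequence)))
      stop("site position beyond template end", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence, sites = sites,
                 topology = topology), class = "polymorphic_template")
}

#' @export
print.polymorphic_template <- function(x, ...) {
  cat(sprintf("polymorphic_template '%s': %d nt backbone, %d site(s), %s\n",
              x$name, nchar(x$sequence), length(x$sites), x$topology))
  for (s in x$sites)
    cat(sprintf("  site @%d (1-based %d): [%s] %s\n", s$position,
                s$position + 1L,
                paste(ifelse(s$alleles == "", "-", s$alleles),
                      collapse = "/"), s$site_kind))
  invisible(x)
}

#' Serialize a template back to bracket notation
#'
#' Inverse of parsing: re-inserts each site as a bracket expression, so
#' that `parse_templates(format_template(x))` reproduces `x`.
#'
#' @param template A [polymorphic_template()] object.
#' @return Single sequence string in bracket notation (no FASTA header).
#' @export
format_template <- function(template) {
  stopifnot(inherits(template, "polymorphic_template"))
  seq <- template$sequence
  out <- character(0)
  last <- 0L
  for (s in template$sites) {
    out <- c(out, substr(seq, last + 1L, s$position),
             paste0("[", paste(ifelse(s$alleles == "", "-", s$alleles),
                               collapse = "/"), "]"))
    last <- s$position
  }
  paste0(paste(out, collapse = ""), substr(seq, last + 1L, nchar(seq)))
}

# Parse one raw record body (sequence text possibly containing bracket
# expressions and IUPAC codes) into a polymorphic_template.
parse_record <- function(name, body, topology = "linear") {
  body <- toupper(body)
  # strip whitespace, digits and any symbol that is neither IUPAC DNA nor
  # part of the bracket grammar (non-DNA symbols are removed, per the
  # pre-processing contract)
  body <- gsub("[^ACGTRYSWKMBDHVN\\[\\]/-]", "", body, perl = TRUE)
  backbone <- character(0)
  sites <- list()
  pos <- 0L
  i <- 1L
  n <- nchar(body)
  while (i <= n) {
    ch <- substr(body, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(body, i, n), fixed = TRUE)
      if (j == -1L)
        stop("unclosed bracket in record '", name, "' at offset ", pos,
             call. = FALSE)
      expr <- substr(body, i, i + j - 1L)
      site <- tryCatch(parse_variant_site(expr, pos), error = function(e)
        stop("record '", name, "', offset ", pos, ": ",
             conditionMessage(e), call. = FALSE))
      sites <- c(sites, list(site))
      i <- i + j
    } else if (ch %in% c("]", "/")) {
      stop("record '", name, "': stray '", ch, "' outside brackets",
           call. = FALSE)
    } else if (ch == "-") {
      i <- i + 1L  # alignment gap outside brackets: drop
    } else if (ch %in% DNA_BASES) {
      backbone <- c(backbone, ch)
      pos <- pos + 1L
      i <- i + 1L
    } else {
      # degenerate IUPAC base == in-place variant site
      sites <- c(sites, list(variant_site(pos, expand_degenerate(ch))))
      i <- i + 1L
    }
  }
  polymorphic_template(name, paste(backbone, collapse = ""), sites,
                       topology)
}

split_fasta <- function(lines) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA headers found", call. = FALSE)
  ends <- c(hdr[-1L] - 1L, length(lines))
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_)
  bodies <- mapply(function(s, e)
    paste(lines[seq(s + 1L, e)[seq(s + 1L, e) > s]], collapse = ""),
    hdr, ends)
  bodies[hdr == ends] <- ""
  stats::setNames(as.character(bodies), names_)
}

#' Parse templates from text input
#'
#' Accepts multi-record FASTA, tabular (`name<TAB>sequence`) or an aligned
#' FASTA of allele sequences.  Polymorphic sites may be written in bracket
#' notation or as IUPAC degenerate bases; non-DNA symbols outside bracket
#' expressions are removed.  With `format = "auto"`, a leading `>` selects
#' FASTA (an aligned FASTA - multiple gapped, equal-length records - is
#' treated as one alignment), and a TAB in the first line selects tabular.
#'
#' @param text Input as a single string or character vector of lines.
#' @param format One of `"auto"`, `"fasta"`, `"tabular"`, `"alignment"`.
#' @param topology `"linear"` or `"circular"`, applied to all records.
#' @return List of [polymorphic_template()] objects.
#' @examples
#' parse_templates(">t1\nAACC[C/G]GGTT")
#' parse_templates("t2\tAACCSGGTT", format = "tabular")
#' @export
parse_templates <- function(text,
                            format = c("auto", "fasta", "tabular",
                                       "alignment"),
                            topology = c("linear", "circular")) {
  format <- match.arg(format)
  topology <- match.arg(topology)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n",
                           fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("^\\s*>", lines[1])) "fasta"
    else if (grepl("\t", lines[1])) "tabular"
    else "fasta_bodyless"
    if (format == "fasta") {
      recs <- split_fasta(lines)
      if (length(recs) >= 2L && any(grepl("-", recs, fixed = TRUE)) &&
          length(unique(nchar(gsub("\\s", "", recs)))) == 1L)
        format <- "alignment"
    }
  }
  if (format == "fasta_bodyless") {
    # bare sequence text without headers: one anonymous record
    return(list(parse_record("seq1", paste(lines, collapse = ""),
                             topology)))
  }
  if (format == "fasta") {
    recs <- split_fasta(lines)
    return(unname(mapply(parse_record, names(recs), recs,
                         MoreArgs = list(topology = topology),
                         SIMPLIFY = FALSE)))
  }
  if (format == "tabular") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) < 2L
    if (any(bad))
      stop("tabular line without TAB-separated name and sequence: ",
           lines[bad][1], call. = FALSE)
    return(lapply(parts, function(p)
      parse_record(p[1], paste(p[-1], collapse = ""), topology)))
  }
  # alignment
  recs <- if (grepl("^\\s*>", lines[1])) split_fasta(lines)
  else stop("alignment input must be aligned FASTA", call. = FALSE)
  list(templates_from_alignment(recs, topology = topology))
}

#' Build one template from a multiple sequence alignment of alleles
#'
#' Columns where the aligned records differ (adjacent variant columns
#' merged into maximal blocks, so gap runs survive as InDel alleles)
#' become variant sites; identical columns form the backbone.
#'
#' @param records Named character vector of >= 2 gapped, equal-length
#'   aligned sequences (gap symbol `-`).
#' @param name Template name (default: name of the first record).
#' @param topology `"linear"` or `"circular"`.
#' @return A single [polymorphic_template()].
#' @examples
#' templates_from_alignment(c(a = "ACG-A", b = "ACGTA"))
#' @export
templates_from_alignment <- function(records, name = NULL,
                                     topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  records <- toupper(gsub("\\s", "", records))
  if (length(records) < 2L)
    stop("alignment needs >= 2 records", call. = FALSE)
  if (length(unique(nchar(records))) != 1L)
    stop("aligned records must have equal length", call. = FALSE)
  if (is.null(name))
    name <- if (!is.null(names(records))) names(records)[1] else "alignment"
  mat <- do.call(rbind, strsplit(records, "", fixed = TRUE))
  if (any(!mat %in% c(DNA_BASES, "-")))
    stop("alignment may contain only A/C/G/T and '-'", call. = FALSE)
  ncol_ <- ncol(mat)
  variant_col <- vapply(seq_len(ncol_), function(j)
    length(unique(mat[, j])) > 1L, logical(1))
  backbone <- character(0)
  sites <- list()
  pos <- 0L
  j <- 1L
  while (j <= ncol_) {
    if (!variant_col[j]) {
      b <- mat[1, j]
      if (b != "-") { backbone <- c(backbone, b); pos <- pos + 1L }
      j <- j + 1L
    } else {
      k <- j
      while (k < ncol_ && variant_col[k + 1L]) k <- k + 1L
      block <- mat[, j:k, drop = FALSE]
      alleles <- unique(apply(block, 1, function(r)
        paste(r[r != "-"], collapse = "")))
      if (length(alleles) > 4L)
        stop("alignment block at column ", j, " has ", length(alleles),
             " distinct variants (max 4)", call. = FALSE)
      sites <- c(sites, list(variant_site(pos, alleles)))
      j <- k + 1L
    }
  }
  polymorphic_template(name, paste(backbone, collapse = ""), sites,
                       topology)
}

#' Substitute one allele into a template
#'
#' Produces the concrete sequence for a chosen allele at a chosen site
#' (all other sites are left at their first allele), with the coordinates
#' of the substituted site on that sequence.
#'
#' @param template A [polymorphic_template()].
#' @param site Site index (1-based within `template$sites`).
#' @param allele Allele index within the site (1-based).
#' @return List: `sequence`, `site_start`/`site_end` (0-based half-open
#'   interval of the inserted allele on `sequence`).
#' @export
substitute_allele <- function(template, site = 1L, allele = 1L) {
  stopifnot(inherits(template, "polymorphic_template"))
  if (site < 1L || site > length(template$sites))
    stop("no such site: ", site, call. = FALSE)
  pieces <- character(0)
  last <- 0L
  shift <- 0L
  site_start <- NA_integer_
  site_end <- NA_integer_
  for (i in seq_along(template$sites)) {
    s <- template$sites[[i]]
    a <- if (i == site) s$alleles[allele] else s$alleles[1]
    if (i == site && (allele < 1L || allele > length(s$alleles)))
      stop("no such allele: ", allele, call. = FALSE)
    pieces <- c(pieces, substr(template$sequence, last + 1L, s$position), a)
    if (i == site) {
      site_start <- s$position + shift
      site_end <- site_start + nchar(a)
    }
    shift <- shift + nchar(a)
    last <- s$position
  }
  pieces <- c(pieces, substr(template$sequence, last + 1L,
                             nchar(template$sequence)))
  list(sequence = paste(pieces, collapse = ""), site_start = site_start,
       site_end = site_end)
}
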