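#' Read a proteome from a FASTA file
#'
#' Reads protein sequences with [Biostrings::readAAStringSet()]. The header
#' token before the first whitespace becomes the accession; the remainder of
#' the header is kept as the description. Sequences are uppercased and
#' validated against the amino-acid alphabet (20 standard letters plus the
#' ambiguity letters X, B, Z, U).
#'
#' @param path Path to a FASTA file.
#' @return A data frame of class `proteome` with columns `accession`,
#'   `sequence`, `description`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">P1 demo protein", "MKVLDED"), fa)
#' read_proteome(fa)
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aas <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("proteome error: illegal residue letters in ", path,
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (length(aas) == 0L)
    stop("proteome error: no FASTA records in ", path, call. = FALSE)
  headers <- names(aas)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0L)
    stop("proteome error: duplicate accession(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  sequence <- toupper(as.character(aas))
  for (i in seq_along(sequence)) {
    res <- try(validate_sequence(sequence[i]), silent = TRUE)
    if (inherits(res, "try-error"))
      stop("proteome error in record '", accession[i], "': ",
           attr(res, "condition")$message, call. = FALSE)
  }
  structure(
    data.frame(accession = accession, sequence = unname(sequence),
               description = unname(description), stringsAsFactors = FALSE),
    class = c("proteome", "data.frame"))
}

#' Construct an annotated protein
#'
#' Bundles a protein sequence with the structural annotations the screens
#' consume: transit-peptide end, transmembrane (TM) spans, terminus
#' orientations, named domain spans and coiled-coil spans. Annotations are
#' inputs to this pipeline, not predictions it makes.
#'
#' Orientation vocabulary is `"in"` (facing the stroma) and `"out"` (lumen /
#' intermembrane side); the transit peptide, when present, always starts at
#' residue 1 and ends at `transit_end` (cleavage after that residue).
#'
#' @param accession Identifier string.
#' @param sequence Amino-acid string.
#' @param transit_end Last residue of the transit peptide, or `NA` for none.
#' @param tm_spans Two-column matrix or data frame of TM `start`,`end` spans
#'   (may be `NULL` for a soluble protein).
#' @param n_orientation,c_orientation `"in"`, `"out"`, or `NA`; both must be
#'   set when the protein has at least one TM span.
#' @param domains Data frame with columns `name`, `start`, `end` (optional).
#' @param coiled_coils Two-column matrix/data frame of coiled-coil spans
#'   (optional).
#' @param description Free-text description.
#' @param orientation_ambiguous Logical; `TRUE` marks proteins whose printed
#'   topology lists alternative orientations, which the screens can then
#'   evaluate under each alternative.
#'
#' @return An object of class `annotated_protein`.
#' @export
annotated_protein <- function(accession, sequence, transit_end = NA,
                              tm_spans = NULL, n_orientation = NA,
                              c_orientation = NA, domains = NULL,
                              coiled_coils = NULL, description = "",
                              orientation_ambiguous = FALSE) {
  chars <- validate_sequence(sequence)
  len <- length(chars)
  transit_end <- if (is.na(transit_end)) NA_integer_ else as.integer(transit_end)
  if (!is.na(transit_end) && (transit_end < 1L || transit_end > len))
    stop("annotation error: transit_end outside sequence", call. = FALSE)
  tm <- normalize_spans(tm_spans, len, "tm_spans")
  if (nrow(tm) > 0L) {
    if (any(tm$start[-1] <= tm$end[-nrow(tm)]))
      stop("annotation error: overlapping or unsorted TM spans", call. = FALSE)
    if (is.na(n_orientation) || is.na(c_orientation))
      stop("annotation error: a protein with TM spans needs both terminus orientations",
           call. = FALSE)
  }
  for (o in c(n_orientation, c_orientation)) {
    if (!is.na(o) && !o %in% c("in", "out"))
      stop("annotation error: orientation must be 'in' or 'out', got '", o, "'",
           call. = FALSE)
  }
  dom <- if (is.null(domains)) {
    data.frame(name = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  } else {
    d <- as.data.frame(domains, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "start", "end") %in% names(d)))
    d$start <- as.integer(d$start); d$end <- as.integer(d$end)
    if (nrow(d) > 0L && any(d$start < 1L | d$end > len | d$start > d$end))
      stop("annotation error: domain span outside sequence", call. = FALSE)
    d[, c("name", "start", "end")]
  }
  cc <- normalize_spans(coiled_coils, len, "coiled_coils")
  structure(
    list(accession = accession, sequence = toupper(sequence),
         length = len, transit_end = transit_end, tm_spans = tm,
         n_orientation = as.character(n_orientation),
         c_orientation = as.character(c_orientation),
         domains = dom, coiled_coils = cc,
         is_soluble = nrow(tm) == 0L,
         orientation_ambiguous = isTRUE(orientation_ambiguous),
         description = description),
    class = "annotated_protein")
}

normalize_spans <- function(spans, len, what) {
  if (is.null(spans) || (is.data.frame(spans) && nrow(spans) == 0L) ||
      (is.matrix(spans) && nrow(spans) == 0L))
    return(data.frame(start = integer(0), end = integer(0)))
  sp <- as.data.frame(spans, stringsAsFactors = FALSE)
  if (ncol(sp) < 2L) stop("annotation error: ", what, " needs start and end columns",
                          call. = FALSE)
  names(sp)[1:2] <- c("start", "end")
  sp$start <- as.integer(sp$start); sp$end <- as.integer(sp$end)
  if (any(is.na(sp$start) | is.na(sp$end)))
    stop("annotation error: non-numeric ", what, call. = FALSE)
  if (any(sp$start > sp$end))
    stop("annotation error: ", what, " span with start > end", call. = FALSE)
  if (any(sp$start < 1L | sp$end > len))
    stop("annotation error: ", what, " span outside sequence", call. = FALSE)
  sp <- sp[order(sp$start), c("start", "end"), drop = FALSE]
  rownames(sp) <- NULL
  sp
}

#' @export
print.annotated_protein <- function(x, ...) {
  cat(sprintf("<annotated_protein> %s (%d aa%s)\n", x$accession, x$length,
              if (x$is_soluble) ", soluble" else ""))
  if (!is.na(x$transit_end))
    cat(sprintf("  transit peptide: 1-%d\n", x$transit_end))
  if (nrow(x$tm_spans) > 0L)
    cat(sprintf("  TM spans: %s  orientation N(%s)-C(%s)\n",
                paste(sprintf("%d-%d", x$tm_spans$start, x$tm_spans$end),
                      collapse = ";"),
                x$n_orientation, x$c_orientation))
  if (nrow(x$domains) > 0L)
    cat(sprintf("  domains: %s\n",
                paste(sprintf("%s:%d-%d", x$domains$name, x$domains$start,
                              x$domains$end), collapse = ";")))
  invisible(x)
}

#' Read per-protein annotations from a TSV file
#'
#' The annotation table is tab-delimited with a header row and `"."` for
#' missing values. Expected columns: `accession`, `transit_end`, `tm_spans`
#' (semicolon-separated `start-end` spans), `n_orientation`, `c_orientation`
#' (`in`/`out`), `domains` (semicolon-separated `NAME:start-end`),
#' `coiled_coils` (semicolon-separated `start-end`). Every malformed row is
#' reported with its line number; nothing is loaded silently.
#'
#' @param path Path to the TSV file.
#' @param proteome A `proteome` data frame from [read_proteome()] (or any data
#'   frame with `accession` and `sequence` columns).
#' @return A named list of [annotated_protein()] objects, one per proteome
#'   accession (proteins without an annotation row get default, soluble,
#'   annotation-free entries).
#' @export
read_annotations <- function(path, proteome) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
  required <- c("accession", "transit_end", "tm_spans", "n_orientation",
                "c_orientation", "domains", "coiled_coils")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L)
    stop("annotation error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  seqs <- setNames(proteome$sequence, proteome$accession)
  desc <- if ("description" %in% names(proteome))
    setNames(proteome$description, proteome$accession)
  else setNames(rep("", nrow(proteome)), proteome$accession)
  out <- list()
  errors <- character(0)
  for (i in seq_len(nrow(tab))) {
    line_no <- i + 1L  # header is line 1
    row <- tab[i, ]
    res <- try({
      acc <- row$accession
      if (!acc %in% names(seqs))
        stop("unknown accession '", acc, "'", call. = FALSE)
      if (acc %in% names(out))
        stop("duplicate annotation row for '", acc, "'", call. = FALSE)
      ambiguous <- grepl("/", row$n_orientation, fixed = TRUE) ||
        grepl("/", row$c_orientation, fixed = TRUE)
      annotated_protein(
        accession = acc, sequence = seqs[[acc]],
        transit_end = parse_missing_int(row$transit_end),
        tm_spans = parse_span_list(row$tm_spans),
        n_orientation = parse_orientation(row$n_orientation),
        c_orientation = parse_orientation(row$c_orientation),
        domains = parse_domain_list(row$domains),
        coiled_coils = parse_span_list(row$coiled_coils),
        description = desc[[acc]],
        orientation_ambiguous = ambiguous)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      errors <- c(errors, sprintf("line %d: %s", line_no,
                                  trimws(attr(res, "condition")$message)))
    } else {
      out[[res$accession]] <- res
    }
  }
  if (length(errors) > 0L)
    stop("annotation error(s) in ", path, ":\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  for (acc in setdiff(names(seqs), names(out)))
    out[[acc]] <- annotated_protein(acc, seqs[[acc]], description = desc[[acc]])
  out[proteome$accession]
}

parse_missing_int <- function(x) {
  x <- trimws(x)
  if (x == "." || x == "") return(NA_integer_)
  v <- suppressWarnings(as.integer(x))
  if (is.na(v)) stop("not an integer: '", x, "'", call. = FALSE)
  v
}

parse_orientation <- function(x) {
  x <- tolower(trimws(x))
  if (x == "." || x == "") return(NA_character_)
  # ambiguous printed topologies like "out/in" default to the first listed
  # alternative; the row is flagged orientation-ambiguous by the caller
  x <- strsplit(x, "/", fixed = TRUE)[[1]][1]
  if (!x %in% c("in", "out"))
    stop("orientation must be 'in' or 'out', got '", x, "'", call. = FALSE)
  x
}

parse_span_list <- function(x) {
  x <- trimws(x)
  if (x == "." || x == "") return(NULL)
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^\\s*([0-9]+)-([0-9]+)\\s*$", parts))
  if (any(lengths(m) == 0L))
    stop("malformed span list '", x, "'", call. = FALSE)
  data.frame(start = as.integer(vapply(m, `[`, character(1), 2)),
             end = as.integer(vapply(m, `[`, character(1), 3)))
}

parse_domain_list <- function(x) {
  x <- trimws(x)
  if (x == "." || x == "") return(NULL)
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^\\s*([^:]+):([0-9]+)-([0-9]+)\\s*$", parts))
  if (any(lengths(m) == 0L))
    stop("malformed domain list '", x, "'", call. = FALSE)
  data.frame(name = vapply(m, `[`, character(1), 2),
             start = as.integer(vapply(m, `[`, character(1), 3)),
             end = as.integer(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Write per-protein annotations to a TSV file
#'
#' Inverse of [read_annotations()]: writing a set of annotated proteins and
#' re-reading the file against the same proteome reproduces the same model.
#'
#' @param annotations Named list of [annotated_protein()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  fmt_spans <- function(sp) {
    if (nrow(sp) == 0L) "." else
      paste(sprintf("%d-%d", sp$start, sp$end), collapse = ";")
  }
  rows <- lapply(annotations, function(p) {
    data.frame(
      accession = p$accession,
      transit_end = if (is.na(p$transit_end)) "." else as.character(p$transit_end),
      tm_spans = fmt_spans(p$tm_spans),
      n_orientation = if (is.na(p$n_orientation)) "." else p$n_orientation,
      c_orientation = if (is.na(p$c_orientation)) "." else p$c_orientation,
      domains = if (nrow(p$domains) == 0L) "." else
        paste(sprintf("%s:%d-%d", p$domains$name, p$domains$start,
                      p$domains$end), collapse = ";"),
      coiled_coils = fmt_spans(p$coiled_coils),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a proteome to a FASTA file
#'
#' @param proteome A `proteome` data frame (columns `accession`, `sequence`,
#'   optionally `description`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  desc <- if ("description" %in% names(proteome)) proteome$description else ""
  header <- ifelse(nzchar(desc),
                   paste(proteome$accession, desc),
                   proteome$accession)
  lines <- character(0)
  for (i in seq_len(nrow(proteome))) {
    body <- gsub("(.{60})", "\\1\n", proteome$sequence[i])
    body <- sub("\n$", "", body)
    lines <- c(lines, paste0(">", header[i]), body)
  }
  writeLines(lines, path)
  invisible(path)
}
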