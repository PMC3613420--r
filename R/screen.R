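#' Screening parameters
#'
#' Collects the tunable knobs of the cargo / receptor screens with their
#' defaults. All distances are in residues.
#'
#' @param nterm_window Proximity window between a basic-motif match and the
#'   first TM span start (default 25).
#' @param c_tail_max_dist Maximum distance of a C-tail motif end from the
#'   C-terminus (default `Inf`: anywhere in the C-tail).
#' @param monobasic Enable the monobasic fallback (a single K/R in the N-tail
#'   window) for the basic-motif class. Off by default because no rule states
#'   when a monobasic signal suffices; enabled matches are flagged.
#' @param strict_topology Passed to [build_region_map()]; when `FALSE`,
#'   orientation alternation mismatches trust the annotated C-tail side.
#' @param terminal_fraction Fraction of the mature sequence (after any transit
#'   peptide) defining the "N-terminal half" / "C-terminal half" used by the
#'   receptor architecture rules (default 0.5).
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(nterm_window = 25, c_tail_max_dist = Inf,
                          monobasic = FALSE, strict_topology = TRUE,
                          terminal_fraction = 0.5) {
  stopifnot(nterm_window >= 0, c_tail_max_dist >= 0,
            terminal_fraction > 0, terminal_fraction < 1)
  structure(list(nterm_window = nterm_window,
                 c_tail_max_dist = c_tail_max_dist,
                 monobasic = isTRUE(monobasic),
                 strict_topology = isTRUE(strict_topology),
                 terminal_fraction = terminal_fraction),
            class = "screen_params")
}

new_cargo_call <- function(accession, cargo_class, matches, filters_passed,
                           verdict, orientation_ambiguous = FALSE) {
  structure(list(accession = accession, cargo_class = cargo_class,
                 matches = matches, filters_passed = filters_passed,
                 verdict = verdict,
                 orientation_ambiguous = orientation_ambiguous),
            class = "cargo_call")
}

#' @export
print.cargo_call <- function(x, ...) {
  cat(sprintf("<cargo_call> %s [%s]: %s (%d candidate match(es)%s)\n",
              x$accession, x$cargo_class,
              if (x$verdict) "PASS" else "fail", nrow(x$matches),
              if (x$orientation_ambiguous) ", orientation-ambiguous" else ""))
  invisible(x)
}

# Evaluate one motif class on one protein: scan, apply the per-match filters,
# and summarize. `filters` is a named list of functions(match, regions).
evaluate_class <- function(protein, regions, pattern, cargo_class, filters,
                           flag = NULL) {
  hits <- scan_pattern(protein$sequence, pattern)
  if (nrow(hits) == 0L) return(NULL)
  for (fname in names(filters)) {
    hits[[fname]] <- vapply(seq_len(nrow(hits)), function(i) {
      filters[[fname]](hits[i, , drop = FALSE], regions)
    }, logical(1))
  }
  hits$passed <- Reduce(`&`, hits[names(filters)])
  if (!is.null(flag)) hits$flag <- flag
  filters_passed <- vapply(names(filters), function(f) any(hits[[f]]),
                           logical(1))
  new_cargo_call(protein$accession, cargo_class, hits, filters_passed,
                 verdict = any(hits$passed),
                 orientation_ambiguous = protein$orientation_ambiguous)
}

#' Screen a transmembrane protein for cargo sorting signals
#'
#' Evaluates the three transmembrane-cargo signal classes against one
#' annotated protein:
#'
#' * `tm_diacidic` (`[DE]-x-[DE]`) and `tm_dihydrophobic` (`[FY](2)`) — the
#'   match must sit in the stromal C-terminal tail
#'   ([motif_in_stromal_c_tail()]) and outside the transit peptide.
#' * `tm_basic` (`[RK]-x(0,1)-[RK]`, optionally a monobasic fallback) — the
#'   match must sit in the N-tail within `nterm_window` residues of the first
#'   TM span ([motif_in_nterm_window()]) and outside the transit peptide.
#'
#' One `cargo_call` is returned per class with at least one candidate match;
#' the per-match filter outcomes are kept so a failing call is attributable.
#' Proteins flagged `orientation_ambiguous` are screened under both the
#' annotated orientation and its flip, and a class passes if it passes under
#' either; such calls carry `orientation_ambiguous = TRUE`.
#'
#' @param protein An [annotated_protein()] with at least one TM span (soluble
#'   proteins yield an empty result, not an error).
#' @param params A [screen_params()] list.
#' @return A list of `cargo_call` objects (possibly empty).
#' @export
screen_tm_cargo <- function(protein, params = screen_params()) {
  stopifnot(inherits(protein, "annotated_protein"))
  if (protein$is_soluble) return(list())
  calls <- screen_tm_cargo_oriented(protein, params)
  if (protein$orientation_ambiguous) {
    alt <- flip_orientation(protein)
    alt_calls <- screen_tm_cargo_oriented(alt, params)
    calls <- merge_orientation_calls(calls, alt_calls)
  }
  calls
}

screen_tm_cargo_oriented <- function(protein, params) {
  pats <- builtin_patterns()
  regions <- build_region_map(protein, strict = params$strict_topology)
  c_tail_filters <- list(
    outside_transit = motif_outside_transit,
    stromal_c_tail = function(m, r)
      motif_in_stromal_c_tail(m, r, params$c_tail_max_dist))
  n_term_filters <- list(
    outside_transit = motif_outside_transit,
    nterm_window = function(m, r)
      motif_in_nterm_window(m, r, params$nterm_window))
  calls <- list(
    evaluate_class(protein, regions, pats$diacidic, "tm_diacidic",
                   c_tail_filters),
    evaluate_class(protein, regions, pats$dihydrophobic, "tm_dihydrophobic",
                   c_tail_filters),
    evaluate_class(protein, regions, pats$basic, "tm_basic", n_term_filters,
                   flag = "dibasic"))
  if (params$monobasic) {
    mono <- evaluate_class(protein, regions, monobasic_pattern(), "tm_basic",
                           n_term_filters, flag = "monobasic")
    if (!is.null(mono)) {
      di_idx <- which(vapply(calls, function(cl)
        !is.null(cl) && cl$cargo_class == "tm_basic", logical(1)))
      if (length(di_idx) == 1L) {
        di <- calls[[di_idx]]
        di$matches <- rbind(di$matches, mono$matches)
        di$matches <- di$matches[order(di$matches$start, di$matches$end), ]
        rownames(di$matches) <- NULL
        di$filters_passed <- di$filters_passed | mono$filters_passed
        di$verdict <- di$verdict || mono$verdict
        calls[[di_idx]] <- di
      } else {
        calls[[length(calls) + 1L]] <- mono
      }
    }
  }
  Filter(Negate(is.null), calls)
}

# Flip both terminus orientations (the two alternatives of an ambiguous
# printed topology are related by a global flip).
flip_orientation <- function(protein) {
  fl <- function(o) if (is.na(o)) o else if (o == "in") "out" else "in"
  protein$n_orientation <- fl(protein$n_orientation)
  protein$c_orientation <- fl(protein$c_orientation)
  protein
}

merge_orientation_calls <- function(primary, alternative) {
  key <- function(cl) cl$cargo_class
  out <- primary
  for (cl in alternative) {
    idx <- which(vapply(out, key, character(1)) == cl$cargo_class)
    if (length(idx) == 1L) {
      merged <- out[[idx]]
      merged$verdict <- merged$verdict || cl$verdict
      merged$filters_passed <- merged$filters_passed | cl$filters_passed
      merged$matches$passed <- merged$matches$passed | cl$matches$passed
      merged$orientation_ambiguous <- TRUE
      out[[idx]] <- merged
    } else {
      cl$orientation_ambiguous <- TRUE
      out[[length(out) + 1L]] <- cl
    }
  }
  for (i in seq_along(out)) out[[i]]$orientation_ambiguous <- TRUE
  out
}

#' Screen a soluble protein for the ILV cargo signal
#'
#' Scans a soluble protein (no TM spans) with the ILV pattern
#' `I-x(2)-L-x(9)-V`; a match may sit anywhere except overlapping the transit
#' peptide.
#'
#' @param protein An [annotated_protein()] with no TM spans.
#' @return A `cargo_call` of class `soluble_ilv`, or `NULL` when the pattern
#'   does not occur at all.
#' @export
screen_soluble_cargo <- function(protein) {
  stopifnot(inherits(protein, "annotated_protein"))
  if (!protein$is_soluble)
    stop("screen_soluble_cargo expects a soluble protein (no TM spans); got ",
         protein$accession, call. = FALSE)
  regions <- build_region_map(protein)
  evaluate_class(protein, regions, builtin_patterns()$ilv, "soluble_ilv",
                 list(outside_transit = motif_outside_transit))
}

#' Screen a protein for the cargo-receptor architecture
#'
#' Evaluates the Sec14-family cargo-receptor architecture: a GOLD domain in
#' the C-terminal half of the mature sequence that contains a dilysine motif
#' (`K-x(0,1)-K-x(2)` wholly inside the GOLD span), plus a CRAL_TRIO domain.
#' A coiled-coil region in the N-terminal half and the absence of TM spans are
#' reported as supporting evidence, not requirements.
#'
#' @param protein An [annotated_protein()] with domain and coiled-coil
#'   annotations loaded.
#' @param params A [screen_params()] list (`terminal_fraction` sets where the
#'   N/C-terminal halves split).
#' @return An object of class `receptor_call` with fields `has_gold_cterm`,
#'   `has_cral_trio`, `dilysine_in_gold`, `coiled_coil_nterm`, `lacks_tm`,
#'   `dilysine_matches` and `verdict`
#'   (`has_gold_cterm & has_cral_trio & dilysine_in_gold`).
#' @export
screen_receptor <- function(protein, params = screen_params()) {
  stopifnot(inherits(protein, "annotated_protein"))
  t_end <- if (is.na(protein$transit_end)) 0L else protein$transit_end
  mature_len <- protein$length - t_end
  boundary <- t_end + params$terminal_fraction * mature_len
  dom <- protein$domains
  gold <- dom[toupper(dom$name) == "GOLD", , drop = FALSE]
  gold_cterm <- gold[gold$start > boundary, , drop = FALSE]
  has_gold_cterm <- nrow(gold_cterm) > 0L
  has_cral_trio <- any(toupper(dom$name) == "CRAL_TRIO")
  dilysine_matches <- data.frame()
  dilysine_in_gold <- FALSE
  for (k in seq_len(nrow(gold))) {
    hits <- scan_pattern(protein$sequence, builtin_patterns()$dilysine,
                         window = c(gold$start[k], gold$end[k]))
    if (nrow(hits) > 0L) {
      hits$in_cterm_gold <- gold$start[k] > boundary
      dilysine_matches <- rbind(dilysine_matches, hits)
    }
  }
  if (nrow(dilysine_matches) > 0L)
    dilysine_in_gold <- any(dilysine_matches$in_cterm_gold)
  cc <- protein$coiled_coils
  coiled_coil_nterm <- nrow(cc) > 0L &&
    any(cc$start > t_end & cc$end <= boundary)
  lacks_tm <- protein$is_soluble
  structure(
    list(accession = protein$accession,
         has_gold_cterm = has_gold_cterm,
         has_cral_trio = has_cral_trio,
         dilysine_in_gold = dilysine_in_gold,
         coiled_coil_nterm = coiled_coil_nterm,
         lacks_tm = lacks_tm,
         dilysine_matches = dilysine_matches,
         verdict = has_gold_cterm && has_cral_trio && dilysine_in_gold),
    class = "receptor_call")
}

#' @export
print.receptor_call <- function(x, ...) {
  cat(sprintf("<receptor_call> %s: %s\n", x$accession,
              if (x$verdict) "PASS" else "fail"))
  cat(sprintf("  GOLD in C-half: %s | CRAL_TRIO: %s | dilysine in GOLD: %s\n",
              x$has_gold_cterm, x$has_cral_trio, x$dilysine_in_gold))
  cat(sprintf("  supporting: coiled-coil in N-half: %s | no TM spans: %s\n",
              x$coiled_coil_nterm, x$lacks_tm))
  invisible(x)
}

#' Categorize screened cargo candidates by function
#'
#' Counts the distinct verdict-true accessions per functional category and
#' forms the photosynthesis super-category (LHC + PSII + PSI + cytb6f). A
#' protein reported under several motif classes is counted once. Accessions
#' without a category are placed in `unknown` with a warning, never dropped.
#'
#' @param calls A list of `cargo_call` objects (nested lists are flattened),
#'   or a character vector already holding the verdict-true accessions.
#' @param categories Data frame with columns `accession`, `category`;
#'   categories must come from
#'   `{LHC, PSII, PSI, cytb6f, transport, thylakoid_biogenesis,
#'   stress_defense, protease_chaperone, unknown}`.
#' @return A list of class `cargo_categories` with `counts` (named integer
#'   vector over all categories), `photosynthesis` (count), `fractions`
#'   (per-category fraction of the deduplicated total), `total` and
#'   `accessions` (the deduplicated verdict-true set).
#' @export
categorize_cargo <- function(calls, categories) {
  valid <- c("LHC", "PSII", "PSI", "cytb6f", "transport",
             "thylakoid_biogenesis", "stress_defense", "protease_chaperone",
             "unknown")
  stopifnot(all(c("accession", "category") %in% names(categories)))
  bad <- setdiff(unique(categories$category), valid)
  if (length(bad) > 0L)
    stop("unknown category level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  acc <- if (is.character(calls)) {
    unique(calls)
  } else {
    flat <- flatten_calls(calls)
    unique(vapply(Filter(function(cl) isTRUE(cl$verdict), flat),
                  `[[`, character(1), "accession"))
  }
  lut <- setNames(categories$category, categories$accession)
  cat_of <- lut[acc]
  if (anyNA(cat_of)) {
    warning("uncategorized accession(s) assigned to 'unknown': ",
            paste(acc[is.na(cat_of)], collapse = ", "), call. = FALSE)
    cat_of[is.na(cat_of)] <- "unknown"
  }
  counts <- vapply(valid, function(v) sum(cat_of == v), integer(1))
  photo <- sum(counts[c("LHC", "PSII", "PSI", "cytb6f")])
  total <- length(acc)
  structure(
    list(counts = counts, photosynthesis = photo,
         fractions = if (total > 0) counts / total else counts * 0,
         photosynthesis_fraction = if (total > 0) photo / total else 0,
         total = total, accessions = sort(acc)),
    class = "cargo_categories")
}

flatten_calls <- function(calls) {
  if (inherits(calls, "cargo_call")) return(list(calls))
  out <- list()
  for (el in calls) {
    if (is.null(el)) next
    if (inherits(el, "cargo_call")) out[[length(out) + 1L]] <- el
    else out <- c(out, flatten_calls(el))
  }
  out
}

#' @export
print.cargo_categories <- function(x, ...) {
  cat(sprintf("<cargo_categories> %d candidate protein(s)\n", x$total))
  nz <- x$counts[x$counts > 0]
  for (nm in names(nz))
    cat(sprintf("  %-20s %3d (%.1f%%)\n", nm, nz[[nm]],
                100 * x$fractions[[nm]]))
  cat(sprintf("  photosynthesis super-category: %d (%.1f%%)\n",
              x$photosynthesis, 100 * x$photosynthesis_fraction))
  invisible(x)
}
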