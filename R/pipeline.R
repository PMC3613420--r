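#' Read a functional-category table
#'
#' Tab-delimited with header; columns `accession`, `category`. Categories use
#' the fixed vocabulary of [categorize_cargo()].
#'
#' @param path Path to the TSV file.
#' @return Data frame with `accession` and `category`.
#' @export
read_categories <- function(path) {
  if (!file.exists(path)) stop("category file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "category") %in% names(tab)))
  if (anyDuplicated(tab$accession))
    stop("category error: duplicate accession(s)", call. = FALSE)
  tab[, c("accession", "category")]
}

#' Locate a packaged fixture file
#'
#' The package ships small plain-text tables transcribed from the published
#' screen — the printed transmembrane-cargo motif table (`tm_cargo_motifs.tsv`),
#' the soluble ILV-cargo table (`soluble_ilv_motifs.tsv`), the localization-evidence
#' table for the initiation/receptor candidates (`localization_evidence.tsv`) and
#' the functional categories of the 32 categorized cargo candidates
#' (`cargo_categories.tsv`).
#'
#' @param name Fixture file name; with no argument, lists available fixtures.
#' @return Full path to the fixture (or a vector of fixture names).
#' @export
fixture_path <- function(name = NULL) {
  dir <- system.file("extdata", package = "chlorocargo")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path))
    stop("no packaged fixture '", name, "'; available: ",
         paste(list.files(dir), collapse = ", "), call. = FALSE)
  path
}

#' Run the full cargo / receptor screen over an annotated proteome
#'
#' For every protein: transmembrane proteins are screened for the three
#' TM-cargo signal classes ([screen_tm_cargo()]), soluble proteins for the
#' ILV signal ([screen_soluble_cargo()]); every protein is screened for the
#' receptor architecture ([screen_receptor()]). When localization evidence is
#' supplied, each protein also gets a [decide_localization()] verdict; when a
#' category table is supplied, verdict-true cargo candidates are categorized.
#'
#' @param annotations Named list of [annotated_protein()] (e.g. from
#'   [read_annotations()] or [generate_proteome()]).
#' @param evidence Optional named list of [localization_evidence()].
#' @param categories Optional data frame `accession`/`category`.
#' @param params A [screen_params()] list.
#' @param threshold,min_tools Passed to [decide_localization()].
#' @return An object of class `cargo_screen` with elements `calls` (flat list
#'   of `cargo_call`), `receptor_calls`, `verdicts`, `categories`
#'   (a `cargo_categories` or `NULL`) and `params`.
#' @export
run_cargo_screen <- function(annotations, evidence = NULL, categories = NULL,
                             params = screen_params(), threshold = 10,
                             min_tools = 2) {
  calls <- list()
  receptor_calls <- list()
  for (p in annotations) {
    if (p$is_soluble) {
      sc <- screen_soluble_cargo(p)
      if (!is.null(sc)) calls[[length(calls) + 1L]] <- sc
    } else {
      calls <- c(calls, screen_tm_cargo(p, params))
    }
    rc <- screen_receptor(p, params)
    if (rc$has_gold_cterm || rc$has_cral_trio || rc$verdict)
      receptor_calls[[length(receptor_calls) + 1L]] <- rc
  }
  verdicts <- NULL
  if (!is.null(evidence))
    verdicts <- lapply(evidence, decide_localization, threshold = threshold,
                       min_tools = min_tools)
  cats <- NULL
  if (!is.null(categories)) cats <- categorize_cargo(calls, categories)
  structure(list(calls = calls, receptor_calls = receptor_calls,
                 verdicts = verdicts, categories = cats, params = params),
            class = "cargo_screen")
}

#' @export
print.cargo_screen <- function(x, ...) {
  tab <- calls_table(x$calls)
  passed <- tab[tab$verdict, , drop = FALSE]
  cat(sprintf("<cargo_screen> %d cargo call(s), %d passing (%d protein(s))\n",
              nrow(tab), nrow(passed), length(unique(passed$accession))))
  rp <- Filter(function(r) r$verdict, x$receptor_calls)
  cat(sprintf("  receptor candidates: %d\n", length(rp)))
  if (!is.null(x$verdicts)) {
    acc <- sum(vapply(x$verdicts, `[[`, logical(1), "accepted"))
    cat(sprintf("  localization: %d/%d accepted\n", acc, length(x$verdicts)))
  }
  if (!is.null(x$categories)) print(x$categories)
  invisible(x)
}

# Flatten cargo calls into one row per (accession, class) with match summary.
calls_table <- function(calls) {
  flat <- flatten_calls(calls)
  if (length(flat) == 0L)
    return(data.frame(accession = character(0), cargo_class = character(0),
                      n_matches = integer(0), n_passing = integer(0),
                      passing_matches = character(0),
                      filters_passed = character(0),
                      orientation_ambiguous = logical(0),
                      verdict = logical(0), stringsAsFactors = FALSE))
  rows <- lapply(flat, function(cl) {
    pm <- cl$matches[cl$matches$passed, , drop = FALSE]
    data.frame(
      accession = cl$accession, cargo_class = cl$cargo_class,
      n_matches = nrow(cl$matches), n_passing = nrow(pm),
      passing_matches = paste(
        sprintf("%s@%d-%d", pm$matched_text, pm$start, pm$end), collapse = ";"),
      filters_passed = paste(
        sprintf("%s=%s", names(cl$filters_passed),
                ifelse(cl$filters_passed, "yes", "no")), collapse = ";"),
      orientation_ambiguous = cl$orientation_ambiguous,
      verdict = cl$verdict, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$accession, tab$cargo_class), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

receptor_table <- function(receptor_calls) {
  if (length(receptor_calls) == 0L)
    return(data.frame(accession = character(0), has_gold_cterm = logical(0),
                      has_cral_trio = logical(0), dilysine_in_gold = logical(0),
                      coiled_coil_nterm = logical(0), lacks_tm = logical(0),
                      verdict = logical(0), stringsAsFactors = FALSE))
  rows <- lapply(receptor_calls, function(r)
    data.frame(accession = r$accession, has_gold_cterm = r$has_gold_cterm,
               has_cral_trio = r$has_cral_trio,
               dilysine_in_gold = r$dilysine_in_gold,
               coiled_coil_nterm = r$coiled_coil_nterm, lacks_tm = r$lacks_tm,
               verdict = r$verdict, stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$accession), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

verdict_table <- function(verdicts) {
  if (is.null(verdicts) || length(verdicts) == 0L)
    return(data.frame(accession = character(0), accepted = logical(0),
                      route = character(0), consensus_score = numeric(0),
                      supporting_tools = character(0),
                      evidence_notes = character(0), stringsAsFactors = FALSE))
  rows <- lapply(verdicts, function(v)
    data.frame(accession = v$accession, accepted = v$accepted,
               route = v$route, consensus_score = v$consensus_score,
               supporting_tools = paste(v$supporting_tools, collapse = ";"),
               evidence_notes = paste(v$evidence_notes, collapse = ";"),
               stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$accession), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write candidate reports
#'
#' Writes the screen results as TSV tables (`cargo_calls.tsv`,
#' `receptor_calls.tsv`, `localization_verdicts.tsv`) plus a machine-readable
#' `report.json` with the category summary. Row order is deterministic
#' (accession, then class); reruns on the same input are byte-identical.
#'
#' @param screen A `cargo_screen` object from [run_cargo_screen()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(screen, dir) {
  stopifnot(inherits(screen, "cargo_screen"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv <- function(tab, name)
    write.table(tab, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  write_tsv(calls_table(screen$calls), "cargo_calls.tsv")
  write_tsv(receptor_table(screen$receptor_calls), "receptor_calls.tsv")
  write_tsv(verdict_table(screen$verdicts), "localization_verdicts.tsv")
  summary <- list(
    n_calls = length(flatten_calls(screen$calls)),
    n_passing_proteins = length(unique(vapply(
      Filter(function(cl) cl$verdict, flatten_calls(screen$calls)),
      `[[`, character(1), "accession"))),
    n_receptor_candidates = sum(vapply(screen$receptor_calls, `[[`,
                                       logical(1), "verdict")))
  if (!is.null(screen$categories)) {
    summary$category_counts <- as.list(screen$categories$counts)
    summary$photosynthesis <- screen$categories$photosynthesis
    summary$photosynthesis_fraction <- screen$categories$photosynthesis_fraction
    summary$total_categorized <- screen$categories$total
  }
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Compare screen results against a synthetic truth table
#'
#' Scores planted-motif recovery at the coordinate level: a planted motif is
#' recovered when a match of its class with exactly its coordinates passes
#' every positional filter on its protein. Sensitivity is the recovered
#' fraction of `should_pass = TRUE` plantings; control rejection is the
#' fraction of `should_pass = FALSE` plantings (the single-rule-violating
#' controls) whose planted coordinates do not pass.
#'
#' @param screen A `cargo_screen` from [run_cargo_screen()].
#' @param truth Truth table from [generate_proteome()].
#' @return A list with `sensitivity`, `control_rejection`, `n_planted`,
#'   `n_controls`, and the per-planting data frame `detail`.
#' @export
evaluate_recovery <- function(screen, truth) {
  flat <- flatten_calls(screen$calls)
  class_of <- c(diacidic = "tm_diacidic", dihydrophobic = "tm_dihydrophobic",
                basic = "tm_basic", ilv = "soluble_ilv")
  planted <- truth[!is.na(truth$class), , drop = FALSE]
  recovered <- logical(nrow(planted))
  for (k in seq_len(nrow(planted))) {
    want_class <- class_of[[planted$class[k]]]
    hit <- FALSE
    for (cl in flat) {
      if (cl$accession == planted$accession[k] &&
          cl$cargo_class == want_class) {
        m <- cl$matches
        hit <- any(m$passed & m$start == planted$start[k] &
                     m$end == planted$end[k])
        break
      }
    }
    recovered[k] <- hit
  }
  pos <- planted$should_pass
  detail <- cbind(planted[, c("accession", "class", "placement", "start",
                              "end", "should_pass")],
                  recovered = recovered)
  list(
    sensitivity = if (any(pos)) mean(recovered[pos]) else NA_real_,
    control_rejection = if (any(!pos)) mean(!recovered[!pos]) else NA_real_,
    n_planted = sum(pos), n_controls = sum(!pos),
    detail = detail)
}
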