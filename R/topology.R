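#' Partition an annotated protein into labeled topological regions
#'
#' Builds the region map on which the positional sorting-signal rules operate:
#' `transit` (the transit peptide, if annotated), `n_tail` (from the end of
#' the transit peptide to the first TM span), `tm` spans, inter-TM `loop`s,
#' and `c_tail` (after the last TM span). Regions tile the sequence exactly.
#'
#' Each non-membrane region carries a side label: the N-tail takes the
#' annotated N-terminus orientation, the side flips across every TM span, and
#' the C-tail must land on the annotated C-terminus orientation. For soluble
#' proteins (no TM spans) the map is `{transit?, n_tail}` with side `"n/a"`.
#'
#' @param protein An [annotated_protein()].
#' @param strict If `TRUE` (default), an alternation mismatch between the two
#'   annotated terminus orientations is an `inconsistent topology` error. If
#'   `FALSE`, the map trusts the C-tail side (set from `c_orientation`) and
#'   records the inconsistency in the `consistent` attribute — useful for
#'   printed topologies carrying alternative orientations.
#'
#' @return A data frame of class `region_map` with columns `label`, `start`,
#'   `end`, `side` (`"in"`, `"out"`, `"membrane"` or `"n/a"`); attribute
#'   `consistent` reports whether the orientation alternation checked out.
#'
#' @examples
#' p <- annotated_protein("P1", strrep("A", 200), transit_end = 50,
#'                        tm_spans = cbind(100, 120),
#'                        n_orientation = "out", c_orientation = "in")
#' build_region_map(p)
#'
#' @export
build_region_map <- function(protein, strict = TRUE) {
  stopifnot(inherits(protein, "annotated_protein"))
  len <- protein$length
  tm <- protein$tm_spans
  regions <- list()
  add <- function(label, start, end, side) {
    if (end >= start)
      regions[[length(regions) + 1L]] <<-
        data.frame(label = label, start = start, end = end, side = side,
                   stringsAsFactors = FALSE)
  }
  t_end <- if (is.na(protein$transit_end)) 0L else protein$transit_end
  add("transit", 1L, t_end, "n/a")

  if (nrow(tm) == 0L) {
    add("n_tail", t_end + 1L, len, "n/a")
    consistent <- TRUE
  } else {
    flip <- function(s) if (s == "in") "out" else "in"
    side <- protein$n_orientation
    if (tm$start[1] <= t_end)
      stop("inconsistent topology: first TM span overlaps the transit peptide",
           call. = FALSE)
    add("n_tail", t_end + 1L, tm$start[1] - 1L, side)
    for (k in seq_len(nrow(tm))) {
      add("tm", tm$start[k], tm$end[k], "membrane")
      side <- flip(side)
      if (k < nrow(tm)) add("loop", tm$end[k] + 1L, tm$start[k + 1] - 1L, side)
    }
    consistent <- identical(side, protein$c_orientation)
    if (!consistent && strict)
      stop(sprintf(
        "inconsistent topology for %s: alternation from N(%s) across %d TM span(s) lands on %s, but C-orientation is %s",
        protein$accession, protein$n_orientation, nrow(tm), side,
        protein$c_orientation), call. = FALSE)
    add("c_tail", tm$end[nrow(tm)] + 1L, len, protein$c_orientation)
  }
  map <- do.call(rbind, regions)
  rownames(map) <- NULL
  structure(map, class = c("region_map", "data.frame"),
            consistent = consistent, seq_length = len)
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d aa, %d regions%s\n", attr(x, "seq_length"),
              nrow(x),
              if (isTRUE(attr(x, "consistent"))) "" else " [orientation inconsistent]"))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

region_of <- function(regions, label) {
  regions[regions$label == label, , drop = FALSE]
}

match_inside <- function(match, span_row) {
  nrow(span_row) == 1L &&
    match$start >= span_row$start && match$end <= span_row$end
}

#' Is a motif match in the stromal C-terminal tail?
#'
#' The C-terminal tail rule for diacidic and dihydrophobic transmembrane-cargo
#' signals: the match must lie wholly inside the C-tail (after the last TM
#' span), the C-tail must face the stroma (side `"in"`), and the match end
#' must be within `max_dist_from_cterm` residues of the final residue.
#'
#' @param match One-row data frame (or list) with `start` and `end`.
#' @param regions A [build_region_map()] result.
#' @param max_dist_from_cterm Maximum distance of the match end from the final
#'   residue; `Inf` (default) imposes no distance cap beyond the tail itself.
#' @return `TRUE` or `FALSE`.
#' @export
motif_in_stromal_c_tail <- function(match, regions, max_dist_from_cterm = Inf) {
  ct <- region_of(regions, "c_tail")
  if (nrow(ct) != 1L || ct$side != "in") return(FALSE)
  if (!match_inside(match, ct)) return(FALSE)
  (attr(regions, "seq_length") - match$end) <= max_dist_from_cterm
}

#' Is a motif match in the N-tail, proximal to the first TM span?
#'
#' The N-terminal rule for di/mono-basic transmembrane-cargo signals: the
#' match must lie wholly inside the N-tail (hence downstream of any transit
#' peptide) and its start must be within `window` residues of the first TM
#' span's start.
#'
#' @inheritParams motif_in_stromal_c_tail
#' @param window Proximity window in residues (default 25).
#' @return `TRUE` or `FALSE`.
#' @export
motif_in_nterm_window <- function(match, regions, window = 25) {
  nt <- region_of(regions, "n_tail")
  tm <- region_of(regions, "tm")
  if (nrow(tm) == 0L || nrow(nt) != 1L) return(FALSE)
  if (!match_inside(match, nt)) return(FALSE)
  (tm$start[1] - match$start) <= window
}

#' Does a motif match avoid the transit peptide?
#'
#' The only positional rule for the soluble-cargo ILV signal: the match may be
#' anywhere in the protein except overlapping the transit peptide. Always
#' `TRUE` when no transit peptide is annotated.
#'
#' @inheritParams motif_in_stromal_c_tail
#' @return `TRUE` or `FALSE`.
#' @export
motif_outside_transit <- function(match, regions) {
  tr <- region_of(regions, "transit")
  if (nrow(tr) == 0L) return(TRUE)
  match$start > tr$end || match$end < tr$start
}
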