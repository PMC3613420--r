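# The 20 standard amino-acid letters; ambiguity letters are matched only by
# wildcards, never by residue classes (a class asserts a chemical identity
# the data does not support).
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("X", "B", "Z", "U")
AA_ALPHABET <- c(AA_STANDARD, AA_AMBIGUOUS)

#' Compile a Prosite-style sorting-signal pattern
#'
#' Parses a pattern written in the Prosite subset used for vesicle-transport
#' sorting signals: single residue letters, `[..]` residue classes, `{..}`
#' negated classes, `x` wildcards, `(n)` / `(n,m)` repeat qualifiers applied to
#' the preceding element, optional `-` separators, and optional `<` / `>`
#' anchors tying the match to the first / last residue.
#'
#' @param pattern_text Pattern string, e.g. `"[DE]-x-[DE]"` (diacidic) or
#'   `"I-x(2)-L-x(9)-V"` (ILV soluble-cargo signal). Uppercase `X` is accepted
#'   as a wildcard alias.
#' @param pattern_id Short identifier stored on the compiled pattern; defaults
#'   to the canonical pattern text.
#'
#' @return An object of class `motif_pattern`: a list with `pattern_id`,
#'   `elements` (each a list with `kind` one of `"class"`, `"negated"`,
#'   `"wildcard"`, a `letters` set for classes, and `min`/`max` repeat counts),
#'   `n_anchor`, `c_anchor`, and the `min_span`/`max_span` in residues.
#'
#' @examples
#' p <- compile_pattern("I-x(2)-L-x(9)-V", "ilv")
#' p$min_span  # 14
#' format(p)
#'
#' @seealso [scan_pattern()], [builtin_patterns()]
#' @export
compile_pattern <- function(pattern_text, pattern_id = NULL) {
  stopifnot(is.character(pattern_text), length(pattern_text) == 1L)
  toks <- tokenize_pattern(pattern_text)
  elements <- list()
  n_anchor <- FALSE
  c_anchor <- FALSE
  seen_element <- FALSE
  for (tk in toks) {
    switch(tk$type,
      n_anchor = {
        if (seen_element || n_anchor)
          pattern_error("'<' is only allowed once, at the start", tk)
        n_anchor <- TRUE
      },
      c_anchor = {
        if (c_anchor) pattern_error("duplicate '>'", tk)
        c_anchor <- TRUE
      },
      class = ,
      negated = {
        if (c_anchor) pattern_error("element after '>'", tk)
        letters <- strsplit(tk$text, "")[[1]]
        bad <- setdiff(letters, AA_STANDARD)
        if (length(bad) > 0L)
          pattern_error(sprintf("letters outside the 20 standard amino acids: %s",
                                paste(bad, collapse = "")), tk)
        if (anyDuplicated(letters))
          pattern_error("duplicate letters in class", tk)
        if (tk$type == "negated" && length(letters) >= length(AA_STANDARD))
          pattern_error("negated class excludes every residue", tk)
        elements[[length(elements) + 1L]] <-
          list(kind = tk$type, letters = sort(letters), min = 1L, max = 1L)
        seen_element <- TRUE
      },
      wildcard = {
        if (c_anchor) pattern_error("element after '>'", tk)
        elements[[length(elements) + 1L]] <-
          list(kind = "wildcard", letters = character(0), min = 1L, max = 1L)
        seen_element <- TRUE
      },
      repeats = {
        if (length(elements) == 0L)
          pattern_error("repeat qualifier with no preceding element", tk)
        last <- elements[[length(elements)]]
        if (!(last$min == 1L && last$max == 1L))
          pattern_error("element already carries a repeat qualifier", tk)
        if (tk$min > tk$max)
          pattern_error(sprintf("repeat minimum %d exceeds maximum %d",
                                tk$min, tk$max), tk)
        last$min <- tk$min
        last$max <- tk$max
        elements[[length(elements)]] <- last
      },
      stop("unreachable token type")  # nocov
    )
  }
  if (length(elements) == 0L)
    stop("pattern error: pattern has no elements: '", pattern_text, "'",
         call. = FALSE)
  min_span <- sum(vapply(elements, `[[`, integer(1), "min"))
  max_span <- sum(vapply(elements, `[[`, integer(1), "max"))
  if (min_span < 1L)
    stop("pattern error: total minimum span must be at least 1 residue",
         call. = FALSE)
  pat <- structure(
    list(pattern_id = pattern_id, elements = elements,
         n_anchor = n_anchor, c_anchor = c_anchor,
         min_span = as.integer(min_span), max_span = as.integer(max_span)),
    class = "motif_pattern")
  if (is.null(pattern_id)) pat$pattern_id <- format(pat)
  pat
}

pattern_error <- function(msg, tk) {
  stop(sprintf("pattern error at column %d ('%s'): %s", tk$col, tk$text, msg),
       call. = FALSE)
}

# Tokenizer: returns a list of tokens with 1-based column positions so parse
# errors can name the offending token and column.
tokenize_pattern <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, txt, col, extra = list()) {
    toks[[length(toks) + 1L]] <<- c(list(type = type, text = txt, col = col), extra)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "-" || ch == " ") {
      i <- i + 1L
    } else if (ch == "<") {
      push("n_anchor", "<", i); i <- i + 1L
    } else if (ch == ">") {
      push("c_anchor", ">", i); i <- i + 1L
    } else if (ch == "x" || ch == "X") {
      push("wildcard", ch, i); i <- i + 1L
    } else if (ch == "[" || ch == "{") {
      close_ch <- if (ch == "[") "]" else "}"
      j <- i + 1L
      while (j <= n && chars[j] != close_ch) j <- j + 1L
      if (j > n)
        stop(sprintf("pattern error at column %d ('%s'): unbalanced bracket",
                     i, ch), call. = FALSE)
      body <- paste(chars[seq.int(i + 1L, length.out = j - i - 1L)], collapse = "")
      if (!nzchar(body))
        stop(sprintf("pattern error at column %d ('%s%s'): empty class",
                     i, ch, close_ch), call. = FALSE)
      push(if (ch == "[") "class" else "negated", toupper(body), i)
      i <- j + 1L
    } else if (ch == "(") {
      j <- i + 1L
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n)
        stop(sprintf("pattern error at column %d ('('): unbalanced parenthesis", i),
             call. = FALSE)
      body <- paste(chars[seq.int(i + 1L, length.out = j - i - 1L)], collapse = "")
      m <- regmatches(body, regexec("^([0-9]+)(,([0-9]+))?$", body))[[1]]
      if (length(m) == 0L)
        stop(sprintf("pattern error at column %d ('(%s)'): malformed repeat qualifier",
                     i, body), call. = FALSE)
      lo <- as.integer(m[2])
      hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
      push("repeats", paste0("(", body, ")"), i, list(min = lo, max = hi))
      i <- j + 1L
    } else if (toupper(ch) %in% AA_STANDARD) {
      push("class", toupper(ch), i)
      i <- i + 1L
    } else {
      stop(sprintf("pattern error at column %d ('%s'): unexpected character",
                   i, ch), call. = FALSE)
    }
  }
  toks
}

#' @export
format.motif_pattern <- function(x, ...) {
  fmt_el <- function(e) {
    core <- switch(e$kind,
      wildcard = "x",
      class = if (length(e$letters) == 1L) e$letters
              else paste0("[", paste(e$letters, collapse = ""), "]"),
      negated = paste0("{", paste(e$letters, collapse = ""), "}"))
    rep_txt <- if (e$min == 1L && e$max == 1L) ""
               else if (e$min == e$max) sprintf("(%d)", e$min)
               else sprintf("(%d,%d)", e$min, e$max)
    paste0(core, rep_txt)
  }
  body <- paste(vapply(x$elements, fmt_el, character(1)), collapse = "-")
  paste0(if (x$n_anchor) "<" else "", body, if (x$c_anchor) ">" else "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s  (span %d", x$pattern_id, format(x),
              x$min_span))
  if (x$max_span > x$min_span) cat("-", x$max_span, sep = "")
  cat(" aa)\n")
  invisible(x)
}

#' Scan a protein sequence for motif pattern matches
#'
#' Reports every distinct match of a compiled pattern, including overlapping
#' matches and every feasible span of variable-repeat wildcards. Coordinates
#' are 1-based and inclusive at both ends throughout the package. Downstream
#' screens deduplicate per protein; the scanner never does.
#'
#' Ambiguity letters (`X`, `B`, `Z`, `U`) in the sequence are matched only by
#' wildcard elements, never by residue classes or negated classes.
#'
#' @param sequence Amino-acid string (lowercase letters are uppercased).
#' @param pattern A `motif_pattern` from [compile_pattern()] or
#'   [builtin_patterns()].
#' @param window Optional `c(start, end)` region bounds; matches must lie
#'   wholly inside the window and anchors bind to the window termini.
#'
#' @return A data frame with columns `pattern_id`, `start`, `end`,
#'   `matched_text`, sorted by `start` then `end`.
#'
#' @examples
#' ilv <- builtin_patterns()$ilv
#' scan_pattern("IDALQIELSCTAGV", ilv)
#' scan_pattern("EEDEE", builtin_patterns()$diacidic)  # 3 overlapping matches
#'
#' @export
scan_pattern <- function(sequence, pattern, window = NULL) {
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- validate_sequence(sequence)
  n <- length(chars)
  if (is.null(window)) {
    win <- c(1L, n)
  } else {
    win <- as.integer(window)
    if (length(win) != 2L || is.na(win[1]) || is.na(win[2]) ||
        win[1] < 1L || win[2] > n || win[1] > win[2])
      stop("window must be c(start, end) within the sequence", call. = FALSE)
  }
  starts <- if (pattern$n_anchor) win[1] else seq.int(win[1], win[2])
  hits_start <- integer(0)
  hits_end <- integer(0)
  for (s in starts) {
    if (s + pattern$min_span - 1L > win[2]) next
    ends <- match_ends(chars, s, pattern$elements, 1L, win[2])
    if (pattern$c_anchor) ends <- ends[ends == win[2]]
    if (length(ends) > 0L) {
      hits_start <- c(hits_start, rep.int(s, length(ends)))
      hits_end <- c(hits_end, ends)
    }
  }
  if (length(hits_start) > 0L) {
    keep <- !duplicated(cbind(hits_start, hits_end))
    hits_start <- hits_start[keep]
    hits_end <- hits_end[keep]
    ord <- order(hits_start, hits_end)
    hits_start <- hits_start[ord]
    hits_end <- hits_end[ord]
  }
  data.frame(
    pattern_id = rep.int(pattern$pattern_id %||% "", length(hits_start)),
    start = hits_start,
    end = hits_end,
    matched_text = vapply(seq_along(hits_start), function(i) {
      paste(chars[hits_start[i]:hits_end[i]], collapse = "")
    }, character(1)),
    stringsAsFactors = FALSE)
}

# Recursive matcher: set of end positions (inclusive) of matches of
# elements[idx..] beginning at pos, never extending past `limit`.
match_ends <- function(chars, pos, elements, idx, limit) {
  if (idx > length(elements)) return(pos - 1L)
  e <- elements[[idx]]
  ends <- integer(0)
  r <- 0L
  repeat {
    if (r >= e$min) {
      ends <- c(ends, match_ends(chars, pos + r, elements, idx + 1L, limit))
    }
    if (r >= e$max) break
    p <- pos + r
    if (p > limit) break
    ch <- chars[p]
    ok <- switch(e$kind,
      wildcard = TRUE,
      class = ch %in% e$letters,
      negated = !(ch %in% e$letters) && !(ch %in% AA_AMBIGUOUS))
    if (!ok) break
    r <- r + 1L
  }
  unique(ends)
}

validate_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0L)
    stop("sequence validation error: empty sequence", call. = FALSE)
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L)
    stop("sequence validation error: illegal residue letters: ",
         paste(bad, collapse = ""), call. = FALSE)
  chars
}

#' The built-in sorting-signal pattern catalog
#'
#' The five hand-defined sorting-signal patterns of the chloroplast cargo
#' screen, compiled once:
#'
#' * `diacidic` — `[DE]-x-[DE]`, C-terminal tail signal of transmembrane cargo.
#' * `dihydrophobic` — `[FY](2)`, C-terminal tail signal of transmembrane cargo.
#' * `basic` — `[RK]-x(0,1)-[RK]`, N-terminal signal of transmembrane cargo.
#'   The zero-length spacer variant is included so that adjacent dibasic pairs
#'   such as `KK` (the form the printed evidence takes) match; the strict
#'   one-residue-spacer form remains available via
#'   `compile_pattern("[RK]-x-[RK]")`. A monobasic fallback (a single `K`/`R`)
#'   is handled separately by the screens and is off by default, because no
#'   rule is given for when a monobasic signal suffices.
#' * `ilv` — `I-x(2)-L-x(9)-V`, the soluble-cargo signal (fixed span 14).
#' * `dilysine` — `K-x(0,1)-K-x(2)`, the cargo-receptor signal inside the
#'   GOLD domain.
#'
#' @return A named list of `motif_pattern` objects keyed by
#'   `{diacidic, dihydrophobic, basic, ilv, dilysine}`.
#'
#' @examples
#' names(builtin_patterns())
#' scan_pattern("KAKLE", builtin_patterns()$dilysine)
#'
#' @export
builtin_patterns <- function() {
  list(
    diacidic      = compile_pattern("[DE]-x-[DE]", "diacidic"),
    dihydrophobic = compile_pattern("[FY](2)", "dihydrophobic"),
    basic         = compile_pattern("[RK]-x(0,1)-[RK]", "basic"),
    ilv           = compile_pattern("I-x(2)-L-x(9)-V", "ilv"),
    dilysine      = compile_pattern("K-x(0,1)-K-x(2)", "dilysine")
  )
}

# The monobasic fallback pattern (single K or R), used by screen_tm_cargo()
# when explicitly enabled.
monobasic_pattern <- function() compile_pattern("[RK]", "monobasic")

`%||%` <- function(a, b) if (is.null(a)) b else a
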