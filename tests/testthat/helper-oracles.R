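# Independent oracles the property tests compare the implementation against.
# Both take a deliberately different route from the package internals: the
# pattern oracle goes through R's regex engine over enumerated repeat-count
# assignments, the alignment oracle is a memoized forward recursion.

aa_standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
aa_any <- c(aa_standard, "X", "B", "Z", "U")

# Brute-force pattern matcher: enumerate every assignment of repeat counts to
# elements, turn each into a fixed regular expression, and test every
# substring of the right length.
oracle_scan <- function(sequence, pattern) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  els <- pattern$elements
  grid <- expand.grid(lapply(els, function(e) seq.int(e$min, e$max)))
  found <- matrix(integer(0), ncol = 2)
  for (g in seq_len(nrow(grid))) {
    rx <- ""
    for (k in seq_along(els)) {
      e <- els[[k]]
      r <- grid[g, k]
      if (r == 0) next
      piece <- switch(e$kind,
        wildcard = paste0("[", paste(aa_any, collapse = ""), "]"),
        class = paste0("[", paste(e$letters, collapse = ""), "]"),
        negated = paste0("[", paste(setdiff(aa_standard, e$letters),
                                    collapse = ""), "]"))
      rx <- paste0(rx, strrep(piece, r))
    }
    L <- sum(unlist(grid[g, , drop = FALSE]))
    if (L < 1 || L > n) next
    starts <- if (pattern$n_anchor) 1L else seq_len(n - L + 1L)
    for (s in starts) {
      e_pos <- s + L - 1L
      if (pattern$c_anchor && e_pos != n) next
      sub <- paste(chars[s:e_pos], collapse = "")
      if (grepl(paste0("^", rx, "$"), sub)) found <- rbind(found, c(s, e_pos))
    }
  }
  if (nrow(found) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  found <- unique(found)
  found <- found[order(found[, 1], found[, 2]), , drop = FALSE]
  data.frame(start = found[, 1], end = found[, 2])
}

# Memoized forward recursion over (i, j, previous-move) states; gap of length
# L costs open + L * ext, matching the package's stated convention.
oracle_align_score <- function(a, b, matrix_name = "BLOSUM62", open = 10,
                               ext = 1) {
  S <- local({
    env <- new.env()
    utils::data(list = matrix_name, package = "Biostrings", envir = env)
    get(matrix_name, envir = env)
  })
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, S[A[i], B[j]] + rec(i + 1L, j + 1L, 0L))
    if (i <= length(A))
      best <- max(best, -(ext + if (state == 1L) 0 else open) +
                    rec(i + 1L, j, 1L))
    if (j <= length(B))
      best <- max(best, -(ext + if (state == 2L) 0 else open) +
                    rec(i, j + 1L, 2L))
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

# Re-score an alignment from its columns: substitution scores for residue
# pairs, open + len * ext for every maximal gap run in either row.
rescore_alignment <- function(al) {
  S <- local({
    env <- new.env()
    utils::data(list = al$substitution_name, package = "Biostrings",
                envir = env)
    get(al$substitution_name, envir = env)
  })
  qa <- strsplit(al$aligned_a, "")[[1]]
  ha <- strsplit(al$aligned_b, "")[[1]]
  score <- 0
  for (k in seq_along(qa)) {
    if (qa[k] != "-" && ha[k] != "-") score <- score + S[qa[k], ha[k]]
  }
  gap_cost <- function(v) {
    r <- rle(v == "-")
    sum(vapply(r$lengths[r$values], function(L)
      al$gap_open + L * al$gap_extend, numeric(1)))
  }
  score - gap_cost(qa) - gap_cost(ha)
}

random_aa_seq <- function(len, pool = aa_standard) {
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

# A reduced planted-motif plan for small test proteomes (21 hosts).
small_plan <- function() {
  plan <- rbind(
    expand.grid(class = "diacidic",
                placement = c("correct", "wrong_region", "wrong_orientation",
                              "inside_transit"), stringsAsFactors = FALSE),
    expand.grid(class = "dihydrophobic",
                placement = c("correct", "wrong_orientation"),
                stringsAsFactors = FALSE),
    expand.grid(class = "basic", placement = c("correct", "wrong_region"),
                stringsAsFactors = FALSE),
    expand.grid(class = "ilv", placement = c("correct", "inside_transit"),
                stringsAsFactors = FALSE))
  plan$count <- ifelse(plan$placement == "correct", 3L, 1L)
  plan
}

small_config <- function(n_proteins, seed, ...) {
  sim_config(n_proteins = n_proteins, seed = seed, motif_plan = small_plan(),
             ...)
}

# A synthetic receptor-architecture protein: CRAL_TRIO mid-protein, GOLD at
# the C-terminus containing a dilysine motif, coiled-coil near the N-terminus,
# no TM spans. Modeled on the At4g09160-type architecture.
make_receptor_protein <- function(accession = "RCPT1", dilysine = TRUE,
                                  gold_nterm = FALSE, cral = TRUE) {
  set.seed(42)
  len <- 400L
  chars <- strsplit(random_aa_seq(len, setdiff(aa_standard, c("K", "R"))),
                    "")[[1]]
  gold_span <- if (gold_nterm) c(60L, 160L) else c(290L, 390L)
  if (dilysine) {
    pos <- gold_span[1] + 50L
    chars[pos:(pos + 4L)] <- c("K", "S", "K", "A", "A")
  }
  domains <- data.frame(
    name = c("GOLD", if (cral) "CRAL_TRIO"),
    start = c(gold_span[1], if (cral) 150L),
    end = c(gold_span[2], if (cral) 260L))
  if (gold_nterm && cral) domains$start[2] <- 180L
  annotated_protein(accession, paste(chars, collapse = ""),
                    transit_end = 45,
                    domains = domains,
                    coiled_coils = data.frame(start = 60, end = 100))
}
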