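SUBSTITUTION_MATRICES <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                           "BLOSUM100", "PAM30", "PAM40", "PAM70", "PAM120",
                           "PAM250")

get_substitution_matrix <- function(name) {
  if (!name %in% SUBSTITUTION_MATRICES)
    stop("unknown substitution matrix '", name, "'; available: ",
         paste(SUBSTITUTION_MATRICES, collapse = ", "), call. = FALSE)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Optimal global alignment with affine gap penalties
#'
#' Needleman–Wunsch global alignment with affine gaps (Gotoh's three-state
#' recursion). A gap of length L costs `gap_open + L * gap_extend`. The
#' traceback is deterministic: on ties it prefers the diagonal move, then the
#' vertical move (gap in `b`), then the horizontal move (gap in `a`).
#'
#' @param a,b Amino-acid sequences (non-empty).
#' @param substitution Name of a published substitution matrix (default
#'   `"BLOSUM62"`); one of `r paste(SUBSTITUTION_MATRICES, collapse = ", ")`.
#' @param gap_open,gap_extend Positive gap penalties (defaults 10 and 1).
#' @return An object of class `protein_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length strings with `-` gap symbols), `score`,
#'   `substitution_name`, `gap_open`, `gap_extend`.
#' @examples
#' al <- global_align("HEAGAWGHEE", "PAWHEAE", substitution = "BLOSUM50")
#' al$score
#' @export
global_align <- function(a, b, substitution = "BLOSUM62", gap_open = 10,
                         gap_extend = 1) {
  A <- validate_sequence(a)
  B <- validate_sequence(b)
  S <- get_substitution_matrix(substitution)
  stopifnot(gap_open >= 0, gap_extend >= 0)
  n <- length(A); m <- length(B)
  NEG <- -Inf
  # state 1 = M (diagonal), 2 = X (gap in b, consumes a), 3 = Y (gap in a)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  ptrM <- matrix(0L, n + 1L, m + 1L)
  ptrX <- matrix(0L, n + 1L, m + 1L)
  ptrY <- matrix(0L, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (n > 0) for (i in 2:(n + 1L)) {
    X[i, 1] <- -(gap_open + (i - 1L) * gap_extend)
    ptrX[i, 1] <- 2L
  }
  if (m > 0) for (j in 2:(m + 1L)) {
    Y[1, j] <- -(gap_open + (j - 1L) * gap_extend)
    ptrY[1, j] <- 3L
  }
  # `best3` prefers M, then X, then Y on ties — the tie-break order that makes
  # the traceback deterministic.
  best3 <- function(vm, vx, vy) {
    if (vm >= vx && vm >= vy) c(vm, 1L)
    else if (vx >= vy) c(vx, 2L)
    else c(vy, 3L)
  }
  for (i in seq_len(n)) {
    Ai <- A[i]
    sub_row <- S[Ai, ]
    for (j in seq_len(m)) {
      ii <- i + 1L; jj <- j + 1L
      bm <- best3(M[ii - 1L, jj - 1L], X[ii - 1L, jj - 1L], Y[ii - 1L, jj - 1L])
      M[ii, jj] <- bm[1] + sub_row[[B[j]]]
      ptrM[ii, jj] <- bm[2]
      bx <- best3(M[ii - 1L, jj] - (gap_open + gap_extend),
                  X[ii - 1L, jj] - gap_extend,
                  Y[ii - 1L, jj] - (gap_open + gap_extend))
      X[ii, jj] <- bx[1]
      ptrX[ii, jj] <- bx[2]
      by <- best3(M[ii, jj - 1L] - (gap_open + gap_extend),
                  X[ii, jj - 1L] - (gap_open + gap_extend),
                  Y[ii, jj - 1L] - gap_extend)
      Y[ii, jj] <- by[1]
      ptrY[ii, jj] <- by[2]
    }
  }
  fin <- best3(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  score <- fin[1]
  state <- fin[2]
  # traceback
  al_a <- character(0); al_b <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      al_a <- c(A[i], al_a); al_b <- c(B[j], al_b)
      state <- ptrM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      al_a <- c(A[i], al_a); al_b <- c("-", al_b)
      state <- ptrX[i + 1L, j + 1L]
      i <- i - 1L
    } else {
      al_a <- c("-", al_a); al_b <- c(B[j], al_b)
      state <- ptrY[i + 1L, j + 1L]
      j <- j - 1L
    }
  }
  structure(
    list(aligned_a = paste(al_a, collapse = ""),
         aligned_b = paste(al_b, collapse = ""),
         score = score, substitution_name = substitution,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> score %.1f (%s, gap open %g extend %g)\n",
              x$score, x$substitution_name, x$gap_open, x$gap_extend))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Measure the unaligned N-terminal overhang of a query
#'
#' Evidence for a chloroplast transit peptide: a candidate protein aligned
#' against its non-plastid homologues shows an extra N-terminal stretch. For
#' each homologue, the overhang is the number of query residues placed before
#' the first alignment column in which both sequences carry a residue; the
#' conservative overhang is the minimum over homologues.
#'
#' @param query Candidate amino-acid sequence.
#' @param homologues Character vector (length ≥ 1) of homologue sequences.
#' @param substitution,gap_open,gap_extend Passed to [global_align()].
#' @return Integer overhang length (minimum over homologues).
#' @examples
#' h <- "MSTKDLVKEWQRLIGHEEAWNK"
#' nterm_overhang(paste0("MAASSSTTLC", h), h)  # 10
#' @export
nterm_overhang <- function(query, homologues, substitution = "BLOSUM62",
                           gap_open = 10, gap_extend = 1) {
  stopifnot(length(homologues) >= 1L)
  per_hom <- vapply(homologues, function(h) {
    al <- global_align(query, h, substitution = substitution,
                       gap_open = gap_open, gap_extend = gap_extend)
    qa <- strsplit(al$aligned_a, "")[[1]]
    ha <- strsplit(al$aligned_b, "")[[1]]
    both <- which(qa != "-" & ha != "-")
    if (length(both) == 0L) return(sum(qa != "-"))
    sum(qa[seq_len(both[1] - 1L)] != "-")
  }, numeric(1))
  as.integer(min(per_hom))
}

#' Call a transit-peptide-like N-terminal extension
#'
#' @param overhang Non-negative overhang length from [nterm_overhang()].
#' @param min_length Minimum extension length to call (default 20, a typical
#'   lower bound for plant chloroplast transit peptides; the boundary is
#'   inclusive).
#' @return `TRUE` iff `overhang >= min_length`.
#' @export
call_extension <- function(overhang, min_length = 20) {
  stopifnot(overhang >= 0)
  overhang >= min_length
}
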