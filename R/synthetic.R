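# Residue pools for the composition the screens assume: transit peptides are
# serine/threonine-enriched, TM spans hydrophobic-enriched.
TRANSIT_POOL <- c(rep(c("S", "T"), 6), AA_STANDARD)
TM_POOL <- c(rep(c("A", "I", "L", "V", "F", "M", "W"), 4), "G", "S", "T", "Y")
AVERAGE_AA_FREQS <- c(
  A = 0.0826, C = 0.0136, D = 0.0546, E = 0.0672, F = 0.0387, G = 0.0708,
  H = 0.0227, I = 0.0598, K = 0.0581, L = 0.0966, M = 0.0241, N = 0.0406,
  P = 0.0475, Q = 0.0394, R = 0.0553, S = 0.0665, T = 0.0534, V = 0.0687,
  W = 0.0110, Y = 0.0292)

default_motif_plan <- function() {
  rbind(
    expand.grid(class = "diacidic",
                placement = c("correct", "wrong_region", "wrong_orientation",
                              "inside_transit"),
                stringsAsFactors = FALSE),
    expand.grid(class = "dihydrophobic",
                placement = c("correct", "wrong_region", "wrong_orientation",
                              "inside_transit"),
                stringsAsFactors = FALSE),
    expand.grid(class = "basic",
                placement = c("correct", "wrong_region", "inside_transit"),
                stringsAsFactors = FALSE),
    expand.grid(class = "ilv",
                placement = c("correct", "inside_transit"),
                stringsAsFactors = FALSE)
  ) -> plan
  plan$count <- ifelse(plan$placement == "correct", 10L, 5L)
  plan
}

#' Simulation configuration for synthetic proteomes
#'
#' Defines the study conditions the synthetic proteome emulates: plant-like
#' proteins with N-terminal transit peptides (30–80 aa, Ser/Thr-enriched),
#' hydrophobic TM spans (18–24 aa), sorting-signal motifs planted at correct
#' positions and as controls that each violate exactly one placement rule, and
#' noisy multi-tool localization evidence.
#'
#' @param n_proteins Number of proteins (default 500).
#' @param fraction_chloroplast Fraction of true chloroplast proteins
#'   (default 0.5).
#' @param transit_length_range Transit-peptide length range (default 30–80).
#' @param tm_count_probs Named probability vector over TM span counts
#'   (default favours 0–2 spans).
#' @param tm_length_range TM span length range (default 18–24).
#' @param tail_length_range N-/C-tail length range (default 30–90).
#' @param loop_length_range Inter-TM loop length range (default 10–40).
#' @param motif_plan Data frame with columns `class`, `placement`, `count`
#'   giving the planted-motif plan per signal class; placements are
#'   `correct`, `wrong_region`, `wrong_orientation` (C-tail classes only) and
#'   `inside_transit`.
#' @param background `"uniform"` (default) or `"average"` residue frequencies
#'   for non-structured segments.
#' @param nterm_window The basic-signal proximity window the generator plants
#'   against (must match the screen parameter; default 25).
#' @param noise Probability that a true chloroplast protein receives a
#'   sub-threshold consensus score (default 0.2).
#' @param fallback_prob Probability that a sub-threshold true chloroplast
#'   protein still receives enough individual chloroplast tool calls to pass
#'   the fallback route (default 0.5).
#' @param fallback_tools Number of chloroplast tool calls given when the
#'   fallback succeeds (default 4).
#' @param min_tools Fallback tool-count threshold mirrored from
#'   [decide_localization()] (default 2).
#' @param threshold Consensus acceptance threshold (default 10).
#' @param consensus_ceiling Maximum consensus score (default 20).
#' @param seed Integer RNG seed (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 500,
                       fraction_chloroplast = 0.5,
                       transit_length_range = c(30, 80),
                       tm_count_probs = c("0" = 0.4, "1" = 0.25, "2" = 0.2,
                                          "3" = 0.1, "4" = 0.05),
                       tm_length_range = c(18, 24),
                       tail_length_range = c(30, 90),
                       loop_length_range = c(10, 40),
                       motif_plan = default_motif_plan(),
                       background = c("uniform", "average"),
                       nterm_window = 25,
                       noise = 0.2,
                       fallback_prob = 0.5,
                       fallback_tools = 4,
                       min_tools = 2,
                       threshold = 10,
                       consensus_ceiling = 20,
                       seed = 1) {
  background <- match.arg(background)
  stopifnot(n_proteins >= 1,
            fraction_chloroplast >= 0, fraction_chloroplast <= 1,
            diff(transit_length_range) > 0, diff(tm_length_range) > 0,
            all(motif_plan$count >= 0),
            noise >= 0, noise <= 1, fallback_prob >= 0, fallback_prob <= 1,
            consensus_ceiling > threshold)
  structure(as.list(environment()), class = "sim_config")
}

MOTIF_POOL_TOOLS <- c("TargetP", "ChloroP", "MultiLoc", "PCLR", "WoLFPSORT",
                      "BaCelLo", "PredSL", "SLPFA")

r_int <- function(n, range) sample(seq.int(range[1], range[2]), n, replace = TRUE)

random_residues <- function(n, config, pool = NULL) {
  if (!is.null(pool)) return(sample(pool, n, replace = TRUE))
  if (config$background == "uniform")
    sample(AA_STANDARD, n, replace = TRUE)
  else
    sample(names(AVERAGE_AA_FREQS), n, replace = TRUE, prob = AVERAGE_AA_FREQS)
}

motif_instance <- function(class) {
  basic_letters <- c("K", "R")
  switch(class,
    diacidic = paste0(sample(c("D", "E"), 1), sample(AA_STANDARD, 1),
                      sample(c("D", "E"), 1)),
    dihydrophobic = paste0(sample(c("F", "Y"), 1), sample(c("F", "Y"), 1)),
    basic = {
      spacer <- sample(0:1, 1)
      paste0(sample(basic_letters, 1),
             if (spacer) sample(setdiff(AA_STANDARD, basic_letters), 1) else "",
             sample(basic_letters, 1))
    },
    ilv = paste0("I", paste(sample(AA_STANDARD, 2, replace = TRUE), collapse = ""),
                 "L", paste(sample(AA_STANDARD, 9, replace = TRUE), collapse = ""),
                 "V"),
    stop("no planted instance defined for class '", class, "'", call. = FALSE))
}

#' Generate a synthetic annotated proteome with ground truth
#'
#' Builds a proteome with the statistical structure the screens assume:
#' chloroplast proteins carry Ser/Thr-enriched transit peptides, membrane
#' proteins carry hydrophobic TM spans with consistent terminus orientations,
#' and sorting-signal motifs are planted verbatim at recorded coordinates —
#' either at positions satisfying every placement rule (`should_pass = TRUE`)
#' or as controls violating exactly one rule (`should_pass = FALSE`).
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `proteome` (data frame: `accession`, `sequence`,
#'   `description`), `annotations` (named list of [annotated_protein()]) and
#'   `truth` (data frame: one row per protein with `accession`,
#'   `is_chloroplast`, `transit_end`, `n_tm`, `class`, `placement`, `start`,
#'   `end`, `motif`, `should_pass`, `category`).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  plan <- config$motif_plan
  hosts <- plan[rep(seq_len(nrow(plan)), plan$count), c("class", "placement")]
  rownames(hosts) <- NULL
  n_hosts <- nrow(hosts)
  if (n_hosts > config$n_proteins)
    stop(sprintf(
      "motif plan infeasible: %d planted motifs exceed n_proteins = %d",
      n_hosts, config$n_proteins), call. = FALSE)
  if (config$transit_length_range[1] < 14 &&
      any(hosts$placement == "inside_transit" & hosts$class == "ilv"))
    stop("motif plan infeasible: transit peptides shorter than the ILV span",
         call. = FALSE)
  bad <- hosts$placement == "wrong_orientation" &
    !hosts$class %in% c("diacidic", "dihydrophobic")
  if (any(bad))
    stop("motif plan infeasible: wrong_orientation applies only to C-tail ",
         "signal classes", call. = FALSE)

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(config$seed)

  n <- config$n_proteins
  n_chl <- max(n_hosts, round(n * config$fraction_chloroplast))
  categories <- c("LHC", "PSII", "PSI", "cytb6f", "transport",
                  "thylakoid_biogenesis", "stress_defense",
                  "protease_chaperone", "unknown")
  proteome_rows <- vector("list", n)
  annotations <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    acc <- sprintf("SYN%04d", i)
    is_host <- i <= n_hosts
    cls <- if (is_host) hosts$class[i] else NA_character_
    plc <- if (is_host) hosts$placement[i] else NA_character_
    is_chl <- i <= n_chl

    transit_len <- if (is_chl) r_int(1, config$transit_length_range) else 0L
    needs_tm <- is_host && cls != "ilv"
    n_tm <- if (is_host) {
      if (cls == "ilv") 0L else max(1L, sample_tm_count(config))
    } else sample_tm_count(config)

    # orientation: C-tail hosts need a stromal (or, for the orientation
    # control, lumenal) C-tail; everything else is random
    c_orient <- if (is_host && cls %in% c("diacidic", "dihydrophobic")) {
      if (plc == "wrong_orientation") "out" else "in"
    } else sample(c("in", "out"), 1)
    n_orient <- if (n_tm %% 2L == 0L) c_orient else
      if (c_orient == "in") "out" else "in"

    seg_transit <- random_residues(transit_len, config, TRANSIT_POOL)
    n_tail_len <- r_int(1, config$tail_length_range)
    seg_n_tail <- random_residues(n_tail_len, config)
    tm_lens <- if (n_tm > 0L) r_int(n_tm, config$tm_length_range) else integer(0)
    loop_lens <- if (n_tm > 1L) r_int(n_tm - 1L, config$loop_length_range)
                 else integer(0)
    c_tail_len <- if (n_tm > 0L) r_int(1, config$tail_length_range) else 0L

    segs <- list(seg_transit, seg_n_tail)
    for (k in seq_len(n_tm)) {
      segs[[length(segs) + 1L]] <- random_residues(tm_lens[k], config, TM_POOL)
      if (k < n_tm)
        segs[[length(segs) + 1L]] <- random_residues(loop_lens[k], config)
    }
    if (n_tm > 0L) segs[[length(segs) + 1L]] <- random_residues(c_tail_len, config)
    chars <- unlist(segs)
    len <- length(chars)

    # region coordinates
    n_tail_start <- transit_len + 1L
    tm_start <- integer(n_tm); tm_end <- integer(n_tm)
    pos <- transit_len + n_tail_len
    for (k in seq_len(n_tm)) {
      tm_start[k] <- pos + 1L
      tm_end[k] <- pos + tm_lens[k]
      pos <- tm_end[k] + if (k < n_tm) loop_lens[k] else 0L
    }
    c_tail_start <- if (n_tm > 0L) tm_end[n_tm] + 1L else NA_integer_

    m_start <- NA_integer_; m_end <- NA_integer_; motif <- NA_character_
    should_pass <- NA
    if (is_host) {
      motif <- motif_instance(cls)
      mlen <- nchar(motif)
      span <- plant_span(cls, plc, mlen, transit_len, n_tail_start,
                         n_tail_len, tm_start, c_tail_start, len,
                         config$nterm_window)
      m_start <- span[1]; m_end <- span[2]
      chars[m_start:m_end] <- strsplit(motif, "")[[1]]
      should_pass <- plc == "correct"
    }

    sequence <- paste(chars, collapse = "")
    proteome_rows[[i]] <- data.frame(
      accession = acc, sequence = sequence,
      description = if (is_chl) "synthetic chloroplast protein"
                    else "synthetic non-chloroplast protein",
      stringsAsFactors = FALSE)
    annotations[[i]] <- annotated_protein(
      accession = acc, sequence = sequence,
      transit_end = if (transit_len > 0L) transit_len else NA,
      tm_spans = if (n_tm > 0L) data.frame(start = tm_start, end = tm_end)
                 else NULL,
      n_orientation = if (n_tm > 0L) n_orient else NA,
      c_orientation = if (n_tm > 0L) c_orient else NA)
    truth_rows[[i]] <- data.frame(
      accession = acc, is_chloroplast = is_chl,
      transit_end = if (transit_len > 0L) transit_len else NA_integer_,
      n_tm = n_tm, class = cls, placement = plc,
      start = m_start, end = m_end, motif = motif,
      should_pass = should_pass,
      category = if (is_chl) sample(categories, 1) else NA_character_,
      stringsAsFactors = FALSE)
  }
  proteome <- do.call(rbind, proteome_rows)
  class(proteome) <- c("proteome", "data.frame")
  names(annotations) <- proteome$accession
  truth <- do.call(rbind, truth_rows)
  list(proteome = proteome, annotations = annotations, truth = truth)
}

sample_tm_count <- function(config) {
  p <- config$tm_count_probs
  as.integer(sample(names(p), 1, prob = p))
}

# Pick the span at which to plant a motif instance so that the placement
# violates exactly the intended rule (or none, for "correct").
plant_span <- function(cls, plc, mlen, transit_len, n_tail_start, n_tail_len,
                       tm_start, c_tail_start, len, window) {
  n_tail_end <- n_tail_start + n_tail_len - 1L
  pick <- function(lo, hi) {
    if (hi < lo)
      stop(sprintf(
        "motif plan infeasible: no room to plant %s/%s (feasible start range %d..%d)",
        cls, plc, lo, hi), call. = FALSE)
    s <- if (lo == hi) lo else sample(seq.int(lo, hi), 1)
    c(s, s + mlen - 1L)
  }
  if (plc == "inside_transit") return(pick(1L, transit_len - mlen + 1L))
  if (cls == "ilv") return(pick(n_tail_start, n_tail_end - mlen + 1L))
  if (cls == "basic") {
    if (plc == "correct")
      return(pick(max(n_tail_start, tm_start[1] - window),
                  tm_start[1] - mlen))
    # wrong_region: in the C-tail, violating only the N-tail rule
    return(pick(c_tail_start, len - mlen + 1L))
  }
  # diacidic / dihydrophobic
  if (plc == "wrong_region")
    return(pick(n_tail_start, n_tail_end - mlen + 1L))
  # correct and wrong_orientation both sit in the C-tail
  pick(c_tail_start, len - mlen + 1L)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Generate synthetic localization evidence for a truth table
#'
#' Emulates the multi-tool evidence the consensus decision tree consumes:
#' true chloroplast proteins receive an above-threshold chloroplast consensus
#' score with probability `1 - noise`; otherwise they receive a sub-threshold
#' score plus — with probability `fallback_prob` — enough individual
#' chloroplast tool calls (`fallback_tools`) to pass the fallback route.
#' Non-chloroplast proteins receive low chloroplast scores and fewer than
#' `min_tools` chloroplast calls. Deterministic per `config$seed`.
#'
#' @param truth Data frame with columns `accession` and `is_chloroplast`
#'   (e.g. the truth table of [generate_proteome()]).
#' @param config A [sim_config()].
#' @return Named list of [localization_evidence()] records.
#' @export
generate_localization_evidence <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"),
            all(c("accession", "is_chloroplast") %in% names(truth)))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(config$seed + 1L)
  thr <- config$threshold
  ceil <- config$consensus_ceiling
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    acc <- truth$accession[i]
    if (truth$is_chloroplast[i]) {
      if (runif(1) >= config$noise) {
        scores <- c(chloroplast = runif(1, thr, ceil),
                    mitochondrion = runif(1, 0, thr / 2),
                    secretory = runif(1, 0, thr / 2))
        tools <- character(0)
      } else {
        scores <- c(chloroplast = runif(1, 0, thr * 0.99),
                    mitochondrion = runif(1, 0, thr / 2),
                    secretory = runif(1, 0, thr / 2))
        n_tools <- if (runif(1) < config$fallback_prob) config$fallback_tools
                   else sample(0:(config$min_tools - 1L), 1)
        tools <- setNames(rep("chloroplast", n_tools),
                          sample(MOTIF_POOL_TOOLS, n_tools))
      }
      flags <- c(proteomics_msms = runif(1) < 0.5,
                 chloroplast2010 = runif(1) < 0.5)
    } else {
      scores <- c(chloroplast = runif(1, 0, thr / 2),
                  mitochondrion = runif(1, 0, ceil),
                  secretory = runif(1, 0, ceil / 2))
      n_tools <- sample(0:(config$min_tools - 1L), 1)
      tools <- setNames(rep("chloroplast", n_tools),
                        sample(MOTIF_POOL_TOOLS, n_tools))
      flags <- c(proteomics_msms = FALSE, chloroplast2010 = FALSE)
    }
    out[[i]] <- localization_evidence(acc, scores, tools, flags)
  }
  names(out) <- truth$accession
  out
}
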