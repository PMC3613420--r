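# A 200-aa carrier with transit 1-50, TM 100-120, N(out)-C(in), built from
# inert residues so planted signals are the only pattern hits.
make_tm_carrier <- function(plant = NULL, at = NULL, c_orientation = "in",
                            accession = "TM1") {
  chars <- rep("G", 200)
  chars[1:50] <- "S"
  chars[100:120] <- "L"
  if (!is.null(plant))
    chars[at:(at + nchar(plant) - 1L)] <- strsplit(plant, "")[[1]]
  n_orientation <- if (c_orientation == "in") "out" else "in"
  annotated_protein(accession, paste(chars, collapse = ""), transit_end = 50,
                    tm_spans = cbind(100, 120),
                    n_orientation = n_orientation,
                    c_orientation = c_orientation)
}

get_call <- function(calls, cls) {
  hits <- Filter(function(cl) cl$cargo_class == cls, calls)
  if (length(hits) == 1L) hits[[1]] else NULL
}

test_that("transmembrane cargo screening enforces the per-class placement rules", {
  # diacidic in the stromal C-tail passes
  calls <- screen_tm_cargo(make_tm_carrier("DID", 180))
  di <- get_call(calls, "tm_diacidic")
  expect_true(di$verdict)
  expect_true(all(di$filters_passed))
  expect_equal(di$matches$start[di$matches$passed], 180)

  # the same motif in the N-tail fails the stromal C-tail filter
  calls <- screen_tm_cargo(make_tm_carrier("DID", 60))
  di <- get_call(calls, "tm_diacidic")
  expect_false(di$verdict)
  expect_false(di$filters_passed[["stromal_c_tail"]])
  expect_true(di$filters_passed[["outside_transit"]])

  # lumenal C-tail fails on orientation
  calls <- screen_tm_cargo(make_tm_carrier("DID", 180, c_orientation = "out"))
  expect_false(get_call(calls, "tm_diacidic")$verdict)

  # dihydrophobic follows the same C-tail rule
  expect_true(get_call(screen_tm_cargo(make_tm_carrier("FF", 150)),
                       "tm_dihydrophobic")$verdict)

  # basic motif must sit in the N-tail near the TM span
  expect_true(get_call(screen_tm_cargo(make_tm_carrier("KK", 85)),
                       "tm_basic")$verdict)
  # inside the transit peptide it is excluded
  calls <- screen_tm_cargo(make_tm_carrier("KK", 30))
  expect_false(get_call(calls, "tm_basic")$verdict)
  # too far upstream of the TM span it fails the proximity window
  calls <- screen_tm_cargo(make_tm_carrier("KK", 55))
  expect_false(get_call(calls, "tm_basic")$verdict)

  # soluble proteins yield an empty result, not an error
  expect_length(screen_tm_cargo(annotated_protein("S1", strrep("A", 80))), 0)
})

test_that("the monobasic fallback is off by default and flagged when enabled", {
  p <- make_tm_carrier("K", 85)
  expect_null(get_call(screen_tm_cargo(p), "tm_basic"))
  calls <- screen_tm_cargo(p, screen_params(monobasic = TRUE))
  basic <- get_call(calls, "tm_basic")
  expect_true(basic$verdict)
  expect_true(all(basic$matches$flag == "monobasic"))
})

test_that("orientation-ambiguous proteins pass if either alternative passes", {
  p <- make_tm_carrier("DID", 180, c_orientation = "out")
  p$orientation_ambiguous <- TRUE
  di <- get_call(screen_tm_cargo(p), "tm_diacidic")
  expect_true(di$verdict)
  expect_true(di$orientation_ambiguous)
})

test_that("soluble ILV screening excludes only the transit peptide", {
  seq14 <- "IVSLYPVSMATALV"
  sol <- annotated_protein("S1", paste0(strrep("S", 40), seq14, strrep("G", 20)),
                           transit_end = 40)
  call <- screen_soluble_cargo(sol)
  expect_true(call$verdict)
  expect_equal(call$matches$start[call$matches$passed], 41)

  # the same 14-mer fully inside the transit peptide yields no passing match
  inside <- annotated_protein("S2", paste0(seq14, strrep("G", 40)),
                              transit_end = 20)
  call2 <- screen_soluble_cargo(inside)
  expect_false(call2$verdict)

  # with no transit annotation the bare motif string passes at 1-14
  bare <- screen_soluble_cargo(annotated_protein("S3", "IDALQIELSCTAGV"))
  expect_true(bare$verdict)
  expect_equal(c(bare$matches$start, bare$matches$end), c(1, 14))

  expect_error(screen_soluble_cargo(make_tm_carrier()), "soluble")
})

test_that("receptor screening requires GOLD-at-C with dilysine plus CRAL_TRIO", {
  rc <- screen_receptor(make_receptor_protein())
  expect_true(rc$verdict)
  expect_true(rc$has_gold_cterm)
  expect_true(rc$dilysine_in_gold)
  expect_true(rc$has_cral_trio)
  expect_true(rc$coiled_coil_nterm)
  expect_true(rc$lacks_tm)

  # GOLD in the N-terminal half fails the architecture
  rc2 <- screen_receptor(make_receptor_protein(gold_nterm = TRUE))
  expect_false(rc2$has_gold_cterm)
  expect_false(rc2$verdict)

  # missing CRAL_TRIO fails even with GOLD + dilysine
  rc3 <- screen_receptor(make_receptor_protein(cral = FALSE))
  expect_false(rc3$verdict)
  expect_true(rc3$has_gold_cterm)

  # no dilysine inside the GOLD domain fails
  rc4 <- screen_receptor(make_receptor_protein(dilysine = FALSE))
  expect_false(rc4$dilysine_in_gold)
  expect_false(rc4$verdict)
})

test_that("categorization counts distinct verdict-true accessions once", {
  cats <- read_categories(fixture_path("cargo_categories.tsv"))
  # two classes on one accession still count once
  calls <- list(
    get_call(screen_tm_cargo(make_tm_carrier("DID", 180, accession = "At1g02910")),
             "tm_diacidic"),
    get_call(screen_tm_cargo(make_tm_carrier("FF", 180, accession = "At1g02910")),
             "tm_dihydrophobic"),
    get_call(screen_tm_cargo(make_tm_carrier("DID", 180, accession = "At1g03160")),
             "tm_diacidic"))
  cc <- categorize_cargo(calls, cats)
  expect_equal(cc$total, 2)
  expect_equal(unname(cc$counts[["PSII"]]), 1)
  expect_equal(unname(cc$counts[["thylakoid_biogenesis"]]), 1)

  # empty call list: all counts zero
  empty <- categorize_cargo(list(), cats)
  expect_equal(sum(empty$counts), 0)
  expect_equal(empty$photosynthesis, 0)

  # uncategorized accessions go to 'unknown' with a warning, never dropped
  stray <- get_call(screen_tm_cargo(make_tm_carrier("DID", 180,
                                                    accession = "NOVEL1")),
                    "tm_diacidic")
  expect_warning(cc2 <- categorize_cargo(list(stray), cats), "NOVEL1")
  expect_equal(unname(cc2$counts[["unknown"]]), 1)

  # counts are invariant under input order
  cc3 <- categorize_cargo(rev(calls), cats)
  expect_equal(cc3$counts, cc$counts)
})
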