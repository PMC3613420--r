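single_span_protein <- function() {
  annotated_protein("P1", strrep("A", 200), transit_end = 50,
                    tm_spans = cbind(100, 120),
                    n_orientation = "out", c_orientation = "in")
}

test_that("region maps partition proteins into transit, tails, TMs and loops", {
  rm1 <- build_region_map(single_span_protein())
  expect_equal(rm1$label, c("transit", "n_tail", "tm", "c_tail"))
  expect_equal(rm1$start, c(1, 51, 100, 121))
  expect_equal(rm1$end, c(50, 99, 120, 200))
  expect_equal(rm1$side, c("n/a", "out", "membrane", "in"))

  # two spans, both termini stromal: the loop between them faces out
  p2 <- annotated_protein("P2", strrep("A", 300),
                          tm_spans = rbind(c(100, 120), c(150, 170)),
                          n_orientation = "in", c_orientation = "in")
  rm2 <- build_region_map(p2)
  loop <- rm2[rm2$label == "loop", ]
  expect_equal(loop$side, "out")
  expect_equal(c(loop$start, loop$end), c(121, 149))

  sol <- annotated_protein("P3", strrep("A", 100), transit_end = 40)
  rm3 <- build_region_map(sol)
  expect_equal(rm3$label, c("transit", "n_tail"))
  expect_equal(rm3$end, c(40, 100))
})

test_that("region maps tile the sequence exactly for generated proteins", {
  sim <- generate_proteome(small_config(60, 11))
  for (p in sim$annotations) {
    rmap <- build_region_map(p)
    expect_equal(sum(rmap$end - rmap$start + 1), p$length)
    expect_equal(rmap$start[1], 1)
    expect_equal(rmap$end[nrow(rmap)], p$length)
    # contiguity: each region starts where the previous one ended
    if (nrow(rmap) > 1)
      expect_equal(rmap$start[-1], rmap$end[-nrow(rmap)] + 1)
  }
})

test_that("orientation alternation is checked and the permissive mode records it", {
  # one span with equal termini orientations contradicts alternation
  bad <- annotated_protein("B1", strrep("A", 200),
                           tm_spans = cbind(100, 120),
                           n_orientation = "in", c_orientation = "in")
  expect_error(build_region_map(bad), "inconsistent topology")
  rmap <- build_region_map(bad, strict = FALSE)
  expect_false(attr(rmap, "consistent"))
  expect_equal(rmap[rmap$label == "c_tail", "side"], "in")  # trusts c_tail

  # flipping the N orientation flips every non-TM side
  p <- single_span_protein()
  flipped <- annotated_protein("P1", strrep("A", 200), transit_end = 50,
                               tm_spans = cbind(100, 120),
                               n_orientation = "in", c_orientation = "out")
  a <- build_region_map(p)
  b <- build_region_map(flipped)
  sel <- a$side %in% c("in", "out")
  expect_true(all(a$side[sel] != b$side[sel]))
})

test_that("the stromal C-tail filter checks region, side and distance", {
  regions <- build_region_map(single_span_protein())
  m <- function(s, e) data.frame(start = s, end = e)
  expect_true(motif_in_stromal_c_tail(m(195, 197), regions))
  expect_true(motif_in_stromal_c_tail(m(121, 123), regions))
  expect_false(motif_in_stromal_c_tail(m(60, 62), regions))    # n_tail
  expect_false(motif_in_stromal_c_tail(m(119, 121), regions))  # crosses TM
  # distance cap from the C-terminus
  expect_false(motif_in_stromal_c_tail(m(121, 123), regions,
                                       max_dist_from_cterm = 50))
  expect_true(motif_in_stromal_c_tail(m(195, 197), regions,
                                      max_dist_from_cterm = 5))

  # lumenal C-tail never passes
  flipped <- annotated_protein("P1", strrep("A", 200), transit_end = 50,
                               tm_spans = cbind(100, 120),
                               n_orientation = "in", c_orientation = "out")
  expect_false(motif_in_stromal_c_tail(m(195, 197),
                                       build_region_map(flipped)))
})

test_that("the N-tail window filter requires proximity to the first TM span", {
  p <- annotated_protein("P1", strrep("A", 200), transit_end = 50,
                         tm_spans = cbind(70, 90),
                         n_orientation = "in", c_orientation = "out")
  regions <- build_region_map(p)
  m <- function(s, e) data.frame(start = s, end = e)
  expect_true(motif_in_nterm_window(m(55, 56), regions, window = 25))
  expect_false(motif_in_nterm_window(m(20, 21), regions, window = 25))  # transit
  # no transit peptide, but too far from the TM span
  p2 <- annotated_protein("P2", strrep("A", 200),
                          tm_spans = cbind(70, 90),
                          n_orientation = "in", c_orientation = "out")
  expect_false(motif_in_nterm_window(m(10, 11), build_region_map(p2),
                                     window = 25))
  expect_true(motif_in_nterm_window(m(50, 51), build_region_map(p2),
                                    window = 25))
  # soluble protein has no TM span to be proximal to
  sol <- annotated_protein("P3", strrep("A", 100))
  expect_false(motif_in_nterm_window(m(50, 51), build_region_map(sol)))
})

test_that("the transit-exclusion filter uses exact overlap at the boundary", {
  p <- annotated_protein("P1", strrep("A", 100), transit_end = 40)
  regions <- build_region_map(p)
  m <- function(s, e) data.frame(start = s, end = e)
  expect_true(motif_outside_transit(m(41, 54), regions))
  expect_false(motif_outside_transit(m(40, 53), regions))  # one-residue overlap
  expect_false(motif_outside_transit(m(5, 10), regions))
  no_transit <- annotated_protein("P2", strrep("A", 100))
  expect_true(motif_outside_transit(m(1, 3), build_region_map(no_transit)))
})
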