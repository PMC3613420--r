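test_that("the decision tree follows consensus first, then tool fallback", {
  # strong consensus accepts outright
  strong <- localization_evidence("At5g63060",
                                  c(chloroplast = 18.1, mitochondrion = 4.2,
                                    secretory = 0.4))
  v <- decide_localization(strong)
  expect_true(v$accepted)
  expect_equal(v$route, "consensus")

  # weak consensus rescued by individual tools
  weak <- localization_evidence(
    "At3g52190", c(chloroplast = 7.6, secretory = 0.3),
    tool_calls = c(MultiLoc = "chloroplast", PCLR = "chloroplast",
                   SLPFA = "chloroplast", TargetP = "chloroplast"))
  v2 <- decide_localization(weak)
  expect_true(v2$accepted)
  expect_equal(v2$route, "tool_fallback")
  expect_setequal(v2$supporting_tools,
                  c("MultiLoc", "PCLR", "SLPFA", "TargetP"))

  # sub-threshold with no tool support is rejected
  none <- localization_evidence("X1", c(chloroplast = 9.9))
  v3 <- decide_localization(none)
  expect_false(v3$accepted)
  expect_equal(v3$route, "rejected")

  # non-chloroplast tool calls do not count towards the fallback
  other <- localization_evidence(
    "X2", c(chloroplast = 5),
    tool_calls = c(TargetP = "mitochondrion", ChloroP = "chloroplast"))
  expect_false(decide_localization(other)$accepted)
})

test_that("the consensus threshold is inclusive and min_tools configurable", {
  at <- localization_evidence("X1", c(chloroplast = 10))
  v <- decide_localization(at, threshold = 10)
  expect_true(v$accepted)
  expect_equal(v$route, "consensus")

  one_tool <- localization_evidence("X2", c(chloroplast = 3),
                                    tool_calls = c(TargetP = "chloroplast"))
  expect_false(decide_localization(one_tool)$accepted)
  expect_true(decide_localization(one_tool, min_tools = 1)$accepted)
})

test_that("experimental flags are reported as notes, never decisive", {
  ev <- localization_evidence("X1", c(chloroplast = 2),
                              experimental_flags = c(proteomics_msms = TRUE))
  v <- decide_localization(ev)
  expect_false(v$accepted)
  expect_match(v$evidence_notes, "proteomics_msms")
})

test_that("acceptance is monotone in chloroplast evidence", {
  set.seed(23)
  tools_pool <- c("TargetP", "ChloroP", "MultiLoc", "PCLR", "WoLFPSORT")
  for (rep in 1:50) {
    score <- runif(1, 0, 15)
    k <- sample(0:4, 1)
    tools <- setNames(rep("chloroplast", k), sample(tools_pool, k))
    ev <- localization_evidence("P", c(chloroplast = score), tools)
    v <- decide_localization(ev)
    # raising the consensus score never flips accepted -> rejected
    ev_up <- localization_evidence("P", c(chloroplast = score + runif(1, 0, 10)),
                                   tools)
    # adding one more chloroplast tool call never flips accepted -> rejected
    extra <- setdiff(tools_pool, names(tools))[1]
    ev_tool <- localization_evidence(
      "P", c(chloroplast = score),
      c(tools, setNames("chloroplast", extra)))
    if (v$accepted) {
      expect_true(decide_localization(ev_up)$accepted)
      expect_true(decide_localization(ev_tool)$accepted)
    }
    # exactly one route per verdict
    expect_true(v$route %in% c("consensus", "tool_fallback", "rejected"))
    expect_equal(v$route == "rejected", !v$accepted)
  }
})

test_that("the stand-in aggregator is a rescaled weighted mean", {
  one <- aggregate_scores(list(c(chloroplast = 1)), ceiling = 20)
  expect_equal(unname(one), c(20, 0, 0))

  two <- aggregate_scores(list(c(chloroplast = 1), c(mitochondrion = 1)),
                          ceiling = 20)
  expect_equal(unname(two), c(10, 10, 0))

  weighted <- aggregate_scores(list(c(chloroplast = 1), c(mitochondrion = 1)),
                               weights = c(2, 1), ceiling = 20)
  expect_equal(unname(weighted), c(40 / 3, 20 / 3, 0))

  expect_error(aggregate_scores(list()), "empty tool set")
  expect_error(aggregate_scores(list(c(chloroplast = 2))), "\\[0, 1\\]")
  expect_error(aggregate_scores(list(c(chloroplast = 1)), weights = 0),
               "not all zero")
})

test_that("evidence tables load scores, tool calls and flags", {
  ev <- read_evidence(fixture_path("localization_evidence.tsv"))
  expect_length(ev, 8)
  expect_equal(unname(ev$At5g63060$consensus_scores[["chloroplast"]]), 18.1)
  expect_equal(sort(names(ev$At3g52190$tool_calls)),
               c("MultiLoc", "PCLR", "SLPFA", "TargetP"))
  expect_true(ev$At4g09160$experimental_flags[["msms"]])
  expect_false(ev$At2g16380$experimental_flags[["msms"]])

  # the printed evidence reproduces the published accept/reject pattern:
  # the strong-consensus Sec14 candidate and the tool-fallback GEF pass,
  # the three receptors fail the prediction tree (their support there is
  # experimental, which is never decisive)
  verdicts <- vapply(ev, function(e) decide_localization(e)$accepted,
                     logical(1))
  expect_true(verdicts[["At5g63060"]])
  expect_true(verdicts[["At3g52190"]])
  expect_false(verdicts[["At1g72150"]])
  expect_false(verdicts[["At4g09160"]])
})
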