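test_that("pattern compilation reflects the text and round-trips canonically", {
  ilv <- compile_pattern("I-x(2)-L-x(9)-V", "ilv")
  expect_length(ilv$elements, 5)
  expect_equal(ilv$min_span, 14)
  expect_equal(ilv$max_span, 14)
  expect_false(ilv$n_anchor)

  di <- compile_pattern("[DE]-x-[DE]")
  expect_length(di$elements, 3)
  expect_equal(di$min_span, 3)

  # compiling the canonical rendering reproduces the same pattern
  for (txt in c("I-x(2)-L-x(9)-V", "[ED]-x-[DE]", "<[RK]-x(0,1)-[RK]>",
                "{P}-x(2,5)-K", "[FY](2)")) {
    p <- compile_pattern(txt)
    q <- compile_pattern(format(p))
    expect_equal(q$elements, p$elements, info = txt)
    expect_equal(format(q), format(p), info = txt)
  }
  # canonical form sorts class letters
  expect_equal(format(compile_pattern("[ED]-x-[ED]")), "[DE]-x-[DE]")
})

test_that("malformed patterns fail with the offending token and column", {
  expect_error(compile_pattern("x("), "column 2")
  expect_error(compile_pattern("[DE-x"), "unbalanced")
  expect_error(compile_pattern("[]x"), "empty class")
  expect_error(compile_pattern("A-x(3,1)"), "minimum 3 exceeds maximum 1")
  expect_error(compile_pattern("(2)A"), "no preceding element")
  expect_error(compile_pattern("A-!"), "column 3")
  expect_error(compile_pattern("[DJ]"), "J")
  expect_error(compile_pattern("-"), "no elements")
})

test_that("scanning reports all overlapping matches with 1-based coordinates", {
  pats <- builtin_patterns()
  expect_named(pats, c("diacidic", "dihydrophobic", "basic", "ilv", "dilysine"))

  hit <- scan_pattern("IDALQIELSCTAGV", pats$ilv)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 1)
  expect_equal(hit$end, 14)
  expect_equal(hit$matched_text, "IDALQIELSCTAGV")

  expect_equal(nrow(scan_pattern("AAAA", pats$diacidic)), 0)

  # all three overlapping diacidic windows of the PsbW motif string
  hits <- scan_pattern("EEDEE", pats$diacidic)
  expect_equal(hits$start, c(1, 2, 3))
  expect_equal(hits$end, c(3, 4, 5))

  # adjacent dibasic pair (zero-length spacer)
  expect_equal(nrow(scan_pattern("KK", pats$basic)), 1)
  # dilysine with one-residue spacer and two trailing wildcards
  kk <- scan_pattern("KAKLE", pats$dilysine)
  expect_true(any(kk$start == 1 & kk$end == 5))

  expect_error(scan_pattern("MKV7", pats$diacidic), "illegal residue")
  expect_error(scan_pattern("", pats$diacidic), "empty")
})

test_that("ambiguity letters are matched only by wildcards", {
  di <- builtin_patterns()$diacidic
  expect_equal(nrow(scan_pattern("DXD", di)), 1)   # X under the wildcard
  expect_equal(nrow(scan_pattern("XAD", di)), 0)   # X never satisfies [DE]
  neg <- compile_pattern("{P}-A")
  expect_equal(nrow(scan_pattern("XA", neg)), 0)   # nor a negated class
  expect_equal(nrow(scan_pattern("GA", neg)), 1)
})

test_that("anchors and windows restrict matches to the termini", {
  anchored <- compile_pattern("<[DE]-x-[DE]")
  expect_equal(scan_pattern("DADXDAD", anchored)$start, 1)
  cterm <- compile_pattern("[DE]-x-[DE]>")
  hits <- scan_pattern("DADADAD", cterm)
  expect_equal(hits$end, 7)
  # window bounds: matches may not cross them, anchors bind to window ends
  di <- builtin_patterns()$diacidic
  expect_equal(scan_pattern("DADADAD", di, window = c(3, 5))$start, 3)
  expect_error(scan_pattern("DAD", di, window = c(2, 9)), "window")
})

test_that("the scanner agrees with a brute-force regex oracle on random sequences", {
  set.seed(101)
  pats <- c(builtin_patterns(),
            list(neg = compile_pattern("{DE}-x(1,3)-[KR]"),
                 anch = compile_pattern("<A-x(0,2)-[ST]>")))
  for (rep in 1:40) {
    len <- sample(5:60, 1)
    sq <- random_aa_seq(len, pool = c(aa_standard, "X", "B"))
    for (p in pats) {
      got <- scan_pattern(sq, p)[, c("start", "end")]
      want <- oracle_scan(sq, p)
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                   info = paste(format(p), sq))
    }
  }
})

test_that("prepending residues shifts unanchored matches by exactly k", {
  set.seed(7)
  pats <- builtin_patterns()
  for (rep in 1:10) {
    sq <- random_aa_seq(40)
    k <- sample(1:10, 1)
    prefix <- random_aa_seq(k, pool = c("G", "P"))  # inert residues
    for (p in pats[c("diacidic", "ilv", "dilysine")]) {
      base <- scan_pattern(sq, p)
      shifted <- scan_pattern(paste0(prefix, sq), p)
      inside <- shifted[shifted$start > k, , drop = FALSE]
      expect_equal(inside$start, base$start + k)
      expect_equal(inside$end, base$end + k)
    }
  }
})

test_that("widening a wildcard's max repeat never removes a match", {
  set.seed(13)
  narrow <- compile_pattern("K-x(0,1)-K-x(2)")
  wide <- compile_pattern("K-x(0,3)-K-x(2,5)")
  for (rep in 1:20) {
    sq <- random_aa_seq(30, pool = c("K", "A", "S"))
    a <- scan_pattern(sq, narrow)
    b <- scan_pattern(sq, wide)
    key <- function(d) paste(d$start, d$end)
    expect_true(all(key(a) %in% key(b)), info = sq)
  }
})
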