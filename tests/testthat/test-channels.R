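test_that("SBS96 channel set has exactly 96 members in COSMIC order", {
  ch <- sbs96_channels()
  expect_length(ch, 96)
  expect_false(anyDuplicated(ch) > 0)
  expect_identical(ch[1], "A[C>A]A")
  expect_identical(ch[96], "T[T>G]T")
})

test_that("classify_sbs96 matches hand-derived examples", {
  expect_identical(classify_sbs96("C", "T", "A", "A"), "A[C>T]A")
  # G>A with flanks T,C: reverse complement -> G[C>T]A
  expect_identical(classify_sbs96("G", "A", "T", "C"), "G[C>T]A")
})

test_that("classify_sbs96 is an exhaustive 96-channel strand-symmetric map", {
  combos <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                        f5 = c("A", "C", "G", "T"), f3 = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  ch <- classify_sbs96(combos$ref, combos$alt, combos$f5, combos$f3)
  expect_length(unique(ch), 96)
  expect_setequal(unique(ch), sbs96_channels())
  # strand symmetry: the reverse-complemented record maps to the same channel
  ch_rc <- classify_sbs96(.comp[combos$ref], .comp[combos$alt],
                          .comp[combos$f3], .comp[combos$f5])
  expect_identical(unname(ch_rc), unname(ch))
  # pyrimidine-ref inputs are fixed points; purine-ref inputs map onto them
  # (involution-respecting bijection between the two strand readings)
  pyr <- combos$ref %in% c("C", "T")
  expect_identical(sum(pyr), 96L)
  expect_setequal(unique(ch[pyr]), unique(ch[!pyr]))
})

test_that("classify_sbs96 rejects invalid input", {
  expect_error(classify_sbs96("C", "C", "A", "A"))
  expect_error(classify_sbs96("C", "X", "A", "A"))
})

test_that("DBS78 channel set has exactly 78 members", {
  ch <- dbs78_channels()
  expect_length(ch, 78)
  expect_false(anyDuplicated(ch) > 0)
})

test_that("classify_dbs78 matches hand examples and collapses to 78", {
  expect_identical(classify_dbs78("CT", "AA"), "CT>AA")
  # reverse complement of AG>TT is CT>AA
  expect_identical(classify_dbs78("AG", "TT"), "CT>AA")
  bases <- c("A", "C", "G", "T")
  dbl <- as.vector(outer(bases, bases, paste0))
  pairs <- expand.grid(ref2 = dbl, alt2 = dbl, stringsAsFactors = FALSE)
  # valid DBS records differ at both positions
  ok <- substr(pairs$ref2, 1, 1) != substr(pairs$alt2, 1, 1) &
    substr(pairs$ref2, 2, 2) != substr(pairs$alt2, 2, 2)
  pairs <- pairs[ok, ]
  ch <- classify_dbs78(pairs$ref2, pairs$alt2)
  expect_length(unique(ch), 78)
  expect_setequal(unique(ch), dbs78_channels())
  # strand symmetry
  rc2 <- function(s) paste0(.comp[substr(s, 2, 2)], .comp[substr(s, 1, 1)])
  ch_rc <- classify_dbs78(rc2(pairs$ref2), rc2(pairs$alt2))
  expect_identical(unname(ch_rc), unname(ch))
})

test_that("classify_dbs78 rejects identical doublets and single-position changes", {
  expect_error(classify_dbs78("CT", "CT"))
  expect_error(classify_dbs78("CT", "CA"))
})

test_that("ID83 channel set has exactly 83 members", {
  ch <- id83_channels()
  expect_length(ch, 83)
  expect_false(anyDuplicated(ch) > 0)
  expect_identical(sum(grepl("^DEL\\.mh", ch)), 11L)
})

test_that("classify_id83 matches hand-derived examples", {
  # 1-bp deletion of T from a TTTT run (length 4): AAA TTTT G
  expect_identical(classify_id83("AT", "A", "GGGGGAAATTTTGAAAAA", 8L),
                   "DEL.T.1.4")
  # 7-bp deletion, no repeats, no microhomology -> 5+ deletion, 0 extra copies
  seq7 <- paste0(strrep("G", 42), "ACGTCAT", strrep("C", 42))
  expect_identical(classify_id83(paste0("G", "ACGTCAT"), "G", seq7, 42L),
                   "DEL.rep.5+.0")
  # insertion of C next to a single C: homopolymer length 1
  expect_identical(classify_id83("C", "CC", "GGGGGGGGCAAAAAAAA", 9L),
                   "INS.C.1.1")
})

test_that("classify_id83 requires sufficient flank", {
  expect_error(classify_id83("AT", "A", "AATG", 2L), "window|flank")
})

test_that("realize_id83 round-trips every one of the 83 channels", {
  for (ch in id83_channels()) {
    r <- realize_id83(ch)
    expect_identical(classify_id83(r$ref, r$alt, r$local_seq, r$offset), ch,
                     info = ch)
  }
})

test_that("parse_sbs96 and parse_dbs78 invert the label formats", {
  p <- parse_sbs96("G[C>T]A")
  expect_identical(unname(unlist(p)), c("G", "C", "T", "A"))
  expect_identical(classify_sbs96(p$ref, p$alt, p$flank5, p$flank3), "G[C>T]A")
  q <- parse_dbs78("CT>AA")
  expect_identical(classify_dbs78(q$ref2, q$alt2), "CT>AA")
  expect_error(parse_sbs96("notachannel"))
})

test_that("revcomp and mutation_class behave", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAG"), "CTT")
  expect_identical(mutation_class("C", "T"), "SBS")
  expect_identical(mutation_class("CT", "AA"), "DBS")
  expect_identical(mutation_class("CTT", "C"), "INDEL")
  expect_identical(mutation_class("C", "CTT"), "INDEL")
})
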