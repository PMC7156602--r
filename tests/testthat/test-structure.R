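test_that("dot-bracket parsing builds the correct pair table", {
  s <- parse_dotbracket("(((...)))", "GGGAAACCC")
  expect_identical(s$pairs, c(9L, 8L, 7L, 0L, 0L, 0L, 3L, 2L, 1L))
  expect_identical(parse_dotbracket("...", "AAA")$pairs, c(0L, 0L, 0L))
  expect_identical(parse_dotbracket("...", "aat")$seq, "AAU")

  expect_error(parse_dotbracket("(()", "GGC"), "unbalanced")
  expect_error(parse_dotbracket("())", "GGC"), "unbalanced")
  expect_error(parse_dotbracket("(((...)))", "GGGAAACC"), "length")
  expect_error(parse_dotbracket("(x.", "GGC"), "only")
  expect_error(parse_dotbracket("...", "GXC"), "outside")
})

test_that("pseudoknotted and malformed pair tables are rejected", {
  expect_error(rna_structure("x", "ACGU", c(3L, 4L, 1L, 2L)),
               "pseudoknot")
  expect_error(rna_structure("x", "ACGU", c(2L, 0L, 0L, 0L)),
               "involution")
  expect_error(rna_structure("x", "ACGU", c(1L, 0L, 0L, 0L)), "itself")
  expect_error(rna_structure("x", "ACGU", c(9L, 0L, 0L, 0L)),
               "out of range")
})

test_that("decomposition matches frozen hand-derived examples", {
  d <- decompose(parse_dotbracket("(((...)))", "GGGAAACCC"))
  expect_identical(unname(d$u_n),
                   c(1L, 1L, 0L, 0L, 0L))  # S H I B M
  expect_identical(d$u_p$S, c(1L, 2L, 3L, 7L, 8L, 9L))
  expect_identical(d$u_p$H, 4:6)

  d2 <- decompose(parse_dotbracket("((..((...))))", strrep("A", 13L)))
  expect_identical(unname(d2$u_n), c(2L, 1L, 0L, 1L, 0L))
  expect_identical(d2$u_p$B, c(3L, 4L))
  expect_identical(d2$u_p$H, 7:9)

  d3 <- decompose(parse_dotbracket(strrep(".", 9L), strrep("A", 9L)))
  expect_true(all(d3$u_n == 0L))
  expect_true(all(lengths(d3$u_p) == 0L))

  # interior loop and multibranch fixture
  d4 <- decompose(all_kinds_structure())
  expect_identical(unname(d4$u_n), c(5L, 2L, 1L, 1L, 1L))
})

test_that("exterior bases belong to no element", {
  d <- decompose(parse_dotbracket("..((...))..", strrep("A", 11L)))
  classified <- sort(unlist(d$u_p, use.names = FALSE))
  expect_identical(classified, 3:9)
})

test_that("a lone pair is a stem of length 1 and degenerate loops are kept", {
  d <- decompose(parse_dotbracket("(...)", "GAAAC"))
  expect_identical(unname(d$u_n["S"]), 1L)
  expect_identical(d$u_p$S, c(1L, 5L))
  # "()" encodes a hairpin with no unpaired bases; count it, empty positions
  d0 <- decompose(parse_dotbracket("()", "GC"))
  expect_identical(unname(d0$u_n["H"]), 1L)
  expect_length(d0$u_p$H, 0L)
})

test_that("decomposition partitions classified positions", {
  set.seed(11)
  for (rep in 1:20) {
    s <- fold_nussinov(random_seq(sample(30:70, 1L)))
    d <- decompose(s)
    paired <- which(s$pairs > 0L)
    expect_identical(d$u_p$S, paired)  # every paired base in exactly 1 stem
    loops <- c(d$u_p$H, d$u_p$I, d$u_p$B, d$u_p$M)
    expect_false(anyDuplicated(loops) > 0L)       # loop sets disjoint
    expect_length(intersect(d$u_p$S, loops), 0L)  # stems disjoint from loops
    expect_true(all(s$pairs[loops] == 0L))        # loop positions unpaired
    # determinism
    expect_identical(d, decompose(s))
  }
})

test_that("decomposition agrees with the brute-force loop classifier", {
  for (n in 1:7) {
    for (db in enum_dotbrackets(n)) expect_same_decomposition(db)
  }
})

test_that("dot-bracket files round-trip and energy annotations are ignored", {
  f <- withr::local_tempfile(fileext = ".db")
  s1 <- fold_nussinov("GGGAAACCCAAGGGAAACCC", id = "t1")
  s2 <- parse_dotbracket("...", "ACG", id = "t2")
  write_dotbracket(list(s1, s2), f)
  back <- read_dotbracket(f)
  expect_length(back, 2L)
  expect_identical(back[[1L]]$pairs, s1$pairs)
  expect_identical(back[[2L]]$id, "t2")

  writeLines(c(">e", "GGGAAACCC", "(((...))) (-1.30)"), f)
  withE <- read_dotbracket(f)[[1L]]
  expect_identical(withE$db, "(((...)))")

  writeLines(c(">bad", "GGGAAACCC"), f)
  expect_error(read_dotbracket(f), "malformed")
})

test_that("CT files round-trip and pseudoknotted CT input is rejected", {
  f <- withr::local_tempfile(fileext = ".ct")
  s <- fold_nussinov("GGGAAACCC", id = "hairpin")
  write_ct(s, f)
  back <- read_ct(f)
  expect_identical(back$pairs, s$pairs)
  expect_identical(back$seq, s$seq)

  # crossing pairs (1,3) and (2,4)
  writeLines(c("4 pk",
               "1 A 0 2 3 1", "2 C 1 3 4 2",
               "3 U 2 4 1 3", "4 G 3 0 2 4"), f)
  expect_error(read_ct(f), "pseudoknot")

  writeLines(c("9 truncated", "1 G 0 2 9 1"), f)
  expect_error(read_ct(f), "truncated")
})
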