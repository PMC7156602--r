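# stem-loop plus an A tail: mutating the last tail base to C cannot create
# a pair (no free G), so the fold is unchanged
neutral_case <- function() {
  seq <- "GGGGGAAAACCCCCAAAAAA"
  list(seq = seq,
       variant = data.frame(rsid = "rs_neutral", transcript_id = "tx",
                            position = nchar(seq), ref = "A", alt = "C",
                            stringsAsFactors = FALSE))
}

test_that("the add-one empirical rank formula is exact", {
  # observed strictly below 19 background scores -> p = 1/20
  expect_identical(empirical_pvalue(1, seq(2, 20)), 1 / 20)
  # observed at the maximum -> p = 1
  expect_identical(empirical_pvalue(10, rep(c(3, 10), 10L)), 1)
  # one background copy ties the observed minimum -> p = 2/(n+1)
  expect_identical(empirical_pvalue(2, c(2, 3:16)), 2 / 16)
  # monotone non-decreasing in the observed score
  bg <- c(1, 2, 2, 5, 7)
  p <- vapply(c(0, 1, 2, 3, 6, 8), empirical_pvalue, numeric(1L),
              background = bg)
  expect_true(all(diff(p) >= 0))
  expect_error(empirical_pvalue(1, numeric(0L)), "non-empty")
})

test_that("a variant that changes nothing gives SS = 10 and p = 1", {
  nc <- neutral_case()
  expect_identical(fold_nussinov(nc$seq)$db,
                   fold_nussinov(apply_variants(nc$seq, nc$variant))$db)
  res <- rs1(nc$seq, nc$variant, n_perm = 30L, rng_seed = 2L,
             empty_kind = "one")
  expect_identical(res$observed_SS, 10)
  expect_identical(res$p_value, 1)
})

test_that("rs1 is reproducible from its seed and validates n_perm", {
  fx <- generate_fixtures(n_transcripts = 1L, length_range = c(80L, 80L),
                          seed = 13L)
  seq <- fx$transcripts[[1L]]
  v <- fx$variants[1L, ]
  a <- rs1(seq, v, n_perm = 25L, rng_seed = 7L)
  b <- rs1(seq, v, n_perm = 25L, rng_seed = 7L)
  expect_identical(a$background, b$background)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$method, "RS1")
  expect_identical(a$n_background, 25L)
  expect_true(a$p_value > 0 && a$p_value <= 1)
  c <- rs1(seq, v, n_perm = 25L, rng_seed = 8L)
  expect_false(identical(a$background, c$background))
  expect_error(rs1(seq, v, n_perm = 0L), "n_perm")
  expect_error(rs1(seq, v[0L, ], n_perm = 5L), "at least one variant")
})

test_that("the rs1 window option restricts shuffling to the flanks", {
  fx <- generate_fixtures(n_transcripts = 1L, length_range = c(100L, 100L),
                          seed = 21L)
  seq <- fx$transcripts[[1L]]
  v <- fx$variants[1L, ]
  res <- rs1(seq, v, n_perm = 10L, rng_seed = 3L, window = 10L)
  expect_identical(res$n_background, 10L)
  # the windowed null move: everything outside the window (and the site
  # itself) is fixed, so only the 10-nt flanks may change
  win <- (v$position - 10L):(v$position + 10L)
  fixed <- setdiff(seq_len(100L), setdiff(win, v$position))
  p <- permute_nonfixed(seq, fixed, rng_seed = 5L)
  outside <- setdiff(seq_len(100L), win)
  expect_identical(substring(p, outside, outside),
                   substring(seq, outside, outside))
  expect_identical(substring(p, v$position, v$position), v$ref)
})

test_that("rs2 enumerates exactly 3N backgrounds, deterministically", {
  fx <- generate_fixtures(n_transcripts = 1L, length_range = c(60L, 60L),
                          seed = 17L)
  seq <- fx$transcripts[[1L]]
  v <- fx$variants[1L, ]
  a <- rs2(seq, v)
  expect_identical(a$method, "RS2")
  expect_identical(a$n_background, 3L * 60L)
  expect_null(a$rng_seed)
  expect_identical(a, rs2(seq, v))  # bit-identical rerun, no randomness
  expect_identical(a$p_value,
                   empirical_pvalue(a$observed_SS, a$background))
  # N = 5 -> 15 backgrounds
  short <- rs2("GCGAA", data.frame(rsid = "r", transcript_id = "t",
                                   position = 1L, ref = "G", alt = "A"))
  expect_identical(short$n_background, 15L)
  expect_error(rs2(seq, fx$variants[c(1L, 1L), ]), "single variant")
})

test_that("an unpairable sequence gives a flat rs2 background and p = 1", {
  v <- data.frame(rsid = "r", transcript_id = "t", position = 2L,
                  ref = "A", alt = "C", stringsAsFactors = FALSE)
  res <- rs2("AAAAAA", v)
  expect_identical(length(unique(res$background)), 1L)
  expect_identical(res$p_value, 1)
})

test_that("a haplotype of one SNP reduces to rs1 of that SNP", {
  fx <- generate_fixtures(n_transcripts = 1L, length_range = c(80L, 80L),
                          seed = 29L)
  seq <- fx$transcripts[[1L]]
  v <- fx$variants[1L, ]
  a <- rs1(seq, v, n_perm = 20L, rng_seed = 11L)
  b <- haplotype_effect(seq, v, n_perm = 20L, rng_seed = 11L)
  expect_identical(a$observed_SS, b$observed_SS)
  expect_identical(a$background, b$background)
  expect_identical(a$p_value, b$p_value)
})

test_that("multi-SNP haplotypes hold every site fixed in the null", {
  fx <- generate_fixtures(n_transcripts = 1L, length_range = c(120L, 120L),
                          n_snps_per_transcript = 3L, seed = 37L)
  seq <- fx$transcripts[[1L]]
  hap <- fx$variants
  res <- haplotype_effect(seq, hap, n_perm = 15L, rng_seed = 9L)
  expect_identical(res$n_background, 15L)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  mt <- apply_variants(seq, hap)
  expect_identical(sum(strsplit(mt, "")[[1L]] != strsplit(seq, "")[[1L]]),
                   3L)
  expect_error(haplotype_effect(seq, hap[0L, ], n_perm = 5L),
               "at least one variant")
})
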