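test_that("process_block hand-evaluates on a 1x1 block", {
  # H = max(0, 0+1, E, F) = 1; E = max(0-7, 0-2) = -2 (carried out as the
  # block's last-column E)
  out <- process_block(dna_seq("A"), dna_seq("A"), scoring_scheme(),
                       list(h = 0L, e = 0L))
  expect_equal(out$boundary_out$h, 1L)
  expect_equal(out$boundary_out$e, -2L)
  expect_equal(out$block_max, 1L)
  expect_equal(c(out$max_i, out$max_j), c(1L, 1L))
})

test_that("a block of pad symbols against a zero boundary stays at zero", {
  out <- process_block(dna_seq("ACGTACGT"), dna_seq("XXXX"),
                       scoring_scheme(), zero_boundary(8))
  expect_equal(out$block_max, 0L)
  expect_true(all(out$boundary_out$h == 0L))
})

test_that("boundary exchange reproduces the oracle's H and E columns at block edges", {
  set.seed(303)
  for (case in 1:8) {
    m <- sample(5:40, 1); n <- sample(8:48, 1); bw <- sample(2:6, 1)
    a <- rand_dna(m)
    b <- rand_dna(n - n %% bw)   # whole blocks only
    n <- nchar(b)
    sch <- scoring_scheme()
    ref <- sw_score_full(a, b, sch, keep_matrices = TRUE)
    bnd <- zero_boundary(m)
    for (k in seq_len(n %/% bw)) {
      blk <- substr(b, (k - 1) * bw + 1, k * bw)
      out <- process_block(dna_seq(a), dna_seq(blk), sch, bnd)
      bnd <- out$boundary_out
      expect_equal(bnd$h, unname(ref$H[-1, k * bw + 1]))
      expect_equal(bnd$e, unname(ref$E[-1, k * bw + 1]))
    }
  }
})

test_that("a boundary of the wrong length is a configuration error", {
  expect_error(process_block(dna_seq("ACGT"), dna_seq("AC"),
                             scoring_scheme(), list(h = 0L, e = 0L)),
               class = "blocksw_config_error")
})

test_that("blocked engine equals the full-matrix engine for every block width", {
  set.seed(404)
  for (case in 1:20) {
    p <- random_pair_case()
    n <- nchar(p$s2)
    full <- sw_score_full(p$s1, p$s2)
    for (bw in unique(c(1, 2, 7, 64, 256, max(1, n), n + 3))) {
      bl <- sw_score_blocked(p$s1, p$s2,
                             config = kernel_config(block_width = bw))
      expect_equal(bl$score, full$score)
      expect_equal(c(bl$max_i, bl$max_j), c(full$max_i, full$max_j))
    }
  }
})

test_that("a single block (BW >= n) degenerates to the full computation", {
  set.seed(505)
  a <- rand_dna(60); b <- rand_dna(45)
  full <- sw_score_full(a, b)
  one <- sw_score_blocked(a, b, config = kernel_config(block_width = 45))
  expect_equal(one$score, full$score)
  expect_equal(c(one$max_i, one$max_j, one$cells),
               c(full$max_i, full$max_j, 60 * 45))
})

test_that("empty sequences are handled by the blocked engine", {
  r <- sw_score_blocked("", "ACGT")
  expect_equal(c(r$score, r$max_i, r$max_j, r$cells), c(0, 0, 0, 0))
  r <- sw_score_blocked("ACGT", "")
  expect_equal(c(r$score, r$cells), c(0, 0))
})

test_that("the engine refuses runs the integer width cannot represent", {
  a <- rand_dna(200)
  err <- expect_error(
    sw_score_blocked(a, a, config = kernel_config(int_width = 8)),
    class = "blocksw_width_error")
  expect_match(conditionMessage(err), "minimum admissible integer width: 16")
  # the same pair runs fine one width up, with an identical result
  r16 <- sw_score_blocked(a, a, config = kernel_config(int_width = 16))
  expect_equal(r16$score, 200L)
})

test_that("padding with a nonnegative mismatch score is refused", {
  expect_error(
    sw_score_blocked("ACGT", "ACGTA", scoring_scheme(mismatch = 0),
                     config = kernel_config(block_width = 4)),
    class = "blocksw_param_error")
  # no padding needed: nonnegative mismatch is fine
  expect_equal(
    sw_score_blocked("ACGT", "ACGT", scoring_scheme(mismatch = 0),
                     config = kernel_config(block_width = 4))$score, 4L)
})

test_that("pad_target extends to the next multiple of the block width", {
  s <- dna_seq(rand_dna(10))
  expect_equal(pad_target(s, 4)$length, 12L)
  expect_equal(substr(pad_target(s, 4)$residues, 11, 12), "XX")
  expect_equal(substr(pad_target(s, 4)$residues, 1, 10), s$residues)
  s8 <- dna_seq(rand_dna(8))
  expect_identical(pad_target(s8, 4), s8)
  expect_equal(pad_target(dna_seq(""), 7)$length, 0L)
})
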