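test_that("random_dna is reproducible, leaves the caller RNG alone, and validates", {
  expect_equal(random_dna(0, 1)$residues, "")
  expect_identical(random_dna(10000, seed = 1)$residues,
                   random_dna(10000, seed = 1)$residues)
  expect_false(identical(random_dna(100, 1)$residues,
                         random_dna(100, 2)$residues))
  set.seed(99); before <- runif(1)
  set.seed(99); random_dna(50, 7); after <- runif(1)
  expect_identical(before, after)
  expect_error(random_dna(-1, 1), class = "blocksw_param_error")
})

test_that("base composition of a large draw is uniform within binomial bounds", {
  s <- random_dna(1e5, seed = 4)$residues
  counts <- table(strsplit(s, "")[[1]])
  expect_setequal(names(counts), c("A", "C", "G", "T"))
  # 3 sigma of Binomial(1e5, 1/4): sqrt(n p (1-p)) ~ 137
  expect_true(all(abs(counts - 25000) <= 3 * sqrt(1e5 * 0.25 * 0.75)))
})

test_that("the identity model copies exactly and self-aligns to |s| * match", {
  p <- make_pair(1000, mutation_model(seed = 5))
  expect_identical(p$reference$residues, p$mutated$residues)
  expect_equal(sw_score_blocked(p$reference, p$mutated)$score, 1000L)
})

test_that("forced substitution changes every position", {
  s <- random_dna(500, seed = 6)
  mut <- mutate_dna(s, mutation_model(substitution_rate = 1, seed = 6))
  expect_equal(mut$length, 500L)
  a <- strsplit(s$residues, "")[[1]]
  b <- strsplit(mut$residues, "")[[1]]
  expect_equal(sum(a == b), 0L)
})

test_that("indel rates change length roughly as expected and stay reproducible", {
  model <- mutation_model(substitution_rate = 0.1, insertion_rate = 0.05,
                          deletion_rate = 0.08, seed = 8)
  s <- random_dna(5000, seed = 8)
  m1 <- mutate_dna(s, model)
  expect_identical(m1$residues, mutate_dna(s, model)$residues)
  # E[length] = n (1 - p_del + p_ins) = 5000 * 0.97 = 4850, sd ~ 25
  expect_lt(abs(m1$length - 4850), 150)
})

test_that("invalid mutation rates are rejected", {
  expect_error(mutation_model(substitution_rate = 1.2),
               class = "blocksw_param_error")
  expect_error(mutation_model(substitution_rate = -0.1),
               class = "blocksw_param_error")
  expect_error(mutation_model(substitution_rate = 0.6, deletion_rate = 0.5),
               class = "blocksw_param_error")
  expect_error(mutation_model(substitution_rate = 0.5, insertion_rate = 0.4,
                              deletion_rate = 0.2),
               class = "blocksw_param_error")
})

test_that("substitution-only divergence tracks the per-column expectation", {
  # With no indels the alignment is essentially column-wise: expected
  # score per column is (1-p)*match + p*mismatch, so 2000 * (1 - 4p) at
  # +1/-3. Sanity band: 4 standard errors of the binomial column sum,
  # sd = sqrt(n * p(1-p) * (match - mismatch)^2), over 20 seeds.
  for (p in c(0.02, 0.05)) {
    scores <- vapply(1:20, function(s) {
      pr <- make_pair(2000, mutation_model(substitution_rate = p, seed = s))
      sw_score_full(pr$reference, pr$mutated)$score
    }, integer(1))
    analytic <- 2000 * (1 - 4 * p)
    se <- sqrt(2000 * p * (1 - p) * 16) / sqrt(20)
    expect_lt(abs(mean(scores) - analytic), 4 * se)
  }
})

test_that("mutated pairs score identically under blocked and full engines", {
  set.seed(31)
  pr <- make_pair(1000, mutation_model(substitution_rate = 1, seed = 31))
  full <- sw_score_full(pr$reference, pr$mutated)
  for (bw in c(1, 37, 512))
    expect_equal(sw_score_blocked(pr$reference, pr$mutated,
                                  config = kernel_config(block_width = bw))$score,
                 full$score)
})

test_that("a fixed seed gives byte-identical FASTA output", {
  p <- make_pair(300, mutation_model(substitution_rate = 0.1, seed = 12))
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(p$reference, f1)
  write_fasta(make_pair(300, mutation_model(substitution_rate = 0.1,
                                            seed = 12))$reference, f2)
  expect_identical(readLines(f1), readLines(f2))
})
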