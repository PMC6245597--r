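# Plain-R full-matrix affine-gap local alignment. Deliberately naive
# (explicit O(mn) double loop over (m+1) x (n+1) matrices with zero
# borders): the independent oracle the compiled engines are checked
# against at small sizes.
sw_oracle <- function(s1, s2, match = 1, mismatch = -3, go = 5, ge = 2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  m <- length(a); n <- length(b)
  H <- matrix(0L, m + 1, n + 1)
  E <- matrix(0L, m + 1, n + 1)
  F <- matrix(0L, m + 1, n + 1)
  acgt <- c("A", "C", "G", "T")
  best <- 0L; bi <- 0L; bj <- 0L
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sm <- if (a[i] == b[j] && a[i] %in% acgt) match else mismatch
      E[i + 1, j + 1] <- max(H[i + 1, j] - (go + ge), E[i + 1, j] - ge)
      F[i + 1, j + 1] <- max(H[i, j + 1] - (go + ge), F[i, j + 1] - ge)
      h <- max(0, H[i, j] + sm, E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  list(score = best, max_i = bi, max_j = bj, H = H, E = E, F = F)
}

rand_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent cross-check through Biostrings' local aligner (score-only).
# Clamped at 0: pairwiseAlignment reports the best single-column score
# even when negative, whereas the zero-clamped recurrence floors at 0.
biostrings_local_score <- function(a, b, match = 1, mismatch = -3,
                                   go = 5, ge = 2) {
  sm <- matrix(as.numeric(mismatch), 4, 4,
               dimnames = list(c("A", "C", "G", "T"),
                               c("A", "C", "G", "T")))
  diag(sm) <- as.numeric(match)
  s <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                     substitutionMatrix = sm,
                                     gapOpening = go, gapExtension = ge,
                                     scoreOnly = TRUE)
  max(0, s)
}

# A divergence-spanning random pair: from identical to unrelated.
random_pair_case <- function() {
  n1 <- sample(1:400, 1)
  kind <- sample(c("identical", "mutated", "unrelated"), 1,
                 prob = c(0.15, 0.6, 0.25))
  s1 <- rand_dna(n1)
  s2 <- switch(kind,
    identical = s1,
    unrelated = rand_dna(sample(1:400, 1)),
    mutated = {
      model <- mutation_model(substitution_rate = runif(1, 0, 0.5),
                              insertion_rate = runif(1, 0, 0.2),
                              deletion_rate = runif(1, 0, 0.2),
                              seed = sample.int(1e6, 1))
      mutate_dna(s1, model)$residues
    })
  list(s1 = s1, s2 = s2)
}
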