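#' Full-matrix Smith-Waterman score (reference engine)
#'
#' Computes the optimal local alignment score of `s1` against `s2` under
#' the affine-gap recurrences
#' \deqn{H_{i,j} = \max\{0,\; H_{i-1,j-1} + SM(S_1[i], S_2[j]),\; E_{i,j},\; F_{i,j}\}}
#' \deqn{E_{i,j} = \max\{H_{i,j-1} - (G_o+G_e),\; E_{i,j-1} - G_e\}}
#' \deqn{F_{i,j} = \max\{H_{i-1,j} - (G_o+G_e),\; F_{i-1,j} - G_e\}}
#' with `H`, `E` and `F` all zero on row 0 and column 0. The score is the
#' maximum of `H`; its first maximal cell in row-major order is reported
#' as `(max_i, max_j)` (1-based), or `(0, 0)` when no cell is positive.
#'
#' This is the straightforward reference engine, computed at full native
#' integer precision with no width limit: it is the oracle the blocked
#' engine ([sw_score_blocked()]) is validated against. With
#' `keep_matrices = TRUE` the complete `H`/`E`/`F` matrices (with their
#' zero borders) are attached — intended for small inputs only, as memory
#' is quadratic.
#'
#' @param s1,s2 [dna_seq()] objects or character strings.
#' @param scheme a [scoring_scheme()].
#' @param keep_matrices also return the full `H`, `E`, `F` matrices.
#' @return An object of class `sw_result`; see [sw_score_blocked()] for
#'   its fields. With `keep_matrices = TRUE` the matrices are attached as
#'   `H`, `E`, `F` ((m+1) x (n+1), including the initialisation border).
#' @examples
#' sw_score_full("ACGT", "AGT")$score   # 2: the shared substring "GT"
#' @export
sw_score_full <- function(s1, s2, scheme = scoring_scheme(),
                          keep_matrices = FALSE) {
  s1 <- as_dna_seq(s1, "s1"); s2 <- as_dna_seq(s2, "s2")
  stopifnot(inherits(scheme, "sw_scheme"))
  t0 <- proc.time()[["elapsed"]]
  raw <- cpp_sw_full(encode_residues(s1$residues), encode_residues(s2$residues),
                     scheme$match, scheme$mismatch,
                     scheme$gap_open, scheme$gap_extend, keep_matrices)
  elapsed <- proc.time()[["elapsed"]] - t0
  res <- sw_result(raw$score, raw$max_i, raw$max_j,
                   s1$length, s2$length, elapsed, scheme, config = NULL)
  if (keep_matrices) {
    res$H <- raw$H; res$E <- raw$E; res$F <- raw$F
  }
  res
}

#' Process one vertical block of the tiled score matrix
#'
#' Computes a `block_width`-column stripe of the `H`/`E`/`F` matrices row
#' by row (top to bottom, left to right) using two row buffers (for `H`
#' and `F`), taking the previous block's last-column `H` and `E` vectors
#' as the left boundary and returning this block's last column for the
#' next block. A zero boundary encodes the `j = 0` initialisation column.
#' `F` needs no boundary state because it propagates vertically within
#' the block. Storage is O(block width) plus the two boundary vectors.
#'
#' This is the kernel [sw_score_blocked()] iterates; it is exported so the
#' boundary-exchange contract can be exercised directly.
#'
#' @param s1 query [dna_seq()] (the `m` rows).
#' @param s2_block [dna_seq()] or string of exactly `block_width` residues.
#' @param scheme a [scoring_scheme()].
#' @param boundary_in list with integer vectors `h` and `e`, both of
#'   length `m`: the last-column `H` and `E` of the previous block. Zero
#'   vectors for the first block.
#' @return A list with `boundary_out` (list `h`, `e`: this block's last
#'   column), `block_max` (maximum `H` in the block, `>= 0`) and
#'   `max_i`/`max_j` (1-based position of its first maximal cell in
#'   row-major order within the block; 0/0 if the block has no positive
#'   cell).
#' @examples
#' process_block(dna_seq("A"), dna_seq("A"), scoring_scheme(),
#'               list(h = 0L, e = 0L))
#' @export
process_block <- function(s1, s2_block, scheme = scoring_scheme(),
                          boundary_in = zero_boundary(s1)) {
  s1 <- as_dna_seq(s1, "s1"); s2_block <- as_dna_seq(s2_block, "block")
  stopifnot(inherits(scheme, "sw_scheme"))
  h <- as.integer(boundary_in$h); e <- as.integer(boundary_in$e)
  if (length(h) != s1$length || length(e) != s1$length)
    stop_blocksw("config", "boundary length mismatch: boundary vectors must ",
                 "have length m = ", s1$length)
  out <- cpp_process_block(encode_residues(s1$residues),
                           encode_residues(s2_block$residues),
                           scheme$match, scheme$mismatch,
                           scheme$gap_open, scheme$gap_extend, h, e)
  list(boundary_out = list(h = out$h_out, e = out$e_out),
       block_max = out$block_max, max_i = out$max_i, max_j = out$max_j)
}

#' Zero block boundary (the j = 0 initialisation column)
#'
#' @param s1 query [dna_seq()] or its length.
#' @return A list with zero integer vectors `h` and `e` of length `m`.
#' @export
zero_boundary <- function(s1) {
  m <- if (inherits(s1, "dna_seq")) s1$length else check_len(s1, "s1")
  list(h = integer(m), e = integer(m))
}

#' Blocked Smith-Waterman score with boundary exchange
#'
#' The memory-bounded engine: the target is padded to a multiple of the
#' block width ([pad_target()]), the score matrix is divided into
#' `ceiling(n / block_width)` vertical blocks, and [process_block()] is
#' applied left to right. Two boundary buffers are kept and swapped after
#' each block — one read (the previous block's last column) and one
#' written (this block's) — so peak memory is O(m + block width)
#' regardless of `n`. The global score is the maximum over block maxima;
#' for every block width the result is identical to [sw_score_full()].
#'
#' Before running, the integer-width guard ([check_width()]) is applied:
#' if the a-priori score bound `min(m, n) * match` exceeds the configured
#' width's maximum the run is refused (a `blocksw_width_error` naming the
#' minimum admissible width) rather than risking silent overflow.
#'
#' Reported positions are in unpadded target coordinates; pad columns
#' cannot host a new maximum because the pad symbol scores `mismatch`.
#' When no cell of `H` is positive the score is 0 and the position is
#' reported as `(0, 0)`. `runtime_s` covers buffer setup, padding, the
#' blocked computation and score retrieval; `gcups` is
#' `m * n / (runtime_s * 1e9)` over the unpadded matrix.
#'
#' @param s1,s2 [dna_seq()] objects or character strings (query, target).
#' @param scheme a [scoring_scheme()].
#' @param config a [kernel_config()].
#' @return An object of class `sw_result`: a list with `score`, `max_i`,
#'   `max_j`, `m`, `n`, `cells` (`m * n`), `runtime_s`, `gcups`, and the
#'   `scheme`/`config` used.
#' @examples
#' r <- sw_score_blocked("ACGT", "AGT", config = kernel_config(block_width = 2))
#' r$score  # 2
#' @export
sw_score_blocked <- function(s1, s2, scheme = scoring_scheme(),
                             config = kernel_config()) {
  s1 <- as_dna_seq(s1, "s1"); s2 <- as_dna_seq(s2, "s2")
  stopifnot(inherits(scheme, "sw_scheme"), inherits(config, "sw_config"))
  guard <- check_width(s1$length, s2$length, scheme, config)
  if (!guard$admissible)
    stop_blocksw("width",
      sprintf(paste0("score bound %.0f exceeds the %d-bit maximum %d; ",
                     "minimum admissible integer width: %s bits"),
              guard$bound, config$int_width, guard$max_value,
              if (is.na(guard$min_width)) "none (not even 32)"
              else guard$min_width))

  m <- s1$length; n <- s2$length
  bw <- config$block_width
  if (n %% bw != 0L && scheme$mismatch >= 0L)
    stop_blocksw("param",
      "padding requires a negative mismatch score (pad columns must not ",
      "be able to host the maximum); choose mismatch < 0 or a block ",
      "width dividing n")
  t0 <- proc.time()[["elapsed"]]
  s2p <- pad_target(s2, bw)
  a <- encode_residues(s1$residues)
  b <- encode_residues(s2p$residues)
  n_blocks <- s2p$length %/% bw

  read_buf <- list(h = integer(m), e = integer(m))  # zero = j = 0 column
  best <- 0L; bi <- 0L; bj <- 0L
  for (k in seq_len(n_blocks)) {
    j0 <- (k - 1L) * bw
    out <- cpp_process_block(a, b[(j0 + 1L):(j0 + bw)],
                             scheme$match, scheme$mismatch,
                             scheme$gap_open, scheme$gap_extend,
                             read_buf$h, read_buf$e)
    gj <- j0 + out$max_j
    # keep the row-major-first global maximum: higher score, then
    # smaller i, then smaller j
    if (out$block_max > best ||
        (out$block_max == best && out$block_max > 0L &&
         (out$max_i < bi || (out$max_i == bi && gj < bj)))) {
      best <- out$block_max; bi <- out$max_i; bj <- gj
    }
    read_buf <- list(h = out$h_out, e = out$e_out)  # buffer swap
  }
  elapsed <- proc.time()[["elapsed"]] - t0

  if (best > config$max_value)  # unreachable when the guard is sound
    stop_blocksw("width", "computed score exceeds the configured width")
  if (best > 0L && bj > n)
    stop_blocksw("internal", "maximum reported in a pad column")
  sw_result(best, bi, bj, m, n, elapsed, scheme, config)
}

# Shared result constructor.
sw_result <- function(score, max_i, max_j, m, n, runtime_s, scheme, config) {
  cells <- as.numeric(m) * as.numeric(n)
  g <- if (cells == 0) 0
       else if (runtime_s > 0) gcups(m, n, runtime_s)
       else NA_real_
  structure(
    list(score = score, max_i = max_i, max_j = max_j,
         m = m, n = n, cells = cells,
         runtime_s = runtime_s, gcups = g,
         scheme = scheme, config = config),
    class = "sw_result"
  )
}

#' @export
print.sw_result <- function(x, ...) {
  cat(sprintf("<sw_result> score %d at (%d, %d); %d x %d = %s cells\n",
              x$score, x$max_i, x$max_j, x$m, x$n,
              format(x$cells, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  runtime %.4f s, %s GCUPS\n", x$runtime_s,
              if (is.na(x$gcups)) "NA" else sprintf("%.2f", x$gcups)))
  invisible(x)
}
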