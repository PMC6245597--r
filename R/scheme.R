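#' Scoring scheme for DNA local alignment
#'
#' Bundles the four parameters of the affine-gap scoring model: the
#' match and mismatch scores of the substitution function and the gap open
#' (`G_o`) and gap extension (`G_e`) penalties. A gap of length `k` costs
#' `gap_open + k * gap_extend`; both penalties are stored as nonnegative
#' magnitudes and subtracted inside the recurrences. The substitution
#' function returns `match` only for identical residues in `{A,C,G,T}`;
#' any other symbol (`N`, IUPAC ambiguity codes, the pad symbol) scores
#' `mismatch` against everything, including itself.
#'
#' The defaults are the standard DNA parameters +1 / -3 with gap open 5
#' and gap extension 2.
#'
#' @param match integer match score, must be positive.
#' @param mismatch integer mismatch score.
#' @param gap_open nonnegative integer gap-open penalty magnitude.
#' @param gap_extend nonnegative integer gap-extension penalty magnitude.
#' @return An object of class `sw_scheme`.
#' @examples
#' scoring_scheme()                      # +1/-3, gaps 5/2
#' scoring_scheme(2, -1, 10, 1)
#' @export
scoring_scheme <- function(match = 1L, mismatch = -3L,
                           gap_open = 5L, gap_extend = 2L) {
  match <- check_int(match, "match")
  mismatch <- check_int(mismatch, "mismatch")
  gap_open <- check_int(gap_open, "gap_open")
  gap_extend <- check_int(gap_extend, "gap_extend")
  if (match <= 0L)
    stop_blocksw("param", "`match` must be > 0 (got ", match, ")")
  if (gap_open < 0L || gap_extend < 0L)
    stop_blocksw("param", "gap penalties must be nonnegative magnitudes")
  structure(
    list(match = match, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "sw_scheme"
  )
}

#' @export
print.sw_scheme <- function(x, ...) {
  cat(sprintf("<sw_scheme> match %+d, mismatch %+d, gap open %d, gap extend %d\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

#' Kernel configuration: block width and integer width
#'
#' The blocked engine processes the target sequence in vertical blocks of
#' `block_width` columns; `int_width` selects the integer score range the
#' run is required to fit in (8, 16 or 32 bits), with the corresponding
#' score ceiling 127, 32767 or 2147483647. Block width affects memory
#' locality only, never the score; integer width determines which sequence
#' pairs are admissible via [check_width()].
#'
#' @param block_width positive integer number of target columns per block.
#' @param int_width one of 8, 16, 32.
#' @return An object of class `sw_config` with fields `block_width`,
#'   `int_width` and the derived `max_value`.
#' @examples
#' kernel_config()             # BW 512, 32-bit
#' kernel_config(1024, 16)$max_value  # 32767
#' @export
kernel_config <- function(block_width = 512L, int_width = 32L) {
  block_width <- check_int(block_width, "block_width")
  int_width <- check_int(int_width, "int_width")
  if (block_width < 1L)
    stop_blocksw("param", "`block_width` must be >= 1 (got ", block_width, ")")
  max_value <- switch(as.character(int_width),
    "8" = 127L, "16" = 32767L, "32" = 2147483647L,
    stop_blocksw("param", "`int_width` must be one of 8, 16, 32 (got ",
                 int_width, ")")
  )
  structure(
    list(block_width = block_width, int_width = int_width,
         max_value = max_value),
    class = "sw_config"
  )
}

#' @export
print.sw_config <- function(x, ...) {
  cat(sprintf("<sw_config> block width %d, %d-bit scores (max %d)\n",
              x$block_width, x$int_width, x$max_value))
  invisible(x)
}

#' A-priori integer-width overflow guard
#'
#' The Smith-Waterman score of an `m x n` comparison cannot exceed
#' `min(m, n) * match` (for positive `match`), so a run is admissible at a
#' given integer width exactly when that bound fits the width's maximum
#' representable value. The engine refuses inadmissible runs rather than
#' silently overflowing; `min_width` names the narrowest of 8/16/32 bits
#' that admits the bound (`NA` if even 32 bits cannot).
#'
#' @param m,n sequence lengths.
#' @param scheme a [scoring_scheme()].
#' @param config a [kernel_config()].
#' @return A list with `admissible` (logical), `bound` (the score ceiling
#'   `min(m, n) * match`), `max_value` (the width's maximum) and
#'   `min_width`.
#' @examples
#' check_width(200, 200, scoring_scheme(), kernel_config(int_width = 8))
#' @export
check_width <- function(m, n, scheme = scoring_scheme(),
                        config = kernel_config()) {
  stopifnot(inherits(scheme, "sw_scheme"), inherits(config, "sw_config"))
  m <- check_len(m, "m"); n <- check_len(n, "n")
  bound <- min(m, n) * as.numeric(scheme$match)
  widths <- c(`8` = 127, `16` = 32767, `32` = 2147483647)
  fits <- widths >= bound
  list(
    admissible = bound <= config$max_value,
    bound = bound,
    max_value = config$max_value,
    min_width = if (any(fits)) as.integer(names(widths)[which(fits)[1]]) else NA_integer_
  )
}

#' Alignment throughput in GCUPS
#'
#' Billions of cell updates per second: `(m * n) / (t * 1e9)` for an
#' `m x n` matrix computed in `t` seconds. The standard throughput metric
#' for Smith-Waterman engines.
#'
#' @param m,n sequence lengths (matrix dimensions).
#' @param t elapsed seconds, must be positive.
#' @return A single number.
#' @examples
#' gcups(1e5, 1e5, 1)  # 10 GCUPS
#' @export
gcups <- function(m, n, t) {
  m <- check_len(m, "m"); n <- check_len(n, "n")
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0)
    stop_blocksw("param", "`t` must be a positive number of seconds")
  (m / 1e9) * n / t
}

# -- internal helpers ---------------------------------------------------

check_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x))
    stop_blocksw("param", "`", name, "` must be a single integer")
  as.integer(x)
}

check_len <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != trunc(x))
    stop_blocksw("param", "`", name, "` must be a single nonnegative integer")
  as.numeric(x)
}

stop_blocksw <- function(kind, ...) {
  stop(structure(
    class = c(paste0("blocksw_", kind, "_error"), "blocksw_error",
              "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
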