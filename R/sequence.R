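# Reserved pad symbol: non-ACGT, so it scores `mismatch` against every
# residue including itself and can never raise the optimal score.
PAD_SYMBOL <- "X"

#' Construct a validated DNA sequence
#'
#' Holds an identifier and an uppercase residue string. Residues must be
#' letters; `A`, `C`, `G`, `T` score as themselves, while every other
#' letter (`N`, IUPAC ambiguity codes, the internal pad symbol `X`) is
#' treated as mismatch-to-all. Lowercase (soft-masked) input is uppercased.
#'
#' @param residues character scalar of residues (may be empty).
#' @param id identifier string.
#' @param description optional free-text description (FASTA header rest).
#' @return An object of class `dna_seq` with fields `id`, `description`,
#'   `residues` and `length`.
#' @examples
#' dna_seq("acgtn", id = "s1")
#' @export
dna_seq <- function(residues, id = "seq", description = "") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop_blocksw("param", "`residues` must be a single character string")
  residues <- toupper(residues)
  if (nzchar(residues)) {
    bad <- unique(strsplit(gsub("[A-Z]", "", residues), "")[[1]])
    if (length(bad))
      stop_blocksw("residue", "illegal residue character(s): ",
                   paste(sQuote(bad), collapse = ", "),
                   " (only letters are accepted)")
  }
  structure(
    list(id = as.character(id), description = as.character(description),
         residues = residues, length = nchar(residues)),
    class = "dna_seq"
  )
}

#' @export
print.dna_seq <- function(x, ...) {
  preview <- if (x$length > 60L) paste0(substr(x$residues, 1L, 57L), "...")
             else x$residues
  cat(sprintf("<dna_seq> %s (%d nt) %s\n", x$id, x$length, preview))
  invisible(x)
}

#' @export
format.dna_seq <- function(x, ...) x$residues

#' Pad the target sequence to a multiple of the block width
#'
#' Extends the target with pad symbols so its length becomes the smallest
#' multiple of `block_width` that is at least the current length. The pad
#' symbol scores `mismatch` against every residue, so for a negative
#' mismatch score the padding provably cannot change the optimal score or
#' its position; [sw_score_blocked()] relies on this to process the target
#' in whole blocks.
#'
#' @param s2 a [dna_seq()] (the target sequence).
#' @param block_width positive integer block width.
#' @return A `dna_seq` of padded length; unchanged if already a multiple.
#' @examples
#' pad_target(dna_seq("ACGTACGTAC"), 4)$length  # 12
#' @export
pad_target <- function(s2, block_width) {
  stopifnot(inherits(s2, "dna_seq"))
  block_width <- check_int(block_width, "block_width")
  if (block_width < 1L)
    stop_blocksw("param", "`block_width` must be >= 1")
  pad <- (block_width - s2$length %% block_width) %% block_width
  if (pad == 0L) return(s2)
  out <- s2
  out$residues <- paste0(s2$residues, strrep(PAD_SYMBOL, pad))
  out$length <- nchar(out$residues)
  out
}

# Coerce character input to dna_seq where convenient.
as_dna_seq <- function(x, id = "seq") {
  if (inherits(x, "dna_seq")) x else dna_seq(x, id = id)
}
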