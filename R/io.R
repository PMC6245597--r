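#' Read one sequence from a FASTA file
#'
#' Parses a (possibly multi-record, multi-line) FASTA file and returns one
#' record as a validated [dna_seq()]. The record id is the header token up
#' to the first whitespace; the remainder of the header line is kept as
#' the description. Sequence bodies wrapped over several lines are
#' concatenated and blank lines are ignored; residues are uppercased.
#' `*` and `-` characters are rejected rather than silently dropped —
#' gapped or translated input almost always signals an upstream mistake.
#'
#' @param path path to a FASTA file.
#' @param record_id optional id of the record to select; by default the
#'   first record is used (one pair is aligned per run).
#' @return A [dna_seq()].
#' @section Errors: distinct conditions are signalled for a missing file
#'   (`blocksw_io_error`), a malformed header (`blocksw_parse_error`), an
#'   unknown `record_id` (`blocksw_lookup_error`) and illegal residue
#'   characters (`blocksw_residue_error`).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "ACGT", "ACGT"), tf)
#' read_fasta(tf)$length  # 8
#' @export
read_fasta <- function(path, record_id = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_blocksw("io", "FASTA file not found: ", path)
  recs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_blocksw("parse", "malformed FASTA in ", path,
                                     ": ", conditionMessage(e))
  )
  if (length(recs) == 0L)
    stop_blocksw("parse", "no FASTA records in ", path)
  headers <- names(recs)
  ids <- sub("\\s.*$", "", headers)
  idx <- 1L
  if (!is.null(record_id)) {
    idx <- match(record_id, ids)
    if (is.na(idx))
      stop_blocksw("lookup", "no record with id ", sQuote(record_id),
                   " in ", path, " (found: ",
                   paste(utils::head(ids, 5L), collapse = ", "), ")")
  }
  residues <- as.character(recs[[idx]])
  if (grepl("[*-]", residues))
    stop_blocksw("residue", "record ", sQuote(ids[idx]),
                 " contains '*' or '-' characters; gapped/translated ",
                 "input is not accepted")
  if (grepl("[^A-Za-z]", residues))
    stop_blocksw("residue", "record ", sQuote(ids[idx]),
                 " contains characters outside [A-Za-z*-]")
  desc <- sub("^\\S+\\s*", "", headers[idx])
  dna_seq(residues, id = ids[idx], description = desc)
}

#' Write sequences to a FASTA file
#'
#' @param seqs a [dna_seq()] or list of them.
#' @param path output path.
#' @param width line-wrap width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  headers <- vapply(seqs, function(s) {
    if (nzchar(s$description)) paste(s$id, s$description) else s$id
  }, character(1))
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, character(1), "residues"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Serialise an alignment result
#'
#' Emits the score, its position, the matrix dimensions, runtime, GCUPS
#' and all run parameters as a single flat record: either a two-line TSV
#' (header + one row) or a flat JSON object. GCUPS is reported with two
#' decimals in both formats; all other numbers keep full precision.
#'
#' @param result an `sw_result` from [sw_score_blocked()] or
#'   [sw_score_full()].
#' @param format `"tsv"` or `"json"`.
#' @return A character scalar (the serialised text).
#' @examples
#' r <- sw_score_blocked("ACGT", "ACGT")
#' cat(write_result(r, "tsv"))
#' @export
write_result <- function(result, format = c("tsv", "json")) {
  stopifnot(inherits(result, "sw_result"))
  format <- match.arg(format)
  scheme <- result$scheme %||% scoring_scheme()
  config <- result$config
  rec <- list(
    score = result$score, max_i = result$max_i, max_j = result$max_j,
    m = result$m, n = result$n, cells = result$cells,
    runtime_s = result$runtime_s,
    gcups = if (is.na(result$gcups)) NA_real_ else round(result$gcups, 2),
    match = scheme$match, mismatch = scheme$mismatch,
    gap_open = scheme$gap_open, gap_extend = scheme$gap_extend,
    block_width = if (is.null(config)) NA_integer_ else config$block_width,
    int_width = if (is.null(config)) NA_integer_ else config$int_width
  )
  if (format == "json")
    return(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                         digits = NA, na = "null")))
  fmt1 <- function(v, name) {
    if (is.na(v)) return("NA")
    if (name == "gcups") return(sprintf("%.2f", v))
    if (is.numeric(v) && v == trunc(v) && abs(v) < 2^53)
      format(v, scientific = FALSE) else format(v, digits = 15)
  }
  paste0(paste(names(rec), collapse = "\t"), "\n",
         paste(mapply(fmt1, rec, names(rec)), collapse = "\t"), "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
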