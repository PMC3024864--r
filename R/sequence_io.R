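#' Normalize a nucleotide sequence into the RNA alphabet
#'
#' Uppercases the input and maps T to U. Any character outside
#' \{A, C, G, U, T, a, c, g, u, t\} — including IUPAC ambiguity codes such
#' as N or R — is rejected, because every downstream feature is a
#' deterministic function of the sequence and random resolution would
#' break reproducibility.
#'
#' @param raw Character scalar, the raw sequence.
#' @return Character scalar over \{A, C, G, U\}.
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  up <- chartr("t", "u", toupper(raw))
  up <- chartr("T", "U", up)
  chars <- strsplit(up, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid alphabet: character '%s' at position %d (only A/C/G/U/T allowed)",
      chars[bad[1]], bad[1]
    ), call. = FALSE)
  }
  up
}

#' Create a sequence record
#'
#' A sequence record is an identifier plus a normalized RNA sequence; it is
#' the unit of input to the folding engine and the feature extractor.
#'
#' @param id Character scalar identifier (FASTA header token).
#' @param seq Character scalar; normalized via [normalize_sequence()].
#' @return An object of class `sequence_record` with fields `id`, `seq`
#'   and `length`.
#' @export
sequence_record <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- normalize_sequence(seq)
  if (nchar(seq) < 1L) stop("empty sequence in record '", id, "'", call. = FALSE)
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d nt)\n", x$id, x$length))
  invisible(x)
}

as_sequence_record <- function(x, id = "seq") {
  if (inherits(x, "sequence_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(sequence_record(id, x))
  stop("expected a sequence_record or a single character string", call. = FALSE)
}

#' Read a FASTA file into a list of sequence records
#'
#' Sequences are normalized into the RNA alphabet (T mapped to U); any
#' ambiguity code raises an error. Gzipped files are read transparently.
#' Record order is preserved.
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return List of [sequence_record()] objects (empty list for an empty
#'   file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- names(set)
  if (is.null(ids)) ids <- as.character(seq_along(set))
  ids <- vapply(strsplit(ids, "[ \t]"), `[`, character(1), 1L)
  seqs <- unname(as.character(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    if (nchar(seqs[i]) == 0L)
      stop("empty sequence body for record '", ids[i], "' in '", path, "'",
           call. = FALSE)
    out[[i]] <- sequence_record(ids[i], seqs[i])
  }
  out
}

#' Write sequence records to a FASTA file
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param records List of [sequence_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- lapply(records, as_sequence_record)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(paste0(">", rec$id), con)
    starts <- seq(1L, rec$length, by = 60L)
    writeLines(substring(rec$seq, starts, pmin(starts + 59L, rec$length)), con)
  }
  invisible(path)
}
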