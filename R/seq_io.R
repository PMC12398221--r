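# Sequence and alignment I/O. All coordinates in the package are 1-based and
# inclusive on both ends; conversion to 0-based offsets never leaves this file.

#' Allowed amino-acid alphabet
#'
#' The 20 standard residues plus `X` for an unknown residue. `X` is accepted
#' in sequences but never satisfies any consensus position (see
#' [lir_consensus()]).
#'
#' @return Character vector of 21 single-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
}

#' Create a sequence record
#'
#' @param id Unique identifier (non-empty string).
#' @param residues Amino-acid string; lower case is normalized to upper case.
#'   Only the 21-letter alphabet of [aa_alphabet()] is allowed; `-` is
#'   forbidden in a plain sequence (use [read_alignment()] for gapped input).
#' @param description Free-text description, defaults to `""`.
#' @return An object of class `seq_record` with fields `id`, `description`
#'   and `residues`.
#' @examples
#' rec <- seq_record("s1", "wvfv")
#' rec$residues  # "WVFV"
#' @export
seq_record <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) {
    stop("seq_record: residues must be non-empty for '", id, "'")
  }
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), aa_alphabet())
  if (length(bad) > 0L) {
    stop("seq_record: illegal residue character(s) ",
         paste(sQuote(bad), collapse = ", "), " in '", id, "'")
  }
  structure(list(id = id, description = description, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d aa)%s\n", x$id, nchar(x$residues),
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

#' Length of a sequence record
#' @param x A `seq_record` or `aln_record`.
#' @export
seq_length <- function(x) nchar(x$residues)

# Internal: gapped record used by alignments. Same fields as seq_record but
# '-' is allowed.
aln_record <- function(id, residues, description = "") {
  residues <- toupper(as.character(residues))
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), c(aa_alphabet(), "-"))
  if (length(bad) > 0L) {
    stop("aln_record: illegal character(s) ",
         paste(sQuote(bad), collapse = ", "), " in '", id, "'")
  }
  structure(list(id = id, description = description, residues = residues),
            class = c("aln_record", "seq_record"))
}

# Internal: locate the file line of the first illegal character so parse
# errors are actionable. Only called on the failure path.
.fasta_error_line <- function(path, allowed) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- sub("\r$", "", lines[i])
    if (startsWith(ln, ">") || !nzchar(ln)) next
    chars <- unique(strsplit(toupper(ln), "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0L) {
      return(list(line = i, char = bad[1]))
    }
  }
  list(line = NA_integer_, char = NA_character_)
}

# Internal: shared FASTA reader; `gapped` switches the allowed alphabet.
.read_fasta_impl <- function(path, gapped) {
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  allowed <- if (gapped) c(aa_alphabet(), "-") else aa_alphabet()
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop("read_fasta: cannot parse '", path, "': ", conditionMessage(e))
    }
  )
  if (length(set) == 0L) {
    warning("read_fasta: no records in '", path, "'")
    return(list())
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop("read_fasta: empty header in '", path, "'")
  }
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicate id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  residues <- toupper(as.character(set))
  for (k in seq_along(residues)) {
    bad <- setdiff(unique(strsplit(residues[k], "")[[1]]), allowed)
    if (length(bad) > 0L) {
      where <- .fasta_error_line(path, allowed)
      stop(sprintf(
        "read_fasta: illegal residue character %s in record '%s' (%s line %s)",
        sQuote(bad[1]), ids[k], path,
        ifelse(is.na(where$line), "?", where$line)))
    }
  }
  maker <- if (gapped) aln_record else seq_record
  recs <- mapply(maker, ids, residues, desc, SIMPLIFY = FALSE)
  names(recs) <- ids
  recs
}

#' Read protein sequences from a FASTA file
#'
#' CRLF line endings are tolerated and residues are uppercased. An illegal
#' residue character aborts with an error naming the offending record and
#' file line.
#'
#' @param path Path to a FASTA file.
#' @return A named list of [seq_record()] objects (possibly empty, with a
#'   warning, for an empty file).
#' @seealso [read_alignment()] for gapped (aligned) FASTA.
#' @export
read_fasta <- function(path) .read_fasta_impl(path, gapped = FALSE)

#' Read a protein multiple sequence alignment from aligned FASTA
#'
#' Like [read_fasta()] but records may contain `-` gap characters and all
#' records must have identical length (the alignment column count).
#'
#' @param path Path to an aligned FASTA file.
#' @return A named list of gapped records (class `aln_record`).
#' @export
read_alignment <- function(path) {
  recs <- .read_fasta_impl(path, gapped = TRUE)
  if (length(recs) > 0L) {
    widths <- vapply(recs, seq_length, integer(1))
    if (length(unique(widths)) != 1L) {
      stop("read_alignment: records differ in length (",
           paste(range(widths), collapse = "-"),
           "); not a valid alignment")
    }
  }
  recs
}

#' Write sequence records to FASTA
#'
#' @param records A list of `seq_record`/`aln_record` objects (or a single
#'   record).
#' @param path Output path.
#' @param width Line-wrap width, default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  headers <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "residues"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Extract a subsequence by 1-based inclusive coordinates
#'
#' @param rec A `seq_record`, or a plain residue string.
#' @param start,end 1-based positions, both inclusive
#'   (`start = end` yields one residue).
#' @return The residue string of length `end - start + 1`.
#' @examples
#' rec <- seq_record("s", "DEELQWVFV")
#' subsequence(rec, 6, 9)  # "WVFV"
#' @export
subsequence <- function(rec, start, end) {
  residues <- if (inherits(rec, "seq_record")) rec$residues else
    toupper(as.character(rec))
  n <- nchar(residues)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end > n || start > end) {
    stop(sprintf("subsequence: range [%s, %s] out of bounds for length %d",
                 start, end, n))
  }
  substr(residues, start, end)
}

#' Path to the bundled human sigma-1 receptor sequence
#'
#' The 223-residue human sigma-1 receptor (UniProt Q99524), an ER/MAM
#' membrane protein used as the package's worked example.
#'
#' @return File path of the bundled FASTA fixture.
#' @export
sigma1r_fasta <- function() {
  system.file("extdata", "sigma1r_human.fasta", package = "lirtriage",
              mustWork = TRUE)
}

#' Load the bundled human sigma-1 receptor record
#'
#' @return A single [seq_record()] of 223 residues.
#' @examples
#' rec <- sigma1r_sequence()
#' subsequence(rec, 81, 84)  # "WVFV"
#' @export
sigma1r_sequence <- function() {
  read_fasta(sigma1r_fasta())[[1]]
}
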