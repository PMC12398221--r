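# Consensus scanning for LIR / GIM cores, flank extraction and scoring,
# point mutations, and the heuristic ATG8-paralog preference.
#
# A LIR core is four residues Theta-X1-X2-Gamma. The canonical consensus is
# [W/F/Y]-X-X-[L/V/I]; the GABARAP interaction motif (GIM) restricts it to
# [W/F]-[V/I]-X-V. Flank windows follow the X-5..X-1 / X4..X10 convention:
# five residues N-terminal of Theta and seven C-terminal of Gamma, truncated
# (never padded) at the sequence termini.

.STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The six human ATG8 paralogs
#' @return Character vector: LC3 subfamily then GABARAP subfamily.
#' @export
atg8_paralogs <- function() {
  c("LC3A", "LC3B", "LC3C", "GABARAP", "GABARAPL1", "GABARAPL2")
}

#' Build a four-position consensus definition
#'
#' @param name Label for the consensus.
#' @param position_sets List of exactly four character vectors of allowed
#'   residues (Theta, X1, X2, Gamma). Use the full 20-letter standard set for
#'   a wildcard position; `X` (unknown residue) never matches any position.
#' @return An object of class `consensus_def`.
#' @seealso [lir_consensus()] for the built-in canonical and GIM definitions.
#' @export
consensus_definition <- function(name, position_sets) {
  stopifnot(is.character(name), length(position_sets) == 4L)
  position_sets <- lapply(position_sets, function(s) {
    s <- toupper(as.character(s))
    bad <- setdiff(s, .STANDARD_AA)
    if (length(s) == 0L || length(bad) > 0L) {
      stop("consensus_definition: each position set must be a non-empty ",
           "subset of the 20 standard residues")
    }
    sort(unique(s))
  })
  structure(list(name = name, position_sets = position_sets),
            class = "consensus_def")
}

#' Built-in LIR consensus definitions
#'
#' `"canonical"` is the canonical LIR core \[W/F/Y\]-X-X-\[L/V/I\];
#' `"gim"` is the GABARAP interaction motif \[W/F\]-\[V/I\]-X-V. Every GIM
#' position set is a subset of the corresponding canonical set, so every GIM
#' match is also a canonical match.
#'
#' @param name `"canonical"` or `"gim"`.
#' @return A [consensus_definition()] object.
#' @export
lir_consensus <- function(name = c("canonical", "gim")) {
  name <- match.arg(name)
  switch(name,
    canonical = consensus_definition("canonical", list(
      c("W", "F", "Y"), .STANDARD_AA, .STANDARD_AA, c("L", "V", "I"))),
    gim = consensus_definition("gim", list(
      c("W", "F"), c("V", "I"), .STANDARD_AA, "V"))
  )
}

#' Read a custom consensus definition from YAML
#'
#' The file must contain `name` and `position_sets`, a list of four
#' residue-string vectors (e.g. `["W","F"]` or the string `"any"` for the
#' 20-residue wildcard).
#'
#' @param path Path to a YAML file.
#' @return A [consensus_definition()] object.
#' @export
read_consensus_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name) || is.null(cfg$position_sets) ||
      length(cfg$position_sets) != 4L) {
    stop("read_consensus_yaml: file must define 'name' and four ",
         "'position_sets'")
  }
  sets <- lapply(cfg$position_sets, function(s) {
    if (identical(tolower(paste(s, collapse = "")), "any")) .STANDARD_AA
    else unlist(strsplit(as.character(s), ""))
  })
  consensus_definition(cfg$name, sets)
}

# Internal: does a 4-residue core match a consensus? 'X' fails every
# position set by construction (sets contain standard residues only).
.matches_consensus <- function(core, consensus) {
  res <- strsplit(core, "")[[1]]
  if (length(res) != 4L) return(FALSE)
  all(vapply(1:4, function(i) res[i] %in% consensus$position_sets[[i]],
             logical(1)))
}

#' Test whether a core matches the GABARAP interaction motif
#'
#' A match means consensus compatibility only, never a binding prediction:
#' experimentally, GIM-compatible cores can still fail to bind (the
#' consensus is necessary, not sufficient).
#'
#' @param core A 4-residue string.
#' @return `TRUE` iff `core` matches \[W/F\]-\[V/I\]-X-V. Non-standard
#'   residues (including `X`) never match.
#' @examples
#' classify_gim("WVFV")  # TRUE
#' classify_gim("WVFL")  # FALSE: Gamma must be V
#' classify_gim("WVLV")  # TRUE:  X2 is unconstrained
#' @export
classify_gim <- function(core) {
  stopifnot(is.character(core), length(core) == 1L)
  if (nchar(core) != 4L) stop("classify_gim: core must have 4 residues")
  .matches_consensus(toupper(core), lir_consensus("gim"))
}

#' Test whether a core matches the canonical LIR consensus
#' @inheritParams classify_gim
#' @return `TRUE` iff `core` matches \[W/F/Y\]-X-X-\[L/V/I\].
#' @export
classify_canonical <- function(core) {
  stopifnot(is.character(core), length(core) == 1L)
  if (nchar(core) != 4L) stop("classify_canonical: core must have 4 residues")
  .matches_consensus(toupper(core), lir_consensus("canonical"))
}

# Internal: D/E and S/T counts for one flank string.
.count_flank <- function(flank, set) {
  if (!nzchar(flank)) return(0L)
  sum(strsplit(flank, "")[[1]] %in% set)
}

#' Score flanking windows for acidic and phosphorylatable residues
#'
#' Acidic residues (D/E) or potential phosphorylation targets (S/T) in the
#' flanks enhance LIR affinity; the score is a plain count per window, with
#' no positional weighting.
#'
#' @param n_flank,c_flank Flank strings (possibly empty).
#' @return Named integer vector `n_acidic`, `n_phospho`, `c_acidic`,
#'   `c_phospho`.
#' @export
score_flanks <- function(n_flank, c_flank) {
  c(n_acidic = .count_flank(n_flank, c("D", "E")),
    n_phospho = .count_flank(n_flank, c("S", "T")),
    c_acidic = .count_flank(c_flank, c("D", "E")),
    c_phospho = .count_flank(c_flank, c("S", "T")))
}

#' Exhaustively scan a protein for consensus LIR cores
#'
#' Every window of four residues is tested against the consensus;
#' overlapping and adjacent matches are all reported (no merging). For each
#' hit, membership in both built-in classes (canonical, GIM) is recorded and
#' the flank windows X-5..X-1 and X4..X10 are extracted and scored.
#'
#' @param rec A [seq_record()] (or plain residue string, scanned under
#'   id `"seq"`).
#' @param consensus A [consensus_definition()]; default canonical LIR.
#' @return A data.frame of class `motif_hits`, one row per hit sorted by
#'   `start`, with columns `protein_id`, `motif_id`, `start`, `end`, `core`,
#'   `is_canonical`, `is_gim`, `classes`, `n_flank`, `c_flank`, `n_acidic`,
#'   `n_phospho`, `c_acidic`, `c_phospho`. Motif ids are `LIR1`, `LIR2`, ...
#'   in sequence order. A sequence shorter than 4 residues yields zero rows
#'   with a warning.
#' @examples
#' hits <- scan_motifs(sigma1r_sequence())
#' hits[hits$is_gim, c("motif_id", "start", "core", "n_flank")]
#' @export
scan_motifs <- function(rec, consensus = lir_consensus("canonical")) {
  if (!inherits(rec, "seq_record")) rec <- seq_record("seq", rec)
  stopifnot(inherits(consensus, "consensus_def"))
  n <- seq_length(rec)
  empty <- data.frame(
    protein_id = character(0), motif_id = character(0),
    start = integer(0), end = integer(0), core = character(0),
    is_canonical = logical(0), is_gim = logical(0), classes = character(0),
    n_flank = character(0), c_flank = character(0),
    n_acidic = integer(0), n_phospho = integer(0),
    c_acidic = integer(0), c_phospho = integer(0),
    stringsAsFactors = FALSE)
  class(empty) <- c("motif_hits", "data.frame")
  if (n < 4L) {
    warning("scan_motifs: sequence '", rec$id, "' shorter than 4 residues")
    return(empty)
  }
  res <- strsplit(rec$residues, "")[[1]]
  sets <- consensus$position_sets
  ok <- vapply(seq_len(n - 3L), function(s) {
    res[s] %in% sets[[1]] && res[s + 1L] %in% sets[[2]] &&
      res[s + 2L] %in% sets[[3]] && res[s + 3L] %in% sets[[4]]
  }, logical(1))
  starts <- which(ok)
  if (length(starts) == 0L) return(empty)
  rows <- lapply(seq_along(starts), function(k) {
    s <- starts[k]; e <- s + 3L
    core <- substr(rec$residues, s, e)
    n_fl <- substr(rec$residues, max(1L, s - 5L), s - 1L)
    c_fl <- substr(rec$residues, e + 1L, min(n, e + 7L))
    can <- classify_canonical(core)
    gim <- classify_gim(core)
    fs <- score_flanks(n_fl, c_fl)
    data.frame(
      protein_id = rec$id, motif_id = paste0("LIR", k),
      start = s, end = e, core = core,
      is_canonical = can, is_gim = gim,
      classes = paste(c(if (can) "canonical", if (gim) "GIM"),
                      collapse = ","),
      n_flank = n_fl, c_flank = c_fl,
      n_acidic = fs[["n_acidic"]], n_phospho = fs[["n_phospho"]],
      c_acidic = fs[["c_acidic"]], c_phospho = fs[["c_phospho"]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Apply a single point mutation to a sequence
#'
#' Returns a modified copy; the input record is untouched. The mutated
#' record id gains a `_<from><pos><to>` suffix unless the mutation is an
#' identity substitution.
#'
#' @param rec A [seq_record()].
#' @param position 1-based residue position.
#' @param new_residue One of the 20 standard residues (or `X`).
#' @return A new [seq_record()].
#' @examples
#' mut <- apply_point_mutation(sigma1r_sequence(), 81, "A")  # W81A
#' subsequence(mut, 81, 84)  # "AVFV"
#' @export
apply_point_mutation <- function(rec, position, new_residue) {
  stopifnot(inherits(rec, "seq_record"))
  position <- as.integer(position)
  new_residue <- toupper(as.character(new_residue))
  if (is.na(position) || position < 1L || position > seq_length(rec)) {
    stop("apply_point_mutation: position ", position,
         " out of range 1..", seq_length(rec))
  }
  if (nchar(new_residue) != 1L || !(new_residue %in% aa_alphabet())) {
    stop("apply_point_mutation: illegal residue '", new_residue, "'")
  }
  old <- substr(rec$residues, position, position)
  if (old == new_residue) return(rec)
  residues <- rec$residues
  substr(residues, position, position) <- new_residue
  seq_record(paste0(rec$id, "_", old, position, new_residue), residues,
             rec$description)
}

#' Heuristic ATG8-paralog preference for a motif hit
#'
#' Without position-weight tables the prediction is deliberately coarse:
#' a GIM-compatible core puts the GABARAP subfamily ahead of the LC3
#' subfamily; a canonical-only core is an unranked six-way tie flagged
#' `"indeterminate"`. With `pssm_set`, paralogs are ranked by the log-odds
#' sum over the 16-position window (5 N-flank + 4 core + 7 C-flank),
#' skipping truncated flank positions.
#'
#' @param hit A single row of a [scan_motifs()] result (data.frame or list
#'   with fields `core`, `is_gim`, `n_flank`, `c_flank`).
#' @param pssm_set Optional named list, one 20 x 16 numeric matrix per
#'   paralog (rownames = standard residues, columns = window positions).
#' @return A data.frame `paralog`, `score`, `rank`, plus attribute
#'   `"status"`: `"gim-heuristic"`, `"indeterminate"` or `"pssm"`.
#' @export
predict_paralog_preference <- function(hit, pssm_set = NULL) {
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1L)
    hit <- as.list(hit)
  }
  paralogs <- atg8_paralogs()
  if (is.null(pssm_set)) {
    if (isTRUE(hit$is_gim)) {
      order <- c("GABARAP", "GABARAPL1", "GABARAPL2", "LC3A", "LC3B", "LC3C")
      out <- data.frame(paralog = order, score = NA_real_,
                        rank = c(1L, 1L, 1L, 4L, 4L, 4L),
                        stringsAsFactors = FALSE)
      attr(out, "status") <- "gim-heuristic"
    } else {
      out <- data.frame(paralog = paralogs, score = NA_real_, rank = 1L,
                        stringsAsFactors = FALSE)
      attr(out, "status") <- "indeterminate"
    }
    return(out)
  }
  window <- strsplit(paste0(hit$n_flank, hit$core, hit$c_flank), "")[[1]]
  # position of the first window residue within the canonical 16-slot frame
  offset <- 5L - nchar(hit$n_flank)
  scores <- vapply(names(pssm_set), function(p) {
    m <- pssm_set[[p]]
    if (!is.matrix(m) || ncol(m) != 16L ||
        !all(window %in% c(rownames(m), "X"))) {
      stop("predict_paralog_preference: malformed weight table for '", p, "'")
    }
    sum(vapply(seq_along(window), function(i) {
      r <- window[i]
      if (r == "X") 0 else m[r, offset + i]
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-scores, names(scores))
  out <- data.frame(paralog = names(scores)[ord], score = scores[ord],
                    rank = rank(-scores, ties.method = "min")[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "status") <- "pssm"
  out
}

#' Write motif hits to TSV
#'
#' @param hits A `motif_hits` data.frame from [scan_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read motif hits from TSV
#' @param path Path to a TSV written by [write_hits_tsv()].
#' @return A `motif_hits` data.frame.
#' @export
read_hits_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(
                             protein_id = "character", motif_id = "character",
                             core = "character", classes = "character",
                             n_flank = "character", c_flank = "character"),
                           stringsAsFactors = FALSE)
  # flanks may be empty strings
  for (col in c("n_flank", "c_flank", "classes")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  class(out) <- c("motif_hits", "data.frame")
  out
}
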