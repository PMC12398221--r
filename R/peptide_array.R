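# SPOT peptide-array tiling design, spot-to-motif mapping, and run-rule
# interaction calling. The reference scheme tiles a protein in 15-mers at a
# 3-residue offset; consecutive grid spots then overlap by 12 residues, and
# a 4-residue core is fully contained in at most floor((15-4)/3)+1 = 4
# consecutive spots.

#' Design an overlapping peptide tiling of a protein
#'
#' Regular-grid spots start at 1, 1+k, 1+2k, ... while they fit; if the last
#' grid spot does not reach the C-terminus and `include_terminal` is `TRUE`
#' (default), one extra spot anchored at the C-terminus is appended so every
#' residue is covered.
#'
#' @param rec A [seq_record()] (or plain residue string).
#' @param L Peptide (window) length in residues, default 15.
#' @param k Offset between consecutive spots, default 3.
#' @param include_terminal Append a C-terminal anchor spot when needed?
#' @return An object of class `tiling_design`: list with `protein_id`, `L`,
#'   `k` and `spots`, a data.frame (`index`, `start`, `end`, `peptide`,
#'   `terminal`).
#' @examples
#' design <- design_tiling(sigma1r_sequence())
#' nrow(design$spots)  # 71: 70 grid spots + 1 terminal spot
#' @export
design_tiling <- function(rec, L = 15L, k = 3L, include_terminal = TRUE) {
  if (!inherits(rec, "seq_record")) rec <- seq_record("seq", rec)
  L <- as.integer(L); k <- as.integer(k)
  stopifnot(k >= 1L)
  n <- seq_length(rec)
  if (L > n) {
    warning("design_tiling: window (", L, ") exceeds sequence length (", n,
            "); emitting a single full-sequence spot")
    starts <- 1L
    L_eff <- n
    spots <- data.frame(index = 1L, start = 1L, end = n,
                        peptide = rec$residues, terminal = TRUE,
                        stringsAsFactors = FALSE)
  } else {
    starts <- seq.int(1L, n - L + 1L, by = k)
    terminal <- rep(FALSE, length(starts))
    last_end <- starts[length(starts)] + L - 1L
    if (include_terminal && last_end < n) {
      starts <- c(starts, n - L + 1L)
      terminal <- c(terminal, TRUE)
    }
    spots <- data.frame(
      index = seq_along(starts), start = starts, end = starts + L - 1L,
      peptide = vapply(starts, function(s) substr(rec$residues, s, s + L - 1L),
                       character(1)),
      terminal = terminal, stringsAsFactors = FALSE)
  }
  structure(list(protein_id = rec$id, L = L, k = k, spots = spots),
            class = "tiling_design")
}

#' @export
print.tiling_design <- function(x, ...) {
  cat(sprintf("<tiling_design> %s: %d spots (%d-mers, offset %d)\n",
              x$protein_id, nrow(x$spots), x$L, x$k))
  invisible(x)
}

#' Spots fully containing a motif core
#'
#' @param design A [design_tiling()] result.
#' @param motif A one-row `motif_hits` data.frame, or a list/vector with
#'   `start` and `end`.
#' @param mode `"cover"` (default): spots whose interval fully contains the
#'   core; `"overlap"`: spots sharing at least one residue with the core.
#' @return Integer vector of spot indices in design order (possibly empty).
#' @export
spots_covering <- function(design, motif, mode = c("cover", "overlap")) {
  mode <- match.arg(mode)
  if (is.data.frame(motif)) {
    stopifnot(nrow(motif) == 1L)
    motif <- as.list(motif)
  }
  s <- as.integer(motif$start); e <- as.integer(motif$end)
  sp <- design$spots
  hitsel <- if (mode == "cover") sp$start <= s & sp$end >= e
            else sp$start <= e & sp$end >= s
  sp$index[hitsel]
}

#' Binarize spot intensities against background spots
#'
#' A spot is positive when its intensity exceeds
#' `mean(background) + 2 * sd(background)`. Calls are invariant to a common
#' rescaling of all intensities.
#'
#' @param signals A data.frame with columns `spot_index`, `probe`,
#'   `intensity` (and optionally a logical `positive`, returned untouched).
#' @param background_spots Spot indices regarded as background (per probe).
#' @param threshold Manual threshold overriding the background rule.
#' @return `signals` with a logical `positive` column.
#' @export
binarize_signals <- function(signals, background_spots = NULL,
                             threshold = NULL) {
  if (!is.null(signals$positive)) {
    signals$positive <- as.logical(signals$positive)
    return(signals)
  }
  if (is.null(signals$intensity)) {
    stop("binarize_signals: need an 'intensity' or 'positive' column")
  }
  if (is.null(threshold) && is.null(background_spots)) {
    stop("binarize_signals: supply 'threshold' or 'background_spots'")
  }
  out <- do.call(rbind, lapply(split(signals, signals$probe), function(df) {
    thr <- threshold
    if (is.null(thr)) {
      bg <- df$intensity[df$spot_index %in% background_spots]
      if (length(bg) < 2L) {
        stop("binarize_signals: fewer than 2 background spots for probe '",
             df$probe[1], "'")
      }
      thr <- mean(bg) + 2 * stats::sd(bg)
    }
    df$positive <- df$intensity > thr
    df
  }))
  rownames(out) <- NULL
  out
}

# Internal: longest run of TRUE in a logical vector.
.longest_run <- function(x) {
  if (length(x) == 0L || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Call motif-probe interactions from spot signals (run rule)
#'
#' For each motif and probe, the positivity pattern over the motif's
#' covering spots (in design order) is reduced to its longest run of
#' consecutive positive spots; the interaction is `positive` iff that run
#' reaches `run_threshold` (default 3 spots in a row). A consensus match is
#' necessary but not sufficient for binding, so only the array signal - not
#' the motif class - drives this call. The result also records whether the
#' last covering spot (the one with the core pushed furthest toward its own
#' N-terminus, i.e. the fewest N-flank residues retained) is negative: a
#' negative N-flank-truncated spot alongside a positive call points at
#' N-terminal flank residues contributing to affinity.
#'
#' @param design A [design_tiling()] result.
#' @param signals Spot signals (see [binarize_signals()]); binarized on the
#'   fly when `background_spots` or `threshold` is given.
#' @param motifs A `motif_hits` data.frame.
#' @param run_threshold Minimum run of consecutive positive covering spots,
#'   default 3.
#' @param mode Covering-spot semantics passed to [spots_covering()].
#' @param background_spots,threshold Passed to [binarize_signals()] when
#'   `signals` lacks a `positive` column.
#' @return A data.frame of class `interaction_calls`: `motif_id`, `probe`,
#'   `n_covering`, `covering`, `pattern`, `longest_run`, `call`,
#'   `nflank_truncated_negative`.
#' @export
call_interactions <- function(design, signals, motifs, run_threshold = 3L,
                              mode = c("cover", "overlap"),
                              background_spots = NULL, threshold = NULL) {
  mode <- match.arg(mode)
  signals <- binarize_signals(signals, background_spots, threshold)
  unknown <- setdiff(unique(signals$spot_index), design$spots$index)
  if (length(unknown) > 0L) {
    stop("call_interactions: signal(s) for unknown spot index: ",
         paste(unknown, collapse = ", "))
  }
  probes <- unique(signals$probe)
  rows <- list()
  for (m in seq_len(nrow(motifs))) {
    cov <- spots_covering(design, motifs[m, ], mode = mode)
    for (p in probes) {
      sig <- signals[signals$probe == p, , drop = FALSE]
      pos <- sig$positive[match(cov, sig$spot_index)]
      if (length(cov) > 0L && anyNA(pos)) {
        stop("call_interactions: no '", p, "' signal for spot(s) ",
             paste(cov[is.na(pos)], collapse = ", "))
      }
      run <- .longest_run(pos)
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = motifs$motif_id[m], probe = p,
        n_covering = length(cov),
        covering = paste(cov, collapse = ","),
        pattern = paste(as.integer(pos), collapse = ""),
        longest_run = run,
        call = if (run >= run_threshold) "positive" else "negative",
        nflank_truncated_negative =
          if (length(cov) == 0L) NA else !pos[length(pos)],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(motif_id = character(0), probe = character(0),
               n_covering = integer(0), covering = character(0),
               pattern = character(0), longest_run = integer(0),
               call = character(0), nflank_truncated_negative = logical(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("interaction_calls", "data.frame")
  out
}

#' Write a tiling design to TSV
#' @param design A [design_tiling()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design$spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read spot signals from TSV
#'
#' Expected columns: `spot_index`, `probe`, and `intensity` and/or
#' `positive`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of spot signals.
#' @export
read_signals_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("spot_index", "probe")
  if (!all(need %in% names(out))) {
    stop("read_signals_tsv: missing column(s): ",
         paste(setdiff(need, names(out)), collapse = ", "))
  }
  out
}
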