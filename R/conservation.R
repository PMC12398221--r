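# Ortholog conservation: reference-coordinate mapping through an alignment,
# per-taxon motif presence calls, frequency-logo information content, and
# parsimony gain/loss reconstruction on a phylogeny.

#' Map reference positions to alignment columns
#'
#' Builds the strictly increasing map from each non-gap position of the
#' reference row to its alignment column (both 1-based), so motif
#' coordinates found on the ungapped reference can be transferred onto the
#' alignment.
#'
#' @param alignment A named list of gapped records from [read_alignment()].
#' @param ref_id Id of the reference record within the alignment.
#' @return An object of class `column_map`: list with `ref_id` and `map`, an
#'   integer vector with `map[p]` the alignment column of reference
#'   position `p`.
#' @export
map_ref_positions <- function(alignment, ref_id) {
  if (!ref_id %in% names(alignment)) {
    stop("map_ref_positions: reference '", ref_id, "' not in alignment")
  }
  row <- strsplit(alignment[[ref_id]]$residues, "")[[1]]
  cols <- which(row != "-")
  if (length(cols) == 0L) {
    stop("map_ref_positions: reference '", ref_id, "' is entirely gaps")
  }
  structure(list(ref_id = ref_id, map = cols), class = "column_map")
}

# Internal: residues of one taxon at the four homologous columns of a core.
.core_at_columns <- function(rec, columns) {
  res <- strsplit(rec$residues, "")[[1]]
  paste(res[columns], collapse = "")
}

#' Call motif presence per taxon across an ortholog alignment
#'
#' For each taxon the four columns homologous to the motif core are
#' extracted; a gap anywhere in the core makes the call `absent`, otherwise
#' the residues are tested against the GIM and then the canonical consensus.
#' Presence is a pattern call only — functional-residue conservation, not
#' percent identity, and never a binding prediction.
#'
#' @param alignment A named list of gapped records.
#' @param colmap A [map_ref_positions()] result for the same alignment.
#' @param hits A `motif_hits` data.frame (coordinates on the ungapped
#'   reference).
#' @return A data.frame of class `presence_matrix`: rows = taxa, one column
#'   per `motif_id`, cells in `c("present_gim", "present_canonical",
#'   "absent")`.
#' @export
motif_presence <- function(alignment, colmap, hits) {
  stopifnot(inherits(colmap, "column_map"))
  ref_len <- length(colmap$map)
  if (any(hits$end > ref_len)) {
    stop("motif_presence: hit coordinates exceed reference length ", ref_len)
  }
  taxa <- names(alignment)
  out <- data.frame(row.names = taxa)
  for (k in seq_len(nrow(hits))) {
    columns <- colmap$map[hits$start[k]:hits$end[k]]
    calls <- vapply(alignment, function(rec) {
      core <- .core_at_columns(rec, columns)
      if (grepl("-", core, fixed = TRUE)) return("absent")
      if (classify_gim(core)) return("present_gim")
      if (classify_canonical(core)) return("present_canonical")
      "absent"
    }, character(1))
    out[[hits$motif_id[k]]] <- unname(calls)
  }
  class(out) <- c("presence_matrix", "data.frame")
  out
}

#' Per-column residue frequencies and information content
#'
#' Frequencies are over the 20 standard residues with gaps (and `X`)
#' excluded from the denominator. Information content per column is
#' `IC = log2(20) - H` with `H` the Shannon entropy in bits of the column's
#' frequency vector — the height scale of a sequence logo. No small-sample
#' correction and no background weighting are applied. A column with no
#' ungapped standard residue has undefined IC, reported as `NA`.
#'
#' @param alignment A named list of gapped records.
#' @param columns Integer vector of alignment columns (1-based).
#' @return An object of class `frequency_profile`: list with `columns`,
#'   `freq` (20 x length(columns) matrix of frequencies) and `ic` (numeric,
#'   bits).
#' @export
frequency_profile <- function(alignment, columns) {
  width <- seq_length(alignment[[1]])
  columns <- as.integer(columns)
  if (any(columns < 1L | columns > width)) {
    stop("frequency_profile: columns out of range 1..", width)
  }
  mat <- do.call(rbind, lapply(alignment, function(rec) {
    strsplit(rec$residues, "")[[1]][columns]
  }))
  freq <- vapply(seq_along(columns), function(j) {
    col <- mat[, j]
    col <- col[col %in% .STANDARD_AA]
    if (length(col) == 0L) return(rep(NA_real_, 20L))
    tab <- table(factor(col, levels = .STANDARD_AA))
    as.numeric(tab) / length(col)
  }, numeric(20L))
  freq <- matrix(freq, nrow = 20L,
                 dimnames = list(.STANDARD_AA, as.character(columns)))
  ic <- apply(freq, 2L, function(f) {
    if (anyNA(f)) return(NA_real_)
    p <- f[f > 0]
    log2(20) - sum(-p * log2(p))
  })
  structure(list(columns = columns, freq = freq, ic = unname(ic)),
            class = "frequency_profile")
}

#' Write a frequency profile as JSON for logo renderers
#'
#' One object per column with the 20 residue frequencies and the
#' information content in bits.
#'
#' @param profile A [frequency_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  cols <- lapply(seq_along(profile$columns), function(j) {
    list(column = profile$columns[j],
         frequencies = as.list(profile$freq[, j]),
         ic_bits = profile$ic[j])
  })
  jsonlite::write_json(cols, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Fraction of taxa retaining a motif
#'
#' @param presence_col Character vector of presence calls (one per taxon),
#'   e.g. one column of a [motif_presence()] matrix; values
#'   `present_gim`/`present_canonical` count as retained.
#' @param taxa Optional character vector restricting to a taxon subset
#'   (names of `presence_col` or row names used upstream).
#' @return Fraction in \[0, 1\].
#' @export
retention_fraction <- function(presence_col, taxa = NULL) {
  if (!is.null(taxa)) {
    if (length(taxa) == 0L) stop("retention_fraction: empty taxon subset")
    if (is.null(names(presence_col))) {
      stop("retention_fraction: presence_col must be named to subset")
    }
    missing <- setdiff(taxa, names(presence_col))
    if (length(missing) > 0L) {
      stop("retention_fraction: unknown taxa: ",
           paste(missing, collapse = ", "))
    }
    presence_col <- presence_col[taxa]
  }
  if (length(presence_col) == 0L) stop("retention_fraction: no taxa")
  mean(presence_col %in% c("present_gim", "present_canonical"))
}

#' Parsimony gain/loss reconstruction of motif presence on a tree
#'
#' Reconstructs the minimum number of presence/absence changes of a motif on
#' a phylogeny and assigns each change to a branch. Internal-node state sets
#' are computed bottom-up by the majority-set generalization of Fitch
#' parsimony (Hartigan's rule), which coincides with classic Fitch on
#' bifurcations and attains the exact minimum change count on
#' multifurcating trees as well: at each internal node the states carried
#' by the largest number of child sets are kept, and the deficit is added
#' to the change count. States are binary; the GIM vs canonical distinction
#' is collapsed to `present`. Root-state ties resolve to `absent`
#' (conservative against inferring ancient motifs) unless `root_prefer`
#' says otherwise; the same preference breaks ties below the root.
#'
#' @param tree An `ape::phylo` tree, or a path to / string of Newick.
#' @param presence Named character (presence calls) or logical vector,
#'   names = tip labels. Every tip must be present in `presence`.
#' @param root_prefer `"absent"` (default) or `"present"`.
#' @return An object of class `gain_loss`: list with `tree`, `min_changes`,
#'   `node_states` (resolved state per node, tips first in
#'   `tree$tip.label` order), `root_state` and `events`, a data.frame with
#'   one row per change (`parent`, `child`, `child_label`, `type` =
#'   `gain`/`loss`).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' fitch_gain_loss(tr, c(A = "present_gim", B = "present_canonical",
#'                       C = "absent"))$min_changes  # 1
#' @export
fitch_gain_loss <- function(tree, presence, root_prefer = c("absent",
                                                            "present")) {
  root_prefer <- match.arg(root_prefer)
  if (is.character(tree)) {
    tree <- suppressWarnings(if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree))
  }
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("fitch_gain_loss: malformed tree")
  }
  if (is.logical(presence)) {
    states <- ifelse(presence, "present", "absent")
    names(states) <- names(presence)
  } else {
    states <- ifelse(presence %in% c("present_gim", "present_canonical",
                                     "present"), "present", "absent")
    names(states) <- names(presence)
  }
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing) > 0L) {
    stop("fitch_gain_loss: no presence state for tip(s): ",
         paste(missing, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # state sets as bitmasks: 1 = absent, 2 = present, 3 = both
  sets <- integer(ntip + nnode)
  sets[seq_len(ntip)] <- ifelse(states[tree$tip.label] == "present", 2L, 1L)
  edge <- tree$edge
  post <- ape::reorder.phylo(tree, "postorder")$edge
  changes <- 0L
  for (node in unique(post[, 1L])) {
    children <- post[post[, 1L] == node, 2L]
    n_abs <- sum(bitwAnd(sets[children], 1L) > 0L)
    n_pre <- sum(bitwAnd(sets[children], 2L) > 0L)
    k <- length(children)
    top <- max(n_abs, n_pre)
    sets[node] <- (if (n_abs == top) 1L else 0L) +
                  (if (n_pre == top) 2L else 0L)
    changes <- changes + (k - top)
  }
  # top-down refinement to one state per node
  prefer <- if (root_prefer == "absent") 1L else 2L
  resolved <- integer(ntip + nnode)
  root <- ntip + 1L
  resolved[root] <- if (bitwAnd(sets[root], prefer) > 0L) prefer else
    bitwXor(3L, prefer)
  pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    parent <- pre[i, 1L]; child <- pre[i, 2L]
    p_state <- resolved[parent]
    resolved[child] <- if (bitwAnd(sets[child], p_state) > 0L) p_state else
      if (bitwAnd(sets[child], prefer) > 0L) prefer else
      bitwXor(3L, prefer)
  }
  flip <- resolved[edge[, 1L]] != resolved[edge[, 2L]]
  events <- data.frame(
    parent = edge[flip, 1L], child = edge[flip, 2L],
    child_label = ifelse(edge[flip, 2L] <= ntip,
                         tree$tip.label[edge[flip, 2L]],
                         paste0("node", edge[flip, 2L])),
    type = ifelse(resolved[edge[flip, 2L]] == 2L, "gain", "loss"),
    stringsAsFactors = FALSE)
  labels <- c("absent", "present")
  structure(list(tree = tree, min_changes = changes,
                 node_states = labels[resolved],
                 root_state = labels[resolved[root]],
                 events = events),
            class = "gain_loss")
}

#' Write a presence matrix to TSV
#' @param presence A [motif_presence()] matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(presence, path) {
  out <- cbind(taxon = rownames(presence), as.data.frame(presence))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
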