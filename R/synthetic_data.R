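# Ground-truth generators for every pipeline stage: ortholog families
# evolved along a tree with a tunable motif-retention parameter, toy atomic
# structures with known burial geometry, and peptide-array spot signals
# with known true binders. Each generator runs on its own explicitly
# seeded PRNG stream and restores the caller's RNG state on exit.

# Internal: run `expr` under a private RNG stream.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Internal: one uniformly chosen standard residue different from `res`.
.mutate_residue <- function(res) {
  sample(setdiff(.STANDARD_AA, res), 1L)
}

#' Simulate an ortholog family along a phylogeny with motif retention
#'
#' The reference sequence is evolved down the tree by independent per-site
#' replacement: on a branch of length `b` each site mutates with
#' probability `1 - exp(-b * rate)`, drawing uniformly from the 19
#' alternative residues. Optionally, sites are irreversibly deleted at the
#' same per-branch probability scaled by `indel_rate`; because homology is
#' known by construction, deletions yield an exact gapped alignment (one
#' column per reference position; insertions are not modeled). After
#' evolution, each motif interval is resolved per leaf: with probability
#' `theta` the leaf retains the motif - core positions that drifted out of
#' their consensus sets are restored to the reference residue - otherwise
#' the Theta anchor position is forced outside the canonical anchor set
#' (W/F/Y), so a non-retained core violates both consensus classes. The
#' truth table records each leaf's intended state.
#'
#' @param ref A [seq_record()] (or residue string) for the root.
#' @param tree An `ape::phylo` with branch lengths, or Newick text/path.
#' @param rate Per-site substitution probability per unit branch length
#'   (default 0.05).
#' @param motifs `NULL`, or a data.frame with columns `motif_id`, `start`,
#'   `end`, `theta` and optionally `consensus` (`"canonical"` default, or
#'   `"gim"`). Reference cores must satisfy their consensus.
#' @param indel_rate Per-site deletion probability scale (default 0: the
#'   alignment is gap-free).
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return List with `alignment` (named list of gapped records, tip-label
#'   order), `truth` (data.frame `taxon`, `motif_id`, `retained`) and
#'   `tree`.
#' @export
simulate_ortholog_family <- function(ref, tree, rate = 0.05, motifs = NULL,
                                     indel_rate = 0, seed = 1L) {
  if (!inherits(ref, "seq_record")) ref <- seq_record("ref", ref)
  if (is.character(tree)) {
    tree <- suppressWarnings(if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree))
  }
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("simulate_ortholog_family: malformed tree")
  }
  if (is.null(tree$edge.length)) {
    stop("simulate_ortholog_family: tree has no branch lengths")
  }
  n <- seq_length(ref)
  if (!is.null(motifs)) {
    if (is.null(motifs$consensus)) motifs$consensus <- "canonical"
    stopifnot(all(motifs$theta >= 0 & motifs$theta <= 1),
              all(motifs$start >= 1 & motifs$end <= n),
              all(motifs$end - motifs$start == 3L))
    for (m in seq_len(nrow(motifs))) {
      core <- subsequence(ref, motifs$start[m], motifs$end[m])
      cons <- lir_consensus(motifs$consensus[m])
      if (!.matches_consensus(core, cons)) {
        stop("simulate_ortholog_family: reference core '", core,
             "' at ", motifs$start[m], " does not satisfy the ",
             cons$name, " consensus")
      }
    }
  }
  .with_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    alive <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- strsplit(ref$residues, "")[[1]]
    alive[[root]] <- rep(TRUE, n)
    pre <- ape::reorder.phylo(tree, "postorder")$edge
    pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]
    lens <- tree$edge.length[match(
      paste(pre[, 1], pre[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))]
    for (i in seq_len(nrow(pre))) {
      parent <- pre[i, 1L]; child <- pre[i, 2L]; b <- lens[i]
      s <- seqs[[parent]]; a <- alive[[parent]]
      p_sub <- 1 - exp(-b * rate)
      mut <- a & (stats::runif(n) < p_sub)
      if (any(mut)) {
        s[mut] <- vapply(s[mut], .mutate_residue, character(1))
      }
      if (indel_rate > 0) {
        p_del <- 1 - exp(-b * rate * indel_rate)
        del <- a & (stats::runif(n) < p_del)
        a[del] <- FALSE
      }
      seqs[[child]] <- s
      alive[[child]] <- a
    }
    truth <- NULL
    if (!is.null(motifs)) {
      truth <- do.call(rbind, lapply(seq_len(ntip), function(tip) {
        data.frame(taxon = tree$tip.label[tip], motif_id = motifs$motif_id,
                   retained = NA, stringsAsFactors = FALSE)
      }))
      for (tip in seq_len(ntip)) {
        for (m in seq_len(nrow(motifs))) {
          span <- motifs$start[m]:motifs$end[m]
          cons <- lir_consensus(motifs$consensus[m])
          keep <- stats::runif(1) < motifs$theta[m]
          row <- truth$taxon == tree$tip.label[tip] &
            truth$motif_id == motifs$motif_id[m]
          if (!all(alive[[tip]][span])) {
            # a deletion trumps the retention draw
            truth$retained[row] <- FALSE
            next
          }
          if (keep) {
            for (j in 1:4) {
              pos <- span[j]
              if (!(seqs[[tip]][pos] %in% cons$position_sets[[j]])) {
                seqs[[tip]][pos] <- substr(ref$residues, pos, pos)
              }
            }
          } else {
            # force the Theta anchor outside the full canonical anchor set
            # so the core violates both consensus classes
            theta_set <- union(cons$position_sets[[1]], c("W", "F", "Y"))
            seqs[[tip]][span[1]] <- sample(setdiff(.STANDARD_AA, theta_set),
                                           1L)
          }
          truth$retained[row] <- keep
        }
      }
    }
    alignment <- lapply(seq_len(ntip), function(tip) {
      res <- seqs[[tip]]
      res[!alive[[tip]]] <- "-"
      aln_record(tree$tip.label[tip], paste(res, collapse = ""))
    })
    names(alignment) <- tree$tip.label
    list(alignment = alignment, truth = truth, tree = tree)
  })
}

# Internal: fixed-column PDB ATOM lines for an atom table.
.pdb_atom_lines <- function(atoms) {
  vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, paste0(" ", atoms$elety[i]), atoms$resid[i], atoms$chain[i],
            atoms$resno[i], atoms$x[i], atoms$y[i], atoms$z[i], 1, 0,
            atoms$element[i])
  }, character(1))
}

#' Write an atom table as PDB text
#'
#' Minimal fixed-column ATOM writer for the toy structures; output parses
#' through [read_structure()].
#'
#' @param atoms An `atom_table`-style data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  writeLines(c(.pdb_atom_lines(atoms), "END"), path)
  invisible(path)
}

# Internal: ideal poly-alanine helix (Ca + Cb level): rise 1.5 A, twist
# 100 degrees, Ca radius 2.3 A, Cb radially 1.5 A further out.
.helix_atoms <- function(n_res, chain = "A", shift = c(0, 0, 0)) {
  ang <- (seq_len(n_res) - 1L) * 100 * pi / 180
  z <- (seq_len(n_res) - 1L) * 1.5
  ca <- data.frame(chain = chain, resno = seq_len(n_res), resid = "ALA",
                   elety = "CA", element = "C",
                   x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = z,
                   stringsAsFactors = FALSE)
  cb <- ca
  cb$elety <- "CB"
  cb$x <- 3.8 * cos(ang); cb$y <- 3.8 * sin(ang)
  out <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    rbind(ca[i, ], cb[i, ])
  }))
  out$x <- out$x + shift[1]; out$y <- out$y + shift[2]
  out$z <- out$z + shift[3]
  rownames(out) <- NULL
  out
}

#' Generate a toy structure with known burial geometry
#'
#' Three geometries: `"lone-helix"` (one ideal poly-alanine helix, every
#' residue solvent-exposed), `"two-helix-dimer"` (a second copy translated
#' along +x to create a known contact face), and `"three-sphere"` (three
#' collinear single-atom "residues" for closed-form occlusion checks). The
#' truth table flags interface residues by construction (any residue whose
#' C-beta lies within `interface_cutoff` of the partner chain) and, for
#' helical geometries, a 4-residue "motif" interval chosen at the contact
#' face (`motif_placement = "interface"`) or on the far surface
#' (`"surface"`).
#'
#' @param geometry One of `"lone-helix"`, `"two-helix-dimer"`,
#'   `"three-sphere"`.
#' @param motif_placement `"interface"` or `"surface"` (helical geometries).
#' @param n_res Residues per helix (default 24).
#' @param separation Dimer translation along x in Angstrom (default 9).
#' @param sphere_distance Center spacing of the three-sphere system
#'   (default 3.0).
#' @param interface_cutoff C-beta-to-partner-atom distance defining the
#'   interface truth (default 8).
#' @return List with `atoms` (an `atom_table`-style data.frame), `truth`
#'   (per-residue `chain`, `resno`, `interface`, `in_motif`), `motif`
#'   (`start`, `end` residue numbers or `NULL`), and `pdb` (character
#'   vector of PDB lines).
#' @export
make_toy_structure <- function(geometry = c("lone-helix", "two-helix-dimer",
                                            "three-sphere"),
                               motif_placement = c("interface", "surface"),
                               n_res = 24L, separation = 9,
                               sphere_distance = 3.0,
                               interface_cutoff = 8) {
  geometry <- match.arg(geometry)
  motif_placement <- match.arg(motif_placement)
  if (geometry == "three-sphere") {
    atoms <- data.frame(chain = "A", resno = 1:3, resid = "ALA",
                        elety = "CB", element = "C",
                        x = c(0, 1, 2) * sphere_distance, y = 0, z = 0,
                        stringsAsFactors = FALSE)
    truth <- data.frame(chain = "A", resno = 1:3,
                        interface = c(FALSE, TRUE, FALSE), in_motif = FALSE,
                        stringsAsFactors = FALSE)
    return(list(atoms = atoms, truth = truth, motif = NULL,
                pdb = c(.pdb_atom_lines(atoms), "END")))
  }
  a <- .helix_atoms(n_res, "A")
  atoms <- a
  if (geometry == "two-helix-dimer") {
    b <- .helix_atoms(n_res, "B", shift = c(separation, 0, 0))
    atoms <- rbind(a, b)
  }
  # interface truth: Cb within cutoff of any partner-chain atom
  truth <- do.call(rbind, lapply(unique(atoms$chain), function(ch) {
    cb <- atoms[atoms$chain == ch & atoms$elety == "CB", , drop = FALSE]
    other <- atoms[atoms$chain != ch, , drop = FALSE]
    iface <- if (nrow(other) == 0L) rep(FALSE, nrow(cb)) else
      vapply(seq_len(nrow(cb)), function(i) {
        min(sqrt((other$x - cb$x[i])^2 + (other$y - cb$y[i])^2 +
                   (other$z - cb$z[i])^2)) <= interface_cutoff
      }, logical(1))
    data.frame(chain = ch, resno = cb$resno, interface = iface,
               in_motif = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  # motif interval on chain A: 4 consecutive residues closest to (interface)
  # or farthest from (surface) the partner face; for the lone helix any
  # window qualifies as surface, scored against the +x direction instead.
  cb_a <- atoms[atoms$chain == "A" & atoms$elety == "CB", , drop = FALSE]
  face_score <- if (geometry == "two-helix-dimer") {
    other <- atoms[atoms$chain == "B", , drop = FALSE]
    vapply(seq_len(nrow(cb_a)), function(i) {
      min(sqrt((other$x - cb_a$x[i])^2 + (other$y - cb_a$y[i])^2 +
                 (other$z - cb_a$z[i])^2))
    }, numeric(1))
  } else {
    -cb_a$x  # lone helix: +x-facing residues stand in for the "face"
  }
  # candidate windows stay clear of the helix termini, whose frayed
  # geometry dominates SASA regardless of orientation
  cand <- seq_len(n_res - 3L)
  if (n_res >= 16L) cand <- cand[cand >= 5L & cand <= n_res - 7L]
  window_sums <- vapply(cand, function(s) {
    sum(face_score[s:(s + 3L)])
  }, numeric(1))
  start <- if (motif_placement == "interface") cand[which.min(window_sums)]
           else cand[which.max(window_sums)]
  truth$in_motif <- truth$chain == "A" & truth$resno %in% start:(start + 3L)
  list(atoms = atoms, truth = truth,
       motif = list(start = start, end = start + 3L),
       pdb = c(.pdb_atom_lines(atoms), "END"))
}

#' Simulate SPOT-array signals with known true binders
#'
#' Spots covering any true-binder motif are positive with probability
#' `1 - fn`; all other spots are positive with probability `fp`.
#'
#' @param design A [design_tiling()] result.
#' @param true_binders `motif_hits`-style data.frame of the truly binding
#'   motifs (may be empty).
#' @param fp,fn False-positive / false-negative rate per spot, in \[0, 1\].
#' @param probe Probe name stamped on every signal row.
#' @param seed Integer seed.
#' @return A data.frame `spot_index`, `probe`, `intensity` (0/1),
#'   `positive`.
#' @export
simulate_array_signals <- function(design, true_binders, fp = 0, fn = 0,
                                   probe = "GABARAP", seed = 1L) {
  stopifnot(fp >= 0, fp <= 1, fn >= 0, fn <= 1)
  idx <- design$spots$index
  covered <- rep(FALSE, length(idx))
  if (!is.null(true_binders) && nrow(true_binders) > 0L) {
    for (m in seq_len(nrow(true_binders))) {
      covered[idx %in% spots_covering(design, true_binders[m, ])] <- TRUE
    }
  }
  .with_seed(seed, {
    u <- stats::runif(length(idx))
    positive <- ifelse(covered, u < (1 - fn), u < fp)
    data.frame(spot_index = idx, probe = probe,
               intensity = as.numeric(positive), positive = positive,
               stringsAsFactors = FALSE)
  })
}
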