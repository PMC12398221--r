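# Solvent-accessible surface area (Shrake-Rupley) and motif accessibility
# calls in monomeric vs oligomeric context.
#
# Test points are a fixed golden-spiral lattice, so SASA is reproducible
# bit-for-bit for a given point count: no RNG anywhere in this file.

#' Van der Waals radius table (Angstrom)
#'
#' Element-based radii used for SASA: C 1.70, N 1.55, O 1.52, S 1.80.
#' Hydrogens are ignored upstream (crystallographic and predicted protein
#' structures typically lack them).
#'
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}

#' Maximum accessible surface area per residue type (Angstrom^2)
#'
#' Theoretical Gly-X-Gly maximum ASA values of Tien et al. (2013),
#' "Maximum allowed solvent accessibilites of residues in proteins",
#' PLoS ONE 8:e80635, used to normalize absolute SASA to relative SASA.
#'
#' @return Named numeric vector, names = three-letter residue codes.
#' @export
max_asa_table <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLU = 223.0, GLN = 225.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}

#' SASA computation parameters
#'
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param n_points Number of test points per atom sphere (default 960);
#'   at least 100.
#' @param radii Named van der Waals radius table; default [vdw_radii()].
#' @return An object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 960L,
                        radii = vdw_radii()) {
  stopifnot(probe_radius >= 0, n_points >= 100L)
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 radii = radii),
            class = "sasa_params")
}

# Internal: deterministic quasi-uniform points on the unit sphere
# (golden-spiral / Fibonacci lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  theta <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records, drops waters and hydrogens,
#' and returns a flat atom table in file order. The element is taken from
#' the PDB element column when present, otherwise derived from the atom
#' name.
#'
#' @param path Path to a PDB fixed-column file.
#' @param include_hetatm Keep non-water HETATM records? Default `FALSE`.
#' @param unknown_element `"skip"` (drop the atom with a warning, default)
#'   or `"error"` for atoms whose element has no van der Waals radius.
#' @param radii Radius table used to decide which elements are known.
#' @return A data.frame of class `atom_table` with columns `chain`,
#'   `resno`, `resid`, `elety` (atom name), `element`, `x`, `y`, `z`.
#' @export
read_structure <- function(path, include_hetatm = FALSE,
                           unknown_element = c("skip", "error"),
                           radii = vdw_radii()) {
  unknown_element <- match.arg(unknown_element)
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("read_structure: cannot parse '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (!include_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  element <- toupper(trimws(at$elesy))
  noel <- is.na(element) | !nzchar(element)
  element[noel] <- substr(gsub("[0-9'\" ]", "", toupper(at$elety[noel])), 1, 1)
  keep <- element != "H" & element != "D"
  at <- at[keep, , drop = FALSE]; element <- element[keep]
  unknown <- !(element %in% names(radii))
  if (any(unknown)) {
    msg <- paste0("unknown element(s) without a radius: ",
                  paste(unique(element[unknown]), collapse = ", "))
    if (unknown_element == "error") stop("read_structure: ", msg)
    warning("read_structure: ", msg, "; ", sum(unknown), " atom(s) skipped")
    at <- at[!unknown, , drop = FALSE]; element <- element[!unknown]
  }
  if (nrow(at) == 0L) stop("read_structure: no usable atoms in '", path, "'")
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    stop("read_structure: non-finite coordinates in '", path, "'")
  }
  out <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                    elety = at$elety, element = element,
                    x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("atom_table", "data.frame")
  out
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, a fixed lattice of `n_points` test points is placed on its
#' solvent-expanded sphere (radius r_i + probe); the accessible fraction is
#' the share of points outside every neighbor's expanded sphere, and the
#' atom's SASA is that fraction times the expanded-sphere area
#' 4*pi*(r_i + probe)^2.
#'
#' @param atoms An `atom_table` (or any data.frame with `element`, `x`,
#'   `y`, `z`).
#' @param params A [sasa_params()] object.
#' @return Numeric vector of per-atom SASA values (Angstrom^2), one per row
#'   of `atoms`.
#' @examples
#' lone <- data.frame(element = "S", x = 0, y = 0, z = 0)
#' shrake_rupley(lone)  # ~ 4*pi*(1.8+1.4)^2
#' @export
shrake_rupley <- function(atoms, params = sasa_params()) {
  stopifnot(nrow(atoms) >= 1L)
  radii <- params$radii
  bad <- setdiff(unique(atoms$element), names(radii))
  if (length(bad) > 0L) {
    stop("shrake_rupley: no radius for element(s): ",
         paste(bad, collapse = ", "))
  }
  r_exp <- unname(radii[atoms$element]) + params$probe_radius
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  n <- nrow(xyz)
  pts <- .sphere_points(params$n_points)
  sasa <- numeric(n)
  # neighbor lists from the pairwise distance matrix (fine up to a few
  # thousand atoms)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cutoff2 <- (r_exp[i] + r_exp)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      sasa[i] <- 4 * pi * r_exp[i]^2
      next
    }
    p <- pts * r_exp[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    centers <- xyz[nb, , drop = FALSE]
    # squared distance of every test point to every neighbor center
    cross <- p %*% t(centers)
    pd2 <- outer(rowSums(p^2), rowSums(centers^2), "+") - 2 * cross
    buried <- rowSums(pd2 < matrix(r_exp[nb]^2, nrow = nrow(p),
                                   ncol = length(nb), byrow = TRUE)) > 0L
    sasa[i] <- 4 * pi * r_exp[i]^2 * mean(!buried)
  }
  sasa
}

#' Per-residue absolute and relative solvent accessibility
#'
#' Absolute SASA is summed over each residue's atoms; relative SASA divides
#' by the residue type's maximum ASA ([max_asa_table()]). Relative values
#' may slightly exceed 1 for extended termini; the raw value is kept in
#' `rel_sasa` and a value capped at 1 in `rel_sasa_capped`.
#'
#' @param atoms An `atom_table`.
#' @param atom_sasa Per-atom SASA from [shrake_rupley()] (same row order).
#' @param max_asa Named maximum-ASA table (three-letter codes).
#' @return A data.frame of class `residue_sasa`: `chain`, `resno`, `resid`,
#'   `abs_sasa`, `rel_sasa`, `rel_sasa_capped`.
#' @export
residue_relative_sasa <- function(atoms, atom_sasa,
                                  max_asa = max_asa_table()) {
  stopifnot(nrow(atoms) == length(atom_sasa))
  missing <- setdiff(unique(atoms$resid), names(max_asa))
  if (length(missing) > 0L) {
    stop("residue_relative_sasa: residue type(s) missing from max-ASA ",
         "table: ", paste(missing, collapse = ", "))
  }
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  first <- !duplicated(key)
  abs_sasa <- as.numeric(tapply(atom_sasa, factor(key, levels = key[first]),
                                sum))
  out <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                    resid = atoms$resid[first], abs_sasa = abs_sasa,
                    stringsAsFactors = FALSE)
  out$rel_sasa <- out$abs_sasa / unname(max_asa[out$resid])
  out$rel_sasa_capped <- pmin(out$rel_sasa, 1)
  rownames(out) <- NULL
  class(out) <- c("residue_sasa", "data.frame")
  out
}

# Internal: does [start, end] overlap any row of a 2-column interval set?
.overlaps_interval <- function(start, end, intervals) {
  if (is.null(intervals)) return(FALSE)
  if (is.vector(intervals) && length(intervals) == 2L) {
    intervals <- matrix(intervals, ncol = 2L, byrow = TRUE)
  }
  any(start <= intervals[, 2L] & end >= intervals[, 1L])
}

#' Accessibility call for a motif in monomeric vs assembly context
#'
#' Computes the mean relative SASA of the motif's core residues twice: with
#' the motif's chain isolated (monomer context) and, if assembly chains are
#' given, within the full assembly. A context is called `exposed` when the
#' mean core relative SASA reaches `exposure_threshold`;
#' `occluded_by_oligomer` is set when the motif is exposed in the monomer
#' and the monomer-to-assembly drop in mean relative SASA reaches
#' `occlusion_threshold`. A motif overlapping a declared transmembrane
#' interval is forced to `buried` with reason `"transmembrane"` regardless
#' of SASA (membrane topology cannot be computed from coordinates alone, so
#' TM intervals are user configuration).
#'
#' @param atoms An `atom_table` holding at least the motif's chain.
#' @param motif_start,motif_end Residue numbers (author numbering) of the
#'   motif core.
#' @param chain Chain id carrying the motif.
#' @param assembly_chains Optional character vector of chains forming the
#'   assembly context (should include `chain`); `NULL` = monomer only.
#' @param params A [sasa_params()].
#' @param exposure_threshold Relative-SASA threshold for `exposed`
#'   (default 0.20, a common exposed/buried convention).
#' @param occlusion_threshold Mean drop in relative SASA that flags
#'   oligomer occlusion (default 0.05).
#' @param tm_intervals Optional transmembrane intervals: numeric vector
#'   `c(start, end)` or a 2-column matrix of intervals.
#' @param motif_id Label copied into the result.
#' @return A one-row data.frame of class `accessibility_call`: `motif_id`,
#'   `chain`, `start`, `end`, `rel_sasa_monomer`, `rel_sasa_assembly`,
#'   `call_monomer`, `call_assembly`, `occluded_by_oligomer`, `reason`.
#' @export
motif_accessibility <- function(atoms, motif_start, motif_end, chain,
                                assembly_chains = NULL,
                                params = sasa_params(),
                                exposure_threshold = 0.20,
                                occlusion_threshold = 0.05,
                                tm_intervals = NULL,
                                motif_id = NA_character_) {
  core_res <- motif_start:motif_end
  mono_atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  present <- core_res %in% mono_atoms$resno
  if (!all(present)) {
    stop("motif_accessibility: residue(s) ",
         paste(core_res[!present], collapse = ", "),
         " missing from chain ", chain)
  }
  mean_core_rel <- function(sub_atoms) {
    sasa <- shrake_rupley(sub_atoms, params)
    rs <- residue_relative_sasa(sub_atoms, sasa)
    mean(rs$rel_sasa[rs$chain == chain & rs$resno %in% core_res])
  }
  rel_mono <- mean_core_rel(mono_atoms)
  rel_asm <- NA_real_
  if (!is.null(assembly_chains)) {
    asm_atoms <- atoms[atoms$chain %in% union(assembly_chains, chain), ,
                       drop = FALSE]
    rel_asm <- mean_core_rel(asm_atoms)
  }
  tm <- .overlaps_interval(motif_start, motif_end, tm_intervals)
  call_mono <- if (tm) "buried" else
    if (rel_mono >= exposure_threshold) "exposed" else "buried"
  call_asm <- if (is.na(rel_asm)) NA_character_ else if (tm) "buried" else
    if (rel_asm >= exposure_threshold) "exposed" else "buried"
  occluded <- !tm && !is.na(rel_asm) && call_mono == "exposed" &&
    (rel_mono - rel_asm) >= occlusion_threshold
  out <- data.frame(
    motif_id = motif_id, chain = chain,
    start = motif_start, end = motif_end,
    rel_sasa_monomer = rel_mono, rel_sasa_assembly = rel_asm,
    call_monomer = call_mono, call_assembly = call_asm,
    occluded_by_oligomer = occluded,
    reason = if (tm) "transmembrane" else "sasa",
    stringsAsFactors = FALSE)
  class(out) <- c("accessibility_call", "data.frame")
  out
}

#' Write per-residue SASA to TSV
#' @param residue_sasa A [residue_relative_sasa()] result.
#' @param path Output path.
#' @param context Optional context label added as a column.
#' @return `path`, invisibly.
#' @export
write_sasa_tsv <- function(residue_sasa, path, context = NA_character_) {
  out <- residue_sasa
  out$context <- context
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
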