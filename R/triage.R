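# Evidence integration: a transparent lexicographic ranking of candidate
# motifs over the accessibility, consensus-class, conservation and
# flank-chemistry layers. The evidence is qualitative in nature, so the
# triage is an ordering rule, not a weighted score - any numeric weighting
# would be invented precision.

#' Assemble an evidence bundle for one motif
#'
#' Missing evidence layers are recorded as `NA` ("absent"), never silently
#' defaulted; [rank_candidates()] treats `NA` conservatively (an unknown
#' accessibility does not count as exposed, unknown retention ranks below
#' any measured retention).
#'
#' @param motif_id Motif label (must exist in the hit list used upstream).
#' @param start 1-based start of the core (tie-break key).
#' @param is_gim Is the core GIM-compatible?
#' @param flank_acidity Total D/E count over both flanks.
#' @param retention Retention fraction across the ortholog set (`NA` when
#'   conservation was not run).
#' @param exposed_monomer,exposed_assembly Accessibility calls per context
#'   (`TRUE`/`FALSE`/`NA`).
#' @param tm_excluded Is the motif inside a declared transmembrane
#'   interval?
#' @param array_call Optional `"positive"`/`"negative"` array evidence;
#'   advisory only (annotated, not ranked on) by default.
#' @return A one-row data.frame.
#' @export
evidence_bundle <- function(motif_id, start, is_gim, flank_acidity,
                            retention = NA_real_,
                            exposed_monomer = NA, exposed_assembly = NA,
                            tm_excluded = FALSE,
                            array_call = NA_character_) {
  data.frame(motif_id = motif_id, start = as.integer(start),
             is_gim = as.logical(is_gim),
             flank_acidity = as.integer(flank_acidity),
             retention = as.numeric(retention),
             exposed_monomer = as.logical(exposed_monomer),
             exposed_assembly = as.logical(exposed_assembly),
             tm_excluded = as.logical(tm_excluded),
             array_call = as.character(array_call),
             stringsAsFactors = FALSE)
}

#' Join evidence layers into bundles
#'
#' Convenience constructor joining a hit table with optional conservation,
#' accessibility and array layers by `motif_id`.
#'
#' @param hits A `motif_hits` data.frame from [scan_motifs()].
#' @param retention Optional named numeric vector of retention fractions
#'   (names = motif ids).
#' @param access Optional data.frame of [motif_accessibility()] rows
#'   (stacked).
#' @param array_calls Optional [call_interactions()] result; a motif is
#'   annotated `"positive"` when any probe calls it positive.
#' @return A data.frame of evidence bundles, one row per hit.
#' @export
bundle_evidence <- function(hits, retention = NULL, access = NULL,
                            array_calls = NULL) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    id <- hits$motif_id[i]
    ret <- if (!is.null(retention) && id %in% names(retention))
      retention[[id]] else NA_real_
    em <- ea <- NA; tm <- FALSE
    if (!is.null(access) && id %in% access$motif_id) {
      a <- access[access$motif_id == id, , drop = FALSE][1L, ]
      tm <- identical(a$reason, "transmembrane")
      em <- a$call_monomer == "exposed"
      ea <- if (is.na(a$call_assembly)) NA else a$call_assembly == "exposed"
    }
    arr <- NA_character_
    if (!is.null(array_calls) && id %in% array_calls$motif_id) {
      sub <- array_calls[array_calls$motif_id == id, , drop = FALSE]
      arr <- if (any(sub$call == "positive")) "positive" else "negative"
    }
    evidence_bundle(id, hits$start[i], hits$is_gim[i],
                    hits$n_acidic[i] + hits$c_acidic[i],
                    retention = ret, exposed_monomer = em,
                    exposed_assembly = ea, tm_excluded = tm,
                    array_call = arr)
  })
  do.call(rbind, rows)
}

#' Rank candidate motifs lexicographically
#'
#' The default rule orders candidates by, in turn: (1) structurally
#' plausible - not transmembrane-excluded and exposed in at least one
#' context; (2) GIM-compatible before canonical-only; (3) higher ortholog
#' retention fraction (`NA` ranks last); (4) higher total flank acidity;
#' ties broken by ascending start coordinate. Every comparison is recorded
#' in a per-candidate rationale string. `keys` can reorder or drop the
#' first four criteria. Rerunning on identical inputs yields identical
#' output.
#'
#' @param bundles A data.frame of evidence bundles ([bundle_evidence()]).
#' @param keys Character vector ordering the criteria; subset of
#'   `c("accessible", "gim", "retention", "acidity")`.
#' @return A data.frame of class `triage_report`: `rank`, `motif_id`, the
#'   evidence columns, and `rationale`.
#' @export
rank_candidates <- function(bundles, keys = c("accessible", "gim",
                                              "retention", "acidity")) {
  if (is.null(bundles) || nrow(bundles) == 0L) {
    stop("rank_candidates: no evidence bundles")
  }
  keys <- match.arg(keys, several.ok = TRUE)
  accessible <- !bundles$tm_excluded &
    (bundles$exposed_monomer %in% TRUE | bundles$exposed_assembly %in% TRUE)
  key_cols <- list(
    accessible = -as.integer(accessible),
    gim = -as.integer(bundles$is_gim %in% TRUE),
    retention = -ifelse(is.na(bundles$retention), -1, bundles$retention),
    acidity = -bundles$flank_acidity)
  ord <- do.call(order, c(unname(key_cols[keys]), list(bundles$start)))
  out <- bundles[ord, , drop = FALSE]
  out$accessible <- accessible[ord]
  out$rank <- seq_len(nrow(out))
  out$rationale <- vapply(seq_len(nrow(out)), function(i) {
    b <- out[i, ]
    paste(c(
      if (b$tm_excluded) "transmembrane-excluded" else
        if (isTRUE(b$accessible)) "exposed in >=1 context" else
          "not exposed in any known context",
      if (isTRUE(b$is_gim)) "GIM-compatible" else "canonical-only",
      if (is.na(b$retention)) "retention unknown" else
        sprintf("retention %.2f", b$retention),
      sprintf("flank acidity %d", b$flank_acidity),
      if (!is.na(b$array_call))
        sprintf("array (advisory): %s", b$array_call)),
      collapse = "; ")
  }, character(1))
  front <- c("rank", "motif_id")
  out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("triage_report", "data.frame")
  out
}

#' Write a triage report deterministically
#'
#' TSV rows mirror the report; JSON additionally nests the full evidence
#' per candidate. Rerunning on identical inputs yields byte-identical
#' files.
#'
#' @param report A [rank_candidates()] result.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    recs <- lapply(seq_len(nrow(report)), function(i) as.list(report[i, ]))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read a triage report back from JSON
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A `triage_report` data.frame.
#' @export
read_report_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  df$array_call <- as.character(df$array_call)
  class(df) <- c("triage_report", "data.frame")
  df
}
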