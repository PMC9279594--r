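#' Clonogenic cell count at a passage
#'
#' The number of clonogenic cells is the number of cells used as inoculum to
#' begin a subculture multiplied by the colony forming efficiency (CFE).
#'
#' @param inoculum Cells plated (>= 0).
#' @param cfe Colony forming efficiency in \[0, 1\].
#' @return `inoculum * cfe`, vectorized over both arguments.
#' @export
#' @examples
#' clonogenic_count(10000, 0.10)  # 1000
clonogenic_count <- function(inoculum, cfe) {
  if (!is.numeric(inoculum) || any(!is.finite(inoculum)) || any(inoculum < 0)) {
    abort_input("inoculum must be non-negative")
  }
  if (!is.numeric(cfe) || any(!is.finite(cfe)) || any(cfe < 0) || any(cfe > 1)) {
    abort_input("cfe must be within [0, 1]")
  }
  inoculum * cfe
}

#' Population doublings within a passage
#'
#' Cell doublings are the log2 of the expansion ratio between the unit cell
#' yield (UCY, cells harvested at the end of the passage) and the clonogenic
#' cells that founded it: `log2(UCY / I)`, equivalently `(1/log10(2)) *
#' log10(UCY / I)` with `1/log10(2) = 3.3219...`.
#'
#' @param cell_yield Cells harvested (UCY, > 0). Vectorized.
#' @param clonogenic Clonogenic founder cells (I, > 0). Vectorized.
#' @return Population doublings; 0 when `cell_yield == clonogenic`.
#' @export
#' @examples
#' population_doublings(1024, 1)  # 10
population_doublings <- function(cell_yield, clonogenic) {
  if (!is.numeric(cell_yield) || any(!is.finite(cell_yield)) ||
      any(cell_yield <= 0)) {
    abort_input("cell_yield must be positive")
  }
  if (!is.numeric(clonogenic) || any(!is.finite(clonogenic)) ||
      any(clonogenic <= 0)) {
    abort_input("clonogenic must be positive")
  }
  log2(cell_yield / clonogenic)
}

validate_passage_records <- function(records) {
  needed <- c("culture_id", "passage", "inoculum", "cfe", "cell_yield",
              "aborted_fraction")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort_input("records missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(records) == 0L) return(invisible(records))
  if (length(unique(records$culture_id)) > 1L) {
    abort_input("records must belong to a single culture")
  }
  if (is.unsorted(records$passage, strictly = TRUE)) {
    abort_input("passages must be strictly increasing (sorted, no duplicates)")
  }
  if (any(records$cfe < 0 | records$cfe > 1) ||
      any(records$aborted_fraction < 0 | records$aborted_fraction > 1)) {
    abort_input("cfe and aborted_fraction must be within [0, 1]")
  }
  if (any(records$inoculum < 0) || any(records$cell_yield < 0)) {
    abort_input("inoculum and cell_yield must be non-negative")
  }
  invisible(records)
}

#' Cumulative population doublings and lifespan of a serial culture
#'
#' Per-passage doublings are computed with [population_doublings()] using that
#' passage's clonogenic count (inoculum x CFE) as the founder population, and
#' summed. A passage with CFE = 0 contributes 0 doublings and terminates the
#' lifespan: any later record claiming CFE > 0 is rejected as inconsistent.
#'
#' @param records Passage-record data frame for one culture (columns
#'   `culture_id`, `passage`, `inoculum`, `cfe`, `cell_yield`,
#'   `aborted_fraction`), sorted by passage.
#' @param abortion_level Level passed to [abortion_crossing()].
#' @param per_passage_clonogenic If `FALSE`, use the first passage's
#'   clonogenic count as the founder population for every passage instead of
#'   each passage's own.
#' @return A `lifespan_summary` list: `culture_id`, `n_passages` (passages
#'   with CFE > 0), `per_passage_doublings`, `cumulative_doublings`, and
#'   `passage_at_half_abortion`.
#' @export
cumulative_doublings <- function(records, abortion_level = 0.5,
                                 per_passage_clonogenic = TRUE) {
  validate_passage_records(records)
  if (nrow(records) == 0L) {
    return(structure(list(culture_id = NA_character_, n_passages = 0L,
                          per_passage_doublings = numeric(0),
                          cumulative_doublings = 0,
                          passage_at_half_abortion = NA_integer_),
                     class = "lifespan_summary"))
  }
  exhausted <- which(records$cfe == 0)
  if (length(exhausted)) {
    after <- records$cfe[seq_len(nrow(records)) > exhausted[1]]
    if (any(after > 0)) {
      abort_input("records after the exhaustion passage (CFE = 0) report ",
                  "CFE > 0; series is inconsistent")
    }
  }
  clono <- clonogenic_count(records$inoculum, records$cfe)
  if (!per_passage_clonogenic && clono[1] > 0) clono[] <- clono[1]
  active <- records$cfe > 0 & clono > 0 & records$cell_yield > 0
  pd <- numeric(nrow(records))
  pd[active] <- population_doublings(records$cell_yield[active], clono[active])
  structure(list(culture_id = records$culture_id[1],
                 n_passages = sum(records$cfe > 0),
                 per_passage_doublings = pd,
                 cumulative_doublings = sum(pd),
                 passage_at_half_abortion =
                   abortion_crossing(records, abortion_level)),
            class = "lifespan_summary")
}

#' First passage at which the aborted-colony fraction reaches a level
#'
#' @param records Passage-record data frame (see [cumulative_doublings()]).
#' @param level Crossing level in (0, 1]; default 0.5 (half of colonies
#'   aborted, the conventional senescence landmark).
#' @return The first passage with `aborted_fraction >= level`, or
#'   `NA_integer_` if the level is never reached.
#' @export
abortion_crossing <- function(records, level = 0.5) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level > 1) {
    abort_input("level must be in (0, 1]")
  }
  validate_passage_records(records)
  hit <- which(records$aborted_fraction >= level)
  if (length(hit)) as.integer(records$passage[hit[1]]) else NA_integer_
}

#' Relative expression by the 2^-ddCt method
#'
#' For each record the delta Ct is `target_ct - reference_ct`; the
#' delta-delta Ct is the sample's delta Ct minus the calibrator's, and the
#' relative expression fold change is `2^(-ddCt)`.
#'
#' @param sample,calibrator Lists (or one-row data frames) with numeric
#'   `target_ct` and `reference_ct` cycle values.
#' @return Fold change of the sample relative to the calibrator.
#' @export
#' @examples
#' ddct_relative_expression(list(target_ct = 25, reference_ct = 20),
#'                          list(target_ct = 24, reference_ct = 20))  # 0.5
ddct_relative_expression <- function(sample, calibrator) {
  ct <- function(rec, who) {
    for (f in c("target_ct", "reference_ct")) {
      v <- rec[[f]]
      if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) ||
          v <= 0) {
        abort_input(who, "$", f, " must be a finite positive Ct value")
      }
    }
    rec$target_ct - rec$reference_ct
  }
  ddct <- ct(sample, "sample") - ct(calibrator, "calibrator")
  2^(-ddct)
}

#' Regression of culture lifespan on a marker's expression level
#'
#' Ordinary least-squares fit of the number of passages each culture achieved
#' on its initial marker expression level, the standard way of asking whether
#' a stemness marker predicts replicative lifespan.
#'
#' @param marker_levels Initial marker expression per culture.
#' @param max_passages Lifespan (passages reached) per culture.
#' @return A [fit_linear()] result (slope, intercept, standard error,
#'   goodness of fit).
#' @export
marker_vs_passage_regression <- function(marker_levels, max_passages) {
  if (length(marker_levels) != length(max_passages)) {
    abort_input("marker_levels and max_passages must have equal length")
  }
  if (length(marker_levels) < 3L) {
    abort_input("at least 3 paired observations are required")
  }
  fit_linear(marker_levels, max_passages)
}
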