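#' @name fpkm-matrix
#' @title The wide FPKM expression-matrix layout
#' @description
#' All pipeline stages operate on a "wide" expression data frame with one row
#' per feature x culture: columns `feature_id`, `feature_kind`
#' (`"gene"`/`"isoform"`), `culture_id`, `status` (`"ok"`/`"fail"`), and one
#' numeric column per time-point named `t0`, `t1`, ... (passage order). All
#' cultures must share the same time-points, FPKM values are non-negative,
#' and feature ids are unique within a kind and culture.
NULL

value_cols <- function(mat) grep("^t[0-9]+$", names(mat), value = TRUE)

validate_fpkm_matrix <- function(mat) {
  needed <- c("feature_id", "feature_kind", "culture_id", "status")
  missing <- setdiff(needed, names(mat))
  if (length(missing)) {
    abort_input("expression matrix missing columns: ",
                paste(missing, collapse = ", "))
  }
  vc <- value_cols(mat)
  if (length(vc) < 2L) abort_input("at least 2 time-point columns (t0, t1, ...) required")
  vals <- as.matrix(mat[vc])
  if (nrow(mat) > 0 && (any(!is.finite(vals)) || any(vals < 0))) {
    abort_input("FPKM values must be finite and non-negative")
  }
  key <- paste(mat$feature_kind, mat$culture_id, mat$feature_id)
  if (anyDuplicated(key)) {
    abort_input("duplicated feature within a culture and kind")
  }
  if (nrow(mat) > 0 && !all(mat$status %in% c("ok", "fail"))) {
    abort_input("status must be 'ok' or 'fail'")
  }
  invisible(mat)
}

feature_key <- function(mat) paste(mat$feature_kind, mat$feature_id, sep = "\r")

new_filter_report <- function(n_input, removed_fail = character(0),
                              removed_low = character(0), n_kept = n_input) {
  list(n_input = n_input,
       n_removed_fail = length(removed_fail),
       n_removed_low = length(removed_low),
       n_kept = n_kept,
       removed_fail = removed_fail,
       removed_low = removed_low)
}

#' Remove features flagged as measurement failures
#'
#' A feature whose FPKM status is `fail` in any culture is removed in every
#' culture (its series cannot be trusted anywhere).
#'
#' @param mat A wide expression data frame (see [fpkm-matrix]).
#' @return A list with the filtered `matrix` and a `report` (`n_input`,
#'   `n_removed_fail`, `n_removed_low`, `n_kept`, removed feature ids).
#' @export
filter_failed <- function(mat) {
  validate_fpkm_matrix(mat)
  key <- feature_key(mat)
  bad <- unique(key[mat$status == "fail"])
  keep <- !(key %in% bad)
  out <- mat[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(matrix = out,
       report = new_filter_report(
         n_input = length(unique(key)),
         removed_fail = sort(unique(mat$feature_id[key %in% bad])),
         n_kept = length(unique(key[keep]))))
}

#' Remove features not expressed in a meaningful way
#'
#' A feature is removed (in every culture) if, in at least one culture, the
#' sum of its FPKM values across time-points is strictly less than
#' `sum_threshold` or its first time-point FPKM is strictly less than
#' `initial_threshold`. Boundary values are kept ("less than" is literal).
#'
#' @param mat A wide expression data frame.
#' @param sum_threshold Minimum summed FPKM across time-points (default 5).
#' @param initial_threshold Minimum FPKM at the first time-point (default 1).
#' @param exempt Feature ids never removed (e.g. the housekeeping gene).
#' @return A list with the filtered `matrix` and a `report`.
#' @export
filter_low_expression <- function(mat, sum_threshold = 5,
                                  initial_threshold = 1,
                                  exempt = character(0)) {
  validate_fpkm_matrix(mat)
  assert_scalar_number(sum_threshold, "sum_threshold", lower = 0)
  assert_scalar_number(initial_threshold, "initial_threshold", lower = 0)
  vc <- value_cols(mat)
  vals <- as.matrix(mat[vc])
  low_row <- rowSums(vals) < sum_threshold | vals[, 1L] < initial_threshold
  key <- feature_key(mat)
  bad <- setdiff(unique(key[low_row]),
                 unique(key[mat$feature_id %in% exempt]))
  keep <- !(key %in% bad)
  out <- mat[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(matrix = out,
       report = new_filter_report(
         n_input = length(unique(key)),
         removed_low = sort(unique(mat$feature_id[key %in% bad])),
         n_kept = length(unique(key[keep]))))
}

hk_series <- function(mat, housekeeping_id) {
  vc <- value_cols(mat)
  hk <- mat[mat$feature_id == housekeeping_id, , drop = FALSE]
  if (nrow(hk) == 0L) {
    abort_input("housekeeping feature '", housekeeping_id, "' not found")
  }
  cultures <- unique(mat$culture_id)
  absent <- setdiff(cultures, hk$culture_id)
  if (length(absent)) {
    abort_input("housekeeping feature missing in culture(s): ",
                paste(absent, collapse = ", "))
  }
  out <- as.matrix(hk[vc])
  rownames(out) <- hk$culture_id
  out
}

#' Normalize every series by the housekeeping gene
#'
#' Divides each feature's FPKM at time t by the housekeeping feature's FPKM
#' at the same time-point in the same culture, removing culture- and
#' passage-level depth effects under the assumption that the housekeeping
#' gene's dynamics are constant.
#'
#' @param mat A wide expression data frame.
#' @param housekeeping_id Feature id of the housekeeping gene (present in
#'   every culture, strictly positive at every time-point).
#' @return The matrix with value columns replaced by housekeeping-normalized
#'   values (the housekeeping feature itself becomes the all-ones series).
#' @export
normalize_housekeeping <- function(mat, housekeeping_id) {
  validate_fpkm_matrix(mat)
  vc <- value_cols(mat)
  hk <- hk_series(mat, housekeeping_id)
  zero <- which(hk <= 0, arr.ind = TRUE)
  if (nrow(zero)) {
    abort_input("housekeeping FPKM is not positive in culture ",
                rownames(hk)[zero[1, 1]], " at time-point ",
                vc[zero[1, 2]])
  }
  out <- mat
  out[vc] <- as.matrix(mat[vc]) / hk[mat$culture_id, , drop = FALSE]
  out
}

#' Flag anomalous housekeeping measurements
#'
#' A time-point is flagged (per culture) when the housekeeping FPKM deviates
#' from the median of its own series by more than `fold_limit` in either
#' direction. Flagged time-points should be excluded from trend
#' classification for that culture; an unrealistically high housekeeping
#' measurement otherwise masquerades as coordinated down-regulation of every
#' other gene.
#'
#' @param mat A wide expression data frame (raw, pre-normalization values).
#' @param housekeeping_id Housekeeping feature id.
#' @param fold_limit Tolerated fold deviation from the series median
#'   (default 3); `Inf` disables flagging.
#' @return A data frame `culture_id`, `timepoint` (value-column name),
#'   `ratio` of flagged points; zero rows when nothing is anomalous.
#' @export
flag_housekeeping_anomaly <- function(mat, housekeeping_id, fold_limit = 3) {
  validate_fpkm_matrix(mat)
  if (!is.numeric(fold_limit) || length(fold_limit) != 1L ||
      is.na(fold_limit) || fold_limit < 1) {
    abort_input("fold_limit must be a single number >= 1 (Inf disables)")
  }
  vc <- value_cols(mat)
  hk <- hk_series(mat, housekeeping_id)
  out <- data.frame(culture_id = character(0), timepoint = character(0),
                    ratio = numeric(0), stringsAsFactors = FALSE)
  if (!is.finite(fold_limit)) return(out)
  for (cid in rownames(hk)) {
    med <- stats::median(hk[cid, ])
    if (med <= 0) next
    ratio <- hk[cid, ] / med
    bad <- which(ratio > fold_limit | ratio < 1 / fold_limit)
    if (length(bad)) {
      out <- rbind(out, data.frame(culture_id = cid, timepoint = vc[bad],
                                   ratio = unname(ratio[bad]),
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Normalize a series to its first time-point
#'
#' Divides a series by its first value so every feature starts at 1 and only
#' relative variation remains.
#'
#' @param series Numeric series with a strictly positive first value (after
#'   an optional pseudocount).
#' @param pseudocount Added to every value before normalization (default 0;
#'   features with a zero first value are normally excluded upstream).
#' @return The baseline-normalized series; first element exactly 1.
#' @export
normalize_baseline <- function(series, pseudocount = 0) {
  assert_scalar_number(pseudocount, "pseudocount", lower = 0)
  s <- series + pseudocount
  if (length(s) < 1L || !is.finite(s[1]) || s[1] <= 0) {
    abort_input("first time-point value must be positive for baseline ",
                "normalization")
  }
  s / s[1]
}

#' Coefficient of variation of a series
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean; a
#' scale-free quality metric for the stability of a series.
#'
#' @param series Numeric series of length >= 2.
#' @return The CV; `NA` with a warning when the mean is 0.
#' @export
coefficient_of_variation <- function(series) {
  if (length(series) < 2L) abort_input("series must have length >= 2")
  m <- mean(series)
  if (m == 0) {
    warning("coefficient of variation undefined for zero-mean series")
    return(NA_real_)
  }
  stats::sd(series) / m
}

#' Log2 evolution of a baseline-normalized series
#'
#' Element-wise log2 so the first time-point sits at 0 and later time-points
#' express fold change relative to it.
#'
#' @param series Strictly positive baseline-normalized series.
#' @return `log2(series)`; first element 0 when the input starts at 1.
#' @export
log2_evolution <- function(series) {
  if (any(!is.finite(series)) || any(series <= 0)) {
    abort_input("log2 evolution requires strictly positive values")
  }
  log2(series)
}

#' Classify the monotone trend of a log2-evolution series
#'
#' `"up"` when every consecutive difference exceeds `min_step`, `"down"` when
#' every difference is below `-min_step`, `"none"` otherwise. Reversing a
#' series in time swaps up and down.
#'
#' @param log2_series Log2-evolution values (flagged time-points already
#'   removed).
#' @param min_step Minimum absolute log2 change per step that counts as
#'   regulation (default 0: any strict monotone change).
#' @return `"up"`, `"down"` or `"none"`.
#' @export
classify_trend <- function(log2_series, min_step = 0) {
  assert_scalar_number(min_step, "min_step", lower = 0)
  if (length(log2_series) < 2L) {
    warning("fewer than 2 usable time-points; trend is 'none'")
    return("none")
  }
  d <- diff(log2_series)
  if (all(d > min_step)) return("up")
  if (all(d < -min_step)) return("down")
  "none"
}

#' Consensus trend across cultures
#'
#' The consensus is the direction shared by all required cultures; it is
#' `"none"` unless every required culture agrees on the same non-none
#' direction (a common age-dependent regulation across samples).
#'
#' @param calls Named character vector of per-culture directions
#'   (`up`/`down`/`none`).
#' @param required Culture ids that must agree (default: all in `calls`).
#' @return `"up"`, `"down"` or `"none"`.
#' @export
consensus_across_cultures <- function(calls, required = names(calls)) {
  if (is.null(names(calls))) abort_input("calls must be named by culture")
  missing <- setdiff(required, names(calls))
  if (length(missing)) {
    abort_input("missing trend call for culture(s): ",
                paste(missing, collapse = ", "))
  }
  u <- unique(unname(calls[required]))
  if (length(u) == 1L && u != "none") u else "none"
}

#' Run the full FPKM time-series trend pipeline
#'
#' Applies, in order: removal of failed measurements, removal of
#' low-expression features, housekeeping-anomaly flagging, housekeeping
#' normalization, baseline normalization, log2 evolution, per-culture
#' monotone-trend classification on the unflagged time-points, and
#' cross-culture consensus. The coefficient of variation of each raw series
#' is reported as a quality metric but is not used to filter.
#'
#' @param mat A wide expression data frame (see [fpkm-matrix]).
#' @param housekeeping_id Housekeeping feature id (default `"GAPDH"`).
#' @param sum_threshold,initial_threshold Low-expression thresholds, see
#'   [filter_low_expression()].
#' @param min_step Trend step threshold, see [classify_trend()].
#' @param fold_limit Housekeeping-anomaly fold limit, see
#'   [flag_housekeeping_anomaly()].
#' @param pseudocount Optional pseudocount for baseline normalization.
#' @return A list: `trends` (data frame `feature_id`, `feature_kind`, one
#'   direction column per culture, `consensus`), `report` (the combined
#'   filter report, satisfying `n_input = n_removed_fail + n_removed_low +
#'   n_kept`), `normalized` (long data frame of housekeeping-, baseline- and
#'   log2-normalized values), `cv` (per series), `anomalies` (flagged
#'   housekeeping time-points), and `excluded` (series that could not be
#'   baseline-normalized, with reasons).
#' @export
run_fpkm_pipeline <- function(mat, housekeeping_id = "GAPDH",
                              sum_threshold = 5, initial_threshold = 1,
                              min_step = 0, fold_limit = 3, pseudocount = 0) {
  validate_fpkm_matrix(mat)
  vc <- value_cols(mat)
  empty <- list(
    trends = data.frame(feature_id = character(0),
                        feature_kind = character(0),
                        consensus = character(0), stringsAsFactors = FALSE),
    report = new_filter_report(0L),
    normalized = data.frame(), cv = data.frame(),
    anomalies = data.frame(), excluded = data.frame())
  if (nrow(mat) == 0L) return(empty)

  st1 <- filter_failed(mat)
  st2 <- filter_low_expression(st1$matrix, sum_threshold, initial_threshold,
                               exempt = housekeeping_id)
  report <- new_filter_report(n_input = st1$report$n_input,
                              removed_fail = st1$report$removed_fail,
                              removed_low = st2$report$removed_low,
                              n_kept = st2$report$n_kept)
  kept <- st2$matrix
  if (nrow(kept) == 0L) {
    empty$report <- report
    return(empty)
  }

  anomalies <- flag_housekeeping_anomaly(kept, housekeeping_id, fold_limit)
  hk_norm <- normalize_housekeeping(kept, housekeeping_id)

  cultures <- unique(kept$culture_id)
  norm_rows <- list()
  cv_rows <- list()
  excluded <- list()
  call_list <- list()
  for (cid in cultures) {
    flagged <- anomalies$timepoint[anomalies$culture_id == cid]
    use <- setdiff(vc, flagged)
    sub <- hk_norm[hk_norm$culture_id == cid, , drop = FALSE]
    raw <- kept[kept$culture_id == cid, , drop = FALSE]
    hv <- as.matrix(sub[use])
    ok <- hv[, 1L] + pseudocount > 0
    if (any(!ok)) {
      excluded[[cid]] <- data.frame(
        feature_id = sub$feature_id[!ok], culture_id = cid,
        reason = "first usable time-point is zero; baseline undefined",
        stringsAsFactors = FALSE)
    }
    base <- (hv + pseudocount) / (hv[, 1L] + pseudocount)
    log2e <- matrix(NA_real_, nrow(hv), ncol(hv))
    log2e[ok, ] <- log2(base[ok, , drop = FALSE])
    dirs <- rep("none", nrow(sub))
    if (ncol(log2e) >= 2L) {
      d <- log2e[, -1L, drop = FALSE] - log2e[, -ncol(log2e), drop = FALSE]
      up <- rowSums(d > min_step) == ncol(d)
      down <- rowSums(d < -min_step) == ncol(d)
      dirs[ok & up] <- "up"
      dirs[ok & down] <- "down"
    }
    call_list[[cid]] <- data.frame(
      feature_id = sub$feature_id, feature_kind = sub$feature_kind,
      culture_id = cid, direction = dirs, stringsAsFactors = FALSE)
    cv_rows[[cid]] <- data.frame(
      feature_id = raw$feature_id, culture_id = cid,
      cv = apply(as.matrix(raw[vc]), 1L, coefficient_of_variation),
      stringsAsFactors = FALSE)
    for (j in seq_along(use)) {
      norm_rows[[paste(cid, j)]] <- data.frame(
        feature_id = sub$feature_id, culture_id = cid, timepoint = use[j],
        hk_normalized = hv[, j],
        baseline_normalized = ifelse(ok, base[, j], NA_real_),
        log2_evolution = log2e[, j], stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, call_list)
  wide <- stats::reshape(calls, idvar = c("feature_id", "feature_kind"),
                         timevar = "culture_id", direction = "wide")
  names(wide) <- sub("^direction\\.", "", names(wide))
  dir_cols <- as.matrix(wide[, cultures, drop = FALSE])
  consensus <- apply(dir_cols, 1L, function(x) {
    u <- unique(x)
    if (length(u) == 1L && u != "none") u else "none"
  })
  wide$consensus <- consensus
  rownames(wide) <- NULL
  # the housekeeping gene trivially has the all-ones series; drop it from calls
  wide <- wide[wide$feature_id != housekeeping_id, , drop = FALSE]
  rownames(wide) <- NULL
  list(trends = wide, report = report,
       normalized = do.call(rbind, unname(norm_rows)),
       cv = do.call(rbind, unname(cv_rows)),
       anomalies = anomalies,
       excluded = if (length(excluded)) do.call(rbind, unname(excluded))
                  else data.frame())
}
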