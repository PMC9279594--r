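# Builders for small in-code fixtures shared across test files.

# Wide expression matrix from a named list culture -> list(feature -> series).
toy_matrix <- function(series_by_culture, kind = "gene", status = NULL) {
  rows <- list()
  for (cid in names(series_by_culture)) {
    feats <- series_by_culture[[cid]]
    for (fid in names(feats)) {
      vals <- as.list(feats[[fid]])
      names(vals) <- sprintf("t%d", seq_along(vals) - 1L)
      st <- if (!is.null(status) && fid %in% status) "fail" else "ok"
      rows[[paste(cid, fid)]] <- data.frame(
        feature_id = fid, feature_kind = kind, culture_id = cid,
        status = st, vals, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Single-culture matrix where every feature shares the housekeeping series.
toy_single_culture <- function(feats, hk = c(10, 10, 10), hk_id = "GAPDH",
                               status = NULL) {
  feats[[hk_id]] <- hk
  toy_matrix(list(C1 = feats), status = status)
}

# Independent brute-force hypergeometric upper tail via binomial coefficients
# (oracle; deliberately avoids phyper).
oracle_hyper_tail <- function(k, K, n, N) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  if (k > hi) return(0)
  x <- max(k, lo):hi
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

# Independent normal-equations OLS oracle (deliberately avoids lm).
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}
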