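# Upper-tail hypergeometric probability P(X >= k) for a 2x2 over-
# representation table: k query hits among n_query draws from a background of
# N_background genes of which K_background carry the term. Vectorized.
hypergeom_tail_p <- function(k, K_background, n_query, N_background) {
  stats::phyper(k - 1, K_background, N_background - K_background, n_query,
                lower.tail = FALSE)
}

#' Fisher's exact overrepresentation of one annotation term
#'
#' One-sided hypergeometric upper-tail test of whether a query gene list is
#' enriched for members of an annotation term, with the standard fold
#' enrichment `(k / n_query) / (K / N_background)`.
#'
#' @param query Character vector of query gene ids (must be contained in the
#'   background).
#' @param term Character vector of the term's member gene ids (intersected
#'   with the background before testing).
#' @param background Character vector of all assayable gene ids.
#' @param term_id,term_name Labels carried into the result row.
#' @return A one-row data frame: `term_id`, `term_name`, `k` (query hits),
#'   `n_query`, `K` (background hits), `N_background`, `fold_enrichment`
#'   (0 when `k = 0`), and one-sided `p`.
#' @export
fisher_overrepresentation <- function(query, term, background,
                                      term_id = "term", term_name = term_id) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (length(background) == 0L) abort_input("background must be non-empty")
  if (length(query) == 0L) abort_input("query must be non-empty")
  outside <- setdiff(query, background)
  if (length(outside)) {
    abort_input("query gene(s) not in background: ",
                paste(utils::head(outside, 5), collapse = ", "))
  }
  members <- intersect(unique(as.character(term)), background)
  k <- length(intersect(query, members))
  n <- length(query)
  K <- length(members)
  N <- length(background)
  fold <- if (k == 0) 0 else (k / n) / (K / N)
  data.frame(term_id = term_id, term_name = term_name, k = k, n_query = n,
             K = K, N_background = N, fold_enrichment = fold,
             p = hypergeom_tail_p(k, K, n, N), stringsAsFactors = FALSE)
}

#' Overrepresentation table across an annotation collection
#'
#' Tests every annotation term against the query with
#' [fisher_overrepresentation()], adjusts p-values across all tested terms by
#' Benjamini-Hochberg FDR, and sorts by q then by decreasing fold enrichment.
#' Terms with no members in the background are skipped (with a message).
#'
#' @param query Character vector of query gene ids.
#' @param annotations Named list of character vectors (term id -> members),
#'   e.g. from [read_gmt()].
#' @param background All assayable gene ids. When `NULL` (default) the union
#'   of all annotation members and the query is used.
#' @param alpha Significance level used for the `significant` flag.
#' @return A data frame of [fisher_overrepresentation()] rows plus `q` and
#'   `significant`.
#' @export
enrich_table <- function(query, annotations, background = NULL,
                         alpha = 0.05) {
  if (!is.list(annotations) || is.null(names(annotations))) {
    abort_input("annotations must be a named list of member vectors")
  }
  if (is.null(background)) {
    background <- unique(c(unlist(annotations, use.names = FALSE),
                           as.character(query)))
  }
  background <- unique(as.character(background))
  rows <- list()
  for (tid in names(annotations)) {
    members <- intersect(unique(as.character(annotations[[tid]])), background)
    if (length(members) == 0L) {
      message("term '", tid, "' has no members in the background; skipped")
      next
    }
    rows[[tid]] <- fisher_overrepresentation(query, members, background,
                                             term_id = tid)
  }
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n_query = integer(0), K = integer(0),
                      N_background = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < alpha
  out <- out[order(out$q, -out$fold_enrichment, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
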