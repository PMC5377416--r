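#' Validate a co-citation query
#'
#' A co-citation query holds the four article counts of the literature
#' screen: `N` articles in the corpus, `n` mentioning the disease, `m`
#' mentioning the gene and `k` mentioning both.
#'
#' @param N,n,m,k Non-negative integer counts with `n <= N`, `m <= N`,
#'   `k <= min(n, m)` and `n + m - k <= N` (the mention sets must fit in
#'   the corpus).
#' @return A list of class `cocitation_query`.
#' @export
cocitation_query <- function(N, n, m, k) {
  vals <- c(N = N, n = n, m = m, k = k)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("N, n, m, k must be non-negative integers", call. = FALSE)
  if (N < 1) stop("corpus size N must be positive", call. = FALSE)
  if (n > N || m > N) stop("n and m cannot exceed N", call. = FALSE)
  if (k > min(n, m)) stop("k cannot exceed min(n, m)", call. = FALSE)
  if (n + m - k > N) stop("mention sets exceed corpus: n + m - k > N", call. = FALSE)
  structure(as.list(vals), class = "cocitation_query")
}

#' Upper-tail hypergeometric co-citation probability
#'
#' Probability of observing at least `k` articles mentioning both the gene
#' and the disease when the `m` gene articles are drawn without replacement
#' from a corpus of `N` articles of which `n` mention the disease:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, n, m)`, i.e.
#' `1 - sum_{i<k} pmf(i)`. Computed from the complement of the CDF at
#' `k - 1` (log-space internally), which stays stable at corpus-scale `N`
#' where the factorial form overflows. Symmetric in `n` and `m`; `k = 0`
#' gives `p = 1`.
#'
#' @param query A [cocitation_query()], or `N` given with `n`, `m`, `k`.
#' @param n,m,k Optional scalar counts when `query` is the numeric `N`.
#' @return List of class `cocitation_score` with the `query` and `p`.
#' @examples
#' cocitation_pvalue(cocitation_query(20, 5, 4, 2))$p # ~0.2487
#' @export
cocitation_pvalue <- function(query, n = NULL, m = NULL, k = NULL) {
  if (!inherits(query, "cocitation_query"))
    query <- cocitation_query(query, n, m, k)
  p <- if (query$k == 0) 1
       else stats::phyper(query$k - 1, query$n, query$N - query$n, query$m,
                          lower.tail = FALSE)
  structure(list(query = query, p = min(1, p)), class = "cocitation_score")
}

#' @export
print.cocitation_score <- function(x, ...) {
  q <- x$query
  cat(sprintf("co-citation tail p = %.4g (N = %d, n = %d, m = %d, k = %d)\n",
              x$p, q$N, q$n, q$m, q$k))
  invisible(x)
}

#' Read an alias map for gene-symbol normalization
#'
#' TSV with columns `mention` and `symbol`; many mentions may map to one
#' canonical symbol, lookup is case-insensitive.
#'
#' @param path Path to the TSV.
#' @return Named character vector (names: lower-cased mentions; values:
#'   canonical symbols) of class `alias_map`.
#' @export
read_alias_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mention", "symbol") %in% names(d)))
    stop("alias map needs columns 'mention' and 'symbol'", call. = FALSE)
  alias_map(d$mention, d$symbol)
}

#' Build an alias map in memory
#'
#' @param mentions Character vector of mention strings.
#' @param symbols Canonical symbol for each mention.
#' @return An `alias_map` (named character vector, lower-cased keys).
#' @export
alias_map <- function(mentions, symbols) {
  stopifnot(length(mentions) == length(symbols))
  key <- tolower(trimws(mentions))
  val <- toupper(trimws(symbols))
  dup <- duplicated(key)
  if (any(dup & !duplicated(paste(key, val))))
    stop("a mention maps to more than one canonical symbol", call. = FALSE)
  structure(stats::setNames(val[!dup], key[!dup]), class = "alias_map")
}

#' Normalize gene mentions within one document
#'
#' Maps each mention to its canonical symbol (case-insensitive), flags
#' unknown mentions as pass-throughs, and collapses duplicates so each
#' symbol counts at most once per document.
#'
#' @param mentions Character vector of mention strings from one document.
#' @param aliases An [alias_map()].
#' @return Data frame `symbol`, `matched` (logical), one row per distinct
#'   symbol.
#' @export
normalize_mentions <- function(mentions, aliases) {
  stopifnot(inherits(aliases, "alias_map"))
  if (length(mentions) == 0)
    return(data.frame(symbol = character(), matched = logical()))
  key <- tolower(trimws(mentions))
  hit <- key %in% names(aliases)
  sym <- ifelse(hit, unname(aliases[key]), trimws(mentions))
  d <- data.frame(symbol = sym, matched = hit)
  d <- d[!duplicated(d$symbol), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Score a gene co-occurrence count table against a disease corpus
#'
#' Each row `(gene, m, k)` is scored with [cocitation_pvalue()] under the
#' shared corpus constants `N` (total articles) and `n` (disease articles).
#' Rows are ranked by ascending p, ties broken by descending `k` then by
#' symbol, and flagged as disease-related at `p <= alpha`. Malformed rows
#' are reported with their index and skipped; the run continues.
#'
#' @param counts Data frame with columns `gene`, `m`, `k`.
#' @param N,n Corpus constants.
#' @param alpha Flagging threshold (default 0.05, no multiplicity
#'   correction, matching per-gene raw-p reporting).
#' @param adjust If `TRUE`, add a Benjamini-Hochberg `q` column.
#' @return Data frame `gene`, `m`, `k`, `p`, `flagged` (+ optional `q`),
#'   sorted as described.
#' @export
score_corpus <- function(counts, N, n, alpha = 0.05, adjust = FALSE) {
  if (!all(c("gene", "m", "k") %in% names(counts)))
    stop("'counts' needs columns gene, m, k", call. = FALSE)
  ok <- rep(TRUE, nrow(counts))
  p <- rep(NA_real_, nrow(counts))
  for (i in seq_len(nrow(counts))) {
    res <- tryCatch(
      cocitation_pvalue(cocitation_query(N, n, counts$m[i], counts$k[i]))$p,
      error = function(e) {
        warning(sprintf("row %d (%s) skipped: %s", i, counts$gene[i],
                        conditionMessage(e)), call. = FALSE)
        NA_real_
      })
    if (is.na(res)) ok[i] <- FALSE else p[i] <- res
  }
  d <- counts[ok, c("gene", "m", "k"), drop = FALSE]
  d$p <- p[ok]
  d$flagged <- d$p <= alpha
  if (adjust) d$q <- stats::p.adjust(d$p, method = "BH")
  d <- d[order(d$p, -d$k, d$gene), , drop = FALSE]
  rownames(d) <- NULL
  d
}
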