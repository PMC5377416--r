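#' Default microRNA target-prediction platform names
#'
#' The eleven platforms whose nominations are tallied by default.
#'
#' @return Character vector of 11 platform labels.
#' @export
default_platforms <- function() {
  c("TargetScan", "MirTarget2", "DIANA-microT", "PicTar", "PITA",
    "MicroInspector", "miRanda", "RNA22", "miTarget", "RNAhybrid",
    "NBmiRTar")
}

#' Build a gene-by-platform prediction matrix
#'
#' Nominations are binary: a platform either lists a gene or it does not.
#' Symbols are upper-cased and, when an alias map is supplied, normalized
#' before tallying so the same gene reported under different symbols by
#' different platforms is merged (rows combined with logical OR).
#'
#' @param nominations Either a long data frame with columns `gene` and
#'   `platform`, or a logical matrix with gene rownames and platform
#'   colnames.
#' @param platforms Platform universe (defaults to the union observed, or
#'   the matrix colnames). Duplicate labels are an error.
#' @param aliases Optional [alias_map()] applied to gene symbols.
#' @return Logical matrix of class `prediction_matrix` (genes x platforms).
#' @export
prediction_matrix <- function(nominations, platforms = NULL, aliases = NULL) {
  if (is.matrix(nominations)) {
    m <- nominations != 0
    genes <- rownames(m); plats <- colnames(m)
    if (is.null(genes) || is.null(plats))
      stop("matrix input needs gene rownames and platform colnames", call. = FALSE)
    long <- data.frame(gene = rep(genes, times = ncol(m)),
                       platform = rep(plats, each = nrow(m)))[as.vector(m), ]
  } else {
    if (!all(c("gene", "platform") %in% names(nominations)))
      stop("'nominations' needs columns gene and platform", call. = FALSE)
    long <- nominations[c("gene", "platform")]
  }
  sym <- toupper(trimws(long$gene))
  if (!is.null(aliases)) {
    key <- tolower(sym)
    hit <- key %in% names(aliases)
    sym[hit] <- unname(aliases[key[hit]])
  }
  if (is.null(platforms)) platforms <- sort(unique(long$platform))
  if (anyDuplicated(platforms)) stop("duplicate platform labels", call. = FALSE)
  unknown <- setdiff(unique(long$platform), platforms)
  if (length(unknown))
    stop("nominations from platforms outside the universe: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  genes <- sort(unique(sym))
  votes <- matrix(FALSE, length(genes), length(platforms),
                  dimnames = list(genes, platforms))
  votes[cbind(match(sym, genes), match(long$platform, platforms))] <- TRUE
  structure(votes, class = c("prediction_matrix", "matrix", "array"))
}

#' Count nominating platforms per gene
#'
#' @param matrix A [prediction_matrix()].
#' @return Data frame `gene`, `vote_count`, one row per gene, in gene
#'   order.
#' @export
tally_votes <- function(matrix) {
  stopifnot(inherits(matrix, "prediction_matrix"))
  d <- data.frame(gene = rownames(matrix), vote_count = rowSums(matrix))
  rownames(d) <- NULL
  d
}

#' Consensus target list at a nomination threshold
#'
#' A gene is accepted as a consensus target when nominated by at least
#' `threshold` platforms (default 4 of the 11).
#'
#' @param matrix A [prediction_matrix()].
#' @param threshold Integer between 1 and the number of platforms.
#' @return Sorted character vector of accepted gene symbols.
#' @export
consensus_targets <- function(matrix, threshold = 4L) {
  stopifnot(inherits(matrix, "prediction_matrix"))
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 1L || threshold > ncol(matrix))
    stop(sprintf("threshold must be in 1..%d (number of platforms)",
                 ncol(matrix)), call. = FALSE)
  t <- tally_votes(matrix)
  sort(t$gene[t$vote_count >= threshold])
}

#' Vote table with acceptance flags
#'
#' @inheritParams consensus_targets
#' @return Data frame `gene`, `vote_count`, `accepted`.
#' @export
vote_table <- function(matrix, threshold = 4L) {
  t <- tally_votes(matrix)
  acc <- consensus_targets(matrix, threshold)
  t$accepted <- t$gene %in% acc
  t
}

#' Read per-platform nomination lists or a long nomination TSV
#'
#' @param paths Either a named character vector of gene-list files (one per
#'   platform, names are platform labels; one symbol per line) or a single
#'   TSV with columns `gene` and `platform`.
#' @param aliases Optional [alias_map()].
#' @return A [prediction_matrix()].
#' @export
read_predictions <- function(paths, aliases = NULL) {
  if (length(paths) == 1L && is.null(names(paths))) {
    long <- utils::read.delim(paths, stringsAsFactors = FALSE)
  } else {
    if (is.null(names(paths)) || any(names(paths) == ""))
      stop("per-platform files must be named by platform", call. = FALSE)
    long <- do.call(rbind, lapply(names(paths), function(pl) {
      genes <- readLines(paths[[pl]])
      genes <- genes[nzchar(trimws(genes))]
      data.frame(gene = genes, platform = pl)
    }))
  }
  prediction_matrix(long, aliases = aliases)
}
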