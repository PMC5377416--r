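#' Named gene set
#'
#' @param name Label for the set.
#' @param members Character vector of gene symbols; de-duplicated, must be
#'   non-empty unless `allow_empty = TRUE` (used for intersection results).
#' @param allow_empty Permit an empty member list.
#' @return List of class `gene_set` with `name` and sorted unique `members`.
#' @export
gene_set <- function(name, members, allow_empty = FALSE) {
  members <- sort(unique(toupper(trimws(as.character(members)))))
  members <- members[nzchar(members)]
  if (!allow_empty && length(members) == 0)
    stop("gene set '", name, "' has no members", call. = FALSE)
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' Intersect two gene sets
#'
#' Commutative, associative and idempotent; the result's name records the
#' provenance. An empty intersection is allowed and signalled with a
#' message.
#'
#' @param a,b [gene_set()] objects.
#' @return A `gene_set` with `members = a$members` intersected with
#'   `b$members`.
#' @export
intersect_sets <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  common <- intersect(a$members, b$members)
  if (length(common) == 0)
    message("gene sets '", a$name, "' and '", b$name, "' are disjoint")
  gene_set(paste(a$name, b$name, sep = " & "), common, allow_empty = TRUE)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to the text file.
#' @param name Set label (defaults to the file name).
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  gene_set(name, readLines(path))
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   then member genes).
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40), call. = FALSE)
    gene_set(f[1], f[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (defaults
#'   to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(s, d)
    paste(c(s$name, d, s$members), collapse = "\t"),
    sets, descriptions)
  writeLines(lines, path)
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway, the probability of an overlap at least as large as
#' observed when `|query|` genes are drawn from a background of size `B`
#' containing the pathway's members as successes: the same upper-tail
#' hypergeometric probability as [cocitation_pvalue()], parameterized as
#' population `B`, successes = pathway size, draws = query size.
#'
#' @param query A [gene_set()] of genes of interest.
#' @param pathways List of [gene_set()] pathways.
#' @param background Either `NULL` (default: the union of all pathway
#'   members), an integer genome size, or a [gene_set()] universe that
#'   must contain every pathway member. Query genes outside an explicit
#'   background are dropped from the draw.
#' @return Data frame `pathway`, `size`, `count`, `p`, `genes`
#'   (comma-joined overlap), sorted by `p` ascending then pathway label.
#' @export
pathway_enrichment <- function(query, pathways, background = NULL) {
  stopifnot(inherits(query, "gene_set"))
  if (inherits(pathways, "gene_set")) pathways <- list(pathways)
  if (length(query$members) == 0) stop("query set is empty", call. = FALSE)
  if (is.null(background)) {
    universe <- sort(unique(unlist(lapply(pathways, `[[`, "members"))))
    B <- length(universe)
    qry <- intersect(query$members, universe)
  } else if (is.numeric(background)) {
    B <- as.integer(background)
    universe <- NULL
    qry <- query$members
  } else if (inherits(background, "gene_set")) {
    universe <- background$members
    bad <- vapply(pathways, function(p) any(!p$members %in% universe), TRUE)
    if (any(bad))
      stop("pathway member(s) outside the explicit background: ",
           paste(vapply(pathways[bad], `[[`, "", "name"), collapse = ", "),
           call. = FALSE)
    B <- length(universe)
    qry <- intersect(query$members, universe)
  } else stop("unsupported 'background'", call. = FALSE)
  rows <- lapply(pathways, function(pw) {
    members <- if (is.null(universe)) pw$members else intersect(pw$members, universe)
    hit <- intersect(qry, members)
    K <- length(members); x <- length(hit); nq <- length(qry)
    p <- if (x == 0) 1
         else stats::phyper(x - 1, K, B - K, nq, lower.tail = FALSE)
    data.frame(pathway = pw$name, size = K, count = x, p = min(1, p),
               genes = paste(sort(hit), collapse = ","))
  })
  d <- do.call(rbind, rows)
  d <- d[order(d$p, d$pathway), , drop = FALSE]
  rownames(d) <- NULL
  d
}

canon_edges <- function(from, to) {
  a <- pmin(from, to); b <- pmax(from, to)
  data.frame(from = a, to = b)
}

new_network <- function(nodes, edges) {
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(nodes)), edges = edges),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene network: %d nodes, %d undirected edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              paste(sort(unique(unlist(strsplit(x$edges$sources, "|",
                                                fixed = TRUE)))),
                    collapse = ", ")))
  invisible(x)
}

#' Assemble an undirected regulatory network from tagged edge sources
#'
#' Merges several edge tables (e.g. pathway relations, protein-protein
#' interactions, literature co-occurrence) into one undirected network.
#' Symbols are upper-cased and trimmed; self-loops are dropped with a
#' message; malformed rows (missing or empty endpoints) are skipped with a
#' message; an edge present in several sources carries all its tags but is
#' counted once.
#'
#' @param edge_sources Named list of data frames, each with the endpoint
#'   symbols in its first two columns; the list names are the source tags
#'   (e.g. `"pathway_relation"`, `"ppi"`, `"literature"`).
#' @return A `gene_network`: sorted `nodes` and an `edges` data frame with
#'   `from`, `to` (from < to) and `sources` (`|`-joined tags).
#' @export
assemble_network <- function(edge_sources) {
  if (length(edge_sources) == 0)
    return(new_network(character(),
                       data.frame(from = character(), to = character(),
                                  sources = character())))
  if (is.null(names(edge_sources)) || any(names(edge_sources) == ""))
    stop("'edge_sources' must be a named list (names are source tags)",
         call. = FALSE)
  all_edges <- list()
  for (tag in names(edge_sources)) {
    d <- edge_sources[[tag]]
    if (ncol(d) < 2) stop("edge table for '", tag, "' needs two symbol columns",
                          call. = FALSE)
    from <- toupper(trimws(as.character(d[[1]])))
    to <- toupper(trimws(as.character(d[[2]])))
    bad <- is.na(from) | is.na(to) | !nzchar(from) | !nzchar(to)
    if (any(bad))
      message(sum(bad), " malformed row(s) skipped in source '", tag, "'")
    from <- from[!bad]; to <- to[!bad]
    loops <- from == to
    if (any(loops))
      message(sum(loops), " self-loop(s) dropped in source '", tag, "'")
    ce <- canon_edges(from[!loops], to[!loops])
    ce <- ce[!duplicated(ce), , drop = FALSE]
    if (nrow(ce)) ce$tag <- tag
    all_edges[[tag]] <- ce
  }
  e <- do.call(rbind, all_edges)
  if (is.null(e) || nrow(e) == 0)
    return(new_network(character(),
                       data.frame(from = character(), to = character(),
                                  sources = character())))
  key <- paste(e$from, e$to, sep = "\r")
  agg <- lapply(split(e$tag, key), function(tags)
    paste(sort(unique(tags)), collapse = "|"))
  uniq <- e[!duplicated(key), c("from", "to"), drop = FALSE]
  uniq$sources <- unlist(agg[paste(uniq$from, uniq$to, sep = "\r")])
  new_network(c(uniq$from, uniq$to), uniq)
}

#' Hub-gene connectivity z-test
#'
#' Each gene's degree is standardized against the degree distribution of
#' the candidate population (all network nodes, or the supplied hub-gene
#' list) using the sample mean and the n - 1 sample sd, and tested with a
#' one-sided upper-tail standard-normal probability: small p marks a gene
#' far more connected than its peers.
#'
#' @param net A `gene_network` from [assemble_network()].
#' @param hub_genes Optional character vector restricting the population;
#'   listed genes absent from the network count with degree 0.
#' @return Data frame `gene`, `degree`, `z`, `p`, sorted by degree
#'   descending then symbol.
#' @export
connectivity_ztest <- function(net, hub_genes = NULL) {
  stopifnot(inherits(net, "gene_network"))
  if (length(net$nodes) == 0) stop("network is empty", call. = FALSE)
  ends <- c(net$edges$from, net$edges$to)
  pop <- if (is.null(hub_genes)) net$nodes else sort(unique(toupper(trimws(hub_genes))))
  deg <- vapply(pop, function(g) sum(ends == g), 0L)
  if (length(pop) < 2 || stats::sd(deg) == 0)
    stop("degenerate degree population: all degrees equal", call. = FALSE)
  z <- (deg - mean(deg)) / stats::sd(deg)
  d <- data.frame(gene = pop, degree = as.integer(deg), z = z,
                  p = stats::pnorm(z, lower.tail = FALSE))
  d <- d[order(-d$degree, d$gene), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read a SIF-style edge list
#'
#' Lines are `source <tab> interaction <tab> target`; a line with a single
#' token declares an isolated node. Multiple relationship tags for one
#' node pair are merged.
#'
#' @param path Path to the SIF file.
#' @return A `gene_network` whose edge `sources` carry the SIF interaction
#'   tags.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  singles <- character(); from <- character(); to <- character(); tag <- character()
  for (l in lines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) == 1) singles <- c(singles, f[1])
    else if (length(f) >= 3) {
      from <- c(from, rep(f[2 - 1], length(f) - 2))
      to <- c(to, f[3:length(f)])
      tag <- c(tag, rep(f[2], length(f) - 2))
    } else stop("malformed SIF line: ", l, call. = FALSE)
  }
  nets <- lapply(split(data.frame(from, to), tag), identity)
  net <- assemble_network(nets)
  new_network(c(net$nodes, toupper(trimws(singles))), net$edges)
}

#' Export a network to SIF or GraphML
#'
#' SIF export writes one line per edge per source tag (and bare lines for
#' isolated nodes); GraphML export (via igraph) stores the joined tags in
#' an edge attribute `sources`. Both formats round-trip through
#' [import_network()] with identical node and edge sets and preserved
#' tags.
#'
#' @param net A `gene_network`.
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  stopifnot(inherits(net, "gene_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- character()
    if (nrow(net$edges)) {
      per_tag <- lapply(seq_len(nrow(net$edges)), function(i) {
        tags <- strsplit(net$edges$sources[i], "|", fixed = TRUE)[[1]]
        sprintf("%s\t%s\t%s", net$edges$from[i], tags, net$edges$to[i])
      })
      lines <- unlist(per_tag)
    }
    iso <- setdiff(net$nodes, c(net$edges$from, net$edges$to))
    writeLines(c(lines, iso), path)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(net$edges)) net$edges else
        data.frame(from = character(), to = character(), sources = character()),
      directed = FALSE, vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"sif"` or `"graphml"`.
#' @return A `gene_network`.
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") return(read_sif(path))
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes <- igraph::V(g)$name
  if (nrow(ed) == 0)
    return(new_network(nodes, data.frame(from = character(), to = character(),
                                         sources = character())))
  ce <- canon_edges(ed$from, ed$to)
  ce$sources <- if ("sources" %in% names(ed)) ed$sources else "imported"
  new_network(nodes, ce[!duplicated(ce[c("from", "to")]), , drop = FALSE])
}
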