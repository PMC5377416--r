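#' Seeded two-group Gaussian cohort
#'
#' Draws sample-level expression values for one case/control cohort from
#' Gaussian arms with the requested means and sds. Identical
#' specification and seed give identical tables.
#'
#' @param n_case,n_control Arm sizes (>= 2).
#' @param mean_case,mean_control Arm means.
#' @param sd_case,sd_control Arm sds (> 0).
#' @param seed Integer seed.
#' @return Data frame `sample_id`, `group`, `value` (the sample-level TSV
#'   dialect read by [read_samples_tsv()]).
#' @export
gen_cohort <- function(n_case, n_control, mean_case, mean_control,
                       sd_case, sd_control, seed) {
  stopifnot(n_case >= 2, n_control >= 2, sd_case > 0, sd_control > 0)
  set.seed(as.integer(seed))
  data.frame(
    sample_id = c(sprintf("case_%03d", seq_len(n_case)),
                  sprintf("ctrl_%03d", seq_len(n_control))),
    group = c(rep("case", n_case), rep("control", n_control)),
    value = c(stats::rnorm(n_case, mean_case, sd_case),
              stats::rnorm(n_control, mean_control, sd_control))
  )
}

#' Seeded random-effects meta-analysis panel
#'
#' Generates `K` two-arm studies under the random-effects model the pooling
#' machinery assumes: each study's true standardized effect is drawn
#' `Normal(true_smd, tau^2)`, arm sizes are drawn uniformly from
#' `n_range`, and arm summaries are computed from Gaussian raw draws
#' (control arm `N(0, 1)`, case arm `N(theta_i, 1)`), so the summaries are
#' internally consistent with the generating effect.
#'
#' @param K Number of studies (>= 1).
#' @param true_smd True standardized mean difference.
#' @param tau Between-study sd (>= 0).
#' @param n_range Length-2 integer range of per-arm sizes (default c(20, 80)).
#' @param seed Integer seed.
#' @return Study summary data frame in the [read_studies_tsv()] layout,
#'   `source = "synthetic"`.
#' @export
gen_meta_panel <- function(K, true_smd, tau, n_range = c(20, 80), seed) {
  stopifnot(K >= 1, tau >= 0, length(n_range) == 2, n_range[1] >= 2)
  set.seed(as.integer(seed))
  sizes <- seq(n_range[1], n_range[2])
  rows <- lapply(seq_len(K), function(i) {
    theta <- stats::rnorm(1, true_smd, tau)
    n1 <- sizes[sample.int(length(sizes), 1)]
    n2 <- sizes[sample.int(length(sizes), 1)]
    case <- stats::rnorm(n1, theta, 1)
    ctrl <- stats::rnorm(n2, 0, 1)
    data.frame(study_id = sprintf("sim_%03d", i),
               n_case = n1, mean_case = mean(case), sd_case = stats::sd(case),
               n_control = n2, mean_control = mean(ctrl),
               sd_control = stats::sd(ctrl), source = "synthetic")
  })
  do.call(rbind, rows)
}

#' Seeded co-citation count corpus
#'
#' For each gene, the article count `m` is drawn uniformly from `m_range`
#' and the co-occurrence count `k` is drawn from the hypergeometric null
#' `Hypergeometric(N, n, m)` and then inflated by the gene's enrichment
#' factor (`k = round(factor * k_null)`, capped at `min(n, m)`). Factor 1
#' leaves the null draw untouched, so the flagged fraction at alpha = 0.05
#' stays at (or, by discreteness, below) the nominal rate; factors well
#' above 1 plant detectable gene-disease associations.
#'
#' @param N Corpus size; `n` disease article count (`n <= N`).
#' @param n Disease article count.
#' @param gene_count Number of genes.
#' @param enrichment_factors Scalar or per-gene multiplier (>= 0),
#'   recycled.
#' @param m_range Range for the per-gene article counts (default
#'   `c(N/200, N/20)` rounded, at least 1).
#' @param seed Integer seed.
#' @return Data frame `gene`, `m`, `k` with attribute `"planted"` marking
#'   genes whose factor differs from 1.
#' @export
gen_corpus <- function(N, n, gene_count, enrichment_factors = 1,
                       m_range = NULL, seed) {
  stopifnot(N >= 1, n >= 0, n <= N, gene_count >= 0,
            all(enrichment_factors >= 0))
  set.seed(as.integer(seed))
  if (gene_count == 0)
    return(data.frame(gene = character(), m = integer(), k = integer()))
  if (is.null(m_range))
    m_range <- pmax(1, round(c(N / 200, N / 20)))
  fac <- rep_len(enrichment_factors, gene_count)
  mvals <- seq(m_range[1], m_range[2])
  m <- mvals[sample.int(length(mvals), gene_count, replace = TRUE)]
  k_null <- stats::rhyper(gene_count, n, N - n, m)
  k <- pmin(pmin(n, m), round(fac * k_null))
  d <- data.frame(gene = sprintf("G%04d", seq_len(gene_count)), m = m, k = k)
  attr(d, "planted") <- d$gene[fac != 1]
  d
}

#' Seeded prediction matrix with planted consensus targets
#'
#' Planted targets receive nominations from at least `min_votes` platforms
#' (vote counts drawn uniformly in `min_votes..n_platforms`); decoys
#' receive at most `min_votes - 1` (0 upward). Which platforms nominate is
#' drawn uniformly.
#'
#' @param n_targets,n_decoys Gene counts.
#' @param platforms Platform labels (default [default_platforms()]).
#' @param min_votes Acceptance threshold being planted (default 4).
#' @param seed Integer seed.
#' @return A [prediction_matrix()] with attribute `"planted"` naming the
#'   target genes.
#' @export
gen_predictions <- function(n_targets, n_decoys,
                            platforms = default_platforms(),
                            min_votes = 4L, seed) {
  stopifnot(n_targets >= 0, n_decoys >= 0,
            min_votes >= 1, min_votes <= length(platforms))
  set.seed(as.integer(seed))
  genes <- c(sprintf("TARGET%03d", seq_len(n_targets)),
             sprintf("DECOY%03d", seq_len(n_decoys)))
  votes <- matrix(FALSE, length(genes), length(platforms),
                  dimnames = list(genes, platforms))
  for (i in seq_along(genes)) {
    nv <- if (i <= n_targets)
      sample(min_votes:length(platforms), 1)
    else
      sample(0:(min_votes - 1L), 1)
    if (nv > 0)
      votes[i, sample(seq_along(platforms), nv)] <- TRUE
  }
  pm <- prediction_matrix(votes)
  attr(pm, "planted") <- toupper(genes[seq_len(n_targets)])
  pm
}

#' Seeded pathway collection with one planted enriched pathway
#'
#' Builds `n_pathways` gene sets over a background universe; the first
#' pathway draws `planted_frac` of its members from the supplied query
#' genes (planted enrichment), the rest draw uniformly from the universe.
#'
#' @param query_genes Character vector the planted pathway over-samples.
#' @param universe_size Number of background genes (symbols `BG0001`...).
#' @param n_pathways Number of pathways.
#' @param pathway_size Members per pathway.
#' @param planted_frac Fraction of the first pathway drawn from
#'   `query_genes` (default 0.8).
#' @param seed Integer seed.
#' @return Named list of [gene_set()]s; the planted pathway is named
#'   `"planted_pathway"`.
#' @export
gen_pathways <- function(query_genes, universe_size = 500, n_pathways = 10,
                         pathway_size = 20, planted_frac = 0.8, seed) {
  stopifnot(planted_frac >= 0, planted_frac <= 1,
            pathway_size <= universe_size)
  set.seed(as.integer(seed))
  universe <- c(sprintf("BG%04d", seq_len(universe_size)),
                toupper(query_genes))
  sets <- vector("list", n_pathways)
  n_from_query <- min(length(query_genes), round(planted_frac * pathway_size))
  planted <- c(sample(toupper(query_genes), n_from_query),
               sample(sprintf("BG%04d", seq_len(universe_size)),
                      pathway_size - n_from_query))
  sets[[1]] <- gene_set("planted_pathway", planted)
  for (i in seq_len(n_pathways - 1)) {
    sets[[i + 1]] <- gene_set(sprintf("null_pathway_%02d", i),
                              sample(universe, pathway_size))
  }
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Realize an exact degree sequence as an undirected network
#'
#' Deterministic Havel-Hakimi pairing: the highest-degree node is
#' connected to the next-highest nodes, repeatedly. Realizes the plan
#' exactly when the sequence is graphical; otherwise (odd degree sum or
#' failure of the Erdos-Gallai condition encountered during pairing) an
#' explanatory error is raised. No randomness is involved, so a given plan
#' always yields the same edge list.
#'
#' @param degrees Named integer vector: node symbols and their intended
#'   degrees.
#' @return A `gene_network` whose degree sequence equals `degrees`
#'   (source tag `"synthetic"`).
#' @export
gen_network <- function(degrees) {
  if (is.null(names(degrees)) || any(names(degrees) == ""))
    stop("'degrees' must be a named vector", call. = FALSE)
  deg <- as.integer(degrees)
  if (any(deg < 0)) stop("degrees must be non-negative", call. = FALSE)
  if (sum(deg) %% 2 != 0)
    stop("degree plan is not graphical: odd degree sum (handshake lemma)",
         call. = FALSE)
  names(deg) <- toupper(names(degrees))
  residual <- deg
  from <- character(); to <- character()
  while (any(residual > 0)) {
    ord <- order(-residual, names(residual))
    v <- ord[1]
    d <- residual[v]
    partners <- ord[-1][residual[ord[-1]] > 0]
    if (length(partners) < d)
      stop("degree plan is not graphical: node '", names(residual)[v],
           "' cannot be saturated", call. = FALSE)
    take <- partners[seq_len(d)]
    from <- c(from, rep(names(residual)[v], d))
    to <- c(to, names(residual)[take])
    residual[v] <- 0L
    residual[take] <- residual[take] - 1L
  }
  net <- assemble_network(list(synthetic = data.frame(from, to)))
  new_network(union(net$nodes, names(deg)), net$edges)
}
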