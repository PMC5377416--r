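#' Packaged fixture paths
#'
#' Convenience accessor for the plain-text fixtures shipped with the
#' package: the 11-cohort hepatocellular-carcinoma study panel, the
#' 104-gene integrated overlap list, the 20 hub genes and their
#' interaction edge list.
#'
#' @param file One of `"studies"`, `"overlap_genes"`, `"hub_genes"`,
#'   `"hub_edges"`.
#' @return Path to the installed fixture file.
#' @export
fixture_path <- function(file = c("studies", "overlap_genes", "hub_genes",
                                  "hub_edges")) {
  file <- match.arg(file)
  fn <- switch(file,
               studies = "hcc_mir146a_studies.tsv",
               overlap_genes = "hcc_mir146a_overlap_genes.txt",
               hub_genes = "hcc_mir146a_hub_genes.txt",
               hub_edges = "hcc_mir146a_hub_edges.sif")
  system.file("extdata", fn, package = "mirnetmeta", mustWork = TRUE)
}

default_config <- function() {
  list(
    seed = 1L,
    outdir = file.path(tempdir(), "mirnetmeta_run"),
    stages = list(stats = TRUE, meta = TRUE, cocite = FALSE, vote = FALSE,
                  integrate = FALSE, enrich = FALSE, connect = TRUE,
                  network = TRUE),
    inputs = list(
      studies = fixture_path("studies"),
      corpus_counts = NULL, corpus_N = NULL, corpus_n = NULL,
      predictions = NULL, nlp_genes = NULL, pathways = NULL,
      edges = fixture_path("hub_edges"),
      hub_genes = fixture_path("hub_genes")
    ),
    thresholds = list(vote = 4L, alpha = 0.05, fc_low = 0.5, fc_high = 2,
                      het_p = 0.05, het_i2 = 50),
    smd_correction = "none"
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  if (th$alpha <= 0 || th$alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (th$vote < 1) stop("vote threshold must be >= 1", call. = FALSE)
  for (nm in c("studies", "corpus_counts", "predictions", "nlp_genes",
               "pathways", "edges", "hub_genes")) {
    p <- cfg$inputs[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop("configured input '", nm, "' does not exist: ", p, call. = FALSE)
  }
  invisible(cfg)
}

write_stage_tsv <- function(d, outdir, name) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the integrative analysis pipeline
#'
#' Orchestrates the stages end-to-end from a declarative configuration:
#' per-study two-group tests (`stats`), SMD meta-analysis with
#' heterogeneity-driven model choice and bias tests (`meta`), literature
#' co-citation scoring (`cocite`), consensus target voting (`vote`), set
#' integration (`integrate`), pathway enrichment (`enrich`), hub
#' connectivity (`connect`) and network assembly/export (`network`). Each
#' enabled stage writes a TSV into the output directory and the run ends
#' with a JSON manifest recording package version, seed, configuration and
#' key results. Identical configuration and seed give identical stage
#' TSVs. A stage failure aborts the run naming the stage; earlier outputs
#' are retained.
#'
#' @param config A list (or path to a YAML file) overriding the defaults:
#'   `seed`, `outdir`, `stages` (logical toggles), `inputs` (file paths;
#'   the packaged fixtures are the defaults for studies, edges and hub
#'   genes), `thresholds` (`vote`, `alpha`, `fc_low`, `fc_high`, `het_p`,
#'   `het_i2`) and `smd_correction` (`"none"` or `"hedges"`).
#' @return Invisibly, a list with `outdir`, `manifest` (the manifest as a
#'   list) and `results` (in-memory stage results).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(merge_config(default_config(), config))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  results <- list()
  files <- character()
  st <- cfg$stages

  if (isTRUE(st$stats) || isTRUE(st$meta)) {
    studies <- run_stage("stats", read_studies_tsv(cfg$inputs$studies))
  }
  if (isTRUE(st$stats)) {
    results$stats <- run_stage("stats", panel_t_tests(studies, "welch"))
    files["stats"] <- write_stage_tsv(results$stats, cfg$outdir, "stats_t_tests")
  }
  if (isTRUE(st$meta)) {
    results$meta <- run_stage("meta", {
      ef <- effect_sizes(studies, correction = cfg$smd_correction)
      m <- select_model(ef, p_cut = cfg$thresholds$het_p,
                        i2_cut = cfg$thresholds$het_i2)
      list(effects = ef, pooled = m,
           egger = if (nrow(ef) >= 3) egger_test(ef),
           begg = if (nrow(ef) >= 3) begg_test(ef),
           funnel = funnel_points(ef),
           loo = if (nrow(ef) >= 3) leave_one_out(ef))
    })
    m <- results$meta$pooled
    files["meta_forest"] <- write_stage_tsv(
      forest_table(results$meta$effects, m), cfg$outdir, "meta_forest")
    files["meta_funnel"] <- write_stage_tsv(results$meta$funnel, cfg$outdir,
                                            "meta_funnel")
    files["meta_summary"] <- write_stage_tsv(
      data.frame(k = m$k, pooled = m$pooled, ci_low = m$ci_low,
                 ci_high = m$ci_high, z = m$z, p = m$p, Q = m$Q,
                 p_Q = m$p_Q, I2 = m$I2, tau2 = m$tau2, model = m$model),
      cfg$outdir, "meta_summary")
  }
  if (isTRUE(st$cocite)) {
    results$cocite <- run_stage("cocite", {
      if (is.null(cfg$inputs$corpus_counts))
        stop("stage needs inputs$corpus_counts plus corpus_N and corpus_n")
      counts <- utils::read.delim(cfg$inputs$corpus_counts,
                                  stringsAsFactors = FALSE)
      score_corpus(counts, N = cfg$inputs$corpus_N, n = cfg$inputs$corpus_n,
                   alpha = cfg$thresholds$alpha)
    })
    files["cocite"] <- write_stage_tsv(results$cocite, cfg$outdir,
                                       "cocitation_scores")
  }
  if (isTRUE(st$vote)) {
    results$vote <- run_stage("vote", {
      if (is.null(cfg$inputs$predictions))
        stop("stage needs inputs$predictions")
      pm <- read_predictions(cfg$inputs$predictions)
      vote_table(pm, threshold = cfg$thresholds$vote)
    })
    files["vote"] <- write_stage_tsv(results$vote, cfg$outdir, "vote_table")
  }
  if (isTRUE(st$integrate)) {
    results$integrate <- run_stage("integrate", {
      disease <- if (!is.null(cfg$inputs$nlp_genes))
        read_gene_list(cfg$inputs$nlp_genes, "disease_related")
      else if (!is.null(results$cocite))
        gene_set("disease_related", results$cocite$gene[results$cocite$flagged])
      else stop("stage needs inputs$nlp_genes or the cocite stage enabled")
      targets <- if (!is.null(results$vote))
        gene_set("consensus_targets",
                 results$vote$gene[results$vote$accepted])
      else stop("stage needs the vote stage enabled")
      intersect_sets(disease, targets)
    })
    files["integrate"] <- write_stage_tsv(
      data.frame(gene = results$integrate$members), cfg$outdir,
      "integrated_genes")
  }
  if (isTRUE(st$enrich)) {
    results$enrich <- run_stage("enrich", {
      if (is.null(cfg$inputs$pathways)) stop("stage needs inputs$pathways (GMT)")
      query <- if (!is.null(results$integrate)) results$integrate
      else gene_set("overlap", readLines(fixture_path("overlap_genes")))
      pathway_enrichment(query, read_gmt(cfg$inputs$pathways))
    })
    files["enrich"] <- write_stage_tsv(results$enrich, cfg$outdir,
                                       "pathway_enrichment")
  }
  if (isTRUE(st$connect) || isTRUE(st$network)) {
    net <- run_stage("network", read_sif(cfg$inputs$edges))
  }
  if (isTRUE(st$connect)) {
    results$connect <- run_stage("connect", {
      hubs <- if (!is.null(cfg$inputs$hub_genes))
        readLines(cfg$inputs$hub_genes)
      connectivity_ztest(net, hub_genes = hubs)
    })
    files["connect"] <- write_stage_tsv(results$connect, cfg$outdir,
                                        "connectivity")
  }
  if (isTRUE(st$network)) {
    results$network <- net
    files["network_sif"] <- export_network(
      net, file.path(cfg$outdir, "network.sif"), "sif")
    files["network_graphml"] <- export_network(
      net, file.path(cfg$outdir, "network.graphml"), "graphml")
  }

  cfg_file <- file.path(cfg$outdir, "config.yaml")
  cfg_serializable <- cfg
  yaml::write_yaml(cfg_serializable, cfg_file)
  manifest <- list(
    package = "mirnetmeta",
    version = as.character(utils::packageVersion("mirnetmeta")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages_run = names(files),
    outputs = as.list(files),
    key_results = list(
      pooled_smd = if (!is.null(results$meta)) results$meta$pooled$pooled,
      meta_model = if (!is.null(results$meta)) results$meta$pooled$model,
      top_hub = if (!is.null(results$connect)) results$connect$gene[1],
      top_hub_p = if (!is.null(results$connect)) results$connect$p[1]
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(outdir = cfg$outdir, manifest = manifest, results = results))
}
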