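#' Default pipeline configuration
#'
#' A nested list with two blocks: `scenario` (arguments passed to
#' [scenario_config()]; used when no `inputs` block supplies file paths) and
#' `params` (per-stage analysis parameters). Every numeric decision of the
#' pipeline is reachable here; there are no hidden constants.
#'
#' @param seed Integer seed applied to the scenario and the resampling.
#' @return A list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    scenario = list(),          # overrides for scenario_config()
    inputs = NULL,              # or list(motifs=, promoters=, focal=,
                                #   de_genes=, universe=, expression=,
                                #   mirna_targets=, target_panel=)
    params = list(
      pseudocount = 0.25,
      background = rep(0.25, 4),
      rel_threshold = 0.8,
      n_resamples = 10000L,
      statistic = "total",
      alpha = 0.05,
      k_sd = 2,
      scale = "linear"
    )
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected by [validate_config()]; missing keys take the
#' defaults of [default_config()].
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- default_config(seed = raw$seed %||% 1L)
  for (k in intersect(names(raw), c("scenario", "inputs"))) cfg[[k]] <- raw[[k]]
  for (k in names(raw$params %||% list())) cfg$params[[k]] <- raw$params[[k]]
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks types and ranges of every tunable parameter; never mutates state.
#'
#' @param config A `pipeline_config` list, or a path to a YAML config file.
#' @return Character vector of violations; empty (`character(0)`) when the
#'   config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  p <- config$params
  chk(is.numeric(config$seed) && length(config$seed) == 1L,
      "seed: must be a single integer")
  chk(is.numeric(p$rel_threshold) && p$rel_threshold >= 0 &&
        p$rel_threshold <= 1, "params.rel_threshold: must lie in [0, 1]")
  chk(is.numeric(p$pseudocount) && p$pseudocount >= 0,
      "params.pseudocount: must be >= 0")
  chk(is.numeric(p$background) && length(p$background) == 4L &&
        all(p$background > 0) && abs(sum(p$background) - 1) < 1e-8,
      "params.background: must be 4 positive probabilities summing to 1")
  chk(is.numeric(p$n_resamples) && p$n_resamples >= 1,
      "params.n_resamples: must be >= 1")
  chk(p$statistic %in% c("total", "genes_with_hit"),
      "params.statistic: must be 'total' or 'genes_with_hit'")
  chk(is.numeric(p$alpha) && p$alpha > 0 && p$alpha < 1,
      "params.alpha: must lie in (0, 1)")
  chk(is.numeric(p$k_sd) && p$k_sd >= 0, "params.k_sd: must be >= 0")
  chk(p$scale %in% c("linear", "log2"),
      "params.scale: must be 'linear' or 'log2'")
  if (is.null(config$inputs)) {
    sc <- tryCatch({
      do.call(scenario_config,
              c(list(seed = config$seed), config$scenario))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(sc)) v <- c(v, paste0("scenario: ", sc))
  }
  v
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full inference pipeline
#'
#' Executes generate (or load) -> scan -> enrichment -> cross-reference ->
#' correlation screen as one reproducible run. Writes per-stage TSVs, a
#' consolidated machine-readable `report.json` (deterministic given the
#' config), and a `manifest.json` with the config snapshot, input digests
#' and timestamps.
#'
#' @param config A `pipeline_config` (see [default_config()]), or a path to
#'   a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @return The report, invisibly (list with `venn`, `final_candidates`,
#'   `enrichment_significant`, `correlations`, output paths).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  violations <- validate_config(config)
  if (length(violations) > 0L) {
    stop("invalid pipeline config:\n  - ",
         paste(violations, collapse = "\n  - "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  log_stage <- function(...) message("[tfbscreen] ", ...)

  # -- synthetic_data ---------------------------------------------------
  truth <- NULL
  if (is.null(config$inputs)) {
    scen <- run_stage("synthetic_data", {
      cfg <- do.call(scenario_config,
                     c(list(seed = config$seed), config$scenario))
      data_dir <- file.path(out_dir, "data")
      generate_scenario(cfg, dir = data_dir)
    })
    log_stage("synthetic_data: generated scenario (",
              length(scen$universe), " genes, ",
              length(scen$motifs), " TFs)")
    motifs_pfm <- scen$motifs
    promoters <- scen$promoters
    focal_seq <- scen$focal_sequence
    genes <- gene_list(scen$de_genes, scen$universe)
    expr <- scen$expression
    mirna <- scen$mirna_targets
    truth <- scen$truth
    slopes <- scen$cfg$target_slopes
    panel <- data.frame(
      gene_id = names(slopes),
      expected_direction = ifelse(slopes < 0, "inverse",
                                  ifelse(slopes > 0, "positive", "none")),
      stringsAsFactors = FALSE)
  } else {
    inp <- config$inputs
    motifs_pfm <- run_stage("motif_model", read_jaspar(inp$motifs))
    promoters <- run_stage("motif_model", read_promoters(inp$promoters))
    focal_seq <- run_stage("crossref_filter",
                           read_promoters(inp$focal)[[1]])
    genes <- run_stage("enrichment",
                       gene_list(read_gene_list(inp$de_genes),
                                 read_gene_list(inp$universe)))
    expr <- run_stage("crossref_filter", read_expression(inp$expression))
    mirna <- run_stage("mirna_correlation",
                       read_mirna_targets(inp$mirna_targets))
    panel <- if (!is.null(inp$target_panel)) {
      run_stage("mirna_correlation",
                utils::read.delim(inp$target_panel,
                                  stringsAsFactors = FALSE))
    } else {
      data.frame(
        gene_id = setdiff(names(mirna),
                          c("sample_id", "group", "mir_a", "mir_b")),
        expected_direction = "inverse", stringsAsFactors = FALSE)
    }
  }

  # -- motif_model ------------------------------------------------------
  counts <- run_stage("motif_model", {
    pwms <- lapply(motifs_pfm, pwm_from_counts,
                   pseudocount = p$pseudocount, background = p$background)
    count_hits(pwms, promoters, rel_threshold = p$rel_threshold)
  })
  write_hit_counts(counts, file.path(out_dir, "hit_counts.tsv"))
  log_stage("motif_model: ", sum(counts), " hits over ",
            nrow(counts), " TFs x ", ncol(counts), " promoters")

  # -- enrichment -------------------------------------------------------
  enr <- run_stage("enrichment", {
    enrich_tfs(counts, genes, n_resamples = as.integer(p$n_resamples),
               seed = config$seed, statistic = p$statistic)
  })
  write_enrichment(enr, file.path(out_dir, "enrichment.tsv"))
  n_sig <- sum(enr$p_empirical < p$alpha)
  log_stage("enrichment: ", n_sig, " / ", nrow(enr), " TFs at p < ", p$alpha)

  # -- crossref_filter --------------------------------------------------
  cross <- run_stage("crossref_filter", {
    pwms <- lapply(motifs_pfm, pwm_from_counts,
                   pseudocount = p$pseudocount, background = p$background)
    focal_set <- focal_promoter_tfs(pwms, focal_seq,
                                    rel_threshold = p$rel_threshold)
    crossref_candidates(enr, focal_set, expr, alpha = p$alpha, k_sd = p$k_sd)
  })
  utils::write.table(format_num_df(cross$table),
                     file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("crossref_filter: |both| = ", length(cross$both),
            ", final candidates = ", length(cross$final_candidates))

  # -- mirna_correlation ------------------------------------------------
  correl <- run_stage("mirna_correlation",
                      screen_targets(mirna, panel, scale = p$scale))
  utils::write.table(format_num_df(correl),
                     file.path(out_dir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("mirna_correlation: ", sum(correl$significant), " / ",
            nrow(correl), " targets at p < 0.05")

  # -- report & manifest ------------------------------------------------
  report <- list(
    seed = config$seed,
    params = p,
    venn = list(enriched_only = length(cross$enriched_only),
                both = length(cross$both),
                focal_only = length(cross$focal_only)),
    enrichment_significant = n_sig,
    final_candidates = cross$final_candidates,
    candidate_table = cross$table[cross$table$venn_class == "both", ],
    correlations = correl,
    truth = truth
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- file.path(out_dir, c("hit_counts.tsv", "enrichment.tsv",
                                  "candidates.tsv", "correlations.tsv",
                                  "report.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("tfbscreen")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = config[c("seed", "scenario", "params")],
    outputs = basename(outputs),
    digests = as.list(stats::setNames(tools::md5sum(outputs),
                                      basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
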