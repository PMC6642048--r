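#' Pipeline configuration
#'
#' One object configures the full run: simulate (or load) per-cancer-type
#' cohorts, correlate every gene with the marker and checkpoint genes, rank
#' by median correlation, score complementarity, run preranked enrichment,
#' and compare responder groups. A single master seed fans out
#' deterministically to the simulation, the responder cohort, and the
#' enrichment permutations.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed.
#' @param sim a \code{sim_config}; default [simulation_config()] over
#'   [default_gene_specs()].
#' @param responder_sim a \code{responder_sim_config}.
#' @param cohort_dir optional directory of expression TSVs used instead of
#'   simulation.
#' @param responder_path optional responder TSV used instead of simulation.
#' @param marker,checkpoints marker gene and checkpoint genes (defaults
#'   CD3E; PDCD1 and CTLA4).
#' @param excluded_types cancer-type labels dropped from correlation
#'   profiling (the reference analysis drops thymoma).
#' @param min_samples minimum complete pairs per correlation cell.
#' @param gmt_path optional GMT; default: sets are derived from the ranked
#'   universe (top-gene set plus seeded random sets) so enrichment always
#'   has input.
#' @param n_perm enrichment permutations.
#' @param exclude_samples sample IDs excluded in the responder rerun;
#'   default: the simulated outlier, if any.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            sim = NULL, responder_sim = NULL,
                            cohort_dir = NULL, responder_path = NULL,
                            marker = "CD3E",
                            checkpoints = c("PDCD1", "CTLA4"),
                            excluded_types = character(0),
                            min_samples = 10L,
                            gmt_path = NULL, n_perm = 1000L,
                            exclude_samples = NULL) {
  seed <- as.integer(seed)
  if (is.null(sim) && is.null(cohort_dir))
    sim <- simulation_config(default_gene_specs(), marker = marker,
                             seed = seed)
  if (is.null(responder_sim) && is.null(responder_path))
    responder_sim <- responder_sim_config(seed = seed + 1000L)
  structure(list(out_dir = out_dir, seed = seed, sim = sim,
                 responder_sim = responder_sim, cohort_dir = cohort_dir,
                 responder_path = responder_path, marker = marker,
                 checkpoints = checkpoints, excluded_types = excluded_types,
                 min_samples = as.integer(min_samples), gmt_path = gmt_path,
                 n_perm = as.integer(n_perm),
                 exclude_samples = exclude_samples),
            class = "pipeline_config")
}

# default gene sets when no GMT is supplied: the top of the ranking plus
# seeded random sets of the same size, so the planted signal is testable
.default_gene_sets <- function(ranked_table, seed, top_k = 20L,
                               n_random = 10L) {
  genes <- ranked_table$gene[!is.na(ranked_table$rank)]
  top_k <- min(top_k, max(2L, length(genes) %/% 4L))
  sets <- list(list(name = "TOP_COEXPRESSED", description = "top of ranking",
                    genes = genes[seq_len(top_k)]))
  set.seed(as.integer(seed))
  for (i in seq_len(n_random))
    sets[[i + 1L]] <- list(name = sprintf("RANDOM_%02d", i),
                           description = "seeded random set",
                           genes = sample(genes, top_k))
  names(sets) <- vapply(sets, `[[`, "", "name")
  structure(sets, class = "gene_set_collection")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> co-expression profiling -> ranking -> complementarity
#' (both scores) -> preranked enrichment -> responder comparison, writing
#' every table plus a log and a reproducibility manifest to
#' \code{config$out_dir}. Identical config and seed give byte-identical
#' outputs. Any stage failure aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the in-memory stage results and the paths
#'   written.
#' @export
run_full_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  paths <- list()

  say("stage cohorts")
  cohorts <- .stage("cohorts", {
    if (!is.null(config$cohort_dir)) {
      files <- sort(list.files(config$cohort_dir, pattern = "\\.tsv$",
                               full.names = TRUE))
      if (!length(files)) stop("no .tsv cohort files in ", config$cohort_dir)
      cs <- lapply(files, read_expression_tsv)
      names(cs) <- vapply(cs, attr, "", "cancer_type")
      cs
    } else simulate_pan_cancer(config$sim)
  })

  say("stage coexpression")
  markers <- c(config$marker, config$checkpoints)
  profiles <- .stage("coexpression", {
    ps <- lapply(markers, function(m)
      marker_correlation_profile(cohorts, m,
                                 min_samples = config$min_samples,
                                 excluded_types = config$excluded_types))
    names(ps) <- markers
    ps
  })
  for (m in markers) {
    p <- file.path(config$out_dir, sprintf("correlation_%s.tsv", m))
    prof <- profiles[[m]]
    df <- data.frame(gene = rownames(prof$r), prof$r, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .write_table_tsv(df, p)
    paths[[sprintf("correlation_%s", m)]] <- p
  }

  say("stage ranking")
  ranked <- .stage("ranking", rank_genes(profiles[[config$marker]]))
  paths$ranked <- file.path(config$out_dir, "ranked_genes.tsv")
  .write_table_tsv(ranked, paths$ranked)
  paths$rnk <- file.path(config$out_dir, "median_coexpression.rnk")
  write_rnk(ranked, paths$rnk)

  say("stage complementarity")
  comp <- .stage("complementarity", {
    ct <- list(pdcd1 = complementarity_table(
      profiles[[config$marker]], profiles[[config$checkpoints[1L]]],
      score_kind = "pdcd1"))
    if (length(config$checkpoints) >= 2L)
      ct$joint <- complementarity_table(
        profiles[[config$marker]], profiles[[config$checkpoints[1L]]],
        profiles[[config$checkpoints[2L]]], score_kind = "joint")
    ct
  })
  for (k in names(comp)) {
    p <- file.path(config$out_dir, sprintf("complementarity_%s.tsv", k))
    .write_table_tsv(comp[[k]], p)
    paths[[sprintf("complementarity_%s", k)]] <- p
  }

  say("stage enrichment")
  gsea <- .stage("enrichment", {
    sets <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
    else .default_gene_sets(ranked, config$seed + 2000L)
    suppressMessages(
      preranked_gsea(read_rnk(paths$rnk), sets, n_perm = config$n_perm,
                     seed = config$seed + 3000L))
  })
  paths$enrichment <- file.path(config$out_dir, "enrichment.tsv")
  .write_table_tsv(gsea, paths$enrichment)

  say("stage responders")
  responders <- .stage("responders", {
    cohort <- if (!is.null(config$responder_path))
      read_responder_tsv(config$responder_path)
    else simulate_responder_cohort(config$responder_sim)
    excl <- config$exclude_samples
    if (is.null(excl)) excl <- attr(cohort, "outlier_id")
    if (is.null(excl)) excl <- character(0)
    list(cohort = cohort, rerun = exclude_and_rerun(cohort, excl))
  })
  paths$responder_cohort <- file.path(config$out_dir, "responder_cohort.tsv")
  write_responder_tsv(responders$cohort, paths$responder_cohort)
  paths$responder_summary <- file.path(config$out_dir,
                                       "responder_summary.tsv")
  rsum <- rbind(cbind(analysis = "full", summary(responders$rerun$full)),
                cbind(analysis = "outlier_excluded",
                      summary(responders$rerun$reduced)))
  .write_table_tsv(rsum, paths$responder_summary)

  say("stage manifest")
  paths$manifest <- file.path(config$out_dir, "manifest.txt")
  manifest <- c(
    sprintf("tmecoexpr %s", as.character(utils::packageVersion("tmecoexpr"))),
    sprintf("seed\t%d", config$seed),
    sprintf("marker\t%s", config$marker),
    sprintf("checkpoints\t%s", paste(config$checkpoints, collapse = ",")),
    sprintf("excluded_types\t%s",
            paste(config$excluded_types, collapse = ",")),
    sprintf("min_samples\t%d", config$min_samples),
    sprintf("n_perm\t%d", config$n_perm),
    sprintf("n_cohorts\t%d", length(cohorts)),
    sprintf("outputs\t%s", paste(basename(unlist(paths)), collapse = ",")))
  writeLines(manifest, paths$manifest)

  invisible(list(cohorts = cohorts, profiles = profiles, ranked = ranked,
                 complementarity = comp, enrichment = gsea,
                 responders = responders, paths = paths))
}
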