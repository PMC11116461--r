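# End-to-end orchestration: filter -> stage -> match -> fit -> summaries
# -> artifacts, with a manifest sufficient to reproduce a run.

#' Pipeline run configuration
#'
#' Either `specimens`/`defects` paths or a [synthetic_config()] must be
#' supplied. Sampler defaults match the reference configuration: 4
#' chains and 8000 retained post-warmup draws in total.
#'
#' @param specimens,defects Input CSV paths (observed-data mode).
#' @param synthetic A [synthetic_config()] (synthetic mode).
#' @param models Which models to fit (`"m1"`, `"m2"`).
#' @param n_chains,n_iter,n_warmup Sampler settings (per chain).
#' @param row_policy Model 2 row policy.
#' @param out_dir Output artifact directory.
#' @param seed Master seed.
#' @param strict If `TRUE`, a failed convergence gate aborts the run.
#' @return A list of class `leh_run_config`.
#' @export
run_config <- function(specimens = NULL, defects = NULL, synthetic = NULL,
                       models = c("m1", "m2"), n_chains = 4,
                       n_iter = 2000, n_warmup = 1000,
                       row_policy = c("observable", "all_stages"),
                       out_dir = "leh_run", seed = 1, strict = FALSE) {
  row_policy <- match.arg(row_policy)
  if (is.null(synthetic) && (is.null(specimens) || is.null(defects))) {
    stop("either input paths or a synthetic config are required",
         call. = FALSE)
  }
  structure(list(specimens = specimens, defects = defects,
                 synthetic = synthetic, models = models,
                 n_chains = n_chains, n_iter = n_iter,
                 n_warmup = n_warmup, row_policy = row_policy,
                 out_dir = out_dir, seed = seed, strict = strict),
            class = "leh_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes filter, staging, episode matching, model fits, summaries,
#' contrasts, curves and derivative change periods, and writes
#' `specimens.csv`/`defects.csv` (synthetic mode), `episodes.csv`,
#' `summaries.json`, `curves.tsv`, `diagnostics.json` and
#' `manifest.json` into the output directory. Models are skipped with a
#' log note when the data cannot support them (e.g. zero defects); in
#' strict mode a failed convergence gate is an error.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results and the artifact
#'   directory.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "leh_run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    say("%s", line)
  }

  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic, seed = config$seed)
    dataset <- cohort$dataset
    write_specimens(dataset$specimens,
                    file.path(config$out_dir, "specimens.csv"))
    write_defects(dataset$defects,
                  file.path(config$out_dir, "defects.csv"))
    jsonlite::write_json(
      list(seed = config$seed, events = cohort$truth$events,
           u_ind = as.list(cohort$truth$u_ind),
           v_site = as.list(cohort$truth$v_site)),
      file.path(config$out_dir, "truth.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    note("synthetic cohort: %d specimens, %d defects",
         nrow(dataset$specimens), nrow(dataset$defects))
  } else {
    dataset <- leh_dataset(read_specimens(config$specimens),
                           read_defects(config$defects))
    note("loaded %d specimens, %d defects", nrow(dataset$specimens),
         nrow(dataset$defects))
  }

  filtered <- filter_included(dataset)
  dropped <- attr(filtered, "dropped")
  note("inclusion filter: %d -> %d specimens (dropped %s)",
       nrow(dataset$specimens), nrow(filtered$specimens),
       paste(sprintf("%s %d", dropped$taxon, dropped$n_dropped),
             collapse = ", "))

  episodes <- match_episodes(filtered)
  write_episodes(episodes, file.path(config$out_dir, "episodes.csv"))
  ep_stage <- vapply(1:11, function(s) sum(episodes$stage == s),
                     integer(1))
  note("matched %d stress episodes across stages [%s]",
       nrow(episodes), paste(ep_stage, collapse = " "))

  results <- list(episodes = episodes)
  summaries <- list()
  diagnostics <- list()
  partial <- character(0)

  if ("m1" %in% config$models) {
    if (nrow(filtered$specimens) == 0L ||
        length(unique(filtered$specimens$taxon)) < 2L) {
      note("model 1 skipped: both taxa are required")
      partial <- c(partial, "m1")
    } else {
      design1 <- build_design_model1(filtered)
      fit1 <- run_mcmc(design1, n_chains = config$n_chains,
                       n_iter = config$n_iter,
                       n_warmup = config$n_warmup,
                       seed = fan_out_seed(config$seed, 11),
                       strict = config$strict)
      diag1 <- diagnose(fit1)
      if (config$strict && !attr(diag1, "pass")) {
        stop("model 1 failed a convergence gate", call. = FALSE)
      }
      results$model1 <- fit1
      diagnostics$model1 <- diag1
      summaries$model1 <- list(
        cells = cell_probabilities(fit1),
        taxon_average = taxon_average(fit1),
        odds_ratios = pairwise_odds_ratios(fit1))
      note("model 1: max R-hat %.4f", max(diag1$rhat))
    }
  }

  curves <- NULL
  if ("m2" %in% config$models) {
    rs <- risk_sets(filtered)
    n_elig <- sum(rs$eligible)
    if (nrow(episodes) == 0L || n_elig == 0L) {
      note("model 2 skipped: no matched episodes or eligible individuals")
      partial <- c(partial, "m2")
    } else {
      design2 <- build_design_model2(filtered, episodes,
                                     row_policy = config$row_policy)
      fit2 <- run_mcmc(design2, n_chains = config$n_chains,
                       n_iter = config$n_iter,
                       n_warmup = config$n_warmup,
                       seed = fan_out_seed(config$seed, 22),
                       strict = config$strict)
      diag2 <- diagnose(fit2)
      if (config$strict && !attr(diag2, "pass")) {
        stop("model 2 failed a convergence gate", call. = FALSE)
      }
      results$model2 <- fit2
      diagnostics$model2 <- diag2
      curves <- smooth_curve(fit2)
      summaries$model2 <- list(
        odds_ratios = pairwise_odds_ratios(fit2, stages = c(3, 6)),
        derivative_segments = derivative_segments(fit2))
      note("model 2: max R-hat %.4f", max(diag2$rhat))
    }
  }

  # per-stage episode count table shaped like the published stage table
  stage_counts <- data.frame(
    stage = 1:11,
    nea = vapply(1:11, function(s)
      sum(episodes$stage == s & episodes$taxon == "NEA"), integer(1)),
    upmh = vapply(1:11, function(s)
      sum(episodes$stage == s & episodes$taxon == "UPMH"), integer(1)))
  summaries$stage_episode_counts <- stage_counts

  jsonlite::write_json(summaries,
                       file.path(config$out_dir, "summaries.json"),
                       dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(curves)) {
    utils::write.table(curves, file.path(config$out_dir, "curves.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    lapply(diagnostics, function(d) {
      d2 <- as.data.frame(d)
      attr(d2, "pass") <- NULL
      list(parameters = d2, pass = attr(d, "pass"),
           max_rhat = max(d$rhat), min_ess = min(d$ess))
    }),
    file.path(config$out_dir, "diagnostics.json"),
    dataframe = "columns", digits = NA, auto_unbox = TRUE, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("lehstress")),
    seed = config$seed,
    sampler = list(n_chains = config$n_chains, n_iter = config$n_iter,
                   n_warmup = config$n_warmup,
                   n_post_warmup_total = config$n_chains * config$n_iter),
    row_policy = config$row_policy,
    models_requested = config$models,
    models_skipped = partial,
    synthetic = !is.null(config$synthetic),
    synthetic_config = if (!is.null(config$synthetic))
      unclass(config$synthetic),
    inputs = list(specimens = config$specimens, defects = config$defects),
    log = log_lines)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(results = results, summaries = summaries,
                 diagnostics = diagnostics,
                 out_dir = config$out_dir, skipped = partial))
}
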