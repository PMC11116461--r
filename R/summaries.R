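# Posterior summaries and derived quantities: population-average cell
# probabilities, taxon averages, pairwise odds-ratio contrasts,
# smooth-curve reconstruction, finite-difference derivative change
# periods, and posterior predictive checks.

require_model <- function(draws, model) {
  if (!identical(draws$design$model, model)) {
    stop("draws are from model '", draws$design$model, "', need '",
         model, "'", call. = FALSE)
  }
}

# per-draw cell logits for model 1 (population average: random effects 0)
m1_cell_logits <- function(draws, labels) {
  param_column(draws, paste0("b[", labels, "]"))
}

#' Population-average cell probabilities (Model 1)
#'
#' For each of the 18 taxon-by-tooth-category cells, the per-draw
#' probability of a tooth manifesting at least one hypoplastic defect is
#' `plogis` of the cell logit with random effects set to zero (the
#' population average), summarized as the posterior median and 95%
#' equal-tailed credible interval.
#'
#' @param draws Model 1 `leh_draws`.
#' @param cells Optional character vector of cell labels
#'   (`"NEA:I1"`, ...); default all 18.
#' @return A data frame with columns `label`, `taxon`, `tooth_class`,
#'   `median`, `lower95`, `upper95`.
#' @export
cell_probabilities <- function(draws, cells = NULL) {
  require_model(draws, "m1")
  info <- draws$design$info$cells
  cells <- cells %||% info$label
  unknown <- setdiff(cells, info$label)
  if (length(unknown)) {
    stop("unknown cell label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  logits <- m1_cell_logits(draws, cells)
  out <- do.call(rbind, lapply(seq_along(cells), function(j)
    summarize_vec(plogis(logits[, j]), cells[j])))
  i <- match(cells, info$label)
  out$taxon <- info$taxon[i]
  out$tooth_class <- info$tooth_class[i]
  out[, c("label", "taxon", "tooth_class", "median", "lower95", "upper95")]
}

#' Taxon-average defect probability (Model 1)
#'
#' Per draw, the nine tooth-category cell logits of a taxon are averaged
#' with equal weights on the link scale and back-transformed; the
#' resulting probability draws are summarized as median and 95% CrI.
#' `scale = "response"` instead averages the cell probabilities.
#'
#' @param draws Model 1 `leh_draws`.
#' @param scale Averaging scale, `"link"` (default) or `"response"`.
#' @return A data frame with one row per taxon.
#' @export
taxon_average <- function(draws, scale = c("link", "response")) {
  require_model(draws, "m1")
  scale <- match.arg(scale)
  info <- draws$design$info$cells
  out <- do.call(rbind, lapply(TAXA, function(t) {
    logits <- m1_cell_logits(draws, info$label[info$taxon == t])
    p <- if (scale == "link") plogis(rowMeans(logits))
         else rowMeans(plogis(logits))
    summarize_vec(p, t)
  }))
  names(out)[1] <- "taxon"
  out
}

#' Pairwise odds-ratio contrasts between taxa
#'
#' Computes per-draw odds ratios `exp(logit_NEA - logit_UPMH)` and their
#' posterior median and 95% CrI: for Model 1, the contrast at each tooth
#' category; for Model 2, the contrast of the fitted stage curves at the
#' requested developmental stages (default 3 and 6). `excludes_one`
#' flags contrasts whose 95% CrI does not contain 1. Swapping `reverse`
#' maps each odds ratio to its reciprocal and mirrors the interval.
#'
#' @param draws An `leh_draws` object from either model.
#' @param tooth_classes Model 1: categories to contrast (default all 9).
#' @param stages Model 2: stages at which to contrast (default `c(3, 6)`).
#' @param reverse If `TRUE`, contrast UPMH vs NEA instead.
#' @return A data frame with columns `label`, `or_median`, `or_lower95`,
#'   `or_upper95`, `excludes_one`.
#' @export
pairwise_odds_ratios <- function(draws, tooth_classes = NULL,
                                 stages = c(3, 6), reverse = FALSE) {
  model <- draws$design$model
  if (model == "m1") {
    tooth_classes <- tooth_classes %||% TOOTH_CLASSES
    unknown <- setdiff(tooth_classes, TOOTH_CLASSES)
    if (length(unknown)) {
      stop("unknown tooth class(es): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    pairs <- lapply(tooth_classes, function(cl) list(
      label = cl,
      a = m1_cell_logits(draws, paste0("NEA:", cl))[, 1],
      b = m1_cell_logits(draws, paste0("UPMH:", cl))[, 1]))
  } else if (model == "m2") {
    if (any(stages < 1 | stages > N_STAGES)) {
      stop("stages must lie in [1, 11]", call. = FALSE)
    }
    pairs <- lapply(stages, function(s) list(
      label = paste0("stage", s),
      a = m2_logit_draws(draws, "NEA", s)[, 1],
      b = m2_logit_draws(draws, "UPMH", s)[, 1]))
  } else {
    stop("unsupported model for contrasts", call. = FALSE)
  }
  out <- do.call(rbind, lapply(pairs, function(p) {
    lo <- if (reverse) p$b - p$a else p$a - p$b
    s <- summarize_vec(exp(lo), p$label)
    names(s) <- c("label", "or_median", "or_lower95", "or_upper95")
    s
  }))
  out$excludes_one <- out$or_lower95 > 1 | out$or_upper95 < 1
  out
}

# per-draw population-average logits of the model-2 stage curve
m2_logit_draws <- function(draws, taxon, stages) {
  require_model(draws, "m2")
  info <- draws$design$info
  if (any(stages < 1 | stages > N_STAGES)) {
    stop("stage grid outside [1, 11]: no extrapolation", call. = FALSE)
  }
  z <- (stages - info$stage_mean) / info$stage_sd
  B <- spline_basis(z, info$n_basis, info$knot_range)
  b0 <- param_column(draws, "(Intercept)")[, 1]
  a <- param_column(draws, paste0("a[", taxon, "]"))[, 1]
  glab <- paste0("sm:", taxon)
  gamma <- param_column(
    draws, paste0("u[", glab, ":", draws$design$groups[[glab]]$labels, "]"))
  # draws x grid
  sweep(gamma %*% t(B), 1, b0 + a, `+`)
}

#' Fitted stress-likelihood curve across stages (Model 2)
#'
#' Per draw, the population-average probability of a systemic stress
#' episode at each grid point is the inverse-logit of intercept +
#' taxon offset + taxon smooth (random effects at zero); summarized as
#' posterior median and 95% CrI per point. The grid must lie within the
#' stage range 1..11 (no extrapolation).
#'
#' @param draws Model 2 `leh_draws`.
#' @param taxon `"NEA"`, `"UPMH"`, or both (default).
#' @param grid Stage values at which to evaluate the curve.
#' @return A data frame with columns `taxon`, `stage`, `median`,
#'   `lower95`, `upper95`.
#' @export
smooth_curve <- function(draws, taxon = TAXA,
                         grid = seq(1, N_STAGES, by = 0.1)) {
  require_model(draws, "m2")
  do.call(rbind, lapply(taxon, function(t) {
    logits <- m2_logit_draws(draws, t, grid)
    p <- plogis(logits)
    data.frame(taxon = t, stage = grid,
               median = apply(p, 2, median),
               lower95 = apply(p, 2, quantile, 0.025),
               upper95 = apply(p, 2, quantile, 0.975),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Change periods of the stage curve by finite-difference derivatives
#'
#' Per draw, the first derivative of the fitted probability curve is
#' estimated by central finite differences `(f(x+h) - f(x-h)) / (2h)` on
#' the probability scale at every interior grid point. Points whose 95%
#' CrI of the derivative excludes zero mark periods of credible increase
#' or decrease; contiguous flagged points of common sign are merged into
#' maximal non-overlapping segments.
#'
#' @param draws Model 2 `leh_draws`.
#' @param taxon Taxa to scan (default both).
#' @param grid Stage grid (default 201 equally spaced points on 1..11).
#' @param h Finite-difference step in stage units; must be positive and
#'   at most half the grid spacing.
#' @return A data frame with columns `taxon`, `start`, `end`, `sign`
#'   (`"INCREASE"`/`"DECREASE"`); zero rows when no period is flagged.
#' @export
derivative_segments <- function(draws, taxon = TAXA,
                                grid = seq(1, N_STAGES, length.out = 201),
                                h = 0.01) {
  require_model(draws, "m2")
  spacing <- min(diff(sort(grid)))
  if (h <= 0) stop("h must be positive", call. = FALSE)
  if (h > spacing / 2) {
    stop("h must be at most half the grid spacing", call. = FALSE)
  }
  interior <- grid[grid - h >= 1 & grid + h <= N_STAGES]
  out <- lapply(taxon, function(t) {
    p_up <- plogis(m2_logit_draws(draws, t, interior + h))
    p_dn <- plogis(m2_logit_draws(draws, t, interior - h))
    d <- (p_up - p_dn) / (2 * h)
    lo <- apply(d, 2, quantile, 0.025)
    hi <- apply(d, 2, quantile, 0.975)
    med <- apply(d, 2, median)
    flagged <- lo > 0 | hi < 0
    sgn <- ifelse(med > 0, "INCREASE", "DECREASE")
    segments_from_flags(interior, flagged, sgn, t)
  })
  do.call(rbind, out)
}

segments_from_flags <- function(x, flagged, sgn, taxon) {
  empty <- data.frame(taxon = character(), start = numeric(),
                      end = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  if (!any(flagged)) return(empty)
  # runs of contiguous flagged points with constant sign
  id <- cumsum(c(TRUE, diff(flagged) != 0 |
                   (sgn[-1] != sgn[-length(sgn)] & flagged[-1])))
  keep <- split(seq_along(x), id)
  segs <- lapply(keep, function(ix) {
    if (!flagged[ix[1]]) return(NULL)
    data.frame(taxon = taxon, start = x[min(ix)], end = x[max(ix)],
               sign = sgn[ix[1]], stringsAsFactors = FALSE)
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Posterior predictive check
#'
#' For each retained (thinned) draw, replicate responses are simulated
#' from the Bernoulli model at the draw's full linear predictor
#' (including its sampled random effects) and the test statistic is
#' recomputed; the two-sided tail probability (mid-p convention, since
#' the statistic is discrete) compares the replicate distribution with
#' the observed statistic.
#'
#' @param draws An `leh_draws` object.
#' @param statistic `"mean"` (overall response proportion) or
#'   `"taxon_mean"` (per-taxon response proportions).
#' @param thin Keep every `thin`-th draw.
#' @return A list (class `leh_ppc`) with elements `statistic`,
#'   `observed`, `replicates` and `tail_prob` (named per group for
#'   `"taxon_mean"`).
#' @export
posterior_predictive_check <- function(draws,
                                       statistic = c("mean", "taxon_mean"),
                                       thin = 10) {
  statistic <- match.arg(statistic)
  design <- draws$design
  m <- draws_matrix(draws)
  keep <- seq(1, nrow(m), by = thin)
  if (length(keep) == 1L) {
    warning("replicate distribution from a single parameter set",
            call. = FALSE)
  }
  nm <- dimnames(draws$draws)[[3]]
  p <- ncol(design$X)
  beta_cols <- seq_len(p)
  taxon <- design$info$rows$taxon
  stat_fun <- switch(statistic,
                     mean = function(y) mean(y),
                     taxon_mean = function(y)
                       vapply(TAXA, function(t) mean(y[taxon == t]),
                              numeric(1)))
  obs <- stat_fun(design$y)
  reps <- vapply(keep, function(i) {
    params <- row_to_params(m[i, ], design)
    pr <- plogis(linear_predictor(params, design))
    stat_fun(rbinom(length(pr), 1L, pr))
  }, numeric(length(obs)))
  reps <- matrix(reps, nrow = length(obs))
  rownames(reps) <- names(obs)
  # mid-p convention: the statistic is discrete, so inclusive tails
  # double-count ties; splitting them keeps the two-sided probability
  # approximately uniform under the true model
  tail_prob <- vapply(seq_along(obs), function(k) {
    lower <- mean(reps[k, ] < obs[k]) + 0.5 * mean(reps[k, ] == obs[k])
    upper <- mean(reps[k, ] > obs[k]) + 0.5 * mean(reps[k, ] == obs[k])
    min(1, 2 * min(lower, upper))
  }, numeric(1))
  names(tail_prob) <- names(obs)
  structure(list(statistic = statistic, observed = obs,
                 replicates = reps, tail_prob = tail_prob),
            class = "leh_ppc")
}

# one stacked-draws row (natural scale) -> leh_params
row_to_params <- function(row, design) {
  p <- ncol(design$X)
  beta <- row[seq_len(p)]
  off <- p
  u <- list(); sig <- numeric(0)
  for (g in names(design$groups)) {
    K <- design$groups[[g]]$K
    u[[g]] <- row[off + seq_len(K)]
    off <- off + K
  }
  for (g in names(design$groups)) {
    off <- off + 1L
    sig[g] <- row[off]
  }
  make_params(design, beta = beta, u = u,
              sigma = if (length(sig)) sig else NULL)
}

#' @export
print.leh_ppc <- function(x, ...) {
  cat(sprintf("<leh_ppc> statistic '%s': observed %s | tail prob %s\n",
              x$statistic,
              paste(signif(x$observed, 4), collapse = ", "),
              paste(signif(x$tail_prob, 3), collapse = ", ")))
  invisible(x)
}
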