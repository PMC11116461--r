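# MCMC sampling via the built-in no-U-turn sampler, and the posterior
# draws container.

#' Sample the posterior of a hierarchical Bernoulli model
#'
#' Runs gradient-based no-U-turn sampling of the model log-posterior on
#' the unconstrained, non-centered scale (adaptive step size targeting
#' `adapt_delta`, windowed diagonal mass-matrix adaptation, multinomial
#' trajectory sampling). The defaults -- 4 chains, 1000 warmup and 2000
#' retained iterations per chain -- yield 8000 post-warmup draws in
#' total. Chains run sequentially with per-chain seeds fanned out
#' deterministically from `seed`, so results are exactly reproducible.
#'
#' @param design An `leh_design` from [build_design_model1()] or
#'   [build_design_model2()].
#' @param priors A [prior_spec()].
#' @param n_chains Number of chains (at least 2).
#' @param n_iter Retained (post-warmup) iterations per chain.
#' @param n_warmup Warmup iterations per chain.
#' @param seed Master seed.
#' @param adapt_delta Target acceptance statistic.
#' @param max_treedepth Maximum trajectory doublings per iteration.
#' @param strict If `TRUE`, more than 1% post-warmup divergent
#'   transitions is an error instead of a warning.
#' @return An object of class `leh_draws`: draws array
#'   `[iteration, chain, parameter]` on the natural scale
#'   (coefficients, random effects `u[...]`, standard deviations
#'   `sigma[...]`), with the design and sampler metadata attached.
#' @export
run_mcmc <- function(design, priors = prior_spec(), n_chains = 4,
                     n_iter = 2000, n_warmup = 1000, seed = 1,
                     adapt_delta = 0.95, max_treedepth = 10,
                     strict = FALSE) {
  stopifnot(inherits(design, "leh_design"), n_chains >= 2, n_iter >= 1,
            n_warmup >= 0)
  data <- design_cpp_data(design, priors)
  npar <- n_unconstrained(design)
  chains <- vector("list", n_chains)
  n_div <- integer(n_chains)
  depths <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(fan_out_seed(seed, ch))
    init <- runif(npar, -0.5, 0.5)
    fit <- lehstress_nuts_chain(data, init, as.integer(n_warmup),
                                as.integer(n_iter), adapt_delta,
                                as.integer(max_treedepth))
    chains[[ch]] <- fit$draws
    n_div[ch] <- fit$n_divergent
    depths[ch] <- mean(fit$treedepths)
  }
  arr <- array(NA_real_, c(n_iter, n_chains, npar),
               dimnames = list(NULL, NULL, unconstrained_names(design)))
  for (ch in seq_len(n_chains)) arr[, ch, ] <- chains[[ch]]
  arr <- transform_draws(arr, design)
  div_frac <- sum(n_div) / (n_chains * n_iter)
  if (div_frac > 0.01) {
    msg <- sprintf("%.2f%% divergent transitions after adaptation",
                   100 * div_frac)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  new_leh_draws(arr, design, seed = seed,
                meta = list(n_divergent = n_div, mean_treedepth = depths,
                            adapt_delta = adapt_delta,
                            n_warmup = n_warmup, priors = priors))
}

# unconstrained (beta, z, log sigma) -> natural (beta, u, sigma)
transform_draws <- function(arr, design) {
  p <- ncol(design$X)
  Ks <- vapply(design$groups, `[[`, integer(1), "K")
  G <- length(Ks)
  out <- arr
  dimnames(out)[[3]] <- natural_names(design)
  if (G == 0L) return(out)
  lam_cols <- p + sum(Ks) + seq_len(G)
  off <- p
  for (g in seq_len(G)) {
    sig <- exp(arr[, , lam_cols[g], drop = FALSE])
    zc <- off + seq_len(Ks[g])
    out[, , zc] <- arr[, , zc, drop = FALSE] *
      array(sig, c(dim(arr)[1], dim(arr)[2], Ks[g]))
    off <- off + Ks[g]
  }
  out[, , lam_cols] <- exp(arr[, , lam_cols, drop = FALSE])
  out
}

#' Construct a posterior-draws object
#'
#' Low-level constructor wrapping an `[iteration, chain, parameter]`
#' array of natural-scale draws (parameter names as produced by
#' [run_mcmc()]). Mainly useful for building degenerate or synthetic
#' posteriors in tests and worked examples.
#'
#' @param arr 3-d array `[iteration, chain, parameter]` with parameter
#'   dimnames, or a matrix `[draw, parameter]` treated as one chain.
#' @param design The `leh_design` the parameters refer to.
#' @param seed Seed recorded for provenance.
#' @param meta Optional sampler metadata.
#' @return An object of class `leh_draws`.
#' @export
new_leh_draws <- function(arr, design, seed = NA_integer_, meta = list()) {
  if (is.matrix(arr)) {
    arr <- array(arr, c(nrow(arr), 1L, ncol(arr)),
                 dimnames = list(NULL, NULL, colnames(arr)))
  }
  stopifnot(length(dim(arr)) == 3L)
  expected <- natural_names(design)
  if (!identical(dimnames(arr)[[3]], expected)) {
    stop("parameter names do not match the design", call. = FALSE)
  }
  if (any(!is.finite(arr))) stop("non-finite draws", call. = FALSE)
  structure(list(draws = arr, design = design, seed = seed,
                 n_chains = dim(arr)[2],
                 n_post_warmup_total = dim(arr)[1] * dim(arr)[2],
                 meta = meta),
            class = "leh_draws")
}

#' @export
print.leh_draws <- function(x, ...) {
  cat(sprintf(paste0("<leh_draws %s> %d chains x %d iterations ",
                     "(%d post-warmup draws), %d parameters\n"),
              x$design$model, x$n_chains, dim(x$draws)[1],
              x$n_post_warmup_total, dim(x$draws)[3]))
  invisible(x)
}

# all chains stacked: matrix [draw, parameter]
draws_matrix <- function(draws) {
  a <- draws$draws
  m <- matrix(aperm(a, c(1, 2, 3)), dim(a)[1] * dim(a)[2], dim(a)[3])
  colnames(m) <- dimnames(a)[[3]]
  m
}

param_column <- function(draws, name) {
  a <- draws$draws
  i <- match(name, dimnames(a)[[3]])
  if (anyNA(i)) stop("unknown parameter(s): ",
                     paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  m <- matrix(a[, , i], dim(a)[1] * dim(a)[2], length(i))
  colnames(m) <- name
  m
}

summarize_vec <- function(x, label = NULL) {
  q <- unname(quantile(x, c(0.5, 0.025, 0.975), names = FALSE))
  data.frame(label = label %||% NA_character_, median = q[1],
             lower95 = q[2], upper95 = q[3], stringsAsFactors = FALSE)
}
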