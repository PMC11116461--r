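# Convergence diagnostics: split rank-normalized R-hat, bulk effective
# sample size, and Monte Carlo standard error, with the three gates used
# to declare a fit reliable: R-hat < 1.01 for every parameter, ESS above
# 10% of the total post-warmup sample size, and MCSE below 5% of the
# posterior sd.

# split each chain in half -> matrix [n/2, 2*chains]
split_chains <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  x <- x[seq_len(2L * h), , drop = FALSE]
  do.call(cbind, lapply(seq_len(ncol(x)), function(ch)
    cbind(x[seq_len(h), ch], x[h + seq_len(h), ch])))
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  array(z, dim(x))
}

rhat_split <- function(x) {
  s <- rank_normalize(split_chains(x))
  n <- nrow(s); m <- ncol(s)
  W <- mean(apply(s, 2, var))
  B <- n * var(colMeans(s))
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_bulk <- function(x) {
  s <- rank_normalize(split_chains(x))
  n <- nrow(s); m <- ncol(s)
  W <- mean(apply(s, 2, var))
  B <- n * var(colMeans(s))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus <= 0) return(NA_real_)
  lag_max <- min(n - 1L, 500L)
  acov <- vapply(seq_len(m), function(j)
    drop(acf(s[, j], lag.max = lag_max, type = "covariance",
             plot = FALSE, demean = TRUE)$acf),
    numeric(lag_max + 1L))
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # rho[1] is lag 0
  # Geyer initial monotone positive sequence over lag pairs
  max_pairs <- (lag_max + 1L) %/% 2L
  tau <- 0; prev <- Inf
  for (k in seq_len(max_pairs)) {
    p <- rho[2 * k - 1] + if (2 * k <= lag_max + 1L) rho[2 * k] else 0
    if (k > 1 && p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + p
  }
  tau <- max(2 * tau - 1, 1 / (n * m))  # tau >= tiny guard
  (n * m) / tau
}

#' Convergence diagnostics report
#'
#' Computes, per parameter, the split rank-normalized R-hat, the bulk
#' effective sample size, the posterior sd and the Monte Carlo standard
#' error (`sd / sqrt(ESS)`), together with pass flags for the three
#' convergence gates: R-hat below `rhat_max`, ESS above `ess_frac` of
#' the total post-warmup sample size, and MCSE below `mcse_frac` of the
#' posterior sd.
#'
#' @param draws An `leh_draws` object with at least 2 chains and 100
#'   iterations per chain.
#' @param rhat_max,ess_frac,mcse_frac Gate thresholds.
#' @return A data frame (class `leh_diagnostics`) with one row per
#'   parameter and columns `parameter`, `rhat`, `ess`, `sd`, `mcse`,
#'   `pass_rhat`, `pass_ess`, `pass_mcse`, `pass`; overall pass flag in
#'   attribute `"pass"`.
#' @export
diagnose <- function(draws, rhat_max = 1.01, ess_frac = 0.10,
                     mcse_frac = 0.05) {
  stopifnot(inherits(draws, "leh_draws"))
  a <- draws$draws
  if (dim(a)[2] < 2L) stop("need at least 2 chains", call. = FALSE)
  if (dim(a)[1] < 100L) stop("need at least 100 draws per chain",
                             call. = FALSE)
  total <- draws$n_post_warmup_total
  pars <- dimnames(a)[[3]]
  out <- do.call(rbind, lapply(seq_along(pars), function(k) {
    x <- a[, , k]
    if (all(apply(x, 2, sd) == 0)) {
      stop("degenerate (constant) chain for parameter '", pars[k],
           "': R-hat undefined", call. = FALSE)
    }
    rhat <- rhat_split(x)
    ess <- ess_bulk(x)
    s <- sd(as.vector(x))
    data.frame(parameter = pars[k], rhat = rhat, ess = ess, sd = s,
               mcse = s / sqrt(ess), stringsAsFactors = FALSE)
  }))
  out$pass_rhat <- out$rhat < rhat_max
  out$pass_ess <- out$ess > ess_frac * total
  out$pass_mcse <- out$mcse < mcse_frac * out$sd
  out$pass <- out$pass_rhat & out$pass_ess & out$pass_mcse
  attr(out, "pass") <- all(out$pass)
  attr(out, "gates") <- c(rhat_max = rhat_max, ess_frac = ess_frac,
                          mcse_frac = mcse_frac)
  class(out) <- c("leh_diagnostics", "data.frame")
  out
}

#' @export
print.leh_diagnostics <- function(x, ...) {
  cat(sprintf(paste0("<leh_diagnostics> %d parameters | max R-hat %.4f | ",
                     "min ESS %.0f | overall %s\n"),
              nrow(x), max(x$rhat), min(x$ess),
              if (attr(x, "pass")) "PASS" else "FAIL"))
  invisible(x)
}
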