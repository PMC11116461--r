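# intercept-only Bernoulli design used by several sampler checks
intercept_design <- function(y) {
  lehstress:::new_design(y, matrix(1, length(y), 1,
                                   dimnames = list(NULL, "b0")),
                         list(), "custom", list())
}

test_that("sampler posterior matches 1-D quadrature on a conjugate-style case", {
  y <- c(rep(1L, 7), rep(0L, 3))
  design <- intercept_design(y)
  draws <- run_mcmc(design, n_chains = 4, n_iter = 2000, n_warmup = 1000,
                    seed = 5)
  p_mcmc <- mean(plogis(lehstress:::param_column(draws, "b0")))
  post <- function(b) exp(7 * plogis(b, log.p = TRUE) +
                            3 * plogis(-b, log.p = TRUE) +
                            dnorm(b, log = TRUE))
  Z <- integrate(post, -10, 10)$value
  p_quad <- integrate(function(b) plogis(b) * post(b), -10, 10)$value / Z
  expect_lt(abs(p_mcmc - p_quad), 0.005)
})

test_that("the same seed reproduces identical draws; defaults retain 8000", {
  y <- rep(c(1L, 0L), 10)
  design <- intercept_design(y)
  d1 <- run_mcmc(design, seed = 9)
  d2 <- run_mcmc(design, seed = 9)
  expect_identical(d1$draws, d2$draws)
  expect_equal(d1$n_post_warmup_total, 8000L)
  expect_equal(d1$n_chains, 4L)
  d3 <- run_mcmc(design, seed = 10)
  expect_false(identical(d1$draws, d3$draws))
})

test_that("diagnostics pass iid chains and fail offset chains", {
  set.seed(71)
  design <- intercept_design(rep(c(1L, 0L), 5))
  arr <- array(rnorm(2000 * 4), c(2000, 4, 1),
               dimnames = list(NULL, NULL, "b0"))
  iid <- new_leh_draws(arr, design)
  dg <- diagnose(iid)
  expect_lt(dg$rhat, 1.01)
  # ESS of iid draws is close to the total draw count
  expect_equal(dg$ess, 8000, tolerance = 0.2)
  expect_true(attr(dg, "pass"))

  # two chains offset by 5 sd: R-hat blows past 1.2
  arr2 <- arr
  arr2[, 1:2, 1] <- arr2[, 1:2, 1] + 5
  bad <- diagnose(new_leh_draws(arr2, design))
  expect_gt(bad$rhat, 1.2)
  expect_false(attr(bad, "pass"))

  # constant chains are a degenerate-chain error
  arr3 <- array(1, c(200, 2, 1), dimnames = list(NULL, NULL, "b0"))
  expect_error(diagnose(new_leh_draws(arr3, design)), "degenerate")
})

test_that("cell probabilities summarize the 18-cell grid correctly", {
  d <- full_cell_dataset()
  design <- build_design_model1(d)
  # degenerate posterior at zero: every cell probability exactly 0.5
  p0 <- make_params(design, beta = 0)
  cp0 <- cell_probabilities(degenerate_draws(design, p0))
  expect_equal(nrow(cp0), 18L)
  expect_equal(cp0$median, rep(0.5, 18))
  expect_equal(cp0$lower95, rep(0.5, 18))

  # known cell logit 1.0 -> plogis(1)
  beta <- rep(0, 18); beta[1] <- 1
  cp1 <- cell_probabilities(degenerate_draws(design, make_params(design, beta)),
                            cells = design$info$cells$label[1])
  expect_equal(cp1$median, plogis(1), tolerance = 1e-6)

  expect_error(cell_probabilities(degenerate_draws(design, p0),
                                  cells = "NEA:M9"), "unknown cell")
})

test_that("taxon averages equal a per-draw loop oracle", {
  d <- full_cell_dataset()
  design <- build_design_model1(d)
  set.seed(73)
  # random non-degenerate posterior over the 18 cells
  nm <- lehstress:::natural_names(design)
  S <- 40
  arr <- array(rnorm(S * 2 * length(nm), sd = 0.3), c(S, 2, length(nm)),
               dimnames = list(NULL, NULL, nm))
  draws <- new_leh_draws(arr, design)
  ta <- taxon_average(draws)

  # brute-force loop over draws and cells
  cells <- design$info$cells
  m <- lehstress:::draws_matrix(draws)
  for (t in c("NEA", "UPMH")) {
    cols <- paste0("b[", cells$label[cells$taxon == t], "]")
    p <- numeric(nrow(m))
    for (s in seq_len(nrow(m))) p[s] <- plogis(mean(m[s, cols]))
    expect_equal(ta$median[ta$taxon == t], median(p), tolerance = 1e-10)
  }

  # invariant to permutation of category order: shuffling the cells
  # table leaves the per-taxon average untouched
  draws2 <- draws
  perm <- sample(18)
  draws2$design$info$cells <- design$info$cells[perm, ]
  expect_equal(taxon_average(draws2)$median, ta$median, tolerance = 1e-12)

  # all cell logits equal L in a taxon -> average probability plogis(L)
  beta <- ifelse(design$info$cells$taxon == "NEA", 1.3, -0.4)
  ta2 <- taxon_average(degenerate_draws(design, make_params(design, beta)))
  expect_equal(ta2$median[ta2$taxon == "NEA"], plogis(1.3))
  expect_equal(ta2$median[ta2$taxon == "UPMH"], plogis(-0.4))
})

test_that("odds-ratio contrasts obey closed forms and reversal", {
  d <- full_cell_dataset()
  design <- build_design_model1(d)
  # identical cell logits -> OR exactly 1, CrI does not exclude 1
  same <- degenerate_draws(design, make_params(design, beta = 0.3))
  or1 <- pairwise_odds_ratios(same, tooth_classes = "C")
  expect_equal(or1$or_median, 1)
  expect_false(or1$excludes_one)

  # logit difference ln 2 everywhere -> OR exactly 2
  cells <- design$info$cells
  beta <- ifelse(cells$taxon == "NEA", log(2), 0)
  or2 <- pairwise_odds_ratios(
    degenerate_draws(design, make_params(design, beta)))
  expect_equal(or2$or_median, rep(2, 9), tolerance = 1e-12)

  # reversal maps ORs to reciprocals with swapped interval endpoints;
  # 81 draws makes the 2.5/50/97.5 percentiles exact order statistics,
  # so the reciprocal relation holds exactly
  set.seed(79)
  nm <- lehstress:::natural_names(design)
  arr <- array(rnorm(81 * 1 * length(nm), sd = 0.4), c(81, 1, length(nm)),
               dimnames = list(NULL, NULL, nm))
  rnd <- new_leh_draws(arr, design)
  fwd <- pairwise_odds_ratios(rnd)
  rev <- pairwise_odds_ratios(rnd, reverse = TRUE)
  expect_equal(rev$or_median, 1 / fwd$or_median, tolerance = 1e-10)
  expect_equal(rev$or_lower95, 1 / fwd$or_upper95, tolerance = 1e-10)
  expect_equal(rev$or_upper95, 1 / fwd$or_lower95, tolerance = 1e-10)
  expect_error(pairwise_odds_ratios(rnd, tooth_classes = "M9"),
               "unknown tooth class")
})

# a small model-2 design with known structure for curve tests
m2_fixture <- function(seed = 83) {
  sim <- simulate_stage_rows(n_individuals = c(NEA = 8, UPMH = 8),
                             obs_prob = 0.9, seed = seed)
  sim$design
}

test_that("smooth curves reduce to closed forms for degenerate posteriors", {
  design <- m2_fixture()
  # zero spline coefficients and offsets: flat curve at plogis(b0)
  p_flat <- make_params(design, beta = c(0.7, 0, 0))
  cv <- smooth_curve(degenerate_draws(design, p_flat), grid = 1:11)
  expect_equal(cv$median, rep(plogis(0.7), 22), tolerance = 1e-12)
  # zero-width CrI for a single-draw posterior
  single <- degenerate_draws(design, p_flat, n_draws = 1, n_chains = 1)
  cv1 <- smooth_curve(single, taxon = "NEA", grid = c(2, 7))
  expect_equal(cv1$lower95, cv1$upper95)
  expect_error(smooth_curve(degenerate_draws(design, p_flat),
                            grid = c(0.5, 3)), "no extrapolation")
})

test_that("curve evaluation at design rows matches direct row evaluation", {
  design <- m2_fixture()
  set.seed(89)
  nm <- lehstress:::natural_names(design)
  arr <- array(rnorm(30 * 2 * length(nm), sd = 0.3), c(30, 2, length(nm)),
               dimnames = list(NULL, NULL, nm))
  draws <- new_leh_draws(arr, design)
  m <- lehstress:::draws_matrix(draws)
  rows <- design$info$rows
  for (pick in c(1, 7, nrow(rows))) {
    taxon <- rows$taxon[pick]; stage <- rows$stage[pick]
    lg <- lehstress:::m2_logit_draws(draws, taxon, stage)[, 1]
    # direct design-row evaluation: X beta + smooth block (pop average)
    glab <- paste0("sm:", taxon)
    Zrow <- design$groups[[glab]]$Z[pick, ]
    ucols <- paste0("u[", glab, ":", design$groups[[glab]]$labels, "]")
    direct <- m[, "(Intercept)"] + m[, paste0("a[", taxon, "]")] +
      drop(m[, ucols] %*% Zrow)
    expect_equal(lg, direct, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("derivative detection matches analytic slopes and flags trends", {
  design <- m2_fixture()
  # flat degenerate posterior -> no flagged segments
  flat <- degenerate_draws(design, make_params(design, beta = c(0.2, 0, 0)))
  expect_equal(nrow(derivative_segments(flat)), 0L)

  # a strictly increasing logistic trend in stage: encode a linear logit
  # through the spline by evaluating that the finite difference matches
  # the analytic derivative of the fitted probability curve
  info <- design$info
  grid <- seq(2, 10, length.out = 21)
  h <- 1e-3
  set.seed(97)
  nm <- lehstress:::natural_names(design)
  arr <- array(rnorm(25 * 2 * length(nm), sd = 0.2), c(25, 2, length(nm)),
               dimnames = list(NULL, NULL, nm))
  draws <- new_leh_draws(arr, design)
  d_num <- plogis(lehstress:::m2_logit_draws(draws, "NEA", grid + h)) -
    plogis(lehstress:::m2_logit_draws(draws, "NEA", grid - h))
  d_num <- d_num / (2 * h)
  # analytic derivative via chain rule on the logit draws
  eps <- 1e-6
  lg <- lehstress:::m2_logit_draws(draws, "NEA", grid)
  dlogit <- (lehstress:::m2_logit_draws(draws, "NEA", grid + eps) - lg) / eps
  d_ana <- plogis(lg) * (1 - plogis(lg)) * dlogit
  expect_equal(d_num, d_ana, tolerance = 1e-4)

  # monotone increasing truth flags one INCREASE segment
  b <- 2  # logit slope per standardized stage unit
  gamma_lin <- approx_linear_spline_coefs(design, b)
  inc <- degenerate_draws(
    design, make_params(design, beta = c(-1, 0, 0),
                        u = gamma_lin$u, sigma = gamma_lin$sigma))
  segs <- derivative_segments(inc, taxon = "NEA")
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$sign, "INCREASE")
  # the segment spans essentially the whole interior grid
  expect_lt(segs$start, 1.2)
  expect_gt(segs$end, 10.8)

  expect_error(derivative_segments(inc, h = 1), "half the grid spacing")
  expect_error(derivative_segments(inc, h = -1), "positive")
})

test_that("posterior predictive replicates center on truth for a fixed draw", {
  set.seed(101)
  y <- rbinom(200, 1, 0.4)
  design <- intercept_design(y)
  # degenerate posterior at the generating parameter
  p_true <- make_params(design, beta = qlogis(0.4))
  draws <- degenerate_draws(design, p_true, n_draws = 400, n_chains = 2)
  # give the ppc a rows table for the statistic machinery
  draws$design$info$rows <- data.frame(taxon = rep("NEA", 200))
  ppc <- posterior_predictive_check(draws, statistic = "mean", thin = 4)
  # binomial sampling oracle: replicate means ~ Binomial(200, 0.4)/200
  expect_equal(mean(ppc$replicates), 0.4,
               tolerance = 4 * sqrt(0.4 * 0.6 / 200 / ncol(ppc$replicates)))
  expect_true(ppc$tail_prob > 0 && ppc$tail_prob <= 1)

  expect_warning(posterior_predictive_check(draws, thin = 1e6),
                 "single parameter set")
})

test_that("ppc tail probabilities are calibrated under the true model", {
  # data simulated from the model itself: across replications the
  # two-sided tail probability should rarely be extreme
  n_in_band <- 0
  for (r in 1:50) {
    set.seed(300 + r)
    b_true <- rnorm(1)
    y <- rbinom(80, 1, plogis(b_true))
    design <- intercept_design(y)
    draws <- run_mcmc(design, n_chains = 2, n_iter = 200, n_warmup = 200,
                      seed = 300 + r)
    ppc <- posterior_predictive_check(draws, statistic = "mean", thin = 4)
    if (ppc$tail_prob > 0.05 && ppc$tail_prob < 0.95) {
      n_in_band <- n_in_band + 1
    }
  }
  expect_gte(n_in_band / 50, 0.80)
})

test_that("design export writes a dense matrix with a JSON sidecar", {
  sim <- simulate_stage_rows(n_individuals = c(NEA = 5, UPMH = 5),
                             obs_prob = 0.9, seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(sim$design, path)
  dumped <- read.csv(path, check.names = FALSE)
  expect_equal(dumped$y, sim$design$y)
  expect_equal(as.matrix(dumped[, colnames(sim$design$X)]),
               sim$design$X, ignore_attr = TRUE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  expect_equal(sidecar$fixed_effects, colnames(sim$design$X))
  expect_equal(sidecar$groups$ind$K, sim$design$groups$ind$K)
})

test_that("summary invariants hold on a real (small) model fit", {
  sim <- simulate_stage_rows(n_individuals = c(NEA = 10, UPMH = 10),
                             obs_prob = 0.8, seed = 13)
  draws <- run_mcmc(sim$design, n_chains = 2, n_iter = 300,
                    n_warmup = 300, seed = 17)
  cv <- smooth_curve(draws, grid = seq(1, 11, by = 0.5))
  expect_true(all(cv$lower95 <= cv$median & cv$median <= cv$upper95))
  expect_true(all(cv$median >= 0 & cv$median <= 1))
  ors <- pairwise_odds_ratios(draws)
  expect_true(all(ors$or_median > 0 & ors$or_lower95 > 0))
  expect_true(all(ors$or_lower95 <= ors$or_median &
                    ors$or_median <= ors$or_upper95))
})
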