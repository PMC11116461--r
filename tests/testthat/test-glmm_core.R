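# textbook Cox-de Boor recursion, the independent oracle for the
# B-spline basis implementation
coxdeboor <- function(x, knots, i, k) {
  if (k == 1) {
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  }
  d1 <- knots[i + k - 1] - knots[i]
  d2 <- knots[i + k] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * coxdeboor(x, knots, i, k - 1) else 0
  t2 <- if (d2 > 0) (knots[i + k] - x) / d2 *
    coxdeboor(x, knots, i + 1, k - 1) else 0
  t1 + t2
}

test_that("model 1 design has 18 cells and the any-form response", {
  d <- full_cell_dataset()
  design <- build_design_model1(d)
  expect_equal(ncol(design$X), 18L)
  expect_true(all(rowSums(design$X) == 1))  # cell-means coding
  # response: >=1 defect of any form
  has_def <- design$info$rows$specimen_id %in% d$defects$specimen_id
  expect_equal(design$y, as.integer(has_def))

  # a tooth with only a PIT defect still scores 1
  sp <- rbind(specimen_row("p1", taxon = "NEA"),
              specimen_row("p2", taxon = "UPMH", individual_id = "i2"),
              specimen_row("p3", taxon = "NEA", individual_id = "i3"))
  def <- defect_row("p1", form = "PIT")
  d2 <- build_design_model1(leh_dataset(sp, def))
  expect_equal(d2$y, c(1L, 0L, 0L))

  # single-taxon data is an error
  expect_error(build_design_model1(leh_dataset(specimen_row("x"))),
               "taxon absent")
})

test_that("model 2 rows follow the observable-stages policy", {
  # one individual observable at {4,5,6} (two P3 crowns), episode at
  # stage 5; another eligible individual so both taxa are present
  sp <- rbind(
    specimen_row("a", tooth_class = "P3", jaw = "LOWER"),
    specimen_row("b", tooth_class = "P3", jaw = "UPPER"),
    specimen_row("c", tooth_class = "I1", jaw = "LOWER",
                 individual_id = "ind2", taxon = "UPMH", site_id = "s2"),
    specimen_row("d", tooth_class = "M1", jaw = "UPPER",
                 individual_id = "ind2", taxon = "UPMH", site_id = "s2"))
  def <- rbind(defect_row("a", crown_third = 2),  # P3/2 -> stage 5
               defect_row("b", crown_third = 2),  # P3/2 -> stage 5
               defect_row("c", crown_third = 1))
  d <- leh_dataset(sp, def)
  design <- build_design_model2(d)
  rows <- design$info$rows
  r1 <- rows[rows$individual_id == "ind1", ]
  expect_equal(r1$stage, c(4L, 5L, 6L, 9L))
  expect_equal(r1$y, c(0L, 1L, 0L, 0L))
  # standardized stage column has mean 0, sd 1
  z <- (rows$stage - design$info$stage_mean) / design$info$stage_sd
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # ineligible individuals contribute zero rows
  expect_false("ind3" %in% rows$individual_id)

  # all-stages policy emits 11 rows per individual
  design_all <- build_design_model2(d, row_policy = "all_stages")
  expect_equal(nrow(design_all$info$rows),
               11L * length(unique(rows$individual_id)))
})

test_that("individuals without furrow defects are excluded from model 2", {
  sp <- rbind(
    specimen_row("a", tooth_class = "P3"),
    specimen_row("b", tooth_class = "P4"),
    specimen_row("c", tooth_class = "P3", individual_id = "ind2",
                 taxon = "UPMH"),
    specimen_row("d", tooth_class = "P4", individual_id = "ind2",
                 taxon = "UPMH"))
  def <- rbind(defect_row("a", crown_third = 2),
               defect_row("c", form = "PIT"))  # ind2 has no furrow
  design <- build_design_model2(leh_dataset(sp, def))
  expect_false("ind2" %in% design$info$rows$individual_id)
  # no eligible individuals at all -> error
  expect_error(
    build_design_model2(leh_dataset(sp, defect_row("a", form = "PIT"))),
    "no eligible")
})

test_that("spline basis is a partition of unity matching Cox-de Boor", {
  x <- seq(-2, 2, length.out = 41)
  B <- spline_basis(x, n_basis = 8, range = c(-2, 2))
  expect_equal(dim(B), c(41L, 8L))
  expect_true(all(B >= 0 & B <= 1))
  expect_equal(rowSums(B), rep(1, 41), tolerance = 1e-12)

  # independent recursion at the midpoint and other interior points
  knots <- lehstress:::spline_knots(8, c(-2, 2))
  # pad so every basis function has k+1 knots available
  for (xx in c(0, -1.3, 0.7)) {
    oracle <- vapply(1:8, function(i) coxdeboor(xx, knots, i, 4), numeric(1))
    expect_equal(drop(spline_basis(xx, 8, c(-2, 2))), oracle,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  expect_error(spline_basis(x, n_basis = 3), "at least 4")
  expect_error(spline_basis(3, n_basis = 8, range = c(-2, 2)),
               "no extrapolation")
})

test_that("log-likelihood matches closed forms and a row-wise oracle", {
  d <- full_cell_dataset()
  design <- build_design_model1(d)

  # all parameters zero -> p = 0.5 everywhere
  n10 <- lehstress:::new_design(rep(c(1L, 0L), 5),
                                matrix(1, 10, 1,
                                       dimnames = list(NULL, "b0")),
                                list(), "custom", list())
  expect_equal(log_likelihood(make_params(n10, beta = 0), n10),
               10 * log(0.5), tolerance = 1e-9)

  # random designs vs scalar loop oracle
  set.seed(41)
  for (rep in 1:100) {
    n <- 37
    X <- cbind(1, matrix(rnorm(n * 2), n))
    colnames(X) <- c("b0", "b1", "b2")
    y <- rbinom(n, 1, 0.5)
    idx <- sample(4, n, replace = TRUE)
    des <- lehstress:::new_design(
      y, X, list(g = list(type = "index", idx = idx, K = 4L,
                          labels = paste0("l", 1:4))), "custom", list())
    beta <- rnorm(3); u <- rnorm(4); sig <- rexp(1) + 0.1
    params <- make_params(des, beta, list(g = u), c(g = sig))
    # brute-force per-row loop
    oracle <- 0
    for (i in seq_len(n)) {
      eta <- sum(X[i, ] * beta) + u[idx[i]]
      p <- 1 / (1 + exp(-eta))
      oracle <- oracle + y[i] * log(p) + (1 - y[i]) * log(1 - p)
    }
    expect_equal(log_likelihood(params, des), oracle, tolerance = 1e-8)

    # duplicating every row doubles the value
    des2 <- lehstress:::new_design(
      rep(y, 2), X[rep(1:n, 2), ],
      list(g = list(type = "index", idx = rep(idx, 2), K = 4L,
                    labels = paste0("l", 1:4))), "custom", list())
    expect_equal(log_likelihood(params, des2),
                 2 * log_likelihood(params, des), tolerance = 1e-10)
  }
})

test_that("log-posterior matches a term-by-term oracle", {
  # prior-only case: empty design, all beta zero, no random effects
  J <- 5
  empty <- lehstress:::new_design(
    integer(0), matrix(numeric(0), 0, J,
                       dimnames = list(NULL, paste0("b", 1:J))),
    list(), "custom", list())
  expect_equal(log_posterior(make_params(empty, beta = 0), empty),
               -J * 0.5 * log(2 * pi), tolerance = 1e-12)

  set.seed(43)
  for (rep in 1:20) {
    n <- 25
    X <- cbind(1, rnorm(n)); colnames(X) <- c("b0", "b1")
    y <- rbinom(n, 1, 0.4)
    idx <- sample(3, n, replace = TRUE)
    Z <- matrix(runif(n * 4), n)
    des <- lehstress:::new_design(
      y, X,
      list(g1 = list(type = "index", idx = idx, K = 3L,
                     labels = paste0("a", 1:3)),
           g2 = list(type = "dense", Z = Z, K = 4L,
                     labels = paste0("s", 1:4))),
      "custom", list())
    beta <- rnorm(2); u1 <- rnorm(3); u2 <- rnorm(4)
    s1 <- rexp(1) + 0.05; s2 <- rexp(1) + 0.05
    params <- make_params(des, beta, list(g1 = u1, g2 = u2),
                          c(g1 = s1, g2 = s2))
    oracle <- log_likelihood(params, des) +
      sum(dnorm(beta, 0, 1, log = TRUE)) +
      sum(dnorm(u1, 0, s1, log = TRUE)) + dexp(s1, 1, log = TRUE) +
      sum(dnorm(u2, 0, s2, log = TRUE)) + dexp(s2, 1, log = TRUE)
    expect_equal(log_posterior(params, des), oracle, tolerance = 1e-8)

    # row permutation invariance
    perm <- sample(n)
    desp <- lehstress:::new_design(
      y[perm], X[perm, ],
      list(g1 = list(type = "index", idx = idx[perm], K = 3L,
                     labels = paste0("a", 1:3)),
           g2 = list(type = "dense", Z = Z[perm, ], K = 4L,
                     labels = paste0("s", 1:4))),
      "custom", list())
    expect_equal(log_posterior(params, desp), log_posterior(params, des),
                 tolerance = 1e-10)
  }

  # non-positive sd is an error; growing |beta_1| lowers the prior term
  des0 <- lehstress:::new_design(
    1L, matrix(1, 1, 1, dimnames = list(NULL, "b0")),
    list(g = list(type = "index", idx = 1L, K = 1L, labels = "l1")),
    "custom", list())
  bad <- make_params(des0, 0, list(g = 0), c(g = 0))
  expect_error(log_posterior(bad, des0), "positive")
  des0 <- lehstress:::new_design(
    1L, matrix(1, 1, 1, dimnames = list(NULL, "b0")), list(), "custom",
    list())
  lp1 <- log_posterior(make_params(des0, beta = 0.5), des0)
  lp2 <- log_posterior(make_params(des0, beta = 1.5), des0)
  prior1 <- lp1 - log_likelihood(make_params(des0, 0.5), des0)
  prior2 <- lp2 - log_likelihood(make_params(des0, 1.5), des0)
  expect_true(prior2 < prior1)
})

test_that("analytic gradient matches finite differences", {
  set.seed(47)
  cohort <- generate_cohort(
    synthetic_config(n_individuals = c(NEA = 6, UPMH = 6),
                     teeth_target = c(NEA = 30, UPMH = 30), n_sites = 4),
    seed = 7)
  d <- filter_included(cohort$dataset)
  design <- build_design_model1(d)
  for (rep in 1:3) {
    theta <- rnorm(lehstress:::n_unconstrained(design), 0, 0.4)
    got <- lehstress:::logp_grad_unconstrained(theta, design)
    h <- 1e-5
    for (k in sample(length(theta), 12)) {
      tp <- theta; tp[k] <- tp[k] + h
      tm <- theta; tm[k] <- tm[k] - h
      num <- (lehstress:::logp_grad_unconstrained(tp, design)$lp -
                lehstress:::logp_grad_unconstrained(tm, design)$lp) / (2 * h)
      expect_equal(got$grad[k], num, tolerance = 1e-5)
    }
  }
})

test_that("cell-means and treatment codings give identical cell logits", {
  # map fixed parameters between codings and compare fitted cell logits
  d <- full_cell_dataset()
  design <- build_design_model1(d)
  set.seed(53)
  cell_logit <- rnorm(18)
  names(cell_logit) <- design$info$cells$label
  # treatment coding: intercept = first cell, offsets = differences
  ref <- cell_logit[1]
  offsets <- cell_logit - ref
  # fitted logit per row under both parameterizations
  eta_cell <- drop(design$X %*% cell_logit)
  eta_treat <- ref + drop(design$X %*% offsets)
  expect_equal(eta_cell, eta_treat, tolerance = 1e-12)
})

test_that("centered log-posterior agrees with the sampler's internal form", {
  set.seed(59)
  cohort <- generate_cohort(
    synthetic_config(n_individuals = c(NEA = 5, UPMH = 5),
                     teeth_target = c(NEA = 25, UPMH = 25), n_sites = 3),
    seed = 11)
  design <- build_design_model1(filter_included(cohort$dataset))
  Ks <- vapply(design$groups, `[[`, integer(1), "K")
  theta <- rnorm(lehstress:::n_unconstrained(design), 0, 0.3)
  p <- ncol(design$X)
  lam <- theta[p + sum(Ks) + seq_along(Ks)]
  off <- p; u <- list()
  for (g in seq_along(Ks)) {
    u[[names(design$groups)[g]]] <-
      exp(lam[g]) * theta[off + seq_len(Ks[g])]
    off <- off + Ks[g]
  }
  params <- make_params(design, theta[1:p], u,
                        setNames(exp(lam), names(design$groups)))
  lp_centered <- log_posterior(params, design)
  lp_internal <- lehstress:::logp_grad_unconstrained(
    theta, design, jacobian = FALSE)$lp
  # the parameterizations differ exactly by the scale factor K*log(sigma)
  expect_equal(lp_centered, lp_internal - sum(Ks * lam), tolerance = 1e-8)
})
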