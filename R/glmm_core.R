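# Design-matrix construction, spline basis, priors, and the exact
# log-likelihood / log-posterior for both hierarchical Bernoulli models.
#
# A design ("leh_design") is a list:
#   y      binary response vector (one row per tooth for model 1, one row
#          per (individual, stage) for model 2)
#   X      dense fixed-effects matrix with named columns, N(0, coef_sd)
#          priors on its coefficients
#   groups named list of random-effect blocks, each either an "index"
#          block (random intercepts: integer index vector into K levels)
#          or a "dense" block (a basis matrix whose K coefficients share
#          one shrinkage sd) -- the latter is the random-effects
#          representation of a penalized spline
#   info   model-specific metadata (cells, stage standardization, knots)

#' Weakly informative prior specification
#'
#' Normal(0, `coef_sd`) priors on all fixed-effect coefficients and
#' Exponential(`sd_rate`) priors on every random-effect and smoothing
#' standard deviation. The defaults (sd 1, rate 1) are the weakly
#' informative priors used throughout.
#'
#' @param coef_sd Prior standard deviation for coefficients.
#' @param sd_rate Exponential prior rate for standard deviations.
#' @return A list of class `leh_priors`.
#' @export
prior_spec <- function(coef_sd = 1, sd_rate = 1) {
  stopifnot(coef_sd > 0, sd_rate > 0)
  structure(list(coef_sd = coef_sd, sd_rate = sd_rate),
            class = "leh_priors")
}

new_design <- function(y, X, groups, model, info) {
  stopifnot(length(y) == nrow(X))
  structure(list(y = as.integer(y), X = X, groups = groups, model = model,
                 info = info),
            class = "leh_design")
}

index_group <- function(levels_chr) {
  f <- factor(levels_chr)
  list(type = "index", idx = as.integer(f), K = nlevels(f),
       labels = levels(f))
}

dense_group <- function(Z, labels = colnames(Z)) {
  list(type = "dense", Z = Z, K = ncol(Z),
       labels = labels %||% paste0("c", seq_len(ncol(Z))))
}

#' @export
print.leh_design <- function(x, ...) {
  cat(sprintf("<leh_design %s> %d rows, %d fixed effects, groups: %s\n",
              x$model, length(x$y), ncol(x$X),
              paste(sprintf("%s[%d]", names(x$groups),
                            vapply(x$groups, `[[`, integer(1), "K")),
                    collapse = ", ")))
  invisible(x)
}

#' Build the tooth-level defect-presence design (Model 1)
#'
#' One row per included tooth; the response is 1 when the tooth carries
#' at least one hypoplastic defect of any form. Fixed effects use
#' cell-means coding over the 18 taxon-by-tooth-category cells (2 taxa
#' times 8 permanent classes plus the pooled deciduous category), so
#' every reported quantity is a cell logit. Individual and site random
#' intercepts account for repeated measurements.
#'
#' @param dataset A filtered [leh_dataset()] containing both taxa.
#' @return An object of class `leh_design` with `model = "m1"`.
#' @export
build_design_model1 <- function(dataset) {
  stopifnot(inherits(dataset, "leh_dataset"))
  sp <- dataset$specimens
  if (nrow(sp) == 0L) stop("empty dataset", call. = FALSE)
  missing_taxon <- setdiff(TAXA, unique(sp$taxon))
  if (length(missing_taxon)) {
    stop("taxon absent from dataset: ",
         paste(missing_taxon, collapse = ", "),
         " (both groups are required for contrasts)", call. = FALSE)
  }
  y <- as.integer(sp$specimen_id %in% dataset$defects$specimen_id)
  cells <- expand.grid(tooth_class = TOOTH_CLASSES, taxon = TAXA,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("taxon", "tooth_class")]
  cells$label <- paste(cells$taxon, cells$tooth_class, sep = ":")
  X <- matrix(0, nrow(sp), nrow(cells),
              dimnames = list(NULL, paste0("b[", cells$label, "]")))
  row_cell <- match(paste(sp$taxon, sp$tooth_class, sep = ":"), cells$label)
  X[cbind(seq_len(nrow(sp)), row_cell)] <- 1
  groups <- list(ind = index_group(sp$individual_id),
                 site = index_group(sp$site_id))
  new_design(y, X, groups, "m1",
             info = list(cells = cells,
                         rows = sp[, c("specimen_id", "individual_id",
                                       "site_id", "taxon", "tooth_class")]))
}

#' Cubic B-spline basis on equally spaced knots
#'
#' Evaluates `n_basis` cubic B-spline basis functions on equally spaced
#' knots spanning `range`. Within the knot range the basis functions are
#' in \[0, 1\] and sum to 1 at every point (partition of unity). No
#' extrapolation: values of `x` outside `range` are an error.
#'
#' @param x Numeric vector of evaluation points.
#' @param n_basis Number of basis functions (at least 4).
#' @param range Length-2 numeric, the knot range.
#' @return A `length(x)` by `n_basis` matrix.
#' @export
spline_basis <- function(x, n_basis = 8, range = range(x)) {
  if (n_basis < 4) stop("n_basis must be at least 4 for a cubic basis",
                        call. = FALSE)
  lo <- range[1]; hi <- range[2]
  if (any(x < lo | x > hi)) {
    stop("x outside the knot range [", lo, ", ", hi,
         "]: no extrapolation", call. = FALSE)
  }
  knots <- spline_knots(n_basis, c(lo, hi))
  B <- splines::splineDesign(knots, x, ord = 4, outer.ok = FALSE)
  colnames(B) <- paste0("s", seq_len(n_basis))
  B
}

spline_knots <- function(n_basis, range) {
  breaks <- seq(range[1], range[2], length.out = n_basis - 2)
  c(rep(range[1], 3), breaks, rep(range[2], 3))
}

#' Build the individual-level stress-episode design (Model 2)
#'
#' One row per (individual, developmental stage) for individuals that
#' manifest at least one linear (furrow) defect and preserve at least two
#' concurrently forming tooth crowns. Under the default `"observable"`
#' row policy an individual contributes their observable stages plus
#' stage 9 as a structural zero (no enamel forms during the hiatus, so
#' no episode can be recorded there, but the stage is kept so the smooth
#' is anchored across the gap); under `"all_stages"` all 11 stages are
#' emitted. The response is 1 when a matched stress episode exists at
#' that (individual, stage).
#'
#' The stage covariate is standardized to mean 0, sd 1 over the emitted
#' rows. The smooth is a per-taxon cubic B-spline (`n_basis` functions on
#' the standardized image of the full stage range 1..11) whose
#' coefficients share a taxon-specific shrinkage sd -- a random-effects
#' representation of a penalized spline. Fixed effects are a global
#' intercept plus a per-taxon offset so the smooths capture shape rather
#' than level.
#'
#' @param dataset A filtered [leh_dataset()].
#' @param episodes Matched episodes; computed via [match_episodes()] when
#'   `NULL`.
#' @param row_policy `"observable"` (default) or `"all_stages"`.
#' @param n_basis Spline basis dimension per taxon.
#' @return An object of class `leh_design` with `model = "m2"`.
#' @export
build_design_model2 <- function(dataset, episodes = NULL,
                                row_policy = c("observable", "all_stages"),
                                n_basis = 8) {
  stopifnot(inherits(dataset, "leh_dataset"))
  row_policy <- match.arg(row_policy)
  if (is.null(episodes)) episodes <- match_episodes(dataset)
  rs <- risk_sets(dataset)
  sp <- dataset$specimens
  def <- dataset$defects
  has_furrow <- vapply(rs$individual_id, function(id) {
    ids <- sp$specimen_id[sp$individual_id == id]
    any(def$form == "FURROW" & def$specimen_id %in% ids)
  }, logical(1))
  rs <- rs[rs$eligible & has_furrow, , drop = FALSE]
  if (nrow(rs) == 0L) {
    stop("no eligible individuals (need a linear defect and at least two ",
         "concurrently forming crowns)", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(rs)), function(i) {
    stages <- switch(row_policy,
                     observable = sort(unique(c(rs$observable_stages[[i]],
                                                HIATUS_STAGE))),
                     all_stages = 1:11)
    data.frame(individual_id = rs$individual_id[i], taxon = rs$taxon[i],
               site_id = rs$site_id[i], stage = stages,
               stringsAsFactors = FALSE)
  }))
  ep_key <- paste(episodes$individual_id, episodes$stage)
  rows$y <- as.integer(paste(rows$individual_id, rows$stage) %in% ep_key)
  make_design_m2(rows, n_basis, row_policy)
}

# shared constructor for model-2-shaped designs (also used by the
# episode-level simulator)
make_design_m2 <- function(rows, n_basis, row_policy = "observable") {
  stopifnot(all(rows$taxon %in% TAXA))
  mu <- mean(rows$stage)
  sdv <- sd(rows$stage)
  if (!is.finite(sdv) || sdv == 0) {
    stop("degenerate stage covariate: cannot standardize", call. = FALSE)
  }
  std <- function(s) (s - mu) / sdv
  rng <- std(c(1, N_STAGES))
  B <- spline_basis(std(rows$stage), n_basis, rng)
  X <- cbind("(Intercept)" = 1,
             "a[NEA]" = as.numeric(rows$taxon == "NEA"),
             "a[UPMH]" = as.numeric(rows$taxon == "UPMH"))
  groups <- list(
    ind = index_group(rows$individual_id),
    site = index_group(rows$site_id),
    "sm:NEA" = dense_group(B * (rows$taxon == "NEA"),
                           paste0("NEA.s", seq_len(n_basis))),
    "sm:UPMH" = dense_group(B * (rows$taxon == "UPMH"),
                            paste0("UPMH.s", seq_len(n_basis)))
  )
  new_design(rows$y, X, groups, "m2",
             info = list(stage_mean = mu, stage_sd = sdv,
                         n_basis = n_basis, knot_range = rng,
                         row_policy = row_policy, rows = rows))
}

# ---- parameters ------------------------------------------------------

#' Construct a parameter vector for a design
#'
#' Parameters live on the natural (centered) scale: fixed-effect
#' coefficients `beta`, per-block random effects `u` (e.g. individual
#' and site intercepts, spline coefficients) and per-block standard
#' deviations `sigma`.
#'
#' @param design An `leh_design`.
#' @param beta Fixed-effect coefficients (recycled scalar allowed).
#' @param u Named list of random-effect vectors, one per design group;
#'   zeros when omitted.
#' @param sigma Named numeric of block sds; ones when omitted.
#' @return A list of class `leh_params`.
#' @export
make_params <- function(design, beta = 0, u = NULL, sigma = NULL) {
  p <- ncol(design$X)
  beta <- rep_len(beta, p)
  names(beta) <- colnames(design$X)
  gn <- names(design$groups)
  if (is.null(u)) {
    u <- lapply(design$groups, function(g) numeric(g$K))
  }
  if (is.null(sigma)) {
    sigma <- rep(1, length(gn)); names(sigma) <- gn
  }
  stopifnot(identical(sort(names(u)), sort(gn)) || length(gn) == 0L)
  structure(list(beta = beta, u = u[gn], sigma = sigma[gn]),
            class = "leh_params")
}

linear_predictor <- function(params, design) {
  eta <- drop(design$X %*% params$beta)
  for (g in names(design$groups)) {
    grp <- design$groups[[g]]
    u <- params$u[[g]]
    if (length(u) != grp$K) {
      stop("dimension mismatch for group '", g, "': expected ", grp$K,
           " effects, got ", length(u), call. = FALSE)
    }
    eta <- eta + if (grp$type == "index") u[grp$idx] else drop(grp$Z %*% u)
  }
  eta
}

#' Bernoulli log-likelihood of a parameter vector
#'
#' Computes `sum(y*log(p) + (1-y)*log(1-p))` with
#' `p = plogis(eta)` and `eta = X beta + sum of group contributions`,
#' using numerically stable log-sigmoid evaluation. Finite for any
#' finite parameters.
#'
#' @param params An [make_params()] list.
#' @param design An `leh_design`.
#' @return A single number.
#' @export
log_likelihood <- function(params, design) {
  if (length(params$beta) != ncol(design$X)) {
    stop("dimension mismatch: ", length(params$beta), " coefficients for ",
         ncol(design$X), " design columns", call. = FALSE)
  }
  if (length(design$y) == 0L) return(0)
  eta <- linear_predictor(params, design)
  sum(ifelse(design$y == 1L, plogis(eta, log.p = TRUE),
             plogis(-eta, log.p = TRUE)))
}

#' Log-posterior density (unnormalized in the data, exact in the priors)
#'
#' `log_likelihood` plus the full prior log-density: independent
#' Normal(0, `coef_sd`) on each fixed-effect coefficient, Normal(0,
#' `sigma[g]`) on every random effect of block `g`, and
#' Exponential(`sd_rate`) on each block sd. All normalizing constants
#' are included.
#'
#' @inheritParams log_likelihood
#' @param priors A [prior_spec()].
#' @return A single number.
#' @export
log_posterior <- function(params, design, priors = prior_spec()) {
  if (any(params$sigma <= 0)) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  lp <- log_likelihood(params, design)
  lp <- lp + sum(dnorm(params$beta, 0, priors$coef_sd, log = TRUE))
  for (g in names(design$groups)) {
    lp <- lp + sum(dnorm(params$u[[g]], 0, params$sigma[[g]], log = TRUE))
    lp <- lp + dexp(params$sigma[[g]], priors$sd_rate, log = TRUE)
  }
  lp
}

# ---- unconstrained parameterization (sampler internal) ---------------
# theta = (beta, z_g for each group, log sigma_g for each group) with the
# non-centered transform u_g = sigma_g * z_g. Identical posterior;
# chosen for sampler stability in hierarchical funnels.

n_unconstrained <- function(design) {
  ncol(design$X) + sum(vapply(design$groups, `[[`, integer(1), "K")) +
    length(design$groups)
}

unconstrained_names <- function(design) {
  gn <- names(design$groups) %||% character(0)
  nm <- colnames(design$X)
  for (g in gn) {
    nm <- c(nm, paste0("z[", g, ":", design$groups[[g]]$labels, "]"))
  }
  c(nm, if (length(gn)) paste0("log_sigma[", gn, "]"))
}

# natural-scale parameter names used in the draws array
natural_names <- function(design) {
  gn <- names(design$groups) %||% character(0)
  nm <- colnames(design$X)
  for (g in gn) {
    nm <- c(nm, paste0("u[", g, ":", design$groups[[g]]$labels, "]"))
  }
  c(nm, if (length(gn)) paste0("sigma[", gn, "]"))
}

params_to_unconstrained <- function(params, design) {
  z <- unlist(lapply(names(design$groups), function(g)
    params$u[[g]] / params$sigma[[g]]), use.names = FALSE)
  c(params$beta, z, log(params$sigma))
}

# data list consumed by the C++ log-posterior / sampler
design_cpp_data <- function(design, priors) {
  groups <- design$groups
  list(
    y = as.numeric(design$y),
    X = design$X,
    group_type = vapply(groups, function(g)
      if (g$type == "index") 0L else 1L, integer(1)),
    group_idx = lapply(groups, function(g)
      if (g$type == "index") g$idx - 1L else integer()),
    group_Z = lapply(groups, function(g)
      if (g$type == "dense") g$Z else matrix(0, 0, 0)),
    group_K = vapply(groups, `[[`, integer(1), "K"),
    coef_sd = priors$coef_sd,
    sd_rate = priors$sd_rate
  )
}

#' Export a design matrix for external inspection
#'
#' Writes the fixed-effects matrix (plus the response and group index
#' columns) as a dense comma-separated file, with a JSON sidecar
#' (`<path>.json`) describing column names, group structure and row
#' count. Intended for debugging and cross-checking against external
#' tools.
#'
#' @param design An `leh_design`.
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @return The path, invisibly.
#' @export
write_design <- function(design, path) {
  out <- data.frame(y = design$y, design$X, check.names = FALSE)
  for (g in names(design$groups)) {
    grp <- design$groups[[g]]
    if (grp$type == "index") out[[paste0("idx_", g)]] <- grp$idx
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    model = design$model,
    n_rows = length(design$y),
    fixed_effects = colnames(design$X),
    groups = lapply(design$groups, function(g)
      list(type = g$type, K = g$K, labels = g$labels)))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# exact log-posterior and analytic gradient on the unconstrained scale;
# jacobian = TRUE adds the log|d sigma / d log sigma| term the sampler
# uses. Exposed for gradient checking.
logp_grad_unconstrained <- function(theta, design,
                                    priors = prior_spec(),
                                    jacobian = TRUE) {
  lehstress_logp_grad(as.numeric(theta), design_cpp_data(design, priors),
                      jacobian)
}
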