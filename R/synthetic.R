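# Seeded synthetic cohort generation with known ground truth, emulating
# the study's hierarchical structure: two taxa, ~56 sites, 74 + 102
# individuals, ~867 included teeth, taxon-specific stage-wise systemic
# stress curves, and individual- and site-level random intercepts.

#' Default taxon-specific stage-wise stress curves
#'
#' Qualitative shapes of the stage-wise systemic stress probabilities:
#' the UPMH curve rises from stage 1 and peaks around 0.30 at stage 3.5
#' before decaying, the NEA curve rises from stage 3, peaks at 0.35 at
#' stage 6, and drops to zero after stage 8. Stage 9 (the formation
#' hiatus) is structurally zero for both. These are qualitative pattern
#' choices, not fitted values.
#'
#' @return A 2 x 11 matrix (rows `NEA`, `UPMH`) of probabilities.
#' @export
default_stress_curves <- function() {
  s <- 1:11
  upmh <- 0.30 * exp(-(s - 3.5)^2 / (2 * 1.5^2))
  nea <- 0.35 * exp(-(s - 6)^2 / (2 * 1.3^2))
  nea[s >= 9] <- 0
  upmh[9] <- 0
  rbind(NEA = nea, UPMH = upmh)
}

# peak stage of a curve defined by Gaussian bumps above (continuous)
stress_curve_peaks <- function() c(NEA = 6, UPMH = 3.5)

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study's declared counts in expectation: 74 NEA
#' and 102 UPMH individuals across 56 sites, and 423 + 444 included
#' teeth after the preservation filter. Teeth per individual follow a
#' zero-truncated Poisson whose mean is chosen so that the expected
#' number of *included* teeth per taxon matches the declared counts,
#' given the preservation pass rate (`include_rate`, default the
#' study-wide 867/1048). Defects arise from two layers: systemic stress
#' events drawn per (individual, stage) from `stress_curves` (on the
#' logit scale, shifted by individual and site random intercepts) that
#' deposit furrow defects on every preserved crown third forming at that
#' stage (subject to `manifest_prob`), plus idiosyncratic defects per
#' tooth from `baseline_logit`.
#'
#' @param n_individuals Named vector, individuals per taxon.
#' @param n_sites Number of sites; individuals are assigned by
#'   `site_weights` (default proportional to 1/rank, a few large and
#'   many small sites).
#' @param site_weights Optional site sampling weights.
#' @param teeth_target Named vector, expected included teeth per taxon.
#' @param include_rate Probability a generated tooth passes the
#'   preservation filter.
#' @param tooth_class_probs Sampling distribution over tooth classes.
#' @param crown_beta Beta(a, b) shape for `crown_fraction_preserved`.
#' @param baseline_logit Idiosyncratic (non-systemic) per-tooth defect
#'   logit: a single number or a 2 x 9 matrix (taxa x classes). Default
#'   `qlogis(0.05)`.
#' @param sigma_ind,sigma_site Random-intercept standard deviations.
#' @param stress_curves 2 x 11 matrix of stage-wise stress
#'   probabilities; row names `NEA`, `UPMH`; column 9 must be 0.
#' @param manifest_prob Probability a systemic event marks any one
#'   concurrently forming tooth.
#' @return A list of class `leh_synth_config`.
#' @export
synthetic_config <- function(n_individuals = c(NEA = 74, UPMH = 102),
                             n_sites = 56,
                             site_weights = NULL,
                             teeth_target = c(NEA = 423, UPMH = 444),
                             include_rate = 867 / 1048,
                             tooth_class_probs = NULL,
                             crown_beta = c(5, 1.5),
                             baseline_logit = qlogis(0.05),
                             sigma_ind = 0.5,
                             sigma_site = 0.3,
                             stress_curves = default_stress_curves(),
                             manifest_prob = 0.9) {
  stopifnot(all(n_individuals >= 1), n_sites >= 1,
            include_rate > 0, include_rate <= 1,
            manifest_prob >= 0, manifest_prob <= 1,
            sigma_ind >= 0, sigma_site >= 0)
  if (!all(stress_curves >= 0 & stress_curves <= 1)) {
    stop("stress probabilities must lie in [0,1]", call. = FALSE)
  }
  if (any(stress_curves[, HIATUS_STAGE] != 0)) {
    stop("stage 9 is a formation hiatus: its stress probability must be 0",
         call. = FALSE)
  }
  if (is.null(tooth_class_probs)) {
    tooth_class_probs <- c(DECIDUOUS = 0.15,
                           stats::setNames(rep(0.85 / 8, 8),
                                           PERMANENT_CLASSES))
  }
  tooth_class_probs <- tooth_class_probs / sum(tooth_class_probs)
  if (is.null(site_weights)) site_weights <- 1 / seq_len(n_sites)
  if (length(baseline_logit) == 1L) {
    baseline_logit <- matrix(baseline_logit, 2, length(TOOTH_CLASSES),
                             dimnames = list(TAXA, TOOTH_CLASSES))
  }
  # pass rate decomposes into the crown-fraction cut and the surface
  # condition; solve the surface probability from the target pass rate
  p_crown <- 1 - stats::pbeta(0.5, crown_beta[1], crown_beta[2])
  p_surface <- include_rate / p_crown
  if (p_surface > 1) {
    stop("include_rate unattainable for the chosen crown_beta shape",
         call. = FALSE)
  }
  # zero-truncated Poisson mean solving E[X | X >= 1] = target
  mean_gen <- teeth_target / n_individuals[names(teeth_target)] /
    include_rate
  lambda <- vapply(mean_gen, function(m) {
    uniroot(function(l) l / (1 - exp(-l)) - m, c(1e-8, 4 * m))$root
  }, numeric(1))
  structure(list(n_individuals = n_individuals, n_sites = n_sites,
                 site_weights = site_weights / sum(site_weights),
                 teeth_target = teeth_target, include_rate = include_rate,
                 tooth_class_probs = tooth_class_probs,
                 crown_beta = crown_beta, p_surface = p_surface,
                 lambda_teeth = lambda, baseline_logit = baseline_logit,
                 sigma_ind = sigma_ind, sigma_site = sigma_site,
                 stress_curves = stress_curves,
                 manifest_prob = manifest_prob),
            class = "leh_synth_config")
}

rtpois <- function(n, lambda) {
  # zero-truncated Poisson by inverse CDF on the truncated distribution
  u <- runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Generate a synthetic cohort with ground truth
#'
#' Deterministic given `seed`. Generation is two-layered: (1) per
#' (individual, stage) a systemic stress event is drawn with probability
#' `plogis(qlogis(pi_taxon(stage)) + u_ind + v_site)`; an event deposits
#' a furrow defect on the earliest-forming crown third of every tooth of
#' that individual forming at that stage, each with probability
#' `manifest_prob`; (2) idiosyncratic defects are added per tooth from
#' the baseline logits. Generated datasets always pass [leh_dataset()]
#' validation.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A list with elements `dataset` (unfiltered [leh_dataset()])
#'   and `truth` (events per (individual, stage), realized random
#'   intercepts, and the config).
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "leh_synth_config"))
  set.seed(seed)
  taxa <- rep(names(config$n_individuals), config$n_individuals)
  n_ind <- length(taxa)
  ind_ids <- sprintf("IND%04d", seq_len(n_ind))
  site_ids <- sprintf("S%02d", seq_len(config$n_sites))
  ind_site <- sample(site_ids, n_ind, replace = TRUE,
                     prob = config$site_weights)
  u_ind <- rnorm(n_ind, 0, config$sigma_ind)
  v_site <- rnorm(config$n_sites, 0, config$sigma_site)
  names(u_ind) <- ind_ids
  names(v_site) <- site_ids

  classes <- names(config$tooth_class_probs)
  sp_list <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    k <- rtpois(1, config$lambda_teeth[[taxa[i]]])
    cls <- sample(classes, k, replace = TRUE,
                  prob = config$tooth_class_probs)
    sp_list[[i]] <- data.frame(
      individual_id = ind_ids[i], site_id = ind_site[i], taxon = taxa[i],
      tooth_class = cls,
      jaw = sample(c("UPPER", "LOWER"), k, replace = TRUE),
      crown_fraction_preserved = round(rbeta(k, config$crown_beta[1],
                                             config$crown_beta[2]), 4),
      surface_ok = runif(k) < config$p_surface,
      stringsAsFactors = FALSE)
  }
  sp <- do.call(rbind, sp_list)
  sp$specimen_id <- sprintf("T%05d", seq_len(nrow(sp)))
  sp <- sp[, SPECIMEN_COLS]

  # stage sets per tooth: earliest-forming third mapping to each stage
  tab <- stage_table()
  jaw_key <- ifelse(sp$tooth_class %in% c("I1", "I2"), sp$jaw, "ANY")
  tooth_stage_third <- lapply(seq_len(nrow(sp)), function(j) {
    e <- tab[tab$tooth_class == sp$tooth_class[j] & tab$jaw == jaw_key[j], ]
    # earliest third per stage
    vapply(split(e$crown_third, e$stage), min, integer(1))
  })

  # layer 1: systemic stress events
  d_spec <- character(0); d_form <- character(0)
  d_third <- integer(0); d_surf <- character(0)
  ev_ind <- character(0); ev_taxon <- character(0); ev_stage <- integer(0)
  curves <- config$stress_curves
  ind_rows <- split(seq_len(nrow(sp)), sp$individual_id)
  for (i in seq_len(n_ind)) {
    pi_s <- curves[taxa[i], ]
    eta <- qlogis(pmin(pmax(pi_s, 1e-12), 1 - 1e-12)) +
      u_ind[i] + v_site[ind_site[i]]
    p <- ifelse(pi_s <= 0, 0, ifelse(pi_s >= 1, 1, plogis(eta)))
    ev <- which(runif(N_STAGES) < p)
    if (length(ev)) {
      ev_ind <- c(ev_ind, rep(ind_ids[i], length(ev)))
      ev_taxon <- c(ev_taxon, rep(taxa[i], length(ev)))
      ev_stage <- c(ev_stage, ev)
      teeth_i <- ind_rows[[ind_ids[i]]]
      for (s in ev) {
        for (j in teeth_i) {
          thirds <- tooth_stage_third[[j]]
          hit <- match(as.character(s), names(thirds))
          if (!is.na(hit) && runif(1) < config$manifest_prob) {
            d_spec <- c(d_spec, sp$specimen_id[j])
            d_form <- c(d_form, "FURROW")
            d_third <- c(d_third, as.integer(thirds[hit]))
            d_surf <- c(d_surf, sample(c("LINGUAL", "BUCCAL_LABIAL"), 1))
          }
        }
      }
    }
  }

  # layer 2: idiosyncratic defects, shifted by the same individual and
  # site intercepts that drive systemic stress
  p_idio <- plogis(config$baseline_logit[cbind(sp$taxon, sp$tooth_class)] +
                     u_ind[sp$individual_id] + v_site[sp$site_id])
  idio <- which(runif(nrow(sp)) < p_idio)
  for (j in idio) {
    form <- if (sp$tooth_class[j] == "DECIDUOUS") {
      sample(DEFECT_FORMS, 1, prob = c(0.5, 0.3, 0.2))
    } else {
      sample(c("FURROW", "PIT"), 1, prob = c(0.65, 0.35))
    }
    d_spec <- c(d_spec, sp$specimen_id[j])
    d_form <- c(d_form, form)
    d_third <- c(d_third, sample(1:3, 1))
    d_surf <- c(d_surf, sample(c("LINGUAL", "BUCCAL_LABIAL"), 1))
  }

  defects <- if (length(d_spec)) {
    data.frame(specimen_id = d_spec, form = d_form, crown_third = d_third,
               surface = d_surf, stringsAsFactors = FALSE)
  } else {
    empty_defects()
  }
  defects <- defects[order(defects$specimen_id, defects$form,
                           defects$crown_third), , drop = FALSE]
  rownames(defects) <- NULL
  events <- data.frame(individual_id = ev_ind, taxon = ev_taxon,
                       stage = ev_stage, stringsAsFactors = FALSE)
  list(dataset = leh_dataset(sp, defects),
       truth = list(events = events, u_ind = u_ind, v_site = v_site,
                    config = config, seed = seed))
}

#' Simulate episode-level model-2 rows directly
#'
#' Bypasses tooth generation and episode matching: draws the binary
#' stress-episode indicator per (individual, stage) row directly from
#' `plogis(qlogis(pi(stage)) + u_ind + v_site)`. Used for calibration of
#' the smooth and derivative machinery with exactly known generating
#' curves. Each individual's observable stages are drawn independently
#' with probability `obs_prob`; with `structural_hiatus = TRUE` stage 9
#' is added as a structural zero row (mirroring the observational
#' design), otherwise stage 9 is treated like any other stage.
#'
#' @param n_individuals Named vector of individuals per taxon.
#' @param curves 2 x 11 probability matrix (rows `NEA`, `UPMH`).
#' @param sigma_ind,sigma_site Random-intercept sds.
#' @param n_sites Number of sites.
#' @param obs_prob Per-stage observability probability.
#' @param structural_hiatus See above.
#' @param n_basis Spline basis size for the resulting design.
#' @param seed Integer seed.
#' @return A list with `design` (`leh_design`, model `"m2"`) and
#'   `truth` (curves and intercepts).
#' @export
simulate_stage_rows <- function(n_individuals = c(NEA = 35, UPMH = 37),
                                curves = default_stress_curves(),
                                sigma_ind = 0.5, sigma_site = 0.3,
                                n_sites = 20, obs_prob = 0.7,
                                structural_hiatus = TRUE, n_basis = 8,
                                seed = 1) {
  set.seed(seed)
  taxa <- rep(names(n_individuals), n_individuals)
  n_ind <- length(taxa)
  ind_ids <- sprintf("IND%04d", seq_len(n_ind))
  site_ids <- sprintf("S%02d", seq_len(n_sites))
  ind_site <- sample(site_ids, n_ind, replace = TRUE)
  u <- rnorm(n_ind, 0, sigma_ind)
  v <- rnorm(n_sites, 0, sigma_site)
  names(v) <- site_ids
  rows <- list()
  for (i in seq_len(n_ind)) {
    stages <- if (structural_hiatus) {
      setdiff(1:11, HIATUS_STAGE)
    } else {
      1:11
    }
    obs <- stages[runif(length(stages)) < obs_prob]
    while (length(obs) < 2L) {  # eligibility needs >= 2 stages
      obs <- stages[runif(length(stages)) < obs_prob]
    }
    if (structural_hiatus) obs <- sort(c(obs, HIATUS_STAGE))
    pi_s <- curves[taxa[i], obs]
    eta <- qlogis(pmin(pmax(pi_s, 1e-12), 1 - 1e-12)) + u[i] +
      v[ind_site[i]]
    p <- ifelse(pi_s <= 0, 0, plogis(eta))
    rows[[i]] <- data.frame(individual_id = ind_ids[i], taxon = taxa[i],
                            site_id = ind_site[i], stage = obs,
                            y = as.integer(runif(length(obs)) < p),
                            stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  list(design = make_design_m2(rows, n_basis),
       truth = list(curves = curves, u_ind = u, v_site = v,
                    sigma_ind = sigma_ind, sigma_site = sigma_site))
}

#' Parameter-recovery and calibration experiments
#'
#' Repeatedly simulates data with known ground truth, fits the relevant
#' model with (scaled-down) sampler settings, and scores recovery.
#' Three experiment kinds:
#'
#' * `"model1_cells"`: cohorts with stress curves off and known per-cell
#'   defect logits; scores bias, RMSE and 95% CrI coverage of the 18
#'   cell probabilities plus bias of `sigma[ind]`.
#' * `"model2_flat"`: episode rows from a constant stress curve (no
#'   structural hiatus), scoring how often any derivative change period
#'   is (falsely) flagged.
#' * `"model2_increasing"`: episode rows from a strongly increasing
#'   stress curve (logistic ramp, no structural hiatus), scoring how
#'   often an INCREASE period is correctly flagged.
#' * `"model2_peaks"`: episode rows from the default peaked curves,
#'   scoring whether the posterior-median curve's argmax per taxon lands
#'   within +-1 stage of the generating peak.
#'
#' Replicates failing the convergence gates are recorded, never dropped.
#'
#' @param kind Experiment kind.
#' @param n_replicates Number of simulated replicates.
#' @param n_individuals Individuals per taxon.
#' @param n_chains,n_iter,n_warmup Sampler settings per replicate.
#' @param seed Master seed; per-replicate seeds are fanned out.
#' @param flat_level Constant episode probability for `"model2_flat"`.
#' @return A list with a per-replicate table `replicates`, a per-cell or
#'   per-taxon summary `summary`, and the experiment settings.
#' @export
recovery_experiment <- function(kind = c("model1_cells", "model2_flat",
                                         "model2_increasing",
                                         "model2_peaks"),
                                n_replicates = 20,
                                n_individuals = c(NEA = 60, UPMH = 60),
                                n_chains = 2, n_iter = 500,
                                n_warmup = 500, seed = 1,
                                flat_level = 0.2) {
  kind <- match.arg(kind)
  if (kind == "model1_cells") {
    return(recovery_model1(n_replicates, n_individuals, n_chains, n_iter,
                           n_warmup, seed))
  }
  curves <- switch(kind,
    model2_flat = matrix(flat_level, 2, 11, dimnames = list(TAXA, NULL)),
    model2_increasing = matrix(rep(plogis(seq(-3, 0.5, length.out = 11)),
                                   each = 2),
                               2, 11, dimnames = list(TAXA, NULL)),
    model2_peaks = default_stress_curves())
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rs <- fan_out_seed(seed, 100 + r)
    sim <- simulate_stage_rows(
      n_individuals = n_individuals, curves = curves,
      structural_hiatus = (kind == "model2_peaks"), seed = rs)
    draws <- run_mcmc(sim$design, n_chains = n_chains, n_iter = n_iter,
                      n_warmup = n_warmup, seed = fan_out_seed(rs, 7))
    diag <- diagnose(draws)
    if (kind %in% c("model2_flat", "model2_increasing")) {
      segs <- derivative_segments(draws)
      reps[[r]] <- data.frame(
        replicate = r, any_flagged = nrow(segs) > 0,
        any_increase = any(segs$sign == "INCREASE"),
        n_segments = nrow(segs), converged = attr(diag, "pass"))
    } else {
      grid <- seq(1, 11, length.out = 201)
      cv <- smooth_curve(draws, grid = grid)
      am <- vapply(TAXA, function(t) {
        ct <- cv[cv$taxon == t, ]
        ct$stage[which.max(ct$median)]
      }, numeric(1))
      truth <- stress_curve_peaks()
      reps[[r]] <- data.frame(replicate = r, taxon = TAXA, argmax = am,
                              true_peak = truth[TAXA],
                              within_1 = abs(am - truth[TAXA]) <= 1,
                              converged = attr(diag, "pass"))
    }
  }
  replicates <- do.call(rbind, reps)
  rownames(replicates) <- NULL
  summary <- if (kind %in% c("model2_flat", "model2_increasing")) {
    data.frame(flagged_fraction = mean(replicates$any_flagged),
               increase_fraction = mean(replicates$any_increase))
  } else {
    stats::aggregate(within_1 ~ taxon, replicates, mean)
  }
  list(kind = kind, replicates = replicates, summary = summary,
       settings = list(n_replicates = n_replicates,
                       n_individuals = n_individuals, seed = seed))
}

recovery_model1 <- function(n_replicates, n_individuals, n_chains, n_iter,
                            n_warmup, seed) {
  # per-replicate cell logits drawn from the model's own N(0,1) prior
  # (simulation-based calibration: credible-interval coverage is then
  # nominal when the sampler is correct)
  sigma_ind_true <- 0.5
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rs <- fan_out_seed(seed, 200 + r)
    set.seed(fan_out_seed(rs, 3))
    true_logit <- matrix(rnorm(18), 2, 9,
                         dimnames = list(TAXA, TOOTH_CLASSES))
    cfg <- synthetic_config(
      n_individuals = n_individuals, n_sites = 20,
      teeth_target = round(5 * n_individuals), include_rate = 867 / 1048,
      baseline_logit = true_logit, sigma_ind = sigma_ind_true,
      sigma_site = 0.3,
      stress_curves = matrix(0, 2, 11, dimnames = list(TAXA, NULL)))
    cohort <- generate_cohort(cfg, seed = rs)
    dat <- filter_included(cohort$dataset)
    design <- build_design_model1(dat)
    draws <- run_mcmc(design, n_chains = n_chains, n_iter = n_iter,
                      n_warmup = n_warmup, seed = fan_out_seed(rs, 7))
    diag <- diagnose(draws)
    cp <- cell_probabilities(draws)
    truth_p <- plogis(true_logit[cbind(cp$taxon, cp$tooth_class)])
    sig <- median(param_column(draws, "sigma[ind]"))
    reps[[r]] <- data.frame(
      replicate = r, label = cp$label, truth = truth_p,
      median = cp$median, lower95 = cp$lower95, upper95 = cp$upper95,
      covered = cp$lower95 <= truth_p & truth_p <= cp$upper95,
      sigma_ind_median = sig, converged = attr(diag, "pass"),
      stringsAsFactors = FALSE)
  }
  replicates <- do.call(rbind, reps)
  rownames(replicates) <- NULL
  per_cell <- stats::aggregate(cbind(covered, err = median - truth) ~ label,
                               replicates, mean)
  list(kind = "model1_cells", replicates = replicates,
       summary = data.frame(
         coverage = mean(replicates$covered),
         bias_sigma_ind = mean(replicates$sigma_ind_median[
           !duplicated(replicates$replicate)]) - sigma_ind_true),
       per_cell = per_cell,
       truth = list(sigma_ind = sigma_ind_true),
       settings = list(n_replicates = n_replicates,
                       n_individuals = n_individuals, seed = seed))
}
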