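# In-code fixtures: small specimen/defect tables and random datasets.

specimen_row <- function(specimen_id, individual_id = "ind1",
                         site_id = "s1", taxon = "NEA",
                         tooth_class = "M1", jaw = "UPPER",
                         crown_fraction_preserved = 0.9,
                         surface_ok = TRUE) {
  data.frame(specimen_id = specimen_id, individual_id = individual_id,
             site_id = site_id, taxon = taxon, tooth_class = tooth_class,
             jaw = jaw,
             crown_fraction_preserved = crown_fraction_preserved,
             surface_ok = surface_ok, stringsAsFactors = FALSE)
}

defect_row <- function(specimen_id, form = "FURROW", crown_third = 1L,
                       surface = "LINGUAL") {
  data.frame(specimen_id = specimen_id, form = form,
             crown_third = as.integer(crown_third), surface = surface,
             stringsAsFactors = FALSE)
}

# random valid specimen table; individuals nested in sites and taxa
random_specimens <- function(n, n_ind = max(2, n %/% 3), n_sites = 3) {
  classes <- c("DECIDUOUS", "I1", "I2", "C", "P3", "P4", "M1", "M2", "M3")
  ind <- sprintf("ind%02d", seq_len(n_ind))
  ind_taxon <- sample(c("NEA", "UPMH"), n_ind, replace = TRUE)
  ind_site <- sample(sprintf("s%02d", seq_len(n_sites)), n_ind,
                     replace = TRUE)
  i <- sample(n_ind, n, replace = TRUE)
  cls <- sample(classes, n, replace = TRUE)
  data.frame(
    specimen_id = sprintf("sp%03d", seq_len(n)),
    individual_id = ind[i], site_id = ind_site[i], taxon = ind_taxon[i],
    tooth_class = cls,
    jaw = ifelse(cls %in% c("I1", "I2"),
                 sample(c("UPPER", "LOWER"), n, replace = TRUE),
                 sample(c("UPPER", "LOWER", "UNKNOWN"), n,
                        replace = TRUE)),
    crown_fraction_preserved = round(runif(n), 3),
    surface_ok = runif(n) < 0.8, stringsAsFactors = FALSE)
}

random_defects <- function(specimens, n) {
  cls <- specimens$tooth_class
  sid <- sample(specimens$specimen_id, n, replace = TRUE)
  form <- vapply(sid, function(s) {
    if (specimens$tooth_class[match(s, specimens$specimen_id)] ==
        "DECIDUOUS") {
      sample(c("FURROW", "PIT", "LHPC"), 1)
    } else {
      sample(c("FURROW", "PIT"), 1)
    }
  }, character(1))
  data.frame(specimen_id = sid, form = form,
             crown_third = sample(1:3, n, replace = TRUE),
             surface = sample(c("LINGUAL", "BUCCAL_LABIAL"), n,
                              replace = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

# small complete two-taxon dataset covering every (taxon, class) cell
full_cell_dataset <- function(defect_rate = 0.3, seed = 99) {
  set.seed(seed)
  classes <- c("DECIDUOUS", "I1", "I2", "C", "P3", "P4", "M1", "M2", "M3")
  rows <- list(); k <- 0
  for (taxon in c("NEA", "UPMH")) {
    for (ind in 1:6) {
      for (cl in classes) {
        k <- k + 1
        rows[[k]] <- specimen_row(
          sprintf("sp%03d", k),
          individual_id = sprintf("%s_ind%d", taxon, ind),
          site_id = sprintf("s%d", 1 + (ind %% 3)), taxon = taxon,
          tooth_class = cl,
          jaw = sample(c("UPPER", "LOWER"), 1))
      }
    }
  }
  sp <- do.call(rbind, rows)
  hit <- runif(nrow(sp)) < defect_rate
  def <- if (any(hit)) {
    do.call(rbind, lapply(which(hit), function(j)
      defect_row(sp$specimen_id[j],
                 form = if (sp$tooth_class[j] == "DECIDUOUS")
                   sample(c("FURROW", "PIT", "LHPC"), 1)
                 else sample(c("FURROW", "PIT"), 1),
                 crown_third = sample(1:3, 1))))
  } else {
    lehstress:::empty_defects()
  }
  leh_dataset(sp, def)
}

# spline coefficients representing an exactly linear logit b * z over
# the knot range, via the Greville abscissae of the cubic basis
approx_linear_spline_coefs <- function(design, slope, taxon = "NEA") {
  info <- design$info
  knots <- lehstress:::spline_knots(info$n_basis, info$knot_range)
  greville <- vapply(seq_len(info$n_basis), function(i)
    mean(knots[i + 1:3]), numeric(1))
  u <- lapply(design$groups, function(g) numeric(g$K))
  u[[paste0("sm:", taxon)]] <- slope * greville
  sigma <- stats::setNames(rep(1, length(design$groups)),
                           names(design$groups))
  list(u = u, sigma = sigma)
}

# degenerate posterior: every draw identical, built from one params list
degenerate_draws <- function(design, params, n_draws = 50, n_chains = 2) {
  nm <- lehstress:::natural_names(design)
  row <- c(params$beta,
           unlist(params$u, use.names = FALSE),
           unname(params$sigma))
  arr <- array(rep(row, each = n_draws * n_chains),
               c(n_draws, n_chains, length(nm)),
               dimnames = list(NULL, NULL, nm))
  new_leh_draws(arr, design)
}
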