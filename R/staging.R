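# The eleven-stage crown-formation staging system: deterministic stage
# assignment of crown thirds, matched systemic-stress-episode detection,
# and per-individual stage risk sets.
#
# Stages mark concurrent formation of crown thirds across tooth types in
# the reference dental development schedule. Stage 1 pools the deciduous
# dentition; stages 2-8 cover permanent crown formation from incisor
# initiation to second-molar completion; stage 9 is the developmental
# hiatus between M2 completion and M3 initiation (no crown forms, so no
# crown third ever maps to it); stages 10-11 cover the third molar.

#' The crown-third to developmental-stage map
#'
#' Returns the deterministic map from (tooth class, jaw, crown third) to
#' developmental stage. Jaw matters only for incisors (upper and lower
#' incisors complete their thirds at different stages); for all other
#' classes the `jaw` column is `ANY`. Deciduous teeth map to stage 1 for
#' every third. No entry maps to stage 9, the crown developmental hiatus.
#'
#' @return A data frame with columns `tooth_class`, `jaw`
#'   (`UPPER`/`LOWER`/`ANY`), `crown_third` (1..3) and `stage` (1..11).
#' @seealso [assign_stage()], [stage_reference_ages()]
#' @export
stage_table <- function() {
  entry <- function(class, jaw, stages) {
    data.frame(tooth_class = class, jaw = jaw, crown_third = 1:3,
               stage = as.integer(stages), stringsAsFactors = FALSE)
  }
  rbind(
    entry("DECIDUOUS", "ANY", c(1, 1, 1)),
    entry("I1", "UPPER", c(2, 3, 5)),
    entry("I1", "LOWER", c(2, 3, 4)),
    entry("I2", "UPPER", c(3, 4, 5)),
    entry("I2", "LOWER", c(2, 3, 4)),
    entry("C",  "ANY",   c(3, 4, 6)),
    entry("P3", "ANY",   c(4, 5, 6)),
    entry("P4", "ANY",   c(5, 6, 7)),
    entry("M1", "ANY",   c(2, 3, 4)),
    entry("M2", "ANY",   c(6, 7, 8)),
    entry("M3", "ANY",   c(10, 11, 11))
  )
}

#' Assign a developmental stage to a crown third
#'
#' Vectorized deterministic lookup in the [stage_table()]. Jaw must be
#' known (`UPPER` or `LOWER`) for incisors because upper and lower
#' incisors differ in the stage at which each third completes; for all
#' other tooth classes jaw is ignored.
#'
#' @param tooth_class Character vector of tooth classes.
#' @param jaw Character vector of jaws (`UPPER`, `LOWER`, `UNKNOWN`).
#' @param crown_third Integer vector in 1..3 (1 = incisal/occlusal,
#'   3 = cervical).
#' @return Integer vector of stages in 1..11 (never 9).
#' @export
assign_stage <- function(tooth_class, jaw, crown_third) {
  n <- max(length(tooth_class), length(jaw), length(crown_third))
  tooth_class <- rep_len(as.character(tooth_class), n)
  jaw <- rep_len(as.character(jaw), n)
  crown_third <- rep_len(as.integer(crown_third), n)
  if (!all(tooth_class %in% TOOTH_CLASSES)) {
    stop("unknown tooth_class: ",
         paste(unique(setdiff(tooth_class, TOOTH_CLASSES)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(crown_third %in% 1:3)) {
    stop("crown_third must be in {1,2,3}", call. = FALSE)
  }
  incisor <- tooth_class %in% c("I1", "I2")
  if (any(incisor & !(jaw %in% c("UPPER", "LOWER")))) {
    stop("jaw is required (UPPER or LOWER) to stage incisors: upper and ",
         "lower incisors map to different stages", call. = FALSE)
  }
  tab <- stage_table()
  jaw_key <- ifelse(incisor, jaw, "ANY")
  key <- paste(tooth_class, jaw_key, crown_third)
  m <- match(key, paste(tab$tooth_class, tab$jaw, tab$crown_third))
  if (anyNA(m)) stop("internal staging error: unmapped combination(s) ",
                     paste(unique(key[is.na(m)]), collapse = "; "),
                     call. = FALSE)
  tab$stage[m]
}

# stages reachable by any crown third of one tooth
stage_set <- function(tooth_class, jaw) {
  sort(unique(assign_stage(rep(tooth_class, 3), rep(jaw, 3), 1:3)))
}

#' Match systemic stress episodes
#'
#' Linear (furrow-form) defects recorded on two or more teeth of a single
#' individual and assigned to the same developmental stage are considered
#' broadly contemporaneous and collapsed into one systemic stress episode
#' at that (individual, stage). Pit and LHPC defects are ignored for
#' matching. At most one episode is emitted per (individual, stage)
#' however many teeth support it.
#'
#' @param dataset A filtered [leh_dataset()].
#' @param distinct_classes_only If `TRUE`, the supporting teeth must span
#'   at least two distinct tooth classes (stricter variant excluding e.g.
#'   antimere pairs); default counts any two distinct specimens.
#' @return A data frame with columns `individual_id`, `taxon`, `stage`,
#'   `n_supporting` and list column `supporting_specimens`, ordered by
#'   individual then stage.
#' @export
match_episodes <- function(dataset, distinct_classes_only = FALSE) {
  stopifnot(inherits(dataset, "leh_dataset"))
  sp <- dataset$specimens
  def <- dataset$defects
  fur <- def[def$form == "FURROW", , drop = FALSE]
  if (nrow(fur) == 0L) return(empty_episodes())
  i <- match(fur$specimen_id, sp$specimen_id)
  unstageable <- sp$tooth_class[i] %in% c("I1", "I2") &
    !(sp$jaw[i] %in% c("UPPER", "LOWER"))
  if (any(unstageable)) {
    stop("furrow defect(s) on incisor(s) with unknown jaw cannot be ",
         "staged: ", paste(unique(fur$specimen_id[unstageable]),
                           collapse = ", "), call. = FALSE)
  }
  stage <- assign_stage(sp$tooth_class[i], sp$jaw[i], fur$crown_third)
  d <- data.frame(individual_id = sp$individual_id[i],
                  taxon = sp$taxon[i],
                  tooth_class = sp$tooth_class[i],
                  specimen_id = fur$specimen_id,
                  stage = stage, stringsAsFactors = FALSE)
  key <- paste(d$individual_id, d$stage, sep = "\r")
  groups <- split(d, key)
  rows <- lapply(groups, function(g) {
    supp <- sort(unique(g$specimen_id))
    enough <- if (distinct_classes_only) {
      length(unique(g$tooth_class)) >= 2L
    } else {
      length(supp) >= 2L
    }
    if (!enough || length(supp) < 2L) return(NULL)
    data.frame(individual_id = g$individual_id[1], taxon = g$taxon[1],
               stage = g$stage[1], n_supporting = length(supp),
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(empty_episodes())
  out <- do.call(rbind, rows[keep])
  out$supporting_specimens <- lapply(groups[keep], function(g)
    sort(unique(g$specimen_id)))
  out <- out[order(out$individual_id, out$stage), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_episodes <- function() {
  out <- data.frame(individual_id = character(), taxon = character(),
                    stage = integer(), n_supporting = integer(),
                    stringsAsFactors = FALSE)
  out$supporting_specimens <- list()
  out
}

#' Per-individual stage risk sets
#'
#' A stage is observable for an individual when at least two of their
#' included tooth crowns were forming concurrently at that stage, i.e.
#' at least two specimens have some crown third mapping to the stage.
#' An individual is eligible for the systemic-stress model when they
#' preserve at least two concurrently forming crowns (some stage is
#' observable). Stage 9 (the formation hiatus) is never observable.
#'
#' @param dataset A filtered [leh_dataset()].
#' @return A data frame with one row per individual: `individual_id`,
#'   `taxon`, `site_id`, list column `observable_stages`, and `eligible`.
#' @export
risk_sets <- function(dataset) {
  stopifnot(inherits(dataset, "leh_dataset"))
  sp <- dataset$specimens
  inds <- unique(sp[, c("individual_id", "taxon", "site_id")])
  inds <- inds[order(inds$individual_id), , drop = FALSE]
  obs <- lapply(inds$individual_id, function(id)
    stage_risk_set(sp[sp$individual_id == id, , drop = FALSE]))
  inds$observable_stages <- obs
  inds$eligible <- vapply(obs, function(s) length(s) > 0L, logical(1))
  rownames(inds) <- NULL
  inds
}

#' @describeIn risk_sets Observable stages for one individual's specimen
#'   table; returns a (possibly empty) sorted integer vector of stages.
#' @param specimens Specimen rows all belonging to one individual.
#' @export
stage_risk_set <- function(specimens) {
  if (nrow(specimens) < 2L) return(integer())
  if (length(unique(specimens$individual_id)) > 1L) {
    stop("specimens must all belong to one individual", call. = FALSE)
  }
  sets <- lapply(seq_len(nrow(specimens)), function(i) {
    cls <- specimens$tooth_class[i]
    jaw <- specimens$jaw[i]
    if (cls %in% c("I1", "I2") && !(jaw %in% c("UPPER", "LOWER"))) {
      # unstageable incisor cannot support stage observability
      return(integer())
    }
    stage_set(cls, jaw)
  })
  all_stages <- sort(unique(unlist(sets)))
  counts <- vapply(all_stages, function(s)
    sum(vapply(sets, function(ss) s %in% ss, logical(1))), integer(1))
  all_stages[counts >= 2L]
}

#' Printed per-stage matched-episode counts
#'
#' The per-stage counts of matched systemic stress episodes in the study
#' sample (49 episodes in 35 Neanderthal individuals; 31 episodes in 37
#' Upper Paleolithic modern human individuals), transcribed from the
#' published stage table. Used as a fixture for cross-checking totals;
#' never used in model fitting.
#'
#' @return A data frame with columns `stage`, `nea`, `upmh`.
#' @export
table1_episode_counts <- function() {
  data.frame(
    stage = 1:11,
    nea  = c(1L, 0L, 5L, 7L, 9L, 15L, 9L, 0L, 0L, 0L, 3L),
    upmh = c(0L, 1L, 12L, 9L, 1L, 5L, 1L, 2L, 0L, 0L, 0L)
  )
}

#' Reference biological age annotations per stage
#'
#' Chronological age-range annotations for the 11 developmental stages:
#' equivalent ages in the modern Northern European reference sample and,
#' where published, for Neanderthals. Carried verbatim as inert metadata
#' for report annotation; never used in any computation (stages, not
#' ages, are the modelling scale).
#'
#' @return A data frame with columns `stage`, `description`,
#'   `modern_age_range`, `neanderthal_age_range`.
#' @export
stage_reference_ages <- function() {
  data.frame(
    stage = 1:11,
    description = c(
      "Deciduous dentition",
      "1/3: I1 upper/lower, I2 lower, M1",
      "2/3: I1, I2 lower, M1; 1/3: I2 upper, C",
      "3/3: I1 lower, I2 lower, M1; 2/3: I2 upper, C; 1/3: P3",
      "3/3: I1 upper, I2 upper; 2/3: P3; 1/3: P4",
      "3/3: C, P3; 2/3: P4; 1/3: M2",
      "3/3: P4; 2/3: M2",
      "3/3: M2",
      "Crown developmental hiatus",
      "1/3: M3",
      "2/3-3/3: M3"
    ),
    modern_age_range = c(NA, "1-1.8 years", "1.5-2.9 years",
                         "2.1-3.7 years", "2.9-4.6 years", "3.4-5.6 years",
                         "4.4-5.5 years", "5.1-5.9 years", NA,
                         "9.4-9.7 years", "9.6-10.9 years"),
    neanderthal_age_range = c(NA, "0.65-1.53 years", "0.81-2.67 years",
                              "1.47-2.75 years", "2.67-3.88 years",
                              "2.37-3.87 years", NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Write matched episodes to CSV
#'
#' @param episodes Result of [match_episodes()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  out <- episodes[, c("individual_id", "taxon", "stage", "n_supporting")]
  names(out)[4] <- "n_supporting_teeth"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
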