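# Domain types and delimited-file I/O for tooth specimens and defect
# observations, plus the preservation-based inclusion filter.

SPECIMEN_COLS <- c("specimen_id", "individual_id", "site_id", "taxon",
                   "tooth_class", "jaw", "crown_fraction_preserved",
                   "surface_ok")
DEFECT_COLS <- c("specimen_id", "form", "crown_third", "surface")

parse_enum <- function(x, levels, field, default_unknown = FALSE) {
  up <- toupper(trimws(as.character(x)))
  bad <- !(up %in% levels)
  if (any(bad)) {
    if (default_unknown && "UNKNOWN" %in% levels) {
      up[bad] <- "UNKNOWN"
    } else {
      rows <- which(bad)
      stop(sprintf("unparseable %s value(s) %s at row(s) %s",
                   field,
                   paste(unique(x[bad]), collapse = ", "),
                   paste(rows, collapse = ", ")), call. = FALSE)
    }
  }
  up
}

parse_logical <- function(x, field) {
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(up))
  out[up %in% c("TRUE", "T", "1", "YES", "Y")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO", "N")] <- FALSE
  if (anyNA(out)) {
    stop(sprintf("unparseable %s value(s) at row(s) %s", field,
                 paste(which(is.na(out)), collapse = ", ")), call. = FALSE)
  }
  out
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read a tooth-specimen table
#'
#' Reads a comma-separated UTF-8 table of scored tooth crowns. Mandatory
#' columns are `specimen_id`, `individual_id`, `site_id`, `taxon`
#' (`NEA`/`UPMH`), `tooth_class` (`DECIDUOUS`, `I1`, `I2`, `C`, `P3`, `P4`,
#' `M1`, `M2`, `M3`), `jaw` (`UPPER`/`LOWER`; anything else maps to
#' `UNKNOWN`), `crown_fraction_preserved` (in \[0, 1\]) and `surface_ok`
#' (logical). Enum fields are parsed case-insensitively.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data frame of specimens, one row per tooth.
#' @seealso [read_defects()], [leh_dataset()], [filter_included()]
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = TRUE)
  check_columns(raw, SPECIMEN_COLS, "specimen")
  if (nrow(raw) == 0L) return(empty_specimens())
  out <- data.frame(
    specimen_id = trimws(raw$specimen_id),
    individual_id = trimws(raw$individual_id),
    site_id = trimws(raw$site_id),
    taxon = parse_enum(raw$taxon, TAXA, "taxon"),
    tooth_class = parse_enum(raw$tooth_class, TOOTH_CLASSES, "tooth_class"),
    jaw = parse_enum(raw$jaw, JAWS, "jaw", default_unknown = TRUE),
    crown_fraction_preserved = as.numeric(raw$crown_fraction_preserved),
    surface_ok = parse_logical(raw$surface_ok, "surface_ok"),
    stringsAsFactors = FALSE
  )
  validate_specimens(out)
  out
}

#' Read a defect-observation table
#'
#' Reads a comma-separated table of hypoplastic defect observations with
#' columns `specimen_id`, `form` (`FURROW`, `PIT`, `LHPC`), `crown_third`
#' (1 = first-formed incisal/occlusal third, 3 = cervical third) and
#' `surface` (`LINGUAL`, `BUCCAL_LABIAL`, else `UNKNOWN`).
#'
#' @param path Path to a CSV file with a header row.
#' @return A data frame of defect observations.
#' @export
read_defects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = TRUE)
  check_columns(raw, DEFECT_COLS, "defect")
  if (nrow(raw) == 0L) return(empty_defects())
  third <- suppressWarnings(as.integer(trimws(raw$crown_third)))
  if (anyNA(third) || !all(third %in% 1:3)) {
    stop("crown_third outside {1,2,3} at row(s) ",
         paste(which(is.na(third) | !(third %in% 1:3)), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    specimen_id = trimws(raw$specimen_id),
    form = parse_enum(raw$form, DEFECT_FORMS, "form"),
    crown_third = third,
    surface = parse_enum(raw$surface, SURFACES, "surface",
                         default_unknown = TRUE),
    stringsAsFactors = FALSE
  )
  out
}

empty_specimens <- function() {
  data.frame(specimen_id = character(), individual_id = character(),
             site_id = character(), taxon = character(),
             tooth_class = character(), jaw = character(),
             crown_fraction_preserved = numeric(), surface_ok = logical(),
             stringsAsFactors = FALSE)
}

empty_defects <- function() {
  data.frame(specimen_id = character(), form = character(),
             crown_third = integer(), surface = character(),
             stringsAsFactors = FALSE)
}

validate_specimens <- function(specimens) {
  dup <- specimens$specimen_id[duplicated(specimens$specimen_id)]
  if (length(dup)) {
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(specimens$crown_fraction_preserved) |
    specimens$crown_fraction_preserved < 0 |
    specimens$crown_fraction_preserved > 1
  if (any(bad)) {
    stop("crown_fraction_preserved outside [0,1] for specimen(s): ",
         paste(specimens$specimen_id[bad], collapse = ", "), call. = FALSE)
  }
  # each individual belongs to exactly one taxon and one site
  by_ind <- unique(specimens[, c("individual_id", "taxon", "site_id")])
  multi <- by_ind$individual_id[duplicated(by_ind$individual_id)]
  if (length(multi)) {
    stop("individual(s) mapped to more than one taxon or site: ",
         paste(unique(multi), collapse = ", "), call. = FALSE)
  }
  invisible(specimens)
}

#' Assemble and validate a hypoplasia dataset
#'
#' Bundles a specimen table and a defect table, checking referential
#' integrity: every defect's `specimen_id` must resolve to a specimen,
#' specimen ids must be unique, each individual must map to exactly one
#' taxon and site, and `LHPC` defects may occur only on deciduous teeth.
#'
#' @param specimens Data frame as returned by [read_specimens()].
#' @param defects Data frame as returned by [read_defects()].
#' @return An object of class `leh_dataset`: a list with elements
#'   `specimens` and `defects`.
#' @export
leh_dataset <- function(specimens, defects = empty_defects()) {
  validate_specimens(specimens)
  orphans <- setdiff(defects$specimen_id, specimens$specimen_id)
  if (length(orphans)) {
    stop("defect(s) reference missing specimen(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (nrow(defects)) {
    cls <- specimens$tooth_class[match(defects$specimen_id,
                                       specimens$specimen_id)]
    bad <- defects$form == "LHPC" & cls != "DECIDUOUS"
    if (any(bad)) {
      stop("LHPC recorded on permanent specimen(s): ",
           paste(unique(defects$specimen_id[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(specimens = specimens, defects = defects),
            class = "leh_dataset")
}

#' @export
print.leh_dataset <- function(x, ...) {
  cat(sprintf("<leh_dataset> %d specimens (%d NEA, %d UPMH), %d defects\n",
              nrow(x$specimens), sum(x$specimens$taxon == "NEA"),
              sum(x$specimens$taxon == "UPMH"), nrow(x$defects)))
  invisible(x)
}

#' Apply the preservation inclusion filter
#'
#' Retains exactly the specimens with at least half of their crown height
#' preserved (`crown_fraction_preserved >= 0.5`) and enamel surfaces in
#' good condition (`surface_ok`), and drops defect observations whose
#' specimen was excluded. The per-taxon counts of dropped specimens are
#' attached as attribute `"dropped"`.
#'
#' The operation is idempotent; an empty result is legal.
#'
#' @param dataset An [leh_dataset()].
#' @return A filtered `leh_dataset`.
#' @export
filter_included <- function(dataset) {
  stopifnot(inherits(dataset, "leh_dataset"))
  sp <- dataset$specimens
  keep <- sp$crown_fraction_preserved >= 0.5 & sp$surface_ok
  dropped <- sp[!keep, , drop = FALSE]
  kept <- sp[keep, , drop = FALSE]
  rownames(kept) <- NULL
  def <- dataset$defects
  def <- def[def$specimen_id %in% kept$specimen_id, , drop = FALSE]
  rownames(def) <- NULL
  out <- leh_dataset(kept, def)
  attr(out, "dropped") <- data.frame(
    taxon = TAXA,
    n_dropped = vapply(TAXA, function(t) sum(dropped$taxon == t), integer(1)),
    row.names = NULL
  )
  out
}

#' Write specimen / defect tables
#'
#' Writers mirroring [read_specimens()] and [read_defects()]; output is
#' plain comma-separated UTF-8 with a header row, in column order
#' `specimen_id, individual_id, site_id, taxon, tooth_class, jaw,
#' crown_fraction_preserved, surface_ok` (specimens) and
#' `specimen_id, form, crown_third, surface` (defects). Writing then
#' re-reading reproduces the table exactly.
#'
#' @param specimens,defects Tables to write.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_specimens <- function(specimens, path) {
  write.csv(specimens[, SPECIMEN_COLS], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_specimens
#' @export
write_defects <- function(defects, path) {
  write.csv(defects[, DEFECT_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
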