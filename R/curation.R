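# Activity curation: harmonize heterogeneous binding data to Ki in nM,
# resolve multiple measurements per compound, and assign activity labels.

#' Convert an activity measurement to Ki in nM
#'
#' All supported measures are funnelled onto a common Ki scale: `Ki` passes
#' through, `IC50` is taken as twice Ki (so Ki = IC50 / 2), and the
#' logarithmic measures `pKi`/`pIC50` are interpreted on the log10 molar
#' scale, giving Ki\[nM\] = 10^(9 - pKi). A `pIC50` is first mapped to an
#' IC50 and then halved.
#'
#' @param measure character vector with entries in `Ki`, `IC50`, `pKi`,
#'   `pIC50`.
#' @param value numeric vector of measurements; nM for `Ki`/`IC50`,
#'   dimensionless (log10 molar) for `pKi`/`pIC50`. Must be positive.
#' @param units optional character vector for `Ki`/`IC50` values; one of
#'   `nM`, `uM`, `µM`, `M`. Values are normalized to nM before conversion.
#'   Ignored for the logarithmic measures.
#' @param id optional identifiers used in error messages.
#' @return numeric vector of Ki values in nM.
#' @examples
#' to_ki("IC50", 150) # 75
#' to_ki("pKi", 9)    # 1
#' @export
to_ki <- function(measure, value, units = NULL, id = NULL) {
  measure <- as.character(measure)
  bad <- !measure %in% c("Ki", "IC50", "pKi", "pIC50")
  if (any(bad)) {
    stopf("unknown measure type: %s", paste(unique(measure[bad]), collapse = ", "))
  }
  if (any(!is.finite(value) | value <= 0)) {
    i <- which(!is.finite(value) | value <= 0)[1L]
    stopf("non-positive activity value%s (measure %s, value %s)",
          if (!is.null(id)) paste0(" for record ", id[i]) else "",
          measure[i], format(value[i]))
  }
  if (!is.null(units)) {
    value <- normalize_units(value, units, measure)
  }
  out <- numeric(length(measure))
  out[measure == "Ki"] <- value[measure == "Ki"]
  out[measure == "IC50"] <- value[measure == "IC50"] / 2
  out[measure == "pKi"] <- 10^(9 - value[measure == "pKi"])
  out[measure == "pIC50"] <- 10^(9 - value[measure == "pIC50"]) / 2
  out
}

#' Normalize concentration units to nM
#'
#' Applies only to the concentration measures (`Ki`, `IC50`); logarithmic
#' measures are dimensionless and pass through unchanged.
#'
#' @param value numeric vector.
#' @param units character vector in `nM`, `uM`, `µM`, `M` (case sensitive
#'   for the micro sign, case insensitive otherwise).
#' @param measure optional measure vector; log measures are left untouched.
#' @return numeric vector in nM.
#' @export
normalize_units <- function(value, units, measure = NULL) {
  factors <- c(nm = 1, um = 1e3, m = 1e9)
  key <- tolower(gsub("µ", "u", as.character(units)))
  key[is.na(key) | key == ""] <- "nm"
  unknown <- !key %in% names(factors)
  if (any(unknown)) {
    stopf("unknown units: %s", paste(unique(units[unknown]), collapse = ", "))
  }
  f <- factors[key]
  if (!is.null(measure)) {
    f[measure %in% c("pKi", "pIC50")] <- 1
  }
  unname(value * f)
}

# Preference rank of a (species, measure) stratum; lower is preferred.
# Species outranks measure within the stated preferences: human Ki, then
# any human data, then rat Ki, then other rat data, then everything else.
stratum_rank <- function(species, measure) {
  species <- tolower(as.character(species))
  is_ki <- measure == "Ki"
  rank <- rep.int(5L, length(species))
  rank[species == "human" & is_ki] <- 1L
  rank[species == "human" & !is_ki] <- 2L
  rank[species == "rat" & is_ki] <- 3L
  rank[species == "rat" & !is_ki] <- 4L
  rank
}

#' Aggregate multiple activity records for one compound
#'
#' When a compound carries several measurements, only the most preferred
#' (species, measure) stratum present is kept -- human Ki data outrank all
#' other human data, which outrank rat Ki, then other rat data, then
#' records from other species. The surviving records are converted to Ki in
#' nM and their median is returned (for an even count, the mean of the two
#' central values).
#'
#' @param records data frame with columns `measure`, `value`, `species` and
#'   optionally `units` and `compound_id`; all rows must describe the same
#'   compound.
#' @return single Ki value in nM.
#' @examples
#' aggregate_activity(data.frame(
#'   measure = c("Ki", "Ki"), value = c(10, 1000),
#'   species = c("human", "rat")
#' )) # 10: human data take precedence
#' @export
aggregate_activity <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stopf("no activity records to aggregate")
  }
  rank <- stratum_rank(records$species, records$measure)
  keep <- records[rank == min(rank), , drop = FALSE]
  ki <- to_ki(keep$measure, keep$value, units = keep$units,
              id = keep$compound_id)
  stats::median(ki)
}

#' Label a compound from its harmonized Ki
#'
#' Actives have Ki at or below 100 nM; inactives have Ki strictly above
#' 1000 nM; everything in between is ambiguous and excluded from both model
#' building and test sets.
#'
#' @param ki_nM positive numeric vector of Ki values in nM.
#' @return character vector in `active`, `ambiguous`, `inactive`.
#' @export
label_compound <- function(ki_nM) {
  if (any(!is.finite(ki_nM) | ki_nM <= 0)) {
    stopf("Ki must be positive and finite")
  }
  ifelse(ki_nM <= 100, "active", ifelse(ki_nM > 1000, "inactive", "ambiguous"))
}

#' Curate a raw activity table
#'
#' Groups records by compound, aggregates each compound's measurements to a
#' single Ki (see [aggregate_activity()]), labels compounds by the 100 /
#' 1000 nM thresholds, and reports ambiguous compounds separately rather
#' than dropping them silently.
#'
#' @param activities data frame with columns `compound_id`, `measure`,
#'   `value`, and optionally `smiles`, `units`, `species`, `preparation`.
#' @return list with `compounds` (data frame: `compound_id`, `smiles`,
#'   `ki_nM`, `label`) and `report` (counts per label plus the ambiguous
#'   compound ids).
#' @export
curate_activities <- function(activities) {
  required <- c("compound_id", "measure", "value")
  missing <- setdiff(required, names(activities))
  if (length(missing)) {
    stopf("activity table lacks columns: %s", paste(missing, collapse = ", "))
  }
  if (is.null(activities$species)) activities$species <- "human"
  if (is.null(activities$units)) activities$units <- "nM"
  ids <- unique(as.character(activities$compound_id))
  smiles <- vapply(ids, function(id) {
    s <- activities$smiles[activities$compound_id == id]
    if (is.null(s) || !length(s) || all(is.na(s) | s == "")) NA_character_
    else as.character(s[!is.na(s) & s != ""][1L])
  }, character(1L))
  ki <- vapply(ids, function(id) {
    aggregate_activity(activities[activities$compound_id == id, , drop = FALSE])
  }, numeric(1L))
  label <- label_compound(ki)
  compounds <- data.frame(
    compound_id = ids, smiles = unname(smiles), ki_nM = unname(ki),
    label = unname(label), stringsAsFactors = FALSE
  )
  report <- list(
    n_compounds = length(ids),
    n_active = sum(label == "active"),
    n_inactive = sum(label == "inactive"),
    n_ambiguous = sum(label == "ambiguous"),
    ambiguous_ids = ids[label == "ambiguous"]
  )
  list(compounds = compounds, report = report)
}

#' Write curation results to disk
#'
#' @param curated result of [curate_activities()].
#' @param dir output directory (created if absent). Writes
#'   `compounds.csv` and `curation_report.json`.
#' @return the directory, invisibly.
#' @export
write_curation <- function(curated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(curated$compounds, file.path(dir, "compounds.csv"),
                   row.names = FALSE)
  jsonlite::write_json(curated$report, file.path(dir, "curation_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
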