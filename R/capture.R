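# Capture records and seasonal cohorts. A cohort is one spring or fall
# mark-recapture sample; seasons are ordered spring < fall within a year, so
# cohorts carry a total chronological order.

SEASONS <- c("spring", "fall")

#' Cohort label from year and season
#' @param year integer year
#' @param season "spring" or "fall"
#' @return label such as "S2010" or "F2012"
#' @export
cohort_label <- function(year, season) {
  paste0(ifelse(season == "spring", "S", "F"), year)
}

#' Numeric chronological index of a cohort label (spring < fall within a year)
#' @param label cohort label, e.g. "F2011"
#' @return numeric sortable index
#' @export
cohort_index <- function(label) {
  yr <- as.integer(substring(label, 2))
  yr * 2 + ifelse(substring(label, 1, 1) == "F", 1, 0)
}

#' Classify a male size morph from snout-vent length
#'
#' Green anole males split into two size morphs at 64 mm SVL: smaller males
#' ("lightweights") lack the enlarged heads and bite forces of territorial
#' "heavyweights".
#'
#' @param svl snout-vent length in mm (vectorised)
#' @return character vector, "lightweight" or "heavyweight"
#' @export
classify_morph <- function(svl) {
  if (any(!is.finite(svl)) || any(svl <= 0)) stop("svl must be positive")
  ifelse(svl >= 64, "heavyweight", "lightweight")
}

#' Read and validate a capture-record table
#'
#' CSV with mandatory header `id, year, season, sex, svl_mm, mass_g, bush_id`.
#' Each row is one observation of a marked individual in one seasonal cohort.
#'
#' @param path CSV file
#' @param habitat `habitat_map` used to validate bush ids
#' @param svl_window plausibility window for SVL in mm
#' @return data.frame of validated capture records with an added `cohort`
#'   label column, ordered by cohort then id
#' @export
read_capture_table <- function(path, habitat, svl_window = c(20, 80)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_captures(df, habitat, svl_window = svl_window)
}

#' Validate an in-memory capture table
#' @inheritParams read_capture_table
#' @param df data.frame with the capture-table columns
#' @return validated data.frame with `cohort` column
#' @export
validate_captures <- function(df, habitat, svl_window = c(20, 80)) {
  need <- c("id", "year", "season", "sex", "svl_mm", "bush_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("capture table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"mass_g" %in% names(df)) df$mass_g <- NA_real_
  if (nrow(df) == 0) {
    df$cohort <- character(0)
    return(df)
  }
  df$season <- tolower(as.character(df$season))
  bad <- which(!df$season %in% SEASONS)
  if (length(bad)) stop(sprintf("row %d: unparseable season '%s'",
                                bad[1], df$season[bad[1]]))
  df$sex <- toupper(substr(as.character(df$sex), 1, 1))
  bad <- which(!df$sex %in% c("M", "F"))
  if (length(bad)) stop(sprintf("row %d: sex must be M or F", bad[1]))
  bad <- which(!df$bush_id %in% habitat$bush_ids)
  if (length(bad)) stop(sprintf("row %d: unknown bush_id %s",
                                bad[1], df$bush_id[bad[1]]))
  bad <- which(!is.finite(df$svl_mm) | df$svl_mm < svl_window[1] |
                 df$svl_mm > svl_window[2])
  if (length(bad)) stop(sprintf("row %d: svl_mm %.2f outside window [%g, %g]",
                                bad[1], df$svl_mm[bad[1]],
                                svl_window[1], svl_window[2]))
  df$cohort <- cohort_label(df$year, df$season)
  dup <- duplicated(df[, c("id", "cohort")])
  if (any(dup)) stop(sprintf("duplicate record for individual %s in cohort %s",
                             df$id[which(dup)[1]], df$cohort[which(dup)[1]]))
  sex_n <- tapply(df$sex, df$id, function(s) length(unique(s)))
  if (any(sex_n > 1))
    stop("individual(s) with inconsistent sex across records: ",
         paste(names(sex_n)[sex_n > 1], collapse = ", "))
  df <- df[order(cohort_index(df$cohort), df$id), ]
  rownames(df) <- NULL
  df
}

#' Write a capture table to CSV
#' @param captures validated capture data.frame
#' @param path output file
#' @export
write_capture_table <- function(captures, path) {
  cols <- c("id", "year", "season", "sex", "svl_mm", "mass_g", "bush_id")
  utils::write.csv(captures[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort membership derived from capture records
#' @param captures validated capture table
#' @return named list: cohort label -> character vector of individual ids,
#'   in chronological order
#' @export
cohort_members <- function(captures) {
  labs <- unique(captures$cohort)
  labs <- labs[order(cohort_index(labs))]
  stats::setNames(lapply(labs, function(l) sort(unique(captures$id[captures$cohort == l]))),
                  labs)
}

#' Per-individual summary from capture records
#'
#' Aggregates records into one row per individual: sex, first/last cohort,
#' number of capture cohorts, maximum SVL.
#' @param captures validated capture table
#' @return data.frame keyed by `id`
#' @export
individuals <- function(captures) {
  ids <- sort(unique(captures$id))
  out <- do.call(rbind, lapply(ids, function(i) {
    r <- captures[captures$id == i, ]
    ord <- order(cohort_index(r$cohort))
    data.frame(id = i, sex = r$sex[1],
               first_cohort = r$cohort[ord[1]],
               last_cohort = r$cohort[ord[length(ord)]],
               n_cohorts = nrow(r),
               max_svl = max(r$svl_mm),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Morph of an individual at a given cohort
#' @param captures validated capture table
#' @param id individual id
#' @param cohort cohort label
#' @return "lightweight"/"heavyweight", or NA if not captured in that cohort
#' @export
morph_at <- function(captures, id, cohort) {
  r <- captures[captures$id == id & captures$cohort == cohort, ]
  if (nrow(r) == 0) return(NA_character_)
  classify_morph(r$svl_mm[1])
}
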