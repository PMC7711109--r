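#' Controlled vocabularies for demographic dual reporting
#'
#' Standardized reporting categories per demographic axis. Records carry both
#' a free-text self-identified description and one of these categories, so
#' summaries can honor lived identities while still producing standard
#' reporting tables. `"No response"` is an explicit value wherever a
#' participant may decline.
#'
#' @return Named list of character vectors, one per axis.
#' @export
demographics_vocabulary <- function() {
  list(
    gender_std = c("Female", "Male",
                   "Another identity", "No response"),
    pronouns = c("He/Him/His", "She/Her/Hers", "They/Them/Theirs",
                 "Other: He/Him/They", "No response"),
    race_std = c("Black or African American",
                 "American Indian or Alaska Native", "Asian",
                 "Native Hawaiian or Pacific Islander", "White",
                 "Multi-racial", "No response"),
    ethnicity_std = c("Hispanic or Latino", "Not Hispanic or Latino",
                      "No response"),
    sexual_orientation_std = c("Lesbian/Gay/Homosexual", "Bisexual/Pansexual",
                               "Straight/Heterosexual", "Asexual",
                               "Do Not Wish to Specify", "No response"),
    education = c("High school or less", "Some college", "Bachelor's degree",
                  "Some graduate work", "Master's degree", "Doctoral degree",
                  "No response"),
    employment = c("Working for pay", "Unemployed and looking for work",
                   "Student", "Retired", "Other", "No response"),
    income_bracket = c("$0-$19,999", "$20,000-$49,999", "$50,000-$99,999",
                       "Over $100,000", "No response"),
    has_insurance = c("yes", "no", "No response"),
    languages = c("English only", "English and other language(s)",
                  "No response"))
}

#' Read participant demographic records
#'
#' Reads a TSV of dual-reporting demographic records (free-text
#' `*_self` columns plus standardized `*_std` and socioeconomic columns) and
#' validates every standardized value against [demographics_vocabulary()].
#'
#' @param path TSV path; defaults to the packaged 15-meditator cohort file.
#'   In that file the per-axis category counts reflect the study sample the
#'   package's examples summarize, but the row-level pairing of categories
#'   across axes is synthetic (the joint table was never published).
#' @return data.frame of participant records.
#' @export
read_participant_records <- function(path = cohort_demographics_path()) {
  rec <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  vocab <- demographics_vocabulary()
  for (axis in names(vocab)) {
    if (!axis %in% names(rec))
      stop("records lack column ", dQuote(axis), call. = FALSE)
    bad <- setdiff(unique(rec[[axis]]), vocab[[axis]])
    if (length(bad) > 0L)
      stop(sprintf("column %s has value(s) outside the vocabulary: %s",
                   dQuote(axis), paste(dQuote(bad), collapse = ", ")),
           call. = FALSE)
  }
  rec
}

#' Path to the packaged cohort demographics file
#' @return File path.
#' @export
cohort_demographics_path <- function() {
  system.file("extdata", "demographics_synthetic_cohort.tsv",
              package = "mindstates", mustWork = TRUE)
}

#' Summarize demographics with dual-reporting percentages
#'
#' Per axis, counts each standardized category and reports its percentage of
#' the full sample, rounded to one decimal. Percentages always use the full
#' n as denominator, with non-responses counted as their own category, so
#' each axis sums to 100 up to rounding. Also derives composite rates:
#' racial minorities (any standardized race other than White alone), sexual
#' minorities (Lesbian/Gay/Homosexual + Bisexual/Pansexual + Asexual),
#' multi-racial participants, and Bachelor's-degree-or-higher education.
#'
#' @param records data.frame from [read_participant_records()].
#' @return Object of class `demographics_summary`: `n`, `axes` (named list
#'   of data.frames with `category`, `n`, `percent`), `composites` (named
#'   list with `*_n` counts and `*_pct` one-decimal percentages).
#' @export
summarize_demographics <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame", call. = FALSE)
  vocab <- demographics_vocabulary()
  n <- nrow(records)
  pct <- function(k) round(100 * k / n, 1)
  axes <- lapply(names(vocab), function(axis) {
    tab <- table(factor(records[[axis]], levels = vocab[[axis]]))
    keep <- tab > 0
    data.frame(category = names(tab)[keep], n = as.integer(tab[keep]),
               percent = pct(as.integer(tab[keep])))
  })
  names(axes) <- names(vocab)
  sexual_minority <- sum(records$sexual_orientation_std %in%
                           c("Lesbian/Gay/Homosexual", "Bisexual/Pansexual",
                             "Asexual"))
  racial_minority <- sum(!records$race_std %in% c("White"))
  multiracial <- sum(records$race_std == "Multi-racial")
  bachelors_up <- sum(records$education %in%
                        c("Bachelor's degree", "Some graduate work",
                          "Master's degree", "Doctoral degree"))
  structure(list(
    n = n, axes = axes,
    composites = list(
      sexual_minority_n = sexual_minority,
      sexual_minority_pct = pct(sexual_minority),
      racial_minority_n = racial_minority,
      racial_minority_pct = pct(racial_minority),
      multiracial_n = multiracial,
      multiracial_pct = pct(multiracial),
      bachelors_or_higher_n = bachelors_up,
      bachelors_or_higher_pct = pct(bachelors_up))),
    class = "demographics_summary")
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat(sprintf("<demographics_summary> n = %d\n", x$n))
  comp <- x$composites
  cat(sprintf(
    "  racial minority %.1f%% (%d), multi-racial %.1f%% (%d),\n  sexual minority %.1f%% (%d), Bachelor's+ %.1f%% (%d)\n",
    comp$racial_minority_pct, comp$racial_minority_n,
    comp$multiracial_pct, comp$multiracial_n,
    comp$sexual_minority_pct, comp$sexual_minority_n,
    comp$bachelors_or_higher_pct, comp$bachelors_or_higher_n))
  invisible(x)
}
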