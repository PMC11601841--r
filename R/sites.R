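# Cancer-site configuration and age-standardization weights.

#' Default cancer-site configuration
#'
#' The eight cancer categories supported by the tool, each with its ICD-O-3
#' topography code list (WHO 2008 site recode) and, where applicable, the sex
#' the site is restricted to.  Used by [validate_query()] to reject or coerce
#' incompatible site/sex combinations (e.g. prostate with a female stratum).
#'
#' @return named list; each element has `label`, `codes` (character vector of
#'   ICD-O codes) and `sex` (`NA` when the site is not sex-restricted).
#' @export
#' @examples
#' names(site_config())       # eight categories
#' site_config()$prostate$sex # "male"
site_config <- function() {
  list(
    colorectal = list(label = "colorectal",
                      codes = c(sprintf("C18%d", 0:9), "C260"), sex = NA_character_),
    breast = list(label = "female breast",
                  codes = sprintf("C50%d", 0:9), sex = "female"),
    cervical = list(label = "cervical",
                    codes = sprintf("C53%d", 0:9), sex = "female"),
    liver = list(label = "liver", codes = "C220", sex = NA_character_),
    lung = list(label = "lung and bronchus",
                codes = sprintf("C34%d", 0:9), sex = NA_character_),
    melanoma = list(label = "melanoma",
                    codes = sprintf("C44%d", 0:9), sex = NA_character_),
    prostate = list(label = "prostate", codes = "C619", sex = "male"),
    nhl = list(label = "non-Hodgkin lymphoma",
               codes = c("C024", "C098", "C099", "C111", "C142", "C379", "C422",
                         sprintf("C77%d", 0:9)), sex = NA_character_)
  )
}

#' Standard population weights for direct age standardization
#'
#' @param weights non-negative weights, one per age group, summing to 1
#'   within 1e-9; names must be the age-group labels.
#' @param name label for provenance.
#' @return a `std_population` object.
#' @export
#' @examples
#' std_population(c(`0-39` = 0.25, `40-59` = 0.25, `60-74` = 0.25, `75+` = 0.25))
std_population <- function(weights, name = "custom") {
  if (any(weights < 0)) ar_stop("standardization weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) {
    ar_stop("standardization weights must sum to 1 (got ", sum(weights), ")")
  }
  if (is.null(names(weights))) ar_stop("weights must be named by age group")
  structure(list(weights = weights, name = name), class = "std_population")
}

#' Flat four-group fixture standard
#'
#' The default standard for the synthetic fixture: equal weight 0.25 on each
#' of the four fixture age groups.  Real deployments substitute the US 2000
#' standard-population weights for their own age grouping.
#'
#' @param age_groups age-group labels.
#' @return a [std_population()].
#' @export
std_flat <- function(age_groups = c("0-39", "40-59", "60-74", "75+")) {
  w <- rep(1 / length(age_groups), length(age_groups))
  std_population(stats::setNames(w, age_groups), name = "flat")
}
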