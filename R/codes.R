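#' Default concept-code lists for the synthetic claims vocabulary
#'
#' Real analyses supply payer-specific ICD/NDC code lists through a YAML
#' config. The package ships a small synthetic vocabulary that the claims
#' simulator emits and all downstream stages understand, so the whole
#' pipeline is runnable end to end without private data. Every list is
#' replaceable: the cohort builder, feature builder and outcome labeler only
#' ever see the config, never these constants.
#'
#' @return A named list of code lists:
#' \describe{
#'   \item{uti}{diagnosis codes that define a UTI episode}
#'   \item{pyelonephritis, sepsis}{failure-subtype diagnosis codes}
#'   \item{antibiotic_classes}{map of class name (`first_line`,
#'     `fluoroquinolone`, `beta_lactam`) to dispensing codes}
#'   \item{complicated_acute}{procedures/diagnoses that mark a complicated
#'     UTI when seen within the lookback window}
#'   \item{complicated_longterm}{comorbidities (e.g. neurogenic bladder,
#'     genitourinary cancer) that complicate a UTI at any prior time}
#'   \item{pregnancy}{codes excluding an episode when seen within 280 days}
#'   \item{comorbidities}{map of named chronic conditions used as expert
#'     confounder groups}
#'   \item{adverse_events}{map of adverse-event endpoint name to codes}
#'   \item{negative_controls}{map of negative-control outcome name to codes}
#'   \item{menopause}{codes for the menopause expert feature}
#' }
#' @export
#' @examples
#' codes <- default_codes()
#' names(codes$antibiotic_classes)
default_codes <- function() {
  list(
    uti = c("C-UTI"),
    pyelonephritis = c("C-PYELO"),
    sepsis = c("C-SEPSIS"),
    antibiotic_classes = list(
      first_line = c("D-NITRO", "D-TMPSMX"),
      fluoroquinolone = c("D-CIPRO", "D-LEVO", "D-OFLOX"),
      beta_lactam = c("D-AMOXCLAV", "D-CEFADROX", "D-CEFPOD")
    ),
    complicated_acute = c("C-COMP-PROC", "C-STONE"),
    complicated_longterm = c("C-NEUROBLADDER", "C-SPINABIFIDA", "C-GUCANCER"),
    pregnancy = c("C-PREGNANCY"),
    comorbidities = list(
      hypertension = "C-HTN",
      diabetes = "C-DM",
      arthritis = "C-ARTH",
      cancer = "C-CANCER",
      chronic_kidney_disease = "C-CKD",
      autoimmune = "C-AUTOIMM",
      thyroid_disorder = "C-THYROID"
    ),
    adverse_events = list(
      diarrhea = "C-DIARRHEA",
      acute_kidney_injury = "C-AKI",
      dermatologic = "C-DERM",
      c_difficile = "C-CDIFF"
    ),
    negative_controls = list(
      fibrocystic_breast = "C-FIBROCYSTIC",
      hernia = "C-HERNIA",
      fracture = "C-FRACTURE"
    ),
    menopause = c("C-MENOPAUSE")
  )
}

#' Read or write a code-list config as YAML
#'
#' @param path file path.
#' @param codes a code-list config shaped like [default_codes()].
#' @return `read_codes()` returns the code list; `write_codes()` returns
#'   `path` invisibly.
#' @export
read_codes <- function(path) {
  codes <- yaml::read_yaml(path)
  validate_codes(codes)
  codes
}

#' @rdname read_codes
#' @export
write_codes <- function(codes, path) {
  validate_codes(codes)
  yaml::write_yaml(codes, path)
  invisible(path)
}

validate_codes <- function(codes) {
  required <- c(
    "uti", "pyelonephritis", "sepsis", "antibiotic_classes",
    "complicated_acute", "complicated_longterm", "pregnancy",
    "comorbidities", "adverse_events", "negative_controls", "menopause"
  )
  missing <- setdiff(required, names(codes))
  if (length(missing)) {
    stop("code config is missing sections: ", paste(missing, collapse = ", "))
  }
  cls <- codes$antibiotic_classes
  all_abx <- unlist(cls, use.names = FALSE)
  if (anyDuplicated(all_abx)) {
    stop("antibiotic class code lists must be disjoint")
  }
  invisible(codes)
}
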