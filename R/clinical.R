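#' Clinico-pathological characteristics of the seven HNSCC donors
#'
#' Returns the packaged clinical table for the seven patients whose tumors
#' yielded the CAF cultures: TNM staging (8th revision), grade, p16 status,
#' treatment and recurrence. `p16`, `surgery_adjuvant_rt`, `adjuvant_chemo`
#' and `recurrence` are 0/1 indicators; `pT`/`pN` keep their TNM
#' subcategory letters and are therefore character columns.
#'
#' @return A data frame with 7 rows and 13 columns (`patient`, `gender`,
#'   `age_at_diagnosis`, `tumor_location`, `pT`, `pN`, `cM`, `G`, `p16`,
#'   `stage`, `surgery_adjuvant_rt`, `adjuvant_chemo`, `recurrence`).
#' @examples
#' clin <- clinical_fixture()
#' sum(clin$recurrence)  # two patients relapsed
#' @export
clinical_fixture <- function() {
  path <- system.file("extdata", "clinical_table.tsv", package = "cafsens",
                      mustWork = TRUE)
  clin <- read.delim(path, colClasses = c(pT = "character", pN = "character"))
  stopifnot(nrow(clin) == 7L)
  clin
}

#' CAF identifiers of the study cohort
#'
#' Convenience accessor for the patient/CAF ids of [clinical_fixture()],
#' in table order.
#'
#' @return Character vector of 7 ids.
#' @export
caf_ids <- function() clinical_fixture()$patient
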