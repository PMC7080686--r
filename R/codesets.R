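#' Packaged code sets and crosswalks
#'
#' The package ships a minimal HCPCS to BETOS crosswalk (~60 codes across the
#' seven top-level clinical categories), a revenue-code to BETOS map for
#' facility claims (operating/recovery-room revenue codes map to
#' `unclassified`), CPT/revenue-code test families for the utilization
#' comparison, and default quality-measure code sets. A full CMS BETOS file
#' (or any user-supplied crosswalk with the same columns) can be loaded with
#' [read_betos_crosswalk()].
#'
#' @name codesets
NULL

#' BETOS top-level categories, in reporting order
#' @export
betos_categories <- function() {
  c("evaluation_management", "procedures", "imaging", "test",
    "durable_medical_equipment", "other", "unclassified")
}

#' Care settings recognised on claims
#' @export
care_settings <- function() {
  c("professional", "outpatient_facility", "inpatient_facility")
}

#' Primary-care specialties used for attribution
#'
#' Family practice, general practice, geriatrics, internal medicine and
#' pediatrics; visits to physicians of any other specialty never count as
#' primary-care visits.
#' @export
pcp_specialties <- function() {
  c("family_practice", "general_practice", "geriatrics",
    "internal_medicine", "pediatrics")
}

ownership_levels <- function() {
  c("physician_owned", "local_hospital_owned", "multi_hospital_system_owned")
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "vertispend")
  if (!nzchar(path)) stop("packaged file not found: ", file)
  path
}

#' Read an HCPCS to BETOS crosswalk file
#'
#' @param path CSV with columns `hcpcs,betos_category`. Defaults to the
#'   packaged minimal crosswalk.
#' @return data.table with columns `hcpcs`, `betos_category`.
#' @export
read_betos_crosswalk <- function(path = extdata("betos_crosswalk.csv")) {
  cw <- data.table::fread(path, colClasses = "character")
  req <- c("hcpcs", "betos_category")
  if (!all(req %in% names(cw))) {
    stop("crosswalk must have columns: ", paste(req, collapse = ", "))
  }
  bad <- setdiff(unique(cw$betos_category), betos_categories())
  if (length(bad)) stop("unknown BETOS categories: ", paste(bad, collapse = ", "))
  cw[, req, with = FALSE]
}

#' Packaged HCPCS to BETOS crosswalk
#' @export
default_betos_crosswalk <- function() read_betos_crosswalk()

#' Packaged revenue-code to BETOS map for facility claims
#'
#' Operating-room (0360) and recovery-room (0710) revenue codes map to
#' `unclassified`; unmapped revenue codes are treated as `unclassified`
#' downstream so that spending conservation always holds.
#' @export
default_revenue_map <- function() {
  data.table::fread(extdata("revenue_betos.csv"), colClasses = "character")
}

#' Packaged CPT/revenue-code crosswalk of test families
#'
#' Five families (chemistry, xray, ct, mri, ultrasound), each with a set of
#' professional HCPCS codes and outpatient revenue codes; code sets are
#' disjoint across families.
#' @export
default_test_families <- function() {
  data.table::fread(extdata("test_families.csv"), colClasses = "character")
}

#' Quality-measure code sets
#'
#' @param path JSON file mapping measure name to a list of HCPCS codes;
#'   defaults to the packaged sets (HbA1c, LDL, retinal exam, mammography).
#' @return named list of character vectors.
#' @export
read_quality_codesets <- function(path = extdata("quality_codesets.json")) {
  sets <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(sets, as.character)
}

#' @rdname read_quality_codesets
#' @export
default_quality_codesets <- function() read_quality_codesets()
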