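#' Write a generated dataset to delimited files
#'
#' Writes `members.csv`, `claims.csv`, `roster.csv`, `betos_crosswalk.csv`
#' and `wage_index.csv` under `out_dir` with ISO-8601 dates. Files
#' round-trip losslessly through [read_dataset()].
#'
#' @param dataset list as returned by [generate_claims_dataset()] (only the
#'   five tabular elements are required).
#' @param out_dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  parts <- c("members", "roster", "claims", "crosswalk", "wage_index")
  for (p in parts) {
    if (is.null(dataset[[p]]) || nrow(dataset[[p]]) == 0L) {
      stop("refusing to write empty dataset component: ", p)
    }
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    members = file.path(out_dir, "members.csv"),
    claims = file.path(out_dir, "claims.csv"),
    roster = file.path(out_dir, "roster.csv"),
    crosswalk = file.path(out_dir, "betos_crosswalk.csv"),
    wage_index = file.path(out_dir, "wage_index.csv"))
  cl <- data.table::as.data.table(dataset$claims)
  cl <- cl[, .(claim_id, member_id, service_date, org_id, setting, hcpcs,
               revenue_code, allowed_amount, specialty, pcp_id, admit_date,
               discharge_date, dx_diabetes)]
  data.table::fwrite(dataset$members, paths["members"], dateTimeAs = "ISO")
  data.table::fwrite(cl, paths["claims"], dateTimeAs = "ISO")
  data.table::fwrite(dataset$roster, paths["roster"])
  data.table::fwrite(dataset$crosswalk, paths["crosswalk"])
  data.table::fwrite(dataset$wage_index, paths["wage_index"])
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the five CSV files.
#' @return list with `members`, `roster`, `claims`, `crosswalk`,
#'   `wage_index` data.tables; claim dates are `Date`, flags logical, and a
#'   `year` column is derived from `service_date`.
#' @export
read_dataset <- function(dir) {
  need <- c("members.csv", "claims.csv", "roster.csv",
            "betos_crosswalk.csv", "wage_index.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("dataset files missing from ", dir, ": ",
         paste(missing, collapse = ", "))
  }
  members <- data.table::fread(
    file.path(dir, "members.csv"), na.strings = "",
    colClasses = list(character = c("member_id", "sex", "msa"),
                      logical = c("cdhp_flag", "continuously_enrolled")))
  claims <- data.table::fread(
    file.path(dir, "claims.csv"), na.strings = "",
    colClasses = list(
      character = c("claim_id", "member_id", "org_id", "setting", "hcpcs",
                    "revenue_code", "specialty", "pcp_id"),
      Date = c("service_date", "admit_date", "discharge_date"),
      integer = "dx_diabetes"))
  for (dcol in c("service_date", "admit_date", "discharge_date")) {
    data.table::set(claims, j = dcol, value = as.Date(claims[[dcol]]))
  }
  claims[, year := as.integer(format(service_date, "%Y"))]
  roster <- data.table::fread(file.path(dir, "roster.csv"),
                              colClasses = "character")
  crosswalk <- data.table::fread(file.path(dir, "betos_crosswalk.csv"),
                                 colClasses = "character")
  wage_index <- data.table::fread(
    file.path(dir, "wage_index.csv"),
    colClasses = list(character = "msa", integer = "year",
                      numeric = "wage_index"))
  list(members = members, roster = roster, claims = claims,
       crosswalk = crosswalk, wage_index = wage_index)
}
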