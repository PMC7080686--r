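#' Mean patients per organization, as displayed
#'
#' Patient count divided by organization count, rounded to the nearest
#' integer — the arithmetic behind the "patients per organization, mean"
#' rows of the descriptive table.
#'
#' @param n_patients attributed patient count.
#' @param n_orgs organization count.
#' @return integer mean patients per organization.
#' @export
mean_patients_per_org <- function(n_patients, n_orgs) {
  if (any(n_orgs <= 0)) stop("organization count must be positive")
  as.integer(round(n_patients / n_orgs))
}

#' Dollar difference as a percent of baseline spending
#'
#' `100 * diff / baseline`; e.g. an adjusted dollar difference over the
#' unadjusted physician-owned mean.
#'
#' @param diff dollar difference.
#' @param baseline baseline dollars (> 0).
#' @return percent.
#' @export
percent_of_baseline <- function(diff, baseline) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  100 * diff / baseline
}

#' Descriptive table of organizations and attributed patients
#'
#' Per ownership type: organization and attributed-patient counts, mean
#' (rounded) and min-max patients per organization, mean risk score with
#' range, mean allowed spending, and mean age.
#'
#' @param attribution attribution table.
#' @param spend spending table with `total`.
#' @param members member-year table.
#' @param roster organization roster.
#' @param year single year to describe (default: all years pooled).
#' @return data.table, one row per ownership type.
#' @export
descriptive_table <- function(attribution, spend, members, roster,
                              year = NULL) {
  att <- data.table::as.data.table(attribution)[!is.na(org_id)]
  if (!is.null(year)) {
    yr <- year
    att <- att[year == yr]
  }
  d <- merge(att, data.table::as.data.table(spend)[, .(member_id, year, total)],
             by = c("member_id", "year"))
  d <- merge(d, data.table::as.data.table(members)[, .(member_id, year, age,
                                                       risk_score)],
             by = c("member_id", "year"))
  ros <- unique(data.table::as.data.table(roster)[, .(org_id, ownership)])
  org_counts <- ros[, .(n_orgs = .N), by = ownership]
  per_org <- d[, .(n = .N), by = .(ownership, org_id)]
  out <- d[, .(
    n_patients = .N,
    mean_risk = mean(risk_score), min_risk = min(risk_score),
    max_risk = max(risk_score),
    mean_spend = mean(total), mean_age = mean(age)), by = ownership]
  out <- merge(org_counts, out, by = "ownership")
  rng <- per_org[, .(min_patients_per_org = min(n),
                     max_patients_per_org = max(n)), by = ownership]
  out <- merge(out, rng, by = "ownership")
  out[, patients_per_org_mean := mean_patients_per_org(n_patients, n_orgs)]
  out[, ownership := factor(ownership, levels = ownership_levels())]
  data.table::setorder(out, ownership)
  out[, ownership := as.character(ownership)]
  data.table::setcolorder(out, c("ownership", "n_orgs", "n_patients",
                                 "patients_per_org_mean",
                                 "min_patients_per_org",
                                 "max_patients_per_org"))
  out[]
}

#' Run manifest for a pipeline output directory
#'
#' Records the configuration hash (MD5 of its canonical JSON), master seed,
#' package version, per-file MD5 digests and a timestamp. Any change to an
#' input changes the hash.
#'
#' @param config the `sim_config` used.
#' @param files character vector of output file paths.
#' @return manifest as a list (also JSON-serializable).
#' @export
run_manifest <- function(config, files) {
  cfg_json <- jsonlite::toJSON(unclass(validate_sim_config(config)),
                               auto_unbox = TRUE, digits = NA,
                               dataframe = "columns")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  digests <- tools::md5sum(files[file.exists(files)])
  list(config_hash = cfg_hash, seed = config$seed,
       package_version = as.character(utils::packageVersion("vertispend")),
       file_digests = as.list(digests),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
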