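#' Default BETOS category mix for the claims generator
#'
#' One row per BETOS category: `lambda` is the expected number of claims per
#' member-year at risk score 1, `meanlog`/`sdlog` parameterize the lognormal
#' per-claim allowed amount, and `out_share` is the baseline probability that
#' a claim in the category is billed as an outpatient facility claim.
#' Values are chosen so that mean annual spending per member and its category
#' composition are on the scale of commercially insured adults (roughly
#' $4,500/year, dominated by evaluation & management and procedures, with a
#' large zero mass in DME and unclassified services, the latter being
#' facility-only operating/recovery-room claims).
#'
#' @return data.table with columns `betos_category`, `lambda`, `meanlog`,
#'   `sdlog`, `out_share`.
#' @export
default_betos_mix <- function() {
  data.table::data.table(
    betos_category = betos_categories(),
    lambda   = c(5.5, 1.2, 1.5, 4.5, 0.35, 0.8, 0.45),
    meanlog  = c(5.17, 6.33, 5.86, 4.69, 6.48, 5.75, 6.82),
    sdlog    = c(0.50, 0.80, 0.70, 0.60, 0.80, 0.70, 0.60),
    out_share = c(0.00, 0.35, 0.20, 0.12, 0.10, 0.25, 1.00)
  )
}

#' Default quality-event probabilities
#'
#' Each rate may be a single probability (applied to all ownership types) or
#' a vector named by ownership type. Defaults are HEDIS-scale rates with no
#' ownership differences, matching a world in which integration does not
#' change care quality.
#' @export
default_quality_rates <- function() {
  list(readmit = 0.07, hba1c = 0.85, ldl = 0.80,
       retinal_exam = 0.50, mammography = 0.70)
}

#' Build a simulation scenario for the synthetic claims generator
#'
#' The default scenario is a scaled-down analogue of a large commercial PPO
#' study population: three years (2014-2016), four metropolitan areas, a
#' physician-organization roster dominated by physician-owned groups
#' (hospital-owned organizations hold ~23% of members), a ground-truth
#' ownership effect of 0.058 on log spending, and a price share of 0.155
#' (roughly 1 percentage point of a 5.8% differential operating through
#' prices, the remainder through utilization).
#'
#' @param n_members number of members (each enrolled in every scenario year).
#' @param n_phys_orgs,n_hosp_local_orgs,n_hosp_system_orgs organization
#'   counts by ownership type; hospital types may be 0 (absent).
#' @param years consecutive calendar years.
#' @param msas region labels.
#' @param ownership_log_effect log-scale multiplicative effect of hospital
#'   ownership on expected annual spending.
#' @param price_share fraction of the ownership effect operating through
#'   per-claim prices; the remainder multiplies expected claim counts.
#' @param betos_mix see [default_betos_mix()].
#' @param risk_distribution list(meanlog, sdlog) of the lognormal concurrent
#'   risk score (defaults give mean ~1.24).
#' @param cdhp_prob probability a member is in a consumer-directed plan.
#' @param quality_rates see [default_quality_rates()]; each element may be
#'   named by ownership type.
#' @param seed master seed; per-stage substreams are derived from it.
#' @param msa_year_sd SD of the MSA-by-year log price level shifts.
#' @param org_sd SD of the organization-level log price intercepts (induces
#'   within-organization correlation, i.e. the clustering the estimators
#'   must be robust to).
#' @param hosp_outpatient_shift extra probability that a hospital-attributed
#'   member's facility-eligible claim is billed in the outpatient setting.
#' @param admit_rate expected inpatient admissions per member-year at risk 1.
#' @param diabetes_prev probability a member is diabetic (constant over years).
#' @param age_out_prob fraction of members with age outside 19-64 (exercises
#'   the cohort filter).
#' @param non_enroll_prob probability a member-year is not continuously
#'   enrolled.
#' @param confound_risk optional log-risk shift for hospital-attributed
#'   members (default 0: risk independent of ownership).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_members = 5000,
                       n_phys_orgs = 40,
                       n_hosp_local_orgs = 8,
                       n_hosp_system_orgs = 4,
                       years = 2014:2016,
                       msas = c("Austin", "Dallas", "Houston", "San Antonio"),
                       ownership_log_effect = 0.058,
                       price_share = 0.155,
                       betos_mix = default_betos_mix(),
                       risk_distribution = list(meanlog = 0.1, sdlog = 0.45),
                       cdhp_prob = 0.30,
                       quality_rates = default_quality_rates(),
                       seed = 20140101L,
                       msa_year_sd = 0.05,
                       org_sd = 0.08,
                       hosp_outpatient_shift = 0.08,
                       admit_rate = 0.06,
                       diabetes_prev = 0.08,
                       age_out_prob = 0.04,
                       non_enroll_prob = 0.03,
                       confound_risk = 0) {
  cfg <- list(
    n_members = n_members, n_phys_orgs = n_phys_orgs,
    n_hosp_local_orgs = n_hosp_local_orgs,
    n_hosp_system_orgs = n_hosp_system_orgs,
    years = as.integer(years), msas = as.character(msas),
    ownership_log_effect = ownership_log_effect, price_share = price_share,
    betos_mix = data.table::as.data.table(betos_mix),
    risk_distribution = risk_distribution, cdhp_prob = cdhp_prob,
    quality_rates = quality_rates, seed = seed,
    msa_year_sd = msa_year_sd, org_sd = org_sd,
    hosp_outpatient_shift = hosp_outpatient_shift, admit_rate = admit_rate,
    diabetes_prev = diabetes_prev, age_out_prob = age_out_prob,
    non_enroll_prob = non_enroll_prob, confound_risk = confound_risk
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation scenario
#'
#' Checks every SimConfig invariant and raises an error naming the offending
#' field.
#' @param config a `sim_config` object or plain list with the same fields.
#' @return the validated config, invisibly classed as `sim_config`.
#' @export
validate_sim_config <- function(config) {
  stopifnot(is.list(config))
  fail <- function(field, why) {
    stop("invalid sim_config field `", field, "`: ", why, call. = FALSE)
  }
  chk_count <- function(x, field, min = 0L) {
    if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
      fail(field, sprintf("must be a single integer >= %d", min))
    }
  }
  chk_prob <- function(x, field) {
    if (length(x) < 1L || anyNA(x) || any(x < 0) || any(x > 1)) {
      fail(field, "must be probability(ies) in [0, 1]")
    }
  }
  chk_count(config$n_members, "n_members", 1L)
  chk_count(config$n_phys_orgs, "n_phys_orgs", 0L)
  chk_count(config$n_hosp_local_orgs, "n_hosp_local_orgs", 0L)
  chk_count(config$n_hosp_system_orgs, "n_hosp_system_orgs", 0L)
  n_orgs <- config$n_phys_orgs + config$n_hosp_local_orgs +
    config$n_hosp_system_orgs
  if (n_orgs < 1L) fail("n_phys_orgs", "at least one organization required")
  if (!is.finite(config$ownership_log_effect)) {
    fail("ownership_log_effect", "must be finite")
  }
  chk_prob(config$price_share, "price_share")
  chk_prob(config$cdhp_prob, "cdhp_prob")
  chk_prob(config$diabetes_prev, "diabetes_prev")
  chk_prob(config$age_out_prob, "age_out_prob")
  chk_prob(config$non_enroll_prob, "non_enroll_prob")
  chk_prob(config$hosp_outpatient_shift, "hosp_outpatient_shift")
  yrs <- config$years
  if (length(yrs) < 1L || anyNA(yrs) ||
      (length(yrs) > 1L && any(diff(yrs) != 1L))) {
    fail("years", "must be one or more consecutive calendar years")
  }
  if (length(config$msas) < 1L) fail("msas", "at least one region required")
  mix <- config$betos_mix
  req <- c("betos_category", "lambda", "meanlog", "sdlog", "out_share")
  if (!all(req %in% names(mix))) {
    fail("betos_mix", paste("must have columns", paste(req, collapse = ", ")))
  }
  if (!setequal(mix$betos_category, betos_categories())) {
    fail("betos_mix", "must cover exactly the seven BETOS categories")
  }
  if (any(mix$lambda < 0)) fail("betos_mix", "lambda must be >= 0")
  chk_prob(mix$out_share, "betos_mix$out_share")
  rd <- config$risk_distribution
  if (!is.list(rd) || !all(c("meanlog", "sdlog") %in% names(rd)) ||
      rd$sdlog < 0) {
    fail("risk_distribution", "must be list(meanlog, sdlog) with sdlog >= 0")
  }
  qr <- config$quality_rates
  need <- c("readmit", "hba1c", "ldl", "retinal_exam", "mammography")
  if (!is.list(qr) || !all(need %in% names(qr))) {
    fail("quality_rates", paste("must name rates:", paste(need, collapse = ", ")))
  }
  for (m in need) chk_prob(qr[[m]], paste0("quality_rates$", m))
  sd_ <- suppressWarnings(as.numeric(config$seed))
  if (length(sd_) != 1L || is.na(sd_) || sd_ < 0 || sd_ > 2147482647 ||
      sd_ != trunc(sd_)) {
    fail("seed", "must be an integer in [0, 2^31 - 1001]")
  }
  config$seed <- as.integer(sd_)
  for (f in c("msa_year_sd", "org_sd")) {
    if (config[[f]] < 0) fail(f, "must be >= 0")
  }
  if (config$admit_rate < 0) fail("admit_rate", "must be >= 0")
  class(config) <- "sim_config"
  invisible(config)
}

#' Read / write a simulation scenario as JSON
#'
#' @param path JSON file mirroring the [sim_config()] field names; omitted
#'   fields take their defaults.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown sim_config fields in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$betos_mix)) raw$betos_mix <- data.table::as.data.table(raw$betos_mix)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(validate_sim_config(config))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

# Deterministic rate lookup: scalar rates recycle over ownership types,
# vectors must name every type present.
rate_by_ownership <- function(rate, ownership) {
  if (length(rate) == 1L && is.null(names(rate))) {
    return(rep(as.numeric(rate), length(ownership)))
  }
  missing <- setdiff(unique(ownership), names(rate))
  if (length(missing)) {
    stop("quality rate vector missing ownership types: ",
         paste(missing, collapse = ", "))
  }
  as.numeric(rate[ownership])
}
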