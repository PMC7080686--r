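# Fixture builders shared across test files. Everything is constructed in
# code; no data files.

library(data.table)

# A compact claims-row constructor with sensible defaults, so hand-written
# fixtures stay readable.
make_claims <- function(member_id, service_date, hcpcs = NA_character_,
                        revenue_code = NA_character_,
                        setting = "professional", allowed_amount = 100,
                        org_id = "P0001", pcp_id = NA_character_,
                        specialty = NA_character_,
                        admit_date = as.Date(NA),
                        discharge_date = as.Date(NA), dx_diabetes = 0L) {
  dt <- data.table(
    member_id = member_id, service_date = as.Date(service_date),
    hcpcs = hcpcs, revenue_code = revenue_code, setting = setting,
    allowed_amount = allowed_amount, org_id = org_id, pcp_id = pcp_id,
    specialty = specialty, admit_date = as.Date(admit_date),
    discharge_date = as.Date(discharge_date), dx_diabetes = dx_diabetes)
  dt[, year := as.integer(format(service_date, "%Y"))]
  dt[, claim_id := sprintf("C%05d", .I)]
  dt[]
}

make_members <- function(member_id, year = 2015L, age = 40L, sex = "F",
                         msa = "Austin", cdhp_flag = FALSE, risk_score = 1,
                         continuously_enrolled = TRUE) {
  data.table(member_id = member_id, year = as.integer(year), age = age,
             sex = sex, msa = msa, cdhp_flag = cdhp_flag,
             risk_score = risk_score,
             continuously_enrolled = continuously_enrolled)
}

make_roster <- function(org_id, ownership = "physician_owned",
                        msa = "Austin", pcp_id) {
  data.table(org_id = org_id, ownership = ownership, msa = msa,
             pcp_id = pcp_id)
}

# Small scenario used by several generator-level tests.
small_config <- function(seed = 101, ...) {
  sim_config(n_members = 200, n_phys_orgs = 10, n_hosp_local_orgs = 3,
             n_hosp_system_orgs = 2, seed = seed, ...)
}

# Single-year scenario sized for replicate loops.
replicate_config <- function(seed, n_members = 1500,
                             ownership_log_effect = 0.058, ...) {
  sim_config(n_members = n_members, years = 2014L,
             ownership_log_effect = ownership_log_effect, seed = seed, ...)
}

# Clustered two-group design for direct model tests (no claims machinery).
make_cluster_design <- function(n_clusters = 10, per_cluster = 20,
                                beta = c(8, 0.05), sd_cluster = 0.1,
                                seed = 1, response = c("lognormal", "linear",
                                                       "binary"),
                                dollar_effect = 280) {
  response <- match.arg(response)
  set.seed(seed)
  cl <- rep(seq_len(n_clusters), each = per_cluster)
  hosp <- as.numeric(cl <= n_clusters / 2)
  b <- rnorm(n_clusters, 0, sd_cluster)[cl]
  X <- cbind(`(Intercept)` = 1, ownership_hospital = hosp)
  y <- switch(response,
    lognormal = rlnorm(length(cl), beta[1] + beta[2] * hosp + b, 0.8),
    linear = 4000 + dollar_effect * hosp + 600 * b + rnorm(length(cl), 0, 800),
    binary = rbinom(length(cl), 1, plogis(-0.5 + 0 * hosp + b)))
  list(X = X, y = y, cluster = sprintf("G%02d", cl),
       effect_cols = "ownership_hospital", dropped = character(),
       notes = character(), n_obs = length(y),
       n_clusters = n_clusters, response = "y")
}
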