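#' Generate a synthetic claims dataset with known ground-truth effects
#'
#' Simulates enrollment, a physician-organization roster, and claim lines for
#' the scenario described by a [sim_config()]. Annual spending per member is
#' built bottom-up from claims: for each BETOS category, claim counts are
#' Poisson with mean `lambda * risk` and per-claim allowed amounts are
#' lognormal, so annual totals are right-skewed with a point mass at zero in
#' low-rate categories. The hospital-ownership effect enters the log mean of
#' expected spending exactly: a share `price_share` multiplies per-claim
#' prices by `exp(price_share * effect)` and the remainder multiplies
#' expected claim counts by `exp((1 - price_share) * effect)`, which makes
#' the price/utilization decomposition identifiable by construction.
#' MSA-by-year level shifts and organization-level intercepts act on prices,
#' inducing the clustered structure the estimators must handle. Quality
#' events (HbA1c, LDL, retinal exam, mammography claims; readmissions) are
#' generated as claims with real codes, so the quality module must find them
#' by the same detection path it would use on real data.
#'
#' Every member has at least one professional evaluation-and-management claim
#' from a single "home" PCP per year, so attribution can recover the true
#' organization for all attributed member-years.
#'
#' @param config a [sim_config()].
#' @return list with elements `members`, `roster`, `claims`, `crosswalk`,
#'   `wage_index`, plus `revenue_map`, `truth` (ground-truth member-year
#'   organization, risk and generated spending in cents) and the validated
#'   `config`. All tabular elements are data.tables.
#' @export
generate_claims_dataset <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  eff <- config$ownership_log_effect
  ps <- config$price_share
  years <- config$years
  msas <- config$msas
  mix <- config$betos_mix
  # Per-stage substreams via a nonlinear integer hash of (master seed,
  # stage). Affine schemes (`seed + stage`, or any linear mix) map
  # consecutive master seeds to arithmetic-progression stage seeds, and
  # replicate loops over a seed range then show measurable cross-replicate
  # correlation; the multiply/fold rounds below break that structure.
  # All arithmetic is exact in doubles (products stay below 2^53).
  stage_seed <- function(stage) {
    mulmod32 <- function(a, b) {
      a_hi <- floor(a / 65536)
      a_lo <- a %% 65536
      (((a_hi * b) %% 4294967296) * 65536 + a_lo * b) %% 4294967296
    }
    h <- (as.numeric(config$seed) + stage * 2654435761) %% 4294967296
    h <- mulmod32(h, 2246822519)
    h <- (h + floor(h / 65536)) %% 4294967296
    h <- mulmod32(h, 2654435761)
    h <- (h + floor(h / 131072)) %% 4294967296
    as.integer(h %% 2147483647)
  }

  ## --- regional price levels and wage index --------------------------------
  set.seed(stage_seed(1L))
  grid <- data.table::CJ(msa = msas, year = years)
  wage_base <- stats::setNames(runif(length(msas), 0.85, 1.15), msas)
  grid[, wage_index := round(wage_base[msa] + 0.01 * (year - years[1]) +
                               rnorm(.N, 0, 0.005), 4)]
  grid[, delta := rnorm(.N, 0, config$msa_year_sd)]
  wage_index_tab <- grid[, .(msa, year, wage_index)]

  ## --- organizations and PCPs ----------------------------------------------
  set.seed(stage_seed(2L))
  orgs <- data.table::rbindlist(list(
    data.table::data.table(
      org_id = sprintf("P%04d", seq_len(config$n_phys_orgs)),
      ownership = "physician_owned"),
    data.table::data.table(
      org_id = sprintf("L%03d", seq_len(config$n_hosp_local_orgs)),
      ownership = "local_hospital_owned"),
    data.table::data.table(
      org_id = sprintf("S%03d", seq_len(config$n_hosp_system_orgs)),
      ownership = "multi_hospital_system_owned")
  ))
  orgs[, msa := rep_len(msas, .N), by = ownership]
  orgs[, hosp := as.integer(ownership != "physician_owned")]
  orgs[, b_org := rnorm(.N, 0, config$org_sd)]
  n_pcps <- 2L + rpois(nrow(orgs), 2)
  pcps <- data.table::data.table(
    org_id = rep(orgs$org_id, n_pcps))
  pcps[, pcp_id := sprintf("D%05d", seq_len(.N))]
  pcps[, pcp_specialty := sample(pcp_specialties(), .N, replace = TRUE,
                                 prob = c(0.35, 0.10, 0.05, 0.45, 0.05))]
  roster <- pcps[orgs, on = "org_id",
                 .(org_id, ownership = i.ownership, msa = i.msa, pcp_id)]
  data.table::setorder(roster, org_id, pcp_id)

  ## --- members --------------------------------------------------------------
  set.seed(stage_seed(3L))
  n <- config$n_members
  mem <- data.table::data.table(member_id = sprintf("M%06d", seq_len(n)))
  mem[, msa := sample(msas, .N, replace = TRUE)]
  # assign each member to an organization in their MSA (any org if none there)
  org_by_msa <- split(orgs$org_id, orgs$msa)
  mem[, org_id := {
    pool <- org_by_msa[[msa[1]]]
    if (is.null(pool)) pool <- orgs$org_id
    sample(pool, .N, replace = TRUE)
  }, by = msa]
  mem[orgs, on = "org_id", `:=`(ownership = i.ownership, hosp = i.hosp,
                                b_org = i.b_org)]
  pcp_by_org <- split(pcps$pcp_id, pcps$org_id)
  mem[, home_pcp := {
    pool <- pcp_by_org[[org_id[1]]]
    pool[sample.int(length(pool), .N, replace = TRUE)]
  }, by = org_id]
  out_of_range <- rbinom(n, 1, config$age_out_prob) == 1
  mem[, age := ifelse(out_of_range,
                      sample(c(18L, 65:70), n, replace = TRUE),
                      sample(19:64, n, replace = TRUE))]
  mem[, sex := sample(c("F", "M"), .N, replace = TRUE)]
  mem[, cdhp_flag := rbinom(.N, 1, config$cdhp_prob) == 1]
  mem[, diabetic := rbinom(.N, 1, config$diabetes_prev) == 1]

  ## --- member-years ---------------------------------------------------------
  set.seed(stage_seed(4L))
  my <- mem[rep(seq_len(n), each = length(years))]
  my[, year := rep(years, n)]
  my[, continuously_enrolled := rbinom(.N, 1, 1 - config$non_enroll_prob) == 1]
  rd <- config$risk_distribution
  my[, risk := rlnorm(.N, rd$meanlog + config$confound_risk * hosp, rd$sdlog)]
  my[grid, on = c("msa", "year"), delta := i.delta]
  my[, u_mult := exp((1 - ps) * eff * hosp)]
  my[, price_mult := exp(ps * eff * hosp + delta + b_org)]
  my[, row := .I]

  members <- my[, .(member_id, year, age, sex, msa, cdhp_flag,
                    risk_score = round(risk, 4), continuously_enrolled)]

  specialist_pool <- c("cardiology", "orthopedics", "dermatology",
                       "gastroenterology", "radiology", "pathology",
                       "general_surgery")
  em_codes <- c("99211", "99212", "99213", "99214", "99215",
                "99203", "99204", "99385")
  em_w <- c(0.05, 0.15, 0.35, 0.25, 0.05, 0.05, 0.05, 0.05)
  fam_prof <- list(
    xray = c("71045", "71046", "73030", "73562"),
    ct = c("70450", "71250", "74177"),
    mri = c("70551", "72148", "73721"),
    ultrasound = c("76700", "76805", "93306"),
    otherimg = "78452",
    chemistry = c("80048", "80053", "82947", "84443", "85025"),
    othertest = c("87086", "36415"))
  fam_rev <- c(xray = "0320", ct = "0350", mri = "0610", ultrasound = "0402",
               chemistry_a = "0300", chemistry_b = "0301")
  proc_codes <- c("10060", "11042", "17110", "20610", "29881",
                  "43239", "45380", "47562", "49505", "66984")
  dme_codes <- c("E0601", "E1390", "K0001", "L1833", "A4253")
  other_codes <- c("A0428", "97110", "97140", "92014", "G0008",
                   "90471", "90686")

  rand_days <- function(yr) as.Date(sprintf("%d-01-01", yr)) +
    sample.int(365, length(yr), replace = TRUE) - 1L

  # one draw per row from the pool of its group, vectorized within groups
  sample_by_group <- function(grp, pools) {
    out <- character(length(grp))
    for (f in unique(grp)) {
      i <- which(grp == f)
      pool <- pools[[f]]
      out[i] <- pool[sample.int(length(pool), length(i), replace = TRUE)]
    }
    out
  }

  claim_blocks <- list()
  add_block <- function(dt) claim_blocks[[length(claim_blocks) + 1L]] <<- dt

  ## --- claims by BETOS category --------------------------------------------
  set.seed(stage_seed(5L))
  for (k in seq_len(nrow(mix))) {
    cat_k <- mix$betos_category[k]
    mu <- mix$lambda[k] * my$risk * my$u_mult
    if (cat_k == "evaluation_management") {
      counts <- 1L + rpois(length(mu), pmax(mu - 1, 0))
    } else {
      counts <- rpois(length(mu), mu)
    }
    if (sum(counts) == 0L) next
    idx <- rep.int(my$row, counts)
    src <- my[idx]
    nn <- nrow(src)
    price <- pmax(round(rlnorm(nn, mix$meanlog[k], mix$sdlog[k]) *
                          src$price_mult, 2), 0.01)
    cl <- data.table::data.table(
      member_id = src$member_id, year = src$year,
      service_date = rand_days(src$year),
      allowed_amount = price, dx_diabetes = 0L)
    if (cat_k == "evaluation_management") {
      cl[, `:=`(setting = "professional",
                hcpcs = sample(em_codes, nn, replace = TRUE, prob = em_w),
                revenue_code = NA_character_,
                org_id = src$org_id, pcp_id = src$home_pcp,
                dx_diabetes = as.integer(src$diabetic))]
      cl[pcps, on = "pcp_id", specialty := i.pcp_specialty]
    } else if (cat_k == "unclassified") {
      cl[, `:=`(setting = "outpatient_facility", hcpcs = NA_character_,
                revenue_code = sample(c("0360", "0710"), nn, replace = TRUE,
                                      prob = c(0.7, 0.3)),
                org_id = sample(orgs$org_id, nn, replace = TRUE),
                pcp_id = NA_character_, specialty = NA_character_)]
    } else {
      p_out <- pmin(mix$out_share[k] +
                      config$hosp_outpatient_shift * src$hosp, 1)
      outp <- runif(nn) < p_out
      if (cat_k == "imaging") {
        fam <- sample(c("xray", "ct", "mri", "ultrasound", "otherimg"), nn,
                      replace = TRUE,
                      prob = c(0.55, 0.153, 0.12, 0.127, 0.05))
        outp <- outp & fam != "otherimg"
        hc <- sample_by_group(fam, fam_prof)
        rev <- unname(fam_rev[fam])
      } else if (cat_k == "test") {
        fam <- sample(c("chemistry", "othertest"), nn, replace = TRUE,
                      prob = c(0.95, 0.05))
        outp <- outp & fam == "chemistry"
        hc <- sample_by_group(fam, fam_prof)
        rev <- sample(c("0300", "0301", "0305"), nn, replace = TRUE)
      } else {
        pool <- switch(cat_k, procedures = proc_codes,
                       durable_medical_equipment = dme_codes,
                       other = other_codes)
        hc <- pool[sample.int(length(pool), nn, replace = TRUE)]
        rev <- switch(cat_k, procedures = rep("0490", nn),
                      durable_medical_equipment = rep("0270", nn),
                      other = sample(c("0250", "0940"), nn, replace = TRUE))
      }
      cl[, `:=`(setting = ifelse(outp, "outpatient_facility", "professional"),
                hcpcs = ifelse(outp, NA_character_, hc),
                revenue_code = ifelse(outp, rev, NA_character_),
                org_id = sample(orgs$org_id, nn, replace = TRUE),
                pcp_id = NA_character_,
                specialty = ifelse(outp, NA_character_,
                                   sample(specialist_pool, nn, replace = TRUE)))]
    }
    add_block(cl)
  }

  ## --- inpatient stays and readmissions ------------------------------------
  set.seed(stage_seed(6L))
  hosp_orgs <- orgs[hosp == 1L, org_id]
  if (length(hosp_orgs) == 0L) hosp_orgs <- orgs$org_id
  n_st <- rpois(nrow(my), config$admit_rate * my$risk * my$u_mult)
  if (sum(n_st) > 0L) {
    src <- my[rep.int(my$row, n_st)]
    nn <- nrow(src)
    admit <- rand_days(src$year)
    los <- 1L + rpois(nn, 3)
    amount <- pmax(round(rlnorm(nn, log(9000) - 0.18, 0.6) *
                           src$price_mult, 2), 0.01)
    stays <- data.table::data.table(
      member_id = src$member_id, year = src$year, service_date = admit,
      admit_date = admit, discharge_date = admit + los,
      allowed_amount = amount,
      setting = "inpatient_facility", hcpcs = NA_character_,
      revenue_code = "0120",
      org_id = sample(hosp_orgs, nn, replace = TRUE),
      pcp_id = NA_character_, specialty = NA_character_, dx_diabetes = 0L)
    add_block(stays)
    p_re <- rate_by_ownership(config$quality_rates$readmit, src$ownership)
    re <- rbinom(nn, 1, p_re) == 1
    if (any(re)) {
      nr <- sum(re)
      gap <- sample.int(30L, nr, replace = TRUE)
      admit2 <- stays$discharge_date[re] + gap
      los2 <- 1L + rpois(nr, 2)
      readm <- data.table::data.table(
        member_id = src$member_id[re],
        year = as.integer(format(admit2, "%Y")),
        service_date = admit2, admit_date = admit2,
        discharge_date = admit2 + los2,
        allowed_amount = pmax(round(rlnorm(nr, log(7000) - 0.18, 0.6) *
                                      src$price_mult[re], 2), 0.01),
        setting = "inpatient_facility", hcpcs = NA_character_,
        revenue_code = "0120",
        org_id = sample(hosp_orgs, nr, replace = TRUE),
        pcp_id = NA_character_, specialty = NA_character_, dx_diabetes = 0L)
      add_block(readm)
    }
  }

  ## --- quality-measure event claims ----------------------------------------
  set.seed(stage_seed(7L))
  qr <- config$quality_rates
  quality_block <- function(src, codes, code_w, mean_price) {
    nn <- nrow(src)
    data.table::data.table(
      member_id = src$member_id, year = src$year,
      service_date = rand_days(src$year),
      allowed_amount = pmax(round(rlnorm(nn, log(mean_price) - 0.045, 0.3) *
                                    src$price_mult, 2), 0.01),
      setting = "professional",
      hcpcs = sample(codes, nn, replace = TRUE, prob = code_w),
      revenue_code = NA_character_,
      org_id = sample(orgs$org_id, nn, replace = TRUE),
      pcp_id = NA_character_,
      specialty = sample(specialist_pool, nn, replace = TRUE),
      dx_diabetes = 0L)
  }
  dia <- my[diabetic == TRUE]
  if (nrow(dia)) {
    for (m in c("hba1c", "ldl", "retinal_exam")) {
      hit <- rbinom(nrow(dia), 1, rate_by_ownership(qr[[m]], dia$ownership)) == 1
      if (!any(hit)) next
      blk <- switch(m,
        hba1c = quality_block(dia[hit], c("83036", "83037"), c(0.9, 0.1), 13),
        ldl = quality_block(dia[hit], c("83721", "80061"), c(0.6, 0.4), 15),
        retinal_exam = quality_block(dia[hit], c("92250", "S0625"),
                                     c(0.85, 0.15), 80))
      blk[, dx_diabetes := 1L]
      add_block(blk)
    }
  }
  mam <- my[sex == "F" & age >= 50 & age <= 64]
  if (nrow(mam)) {
    hit <- rbinom(nrow(mam), 1,
                  rate_by_ownership(qr$mammography, mam$ownership)) == 1
    if (any(hit)) {
      add_block(quality_block(mam[hit], c("77067", "77063"), c(0.9, 0.1), 150))
    }
  }

  ## --- assemble -------------------------------------------------------------
  claims <- data.table::rbindlist(claim_blocks, fill = TRUE)
  if (!"admit_date" %in% names(claims)) {
    claims[, `:=`(admit_date = as.Date(NA), discharge_date = as.Date(NA))]
  }
  data.table::setcolorder(claims, c(
    "member_id", "year", "service_date", "org_id", "setting", "hcpcs",
    "revenue_code", "allowed_amount", "specialty", "pcp_id",
    "admit_date", "discharge_date", "dx_diabetes"))
  data.table::setorder(claims, member_id, service_date, setting, hcpcs,
                       revenue_code, allowed_amount, na.last = TRUE)
  claims[, claim_id := sprintf("C%08d", seq_len(.N))]
  data.table::setcolorder(claims, "claim_id")

  truth <- my[, .(member_id, year, org_id, ownership, pcp_id = home_pcp,
                  risk_score = round(risk, 4), diabetic)]
  cents <- claims[, .(sim_total_cents = sum(as.numeric(round(
    100 * allowed_amount)))), by = .(member_id, year)]
  truth[cents, on = c("member_id", "year"), sim_total_cents := sim_total_cents]
  truth[is.na(sim_total_cents), sim_total_cents := 0]

  list(members = members, roster = roster, claims = claims,
       crosswalk = default_betos_crosswalk(), wage_index = wage_index_tab,
       revenue_map = default_revenue_map(), truth = truth, config = config)
}
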