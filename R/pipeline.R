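#' Attribute, aggregate and fit the headline spending models on a dataset
#'
#' Lean end-to-end path for a generated dataset: cohort filtering and
#' attribution, spending aggregation (with median-price standardization),
#' covariate assembly, and the log-link quasi-likelihood fit of total
#' spending; optionally the standardized-spending fit and the dollar-scale
#' linear fit on the identical design.
#'
#' @param dataset list from [generate_claims_dataset()] (or [read_dataset()]
#'   plus a `revenue_map`).
#' @param standardize also fit the median-price-standardized response?
#' @param dollars also fit the dollar-scale linear model?
#' @param covariates covariate blocks passed to [build_design()].
#' @return list with `attribution`, `frame`, `design` and fits `actual`,
#'   and optionally `standardized` and `dollars`.
#' @export
estimate_scenario <- function(dataset, standardize = TRUE, dollars = FALSE,
                              covariates = c("ownership", "year", "age",
                                             "sex", "risk", "cdhp", "wage",
                                             "size", "specialty",
                                             "msa_year")) {
  ds <- dataset
  rmap <- if (!is.null(ds$revenue_map)) ds$revenue_map else
    default_revenue_map()
  att <- attribution_table(ds$members, ds$claims, ds$roster, ds$crosswalk)
  sizes <- practice_size_category(att, roster = ds$roster)
  cohort <- att[!is.na(org_id), .(member_id, year)]
  sp <- annual_spend_table(ds$claims, cohort, ds$crosswalk, rmap,
                           standardize = standardize)
  fr <- build_analysis_frame(att, ds$members, ds$wage_index, sizes, sp)
  des <- build_design(fr, "total", covariates)
  out <- list(attribution = att, frame = fr, design = des,
              actual = fit_glm_log(des))
  if (standardize) {
    d2 <- des
    d2$y <- fr$total_std
    d2$response <- "total_std"
    out$standardized <- fit_glm_log(d2)
  }
  if (dollars) out$dollars <- fit_linear_dollars(des)
  out
}

#' Run the full analysis pipeline on a simulated scenario
#'
#' Executes simulate, attribute, aggregate, quality, estimate and report in
#' order, writing analogues of the study's four display tables plus stage
#' outputs and a run manifest to `out_dir`. Deterministic given the
#' configuration seed.
#'
#' @param config a [sim_config()] (or path to a JSON config file).
#' @param out_dir output directory.
#' @param seed optional master-seed override.
#' @param quality_codesets quality-measure code sets.
#' @return invisibly, a list with all stage objects, fits and tables.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         quality_codesets = default_quality_codesets()) {
  if (is.character(config)) config <- read_sim_config(config)
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config <- validate_sim_config(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ds <- stage("simulate", generate_claims_dataset(config))
  att <- stage("attribute",
               attribution_table(ds$members, ds$claims, ds$roster,
                                 ds$crosswalk))
  sizes <- stage("attribute",
                 practice_size_category(att, roster = ds$roster))
  cohort_my <- att[!is.na(org_id), .(member_id, year)]
  spend <- stage("aggregate",
                 annual_spend_table(ds$claims, cohort_my, ds$crosswalk,
                                    ds$revenue_map))
  qrec <- stage("quality", {
    coh_full <- merge(cohort_my, ds$members, by = c("member_id", "year"))
    quality_records(ds$claims, coh_full, quality_codesets)
  })

  frame <- stage("estimate",
                 build_analysis_frame(att, ds$members, ds$wage_index,
                                      sizes, spend))
  spend_cov <- c("ownership", "year", "age", "sex", "risk", "cdhp", "wage",
                 "size", "specialty", "msa_year")
  fit_safe <- function(fun, design) {
    tryCatch(fun(design), error = function(e) e)
  }
  estimates <- list()
  add_est <- function(model_label, fit) {
    if (inherits(fit, "error")) {
      estimates[[length(estimates) + 1L]] <<- data.table::data.table(
        model = model_label, estimand = NA_character_, point = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
        n_obs = NA_integer_, n_clusters = NA_integer_,
        note = conditionMessage(fit))
      return(invisible(NULL))
    }
    ee <- effect_estimate(fit)[1]
    ee[, `:=`(model = model_label, note = "")]
    ee[, term := NULL]
    estimates[[length(estimates) + 1L]] <<- ee
    invisible(fit)
  }

  des_total <- stage("estimate", build_design(frame, "total", spend_cov))
  fit_total <- stage("estimate", fit_glm_log(des_total))
  add_est("spend_total_pct", fit_total)
  des_std <- des_total
  des_std$y <- frame$total_std
  fit_std <- fit_safe(fit_glm_log, des_std)
  add_est("spend_total_std_pct", fit_std)
  fit_dollars <- fit_safe(fit_linear_dollars, des_total)
  add_est("spend_total_dollars", fit_dollars)
  des3 <- build_design(frame, "total", spend_cov,
                       ownership_coding = "three_level")
  fit3 <- fit_safe(fit_glm_log, des3)
  hosp_eq <- if (!inherits(fit3, "error") &&
                 length(fit3$effect_cols) == 2L) {
    test_hospital_equality(fit3)
  } else NULL

  decomp <- if (!inherits(fit_std, "error")) {
    price_utilization_decomposition(fit_total, fit_std)
  } else NULL

  by_rows <- list()
  for (cat in betos_categories()) {
    col <- paste0("betos_", cat)
    d <- des_total; d$y <- frame[[col]]; d$response <- col
    f <- fit_safe(fit_glm_log, d)
    add_est(paste0("spend_", col, "_pct"), f)
    fd <- fit_safe(fit_linear_dollars, d)
    add_est(paste0("spend_", col, "_dollars"), fd)
  }
  for (st in care_settings()) {
    col <- paste0("setting_", st)
    d <- des_total; d$y <- frame[[col]]; d$response <- col
    add_est(paste0("spend_", col, "_pct"), fit_safe(fit_glm_log, d))
    add_est(paste0("spend_", col, "_dollars"),
            fit_safe(fit_linear_dollars, d))
  }

  qual_cov <- c("ownership", "year", "age", "sex", "risk", "cdhp", "wage",
                "size", "specialty", "msa")
  for (m in unique(qrec$measure)) {
    qf <- merge(qrec[measure == m & eligible == TRUE],
                frame, by = c("member_id", "year"))
    if (nrow(qf) == 0L) next
    qf[, numer := as.numeric(numerator)]
    dq <- tryCatch(build_design(qf, "numer", qual_cov),
                   error = function(e) e)
    fq <- if (inherits(dq, "error")) dq else fit_safe(fit_logistic_quality, dq)
    add_est(paste0("quality_", m, "_or"), fq)
  }

  pos_betos <- stage("report", positive_spending_shares(spend, att, "betos"))
  pos_setting <- stage("report",
                       positive_spending_shares(spend, att, "setting"))
  cpm <- stage("report", claims_per_member(ds$claims, att))
  pout <- stage("report", percent_outpatient(ds$claims, att))

  est_tab <- data.table::rbindlist(estimates, use.names = TRUE, fill = TRUE)
  data.table::setcolorder(est_tab, c("model", "estimand", "point", "ci_low",
                                     "ci_high", "p_value", "n_obs",
                                     "n_clusters", "note"))

  ## ---- rendered tables -----------------------------------------------------
  mid_year <- config$years[ceiling(length(config$years) / 2)]
  table1 <- stage("report",
                  descriptive_table(att, spend, ds$members, ds$roster,
                                    year = mid_year))
  unadj <- merge(spend, att[!is.na(org_id),
                            .(member_id, year, ownership)],
                 by = c("member_id", "year"))
  unadj[, grp := data.table::fifelse(ownership == "physician_owned",
                                     "physician", "hospital")]
  mean_by <- function(col) {
    u <- unadj[, .(v = mean(get(col))), by = grp]
    c(physician = u[grp == "physician", v], hospital = u[grp == "hospital", v])
  }
  t2_rows <- c(total = "total", total_std = "total_std",
               stats::setNames(paste0("betos_", betos_categories()),
                               paste0("betos_", betos_categories())),
               stats::setNames(paste0("setting_", care_settings()),
                               paste0("setting_", care_settings())))
  table2 <- data.table::rbindlist(lapply(names(t2_rows), function(lbl) {
    col <- t2_rows[[lbl]]
    mdl_pct <- if (lbl == "total_std") "spend_total_std_pct" else
      paste0("spend_", col, "_pct")
    mdl_dol <- paste0("spend_", col, "_dollars")
    u <- mean_by(col)
    pct <- est_tab[get("model") == mdl_pct]
    dol <- est_tab[get("model") == mdl_dol]
    data.table::data.table(
      row = lbl,
      unadj_physician = round(u["physician"], 2),
      unadj_hospital = round(u["hospital"], 2),
      adj_pct = if (nrow(pct)) round(pct$point, 2) else NA_real_,
      adj_pct_p = if (nrow(pct)) pct$p_value else NA_real_,
      adj_dollars = if (nrow(dol)) round(dol$point, 2) else NA_real_,
      adj_dollars_p = if (nrow(dol)) dol$p_value else NA_real_)
  }))
  table3 <- merge(cpm[, .(test_family, claims_per_member_hospital =
                            round(rate_hospital, 2),
                          claims_per_member_physician =
                            round(rate_physician, 2),
                          p_rate = p_value)],
                  pout[, .(test_family,
                           pct_outpatient_hospital =
                             round(pct_outpatient_hospital, 1),
                           pct_outpatient_physician =
                             round(pct_outpatient_physician, 1),
                           p_pct = p_value)],
                  by = "test_family")
  table4 <- est_tab[grepl("^quality_", get("model")),
                    .(measure = sub("^quality_(.*)_or$", "\\1", get("model")),
                      odds_ratio = round(point, 2),
                      ci_low = round(ci_low, 2), ci_high = round(ci_high, 2),
                      p_value)]

  ## ---- write outputs -------------------------------------------------------
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fwrite_ <- function(x, f) {
    p <- file.path(out_dir, f)
    data.table::fwrite(x, p)
    p
  }
  files <- c(
    fwrite_(table1, "table1_descriptive.csv"),
    fwrite_(table2, "table2_spending.csv"),
    fwrite_(table3, "table3_utilization.csv"),
    fwrite_(table4, "table4_quality.csv"),
    fwrite_(est_tab, "estimates.csv"),
    fwrite_(att, "attribution.csv"),
    fwrite_(spend, "annual_spend.csv"),
    fwrite_(build_median_prices(ds$claims, ds$crosswalk, ds$revenue_map),
            "median_prices.csv"),
    fwrite_(qrec, "quality_records.csv"),
    fwrite_(pos_betos, "positive_shares_betos.csv"),
    fwrite_(pos_setting, "positive_shares_setting.csv"))
  exc_log <- att[, .N, by = exclusion_reason]
  files <- c(files, fwrite_(exc_log, "exclusions.csv"))
  card <- c(
    "vertispend model card",
    sprintf("variance family: quasi-Poisson (variance proportional to mean)"),
    sprintf("cluster covariance: CR0 with G/(G-1) factor, t(G-1) inference"),
    sprintf("ownership coding: pooled hospital vs physician-owned (primary)"),
    sprintf("hospital-coefficient equality test p = %s",
            if (is.null(hosp_eq)) "NA" else format(hosp_eq$p_value,
                                                   digits = 3)),
    sprintf("attribution window: calendar year +/- 6 months"),
    sprintf("median prices pooled across ownership within BETOS category x year"),
    sprintf("references: physician_owned, age 19-29, first year, first MSA"),
    sprintf("risk deciles computed on the estimation sample"))
  card_path <- file.path(out_dir, "model_card.txt")
  writeLines(card, card_path)
  manifest <- run_manifest(config, c(files, card_path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    config = config, dataset = ds, attribution = att, sizes = sizes,
    spend = spend, quality = qrec, frame = frame,
    fits = list(total = fit_total, total_std = fit_std,
                dollars = fit_dollars, three_level = fit3),
    hospital_equality = hosp_eq, decomposition = decomp,
    estimates = est_tab,
    tables = list(table1 = table1, table2 = table2, table3 = table3,
                  table4 = table4),
    positive_shares = list(betos = pos_betos, setting = pos_setting),
    manifest = manifest, files = files))
}
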