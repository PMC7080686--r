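#' Assign a BETOS category to every claim
#'
#' Professional claims map through the HCPCS crosswalk; facility claims map
#' through the revenue-code map (operating/recovery-room codes are
#' `unclassified`). Unmapped codes fall into `unclassified` with a warning,
#' so decomposition conservation always holds.
#'
#' @param claims claims table.
#' @param crosswalk HCPCS to BETOS crosswalk.
#' @param revenue_map revenue-code to BETOS map.
#' @return the claims table with a `betos_category` column added (a copy).
#' @export
assign_betos <- function(claims, crosswalk, revenue_map = default_revenue_map()) {
  cl <- data.table::copy(ensure_claim_year(claims))
  cw <- data.table::as.data.table(crosswalk)
  rm_ <- data.table::as.data.table(revenue_map)
  cl[, betos_category := NA_character_]
  cl[setting == "professional",
     betos_category := cw$betos_category[match(hcpcs, cw$hcpcs)]]
  cl[setting != "professional",
     betos_category := rm_$betos_category[match(revenue_code, rm_$revenue_code)]]
  n_unmapped <- cl[setting == "professional" & is.na(betos_category), .N]
  if (n_unmapped > 0L) {
    warning(n_unmapped, " professional claim(s) with HCPCS missing from the ",
            "crosswalk assigned to `unclassified`")
  }
  cl[is.na(betos_category), betos_category := "unclassified"]
  cl[]
}

#' Aggregate claims into per-member-year spending records
#'
#' Sums allowed amounts per cohort member-year, overall and by BETOS
#' category and by site of care, in exact cents. Claims of non-cohort
#' members are ignored; cohort member-years without claims get all-zero
#' rows. Column layout is wide: `total`, `betos_<category>`,
#' `setting_<setting>`.
#'
#' @param claims claims table.
#' @param cohort member-years to aggregate for (`member_id`, `year`).
#' @param crosswalk,revenue_map BETOS maps, see [assign_betos()].
#' @return data.table, one row per cohort member-year.
#' @export
aggregate_spending <- function(claims, cohort, crosswalk,
                               revenue_map = default_revenue_map()) {
  if (any(claims$allowed_amount < 0)) {
    stop("negative allowed_amount found; adjustment claims are unsupported")
  }
  cl <- assign_betos(claims, crosswalk, revenue_map)
  coh <- data.table::as.data.table(cohort)[, .(member_id, year)]
  cl <- cl[coh, on = c("member_id", "year"), nomatch = NULL]
  cl[, cents := as.numeric(round(100 * allowed_amount))]
  wide_sum <- function(col, prefix, levels) {
    f <- cl[, .(value = sum(cents) / 100), by = c("member_id", "year", col)]
    w <- data.table::dcast(f, member_id + year ~ get(col), value.var = "value",
                           fill = 0)
    for (lv in setdiff(levels, names(w))) w[, (lv) := 0]
    data.table::setnames(w, levels, paste0(prefix, levels))
    w[, c("member_id", "year", paste0(prefix, levels)), with = FALSE]
  }
  bet <- wide_sum("betos_category", "betos_", betos_categories())
  set_ <- wide_sum("setting", "setting_", care_settings())
  tot <- cl[, .(total = sum(cents) / 100), by = .(member_id, year)]
  out <- merge(coh, tot, by = c("member_id", "year"), all.x = TRUE)
  out <- merge(out, bet, by = c("member_id", "year"), all.x = TRUE)
  out <- merge(out, set_, by = c("member_id", "year"), all.x = TRUE)
  for (j in setdiff(names(out), c("member_id", "year"))) {
    data.table::set(out, which(is.na(out[[j]])), j, 0)
  }
  data.table::setorder(out, member_id, year)
  out[]
}

#' Median allowed amount per BETOS category and year
#'
#' Medians are pooled across ownership types within each category-year; an
#' even claim count yields the mean of the central pair.
#'
#' @inheritParams aggregate_spending
#' @return data.table `betos_category`, `year`, `median_price`.
#' @export
build_median_prices <- function(claims, crosswalk,
                                revenue_map = default_revenue_map()) {
  if (nrow(claims) == 0L) stop("cannot build median prices from zero claims")
  cl <- assign_betos(claims, crosswalk, revenue_map)
  out <- cl[, .(median_price = median(allowed_amount)),
            by = .(betos_category, year)]
  data.table::setorder(out, betos_category, year)
  out[]
}

#' Replace claim prices with category-year median prices
#'
#' Standardization keeps every claim (counts unchanged) but substitutes the
#' median price of its BETOS category and year, so re-aggregated spending
#' reflects utilization only. Idempotent: standardizing already-standardized
#' claims is a no-op.
#'
#' @inheritParams aggregate_spending
#' @param price_table output of [build_median_prices()]; must cover every
#'   claim's category-year.
#' @return claims table (copy) with `allowed_amount` replaced.
#' @export
standardize_claims <- function(claims, price_table, crosswalk,
                               revenue_map = default_revenue_map()) {
  cl <- assign_betos(claims, crosswalk, revenue_map)
  pt <- data.table::as.data.table(price_table)
  cl[pt, on = c("betos_category", "year"), median_price := i.median_price]
  if (anyNA(cl$median_price)) {
    miss <- unique(cl[is.na(median_price),
                      paste(betos_category, year, sep = "/")])
    stop("median price table missing category-years: ",
         paste(miss, collapse = ", "))
  }
  cl[, allowed_amount := median_price]
  cl[, median_price := NULL]
  cl[]
}

#' Actual and price-standardized annual spending, wide
#'
#' Runs [aggregate_spending()] on the claims as billed and, when
#' `standardize` is `TRUE`, again after [standardize_claims()] with medians
#' built from the same claims; standardized columns carry the suffix
#' `_std`.
#'
#' @inheritParams aggregate_spending
#' @param standardize build standardized columns too?
#' @return data.table, one row per cohort member-year.
#' @export
annual_spend_table <- function(claims, cohort, crosswalk,
                               revenue_map = default_revenue_map(),
                               standardize = TRUE) {
  actual <- aggregate_spending(claims, cohort, crosswalk, revenue_map)
  if (!standardize) return(actual)
  prices <- build_median_prices(claims, crosswalk, revenue_map)
  std_claims <- standardize_claims(claims, prices, crosswalk, revenue_map)
  std <- aggregate_spending(std_claims, cohort, crosswalk, revenue_map)
  val_cols <- setdiff(names(std), c("member_id", "year"))
  data.table::setnames(std, val_cols, paste0(val_cols, "_std"))
  merge(actual, std, by = c("member_id", "year"))
}

#' Share of members with positive spending, by ownership, with z-tests
#'
#' For each BETOS category (or site of care), computes the share of
#' attributed members with positive annual spending in physician-owned
#' versus hospital-owned (pooled) practices, and a two-sided two-proportion
#' z-test (pooled variance, no continuity correction).
#'
#' @param spend output of [aggregate_spending()]/[annual_spend_table()].
#' @param attribution attribution table (rows with `org_id` are attributed).
#' @param by `"betos"` or `"setting"`.
#' @return data.table with per-category shares, counts, z and p-value;
#'   `flagged` marks cells with an empty ownership group (share undefined).
#' @export
positive_spending_shares <- function(spend, attribution, by = "betos") {
  att <- data.table::as.data.table(attribution)
  att <- att[!is.na(org_id), .(member_id, year, ownership)]
  sp <- merge(data.table::as.data.table(spend), att,
              by = c("member_id", "year"))
  sp[, grp := data.table::fifelse(ownership == "physician_owned",
                                  "physician", "hospital")]
  prefix <- if (by == "betos") "betos_" else "setting_"
  cols <- grep(paste0("^", prefix, "[a-z_]+$"), names(sp), value = TRUE)
  cols <- cols[!grepl("_std$", cols)]
  res <- lapply(cols, function(cn) {
    n1 <- sp[grp == "hospital", .N]; n0 <- sp[grp == "physician", .N]
    x1 <- sp[grp == "hospital", sum(get(cn) > 0)]
    x0 <- sp[grp == "physician", sum(get(cn) > 0)]
    tst <- two_proportion_test(x1, n1, x0, n0)
    data.table::data.table(
      category = sub(prefix, "", cn),
      share_hospital = if (n1 > 0) x1 / n1 else NA_real_,
      share_physician = if (n0 > 0) x0 / n0 else NA_real_,
      n_hospital = n1, n_physician = n0,
      z = tst$z, p_value = tst$p, flagged = n1 == 0L || n0 == 0L)
  })
  data.table::rbindlist(res)
}

# Pooled two-proportion z-test, two-sided, no continuity correction.
two_proportion_test <- function(x1, n1, x0, n0) {
  if (n1 == 0L || n0 == 0L) return(list(z = NA_real_, p = NA_real_))
  p1 <- x1 / n1; p0 <- x0 / n0
  pp <- (x1 + x0) / (n1 + n0)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n0))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (p1 - p0) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}
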