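#' Raw annual spending totals per member-year
#'
#' Sums allowed amounts over all claims in each calendar year, before any
#' cohort restriction or price standardization; member-years with no claims
#' get a zero row so the cohort filter can require a total for everyone.
#'
#' @param claims claims table (needs `member_id`, `year` or `service_date`,
#'   `allowed_amount`).
#' @param members member-year table (`member_id`, `year`).
#' @return data.table `member_id`, `year`, `total` (dollars, cent-exact).
#' @export
raw_annual_totals <- function(claims, members) {
  cl <- ensure_claim_year(claims)
  tot <- cl[, .(total = sum(as.numeric(round(100 * allowed_amount))) / 100),
            by = .(member_id, year)]
  out <- data.table::as.data.table(members)[, .(member_id, year)]
  out[tot, on = c("member_id", "year"), total := total]
  out[is.na(total), total := 0]
  out[]
}

ensure_claim_year <- function(claims) {
  cl <- data.table::as.data.table(claims)
  if (!"year" %in% names(cl)) {
    cl <- data.table::copy(cl)  # never mutate the caller's table
    cl[, year := as.integer(format(service_date, "%Y"))]
  }
  cl
}

#' Filter member-years into the analytic cohort
#'
#' Retains adults aged 19 to 64, continuously enrolled, with annual raw
#' spending of at most $100,000 (strictly greater is excluded, so a total of
#' exactly $100,000.00 is retained). Exclusion reasons are applied in the
#' order age, enrollment, spending cap, so each dropped member-year carries
#' exactly one reason.
#'
#' @param members member-year table.
#' @param annual_totals output of [raw_annual_totals()]; must cover every
#'   member-year in `members`.
#' @return list with `cohort` (retained member-years) and `exclusions`
#'   (`member_id`, `year`, `exclusion_reason`).
#' @export
filter_cohort <- function(members, annual_totals) {
  mem <- data.table::as.data.table(members)
  tot <- data.table::as.data.table(annual_totals)
  mem <- merge(mem, tot[, .(member_id, year, total)],
               by = c("member_id", "year"), all.x = TRUE, sort = FALSE)
  if (anyNA(mem$total)) {
    bad <- mem[is.na(total), paste(member_id, year, sep = "/")]
    stop("annual totals missing for member-years: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
  }
  reason <- rep("none", nrow(mem))
  reason[mem$age < 19 | mem$age > 64] <- "age_out_of_range"
  reason[reason == "none" & !mem$continuously_enrolled] <-
    "not_continuously_enrolled"
  reason[reason == "none" & mem$total > 100000] <- "spend_over_cap"
  keep_row <- reason == "none"
  list(cohort = mem[keep_row][, total := NULL][],
       exclusions = data.table::data.table(
         member_id = mem$member_id[!keep_row],
         year = mem$year[!keep_row],
         exclusion_reason = reason[!keep_row]))
}

month_shift <- function(year, month) {
  # first day of `month` (may be outside 1..12) in `year`
  yy <- year + (month - 1) %/% 12
  mm <- (month - 1) %% 12 + 1
  as.Date(sprintf("%04d-%02d-01", yy, mm))
}

#' Attribute cohort member-years to physician organizations
#'
#' Counts professional evaluation-and-management visits to primary-care
#' physicians (the five PCP specialties) in a 24-month window: the calendar
#' year plus `flank_months` months on each side (default 6, i.e. July 1 of
#' the prior year through June 30 of the following year). Each member-year
#' is attributed to the PCP — and hence the organization on that PCP's most
#' recent in-window claim — with the plurality of visits; ties are broken by
#' most recent visit date, then by lexicographically smallest `pcp_id`.
#' Member-years with no PCP visits in the window are excluded with reason
#' `no_pcp_visits`.
#'
#' @param cohort member-year table (from [filter_cohort()]).
#' @param claims claims table.
#' @param roster long-form roster (`org_id`, `ownership`, `msa`, `pcp_id`).
#' @param crosswalk HCPCS to BETOS crosswalk (identifies E&M visits).
#' @param pcp_specs PCP specialty list.
#' @param flank_months months added on each side of the calendar year.
#' @return data.table `member_id`, `year`, `pcp_id`, `specialty`, `org_id`,
#'   `ownership`, `exclusion_reason` (`none` or `no_pcp_visits`).
#' @export
attribute_members <- function(cohort, claims, roster, crosswalk,
                              pcp_specs = pcp_specialties(),
                              flank_months = 6L) {
  cl <- ensure_claim_year(claims)
  ros <- data.table::as.data.table(roster)
  cw <- data.table::as.data.table(crosswalk)
  em_codes <- cw[betos_category == "evaluation_management", hcpcs]
  visits <- cl[setting == "professional" & !is.na(pcp_id) &
                 specialty %in% pcp_specs & hcpcs %in% em_codes,
               .(member_id, service_date, pcp_id, org_id, specialty)]
  orphans <- setdiff(unique(visits$pcp_id), unique(ros$pcp_id))
  if (length(orphans)) {
    stop("PCP ids on claims absent from roster: ",
         paste(sort(orphans), collapse = ", "))
  }
  coh <- data.table::as.data.table(cohort)[, .(member_id, year)]
  years <- sort(unique(coh$year))
  tallies <- vector("list", length(years))
  for (i in seq_along(years)) {
    y <- years[i]
    lo <- month_shift(y, 1L - flank_months)
    hi <- month_shift(y + 1L, 1L + flank_months) - 1L
    v <- visits[service_date >= lo & service_date <= hi]
    v <- v[coh[year == y], on = "member_id", nomatch = NULL]
    if (nrow(v) == 0L) next
    t_i <- v[, .(n_visits = .N, last_visit = max(service_date)),
             by = .(member_id, pcp_id)]
    # organization and specialty from the PCP's most recent in-window claim
    data.table::setorder(v, member_id, pcp_id, service_date)
    last <- v[v[, .I[.N], by = .(member_id, pcp_id)]$V1]
    t_i[last, on = c("member_id", "pcp_id"),
        `:=`(org_id = i.org_id, specialty = i.specialty)]
    t_i[, window_year := y]
    tallies[[i]] <- t_i
  }
  tal <- data.table::rbindlist(tallies)
  if (nrow(tal)) {
    data.table::setorder(tal, window_year, member_id, -n_visits, -last_visit,
                         pcp_id)
    win <- tal[tal[, .I[1L], by = .(window_year, member_id)]$V1]
    win <- win[, .(member_id, year = window_year, pcp_id, specialty, org_id)]
    own <- unique(ros[, .(org_id, ownership)])
    win[own, on = "org_id", ownership := i.ownership]
    win[, exclusion_reason := "none"]
  } else {
    win <- data.table::data.table(
      member_id = character(), year = integer(), pcp_id = character(),
      specialty = character(), org_id = character(), ownership = character(),
      exclusion_reason = character())
  }
  out <- merge(coh, win, by = c("member_id", "year"), all.x = TRUE,
               sort = FALSE)
  out[is.na(exclusion_reason), exclusion_reason := "no_pcp_visits"]
  data.table::setorder(out, member_id, year)
  out[]
}

#' Full attribution table with exclusion reasons
#'
#' Convenience wrapper running [raw_annual_totals()], [filter_cohort()] and
#' [attribute_members()], returning one row per member-year with either an
#' organization or an exclusion reason (mutually exclusive, collectively
#' exhaustive).
#'
#' @inheritParams attribute_members
#' @param members member-year table.
#' @return data.table with columns `member_id`, `year`, `pcp_id`,
#'   `specialty`, `org_id`, `ownership`, `exclusion_reason`.
#' @export
attribution_table <- function(members, claims, roster, crosswalk,
                              pcp_specs = pcp_specialties(),
                              flank_months = 6L) {
  totals <- raw_annual_totals(claims, members)
  fc <- filter_cohort(members, totals)
  att <- attribute_members(fc$cohort, claims, roster, crosswalk,
                           pcp_specs, flank_months)
  exc <- fc$exclusions[, .(member_id, year, pcp_id = NA_character_,
                           specialty = NA_character_, org_id = NA_character_,
                           ownership = NA_character_, exclusion_reason)]
  out <- data.table::rbindlist(list(att, exc), use.names = TRUE)
  data.table::setorder(out, member_id, year)
  out[]
}

#' Practice-size categories from attributed patient counts
#'
#' Four categories per organization-year: up to 500 attributed patients;
#' 501 to 10,000; 10,001 to 15,000; and 15,001 or more.
#'
#' @param attribution attribution table (attributed rows are those with a
#'   non-missing `org_id`).
#' @param roster optional roster so organizations with zero attributed
#'   patients appear (category 1).
#' @param n_bins `4` for the standard categories, or `10` for decile bins of
#'   org-year patient counts (sensitivity analysis).
#' @return data.table `org_id`, `year`, `n_patients`, `size_category`.
#' @export
practice_size_category <- function(attribution, roster = NULL, n_bins = 4L) {
  att <- data.table::as.data.table(attribution)
  counts <- att[!is.na(org_id), .(n_patients = .N), by = .(org_id, year)]
  if (!is.null(roster)) {
    ros <- unique(data.table::as.data.table(roster)[, .(org_id)])
    grid <- data.table::CJ(org_id = ros$org_id,
                           year = sort(unique(att$year)))
    counts <- merge(grid, counts, by = c("org_id", "year"), all.x = TRUE)
    counts[is.na(n_patients), n_patients := 0L]
  }
  if (n_bins == 4L) {
    counts[, size_category := cut(n_patients, c(-Inf, 500, 10000, 15000, Inf),
                                  labels = paste0("size", 1:4))]
  } else {
    qs <- unique(quantile(counts$n_patients, probs = seq(0, 1, length.out = n_bins + 1)))
    counts[, size_category := cut(n_patients, qs, include.lowest = TRUE,
                                  labels = paste0("size", seq_len(length(qs) - 1L)))]
  }
  counts[, size_category := as.character(size_category)]
  data.table::setorder(counts, org_id, year)
  counts[]
}
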