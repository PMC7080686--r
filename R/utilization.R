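#' Match claims to test families
#'
#' A professional claim matches a family when its HCPCS is in the family's
#' professional code set; an outpatient facility claim matches when its
#' revenue code is in the family's revenue set. Families are disjoint, and a
#' claim carrying both code systems is classified by its `setting` field, so
#' each matched claim lands in exactly one family and one setting.
#'
#' @param claims claims table.
#' @param families test-family crosswalk ([default_test_families()]).
#' @return data.table of matched claims with `test_family` added.
#' @export
match_test_families <- function(claims, families = default_test_families()) {
  cl <- data.table::copy(ensure_claim_year(claims))
  fam <- data.table::as.data.table(families)
  prof <- fam[code_type == "professional"]
  rev <- fam[code_type == "revenue"]
  cl[, test_family := NA_character_]
  cl[setting == "professional",
     test_family := prof$test_family[match(hcpcs, prof$code)]]
  cl[setting == "outpatient_facility",
     test_family := rev$test_family[match(revenue_code, rev$code)]]
  cl[!is.na(test_family)]
}

#' Claims per attributed member by test family and ownership
#'
#' The numerator is matched claims of attributed members (professional code
#' or outpatient revenue code in the family); the denominator is attributed
#' members in the ownership group. The rate difference is tested with a
#' two-sided z-test on member-level claim counts.
#'
#' @param claims claims table.
#' @param attribution attribution table.
#' @param families test-family crosswalk.
#' @return data.table: family, per-group rates, member counts, z, p-value;
#'   `flagged` marks empty ownership groups.
#' @export
claims_per_member <- function(claims, attribution,
                              families = default_test_families()) {
  att <- data.table::as.data.table(attribution)
  att <- att[!is.na(org_id), .(member_id, year, ownership)]
  att[, grp := data.table::fifelse(ownership == "physician_owned",
                                   "physician", "hospital")]
  mt <- match_test_families(claims, families)
  mt <- mt[att, on = c("member_id", "year"), nomatch = NULL]
  fams <- sort(unique(data.table::as.data.table(families)$test_family))
  n_h <- att[grp == "hospital", .N]
  n_p <- att[grp == "physician", .N]
  out <- lapply(fams, function(f) {
    cnt <- mt[test_family == f, .(n_claims = .N),
              by = .(member_id, year, grp)]
    cnt <- merge(att[, .(member_id, year, grp)], cnt,
                 by = c("member_id", "year", "grp"), all.x = TRUE)
    cnt[is.na(n_claims), n_claims := 0L]
    xh <- cnt[grp == "hospital", n_claims]
    xp <- cnt[grp == "physician", n_claims]
    if (n_h > 0L && n_p > 0L) {
      se <- sqrt(stats::var(xh) / n_h + stats::var(xp) / n_p)
      z <- if (se > 0) (mean(xh) - mean(xp)) / se else 0
      p <- if (se > 0) 2 * pnorm(-abs(z)) else 1
    } else {
      z <- NA_real_; p <- NA_real_
    }
    data.table::data.table(
      test_family = f,
      rate_hospital = if (n_h > 0L) sum(xh) / n_h else NA_real_,
      rate_physician = if (n_p > 0L) sum(xp) / n_p else NA_real_,
      n_hospital = n_h, n_physician = n_p, z = z, p_value = p,
      flagged = n_h == 0L || n_p == 0L)
  })
  data.table::rbindlist(out)
}

#' Percent of matched claims billed in the outpatient setting
#'
#' Per family and ownership group: `100 * outpatient-matched /
#' (outpatient-matched + professional-matched)`, with a two-sided
#' two-proportion z-test of the hospital/physician difference.
#'
#' @inheritParams claims_per_member
#' @return data.table: family, per-group percentages, matched-claim counts,
#'   z, p-value; `flagged` marks cells with zero matched claims.
#' @export
percent_outpatient <- function(claims, attribution,
                               families = default_test_families()) {
  att <- data.table::as.data.table(attribution)
  att <- att[!is.na(org_id), .(member_id, year, ownership)]
  att[, grp := data.table::fifelse(ownership == "physician_owned",
                                   "physician", "hospital")]
  mt <- match_test_families(claims, families)
  mt <- mt[att, on = c("member_id", "year"), nomatch = NULL]
  fams <- sort(unique(data.table::as.data.table(families)$test_family))
  out <- lapply(fams, function(f) {
    m <- mt[test_family == f]
    nh <- m[grp == "hospital", .N]
    np <- m[grp == "physician", .N]
    xh <- m[grp == "hospital" & setting == "outpatient_facility", .N]
    xp <- m[grp == "physician" & setting == "outpatient_facility", .N]
    tst <- two_proportion_test(xh, nh, xp, np)
    data.table::data.table(
      test_family = f,
      pct_outpatient_hospital = if (nh > 0L) 100 * xh / nh else NA_real_,
      pct_outpatient_physician = if (np > 0L) 100 * xp / np else NA_real_,
      matched_hospital = nh, matched_physician = np,
      z = tst$z, p_value = tst$p, flagged = nh == 0L || np == 0L)
  })
  data.table::rbindlist(out)
}
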