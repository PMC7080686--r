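#' Merge overlapping inpatient stays into episodes
#'
#' Stays are merged when one admission starts on or before the discharge
#' date of the previous stay (transfers, with admission equal to discharge,
#' merge rather than count as readmissions).
#'
#' @param ip inpatient claims (`member_id`, `admit_date`, `discharge_date`).
#' @return data.table `member_id`, `admit_date`, `discharge_date`, one row
#'   per merged episode.
#' @keywords internal
merge_stays <- function(ip) {
  st <- data.table::as.data.table(ip)[, .(member_id, admit_date,
                                          discharge_date)]
  data.table::setorder(st, member_id, admit_date, discharge_date)
  st[, prev_disch := data.table::shift(cummax(as.integer(discharge_date))),
     by = member_id]
  st[, episode := cumsum(is.na(prev_disch) |
                           as.integer(admit_date) > prev_disch),
     by = member_id]
  st[, .(admit_date = min(admit_date),
         discharge_date = max(discharge_date)),
     by = .(member_id, episode)][, episode := NULL][]
}

#' 30-day all-cause readmission records
#'
#' After merging overlapping/contiguous stays, a member-year is eligible if
#' it contains at least one episode discharge; the numerator is true when
#' any episode discharge in the year is followed by an admission 1 to 30
#' days later (day 30 counts, day 31 does not).
#'
#' @param claims claims table; inpatient rows must carry admit and discharge
#'   dates.
#' @return data.table of QualityRecords: `member_id`, `year`,
#'   `measure = "readmit_30d"`, `eligible`, `numerator`.
#' @export
readmissions <- function(claims) {
  cl <- data.table::as.data.table(claims)
  ip <- cl[setting == "inpatient_facility"]
  if (nrow(ip) == 0L) {
    return(data.table::data.table(
      member_id = character(), year = integer(), measure = character(),
      eligible = logical(), numerator = logical()))
  }
  if (anyNA(ip$admit_date) || anyNA(ip$discharge_date)) {
    stop("inpatient claims missing admit/discharge dates")
  }
  if (any(ip$discharge_date < ip$admit_date)) {
    stop("inpatient claim discharged before admission")
  }
  ep <- merge_stays(ip)
  data.table::setorder(ep, member_id, admit_date)
  ep[, gap := as.integer(data.table::shift(admit_date, type = "lead") -
                           discharge_date), by = member_id]
  ep[, readmit := !is.na(gap) & gap >= 1L & gap <= 30L]
  ep[, year := as.integer(format(discharge_date, "%Y"))]
  out <- ep[, .(eligible = TRUE, numerator = any(readmit)),
            by = .(member_id, year)]
  out[, measure := "readmit_30d"]
  out[, .(member_id, year, measure, eligible, numerator)]
}

#' Diabetes process measures (HbA1c, LDL, retinal exam)
#'
#' A cohort member-year is diabetic — hence eligible — if it has at least
#' one claim flagged `dx_diabetes` in the year; the numerator for each
#' measure is at least one claim whose HCPCS is in the measure's code set
#' that year.
#'
#' @param claims claims table.
#' @param cohort member-years under analysis.
#' @param codesets named list of HCPCS code sets (defaults packaged); names
#'   `hba1c`, `ldl`, `retinal_exam` are used.
#' @return data.table of QualityRecords for the three measures (eligible
#'   member-years only).
#' @export
diabetes_measures <- function(claims, cohort,
                              codesets = default_quality_codesets()) {
  cl <- ensure_claim_year(claims)
  coh <- data.table::as.data.table(cohort)[, .(member_id, year)]
  cl <- cl[coh, on = c("member_id", "year"), nomatch = NULL]
  dia <- unique(cl[dx_diabetes == 1, .(member_id, year)])
  out <- lapply(c("hba1c", "ldl", "retinal_exam"), function(m) {
    codes <- codesets[[m]]
    hits <- unique(cl[hcpcs %in% codes, .(member_id, year)])
    rec <- data.table::copy(dia)
    rec[, `:=`(measure = m, eligible = TRUE)]
    rec[, numerator := FALSE]
    rec[hits, on = c("member_id", "year"), numerator := TRUE]
    rec
  })
  data.table::rbindlist(out)[, .(member_id, year, measure, eligible, numerator)]
}

#' Screening mammography for women ages 50 to 64
#'
#' Eligible member-years are women aged 50 to 64 in the year (age 49 is not
#' eligible, age 50 is); the numerator is at least one claim with a
#' screening-mammography code that year.
#'
#' @inheritParams diabetes_measures
#' @param cohort member-years with `age` and `sex` columns.
#' @return data.table of QualityRecords (eligible member-years only).
#' @export
mammography <- function(claims, cohort,
                        codesets = default_quality_codesets()) {
  cl <- ensure_claim_year(claims)
  coh <- data.table::as.data.table(cohort)
  elig <- coh[sex == "F" & age >= 50 & age <= 64, .(member_id, year)]
  hits <- unique(cl[hcpcs %in% codesets$mammography, .(member_id, year)])
  rec <- data.table::copy(elig)
  rec[, `:=`(measure = "mammography", eligible = TRUE, numerator = FALSE)]
  rec[hits, on = c("member_id", "year"), numerator := TRUE]
  rec[, .(member_id, year, measure, eligible, numerator)]
}

#' All five claims-based quality measures
#'
#' Builds the member-level analytic records for 30-day readmission, the
#' three diabetes process measures and screening mammography, restricted to
#' cohort member-years.
#'
#' @inheritParams diabetes_measures
#' @param cohort member-years with `age` and `sex`.
#' @return data.table of QualityRecords, one row per member-year-measure
#'   (eligible rows only; `numerator` implies `eligible`).
#' @export
quality_records <- function(claims, cohort,
                            codesets = default_quality_codesets()) {
  coh <- data.table::as.data.table(cohort)
  re <- readmissions(claims)
  re <- re[coh[, .(member_id, year)], on = c("member_id", "year"),
           nomatch = NULL]
  out <- data.table::rbindlist(list(
    re, diabetes_measures(claims, coh, codesets),
    mammography(claims, coh, codesets)))
  data.table::setorder(out, measure, member_id, year)
  out[]
}
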