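cw <- default_betos_crosswalk()

# Visits fixture: professional 99213 claims by PCPs; helper keeps the E&M /
# specialty plumbing out of the way.
visit <- function(member, date, pcp, org = "P0001",
                  spec = "internal_medicine") {
  make_claims(member, date, hcpcs = "99213", org_id = org, pcp_id = pcp,
              specialty = spec)
}

test_that("cohort filter applies the age, enrollment and spending rules", {
  mem <- make_members(sprintf("M%02d", 1:6), age = c(18, 19, 64, 65, 40, 40),
                      continuously_enrolled = c(rep(TRUE, 5), FALSE))
  tot <- data.table(member_id = mem$member_id, year = 2015L,
                    total = c(0, 0, 0, 0, 100000.00, 50))
  fc <- filter_cohort(mem, tot)
  expect_setequal(fc$cohort$member_id, c("M02", "M03", "M05"))
  expect_equal(fc$exclusions[member_id == "M01", exclusion_reason],
               "age_out_of_range")
  expect_equal(fc$exclusions[member_id == "M04", exclusion_reason],
               "age_out_of_range")
  expect_equal(fc$exclusions[member_id == "M06", exclusion_reason],
               "not_continuously_enrolled")
  # boundary: exactly $100,000.00 retained, a cent more excluded
  tot2 <- copy(tot)[member_id == "M05", total := 100000.01]
  fc2 <- filter_cohort(mem, tot2)
  expect_equal(fc2$exclusions[member_id == "M05", exclusion_reason],
               "spend_over_cap")
})

test_that("cohort filter demands a spending total for every member-year", {
  mem <- make_members(c("M01", "M02"))
  tot <- data.table(member_id = "M01", year = 2015L, total = 10)
  expect_error(filter_cohort(mem, tot), "M02")
})

test_that("empty member list yields empty cohort and log", {
  fc <- filter_cohort(make_members(character()),
                      data.table(member_id = character(), year = integer(),
                                 total = numeric()))
  expect_equal(nrow(fc$cohort), 0L)
  expect_equal(nrow(fc$exclusions), 0L)
})

test_that("plurality of PCP visits decides the organization", {
  ros <- make_roster(c("P0001", "P0002"), pcp_id = c("D1", "D2"))
  cl <- rbind(
    visit("M01", "2015-02-01", "D1"), visit("M01", "2015-03-01", "D1"),
    visit("M01", "2015-04-01", "D1"), visit("M01", "2015-05-01", "D2",
                                            org = "P0002"))
  att <- attribute_members(make_members("M01"), cl, ros, cw)
  expect_equal(att$org_id, "P0001")
  expect_equal(att$pcp_id, "D1")
  expect_equal(att$exclusion_reason, "none")
})

test_that("ties break by most recent visit then smallest pcp_id", {
  ros <- make_roster(c("P0001", "P0002"), pcp_id = c("D1", "D2"))
  cl <- rbind(
    visit("M01", "2015-02-01", "D1"), visit("M01", "2015-03-01", "D1"),
    visit("M01", "2015-04-01", "D2", org = "P0002"),
    visit("M01", "2015-08-01", "D2", org = "P0002"))
  att <- attribute_members(make_members("M01"), cl, ros, cw)
  expect_equal(att$org_id, "P0002")  # D2's latest visit is more recent

  # equal counts and equal latest dates: smallest pcp_id wins
  cl2 <- rbind(
    visit("M02", "2015-02-01", "D9", org = "P0002"),
    visit("M02", "2015-02-01", "D1"))
  ros2 <- make_roster(c("P0001", "P0002"), pcp_id = c("D1", "D9"))
  att2 <- attribute_members(make_members("M02"), cl2, ros2, cw)
  expect_equal(att2$pcp_id, "D1")

  # brute-force oracle: recount visits independently for the tie case
  counts <- table(cl$pcp_id)
  expect_true(all(counts == max(counts)))  # genuinely tied
  latest <- tapply(cl$service_date, cl$pcp_id, max)
  expect_equal(names(which.max(latest)), att$pcp_id)
})

test_that("specialist-only visits leave the member unattributed", {
  ros <- make_roster("P0001", pcp_id = "D1")
  cl <- make_claims("M01", "2015-03-01", hcpcs = "99213", org_id = "P0001",
                    pcp_id = "D1", specialty = "cardiology")
  att <- attribute_members(make_members("M01"), cl, ros, cw)
  expect_equal(att$exclusion_reason, "no_pcp_visits")
  expect_true(is.na(att$org_id))
})

test_that("the 24-month window is the year plus six flanking months", {
  ros <- make_roster("P0001", pcp_id = "D1")
  inside <- rbind(visit("M01", "2014-07-01", "D1"),   # first in-window day
                  visit("M02", "2016-06-30", "D1"))   # last in-window day
  outside <- rbind(visit("M03", "2014-06-30", "D1"),
                   visit("M04", "2016-07-01", "D1"))
  mem <- make_members(c("M01", "M02", "M03", "M04"))
  att <- attribute_members(mem, rbind(inside, outside), ros, cw)
  expect_equal(att[member_id %in% c("M01", "M02"), exclusion_reason],
               rep("none", 2))
  expect_equal(att[member_id %in% c("M03", "M04"), exclusion_reason],
               rep("no_pcp_visits", 2))
})

test_that("a PCP on a claim but missing from the roster is an error", {
  ros <- make_roster("P0001", pcp_id = "D1")
  cl <- visit("M01", "2015-03-01", "D999")
  expect_error(attribute_members(make_members("M01"), cl, ros, cw), "D999")
})

test_that("attribution is invariant to claim-file row order", {
  ds <- generate_claims_dataset(small_config(seed = 21))
  att1 <- attribution_table(ds$members, ds$claims, ds$roster, ds$crosswalk)
  set.seed(1)
  shuffled <- ds$claims[sample(.N)]
  att2 <- attribution_table(ds$members, shuffled, ds$roster, ds$crosswalk)
  expect_equal(att1, att2)
})

test_that("exclusion reasons partition the member-years", {
  ds <- generate_claims_dataset(small_config(seed = 33))
  att <- attribution_table(ds$members, ds$claims, ds$roster, ds$crosswalk)
  expect_equal(nrow(att), nrow(ds$members))
  expect_equal(nrow(unique(att[, .(member_id, year)])), nrow(att))
  expect_true(all(att$exclusion_reason %in%
                    c("none", "age_out_of_range", "not_continuously_enrolled",
                      "no_pcp_visits", "spend_over_cap")))
  expect_true(all(is.na(att[exclusion_reason != "none", org_id])))
  expect_true(all(!is.na(att[exclusion_reason == "none", org_id])))
})

test_that("single-PCP members are attributed to their true organization", {
  ds <- generate_claims_dataset(small_config(seed = 34))
  att <- attribution_table(ds$members, ds$claims, ds$roster, ds$crosswalk)
  m <- merge(att[exclusion_reason == "none"], ds$truth,
             by = c("member_id", "year"), suffixes = c("", ".true"))
  expect_gt(nrow(m), 0)
  expect_equal(mean(m$org_id == m$org_id.true), 1)
})

test_that("practice size categories use the printed boundaries", {
  att <- data.table(
    member_id = sprintf("M%05d", 1:26003),
    year = 2015L,
    org_id = rep(c("A", "B", "C", "D"), c(500, 501, 10001, 15001)),
    exclusion_reason = "none")
  sz <- practice_size_category(att)
  expect_equal(sz[org_id == "A", size_category], "size1")
  expect_equal(sz[org_id == "B", size_category], "size2")
  expect_equal(sz[org_id == "C", size_category], "size3")
  expect_equal(sz[org_id == "D", size_category], "size4")
  # zero attributed patients -> category 1 (via roster)
  ros <- make_roster(c("A", "B", "C", "D", "E"),
                     pcp_id = paste0("D", 1:5))
  sz2 <- practice_size_category(att, roster = ros)
  expect_equal(sz2[org_id == "E", size_category], "size1")
  expect_equal(sz2[org_id == "E", n_patients], 0L)
})

test_that("attributed counts match an independent group-by oracle", {
  ds <- generate_claims_dataset(small_config(seed = 35))
  att <- attribution_table(ds$members, ds$claims, ds$roster, ds$crosswalk)
  sz <- practice_size_category(att)
  oracle <- as.data.frame(table(att[!is.na(org_id), paste(org_id, year)]))
  got <- sz[, stats::setNames(n_patients, paste(org_id, year))]
  expect_equal(unname(got[as.character(oracle$Var1)]), oracle$Freq)
})
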