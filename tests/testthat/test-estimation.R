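# Frame fixture for design-building tests
design_frame <- function(n = 60, msas = c("A", "B"), years = 2014:2016,
                         risk = NULL) {
  set.seed(4)
  data.table(
    member_id = sprintf("M%03d", 1:n), year = sample(years, n, TRUE),
    org_id = sample(c("P1", "P2", "L1"), n, TRUE),
    ownership = sample(c("physician_owned", "local_hospital_owned"), n, TRUE),
    specialty = sample(c("internal_medicine", "family_practice"), n, TRUE),
    age = sample(19:64, n, TRUE), sex = sample(c("F", "M"), n, TRUE),
    msa = sample(msas, n, TRUE), cdhp_flag = sample(c(TRUE, FALSE), n, TRUE),
    risk_score = if (is.null(risk)) rlnorm(n) else risk,
    wage_index = runif(n, 0.9, 1.1), size_category = "size1",
    total = rlnorm(n, 8, 1))
}

test_that("MSA-by-year cells expand to the expected indicator columns", {
  fr <- design_frame()
  d <- build_design(fr, "total", covariates = c("ownership", "msa_year"))
  # 2 MSAs x 3 years -> 6 cells -> 5 columns after reference drop
  expect_equal(sum(grepl("^msa_year_", colnames(d$X))), 5L)
  expect_equal(ncol(d$X), 1L + 1L + 5L)
})

test_that("degenerate blocks are dropped and logged", {
  fr <- design_frame(risk = rep(1, 60))  # single risk value
  d <- build_design(fr, "total")
  expect_false(any(grepl("^risk_", colnames(d$X))))
  expect_true(any(grepl("risk", d$notes)))
  # single-level practice size dropped too
  expect_false(any(grepl("^size_", colnames(d$X))))
})

test_that("design column count matches a formula-expansion oracle", {
  fr <- design_frame()
  d <- build_design(fr, "total",
                    covariates = c("ownership", "year", "age", "sex",
                                   "cdhp", "specialty", "msa_year"))
  oracle <- model.matrix(
    ~ I(ownership != "physician_owned") + factor(year) +
      cut(age, c(-Inf, 29, 39, 54, Inf)) + sex + cdhp_flag + specialty +
      factor(paste(msa, year)), data = fr)
  expect_equal(ncol(d$X), qr(d$X)$rank)          # full rank after drops
  expect_equal(qr(d$X)$rank, qr(oracle)$rank)    # same column space size
})

test_that("two-group log-link fit returns the closed-form log mean ratio", {
  y <- c(rep(c(10, 30, 50), 4), rep(c(100, 140), 6))
  hosp <- rep(c(0, 1), each = 12)
  des <- list(X = cbind(`(Intercept)` = 1, ownership_hospital = hosp),
              y = y, cluster = rep(sprintf("G%d", 1:6), each = 4),
              effect_cols = "ownership_hospital", dropped = character(),
              notes = character(), n_obs = 24L, n_clusters = 6L,
              response = "y")
  fit <- fit_glm_log(des)
  m1 <- mean(y[hosp == 1]); m0 <- mean(y[hosp == 0])
  expect_equal(unname(fit$coefficients["ownership_hospital"]), log(m1 / m0),
               tolerance = 1e-10)
  expect_equal(effect_estimate(fit)$point, 100 * (m1 / m0 - 1),
               tolerance = 1e-8)
})

test_that("GLM recovers exact coefficients on noiseless exponential data", {
  set.seed(2)
  X <- cbind(`(Intercept)` = 1, ownership_hospital = rbinom(40, 1, 0.5),
             x1 = rnorm(40))
  beta <- c(5, 0.058, 0.3)
  y <- exp(drop(X %*% beta))
  des <- list(X = X, y = y, cluster = sprintf("G%d", rep(1:8, 5)),
              effect_cols = "ownership_hospital", dropped = character(),
              notes = character(), n_obs = 40L, n_clusters = 8L,
              response = "y")
  fit <- fit_glm_log(des)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
})

test_that("all-zero and negative responses are rejected", {
  des <- make_cluster_design(response = "lognormal")
  des$y <- rep(0, des$n_obs)
  expect_error(fit_glm_log(des), "all-zero")
  des$y <- c(-1, rep(1, des$n_obs - 1))
  expect_error(fit_glm_log(des), "negative")
})

test_that("sandwich covariance equals a brute-force per-cluster oracle", {
  des <- make_cluster_design(n_clusters = 5, per_cluster = 8, seed = 6)
  fit <- fit_glm_log(des)
  # brute force: bread and per-cluster score outer products, from scratch
  X <- des$X
  mu <- exp(drop(X %*% fit$coefficients))
  bread <- solve(t(X) %*% diag(mu) %*% X)
  meat <- matrix(0, 2, 2)
  for (g in unique(des$cluster)) {
    i <- des$cluster == g
    s_g <- t(X[i, , drop = FALSE]) %*% (des$y[i] - mu[i])
    meat <- meat + s_g %*% t(s_g)
  }
  G <- 5
  v_oracle <- bread %*% meat %*% bread * G / (G - 1)
  expect_lt(max(abs(fit$vcov - v_oracle)), 1e-8)
})

test_that("sandwich reduces to HC0 with singleton clusters", {
  des <- make_cluster_design(n_clusters = 4, per_cluster = 5,
                             response = "linear", seed = 3)
  des$cluster <- sprintf("row%02d", seq_len(des$n_obs))  # one row per cluster
  des$n_clusters <- des$n_obs
  fit <- fit_linear_dollars(des, small_sample = FALSE)
  X <- des$X
  e <- des$y - drop(X %*% fit$coefficients)
  hc0 <- solve(crossprod(X)) %*% t(X) %*% diag(e^2) %*% X %*% solve(crossprod(X))
  expect_lt(max(abs(fit$vcov - hc0)), 1e-8)
})

test_that("OLS matches the normal equations and handles exact fits", {
  set.seed(11)
  X <- cbind(`(Intercept)` = 1, ownership_hospital = rbinom(20, 1, 0.5),
             x1 = rnorm(20))
  beta <- c(4000, 280, 55)
  y_exact <- drop(X %*% beta)
  des <- list(X = X, y = y_exact, cluster = sprintf("G%d", rep(1:5, 4)),
              effect_cols = "ownership_hospital", dropped = character(),
              notes = character(), n_obs = 20L, n_clusters = 5L,
              response = "y")
  fit <- fit_linear_dollars(des)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-9)
  expect_lt(max(abs(fit$se)), 1e-6)  # residuals 0 -> SEs 0
  # noisy response: coefficients match solve(X'X) X'y
  des$y <- y_exact + rnorm(20, 0, 300)
  fit2 <- fit_linear_dollars(des)
  expect_equal(unname(fit2$coefficients),
               unname(drop(solve(crossprod(X), crossprod(X, des$y)))),
               tolerance = 1e-9)
})

test_that("rank-deficient designs error naming the collinear columns", {
  des <- make_cluster_design(response = "linear")
  des$X <- cbind(des$X, ownership_copy = des$X[, "ownership_hospital"])
  expect_error(fit_linear_dollars(des), "ownership_copy")
})

test_that("dollar-scale effect is recovered over 200 replicates", {
  effect <- 280
  est <- vapply(1:200, function(i) {
    des <- make_cluster_design(n_clusters = 30, per_cluster = 30,
                               response = "linear", seed = 700 + i,
                               dollar_effect = effect)
    effect_estimate(fit_linear_dollars(des))$point
  }, 0.0)
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - effect), 2 * mc_se)
})

test_that("logistic fit reproduces the 2x2 cross-product odds ratio", {
  # a=40 exposed cases, b=10 exposed non-cases, c=20, d=30
  y <- c(rep(1, 40), rep(0, 10), rep(1, 20), rep(0, 30))
  x <- c(rep(1, 50), rep(0, 50))
  des <- list(X = cbind(`(Intercept)` = 1, ownership_hospital = x), y = y,
              cluster = sprintf("G%d", rep(1:10, 10)),
              effect_cols = "ownership_hospital", dropped = character(),
              notes = character(), n_obs = 100L, n_clusters = 10L,
              response = "y")
  fit <- fit_logistic_quality(des)
  expect_equal(effect_estimate(fit)$point, (40 * 30) / (10 * 20),
               tolerance = 1e-8)
  # matches R's iterative fit to 1e-6
  oracle <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients),
               unname(coef(oracle)), tolerance = 1e-6)
})

test_that("logistic separation raises an informative error", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- c(rep(0, 20), rep(1, 20))  # perfect separation
  des <- list(X = cbind(`(Intercept)` = 1, ownership_hospital = x), y = y,
              cluster = sprintf("G%d", rep(1:8, 5)),
              effect_cols = "ownership_hospital", dropped = character(),
              notes = character(), n_obs = 40L, n_clusters = 8L,
              response = "y")
  expect_error(fit_logistic_quality(des), "separation")
})

test_that("null logistic CIs cover OR = 1 in at least 93% of simulations", {
  covered <- vapply(1:200, function(i) {
    des <- make_cluster_design(n_clusters = 20, per_cluster = 20,
                               response = "binary", seed = 900 + i)
    ee <- effect_estimate(fit_logistic_quality(des))
    ee$ci_low <= 1 && ee$ci_high >= 1
  }, TRUE)
  expect_gte(mean(covered), 0.93)
})

test_that("decomposition reports zero price effect for identical responses", {
  des <- make_cluster_design(seed = 12)
  f1 <- fit_glm_log(des)
  f2 <- fit_glm_log(des)
  dec <- price_utilization_decomposition(f1, f2)
  expect_equal(dec[component == "price", point], 0)
  expect_equal(dec[component == "actual", point],
               dec[component == "utilization", point])
  # mismatched samples refuse to decompose
  des_small <- make_cluster_design(n_clusters = 4, seed = 13)
  expect_error(price_utilization_decomposition(f1, fit_glm_log(des_small)),
               "sample mismatch")
})

test_that("hospital-coefficient equality test runs on three-level fits", {
  ds <- generate_claims_dataset(small_config(seed = 88))
  est <- estimate_scenario(ds, standardize = FALSE,
                           covariates = c("ownership", "year", "age", "sex",
                                          "risk", "cdhp"))
  des3 <- build_design(est$frame, "total",
                       covariates = c("ownership", "year", "age", "sex",
                                      "risk", "cdhp"),
                       ownership_coding = "three_level")
  fit3 <- fit_glm_log(des3)
  expect_length(fit3$effect_cols, 2L)
  eq <- test_hospital_equality(fit3)
  expect_true(eq$p_value >= 0 && eq$p_value <= 1)
  expect_equal(eq$df, fit3$n_clusters - 1L)
})

test_that("sensitivity specification changes sign-stable, CI-overlapping effects", {
  cfg <- replicate_config(seed = 2024, n_members = 3000)
  ds <- generate_claims_dataset(cfg)
  est <- estimate_scenario(ds, standardize = FALSE)
  primary <- effect_estimate(est$actual)
  # deciles of practice size and quadratic age instead of categories
  att <- est$attribution
  sizes10 <- practice_size_category(att, roster = ds$roster, n_bins = 10L)
  fr <- build_analysis_frame(att, ds$members, ds$wage_index, sizes10,
                             est$frame[, .(member_id, year, total)])
  des <- build_design(fr, "total", age_spec = "quadratic")
  alt <- effect_estimate(fit_glm_log(des))
  expect_equal(sign(alt$point), sign(primary$point))
  expect_true(alt$ci_low <= primary$ci_high &&
                primary$ci_low <= alt$ci_high)
})
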