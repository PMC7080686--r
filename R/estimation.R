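#' Assemble the member-year analysis frame
#'
#' Joins attributed member-years with member characteristics, the wage
#' index, practice-size categories and (optionally) spending records into
#' one flat table for model building. Errors if any attributed member-year
#' cannot be joined.
#'
#' @param attribution attribution table; only rows with an `org_id` enter.
#' @param members member-year table (`age`, `sex`, `msa`, `cdhp_flag`,
#'   `risk_score`).
#' @param wage_index table `msa`, `year`, `wage_index`.
#' @param practice_sizes output of [practice_size_category()].
#' @param spend optional spending table ([annual_spend_table()]) merged on
#'   member-year.
#' @return data.table, one row per attributed member-year.
#' @export
build_analysis_frame <- function(attribution, members, wage_index,
                                 practice_sizes, spend = NULL) {
  att <- data.table::as.data.table(attribution)
  att <- att[!is.na(org_id),
             .(member_id, year, org_id, ownership, specialty)]
  mem <- data.table::as.data.table(members)
  fr <- merge(att, mem, by = c("member_id", "year"), all.x = TRUE,
              sort = FALSE)
  if (anyNA(fr$age)) {
    bad <- fr[is.na(age), paste(member_id, year, sep = "/")]
    stop("member-years missing from members table: ",
         paste(head(bad, 5), collapse = ", "))
  }
  fr[data.table::as.data.table(wage_index), on = c("msa", "year"),
     wage_index := i.wage_index]
  if (anyNA(fr$wage_index)) {
    stop("wage index missing for some MSA-years: ",
         paste(unique(fr[is.na(wage_index), paste(msa, year)]), collapse = ", "))
  }
  fr[data.table::as.data.table(practice_sizes), on = c("org_id", "year"),
     size_category := i.size_category]
  if (anyNA(fr$size_category)) {
    stop("practice size missing for organizations: ",
         paste(unique(fr[is.na(size_category), org_id]), collapse = ", "))
  }
  if (!is.null(spend)) {
    sp <- data.table::as.data.table(spend)
    fr <- merge(fr, sp, by = c("member_id", "year"), all.x = TRUE,
                sort = FALSE)
    if (anyNA(fr$total)) {
      bad <- fr[is.na(total), paste(member_id, year, sep = "/")]
      stop("spending records missing for member-years: ",
           paste(head(bad, 5), collapse = ", "))
    }
  }
  fr[]
}

drop_reference <- function(f, prefix) {
  f <- factor(f)
  if (nlevels(f) < 2L) return(NULL)
  m <- model.matrix(~f)[, -1L, drop = FALSE]
  colnames(m) <- paste0(prefix, levels(f)[-1L])
  m
}

#' Build a regression design from an analysis frame
#'
#' Constructs the covariate matrix used throughout: ownership indicator(s),
#' year indicators, age bands 19-29/30-39/40-54/55-64 (or age + age^2),
#' sex, risk-score decile indicators (cut points computed on this sample),
#' CDHP flag, wage index and its square, practice-size category indicators,
#' attributed-PCP specialty indicators, and MSA-by-year interaction cells.
#' Reference levels (physician-owned, youngest age band, first year, first
#' MSA, first levels otherwise) are dropped, then any remaining linearly
#' dependent columns are removed (e.g. the wage index is constant within
#' MSA-year cells, so the MSA-year block loses aliased columns); all drops
#' are recorded in the returned book-keeping.
#'
#' @param frame output of [build_analysis_frame()] (optionally merged with
#'   quality records).
#' @param response name of the response column in `frame`.
#' @param covariates subset of `c("ownership","year","age","sex","risk",
#'   "cdhp","wage","size","specialty","msa_year")` to include.
#' @param ownership_coding `"pooled"` (hospital-owned combined, the primary
#'   contrast) or `"three_level"` (local and multi-hospital system coded
#'   separately).
#' @param age_spec `"bands"` or `"quadratic"` (sensitivity analysis).
#' @param risk_deciles number of risk-score quantile bins (default 10).
#' @return list with design matrix `X`, response `y`, `cluster` (attributed
#'   organization, constant across years), `effect_cols`, `dropped`
#'   (aliased columns), `notes` (degenerate blocks), `n_obs`, `n_clusters`.
#' @export
build_design <- function(frame, response,
                         covariates = c("ownership", "year", "age", "sex",
                                        "risk", "cdhp", "wage", "size",
                                        "specialty", "msa_year"),
                         ownership_coding = c("pooled", "three_level"),
                         age_spec = c("bands", "quadratic"),
                         risk_deciles = 10L) {
  ownership_coding <- match.arg(ownership_coding)
  age_spec <- match.arg(age_spec)
  fr <- data.table::as.data.table(frame)
  if (!response %in% names(fr)) stop("response column not found: ", response)
  y <- fr[[response]]
  notes <- character()
  blocks <- list(`(Intercept)` = matrix(1, nrow(fr), 1,
                                        dimnames = list(NULL, "(Intercept)")))
  effect_cols <- character()
  for (cv in covariates) {
    b <- switch(cv,
      ownership = {
        if (ownership_coding == "pooled") {
          m <- cbind(ownership_hospital =
                       as.numeric(fr$ownership != "physician_owned"))
          effect_cols <- "ownership_hospital"
          m
        } else {
          f <- factor(fr$ownership, levels = ownership_levels())
          m <- drop_reference(droplevels(f), "ownership_")
          effect_cols <- colnames(m)
          m
        }
      },
      year = drop_reference(fr$year, "year_"),
      age = {
        if (age_spec == "bands") {
          band <- cut(fr$age, c(-Inf, 29, 39, 54, Inf),
                      labels = c("19_29", "30_39", "40_54", "55_64"))
          drop_reference(band, "age_")
        } else {
          cbind(age = fr$age, age_sq = fr$age^2)
        }
      },
      sex = drop_reference(fr$sex, "sex_"),
      risk = {
        qs <- unique(quantile(fr$risk_score,
                              probs = seq(0, 1, length.out = risk_deciles + 1)))
        if (length(qs) < 3L) {
          notes <- c(notes, "risk deciles degenerate; block dropped")
          NULL
        } else {
          if (length(qs) < risk_deciles + 1L) {
            notes <- c(notes, sprintf(
              "risk cut points not unique; %d bins used", length(qs) - 1L))
          }
          dec <- cut(fr$risk_score, qs, include.lowest = TRUE,
                     labels = paste0("d", seq_len(length(qs) - 1L)))
          drop_reference(dec, "risk_")
        }
      },
      cdhp = cbind(cdhp = as.numeric(fr$cdhp_flag)),
      wage = cbind(wage_index = fr$wage_index,
                   wage_index_sq = fr$wage_index^2),
      size = drop_reference(fr$size_category, "size_"),
      specialty = drop_reference(fr$specialty, "specialty_"),
      msa = drop_reference(fr$msa, "msa_"),
      msa_year = drop_reference(paste(fr$msa, fr$year, sep = "_"),
                                "msa_year_"),
      stop("unknown covariate block: ", cv)
    )
    if (is.null(b)) {
      if (cv != "risk") {
        notes <- c(notes, sprintf("block `%s` degenerate (single level); dropped", cv))
      }
      next
    }
    blocks[[cv]] <- b
  }
  X <- do.call(cbind, blocks)
  qrx <- qr(X)
  dropped <- character()
  if (qrx$rank < ncol(X)) {
    keep_idx <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(X)[-keep_idx]
    if (any(effect_cols %in% dropped)) {
      stop("ownership effect column(s) aliased with other covariates: ",
           paste(intersect(effect_cols, dropped), collapse = ", "))
    }
    X <- X[, sort(keep_idx), drop = FALSE]
  }
  cluster <- if ("org_id" %in% names(fr)) fr$org_id else
    rep("all", nrow(fr))
  list(X = X, y = y, cluster = cluster, effect_cols = effect_cols,
       dropped = dropped, notes = notes, n_obs = nrow(X),
       n_clusters = length(unique(cluster)), response = response)
}

#' Cluster-robust (CR0) sandwich covariance
#'
#' `vcov = B (sum_g s_g s_g') B` with `B` the inverse expected-information
#' bread and `s_g` the summed score contributions of cluster `g`, times a
#' `G/(G-1)` small-sample factor when `small_sample` is `TRUE`. With one
#' observation per cluster and the factor off this is exactly HC0.
#'
#' @param X design matrix.
#' @param resid working residuals `y - mu` (score residuals).
#' @param w_info information weights (`1` for OLS, `mu` for log-link
#'   quasi-Poisson, `p(1-p)` for logistic).
#' @param cluster cluster id vector.
#' @param small_sample apply the `G/(G-1)` factor?
#' @return covariance matrix of the coefficients.
#' @export
cluster_vcov <- function(X, resid, w_info, cluster, small_sample = TRUE) {
  S <- rowsum(X * resid, group = cluster)   # per-cluster score sums
  G <- nrow(S)
  # factored form B S' S B = (B S')(B S')': positive semi-definite by
  # construction. Solving through the QR factor of sqrt(w) X (rather than
  # forming X'WX) keeps the condition number at its square root.
  qx <- qr(X * sqrt(w_info))
  if (qx$rank < ncol(X)) {
    stop("information matrix is singular; columns: ",
         paste(colnames(X)[-qx$pivot[seq_len(qx$rank)]], collapse = ", "))
  }
  R <- qr.R(qx)
  piv <- qx$pivot
  tmp <- backsolve(R, backsolve(R, t(S)[piv, , drop = FALSE],
                                transpose = TRUE))
  BSt <- tmp
  BSt[piv, ] <- tmp
  v <- tcrossprod(BSt)
  if (small_sample) v <- v * G / (G - 1)
  dimnames(v) <- list(colnames(X), colnames(X))
  v
}

new_fit <- function(model, estimand, design, coef, vcov_mat, df, extra = list()) {
  se <- sqrt(diag(vcov_mat))
  tstat <- coef / se
  p <- 2 * pt(-abs(tstat), df)
  tab <- data.table::data.table(
    term = names(coef), estimate = coef, se = se, t = tstat, p_value = p)
  structure(c(list(model = model, estimand = estimand, coefficients = coef,
                   vcov = vcov_mat, se = se, df = df,
                   coef_table = tab, effect_cols = design$effect_cols,
                   n_obs = design$n_obs, n_clusters = design$n_clusters,
                   dropped = design$dropped, notes = design$notes),
              extra),
            class = "vertispend_fit")
}

#' @export
print.vertispend_fit <- function(x, ...) {
  cat(sprintf("<vertispend_fit: %s, %d obs, %d clusters, df = %d>\n",
              x$model, x$n_obs, x$n_clusters, x$df))
  print(effect_estimate(x))
  invisible(x)
}

#' Extract the ownership effect estimate from a fit
#'
#' Transforms the ownership coefficient(s) to the fit's estimand scale:
#' percent difference `100 (exp(b) - 1)` for log-link spending models,
#' dollars for linear models, odds ratio `exp(b)` for logistic models.
#' Confidence limits are the transformed endpoints of the t-interval with
#' `n_clusters - 1` degrees of freedom.
#'
#' @param fit a `vertispend_fit`.
#' @return data.table: `term`, `estimand`, `point`, `ci_low`, `ci_high`,
#'   `p_value`, `n_obs`, `n_clusters`.
#' @export
effect_estimate <- function(fit) {
  stopifnot(inherits(fit, "vertispend_fit"))
  b <- fit$coefficients[fit$effect_cols]
  se <- fit$se[fit$effect_cols]
  tc <- qt(0.975, fit$df)
  lo <- b - tc * se
  hi <- b + tc * se
  trans <- switch(fit$estimand,
                  percent_diff = function(z) 100 * (exp(z) - 1),
                  dollar_diff = identity,
                  odds_ratio = exp)
  data.table::data.table(
    term = fit$effect_cols, estimand = fit$estimand,
    point = trans(b), ci_low = trans(lo), ci_high = trans(hi),
    p_value = 2 * pt(-abs(b / se), fit$df),
    n_obs = fit$n_obs, n_clusters = fit$n_clusters)
}

#' Log-link quasi-likelihood spending model with clustered inference
#'
#' Fits a quasi-Poisson GLM (variance proportional to the mean, the standard
#' quasi-likelihood choice for non-negative spending with zeros; a
#' gamma-type variance `mu^2` is available via `variance`) by IRLS to a
#' relative-deviance tolerance of 1e-8 (max 100 iterations), then computes
#' the CR0 cluster-robust covariance by organization and t inference with
#' `n_clusters - 1` degrees of freedom. The ownership coefficient is
#' reported as a percent difference, `100 (exp(b) - 1)`.
#'
#' @param design output of [build_design()]; response must be non-negative
#'   (zeros permitted, the log-link quasi-likelihood keeps them in sample).
#' @param variance `"mu"` (quasi-Poisson) or `"mu2"` (gamma-type).
#' @param small_sample apply the `G/(G-1)` cluster correction.
#' @return a `vertispend_fit` with estimand `percent_diff`.
#' @export
fit_glm_log <- function(design, variance = c("mu", "mu2"),
                        small_sample = TRUE) {
  variance <- match.arg(variance)
  y <- design$y
  X <- design$X
  if (any(y < 0)) stop("negative response; spending must be >= 0")
  if (all(y == 0)) stop("all-zero response; no model can be fit")
  fam <- if (variance == "mu") quasipoisson(link = "log") else
    statmod_gamma_quasi()
  fit <- glm.fit(X, y, family = fam,
                 control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    stop(sprintf(paste0("log-link quasi-likelihood fit did not converge in ",
                        "%d iterations (deviance %.6g)"),
                 fit$iter, fit$deviance))
  }
  mu <- fit$fitted.values
  w_info <- if (variance == "mu") mu else rep(1, length(mu))
  resid <- if (variance == "mu") y - mu else (y - mu) / mu
  v <- cluster_vcov(X, resid, w_info, design$cluster, small_sample)
  df <- design$n_clusters - 1L
  new_fit("glm_log", "percent_diff", design, fit$coefficients, v, df,
          extra = list(fitted = mu, deviance = fit$deviance,
                       iterations = fit$iter))
}

# quasi family with gamma variance mu^2 and log link (no shape estimation)
statmod_gamma_quasi <- function() {
  fam <- quasipoisson(link = "log")
  fam$variance <- function(mu) mu^2
  fam$family <- "quasi_gamma"
  fam
}

#' Linear spending model in dollars with clustered inference
#'
#' Ordinary least squares with the same CR0 cluster-robust covariance and
#' t(`n_clusters - 1`) inference as the log-link model; the ownership
#' coefficient is an adjusted dollar difference.
#'
#' @inheritParams fit_glm_log
#' @return a `vertispend_fit` with estimand `dollar_diff`.
#' @export
fit_linear_dollars <- function(design, small_sample = TRUE) {
  X <- design$X
  y <- design$y
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[-qrx$pivot[seq_len(qrx$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  resid <- y - drop(X %*% beta)
  v <- cluster_vcov(X, resid, rep(1, nrow(X)), design$cluster, small_sample)
  new_fit("linear_dollars", "dollar_diff", design, beta, v,
          design$n_clusters - 1L, extra = list(residuals = resid))
}

#' Logistic quality model with clustered inference
#'
#' Maximum-likelihood logistic regression on eligible member-years, with
#' CR0 cluster-robust covariance by organization; the ownership coefficient
#' is reported as an odds ratio. Separation (fitted probabilities pinned at
#' 0/1 with a diverging coefficient) raises an error rather than returning
#' a meaningless estimate; penalized fits are deliberately not applied by
#' default.
#'
#' @inheritParams fit_glm_log
#' @return a `vertispend_fit` with estimand `odds_ratio`.
#' @export
fit_logistic_quality <- function(design, small_sample = TRUE) {
  X <- design$X
  y <- as.numeric(design$y)
  if (!all(y %in% c(0, 1))) stop("logistic response must be binary 0/1")
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  mu <- fit$fitted.values
  if ((any(mu < 1e-8) || any(mu > 1 - 1e-8)) &&
      max(abs(fit$coefficients)) > 12) {
    stop("separation detected in logistic fit; consider collapsing ",
         "covariates (penalization is off by default)")
  }
  if (!fit$converged) stop("logistic fit did not converge")
  v <- cluster_vcov(X, y - mu, mu * (1 - mu), design$cluster, small_sample)
  new_fit("logistic", "odds_ratio", design, fit$coefficients, v,
          design$n_clusters - 1L, extra = list(fitted = mu))
}

#' Wald test that the two hospital-ownership coefficients are equal
#'
#' For a three-level ownership fit, tests equality of the local-hospital and
#' multi-hospital-system coefficients — the stated justification for pooling
#' them in the primary contrast.
#'
#' @param fit a `vertispend_fit` from a `three_level` design.
#' @return list with `diff`, `se`, `t`, `p_value`, `df`.
#' @export
test_hospital_equality <- function(fit) {
  ec <- fit$effect_cols
  if (length(ec) != 2L) {
    stop("fit does not have two hospital ownership coefficients")
  }
  d <- fit$coefficients[ec[1]] - fit$coefficients[ec[2]]
  se <- sqrt(fit$vcov[ec[1], ec[1]] + fit$vcov[ec[2], ec[2]] -
               2 * fit$vcov[ec[1], ec[2]])
  t <- d / se
  list(diff = unname(d), se = unname(se), t = unname(t),
       p_value = unname(2 * pt(-abs(t), fit$df)), df = fit$df)
}

#' Price/utilization decomposition of the spending differential
#'
#' Compares the adjusted percent difference estimated on actual spending
#' with the one estimated on median-price-standardized spending (identical
#' samples and designs). The standardized effect is the utilization effect;
#' the price effect is the difference of the two percentage-point
#' estimates.
#'
#' @param actual_fit,standardized_fit `vertispend_fit`s with estimand
#'   `percent_diff` on the same sample.
#' @return data.table with rows `actual`, `utilization`, `price`.
#' @export
price_utilization_decomposition <- function(actual_fit, standardized_fit) {
  if (actual_fit$n_obs != standardized_fit$n_obs ||
      actual_fit$n_clusters != standardized_fit$n_clusters) {
    stop("sample mismatch: actual and standardized fits must use identical ",
         "samples and designs")
  }
  a <- effect_estimate(actual_fit)
  s <- effect_estimate(standardized_fit)
  data.table::data.table(
    component = c("actual", "utilization", "price"),
    point = c(a$point[1], s$point[1], a$point[1] - s$point[1]),
    ci_low = c(a$ci_low[1], s$ci_low[1], NA_real_),
    ci_high = c(a$ci_high[1], s$ci_high[1], NA_real_),
    p_value = c(a$p_value[1], s$p_value[1], NA_real_))
}
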