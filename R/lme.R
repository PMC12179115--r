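#' Random-intercept mixed-effects model of hemispheric DVR
#'
#' Fits, by REML, the linear mixed model
#' `DVR ~ hemisphere + age + sex + handedness + centre +
#' centre:hemisphere + (1 | subject)` on a long table with one row per
#' subject and hemisphere.  Subjects with unknown handedness are excluded
#' before fitting (their handedness cannot enter the model).  Categorical
#' reference levels are fixed so estimate signs read as right-vs-left,
#' male-vs-female, right-vs-left-handed and Turku-vs-Manchester.
#' Satterthwaite degrees of freedom (via lmerTest) give the p-values, with a
#' Wald normal approximation as fallback; 95% CIs are Wald.  The df method
#' used is recorded in the result.
#'
#' @param data data frame with columns `subject_id`, `hemisphere`
#'   (`"left"`/`"right"`), `DVR`, and -- unless dropped via `covariates` --
#'   `age`, `sex`, `handedness`, `centre`.
#' @param covariates character vector of fixed-effect terms beyond
#'   `hemisphere`; default the full battery.  Use `character(0)` for the
#'   hemisphere-only model (whose estimate, in a balanced design, is exactly
#'   the mean paired difference).
#' @param response response column name.
#' @return an object of class `"lme_asym"`: data frame `fixed` (term,
#'   estimate, se, df, ci_lo, ci_hi, p), `varcomp` (random-intercept and
#'   residual variance), `n_subjects`, `n_rows`, `n_excluded`, `df_method`,
#'   and the underlying `model`.
#' @export
fit_lme_random_intercept <- function(data,
                                     covariates = c("age", "sex",
                                                    "handedness", "centre",
                                                    "centre:hemisphere"),
                                     response = "DVR") {
  need <- c("subject_id", "hemisphere", response,
            setdiff(unique(unlist(strsplit(covariates, ":"))), "hemisphere"))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))

  n_excl <- 0
  if ("handedness" %in% need) {
    drop <- data$handedness == "unknown" | is.na(data$handedness)
    n_excl <- length(unique(data$subject_id[drop]))
    data <- data[!drop, , drop = FALSE]
  }
  if (anyNA(data[, need])) stop("missing covariate values after exclusion")
  if (length(unique(data$subject_id)) < 10)
    stop("need at least 10 subjects for the mixed model")

  data$hemisphere <- factor(data$hemisphere, levels = c("left", "right"))
  if ("sex" %in% need) data$sex <- factor(data$sex, levels = c("female", "male"))
  if ("handedness" %in% need)
    data$handedness <- factor(data$handedness, levels = c("left", "right"))
  if ("centre" %in% need) {
    lev <- unique(as.character(data$centre))
    lev <- c(intersect("Manchester", lev), setdiff(lev, "Manchester"))
    data$centre <- factor(data$centre, levels = lev)
  }
  # singular designs: every requested categorical term needs >= 2 levels
  for (term in c("hemisphere", intersect(covariates, c("sex", "handedness", "centre")))) {
    if (nlevels(droplevels(data[[term]])) < 2)
      stop("singular design: term `", term, "` has a single level")
  }
  if ("centre:hemisphere" %in% covariates &&
      nlevels(droplevels(data$centre)) < 2)
    stop("singular design: term `centre:hemisphere` needs two centres")

  fml <- stats::reformulate(c("hemisphere", covariates, "(1 | subject_id)"),
                            response = response)
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  smry <- tryCatch(summary(fit, ddf = "Satterthwaite"), error = function(e) NULL)
  co <- if (!is.null(smry) && ncol(stats::coef(smry)) >= 5) {
    df_method <- "Satterthwaite"
    stats::coef(smry)
  } else {
    df_method <- "Wald-normal"
    cc <- summary(fit)$coefficients
    cbind(cc[, 1:2, drop = FALSE], df = Inf, `t value` = cc[, 1] / cc[, 2],
          `Pr(>|t|)` = 2 * stats::pnorm(-abs(cc[, 1] / cc[, 2])))
  }
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  dfv <- unname(co[, "df"])
  tcrit <- ifelse(is.finite(dfv) & dfv > 0, stats::qt(0.975, dfv), 1.96)
  fixed <- data.frame(term = rownames(co), estimate = unname(est),
                      se = unname(se), df = dfv,
                      ci_lo = unname(est - tcrit * se),
                      ci_hi = unname(est + tcrit * se),
                      p = unname(co[, ncol(co)]))
  rownames(fixed) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(subject = vc$vcov[vc$grp == "subject_id"],
               residual = vc$vcov[vc$grp == "Residual"])
  structure(list(fixed = fixed, varcomp = varcomp,
                 n_subjects = length(unique(data$subject_id)),
                 n_rows = nrow(data), n_excluded = n_excl,
                 df_method = df_method, model = fit),
            class = "lme_asym")
}

#' @export
print.lme_asym <- function(x, digits = 4, ...) {
  cat("Random-intercept LME of hemispheric DVR (REML, ", x$df_method,
      " df)\n", sep = "")
  cat("  ", x$n_subjects, " subjects, ", x$n_rows, " rows",
      if (x$n_excluded > 0)
        paste0(" (", x$n_excluded, " excluded: unknown handedness)"),
      "\n", sep = "")
  df <- x$fixed
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  cat(sprintf("  variance: subject %.3g, residual %.3g\n",
              x$varcomp["subject"], x$varcomp["residual"]))
  invisible(x)
}

#' @export
coef.lme_asym <- function(object, ...) {
  stats::setNames(object$fixed$estimate, object$fixed$term)
}

#' Per-region hemisphere effects
#'
#' Fits the full random-intercept model of [fit_lme_random_intercept]
#' separately to each region's left/right DVR and returns one row per
#' region: the hemisphere (right vs left) estimate with its 95% CI and
#' p-value.
#'
#' @param data long table with a `region` column in addition to the columns
#'   of [fit_lme_random_intercept].
#' @inheritParams fit_lme_random_intercept
#' @return data frame: region, estimate, ci_lo, ci_hi, p.
#' @export
fit_lme_by_region <- function(data,
                              covariates = c("age", "sex", "handedness",
                                             "centre", "centre:hemisphere"),
                              response = "DVR") {
  regions <- unique(data$region)
  rows <- lapply(regions, function(rg) {
    fit <- fit_lme_random_intercept(data[data$region == rg, , drop = FALSE],
                                    covariates = covariates,
                                    response = response)
    h <- fit$fixed[fit$fixed$term == "hemisphereright", ]
    data.frame(region = rg, estimate = h$estimate, se = h$se,
               ci_lo = h$ci_lo, ci_hi = h$ci_hi, p = h$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
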