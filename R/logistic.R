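#' Logistic regression for out-of-province cancer diagnosis
#'
#' Maximum-likelihood logistic regression of the out-of-province indicator
#' (1 = cancer diagnosed outside the province of HIV care) on age at
#' diagnosis (continuous, years), gender (reference Female), race (Black
#' vs non-Black, reference non-Black) and cancer type (reference
#' `"cervix"`, the most common type). Odds ratios are exponentiated
#' coefficients with Wald 95% confidence intervals. Cancer types observed
#' fewer than `min_level_count` times, or with an empty outcome cell (which
#' would separate the likelihood), are pooled into `"other"`; if complete
#' separation remains, it is raised as an error naming the offending terms.
#'
#' @param cases A case tibble from [build_cases()].
#' @param covariates Character subset of
#'   `c("age", "gender", "race", "cancer_type")`.
#' @param min_level_count Minimum cases per retained cancer-type level.
#' @return An object of class `hcm_logistic`; see [tidy.hcm_logistic()].
#' @export
logistic_fit <- function(cases,
                         covariates = c("age", "gender", "race", "cancer_type"),
                         min_level_count = 20) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  df <- tibble::tibble(out = as.integer(cases$out_of_province))
  if ("age" %in% covariates) df$age <- as.numeric(cases$age_at_diagnosis)
  if ("gender" %in% covariates) {
    df$gender <- factor(ifelse(cases$sex == "M", "Male", "Female"),
                        levels = c("Female", "Male"))
  }
  if ("race" %in% covariates) {
    df$race <- factor(ifelse(cases$race == "Black", "Black", "non-Black"),
                      levels = c("non-Black", "Black"))
  }
  if ("cancer_type" %in% covariates) {
    ct <- cases$cancer_type
    cells <- table(ct, df$out)
    sparse <- rownames(cells)[rowSums(cells) < min_level_count |
                                apply(cells, 1, min) == 0]
    ct[ct %in% setdiff(sparse, "cervix")] <- "other"
    present <- intersect(cancer_type_labels(), unique(ct))
    df$cancer_type <- droplevels(factor(ct, levels = union("cervix", present)))
    if (dplyr::n_distinct(ct) < 2) df$cancer_type <- NULL
  }
  if (length(unique(df$out)) < 2) {
    stop("outcome is single-class: every case is ",
         if (all(df$out == 1)) "outside" else "within",
         " the province of HIV care", call. = FALSE)
  }
  fit <- glm(out ~ ., data = df, family = binomial())
  co <- coef(fit)
  if (!fit$converged || any(abs(co[-1]) > 15, na.rm = TRUE)) {
    bad <- names(co[-1])[abs(co[-1]) > 15]
    stop("logistic fit did not converge cleanly",
         if (length(bad)) paste0(" (possible complete separation in: ",
                                 paste(bad, collapse = ", "), ")"),
         call. = FALSE)
  }
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(0.975)
  result <- tibble::tibble(
    term = names(co),
    odds_ratio = exp(unname(co)),
    ci_low = exp(unname(co) - z * se),
    ci_high = exp(unname(co) + z * se),
    p_value = 2 * pnorm(-abs(unname(co) / se))
  )
  result <- result[result$term != "(Intercept)", ]
  structure(
    list(result = result, fit = fit, n = nrow(df),
         reference_levels = c(gender = "Female", race = "non-Black",
                              cancer_type = "cervix")),
    class = "hcm_logistic"
  )
}

#' @export
print.hcm_logistic <- function(x, ...) {
  cat("<hcm_logistic> out-of-province diagnosis,", x$n, "cases\n")
  print(x$result, n = Inf)
  invisible(x)
}

#' Tidy and summarise a fitted out-of-province model
#'
#' `tidy()` returns one row per model term with the odds ratio, Wald 95%
#' confidence interval and p-value; `glance()` returns one-row model-level
#' fit statistics.
#'
#' @param x An `hcm_logistic` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hcm_logistic <- function(x, ...) {
  x$result
}

#' @rdname tidy.hcm_logistic
#' @export
glance.hcm_logistic <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    converged = x$fit$converged,
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    aic = x$fit$aic
  )
}
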