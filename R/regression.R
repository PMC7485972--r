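## Fit a random-intercept LMM (REML) and extract slope, Wald chi-square and
## the variance-component R-squared decomposition. The R2 formulas are
## implemented here: with sigma2_f the variance of the fixed-effect linear
## predictor, sigma2_alpha the random-intercept variance and sigma2_eps the
## residual variance,
##   R2_marginal    = sigma2_f / (sigma2_f + sigma2_alpha + sigma2_eps)
##   R2_conditional = (sigma2_f + sigma2_alpha) / (same denominator).
fit_lmm_r2 <- function(formula, data, term) {
  # degenerate inputs (e.g. zero residual variance) trip lme4's convergence
  # checks; the variance components are still usable, so warnings are muted
  # and singularity is reported through the flag instead
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lme4::lmer(formula, data = data,
                                                 REML = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(mixed_model_result(flag = "fit_failed"))
  }
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  slope <- unname(fe[term])
  slope_se <- unname(se[term])
  wald <- (slope / slope_se)^2
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_alpha <- vc$vcov[vc$grp != "Residual"][1L]
  sigma2_eps <- vc$vcov[vc$grp == "Residual"]
  X <- stats::model.matrix(fit)
  sigma2_f <- var(as.vector(X %*% fe))
  tot <- sigma2_f + sigma2_alpha + sigma2_eps
  mixed_model_result(
    slope = slope, slope_se = slope_se, wald_chi2 = wald, df = 1L,
    p = stats::pchisq(wald, df = 1, lower.tail = FALSE),
    r2_marginal = sigma2_f / tot,
    r2_conditional = (sigma2_f + sigma2_alpha) / tot,
    sigma2_f = sigma2_f, sigma2_alpha = sigma2_alpha, sigma2_eps = sigma2_eps,
    n_obs = nrow(X),
    flag = if (lme4::isSingular(fit)) "singular" else "ok")
}

mixed_model_result <- function(slope = NA_real_, slope_se = NA_real_,
                               wald_chi2 = NA_real_, df = 1L, p = NA_real_,
                               r2_marginal = NA_real_,
                               r2_conditional = NA_real_,
                               sigma2_f = NA_real_, sigma2_alpha = NA_real_,
                               sigma2_eps = NA_real_, n_obs = 0L,
                               flag = "ok") {
  structure(
    list(slope = slope, slope_se = slope_se, wald_chi2 = wald_chi2, df = df,
         p = p, r2_marginal = r2_marginal, r2_conditional = r2_conditional,
         sigma2_f = sigma2_f, sigma2_alpha = sigma2_alpha,
         sigma2_eps = sigma2_eps, n_obs = n_obs, flag = flag),
    class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  if (x$flag %in% c("empty_input", "fit_failed", "degenerate")) {
    cat(sprintf("<mixed_model_result> %s\n", x$flag))
    return(invisible(x))
  }
  cat(sprintf(paste0("<mixed_model_result> slope = %.4g (SE %.3g), ",
                     "Wald chi2 = %.4g (df = %d, P = %.3g)\n",
                     "  R2 marginal = %.3f, R2 conditional = %.3f (n = %d%s)\n"),
              x$slope, x$slope_se, x$wald_chi2, x$df, x$p,
              x$r2_marginal, x$r2_conditional, x$n_obs,
              if (x$flag == "singular") ", singular fit" else ""))
  invisible(x)
}

#' Mixed-effects model of feasibility contribution on vulnerability
#'
#' Linear mixed model (REML) with feasibility contribution as the response,
#' vulnerability as a fixed effect and network identity as a random
#' intercept. Reports the slope, its standard error, the Wald chi-square
#' (squared slope t, df = 1) and the marginal/conditional R-squared computed
#' from the variance components.
#'
#' Excluded links (no `I_percent`) are dropped. A degenerate input (fewer
#' than 2 networks, no usable links, or zero response variance) yields a
#' flagged result rather than an error.
#'
#' @param link_table a populated link table.
#' @return A `mixed_model_result`.
#' @export
fit_vulnerability_model <- function(link_table) {
  use <- !is.na(link_table$I_percent) & !is.na(link_table$V) &
    !isTRUE_vec(link_table$excluded)
  dat <- link_table[use, , drop = FALSE]
  if (nrow(dat) < 3L || length(unique(dat$network_id)) < 2L) {
    return(mixed_model_result(flag = "empty_input"))
  }
  if (var(dat$I_percent) == 0 || var(dat$V) == 0) {
    return(mixed_model_result(flag = "degenerate", n_obs = nrow(dat)))
  }
  fit_lmm_r2(I_percent ~ V + (1 | network_id), dat, "V")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Diagnostic mixed-effects regressions
#'
#' Companion fits used to decompose the vulnerability signal, all with a
#' network random intercept: feasibility contribution on standardised
#' generalisation, feasibility contribution on standardised frequency, and
#' log(generalisation) on log(frequency). The last fit's marginal R-squared
#' is reported as the share of generalisation variance explained by
#' frequency (as a percentage).
#'
#' @param link_table a populated link table.
#' @return List with elements `contribution_vs_generalisation`,
#'   `contribution_vs_frequency`, `generalisation_vs_frequency` (each a
#'   `mixed_model_result`) and `frequency_variance_share_percent`.
#' @export
diagnostic_regressions <- function(link_table) {
  use <- !is.na(link_table$I_percent) & !isTRUE_vec(link_table$excluded)
  dat <- link_table[use, , drop = FALSE]
  m_gen <- if (nrow(dat) >= 3L) {
    fit_lmm_r2(I_percent ~ D_std + (1 | network_id), dat, "D_std")
  } else mixed_model_result(flag = "empty_input")
  m_frq <- if (nrow(dat) >= 3L) {
    fit_lmm_r2(I_percent ~ f_std + (1 | network_id), dat, "f_std")
  } else mixed_model_result(flag = "empty_input")
  all_links <- link_table[!is.na(link_table$D_raw) & link_table$weight > 0, ,
                          drop = FALSE]
  all_links$log_gen <- log(all_links$D_raw)
  all_links$log_frq <- log(all_links$weight)
  m_ff <- if (nrow(all_links) >= 3L) {
    fit_lmm_r2(log_gen ~ log_frq + (1 | network_id), all_links, "log_frq")
  } else mixed_model_result(flag = "empty_input")
  list(contribution_vs_generalisation = m_gen,
       contribution_vs_frequency = m_frq,
       generalisation_vs_frequency = m_ff,
       frequency_variance_share_percent = 100 * m_ff$r2_marginal)
}
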