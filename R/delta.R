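#' Estimate the mutualistic trade-off delta
#'
#' The trade-off discounts per-partner mutualistic benefit with degree
#' (`gamma_ij = gamma0 * L_ij / d_i^delta`). It is estimated from observed
#' link frequencies by two linear regressions fitted jointly on the whole
#' dataset with a common slope and guild-specific intercepts:
#' `log(f_ij / (d_i^P * d_j^A)) = a^P - delta * log(d_i^P)` for the plant
#' side, and the analogous equation with the animal degree as predictor for
#' the animal side. Each link therefore contributes two stacked observations.
#'
#' @param link_table a link table with `weight`, `d_plant`, `d_animal`.
#' @return Object of class `delta_regression`: list with `delta` (sign-
#'   flipped common slope), `intercept_plants`, `intercept_animals`, `n_obs`.
#' @export
estimate_delta <- function(link_table) {
  stopifnot(all(c("weight", "d_plant", "d_animal") %in% names(link_table)))
  if (nrow(link_table) < 3L) stop("too few links to estimate delta", call. = FALSE)
  if (any(link_table$weight <= 0) ||
      any(link_table$d_plant < 1) || any(link_table$d_animal < 1)) {
    stop("all links need positive weight and endpoint degrees >= 1",
         call. = FALSE)
  }
  y <- log(link_table$weight / (link_table$d_plant * link_table$d_animal))
  dat <- data.frame(
    y = c(y, y),
    x = c(log(link_table$d_plant), log(link_table$d_animal)),
    guild = rep(c("plant", "animal"), each = nrow(link_table)))
  if (max(dat$x) - min(dat$x) < .Machine$double.eps^0.5) {
    stop("delta is unidentifiable: no degree variation in the dataset",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ 0 + guild + x, data = dat)
  cf <- coef(fit)
  if (anyNA(cf)) stop("delta regression is rank deficient", call. = FALSE)
  structure(
    list(delta = unname(-cf[["x"]]),
         intercept_plants = unname(cf[["guildplant"]]),
         intercept_animals = unname(cf[["guildanimal"]]),
         n_obs = nrow(dat)),
    class = "delta_regression")
}

#' @export
print.delta_regression <- function(x, ...) {
  cat(sprintf("<delta_regression> delta = %.4f (a^P = %.3f, a^A = %.3f, n = %d)\n",
              x$delta, x$intercept_plants, x$intercept_animals, x$n_obs))
  invisible(x)
}
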