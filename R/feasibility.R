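#' Sample uniform directions on the unit sphere
#'
#' @param n number of directions.
#' @param s dimension.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return `n x s` matrix of unit row vectors.
#' @export
sample_directions <- function(n, s, seed = NULL) {
  draw <- function() {
    m <- matrix(rnorm(n * s), n, s)
    m / sqrt(rowSums(m^2))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

feasibility_estimate <- function(omega, estimator, n_directions, seed, se) {
  structure(
    list(omega = omega, estimator = estimator,
         n_directions = as.integer(n_directions),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         mc_standard_error = se),
    class = "feasibility_estimate")
}

#' @export
print.feasibility_estimate <- function(x, ...) {
  cat(sprintf("<feasibility_estimate> omega = %.6g (%s, %d directions, MC SE %.2g)\n",
              x$omega, x$estimator, x$n_directions, x$mc_standard_error))
  invisible(x)
}

#' Feasibility as a solid angle
#'
#' Fraction of directions drawn uniformly on the unit `S`-sphere that fall
#' inside the feasibility cone (`solve(B, r) > 0` componentwise), i.e. the
#' normalised solid angle of the set of intrinsic growth-rate vectors
#' compatible with positive abundances of all species.
#'
#' @param sys a [build_system()] result (`B` must be invertible).
#' @param n_directions Monte Carlo sample size.
#' @param seed optional integer seed.
#' @param directions optional pre-drawn direction matrix (rows = unit
#'   vectors); used for common-random-number comparisons.
#' @return A `feasibility_estimate` with `omega` in `[0, 1]` and
#'   `mc_standard_error = sqrt(omega * (1 - omega) / n)`.
#' @export
omega_solid_angle <- function(sys, n_directions = 10000L, seed = NULL,
                              directions = NULL) {
  B <- sys$B
  Binv <- tryCatch(solve(B), error = function(e)
    stop("interaction matrix is singular", call. = FALSE))
  if (is.null(directions)) {
    directions <- sample_directions(n_directions, nrow(B), seed)
  }
  n <- nrow(directions)
  X <- directions %*% t(Binv)
  omega <- mean(rowSums(X > 0) == ncol(X))
  feasibility_estimate(omega, "solid_angle", n, seed,
                       sqrt(omega * (1 - omega) / n))
}

#' Feasibility by perturbation from the structural center
#'
#' Mirrors the construction in which the center of the feasibility domain is
#' estimated analytically and its boundary probed by random perturbations:
#' for each sampled tangent direction the central growth-rate vector is
#' rotated along the great circle toward that direction, and the critical arc
#' angle `theta*` at which feasibility is first lost is found by bisection
#' (tolerance `angle_tol` radians; `pi` if feasibility never fails).
#'
#' Because the feasibility region on the sphere is geodesically convex and
#' contains the center, the sphere decomposes exactly in geodesic polar
#' coordinates around it: the fraction of sphere measure inside the region is
#' the average over tangent directions of
#' `G(theta*) = pbeta((1 - cos(theta*)) / 2, (S - 1) / 2, (S - 1) / 2)`,
#' the normalised cap integral of `sin^(S-2)`. `omega` is therefore the mean
#' of `G(theta*)` — the same feasibility volume that [omega_solid_angle()]
#' estimates, but with lower Monte Carlo variance (each direction contributes
#' a conditional expectation rather than a 0/1 hit). For `S = 2`, `G`
#' reduces to `theta*/pi`.
#'
#' @inheritParams omega_solid_angle
#' @param angle_tol bisection tolerance in radians.
#' @return A `feasibility_estimate` with `omega` in `[0, 1]`.
#' @export
omega_center_deviation <- function(sys, n_directions = 10000L, seed = NULL,
                                   directions = NULL, angle_tol = 1e-4) {
  B <- sys$B
  S <- nrow(B)
  Binv <- tryCatch(solve(B), error = function(e)
    stop("interaction matrix is singular", call. = FALSE))
  rc <- structural_center(sys)
  a <- as.vector(Binv %*% rc)
  if (any(a <= 0)) {
    stop("structural center is not feasible: degenerate cone", call. = FALSE)
  }
  if (is.null(directions)) {
    directions <- sample_directions(n_directions, S, seed)
  }
  n <- nrow(directions)
  # tangent components of the sampled directions at rc
  proj <- as.vector(directions %*% rc)
  V <- directions - outer(proj, rc)
  vnorm <- sqrt(rowSums(V^2))
  ok <- vnorm > 1e-12
  theta <- rep(pi, n)                    # directions parallel to rc never exit
  if (any(ok)) {
    Bv <- Binv %*% t(V[ok, , drop = FALSE] / vnorm[ok])   # S x m
    m <- ncol(Bv)
    # abundance path N(theta) = a*cos(theta) + Bv*sin(theta); feasible while
    # all components positive; positivity is lost once and never regained on
    # (0, pi], so bisection on the all-positive predicate is valid.
    feasible_at <- function(th, cols) {
      F <- outer(a, cos(th))[, seq_along(cols), drop = FALSE] +
        sweep(Bv[, cols, drop = FALSE], 2, sin(th), "*")
      colSums(F > 0) == S
    }
    lo <- numeric(m); hi <- rep(pi, m)
    at_pi <- feasible_at(rep(pi, m), seq_len(m))
    lo[at_pi] <- pi
    active <- which(!at_pi)
    while (length(active) > 0L) {
      mid <- (lo[active] + hi[active]) / 2
      feas <- feasible_at(mid, active)
      lo[active[feas]] <- mid[feas]
      hi[active[!feas]] <- mid[!feas]
      active <- active[(hi[active] - lo[active]) > angle_tol]
    }
    th <- (lo + hi) / 2
    th[at_pi] <- pi
    theta[ok] <- th
  }
  # geodesic-polar cap measure of each critical angle
  g <- stats::pbeta((1 - cos(theta)) / 2, (S - 1) / 2, (S - 1) / 2)
  feasibility_estimate(mean(g), "center_deviation", n, seed,
                       sd(g) / sqrt(n))
}

## Dispatch on estimator name with a shared direction sample.
estimate_omega <- function(sys, estimator, n_directions, seed, directions) {
  switch(estimator,
         solid_angle = omega_solid_angle(sys, n_directions, seed, directions),
         center_deviation = omega_center_deviation(sys, n_directions, seed,
                                                   directions),
         stop("unknown estimator: ", estimator, call. = FALSE))
}

#' Feasibility contribution of a single link
#'
#' The percent change in feasibility caused by removing the focal link:
#' `100 * Omega_O / Omega_R - 100`, where `Omega_O` is the feasibility of the
#' original network and `Omega_R` that of the network with the link removed
#' (degrees, and hence the mutualistic benefits of the remaining links, are
#' recomputed; `gamma0`, `delta`, `rho` are held fixed). Both feasibilities
#' are estimated with the same direction sample (common random numbers).
#' Positive values mean removal shrinks the feasibility domain.
#'
#' If removing the link would leave a species with no connections, the link
#' is flagged `excluded` and `I_percent` is `NA` (its contribution is not
#' defined by link removal alone).
#'
#' @param net a [bipartite_network()].
#' @param plant,animal species names identifying the focal link.
#' @param gamma0,delta,rho GLV parameters (fixed across the removal).
#' @param estimator `"solid_angle"` or `"center_deviation"`.
#' @param n_directions Monte Carlo sample size.
#' @param seed optional integer seed.
#' @param directions optional shared direction matrix.
#' @param omega_original optional precomputed `Omega_O` (must come from the
#'   same `directions`).
#' @return One-row data frame with `I_percent`, `excluded`, `omega_original`,
#'   `omega_removed`.
#' @export
feasibility_contribution <- function(net, plant, animal, gamma0, delta,
                                     rho = 0,
                                     estimator = c("solid_angle",
                                                   "center_deviation"),
                                     n_directions = 10000L, seed = NULL,
                                     directions = NULL,
                                     omega_original = NULL) {
  estimator <- match.arg(estimator)
  i <- match(plant, net$plant_names)
  j <- match(animal, net$animal_names)
  if (is.na(i) || is.na(j) || net$weights[i, j] <= 0) {
    stop("focal link not present in the network", call. = FALSE)
  }
  w2 <- net$weights
  w2[i, j] <- 0
  if (sum(w2[i, ] > 0) == 0 || sum(w2[, j] > 0) == 0) {
    return(data.frame(I_percent = NA_real_, excluded = TRUE,
                      omega_original = NA_real_, omega_removed = NA_real_))
  }
  S <- nrow(w2) + ncol(w2)
  if (is.null(directions)) directions <- sample_directions(n_directions, S, seed)
  if (is.null(omega_original)) {
    sysO <- build_system(net, glv_params(net, gamma0, delta, rho))
    omega_original <- estimate_omega(sysO, estimator, n_directions, seed,
                                     directions)$omega
  }
  netR <- bipartite_network(w2, paste0(net$network_id, "_removed"),
                            net$network_type)
  sysR <- build_system(netR, glv_params(netR, gamma0, delta, rho))
  omega_removed <- estimate_omega(sysR, estimator, n_directions, seed,
                                  directions)$omega
  if (omega_removed == 0) {
    stop("undefined contribution ratio: Omega_R estimated as 0 ",
         "(increase n_directions or use the center_deviation estimator)",
         call. = FALSE)
  }
  data.frame(I_percent = 100 * omega_original / omega_removed - 100,
             excluded = FALSE,
             omega_original = omega_original, omega_removed = omega_removed)
}

#' Per-link feasibility contributions for a whole network
#'
#' Orchestrates one network: finds the stability threshold on the original
#' topology, sets `gamma0` to half of it (held fixed across all removals),
#' estimates `Omega_O` once, then computes the contribution of every link
#' with a shared direction sample. Links whose removal would isolate a
#' species are flagged excluded.
#'
#' @param net a [bipartite_network()].
#' @param delta mutualistic trade-off.
#' @param rho within-guild interspecific competition.
#' @param estimator `"solid_angle"` or `"center_deviation"`.
#' @param n_directions Monte Carlo sample size.
#' @param seed optional integer seed for the direction sample.
#' @param gamma0 optional override of the mutualistic strength (default: half
#'   the stability threshold).
#' @return Data frame with one row per link in canonical order (`network_id`,
#'   `plant`, `animal`, `I_percent`, `excluded`), with attributes
#'   `gamma0_max`, `gamma0`, `omega_original`, `estimator`, `n_excluded`,
#'   `n_included`.
#' @export
network_feasibility_run <- function(net, delta, rho = 0,
                                    estimator = c("solid_angle",
                                                  "center_deviation"),
                                    n_directions = 10000L, seed = NULL,
                                    gamma0 = NULL) {
  estimator <- match.arg(estimator)
  gamma0_max <- stability_threshold(net, delta, rho)
  g0 <- gamma0 %||% (as.numeric(gamma0_max) / 2)
  S <- nrow(net$weights) + ncol(net$weights)
  directions <- sample_directions(n_directions, S, seed)
  sysO <- build_system(net, glv_params(net, g0, delta, rho))
  omega_O <- estimate_omega(sysO, estimator, n_directions, seed,
                            directions)$omega
  deg <- species_degrees(net)
  pos <- which(net$weights > 0, arr.ind = TRUE)
  links <- data.frame(plant = net$plant_names[pos[, 1L]],
                      animal = net$animal_names[pos[, 2L]],
                      stringsAsFactors = FALSE)
  links <- links[order(links$plant, links$animal, method = "radix"), ,
                 drop = FALSE]
  I <- rep(NA_real_, nrow(links))
  excl <- rep(FALSE, nrow(links))
  for (k in seq_len(nrow(links))) {
    p <- links$plant[k]; a <- links$animal[k]
    if (deg$plants[[p]] == 1L || deg$animals[[a]] == 1L) {
      excl[k] <- TRUE
      next
    }
    res <- feasibility_contribution(net, p, a, g0, delta, rho,
                                    estimator = estimator,
                                    directions = directions,
                                    omega_original = omega_O)
    I[k] <- res$I_percent
    excl[k] <- res$excluded
  }
  out <- data.frame(network_id = net$network_id, plant = links$plant,
                    animal = links$animal, I_percent = I, excluded = excl,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, gamma0_max = as.numeric(gamma0_max), gamma0 = g0,
            omega_original = omega_O, estimator = estimator,
            n_excluded = sum(excl), n_included = sum(!excl))
}

#' Populate the feasibility-contribution columns of a link table
#'
#' Runs [network_feasibility_run()] for every network in the collection, with
#' a per-network seed derived from the master seed, and merges `I_percent`
#' and `excluded` into the link table.
#'
#' @param link_table a link table from [assemble_link_table()].
#' @param nets the list of [bipartite_network()] objects the table came from.
#' @param delta,rho,estimator,n_directions as in [network_feasibility_run()].
#' @param seed master integer seed.
#' @return The link table with `I_percent` and `excluded` filled, plus a
#'   `gamma0_table` attribute (per-network `gamma0_max`, `gamma0`,
#'   `omega_original`, seed used).
#' @export
add_feasibility <- function(link_table, nets, delta, rho = 0,
                            estimator = c("solid_angle", "center_deviation"),
                            n_directions = 10000L, seed = 1L) {
  estimator <- match.arg(estimator)
  gamma0_rows <- list()
  for (net in nets) {
    net_seed <- derive_seed(seed, "feasibility", net$network_id)
    run <- network_feasibility_run(net, delta, rho, estimator = estimator,
                                   n_directions = n_directions,
                                   seed = net_seed)
    key_tab <- paste(link_table$network_id, link_table$plant, link_table$animal)
    key_run <- paste(run$network_id, run$plant, run$animal)
    idx <- match(key_run, key_tab)
    link_table$I_percent[idx] <- run$I_percent
    link_table$excluded[idx] <- run$excluded
    gamma0_rows[[net$network_id]] <- data.frame(
      network_id = net$network_id,
      gamma0_max = attr(run, "gamma0_max"), gamma0 = attr(run, "gamma0"),
      omega_original = attr(run, "omega_original"),
      n_excluded = attr(run, "n_excluded"),
      n_included = attr(run, "n_included"),
      seed = net_seed, stringsAsFactors = FALSE)
  }
  gtab <- do.call(rbind, gamma0_rows)
  rownames(gtab) <- NULL
  structure(link_table, gamma0_table = gtab)
}

#' Re-run feasibility contributions over a grid of trade-off values
#'
#' Convenience sweep over `delta` values (each with the same master seed and
#' estimator), returning one populated link table per value.
#'
#' @param link_table,nets,rho,estimator,n_directions,seed as in
#'   [add_feasibility()].
#' @param delta_values numeric vector of trade-off values.
#' @return Named list of link tables, one per `delta`.
#' @export
feasibility_delta_sweep <- function(link_table, nets, delta_values, rho = 0,
                                    estimator = c("solid_angle",
                                                  "center_deviation"),
                                    n_directions = 10000L, seed = 1L) {
  estimator <- match.arg(estimator)
  out <- lapply(delta_values, function(d) {
    add_feasibility(link_table, nets, delta = d, rho = rho,
                    estimator = estimator, n_directions = n_directions,
                    seed = seed)
  })
  names(out) <- sprintf("delta=%g", delta_values)
  out
}
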