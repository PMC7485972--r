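#' GLV parameter set for a mutualistic network
#'
#' Bundles the dynamical parameters of the generalized Lotka-Volterra
#' mutualism model: mean-field intraguild competition (`alpha_ii = 1`,
#' `alpha_ij = rho` within a guild), mutualistic trade-off `delta`, overall
#' mutualistic strength `gamma0`, and the binary adjacency and degrees of the
#' network, from which the benefit matrix `gamma_ij = gamma0 * L_ij /
#' d_i^delta` is reproducible.
#'
#' @param net a [bipartite_network()].
#' @param gamma0 overall mutualistic strength (>= 0; 0 is the
#'   competition-only limit).
#' @param delta mutualistic trade-off (>= 0).
#' @param rho interspecific within-guild competition (>= 0; the study designs
#'   use 0 and 0.01).
#' @return Object of class `glv_params`.
#' @export
glv_params <- function(net, gamma0, delta, rho = 0) {
  stopifnot(gamma0 >= 0, delta >= 0, rho >= 0)
  L <- (net$weights > 0) * 1
  structure(
    list(gamma0 = gamma0, delta = delta, rho = rho, L = L,
         d_plants = rowSums(L), d_animals = colSums(L)),
    class = "glv_params")
}

## Interaction matrix B such that r = B %*% N at equilibrium, with
## N = (P_1..P_np, A_1..A_na). Block form [[alpha^P, -gamma^P],
## [-gamma^A, alpha^A]].
assemble_interaction_matrix <- function(L, d_plants, d_animals,
                                        gamma0, delta, rho) {
  np <- nrow(L); na <- ncol(L)
  alphaP <- matrix(rho, np, np); diag(alphaP) <- 1
  alphaA <- matrix(rho, na, na); diag(alphaA) <- 1
  gammaP <- gamma0 * L / d_plants^delta          # benefit to plants
  gammaA <- gamma0 * t(L) / d_animals^delta      # benefit to animals
  rbind(cbind(alphaP, -gammaP), cbind(-gammaA, alphaA))
}

#' Build the GLV system matrix for a network
#'
#' @param net a [bipartite_network()].
#' @param params a [glv_params()] consistent with `net` (same adjacency).
#' @return Object of class `glv_system`: list with the `S x S` matrix `B`
#'   (`S = n_plants + n_animals`), guild sizes and species names. The
#'   feasible growth-rate set is the cone `{B %*% N : N > 0}`.
#' @export
build_system <- function(net, params) {
  stopifnot(inherits(params, "glv_params"))
  L <- (net$weights > 0) * 1
  if (!identical(dim(L), dim(params$L)) || any(L != params$L)) {
    stop("parameter set adjacency does not match the network", call. = FALSE)
  }
  B <- assemble_interaction_matrix(L, params$d_plants, params$d_animals,
                                   params$gamma0, params$delta, params$rho)
  structure(
    list(B = B, n_plants = nrow(L), n_animals = ncol(L),
         species = c(net$plant_names, net$animal_names), params = params),
    class = "glv_system")
}

#' @export
print.glv_system <- function(x, ...) {
  cat(sprintf("<glv_system> S = %d (%d plants + %d animals), gamma0 = %.4g, delta = %.3g, rho = %.3g\n",
              nrow(x$B), x$n_plants, x$n_animals,
              x$params$gamma0, x$params$delta, x$params$rho))
  invisible(x)
}

## Global stability criterion: positive definiteness of the symmetric part
## (B + t(B))/2, sufficient for global stability of the feasible equilibrium.
is_stable_gamma0 <- function(L, dP, dA, delta, rho, gamma0) {
  B <- assemble_interaction_matrix(L, dP, dA, gamma0, delta, rho)
  sym <- (B + t(B)) / 2
  min(eigen(sym, symmetric = TRUE, only.values = TRUE)$values) > 0
}

#' Stability threshold of the mutualistic strength
#'
#' Largest `gamma0` at which the symmetric part of the GLV interaction matrix
#' remains positive definite (global stability), found by bisection to a
#' relative tolerance of 1e-6. The study parameterisation sets the working
#' mutualistic strength to half this threshold.
#'
#' @param net a [bipartite_network()].
#' @param delta mutualistic trade-off.
#' @param rho within-guild interspecific competition.
#' @param tol relative bisection tolerance.
#' @return `gamma0_max` (numeric), with attribute `n_evaluations`.
#' @export
stability_threshold <- function(net, delta, rho = 0, tol = 1e-6) {
  L <- (net$weights > 0) * 1
  dP <- rowSums(L); dA <- colSums(L)
  evals <- 0L
  stable <- function(g) {
    evals <<- evals + 1L
    is_stable_gamma0(L, dP, dA, delta, rho, g)
  }
  S <- nrow(L) + ncol(L)
  # competition-only matrix has eigenvalues 1 - rho and 1 + (n-1) rho
  if (rho >= 1) {
    stop("no stable gamma0 exists: competition matrix is not positive definite",
         call. = FALSE)
  }
  lo <- 0; hi <- 1
  while (stable(hi)) {
    lo <- hi
    hi <- hi * 2
    if (hi > 2^40) stop("stability threshold search did not bracket", call. = FALSE)
  }
  if (lo == 0) {
    while (!stable(hi / 2)) {
      hi <- hi / 2
      if (hi < 1e-12) {
        stop("positive definiteness fails as gamma0 approaches 0", call. = FALSE)
      }
    }
    lo <- hi / 2
  }
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (stable(mid)) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, n_evaluations = evals)
}

#' Structural center of the feasibility domain
#'
#' Analytic estimate of the intrinsic growth-rate vector at the center of
#' the feasibility cone: the normalised sum of the normalised columns
#' (cone generators) of `B`. Strictly inside the cone whenever `B` is
#' invertible and the cone is pointed.
#'
#' @param sys a [build_system()] result.
#' @return Unit-norm numeric vector of length `S`.
#' @export
structural_center <- function(sys) {
  B <- sys$B
  norms <- sqrt(colSums(B^2))
  if (any(norms < .Machine$double.eps^0.5)) {
    stop("zero column in interaction matrix", call. = FALSE)
  }
  rc <- rowSums(sweep(B, 2, norms, "/"))
  rc / sqrt(sum(rc^2))
}
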