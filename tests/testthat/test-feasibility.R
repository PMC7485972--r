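test_that("both estimators recover the orthant fraction of identity cones", {
  for (S in c(7, 8)) {
    sys <- identity_system(S)
    est <- omega_solid_angle(sys, n_directions = 1e5, seed = S)
    expect_lt(abs(est$omega - 1 / 2^S), 3 * est$mc_standard_error + 1e-12)
    cd <- omega_center_deviation(sys, n_directions = 2e4, seed = S)
    expect_equal(cd$omega, 1 / 2^S, tolerance = 0.15)
  }
})

test_that("feasibility is invariant to positive column rescaling", {
  net <- generate_glv_fixture(3, 3, 0.7, seed = 4)
  g0 <- as.numeric(stability_threshold(net, 0.339, 0)) / 2
  sys <- build_system(net, glv_params(net, g0, 0.339, 0))
  sys2 <- sys
  sys2$B <- sys$B %*% diag(exp(seq(-1, 1, length.out = nrow(sys$B))))
  dirs <- sample_directions(5e4, nrow(sys$B), seed = 8)
  expect_equal(omega_solid_angle(sys, directions = dirs)$omega,
               omega_solid_angle(sys2, directions = dirs)$omega)
  expect_equal(omega_center_deviation(sys, directions = dirs)$omega,
               omega_center_deviation(sys2, directions = dirs)$omega,
               tolerance = 1e-3)
})

test_that("the bisected critical angles match the closed-form exit angles", {
  net <- generate_glv_fixture(3, 4, 0.6, seed = 12)
  g0 <- as.numeric(stability_threshold(net, 0.339, 0)) / 2
  sys <- build_system(net, glv_params(net, g0, 0.339, 0))
  B <- sys$B
  S <- nrow(B)
  rc <- structural_center(sys)
  a <- solve(B, rc)
  dirs <- sample_directions(500, S, seed = 3)
  # closed form: along r(theta) = cos(theta) rc + sin(theta) v, component i
  # of B^-1 r is a_i cos(theta) + b_i sin(theta), first zero at
  # atan2(b_i, a_i) + pi/2; the exit angle is the minimum over components
  proj <- as.vector(dirs %*% rc)
  V <- dirs - outer(proj, rc)
  V <- V / sqrt(rowSums(V^2))
  Bv <- solve(B, t(V))
  theta_exact <- pmin(apply(atan2(Bv, a) + pi / 2, 2, min), pi)
  g_exact <- stats::pbeta((1 - cos(theta_exact)) / 2, (S - 1) / 2, (S - 1) / 2)
  est <- omega_center_deviation(sys, directions = dirs)
  # bisection midpoint error is at most 5e-5 rad per direction
  expect_lt(abs(est$omega - mean(g_exact)), 1e-4)
})

test_that("omega estimates are deterministic given a seed", {
  net <- generate_glv_fixture(3, 3, 0.8, seed = 2)
  g0 <- as.numeric(stability_threshold(net, 0.339, 0)) / 2
  sys <- build_system(net, glv_params(net, g0, 0.339, 0))
  expect_identical(omega_solid_angle(sys, 5000, seed = 5),
                   omega_solid_angle(sys, 5000, seed = 5))
  expect_identical(omega_center_deviation(sys, 2000, seed = 5),
                   omega_center_deviation(sys, 2000, seed = 5))
})

test_that("link removal recomputes degrees and flags isolating removals", {
  # p1-a1, p1-a2, p2-a1: removing p1-a2 isolates a2
  w <- rbind(c(1, 1), c(1, 0))
  net <- toy_net(w, "tri")
  res <- feasibility_contribution(net, "P1", "A2", gamma0 = 0.2,
                                  delta = 0.339, n_directions = 2000,
                                  seed = 1)
  expect_true(res$excluded)
  expect_true(is.na(res$I_percent))
  res2 <- feasibility_contribution(net, "P1", "A1", gamma0 = 0.2,
                                   delta = 0.339, n_directions = 20000,
                                   seed = 1)
  expect_false(res2$excluded)
  expect_true(is.finite(res2$I_percent))
  expect_error(feasibility_contribution(net, "P2", "A2", 0.2, 0.339),
               "not present")
})

test_that("low-precision contributions agree with a high-precision rerun", {
  net <- generate_glv_fixture(3, 3, 0.9, seed = 6)
  g0 <- as.numeric(stability_threshold(net, 0.339, 0)) / 2
  lo <- feasibility_contribution(net, net$plant_names[1], net$animal_names[1],
                                 g0, 0.339, n_directions = 1e4, seed = 2)
  hi <- feasibility_contribution(net, net$plant_names[1], net$animal_names[1],
                                 g0, 0.339, n_directions = 4e5, seed = 3)
  se_ratio <- function(r, n) {
    o <- r$omega_original; q <- r$omega_removed
    100 * (o / q) * sqrt(o * (1 - o) / (n * o^2) + q * (1 - q) / (n * q^2))
  }
  tol <- 3 * (se_ratio(lo, 1e4) + se_ratio(hi, 4e5))
  expect_lt(abs(lo$I_percent - hi$I_percent), tol)
  expect_equal(sign(lo$I_percent), sign(hi$I_percent))
})

test_that("network runs exclude exactly the links with a degree-1 endpoint", {
  run <- network_feasibility_run(toy_net(matrix(1, 2, 2)), delta = 0.339,
                                 n_directions = 1000, seed = 1)
  expect_equal(attr(run, "n_excluded"), 0L)
  expect_equal(attr(run, "n_included"), 4L)

  star <- two_star_net()
  run2 <- network_feasibility_run(star, delta = 0.339, n_directions = 1000,
                                  seed = 1)
  expect_true(all(run2$excluded))

  fix <- fixture_10x15()
  run3 <- network_feasibility_run(fix, delta = 0.339,
                                  estimator = "center_deviation",
                                  n_directions = 500, seed = 1)
  L <- fix$weights > 0
  dp <- rowSums(L); da <- colSums(L)
  pos <- which(L, arr.ind = TRUE)
  brute <- sum(dp[pos[, 1]] == 1 | da[pos[, 2]] == 1)
  expect_equal(attr(run3, "n_excluded"), brute)
  # gamma0 is set to half the stability threshold of the original topology
  expect_equal(attr(run3, "gamma0"), attr(run3, "gamma0_max") / 2,
               tolerance = 1e-12)
})

test_that("the two estimators rank link contributions consistently", {
  panel_sa <- numeric(0); panel_cd <- numeric(0)
  for (s in 1:3) {
    net <- generate_glv_fixture(2 + s, 3 + s, 0.7, seed = 40 + s)
    sa <- network_feasibility_run(net, delta = 0.339,
                                  estimator = "solid_angle",
                                  n_directions = 1e5, seed = 9)
    cd <- network_feasibility_run(net, delta = 0.339,
                                  estimator = "center_deviation",
                                  n_directions = 2e4, seed = 9)
    panel_sa <- c(panel_sa, sa$I_percent)
    panel_cd <- c(panel_cd, cd$I_percent)
  }
  keep <- !is.na(panel_sa)
  expect_gte(cor(panel_sa[keep], panel_cd[keep], method = "spearman"), 0.8)
})
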