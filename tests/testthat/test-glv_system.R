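test_that("the interaction matrix has the documented block structure", {
  # two disjoint links, rho = 0, delta = 0, gamma0 = 0.5: four -0.5 entries
  w <- diag(2); rownames(w) <- c("P1", "P2"); colnames(w) <- c("A1", "A2")
  net <- bipartite_network(w, "pair")
  sys <- build_system(net, glv_params(net, gamma0 = 0.5, delta = 0, rho = 0))
  expected <- rbind(cbind(diag(2), -0.5 * diag(2)),
                    cbind(-0.5 * diag(2), diag(2)))
  expect_equal(unname(sys$B), expected)

  # gamma0 = 0 with rho = 0 gives the identity
  sys0 <- build_system(net, glv_params(net, gamma0 = 0, delta = 0.3, rho = 0))
  expect_equal(unname(sys0$B), diag(4))

  # competition blocks: diagonal 1, off-diagonal rho within guilds
  net2 <- toy_net(matrix(1, 3, 2))
  sys2 <- build_system(net2, glv_params(net2, 0.1, 0.339, rho = 0.01))
  alphaP <- sys2$B[1:3, 1:3]
  expect_equal(unname(diag(alphaP)), rep(1, 3))
  expect_true(all(alphaP[upper.tri(alphaP)] == 0.01))

  # benefits are discounted by the receiving species' degree
  w3 <- rbind(c(1, 1, 1), c(1, 0, 0))
  rownames(w3) <- c("P1", "P2"); colnames(w3) <- c("A1", "A2", "A3")
  net3 <- bipartite_network(w3, "deg")
  sys3 <- build_system(net3, glv_params(net3, gamma0 = 1, delta = 1, rho = 0))
  # plant P1 has degree 3: each of its benefits is 1/3; P2 degree 1: benefit 1
  expect_equal(unname(sys3$B[1, 3:5]), rep(-1 / 3, 3))
  expect_equal(unname(sys3$B[2, 3:5]), c(-1, 0, 0))
  # animal A1 has degree 2: benefits 1/2 from each partner
  expect_equal(unname(sys3$B[3, 1:2]), c(-0.5, -0.5))
})

test_that("the stability threshold matches analytic and grid oracles", {
  # disjoint pairs, all degrees 1: blocks [[1, -g], [-g, 1]], threshold 1
  w <- diag(2); rownames(w) <- c("P1", "P2"); colnames(w) <- c("A1", "A2")
  net <- bipartite_network(w, "pair")
  thr <- stability_threshold(net, delta = 0.7, rho = 0)
  expect_equal(as.numeric(thr), 1, tolerance = 1e-5)

  # fully connected 2x2 vs a dense eigenvalue grid scan
  net2 <- toy_net(matrix(1, 2, 2))
  thr2 <- as.numeric(stability_threshold(net2, delta = 0.339, rho = 0))
  L <- (net2$weights > 0) * 1
  min_eig <- function(g) {
    B <- linkrisk:::assemble_interaction_matrix(L, rowSums(L), colSums(L),
                                                g, 0.339, 0)
    min(eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  }
  grid <- seq(thr2 - 0.01, thr2 + 0.01, by = 1e-5)
  eigs <- vapply(grid, min_eig, 0)
  crossing <- grid[which(diff(sign(eigs)) != 0)[1]]
  expect_equal(thr2, crossing, tolerance = 1e-4)

  # the smallest eigenvalue of the symmetric part decreases with gamma0
  gammas <- seq(0.05, 1.5, by = 0.05)
  expect_true(all(diff(vapply(gammas, min_eig, 0)) < 0))
})

test_that("adding a link cannot raise the stability threshold", {
  w <- matrix(0, 3, 3)
  w[1, 1] <- w[2, 2] <- w[3, 3] <- w[1, 2] <- 1
  net <- toy_net(w, "base")
  w2 <- w; w2[2, 3] <- 1
  net2 <- toy_net(w2, "plus")
  expect_lte(as.numeric(stability_threshold(net2, 0.339, 0)),
             as.numeric(stability_threshold(net, 0.339, 0)) + 1e-9)
})

test_that("the structural center bisects the feasibility cone", {
  expect_equal(structural_center(identity_system(3)), rep(1 / sqrt(3), 3))

  sys <- identity_system(2)
  sys$B <- cbind(c(1, 0), c(1, 1))
  rc <- structural_center(sys)
  expect_equal(atan2(rc[2], rc[1]), pi / 8, tolerance = 1e-12)  # 22.5 degrees

  # invariant to positive rescaling of columns
  sys2 <- sys
  sys2$B <- sys$B %*% diag(c(7, 0.03))
  expect_equal(structural_center(sys2), rc, tolerance = 1e-12)

  sys$B[, 1] <- 0
  expect_error(structural_center(sys), "zero column")

  # the center is strictly feasible for a mutualistic system
  net <- generate_glv_fixture(3, 4, 0.6, seed = 5)
  g0 <- as.numeric(stability_threshold(net, 0.339, 0)) / 2
  s <- build_system(net, glv_params(net, g0, 0.339, 0))
  expect_true(all(solve(s$B, structural_center(s)) > 0))
})
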