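make_lt <- function(values, networks = NULL) {
  n <- length(values)
  data.frame(network_id = networks %||% rep("n1", n),
             plant = sprintf("p%d", seq_len(n)),
             animal = sprintf("a%d", seq_len(n)),
             weight = 1, V = values, I_percent = values,
             f_std = values, D_std = values,
             stringsAsFactors = FALSE)
}

test_that("relative rescaling is per network, with pass-through for I", {
  lt <- make_lt(c(0.2, 0.6), c("n1", "n1"))
  expect_equal(rescale_relative(lt, "vulnerability"), c(0, 1))
  expect_identical(rescale_relative(lt, "feasibility_contribution"),
                   lt$I_percent)

  mw <- generate_metaweb(metaweb_config(n_networks = 3, seed = 13))
  lt3 <- add_vulnerability(assemble_link_table(mw$networks))
  r <- rescale_relative(lt3, "vulnerability")
  for (id in unique(lt3$network_id)) {
    v <- r[lt3$network_id == id]
    if (length(unique(v)) >= 2) expect_equal(range(v), c(0, 1))
  }
})

test_that("aggregation pools links by taxon pair and drops singletons", {
  lt <- data.frame(network_id = c("n1", "n2", "n1"),
                   plant = c("p1", "p2", "p3"),
                   animal = c("a1", "a2", "a3"),
                   stringsAsFactors = FALSE)
  tax <- toy_taxonomy(c("p1", "p2", "p3"), c("a1", "a2", "a3"),
                      plant_genus = c("G", "G", "H"),
                      animal_genus = c("Z", "Z", "Y"))
  agg <- suppressMessages(aggregate_links(lt, tax, "genus"))
  expect_equal(unique(agg$interaction_id), "G -- Z")
  expect_equal(nrow(agg), 2L)          # the singleton H--Y is dropped
  expect_equal(attr(agg, "n_singletons"), 1L)

  lt_bad <- rbind(lt, data.frame(network_id = "n1", plant = "mystery",
                                 animal = "a1"))
  expect_error(suppressMessages(aggregate_links(lt_bad, tax, "genus")),
               "mystery")
})

test_that("metaweb aggregation matches an independent grouping oracle", {
  mw <- generate_metaweb(metaweb_config(n_networks = 6, seed = 17))
  lt <- add_vulnerability(assemble_link_table(mw$networks))
  for (level in c("genus", "family", "order")) {
    agg <- suppressMessages(aggregate_links(lt, mw$taxonomy, level))
    tx <- as.data.frame(mw$taxonomy)
    pl <- tx[tx$guild == "plant", ]; an <- tx[tx$guild == "animal", ]
    key <- paste(pl[[level]][match(lt$plant, pl$species)],
                 an[[level]][match(lt$animal, an$species)])
    oracle <- table(key)
    kept <- oracle[oracle >= 2]
    expect_equal(nrow(agg), sum(kept))
    expect_equal(length(unique(agg$interaction_id)), length(kept))
  }
})

test_that("the null variance test matches its definition and an
           enumeration oracle", {
  # a perfectly consistent group against a scattered pool
  vals <- c(0.5, 0.5, 0.5, 0.1, 0.9, 0.2, 0.8, 0.05, 0.95)
  res <- null_variance_test(vals, 1:3, n_null = 200, seed = 1)
  expect_equal(res$p_value, 0)
  expect_gt(res$mean_paired_diff, 0)
  expect_true(res$significant)
  expect_equal(res$var_obs, 0)

  # sample variance with n-1 denominator on a pair
  res2 <- null_variance_test(c(0.1, 0.7, 0.3, 0.35, 0.4, 0.9), 1:2,
                             n_null = 100, seed = 2)
  expect_equal(res2$var_obs, (0.1 - 0.7)^2 / 2)

  # determinism
  expect_identical(null_variance_test(vals, 1:3, 500, seed = 9),
                   null_variance_test(vals, 1:3, 500, seed = 9))

  # exhaustive enumeration over the C(4, 2) = 6 null pairs
  pool <- c(0.42, 0.40, 0.1, 0.5, 0.8, 0.33)
  group <- 1:2
  rest <- pool[-group]
  pairs <- utils::combn(4, 2)
  var_null <- apply(pairs, 2, function(ix) var(rest[ix]))
  p_exact <- mean(var_null < var(pool[group]))
  res3 <- null_variance_test(pool, group, n_null = 4000, seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res3$p_value - p_exact), 3 * se + 1e-12)

  # error paths
  expect_error(null_variance_test(c(1, 2, 3), 1:2), "insufficient pool")
  expect_error(null_variance_test(vals, 1L), "at least 2")
})

test_that("summaries report positive and significant proportions", {
  mw <- generate_metaweb(metaweb_config(
    n_networks = 8, seed = 23, consistency_planted = TRUE,
    within_interaction_sd = 0.02, between_interaction_sd = 2,
    noise_sigma = 0.05))
  lt <- add_vulnerability(assemble_link_table(mw$networks))
  res <- suppressMessages(consistency_analysis(
    lt, mw$taxonomy, levels = "genus", properties = "frequency",
    n_null = 100, seed = 4))
  s <- consistency_summary(res)
  expect_equal(s$n_interactions, nrow(res))
  expect_equal(s$prop_positive, mean(res$mean_paired_diff > 0))
  expect_equal(s$prop_significant, mean(res$significant))
  expect_true(all(res$significant == (res$p_value < 0.05)))
  # strongly planted consistency shows up as mostly positive differences
  expect_gt(s$prop_positive, 0.9)
})
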