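test_that("network construction enforces the guild invariants", {
  expect_error(bipartite_network(matrix(-1, 2, 2), "x"), "negative")
  expect_error(bipartite_network(matrix(1, 1, 3), "x"), "fewer than 2")
  w <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(bipartite_network(w, "x"), "duplicated")
  w2 <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_error(toy_net(w2), "positive link")
})

test_that("incidence matrices read, prune and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",A1,A2", "P1,1,1", "P2,1,1"), path)
  net <- read_incidence_matrix(path, "id1")
  expect_equal(length(net$plant_names), 2L)
  expect_equal(length(net$animal_names), 2L)
  expect_equal(n_links(net), 4L)

  # all-zero row pruned with a warning; blank cells mean absence
  writeLines(c(",A1,A2,A3", "P1,2,,1", "P2,0,0,0", "P3,1,3,"), path)
  expect_warning(net3 <- read_incidence_matrix(path, "id3"), "P2")
  expect_equal(net3$plant_names, c("P1", "P3"))
  expect_equal(unname(net3$weights["P1", ]), c(2, 0, 1))

  writeLines(c(",A1,A2", "P1,-1,1", "P2,1,1"), path)
  expect_error(read_incidence_matrix(path, "bad"), "negative")

  # round-trip is bit-exact for decimal weights
  w <- matrix(c(0.5, 2, 1.25, 0.125), 2, 2)
  net0 <- toy_net(w, "rt")
  out <- withr::local_tempfile(fileext = ".csv")
  write_incidence_matrix(net0, out)
  back <- read_incidence_matrix(out, "rt")
  expect_identical(back$weights, net0$weights)
})

test_that("degenerate networks after pruning are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",A1,A2", "P1,4,0", "P2,0,0"), path)
  expect_error(suppressWarnings(read_incidence_matrix(path, "deg")),
               "degenerate")
})

test_that("sampling intensity is the root mean events per possible link", {
  expect_equal(sampling_intensity(toy_net(matrix(1, 2, 2))), 1)
  fix <- fixture_10x15()
  expect_equal(sum(fix$weights), 60)
  expect_equal(sampling_intensity(fix), sqrt(60 / 150), tolerance = 1e-12)
})

test_that("link tables enumerate positive cells with endpoint degrees", {
  n1 <- toy_net(matrix(1, 2, 2), "n1")
  n2 <- toy_net(matrix(1, 2, 2), "n2")
  lt <- assemble_link_table(list(n1, n2))
  expect_equal(nrow(lt), 8L)
  expect_true(all(is.na(lt$V)))

  expect_error(assemble_link_table(list(n1, n1)), "duplicate network_id")
  expect_equal(nrow(assemble_link_table(list())), 0L)

  # record count equals a direct scan of positive cells
  mw <- generate_metaweb(metaweb_config(n_networks = 3, seed = 42))
  lt2 <- assemble_link_table(mw$networks)
  expect_equal(nrow(lt2),
               sum(vapply(mw$networks, function(n) sum(n$weights > 0), 0L)))
  # the 10x15 fixture reports exactly its 15 positive cells
  expect_equal(nrow(assemble_link_table(list(fixture_10x15()))), 15L)
})

test_that("link tables are invariant to species-order permutations", {
  mw <- generate_metaweb(metaweb_config(n_networks = 1, seed = 7))
  net <- mw$networks[[1]]
  w <- net$weights
  wp <- w[sample(nrow(w)), sample(ncol(w))]
  perm <- bipartite_network(wp, net$network_id, net$network_type)
  lt1 <- assemble_link_table(list(net))
  lt2 <- assemble_link_table(list(perm))
  expect_identical(lt1, lt2)
})

test_that("taxonomy tables validate the genus-family-order hierarchy", {
  tax <- toy_taxonomy(c("p1", "p2"), c("a1", "a2"))
  expect_s3_class(tax, "taxonomy_table")
  bad <- as.data.frame(tax)
  bad$family[bad$species == "p1"] <- "OtherFam"
  bad$genus[bad$species == "p1"] <- bad$genus[bad$species == "p2"]
  expect_error(taxonomy_table(bad), "exactly one family")
  path <- withr::local_tempfile(fileext = ".csv")
  write_taxonomy(tax, path)
  expect_equal(as.data.frame(read_taxonomy(path)), as.data.frame(tax))
})
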