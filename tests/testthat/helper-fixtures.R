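## Small networks built in code; no stored fixtures.

toy_net <- function(w, id = "toy", type = "pollination") {
  if (is.null(rownames(w))) rownames(w) <- sprintf("P%d", seq_len(nrow(w)))
  if (is.null(colnames(w))) colnames(w) <- sprintf("A%d", seq_len(ncol(w)))
  bipartite_network(w, id, type)
}

## 2 plants x 4 animals, each animal visiting exactly one plant: every link
## has a degree-1 endpoint, so every removal isolates a species.
two_star_net <- function(id = "two_star") {
  w <- matrix(0, 2, 4)
  w[1, 1:2] <- 1
  w[2, 3:4] <- 1
  toy_net(w, id)
}

## 10 x 15 sparse fixture with a known positive-cell pattern and total
## weight 60: diagonal 2s cover the plants and first ten animals, animals
## 11-15 hang off plant 1 with weight 8 each.
fixture_10x15 <- function(id = "fix10x15") {
  w <- matrix(0, 10, 15)
  for (i in 1:10) w[i, i] <- 2
  w[1, 11:15] <- 8
  toy_net(w, id)
}

## Identity GLV system of size S without going through a network.
identity_system <- function(S) {
  structure(list(B = diag(S), n_plants = 1L, n_animals = S - 1L,
                 species = sprintf("s%d", seq_len(S))),
            class = "glv_system")
}

## Minimal taxonomy covering the species of the synthetic-free toy networks.
toy_taxonomy <- function(plants, animals,
                         plant_genus = NULL, animal_genus = NULL) {
  pg <- plant_genus %||% plants
  ag <- animal_genus %||% animals
  taxonomy_table(rbind(
    data.frame(species = plants, guild = "plant", genus = pg,
               family = paste0("F", pg), order = paste0("O", pg),
               stringsAsFactors = FALSE),
    data.frame(species = animals, guild = "animal", genus = ag,
               family = paste0("F", ag), order = paste0("O", ag),
               stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
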