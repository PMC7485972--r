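#' Configuration for a synthetic metaweb
#'
#' Describes a multi-network metaweb with a shared species pool, hierarchical
#' taxonomy, heavy-tailed degree distributions and log-normal visitation
#' rates obeying a planted degree/frequency power law
#' `log f_ij = a + log(d_i d_j) - true_delta * log(d_i)` (plant degree
#' discounted by the mutualistic trade-off). Optionally plants
#' interaction-level consistency: each genus-pair interaction carries a latent
#' log-frequency effect drawn with standard deviation
#' `between_interaction_sd`, realised across its occurrences with standard
#' deviation `within_interaction_sd`.
#'
#' @param n_networks number of local networks.
#' @param n_plant_species,n_animal_species species-pool sizes (>= 4).
#' @param genera_per_family,families_per_order taxonomy shape.
#' @param inclusion_prob per-network probability that a pool species occurs.
#' @param connectance target proportion of realised links per network.
#' @param true_delta planted mutualistic trade-off (>= 0).
#' @param noise_sigma log-normal sigma of link-level frequency noise (natural
#'   log scale).
#' @param consistency_planted logical; plant interaction-level effects?
#' @param within_interaction_sd,between_interaction_sd latent link-property
#'   dispersion within and between interactions (log scale).
#' @param topology `"propensity"` (heavy-tailed specialist/generalist mix via
#'   log-normal species propensities) or `"modular"` (unions of fully
#'   connected plant-animal modules of varying size, on which the planted
#'   power law is exactly identifiable from both guilds).
#' @param base_log_frequency intercept `a` of the planted law (natural log).
#'   The default puts the median sampling intensity of the generated
#'   networks near 0.9, the magnitude typical of quantitative visitation
#'   surveys.
#' @param seed integer RNG seed.
#' @return A validated list of class `metaweb_config`.
#' @export
metaweb_config <- function(n_networks = 10L,
                           n_plant_species = 24L,
                           n_animal_species = 36L,
                           genera_per_family = 3L,
                           families_per_order = 3L,
                           inclusion_prob = 0.5,
                           connectance = 0.2,
                           true_delta = 0.339,
                           noise_sigma = 0.3,
                           consistency_planted = FALSE,
                           within_interaction_sd = 0.1,
                           between_interaction_sd = 1,
                           topology = c("propensity", "modular"),
                           base_log_frequency = -2,
                           seed = 1L) {
  cfg <- list(n_networks = as.integer(n_networks),
              n_plant_species = as.integer(n_plant_species),
              n_animal_species = as.integer(n_animal_species),
              genera_per_family = as.integer(genera_per_family),
              families_per_order = as.integer(families_per_order),
              inclusion_prob = inclusion_prob, connectance = connectance,
              true_delta = true_delta, noise_sigma = noise_sigma,
              consistency_planted = isTRUE(consistency_planted),
              within_interaction_sd = within_interaction_sd,
              between_interaction_sd = between_interaction_sd,
              topology = match.arg(topology),
              base_log_frequency = base_log_frequency,
              seed = as.integer(seed))
  stopifnot(cfg$n_networks >= 1L,
            cfg$n_plant_species >= 4L, cfg$n_animal_species >= 4L,
            cfg$genera_per_family >= 1L, cfg$families_per_order >= 1L,
            cfg$inclusion_prob > 0, cfg$inclusion_prob <= 1,
            cfg$connectance > 0, cfg$connectance < 1,
            cfg$true_delta >= 0, cfg$noise_sigma >= 0,
            cfg$within_interaction_sd >= 0, cfg$between_interaction_sd >= 0)
  class(cfg) <- "metaweb_config"
  cfg
}

## Hierarchical taxonomy for one guild: species assigned round-robin to
## genera (~2 species each) so genus-level interactions recur.
guild_taxonomy <- function(n_species, prefix, guild, genera_per_family,
                           families_per_order) {
  species <- sprintf("%s_%03d", prefix, seq_len(n_species))
  n_genera <- max(2L, ceiling(n_species / 2))
  gi <- rep_len(seq_len(n_genera), n_species)
  fi <- ceiling(gi / genera_per_family)
  oi <- ceiling(fi / families_per_order)
  data.frame(species = species, guild = guild,
             genus = sprintf("%sGen_%02d", substr(prefix, 1, 1), gi),
             family = sprintf("%sFam_%02d", substr(prefix, 1, 1), fi),
             order = sprintf("%sOrd_%02d", substr(prefix, 1, 1), oi),
             stringsAsFactors = FALSE)
}

## One local adjacency via thresholded products of log-normal species
## propensities (specialist/generalist mix), pruned to positive degrees.
local_adjacency_propensity <- function(cfg, pool_p, pool_a) {
  for (attempt in 1:200) {
    inc_p <- pool_p[runif(length(pool_p)) < cfg$inclusion_prob]
    inc_a <- pool_a[runif(length(pool_a)) < cfg$inclusion_prob]
    if (length(inc_p) < 2L || length(inc_a) < 2L) next
    np <- length(inc_p); na <- length(inc_a)
    score <- outer(rlnorm(np, 0, 1), rlnorm(na, 0, 1)) *
      exp(matrix(rnorm(np * na, 0, 0.5), np, na))
    dimnames(score) <- list(inc_p, inc_a)
    n_link <- max(2L, round(cfg$connectance * np * na))
    thr <- sort(score, decreasing = TRUE)[min(n_link, np * na)]
    L <- score >= thr
    repeat {
      zr <- rowSums(L) == 0; zc <- colSums(L) == 0
      if (!any(zr) && !any(zc)) break
      L <- L[!zr, !zc, drop = FALSE]
    }
    if (nrow(L) >= 2L && ncol(L) >= 2L) return(L * 1)
  }
  stop("could not generate a valid network under this configuration",
       call. = FALSE)
}

## One local adjacency as a union of complete bipartite modules of size 2-4.
## Within a module every plant and animal has equal degree, so the planted
## frequency law is consistent with both guild-side regressions.
local_adjacency_modular <- function(cfg, pool_p, pool_a) {
  for (attempt in 1:200) {
    inc_p <- pool_p[runif(length(pool_p)) < cfg$inclusion_prob]
    inc_a <- pool_a[runif(length(pool_a)) < cfg$inclusion_prob]
    if (length(inc_p) < 2L || length(inc_a) < 2L) next
    inc_p <- sample(inc_p); inc_a <- sample(inc_a)
    L <- matrix(0, length(inc_p), length(inc_a),
                dimnames = list(inc_p, inc_a))
    ip <- 1L; ia <- 1L
    while (length(inc_p) - ip + 1L >= 2L && length(inc_a) - ia + 1L >= 2L) {
      m <- sample(2:4, 1L)
      m <- min(m, length(inc_p) - ip + 1L, length(inc_a) - ia + 1L)
      L[ip:(ip + m - 1L), ia:(ia + m - 1L)] <- 1
      ip <- ip + m; ia <- ia + m
    }
    keep_p <- rowSums(L) > 0; keep_a <- colSums(L) > 0
    L <- L[keep_p, keep_a, drop = FALSE]
    if (nrow(L) >= 2L && ncol(L) >= 2L) return(L)
  }
  stop("could not generate a valid modular network", call. = FALSE)
}

#' Generate a synthetic metaweb with known ground truth
#'
#' Produces a collection of local networks sharing a species pool and
#' taxonomy, with visitation rates following the planted power law of
#' [metaweb_config()]. The same seed yields byte-identical output.
#'
#' @param cfg a [metaweb_config()].
#' @return List with elements `networks` (list of [bipartite_network()]),
#'   `taxonomy` (a [taxonomy_table()]), and `truth` (list holding the config,
#'   the genus-pair `interaction_effects` matrix when consistency is planted,
#'   and a per-link data frame `links` with the latent expected
#'   log-frequencies).
#' @export
generate_metaweb <- function(cfg) {
  stopifnot(inherits(cfg, "metaweb_config"))
  with_seed(cfg$seed, {
    tax <- taxonomy_table(rbind(
      guild_taxonomy(cfg$n_plant_species, "Plant", "plant",
                     cfg$genera_per_family, cfg$families_per_order),
      guild_taxonomy(cfg$n_animal_species, "Animal", "animal",
                     cfg$genera_per_family, cfg$families_per_order)))
    pool_p <- tax$species[tax$guild == "plant"]
    pool_a <- tax$species[tax$guild == "animal"]
    genus_of <- setNames(tax$genus, paste(tax$guild, tax$species))

    pgen <- unique(tax$genus[tax$guild == "plant"])
    agen <- unique(tax$genus[tax$guild == "animal"])
    beta <- matrix(0, length(pgen), length(agen), dimnames = list(pgen, agen))
    if (cfg$consistency_planted) {
      beta[] <- rnorm(length(beta), 0, cfg$between_interaction_sd)
    }

    nets <- vector("list", cfg$n_networks)
    truth_rows <- vector("list", cfg$n_networks)
    for (k in seq_len(cfg$n_networks)) {
      L <- switch(cfg$topology,
                  propensity = local_adjacency_propensity(cfg, pool_p, pool_a),
                  modular = local_adjacency_modular(cfg, pool_p, pool_a))
      dP <- rowSums(L); dA <- colSums(L)
      pos <- which(L > 0, arr.ind = TRUE)
      plant <- rownames(L)[pos[, 1L]]
      animal <- colnames(L)[pos[, 2L]]
      mu <- cfg$base_log_frequency +
        log(dP[pos[, 1L]] * dA[pos[, 2L]]) -
        cfg$true_delta * log(dP[pos[, 1L]])
      eff <- rep(0, nrow(pos))
      if (cfg$consistency_planted) {
        eff <- beta[cbind(genus_of[paste("plant", plant)],
                          genus_of[paste("animal", animal)])] +
          rnorm(nrow(pos), 0, cfg$within_interaction_sd)
      }
      lw <- mu + eff + rnorm(nrow(pos), 0, cfg$noise_sigma)
      w <- L * 0
      w[pos] <- exp(lw)
      id <- sprintf("synthetic_%02d", k)
      nets[[k]] <- bipartite_network(w, id, "pollination")
      truth_rows[[k]] <- data.frame(
        network_id = id, plant = plant, animal = animal,
        d_plant = as.integer(dP[pos[, 1L]]), d_animal = as.integer(dA[pos[, 2L]]),
        mu_log = unname(mu), interaction_effect = unname(eff),
        stringsAsFactors = FALSE)
    }
    truth_links <- do.call(rbind, truth_rows)
    rownames(truth_links) <- NULL
    list(networks = nets, taxonomy = tax,
         truth = list(config = cfg,
                      interaction_effects = beta,
                      links = truth_links))
  })
}

#' Generate a small random network fixture for feasibility tests
#'
#' Rejection-samples a Bernoulli adjacency at the requested connectance until
#' every species has degree >= 1; weights are set to 1 (feasibility depends
#' only on topology).
#'
#' @param n_plants,n_animals guild sizes (>= 2).
#' @param connectance probability of each link; must admit degree >= 1 for
#'   every species (`connectance * n_plants * n_animals >= max(n_plants,
#'   n_animals)`).
#' @param seed integer RNG seed.
#' @return A [bipartite_network()].
#' @export
generate_glv_fixture <- function(n_plants, n_animals, connectance, seed = 1L) {
  stopifnot(n_plants >= 2L, n_animals >= 2L,
            connectance > 0, connectance <= 1)
  if (connectance * n_plants * n_animals < max(n_plants, n_animals)) {
    stop("connectance too low: cannot give every species a link",
         call. = FALSE)
  }
  with_seed(seed, {
    for (attempt in 1:10000) {
      L <- matrix(as.numeric(runif(n_plants * n_animals) < connectance),
                  n_plants, n_animals)
      if (all(rowSums(L) >= 1) && all(colSums(L) >= 1)) {
        rownames(L) <- sprintf("Plant_%02d", seq_len(n_plants))
        colnames(L) <- sprintf("Animal_%02d", seq_len(n_animals))
        return(bipartite_network(L, sprintf("fixture_%d", seed), "pollination"))
      }
    }
    stop("could not satisfy degree >= 1 at this connectance", call. = FALSE)
  })
}
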