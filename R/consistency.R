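## Property name -> link-table column.
property_column <- function(property) {
  switch(property,
         vulnerability = "V",
         feasibility_contribution = "I_percent",
         frequency = "f_std",
         generalisation = "D_std",
         stop("unknown property: ", property, call. = FALSE))
}

#' Per-network relative values of a link property
#'
#' Consistency comparisons use relative values so that network-level effects
#' are controlled for: vulnerability (and, for the diagnostic runs, frequency
#' and generalisation) is min-max rescaled to `[0, 1]` within each network
#' (ties to 0.5); feasibility contribution is already a relative quantity and
#' is passed through unchanged (excluded links stay `NA`).
#'
#' @param link_table a populated link table.
#' @param property one of `"vulnerability"`, `"feasibility_contribution"`,
#'   `"frequency"`, `"generalisation"`.
#' @return Numeric vector aligned with the rows of `link_table`.
#' @export
rescale_relative <- function(link_table,
                             property = c("vulnerability",
                                          "feasibility_contribution",
                                          "frequency", "generalisation")) {
  property <- match.arg(property)
  col <- property_column(property)
  vals <- link_table[[col]]
  if (is.null(vals)) stop("column '", col, "' missing", call. = FALSE)
  if (property == "feasibility_contribution") return(vals)
  if (anyNA(vals)) {
    stop("property '", property, "' is not populated for all links",
         call. = FALSE)
  }
  out <- rep(NA_real_, length(vals))
  for (id in unique(link_table$network_id)) {
    sel <- link_table$network_id == id
    if (!any(sel)) stop("empty network group", call. = FALSE)
    out[sel] <- unit_rescale(vals[sel])
  }
  out
}

#' Aggregate links into taxon-level interactions
#'
#' Groups the links of a link table by the (plant taxon, animal taxon) pair
#' at the requested taxonomic level. Interactions occurring only once are
#' dropped (their consistency is undefined); the number dropped is reported
#' via `message()` and the `n_singletons` attribute. Multiple links of one
#' interaction may come from the same network (different congeneric species
#' pairs aggregate to the same interaction).
#'
#' @param link_table a link table.
#' @param taxonomy a [taxonomy_table()] covering every species in the table.
#' @param level `"genus"`, `"family"` or `"order"`.
#' @return Data frame with one row per retained link: `link_row` (row index
#'   into `link_table`), `interaction_id`, `plant_taxon`, `animal_taxon`.
#' @export
aggregate_links <- function(link_table, taxonomy,
                            level = c("genus", "family", "order")) {
  level <- match.arg(level)
  tax <- as.data.frame(taxonomy)
  lut <- setNames(tax[[level]], paste(tax$guild, tax$species))
  pt <- lut[paste("plant", link_table$plant)]
  at <- lut[paste("animal", link_table$animal)]
  missing <- unique(c(link_table$plant[is.na(pt)], link_table$animal[is.na(at)]))
  if (length(missing) > 0L) {
    stop("species missing from taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  id <- paste(pt, at, sep = " -- ")
  counts <- table(id)
  keep <- counts[id] >= 2L
  n_singletons <- sum(counts == 1L)
  if (n_singletons > 0L) {
    message(sprintf("dropped %d singleton interaction(s) at %s level",
                    n_singletons, level))
  }
  out <- data.frame(link_row = which(keep),
                    interaction_id = id[keep],
                    plant_taxon = unname(pt[keep]),
                    animal_taxon = unname(at[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, level = level, n_singletons = n_singletons)
}

#' Null-model variance test for one interaction
#'
#' Tests whether the links of an interaction have more similar property
#' values than random same-size sets: `n_null` null sets are drawn without
#' replacement from all other links' values (the focal interaction's links
#' are excluded from the pool), the sample variance (n-1 denominator) of each
#' is compared with the observed variance, and `P` is the proportion of null
#' sets with strictly lower variance than the observed set. Consistency is
#' significant when `P < 0.05`; the mean paired difference
#' `mean(Var_null - Var_obs)` is positive when the interaction is more
#' consistent than chance.
#'
#' @param values numeric vector of the property values of all links in the
#'   dataset (relative scale; see [rescale_relative()]).
#' @param group_rows integer indices into `values` identifying the focal
#'   interaction's links (>= 2).
#' @param n_null number of null sets.
#' @param seed optional integer seed.
#' @return Object of class `consistency_result`: list with `n_links`,
#'   `var_obs`, `mean_paired_diff`, `p_value`, `significant`, `n_null`,
#'   `seed`.
#' @export
null_variance_test <- function(values, group_rows, n_null = 1000L,
                               seed = NULL) {
  k <- length(group_rows)
  if (k < 2L) stop("interaction must have at least 2 links", call. = FALSE)
  g <- values[group_rows]
  rest <- values[-group_rows]
  if (length(rest) < k) {
    stop("insufficient pool: fewer remaining links than the group size",
         call. = FALSE)
  }
  if (anyNA(g) || anyNA(rest)) stop("missing property values", call. = FALSE)
  var_obs <- var(g)
  draw <- function() {
    idx <- vapply(seq_len(n_null),
                  function(i) sample.int(length(rest), k), integer(k))
    M <- matrix(rest[idx], nrow = k)
    apply(M, 2L, var)
  }
  var_null <- if (is.null(seed)) draw() else with_seed(seed, draw())
  p <- mean(var_null < var_obs)
  structure(
    list(n_links = k, var_obs = var_obs,
         mean_paired_diff = mean(var_null - var_obs),
         p_value = p, significant = p < 0.05,
         n_null = as.integer(n_null),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "consistency_result")
}

#' Taxonomic-consistency analysis over levels and properties
#'
#' Runs [null_variance_test()] for every aggregated interaction at each
#' requested taxonomic level and property, using per-interaction seeds
#' derived from the master seed. For `feasibility_contribution`, excluded
#' links (no `I_percent`) are dropped before aggregation.
#'
#' @param link_table a populated link table.
#' @param taxonomy a [taxonomy_table()].
#' @param levels character subset of `c("genus", "family", "order")`.
#' @param properties character subset of the [rescale_relative()] properties.
#' @param n_null number of null sets per interaction.
#' @param seed master integer seed.
#' @return Data frame with one row per (level, property, interaction):
#'   identification columns plus `n_links`, `var_obs`, `mean_paired_diff`,
#'   `p_value`, `significant`, `n_null`, `seed`.
#' @export
consistency_analysis <- function(link_table, taxonomy,
                                 levels = c("genus", "family", "order"),
                                 properties = c("vulnerability",
                                                "feasibility_contribution"),
                                 n_null = 1000L, seed = 1L) {
  rows <- list()
  for (property in properties) {
    vals_all <- rescale_relative(link_table, property)
    use <- !is.na(vals_all)
    sub <- link_table[use, , drop = FALSE]
    vals <- vals_all[use]
    for (level in levels) {
      agg <- aggregate_links(sub, taxonomy, level)
      for (iid in unique(agg$interaction_id)) {
        grp <- agg[agg$interaction_id == iid, , drop = FALSE]
        res <- tryCatch(
          null_variance_test(vals, grp$link_row, n_null = n_null,
                             seed = derive_seed(seed, property, level, iid)),
          error = function(e) NULL)
        if (is.null(res)) next   # insufficient pool for very large groups
        rows[[length(rows) + 1L]] <- data.frame(
          level = level, property = property, interaction_id = iid,
          plant_taxon = grp$plant_taxon[1L], animal_taxon = grp$animal_taxon[1L],
          n_links = res$n_links, var_obs = res$var_obs,
          mean_paired_diff = res$mean_paired_diff, p_value = res$p_value,
          significant = res$significant, n_null = res$n_null, seed = res$seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(level = character(0), property = character(0),
               interaction_id = character(0), plant_taxon = character(0),
               animal_taxon = character(0), n_links = integer(0),
               var_obs = numeric(0), mean_paired_diff = numeric(0),
               p_value = numeric(0), significant = logical(0),
               n_null = integer(0), seed = integer(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

#' Summarise consistency results per level and property
#'
#' @param results output of [consistency_analysis()].
#' @return Data frame with, per (level, property): `n_interactions`,
#'   `prop_positive` (share with `mean_paired_diff > 0`, i.e. observed
#'   variance below the null mean) and `prop_significant` (share with
#'   `P < 0.05`).
#' @export
consistency_summary <- function(results) {
  if (nrow(results) == 0L) stop("no consistency results to summarise",
                                call. = FALSE)
  keys <- unique(results[c("level", "property")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- results$level == keys$level[i] & results$property == keys$property[i]
    data.frame(level = keys$level[i], property = keys$property[i],
               n_interactions = sum(sel),
               prop_positive = mean(results$mean_paired_diff[sel] > 0),
               prop_significant = mean(results$significant[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
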