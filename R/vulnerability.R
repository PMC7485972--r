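#' Standardised link frequency of a network
#'
#' Link frequencies (visitation weights) are log10-transformed, then min-max
#' rescaled to `[0, 1]` within the network. If all frequencies are equal the
#' standardised value is 0.5 for every link (ties carry no ranking
#' information).
#'
#' @param net a [bipartite_network()].
#' @return Data frame with columns `plant`, `animal`, `f_std`, one row per
#'   link in canonical order.
#' @export
standardize_frequency <- function(net) {
  w <- net$weights
  pos <- which(w > 0, arr.ind = TRUE)
  df <- data.frame(plant = net$plant_names[pos[, 1L]],
                   animal = net$animal_names[pos[, 2L]],
                   weight = w[pos], stringsAsFactors = FALSE)
  df <- df[order(df$plant, df$animal, method = "radix"), , drop = FALSE]
  if (any(df$weight <= 0)) {
    stop("non-positive weight on a present link", call. = FALSE)
  }
  df$f_std <- unit_rescale(log10(df$weight))
  rownames(df) <- NULL
  df[c("plant", "animal", "f_std")]
}

#' Link generalisation of a network
#'
#' The generalisation of a link is the mean binary degree of its two endpoint
#' species (`D_raw`), min-max rescaled to `[0, 1]` within the network
#' (`D_std`, ties to 0.5). Degrees are presence-based, not weighted, and no
#' log transform is applied.
#'
#' @param net a [bipartite_network()].
#' @return Data frame with columns `plant`, `animal`, `D_raw`, `D_std`.
#' @export
link_generalisation <- function(net) {
  w <- net$weights
  deg <- species_degrees(net)
  pos <- which(w > 0, arr.ind = TRUE)
  df <- data.frame(plant = net$plant_names[pos[, 1L]],
                   animal = net$animal_names[pos[, 2L]],
                   D_raw = (deg$plants[pos[, 1L]] + deg$animals[pos[, 2L]]) / 2,
                   stringsAsFactors = FALSE)
  df <- df[order(df$plant, df$animal, method = "radix"), , drop = FALSE]
  df$D_std <- unit_rescale(df$D_raw)
  rownames(df) <- NULL
  df
}

#' Link vulnerability index
#'
#' `V = (1 - f_std) * (1 - D_std)`: the likelihood of a link being lost,
#' ranging from 0 (frequent link between generalists, least vulnerable) to 1
#' (rare link between specialists, most vulnerable).
#'
#' @param f_std standardised frequency in `[0, 1]` (vectorised).
#' @param D_std standardised generalisation in `[0, 1]` (vectorised).
#' @return Numeric vector of vulnerabilities in `[0, 1]`.
#' @export
vulnerability_index <- function(f_std, D_std) {
  if (any(f_std < 0 | f_std > 1 | D_std < 0 | D_std > 1, na.rm = TRUE)) {
    stop("standardised inputs must lie in [0, 1]", call. = FALSE)
  }
  (1 - f_std) * (1 - D_std)
}

#' Populate the vulnerability columns of a link table
#'
#' Computes `f_std`, `D_raw`, `D_std` and `V` network by network, using the
#' weights and binary endpoint degrees already present in the table.
#'
#' @param link_table a link table from [assemble_link_table()].
#' @return The link table with the four columns filled.
#' @export
add_vulnerability <- function(link_table) {
  if (nrow(link_table) == 0L) return(link_table)
  if (any(link_table$weight <= 0)) {
    stop("non-positive weight on a present link", call. = FALSE)
  }
  for (id in unique(link_table$network_id)) {
    sel <- link_table$network_id == id
    link_table$f_std[sel] <- unit_rescale(log10(link_table$weight[sel]))
    D_raw <- (link_table$d_plant[sel] + link_table$d_animal[sel]) / 2
    link_table$D_raw[sel] <- D_raw
    link_table$D_std[sel] <- unit_rescale(D_raw)
  }
  link_table$V <- vulnerability_index(link_table$f_std, link_table$D_std)
  link_table
}
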