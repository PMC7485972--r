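#' Weighted bipartite mutualistic network
#'
#' Container for one local network: a non-negative plant-by-animal weight
#' matrix (rows = plants, columns = animals) where `w[i, j]` is the visitation
#' count or rate between plant `i` and animal `j`, plus identifiers.
#'
#' Invariants enforced at construction: at least 2 species per guild, no
#' duplicated species names within a guild, every row and every column with at
#' least one strictly positive entry, and no negative or missing weights.
#'
#' @param weights numeric matrix of non-negative weights; dimnames are used as
#'   species names (default names are generated when absent).
#' @param network_id character identifier, unique within a collection.
#' @param network_type `"pollination"` or `"seed_dispersal"`.
#' @return An object of class `bipartite_network`: a list with elements
#'   `network_id`, `network_type`, `plant_names`, `animal_names`, `weights`.
#' @examples
#' w <- matrix(c(4, 1, 0, 2), 2, 2)
#' net <- bipartite_network(w, "toy", "pollination")
#' n_links(net)
#' @export
bipartite_network <- function(weights, network_id,
                              network_type = c("pollination", "seed_dispersal")) {
  network_type <- match.arg(network_type)
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(weights)) stop("`weights` contains missing values", call. = FALSE)
  if (any(weights < 0)) {
    stop("negative interaction weights are not allowed", call. = FALSE)
  }
  if (nrow(weights) < 2L || ncol(weights) < 2L) {
    stop("degenerate network: fewer than 2 species in a guild", call. = FALSE)
  }
  if (is.null(rownames(weights))) {
    rownames(weights) <- sprintf("Plant_%02d", seq_len(nrow(weights)))
  }
  if (is.null(colnames(weights))) {
    colnames(weights) <- sprintf("Animal_%02d", seq_len(ncol(weights)))
  }
  if (anyDuplicated(rownames(weights)) || anyDuplicated(colnames(weights))) {
    stop("duplicated species names within a guild", call. = FALSE)
  }
  if (any(rowSums(weights) == 0) || any(colSums(weights) == 0)) {
    stop("every species must have at least one positive link ",
         "(prune all-zero rows/columns first)", call. = FALSE)
  }
  structure(
    list(network_id = as.character(network_id),
         network_type = network_type,
         plant_names = rownames(weights),
         animal_names = colnames(weights),
         weights = weights),
    class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %s (%s): %d plants x %d animals, %d links\n",
              x$network_id, x$network_type, length(x$plant_names),
              length(x$animal_names), n_links(x)))
  invisible(x)
}

#' Number of links (positive cells) in a network
#' @param net a [bipartite_network()].
#' @return Integer count of strictly positive cells.
#' @export
n_links <- function(net) sum(net$weights > 0)

#' Binary species degrees of a network
#' @param net a [bipartite_network()].
#' @return List with named integer vectors `plants` and `animals`
#'   (presence-based degrees).
#' @export
species_degrees <- function(net) {
  L <- net$weights > 0
  list(plants = rowSums(L), animals = colSums(L))
}

## Drop all-zero rows/columns (iteratively is unnecessary: zero rows do not
## create zero columns), warning once per removed species.
prune_empty <- function(weights) {
  zr <- rowSums(weights) == 0
  zc <- colSums(weights) == 0
  for (nm in rownames(weights)[zr]) {
    warning(sprintf("removed plant '%s': no positive interactions", nm),
            call. = FALSE)
  }
  for (nm in colnames(weights)[zc]) {
    warning(sprintf("removed animal '%s': no positive interactions", nm),
            call. = FALSE)
  }
  weights[!zr, !zc, drop = FALSE]
}

#' Read a web-of-life style weighted incidence matrix
#'
#' Expects comma-separated UTF-8 text with animal names in the header row and
#' plant names in the first column; blank cells and `"0"` both mean absence.
#' All-zero rows/columns are pruned with a warning per removed species.
#'
#' @param path path to a CSV file.
#' @param network_id identifier to attach (defaults to the file base name).
#' @param network_type `"pollination"` or `"seed_dispersal"`.
#' @return A [bipartite_network()].
#' @export
read_incidence_matrix <- function(path, network_id = NULL,
                                  network_type = c("pollination", "seed_dispersal")) {
  network_type <- match.arg(network_type)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("incidence matrix needs at least one animal column",
                           call. = FALSE)
  plants <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (is.character(body[[j]])) {
      # blank cells mean absence; anything else must parse as a number
      body[[j]][!nzchar(trimws(body[[j]]))] <- "0"
      suppressWarnings(body[[j]] <- as.numeric(body[[j]]))
      if (anyNA(body[[j]])) {
        stop("non-numeric cell in incidence matrix body", call. = FALSE)
      }
    } else {
      # numeric columns: NA can only come from blank cells
      body[[j]] <- as.numeric(body[[j]])
      body[[j]][is.na(body[[j]])] <- 0
    }
  }
  w <- as.matrix(body)
  if (any(w < 0)) stop("negative entry in incidence matrix", call. = FALSE)
  rownames(w) <- plants
  w <- prune_empty(w)
  if (nrow(w) < 2L || ncol(w) < 2L) {
    stop("degenerate network after pruning: fewer than 2 species in a guild",
         call. = FALSE)
  }
  bipartite_network(w, network_id %||% sub("\\.[^.]*$", "", basename(path)),
                    network_type)
}

#' Write a network as a weighted incidence matrix CSV
#'
#' Inverse of [read_incidence_matrix()]: header row of animal names, first
#' column of plant names. Weights with exact decimal representations
#' round-trip bit-exactly.
#'
#' @param net a [bipartite_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_incidence_matrix <- function(net, path) {
  df <- data.frame(species = net$plant_names, net$weights,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Sampling intensity of a network
#'
#' Root of the mean number of interaction events per possible link:
#' `sqrt(sum(w) / (n_plants * n_animals))`. Used as a descriptor of how
#' thoroughly a community was sampled.
#'
#' @param net a [bipartite_network()].
#' @return A single non-negative number.
#' @export
sampling_intensity <- function(net) {
  sqrt(sum(net$weights) / (nrow(net$weights) * ncol(net$weights)))
}
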