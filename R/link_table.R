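## Canonical empty link table; downstream stages fill f_std, D_raw, D_std, V,
## I_percent and excluded.
empty_link_table <- function() {
  data.frame(network_id = character(0), network_type = character(0),
             plant = character(0), animal = character(0),
             weight = numeric(0), d_plant = integer(0), d_animal = integer(0),
             f_std = numeric(0), D_raw = numeric(0), D_std = numeric(0),
             V = numeric(0), I_percent = numeric(0), excluded = logical(0),
             stringsAsFactors = FALSE)
}

#' Assemble the per-link table of a network collection
#'
#' One record per strictly positive cell per network, in canonical order
#' (networks in input order; links sorted by plant then animal name within a
#' network). Binary endpoint degrees are attached; the property columns
#' (`f_std`, `D_raw`, `D_std`, `V`, `I_percent`, `excluded`) are initialised
#' to `NA` and populated by [add_vulnerability()] and [add_feasibility()].
#'
#' @param nets list of [bipartite_network()] objects with unique ids.
#' @return A data frame (link table); see Details.
#' @export
assemble_link_table <- function(nets) {
  if (length(nets) == 0L) return(empty_link_table())
  ids <- vapply(nets, function(n) n$network_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate network_id: ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "), call. = FALSE)
  }
  rows <- lapply(nets, function(net) {
    w <- net$weights
    pos <- which(w > 0, arr.ind = TRUE)
    deg <- species_degrees(net)
    df <- data.frame(
      network_id = net$network_id,
      network_type = net$network_type,
      plant = net$plant_names[pos[, 1L]],
      animal = net$animal_names[pos[, 2L]],
      weight = w[pos],
      d_plant = as.integer(deg$plants[pos[, 1L]]),
      d_animal = as.integer(deg$animals[pos[, 2L]]),
      stringsAsFactors = FALSE)
    df <- df[order(df$plant, df$animal, method = "radix"), , drop = FALSE]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$f_std <- NA_real_
  out$D_raw <- NA_real_
  out$D_std <- NA_real_
  out$V <- NA_real_
  out$I_percent <- NA_real_
  out$excluded <- NA
  out
}

#' Write a link table to CSV
#'
#' Missing `I_percent` (excluded links) is written as an empty cell.
#'
#' @param link_table a link table from [assemble_link_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_link_table <- function(link_table, path) {
  utils::write.csv(link_table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a link table written by [write_link_table()]
#' @param path CSV file path.
#' @return A link table data frame.
#' @export
read_link_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$excluded <- as.logical(df$excluded)
  df
}
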