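#' Taxonomy table
#'
#' Validates a species-to-taxonomy mapping with columns `species`, `guild`
#' (`"plant"` or `"animal"`), `genus`, `family`, `order`. Species names must
#' be unique within a guild, and the genus-to-family and family-to-order
#' mappings must each be functions (a genus belongs to exactly one family, a
#' family to exactly one order).
#'
#' @param df data frame with the five columns above.
#' @return The validated data frame with class `taxonomy_table` prepended.
#' @export
taxonomy_table <- function(df) {
  need <- c("species", "guild", "genus", "family", "order")
  if (!all(need %in% names(df))) {
    stop("taxonomy needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  for (nm in need) df[[nm]] <- as.character(df[[nm]])
  if (!all(df$guild %in% c("plant", "animal"))) {
    stop("guild must be 'plant' or 'animal'", call. = FALSE)
  }
  if (anyDuplicated(df[c("species", "guild")])) {
    stop("species names must be unique within a guild", call. = FALSE)
  }
  g2f <- unique(df[c("genus", "family")])
  if (anyDuplicated(g2f$genus)) {
    stop("each genus must map to exactly one family", call. = FALSE)
  }
  f2o <- unique(df[c("family", "order")])
  if (anyDuplicated(f2o$family)) {
    stop("each family must map to exactly one order", call. = FALSE)
  }
  class(df) <- c("taxonomy_table", class(df))
  df
}

#' Read a taxonomy CSV
#'
#' @param path CSV with columns `species,guild,genus,family,order`.
#' @return A [taxonomy_table()].
#' @export
read_taxonomy <- function(path) {
  taxonomy_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a taxonomy table to CSV
#' @param taxonomy a [taxonomy_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.csv(as.data.frame(unclass(taxonomy)), path, row.names = FALSE)
  invisible(path)
}
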