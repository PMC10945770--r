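#' Read a species map table
#'
#' Tab-separated file with header columns `label` (leaf label) and `species`.
#'
#' @param path File path.
#' @return Data frame with character columns `label` and `species`.
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("label", "species") %in% names(df))) {
    stop("species map file needs header columns 'label' and 'species'")
  }
  df$label <- as.character(df$label)
  df$species <- as.character(df$species)
  df
}

#' Read a species-keyed trait table
#'
#' Tab- or comma-separated (by file extension) table with a `species` column
#' and numeric trait columns; missing values as `NA` or empty fields.
#'
#' @param path File path (`.csv` is read as comma-separated, anything else as
#'   tab-separated).
#' @return Data frame with one row per species.
#' @export
read_trait_table <- function(path) {
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!"species" %in% names(df)) stop("trait table needs a 'species' column")
  if (anyDuplicated(df$species)) {
    stop("trait table has duplicated species: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  }
  df
}

#' Read a per-species distance table
#'
#' Tab-separated file with header columns `species` and `distance`
#' (root-to-tip distance in substitutions per site).
#'
#' @param path File path.
#' @return Named numeric vector (species -> distance).
#' @export
read_distance_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("species", "distance") %in% names(df))) {
    stop("distance table needs header columns 'species' and 'distance'")
  }
  out <- as.numeric(df$distance)
  names(out) <- as.character(df$species)
  out
}

#' Write a data frame as TSV
#'
#' Tab separation, `.` decimal, `NA` for missing, no quoting or row names —
#' the package's standard tabular output format.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
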