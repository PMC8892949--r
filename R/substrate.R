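#' Substrate categories recognized in rearing tables
#' @export
substrate_categories <- function() {
  c("bark", "leaf", "sap", "fungus", "flower", "fruit", "spider egg mass",
    "generalist", "unknown")
}

#' Classify one species' oviposition substrate from rearing records
#'
#' A species is a *generalist* if any two substrate categories each comprise
#' more than 1/4 of its rearing records, or if no category comprises more
#' than 2/3 of them; otherwise it is a *specialist* in the unique category
#' exceeding 2/3. A species with no records is *unknown*.
#'
#' @param counts Named nonnegative numeric vector of rearing-record counts
#'   per substrate category.
#' @return List with `class` (`"specialist"`, `"generalist"` or
#'   `"unknown"`) and `category` (the specialist substrate, else `NA`).
#' @examples
#' classify_substrate(c(bark = 10))                     # specialist(bark)
#' classify_substrate(c(bark = 5, leaf = 5))            # generalist
#' classify_substrate(c(bark = 7, leaf = 2, fungus = 1))# specialist(bark)
#' @export
classify_substrate <- function(counts) {
  if (any(counts < 0)) stop("negative rearing-record count")
  total <- sum(counts)
  if (total == 0) return(list(class = "unknown", category = NA_character_))
  frac <- counts / total
  if (sum(frac > 1 / 4) >= 2 || !any(frac > 2 / 3)) {
    return(list(class = "generalist", category = NA_character_))
  }
  list(class = "specialist", category = names(counts)[which(frac > 2 / 3)])
}

#' Classify every species in a rearing table
#'
#' @param rearing Data frame with columns `species`, `substrate`, `count`
#'   (long format; one row per species x substrate). Substrates outside
#'   [substrate_categories()] are mapped to `"other"` with a warning.
#' @return Tibble with `species`, `class` and `category`; `state` combines
#'   them into a single trait value (the specialist category, or
#'   `"generalist"` / `"unknown"`), ready for Mk fitting.
#' @export
classify_substrates <- function(rearing) {
  rearing <- as_tibble(rearing)
  known <- setdiff(substrate_categories(), c("generalist", "unknown"))
  odd <- setdiff(unique(rearing$substrate), known)
  if (length(odd) > 0) {
    warning("unlisted substrate(s) mapped to 'other': ",
            paste(odd, collapse = ", "))
    rearing$substrate[rearing$substrate %in% odd] <- "other"
  }
  purrr::map_dfr(split(rearing, rearing$species), function(df) {
    counts <- tapply(df$count, df$substrate, sum)
    cl <- classify_substrate(counts)
    tibble(species = df$species[1], class = cl$class,
           category = cl$category %||% NA_character_,
           state = if (cl$class == "specialist") cl$category else cl$class)
  })
}

#' Read/write a rearing-record table (CSV: species, substrate, count)
#'
#' @param path File path.
#' @return Tibble (read) or `path` invisibly (write).
#' @export
read_rearing_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "substrate", "count") %in% names(df)))
  if (any(df$count < 0)) stop("negative rearing-record count")
  as_tibble(df)
}

#' @rdname read_rearing_table
#' @param rearing Rearing tibble.
#' @export
write_rearing_table <- function(rearing, path) {
  utils::write.csv(as.data.frame(rearing), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
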