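#' Animal-by-region c-Fos density tables
#'
#' A `density_table` couples per-animal metadata with an animals x regions
#' matrix of c-Fos+ cell densities (cells/mm^2). Each animal belongs to one
#' of four groups defined by the crossing of `stimulation` (sham/active)
#' and `time` (acute/chronic). Densities are non-negative reals; missing
#' cells are `NA` and propagate as pairwise-complete observations in
#' correlations and as dropped rows in per-region model fits.
#'
#' @section Structure:
#' A list with components:
#' \describe{
#'   \item{animals}{data frame: `animal_id`, `stimulation` (factor
#'     sham/active), `time` (factor acute/chronic), `sex` (M/F/unknown).}
#'   \item{regions}{character vector of region acronyms, in ontology order.}
#'   \item{values}{numeric matrix, `length(animal_id)` x `length(regions)`,
#'     `NA` = missing, dimnames set.}
#' }
#' @name density_table
NULL

stim_levels <- function() c("sham", "active")
time_levels <- function() c("acute", "chronic")

new_density_table <- function(animals, regions, values) {
  stopifnot(is.data.frame(animals), is.character(regions), is.matrix(values))
  stopifnot(nrow(values) == nrow(animals), ncol(values) == length(regions))
  if (anyDuplicated(animals$animal_id)) {
    stop("duplicate animal_id: ",
         paste(unique(animals$animal_id[duplicated(animals$animal_id)]),
               collapse = ", "))
  }
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative density for animal '", animals$animal_id[neg[1, 1]],
         "', region '", regions[neg[1, 2]], "'")
  }
  dimnames(values) <- list(animals$animal_id, regions)
  out <- list(animals = animals, regions = regions, values = values)
  class(out) <- "density_table"
  out
}

#' Load an animal-by-region density table from a wide CSV
#'
#' Expected wide format: columns `animal_id`, `stimulation`, `time`,
#' optionally `sex`, then one column per region acronym. Empty cells are
#' missing. Region columns are restricted to, and reordered to follow, the
#' ontology; unparseable numeric cells become missing with a warning
#' giving the count.
#'
#' @param path CSV path.
#' @param ontology A `region_ontology` (see [load_ontology()]).
#' @return A `density_table`.
#' @export
load_density_table <- function(path, ontology) {
  stopifnot(inherits(ontology, "region_ontology"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         encoding = "UTF-8", colClasses = "character")
  meta_cols <- c("animal_id", "stimulation", "time")
  missing_cols <- setdiff(meta_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("density CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!nzchar(raw$stimulation)) || any(!nzchar(raw$time))) {
    stop("animal(s) with no group labels: ",
         paste(raw$animal_id[!nzchar(raw$stimulation) | !nzchar(raw$time)],
               collapse = ", "))
  }
  bad_stim <- setdiff(unique(raw$stimulation), stim_levels())
  bad_time <- setdiff(unique(raw$time), time_levels())
  if (length(bad_stim) > 0) stop("unknown stimulation level(s): ",
                                 paste(bad_stim, collapse = ", "))
  if (length(bad_time) > 0) stop("unknown time level(s): ",
                                 paste(bad_time, collapse = ", "))
  animals <- data.frame(
    animal_id   = raw$animal_id,
    stimulation = factor(raw$stimulation, levels = stim_levels()),
    time        = factor(raw$time, levels = time_levels()),
    sex         = if ("sex" %in% names(raw)) {
      ifelse(raw$sex %in% c("M", "F"), raw$sex, "unknown")
    } else "unknown",
    stringsAsFactors = FALSE
  )
  regions <- intersect(ontology$acronym, names(raw))  # ontology order
  if (length(regions) == 0) stop("no region columns match the ontology")
  vals_chr <- as.matrix(raw[, regions, drop = FALSE])
  vals_chr[!nzchar(trimws(vals_chr))] <- NA_character_
  suppressWarnings(vals <- matrix(as.numeric(vals_chr), nrow = nrow(vals_chr)))
  n_unparseable <- sum(is.na(vals) & !is.na(vals_chr))
  if (n_unparseable > 0) {
    warning(n_unparseable, " unparseable density cell(s) set to missing")
  }
  neg <- which(!is.na(vals) & vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative density at row ", neg[1, 1], " (animal '",
         animals$animal_id[neg[1, 1]], "'), column '", regions[neg[1, 2]], "'")
  }
  new_density_table(animals, regions, vals)
}

#' Write a density table back to the wide CSV format
#'
#' Inverse of [load_density_table()]: all non-missing values round-trip
#' bit-exactly (full-precision decimal representation).
#'
#' @param table A `density_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_table <- function(table, path) {
  stopifnot(inherits(table, "density_table"))
  vals <- table$values
  chr <- matrix(vapply(vals, function(v) {
    if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1)), nrow = nrow(vals), dimnames = dimnames(vals))
  out <- cbind(table$animals[, c("animal_id", "stimulation", "time", "sex")],
               as.data.frame(chr, stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

group_labels <- function(animals) {
  interaction(animals$time, animals$stimulation, sep = "-", drop = FALSE)
}

#' Exclude regions with too few observations in any group
#'
#' A region is retained only if every one of the four stimulation-by-time
#' groups has at least `min_n` non-missing values for it. The operation is
#' idempotent.
#'
#' @param table A `density_table` with at least one animal per group.
#' @param min_n Minimum per-group non-missing count (default 3).
#' @return A list: `table` (filtered `density_table`) and `excluded`
#'   (sorted character vector of dropped acronyms).
#' @export
filter_regions_min_group_count <- function(table, min_n = 3) {
  stopifnot(inherits(table, "density_table"))
  g <- group_labels(table$animals)
  if (any(table(g) == 0)) {
    stop("density table must contain at least one animal in each of the four groups")
  }
  counts <- rowsum((!is.na(table$values)) * 1L, group = g)
  keep <- apply(counts >= min_n, 2, all)
  excluded <- sort(table$regions[!keep])
  filtered <- new_density_table(table$animals,
                                table$regions[keep],
                                table$values[, keep, drop = FALSE])
  list(table = filtered, excluded = excluded)
}

#' @export
print.density_table <- function(x, ...) {
  g <- table(group_labels(x$animals))
  cat("Density table:", nrow(x$animals), "animals x", length(x$regions),
      "regions (", sum(is.na(x$values)), "missing cells )\n")
  print(g)
  invisible(x)
}
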