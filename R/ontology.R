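#' Region ontology: acronyms and higher-order classifications
#'
#' A `region_ontology` maps short region acronyms (e.g. `"VISp"`) to full
#' names and to one of ten higher-order anatomical classifications used to
#' organise brain-wide results: isocortex (`ISO`), hippocampal formation
#' (`HPF`), amygdala (`AMYG`), striatum (`STR`), pallidum (`PAL`),
#' cerebellum (`CB`), thalamus (`TH`), hypothalamus (`HY`), midbrain
#' (`MB`) and hindbrain (`HB`). The order of entries is meaningful: density
#' tables and correlation matrices follow it, so two analyses built on the
#' same ontology are directly comparable row-for-row.
#'
#' @param path Path to an ontology CSV with columns `acronym`, `full_name`,
#'   `higher_order`.
#' @return A `region_ontology`: a data frame with columns `acronym`,
#'   `full_name`, `higher_order` (factor over the 10 classifications),
#'   entries in file order.
#' @examples
#' ont <- load_ontology(default_ontology_path())
#' nrow(ont)            # 115
#' table(ont$higher_order)
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) {
    stop("ontology file not found: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("acronym", "full_name", "higher_order")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("ontology file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- df$acronym[duplicated(df$acronym)]
  if (length(dup) > 0) {
    stop("duplicate region acronym(s) in ontology: ",
         paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(df$higher_order), higher_order_levels())
  if (length(bad) > 0) {
    stop("unknown higher-order classification(s): ",
         paste(bad, collapse = ", "),
         " (expected one of ", paste(higher_order_levels(), collapse = ", "), ")")
  }
  out <- data.frame(
    acronym      = as.character(df$acronym),
    full_name    = as.character(df$full_name),
    higher_order = factor(df$higher_order, levels = higher_order_levels()),
    stringsAsFactors = FALSE
  )
  class(out) <- c("region_ontology", "data.frame")
  out
}

#' The ten higher-order anatomical classifications, in display order
#' @return Character vector of length 10.
#' @export
higher_order_levels <- function() {
  c("ISO", "HPF", "AMYG", "STR", "PAL", "CB", "TH", "HY", "MB", "HB")
}

#' Path to the bundled default ontology
#'
#' The package ships a default 115-region ontology
#' (`default_regions_synthetic.csv`): a synthetic, package-curated
#' selection of Allen Mouse Brain Atlas acronyms spanning all ten
#' higher-order classifications. It is a convenient stand-in for a study's
#' own region list, not a published one; studies should normally supply
#' their own file so that matrix ordering matches their reports.
#'
#' @return Path to the packaged CSV.
#' @export
default_ontology_path <- function() {
  system.file("extdata", "default_regions_synthetic.csv",
              package = "fosnet", mustWork = TRUE)
}

#' @export
print.region_ontology <- function(x, ...) {
  cat("Region ontology:", nrow(x), "regions across",
      nlevels(droplevels(x$higher_order)), "higher-order classifications\n")
  print(table(x$higher_order))
  invisible(x)
}
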