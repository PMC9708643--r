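#' Group-wise inter-regional correlation network
#'
#' Builds the functional connectivity network for one stimulation-by-time
#' group: the Pearson correlation of c-Fos density across the group's
#' animals, for every pair of regions, over pairwise-complete
#' observations. Two-tailed p-values use the exact t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with \eqn{n - 2} degrees of freedom,
#' where \eqn{n} is the pair's complete-observation count. Pairs with an
#' undefined correlation (zero variance, or fewer than 3 complete
#' observations) are flagged: r is stored as 0 and p as 1, so a
#' degenerate region can never become an edge or abort a network.
#'
#' @param table A `density_table`.
#' @param stimulation `"sham"` or `"active"`.
#' @param time `"acute"` or `"chronic"`.
#' @return A `correlation_network`: list with `regions`, `r`, `p`,
#'   `n_pairs`, `undefined` (logical matrix), `group`, `n_animals`.
#' @export
group_correlation <- function(table, stimulation, time) {
  stopifnot(inherits(table, "density_table"))
  stimulation <- match.arg(stimulation, stim_levels())
  time <- match.arg(time, time_levels())
  sel <- table$animals$stimulation == stimulation & table$animals$time == time
  if (sum(sel) < 3) stop("need at least 3 animals in group ",
                         time, "-", stimulation)
  V <- table$values[sel, , drop = FALSE]
  R <- ncol(V)
  obs <- !is.na(V)
  n_pairs <- crossprod(obs * 1L)
  suppressWarnings(r <- stats::cor(V, use = "pairwise.complete.obs"))
  undefined <- !is.finite(r) | n_pairs < 3
  r[undefined] <- 0
  df <- n_pairs - 2
  tstat <- r * sqrt(pmax(df, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- matrix(1, R, R)
  okdf <- df >= 1 & !undefined
  p[okdf] <- 2 * stats::pt(-abs(tstat[okdf]), df[okdf])
  p[p > 1] <- 1
  diag(r) <- 1; diag(p) <- 1; diag(undefined) <- FALSE
  dimnames(r) <- dimnames(p) <- dimnames(n_pairs) <- dimnames(undefined) <-
    list(table$regions, table$regions)
  if (any(undefined[upper.tri(undefined)])) {
    warning(sum(undefined[upper.tri(undefined)]),
            " region pair(s) with undefined correlation (zero variance or n < 3)")
  }
  structure(list(regions = table$regions, r = r, p = p, n_pairs = n_pairs,
                 undefined = undefined,
                 group = paste(time, stimulation, sep = "-"),
                 n_animals = sum(sel)),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Correlation network:", x$group, "(", x$n_animals, "animals ),",
      length(x$regions), "regions\n")
  invisible(x)
}

#' Filter network edges by significance and FDR
#'
#' An edge is retained when its two-tailed p-value passes the chosen
#' filter; its sign is the sign of r. The default filter is the
#' conjunction of a raw alpha threshold (p < `alpha`) and a
#' Benjamini-Hochberg step-up at `fdr_q` over all R(R-1)/2 p-values;
#' alpha-only and FDR-only variants are available because the combined
#' convention varies between analyses.
#'
#' @param net A `correlation_network`.
#' @param alpha Raw significance threshold (default 0.005).
#' @param fdr_q BH FDR level over all pairs (default 0.05).
#' @param mode `"conjunction"` (default), `"alpha_only"`, or `"fdr_only"`.
#' @return An `edge_mask`: list with `regions`, `mask` (R x R matrix of
#'   -1/0/+1), and the filter parameters.
#' @export
filter_edges <- function(net, alpha = 0.005, fdr_q = 0.05,
                         mode = c("conjunction", "alpha_only", "fdr_only")) {
  stopifnot(inherits(net, "correlation_network"))
  mode <- match.arg(mode)
  R <- length(net$regions)
  ut <- upper.tri(net$p)
  pv <- net$p[ut]
  pass_alpha <- pv < alpha
  pass_fdr <- bh_fdr(pv, fdr_q)
  pass <- switch(mode,
                 conjunction = pass_alpha & pass_fdr,
                 alpha_only = pass_alpha,
                 fdr_only = pass_fdr)
  pass <- pass & !net$undefined[ut]
  m <- matrix(0L, R, R, dimnames = dimnames(net$p))
  m[ut][pass] <- as.integer(sign(net$r[ut][pass]))
  m <- m + t(m)
  structure(list(regions = net$regions, mask = m,
                 alpha = alpha, fdr_q = fdr_q, mode = mode,
                 group = net$group),
            class = "edge_mask")
}

#' Network density of signed edges
#'
#' The proportion of actual connections relative to the number possible
#' in a fully saturated network: the count of region pairs carrying an
#' edge of the requested sign divided by R(R-1)/2.
#'
#' @param mask An `edge_mask`.
#' @param sign `"positive"`, `"negative"` or `"any"`.
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(mask, sign = c("any", "positive", "negative")) {
  stopifnot(inherits(mask, "edge_mask"))
  sign <- match.arg(sign)
  R <- length(mask$regions)
  if (R < 2) stop("need at least 2 regions")
  ut <- mask$mask[upper.tri(mask$mask)]
  k <- switch(sign,
              any = sum(ut != 0),
              positive = sum(ut > 0),
              negative = sum(ut < 0))
  k / (R * (R - 1) / 2)
}

#' Summary density statistics for a filtered network
#'
#' @param net A `correlation_network`.
#' @param mask The matching `edge_mask`.
#' @return A `network_density_stats` list: region/pair counts, signed
#'   edge counts and densities, and the mean Pearson coefficient over
#'   all defined pairs and over significant edges (both reported because
#'   either convention is seen in practice).
#' @export
network_density_stats <- function(net, mask) {
  stopifnot(inherits(net, "correlation_network"), inherits(mask, "edge_mask"))
  R <- length(net$regions)
  ut <- upper.tri(net$r)
  m <- mask$mask[ut]
  r <- net$r[ut]
  defined <- !net$undefined[ut]
  npot <- R * (R - 1) / 2
  structure(list(
    group = net$group,
    n_regions = R, n_potential = npot,
    positive_edges = sum(m > 0), negative_edges = sum(m < 0),
    positive_density = sum(m > 0) / npot,
    negative_density = sum(m < 0) / npot,
    mean_r_all = if (any(defined)) mean(r[defined]) else NA_real_,
    mean_r_significant = if (any(m != 0)) mean(r[m != 0]) else NA_real_
  ), class = "network_density_stats")
}

#' @export
print.network_density_stats <- function(x, ...) {
  cat(sprintf("Network density [%s]: %d regions, %d pairs\n",
              x$group, x$n_regions, x$n_potential))
  cat(sprintf("  positive: %d edges, density %.5f\n",
              x$positive_edges, x$positive_density))
  cat(sprintf("  negative: %d edges, density %.5f\n",
              x$negative_edges, x$negative_density))
  cat(sprintf("  mean r (all defined pairs): %.4f; (significant edges): %.4f\n",
              x$mean_r_all, x$mean_r_significant))
  invisible(x)
}

#' Ratio of an active-group density to its sham counterpart
#'
#' @param active,sham Densities (sham must be positive; zero gives `NA`).
#' @return `active / sham`, or `NA` when undefined.
#' @export
density_ratio <- function(active, sham) {
  ifelse(is.na(sham) | sham == 0, NA_real_, active / sham)
}

#' Compare sham and active network density statistics
#'
#' Pairs the signed densities of two networks over the same region set
#' and reports ratios (active/sham) and edge-count deltas. A zero sham
#' density yields a missing ratio but the delta is still reported.
#'
#' @param sham,active `network_density_stats` objects.
#' @return A `network_comparison` data frame: one row per sign with
#'   sham/active densities, ratio, and edge-count delta.
#' @export
compare_networks <- function(sham, active) {
  stopifnot(inherits(sham, "network_density_stats"),
            inherits(active, "network_density_stats"))
  if (sham$n_regions != active$n_regions ||
      sham$n_potential != active$n_potential) {
    stop("networks cover different region sets")
  }
  out <- data.frame(
    sign = c("positive", "negative"),
    sham_density = c(sham$positive_density, sham$negative_density),
    active_density = c(active$positive_density, active$negative_density),
    ratio = c(density_ratio(active$positive_density, sham$positive_density),
              density_ratio(active$negative_density, sham$negative_density)),
    edge_delta = c(active$positive_edges - sham$positive_edges,
                   active$negative_edges - sham$negative_edges),
    stringsAsFactors = FALSE
  )
  class(out) <- c("network_comparison", "data.frame")
  out
}

#' Signed edge counts aggregated by higher-order classification blocks
#'
#' Aggregates an edge mask into the 10 x 10 grid of higher-order
#' classification pairs (diagonal blocks = within-classification edges).
#' Block sums over all pairs conserve the total signed edge counts.
#'
#' @param mask An `edge_mask`.
#' @param ontology A `region_ontology` covering all mask regions.
#' @return A data frame with columns `block_a`, `block_b` (block_a <=
#'   block_b in ontology order), `positive_edges`, `negative_edges`.
#' @export
hierarchical_block_summary <- function(mask, ontology) {
  stopifnot(inherits(mask, "edge_mask"), inherits(ontology, "region_ontology"))
  missing_r <- setdiff(mask$regions, ontology$acronym)
  if (length(missing_r) > 0) {
    stop("region(s) missing from ontology: ", paste(missing_r, collapse = ", "))
  }
  ho <- ontology$higher_order[match(mask$regions, ontology$acronym)]
  lv <- higher_order_levels()
  idx <- as.integer(factor(ho, levels = lv))
  pos <- matrix(0L, 10, 10, dimnames = list(lv, lv))
  neg <- matrix(0L, 10, 10, dimnames = list(lv, lv))
  R <- length(mask$regions)
  ut <- which(upper.tri(mask$mask) & mask$mask != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(ut))) {
    a <- min(idx[ut[k, 1]], idx[ut[k, 2]])
    b <- max(idx[ut[k, 1]], idx[ut[k, 2]])
    if (mask$mask[ut[k, 1], ut[k, 2]] > 0) pos[a, b] <- pos[a, b] + 1L
    else neg[a, b] <- neg[a, b] + 1L
  }
  grid <- which(upper.tri(pos, diag = TRUE), arr.ind = TRUE)
  data.frame(
    block_a = lv[grid[, 1]], block_b = lv[grid[, 2]],
    positive_edges = pos[grid], negative_edges = neg[grid],
    stringsAsFactors = FALSE
  )
}
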