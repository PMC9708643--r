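#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> per-region density screen ->
#' group connectivity networks -> co-expression analysis as one
#' reproducible run. Inputs are either file paths (`density_csv`,
#' `coexpression_csv`) or a `synthetic_config`, never both. Each stage's
#' outputs are written under `out_dir`; stage failures are recorded in
#' the report and independent stages still run.
#'
#' @param out_dir Output directory (created if needed).
#' @param density_csv,coexpression_csv Paths to real input tables
#'   (wide density CSV and long co-expression CSV), or `NULL`.
#' @param synthetic A `synthetic_config`, or `NULL`. Exactly one of
#'   real paths / synthetic config must be supplied.
#' @param ontology A `region_ontology`; defaults to the packaged one
#'   when loading real density data.
#' @param screen A `screen_config`.
#' @param alpha,fdr_q,edge_mode Edge filter parameters for the networks
#'   (see [filter_edges()]).
#' @param stages Character subset of `c("density", "network",
#'   "coexpression")`.
#' @param pv_counts,p_active Forwarded to [generate_coexpression()] for
#'   synthetic runs (defaults: 40 PV cells per higher-order region,
#'   co-expression probability 0.3).
#' @return A `run_report`: file manifest, parameter echo, warnings, and
#'   a summary block (significant-region count, per-group density stats,
#'   density ratios, ANOVA headline, top-|g| regions). Also written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(out_dir,
                         density_csv = NULL, coexpression_csv = NULL,
                         synthetic = NULL,
                         ontology = NULL,
                         screen = screen_config(),
                         alpha = 0.005, fdr_q = 0.05,
                         edge_mode = "conjunction",
                         stages = c("density", "network", "coexpression"),
                         pv_counts = NULL, p_active = 0.3) {
  real_in <- !is.null(density_csv) || !is.null(coexpression_csv)
  if (real_in == !is.null(synthetic)) {
    stop("supply exactly one of: real input paths, or a synthetic config")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  manifest <- character(0)
  warn <- character(0)
  summary_block <- list()
  note <- function(msg) warn <<- c(warn, msg)
  emit <- function(name) {
    manifest <<- c(manifest, name)
    file.path(out_dir, name)
  }

  if (is.null(ontology)) ontology <- load_ontology(default_ontology_path())

  dens <- NULL
  coex <- NULL
  if (!is.null(synthetic)) {
    sim <- generate_cohort(synthetic)
    dens <- sim$table
    write_density_table(dens, emit("density.csv"))
    jsonlite::write_json(
      list(group_means = sim$truth$group_means,
           negative_pairs = sim$truth$negative_pairs,
           seed = synthetic$seed),
      emit("truth.json"), auto_unbox = TRUE, digits = NA)
    if ("coexpression" %in% stages) {
      if (is.null(pv_counts)) {
        pv_counts <- stats::setNames(rep(40L, 10), higher_order_levels())
      }
      co <- generate_coexpression(synthetic, pv_counts, p_active)
      coex <- co$table
      utils::write.csv(
        coex[, c("animal_id", "stimulation", "time", "region",
                 "pv_count", "copositive_count")],
        emit("coexpression.csv"), row.names = FALSE)
    }
  } else {
    if (!is.null(density_csv)) {
      dens <- withCallingHandlers(
        load_density_table(density_csv, ontology),
        warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    }
    if (!is.null(coexpression_csv)) coex <- load_coexpression_table(coexpression_csv)
  }

  if ("density" %in% stages && !is.null(dens)) {
    res <- tryCatch({
      scr <- analyze_brainwide(dens, screen)
      utils::write.csv(scr$summary, emit("region_screen.csv"), row.names = FALSE)
      summary_block$n_regions_analysed <- nrow(scr$summary)
      summary_block$n_regions_excluded <- length(scr$excluded_regions)
      summary_block$n_omnibus_significant <-
        sum(scr$summary$omnibus_significant, na.rm = TRUE)
      summary_block$n_cook_excluded <- sum(scr$summary$n_cook_excluded)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) note(paste("density stage failed:", res))
  }

  if ("network" %in% stages && !is.null(dens)) {
    res <- tryCatch({
      stats_by_group <- list()
      for (tl in time_levels()) for (st in stim_levels()) {
        g <- paste(tl, st, sep = "-")
        net <- withCallingHandlers(
          group_correlation(dens, st, tl),
          warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
        mask <- filter_edges(net, alpha = alpha, fdr_q = fdr_q, mode = edge_mode)
        st_g <- network_density_stats(net, mask)
        stats_by_group[[g]] <- st_g
        utils::write.csv(as.data.frame(net$r), emit(paste0("r_", g, ".csv")))
        utils::write.csv(as.data.frame(net$p), emit(paste0("p_", g, ".csv")))
        el <- which(upper.tri(mask$mask) & mask$mask != 0, arr.ind = TRUE)
        utils::write.csv(data.frame(
          region_a = net$regions[el[, 1]], region_b = net$regions[el[, 2]],
          r = net$r[el], p = net$p[el], sign = mask$mask[el]),
          emit(paste0("edges_", g, ".csv")), row.names = FALSE)
        if (all(net$regions %in% ontology$acronym)) {
          utils::write.csv(hierarchical_block_summary(mask, ontology),
                           emit(paste0("blocks_", g, ".csv")), row.names = FALSE)
        } else {
          note(paste0("block summary skipped for ", g,
                      ": regions not covered by the ontology"))
        }
      }
      dens_stats <- lapply(stats_by_group, function(s)
        list(positive_edges = s$positive_edges, negative_edges = s$negative_edges,
             positive_density = s$positive_density,
             negative_density = s$negative_density,
             mean_r_all = s$mean_r_all,
             mean_r_significant = s$mean_r_significant))
      summary_block$network_density <- dens_stats
      ratios <- list()
      for (tl in time_levels()) {
        cmp <- compare_networks(stats_by_group[[paste0(tl, "-sham")]],
                                stats_by_group[[paste0(tl, "-active")]])
        ratios[[tl]] <- stats::setNames(as.list(cmp$ratio), cmp$sign)
      }
      summary_block$density_ratios <- ratios
      jsonlite::write_json(dens_stats, emit("network_density.json"),
                           auto_unbox = TRUE, digits = NA)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) note(paste("network stage failed:", res))
  }

  if ("coexpression" %in% stages && !is.null(coex)) {
    res <- tryCatch({
      for (tl in time_levels()) {
        sub <- coex[coex$time == tl, , drop = FALSE]
        if (nrow(sub) == 0) next
        an <- two_way_anova(sub$percent, sub$stimulation, sub$region)
        utils::write.csv(an, emit(paste0("anova_", tl, ".csv")), row.names = FALSE)
        prof <- effect_profile(coex, tl)
        utils::write.csv(prof, emit(paste0("effect_profile_", tl, ".csv")),
                         row.names = FALSE)
        summary_block[[paste0("anova_", tl)]] <- list(
          F_stimulation = an$F[an$effect == "stimulation"],
          df = c(an$df[an$effect == "stimulation"],
                 an$df[an$effect == "residual"]),
          p_stimulation = an$p[an$effect == "stimulation"])
        top <- utils::head(prof$region[!is.na(prof$g_abs)], 3)
        summary_block[[paste0("top_g_regions_", tl)]] <- top
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) note(paste("coexpression stage failed:", res))
  }

  params <- list(
    stages = stages, alpha = alpha, fdr_q = fdr_q, edge_mode = edge_mode,
    screen = unclass(screen),
    seed = if (!is.null(synthetic)) synthetic$seed else NULL,
    inputs = if (!is.null(synthetic)) "synthetic"
             else c(density_csv = density_csv, coexpression_csv = coexpression_csv)
  )
  report <- structure(list(manifest = manifest, parameters = params,
                           warnings = warn, summary = summary_block),
                      class = "run_report")
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", length(x$manifest), "artifact(s),",
      length(x$warnings), "warning(s)\n")
  if (!is.null(x$summary$n_omnibus_significant)) {
    cat("  regions analysed:", x$summary$n_regions_analysed,
        "| omnibus-significant:", x$summary$n_omnibus_significant, "\n")
  }
  if (!is.null(x$summary$density_ratios)) {
    for (tl in names(x$summary$density_ratios)) {
      r <- x$summary$density_ratios[[tl]]
      cat(sprintf("  %s density ratio (active/sham): positive %.2f, negative %.2f\n",
                  tl, r$positive, r$negative))
    }
  }
  invisible(x)
}
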