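#' Parvalbumin/c-Fos co-expression tables
#'
#' A `coexpression_table` is a long data frame with one row per animal
#' and higher-order region: `animal_id`, `stimulation`, `time`,
#' `region`, `pv_count` (PV+ cells), `copositive_count` (cells both PV+
#' and c-Fos+) and `percent` (100 * copositive / pv; `NA` when
#' `pv_count` is 0, an undefined proportion).
#'
#' @param df Data frame with the columns above except `percent`.
#' @return A validated `coexpression_table`.
#' @export
as_coexpression_table <- function(df) {
  need <- c("animal_id", "stimulation", "time", "region",
            "pv_count", "copositive_count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$stimulation <- factor(as.character(df$stimulation), levels = stim_levels())
  df$time <- factor(as.character(df$time), levels = time_levels())
  if (anyNA(df$stimulation) || anyNA(df$time)) stop("unknown group labels")
  if (any(df$pv_count < 0)) stop("pv_count must be non-negative")
  bad <- df$copositive_count > df$pv_count | df$copositive_count < 0
  if (any(bad)) {
    stop("copositive_count exceeds pv_count for animal '",
         df$animal_id[which(bad)[1]], "', region '",
         df$region[which(bad)[1]], "' (labelling inconsistency)")
  }
  df$percent <- percent_coexpression(df$pv_count, df$copositive_count)
  class(df) <- c("coexpression_table", "data.frame")
  df
}

#' Load a long-format co-expression CSV
#'
#' Columns: `animal_id`, `stimulation`, `time`, `region`, `pv_count`,
#' `copositive_count`.
#'
#' @param path CSV path.
#' @return A `coexpression_table`.
#' @export
load_coexpression_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_coexpression_table(df)
}

#' Percentage of PV+ cells that are c-Fos+
#'
#' @param pv_count Total PV+ cells (non-negative integer, vectorised).
#' @param copositive_count PV+ cells also c-Fos+ (0 <= copositive <= pv).
#' @return `100 * copositive / pv`; `NA` when `pv_count` is 0.
#' @export
percent_coexpression <- function(pv_count, copositive_count) {
  if (any(copositive_count > pv_count | copositive_count < 0)) {
    stop("copositive_count must lie in [0, pv_count]")
  }
  ifelse(pv_count == 0, NA_real_, 100 * copositive_count / pv_count)
}

#' Two-factor between-cells ANOVA (stimulation x region)
#'
#' Fixed-effects ANOVA of co-expression percentages with factors
#' stimulation (2 levels) and region, treating every animal-by-region
#' value as an independent cell observation. Sums of squares are Type
#' III (via [car::Anova()] with sum-to-zero contrasts), which coincides
#' with the classical decomposition when the layout is balanced. A full
#' factorial with at least one observation per cell is required.
#'
#' @param values Numeric response (e.g. percent co-expression).
#' @param stim Factor/character of stimulation levels.
#' @param region Factor/character of regions.
#' @return An `anova_table` data frame: rows `stimulation`, `region`,
#'   `stimulation:region`, `residual`; columns `ss`, `df`, `F`, `p`.
#' @export
two_way_anova <- function(values, stim, region) {
  keep <- !is.na(values)
  values <- values[keep]
  stim <- droplevels(factor(stim[keep]))
  region <- droplevels(factor(region[keep]))
  if (nlevels(stim) < 2 || nlevels(region) < 2) {
    stop("need at least 2 levels of each factor")
  }
  cells <- table(stim, region)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: stimulation '", levels(stim)[empty[1]],
         "' x region '", levels(region)[empty[2]], "'")
  }
  dat <- data.frame(y = values, stim = stim, region = region)
  fit <- stats::lm(y ~ stim * region, data = dat,
                   contrasts = list(stim = "contr.sum", region = "contr.sum"))
  resid_ss <- sum(stats::residuals(fit)^2)
  resid_df <- fit$df.residual
  if (resid_df == 0 || resid_ss < 1e-12 * max(1, sum(values^2))) {
    # degenerate layout: no residual variation to test against
    out <- data.frame(
      effect = c("stimulation", "region", "stimulation:region", "residual"),
      ss = c(NA_real_, NA_real_, NA_real_, resid_ss),
      df = c(1L, nlevels(region) - 1L,
             nlevels(region) - 1L, resid_df),
      F = NA_real_, p = NA_real_, stringsAsFactors = FALSE
    )
    attr(out, "degenerate") <- TRUE
    class(out) <- c("anova_table", "data.frame")
    return(out)
  }
  a3 <- car::Anova(fit, type = 3)
  pick <- function(nm) {
    i <- match(nm, rownames(a3))
    c(ss = a3[i, "Sum Sq"], df = a3[i, "Df"],
      F = a3[i, "F value"], p = a3[i, "Pr(>F)"])
  }
  s <- pick("stim"); r <- pick("region"); i <- pick("stim:region")
  out <- data.frame(
    effect = c("stimulation", "region", "stimulation:region", "residual"),
    ss = c(s["ss"], r["ss"], i["ss"], resid_ss),
    df = c(s["df"], r["df"], i["df"], resid_df),
    F = c(s["F"], r["F"], i["F"], NA_real_),
    p = c(s["p"], r["p"], i["p"], NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "degenerate") <- FALSE
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Hedge's g (absolute standardised mean difference, small-sample corrected)
#'
#' \deqn{|g| = \left| J \cdot \frac{\bar{x}_a - \bar{x}_b}{s_p} \right|,
#'   \quad s_p = \sqrt{\frac{(n_a-1)s_a^2 + (n_b-1)s_b^2}{n_a+n_b-2}},
#'   \quad J = 1 - \frac{3}{4(n_a+n_b) - 9}.}
#' With zero pooled variance, equal means give 0 and unequal means give
#' `Inf`.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 finite
#'   values.
#' @return Non-negative effect size.
#' @export
hedges_g <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 finite values")
  }
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  J <- 1 - 3 / (4 * (na + nb) - 9)
  diff <- mean(a) - mean(b)
  if (sp2 <= 0) {
    return(if (diff == 0) 0 else Inf)
  }
  abs(J * diff / sqrt(sp2))
}

#' Per-region absolute Hedge's g profile (active vs sham)
#'
#' For one time cohort (acute or chronic), computes the absolute Hedge's
#' g of active vs sham co-expression percentages in each region, ranked
#' descending. Regions with fewer than 2 usable values in either group
#' are reported missing.
#'
#' @param table A `coexpression_table`.
#' @param cohort `"acute"` or `"chronic"`.
#' @return An `effect_size_profile` data frame: `region`, `g_abs`,
#'   `n_active`, `n_sham`, sorted by decreasing `g_abs` (NA last).
#' @export
effect_profile <- function(table, cohort = c("acute", "chronic")) {
  stopifnot(inherits(table, "coexpression_table"))
  cohort <- match.arg(cohort)
  sub <- table[table$time == cohort, , drop = FALSE]
  if (!all(stim_levels() %in% unique(as.character(sub$stimulation)))) {
    stop("cohort '", cohort, "' must contain both stimulation groups")
  }
  regions <- unique(sub$region)
  rows <- lapply(regions, function(r) {
    va <- sub$percent[sub$region == r & sub$stimulation == "active"]
    vs <- sub$percent[sub$region == r & sub$stimulation == "sham"]
    va <- va[is.finite(va)]; vs <- vs[is.finite(vs)]
    g <- if (length(va) >= 2 && length(vs) >= 2) hedges_g(va, vs) else NA_real_
    data.frame(region = r, g_abs = g,
               n_active = length(va), n_sham = length(vs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$g_abs, out$region, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("effect_size_profile", "data.frame")
  out
}
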