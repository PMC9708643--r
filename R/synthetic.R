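#' Configuration for a synthetic c-Fos cohort
#'
#' Defines the study design the simulator emulates: four groups from the
#' crossing of stimulation (sham/active) and time (acute/chronic), with
#' default sizes of 6 animals per acute group and 5 per chronic group;
#' per-region negative binomial (NB2) density marginals with log-scale
#' group effects; and a Gaussian copula that plants an inter-regional
#' correlation structure, including negative entries.
#'
#' Per animal in group \eqn{g}, a latent vector
#' \eqn{z \sim N(0, \Sigma)} (\eqn{\Sigma} = `copula_corr`) is drawn,
#' mapped to uniforms \eqn{u = \Phi(z)}, and each region's density is the
#' NB quantile \eqn{F^{-1}_{NB}(u_r;\, \mu_{g,r}, \theta_r)} where
#' \deqn{\log \mu_{g,r} = \log \mathrm{baseline}_r
#'   + \beta_{stim}\,[active] + \beta_{time}\,[chronic]
#'   + \beta_{int}\,[active \wedge chronic].}
#' The NB2 parameterisation has variance \eqn{\mu + \mu^2/\theta}
#' (`dispersion` \eqn{= \theta}); the Poisson limit is
#' \eqn{\theta \to \infty}. Note the copula correlation is not the Pearson
#' correlation of the resulting counts; it controls sign and ordering of
#' dependence, which is what recovery tests assert.
#'
#' @param n_per_group Named integer vector over the four groups
#'   `acute-sham`, `acute-active`, `chronic-sham`, `chronic-active`.
#' @param regions A `region_ontology`, a character vector of acronyms, or
#'   an integer count (regions named `R001`, `R002`, ...).
#' @param baseline_mean Per-region expected sham/acute density
#'   (cells/mm^2); scalar recycled. Default 200, a mid-range value for
#'   c-Fos+ densities in activity-mapping data.
#' @param dispersion Per-region NB shape; scalar recycled. Default 2
#'   (marked overdispersion), a conventional choice.
#' @param effect_stim,effect_time,effect_interaction Per-region log-scale
#'   effects; scalars recycled. Default 0.
#' @param copula_corr Correlation matrix over regions (unit diagonal,
#'   symmetric, positive semi-definite), or a named list of four such
#'   matrices (one per group) to plant group-specific dependence, e.g.
#'   anticorrelations in the active groups only. Default identity.
#' @param repair_copula If `TRUE`, project a non-PSD `copula_corr` to the
#'   nearest PSD correlation matrix (eigenvalue clipping) instead of
#'   erroring. Off by default: silent repair would corrupt planted truth.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_group = c("acute-sham" = 6L, "acute-active" = 6L,
                                             "chronic-sham" = 5L, "chronic-active" = 5L),
                             regions = 115L,
                             baseline_mean = 200,
                             dispersion = 2,
                             effect_stim = 0,
                             effect_time = 0,
                             effect_interaction = 0,
                             copula_corr = NULL,
                             repair_copula = FALSE,
                             seed = 1L) {
  groups <- c("acute-sham", "acute-active", "chronic-sham", "chronic-active")
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  if (!setequal(names(n_per_group), groups)) {
    stop("n_per_group must be named over: ", paste(groups, collapse = ", "))
  }
  n_per_group <- as.integer(n_per_group[groups])
  names(n_per_group) <- groups
  if (any(n_per_group < 1)) stop("each group needs at least one animal")

  if (inherits(regions, "region_ontology")) {
    region_names <- regions$acronym
  } else if (is.character(regions)) {
    region_names <- regions
  } else {
    region_names <- sprintf("R%03d", seq_len(as.integer(regions)))
  }
  R <- length(region_names)

  recycle <- function(x, what) {
    if (length(x) == 1) x <- rep(x, R)
    if (length(x) != R) stop(what, " must have length 1 or ", R)
    x
  }
  baseline_mean <- recycle(baseline_mean, "baseline_mean")
  dispersion <- recycle(dispersion, "dispersion")
  effect_stim <- recycle(effect_stim, "effect_stim")
  effect_time <- recycle(effect_time, "effect_time")
  effect_interaction <- recycle(effect_interaction, "effect_interaction")
  if (any(baseline_mean <= 0)) stop("baseline_mean must be positive")
  if (any(dispersion <= 0)) stop("dispersion must be positive")

  if (is.null(copula_corr)) copula_corr <- diag(R)
  if (is.list(copula_corr)) {
    if (!setequal(names(copula_corr), groups)) {
      stop("a per-group copula_corr list must be named over: ",
           paste(groups, collapse = ", "))
    }
    copula_corr <- lapply(copula_corr[groups], validate_copula, R = R,
                          repair = repair_copula)
  } else {
    copula_corr <- validate_copula(copula_corr, R, repair = repair_copula)
  }

  structure(list(
    n_per_group = n_per_group, regions = region_names,
    baseline_mean = baseline_mean, dispersion = dispersion,
    effect_stim = effect_stim, effect_time = effect_time,
    effect_interaction = effect_interaction,
    copula_corr = copula_corr, seed = as.integer(seed)
  ), class = "synthetic_config")
}

validate_copula <- function(C, R, repair = FALSE, tol = 1e-8) {
  if (!is.matrix(C) || nrow(C) != R || ncol(C) != R) {
    stop("copula_corr must be a ", R, " x ", R, " matrix")
  }
  if (max(abs(C - t(C))) > tol) stop("copula_corr must be symmetric")
  if (max(abs(diag(C) - 1)) > tol) stop("copula_corr must have unit diagonal")
  if (any(abs(C) > 1 + tol)) stop("copula_corr entries must lie in [-1, 1]")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, abs(ev[1]))) {
    if (!repair) {
      stop("copula_corr is not positive semi-definite (min eigenvalue ",
           signif(min(ev), 3), "); set repair_copula = TRUE to project")
    }
    C <- nearest_psd_correlation(C)
  }
  C
}

#' Nearest positive semi-definite correlation matrix (eigenvalue clipping)
#'
#' Clips negative eigenvalues to zero, reconstructs, and rescales to unit
#' diagonal. A simple projection, adequate for mildly indefinite inputs.
#'
#' @param C Symmetric matrix with unit diagonal.
#' @return A PSD correlation matrix.
#' @export
nearest_psd_correlation <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  M <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(pmax(diag(M), .Machine$double.eps))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  (M + t(M)) / 2
}

#' Negative binomial inverse CDF (smallest k with F(k) >= u)
#'
#' NB2 quantile in the (mean, dispersion) parameterisation,
#' variance \eqn{\mu + \mu^2/\theta}.
#'
#' @param u Probabilities in `[0, 1)`; `u = 1` is an error (support is
#'   unbounded).
#' @param mean Positive mean \eqn{\mu}.
#' @param dispersion Positive shape \eqn{\theta}.
#' @return Non-negative integer quantiles.
#' @export
nb_inverse_cdf <- function(u, mean, dispersion) {
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1); u = 1 is unbounded")
  if (any(mean <= 0) || any(dispersion <= 0)) {
    stop("mean and dispersion must be positive")
  }
  stats::qnbinom(u, size = dispersion, mu = mean)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

config_group_means <- function(config) {
  groups <- names(config$n_per_group)
  mu <- matrix(NA_real_, nrow = 4, ncol = length(config$regions),
               dimnames = list(groups, config$regions))
  for (g in groups) {
    active <- grepl("-active$", g)
    chronic <- grepl("^chronic", g)
    mu[g, ] <- exp(log(config$baseline_mean) +
                     config$effect_stim * active +
                     config$effect_time * chronic +
                     config$effect_interaction * (active && chronic))
  }
  mu
}

#' Generate a synthetic cohort density table
#'
#' Draws a `density_table` from the model described in
#' [synthetic_config()]. Deterministic given `config$seed`.
#'
#' @param config A `synthetic_config`.
#' @return A list: `table` (a `density_table`) and `truth` (a
#'   `synthetic_truth`: the config, the true group mean matrix, and the
#'   planted anti-correlated region pairs, i.e. copula entries < 0).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  R <- length(config$regions)
  mu_groups <- config_group_means(config)
  per_group <- is.list(config$copula_corr)
  Ls <- if (per_group) {
    lapply(config$copula_corr, function(C) t(chol_psd(C)))
  } else {
    L1 <- t(chol_psd(config$copula_corr))
    stats::setNames(rep(list(L1), 4), names(config$n_per_group))
  }

  with_seed(config$seed, {
    rows <- list(); meta <- list(); k <- 0L
    for (g in names(config$n_per_group)) {
      ng <- config$n_per_group[[g]]
      L <- Ls[[g]]
      parts <- strsplit(g, "-", fixed = TRUE)[[1]]
      for (i in seq_len(ng)) {
        k <- k + 1L
        z <- as.vector(L %*% stats::rnorm(R))
        u <- stats::pnorm(z)
        u <- pmin(u, 1 - 1e-12)  # guard the unbounded upper tail
        y <- nb_inverse_cdf(u, mean = mu_groups[g, ], dispersion = config$dispersion)
        rows[[k]] <- as.numeric(y)
        meta[[k]] <- data.frame(
          animal_id = sprintf("%s-%02d", g, i),
          stimulation = parts[2], time = parts[1],
          sex = if (i %% 2 == 0) "F" else "M",
          stringsAsFactors = FALSE
        )
      }
    }
    animals <- do.call(rbind, meta)
    animals$stimulation <- factor(animals$stimulation, levels = stim_levels())
    animals$time <- factor(animals$time, levels = time_levels())
    values <- do.call(rbind, rows)
    table <- new_density_table(animals, config$regions, values)

    neg_pairs_of <- function(C, group) {
      neg <- which(C < 0 & upper.tri(C), arr.ind = TRUE)
      if (nrow(neg) == 0) {
        return(data.frame(group = character(0), region_a = character(0),
                          region_b = character(0), copula_r = numeric(0),
                          stringsAsFactors = FALSE))
      }
      data.frame(group = group,
                 region_a = config$regions[neg[, 1]],
                 region_b = config$regions[neg[, 2]],
                 copula_r = C[neg],
                 stringsAsFactors = FALSE)
    }
    negative_pairs <- if (per_group) {
      do.call(rbind, Map(neg_pairs_of, config$copula_corr,
                         names(config$copula_corr)))
    } else {
      neg_pairs_of(config$copula_corr, "all")
    }
    rownames(negative_pairs) <- NULL
    truth <- structure(list(
      config = config,
      group_means = mu_groups,
      negative_pairs = negative_pairs
    ), class = "synthetic_truth")
    list(table = table, truth = truth)
  })
}

# Cholesky-like factor valid for PSD (possibly singular) matrices.
chol_psd <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  t(e$vectors %*% (sqrt(lam) * t(e$vectors)))
}

#' Generate synthetic parvalbumin/c-Fos co-expression data
#'
#' For each animal of the cohort design and each higher-order region, the
#' number of PV+ cells that are also c-Fos+ is drawn as
#' Binomial(`pv_counts[region]`, `p_active[group, region]`); the table
#' stores the percentage 100 * copositive / pv. Regions with zero PV
#' count give a missing percentage (an undefined proportion, not 0).
#'
#' @param config A `synthetic_config` (supplies group sizes and seed).
#' @param pv_counts Named non-negative integer vector: PV+ cells counted
#'   per higher-order region (same for every animal).
#' @param p_active Numeric matrix, 4 groups x regions (rownames the group
#'   labels, colnames the regions), of co-expression probabilities in
#'   `[0, 1]`; or a scalar recycled.
#' @return A list: `table` (a `coexpression_table` data frame) and
#'   `truth` (config plus the probability matrix used).
#' @export
generate_coexpression <- function(config, pv_counts, p_active) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(names(pv_counts))) stop("pv_counts must be named by region")
  if (any(pv_counts < 0)) stop("pv_counts must be non-negative")
  regions <- names(pv_counts)
  groups <- names(config$n_per_group)
  if (length(p_active) == 1) {
    p_active <- matrix(p_active, nrow = 4, ncol = length(regions),
                       dimnames = list(groups, regions))
  }
  if (any(p_active < 0 | p_active > 1)) stop("p_active must lie in [0, 1]")

  with_seed(config$seed + 1L, {
    recs <- list(); k <- 0L
    for (g in groups) {
      parts <- strsplit(g, "-", fixed = TRUE)[[1]]
      for (i in seq_len(config$n_per_group[[g]])) {
        for (r in regions) {
          k <- k + 1L
          pv <- pv_counts[[r]]
          co <- if (pv > 0) stats::rbinom(1, pv, p_active[g, r]) else 0L
          recs[[k]] <- data.frame(
            animal_id = sprintf("%s-%02d", g, i),
            stimulation = parts[2], time = parts[1],
            region = r, pv_count = pv, copositive_count = co,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    df <- do.call(rbind, recs)
    table <- as_coexpression_table(df)
    truth <- structure(list(config = config, p_active = p_active,
                            pv_counts = pv_counts),
                       class = "synthetic_truth")
    list(table = table, truth = truth)
  })
}
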