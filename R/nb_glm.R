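#' Negative binomial GLM for c-Fos density (NB2, log link)
#'
#' Fits the NB2 model \eqn{y_i \sim NB(\mu_i, \theta)},
#' \eqn{\log \mu_i = x_i'\beta}, variance \eqn{\mu + \mu^2/\theta}, by
#' joint maximum likelihood over \eqn{\beta} and \eqn{\theta}. The
#' log-likelihood is written with Gamma functions,
#' \deqn{\ell_i = \log\Gamma(y_i+\theta) - \log\Gamma(\theta)
#'   - \log\Gamma(y_i+1) + \theta\log\frac{\theta}{\theta+\mu_i}
#'   + y_i\log\frac{\mu_i}{\theta+\mu_i},}
#' so non-integer responses (densities in cells/mm^2, i.e. counts divided
#' by region area) are admissible as a quasi-likelihood extension.
#'
#' The fit alternates iteratively reweighted least squares for
#' \eqn{\beta} given \eqn{\theta} with one-dimensional likelihood
#' maximisation for \eqn{\log\theta} given \eqn{\beta}. The Wald
#' covariance of \eqn{\beta} comes from the observed information of the
#' joint likelihood (numerical Hessian), falling back to the expected
#' information \eqn{(X'WX)^{-1}} at fixed \eqn{\theta} if that fails.
#'
#' @param y Non-negative numeric response.
#' @param X Model (design) matrix, one row per observation; typically the
#'   four-column stimulation-by-time factorial matrix.
#' @return An object of class `nb_glm_fit`: coefficients, `vcov`,
#'   `theta` (dispersion), `loglik`, `deviance`, `fitted`, `leverage`,
#'   `pearson_resid`, `converged`, `n_used`, `degenerate`.
#' @export
fit_nb_glm <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (any(!is.finite(y)) || any(y < 0)) stop("response must be finite and non-negative")
  n <- length(y)
  p <- ncol(X)

  degenerate <- FALSE
  if (qr(X)$rank < p) {
    stop("design matrix is rank deficient")
  }
  if (all(y == 0)) {
    warning("all-zero response: intercept fitted at a small floor")
    mu <- rep(1e-8, n)
    beta <- c(log(1e-8), rep(0, p - 1))
    names(beta) <- colnames(X)
    return(structure(list(
      coefficients = beta, vcov = matrix(NA_real_, p, p), theta = Inf,
      loglik = 0, deviance = 0, fitted = mu,
      leverage = rep(p / n, n), pearson_resid = rep(0, n),
      converged = TRUE, n_used = n, degenerate = TRUE,
      y = y, X = X), class = "nb_glm_fit"))
  }

  loglik_nb <- function(beta, log_theta) {
    theta <- exp(log_theta)
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
          theta * (log_theta - log(theta + mu)) +
          y * (eta - log(theta + mu)))
  }

  irls_beta <- function(beta, theta, maxit = 50, tol = 1e-10) {
    for (it in seq_len(maxit)) {
      eta <- pmin(pmax(drop(X %*% beta), -30), 30)
      mu <- exp(eta)
      W <- mu * theta / (mu + theta)
      z <- eta + (y - mu) / mu
      fit <- stats::lm.wfit(X, z, W)
      beta_new <- fit$coefficients
      if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
        beta <- beta_new; break
      }
      beta <- beta_new
    }
    beta
  }

  # moment start: shift zeros slightly so log is defined
  mu0 <- max(mean(y), 1e-4)
  beta <- c(log(mu0), rep(0, p - 1))
  v <- stats::var(y)
  log_theta <- if (is.finite(v) && v > mu0) log(max(mu0^2 / (v - mu0), 1e-2)) else log(10)

  ll_old <- -Inf
  converged <- FALSE
  for (outer in seq_len(100)) {
    beta <- irls_beta(beta, exp(log_theta))
    opt <- stats::optimize(function(lt) loglik_nb(beta, lt),
                           interval = c(-7, 25), maximum = TRUE, tol = 1e-9)
    log_theta <- opt$maximum
    ll <- opt$objective
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-10 * (1 + abs(ll))) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  theta <- exp(log_theta)
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  mu <- exp(eta)
  names(beta) <- colnames(X)

  # observed-information Wald covariance for beta (joint in beta, log theta)
  vcov_beta <- tryCatch({
    nll <- function(par) -loglik_nb(par[1:p], par[p + 1])
    H <- stats::optimHess(c(beta, log_theta), nll)
    V <- solve(H)[1:p, 1:p, drop = FALSE]
    if (any(!is.finite(V)) || any(diag(V) <= 0)) stop("bad hessian")
    V
  }, error = function(e) {
    W <- mu * theta / (mu + theta)
    solve(crossprod(X, W * X))
  })
  dimnames(vcov_beta) <- list(names(beta), names(beta))

  W <- mu * theta / (mu + theta)
  Xw <- X * sqrt(W)
  h <- rowSums(qr.Q(qr(Xw))^2)
  pearson <- (y - mu) / sqrt(mu + mu^2 / theta)

  # saturated NB2 deviance (continuous extension; terms with y = 0 handled)
  dev_terms <- ifelse(y > 0,
                      y * log(y / mu) - (y + theta) * log((y + theta) / (mu + theta)),
                      theta * log((mu + theta) / theta))
  deviance <- 2 * sum(dev_terms)

  structure(list(
    coefficients = beta, vcov = vcov_beta, theta = theta,
    loglik = loglik_nb(beta, log_theta), deviance = deviance,
    fitted = mu, leverage = h, pearson_resid = pearson,
    converged = converged, n_used = n, degenerate = degenerate,
    y = y, X = X), class = "nb_glm_fit")
}

#' @export
print.nb_glm_fit <- function(x, ...) {
  cat("NB2 GLM (log link):", x$n_used, "observations, theta =",
      signif(x$theta, 4), "\n")
  se <- sqrt(diag(x$vcov))
  print(cbind(estimate = x$coefficients, se = se,
              z = x$coefficients / se,
              p = 2 * stats::pnorm(-abs(x$coefficients / se))))
  invisible(x)
}

#' One-step generalised Cook's distance for an NB GLM fit
#'
#' \deqn{D_i = \frac{r_{P,i}^2}{1 - h_i} \cdot \frac{h_i}{p\,(1 - h_i)},}
#' the squared standardised Pearson residual times
#' \eqn{h_i / (p (1 - h_i))}, with \eqn{h_i} the hat-matrix leverage of
#' the weighted least-squares representation and \eqn{p} the number of
#' coefficients. Observations with \eqn{h_i = 1} get `Inf`.
#'
#' @param model An `nb_glm_fit`.
#' @param ... Unused.
#' @return Numeric vector of per-observation distances.
#' @export
cooks.distance.nb_glm_fit <- function(model, ...) {
  h <- model$leverage
  p <- length(model$coefficients)
  r_std2 <- model$pearson_resid^2 / (1 - h)
  d <- r_std2 * h / (p * (1 - h))
  d[h >= 1 - 1e-12] <- Inf
  d
}

#' Benjamini-Hochberg step-up rejections at level q
#'
#' Thin wrapper over [stats::p.adjust()] (method `"BH"`): a p-value is
#' rejected iff its BH-adjusted value is at most `q`. Flags are aligned
#' with the input order.
#'
#' @param pvalues Numeric vector in `[0, 1]` (NA allowed, propagates).
#' @param q FDR level.
#' @return Logical rejection flags.
#' @export
bh_fdr <- function(pvalues, q) {
  if (length(pvalues) == 0) stop("empty p-value list")
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stop("p-values outside [0, 1]")
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Percent change of an active-group mean relative to sham
#'
#' @param mean_active,mean_sham Group means; `mean_sham` must be positive
#'   (zero gives `NA`, an undefined change).
#' @return `100 * (mean_active - mean_sham) / mean_sham`.
#' @export
percent_change <- function(mean_active, mean_sham) {
  ifelse(is.na(mean_sham) | mean_sham == 0, NA_real_,
         100 * (mean_active - mean_sham) / mean_sham)
}

#' Direction band for a percent change
#'
#' Banding convention for summarising direction and magnitude of density
#' change: `n.s.` when not significant; otherwise `-` for negative
#' changes (-200 to 0%), `+` for 0-200%, `++` for 201-500% and `+++`
#' above 500%.
#'
#' @param pct Percent change (vectorised).
#' @param significant Logical flag(s); gates banding.
#' @return Character band symbols.
#' @export
direction_band <- function(pct, significant) {
  n <- max(length(pct), length(significant))
  pct <- rep_len(pct, n); significant <- rep_len(significant, n)
  out <- rep("n.s.", n)
  sig <- !is.na(significant) & significant & !is.na(pct)
  out[sig & pct < 0] <- "-"
  out[sig & pct >= 0 & pct <= 200] <- "+"
  out[sig & pct > 200 & pct <= 500] <- "++"
  out[sig & pct > 500] <- "+++"
  out
}

#' Screening configuration
#'
#' @param cooks_threshold Cook's distance above which an observation is
#'   excluded (default 0.5).
#' @param min_group_n Minimum non-missing values per group (default 3).
#' @param omnibus_fdr_q FDR level for the omnibus tests across regions
#'   (default 0.01).
#' @param followup_alpha Alpha for follow-up main effects, interaction
#'   and simple main effects (default 0.05, uncorrected).
#' @param omnibus_test Omnibus construction. `"lr"` (default): deviance
#'   (likelihood-ratio) comparison of the full factorial model against
#'   intercept-only, referred to an F(3, n - 4) distribution with the
#'   dispersion held at the full-model estimate — the small-sample
#'   calibrated choice at cohort-sized n. `"lr_chisq"`: the same
#'   comparison with each model's dispersion profiled, referred to
#'   chi-square(3) (asymptotic; anticonservative at small n).
#'   `"wald"`: joint Wald chi-square on the three non-intercept
#'   coefficients.
#' @return A `screen_config` list.
#' @export
screen_config <- function(cooks_threshold = 0.5, min_group_n = 3,
                          omnibus_fdr_q = 0.01, followup_alpha = 0.05,
                          omnibus_test = c("lr", "lr_chisq", "wald")) {
  omnibus_test <- match.arg(omnibus_test)
  stopifnot(cooks_threshold > 0, min_group_n >= 1,
            omnibus_fdr_q > 0, omnibus_fdr_q < 1,
            followup_alpha > 0, followup_alpha < 1)
  structure(list(cooks_threshold = cooks_threshold,
                 min_group_n = as.integer(min_group_n),
                 omnibus_fdr_q = omnibus_fdr_q,
                 followup_alpha = followup_alpha,
                 omnibus_test = omnibus_test),
            class = "screen_config")
}

factorial_design <- function(animals) {
  active <- as.numeric(animals$stimulation == "active")
  chronic <- as.numeric(animals$time == "chronic")
  cbind("(Intercept)" = 1, stim = active, time = chronic,
        "stim:time" = active * chronic)
}

min_group_ok <- function(animals, min_n) {
  all(table(group_labels(animals)) >= min_n)
}

# Wald coefficient tests with a t(n - p) reference (small-sample choice;
# the normal reference is anticonservative at cohort-sized n).
wald_p <- function(fit) {
  se <- sqrt(diag(fit$vcov))
  df <- max(fit$n_used - length(fit$coefficients), 1)
  2 * stats::pt(-abs(fit$coefficients / se), df = df)
}

nb_deviance_at <- function(y, mu, theta) {
  2 * sum(ifelse(y > 0,
                 y * log(y / mu) - (y + theta) * log((y + theta) / (mu + theta)),
                 theta * log((mu + theta) / theta)))
}

omnibus_p_value <- function(y, X, fit, test) {
  p <- ncol(X)
  if (test == "wald") {
    b <- fit$coefficients[-1]
    V <- fit$vcov[-1, -1, drop = FALSE]
    stat <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
    return(stats::pchisq(stat, df = length(b), lower.tail = FALSE))
  }
  if (test == "lr_chisq") {
    fit0 <- suppressWarnings(fit_nb_glm(y, X[, 1, drop = FALSE]))
    lr <- max(0, 2 * (fit$loglik - fit0$loglik))
    return(stats::pchisq(lr, df = p - 1, lower.tail = FALSE))
  }
  # "lr": deviance comparison at the full-model dispersion, F reference.
  # The intercept-only NB2 ML mean at fixed theta is the sample mean.
  theta <- fit$theta
  mu0 <- max(mean(y), 1e-8)
  d0 <- nb_deviance_at(y, rep(mu0, length(y)), theta)
  d1 <- nb_deviance_at(y, fit$fitted, theta)
  df2 <- fit$n_used - p
  if (df2 < 1 || d1 <= 0) {
    lr <- max(0, d0 - d1)
    return(stats::pchisq(lr, df = p - 1, lower.tail = FALSE))
  }
  fstat <- max(0, (d0 - d1) / (p - 1)) / (d1 / df2)
  stats::pf(fstat, p - 1, df2, lower.tail = FALSE)
}

simple_main_effect_p <- function(fit, level) {
  # Wald contrast for stimulation within one time level, from the
  # interaction model: acute -> beta_stim; chronic -> beta_stim + beta_int
  cvec <- c(0, 1, 0, if (level == "chronic") 1 else 0)
  est <- sum(cvec * fit$coefficients)
  v <- drop(t(cvec) %*% fit$vcov %*% cvec)
  df <- max(fit$n_used - length(fit$coefficients), 1)
  2 * stats::pt(-abs(est / sqrt(v)), df = df)
}

#' Screen one region: fit, influence exclusion, refit, tests
#'
#' Runs the per-region protocol: (1) fit the full stimulation-by-time NB
#' GLM; (2) drop observations with Cook's distance above the threshold,
#' re-apply the minimum-per-group rule, and refit once; (3) omnibus test
#' of the full model against intercept-only; (4) Wald tests for the
#' stimulation and time main effects and their interaction; (5) Wald
#' simple-main-effect contrasts of stimulation within each time level;
#' (6) percent change of active vs sham within each time level, with
#' direction bands gated on follow-up significance. The omnibus q-value
#' is filled in by [analyze_brainwide()], which also re-gates bands.
#'
#' @param y Numeric region column (NA = missing).
#' @param animals Animal metadata data frame (as in a `density_table`).
#' @param config A `screen_config`.
#' @param region Region acronym for labelling.
#' @return A `region_test_summary` (list).
#' @export
screen_region <- function(y, animals, config = screen_config(), region = NA_character_) {
  keep <- !is.na(y)
  y0 <- y[keep]; an0 <- animals[keep, , drop = FALSE]
  base <- list(region = region, status = "ok",
               omnibus_p = NA_real_, omnibus_q = NA_real_,
               omnibus_significant = NA,
               p_stim = NA_real_, p_time = NA_real_, p_interaction = NA_real_,
               interaction_significant = NA,
               simple_main_effects = c(acute = NA_real_, chronic = NA_real_),
               excluded_observations = character(0),
               percent_change = c(acute = NA_real_, chronic = NA_real_),
               direction_band = c(acute = "n.s.", chronic = "n.s."),
               n_used = length(y0))
  class(base) <- "region_test_summary"
  if (!min_group_ok(an0, config$min_group_n)) {
    base$status <- "excluded_min_group"; return(base)
  }

  X <- factorial_design(an0)
  fit <- tryCatch(suppressWarnings(fit_nb_glm(y0, X)),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    base$status <- "not_analysable"; return(base)
  }

  d <- cooks.distance.nb_glm_fit(fit)
  drop_idx <- which(d > config$cooks_threshold)
  excluded <- an0$animal_id[drop_idx]
  if (length(drop_idx) > 0) {
    y1 <- y0[-drop_idx]; an1 <- an0[-drop_idx, , drop = FALSE]
    if (!min_group_ok(an1, config$min_group_n)) {
      base$status <- "excluded_post_cook"
      base$excluded_observations <- excluded
      return(base)
    }
    X <- factorial_design(an1)
    fit <- tryCatch(suppressWarnings(fit_nb_glm(y1, X)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      base$status <- "not_analysable"
      base$excluded_observations <- excluded
      return(base)
    }
    y0 <- y1; an0 <- an1
  }

  p_eff <- wald_p(fit)
  omni <- omnibus_p_value(y0, X, fit, config$omnibus_test)
  interaction_sig <- !is.na(p_eff[["stim:time"]]) &&
    p_eff[["stim:time"]] < config$followup_alpha
  sme <- c(acute = NA_real_, chronic = NA_real_)
  if (interaction_sig) {
    sme <- c(acute = simple_main_effect_p(fit, "acute"),
             chronic = simple_main_effect_p(fit, "chronic"))
  }

  pct <- c(acute = NA_real_, chronic = NA_real_)
  sig <- c(acute = FALSE, chronic = FALSE)
  for (tl in c("acute", "chronic")) {
    sel <- an0$time == tl
    m_act <- mean(y0[sel & an0$stimulation == "active"])
    m_sham <- mean(y0[sel & an0$stimulation == "sham"])
    pct[tl] <- percent_change(m_act, m_sham)
    sig[tl] <- if (interaction_sig) {
      !is.na(sme[tl]) && sme[tl] < config$followup_alpha
    } else {
      !is.na(p_eff[["stim"]]) && p_eff[["stim"]] < config$followup_alpha
    }
  }

  base$omnibus_p <- omni
  base$p_stim <- p_eff[["stim"]]
  base$p_time <- p_eff[["time"]]
  base$p_interaction <- p_eff[["stim:time"]]
  base$interaction_significant <- interaction_sig
  base$simple_main_effects <- sme
  base$excluded_observations <- excluded
  base$percent_change <- pct
  base$direction_band <- stats::setNames(direction_band(pct, sig), names(pct))
  base$n_used <- fit$n_used
  base$fit <- fit
  base
}

#' Brain-wide per-region screen with FDR across regions
#'
#' Applies the minimum-per-group region filter, screens every retained
#' region with [screen_region()], adjusts the omnibus p-values across
#' regions by Benjamini-Hochberg at `config$omnibus_fdr_q`, and gates all
#' follow-up reporting (interaction, simple main effects, direction
#' bands) on omnibus significance. Per-region failures are carried as
#' flagged rows, never aborting the screen.
#'
#' @param table A `density_table`.
#' @param config A `screen_config`.
#' @return A `brainwide_screen`: list with `summary` (one data-frame row
#'   per analysed region), `excluded_regions` (pre-filter) and `config`.
#' @export
analyze_brainwide <- function(table, config = screen_config()) {
  stopifnot(inherits(table, "density_table"))
  flt <- filter_regions_min_group_count(table, config$min_group_n)
  tab <- flt$table
  screens <- lapply(seq_along(tab$regions), function(j) {
    screen_region(tab$values[, j], tab$animals, config, region = tab$regions[j])
  })
  omni_p <- vapply(screens, function(s) s$omnibus_p, numeric(1))
  q <- rep(NA_real_, length(omni_p))
  sig <- rep(NA, length(omni_p))
  ok <- !is.na(omni_p)
  if (any(ok)) {
    q[ok] <- stats::p.adjust(omni_p[ok], method = "BH")
    sig[ok] <- q[ok] <= config$omnibus_fdr_q
  }
  rows <- lapply(seq_along(screens), function(i) {
    s <- screens[[i]]
    omn_sig <- isTRUE(sig[i])
    band <- s$direction_band
    sme <- s$simple_main_effects
    int_sig <- s$interaction_significant
    if (!omn_sig) {  # follow-ups only for omnibus-significant regions
      band <- c(acute = "n.s.", chronic = "n.s.")
      sme <- c(acute = NA_real_, chronic = NA_real_)
      int_sig <- NA
    }
    data.frame(
      region = s$region, status = s$status, n_used = s$n_used,
      n_cook_excluded = length(s$excluded_observations),
      omnibus_p = s$omnibus_p, omnibus_q = q[i], omnibus_significant = sig[i],
      p_stim = s$p_stim, p_time = s$p_time, p_interaction = s$p_interaction,
      interaction_significant = int_sig,
      p_simple_acute = sme[["acute"]], p_simple_chronic = sme[["chronic"]],
      pct_change_acute = s$percent_change[["acute"]],
      pct_change_chronic = s$percent_change[["chronic"]],
      band_acute = band[["acute"]], band_chronic = band[["chronic"]],
      stringsAsFactors = FALSE
    )
  })
  out <- list(summary = do.call(rbind, rows),
              excluded_regions = flt$excluded,
              screens = screens,
              config = config)
  class(out) <- "brainwide_screen"
  out
}

#' @export
print.brainwide_screen <- function(x, ...) {
  s <- x$summary
  cat("Brain-wide screen:", nrow(s), "regions analysed,",
      length(x$excluded_regions), "excluded pre-filter\n")
  cat("Omnibus-significant (BH q <=", x$config$omnibus_fdr_q, "):",
      sum(s$omnibus_significant, na.rm = TRUE), "\n")
  invisible(x)
}
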