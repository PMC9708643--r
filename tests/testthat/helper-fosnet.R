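# Shared fixtures and independent oracles, built in code.

# Animal metadata for a 2x2 cohort with the given per-group sizes
# (order: acute-sham, acute-active, chronic-sham, chronic-active).
make_animals <- function(n = c(6, 6, 5, 5)) {
  grp <- rep(c("acute-sham", "acute-active", "chronic-sham", "chronic-active"), n)
  parts <- strsplit(grp, "-", fixed = TRUE)
  data.frame(
    animal_id = sprintf("an%02d", seq_along(grp)),
    stimulation = factor(vapply(parts, `[`, "", 2), levels = c("sham", "active")),
    time = factor(vapply(parts, `[`, "", 1), levels = c("acute", "chronic")),
    sex = "unknown",
    stringsAsFactors = FALSE
  )
}

make_table <- function(values, animals = make_animals(),
                       regions = sprintf("R%03d", seq_len(ncol(values)))) {
  fosnet:::new_density_table(animals, regions, values)
}

# Construct an edge mask directly from a signed pair list (documented
# edge_mask structure), for density arithmetic that needs exact counts.
make_mask <- function(n_regions, pos_pairs = 0L, neg_pairs = 0L) {
  regions <- sprintf("R%03d", seq_len(n_regions))
  m <- matrix(0L, n_regions, n_regions, dimnames = list(regions, regions))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  stopifnot(pos_pairs + neg_pairs <= nrow(ut))
  take <- seq_len(pos_pairs + neg_pairs)
  signs <- c(rep(1L, pos_pairs), rep(-1L, neg_pairs))
  m[ut[take, , drop = FALSE]] <- signs
  m <- m + t(m)
  structure(list(regions = regions, mask = m, alpha = 0.005, fdr_q = 0.05,
                 mode = "conjunction", group = "test"),
            class = "edge_mask")
}

# Brute-force Benjamini-Hochberg step-up by direct enumeration.
bh_brute <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * q) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# Direct cell-means sums-of-squares decomposition for a balanced
# two-way layout (classic textbook formulas).
anova_brute_balanced <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  nab <- table(A, B)
  stopifnot(length(unique(c(nab))) == 1)  # balanced
  n <- nab[1, 1]; a <- nlevels(A); b <- nlevels(B)
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_a <- n * b * sum((mA - grand)^2)
  ss_b <- n * a * sum((mB - grand)^2)
  ss_ab <- n * sum((mAB - outer(mA, rep(1, b)) -
                      outer(rep(1, a), mB) + grand)^2)
  ss_res <- sum((y - mAB[cbind(A, B)])^2)
  df_res <- length(y) - a * b
  list(
    ss = c(A = ss_a, B = ss_b, AB = ss_ab, res = ss_res),
    df = c(A = a - 1, B = b - 1, AB = (a - 1) * (b - 1), res = df_res),
    F = c(A = (ss_a / (a - 1)) / (ss_res / df_res),
          B = (ss_b / (b - 1)) / (ss_res / df_res),
          AB = (ss_ab / ((a - 1) * (b - 1))) / (ss_res / df_res))
  )
}

# All permutations of 1..n (n small), for exhaustive permutation p-values.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (i in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = i)
    }
  }
  out
}

# IRLS refit of an NB GLM with the dispersion held fixed (for the
# leave-one-out Cook's distance oracle).
nb_refit_fixed_theta <- function(y, X, theta, beta0) {
  beta <- beta0
  for (it in 1:200) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- exp(eta)
    W <- mu * theta / (mu + theta)
    z <- eta + (y - mu) / mu
    bn <- stats::lm.wfit(X, z, W)$coefficients
    if (max(abs(bn - beta)) < 1e-12) { beta <- bn; break }
    beta <- bn
  }
  beta
}
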