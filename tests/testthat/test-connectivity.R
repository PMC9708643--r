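make_corr_table <- function(values_by_group, regions) {
  # values_by_group: list of 4 matrices (rows = animals) in group order
  n <- vapply(values_by_group, nrow, 1L)
  make_table(do.call(rbind, values_by_group), make_animals(n), regions)
}

test_that("group correlations match closed-form, reference, and oracle p-values", {
  set.seed(11)
  x <- rnorm(6); y0 <- rnorm(6)
  vals <- rbind(cbind(x, y0) + 10, matrix(rnorm(18) + 10, ncol = 2))
  tab <- make_table(vals, make_animals(c(6, 3, 3, 3)), c("X", "Y"))
  net <- group_correlation(tab, "sham", "acute")

  expect_equal(net$r["X", "Y"], cor(x, y0))
  ref <- cor.test(x, y0)
  expect_equal(net$p["X", "Y"], ref$p.value, tolerance = 1e-12)

  # numeric t-CDF integration oracle
  r <- net$r["X", "Y"]
  tt <- r * sqrt(4 / (1 - r^2))
  p_int <- 2 * integrate(function(u) dt(u, 4), abs(tt), Inf,
                         rel.tol = 1e-12)$value
  expect_equal(net$p["X", "Y"], p_int, tolerance = 1e-6)

  # exhaustive permutation oracle (720 permutations at n = 6)
  rs <- vapply(all_perms(6), function(pm) cor(x, y0[pm]), numeric(1))
  p_perm <- mean(abs(rs) >= abs(r) - 1e-12)
  expect_lt(abs(net$p["X", "Y"] - p_perm), 0.06)
})

test_that("correlation edge cases: identical vectors, orthogonal vectors, zero variance", {
  x <- c(1, 2, 3, 4, 5, 6)
  orth <- c(-1, 1, -1, 1, -1, 1) - mean(c(-1, 1, -1, 1, -1, 1))
  xc <- x - mean(x)
  orth_x <- orth - sum(orth * xc) / sum(xc^2) * xc  # orthogonalise against x
  vals <- cbind(x, x * 2 + 1, orth_x + 10, 5)
  colnames(vals) <- NULL
  tab <- make_table(rbind(vals, matrix(8, 9, 4)),
                    make_animals(c(6, 3, 3, 3)),
                    c("A", "B", "C", "D"))
  expect_warning(net <- group_correlation(tab, "sham", "acute"), "undefined")
  expect_equal(net$r["A", "B"], 1)                  # identical up to affine map
  expect_equal(net$p["A", "C"], 1, tolerance = 1e-12)  # r = 0 so t = 0
  expect_true(net$undefined["A", "D"])              # zero-variance region
  expect_equal(net$r["A", "D"], 0)
  expect_equal(net$p["A", "D"], 1)
  # undefined pairs never become edges, even with filters disabled
  mask <- filter_edges(net, alpha = 1, fdr_q = 1)
  expect_equal(mask$mask["A", "D"], 0L)
  expect_equal(mask$mask["A", "B"], 1L)
})

test_that("pairwise-complete observations drive per-pair n and df", {
  set.seed(3)
  vals <- matrix(rnorm(18) + 20, 6, 3)
  vals[1:2, 2] <- NA
  tab <- make_table(rbind(vals, matrix(rnorm(27) + 20, 9, 3)),
                    make_animals(c(6, 3, 3, 3)), c("A", "B", "C"))
  net <- group_correlation(tab, "sham", "acute")
  expect_equal(net$n_pairs["A", "B"], 4)
  expect_equal(net$n_pairs["A", "C"], 6)
  cc <- complete.cases(vals[, 1:2])
  ref <- cor.test(vals[cc, 1], vals[cc, 2])
  expect_equal(net$r["A", "B"], unname(ref$estimate))
  expect_equal(net$p["A", "B"], ref$p.value, tolerance = 1e-12)
})

test_that("edge filtering: planted signals, disabled filters, and monotonicity", {
  set.seed(9)
  base <- matrix(rnorm(6 * 20), 6, 20)
  planted <- list(c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(9, 10))
  for (pr in planted) base[, pr[2]] <- base[, pr[1]] * 2 + 3  # r = 1, p ~ 0
  tab <- make_table(rbind(base + 50, matrix(rnorm(9 * 20) + 50, 9, 20)),
                    make_animals(c(6, 3, 3, 3)))
  net <- group_correlation(tab, "sham", "acute")
  mask <- filter_edges(net, alpha = 0.005, fdr_q = 0.05)
  hits <- which(upper.tri(mask$mask) & mask$mask != 0, arr.ind = TRUE)
  expect_equal(nrow(hits), 5)
  expect_setequal(paste(hits[, 1], hits[, 2]),
                  vapply(planted, function(p) paste(p[1], p[2]), ""))
  expect_true(all(mask$mask[hits] == 1L))

  # filters that nothing can pass give an empty mask
  empty <- filter_edges(net, alpha = 1e-300, fdr_q = 1e-300)
  expect_true(all(empty$mask == 0L))

  # disabled filters flag every defined pair with sign(r)
  all_mask <- filter_edges(net, alpha = 1, fdr_q = 1)
  ut <- upper.tri(net$r)
  expect_equal(all_mask$mask[ut][!net$undefined[ut]],
               as.integer(sign(net$r[ut][!net$undefined[ut]])))

  # monotone in alpha at fixed fdr_q
  m1 <- filter_edges(net, alpha = 0.05, fdr_q = 0.05)$mask != 0
  m2 <- filter_edges(net, alpha = 0.005, fdr_q = 0.05)$mask != 0
  expect_true(all(m1 | !m2))

  # the three filter variants nest as expected
  m_alpha <- filter_edges(net, alpha = 0.05, fdr_q = 0.05, mode = "alpha_only")$mask != 0
  m_fdr <- filter_edges(net, alpha = 0.05, fdr_q = 0.05, mode = "fdr_only")$mask != 0
  m_conj <- filter_edges(net, alpha = 0.05, fdr_q = 0.05)$mask != 0
  expect_true(all((m_alpha & m_fdr) == m_conj))
})

test_that("network density uses the R(R-1)/2 denominator exactly", {
  sat <- make_mask(10, pos_pairs = 45)
  expect_equal(network_density(sat, "any"), 1)

  m <- make_mask(115, pos_pairs = 1160, neg_pairs = 3)
  expect_equal(network_density(m, "negative"), 3 / 6555)
  expect_equal(network_density(m, "positive"), 1160 / 6555)
  expect_equal(network_density(m, "positive") + network_density(m, "negative"),
               network_density(m, "any"))

  # invariant to region permutation
  perm <- sample(115)
  mp <- m
  mp$mask <- m$mask[perm, perm]
  mp$regions <- m$regions[perm]
  expect_equal(network_density(mp, "negative"), network_density(m, "negative"))
})

test_that("density ratios and network comparison behave on constructed pairs", {
  expect_equal(density_ratio(5, 5), 1)
  expect_true(is.na(density_ratio(0.1, 0)))

  stats_of <- function(pos, neg) {
    mask <- make_mask(20, pos, neg)
    net <- list(regions = mask$regions,
                r = mask$mask * 0.9, p = (mask$mask == 0) * 1,
                n_pairs = matrix(6, 20, 20),
                undefined = matrix(FALSE, 20, 20), group = "g", n_animals = 6)
    class(net) <- "correlation_network"
    network_density_stats(net, mask)
  }
  sham <- stats_of(10, 2)
  active <- stats_of(10, 8)
  cmp <- compare_networks(sham, active)
  expect_equal(cmp$ratio[cmp$sign == "positive"], 1)
  expect_equal(cmp$edge_delta[cmp$sign == "positive"], 0)
  expect_gt(cmp$ratio[cmp$sign == "negative"], 1)

  same <- compare_networks(sham, sham)
  expect_true(all(same$ratio == 1))
  expect_true(all(same$edge_delta == 0))

  none <- stats_of(5, 0)
  cmp0 <- compare_networks(none, active)
  expect_true(is.na(cmp0$ratio[cmp0$sign == "negative"]))
  expect_equal(cmp0$edge_delta[cmp0$sign == "negative"], 8)

  small <- stats_of(1, 1)
  small$n_regions <- 10; small$n_potential <- 45
  expect_error(compare_networks(small, active), "different region sets")
})

test_that("hierarchical block summaries conserve and localise edge counts", {
  ont <- load_ontology(default_ontology_path())
  # single AMYG-STR negative edge
  m <- make_mask(115)
  m$regions <- ont$acronym
  dimnames(m$mask) <- list(ont$acronym, ont$acronym)
  i <- which(ont$acronym == "CEA"); j <- which(ont$acronym == "CP")
  m$mask[i, j] <- m$mask[j, i] <- -1L
  bs <- hierarchical_block_summary(m, ont)
  expect_equal(sum(bs$negative_edges), 1)
  expect_equal(sum(bs$positive_edges), 0)
  expect_equal(bs$negative_edges[bs$block_a == "AMYG" & bs$block_b == "STR"], 1)

  # random mask: block sums equal a brute-force recount and conserve totals
  set.seed(15)
  rnd <- make_mask(115, pos_pairs = 200, neg_pairs = 40)
  rnd$regions <- ont$acronym
  dimnames(rnd$mask) <- list(ont$acronym, ont$acronym)
  bs2 <- hierarchical_block_summary(rnd, ont)
  expect_equal(sum(bs2$positive_edges), 200)
  expect_equal(sum(bs2$negative_edges), 40)
  ho <- as.character(ont$higher_order)
  ut <- which(upper.tri(rnd$mask) & rnd$mask < 0, arr.ind = TRUE)
  recount <- table(apply(ut, 1, function(ij)
    paste(sort(c(ho[ij[1]], ho[ij[2]])), collapse = "|")))
  for (key in names(recount)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    row <- bs2[(bs2$block_a == parts[1] & bs2$block_b == parts[2]) |
                 (bs2$block_a == parts[2] & bs2$block_b == parts[1]), ]
    expect_equal(sum(row$negative_edges), unname(recount[key]))
  }

  bad <- make_mask(3)
  expect_error(hierarchical_block_summary(bad, ont), "R001")
})
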