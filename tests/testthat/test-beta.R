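test_that("Bray-Curtis matches the hand formula and its bounds", {
  tab <- make_otu_table(rbind(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3),
                              c(10, 0, 0)))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["s1", "s2"], (2 + 0 + 2) / 12)
  expect_equal(d["s1", "s3"], 0)                      # identical sites
  expect_equal(as.numeric(as.matrix(bray_curtis(
    make_otu_table(rbind(c(5, 0), c(0, 3)))))[1, 2]), 1) # disjoint supports
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_error(bray_curtis(tab[1, ]), "two sites")
})

test_that("PCoA recovers a Euclidean configuration exactly", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4), c(3, 4))
  rownames(pts) <- paste0("s", 1:4)
  d <- dist(pts)
  ord <- pcoa_ordination(d)
  rec <- dist(as.matrix(ord$coordinates[-1]))
  expect_equal(as.vector(rec), as.vector(d), tolerance = 1e-8)
  expect_true(all(ord$eigenvalues[1:2] > 0))
})

test_that("coincident sites get coincident coordinates", {
  tab <- make_otu_table(rbind(c(4, 1), c(4, 1), c(0, 9)))
  ord <- pcoa_ordination(bray_curtis(tab))
  co <- as.matrix(ord$coordinates[-1])
  expect_equal(co[1, ], co[2, ], tolerance = 1e-10)
})

test_that("PCoA eigenvalue sum equals the trace of the centered matrix", {
  for (s in 1:5) {
    tab <- random_otu_table(8, 20, seed = s)
    d <- bray_curtis(tab)
    ord <- pcoa_ordination(d)
    # independent Gower double-centering: B = -0.5 * J D^2 J
    D2 <- as.matrix(d)^2
    n <- nrow(D2)
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% D2 %*% J
    expect_equal(sum(ord$eigenvalues), sum(diag(B)), tolerance = 1e-9)
  }
})

test_that("PERMANOVA agrees with the exhaustive-enumeration oracle", {
  tab <- random_otu_table(6, 12, seed = 21)
  md <- two_group_metadata(tab, 3)
  d <- bray_curtis(tab)
  oracle <- permanova_oracle(d, md$land_use)

  fit <- permanova(d, md, "land_use", n_perm = 9999, seed = 1)
  row <- fit[fit$term == "land_use", ]
  expect_equal(row$f, oracle$f, tolerance = 1e-10)
  expect_equal(row$sum_sq, oracle$ss, tolerance = 1e-10)
  # permutation p converges to the enumeration value (within MC noise)
  expect_lt(abs(row$p_value - oracle$p_exact), 0.02)
})

test_that("PERMANOVA partitions variance and ignores site order", {
  sim <- small_sim(seed = 13)
  d <- bray_curtis(sim$counts)
  fit <- permanova(d, sim$metadata, c("country", "land_use", "country:land_use"),
                   n_perm = 99, seed = 2)
  expect_equal(sum(fit$r_squared[fit$term != "Total"]), 1, tolerance = 1e-9)
  expect_true(all(fit$p_value >= 1 / 100, na.rm = TRUE))

  # permuting input site order leaves every statistic unchanged
  shuffle <- sample(nrow(sim$counts))
  tab2 <- sim$counts[shuffle, ]
  fit2 <- permanova(bray_curtis(tab2), sim$metadata,
                    c("country", "land_use", "country:land_use"),
                    n_perm = 99, seed = 2)
  expect_equal(fit2$f, fit$f, tolerance = 1e-10)
  expect_equal(fit2$sum_sq, fit$sum_sq, tolerance = 1e-10)

  expect_error(permanova(d, dplyr::mutate(sim$metadata, land_use = "arable"),
                         "land_use"), "single level")
})

test_that("equal nonzero distances give the degenerate F = 1", {
  # with all off-diagonal distances equal to c, the sequential SS for a
  # k-level factor is c^2 (k-1)/2 and the pseudo-F is exactly 1
  n <- 8
  m <- matrix(1, n, n); diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  d <- as.dist(m * 0.6)
  md <- tibble::tibble(site_id = paste0("s", 1:n),
                       land_use = rep(c("arable", "grassland"), each = 4))
  fit <- permanova(d, md, "land_use", n_perm = 99, seed = 1)
  row <- fit[fit$term == "land_use", ]
  expect_equal(row$sum_sq, 0.6^2 * (2 - 1) / 2, tolerance = 1e-10)
  expect_equal(row$f, 1, tolerance = 1e-10)
})

test_that("Mantel statistics match the correlation formulas", {
  set.seed(5)
  tab <- random_otu_table(10, 25, seed = 31)
  a <- bray_curtis(tab)
  expect_equal(mantel_test(a, a, n_perm = 99, seed = 1)$r, 1) # a = b

  # partial r from the hand-substituted three-correlation formula
  mk <- function(seed) { set.seed(seed); dist(matrix(rnorm(5 * 3), 5)) }
  a5 <- mk(1); b5 <- mk(2); c5 <- mk(3)
  r_ab <- cor(as.vector(a5), as.vector(b5))
  r_ac <- cor(as.vector(a5), as.vector(c5))
  r_bc <- cor(as.vector(b5), as.vector(c5))
  expected <- (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  got <- partial_mantel_test(a5, b5, c5, n_perm = 99, seed = 1)
  expect_equal(got$r, expected, tolerance = 1e-12)

  # conditioning on an uncorrelated third matrix reduces to the simple r
  expect_equal(
    partial_mantel_test(a5, b5, c5, n_perm = 49, seed = 1)$conditioning,
    "third_matrix")
  expect_error(mantel_test(a5, as.dist(matrix(0.5, 5, 5) - diag(0.5, 5)),
                           n_perm = 9, seed = 1), "constant")
})

test_that("Mantel r is centered at zero for independent matrices", {
  rs <- vapply(1:200, function(s) {
    set.seed(s)
    a <- dist(matrix(rnorm(20 * 3), 20))
    b <- dist(matrix(rnorm(20 * 3), 20))
    cor(as.vector(a), as.vector(b))
  }, 0)
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("geographic and environmental distances have the stated geometry", {
  md <- tibble::tibble(site_id = c("a", "b", "c"),
                       latitude = c(90, 0, 0), longitude = c(0, 0, 0))
  g <- as.matrix(geo_distance(md))
  expect_equal(g["a", "b"], 10007.5, tolerance = 10007.5 * 0.001) # pole-equator
  expect_equal(g["b", "c"], 0)

  md2 <- tibble::tibble(site_id = c("a", "b"), x = c(1, 3))
  e <- env_distance(md2, vars = "x")
  expect_equal(as.numeric(e), 2) # two sites at z = +/-1

  md3 <- tibble::tibble(site_id = c("a", "b", "c"),
                        x = c(1, 2, NA), y = c(0, 1, 2))
  expect_warning(e3 <- env_distance(md3, vars = c("x", "y")), "missing")
  expect_equal(attr(e3, "Size"), 2)
})

test_that("strong country blocks separate in PCoA space", {
  # the generator's latitudinal niche kernel produces community turnover
  # along the gradient; a narrow bandwidth makes country blocks distinct
  sim <- simulate_community(sim_config(
    n_sites_arable = 25, n_sites_grassland = 25, n_otus = 400,
    depth = 1000, h = 0, geo_bandwidth = 4, seed = 17))
  ord <- pcoa_ordination(bray_curtis(sim$counts), k = 2)
  co_f <- factor(sim$metadata$country)
  xy <- as.matrix(ord$coordinates[-1])
  # mean silhouette on the first two axes must be positive
  dmat <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    own <- mean(dmat[i, co_f == co_f[i] & seq_along(co_f) != i])
    oth <- min(vapply(setdiff(levels(co_f), co_f[i]),
                      function(l) mean(dmat[i, co_f == l]), 0))
    (oth - own) / max(own, oth)
  }, 0)
  expect_gt(mean(sil), 0)
})
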