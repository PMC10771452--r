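test_that("cumulative curves match hand computation", {
  # one site, counts [4, 1]: sqrt gives [2, 1]
  tab <- make_otu_table(matrix(c(4, 1), 1))
  md <- tibble::tibble(site_id = tab$site_id, land_use = "grassland")
  cc <- cumulative_curve(tab, md)
  expect_equal(cc$mean_sqrt_abundance, c(2, 1))
  expect_equal(cc$cumulative, c(2, 3))
  expect_equal(unname(attr(cc, "endpoints")), 3)

  # two sites [[4,1],[9,0]]: rank means [(2+3)/2, (1+0)/2]
  tab2 <- make_otu_table(rbind(c(4, 1), c(9, 0)))
  md2 <- tibble::tibble(site_id = tab2$site_id, land_use = "grassland")
  cc2 <- cumulative_curve(tab2, md2)
  expect_equal(cc2$mean_sqrt_abundance, c(2.5, 0.5))
  expect_equal(unname(attr(cc2, "endpoints")), 3.0)

  expect_error(cumulative_curve(tab, md, land_use = "arable"), "no sites")
})

test_that("curve endpoint equals the mean per-site sqrt-count total", {
  for (s in 1:10) {
    tab <- random_otu_table(12, 30, seed = s)
    md <- two_group_metadata(tab, 7)
    cc <- cumulative_curve(tab, md)
    m <- as.matrix(tab[-1])
    for (u in c("arable", "grassland")) {
      expected <- mean(rowSums(sqrt(m[md$land_use == u, , drop = FALSE])))
      expect_equal(unname(attr(cc, "endpoints")[u]), expected,
                   tolerance = 1e-9)
    }
    # cumulative sequences are non-decreasing
    expect_true(all(tapply(cc$cumulative, cc$land_use,
                           function(x) all(diff(x) >= -1e-12))))
  }
})

test_that("per-rank Welch tests match the formula and handle degeneracies", {
  # identical strata: t must be exactly zero at every rank
  tab <- make_otu_table(rbind(c(9, 4, 1), c(9, 4, 1), c(9, 4, 1), c(9, 4, 1)))
  md <- two_group_metadata(tab, 2)
  res <- curve_rank_tests(tab, md)
  expect_true(all(res$t == 0))
  expect_true(all(res$p_value == 1))

  # hand-computed Welch t for {2,2,2} vs {5,5,6}
  x <- c(2, 2, 2); y <- c(5, 5, 6)
  se2 <- var(x) / 3 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  tab2 <- make_otu_table(matrix(c(x, y)^2, ncol = 1))
  md2 <- two_group_metadata(tab2, 3)
  res2 <- curve_rank_tests(tab2, md2, adjust = FALSE)
  expect_equal(res2$t, t_hand, tolerance = 1e-12)
  expect_equal(res2$df, df_hand, tolerance = 1e-12)
  expect_equal(res2$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  expect_error(curve_rank_tests(tab2, tibble::tibble(
    site_id = tab2$site_id, land_use = c("a", "a", "a", "b", "b", "c"))),
    "exactly two")
})

test_that("occupancy-abundance transformation and correlation direction", {
  tab <- make_otu_table(rbind(c(50, 3, 0), c(30, 1, 0), c(20, 0, 5)))
  oa <- occupancy_abundance(tab)
  expect_equal(oa$occupancy, c(3L, 2L, 1L))
  expect_equal(oa$transformed_abundance[1], log10(sqrt(100)))
  expect_equal(oa$transformed_abundance[1], 1) # 100 reads -> log10(10)

  sim <- small_sim(seed = 19)
  oa2 <- occupancy_abundance(sim$counts)
  sp <- attr(oa2, "spearman")
  expect_gt(sp[["rho"]], 0)
  expect_lt(sp[["p_value"]], 0.05)
})

test_that("Levins' niche breadth matches the formula and its bounds", {
  tab <- make_otu_table(cbind(c(5, 5, 5, 5), c(10, 0, 0, 0), c(6, 2, 1, 1)))
  bn <- levins_bn(tab)
  expect_equal(bn$b, c(4, 1, 1 / 0.42))
  expect_equal(bn$bn, c(1, 0.25, 1 / 0.42 / 4))
  expect_equal(bn$bn[3], 0.5952381, tolerance = 1e-6)

  # invariance: scaling one OTU's counts leaves its Bn unchanged
  tab2 <- tab
  tab2$otu3 <- tab2$otu3 * 7L
  expect_equal(levins_bn(tab2)$bn, bn$bn)

  # Bn in [1/R, 1], with 1 iff uniform
  for (s in 1:10) {
    x <- random_otu_table(6, 15, seed = 100 + s)
    v <- levins_bn(x)$bn
    expect_true(all(v >= 1 / 6 - 1e-12 & v <= 1 + 1e-12))
  }
  expect_error(levins_bn(tab[1, ]), "two sites")
})

test_that("the permutation null flags planted specialists only", {
  # an OTU proportional to site depths is a textbook generalist
  not_specialist <- vapply(1:60, function(s) {
    set.seed(s)
    depths <- sample(200:400, 8)
    focal <- round(0.15 * depths) # counts proportional to site totals
    other <- t(sapply(seq_along(depths), function(i) {
      as.vector(rmultinom(1, depths[i] - focal[i], rep(1, 10)))
    }))
    tab <- make_otu_table(cbind(other, focal))
    res <- bn_null_test(tab, n_perm = 199, seed = s)
    !res$specialist[11]
  }, NA)
  expect_gte(mean(not_specialist), 0.9)

  # all reads at one of 50 equal-depth sites: specialist with certainty
  m <- matrix(10, 50, 3)
  m <- cbind(m, c(40, rep(0, 49)))
  res <- bn_null_test(make_otu_table(m), n_perm = 999, seed = 1)
  expect_true(res$specialist[4])
  # permutation p floor
  expect_gte(min(res$p_null), 1 / 1000)
  expect_error(bn_null_test(make_otu_table(m), n_perm = 0, seed = 1), "n_perm")
})

test_that("rarity classification applies both gates and the partition", {
  # 4 grassland + 4 arable sites; otu1 at 1 grassland site only (rare);
  # otu2 at 3 grassland sites (occupancy gate fails); otu3 everywhere
  m <- rbind(
    c(8, 5, 9), c(0, 5, 9), c(0, 5, 9), c(0, 0, 9),  # grassland
    c(0, 0, 9), c(0, 0, 9), c(0, 0, 9), c(0, 0, 9))  # arable
  tab <- make_otu_table(m)
  md <- tibble::tibble(site_id = tab$site_id,
                       land_use = rep(c("grassland", "arable"), each = 4))
  cl <- classify_rarity(tab, md)
  expect_true(cl$rare_in_grassland[1])
  expect_false(cl$rare_in_arable[1])
  expect_equal(cl$partition, c("grassland_only", "grassland_only", "shared"))
  expect_false(cl$rare_in_grassland[2]) # occupancy 3 > cutoff
  expect_false(cl$rare_in_grassland[3]) # generalist Bn

  # flags invariant to site and OTU ordering
  perm_sites <- sample(nrow(tab)); perm_otus <- sample(2:ncol(tab))
  cl2 <- classify_rarity(tab[perm_sites, c(1, perm_otus)], md)
  cl2 <- cl2[match(cl$otu_id, cl2$otu_id), ]
  expect_equal(cl2$rare_in_grassland, cl$rare_in_grassland)
  expect_equal(cl2$partition, cl$partition)

  expect_error(classify_rarity(tab, md, occupancy_cutoff = 0), "occupancy_cutoff")
  expect_error(classify_rarity(tab, md, bn_cutoff = 1.5), "bn_cutoff")
})

test_that("planted rare OTUs are recovered from synthetic data", {
  sim <- small_sim(seed = 23)
  cl <- classify_rarity(sim$counts, sim$metadata)
  rec <- rarity_recall(cl, sim$truth, sim$counts, sim$metadata)
  gr <- rec$recall[rec$land_use == "grassland"]
  expect_true(is.na(gr) || gr >= 0.95)
  sm <- summarise_rarity(cl)
  expect_equal(sm$pct_shared + sm$pct_only_arable + sm$pct_only_grassland, 100,
               tolerance = 1e-9)
})

test_that("per-country rare proportions are well-formed", {
  sim <- small_sim(seed = 29)
  cl <- classify_rarity(sim$counts, sim$metadata)
  pr <- rare_proportion_by_country(sim$counts, sim$metadata, cl)
  expect_equal(nrow(pr), 5)
  expect_true(all(pr$proportion_rare >= 0 & pr$proportion_rare <= 1))
  expect_equal(pr$n_rare / pr$n_otus, pr$proportion_rare)
})

test_that("prevalent concentration finds the smallest dominating set", {
  tab <- make_otu_table(matrix(c(40, 60), 2, 1))
  md <- tibble::tibble(site_id = tab$site_id, land_use = "arable")
  expect_equal(prevalent_concentration(tab, md, "arable", 0.99), 1L)

  tab2 <- make_otu_table(rbind(c(25, 15, 10), c(25, 15, 10)))
  md2 <- tibble::tibble(site_id = tab2$site_id, land_use = "arable")
  expect_equal(prevalent_concentration(tab2, md2, "arable", 0.75), 2L)

  # k non-decreasing in the fraction
  tab3 <- random_otu_table(6, 25, seed = 37)
  md3 <- two_group_metadata(tab3, 3)
  ks <- vapply(seq(0.1, 1, by = 0.1), function(f) {
    prevalent_concentration(tab3, md3, "arable", f)
  }, 1L)
  expect_true(all(diff(ks) >= 0))
  expect_error(prevalent_concentration(tab3, md3, "arable", 1.2), "fraction")
})
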