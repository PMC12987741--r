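test_that("regional extraction averages exactly over parcel voxels", {
  lab <- array(0L, c(3, 1, 1))
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 2L
  tab <- data.frame(label = 1:2, name = c("a", "b"), network = "N")
  X <- rbind(c(1, 5, 9), c(2, 6, 10), c(0, 0, 0))
  s <- quick_series(as.vector(X), c(3, 1, 1))
  rt <- extract_regional_timeseries(s, parcel_map(lab, tab))
  expect_equal(unname(rt$values), X[1:2, ])          # single-voxel parcels

  lab2 <- array(0L, c(4, 1, 1)); lab2[1:2] <- 1L; lab2[3:4] <- 2L
  X2 <- rbind(c(1, 1, 1), c(3, 3, 3), c(5, 0, 1), c(7, 2, 1))
  s2 <- quick_series(as.vector(X2), c(4, 1, 1))
  rt2 <- extract_regional_timeseries(s2, parcel_map(lab2, tab))
  expect_equal(unname(rt2$values[1, ]), c(2, 2, 2))  # mean of (1,3) is 2

  expect_error(extract_regional_timeseries(quick_series(rnorm(8), c(2, 2, 1)),
                                           parcel_map(lab, tab)), "grid")
})

test_that("the full-scale parcellation yields one row per region", {
  sim <- simulate_subject(tiny_config(seed = 81, grid = c(16, 16, 12),
                                      n_parcels = 114))
  rt <- extract_regional_timeseries(sim$series, sim$parcels)
  expect_equal(nrow(rt$values), 114)
})

test_that("Pearson connectivity matches the direct covariance formula", {
  v <- with_test_seed(41, matrix(rnorm(5 * 50), 5, 50))
  rt <- region_timeseries(v, 1:5, 1)
  cm <- pearson_connectivity(rt)
  oracle <- matrix(1, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    xi <- v[i, ] - mean(v[i, ]); xj <- v[j, ] - mean(v[j, ])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_lt(max(abs(cm$values - oracle)), 1e-12)

  dup <- region_timeseries(rbind(v[1, ], v[1, ]), 1:2, 1)
  expect_equal(pearson_connectivity(dup)$values[1, 2], 1)
  opp <- region_timeseries(rbind(v[1, ], -v[1, ]), 1:2, 1)
  expect_equal(pearson_connectivity(opp)$values[1, 2], -1)
  const <- region_timeseries(rbind(v[1, ], rep(2, 50), rep(3, 50)), 1:3, 1)
  expect_error(pearson_connectivity(const), "region\\(s\\): 2, 3")
})

test_that("partial correlation removes shared confounds", {
  # intercept-only confound reduces to plain Pearson
  v <- with_test_seed(42, matrix(rnorm(4 * 80), 4, 80))
  rt <- region_timeseries(v, 1:4, 1)
  pc <- partial_corr_connectivity(rt, matrix(1, 80, 1))
  expect_lt(max(abs(pc$values - pearson_connectivity(rt)$values)), 1e-12)

  # two regions driven by the same confound decorrelate after adjustment
  T <- 500
  z <- with_test_seed(43, rnorm(T))
  noise <- with_test_seed(44, matrix(rnorm(3 * T), 3, T))
  rows <- rbind(z + 0.2 * noise[1, ], z + 0.2 * noise[2, ], noise[3, ])
  rt2 <- region_timeseries(rows, 1:3, 1)
  expect_gt(pearson_connectivity(rt2)$values[1, 2], 0.9)
  expect_lt(abs(partial_corr_connectivity(rt2, cbind(z))$values[1, 2]), 0.1)

  # closed-form single-confound oracle
  r12 <- pearson_connectivity(rt2)$values[1, 2]
  r1z <- cor(rows[1, ], z); r2z <- cor(rows[2, ], z)
  oracle <- (r12 - r1z * r2z) / sqrt((1 - r1z^2) * (1 - r2z^2))
  expect_equal(partial_corr_connectivity(rt2, cbind(z))$values[1, 2],
               oracle, tolerance = 1e-10)
})

test_that("top edges follow the ceil-plus-ties rule", {
  cm3 <- random_connectivity(3, 30, seed = 45)
  expect_equal(nrow(top_edges(cm3, 0.05)), 1)        # ceil(0.05*3) = 1
  cm10 <- random_connectivity(10, 40, seed = 46)
  expect_equal(nrow(top_edges(cm10, 1.0)), 45)
  # brute-force sort oracle
  vals <- sort(cm10$values[upper.tri(cm10$values)], decreasing = TRUE)
  for (fr in c(0.05, 0.2, 0.5)) {
    n <- ceiling(fr * 45)
    te <- top_edges(cm10, fr)
    expect_equal(te$value, vals[seq_len(n)])         # distinct values here
  }
  # ties at the cutoff are all included
  m <- diag(4); m[upper.tri(m)] <- c(0.5, 0.5, 0.5, 0.2, 0.2, 0.1)
  m <- m + t(m); diag(m) <- 1
  tied <- connectivity_matrix(m, 1:4)
  expect_equal(nrow(top_edges(tied, 1 / 6)), 3)
})

test_that("matrix comparison is rank-invariant where it should be", {
  a <- random_connectivity(6, 60, seed = 47)
  expect_equal(compare_matrices(a, a)$estimate, 1.0)
  expect_equal(compare_matrices(a, a)$n_pairs, 15)
  b <- connectivity_matrix(ifelse(diag(6) == 1, 1, a$values^3),
                           a$region_ids)
  expect_equal(compare_matrices(a, b, "spearman")$estimate, 1.0)
  expect_lt(compare_matrices(a, b, "pearson")$estimate, 1.0)
  # rank-then-Pearson oracle
  c2 <- random_connectivity(6, 30, seed = 48)
  la <- rank(a$values[lower.tri(a$values)])
  lc <- rank(c2$values[lower.tri(c2$values)])
  expect_equal(compare_matrices(a, c2)$estimate, cor(la, lc),
               tolerance = 1e-12)
  bad <- random_connectivity(5, 30, seed = 49)
  expect_error(compare_matrices(a, bad), "region")
})

test_that("group averaging is the element-wise mean with unit diagonal", {
  a <- random_connectivity(5, 40, seed = 50)
  expect_equal(group_mean_matrix(list(a))$values, a$values)
  neg <- connectivity_matrix(ifelse(diag(5) == 1, 1, -a$values),
                             a$region_ids)
  z <- group_mean_matrix(list(a, neg))
  expect_equal(z$values[lower.tri(z$values)], rep(0, 10))
  ms <- lapply(51:53, function(s) random_connectivity(5, 40, seed = s))
  gm <- group_mean_matrix(ms)
  oracle <- (ms[[1]]$values + ms[[2]]$values + ms[[3]]$values) / 3
  expect_lt(max(abs(gm$values - oracle)), 1e-15)
  expect_error(group_mean_matrix(list()), "empty")
  # fisher-z averaging shrinks less toward zero for strong edges
  expect_true(all(abs(group_mean_matrix(ms, fisher_z = TRUE)$values) >=
                    abs(gm$values) - 1e-12))
})

test_that("permuting regions permutes connectivity consistently", {
  v <- with_test_seed(54, matrix(rnorm(6 * 50), 6, 50))
  rt <- region_timeseries(v, 1:6, 1)
  perm <- c(3, 1, 6, 2, 5, 4)
  rtp <- region_timeseries(v[perm, ], perm, 1)
  a <- pearson_connectivity(rt)$values
  b <- pearson_connectivity(rtp)$values
  expect_lt(max(abs(b - a[perm, perm])), 1e-14)
})
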