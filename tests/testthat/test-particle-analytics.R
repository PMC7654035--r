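test_that("pooling concatenates replicates and reports missing keys", {
  ds <- sample_particles("anoxic0", 34, n_per_replicate = 1000, seed = 5)
  pooled <- pool_triplicates(ds, "anoxic0", 34)
  expect_equal(nrow(pooled), 3000)
  expect_equal(sort(unique(pooled$replicate)), 1:3)

  # single replicate: identity
  one <- ds$particles[ds$particles$replicate == 1, ]
  expect_equal(pool_triplicates(one, "anoxic0", 34)$diameter_nm, one$diameter_nm)

  expect_error(pool_triplicates(ds, "anoxic0", 99), "available")
  expect_error(pool_triplicates(ds, "nope", 34), "available")
})

test_that("size summaries match hand arithmetic and are order-invariant", {
  s1 <- summarize_sizes(c(30, 30, 30))
  expect_equal(s1$mean, 30); expect_equal(s1$sd, 0)
  expect_equal(s1$median, 30); expect_equal(s1$fraction_above, 0)

  s2 <- summarize_sizes(c(20, 30, 40))
  expect_equal(s2$mean, 30); expect_equal(s2$sd, 10)
  expect_equal(s2$median, 30); expect_equal(s2$fraction_above, 1 / 3)

  set.seed(1)
  d <- rlnorm(500, 3, 0.3)
  sa <- summarize_sizes(d); sb <- summarize_sizes(sample(d))
  expect_equal(sa$mean, sb$mean); expect_equal(sa$sd, sb$sd)
  expect_equal(sa$median, sb$median)

  # fraction above is monotone non-increasing in the threshold
  fr <- vapply(c(10, 20, 30, 40), function(th)
    summarize_sizes(d, threshold_nm = th)$fraction_above, numeric(1))
  expect_true(all(diff(fr) <= 0))

  expect_error(summarize_sizes(c(10, -2, 30)), "row")
  expect_error(summarize_sizes(25), "at least 2")
})

test_that("pooling then summarizing equals summarizing the concatenation", {
  ds <- sample_particles("microoxic1", 18, n_per_replicate = 400, seed = 8)
  pooled <- pool_triplicates(ds, "microoxic1", 18)
  expect_equal(summarize_sizes(pooled$diameter_nm)$mean,
               summarize_sizes(ds$particles$diameter_nm)$mean)
  expect_equal(summarize_sizes(pooled$diameter_nm)$sd,
               summarize_sizes(ds$particles$diameter_nm)$sd)
})

test_that("summaries recover the generating Gaussian within 3 standard errors", {
  for (case in list(list(r = "anoxic0", t = 34, m = 33.8, s = 9.4),
                    list(r = "microoxic1", t = 18, m = 29.3, s = 7.9))) {
    ds <- sample_particles(case$r, case$t, n_per_replicate = 1000, seed = 21)
    sm <- summarize_sizes(ds)
    se <- case$s / sqrt(sm$n)
    expect_lt(abs(sm$mean - case$m), 3 * se)
    expect_lt(abs(sm$sd - case$s), 3 * case$s / sqrt(2 * sm$n))
  }
})

test_that("per-cell densities follow the count/length tables", {
  one <- data.frame(length_um = 3, ms_count = 24)
  d1 <- per_cell_density(one)
  expect_equal(unname(d1$ms_per_cell["mean"]), 24)
  expect_equal(unname(d1$ms_per_um["mean"]), 8)
  expect_equal(unname(d1$ms_per_cell["sd"]), 0)

  same <- data.frame(length_um = rep(2, 5), ms_count = rep(16, 5))
  expect_equal(unname(per_cell_density(same)$ms_per_um["sd"]), 0)

  expect_error(per_cell_density(data.frame(length_um = 0, ms_count = 3)),
               "zero-length")

  # anoxic end-of-growth fixture: ~25 magnetosomes per cell, ~8.1 per um
  ds <- sample_particles("anoxic0", 34, seed = 7)
  dens <- per_cell_density(ds)
  expect_lt(abs(dens$ms_per_cell[["mean"]] - 25.3), 1)
  expect_lt(abs(dens$ms_per_um[["mean"]] - 8.1), 0.5)
})

test_that("rank-sum test: exchangeable null, small-sample enumeration, rejection rules", {
  # identical samples: p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # fully separated toy case: 1/C(4,2) one-sided, doubled
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r$p_value, 1 / 3)

  # exact mode refuses intractable tied problems
  set.seed(2)
  a <- rep(1:7, 2); b <- rep(4:10, 2)
  expect_error(wilcoxon_rank_sum(a, b, mode = "exact"), "n_a \\+ n_b")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact p-values agree with brute-force enumeration (with and without ties)", {
  set.seed(31)
  for (i in 1:5) {
    a <- round(runif(4, 0, 10), if (i %% 2) 3 else 0)  # integers force ties
    b <- round(runif(5, 0, 10), if (i %% 2) 3 else 0)
    res <- wilcoxon_rank_sum(a, b, mode = "exact")
    # oracle: enumerate all C(9,4) rank assignments with midranks
    rk <- rank(c(a, b))
    combos <- combn(9, 4)
    Ws <- colSums(matrix(rk[combos], nrow = 4))
    W <- sum(rk[1:4])
    p_oracle <- min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
    expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation p-values agree for moderate samples", {
  # balanced tie-free samples of n >= 10; agreement is asserted at moderate
  # significance levels, where the continuity-corrected normal
  # approximation is accurate in relative terms
  set.seed(170)
  tested <- 0
  for (i in 1:30) {
    n <- sample(10:14, 1)
    a <- rnorm(n); b <- rnorm(n, runif(1, 0.2, 0.6))
    pe <- wilcoxon_rank_sum(a, b, mode = "exact")$p_value
    # cross-check against the reference implementation in all cases
    expect_equal(pe, stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-10)
    if (pe < 0.05 || pe > 0.8) next
    pn <- wilcoxon_rank_sum(a, b, mode = "normal")$p_value
    expect_lt(abs(pe - pn) / pe, 0.10)
    tested <- tested + 1
  }
  expect_gte(tested, 10)
})

test_that("normal approximation matches the reference under heavy ties", {
  set.seed(23)
  a <- sample(1:8, 60, replace = TRUE)
  b <- sample(3:10, 70, replace = TRUE)
  ours <- wilcoxon_rank_sum(a, b, mode = "normal")$p_value
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("condition contrast on full-size fixtures is overwhelmingly significant", {
  seedtrain <- sample_particles("anoxic0", 0, n_per_replicate = 975, seed = 41)
  end <- sample_particles("anoxic0", 20, n_per_replicate = 1019, seed = 42)
  r <- wilcoxon_rank_sum(seedtrain$particles$diameter_nm,
                         end$particles$diameter_nm)
  expect_lt(r$p_value, 1e-4)

  # same-distribution contrast is not significant
  a <- sample_particles("anoxic0", 34, n_per_replicate = 500, seed = 43)
  b <- sample_particles("anoxic0", 34, n_per_replicate = 500, seed = 44)
  r2 <- wilcoxon_rank_sum(a$particles$diameter_nm, b$particles$diameter_nm)
  expect_gt(r2$p_value, 0.01)
})
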