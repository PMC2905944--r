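test_that("pca_reduce whitens exactly and accounts for variance", {
  set.seed(3)
  fx <- mc_fixture(t = 30, v = 400, n = 2)
  white <- pca_reduce(fx$run, 2)
  v <- ncol(fx$run$data)
  expect_lt(max(abs(tcrossprod(white$scores) / v - diag(2))), 1e-6)
  expect_lt(white$residual_variance_fraction, 1e-10)   # exact rank 2

  # reconstruction error equals the sum of discarded eigenvalues
  set.seed(4)
  x <- matrix(rnorm(50 * 500), 50, 500)
  run <- mat_run(x)
  white10 <- pca_reduce(run, 10)
  xc <- sweep(x, 2, colMeans(x), "-")
  recon <- white10$dewhitening %*% white10$scores
  err <- sum((xc - recon)^2) / 500
  eig <- eigen(tcrossprod(xc) / 500, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(err, sum(eig[-(1:10)]), tolerance = 1e-8)
  expect_equal(white10$explained_variance, eig[1:10] / sum(eig),
               tolerance = 1e-10)

  white1 <- pca_reduce(run, 1)
  expect_length(white1$explained_variance, 1)
  expect_equal(white1$explained_variance, eig[1] / sum(eig),
               tolerance = 1e-10)
  expect_error(pca_reduce(run, 50), "n_components")
})

test_that("fastica recovers sparse non-Gaussian sources and is seed-deterministic", {
  set.seed(7)
  v <- 2000
  s <- matrix(rnorm(2 * v), 2, v)
  s[abs(s) < 1.2] <- 0                       # sparse sources
  a <- matrix(c(1, 0.6, -0.4, 1), 2, 2)      # mixing
  x <- cbind(sin(1:40), cos(1:40)) %*% a %*% s   # t=40 run, rank 2
  run <- mat_run(x)
  white <- pca_reduce(run, 2)
  cs <- fastica_spatial(white, rng_seed = 11)
  expect_true(cs$converged)
  expect_true(all(best_match_r(s, cs$zmaps) > 0.95))

  cs2 <- fastica_spatial(white, rng_seed = 11)
  expect_identical(cs$timecourses, cs2$timecourses)  # bit-identical
  expect_identical(cs$zmaps, cs2$zmaps)

  # z-scored maps have mean 0, variance 1
  expect_true(all(abs(rowMeans(cs$zmaps)) < 1e-8))
  expect_true(all(abs(apply(cs$zmaps, 1, var) - 1) < 1e-8))
  # map skewness sign convention
  sk <- apply(cs$zmaps, 1, function(m) mean((m - mean(m))^3))
  expect_true(all(sk >= 0))
})

test_that("ICA reconstruction matches the rank-N PCA reconstruction", {
  set.seed(12)
  fx <- mc_fixture(t = 40, v = 800, n = 3, seed = 12)
  x <- fx$run$data
  x <- x + matrix(rnorm(length(x), sd = 0.05), nrow(x))
  run <- mat_run(x)
  white <- pca_reduce(run, 3)
  cs <- fastica_spatial(white, rng_seed = 5)
  xc <- sweep(x, 2, colMeans(x), "-")
  pca_recon <- white$dewhitening %*% white$scores
  ica_recon <- cs$timecourses %*% cs$maps
  expect_lt(sum((ica_recon - pca_recon)^2) / sum(pca_recon^2), 1e-6)
  # variance fractions are nonincreasing and sum to the retained share
  expect_true(all(diff(cs$variance_fraction) <= 1e-12))
  expect_equal(sum(cs$variance_fraction),
               1 - white$residual_variance_fraction, tolerance = 1e-6)
})

test_that("source recovery holds across seeds and source counts", {
  rs <- c()
  for (seed in 1:10) {
    set.seed(seed + 100)
    k <- sample(2:5, 1)
    v <- 1500
    s <- matrix(rnorm(k * v), k, v); s[abs(s) < 1.2] <- 0
    tt <- 50
    m <- sapply(seq_len(k), function(i) sin(2 * pi * i * seq_len(tt) / tt + i))
    run <- mat_run(m %*% s)
    cs <- fastica_spatial(pca_reduce(run, k), rng_seed = seed)
    rs <- c(rs, best_match_r(s, cs$zmaps))
  }
  expect_gt(mean(rs), 0.95)
})

test_that("rank_by_variance orders descending with stable ties", {
  set.seed(2)
  t <- 30; v <- 300
  # zero-mean orthogonal time courses and spatially orthogonal maps (as ICA
  # components are): cross-terms vanish, so per-component variances add up
  m <- qr.Q(qr(cbind(1, matrix(rnorm(t * 3), t, 3))))[, 2:4]
  cmaps <- t(qr.Q(qr(matrix(rnorm(3 * v), v, 3))))
  scale <- sqrt(c(0.1, 0.3, 0.2))
  x <- m %*% (scale * cmaps)
  run <- mat_run(x)
  cs <- component_set(m, scale * cmaps)
  ranked <- rank_by_variance(cs, run)
  expect_true(all(diff(ranked$variance_fraction) <= 1e-12))
  # noise-free: fractions sum to 1
  expect_equal(sum(ranked$variance_fraction), 1, tolerance = 1e-6)

  # tie rule: exactly equal fractions stay in original order (fixture uses
  # binary-exact values so the tie is bitwise)
  m2 <- cbind(c(0.5, -0.5, 0.5, -0.5, rep(0, 8)),
              c(rep(0, 4), 0.5, -0.5, 0.5, -0.5, rep(0, 4)))
  maps2 <- rbind(c(1, 0, 0, 0, rep(0, 6)), c(0, 1, 0, 0, rep(0, 6)))
  cs_tie <- component_set(m2, maps2)
  ranked_tie <- rank_by_variance(cs_tie, mat_run(m2 %*% maps2))
  expect_identical(ranked_tie$maps[1, ], maps2[1, ])
  expect_identical(ranked_tie$maps[2, ], maps2[2, ])
})

test_that("group_ica finds a shared source and reduces to single-run ICA", {
  tpl <- group_config(noise_sd_pct = 0.5, n_subjects = 3)
  # subjects share the sources exactly: no jitter, no amplitude spread
  tpl$components <- lapply(tpl$components, function(cs) {
    cs$per_subject_amplitude_sd <- 0; cs$spatial_jitter_voxels <- 0; cs
  })
  subs <- make_group(tpl, 3, rng_seed = 21)
  runs <- lapply(subs, function(s) normalize_run(s$run))
  model <- group_ica(runs, 4, rng_seed = 2)
  expect_equal(vapply(model$subject_ranges, function(r) diff(r) + 1L,
                      integer(1)), rep(tpl$t, 3))
  truth <- subs[[1]]$truth$component_masks$motor$include
  rs <- abs(cor(t(model$group_components$zmaps), as.numeric(truth)))
  expect_gt(max(rs), 0.9)

  # single subject: group ICA equals single-run ICA at the same seed
  m1 <- group_ica(runs[1], 3, rng_seed = 9)
  direct <- fastica_spatial(pca_reduce(runs[[1]], 3), rng_seed = 9)
  expect_equal(m1$group_components$zmaps, direct$zmaps, tolerance = 1e-8)
})

test_that("back_reconstruct degenerates correctly and respects amplitude", {
  tpl <- group_config(noise_sd_pct = 0.5, n_subjects = 1)
  subs <- make_group(tpl, 1, rng_seed = 31)
  runs <- lapply(subs, function(s) normalize_run(s$run))
  model <- group_ica(runs, 3, rng_seed = 4)
  br <- back_reconstruct(model, runs, 1)
  # one-subject group: per-component |r| = 1 against group maps
  rs <- abs(diag(cor(t(br$zmaps), t(model$group_components$zmaps))))
  expect_true(all(rs > 1 - 1e-6))
  expect_error(back_reconstruct(model, runs, 5), "subject")

  # a subject with zero amplitude on one component shows a suppressed map:
  # compact high-contrast blobs so the z-scored peak clears the noise floor
  g2 <- geometry(c(24, 24, 4), tr = 4)
  blob_a <- component_spec("a", voxels_sphere(g2, c(6, 6, 1), 1.9),
                           block_hrf(seq(12, by = 24, length.out = 9), 12),
                           amplitude_pct = 2)
  blob_b <- component_spec("b", voxels_sphere(g2, c(17, 17, 2), 1.9),
                           block_hrf(seq(8, by = 32, length.out = 7), 16),
                           amplitude_pct = 2)
  tpl2 <- list(grid = g2, baseline_mean = 1000,
               components = list(blob_a, blob_b), noise_sd_pct = 0.5,
               t = 60)
  subs2 <- make_group(tpl2, 3, rng_seed = 32)
  tpl_null <- tpl2
  tpl_null$components[[2]]$amplitude_pct <- 0   # subject 2 lacks blob b
  subs2[[2]] <- make_group(tpl_null, 3, rng_seed = 32)[[2]]
  runs2 <- lapply(subs2, function(s) normalize_run(s$run))
  model2 <- group_ica(runs2, 4, rng_seed = 6)
  b_mask <- subs2[[1]]$truth$component_masks$b$include
  ref <- stat_map(as.numeric(b_mask), runs2[[1]]$mask, "raw")
  k <- match_component(model2$group_components, ref)$index
  grp_peak <- max(abs(model2$group_components$zmaps[k, b_mask]))
  br2 <- back_reconstruct(model2, runs2, 2)
  sub_peak <- max(abs(br2$zmaps[k, b_mask]))
  expect_lt(sub_peak, grp_peak / 2)

  # variance accounting: the reconstruction residual is bounded by the
  # injected noise fraction (computed from the generating truth) plus the
  # PCA-discarded share plus 10% slack
  br1 <- back_reconstruct(model2, runs2, 1)
  x1 <- runs2[[1]]$data                       # variance-normalized
  resid <- x1 - br1$timecourses %*% br1$maps
  noise_sd <- tpl2$noise_sd_pct / 100 * tpl2$baseline_mean
  noise_frac_total <- mean(vapply(seq_len(ncol(x1)), function(j) {
    sig_var <- 0
    for (cs in subs2[[1]]$truth$component_masks)
      if (cs$include[j]) {
        nm <- names(which(vapply(subs2[[1]]$truth$component_masks,
                                 function(m) m$include[j], logical(1))))[1]
        w <- subs2[[1]]$truth$waveforms[[nm]]$values
        amp <- subs2[[1]]$truth$amplitudes[[nm]]
        sig_var <- var(w) * (amp / 100 * tpl2$baseline_mean)^2
      }
    noise_sd^2 / (noise_sd^2 + sig_var)
  }, numeric(1)))
  cat_run <- concat_group(runs2)
  discarded <- pca_reduce(cat_run, 4)$residual_variance_fraction
  expect_lt(sum(resid^2) / sum(x1^2), noise_frac_total + discarded + 0.1)
})

test_that("match_component picks the best map and fixes sign", {
  set.seed(13)
  cs <- component_set(matrix(rnorm(20 * 3), 20, 3),
                      matrix(rnorm(3 * 500), 3, 500))
  mask <- full_mask(flat_geom(500))
  ref <- stat_map(cs$zmaps[3, ], mask, "z")
  m <- match_component(cs, ref)
  expect_equal(m$index, 3)
  expect_equal(m$correlation, 1, tolerance = 1e-10)
  expect_false(m$flipped)

  ref_neg <- stat_map(-cs$zmaps[3, ], mask, "z")
  m2 <- match_component(cs, ref_neg)
  expect_equal(m2$index, 3)
  expect_equal(m2$correlation, 1, tolerance = 1e-10)
  expect_true(m2$flipped)
  expect_equal(cor(m2$component$zmaps[1, ], ref_neg$values), 1,
               tolerance = 1e-10)

  set.seed(14)
  mask5k <- full_mask(flat_geom(5000))
  cs5 <- component_set(matrix(rnorm(20 * 3), 20, 3),
                       matrix(rnorm(3 * 5000), 3, 5000))
  ref_orth <- stat_map(rnorm(5000), mask5k, "z")
  m3 <- match_component(cs5, ref_orth)
  expect_lt(m3$correlation, 0.2)
  expect_true(m3$weak)
  expect_error(match_component(cs5, stat_map(rep(1, 5000), mask5k, "z")),
               "constant")
})

test_that("model order estimation follows the eigen-spectrum", {
  set.seed(40)
  t <- 60; v <- 2000
  s <- qr.Q(qr(matrix(rnorm(t * 3), t, 3)))
  run <- mat_run(s %*% matrix(rnorm(3 * v), 3, v) * 10 +
                   matrix(rnorm(t * v, sd = 1e-3), t, v))
  for (meth in c("AIC", "BIC", "MDL")) {
    est <- estimate_dim(run, meth)
    expect_gte(est, 3)
    expect_identical(est, estimate_dim(run, meth))  # deterministic
  }
  # pure noise: BIC/MDL majority at most 3 over seeds
  low <- sapply(1:20, function(sd) {
    set.seed(sd + 500)
    r <- mat_run(matrix(rnorm(t * v), t, v))
    c(estimate_dim(r, "BIC"), estimate_dim(r, "MDL"))
  })
  expect_gt(mean(low <= 3), 0.5)
})
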