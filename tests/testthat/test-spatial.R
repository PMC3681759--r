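test_that("empirical CDF summaries follow the order-statistic definition", {
  e <- empirical_cdf(c(3, 1, 2))
  expect_equal(e$d50, 2)
  expect_equal(e$mean_um, 2)
  expect_equal(empirical_cdf(rep(4.2, 9))$d50, 4.2)
  expect_equal(distance_d50(c(5, 1)), 1)  # CDF reaches 0.5 at the 1st of 2
  expect_error(empirical_cdf(numeric(0)), "empty")
})

test_that("the closed-form CSR curve matches algebra and a Poisson oracle", {
  expect_equal(csr_closed_form(0, 3), 0)
  lam <- 2
  r_half <- sqrt(log(2) / (lam * pi))
  expect_equal(csr_closed_form(r_half, lam), 0.5)
  expect_error(csr_closed_form(-1, 1), "non-negative")

  # oracle: nearest-event distances from reference points to a simulated
  # homogeneous Poisson process (1e5 events), found by slab-binned exact search
  set.seed(42)
  L <- 100; lambda <- 10
  n_ev <- rpois(1, lambda * L^2)
  ex <- runif(n_ev, 0, L); ey <- runif(n_ev, 0, L)
  ord <- order(ex); ex <- ex[ord]; ey <- ey[ord]
  rmax <- 0.6
  refd <- numeric(0)
  for (b in 1:98) {
    px <- runif(300, b, b + 1); py <- runif(300, 1, L - 1)
    lo <- findInterval(b - rmax, ex); hi <- findInterval(b + 1 + rmax, ex)
    cx <- ex[(lo + 1):hi]; cy <- ey[(lo + 1):hi]
    d2 <- outer(px^2 + py^2, cx^2 + cy^2, "+") -
      2 * cbind(px, py) %*% rbind(cx, cy)
    best <- max.col(-d2, ties.method = "first")
    refd <- c(refd, sqrt(pmax(0, d2[cbind(1:300, best)])))
  }
  rs <- seq(0, 0.5, by = 0.005)
  expect_lt(max(abs(ecdf(refd)(rs) - csr_closed_form(rs, lambda))), 0.01)
})

test_that("pCSR on a full frame reproduces the analytic lattice CDF", {
  # square: frame = 10 x 10 whole cells, margin so edge points see the true
  # nearest centre of the infinite lattice
  lat <- make_lattice(lattice_spec("square", 1, 1, c(20, 20), 0.1,
                                   border_x_um = -1e9), margin_um = 2)
  fm <- full_frame_mask(200, 200)
  d <- simulate_pcsr(fm, n_patches = 10000, lattice = lat, n_reps = 19,
                     seed = 7)[[1]]
  rs <- seq(0, 1.45, by = 0.01)
  expect_lt(max(abs(ecdf(d)(rs) - lattice_distance_cdf(rs, "square", 2))),
            0.02)
  # hexagonal, frame covering whole periods to rounding
  lath <- make_lattice(lattice_spec("hexagonal", 1, 1, c(17.3, 20), 0.1,
                                    border_x_um = -1e9), margin_um = 3)
  dh <- simulate_pcsr(full_frame_mask(173, 200), 10000, lath, 19,
                      seed = 8)[[1]]
  rsh <- seq(0, 1.2, by = 0.01)
  expect_lt(max(abs(ecdf(dh)(rsh) - lattice_distance_cdf(rsh, "hexagonal", 2))),
            0.02)
})

test_that("pCSR replicates are seeded, mask-bound and guard their inputs", {
  lat <- fixture_lattice(extent = c(20, 20))
  mask <- generate_neurite_mask(c(20, 20), 1, seed = 3)
  r1 <- simulate_pcsr(mask, 30, lat, 19, seed = 5)
  r2 <- simulate_pcsr(mask, 30, lat, 19, seed = 5)
  expect_identical(r1, r2)
  expect_error(simulate_pcsr(mask, sum(mask$mask) + 1L, lat, 19, seed = 1),
               "exceeds")
  # degenerate mask: the single pixel containing a pillar centre
  one <- matrix(FALSE, 200, 200)
  ctr <- lat$centers[1, ]
  one[round(ctr$y_um / 0.1 + 0.5), round(ctr$x_um / 0.1 + 0.5)] <- TRUE
  m1 <- neurite_mask_from_matrix(one, 0.1)
  d <- simulate_pcsr(m1, 1, lat, 19, seed = 2, jitter = FALSE)
  expect_true(all(abs(unlist(d)) < 0.1))  # pixel centre vs exact centre
})

test_that("envelopes follow the linear-interpolation percentile rule", {
  expect_equal(unname(envelope(rep(2.5, 50))), c(2.5, 2.5))
  env <- envelope(as.numeric(1:100), level = 0.95)
  expect_equal(unname(env), c(3.475, 97.525))
  env90 <- envelope(as.numeric(1:100), level = 0.90)
  expect_gte(env90[1], env[1])  # narrower level, narrower interval
  expect_lte(env90[2], env[2])
  expect_error(envelope(1:10), "19")
  expect_error(envelope(1:19, level = 0.95), "replicates")
})

test_that("rank p-values count ties as exceedances", {
  reps <- as.numeric(1:999)
  expect_equal(mc_pvalue(0.5, reps, "attraction"), 1 / 1000)
  expect_equal(mc_pvalue(1000, reps, "repulsion"), 1 / 1000)
  expect_equal(mc_pvalue(500, reps, "attraction"), 501 / 1000)
  # a tie with the smallest replicate counts against attraction
  expect_equal(mc_pvalue(1, reps, "attraction"), 2 / 1000)
  expect_error(mc_pvalue(1, 1:5, "attraction"), "19")
})

test_that("per-image analysis detects built-in attraction and composes", {
  img <- fixture_spatial_image(seed = 77, alpha = 1, sigma = 0.2)
  res <- analyze_image(img$patches, img$mask, img$lattice, n_reps = 199,
                       seed = 78)
  expect_lt(res$observed_d50, res$lower_um)
  expect_lt(res$p_attraction, 0.05)
  expect_equal(res$n_patches, nrow(img$patches))
  expect_lte(res$lower_um, res$upper_um)
  expect_gt(res$p_repulsion, res$p_attraction)
  # the mean statistic is exposed through the switch
  res_m <- analyze_image(img$patches, img$mask, img$lattice, n_reps = 199,
                         seed = 78, statistic = "mean")
  expect_equal(res_m$observed_stat, res_m$observed_mean)
  expect_error(analyze_image(img$patches[0, ], img$mask, img$lattice),
               "no observed patches")
})

test_that("aggregation averages envelopes and applies the verdict rule", {
  img <- fixture_spatial_image(seed = 81)
  res <- analyze_image(img$patches, img$mask, img$lattice, n_reps = 199,
                       seed = 82)
  agg1 <- aggregate_condition(list(res))
  expect_equal(agg1$mean_observed_um, res$observed_stat)
  expect_equal(agg1$mean_lower_um, res$lower_um)
  expect_equal(agg1$n_images, 1L)
  fake <- function(obs, lo, hi) structure(
    list(observed_stat = obs, lower_um = lo, upper_um = hi,
         statistic = "d50"), class = "envelope_result")
  expect_equal(aggregate_condition(list(fake(1, 2, 3), fake(1.5, 2.5, 3.5)))$verdict,
               "attraction")
  expect_equal(aggregate_condition(list(fake(4, 2, 3)))$verdict, "repulsion")
  expect_equal(aggregate_condition(list(fake(2.5, 2, 3)))$verdict, "neutral")
  expect_error(aggregate_condition(list()), "no per-image")
})

test_that("mean patch-to-pillar distance grows with pillar spacing", {
  means <- vapply(seq_along(c(0.6, 2, 5)), function(i) {
    s <- c(0.6, 2, 5)[i]
    lat <- fixture_lattice(width = 1.6, spacing = s, extent = c(35, 35))
    img <- fixture_spatial_image(seed = 200 + i, lattice = lat,
                                 extent = c(35, 35))
    mean(nearest_pillar_distances(img$patches$x_um, img$patches$y_um, lat))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
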