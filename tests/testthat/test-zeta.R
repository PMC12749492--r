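test_that("worked three-site example matches hand enumeration", {
  inc <- sets_to_incidence(three_site_sets)
  expect_equal(zeta_order(inc, 1)$mean, 3)
  expect_equal(zeta_order(inc, 2)$mean, 5 / 3)
  expect_equal(zeta_order(inc, 2, normalization = "jaccard")$mean, 0.4)
  expect_equal(zeta_order(inc, 3)$mean, 1)
  expect_equal(zeta_order(inc, 3, normalization = "jaccard")$mean, 0.2)
})

test_that("degenerate incidence structures give the expected zeta", {
  # identical sites: jaccard zeta = 1 at every order
  ident <- sets_to_incidence(list(a = c("x", "y"), b = c("x", "y"),
                                  c = c("x", "y")))
  for (i in 1:3) {
    expect_equal(zeta_order(ident, i, normalization = "jaccard")$mean, 1)
  }
  # pairwise-disjoint sites: zeta2 = 0
  disj <- sets_to_incidence(list(a = "x", b = "y", c = "z"))
  expect_equal(zeta_order(disj, 2)$mean, 0)
})

test_that("zeta order validates its arguments", {
  inc <- sets_to_incidence(three_site_sets)
  expect_error(zeta_order(inc, 0), ">= 1")
  expect_error(zeta_order(inc, 4), "exceeds")
})

test_that("raw zeta1 equals mean site richness and decline is non-increasing", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(runif(200) < 0.4, 20, 10,
                dimnames = list(paste0("t", 1:20), paste0("s", 1:10)))
    inc <- incidence_matrix(m * 1)
    expect_equal(zeta_order(inc, 1)$mean, mean(colSums(m)))
    z <- vapply(1:6, function(i) zeta_order(inc, i)$mean, numeric(1))
    expect_true(all(diff(z) <= 1e-12))
  }
})

test_that("monte-carlo zeta agrees with exhaustive enumeration within 3 SE", {
  inc <- simulate_incidence("uniform_random", 50, 10, p = 0.4, seed = 3)
  sets <- apply(unclass(inc), 2, function(col) rownames(inc)[col],
                simplify = FALSE)
  for (i in 2:4) {
    ex <- oracle_zeta(sets, i)
    mc <- zeta_order(inc, i, mode = "monte_carlo", n_subsamples = 1000,
                     seed = 99)
    se <- mc$sd / sqrt(mc$n_evaluated)
    expect_lt(abs(mc$mean - ex), 3 * se + 1e-12)
    expect_equal(zeta_order(inc, i)$mean, ex) # auto mode = exhaustive here
  }
})

test_that("zeta statistics are invariant to taxon relabelling and site order", {
  inc <- simulate_incidence("niche_gradient", 30, 8, seed = 5)
  base <- vapply(1:4, function(i) zeta_order(inc, i)$mean, numeric(1))
  m <- unclass(inc)
  shuffled <- m[sample(nrow(m)), sample(ncol(m))]
  inc2 <- incidence_matrix(shuffled * 1)
  expect_equal(vapply(1:4, function(i) zeta_order(inc2, i)$mean, numeric(1)),
               base)
})

test_that("decline fits recover exactly generated power and exponential curves", {
  # bypass the incidence layer: feed exact decline points to the fitter
  orders <- 1:6
  pw <- forelandr:::fit_decline_models(orders, 10 * orders^-1)
  expect_equal(pw$selected_model, "power")
  expect_equal(pw$power$slope, -1, tolerance = 1e-9)
  expect_lt(pw$power$aic, pw$exponential$aic)

  ex <- forelandr:::fit_decline_models(orders, 10 * exp(-0.5 * orders))
  expect_equal(ex$selected_model, "exponential")
  expect_equal(ex$exponential$slope, -0.5, tolerance = 1e-9)
})

test_that("zeta_decline output is internally consistent", {
  inc <- simulate_incidence("niche_gradient", 40, 10, seed = 2)
  d <- zeta_decline(inc, i_max = 6, n_subsamples = 300, seed = 2)
  expect_equal(d$orders$order, 1:6)
  expect_true(all(diff(d$orders$zeta) <= 1e-9))
  expect_true(all(d$orders$zeta_jaccard >= 0 & d$orders$zeta_jaccard <= 1))
  expect_true(d$selected_model %in% c("power", "exponential"))
  expect_equal(d$ratio_z2_z1, d$orders$zeta[2] / d$orders$zeta[1])
})

test_that("assembly process drives decline model selection", {
  # deterministic niche-gradient incidence -> power law; uniform-random
  # incidence -> exponential (majority over seeds)
  n_seeds <- 40
  pick <- function(type) {
    vapply(seq_len(n_seeds), function(s) {
      inc <- simulate_incidence(type, 50, 10, p = 0.3, seed = s)
      suppressWarnings(
        zeta_decline(inc, 6, n_subsamples = 200, seed = s)$selected_model)
    }, character(1))
  }
  expect_gt(mean(pick("niche_gradient") == "power"), 0.5)
  expect_gt(mean(pick("uniform_random") == "exponential"), 0.5)
})

test_that("distance decay handles identical composition and co-located sites", {
  coords <- data.frame(site = paste0("s", 1:4), lat = c(0, 0.1, 0.2, 0.3),
                       lon = 0)
  ident <- sets_to_incidence(
    setNames(rep(list(c("x", "y")), 4), paste0("s", 1:4)), coords = coords)
  d <- zeta_distance_decay(ident, i = 2)
  expect_equal(d$slope, 0)
  expect_false(d$r2_defined)

  same <- coords; same$lat <- 0
  inc2 <- sets_to_incidence(list(s1 = "x", s2 = "y", s3 = "z", s4 = "w"),
                            coords = same)
  expect_error(zeta_distance_decay(inc2, i = 2), "co-located")
})

test_that("distance decay recovers a constructed near-linear similarity slope", {
  # sites 1 km apart on a planar transect; taxa are windows of width 50 in
  # site coordinates, so pairwise jaccard = (W - d)/(W + d) ~ 1 - 2d/W,
  # linear to first order with slope -2/W per km
  n_sites <- 8; W <- 50
  pos <- seq_len(n_sites)
  starts <- seq(-W + 1, n_sites - 0.5, by = 0.25)
  m <- t(vapply(starts, function(s0) pos >= s0 & pos <= s0 + W, logical(n_sites)))
  dimnames(m) <- list(sprintf("w%03d", seq_along(starts)),
                      sprintf("s%d", seq_len(n_sites)))
  coords <- data.frame(site = colnames(m), lat = pos, lon = 0)
  inc <- structure(m, coords = coords,
                   class = c("incidence_matrix", "matrix"))
  d <- zeta_distance_decay(inc, i = 2, planar = TRUE)
  expect_equal(d$slope, -2 / W, tolerance = 0.05)
  expect_gt(d$r2, 0.95)
})

test_that("pairwise decay is steeper than four-way decay for generalist/specialist mixtures", {
  # widespread generalists co-existing with narrow-range specialists: the
  # four-way intersections are dominated by the slow-turnover generalists,
  # so the two-way decay coefficient has the larger magnitude
  mix_inc <- function(n_sites, n_gen, n_narrow, seed) {
    set.seed(seed)
    m <- matrix(FALSE, n_gen + n_narrow, n_sites)
    m[seq_len(n_gen), ] <- TRUE
    for (t in (n_gen + 1):(n_gen + n_narrow)) {
      b <- sample(1:3, 1)
      s0 <- sample.int(n_sites - b + 1, 1)
      m[t, s0:(s0 + b - 1)] <- TRUE
    }
    dimnames(m) <- list(sprintf("t%03d", seq_len(nrow(m))),
                        sprintf("s%02d", seq_len(n_sites)))
    structure(m, coords = data.frame(site = colnames(m),
                                     lat = seq_len(n_sites), lon = 0),
              class = c("incidence_matrix", "matrix"))
  }
  wins <- vapply(1:5, function(s) {
    inc <- mix_inc(12, 30, 120, seed = s)
    b2 <- zeta_distance_decay(inc, i = 2, planar = TRUE, seed = 1)$slope
    b4 <- zeta_distance_decay(inc, i = 4, planar = TRUE, seed = 1,
                              n_subsamples = 400)$slope
    abs(b2) > abs(b4)
  }, logical(1))
  expect_true(all(wins))
})

test_that("variation partitioning fractions behave and sum to one", {
  set.seed(21)
  n <- 10
  age <- seq(0, 100, length.out = n)
  # composition driven by age: taxa occupy contiguous age ranges
  taxa_ranges <- cbind(runif(60, -30, 90), width = runif(60, 20, 60))
  m <- t(apply(taxa_ranges, 1, function(r) age >= r[1] & age <= r[1] + r[2]))
  dimnames(m) <- list(sprintf("t%02d", 1:60), sprintf("s%02d", 1:n))
  inc <- incidence_matrix(m * 1)
  env <- data.frame(age = age, noise1 = rnorm(n), noise2 = rnorm(n))

  vp <- zeta_varpart(inc, env, group1 = "age", group2 = c("noise1", "noise2"))
  expect_equal(vp$a + vp$b + vp$c + vp$d, 1, tolerance = 1e-9)
  expect_equal(sum(vp$raw), 1, tolerance = 1e-9)
  expect_gt(vp$a, vp$c)          # age dominates over pure noise
  expect_gt(vp$a, 0.3)
  expect_lt(abs(vp$raw[["c"]]), 0.15)

  # both groups identical copies of one variable: shared fraction takes all
  env2 <- data.frame(a1 = age, a2 = age + 0)
  vp2 <- zeta_varpart(inc, env2, "a1", "a2")
  expect_gt(vp2$b, 0.9 * (1 - vp2$d))

  # no structure at all: unexplained dominates
  m0 <- matrix(rbinom(60 * n, 1, 0.5), 60, n,
               dimnames = dimnames(m))
  vp0 <- zeta_varpart(incidence_matrix(m0), env, "age", c("noise1", "noise2"))
  expect_gt(vp0$d, 0.7)

  expect_error(zeta_varpart(inc, env, "age", "age"), "disjoint")
  expect_error(zeta_varpart(inc, env, character(), "age"), "non-empty")
})
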