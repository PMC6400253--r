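test_that("stationary dose follows the thin-crystal absorption closed form", {
  # 10 x 15 um beam carrying the full 1e10 ph/um^2/s flux density
  b <- beam_params(size = c(10, 15), flux = 1e10 * 10 * 15,
                   energy_kev = 12.4, transmission = 1)
  m <- dose_model_params(mu_en_rho = 0.24)

  expect_equal(stationary_dose(b, 0), 0)

  # independent re-derivation: fluence (ph/m^2) x photon energy (J) x
  # mu_en/rho (m^2/kg), in MGy
  t <- 0.1
  fluence <- 1e10 * 1e12 * t        # ph/um^2 -> ph/m^2
  e_j <- 12.4 * 1.602176634e-16
  want <- fluence * e_j * 0.24 / 1e6
  expect_equal(stationary_dose(b, t), want, tolerance = 1e-12)

  # linear in time, flux and transmission
  expect_equal(stationary_dose(b, 2 * t), 2 * stationary_dose(b, t))
  b2 <- b; b2$flux <- 3 * b$flux
  expect_equal(stationary_dose(b2, t), 3 * stationary_dose(b, t))
  b3 <- b; b3$transmission <- 0.5
  expect_equal(stationary_dose(b3, t), 0.5 * stationary_dose(b, t))

  expect_error(beam_params(transmission = 0), "transmission")
  expect_error(stationary_dose(b, -1), ">= 0")
})

test_that("helical profiles accumulate overlapping frames correctly", {
  b <- beam_params(size = c(10, 15), flux = 1.5e12)
  d1 <- stationary_dose(b, 0.02)

  # translation per frame >= beam width: disjoint blocks, peak = one frame
  v <- helical_vector(c(0, 0, 0), c(0, 0, 100))
  p_nd <- helical_dose_profile(v, b, 0.02, n_frames = 10) # step 10 = width
  expect_equal(p_nd$peak, d1, tolerance = 1e-9)

  # translation = width / 4: interior plateau of 4 frame doses
  p4 <- helical_dose_profile(v, b, 0.02, n_frames = 40)   # step 2.5
  expect_equal(p4$peak / p4$per_frame_dose, 4)
  mid <- p4$dose[abs(p4$s - 50) < 5]
  expect_true(all(abs(mid / p4$per_frame_dose - 4) <= 1))

  # n_frames = 1 reduces to the stationary footprint
  p1 <- helical_dose_profile(v, b, 0.02, n_frames = 1)
  expect_equal(p1$peak, d1, tolerance = 1e-9)
  expect_equal(max(p1$dose), min(p1$dose[p1$dose > 0]))

  expect_error(helical_dose_profile(helical_vector(c(0, 0, 0), c(0, 1, 0)),
                                    b, 0.02, 0), "n_frames")
  expect_error(helical_vector(c(1, 2, 3), c(1, 2, 3)), "differ")
})

test_that("helical peak dose matches the voxel accumulation oracle", {
  set.seed(77)
  for (k in 1:50) {
    len <- runif(1, 30, 250)
    bw <- runif(1, 2, 20)
    n <- sample(5:80, 1)
    t_f <- runif(1, 0.005, 0.1)
    b <- beam_params(size = c(bw, 15), flux = 1.5e12)
    v <- helical_vector(c(0, 0, 0), c(0, 0, len))
    p <- helical_dose_profile(v, b, t_f, n)
    o <- oracle_helical_profile(len, bw, stationary_dose(b, t_f), n)
    expect_lt(abs(p$peak - o$peak) / o$peak, 0.01)
  }
})

test_that("damage spreading conserves integrated dose", {
  b <- beam_params(size = c(10, 15), flux = 1.5e12)
  v <- helical_vector(c(0, 0, 0), c(0, 0, 80))
  p <- helical_dose_profile(v, b, 0.02, 20)

  # sigma = 0 is the identity
  expect_identical(spread_damage(p, dose_model_params(propagation_length = 0)),
                   p)

  # delta-like profile becomes a Gaussian with the same integral
  delta <- structure(
    list(s = seq(-30, 30, by = 0.1), dose = numeric(601),
         peak = 0, per_frame_dose = 0, beam_width_travel = 0, n_frames = 1),
    class = "dose_profile")
  delta$dose[301] <- 100
  delta$peak <- 100
  sm <- spread_damage(delta, dose_model_params(propagation_length = 5))
  expect_equal(sum(sm$dose), sum(delta$dose), tolerance = 1e-3)
  expect_equal(sm$peak, 100 * 0.1 * dnorm(0, sd = 5), tolerance = 1e-3)
  # symmetric around the impulse
  ctr <- which.max(sm$dose)
  expect_equal(sm$s[ctr], 0, tolerance = 0.1001)

  # two-block profile: matches a direct numerical convolution oracle
  two <- delta
  two$dose <- as.numeric(abs(two$s + 12) <= 4) * 7 +
    as.numeric(abs(two$s - 10) <= 6) * 3
  sm2 <- spread_damage(two, dose_model_params(propagation_length = 4))
  oracle <- vapply(sm2$s, function(x) {
    sum(two$dose * dnorm(x - two$s, sd = 4) * 0.1)
  }, numeric(1))
  expect_lt(max(abs(sm2$dose - oracle)) / max(oracle), 0.005)
  expect_equal(sum(sm2$dose), sum(two$dose), tolerance = 1e-3)
})

test_that("suggested exposure hits the dose budget exactly and errs on bad budgets", {
  b <- beam_params(size = c(10, 15), flux = 1.5e12, transmission = 0.5)
  v <- helical_vector(c(0, 0, 0), c(0, 0, 120))

  for (budget in c(8, 10, 12)) {
    st <- suggest_exposure("stationary", b, budget = budget, n_frames = 50)
    expect_lte(st$est_peak_dose, budget * (1 + 1e-6))
    expect_gte(st$est_peak_dose, 0.999 * budget)
    # re-estimate from scratch with the returned settings
    b_rt <- b; b_rt$transmission <- st$transmission
    expect_equal(stationary_dose(b_rt, st$frame_time * st$n_frames),
                 st$est_peak_dose, tolerance = 1e-9)

    he <- suggest_exposure("helical", b, budget = budget, n_frames = 48,
                           vector = v)
    expect_lte(he$est_peak_dose, budget * (1 + 1e-6))
    expect_gte(he$est_peak_dose, 0.999 * budget)
    b_rt <- b; b_rt$transmission <- he$transmission
    expect_equal(helical_dose_profile(v, b_rt, he$frame_time, 48)$peak,
                 he$est_peak_dose, tolerance = 1e-9)

    ss <- suggest_exposure("ssrox", b, budget = budget, n_frames = 60,
                           line_length = 600)
    expect_lte(ss$est_peak_dose, budget * (1 + 1e-6))
    expect_gte(ss$est_peak_dose, 0.999 * budget)
  }

  # doubling the flux halves the suggested time
  b2 <- b; b2$flux <- 2 * b$flux
  t1 <- suggest_exposure("helical", b, budget = 8, n_frames = 48,
                         vector = v)$frame_time
  t2 <- suggest_exposure("helical", b2, budget = 8, n_frames = 48,
                         vector = v)$frame_time
  expect_equal(t2, t1 / 2, tolerance = 1e-12)

  # monotone in budget
  t12 <- suggest_exposure("helical", b, budget = 12, n_frames = 48,
                          vector = v)$frame_time
  expect_gt(t12, t1)

  # transmission optimization round-trips too
  tr <- suggest_exposure("stationary", b, budget = 10, n_frames = 50,
                         optimize = "transmission", frame_time = 0.05)
  expect_lte(tr$est_peak_dose, 10 * (1 + 1e-6))

  # invalid or unreachable budgets
  expect_error(suggest_exposure("stationary", b, budget = 0), "positive")
  hot <- beam_params(size = c(1, 1), flux = 1e14)
  expect_error(
    suggest_exposure("stationary", hot, budget = 1e-6, n_frames = 100,
                     min_frame_time = 1e-3),
    "minimum frame time")
})

test_that("dose is homogeneous of degree one across schemes", {
  set.seed(99)
  for (k in 1:10) {
    b <- beam_params(size = runif(2, 3, 20), flux = runif(1, 1e11, 1e13),
                     transmission = runif(1, 0.05, 1))
    v <- helical_vector(c(0, 0, 0), c(0, runif(1, 0, 30), runif(1, 40, 200)))
    tt <- runif(1, 0.005, 0.1)
    n <- sample(4:40, 1)
    lam <- runif(1, 1.2, 4)
    scale_beam <- function(bb, f) { bb$flux <- f * bb$flux; bb }
    expect_equal(helical_dose_profile(v, scale_beam(b, lam), tt, n)$peak,
                 lam * helical_dose_profile(v, b, tt, n)$peak,
                 tolerance = 1e-9)
    expect_equal(stationary_dose(scale_beam(b, lam), tt),
                 lam * stationary_dose(b, tt), tolerance = 1e-9)
  }
})
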