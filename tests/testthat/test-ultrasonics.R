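test_that("echo velocities follow c = 2L/t with unit conversion", {
  expect_equal(velocity_from_echoes(1, 2), 1000)
  expect_equal(velocity_from_echoes(11.59, 6.26), 3702.875, tolerance = 1e-6)
  expect_equal(velocity_from_echoes(3, 1), 2 * velocity_from_echoes(3, 2))
  expect_error(velocity_from_echoes(-1, 2), "positive")
})

test_that("pulse-echo Young's modulus hits the cl = 2 ct closed form", {
  # tl = ts/2 gives cl = 2 ct; with rho = 1000, ct = 1000 m/s: E = 8/3 GPa
  m <- echo_measurement(ts = 2, tl = 1, L = 1)
  expect_equal(youngs_modulus_pulse_echo(m, rho = 1000), 8 / 3)
  expect_equal(youngs_modulus_from_velocities(2000, 1000, 1000), 8 / 3)
})

test_that("the echo-time and velocity forms of E are identical", {
  set.seed(41)
  for (i in 1:100) {
    L <- runif(1, 5, 20)
    tl <- runif(1, 1, 4)
    ts <- tl * runif(1, 1.5, 4)          # keeps 3 ts^2 > 4 tl^2
    rho <- runif(1, 1000, 5000)
    e_time <- youngs_modulus_pulse_echo(list(ts = ts, tl = tl, L = L), rho)
    e_vel <- youngs_modulus_from_velocities(velocity_from_echoes(L, tl),
                                            velocity_from_echoes(L, ts), rho)
    expect_equal(e_time, e_vel, tolerance = 1e-12)
    expect_equal(youngs_modulus_pulse_echo(list(ts = ts, tl = tl, L = L),
                                           2 * rho), 2 * e_time)
  }
})

test_that("pulse-echo E equals the isotropic 2G(1+nu) relation", {
  set.seed(42)
  for (i in 1:50) {
    ct <- runif(1, 1000, 4000)
    cl <- ct * runif(1, 1.6, 3)
    rho <- runif(1, 1000, 5000)
    G <- rho * ct^2 / 1e9
    nu <- (cl^2 - 2 * ct^2) / (2 * (cl^2 - ct^2))
    expect_equal(youngs_modulus_from_velocities(cl, ct, rho),
                 2 * G * (1 + nu), tolerance = 1e-12)
  }
})

test_that("unphysical echo measurements are rejected", {
  expect_error(echo_measurement(2, 3, 10), "ts > tl")
  expect_error(echo_measurement(2, 1, -1), "positive")
  # ts > tl but 3 ts^2 < 4 tl^2
  expect_error(youngs_modulus_pulse_echo(list(ts = 1, tl = 0.9, L = 10),
                                         1000), "unphysical")
})

test_that("stiffness constants follow rho V^2 and the Christoffel
           quasi-wave relations", {
  # transverse mode: C44 = rho V23^2
  C <- hex_stiffness(135.78, 49.21, 56.62, 179.22, 41.73)
  v <- christoffel_velocities(C, rho = 3140)
  expect_equal(3140 * v$V23^2 / 1e9, 41.73, tolerance = 1e-12)
  # isotropic medium: C12 = C13 = C11 - 2 C44 from the 45-degree waves
  mu <- 40; lam <- 55
  iso <- hex_stiffness(lam + 2 * mu, lam, lam, lam + 2 * mu, mu)
  vi <- christoffel_velocities(iso, rho = 3000)
  rec <- stiffness_from_velocities(vi)
  expect_equal(rec$C12, rec$C11 - 2 * rec$C44, tolerance = 1e-9)
  expect_equal(rec$C13, rec$C11 - 2 * rec$C44, tolerance = 1e-9)
  expect_equal(unlist(rec), unlist(iso), tolerance = 1e-9)
})

test_that("velocity synthesis and stiffness recovery round-trip", {
  set.seed(43)
  for (i in 1:30) {
    # the quasi-wave speed only determines (C13 + C55)^2, so inversion is
    # unique on the physical branch C13 + C44 > 0
    repeat {
      C <- random_stable_stiffness()
      if (C$C13 + C$C44 > 0) break
    }
    rho <- runif(1, 1500, 6000)
    rec <- stiffness_from_velocities(christoffel_velocities(C, rho))
    expect_equal(unlist(rec), unlist(C), tolerance = 1e-9)
  }
})

test_that("replicate summaries have the expected dispersion", {
  same <- data.frame(replicate = 1:3, ts_us = 6.26, tl_us = 2.52,
                     L_mm = 11.59)
  expect_equal(replicate_summary(same, 2940)$sd, 0)
  # bench replicates: relative SD is density-independent and ~0.1-0.2%
  s1 <- replicate_summary(echo_table, rho = 2940)
  s2 <- replicate_summary(echo_table, rho = 1000)
  expect_equal(s1$sd / s1$mean, s2$sd / s2$mean, tolerance = 1e-12)
  expect_gt(s1$sd / s1$mean, 0.001)
  expect_lt(s1$sd / s1$mean, 0.002)
  # mean invariant under reordering
  perm <- echo_table[c(3, 1, 5, 2, 4), ]
  expect_equal(replicate_summary(perm, 2940)$mean, s1$mean)
  expect_error(replicate_summary(echo_table[1, , drop = FALSE], 2940),
               "at least two")
})
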