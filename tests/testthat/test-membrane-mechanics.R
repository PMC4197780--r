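# Static membrane mechanics: Laplace coupling, dilation law and its
# inverse, pore energetics, open-pore tension relaxation.

test_that("Laplace tension and pressure are exact inverses", {
  expect_equal(laplace_tension(0.5e6, 10e-6), 2.5)
  expect_equal(laplace_tension(0, 20e-6), 0)
  expect_equal(laplace_tension(1e5, 20e-6), 1.0)
  for (dP in c(1, 1e3, 0.5e6)) {
    for (R in c(1e-6, 10e-6, 40e-6)) {
      expect_equal(laplace_pressure(laplace_tension(dP, R), R), dP)
    }
  }
  expect_error(laplace_tension(1e3, 0), "positive")
  expect_error(laplace_tension(-1, 1e-5), "non-negative")
})

test_that("area dilation vanishes at zero tension and matches direct evaluation", {
  p <- membrane_params(E_area = 0.2, T = 298)
  A0 <- 4 * pi * (10e-6)^2
  expect_equal(area_dilation(0, A0, p), 0)
  # frozen value from independent hand evaluation of
  # (kT/8*pi*kappa) ln(1 + c sigma A0 / kappa) + sigma/E
  expect_equal(area_dilation(1e-3, A0, p), 0.02468339, tolerance = 1e-6)
  expect_error(area_dilation(-1e-3, A0, p), "non-negative")
})

test_that("dilation is monotone in tension and logarithmic beyond the crossover", {
  p <- membrane_params(T = 298)
  A0 <- 4 * pi * (10e-6)^2
  sig <- 10^seq(-7, -1, length.out = 200)
  al <- area_dilation(sig, A0, p)
  expect_true(all(diff(al) > 0))
  # undulation part grows less than 2x when tension grows 10x (high-tension regime)
  for (s in c(1e-3, 5e-3, 2e-2)) {
    und1 <- area_dilation(s, A0, p) - s / p$E_area
    und10 <- area_dilation(10 * s, A0, p) - 10 * s / p$E_area
    expect_lt(und10, 2 * und1)
  }
})

test_that("tension_from_dilation round-trips area_dilation to 1e-10", {
  p <- membrane_params(T = 298)
  A0 <- 4 * pi * (10e-6)^2
  expect_equal(tension_from_dilation(0, A0, p), 0)
  sig <- 10^seq(-7, -1, length.out = 41)
  back <- tension_from_dilation(area_dilation(sig, A0, p), A0, p)
  expect_true(all(abs(back - sig) <= 1e-10 * sig))
  # inverse of the frozen forward example
  expect_equal(tension_from_dilation(0.02468339, A0, p), 1e-3,
               tolerance = 1e-4)
})

test_that("pore energy has its single maximum at gamma/sigma", {
  expect_equal(pore_energy(0, 5e-3, 1e-11), 0)
  expect_equal(pore_energy(2e-9, 5e-3, 1e-11), pi * 2e-20, tolerance = 1e-12)
  gam <- 1e-11; sig <- 5e-3
  opt <- optimize(function(r) pore_energy(r, sig, gam),
                  c(0, 1e-7), maximum = TRUE)
  expect_equal(opt$maximum, gam / sig, tolerance = 1e-4)
  # beyond 2 gamma/sigma the pore is energetically downhill
  r_big <- seq(2 * gam / sig * 1.0001, 10 * gam / sig, length.out = 20)
  expect_true(all(pore_energy(r_big, sig, gam) < 0))
})

test_that("nucleation barrier scales as 1/sigma and matches hand values", {
  b <- pore_nucleation_barrier(5e-3, 1e-11, T = 298)
  expect_equal(b$r_star, 2e-9)
  expect_equal(b$barrier, pi * 1e-22 / 5e-3, tolerance = 1e-12)
  expect_equal(b$barrier_kT, 15.27145, tolerance = 1e-5)
  b2 <- pore_nucleation_barrier(1e-2, 1e-11, T = 298)
  expect_equal(b2$barrier, b$barrier / 2)
  # barrier exceeds 40 kT only below ~1.9e-3 N/m at gamma = 1e-11 N
  sig_40 <- pi * 1e-22 / (40 * physical_constants()$k_B * 298)
  expect_equal(sig_40, 1.908931e-3, tolerance = 1e-5)
  expect_gt(pore_nucleation_barrier(sig_40 * 0.99, 1e-11, T = 298)$barrier_kT, 40)
  expect_lt(pore_nucleation_barrier(sig_40 * 1.01, 1e-11, T = 298)$barrier_kT, 40)
  expect_error(pore_nucleation_barrier(0, 1e-11), "no finite barrier")
})

test_that("critical pore radius follows 2 R0 sqrt(sigma0/E)", {
  expect_equal(critical_pore_radius(10e-6, 0, 0.2), 0)
  expect_equal(critical_pore_radius(10e-6, 0.2, 0.2), 2 * 10e-6)
  expect_equal(critical_pore_radius(10e-6, 5e-3, 0.2), 3.162278e-6,
               tolerance = 1e-6)
})

test_that("open-pore tension ratio endpoints, monotonicity and clamping", {
  r_c <- 3.162278e-6; R_i <- 1e-5
  expect_equal(as.numeric(open_pore_tension_ratio(0, r_c, R_i, R_i)), 1)
  expect_equal(as.numeric(open_pore_tension_ratio(r_c, r_c, R_i, R_i)), 0)
  expect_equal(as.numeric(open_pore_tension_ratio(r_c / 2, r_c, R_i, R_i)), 0.75)
  # growing pore and content efflux each strictly reduce the ratio
  r_seq <- seq(0, r_c, length.out = 10)
  v1 <- as.numeric(open_pore_tension_ratio(r_seq, r_c, R_i, R_i))
  expect_true(all(diff(v1) < 0))
  R_seq <- seq(R_i, R_i * 0.9999, length.out = 10)
  v2 <- as.numeric(open_pore_tension_ratio(1e-6, r_c, R_i, R_seq))
  expect_true(all(diff(v2) < 0))
  # clamp at zero with the fully-relaxed flag
  v3 <- open_pore_tension_ratio(2 * r_c, r_c, R_i, R_i)
  expect_equal(as.numeric(v3), 0)
  expect_true(attr(v3, "fully_relaxed"))
  expect_error(open_pore_tension_ratio(1e-6, 0, R_i, R_i), "positive")
  expect_error(open_pore_tension_ratio(1e-6, r_c, R_i, R_i * 1.01), "exceeds")
})

test_that("membrane_params validates invariants", {
  expect_error(membrane_params(kappa = -1), "positive")
  expect_error(membrane_params(sigma_lys = 1e-3, sigma_close = 2e-3), "below")
  expect_equal(membrane_params(preset = "high_lysis")$sigma_lys, 0.035)
})
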