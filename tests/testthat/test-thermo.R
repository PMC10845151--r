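# pinned constants, duplicated here so oracle formulas are independent code
.h <- 6.62607015e-34; .kB <- 1.380649e-23; .c <- 2.99792458e10
.amu <- 1.66053906660e-27; .Rk <- 8.31446261815324 / 4184  # kcal/(mol K)

test_that("frequency scaling is element-wise and validated", {
  f <- c(-500, 1000, 2000)
  expect_equal(scaleFrequencies(f, 1.0), f)
  expect_equal(scaleFrequencies(1000, 0.9914), 991.4)
  expect_error(scaleFrequencies(f, 0), "factor")
  expect_error(scaleFrequencies(f, 1.5), "factor")
})

test_that("ZPE uses the pinned conversion and is additive", {
  expect_equal(zpe(numeric(0)), 0)
  expect_equal(zpe(1000), 1.42957)
  a <- c(800, 1600); b <- c(3000, 120, 450)
  expect_equal(zpe(c(a, b)), zpe(a) + zpe(b))
  expect_error(zpe(c(1000, -300)), "positive")
})

test_that("G tends to E + ZPE at 1 K for a formaldehyde-like species", {
  inp <- thermoInput(h2coGeometry(), c(1200, 1800, 3000),
                     electronic_energy = -10)
  g1 <- gibbs(inp, 1)
  expect_lt(abs(g1$g - (-10 + g1$zpe)), 1e-3)
})

test_that("monatomic entropy equals the Sackur-Tetrode closed form", {
  for (elem in c("H", "O")) {
    for (T_K in c(298.15, 1000)) {
      mult <- if (elem == "H") 2L else 3L
      inp <- thermoInput(Geometry(elem, matrix(0, 1, 3)), numeric(0), 0,
                         multiplicity = mult)
      g <- gibbs(inp, T_K)
      m <- supportedElements()[elem, "mass"] * .amu
      s_st <- .Rk * (1.5 * log(2 * pi * m * .kB * T_K / .h^2) +
                       log(.kB * T_K / 101325) + 2.5) + .Rk * log(mult)
      expect_equal(g$s_total, s_st * 1000, tolerance = 1e-10)
      expect_equal(g$h_corr, 2.5 * .Rk * T_K, tolerance = 1e-12)
    }
  }
})

test_that("one harmonic mode matches the exact oscillator formulas at 300 K", {
  nu <- 500
  inp <- thermoInput(Geometry(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.13))),
                     nu, 0)
  g <- gibbs(inp, 300)
  x <- .h * .c * nu / (.kB * 300)
  s_vib <- .Rk * (x / (exp(x) - 1) - log(1 - exp(-x)))
  # subtract the independent translational + rotational entropies
  m <- sum(supportedElements()[c("C", "O"), "mass"]) * .amu
  s_tr <- .Rk * (1.5 * log(2 * pi * m * .kB * 300 / .h^2) +
                   log(.kB * 300 / 101325) + 2.5)
  mu <- prod(supportedElements()[c("C", "O"), "mass"]) /
    sum(supportedElements()[c("C", "O"), "mass"]) * .amu
  I <- mu * (1.13e-10)^2
  s_rot <- .Rk * (log(8 * pi^2 * I * .kB * 300 / .h^2) + 1)
  expect_equal(g$s_total / 1000 - s_tr - s_rot, s_vib, tolerance = 1e-10)
})

test_that("gibbs matches an independent partition-function formulation", {
  # oracle: G = E + ZPE - RT ln(q_trans q_rot q_vib q_el), with q_vib
  # ZPE-referenced and q_trans at the molar volume per molecule (the
  # Sackur-Tetrode convention) -- an independent route to the same quantity
  oracle <- function(inp, T_K, P_atm = 1) {
    geom <- inp$geometry
    mass <- sum(supportedElements()[atomSymbols(geom), "mass"]) * .amu
    qt <- (2 * pi * mass * .kB * T_K / .h^2)^1.5 * (.kB * T_K / (P_atm * 101325))
    n <- nAtoms(geom)
    qr <- 1
    if (n > 1) {
      msym <- supportedElements()[atomSymbols(geom), "mass"] * .amu
      x <- atomCoords(geom) * 1e-10
      com <- colSums(x * msym) / sum(msym)
      x <- sweep(x, 2, com)
      Imat <- matrix(0, 3, 3)
      for (a in seq_len(n)) {
        r2 <- sum(x[a, ]^2)
        Imat <- Imat + msym[a] * (diag(r2, 3) - outer(x[a, ], x[a, ]))
      }
      Iev <- sort(eigen(Imat, symmetric = TRUE)$values)
      if (Iev[1] / Iev[3] < 1e-8) {
        qr <- 8 * pi^2 * Iev[3] * .kB * T_K / (inp$symmetry_number * .h^2)
      } else {
        qr <- sqrt(pi * prod(Iev)) / inp$symmetry_number *
          (8 * pi^2 * .kB * T_K / .h^2)^1.5
      }
    }
    nu <- inp$frequencies[inp$frequencies > 0]
    qv <- prod(1 / (1 - exp(-.h * .c * nu / (.kB * T_K))))
    qe <- inp$multiplicity
    inp$electronic_energy + zpe(nu) -
      .Rk * T_K * log(qt * qr * qv * qe)
  }
  set.seed(12)
  for (rep in 1:5) {
    sp <- genSpecies(generatorConfig(seed = 500L + rep), seed = 500L + rep)
    inp <- thermoInput(sp$geometry, abs(sp$species@frequencies),
                       sp$species@energy)
    for (T_K in c(300, 1000)) {
      expect_equal(gibbs(inp, T_K)$g, oracle(inp, T_K), tolerance = 1e-6)
    }
  }
})

test_that("delta G of activation batches temperatures and cancels cleanly", {
  r_inp <- thermoInput(h2coGeometry(), c(1200, 1800, 3000), 0)
  expect_equal(unname(deltaGActivation(r_inp, r_inp)), c(0, 0, 0))

  # same geometry and frequencies, energies differ by 10: all thermal terms
  # cancel exactly
  ts_inp <- thermoInput(h2coGeometry(), c(1200, 1800, 3000), 10)
  dg <- deltaGActivation(r_inp, ts_inp, T_K = c(300, 500, 1000))
  expect_equal(unname(dg), c(10, 10, 10))
  expect_named(dg, c("T300", "T500", "T1000"))

  # TS imaginary modes are ignored in thermal sums
  ts_im <- thermoInput(h2coGeometry(), c(-900, 1200, 1800, 3000), 10)
  expect_equal(unname(deltaGActivation(r_inp, ts_im)), unname(dg))
})

test_that("thermodynamic limits behave physically", {
  inp <- thermoInput(h2coGeometry(), c(800, 1500, 2900), 0)
  temps <- c(50, 150, 300, 600, 1200)
  gs <- vapply(temps, function(tt) gibbs(inp, tt)$g, numeric(1))
  expect_true(all(diff(gs) < 0))  # G decreasing in T (S > 0)

  # S_vib -> 0 as T -> 0
  s_vib_low <- gibbs(inp, 5)$s_total - gibbs(
    thermoInput(h2coGeometry(), numeric(0), 0), 5)$s_total
  expect_lt(abs(s_vib_low), 1e-6)

  # classical limit: total vibrational internal energy (ZPE + thermal)
  # approaches kT per mode at 5000 K
  soft <- c(400, 900, 1400)
  inp_soft <- thermoInput(h2coGeometry(), soft, 0)
  u_vib <- gibbs(inp_soft, 5000)$h_corr - gibbs(
    thermoInput(h2coGeometry(), numeric(0), 0), 5000)$h_corr + zpe(soft)
  classical <- length(soft) * .Rk * 5000
  expect_lt(abs(u_vib - classical) / classical, 0.02)
})
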