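test_that("combination rules give arithmetic sigma, geometric epsilon, charge product", {
  cross <- combine_params(1, c(0, 148, 3.73), c(0, 98, 3.75))
  expect_equal(cross[[3]], 3.74)
  expect_equal(cross[[2]], sqrt(148 * 98))
  expect_equal(cross[[1]], 0)
  expect_equal(combine_params(1, c(0, 148, 3.7), c(0, 148, 3.7))[[2]], 148)
  expect_equal(combine_params(2, c(0, 100, 3.7, 12), c(0, 100, 3.7, 16))[[4]], 14)
  expect_equal(combine_params(1, c(0.435, 0, 0), c(-0.7, 93, 3.02))[[1]],
               0.435 * -0.7)
  expect_error(combine_params(9, c(0, 1, 1), c(0, 1, 1)),
               class = "ffdat_registry_error")
})

test_that("the Mie prefactor reduces to 4 at n = 12 and matches direct substitution", {
  expect_equal(mie_prefactor(12), 4, tolerance = 1e-14)
  # independent evaluation through logs
  n <- 16
  expect_equal(mie_prefactor(16), exp(log(n / (n - 6)) + 6 / (n - 6) * log(n / 6)),
               tolerance = 1e-14)
  expect_error(mie_prefactor(6), class = "ffdat_domain_error")
  expect_error(mie_prefactor(5.5), class = "ffdat_domain_error")
})

test_that("Lennard-Jones crosses zero at sigma and bottoms out at -epsilon", {
  k <- unit_profile("K-A-e")
  p <- c(0, 148, 3.73)
  expect_equal(eval_intermolecular(1, p, 3.73, k), 0)
  expect_equal(eval_intermolecular(1, p, 2^(1/6) * 3.73, k), -148)
  expect_error(eval_intermolecular(1, p, 0, k), class = "ffdat_domain_error")
  # the charge term scales with the profile's Coulomb constant
  pq <- c(0.25, 0, 1)
  expect_equal(eval_intermolecular(1, pq, 2, k), k$coulomb * 0.25 / 2)
  ev <- unit_profile("eV-A-e")
  expect_equal(eval_intermolecular(1, pq, 2, ev), ev$coulomb * 0.25 / 2)
})

test_that("Mie with n = 12 is the Lennard-Jones potential on an r-grid", {
  r <- seq(3.2, 12, length.out = 97)
  k <- unit_profile("K-A-e")
  lj <- eval_intermolecular(1, c(0, 148, 3.73), r, k)
  mie <- eval_intermolecular(2, c(0, 148, 3.73, 12), r, k)
  expect_equal(mie, lj, tolerance = 1e-12)
})

test_that("bond forms vanish at their reference value and match worked examples", {
  expect_equal(eval_bond(1, c(62500, 1.54), 1.54), 0)
  expect_equal(eval_bond(1, c(2, 1), 2), 1)
  expect_equal(eval_bond(2, c(5, -3, 2, 1.2), 1.2), 0)
  expect_equal(eval_bond(3, c(4, 1), 0), 1)
  expect_equal(eval_bond(3, c(4, 1.1), 1.1), 0)
  expect_error(eval_bond(7, c(1, 1), 1), class = "ffdat_registry_error")
})

test_that("angle forms use degrees and the coupled form requires distances", {
  expect_equal(eval_angle(1, c(62500, 114), 114), 0)
  expect_equal(eval_angle(1, c(62500, 114), 115), 31250)
  expect_equal(eval_angle(3, c(109.47, 50), 109.47), 0)
  expect_error(eval_angle(2, rep(1, 9), 110), class = "ffdat_usage_error")
  p2 <- c(10, 0, 0, 110, 5, 1.5, 1.5, 2, 2)
  expect_equal(eval_angle(2, p2, 110, r_ij = 1.5, r_jk = 1.5), 0)
  expect_equal(eval_angle(2, p2, 111, r_ij = 1.5, r_jk = 1.5), 10)
})

test_that("the cosine-series torsion vanishes at trans and gives 2(c1+c3) at cis", {
  p <- c(0, 355.03, -68.19, 791.32)
  expect_equal(eval_torsion(1, p, 180), 0, tolerance = 1e-12)
  expect_equal(eval_torsion(1, p, 0), 2292.70, tolerance = 1e-10)
  expect_equal(eval_torsion(1, p, 0), 2 * (p[2] + p[4]))
  expect_equal(eval_torsion(2, c(40, 60), 60), 0)
  expect_equal(eval_torsion(4, c(10, 0), 0), 0)
  expect_equal(eval_torsion(3, c(1, 0, 0, 0, 0, 0, 0), 123), 1)
  expect_equal(eval_torsion(5, c(0, 1, rep(0, 6)), 60), cospi(1/3))
  expect_equal(eval_torsion(6, c(2, 3, 0, 0, 1, 0, 0, 1, 0, 0, 1, 0), 60),
               2 * (1 + cospi(1)))
})

test_that("torsion forms are 2-pi periodic", {
  phi <- seq(-360, 360, by = 7.5)
  for (case in list(list(1, c(0, 355.03, -68.19, 791.32)),
                    list(3, c(1, -2, 3, -4, 5, -6, 7)),
                    list(4, c(10, 30)),
                    list(5, 8:1),
                    list(6, c(1, 1, 10, 2, 2, 20, 3, 3, 30, 4, 4, 40)))) {
    expect_equal(eval_torsion(case[[1]], case[[2]], phi),
                 eval_torsion(case[[1]], case[[2]], phi + 360),
                 tolerance = 1e-10)
  }
})

test_that("harmonic forms are nonnegative and zero exactly at the reference", {
  set.seed(7)
  for (rep_ in 1:25) {
    k <- runif(1, 1, 1e5); x0 <- runif(1, 0.5, 179)
    x <- x0 + runif(9, -20, 20)
    expect_true(all(eval_bond(1, c(k, x0), abs(x)) >= 0))
    expect_equal(eval_bond(1, c(k, x0), x0), 0)
    expect_true(all(eval_angle(1, c(k, x0), x) >= 0))
    expect_equal(eval_angle(1, c(k, x0), x0), 0)
    expect_true(all(eval_improper(1, c(k, x0), x) >= 0))
    expect_equal(eval_improper(1, c(k, x0), x0), 0)
    expect_true(all(eval_torsion(2, c(k, x0), x) >= 0))
    expect_equal(eval_torsion(2, c(k, x0), x0), 0)
  }
})

test_that("the special repulsion follows k12/r^12 and decays monotonically", {
  expect_equal(eval_special(1, 75000000, 10), 75000000 / 10^12)
  expect_equal(eval_special(1, 0, 3), 0)
  r <- seq(2, 20, by = 0.5)
  e <- eval_special(1, 75000000, r)
  expect_true(all(diff(e) < 0))
  expect_lt(e[length(e)], 1e-8 * e[1])
  expect_error(eval_special(1, 1, -1), class = "ffdat_domain_error")
  expect_error(eval_special(2, 1, 1), class = "ffdat_registry_error")
})

test_that("1,n scaling defaults to 0 through n = 4 and 1 beyond", {
  expect_equal(scale_1n(NULL, 4), c(vdw = 0, elec = 0))
  expect_equal(scale_1n(NULL, 5), c(vdw = 1, elec = 1))
  expect_equal(scale_1n(NULL, 2), c(vdw = 0, elec = 0))
  rules <- tibble::tibble(n = 4L, scaling1 = 0.5, scaling2 = 0.833,
                          ref = "10.0/x")
  expect_equal(scale_1n(rules, 4), c(vdw = 0.5, elec = 0.833))
  expect_equal(scale_1n(rules, 5), c(vdw = 1, elec = 1))
})

test_that("evaluators agree with central-difference derivatives at generic points", {
  k <- unit_profile("K-A-e")
  cases <- list(
    list(f = function(x) eval_intermolecular(1, c(0.1, 148, 3.73), x, k),
         x = 4.1),
    list(f = function(x) eval_bond(2, c(100, -20, 5, 1.5), x), x = 1.8),
    list(f = function(x) eval_angle(1, c(62500, 114), x), x = 104),
    list(f = function(x) eval_torsion(1, c(0, 355.03, -68.19, 791.32), x), x = 47),
    list(f = function(x) eval_torsion(6, c(1, 1, 10, 2, 2, 20, 3, 3, 30, 4, 4, 40), x),
         x = 33),
    list(f = function(x) eval_improper(1, c(40, 2), x), x = 9),
    list(f = function(x) eval_special(1, 75e6, x), x = 2.6)
  )
  for (case in cases) {
    f <- case$f; x <- case$x
    h <- 1e-4 * max(1, abs(x))
    analytic_free <- (f(x + h) - f(x - h)) / (2 * h)     # coarse stencil
    refined <- (f(x + h / 16) - f(x - h / 16)) / (2 * h / 16)
    richardson <- (16^2 * refined - analytic_free) / (16^2 - 1)
    expect_equal(refined, richardson,
                 tolerance = 1e-6 * max(1, abs(richardson)))
  }
})
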