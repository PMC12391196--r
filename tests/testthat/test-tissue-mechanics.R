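test_that("zero-load length scales the initial length by the reference ratio", {
  expect_equal(zero_load_length(100, 1.0), 100)
  expect_equal(zero_load_length(100, 1.25), 125)
  expect_equal(zero_load_length(80, 0.95), 76)
  expect_error(zero_load_length(-1, 1), "positive")
  expect_error(zero_load_length(100, 0), "positive")
})

test_that("fiber force is tension-only with the documented toe and linear branches", {
  expect_equal(fiber_force(99, L0 = 100, k = 100), 0)
  expect_equal(fiber_force(100, L0 = 100, k = 100), 0)
  # at the toe/linear junction (eps = 2*eps_l) both branches give k*eps_l*L0
  expect_equal(fiber_force(106, L0 = 100, k = 100, eps_l = 0.03), 300)
  # linear branch: k * (d - eps_l * L0)
  expect_equal(fiber_force(110, L0 = 100, k = 100, eps_l = 0.03), 700)
})

test_that("fiber force is C1-continuous at the toe/linear junction", {
  L0 <- 87.3; k <- 123.4; eps <- 0.03
  dj <- 2 * eps * L0
  h <- 1e-7
  f_left <- fiber_force(L0 + dj - h, L0, k, eps)
  f_right <- fiber_force(L0 + dj + h, L0, k, eps)
  expect_lt(abs(f_right - f_left), 1e-4)
  s_left <- (fiber_force(L0 + dj - h, L0, k, eps) -
               fiber_force(L0 + dj - 2 * h, L0, k, eps)) / h
  s_right <- (fiber_force(L0 + dj + 2 * h, L0, k, eps) -
                fiber_force(L0 + dj + h, L0, k, eps)) / h
  expect_equal(s_left, k, tolerance = 1e-4)
  expect_equal(s_right, k, tolerance = 1e-4)
})

test_that("fiber force is non-negative, monotone and scales linearly with stiffness", {
  L0 <- 50
  len <- seq(40, 80, by = 0.05)
  f1 <- fiber_force(len, L0, k = 80)
  f2 <- fiber_force(len, L0, k = 160)
  expect_true(all(f1 >= 0))
  expect_true(all(diff(f1) >= 0))
  expect_true(all(f1[len <= L0] == 0))
  expect_equal(f2, 2 * f1)
})

test_that("fiber energy integrates the force law", {
  L0 <- 100; k <- 100; eps <- 0.03
  expect_equal(fiber_energy(95, L0, k, eps), 0)
  # symbolic toe integral at the junction: k d^3 / (12 eps L0)
  dj <- 2 * eps * L0
  expect_equal(fiber_energy(L0 + dj, L0, k, eps), k * dj^3 / (12 * eps * L0),
               tolerance = 1e-12)
  # derivative matches the force over a dense grid spanning both branches
  h <- 1e-4
  len <- seq(100.2, 120, length.out = 200)
  dU <- (fiber_energy(len + h, L0, k, eps) -
           fiber_energy(len - h, L0, k, eps)) / (2 * h)
  f <- fiber_force(len, L0, k, eps)
  expect_lt(max(abs(dU - f) / pmax(f, 1)), 1e-6)
})

test_that("tri-linear contact force follows the cumulative segment sums", {
  el <- contact_element("medial", c(0, 0, 0), 20, c(0, 0, -20),
                        slopes = c(100, 500, 2000), breakpoints = c(0.1, 0.3))
  expect_equal(contact_force(-0.5, el), 0)
  expect_equal(contact_force(0.1, el), 10)
  expect_equal(contact_force(0.3, el), 100 * 0.1 + 500 * 0.2)
  expect_equal(contact_force(0.5, el), 110 + 2000 * 0.2)
  d <- seq(-0.2, 1, by = 0.001)
  expect_true(all(diff(contact_force(d, el)) >= 0))
})

test_that("contact energy integrates the contact force", {
  el <- contact_element("lateral", c(0, 0, 0), 20, c(0, 0, -20),
                        slopes = c(100, 500, 2000), breakpoints = c(0.1, 0.3))
  expect_equal(contact_energy(-1, el), 0)
  # first segment is the quadratic closed form
  expect_equal(contact_energy(0.05, el), 0.5 * 100 * 0.05^2)
  h <- 1e-6
  d <- seq(0.005, 1, length.out = 150)
  dU <- (contact_energy(d + h, el) - contact_energy(d - h, el)) / (2 * h)
  f <- contact_force(d, el)
  expect_lt(max(abs(dU - f) / pmax(f, 1)), 1e-6)
})

test_that("contact element validation enforces the tri-linear invariants", {
  expect_error(contact_element("medial", c(0, 0, 0), 20, c(0, 0, -20),
                               slopes = c(500, 100, 2000)),
               "non-decreasing")
  expect_error(contact_element("medial", c(0, 0, 0), 20, c(0, 0, -20),
                               breakpoints = c(0.3, 0.1)),
               "increasing")
  expect_error(contact_element("medial", c(0, 0, 0), 20, c(0, 0, -20),
                               dish_radius = 10), "exceed")
})

test_that("ligament bundles validate geometry and share material parameters", {
  b <- ligament_bundle("LCL", origins = rbind(c(0, 0, 0), c(1, 0, 0)),
                       insertions = rbind(c(0, 0, -40), c(1, 0, -40)),
                       r = 0.9, k = 120)
  expect_equal(b$initial_length, c(40, 40))
  expect_error(ligament_bundle("LCL", c(0, 0, 0), c(0, 0, 0)), "differ")
  expect_error(ligament_bundle("XXX", c(0, 0, 0), c(0, 0, -1)))
})
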