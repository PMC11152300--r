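test_that("design matrix has the promised rows and shape", {
  expect_equal(
    unname(circ_design(rep(0, 3), 1)[1, ]), c(1, 1, 0)
  )
  expect_equal(
    unname(drop(circ_design(rep(pi / 2, 5), 2)[1, ])),
    c(1, 0, 1, -1, 0),
    tolerance = 1e-12
  )
  for (m in 1:4) {
    expect_equal(ncol(circ_design(seq_len(2 * m + 1), m)), 2 * m + 1)
  }
  expect_error(circ_design(c(0, 1), 1), class = "circmag_underdetermined_design")
})

test_that("identity data is fitted exactly", {
  a <- vm_sample(100, 3, 0.5, seed = 1)
  fit <- circ_reg(a, a, degree = 1)
  expect_equal(unname(fit$coef_cos), c(0, 1, 0), tolerance = 1e-10)
  expect_equal(unname(fit$coef_sin), c(0, 0, 1), tolerance = 1e-10)
  expect_lt(max(abs(fit$sigma)), 1e-20)
  expect_equal(fit$rho_model, 1, tolerance = 1e-10)
  grid <- seq(0.1, 6.2, length.out = 50)
  expect_lt(max(abs(wrap_pi(predict(fit, grid) - grid))), 1e-10)
})

test_that("a constant rotation is absorbed by the angle-addition identity", {
  a <- vm_sample(200, 2, 0.3, seed = 2)
  fit <- circ_reg(a, wrap_2pi(a + pi / 4), degree = 1)
  expect_equal(
    unname(fit$coef_cos), c(0, cos(pi / 4), -sin(pi / 4)),
    tolerance = 1e-9
  )
  expect_equal(
    unname(fit$coef_sin), c(0, sin(pi / 4), cos(pi / 4)),
    tolerance = 1e-9
  )
})

test_that("fits are rotation-equivariant in the response", {
  a <- vm_sample(150, 1, 0.8, seed = 3)
  b <- wrap_2pi(a + withr::with_seed(4, circmag:::rvm_centred(150, 6)))
  shift <- 1.1
  f1 <- circ_reg(a, b, degree = 1)
  f2 <- circ_reg(a, wrap_2pi(b + shift), degree = 1)
  grid <- seq(0, 2 * pi, length.out = 25)
  expect_lt(
    max(abs(wrap_pi(predict(f2, grid) - predict(f1, grid) - shift))), 1e-8
  )
})

test_that("coefficients minimise the least-squares objective locally", {
  a <- vm_sample(80, 1, 1, seed = 5)
  b <- wrap_2pi(a + 0.5 + withr::with_seed(6, circmag:::rvm_centred(80, 3)))
  fit <- circ_reg(a, b, degree = 1)
  x <- circ_design(a, 1)
  rss <- function(c1, c2) {
    sum((cos(b) - x %*% c1)^2) + sum((sin(b) - x %*% c2)^2)
  }
  base <- rss(fit$coef_cos, fit$coef_sin)
  for (j in 1:3) {
    for (d in c(-1e-3, 1e-3)) {
      c1 <- fit$coef_cos
      c1[j] <- c1[j] + d
      expect_gte(rss(c1, fit$coef_sin), base)
      c2 <- fit$coef_sin
      c2[j] <- c2[j] + d
      expect_gte(rss(fit$coef_cos, c2), base)
    }
  }
})

test_that("coefficients are recovered up to von Mises shrinkage", {
  # beta = alpha + pi/6 + VM(kappa = 5) error; the conditional
  # expectation of the unit vector is the A1(5)-shrunk rotation
  shrink <- circmag:::a1_ratio(5)
  true_cos <- c(0, cos(pi / 6), -sin(pi / 6)) * shrink
  true_sin <- c(0, sin(pi / 6), cos(pi / 6)) * shrink
  rmse <- vapply(1:25, function(s) {
    a <- vm_sample(500, 2, 0.4, seed = 300 + s)
    b <- wrap_2pi(a + pi / 6 +
      withr::with_seed(600 + s, circmag:::rvm_centred(500, 5)))
    fit <- circ_reg(a, b, degree = 1)
    sqrt(mean(c(fit$coef_cos - true_cos, fit$coef_sin - true_sin)^2))
  }, numeric(1))
  expect_lt(median(rmse), 0.1)
})

test_that("model association reacts to coupling and to independence", {
  a <- vm_sample(2000, 1, 1, seed = 7)
  b_ind <- vm_sample(2000, 2, 2, seed = 8)
  fit <- circ_reg(a, b_ind, degree = 1)
  expect_lt(abs(fit$rho_model), 0.1)
  rhos <- vapply(c(0, 0.3, 0.7), function(cp) {
    aa <- vm_sample(500, 1, 1, seed = 40)
    bb <- wrap_2pi((1 - cp) * 2 + cp * aa +
      withr::with_seed(41, circmag:::rvm_centred(500, 4)))
    circ_reg(aa, bb, degree = 1)$rho_model
  }, numeric(1))
  expect_true(all(diff(rhos) > 0))
})

test_that("residual dispersion shrinks as the error concentrates", {
  a <- vm_sample(400, 1, 0.6, seed = 9)
  tr <- vapply(c(2, 50), function(kap) {
    b <- wrap_2pi(a + withr::with_seed(10, circmag:::rvm_centred(400, kap)))
    sum(diag(circ_reg(a, b, degree = 1)$sigma))
  }, numeric(1))
  expect_lt(tr[2], tr[1] / 5)
})

test_that("degenerate designs are refused", {
  expect_error(
    circ_reg(rep(1, 20), vm_sample(20, 1, 2, seed = 11)),
    class = "circmag_degenerate_covariate"
  )
  expect_error(
    circ_reg(1:3, 1:3, degree = 1),
    class = "circmag_underdetermined_design"
  )
})

test_that("degree selection finds the generative order", {
  # noiseless doubling map beta = 2 alpha + c: cos(beta), sin(beta)
  # are exact degree-2 trigonometric polynomials, so the m = 2 fit has
  # zero residual and the penalty keeps the degree from growing
  a <- vm_sample(200, 3, 0.4, seed = 12)
  b <- wrap_2pi(2 * a + 0.5)
  expect_equal(as.integer(select_degree(a, b, m_max = 3)), 2L)
  expect_lt(circ_reg(a, b, degree = 2)$rss, 1e-18)
  # degree-1 data with moderate noise selects degree 1 usually
  picks <- vapply(1:20, function(s) {
    aa <- vm_sample(300, 1, 0.5, seed = 700 + s)
    bb <- wrap_2pi(aa + 0.4 +
      withr::with_seed(900 + s, circmag:::rvm_centred(300, 5)))
    as.integer(select_degree(aa, bb, m_max = 3))
  }, integer(1))
  expect_gte(mean(picks == 1), 0.9)
  expect_error(
    select_degree(1:7, 1:7, m_max = 3),
    class = "circmag_underdetermined_design"
  )
})

test_that("tidy and glance summarise the fit", {
  a <- vm_sample(100, 1, 0.5, seed = 13)
  fit <- circ_reg(a, wrap_2pi(a + 1), degree = 2,
    covariate_label = "inclination"
  )
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_named(td, c("term", "cos_coef", "sin_coef"))
  gl <- glance(fit)
  expect_equal(gl$degree, 2)
  expect_true(gl$rho_model >= -1 && gl$rho_model <= 1)
})
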