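test_that("noiseless exponential data returns the generating parameters exactly", {
  a <- 127.29; b <- 0.0248
  x <- c(-69.0, -127.0, -128.9)
  d <- tibble::tibble(name = c("A", "G", "F"), delta_g = x,
                      efficiency = a * exp(b * x))
  m <- fit_efficiency_model(d)
  expect_equal(m$a, a, tolerance = 1e-12)
  expect_equal(m$b, b, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$n_points, 3L)
})

test_that("two points are interpolated exactly", {
  d <- tibble::tibble(delta_g = c(-10, -50), efficiency = c(80, 20))
  m <- fit_efficiency_model(d)
  expect_equal(predict_efficiency(m, -10), 80, tolerance = 1e-12)
  expect_equal(predict_efficiency(m, -50), 20, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
})

test_that("noisy synthetic data recovers the exponent within Monte-Carlo bounds", {
  withr::local_seed(404)
  n <- 50; a <- 100; b <- 0.03
  x <- runif(n, -150, -5)
  y <- a * exp(b * x) * exp(rnorm(n, 0, 0.1)) # multiplicative log-normal noise
  m <- fit_efficiency_model(tibble::tibble(delta_g = x, efficiency = y))
  fit <- lm(log(y) ~ x)
  se_b <- summary(fit)$coefficients["x", "Std. Error"]
  expect_lt(abs(m$b - b), 3 * se_b)
})

test_that("degenerate and out-of-domain inputs raise named errors", {
  expect_error(
    fit_efficiency_model(tibble::tibble(delta_g = c(-5, -5), efficiency = c(1, 2))),
    class = "dg_degenerate_fit_error"
  )
  expect_error(
    fit_efficiency_model(tibble::tibble(name = c("ok", "bad"),
                                        delta_g = c(-5, -9),
                                        efficiency = c(10, -1))),
    regexp = "bad", class = "dg_domain_error"
  )
  expect_error(regulatory_potential(0, 5), class = "dg_domain_error")
  expect_error(regulatory_potential(5, -1), class = "dg_domain_error")
})

test_that("scale equivariance: rescaling efficiencies only rescales the prefactor", {
  withr::local_seed(5)
  x <- runif(10, -120, -10)
  y <- 90 * exp(0.02 * x) * exp(rnorm(10, 0, 0.2))
  m1 <- fit_efficiency_model(tibble::tibble(delta_g = x, efficiency = y))
  m2 <- fit_efficiency_model(tibble::tibble(delta_g = x, efficiency = 7 * y))
  expect_equal(m2$a, 7 * m1$a, tolerance = 1e-10)
  expect_equal(m2$b, m1$b, tolerance = 1e-10)
  expect_equal(m2$r_squared, m1$r_squared, tolerance = 1e-10)
})

test_that("shifting delta_g multiplies the prefactor by exp(-b * shift)", {
  withr::local_seed(6)
  x <- runif(10, -120, -10)
  y <- 90 * exp(0.02 * x) * exp(rnorm(10, 0, 0.2))
  m1 <- fit_efficiency_model(tibble::tibble(delta_g = x, efficiency = y))
  m2 <- fit_efficiency_model(tibble::tibble(delta_g = x + 15, efficiency = y))
  expect_equal(m2$b, m1$b, tolerance = 1e-10)
  expect_equal(m2$a, m1$a * exp(-m1$b * 15), tolerance = 1e-10)
})

test_that("predictions are strictly increasing in delta_g for b > 0", {
  m <- preset_efficiency_model("trb1_primary")
  xs <- seq(-140, 0, by = 5)
  expect_true(all(diff(predict_efficiency(m, xs)) > 0))
  expect_equal(predict_efficiency(m, 0), m$a) # exact at the origin
})

test_that("presets expose both published equations and predict sensibly", {
  p1 <- preset_efficiency_model("trb1_primary")
  expect_equal(c(p1$a, p1$b), c(127.29, 0.0248))
  p2 <- preset_efficiency_model("trb1_alternate")
  expect_equal(c(p2$a, p2$b), c(140.46, 0.0307))
  expect_equal(predict_efficiency(p1, -69.0), 22.99480, tolerance = 1e-6)
  expect_equal(predict_efficiency(p1, -6.8), 107.5362, tolerance = 1e-6)
})

test_that("regulatory potential is a plain positive ratio with a closed form", {
  expect_equal(regulatory_potential(3.7, 3.7), 1)
  m <- preset_efficiency_model("trb1_primary")
  expect_equal(predicted_potential(m, -69.0, -128.9),
               exp(0.0248 * (128.9 - 69.0)), tolerance = 1e-12)
})

test_that("tidy and glance expose the coefficients broom-style", {
  d <- tibble::tibble(delta_g = c(-10, -60, -110), efficiency = c(90, 30, 9))
  m <- fit_efficiency_model(d)
  td <- tidy(m)
  expect_equal(td$term, c("a", "b"))
  expect_equal(td$estimate, c(m$a, m$b))
  gl <- glance(m)
  expect_equal(gl$nobs, 3L)
  expect_true(gl$r.squared > 0.9)
})

test_that("models survive a JSON round trip", {
  d <- tibble::tibble(delta_g = c(-10, -60, -110), efficiency = c(90, 30, 9))
  m <- fit_efficiency_model(d)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$a, m$a, tolerance = 1e-12)
  expect_equal(m2$b, m$b, tolerance = 1e-12)
  expect_equal(m2$r_squared, m$r_squared, tolerance = 1e-12)
})
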