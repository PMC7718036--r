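# ISI model families: normalization, moments, scale-family property,
# Laplace transforms, and the MPP parameterization.

admissible <- function(family, fano) {
  switch(family,
    gamma = fano > 0,
    invgauss = fano > 0,
    exp_refractory = fano > 0 && fano <= 1,
    exponential = fano == 1,
    FALSE)
}

make_model <- function(family, rate, fano) {
  switch(family,
    gamma = isi_gamma(rate, fano),
    invgauss = isi_invgauss(rate, fano),
    exp_refractory = isi_exp_refractory(rate, fano),
    exponential = isi_exponential(rate))
}

test_that("pdf normalization, mean 1/rate and CV^2 = fano hold across the parameter grid", {
  for (family in c("gamma", "invgauss", "exp_refractory", "exponential")) {
    for (rate in c(0.2, 1, 5)) {
      for (fano in c(0.25, 0.5, 1, 1.5, 3)) {
        if (!admissible(family, fano)) next
        m <- make_model(family, rate, fano)
        # integrate from the support start (the refractory family's pdf
        # jumps there, which defeats quadrature across the kink)
        lo <- if (family == "exp_refractory") m$refractory else 0
        total <- integrate(function(t) isi_pdf(m, t), lo, Inf,
                           rel.tol = 1e-9)$value
        mu <- integrate(function(t) t * isi_pdf(m, t), lo, Inf,
                        rel.tol = 1e-9)$value
        m2 <- integrate(function(t) t^2 * isi_pdf(m, t), lo, Inf,
                        rel.tol = 1e-9)$value
        expect_equal(total, 1, tolerance = 1e-6)
        expect_equal(mu, 1 / rate, tolerance = 1e-6)
        expect_equal((m2 - mu^2) / mu^2, fano, tolerance = 1e-6)
        expect_equal(isi_mean(m), 1 / rate)
        expect_equal(isi_cv2(m), fano)
      }
    }
  }
})

test_that("every family is a scale family: f(t; rate, F) = rate * f(rate t; 1, F)", {
  tgrid <- c(0.05, 0.3, 0.8, 1.5, 4)
  for (family in c("gamma", "invgauss", "exp_refractory", "exponential")) {
    fano <- if (family == "exponential") 1 else 0.5
    for (rate in c(0.2, 5)) {
      m <- make_model(family, rate, fano)
      m1 <- make_model(family, 1, fano)
      expect_equal(isi_pdf(m, tgrid), rate * isi_pdf(m1, rate * tgrid),
                   tolerance = 1e-12)
    }
  }
})

test_that("gamma with F = 1 reduces to the exponential density", {
  t <- c(0.1, 0.5, 1, 3)
  expect_equal(isi_pdf(isi_gamma(1, 1), t), exp(-t), tolerance = 1e-12)
  expect_equal(isi_pdf(isi_gamma(2, 1), t), isi_pdf(isi_exponential(2), t),
               tolerance = 1e-12)
})

test_that("refractory exponential has the stated dead time and reduces to exponential at F = 1", {
  m <- isi_exp_refractory(1, 0.5)
  r <- (1 - sqrt(0.5))  # dead time at rate 1
  expect_equal(isi_pdf(m, r * 0.99), 0)
  expect_gt(isi_pdf(m, r * 1.01), 0)
  m1 <- isi_exp_refractory(1, 1)
  expect_equal(m1$refractory, 0)
  expect_equal(isi_pdf(m1, c(0.2, 1)), dexp(c(0.2, 1)), tolerance = 1e-12)
})

test_that("closed-form Laplace transforms match direct quadrature of the pdf", {
  models <- list(isi_gamma(1, 0.5), isi_gamma(2, 1.5), isi_invgauss(1, 0.5),
                 isi_invgauss(1, 1.5), isi_exponential(1),
                 isi_exp_refractory(1, 0.5))
  for (m in models) {
    lo <- if (inherits(m, "isi_exp_refractory")) m$refractory else 0
    for (s in c(0.1, 1, 10)) {
      quad <- integrate(function(t) exp(-s * t) * isi_pdf(m, t), lo, Inf,
                        rel.tol = 1e-12, abs.tol = 1e-13)$value
      expect_lt(abs(laplace_pdf(m, s) - quad), 1e-8)
    }
  }
})

test_that("Laplace transform worked values and limits", {
  expect_equal(laplace_pdf(isi_exponential(1), 1), 0.5)
  expect_equal(laplace_pdf(isi_gamma(1, 0.5), 1), 1.5^-2)
  for (m in list(isi_gamma(1, 1.5), isi_invgauss(2, 0.5),
                 isi_exp_refractory(1, 0.25)))
    expect_equal(laplace_pdf(m, 1e-12), 1, tolerance = 1e-9)
  expect_error(laplace_pdf(isi_pacemaker(1), 1), "pacemaker")
})

test_that("constructors reject inadmissible parameters", {
  expect_error(isi_gamma(-1, 0.5), "positive")
  expect_error(isi_gamma(1, 0), "positive")
  expect_error(isi_invgauss(0, 1), "positive")
  expect_error(isi_exp_refractory(1, 1.2), "0, 1")
  expect_error(isi_exp_refractory(1, 0), "positive")
  expect_error(isi_pacemaker(0), "positive")
})

test_that("MPP state means solve the intensity and Fano-factor constraints", {
  mus <- mpp_state_means(rate = 1, fano = 1.5, p = 0.1)
  expect_equal(unname(mus[1]), 1.2236, tolerance = 1e-4)
  expect_equal(unname(mus[2]), 0.7764, tolerance = 1e-4)
  # round trip through the intensity and MPP-limit formulas
  for (rate in c(0.5, 1, 2)) {
    for (fano in c(1.2, 1.5, 3)) {
      for (p in c(0.05, 0.1, 1)) {
        if (p * (fano - 1) >= 1) next
        mus <- mpp_state_means(rate, fano, p)
        mu1 <- mus[["mu1"]]; mu2 <- mus[["mu2"]]
        expect_equal(2 / (mu1 + mu2), rate, tolerance = 1e-12)
        expect_equal(1 + (1 / p) * (mu2 - mu1)^2 / (mu1 + mu2)^2, fano,
                     tolerance = 1e-12)
      }
    }
  }
  # Poisson limit and the p = 1 sum identity
  mus <- mpp_state_means(1, 1 + 1e-12, 0.5)
  expect_equal(unname(mus), c(1, 1), tolerance = 1e-5)
  mus <- mpp_state_means(2, 1.5, 1)
  expect_equal(sum(mus), 1)
  expect_error(mpp_state_means(1, 0.8, 0.5), "> 1")
  expect_error(mpp_state_means(1, 3, 0.9), "non-positive mu2")
})

test_that("MRP model validation and intensity", {
  m <- mrp_model(3, 1, switch_prob = 1)
  expect_equal(m$rate, 0.5)
  expect_error(mrp_model(1, 1, switch_prob = 1.5), "probability")
  expect_error(mrp_model(1, 1, cv1 = 2, switch_prob = 0.5), "exponential")
  m2 <- mrp_model(2, 1, cv1 = 0.5, cv2 = 2, switch_prob = 0.3,
                  state_family = "gamma")
  expect_s3_class(m2$states[[1]], "isi_gamma")
})

test_that("model configs round-trip through the flat key-value form", {
  models <- list(isi_gamma(2, 1.5), isi_invgauss(0.5, 0.25),
                 isi_exponential(3), isi_exp_refractory(1, 0.5),
                 isi_pacemaker(2), mpp_model(1, 1.5, 0.1),
                 mrp_model(2, 1, cv1 = 0.5, cv2 = 1.5, switch_prob = 0.4,
                           state_family = "gamma"))
  for (m in models)
    expect_equal(model_from_config(model_to_config(m)), m)
  # via a JSON file
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(model_to_config(isi_gamma(2, 1.5)), path,
                       auto_unbox = TRUE, digits = NA)
  expect_equal(model_from_config(path), isi_gamma(2, 1.5))
})
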