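# Model abstraction: builtin structure, rates, production, validation.

test_that("builtin models have the documented deme and mark structure", {
  m <- seirs_small()
  expect_length(m$demes, 2L)
  expect_length(m$marks, 5L)
  expect_setequal(vapply(m$marks, `[[`, character(1), "event_class"),
                  c("birth", "migration", "death", "sample", "neutral"))
  expect_identical(production(m$marks$Trans), c(1L, 1L))
  expect_identical(production(m$marks$Prog), c(0L, 1L))
  expect_identical(production(m$marks$Recov), c(0L, 0L))

  mo <- builtin_model("moran", list(n = 10, mu = 1))
  expect_identical(mo$marks$Event$event_class, "compound")
  expect_identical(production(mo$marks$Event), 2L)
  x <- mo$state0
  expect_identical(mo$occupancy(mo$marks$Event$jump(x)), mo$occupancy(x))

  lb <- builtin_model("lbd", list(lambda = 0, mu = 0, psi = 0, rho = 1, x0 = 1))
  for (x in c(0, 3, 10))
    expect_equal(total_rate(lb, 0, c(X = x)), 0)
})

test_that("total rate is additive over marks and matches hand sums", {
  lb <- builtin_model("lbd", list(lambda = 1, mu = 2, psi = 0.5, x0 = 3))
  x <- c(X = 3)
  expect_equal(total_rate(lb, 0, x), 3 * (1 + 2 + 0.5))
  expect_equal(total_rate(lb, 0, x),
               sum(vapply(lb$marks, function(m) m$rate(0, x), numeric(1))))
  m <- seirs_small(N = 100)
  x_noI <- c(S = 100, E = 0, I = 0, R = 0)
  expect_equal(m$marks$Trans$rate(0, x_noI), 0)
  expect_equal(total_rate(m, 0, x_noI), 0)
})

test_that("validate_model passes builtins and flags broken occupancy accounting", {
  for (nm in c("sirs", "seirs", "moran", "lbd")) {
    model <- switch(nm,
      sirs = builtin_model("sirs", list(N = 20, beta = 2, gamma = 1, psi = 0.3)),
      seirs = seirs_small(),
      moran = moran_serial_model(),
      lbd = lbd_small())
    expect_identical(validate_model(model), character(0))
  }
  big <- builtin_model("two_strain",
    list(N = 8, beta1 = 2, beta2 = 1.5, sigma1 = 1, sigma2 = 1, gamma1 = 0.5,
         gamma2 = 0.5, psi1 = 0.2, psi2 = 0.2))
  expect_identical(validate_model(big), character(0))
  sup <- builtin_model("superspreading",
    list(N = 10, beta_l = 1, beta_h = 4, sigma = 1, f_h = 0.2, eta_lh = 0.3,
         eta_hl = 0.5, gamma = 0.7, psi = 0.2))
  expect_identical(validate_model(sup), character(0))
  prg <- builtin_model("progression",
    list(N = 10, beta_a = 1, beta_s = 2, sigma_a = 0.6, sigma_s = 0.9,
         gamma_a = 0.5, gamma_s = 0.5, eta = 0.3, delta_h = 0.2, psi = 0.3))
  expect_identical(validate_model(prg), character(0))

  ## a mark whose state update does not move the lineage its descriptor
  ## claims to move must be reported
  broken <- population_model(
    "broken", "I", c("S", "I"),
    list(jump_mark("BadRecov", function(t, x) x[["I"]],
                   identity, 1L, deaths = 1L)),
    occupancy = function(x) x[["I"]],
    state0 = c(S = 4, I = 1),
    enumerate = function() {
      m <- genfilter:::compositions(5, 2); colnames(m) <- c("S", "I"); m
    })
  expect_match(validate_model(broken), "inconsistent", all = FALSE)
})

test_that("errors: unknown model names and bad parameters", {
  expect_error(builtin_model("nope"), "arg")
  expect_error(builtin_model("seirs", list(N = 10)), "missing parameter")
  expect_error(builtin_model("lbd", list(lambda = -1, mu = 0, psi = 0)),
               "non-negative")
  expect_error(builtin_model("lbd", list(lambda = 1, mu = 1, psi = 0, rho = 2)),
               "rho")
})

test_that("model configs round-trip exactly through JSON", {
  cfg <- list(model = "seirs",
              params = list(N = 20L, beta = 2.123456789012345, sigma = 1,
                            gamma = 0.7, psi = 0.35, omega = 0.1, E0 = 1L, I0 = 2L),
              horizon = 3.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_config(cfg, path)
  cfg2 <- read_model_config(path)
  expect_equal(cfg2$params$beta, cfg$params$beta, tolerance = 0)
  expect_equal(cfg2$horizon, cfg$horizon, tolerance = 0)
  m <- model_from_config(path)
  expect_s3_class(m, "population_model")
  expect_equal(unname(m$state0), c(17, 1, 2, 0))
})
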