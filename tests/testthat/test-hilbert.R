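fv <- fruits_vegetables_table()
ref <- fruits_vegetables_reference()

test_that("interference budget matches published per-item values", {
  lam <- interference_lambda(fv$mu_A, fv$mu_B, fv$mu_AorB, fv$item)
  expect_lt(max(abs(lam - ref$lambda)), 3e-4)
  # zero-deviation case collapses to the geometric mean bound
  expect_equal(interference_lambda(0.2, 0.05, 0.125), sqrt(0.2 * 0.05))
  expect_error(interference_lambda(0.01, 0.01, 0.5, item = "bad"),
               "infeasible.*bad")
})

test_that("interference phase reproduces published angles", {
  expect_equal(interference_phase(0.0359, 0.0133, 0.0269), 84.0,
               tolerance = 0.5 / 84)
  expect_equal(interference_phase(0.0755, 0.0125, 0.0604), 57.7,
               tolerance = 0.5 / 57.7)
  expect_equal(interference_phase(0.3, 0.1, 0.2), 90)
  expect_equal(interference_phase(0.3, 0.1, 0.2, epsilon = -1), -90)
  expect_error(interference_phase(0.04, 0.03, 0.3), "outside")
})

test_that("greedy partial-sum scheme keeps the running sum nonnegative", {
  one <- partial_sum_signs(0.4)
  expect_equal(one$epsilon, 1L)
  expect_equal(one$S_n, 0.4)

  # three-step hand trace: 0.5 -> subtract 0.3 (0.2) -> subtract 0.2 (0)
  tri <- partial_sum_signs(c(0.5, 0.3, 0.2))
  expect_equal(tri$epsilon, c(1L, -1L, -1L))
  expect_equal(tri$S_n, 0)
  expect_equal(tri$trace$S, c(0.5, 0.2, 0))

  # equal pair cancels exactly
  expect_equal(partial_sum_signs(c(0.3, 0.3))$S_n, 0)

  for (seed in 1:20) {
    set.seed(seed)
    sc <- partial_sum_signs(runif(sample(2:40, 1)))
    expect_true(all(sc$trace$S >= 0))
    expect_gte(sc$S_n, 0)
    # the scheme is a signed sum of all budgets
    expect_equal(sum(sc$epsilon * sc$trace$lambda[order(sc$trace$index)]),
                 sc$S_n)
  }
  expect_error(partial_sum_signs(numeric(0)), "empty")
})

test_that("ranking and signs reproduce the published scheme", {
  lam <- interference_lambda(fv$mu_A, fv$mu_B, fv$mu_AorB)
  sc <- partial_sum_signs(lam)
  expect_identical(sc$rank, ref$rank)
  expect_identical(sc$epsilon, as.integer(ref$epsilon))
  expect_equal(sc$S_n, 0.0154, tolerance = 0.001 / 0.0154)
})

test_that("basis overlap closes the sine-sum constraint", {
  expect_equal(basis_overlap(0.07, 0.07, 0.1, 0.2, 0.15), 0)
  expect_error(basis_overlap(0, 1, 0.1, 0.1, 0.1), "c_m")

  # residual oracle: substituting c_m back makes the sine sum vanish
  for (seed in 1:5) {
    tab <- gen_quantum_table(10, seed = seed)
    lam <- interference_lambda(tab$mu_A, tab$mu_B, tab$mu_AorB)
    sc <- partial_sum_signs(lam)
    m <- which(sc$rank == 1)
    cm <- basis_overlap(sc$S_n, lam[m], tab$mu_A[m], tab$mu_B[m],
                        tab$mu_AorB[m])
    ck <- rep(1, 10); ck[m] <- cm
    phi <- interference_phase(tab$mu_A, tab$mu_B, tab$mu_AorB,
                              c = ck, epsilon = sc$epsilon)
    sine_sum <- sum(ck * sqrt(tab$mu_A * tab$mu_B) * sinpi(phi / 180))
    expect_lt(abs(sine_sum), 1e-12)
  }
})

test_that("assembled concept vectors have the constructed coordinates", {
  fit <- disjunction_model(fv)
  expect_equal(Mod(fit$vector_A[1]), 0.1895, tolerance = 5e-4 / 0.1895)
  expect_equal(Mod(fit$vector_B[21]), 0.3583, tolerance = 5e-4 / 0.3583)
  expect_equal(fit$table$item[fit$m], "Tomato")
  # coordinate construction returns the inputs as squared moduli
  expect_equal(Mod(fit$vector_A[1:24])^2, fv$mu_A, tolerance = 1e-12)
  not_m <- setdiff(1:24, fit$m)
  expect_equal(Mod(fit$vector_B[not_m])^2, fv$mu_B[not_m], tolerance = 1e-12)
  expect_equal(Mod(fit$vector_B[fit$m])^2 + Mod(fit$vector_B[25])^2,
               fv$mu_B[fit$m], tolerance = 1e-12)

  # unit norms and superposition norm on exactly normalised data
  ex <- exact_quantum_table(10, seed = 4)
  fe <- disjunction_model(ex)
  expect_equal(sum(Mod(fe$vector_A)^2), 1, tolerance = 1e-10)
  expect_equal(sum(Mod(fe$vector_B)^2), 1, tolerance = 1e-10)
  sup <- (fe$vector_A + fe$vector_B) / sqrt(2)
  expect_equal(sum(Mod(sup)^2), 1, tolerance = 1e-9)
})

test_that("model reconstruction returns the observed disjunction column", {
  fit <- disjunction_model(fv)
  expect_equal(unname(fitted(fit)), fv$mu_AorB, tolerance = 1e-12)
  # interference term of the first item is the deviation from the average
  expect_equal(unname(residuals(fit)["Almond"]),
               0.0269 - (0.0359 + 0.0133) / 2)
  expect_lt(max(abs(residuals(fit, type = "reconstruction"))), 1e-14)

  # projector expectation on the superposition equals the reconstruction
  sup <- (fit$vector_A + fit$vector_B) / sqrt(2)
  per_item <- Mod(sup[1:24])^2
  per_item[fit$m] <- per_item[fit$m] + Mod(sup[25])^2
  expect_equal(per_item, fv$mu_AorB, tolerance = 1e-12)

  # all phases at 90 degrees: the disjunction is the classical average
  mt <- mean_table(6, seed = 11)
  fm <- disjunction_model(mt, check_normalization = FALSE)
  expect_equal(abs(fm$angles$phi_deg), rep(90, 6))
  expect_equal(unname(fitted(fm)), (mt$mu_A + mt$mu_B) / 2, tolerance = 1e-12)
})

test_that("concept vectors are orthogonal up to input rounding", {
  fit <- disjunction_model(fv)
  o <- verify_orthogonality(fit)
  expect_lt(abs(o$sine_residual), 1e-10)
  expect_lt(abs(o$cosine_residual), 5e-4)
  expect_equal(o$inner_product_modulus,
               sqrt(o$cosine_residual^2 + o$sine_residual^2))

  oe <- verify_orthogonality(disjunction_model(exact_quantum_table(9, 6)))
  expect_lt(abs(oe$cosine_residual), 1e-10)
  expect_lt(abs(oe$sine_residual), 1e-10)
})

test_that("fitted phases recover the generating phases in magnitude", {
  for (seed in c(1, 2)) {
    tab <- gen_quantum_table(15, seed = seed)
    phi_true <- attr(tab, "phi_true")
    fit <- disjunction_model(tab, check_normalization = FALSE)
    not_m <- setdiff(seq_len(15), fit$m)
    expect_lt(max(abs(abs(fit$angles$phi_deg[not_m]) -
                        abs(phi_true[not_m]))), 1e-9)
    # unit-overlap convention recovers every item, rank-1 included
    expect_lt(max(abs(abs(theta_targets(tab)) - abs(phi_true))), 1e-9)
  }
})

test_that("model methods print, predict, simulate and serialize", {
  fit <- disjunction_model(fv)
  expect_output(print(fit), "S_24 = 0.0154")
  expect_output(print(summary(fit)), "classical")
  expect_named(coef(fit), c("item", "lambda", "rank", "epsilon", "phi_deg",
                            "c"))

  nd <- data.frame(item = c("Almond", "Tomato"), mu_A = c(0.04, 0.09),
                   mu_B = c(0.015, 0.07))
  pr <- predict(fit, nd)
  k <- match(nd$item, fit$angles$item)
  expect_equal(unname(pr),
               (nd$mu_A + nd$mu_B) / 2 + fit$angles$c[k] *
                 sqrt(nd$mu_A * nd$mu_B) * cospi(fit$angles$phi_deg[k] / 180))
  expect_error(predict(fit, data.frame(item = "Durian", mu_A = .1,
                                       mu_B = .1)), "not in the fitted")

  sims <- simulate(fit, nsim = 2, seed = 99, participants = 5000)
  sims2 <- simulate(fit, nsim = 2, seed = 99, participants = 5000)
  expect_equal(sims, sims2)
  expect_s3_class(sims[[1]], "membership_table")

  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit, items = c("Almond", "Coconut")))

  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  payload <- jsonlite::read_json(path)
  expect_equal(payload$S_n, fit$S_n, tolerance = 1e-12)
  expect_equal(payload$rank1_item, "Tomato")
  expect_length(payload$vector_B, 25)
})

test_that("degenerate and infeasible tables abort with diagnostics", {
  bad <- membership_table(c("ok", "bad"), c(0.5, 0.02), c(0.5, 0.02),
                          c(0.45, 0.55))
  expect_error(disjunction_model(bad, check_normalization = FALSE),
               "bad")
  unnorm <- membership_table(c("a", "b"), c(0.2, 0.3), c(0.3, 0.2),
                             c(0.25, 0.25))
  expect_error(disjunction_model(unnorm), "not normalized")
})
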