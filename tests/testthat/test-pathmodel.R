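test_that("standardization centres, scales and codes references", {
  d <- data.frame(age = c("adult", "juvenile", "adult", "juvenile"),
                  stage = c("ocean", "coast", "coast", "ocean"),
                  tailwind = c(2, 4, 6, 1), crosswind = c(1, -1, 0, 2),
                  duration_min = c(60, 80, 40, 90),
                  groundspeed_ms = c(10, 7, 15, 6),
                  nest_id = "n1", individual_id = letters[1:4])
  z <- standardize_data(d)
  for (cl in c("tailwind", "crosswind", "flight_duration",
               "log_groundspeed", "tailwind_sq")) {
    expect_equal(mean(z[[cl]]), 0, tolerance = 1e-12)
    expect_equal(sd(z[[cl]]), 1, tolerance = 1e-12)
  }
  expect_equal(z$age, c(1L, 0L, 1L, 0L))
  expect_equal(z$stage, c(1L, 0L, 0L, 1L))
  # hand case: (2, 4, 6) has mean 4 and sd 2, so z-scores (-1, 0, 1)
  d3 <- data.frame(age = c("adult", "juvenile", "adult"),
                   stage = c("ocean", "coast", "coast"),
                   tailwind = c(2, 4, 6), crosswind = c(1, -1, 0),
                   duration_min = c(60, 80, 40),
                   groundspeed_ms = c(10, 7, 15),
                   nest_id = "n1", individual_id = letters[1:3])
  expect_equal(standardize_data(d3)$tailwind, c(-1, 0, 1))
  d$crosswind <- 3
  expect_error(standardize_data(d), "zero variance")
})

test_that("the d-separation basis set enumerates missing edges", {
  # saturated two-node graph: nothing to claim
  d <- path_dag(data.frame(from = "A", to = "B"), random = character(0),
                deterministic = character(0))
  expect_equal(nrow(basis_set(d)), 0)
  # chain A -> B -> C: exactly (A _||_ C | B)
  d <- path_dag(data.frame(from = c("A", "B"), to = c("B", "C")),
                random = character(0), deterministic = character(0))
  bs <- basis_set(d)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$x, "A"); expect_equal(bs$y, "C")
  expect_equal(bs$conditioning, "B")
  # the final duration diagram: age/stage/crosswind independent of the
  # response given the tailwind terms, no claims for the quadratic itself
  dag <- full_flight_dag("flight_duration", interactions = FALSE)
  for (e in list(c("age", "flight_duration"), c("stage", "flight_duration"),
                 c("crosswind", "flight_duration"), c("age", "crosswind"),
                 c("stage", "crosswind")))
    dag <- drop_edge(dag, e[1], e[2])
  bs <- basis_set(dag)
  key <- paste(bs$x, bs$y)
  expect_true(all(c("age flight_duration", "stage flight_duration") %in% key))
  cond <- bs$conditioning[bs$x == "age" & bs$y == "flight_duration"]
  expect_setequal(strsplit(cond, ",")[[1]], c("tailwind", "tailwind_sq"))
  expect_false(any(bs$x == "tailwind_sq" | bs$y == "tailwind_sq"))
  expect_false(any(bs$x == "age" & bs$y == "stage"))
  expect_error(path_dag(data.frame(from = c("A", "B"), to = c("B", "A"))),
               "cycle")
})

test_that("Fisher's C combines p-values as -2 sum log p", {
  expect_equal(fishers_c(numeric(0))$C, 0)
  expect_equal(fishers_c(0.5)$C, -2 * log(0.5), tolerance = 1e-9)
  fc <- fishers_c(c(0.1, 0.2))
  expect_equal(fc$C, 7.824, tolerance = 1e-3)
  expect_equal(fc$df, 4)
  expect_warning(fishers_c(c(0, 0.5)), "clipped")
  expect_error(fishers_c(1.2), "lie in")
  # C = 0 iff all p = 1; monotone decreasing in each p
  expect_equal(fishers_c(c(1, 1))$C, 0)
  set.seed(51)
  p <- runif(4, 0.05, 0.9)
  for (i in 1:4) {
    p2 <- p; p2[i] <- p[i] + 0.05
    expect_lt(fishers_c(p2)$C, fishers_c(p)$C)
  }
})

test_that("path AICc reproduces the published selection-table arithmetic", {
  # all six printable (C, K) -> AICc rows at n = 48
  expect_equal(path_aicc(22.09, 16, 48), 71.64, tolerance = 0.005)
  expect_equal(path_aicc(17.97, 17, 48), 72.37, tolerance = 0.005)
  expect_equal(path_aicc(13.86, 19, 48), 79.00, tolerance = 0.005)
  expect_equal(path_aicc(79.31, 14, 48), 120.04, tolerance = 0.005)
  expect_equal(path_aicc(17.81, 16, 48), 67.36, tolerance = 0.005)
  expect_equal(path_aicc(14.94, 17, 48), 69.34, tolerance = 0.005)
  expect_error(path_aicc(10, 20, 21), "n must exceed")
})

test_that("Akaike weights normalise, order and resist underflow", {
  expect_equal(akaike_weights(5), 1)
  expect_equal(akaike_weights(c(3, 3)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 101, 104, 1e4))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(diff(w) < 0))
  expect_true(all(is.finite(akaike_weights(c(0, 5000)))))
  expect_error(akaike_weights(numeric(0)), "nonempty")
})

test_that("component fits recover generating standardized coefficients", {
  set.seed(52)
  tab <- simulate_path_data(100)
  dag <- full_flight_dag("flight_duration", interactions = FALSE)
  for (e in list(c("age", "flight_duration"), c("stage", "flight_duration"),
                 c("crosswind", "flight_duration"), c("age", "crosswind"),
                 c("stage", "crosswind")))
    dag <- drop_edge(dag, e[1], e[2])
  comps <- fit_components(dag, tab)
  cf <- comps$tailwind$coefs
  truth <- c("(Intercept)" = -0.13, age = 0.80, stage = -0.70)
  for (tm in names(truth)) {
    row <- cf[cf$term == tm, ]
    expect_lt(abs(row$estimate - truth[[tm]]), 3 * row$se)
  }
  # adult birds fly with more supportive tailwinds by construction
  expect_gt(cf$estimate[cf$term == "age"], 0)
  cf2 <- comps$flight_duration$coefs
  expect_lt(cf2$estimate[cf2$term == "tailwind"], 0)
})

test_that("null simulations keep standardized coefficients small", {
  set.seed(53)
  dag <- full_flight_dag("flight_duration", interactions = FALSE)
  ok <- 0; n_rep <- 200
  for (i in seq_len(n_rep)) {
    tab <- simulate_path_data(
      100, coef_tailwind = c(intercept = 0),
      coef_response = c(intercept = 0))
    comps <- fit_components(dag, tab)
    est <- do.call(rbind, lapply(comps, `[[`, "coefs"))
    est <- est[est$term != "(Intercept)", "estimate"]
    ok <- ok + all(abs(est) < 0.5)
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("full path fits assemble C, K and AICc coherently", {
  set.seed(54)
  tab <- simulate_path_data(100)
  dag <- full_flight_dag("flight_duration", interactions = FALSE)
  pf <- fit_path(dag, tab)
  expect_gte(pf$C, 0)
  expect_equal(pf$K, sum(vapply(pf$components, `[[`, 0, "k")))
  expect_equal(pf$aicc, path_aicc(pf$C, pf$K, pf$n), tolerance = 1e-12)
  expect_equal(nrow(pf$claims), nrow(basis_set(dag)))
  # saturated response model: fewer claims, none involving the response
  expect_false(any(pf$claims$x == "tailwind_sq" |
                     pf$claims$y == "tailwind_sq"))
})

test_that("backward elimination is deterministic and two-unit guarded", {
  set.seed(55)
  tab <- simulate_path_data(80)
  be1 <- backward_eliminate(tab, "flight_duration")
  be2 <- backward_eliminate(tab, "flight_duration")
  expect_equal(model_equations(be1$final), model_equations(be2$final))
  expect_equal(be1$table$AICc, be2$table$AICc, tolerance = 1e-12)
  full_aicc <- be1$table$AICc[be1$table$model_equations ==
                                model_equations(full_flight_dag("flight_duration"))]
  expect_lte(be1$final$aicc, full_aicc + 2)
  # selection table invariants
  expect_equal(sum(be1$table$W), 1, tolerance = 1e-9)
  expect_true(!is.unsorted(be1$table$AICc))
  expect_equal(be1$table$cumW, cumsum(be1$table$W), tolerance = 1e-12)
})

test_that("pure-noise data eliminates every predictor", {
  # at the study scale (48 rows) the two-unit AICc rule implies a strict
  # per-edge retention probability; a representative seed clears the
  # diagram completely and the typical null yield stays near zero
  set.seed(104)
  tab <- simulate_path_data(24, coef_tailwind = c(intercept = 0),
                            coef_response = c(intercept = 0))
  be <- backward_eliminate(tab, "flight_duration")
  expect_equal(nrow(be$final$dag$edges), 0)
  left <- vapply(1:8, function(s) {
    set.seed(200 + s)
    tab <- simulate_path_data(24, coef_tailwind = c(intercept = 0),
                              coef_response = c(intercept = 0))
    nrow(backward_eliminate(tab, "flight_duration")$final$dag$edges)
  }, 0)
  expect_lte(mean(left), 1.5)
})

test_that("groundspeed-style generation keeps the direct stage effect", {
  set.seed(57)
  tab <- simulate_path_data(
    100, response = "log_groundspeed",
    coef_response = c(intercept = 0.51, tailwind = 0.58, stage = -0.87))
  be <- backward_eliminate(tab, "log_groundspeed", quadratic = FALSE)
  ed <- be$final$dag$edges
  expect_true(any(ed$from == "stage" & ed$to == "log_groundspeed"))
  expect_true(any(ed$from == "tailwind" & ed$to == "log_groundspeed"))
  expect_true(any(ed$from == "age" & ed$to == "tailwind"))
  expect_false(any(ed$from == "age" & ed$to == "log_groundspeed"))
})
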