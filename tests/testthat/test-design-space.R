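test_that("OLS response surface is exact on linear data and matches
           the normal equations", {
  set.seed(1)
  n <- 20
  d <- data.frame(C = runif(n, 20, 24), F = runif(n, 10, 20),
                  G = runif(n, 3, 3.2))
  y <- 5 + 2 * d$C - d$F + 10 * d$G
  rs <- suppressWarnings(
    fit_response_surface(d, y, c("C", "F", "G"), "lin"))
  expect_equal(rs$r2, 1, tolerance = 1e-10)
  expect_lt(rs$anova_p, 1e-12)
  expect_equal(unname(rs$coefficients), c(5, 2, -1, 10),
               tolerance = 1e-8)
  # pseudoinverse oracle on noisy data with interaction + quadratic
  y2 <- y + rnorm(n)
  terms <- c("C", "F", "G", "C*F", "G^2")
  rs2 <- fit_response_surface(d, y2, terms, "quad")
  M <- cbind(1, d$C, d$F, d$G, d$C * d$F, d$G^2)
  beta <- drop(solve(crossprod(M), crossprod(M, y2)))
  expect_equal(unname(rs2$coefficients), beta, tolerance = 1e-10)
  expect_lte(rs2$r2_adj, rs2$r2)
})

test_that("aliased terms are reported on rank deficiency", {
  d <- data.frame(A = 1:12, B = 2 * (1:12))
  set.seed(2)
  y <- rnorm(12)
  expect_error(fit_response_surface(d, y, c("A", "B"), "bad"),
               "aliased.*B")
})

test_that("coefficient recovery from the packaged TS structure", {
  fx <- load_fixture_design()
  d <- data.frame(binder = fx$table2$C, lubrication = fx$table2$F,
                  distance = fx$table2$G)
  cf_true <- c(31.086, -0.292, -0.065, -6.333)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    y <- drop(cbind(1, as.matrix(d)) %*% cf_true) + rnorm(52, sd = 0.2)
    rs <- fit_response_surface(d, y,
                               c("binder", "lubrication", "distance"))
    all(abs(rs$coefficients - cf_true) <= 3 * rs$std_errors)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("packaged models evaluate to the published arithmetic", {
  p <- evaluate_printed_models(22, 15, 3.15)
  expect_equal(unname(p["TS"]), 3.738, tolerance = 1e-3)
  expect_equal(unname(p["DT"]), 3.87, tolerance = 1e-2)
  expect_warning(p2 <- evaluate_printed_models(23, 20, 3.2), NA)
  expect_equal(unname(p2["TS"]), 2.804, tolerance = 1e-3)
  pm <- printed_models()
  expect_equal(unname(pm$TS$coefficients),
               c(31.086, -0.292, -0.065, -6.333))
  expect_equal(unname(pm$DT$coefficients),
               c(584.813, 0.885, 0.540, -376.339, -0.023, 58.911))
  expect_warning(evaluate_printed_models(30, 15, 3.1), "outside")
})

test_that("unbounded attributes make the whole grid feasible", {
  fr <- feasible_region(printed_models(),
                        list(cqa_spec("TS", upper = 1e9),
                             cqa_spec("DT", lower = -1e9)),
                        grids = default_grids())
  expect_true(all(fr$mask))
})

test_that("the overlapped region matches the published membership
           examples", {
  fr <- feasible_region(printed_models(),
                        list(cqa_spec("TS", 3, 5, "MPa"),
                             cqa_spec("DT", upper = 5, units = "min")))
  expect_gt(sum(fr$mask), 0)
  expect_lt(sum(fr$mask), length(fr$mask))
  expect_true(in_region(fr, c(binder = 22, lubrication = 15,
                              distance = 3.15)))
  expect_false(in_region(fr, c(binder = 23, lubrication = 20,
                               distance = 3.2)))
})

test_that("shrinking a bound never enlarges the region and refinement
           is stable", {
  wide <- feasible_region(printed_models(),
                          list(cqa_spec("TS", 3, 5),
                               cqa_spec("DT", upper = 5)))
  narrow <- feasible_region(printed_models(),
                            list(cqa_spec("TS", 3.5, 4.5),
                                 cqa_spec("DT", upper = 4.5)))
  expect_true(all(!narrow$mask | wide$mask))
  expect_lte(sum(narrow$mask), sum(wide$mask))
  # grid refinement: halving steps moves bounds by at most one coarse
  # step
  g_coarse <- list(binder = list(min = 20, max = 24, step = 0.2),
                   lubrication = list(min = 10, max = 20, step = 1),
                   distance = list(min = 3, max = 3.2, step = 0.01))
  g_fine <- lapply(g_coarse, function(g) {
    g$step <- g$step / 2
    g
  })
  fc <- feasible_region(printed_models(),
                        list(cqa_spec("TS", 3, 5),
                             cqa_spec("DT", upper = 5)), g_coarse)
  ff <- feasible_region(printed_models(),
                        list(cqa_spec("TS", 3, 5),
                             cqa_spec("DT", upper = 5)), g_fine)
  for (f in names(g_coarse)) {
    expect_lte(abs(fc$bounds[[f]]["min"] - ff$bounds[[f]]["min"]),
               g_coarse[[f]]$step + 1e-9)
    expect_lte(abs(fc$bounds[[f]]["max"] - ff$bounds[[f]]["max"]),
               g_coarse[[f]]$step + 1e-9)
  }
})

test_that("the region is a strict subset of the published bounding
           box", {
  grids <- list(binder = list(min = 21, max = 23, step = 0.1),
                lubrication = list(min = 10, max = 20, step = 1),
                distance = list(min = 3.1, max = 3.2, step = 0.01))
  fr <- feasible_region(printed_models(),
                        list(cqa_spec("TS", 3, 5),
                             cqa_spec("DT", upper = 5)), grids)
  expect_gt(sum(fr$mask), 0)
  expect_lt(sum(fr$mask), length(fr$mask))
})

test_that("an impossible bound empties the region with a warning", {
  expect_warning(
    fr <- feasible_region(printed_models(),
                          list(cqa_spec("TS", lower = 100))),
    "empty")
  expect_true(all(is.na(unlist(fr$bounds))))
})

test_that("contour export reflects the model's shape", {
  grids <- list(binder = list(min = 20, max = 24, step = 0.5),
                lubrication = list(min = 10, max = 20, step = 1),
                distance = list(min = 3, max = 3.2, step = 0.01))
  flat <- structure(list(response = "K", terms = "binder",
                         coefficients = c("(Intercept)" = 2,
                                          binder = 0)),
                    class = "response_surface")
  ct <- suppressWarnings(
    export_contours(flat, list(distance = 3.1),
                    axes = c("binder", "lubrication"), grids = grids))
  expect_equal(max(ct$z) - min(ct$z), 0)
  # linear model: straight, equispaced contours
  lin <- structure(list(response = "L", terms = c("binder"),
                        coefficients = c("(Intercept)" = 0,
                                         binder = 1)),
                   class = "response_surface")
  ctl <- export_contours(lin, list(distance = 3.1),
                         axes = c("binder", "lubrication"),
                         grids = grids)
  expect_true(all(apply(ctl$z, 2, function(col) all(col == ctl$z[, 1]))))
  # DT surface curves in distance (positive second difference)
  ctd <- export_contours(printed_models()$DT, list(binder = 22),
                         axes = c("lubrication", "distance"),
                         grids = grids)
  d2 <- diff(t(ctd$z)[, 1], differences = 2)
  expect_true(all(d2 > 0))
  expect_error(export_contours(lin, list(), axes = "binder"),
               "two free axes")
})
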