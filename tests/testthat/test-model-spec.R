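test_that("the canonical CBT model matches its documented shape", {
  m <- cbt
  expect_length(m$dag$nodes, 20L)
  expect_equal(total_patients(m), 6000L)
  expect_setequal(m$parents$D2, c("Z1", "Z2", "B1", "W1", "W2"))
  expect_true(all(c("Z1", "W1") %in% m$parents$D2))
  expect_equal(m$equations$W$link, "deterministic-sum")
  expect_equal(m$selection_node, "D1")

  small <- canonical_cbt_model(overrides = list(
    hierarchy = c(organizations = 2, practitioners_per_organization = 2,
                  patients_per_practitioner = 5)))
  expect_equal(total_patients(small), 20L)

  expect_error(canonical_cbt_model(overrides = list(
    equations = list(X4 = list(coefficients = c(V1 = 1))))),
    class = "junctures_input_error")
  expect_error(canonical_cbt_model(overrides = list(bogus = 1)),
               class = "junctures_input_error")
})

test_that("model constructor enforces its invariants", {
  dag <- causal_dag(c("A", "B"), directed = list(c("A", "B")))
  ns <- list(A = node_spec("A", "organization", "continuous"),
             B = node_spec("B", "organization", "binary-decision"))
  eqB <- structural_equation("B", "A", 0, 0.5, "latent-utility-threshold")
  # equation parents must match the DAG
  bad_eq <- structural_equation("B", character(0), 0, numeric(0),
                                "latent-utility-threshold")
  expect_error(
    juncture_model(dag, ns, list(B = bad_eq), list(),
                   c(organizations = 2, practitioners_per_organization = 1,
                     patients_per_practitioner = 1), "B"),
    class = "junctures_input_error")
  # link/kind mismatch
  ns_bad <- ns
  ns_bad$B <- node_spec("B", "organization", "continuous")
  expect_error(
    juncture_model(dag, ns_bad, list(B = eqB), list(),
                   c(organizations = 2, practitioners_per_organization = 1,
                     patients_per_practitioner = 1), "A"),
    class = "junctures_input_error")
  expect_error(structural_equation("B", "A", 0, 0.5, "linear", -1),
               class = "junctures_input_error")
})

test_that("identification claims all pass on the canonical model", {
  rep <- validate_claims(cbt)
  expect_true(all(rep$pass))
  ms <- attr(rep, "minimal_sets")
  # the documented set for the feasibility effect is itself minimal here
  expect_true(any(vapply(ms[["X4->T1"]],
                         function(s) setequal(s, c("Z1", "X2", "X5")),
                         logical(1))))
  # precision covariates appear in no minimal set
  for (v in c("X3", "V1", "V2", "Y1")) {
    expect_false(any(vapply(ms[["X4->T1"]], function(s) v %in% s, logical(1))))
  }
})

test_that("claim report tracks structural edits of the graph", {
  # removing Z1 -> X4 leaves the strategy-effect claim valid but Z1 is no
  # longer needed: some minimal set for D2 -> X4 excludes it
  m1 <- cbt_variant(drop_edges = list(c("Z1", "X4")))
  rep1 <- validate_claims(m1)
  expect_true(rep1$pass[rep1$claim == "a"])
  ms1 <- attr(rep1, "minimal_sets")[["D2->X4"]]
  expect_true(any(vapply(ms1, function(s) !("Z1" %in% s), logical(1))))

  # adding X4 -> Y2 makes feasibility a confounder of the treatment effect:
  # the case-mix set no longer suffices, while the X4 -> T1 claims survive
  m2 <- cbt_variant(add_edges = list("X4->Y2" = 0.3))
  rep2 <- validate_claims(m2)
  expect_false(rep2$pass[rep2$claim == "d"])
  expect_true(rep2$pass[rep2$claim == "b"])
  expect_true(rep2$pass[rep2$claim == "e"])
  ms2 <- attr(rep2, "minimal_sets")[["T1->Y2"]]
  expect_true(all(vapply(ms2, function(s) "X4" %in% s, logical(1))))
})

test_that("decision probabilities stay interior under default coefficients", {
  d <- draw_population(cbt, population_config(seed = 5))
  p_d1 <- mean(d$organizations$D1)
  p_d2 <- mean(d$organizations$D2, na.rm = TRUE)
  p_t1 <- mean(d$patients$T1, na.rm = TRUE)
  expect_gt(p_d1, 0.05); expect_lt(p_d1, 0.95)
  expect_gt(p_d2, 0.05); expect_lt(p_d2, 0.95)
  expect_gt(p_t1, 0.05); expect_lt(p_t1, 0.95)
})

test_that("models round-trip through JSON and YAML", {
  for (ext in c(".json", ".yaml")) {
    f <- withr::local_tempfile(fileext = ext)
    write_model(cbt, f)
    m2 <- read_model(f)
    expect_equal(m2$dag$nodes, cbt$dag$nodes)
    expect_equal(m2$dag$directed, cbt$dag$directed)
    expect_equal(m2$dag$bidirected, cbt$dag$bidirected)
    expect_equal(m2$equations, cbt$equations)
    expect_equal(m2$hierarchy, cbt$hierarchy)
    expect_equal(m2$correlated_errors, cbt$correlated_errors)
    expect_equal(m2$selection_node, cbt$selection_node)
  }
})

test_that("model files with schema violations are rejected with field paths", {
  f <- withr::local_tempfile(fileext = ".json")
  obj <- jsonlite::read_json(write_model(cbt, f), simplifyVector = FALSE)

  bad <- obj
  bad$equations[[2]]$parents <- list("NOPE", "Z2", "Z3", "B1", "W")
  jsonlite::write_json(bad, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(f), "undeclared node",
               class = "junctures_input_error")

  bad <- obj
  eq_y1 <- which(vapply(obj$equations, function(e) e$child == "Y1", logical(1)))
  bad$equations[[eq_y1]]$error_sd <- -0.5
  jsonlite::write_json(bad, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(f), "error_sd", class = "junctures_input_error")

  bad <- obj
  bad$hierarchy <- NULL
  jsonlite::write_json(bad, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(f), "hierarchy", class = "junctures_input_error")
})

test_that("the shipped canonical model file equals the built-in model", {
  f <- system.file("extdata", "cbt_model.json", package = "junctures")
  expect_true(nzchar(f))
  m <- read_model(f)
  expect_equal(m$equations, cbt$equations)
  expect_equal(m$dag$directed, cbt$dag$directed)
  expect_equal(m$hierarchy, cbt$hierarchy)
})
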