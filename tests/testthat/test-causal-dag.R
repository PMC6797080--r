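test_that("DAG construction validates structure", {
  expect_error(causal_dag(c("A", "B"), directed = list(c("A", "B"), c("B", "A"))),
               class = "junctures_structural_error")
  expect_error(causal_dag(c("A", "B"), directed = list(c("A", "C"))),
               class = "junctures_input_error")
  expect_error(causal_dag(c("A", "A")), class = "junctures_input_error")
  expect_error(causal_dag(c("A", "B"), bidirected = list(c("A", "A"))),
               class = "junctures_input_error")

  chain <- causal_dag(c("A", "B", "C"),
                      directed = list(c("A", "B"), c("B", "C")))
  expect_s3_class(chain, "causal_dag")
  expect_equal(nrow(chain$directed), 2L)

  # bidirected pairs are canonicalized and deduplicated
  g <- causal_dag(c("A", "B"), bidirected = list(c("B", "A"), c("A", "B")))
  expect_equal(nrow(g$bidirected), 1L)
  expect_equal(unname(g$bidirected[1, ]), c("A", "B"))

  expect_length(canonical_cbt_model()$dag$nodes, 20L)
})

test_that("d-separation blocks chains and opens colliders", {
  chain <- causal_dag(c("A", "B", "C"),
                      directed = list(c("A", "B"), c("B", "C")))
  expect_false(d_separated(chain, "A", "C"))
  expect_true(d_separated(chain, "A", "C", "B"))

  coll <- causal_dag(c("A", "B", "C"),
                     directed = list(c("A", "B"), c("C", "B")))
  expect_true(d_separated(coll, "A", "C"))
  expect_false(d_separated(coll, "A", "C", "B"))

  # descendant of a collider opens it too
  coll2 <- causal_dag(c("A", "B", "C", "D"),
                      directed = list(c("A", "B"), c("C", "B"), c("B", "D")))
  expect_false(d_separated(coll2, "A", "C", "D"))

  expect_error(d_separated(chain, "A", "Z"), class = "junctures_input_error")
  expect_error(d_separated(chain, "A", "A"), class = "junctures_input_error")
})

test_that("on the canonical DAG, V1 and D2 are marginally separated", {
  dag <- cbt$dag
  # the only V1--D2 routes pass through the collider T1
  expect_true(d_separated(dag, "V1", "D2"))
  expect_true(oracle_dsep_dag(dag, "V1", "D2"))
  # conditioning on the collider T1 connects them
  expect_false(d_separated(dag, "V1", "D2", "T1"))
})

test_that("d-separation is symmetric and agrees with the path oracle", {
  set.seed(11)
  for (i in 1:60) {
    g <- random_dag(sample(3:8, 1))
    pick <- sample(g$nodes, 2)
    z <- setdiff(g$nodes, pick)
    z <- z[stats::runif(length(z)) < 0.4]
    got <- d_separated(g, pick[1], pick[2], z)
    expect_identical(got, d_separated(g, pick[2], pick[1], z))
    expect_identical(got, oracle_dsep_dag(g, pick[1], pick[2], z))
  }
})

test_that("a bidirected edge behaves like a fresh latent common parent", {
  set.seed(23)
  for (i in 1:20) {
    g <- random_dag(sample(3:6, 1), p_bidir = 0.3)
    if (!nrow(g$bidirected)) next
    # replace every bidirected edge by an explicit latent parent
    lat <- paste0("LL", seq_len(nrow(g$bidirected)))
    directed <- lapply(seq_len(nrow(g$directed)),
                       function(i) g$directed[i, ])
    for (j in seq_len(nrow(g$bidirected))) {
      directed <- c(directed, list(c(lat[j], g$bidirected[j, 1])),
                    list(c(lat[j], g$bidirected[j, 2])))
    }
    g2 <- causal_dag(c(g$nodes, lat), directed = directed)
    pick <- sample(g$nodes, 2)
    z <- setdiff(g$nodes, pick)
    z <- z[stats::runif(length(z)) < 0.4]
    expect_identical(d_separated(g, pick[1], pick[2], z),
                     d_separated(g2, pick[1], pick[2], z))
  }
})

test_that("back-door validity matches the documented adjustment sets", {
  dag <- cbt$dag
  expect_true(is_valid_backdoor(dag, "D2", "X4", c("Z1", "X2"),
                                selection = "D1"))
  expect_true(is_valid_backdoor(dag, "T1", "Y2", c("V1", "V2", "Y1"),
                                selection = "D1"))
  # unadjusted, the patient-level confounders leave open back-door paths
  expect_false(is_valid_backdoor(dag, "T1", "Y2", character(0),
                                 selection = "D1"))
  # descendants of the treatment are never admissible
  expect_false(is_valid_backdoor(dag, "X4", "T1", c("Z1", "X2", "X5", "Y2"),
                                 selection = "D1"))
  expect_error(is_valid_backdoor(dag, "T1", "Y2", c("T1")),
               class = "junctures_input_error")
})

test_that("minimal adjustment sets are valid, minimal and complete", {
  chain <- causal_dag(c("A", "B", "C"),
                      directed = list(c("A", "B"), c("B", "C")))
  expect_equal(minimal_adjustment_sets(chain, "A", "C"), list(character(0)))

  conf <- causal_dag(c("U", "A", "C"),
                     directed = list(c("U", "A"), c("U", "C"), c("A", "C")))
  expect_equal(minimal_adjustment_sets(conf, "A", "C"), list("U"))

  # unblockable confounding: latent parent only
  lat <- causal_dag(c("A", "C"), directed = list(c("A", "C")),
                    bidirected = list(c("A", "C")))
  expect_equal(minimal_adjustment_sets(lat, "A", "C"), list())

  # canonical feasibility effect: a subset of {Z1, X2, X5} appears
  sets <- minimal_adjustment_sets(cbt$dag, "X4", "T1", selection = "D1")
  expect_true(any(vapply(sets, function(s) all(s %in% c("Z1", "X2", "X5")),
                         logical(1))))

  # every returned set is valid and inclusion-minimal (random graphs)
  set.seed(37)
  for (i in 1:15) {
    g <- random_dag(sample(4:7, 1))
    pick <- sample(g$nodes, 2)
    sets <- minimal_adjustment_sets(g, pick[1], pick[2])
    for (s in sets) {
      expect_true(is_valid_backdoor(g, pick[1], pick[2], s))
      for (v in s) {
        expect_false(is_valid_backdoor(g, pick[1], pick[2], setdiff(s, v)))
      }
    }
  }
})

test_that("DAG serialization round-trips through text and JSON", {
  g <- causal_dag(c("A", "B", "C", "ISO"),
                  directed = list(c("A", "B"), c("B", "C")),
                  bidirected = list(c("A", "C")))
  for (ext in c("txt", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_dag(g, f)
    g2 <- read_dag(f)
    expect_setequal(g2$nodes, g$nodes)
    expect_equal(g2$directed[order(g2$directed[, 1]), ],
                 g$directed[order(g$directed[, 1]), ])
    expect_equal(g2$bidirected, g$bidirected)
  }
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("A -> ", f)
  expect_error(read_dag(f), class = "junctures_input_error")
})
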