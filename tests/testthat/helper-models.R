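# Shared fixtures: model variants and a lazily computed Monte Carlo study
# reused by several test files.

cbt <- canonical_cbt_model()

# rebuild the canonical system with edges removed and/or added; added
# edges get the supplied structural coefficient
cbt_variant <- function(drop_edges = list(), add_edges = list()) {
  directed <- junctures:::canonical_directed_edges()
  for (e in drop_edges) {
    keep <- !vapply(directed, function(d) all(d == e), logical(1))
    directed <- directed[keep]
  }
  coefs <- junctures:::canonical_coefficients()
  for (e in drop_edges) {
    child <- e[2]
    if (child %in% names(coefs)) {
      cf <- coefs[[child]]$coefficients
      coefs[[child]]$coefficients <- cf[setdiff(names(cf), e[1])]
    }
  }
  for (nm in names(add_edges)) {
    e <- strsplit(nm, "->", fixed = TRUE)[[1]]
    directed[[length(directed) + 1L]] <- e
    coefs[[e[2]]]$coefficients <- c(coefs[[e[2]]]$coefficients,
                                    stats::setNames(add_edges[[nm]], e[1]))
  }
  tab <- junctures:::canonical_node_table()
  node_specs <- stats::setNames(
    lapply(seq_len(nrow(tab)), function(i) {
      node_spec(tab[i, 1], tab[i, 2], tab[i, 3], tab[i, 4],
                dist = if (tab[i, 1] == "V2") "bernoulli" else "normal")
    }),
    tab[, 1])
  dag <- causal_dag(tab[, 1], directed = directed,
                    bidirected = list(c("Z2", "X2")))
  equations <- stats::setNames(
    lapply(names(coefs), function(child) {
      cf <- coefs[[child]]
      structural_equation(child, names(cf$coefficients), cf$intercept,
                          cf$coefficients, cf$link, cf$error_sd)
    }),
    names(coefs))
  juncture_model(dag, node_specs, equations, c("X2|Z2" = 0.5),
                 c(organizations = 40L, practitioners_per_organization = 5L,
                   patients_per_practitioner = 30L),
                 selection_node = "D1")
}

# zero out every structural coefficient (intercepts stay 0)
cbt_all_zero <- function() {
  ov <- lapply(junctures:::canonical_coefficients(), function(cf) {
    list(coefficients = cf$coefficients * 0)
  })
  ov$W <- NULL # keep the deterministic aggregate W = W1 + W2
  canonical_cbt_model(overrides = list(equations = ov))
}

# the main Monte Carlo study (default model, R = 1000): computed once per
# test run, shared by the bias-bound, variability and summary tests
mc_study_cache <- new.env()
mc_study <- function() {
  if (is.null(mc_study_cache$result)) {
    mc_study_cache$result <- run_mc(canonical_cbt_model(), reps = 1000,
                                    seed = 1)
  }
  mc_study_cache$result
}
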