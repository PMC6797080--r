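#' Population configuration for a simulation draw
#'
#' @param organizations,practitioners_per_organization,patients_per_practitioner
#'   positive integer hierarchy counts; defaults are taken from the model
#'   when `NULL` in [draw_population()].
#' @param seed integer seed fixing the entire draw.
#' @return an object of class `population_config`.
#' @export
population_config <- function(organizations = NULL,
                              practitioners_per_organization = NULL,
                              patients_per_practitioner = NULL,
                              seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop_input("population_config requires an integer seed")
  }
  structure(
    list(organizations = organizations,
         practitioners_per_organization = practitioners_per_organization,
         patients_per_practitioner = patients_per_practitioner,
         seed = as.integer(seed)),
    class = "population_config"
  )
}

level_rank <- c(organization = 1L, intervention = 1L, practitioner = 2L,
                patient = 3L)

# unit level at which a node's values are stored; "intervention" variables
# are organization-specific anticipations, so they live in the org table
node_unit_level <- function(model, id) {
  lv <- model$node_specs[[id]]$level
  if (lv == "intervention") "organization" else lv
}

#' Draw one hierarchical sample from a juncture model
#'
#' Samples all variables in topological order: exogenous nodes are drawn
#' from their declared family (standard normal, or Bernoulli(0.5)), with
#' each bidirected pair drawn jointly at the configured error correlation
#' (the finer-level member inherits the coarser-level member's value
#' scaled by the correlation, plus idiosyncratic noise, so e.g.
#' practitioner-level perceptions carry an organization-level shock).
#' Binary decisions are latent-utility thresholds `d = 1[index + e > 0]`
#' with standard-normal `e` (so probit is the correctly specified
#' estimator); linear nodes are `index + e` with `e ~ N(0, error_sd)`;
#' deterministic sums are computed exactly. Organization-level values are
#' replicated down to practitioner and patient rows as needed.
#'
#' Organizations with selection node (D1) equal to 0 do not participate in
#' subsequent junctures: their post-selection decisions and all
#' descendants of those decisions are marked missing-by-selection (`NA`)
#' in the returned tables, rather than their rows being dropped, so
#' negative-control analyses on the full table remain possible. All error
#' draws are retained (unmasked) for potential-outcome replay.
#'
#' @param model a [juncture_model()].
#' @param config a [population_config()]; hierarchy entries left `NULL`
#'   default to the model's.
#' @return An object of class `juncture_data`: list with data frames
#'   `organizations`, `practitioners`, `patients`, the retained `errors`
#'   (one numeric vector per stochastic endogenous node, at that node's
#'   unit level), `hierarchy`, `seed`, and `gated` (the nodes subject to
#'   selection masking).
#' @examples
#' m <- canonical_cbt_model()
#' d <- draw_population(m, population_config(seed = 1))
#' nrow(d$patients) # 6000
#' @export
draw_population <- function(model, config) {
  stopifnot(inherits(model, "juncture_model"))
  if (!inherits(config, "population_config")) {
    stop_input("config must be a population_config")
  }
  h <- model$hierarchy
  for (nm in names(h)) if (!is.null(config[[nm]])) h[[nm]] <- as.integer(config[[nm]])
  h <- validate_hierarchy(h)

  n_org <- h[["organizations"]]
  n_pr <- n_org * h[["practitioners_per_organization"]]
  n_pt <- n_pr * h[["patients_per_practitioner"]]
  org_of_pr <- rep(seq_len(n_org), each = h[["practitioners_per_organization"]])
  pr_of_pt <- rep(seq_len(n_pr), each = h[["patients_per_practitioner"]])
  org_of_pt <- org_of_pr[pr_of_pt]
  idx <- list(organization = seq_len(n_org), practitioner = org_of_pr,
              patient_pr = pr_of_pt, patient_org = org_of_pt)
  n_at <- c(organization = n_org, practitioner = n_pr, patient = n_pt)

  expand <- function(v, from, to) {
    if (from == to) return(v)
    if (from == "organization" && to == "practitioner") return(v[org_of_pr])
    if (from == "organization" && to == "patient") return(v[org_of_pt])
    if (from == "practitioner" && to == "patient") return(v[pr_of_pt])
    stop_input("parent varies at a finer level (", from,
               ") than its child (", to, ")")
  }

  set.seed(config$seed)
  values <- list()
  errors <- list()

  # bidirected pairs: finer member derived from coarser member + idiosyncrasy
  pair_of <- list()
  if (nrow(model$dag$bidirected)) {
    for (i in seq_len(nrow(model$dag$bidirected))) {
      a <- model$dag$bidirected[i, 1L]
      b <- model$dag$bidirected[i, 2L]
      if (length(model$parents[[a]]) || length(model$parents[[b]])) {
        stop_input("correlated errors are supported for exogenous node pairs ",
                   "only (", a, " <-> ", b, ")")
      }
      rho <- unname(model$correlated_errors[paste(a, b, sep = "|")])
      # draw the coarser-level member first
      if (level_rank[node_unit_level(model, b)] <
          level_rank[node_unit_level(model, a)]) {
        tmp <- a; a <- b; b <- tmp
      }
      pair_of[[b]] <- list(base = a, rho = rho)
    }
  }

  draw_exogenous <- function(id) {
    lv <- node_unit_level(model, id)
    n <- n_at[[lv]]
    spec <- model$node_specs[[id]]
    if (!is.null(pair_of[[id]])) {
      base <- pair_of[[id]]$base
      rho <- pair_of[[id]]$rho
      if (spec$dist != "normal" || model$node_specs[[base]]$dist != "normal") {
        stop_input("correlated errors require normal exogenous pairs")
      }
      if (is.null(values[[base]])) values[[base]] <<- draw_exogenous(base)
      bv <- expand(values[[base]], node_unit_level(model, base), lv)
      return(rho * bv + sqrt(1 - rho^2) * stats::rnorm(n))
    }
    switch(spec$dist,
           normal = stats::rnorm(n),
           bernoulli = as.numeric(stats::runif(n) < 0.5))
  }

  for (id in model$topo_order) {
    if (!is.null(values[[id]])) next # pair base drawn on demand
    lv <- node_unit_level(model, id)
    n <- n_at[[lv]]
    pa <- model$parents[[id]]
    if (!length(pa)) {
      values[[id]] <- draw_exogenous(id)
      next
    }
    eq <- model$equations[[id]]
    index <- rep(eq$intercept, n)
    for (p in pa) {
      index <- index +
        eq$coefficients[[p]] * expand(values[[p]], node_unit_level(model, p), lv)
    }
    if (any(!is.finite(index))) {
      stop_numeric("non-finite structural index in equation for ", id)
    }
    if (eq$link == "deterministic-sum") {
      values[[id]] <- index
    } else if (eq$link == "latent-utility-threshold") {
      eps <- stats::rnorm(n)
      errors[[id]] <- eps
      values[[id]] <- as.numeric(index + eps > 0)
    } else {
      eps <- stats::rnorm(n, sd = eq$error_sd)
      errors[[id]] <- eps
      values[[id]] <- index + eps
    }
  }

  gated <- selection_gated_nodes(model)
  sel_org <- values[[model$selection_node]] # organization level, 0/1
  masked <- values
  for (id in gated) {
    lv <- node_unit_level(model, id)
    keep <- expand(sel_org, "organization", lv) == 1
    masked[[id]][!keep] <- NA_real_
  }

  at_level <- function(lv) {
    ids <- model$topo_order[vapply(model$topo_order, node_unit_level,
                                   character(1), model = model) == lv]
    # stable column order: declaration order of the model's nodes
    ids[order(match(ids, model$dag$nodes))]
  }
  org_tab <- data.frame(org = seq_len(n_org))
  for (id in at_level("organization")) org_tab[[id]] <- masked[[id]]
  pr_tab <- data.frame(pract = seq_len(n_pr), org = org_of_pr)
  for (id in at_level("practitioner")) pr_tab[[id]] <- masked[[id]]
  pt_tab <- data.frame(patient = seq_len(n_pt), pract = pr_of_pt,
                       org = org_of_pt)
  for (id in at_level("patient")) pt_tab[[id]] <- masked[[id]]

  structure(
    list(organizations = org_tab, practitioners = pr_tab, patients = pt_tab,
         errors = errors, hierarchy = h, seed = config$seed, gated = gated,
         selection_node = model$selection_node, unmasked = values),
    class = "juncture_data"
  )
}

# decisions taken after the selection juncture, plus everything downstream
# of them, exist only in selected (D1 = 1) organizations
selection_gated_nodes <- function(model) {
  A <- expanded_adjacency(model$dag)
  sel <- model$selection_node
  anc_sel <- ancestors_of(A, sel)
  decisions <- names(Filter(function(s) s$kind == "binary-decision",
                            model$node_specs))
  post <- setdiff(decisions, c(sel, anc_sel))
  down <- unique(unlist(lapply(post, descendants_of, A = A)))
  intersect(model$dag$nodes, union(post, down))
}

#' @export
print.juncture_data <- function(x, ...) {
  n_impl <- sum(x$organizations[[x$selection_node]] == 1, na.rm = TRUE)
  cat("Simulated juncture dataset (seed ", x$seed, ")\n", sep = "")
  cat("  ", nrow(x$organizations), " organizations (", n_impl,
      " implementing), ", nrow(x$practitioners), " practitioners, ",
      nrow(x$patients), " patients\n", sep = "")
  cat("  selection-gated nodes:", paste(x$gated, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname draw_population
#' @param object a `juncture_model` (S3 `simulate` method).
#' @param nsim number of independent draws.
#' @param seed integer seed; draw `i` uses `seed + i - 1`.
#' @param ... ignored.
#' @return `simulate.juncture_model`: a list of `nsim` `juncture_data`
#'   objects (a single object when `nsim = 1`).
#' @export
simulate.juncture_model <- function(object, nsim = 1, seed = 1, ...) {
  out <- lapply(seq_len(nsim), function(i) {
    draw_population(object, population_config(seed = seed + i - 1))
  })
  if (nsim == 1) out[[1]] else out
}

# ---- potential-outcome replay ------------------------------------------

# Recompute all endogenous nodes from the retained errors, optionally
# forcing nodes to intervention values (scalar, or a vector at the node's
# unit level). Returns unmasked value vectors at each node's unit level.
# This is abduction-action-prediction: exogenous values and all error
# draws are held fixed at their factual realisations.
replay_structural <- function(model, data, intervene = list()) {
  if (is.null(data$errors) || is.null(data$unmasked)) {
    stop_contract("dataset does not carry retained errors; replay impossible")
  }
  h <- data$hierarchy
  n_org <- h[["organizations"]]
  n_pr <- n_org * h[["practitioners_per_organization"]]
  org_of_pr <- rep(seq_len(n_org), each = h[["practitioners_per_organization"]])
  pr_of_pt <- rep(seq_len(n_pr), each = h[["patients_per_practitioner"]])
  org_of_pt <- org_of_pr[pr_of_pt]
  expand <- function(v, from, to) {
    if (from == to) return(v)
    if (from == "organization" && to == "practitioner") return(v[org_of_pr])
    if (from == "organization" && to == "patient") return(v[org_of_pt])
    if (from == "practitioner" && to == "patient") return(v[pr_of_pt])
    stop_input("parent varies at a finer level than its child")
  }
  n_at <- c(organization = n_org, practitioner = n_pr,
            patient = n_pr * h[["patients_per_practitioner"]])

  values <- data$unmasked
  for (id in model$topo_order) {
    lv <- node_unit_level(model, id)
    if (!is.null(intervene[[id]])) {
      values[[id]] <- rep_len(as.numeric(intervene[[id]]), n_at[[lv]])
      next
    }
    pa <- model$parents[[id]]
    if (!length(pa)) next # exogenous: factual value retained
    eq <- model$equations[[id]]
    index <- rep(eq$intercept, n_at[[lv]])
    for (p in pa) {
      index <- index +
        eq$coefficients[[p]] * expand(values[[p]], node_unit_level(model, p), lv)
    }
    values[[id]] <- switch(eq$link,
      "deterministic-sum" = index,
      "latent-utility-threshold" = as.numeric(index + data$errors[[id]] > 0),
      index + data$errors[[id]]
    )
  }
  values
}

# linear predictor of a decision node at the factual (or replayed) values
node_index <- function(model, data, id, values = NULL) {
  if (is.null(values)) values <- replay_structural(model, data)
  lv <- node_unit_level(model, id)
  h <- data$hierarchy
  n_org <- h[["organizations"]]
  n_pr <- n_org * h[["practitioners_per_organization"]]
  org_of_pr <- rep(seq_len(n_org), each = h[["practitioners_per_organization"]])
  pr_of_pt <- rep(seq_len(n_pr), each = h[["patients_per_practitioner"]])
  org_of_pt <- org_of_pr[pr_of_pt]
  expand <- function(v, from, to) {
    if (from == to) return(v)
    if (from == "organization" && to == "practitioner") return(v[org_of_pr])
    if (from == "organization" && to == "patient") return(v[org_of_pt])
    if (from == "practitioner" && to == "patient") return(v[pr_of_pt])
    stop_input("parent varies at a finer level than its child")
  }
  eq <- model$equations[[id]]
  n <- switch(lv, organization = n_org, practitioner = n_pr,
              patient = n_pr * h[["patients_per_practitioner"]])
  index <- rep(eq$intercept, n)
  for (p in eq$parents) {
    index <- index +
      eq$coefficients[[p]] * expand(values[[p]], node_unit_level(model, p), lv)
  }
  index
}

#' Sample-specific true effects by potential-outcome replay
#'
#' Computes, for the drawn sample and with all error draws held fixed
#' (abduction-action-prediction), the true values of the five estimands of
#' the CBT system over their eligible (selected, D1 = 1) populations:
#' \describe{
#'   \item{ate_D2_X4, ate_D2_X5}{mean over practitioners in implementing
#'     organizations of `X4(D2 := 1) - X4(D2 := 0)` (resp. X5); for linear
#'     children this equals the structural coefficient exactly.}
#'   \item{ame_X4_T1, ame_X5_T1}{average marginal effect of feasibility
#'     (resp. appropriateness) on the treatment-assignment probability:
#'     mean over eligible patients of `dnorm(index) * coefficient`, the
#'     derivative of the threshold-crossing probability at the observed
#'     covariates.}
#'   \item{ate_T1_Y2}{mean over eligible patients of
#'     `Y2(T1 := 1) - Y2(T1 := 0)`.}
#' }
#'
#' @param model a [juncture_model()].
#' @param data a [draw_population()] result carrying retained errors.
#' @return named numeric vector of the five true sample effects.
#' @export
true_sample_effects <- function(model, data) {
  stopifnot(inherits(model, "juncture_model"), inherits(data, "juncture_data"))
  if (is.null(data$errors)) {
    stop_contract("dataset does not carry retained errors")
  }
  h <- data$hierarchy
  sel <- data$unmasked[[model$selection_node]] == 1
  sel_pr <- rep(sel, each = h[["practitioners_per_organization"]])
  sel_pt <- rep(sel_pr, each = h[["patients_per_practitioner"]])

  v1 <- replay_structural(model, data, intervene = list(D2 = 1))
  v0 <- replay_structural(model, data, intervene = list(D2 = 0))
  ate_D2_X4 <- mean((v1$X4 - v0$X4)[sel_pr])
  ate_D2_X5 <- mean((v1$X5 - v0$X5)[sel_pr])

  idx <- node_index(model, data, "T1", values = data$unmasked)
  ame_X4_T1 <- mean(stats::dnorm(idx[sel_pt])) * model$equations$T1$coefficients[["X4"]]
  ame_X5_T1 <- mean(stats::dnorm(idx[sel_pt])) * model$equations$T1$coefficients[["X5"]]

  w1 <- replay_structural(model, data, intervene = list(T1 = 1))
  w0 <- replay_structural(model, data, intervene = list(T1 = 0))
  ate_T1_Y2 <- mean((w1$Y2 - w0$Y2)[sel_pt])

  out <- c(ate_D2_X4 = ate_D2_X4, ate_D2_X5 = ate_D2_X5,
           ame_X4_T1 = ame_X4_T1, ame_X5_T1 = ame_X5_T1,
           ate_T1_Y2 = ate_T1_Y2)
  if (any(!is.finite(out))) stop_numeric("non-finite true sample effect")
  out
}
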