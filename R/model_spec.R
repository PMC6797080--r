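#' @importFrom stats setNames
NULL

NODE_LEVELS <- c("organization", "practitioner", "patient", "intervention")
NODE_KINDS <- c("continuous", "binary-decision", "deterministic-aggregate")
EQ_LINKS <- c("linear", "latent-utility-threshold", "deterministic-sum")

#' Node metadata for a juncture model
#'
#' @param id node identifier (must match a DAG node).
#' @param level hierarchy level the variable varies at: `"organization"`,
#'   `"practitioner"`, `"patient"`, or `"intervention"` (strategy-specific
#'   quantities anticipated by each organization; stored with the
#'   organization rows).
#' @param kind `"continuous"`, `"binary-decision"` (a latent-utility
#'   juncture), or `"deterministic-aggregate"`.
#' @param label free-text description.
#' @param dist sampling family when the node is exogenous: `"normal"`
#'   (standard normal) or `"bernoulli"` (p = 0.5); ignored for endogenous
#'   nodes.
#' @return a `node_spec` list.
#' @export
node_spec <- function(id, level, kind, label = "", dist = "normal") {
  if (!level %in% NODE_LEVELS) stop_input("unknown level '", level, "' for node ", id)
  if (!kind %in% NODE_KINDS) stop_input("unknown kind '", kind, "' for node ", id)
  if (!dist %in% c("normal", "bernoulli")) {
    stop_input("unknown exogenous distribution '", dist, "' for node ", id)
  }
  list(id = id, level = level, kind = kind, label = label, dist = dist)
}

#' Structural equation of one endogenous node
#'
#' The child's value is `intercept + sum(coefficients * parents)` plus a
#' normal error: thresholded at zero for `"latent-utility-threshold"`
#' decisions (error sd fixed to 1, the probit normalisation), added
#' directly for `"linear"` nodes, or omitted for `"deterministic-sum"`
#' aggregates (error sd fixed to 0).
#'
#' @param child node id.
#' @param parents character vector, exactly the child's DAG parents.
#' @param intercept numeric.
#' @param coefficients one numeric per parent, in `parents` order.
#' @param link `"linear"`, `"latent-utility-threshold"` or
#'   `"deterministic-sum"`.
#' @param error_sd nonnegative error standard deviation (linear links).
#' @return a `structural_equation` list.
#' @export
structural_equation <- function(child, parents, intercept, coefficients,
                                link, error_sd = 1) {
  parents <- as.character(parents)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != length(parents)) {
    stop_input("equation for ", child, ": need one coefficient per parent")
  }
  if (!link %in% EQ_LINKS) stop_input("equation for ", child, ": unknown link '", link, "'")
  if (!is.finite(intercept)) stop_input("equation for ", child, ": non-finite intercept")
  if (any(!is.finite(coefficients))) {
    stop_input("equation for ", child, ": non-finite coefficient")
  }
  if (link == "latent-utility-threshold") error_sd <- 1
  if (link == "deterministic-sum") error_sd <- 0
  if (!is.finite(error_sd) || error_sd < 0) {
    stop_input("equation for ", child, ": error_sd must be nonnegative")
  }
  list(child = child, parents = parents, intercept = intercept,
       coefficients = setNames(coefficients, parents),
       link = link, error_sd = error_sd)
}

#' Assemble a multilevel decision-juncture model
#'
#' Couples a [causal_dag()] with node metadata (hierarchy level and
#' variable kind), one structural equation per endogenous node, error
#' correlations for the bidirected edges, the hierarchy sizes and the
#' selection node, and validates their mutual consistency. Exogenous nodes
#' (no parents, no equation) are drawn standard normal unless their spec
#' says otherwise in [draw_population()].
#'
#' @param dag a [causal_dag()].
#' @param node_specs named list: per node id a list with `level`, `kind`
#'   and optional `label`.
#' @param equations named list of structural equations (child, parents,
#'   intercept, coefficients, link, error_sd).
#' @param correlated_errors named numeric vector, one entry per bidirected
#'   edge keyed `"A|B"` (canonical order), values in (-1, 1).
#' @param hierarchy named integer vector or list with `organizations`,
#'   `practitioners_per_organization`, `patients_per_practitioner`.
#' @param selection_node node id of the decision gating all downstream
#'   participation (must be a binary-decision node).
#' @return An object of class `juncture_model`.
#' @seealso [canonical_cbt_model()] for the built-in CBT implementation
#'   system.
#' @export
juncture_model <- function(dag, node_specs, equations, correlated_errors,
                           hierarchy, selection_node) {
  stopifnot(inherits(dag, "causal_dag"))
  if (!setequal(names(node_specs), dag$nodes)) {
    stop_input("node_specs must cover exactly the DAG nodes")
  }
  A <- dag_adjacency(dag)
  parents <- lapply(setNames(dag$nodes, dag$nodes),
                    function(v) rownames(A)[A[, v]])
  endo <- dag$nodes[lengths(parents) > 0]
  if (!setequal(names(equations), endo)) {
    stop_input("need exactly one equation per non-exogenous node; missing: ",
               paste(setdiff(endo, names(equations)), collapse = ", "),
               "; extra: ",
               paste(setdiff(names(equations), endo), collapse = ", "))
  }
  for (v in endo) {
    eq <- equations[[v]]
    if (!setequal(eq$parents, parents[[v]])) {
      stop_input("equation parents for ", v, " do not match DAG parents")
    }
    kind <- node_specs[[v]]$kind
    if (eq$link == "latent-utility-threshold" && kind != "binary-decision") {
      stop_input("latent-utility-threshold child ", v, " must be a binary-decision node")
    }
    if (eq$link == "linear" && kind != "continuous") {
      stop_input("linear child ", v, " must be a continuous node")
    }
  }
  bkeys <- if (nrow(dag$bidirected)) {
    paste(dag$bidirected[, 1L], dag$bidirected[, 2L], sep = "|")
  } else character(0)
  if (!setequal(names(correlated_errors), bkeys)) {
    stop_input("correlated_errors keys must equal the bidirected edge set")
  }
  if (length(correlated_errors) &&
      any(abs(as.numeric(correlated_errors)) >= 1)) {
    stop_input("error correlations must lie strictly inside (-1, 1)")
  }
  hierarchy <- validate_hierarchy(hierarchy)
  if (!selection_node %in% dag$nodes ||
      node_specs[[selection_node]]$kind != "binary-decision") {
    stop_input("selection_node must be a binary-decision node of the DAG")
  }
  structure(
    list(dag = dag, node_specs = node_specs, equations = equations,
         correlated_errors = unlist(correlated_errors)[bkeys],
         hierarchy = hierarchy, selection_node = selection_node,
         parents = parents,
         topo_order = topological_order(A)),
    class = "juncture_model"
  )
}

validate_hierarchy <- function(hierarchy) {
  need <- c("organizations", "practitioners_per_organization",
            "patients_per_practitioner")
  hierarchy <- unlist(hierarchy)
  if (!all(need %in% names(hierarchy))) {
    stop_input("hierarchy needs counts: ", paste(need, collapse = ", "))
  }
  hierarchy <- hierarchy[need]
  if (any(hierarchy != round(hierarchy)) || any(hierarchy < 1)) {
    stop_input("hierarchy counts must be positive integers")
  }
  storage.mode(hierarchy) <- "integer"
  hierarchy
}

topological_order <- function(A) {
  n <- nrow(A)
  indeg <- colSums(A)
  out <- character(0)
  avail <- sort(colnames(A)[indeg == 0])
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    ch <- colnames(A)[A[v, ]]
    indeg[ch] <- indeg[ch] - 1L
    avail <- sort(c(avail, ch[indeg[ch] == 0]))
  }
  if (length(out) != n) stop_structural("cycle detected in topological sort")
  out
}

#' Total number of patients implied by the hierarchy
#' @param model a `juncture_model`.
#' @return integer: organizations x practitioners/org x patients/practitioner.
#' @export
total_patients <- function(model) {
  stopifnot(inherits(model, "juncture_model"))
  prod(model$hierarchy)
}

#' @export
print.juncture_model <- function(x, ...) {
  h <- x$hierarchy
  cat("Multilevel decision-juncture model\n")
  cat("  ", length(x$dag$nodes), " nodes, ", nrow(x$dag$directed),
      " directed edges, ", nrow(x$dag$bidirected), " bidirected\n", sep = "")
  cat("  hierarchy: ", h[["organizations"]], " organizations x ",
      h[["practitioners_per_organization"]], " practitioners x ",
      h[["patients_per_practitioner"]], " patients = ",
      prod(h), " patients\n", sep = "")
  cat("  selection node:", x$selection_node, "\n")
  invisible(x)
}

# ---- the canonical CBT implementation system ---------------------------

canonical_node_table <- function() {
  # id, level, kind, label
  rbind(
    c("Z1", "organization", "continuous", "intra-organizational networks"),
    c("Z2", "organization", "continuous", "management style"),
    c("Z3", "organization", "continuous", "organizational structure"),
    c("B1", "organization", "continuous", "empirical evidence of effectiveness"),
    c("W1", "intervention", "continuous", "anticipated cost, standard strategy"),
    c("W2", "intervention", "continuous", "anticipated cost, enhanced strategy"),
    c("W",  "intervention", "deterministic-aggregate", "aggregate cost"),
    c("D1", "organization", "binary-decision", "organization adopts CBT"),
    c("D2", "organization", "binary-decision", "enhanced implementation strategy"),
    c("X1", "practitioner", "continuous", "practitioner age"),
    c("X2", "practitioner", "continuous", "perceived leadership"),
    c("X3", "practitioner", "continuous", "tenure in current job"),
    c("X4", "practitioner", "continuous", "perceived feasibility"),
    c("X5", "practitioner", "continuous", "perceived appropriateness"),
    c("V1", "patient", "continuous", "patient age"),
    c("V2", "patient", "continuous", "patient gender"),
    c("V3", "patient", "continuous", "socio-economic status"),
    c("Y1", "patient", "continuous", "baseline outcome score"),
    c("T1", "patient", "binary-decision", "practitioner assigns treatment"),
    c("Y2", "patient", "continuous", "follow-up outcome score")
  )
}

canonical_directed_edges <- function() {
  list(
    c("Z1", "D1"), c("Z2", "D1"), c("Z3", "D1"), c("B1", "D1"), c("W", "D1"),
    c("W1", "W"), c("W2", "W"),
    c("Z1", "D2"), c("Z2", "D2"), c("B1", "D2"), c("W1", "D2"), c("W2", "D2"),
    c("D2", "X4"), c("D2", "X5"),
    c("Z1", "X4"), c("Z1", "X5"),
    c("X1", "X4"), c("X1", "X5"),
    c("X2", "X4"), c("X2", "X5"),
    c("Z1", "T1"), c("X2", "T1"), c("X3", "T1"), c("X4", "T1"), c("X5", "T1"),
    c("V1", "T1"), c("V2", "T1"), c("Y1", "T1"),
    c("V3", "Y1"),
    c("T1", "Y2"), c("V1", "Y2"), c("V2", "Y2"), c("V3", "Y2"), c("Y1", "Y2")
  )
}

canonical_coefficients <- function() {
  # child -> list(intercept, coefficients (named by parent), link, error_sd)
  list(
    W  = list(intercept = 0, coefficients = c(W1 = 1, W2 = 1),
              link = "deterministic-sum", error_sd = 0),
    D1 = list(intercept = 0,
              coefficients = c(Z1 = 0.4, Z2 = 0.3, Z3 = 0.3, B1 = 0.4, W = -0.3),
              link = "latent-utility-threshold", error_sd = 1),
    D2 = list(intercept = 0,
              coefficients = c(Z1 = 0.3, Z2 = 0.3, B1 = 0.3, W1 = 0.3, W2 = -0.3),
              link = "latent-utility-threshold", error_sd = 1),
    X4 = list(intercept = 0,
              coefficients = c(D2 = 0.5, Z1 = 0.3, X1 = 0.3, X2 = 0.3),
              link = "linear", error_sd = 1),
    X5 = list(intercept = 0,
              coefficients = c(D2 = 0.5, Z1 = 0.3, X1 = 0.3, X2 = 0.3),
              link = "linear", error_sd = 1),
    Y1 = list(intercept = 0, coefficients = c(V3 = 0.3),
              link = "linear", error_sd = 1),
    T1 = list(intercept = 0,
              coefficients = c(X4 = 0.4, X5 = 0.3, Z1 = 0.3, X2 = 0.3,
                               X3 = 0.3, V1 = 0.3, V2 = 0.3, Y1 = 0.3),
              link = "latent-utility-threshold", error_sd = 1),
    Y2 = list(intercept = 0,
              coefficients = c(T1 = 1.0, V1 = 0.3, V2 = 0.3, V3 = 0.3, Y1 = 0.5),
              link = "linear", error_sd = 1)
  )
}

#' The canonical CBT implementation system
#'
#' Returns the built-in model of a hypothetical cognitive behavioural
#' therapy (CBT) implementation system: 40 organizations each employing 5
#' practitioners who each treat 30 patients (6000 patients in total).
#' Organizations observe their context (networks Z1, management style Z2,
#' structure Z3, evidence B1, strategy costs W1/W2 aggregated into W) and
#' decide whether to adopt CBT (D1, the selection juncture) and, if so,
#' whether to use an enhanced implementation strategy (D2). The strategy
#' shapes practitioners' perceived feasibility (X4) and appropriateness
#' (X5), which drive the practitioner's per-patient treatment-assignment
#' decision (T1), which in turn moves the follow-up outcome score (Y2)
#' given baseline severity (Y1) and case mix (V1-V3). Management style and
#' perceived leadership share a correlated error (Z2 <-> X2).
#'
#' All decisions are probit-consistent latent-utility thresholds
#' (`d = 1[index + e > 0]`, e standard normal); continuous nodes are linear
#' with normal errors; W is the deterministic sum W1 + W2.
#'
#' @param overrides optional named list. Recognised entries:
#'   `hierarchy` (see [juncture_model()]), `correlated_errors`, and
#'   per-node coefficient overrides as `equations = list(<child> =
#'   list(intercept = , coefficients = c(parent = value, ...), error_sd = ))`
#'   which are merged into the defaults (parents cannot be added or
#'   removed this way).
#' @return a [juncture_model()].
#' @examples
#' m <- canonical_cbt_model()
#' total_patients(m) # 6000
#' @export
canonical_cbt_model <- function(overrides = NULL) {
  tab <- canonical_node_table()
  node_specs <- setNames(
    lapply(seq_len(nrow(tab)), function(i) {
      node_spec(tab[i, 1], tab[i, 2], tab[i, 3], tab[i, 4],
                    dist = if (tab[i, 1] == "V2") "bernoulli" else "normal")
    }),
    tab[, 1]
  )
  dag <- causal_dag(tab[, 1],
                    directed = canonical_directed_edges(),
                    bidirected = list(c("Z2", "X2")))
  coefs <- canonical_coefficients()
  hierarchy <- c(organizations = 40L, practitioners_per_organization = 5L,
                 patients_per_practitioner = 30L)
  correlated_errors <- c("X2|Z2" = 0.5)

  if (!is.null(overrides)) {
    if (!is.list(overrides)) stop_input("overrides must be a named list")
    bad <- setdiff(names(overrides),
                   c("hierarchy", "correlated_errors", "equations"))
    if (length(bad)) stop_input("unknown override(s): ", paste(bad, collapse = ", "))
    if (!is.null(overrides$hierarchy)) {
      hierarchy <- validate_hierarchy(overrides$hierarchy)
    }
    if (!is.null(overrides$correlated_errors)) {
      ce <- unlist(overrides$correlated_errors)
      unknown <- setdiff(names(ce), names(correlated_errors))
      if (length(unknown)) stop_input("no such bidirected edge: ", unknown[1])
      correlated_errors[names(ce)] <- ce
    }
    for (child in names(overrides$equations)) {
      if (!child %in% names(coefs)) {
        stop_input("equation override for non-endogenous node ", child)
      }
      ov <- overrides$equations[[child]]
      if (!is.null(ov$intercept)) coefs[[child]]$intercept <- ov$intercept
      if (!is.null(ov$error_sd)) coefs[[child]]$error_sd <- ov$error_sd
      if (!is.null(ov$coefficients)) {
        unknown <- setdiff(names(ov$coefficients),
                           names(coefs[[child]]$coefficients))
        if (length(unknown)) {
          stop_input(child, ": override references non-parent ",
                     paste(unknown, collapse = ", "))
        }
        coefs[[child]]$coefficients[names(ov$coefficients)] <- ov$coefficients
      }
    }
  }

  equations <- setNames(
    lapply(names(coefs), function(child) {
      cf <- coefs[[child]]
      structural_equation(child, names(cf$coefficients), cf$intercept,
                              cf$coefficients, cf$link, cf$error_sd)
    }),
    names(coefs)
  )
  juncture_model(dag, node_specs, equations, correlated_errors,
                 hierarchy, selection_node = "D1")
}

# ---- identification claims ---------------------------------------------

#' Certify the model against its identification claims
#'
#' Runs every identification statement the canonical CBT system is built
#' to satisfy against the model's DAG, always conditioning on the
#' selection node:
#' \describe{
#'   \item{a}{`{Z1, X2}` is a valid back-door set for D2 -> X4 and for
#'     D2 -> X5.}
#'   \item{b}{`{Z1, X2, X5}` is valid for X4 -> T1.}
#'   \item{c}{the symmetric set `{Z1, X2, X4}` is valid for X5 -> T1.}
#'   \item{d}{`{V1, V2, Y1}` is valid for T1 -> Y2.}
#'   \item{e}{X3, V1, V2 and Y1 are pure precision covariates for
#'     X4 -> T1: none is a member of any inclusion-minimal adjustment
#'     set.}
#' }
#' The minimal adjustment sets found for each estimand are attached so a
#' user can inspect whether a quoted set is also minimal, rather than
#' assuming it.
#'
#' @param model a [juncture_model()].
#' @return An object of class `claim_report`: a data frame with columns
#'   `claim`, `description`, `pass`, plus attribute `minimal_sets` (named
#'   list per estimand).
#' @export
validate_claims <- function(model) {
  stopifnot(inherits(model, "juncture_model"))
  dag <- model$dag
  sel <- model$selection_node
  bd <- function(t, o, z) is_valid_backdoor(dag, t, o, z, selection = sel)
  ms <- list(
    "D2->X4" = minimal_adjustment_sets(dag, "D2", "X4", selection = sel),
    "D2->X5" = minimal_adjustment_sets(dag, "D2", "X5", selection = sel),
    "X4->T1" = minimal_adjustment_sets(dag, "X4", "T1", selection = sel),
    "X5->T1" = minimal_adjustment_sets(dag, "X5", "T1", selection = sel),
    "T1->Y2" = minimal_adjustment_sets(dag, "T1", "Y2", selection = sel)
  )
  in_any_minimal <- function(est, node) {
    any(vapply(ms[[est]], function(s) node %in% s, logical(1)))
  }
  rows <- list(
    list(claim = "a", description = "{Z1,X2} valid for D2->X4 and D2->X5",
         pass = bd("D2", "X4", c("Z1", "X2")) && bd("D2", "X5", c("Z1", "X2"))),
    list(claim = "b", description = "{Z1,X2,X5} valid for X4->T1",
         pass = bd("X4", "T1", c("Z1", "X2", "X5"))),
    list(claim = "c", description = "{Z1,X2,X4} valid for X5->T1",
         pass = bd("X5", "T1", c("Z1", "X2", "X4"))),
    list(claim = "d", description = "{V1,V2,Y1} valid for T1->Y2",
         pass = bd("T1", "Y2", c("V1", "V2", "Y1"))),
    list(claim = "e",
         description = "X3,V1,V2,Y1 are precision-only for X4->T1 (in no minimal set)",
         pass = !any(vapply(c("X3", "V1", "V2", "Y1"),
                            function(v) in_any_minimal("X4->T1", v),
                            logical(1))))
  )
  rep <- do.call(rbind, lapply(rows, as.data.frame))
  attr(rep, "minimal_sets") <- ms
  class(rep) <- c("claim_report", "data.frame")
  rep
}

#' @export
print.claim_report <- function(x, ...) {
  cat("Identification claim report (", sum(x$pass), "/", nrow(x),
      " pass)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %-65s %s\n", x$claim[i], x$description[i],
                if (x$pass[i]) "PASS" else "FAIL"))
  }
  ms <- attr(x, "minimal_sets")
  cat("Minimal adjustment sets (selection node conditioned):\n")
  for (est in names(ms)) {
    sets <- vapply(ms[[est]], function(s) {
      if (!length(s)) "{}" else paste0("{", paste(s, collapse = ","), "}")
    }, character(1))
    cat("  ", est, ": ", paste(sets, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
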