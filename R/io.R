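# Plain-text serialization: DAG edge lists, model files, dataset bundles.

#' Read and write causal DAGs
#'
#' Two interchangeable formats, chosen by file extension: a plain-text
#' edge list (one record per line, `A -> B` for directed edges,
#' `A <-> B` for bidirected edges, a bare node id for isolated nodes) and
#' a JSON equivalent with fields `nodes`, `directed`, `bidirected`.
#' Round trips are lossless.
#'
#' @param dag a [causal_dag()].
#' @param path file path; `.json` selects JSON, anything else the edge
#'   list.
#' @return `read_dag` returns a [causal_dag()]; `write_dag` returns
#'   `path` invisibly.
#' @export
write_dag <- function(dag, path) {
  stopifnot(inherits(dag, "causal_dag"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(nodes = dag$nodes,
           directed = apply(dag$directed, 1L, identity, simplify = FALSE),
           bidirected = apply(dag$bidirected, 1L, identity, simplify = FALSE)),
      path, auto_unbox = FALSE, pretty = TRUE)
  } else {
    used <- unique(c(dag$directed, dag$bidirected))
    lines <- c(
      setdiff(dag$nodes, used), # isolated nodes, one per line
      if (nrow(dag$directed)) paste(dag$directed[, 1L], "->", dag$directed[, 2L]),
      if (nrow(dag$bidirected)) paste(dag$bidirected[, 1L], "<->", dag$bidirected[, 2L])
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_dag
#' @export
read_dag <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
    to_pairs <- function(x) lapply(x, as.character)
    return(causal_dag(as.character(obj$nodes),
                      directed = to_pairs(obj$directed),
                      bidirected = to_pairs(obj$bidirected)))
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bid <- grepl("<->", lines, fixed = TRUE)
  dir <- !bid & grepl("->", lines, fixed = TRUE)
  iso <- !bid & !dir
  split_pair <- function(s, sep) {
    parts <- trimws(strsplit(s, sep, fixed = TRUE)[[1L]])
    if (length(parts) != 2L || !all(nzchar(parts))) {
      stop_input("malformed edge record: '", s, "'")
    }
    parts
  }
  directed <- lapply(lines[dir], split_pair, sep = "->")
  bidirected <- lapply(lines[bid], split_pair, sep = "<->")
  nodes <- unique(c(lines[iso], unlist(directed), unlist(bidirected)))
  causal_dag(nodes, directed = directed, bidirected = bidirected)
}

# ---- model files --------------------------------------------------------

model_to_list <- function(model) {
  list(
    nodes = lapply(model$dag$nodes, function(id) model$node_specs[[id]]),
    directed = apply(model$dag$directed, 1L, identity, simplify = FALSE),
    bidirected = apply(model$dag$bidirected, 1L, identity, simplify = FALSE),
    equations = lapply(unname(model$equations), function(eq) {
      list(child = eq$child, parents = eq$parents,
           intercept = eq$intercept,
           coefficients = as.numeric(eq$coefficients),
           link = eq$link, error_sd = eq$error_sd)
    }),
    correlated_errors = as.list(model$correlated_errors),
    hierarchy = as.list(model$hierarchy),
    selection_node = model$selection_node
  )
}

list_to_model <- function(obj) {
  need <- c("nodes", "directed", "equations", "hierarchy", "selection_node")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    stop_input("model file missing section(s): ", paste(missing, collapse = ", "))
  }
  node_specs <- list()
  for (ns in obj$nodes) {
    for (f in c("id", "level", "kind")) {
      if (is.null(ns[[f]])) stop_input("nodes[].", f, " is required")
    }
    node_specs[[ns$id]] <- node_spec(ns$id, ns$level, ns$kind,
                                         ns$label %||% "",
                                         ns$dist %||% "normal")
  }
  dag <- causal_dag(names(node_specs),
                    directed = lapply(obj$directed, as.character),
                    bidirected = lapply(obj$bidirected %||% list(), as.character))
  equations <- list()
  for (eq in obj$equations) {
    for (f in c("child", "parents", "intercept", "coefficients", "link")) {
      if (is.null(eq[[f]])) {
        stop_input("equations[", eq$child %||% "?", "].", f, " is required")
      }
    }
    parents <- as.character(unlist(eq$parents))
    unknown <- setdiff(parents, dag$nodes)
    if (length(unknown)) {
      stop_input("equations[", eq$child, "].parents references undeclared node ",
                 paste(unknown, collapse = ", "))
    }
    equations[[eq$child]] <- structural_equation(
      eq$child, parents, as.numeric(eq$intercept),
      as.numeric(unlist(eq$coefficients)), eq$link,
      as.numeric(eq$error_sd %||% 1))
  }
  juncture_model(dag, node_specs, equations,
                 lapply(obj$correlated_errors %||% list(), as.numeric),
                 obj$hierarchy, obj$selection_node)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write juncture models
#'
#' Serializes the full model (node specs, edges, structural equations,
#' error correlations, hierarchy, selection node) to JSON (`.json`) or
#' YAML (`.yml`/`.yaml`); round trips are lossless. Schema violations
#' raise an input error naming the offending field.
#'
#' @param model a [juncture_model()].
#' @param path file path ending in `.json`, `.yml` or `.yaml`.
#' @return `read_model` returns a [juncture_model()]; `write_model`
#'   returns `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "juncture_model"))
  obj <- model_to_list(model)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 15)
  } else {
    stop_input("unsupported model file extension: ", path)
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop_input("unsupported model file extension: ", path)
  }
  list_to_model(obj)
}

# ---- dataset bundles ----------------------------------------------------

#' Read and write simulated dataset bundles
#'
#' A dataset is persisted as a directory holding three CSV tables
#' (`organizations.csv`, `practitioners.csv`, `patients.csv`) and a JSON
#' manifest. Selection-missing cells are written as empty fields. Retained
#' error draws are stored as `eps_` columns and the pre-masking values of
#' selection-gated nodes as `full_` columns, so potential-outcome replay
#' survives a round trip. Values round-trip losslessly to at least 12
#' significant digits.
#'
#' @param data a [draw_population()] result.
#' @param path directory path (created if needed).
#' @return `read_dataset` returns a `juncture_data`; `write_dataset`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "juncture_data"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tables <- list(organizations = data$organizations,
                 practitioners = data$practitioners,
                 patients = data$patients)
  n_row <- vapply(tables, nrow, integer(1))
  level_of <- c(organizations = nrow(data$organizations),
                practitioners = nrow(data$practitioners),
                patients = nrow(data$patients))
  aug <- function(tab, which) {
    for (id in names(data$errors)) {
      if (length(data$errors[[id]]) == level_of[[which]] &&
          id %in% names(tab)) {
        tab[[paste0("eps_", id)]] <- data$errors[[id]]
      }
    }
    for (id in data$gated) {
      if (id %in% names(tab)) {
        tab[[paste0("full_", id)]] <- data$unmasked[[id]]
      }
    }
    tab
  }
  for (nm in names(tables)) {
    utils::write.csv(aug(tables[[nm]], nm),
                     file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  manifest <- list(
    format = "juncture_data_bundle",
    hierarchy = as.list(data$hierarchy),
    seed = data$seed,
    selection_node = data$selection_node,
    gated = data$gated,
    error_nodes = names(data$errors),
    tables = lapply(names(tables), function(nm) {
      list(name = nm, rows = n_row[[nm]], columns = names(tables[[nm]]))
    })
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop_input("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  tabs <- list()
  for (t in manifest$tables) {
    f <- file.path(path, paste0(t$name, ".csv"))
    if (!file.exists(f)) stop_input("bundle table missing: ", f)
    tab <- utils::read.csv(f, na.strings = "")
    # an all-missing (fully selection-masked) column must stay numeric
    tab[] <- lapply(tab, function(col) if (is.logical(col)) as.numeric(col) else col)
    if (nrow(tab) != t$rows) {
      stop_input("table ", t$name, ": ", nrow(tab), " rows but manifest says ",
                 t$rows)
    }
    missing_cols <- setdiff(unlist(t$columns), names(tab))
    if (length(missing_cols)) {
      stop_input("table ", t$name, " missing column(s): ",
                 paste(missing_cols, collapse = ", "))
    }
    tabs[[t$name]] <- tab
  }
  org <- tabs$organizations
  pr <- tabs$practitioners
  pt <- tabs$patients
  if (!all(pr$org %in% org$org)) {
    stop_input("practitioner table references unknown organization(s)")
  }
  if (!all(pt$pract %in% pr$pract) || !all(pt$org %in% org$org)) {
    stop_input("patient table references unknown practitioner or organization")
  }

  strip <- function(tab) tab[, !grepl("^(eps|full)_", names(tab)), drop = FALSE]
  errors <- list()
  unmasked <- list()
  collect <- function(tab) {
    for (nm in names(tab)) {
      if (startsWith(nm, "eps_")) errors[[sub("^eps_", "", nm)]] <<- tab[[nm]]
      if (startsWith(nm, "full_")) unmasked[[sub("^full_", "", nm)]] <<- tab[[nm]]
    }
    for (nm in setdiff(names(tab), c("org", "pract", "patient"))) {
      if (!grepl("^(eps|full)_", nm) && !nm %in% manifest$gated) {
        unmasked[[nm]] <<- tab[[nm]]
      }
    }
  }
  collect(org); collect(pr); collect(pt)
  missing_err <- setdiff(manifest$error_nodes, names(errors))
  if (length(missing_err)) {
    stop_input("bundle lacks retained errors for: ",
               paste(missing_err, collapse = ", "))
  }
  structure(
    list(organizations = strip(org), practitioners = strip(pr),
         patients = strip(pt),
         errors = errors[manifest$error_nodes],
         hierarchy = validate_hierarchy(manifest$hierarchy),
         seed = manifest$seed,
         gated = as.character(manifest$gated),
         selection_node = manifest$selection_node,
         unmasked = unmasked),
    class = "juncture_data"
  )
}
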