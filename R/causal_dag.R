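#' Construct a causal DAG with directed and bidirected edges
#'
#' Builds a structural causal graph in the acyclic directed mixed graph
#' (ADMG) sense: solid directed edges encode direct causal effects, dashed
#' bidirected edges encode unobserved correlated errors between two
#' variables. Bidirected edges are interpreted everywhere in the package as
#' a hidden common parent of the two endpoints.
#'
#' @param nodes character vector of unique node identifiers.
#' @param directed list of length-2 character vectors (or a 2-column
#'   matrix), each a `(parent, child)` pair.
#' @param bidirected list of length-2 character vectors (or a 2-column
#'   matrix), each an unordered pair carrying correlated errors. Pairs are
#'   canonicalized (sorted within pair) and deduplicated.
#' @return An object of class `causal_dag` with components `nodes`,
#'   `directed` (2-column character matrix, columns `from`/`to`) and
#'   `bidirected` (2-column character matrix, canonical order).
#' @examples
#' g <- causal_dag(c("A", "B", "C"), directed = list(c("A", "B"), c("B", "C")))
#' d_separated(g, "A", "C", "B")
#' @export
causal_dag <- function(nodes, directed = list(), bidirected = list()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop_input("duplicate node ids: ",
               paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (any(!nzchar(nodes))) stop_input("empty node id")

  directed <- as_edge_matrix(directed, "directed")
  bidirected <- as_edge_matrix(bidirected, "bidirected")

  endpoints <- c(directed, bidirected)
  unknown <- setdiff(endpoints, nodes)
  if (length(unknown)) {
    stop_input("edge endpoint(s) not declared as nodes: ",
               paste(unknown, collapse = ", "))
  }
  if (nrow(directed) && any(directed[, 1L] == directed[, 2L])) {
    stop_input("self-loop in directed edges")
  }
  if (nrow(bidirected) && any(bidirected[, 1L] == bidirected[, 2L])) {
    stop_input("self-loop in bidirected edges")
  }

  # canonicalize bidirected pairs as unordered, unique
  if (nrow(bidirected)) {
    bidirected <- t(apply(bidirected, 1L, sort))
    colnames(bidirected) <- c("a", "b")
    bidirected <- unique(bidirected)
  }
  if (nrow(directed)) directed <- unique(directed)

  dag <- structure(
    list(nodes = nodes, directed = directed, bidirected = bidirected),
    class = "causal_dag"
  )
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stop_structural("directed part is cyclic: ",
                    paste(c(cyc, cyc[1L]), collapse = " -> "))
  }
  dag
}

as_edge_matrix <- function(edges, what) {
  if (is.matrix(edges)) {
    if (ncol(edges) != 2L) stop_input(what, " edges must have two endpoints")
    m <- matrix(as.character(edges), ncol = 2L)
  } else if (is.list(edges)) {
    if (!length(edges)) {
      m <- matrix(character(), ncol = 2L)
    } else {
      if (any(lengths(edges) != 2L)) {
        stop_input(what, " edges must be pairs of node ids")
      }
      m <- matrix(as.character(unlist(edges)), ncol = 2L, byrow = TRUE)
    }
  } else {
    stop_input(what, " edges must be a list of pairs or a 2-column matrix")
  }
  colnames(m) <- if (what == "directed") c("from", "to") else c("a", "b")
  m
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("Causal DAG:", length(x$nodes), "nodes,",
      nrow(x$directed), "directed and",
      nrow(x$bidirected), "bidirected edges\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

# ---- internal graph machinery ------------------------------------------

# adjacency matrix of the directed part, rows = parents, cols = children
dag_adjacency <- function(dag) {
  n <- length(dag$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$directed)) A[dag$directed] <- TRUE
  A
}

# returns one directed cycle as a node vector, or NULL if acyclic
find_cycle <- function(dag) {
  A <- dag_adjacency(dag)
  n <- nrow(A)
  state <- integer(n) # 0 unvisited, 1 on stack, 2 done
  names(state) <- rownames(A)
  path <- character(0)
  cycle <- NULL
  visit <- function(v) {
    if (!is.null(cycle)) return(invisible(NULL))
    state[v] <<- 1L
    path <<- c(path, v)
    for (w in rownames(A)[A[v, ]]) {
      if (!is.null(cycle)) break
      if (state[w] == 1L) {
        cycle <<- path[seq(match(w, path), length(path))]
      } else if (state[w] == 0L) {
        visit(w)
      }
    }
    state[v] <<- 2L
    path <<- path[-length(path)]
    invisible(NULL)
  }
  for (v in rownames(A)) if (state[v] == 0L) visit(v)
  cycle
}

# expand bidirected edges into fresh latent parents; returns an adjacency
# matrix over original + latent nodes. Latent ids are prefixed ".L" and are
# never eligible for conditioning or adjustment.
expanded_adjacency <- function(dag) {
  A <- dag_adjacency(dag)
  nb <- nrow(dag$bidirected)
  if (nb == 0L) return(A)
  lat <- paste0(".L.", dag$bidirected[, 1L], ".", dag$bidirected[, 2L])
  n <- nrow(A)
  B <- matrix(FALSE, n + nb, n + nb,
              dimnames = list(c(rownames(A), lat), c(colnames(A), lat)))
  B[seq_len(n), seq_len(n)] <- A
  for (i in seq_len(nb)) {
    B[lat[i], dag$bidirected[i, 1L]] <- TRUE
    B[lat[i], dag$bidirected[i, 2L]] <- TRUE
  }
  B
}

# transitive-closure reachability: anc[i, j] TRUE if i is an ancestor of j
# (proper; diagonal FALSE). Works on any boolean adjacency matrix.
reachability <- function(A) {
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

ancestors_of <- function(A, targets) {
  # nodes with a directed path INTO any target, plus the targets themselves
  R <- reachability(A)
  keep <- colnames(A) %in% targets
  rownames(A)[rowSums(R[, keep, drop = FALSE]) > 0 | keep]
}

descendants_of <- function(A, node) {
  R <- reachability(A)
  colnames(A)[R[node, ]]
}

check_nodes_known <- function(dag, ids) {
  unknown <- setdiff(ids, dag$nodes)
  if (length(unknown)) {
    stop_input("unknown node(s): ", paste(unknown, collapse = ", "))
  }
}

# moralization-based d-separation on an expanded adjacency matrix
dsep_on_adjacency <- function(A, x, y, z) {
  keep <- ancestors_of(A, c(x, y, z))
  A <- A[keep, keep, drop = FALSE]
  # moral graph: undirect all edges, marry parents of every node
  M <- A | t(A)
  for (v in colnames(A)) {
    pa <- which(A[, v])
    if (length(pa) > 1L) M[pa, pa] <- TRUE
  }
  diag(M) <- FALSE
  # delete conditioning nodes, then test connectivity x -- y
  keep2 <- setdiff(colnames(M), z)
  if (!(x %in% keep2) || !(y %in% keep2)) return(TRUE) # degenerate, cannot happen
  M <- M[keep2, keep2, drop = FALSE]
  reached <- colnames(M) == x
  repeat {
    new <- unname(reached | (colSums(M[reached, , drop = FALSE]) > 0))
    if (identical(new, reached)) break
    reached <- new
  }
  !reached[[match(y, colnames(M))]]
}

#' Test d-separation in a causal DAG
#'
#' Determines whether `x` and `y` are d-separated given the conditioning
#' set `z`, i.e. whether every path between them is blocked. Bidirected
#' edges are treated as a latent common parent of their endpoints for path
#' blocking. Implemented by the ancestral-moralization reduction: `x` and
#' `y` are d-separated by `z` iff they are disconnected in the moral graph
#' of the subgraph induced by the ancestors of `{x, y} \\u222a z`, after
#' deleting `z`.
#'
#' @param dag a [causal_dag()].
#' @param x,y node ids, distinct, not in `z`.
#' @param z character vector of conditioning node ids (may be empty).
#' @return `TRUE` if separated, `FALSE` if d-connected. Symmetric in `x`
#'   and `y`.
#' @examples
#' g <- causal_dag(c("A", "B", "C"), directed = list(c("A", "B"), c("C", "B")))
#' d_separated(g, "A", "C", character(0)) # collider blocks
#' d_separated(g, "A", "C", "B")          # conditioning opens it
#' @export
d_separated <- function(dag, x, y, z = character(0)) {
  stopifnot(inherits(dag, "causal_dag"))
  z <- as.character(z)
  check_nodes_known(dag, c(x, y, z))
  if (x == y) stop_input("x and y must differ")
  if (x %in% z || y %in% z) stop_input("x and y must not be in z")
  dsep_on_adjacency(expanded_adjacency(dag), x, y, z)
}

#' Check the back-door criterion for an adjustment set
#'
#' An adjustment set `conditioning` (together with the always-conditioned
#' selection node, if any) satisfies the back-door criterion for the effect
#' of `treatment` on `outcome` when (a) no member of the set is a
#' descendant of the treatment, and (b) the set d-separates treatment from
#' outcome in the graph with all arrows out of the treatment removed.
#' Bidirected edges at the treatment are retained: through their latent
#' parent they are arrows *into* the treatment.
#'
#' The selection node models a decision that gates whether downstream
#' variables exist at all (here: the organizational adoption decision);
#' analyses of post-selection estimands implicitly condition on it, so it
#' is added to the conditioning set for the separation check and subjected
#' to the same no-descendant requirement.
#'
#' @param dag a [causal_dag()].
#' @param treatment,outcome node ids, distinct.
#' @param conditioning character vector of adjustment node ids.
#' @param selection optional node id always treated as conditioned on.
#' @return `TRUE` if the set is a valid back-door adjustment set.
#' @export
is_valid_backdoor <- function(dag, treatment, outcome,
                              conditioning = character(0), selection = NULL) {
  stopifnot(inherits(dag, "causal_dag"))
  conditioning <- as.character(conditioning)
  check_nodes_known(dag, c(treatment, outcome, conditioning, selection))
  if (treatment == outcome) stop_input("treatment and outcome must differ")
  if (treatment %in% conditioning || outcome %in% conditioning) {
    stop_input("conditioning set must not contain treatment or outcome")
  }
  A <- expanded_adjacency(dag)
  cond <- union(conditioning, selection)
  if (length(cond) && any(cond %in% descendants_of(A, treatment))) {
    return(FALSE)
  }
  A[treatment, dag$nodes] <- FALSE # remove arrows out of treatment
  dsep_on_adjacency(A, treatment, outcome, cond)
}

#' Enumerate all inclusion-minimal back-door adjustment sets
#'
#' Searches the observed, pre-treatment nodes for every inclusion-minimal
#' set `Z` such that [is_valid_backdoor()] holds for `treatment` on
#' `outcome` (with `selection` always conditioned). The candidate pool is
#' restricted to ancestors of the treatment, outcome or selection node:
#' members of a minimal separator with a forced conditioning set always lie
#' in that ancestral set, so the restriction is lossless. Subsets are
#' enumerated in increasing size with supersets of already-found sets
#' pruned, guaranteeing inclusion-minimality.
#'
#' @inheritParams is_valid_backdoor
#' @return A list of character vectors (possibly containing `character(0)`
#'   when the empty set is valid), each sorted, ordered lexicographically
#'   by their comma-joined members; an empty list if no valid set exists.
#' @examples
#' g <- causal_dag(c("U", "A", "C"),
#'                 directed = list(c("U", "A"), c("U", "C"), c("A", "C")))
#' minimal_adjustment_sets(g, "A", "C") # list(c("U"))
#' @export
minimal_adjustment_sets <- function(dag, treatment, outcome, selection = NULL) {
  stopifnot(inherits(dag, "causal_dag"))
  check_nodes_known(dag, c(treatment, outcome, selection))
  if (treatment == outcome) stop_input("treatment and outcome must differ")

  A <- expanded_adjacency(dag)
  desc <- descendants_of(A, treatment)
  sel <- as.character(selection)
  if (length(sel) && sel %in% desc) return(list()) # selection breaks condition (a)

  # proper back-door graph: arrows out of the treatment removed (bidirected
  # edges stay: via their latent parent they point INTO the treatment)
  Abd <- A
  Abd[treatment, dag$nodes] <- FALSE

  # minimal separators with the selection forced into the conditioning set
  # lie inside this ancestral set; moralizing its induced subgraph reduces
  # every back-door check below to monotone vertex separation
  W <- ancestors_of(Abd, c(treatment, outcome, sel))
  pool <- sort(setdiff(intersect(dag$nodes, W),
                       c(treatment, outcome, sel, desc)))
  Asub <- Abd[W, W, drop = FALSE]
  H <- Asub | t(Asub)
  for (v in colnames(Asub)) {
    pa <- which(Asub[, v])
    if (length(pa) > 1L) H[pa, pa] <- TRUE
  }
  diag(H) <- FALSE

  vn <- colnames(H)
  nbr <- lapply(seq_along(vn), function(i) which(H[i, ]))
  xi <- match(treatment, vn)
  yi <- match(outcome, vn)
  sel_i <- match(sel, vn)
  separates <- function(set) {
    blocked <- logical(length(vn))
    blocked[c(match(set, vn), sel_i)] <- TRUE
    seen <- blocked
    seen[xi] <- TRUE
    frontier <- xi
    while (length(frontier)) {
      nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
      if (seen[yi]) return(FALSE)
    }
    TRUE
  }

  if (!separates(pool)) return(list()) # separation is monotone in H
  necessary <- pool[!vapply(pool, function(v) separates(setdiff(pool, v)),
                            logical(1))]
  free <- setdiff(pool, necessary)

  # every valid set contains `necessary`; enumerate additions from `free`
  # in increasing size, pruning supersets of already-found additions
  found_extra <- list()
  for (k in 0:length(free)) {
    if (k == 0L) {
      if (separates(necessary)) found_extra <- list(character(0))
      next
    }
    cmb <- utils::combn(free, k)
    for (j in seq_len(ncol(cmb))) {
      extra <- cmb[, j]
      pruned <- FALSE
      for (f in found_extra) if (all(f %in% extra)) { pruned <- TRUE; break }
      if (pruned) next
      if (separates(c(necessary, extra))) {
        found_extra[[length(found_extra) + 1L]] <- extra
      }
    }
  }
  found <- lapply(found_extra, function(e) sort(c(necessary, e)))
  keys <- vapply(found, paste, character(1), collapse = ",")
  found[order(keys)]
}
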