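# Independent oracles the implementation is checked against.

# ---- brute-force d-separation by path enumeration ----------------------
# Expands bidirected edges to explicit latent parents, enumerates every
# simple path between x and y, and applies the blocking rules directly:
# a non-collider blocks iff it is conditioned on, a collider blocks iff
# neither it nor any of its descendants is conditioned on.
oracle_d_separated <- function(nodes, directed, bidirected, x, y, z) {
  lat <- character(0)
  if (length(bidirected)) {
    for (i in seq_along(bidirected)) {
      l <- paste0("..L", i)
      lat <- c(lat, l)
      directed <- c(directed, list(c(l, bidirected[[i]][1])),
                    list(c(l, bidirected[[i]][2])))
    }
  }
  nodes <- c(nodes, lat)
  if (!length(directed)) return(TRUE) # no edges, no paths
  edges <- do.call(rbind, directed)

  desc_cache <- new.env()
  descendants <- function(v) {
    if (!is.null(desc_cache[[v]])) return(desc_cache[[v]])
    out <- character(0)
    frontier <- v
    while (length(frontier)) {
      ch <- edges[edges[, 1] %in% frontier, 2]
      ch <- setdiff(ch, out)
      out <- c(out, ch)
      frontier <- ch
    }
    desc_cache[[v]] <- out
    out
  }

  # walk all simple undirected paths, tracking edge directions
  open_path_found <- FALSE
  walk <- function(path, dirs) {
    # dirs[i]: TRUE if edge i points forward along the path
    last <- path[length(path)]
    if (last == y) {
      if (length(path) >= 3L) {
        for (k in 2:(length(path) - 1L)) {
          v <- path[k]
          collider <- dirs[k - 1L] && !dirs[k]
          blocked <- if (collider) {
            !(v %in% z) && !any(descendants(v) %in% z)
          } else {
            v %in% z
          }
          if (blocked) return(invisible(NULL))
        }
      }
      open_path_found <<- TRUE
      return(invisible(NULL))
    }
    if (open_path_found) return(invisible(NULL))
    out_nb <- edges[edges[, 1] == last, 2]
    in_nb <- edges[edges[, 2] == last, 1]
    for (w in out_nb) {
      if (!w %in% path) walk(c(path, w), c(dirs, TRUE))
    }
    for (w in in_nb) {
      if (!w %in% path) walk(c(path, w), c(dirs, FALSE))
    }
    invisible(NULL)
  }
  walk(x, logical(0))
  !open_path_found
}

# convenience wrapper taking a causal_dag
oracle_dsep_dag <- function(dag, x, y, z = character(0)) {
  directed <- if (nrow(dag$directed)) {
    lapply(seq_len(nrow(dag$directed)), function(i) dag$directed[i, ])
  } else list()
  bidirected <- if (nrow(dag$bidirected)) {
    lapply(seq_len(nrow(dag$bidirected)), function(i) dag$bidirected[i, ])
  } else list()
  oracle_d_separated(dag$nodes, directed, bidirected, x, y, z)
}

# ---- random-DAG fixture -------------------------------------------------
random_dag <- function(n_nodes, p_edge = 0.35, p_bidir = 0.1) {
  nodes <- LETTERS[seq_len(n_nodes)]
  directed <- list()
  for (i in seq_len(n_nodes - 1L)) {
    for (j in seq(i + 1L, n_nodes)) {
      if (stats::runif(1) < p_edge) {
        directed[[length(directed) + 1L]] <- c(nodes[i], nodes[j])
      }
    }
  }
  bidirected <- list()
  for (i in seq_len(n_nodes - 1L)) {
    for (j in seq(i + 1L, n_nodes)) {
      if (stats::runif(1) < p_bidir) {
        bidirected[[length(bidirected) + 1L]] <- c(nodes[i], nodes[j])
      }
    }
  }
  causal_dag(nodes, directed = directed, bidirected = bidirected)
}

# ---- brute-force least squares (normal equations) ----------------------
oracle_ols <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# ---- patient-level analysis frame built independently of the package ---
merged_patient_frame <- function(d) {
  pt <- d$patients
  pr <- d$practitioners
  org <- d$organizations
  cbind(pt,
        pr[match(pt$pract, pr$pract), setdiff(names(pr), c("pract", "org"))],
        org[match(pt$org, org$org), setdiff(names(org), "org")],
        row.names = NULL)
}
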