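# Independent oracles used across the suite: plain-R graph walks and
# finite differences, deliberately sharing no code with the package
# internals they check.

# adjacency list from a bond table
oracle_adj <- function(n, bonds) {
  adj <- rep(list(integer()), n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# all simple paths with `len` edges, deduplicated under reversal, as a
# sorted character vector of index tuples
oracle_paths <- function(n, bonds, len) {
  adj <- oracle_adj(n, bonds)
  out <- character()
  walk <- function(path) {
    if (length(path) == len + 1L) {
      fwd <- paste(path, collapse = ",")
      rev_ <- paste(rev(path), collapse = ",")
      out[[length(out) + 1L]] <<- min(fwd, rev_)
      return(invisible())
    }
    for (nxt in adj[[path[length(path)]]]) {
      if (!nxt %in% path) walk(c(path, nxt))
    }
  }
  for (start in seq_len(n)) walk(start)
  sort(unique(out))
}

# BFS shortest-path bond distances
oracle_distances <- function(n, bonds) {
  adj <- oracle_adj(n, bonds)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# total bond order at every atom, for the valence check
oracle_valence_used <- function(graph) {
  used <- integer(nrow(graph$atoms))
  for (k in seq_len(nrow(graph$bonds))) {
    used[graph$bonds$i[k]] <- used[graph$bonds$i[k]] + graph$bonds$order[k]
    used[graph$bonds$j[k]] <- used[graph$bonds$j[k]] + graph$bonds$order[k]
  }
  used
}

# central-difference derivative
oracle_deriv <- function(f, x, h = 1e-5) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# relabel the atoms of a molecular graph
permute_graph <- function(graph, perm) {
  inv <- order(perm)
  molecular_graph(graph$atoms$element[perm],
                  data.frame(i = inv[graph$bonds$i], j = inv[graph$bonds$j],
                             order = graph$bonds$order),
                  name = graph$name)
}

# canonical text form of enumerated tuples for set comparison
canon_terms <- function(terms, kind) {
  rows <- terms[terms$kind == kind, ]
  vapply(rows$sites, function(idx) {
    if (kind == "improper") {
      paste(c(idx[1L], sort(idx[2:4])), collapse = ",")
    } else {
      fwd <- paste(idx, collapse = ",")
      rev_ <- paste(rev(idx), collapse = ",")
      min(fwd, rev_)
    }
  }, character(1))
}

ua_fixture_names <- c("methane", "ethane", "propane", "n-butane", "n-pentane",
                      "isobutane", "ethanol", "methanol", "1,2-ethanediol")

# heavy-atom skeleton -> explicit-H graph (internal helper surfaced for tests)
fill_hydrogens_test <- function(elements, bonds) {
  ffdat:::fill_hydrogens(elements, bonds)
}
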