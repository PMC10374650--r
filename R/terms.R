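#' Enumerate interaction terms on a site graph
#'
#' Walks the site graph and lists every candidate interaction the data
#' scheme covers: bonds (edges), angles (paths of length 2), torsions
#' (simple in-line paths of length 3), improper candidates (one per
#' combination of three neighbors around a site of degree >= 3), 1,n pairs
#' (site pairs at shortest-path bond distance d >= 3, labeled n = d + 1)
#' and, when asked, special-pair candidates at given bond separations.
#' Tuples are deduplicated under reversal and reported with the
#' lexicographically smaller orientation.
#'
#' @param sg an `ff_sitegraph`.
#' @param special_dists integer vector of bond separations at which
#'   special-pair candidates should be listed (typically the distinct
#'   `dist` values of a dataset's special table).
#' @return a tibble with columns `kind`, `sites` (list of index tuples,
#'   improper tuples center-first), `orders` (list of the bond orders
#'   along the tuple) and `separation` (bond-count distance, `NA` except
#'   for `one_n`/`special`; for `one_n` rows it holds d, so n = d + 1).
#' @examples
#' enumerate_terms(type_molecule(make_fixture("n-butane")$graph))
#' @export
enumerate_terms <- function(sg, special_dists = integer()) {
  stopifnot(inherits(sg, "ff_sitegraph"))
  adj <- site_adjacency(sg)
  n <- nrow(sg$sites)
  order_of <- function(i, j) {
    k <- match(TRUE, (sg$bonds$i == min(i, j)) & (sg$bonds$j == max(i, j)))
    sg$bonds$order[k]
  }
  rows <- list()
  add <- function(kind, sites, orders, separation = NA_integer_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      kind = kind, sites = list(as.integer(sites)),
      orders = list(as.integer(orders)), separation = as.integer(separation))
  }

  for (k in seq_len(nrow(sg$bonds))) {
    add("bond", c(sg$bonds$i[k], sg$bonds$j[k]), sg$bonds$order[k])
  }
  for (j in seq_len(n)) {
    nb <- sort(adj$nbrs[[j]])
    if (length(nb) >= 2L) {
      for (pair in utils::combn(nb, 2L, simplify = FALSE)) {
        add("angle", c(pair[1L], j, pair[2L]),
            c(order_of(pair[1L], j), order_of(j, pair[2L])))
      }
    }
  }
  for (k in seq_len(nrow(sg$bonds))) {
    j <- sg$bonds$i[k]; l <- sg$bonds$j[k]
    for (i in setdiff(adj$nbrs[[j]], l)) {
      for (m in setdiff(adj$nbrs[[l]], j)) {
        if (i == m) next                        # 4-membered ring closure
        fwd <- c(i, j, l, m)
        if (paste(fwd, collapse = ",") > paste(rev(fwd), collapse = ",")) next
        add("torsion", fwd, c(order_of(i, j), order_of(j, l), order_of(l, m)))
      }
    }
  }
  for (center in which(lengths(adj$nbrs) >= 3L)) {
    for (trip in utils::combn(sort(adj$nbrs[[center]]), 3L, simplify = FALSE)) {
      add("improper", c(center, trip),
          vapply(trip, function(t) order_of(center, t), integer(1)))
    }
  }
  if (n >= 2L && nrow(sg$bonds) > 0L) {
    d <- igraph::distances(mol_igraph(n, sg$bonds))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (is.finite(d[i, j]) && d[i, j] >= 3) {
          add("one_n", c(i, j), integer(), separation = d[i, j])
        }
        if (is.finite(d[i, j]) && d[i, j] %in% special_dists) {
          add("special", c(i, j), integer(), separation = d[i, j])
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(kind = character(), sites = list(),
                          orders = list(), separation = integer()))
  }
  dplyr::bind_rows(rows)
}
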