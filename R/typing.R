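#' Fuse hydrogens into united-atom sites
#'
#' Turns an all-atom molecular graph into a site graph: every hydrogen is
#' fused into its single heavy neighbor (incrementing that site's
#' `fused_h` count) unless its chemical context asks for an explicit site.
#' By default the polar hydrogens — on oxygen (hydroxyl), sulfur (thiol)
#' and nitrogen (amine/amide) — stay explicit, which is the united-atom
#' convention of force fields like TraPPE.  Heavy-atom connectivity is
#' unchanged.
#'
#' @param graph an [molecular_graph()].
#' @param keep_h which hydrogens stay explicit sites: a subset of
#'   `c("hydroxyl", "thiol", "amine", "amide")`, or `"all"` (all-atom
#'   mode), or `"none"`.
#' @return an object of class `ff_sitegraph`: `name`, `sites` (tibble
#'   `element`, `fused_h`, `group`, `tag`; the last two `NA` until
#'   assigned), `bonds` (tibble `i`, `j`, `order` between sites) and
#'   `atom_site` (the site index of every source atom).
#' @examples
#' fx <- make_fixture("ethanol")
#' unite_atoms(fx$graph)
#' @export
unite_atoms <- function(graph,
                        keep_h = c("hydroxyl", "thiol", "amine", "amide")) {
  stopifnot(inherits(graph, "ff_molgraph"))
  el <- graph$atoms$element
  n <- length(el)
  is_h <- el == "H"
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[k]; j <- graph$bonds$j[k]
    nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
  }
  bad_h <- which(is_h & lengths(nbrs) != 1L)
  if (length(bad_h) > 0L) {
    rlang::abort(sprintf("hydrogen atom %d has %d neighbors; exactly 1 required",
                         bad_h[1L], length(nbrs[[bad_h[1L]]])),
                 class = "ffdat_structure_error")
  }
  h_context <- function(a) {
    hv <- nbrs[[a]][1L]
    switch(el[hv],
      O = "hydroxyl",
      S = "thiol",
      N = {
        carbonyl <- any(vapply(nbrs[[hv]], function(c_) {
          el[c_] == "C" && any(vapply(seq_len(nrow(graph$bonds)), function(k) {
            b <- graph$bonds[k, ]
            ((b$i == c_ && el[b$j] == "O") || (b$j == c_ && el[b$i] == "O")) && b$order == 2L
          }, logical(1)))
        }, logical(1)))
        if (carbonyl) "amide" else "amine"
      },
      "apolar")
  }
  keep <- if (identical(keep_h, "all")) rep(TRUE, n)
          else if (identical(keep_h, "none")) rep(FALSE, n)
          else vapply(seq_len(n), function(a) is_h[a] && h_context(a) %in% keep_h,
                      logical(1))
  site_of <- integer(n)
  retained <- which(!is_h | keep)
  site_of[retained] <- seq_along(retained)
  fused_h <- integer(length(retained))
  for (a in which(is_h & !keep)) {
    heavy <- nbrs[[a]][1L]
    if (el[heavy] == "H") {
      rlang::abort("cannot fuse an H-H bond into a united site",
                   class = "ffdat_structure_error")
    }
    site_of[a] <- site_of[heavy]
    fused_h[site_of[heavy]] <- fused_h[site_of[heavy]] + 1L
  }
  bonds <- graph$bonds[!(is_h[graph$bonds$i] & !keep[graph$bonds$i]) &
                       !(is_h[graph$bonds$j] & !keep[graph$bonds$j]), ]
  bonds <- tibble::tibble(i = pmin(site_of[bonds$i], site_of[bonds$j]),
                          j = pmax(site_of[bonds$i], site_of[bonds$j]),
                          order = bonds$order)
  structure(
    list(name = graph$name,
         sites = tibble::tibble(element = el[retained], fused_h = fused_h,
                                group = NA_character_, tag = NA_character_),
         bonds = bonds,
         atom_site = site_of),
    class = "ff_sitegraph"
  )
}

#' @export
print.ff_sitegraph <- function(x, ...) {
  cat(sprintf("<ff_sitegraph> %s: %d sites, %d bonds\n",
              x$name, nrow(x$sites), nrow(x$bonds)))
  print(site_report(x))
  invisible(x)
}

# neighbor lists + incident orders on a site graph
site_adjacency <- function(sg) {
  n <- nrow(sg$sites)
  nbrs <- rep(list(integer()), n)
  ords <- rep(list(integer()), n)
  for (k in seq_len(nrow(sg$bonds))) {
    i <- sg$bonds$i[k]; j <- sg$bonds$j[k]; o <- sg$bonds$order[k]
    nbrs[[i]] <- c(nbrs[[i]], j); ords[[i]] <- c(ords[[i]], o)
    nbrs[[j]] <- c(nbrs[[j]], i); ords[[j]] <- c(ords[[j]], o)
  }
  list(nbrs = nbrs, ords = ords)
}

# Built-in functional-group matchers.  Each matcher inspects the united
# site graph and returns the indices of every site inside one occurrence of
# its motif (the group label covers the whole motif; carbons beyond the
# alpha position revert to the alkane default).  Matchers run in priority
# order and the first assignment wins, so specific motifs (ester, acid,
# acetal) shade the general ones (ether, ketone, alcohol).
group_matchers <- function() {
  nb_of <- function(adj, i) adj$nbrs[[i]]
  ord_between <- function(sg, i, j) {
    hit <- (sg$bonds$i == min(i, j)) & (sg$bonds$j == max(i, j))
    sg$bonds$order[hit][1L]
  }
  el <- function(sg, i) sg$sites$element[i]
  carbonyl_o <- function(sg, adj, c_) {
    os <- nb_of(adj, c_)[el(sg, nb_of(adj, c_)) == "O"]
    os[vapply(os, function(o) ord_between(sg, c_, o) == 2L, logical(1))]
  }
  single_o <- function(sg, adj, c_) {
    os <- nb_of(adj, c_)[el(sg, nb_of(adj, c_)) == "O"]
    os[vapply(os, function(o) ord_between(sg, c_, o) == 1L, logical(1))]
  }

  list(
    Cac = function(sg, adj) {          # CHx-C(=O)-O-H
      hits <- list()
      for (c_ in which(el(sg, seq_len(nrow(sg$sites))) == "C")) {
        co <- carbonyl_o(sg, adj, c_); so <- single_o(sg, adj, c_)
        for (o in so) {
          h <- nb_of(adj, o)[el(sg, nb_of(adj, o)) == "H"]
          if (length(co) == 1L && length(h) >= 1L) {
            hits[[length(hits) + 1L]] <- c(c_, co, o, h)
          }
        }
      }
      hits
    },
    Es = function(sg, adj) {           # CHx-C(=O)-O-CHx
      hits <- list()
      for (c_ in which(el(sg, seq_len(nrow(sg$sites))) == "C")) {
        co <- carbonyl_o(sg, adj, c_); so <- single_o(sg, adj, c_)
        for (o in so) {
          other <- setdiff(nb_of(adj, o), c_)
          if (length(co) == 1L && length(other) == 1L && el(sg, other) == "C") {
            alpha <- setdiff(nb_of(adj, c_)[el(sg, nb_of(adj, c_)) == "C"], other)
            hits[[length(hits) + 1L]] <- c(c_, co, o, other, alpha)
          }
        }
      }
      hits
    },
    Ace = function(sg, adj) {          # CHx-O-C(-X)2-O-CHx
      hits <- list()
      for (c_ in which(el(sg, seq_len(nrow(sg$sites))) == "C")) {
        so <- single_o(sg, adj, c_)
        if (length(so) == 2L && length(carbonyl_o(sg, adj, c_)) == 0L) {
          outer <- unlist(lapply(so, function(o) setdiff(nb_of(adj, o), c_)))
          if (length(outer) == 2L && all(el(sg, outer) == "C")) {
            hits[[length(hits) + 1L]] <- c(c_, so, outer)
          }
        }
      }
      hits
    },
    Ad = function(sg, adj) {           # CHx-C(=O)-N-X2
      hits <- list()
      for (c_ in which(el(sg, seq_len(nrow(sg$sites))) == "C")) {
        co <- carbonyl_o(sg, adj, c_)
        ns <- nb_of(adj, c_)[el(sg, nb_of(adj, c_)) == "N"]
        if (length(co) == 1L && length(ns) >= 1L) {
          hs <- unlist(lapply(ns, function(nn) nb_of(adj, nn)[el(sg, nb_of(adj, nn)) == "H"]))
          hits[[length(hits) + 1L]] <- c(c_, co, ns, hs)
        }
      }
      hits
    },
    K = function(sg, adj) {            # CHx-C(=O)-CHx
      hits <- list()
      for (c_ in which(el(sg, seq_len(nrow(sg$sites))) == "C")) {
        co <- carbonyl_o(sg, adj, c_)
        cs <- nb_of(adj, c_)[el(sg, nb_of(adj, c_)) == "C"]
        if (length(co) == 1L && length(cs) == 2L) {
          hits[[length(hits) + 1L]] <- c(c_, co, cs)
        }
      }
      hits
    },
    Al = function(sg, adj) {           # X-C(-H)=O: under UA the aldehyde H is fused
      hits <- list()
      for (c_ in which(el(sg, seq_len(nrow(sg$sites))) == "C")) {
        co <- carbonyl_o(sg, adj, c_)
        cs <- nb_of(adj, c_)[el(sg, nb_of(adj, c_)) == "C"]
        has_h <- sg$sites$fused_h[c_] >= 1L ||
          any(el(sg, nb_of(adj, c_)) == "H")
        if (length(co) == 1L && length(cs) <= 1L && has_h) {
          hits[[length(hits) + 1L]] <- c(c_, co)
        }
      }
      hits
    },
    Ak = function(sg, adj) {           # CHx-O-H
      hits <- list()
      for (o in which(el(sg, seq_len(nrow(sg$sites))) == "O")) {
        nb <- nb_of(adj, o)
        cs <- nb[el(sg, nb) == "C"]
        hs <- nb[el(sg, nb) == "H"]
        hydroxyl <- length(hs) >= 1L || (sg$sites$fused_h[o] >= 1L && length(cs) == 1L)
        if (hydroxyl && length(cs) == 1L) {
          hits[[length(hits) + 1L]] <- c(o, hs, cs)
        }
      }
      hits
    },
    Tl = function(sg, adj) {           # CHx-S-H
      hits <- list()
      for (s in which(el(sg, seq_len(nrow(sg$sites))) == "S")) {
        nb <- nb_of(adj, s)
        cs <- nb[el(sg, nb) == "C"]; hs <- nb[el(sg, nb) == "H"]
        if ((length(hs) >= 1L || sg$sites$fused_h[s] >= 1L) && length(cs) == 1L) {
          hits[[length(hits) + 1L]] <- c(s, hs, cs)
        }
      }
      hits
    },
    DS = function(sg, adj) {           # CHx-S-S-CHx
      hits <- list()
      for (k in seq_len(nrow(sg$bonds))) {
        i <- sg$bonds$i[k]; j <- sg$bonds$j[k]
        if (el(sg, i) == "S" && el(sg, j) == "S") {
          cs <- c(nb_of(adj, i)[el(sg, nb_of(adj, i)) == "C"],
                  nb_of(adj, j)[el(sg, nb_of(adj, j)) == "C"])
          hits[[length(hits) + 1L]] <- c(i, j, cs)
        }
      }
      hits
    },
    Sd = function(sg, adj) {           # CHx-S-CHx
      hits <- list()
      for (s in which(el(sg, seq_len(nrow(sg$sites))) == "S")) {
        cs <- nb_of(adj, s)[el(sg, nb_of(adj, s)) == "C"]
        if (length(cs) == 2L) hits[[length(hits) + 1L]] <- c(s, cs)
      }
      hits
    },
    E = function(sg, adj) {            # CHx-O-CHx
      hits <- list()
      for (o in which(el(sg, seq_len(nrow(sg$sites))) == "O")) {
        cs <- nb_of(adj, o)[el(sg, nb_of(adj, o)) == "C"]
        if (length(cs) == 2L) hits[[length(hits) + 1L]] <- c(o, cs)
      }
      hits
    },
    Nl = function(sg, adj) {           # CHx-C#N
      hits <- list()
      for (k in seq_len(nrow(sg$bonds))) {
        if (sg$bonds$order[k] == 3L) {
          i <- sg$bonds$i[k]; j <- sg$bonds$j[k]
          pair <- sort(c(i, j))
          if (setequal(el(sg, pair), c("C", "N"))) {
            c_ <- pair[el(sg, pair) == "C"]
            alpha <- nb_of(adj, c_)[el(sg, nb_of(adj, c_)) == "C"]
            hits[[length(hits) + 1L]] <- c(pair, alpha)
          }
        }
      }
      hits
    },
    No = function(sg, adj) {           # CHx-N-O2
      hits <- list()
      for (nn in which(el(sg, seq_len(nrow(sg$sites))) == "N")) {
        os <- nb_of(adj, nn)[el(sg, nb_of(adj, nn)) == "O"]
        cs <- nb_of(adj, nn)[el(sg, nb_of(adj, nn)) == "C"]
        if (length(os) == 2L) hits[[length(hits) + 1L]] <- c(nn, os, cs)
      }
      hits
    },
    Am = function(sg, adj) {           # CHx-N-X2
      hits <- list()
      for (nn in which(el(sg, seq_len(nrow(sg$sites))) == "N")) {
        nb <- nb_of(adj, nn)
        hits[[length(hits) + 1L]] <- c(nn, nb[el(sg, nb) %in% c("H", "C")])
      }
      hits
    }
  )
}

ring_groups <- function(sg) {
  n <- nrow(sg$sites)
  if (nrow(sg$bonds) == 0L) return(rep(NA_character_, n))
  g <- mol_igraph(n, sg$bonds)
  out <- rep(NA_character_, n)
  # minimum cycle membership via shortest alternative path per edge
  rings <- list()
  for (k in seq_len(nrow(sg$bonds))) {
    i <- sg$bonds$i[k]; j <- sg$bonds$j[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = i, to = j)$vpath[[1L]])
    if (length(sp) > 0L) rings[[length(rings) + 1L]] <- as.integer(sp)
  }
  rings <- unique(lapply(rings, function(r) sort(r)))
  for (r in rings) {
    size <- length(r)
    if (!all(sg$sites$element[r] == "C")) next
    orders <- sg$bonds$order[sg$bonds$i %in% r & sg$bonds$j %in% r]
    aromatic <- size == 6L && sum(orders == 2L) == 3L && sum(orders == 1L) == 3L
    label <- if (aromatic) "B"
             else if (any(orders > 1L)) NA_character_
             else if (size == 5L) "CA5"
             else if (size == 6L) "CA6"
             else if (size > 6L && size < 18L) "CA"
             else NA_character_
    if (!is.na(label)) out[r] <- ifelse(is.na(out[r]), label, out[r])
  }
  out
}

#' Assign functional groups to sites
#'
#' Labels every site of a united site graph with a functional-group
#' abbreviation.  Motif matchers run in a fixed priority order (most
#' specific first: acid before alcohol, ester before ether and ketone,
#' acetal before ether); ring membership (benzene, cyclopentane,
#' cyclohexane, larger cycloalkanes) is applied next, and any remaining
#' carbon site defaults to the alkane group `"A"` (alkene and alkyne
#' carbons included).  The group label covers every site inside the motif
#' — e.g. the O, the hydroxyl H and the alpha-carbon of an alcohol are all
#' `"Ak"` — while carbons beyond the alpha position stay `"A"`, which is
#' what keeps e.g. the ethanol CH3 on the uncharged alkane parameters.
#'
#' @param sg an `ff_sitegraph` from [unite_atoms()].
#' @param groups group registry (used to validate labels).
#' @return the site graph with `sites$group` filled in.
#' @export
assign_groups <- function(sg, groups = ff_groups()) {
  stopifnot(inherits(sg, "ff_sitegraph"))
  adj <- site_adjacency(sg)
  lab <- rep(NA_character_, nrow(sg$sites))
  for (grp in names(group_matchers())) {
    hits <- group_matchers()[[grp]](sg, adj)
    for (h in hits) {
      h <- unique(h[!is.na(h)])
      lab[h] <- ifelse(is.na(lab[h]), grp, lab[h])
    }
  }
  ring <- ring_groups(sg)
  lab <- ifelse(is.na(lab), ring, lab)
  lab <- ifelse(is.na(lab) & sg$sites$element == "C", "A", lab)
  if (anyNA(lab)) {
    bad <- which(is.na(lab))
    rlang::abort(
      sprintf("cannot assign a functional group to site(s) %s (element %s)",
              paste(bad, collapse = ", "),
              paste(unique(sg$sites$element[bad]), collapse = ", ")),
      class = "ffdat_typing_error")
  }
  unknown <- !known_group(lab, groups)
  if (any(unknown)) {
    rlang::abort(sprintf("group '%s' is not in the registry", lab[unknown][1L]),
                 class = "ffdat_typing_error")
  }
  sg$sites$group <- lab
  sg
}

#' Derive tags for typed sites
#'
#' Computes the concrete four-part tag of every site: the assigned group,
#' the site symbol (the element; a carbon with fused hydrogens is written
#' `"C"`), the number of bonds to other interaction sites (the site-graph
#' degree — fused hydrogens are not sites, explicit polar hydrogens are),
#' and the highest incident bond order.  An isolated united site such as
#' methane gets `n_bonds = 0`, `max_order = 0`.
#'
#' @param sg an `ff_sitegraph` with groups assigned.
#' @return the site graph with `sites$tag` filled in (all tags concrete).
#' @export
assign_tags <- function(sg) {
  stopifnot(inherits(sg, "ff_sitegraph"))
  if (anyNA(sg$sites$group)) {
    rlang::abort("assign groups before tags", class = "ffdat_usage_error")
  }
  adj <- site_adjacency(sg)
  deg <- lengths(adj$nbrs)
  maxo <- vapply(adj$ords, function(o) if (length(o) == 0L) 0L else max(o), integer(1))
  sg$sites$tag <- format_tag(group = sg$sites$group, site = sg$sites$element,
                             n_bonds = deg, max_order = maxo)
  sg
}

#' Type a molecule in one call
#'
#' Convenience pipeline: [unite_atoms()], [assign_groups()],
#' [assign_tags()].
#'
#' @inheritParams unite_atoms
#' @inheritParams assign_groups
#' @return a fully typed `ff_sitegraph`.
#' @examples
#' type_molecule(make_fixture("ethanol")$graph)$sites
#' @export
type_molecule <- function(graph,
                          keep_h = c("hydroxyl", "thiol", "amine", "amide"),
                          groups = ff_groups()) {
  assign_tags(assign_groups(unite_atoms(graph, keep_h = keep_h), groups = groups))
}

#' @rdname type_molecule
#' @param sg a typed site graph.
#' @return `site_report()` returns a tibble (site, element, fused_h,
#'   group, tag) suitable for printing or writing as delimited text.
#' @export
site_report <- function(sg) {
  tibble::tibble(site = seq_len(nrow(sg$sites)),
                 element = sg$sites$element, fused_h = sg$sites$fused_h,
                 group = sg$sites$group, tag = sg$sites$tag)
}
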