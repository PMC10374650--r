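#' Built-in molecule fixtures
#'
#' Small molecules used throughout the examples and tests: each fixture is
#' an explicit-hydrogen molecular graph built programmatically (hydrogens
#' filled in from standard valences), plus, where the bundled TraPPE-UA
#' parameters define the geometry, reference united-atom site coordinates
#' at the idealized equilibrium (bonds 1.54/1.43/0.945 Angstrom, angles
#' 114/112/109.47/108.5 degrees, torsions trans).
#'
#' @param name one of `"methane"`, `"ethane"`, `"propane"`, `"n-butane"`,
#'   `"n-pentane"`, `"isobutane"`, `"ethanol"`, `"methanol"`,
#'   `"1,2-ethanediol"`, `"dimethyl-ether"`, `"3-methyl-1-butene"`.
#' @return a list with elements `name`, `graph` (an `ff_molgraph` with
#'   explicit hydrogens) and `coords` (site coordinates for the default
#'   united-atom typing, or `NULL` where the bundled dataset does not fix
#'   the geometry).
#' @examples
#' make_fixture("n-butane")$graph
#' @export
make_fixture <- function(name) {
  fixtures <- c("methane", "ethane", "propane", "n-butane", "n-pentane",
                "isobutane", "ethanol", "methanol", "1,2-ethanediol",
                "dimethyl-ether", "3-methyl-1-butene")
  if (!name %in% fixtures) {
    rlang::abort(sprintf("unknown fixture '%s'; available: %s",
                         name, paste(fixtures, collapse = ", ")),
                 class = "ffdat_usage_error")
  }
  cc <- 1.54; co <- 1.43; oh <- 0.945
  a_ccc <- 114; a_br <- 112; a_cco <- 109.47; a_coh <- 108.5

  skeleton <- switch(name,
    "methane"   = list(el = "C", bonds = NULL),
    "ethane"    = list(el = c("C", "C"), bonds = cbind(1, 2, 1)),
    "propane"   = list(el = rep("C", 3), bonds = cbind(1:2, 2:3, 1)),
    "n-butane"  = list(el = rep("C", 4), bonds = cbind(1:3, 2:4, 1)),
    "n-pentane" = list(el = rep("C", 5), bonds = cbind(1:4, 2:5, 1)),
    "isobutane" = list(el = rep("C", 4), bonds = cbind(1, 2:4, 1)),
    "ethanol"   = list(el = c("C", "C", "O"), bonds = cbind(1:2, 2:3, 1)),
    "methanol"  = list(el = c("C", "O"), bonds = cbind(1, 2, 1)),
    "1,2-ethanediol" = list(el = c("C", "C", "O", "O"),
                            bonds = cbind(c(1, 1, 2), c(2, 3, 4), 1)),
    "dimethyl-ether" = list(el = c("C", "O", "C"), bonds = cbind(1:2, 2:3, 1)),
    "3-methyl-1-butene" = list(el = rep("C", 5),
                               bonds = cbind(c(1, 2, 3, 3), c(2, 3, 4, 5),
                                             c(2, 1, 1, 1)))
  )
  bonds <- if (is.null(skeleton$bonds)) {
    data.frame(i = integer(), j = integer(), order = integer())
  } else {
    data.frame(i = skeleton$bonds[, 1], j = skeleton$bonds[, 2],
               order = skeleton$bonds[, 3])
  }
  graph <- fill_hydrogens(skeleton$el, bonds, name = name)

  coords <- switch(name,
    "methane"   = matrix(0, 1, 3),
    "ethane"    = chain_coords(cc),
    "propane"   = chain_coords(c(cc, cc), a_ccc),
    "n-butane"  = chain_coords(rep(cc, 3), rep(a_ccc, 2), 180),
    "n-pentane" = chain_coords(rep(cc, 4), rep(a_ccc, 3), c(180, 180)),
    "isobutane" = {
      # three methyls symmetric about the z-axis through the CH center,
      # pairwise angles all at the branched-carbon reference
      cos_polar2 <- (cosd(a_br) + 0.5) / 1.5
      polar <- acos(sqrt(cos_polar2))
      az <- 2 * pi * (0:2) / 3
      rbind(c(0, 0, 0),
            cc * cbind(sin(polar) * cos(az), sin(polar) * sin(az),
                       rep(cos(polar), 3)))
    },
    "ethanol"   = chain_coords(c(cc, co, oh), c(a_cco, a_coh), 180),
    "methanol"  = chain_coords(c(co, oh), a_coh),
    "1,2-ethanediol" = {
      # chain H-O-C-C-O-H, then reorder to site order (C, C, O, O, H, H)
      ch <- chain_coords(c(oh, co, cc, co, oh),
                         c(a_coh, a_cco, a_cco, a_coh), c(180, 180, 180))
      ch[c(3, 4, 2, 5, 1, 6), ]
    },
    NULL
  )
  list(name = name, graph = graph, coords = coords)
}

# complete a heavy-atom skeleton with explicit hydrogens from standard
# valences (C 4, N 3, O 2, S 2); existing bond orders count against the
# valence
fill_hydrogens <- function(elements, bonds, name = "molecule") {
  valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, H = 1L)
  used <- integer(length(elements))
  for (k in seq_len(nrow(bonds))) {
    used[bonds$i[k]] <- used[bonds$i[k]] + bonds$order[k]
    used[bonds$j[k]] <- used[bonds$j[k]] + bonds$order[k]
  }
  el <- elements
  for (a in seq_along(elements)) {
    need <- valence[[elements[a]]] - used[a]
    if (need < 0L) {
      rlang::abort(sprintf("atom %d (%s) exceeds its valence", a, elements[a]),
                   class = "ffdat_structure_error")
    }
    if (need > 0L) {
      h_idx <- length(el) + seq_len(need)
      el <- c(el, rep("H", need))
      bonds <- rbind(bonds, data.frame(i = a, j = h_idx, order = 1L))
    }
  }
  molecular_graph(el, bonds, name = name)
}
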