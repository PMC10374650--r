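#' Build a component-specific force field
#'
#' Derives the complete, molecule-specific model from a transferable
#' dataset: the molecule is typed (united-atom fusion, group assignment,
#' tag derivation), every interaction term is enumerated on the site graph
#' and resolved against the dataset with wildcard/specificity semantics,
#' site charges and van der Waals parameters come from the intermolecular
#' table, 1,n pairs are scaled per the sixth section (pairs scaled to
#' (0, 0) are recorded as exclusions rather than terms), and special pairs
#' are attached where the special table matches both tags and separation.
#' Improper candidates that no record covers are dropped — an empty
#' improper section means the force field defines none — while an
#' unresolved bond, angle or torsion is an error.
#'
#' @param dataset an [ff_dataset()].
#' @param molecule an `ff_molgraph`, a typed `ff_sitegraph`, or a path to
#'   a MOL/SDF file.
#' @param keep_h,groups typing options, see [type_molecule()].
#' @return an object of class `ff_component`: `name`, `units`, `sites`
#'   (tibble with tag, intermolecular id/params, charge), `terms` (tibble
#'   of resolved bonded/special terms with function id, parameters and the
#'   source record's DOI), `scalings` (active 1,n pairs with per-channel
#'   factors), `exclusions` (1,n pairs scaled to zero) and `source`
#'   (dataset name).
#' @examples
#' ff <- build_component_ff(load_bundled(), make_fixture("ethanol")$graph)
#' glance(ff)
#' @export
build_component_ff <- function(dataset, molecule,
                               keep_h = c("hydroxyl", "thiol", "amine", "amide"),
                               groups = ff_groups()) {
  stopifnot(is_ff_dataset(dataset))
  sg <- if (inherits(molecule, "ff_sitegraph")) {
    molecule
  } else {
    graph <- if (inherits(molecule, "ff_molgraph")) molecule
             else read_molfile(molecule)
    type_molecule(graph, keep_h = keep_h, groups = groups)
  }
  if (anyNA(sg$sites$tag)) sg <- assign_tags(sg)
  with_context <- function(expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("while building '%s': %s", sg$name, conditionMessage(e)),
                   class = class(e)[1L])
    })
  }

  site_res <- with_context(lapply(sg$sites$tag, function(t) resolve_site(dataset, t)))
  id1 <- vapply(site_res, `[[`, integer(1), "id1")
  sites <- dplyr::mutate(site_report(sg),
    id1 = id1,
    params = purrr::map(site_res, "params"),
    charge = vapply(site_res, function(r) r$params[[1L]], numeric(1)),
    ref = vapply(site_res, `[[`, character(1), "ref"))

  terms_all <- enumerate_terms(sg, special_dists = unique(dataset$special$dist))
  term_rows <- list(); scal_rows <- list(); excl_rows <- list()
  for (r in seq_len(nrow(terms_all))) {
    kind <- terms_all$kind[r]
    idx <- terms_all$sites[[r]]
    orders <- terms_all$orders[[r]]
    tags <- sg$sites$tag[idx]
    if (kind == "one_n") {
      n <- terms_all$separation[[r]] + 1L
      sc <- scale_1n(dataset$one_n, n)
      if (all(sc == 0)) {
        excl_rows[[length(excl_rows) + 1L]] <- tibble::tibble(
          i = idx[1L], j = idx[2L], n = n)
      } else {
        scal_rows[[length(scal_rows) + 1L]] <- tibble::tibble(
          i = idx[1L], j = idx[2L], n = n,
          scale_vdw = sc[["vdw"]], scale_elec = sc[["elec"]])
      }
    } else if (kind == "special") {
      res <- tryCatch(
        resolve_term(dataset, "special", tags, dist = terms_all$separation[[r]]),
        ffdat_unparameterized_error = function(e) NULL)
      if (!is.null(res)) {
        term_rows[[length(term_rows) + 1L]] <- tibble::tibble(
          kind = "special", sites = list(idx), orders = list(orders),
          separation = terms_all$separation[[r]], id = res$id,
          params = list(res$params), rigid = FALSE, ref = res$ref,
          record_row = res$row)
      }
    } else {
      res <- if (kind == "improper") {
        tryCatch(resolve_term(dataset, kind, tags, orders),
                 ffdat_unparameterized_error = function(e) NULL)
      } else {
        with_context(resolve_term(dataset, kind, tags, orders))
      }
      if (!is.null(res)) {
        term_rows[[length(term_rows) + 1L]] <- tibble::tibble(
          kind = kind, sites = list(idx), orders = list(orders),
          separation = NA_integer_, id = res$id, params = list(res$params),
          rigid = res$rigid, ref = res$ref, record_row = res$row)
      }
    }
  }
  empty_terms <- tibble::tibble(
    kind = character(), sites = list(), orders = list(),
    separation = integer(), id = integer(), params = list(),
    rigid = logical(), ref = character(), record_row = integer())
  terms <- if (length(term_rows) > 0L) dplyr::bind_rows(term_rows) else empty_terms
  kind_order <- c("bond", "angle", "torsion", "improper", "special")
  terms <- terms[order(match(terms$kind, kind_order),
                       vapply(terms$sites, paste, character(1), collapse = ",")), ]
  structure(
    list(name = sg$name, units = dataset$units, sites = sites, terms = terms,
         scalings = if (length(scal_rows) > 0L) dplyr::bind_rows(scal_rows)
                    else tibble::tibble(i = integer(), j = integer(), n = integer(),
                                        scale_vdw = double(), scale_elec = double()),
         exclusions = if (length(excl_rows) > 0L) dplyr::bind_rows(excl_rows)
                      else tibble::tibble(i = integer(), j = integer(), n = integer()),
         source = dataset$name),
    class = "ff_component")
}

#' @export
print.ff_component <- function(x, ...) {
  cat(sprintf("<ff_component> %s from %s [%s]\n", x$name, x$source, x$units))
  cat(sprintf("  %d site(s); net charge %.6g e\n", nrow(x$sites), net_charge(x)))
  counts <- table(factor(x$terms$kind,
                         levels = c("bond", "angle", "torsion", "improper", "special")))
  cat("  terms:", paste(sprintf("%s %d", names(counts), counts), collapse = ", "),
      sprintf("; 1,n scaled %d, excluded %d\n", nrow(x$scalings), nrow(x$exclusions)))
  invisible(x)
}

#' Net charge of a component force field
#'
#' @param ff an `ff_component`.
#' @return the sum of site charges, in e.
#' @examples
#' net_charge(build_component_ff(load_bundled(), make_fixture("ethanol")$graph))
#' @export
net_charge <- function(ff) {
  stopifnot(inherits(ff, "ff_component"))
  sum(ff$sites$charge)
}

#' Evaluate the intramolecular energy of a component force field
#'
#' Computes the per-kind energy sums of all resolved terms on one set of
#' site coordinates.  Rigid (`"none"`) terms contribute zero energy; their
#' geometric deviation from the fixed reference value is reported as a
#' constraint residual instead, with a warning when it exceeds
#' `rigid_tol`.  The 1,n contribution evaluates the intermolecular form on
#' the pair's combined parameters, with the van der Waals and
#' electrostatic channels scaled separately.
#'
#' @param ff an `ff_component`.
#' @param coords n_sites x 3 matrix of coordinates in Angstrom.
#' @param units unit profile; defaults to the profile the component was
#'   built on.
#' @param rigid_tol warn when a rigid constraint deviates by more than
#'   this (Angstrom or degrees).
#' @return an object of class `ff_energy`: `breakdown` (tibble `kind`,
#'   `energy` over bond/angle/torsion/improper/one_n/special), `residuals`
#'   (tibble of rigid-constraint deviations), `total` and `total_bonded`
#'   (bond + angle + torsion + improper).
#' @examples
#' fx <- make_fixture("n-butane")
#' ff <- build_component_ff(load_bundled(), fx$graph)
#' molecule_energy(ff, fx$coords)
#' @export
molecule_energy <- function(ff, coords, units = NULL, rigid_tol = 1e-6) {
  stopifnot(inherits(ff, "ff_component"))
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(ff$sites) || ncol(coords) != 3L) {
    rlang::abort(sprintf("expected %d x 3 coordinates, got %d x %d",
                         nrow(ff$sites), nrow(coords), ncol(coords)),
                 class = "ffdat_usage_error")
  }
  units <- units %||% unit_profile(ff$units)
  sums <- c(bond = 0, angle = 0, torsion = 0, improper = 0,
            one_n = 0, special = 0)
  resid <- list()

  geom_value <- function(kind, idx) {
    switch(kind,
      bond = dist3(coords, idx[1L], idx[2L]),
      angle = angle3(coords, idx[1L], idx[2L], idx[3L]),
      torsion = dihedral4(coords, idx[1L], idx[2L], idx[3L], idx[4L]),
      improper = improper4(coords, idx[1L], idx[2L], idx[3L], idx[4L]),
      special = dist3(coords, idx[1L], idx[2L]))
  }
  for (r in seq_len(nrow(ff$terms))) {
    kind <- ff$terms$kind[r]
    idx <- ff$terms$sites[[r]]
    g <- geom_value(kind, idx)
    p <- ff$terms$params[[r]]
    if (isTRUE(ff$terms$rigid[r])) {
      dev <- if (kind == "torsion") {
        # angular deviation on the circle
        d <- (g - p[[1L]] + 180) %% 360 - 180
        d
      } else g - p[[1L]]
      resid[[length(resid) + 1L]] <- tibble::tibble(
        kind = kind, sites = paste(idx, collapse = "-"),
        target = p[[1L]], actual = g, deviation = dev,
        ok = abs(dev) <= rigid_tol)
      next
    }
    id <- ff$terms$id[r]
    e <- switch(kind,
      bond = eval_bond(id, p, g),
      angle = {
        if (id == 2L) {
          eval_angle(id, p, g, r_ij = dist3(coords, idx[1L], idx[2L]),
                     r_jk = dist3(coords, idx[2L], idx[3L]))
        } else eval_angle(id, p, g)
      },
      torsion = eval_torsion(id, p, g),
      improper = eval_improper(id, p, g),
      special = eval_special(id, p, g))
    sums[[kind]] <- sums[[kind]] + e
  }
  for (r in seq_len(nrow(ff$scalings))) {
    i <- ff$scalings$i[r]; j <- ff$scalings$j[r]
    pi_ <- ff$sites$params[[i]]; pj <- ff$sites$params[[j]]
    id1 <- ff$sites$id1[i]
    cross <- combine_params(id1, pi_, pj)
    ch <- eval_intermolecular_channels(id1, cross, dist3(coords, i, j), units)
    sums[["one_n"]] <- sums[["one_n"]] +
      ff$scalings$scale_vdw[r] * ch$vdw + ff$scalings$scale_elec[r] * ch$elec
  }
  residuals <- if (length(resid) > 0L) dplyr::bind_rows(resid) else
    tibble::tibble(kind = character(), sites = character(), target = double(),
                   actual = double(), deviation = double(), ok = logical())
  if (any(!residuals$ok)) {
    rlang::warn(sprintf("%d rigid constraint(s) deviate from their fixed value by more than %g",
                        sum(!residuals$ok), rigid_tol))
  }
  structure(
    list(breakdown = tibble::tibble(kind = names(sums), energy = unname(sums)),
         residuals = residuals,
         total_bonded = sum(sums[c("bond", "angle", "torsion", "improper")]),
         total = sum(sums)),
    class = "ff_energy")
}

#' @export
print.ff_energy <- function(x, ...) {
  cat(sprintf("<ff_energy> total %.6g (bonded %.6g)\n", x$total, x$total_bonded))
  print(x$breakdown)
  if (nrow(x$residuals) > 0L) {
    cat(sprintf("  %d rigid constraint(s), max |deviation| %.3g\n",
                nrow(x$residuals), max(abs(x$residuals$deviation))))
  }
  invisible(x)
}

#' Intermolecular energy between two molecules
#'
#' Sums the intermolecular potential over all site pairs of two component
#' force fields, with cross parameters from the combination rules.  Both
#' components must share the intermolecular function id and unit profile.
#'
#' @param ff_a,ff_b `ff_component` objects.
#' @param coords_a,coords_b site-coordinate matrices.
#' @param units unit profile (defaults to the shared profile).
#' @return the pair interaction energy (scalar).
#' @examples
#' ff <- build_component_ff(load_bundled(), make_fixture("methane")$graph)
#' x <- matrix(0, 1, 3)
#' pair_interaction_energy(ff, ff, x, x + c(2^(1/6) * 3.73, 0, 0))  # -148
#' @export
pair_interaction_energy <- function(ff_a, ff_b, coords_a, coords_b,
                                    units = NULL) {
  stopifnot(inherits(ff_a, "ff_component"), inherits(ff_b, "ff_component"))
  if (!identical(ff_a$units, ff_b$units)) {
    rlang::abort("components are on different unit profiles",
                 class = "ffdat_usage_error")
  }
  ids <- unique(c(ff_a$sites$id1, ff_b$sites$id1))
  if (length(ids) != 1L) {
    rlang::abort("components use different intermolecular function ids",
                 class = "ffdat_usage_error")
  }
  units <- units %||% unit_profile(ff_a$units)
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  total <- 0
  for (i in seq_len(nrow(ff_a$sites))) {
    for (j in seq_len(nrow(ff_b$sites))) {
      r <- vnorm(coords_b[j, ] - coords_a[i, ])
      cross <- combine_params(ids, ff_a$sites$params[[i]], ff_b$sites$params[[j]])
      total <- total + eval_intermolecular(ids, cross, r, units)
    }
  }
  total
}
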