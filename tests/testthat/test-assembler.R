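trappe <- load_bundled()

test_that("term enumeration equals the brute-force path oracle on every fixture", {
  for (nm in ua_fixture_names) {
    sg <- type_molecule(make_fixture(nm)$graph)
    terms <- enumerate_terms(sg, special_dists = unique(trappe$special$dist))
    n <- nrow(sg$sites)
    expect_setequal(canon_terms(terms, "bond"), oracle_paths(n, sg$bonds, 1L))
    expect_setequal(canon_terms(terms, "angle"), oracle_paths(n, sg$bonds, 2L))
    expect_setequal(canon_terms(terms, "torsion"), oracle_paths(n, sg$bonds, 3L))
    # 1,n separations against a BFS oracle
    d <- oracle_distances(n, sg$bonds)
    expected_pairs <- character()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && is.finite(d[i, j]) && d[i, j] >= 3) {
        expected_pairs <- c(expected_pairs,
                            sprintf("%d,%d:%d", i, j, d[i, j] + 1))
      }
    }
    got <- terms[terms$kind == "one_n", ]
    expect_setequal(
      sprintf("%d,%d:%d",
              vapply(got$sites, `[`, integer(1), 1),
              vapply(got$sites, `[`, integer(1), 2),
              got$separation + 1L),
      expected_pairs)
  }
})

test_that("chain and branched fixtures enumerate the expected term counts", {
  bu <- enumerate_terms(type_molecule(make_fixture("n-butane")$graph))
  counts <- vapply(c("bond", "angle", "torsion", "improper", "one_n"),
                   function(k) sum(bu$kind == k), integer(1))
  expect_identical(unname(counts), c(3L, 2L, 1L, 0L, 1L))
  expect_identical(bu$separation[bu$kind == "one_n"] + 1L, 4L)

  pe <- enumerate_terms(type_molecule(make_fixture("n-pentane")$graph))
  expect_identical(sum(pe$kind == "bond"), 4L)
  expect_identical(sum(pe$kind == "angle"), 3L)
  expect_identical(sum(pe$kind == "torsion"), 2L)
  expect_identical(sort(pe$separation[pe$kind == "one_n"] + 1L), c(4L, 4L, 5L))

  iso <- enumerate_terms(type_molecule(make_fixture("isobutane")$graph))
  expect_identical(sum(iso$kind == "angle"), 3L)
  expect_identical(sum(iso$kind == "improper"), 1L)
  expect_identical(iso$sites[iso$kind == "improper"][[1]][1], 1L)  # center first
})

test_that("resolution picks the published records for concrete tuples", {
  b <- resolve_term(trappe, "bond", c("A-C-1-1", "A-C-2-1"), 1)
  expect_true(b$rigid)
  expect_equal(b$params, 1.54)

  a <- resolve_term(trappe, "angle", c("A-C-1-1", "A-C-2-1", "A-C-1-1"), c(1, 1))
  expect_identical(a$id, 1L)
  expect_equal(a$params, c(62500, 114))

  t <- resolve_term(trappe, "torsion",
                    c("A-C-1-1", "Ak-C-2-1", "Ak-O-2-1", "Ak-H-1-1"), c(1, 1, 1))
  expect_identical(t$id, 1L)
  expect_equal(t$params, c(0, 209.82, -29.17, 187.93))

  s <- resolve_term(trappe, "special", c("Ak-O-2-1", "Ak-H-1-1"), dist = 4L)
  expect_equal(s$params, 75000000)

  expect_error(resolve_term(trappe, "bond", c("A-C-1-1", "Ak-O-2-1"), 1),
               class = "ffdat_unparameterized_error")
  expect_error(resolve_term(trappe, "bond", c("A-C-X-1", "A-C-2-1"), 1),
               class = "ffdat_usage_error")
})

test_that("resolution is orientation-invariant", {
  tuples <- list(
    list(kind = "bond", tags = c("A-C-1-1", "A-C-2-1"), orders = 1),
    list(kind = "angle", tags = c("A-C-1-1", "Ak-C-2-1", "Ak-O-2-1"),
         orders = c(1, 1)),
    list(kind = "torsion", tags = c("A-C-1-1", "Ak-C-2-1", "Ak-O-2-1", "Ak-H-1-1"),
         orders = c(1, 1, 1)))
  for (tp in tuples) {
    fwd <- resolve_term(trappe, tp$kind, tp$tags, tp$orders)
    bwd <- resolve_term(trappe, tp$kind, rev(tp$tags), rev(tp$orders))
    expect_identical(fwd$row, bwd$row)
    expect_identical(fwd$specificity, bwd$specificity)
  }
})

test_that("a strictly more specific record wins, and ties are an error", {
  augmented <- trappe
  augmented$bond <- dplyr::bind_rows(
    trappe$bond,
    tibble::tibble(tag1 = "A-C-1-1", order = 1L, tag2 = "A-C-2-1",
                   id2 = 1L, p1 = 900000, p2 = 1.54, p3 = NA, p4 = NA,
                   ref = "10.0/synthetic"))
  base <- resolve_term(trappe, "bond", c("A-C-1-1", "A-C-2-1"), 1)
  more <- resolve_term(augmented, "bond", c("A-C-1-1", "A-C-2-1"), 1)
  expect_false(more$rigid)
  expect_gt(more$specificity, base$specificity)
  # removing the specific record again restores the previous winner
  pruned <- augmented
  pruned$bond <- pruned$bond[pruned$bond$ref != "10.0/synthetic", ]
  restored <- resolve_term(pruned, "bond", c("A-C-1-1", "A-C-2-1"), 1)
  expect_identical(restored$row, base$row)
  expect_true(restored$rigid)
  # an equally specific duplicate pattern ties
  tied <- trappe
  tied$bond <- dplyr::bind_rows(
    trappe$bond,
    tibble::tibble(tag1 = "X-C-X-1", order = 1L, tag2 = "A-C-X-X",
                   id2 = 1L, p1 = 1, p2 = 1.54, p3 = NA, p4 = NA,
                   ref = "10.0/synthetic"))
  expect_error(resolve_term(tied, "bond", c("A-C-1-1", "A-C-2-1"), 1),
               class = "ffdat_ambiguity_error")
})

test_that("site resolution uses specificity over the intermolecular table", {
  res <- resolve_site(trappe, "A-C-0-0")
  expect_equal(res$params, c(0, 148, 3.73))
  wild <- trappe
  wild$intermolecular <- dplyr::bind_rows(
    trappe$intermolecular,
    tibble::tibble(tag = "X-C-X-X", id1 = 1L, p1 = 0, p2 = 1, p3 = 1,
                   p4 = NA, ref = "10.0/synthetic"))
  expect_equal(resolve_site(wild, "A-C-0-0")$params, c(0, 148, 3.73))
  expect_error(resolve_site(trappe, "E-O-2-1"),
               class = "ffdat_unparameterized_error")
})

test_that("component builds match the worked examples", {
  eth <- build_component_ff(trappe, make_fixture("ethanol")$graph)
  g <- glance(eth)
  expect_identical(unlist(g[c("n_sites", "n_bond", "n_angle", "n_torsion",
                              "n_improper", "n_special")], use.names = FALSE),
                   c(4L, 3L, 2L, 1L, 0L, 0L))
  expect_true(all(eth$terms$rigid[eth$terms$kind == "bond"]))

  diol <- build_component_ff(trappe, make_fixture("1,2-ethanediol")$graph)
  sp <- diol$terms[diol$terms$kind == "special", ]
  expect_identical(nrow(sp), 2L)
  expect_identical(sp$separation, c(4L, 4L))
  for (k in 1:2) {
    pair <- diol$sites$element[sp$sites[[k]]]
    expect_setequal(pair, c("O", "H"))
  }

  met <- build_component_ff(trappe, make_fixture("methane")$graph)
  expect_identical(nrow(met$terms), 0L)
  expect_identical(nrow(met$sites), 1L)

  # isobutane's improper candidate has no record and is dropped, not fatal
  iso <- build_component_ff(trappe, make_fixture("isobutane")$graph)
  expect_identical(sum(iso$terms$kind == "improper"), 0L)

  # an ether cannot be parameterized by the alkane/alcohol subset
  expect_error(build_component_ff(trappe, make_fixture("dimethyl-ether")$graph),
               class = "ffdat_unparameterized_error")
})

test_that("every neutral fixture is charge-neutral to numerical precision", {
  for (nm in ua_fixture_names) {
    ff <- build_component_ff(trappe, make_fixture(nm)$graph)
    expect_lt(abs(net_charge(ff)), 1e-12)
  }
  # a bare hydroxyl fragment carries the O+H partial charges
  oh <- structure(list(
    name = "hydroxyl", sites = tibble::tibble(element = c("O", "H"),
      fused_h = 0L, group = "Ak", tag = c("Ak-O-2-1", "Ak-H-1-1")),
    bonds = tibble::tibble(i = 1L, j = 2L, order = 1L),
    atom_site = 1:2), class = "ff_sitegraph")
  charges <- vapply(oh$sites$tag, function(t) resolve_site(trappe, t)$params[[1]],
                    numeric(1))
  expect_equal(sum(charges), -0.265)
})

test_that("bonded energies vanish at the reference geometry and match the cis barrier", {
  bu <- make_fixture("n-butane")
  ff <- build_component_ff(trappe, bu$graph)
  e <- molecule_energy(ff, bu$coords)
  expect_equal(e$total_bonded, 0, tolerance = 1e-9)
  expect_true(all(abs(e$residuals$deviation) < 1e-6))

  cis <- ffdat:::chain_coords(rep(1.54, 3), rep(114, 2), 0)
  ec <- molecule_energy(ff, cis)
  expect_equal(ec$breakdown$energy[ec$breakdown$kind == "torsion"], 2292.70,
               tolerance = 1e-6)

  single <- build_component_ff(trappe, make_fixture("methane")$graph)
  es <- molecule_energy(single, matrix(0, 1, 3))
  expect_equal(es$total, 0)

  # distorted rigid bond -> warning plus a flagged residual, still zero energy
  stretched <- bu$coords
  stretched[4, ] <- stretched[4, ] * 1.05
  expect_warning(ed <- molecule_energy(ff, stretched), "rigid")
  expect_true(any(!ed$residuals$ok))
  expect_equal(ed$breakdown$energy[ed$breakdown$kind == "bond"], 0)
})

test_that("1,n channels are scaled separately and excluded pairs are recorded", {
  diol <- make_fixture("1,2-ethanediol")
  ff <- build_component_ff(trappe, diol$graph)
  expect_identical(sort(ff$scalings$n), c(5L, 5L, 6L))
  expect_identical(sort(ff$exclusions$n), c(4L, 4L, 4L))
  e <- molecule_energy(ff, diol$coords)
  one_n <- e$breakdown$energy[e$breakdown$kind == "one_n"]
  # recompute by hand from the scaled channels
  manual <- 0
  for (r in seq_len(nrow(ff$scalings))) {
    i <- ff$scalings$i[r]; j <- ff$scalings$j[r]
    cross <- combine_params(1, ff$sites$params[[i]], ff$sites$params[[j]])
    ch <- eval_intermolecular_channels(1, cross,
                                       sqrt(sum((diol$coords[i, ] - diol$coords[j, ])^2)),
                                       unit_profile("K-A-e"))
    manual <- manual + ff$scalings$scale_vdw[r] * ch$vdw +
      ff$scalings$scale_elec[r] * ch$elec
  }
  expect_equal(one_n, manual)
})

test_that("pair interaction energies follow the combination rules", {
  met <- build_component_ff(trappe, make_fixture("methane")$graph)
  x0 <- matrix(0, 1, 3)
  at <- function(r) matrix(c(r, 0, 0), 1, 3)
  expect_equal(pair_interaction_energy(met, met, x0, at(3.73)), 0)
  expect_equal(pair_interaction_energy(met, met, x0, at(2^(1/6) * 3.73)), -148)
  # methane against a lone CH3-type site: combined sigma 3.74 -> zero crossing
  ch3 <- met
  ch3$sites$tag <- "A-C-1-1"
  ch3$sites$params[[1]] <- resolve_site(trappe, "A-C-1-1")$params
  expect_equal(pair_interaction_energy(met, ch3, x0, at(3.74)), 0)
})

test_that("component JSON export is deterministic", {
  ff <- build_component_ff(trappe, make_fixture("ethanol")$graph)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_component_json(ff, f1)
  write_component_json(ff, f2)
  expect_identical(readLines(f1), readLines(f2))
  doc <- jsonlite::fromJSON(f1)
  expect_identical(doc$units, "K-A-e")
  expect_identical(nrow(doc$sites), 4L)
  expect_true(all(startsWith(doc$terms$ref, "10.")))
})
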