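# e^2 / (4 pi eps0) in eV * Angstrom, and Boltzmann's constant in eV/K
.e2_4pieps0_eV_A <- 14.399645
.kB_eV <- 8.617333262e-5

#' Unit profiles
#'
#' Potential evaluators are unit-agnostic: energies come out on whatever
#' scale the stored parameters use.  The only place a physical constant
#' enters is the point-charge Coulomb term, whose prefactor
#' \eqn{e^2/(4\pi\varepsilon_0)} depends on the energy unit.  Two profiles
#' are provided: `"eV-A-e"` (energies in eV) and `"K-A-e"` (energies divided
#' by Boltzmann's constant, the Kelvin scale on which TraPPE parameters are
#' conventionally printed).  No conversion between scales is ever performed
#' implicitly.
#'
#' @param name `"K-A-e"` or `"eV-A-e"`.
#' @param dielectric relative dielectric constant used by the intermolecular
#'   form with an explicit \eqn{1/\varepsilon_l} factor (default 1, vacuum).
#' @return a list with elements `name`, `energy_unit`, `coulomb`
#'   (energy*Angstrom/e^2) and `dielectric`, of class `ff_units`.
#' @examples
#' unit_profile("K-A-e")$coulomb
#' @export
unit_profile <- function(name = c("K-A-e", "eV-A-e"), dielectric = 1) {
  name <- match.arg(name)
  coulomb <- switch(name,
    "eV-A-e" = .e2_4pieps0_eV_A,
    "K-A-e"  = .e2_4pieps0_eV_A / .kB_eV
  )
  structure(
    list(name = name,
         energy_unit = if (name == "K-A-e") "K" else "eV",
         coulomb = coulomb, dielectric = dielectric),
    class = "ff_units"
  )
}

#' Potential-function registry
#'
#' Every interaction in the data scheme is written against a registry of
#' parametric potential functions, keyed by (section, id).  The registry
#' records the arity (number of stored parameters) and parameter names of
#' each form; the built-in entries cover the published function lists for
#' the intermolecular, bond, angle, torsion, improper and special sections.
#' New forms can be added at runtime by row-binding an entry with a `fun`
#' closure and passing the extended registry to the evaluators.
#'
#' Angles are stored and passed in degrees throughout; harmonic angle
#' constants are therefore on the energy/deg^2 scale of the stored data.
#'
#' @return a tibble with columns `section`, `id`, `arity`, `params`
#'   (list of parameter-name vectors) and `fun` (list of evaluator
#'   closures).
#' @examples
#' ff_potentials()
#' @export
ff_potentials <- function() {
  reg <- tibble::tribble(
    ~section, ~id, ~arity, ~params,
    "intermolecular", 1L, 3L, c("q", "eps", "sigma"),
    "intermolecular", 2L, 4L, c("q", "eps", "sigma", "n"),
    "intermolecular", 3L, 3L, c("q", "eps", "sigma"),
    "intermolecular", 4L, 3L, c("q", "eps", "r_min"),
    "bond", 1L, 2L, c("k2", "r0"),
    "bond", 2L, 4L, c("k2", "k3", "k4", "r0"),
    "bond", 3L, 2L, c("k4", "r0"),
    "angle", 1L, 2L, c("l2", "theta0"),
    "angle", 2L, 9L, c("l2", "l3", "l4", "theta0", "k2", "r1", "r2", "N1", "N2"),
    "angle", 3L, 2L, c("theta0", "c"),
    "torsion", 1L, 4L, c("c0", "c1", "c2", "c3"),
    "torsion", 2L, 2L, c("c", "phi0"),
    "torsion", 3L, 7L, paste0("c", 0:6),
    "torsion", 4L, 2L, c("c0", "phi0"),
    "torsion", 5L, 8L, paste0("c", 0:7),
    "torsion", 6L, 12L, c("c1", "n1", "phi1", "c2", "n2", "phi2",
                          "c3", "n3", "phi3", "c4", "n4", "phi4"),
    "improper", 1L, 2L, c("l2", "psi0"),
    "special", 1L, 1L, "k12"
  )
  reg$fun <- purrr::pmap(reg[c("section", "id")], function(section, id) {
    switch(section,
      bond     = function(p, r) eval_bond(id, p, r),
      angle    = function(p, theta, ...) eval_angle(id, p, theta, ...),
      torsion  = function(p, phi) eval_torsion(id, p, phi),
      improper = function(p, psi) eval_improper(id, p, psi),
      special  = function(p, r) eval_special(id, p, r),
      intermolecular = function(p, r, units = unit_profile())
        eval_intermolecular(id, p, r, units)
    )
  })
  reg
}

#' @rdname ff_potentials
#' @param section section name; `id` the function identifier within it.
#' @param id integer function identifier.
#' @return `potential_arity()` returns the arity of a registered form.
#' @export
potential_arity <- function(section, id, registry = ff_potentials()) {
  row <- registry[registry$section == section & registry$id == id, ]
  if (nrow(row) == 0L) {
    rlang::abort(sprintf("no potential function with id %s in section '%s'",
                         format(id), section),
                 class = "ffdat_registry_error")
  }
  row$arity[[1L]]
}

#' @rdname ff_potentials
#' @param registry a potential registry tibble.
#' @export
known_potential <- function(section, id, registry = ff_potentials()) {
  nrow(registry[registry$section == section & registry$id == id, ]) > 0L
}

cosd <- function(x) cospi(x / 180)

#' Mie prefactor
#'
#' The repulsive-exponent-dependent prefactor
#' \eqn{C_n = (n/(n-6)) (n/6)^{6/(n-6)}} of the (n, 6) Mie potential.
#' For n = 12 it reduces to the familiar Lennard-Jones factor 4.
#'
#' @param n_ij repulsive exponent(s), must exceed 6.
#' @return numeric vector of prefactors.
#' @examples
#' mie_prefactor(12)  # 4
#' @export
mie_prefactor <- function(n_ij) {
  if (any(n_ij <= 6)) {
    rlang::abort("the Mie prefactor requires n > 6", class = "ffdat_domain_error")
  }
  (n_ij / (n_ij - 6)) * (n_ij / 6)^(6 / (n_ij - 6))
}

#' Combination rules for unlike intermolecular pairs
#'
#' Cross parameters between two site types follow the rule attached to the
#' intermolecular form: charges multiply (`q_ij = q_ii q_jj`), dispersion
#' energies combine geometrically, size parameters (`sigma` or `r_min`)
#' arithmetically, and for the Mie form the exponent combines arithmetically
#' as well.
#'
#' @param id1 intermolecular function id (1-4).
#' @param params_i,params_j like-pair parameter vectors, aligned to the
#'   form's parameter names (see [ff_potentials()]).
#' @return the cross-interaction parameter vector, same layout; its first
#'   entry is the charge *product* `q_ij`.
#' @examples
#' combine_params(1, c(0, 148, 3.73), c(0, 98, 3.75))
#' @export
combine_params <- function(id1, params_i, params_j) {
  arity <- potential_arity("intermolecular", id1)
  if (length(params_i) < arity || length(params_j) < arity) {
    rlang::abort(sprintf("intermolecular id %d needs %d parameters", id1, arity),
                 class = "ffdat_usage_error")
  }
  q <- params_i[[1L]] * params_j[[1L]]
  eps <- sqrt(params_i[[2L]] * params_j[[2L]])
  size <- (params_i[[3L]] + params_j[[3L]]) / 2
  if (id1 == 2L) c(q, eps, size, (params_i[[4L]] + params_j[[4L]]) / 2)
  else c(q, eps, size)
}

#' Evaluate potential functions
#'
#' Closed-form energy evaluators for each registered potential form.  All
#' distances are in Angstrom, all angles in degrees; the energy scale is
#' whatever scale the parameters are on (see [unit_profile()] for the
#' Coulomb term).
#'
#' `eval_intermolecular()` evaluates the van der Waals plus point-charge
#' energy of a *cross* parameter set (as returned by [combine_params()]);
#' `eval_intermolecular_channels()` returns the two channels separately,
#' which is what the scaled 1,n machinery needs.
#'
#' @param id1,id2,id3,id4,id5,id7 function identifier within the respective
#'   section.
#' @param p numeric parameter vector aligned to the form's parameter names.
#' @param r,r_ij,r_jk distances in Angstrom.
#' @param theta,phi,psi bond angle, torsion angle, out-of-plane angle in
#'   degrees.
#' @param units a [unit_profile()].
#' @return energy (numeric, vectorized over the geometric argument).
#' @examples
#' eval_intermolecular(1, c(0, 148, 3.73), 3.73, unit_profile("K-A-e"))  # 0
#' eval_torsion(1, c(0, 355.03, -68.19, 791.32), 180)                    # 0
#' @export
eval_intermolecular <- function(id1, p, r, units = unit_profile("K-A-e")) {
  ch <- eval_intermolecular_channels(id1, p, r, units)
  ch$vdw + ch$elec
}

#' @rdname eval_intermolecular
#' @return `eval_intermolecular_channels()`: a list with numeric elements
#'   `vdw` and `elec`.
#' @export
eval_intermolecular_channels <- function(id1, p, r, units = unit_profile("K-A-e")) {
  if (any(r <= 0)) {
    rlang::abort("intermolecular potentials require r > 0", class = "ffdat_domain_error")
  }
  q <- p[[1L]]
  if (id1 %in% c(1L, 2L, 3L)) {
    eps <- p[[2L]]; sigma <- p[[3L]]
    sr6 <- (sigma / r)^6
    vdw <- if (id1 == 2L) {
      n <- p[[4L]]
      mie_prefactor(n) * eps * ((sigma / r)^n - sr6)
    } else {
      4 * eps * (sr6^2 - sr6)
    }
    elec <- units$coulomb * q / r
  } else if (id1 == 4L) {
    eps <- p[[2L]]; rmin <- p[[3L]]
    rr6 <- (rmin / r)^6
    vdw <- eps * (rr6^2 - rr6)
    elec <- units$coulomb * q / (units$dielectric * r)
  } else {
    rlang::abort(sprintf("no intermolecular function with id %s", format(id1)),
                 class = "ffdat_registry_error")
  }
  list(vdw = vdw, elec = elec)
}

#' @rdname eval_intermolecular
#' @export
eval_bond <- function(id2, p, r) {
  switch(as.character(id2),
    "1" = p[[1L]] / 2 * (r - p[[2L]])^2,
    "2" = {
      d <- r - p[[4L]]
      p[[1L]] * d^2 + p[[2L]] * d^3 + p[[3L]] * d^4
    },
    "3" = p[[1L]] / 4 * (r^2 - p[[2L]]^2)^2,
    rlang::abort(sprintf("no bond function with id %s", format(id2)),
                 class = "ffdat_registry_error")
  )
}

#' @rdname eval_intermolecular
#' @export
eval_angle <- function(id3, p, theta, r_ij = NULL, r_jk = NULL) {
  switch(as.character(id3),
    "1" = p[[1L]] / 2 * (theta - p[[2L]])^2,
    "2" = {
      if (is.null(r_ij) || is.null(r_jk)) {
        rlang::abort("angle form 2 couples to distances: r_ij and r_jk are required",
                     class = "ffdat_usage_error")
      }
      dth <- theta - p[[4L]]
      d1 <- r_ij - p[[6L]]; d2 <- r_jk - p[[7L]]
      p[[1L]] * dth^2 + p[[2L]] * dth^3 + p[[3L]] * dth^4 +
        p[[5L]] * d1 * d2 + p[[8L]] * d1 * dth + p[[9L]] * d2 * dth
    },
    "3" = p[[2L]] * (cosd(theta) - cosd(p[[1L]]))^2 / 2,
    rlang::abort(sprintf("no angle function with id %s", format(id3)),
                 class = "ffdat_registry_error")
  )
}

#' @rdname eval_intermolecular
#' @export
eval_torsion <- function(id4, p, phi) {
  switch(as.character(id4),
    "1" = p[[1L]] + p[[2L]] * (1 + cosd(phi)) + p[[3L]] * (1 - cosd(2 * phi)) +
          p[[4L]] * (1 + cosd(3 * phi)),
    "2" = p[[1L]] * (phi - p[[2L]])^2 / 2,
    "3" = {
      out <- 0
      for (i in 0:6) out <- out + p[[i + 1L]] * cosd(i * phi)
      out
    },
    "4" = p[[1L]] * (1 - cosd(2 * phi + p[[2L]])),
    "5" = {
      out <- 0
      for (i in 0:7) out <- out + p[[i + 1L]] * cosd(phi)^i
      out
    },
    "6" = {
      out <- 0
      for (i in 1:4) {
        ci <- p[[3L * (i - 1L) + 1L]]
        ni <- p[[3L * (i - 1L) + 2L]]
        phii <- p[[3L * (i - 1L) + 3L]]
        out <- out + ci * (1 + cosd(ni * phi - phii))
      }
      out
    },
    rlang::abort(sprintf("no torsion function with id %s", format(id4)),
                 class = "ffdat_registry_error")
  )
}

#' @rdname eval_intermolecular
#' @export
eval_improper <- function(id5, p, psi) {
  if (!identical(as.integer(id5), 1L)) {
    rlang::abort(sprintf("no improper function with id %s", format(id5)),
                 class = "ffdat_registry_error")
  }
  p[[1L]] * (psi - p[[2L]])^2 / 2
}

#' @rdname eval_intermolecular
#' @export
eval_special <- function(id7, p, r) {
  if (!identical(as.integer(id7), 1L)) {
    rlang::abort(sprintf("no special function with id %s", format(id7)),
                 class = "ffdat_registry_error")
  }
  if (any(r <= 0)) {
    rlang::abort("special potentials require r > 0", class = "ffdat_domain_error")
  }
  p[[1L]] / r^12
}

#' Scaled 1,n interactions
#'
#' Sites of one molecule separated by n-1 bonds interact through the
#' intermolecular form scaled per channel.  An explicit rule table (the
#' sixth dataset section) overrides the defaults; absent a rule, the scaling
#' is 0 for n <= 4 and 1 for n > 4 on both the van der Waals and the
#' electrostatic channel.
#'
#' @param rules a tibble with columns `n`, `scaling1` (vdW), `scaling2`
#'   (electrostatic); may have zero rows.
#' @param n bond-count separation plus one (n > 1).
#' @return named numeric vector `c(vdw = , elec = )`.
#' @examples
#' scale_1n(NULL, 4)  # c(vdw = 0, elec = 0)
#' scale_1n(NULL, 5)  # c(vdw = 1, elec = 1)
#' @export
scale_1n <- function(rules, n) {
  stopifnot(length(n) == 1L, n > 1)
  if (!is.null(rules) && nrow(rules) > 0L) {
    hit <- rules[rules$n == n, ]
    if (nrow(hit) > 0L) {
      return(c(vdw = hit$scaling1[[1L]], elec = hit$scaling2[[1L]]))
    }
  }
  if (n <= 4) c(vdw = 0, elec = 0) else c(vdw = 1, elec = 1)
}
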