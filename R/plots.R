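#' Plot a potential-energy curve
#'
#' Draws one registered potential form over a range of its geometric
#' argument — distance for intermolecular/bond/special forms, angle for
#' the rest.
#'
#' @param section section name (see [ff_potentials()]).
#' @param id function id within the section.
#' @param params numeric parameter vector.
#' @param from,to range of the geometric argument (Angstrom or degrees;
#'   defaults: 0-360 for torsions, 0-180 for angles/impropers, and a
#'   size-parameter based window otherwise).
#' @param units unit profile for the Coulomb term of intermolecular forms.
#' @param n number of grid points.
#' @return a ggplot object.
#' @examples
#' plot_potential("torsion", 1, c(0, 355.03, -68.19, 791.32))
#' @export
plot_potential <- function(section, id, params, from = NULL, to = NULL,
                           units = unit_profile("K-A-e"), n = 361) {
  angular <- section %in% c("angle", "torsion", "improper")
  size <- if (!angular && length(params) >= 3L) params[[3L]] else 1
  if (is.null(from)) from <- if (angular) 0 else 0.8 * size
  if (is.null(to)) to <- if (section == "torsion") 360 else if (angular) 180 else 2.5 * size
  x <- seq(from, to, length.out = n)
  y <- switch(section,
    intermolecular = vapply(x, function(r) eval_intermolecular(id, params, r, units), numeric(1)),
    bond = eval_bond(id, params, x),
    angle = eval_angle(id, params, x),
    torsion = eval_torsion(id, params, x),
    improper = eval_improper(id, params, x),
    special = eval_special(id, params, x),
    rlang::abort(sprintf("unknown section '%s'", section), class = "ffdat_usage_error"))
  ggplot2::ggplot(tibble::tibble(x = x, energy = y),
                  ggplot2::aes(x = .data$x, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (angular) "angle [deg]" else "r [Å]",
      y = sprintf("energy [%s]", units$energy_unit),
      title = sprintf("%s potential, id %d", section, id)) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.ff_dataset
#' @param object an `ff_component`.
#' @return `autoplot()` returns a ggplot bar chart of the component's term
#'   counts by kind.
#' @export
autoplot.ff_component <- function(object, ...) {
  counts <- dplyr::count(object$terms, .data$kind)
  extra <- tibble::tibble(
    kind = c("1,n scaled", "1,n excluded"),
    n = c(nrow(object$scalings), nrow(object$exclusions)))
  df <- dplyr::bind_rows(counts, extra)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "count",
                  title = sprintf("%s: resolved interaction terms", object$name)) +
    ggplot2::theme_minimal()
}
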