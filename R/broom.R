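#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summarize datasets and components
#'
#' `tidy()` on an `ff_dataset` stacks all seven sections into one long
#' tibble with a `section` column; on an `ff_component` it returns one row
#' per resolved term.  `glance()` gives the one-row summary (record or
#' term counts, net charge, unit profile).
#'
#' @param x an `ff_dataset` or `ff_component`.
#' @param ... unused.
#' @return a tibble.
#' @examples
#' tidy(load_bundled())
#' glance(build_component_ff(load_bundled(), make_fixture("ethanol")$graph))
#' @export
tidy.ff_dataset <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(
    stats::setNames(names(.ff_sections), names(.ff_sections)),
    function(sec, nm) {
      df <- section_to_storage(x[[sec]], sec)
      if (nrow(df) == 0L) return(NULL)
      df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.character))
      dplyr::bind_cols(tibble::tibble(section = sec), df)
    }))
}

#' @rdname tidy.ff_dataset
#' @export
glance.ff_dataset <- function(x, ...) {
  counts <- purrr::map_int(names(.ff_sections), ~ nrow(x[[.x]]))
  out <- tibble::as_tibble(as.list(stats::setNames(counts, paste0("n_", names(.ff_sections)))))
  dplyr::bind_cols(tibble::tibble(name = x$name, units = x$units), out)
}

#' @rdname tidy.ff_dataset
#' @export
tidy.ff_component <- function(x, ...) {
  dplyr::mutate(x$terms,
    sites = vapply(x$terms$sites, paste, character(1), collapse = "-"),
    orders = vapply(x$terms$orders, paste, character(1), collapse = "-"),
    tags = vapply(x$terms$sites, function(idx)
      paste(x$sites$tag[idx], collapse = " "), character(1)),
    params = vapply(x$terms$params, paste, character(1), collapse = ", "))
}

#' @rdname tidy.ff_dataset
#' @export
glance.ff_component <- function(x, ...) {
  counts <- table(factor(x$terms$kind,
                         levels = c("bond", "angle", "torsion", "improper", "special")))
  tibble::tibble(
    name = x$name, source = x$source, units = x$units,
    n_sites = nrow(x$sites),
    n_bond = as.integer(counts[["bond"]]),
    n_angle = as.integer(counts[["angle"]]),
    n_torsion = as.integer(counts[["torsion"]]),
    n_improper = as.integer(counts[["improper"]]),
    n_special = as.integer(counts[["special"]]),
    n_one_n_scaled = nrow(x$scalings),
    n_one_n_excluded = nrow(x$exclusions),
    net_charge = net_charge(x))
}
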