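#' Interaction-site tags
#'
#' A tag is the four-part identifier naming an interaction-site type in a
#' transferable force field: `group-site-nbonds-maxorder`, e.g. `"A-C-2-1"`
#' for the CH2 site of an alkane chain.  The four parts are
#' \describe{
#'   \item{group}{functional-group abbreviation (see [ff_groups()])}
#'   \item{site}{element symbol of the atom, or `"C"` for a carbon with its
#'     fused hydrogens in a united-atom model}
#'   \item{n_bonds}{number of bonds the site forms with other interaction
#'     sites (fused hydrogens are not sites; explicit polar hydrogens are)}
#'   \item{max_order}{highest bond order the site enters into}
#' }
#' The literal `"X"` in any part is a wildcard matching an arbitrary entry.
#' A tag with no wildcard is *concrete*; otherwise it is a *pattern*.
#'
#' @param x character vector of tag strings.
#' @return `parse_tag()` returns a tibble with one row per tag and columns
#'   `group`, `site` (character, `NA` = wildcard), `n_bonds`, `max_order`
#'   (integer, `NA` = wildcard).
#' @examples
#' parse_tag(c("A-C-2-1", "X-C-X-1"))
#' format_tag(parse_tag("Ak-O-2-1"))
#' tag_matches("A-C-X-X", "A-C-1-1")
#' tag_specificity(c("A-C-2-1", "X-X-X-X"))
#' @export
parse_tag <- function(x) {
  stopifnot(is.character(x), length(x) > 0L)
  parts <- stringr::str_split(x, stringr::fixed("-"))
  bad_n <- lengths(parts) != 4L
  if (any(bad_n)) {
    rlang::abort(
      sprintf("tag '%s' has %d field(s); a tag is exactly 4 fields joined by '-'",
              x[bad_n][1L], lengths(parts)[bad_n][1L]),
      class = "ffdat_parse_error"
    )
  }
  m <- do.call(rbind, parts)
  for (k in 1:2) {
    empty <- !nzchar(m[, k])
    if (any(empty)) {
      rlang::abort(
        sprintf("tag '%s': part %d is empty", x[empty][1L], k),
        class = "ffdat_parse_error"
      )
    }
  }
  int_part <- function(v, k) {
    out <- rep(NA_integer_, length(v))
    conc <- v != "X"
    bad <- conc & !stringr::str_detect(v, "^[0-9]+$")
    if (any(bad)) {
      rlang::abort(
        sprintf("tag '%s': part %d ('%s') must be a nonnegative integer or 'X'",
                x[bad][1L], k, v[bad][1L]),
        class = "ffdat_parse_error"
      )
    }
    out[conc] <- as.integer(v[conc])
    out
  }
  tibble::tibble(
    group     = ifelse(m[, 1] == "X", NA_character_, m[, 1]),
    site      = ifelse(m[, 2] == "X", NA_character_, m[, 2]),
    n_bonds   = int_part(m[, 3], 3L),
    max_order = int_part(m[, 4], 4L)
  )
}

#' @rdname parse_tag
#' @param tags a tibble as returned by [parse_tag()], or four vectors given
#'   via `group`, `site`, `n_bonds`, `max_order`.
#' @param group,site,n_bonds,max_order tag fields (`NA` = wildcard); used
#'   when `tags` is missing.
#' @return `format_tag()` returns the canonical tag strings;
#'   `parse_tag(format_tag(t))` recovers `t`.
#' @export
format_tag <- function(tags = NULL, group = NULL, site = NULL,
                       n_bonds = NULL, max_order = NULL) {
  if (!is.null(tags)) {
    group <- tags$group; site <- tags$site
    n_bonds <- tags$n_bonds; max_order <- tags$max_order
  }
  fmt <- function(v) ifelse(is.na(v), "X", as.character(v))
  ok_str <- function(v, part) {
    conc <- !is.na(v)
    if (any(conc & (!nzchar(v) | stringr::str_detect(v, stringr::fixed("-"))), na.rm = TRUE))
      rlang::abort(sprintf("tag part %d may not be empty or contain '-'", part),
                   class = "ffdat_usage_error")
  }
  ok_str(group, 1L); ok_str(site, 2L)
  if (any(c(n_bonds, max_order) < 0, na.rm = TRUE))
    rlang::abort("tag parts 3-4 must be >= 0", class = "ffdat_usage_error")
  paste(fmt(group), fmt(site), fmt(n_bonds), fmt(max_order), sep = "-")
}

#' @rdname parse_tag
#' @param pattern,concrete tag strings; `pattern` may contain wildcards,
#'   `concrete` must not.
#' @return `tag_matches()` returns a logical vector: `TRUE` where every
#'   non-wildcard field of `pattern` equals the corresponding field of
#'   `concrete` (both arguments are recycled to a common length).
#' @export
tag_matches <- function(pattern, concrete) {
  p <- parse_tag(pattern)
  c_ <- parse_tag(concrete)
  if (anyNA(c_)) {
    rlang::abort("'concrete' tags may not contain wildcards",
                 class = "ffdat_usage_error")
  }
  n <- max(nrow(p), nrow(c_))
  p <- p[rep_len(seq_len(nrow(p)), n), ]
  c_ <- c_[rep_len(seq_len(nrow(c_)), n), ]
  field_ok <- function(pf, cf) is.na(pf) | (!is.na(cf) & pf == cf)
  field_ok(p$group, c_$group) & field_ok(p$site, c_$site) &
    field_ok(p$n_bonds, c_$n_bonds) & field_ok(p$max_order, c_$max_order)
}

#' @rdname parse_tag
#' @return `tag_specificity()` returns the number of non-wildcard fields of
#'   each tag, an integer in 0..4 used to rank competing pattern matches.
#' @export
tag_specificity <- function(x) {
  p <- parse_tag(x)
  as.integer(rowSums(!is.na(p)))
}

#' @rdname parse_tag
#' @return `is_concrete_tag()` returns `TRUE` where the tag has no wildcard
#'   field.
#' @export
is_concrete_tag <- function(x) {
  tag_specificity(x) == 4L
}

#' Functional-group registry
#'
#' The built-in list of functional groups available as the first tag part.
#' Each row gives the abbreviation, a human name, and the structural motif
#' the group stands for (as a formula-style description).  The registry is
#' data: extend it by row-binding your own entries and passing the result to
#' functions that take a `groups` argument.
#'
#' @return a tibble with columns `abbrev`, `name`, `motif`.
#' @examples
#' ff_groups()
#' known_group("Ak")
#' @export
ff_groups <- function() {
  tibble::tribble(
    ~abbrev, ~name,              ~motif,
    "A",     "alkane",           "CHx-CHx, CHx=CHx, CHx#CHx (alkene/alkyne also 'A')",
    "Ac",    "acrylate",         "CHx-O-C(=O)-CH=CH2",
    "Ace",   "acetal",           "CHx-O-C(-X)2-O-CHx",
    "Ad",    "amide",            "CHx-C(=O)-N-X2",
    "Ak",    "alcohol",          "CHx-O-H",
    "Al",    "aldehyde",         "X-C(-H)=O",
    "Am",    "amine",            "CHx-N-X2",
    "B",     "benzene",          "CH-CH (aromatic 6-ring)",
    "CA",    "cycloalkane",      "CH2-CH2 (ring, 6 < size < 18)",
    "CA5",   "cyclopentane",     "CH2-CH2 (ring size 5)",
    "CA6",   "cyclohexane",      "CH2-CH2 (ring size 6)",
    "Cac",   "carboxylic acid",  "CHx-C(=O)-O-H",
    "DS",    "disulfide",        "CHx-S-S-CHx",
    "E",     "ether",            "CHx-O-CHx",
    "Es",    "ester",            "CHx-C(=O)-O-CHx",
    "K",     "ketone",           "CHx-C(=O)-CHx",
    "mAc",   "methacrylate",     "CHx-O-C(=O)-C(-CH3)=CHx",
    "Nl",    "nitrile",          "CHx-C#N",
    "No",    "nitro",            "CHx-N-O2",
    "Sd",    "sulfide",          "CHx-S-CHx",
    "Tl",    "thiol",            "CHx-S-H"
  )
}

#' @rdname ff_groups
#' @param abbrev character vector of group abbreviations.
#' @param groups a group registry tibble (default: the built-in one).
#' @return `known_group()` returns `TRUE` where `abbrev` is registered.
#' @export
known_group <- function(abbrev, groups = ff_groups()) {
  abbrev %in% groups$abbrev
}
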