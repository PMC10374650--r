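#' Resolve a term against a dataset
#'
#' Finds the dataset record governing a concrete interaction tuple.
#' Candidates are records whose tag tuple and bond orders match in forward
#' or reversed orientation (improper: the central tag fixed, the three
#' neighbors matched as a multiset); the winner is the candidate with the
#' highest total specificity — the number of non-wildcard tag fields
#' matched plus one per exact (non-wildcard) bond order.  A tie between
#' two distinct records is an error rather than a silent first match, and
#' so is the absence of any candidate.
#'
#' @param dataset an [ff_dataset()].
#' @param kind `"bond"`, `"angle"`, `"torsion"`, `"improper"` or
#'   `"special"`.
#' @param tags concrete tag strings of the participating sites, in tuple
#'   order (improper: center first).
#' @param orders integer bond orders along the tuple (not used for
#'   `special`).
#' @param dist bond-count separation (`special` only).
#' @return a list with elements `section`, `row` (record index in the
#'   section tibble), `id` (function id, `NA` = rigid), `params` (numeric,
#'   trimmed to the function's arity; for rigid entries the fixed value),
#'   `rigid`, `ref` and `specificity`.
#' @examples
#' resolve_term(load_bundled(), "bond", c("A-C-1-1", "A-C-2-1"), 1)
#' @export
resolve_term <- function(dataset, kind, tags, orders = integer(),
                         dist = NULL) {
  stopifnot(is_ff_dataset(dataset))
  kind <- match.arg(kind, c("bond", "angle", "torsion", "improper", "special"))
  if (!all(is_concrete_tag(tags))) {
    rlang::abort("term tags must be concrete (no wildcards)",
                 class = "ffdat_usage_error")
  }
  df <- dataset[[kind]]
  s <- .ff_sections[[kind]]
  cand_rows <- integer(); cand_spec <- integer()
  for (r in seq_len(nrow(df))) {
    spec <- record_match_spec(df[r, ], kind, tags, orders, dist)
    if (!is.na(spec)) {
      cand_rows <- c(cand_rows, r); cand_spec <- c(cand_spec, spec)
    }
  }
  if (length(cand_rows) == 0L) {
    rlang::abort(
      sprintf("no %s record matches (%s)%s", kind,
              paste(tags, collapse = ", "),
              if (!is.null(dist)) sprintf(" at dist %d", dist) else ""),
      class = "ffdat_unparameterized_error")
  }
  best <- max(cand_spec)
  winners <- cand_rows[cand_spec == best]
  if (length(winners) > 1L) {
    rlang::abort(
      c(sprintf("ambiguous %s resolution for (%s): %d records tie at specificity %d",
                kind, paste(tags, collapse = ", "), length(winners), best),
        vapply(winners, function(r) {
          paste(unlist(section_to_storage(df[r, ], kind)[
            c(s$tags, s$orders, intersect("dist", names(df)))]), collapse = " ")
        }, character(1))),
      class = "ffdat_ambiguity_error")
  }
  r <- winners[[1L]]
  id <- df[[s$id]][r]
  rigid <- is.na(id)
  np <- if (rigid) 1L else potential_arity(if (kind == "special") "special" else kind, id)
  params <- as.numeric(unlist(df[r, paste0("p", seq_len(np))]))
  list(section = kind, row = r, id = id, params = params, rigid = rigid,
       ref = df$ref[r], specificity = as.integer(best))
}

# specificity of one record against a concrete tuple, NA when it does not
# match in either orientation
record_match_spec <- function(rec, kind, tags, orders, dist = NULL) {
  s <- .ff_sections[[kind]]
  rec_tags <- as.character(rec[1, s$tags])
  rec_orders <- as.integer(rec[1, s$orders])

  tuple_spec <- function(ptags, porders, ctags, corders) {
    if (!all(tag_matches(ptags, ctags))) return(NA_integer_)
    omatch <- is.na(porders) | porders == corders
    if (!all(omatch)) return(NA_integer_)
    sum(tag_specificity(ptags)) + sum(!is.na(porders))
  }

  if (kind == "improper") {
    if (!isTRUE(tag_matches(rec_tags[1L], tags[1L]))) return(NA_integer_)
    best <- NA_integer_
    for (perm in .perm3) {
      # record neighbor slots (tag, order) are permuted together and
      # matched against the concrete neighbors as a multiset
      sp <- tuple_spec(rec_tags[1L + perm], rec_orders[perm],
                       tags[2:4], orders)
      if (!is.na(sp)) sp <- sp + tag_specificity(rec_tags[1L])
      best <- if (is.na(best)) sp else max(best, sp, na.rm = TRUE)
    }
    return(best)
  }
  if (kind == "special") {
    if (rec$dist != dist) return(NA_integer_)
    fwd <- tuple_spec(rec_tags, integer(), tags, integer())
    rev_ <- tuple_spec(rev(rec_tags), integer(), tags, integer())
    return(if (all(is.na(c(fwd, rev_)))) NA_integer_ else max(fwd, rev_, na.rm = TRUE))
  }
  fwd <- tuple_spec(rec_tags, rec_orders, tags, orders)
  rev_ <- tuple_spec(rev(rec_tags), rev(rec_orders), tags, rev(orders))
  if (all(is.na(c(fwd, rev_)))) NA_integer_ else max(fwd, rev_, na.rm = TRUE)
}

.perm3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

#' Resolve the intermolecular record of a concrete site tag
#'
#' @param dataset an [ff_dataset()].
#' @param tag a concrete tag string.
#' @return a list with `row`, `id1`, `params` (trimmed to arity; `params[1]`
#'   is the site charge), `ref`, `specificity`.
#' @examples
#' resolve_site(load_bundled(), "A-C-0-0")
#' @export
resolve_site <- function(dataset, tag) {
  stopifnot(is_ff_dataset(dataset), length(tag) == 1L)
  if (!is_concrete_tag(tag)) {
    rlang::abort("site tag must be concrete", class = "ffdat_usage_error")
  }
  df <- dataset$intermolecular
  hits <- which(tag_matches(df$tag, rep(tag, nrow(df))))
  if (length(hits) == 0L) {
    rlang::abort(sprintf("no intermolecular record matches tag %s", tag),
                 class = "ffdat_unparameterized_error")
  }
  spec <- tag_specificity(df$tag[hits])
  best <- max(spec)
  winners <- hits[spec == best]
  if (length(winners) > 1L) {
    rlang::abort(
      sprintf("ambiguous intermolecular resolution for %s: records %s tie",
              tag, paste(winners, collapse = ", ")),
      class = "ffdat_ambiguity_error")
  }
  r <- winners[[1L]]
  id1 <- df$id1[r]
  np <- potential_arity("intermolecular", id1)
  list(row = r, id1 = id1,
       params = as.numeric(unlist(df[r, paste0("p", seq_len(np))])),
       ref = df$ref[r], specificity = as.integer(best))
}
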