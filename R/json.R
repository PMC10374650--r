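#' Serialize a component force field as JSON
#'
#' Writes the built model — typed sites with intermolecular parameters,
#' resolved term lists, 1,n scalings and exclusions, provenance DOIs and
#' the unit profile — as a JSON document with sorted keys and full float
#' precision, so identical inputs always produce byte-identical files.
#'
#' @param ff an `ff_component`.
#' @param path output file.
#' @return `path`, invisibly.
#' @examples
#' ff <- build_component_ff(load_bundled(), make_fixture("ethanol")$graph)
#' write_component_json(ff, tempfile(fileext = ".json"))
#' @export
write_component_json <- function(ff, path) {
  stopifnot(inherits(ff, "ff_component"))
  doc <- list(
    exclusions = purrr::pmap(ff$exclusions, function(i, j, n)
      list(i = i, j = j, n = n)),
    name = ff$name,
    scalings = purrr::pmap(ff$scalings, function(i, j, n, scale_vdw, scale_elec)
      list(i = i, j = j, n = n, scale_elec = scale_elec, scale_vdw = scale_vdw)),
    sites = purrr::pmap(ff$sites,
      function(site, element, fused_h, group, tag, id1, params, charge, ref)
        list(charge = charge, element = element, fused_h = fused_h,
             group = group, id1 = id1, params = params, ref = ref,
             site = site, tag = tag)),
    source = ff$source,
    terms = purrr::pmap(ff$terms,
      function(kind, sites, orders, separation, id, params, rigid, ref, record_row)
        list(id = if (is.na(id)) "none" else id, kind = kind,
             orders = orders, params = params, ref = ref, rigid = rigid,
             separation = separation, sites = sites)),
    units = ff$units
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
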