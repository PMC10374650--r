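#' Molecular graphs
#'
#' A molecular graph is the all-atom connectivity of one molecule: a tibble
#' of atoms (element symbols) and a tibble of bonds with integer orders.
#' Build one programmatically with `molecular_graph()` or read it from a
#' MOL/SDF V2000 file with [read_molfile()].
#'
#' @param elements character vector of element symbols (case-sensitive,
#'   multi-letter symbols like `"Cl"` allowed).
#' @param bonds a data frame (or matrix) with columns `i`, `j`, `order`;
#'   1-based atom indices, integer order >= 1.
#' @param name optional molecule name.
#' @return an object of class `ff_molgraph` with elements `name`, `atoms`
#'   (tibble with column `element`) and `bonds` (tibble `i`, `j`, `order`,
#'   stored with `i < j`).
#' @examples
#' methane <- molecular_graph(c("C", "H", "H", "H", "H"),
#'   data.frame(i = 1, j = 2:5, order = 1), name = "methane")
#' @export
molecular_graph <- function(elements, bonds, name = NULL) {
  stopifnot(is.character(elements), length(elements) > 0L)
  bonds <- tibble::as_tibble(as.data.frame(bonds))
  if (nrow(bonds) > 0L) {
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    bonds <- tibble::tibble(
      i = pmin(as.integer(bonds$i), as.integer(bonds$j)),
      j = pmax(as.integer(bonds$i), as.integer(bonds$j)),
      order = as.integer(bonds$order)
    )
    if (any(bonds$i == bonds$j)) {
      rlang::abort("self-loops are not allowed", class = "ffdat_structure_error")
    }
    if (any(bonds$j > length(elements)) || any(bonds$i < 1L)) {
      rlang::abort("bond index out of range", class = "ffdat_structure_error")
    }
    if (anyDuplicated(bonds[c("i", "j")])) {
      rlang::abort("duplicate bonds are not allowed", class = "ffdat_structure_error")
    }
    if (any(bonds$order < 1L)) {
      rlang::abort("bond orders must be >= 1", class = "ffdat_structure_error")
    }
  } else {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = integer())
  }
  structure(
    list(name = name %||% "molecule",
         atoms = tibble::tibble(element = elements),
         bonds = bonds),
    class = "ff_molgraph"
  )
}

#' @export
print.ff_molgraph <- function(x, ...) {
  counts <- sort(table(x$atoms$element), decreasing = TRUE)
  cat(sprintf("<ff_molgraph> %s: %d atoms (%s), %d bonds\n", x$name,
              nrow(x$atoms),
              paste(sprintf("%s%d", names(counts), counts), collapse = " "),
              nrow(x$bonds)))
  invisible(x)
}

#' Read a MOL/SDF V2000 file
#'
#' Parses the first molecule of a MOL or SDF V2000 file (via ChemmineR)
#' into a molecular graph.  The file must be kekulized: the aromatic bond
#' type 4 is rejected, as are query bond types and the V3000 format.
#'
#' @param path file path.
#' @param name molecule name (default: the file's title line, falling back
#'   to the file stem).
#' @return an `ff_molgraph` (see [molecular_graph()]).
#' @export
read_molfile <- function(path, name = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: %s", path), class = "ffdat_format_error")
  }
  txt <- readLines(path, warn = FALSE)
  if (any(stringr::str_detect(txt, stringr::fixed("V3000")))) {
    rlang::abort("V3000 connection tables are not supported; supply V2000",
                 class = "ffdat_format_error")
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) {
      rlang::abort(sprintf("cannot parse '%s' as MOL/SDF V2000: %s",
                           path, conditionMessage(e)),
                   class = "ffdat_format_error")
    })
  mol <- sdf[[1L]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  bonds <- tibble::tibble(
    i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
    order = as.integer(bb[, 3L])
  )
  if (any(bonds$order == 4L)) {
    rlang::abort("aromatic bond type 4 found: kekulized input required",
                 class = "ffdat_format_error")
  }
  if (any(bonds$order > 4L)) {
    rlang::abort("query bond types (> 4) are not supported",
                 class = "ffdat_format_error")
  }
  title <- stringr::str_trim(txt[1L])
  molecular_graph(elements, bonds,
                  name = name %||% (if (nzchar(title)) title
                                    else sub("\\.[^.]*$", "", basename(path))))
}

#' Write a molecular graph as a MOL V2000 file
#'
#' Companion writer for [read_molfile()]; coordinates default to zeros
#' (the connection table, not geometry, is the payload).
#'
#' @param graph an `ff_molgraph`.
#' @param path output file.
#' @param coords optional n x 3 matrix of atom coordinates.
#' @return `path`, invisibly.
#' @export
write_molfile <- function(graph, path, coords = NULL) {
  stopifnot(inherits(graph, "ff_molgraph"))
  n <- nrow(graph$atoms); m <- nrow(graph$bonds)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  lines <- c(
    graph$name, "  ffdat", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], graph$atoms$element),
    if (m > 0L) sprintf("%3d%3d%3d  0", graph$bonds$i, graph$bonds$j, graph$bonds$order),
    "M  END"
  )
  writeLines(lines, path)
  invisible(path)
}

mol_igraph <- function(atoms_n, bonds) {
  igraph::graph_from_data_frame(
    d = if (nrow(bonds) > 0L) bonds[, c("i", "j")] else data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(atoms_n))
  )
}
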