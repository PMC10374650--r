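#' Bundled transferable force field: TraPPE-UA alkanes and alcohols
#'
#' The alkane and alcohol subset of the TraPPE united-atom force field,
#' transcribed into the seven-section data scheme.  TraPPE-UA is
#' semi-flexible: all bonds are rigid (`"none"` entries with the fixed
#' length in `p1`), angles are harmonic, torsions use the four-coefficient
#' cosine series, the improper section is empty, 1,n interactions follow
#' the scheme defaults (no explicit rules), and two special `k12/r^12`
#' repulsions guard the hydroxyl hydrogen at bond separations 4 and 5.
#' Energies are on the Kelvin scale (epsilon/kB), distances in Angstrom,
#' angles in degrees; `ref` columns carry the DOIs of the original TraPPE
#' publications.
#'
#' @param name dataset identifier; only `"trappe-ua-alkane-alcohol"` is
#'   bundled.
#' @return an [ff_dataset()] with 11 intermolecular, 3 bond, 5 angle,
#'   11 torsion, 0 improper, 0 explicit 1,n and 2 special records.
#' @examples
#' trappe <- load_bundled()
#' trappe$intermolecular
#' @export
load_bundled <- function(name = "trappe-ua-alkane-alcohol") {
  if (!identical(name, "trappe-ua-alkane-alcohol")) {
    rlang::abort(sprintf("no bundled dataset named '%s'", name),
                 class = "ffdat_usage_error")
  }
  doi1 <- "10.1021/jp972543+"   # TraPPE 1: linear alkanes
  doi2 <- "10.1021/jp984742e"   # TraPPE 2: branched alkanes
  doi5 <- "10.1021/jp003882x"   # TraPPE 5: alcohols
  doi6 <- "10.1021/jp049459w"   # TraPPE 6: glycols/multifunctional

  intermolecular <- tibble::tribble(
    ~tag,        ~id1, ~p1,    ~p2,  ~p3,  ~ref,
    "A-C-0-0",   1L,   0,      148,  3.73, doi1,
    "A-C-1-1",   1L,   0,      98,   3.75, doi1,
    "A-C-2-1",   1L,   0,      46,   3.95, doi1,
    "A-C-3-1",   1L,   0,      10,   4.68, doi2,
    "A-C-4-1",   1L,   0,      0.5,  6.4,  doi2,
    "Ak-O-2-1",  1L,   -0.700, 93,   3.02, doi5,
    "Ak-H-1-1",  1L,   0.435,  0,    0,    doi5,
    "Ak-C-1-1",  1L,   0.265,  98,   3.75, doi5,
    "Ak-C-2-1",  1L,   0.265,  46,   3.95, doi5,
    "Ak-C-3-1",  1L,   0.265,  10,   4.33, doi5,
    "Ak-C-4-1",  1L,   0.265,  0.5,  5.8,  doi5
  )
  intermolecular$p4 <- NA_real_

  bond <- tibble::tribble(
    ~tag1,       ~order, ~tag2,       ~id2,          ~p1,   ~ref,
    "X-C-X-1",   1L,     "X-C-X-1",   NA_integer_,   1.54,  doi1,
    "Ak-C-X-X",  1L,     "Ak-O-2-1",  NA_integer_,   1.43,  doi5,
    "Ak-H-1-1",  1L,     "Ak-O-2-1",  NA_integer_,   0.945, doi5
  )
  bond[paste0("p", 2:4)] <- NA_real_

  angle <- tibble::tribble(
    ~tag1,       ~order1, ~tag2,       ~order2, ~tag3,       ~id3, ~p1,    ~p2,     ~ref,
    "X-C-X-X",   1L,      "X-C-2-1",   1L,      "X-C-X-X",   1L,   62500,  114,     doi1,
    "X-C-X-X",   1L,      "X-C-3-1",   1L,      "X-C-X-X",   1L,   62500,  112,     doi2,
    "X-C-X-X",   1L,      "X-C-4-1",   1L,      "X-C-X-X",   1L,   62500,  109.47,  doi2,
    "X-C-X-X",   1L,      "Ak-C-X-1",  1L,      "Ak-O-2-1",  1L,   50400,  109.47,  doi5,
    "Ak-C-X-1",  1L,      "Ak-O-2-1",  1L,      "Ak-H-1-1",  1L,   55400,  108.5,   doi5
  )
  angle[paste0("p", 3:9)] <- NA_real_

  torsion <- tibble::tribble(
    ~tag1,      ~order1, ~tag2,       ~order2, ~tag3,       ~order3, ~tag4,       ~id4, ~p1,     ~p2,    ~p3,     ~p4,     ~ref,
    "X-C-X-X",  1L,      "X-C-2-1",   1L,      "X-C-2-1",   1L,      "X-C-X-X",   1L,   0,       355.03, -68.19,  791.32,  doi1,
    "X-C-X-X",  1L,      "X-C-2-1",   1L,      "X-C-3-1",   1L,      "X-C-X-X",   1L,   -251.06, 428.73, -111.85, 441.27,  doi2,
    "X-C-X-X",  1L,      "X-C-2-1",   1L,      "X-C-4-1",   1L,      "X-C-X-X",   1L,   0,       0,      0,       461.29,  doi2,
    "X-C-X-X",  1L,      "X-C-3-1",   1L,      "X-C-3-1",   1L,      "X-C-X-X",   1L,   -251.06, 428.73, -111.85, 441.27,  doi2,
    "X-C-X-X",  1L,      "X-C-2-1",   1L,      "X-C-3-2",   1L,      "X-C-X-X",   1L,   0,       0,      0,       461.29,  doi2,
    "X-C-X-X",  1L,      "Ak-C-2-1",  1L,      "Ak-O-2-1",  1L,      "Ak-H-1-1",  1L,   0,       209.82, -29.17,  187.93,  doi5,
    "X-C-X-X",  1L,      "Ak-C-3-1",  1L,      "Ak-O-2-1",  1L,      "Ak-H-1-1",  1L,   215.96,  197.33, 31.46,   -173.92, doi5,
    "X-C-X-X",  1L,      "Ak-C-4-1",  1L,      "Ak-O-2-1",  1L,      "Ak-H-1-1",  1L,   0,       0,      0,       163.56,  doi5,
    "X-C-X-X",  1L,      "X-C-2-X",   1L,      "X-C-2-1",   1L,      "X-O-2-1",   1L,   0,       176.62, -53.34,  769.93,  doi5,
    "X-C-X-X",  1L,      "X-C-X-1",   1L,      "X-O-2-1",   1L,      "X-C-X-1",   1L,   0,       725.35, -163.75, 558.2,   doi6,
    "X-O-2-1",  1L,      "X-C-2-1",   1L,      "X-C-2-1",   1L,      "X-O-2-1",   1L,   503.24,  0,      -251.62, 1006.47, doi6
  )
  torsion[paste0("p", 5:12)] <- NA_real_

  special <- tibble::tribble(
    ~tag1,       ~dist, ~tag2,       ~id7, ~p1,       ~ref,
    "Ak-O-X-X",  4L,    "X-H-1-1",   1L,   75000000,  doi6,
    "Ak-O-X-X",  5L,    "X-H-1-1",   1L,   75000000,  doi6
  )
  special$p2 <- NA_real_

  ff_dataset(name = name, units = "K-A-e",
             intermolecular = intermolecular, bond = bond, angle = angle,
             torsion = torsion, special = special)
}
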