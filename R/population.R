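# Mulliken population analysis from precomputed density (P) and overlap
# (S) matrices: q_A = Z_A - sum_{mu in A} (P S)_{mu mu}. The SCF step that
# produces P is a separate concern; this module only partitions electrons.

#' Validated input for population analysis
#'
#' @param P Symmetric density matrix (n basis functions square).
#' @param S Symmetric overlap matrix, unit diagonal.
#' @param basis_map Integer vector: basis function index -> atom index.
#' @param Z Nuclear charge per atom.
#' @param total_charge Total molecular charge (integer).
#' @return An object of class `population_input`.
#' @details Validation enforces matching dimensions, `diag(S) = 1` within
#'   1e-8, symmetry of both matrices, and the electron-count consistency
#'   `trace(P S) = sum(Z) - total_charge` within 1e-6. Inconsistent inputs
#'   are refused rather than silently renormalized.
#' @export
population_input <- function(P, S, basis_map, Z, total_charge = 0L) {
  P <- as.matrix(P); S <- as.matrix(S)
  nb <- nrow(P)
  if (ncol(P) != nb || any(dim(S) != nb)) {
    stop("P and S must be square matrices of the same dimension",
         call. = FALSE)
  }
  if (length(basis_map) != nb) {
    stop("`basis_map` must have one entry per basis function", call. = FALSE)
  }
  basis_map <- as.integer(basis_map)
  n_atoms <- length(Z)
  if (any(basis_map < 1L | basis_map > n_atoms)) {
    stop("`basis_map` entries must index into `Z`", call. = FALSE)
  }
  if (max(abs(P - t(P))) > 1e-8 || max(abs(S - t(S))) > 1e-8) {
    stop("P and S must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(S) - 1)) > 1e-8) {
    stop("S must have a unit diagonal", call. = FALSE)
  }
  n_elec <- sum(diag(P %*% S))
  expected <- sum(Z) - total_charge
  if (abs(n_elec - expected) > 1e-6) {
    stop(sprintf(
      "electron-count inconsistency: trace(PS) = %.8f but sum(Z) - charge = %g",
      n_elec, expected), call. = FALSE)
  }
  structure(list(P = P, S = S, basis_map = basis_map, Z = as.numeric(Z),
                 total_charge = as.integer(total_charge)),
            class = "population_input")
}

#' Read a population-analysis input directory
#'
#' Expects `P.txt` and `S.txt` (whitespace-delimited square matrices) and
#' `header.json` with `basis_map`, `Z` and `total_charge`, as written by
#' [make_mulliken_fixture()].
#'
#' @param dir Directory path.
#' @return A `population_input`.
#' @export
read_population_dir <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                             simplifyVector = TRUE)
  population_input(read_matrix_file(file.path(dir, "P.txt")),
                   read_matrix_file(file.path(dir, "S.txt")),
                   hdr$basis_map, hdr$Z, hdr$total_charge)
}

#' Mulliken atomic partial charges
#'
#' Computes gross orbital populations `diag(P S)` and atomic charges
#' `q_A = Z_A - sum_{mu in A} (P S)_{mu mu}`. Charge conservation
#' `sum(q) = total_charge` holds by construction given the validated
#' electron count.
#'
#' @param input A [population_input()].
#' @return Object of class `mulliken_charges`: list with `q` (per atom,
#'   elementary charge units), `gross_orbital_populations` (per basis
#'   function), and `total_charge`.
#' @export
mulliken_charges <- function(input) {
  stopifnot(inherits(input, "population_input"))
  gop <- diag(input$P %*% input$S)
  q <- input$Z - as.numeric(tapply(gop, factor(input$basis_map,
                                               levels = seq_along(input$Z)),
                                   sum, default = 0))
  structure(list(q = unname(q), gross_orbital_populations = gop,
                 total_charge = input$total_charge),
            class = "mulliken_charges")
}

#' @export
print.mulliken_charges <- function(x, ...) {
  cat("Mulliken atomic charges (e):\n")
  print(round(x$q, 6))
  cat(sprintf("  sum = %g (total molecular charge %d)\n", sum(x$q),
              x$total_charge))
  invisible(x)
}

#' Charge-colored molecule depiction
#'
#' Renders the molecule with atoms colored by Mulliken charge on a
#' diverging red/blue scale. By default negative charge (high electron
#' density) is red and positive charge blue; set
#' `negative_color = "blue"` for the opposite orientation.
#'
#' @param mol A `molgraph` whose atom count matches the charge vector.
#' @param charges A `mulliken_charges` result.
#' @param file Optional SVG output path.
#' @param negative_color `"red"` (default) or `"blue"`.
#' @param ... Passed to [render_molecule_map()].
#' @return The SVG document as a character string (invisibly when written
#'   to file).
#' @export
charge_map <- function(mol, charges, file = NULL,
                       negative_color = c("red", "blue"), ...) {
  stopifnot(inherits(mol, "molgraph"), inherits(charges, "mulliken_charges"))
  negative_color <- match.arg(negative_color)
  if (nrow(mol$atoms) != length(charges$q)) {
    stop(sprintf("molecule has %d atoms but %d charges were supplied",
                 nrow(mol$atoms), length(charges$q)), call. = FALSE)
  }
  w <- if (negative_color == "red") -charges$q else charges$q
  render_molecule_map(mol, w, file = file, ...)
}
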