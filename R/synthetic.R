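# Synthetic inputs with exact ground truth for every downstream stage:
# a solubility table whose logS is an exact additive function of
# functional-group counts, analytic Mulliken population fixtures, and the
# transcribed ROESY contact lists.

.FRAGMENT_CATALOGUE <- c("methyl", "methylene", "hydroxyl", "carbonyl",
                         "phenyl", "carboxyl")

# default group contributions, logS units (log10 mol/L) per group instance:
# hydrophobic groups depress aqueous solubility, polar groups raise it
.DEFAULT_CONTRIBUTION <- c(
  methyl = -0.55, methylene = -0.45, hydroxyl = 0.9,
  carbonyl = 0.5, phenyl = -1.3, carboxyl = 0.7
)

#' Specification for a synthetic solubility data set
#'
#' The generator grows a random linear or singly branched alkane skeleton
#' (3-12 carbons) and decorates it with functional groups; every heavy atom
#' then belongs to exactly one fragment class (skeletal CH3 count as
#' `methyl`, other skeletal carbons as `methylene`), and the noiseless logS
#' is `intercept_true + sum_f count_f * true_contribution_f` exactly.
#'
#' @param n_molecules Number of molecules to generate (>= 1).
#' @param fragment_vocab Fragment identifiers to use; must be drawn from
#'   `methyl`, `methylene`, `hydroxyl`, `carbonyl`, `phenyl`, `carboxyl`.
#' @param true_contribution Named numeric map fragment -> logS increment;
#'   defaults to built-in group-contribution values.
#' @param intercept_true Baseline logS.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param seed Integer seed; the same spec always generates a byte-identical
#'   table.
#' @return An object of class `solubility_spec`.
#' @export
solubility_spec <- function(n_molecules = 500L,
                            fragment_vocab = .FRAGMENT_CATALOGUE,
                            true_contribution = NULL,
                            intercept_true = 0.5,
                            noise_sd = 0.3,
                            seed = 1L) {
  if (!(length(n_molecules) == 1L && n_molecules >= 1)) {
    stop("`n_molecules` must be at least 1", call. = FALSE)
  }
  if (!(length(noise_sd) == 1L && noise_sd >= 0)) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  bad <- setdiff(fragment_vocab, .FRAGMENT_CATALOGUE)
  if (length(bad) > 0L) {
    stop(sprintf("configuration error: unknown fragment identifier(s): %s (available: %s)",
                 paste(bad, collapse = ", "),
                 paste(.FRAGMENT_CATALOGUE, collapse = ", ")), call. = FALSE)
  }
  if (is.null(true_contribution)) {
    true_contribution <- .DEFAULT_CONTRIBUTION[fragment_vocab]
  }
  bad <- setdiff(names(true_contribution), .FRAGMENT_CATALOGUE)
  if (length(bad) > 0L) {
    stop(sprintf("configuration error: unknown fragment identifier(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(
    n_molecules = as.integer(n_molecules),
    fragment_vocab = fragment_vocab,
    true_contribution = true_contribution,
    intercept_true = intercept_true,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "solubility_spec")
}

# run `expr` under a private RNG stream, restoring global state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic SMILES + logS table with exact ground truth
#'
#' @param spec A [solubility_spec()].
#' @return A list with:
#'   \describe{
#'     \item{table}{Data frame `id`, `smiles`, `logS`.}
#'     \item{truth}{List with `fragment_counts` (molecules x fragments
#'       matrix), `noiseless` (logS without noise), `atom_fragments`
#'       (per molecule, the fragment class of each heavy atom, indexed in
#'       SMILES atom order), `molecules` (the `molgraph` objects, same
#'       order), `intercept_true`, and `true_contribution`.}
#'   }
#' @export
generate_solubility_dataset <- function(spec) {
  stopifnot(inherits(spec, "solubility_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_molecules
    mols <- vector("list", n)
    atom_frag <- vector("list", n)
    counts <- matrix(0L, nrow = n, ncol = length(.FRAGMENT_CATALOGUE),
                     dimnames = list(NULL, .FRAGMENT_CATALOGUE))
    smiles <- character(n)
    for (i in seq_len(n)) {
      g <- .generate_molecule(spec$fragment_vocab)
      sm <- write_smiles(g$mol)
      ord <- attr(sm, "atom_order")
      mol <- .permute_molgraph(g$mol, ord)
      mol$smiles <- as.character(sm)
      smiles[i] <- as.character(sm)
      mols[[i]] <- mol
      atom_frag[[i]] <- g$atom_fragment[ord]
      counts[i, names(g$counts)] <- g$counts
    }
    contrib <- numeric(length(.FRAGMENT_CATALOGUE))
    names(contrib) <- .FRAGMENT_CATALOGUE
    contrib[names(spec$true_contribution)] <- spec$true_contribution
    noiseless <- spec$intercept_true + as.numeric(counts %*% contrib)
    logS <- noiseless + rnorm(n, 0, spec$noise_sd)
    list(
      table = data.frame(id = sprintf("mol%04d", seq_len(n)),
                         smiles = smiles, logS = logS,
                         stringsAsFactors = FALSE),
      truth = list(fragment_counts = counts, noiseless = noiseless,
                   atom_fragments = atom_frag, molecules = mols,
                   intercept_true = spec$intercept_true,
                   true_contribution = spec$true_contribution)
    )
  })
}

# reorder atoms of a molgraph by `ord` (ord[k] = old index of new atom k)
.permute_molgraph <- function(mol, ord) {
  inv <- integer(length(ord))
  inv[ord] <- seq_along(ord)
  mol$atoms <- mol$atoms[ord, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol$bonds$from <- inv[mol$bonds$from]
  mol$bonds$to <- inv[mol$bonds$to]
  mol
}

# one random decorated alkane; returns construction-order molgraph,
# per-atom fragment class, and instance counts
.generate_molecule <- function(vocab) {
  element <- character(0); aromatic <- logical(0)
  bf <- integer(0); bt <- integer(0); bo <- numeric(0)
  frag <- character(0)            # per-atom fragment tag ("" = skeletal C)
  free_h <- integer(0)            # spare valence per atom

  add_atom <- function(el, arom, tag, valence) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    frag[length(frag) + 1L] <<- tag
    free_h[length(free_h) + 1L] <<- valence
    length(element)
  }
  add_bond <- function(a, b, o) {
    bf[length(bf) + 1L] <<- a; bt[length(bt) + 1L] <<- b
    bo[length(bo) + 1L] <<- o
    free_h[a] <<- free_h[a] - o; free_h[b] <<- free_h[b] - o
  }

  # Skeleton: linear chain with one optional branch, 3-7 carbons total.
  # The cap keeps every skeletal carbon within graph distance 3 of a chain
  # end, so radius-2 environments identify the skeleton and the additive
  # ground truth stays representable by binary ECFP4 bits (interior CH2
  # runs of longer chains hash to one shared bit, which would make the
  # methylene count unrecoverable by design).
  len <- sample(3:7, 1L)
  prev <- add_atom("C", FALSE, "", 4L)
  for (k in seq_len(len - 1L)) {
    a <- add_atom("C", FALSE, "", 4L)
    add_bond(prev, a, 1); prev <- a
  }
  if (len >= 5L && len < 7L && runif(1) < 0.3) {
    blen <- sample(seq_len(min(2L, 7L - len)), 1L)
    at <- sample(2:(len - 1L), 1L)
    prev <- at
    for (k in seq_len(blen)) {
      a <- add_atom("C", FALSE, "", 4L)
      add_bond(prev, a, 1); prev <- a
    }
  }

  decorations <- intersect(vocab, c("hydroxyl", "carbonyl", "carboxyl",
                                    "phenyl", "methyl"))
  counts <- integer(length(.FRAGMENT_CATALOGUE))
  names(counts) <- .FRAGMENT_CATALOGUE
  n_dec <- min(rpois(1L, 1.3), 3L)
  if (length(decorations) > 0L && n_dec > 0L) {
    for (d in seq_len(n_dec)) {
      kind <- sample(decorations, 1L)
      need <- if (kind == "carbonyl") 2L else 1L
      sites <- which(frag == "" & element == "C" & free_h >= need)
      if (kind == "carbonyl") {
        # avoid aldehyde-like terminal carbonyls: keep interior carbons
        deg <- tabulate(c(bf, bt), nbins = length(element))
        sites <- sites[deg[sites] >= 2L]
      }
      if (length(sites) == 0L) next
      at <- if (length(sites) == 1L) sites else sample(sites, 1L)
      if (kind == "hydroxyl") {
        o <- add_atom("O", FALSE, "hydroxyl", 2L)
        add_bond(at, o, 1)
        counts["hydroxyl"] <- counts["hydroxyl"] + 1L
      } else if (kind == "methyl") {
        c1 <- add_atom("C", FALSE, "", 4L)   # classified by H count later
        add_bond(at, c1, 1)
      } else if (kind == "carbonyl") {
        o <- add_atom("O", FALSE, "carbonyl", 2L)
        add_bond(at, o, 2)
        frag[at] <- "carbonyl"
        counts["carbonyl"] <- counts["carbonyl"] + 1L
      } else if (kind == "carboxyl") {
        c1 <- add_atom("C", FALSE, "carboxyl", 4L)
        o1 <- add_atom("O", FALSE, "carboxyl", 2L)
        o2 <- add_atom("O", FALSE, "carboxyl", 2L)
        add_bond(at, c1, 1); add_bond(c1, o1, 2); add_bond(c1, o2, 1)
        counts["carboxyl"] <- counts["carboxyl"] + 1L
      } else if (kind == "phenyl") {
        ring <- vapply(1:6, function(j) add_atom("C", TRUE, "phenyl", 4L),
                       integer(1))
        for (j in 1:5) add_bond(ring[j], ring[j + 1L], 1.5)
        add_bond(ring[6L], ring[1L], 1.5)
        add_bond(at, ring[1L], 1)
        counts["phenyl"] <- counts["phenyl"] + 1L
      }
    }
  }

  # classify remaining carbons by attached hydrogen count
  skeletal <- which(frag == "")
  frag[skeletal] <- ifelse(free_h[skeletal] == 3L, "methyl", "methylene")
  counts["methyl"] <- sum(frag == "methyl")
  counts["methylene"] <- sum(frag == "methylene")

  mol <- .build_molgraph(element, aromatic, rep(0L, length(element)),
                         rep(NA_integer_, length(element)),
                         bf, bt, bo, NA_character_)
  list(mol = mol, atom_fragment = frag, counts = counts[names(counts) %in%
                                                          .FRAGMENT_CATALOGUE])
}

# ---------------------------------------------------------------------------
# Mulliken population fixtures with analytically known charges

.MULLIKEN_CASES <- c("orthonormal_neutral", "h2_symmetric", "asymmetric_ionic")

#' Analytic population-analysis fixtures
#'
#' Three small cases whose Mulliken charges are known in closed form:
#' \describe{
#'   \item{orthonormal_neutral}{Identity overlap, diagonal density with
#'     per-atom traces equal to the nuclear charges: all charges 0.}
#'   \item{h2_symmetric}{Two-center minimal-basis H2 with overlap
#'     s = 0.659 and P = (1/(1+s)) * ones: diag(PS) = 1 per atom, charges
#'     (0, 0) for any s in (0, 1).}
#'   \item{asymmetric_ionic}{Identity overlap, P = diag(1.8, 0.2), Z =
#'     (1, 1): charges (-0.8, +0.8).}
#' }
#'
#' @param case_name One of `orthonormal_neutral`, `h2_symmetric`,
#'   `asymmetric_ionic`.
#' @param dir Optional directory; when given, the fixture is written as
#'   plain-text matrix files `P.txt` and `S.txt` plus `header.json`
#'   (basis -> atom map, nuclear charges, total charge) and
#'   `expected.json` (the analytic charges).
#' @return A list with `P`, `S`, `basis_map`, `Z`, `total_charge`,
#'   `expected_charges`, and `case`.
#' @export
make_mulliken_fixture <- function(case_name, dir = NULL) {
  if (!(is.character(case_name) && length(case_name) == 1L &&
        case_name %in% .MULLIKEN_CASES)) {
    stop(sprintf("unknown population-analysis case '%s'; available: %s",
                 as.character(case_name)[1],
                 paste(.MULLIKEN_CASES, collapse = ", ")), call. = FALSE)
  }
  fx <- switch(case_name,
    orthonormal_neutral = {
      # C and O, 3 + 4 orthonormal basis functions, diagonal density
      P <- diag(c(2, 2, 2, 2, 2, 2, 2))
      list(P = P, S = diag(7), basis_map = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
           Z = c(6, 8), total_charge = 0L, expected_charges = c(0, 0))
    },
    h2_symmetric = {
      s <- 0.659
      P <- matrix(1 / (1 + s), 2, 2)
      S <- matrix(c(1, s, s, 1), 2, 2)
      list(P = P, S = S, basis_map = c(1L, 2L), Z = c(1, 1),
           total_charge = 0L, expected_charges = c(0, 0))
    },
    asymmetric_ionic = {
      list(P = diag(c(1.8, 0.2)), S = diag(2), basis_map = c(1L, 2L),
           Z = c(1, 1), total_charge = 0L, expected_charges = c(-0.8, 0.8))
    })
  fx$case <- case_name
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_file(fx$P, file.path(dir, "P.txt"))
    write_matrix_file(fx$S, file.path(dir, "S.txt"))
    jsonlite::write_json(
      list(basis_map = fx$basis_map, Z = fx$Z,
           total_charge = fx$total_charge, case = case_name),
      file.path(dir, "header.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(expected_charges = fx$expected_charges),
                         file.path(dir, "expected.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  fx
}

#' Write / read a whitespace-delimited plain-text matrix
#' @param m A numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_file <- function(m, path) {
  write.table(format(m, digits = 17, scientific = FALSE, trim = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_file
#' @export
read_matrix_file <- function(path) {
  as.matrix(read.table(path, header = FALSE))
}

# ---------------------------------------------------------------------------
# ROESY contact fixtures (transcribed cross-peak lists)

#' Transcribed ROESY contact tables for the 14-6-14 gemini / MP system
#'
#' The 2 mM spectrum shows exactly two solute-surfactant cross-peaks
#' (H4-Hc, H22-Hc); the 5 mM spectrum shows three (H4-Hc, H20-He, H22-Hc).
#' Intensities are presence/absence (1): the source spectra are reported
#' qualitatively.
#'
#' @param concentration_label `"2mM"` or `"5mM"`.
#' @param path Optional CSV path to write the table to (columns
#'   `solute_proton,surfactant_proton,intensity`).
#' @return A `contact_table` (see [contact_table()]) with concentration and
#'   temperature metadata.
#' @export
make_contact_fixture <- function(concentration_label, path = NULL) {
  entries <- switch(as.character(concentration_label)[1],
    "2mM" = data.frame(solute_proton = c("H4", "H22"),
                       surfactant_proton = c("Hc", "Hc"),
                       intensity = c(1, 1), stringsAsFactors = FALSE),
    "5mM" = data.frame(solute_proton = c("H4", "H20", "H22"),
                       surfactant_proton = c("Hc", "He", "Hc"),
                       intensity = c(1, 1, 1), stringsAsFactors = FALSE),
    stop(sprintf("unknown concentration label '%s'; available: 2mM, 5mM",
                 as.character(concentration_label)[1]), call. = FALSE))
  tab <- contact_table(entries,
                       concentration_mM = as.numeric(sub("mM", "",
                                                         concentration_label)),
                       temperature_K = 298.2)
  if (!is.null(path)) write_contact_table(tab, path)
  tab
}
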