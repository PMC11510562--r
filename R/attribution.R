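# From bit coefficients to atoms: every on bit of a query fingerprint
# carries its model coefficient; that contribution is assigned to the
# center atoms of the environments that set the bit (the similarity-map
# convention), split equally when one bit has several environments.
# Summed per atom, the weights conserve the non-intercept part of the
# prediction exactly.

#' Per-bit contributions of a query fingerprint under a model
#'
#' For binary fingerprints the contribution of each on bit is simply its
#' model coefficient; off bits contribute nothing and are absent.
#'
#' @param model A `bayes_ridge` fit.
#' @param fp A `fingerprint` with matching `nbits`.
#' @return Named numeric vector: on-bit index (0-based, as a name) ->
#'   contribution (logS units). The values sum to
#'   `predict(model, fp) - intercept`.
#' @export
bit_contributions <- function(model, fp) {
  stopifnot(inherits(model, "bayes_ridge"), inherits(fp, "fingerprint"))
  if (fp$nbits != model$p) {
    stop(sprintf("fingerprint length %g does not match model (%d bits)",
                 fp$nbits, model$p), call. = FALSE)
  }
  contrib <- model$coefficients[fp$on_bits + 1]
  names(contrib) <- format(fp$on_bits, scientific = FALSE, trim = TRUE)
  contrib
}

#' Map bit contributions onto atoms
#'
#' @param mol The query `molgraph`.
#' @param fp Its `fingerprint` (with `bit_info` provenance).
#' @param contributions Named vector from [bit_contributions()].
#' @param mode `"center"` (default): each bit's contribution is split
#'   equally across the center atoms of its environments. `"spread"`:
#'   each environment's share is further divided equally over all atoms of
#'   the environment (a sensitivity-analysis alternative).
#' @return Object of class `atom_attribution`: list with `weights` (one
#'   signed logS contribution per atom), `normalization` (max absolute
#'   weight, used for symmetric color scaling), and `mode`.
#' @export
atom_attribution <- function(mol, fp, contributions,
                             mode = c("center", "spread")) {
  stopifnot(inherits(mol, "molgraph"), inherits(fp, "fingerprint"))
  mode <- match.arg(mode)
  w <- numeric(nrow(mol$atoms))
  for (bit in names(contributions)) {
    envs <- fp$bit_info[[bit]]
    if (is.null(envs) || nrow(envs) == 0L) {
      stop(sprintf("internal inconsistency: bit %s has no environments", bit),
           call. = FALSE)
    }
    share <- contributions[[bit]] / nrow(envs)
    for (e in seq_len(nrow(envs))) {
      if (mode == "center") {
        w[envs$center[e]] <- w[envs$center[e]] + share
      } else {
        atoms <- environment_atoms(mol, envs$center[e], envs$radius[e])
        w[atoms] <- w[atoms] + share / length(atoms)
      }
    }
  }
  structure(list(weights = w,
                 normalization = if (any(w != 0)) max(abs(w)) else 0,
                 mode = mode),
            class = "atom_attribution")
}

#' @export
print.atom_attribution <- function(x, ...) {
  cat(sprintf("<atom_attribution> %d atoms, total contribution %+.4f logS\n",
              length(x$weights), sum(x$weights)))
  invisible(x)
}

#' One-call structural fingerprint of a query molecule
#'
#' Convenience wrapper: fingerprint the query, pull bit contributions from
#' the model, and map them onto atoms.
#'
#' @param model A `bayes_ridge` fit (or `solubility_model`).
#' @param mol A `molgraph` or SMILES string.
#' @param radius,nbits Fingerprint settings; defaults come from the model
#'   when it is a `solubility_model`.
#' @param mode Passed to [atom_attribution()].
#' @return List with `mol`, `fingerprint`, `prediction`, and
#'   `attribution`.
#' @export
structural_fingerprint <- function(model, mol, radius = NULL, nbits = NULL,
                                   mode = "center") {
  if (inherits(model, "solubility_model")) {
    if (is.null(radius)) radius <- model$radius
    if (is.null(nbits)) nbits <- model$nbits
    model <- model$fit
  }
  if (is.null(radius)) radius <- 2L
  if (is.null(nbits)) nbits <- model$p
  if (is.character(mol)) mol <- parse_smiles(mol)
  fp <- circular_fingerprint(mol, radius = radius, nbits = nbits)
  contrib <- bit_contributions(model, fp)
  att <- atom_attribution(mol, fp, contrib, mode = mode)
  list(mol = mol, fingerprint = fp,
       prediction = model$intercept + sum(contrib),
       attribution = att)
}

# Vectorized equivalent of circular_fingerprint() + bit_contributions() +
# atom_attribution(mode = "center") for batch use; agreement with the
# public path is asserted in the test suite.
.atom_weights_fast <- function(mol, coefficients, radius, nbits) {
  surv <- .surviving_envs(mol, radius, nbits)
  bit <- surv$id %% nbits
  k <- table(bit)
  share <- coefficients[bit + 1] / as.numeric(k[as.character(bit)])
  w <- numeric(nrow(mol$atoms))
  agg <- tapply(share, surv$center, sum)
  w[as.integer(names(agg))] <- as.numeric(agg)
  w
}

# ---------------------------------------------------------------------------
# SVG rendering

# diverging red-white-blue scale, symmetric about zero
# t in [-1, 1]: -1 -> blue (#2166AC), 0 -> white (#F7F7F7), +1 -> red (#B2182B)
.diverging_color <- function(t) {
  t <- max(-1, min(1, t))
  lerp <- function(a, b, f) round(a + (b - a) * f)
  if (t >= 0) {
    rgb <- c(lerp(247, 178, t), lerp(247, 24, t), lerp(247, 43, t))
  } else {
    rgb <- c(lerp(247, 33, -t), lerp(247, 102, -t), lerp(247, 172, -t))
  }
  sprintf("#%02X%02X%02X", rgb[1], rgb[2], rgb[3])
}

# deterministic 2D coordinates: Kamada-Kawai from a fixed circular start
.layout_coords <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 1L) return(matrix(0, 1, 2))
  g <- .mol_igraph(mol)
  init <- cbind(cos(2 * pi * seq_len(n) / n), sin(2 * pi * seq_len(n) / n))
  xy <- igraph::layout_with_kk(g, coords = init, dim = 2)
  xy
}

#' Render a molecule map colored by per-atom weights
#'
#' Produces a 2D depiction (deterministic force-free Kamada-Kawai layout)
#' with each atom drawn as a disc colored on a diverging red/white/blue
#' scale: positive weights red, negative blue, intensity proportional to
#' `|weight| / normalization`. Atoms with `|weight| < 1e-12` are left
#' uncolored. Rendering identical inputs yields byte-identical SVG.
#'
#' @param mol A `molgraph`.
#' @param weights Numeric vector, one per atom (e.g. solubility
#'   contributions or partial charges).
#' @param file Optional path; when given the SVG is written there.
#' @param normalization Positive scale for full color saturation; default
#'   is `max(abs(weights))`.
#' @param size Canvas size in pixels (square).
#' @return SVG document as a single character string (invisibly when
#'   written to `file`).
#' @export
render_molecule_map <- function(mol, weights, file = NULL,
                                normalization = NULL, size = 400) {
  stopifnot(inherits(mol, "molgraph"))
  n <- nrow(mol$atoms)
  if (length(weights) != n) {
    stop(sprintf("need one weight per atom (%d atoms, %d weights)",
                 n, length(weights)), call. = FALSE)
  }
  if (is.null(normalization)) {
    normalization <- if (any(abs(weights) > 0)) max(abs(weights)) else 1
  }
  if (normalization <= 0) normalization <- 1

  xy <- .layout_coords(mol)
  # scale into the canvas with a margin
  rng <- apply(xy, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-9)
  margin <- 0.12 * size
  pos <- cbind(
    margin + (xy[, 1] - rng[1, 1]) / max(span) * (size - 2 * margin),
    margin + (xy[, 2] - rng[1, 2]) / max(span) * (size - 2 * margin)
  )

  fmt <- function(x) sprintf("%.2f", x)
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            size, size, size, size),
    sprintf('<rect width="%d" height="%d" fill="white"/>', size, size)
  )
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$from[k]; b <- mol$bonds$to[k]
    o <- mol$bonds$order[k]
    wd <- if (o >= 2) 3.2 else if (o == 1.5) 2.4 else 1.6
    lines <- c(lines, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="%s"%s/>',
      fmt(pos[a, 1]), fmt(pos[a, 2]), fmt(pos[b, 1]), fmt(pos[b, 2]),
      fmt(wd), if (o == 1.5) ' stroke-dasharray="4,2"' else ""))
  }
  r_atom <- max(6, 0.035 * size)
  for (a in seq_len(n)) {
    w <- weights[a]
    colored <- abs(w) >= 1e-12
    fill <- if (colored) .diverging_color(w / normalization) else "white"
    lines <- c(lines, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="0.8"/>',
      fmt(pos[a, 1]), fmt(pos[a, 2]), fmt(r_atom), fill,
      if (colored) "black" else "#999999"))
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="%s" text-anchor="middle" dominant-baseline="central">%s</text>',
      fmt(pos[a, 1]), fmt(pos[a, 2]), fmt(0.55 * r_atom * 2),
      mol$atoms$element[a]))
  }
  lines <- c(lines, "</svg>")
  svg <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(svg, file)
    return(invisible(svg))
  }
  svg
}

#' Write per-atom attribution weights as CSV
#'
#' @param mol The `molgraph` the weights belong to.
#' @param attribution An `atom_attribution`.
#' @param file Output CSV path (columns `atom_index,element,weight`).
#' @export
write_attribution_csv <- function(mol, attribution, file) {
  stopifnot(inherits(attribution, "atom_attribution"))
  write.csv(data.frame(atom_index = seq_len(nrow(mol$atoms)),
                       element = mol$atoms$element,
                       weight = attribution$weights),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
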