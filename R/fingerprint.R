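# Extended-connectivity (circular) fingerprints with bit->environment
# provenance. The provenance is the point: every on bit remembers which
# (center atom, radius) environments produced it, so model coefficients can
# later be pushed back onto atoms.

# --- 32-bit FNV-1a over a byte sequence, in double arithmetic -------------
# R has no unsigned 32-bit integers; the multiply-mod-2^32 is done by
# splitting the accumulator into 16-bit halves (products stay < 2^53).
.FNV_OFFSET <- 2166136261
.FNV_PRIME <- 16777619
.TWO32 <- 4294967296

.fnv1a <- function(bytes) {
  h <- .FNV_OFFSET
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * .FNV_PRIME + ((hi * .FNV_PRIME) %% 65536) * 65536) %% .TWO32
  }
  h
}

.hash_string <- function(s) .fnv1a(utf8ToInt(s))

#' Compute an ECFP-style circular fingerprint
#'
#' Implements the extended-connectivity algorithm: each atom starts from an
#' invariant tuple (atomic number, heavy-atom degree, attached hydrogen
#' count, formal charge, ring-membership flag) hashed to a 32-bit
#' identifier; for rounds `r = 1..radius` each atom's identifier is rehashed
#' together with the sorted (bond order, neighbor identifier) pairs of its
#' neighbors. Every (center, radius) environment yields a candidate
#' identifier; environments covering an atom set already covered by an
#' earlier (smaller-radius, then smaller-identifier) environment are
#' dropped; surviving identifiers are folded to `bit = id mod nbits`.
#'
#' The default `radius = 2` gives the ECFP4 (diameter-4) fingerprint. Bits
#' are binary (presence/absence). Stereochemistry is ignored.
#'
#' @param mol A `molgraph` from [parse_smiles()].
#' @param radius Maximum environment radius (non-negative integer).
#' @param nbits Fingerprint length (>= 16); identifiers are folded modulo
#'   `nbits`.
#' @return An object of class `fingerprint`: list with `nbits`, `on_bits`
#'   (sorted 0-based bit indices), and `bit_info` — a named list mapping
#'   each on bit to a data frame of its surviving environments
#'   (`center`, `radius`, columns; centers are 1-based atom indices).
#' @examples
#' fp <- circular_fingerprint(parse_smiles("CCO"))
#' length(fp$on_bits)
#' @export
circular_fingerprint <- function(mol, radius = 2L, nbits = 2048L) {
  stopifnot(inherits(mol, "molgraph"))
  if (!(length(radius) == 1L && radius >= 0)) {
    stop("`radius` must be a non-negative integer", call. = FALSE)
  }
  if (!(length(nbits) == 1L && nbits >= 16)) {
    stop("`nbits` must be at least 16", call. = FALSE)
  }
  radius <- as.integer(radius); nbits <- as.double(nbits)
  surv <- .surviving_envs(mol, radius, nbits)
  bit <- surv$id %% nbits

  on_bits <- sort(unique(bit))
  fbit <- factor(bit, levels = on_bits)
  bit_info <- mapply(function(ce, ra) {
    o <- order(ra, ce)
    data.frame(center = ce[o], radius = ra[o])
  }, split(surv$center, fbit), split(surv$radius, fbit),
  SIMPLIFY = FALSE)
  names(bit_info) <- format(on_bits, scientific = FALSE, trim = TRUE)

  structure(list(nbits = nbits, on_bits = on_bits, bit_info = bit_info,
                 radius = radius),
            class = "fingerprint")
}

# environments surviving atom-set deduplication, as plain vectors
.surviving_envs <- function(mol, radius, nbits) {
  ev <- .ecfp_envs_cpp(as.integer(mol$atoms$atomic_num),
                       as.integer(mol$atoms$degree),
                       as.integer(mol$atoms$n_h),
                       as.integer(mol$atoms$charge),
                       as.integer(mol$atoms$in_ring),
                       as.integer(mol$bonds$from),
                       as.integer(mol$bonds$to),
                       as.numeric(mol$bonds$order),
                       radius)
  # prefer smaller radius, then smaller identifier, then smaller center
  ord <- order(ev$radius, ev$id, ev$center)
  keep <- ord[!duplicated(ev$atom_key[ord])]
  list(center = ev$center[keep], radius = ev$radius[keep], id = ev$id[keep])
}

# on-bit indices only (0-based), skipping bit_info assembly
.on_bits_only <- function(mol, radius, nbits) {
  surv <- .surviving_envs(mol, radius, nbits)
  sort(unique(surv$id %% nbits))
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d/%g bits on (radius %d)\n",
              length(x$on_bits), x$nbits, x$radius))
  invisible(x)
}

#' Dense 0/1 vector form of a fingerprint
#' @param fp A `fingerprint`.
#' @return Numeric vector of length `nbits` with ones at the on bits.
#' @export
as_bit_vector <- function(fp) {
  stopifnot(inherits(fp, "fingerprint"))
  v <- numeric(fp$nbits)
  v[fp$on_bits + 1] <- 1
  v
}

#' Featurize a molecule table into a fingerprint design matrix
#'
#' @param table Data frame with at least a `smiles` column; an `id` column
#'   is used for error reporting when present.
#' @param radius,nbits Passed to [circular_fingerprint()].
#' @return Binary matrix with one row per molecule and `nbits` columns;
#'   row names from `table$id` when available.
#' @export
featurize_table <- function(table, radius = 2L, nbits = 2048L) {
  stopifnot(is.data.frame(table), "smiles" %in% names(table))
  ids <- if ("id" %in% names(table)) as.character(table$id)
         else as.character(seq_len(nrow(table)))
  if (nrow(table) == 0L) {
    return(matrix(0, nrow = 0L, ncol = nbits))
  }
  parsed <- lapply(table$smiles, function(s) {
    tryCatch(parse_smiles(s), error = function(e) e)
  })
  bad <- vapply(parsed, inherits, logical(1), "condition")
  if (any(bad)) {
    stop(sprintf("unparseable SMILES for molecule(s): %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  X <- matrix(0, nrow = nrow(table), ncol = nbits,
              dimnames = list(ids, NULL))
  for (i in seq_len(nrow(table))) {
    X[i, .on_bits_only(parsed[[i]], radius, nbits) + 1] <- 1
  }
  X
}

# featurize pre-parsed molgraphs (no SMILES round trip)
.featurize_mols <- function(mols, radius = 2L, nbits = 2048L) {
  X <- matrix(0, nrow = length(mols), ncol = nbits)
  for (i in seq_along(mols)) {
    X[i, .on_bits_only(mols[[i]], radius, nbits) + 1] <- 1
  }
  X
}
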