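# Molecular graphs: SMILES parsing, ring perception, implicit hydrogens.
#
# Atom indices are input order (the order atoms appear in the SMILES string),
# which downstream attribution relies on: atom k of the parsed graph is atom
# k of every fingerprint environment and of every rendered map.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

.ATOMIC_NUM <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53, Si = 14, Se = 34, As = 33
)

# default (lowest) valences; S and P may expand
.DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, Si = 4, Se = 2, As = 3, H = 1
)
.EXPANDED_VALENCE <- list(S = c(2, 4, 6), P = c(3, 5))

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (`B C N O P S F Cl Br I`), aromatic lowercase
#' atoms, bracket atoms with explicit hydrogen counts and formal charges,
#' single/double/triple/aromatic bonds, branches, ring-bond closures
#' (including `%nn` two-digit labels and label reuse), and dot-separated
#' fragments. Stereo markers (`/ \ @ @@`) are accepted and ignored.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `molgraph`: a list with components
#'   `atoms` (data frame: `element`, `atomic_num`, `charge`, `n_h`,
#'   `degree`, `in_ring`, `aromatic`), `bonds` (data frame: `from`, `to`,
#'   `order` — aromatic bonds have order 1.5), `n_fragments`, and the
#'   originating `smiles` string. Hydrogens are implicit: `n_h` counts them
#'   per heavy atom.
#' @examples
#' mol <- parse_smiles("CC(=O)O")
#' n_atoms(mol)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  perr <- function(pos, msg) {
    stop(sprintf("SMILES parse error at position %d ('%s') in \"%s\": %s",
                 pos, if (pos <= n) chars[pos] else "<end>", smiles, msg),
         call. = FALSE)
  }

  element <- character(0); aromatic <- logical(0)
  charge <- integer(0); explicit_h <- integer(0)
  bf <- integer(0); bt <- integer(0); bo <- numeric(0)

  prev_atom <- NA_integer_     # atom awaiting a bond to the next atom
  pending_order <- NA_real_    # bond symbol seen since last atom
  stack <- integer(0)          # open branch points
  ring_open <- list()          # label -> list(atom, order, pos)
  frag_breaks <- 0L
  i <- 1L

  add_atom <- function(sym, arom, chg, exh) {
    element[length(element) + 1L] <<- sym
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    explicit_h[length(explicit_h) + 1L] <<- exh
    length(element)
  }
  add_bond <- function(a, b, order) {
    bf[length(bf) + 1L] <<- a; bt[length(bt) + 1L] <<- b
    bo[length(bo) + 1L] <<- order
  }
  connect <- function(idx, pos) {
    if (!is.na(prev_atom)) {
      ord <- pending_order
      if (is.na(ord)) {
        ord <- if (aromatic[prev_atom] && aromatic[idx]) 1.5 else 1
      }
      add_bond(prev_atom, idx, ord)
    }
    prev_atom <<- idx
    pending_order <<- NA_real_
  }
  close_ring <- function(label, pos) {
    key <- as.character(label)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      if (op$atom == prev_atom) perr(pos, "ring bond to the same atom")
      ord <- pending_order
      if (is.na(ord)) ord <- op$order
      if (is.na(ord)) {
        ord <- if (aromatic[op$atom] && aromatic[prev_atom]) 1.5 else 1
      }
      add_bond(op$atom, prev_atom, ord)
      pending_order <<- NA_real_
    } else {
      if (is.na(prev_atom)) perr(pos, "ring closure before any atom")
      ring_open[[key]] <<- list(atom = prev_atom, order = pending_order,
                                pos = pos)
      pending_order <<- NA_real_
    }
  }

  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""

    if (two %in% c("Cl", "Br")) {
      idx <- add_atom(two, FALSE, 0L, NA_integer_)
      connect(idx, i); i <- i + 2L
    } else if (ch %in% .ORGANIC_SUBSET) {
      idx <- add_atom(ch, FALSE, 0L, NA_integer_)
      connect(idx, i); i <- i + 1L
    } else if (ch %in% .AROMATIC_OK) {
      idx <- add_atom(toupper(ch), TRUE, 0L, NA_integer_)
      connect(idx, i); i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) perr(i, "unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parse_bracket_atom(body)
      if (is.null(at)) perr(i, sprintf("cannot interpret bracket atom [%s]", body))
      idx <- add_atom(at$element, at$aromatic, at$charge, at$n_h)
      connect(idx, i); i <- j + 1L
    } else if (ch == "-") { pending_order <- 1; i <- i + 1L
    } else if (ch == "=") { pending_order <- 2; i <- i + 1L
    } else if (ch == "#") { pending_order <- 3; i <- i + 1L
    } else if (ch == ":") { pending_order <- 1.5; i <- i + 1L
    } else if (ch %in% c("/", "\\")) { pending_order <- 1; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev_atom)) perr(i, "branch opened before any atom")
      stack <- c(stack, prev_atom); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) perr(i, "unmatched ')'")
      prev_atom <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      if (is.na(prev_atom)) perr(i, "ring closure before any atom")
      close_ring(as.integer(ch), i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L]))) {
        perr(i, "'%' must be followed by two digits")
      }
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L
    } else if (ch == ".") {
      prev_atom <- NA_integer_; pending_order <- NA_real_
      frag_breaks <- frag_breaks + 1L
      i <- i + 1L
    } else {
      perr(i, "unexpected character")
    }
  }
  if (length(stack) > 0L) perr(n, "unclosed branch '('")
  if (length(ring_open) > 0L) {
    op <- ring_open[[1L]]
    perr(op$pos, "unmatched ring-closure label")
  }
  if (length(element) == 0L) perr(1L, "no atoms")

  .build_molgraph(element, aromatic, charge, explicit_h, bf, bt, bo, smiles)
}

# "[<iso?><El|el><@...?><Hn?><charge?>]" -> list or NULL
.parse_bracket_atom <- function(body) {
  m <- regmatches(body, regexec(
    "^([0-9]*)(@{0,2})?([A-Z][a-z]?|[a-z])(@{1,2})?(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]|-[0-9])?$",
    body))[[1]]
  if (length(m) == 0L) return(NULL)
  sym <- m[4]
  arom <- sym %in% .AROMATIC_OK
  if (arom) sym <- toupper(sym)
  if (!(sym %in% names(.ATOMIC_NUM))) return(NULL)
  hspec <- m[6]
  n_h <- if (!nzchar(hspec)) 0L
         else if (hspec == "H") 1L
         else as.integer(sub("H", "", hspec))
  cspec <- m[7]
  chg <- 0L
  if (nzchar(cspec)) {
    chg <- if (grepl("[0-9]", cspec)) {
      as.integer(sub("([+-])", "\\1", cspec))
    } else {
      (nchar(cspec)) * (if (substr(cspec, 1, 1) == "+") 1L else -1L)
    }
  }
  list(element = sym, aromatic = arom, charge = chg, n_h = n_h)
}

# Assemble the molgraph: degrees, implicit H, ring flags, valence checks.
.build_molgraph <- function(element, aromatic, charge, explicit_h,
                            bf, bt, bo, smiles) {
  n_atoms <- length(element)
  if (length(bf) > 0L && any(duplicated(paste(pmin(bf, bt), pmax(bf, bt))))) {
    stop("chemistry error: duplicate bond between the same atom pair",
         call. = FALSE)
  }
  degree <- tabulate(c(bf, bt), nbins = n_atoms)
  bond_sum <- numeric(n_atoms)
  for (k in seq_along(bf)) {
    bond_sum[bf[k]] <- bond_sum[bf[k]] + bo[k]
    bond_sum[bt[k]] <- bond_sum[bt[k]] + bo[k]
  }

  n_h <- integer(n_atoms)
  for (a in seq_len(n_atoms)) {
    if (!is.na(explicit_h[a])) {        # bracket atom: H count is explicit
      n_h[a] <- explicit_h[a]
      next
    }
    el <- element[a]
    dv <- .DEFAULT_VALENCE[[el]]
    eff <- dv + if (el %in% c("N", "P")) charge[a]
           else if (el %in% c("O", "S")) charge[a]
           else if (el == "C") -abs(charge[a]) else 0L
    occupied <- if (aromatic[a]) floor(bond_sum[a]) else bond_sum[a]
    exp_v <- .EXPANDED_VALENCE[[el]]
    if (!is.null(exp_v) && charge[a] == 0L) {
      cand <- exp_v[exp_v >= occupied]
      if (length(cand) > 0L) eff <- cand[1L]
    }
    h <- eff - occupied
    if (h < -1e-9) {
      stop(sprintf(
        "chemistry error: valence violation at atom %d (%s) in \"%s\": %g bonds exceed allowed valence %g",
        a, el, smiles, bond_sum[a], eff), call. = FALSE)
    }
    n_h[a] <- as.integer(max(0, floor(h + 1e-9)))
  }

  in_ring <- .ring_atoms(n_atoms, bf, bt)
  n_comp <- .n_components(n_atoms, bf, bt)

  structure(list(
    atoms = data.frame(
      element = element,
      atomic_num = unname(.ATOMIC_NUM[element]),
      charge = charge,
      n_h = n_h,
      degree = degree,
      in_ring = in_ring,
      aromatic = aromatic,
      stringsAsFactors = FALSE
    ),
    bonds = data.frame(from = bf, to = bt, order = bo),
    n_fragments = n_comp,
    smiles = smiles
  ), class = "molgraph")
}

# atoms on at least one cycle = endpoints of non-bridge edges
.ring_atoms <- function(n_atoms, bf, bt) {
  ring <- logical(n_atoms)
  if (length(bf) == 0L) return(ring)
  g <- igraph::make_graph(rbind(bf, bt), n = n_atoms, directed = FALSE)
  br <- igraph::bridges(g)
  non_bridge <- setdiff(seq_along(bf), as.integer(br))
  ring[unique(c(bf[non_bridge], bt[non_bridge]))] <- TRUE
  ring
}

.n_components <- function(n_atoms, bf, bt) {
  g <- igraph::make_graph(rbind(bf, bt), n = n_atoms, directed = FALSE)
  igraph::components(g)$no
}

.mol_igraph <- function(mol) {
  igraph::make_graph(rbind(mol$bonds$from, mol$bonds$to),
                     n = nrow(mol$atoms), directed = FALSE)
}

#' Number of heavy atoms in a molecular graph
#' @param mol A `molgraph`.
#' @return Integer count of heavy (non-hydrogen) atoms.
#' @export
n_atoms <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  nrow(mol$atoms)
}

#' Atoms within a graph radius of a center atom
#'
#' Returns the set of atom indices at graph (bond-count) distance at most
#' `radius` from `center` — the atom environment that a circular-fingerprint
#' identifier of that radius describes.
#'
#' @param mol A `molgraph`.
#' @param center Atom index (1-based).
#' @param radius Non-negative integer graph radius.
#' @return Sorted integer vector of atom indices (always includes `center`).
#' @export
environment_atoms <- function(mol, center, radius) {
  stopifnot(inherits(mol, "molgraph"))
  n <- nrow(mol$atoms)
  if (!(is.numeric(center) && length(center) == 1L && center >= 1 && center <= n)) {
    stop("`center` must be an atom index in 1..", n, call. = FALSE)
  }
  if (!(is.numeric(radius) && length(radius) == 1L && radius >= 0)) {
    stop("`radius` must be a non-negative integer", call. = FALSE)
  }
  adj <- .adjacency_list(mol)
  .env_atoms_bfs(adj, as.integer(center), as.integer(radius))
}

.adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$from[k]; b <- mol$bonds$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

.env_atoms_bfs <- function(adj, center, radius) {
  seen <- center
  frontier <- center
  r <- 0L
  while (r < radius && length(frontier) > 0L) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
    r <- r + 1L
  }
  sort(seen)
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d heavy atoms, %d bonds%s\n",
              nrow(x$atoms), nrow(x$bonds),
              if (x$n_fragments > 1L)
                sprintf(" (%d fragments)", x$n_fragments) else ""))
  counts <- table(x$atoms$element)
  h <- sum(x$atoms$n_h)
  formula <- paste0(names(counts), ifelse(counts > 1L, counts, ""),
                    collapse = "")
  cat(sprintf("  formula (heavy + implicit H): %s%s\n", formula,
              if (h > 0) paste0("H", h) else ""))
  if (!is.null(x$smiles) && !is.na(x$smiles)) cat("  smiles:", x$smiles, "\n")
  invisible(x)
}

#' Write a molecular graph as a SMILES string
#'
#' Depth-first serialization with ring-closure labels. Not canonical: the
#' output follows atom input order, but re-parsing it reproduces an
#' isomorphic graph with identical per-atom element, charge, hydrogen-count
#' and ring-membership multisets.
#'
#' @param mol A `molgraph`.
#' @return A SMILES string.
#' @export
write_smiles <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  n <- nrow(mol$atoms)
  nb_bonds <- nrow(mol$bonds)
  adj <- vector("list", n)   # each: matrix cols (neighbor, order, bond_id)
  for (k in seq_len(nb_bonds)) {
    a <- mol$bonds$from[k]; b <- mol$bonds$to[k]; o <- mol$bonds$order[k]
    adj[[a]] <- rbind(adj[[a]], c(b, o, k))
    adj[[b]] <- rbind(adj[[b]], c(a, o, k))
  }

  bond_sym <- function(o, a, b) {
    if (o == 2) "=" else if (o == 3) "#"
    else if (o == 1.5 && !(mol$atoms$aromatic[a] && mol$atoms$aromatic[b])) ":"
    else ""
  }
  atom_token <- function(a) {
    el <- mol$atoms$element[a]
    sym <- if (mol$atoms$aromatic[a]) tolower(el) else el
    chg <- mol$atoms$charge[a]
    if (chg == 0L && el %in% .ORGANIC_SUBSET) return(sym)
    h <- mol$atoms$n_h[a]
    hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    cs <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
          else sprintf("%+d", chg)
    paste0("[", sym, hs, cs, "]")
  }

  # pass 1: DFS spanning forest; non-tree edges become ring closures
  visited <- logical(n)
  tree_kids <- vector("list", n)       # ordered (child, order) per atom
  is_tree <- logical(nb_bonds)
  back_edges <- NULL                   # rows: (a, b, order) discovered a->b
  roots <- integer(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    roots <- c(roots, root)
    stack_a <- root; visited[root] <- TRUE
    # iterative DFS preserving neighbor order
    dfs_stack <- list(list(atom = root, next_row = 1L))
    while (length(dfs_stack) > 0L) {
      fr <- dfs_stack[[length(dfs_stack)]]
      a <- fr$atom; r <- fr$next_row
      nb <- adj[[a]]
      if (is.null(nb) || r > nrow(nb)) {
        dfs_stack[[length(dfs_stack)]] <- NULL
        next
      }
      dfs_stack[[length(dfs_stack)]]$next_row <- r + 1L
      b <- nb[r, 1]; o <- nb[r, 2]; k <- nb[r, 3]
      if (is_tree[k] || (!is.null(back_edges) &&
                         any(back_edges[, 4] == k))) next
      if (!visited[b]) {
        visited[b] <- TRUE
        is_tree[k] <- TRUE
        tree_kids[[a]] <- rbind(tree_kids[[a]], c(b, o))
        dfs_stack[[length(dfs_stack) + 1L]] <- list(atom = b, next_row = 1L)
      } else {
        back_edges <- rbind(back_edges, c(a, b, o, k))
      }
    }
  }

  # assign ring-closure labels; both endpoints emit the same label
  closure_str <- vector("list", n)
  if (!is.null(back_edges)) {
    for (e in seq_len(nrow(back_edges))) {
      a <- back_edges[e, 1]; b <- back_edges[e, 2]; o <- back_edges[e, 3]
      labstr <- if (e < 10L) as.character(e) else sprintf("%%%02d", e)
      sym <- bond_sym(o, a, b)
      closure_str[[b]] <- c(closure_str[[b]], paste0(sym, labstr))
      closure_str[[a]] <- c(closure_str[[a]], paste0(sym, labstr))
    }
  }

  # pass 2: emit along the spanning tree
  atom_order <- integer(0)
  emit <- function(a, pre_sym) {
    atom_order[length(atom_order) + 1L] <<- a
    cl <- closure_str[[a]]
    out <- paste0(pre_sym, atom_token(a),
                  if (is.null(cl)) "" else paste(cl, collapse = ""))
    kids <- tree_kids[[a]]
    if (!is.null(kids)) {
      nk <- nrow(kids)
      for (r in seq_len(nk)) {
        b <- kids[r, 1]; o <- kids[r, 2]
        sub <- emit(b, bond_sym(o, a, b))
        out <- if (r < nk) paste0(out, "(", sub, ")") else paste0(out, sub)
      }
    }
    out
  }
  out <- paste(vapply(roots, function(rt) emit(rt, ""), character(1)),
               collapse = ".")
  # emission order: atom_order[k] is the original index of the k-th atom
  # in the output string (useful for permuting per-atom annotations)
  attr(out, "atom_order") <- atom_order
  out
}

#' Read molecules from an SDF (V2000) file
#'
#' Thin wrapper over `ChemmineR::read.SDFset()` that converts each record to
#' a [parse_smiles()]-compatible `molgraph`. Implicit hydrogen counts are
#' recomputed from standard valences; explicit hydrogen atoms in the file
#' are folded into their heavy neighbor's hydrogen count.
#'
#' @param file Path to an SDF file.
#' @return A list of `molgraph` objects.
#' @export
read_sdf <- function(file) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("read_sdf() requires the ChemmineR package", call. = FALSE)
  }
  sdfset <- ChemmineR::read.SDFset(file)
  lapply(seq_along(sdfset), function(i) .sdf_to_molgraph(sdfset[[i]]))
}

.sdf_to_molgraph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  # old-style molfile charge codes in the 4th field (1..7 -> +3..-3)
  code_col <- if (ncol(ab) >= 4) ab[, 4] else rep(0, nrow(ab))
  code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
                `6` = -2L, `7` = -3L)
  charges <- ifelse(code_col %in% 1:7,
                    code_map[as.character(code_col)], 0L)
  bf <- as.integer(bb[, 1]); bt <- as.integer(bb[, 2])
  bo <- as.numeric(bb[, 3]); bo[bo == 4] <- 1.5

  heavy <- which(elements != "H")
  remap <- match(seq_along(elements), heavy)
  extra_h <- integer(length(heavy))
  keep <- logical(length(bf))
  for (k in seq_along(bf)) {
    a <- bf[k]; b <- bt[k]
    if (elements[a] == "H" || elements[b] == "H") {
      hv <- if (elements[a] == "H") b else a
      if (elements[hv] != "H") extra_h[remap[hv]] <- extra_h[remap[hv]] + 1L
    } else keep[k] <- TRUE
  }
  bf <- remap[bf[keep]]; bt <- remap[bt[keep]]; bo <- bo[keep]

  mol <- .build_molgraph(elements[heavy], rep(FALSE, length(heavy)),
                         as.integer(charges[heavy]),
                         rep(NA_integer_, length(heavy)),
                         bf, bt, bo, NA_character_)
  mol$atoms$n_h <- mol$atoms$n_h + extra_h
  mol
}
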