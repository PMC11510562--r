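# Shared fixtures and independent oracles used across the suite.

# independent penalized least-squares oracle: explicit normal equations
# on the centered problem (never calls the package's SVD path)
ridge_oracle <- function(X, y, alpha, beta) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(X)
  m <- solve(alpha * diag(p) + beta * crossprod(Xc),
             beta * crossprod(Xc, yc))
  list(m = as.numeric(m), b = mean(y) - sum(m * colMeans(X)))
}

# a deterministic pool of valid drug-like SMILES spanning rings, aromatics,
# charges, branches and heteroatoms
smiles_pool <- c(
  "C", "CC", "CCO", "CC(=O)O", "c1ccccc1", "Cc1ccccc1O",
  "CC(C)CC(=O)O", "OCC(O)CO", "CC(=O)[O-]", "C[N+](C)(C)C",
  "CCCCCCO", "CC1CCCCC1", "O=C1CCCCC1", "c1ccc2ccccc2c1",
  "CC(C)(C)c1ccc(O)cc1", "N#CCC#N", "ClCCBr", "CSC", "CCOC(=O)C",
  "CC1CC2C(CCC3(C)C2CCC3(O)C(C)=O)C2(C)CCC(=O)C=C12"  # medroxyprogesterone
)

mp_smiles <- "CC1CC2C(CCC3(C)C2CCC3(O)C(C)=O)C2(C)CCC(=O)C=C12"

# random but seeded molecule set with ground truth, shared by several files
make_fixture_dataset <- function(n = 150, seed = 11, noise_sd = 0.3) {
  generate_solubility_dataset(
    solubility_spec(n_molecules = n, noise_sd = noise_sd, seed = seed))
}

# randomly permute the atom order of a molgraph (seeded by caller)
permute_molecule <- function(mol) {
  n <- nrow(mol$atoms)
  soluprint:::.permute_molgraph(mol, sample.int(n))
}

# random valid population-analysis input: random symmetric S with unit
# diagonal (small off-diagonals, as a plausible overlap), random symmetric
# positive P rescaled so trace(PS) hits the required electron count
random_population_input <- function(n_atoms = 3, nb_per_atom = 2) {
  nb <- n_atoms * nb_per_atom
  S <- matrix(runif(nb * nb, -0.3, 0.3) / nb, nb, nb)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  Z <- sample(1:8, n_atoms, replace = TRUE)
  total_charge <- sample(-1:1, 1)
  P0 <- crossprod(matrix(rnorm(nb * nb), nb, nb)) / nb
  target <- sum(Z) - total_charge
  P <- P0 * target / sum(diag(P0 %*% S))
  population_input(P, S, rep(seq_len(n_atoms), each = nb_per_atom), Z,
                   total_charge)
}
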