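# Shared fixtures: tiny configurations and seeded random structures used
# across the test files. Everything is generated in code at test time.

tiny_rep_cfg <- function(seed = 1L, n = 8L, n_interactions = 2L, n_rbf = 6L,
                         r_cut = 5.0) {
  rep_config(n = n, n_interactions = n_interactions, r_cut = r_cut,
             n_rbf = n_rbf, seed = seed)
}

# a water-like 3-atom molecule
fix_water <- function() {
  molecule(c(8, 1, 1),
           rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
           id = "water")
}

# random CHON molecule drawn from the surrogate geometry model
fix_random_mol <- function(seed, M = NULL) {
  generate_geometry(surrogate_params(), M = M, seed = seed,
                    id = paste0("fix", seed))
}

# random rigid isometry: rotation matrix (from QR) + translation
fix_isometry <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(rot = Q, shift = rnorm(3, sd = 5))
}

apply_isometry <- function(mol, iso) {
  molecule(mol$Z, mol$R %*% iso$rot + rep(iso$shift, each = n_atoms(mol)),
           id = mol$id)
}

permute_atoms <- function(mol, perm) {
  molecule(mol$Z[perm], mol$R[perm, , drop = FALSE], id = mol$id)
}

# small labeled dataset reused by training tests
fix_records <- function(n, seed = 7L) {
  generate_dataset(n, surrogate_params(), seed = seed)
}
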