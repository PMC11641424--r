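# Independent oracles and fixture builders used across the suite.

# Horn's quaternion method for optimal rigid superposition RMSD.
# Independent of the SVD route used by the package.
horn_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- crossprod(ac, bc)                       # S_ij = sum_k a_ki b_kj
  n4 <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],       s[3,1]-s[1,3],       s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],       s[3,1]+s[1,3],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],       -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[3,1]+s[1,3],       s[2,3]+s[3,2],       -s[1,1]-s[2,2]+s[3,3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(n4, symmetric = TRUE, only.values = TRUE)$values)
  sq <- (sum(ac^2) + sum(bc^2) - 2 * lam) / nrow(a)
  sqrt(max(0, sq))
}

# random proper rotation (QR of a Gaussian matrix, det-corrected)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# jittered copy of a structure model (deterministic given the RNG state)
jitter_model <- function(model, sd, source = "predicted") {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  model$atoms[, c("x", "y", "z")] <-
    xyz + matrix(rnorm(length(xyz), sd = sd), ncol = 3)
  model$source <- source
  model
}

# fixed-width PDB ATOM/HETATM line
pdb_line <- function(type, serial, name, alt, resn, chain, resno, x, y, z,
                     occ = 1, b = 0) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, serial, name, alt, resn, chain, resno, x, y, z, occ, b)
}

# ensemble of noisy copies drawn around given basin models, with known labels
basin_ensemble <- function(basins, n_each, sd, seed = 1) {
  set.seed(seed)
  models <- list()
  lab <- integer(0)
  for (k in seq_along(basins)) {
    for (i in seq_len(n_each)) {
      models[[length(models) + 1L]] <- jitter_model(basins[[k]], sd)
      lab <- c(lab, k)
    }
  }
  prov <- data.frame(conformer = seq_along(models), model = NA, seed_index = NA,
                     recycle = NA, final = NA, replica = NA, seed = seed,
                     basin = c("A", "B", "C")[lab])
  list(ensemble = conformer_ensemble(models, provenance = prov),
       labels = lab)
}

# agreement of two labelings up to label permutation (exact partitions only)
same_partition <- function(a, b) {
  all(rowSums(table(a, b) > 0) == 1) && all(colSums(table(a, b) > 0) == 1)
}
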