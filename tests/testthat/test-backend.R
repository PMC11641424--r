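hinge_basins <- function(n = 20, rmsd = 3.5) {
  hp <- synthetic_hinge_pair(n, target_rmsd = rmsd)
  list(a = hp$open, b = hp$closed)
}

test_that("conformer count contract holds over a parameter grid", {
  bs <- hinge_basins()
  be <- mock_backend(bs$a, bs$b, noise_scale = 0.1)
  grid <- expand.grid(models = c(1, 3, 5), recycles = c(0, 1, 12),
                      seeds = c(1, 2))
  for (i in seq_len(nrow(grid))) {
    req <- prediction_request(num_models = grid$models[i],
                              num_recycles = grid$recycles[i],
                              num_seeds = grid$seeds[i], seed = i)
    ens <- run_backend(req, be)
    expect_equal(ensemble_size(ens),
                 grid$models[i] * grid$seeds[i] * (grid$recycles[i] + 2))
  }
  # the named cases: 5x12x1 -> 70, 1x0x1 -> 2, 3x1x2 -> 18
  expect_equal(expected_conformers(prediction_request(num_models = 5,
                                                      num_recycles = 12)), 70)
  expect_equal(expected_conformers(prediction_request(num_models = 1,
                                                      num_recycles = 0)), 2)
  expect_equal(expected_conformers(
    prediction_request(num_models = 3, num_recycles = 1, num_seeds = 2)), 18)
})

test_that("provenance enumerates recycles 0..R plus a flagged final structure", {
  bs <- hinge_basins()
  be <- mock_backend(bs$a, bs$b)
  ens <- run_backend(prediction_request(num_models = 2, num_recycles = 3,
                                        seed = 1), be)
  pr <- ens$provenance
  expect_equal(nrow(pr), 10)
  per_model <- split(pr, pr$model)
  for (p in per_model) {
    expect_equal(sort(p$recycle[!p$final]), 0:3)
    expect_equal(sum(p$final), 1)
    expect_true(is.na(p$recycle[p$final]))
  }
})

test_that("zero noise with full weight on basin A reproduces basin A exactly", {
  bs <- hinge_basins()
  be <- mock_backend(bs$a, bs$b, weight_a = 1, noise_scale = 0)
  ens <- run_backend(prediction_request(num_models = 2, num_recycles = 2,
                                        seed = 4), be)
  corr <- build_correspondence(bs$a, bs$a)
  for (m in ens$conformers) {
    expect_lt(as.numeric(rmsd_between(m, bs$a, corr, "backbone")), 1e-8)
  }
  pl <- ensemble_plddt(ens)
  expect_true(all(pl == 100))                  # zero displacement
})

test_that("basin labels are recoverable by nearest-reference classification", {
  bs <- hinge_basins(n = 30, rmsd = 3.5)       # inter-basin RMSD >> noise
  be <- mock_backend(bs$a, bs$b, weight_a = 0.5, noise_scale = 0.3)
  ens <- run_backend(prediction_request(num_models = 5, num_recycles = 12,
                                        seed = 2), be)
  expect_equal(ensemble_size(ens), 70)
  # oracle: nearest-centroid labeling with quaternion-oracle distances
  xa <- as.matrix(bs$a$atoms[, c("x", "y", "z")])
  xb <- as.matrix(bs$b$atoms[, c("x", "y", "z")])
  oracle <- vapply(ens$conformers, function(m) {
    x <- as.matrix(m$atoms[, c("x", "y", "z")])
    if (horn_rmsd(x, xa) < horn_rmsd(x, xb)) "A" else "B"
  }, character(1))
  expect_identical(oracle, ens$provenance$basin)
  expect_gt(sum(oracle == "A"), 10)            # both basins populated
  expect_gt(sum(oracle == "B"), 10)
})

test_that("mock ensembles are seed-deterministic", {
  bs <- hinge_basins()
  be <- mock_backend(bs$a, bs$b, noise_scale = 0.3)
  req <- prediction_request(num_models = 2, num_recycles = 2, seed = 99)
  e1 <- run_backend(req, be)
  e2 <- run_backend(req, be)
  expect_identical(e1, e2)
  e3 <- run_backend(prediction_request(num_models = 2, num_recycles = 2,
                                       seed = 100), be)
  expect_false(identical(e1$conformers[[1]]$atoms$x,
                         e3$conformers[[1]]$atoms$x))
})

test_that("mock pLDDT decays with per-residue displacement", {
  bs <- hinge_basins()
  be <- mock_backend(bs$a, bs$b, weight_a = 1, noise_scale = 0.4)
  ens <- run_backend(prediction_request(num_models = 3, num_recycles = 8,
                                        seed = 6), be)
  ca_idx <- which(bs$a$atoms$elety == "CA")
  xa <- as.matrix(bs$a$atoms[ca_idx, c("x", "y", "z")])
  disp <- plddt <- numeric(0)
  for (i in seq_len(ensemble_size(ens))) {
    x <- as.matrix(ens$conformers[[i]]$atoms[ca_idx, c("x", "y", "z")])
    disp <- c(disp, sqrt(rowSums((x - xa)^2)))
    plddt <- c(plddt, unname(extract_plddt(ens$conformers[[i]])))
  }
  expect_lt(cor(disp, plddt, method = "spearman"), 0)
  expect_true(all(plddt >= 30 & plddt <= 100))
})

test_that("backend input errors are informative", {
  bs <- hinge_basins()
  short <- synthetic_hinge_structure(10)
  expect_error(mock_backend(bs$a, short), "topology")
  be <- mock_backend(bs$a, bs$b)
  expect_error(run_backend(prediction_request(sequence = "MKT"), be),
               "does not match basin residue count")
  expect_error(
    run_backend(prediction_request(),
                colabfold_backend(exe = "definitely_not_installed_xyz")),
    "not found on PATH")
})
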