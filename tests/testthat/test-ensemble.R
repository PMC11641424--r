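# small ensemble with prescribed per-residue pLDDT (set via B-factors)
plddt_ensemble <- function(plddt_rows, base = synthetic_hinge_structure(10)) {
  models <- lapply(seq_len(nrow(plddt_rows)), function(i) {
    m <- base
    m$source <- "predicted"
    m$atoms$b <- rep(plddt_rows[i, ], each = 4)
    m
  })
  conformer_ensemble(models)
}

test_that("confidence reranking keeps conformers with >70% residues at pLDDT >= 85", {
  n_res <- 20
  rows <- rbind(rep(90, n_res),                          # fraction 1 -> kept
                rep(50, n_res),                          # fraction 0 -> removed
                c(rep(90, n_res / 2), rep(50, n_res / 2)))  # 0.5 -> removed
  ens <- plddt_ensemble(rows)
  rr <- rerank_by_confidence(ens)
  expect_equal(rr$table$confident_fraction, c(1, 0, 0.5))
  expect_equal(rr$table$kept, c(TRUE, FALSE, FALSE))
  expect_equal(ensemble_size(rr$ensemble), 1)

  # threshold 0 keeps everything; never increases the size
  all_kept <- rerank_by_confidence(ens, plddt_threshold = 0)
  expect_equal(ensemble_size(all_kept$ensemble), 3)
  expect_lte(ensemble_size(rr$ensemble), ensemble_size(ens))

  # ordering: descending confident fraction, ties by mean pLDDT
  rows2 <- rbind(rep(86, n_res), rep(95, n_res))
  rr2 <- rerank_by_confidence(plddt_ensemble(rows2))
  expect_equal(rr2$ensemble$provenance$conformer, c(2, 1))

  none <- plddt_ensemble(rbind(rep(40, n_res)))
  expect_warning(out <- rerank_by_confidence(none), "no conformer")
  expect_null(out$ensemble)
})

test_that("RMSD profile of an apo copy and a zero-noise two-basin ensemble is exact", {
  hp <- synthetic_hinge_pair(30, target_rmsd = 3.5)
  pair <- characterize_pair(reference_pair(hp$open, hp$closed))

  apo_copy <- hp$open
  apo_copy$source <- "predicted"
  prof1 <- rmsd_profile(conformer_ensemble(list(apo_copy)), pair)
  expect_equal(prof1$table$rmsd_to_apo, 0, tolerance = 1e-10)
  expect_equal(prof1$table$rmsd_to_holo, pair$metrics$rmsd_backbone,
               tolerance = 1e-10)

  # exactly half the conformers in each basin, no noise
  basins <- rep(list(hp$open, hp$closed), each = 10)
  ens <- conformer_ensemble(lapply(basins, function(m) {
    m$source <- "predicted"; m
  }))
  prof <- rmsd_profile(ens, pair)
  modes_apo <- histogram_modes(prof$histogram$apo)
  modes_holo <- histogram_modes(prof$histogram$holo)
  w <- prof$histogram$apo$binwidth
  expect_equal(length(modes_apo), 2)
  expect_lte(abs(modes_apo[1] - 0), w)
  expect_lte(abs(modes_apo[2] - 3.5), w)
  expect_lte(abs(modes_holo[1] - 0), w)
  expect_lte(abs(modes_holo[2] - 3.5), w)

  # summary mean equals the arithmetic mean of the rows
  expect_equal(prof$summary["apo", "mean"], mean(prof$table$rmsd_to_apo))
  expect_equal(prof$summary["holo", "mean"], mean(prof$table$rmsd_to_holo))
})

test_that("state classification follows the margin rule", {
  hp <- synthetic_hinge_pair(30, target_rmsd = 3.5)
  pair <- reference_pair(hp$open, hp$closed)

  apo_copy <- hp$open; apo_copy$source <- "predicted"
  mid <- hp$open
  mid$atoms[, c("x", "y", "z")] <-
    (as.matrix(hp$open$atoms[, c("x", "y", "z")]) +
     as.matrix(hp$closed$atoms[, c("x", "y", "z")])) / 2
  mid$source <- "predicted"
  holo_copy <- hp$closed; holo_copy$source <- "predicted"

  prof <- rmsd_profile(conformer_ensemble(list(apo_copy, mid, holo_copy)),
                       pair)
  states <- classify_states(prof, margin = 0.5)
  expect_equal(as.character(states), c("apo", "intermediate", "holo"))

  # generating-basin recovery on a noisy two-basin ensemble
  be <- basin_ensemble(list(hp$open, hp$closed), n_each = 15, sd = 0.3,
                       seed = 8)
  prof2 <- rmsd_profile(be$ensemble, pair)
  got <- classify_states(prof2)
  expect_equal(as.character(got), c("apo", "holo")[be$labels])
})

test_that("clustering recovers two and three basins and picks k by silhouette", {
  hp <- synthetic_hinge_pair(30, target_rmsd = 4)
  two <- basin_ensemble(list(hp$open, hp$closed), n_each = 12, sd = 0.2,
                        seed = 2)
  sol <- cluster_ensemble(two$ensemble, k_range = 2:8)
  expect_equal(sol$k, 2)
  expect_true(same_partition(sol$labels, two$labels))
  expect_equal(sol$k, as.integer(names(which.max(sol$silhouette))))

  # oracle: partition from a threshold cut of quaternion-oracle distances
  n <- ensemble_size(two$ensemble)
  d <- matrix(0, n, n)
  xs <- lapply(two$ensemble$conformers,
               function(m) as.matrix(m$atoms[, c("x", "y", "z")]))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- horn_rmsd(xs[[i]], xs[[j]])
  }
  cut_lab <- stats::cutree(stats::hclust(stats::as.dist(d), "single"), h = 2)
  expect_true(same_partition(sol$labels, cut_lab))

  third <- synthetic_hinge_structure(30, angle = -hp$angle, id = "alt")
  three <- basin_ensemble(list(hp$open, hp$closed, third), n_each = 10,
                          sd = 0.2, seed = 3)
  sol3 <- cluster_ensemble(three$ensemble, k_range = 2:8)
  expect_equal(sol3$k, 3)
  expect_true(same_partition(sol3$labels, three$labels))
})

test_that("cluster labels are invariant under conformer reordering", {
  hp <- synthetic_hinge_pair(20, target_rmsd = 4)
  be <- basin_ensemble(list(hp$open, hp$closed), n_each = 8, sd = 0.2,
                       seed = 5)
  sol <- cluster_ensemble(be$ensemble, k_range = 2:5)
  perm <- c(seq(2, 16, by = 2), seq(1, 15, by = 2))
  sol_p <- cluster_ensemble(subset_ensemble(be$ensemble, perm),
                            k_range = 2:5)
  expect_equal(sol_p$k, sol$k)
  expect_true(same_partition(sol$labels[perm], sol_p$labels))
})

test_that("degenerate and undersized ensembles are rejected", {
  m <- synthetic_hinge_structure(20, source = "predicted")
  set.seed(1)
  tiny <- conformer_ensemble(lapply(1:6, function(i) jitter_model(m, 1e-8)))
  expect_error(cluster_ensemble(tiny, k_range = 2:5), "k = 1")
  expect_error(cluster_ensemble(tiny, k_range = 2:10), "too small")
})

test_that("pLDDT/RMSD table reports rank correlations or flags them undefined", {
  hp <- synthetic_hinge_pair(20, target_rmsd = 3.5)
  pair <- reference_pair(hp$open, hp$closed)
  # all conformers from the apo basin, confidence decaying with displacement
  be <- mock_backend(hp$open, hp$closed, weight_a = 1, noise_scale = 0.35)
  ens <- run_backend(prediction_request(num_models = 5, num_recycles = 10,
                                        seed = 3), be)
  prof <- rmsd_profile(ens, pair)
  sc <- plddt_rmsd_scatter(ens, prof)
  expect_equal(nrow(sc$table), 60)
  expect_lt(sc$spearman[["vs_apo"]], 0)        # apo is the generating basin

  # constant pLDDT -> undefined
  flat <- plddt_ensemble(rbind(rep(80, 40), rep(80, 40)),
                         base = synthetic_hinge_structure(20))
  proff <- rmsd_profile(flat, pair)
  scf <- plddt_rmsd_scatter(flat, proff)
  expect_true(all(is.na(scf$spearman)))

  single <- plddt_ensemble(rbind(rep(80, 40)),
                           base = synthetic_hinge_structure(20))
  sc1 <- plddt_rmsd_scatter(single, rmsd_profile(single, pair))
  expect_true(all(is.na(sc1$spearman)))
})

test_that("distribution summaries use fixed grids and defined densities", {
  one <- distribution_summary(2.3, "rmsd")
  expect_equal(sum(one$counts > 0), 1)
  expect_null(one$density)

  flat <- distribution_summary(seq(0.125, 4.875, by = 0.25), "rmsd")
  expect_true(all(flat$counts == 1))
  expect_equal(flat$binwidth, 0.25)

  two <- distribution_summary(rep(c(1, 3), each = 30), "rmsd")
  d <- two$density
  peaks <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
  expect_true(any(abs(peaks - 1) <= two$binwidth))
  expect_true(any(abs(peaks - 3) <= two$binwidth))

  pl <- distribution_summary(c(70, 91.2, 88), "plddt")
  expect_equal(pl$binwidth, 2.5)
  tm <- distribution_summary(c(0.5, 0.77), "tm")
  expect_equal(tm$binwidth, 0.025)
})
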