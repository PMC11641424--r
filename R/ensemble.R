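#' Conformer ensemble container
#'
#' An ordered set of predicted conformations sharing residue numbering and
#' atom topology, with per-residue pLDDT (B-factor column of each model)
#' and a provenance table (model id, recycle index or final flag, replica,
#' seed).
#'
#' @param models list of predicted `structure_model`s with identical
#'   residue counts.
#' @param provenance optional data frame with one row per conformer; a
#'   minimal one is synthesized when absent.
#' @return object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(models, provenance = NULL) {
  if (length(models) == 0L) {
    stop("ensemble must contain at least one conformer", call. = FALSE)
  }
  stopifnot(all(vapply(models, inherits, logical(1), "structure_model")))
  n_res <- vapply(models, function(m) nrow(residue_table(m)), integer(1))
  if (length(unique(n_res)) != 1L) {
    stop("conformers differ in residue count: ",
         paste(range(n_res), collapse = "-"), call. = FALSE)
  }
  if (is.null(provenance)) {
    provenance <- data.frame(conformer = seq_along(models),
                             model = NA_integer_, seed_index = NA_integer_,
                             recycle = NA_integer_, final = NA,
                             replica = NA_integer_, seed = NA_integer_,
                             basin = NA_character_)
  }
  stopifnot(nrow(provenance) == length(models))
  structure(list(conformers = models, provenance = provenance,
                 n_residues = n_res[1L]),
            class = "conformer_ensemble")
}

#' Number of conformers in an ensemble
#' @param ensemble a `conformer_ensemble`.
#' @return integer.
#' @export
ensemble_size <- function(ensemble) length(ensemble$conformers)

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("conformer_ensemble: %d conformers x %d residues\n",
              ensemble_size(x), x$n_residues))
  invisible(x)
}

#' Subset an ensemble, keeping provenance aligned
#' @param ensemble a `conformer_ensemble`.
#' @param idx integer indices of the conformers to keep (order respected).
#' @return a `conformer_ensemble`.
#' @export
subset_ensemble <- function(ensemble, idx) {
  conformer_ensemble(ensemble$conformers[idx],
                     provenance = ensemble$provenance[idx, , drop = FALSE])
}

#' Per-residue pLDDT matrix of an ensemble
#' @param ensemble a `conformer_ensemble`.
#' @return numeric matrix, conformers x residues.
#' @export
ensemble_plddt <- function(ensemble) {
  t(vapply(ensemble$conformers, function(m) unname(extract_plddt(m)),
           numeric(ensemble$n_residues)))
}

#' Rerank and filter an ensemble by prediction confidence
#'
#' Keeps the conformers in which more than `min_fraction` of residues reach
#' pLDDT >= `plddt_threshold` -- the stable, presumably functionally
#' relevant states -- and orders them by descending confident fraction
#' (ties by mean pLDDT). With `plddt_threshold = 0` this is the identity
#' (up to ordering).
#'
#' @param ensemble a `conformer_ensemble`.
#' @param plddt_threshold confidence threshold (default 85).
#' @param min_fraction required fraction of confident residues, exclusive
#'   (default 0.70).
#' @return list with `ensemble` (the filtered, reordered ensemble, or
#'   `NULL` when nothing passes) and `table` (per-conformer
#'   `confident_fraction`, `mean_plddt`, `kept`).
#' @export
rerank_by_confidence <- function(ensemble, plddt_threshold = 85,
                                 min_fraction = 0.70) {
  if (ensemble_size(ensemble) == 0L) {
    warning("empty ensemble", call. = FALSE)
    return(list(ensemble = NULL,
                table = data.frame(conformer = integer(0),
                                   confident_fraction = numeric(0),
                                   mean_plddt = numeric(0),
                                   kept = logical(0))))
  }
  pl <- ensemble_plddt(ensemble)
  frac <- rowMeans(pl >= plddt_threshold)
  meanpl <- rowMeans(pl)
  kept <- frac > min_fraction
  tab <- data.frame(conformer = seq_len(nrow(pl)),
                    confident_fraction = frac, mean_plddt = meanpl,
                    kept = kept)
  if (!any(kept)) {
    warning("no conformer passed the confidence filter", call. = FALSE)
    return(list(ensemble = NULL, table = tab))
  }
  ord <- order(-frac, -meanpl)
  ord <- ord[kept[ord]]
  list(ensemble = subset_ensemble(ensemble, ord), table = tab)
}

#' RMSD profile of an ensemble against an apo/holo pair
#'
#' Computes, for every conformer, the RMSD to the apo and to the holo
#' reference over the selected atom set, plus box-plot summaries (Tukey
#' convention) and fixed-width histograms of both columns.
#'
#' @param ensemble a `conformer_ensemble` whose residue numbering matches
#'   the references (up to `offset`).
#' @param pair a [reference_pair()].
#' @param atom_set `"backbone"` (default), `"ca"`, or
#'   `"pocket_sidechain_heavy"` (pocket defined on the holo form and mapped
#'   to apo numbering through the pair correspondence).
#' @param offset numbering offset from conformer residues to apo residues.
#' @param min_matched minimum matched residues for the conformer/reference
#'   correspondences.
#' @return object of class `rmsd_profile`: `table` (per-conformer
#'   `rmsd_to_apo`, `rmsd_to_holo` in Angstrom), `summary` (per reference:
#'   mean, median, quartiles, Tukey whiskers), and `histogram` (per
#'   reference, from [distribution_summary()]).
#' @export
rmsd_profile <- function(ensemble, pair, atom_set = "backbone", offset = 0L,
                         min_matched = 30L) {
  stopifnot(inherits(ensemble, "conformer_ensemble"),
            inherits(pair, "reference_pair"))
  tmpl <- ensemble$conformers[[1L]]
  corr_apo <- build_correspondence(tmpl, pair$apo, offset = offset,
                                   min_matched = min_matched)
  corr_holo <- build_correspondence(tmpl, pair$holo,
                                    offset = offset + pair$offset,
                                    min_matched = min_matched)
  pocket_holo <- pair$pocket
  pocket_apo <- NULL
  if (identical(atom_set, "pocket_sidechain_heavy")) {
    if (is.null(pocket_holo)) {
      stop("pair has no pocket; construct it with a ligand selector",
           call. = FALSE)
    }
    pc <- pair$correspondence
    hit <- paste(pc$resno_b, pc$insert_b) %in%
      paste(pocket_holo$resno, pocket_holo$insert)
    pocket_apo <- data.frame(resno = pc$resno_a[hit],
                             insert = pc$insert_a[hit])
  }
  n <- ensemble_size(ensemble)
  to_apo <- to_holo <- numeric(n)
  for (i in seq_len(n)) {
    m <- ensemble$conformers[[i]]
    to_apo[i] <- as.numeric(rmsd_between(m, pair$apo, corr_apo, atom_set,
                                         pocket = pocket_apo))
    to_holo[i] <- as.numeric(rmsd_between(m, pair$holo, corr_holo, atom_set,
                                          pocket = pocket_holo))
  }
  tab <- data.frame(conformer = seq_len(n), rmsd_to_apo = to_apo,
                    rmsd_to_holo = to_holo)
  box <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    c(mean = mean(v), median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = lo, whisker_high = hi)
  }
  structure(list(
    table = tab,
    atom_set = atom_set,
    summary = rbind(apo = box(to_apo), holo = box(to_holo)),
    histogram = list(apo = distribution_summary(to_apo, "rmsd"),
                     holo = distribution_summary(to_holo, "rmsd"))
  ), class = "rmsd_profile")
}

#' @export
print.rmsd_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf("rmsd_profile (%s): %d conformers\n  vs apo : mean %.2f A, median %.2f A\n  vs holo: mean %.2f A, median %.2f A\n",
              x$atom_set, nrow(x$table),
              s["apo", "mean"], s["apo", "median"],
              s["holo", "mean"], s["holo", "median"]))
  invisible(x)
}

#' Classify conformers as apo-like, holo-like or intermediate
#'
#' A conformer is labelled `apo` when its RMSD to the apo reference is
#' smaller than its RMSD to the holo reference by more than `margin` (and
#' `holo` in the reverse case); conformers inside the margin band are
#' `intermediate`. The default margin of 0.5 Angstrom sits below typical
#' coordinate noise, so only genuinely ambiguous geometries are called
#' intermediate.
#'
#' @param profile an [rmsd_profile()].
#' @param margin classification margin in Angstrom (default 0.5).
#' @return factor of labels (`apo`, `holo`, `intermediate`), one per
#'   conformer.
#' @export
classify_states <- function(profile, margin = 0.5) {
  stopifnot(inherits(profile, "rmsd_profile"))
  a <- profile$table$rmsd_to_apo
  h <- profile$table$rmsd_to_holo
  lab <- ifelse(a + margin < h, "apo",
                ifelse(h + margin < a, "holo", "intermediate"))
  factor(lab, levels = c("apo", "holo", "intermediate"))
}

#' Pairwise RMSD matrix of an ensemble
#'
#' All-vs-all RMSD after pairwise Kabsch superposition on the selected atom
#' set; conformers share topology, so atoms pair positionally.
#'
#' @param ensemble a `conformer_ensemble`.
#' @param atom_set `"ca"` (default) or `"backbone"`.
#' @return symmetric numeric matrix (Angstrom).
#' @export
pairwise_rmsd <- function(ensemble, atom_set = c("ca", "backbone")) {
  atom_set <- match.arg(atom_set)
  names_keep <- if (atom_set == "ca") "CA" else c("N", "CA", "C", "O")
  tmpl <- ensemble$conformers[[1L]]$atoms
  sel <- which(!tmpl$het & tmpl$elety %in% names_keep)
  coords <- lapply(ensemble$conformers, function(m) {
    as.matrix(m$atoms[sel, c("x", "y", "z")])
  })
  n <- length(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
    }
  }
  d
}

#' Cluster an ensemble by pairwise RMSD
#'
#' Agglomerative hierarchical clustering with Ward's linkage on the
#' all-vs-all superposed RMSD matrix; the number of clusters is chosen by
#' maximizing the mean silhouette width (computed from the same distances)
#' over `k_range`, with ties broken toward the smaller k. Note that RMSD
#' distances are not an exact Euclidean embedding, so Ward linkage is used
#' in its dissimilarity form (`ward.D2`).
#'
#' @param ensemble a `conformer_ensemble`, size >= `max(k_range) + 1`.
#' @param atom_set passed to [pairwise_rmsd()] (default `"ca"`).
#' @param k_range candidate cluster counts (default `2:10`).
#' @return object of class `cluster_solution`: `labels` (integer in
#'   `1..k`), `k`, `silhouette` (named mean widths per candidate k),
#'   `linkage`, `distance` (the RMSD matrix), and the `hclust` tree.
#' @export
cluster_ensemble <- function(ensemble, atom_set = "ca", k_range = 2:10) {
  n <- ensemble_size(ensemble)
  if (n < max(k_range) + 1L) {
    stop("ensemble of ", n, " conformers is too small for k up to ",
         max(k_range), call. = FALSE)
  }
  d <- pairwise_rmsd(ensemble, atom_set)
  if (max(d) < 1e-6) {
    stop("all conformers are identical to within 1e-6 A: the distance ",
         "matrix is degenerate and clustering is meaningless (use k = 1)",
         call. = FALSE)
  }
  tree <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(tree, k = k)
    if (length(unique(lab)) < 2L) return(NA_real_)
    mean(cluster::silhouette(lab, dmatrix = d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  best <- k_range[which.max(sil)]       # which.max takes the first maximum
  structure(list(labels = unname(stats::cutree(tree, k = best)),
                 k = best, silhouette = sil, linkage = "ward.D2",
                 distance = d, tree = tree),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: k = %d (Ward linkage), silhouette %.3f\n",
              x$k, x$silhouette[as.character(x$k)]))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Cluster/state contingency table
#'
#' Cross-validates a clustering against state labels (e.g. the apo/holo
#' classification): how the conformers of each cluster distribute over the
#' functional states.
#'
#' @param solution a [cluster_ensemble()] solution.
#' @param states factor of state labels per conformer.
#' @return a contingency table.
#' @export
cluster_state_table <- function(solution, states) {
  stopifnot(inherits(solution, "cluster_solution"))
  table(cluster = solution$labels, state = states)
}

#' Confidence/deviation table and rank correlation
#'
#' Emits the per-conformer (mean pLDDT, RMSD-to-apo, RMSD-to-holo) table
#' and the Spearman rank correlation of mean pLDDT against each RMSD
#' column. A strong negative correlation indicates that the predictor's
#' confidence tracks closeness to that reference. With constant pLDDT (or
#' a single conformer) the correlation is undefined and reported as `NA`.
#'
#' @param ensemble a `conformer_ensemble`.
#' @param profile the matching [rmsd_profile()].
#' @return list with `table` and `spearman` (named: `vs_apo`, `vs_holo`;
#'   `NA` when undefined).
#' @export
plddt_rmsd_scatter <- function(ensemble, profile) {
  stopifnot(inherits(profile, "rmsd_profile"),
            ensemble_size(ensemble) == nrow(profile$table))
  meanpl <- rowMeans(ensemble_plddt(ensemble))
  tab <- data.frame(conformer = profile$table$conformer,
                    mean_plddt = meanpl,
                    rmsd_to_apo = profile$table$rmsd_to_apo,
                    rmsd_to_holo = profile$table$rmsd_to_holo)
  rho <- function(y) {
    if (length(meanpl) < 2L || stats::sd(meanpl) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(meanpl, y, method = "spearman")
  }
  list(table = tab,
       spearman = c(vs_apo = rho(tab$rmsd_to_apo),
                    vs_holo = rho(tab$rmsd_to_holo)))
}

#' Fixed-grid histogram and kernel density of a metric
#'
#' Histograms use fixed bin widths per metric kind (RMSD 0.25 Angstrom,
#' TM-score 0.025, pLDDT 2.5) with bin edges anchored at 0, so outputs are
#' comparable across runs; the density is a Gaussian kernel estimate with
#' Silverman's rule-of-thumb bandwidth. With fewer than two distinct
#' values the density is undefined and omitted.
#'
#' @param values numeric vector, length >= 1.
#' @param kind `"rmsd"`, `"tm"`, or `"plddt"`.
#' @return object of class `distribution_summary`: `kind`, `binwidth`,
#'   `breaks`, `mids`, `counts`, and `density` (data frame `x`, `y`, or
#'   `NULL` when undefined).
#' @export
distribution_summary <- function(values, kind = c("rmsd", "tm", "plddt")) {
  kind <- match.arg(kind)
  if (length(values) < 1L) stop("no values", call. = FALSE)
  w <- switch(kind, rmsd = 0.25, tm = 0.025, plddt = 2.5)
  lo <- w * floor(min(values) / w)
  hi <- w * ceiling(max(values) / w)
  if (hi <= lo) hi <- lo + w
  breaks <- seq(lo, hi, by = w)
  if (max(values) >= breaks[length(breaks)]) {     # guard fp edge
    breaks <- c(breaks, breaks[length(breaks)] + w)
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE, right = FALSE)
  dens <- NULL
  if (length(values) >= 2L && stats::sd(values) > 0) {
    d <- stats::density(values, bw = "nrd0")
    dens <- data.frame(x = d$x, y = d$y)
  }
  structure(list(kind = kind, binwidth = w, breaks = h$breaks,
                 mids = h$mids, counts = h$counts, density = dens),
            class = "distribution_summary")
}

#' Locate the occupied modes of a distribution summary
#'
#' Returns the bin midpoints of the `n` highest local maxima of the
#' histogram (bins higher than both neighbours; plateau edges count),
#' ordered by position. Used to read off the basin positions of bimodal
#' RMSD profiles.
#'
#' @param ds a [distribution_summary()].
#' @param n number of modes to return.
#' @return numeric vector of bin midpoints (length <= n).
#' @export
histogram_modes <- function(ds, n = 2L) {
  stopifnot(inherits(ds, "distribution_summary"))
  cnt <- ds$counts
  k <- length(cnt)
  pad <- c(-Inf, cnt, -Inf)
  is_peak <- vapply(seq_len(k), function(i) {
    cnt[i] > 0 && pad[i] <= cnt[i] && cnt[i] >= pad[i + 2] &&
      (pad[i] < cnt[i] || pad[i + 2] < cnt[i])
  }, logical(1))
  peaks <- which(is_peak)
  if (length(peaks) == 0L) peaks <- which.max(cnt)
  top <- peaks[order(-cnt[peaks])][seq_len(min(n, length(peaks)))]
  sort(ds$mids[top])
}
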