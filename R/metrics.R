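#' Kabsch least-squares superposition
#'
#' Closed-form rigid-body alignment of two paired point sets via singular
#' value decomposition of the cross-covariance matrix, with the determinant
#' correction that excludes reflections. The returned transform maps `b`
#' onto `a`: `x_a ~ R x_b + t`.
#'
#' @param a,b numeric N x 3 coordinate matrices (Angstrom), N >= 3, paired
#'   row-wise.
#' @return object of class `superposition`: `rotation` (3 x 3 proper
#'   rotation), `translation` (length-3), `rmsd` (Angstrom), `n` (points
#'   used), and logical `degenerate` (set for collinear/planar-rank-deficient
#'   inputs, which are still solved).
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3L || ncol(b) != 3L) {
    stop("coordinate sets must be N x 3 with equal N", call. = FALSE)
  }
  if (nrow(a) < 3L) stop("at least 3 points required", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  h <- crossprod(bc, ac)                       # 3x3 cross-covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- bc %*% t(r)
  rmsd <- sqrt(mean(rowSums((ac - fitted)^2)))
  degenerate <- s$d[2L] <= 1e-8 * max(s$d[1L], 1e-12)
  structure(list(rotation = r,
                 translation = as.numeric(ca - r %*% cb),
                 rmsd = rmsd, n = nrow(a), degenerate = degenerate),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A over %d points%s\n", x$rmsd, x$n,
              if (x$degenerate) " (degenerate point set)" else ""))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup a `superposition`.
#' @param coords N x 3 matrix in the frame of the second (`b`) point set.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  stopifnot(inherits(sup, "superposition"))
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, `+`)
}

# Paired coordinates of matched residues for a named atom selection.
# Atoms missing in either residue are dropped pairwise.
paired_coords <- function(a, b, correspondence,
                          atom_set = c("backbone", "ca",
                                       "pocket_sidechain_heavy"),
                          pocket = NULL) {
  atom_set <- match.arg(atom_set)
  rows <- correspondence
  if (atom_set == "pocket_sidechain_heavy") {
    if (is.null(pocket) || nrow(pocket) == 0L) {
      stop("pocket residue set is empty; define a pocket first",
           call. = FALSE)
    }
    keep <- paste(rows$resno_b, rows$insert_b) %in%
      paste(pocket$resno, pocket$insert)
    rows <- rows[keep, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("no pocket residues present in the correspondence", call. = FALSE)
    }
  }
  at_a <- a$atoms[!a$atoms$het, , drop = FALSE]
  at_b <- b$atoms[!b$atoms$het, , drop = FALSE]
  at_a <- at_a[at_a$chain == at_a$chain[1L], , drop = FALSE]
  at_b <- at_b[at_b$chain == at_b$chain[1L], , drop = FALSE]
  backbone <- c("N", "CA", "C", "O", "OXT")
  sel_names <- function(at) {
    if (atom_set == "ca") at$elety == "CA"
    else if (atom_set == "backbone") at$elety %in% c("N", "CA", "C", "O")
    else !(at$elety %in% backbone) & !grepl("^[0-9]*H", at$elety)
  }
  at_a <- at_a[sel_names(at_a), , drop = FALSE]
  at_b <- at_b[sel_names(at_b), , drop = FALSE]
  key_a <- paste(at_a$resno, at_a$insert, at_a$elety, sep = "\r")
  key_b <- paste(at_b$resno, at_b$insert, at_b$elety, sep = "\r")
  want_a <- paste(rep(rows$resno_a, each = 1L), rows$insert_a, sep = "\r")
  # expand residue pairs to atom pairs present in both structures
  idx_a <- integer(0); idx_b <- integer(0)
  split_a <- split(seq_along(key_a), paste(at_a$resno, at_a$insert, sep = "\r"))
  split_b <- split(seq_along(key_b), paste(at_b$resno, at_b$insert, sep = "\r"))
  for (i in seq_len(nrow(rows))) {
    ia <- split_a[[paste(rows$resno_a[i], rows$insert_a[i], sep = "\r")]]
    ib <- split_b[[paste(rows$resno_b[i], rows$insert_b[i], sep = "\r")]]
    if (is.null(ia) || is.null(ib)) next
    common <- intersect(at_a$elety[ia], at_b$elety[ib])
    if (length(common) == 0L) next
    idx_a <- c(idx_a, ia[match(common, at_a$elety[ia])])
    idx_b <- c(idx_b, ib[match(common, at_b$elety[ib])])
  }
  n_requested <- nrow(rows) * (if (atom_set == "ca") 1L else 4L)
  list(a = as.matrix(at_a[idx_a, c("x", "y", "z")]),
       b = as.matrix(at_b[idx_b, c("x", "y", "z")]),
       n_atoms = length(idx_a),
       n_dropped = max(0L, n_requested - length(idx_a)))
}

#' RMSD between two structures over a selectable atom set
#'
#' Fits the Kabsch superposition on the selected atoms and reports the
#' minimized RMSD on that same selection. Atoms missing in either structure
#' are dropped pairwise; the count used is attached as an attribute.
#'
#' @param a,b `structure_model`s.
#' @param correspondence residue pairing from [build_correspondence()].
#' @param atom_set `"backbone"` (N, CA, C, O; default), `"ca"`, or
#'   `"pocket_sidechain_heavy"` (side-chain heavy atoms of the pocket
#'   residues).
#' @param pocket pocket residue set from [define_pocket()] (in `b`'s
#'   numbering); required for the pocket atom set.
#' @return RMSD in Angstrom, with attributes `n_atoms` and `superposition`.
#' @export
rmsd_between <- function(a, b, correspondence, atom_set = "backbone",
                         pocket = NULL) {
  pc <- paired_coords(a, b, correspondence, atom_set, pocket)
  if (pc$n_atoms < 3L) {
    stop("fewer than 3 paired atoms for atom set '", atom_set, "'",
         call. = FALSE)
  }
  sup <- kabsch_superpose(pc$a, pc$b)
  out <- sup$rmsd
  attr(out, "n_atoms") <- pc$n_atoms
  attr(out, "superposition") <- sup
  out
}

#' TM-score distance scale d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, floored at `d0_min` so short chains
#' keep a positive scale.
#'
#' @param l_ref normalizing chain length.
#' @param d0_min floor (default 0.5).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_ref, d0_min = 0.5) {
  max(d0_min, 1.24 * (max(l_ref - 15, 0))^(1 / 3) - 1.8)
}

#' Template-modeling score between two structures
#'
#' Computes `TM = max over superpositions of (1/L_ref) * sum_i
#' 1 / (1 + (d_i/d0)^2)` over the Calpha atoms of the matched residues,
#' with `d0 = 1.24 (L_ref - 15)^(1/3) - 1.8`. The maximization follows the
#' TM-align convention for a fixed residue equivalency: superpositions are
#' seeded from the full length, halves, and sliding fragments, then refined
#' iteratively by re-fitting on the residues currently within the distance
#' cutoff until the selected set is stable; the best score over all
#' superpositions is returned. Scores lie in (0, 1]; 1 is a perfect match
#' and > 0.5 indicates the same fold.
#'
#' @param a,b `structure_model`s.
#' @param correspondence residue pairing from [build_correspondence()]
#'   (length >= 3).
#' @param normalize_by `"b"` (default; `b` is conventionally the reference,
#'   e.g. the holo form) or `"a"`: which full chain length sets `L_ref`.
#' @return TM-score in (0, 1], with attribute `d0`.
#' @export
tm_score <- function(a, b, correspondence, normalize_by = c("b", "a")) {
  normalize_by <- match.arg(normalize_by)
  pc <- paired_coords(a, b, correspondence, atom_set = "ca")
  n <- pc$n_atoms
  if (n < 3L) stop("TM-score needs at least 3 matched residues", call. = FALSE)
  l_ref <- nrow(residue_table(if (normalize_by == "b") b else a))
  if (l_ref < 3L) stop("normalizing length below 3", call. = FALSE)
  d0 <- tm_d0(l_ref)

  score_of <- function(sup) {
    d <- sqrt(rowSums((pc$a - apply_superposition(sup, pc$b))^2))
    list(score = sum(1 / (1 + (d / d0)^2)) / l_ref, d = d)
  }
  refine <- function(idx) {
    best <- 0
    prev <- integer(0)
    for (iter in 1:20) {
      if (length(idx) < 3L) break
      sup <- kabsch_superpose(pc$a[idx, , drop = FALSE],
                              pc$b[idx, , drop = FALSE])
      sc <- score_of(sup)
      best <- max(best, sc$score)
      d_cut <- max(d0, 1.5)
      sel <- which(sc$d < d_cut)
      while (length(sel) < 3L) {
        d_cut <- d_cut + 0.5
        sel <- which(sc$d < d_cut)
      }
      if (identical(sel, prev)) break
      prev <- idx <- sel
    }
    best
  }

  lens <- unique(pmax(4L, n %/% c(1L, 2L, 4L, 8L, 16L)))
  lens <- lens[lens <= n]
  best <- 0
  for (L in lens) {
    starts <- seq(1L, n - L + 1L, by = max(1L, L %/% 2L))
    for (s in starts) {
      best <- max(best, refine(s:(s + L - 1L)))
    }
  }
  structure(min(best, 1), d0 = d0)
}

#' Pair an apo and a holo reference structure
#'
#' Builds the residue correspondence (and, when a ligand is named, the
#' binding pocket on the holo form) needed to characterize a conformational
#' change or to profile a predicted ensemble against both endpoints.
#'
#' @param apo,holo `structure_model`s of the unbound and ligand-bound forms.
#' @param ligand optional ligand selector for [define_pocket()].
#' @param offset numbering offset passed to [build_correspondence()]
#'   (`resno_holo = resno_apo + offset`).
#' @param pocket_cutoff pocket heavy-atom cutoff in Angstrom.
#' @param min_matched minimum matched residues.
#' @return object of class `reference_pair` with `apo`, `holo`,
#'   `correspondence`, `pocket` (or `NULL`), and empty `metrics`.
#' @export
reference_pair <- function(apo, holo, ligand = NULL, offset = 0L,
                           pocket_cutoff = 4.5, min_matched = 30L) {
  stopifnot(inherits(apo, "structure_model"),
            inherits(holo, "structure_model"))
  corr <- build_correspondence(apo, holo, offset = offset,
                               min_matched = min_matched)
  pocket <- if (!is.null(ligand)) {
    define_pocket(holo, ligand, cutoff = pocket_cutoff)
  }
  structure(list(apo = apo, holo = holo, correspondence = corr,
                 pocket = pocket, offset = as.integer(offset),
                 metrics = NULL),
            class = "reference_pair")
}

#' Characterize an apo/holo reference pair
#'
#' Computes the pairwise similarity metrics between the unbound and bound
#' forms: Calpha and backbone RMSD, side-chain heavy-atom RMSD over the
#' binding pocket (when a ligand was given), and the TM-score normalized by
#' each chain length (holo normalization is the headline value).
#'
#' @param pair a [reference_pair()].
#' @return the pair with `metrics` filled: `rmsd_ca`, `rmsd_backbone`,
#'   `rmsd_pocket_sidechain` (`NA` without a ligand), `tm_score`
#'   (holo-normalized), `tm_score_apo_norm`, `n_matched`.
#' @export
characterize_pair <- function(pair) {
  stopifnot(inherits(pair, "reference_pair"))
  corr <- pair$correspondence
  rmsd_ca <- rmsd_between(pair$apo, pair$holo, corr, atom_set = "ca")
  rmsd_bb <- rmsd_between(pair$apo, pair$holo, corr, atom_set = "backbone")
  rmsd_pocket <- if (!is.null(pair$pocket)) {
    rmsd_between(pair$apo, pair$holo, corr,
                 atom_set = "pocket_sidechain_heavy", pocket = pair$pocket)
  } else NA_real_
  tm_holo <- tm_score(pair$apo, pair$holo, corr, normalize_by = "b")
  tm_apo <- tm_score(pair$apo, pair$holo, corr, normalize_by = "a")
  pair$metrics <- data.frame(
    rmsd_ca = as.numeric(rmsd_ca),
    rmsd_backbone = as.numeric(rmsd_bb),
    rmsd_pocket_sidechain = as.numeric(rmsd_pocket),
    tm_score = as.numeric(tm_holo),
    tm_score_apo_norm = as.numeric(tm_apo),
    n_matched = attr(corr, "n_matched")
  )
  pair
}

#' @export
print.reference_pair <- function(x, ...) {
  cat(sprintf("reference_pair: apo '%s' vs holo '%s', %d matched residues\n",
              x$apo$id, x$holo$id, attr(x$correspondence, "n_matched")))
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  backbone RMSD %.2f A | Calpha RMSD %.2f A | TM-score %.3f (holo-normalized)\n",
                m$rmsd_backbone, m$rmsd_ca, m$tm_score))
  }
  invisible(x)
}
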