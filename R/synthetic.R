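#' Synthetic two-domain hinge structure
#'
#' Builds an idealized two-domain protein backbone (N, CA, C, O per
#' residue) whose Calpha trace follows an alpha-helical curve (radius 2.3
#' Angstrom, rise 1.5, 100 degrees per residue, giving the canonical 3.8
#' Angstrom Calpha spacing). The second domain can be bent about a hinge
#' through the last Calpha of the first domain, emulating the open/closed
#' (apo/holo) hinge motions of periplasmic binding proteins. The geometry
#' is deterministic and intentionally idealized: it carries realistic
#' inter-atomic scales for superposition metrics, not stereochemistry.
#'
#' @param n_per_domain residues per domain (default 60).
#' @param angle hinge bend in radians (0 = open form).
#' @param id model id.
#' @param source model source tag.
#' @return a [structure_model()] with polyalanine residues numbered
#'   `1..2*n_per_domain`, chain A, B-factor 100.
#' @export
synthetic_hinge_structure <- function(n_per_domain = 60L, angle = 0,
                                      id = "hinge",
                                      source = "experimental") {
  n <- 2L * as.integer(n_per_domain)
  i <- seq_len(n)
  phi <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * i)
  # local cylindrical frame for the remaining backbone atoms
  rad <- cbind(cos(phi), sin(phi), 0)
  tan_ <- cbind(-sin(phi), cos(phi), 0)
  up <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  npos <- ca - 0.55 * tan_ - 1.20 * up + 0.35 * rad
  cpos <- ca + 0.70 * tan_ + 1.10 * up + 0.20 * rad
  opos <- cpos + 1.23 * rad

  xyz <- matrix(NA_real_, nrow = 4L * n, ncol = 3)
  xyz[seq(1, 4 * n, by = 4), ] <- npos
  xyz[seq(2, 4 * n, by = 4), ] <- ca
  xyz[seq(3, 4 * n, by = 4), ] <- cpos
  xyz[seq(4, 4 * n, by = 4), ] <- opos

  if (angle != 0) {
    hinge <- ca[n_per_domain, ]
    rot <- matrix(c(1, 0, 0,
                    0, cos(angle), -sin(angle),
                    0, sin(angle), cos(angle)), 3, 3, byrow = TRUE)
    move <- rep(i > n_per_domain, each = 4L)
    shifted <- sweep(xyz[move, , drop = FALSE], 2, hinge)
    xyz[move, ] <- sweep(shifted %*% t(rot), 2, hinge, `+`)
  }

  atoms <- data.frame(
    eleno = seq_len(4L * n),
    elety = rep(c("N", "CA", "C", "O"), times = n),
    resid = "ALA", chain = "A",
    resno = rep(i, each = 4L), insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = 100, o = 1, het = FALSE,
    stringsAsFactors = FALSE
  )
  structure_model(atoms, id = id, source = source)
}

#' Hinge angle producing a target open/closed RMSD
#'
#' Solves for the bend angle at which the backbone RMSD between the open
#' and closed forms of [synthetic_hinge_structure()] equals `target_rmsd`.
#' The RMSD grows monotonically with the angle over (0, pi/2], so the root
#' is unique.
#'
#' @param target_rmsd desired backbone RMSD in Angstrom (default 3.5).
#' @param n_per_domain residues per domain.
#' @return angle in radians.
#' @export
calibrate_hinge_angle <- function(target_rmsd = 3.5, n_per_domain = 60L) {
  open <- synthetic_hinge_structure(n_per_domain, angle = 0)
  corr <- build_correspondence(open, open)
  f <- function(theta) {
    closed <- synthetic_hinge_structure(n_per_domain, angle = theta)
    as.numeric(rmsd_between(open, closed, corr, atom_set = "backbone")) -
      target_rmsd
  }
  stats::uniroot(f, lower = 1e-3, upper = pi / 2, tol = 1e-6)$root
}

#' Synthetic apo/holo hinge pair
#'
#' Open (apo) and closed (holo) forms of the synthetic hinge protein, the
#' closed form bent to a specified inter-basin backbone RMSD (default 3.5
#' Angstrom, a typical hinge-type apo/holo difference). Both models share
#' residue numbering, so they plug directly into [reference_pair()] and
#' [mock_backend()].
#'
#' @param n_per_domain residues per domain (default 60).
#' @param target_rmsd inter-basin backbone RMSD in Angstrom; ignored when
#'   `angle` is given.
#' @param angle explicit hinge angle in radians (optional).
#' @return list with `open` and `closed` `structure_model`s, the `angle`
#'   used, and the achieved backbone `rmsd`.
#' @export
synthetic_hinge_pair <- function(n_per_domain = 60L, target_rmsd = 3.5,
                                 angle = NULL) {
  if (is.null(angle)) {
    angle <- calibrate_hinge_angle(target_rmsd, n_per_domain)
  }
  open <- synthetic_hinge_structure(n_per_domain, angle = 0,
                                    id = "hinge_open")
  closed <- synthetic_hinge_structure(n_per_domain, angle = angle,
                                      id = "hinge_closed")
  corr <- build_correspondence(open, closed)
  rmsd <- as.numeric(rmsd_between(open, closed, corr,
                                  atom_set = "backbone"))
  list(open = open, closed = closed, angle = angle, rmsd = rmsd)
}
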