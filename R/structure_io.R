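#' Construct a structure model from an atom table
#'
#' The atom table is the single coordinate carrier used throughout the
#' package. Columns: `eleno`, `elety` (PDB atom name), `resid` (3-letter
#' residue name), `chain`, `resno` (author numbering), `insert` (insertion
#' code, `""` if none), `x`, `y`, `z` (Angstrom), `b` (B-factor; pLDDT for
#' predictions), `o` (occupancy), `het` (logical heteroatom flag).
#'
#' @param atoms data frame as described above.
#' @param id model identifier.
#' @param source `"experimental"` or `"predicted"`.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, id = "model",
                            source = c("experimental", "predicted")) {
  source <- match.arg(source)
  need <- c("eleno", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z", "b", "o", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L) {
    stop("atom table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in atom table", call. = FALSE)
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  rownames(atoms) <- NULL
  structure(list(id = id, source = source, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("structure_model '%s' (%s): %d atoms, %d protein residues, chains %s\n",
              x$id, x$source, nrow(x$atoms), nrow(rt),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Read a PDB or mmCIF structure
#'
#' Heteroatoms are retained but flagged (`het`); alternate locations are
#' resolved to the highest-occupancy conformer (ties to the first altloc
#' code); insertion codes are preserved.
#'
#' @param path structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param chain optional chain selector; an error is raised when the chain
#'   is absent.
#' @param source `"experimental"` (default) or `"predicted"` (pLDDT in the
#'   B-factor column).
#' @param id model id; defaults to the file name.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           chain = NULL,
                           source = c("experimental", "predicted"),
                           id = tools::file_path_sans_ext(basename(path))) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- if (format == "cif") {
    bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  if (!is.null(chain)) {
    if (!chain %in% at$chain) {
      stop("chain '", chain, "' not present in ", path, call. = FALSE)
    }
    at <- at[at$chain == chain, , drop = FALSE]
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc resolution: keep the highest-occupancy alternate per atom site
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(at$eleno, pdb$atom$eleno)), , drop = FALSE]

  atoms <- data.frame(
    eleno = at$eleno, elety = at$elety, resid = at$resid, chain = at$chain,
    resno = at$resno, insert = at$insert,
    x = at$x, y = at$y, z = at$z, b = at$b, o = at$o,
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  structure_model(atoms, id = id, source = source)
}

#' Write a structure model as PDB
#'
#' For predicted models the per-residue confidence travels in the B-factor
#' column. Coordinates survive a round trip to within PDB fixed-width
#' precision (1e-3 Angstrom).
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, insert = a$insert,
    eleno = a$eleno, elety = a$elety, chain = a$chain,
    o = a$o, b = a$b
  )
  invisible(path)
}

#' Fetch a structure from the RCSB PDB by accession
#'
#' Disabled by default: the standard workflow is fully offline and any
#' download must be opted into explicitly.
#'
#' @param accession 4-character PDB id.
#' @param dir download directory.
#' @param allow_download set `TRUE` to permit network access.
#' @return path to the downloaded PDB file.
#' @export
fetch_structure <- function(accession, dir = tempdir(),
                            allow_download = FALSE) {
  if (!allow_download) {
    stop("downloads are disabled; pass allow_download = TRUE to fetch ",
         accession, " from the RCSB PDB", call. = FALSE)
  }
  dest <- file.path(dir, paste0(toupper(accession), ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb",
                   toupper(accession))
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}

#' Protein residue table of a model
#'
#' One row per non-heteroatom residue that has a Calpha atom, in file
#' order, keyed by (chain, resno, insert).
#'
#' @param model a `structure_model`.
#' @return data frame with `chain`, `resno`, `insert`, `resid`.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  ca <- a[!a$het & a$elety == "CA", , drop = FALSE]
  data.frame(chain = ca$chain, resno = ca$resno, insert = ca$insert,
             resid = ca$resid, stringsAsFactors = FALSE)
}

#' Extract per-residue pLDDT from a predicted model
#'
#' Reads the Calpha B-factor of every protein residue. Values outside the
#' pLDDT scale [0, 100] are reported as-is with a warning; residues without
#' a Calpha are skipped with a warning.
#'
#' @param model a predicted `structure_model`.
#' @return named numeric vector of pLDDT values, names `chain:resno`.
#' @export
extract_plddt <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms[!model$atoms$het, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$insert, sep = ":")
  res_keys <- unique(key)
  ca <- a[a$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, ca$insert, sep = ":")
  missing <- setdiff(res_keys, ca_key)
  if (length(missing) > 0L) {
    warning(length(missing), " residue(s) without Calpha skipped",
            call. = FALSE)
  }
  vals <- stats::setNames(ca$b, sub(":$", "", ca_key))
  out_of_range <- vals < 0 | vals > 100
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " pLDDT value(s) outside [0, 100]; reported as-is",
            call. = FALSE)
  }
  vals
}

#' Residue correspondence between two models
#'
#' Pairs residues by author residue number (plus insertion code) within the
#' first protein chain of each model, restricted to residues whose Calpha is
#' resolved in both. An optional declared numbering offset maps
#' `resno_b = resno_a + offset` (for constructs whose author numbering is
#' shifted). Fewer matches than `min_matched` is an error, because a
#' superposition fitted on too few residues is unreliable.
#'
#' @param a,b `structure_model`s of the same underlying protein.
#' @param offset integer numbering offset applied to `a`'s residue numbers.
#' @param min_matched minimum acceptable number of matched residues
#'   (default 30).
#' @return data frame with columns `resno_a`, `insert_a`, `resno_b`,
#'   `insert_b`; attributes `n_matched` and `n_dropped` report coverage.
#' @export
build_correspondence <- function(a, b, offset = 0L, min_matched = 30L) {
  ra <- residue_table(a)
  rb <- residue_table(b)
  ra <- ra[ra$chain == ra$chain[1L], , drop = FALSE]
  rb <- rb[rb$chain == rb$chain[1L], , drop = FALSE]
  key_a <- paste(ra$resno + as.integer(offset), ra$insert, sep = "\r")
  key_b <- paste(rb$resno, rb$insert, sep = "\r")
  hit <- match(key_a, key_b)
  keep <- !is.na(hit)
  out <- data.frame(
    resno_a = ra$resno[keep], insert_a = ra$insert[keep],
    resno_b = rb$resno[hit[keep]], insert_b = rb$insert[hit[keep]],
    stringsAsFactors = FALSE
  )
  n_dropped <- (nrow(ra) - nrow(out)) + (nrow(rb) - nrow(out))
  if (nrow(out) < min_matched) {
    stop("only ", nrow(out), " residues matched between '", a$id, "' and '",
         b$id, "' (minimum ", min_matched, "); superposition would be unreliable",
         call. = FALSE)
  }
  attr(out, "n_matched") <- nrow(out)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Define a binding pocket around a ligand
#'
#' Selects protein residues with any heavy atom within `cutoff` (inclusive)
#' of any heavy atom of the chosen ligand. Waters are never treated as the
#' ligand.
#'
#' @param holo a `structure_model` containing the ligand as a heteroatom
#'   group.
#' @param ligand ligand residue name (e.g. `"RIB"`), optionally with an
#'   instance as `list(resid =, resno =)` when several copies are bound.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5).
#' @return data frame of pocket residues (`chain`, `resno`, `insert`).
#' @export
define_pocket <- function(holo, ligand, cutoff = 4.5) {
  stopifnot(inherits(holo, "structure_model"))
  a <- holo$atoms
  is_h <- grepl("^[0-9]*H", a$elety)
  water <- a$resid %in% c("HOH", "WAT", "DOD")
  if (is.character(ligand)) ligand <- list(resid = ligand)
  lig <- a$het & !water & a$resid == ligand$resid & !is_h
  if (!is.null(ligand$resno)) lig <- lig & a$resno == ligand$resno
  if (!any(lig)) {
    stop("ligand '", ligand$resid, "' not found in '", holo$id, "'",
         call. = FALSE)
  }
  prot <- !a$het & !is_h
  lxyz <- as.matrix(a[lig, c("x", "y", "z")])
  pxyz <- as.matrix(a[prot, c("x", "y", "z")])
  # min distance from each protein heavy atom to any ligand heavy atom
  d2min <- rep(Inf, nrow(pxyz))
  for (j in seq_len(nrow(lxyz))) {
    d2 <- (pxyz[, 1] - lxyz[j, 1])^2 + (pxyz[, 2] - lxyz[j, 2])^2 +
      (pxyz[, 3] - lxyz[j, 3])^2
    d2min <- pmin(d2min, d2)
  }
  near <- d2min <= cutoff^2
  pa <- a[prot, , drop = FALSE][near, , drop = FALSE]
  unique(data.frame(chain = pa$chain, resno = pa$resno, insert = pa$insert,
                    stringsAsFactors = FALSE))
}
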