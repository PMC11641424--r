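#' Prediction request for a structure-predictor backend
#'
#' Bundles one perturbed query replica with its subsampled alignment and the
#' run options of the prediction protocol. The defaults follow the ensemble
#' protocol: 5 pretrained models, 12 recycles (every recycle structure is
#' collected, plus one final refined structure per model), 1 seed, dropout
#' active at inference time.
#'
#' @param sequence replica query sequence (ungapped string), or `NULL` when
#'   the backend does not need it (pure mock runs).
#' @param msa optional `alignment_stack`.
#' @param partition optional `subsample_partition` of `msa`.
#' @param num_models number of predictor models (default 5).
#' @param num_recycles recycles collected per model (default 12).
#' @param num_seeds random seeds iterated per model (default 1).
#' @param use_dropout keep dropout layers active during inference
#'   (default `TRUE`), which broadens the sampled ensemble.
#' @param replica_id id of the masked replica this request came from.
#' @param seed RNG seed for the backend.
#' @return a `prediction_request`.
#' @export
prediction_request <- function(sequence = NULL, msa = NULL, partition = NULL,
                               num_models = 5L, num_recycles = 12L,
                               num_seeds = 1L, use_dropout = TRUE,
                               replica_id = 1L, seed = 1L) {
  num_models <- as.integer(num_models)
  num_recycles <- as.integer(num_recycles)
  num_seeds <- as.integer(num_seeds)
  if (num_models < 1L) stop("num_models must be >= 1", call. = FALSE)
  if (num_recycles < 0L) stop("num_recycles must be >= 0", call. = FALSE)
  if (num_seeds < 1L) stop("num_seeds must be >= 1", call. = FALSE)
  structure(list(sequence = sequence, msa = msa, partition = partition,
                 num_models = num_models, num_recycles = num_recycles,
                 num_seeds = num_seeds, use_dropout = isTRUE(use_dropout),
                 replica_id = as.integer(replica_id),
                 seed = as.integer(seed)),
            class = "prediction_request")
}

#' Expected number of conformers for a request
#'
#' Each model and seed yields one structure per recycle 0..num_recycles
#' plus a final refined structure: `num_models * num_seeds *
#' (num_recycles + 2)` conformers in total (70 at the defaults).
#'
#' @param request a `prediction_request`.
#' @return integer count.
#' @export
expected_conformers <- function(request) {
  request$num_models * request$num_seeds * (request$num_recycles + 2L)
}

#' Run a predictor backend on a request
#'
#' Dispatches to the backend implementation and enforces the count
#' contract: exactly `num_models * num_seeds * (num_recycles + 2)`
#' conformers, each carrying provenance (model id, recycle index or
#' final-structure flag, replica id, seed).
#'
#' @param request a [prediction_request()].
#' @param backend a backend object, e.g. [mock_backend()] or
#'   [colabfold_backend()].
#' @return a [conformer_ensemble()].
#' @export
run_backend <- function(request, backend) {
  stopifnot(inherits(request, "prediction_request"))
  ens <- predict_structures(backend, request)
  n_expect <- expected_conformers(request)
  if (ensemble_size(ens) != n_expect) {
    stop("backend returned ", ensemble_size(ens), " conformers, expected ",
         n_expect, call. = FALSE)
  }
  ens
}

#' Backend generic
#' @param backend backend object.
#' @param request a `prediction_request`.
#' @return a `conformer_ensemble`.
#' @export
predict_structures <- function(backend, request) {
  UseMethod("predict_structures")
}

#' Deterministic two-basin mock predictor
#'
#' A desk-scale stand-in for the neural-network predictor: every conformer
#' is drawn from one of two reference conformations ("basins", e.g. an open
#' and a closed hinge state) with mixture weight `weight_a`, then perturbed
#' with isotropic Gaussian coordinate noise. The synthetic per-residue
#' confidence decays with the residue's Calpha displacement `d_i` from its
#' basin position, `pLDDT_i = 100 exp(-d_i / sigma)` clipped to [30, 100],
#' so confidence is anti-correlated with displacement as it is for real
#' predictions. With the default `sigma = 2` Angstrom, rigid-core residues
#' stay above ~85 while residues displaced by more than ~0.7 Angstrom drop
#' below 70.
#'
#' @param basin_a,basin_b `structure_model`s with identical atom topology.
#' @param weight_a probability of drawing basin A (default 0.5).
#' @param noise_scale per-coordinate Gaussian noise SD in Angstrom
#'   (default 0.3).
#' @param plddt_sigma confidence decay constant in Angstrom (default 2).
#' @return a `mock_backend` object for [run_backend()].
#' @export
mock_backend <- function(basin_a, basin_b, weight_a = 0.5,
                         noise_scale = 0.3, plddt_sigma = 2.0) {
  stopifnot(inherits(basin_a, "structure_model"),
            inherits(basin_b, "structure_model"))
  if (nrow(basin_a$atoms) != nrow(basin_b$atoms) ||
      !all(basin_a$atoms$elety == basin_b$atoms$elety) ||
      !all(basin_a$atoms$resno == basin_b$atoms$resno)) {
    stop("basin conformations must share atom topology and residue numbering",
         call. = FALSE)
  }
  if (weight_a < 0 || weight_a > 1) {
    stop("weight_a must lie in [0, 1]", call. = FALSE)
  }
  structure(list(basin_a = basin_a, basin_b = basin_b, weight_a = weight_a,
                 noise_scale = noise_scale, plddt_sigma = plddt_sigma),
            class = "mock_backend")
}

#' @export
predict_structures.mock_backend <- function(backend, request) {
  if (!is.null(request$sequence)) {
    n_res <- nrow(residue_table(backend$basin_a))
    if (nchar(request$sequence) != n_res) {
      stop("query length ", nchar(request$sequence),
           " does not match basin residue count ", n_res, call. = FALSE)
    }
  }
  atoms_a <- backend$basin_a$atoms
  atoms_b <- backend$basin_b$atoms
  ca_idx <- which(!atoms_a$het & atoms_a$elety == "CA")
  set.seed(request$seed)
  models <- list()
  prov <- list()
  i <- 0L
  for (m in seq_len(request$num_models)) {
    for (s in seq_len(request$num_seeds)) {
      for (rec in c(0:request$num_recycles, NA_integer_)) {   # NA = final
        i <- i + 1L
        from_a <- stats::runif(1) < backend$weight_a
        base <- if (from_a) atoms_a else atoms_b
        xyz <- as.matrix(base[, c("x", "y", "z")])
        noise <- matrix(stats::rnorm(length(xyz), sd = backend$noise_scale),
                        ncol = 3L)
        at <- base
        at[, c("x", "y", "z")] <- xyz + noise
        d_ca <- sqrt(rowSums(noise[ca_idx, , drop = FALSE]^2))
        plddt <- pmin(100, pmax(30, 100 * exp(-d_ca / backend$plddt_sigma)))
        at$b <- plddt[match(paste(at$resno, at$insert),
                            paste(at$resno[ca_idx], at$insert[ca_idx]))]
        models[[i]] <- structure_model(
          at, id = sprintf("m%d_s%d_r%s", m, s,
                           if (is.na(rec)) "final" else rec),
          source = "predicted")
        prov[[i]] <- data.frame(
          conformer = i, model = m, seed_index = s,
          recycle = if (is.na(rec)) NA_integer_ else rec,
          final = is.na(rec), replica = request$replica_id,
          seed = request$seed, basin = if (from_a) "A" else "B",
          stringsAsFactors = FALSE)
      }
    }
  }
  conformer_ensemble(models, provenance = do.call(rbind, prov))
}

#' Adapter for an external ColabFold-style predictor
#'
#' Thin subprocess wrapper around a `colabfold_batch`-compatible
#' executable. The adapter writes the replica query (and its subsampled
#' alignment, when given) to a work directory, invokes the executable with
#' the request's run options, and reads the produced PDB files (pLDDT in
#' the B-factor column) back as a conformer ensemble. No model weights are
#' bundled; a missing or failing executable raises an error carrying the
#' subprocess diagnostics.
#'
#' @param exe executable name or path (default `"colabfold_batch"`).
#' @param work_dir run directory (default a fresh temporary directory).
#' @param extra_args extra command-line arguments.
#' @return a `colabfold_backend` object for [run_backend()].
#' @export
colabfold_backend <- function(exe = "colabfold_batch",
                              work_dir = tempfile("colabfold_"),
                              extra_args = character()) {
  structure(list(exe = exe, work_dir = work_dir, extra_args = extra_args),
            class = "colabfold_backend")
}

#' @export
predict_structures.colabfold_backend <- function(backend, request) {
  path <- Sys.which(backend$exe)
  if (!nzchar(path)) {
    stop("external predictor backend '", backend$exe,
         "' not found on PATH; install ColabFold or use mock_backend()",
         call. = FALSE)
  }
  dir.create(backend$work_dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(backend$work_dir, "query.fasta")
  writeLines(c(sprintf(">replica_%03d", request$replica_id),
               request$sequence), fa)
  input <- fa
  if (!is.null(request$msa) && !is.null(request$partition)) {
    sub <- apply_partition(request$msa, request$partition)
    a3m <- file.path(backend$work_dir, "query.a3m")
    write_alignment(sub$attention, a3m)
    input <- a3m
  }
  args <- c(input, file.path(backend$work_dir, "out"),
            "--num-recycle", request$num_recycles,
            "--num-seeds", request$num_seeds,
            "--num-models", request$num_models,
            "--save-recycles",
            "--random-seed", request$seed,
            if (request$use_dropout) "--use-dropout",
            backend$extra_args)
  status <- suppressWarnings(
    system2(path, args, stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("external predictor failed (exit ", code, "):\n",
         paste(utils::tail(status, 20), collapse = "\n"), call. = FALSE)
  }
  pdbs <- sort(list.files(file.path(backend$work_dir, "out"),
                          pattern = "\\.pdb$", full.names = TRUE))
  if (length(pdbs) == 0L) {
    stop("external predictor produced no PDB output in ",
         backend$work_dir, call. = FALSE)
  }
  models <- lapply(pdbs, read_structure, source = "predicted")
  conformer_ensemble(models)
}
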