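#' Pipeline run configuration
#'
#' Assembles the configuration for [run_pipeline()], merging user settings
#' (an R list or a JSON file) over the protocol defaults: 45 scan replicas
#' with per-position substitution probability U(0.05, 0.15), a 16:32
#' max_seqs:extra_seqs subsampling preset, and 5 models x 12 recycles x 1
#' seed with dropout (70 structures per replica).
#'
#' @param config named list of overrides, or the path of a JSON file
#'   holding one.
#' @param ... further overrides applied on top (nested lists merge by
#'   name).
#' @return a `rass_config` list. Main fields: `query_fasta`, `msa_path`
#'   (optional), `region`, `n_replicas`, `p_low`, `p_high`, `seed`,
#'   `max_seqs`, `extra_seqs`, `num_models`, `num_recycles`, `num_seeds`,
#'   `use_dropout`, `backend` (`type` `"mock"` or `"colabfold"` plus its
#'   parameters), `references` (`apo`, `holo` paths, `chain`, `ligand`,
#'   `offset`, `min_matched`), `analysis` (`atom_set`, `plddt_threshold`,
#'   `min_fraction`, `k_min`, `k_max`, `margin`), `out_dir`.
#' @export
rass_config <- function(config = list(), ...) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(
    query_fasta = NULL, msa_path = NULL, msa_dialect = "a3m",
    region = NULL,
    n_replicas = 45L, p_low = 0.05, p_high = 0.15, seed = 1L,
    max_seqs = 16L, extra_seqs = 32L,
    num_models = 5L, num_recycles = 12L, num_seeds = 1L, use_dropout = TRUE,
    backend = list(type = "mock", basin_apo = NULL, basin_holo = NULL,
                   weight_a = 0.5, noise_scale = 0.3, plddt_sigma = 2.0,
                   exe = "colabfold_batch"),
    references = list(apo = NULL, holo = NULL, chain = NULL, ligand = NULL,
                      offset = 0L, min_matched = 30L),
    analysis = list(atom_set = "backbone", plddt_threshold = 85,
                    min_fraction = 0.70, k_min = 2L, k_max = 10L,
                    margin = 0.5),
    out_dir = "rass_run"
  )
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  out <- merge_lists(merge_lists(defaults, config), list(...))
  class(out) <- "rass_config"
  out
}

stage_need <- function(path, stage, producer) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' needs missing artifact '", path,
         "'; run the '", producer, "' stage first", call. = FALSE)
  }
  path
}

stage_done <- function(marker, force) {
  file.exists(marker) && !force
}

#' Run the ensemble-generation pipeline
#'
#' Orchestrates mask -> subsample -> predict -> analyze -> report over a
#' deterministic artifact directory:
#' \describe{
#'   \item{masked/}{replica FASTA plus JSON substitution records.}
#'   \item{subsampled/}{attention/extra partitions per replica (JSON).}
#'   \item{predictions/}{one PDB per conformer (pLDDT in the B-factor
#'     column) plus a provenance table.}
#'   \item{analysis/}{pair metrics, per-conformer report table, summary
#'     JSON.}
#'   \item{logs/}{the effective configuration and package version.}
#' }
#' A completed stage is skipped unless `force = TRUE`; a stage whose
#' inputs are missing raises an error naming the missing artifact.
#' Replica `r` derives its subsampling seed as `seed + r` and its
#' prediction seed as `seed + 65536 + r`, so stages are individually
#' reproducible.
#'
#' @param config a [rass_config()].
#' @param stages subset of `c("mask", "subsample", "predict", "analyze",
#'   "report")`, in pipeline order.
#' @param force re-run stages whose outputs already exist.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config,
                         stages = c("mask", "subsample", "predict",
                                    "analyze", "report"),
                         force = FALSE) {
  stopifnot(inherits(config, "rass_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  for (d in c("masked", "subsampled", "predictions", "analysis", "logs")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  cfg_echo <- config
  class(cfg_echo) <- NULL
  jsonlite::write_json(
    c(cfg_echo, list(package_version = as.character(
      utils::packageVersion("rassemble")))),
    file.path(out, "logs", "run_config.json"),
    auto_unbox = TRUE, digits = NA, null = "null")

  masked_fa <- file.path(out, "masked", "replicas.fasta")
  masked_json <- file.path(out, "masked", "replicas.json")
  parts_json <- file.path(out, "subsampled", "partitions.json")
  prov_tsv <- file.path(out, "predictions", "provenance.tsv")
  report_json <- file.path(out, "analysis", "report.json")

  if ("mask" %in% stages && !stage_done(masked_fa, force)) {
    if (is.null(config$query_fasta)) {
      stop("config$query_fasta is required for the mask stage",
           call. = FALSE)
    }
    query <- read_query_fasta(config$query_fasta, region = config$region)
    masked <- randomized_alanine_scan(query,
                                      n_replicas = config$n_replicas,
                                      p_low = config$p_low,
                                      p_high = config$p_high,
                                      seed = config$seed)
    write_masked_fasta(masked, masked_fa, masked_json)
  }

  if ("subsample" %in% stages && !stage_done(parts_json, force)) {
    stage_need(masked_fa, "subsample", "mask")
    msa <- if (!is.null(config$msa_path)) {
      read_alignment(config$msa_path, dialect = config$msa_dialect)
    } else {
      # query-only alignment: the mock backend needs no homologs
      q <- read_query_fasta(config$query_fasta, region = config$region)
      structure(list(ids = q$id, rows = q$residues, depth = 1L,
                     dialect = "a3m"), class = "alignment_stack")
    }
    reps <- Biostrings::readBStringSet(masked_fa)
    parts <- lapply(seq_along(reps), function(r) {
      p <- subsample(msa, max_seqs = config$max_seqs,
                     extra_seqs = config$extra_seqs,
                     seed = config$seed + r)
      list(replica = r, attention = p$attention, extra = p$extra,
           seed = p$seed, depth = p$depth)
    })
    jsonlite::write_json(
      list(max_seqs = config$max_seqs, extra_seqs = config$extra_seqs,
           partitions = parts),
      parts_json, auto_unbox = TRUE, digits = NA)
  }

  if ("predict" %in% stages && !stage_done(prov_tsv, force)) {
    stage_need(masked_fa, "predict", "mask")
    backend <- build_backend(config)
    reps <- Biostrings::readBStringSet(masked_fa)
    msa <- if (!is.null(config$msa_path)) {
      read_alignment(config$msa_path, dialect = config$msa_dialect)
    } else NULL
    prov_all <- list()
    for (r in seq_along(reps)) {
      # the masked replica becomes the alignment's query row
      msa_r <- if (!is.null(msa)) {
        set_query_row(msa, as.character(reps[[r]]), id = names(reps)[r])
      } else NULL
      part <- if (!is.null(msa_r)) {
        subsample(msa_r, config$max_seqs, config$extra_seqs,
                  seed = config$seed + r)
      } else NULL
      req <- prediction_request(
        sequence = as.character(reps[[r]]), msa = msa_r, partition = part,
        num_models = config$num_models, num_recycles = config$num_recycles,
        num_seeds = config$num_seeds, use_dropout = config$use_dropout,
        replica_id = r, seed = config$seed + 65536L + r)
      ens <- run_backend(req, backend)
      rep_dir <- file.path(out, "predictions", sprintf("replica_%03d", r))
      dir.create(rep_dir, showWarnings = FALSE)
      for (i in seq_len(ensemble_size(ens))) {
        write_structure(ens$conformers[[i]],
                        file.path(rep_dir, sprintf("conf_%03d.pdb", i)))
      }
      pr <- ens$provenance
      pr$file <- file.path(sprintf("replica_%03d", r),
                           sprintf("conf_%03d.pdb",
                                   seq_len(ensemble_size(ens))))
      prov_all[[r]] <- pr
    }
    prov <- do.call(rbind, prov_all)
    prov$conformer <- seq_len(nrow(prov))
    utils::write.table(prov, prov_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("analyze" %in% stages && !stage_done(report_json, force)) {
    stage_need(prov_tsv, "analyze", "predict")
    refs <- config$references
    if (is.null(refs$apo) || is.null(refs$holo)) {
      stop("config$references$apo and $holo are required for the analyze ",
           "stage", call. = FALSE)
    }
    prov <- utils::read.table(prov_tsv, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    models <- lapply(file.path(out, "predictions", prov$file),
                     read_structure, source = "predicted")
    ens <- conformer_ensemble(models, provenance = prov)
    apo <- read_structure(refs$apo, chain = refs$chain)
    holo <- read_structure(refs$holo, chain = refs$chain)
    pair <- characterize_pair(reference_pair(
      apo, holo, ligand = refs$ligand, offset = refs$offset,
      min_matched = refs$min_matched))

    ana <- config$analysis
    prof <- rmsd_profile(ens, pair, atom_set = ana$atom_set,
                         min_matched = refs$min_matched)
    states <- classify_states(prof, margin = ana$margin)
    k_max <- min(ana$k_max, ensemble_size(ens) - 1L)
    clus <- cluster_ensemble(ens, atom_set = "ca",
                             k_range = ana$k_min:k_max)
    rer <- rerank_by_confidence(ens, plddt_threshold = ana$plddt_threshold,
                                min_fraction = ana$min_fraction)
    scat <- plddt_rmsd_scatter(ens, prof)

    # per-conformer report: every row traces back to a provenance tuple
    report <- data.frame(
      prov[, c("conformer", "model", "seed_index", "recycle", "final",
               "replica", "seed")],
      rmsd_to_apo = prof$table$rmsd_to_apo,
      rmsd_to_holo = prof$table$rmsd_to_holo,
      mean_plddt = scat$table$mean_plddt,
      confident_fraction = rer$table$confident_fraction,
      cluster = clus$labels,
      state = as.character(states))
    utils::write.table(
      report, file.path(out, "analysis", "ensemble_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      pair$metrics, file.path(out, "analysis", "pair_metrics.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

    jsonlite::write_json(list(
      units = list(rmsd = "Angstrom", plddt = "0-100",
                   conformer_index = "1-based"),
      pair_metrics = as.list(pair$metrics),
      pocket_cutoff = if (!is.null(pair$pocket)) 4.5 else NULL,
      ensemble_size = ensemble_size(ens),
      rmsd_summary = list(apo = as.list(prof$summary["apo", ]),
                          holo = as.list(prof$summary["holo", ])),
      state_counts = as.list(table(states)),
      cluster_k = clus$k,
      silhouette = as.list(clus$silhouette),
      cluster_state_table = as.data.frame(cluster_state_table(clus, states)),
      n_confident = sum(rer$table$kept),
      plddt_threshold = ana$plddt_threshold,
      min_fraction = ana$min_fraction,
      spearman = as.list(scat$spearman)
    ), report_json, auto_unbox = TRUE, digits = NA, null = "null")
  }

  if ("report" %in% stages) {
    stage_need(report_json, "report", "analyze")
    file.copy(report_json, file.path(out, "report.json"), overwrite = TRUE)
  }

  invisible(out)
}

# backend object from a config
build_backend <- function(config) {
  be <- config$backend
  if (identical(be$type, "mock")) {
    if (is.null(be$basin_apo) || is.null(be$basin_holo)) {
      stop("mock backend requires backend$basin_apo and $basin_holo ",
           "structure paths", call. = FALSE)
    }
    mock_backend(read_structure(be$basin_apo),
                 read_structure(be$basin_holo),
                 weight_a = be$weight_a, noise_scale = be$noise_scale,
                 plddt_sigma = be$plddt_sigma)
  } else if (identical(be$type, "colabfold")) {
    colabfold_backend(exe = be$exe)
  } else {
    stop("unknown backend type '", be$type, "'", call. = FALSE)
  }
}
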