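#' Query sequence for alanine scanning
#'
#' Light container for a single-chain amino-acid query. Residues are the
#' 20 canonical one-letter codes plus `X` for unknown identity. An optional
#' region restricts which positions are eligible for alanine substitution
#' (1-based, e.g. a functional region under study); by default every
#' position is eligible.
#'
#' @param id record identifier.
#' @param residues one-letter amino-acid string, length >= 1.
#' @param region optional integer vector of 1-based positions eligible for
#'   substitution. Defaults to all positions.
#' @return An object of class `query_sequence` with fields `id`, `residues`
#'   (character scalar), `length`, and `region`.
#' @export
query_sequence <- function(id, residues, region = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  residues <- toupper(as.character(residues)[1L])
  if (is.na(residues) || !nzchar(residues)) {
    stop("query sequence is empty", call. = FALSE)
  }
  letters <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(letters), c(AA_CANONICAL, "X"))
  if (length(bad) > 0L) {
    stop("non amino-acid letters in query: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  L <- length(letters)
  if (is.null(region)) {
    region <- seq_len(L)
  } else {
    region <- sort(unique(as.integer(region)))
    if (any(region < 1L) || any(region > L)) {
      stop("region positions must lie in [1, ", L, "]", call. = FALSE)
    }
  }
  structure(
    list(id = id, residues = residues, length = L, region = region),
    class = "query_sequence"
  )
}

#' The twenty canonical amino-acid one-letter codes
#' @keywords internal
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a single-record FASTA file as a query sequence
#'
#' @param path path to a FASTA file containing exactly one record.
#' @param region optional eligible-position vector, see [query_sequence()].
#' @return a `query_sequence`.
#' @export
read_query_fasta <- function(path, region = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L) {
    stop("expected exactly one FASTA record, found ", length(set),
         call. = FALSE)
  }
  query_sequence(id = names(set)[1L],
                 residues = as.character(set[[1L]]),
                 region = region)
}

#' Randomized alanine sequence scanning (RASS)
#'
#' Produces `n_replicas` perturbed copies of the query in which residues are
#' stochastically replaced by alanine. For every replica and every eligible
#' position `i` an independent substitution probability
#' `p_i ~ Uniform(p_low, p_high)` is drawn, and the residue is then replaced
#' by `A` with probability `p_i`. The marginal substitution probability per
#' eligible position is therefore `(p_low + p_high) / 2` (0.10 at the
#' defaults). Replica `r` uses the derived seed `seed + r - 1` on R's
#' Mersenne-Twister stream, so runs and partial re-runs are reproducible.
#'
#' Positions outside the eligible region and positions holding `X` are never
#' altered. Alanine positions in the source remain eligible: an A->A
#' substitution is recorded in the substitution set but leaves the string
#' unchanged, keeping the perturbation process uniform across positions.
#'
#' @param query a [query_sequence()].
#' @param n_replicas number of scan replicas (default 45; the protocol is
#'   typically run ~40-50 times).
#' @param p_low,p_high bounds of the per-position substitution probability
#'   (defaults 0.05 and 0.15).
#' @param seed integer base seed.
#' @return An object of class `masked_sequence_set`: list with `source`,
#'   `p_low`, `p_high`, `base_seed`, and `replicas`, a list whose elements
#'   carry `sequence`, `substituted` (1-based positions replaced, possibly
#'   including silent A->A events), `p_draws` (the per-position probability
#'   draws over eligible positions), and `seed`.
#' @examples
#' q <- query_sequence("demo", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
#' ms <- randomized_alanine_scan(q, n_replicas = 5, seed = 7)
#' vapply(ms$replicas, function(r) length(r$substituted), integer(1))
#' @export
randomized_alanine_scan <- function(query, n_replicas = 45L,
                                    p_low = 0.05, p_high = 0.15,
                                    seed = 1L) {
  if (!inherits(query, "query_sequence")) {
    stop("query must be a query_sequence", call. = FALSE)
  }
  n_replicas <- as.integer(n_replicas)
  stopifnot(n_replicas >= 1L)
  if (!(p_low >= 0 && p_high <= 1)) {
    stop("substitution probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_low > p_high) {
    stop("p_low must not exceed p_high", call. = FALSE)
  }
  letters <- strsplit(query$residues, "", fixed = TRUE)[[1L]]
  eligible <- setdiff(query$region, which(letters == "X"))

  replicas <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    rseed <- as.integer(seed) + r - 1L
    set.seed(rseed)
    p <- stats::runif(length(eligible), min = p_low, max = p_high)
    hit <- stats::runif(length(eligible)) < p
    sub_pos <- eligible[hit]
    out <- letters
    out[sub_pos] <- "A"
    replicas[[r]] <- list(
      sequence = paste(out, collapse = ""),
      substituted = sub_pos,
      p_draws = stats::setNames(p, eligible),
      seed = rseed
    )
  }
  structure(
    list(source = query, replicas = replicas,
         p_low = p_low, p_high = p_high, base_seed = as.integer(seed)),
    class = "masked_sequence_set"
  )
}

#' @export
print.masked_sequence_set <- function(x, ...) {
  fr <- substitution_fractions(x)
  cat(sprintf(
    "masked_sequence_set: %d replicas of '%s' (L = %d)\n", length(x$replicas),
    x$source$id, x$source$length))
  cat(sprintf("  p ~ U(%.3g, %.3g); substitution fraction %.3f (mean), range [%.3f, %.3f]\n",
              x$p_low, x$p_high, mean(fr), min(fr), max(fr)))
  invisible(x)
}

#' Per-replica substitution fractions
#'
#' Fraction of eligible positions substituted in each replica (silent A->A
#' events count as substitutions, matching the perturbation model).
#'
#' @param masked a `masked_sequence_set`.
#' @return numeric vector, one fraction per replica.
#' @export
substitution_fractions <- function(masked) {
  stopifnot(inherits(masked, "masked_sequence_set"))
  n_elig <- length(masked$replicas[[1L]]$p_draws)
  vapply(masked$replicas,
         function(r) length(r$substituted) / n_elig, numeric(1))
}

#' Write a masked-sequence set to FASTA with a JSON sidecar
#'
#' Writes one FASTA record per replica, with ids
#' `"{query_id}|rass_{replica:03d}"`, and a JSON sidecar recording the
#' per-replica seeds and substituted positions (1-based) so any replica can
#' be regenerated.
#'
#' @param masked a `masked_sequence_set`.
#' @param fasta_path output FASTA path.
#' @param json_path output JSON path; default replaces the FASTA extension
#'   with `.json`.
#' @return invisibly, the two paths written.
#' @export
write_masked_fasta <- function(masked, fasta_path,
                               json_path = paste0(
                                 tools::file_path_sans_ext(fasta_path),
                                 ".json")) {
  stopifnot(inherits(masked, "masked_sequence_set"))
  ids <- sprintf("%s|rass_%03d", masked$source$id,
                 seq_along(masked$replicas))
  seqs <- Biostrings::BStringSet(
    vapply(masked$replicas, `[[`, character(1), "sequence"))
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, fasta_path)
  side <- list(
    query_id = masked$source$id,
    length = masked$source$length,
    p_low = masked$p_low, p_high = masked$p_high,
    base_seed = masked$base_seed,
    region = masked$source$region,
    replicas = lapply(seq_along(masked$replicas), function(r) {
      rep <- masked$replicas[[r]]
      list(id = ids[r], seed = rep$seed,
           substituted = as.integer(rep$substituted))
    })
  )
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta_path, json = json_path))
}
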