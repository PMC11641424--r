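#' Read a multiple sequence alignment (A3M or aligned FASTA)
#'
#' In the A3M dialect, lowercase letters are insertions relative to the
#' query and `-` is a deletion; rows have equal length only after removing
#' lowercase states. Aligned FASTA requires equal-length uppercase rows.
#' Row 1 is taken to be the query.
#'
#' @param path alignment file.
#' @param dialect `"a3m"` (default) or `"aligned-fasta"`.
#' @return An `alignment_stack`: list with `ids`, `rows` (character vector,
#'   case preserved), `depth`, and `dialect`.
#' @export
read_alignment <- function(path, dialect = c("a3m", "aligned-fasta")) {
  dialect <- match.arg(dialect)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("alignment file contains no sequences: ", path, call. = FALSE)
  }
  rows <- unname(as.character(set))
  ids <- names(set)
  # A3M rows must agree in length once insertion (lowercase) states are removed
  ulen <- vapply(rows, function(s) nchar(gsub("[a-z]", "", s)), integer(1),
                 USE.NAMES = FALSE)
  if (length(unique(ulen)) != 1L) {
    stop("ragged alignment: rows differ in match-state length (",
         paste(range(ulen), collapse = "-"), ")", call. = FALSE)
  }
  if (dialect == "aligned-fasta" && any(grepl("[a-z]", rows))) {
    stop("aligned-fasta dialect does not allow lowercase insertion states",
         call. = FALSE)
  }
  structure(list(ids = ids, rows = rows, depth = length(rows),
                 dialect = dialect),
            class = "alignment_stack")
}

#' Write an alignment stack back to disk
#'
#' Round-trips exactly: case, gaps and record order are preserved.
#'
#' @param msa an `alignment_stack`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "alignment_stack"))
  set <- Biostrings::BStringSet(msa$rows)
  names(set) <- msa$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.alignment_stack <- function(x, ...) {
  cat(sprintf("alignment_stack: depth %d (%s), query '%s'\n",
              x$depth, x$dialect, x$ids[1L]))
  invisible(x)
}

#' Replace the query row of an alignment
#'
#' Substitutes a perturbed (e.g. alanine-masked) sequence as row 1 of an
#' existing alignment, mapping the replacement onto the query's match
#' states. The replacement must have the same number of residues as the
#' original query has non-gap match states.
#'
#' @param msa an `alignment_stack`.
#' @param sequence replacement residue string (ungapped).
#' @param id id for the new query row; defaults to the old id.
#' @return a new `alignment_stack`.
#' @export
set_query_row <- function(msa, sequence, id = msa$ids[1L]) {
  stopifnot(inherits(msa, "alignment_stack"))
  q <- strsplit(msa$rows[1L], "", fixed = TRUE)[[1L]]
  res_idx <- which(!(q %in% c("-", ".")) & q == toupper(q))
  repl <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (length(repl) != length(res_idx)) {
    stop("replacement query has ", length(repl), " residues; alignment query has ",
         length(res_idx), " match states", call. = FALSE)
  }
  q[res_idx] <- repl
  msa$rows[1L] <- paste(q, collapse = "")
  msa$ids[1L] <- id
  msa
}

#' Shallow MSA subsampling into an attention / extra partition
#'
#' Randomly partitions alignment rows into the set passed to the predictor's
#' row/column attention track (at most `max_seqs` rows, always containing
#' the query) and the extra set processed by the main stack (at most
#' `extra_seqs` further rows). Sampling is uniform without replacement over
#' the non-query rows; when the alignment has no more than `max_seqs` rows
#' the attention set is the whole alignment and the extra set is empty.
#' Shallow presets such as 16:32 maximize conformational diversity in the
#' downstream predictions.
#'
#' @param msa an `alignment_stack`.
#' @param max_seqs attention-track capacity (default 16).
#' @param extra_seqs extra-stack capacity (default 32).
#' @param seed integer seed; the partition is reproducible from it.
#' @return A `subsample_partition`: list with integer row indices
#'   `attention` and `extra` (1-based into `msa$rows`, disjoint; the query
#'   index 1 is always in `attention`), plus the bounds and seed.
#' @export
subsample <- function(msa, max_seqs = 16L, extra_seqs = 32L, seed = 1L) {
  stopifnot(inherits(msa, "alignment_stack"))
  max_seqs <- as.integer(max_seqs)
  extra_seqs <- as.integer(extra_seqs)
  if (max_seqs < 1L) stop("max_seqs must be >= 1", call. = FALSE)
  if (extra_seqs < 0L) stop("extra_seqs must be >= 0", call. = FALSE)

  n <- msa$depth
  others <- setdiff(seq_len(n), 1L)
  if (n <= max_seqs) {
    attention <- seq_len(n)
    extra <- integer(0)
  } else {
    set.seed(as.integer(seed))
    perm <- sample(others, length(others), replace = FALSE)
    attention <- sort(c(1L, perm[seq_len(max_seqs - 1L)]))
    pool <- perm[-seq_len(max_seqs - 1L)]
    extra <- sort(pool[seq_len(min(extra_seqs, length(pool)))])
  }
  structure(list(attention = attention, extra = extra,
                 max_seqs = max_seqs, extra_seqs = extra_seqs,
                 seed = as.integer(seed), depth = n),
            class = "subsample_partition")
}

#' @export
print.subsample_partition <- function(x, ...) {
  cat(sprintf("subsample_partition: %d:%d over depth %d -> |attention| = %d, |extra| = %d\n",
              x$max_seqs, x$extra_seqs, x$depth,
              length(x$attention), length(x$extra)))
  invisible(x)
}

#' Materialize a partition as two alignment stacks
#'
#' @param msa an `alignment_stack`.
#' @param partition a `subsample_partition` of `msa`.
#' @return list of `alignment_stack`s `attention` and `extra` (the latter
#'   `NULL` when empty).
#' @export
apply_partition <- function(msa, partition) {
  stopifnot(inherits(msa, "alignment_stack"),
            inherits(partition, "subsample_partition"))
  pick <- function(idx) {
    if (length(idx) == 0L) return(NULL)
    structure(list(ids = msa$ids[idx], rows = msa$rows[idx],
                   depth = length(idx), dialect = msa$dialect),
              class = "alignment_stack")
  }
  list(attention = pick(partition$attention), extra = pick(partition$extra))
}
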