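#' Labeled protein sequence sets
#'
#' A \code{sequence_set} is a named character vector of ungapped protein
#' sequences over the 20-letter alphabet: one simulation replicate's leaves,
#' or an observed domain collection. Labels must be unique and non-empty and
#' sequences non-empty; within one simulation replicate all sequences have
#' equal length (the model has no indels).
#'
#' @param x Named character vector of sequences.
#' @param equal_length Require all sequences to have the same length.
#' @return \code{x} with class \code{sequence_set}.
#' @export
#' @examples
#' sequence_set(c(human = "RHDSGY", fly = "AHDSEF"))
sequence_set <- function(x, equal_length = FALSE) {
  stopifnot(is.character(x), length(x) >= 1L)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("every sequence needs a non-empty label", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicate sequence label: ", names(x)[anyDuplicated(names(x))], call. = FALSE)
  if (any(!nzchar(x))) stop("empty sequence", call. = FALSE)
  if (equal_length && length(unique(nchar(x))) != 1L)
    stop("sequences in a simulation replicate must have equal length", call. = FALSE)
  structure(x, class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d sequences, lengths %s\n", length(x),
              paste(range(nchar(x)), collapse = "-")))
  show <- utils::head(unclass(x), 3)
  for (i in seq_along(show))
    cat(sprintf("  %s  %s%s\n", names(show)[i], substr(show[i], 1, 50),
                if (nchar(show[i]) > 50) "..." else ""))
  if (length(x) > 3) cat(sprintf("  ... and %d more\n", length(x) - 3))
  invisible(x)
}

# Transition-matrix cache: one row-cumulative P per distinct branch length,
# since thousands of replicates reuse the same tree. Rows are cumulative so
# a uniform draw can be inverted directly.
.p_cache <- function(model) {
  cache <- new.env(parent = emptyenv())
  function(t) {
    key <- sprintf("%.15g", t)
    cp <- cache[[key]]
    if (is.null(cp)) {
      p <- transition_matrix(model, t)$p
      cp <- t(apply(p, 1, cumsum))
      cache[[key]] <- cp
    }
    cp
  }
}

# Draw descendant residues for one edge: `parent` is an integer-coded
# sequence, `cum_p` the row-wise cumulative transition matrix.
.evolve_edge <- function(parent, cum_p) {
  r <- stats::runif(length(parent))
  1L + rowSums(cum_p[parent, , drop = FALSE] < r)
}

#' Simulate neutral evolution of a root sequence down a tree
#'
#' Evolves \code{root_seq} from the root towards the leaves under the
#' continuous-time Markov substitution model \code{model}. Each site evolves
#' independently of every other site, and each branch independently of every
#' other branch: for an edge of length \code{t}, the residue at the child
#' node is drawn, site by site, from the row of \code{P(t) = exp(Q t)}
#' selected by the parent's residue at that site. Only the leaf sequences
#' are returned.
#'
#' @param tree A validated \code{phylo} tree (see \code{\link{parse_newick}}).
#' @param root_seq Ungapped protein sequence labeling the root. Gap or
#'   nonstandard characters are an error, not silently stripped; degap
#'   alignment columns explicitly beforehand.
#' @param model A \code{rate_matrix}.
#' @param p_for Optional transition-matrix cache (internal reuse across
#'   replicates); built fresh when NULL.
#' @return A \code{sequence_set} of leaf sequences in \code{tree$tip.label}
#'   order, each the length of \code{root_seq}.
#' @export
#' @examples
#' m <- blosum62_rate_matrix()
#' tr <- parse_newick("(A:0.1,(B:0.2,C:0.3):0.05);")
#' set.seed(1)
#' evolve_once(tr, "MHDSGYEVHHQKLVFFAEDV", m)
evolve_once <- function(tree, root_seq, model, p_for = NULL) {
  tree <- validate_phylo(tree)
  stopifnot(inherits(model, "rate_matrix"))
  root <- .aa_encode(root_seq, what = "root sequence")
  if (length(root) == 0L) stop("root sequence is empty", call. = FALSE)
  if (is.null(p_for)) p_for <- .p_cache(model)

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root_node <- setdiff(seq_len(nnode), tree$edge[, 2])
  seqs <- vector("list", nnode)
  seqs[[root_node]] <- root

  ord <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  lens <- ord$edge.length
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1]; child <- ord$edge[i, 2]
    seqs[[child]] <- .evolve_edge(seqs[[par]], p_for(lens[i]))
  }

  out <- vapply(seq_len(ntip), function(i) .aa_decode(seqs[[i]]), character(1))
  names(out) <- tree$tip.label
  sequence_set(out, equal_length = TRUE)
}

# L'Ecuyer-CMRG substream seeds: one master seed, one independent stream per
# replicate, so replicate i is reproducible from (seed, i) alone and streams
# do not overlap.
.rng_substreams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

# Run `fun()` with the RNG positioned at `stream`, restoring state after.
.with_stream <- function(stream, fun) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  assign(".Random.seed", stream, envir = globalenv())
  fun()
}

#' Monte-Carlo replicates of neutral evolution
#'
#' Runs \code{\link{evolve_once}} \code{n_reps} times under independent,
#' individually reproducible random substreams derived from one master seed
#' (L'Ecuyer-CMRG; replicate \code{i} always sees stream \code{i} regardless
#' of how many replicates are requested). When \code{FUN} is supplied each
#' replicate is reduced immediately and only the reduced values are kept, so
#' memory does not grow with the number of replicates; this is how the null
#' distributions over 10 000 replicates are accumulated.
#'
#' @inheritParams evolve_once
#' @param n_reps Number of replicates, at least 1.
#' @param seed Master seed (integer).
#' @param FUN Optional function applied to each replicate's
#'   \code{sequence_set}; its results are returned instead of the sequences.
#' @return A list of \code{n_reps} \code{sequence_set}s, or of \code{FUN}
#'   values when \code{FUN} is given.
#' @export
#' @examples
#' m <- blosum62_rate_matrix()
#' tr <- parse_newick("(A:0.1,(B:0.2,C:0.3):0.05);")
#' reps <- simulate_replicates(tr, "MHDSGYEVHHQKLVFFAEDV", m, n_reps = 5, seed = 42)
#' length(reps)
simulate_replicates <- function(tree, root_seq, model, n_reps, seed, FUN = NULL) {
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1 || n_reps != round(n_reps))
    stop("'n_reps' must be a positive integer", call. = FALSE)
  tree <- validate_phylo(tree)
  p_for <- .p_cache(model)
  streams <- .rng_substreams(seed, n_reps)
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    s <- .with_stream(streams[[i]], function() evolve_once(tree, root_seq, model, p_for = p_for))
    out[[i]] <- if (is.null(FUN)) s else FUN(s)
  }
  out
}

#' Write a sequence set as FASTA
#'
#' @param s A \code{sequence_set} (or named character vector).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(s, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(unclass(s)), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Reads a (plain or gzipped) protein FASTA file into a named character
#' vector. Record descriptions are kept as names; with \code{id_only} the
#' name is truncated at the first whitespace.
#'
#' @param path FASTA file path.
#' @param id_only Keep only the first whitespace-delimited token of each
#'   header.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, id_only = FALSE) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  if (id_only) names(out) <- sub("\\s.*$", "", names(out))
  out
}
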