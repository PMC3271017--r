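#' Specification for synthetic benchmark data
#'
#' Bundles the knobs of the synthetic-data generator. The defaults emulate
#' the scale of a domain-family analysis: a 41-leaf rooted tree over
#' 70-residue domain sequences, exponentially distributed branch lengths
#' with mean 0.2 expected substitutions per site, and a root drawn from the
#' substitution model's stationary distribution.
#'
#' @param n_leaves Number of leaves (at least 2).
#' @param seq_length Root/domain length in residues (at least 2).
#' @param branch_mean Mean branch length, expected substitutions per site.
#' @param branch_law \code{"exponential"} (default) or \code{"fixed"} (all
#'   branches equal to \code{branch_mean}).
#' @param root_mode \code{"stationary"} (i.i.d. draws from the stationary
#'   distribution), \code{"dyad_seeded"} (stationary with exactly one copy
#'   of \code{dyad} planted at a random position), or \code{"fixed"} (use
#'   \code{root_seq}).
#' @param root_seq Root sequence for \code{root_mode = "fixed"}.
#' @param dyad Target motif for seeding and/or selection.
#' @param selection \code{"none"} or \code{"keep_dyad"}: maintain at least
#'   one copy of \code{dyad} at every node of the tree.
#' @param seed Master seed.
#' @return An object of class \code{synth_spec}.
#' @export
#' @examples
#' synth_spec(n_leaves = 8, seq_length = 30, seed = 7)
synth_spec <- function(n_leaves = 41, seq_length = 70, branch_mean = 0.2,
                       branch_law = c("exponential", "fixed"),
                       root_mode = c("stationary", "dyad_seeded", "fixed"),
                       root_seq = NULL, dyad = "HD",
                       selection = c("none", "keep_dyad"), seed = 1) {
  branch_law <- match.arg(branch_law)
  root_mode <- match.arg(root_mode)
  selection <- match.arg(selection)
  stopifnot(n_leaves >= 2, seq_length >= 2, branch_mean > 0)
  if (root_mode == "fixed" && is.null(root_seq))
    stop("'root_seq' is required when root_mode = \"fixed\"", call. = FALSE)
  dyad <- .check_dyad(dyad)
  structure(list(n_leaves = as.integer(n_leaves),
                 seq_length = as.integer(seq_length),
                 branch_mean = branch_mean, branch_law = branch_law,
                 root_mode = root_mode, root_seq = root_seq, dyad = dyad,
                 selection = selection, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Sample a random rooted tree
#'
#' Draws a rooted bifurcating topology by sequential random joins (pick two
#' available subtrees uniformly at random, join them under a new parent,
#' repeat) and assigns every edge an independent branch length from the
#' configured branch law. Deterministic under the spec's seed.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @return A validated \code{phylo} tree with \code{spec$n_leaves} leaves
#'   labeled \code{t1..tn}.
#' @export
#' @examples
#' tr <- sample_tree(synth_spec(n_leaves = 5, seed = 3))
#' ape::Ntip(tr)
sample_tree <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  bl <- function(n) switch(spec$branch_law,
                           exponential = stats::rexp(n, rate = 1 / spec$branch_mean),
                           fixed = rep(spec$branch_mean, n))
  sub <- paste0("t", seq_len(spec$n_leaves))
  while (length(sub) > 1L) {
    pick <- sample.int(length(sub), 2L)
    joined <- sprintf("(%s:%.10g,%s:%.10g)", sub[pick[1]], bl(1), sub[pick[2]], bl(1))
    sub <- c(sub[-pick], joined)
  }
  parse_newick(paste0(sub, ";"))
}

#' Sample a root sequence
#'
#' Stationary mode draws residues i.i.d. from the model's stationary
#' distribution; dyad-seeded mode additionally overwrites one random
#' position with the target dyad, guaranteeing at least one copy.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @param model A \code{rate_matrix}.
#' @return A protein sequence string of length \code{spec$seq_length}.
#' @export
sample_root <- function(spec, model) {
  stopifnot(inherits(spec, "synth_spec"), inherits(model, "rate_matrix"))
  if (spec$root_mode == "fixed") return(spec$root_seq)
  set.seed(spec$seed + 1L)
  code <- sample.int(20L, spec$seq_length, replace = TRUE, prob = model$pi)
  if (spec$root_mode == "dyad_seeded") {
    pos <- sample.int(spec$seq_length - 1L, 1L)
    code[pos:(pos + 1L)] <- .aa_encode(spec$dyad, what = "dyad")
  }
  .aa_decode(code)
}

#' Generate one synthetic dataset
#'
#' Draws (or accepts) a tree and root and evolves one replicate. With
#' \code{selection = "none"} this is plain neutral evolution; with
#' \code{selection = "keep_dyad"} it is the alternative-hypothesis
#' generator: every per-edge outcome that would leave a node with zero
#' copies of the target dyad is resampled (rejection sampling, capped), so
#' every internal node and every leaf carries at least one copy, while the
#' copy's position is free to migrate along the sequence — motif turnover:
#' a copy newly arisen by mutation can be the one retained while the
#' ancestral copy decays.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @param model A \code{rate_matrix}.
#' @param tree Optional tree (drawn from \code{spec} when NULL).
#' @param root_seq Optional root sequence (drawn from \code{spec} when
#'   NULL). Under selection the root must contain the dyad.
#' @param max_rejects Per-edge cap on rejection resampling; exceeding it
#'   signals a branch too long for the constraint.
#' @return A \code{sequence_set} of leaf sequences, with attributes
#'   \code{tree} and \code{root_seq}.
#' @export
#' @examples
#' m <- blosum62_rate_matrix()
#' spec <- synth_spec(n_leaves = 6, seq_length = 30,
#'                    root_mode = "dyad_seeded", selection = "keep_dyad", seed = 2)
#' leaves <- generate_selected_dataset(spec, m)
#' count_occurrences(unclass(leaves), "HD")  # all >= 1
generate_selected_dataset <- function(spec, model, tree = NULL, root_seq = NULL,
                                      max_rejects = 10000L) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(tree)) tree <- sample_tree(spec)
  tree <- validate_phylo(tree)
  if (is.null(root_seq)) root_seq <- sample_root(spec, model)
  constrained <- spec$selection == "keep_dyad"
  if (constrained && count_occurrences(root_seq, spec$dyad) < 1L)
    stop("selection requires the root to contain the target dyad; use root_mode = \"dyad_seeded\"",
         call. = FALSE)
  root <- .aa_encode(root_seq, what = "root sequence")
  d <- .aa_encode(spec$dyad, what = "dyad")
  has_dyad <- function(code) {
    n <- length(code)
    any(code[-n] == d[1L] & code[-1] == d[2L])
  }

  set.seed(spec$seed + 2L)
  p_for <- .p_cache(model)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root_node <- setdiff(seq_len(nnode), tree$edge[, 2])
  seqs <- vector("list", nnode)
  seqs[[root_node]] <- root
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    cp <- p_for(ord$edge.length[i])
    parent <- seqs[[ord$edge[i, 1]]]
    tries <- 0L
    repeat {
      child <- .evolve_edge(parent, cp)
      if (!constrained || has_dyad(child)) break
      tries <- tries + 1L
      if (tries >= max_rejects)
        stop(sprintf("rejection cap (%d) exceeded on an edge of length %.3g: branch too long to maintain the %s constraint",
                     max_rejects, ord$edge.length[i], spec$dyad), call. = FALSE)
    }
    seqs[[ord$edge[i, 2]]] <- child
  }
  out <- vapply(seq_len(ntip), function(i) .aa_decode(seqs[[i]]), character(1))
  names(out) <- tree$tip.label
  res <- sequence_set(out, equal_length = TRUE)
  attr(res, "tree") <- tree
  attr(res, "root_seq") <- root_seq
  res
}

#' Paths of the checked-in synthetic domain-scale fixture
#'
#' A 41-leaf tree with 70-residue root, generated by this package's own
#' generator (synthetic, not biological data) and checked in for fast
#' tests: \code{caed41_synthetic.nwk} and
#' \code{caed41_synthetic_root.fa}.
#'
#' @return Named character vector with elements \code{tree} and
#'   \code{root}.
#' @export
synthetic_caed_files <- function() {
  c(tree = system.file("extdata", "caed41_synthetic.nwk", package = "dyadsel", mustWork = TRUE),
    root = system.file("extdata", "caed41_synthetic_root.fa", package = "dyadsel", mustWork = TRUE))
}
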