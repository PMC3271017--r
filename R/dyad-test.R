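#' Empirical null distribution of dyad presence counts
#'
#' Builds, from neutral-evolution replicates, the empirical distribution of
#' "number of sequences in a replicate containing at least one copy of the
#' dyad". The histogram's support is \code{0..n_leaves}; because the leaf
#' sequences of one replicate share ancestry, the distribution is typically
#' multimodal, not binomial.
#'
#' @param reps List of \code{sequence_set}s, all with the same number of
#'   sequences (e.g. from \code{\link{simulate_replicates}}).
#' @param dyad Two-residue motif, e.g. \code{"HD"}.
#' @return An object of class \code{dyad_null}: list with \code{dyad},
#'   \code{histogram} (named integer vector over \code{0..n_leaves} summing
#'   to \code{n_reps}), \code{n_reps} and \code{n_leaves}.
#' @export
#' @examples
#' reps <- list(c(a = "HDA", b = "AHD"), c(a = "AAA", b = "HDA"))
#' build_null(reps, "HD")
build_null <- function(reps, dyad) {
  stopifnot(is.list(reps), length(reps) >= 1L)
  sizes <- lengths(reps)
  if (length(unique(sizes)) != 1L)
    stop("replicates have heterogeneous leaf counts: ", paste(unique(sizes), collapse = ", "),
         call. = FALSE)
  counts <- vapply(reps, n_sequences_containing, integer(1), dyad = dyad)
  .null_from_counts(counts, sizes[1L], dyad)
}

.null_from_counts <- function(counts, n_leaves, dyad) {
  dyad <- .check_dyad(dyad)
  h <- tabulate(counts + 1L, nbins = n_leaves + 1L)
  names(h) <- 0:n_leaves
  structure(list(dyad = dyad, histogram = h, n_reps = length(counts),
                 n_leaves = n_leaves),
            class = "dyad_null")
}

#' @export
print.dyad_null <- function(x, ...) {
  cat(sprintf("Empirical null for dyad %s: %d replicates, %d leaves\n",
              x$dyad, x$n_reps, x$n_leaves))
  nz <- x$histogram[x$histogram > 0]
  cat("  presence-count frequencies (%):\n")
  print(round(100 * nz / x$n_reps, 2))
  invisible(x)
}

#' Empirical p-value of an observed dyad presence count
#'
#' The p-value is the probability, under the neutral null, of a presence
#' count at least as high as the observed one: the fraction of replicates
#' whose simulated count reaches \code{observed}. When no replicate reaches
#' it, the p-value is reported as the upper bound \code{1/n_reps} with
#' \code{upper_bound = TRUE} (printed as \code{p < 1/n_reps}), never as 0.
#'
#' @param null A \code{dyad_null}.
#' @param observed Observed number of sequences containing the dyad, in
#'   \code{0..n_leaves}.
#' @return An object of class \code{dyad_test}: list with \code{dyad},
#'   \code{observed}, \code{exceedances}, \code{n_reps}, \code{p_value} and
#'   \code{upper_bound}.
#' @export
#' @examples
#' null <- build_null(list(c(a = "HDA", b = "AHD"), c(a = "AAA", b = "HDA")), "HD")
#' empirical_pvalue(null, 2)
empirical_pvalue <- function(null, observed) {
  stopifnot(inherits(null, "dyad_null"))
  if (!is.numeric(observed) || length(observed) != 1L || observed != round(observed) ||
      observed < 0 || observed > null$n_leaves)
    stop(sprintf("'observed' must be an integer in 0..%d (the leaf count)", null$n_leaves),
         call. = FALSE)
  exc <- sum(null$histogram[(observed + 1L):(null$n_leaves + 1L)])
  structure(list(dyad = null$dyad, observed = as.integer(observed),
                 exceedances = as.integer(exc), n_reps = null$n_reps,
                 p_value = if (exc > 0) exc / null$n_reps else 1 / null$n_reps,
                 upper_bound = exc == 0L),
            class = "dyad_test")
}

#' @export
print.dyad_test <- function(x, ...) {
  cat(sprintf("Dyad presence test: %s, observed in %d sequences\n", x$dyad, x$observed))
  cat(sprintf("  %d of %d neutral replicates reached the observed count\n",
              x$exceedances, x$n_reps))
  cat(sprintf("  p %s %.4g\n", if (x$upper_bound) "<" else "=", x$p_value))
  invisible(x)
}

#' Cross-validation scan over all 400 ordered dyads
#'
#' Applies the presence-count test to every ordered amino-acid pair in a
#' single pass over the replicates, accumulating all 400 null histograms
#' simultaneously. Raw p-values are reported with no multiple-testing
#' correction: the scan's purpose is to compare the number of dyads flagged
#' at level \code{alpha} with the \code{400 * alpha} expected by chance
#' (about 4 at the 1\% level), which calibrates the test itself.
#'
#' @param reps List of \code{sequence_set}s (neutral replicates).
#' @param observed A \code{sequence_set} of observed sequences with the same
#'   number of records as each replicate.
#' @param alpha Flagging level for the \code{flagged} column.
#' @return A data frame with one row per dyad: \code{dyad}, \code{observed},
#'   \code{exceedances}, \code{n_reps}, \code{p_value}, \code{upper_bound},
#'   \code{flagged}; attribute \code{expected_flagged = 400 * alpha}.
#' @export
scan_all_dyads <- function(reps, observed, alpha = 0.01) {
  stopifnot(is.list(reps), length(reps) >= 1L)
  sizes <- lengths(reps)
  if (length(unique(sizes)) != 1L)
    stop("replicates have heterogeneous leaf counts", call. = FALSE)
  n_leaves <- sizes[1L]
  if (length(observed) != n_leaves)
    stop(sprintf("observed set has %d sequences but replicates have %d",
                 length(observed), n_leaves), call. = FALSE)
  hist <- matrix(0L, nrow = 400L, ncol = n_leaves + 1L)
  for (s in reps) {
    cnt <- .dyad_presence_counts(s)
    idx <- cbind(seq_len(400L), cnt + 1L)
    hist[idx] <- hist[idx] + 1L
  }
  .scan_from_hist(hist, length(reps), n_leaves,
                  .dyad_presence_counts(observed), alpha)
}

.scan_from_hist <- function(hist, n_reps, n_leaves, obs_counts, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("'alpha' must be a probability", call. = FALSE)
  rev_cum <- t(apply(hist, 1, function(h) rev(cumsum(rev(h)))))
  exc <- rev_cum[cbind(seq_len(400L), obs_counts + 1L)]
  p <- ifelse(exc > 0, exc / n_reps, 1 / n_reps)
  out <- data.frame(dyad = .all_dyads(), observed = obs_counts,
                    exceedances = as.integer(exc), n_reps = n_reps,
                    p_value = p, upper_bound = exc == 0L,
                    flagged = p <= alpha & alpha > 0,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "expected_flagged") <- 400 * alpha
  out
}

#' Fraction of replicates with a multi-copy sequence
#'
#' The fraction of replicates containing at least one sequence with two or
#' more copies of the dyad. Under neutral evolution on a domain-scale tree
#' this fraction is substantial, which is what makes motif turnover (an old
#' copy lost, a new copy retained elsewhere) a plausible route to
#' position-independent conservation.
#'
#' @inheritParams build_null
#' @return A number in \code{[0, 1]}.
#' @export
multi_copy_fraction <- function(reps, dyad) {
  stopifnot(is.list(reps), length(reps) >= 1L)
  mean(vapply(reps, function(s) any(count_occurrences(unclass(s), dyad) >= 2L), logical(1)))
}

#' Mean presence count across replicates
#'
#' Arithmetic mean over replicates of the number of sequences containing the
#' dyad; used to contrast simulations rooted at motif-bearing versus
#' motif-free ancestral sequences.
#'
#' @inheritParams build_null
#' @return A number in \code{[0, n_leaves]}.
#' @export
mean_containing_count <- function(reps, dyad) {
  stopifnot(is.list(reps), length(reps) >= 1L)
  mean(vapply(reps, n_sequences_containing, integer(1), dyad = dyad))
}

#' One-pass simulation variants
#'
#' \code{simulate_null} and \code{simulate_scan} run the neutral simulation
#' and reduce each replicate as it is produced, so 10 000 replicates never
#' sit in memory together.
#'
#' @inheritParams simulate_replicates
#' @param dyad Two-residue motif.
#' @return \code{simulate_null}: a \code{dyad_null}. \code{simulate_scan}:
#'   the \code{\link{scan_all_dyads}} data frame.
#' @export
simulate_null <- function(tree, root_seq, model, dyad, n_reps, seed) {
  dyad <- .check_dyad(dyad)
  tree <- validate_phylo(tree)
  counts <- unlist(simulate_replicates(tree, root_seq, model, n_reps, seed,
                                       FUN = function(s) n_sequences_containing(s, dyad)))
  .null_from_counts(counts, length(tree$tip.label), dyad)
}

#' @rdname simulate_null
#' @param observed A \code{sequence_set} with as many records as the tree
#'   has leaves.
#' @param alpha Flagging level.
#' @export
simulate_scan <- function(tree, root_seq, model, observed, n_reps, seed, alpha = 0.01) {
  tree <- validate_phylo(tree)
  n_leaves <- length(tree$tip.label)
  if (length(observed) != n_leaves)
    stop(sprintf("observed set has %d sequences but the tree has %d leaves",
                 length(observed), n_leaves), call. = FALSE)
  hist <- matrix(0L, nrow = 400L, ncol = n_leaves + 1L)
  invisible(simulate_replicates(tree, root_seq, model, n_reps, seed,
    FUN = function(s) {
      cnt <- .dyad_presence_counts(s)
      idx <- cbind(seq_len(400L), cnt + 1L)
      hist[idx] <<- hist[idx] + 1L
      NULL
    }))
  .scan_from_hist(hist, n_reps, n_leaves, .dyad_presence_counts(observed), alpha)
}

#' Write a dyad scan (or single test) as TSV
#'
#' @param x A \code{scan_all_dyads} data frame or a \code{dyad_test}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_dyad_tsv <- function(x, path) {
  if (inherits(x, "dyad_test"))
    x <- data.frame(dyad = x$dyad, observed = x$observed,
                    exceedances = x$exceedances, n_reps = x$n_reps,
                    p_value = x$p_value, upper_bound = x$upper_bound)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
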