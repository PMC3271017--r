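#' Count occurrences of a dyad in a sequence
#'
#' Counts positions \code{i} with \code{seq[i] == dyad[1]} and
#' \code{seq[i+1] == dyad[2]}. Occurrences may overlap ("HHH" contains "HH"
#' twice) and order matters ("DH" contains no "HD").
#'
#' @param seq Protein sequence(s), character vector; counting is vectorized
#'   over elements.
#' @param dyad Two-residue motif, e.g. \code{"HD"}.
#' @return Integer vector of counts, one per sequence.
#' @export
#' @examples
#' count_occurrences("HDHD", "HD")  # 2
#' count_occurrences("HHH", "HH")   # 2: overlaps count
#' count_occurrences("DH", "HD")    # 0: order matters
count_occurrences <- function(seq, dyad) {
  dyad <- .check_dyad(dyad)
  d1 <- substr(dyad, 1, 1); d2 <- substr(dyad, 2, 2)
  vapply(strsplit(seq, "", fixed = TRUE), function(ch) {
    n <- length(ch)
    if (n < 2L) return(0L)
    sum(ch[-n] == d1 & ch[-1] == d2)
  }, integer(1))
}

#' Number of sequences containing at least one copy of a dyad
#'
#' The test statistic of the positive-selection test: how many sequences in
#' a set carry the motif at all. Multiple copies in one sequence still count
#' that sequence once.
#'
#' @param s A \code{sequence_set} (or character vector of sequences).
#' @param dyad Two-residue motif.
#' @return Integer count in \code{0..length(s)}.
#' @export
#' @examples
#' n_sequences_containing(c(a = "HDA", b = "AAA"), "HD")  # 1
n_sequences_containing <- function(s, dyad) {
  sum(count_occurrences(unclass(s), dyad) >= 1L)
}

# Per-set presence counts for all 400 ordered dyads at once: element
# (a-1)*20 + b of the result is the number of sequences containing the dyad
# whose first residue has code a and second has code b.
.dyad_presence_counts <- function(s) {
  acc <- integer(400L)
  for (seq in unclass(s)) {
    ch <- match(strsplit(seq, "", fixed = TRUE)[[1]], .AA)
    n <- length(ch)
    if (n < 2L) next
    a <- ch[-n]; b <- ch[-1]
    keep <- !is.na(a) & !is.na(b)
    ids <- unique((a[keep] - 1L) * 20L + b[keep])
    acc[ids] <- acc[ids] + 1L
  }
  acc
}

.all_dyads <- function() {
  as.vector(t(outer(.AA, .AA, paste0)))  # "AA","AC",... first residue varies slowest
}
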