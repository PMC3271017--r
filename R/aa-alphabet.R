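# Fixed residue ordering used throughout the package: the 20 standard amino
# acids in alphabetical one-letter order.
.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The amino-acid alphabet
#'
#' Returns the fixed ordering of the 20 standard amino acids (alphabetical
#' one-letter codes) used for every matrix, vector and sequence in this
#' package. Rate matrices, transition matrices, composition tables and
#' log-odds tables are all indexed in this order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() .AA

# Map a protein sequence string to integer codes 1..20 in .AA order.
# Residues outside the alphabet become NA unless `strict`, in which case the
# first offending position is reported.
.aa_encode <- function(seq, strict = TRUE, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, .AA)
  if (strict && anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("invalid residue '%s' at position %d of %s (only the 20 standard amino acids are allowed)",
                 chars[bad], bad, what), call. = FALSE)
  }
  idx
}

.aa_decode <- function(idx) paste(.AA[idx], collapse = "")

# Validate a two-residue motif given as a 2-character string ("HD") or a
# length-2 character vector; returns the canonical 2-character string.
.check_dyad <- function(dyad) {
  if (length(dyad) == 2L && all(nchar(dyad) == 1L)) dyad <- paste(dyad, collapse = "")
  if (!is.character(dyad) || length(dyad) != 1L || nchar(dyad) != 2L)
    stop("'dyad' must be two amino-acid one-letter codes, e.g. \"HD\"", call. = FALSE)
  .aa_encode(dyad, what = "dyad")
  dyad
}
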