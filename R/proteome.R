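#' Single-residue and dyad composition of a protein collection
#'
#' Tallies single amino acids and adjacent ordered amino-acid pairs (dyads)
#' across a collection of protein sequences. Dyads are counted with a
#' per-sequence sliding window, never across sequence boundaries, and never
#' pooled with their reverse (\code{HD} and \code{DH} are distinct cells).
#' Residues outside the 20-letter standard alphabet (\code{B J O U X Z},
#' gaps, \code{*}) are excluded from the single counts, and any adjacent
#' pair touching one is excluded from the dyad counts; they are skipped, not
#' remapped, so they cannot distort the distributions.
#'
#' @param x A protein FASTA path, an \code{AAStringSet}, or a character
#'   vector of sequences.
#' @param label Collection label carried into downstream tables.
#' @return An object of class \code{composition_table}: list with
#'   \code{single} (named length-20 probability vector), \code{dyad}
#'   (20 x 20 probability matrix, first residue on rows), the raw
#'   \code{single_counts} and \code{dyad_counts}, and \code{n_sequences},
#'   \code{n_residues}, \code{n_dyads}, \code{source}.
#' @export
#' @examples
#' comp <- composition(c("RHDSGY", "AHDSEF"))
#' comp$dyad["H", "D"]
composition <- function(x, label = NA_character_) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (is.na(label)) label <- basename(x)
    x <- read_fasta(x)
  }
  if (inherits(x, "AAStringSet")) x <- as.character(x)
  stopifnot(is.character(x), length(x) >= 1L)

  single <- integer(20L); names(single) <- .AA
  dyad <- matrix(0L, 20L, 20L, dimnames = list(.AA, .AA))
  for (seq in x) {
    code <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], .AA)
    valid <- !is.na(code)
    single <- single + tabulate(code[valid], nbins = 20L)
    n <- length(code)
    if (n >= 2L) {
      a <- code[-n]; b <- code[-1]
      keep <- !is.na(a) & !is.na(b)
      if (any(keep))
        dyad <- dyad + matrix(tabulate((a[keep] - 1L) * 20L + b[keep], nbins = 400L),
                              20L, 20L, byrow = TRUE)
    }
  }
  n_dyads <- sum(dyad)
  if (n_dyads == 0L)
    stop("no valid dyads: every adjacent pair touches a nonstandard residue or sequences are too short",
         call. = FALSE)
  structure(list(single = single / sum(single), dyad = dyad / n_dyads,
                 single_counts = single, dyad_counts = dyad,
                 n_sequences = length(x), n_residues = sum(single),
                 n_dyads = n_dyads, source = label),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("Composition table%s: %d sequences, %d residues, %d dyads\n",
              if (is.na(x$source)) "" else paste0(" [", x$source, "]"),
              x$n_sequences, x$n_residues, x$n_dyads))
  cat("  most frequent residues:\n")
  top <- sort(x$single, decreasing = TRUE)[1:5]
  cat("   ", paste(sprintf("%s=%.3f", names(top), top), collapse = " "), "\n")
  invisible(x)
}

#' Dyad log-odds table
#'
#' For every ordered pair of amino acids, the log (in an explicit base) of
#' the ratio between the dyad's observed frequency and the frequency
#' expected if its two residues occurred independently:
#' \deqn{s(a,b) = \log_{base} \frac{\pi(a,b)}{p(a)\,p(b)}}
#' Positive values mean the pair is overrepresented in the collection,
#' negative values underrepresented. Cells with zero observed dyad
#' frequency are undefined and returned as \code{NA}, never as a numeric
#' stand-in.
#'
#' @param comp A \code{composition_table}.
#' @param base Logarithm base; always reported alongside the values since it
#'   sets their absolute scale.
#' @return An object of class \code{log_odds_table}: the 20 x 20 matrix
#'   \code{s} (first residue on rows) with attributes \code{base} and
#'   \code{source}.
#' @export
#' @examples
#' lo <- log_odds(composition(c("RHDSGY", "AHDSEF")), base = 2)
#' lo$s["H", "D"]
log_odds <- function(comp, base = 2) {
  stopifnot(inherits(comp, "composition_table"))
  if (!is.numeric(base) || length(base) != 1L || base <= 0 || base == 1)
    stop("'base' must be a positive number different from 1", call. = FALSE)
  expected <- outer(comp$single, comp$single)
  s <- log(comp$dyad / expected, base = base)
  s[comp$dyad == 0] <- NA_real_
  structure(list(s = s, base = base, source = comp$source),
            class = "log_odds_table")
}

#' @export
print.log_odds_table <- function(x, ...) {
  cat(sprintf("Dyad log-odds (base %g%s); %d undefined cells\n", x$base,
              if (is.na(x$source)) "" else paste0(", ", x$source),
              sum(is.na(x$s))))
  ext <- range(x$s, na.rm = TRUE)
  cat(sprintf("  range: %.3f .. %.3f\n", ext[1], ext[2]))
  invisible(x)
}

#' Split a sequence database by species
#'
#' Partitions a FASTA collection by the species named in each record header
#' and keeps the species represented by strictly more than
#' \code{min_sequences} records. The UniProt \code{OS=...} convention is
#' tried first; \code{pattern} is the fallback for other header dialects
#' (its first capture group is the species).
#'
#' @param x FASTA path, \code{AAStringSet}, or named character vector.
#' @param min_sequences Keep species with more than this many records
#'   (strictly; the default mirrors the usual "more than a thousand"
#'   proteome filter).
#' @param pattern Fallback regular expression with one capture group.
#' @return Named list of character vectors of sequences, one per retained
#'   species; attribute \code{dropped} gives per-species record counts for
#'   the species filtered out.
#' @export
split_by_species <- function(x, min_sequences = 1000,
                             pattern = "\\[([^]]+)\\]\\s*$") {
  if (is.character(x) && length(x) == 1L && file.exists(x)) x <- read_fasta(x)
  if (inherits(x, "AAStringSet")) x <- as.character(x)
  headers <- names(x)
  if (is.null(headers)) stop("records carry no headers to parse a species from", call. = FALSE)
  species <- rep(NA_character_, length(x))
  has_os <- grepl("OS=", headers, fixed = TRUE)
  # UniProt dialect: OS=<species> runs until the next TAG= or end of header
  species[has_os] <- sub("\\s+[A-Z]{2}=.*$", "", sub("^.*OS=", "", headers[has_os]))
  fb <- is.na(species) | !nzchar(species)
  if (any(fb)) {
    mm <- regmatches(headers[fb], regexec(pattern, headers[fb]))
    species[fb] <- vapply(mm, function(m) if (length(m) >= 2L) m[2] else NA_character_,
                          character(1))
  }
  if (anyNA(species) || any(!nzchar(species))) {
    bad <- which(is.na(species) | !nzchar(species))[1L]
    stop("cannot parse a species from record: ", headers[bad], call. = FALSE)
  }
  tab <- table(species)
  keep <- names(tab)[tab > min_sequences]
  out <- split(unname(x), species)[keep]
  dropped <- tab[setdiff(names(tab), keep)]
  message(sprintf("kept %d species, dropped %d below the %d-sequence threshold",
                  length(keep), length(dropped), min_sequences))
  attr(out, "dropped") <- dropped
  out
}

#' Write / read composition and log-odds tables as TSV
#'
#' The composition TSV stores raw integer counts (single residues and the
#' 20 x 20 dyad counts) so that reading it back reproduces the table
#' exactly; the log-odds TSV stores the 20 x 20 matrix with one-letter
#' row/column headers, first residue on rows, with the base recorded in a
#' header comment.
#'
#' @param comp A \code{composition_table}.
#' @param path Output (or input) file path.
#' @return \code{path} invisibly for writers; the parsed object for
#'   \code{read_composition_tsv}.
#' @export
write_composition_tsv <- function(comp, path) {
  stopifnot(inherits(comp, "composition_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# composition\tsequences=%d\tresidues=%d\tdyads=%d\tsource=%s",
                     comp$n_sequences, comp$n_residues, comp$n_dyads, comp$source), con)
  writeLines(paste(c("single", .AA), collapse = "\t"), con)
  writeLines(paste(c("count", comp$single_counts), collapse = "\t"), con)
  writeLines(paste(c("dyad", .AA), collapse = "\t"), con)
  for (a in .AA)
    writeLines(paste(c(a, comp$dyad_counts[a, ]), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_composition_tsv
#' @export
read_composition_tsv <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(sub("^# composition\t", "", lines[1]), "\t")[[1]]
  fields <- do.call(rbind, strsplit(meta, "="))
  single <- as.integer(strsplit(lines[3], "\t")[[1]][-1])
  names(single) <- .AA
  dyad <- matrix(0L, 20, 20, dimnames = list(.AA, .AA))
  for (i in seq_len(20))
    dyad[i, ] <- as.integer(strsplit(lines[4 + i], "\t")[[1]][-1])
  structure(list(single = single / sum(single), dyad = dyad / sum(dyad),
                 single_counts = single, dyad_counts = dyad,
                 n_sequences = as.integer(fields[fields[, 1] == "sequences", 2]),
                 n_residues = sum(single), n_dyads = sum(dyad),
                 source = fields[fields[, 1] == "source", 2]),
            class = "composition_table")
}

#' @rdname write_composition_tsv
#' @param lo A \code{log_odds_table}.
#' @export
write_log_odds_tsv <- function(lo, path) {
  stopifnot(inherits(lo, "log_odds_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dyad log-odds\tbase=%g\tsource=%s", lo$base, lo$source), con)
  writeLines(paste(c("", .AA), collapse = "\t"), con)
  for (a in .AA)
    writeLines(paste(c(a, sprintf("%.6g", lo$s[a, ])), collapse = "\t"), con)
  invisible(path)
}

#' Merge two composition tables
#'
#' Count-weighted merge: the composition of the concatenation of the two
#' underlying collections. Exact on the integer counts.
#'
#' @param a,b \code{composition_table}s.
#' @return A \code{composition_table}.
#' @export
merge_compositions <- function(a, b) {
  stopifnot(inherits(a, "composition_table"), inherits(b, "composition_table"))
  single <- a$single_counts + b$single_counts
  dyad <- a$dyad_counts + b$dyad_counts
  structure(list(single = single / sum(single), dyad = dyad / sum(dyad),
                 single_counts = single, dyad_counts = dyad,
                 n_sequences = a$n_sequences + b$n_sequences,
                 n_residues = sum(single), n_dyads = sum(dyad),
                 source = paste(a$source, b$source, sep = "+")),
            class = "composition_table")
}
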