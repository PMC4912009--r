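# PHYLIP nucleotide alignment input/output.
#
# The reader auto-detects sequential vs. interleaved layout and relaxed
# (whitespace-delimited name) vs. strict (10-column name field) dialects.
# The writer emits the canonical dialect: relaxed sequential.

# IUPAC nucleotide codes as 4-bit base masks (A=1, C=2, G=4, T=8).
# '-' and '?' are treated as full ambiguity {A,C,G,T}.
.iupac <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
  "-" = 15L, "?" = 15L
)

#' Construct a nucleotide alignment
#'
#' An alignment holds an ordered set of unique taxon labels and one
#' equal-length nucleotide sequence per taxon. Recognised characters are the
#' IUPAC codes `A C G T R Y S W K M B D H V N` plus gap `-` and missing `?`
#' (case-insensitive on input, stored upper-case).
#'
#' @param taxa character vector of unique taxon labels.
#' @param sequences character vector of sequences, one per taxon, all of the
#'   same length.
#' @return An object of class `"aln"` with fields `taxa`, `seqs`, `n_taxa`
#'   and `n_sites`.
#' @examples
#' a <- alignment(c("t1", "t2", "t3", "t4"), c("ACGT", "ACGT", "AGGT", "AGGA"))
#' a$n_sites
#' @export
alignment <- function(taxa, sequences) {
  taxa <- as.character(taxa)
  sequences <- toupper(as.character(sequences))
  if (length(taxa) == 0L)
    amp_stop("alignment needs at least one taxon", "aln_empty_error")
  if (length(taxa) != length(sequences))
    amp_stop(sprintf("%d labels but %d sequences", length(taxa),
                     length(sequences)), "aln_dim_error")
  if (anyDuplicated(taxa))
    amp_stop(sprintf("duplicate taxon label(s): %s",
                     paste(unique(taxa[duplicated(taxa)]), collapse = ", ")),
             "aln_dup_error")
  ns <- nchar(sequences)
  if (length(unique(ns)) != 1L)
    amp_stop(sprintf("sequences differ in length (%s)",
                     paste(unique(ns), collapse = ", ")), "aln_dim_error")
  if (ns[1] < 1L)
    amp_stop("alignment has zero sites", "aln_dim_error")
  chars <- unique(unlist(strsplit(sequences, "", fixed = TRUE)))
  bad <- setdiff(chars, names(.iupac))
  if (length(bad))
    amp_stop(sprintf("unrecognised sequence character(s): %s",
                     paste(bad, collapse = " ")), "aln_char_error")
  structure(list(taxa = taxa, seqs = sequences,
                 n_taxa = length(taxa), n_sites = ns[1]),
            class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("Nucleotide alignment: %d taxa x %d sites\n", x$n_taxa,
              x$n_sites))
  show <- head(seq_len(x$n_taxa), 6L)
  for (i in show)
    cat(sprintf("  %-12s %s%s\n", x$taxa[i], substr(x$seqs[i], 1, 50),
                if (x$n_sites > 50) "..." else ""))
  if (x$n_taxa > 6L) cat(sprintf("  ... %d more taxa\n", x$n_taxa - 6L))
  invisible(x)
}

.strip_ws <- function(x) gsub("[ \t]+", "", x)

# One parse attempt for a fixed layout/dialect. Returns list(taxa, seqs) if
# the declared dimensions are structurally met, otherwise NULL. Character
# validity is checked later, by the alignment() constructor.
.try_layout <- function(body, n_taxa, n_sites, interleaved, relaxed) {
  split_name <- function(line) {
    if (relaxed) {
      m <- regexpr("^\\s*\\S+", line)
      name <- trimws(regmatches(line, m))
      rest <- substr(line, attr(m, "match.length") + 1L, nchar(line))
    } else {
      name <- trimws(substr(line, 1L, 10L))
      rest <- substr(line, 11L, nchar(line))
    }
    list(name = name, rest = rest)
  }
  first <- lapply(body[seq_len(n_taxa)], split_name)
  taxa <- vapply(first, `[[`, "", "name")
  seqs <- .strip_ws(vapply(first, `[[`, "", "rest"))
  if (any(taxa == "")) return(NULL)
  if (interleaved) {
    extra <- body[-seq_len(n_taxa)]
    n_blocks <- length(extra) / n_taxa
    for (bl in seq_len(n_blocks)) {
      chunk <- .strip_ws(extra[(bl - 1L) * n_taxa + seq_len(n_taxa)])
      seqs <- paste0(seqs, chunk)
    }
  }
  if (!all(nchar(seqs) == n_sites)) return(NULL)
  list(taxa = taxa, seqs = seqs)
}

#' Read a PHYLIP nucleotide alignment
#'
#' Reads sequential or interleaved PHYLIP, in either the relaxed
#' (whitespace-delimited name) or strict (10-column name field) dialect.
#' Layout and dialect are auto-detected: a file whose body holds exactly the
#' declared number of taxon lines is parsed as sequential, a body holding a
#' whole multiple of that count as interleaved (name block first, then
#' continuation blocks without names); for each layout the relaxed dialect is
#' tried before the strict one, accepting the first interpretation that
#' reproduces the declared dimensions.
#'
#' @param source a file path, a single string containing newlines, or a
#'   character vector of lines.
#' @return An [alignment()] object.
#' @examples
#' txt <- c("4 5", "t1 ACGTA", "t2 ACGTT", "t3 AGGTA", "t4 AGGAA")
#' read_phylip(txt)
#' @export
read_phylip <- function(source) {
  if (length(source) == 1L && !grepl("\n", source)) {
    if (!file.exists(source))
      amp_stop(sprintf("file not found: %s", source), "aln_io_error")
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L)
    amp_stop("empty PHYLIP input", "aln_empty_error")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    amp_stop(sprintf("malformed PHYLIP header: '%s'", lines[1]),
             "aln_header_error")
  n_taxa <- as.integer(hdr[1])
  n_sites <- as.integer(hdr[2])
  if (n_taxa < 1L || n_sites < 1L)
    amp_stop("PHYLIP header must declare positive dimensions",
             "aln_header_error")
  body <- lines[-1]
  if (length(body) < n_taxa)
    amp_stop(sprintf("header declares %d taxa but only %d sequence lines",
                     n_taxa, length(body)), "aln_dim_error")
  interleaved <- length(body) != n_taxa
  if (interleaved && length(body) %% n_taxa != 0L)
    amp_stop(sprintf(
      "cannot determine layout: %d body lines for %d declared taxa",
      length(body), n_taxa), "aln_dim_error")
  res <- .try_layout(body, n_taxa, n_sites, interleaved, relaxed = TRUE)
  if (is.null(res))
    res <- .try_layout(body, n_taxa, n_sites, interleaved, relaxed = FALSE)
  if (is.null(res))
    amp_stop(sprintf(
      "dimension mismatch: sequences do not match the declared %d sites",
      n_sites), "aln_dim_error")
  alignment(res$taxa, res$seqs)
}

#' Shorten taxon labels to 10 characters and disambiguate clashes
#'
#' Labels are truncated to at most 10 characters. Where truncation makes two
#' or more labels identical, every member of the clashing group is renamed to
#' its first 7 characters followed by a zero-padded three-digit counter
#' assigned in input order (so the result stays within 10 characters). If a
#' generated name is already taken the counter advances until a free one is
#' found; more than 999 clashes on one stem is an error.
#'
#' @param a an [alignment()].
#' @return A list with elements `alignment` (the renamed alignment) and
#'   `mapping` (named character vector, old label -> new label).
#' @examples
#' a <- alignment(c("Drosophila_melanogaster", "Drosophila_simulans",
#'                  "Homo", "Mus"), rep("ACGT", 4))
#' normalize_names(a)$mapping
#' @export
normalize_names <- function(a) {
  stopifnot(inherits(a, "aln"))
  orig <- a$taxa
  trunc10 <- substr(orig, 1L, 10L)
  new <- trunc10
  clash_vals <- unique(trunc10[duplicated(trunc10)])
  taken <- new[!trunc10 %in% clash_vals]
  for (g in clash_vals) {
    idx <- which(trunc10 == g)
    stem <- substr(g, 1L, 7L)
    counter <- 0L
    for (i in idx) {
      repeat {
        counter <- counter + 1L
        if (counter > 999L)
          amp_stop(sprintf(
            "cannot disambiguate: more than 999 clashes on stem '%s'", stem),
            "aln_name_collision")
        cand <- sprintf("%s%03d", stem, counter)
        if (!cand %in% taken) break
      }
      new[i] <- cand
      taken <- c(taken, cand)
    }
  }
  out <- alignment(new, a$seqs)
  mapping <- stats::setNames(new, orig)
  list(alignment = out, mapping = mapping)
}

#' Write an alignment in relaxed sequential PHYLIP
#'
#' Labels containing whitespace are refused because they would break the
#' relaxed dialect on re-reading. `read_phylip(write_phylip(a))` reproduces
#' `a` exactly.
#'
#' @param a an [alignment()].
#' @param path optional file path; when omitted, the lines are only returned.
#' @return Invisibly, the character vector of output lines.
#' @export
write_phylip <- function(a, path = NULL) {
  stopifnot(inherits(a, "aln"))
  if (any(grepl("\\s", a$taxa)))
    amp_stop("taxon labels must not contain whitespace in relaxed PHYLIP",
             "aln_label_error")
  lines <- c(sprintf("%d %d", a$n_taxa, a$n_sites),
             paste(a$taxa, a$seqs))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
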