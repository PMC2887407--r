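#' Construct a validated in-frame codon alignment
#'
#' The container every analysis in this package operates on: equal-length,
#' in-frame nucleotide sequences over the alphabet ACGTN-. IUPAC ambiguity
#' codes are collapsed to N on construction, and a codon containing any gap
#' character is normalised to the full-codon gap \code{"---"} (with a
#' warning) so that reading frame is always intact. Codons containing N or a
#' gap are treated as missing by every codon-level statistic.
#'
#' @param names character vector of sequence identifiers (unique, non-empty).
#' @param sequences character vector of nucleotide strings, equal lengths
#'   divisible by 3.
#' @param frame_check if TRUE (default), an in-frame stop codon in any
#'   sequence is an error naming the sequence and the 1-based codon index.
#' @return An object of class \code{codon_alignment}: list with elements
#'   \code{names}, \code{sequences} (normalised), \code{length_nt},
#'   \code{n_codons}.
#' @examples
#' aln <- codon_alignment(c("a", "b"), c("ATGTTT", "ATGTTC"))
#' aln$n_codons  # 2
#' @export
codon_alignment <- function(names, sequences, frame_check = TRUE) {
  if (length(names) != length(sequences) || length(names) < 1L)
    stop("need one name per sequence and at least one sequence")
  if (anyDuplicated(names)) stop("duplicate sequence names")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(range(lens), collapse = "-"), ")")
  if (lens[1] %% 3L != 0L)
    stop("alignment error: length ", lens[1], " nt is not divisible by 3")
  # collapse ambiguity codes (R, Y, S, W, K, M, B, D, H, V, U, ?, .) to N;
  # only A, C, G, T, N and '-' survive.
  sequences <- chartr("U", "T", sequences)
  sequences <- gsub("[^ACGTN-]", "N", sequences)
  # normalise partial-codon gaps to full-codon gaps
  cod <- vapply(sequences, split_codons, character(lens[1] %/% 3L),
                USE.NAMES = FALSE)
  cod <- matrix(cod, nrow = lens[1] %/% 3L)
  partial <- grepl("-", cod) & cod != "---"
  if (any(partial)) {
    warning(sum(partial), " partial-codon gap(s) normalised to '---'")
    cod[partial] <- "---"
    sequences <- apply(cod, 2, paste, collapse = "")
  }
  if (frame_check) {
    stops <- matrix(is_stop_codon(cod), nrow = nrow(cod))
    if (any(stops)) {
      hit <- which(stops, arr.ind = TRUE)[1L, ]
      stop("frame error: internal stop codon in sequence '",
           names[hit["col"]], "' at codon ", hit["row"])
    }
  }
  structure(
    list(names = as.character(names), sequences = sequences,
         length_nt = lens[1], n_codons = lens[1] %/% 3L),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$names), "sequences x", x$n_codons,
      "codons (", x$length_nt, "nt )\n")
  invisible(x)
}

#' Codon matrix of an alignment
#'
#' @param aln a \code{codon_alignment}.
#' @return character matrix, \code{n_codons} rows x one column per sequence.
#' @keywords internal
codon_matrix <- function(aln) {
  m <- vapply(aln$sequences, split_codons, character(aln$n_codons),
              USE.NAMES = FALSE)
  m <- matrix(m, nrow = aln$n_codons)
  colnames(m) <- aln$names
  m
}

# Integer sense-codon state matrix (NA for gap / N / anything unresolvable).
#' @noRd
codon_state_matrix <- function(aln, code = the_code()) {
  m <- codon_matrix(aln)
  s <- matrix(codon_index(m, code), nrow = nrow(m),
              dimnames = list(NULL, colnames(m)))
  s
}

#' Read an in-frame codon alignment from FASTA
#'
#' @param path path to a FASTA file of aligned coding sequences.
#' @param frame_check reject sequences containing in-frame stop codons
#'   (default TRUE).
#' @return a \code{codon_alignment}; record order is preserved.
#' @seealso [write_codon_fasta()]
#' @export
read_codon_fasta <- function(path, frame_check = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) stop("empty FASTA record in ", path)
  # first whitespace-delimited token of the header is the identifier
  ids <- sub("\\s.*$", "", names(set))
  codon_alignment(ids, unname(seqs), frame_check = frame_check)
}

#' Write a codon alignment to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param aln a \code{codon_alignment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_codon_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(stats::setNames(aln$sequences, aln$names))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Per-sequence GC composition of a codon alignment
#'
#' GC fraction overall and at each of the three codon positions. Gaps and N
#' are excluded from both numerator and denominator; a sequence with no
#' resolved base at some position class gets \code{NA} there and is flagged
#' \code{undefined}.
#'
#' @param aln a \code{codon_alignment}.
#' @return data.frame with columns \code{seq_id}, \code{gc_total},
#'   \code{gc1}, \code{gc2}, \code{gc3}, \code{undefined}.
#' @examples
#' aln <- codon_alignment("s", "ATGCAT", frame_check = FALSE)
#' gc_content(aln)$gc_total  # 2/6
#' @export
gc_content <- function(aln) {
  pos <- rep_len(1:3, aln$length_nt)
  res <- lapply(seq_along(aln$names), function(i) {
    b <- strsplit(aln$sequences[i], "", fixed = TRUE)[[1]]
    ok <- b %in% c("A", "C", "G", "T")
    gc <- b %in% c("G", "C")
    frac <- function(sel) {
      n <- sum(ok & sel)
      if (n == 0L) NA_real_ else sum(gc & sel) / n
    }
    c(total = frac(TRUE), gc1 = frac(pos == 1L),
      gc2 = frac(pos == 2L), gc3 = frac(pos == 3L))
  })
  res <- do.call(rbind, res)
  data.frame(
    seq_id = aln$names,
    gc_total = res[, "total"], gc1 = res[, "gc1"],
    gc2 = res[, "gc2"], gc3 = res[, "gc3"],
    undefined = !is.finite(res[, "total"]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Count parsimony-informative nucleotide columns
#'
#' A column is parsimony informative when at least two distinct residues
#' each occur in at least two sequences; gaps and N are not residues.
#'
#' @param aln a \code{codon_alignment} with at least 4 sequences.
#' @return integer count of informative columns.
#' @export
count_informative_sites <- function(aln) {
  if (length(aln$names) < 4L)
    stop("parsimony informativeness is undefined for fewer than 4 sequences")
  m <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  sum(apply(m, 2, function(col) {
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    sum(tab >= 2L) >= 2L
  }))
}

#' Write a per-sequence composition report
#'
#' TSV with columns seq_id, gc_total, gc1, gc2, gc3.
#'
#' @param aln a \code{codon_alignment}.
#' @param path output TSV path.
#' @return the data.frame, invisibly.
#' @export
write_composition_tsv <- function(aln, path) {
  d <- gc_content(aln)[, c("seq_id", "gc_total", "gc1", "gc2", "gc3")]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}
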