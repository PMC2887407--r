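#' Classify query sequences into reference clades by neighbor joining
#'
#' Builds a neighbor-joining tree from Jukes-Cantor distances over the
#' queries plus the labelled references, then assigns each query the label
#' of the reference clade it nests within. A query nests within clade L when
#' the references of L together with the query are monophyletic on the tree
#' rooted at a reference of another label; queries for which no (or more
#' than one) label satisfies this are reported \code{"ambiguous"}. Each
#' query is placed on its own tree (references + that query) so queries do
#' not interfere with one another.
#'
#' Queries sharing fewer than 50\% resolved positions with the references
#' are excluded with a warning.
#'
#' @param aln a \code{codon_alignment} containing queries and references.
#' @param queries character vector of query sequence ids.
#' @param references named character vector: names are reference sequence
#'   ids, values are clade labels (at least 2 distinct labels, each with at
#'   least one reference).
#' @return named character vector: query id -> assigned label
#'   (\code{"ambiguous"} or \code{NA} for excluded queries).
#' @export
nj_classify <- function(aln, queries, references) {
  labs <- unique(unname(references))
  if (length(labs) < 2L) stop("need at least 2 reference labels")
  ids <- c(names(references), queries)
  idx <- match(ids, aln$names)
  if (anyNA(idx)) stop("unknown sequence id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))

  resolved <- function(s) strsplit(s, "", fixed = TRUE)[[1]] %in%
    c("A", "C", "G", "T")
  ref_res <- Reduce(`|`, lapply(aln$sequences[match(names(references),
                                                    aln$names)], resolved))
  out <- stats::setNames(rep(NA_character_, length(queries)), queries)
  for (q in queries) {
    qseq <- aln$sequences[match(q, aln$names)]
    if (mean(resolved(qseq) & ref_res) / mean(ref_res) < 0.5) {
      warning("query '", q, "' excluded: <50% overlap with references")
      next
    }
    tre_ids <- c(names(references), q)
    n <- length(tre_ids)
    D <- matrix(0, n, n, dimnames = list(tre_ids, tre_ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- jc_distance(aln$sequences[match(tre_ids[i], aln$names)],
                       aln$sequences[match(tre_ids[j], aln$names)])
      if (!is.finite(d)) d <- 3  # saturated: large but finite for NJ
      D[i, j] <- D[j, i] <- d
    }
    tr <- ape::nj(as.dist(D))
    hits <- character(0)
    for (L in labs) {
      group <- c(names(references)[references == L], q)
      others <- setdiff(names(references), group)
      if (length(others) == 0L) next
      rooted <- tryCatch(ape::root(tr, outgroup = others[1],
                                   resolve.root = TRUE),
                         error = function(e) NULL)
      if (is.null(rooted)) next
      if (ape::is.monophyletic(rooted, tips = group)) hits <- c(hits, L)
    }
    if (length(hits) > 1L) {
      # the query attaches on the junction between reference clades, where
      # more than one grouping is a clade; break the tie by patristic
      # proximity on the NJ tree
      pat <- ape::cophenetic.phylo(tr)
      md <- vapply(hits, function(L)
        mean(pat[q, names(references)[references == L]]), numeric(1))
      hits <- if (sum(md == min(md)) == 1L) hits[which.min(md)]
              else hits  # exact tie stays ambiguous
    }
    out[q] <- if (length(hits) == 1L) hits else "ambiguous"
  }
  out
}
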