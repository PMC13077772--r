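# Proteome cross-reactivity scan: sliding-window enumeration, HLA
# anchor-motif filtering, outward-position-weighted similarity scoring and
# ranked hit reporting.

.default_motifs <- list(
  "A*01:01" = list("3" = c("D", "E"), "C" = c("Y")),
  "A*02:01" = list("2" = c("L", "M", "I", "V"), "C" = c("V", "L", "I")),
  "A*03:01" = list("2" = c("L", "M", "I", "V", "A", "T"), "C" = c("K", "R")),
  "C*07:02" = list("2" = c("Y", "F"), "C" = c("F", "Y", "L"))
)

#' Anchor-motif table for an HLA allele
#'
#' Returns the packaged anchor preference table for the allele: a list
#' mapping peptide position (1-based, `"C"` = C-terminal position) to the
#' set of allowed residue letters. These are editable defaults capturing
#' the textbook primary anchors of each allele, not measured binding
#' motifs; pass your own list of the same shape for anything quantitative.
#'
#' @param allele Allele name, e.g. `"A*01:01"`.
#' @return Named list position -> character vector of allowed letters, with
#'   attribute `allele`.
#' @export
#' @examples
#' motif_table("A*01:01")
motif_table <- function(allele) {
  if (!allele %in% names(.default_motifs)) {
    stop("no packaged motif for allele ", allele, "; available: ",
         paste(names(.default_motifs), collapse = ", "), call. = FALSE)
  }
  m <- .default_motifs[[allele]]
  attr(m, "allele") <- allele
  m
}

# coerce proteome input to a named character vector of sequences
proteome_sequences <- function(proteome) {
  if (inherits(proteome, "AAStringSet") || inherits(proteome, "XStringSet")) {
    stats::setNames(as.character(proteome), names(proteome))
  } else if (is.character(proteome)) {
    if (length(proteome) == 0) return(character(0))
    if (is.null(names(proteome))) {
      names(proteome) <- paste0("protein_", seq_along(proteome))
    }
    proteome
  } else {
    stop("proteome must be an AAStringSet or a named character vector",
         call. = FALSE)
  }
}

#' Enumerate all length-k windows of a proteome
#'
#' Every length-`k` substring of every protein appears exactly once, with
#' its provenance (1-based offset, closed interval). Records containing
#' letters outside the 20 standard amino acids (B, J, O, U, X, Z, ...) are
#' skipped with a warning rather than silently scored.
#'
#' @param proteome `Biostrings::AAStringSet` or named character vector.
#' @param k Window length, 8–11.
#' @return Tibble `protein_id`, `start`, `sequence`.
#' @export
enumerate_windows <- function(proteome, k) {
  stopifnot(k >= 8, k <= 11)
  seqs <- proteome_sequences(proteome)
  if (length(seqs) == 0) stop("empty proteome", call. = FALSE)
  std <- paste(names(.aa1), collapse = "")
  ok <- !grepl(sprintf("[^%s]", std), seqs)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with non-standard letters skipped: ",
            paste(utils::head(names(seqs)[!ok], 5), collapse = ", "),
            call. = FALSE)
    seqs <- seqs[ok]
  }
  purrr::map2_dfr(names(seqs), unname(seqs), function(id, s) {
    n <- nchar(s) - k + 1
    if (n < 1) return(NULL)
    tibble::tibble(
      protein_id = id,
      start = seq_len(n),
      sequence = substring(s, seq_len(n), seq_len(n) + k - 1)
    )
  })
}

#' Filter peptide windows on an anchor motif
#'
#' Keeps windows whose residue at every motif position lies in that
#' position's allowed set and marks them with `anchors_pass = TRUE`; an
#' empty motif (`NULL` or `list()`) passes everything. The output is always
#' a subset of the input, so successive filters compose monotonically.
#'
#' @param hits Tibble with a `sequence` column (e.g. from
#'   [enumerate_windows()]); all sequences must share one length.
#' @param motif A [motif_table()]-shaped list.
#' @return The passing rows, with `anchors_pass` added.
#' @export
anchor_filter <- function(hits, motif) {
  if (is.null(motif) || length(motif) == 0) {
    hits$anchors_pass <- TRUE
    return(hits)
  }
  if (nrow(hits) == 0) {
    hits$anchors_pass <- logical(0)
    return(hits)
  }
  k <- unique(nchar(hits$sequence))
  if (length(k) != 1) stop("sequences of mixed length", call. = FALSE)
  pos <- ifelse(names(motif) == "C", k, suppressWarnings(as.integer(names(motif))))
  if (anyNA(pos) || any(pos < 1 | pos > k)) {
    stop("motif positions invalid for k = ", k, call. = FALSE)
  }
  pass <- rep(TRUE, nrow(hits))
  for (i in seq_along(motif)) {
    pass <- pass & substring(hits$sequence, pos[i], pos[i]) %in% motif[[i]]
  }
  out <- hits[pass, , drop = FALSE]
  out$anchors_pass <- TRUE
  out
}

#' Identity substitution matrix (match 1, mismatch 0)
#'
#' With unit weights, [positional_similarity()] under this matrix equals
#' the number of matching positions (k minus the Hamming distance).
#'
#' @return 20 x 20 matrix over the one-letter amino-acid codes.
#' @export
identity_matrix <- function() {
  aa <- sort(names(.aa1))
  m <- diag(length(aa))
  dimnames(m) <- list(aa, aa)
  m
}

#' BLOSUM62 substitution matrix
#'
#' Re-exported from \pkg{Biostrings} data; the default scoring matrix for
#' the proteome scan.
#'
#' @return The BLOSUM62 integer matrix.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Position-weighted substitution similarity between two peptides
#'
#' `sum_i weights[i] * matrix[query[i], candidate[i]]`. With the default
#' outward-position weighting (1 at outward-facing positions, 0 at
#' anchors), this scores only the face of the peptide a binder can read —
#' two peptides sharing their outward-facing residues are maximally
#' similar regardless of their groove-buried anchors.
#'
#' @param query,candidate Equal-length one-letter sequences.
#' @param weights Non-negative numeric vector, length k (default all 1).
#' @param matrix Substitution matrix indexed by letters; default
#'   [blosum62()].
#' @return Numeric similarity.
#' @export
#' @examples
#' positional_similarity("EVDPIGHLY", "ESDPIVAQY",
#'                       matrix = identity_matrix())  # 5 identities
positional_similarity <- function(query, candidate,
                                  weights = rep(1, nchar(query)),
                                  matrix = blosum62()) {
  k <- nchar(query)
  if (nchar(candidate) != k) {
    stop("query and candidate lengths differ", call. = FALSE)
  }
  if (length(weights) != k) stop("weights must have length ", k, call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  q <- strsplit(query, "")[[1]]
  s <- strsplit(candidate, "")[[1]]
  sum(weights * matrix[cbind(q, s)])
}

#' Outward-position weights for the scan
#'
#' Builds the per-position weight vector used by [scan_proteome()]: 1 at
#' positions to be read by the binder, 0 at anchors. Positions can come
#' from a structure-derived classification (weight 1 exactly at `OUTWARD`
#' positions) or, lacking a structure, from a motif table (weight 0 at
#' motif anchor positions, 1 elsewhere).
#'
#' @param k Peptide length.
#' @param position_classes Optional [classify_peptide_positions()] output.
#' @param motif Optional [motif_table()] list (used when
#'   `position_classes` is `NULL`).
#' @return Numeric weight vector of length `k`.
#' @export
outward_weights <- function(k, position_classes = NULL, motif = NULL) {
  if (!is.null(position_classes)) {
    w <- numeric(k)
    w[position_classes$position[position_classes$class == "OUTWARD"]] <- 1
    return(w)
  }
  w <- rep(1, k)
  if (!is.null(motif) && length(motif) > 0) {
    pos <- ifelse(names(motif) == "C", k,
                  suppressWarnings(as.integer(names(motif))))
    w[pos] <- 0
  }
  w
}

#' Scan a proteome for potential cross-reactive peptides
#'
#' The in-silico cross-reactivity funnel: enumerate all length-k windows,
#' keep those satisfying the allele's anchor motif (presentable peptides),
#' score each against the query with a position-weighted substitution
#' similarity, and return the top `top_n` by similarity (ties broken by
#' `protein_id`, then `start`). When the query itself occurs in the
#' proteome it ranks first for any non-negative weighting under a matrix
#' whose diagonal dominates each row.
#'
#' @param proteome `Biostrings::AAStringSet` or named character vector.
#' @param query Query peptide (the design's target).
#' @param motif [motif_table()]-shaped list, or `NULL` for no filtering.
#' @param weights Per-position weights; default [outward_weights()] from
#'   the motif.
#' @param matrix Substitution matrix; default [blosum62()].
#' @param top_n Number of hits to return.
#' @return Tibble `rank`, `protein_id`, `start`, `sequence`,
#'   `anchors_pass`, `similarity`.
#' @export
scan_proteome <- function(proteome, query, motif = NULL,
                          weights = outward_weights(nchar(query), motif = motif),
                          matrix = blosum62(), top_n = 50L) {
  k <- nchar(query)
  hits <- enumerate_windows(proteome, k) |>
    anchor_filter(motif)
  if (nrow(hits) == 0 || top_n == 0) {
    return(tibble::tibble(rank = integer(), protein_id = character(),
                          start = integer(), sequence = character(),
                          anchors_pass = logical(), similarity = numeric()))
  }
  q <- strsplit(query, "")[[1]]
  # vectorized scoring: one matrix lookup per position over all hits
  sim <- numeric(nrow(hits))
  for (i in seq_len(k)) {
    if (weights[i] == 0) next
    sim <- sim + weights[i] * matrix[cbind(q[i], substring(hits$sequence, i, i))]
  }
  hits$similarity <- sim
  hits |>
    dplyr::arrange(dplyr::desc(.data$similarity), .data$protein_id,
                   .data$start) |>
    utils::head(top_n) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "protein_id", "start", "sequence", "anchors_pass",
                  "similarity")
}
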