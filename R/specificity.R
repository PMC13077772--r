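# On/off-target specificity: a model-agnostic scoring contract (higher =
# more favorable), a deterministic contact-potential proxy scorer, margin /
# rank computation, and TSV score-table interop so outputs of real
# predictors can be ranked with the same logic.

# CB coordinate per residue (CA for glycine), one row per residue
cb_coords <- function(atoms) {
  atoms |>
    dplyr::group_by(.data$chain_id, .data$residue_index, .data$residue_name) |>
    dplyr::summarise(
      x = if (any(.data$atom_name == "CB")) .data$x[.data$atom_name == "CB"][1]
          else .data$x[.data$atom_name == "CA"][1],
      y = if (any(.data$atom_name == "CB")) .data$y[.data$atom_name == "CB"][1]
          else .data$y[.data$atom_name == "CA"][1],
      z = if (any(.data$atom_name == "CB")) .data$z[.data$atom_name == "CB"][1]
          else .data$z[.data$atom_name == "CA"][1],
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$x))
}

#' Deterministic contact-potential proxy score for a threaded peptide
#'
#' Threads `peptide_seq` onto the peptide backbone of the complex (sequence
#' only — coordinates are untouched) and scores it against the binder with
#' a coarse-grained residue contact potential: for every (peptide position
#' i, binder residue j) pair whose C-beta–C-beta distance (C-alpha for
#' glycine) is at most `cb_cutoff`, the potential value for the residue
#' pair is accumulated, and the score is the negated sum, so that higher
#' scores are more favorable (the package-wide scorer orientation). The
#' scorer is a deterministic stand-in for learned sequence/structure
#' confidence models, letting the downstream specificity logic run at desk
#' scale.
#'
#' @param x A [pmhc_complex()] with `PEPTIDE` and `BINDER` chains.
#' @param peptide_seq One-letter sequence, same length as the peptide chain.
#' @param potential Symmetric 20 x 20 matrix indexed by one-letter codes;
#'   defaults to [contact_potential()].
#' @param cb_cutoff C-beta contact cutoff in \enc{Å}{Angstrom} (default 8,
#'   the usual coarse-grained contact convention).
#' @return A single numeric score (higher = more favorable).
#' @export
proxy_peptide_score <- function(x, peptide_seq,
                                potential = contact_potential(),
                                cb_cutoff = 8) {
  k <- nchar(x$peptide_sequence)
  if (nchar(peptide_seq) != k) {
    stop("peptide_seq has ", nchar(peptide_seq),
         " residues; peptide chain has ", k, call. = FALSE)
  }
  if (!isTRUE(all.equal(potential, t(potential)))) {
    stop("potential matrix is not symmetric", call. = FALSE)
  }
  letters_pep <- strsplit(peptide_seq, "")[[1]]
  if (!all(letters_pep %in% rownames(potential))) {
    stop("unknown residue letter(s) in peptide_seq: ",
         paste(setdiff(letters_pep, rownames(potential)), collapse = ", "),
         call. = FALSE)
  }
  pep_cb <- cb_coords(role_atoms(x, "PEPTIDE")) |>
    dplyr::arrange(.data$residue_index)
  bnd <- role_atoms(x, "BINDER")
  if (nrow(bnd) == 0) stop("complex has no BINDER chain", call. = FALSE)
  bnd_cb <- cb_coords(bnd)
  bnd_aa <- aa_three_to_one(bnd_cb$residue_name)
  if (!all(bnd_aa %in% rownames(potential))) {
    stop("binder residue(s) missing from potential: ",
         paste(setdiff(bnd_aa, rownames(potential)), collapse = ", "),
         call. = FALSE)
  }
  d2 <- cross_dist2(as.matrix(pep_cb[, c("x", "y", "z")]),
                    as.matrix(bnd_cb[, c("x", "y", "z")]))
  hit <- which(d2 <= cb_cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(0)
  -sum(potential[cbind(letters_pep[hit[, 1]], bnd_aa[hit[, 2]])])
}

#' Margin and rank of an on-target score against off-target scores
#'
#' `margin = on_score - aggregate(off_scores)` where the aggregate is the
#' maximum (`"worst_case_max"`, default: the margin against the most
#' dangerous off-target) or the mean. `target_rank` is 1 plus the number of
#' off-target scores strictly greater than the on-target score, so ties
#' share the better rank.
#'
#' @param on_score Numeric scalar.
#' @param off_scores Named (or unnamed) numeric vector, non-empty.
#' @param aggregation `"worst_case_max"` or `"mean"`.
#' @return One-row tibble with `margin` and `target_rank`.
#' @export
specificity_margin <- function(on_score,
                               off_scores,
                               aggregation = c("worst_case_max", "mean")) {
  aggregation <- match.arg(aggregation)
  if (length(off_scores) == 0) stop("off_scores is empty", call. = FALSE)
  agg <- if (aggregation == "worst_case_max") max(off_scores) else
    mean(off_scores)
  tibble::tibble(margin = on_score - agg,
                 target_rank = 1L + sum(off_scores > on_score))
}

#' Score a design's peptide-identity specificity against decoy sequences
#'
#' Scores the target and each decoy sequence on the same structure with a
#' common scorer and summarises the result as a specificity record. This
#' realizes the sequence-recovery filter of the design funnel: a specific
#' design should score its own peptide above closely related alternatives.
#'
#' @param x A [pmhc_complex()].
#' @param target_seq On-target peptide sequence.
#' @param decoy_seqs Character vector of off-target sequences (non-empty,
#'   same length as the peptide chain); names, if present, label the
#'   off-target scores.
#' @param scorer Function `(x, seq) -> numeric` obeying the higher-is-better
#'   orientation; defaults to [proxy_peptide_score()].
#' @param aggregation Passed to [specificity_margin()].
#' @param design_id Label for the record.
#' @return One-row tibble: `design_id`, `on_target_peptide`, `on_score`,
#'   `off_scores` (list column, named numeric), `margin`, `aggregation`,
#'   `target_rank`.
#' @export
peptide_identity_margin <- function(x, target_seq, decoy_seqs,
                                    scorer = proxy_peptide_score,
                                    aggregation = c("worst_case_max", "mean"),
                                    design_id = "design") {
  aggregation <- match.arg(aggregation)
  if (length(decoy_seqs) == 0) stop("decoy_seqs is empty", call. = FALSE)
  if (is.null(names(decoy_seqs))) names(decoy_seqs) <- decoy_seqs
  score_one <- function(seq) {
    tryCatch(scorer(x, seq), error = function(e) {
      stop("scorer failed on sequence ", seq, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  on_score <- score_one(target_seq)
  off_scores <- vapply(decoy_seqs, score_one, numeric(1))
  m <- specificity_margin(on_score, off_scores, aggregation)
  tibble::tibble(
    design_id = design_id, on_target_peptide = target_seq,
    on_score = on_score, off_scores = list(off_scores),
    margin = m$margin, aggregation = aggregation,
    target_rank = m$target_rank
  )
}

#' Rank designs passing a specificity-margin threshold
#'
#' Keeps records with `margin >= min_margin` and orders them by margin
#' descending, breaking ties by `design_id` lexicographically. The default
#' `min_margin = 0` demands strict on-target superiority and nothing more;
#' any stronger notion of "considerably more confident" is a campaign
#' choice and must be passed explicitly.
#'
#' @param records Tibble with at least `design_id` and `margin` columns
#'   (e.g. rows of [peptide_identity_margin()]).
#' @param min_margin Minimum margin to keep.
#' @return The filtered, ordered tibble.
#' @export
rank_designs <- function(records, min_margin = 0) {
  records |>
    dplyr::filter(.data$margin >= min_margin) |>
    dplyr::arrange(dplyr::desc(.data$margin), .data$design_id)
}

#' Read / write predictor score tables
#'
#' Tab-separated tables with columns `design_id`, `peptide`, `score` — the
#' interchange format for external predictor confidences, so that real
#' model outputs flow through the same margin/rank logic as the proxy
#' scorer.
#'
#' @param path File path.
#' @return `read_score_table()`: tibble with the three columns.
#' @export
read_score_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           design_id = readr::col_character(),
                           peptide = readr::col_character(),
                           score = readr::col_double()
                         ))
  required <- c("design_id", "peptide", "score")
  if (!all(required %in% names(out))) {
    stop("score table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname read_score_table
#' @param scores Tibble with columns `design_id`, `peptide`, `score`.
#' @export
write_score_table <- function(scores, path) {
  readr::write_tsv(scores[, c("design_id", "peptide", "score")], path)
  invisible(path)
}

#' Specificity records from a long score table
#'
#' @param scores Tibble `design_id`, `peptide`, `score` (one row per scored
#'   peptide per design).
#' @param on_target Either a single peptide (same target for every design)
#'   or a named character vector design_id -> target peptide.
#' @param aggregation Passed to [specificity_margin()].
#' @return Tibble of specificity records, one row per design (see
#'   [peptide_identity_margin()] for columns).
#' @export
specificity_from_table <- function(scores, on_target,
                                   aggregation = c("worst_case_max", "mean")) {
  aggregation <- match.arg(aggregation)
  scores |>
    dplyr::group_by(.data$design_id) |>
    dplyr::group_modify(function(df, key) {
      tgt <- if (length(on_target) == 1 && is.null(names(on_target))) {
        on_target
      } else {
        unname(on_target[key$design_id])
      }
      if (is.na(tgt) || !tgt %in% df$peptide) {
        stop("no on-target score for design ", key$design_id, call. = FALSE)
      }
      on_score <- df$score[df$peptide == tgt][1]
      off <- df[df$peptide != tgt, ]
      off_scores <- stats::setNames(off$score, off$peptide)
      m <- specificity_margin(on_score, off_scores, aggregation)
      tibble::tibble(
        on_target_peptide = tgt, on_score = on_score,
        off_scores = list(off_scores), margin = m$margin,
        aggregation = aggregation, target_rank = m$target_rank
      )
    }) |>
    dplyr::ungroup()
}
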