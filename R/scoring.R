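#' Distance-weighting scheme for local-to-global integration
#'
#' Interface pairs are identified at \code{identification_cutoff} (COM-COM,
#' default 12 A); their predicted energies are combined with normalized
#' exponential-decay weights of characteristic length \code{r0} (default
#' 9 A), so interactions below ~9 A dominate the score.
#'
#' @param r0 decay length, Angstrom.
#' @param identification_cutoff pair identification cutoff, Angstrom.
#' @export
weighting_scheme <- function(r0 = 9, identification_cutoff = 12) {
  if (r0 <= 0 || identification_cutoff <= 0)
    stop_domain("r0 and identification_cutoff must be > 0")
  structure(list(r0 = r0, identification_cutoff = identification_cutoff),
            class = "panther_weighting_scheme")
}

#' Normalized exponential-decay distance weights
#'
#' \code{w_i = exp(-r_i / r0) / sum_j exp(-r_j / r0)}. Weights sum to one
#' and decrease strictly with distance. Computed with a shifted exponent so
#' the small-\code{r0} limit (all weight on the closest pair) is
#' numerically stable.
#'
#' @param distances positive COM distances, Angstrom; non-empty.
#' @param scheme a [weighting_scheme()].
#' @return numeric weights summing to 1.
#' @export
compute_weights <- function(distances, scheme = weighting_scheme()) {
  if (!length(distances)) stop_domain("compute_weights needs at least one distance")
  if (any(distances <= 0)) stop_domain("distances must be > 0")
  w <- exp(-(distances - min(distances)) / scheme$r0)
  w / sum(w)
}

#' Weighted-sum complex score from per-pair energies
#'
#' \code{score = sum_i w_i E_i}, kcal/mol. Because the weights are
#' normalized this is a weighted average of the local energies and is
#' bounded by their range.
#'
#' @param energies predicted local energies, kcal/mol.
#' @param weights normalized weights from [compute_weights()].
#' @export
panther_score <- function(energies, weights) {
  if (length(energies) != length(weights))
    stop_domain("energies and weights lengths differ (%d vs %d)",
                length(energies), length(weights))
  if (!length(energies)) stop_domain("cannot score zero pairs")
  if (abs(sum(weights) - 1) > 1e-6)
    stop_domain("weights must sum to 1 (got %.8f)", sum(weights))
  sum(weights * energies)
}

#' End-to-end static-structure scoring
#'
#' Parse (if needed), identify interface pairs at the identification cutoff,
#' build feature records, predict per-pair local energies with the trained
#' model, weight them by COM distance, and sum. The result keeps full
#' per-pair provenance (record, predicted energy, weight) so an
#' interaction-map style breakdown can be reported. A complex with no pairs
#' inside the cutoff is flagged unscorable; no number is fabricated.
#'
#' @param pdb PDB text, a path, or an already parsed
#'   \code{panther_structure}.
#' @param model trained model accepted by [predict_local_energies()].
#' @param params [parameter_table()] used when parsing.
#' @param criteria [hbond_criteria()].
#' @param scheme [weighting_scheme()].
#' @param frame frame index for static scoring.
#' @return object of class \code{panther_score_result}: complex_id, pairs
#'   (records plus energy and weight columns), score, unscorable flag.
#' @export
score_complex <- function(pdb, model, params = default_parameter_table(),
                          criteria = hbond_criteria(),
                          scheme = weighting_scheme(), frame = 1) {
  x <- if (inherits(pdb, "panther_structure")) pdb
       else parse_structure(pdb, params = params)
  records <- build_records(x, cutoff = scheme$identification_cutoff,
                           criteria = criteria, frame = frame)
  if (!nrow(records)) {
    return(structure(list(complex_id = x$pdb_id, pairs = records,
                          score = NA_real_, unscorable = TRUE),
                     class = "panther_score_result"))
  }
  energies <- predict_local_energies(model, records)
  weights <- compute_weights(records$com_distance, scheme)
  records$energy <- energies
  records$weight <- weights
  structure(list(complex_id = x$pdb_id, pairs = records,
                 score = panther_score(energies, weights),
                 unscorable = FALSE),
            class = "panther_score_result")
}

#' @export
print.panther_score_result <- function(x, ...) {
  if (x$unscorable) {
    cat(sprintf("complex %s: unscorable (no interface pairs within cutoff)\n",
                x$complex_id))
  } else {
    cat(sprintf("complex %s: score %.3f kcal/mol over %d pair(s)\n",
                x$complex_id, x$score, nrow(x$pairs)))
  }
  invisible(x)
}

#' Compare complex scores against experimental binding free energies
#'
#' Joins the two tables on \code{complex_id} (unmatched ids are an error
#' listing the offenders) and reports Pearson r, MAE, Spearman r_s and the
#' correlation p-value, plus a rank table for rank-agreement inspection.
#'
#' @param scores data.frame with columns complex_id, score.
#' @param experimental data.frame with columns complex_id, dg (kcal/mol).
#' @return list with \code{metrics} (see [evaluate_predictions()]) and
#'   \code{ranks} (per-complex score/dg ranks).
#' @export
evaluate_scores <- function(scores, experimental) {
  stopifnot(is.data.frame(scores), is.data.frame(experimental))
  if (!all(c("complex_id", "score") %in% names(scores)))
    stop_domain("scores needs columns complex_id, score")
  if (!all(c("complex_id", "dg") %in% names(experimental)))
    stop_domain("experimental needs columns complex_id, dg")
  un1 <- setdiff(scores$complex_id, experimental$complex_id)
  un2 <- setdiff(experimental$complex_id, scores$complex_id)
  if (length(un1) || length(un2))
    stop_domain("unmatched complex ids: %s",
                paste(c(un1, un2), collapse = ", "))
  m <- merge(scores, experimental, by = "complex_id")
  if (nrow(m) < 3) stop_domain("need at least 3 matched complexes")
  metrics <- evaluate_predictions(m$score, m$dg)
  ranks <- data.frame(complex_id = m$complex_id,
                      score = m$score, dg = m$dg,
                      score_rank = rank(m$score), dg_rank = rank(m$dg))
  list(metrics = metrics, ranks = ranks)
}

#' Write per-complex scores as CSV
#'
#' @param results list of \code{panther_score_result} objects (or a single
#'   one).
#' @param path output file.
#' @export
write_scores_csv <- function(results, path) {
  if (inherits(results, "panther_score_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(complex_id = r$complex_id,
               n_pairs = nrow(r$pairs),
               score = r$score,
               unscorable = r$unscorable,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
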