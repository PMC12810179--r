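#' Amino-acid and nucleotide vocabularies
#'
#' Closed categorical vocabularies used by the one-hot encoding: the 20
#' standard amino acids (3-letter codes, alphabetical) and the 4
#' ribonucleotide bases.
#' @export
aa_vocabulary <- function() AA3

#' @rdname aa_vocabulary
#' @export
nt_vocabulary <- function() NT1

#' Build interaction records from a static structure
#'
#' One record per interface pair found within \code{cutoff} at the given
#' frame, carrying the feature set used by the regression models: amino-acid
#' type, base type, COM distance and hydrogen-bond count. \code{local_energy}
#' is absent (NA) in this prediction-mode path.
#'
#' @param x a \code{panther_structure}.
#' @param cutoff identification cutoff, Angstrom (default 12).
#' @param criteria [hbond_criteria()].
#' @param frame frame index.
#' @return data.frame with columns complex_id, chain_p, res_p, aa, chain_r,
#'   res_r, nt, com_distance, hbonds, local_energy.
#' @export
build_records <- function(x, cutoff = 12, criteria = hbond_criteria(),
                          frame = 1) {
  pairs <- find_pairs(x, frame = frame, cutoff = cutoff)
  hb <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs)))
    hb[k] <- count_hbonds(x, pairs$p_group[k], pairs$r_group[k],
                          criteria, frame)
  data.frame(complex_id = rep(x$pdb_id, nrow(pairs)),
             chain_p = pairs$chain_p, res_p = pairs$res_p, aa = pairs$aa,
             chain_r = pairs$chain_r, res_r = pairs$res_r, nt = pairs$nt,
             com_distance = pairs$com_distance, hbonds = hb,
             local_energy = rep(NA_real_, nrow(pairs)),
             stringsAsFactors = FALSE)
}

#' Convert a trajectory decomposition into training records
#'
#' Retained pairs only. The regression target \code{local_energy} is the
#' pair's \code{mean_local_energy}; distance and H-bond features are the
#' presence-weighted trajectory means, mirroring the energy averaging.
#'
#' @param decomp result of [decompose_trajectory()].
#' @param complex_id identifier; defaults to the decomposition's source id.
#' @return records data.frame as in [build_records()] but with targets.
#' @export
records_from_decomposition <- function(decomp,
                                       complex_id = attr(decomp, "pdb_id")) {
  df <- as.data.frame(decomp)
  df <- df[df$retained %in% TRUE, , drop = FALSE]
  data.frame(complex_id = rep(complex_id %||% "complex", nrow(df)),
             chain_p = df$chain_p, res_p = df$res_p, aa = df$aa,
             chain_r = df$chain_r, res_r = df$res_r, nt = df$nt,
             com_distance = df$mean_com_distance,
             hbonds = df$mean_hbonds,
             local_energy = df$mean_local_energy,
             stringsAsFactors = FALSE)
}

#' Fit the feature encoding on training records
#'
#' Numeric features are standardized (zero mean, unit variance) with
#' statistics frozen from the training data; zero-variance columns map to 0.
#' Categorical features are one-hot encoded over the full closed vocabulary
#' in fixed column order, so the encoding of a record never depends on the
#' batch it appears in.
#'
#' @param records training records (see [build_records()]).
#' @param numeric character vector of numeric feature columns; default
#'   \code{c("com_distance", "hbonds")}. Extra numeric columns present in the
#'   records (a feature-registry hook) may be named here.
#' @return object of class \code{panther_encoding}.
#' @export
fit_encoding <- function(records, numeric = c("com_distance", "hbonds")) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  miss <- setdiff(c(numeric, "aa", "nt"), names(records))
  if (length(miss))
    stop_domain("records lack feature column(s): %s", paste(miss, collapse = ", "))
  stats <- lapply(numeric, function(f) {
    v <- records[[f]]
    if (anyNA(v)) stop_domain("numeric feature '%s' has missing values", f)
    list(mean = mean(v), sd = stats::sd(v))
  })
  names(stats) <- numeric
  structure(list(numeric = numeric, stats = stats,
                 aa_levels = aa_vocabulary(), nt_levels = nt_vocabulary()),
            class = "panther_encoding")
}

#' Encode records into a numeric design matrix
#'
#' Deterministic and total over the closed vocabularies: numeric columns are
#' standardized by the frozen training statistics (zero-variance columns
#' become 0), then amino-acid and base one-hot blocks follow in fixed order.
#' Unseen categories raise an error naming the offending value.
#'
#' @param records records data.frame.
#' @param encoding a \code{panther_encoding} from [fit_encoding()].
#' @return numeric matrix, one row per record.
#' @export
encode_records <- function(records, encoding) {
  stopifnot(inherits(encoding, "panther_encoding"))
  n <- nrow(records)
  num <- lapply(encoding$numeric, function(f) {
    st <- encoding$stats[[f]]
    v <- records[[f]]
    if (is.null(v)) stop_domain("records lack numeric feature '%s'", f)
    if (is.na(st$sd) || st$sd == 0) rep(0, n) else (v - st$mean) / st$sd
  })
  num <- do.call(cbind, num)
  colnames(num) <- encoding$numeric

  onehot <- function(v, levels, prefix) {
    bad <- setdiff(unique(v), levels)
    if (length(bad))
      stop_domain("unknown %s value(s): %s", prefix, paste(bad, collapse = ", "))
    m <- matrix(0, n, length(levels),
                dimnames = list(NULL, paste0(prefix, "_", levels)))
    m[cbind(seq_len(n), match(v, levels))] <- 1
    m
  }
  cbind(num,
        onehot(records$aa, encoding$aa_levels, "aa"),
        onehot(records$nt, encoding$nt_levels, "nt"))
}

#' Read / write the interaction-record CSV dialect
#'
#' The lingua franca between modules: columns complex_id, aa, nt,
#' com_distance, hbonds, local_energy (empty when absent); extra columns such
#' as residue identifiers are preserved.
#'
#' @param path file path.
#' @export
read_records_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_records_csv
#' @param records records data.frame.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
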