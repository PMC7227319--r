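#' Names of the 340 k-mer sequence features
#'
#' All DNA words of length 1 to 4 in lexicographic order within each
#' length block (4 + 16 + 64 + 256 = 340).
#'
#' @return character vector of length 340.
#' @export
kmer_feature_names <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(1:4, function(k) {
    grid <- do.call(expand.grid,
                    c(rev(replicate(k, bases, simplify = FALSE)),
                      list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
    # expand.grid varies the first factor fastest; reversed columns give
    # lexicographic order
    apply(as.matrix(grid[, rev(seq_len(k)), drop = FALSE]), 1, paste, collapse = "")
  }), use.names = FALSE)
}

#' k-mer occurrence frequencies of a flanking sequence
#'
#' For each k in 1..4, every sliding window of length k is counted and
#' each count is divided by the total number of valid k-mers of that
#' length in the sequence (windows containing `N` are skipped). Blocks
#' with no valid window are all zero.
#'
#' @param flank_sequence nucleotide string over `{A,C,G,T,N}`.
#' @return named numeric vector of length 340 (see [kmer_feature_names()]).
#' @export
kmer_features <- function(flank_sequence) {
  nm <- kmer_feature_names()
  out <- stats::setNames(numeric(length(nm)), nm)
  s <- toupper(as.character(flank_sequence))
  if (is.na(s) || nchar(s) == 0) {
    warning("empty flanking sequence: all-zero k-mer feature vector")
    return(out)
  }
  dna <- Biostrings::DNAString(s)
  for (k in 1:4) {
    counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
    total <- sum(counts)
    if (total > 0) out[names(counts)] <- counts / total
  }
  out
}

#' Pearson correlation between two beta vectors across samples
#'
#' Computed over pairwise-complete samples only. Pairs with fewer than
#' `min_samples` complete observations, or with zero variance in either
#' vector, are undefined (`NA`) and thus excluded from downstream argmax
#' selection.
#'
#' @param a,b numeric beta vectors aligned on the same sample order.
#' @param min_samples minimum complete pairs required (default 30).
#' @return list with `r` (correlation or `NA`) and `n_used`.
#' @export
pearson_methylation <- function(a, b, min_samples = 30) {
  if (length(a) != length(b)) stop("beta vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < min_samples || n < 2)
    return(list(r = NA_real_, n_used = n))
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    return(list(r = NA_real_, n_used = n))
  list(r = stats::cor(a[ok], b[ok]), n_used = n)
}

#' Pearson correlation between two k-mer feature vectors
#'
#' @param s1,s2 numeric vectors of length 340.
#' @return correlation in \[-1, 1\], or `NA` when either vector has zero
#'   variance.
#' @export
pearson_sequence <- function(s1, s2) {
  if (length(s1) != 340 || length(s2) != 340)
    stop("sequence feature vectors must have length 340")
  if (stats::sd(s1) == 0 || stats::sd(s2) == 0) return(NA_real_)
  stats::cor(s1, s2)
}

# Genomic distance from one probe to a set of probes; Inf across
# chromosomes or for probes absent from the manifest.
.probe_distances <- function(model_probe, candidates, manifest) {
  idx <- match(model_probe, manifest$probe_id)
  if (is.na(idx)) return(rep(Inf, length(candidates)))
  cidx <- match(candidates, manifest$probe_id)
  d <- rep(Inf, length(candidates))
  known <- !is.na(cidx)
  same <- known & manifest$chr[cidx] == manifest$chr[idx]
  d[same] <- abs(manifest$pos[cidx[same]] - manifest$pos[idx])
  d
}

# Deterministic argmax over candidate scores: highest score, ties broken
# by smallest genomic distance (when a manifest is given), then smallest
# probe ID.
.argmax_candidate <- function(candidates, scores, model_probe, manifest = NULL) {
  ok <- !is.na(scores)
  if (!any(ok)) return(NULL)
  candidates <- candidates[ok]
  scores <- scores[ok]
  best <- scores == max(scores)
  cand <- candidates[best]
  if (length(cand) > 1 && !is.null(manifest)) {
    d <- .probe_distances(model_probe, cand, manifest)
    cand <- cand[d == min(d)]
  }
  pick <- sort(cand)[1]
  list(probe_id = pick, score = scores[match(pick, candidates)])
}

#' Nearest neighbouring feature locus on the same chromosome
#'
#' @param model_probe model probe ID.
#' @param manifest probe manifest.
#' @param feature_loci character vector of feature probe IDs.
#' @param max_distance maximum allowed distance in bp (default unlimited).
#' @return list with `probe_id` and `distance`, or `NULL` when no feature
#'   locus qualifies.
#' @export
nearest_neighbour <- function(model_probe, manifest, feature_loci,
                              max_distance = Inf) {
  idx <- match(model_probe, manifest$probe_id)
  if (is.na(idx)) stop("model probe not in manifest: ", model_probe)
  cand <- setdiff(intersect(feature_loci, manifest$probe_id), model_probe)
  if (length(cand) == 0) return(NULL)
  d <- .probe_distances(model_probe, cand, manifest)
  keep <- is.finite(d) & d <= max_distance
  if (!any(keep)) return(NULL)
  cand <- cand[keep]
  d <- d[keep]
  best <- d == min(d)
  pick <- sort(cand[best])[1]
  list(probe_id = pick, distance = d[match(pick, cand)])
}

# Correlations of one beta vector against many probe rows, with
# pairwise-complete counts. `block_size` chunks the scan; results are
# identical to the unchunked scan.
.cor_against_rows <- function(y, features, block_size = NULL) {
  n_feat <- nrow(features)
  r <- numeric(n_feat)
  n <- integer(n_feat)
  if (is.null(block_size)) block_size <- n_feat
  starts <- seq(1L, n_feat, by = block_size)
  ok_y <- !is.na(y)
  for (s in starts) {
    rows <- s:min(s + block_size - 1L, n_feat)
    block <- features[rows, , drop = FALSE]
    r[rows] <- suppressWarnings(as.vector(stats::cor(y, t(block),
                                                     use = "pairwise.complete.obs")))
    n[rows] <- as.integer((!is.na(block)) %*% ok_y)
  }
  list(r = r, n = n)
}

#' Select the co-methylated feature locus for a model locus
#'
#' The feature locus whose cross-sample beta vector has the maximal
#' Pearson correlation with the model locus, over pairwise-complete
#' samples. Pairs with fewer than `min_samples` complete observations or
#' zero variance are ineligible. Ties are broken by smallest genomic
#' distance (when a manifest is supplied), then smallest probe ID.
#'
#' @param model_probe model probe ID (must be a row of `training`).
#' @param training beta matrix of training samples.
#' @param feature_loci character vector of candidate feature probe IDs.
#' @param min_samples minimum complete pairs (default 30).
#' @param manifest optional manifest for the distance tie-break.
#' @param block_size optional chunk size for the correlation scan; any
#'   value yields results identical to the full scan.
#' @return list with `probe_id`, `score` and `n_used`, or `NULL` when no
#'   feature locus is eligible (model locus unmodelable).
#' @export
select_comethylated <- function(model_probe, training, feature_loci,
                                min_samples = 30, manifest = NULL,
                                block_size = NULL) {
  if (!model_probe %in% rownames(training))
    stop("model probe not in training matrix: ", model_probe)
  cand <- setdiff(intersect(feature_loci, rownames(training)), model_probe)
  if (length(cand) == 0) return(NULL)
  y <- training[model_probe, ]
  cc <- .cor_against_rows(y, training[cand, , drop = FALSE], block_size)
  scores <- cc$r
  scores[cc$n < min_samples] <- NA_real_
  hit <- .argmax_candidate(cand, scores, model_probe, manifest)
  if (is.null(hit)) return(NULL)
  hit$n_used <- cc$n[match(hit$probe_id, cand)]
  hit
}

#' Select the feature locus with the most similar flanking sequence
#'
#' Argmax of the Pearson correlation between 340-component k-mer
#' frequency vectors. Ties are broken by smallest genomic distance (when
#' a manifest is supplied), then smallest probe ID.
#'
#' @param model_probe model probe ID (must be a row of `seq_features`).
#' @param seq_features numeric matrix, probes x 340 k-mer frequencies.
#' @param feature_loci candidate feature probe IDs.
#' @param manifest optional manifest for the distance tie-break.
#' @return list with `probe_id` and `score`, or `NULL` when no candidate
#'   has a defined correlation.
#' @export
select_sequence_match <- function(model_probe, seq_features, feature_loci,
                                  manifest = NULL) {
  if (!model_probe %in% rownames(seq_features))
    stop("model probe has no sequence feature vector: ", model_probe)
  cand <- setdiff(intersect(feature_loci, rownames(seq_features)), model_probe)
  if (length(cand) == 0) return(NULL)
  v <- seq_features[model_probe, ]
  if (stats::sd(v) == 0) return(NULL)
  scores <- suppressWarnings(as.vector(stats::cor(v, t(seq_features[cand, , drop = FALSE]))))
  .argmax_candidate(cand, scores, model_probe, manifest)
}

#' Compute k-mer feature vectors for a set of probes
#'
#' @param probes probe IDs to featurize.
#' @param manifest probe manifest (chromosome and position lookup).
#' @param seqs genome sequences (named `DNAStringSet` or character).
#' @param flank flank size in bp (default 200).
#' @return numeric matrix, probes x 340.
#' @export
sequence_feature_table <- function(probes, manifest, seqs, flank = 200) {
  idx <- match(probes, manifest$probe_id)
  if (any(is.na(idx)))
    stop("probe(s) absent from manifest: ",
         paste(probes[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
  out <- matrix(0, nrow = length(probes), ncol = 340,
                dimnames = list(probes, kmer_feature_names()))
  for (i in seq_along(probes)) {
    fl <- fetch_flank(seqs, manifest$chr[idx[i]], manifest$pos[idx[i]], flank)
    out[i, ] <- kmer_features(fl)
  }
  out
}

#' Build the per-model-locus feature assignment table
#'
#' For every model locus, selects the co-methylated feature locus
#' (required; loci without an eligible partner go to the exclusion list),
#' the nearest neighbouring feature locus, and — when sequences are
#' supplied — the feature locus with the most similar flanking sequence.
#' Features are defined on the training samples only.
#'
#' @param manifest probe manifest.
#' @param training beta matrix of training samples.
#' @param model_loci,feature_loci probe ID vectors from [partition_loci()].
#' @param seqs optional genome sequences; enables the sequence feature.
#' @param min_samples minimum complete pairs for co-methylation (default 30).
#' @param nn_max_distance distance cap for the nearest neighbour (default
#'   unlimited).
#' @param flank flank size for sequence features (default 200).
#' @param block_size optional chunk size for the correlation scans.
#' @return list with `assignments` (data.frame: `model_probe`,
#'   `cometh_probe`, `cometh_r`, `n_samples`, `nn_probe`, `nn_distance`,
#'   `seq_probe`, `seq_r`) and `excluded` (data.frame: `model_probe`,
#'   `reason`).
#' @export
build_assignments <- function(manifest, training, model_loci, feature_loci,
                              seqs = NULL, min_samples = 30,
                              nn_max_distance = Inf, flank = 200,
                              block_size = NULL) {
  validate_manifest(manifest)
  validate_beta_matrix(training)
  model_loci <- intersect(model_loci, rownames(training))
  feature_loci <- intersect(feature_loci, rownames(training))
  seq_feats <- NULL
  if (!is.null(seqs)) {
    seq_feats <- sequence_feature_table(union(model_loci, feature_loci),
                                        manifest, seqs, flank)
  }
  rows <- vector("list", length(model_loci))
  excl <- list()
  for (i in seq_along(model_loci)) {
    mp <- model_loci[i]
    cm <- select_comethylated(mp, training, feature_loci,
                              min_samples = min_samples, manifest = manifest,
                              block_size = block_size)
    if (is.null(cm)) {
      excl[[length(excl) + 1L]] <- data.frame(
        model_probe = mp, reason = "no_eligible_comethylated_locus",
        stringsAsFactors = FALSE)
      next
    }
    nn <- nearest_neighbour(mp, manifest, feature_loci,
                            max_distance = nn_max_distance)
    sq <- if (!is.null(seq_feats))
      select_sequence_match(mp, seq_feats, feature_loci, manifest = manifest)
    else NULL
    rows[[i]] <- data.frame(
      model_probe = mp,
      cometh_probe = cm$probe_id, cometh_r = cm$score, n_samples = cm$n_used,
      nn_probe = if (is.null(nn)) NA_character_ else nn$probe_id,
      nn_distance = if (is.null(nn)) NA_real_ else nn$distance,
      seq_probe = if (is.null(sq)) NA_character_ else sq$probe_id,
      seq_r = if (is.null(sq)) NA_real_ else sq$score,
      stringsAsFactors = FALSE
    )
  }
  assignments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(assignments))
    assignments <- data.frame(model_probe = character(0),
                              cometh_probe = character(0), cometh_r = numeric(0),
                              n_samples = integer(0), nn_probe = character(0),
                              nn_distance = numeric(0), seq_probe = character(0),
                              seq_r = numeric(0), stringsAsFactors = FALSE)
  excluded <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(model_probe = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  list(assignments = assignments, excluded = excluded)
}

#' Write / read a feature assignment table
#'
#' Tab-delimited with columns `model_probe`, `cometh_probe`, `cometh_r`,
#' `n_samples`, `nn_probe`, `nn_distance`, `seq_probe`, `seq_r`.
#'
#' @param assignments assignment data.frame.
#' @param path file path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = c(model_probe = "character",
                                   cometh_probe = "character",
                                   cometh_r = "numeric", n_samples = "integer",
                                   nn_probe = "character",
                                   nn_distance = "numeric",
                                   seq_probe = "character", seq_r = "numeric"))
}
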