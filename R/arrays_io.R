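#' Validate a beta-value matrix
#'
#' A beta matrix is a base numeric matrix with probes in rows and samples
#' in columns, unique dimnames, and every non-missing value in \[0, 1\].
#'
#' @param m numeric matrix, probes x samples.
#' @return `m`, invisibly, after validation.
#' @export
validate_beta_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("beta matrix must be a numeric matrix (probes x samples)")
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    stop("beta matrix must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate probe IDs: ", paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample IDs: ", paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value %g out of [0,1] for probe %s, sample %s",
                 m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  invisible(m)
}

.guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta-value matrix from delimited text
#'
#' Expects a header row of sample IDs, a first column of probe IDs and one
#' row per probe. Empty fields, `"NA"` and `"NaN"` become missing values;
#' any value outside \[0, 1\] is an error naming the offending probe and
#' sample.
#'
#' @param path file path.
#' @param sep field delimiter; default is guessed from the extension
#'   (`","` for `.csv`, otherwise tab).
#' @return numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 1) stop("beta matrix file has no columns: ", path)
  probe_ids <- trimws(df[[1]])
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ID in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  sample_ids <- colnames(df)[-1]
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_ids),
              dimnames = list(probe_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- trimws(df[[j + 1L]])
    miss <- is.na(col) | col %in% c("", "NA", "NaN", "nan")
    v <- suppressWarnings(as.numeric(col))
    bad <- !miss & is.na(v)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("non-numeric beta value '%s' for probe %s, sample %s in %s",
                   col[i], probe_ids[i], sample_ids[j], path))
    }
    v[miss] <- NA_real_
    m[, j] <- v
  }
  validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix to delimited text
#'
#' Deterministic row/column order (as stored); missing entries written as
#' `"NA"`; first column named `probe_id`.
#'
#' @param m numeric beta matrix.
#' @param path output file path.
#' @param sep field delimiter; default guessed from the extension.
#' @export
write_beta_matrix <- function(m, path, sep = NULL) {
  validate_beta_matrix(m)
  if (is.null(sep)) sep <- .guess_sep(path)
  # %.17g keeps doubles exact under round-trip and output byte-stable
  fmt <- matrix(ifelse(is.na(m), "NA", sprintf("%.17g", m)),
                nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(m)), collapse = sep), con)
  if (nrow(m) > 0) {
    writeLines(paste(rownames(m), apply(fmt, 1, paste, collapse = sep),
                     sep = if (ncol(m) > 0) sep else ""), con)
  }
  invisible(path)
}

.normalize_cgi <- function(x) {
  x_chr <- as.character(x)
  key <- tolower(gsub("[_ '-]", "", x_chr))
  out <- rep(NA_character_, length(key))
  out[key %in% "island"] <- "island"
  out[key %in% c("shore", "nshore", "sshore")] <- "shore"
  out[key %in% c("shelf", "nshelf", "sshelf")] <- "shelf"
  out[key %in% c("opensea", "") | is.na(x_chr)] <- "open sea"
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sum(unknown), " unknown CGI relation token(s) (e.g. '",
            x_chr[which(unknown)[1]], "') mapped to 'open sea'")
    out[unknown] <- "open sea"
  }
  out
}

#' Read a probe manifest
#'
#' CSV with columns `probe_id`, `chr`, `pos` (1-based CpG coordinate),
#' `on450k` (0/1), `onEPIC` (0/1), `gene_annotation`
#' (`"GENE;CATEGORY|GENE;CATEGORY"`, possibly empty) and `cgi_relation`.
#' Illumina-style CGI tokens (`N_Shore`, `S_Shelf`, `OpenSea`, blank) are
#' normalized to island / shore / shelf / open sea; unknown tokens map to
#' open sea with a warning.
#'
#' @param path file path.
#' @param sep field delimiter, default `","`.
#' @return data.frame with the columns above (flags as logical, CGI
#'   relation normalized).
#' @export
read_manifest <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", colClasses = "character")
  required <- c("probe_id", "chr", "pos", "on450k", "onEPIC",
                "gene_annotation", "cgi_relation")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0)
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    probe_id = trimws(df$probe_id),
    chr = trimws(df$chr),
    pos = as.integer(df$pos),
    on450k = as.integer(df$on450k) != 0L,
    onEPIC = as.integer(df$onEPIC) != 0L,
    gene_annotation = ifelse(is.na(df$gene_annotation), "", trimws(df$gene_annotation)),
    cgi_relation = .normalize_cgi(df$cgi_relation),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$probe_id))
    stop("duplicate probe ID in manifest: ",
         paste(unique(out$probe_id[duplicated(out$probe_id)]), collapse = ", "))
  if (any(is.na(out$pos)) || any(out$pos < 1))
    stop("manifest positions must be integers >= 1")
  validate_manifest(out)
  out
}

#' Validate a probe manifest data.frame
#' @param manifest data.frame as returned by [read_manifest()].
#' @return `manifest`, invisibly.
#' @export
validate_manifest <- function(manifest) {
  required <- c("probe_id", "chr", "pos", "on450k", "onEPIC",
                "gene_annotation", "cgi_relation")
  missing_cols <- setdiff(required, colnames(manifest))
  if (length(missing_cols) > 0)
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(manifest$probe_id)) stop("duplicate probe IDs in manifest")
  if (any(manifest$pos < 1)) stop("manifest positions must be >= 1")
  bad <- setdiff(unique(manifest$cgi_relation), CGI_RELATIONS)
  if (length(bad) > 0)
    stop("manifest cgi_relation outside {",
         paste(CGI_RELATIONS, collapse = ", "), "}: ", paste(bad, collapse = ", "))
  invisible(manifest)
}

#' Partition probes into model and feature loci
#'
#' Model loci are covered by EPIC but not 450K; feature loci are covered
#' by both platforms. Probes covered by neither platform are excluded
#' with a warning.
#'
#' @param manifest probe manifest data.frame.
#' @return list with character vectors `model_loci` and `feature_loci`.
#' @export
partition_loci <- function(manifest) {
  validate_manifest(manifest)
  neither <- !manifest$on450k & !manifest$onEPIC
  if (any(neither))
    warning(sum(neither), " probe(s) covered by neither platform excluded")
  list(
    model_loci = manifest$probe_id[manifest$onEPIC & !manifest$on450k],
    feature_loci = manifest$probe_id[manifest$onEPIC & manifest$on450k]
  )
}

#' Quantile-normalize a beta matrix across samples
#'
#' Each sample's values are mapped onto the across-sample mean quantile
#' curve, so that for complete data every column shares the same multiset
#' of values while within-sample ranks are preserved. Missing entries are
#' left missing; the non-missing values of each sample are normalized
#' against the reference curve by quantile interpolation, and tied input
#' values receive the mean reference quantile of their tied ranks.
#'
#' @param m numeric beta matrix with at least 2 samples.
#' @return quantile-normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(m) {
  validate_beta_matrix(m)
  if (ncol(m) < 2) stop("quantile normalization requires >= 2 samples")
  n_ok <- colSums(!is.na(m))
  if (any(n_ok == 0))
    stop("sample(s) with zero non-missing values: ",
         paste(colnames(m)[n_ok == 0], collapse = ", "))
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  # means of values in [0,1] stay in [0,1]; guard against tiny drift
  out[!is.na(out) & out < 0] <- 0
  out[!is.na(out) & out > 1] <- 1
  out
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file path.
#' @return a [Biostrings::DNAStringSet] named by the first whitespace-
#'   delimited token of each FASTA header.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names in ", path)
  seqs
}

#' Extract the flanking window around a CpG locus
#'
#' The CpG dinucleotide occupies positions `[position, position + 1]`;
#' the returned window is `[position - flank, position + flank + 1]`
#' (1-based, inclusive), clipped at the chromosome ends without padding,
#' and uppercased.
#'
#' @param seqs named `DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @param chromosome chromosome name.
#' @param position 1-based coordinate of the CpG cytosine.
#' @param flank bases to include on each side (default 200).
#' @return nucleotide string.
#' @export
fetch_flank <- function(seqs, chromosome, position, flank = 200) {
  if (!chromosome %in% names(seqs))
    stop("unknown chromosome: ", chromosome)
  s <- seqs[[chromosome]]
  len <- if (is.character(s)) nchar(s) else length(s)
  if (position < 1 || position > len)
    stop(sprintf("position %d outside chromosome %s (length %d)",
                 position, chromosome, len))
  start <- max(1L, as.integer(position) - as.integer(flank))
  end <- min(len, as.integer(position) + as.integer(flank) + 1L)
  if (is.character(s)) {
    toupper(substr(s, start, end))
  } else {
    toupper(as.character(Biostrings::subseq(s, start, end)))
  }
}
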