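#' Parse a manifest gene annotation string
#'
#' `"GENE;CATEGORY|GENE;CATEGORY"` into a data.frame of (gene, category)
#' pairs. Category spellings are normalized (`"1st Exon"` to `"1stExon"`,
#' `"5UTR"` to `"5'UTR"`, etc.); an unknown category token is an error.
#'
#' @param annotation annotation string (may be empty or `NA`).
#' @return data.frame with columns `gene`, `category` (zero rows when
#'   unannotated).
#' @export
parse_gene_annotation <- function(annotation) {
  empty <- data.frame(gene = character(0), category = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(annotation) || !nzchar(trimws(annotation))) return(empty)
  pairs <- strsplit(trimws(annotation), "|", fixed = TRUE)[[1]]
  parts <- strsplit(pairs, ";", fixed = TRUE)
  genes <- vapply(parts, function(p) trimws(p[1]), character(1))
  cats <- vapply(parts, function(p) if (length(p) > 1) trimws(p[2]) else "",
                 character(1))
  key <- tolower(gsub("[ '_-]", "", cats))
  lookup <- c(tss200 = "TSS200", tss1500 = "TSS1500",
              "5utr" = "5'UTR", "1stexon" = "1stExon", firstexon = "1stExon",
              body = "Body", genebody = "Body", "3utr" = "3'UTR")
  norm <- unname(lookup[key])
  if (anyNA(norm))
    stop("unknown gene region category token: ",
         paste(unique(cats[is.na(norm)]), collapse = ", "))
  data.frame(gene = genes, category = norm, stringsAsFactors = FALSE)
}

#' Annotate probes with a prioritized genomic region category
#'
#' Among all (gene, category) pairs of a probe the highest-priority
#' category wins, following the 5'-to-3' order TSS200 > TSS1500 > 5'UTR >
#' 1stExon > Body > 3'UTR > Intergenic; probes with no gene annotation
#' are Intergenic. The CGI relation is copied through.
#'
#' @param probe_ids probe IDs (must be present in the manifest).
#' @param manifest probe manifest.
#' @return data.frame with columns `probe_id`, `region_category`,
#'   `cgi_relation` and `genes` (comma-joined gene symbols, `""` for
#'   intergenic probes).
#' @export
annotate_region <- function(probe_ids, manifest) {
  idx <- match(probe_ids, manifest$probe_id)
  if (anyNA(idx))
    stop("probe(s) absent from manifest: ",
         paste(probe_ids[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
  region <- character(length(probe_ids))
  genes <- character(length(probe_ids))
  for (i in seq_along(probe_ids)) {
    pairs <- parse_gene_annotation(manifest$gene_annotation[idx[i]])
    if (nrow(pairs) == 0) {
      region[i] <- "Intergenic"
      genes[i] <- ""
    } else {
      pr <- match(pairs$category, REGION_CATEGORIES)
      region[i] <- REGION_CATEGORIES[min(pr)]
      genes[i] <- paste(unique(pairs$gene), collapse = ",")
    }
  }
  data.frame(probe_id = probe_ids, region_category = region,
             cgi_relation = manifest$cgi_relation[idx], genes = genes,
             stringsAsFactors = FALSE)
}

#' Welch's unequal-variance t-test for one probe
#'
#' Two-sided t-statistic, Welch-Satterthwaite degrees of freedom and
#' p-value for the difference in mean beta value between two groups.
#' Undefined (all-`NA` result with a reason) when either group has fewer
#' than 2 non-missing values or both groups have zero variance.
#'
#' @param group1,group2 numeric beta values (missing entries dropped).
#' @return list with `t`, `df`, `p` and `reason` (`NA` when defined).
#' @export
welch_t <- function(group1, group2) {
  g1 <- group1[!is.na(group1)]
  g2 <- group2[!is.na(group2)]
  if (length(g1) < 2 || length(g2) < 2)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                reason = "too_few_samples"))
  if (stats::sd(g1) == 0 && stats::sd(g2) == 0)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                reason = "zero_variance"))
  ht <- stats::t.test(g1, g2, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), reason = NA_character_)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Missing p-values are passed through as missing and excluded from the
#' family size m; adjusted values are clipped at 1 and preserve the
#' p-value ordering.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Call differentially methylated loci between two sample groups
#'
#' Per probe: Welch's t-test on the non-missing beta values of each
#' group; Benjamini-Hochberg correction across all tested probes; a
#' probe is a DML iff `q < q_threshold` and `|delta_beta| >
#' delta_threshold`, where `delta_beta` is the group1 minus group2 mean
#' difference. Direction is `"hyper"` when group1 (by convention the
#' tumor group) is more methylated, `"hypo"` otherwise.
#'
#' @param predictions beta matrix (probes x samples), e.g. the expanded
#'   matrix from [predictions_to_matrix()].
#' @param group_labels character/factor of group memberships named by
#'   sample ID (exactly two groups), or aligned with `colnames`.
#' @param delta_threshold minimum absolute mean difference (default 0.1).
#' @param q_threshold BH q-value cutoff (default 0.05).
#' @param group1 label to treat as group1 (default: first factor level /
#'   first label in sorted order).
#' @return data.frame with columns `probe_id`, `n1`, `n2`, `mean_g1`,
#'   `mean_g2`, `delta_beta`, `t`, `df`, `p`, `q`, `is_dml`, `direction`;
#'   probes skipped for insufficient data are counted in attribute
#'   `"n_skipped"`.
#' @export
call_dml <- function(predictions, group_labels, delta_threshold = 0.1,
                     q_threshold = 0.05, group1 = NULL) {
  validate_beta_matrix(predictions)
  labels <- as.character(group_labels)
  if (!is.null(names(group_labels))) {
    if (!all(colnames(predictions) %in% names(group_labels)))
      stop("group_labels must cover every sample")
    labels <- unname(labels[match(colnames(predictions), names(group_labels))])
  } else if (length(labels) != ncol(predictions)) {
    stop("group_labels must be named by sample or aligned with columns")
  }
  lev <- if (is.factor(group_labels)) levels(group_labels) else sort(unique(labels))
  if (length(lev) != 2) stop("exactly two sample groups required")
  if (is.null(group1)) group1 <- lev[1]
  if (!group1 %in% lev) stop("group1 label not present: ", group1)
  group2 <- setdiff(lev, group1)
  in1 <- labels == group1
  in2 <- labels == group2
  if (!any(in1) || !any(in2)) stop("both groups must be non-empty")

  probes <- rownames(predictions)
  n <- length(probes)
  res <- data.frame(probe_id = probes, n1 = NA_integer_, n2 = NA_integer_,
                    mean_g1 = NA_real_, mean_g2 = NA_real_,
                    delta_beta = NA_real_, t = NA_real_, df = NA_real_,
                    p = NA_real_, q = NA_real_, is_dml = FALSE,
                    direction = NA_character_, stringsAsFactors = FALSE)
  skipped <- 0L
  for (i in seq_len(n)) {
    g1 <- predictions[i, in1]
    g2 <- predictions[i, in2]
    res$n1[i] <- sum(!is.na(g1))
    res$n2[i] <- sum(!is.na(g2))
    wt <- welch_t(g1, g2)
    if (!is.na(wt$reason)) { skipped <- skipped + 1L; next }
    res$mean_g1[i] <- mean(g1, na.rm = TRUE)
    res$mean_g2[i] <- mean(g2, na.rm = TRUE)
    res$delta_beta[i] <- res$mean_g1[i] - res$mean_g2[i]
    res$t[i] <- wt$t
    res$df[i] <- wt$df
    res$p[i] <- wt$p
  }
  res$q <- bh_adjust(res$p)
  res$is_dml <- !is.na(res$q) & res$q < q_threshold &
    abs(res$delta_beta) > delta_threshold
  res$direction[res$is_dml] <- ifelse(res$delta_beta[res$is_dml] > 0,
                                      "hyper", "hypo")
  attr(res, "n_skipped") <- skipped
  attr(res, "groups") <- c(group1 = group1, group2 = group2)
  res
}

#' Roll DMLs up to differentially methylated genes
#'
#' A gene is a DMG iff at least one DML probe carries a (gene, category)
#' pair with a promoter category (TSS200, TSS1500, 5'UTR or 1stExon) for
#' that gene. Promoter membership is judged on the raw per-gene pairs,
#' not the single prioritized category, since prioritization collapses
#' multi-gene information.
#'
#' @param dmls data.frame from [call_dml()].
#' @param manifest probe manifest.
#' @return data.frame with columns `gene`, `n_supporting_dmls`, `probes`
#'   and `directions` (semicolon-joined), sorted by gene.
#' @export
call_dmg <- function(dmls, manifest) {
  hits <- dmls[dmls$is_dml, , drop = FALSE]
  empty <- data.frame(gene = character(0), n_supporting_dmls = integer(0),
                      probes = character(0), directions = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  idx <- match(hits$probe_id, manifest$probe_id)
  if (anyNA(idx))
    stop("DML probe(s) absent from manifest: ",
         paste(hits$probe_id[is.na(idx)][1], collapse = ", "))
  recs <- list()
  for (i in seq_len(nrow(hits))) {
    pairs <- parse_gene_annotation(manifest$gene_annotation[idx[i]])
    pairs <- pairs[pairs$category %in% PROMOTER_CATEGORIES, , drop = FALSE]
    for (g in unique(pairs$gene)) {
      recs[[length(recs) + 1L]] <- data.frame(
        gene = g, probe = hits$probe_id[i], direction = hits$direction[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) return(empty)
  long <- do.call(rbind, recs)
  out <- do.call(rbind, lapply(split(long, long$gene), function(d) {
    data.frame(gene = d$gene[1], n_supporting_dmls = nrow(d),
               probes = paste(d$probe, collapse = ";"),
               directions = paste(d$direction, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize DML proportions by region and CGI relation
#'
#' @param dmls data.frame from [call_dml()].
#' @param annotations data.frame from [annotate_region()]; DML probes
#'   missing from it are counted as Intergenic / open sea with a warning.
#' @return list of two data.frames (`region`, `cgi`) with columns
#'   `category`, `n`, `proportion`; proportions sum to 1 per axis.
#' @export
summarize_dml_regions <- function(dmls, annotations) {
  hits <- dmls$probe_id[dmls$is_dml]
  if (length(hits) == 0) stop("no DMLs to summarize")
  idx <- match(hits, annotations$probe_id)
  region <- annotations$region_category[idx]
  cgi <- annotations$cgi_relation[idx]
  if (anyNA(idx)) {
    warning(sum(is.na(idx)),
            " unannotated DML probe(s) counted as Intergenic / open sea")
    region[is.na(idx)] <- "Intergenic"
    cgi[is.na(idx)] <- "open sea"
  }
  tab <- function(x, levels) {
    counts <- table(factor(x, levels = levels))
    data.frame(category = names(counts), n = as.integer(counts),
               proportion = as.numeric(counts) / length(x),
               stringsAsFactors = FALSE)
  }
  list(region = tab(region, c(REGION_CATEGORIES, "Intergenic")),
       cgi = tab(cgi, CGI_RELATIONS))
}
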