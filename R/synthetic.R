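#' Specification for a synthetic methylation fixture
#'
#' Defines a self-contained simulated study: feature-locus beta values
#' drawn from a bimodal mixture (0.4 Beta(0.5, 8) + 0.4 Beta(8, 0.5) +
#' 0.2 Beta(2, 2), reflecting the bimodality of real array betas), model
#' loci generated through planted sigmoid links to a partner feature
#' locus plus Gaussian noise on the beta scale (clipped to \[0, 1\]),
#' per-locus noise sd cycling through `noise_tiers`, uniform missingness,
#' and an optional two-group mean shift for differential analysis. Link
#' slopes are drawn from `link_w_range` with intercept `-w/2`, keeping
#' locus means in the interior of the beta scale so that the planted
#' noise sd is the realized prediction error scale.
#'
#' @param n_model_loci number of model loci (default 60).
#' @param n_feature_loci number of feature loci (default 240; must be at
#'   least `n_model_loci` so planted partners are distinct).
#' @param n_samples number of samples (default 120).
#' @param noise_tiers per-locus noise standard deviations, assigned
#'   round-robin (default `c(0.02, 0.07, 0.12, 0.2)`).
#' @param missing_rate uniform missingness probability in \[0, 1)
#'   (default 0).
#' @param group_effect list with `n_loci` (loci carrying a group mean
#'   shift), `delta` (shift size) and `sd` (within-group noise sd); used
#'   by [generate_grouped_fixture()].
#' @param n_group_samples samples per group for grouped fixtures
#'   (default `c(20, 20)`).
#' @param link_w_range range of planted sigmoid slopes (default
#'   `c(1.5, 3)`).
#' @param seq_mutation_rate per-base mutation rate applied when copying a
#'   partner's flanking window to its model locus (default 0.05).
#' @param seed RNG seed driving all randomness (default 1).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_model_loci = 60, n_feature_loci = 240,
                            n_samples = 120,
                            noise_tiers = c(0.02, 0.07, 0.12, 0.2),
                            missing_rate = 0,
                            group_effect = list(n_loci = 0, delta = 0,
                                                sd = 0.05),
                            n_group_samples = c(20, 20),
                            link_w_range = c(1.5, 3),
                            seq_mutation_rate = 0.05, seed = 1) {
  if (n_model_loci > n_feature_loci)
    stop("infeasible spec: more planted links than feature loci")
  if (any(noise_tiers < 0)) stop("noise sd must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (group_effect$n_loci > n_model_loci)
    stop("infeasible spec: more group-effect loci than loci")
  spec <- list(n_model_loci = as.integer(n_model_loci),
               n_feature_loci = as.integer(n_feature_loci),
               n_samples = as.integer(n_samples),
               noise_tiers = noise_tiers, missing_rate = missing_rate,
               group_effect = group_effect,
               n_group_samples = as.integer(n_group_samples),
               link_w_range = link_w_range,
               seq_mutation_rate = seq_mutation_rate,
               seed = as.integer(seed))
  class(spec) <- "simulation_spec"
  spec
}

# Bimodal marginal distribution of feature-locus beta values.
.rbeta_mixture <- function(n) {
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  v <- numeric(n)
  v[comp == 1] <- stats::rbeta(sum(comp == 1), 0.5, 8)
  v[comp == 2] <- stats::rbeta(sum(comp == 2), 8, 0.5)
  v[comp == 3] <- stats::rbeta(sum(comp == 3), 2, 2)
  v
}

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.mutate_dna <- function(s, rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate a self-contained methylation fixture
#'
#' Produces a beta matrix (feature rows then model rows), a probe
#' manifest with controllable model-to-partner distances (a quarter of
#' model loci adjacent to their partner, most over 2 kb away on the same
#' chromosome, the remainder on a chromosome without feature loci),
#' genome sequences in which each model locus's flanking window is a
#' mutated copy of its partner's window, and a truth table of the
#' planted links. All randomness derives from `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return list with `betas`, `manifest`, `sequences` (named character
#'   vector of chromosome sequences), `truth` (data.frame:
#'   `model_probe`, `partner`, `w`, `b`, `noise_sd`, `tier`) and `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_local_seed(spec$seed, {
    nF <- spec$n_feature_loci
    nM <- spec$n_model_loci
    nS <- spec$n_samples
    feature_ids <- sprintf("cgF%04d", seq_len(nF))
    model_ids <- sprintf("cgM%04d", seq_len(nM))
    sample_ids <- sprintf("S%03d", seq_len(nS))

    # manifest layout: features on a 1.5 kb grid over chr1/chr2
    f_chr <- rep(c("chr1", "chr2"), length.out = nF)
    f_pos <- integer(nF)
    f_pos[f_chr == "chr1"] <- 10000L + 1500L * (seq_len(sum(f_chr == "chr1")) - 1L)
    f_pos[f_chr == "chr2"] <- 10000L + 1500L * (seq_len(sum(f_chr == "chr2")) - 1L)

    partners <- sample(feature_ids, nM)
    p_idx <- match(partners, feature_ids)
    m_chr <- character(nM)
    m_pos <- integer(nM)
    n_near <- ceiling(nM * 0.25)
    n_far <- floor(nM * 0.15)
    placement <- c(rep("near", n_near), rep("distal", nM - n_near - n_far),
                   rep("other_chr", n_far))
    for (j in seq_len(nM)) {
      if (placement[j] == "near") {
        m_chr[j] <- f_chr[p_idx[j]]
        m_pos[j] <- f_pos[p_idx[j]] + 500L + j  # < 2 kb from partner
      } else if (placement[j] == "distal") {
        m_chr[j] <- f_chr[p_idx[j]]
        m_pos[j] <- f_pos[p_idx[j]] + 2300L + 7L * j  # > 2 kb, off-grid
      } else {
        m_chr[j] <- "chr3"  # no feature loci here: nearest neighbour absent
        m_pos[j] <- 10000L + 1000L * j
      }
    }

    gene_pool <- sprintf("GENE%03d", seq_len(40))
    all_ids <- c(feature_ids, model_ids)
    ann <- character(length(all_ids))
    cgi_pool <- c("Island", "N_Shore", "S_Shelf", "OpenSea")
    for (i in seq_along(all_ids)) {
      k <- (i - 1L) %% 8L
      ann[i] <- switch(as.character(k %% 4L),
        "0" = sprintf("%s;%s", gene_pool[(i %% 40) + 1],
                      REGION_CATEGORIES[(i %% 6) + 1]),
        "1" = sprintf("%s;%s|%s;%s", gene_pool[(i %% 40) + 1],
                      REGION_CATEGORIES[(i %% 6) + 1],
                      gene_pool[((i + 7) %% 40) + 1],
                      REGION_CATEGORIES[((i + 3) %% 6) + 1]),
        "2" = sprintf("%s;%s", gene_pool[(i %% 40) + 1],
                      REGION_CATEGORIES[((i + 1) %% 6) + 1]),
        "3" = "")  # intergenic
    }
    manifest <- data.frame(
      probe_id = all_ids,
      chr = c(f_chr, m_chr),
      pos = c(f_pos, m_pos),
      on450k = c(rep(TRUE, nF), rep(FALSE, nM)),
      onEPIC = TRUE,
      gene_annotation = ann,
      cgi_relation = .normalize_cgi(cgi_pool[(seq_along(all_ids) %% 4) + 1]),
      stringsAsFactors = FALSE)
    manifest <- manifest[order(manifest$chr, manifest$pos), , drop = FALSE]
    rownames(manifest) <- NULL

    # chromosome sequences covering every locus plus the flank
    chr_len <- vapply(c("chr1", "chr2", "chr3"), function(ch) {
      max(manifest$pos[manifest$chr == ch], 1000L) + 500L
    }, integer(1))
    sequences <- vapply(chr_len, .random_dna, character(1))
    # plant flanking-sequence similarity: model window = mutated partner window
    flank <- 200L
    for (j in seq_len(nM)) {
      src_chr <- f_chr[p_idx[j]]
      src_pos <- f_pos[p_idx[j]]
      window <- substr(sequences[src_chr], src_pos - flank, src_pos + flank + 1L)
      mut <- .mutate_dna(window, spec$seq_mutation_rate)
      s <- sequences[m_chr[j]]
      substr(s, m_pos[j] - flank, m_pos[j] + flank + 1L) <- mut
      sequences[m_chr[j]] <- s
    }

    # beta values: features from the mixture, models through planted links
    F_mat <- matrix(.rbeta_mixture(nF * nS), nrow = nF,
                    dimnames = list(feature_ids, sample_ids))
    w <- stats::runif(nM, spec$link_w_range[1], spec$link_w_range[2])
    b <- -w / 2
    tier_sd <- spec$noise_tiers[((seq_len(nM) - 1L) %% length(spec$noise_tiers)) + 1L]
    M_mat <- matrix(NA_real_, nrow = nM, ncol = nS,
                    dimnames = list(model_ids, sample_ids))
    for (j in seq_len(nM)) {
      mu <- sigmoid(w[j] * F_mat[p_idx[j], ] + b[j])
      M_mat[j, ] <- pmin(pmax(mu + stats::rnorm(nS, 0, tier_sd[j]), 0), 1)
    }
    betas <- rbind(F_mat, M_mat)
    if (spec$missing_rate > 0) {
      drop <- stats::runif(length(betas)) < spec$missing_rate
      betas[drop] <- NA_real_
    }
    truth <- data.frame(model_probe = model_ids, partner = partners,
                        w = w, b = b, noise_sd = tier_sd,
                        tier = categorize(tier_sd), placement = placement,
                        stringsAsFactors = FALSE)
    list(betas = betas, manifest = manifest, sequences = sequences,
         truth = truth, spec = spec)
  })
}

#' Generate a two-group fixture for differential analysis
#'
#' `spec$n_model_loci` probes over two sample groups of sizes
#' `spec$n_group_samples`. The first `spec$group_effect$n_loci` probes
#' carry a planted mean shift of `delta` (group2 minus group1); all
#' values are Gaussian around the probe mean with sd
#' `spec$group_effect$sd`, clipped to \[0, 1\]. Baseline means are drawn
#' from U(0.25, 0.55) so the shift survives clipping.
#'
#' @param spec a [simulation_spec()] with `group_effect` set.
#' @return list with `betas`, `labels` (named character vector,
#'   `"group1"` / `"group2"`), `manifest`, `truth` (data.frame `probe_id`,
#'   `is_dml`, `delta`) and `spec`.
#' @export
generate_grouped_fixture <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_local_seed(spec$seed + 1L, {
    nP <- spec$n_model_loci
    n1 <- spec$n_group_samples[1]
    n2 <- spec$n_group_samples[2]
    delta <- spec$group_effect$delta
    sd <- spec$group_effect$sd
    n_eff <- spec$group_effect$n_loci
    probe_ids <- sprintf("cgD%04d", seq_len(nP))
    sample_ids <- c(sprintf("T%03d", seq_len(n1)), sprintf("N%03d", seq_len(n2)))
    labels <- stats::setNames(rep(c("group1", "group2"), c(n1, n2)), sample_ids)
    mu <- stats::runif(nP, 0.25, 0.55)
    betas <- matrix(NA_real_, nP, n1 + n2,
                    dimnames = list(probe_ids, sample_ids))
    for (i in seq_len(nP)) {
      m2 <- mu[i] + if (i <= n_eff) delta else 0
      v <- c(stats::rnorm(n1, mu[i], sd), stats::rnorm(n2, m2, sd))
      betas[i, ] <- pmin(pmax(v, 0), 1)
    }
    if (spec$missing_rate > 0) {
      drop <- stats::runif(length(betas)) < spec$missing_rate
      betas[drop] <- NA_real_
    }
    gene_pool <- sprintf("DGENE%03d", seq_len(30))
    cats <- c(PROMOTER_CATEGORIES, "Body", "3'UTR")
    manifest <- data.frame(
      probe_id = probe_ids, chr = "chr1",
      pos = 10000L + 1000L * seq_len(nP),
      on450k = TRUE, onEPIC = TRUE,
      gene_annotation = sprintf("%s;%s", gene_pool[(seq_len(nP) %% 30) + 1],
                                cats[(seq_len(nP) %% 6) + 1]),
      cgi_relation = .normalize_cgi(
        c("Island", "N_Shore", "S_Shelf", "OpenSea")[(seq_len(nP) %% 4) + 1]),
      stringsAsFactors = FALSE)
    truth <- data.frame(probe_id = probe_ids,
                        is_dml = seq_len(nP) <= n_eff,
                        delta = ifelse(seq_len(nP) <= n_eff, delta, 0),
                        stringsAsFactors = FALSE)
    list(betas = betas, labels = labels, manifest = manifest, truth = truth,
         spec = spec)
  })
}

#' Write a fixture to standard on-disk formats
#'
#' Beta matrix as TSV, manifest as CSV, sequences as FASTA and the truth
#' table as TSV, into `out_dir`.
#'
#' @param fixture list from [generate_fixture()].
#' @param out_dir output directory (created if absent).
#' @return invisible character vector of written paths.
#' @export
write_fixture <- function(fixture, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(betas = file.path(out_dir, "betas.tsv"),
             manifest = file.path(out_dir, "manifest.csv"),
             sequences = file.path(out_dir, "genome.fa"),
             truth = file.path(out_dir, "truth.tsv"))
  write_beta_matrix(fixture$betas, paths["betas"])
  man <- fixture$manifest
  man$on450k <- as.integer(man$on450k)
  man$onEPIC <- as.integer(man$onEPIC)
  utils::write.table(man, paths["manifest"], sep = ",", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(fixture$sequences)) {
    con <- file(paths["sequences"], "wt")
    for (ch in names(fixture$sequences)) {
      writeLines(paste0(">", ch), con)
      writeLines(fixture$sequences[[ch]], con)
    }
    close(con)
  }
  utils::write.table(fixture$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(paths)
}
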