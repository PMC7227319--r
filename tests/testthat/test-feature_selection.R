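test_that("k-mer frequency blocks match composition on simple sequences", {
  v <- kmer_features("ACGT")
  expect_length(v, 340)
  expect_equal(unname(v[c("A", "C", "G", "T")]), rep(0.25, 4))

  hp <- kmer_features("AAAA")
  expect_equal(unname(hp[c("A", "AA", "AAA", "AAAA")]), rep(1, 4))
  expect_equal(sum(hp), 4)
})

test_that("k-mer counting drops windows containing N, matching a brute-force counter", {
  seqs <- c("ACGTNAC", "NNACGTACGTNNGG", "ACGNNNGT")
  for (s in seqs) {
    expect_equal(unname(kmer_features(s)), unname(oracle_kmer_vector(s)),
                 tolerance = 1e-14)
  }
  expect_warning(v <- kmer_features(""), "empty")
  expect_equal(sum(v), 0)
})

test_that("each k-mer block sums to 1 (or 0) on randomized sequences", {
  blocks <- list(1:4, 5:20, 21:84, 85:340)
  withr::with_seed(42, {
    for (i in 1:20) {
      len <- sample(0:60, 1)
      s <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
      v <- if (len == 0) suppressWarnings(kmer_features(s)) else kmer_features(s)
      for (b in blocks) expect_true(abs(sum(v[b]) - 1) < 1e-12 || sum(v[b]) == 0)
    }
  })
})

test_that("methylation correlation is pairwise-complete Pearson with eligibility rules", {
  a <- c(0.1, 0.2, 0.3)
  expect_equal(pearson_methylation(a, a, min_samples = 2)$r, 1.0)
  expect_equal(pearson_methylation(a, c(0.9, 0.8, 0.7), min_samples = 2)$r, -1.0)

  withr::with_seed(5, {
    x <- runif(10); y <- runif(10)
    x[c(2, 7)] <- NA
    res <- pearson_methylation(x, y, min_samples = 5)
    expect_equal(res$n_used, 8)
    expect_equal(res$r, oracle_pearson(x, y), tolerance = 1e-12)
  })

  # below the complete-pair floor the pair is ineligible
  expect_true(is.na(pearson_methylation(runif(10), runif(10), min_samples = 30)$r))
  # zero variance is undefined
  expect_true(is.na(pearson_methylation(rep(0.5, 40), runif(40))$r))
})

test_that("correlations agree with the two-pass textbook formula to 1e-12", {
  withr::with_seed(8, {
    for (i in 1:50) {
      a <- runif(60); b <- runif(60)
      a[sample(60, 5)] <- NA
      expect_equal(pearson_methylation(a, b)$r, oracle_pearson(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("sequence correlation is symmetric and matches the oracle", {
  s1 <- kmer_features(strrep("ACGT", 30))
  expect_equal(pearson_sequence(s1, s1), 1.0)
  s2 <- kmer_features(strrep("AATG", 30))
  expect_equal(pearson_sequence(s1, s2), pearson_sequence(s2, s1))
  expect_equal(pearson_sequence(s1, s2), oracle_pearson(s1, s2),
               tolerance = 1e-12)
  expect_true(is.na(pearson_sequence(rep(0.5, 340), s1)))
  expect_error(pearson_sequence(s1[1:10], s2), "340")
})

make_nn_manifest <- function(positions, model_pos = 10000) {
  data.frame(probe_id = c("M", sprintf("f%02d", seq_along(positions))),
             chr = "chr1", pos = c(model_pos, positions),
             on450k = c(FALSE, rep(TRUE, length(positions))), onEPIC = TRUE,
             gene_annotation = "", cgi_relation = "island",
             stringsAsFactors = FALSE)
}

test_that("nearest neighbour minimizes same-chromosome distance with a 2 kb cap", {
  man <- make_nn_manifest(10000 + c(1500, 300, 5000))
  nn <- nearest_neighbour("M", man, c("f01", "f02", "f03"))
  expect_identical(nn$probe_id, "f02")
  expect_equal(nn$distance, 300)

  man <- make_nn_manifest(10000 + c(2500, 3000, -4000))
  expect_null(nearest_neighbour("M", man, sprintf("f%02d", 1:3),
                                max_distance = 2000))

  # equidistant candidates: brute-force scan confirms the minimum, the
  # smaller probe ID wins the tie
  man <- make_nn_manifest(10000 + c(-400, 400, 900))
  nn <- nearest_neighbour("M", man, sprintf("f%02d", 1:3))
  d <- abs(man$pos[-1] - 10000)
  expect_equal(nn$distance, min(d))
  expect_identical(nn$probe_id, "f01")

  # different chromosome candidates are ignored
  man$chr[man$probe_id == "f01"] <- "chr2"
  expect_identical(nearest_neighbour("M", man, sprintf("f%02d", 1:3))$probe_id,
                   "f02")
  expect_error(nearest_neighbour("missing", man, "f01"), "not in manifest")
})

test_that("co-methylated selection equals exhaustive argmax over candidates", {
  # planted exact copy wins with score 1
  tr <- random_beta_matrix(20, 50, seed = 2)
  tr <- rbind(tr, M = tr["p0007", ])
  sel <- select_comethylated("M", tr, rownames(tr)[1:20], min_samples = 10)
  expect_identical(sel$probe_id, "p0007")
  expect_equal(sel$score, 1.0)

  # 50-candidate random fixture vs brute-force argmax, several model rows
  tr <- random_beta_matrix(55, 60, missing_rate = 0.05, seed = 9)
  features <- rownames(tr)[1:50]
  for (mp in rownames(tr)[51:55]) {
    sel <- select_comethylated(mp, tr, features, min_samples = 10)
    rs <- vapply(features, function(f)
      pearson_methylation(tr[mp, ], tr[f, ], min_samples = 10)$r, numeric(1))
    expect_identical(sel$probe_id, names(which.max(rs)))
    expect_equal(sel$score, max(rs, na.rm = TRUE), tolerance = 1e-12)
  }

  # blocked scan is result-identical to the naive scan
  sel_b <- select_comethylated("p0051", tr, features, min_samples = 10,
                               block_size = 7)
  sel_n <- select_comethylated("p0051", tr, features, min_samples = 10)
  expect_identical(sel_b, sel_n)
})

test_that("co-methylation search is genome-wide: a distal strong partner beats an adjacent weak one", {
  withr::with_seed(3, {
    x <- runif(80)
    tr <- rbind(M = pmin(pmax(x + rnorm(80, 0, 0.01), 0), 1),
                near_weak = runif(80), far_strong = x)
    colnames(tr) <- sprintf("s%02d", 1:80)
  })
  man <- data.frame(probe_id = c("M", "near_weak", "far_strong"),
                    chr = c("chr1", "chr1", "chr2"),
                    pos = c(10000, 10050, 500000),
                    on450k = c(FALSE, TRUE, TRUE), onEPIC = TRUE,
                    gene_annotation = "", cgi_relation = "island",
                    stringsAsFactors = FALSE)
  sel <- select_comethylated("M", tr, c("near_weak", "far_strong"),
                             manifest = man)
  expect_identical(sel$probe_id, "far_strong")
})

test_that("sequence-match selection equals exhaustive argmax and breaks ties by probe ID", {
  withr::with_seed(12, {
    seqs <- vapply(1:21, function(i)
      paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""),
      character(1))
  })
  feats <- t(vapply(seqs, kmer_features, numeric(340)))
  rownames(feats) <- c("M", sprintf("f%02d", 1:20))
  cand <- sprintf("f%02d", 1:20)
  sel <- select_sequence_match("M", feats, cand)
  rs <- vapply(cand, function(f) pearson_sequence(feats["M", ], feats[f, ]),
               numeric(1))
  expect_identical(sel$probe_id, names(which.max(rs)))
  expect_equal(sel$score, max(rs), tolerance = 1e-12)

  # identical flanking sequence wins with score 1
  feats2 <- rbind(feats, fident = feats["M", ])
  sel <- select_sequence_match("M", feats2, c(cand, "fident"))
  expect_identical(sel$probe_id, "fident")
  expect_equal(sel$score, 1.0)

  # all candidates identical: lowest probe ID
  same <- matrix(rep(feats["M", ], 4), nrow = 4, byrow = TRUE,
                 dimnames = list(c("M", "fC", "fB", "fA"), NULL))
  same["M", 1] <- same["M", 1] + 0.01  # keep the model vector non-identical
  sel <- select_sequence_match("M", same, c("fC", "fB", "fA"))
  expect_identical(sel$probe_id, "fA")
})

test_that("assignment tables are complete, deterministic, and exclude constant loci", {
  fx <- generate_fixture(simulation_spec(n_model_loci = 5, n_feature_loci = 30,
                                         n_samples = 50, seed = 21))
  parts <- partition_loci(fx$manifest)
  asg <- build_assignments(fx$manifest, fx$betas,
                           model_loci = parts$model_loci,
                           feature_loci = parts$feature_loci,
                           seqs = fx$sequences, min_samples = 20)
  expect_equal(nrow(asg$assignments), 5)
  expect_true(all(!is.na(asg$assignments$cometh_probe)))
  expect_true(all(!is.na(asg$assignments$seq_r)))
  # planted partners recovered
  expect_identical(asg$assignments$cometh_probe,
                   fx$truth$partner[match(asg$assignments$model_probe,
                                          fx$truth$model_probe)])

  # recomputation is byte-identical
  asg2 <- build_assignments(fx$manifest, fx$betas,
                            model_loci = parts$model_loci,
                            feature_loci = parts$feature_loci,
                            seqs = fx$sequences, min_samples = 20)
  expect_identical(asg, asg2)

  # a constant model locus has undefined correlations and is excluded
  betas <- fx$betas
  betas[parts$model_loci[1], ] <- 0.5
  asg3 <- build_assignments(fx$manifest, betas,
                            model_loci = parts$model_loci,
                            feature_loci = parts$feature_loci,
                            min_samples = 20)
  expect_true(parts$model_loci[1] %in% asg3$excluded$model_probe)
  expect_false(parts$model_loci[1] %in% asg3$assignments$model_probe)

  # round-trip of the assignment table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(asg$assignments, path)
  expect_equal(read_assignments(path), asg$assignments, tolerance = 1e-12)
})

test_that("feature selection depends on training samples only", {
  fx <- generate_fixture(simulation_spec(n_model_loci = 6, n_feature_loci = 40,
                                         n_samples = 80, seed = 33))
  train_cols <- colnames(fx$betas)[1:50]
  parts <- partition_loci(fx$manifest)
  base <- build_assignments(fx$manifest, fx$betas[, train_cols],
                            model_loci = parts$model_loci,
                            feature_loci = parts$feature_loci,
                            min_samples = 20)
  # perturbing held-out samples never changes any assignment
  perturbed <- fx$betas
  perturbed[, setdiff(colnames(fx$betas), train_cols)] <-
    random_beta_matrix(nrow(fx$betas), 30, seed = 99)
  again <- build_assignments(fx$manifest, perturbed[, train_cols],
                             model_loci = parts$model_loci,
                             feature_loci = parts$feature_loci,
                             min_samples = 20)
  expect_identical(base, again)
})

test_that("same-region pairs correlate at least as strongly on planted fixtures", {
  # plant two promoter-region loci sharing a latent signal and one distal
  # body-region locus with weaker coupling; the region-stratified summary
  # orders same-region pairs first
  withr::with_seed(50, {
    z <- runif(100)
    tr <- rbind(M = pmin(pmax(z + rnorm(100, 0, 0.02), 0), 1),
                promo = pmin(pmax(z + rnorm(100, 0, 0.02), 0), 1),
                body = pmin(pmax(z + rnorm(100, 0, 0.3), 0), 1))
    colnames(tr) <- sprintf("s%03d", 1:100)
  })
  r_same <- pearson_methylation(tr["M", ], tr["promo", ])$r
  r_diff <- pearson_methylation(tr["M", ], tr["body", ])$r
  expect_gte(r_same, r_diff)
})
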