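# Independent brute-force oracles, deliberately written from first
# principles and kept free of the package's implementation paths.

# Two-pass textbook Pearson correlation over pairwise-complete entries.
oracle_pearson <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  cov <- sum((a - ma) * (b - mb)) / (n - 1)
  sa <- sqrt(sum((a - ma)^2) / (n - 1))
  sb <- sqrt(sum((b - mb)^2) / (n - 1))
  cov / (sa * sb)
}

# Sliding-window k-mer counter that drops every window containing a
# non-ACGT character; returns occurrence frequencies for one k.
oracle_kmer_block <- function(s, k) {
  bases <- c("A", "C", "G", "T")
  words <- bases
  if (k > 1) for (i in 2:k) words <- as.vector(t(outer(words, bases, paste0)))
  counts <- setNames(rep(0L, length(words)), sort(words))
  s <- toupper(s)
  n <- nchar(s)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("^[ACGT]+$", w)) counts[w] <- counts[w] + 1L
    }
  }
  total <- sum(counts)
  if (total == 0) counts * 0 else counts / total
}

oracle_kmer_vector <- function(s) {
  unlist(lapply(1:4, function(k) oracle_kmer_block(s, k)))
}

# Welch statistic, Welch-Satterthwaite df and two-sided p from the
# textbook formulas.
oracle_welch <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  v1 <- sum((g1 - mean(g1))^2) / (n1 - 1)
  v2 <- sum((g2 - mean(g2))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(g1) - mean(g2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Step-up BH: sort descending, p * m / rank, cumulative min from the
# largest rank, clip at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  ranks <- m:1
  q_sorted <- pmin(1, cummin(p[ord] * m / ranks))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# The eight performance metrics from independent formulas; AUC by
# explicit all-pairs comparison (ties count 1/2).
oracle_metrics <- function(pred, obs) {
  n <- length(pred)
  rmse <- sqrt(sum((pred - obs)^2) / n)
  mae <- sum(abs(pred - obs)) / n
  r <- if (length(unique(pred)) > 1 && length(unique(obs)) > 1)
    oracle_pearson(pred, obs) else NA_real_
  obs_s <- ifelse(obs > 0.5, 1, -1)
  pred_s <- ifelse(pred > 0.5, 1, -1)
  tp <- sum(pred_s == 1 & obs_s == 1)
  tn <- sum(pred_s == -1 & obs_s == -1)
  fp <- sum(pred_s == 1 & obs_s == -1)
  fn <- sum(pred_s == -1 & obs_s == 1)
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  den <- sqrt(tn + fn) * sqrt(tn + fp) * sqrt(tp + fn) * sqrt(tp + fp)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else NA_real_
  pos <- pred[obs_s == 1]
  neg <- pred[obs_s == -1]
  auc <- if (length(pos) > 0 && length(neg) > 0) {
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  } else NA_real_
  c(r = r, rmse = rmse, mae = mae, se = se, sp = sp, mcc = mcc,
    acc = acc, auc = auc)
}

# Small in-memory training fixture: one model probe linked to a feature
# probe through a noisy sigmoid.
make_linked_training <- function(n = 100, w = 3, b = -1, sd = 0, seed = 1,
                                 model_id = "M", feature_id = "F") {
  withr::with_seed(seed, {
    x <- runif(n)
    y <- pmin(pmax(plogis(w * x + b) + rnorm(n, 0, sd), 0), 1)
    tr <- rbind(y, x)
    rownames(tr) <- c(model_id, feature_id)
    colnames(tr) <- sprintf("s%04d", seq_len(n))
    tr
  })
}

one_row_assignment <- function(model = "M", cometh = "F", nn = NA_character_,
                               seq_probe = NA_character_) {
  data.frame(model_probe = model, cometh_probe = cometh, cometh_r = NA_real_,
             n_samples = NA_integer_, nn_probe = nn, nn_distance = NA_real_,
             seq_probe = seq_probe, seq_r = NA_real_, stringsAsFactors = FALSE)
}

random_beta_matrix <- function(n_probes, n_samples, missing_rate = 0, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_probes * n_samples), n_probes,
                dimnames = list(sprintf("p%04d", seq_len(n_probes)),
                                sprintf("s%04d", seq_len(n_samples))))
    if (missing_rate > 0) m[runif(length(m)) < missing_rate] <- NA
    m
  })
}
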