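# Independent oracles used across the suite. Deliberately brute-force and
# separate from the package's code paths.

# Mann-Whitney AUC by explicit pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Best Youden J by exhaustive enumeration over every candidate threshold
# (all observed values plus -Inf), positivity rule score > c.
oracle_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  best <- -Inf
  for (c in c(-Inf, unique(scores))) {
    j <- mean(pos > c) + mean(neg <= c) - 1
    if (j > best) best <- j
  }
  best
}

# Random small ROC instance with ties, both classes guaranteed.
random_roc_instance <- function(n_max = 30) {
  n <- sample(4:n_max, 1)
  scores <- sample(0:8, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
  labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
  list(scores = scores, labels = labels)
}

# A minimal valid single-subject cohort row; override fields as needed.
make_record <- function(id = "X1", sex = "male", height = 175, weight = 80,
                        wc = 80, sbp = 120, dbp = 78, fpg = 90, tg = 110,
                        hdl = 55, tc = 180,
                        treat_glucose = FALSE, treat_bp = FALSE,
                        treat_tg = FALSE, treat_hdl = FALSE) {
  tibble::tibble(
    id = id, sex = sex, age = 40, height_cm = height, weight_kg = weight,
    wc_cm = wc, sbp1 = sbp, sbp2 = sbp, dbp1 = dbp, dbp2 = dbp,
    fpg_mgdl = fpg, tg_mgdl = tg, hdl_mgdl = hdl, tc_mgdl = tc,
    treat_glucose = treat_glucose, treat_bp = treat_bp,
    treat_tg = treat_tg, treat_hdl = treat_hdl,
    smoking = "non-smoker", education = "<BSc", income = "350-575",
    marital = "married"
  )
}

# Random valid cohort rows for property tests.
random_records <- function(n) {
  tibble::tibble(
    id = sprintf("R%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = sample(20:75, n, replace = TRUE),
    height_cm = runif(n, 145, 195),
    weight_kg = runif(n, 40, 140),
    wc_cm = runif(n, 55, 140),
    sbp1 = runif(n, 95, 175), sbp2 = runif(n, 95, 175),
    dbp1 = runif(n, 55, 110), dbp2 = runif(n, 55, 110),
    fpg_mgdl = runif(n, 65, 220),
    tg_mgdl = runif(n, 40, 420),
    hdl_mgdl = runif(n, 22, 90),
    tc_mgdl = runif(n, 120, 280),
    treat_glucose = runif(n) < 0.05, treat_bp = runif(n) < 0.08,
    treat_tg = runif(n) < 0.03, treat_hdl = runif(n) < 0.02,
    smoking = "non-smoker", education = "<BSc", income = "350-575",
    marital = "married"
  )
}
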