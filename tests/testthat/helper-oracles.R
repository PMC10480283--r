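# Brute-force pairwise oracle for Krippendorff's alpha: enumerates every
# ordered within-unit pair for the observed disagreement and every ordered
# pair of pooled pairable values for the expected disagreement. Independent
# of the package's coincidence-matrix algebra.
oracle_alpha <- function(ratings, metric, domain = NULL) {
  ratings <- ratings[!is.na(ratings$score), ]
  if (is.null(domain)) domain <- sort(unique(ratings$score))
  per_unit <- split(ratings$score, ratings$patient_id)
  per_unit <- per_unit[vapply(per_unit, length, integer(1)) >= 2]
  pooled <- unlist(per_unit, use.names = FALSE)
  n <- length(pooled)
  n_c <- vapply(domain, function(v) sum(pooled == v), numeric(1))
  dsq <- function(a, b) {
    if (a == b) return(0)
    if (metric == "nominal") return(1)
    ia <- match(a, domain); ib <- match(b, domain)
    lo <- min(ia, ib); hi <- max(ia, ib)
    (sum(n_c[lo:hi]) - (n_c[ia] + n_c[ib]) / 2)^2
  }
  d_o_num <- 0
  for (vals in per_unit) {
    m <- length(vals)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j) d_o_num <- d_o_num + dsq(vals[i], vals[j]) / (m - 1)
      }
    }
  }
  d_o <- d_o_num / n
  d_e_num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d_e_num <- d_e_num + dsq(pooled[i], pooled[j])
    }
  }
  d_e <- d_e_num / (n * (n - 1))
  if (d_e == 0) stop("degenerate oracle case")
  1 - d_o / d_e
}

# Random long rating table with missing cells; regenerated until it has a
# pairable unit and a non-degenerate value distribution.
random_ratings <- function(n_raters, n_units, n_values, p_missing = 0.2) {
  repeat {
    df <- expand.grid(patient_id = seq_len(n_units),
                      reader_id = seq_len(n_raters))
    df$score <- sample.int(n_values, nrow(df), replace = TRUE)
    df$score[runif(nrow(df)) < p_missing] <- NA
    m_u <- tapply(!is.na(df$score), df$patient_id, sum)
    pooled <- df$score[!is.na(df$score) &
                         df$patient_id %in% as.integer(names(m_u)[m_u >= 2])]
    if (any(m_u >= 2) && length(unique(pooled)) >= 2) {
      return(tibble::as_tibble(df))
    }
  }
}

# A staging profile row (vector overrides recycle the defaults).
make_profile <- function(...) {
  base <- list(
    patient_id = "P1", t_stage = "t3b", size_cm = 4, signal = "homogeneous",
    shape = "regular", n_stage = "n0", emvi = FALSE, mrf = FALSE
  )
  args <- list(...)
  base[names(args)] <- args
  tibble::as_tibble(base)
}

# Small fully-crossed study fixture for table-level tests.
tiny_study <- function(seed = 7, n_patients = 25, n_expert = 2,
                       n_nonexpert = 3, ...) {
  cfg <- sim_config(n_patients = n_patients, n_expert_readers = n_expert,
                    n_nonexpert_readers = n_nonexpert, seed = seed, ...)
  simulate_study(cfg)
}

zero_error <- list(
  expert = list(p_miss = 0, p_false_call = 0, t_adjacent = 0, size_sdlog = 0),
  nonexpert = list(p_miss = 0, p_false_call = 0, t_adjacent = 0,
                   size_sdlog = 0)
)

# Balanced synthetic correctness-style data with a patient random intercept;
# Gaussian noise keeps the linear-model oracle exact.
make_lpm_data <- function(n_pat = 30, n_exp = 3, n_non = 5, beta1 = 0.08,
                          sd_pat = 0.2, sd_res = 0.4, binary = FALSE) {
  panel <- tibble::tibble(
    reader_id = sprintf("R%02d", seq_len(n_exp + n_non)),
    stratum = rep(c("expert", "nonexpert"), c(n_exp, n_non)))
  df <- tidyr::expand_grid(patient_id = sprintf("P%03d", seq_len(n_pat)),
                           reader_id = panel$reader_id)
  df <- dplyr::left_join(df, panel, by = "reader_id")
  b <- rnorm(n_pat, 0, sd_pat)
  mu <- 0.55 + beta1 * (df$stratum == "expert") +
    b[match(df$patient_id, unique(df$patient_id))]
  if (binary) {
    df$correct <- runif(nrow(df)) < mu
  } else {
    df$correct <- mu + rnorm(nrow(df), 0, sd_res)
  }
  df
}
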