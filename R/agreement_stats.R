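#' Coincidence matrix for Krippendorff's alpha
#'
#' Builds the value-by-value coincidence matrix underlying Krippendorff's
#' alpha from a long rating table. Within each unit (patient) holding
#' `m_u >= 2` non-missing ratings, every ordered pair of ratings from
#' distinct raters contributes `1 / (m_u - 1)` to its value pair's cell;
#' units with fewer than two ratings are excluded from pairing. The total
#' mass of the matrix equals the number of pairable values.
#'
#' @param data Long data frame of ratings.
#' @param unit,rater,value Columns identifying the unit (patient), the rater
#'   (reader), and the rating (tidy evaluation; defaults `patient_id`,
#'   `reader_id`, `score`). Missing ratings may be `NA` rows or simply
#'   absent rows.
#' @param domain Ordered vector of admissible values; defaults to the sorted
#'   unique observed values. Ratings outside the domain are an error.
#' @return A symmetric numeric matrix with `domain` as dimnames and an
#'   attribute `n_pairable` (total pairable values).
#' @export
coincidence_matrix <- function(data, unit = patient_id, rater = reader_id,
                               value = score, domain = NULL) {
  df <- dplyr::transmute(
    data,
    unit = {{ unit }},
    rater = {{ rater }},
    value = {{ value }}
  )
  df <- dplyr::filter(df, !is.na(.data$value))
  if (is.null(domain)) domain <- sort(unique(df$value))
  if (length(setdiff(unique(df$value), domain)) > 0) {
    abort("ratings outside the declared domain")
  }
  counts <- dplyr::count(df, .data$unit, .data$value)
  m_u <- dplyr::summarise(dplyr::group_by(counts, .data$unit),
                          m = sum(.data$n), .groups = "drop")
  keep <- m_u$unit[m_u$m >= 2]
  if (length(keep) == 0) {
    abort("no unit has two or more ratings; nothing is pairable")
  }
  counts <- dplyr::left_join(counts[counts$unit %in% keep, ],
                             m_u, by = "unit")
  k <- length(domain)
  o <- matrix(0, k, k, dimnames = list(domain, domain))
  # per unit, ordered pairs of values (c,k): n_uc * n_uk off-diagonal,
  # n_uc * (n_uc - 1) on the diagonal, all divided by (m_u - 1)
  for (u in unique(counts$unit)) {
    cu <- counts[counts$unit == u, ]
    n_uc <- setNames(rep(0, k), domain)
    n_uc[as.character(cu$value)] <- cu$n
    pair <- outer(n_uc, n_uc)
    diag(pair) <- n_uc * (n_uc - 1)
    o <- o + pair / (cu$m[1] - 1)
  }
  structure(o, n_pairable = sum(m_u$m[m_u$m >= 2]))
}

# Squared-distance matrix for a given metric over the (ordered) domain,
# given the marginal pairable counts n_c.
delta_sq <- function(metric, n_c) {
  k <- length(n_c)
  d <- matrix(0, k, k)
  if (metric == "nominal") {
    d[] <- 1
    diag(d) <- 0
  } else if (metric == "ordinal") {
    cum <- cumsum(n_c)
    for (c in seq_len(k)) {
      for (kk in seq_len(k)) {
        if (c == kk) next
        lo <- min(c, kk); hi <- max(c, kk)
        between <- cum[hi] - if (lo > 1) cum[lo - 1] else 0
        d[c, kk] <- (between - (n_c[c] + n_c[kk]) / 2)^2
      }
    }
  } else {
    abort(paste0("unknown metric: ", metric))
  }
  d
}

alpha_from_coincidence <- function(o, metric) {
  n_c <- rowSums(o)
  n <- sum(n_c)
  d <- delta_sq(metric, n_c)
  d_o <- sum(o * d) / n
  d_e <- sum(outer(n_c, n_c) * d) / (n * (n - 1))
  if (d_e == 0) {
    abort(paste0("degenerate agreement: all pairable ratings share one ",
                 "value, so chance-corrected agreement is undefined"))
  }
  list(alpha = 1 - d_o / d_e, d_o = d_o, d_e = d_e, n_pairable = n)
}

#' Krippendorff's alpha for many raters with missing data
#'
#' Chance-corrected interobserver agreement for any number of raters and
#' missing cells, via the coincidence-matrix estimator. Supports the nominal
#' metric (disagreement 0/1) and the ordinal metric, whose squared distance
#' between categories `c` and `k` is the squared count of pairable values
#' lying between them, counting half of each endpoint's marginal.
#'
#' Alpha is `1 - D_o / D_e`: observed over expected disagreement. A table in
#' which every pairable rating has the same value has `D_e = 0` and raises
#' an error (such data carry no chance-corrected information).
#'
#' @inheritParams coincidence_matrix
#' @param metric `"ordinal"` (default) or `"nominal"`.
#' @param ci If `TRUE`, attach a percentile bootstrap confidence interval.
#' @param n_boot,conf_level,seed Bootstrap settings (units are resampled,
#'   matching a design with a fixed reader panel and sampled patients).
#' @return Object of class `kripp_alpha`: a list with `alpha`, `metric`,
#'   `n_pairable`, `d_o`, `d_e`, and optionally `ci_low`/`ci_high`.
#'   [tidy()] returns it as a one-row tibble.
#' @examples
#' ratings <- tibble::tibble(
#'   patient_id = rep(1:4, each = 3),
#'   reader_id = rep(1:3, times = 4),
#'   score = c(1, 1, 2, 2, 2, 2, 3, 3, 3, 1, 2, 1)
#' )
#' krippendorff_alpha(ratings, metric = "ordinal")
#' @export
krippendorff_alpha <- function(data, unit = patient_id, rater = reader_id,
                               value = score, metric = c("ordinal", "nominal"),
                               domain = NULL, ci = FALSE, n_boot = 1000,
                               conf_level = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  o <- coincidence_matrix(data, {{ unit }}, {{ rater }}, {{ value }},
                          domain = domain)
  res <- alpha_from_coincidence(o, metric)
  out <- structure(
    list(alpha = res$alpha, metric = metric, n_pairable = res$n_pairable,
         d_o = res$d_o, d_e = res$d_e, ci_low = NA_real_, ci_high = NA_real_,
         conf_level = if (ci) conf_level else NA_real_),
    class = "kripp_alpha"
  )
  if (ci) {
    interval <- alpha_bootstrap_ci(data, {{ unit }}, {{ rater }}, {{ value }},
                                   metric = metric, domain = domain,
                                   n_boot = n_boot, conf_level = conf_level,
                                   seed = seed)
    out$ci_low <- interval[1]
    out$ci_high <- interval[2]
  }
  out
}

#' @export
print.kripp_alpha <- function(x, ...) {
  cat(sprintf("Krippendorff's alpha (%s metric): %.4f  [n pairable = %d]\n",
              x$metric, x$alpha, as.integer(round(x$n_pairable))))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  %.0f%% bootstrap CI: (%.4f, %.4f)\n",
                100 * x$conf_level, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' @method tidy kripp_alpha
#' @export
tidy.kripp_alpha <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, metric = x$metric,
                 n_pairable = x$n_pairable, d_o = x$d_o, d_e = x$d_e,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Percentile bootstrap confidence interval for Krippendorff's alpha
#'
#' Resamples units (patients) with replacement, keeping the reader panel
#' fixed, and returns the percentile interval of the resampled alphas.
#' Degenerate resamples (expected disagreement zero) are redrawn; the number
#' of redraws is attached as an attribute.
#'
#' @inheritParams krippendorff_alpha
#' @return Numeric vector `c(lower, upper)` with attribute `n_degenerate`.
#' @export
alpha_bootstrap_ci <- function(data, unit = patient_id, rater = reader_id,
                               value = score, metric = c("ordinal", "nominal"),
                               domain = NULL, n_boot = 1000, conf_level = 0.95,
                               seed = 1L) {
  metric <- match.arg(metric)
  if (n_boot < 100) abort("n_boot must be at least 100")
  df <- dplyr::transmute(data, unit = {{ unit }}, rater = {{ rater }},
                         value = {{ value }})
  df <- dplyr::filter(df, !is.na(.data$value))
  if (is.null(domain)) domain <- sort(unique(df$value))
  units <- unique(df$unit)
  by_unit <- split(df, df$unit)
  n_degenerate <- 0L
  alphas <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        take <- sample(units, length(units), replace = TRUE)
        boot <- dplyr::bind_rows(by_unit[as.character(take)],
                                 .id = "draw")
        boot$unit <- boot$draw
        o <- try(coincidence_matrix(boot, .data$unit, .data$rater,
                                    .data$value, domain = domain),
                 silent = TRUE)
        if (!inherits(o, "try-error")) {
          res <- try(alpha_from_coincidence(o, metric), silent = TRUE)
          if (!inherits(res, "try-error")) return(res$alpha)
        }
        n_degenerate <<- n_degenerate + 1L
        if (n_degenerate > 100 * n_boot) {
          abort("bootstrap cannot escape degenerate resamples")
        }
      }
    }, numeric(1))
  })
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  structure(unname(quantile(alphas, probs, type = 7)),
            n_degenerate = n_degenerate)
}

#' Interobserver-agreement report by method and reader stratum
#'
#' Computes Krippendorff's alpha for each scoring method within each reader
#' stratum (all readers, experts, non-experts): ordinal metric for the 5-
#' and 4-point scores, nominal for the 2-point score. If the staging
#' assessments are supplied, per-feature nominal alphas for the four
#' 4-point booleans are appended.
#'
#' @param scores Long score table (`patient_id`, `reader_id`, `method`,
#'   `score`).
#' @param panel Reader panel (`reader_id`, `stratum`).
#' @param assessments Optional staging-assessment table carrying
#'   `mrf_obvious`, `t_high_risk`, `nodal_obvious`, `emvi_obvious`.
#' @param ci,n_boot,seed Passed to [krippendorff_alpha()].
#' @return Tibble with columns `item`, `stratum`, `metric`, `alpha`,
#'   `n_pairable` (and `ci_low`/`ci_high` when `ci = TRUE`).
#' @export
agreement_table <- function(scores, panel, assessments = NULL, ci = FALSE,
                            n_boot = 1000, seed = 1L) {
  strata <- list(all = unique(panel$reader_id))
  for (s in c("expert", "nonexpert")) {
    ids <- panel$reader_id[panel$stratum == s]
    if (length(ids) == 0) {
      warn(paste0("no readers in stratum '", s, "'; column omitted"))
    } else {
      strata[[s]] <- ids
    }
  }
  items <- dplyr::distinct(scores, .data$method)$method
  rows <- purrr::map_dfr(items, function(m) {
    metric <- if (m %in% c("five_point", "four_point")) "ordinal" else
      "nominal"
    purrr::map_dfr(names(strata), function(s) {
      sub <- scores[scores$method == m &
                      scores$reader_id %in% strata[[s]], ]
      ka <- krippendorff_alpha(sub, metric = metric,
                               domain = score_domain(m),
                               ci = ci, n_boot = n_boot, seed = seed)
      dplyr::bind_cols(tibble::tibble(item = m, stratum = s), tidy(ka))
    })
  })
  if (!is.null(assessments)) {
    feats <- c("mrf_obvious", "t_high_risk", "nodal_obvious", "emvi_obvious")
    frows <- purrr::map_dfr(feats, function(f) {
      purrr::map_dfr(names(strata), function(s) {
        sub <- assessments[assessments$reader_id %in% strata[[s]], ]
        sub <- tibble::tibble(patient_id = sub$patient_id,
                              reader_id = sub$reader_id,
                              score = as.integer(sub[[f]]))
        ka <- krippendorff_alpha(sub, metric = "nominal", domain = 0:1,
                                 ci = ci, n_boot = n_boot, seed = seed)
        dplyr::bind_cols(tibble::tibble(item = f, stratum = s), tidy(ka))
      })
    })
    rows <- dplyr::bind_rows(rows, frows)
  }
  keep <- c("item", "stratum", "metric", "alpha", "n_pairable")
  if (ci) keep <- c(keep, "ci_low", "ci_high")
  rows[keep]
}
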