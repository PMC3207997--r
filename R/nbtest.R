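#' Median-of-ratios size factors
#'
#' Per-sample normalization scalars: each sample's median ratio of its
#' counts to the per-family geometric mean across samples. Families whose
#' geometric mean is zero (a zero in any sample) are excluded from the
#' median; zero counts in the remaining families are likewise skipped.
#'
#' @param counts integer matrix (families x samples) or a
#'   \code{\link{family_count_matrix}}.
#' @return positive numeric vector, one size factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "family_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  loggeo <- rowMeans(log(counts))
  if (!any(is.finite(loggeo)))
    stop("no family has nonzero counts in every sample; ",
         "add a pseudocount or drop empty samples")
  s <- apply(counts, 2, function(cnts)
    exp(stats::median((log(cnts) - loggeo)[is.finite(loggeo) & cnts > 0])))
  if (any(!is.finite(s) | s <= 0))
    stop("degenerate size factor for sample(s): ",
         paste(colnames(counts)[!is.finite(s) | s <= 0], collapse = ", "))
  s
}

#' Fit the mean-variance relation of one condition
#'
#' For each family, the base mean \code{q} and sample variance \code{w} of
#' size-factor-normalized counts are computed across the condition's
#' samples; the pooled variance function w(q) is fitted by isotonic
#' regression of w on q (variance grows with the mean for NB counts; with
#' only a dozen families a local regression is not identifiable). The raw
#' (overdispersion) variance is the fitted variance minus the shot-noise
#' (Poisson sampling) term \code{z = q * mean(1/s)}, floored at zero — a
#' family can never be modeled as less variable than Poisson. With
#' \code{sharing = "maximum"} each family uses the larger of its own and
#' the fitted variance (conservative, guards against families above the
#' trend).
#'
#' @param counts matrix of the condition's columns (families x samples).
#' @param size_factors size factors for these samples.
#' @param method \code{"isotonic"} (pooled fit) or \code{"per-family"}
#'   (method-of-moments, no pooling).
#' @param sharing \code{"maximum"} or \code{"fit-only"}.
#' @return object of class \code{dispersion_fit}: data.frame with
#'   \code{family, base_mean, w_obs, w_fit, z, raw_var, raw_scv} plus the
#'   fit settings. \code{raw_scv} is the raw variance divided by the
#'   squared base mean (the NB dispersion alpha).
#' @export
fit_dispersion <- function(counts, size_factors,
                           method = c("isotonic", "per-family"),
                           sharing = c("maximum", "fit-only")) {
  method <- match.arg(method)
  sharing <- match.arg(sharing)
  counts <- as.matrix(counts)
  if (ncol(counts) < 2)
    stop("need at least 2 samples to estimate a variance")
  if (length(size_factors) != ncol(counts))
    stop("one size factor per sample required")
  norm <- sweep(counts, 2, size_factors, "/")
  q <- rowMeans(norm)
  w <- apply(norm, 1, stats::var)
  z <- q * mean(1 / size_factors)
  w_fit <- if (method == "isotonic" && nrow(counts) >= 3) {
    ord <- order(q)
    yf <- numeric(length(q))
    yf[ord] <- stats::isoreg(q[ord], w[ord])$yf
    yf
  } else w
  w_use <- if (sharing == "maximum") pmax(w_fit, w) else w_fit
  raw_var <- pmax(w_use - z, 0)
  res <- data.frame(family = rownames(counts), base_mean = q, w_obs = w,
                    w_fit = w_fit, z = z, raw_var = raw_var,
                    raw_scv = ifelse(q > 0, raw_var / q^2, 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = res, method = method, sharing = sharing,
                 size_factors = size_factors),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat("dispersion_fit (", x$method, ", sharing=", x$sharing, "), ",
      nrow(x$table), " families\n", sep = "")
  print(utils::head(x$table))
  invisible(x)
}

nb_log_mass <- function(x, mu, size) {
  if (mu <= 0) return(ifelse(x == 0, 0, -Inf))
  if (!is.finite(size)) stats::dpois(x, mu, log = TRUE)
  else stats::dnbinom(x, mu = mu, size = size, log = TRUE)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Negative-binomial exact test for a two-condition count split
#'
#' Given summed counts \code{k_a}, \code{k_b} with condition-specific NB
#' laws (means \code{mu_a}, \code{mu_b} and variances \code{var_a},
#' \code{var_b}), the p-value is the total probability, conditional on the
#' sum S = k_a + k_b, of all splits (a, b = S - a) no more likely than the
#' observed one:
#' \deqn{p = \frac{\sum_{a+b=S,\ P(a)P(b) \le P(k_a)P(k_b)} P(a)P(b)}
#'            {\sum_{a+b=S} P(a)P(b)}}
#' All masses are computed in log space so astronomically small p-values
#' retain a meaningful log10; the returned \code{p} may underflow to 0
#' while \code{log10_p} does not. A variance at or below the mean
#' degenerates to the Poisson law.
#'
#' @param k_a,k_b observed summed counts in conditions A and B.
#' @param mu_a,mu_b NB means.
#' @param var_a,var_b NB variances (>= means; clipped to Poisson below).
#' @return list with \code{p} (double in [0,1], 0 only on underflow) and
#'   \code{log10_p}. \code{k_a + k_b == 0} returns p = 1 with a flag.
#' @export
nb_exact_test <- function(k_a, k_b, mu_a, mu_b, var_a = mu_a, var_b = mu_b) {
  S <- k_a + k_b
  if (S == 0)
    return(list(p = 1, log10_p = 0, flag = "zero_total"))
  size_a <- nb_size(mu_a, var_a)
  size_b <- nb_size(mu_b, var_b)
  a <- 0:S
  la <- nb_log_mass(a, mu_a, size_a)
  lb <- nb_log_mass(a, mu_b, size_b)
  lab <- la + rev(lb)                 # split (a, S - a)
  lobs <- lab[k_a + 1]
  denom <- logsumexp(lab)
  num <- logsumexp(lab[lab <= lobs + 1e-7])
  lp <- min(num - denom, 0)
  list(p = exp(lp), log10_p = lp / log(10), flag = NA_character_)
}

nb_size <- function(mu, var) {
  if (var <= mu * (1 + 1e-8)) Inf else mu^2 / (var - mu)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: sort p-values ascending, set
#' \code{adj_(i) = min_{j >= i} p_(j) * n / j} capped at 1, and return in
#' the input order.
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p_values)
  if (n == 0) return(numeric(0))
  o <- order(p_values)
  adj <- pmin(1, rev(cummin(rev(p_values[o] * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj
  names(out) <- names(p_values)
  out
}

#' Family-level differential test against the uniform null
#'
#' The full testing pipeline: joint (or per-condition) size factors,
#' per-condition mean-variance fits, NB exact test per family on the
#' summed counts, and Benjamini-Hochberg correction across families.
#' Fold change is reported as simulated over observed base mean, so an
#' overexpressed family (observed above the null) has fold change < 1.
#'
#' @param observed \code{\link{family_count_matrix}} of observed samples.
#' @param simulated \code{\link{family_count_matrix}} of simulated-null
#'   datasets; family ordering must match.
#' @param size_factor_scope \code{"joint"} (default) or
#'   \code{"per-condition"}.
#' @param dispersion_method,sharing passed to \code{\link{fit_dispersion}}.
#' @return data.frame of class \code{nb_test_result} with columns
#'   \code{family, base_mean_observed, base_mean_simulated, fold_change,
#'   p_raw, p_adj, log10_p_raw, log10_p_adj, flag}.
#' @export
run_family_test <- function(observed, simulated,
                            size_factor_scope = c("joint", "per-condition"),
                            dispersion_method = "isotonic",
                            sharing = "maximum") {
  stopifnot(inherits(observed, "family_counts"),
            inherits(simulated, "family_counts"))
  size_factor_scope <- match.arg(size_factor_scope)
  if (!identical(rownames(observed$counts), rownames(simulated$counts)))
    stop("observed and simulated matrices must share family ordering")
  kA_mat <- observed$counts
  kB_mat <- simulated$counts
  if (size_factor_scope == "joint") {
    s <- estimate_size_factors(cbind(kA_mat, kB_mat))
    sA <- s[seq_len(ncol(kA_mat))]
    sB <- s[-seq_len(ncol(kA_mat))]
  } else {
    sA <- estimate_size_factors(kA_mat)
    sB <- estimate_size_factors(kB_mat)
  }
  dispA <- fit_dispersion(kA_mat, sA, method = dispersion_method,
                          sharing = sharing)
  dispB <- fit_dispersion(kB_mat, sB, method = dispersion_method,
                          sharing = sharing)
  kA <- rowSums(kA_mat)
  kB <- rowSums(kB_mat)
  SsA <- sum(sA); SsB <- sum(sB)
  Ss2A <- sum(sA^2); Ss2B <- sum(sB^2)
  q0 <- (kA + kB) / (SsA + SsB)   # pooled mean per normalized unit
  n_fam <- nrow(kA_mat)
  p <- numeric(n_fam); lp <- numeric(n_fam); flag <- rep(NA_character_, n_fam)
  for (i in seq_len(n_fam)) {
    mu_a <- q0[i] * SsA
    mu_b <- q0[i] * SsB
    var_a <- mu_a + dispA$table$raw_scv[i] * q0[i]^2 * Ss2A
    var_b <- mu_b + dispB$table$raw_scv[i] * q0[i]^2 * Ss2B
    res <- nb_exact_test(kA[i], kB[i], mu_a, mu_b, var_a, var_b)
    p[i] <- res$p; lp[i] <- res$log10_p; flag[i] <- res$flag
  }
  p_adj <- bh_adjust(p)
  # BH on the log scale for the adjusted log10 (same step-up, underflow-safe)
  n <- n_fam
  o <- order(lp)
  lp_adj_sorted <- pmin(0, rev(cummin(rev(lp[o] + log10(n / seq_len(n))))))
  lp_adj <- numeric(n); lp_adj[o] <- lp_adj_sorted
  base_obs <- dispA$table$base_mean
  base_sim <- dispB$table$base_mean
  out <- data.frame(
    family = rownames(kA_mat),
    base_mean_observed = base_obs,
    base_mean_simulated = base_sim,
    fold_change = ifelse(base_obs > 0, base_sim / base_obs, NA_real_),
    p_raw = p, p_adj = p_adj,
    log10_p_raw = lp, log10_p_adj = lp_adj,
    flag = flag, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("nb_test_result", "data.frame")
  out
}

#' Write test results as TSV
#'
#' @param result an \code{nb_test_result}.
#' @param path output TSV path.
#' @export
write_test_results <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
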