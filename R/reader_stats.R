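#' Minimum sample size for a paired comparison
#'
#' Two-sided normal-approximation sample size for detecting a mean paired
#' difference `delta` with SD of differences `sd`:
#' `n = ceil( ((z_{1-alpha/2} + z_{power}) * sd / |delta|)^2 )`.
#'
#' @param delta Expected mean difference (non-zero).
#' @param sd SD of the paired differences, `> 0`.
#' @param power Target power `1 - beta`, in (0, 1).
#' @param alpha Two-sided significance level, in (0, 1).
#'
#' @return Integer sample size.
#' @export
#' @examples
#' min_sample_size(0.5, 0.4, 0.8, 0.01)  # 8
min_sample_size <- function(delta, sd, power, alpha) {
  stop_if_not_scalar_prob(power, "power")
  stop_if_not_scalar_prob(alpha, "alpha")
  if (!is.finite(delta) || delta == 0) stop("delta must be non-zero", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  as.integer(ceiling((z * sd / abs(delta))^2))
}

#' Simulate ordinal Likert reader scores
#'
#' Draws 1-5 (or 1-K) evaluability scores from a cumulative-logit model
#' with crossed Gaussian random intercepts: the latent predictor is
#' `eta = beta[sequence] + u_structure + u_reader + u_specimen` and
#' `P(score <= s) = logistic(theta_s - eta)`. Every
#' specimen x reader x structure x sequence cell is observed once.
#'
#' @param sequences Character vector of sequence levels; the first level
#'   is the reference in downstream model fits.
#' @param beta Latent sequence effects, one per level of `sequences`
#'   (reference conventionally 0).
#' @param thresholds Strictly increasing latent cutpoints (K-1 values for
#'   K score categories).
#' @param n_specimen,n_reader,n_structure Design sizes.
#' @param re_sd Named numeric: random-intercept SDs for `structure`,
#'   `reader`, `specimen` (all `>= 0`).
#' @param seed Integer seed; deterministic output.
#'
#' @return A tibble with columns `specimen`, `reader`, `structure`
#'   (factors), `sequence` (factor with `sequences` levels), `score`
#'   (integer).
#' @export
simulate_likert <- function(sequences = c("2D TSE", "MIXTURE", "3D TSE"),
                            beta = c(0, 0.5, 0.25),
                            thresholds = c(-2.5, -1, 0.5, 2),
                            n_specimen = 10, n_reader = 3, n_structure = 22,
                            re_sd = c(structure = 0.5, reader = 0.3,
                                      specimen = 0.4),
                            seed = 1L) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  stopifnot(length(beta) == length(sequences), all(re_sd >= 0),
            n_specimen >= 1, n_reader >= 1, n_structure >= 1)
  re_sd <- re_sd[c("structure", "reader", "specimen")]
  if (anyNA(re_sd)) {
    stop("re_sd must name structure, reader and specimen", call. = FALSE)
  }
  with_seed(seed, {
    u_structure <- rnorm(n_structure, 0, re_sd[["structure"]])
    u_reader <- rnorm(n_reader, 0, re_sd[["reader"]])
    u_specimen <- rnorm(n_specimen, 0, re_sd[["specimen"]])
    grid <- expand.grid(
      structure = seq_len(n_structure), reader = seq_len(n_reader),
      specimen = seq_len(n_specimen), sequence = seq_along(sequences),
      KEEP.OUT.ATTRS = FALSE
    )
    eta <- beta[grid$sequence] + u_structure[grid$structure] +
      u_reader[grid$reader] + u_specimen[grid$specimen]
    cum <- plogis(outer(eta, thresholds, function(e, th) th - e))
    u <- runif(nrow(grid))
    score <- 1L + as.integer(rowSums(u > cum))
    tibble::tibble(
      specimen = factor(paste0("S", grid$specimen)),
      reader = factor(paste0("R", grid$reader)),
      structure = factor(paste0("A", grid$structure)),
      sequence = factor(sequences[grid$sequence], levels = sequences),
      score = score
    )
  })
}

# ---- cumulative link mixed model (Laplace approximation) -------------------

# per-observation loglik pieces of the cumulative logit model given eta;
# score categories 1..K index the extended threshold vector (-Inf, theta, Inf)
clm_obs_terms <- function(eta, theta, score) {
  theta_ext <- c(-Inf, theta, Inf)
  up <- theta_ext[score + 1L] - eta
  lo <- theta_ext[score] - eta
  Fu <- 1 / (1 + exp(-up))   # logistic cdf; exp(-(-Inf)) = Inf -> 0, etc.
  Fl <- 1 / (1 + exp(-lo))
  fu <- Fu * (1 - Fu)        # logistic density; 0 at +-Inf
  fl <- Fl * (1 - Fl)
  fpu <- fu * (1 - 2 * Fu); fpl <- fl * (1 - 2 * Fl)
  p <- pmax(Fu - Fl, 1e-300)
  A <- fu - fl
  list(logp = log(p), p = p, fu = fu, fl = fl,
       deta = -A / p,                                    # d log p / d eta
       w = pmax((A^2 - (fpu - fpl) * p) / p^2, 0))       # -d2 log p / d eta2
}

# exact ML of the fixed-effects proportional-odds model (analytic gradient)
clm_fixed_ml <- function(score, K, X, tol = 1e-12) {
  n <- length(score)
  p_beta <- ncol(X)
  to_theta <- function(zeta) cumsum(c(zeta[1], exp(zeta[-1])))
  nll <- function(par) {
    theta <- to_theta(par[seq_len(K - 1)])
    eta <- if (p_beta > 0) as.vector(X %*% par[K - 1 + seq_len(p_beta)]) else numeric(n)
    -sum(clm_obs_terms(eta, theta, score)$logp)
  }
  ngr <- function(par) {
    zeta <- par[seq_len(K - 1)]
    theta <- to_theta(zeta)
    eta <- if (p_beta > 0) as.vector(X %*% par[K - 1 + seq_len(p_beta)]) else numeric(n)
    tm <- clm_obs_terms(eta, theta, score)
    # d logp / d theta_j: fu/p on rows with score == j, -fl/p on score == j+1
    g_theta <- vapply(seq_len(K - 1), function(j) {
      sum(tm$fu[score == j] / tm$p[score == j]) -
        sum(tm$fl[score == j + 1L] / tm$p[score == j + 1L])
    }, 0)
    # chain rule to the (theta1, log-diff) parametrization
    J <- matrix(0, K - 1, K - 1)
    J[, 1] <- 1
    if (K > 2) for (j in 2:(K - 1)) J[j:(K - 1), j] <- exp(zeta[j])
    g_zeta <- as.vector(g_theta %*% J)
    g_beta <- if (p_beta > 0) as.vector(crossprod(X, tm$deta)) else numeric(0)
    -c(g_zeta, g_beta)
  }
  cum_prop <- cumsum(tabulate(score, K) / n)[seq_len(K - 1)]
  theta0 <- qlogis(pmin(pmax(cum_prop, 1e-3), 1 - 1e-3))
  start <- c(theta0[1], log(pmax(diff(theta0), 1e-3)), rep(0, p_beta))
  opt <- stats::nlminb(start, nll, ngr,
                       control = list(rel.tol = tol, iter.max = 1000,
                                      eval.max = 3000))
  list(theta = to_theta(opt$par[seq_len(K - 1)]),
       beta = opt$par[K - 1 + seq_len(p_beta)],
       loglik = -opt$objective, convergence = opt$convergence)
}

#' Fit a cumulative link mixed model by the Laplace approximation
#'
#' Proportional-odds (cumulative logit) regression of an ordinal score on
#' the sequence factor, with independent Gaussian random intercepts for
#' any subset of structure, reader and specimen. The marginal likelihood
#' is approximated by the Laplace method: an inner Newton maximization
#' over the stacked random-effect vector (gradient tolerance 1e-8) inside
#' an outer quasi-Newton optimization over thresholds, fixed effects and
#' log random-effect SDs. With `random_terms = character(0)` the model
#' reduces to the fixed-effects proportional-odds model and its exact
#' maximum likelihood.
#'
#' @param data Data frame with integer `score` (values in 1..K), factor
#'   `sequence`, and factor columns for the requested random terms.
#' @param random_terms Subset of `c("structure", "reader", "specimen")`
#'   (more generally, factor column names of `data`).
#' @param control List: `inner_tol`, `outer_tol`, `max_inner`.
#'
#' @return A `clmm_fit`: thresholds, `beta` (named, reference level
#'   omitted), `re_sd`, `loglik`, `vcov` (thresholds + fixed effects),
#'   `se_beta`, `convergence` flag, and fit metadata.
#' @export
fit_clmm <- function(data,
                     random_terms = intersect(c("structure", "reader",
                                                "specimen"), names(data)),
                     control = list()) {
  ctrl <- modifyList(list(inner_tol = 1e-8, outer_tol = 1e-6,
                          max_inner = 50L), control)
  stopifnot(is.data.frame(data), all(c("score", "sequence") %in% names(data)))
  data$sequence <- droplevels(as.factor(data$sequence))
  if (nlevels(data$sequence) < 2L) {
    stop("need >= 2 sequence levels", call. = FALSE)
  }
  score <- as.integer(data$score)
  K <- max(score)
  if (length(unique(score)) < 2L) {
    stop("all scores in one category", call. = FALSE)
  }
  # collapse to observed categories so every threshold is identified
  score <- match(score, sort(unique(score)))
  K <- max(score)
  n <- length(score)

  X <- stats::model.matrix(~sequence, data)[, -1, drop = FALSE]
  colnames(X) <- levels(data$sequence)[-1]
  p_beta <- ncol(X)

  missing_terms <- setdiff(random_terms, names(data))
  if (length(missing_terms)) {
    stop("random term(s) absent from data: ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  }
  fac <- lapply(random_terms, function(g) droplevels(as.factor(data[[g]])))
  names(fac) <- random_terms
  fac_int <- lapply(fac, as.integer)
  m_g <- vapply(fac, nlevels, 0L)
  q <- sum(m_g)
  n_re <- length(random_terms)
  offset_g <- cumsum(c(0L, m_g))[seq_len(max(n_re, 1L))]
  re_index <- rep(seq_len(n_re), m_g)
  # dense incidence matrix of the stacked random effects (q is small)
  Z <- NULL
  if (n_re > 0L) {
    Z <- matrix(0, n, q)
    for (g in seq_len(n_re)) {
      Z[cbind(seq_len(n), offset_g[g] + fac_int[[g]])] <- 1
    }
  }

  # exact fixed-effects ML: the no-RE answer and the mixed-model start
  fml <- clm_fixed_ml(score, K, X,
                      tol = if (n_re == 0L) 1e-13 else 1e-8)

  # unconstrained parametrization of ordered thresholds
  to_theta <- function(zeta) cumsum(c(zeta[1], exp(zeta[-1])))
  from_theta <- function(theta) c(theta[1], log(diff(theta)))

  u_warm <- rep(0, max(q, 1L))

  laplace_nll <- function(theta, beta, log_sd) {
    offs <- if (p_beta > 0) as.vector(X %*% beta) else numeric(n)
    if (n_re == 0L) {
      return(-sum(clm_obs_terms(offs, theta, score)$logp))
    }
    sig2 <- exp(2 * log_sd)[re_index]
    u <- u_warm
    terms <- clm_obs_terms(offs + as.vector(Z %*% u), theta, score)
    l_cur <- sum(terms$logp) - sum(u^2 / (2 * sig2))
    H <- NULL
    for (it in seq_len(ctrl$max_inner)) {
      grad <- as.vector(crossprod(Z, terms$deta)) - u / sig2
      H <- crossprod(Z * sqrt(terms$w))
      diag(H) <- diag(H) + 1 / sig2
      if (max(abs(grad)) < ctrl$inner_tol) break
      step <- tryCatch(solve(H, grad), error = function(e) grad)
      # step halving keeps the penalized loglik increasing
      lambda <- 1
      repeat {
        u_new <- u + lambda * step
        terms_new <- clm_obs_terms(offs + as.vector(Z %*% u_new), theta, score)
        l_new <- sum(terms_new$logp) - sum(u_new^2 / (2 * sig2))
        if (is.finite(l_new) && l_new >= l_cur - 1e-12) break
        lambda <- lambda / 2
        if (lambda < 1e-8) { u_new <- u; terms_new <- terms; l_new <- l_cur; break }
      }
      if (identical(u_new, u)) break
      u <- u_new; terms <- terms_new; l_cur <- l_new
    }
    u_warm <<- u
    ld <- determinant(H, logarithm = TRUE)$modulus
    -(l_cur - sum(m_g * log_sd) - 0.5 * as.numeric(ld))
  }

  if (n_re == 0L) {
    theta <- fml$theta
    beta <- fml$beta
    log_sd <- numeric(0)
    opt <- list(objective = -fml$loglik, convergence = fml$convergence,
                message = "fixed-effects ML")
  } else {
    nll_packed <- function(par) {
      zeta <- par[seq_len(K - 1)]
      beta <- par[K - 1 + seq_len(p_beta)]
      log_sd <- par[K - 1 + p_beta + seq_len(n_re)]
      val <- laplace_nll(to_theta(zeta), beta, log_sd)
      if (!is.finite(val)) 1e10 else val
    }
    start <- c(from_theta(fml$theta), fml$beta, rep(log(0.3), n_re))
    lower <- c(rep(-Inf, K - 1 + p_beta), rep(-8, n_re))
    upper <- c(rep(Inf, K - 1 + p_beta), rep(4, n_re))
    opt <- stats::nlminb(start, nll_packed, lower = lower, upper = upper,
                         control = list(rel.tol = ctrl$outer_tol,
                                        iter.max = 500, eval.max = 2000))
    zeta <- opt$par[seq_len(K - 1)]
    theta <- to_theta(zeta)
    beta <- opt$par[K - 1 + seq_len(p_beta)]
    log_sd <- opt$par[K - 1 + p_beta + seq_len(n_re)]
  }

  # observed-information vcov in the natural (theta, beta, log_sd) scale;
  # log-sd parameters stuck at the boundary are held fixed
  nll_nat <- function(par) {
    th <- par[seq_len(K - 1)]
    if (is.unsorted(th, strictly = TRUE)) return(1e10)
    laplace_nll(th, par[K - 1 + seq_len(p_beta)],
                par[K - 1 + p_beta + seq_len(n_re)])
  }
  par_nat <- c(theta, beta, log_sd)
  n_par <- length(par_nat)
  at_bound <- c(rep(FALSE, K - 1 + p_beta), log_sd <= -8 + 1e-4)
  free <- which(!at_bound)
  V <- matrix(NA_real_, n_par, n_par)
  hess_ok <- TRUE
  H_nat <- tryCatch(
    stats::optimHess(par_nat[free], function(pf) {
      pp <- par_nat; pp[free] <- pf; nll_nat(pp)
    }),
    error = function(e) NULL)
  if (!is.null(H_nat)) {
    Vf <- tryCatch(solve(H_nat), error = function(e) NULL)
    if (!is.null(Vf)) V[free, free] <- Vf else hess_ok <- FALSE
  } else {
    hess_ok <- FALSE
  }
  idx_fix <- seq_len(K - 1 + p_beta)
  names(beta) <- colnames(X)
  par_names <- c(paste0("theta", seq_len(K - 1)), colnames(X))
  vcov_fix <- V[idx_fix, idx_fix, drop = FALSE]
  dimnames(vcov_fix) <- list(par_names, par_names)
  re_sd <- exp(log_sd)
  names(re_sd) <- random_terms

  structure(
    list(thresholds = theta, beta = beta, re_sd = re_sd,
         loglik = -opt$objective, vcov = vcov_fix,
         se_beta = sqrt(diag(vcov_fix))[K - 1 + seq_len(p_beta)],
         convergence = (opt$convergence == 0) && hess_ok,
         n = n, n_categories = K,
         sequence_levels = levels(data$sequence),
         random_terms = random_terms, message = opt$message),
    class = "clmm_fit"
  )
}

#' @export
print.clmm_fit <- function(x, ...) {
  cat(sprintf("<clmm_fit> cumulative logit, %d obs, %d categories, loglik %.3f\n",
              x$n, x$n_categories, x$loglik))
  cat("thresholds:", paste(signif(x$thresholds, 4), collapse = " "), "\n")
  if (length(x$beta)) {
    cat("fixed effects (ref:", x$sequence_levels[1], "):\n")
    print(round(rbind(estimate = x$beta, se = x$se_beta), 4))
  }
  if (length(x$re_sd)) {
    cat("random-intercept SDs:\n")
    print(round(x$re_sd, 4))
  }
  if (!x$convergence) cat("WARNING: fit did not converge cleanly\n")
  invisible(x)
}

# Seeded Monte-Carlo equicoordinate probability of max |Z| over correlated
# contrasts; returns the adjusted p for each observed |z|.
tukey_mvn_adjust <- function(z_obs, R, nsim = 2e5, seed = 7L) {
  k <- length(z_obs)
  if (k == 1L) return(2 * pnorm(-abs(z_obs)))
  with_seed(seed, {
    L <- tryCatch(chol(R), error = function(e) {
      chol(R + diag(1e-8, nrow(R)))
    })
    Zs <- matrix(rnorm(nsim * k), nsim, k) %*% L
    M <- apply(abs(Zs), 1, max)
    vapply(abs(z_obs), function(z) mean(M >= z), 0)
  })
}

#' Latent-scale estimated marginal means with Tukey-adjusted contrasts
#'
#' EMMs for the sequence levels on the latent scale of a fitted cumulative
#' link (mixed) model: the linear predictor at each level with random
#' effects at zero, centered by the mean threshold (latent EMMs are
#' identified only up to threshold location). Pairwise contrasts use the
#' fixed-effect covariance; the multiplicity adjustment is the
#' equicoordinate multivariate-normal bound over the contrast set,
#' evaluated by seeded Monte Carlo.
#'
#' @param fit A converged `clmm_fit`.
#' @param nsim Monte-Carlo draws for the adjustment.
#' @param seed Seed for the adjustment draws.
#'
#' @return An `emm_table`: list with tibbles `emm` (`sequence`, `emm`,
#'   `se`) and `contrasts` (`contrast`, `estimate`, `se`, `z`, `p_raw`,
#'   `p_tukey`).
#' @export
emm_and_tukey <- function(fit, nsim = 2e5, seed = 7L) {
  stopifnot(inherits(fit, "clmm_fit"))
  if (!fit$convergence) stop("fit did not converge", call. = FALSE)
  K1 <- length(fit$thresholds)
  lev <- fit$sequence_levels
  k <- length(lev)
  n_par <- K1 + length(fit$beta)
  # rows: one EMM per level = beta_level - mean(theta) (beta_ref = 0)
  A <- matrix(0, k, n_par)
  A[, seq_len(K1)] <- -1 / K1
  for (j in seq_len(k - 1)) A[j + 1, K1 + j] <- 1
  est <- as.vector(A %*% c(fit$thresholds, fit$beta))
  V <- fit$vcov
  if (anyNA(V)) stop("fit has no covariance; cannot compute EMMs", call. = FALSE)
  se <- sqrt(rowSums((A %*% V) * A))
  emm <- tibble::tibble(sequence = lev, emm = est, se = se)

  pairs <- utils::combn(k, 2)
  C <- matrix(0, ncol(pairs), n_par)
  for (c_i in seq_len(ncol(pairs))) {
    C[c_i, ] <- A[pairs[2, c_i], ] - A[pairs[1, c_i], ]
  }
  c_est <- as.vector(C %*% c(fit$thresholds, fit$beta))
  CV <- C %*% V %*% t(C)
  c_se <- sqrt(diag(CV))
  z <- c_est / c_se
  p_raw <- 2 * pnorm(-abs(z))
  R <- stats::cov2cor(CV)
  p_tukey <- pmin(1, pmax(tukey_mvn_adjust(z, R, nsim = nsim, seed = seed),
                          p_raw))
  contrasts <- tibble::tibble(
    contrast = paste(lev[pairs[2, ]], "-", lev[pairs[1, ]]),
    estimate = c_est, se = c_se, z = z, p_raw = p_raw, p_tukey = p_tukey
  )
  structure(list(emm = emm, contrasts = contrasts), class = "emm_table")
}

#' @export
print.emm_table <- function(x, ...) {
  cat("Latent-scale estimated marginal means:\n")
  print(x$emm)
  cat("\nPairwise contrasts (Tukey-adjusted):\n")
  print(x$contrasts)
  invisible(x)
}

#' One-way repeated-measures ANOVA with Tukey-Kramer post hoc test
#'
#' Decomposes a complete specimen x sequence metric table into specimen
#' (block) and sequence effects; the sequence effect is tested against the
#' residual mean square with `F = MS_sequence / MS_residual` on
#' `(k-1, (k-1)(n-1))` degrees of freedom. All pairwise sequence
#' comparisons are adjusted with the studentized-range (Tukey-Kramer)
#' distribution on the residual degrees of freedom.
#'
#' @param table Either a long data frame with columns `specimen`,
#'   `sequence`, `value`, or a numeric matrix/wide data frame with one row
#'   per specimen and one column per sequence. The design must be
#'   complete.
#'
#' @return An `rm_anova_fit`: list with `f`, `df1`, `df2`, `p_value`,
#'   sums of squares, `means` tibble and `pairwise` tibble (`contrast`,
#'   `estimate`, `se`, `q`, `p_tukey`).
#' @export
rm_anova_tukey <- function(table) {
  if (is.data.frame(table) &&
      all(c("specimen", "sequence", "value") %in% names(table))) {
    sp <- factor(as.character(table$specimen))
    sq <- factor(as.character(table$sequence))
    wide <- tapply(table$value, list(sp, sq), mean)
    counts <- tapply(table$value, list(sp, sq), length)
    if (anyNA(counts) || any(counts != 1)) {
      stop("incomplete specimen x sequence table (missing cells)", call. = FALSE)
    }
  } else {
    wide <- as.matrix(table)
  }
  if (anyNA(wide)) stop("missing cells in the metric table", call. = FALSE)
  n <- nrow(wide); k <- ncol(wide)
  if (n < 2L || k < 2L) {
    stop("need >= 2 specimens and >= 2 sequences", call. = FALSE)
  }
  grand <- mean(wide)
  row_m <- rowMeans(wide); col_m <- colMeans(wide)
  ss_total <- sum((wide - grand)^2)
  ss_subject <- k * sum((row_m - grand)^2)
  ss_seq <- n * sum((col_m - grand)^2)
  ss_err <- max(ss_total - ss_subject - ss_seq, 0)
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  ms_seq <- ss_seq / df1; ms_err <- ss_err / df2

  seq_names <- colnames(wide) %||% paste0("seq", seq_len(k))
  pairs <- utils::combn(k, 2)
  diffs <- col_m[pairs[2, ]] - col_m[pairs[1, ]]
  if (ss_seq <= 1e-14 * max(ss_total, 1)) {
    f <- 0; p <- 1
    q_stat <- rep(0, ncol(pairs)); p_tk <- rep(1, ncol(pairs))
    se_pair <- rep(sqrt(max(ms_err, 0) / n), ncol(pairs))
  } else {
    f <- ms_seq / ms_err
    p <- pf(f, df1, df2, lower.tail = FALSE)
    se_pair <- rep(sqrt(ms_err / n), ncol(pairs))
    q_stat <- unname(abs(diffs) / se_pair)
    p_tk <- ptukey(q_stat, nmeans = k, df = df2, lower.tail = FALSE)
  }
  structure(
    list(f = f, df1 = df1, df2 = df2, p_value = p,
         ss_sequence = ss_seq, ss_subject = ss_subject, ss_error = ss_err,
         ms_sequence = ms_seq, ms_error = ms_err,
         n_specimens = n,
         means = tibble::tibble(sequence = seq_names, mean = as.vector(col_m)),
         pairwise = tibble::tibble(
           contrast = paste(seq_names[pairs[2, ]], "-", seq_names[pairs[1, ]]),
           estimate = as.vector(diffs), se = se_pair, q = q_stat,
           p_tukey = as.vector(p_tk))),
    class = "rm_anova_fit"
  )
}

#' @export
print.rm_anova_fit <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df1, x$df2, x$f, x$p_value))
  cat("\nTukey-Kramer pairwise comparisons:\n")
  print(x$pairwise)
  invisible(x)
}
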