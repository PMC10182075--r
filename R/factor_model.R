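#' Group traits by thresholded genetic correlation
#'
#' Builds a graph with an edge wherever the pairwise genetic correlation
#' meets the threshold and returns its connected components: the empirical
#' grouping used to motivate candidate factor models.
#'
#' @param rg Symmetric genetic-correlation matrix with unit diagonal
#'   (dimnames = trait names).
#' @param threshold Edge threshold (default 0.4); edges where `rg >= threshold`.
#' @return A tibble with columns trait, group (integer id); groups are
#'   numbered in order of their first member.
#' @export
propose_groups <- function(rg, threshold = 0.4) {
  rg <- as.matrix(rg)
  if (!isTRUE(all.equal(rg, t(rg), tolerance = 1e-8))) {
    stop("rg must be symmetric", call. = FALSE)
  }
  k <- nrow(rg)
  traits <- rownames(rg) %||% paste0("T", seq_len(k))
  adj <- rg >= threshold
  diag(adj) <- TRUE
  group <- rep(NA_integer_, k)
  g <- 0L
  for (s in seq_len(k)) {
    if (!is.na(group[s])) next
    g <- g + 1L
    queue <- s
    group[s] <- g
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(group))
      group[nb] <- g
      queue <- c(queue, nb)
    }
  }
  tibble::tibble(trait = traits, group = group)
}

#' Specify a confirmatory factor model
#'
#' Factors are scaled to unit variance so loadings are directly standardized
#' paths; factor correlations are free when `correlated_factors` is TRUE;
#' every trait gets a free residual variance. Cross-loadings (a trait listed
#' under several factors) are supported.
#'
#' @param loading_pattern Named list: factor name -> character vector of
#'   traits with free loadings on that factor.
#' @param correlated_factors Free factor correlations (default TRUE)?
#' @param name Optional model label.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(loading_pattern, correlated_factors = TRUE, name = NULL) {
  traits <- unique(unlist(loading_pattern))
  if (length(loading_pattern) > 0 && length(traits) == 0) {
    stop("loading_pattern must name at least one trait", call. = FALSE)
  }
  structure(
    list(loading_pattern = loading_pattern,
         correlated_factors = correlated_factors,
         name = name %||% paste0(length(loading_pattern), "-factor")),
    class = "model_spec"
  )
}

# Parameter bookkeeping: theta = (free loadings, atanh factor correlations,
# residual variances). Returns builders mapping theta <-> (Lambda, Phi, Theta).
spec_layout <- function(spec, traits) {
  lp <- spec$loading_pattern
  nf <- length(lp)
  k <- length(traits)
  missing <- setdiff(unlist(lp), traits)
  if (length(missing) > 0) {
    stop("spec names traits absent from the estimate: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  load_idx <- do.call(rbind, lapply(seq_along(lp), function(f) {
    cbind(trait = match(lp[[f]], traits), factor = f)
  }))
  if (is.null(load_idx)) load_idx <- matrix(integer(0), 0, 2)
  n_load <- nrow(load_idx)
  n_phi <- if (spec$correlated_factors && nf > 1) nf * (nf - 1) / 2 else 0L
  n_free <- n_load + n_phi + k
  if (n_free > k * (k + 1) / 2) {
    stop("model is not identified: more free parameters than distinct covariance elements",
         call. = FALSE)
  }
  phi_idx <- if (n_phi > 0) which(lower.tri(diag(nf))) else integer(0)
  build <- function(theta) {
    L <- matrix(0, k, nf)
    if (n_load > 0) L[load_idx] <- theta[seq_len(n_load)]
    Phi <- diag(1, max(nf, 1))
    if (n_phi > 0) {
      Phi[phi_idx] <- tanh(theta[n_load + seq_len(n_phi)])
      Phi[upper.tri(Phi)] <- t(Phi)[upper.tri(Phi)]
    }
    Th <- theta[n_load + n_phi + seq_len(k)]
    list(L = L, Phi = Phi, Th = Th)
  }
  implied <- function(theta) {
    p <- build(theta)
    if (nf > 0) {
      p$L %*% p$Phi %*% t(p$L) + diag(p$Th, k)
    } else {
      diag(p$Th, k)
    }
  }
  list(build = build, implied = implied, n_load = n_load, n_phi = n_phi,
       n_free = n_free, k = k, nf = nf, load_idx = load_idx, phi_idx = phi_idx)
}

# numeric Jacobian of vech(implied) wrt theta
sigma_jacobian <- function(implied, theta, k) {
  p <- k * (k + 1) / 2
  J <- matrix(0, p, length(theta))
  h <- 1e-6
  for (i in seq_along(theta)) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    J[, i] <- (vech(implied(tp)) - vech(implied(tm))) / (2 * h)
  }
  J
}

#' Fit a factor model to a genetic covariance estimate by weighted least squares
#'
#' Minimizes `(s - sigma(theta))' W (s - sigma(theta))` over the free
#' parameters, where `s` are the distinct elements of S, `sigma(theta)` the
#' model-implied elements, and `W` the inverse of the diagonal of the
#' sampling covariance V (full-V weighting behind `weights = "full"`).
#' Optimization runs quasi-Newton from several deterministic starts and is
#' polished with damped Gauss-Newton iterations. Parameter standard errors
#' use the sandwich formula with the full V. The fit statistic is the WLS
#' quadratic form at the optimum with `df = k(k+1)/2 - n_free`; CFI and SRMR
#' are computed against the independence baseline. Negative residual
#' variances (Heywood cases) are flagged, not clamped.
#'
#' If S is not positive definite it is projected to the nearest PSD matrix
#' (eigenvalue floor 1e-6) before fitting and `smoothed` is set.
#'
#' @param est A `genetic_covariance` object (or a list with S and V).
#' @param spec A `model_spec`.
#' @param weights `"diag"` (default) or `"full"`.
#' @return An object of class `factor_fit`.
#' @export
fit_wls <- function(est, spec, weights = c("diag", "full")) {
  weights <- match.arg(weights)
  S <- as.matrix(est$S)
  V <- as.matrix(est$V)
  k <- nrow(S)
  traits <- rownames(S) %||% est$traits %||% paste0("T", seq_len(k))
  rownames(S) <- colnames(S) <- traits

  smoothed <- FALSE
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    S <- ev$vectors %*% diag(pmax(ev$values, 1e-6), k) %*% t(ev$vectors)
    dimnames(S) <- list(traits, traits)
    smoothed <- TRUE
  }

  s <- vech(S)
  dV <- pmax(diag(V), 1e-12)
  if (any(diag(V) <= 0)) {
    stop("V must have strictly positive diagonal", call. = FALSE)
  }
  W <- if (weights == "diag") diag(1 / dV) else {
    evV <- eigen((V + t(V)) / 2, symmetric = TRUE)
    evV$vectors %*% diag(1 / pmax(evV$values, 1e-10)) %*% t(evV$vectors)
  }

  lay <- spec_layout(spec, traits)
  objective <- function(theta) {
    r <- s - vech(lay$implied(theta))
    drop(crossprod(r, W %*% r))
  }

  # deterministic starts: moderate and high communality
  starts <- list()
  for (comm in c(0.5, 0.8)) {
    th <- numeric(lay$n_free)
    if (lay$n_load > 0) {
      n_on <- tabulate(lay$load_idx[, 1], nbins = k)
      th[seq_len(lay$n_load)] <-
        sqrt(comm * pmax(diag(S)[lay$load_idx[, 1]], 1e-8) /
               pmax(n_on[lay$load_idx[, 1]], 1))
    }
    if (lay$n_phi > 0) th[lay$n_load + seq_len(lay$n_phi)] <- atanh(0.3)
    th[lay$n_load + lay$n_phi + seq_len(k)] <- (1 - comm) * pmax(diag(S), 1e-8)
    starts[[length(starts) + 1]] <- th
  }

  best <- NULL
  converged <- FALSE
  for (th0 in starts) {
    opt <- tryCatch(
      stats::optim(th0, objective, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      converged <- opt$convergence == 0
    }
  }
  if (is.null(best)) {
    stop("optimization failed from all starting points", call. = FALSE)
  }

  # damped Gauss-Newton polish for high-precision optima
  theta <- best$par
  obj <- objective(theta)
  for (it in 1:50) {
    J <- sigma_jacobian(lay$implied, theta, k)
    r <- s - vech(lay$implied(theta))
    A <- crossprod(J, W %*% J)
    g <- crossprod(J, W %*% r)
    step <- tryCatch(solve(A + diag(1e-10, ncol(A)), g), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    improved <- FALSE
    for (half in 1:20) {
      cand <- theta + lam * drop(step)
      oc <- objective(cand)
      if (is.finite(oc) && oc <= obj) {
        theta <- cand; obj_new <- oc; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break
    if (obj - obj_new < 1e-14 * (1 + obj)) { obj <- obj_new; break }
    obj <- obj_new
  }

  pars <- lay$build(theta)
  implied <- lay$implied(theta)
  dimnames(implied) <- list(traits, traits)

  # sandwich SEs with full V
  J <- sigma_jacobian(lay$implied, theta, k)
  A <- crossprod(J, W %*% J)
  Ainv <- tryCatch(solve(A), error = function(e) MASS_ginv(A))
  covtheta <- Ainv %*% crossprod(J, W %*% V %*% W %*% J) %*% Ainv
  se_theta <- sqrt(pmax(diag(covtheta), 0))

  p_elem <- k * (k + 1) / 2
  chi2 <- obj
  df <- p_elem - lay$n_free

  # SRMR on the correlation (standardized) scale, observed diagonal
  d <- sqrt(pmax(diag(S), 1e-12))
  Dstd <- tcrossprod(d)
  resid_std <- (S - implied) / Dstd
  srmr <- sqrt(mean(vech(resid_std)^2))
  heywood <- any(pars$Th < 0)

  fit <- structure(
    list(
      spec = spec, traits = traits,
      loadings = `dimnames<-`(pars$L, list(traits, names(spec$loading_pattern))),
      phi = pars$Phi, theta_resid = stats::setNames(pars$Th, traits),
      par = theta, se = se_theta, cov_par = covtheta, layout = lay,
      implied = implied, S = S, V = V,
      chi2 = chi2, df = df, srmr = srmr,
      converged = converged, heywood = heywood, smoothed = smoothed,
      n_free = lay$n_free, objective = obj
    ),
    class = "factor_fit"
  )
  # CFI needs the independence baseline: fit it unless this IS the baseline
  if (lay$nf > 0) {
    base_spec <- model_spec(stats::setNames(list(), character(0)),
                            name = "independence")
    baseline <- fit_wls_baseline(est, S, V, W, traits)
    fit$baseline_chi2 <- baseline$chi2
    fit$baseline_df <- baseline$df
    fit$cfi <- cfi_from_chi2(chi2, df, baseline$chi2, baseline$df)
  } else {
    fit$baseline_chi2 <- chi2
    fit$baseline_df <- df
    fit$cfi <- NA_real_
  }
  fit
}

# Independence model: diagonal Theta free, all off-diagonals implied zero.
# WLS solution is closed-form under diagonal weighting of distinct elements.
fit_wls_baseline <- function(est, S, V, W, traits) {
  k <- nrow(S)
  s <- vech(S)
  idx <- lower_tri_pairs(k)
  is_diag <- idx[, 1] == idx[, 2]
  # with a diagonal W the optimum fits the diagonal exactly; with full W use
  # the constrained GLS solution
  X <- matrix(0, length(s), k)
  X[cbind(which(is_diag), seq_len(k))] <- 1
  A <- crossprod(X, W %*% X)
  th <- solve(A, crossprod(X, W %*% s))
  r <- s - X %*% th
  chi2 <- drop(crossprod(r, W %*% r))
  list(chi2 = chi2, df = k * (k + 1) / 2 - k)
}

cfi_from_chi2 <- function(chi2_m, df_m, chi2_b, df_b) {
  num <- max(chi2_m - df_m, 0)
  den <- max(chi2_b - df_b, chi2_m - df_m, 0)
  if (den == 0) return(1)
  1 - num / den
}

MASS_ginv <- function(A) {
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
    t(sv$u[, pos, drop = FALSE])
}

#' Model-fit indices from a fitted model and its independence baseline
#'
#' `cfi = 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b, chi2_m - df_m, 0)`;
#' SRMR is the root mean square of standardized residuals between the
#' observed and implied matrices over the distinct elements.
#'
#' @param fit A `factor_fit`.
#' @param baseline Optional independence-model fit; defaults to the baseline
#'   stored in `fit`.
#' @return Named list with `cfi` and `srmr`.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  chi2_b <- if (is.null(baseline)) fit$baseline_chi2 else baseline$chi2
  df_b <- if (is.null(baseline)) fit$baseline_df else baseline$df
  if (df_b <= fit$df) stop("baseline df must exceed model df", call. = FALSE)
  list(cfi = cfi_from_chi2(fit$chi2, fit$df, chi2_b, df_b), srmr = fit$srmr)
}

#' Select among candidate factor-model fits
#'
#' Filters candidates by fit thresholds (CFI above `cfi_min`, SRMR below
#' `srmr_max`), removes any models excluded by name (interpretability
#' exclusions are declared, never inferred), and among survivors prefers the
#' model with the fewest factors.
#'
#' @param fits List of `factor_fit` objects.
#' @param cfi_min CFI threshold (default 0.95).
#' @param srmr_max SRMR threshold (default 0.10).
#' @param exclude Character vector of model names to exclude.
#' @return List with `chosen` (a `factor_fit` or NULL when no candidate is
#'   adequate) and `report` (a tibble of all candidates with pass flags).
#' @export
select_model <- function(fits, cfi_min = 0.95, srmr_max = 0.10,
                         exclude = character()) {
  if (length(fits) == 0) stop("need at least one candidate", call. = FALSE)
  report <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      model = f$spec$name,
      n_factors = length(f$spec$loading_pattern),
      chi2 = f$chi2, df = f$df, cfi = f$cfi, srmr = f$srmr,
      converged = f$converged, heywood = f$heywood,
      excluded = f$spec$name %in% exclude,
      pass = f$cfi > cfi_min & f$srmr < srmr_max & f$converged &
        !(f$spec$name %in% exclude)
    )
  })
  ok <- which(report$pass)
  chosen <- if (length(ok) == 0) NULL else fits[[ok[which.min(report$n_factors[ok])]]]
  list(chosen = chosen, report = report)
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("<factor_fit> %s: chi2 = %.4g (df = %d), CFI = %.4f, SRMR = %.4f%s%s\n",
              x$spec$name, x$chi2, x$df, x$cfi, x$srmr,
              if (x$heywood) " [Heywood]" else "",
              if (x$smoothed) " [S smoothed to PSD]" else ""))
  cat("standardized loadings:\n")
  print(round(standardized_loadings(x), 3))
  invisible(x)
}

#' Standardized loadings of a fitted factor model
#'
#' With unit factor variances the standardized loading is the raw loading
#' divided by the implied trait standard deviation.
#'
#' @param fit A `factor_fit`.
#' @return Trait x factor matrix.
#' @export
standardized_loadings <- function(fit) {
  d <- sqrt(pmax(diag(fit$implied), 1e-12))
  sweep(fit$loadings, 1, d, `/`)
}

#' Tidy a fitted factor model into one row per free parameter
#'
#' @param x A `factor_fit`.
#' @param ... Unused.
#' @return Tibble: term, type (loading / factor_cor / residual), estimate,
#'   std_estimate (standardized loadings; NA otherwise), se.
#' @method tidy factor_fit
#' @export
tidy.factor_fit <- function(x, ...) {
  lay <- x$layout
  std <- standardized_loadings(x)
  rows <- list()
  if (lay$n_load > 0) {
    fn <- names(x$spec$loading_pattern)
    rows$load <- tibble::tibble(
      term = sprintf("%s =~ %s", fn[lay$load_idx[, 2]],
                     x$traits[lay$load_idx[, 1]]),
      type = "loading",
      estimate = x$par[seq_len(lay$n_load)],
      std_estimate = unname(std[lay$load_idx]),
      se = x$se[seq_len(lay$n_load)]
    )
  }
  if (lay$n_phi > 0) {
    nf <- lay$nf
    ij <- which(lower.tri(diag(nf)), arr.ind = TRUE)
    raw <- x$par[lay$n_load + seq_len(lay$n_phi)]
    # delta-method SE through tanh
    rows$phi <- tibble::tibble(
      term = sprintf("%s ~~ %s", names(x$spec$loading_pattern)[ij[, 2]],
                     names(x$spec$loading_pattern)[ij[, 1]]),
      type = "factor_cor",
      estimate = tanh(raw),
      std_estimate = tanh(raw),
      se = x$se[lay$n_load + seq_len(lay$n_phi)] * (1 - tanh(raw)^2)
    )
  }
  rows$resid <- tibble::tibble(
    term = sprintf("%s ~~ %s", x$traits, x$traits),
    type = "residual",
    estimate = x$par[lay$n_load + lay$n_phi + seq_len(lay$k)],
    std_estimate = unname(x$par[lay$n_load + lay$n_phi + seq_len(lay$k)] /
      pmax(diag(x$implied), 1e-12)),
    se = x$se[lay$n_load + lay$n_phi + seq_len(lay$k)]
  )
  dplyr::bind_rows(rows)
}

#' @method glance factor_fit
#' @export
glance.factor_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$name,
    n_factors = length(x$spec$loading_pattern),
    n_free = x$n_free,
    chi2 = x$chi2, df = x$df, cfi = x$cfi, srmr = x$srmr,
    converged = x$converged, heywood = x$heywood, smoothed = x$smoothed
  )
}

#' Serialize a fitted factor model to JSON with a path-diagram text summary
#' @param fit A `factor_fit`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_factor_fit <- function(fit, path) {
  td <- tidy.factor_fit(fit)
  jsonlite::write_json(
    list(
      model = fit$spec$name,
      parameters = td,
      fit = list(chi2 = fit$chi2, df = fit$df, cfi = fit$cfi, srmr = fit$srmr,
                 converged = fit$converged, heywood = fit$heywood),
      path_diagram = paste(
        sprintf("%s (est %.3f, std %.3f)", td$term, td$estimate, td$std_estimate),
        collapse = "\n")
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
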