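# Mixed models for route placement: Gaussian LMMs (fitted by ML so that
# likelihood-ratio tests are valid) and binomial GLMMs (Laplace), with
# uncorrelated random slopes by group, Wald 95% CIs, likelihood-ratio and
# drop1 inference, and a distance-weighted residual autocorrelation term
# whose Gaussian kernel SD D is chosen to maximise the full-model
# log-likelihood.

#' Specify a mixed model
#'
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms; transforms and one
#'   interaction are written in formula syntax (e.g. `"sqrt(slope_deg)"`,
#'   `"rel_elevation:ft_density"`). Interaction terms must also appear as
#'   main effects.
#' @param random grouping column (random intercept plus uncorrelated
#'   per-term slopes).
#' @param family `"gaussian"` or `"binomial"`.
#' @param random_slopes terms given random slopes (default: all fixed terms);
#'   use `character(0)` for a random intercept only.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(response, fixed, random = "group_id",
                       family = c("gaussian", "binomial"),
                       random_slopes = fixed) {
  family <- match.arg(family)
  mains <- fixed[!grepl(":", fixed, fixed = TRUE)]
  for (tm in fixed[grepl(":", fixed, fixed = TRUE)]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% mains))
      stop("interaction ", tm, " lacks main effect(s): ",
           paste(setdiff(parts, mains), collapse = ", "))
  }
  structure(list(response = response, fixed = fixed, random = random,
                 family = family, random_slopes = random_slopes),
            class = "model_spec")
}

.spec_formula <- function(spec, extra_fixed = character(0),
                          drop_terms = character(0)) {
  # reduced models drop fixed terms only: the random-effect structure is
  # held constant across nested fits so LRTs test population-level effects
  fx <- c(setdiff(spec$fixed, drop_terms), extra_fixed)
  rs <- c(spec$random_slopes, extra_fixed)
  fx_str <- if (length(fx)) paste(fx, collapse = " + ") else "1"
  re_str <- if (length(rs))
    sprintf("(1 + %s || %s)", paste(rs, collapse = " + "), spec$random)
  else sprintf("(1 | %s)", spec$random)
  stats::as.formula(paste(spec$response, "~", fx_str, "+", re_str))
}

#' Fit a mixed model
#'
#' Gaussian responses are fitted with `lme4::lmer` by maximum likelihood
#' (`REML = FALSE`, so nested models can be compared by LRT); binomial
#' responses with `lme4::glmer` (Laplace approximation, logit link). Random
#' effects are an intercept plus uncorrelated slopes (`||`) by the grouping
#' factor. Non-convergence and singular fits are flagged, not hidden.
#'
#' @param spec a [model_spec()].
#' @param data data.frame containing all columns.
#' @param extra_fixed additional fixed-effect columns (e.g. the
#'   autocorrelation term), also given a random slope.
#' @param drop_terms fixed terms to omit (for reduced models).
#' @return Object of class `"fit_result"`: `coefficients` (data.frame with
#'   estimate, SE, Wald 95% CI, z/t and p), `loglik`, `df`, `n_obs`,
#'   `converged`, `singular`, `varcomp`, and the underlying `model`.
#' @export
fit_mixed <- function(spec, data, extra_fixed = character(0),
                      drop_terms = character(0)) {
  need <- unique(c(spec$response, all.vars(.spec_formula(spec, extra_fixed))))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(data[need])) stop("data contain NA in model columns")
  f <- .spec_formula(spec, extra_fixed, drop_terms)
  fit <- withCallingHandlers(
    if (spec$family == "gaussian")
      lme4::lmer(f, data = data, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    else
      lme4::glmer(f, data = data, family = stats::binomial(),
                  control = lme4::glmerControl(check.conv.singular = "ignore")),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
  .as_fit_result(fit, spec)
}

.as_fit_result <- function(fit, spec) {
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zc <- stats::qnorm(0.975)
  stat <- beta / se
  coefs <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    ci_lower = unname(beta - zc * se), ci_upper = unname(beta + zc * se),
    statistic = unname(stat),
    p_wald = unname(2 * stats::pnorm(-abs(stat))))
  ll <- stats::logLik(fit)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0)
  vc <- as.data.frame(lme4::VarCorr(fit))
  res <- list(coefficients = coefs, loglik = as.numeric(ll),
              df = attr(ll, "df"), n_obs = stats::nobs(fit),
              converged = conv, singular = lme4::isSingular(fit),
              varcomp = vc, family = spec$family, spec = spec, model = fit)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s mixed model, n = %d, logLik = %.2f, df = %d%s%s\n",
              x$family, x$n_obs, x$loglik, x$df,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$singular) " [singular fit]" else ""))
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Distance-weighted residual autocorrelation term
#'
#' For observation `i`, the weighted average of the residuals of all *other*
#' observations of the same group, with Gaussian weights
#' `w_ij = exp(-d_ij^2 / (2 D^2))`. The focal observation is excluded from
#' its own average; observations alone in their group (or with all-zero
#' weights) get 0.
#'
#' @param residuals numeric vector of model residuals.
#' @param coords two-column matrix of observation coordinates (m).
#' @param group_ids grouping vector.
#' @param D kernel SD in meters (> 0).
#' @return Numeric vector, one value per observation.
#' @export
autocorr_term <- function(residuals, coords, group_ids, D) {
  if (!is.numeric(D) || length(D) != 1 || D <= 0) stop("D must be > 0")
  coords <- as_xy(coords)
  n <- length(residuals)
  stopifnot(nrow(coords) == n, length(group_ids) == n)
  out <- numeric(n)
  for (g in unique(group_ids)) {
    sel <- which(group_ids == g)
    if (length(sel) < 2) { out[sel] <- 0; next }
    d <- as.matrix(stats::dist(coords[sel, , drop = FALSE]))
    w <- exp(-d^2 / (2 * D^2))
    diag(w) <- 0
    sw <- rowSums(w)
    val <- as.vector(w %*% residuals[sel])
    out[sel] <- ifelse(sw > 0, val / sw, 0)
  }
  out
}

# residuals on the response scale (response minus fitted mean)
.resp_residuals <- function(fit_result) {
  stats::residuals(fit_result$model, type = "response")
}

#' Optimise the autocorrelation kernel width D
#'
#' Fits the model without the term, computes the term from those residuals
#' for each candidate `D`, refits with the term as an extra covariate, and
#' returns the `D` maximising the full-model log-likelihood (ties broken
#' toward the smallest `D`). The residuals are computed once from the initial
#' fit (single pass); set `iterate = TRUE` to recompute residuals from the
#' refitted model and repeat until `D` stabilises (at most 5 rounds).
#'
#' @param spec a [model_spec()].
#' @param data data.frame with model columns plus `x`/`y` coordinates (or
#'   supply `coords`).
#' @param D_grid candidate kernel SDs (default 1..30 m).
#' @param coords optional two-column coordinate matrix.
#' @param term_name column name for the term (default `"ac_term"`).
#' @param iterate recompute residuals from the refit and repeat.
#' @param random_slope_term give the term a random slope too (default TRUE,
#'   matching the full model structure).
#' @return List `D` (optimum), `fit` (refit at the optimum), `profile`
#'   (data.frame `D`, `loglik`), `term` (the covariate at the optimum),
#'   `fit0` (initial fit without the term).
#' @export
optimize_D <- function(spec, data, D_grid = 1:30, coords = NULL,
                       term_name = "ac_term", iterate = FALSE,
                       random_slope_term = TRUE) {
  if (is.null(coords)) {
    if (!all(c("x", "y") %in% names(data)) && all(c("cx", "cy") %in% names(data)))
      coords <- cbind(data$cx, data$cy)
    else coords <- cbind(data$x, data$y)
  }
  coords <- as_xy(coords)
  fit0 <- fit_mixed(spec, data)
  gids <- data[[spec$random]]
  res <- .resp_residuals(fit0)
  refit <- function(d) {
    if (random_slope_term) fit_mixed(spec, d, extra_fixed = term_name)
    else {
      spec_t <- spec
      spec_t$fixed <- c(spec$fixed, term_name)
      fit_mixed(spec_t, d)
    }
  }
  best <- NULL
  for (round in seq_len(if (iterate) 5L else 1L)) {
    prof <- data.frame(D = D_grid, loglik = NA_real_)
    fits <- vector("list", length(D_grid))
    for (i in seq_along(D_grid)) {
      data[[term_name]] <- autocorr_term(res, coords, gids, D_grid[i])
      fits[[i]] <- refit(data)
      prof$loglik[i] <- fits[[i]]$loglik
    }
    iopt <- which(prof$loglik >= max(prof$loglik) - 1e-9)[1]
    data[[term_name]] <- autocorr_term(res, coords, gids, D_grid[iopt])
    best <- list(D = D_grid[iopt], fit = fits[[iopt]], profile = prof,
                 term = data[[term_name]], fit0 = fit0)
    if (!iterate) break
    new_res <- .resp_residuals(best$fit)
    if (!is.null(attr(best, "lastD")) && attr(best, "lastD") == best$D) break
    attr(best, "lastD") <- best$D
    res <- new_res
  }
  best
}

#' Likelihood-ratio test between nested fits
#'
#' @param full,null `"fit_result"`s fitted by ML on the same data, with the
#'   null nested in the full model.
#' @return List `chi2`, `df`, `p`.
#' @export
lrt <- function(full, null) {
  if (full$n_obs != null$n_obs) stop("fits use different data (n differs)")
  if (!full$converged || !null$converged)
    stop("refusing LRT on a non-converged fit")
  chi2 <- max(0, 2 * (full$loglik - null$loglik))
  df <- full$df - null$df
  if (df <= 0) return(list(chi2 = chi2, df = max(df, 0), p = 1))
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Per-term likelihood-ratio tests (drop1)
#'
#' Each droppable fixed term is tested by refitting without it. An
#' interaction is tested first; while it is in the model its main effects are
#' not individually tested (marginality is respected).
#'
#' @param spec a [model_spec()].
#' @param data data.frame (include the autocorrelation term as a plain fixed
#'   term in `spec` if wanted).
#' @param keep terms never dropped (controls), default `character(0)`.
#' @return data.frame `term`, `chi2`, `df`, `p`.
#' @export
drop1_tests <- function(spec, data, keep = character(0)) {
  full <- fit_mixed(spec, data)
  if (!full$converged) stop("full model did not converge; refusing drop1")
  inters <- spec$fixed[grepl(":", spec$fixed, fixed = TRUE)]
  inter_parents <- unique(unlist(strsplit(inters, ":", fixed = TRUE)))
  droppable <- setdiff(spec$fixed, keep)
  droppable <- setdiff(droppable, setdiff(inter_parents, character(0)))
  droppable <- unique(c(inters, droppable))
  rows <- lapply(droppable, function(tm) {
    # drop the fixed term only; the random-effect structure is held constant
    # so the LRT has 1 df and tests the population-level effect
    spec_r <- spec
    spec_r$fixed <- setdiff(spec$fixed, tm)
    red <- fit_mixed(spec_r, data)
    lt <- lrt(full, red)
    data.frame(term = tm, chi2 = lt$chi2, df = lt$df, p = lt$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

#' Z-standardize covariate columns
#'
#' @param data data.frame.
#' @param cols columns to scale.
#' @return The data.frame with listed columns centered and scaled; attribute
#'   `"scaling"` records means and SDs.
#' @export
standardize_covariates <- function(data, cols) {
  sc <- data.frame(col = cols, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(cols)) {
    v <- data[[cols[i]]]
    sc$mean[i] <- mean(v); sc$sd[i] <- stats::sd(v)
    data[[cols[i]]] <- if (sc$sd[i] > 0) (v - sc$mean[i]) / sc$sd[i] else v - sc$mean[i]
  }
  attr(data, "scaling") <- sc
  data
}

#' Fit the pipeline's three route-placement models
#'
#' * Model 1 (Gaussian): buffer counts ~ location type (observed vs simulated
#'   mean) + buffer size, random slopes by group.
#' * Model 2 (Gaussian): log(trees per meter) ~ weeks used + buffer size,
#'   random slopes by group; zero rates get `log(x + half the minimum
#'   positive rate)`.
#' * Model 3 (binomial, fitted twice for the 2-week and 4-week thresholds):
#'   route presence ~ sqrt(slope) + gap presence + relative elevation x
#'   tree-density index + overlap + core flags + optimised autocorrelation
#'   term, uncorrelated random slopes by group.
#'
#' @param buffer_counts [csr_null()]-shaped table (per group and buffer:
#'   `observed_count`, `sim_mean`).
#' @param seg_rates [segment_rates()] output (all groups bound together).
#' @param quadrats quadrat tables (all groups bound together) with a
#'   `route_ge2`/`route_ge4` response and `cx`, `cy` coordinates.
#' @param exclude_groups groups dropped from models 1-2 (e.g. a group whose
#'   range shifted mid-study); default none.
#' @param standardize z-standardize model-3 covariates (default TRUE).
#' @param D_grid autocorrelation kernel grid (default 1..30 m).
#' @param zero_rate_policy `"half_min"` (default) or `"drop"` for zero
#'   trees-per-meter rows in model 2.
#' @param fixed_effects_check also fit model 3 with group as a fixed factor
#'   (no random effects) and flag coefficient sign disagreements (default
#'   TRUE; with few groups random-effect variances are weakly identified).
#' @return List of class `"route_models"`: `model1`, `model2`, `model3_ge2`,
#'   `model3_ge4` (each with fit, D where relevant, LRT vs null, drop1
#'   table), and `report` (a tidy coefficient table across models).
#' @export
run_route_models <- function(buffer_counts, seg_rates, quadrats,
                             exclude_groups = character(0),
                             standardize = TRUE, D_grid = 1:30,
                             zero_rate_policy = c("half_min", "drop"),
                             fixed_effects_check = TRUE) {
  zero_rate_policy <- match.arg(zero_rate_policy)
  out <- list()

  ## model 1: observed vs simulated counts
  bc <- buffer_counts[!buffer_counts$group_id %in% exclude_groups, ]
  m1dat <- rbind(
    data.frame(group_id = bc$group_id, buffer_m = bc$buffer_m,
               n_fts = bc$observed_count, loc_type = "observed"),
    data.frame(group_id = bc$group_id, buffer_m = bc$buffer_m,
               n_fts = bc$sim_mean, loc_type = "simulated"))
  m1dat$loc_type <- factor(m1dat$loc_type, levels = c("simulated", "observed"))
  m1dat$buffer_m <- as.numeric(m1dat$buffer_m)
  spec1 <- model_spec("n_fts", c("loc_type", "buffer_m"), "group_id", "gaussian")
  m1_full <- fit_mixed(spec1, m1dat)
  m1_null <- fit_mixed(spec1, m1dat, drop_terms = "loc_type")
  out$model1 <- list(fit = m1_full, null = m1_null, lrt = lrt(m1_full, m1_null),
                     data = m1dat)

  ## model 2: log rate ~ usage frequency
  sr <- seg_rates[!seg_rates$group_id %in% exclude_groups, ]
  if (zero_rate_policy == "drop") {
    sr <- sr[sr$trees_per_m > 0, ]
    sr$log_rate <- log(sr$trees_per_m)
  } else {
    minpos <- min(sr$trees_per_m[sr$trees_per_m > 0])
    sr$log_rate <- log(sr$trees_per_m + minpos / 2)
  }
  sr$buffer_m <- as.numeric(sr$buffer_m)
  sr$weeks_used <- as.numeric(sr$weeks_used)
  spec2 <- model_spec("log_rate", c("weeks_used", "buffer_m"), "group_id",
                      "gaussian")
  m2_full <- fit_mixed(spec2, sr)
  m2_null <- fit_mixed(spec2, sr, drop_terms = "weeks_used")
  out$model2 <- list(fit = m2_full, null = m2_null, lrt = lrt(m2_full, m2_null),
                     data = sr)

  ## model 3 (both usage thresholds)
  q <- quadrats
  q$sqrt_slope <- sqrt(q$slope_deg)
  q$gap_presence <- as.numeric(q$gap_pct > 0)
  covs <- c("sqrt_slope", "rel_elevation", "ft_density")
  if (standardize) q <- standardize_covariates(q, covs)
  fixed3 <- c("sqrt_slope", "gap_presence", "rel_elevation", "ft_density",
              "rel_elevation:ft_density", "overlap_flag", "core_flag")
  controls <- c("overlap_flag", "core_flag")
  for (resp in c("route_ge2", "route_ge4")) {
    spec3 <- model_spec(resp, fixed3, "group_id", "binomial")
    opt <- optimize_D(spec3, q, D_grid = D_grid, coords = cbind(q$cx, q$cy))
    qd <- q; qd$ac_term <- opt$term
    # null: controls + autocorrelation term only, full random structure
    spec3n <- spec3
    spec3n$fixed <- c(controls, "ac_term")
    spec3n$random_slopes <- c(spec3$random_slopes, "ac_term")
    fit_null <- fit_mixed(spec3n, qd)
    full_lrt <- tryCatch(lrt(opt$fit, fit_null), error = function(e) NULL)
    spec3f <- spec3
    spec3f$fixed <- c(fixed3, "ac_term")
    spec3f$random_slopes <- c(spec3$random_slopes, "ac_term")
    d1 <- tryCatch(drop1_tests(spec3f, qd, keep = c(controls, "ac_term")),
                   error = function(e) NULL)
    fe_check <- NULL
    if (fixed_effects_check) {
      ff <- stats::as.formula(paste(resp, "~",
        paste(c(fixed3, "ac_term", "group_id"), collapse = " + ")))
      glmfit <- stats::glm(ff, data = qd, family = stats::binomial())
      shared <- intersect(names(stats::coef(glmfit)),
                          opt$fit$coefficients$term)
      sgn_mixed <- sign(opt$fit$coefficients$estimate[
        match(shared, opt$fit$coefficients$term)])
      sgn_fixed <- sign(stats::coef(glmfit)[shared])
      fe_check <- data.frame(term = shared,
                             sign_agrees = sgn_mixed == sgn_fixed)
    }
    out[[paste0("model3_", sub("route_", "", resp))]] <-
      list(fit = opt$fit, D = opt$D, profile = opt$profile, null = fit_null,
           lrt = full_lrt, drop1 = d1, fe_check = fe_check, data = qd)
  }

  out$report <- .models_report(out)
  class(out) <- "route_models"
  out
}

.models_report <- function(out) {
  rows <- list()
  for (id in c("model1", "model2", "model3_ge2", "model3_ge4")) {
    m <- out[[id]]
    if (is.null(m)) next
    cf <- m$fit$coefficients
    cf$model <- id
    cf$D <- if (!is.null(m$D)) m$D else NA
    if (!is.null(m$drop1)) {
      cf$p_lrt <- m$drop1$p[match(cf$term, m$drop1$term)]
    } else cf$p_lrt <- NA_real_
    rows[[id]] <- cf
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  rep
}

#' @export
print.route_models <- function(x, ...) {
  for (id in c("model1", "model2", "model3_ge2", "model3_ge4")) {
    m <- x[[id]]
    if (is.null(m)) next
    cat("==", id, "==\n")
    if (!is.null(m$lrt))
      cat(sprintf("  full vs null: chi2 = %.2f, df = %d, p = %.4g\n",
                  m$lrt$chi2, m$lrt$df, m$lrt$p))
    if (!is.null(m$D)) cat(sprintf("  autocorrelation kernel D = %g m\n", m$D))
    print(m$fit$coefficients, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
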