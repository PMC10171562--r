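# Random-intercept linear mixed model baseline (one model per tissue) and the
# drop-latest-scan Fisher-Rao holdout benchmark comparing it with RFPCA.

#' Fit a random-intercept linear mixed model
#'
#' Maximum-likelihood fit of `y_ij = a0 + a1 * t_ij + b_i + e_ij` with
#' subject-level random intercepts `b_i` (via `lme4::lmer`). Random slopes
#' are deliberately excluded: with mostly 1–2 visits per subject they are not
#' identifiable.
#'
#' @param times Observation times.
#' @param values Responses (e.g. one tissue proportion per scan).
#' @param subject_ids Subject identifier per observation.
#' @return List of class `lmm_fit`: `intercept`, `slope`, `var_intercept`,
#'   `var_resid`, and per-subject BLUP intercepts `blups`.
#' @export
fit_random_intercept_lmm <- function(times, values, subject_ids) {
  stopifnot(length(times) == length(values), length(values) == length(subject_ids))
  if (length(unique(subject_ids)) < 2) stop("need at least 2 subjects")
  if (length(values) < 3) stop("need at least 3 observations")
  if (stats::var(times) == 0) stop("all times identical: slope not identifiable")
  df <- data.frame(y = values, t = times, id = factor(subject_ids))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ t + (1 | id), data = df, REML = FALSE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate data (e.g. an exact line): ordinary least squares, zero
    # variance components
    ls <- stats::lm(y ~ t, data = df)
    co <- stats::coef(ls)
    bl <- setNames(rep(0, nlevels(df$id)), levels(df$id))
    return(structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                          var_intercept = 0, var_resid = max(mean(stats::residuals(ls)^2), 0),
                          blups = bl), class = "lmm_fit"))
  }
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_b <- vc$vcov[vc$grp == "id"][1]
  var_e <- stats::sigma(fit)^2
  re <- lme4::ranef(fit)$id
  bl <- setNames(re[["(Intercept)"]], rownames(re))
  structure(list(intercept = unname(fe[1]), slope = unname(fe[2]),
                 var_intercept = var_b, var_resid = var_e, blups = bl),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM: y = %.4g + %.4g t + b_i\n",
              x$intercept, x$slope))
  cat(sprintf("  var(b) = %.4g, var(resid) = %.4g, %d subjects\n",
              x$var_intercept, x$var_resid, length(x$blups)))
  invisible(x)
}

#' Predict from a random-intercept LMM given a subject history
#'
#' Returns `a0 + a1 * age + b_hat`, where the BLUP intercept is the shrunken
#' mean history residual `b_hat = sigma_b^2 * m / (sigma_b^2 * m +
#' sigma_e^2) * mean(r)`. An empty history predicts the population line.
#'
#' @param fit An `lmm_fit`.
#' @param history_times,history_values The subject's available observations
#'   (may be empty).
#' @param age Prediction time.
#' @return Predicted value.
#' @export
lmm_predict <- function(fit, history_times, history_values, age) {
  m <- length(history_times)
  b <- 0
  if (m > 0 && fit$var_intercept > 0) {
    r <- history_values - (fit$intercept + fit$slope * history_times)
    denom <- fit$var_intercept * m + fit$var_resid
    shrink <- if (denom > 0) fit$var_intercept * m / denom else 0
    b <- shrink * mean(r)
  }
  fit$intercept + fit$slope * age + b
}

# Compositions (rows sum to 1) for every pooled observation of a sample.
.pooled_compositions <- function(sample) {
  pool <- .pool_sample(sample)
  comp <- pool$obs^2
  comp <- comp / rowSums(comp)
  list(pool = pool, comp = comp)
}

# Maximum pairwise Fisher-Rao distance among all observed compositions:
# identical to the maximum geodesic distance between the observed sphere
# points.
.max_pairwise_fr <- function(obs) {
  G <- tcrossprod(obs)
  acos(.clip1(min(G)))
}

#' Drop-latest-scan holdout benchmark: RFPCA vs. LMM
#'
#' For every subject with at least `min_visits` scans, the latest observation
#' is dropped, both models are refit on the remaining data, and the dropped
#' composition is predicted: RFPCA through [predict_at_age()], the LMM
#' baseline through three per-tissue random-intercept models whose
#' predictions are floored at `1e-6` and renormalized to a composition.
#' Errors are Fisher–Rao distances to the held-out composition; the summary
#' scales the per-method average by the maximum pairwise Fisher–Rao distance
#' among all observed compositions.
#'
#' @param sample A [longitudinal_sample()].
#' @param options RFPCA fitting options; bandwidths are resolved once on the
#'   full sample and reused for every leave-one-out refit.
#' @param min_visits Minimum scans for eligibility (default 3).
#' @param progress Print one line per held-out subject.
#' @return List of class `prediction_benchmark`: per-subject table,
#'   per-method average and scaled average errors, and the scaling constant.
#' @export
holdout_benchmark <- function(sample, options = rfpca_options(),
                              min_visits = 3, progress = FALSE) {
  m <- lengths(sample$times)
  eligible <- which(m >= min_visits)
  if (length(eligible) == 0) stop("no subject has enough scans for the holdout")
  pc <- .pooled_compositions(sample)
  max_fr <- .max_pairwise_fr(pc$pool$obs)

  # resolve bandwidths once on the full sample so every refit shares them
  span <- diff(range(pc$pool$times))
  opts <- options
  if (is.null(opts$bw_mean)) opts$bw_mean <- 0.10 * span
  if (is.null(opts$bw_cov)) opts$bw_cov <- 0.20 * span
  if (is.null(opts$bw_noise)) opts$bw_noise <- 0.15 * span

  res <- data.frame(subject = character(0), age = numeric(0),
                    error_rfpca = numeric(0), error_lmm = numeric(0))
  for (i in eligible) {
    mi <- m[i]
    drop_j <- mi  # times are sorted; ties broken by input order (last wins)
    held_time <- sample$times[[i]][drop_j]
    held_comp <- as_composition(sample$obs[[i]][drop_j, ]^2, renormalize = TRUE)

    train <- sample
    train$times[[i]] <- sample$times[[i]][-drop_j]
    train$obs[[i]] <- sample$obs[[i]][-drop_j, , drop = FALSE]

    fit <- fit_rfpca(train, opts)
    pred_time <- min(max(held_time, fit$grid[1]), fit$grid[length(fit$grid)])
    pr <- predict_at_age(fit, train$times[[i]], train$obs[[i]], pred_time)
    err_r <- fisher_rao_distance(pr, held_comp)

    tp <- .pooled_compositions(train)
    lmm_pred <- numeric(3)
    for (d in 1:3) {
      lf <- fit_random_intercept_lmm(tp$pool$times, tp$comp[, d],
                                     train$ids[tp$pool$subject])
      hist_t <- train$times[[i]]
      hist_v <- train$obs[[i]][, d]^2 / rowSums(train$obs[[i]]^2)
      lmm_pred[d] <- lmm_predict(lf, hist_t, hist_v, held_time)
    }
    lmm_pred <- pmax(lmm_pred, 1e-6)
    lmm_comp <- lmm_pred / sum(lmm_pred)
    err_l <- fisher_rao_distance(lmm_comp, held_comp)

    res <- rbind(res, data.frame(subject = sample$ids[i], age = held_time,
                                 error_rfpca = err_r, error_lmm = err_l))
    if (progress)
      message(sprintf("held out %s @ %.2f: rfpca %.4f, lmm %.4f",
                      sample$ids[i], held_time, err_r, err_l))
  }
  structure(list(
    table = res,
    avg_error = c(rfpca = mean(res$error_rfpca), lmm = mean(res$error_lmm)),
    scaled_error = c(rfpca = mean(res$error_rfpca) / max_fr,
                     lmm = mean(res$error_lmm) / max_fr),
    max_pairwise_fr = max_fr,
    n_subjects = nrow(res)), class = "prediction_benchmark")
}

#' @export
print.prediction_benchmark <- function(x, ...) {
  cat(sprintf("Drop-latest-scan holdout benchmark (%d subjects)\n", x$n_subjects))
  cat(sprintf("  scaled Fisher-Rao error: RFPCA %.4f, LMM %.4f\n",
              x$scaled_error["rfpca"], x$scaled_error["lmm"]))
  cat(sprintf("  (average errors %.4f / %.4f, scaling constant %.4f)\n",
              x$avg_error["rfpca"], x$avg_error["lmm"], x$max_pairwise_fr))
  invisible(x)
}
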