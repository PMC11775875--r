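#' Fit a linear mixed model with participant random intercept
#'
#' REML fit of `value ~ <full factorial of fixed factors> + (1 |
#' participant)` via lme4, with F-tests per fixed term. Intensity (if
#' among the factors) is treated as an ordered 5-level factor so that
#' its contrasts are orthogonal polynomials. lme4 supplies no
#' denominator degrees of freedom; they are approximated by the residual
#' rule `n_obs - rank(X) - (n_participants - 1)` and reported, not
#' asserted. Effect size is partial eta-squared computed from F and the
#' dfs. A singular fit falls back to a fixed-effects ANOVA with a
#' warning.
#'
#' @param data data.frame in long format.
#' @param response name of the response column.
#' @param fixed character vector of fixed-factor columns.
#' @param participant name of the participant column.
#' @return object of class `fpvs_lmm`: `effects` (data.frame `term`,
#'   `F`, `df_num`, `df_den`, `p`, `partial_eta_sq`), `model`, `data`,
#'   `fixed`, `singular`.
#' @export
fit_lmm <- function(data, response = "value", fixed = c("emotion", "roi"),
                    participant = "participant") {
  stopifnot(all(c(response, fixed, participant) %in% names(data)))
  if (length(unique(data[[participant]])) < 2L)
    stop("need at least 2 participants for a mixed model")
  d <- data
  for (f in fixed)
    d[[f]] <- if (f == "intensity") factor(d[[f]], ordered = TRUE)
              else factor(d[[f]])
  d[[participant]] <- factor(d[[participant]])
  rhs <- paste(fixed, collapse = " * ")
  fml <- stats::as.formula(paste(response, "~", rhs,
                                 "+ (1 |", participant, ")"))
  m <- suppressMessages(lme4::lmer(fml, data = d, REML = TRUE))
  singular <- lme4::isSingular(m, tol = 1e-5)
  if (singular) {
    warning("singular mixed-model fit; falling back to fixed-effects ANOVA")
    m_fix <- stats::lm(stats::as.formula(paste(response, "~", rhs)), data = d)
    an <- stats::anova(m_fix)
    terms <- rownames(an)[rownames(an) != "Residuals"]
    df_den <- an["Residuals", "Df"]
    eff <- data.frame(term = terms, F = an[terms, "F value"],
                      df_num = an[terms, "Df"], df_den = df_den,
                      stringsAsFactors = FALSE)
  } else {
    an <- stats::anova(m)
    X <- lme4::getME(m, "X")
    df_den <- nrow(d) - qr(X)$rank -
      (length(unique(d[[participant]])) - 1L)
    df_den <- max(df_den, 1L)
    eff <- data.frame(term = rownames(an), F = an[, "F value"],
                      df_num = an[, "npar"], df_den = df_den,
                      stringsAsFactors = FALSE)
  }
  eff$p <- stats::pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE)
  eff$partial_eta_sq <- mapply(partial_eta_squared, eff$F, eff$df_num,
                               eff$df_den)
  rownames(eff) <- NULL
  structure(list(effects = eff, model = m, data = d, fixed = fixed,
                 participant = participant, response = response,
                 singular = singular),
            class = "fpvs_lmm")
}

#' @export
print.fpvs_lmm <- function(x, ...) {
  cat("<fpvs_lmm>", x$response, "~", paste(x$fixed, collapse = " * "),
      "+ (1 |", x$participant, ")\n")
  print(x$effects, digits = 3)
  invisible(x)
}

#' Partial eta-squared from an F statistic
#'
#' `F * df_num / (F * df_num + df_den)`: the proportion of
#' effect-plus-error variance attributable to the effect. Strictly
#' increasing in F for fixed dfs.
#'
#' @param F F statistic (>= 0).
#' @param df_num,df_den numerator / denominator degrees of freedom (> 0).
#' @return value in `[0, 1]`.
#' @examples
#' partial_eta_squared(6.09, 1, 225)  # 0.026
#' @export
partial_eta_squared <- function(F, df_num, df_den) {
  if (df_num <= 0 || df_den <= 0) stop("degrees of freedom must be positive")
  if (F < 0) stop("F must be non-negative")
  F * df_num / (F * df_num + df_den)
}

#' Orthogonal polynomial trend coefficients for 5 equally spaced levels
#'
#' @return matrix with rows `linear`, `quadratic`, `cubic`.
#' @export
trend_contrasts <- function() {
  rbind(linear = c(-2, -1, 0, 1, 2),
        quadratic = c(2, -1, -2, -1, 2),
        cubic = c(-1, 2, 0, -2, 1))
}

#' Polynomial trend contrasts over 5 intensity levels
#'
#' With a numeric vector of 5 per-intensity means, returns the contrast
#' estimates (no inference). With a data.frame (`participant`,
#' `intensity`, `value`), computes each participant's contrast score
#' (after averaging any replicate cells) and tests it against zero with
#' a one-sample t-test.
#'
#' @param x numeric vector of length 5, or data.frame with columns
#'   `participant`, `intensity`, `value`.
#' @param intensities the 5 expected levels, ascending.
#' @return data.frame: `trend`, `estimate`, `se`, `t`, `df`, `p` (the
#'   inferential columns are NA for vector input).
#' @export
polynomial_trends <- function(x, intensities = c(20, 40, 60, 80, 100)) {
  C <- trend_contrasts()
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 5L) stop("exactly 5 intensity levels required")
    return(data.frame(trend = rownames(C), estimate = as.numeric(C %*% x),
                      se = NA_real_, t = NA_real_, df = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE))
  }
  stopifnot(all(c("participant", "intensity", "value") %in% names(x)))
  if (!setequal(unique(x$intensity), intensities))
    stop("exactly 5 intensity levels required: ",
         paste(intensities, collapse = ", "))
  cell <- stats::aggregate(value ~ participant + intensity, data = x,
                           FUN = mean)
  wide <- stats::reshape(cell, idvar = "participant",
                         timevar = "intensity", direction = "wide")
  vals <- as.matrix(wide[, paste0("value.", intensities)])
  out <- lapply(rownames(C), function(tr) {
    sc <- as.numeric(vals %*% C[tr, ])
    tt <- stats::t.test(sc)
    data.frame(trend = tr, estimate = mean(sc),
               se = stats::sd(sc) / sqrt(length(sc)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tukey-corrected pairwise comparisons of a fixed factor
#'
#' Estimated marginal means are computed on a balanced grid of the fixed
#' factors from the model's fixed-effect coefficients; all pairwise
#' differences of the target factor's levels are tested with t
#' statistics (difference / SE from the coefficient covariance) and
#' p-values adjusted with the studentized range distribution (for 2
#' levels this reduces to the unadjusted two-sided p).
#'
#' @param fit an `fpvs_lmm`.
#' @param factor name of the fixed factor to compare.
#' @return data.frame: `level_1`, `level_2`, `estimate`, `se`, `t`,
#'   `df`, `p_tukey`.
#' @export
posthoc_pairwise <- function(fit, factor) {
  stopifnot(inherits(fit, "fpvs_lmm"), factor %in% fit$fixed)
  d <- fit$data
  grid <- expand.grid(lapply(fit$fixed, function(f) levels(d[[f]])),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- fit$fixed
  for (f in fit$fixed)
    grid[[f]] <- factor(grid[[f]], levels = levels(d[[f]]),
                        ordered = is.ordered(d[[f]]))
  rhs <- stats::as.formula(paste("~", paste(fit$fixed, collapse = " * ")))
  X <- stats::model.matrix(rhs, grid)
  beta <- if (inherits(fit$model, "merMod")) lme4::fixef(fit$model)
          else stats::coef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  X <- X[, names(beta), drop = FALSE]
  levs <- levels(d[[factor]])
  A <- t(vapply(levs, function(l)
    colMeans(X[grid[[factor]] == l, , drop = FALSE]), numeric(ncol(X))))
  df_den <- fit$effects$df_den[1]
  k <- length(levs)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(pr) {
    ct <- A[pr[1], ] - A[pr[2], ]
    est <- sum(ct * beta)
    se <- sqrt(drop(t(ct) %*% V %*% ct))
    tval <- est / se
    data.frame(level_1 = levs[pr[1]], level_2 = levs[pr[2]],
               estimate = est, se = se, t = tval, df = df_den,
               p_tukey = stats::ptukey(sqrt(2) * abs(tval), k, df_den,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize an emotion-recognition task trial table
#'
#' Accuracy per emotion x intensity cell (neutral trials are the
#' intensity-0 cell) and reaction-time statistics over correct,
#' non-timeout trials.
#'
#' @param trials data.frame from [simulate_ert()] (columns `emotion`,
#'   `intensity`, `correct`, `rt_s`, `timeout`).
#' @return data.frame: `emotion`, `intensity`, `n`, `accuracy`,
#'   `mean_rt`, `median_rt` (RT columns NA when no correct responses).
#' @export
ert_summarize <- function(trials) {
  stopifnot(all(c("emotion", "intensity", "correct") %in% names(trials)))
  cells <- unique(trials[, c("emotion", "intensity")])
  cells <- cells[order(cells$emotion, cells$intensity), ]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$emotion == cells$emotion[i] &
                    trials$intensity == cells$intensity[i], ]
    ok <- sub$correct & !sub$timeout & !is.na(sub$rt_s)
    data.frame(emotion = cells$emotion[i], intensity = cells$intensity[i],
               n = nrow(sub), accuracy = mean(sub$correct),
               mean_rt = if (any(ok)) mean(sub$rt_s[ok]) else NA_real_,
               median_rt = if (any(ok)) stats::median(sub$rt_s[ok])
                           else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
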