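# Inferential statistics on the compound exploration dimensions: a 2 x 3
# mixed repeated-measures ANCOVA (sex between, exploration type within, age
# as covariate) with Greenhouse-Geisser correction, Bonferroni post-hoc
# sex t-tests per type, Pearson age correlations, and a BIC-approximated
# Bayes factor for the absence of a sex-by-age interaction.

#' Exploration type labels
#' @return character vector of the three within-subject levels.
#' @export
exploration_types <- function() c("activity", "shape", "efficiency")

#' Join compound scores with participant metadata into long format
#'
#' @param scores compound-score data frame (`participant_id` + the three
#'   type columns).
#' @param meta metadata data frame (`participant_id`, `sex`, `age`).
#' @return long data frame with one row per participant x exploration type:
#'   `participant_id`, `sex`, `age`, `exploration_type`, `score`.
#'   Participants missing from the metadata are dropped with a warning.
#' @export
to_long <- function(scores, meta) {
  types <- intersect(exploration_types(), names(scores))
  if (length(types) != 3) {
    et_error("scores must contain the three exploration type columns",
             "et_contract_error")
  }
  missing_meta <- setdiff(scores$participant_id, meta$participant_id)
  if (length(missing_meta)) {
    et_warn(sprintf("%d participant(s) missing metadata dropped: %s",
                    length(missing_meta),
                    paste(head(missing_meta, 5), collapse = ", ")),
            "et_quality_warning")
    scores <- scores[!(scores$participant_id %in% missing_meta), ,
                     drop = FALSE]
  }
  meta_idx <- match(scores$participant_id, meta$participant_id)
  long <- do.call(rbind, lapply(types, function(tp) {
    data.frame(participant_id = scores$participant_id,
               sex = meta$sex[meta_idx],
               age = meta$age[meta_idx],
               exploration_type = tp,
               score = scores[[tp]],
               stringsAsFactors = FALSE)
  }))
  long$exploration_type <- factor(long$exploration_type,
                                  levels = exploration_types())
  long <- long[order(long$participant_id, long$exploration_type), ]
  rownames(long) <- NULL
  long
}

# long -> N x 3 score matrix plus per-participant sex/age vectors
long_to_wide <- function(data) {
  ids <- unique(data$participant_id)
  types <- exploration_types()
  y <- matrix(NA_real_, length(ids), 3,
              dimnames = list(ids, types))
  for (tp in types) {
    rows <- data[data$exploration_type == tp, ]
    y[match(rows$participant_id, ids), tp] <- rows$score
  }
  if (anyNA(y)) {
    et_error("each participant needs a complete set of 3 scores",
             "et_contract_error")
  }
  first <- data[!duplicated(data$participant_id), ]
  first <- first[match(ids, first$participant_id), ]
  list(y = y, sex = first$sex, age = first$age, ids = ids)
}

#' Mixed repeated-measures ANCOVA with Greenhouse-Geisser correction
#'
#' A 2 (sex, between) x 3 (exploration type, within) mixed ANCOVA with
#' grand-mean-centered age as a continuous covariate, computed via
#' orthonormal within-subject contrasts and Type III sums of squares.
#' Between-subject effects (sex, age, sex:age) are tested against the
#' between-subject error with `N - 4` denominator df; within effects
#' (type and its interactions) against the within error with
#' Greenhouse-Geisser corrected df, where
#' \eqn{\hat\epsilon = \mathrm{tr}(\tilde\Sigma)^2 /
#'   ((k-1)\,\mathrm{tr}(\tilde\Sigma^2))}
#' comes from the covariance of the contrast-transformed residuals.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data long scores from [to_long()].
#' @return data frame of effects: `effect`, `F`, `df_num`, `df_den`
#'   (GG-corrected for within effects), `p`, `partial_eta_sq`,
#'   `gg_epsilon` (`NA` for between effects).
#' @export
mixed_ancova <- function(data) {
  w <- long_to_wide(data)
  n <- nrow(w$y)
  sexes <- unique(w$sex)
  if (length(sexes) != 2 || min(table(w$sex)) < 2) {
    et_error("need at least 2 participants of each sex", "et_model_error")
  }
  s <- ifelse(w$sex == "male", 0.5, -0.5)      # effect coding
  a <- w$age - mean(w$age)                     # centered covariate
  x <- cbind(intercept = 1, sex = s, age = a, `sex:age` = s * a)
  if (qr(x)$rank < ncol(x)) {
    et_error("singular between-subjects design", "et_model_error")
  }
  xtx_inv <- solve(crossprod(x))
  df_err <- n - ncol(x)

  # orthonormal within-subject basis: unit vector + 2 normalized contrasts
  k <- 3
  m_between <- rep(1, k) / sqrt(k)
  m_within <- cbind(c(1, -1, 0) / sqrt(2), c(1, 1, -2) / sqrt(6))

  # between-subjects part: project scores on the unit contrast
  u <- drop(w$y %*% m_between)
  bu <- xtx_inv %*% crossprod(x, u)
  res_u <- u - drop(x %*% bu)
  sse_b <- sum(res_u^2)
  between <- lapply(c("sex", "age", "sex:age"), function(term) {
    j <- match(term, colnames(x))
    ss <- bu[j]^2 / xtx_inv[j, j]      # Type III SS for a single-df term
    f <- (ss / 1) / (sse_b / df_err)
    data.frame(effect = term, F = f, df_num = 1, df_den = df_err,
               p = pf(f, 1, df_err, lower.tail = FALSE),
               partial_eta_sq = ss / (ss + sse_b),
               gg_epsilon = NA_real_)
  })

  # within-subjects part: the two orthonormal type contrasts
  z <- w$y %*% m_within
  bz <- xtx_inv %*% crossprod(x, z)
  res_z <- z - x %*% bz
  sse_w <- sum(res_z^2)
  df_w_err <- (k - 1) * df_err
  sigma <- crossprod(res_z) / df_err
  eps <- sum(diag(sigma))^2 / ((k - 1) * sum(sigma^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  within_terms <- c(type = "intercept", `type:sex` = "sex",
                    `type:age` = "age", `type:sex:age` = "sex:age")
  within <- lapply(seq_along(within_terms), function(i) {
    j <- match(within_terms[i], colnames(x))
    ss <- sum(bz[j, ]^2) / xtx_inv[j, j]
    f <- (ss / (k - 1)) / (sse_w / df_w_err)
    data.frame(effect = names(within_terms)[i], F = f,
               df_num = (k - 1) * eps, df_den = df_w_err * eps,
               p = pf(f, (k - 1) * eps, df_w_err * eps,
                      lower.tail = FALSE),
               partial_eta_sq = ss / (ss + sse_w),
               gg_epsilon = eps)
  })
  out <- rbind(within[[1]], between[[1]], between[[2]], within[[2]],
               within[[3]], between[[3]], within[[4]])
  rownames(out) <- NULL
  out
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance. When the pooled variance is zero the
#' statistic is 0 (equal means) or signed infinity with `p = 0`
#' (degenerate separation), flagged via attribute `degenerate`.
#'
#' @param x,y numeric samples.
#' @return list with `t`, `df`, `p`, `mean_diff`, `pooled_sd`.
#' @export
two_sample_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) et_error("need >= 2 values per group",
                                 "et_contract_error")
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / df
  diff <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (diff == 0) {
      return(list(t = 0, df = df, p = 1, mean_diff = 0, pooled_sd = 0))
    }
    out <- list(t = sign(diff) * Inf, df = df, p = 0,
                mean_diff = diff, pooled_sd = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tval <- diff / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df),
       mean_diff = diff, pooled_sd = sqrt(sp2))
}

#' Post-hoc sex comparisons per exploration type
#'
#' Three independent pooled-variance t-tests (male vs female), one per
#' exploration type, with Bonferroni correction over the three contrasts.
#' `mean_diff` is male minus female.
#'
#' @param data long scores from [to_long()].
#' @return data frame: `exploration_type`, `t`, `df`, `p_raw`,
#'   `p_bonferroni`, `mean_diff`, `pooled_sd`.
#' @export
posthoc_sex_ttests <- function(data) {
  m <- 3
  rows <- lapply(exploration_types(), function(tp) {
    d <- data[data$exploration_type == tp, ]
    tt <- two_sample_t(d$score[d$sex == "male"],
                       d$score[d$sex == "female"])
    data.frame(exploration_type = tp, t = tt$t, df = tt$df,
               p_raw = tt$p, p_bonferroni = min(1, m * tt$p),
               mean_diff = tt$mean_diff, pooled_sd = tt$pooled_sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age correlations per exploration type
#'
#' Pearson correlation between age and each compound dimension, two-sided
#' p via \eqn{t = r\sqrt{(n-2)/(1-r^2)}}, Bonferroni over the three types.
#'
#' @param data long scores from [to_long()].
#' @return data frame: `exploration_type`, `r`, `n`, `p_raw`,
#'   `p_bonferroni`.
#' @export
age_correlations <- function(data) {
  m <- 3
  rows <- lapply(exploration_types(), function(tp) {
    d <- data[data$exploration_type == tp, ]
    ok <- is.finite(d$age) & is.finite(d$score)
    n <- sum(ok)
    r <- cor(d$age[ok], d$score[ok])
    p <- if (abs(r) >= 1) 0 else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tval), n - 2)
    }
    data.frame(exploration_type = tp, r = r, n = n, p_raw = p,
               p_bonferroni = min(1, m * p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' BIC-approximated Bayes factor against a sex-by-age interaction
#'
#' Compares the full fixed-effects model (type, sex, age and all their
#' interactions, random participant intercept) against the model without
#' any sex:age term (both `sex:age` and `type:sex:age` are dropped,
#' preserving model hierarchy), both fit by maximum likelihood with
#' `lme4::lmer`. `BF01 = exp((BIC_full - BIC_reduced) / 2)`: values above 1
#' favor the additive (no-interaction) model. This is the Schwarz
#' approximation to the Bayes factor, not a JZS-prior replication.
#'
#' @param data long scores from [to_long()].
#' @return the Bayes factor `BF01` (single number), with the two BIC values
#'   as attributes.
#' @export
bf01_sex_age_interaction <- function(data) {
  d <- data
  d$age_c <- d$age - mean(d$age[!duplicated(d$participant_id)])
  full <- lme4::lmer(
    score ~ exploration_type * sex * age_c + (1 | participant_id),
    data = d, REML = FALSE)
  reduced <- lme4::lmer(
    score ~ exploration_type + sex + age_c +
      exploration_type:sex + exploration_type:age_c +
      (1 | participant_id),
    data = d, REML = FALSE)
  bic_full <- stats::BIC(full)
  bic_reduced <- stats::BIC(reduced)
  structure(exp((bic_full - bic_reduced) / 2),
            bic_full = bic_full, bic_reduced = bic_reduced)
}

#' Run the full inferential stack
#'
#' @param data long scores from [to_long()].
#' @return list with `ancova`, `posthoc`, `correlations`, `bf01`, `n`.
#' @export
group_statistics <- function(data) {
  list(
    n = length(unique(data$participant_id)),
    ancova = mixed_ancova(data),
    posthoc = posthoc_sex_ttests(data),
    correlations = age_correlations(data),
    bf01 = as.numeric(bf01_sex_age_interaction(data)))
}
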