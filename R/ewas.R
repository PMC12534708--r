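# build the EWAS design matrix from the sample sheet; errors on aliasing
ewas_design <- function(sheet, covariates) {
  covariates <- intersect(covariates, names(sheet))
  present <- covariates[vapply(covariates, function(v) {
    x <- sheet[[v]]
    if (is.character(x) || is.factor(x)) length(unique(x[!is.na(x)])) > 1 else TRUE
  }, TRUE)]
  if (length(present) == 0) stop("no usable covariates")
  fml <- stats::as.formula(paste("~", paste(present, collapse = " + ")))
  df <- sheet
  for (v in present) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  X <- stats::model.matrix(fml, data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear design; aliased columns: ", paste(aliased, collapse = ", "))
  }
  X
}

#' Per-CpG linear EWAS with age, sex and tissue covariates
#'
#' Fits `beta ~ age + sex + tissue` (or the subset of those covariates
#' present and non-constant in the sheet) by ordinary least squares at
#' every CpG, with two-sided t-tests per coefficient and
#' Benjamini-Hochberg q-values computed separately within each coefficient
#' family. Categorical covariates are dummy-coded against their first
#' level. Probes with NA betas are fit on complete cases; probes with
#' fewer than rank(design) + 2 usable samples — or zero residual variance
#' (constant betas) — are emitted with NA p-values rather than spurious
#' zeros.
#'
#' @param bm beta matrix (probes x samples).
#' @param sheet sample sheet with `sample_id` and the covariates.
#' @param covariates character vector among "age", "sex", "tissue".
#' @return data.frame in long form: probe_id, term, estimate, se,
#'   t_statistic, p_value, q_value.
#' @export
fit_linear_ewas <- function(bm, sheet, covariates = c("age", "sex", "tissue")) {
  sheet <- sheet[match(colnames(bm), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("samples missing from sheet")
  X <- ewas_design(sheet, covariates)
  k <- ncol(X); n <- nrow(X)
  terms <- colnames(X)
  est <- se <- matrix(NA_real_, nrow(bm), k,
                      dimnames = list(rownames(bm), terms))
  dfree <- rep(NA_real_, nrow(bm))

  complete <- rowSums(is.na(bm)) == 0
  if (any(complete)) {
    qx <- qr(X)
    B <- qr.coef(qx, t(bm[complete, , drop = FALSE]))      # k x p
    fitted <- X %*% B
    resid <- t(bm[complete, , drop = FALSE]) - fitted
    s2 <- colSums(resid^2) / (n - k)
    xtx_inv_diag <- diag(chol2inv(qr.R(qx)))
    est[complete, ] <- t(B)
    se[complete, ] <- sqrt(outer(s2, xtx_inv_diag))
    dfree[complete] <- n - k
    # zero residual variance: keep estimates, mark SE as NA -> p NA
    zerovar <- which(complete)[s2 <= 1e-20]
    se[zerovar, ] <- NA_real_
  }
  for (i in which(!complete)) {
    ok <- !is.na(bm[i, ])
    if (sum(ok) < k + 2) next
    Xi <- X[ok, , drop = FALSE]
    if (qr(Xi)$rank < k) next
    fit <- lm.fit(Xi, bm[i, ok])
    s2 <- sum(fit$residuals^2) / (sum(ok) - k)
    est[i, ] <- fit$coefficients
    if (s2 > 1e-20) {
      se[i, ] <- sqrt(s2 * diag(chol2inv(qr.R(fit$qr))))
    }
    dfree[i] <- sum(ok) - k
  }
  tstat <- est / se
  pval <- 2 * pt(-abs(tstat), dfree)
  out <- do.call(rbind, lapply(seq_along(terms), function(j) {
    data.frame(probe_id = rownames(bm), term = terms[j],
               estimate = est[, j], se = se[, j], t_statistic = tstat[, j],
               p_value = pval[, j], row.names = NULL)
  }))
  qv <- stats::ave(out$p_value, out$term,
                   FUN = function(p) p.adjust(p, method = "BH"))
  out$q_value <- qv
  out
}

# mean-impute a features x samples matrix column-block using given means
impute_with_means <- function(m, means) {
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx) > 0) m[idx] <- means[idx[, 1]]
  m
}

# cv.glmnet warns when inner folds have < 3 observations and silently
# switches to grouped = FALSE; expected at LOOCV scale, so muted
quiet_cv_glmnet <- function(...) {
  withCallingHandlers(glmnet::cv.glmnet(...), warning = function(w) {
    if (grepl("grouped=FALSE", conditionMessage(w), fixed = TRUE)) {
      invokeRestart("muffleWarning")
    }
  })
}

train_clock_once <- function(bm, sheet, n_features, alpha, inner_folds,
                             fold_seed, covariates) {
  ew <- fit_linear_ewas(bm, sheet, covariates)
  age_p <- ew[ew$term == "age", ]
  age_p <- age_p[!is.na(age_p$p_value), ]
  age_p <- age_p[order(age_p$p_value, age_p$probe_id), ]
  n_take <- min(n_features, nrow(age_p))
  if (n_take < n_features) {
    warning("only ", n_take, " usable CpGs for clock feature selection")
  }
  feats <- age_p$probe_id[seq_len(n_take)]
  sub <- bm[feats, order(colnames(bm)), drop = FALSE]  # sample-order invariant folds
  means <- rowMeans(sub, na.rm = TRUE)
  x <- t(impute_with_means(sub, means))
  y <- sheet$age[match(rownames(x), sheet$sample_id)]
  set.seed(fold_seed)
  foldid <- sample(rep_len(seq_len(inner_folds), nrow(x)))
  cv <- quiet_cv_glmnet(x, y, alpha = alpha, foldid = foldid,
                        family = "gaussian")
  co <- as.matrix(coef(cv, s = "lambda.min"))
  list(intercept = co[1, 1],
       weights = setNames(co[-1, 1], rownames(co)[-1]),
       lambda = cv$lambda.min, alpha = alpha,
       training_means = means, features = feats,
       transform = "identity")
}

#' Leave-one-out cross-validated elastic-net age clock
#'
#' For each held-out sample, an EWAS (`beta ~ age + sex + tissue`) is run
#' on the remaining samples only; the `n_features` CpGs with the smallest
#' age p-values (ties broken by probe ID) are selected and an elastic net
#' (`alpha`, penalty chosen by `inner_folds`-fold cross-validation
#' minimizing squared error, lambda.min) is trained on their betas to
#' predict age. Feature selection happens strictly inside each fold — no
#' information from the held-out sample touches selection or fitting.
#' Fold RNG is seeded from (seed, held-out sample ID), so results are
#' invariant to sample ordering. The final model is retrained on all
#' samples by the same recipe.
#'
#' @param bm beta matrix.
#' @param sheet sample sheet with non-NA `age` for all samples.
#' @param n_features CpGs selected per fold (default 50).
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param inner_folds inner CV folds for the penalty (default 10).
#' @param seed global seed (mandatory).
#' @param covariates EWAS covariates for feature selection.
#' @param select_in_fold internal switch used to demonstrate selection
#'   leakage; keep TRUE for valid estimates.
#' @return list with `predictions` (data.frame sample_id, age, predicted),
#'   `mae`, `pearson_r`, and `model` (a clock model usable by
#'   [apply_clock()]).
#' @export
loocv_clock <- function(bm, sheet, n_features = 50, alpha = 0.5,
                        inner_folds = 10, seed,
                        covariates = c("age", "sex", "tissue"),
                        select_in_fold = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  sheet <- sheet[match(colnames(bm), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$age)) stop("all samples need a non-NA age")
  if (ncol(bm) < 10) stop("need >= 10 samples for LOOCV")
  leak_feats <- NULL
  if (!select_in_fold) {
    # leakage demonstration: select features once, on all samples
    ew <- fit_linear_ewas(bm, sheet, covariates)
    ap <- ew[ew$term == "age" & !is.na(ew$p_value), ]
    ap <- ap[order(ap$p_value, ap$probe_id), ]
    leak_feats <- ap$probe_id[seq_len(min(n_features, nrow(ap)))]
  }
  ids <- sort(colnames(bm))
  preds <- setNames(rep(NA_real_, length(ids)), ids)
  for (s in ids) {
    train <- setdiff(colnames(bm), s)
    btr <- bm[, train, drop = FALSE]
    str <- sheet[sheet$sample_id %in% train, , drop = FALSE]
    if (!select_in_fold) {
      sub <- btr[leak_feats, order(colnames(btr)), drop = FALSE]
      means <- rowMeans(sub, na.rm = TRUE)
      x <- t(impute_with_means(sub, means))
      y <- str$age[match(rownames(x), str$sample_id)]
      set.seed(derive_seed(seed, s))
      foldid <- sample(rep_len(seq_len(inner_folds), nrow(x)))
      cv <- quiet_cv_glmnet(x, y, alpha = alpha, foldid = foldid)
      newx <- matrix(impute_with_means(bm[leak_feats, s, drop = FALSE], means),
                     nrow = 1, dimnames = list(s, leak_feats))
      preds[s] <- as.numeric(predict(cv, newx = newx, s = "lambda.min"))
    } else {
      mod <- train_clock_once(btr, str, n_features, alpha, inner_folds,
                              derive_seed(seed, s), covariates)
      newx <- matrix(impute_with_means(bm[mod$features, s, drop = FALSE],
                                       mod$training_means),
                     nrow = 1, dimnames = list(s, mod$features))
      preds[s] <- mod$intercept + sum(mod$weights[mod$features] * newx[1, ])
    }
  }
  age <- sheet$age[match(ids, sheet$sample_id)]
  model <- train_clock_once(bm, sheet, n_features, alpha, inner_folds,
                            derive_seed(seed, "final"), covariates)
  list(predictions = data.frame(sample_id = ids, age = age,
                                predicted = unname(preds)),
       mae = mean(abs(preds - age)),
       pearson_r = cor(preds, age),
       model = model)
}

#' Apply a clock model to a beta matrix
#'
#' Prediction is `intercept + sum_i w_i beta_i` after resolving probes
#' absent from the matrix by the missing policy: "error" stops and lists
#' them; "mean_impute" substitutes the model's stored training means;
#' "neighbor_map" first projects the matrix onto the model's probe space
#' via [substitute_betas()] with the supplied map, then mean-imputes any
#' remaining gaps. NA cells of present probes are always filled with
#' training means. If the model carries an invertible response transform,
#' its inverse is applied to the linear predictor.
#'
#' @param bm beta matrix.
#' @param model clock model (from [loocv_clock()], or a list with
#'   `weights`, `intercept`, optionally `training_means`, `features`,
#'   `inverse_transform`).
#' @param missing_policy one of "error", "mean_impute", "neighbor_map".
#' @param map neighbor map for the "neighbor_map" policy.
#' @return named numeric vector of per-sample predictions.
#' @export
apply_clock <- function(bm, model,
                        missing_policy = c("error", "mean_impute", "neighbor_map"),
                        map = NULL) {
  missing_policy <- match.arg(missing_policy)
  feats <- model$features %||% names(model$weights)
  w <- model$weights[feats]
  absent <- setdiff(feats, rownames(bm))
  if (missing_policy == "error" && length(absent) > 0) {
    stop("clock probes absent: ", paste(head(absent, 5), collapse = ", "))
  }
  if (missing_policy == "neighbor_map") {
    if (is.null(map)) stop("neighbor_map policy requires a map")
    sub <- substitute_betas(bm, map, feats)
    m <- sub$betas
  } else {
    m <- matrix(NA_real_, length(feats), ncol(bm),
                dimnames = list(feats, colnames(bm)))
    present <- intersect(feats, rownames(bm))
    m[present, ] <- bm[present, , drop = FALSE]
  }
  means <- model$training_means[feats]
  if (is.null(means) && anyNA(m)) stop("model lacks training means for imputation")
  if (!is.null(means)) m <- impute_with_means(m, means)
  pred <- model$intercept + as.numeric(t(m) %*% w)
  if (!is.null(model$inverse_transform)) pred <- model$inverse_transform(pred)
  setNames(pred, colnames(bm))
}

#' Sex score from sex-associated CpG sets
#'
#' Score = mean beta over male-hypermethylated CpGs minus mean beta over
#' male-hypomethylated CpGs (non-NA probes only); a sample is called male
#' when the score strictly exceeds the threshold — a score exactly at the
#' boundary is called female.
#'
#' @param bm beta matrix.
#' @param male_hyper,male_hypo probe ID sets (intersected with the matrix).
#' @param threshold decision boundary (default 0).
#' @return data.frame (sample_id, score, predicted_sex).
#' @export
sex_score <- function(bm, male_hyper, male_hypo, threshold = 0) {
  hyper <- intersect(male_hyper, rownames(bm))
  hypo <- intersect(male_hypo, rownames(bm))
  if (length(hyper) == 0 && length(hypo) == 0) {
    stop("no sex-associated probes present in the matrix")
  }
  mh <- if (length(hyper) > 0) colMeans(bm[hyper, , drop = FALSE], na.rm = TRUE) else 0
  ml <- if (length(hypo) > 0) colMeans(bm[hypo, , drop = FALSE], na.rm = TRUE) else 0
  score <- mh - ml
  data.frame(sample_id = colnames(bm), score = as.numeric(score),
             predicted_sex = ifelse(score > threshold, "M", "F"),
             row.names = NULL)
}
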