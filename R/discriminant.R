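# Two-class stepwise linear discriminant analysis.
#
# The canonical discriminant value (DV) is the Fisher direction
# w = Sw^-1 (mu_African - mu_Asian) on the selected ratios, scaled to unit
# pooled within-class variance and centred so the grand mean maps to 0.
# Stepwise selection minimises Wilks' lambda with the classic
# F-to-enter / F-to-remove rules.

# Wilks' lambda det(W)/det(T) for a column subset; W, T are the within-group
# and total cross-product matrices of the full feature set.
wilks_lambda <- function(W, T, idx) {
  if (!length(idx)) return(1)
  dW <- det(W[idx, idx, drop = FALSE])
  dT <- det(T[idx, idx, drop = FALSE])
  if (!is.finite(dW) || !is.finite(dT) || dT <= 0) return(NA_real_)
  max(dW / dT, 0)
}

crossprod_matrices <- function(X, y) {
  lv <- levels(y)
  Xc_t <- sweep(X, 2, colMeans(X))
  T <- crossprod(Xc_t)
  W <- matrix(0, ncol(X), ncol(X))
  for (l in lv) {
    Xl <- X[y == l, , drop = FALSE]
    W <- W + crossprod(sweep(Xl, 2, colMeans(Xl)))
  }
  list(W = W, T = T)
}

# Forward-backward stepwise selection by Wilks' lambda (two groups).
stepwise_select <- function(X, y, f_enter = 3.84, f_remove = 2.71,
                            max_steps = 200) {
  n <- nrow(X); g <- 2L
  cp <- crossprod_matrices(X, y)
  included <- integer(0)
  lambda <- 1
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    p <- length(included)
    # entry: largest partial F among excluded candidates
    cand <- setdiff(seq_len(ncol(X)), included)
    if (length(cand) && n - g - p > 0) {
      lam_new <- vapply(cand, function(j)
        wilks_lambda(cp$W, cp$T, c(included, j)), numeric(1))
      F_in <- (n - g - p) / (g - 1) * (lambda / lam_new - 1)
      F_in[!is.finite(F_in)] <- -Inf
      if (any(F_in > f_enter)) {
        j <- cand[which.max(F_in)]       # ties: which.max takes lowest index
        included <- c(included, j)
        lambda <- wilks_lambda(cp$W, cp$T, included)
        changed <- TRUE
      }
    }
    # removal: smallest partial F among included (never the one just added)
    p <- length(included)
    if (p > 1) {
      lam_wo <- vapply(seq_len(p), function(k)
        wilks_lambda(cp$W, cp$T, included[-k]), numeric(1))
      F_out <- (n - g - p + 1) / (g - 1) * (lam_wo / lambda - 1)
      F_out[!is.finite(F_out)] <- Inf
      drop_ok <- rep(TRUE, p)
      if (changed) drop_ok[p] <- FALSE        # protect the newest entry
      worst <- which(F_out == min(F_out[drop_ok]) & drop_ok)[1]
      if (F_out[worst] < f_remove) {
        included <- included[-worst]
        lambda <- wilks_lambda(cp$W, cp$T, included)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(included)
}

fisher_direction <- function(X, y, ridge = 0) {
  lv <- levels(y)
  n <- nrow(X)
  mu1 <- colMeans(X[y == lv[1], , drop = FALSE])
  mu2 <- colMeans(X[y == lv[2], , drop = FALSE])
  Sw <- crossprod_matrices(X, y)$W / (n - 2)
  if (ridge > 0) Sw <- Sw + diag(ridge, ncol(Sw))
  w <- tryCatch(solve(Sw, mu2 - mu1), error = function(err) NULL)
  if (is.null(w)) {
    eps <- 1e-6 * mean(diag(Sw))
    warning("singular within-class scatter; ridge-regularised")
    w <- solve(Sw + diag(eps, ncol(Sw)), mu2 - mu1)
  }
  # unit pooled within-class variance of the DV
  s2 <- drop(crossprod(w, Sw %*% w))
  if (s2 > 0) w <- w / sqrt(s2)
  w
}

#' Fit a (stepwise) linear discriminant function on ratio features
#'
#' Two-class canonical discriminant analysis of species on element-ratio
#' features. With \code{stepwise = TRUE}, ratios are selected by forward-
#' backward minimisation of Wilks' lambda with F-to-enter/F-to-remove
#' thresholds; the final discriminant value is the Fisher direction on the
#' selected ratios, signed so that the African centroid is positive and
#' centred so the grand mean scores 0.
#'
#' @param features A [build_ratios()] object, or a numeric matrix.
#' @param labels Species labels ("Asian"/"African") for the feature rows;
#'   defaults to the labels carried by \code{features}.
#' @param stepwise Run stepwise selection (default) or use all features.
#' @param f_enter,f_remove Partial-F thresholds (classic defaults 3.84/2.71).
#' @param loo Leave-one-out evaluation: \code{"stepwise"} re-runs selection
#'   in every fold (honest, default), \code{"fixed"} freezes the selected
#'   set, \code{"none"} skips LOO.
#' @return Object of class \code{discriminant_model}: selected features,
#'   canonical coefficients and constant, eigenvalue (between/within SS
#'   ratio of the DV), group DV centroids, LOO accuracy and confusion.
#' @export
fit_stepwise_lda <- function(features, labels = NULL, stepwise = TRUE,
                             f_enter = 3.84, f_remove = 2.71,
                             loo = c("stepwise", "fixed", "none")) {
  loo <- match.arg(loo)
  X <- if (inherits(features, "ratio_features")) features$features else
    as.matrix(features)
  if (is.null(labels) && inherits(features, "ratio_features"))
    labels <- features$species
  y <- factor(labels, levels = c("Asian", "African"))
  if (any(is.na(y))) stop("labels must be 'Asian' or 'African'")
  if (nrow(X) != length(y)) stop("feature rows and labels differ in length")
  if (min(table(y)) < 2) stop("need at least 2 specimens per species")
  keep <- apply(X, 2, stats::var) > 0
  if (!all(keep)) X <- X[, keep, drop = FALSE]
  if (!ncol(X)) stop("no non-constant features")

  sel <- if (stepwise) stepwise_select(X, y, f_enter, f_remove)
         else seq_len(ncol(X))
  if (!length(sel)) {
    warning("stepwise selection admitted no feature; using the single best")
    cp <- crossprod_matrices(X, y)
    lam <- vapply(seq_len(ncol(X)), function(j) wilks_lambda(cp$W, cp$T, j),
                  numeric(1))
    sel <- which.min(lam)
  }
  Xs <- X[, sel, drop = FALSE]
  w <- fisher_direction(Xs, y)
  b <- -drop(colMeans(Xs) %*% w)
  dv <- drop(Xs %*% w) + b
  mu_dv <- tapply(dv, y, mean)
  ss_b <- sum(tapply(dv, y, length) * (mu_dv - mean(dv))^2)
  ss_w <- sum((dv - mu_dv[y])^2)
  model <- structure(
    list(selected_features = colnames(Xs),
         coefficients = stats::setNames(w, colnames(Xs)),
         constant = b,
         eigenvalue = ss_b / ss_w,
         group_means_dv = mu_dv,
         threshold_dv = mean(mu_dv),    # equal-prior midpoint rule
         n_valid = nrow(Xs),
         stepwise = stepwise, f_enter = f_enter, f_remove = f_remove),
    class = "discriminant_model"
  )
  if (loo != "none") {
    cv <- loo_classify(X, y, stepwise = stepwise && loo == "stepwise",
                       f_enter = f_enter, f_remove = f_remove,
                       fixed_features = if (loo == "fixed") colnames(Xs))
    model$loo_accuracy <- cv$accuracy
    model$loo_confusion <- cv$confusion
  }
  model
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("Two-class discriminant function\n")
  cat(sprintf("  %d ratio(s): %s\n", length(x$selected_features),
              paste(x$selected_features, collapse = ", ")))
  cat(sprintf("  eigenvalue %.3f; centroids Asian %.2f / African %.2f\n",
              x$eigenvalue, x$group_means_dv[["Asian"]],
              x$group_means_dv[["African"]]))
  if (!is.null(x$loo_accuracy))
    cat(sprintf("  leave-one-out accuracy %.1f%% (n = %d)\n",
                100 * x$loo_accuracy, x$n_valid))
  invisible(x)
}

#' Discriminant values and nearest-centroid classes for new specimens
#'
#' @param object A \code{discriminant_model}.
#' @param newdata Matrix/data.frame containing the selected ratio columns,
#'   or a \code{ratio_features} object.
#' @param ... Unused.
#' @return data.frame with \code{dv} and \code{class} (midpoint rule,
#'   African side positive).
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "ratio_features")) newdata$features else
    as.matrix(newdata)
  miss <- setdiff(object$selected_features, colnames(X))
  if (length(miss))
    stop("newdata lacks selected feature(s): ", paste(miss, collapse = ", "))
  dv <- drop(X[, object$selected_features, drop = FALSE] %*%
               object$coefficients) + object$constant
  data.frame(dv = dv,
             class = ifelse(dv >= object$threshold_dv, "African", "Asian"),
             stringsAsFactors = FALSE)
}

#' Leave-one-out classification ("successive discrimination")
#'
#' Each specimen is classified by the nearest-centroid (midpoint) rule on a
#' discriminant function fitted without it; by default stepwise selection is
#' re-run inside every fold.
#'
#' @param features Matrix or \code{ratio_features}.
#' @param labels Species labels (taken from \code{features} when omitted).
#' @param stepwise Re-run stepwise selection per fold.
#' @param f_enter,f_remove Stepwise thresholds.
#' @param fixed_features Optional fixed feature set (overrides stepwise).
#' @return List with \code{accuracy} and a 2x2 \code{confusion} table
#'   (rows = truth, cols = prediction).
#' @export
loo_classify <- function(features, labels = NULL, stepwise = TRUE,
                         f_enter = 3.84, f_remove = 2.71,
                         fixed_features = NULL) {
  X <- if (inherits(features, "ratio_features")) features$features else
    as.matrix(features)
  if (is.null(labels) && inherits(features, "ratio_features"))
    labels <- features$species
  y <- factor(labels, levels = c("Asian", "African"))
  n <- nrow(X)
  pred <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (min(table(yi)) < 2) {
      warning("fold ", i, " skipped: a species has fewer than 2 specimens")
      next
    }
    Xi <- X[-i, , drop = FALSE]
    keep <- apply(Xi, 2, stats::var) > 0
    Xi <- Xi[, keep, drop = FALSE]
    sel <- if (!is.null(fixed_features)) {
      intersect(fixed_features, colnames(Xi))
    } else if (stepwise) {
      s <- stepwise_select(Xi, yi, f_enter, f_remove)
      if (!length(s)) colnames(Xi) else colnames(Xi)[s]
    } else colnames(Xi)
    Xs <- Xi[, sel, drop = FALSE]
    w <- fisher_direction(Xs, yi)
    b <- -drop(colMeans(Xs) %*% w)
    mu <- tapply(drop(Xs %*% w) + b, yi, mean)
    dv_i <- drop(X[i, sel, drop = FALSE] %*% w) + b
    pred[i] <- if (dv_i >= mean(mu)) "African" else "Asian"
  }
  ok <- !is.na(pred)
  confusion <- table(truth = y[ok],
                     prediction = factor(pred[ok], levels = c("Asian", "African")))
  list(accuracy = mean(pred[ok] == as.character(y[ok])), confusion = confusion)
}

#' Compare discriminant functions across ratio denominators
#'
#' Builds one discriminant function per candidate denominator (including
#' \code{"none"}, raw ppm, and \code{"combined"}, pooled ratios) and reports
#' the trade-off columns: valid data %, eigenvalue, number of ratios used,
#' and leave-one-out accuracy.
#'
#' @param panels Specimen panels with species labels.
#' @param denominators Character vector of denominators to compare.
#' @param loo \code{"stepwise"} (honest, slower) or \code{"fixed"}.
#' @return data.frame, one row per denominator; failed rows carry NA and a
#'   \code{note}.
#' @export
compare_denominators <- function(panels,
                                 denominators = c("none", "Zr", "P", "Ag",
                                                  "Cd", "Sn", "Sb", "combined"),
                                 loo = c("stepwise", "fixed")) {
  loo <- match.arg(loo)
  rows <- lapply(denominators, function(d) {
    res <- tryCatch({
      rf <- build_ratios(panels, d)
      m <- fit_stepwise_lda(rf, loo = loo)
      data.frame(denominator = d, valid_pct = 100 * rf$valid_fraction,
                 eigenvalue = m$eigenvalue,
                 n_ratios = length(m$selected_features),
                 loo_pct = 100 * m$loo_accuracy,
                 note = "", stringsAsFactors = FALSE)
    }, error = function(err)
      data.frame(denominator = d, valid_pct = NA_real_, eigenvalue = NA_real_,
                 n_ratios = NA_integer_, loo_pct = NA_real_,
                 note = conditionMessage(err), stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, rows)
}
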