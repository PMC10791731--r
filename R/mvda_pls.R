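## Batch-level multivariate analysis -----------------------------------------
##
## Decomposes the qualified culture dataset into a batch-level matrix (one
## row per batch, variables unfolded across post-feeding timepoints), fits a
## NIPALS PLS1 regression of the normalized final titer on it, and ranks
## nutrients by the sum of their regression coefficients at VIP-significant
## timepoints — the screen for residual nutrients consistently associated
## with higher or lower final titer.

#' Unfold a culture set into a batch-level matrix
#'
#' One row per batch; columns are (variable, day) pairs over the
#' post-feeding timepoints. The response is the final-day titer normalized
#' to the maximum final titer across batches. Zero-variance columns are
#' dropped with a message.
#'
#' @param set a `culture_set` (after outlier filtering).
#' @param days timepoints to unfold (default the post-feeding sampling days
#'   4, 5, 6, 7, 8, 10, 12, 14).
#' @param variables variables to include (default: all measured at those
#'   days, i.e. VCD, viability, titer and metabolite concentrations).
#' @return list (class `batch_level_matrix`): `X` (batches x columns),
#'   `y` (normalized final titer), `columns` (variable, day per column),
#'   `batch_ids`, `condition_ids`.
#' @export
unfold_batch_level <- function(set, days = c(4, 5, 6, 7, 8, 10, 12, 14),
                               variables = NULL) {
  m <- set$measurements
  if (is.null(variables)) {
    at_days <- unique(m$variable[m$day %in% days])
    variables <- at_days[vapply(at_days, function(v)
      all(days %in% m$day[m$variable == v]), TRUE)]
  }
  batches <- unique(m$batch_id)
  cols <- expand.grid(day = days, variable = variables,
                      stringsAsFactors = FALSE)[, c("variable", "day")]
  X <- matrix(NA_real_, length(batches), nrow(cols),
              dimnames = list(batches,
                              paste0(cols$variable, "@d", cols$day)))
  for (b in seq_along(batches)) {
    mb <- m[m$batch_id == batches[b], ]
    for (j in seq_len(nrow(cols))) {
      v <- mb$value[mb$variable == cols$variable[j] & mb$day == cols$day[j]]
      if (length(v)) X[b, j] <- v[1]
    }
  }
  if (anyNA(X)) {
    gaps <- which(is.na(X), arr.ind = TRUE)
    stop("missing (variable, day) cells, e.g. ",
         paste(utils::head(colnames(X)[unique(gaps[, 2])], 5), collapse = ", "))
  }
  final_day <- max(m$day[m$variable == "titer"])
  y_raw <- vapply(batches, function(b)
    m$value[m$batch_id == b & m$variable == "titer" & m$day == final_day][1],
    numeric(1))
  y <- y_raw / max(y_raw)
  keep <- apply(X, 2, stats::sd) > 0
  if (any(!keep))
    message("dropping zero-variance columns: ",
            paste(colnames(X)[!keep], collapse = ", "))
  cond <- vapply(batches, function(b) m$condition_id[m$batch_id == b][1], "")
  structure(list(X = X[, keep, drop = FALSE], y = y,
                 columns = cols[keep, , drop = FALSE],
                 batch_ids = batches, condition_ids = cond),
            class = "batch_level_matrix")
}

#' Fit a PLS1 regression by NIPALS
#'
#' X and y are autoscaled (mean-centered, unit variance); components are
#' extracted by NIPALS with deflation of X after each component
#' (convergence when the weight change drops below 1e-10, cap 500
#' iterations; for a single response NIPALS converges in one pass).
#' Regression coefficients are reported in autoscaled space so sums across
#' differently scaled variables are comparable.
#'
#' @param M a `batch_level_matrix`, or a plain matrix (then `y` must be
#'   given).
#' @param ncomp number of components; `NULL` selects by leave-one-out
#'   cross-validated Q2, capped at `max_ncomp`.
#' @param y response vector (when `M` is a matrix).
#' @param max_ncomp cap for automatic component selection (default 5).
#' @return object of class `pls_model`: weights `W`, loadings `P`, scores
#'   `T`, y-loadings `q`, autoscaled coefficients `b`, per-component
#'   explained y-variance `ssy`, scaling vectors, `vip`.
#' @export
fit_pls <- function(M, ncomp = NULL, y = NULL, max_ncomp = 5) {
  if (inherits(M, "batch_level_matrix")) { X <- M$X; y <- M$y } else X <- M
  if (is.null(y)) stop("y required")
  n <- nrow(X); p <- ncol(X)
  if (is.null(ncomp)) {
    cap <- min(max_ncomp, n - 2, p)
    q2 <- vapply(seq_len(cap), function(a) loo_q2(X, y, a), numeric(1))
    ncomp <- which.max(q2)
  }
  if (ncomp > min(n - 1, p)) stop("too many components for the data")
  fit <- nipals_pls1(scale(X), as.numeric(scale(y)), ncomp)
  fit$x_center <- colMeans(X); fit$x_scale <- apply(X, 2, stats::sd)
  fit$y_center <- mean(y); fit$y_scale <- stats::sd(y)
  fit$ncomp <- ncomp
  fit$vip <- vip_scores(fit)
  class(fit) <- "pls_model"
  fit
}

nipals_pls1 <- function(X, y, ncomp, tol = 1e-10, max_iter = 500) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp); ssy <- numeric(ncomp)
  Xa <- X; ya <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xa, ya); w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      t_ <- Xa %*% w
      w_new <- crossprod(Xa, ya)          # PLS1: weight fixed by y
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
      w <- w_new
    }
    t_ <- as.numeric(Xa %*% w); tt <- sum(t_^2)
    p_ <- as.numeric(crossprod(Xa, t_)) / tt
    q_ <- sum(ya * t_) / tt
    Xa <- Xa - tcrossprod(t_, p_)
    ya <- ya - t_ * q_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
    ssy[a] <- q_^2 * tt
  }
  R <- W %*% solve(crossprod(P, W))
  b <- as.numeric(R %*% q)
  names(b) <- colnames(X)
  list(W = W, P = P, T = Tm, q = q, b = b, ssy = ssy,
       r2y = cumsum(ssy) / sum(y^2), columns_names = colnames(X))
}

loo_q2 <- function(X, y, ncomp) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    sdx <- apply(Xi, 2, stats::sd)
    keep <- sdx > 0
    f <- nipals_pls1(scale(Xi[, keep, drop = FALSE]), as.numeric(scale(yi)),
                     min(ncomp, n - 3, sum(keep)))
    xs <- (X[i, keep] - colMeans(Xi[, keep, drop = FALSE])) / sdx[keep]
    pred <- sum(xs * f$b) * stats::sd(yi) + mean(yi)
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model: ", x$ncomp, " component(s), cumulative R2Y = ",
      round(max(x$r2y), 4), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix with the model's columns.
#' @param ... unused.
#' @return predicted response on the original scale.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  as.numeric(xs %*% object$b) * object$y_scale + object$y_center
}

#' Variable influence on projection (VIP) scores
#'
#' Wold VIP: `VIP_j = sqrt(p * sum_a(SSY_a (w_ja/||w_a||)^2) / sum_a SSY_a)`
#' where `SSY_a` is the y-variance explained by component `a`. Squared VIPs
#' average to exactly 1 over columns.
#'
#' @param model a `pls_model`.
#' @return named numeric vector of VIP scores per column.
#' @export
vip_scores <- function(model) {
  W <- model$W; ssy <- model$ssy
  p <- nrow(W)
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  v <- sqrt(p * as.numeric(wn^2 %*% ssy) / sum(ssy))
  names(v) <- model$columns_names
  v
}

#' Coefficient-sum nutrient ranking
#'
#' For each variable, sums the autoscaled regression coefficients over the
#' timepoints whose columns reach the VIP threshold, then ranks variables by
#' the signed sum (most negative first) or by magnitude. Variables with no
#' significant timepoint are omitted; an empty ranking gives a warning.
#'
#' @param model a `pls_model` fitted on a batch-level matrix.
#' @param columns the `columns` data.frame of the batch-level matrix (or
#'   taken from `model` names `variable@dday`).
#' @param vip_threshold VIP significance cut (default 1.00).
#' @param by rank by `"signed"` sum ascending (most negative first) or by
#'   `"magnitude"` descending.
#' @param exclude variables to leave out of the ranking (default the
#'   non-nutrient profile variables).
#' @return data.frame (class `nutrient_ranking`): variable, coef_sum,
#'   n_significant, rank; ties broken lexicographically.
#' @export
coefficient_sum_ranking <- function(model, columns = NULL,
                                    vip_threshold = 1.00,
                                    by = c("signed", "magnitude"),
                                    exclude = c("VCD", "viability", "titer")) {
  by <- match.arg(by)
  if (is.null(columns)) {
    nm <- model$columns_names
    columns <- data.frame(variable = sub("@d[0-9.]+$", "", nm),
                          day = as.numeric(sub("^.*@d", "", nm)))
  }
  sig <- model$vip >= vip_threshold
  keep <- !columns$variable %in% exclude
  tab <- stats::aggregate(
    data.frame(coef_sum = ifelse(sig, model$b, 0)[keep],
               n_significant = as.integer(sig)[keep]),
    by = list(variable = columns$variable[keep]), FUN = sum)
  tab <- tab[tab$n_significant > 0, , drop = FALSE]
  if (!nrow(tab)) {
    warning("no column passes the VIP threshold; empty ranking")
    return(structure(data.frame(variable = character(), coef_sum = numeric(),
                                n_significant = integer(), rank = integer()),
                     class = c("nutrient_ranking", "data.frame")))
  }
  ord <- if (by == "signed")
    order(tab$coef_sum, tab$variable)
  else
    order(-abs(tab$coef_sum), tab$variable)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, class = c("nutrient_ranking", "data.frame"))
}
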