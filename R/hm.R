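#' Ordinary least squares fit with QSAR summary statistics
#'
#' Fits `y ~ intercept + X` and reports the statistics the heuristic model
#' search ranks by: R-squared, residual variance S^2 = RSS/(n-k-1), the
#' overall F statistic and per-coefficient t values.
#'
#' A zero-variance response yields R^2 = 0 (with a warning) rather than 0/0.
#'
#' @param X Numeric matrix or data.frame of descriptors (n x k, named
#'   columns).
#' @param y Numeric response vector, length n.
#' @return Object of class `linear_model`: list with `descriptors`,
#'   `coefficients`, `intercept`, `fitted`, `residuals`, `r2`, `s2`, `f`,
#'   `t_values`, `n`, `k`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (n <= k + 1L) stop("need n > k + 1 observations for the fit")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  Xd <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) stop("rank-deficient descriptor matrix")
  coef <- qr.coef(qr_x, y)
  fitted <- drop(Xd %*% coef)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) {
    warning("zero-variance response: R^2 defined as 0")
    r2 <- 0
  } else r2 <- 1 - rss / tss
  s2 <- rss / (n - k - 1L)
  f <- if (tss <= 0 || rss == 0 && tss == 0) NA_real_
       else ((tss - rss) / k) / (rss / (n - k - 1L))
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(xtx_inv), 0) * s2)
  tv <- ifelse(se > 0, coef / se, Inf * sign(coef))
  structure(list(descriptors = colnames(X),
                 coefficients = stats::setNames(coef[-1L], colnames(X)),
                 intercept = unname(coef[1L]),
                 fitted = fitted, residuals = resid,
                 r2 = r2, s2 = s2, f = f,
                 t_values = stats::setNames(tv, colnames(Xd)),
                 n = n, k = k),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat("<linear_model> ", x$k, " descriptor(s), n = ", x$n, "\n", sep = "")
  cat("  intercept ", format(x$intercept, digits = 6), "\n", sep = "")
  for (d in x$descriptors)
    cat("  ", d, " = ", format(x$coefficients[[d]], digits = 6),
        " (t = ", format(x$t_values[[d]], digits = 4), ")\n", sep = "")
  cat("  R2 = ", format(x$r2, digits = 4), ", S2 = ",
      format(x$s2, digits = 4), ", F = ", format(x$f, digits = 5),
      if (!is.null(x$r2cv)) paste0(", R2cv = ", format(x$r2cv, digits = 4)),
      "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted linear model
#' @param object A `linear_model`.
#' @param newdata Matrix or data.frame carrying the model's descriptor
#'   columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.linear_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$descriptors, drop = FALSE])
  drop(object$intercept + X %*% object$coefficients)
}

#' Leave-one-out cross-validated R-squared
#'
#' `R2cv = 1 - PRESS/TSS` where PRESS accumulates squared leave-one-out
#' prediction errors.  Computed through the hat-matrix identity
#' `e_(i) = e_i / (1 - h_ii)`, which agrees with n explicit refits to
#' numerical precision.
#'
#' @inheritParams fit_ols
#' @return Numeric R2cv (at most 1; can be negative).
#' @export
loo_r2cv <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (n < k + 3L) stop("need n >= k + 3 observations for leave-one-out")
  Xd <- cbind(1, X)
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) stop("rank-deficient descriptor matrix")
  resid <- y - drop(Xd %*% qr.coef(qr_x, y))
  h <- rowSums(qr.Q(qr_x)^2)
  if (any(h >= 1 - 1e-12))
    stop("leverage 1 observation: leave-one-out prediction undefined")
  press <- sum((resid / (1 - h))^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("zero-variance response")
  1 - press / tss
}

#' Heuristic search configuration
#'
#' @param max_size Largest model size explored (default 5).
#' @param cap Pairwise collinearity cap: two descriptors with absolute
#'   Pearson correlation above this value are never co-selected (default
#'   0.8, the conventional independence criterion).
#' @param t_min Minimum absolute t value a candidate's coefficient must reach
#'   in the trial fit to be admissible (default 0 = off).
#' @param prefilter_t One-parameter t threshold used by [prefilter()]
#'   (default 1).
#' @param delta_r2 Diminishing-returns threshold for [choose_model_size()]
#'   (default 0.02).
#' @return List of class `hm_config`.
#' @export
hm_config <- function(max_size = 5L, cap = 0.8, t_min = 0,
                      prefilter_t = 1, delta_r2 = 0.02) {
  if (max_size < 1L) stop("max_size must be >= 1")
  if (cap <= 0 || cap > 1) stop("cap must be in (0, 1]")
  structure(list(max_size = as.integer(max_size), cap = cap, t_min = t_min,
                 prefilter_t = prefilter_t, delta_r2 = delta_r2),
            class = "hm_config")
}

#' Pre-screen a descriptor matrix
#'
#' Drops constant columns, columns containing missing values, and columns
#' whose one-parameter regression t value falls below the threshold — the
#' cheap screening pass applied before the stepwise search.
#'
#' @param X Descriptor matrix or data.frame (named columns).
#' @param y Response vector.
#' @param t_min One-parameter |t| threshold (default 1).
#' @return The reduced matrix (same type as a matrix), with attribute
#'   `dropped` naming the removed columns.
#' @export
prefilter <- function(X, y, t_min = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    if (anyNA(xj) || stats::sd(xj) == 0) next
    t_j <- abs(fit_ols(X[, j, drop = FALSE], y)$t_values[[2L]])
    keep[j] <- t_j >= t_min
  }
  if (!any(keep)) stop("prefilter dropped every column")
  out <- X[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(X)[!keep]
  out
}

#' Stepwise heuristic model search
#'
#' CODESSA-style forward search: the best descriptor pair by R^2 among all
#' pairs passing the pairwise collinearity cap is found first; descriptors
#' not yet in use are then added greedily, each step taking the single
#' descriptor that maximises R^2 subject to the cap (against every selected
#' descriptor) and the t-significance threshold, until `max_size`.  The best
#' model of every size is recorded together with its R^2, R2cv and S^2.
#'
#' Ties in R^2 are broken by the larger minimum absolute coefficient t value,
#' then by column order, so the search is deterministic.
#'
#' @param X Descriptor matrix (pre-screened; see [prefilter()]).
#' @param y Response vector.
#' @param config An [hm_config()].
#' @return Object of class `hm_trace`: list of per-size records
#'   (`size`, `descriptors`, `model`, `r2`, `r2cv`, `s2`), plus the
#'   configuration.
#' @export
heuristic_search <- function(X, y, config = hm_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop("need at least two descriptors to search")
  if (n <= config$max_size + 2L)
    stop("too few observations for max_size = ", config$max_size)
  cmat <- abs(stats::cor(X))
  admissible_pair <- function(i, j) cmat[i, j] <= config$cap
  score <- function(cols) {
    m <- tryCatch(fit_ols(X[, cols, drop = FALSE], y),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    tmin <- min(abs(m$t_values[-1L]))
    if (config$t_min > 0 && tmin < config$t_min) return(NULL)
    list(model = m, r2 = m$r2, tmin = tmin)
  }
  better <- function(a, b) {           # is candidate a better than incumbent b?
    if (is.null(b)) return(TRUE)
    if (a$r2 > b$r2 + 1e-12) return(TRUE)
    if (a$r2 < b$r2 - 1e-12) return(FALSE)
    a$tmin > b$tmin + 1e-12            # tie in R2: larger min |t| wins
  }
  # stage 1: best admissible pair
  best <- NULL; best_cols <- NULL
  for (i in seq_len(p - 1L)) for (j in seq.int(i + 1L, p)) {
    if (!admissible_pair(i, j)) next
    sc <- score(c(i, j))
    if (!is.null(sc) && better(sc, best)) { best <- sc; best_cols <- c(i, j) }
  }
  if (is.null(best))
    stop("no admissible descriptor pair under the collinearity cap")
  trace <- list(make_trace_entry(best$model, X, y, best_cols))
  # stage 2: greedy forward additions
  cols <- best_cols
  while (length(cols) < config$max_size) {
    cand_best <- NULL; cand_col <- NULL
    for (j in setdiff(seq_len(p), cols)) {
      if (any(cmat[j, cols] > config$cap)) next
      sc <- score(c(cols, j))
      if (!is.null(sc) && better(sc, cand_best)) {
        cand_best <- sc; cand_col <- j
      }
    }
    if (is.null(cand_best)) break
    cols <- c(cols, cand_col)
    trace[[length(trace) + 1L]] <- make_trace_entry(cand_best$model, X, y, cols)
  }
  structure(list(steps = trace, config = config,
                 descriptor_names = colnames(X)),
            class = "hm_trace")
}

make_trace_entry <- function(model, X, y, cols) {
  model$r2cv <- tryCatch(loo_r2cv(X[, cols, drop = FALSE], y),
                         error = function(e) NA_real_)
  list(size = length(cols), descriptors = colnames(X)[cols],
       columns = cols, model = model, r2 = model$r2, r2cv = model$r2cv,
       s2 = model$s2)
}

#' @export
print.hm_trace <- function(x, ...) {
  cat("<hm_trace> best model per size:\n")
  for (st in x$steps)
    cat(sprintf("  size %d: R2 = %.4f, R2cv = %.4f, S2 = %.4g  [%s]\n",
                st$size, st$r2, st$r2cv, st$s2,
                paste(st$descriptors, collapse = ", ")))
  invisible(x)
}

#' Pairwise correlation table of a model's descriptors
#'
#' The multicollinearity check reported alongside the selected model: Pearson
#' correlations between every pair of selected descriptors (values below the
#' cap, conventionally 0.8, indicate the descriptors act independently).
#'
#' @param model A `linear_model` (or character vector of descriptor names).
#' @param X The descriptor matrix the model was fitted on.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_table <- function(model, X) {
  sel <- if (inherits(model, "linear_model")) model$descriptors
         else as.character(model)
  X <- as.data.frame(X)
  missing_cols <- setdiff(sel, names(X))
  if (length(missing_cols) > 0L)
    stop("descriptor(s) absent from matrix: ",
         paste(missing_cols, collapse = ", "))
  stats::cor(as.matrix(X[, sel, drop = FALSE]))
}

#' Recommend a model size from a search trace
#'
#' Scans the per-size best-R^2 trace and recommends the smallest size after
#' which the R^2 gain drops below `delta_r2` — the diminishing-returns rule
#' used to stop growing the stepwise model.  The full trace remains available
#' for user override.
#'
#' @param trace An `hm_trace`.
#' @param delta_r2 Gain threshold (default from the trace's config).
#' @return Integer recommended size.
#' @export
choose_model_size <- function(trace, delta_r2 = NULL) {
  stopifnot(inherits(trace, "hm_trace"))
  if (is.null(delta_r2)) delta_r2 <- trace$config$delta_r2
  r2 <- vapply(trace$steps, `[[`, 0, "r2")
  sizes <- vapply(trace$steps, `[[`, 0L, "size")
  if (length(r2) < 2L) return(sizes[length(sizes)])
  gains <- diff(r2)
  below <- which(gains < delta_r2)
  if (length(below) == 0L) return(sizes[length(sizes)])
  sizes[below[1L]]
}

#' Coefficients of the published five-descriptor activity model
#'
#' The reference multilinear model for VEGFR3 inhibitory activity over the
#' descriptors MREB (maximum C-H resonance energy), NN (nitrogen count),
#' YZS/YZR (shadow ratio), MPCO(ZPC) (minimum oxygen partial charge) and
#' MSEC (minimum carbon atomic state energy).
#'
#' @return Named numeric vector with `intercept` and the five coefficients.
#' @export
hm_published_coefficients <- function() {
  c(intercept = 49.779, MREB = -4.0867, NN = 6.6215e-2,
    YZS_YZR = 6.3779, MPCO_ZPC = 3.7446, MSEC = -1.0425e-1)
}

#' Evaluate the published five-descriptor linear model
#'
#' @param mreb,nn,yzs_yzr,mpco,msec Descriptor values (vectors recycle in the
#'   usual way).
#' @return Predicted activity (LogIC50 scale of the reference model).
#' @examples
#' hm_published_predict(0, 0, 0, 0, 0)  # intercept: 49.779
#' @export
hm_published_predict <- function(mreb, nn, yzs_yzr, mpco, msec) {
  b <- hm_published_coefficients()
  stopifnot(all(is.finite(c(mreb, nn, yzs_yzr, mpco, msec))))
  b[["intercept"]] + b[["MREB"]] * mreb + b[["NN"]] * nn +
    b[["YZS_YZR"]] * yzs_yzr + b[["MPCO_ZPC"]] * mpco + b[["MSEC"]] * msec
}
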