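## Questionnaire scale construction and the moderation analysis.

#' Cronbach's alpha
#'
#' `alpha = (k/(k-1)) (1 - sum(item variances) / variance(total))`.
#'
#' @param items Subjects x items numeric matrix (already reverse-scored
#'   as needed).
#' @return Scalar alpha (can be negative; at most 1).
#' @export
cronbach_alpha <- function(items) {
  k <- ncol(items)
  if (k < 2) return(NA_real_)
  tot <- rowSums(items)
  vt <- stats::var(tot)
  if (vt == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / vt)
}

#' Construct questionnaire scales by varimax-rotated PCA
#'
#' Principal components of the item correlation matrix are varimax
#' rotated; each item is assigned to the factor carrying its largest
#' absolute loading, provided it exceeds `loading_threshold`, with the
#' loading sign marking reverse-scored items.  Scale scores are means of
#' the signed items (reverse scoring as `max + min - x` on the Likert
#' range); Cronbach's alpha is reported per scale.
#'
#' @param items Subjects x items matrix of Likert responses (1-5).
#' @param n_factors Number of factors to extract (default 4).
#' @param loading_threshold Minimum absolute loading for assignment
#'   (default 0.3).
#' @param likert_range Response range used for reverse scoring
#'   (default `c(1, 5)`).
#' @return Object of class `dmn_scale_set`: per scale the member items,
#'   reverse flags, subject scores and alpha, plus the rotated loading
#'   matrix.
#' @export
construct_scales <- function(items, n_factors = 4,
                             loading_threshold = 0.3,
                             likert_range = c(1, 5)) {
  items <- as.matrix(items)
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (nrow(items) <= ncol(items))
    warning("fewer subjects than items; loadings may be unstable")
  if (is.null(colnames(items)))
    colnames(items) <- sprintf("item%02d", seq_len(ncol(items)))
  R <- stats::cor(items)
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(n_factors)], 0)), n_factors)
  rot <- stats::varimax(L)
  L <- unclass(rot$loadings)
  rownames(L) <- colnames(items)
  ## deterministic factor signs: make each factor's largest loading +
  fs <- vapply(seq_len(n_factors), function(j)
    sign(L[which.max(abs(L[, j])), j]), 0)
  L <- sweep(L, 2, ifelse(fs == 0, 1, fs), "*")
  best <- apply(abs(L), 1, which.max)
  maxl <- abs(L)[cbind(seq_len(nrow(L)), best)]
  assigned <- maxl >= loading_threshold
  scales <- vector("list", n_factors)
  for (f in seq_len(n_factors)) {
    member <- which(best == f & assigned)
    if (!length(member)) {
      warning("factor ", f, " has no items above the loading threshold")
      scales[[f]] <- list(items = integer(0), reversed = logical(0),
                          scores = rep(NA_real_, nrow(items)),
                          alpha = NA_real_)
      next
    }
    rev_ <- L[member, f] < 0
    sc <- items[, member, drop = FALSE]
    sc[, rev_] <- sum(likert_range) - sc[, rev_, drop = FALSE]
    scales[[f]] <- list(items = member,
                        item_names = colnames(items)[member],
                        reversed = rev_,
                        scores = rowMeans(sc),
                        alpha = cronbach_alpha(sc))
  }
  names(scales) <- sprintf("factor%d", seq_len(n_factors))
  structure(list(scales = scales, loadings = L,
                 n_factors = n_factors,
                 loading_threshold = loading_threshold),
            class = "dmn_scale_set")
}

#' @export
print.dmn_scale_set <- function(x, ...) {
  for (nm in names(x$scales)) {
    s <- x$scales[[nm]]
    cat(sprintf("%s: %d items, alpha = %.3f\n", nm, length(s$items),
                s$alpha))
  }
  invisible(x)
}

.zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance variable; z-score undefined")
  (x - mean(x)) / s
}

#' Hierarchical moderated regression
#'
#' All continuous variables are z-scored; step 1 regresses the outcome
#' on the factor and the moderator, step 2 adds their product (formed
#' from the z-scored variables and not re-standardized).  Reports
#' coefficients with SE, t, df and p for both steps, and the R-squared
#' increment of the interaction step.
#'
#' @param y Outcome vector.
#' @param x Factor of interest (e.g. the posterior-vs-anterior network
#'   score).
#' @param m Moderator (e.g. an extraversion facet).
#' @return Object of class `dmn_moderation`: `step1`, `step2`
#'   (coefficient data.frames), `delta_r2`, `r2_step1`, `r2_step2`,
#'   `df`, `n`, `vcov2`.
#' @export
hierarchical_moderation <- function(y, x, m) {
  n <- length(y)
  if (length(x) != n || length(m) != n) stop("length mismatch")
  if (n < 10) stop("need n >= 10")
  zy <- .zscore(y); zx <- .zscore(x); zm <- .zscore(m)
  xm <- zx * zm
  X1 <- cbind(`(Intercept)` = 1, x = zx, m = zm)
  X2 <- cbind(X1, x_m = xm)
  if (kappa(crossprod(X2)) > 1e10)
    stop("collinear predictors (condition number > 1e10)")
  fit <- function(X) {
    co <- solve(crossprod(X), crossprod(X, zy))
    res <- zy - X %*% co
    df <- n - ncol(X)
    s2 <- sum(res^2) / df
    vc <- s2 * solve(crossprod(X))
    se <- sqrt(diag(vc))
    tt <- drop(co) / se
    p <- 2 * stats::pt(-abs(tt), df)
    p[s2 < 1e-24] <- 0          # perfect-fit guard: t -> infinity
    r2 <- 1 - sum(res^2) / sum((zy - mean(zy))^2)
    list(coef = data.frame(term = colnames(X), B = drop(co), SE = se,
                           T = tt, df = df, p = p,
                           stringsAsFactors = FALSE),
         r2 = r2, vcov = vc, df = df)
  }
  f1 <- fit(X1)
  f2 <- fit(X2)
  structure(list(step1 = f1$coef, step2 = f2$coef,
                 r2_step1 = f1$r2, r2_step2 = f2$r2,
                 delta_r2 = f2$r2 - f1$r2,
                 df = f2$df, n = n, vcov2 = f2$vcov),
            class = "dmn_moderation")
}

#' @export
print.dmn_moderation <- function(x, ...) {
  cat(sprintf("Hierarchical moderation, n = %d\n", x$n))
  cat("Step 2 (with interaction):\n")
  print(x$step2, row.names = FALSE, digits = 3)
  cat(sprintf("delta R^2 = %.4f\n", x$delta_r2))
  invisible(x)
}

#' Simple slopes of the factor at fixed moderator values
#'
#' `slope(m0) = B_x + B_int * m0` with delta-method standard errors from
#' the step-2 covariance matrix.
#'
#' @param res A `dmn_moderation` result.
#' @param at_sd Moderator values (in SD units) at which to evaluate
#'   (default `c(0.5, -0.5)`).
#' @return data.frame with `at`, `slope`, `SE`, `T`, `df`, `p`.
#' @export
simple_slopes <- function(res, at_sd = c(0.5, -0.5)) {
  stopifnot(inherits(res, "dmn_moderation"))
  b <- res$step2$B
  names(b) <- res$step2$term
  vc <- res$vcov2
  out <- lapply(at_sd, function(m0) {
    sl <- b[["x"]] + b[["x_m"]] * m0
    v <- vc["x", "x"] + m0^2 * vc["x_m", "x_m"] + 2 * m0 * vc["x", "x_m"]
    se <- sqrt(v)
    tt <- sl / se
    data.frame(at = m0, slope = sl, SE = se, T = tt, df = res$df,
               p = 2 * stats::pt(-abs(tt), res$df))
  })
  do.call(rbind, out)
}

#' Correlations within high and low moderator subgroups
#'
#' Pearson correlations (with two-sided p) between the outcome and each
#' network score, within the subgroups of subjects whose z-scored
#' moderator exceeds `+threshold_sd` (high) or falls below
#' `-threshold_sd` (low), by strict inequality.
#'
#' @param outcome Outcome vector.
#' @param moderator Moderator vector.
#' @param scores Named list (or data.frame) of score vectors, e.g.
#'   `list(PDMN = ..., ADMN = ...)`.
#' @param threshold_sd Subgroup threshold in SD units (default 0.5).
#' @return data.frame with `group`, `score`, `r`, `p`, `n`; constant
#'   outcome or score within a subgroup yields NA with a warning.
#' @export
subgroup_correlations <- function(outcome, moderator, scores,
                                  threshold_sd = 0.5) {
  zm <- .zscore(moderator)
  groups <- list(high = zm > threshold_sd, low = zm < -threshold_sd)
  out <- NULL
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (sum(sel) < 3)
      stop("subgroup '", g, "' has fewer than 3 subjects")
    for (s in names(scores)) {
      yv <- outcome[sel]; xv <- scores[[s]][sel]
      if (stats::sd(yv) == 0 || stats::sd(xv) == 0) {
        warning("constant values in subgroup '", g, "' for ", s)
        row <- data.frame(group = g, score = s, r = NA_real_,
                          p = NA_real_, n = sum(sel))
      } else {
        ct <- stats::cor.test(xv, yv)
        row <- data.frame(group = g, score = s, r = unname(ct$estimate),
                          p = ct$p.value, n = sum(sel))
      }
      out <- rbind(out, row)
    }
  }
  out
}
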