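#' Mixed-design type-III ANOVA with subject nested in group
#'
#' Classical univariate repeated-measures ANOVA for designs with one
#' optional between-subject factor (e.g. group) and one or more
#' within-subject factors (e.g. hemisphere, condition), with a random
#' factor of subject nested within group. Between-subject effects are
#' tested against the Subject(Group) mean square; each within-subject
#' effect and its interaction with group are tested against the
#' corresponding Within x Subject(Group) mean square. Sums of squares are
#' type III (unweighted means under sum-to-zero contrasts), so unequal
#' group sizes are handled; within-subject cells must be complete per
#' subject (one observation per cell).
#'
#' @param data Long-format data.frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject id column.
#' @param within Character vector of within-subject factor column names.
#' @param between Optional name of the between-subject factor column.
#' @param drop_incomplete If `TRUE`, subjects missing any within cell are
#'   dropped (with a message); otherwise missing cells are an error naming
#'   the cell.
#' @return Data.frame of class `anova_table`: one row per fixed effect with
#'   `term`, `ss`, `df`, `error_term`, `error_ss`, `error_df`, `F`, `p`.
#'   The significance level used throughout the package is 0.05.
#' @examples
#' d <- expand.grid(subject = paste0("s", 1:6), condition = c("a", "b"))
#' d$value <- rnorm(nrow(d)) + (d$condition == "b")
#' mixed_anova_type3(d, dv = "value", subject = "subject", within = "condition")
#' @export
mixed_anova_type3 <- function(data, dv, subject, within, between = NULL,
                              drop_incomplete = FALSE) {
  stopifnot(is.data.frame(data), length(within) >= 1)
  for (col in c(dv, subject, within, between))
    if (!col %in% names(data)) stop(sprintf("column '%s' not found", col))
  data[[subject]] <- as.character(data[[subject]])
  if (!is.null(between)) {
    gmap <- unique(data[, c(subject, between)])
    dup <- gmap[[subject]][duplicated(gmap[[subject]])]
    if (length(dup))
      stop(sprintf("subject(s) %s appear in more than one %s",
                   paste(unique(dup), collapse = ", "), between))
  }
  lev <- lapply(within, function(w) sort(unique(as.character(data[[w]]))))
  names(lev) <- within
  cells <- expand.grid(lev, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_key <- do.call(paste, c(cells, sep = "\r"))
  data_key <- do.call(paste, c(lapply(within, function(w) as.character(data[[w]])),
                               list(sep = "\r")))
  subj <- sort(unique(data[[subject]]))
  M <- matrix(NA_real_, length(subj), nrow(cells),
              dimnames = list(subj, cell_key))
  for (r in seq_len(nrow(data))) {
    i <- match(data[[subject]][r], subj); j <- match(data_key[r], cell_key)
    if (!is.na(M[i, j]))
      stop(sprintf("duplicate observation for subject %s in cell (%s)",
                   subj[i], gsub("\r", ", ", cell_key[j])))
    M[i, j] <- data[[dv]][r]
  }
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)
    if (drop_incomplete) {
      drop <- unique(rownames(M)[bad[, 1]])
      message(sprintf("dropping %d subject(s) with incomplete cells: %s",
                      length(drop), paste(drop, collapse = ", ")))
      M <- M[!rownames(M) %in% drop, , drop = FALSE]
      subj <- rownames(M)
      if (nrow(M) < 2) stop("fewer than 2 complete subjects remain")
    } else {
      stop(sprintf("empty cell: subject %s, cell (%s)",
                   rownames(M)[bad[1, 1]], gsub("\r", ", ", cell_key[bad[1, 2]])))
    }
  }
  G <- NULL
  if (!is.null(between)) {
    gmap <- unique(data[, c(subject, between)])
    G <- factor(gmap[[between]][match(subj, gmap[[subject]])])
    if (any(table(G) < 2)) stop("need >= 2 subjects per group")
  }

  # orthonormal basis per factor: Q (levels x levels-1, columns _|_ 1) for
  # factors in the effect, normalized unit vector for averaged-over factors
  ortho_contrast <- function(l) {
    qr.Q(qr(cbind(rep(1, l), stats::contr.helmert(l))))[, -1, drop = FALSE]
  }
  unit_vec <- function(l) matrix(rep(1 / sqrt(l), l), ncol = 1)

  # contrast matrix over within cells for one effect subset; expand.grid
  # orders cells with the first factor varying fastest, so the kronecker
  # product runs from the last factor outward
  build_C <- function(in_effect) {
    Bs <- lapply(within, function(f) {
      if (f %in% in_effect) ortho_contrast(length(lev[[f]])) else
        unit_vec(length(lev[[f]]))
    })
    # expand.grid: first factor varies fastest -> kron(B_k, ..., B_1)
    C <- Bs[[length(Bs)]]
    if (length(Bs) > 1)
      for (k in rev(seq_len(length(Bs) - 1))) C <- C %x% Bs[[k]]
    C
  }

  n_subj <- nrow(M)
  g <- if (is.null(G)) 1L else nlevels(G)
  rows <- list()
  add_row <- function(term, ss, df, err_term, err_ss, err_df) {
    Fv <- (ss / df) / (err_ss / err_df)
    rows[[length(rows) + 1]] <<- data.frame(
      term = term, ss = ss, df = df, error_term = err_term,
      error_ss = err_ss, error_df = err_df, F = Fv,
      p = stats::pf(Fv, df, err_df, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }

  # between-subject stratum
  y_between <- as.numeric(M %*% build_C(character(0)))
  subj_err_name <- if (is.null(between)) "subject" else
    sprintf("subject(%s)", between)
  if (!is.null(between)) {
    fit <- stats::lm(y_between ~ G,
                     contrasts = list(G = stats::contr.sum))
    a3 <- car::Anova(fit, type = "III")
    ss_g <- a3["G", "Sum Sq"]; df_g <- a3["G", "Df"]
    ss_s <- a3["Residuals", "Sum Sq"]; df_s <- a3["Residuals", "Df"]
    add_row(between, ss_g, df_g, subj_err_name, ss_s, df_s)
  } else {
    ss_s <- sum((y_between - mean(y_between))^2); df_s <- n_subj - 1
  }

  # within-subject strata: every non-empty subset of within factors
  subsets <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  for (E in subsets) {
    S <- M %*% build_C(E)
    d_E <- ncol(S)
    if (!is.null(between)) {
      ss_eff <- 0; ss_int <- 0; ss_err <- 0
      for (j in seq_len(d_E)) {
        fit <- stats::lm(S[, j] ~ G,
                         contrasts = list(G = stats::contr.sum))
        a3 <- car::Anova(fit, type = "III")
        ss_eff <- ss_eff + a3["(Intercept)", "Sum Sq"]
        ss_int <- ss_int + a3["G", "Sum Sq"]
        ss_err <- ss_err + a3["Residuals", "Sum Sq"]
      }
      err_name <- sprintf("%s:subject(%s)", paste(E, collapse = ":"), between)
      err_df <- d_E * (n_subj - g)
      add_row(paste(E, collapse = ":"), ss_eff, d_E, err_name, ss_err, err_df)
      add_row(paste(c(between, E), collapse = ":"), ss_int, d_E * (g - 1),
              err_name, ss_err, err_df)
    } else {
      ss_eff <- sum(colMeans(S)^2) * n_subj
      ss_err <- sum(sweep(S, 2, colMeans(S))^2)
      err_name <- sprintf("%s:subject", paste(E, collapse = ":"))
      add_row(paste(E, collapse = ":"), ss_eff, d_E, err_name, ss_err,
              d_E * (n_subj - 1))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("anova_table", "data.frame")
  attr(out, "alpha") <- 0.05
  out
}

#' Correlation with optional covariates
#'
#' Pearson, Spearman (Pearson on mid-ranks), or partial Spearman
#' (rank-transform all variables, residualize `x` and `y` on the covariates,
#' then correlate the residuals). Two-sided p values; for partial
#' correlations the t test uses `n - 2 - k` degrees of freedom with `k`
#' covariates. Which method fits a given pair of variables is the caller's
#' choice (e.g. rank-based methods for bounded variables such as percent
#' spared).
#'
#' @param x,y Numeric vectors of equal length (pairwise-complete rows with
#'   any covariates are used).
#' @param method `"pearson"`, `"spearman"`, or `"partial_spearman"`.
#' @param covariates Optional numeric vector, matrix, or data.frame of
#'   control variables (required for `"partial_spearman"`; allowed with
#'   `"pearson"` for a partial Pearson correlation).
#' @return List of class `correlation_result`: `estimate`, `p`, `n`,
#'   `method`, `covariates` (count).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman", "partial_spearman"),
                      covariates = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  Z <- NULL
  if (!is.null(covariates)) {
    Z <- as.matrix(as.data.frame(covariates))
    if (nrow(Z) != length(x)) stop("covariates must match `x` length")
  }
  if (method == "partial_spearman" && is.null(Z))
    stop("partial_spearman requires covariates")
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(Z)) keep <- keep & apply(Z, 1, function(r) all(is.finite(r)))
  x <- x[keep]; y <- y[keep]; if (!is.null(Z)) Z <- Z[keep, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n < 3 + k) stop("too few complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a correlated variable")
  if (method %in% c("spearman", "partial_spearman")) {
    x <- rank(x); y <- rank(y)
    if (!is.null(Z)) Z <- apply(Z, 2, rank)
  }
  if (is.null(Z)) {
    ct <- stats::cor.test(x, y, method = "pearson")
    res <- list(estimate = unname(ct$estimate), p = ct$p.value, n = n,
                method = method, covariates = 0L)
  } else {
    rx <- stats::resid(stats::lm(x ~ Z))
    ry <- stats::resid(stats::lm(y ~ Z))
    r <- stats::cor(rx, ry)
    df <- n - 2 - k
    tval <- r * sqrt(df / (1 - r^2))
    res <- list(estimate = r, p = 2 * stats::pt(-abs(tval), df), n = n,
                method = method, covariates = k)
  }
  structure(res, class = "correlation_result")
}

#' One- and two-sample t tests with degenerate-variance guards
#'
#' Two-sample tests use the pooled equal-variance form by default (Welch via
#' `var_equal = FALSE`); one-sample tests compare the mean against `mu`;
#' `paired = TRUE` tests the pairwise differences. All p values are
#' two-tailed. Zero-variance data with equal means yield `t = 0, p = 1`;
#' zero variance with unequal means is an explicit error rather than an
#' infinite statistic.
#'
#' @param a Numeric vector.
#' @param b Optional second sample.
#' @param paired Pair `a` and `b` (requires equal lengths).
#' @param mu Null value for the (one-sample) mean (default 0).
#' @param var_equal Use the pooled-variance two-sample form (default TRUE).
#' @return List: `statistic`, `df`, `p`, `estimate` (mean or mean
#'   difference), `method`.
#' @export
t_tests <- function(a, b = NULL, paired = FALSE, mu = 0, var_equal = TRUE) {
  a <- a[is.finite(a)]
  if (!is.null(b)) b <- b[is.finite(b)]
  if (paired) {
    if (is.null(b) || length(a) != length(b))
      stop("paired test requires two equal-length samples")
    a <- a - b; b <- NULL
  }
  if (is.null(b)) {
    if (length(a) < 2) stop("need n >= 2")
    if (stats::sd(a) == 0) {
      if (mean(a) == mu)
        return(list(statistic = 0, df = length(a) - 1, p = 1,
                    estimate = mean(a), method = "one-sample"))
      stop("zero variance with mean != mu: t undefined")
    }
    tt <- stats::t.test(a, mu = mu)
    return(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, estimate = unname(tt$estimate),
                method = if (paired) "paired" else "one-sample"))
  }
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per sample")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2, p = 1,
                  estimate = 0, method = "two-sample"))
    stop("zero variance with unequal means: t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, estimate = unname(diff(rev(tt$estimate))),
       method = if (var_equal) "two-sample" else "welch")
}

#' Pure-tone average (PTA)
#'
#' The mean audiometric threshold at 500, 1000, and 2000 Hz, per ear, in dB
#' HL — a summary of hearing sensitivity in the speech range.
#'
#' @param thresholds Data.frame with columns `ear`, `freq_hz`, `db_hl`.
#' @param freqs Frequencies entering the average (default
#'   `c(500, 1000, 2000)`).
#' @return Named numeric vector: PTA per ear.
#' @export
pure_tone_average <- function(thresholds, freqs = c(500, 1000, 2000)) {
  need <- c("ear", "freq_hz", "db_hl")
  if (!all(need %in% names(thresholds)))
    stop("thresholds must have columns ear, freq_hz, db_hl")
  ears <- unique(thresholds$ear)
  out <- vapply(ears, function(e) {
    d <- thresholds[thresholds$ear == e, ]
    vals <- vapply(freqs, function(f) {
      v <- d$db_hl[d$freq_hz == f]
      if (length(v) != 1 || !is.finite(v))
        stop(sprintf("missing %d Hz threshold for %s ear", f, e))
      v
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  stats::setNames(out, ears)
}
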