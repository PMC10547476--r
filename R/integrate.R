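# Z-score / Pearson integration of animal-level Ca2+ parameters with a
# protein abundance matrix, candidate flagging at the |r| >= 0.5 / >= 3
# focus-parameter rule, and strain/sex term-effect statistics. Sample SD
# (n - 1) throughout; correlations are pairwise-complete.

#' Z-score a trait column
#'
#' `z = (x - mu) / sigma` with the sample mean and sample SD (n - 1) over the
#' non-missing values; missing values stay missing. A constant column cannot
#' be scored: it is skipped with a warning (all-`NA` result).
#'
#' @param x Numeric vector with at least 2 non-missing values.
#' @return Numeric vector of Z-scores.
#' @export
zscore <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("zscore needs at least 2 non-missing values")
  s <- stats::sd(x[ok])
  if (s == 0) {
    warning("constant column skipped in Z-scoring")
    return(rep(NA_real_, length(x)))
  }
  (x - mean(x[ok])) / s
}

#' Rank-based normal-scores transform
#'
#' Maps ranks (ties averaged) to normal quantiles at offset-0.5 plotting
#' positions, `qnorm((rank - 0.5) / n)`, then rescales so the output keeps the
#' input's sample mean and variance. Strictly monotone in the input; missing
#' values stay missing.
#'
#' @param x Numeric vector with at least 3 non-missing values.
#' @return Transformed vector.
#' @export
normal_scores <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3L) stop("normal_scores needs at least 3 non-missing values")
  q <- stats::qnorm((rank(x[ok], ties.method = "average") - 0.5) / n)
  sq <- stats::sd(q)
  out <- x
  out[ok] <- if (sq > 0) (q - mean(q)) * stats::sd(x[ok]) / sq + mean(x[ok])
             else mean(x[ok])
  out
}

#' Pearson correlation (CORREL form), pairwise complete
#'
#' `r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2) *
#' sum((y - mean(y))^2))` over the pairwise-complete observations. Fewer than
#' 3 complete pairs, or a constant argument on the complete set, yields `NA`;
#' the number of pairs used is attached as attribute `n_used`.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation coefficient in \[-1, 1\] with attribute `n_used`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(structure(NA_real_, n_used = n))
  xx <- x[ok] - mean(x[ok])
  yy <- y[ok] - mean(y[ok])
  den <- sqrt(sum(xx^2) * sum(yy^2))
  r <- if (den == 0) NA_real_ else sum(xx * yy) / den
  structure(r, n_used = n)
}

align_on_keys <- function(a, b, align) {
  has_animal <- "animal" %in% names(a) && "animal" %in% names(b)
  if (align == "auto") {
    align <- if (has_animal &&
                 setequal(a$animal, b$animal)) "animal" else "group"
  }
  if (align == "animal") {
    if (!has_animal) stop("animal-level alignment needs an animal column in both tables")
    key_a <- a$animal; key_b <- b$animal
  } else {
    group_means <- function(df) {
      keys <- df[c("strain", "sex")]
      num <- vapply(df, is.numeric, logical(1))
      stats::aggregate(df[num], by = keys,
                       FUN = function(v) mean(v, na.rm = TRUE))
    }
    a <- group_means(a); b <- group_means(b)
    key_a <- paste(a$strain, a$sex, sep = "|")
    key_b <- paste(b$strain, b$sex, sep = "|")
  }
  shared <- intersect(key_a, key_b)
  if (!length(shared)) stop("no shared animal or strain-by-sex keys to align on")
  list(a = a[match(shared, key_a), , drop = FALSE],
       b = b[match(shared, key_b), , drop = FALSE])
}

#' Correlate Ca2+ parameters with protein abundances
#'
#' Z-scores each trait column (constant columns are skipped with a warning)
#' and computes the pairwise-complete Pearson correlation for every parameter
#' x protein pair. Rows are aligned on animal ids when both tables carry the
#' same animals, and on strain-by-sex group means otherwise (the two
#' experiments may have used different mice); `align` forces either behavior.
#'
#' @param params Data frame of key columns (`strain`, `sex`, optionally
#'   `animal`) plus numeric parameter columns (e.g. from
#'   [animal_trait_matrix()]).
#' @param proteins Data frame of the same key structure plus protein columns.
#' @param align `"auto"`, `"animal"`, or `"group"`.
#' @param scope Optional character vector of strains; the correlation is
#'   recomputed on that subset only.
#' @return Data frame of class `correlation_result`: `parameter, protein, r,
#'   n_used`.
#' @export
correlate_matrix <- function(params, proteins, align = c("auto", "animal", "group"),
                             scope = NULL) {
  align <- match.arg(align)
  if (!is.null(scope)) {
    params <- params[params$strain %in% scope, , drop = FALSE]
    proteins <- proteins[proteins$strain %in% scope, , drop = FALSE]
  }
  al <- align_on_keys(params, proteins, align)
  keys <- c("strain", "sex", "animal")
  pcols <- setdiff(names(al$a)[vapply(al$a, is.numeric, logical(1))], keys)
  qcols <- setdiff(names(al$b)[vapply(al$b, is.numeric, logical(1))], keys)
  zs <- function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 2L || stats::sd(v[ok]) == 0) return(v)  # r unaffected; avoid noise warnings
    zscore(v)
  }
  za <- lapply(al$a[pcols], zs)
  zb <- lapply(al$b[qcols], zs)
  grid <- expand.grid(parameter = pcols, protein = qcols,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rr <- mapply(function(p, q) {
    r <- pearson(za[[p]], zb[[q]])
    c(as.numeric(r), attr(r, "n_used"))
  }, grid$parameter, grid$protein)
  grid$r <- rr[1L, ]
  grid$n_used <- as.integer(rr[2L, ])
  class(grid) <- c("correlation_result", "data.frame")
  grid
}

#' Flag candidate proteins by high correlation to focus parameters
#'
#' A protein is flagged when its absolute correlation reaches `threshold`
#' (default `|r| >= 0.5`) for at least `min_params` (default 3) of the focus
#' parameters.
#'
#' @param result A `correlation_result` from [correlate_matrix()].
#' @param focus Character vector of focus parameter ids (default
#'   [default_focus_params()]).
#' @param threshold Absolute-correlation threshold (default 0.5, inclusive).
#' @param min_params Minimum number of focus parameters at or above the
#'   threshold (default 3).
#' @return Data frame: `protein_id, n_high, flagged`.
#' @export
flag_candidates <- function(result, focus = default_focus_params(),
                            threshold = 0.5, min_params = 3) {
  unknown <- setdiff(focus, unique(result$parameter))
  if (length(unknown)) {
    stop("unknown focus parameter(s): ", paste(unknown, collapse = ", "))
  }
  sub <- result[result$parameter %in% focus, , drop = FALSE]
  hi <- !is.na(sub$r) & abs(sub$r) >= threshold
  counts <- tapply(hi, sub$protein, sum)
  out <- data.frame(protein_id = names(counts),
                    n_high = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$flagged <- out$n_high >= min_params
  rownames(out) <- NULL
  out[order(out$protein_id), , drop = FALSE]
}

#' Strain/sex term-effect statistics for one trait
#'
#' Least-squares fit of `trait ~ strain * sex`. Each term's effect size is
#' sqrt(term mean square) divided by the trait's raw SD, with the p-value from
#' the term's sequential F test. The composite `signal` term is the joint F
#' test of all strain-involving terms (strain and strain:sex) against the
#' sex-only model. Terms that cannot be estimated (rank-deficient designs,
#' e.g. a single sex) are reported missing.
#'
#' @param value Numeric trait vector (animal-level).
#' @param strain,sex Matching design labels.
#' @return Data frame: `term, df, effect_sd_ratio, p_value, neg_log10_p` with
#'   rows `strain`, `sex`, `strain:sex`, `signal`.
#' @export
term_effects <- function(value, strain, sex) {
  ok <- !is.na(value)
  df0 <- data.frame(value = value[ok],
                    strain = factor(strain[ok]), sex = factor(sex[ok]))
  raw_sd <- stats::sd(df0$value)
  terms <- c("strain", "sex", "strain:sex", "signal")
  blank <- data.frame(term = terms, df = NA_real_,
                      effect_sd_ratio = NA_real_, p_value = NA_real_,
                      neg_log10_p = NA_real_, stringsAsFactors = FALSE)
  fill <- function(tab, term, df, ratio, p) {
    i <- match(term, tab$term)
    tab$df[i] <- df
    tab$effect_sd_ratio[i] <- ratio
    tab$p_value[i] <- p
    tab$neg_log10_p[i] <- -log10(p)
    tab
  }
  out <- blank
  res <- tryCatch({
    fit <- stats::lm(value ~ strain * sex, data = df0)
    av <- stats::anova(fit)
    for (tm in intersect(rownames(av), c("strain", "sex", "strain:sex"))) {
      ms <- av[tm, "Mean Sq"]
      p <- av[tm, "Pr(>F)"]
      if (is.finite(ms) && raw_sd > 0) {
        out <- fill(out, tm, av[tm, "Df"], sqrt(ms) / raw_sd, max(p, 1e-300))
      }
    }
    m0 <- stats::lm(value ~ sex, data = df0)
    cmp <- stats::anova(m0, fit)
    dfd <- cmp$Df[2L]
    if (is.finite(dfd) && dfd > 0 && is.finite(cmp$`Pr(>F)`[2L])) {
      ms <- (cmp$RSS[1L] - cmp$RSS[2L]) / dfd
      out <- fill(out, "signal", dfd, sqrt(ms) / raw_sd,
                  max(cmp$`Pr(>F)`[2L], 1e-300))
    }
    out
  }, error = function(e) {
    # fall back to a strain-only fit (e.g. a single sex level)
    tryCatch({
      fit <- stats::lm(value ~ strain, data = df0)
      av <- stats::anova(fit)
      fill(blank, "strain", av["strain", "Df"],
           sqrt(av["strain", "Mean Sq"]) / raw_sd,
           max(av["strain", "Pr(>F)"], 1e-300))
    }, error = function(e2) blank)
  })
  res
}

#' Term effects for every trait column of a matrix
#'
#' @param traits Data frame with key columns `strain`, `sex` (and optionally
#'   `animal`) plus numeric trait columns.
#' @param adjust Optional multiple-testing adjustment for the p-values across
#'   traits within each term (`"none"`, the default, or any
#'   [stats::p.adjust()] method such as `"BH"`).
#' @return Data frame: `trait_id` plus the [term_effects()] columns.
#' @export
term_effects_table <- function(traits, adjust = "none") {
  keys <- c("strain", "sex", "animal")
  cols <- setdiff(names(traits)[vapply(traits, is.numeric, logical(1))], keys)
  rows <- lapply(cols, function(cc) {
    cbind(data.frame(trait_id = cc, stringsAsFactors = FALSE),
          term_effects(traits[[cc]], traits$strain, traits$sex))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (adjust != "none") {
    for (tm in unique(out$term)) {
      i <- out$term == tm
      out$p_value[i] <- stats::p.adjust(out$p_value[i], method = adjust)
      out$neg_log10_p[i] <- -log10(out$p_value[i])
    }
  }
  out
}
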